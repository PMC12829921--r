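test_that("moment update of the frailty variance", {
  expect_equal(update_theta(rep(0, 10)), 1e-4)
  expect_equal(update_theta(c(1, -1)), 1)
  expect_error(update_theta(1), "2 clusters")
  set.seed(3)
  b <- rnorm(200, 0, sqrt(2.5))
  expect_lt(abs(update_theta(b) - 2.5), 0.5)
})

test_that("Breslow estimator matches hand computations", {
  # zero scores, no censoring, distinct times: Nelson-Aalen jumps
  n <- 7
  sc <- breslow_baseline(seq_len(n), rep(1L, n), rep(0, n))
  expect_equal(sc$values, cumsum(1 / (n:1)), tolerance = 1e-12)
  # three subjects, middle one censored
  sc3 <- breslow_baseline(c(1, 2, 3), c(1, 0, 1), c(0, 0, 0))
  expect_equal(sc3$times, c(1, 3))
  expect_equal(sc3$values, c(1 / 3, 1 / 3 + 1), tolerance = 1e-12)
  # adding a constant to all scores scales every jump by exp(-c)
  set.seed(4)
  tt <- rexp(20); ss <- rbinom(20, 1, 0.7); ss[1] <- 1
  g <- rnorm(20)
  a <- breslow_baseline(tt, ss, g)
  b <- breslow_baseline(tt, ss, g + 2)
  expect_equal(b$values, a$values * exp(-2), tolerance = 1e-10)
  # evaluation: 0 before the first jump, right continuous
  expect_equal(step_cumhaz_at(sc3, c(0.5, 1, 2.9, 3, 10)),
               c(0, 1 / 3, 1 / 3, 4 / 3, 4 / 3), tolerance = 1e-12)
})

test_that("tied event times contribute through a common risk set", {
  # times (1, 1, 2), all events, zero scores: jump 2/3 at t=1, then 1
  sc <- breslow_baseline(c(1, 1, 2), c(1, 1, 1), c(0, 0, 0))
  expect_equal(sc$times, c(1, 2))
  expect_equal(sc$values, c(2 / 3, 2 / 3 + 1), tolerance = 1e-12)
})

test_that("survival predictions follow S = exp(-Lambda0 exp(g))", {
  d <- sim_linear_clustered(8, 10, c(0.6, -0.4), theta = 0.5,
                            cens_upper = 3, seed = 21)
  fit <- fit_cox_frailty_linear(d)
  tgrid <- unname(quantile(d$time, c(0.2, 0.5, 0.8)))
  S <- predict_survival(fit, d, tgrid)
  expect_true(all(S > 0 & S <= 1))
  # nonincreasing in t per subject
  expect_true(all(S[, 1] >= S[, 2] & S[, 2] >= S[, 3]))
  # S = 1 before the first event time
  expect_equal(predict_survival(fit, d, min(fit$baseline$times) / 2)[, 1],
               rep(1, nrow(d)))
  # direct formula check
  g <- predict_risk(fit, d)
  expect_equal(S[, 2],
               exp(-step_cumhaz_at(fit$baseline, tgrid[2]) * exp(g)),
               tolerance = 1e-12)
  # exp(-0.5) when the cumulative hazard is 0.5 and the risk score 0
  expect_equal(exp(-0.5), 0.6065307, tolerance = 1e-6)
  # larger risk score gives pointwise smaller survival
  ord <- order(g)
  expect_true(all(diff(S[ord, 2]) <= 1e-12))
})

test_that("linear special case recovers a linear frailty Cox signal", {
  d <- sim_linear_clustered(50, 60, c(0.5, 0.5, 0.5), theta = 1,
                            cens_upper = 4, seed = 22)
  fit <- fit_frailty_net(d, network_config(3, integer(0), "identity", 0, 0),
                         train_config(seed = 23))
  expect_gt(cor(predict_risk(fit, d), d$risk), 0.95)
})

test_that("frailty variance estimate tracks the reference penalized fit", {
  # The alternating moment update must land in the same regime as the
  # Gaussian-frailty Cox estimate of the survival package on shared data.
  d <- simulate_clusters(scenario_config(1, theta = 2.5, n_clusters = 120,
                                         cluster_size_range = c(20, 60),
                                         seed = 44))
  ours <- fit_cox_frailty_linear(d)
  ref <- survival::coxph(
    survival::Surv(time, status) ~ m1 + m2 + m3 + m4 + m5 +
      survival::frailty(cluster, dist = "gauss"),
    data = d, ties = "breslow")
  theta_ref <- ref$history[[1]]$theta
  expect_gt(ours$state$theta, 0.5 * theta_ref)
  expect_lt(ours$state$theta, 1.5 * theta_ref)
  # and the random-effect estimates rank the clusters the same way
  expect_gt(cor(ours$state$b_hat, ref$frail), 0.99)
})

test_that("training is deterministic under a fixed seed", {
  d <- simulate_clusters(scenario_config(1, n_clusters = 20,
                                         cluster_size_range = c(8, 15),
                                         theta = 1.5, seed = 31))
  nc <- network_config(5, c(8L, 8L))
  f1 <- fit_frailty_net(d, nc, small_train_config(seed = 32, epochs = 8L))
  f2 <- fit_frailty_net(d, nc, small_train_config(seed = 32, epochs = 8L))
  expect_identical(f1$log$train_loss, f2$log$train_loss)
  expect_identical(f1$params$W, f2$params$W)
  f3 <- fit_frailty_net(d, nc, small_train_config(seed = 33, epochs = 8L))
  expect_false(identical(f1$log$train_loss, f3$log$train_loss))
})

test_that("training loss decreases over early epochs", {
  d <- simulate_clusters(scenario_config(1, n_clusters = 40,
                                         cluster_size_range = c(15, 30),
                                         theta = 1.5, seed = 41))
  fit <- fit_frailty_net(d, network_config(5, c(16L, 16L)),
                         small_train_config(seed = 42, epochs = 10L,
                                            val_fraction = 0))
  tl <- fit$log$train_loss
  expect_lt(mean(tl[8:10]), mean(tl[1:3]))
  expect_true(all(is.finite(tl)))
})

test_that("fitting without events fails loudly", {
  d <- sim_linear_clustered(4, 5, c(1), theta = 0, cens_upper = 2, seed = 51)
  d$status <- 0L
  expect_error(fit_frailty_net(d), "no events")
})

test_that("Breslow baseline is consistent for the unit exponential hazard", {
  # theta = 0, linear risk, known Lambda0(t) = t
  d <- sim_linear_clustered(100, 100, c(0.4, -0.4), theta = 0,
                            cens_upper = 4, seed = 61)
  fit <- fit_frailty_net(d, network_config(2, integer(0), "identity", 0, 0),
                         train_config(seed = 62), frailty = FALSE)
  qs <- unname(quantile(d$time[d$status == 1], seq(0.1, 0.9, 0.1)))
  est <- step_cumhaz_at(fit$baseline, qs)
  expect_true(all(abs(est / qs - 1) < 0.10))
})

test_that("no-frailty mode on independent data matches a classical Cox fit", {
  d <- sim_linear_clustered(40, 40, c(0.7, -0.7), theta = 0,
                            cens_upper = 4, seed = 71)
  sp <- split_within_cluster(d, 0.5, seed = 72)
  lin <- fit_frailty_net(sp$train,
                         network_config(2, integer(0), "identity", 0, 0),
                         train_config(seed = 73), frailty = FALSE)
  cox <- fit_cox(sp$train)
  c1 <- c_index(sp$test$time, sp$test$status, predict_risk(lin, sp$test))
  c2 <- c_index(sp$test$time, sp$test$status, predict_risk(cox, sp$test))
  expect_lt(abs(c1$c_index - c2$c_index), 0.01)
})
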