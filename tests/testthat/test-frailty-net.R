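make_net <- function(p = 3, hidden = 4L, act = "softplus", gamma = 0.01,
                     s = 4, seed = 1) {
  set.seed(seed)
  cfg <- network_config(p, hidden_sizes = hidden, activation = act,
                        dropout_rate = 0, weight_decay = gamma)
  params <- frailtynet:::init_params(cfg, seq_len(s))
  params$eta_b[] <- rnorm(s, 0, 0.5)
  list(cfg = cfg, params = params)
}

rand_data <- function(n = 35, s = 4, p = 3, seed = 2) {
  set.seed(seed)
  list(data = data.frame(cluster = sample(seq_len(s), n, TRUE),
                         time = rexp(n),
                         status = rbinom(n, 1, 0.6)),
       M = matrix(rnorm(n * p), n, p))
}

test_that("forward pass matches hand computation", {
  # all-zero weights give zero risk
  net <- make_net()
  net$params$W <- lapply(net$params$W, function(w) { w[] <- 0; w })
  net$params$eta_b[] <- 0
  M <- matrix(rnorm(12), 4, 3)
  expect_equal(forward_risk(net$params, net$cfg, M, rep(1, 4)), rep(0, 4))

  # linear special case reduces to the classical frailty predictor
  cfg <- network_config(3, integer(0), "identity", 0, 0)
  params <- frailtynet:::init_params(cfg, 1:2)
  beta <- c(0.5, -1, 2)
  params$W[[1]] <- matrix(beta, 1)
  params$b[[1]] <- 0
  params$eta_x <- 1
  params$eta_b <- c("1" = 0.7, "2" = -0.3)
  cl <- c(1, 2, 2)
  expect_equal(forward_risk(params, cfg, M[1:3, ], cl),
               drop(M[1:3, ] %*% beta) + c(0.7, -0.3, -0.3))

  # single ReLU hidden node, hand-set weights
  cfg1 <- network_config(1, 1L, "relu", 0, 0)
  p1 <- frailtynet:::init_params(cfg1, 1)
  p1$W[[1]] <- matrix(2, 1, 1); p1$b[[1]] <- -1   # h = relu(2x - 1)
  p1$W[[2]] <- matrix(3, 1, 1)                    # alpha = 3h
  p1$eta_x <- 0.5; p1$eta_b <- c("1" = 0.1)
  x <- matrix(c(1, 0.25), 2, 1)
  # x=1: relu(1)=1, alpha=3, g=1.6 ; x=0.25: relu(-0.5)=0, g=0.1
  expect_equal(forward_risk(p1, cfg1, x, c(1, 1)), c(1.6, 0.1))
})

test_that("unseen clusters are rejected at prediction", {
  net <- make_net()
  M <- matrix(rnorm(6), 2, 3)
  expect_error(forward_risk(net$params, net$cfg, M, c(1, 99)), "99")
})

test_that("plnn loss reproduces the hand-computed partial likelihood", {
  # three subjects, all events, known risk scores
  d3 <- data.frame(cluster = c(1, 1, 2), time = c(1, 2, 3), status = 1)
  g <- c(0.3, -0.2, 0.5)
  got <- frailtynet:::cox_negloglik(d3$time, d3$status, g, grad = FALSE)$value
  hand <- -((g[1] - log(sum(exp(g)))) +
              (g[2] - log(exp(g[2]) + exp(g[3]))) + (g[3] - g[3]))
  expect_equal(got, hand, tolerance = 1e-12)

  # equal scores: sum over events of log risk-set size
  n <- 6
  gg <- rep(1.3, n)
  got <- frailtynet:::cox_negloglik(seq_len(n), rep(1, n), gg, grad = FALSE)$value
  expect_equal(got, sum(log(n:1)), tolerance = 1e-12)

  # full plnn value: likelihood term + frailty quadratic + n*gamma L2
  net <- make_net(gamma = 0.05)
  rd <- rand_data()
  st <- list(theta = 1.7)
  gfull <- forward_risk(net$params, net$cfg, rd$M, rd$data$cluster)
  manual <- frailtynet:::cox_negloglik(rd$data$time, rd$data$status, gfull,
                                       grad = FALSE)$value +
    sum(net$params$eta_b^2) / (2 * 1.7) +
    nrow(rd$M) * 0.05 * (sum(unlist(lapply(net$params$W, function(w) sum(w^2)))) +
                           sum(unlist(net$params$b)^2))
  expect_equal(plnn_loss(net$params, net$cfg, st, rd$data, rd$M), manual,
               tolerance = 1e-12)
})

test_that("plnn loss agrees with the reference Cox partial likelihood", {
  d <- sim_linear_clustered(6, 10, c(0.5, -0.8), theta = 0,
                            cens_upper = 3, seed = 5)
  beta <- c(0.4, -0.6)
  g <- as.matrix(d[, c("m1", "m2")]) %*% beta
  ref <- survival::coxph(survival::Surv(time, status) ~ m1 + m2, data = d,
                         ties = "breslow", init = beta,
                         control = survival::coxph.control(iter.max = 0))
  expect_equal(frailtynet:::cox_negloglik(d$time, d$status, drop(g),
                                          grad = FALSE)$value,
               -ref$loglik[2], tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  net <- make_net()
  rd <- rand_data()
  rd$data$status <- 0L
  expect_error(plnn_loss(net$params, net$cfg, list(theta = 1), rd$data, rd$M),
               "events")
  rd2 <- rand_data()
  expect_error(plnn_loss(net$params, net$cfg, list(theta = 0), rd2$data,
                         rd2$M), "theta")
  expect_error(analytic_scores_single_layer(
    make_net(hidden = c(4L, 4L))$params,
    network_config(3, c(4L, 4L), "softplus", 0, 0),
    list(theta = 1), rd2$data, rd2$M), "one hidden layer")
})

test_that("analytic quasi-scores match backprop and finite differences", {
  for (rep in 1:10) {
    net <- make_net(seed = 100 + rep)
    rd <- rand_data(seed = 200 + rep)
    st <- list(theta = 1.3)
    an <- analytic_scores_single_layer(net$params, net$cfg, st, rd$data, rd$M)
    bp <- frailtynet:::plnn_grad(net$params, net$cfg, st, rd$data, rd$M)
    # scores are derivatives of the maximized quantity; backprop of the loss
    expect_equal(bp$dW[[1]], -an$w0, tolerance = 1e-8)
    expect_equal(bp$dW[[2]], -an$w1, tolerance = 1e-8)
    expect_equal(bp$db[[1]], -an$delta0, tolerance = 1e-8)
    expect_equal(bp$d_eta_b, -an$eta_b, tolerance = 1e-8)
    expect_equal(bp$d_eta_x, -an$eta_x, tolerance = 1e-8)
  }
  # central finite differences on the input-layer weights and eta_b
  net <- make_net(seed = 7)
  rd <- rand_data(seed = 8)
  st <- list(theta = 1.3)
  an <- analytic_scores_single_layer(net$params, net$cfg, st, rd$data, rd$M)
  f_w0 <- function(v) {
    p <- net$params; p$W[[1]][] <- v
    plnn_loss(p, net$cfg, st, rd$data, rd$M)
  }
  fd <- fd_grad(f_w0, as.vector(net$params$W[[1]]))
  expect_equal(fd, as.vector(-an$w0), tolerance = 1e-5)
  f_eb <- function(v) {
    p <- net$params; p$eta_b[] <- v
    plnn_loss(p, net$cfg, st, rd$data, rd$M)
  }
  fd2 <- fd_grad(f_eb, unname(net$params$eta_b))
  expect_equal(fd2, unname(-an$eta_b), tolerance = 1e-5)
})

test_that("random-effect score at eta_b = 0 reduces to event counts minus softmax shares", {
  net <- make_net(seed = 11)
  net$params$eta_b[] <- 0
  rd <- rand_data(seed = 12)
  st <- list(theta = 1e12)   # frailty anchor negligible
  an <- analytic_scores_single_layer(net$params, net$cfg, st, rd$data, rd$M)
  g <- forward_risk(net$params, net$cfg, rd$M, rd$data$cluster)
  expected <- structure(numeric(4), names = names(net$params$eta_b))
  for (i in which(rd$data$status == 1)) {
    R <- which(rd$data$time >= rd$data$time[i])
    sh <- exp(g[R]) / sum(exp(g[R]))
    expected[as.character(rd$data$cluster[i])] <-
      expected[as.character(rd$data$cluster[i])] + 1
    for (q in seq_along(R))
      expected[as.character(rd$data$cluster[R[q]])] <-
        expected[as.character(rd$data$cluster[R[q]])] - sh[q]
  }
  expect_equal(an$eta_b, expected, tolerance = 1e-8)
})

test_that("the partial-likelihood term is shift invariant", {
  rd <- rand_data(seed = 13)
  g <- rnorm(nrow(rd$M))
  v1 <- frailtynet:::cox_negloglik(rd$data$time, rd$data$status, g,
                                   grad = FALSE)$value
  v2 <- frailtynet:::cox_negloglik(rd$data$time, rd$data$status, g + 5.3,
                                   grad = FALSE)$value
  expect_equal(v1, v2, tolerance = 1e-9)
})
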