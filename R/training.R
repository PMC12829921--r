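#' Training configuration
#'
#' Optimization protocol for the frailty network: Adam with inverse-time
#' learning-rate decay (\eqn{lr_t = lr_0 / (1 + d \cdot epoch)}), mini-batches
#' with batch-local risk sets, early stopping on a within-cluster validation
#' split of the training data, and a periodic moment-type refresh of the
#' frailty variance.
#'
#' @param epochs Training epochs (benchmark protocol: 100).
#' @param batch_size Mini-batch size (benchmark protocol: 128).
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay Inverse-time decay constant \eqn{d}.
#' @param patience Early-stopping patience in epochs; training stops when the
#'   validation loss has not improved for this many epochs and the best
#'   parameters are restored.
#' @param theta_update_every Epochs between frailty-variance updates.
#' @param theta_burnin Epochs before the first frailty-variance update; gives
#'   the random-effect weights time to move away from their zero start before
#'   the moment estimate is first taken.
#' @param theta_init Initial frailty variance.
#' @param val_fraction Within-cluster fraction of the training data held out
#'   for early stopping; 0 disables early stopping.
#' @param seed Integer seed controlling initialization, batching, dropout and
#'   the validation split.
#' @return Object of class \code{"train_config"}.
#' @export
train_config <- function(epochs = 100L, batch_size = 128L,
                         learning_rate = 1e-3, lr_decay = 0.01,
                         patience = 10L, theta_update_every = 5L,
                         theta_burnin = 20L, theta_init = 1,
                         val_fraction = 0.2, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            patience >= 1, theta_update_every >= 1, theta_init > 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 patience = as.integer(patience),
                 theta_update_every = as.integer(theta_update_every),
                 theta_burnin = as.integer(theta_burnin),
                 theta_init = theta_init,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Moment-type update of the frailty variance
#'
#' \eqn{\hat\theta = s^{-1} \sum_i \hat b_i^2}, floored at a small positive
#' constant so the frailty quadratic never divides by zero.
#'
#' @param b_hat Vector of per-cluster random-effect estimates.
#' @param floor Lower bound for the estimate.
#' @return Positive scalar.
#' @export
update_theta <- function(b_hat, floor = 1e-4) {
  if (length(b_hat) < 2L) stop("theta update needs at least 2 clusters")
  max(mean(b_hat^2), floor)
}

#' Breslow estimator of the baseline cumulative hazard
#'
#' Step-function estimator \eqn{\hat\Lambda_0(t) = \sum_{ij: U_{ij} \le t}
#' \Delta_{ij} / \sum_{dq \in R(U_{ij})} e^{g_{dq}}} with risk sets
#' \eqn{U \ge U_{ij}}; tied event times each contribute to a common jump.
#'
#' @param time Observed times.
#' @param status Event indicators (0/1).
#' @param risk_scores Fitted risk scores \eqn{g} aligned with the rows.
#' @return Object of class \code{"step_cumhaz"}: right-continuous step
#'   function, zero before the first event time.
#' @export
breslow_baseline <- function(time, status, risk_scores) {
  stopifnot(length(time) == length(status),
            length(time) == length(risk_scores))
  ord <- order(time)
  t_s <- time[ord]; d_s <- status[ord]
  mx <- max(risk_scores)
  w <- exp(risk_scores[ord] - mx)
  grp <- cumsum(!duplicated(t_s))
  rs_pos <- rev(cumsum(rev(w)))
  S_grp <- rs_pos[!duplicated(grp)]
  if (any(S_grp <= 0)) stop("empty risk set in Breslow estimator")
  d_grp <- as.vector(rowsum(d_s, grp))
  t_grp <- t_s[!duplicated(grp)]
  keep <- d_grp > 0
  jumps <- d_grp[keep] / (S_grp[keep] * exp(mx))
  structure(list(times = t_grp[keep], values = cumsum(jumps)),
            class = "step_cumhaz")
}

#' Evaluate a cumulative-hazard step function
#'
#' @param sc A \code{"step_cumhaz"} object.
#' @param t Evaluation times.
#' @return \eqn{\hat\Lambda_0(t)}: right-continuous, 0 before the first jump.
#' @export
step_cumhaz_at <- function(sc, t) {
  stopifnot(inherits(sc, "step_cumhaz"))
  idx <- findInterval(t, sc$times)
  c(0, sc$values)[idx + 1L]
}

#' @export
print.step_cumhaz <- function(x, ...) {
  cat(sprintf("Breslow cumulative hazard: %d jumps on [%g, %g], Lambda(max) = %g\n",
              length(x$times), min(x$times), max(x$times),
              max(x$values)))
  invisible(x)
}

# --- internal helpers -------------------------------------------------------

# Standardization statistics are computed on the training half only and
# frozen; columns with <= 2 distinct values (e.g. binarized covariates) are
# left untouched.
make_preprocessor <- function(M) {
  cont <- apply(M, 2, function(x) length(unique(x)) > 2L)
  center <- ifelse(cont, colMeans(M), 0)
  scale <- ifelse(cont, apply(M, 2, stats::sd), 1)
  scale[scale == 0 | !is.finite(scale)] <- 1
  structure(list(center = center, scale = scale), class = "fn_preproc")
}

apply_preprocessor <- function(pp, M) {
  sweep(sweep(M, 2, pp$center, "-"), 2, pp$scale, "/")
}

feature_matrix <- function(data, features = NULL) {
  if (is.null(features))
    features <- grep("^m[0-9]+$", names(data), value = TRUE)
  if (!length(features)) stop("no model covariates (m1..mp) found")
  as.matrix(data[, features, drop = FALSE])
}

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), st = st)
}

flatten_params <- function(params, frailty) {
  v <- c(unlist(params$W), unlist(params$b))
  if (frailty) v <- c(v, params$eta_b)
  v
}

unflatten_params <- function(v, skel, frailty) {
  out <- skel
  pos <- 0L
  for (l in seq_along(skel$W)) {
    nl <- length(skel$W[[l]])
    out$W[[l]] <- matrix(v[pos + seq_len(nl)], nrow(skel$W[[l]]))
    pos <- pos + nl
  }
  for (l in seq_along(skel$b)) {
    nl <- length(skel$b[[l]])
    out$b[[l]] <- v[pos + seq_len(nl)]
    pos <- pos + nl
  }
  if (frailty) {
    out$eta_b[] <- v[pos + seq_along(out$eta_b)]
  }
  out
}

# Deterministic fit of the linear special case: full-batch BFGS on the
# penalized approximated partial log-likelihood, alternating with the
# moment update of theta.  eta_x is fixed at 1 (its scale is absorbed by
# the weights).
fit_linear_plnn <- function(data, M, config, frailty, theta_init = 1,
                            theta_fixed = NULL, max_outer = 25L,
                            tol = 1e-5) {
  clusters <- sort(unique(data$cluster))
  params <- init_params(config, clusters)
  params$W[[1]][] <- 0
  params$b[[1]][] <- 0
  params$eta_x <- 1
  theta <- if (is.null(theta_fixed)) theta_init else theta_fixed
  if (!frailty) theta <- 0
  skel <- params
  obj <- function(v, theta) {
    p <- unflatten_params(v, skel, frailty)
    st <- list(theta = theta)
    cl_arg <- if (frailty) data$cluster else NULL
    g <- forward_risk(p, config, M, cl_arg)
    neg <- cox_negloglik(data$time, data$status, g, grad = FALSE)$value
    pen_f <- if (frailty) sum(p$eta_b^2) / (2 * theta) else 0
    pen_w <- nrow(M) * config$weight_decay *
      (sum(unlist(lapply(p$W, function(w) sum(w^2)))) +
         sum(unlist(lapply(p$b, function(bb) sum(bb^2)))))
    neg + pen_f + pen_w
  }
  grd <- function(v, theta) {
    p <- unflatten_params(v, skel, frailty)
    st <- list(theta = if (frailty) theta else 0)
    dat <- data
    if (!frailty) {
      g <- plnn_grad_nofrail(p, config, dat, M)
      return(c(unlist(g$dW), unlist(g$db)))
    }
    g <- plnn_grad(p, config, st, dat, M)
    c(unlist(g$dW), unlist(g$db), g$d_eta_b)
  }
  theta_trace <- theta
  for (outer in seq_len(max_outer)) {
    v0 <- flatten_params(params, frailty)
    fit <- stats::optim(v0, fn = obj, gr = grd, theta = theta,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    params <- unflatten_params(fit$par, skel, frailty)
    if (!frailty || !is.null(theta_fixed)) break
    theta_new <- update_theta(params$eta_b)
    theta_trace <- c(theta_trace, theta_new)
    if (abs(theta_new - theta) < tol * max(theta, 1)) { theta <- theta_new; break }
    theta <- theta_new
  }
  list(params = params, theta = theta, value = fit$value,
       theta_trace = theta_trace, convergence = fit$convergence)
}

# full-batch gradient without frailty term (eta_b frozen at zero)
plnn_grad_nofrail <- function(params, config, data, M) {
  fw <- forward_pass(params, config, M, NULL)
  cl <- cox_negloglik(data$time, data$status, fw$g)
  bp <- backprop(params, config, fw, cl$grad)
  n <- nrow(data); gam <- config$weight_decay
  list(dW = lapply(seq_along(params$W),
                   function(l) bp$dW[[l]] + 2 * n * gam * params$W[[l]]),
       db = lapply(seq_along(params$b),
                   function(l) bp$db[[l]] + 2 * n * gam * params$b[[l]]),
       d_eta_x = bp$d_eta_x)
}

# mean negative log partial likelihood per event (validation criterion,
# evaluation mode: no dropout, full risk sets within the given data)
val_criterion <- function(params, config, data, M, frailty) {
  cl_arg <- if (frailty) data$cluster else NULL
  g <- forward_risk(params, config, M, cl_arg)
  cox_negloglik(data$time, data$status, g, grad = FALSE)$value /
    sum(data$status)
}

#' Fit the neural-network frailty Cox model
#'
#' Trains the risk network on clustered right-censored data by minimizing
#' the penalized approximated partial log-likelihood with mini-batch Adam.
#' Batches are drawn at random each epoch and sorted by observed time so the
#' partial-likelihood term uses batch-local risk sets; weight decay is
#' applied per step to weights and biases, the frailty quadratic
#' \eqn{\sum_i (\eta_i^{(b)})^2 / 2\theta} (scaled by the batch fraction) to
#' the per-cluster weights.  The frailty variance \eqn{\theta} is refreshed
#' by \code{\link{update_theta}} on the schedule in the training
#' configuration; early stopping monitors a within-cluster validation split
#' and restores the best parameters.  After training the baseline cumulative
#' hazard is recovered with \code{\link{breslow_baseline}} on the full
#' training data.
#'
#' With empty \code{hidden_sizes} the model is the classical Gaussian-frailty
#' Cox model with a linear predictor; this special case is fitted by
#' deterministic full-batch BFGS (alternating with the moment theta-update)
#' rather than stochastic gradients.
#'
#' @param train Clustered survival data (\code{cluster}, \code{time},
#'   \code{status}, covariates \code{m1..mp}).
#' @param net_config A \code{\link{network_config}}; default: two hidden
#'   layers of 64 ReLU units, dropout 0.2, weight decay 0.001.
#' @param tr_config A \code{\link{train_config}}.
#' @param frailty \code{FALSE} freezes all per-cluster weights at zero (the
#'   no-frailty deep survival model).
#' @param features Covariate columns (default: all \code{m<k>} columns).
#' @param theta_fixed Optional fixed frailty variance (disables updates).
#' @return Object of class \code{"frailty_net_fit"}.
#' @export
fit_frailty_net <- function(train, net_config = NULL,
                            tr_config = train_config(), frailty = TRUE,
                            features = NULL, theta_fixed = NULL) {
  if (!any(train$status == 1)) stop("training data contain no events")
  clusters <- sort(unique(train$cluster))
  if (frailty && length(clusters) < 2L)
    stop("frailty model needs at least 2 clusters")
  M_raw <- feature_matrix(train, features)
  feature_names <- colnames(M_raw)
  if (is.null(net_config))
    net_config <- network_config(input_dim = ncol(M_raw))
  if (net_config$input_dim != ncol(M_raw))
    stop("net_config$input_dim does not match the covariate count")
  set.seed(tr_config$seed)
  pp <- make_preprocessor(M_raw)
  M <- apply_preprocessor(pp, M_raw)

  if (length(net_config$hidden_sizes) == 0L) {
    lin <- fit_linear_plnn(train, M, net_config, frailty,
                           theta_init = tr_config$theta_init,
                           theta_fixed = theta_fixed)
    params <- lin$params
    theta <- if (frailty) lin$theta else 0
    log_df <- data.frame(epoch = seq_along(lin$theta_trace) - 1L,
                         lr = NA_real_, train_loss = NA_real_,
                         val_loss = NA_real_, theta = lin$theta_trace)
  } else {
    res <- sgd_train(train, M, net_config, tr_config, frailty, theta_fixed)
    params <- res$params
    theta <- res$theta
    log_df <- res$log
  }

  cl_arg <- if (frailty) train$cluster else NULL
  g_train <- forward_risk(params, net_config, M, cl_arg)
  baseline <- breslow_baseline(train$time, train$status, g_train)
  structure(list(params = params,
                 state = list(b_hat = params$eta_b, theta = theta),
                 net_config = net_config, tr_config = tr_config,
                 frailty = frailty, preproc = pp,
                 feature_names = feature_names,
                 clusters = clusters, baseline = baseline,
                 log = log_df),
            class = c("frailty_net_fit", "fn_model"))
}

# Mini-batch Adam training loop.
sgd_train <- function(train, M, net_config, tr_config, frailty,
                      theta_fixed = NULL) {
  n_all <- nrow(train)
  # within-cluster validation split for early stopping
  use_val <- tr_config$val_fraction > 0 &&
    all(table(train$cluster) >= 2L)
  if (use_val) {
    sp <- split_within_cluster(cbind(train, .row = seq_len(n_all)),
                               train_fraction = 1 - tr_config$val_fraction,
                               seed = tr_config$seed + 1L)
    fit_rows <- sp$train$.row; val_rows <- sp$test$.row
  } else {
    fit_rows <- seq_len(n_all); val_rows <- integer(0)
  }
  datf <- train[fit_rows, , drop = FALSE]
  Mf <- M[fit_rows, , drop = FALSE]
  if (!any(datf$status == 1)) stop("no events left after validation split")
  datv <- train[val_rows, , drop = FALSE]
  Mv <- M[val_rows, , drop = FALSE]
  n <- nrow(datf)

  params <- init_params(net_config, sort(unique(train$cluster)))
  theta <- if (!is.null(theta_fixed)) theta_fixed else tr_config$theta_init
  if (!frailty) theta <- 0
  wd <- net_config$weight_decay
  L <- length(net_config$hidden_sizes)
  p_drop <- net_config$dropout_rate

  zero_like <- function(x) { x[] <- 0; x }
  ad <- list(W = lapply(params$W, function(w) list(m = zero_like(w), v = zero_like(w), t = 0)),
             b = lapply(params$b, function(bb) list(m = zero_like(bb), v = zero_like(bb), t = 0)),
             eta_x = list(m = 0, v = 0, t = 0),
             eta_b = list(m = zero_like(params$eta_b), v = zero_like(params$eta_b), t = 0))

  best <- list(val = Inf, params = params, theta = theta, epoch = 0L)
  stall <- 0L
  log_rows <- vector("list", tr_config$epochs)

  for (epoch in seq_len(tr_config$epochs)) {
    lr <- tr_config$learning_rate / (1 + tr_config$lr_decay * (epoch - 1L))
    perm <- sample.int(n)
    nb <- ceiling(n / tr_config$batch_size)
    epoch_loss <- 0; epoch_events <- 0L
    for (bi in seq_len(nb)) {
      rows <- perm[((bi - 1L) * tr_config$batch_size + 1L):
                     min(bi * tr_config$batch_size, n)]
      db_ <- datf[rows, , drop = FALSE]
      if (!any(db_$status == 1)) next      # batch-local likelihood undefined
      Mb <- Mf[rows, , drop = FALSE]
      m_b <- length(rows)
      masks <- NULL
      if (p_drop > 0 && L > 0L)
        masks <- lapply(net_config$hidden_sizes, function(k)
          matrix(stats::rbinom(m_b * k, 1L, 1 - p_drop) / (1 - p_drop), m_b, k))
      cl_arg <- if (frailty) db_$cluster else NULL
      fw <- forward_pass(params, net_config, Mb, cl_arg, masks)
      cl <- cox_negloglik(db_$time, db_$status, fw$g)
      bp <- backprop(params, net_config, fw, cl$grad, masks)
      epoch_loss <- epoch_loss + cl$value
      epoch_events <- epoch_events + sum(db_$status)
      for (l in seq_along(params$W)) {
        ad$W[[l]]$t <- ad$W[[l]]$t + 1L
        upd <- adam_step(params$W[[l]], bp$dW[[l]] + wd * params$W[[l]],
                         ad$W[[l]], lr)
        params$W[[l]] <- upd$par; ad$W[[l]] <- upd$st
      }
      for (l in seq_along(params$b)) {
        ad$b[[l]]$t <- ad$b[[l]]$t + 1L
        upd <- adam_step(params$b[[l]], bp$db[[l]] + wd * params$b[[l]],
                         ad$b[[l]], lr)
        params$b[[l]] <- upd$par; ad$b[[l]] <- upd$st
      }
      ad$eta_x$t <- ad$eta_x$t + 1L
      upd <- adam_step(params$eta_x, bp$d_eta_x, ad$eta_x, lr)
      params$eta_x <- upd$par; ad$eta_x <- upd$st
      if (frailty) {
        key <- as.character(db_$cluster)
        rs <- rowsum(cl$grad, key)
        geb <- zero_like(params$eta_b)
        geb[rownames(rs)] <- as.vector(rs)
        geb <- geb + (m_b / n) * params$eta_b / theta
        ad$eta_b$t <- ad$eta_b$t + 1L
        upd <- adam_step(params$eta_b, geb, ad$eta_b, lr)
        params$eta_b <- upd$par; ad$eta_b <- upd$st
      }
    }
    if (!is.finite(epoch_loss))
      stop("training loss became non-finite at epoch ", epoch)
    if (frailty && is.null(theta_fixed) &&
        epoch >= tr_config$theta_burnin &&
        (epoch - tr_config$theta_burnin) %% tr_config$theta_update_every == 0L)
      theta <- update_theta(params$eta_b)
    vl <- if (use_val)
      val_criterion(params, net_config, datv, Mv, frailty) else NA_real_
    log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                    train_loss = epoch_loss / max(epoch_events, 1L),
                                    val_loss = vl, theta = theta)
    if (use_val) {
      if (vl < best$val - 1e-8) {
        best <- list(val = vl, params = params, theta = theta, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tr_config$patience) break
      }
    }
  }
  log_df <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  if (use_val && is.finite(best$val)) {
    params <- best$params; theta <- best$theta
  }
  list(params = params, theta = theta, log = log_df)
}

#' @export
print.frailty_net_fit <- function(x, ...) {
  hs <- x$net_config$hidden_sizes
  arch <- if (length(hs)) paste(c(x$net_config$input_dim, hs, 1), collapse = "-")
  else paste0("linear (p = ", x$net_config$input_dim, ")")
  cat("Neural-network frailty Cox model\n")
  cat("  architecture: ", arch, " (", x$net_config$activation, ")\n", sep = "")
  cat(sprintf("  clusters: %d, frailty: %s, theta = %.4g\n",
              length(x$clusters), ifelse(x$frailty, "yes", "no"),
              x$state$theta))
  invisible(x)
}

#' Risk scores for new subjects
#'
#' @param object A fitted model (\code{frailty_net_fit} or a baseline fit).
#' @param newdata Data with the model's covariate columns (and
#'   \code{cluster} for frailty/fixed-effect models; within-cluster
#'   prediction requires clusters seen in training).
#' @param ... Unused.
#' @return Numeric risk-score vector.
#' @export
predict_risk <- function(object, newdata, ...) UseMethod("predict_risk")

#' @export
predict_risk.frailty_net_fit <- function(object, newdata, ...) {
  M <- apply_preprocessor(object$preproc,
                          feature_matrix(newdata, object$feature_names))
  cl_arg <- if (object$frailty) newdata$cluster else NULL
  forward_risk(object$params, object$net_config, M, cl_arg)
}

#' Predicted survival probabilities
#'
#' \eqn{\hat S(t \mid X, cluster) = \exp\{-\hat\Lambda_0(t) e^{g}\}} with the
#' Breslow baseline from the training data and the network risk score
#' \eqn{g}.
#'
#' @param model A fitted model carrying a \code{baseline} component.
#' @param newdata New subjects (clusters must have been seen in training for
#'   frailty models).
#' @param times Time grid.
#' @return Matrix (subjects x times) of probabilities in (0, 1].
#' @export
predict_survival <- function(model, newdata, times) {
  g <- predict_risk(model, newdata)
  H <- step_cumhaz_at(model$baseline, times)
  exp(-outer(exp(g), H))
}
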