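#' Network configuration for the frailty risk network
#'
#' Describes the feed-forward risk network: hidden-layer widths, activation,
#' dropout and the L2 regularization strength applied to the network weights
#' and biases.  An empty \code{hidden_sizes} gives the linear special case
#' (the classical frailty Cox linear predictor).
#'
#' @param input_dim Number of input covariates \code{p}.
#' @param hidden_sizes Integer vector of hidden-layer widths; \code{c(64, 64)}
#'   is the benchmark configuration.  \code{integer(0)} selects the linear
#'   special case.
#' @param activation Hidden activation: one of \code{"relu"},
#'   \code{"softplus"}, \code{"sigmoid"}, \code{"tanh"}, \code{"identity"}.
#'   The output layer is always linear.
#' @param dropout_rate Dropout probability on hidden activations during
#'   training, in [0, 1).
#' @param weight_decay L2 regularization strength \eqn{\gamma} on weights and
#'   biases (the per-cluster random-effect weights are regularized by the
#'   frailty term instead, and the output scale weight not at all).
#' @return Object of class \code{"network_config"}.
#' @export
network_config <- function(input_dim, hidden_sizes = c(64L, 64L),
                           activation = "relu", dropout_rate = 0.2,
                           weight_decay = 0.001) {
  activation <- match.arg(activation,
                          c("relu", "softplus", "sigmoid", "tanh", "identity"))
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (weight_decay < 0) stop("weight_decay must be >= 0")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_sizes = as.integer(hidden_sizes),
                 activation = activation,
                 dropout_rate = dropout_rate,
                 weight_decay = weight_decay),
            class = "network_config")
}

activation_fun <- function(name) {
  switch(name,
         relu = function(z) pmax(z, 0),
         softplus = function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30)))),
         sigmoid = function(z) 1 / (1 + exp(-z)),
         tanh = tanh,
         identity = identity)
}

activation_grad <- function(name) {
  switch(name,
         relu = function(z) as.numeric(z > 0),
         softplus = function(z) 1 / (1 + exp(-z)),
         sigmoid = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) },
         tanh = function(z) 1 - tanh(z)^2,
         identity = function(z) rep(1, length(z)))
}

#' Initialize frailty-network parameters
#'
#' Weights use He-style Gaussian initialization (sd \eqn{\sqrt{2/fan_{in}}}),
#' biases start at zero, the output scale weight \code{eta_x} at one, and the
#' per-cluster random-effect weights \code{eta_b} at zero.
#'
#' @param config A \code{\link{network_config}}.
#' @param clusters Vector of cluster identifiers (one weight is created per
#'   cluster, named by the identifier).
#' @return List with components \code{W} (weight matrices, the last one the
#'   \code{1 x k} output row), \code{b} (bias vectors for the hidden layers;
#'   in the linear special case a single scalar bias), \code{eta_x}, and
#'   \code{eta_b}.
#' @export
init_params <- function(config, clusters) {
  stopifnot(inherits(config, "network_config"))
  sizes <- c(config$input_dim, config$hidden_sizes, 1L)
  W <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W))
    W[[l]] <- matrix(rnorm(sizes[l + 1] * sizes[l], 0, sqrt(2 / sizes[l])),
                     sizes[l + 1], sizes[l])
  nb <- if (length(config$hidden_sizes)) length(config$hidden_sizes) else 1L
  b <- lapply(seq_len(nb), function(l) numeric(sizes[l + 1]))
  eta_b <- structure(numeric(length(clusters)), names = as.character(clusters))
  list(W = W, b = b, eta_x = 1, eta_b = eta_b)
}

# Forward pass.  M is an n x p numeric matrix (already standardized),
# cluster chr/int vector indexing params$eta_b (NULL => no frailty term).
# masks: optional list of dropout masks (n x k_l matrices) per hidden layer.
# Returns list(g, alpha_out, H = activations per layer, Z = pre-activations).
forward_pass <- function(params, config, M, cluster = NULL, masks = NULL) {
  act <- activation_fun(config$activation)
  L <- length(config$hidden_sizes)
  H <- vector("list", L); Z <- vector("list", L)
  A <- M
  if (L == 0L) {
    alpha <- drop(A %*% t(params$W[[1]])) + params$b[[1]]
  } else {
    for (l in seq_len(L)) {
      Z[[l]] <- sweep(A %*% t(params$W[[l]]), 2, params$b[[l]], "+")
      A <- act(Z[[l]])
      if (!is.null(masks)) A <- A * masks[[l]]
      H[[l]] <- A
    }
    alpha <- drop(A %*% t(params$W[[L + 1L]]))
  }
  g <- params$eta_x * alpha
  if (!is.null(cluster)) {
    key <- as.character(cluster)
    unseen <- setdiff(unique(key), names(params$eta_b))
    if (length(unseen))
      stop("prediction requested for cluster(s) never seen in training: ",
           paste(unseen, collapse = ", "))
    g <- g + unname(params$eta_b[key])
  }
  list(g = g, alpha = alpha, H = H, Z = Z, M = M)
}

#' Network risk scores
#'
#' Evaluates the risk score \eqn{g_{ij} = \eta^{(x)} \alpha^{(L)}_{ij} +
#' \eta^{(b)}_{cluster(ij)}} for a covariate matrix, where
#' \eqn{\alpha^{(L)}} is the nested activation composition of the network
#' (for empty hidden layers, \eqn{\alpha^{(L)} = \omega^T M + \delta}).
#'
#' @param params Parameter list from \code{\link{init_params}}.
#' @param config A \code{\link{network_config}}.
#' @param M Covariate matrix (n x p).
#' @param cluster Cluster id per row (indexes \code{eta_b}); \code{NULL}
#'   omits the random-effect term.
#' @return Numeric vector of risk scores.
#' @export
forward_risk <- function(params, config, M, cluster = NULL) {
  if (ncol(M) != config$input_dim)
    stop("covariate count ", ncol(M), " does not match input_dim ",
         config$input_dim)
  forward_pass(params, config, M, cluster)$g
}

# Negative Cox log partial likelihood and its gradient in the risk scores.
# Risk set convention U_dq >= U_ij; Breslow handling of tied event times.
# Returns list(value, grad) where grad = d(-logPL)/dg.
cox_negloglik <- function(time, status, g, grad = TRUE) {
  if (!any(status == 1)) stop("no events: partial likelihood undefined")
  ord <- order(time)
  t_s <- time[ord]; d_s <- status[ord]; g_s <- g[ord]
  mx <- max(g_s)
  w <- exp(g_s - mx)
  # risk-set exp-sums, shared within tied-time groups
  grp <- cumsum(!duplicated(t_s))           # group index per sorted row
  rs_pos <- rev(cumsum(rev(w)))             # sum_{k >= j} w_k by position
  first_of_grp <- which(!duplicated(grp))
  S_grp <- rs_pos[first_of_grp]             # risk-set sum per time group
  d_grp <- as.vector(rowsum(d_s, grp))      # events per time group
  ev_grp <- d_grp > 0
  value <- -(sum(g_s[d_s == 1]) - sum(d_grp[ev_grp] * (log(S_grp[ev_grp]) + mx)))
  if (!grad) return(list(value = value, grad = NULL))
  # d(-logPL)/dg_k = -(Delta_k - w_k * sum_{event groups with t <= U_k} d/S)
  cum_inv <- cumsum(d_grp / S_grp)          # over groups, ascending time
  A <- cum_inv[grp]
  g_grad_s <- -(d_s - w * A)
  grad_out <- numeric(length(g))
  grad_out[ord] <- g_grad_s
  list(value = value, grad = grad_out)
}

#' Penalized approximated partial log-likelihood loss
#'
#' The training objective of the frailty network, returned as a
#' minimization loss (the negative of the penalized approximated partial
#' log-likelihood):
#' \deqn{-\sum_{ij} \Delta_{ij}\left[g_{ij} - \log\!\!\sum_{dq \in R(t_{ij})}
#'   e^{g_{dq}}\right] + \frac{1}{2\theta}\sum_i (\eta^{(b)}_i)^2 +
#'   n\gamma(\omega^T\omega + \delta^T\delta)}
#' with risk sets \eqn{R(t_{ij}) = \{dq : U_{dq} \ge U_{ij}\}} and Breslow
#' handling of tied event times.  The L2 term covers the network weights and
#' biases only: \code{eta_b} is anchored by the frailty term and
#' \code{eta_x} is unpenalized.
#'
#' @param params Parameter list (see \code{\link{init_params}}).
#' @param config A \code{\link{network_config}} (supplies \eqn{\gamma}).
#' @param state List with \code{theta} (frailty variance, > 0 unless all
#'   \code{eta_b} are zero).
#' @param data Clustered survival data with columns \code{time},
#'   \code{status}, \code{cluster}.
#' @param M Covariate matrix aligned with \code{data} rows.
#' @return Scalar loss.
#' @export
plnn_loss <- function(params, config, state, data, M) {
  if (!any(data$status == 1)) stop("no events in the data")
  if (state$theta <= 0 && any(params$eta_b != 0))
    stop("theta <= 0 requires all eta_b to be zero (no-frailty mode)")
  g <- forward_risk(params, config, M, data$cluster)
  neg <- cox_negloglik(data$time, data$status, g, grad = FALSE)$value
  pen_frail <- if (state$theta > 0)
    sum(params$eta_b^2) / (2 * state$theta) else 0
  n <- nrow(data)
  pen_l2 <- n * config$weight_decay *
    (sum(unlist(lapply(params$W, function(w) sum(w^2)))) +
       sum(unlist(lapply(params$b, function(bb) sum(bb^2)))))
  neg + pen_frail + pen_l2
}

# Backpropagation through the network given dL/dg.  fw is a forward_pass()
# result computed WITH the same masks.  Returns gradients for W, b, eta_x
# (likelihood part only; penalty terms are added by callers).
backprop <- function(params, config, fw, dg, masks = NULL) {
  L <- length(config$hidden_sizes)
  actg <- activation_grad(config$activation)
  dW <- vector("list", length(params$W))
  db <- vector("list", length(params$b))
  d_eta_x <- sum(dg * fw$alpha)
  if (L == 0L) {
    dZ <- dg * params$eta_x
    dW[[1]] <- matrix(colSums(dZ * fw$M), 1L)
    db[[1]] <- sum(dZ)
    return(list(dW = dW, db = db, d_eta_x = d_eta_x))
  }
  d_alpha <- matrix(dg * params$eta_x, ncol = 1L)
  dW[[L + 1L]] <- t(d_alpha) %*% fw$H[[L]]
  dH <- d_alpha %*% params$W[[L + 1L]]
  for (l in rev(seq_len(L))) {
    if (!is.null(masks)) dH <- dH * masks[[l]]
    dZ <- dH * matrix(actg(fw$Z[[l]]), nrow(dH), ncol(dH))
    Hprev <- if (l == 1L) fw$M else fw$H[[l - 1L]]
    dW[[l]] <- t(dZ) %*% Hprev
    db[[l]] <- colSums(dZ)
    if (l > 1L) dH <- dZ %*% params$W[[l]]
  }
  list(dW = dW, db = db, d_eta_x = d_eta_x)
}

# Full-batch gradient of plnn_loss (the literal objective, including the
# n*gamma L2 term and the frailty quadratic).  Used by the deterministic
# linear-path optimizer and by gradient tests.
plnn_grad <- function(params, config, state, data, M) {
  fw <- forward_pass(params, config, M, data$cluster)
  cl <- cox_negloglik(data$time, data$status, fw$g)
  bp <- backprop(params, config, fw, cl$grad)
  n <- nrow(data)
  gam <- config$weight_decay
  dW <- lapply(seq_along(params$W),
               function(l) bp$dW[[l]] + 2 * n * gam * params$W[[l]])
  db <- lapply(seq_along(params$b),
               function(l) bp$db[[l]] + 2 * n * gam * params$b[[l]])
  key <- as.character(data$cluster)
  rs <- rowsum(cl$grad, key)
  d_eta_b <- structure(as.vector(rs), names = rownames(rs))
  full <- structure(numeric(length(params$eta_b)), names = names(params$eta_b))
  full[names(d_eta_b)] <- d_eta_b
  if (state$theta > 0) full <- full + params$eta_b / state$theta
  list(dW = dW, db = db, d_eta_x = bp$d_eta_x, d_eta_b = full)
}

#' Quasi-score equations for a single-hidden-layer network
#'
#' Evaluates the derivatives of the penalized approximated partial
#' log-likelihood (the quantity whose negative \code{\link{plnn_loss}}
#' returns) with respect to the output scale weight, the per-cluster
#' random-effect weights, the output-layer weights, the input-layer weights
#' and the input-layer biases, for a network with exactly one hidden layer.
#' The derivatives are accumulated literally event by event with explicit
#' softmax shares over each risk set, independently of the vectorized
#' backpropagation used in training, and serve as its analytic oracle.
#'
#' @inheritParams plnn_loss
#' @return List with elements \code{eta_x} (scalar), \code{eta_b} (vector
#'   over clusters), \code{w1} (1 x k), \code{w0} (k x p), \code{delta0}
#'   (length k), each the derivative of the penalized approximated partial
#'   log-likelihood (a quantity to be maximized).
#' @export
analytic_scores_single_layer <- function(params, config, state, data, M) {
  if (length(config$hidden_sizes) != 1L)
    stop("analytic scores are defined for exactly one hidden layer")
  act <- activation_fun(config$activation)
  actg <- activation_grad(config$activation)
  n <- nrow(M); k <- config$hidden_sizes
  key <- as.character(data$cluster)
  # per-subject pieces
  Z0 <- sweep(M %*% t(params$W[[1]]), 2, params$b[[1]], "+")  # n x k
  A0 <- act(Z0)
  alpha1 <- drop(A0 %*% t(params$W[[2]]))                     # n
  g <- params$eta_x * alpha1 + unname(params$eta_b[key])
  # dg/dparam for every subject
  dgp <- actg(Z0)                                             # n x k
  dg_eta_x <- alpha1                                          # n
  dg_w1 <- params$eta_x * A0                                  # n x k
  dg_delta0 <- params$eta_x * dgp *
    matrix(params$W[[2]], n, k, byrow = TRUE)                 # n x k
  s_eta_x <- 0
  s_eta_b <- structure(numeric(length(params$eta_b)),
                       names = names(params$eta_b))
  s_w1 <- numeric(k)
  s_w0 <- matrix(0, k, ncol(M))
  s_d0 <- numeric(k)
  for (i in which(data$status == 1)) {
    R <- which(data$time >= data$time[i])
    sh <- exp(g[R] - max(g[R]))
    sh <- sh / sum(sh)                                        # softmax shares
    s_eta_x <- s_eta_x + dg_eta_x[i] - sum(sh * dg_eta_x[R])
    sb <- rowsum(sh, key[R])
    s_eta_b[key[i]] <- s_eta_b[key[i]] + 1
    s_eta_b[rownames(sb)] <- s_eta_b[rownames(sb)] - as.vector(sb)
    s_w1 <- s_w1 + dg_w1[i, ] - colSums(sh * dg_w1[R, , drop = FALSE])
    s_d0 <- s_d0 + dg_delta0[i, ] - colSums(sh * dg_delta0[R, , drop = FALSE])
    s_w0 <- s_w0 + dg_delta0[i, ] %o% M[i, ] -
      t(sh * dg_delta0[R, , drop = FALSE]) %*% M[R, , drop = FALSE]
  }
  gam <- config$weight_decay
  if (state$theta > 0) s_eta_b <- s_eta_b - params$eta_b / state$theta
  list(eta_x = s_eta_x,
       eta_b = s_eta_b,
       w1 = matrix(s_w1, 1L) - 2 * n * gam * params$W[[2]],
       w0 = s_w0 - 2 * n * gam * params$W[[1]],
       delta0 = s_d0 - 2 * n * gam * params$b[[1]])
}
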