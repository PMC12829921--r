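#' Two-way interaction expansion
#'
#' Expands a covariate matrix to all main effects plus all pairwise
#' products, ordered lexicographically by index pair.
#'
#' @param M Covariate matrix with at least 2 columns.
#' @return Matrix with \eqn{p + p(p-1)/2} columns; product columns are named
#'   \code{"a:b"} from the parent column names.
#' @export
expand_interactions <- function(M) {
  M <- as.matrix(M)
  p <- ncol(M)
  if (p < 2L) stop("interaction expansion needs at least 2 covariates")
  if (is.null(colnames(M))) colnames(M) <- paste0("m", seq_len(p))
  pairs <- utils::combn(p, 2L)
  inter <- M[, pairs[1, ], drop = FALSE] * M[, pairs[2, ], drop = FALSE]
  colnames(inter) <- paste(colnames(M)[pairs[1, ]],
                           colnames(M)[pairs[2, ]], sep = ":")
  cbind(M, inter)
}

# Shared engine: Cox partial-likelihood fit (Breslow ties) on an explicit
# feature matrix, via survival::coxph.  Non-convergence (monotone
# likelihood) and rank deficiency are flagged rather than fatal; dropped
# columns predict as zero effect.
cox_engine <- function(time, status, Xmat, label) {
  if (!any(status == 1)) stop("no events: cannot fit a Cox model")
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, status) ~ Xmat,
                    ties = "breslow",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|singular|rank", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  names(beta) <- colnames(Xmat)
  if (anyNA(beta)) { converged <- FALSE; beta[is.na(beta)] <- 0 }
  if (any(abs(beta) > 15)) converged <- FALSE
  structure(list(beta = beta, feature_names = colnames(Xmat),
                 converged = converged,
                 loglik = fit$loglik[length(fit$loglik)],
                 label = label),
            class = c("linear_cox_fit", "fn_model"))
}

#' Linear Cox proportional-hazards baseline
#'
#' Standard partial-likelihood Cox fit (Breslow ties) on the raw model
#' covariates, the no-frailty, no-interaction comparison arm of the
#' benchmark.  Monotone-likelihood or rank problems set
#' \code{converged = FALSE} and the partial result is returned.
#'
#' @param train Clustered survival data.
#' @param features Covariate columns (default \code{m1..mp}).
#' @param interactions Add all two-way interactions
#'   (\code{\link{expand_interactions}}).
#' @return A \code{"linear_cox_fit"}: coefficients, convergence flag, log
#'   partial likelihood at the optimum.
#' @export
fit_cox <- function(train, features = NULL, interactions = FALSE) {
  X <- feature_matrix(train, features)
  base <- colnames(X)
  if (interactions) X <- expand_interactions(X)
  out <- cox_engine(train$time, train$status, X,
                    if (interactions) "cox_int" else "cox")
  out$base_features <- base
  out
}

#' @export
predict_risk.linear_cox_fit <- function(object, newdata, ...) {
  X <- feature_matrix(newdata, object$base_features)
  if (any(grepl(":", object$feature_names))) X <- expand_interactions(X)
  if (!is.null(object$cluster_levels)) {
    dm <- cluster_dummies(newdata$cluster, object$cluster_levels)
    X <- cbind(X, dm)
  }
  drop(X[, object$feature_names, drop = FALSE] %*% object$beta)
}

cluster_dummies <- function(cluster, levels) {
  # indicator columns for levels[-1] (first cluster is the reference)
  dm <- vapply(levels[-1], function(cl) as.numeric(cluster == cl),
               numeric(length(cluster)))
  dm <- matrix(dm, nrow = length(cluster))
  colnames(dm) <- paste0("cl", levels[-1])
  dm
}

#' Cox model with fixed cluster effects
#'
#' Linear Cox fit on the raw covariates augmented with \eqn{s - 1} cluster
#' indicator columns (first cluster as reference).  Clusters that
#' contribute no events would take an infinitely negative effect; their
#' indicator is dropped with a warning and they predict at the reference
#' level.
#'
#' @inheritParams fit_cox
#' @return A \code{"linear_cox_fit"} carrying the cluster dummy coding.
#' @export
fit_cox_fixed_clusters <- function(train, features = NULL) {
  X <- feature_matrix(train, features)
  levels <- sort(unique(train$cluster))
  dm <- cluster_dummies(train$cluster, levels)
  ev <- tapply(train$status, train$cluster, sum)[as.character(levels)]
  dead <- levels[-1][ev[-1] == 0]
  if (length(dead)) {
    warning("dropping indicator(s) for cluster(s) without events: ",
            paste(dead, collapse = ", "))
    dm <- dm[, !colnames(dm) %in% paste0("cl", dead), drop = FALSE]
  }
  out <- cox_engine(train$time, train$status, cbind(X, dm), "cox_fixed")
  out$base_features <- colnames(X)
  out$cluster_levels <- levels
  # ensure dropped dummies predict as zero
  full <- structure(numeric(ncol(X) + length(levels) - 1L),
                    names = c(colnames(X), paste0("cl", levels[-1])))
  full[names(out$beta)] <- out$beta
  out$beta <- full
  out$feature_names <- names(full)
  out
}

#' Gaussian-frailty Cox model with a linear predictor
#'
#' The classical shared-frailty Cox fit (linear effects, optionally all
#' two-way interactions), realized through the same penalized
#' partial-likelihood machinery as the network model with empty hidden
#' layers, so risk-set and tie conventions are identical across the
#' benchmark arms.
#'
#' @inheritParams fit_cox
#' @param theta_fixed Optional fixed frailty variance (otherwise estimated
#'   by the alternating moment update).
#' @return A \code{"frailty_net_fit"} (linear special case).
#' @export
fit_cox_frailty_linear <- function(train, features = NULL,
                                   interactions = FALSE, theta_fixed = NULL) {
  M <- feature_matrix(train, features)
  if (interactions) {
    X <- expand_interactions(M)
    train2 <- cbind(train[, c("cluster", "time", "status")], as.data.frame(X))
    names(train2) <- c("cluster", "time", "status",
                       paste0("f", seq_len(ncol(X))))
    feats <- paste0("f", seq_len(ncol(X)))
  } else {
    train2 <- train; feats <- colnames(M)
  }
  cfg <- network_config(input_dim = length(feats),
                        hidden_sizes = integer(0), activation = "identity",
                        dropout_rate = 0, weight_decay = 0)
  fit <- fit_frailty_net(train2, cfg, train_config(), frailty = TRUE,
                         features = feats, theta_fixed = theta_fixed)
  fit$interactions <- interactions
  fit$base_features <- colnames(M)
  fit
}

#' No-frailty deep survival model
#'
#' The Deepsurv-style comparison arm: the identical network, loss and
#' training protocol with every per-cluster weight frozen at zero.
#'
#' @inheritParams fit_frailty_net
#' @return A \code{"frailty_net_fit"} with \code{frailty = FALSE}.
#' @export
deepsurv_equivalent <- function(train, net_config = NULL,
                                tr_config = train_config(),
                                features = NULL) {
  fit_frailty_net(train, net_config, tr_config, frailty = FALSE,
                  features = features)
}

#' True-model oracle scores
#'
#' Ranks test subjects by the generator's true risk score (covariate effect
#' plus the cluster's frailty), the performance ceiling of the simulation
#' benchmark.  Only available for simulated data carrying oracle columns.
#'
#' @param test Simulated clustered survival data with a \code{risk} column.
#' @return Numeric risk-score vector.
#' @export
true_model_oracle <- function(test) {
  if (is.null(test$risk))
    stop("true-model oracle needs the simulated 'risk' column")
  test$risk
}

# registry used by the benchmark runner and the command-line interface
method_registry <- function() {
  list(
    cox = function(train, test, nc, tc)
      predict_risk(fit_cox(train), test),
    cox_int = function(train, test, nc, tc)
      predict_risk(fit_cox(train, interactions = TRUE), test),
    cox_frailty = function(train, test, nc, tc)
      predict_risk(fit_cox_frailty_linear(train), test),
    cox_frailty_int = function(train, test, nc, tc) {
      fit <- fit_cox_frailty_linear(train, interactions = TRUE)
      predict_risk_interactions(fit, test)
    },
    cox_fixed = function(train, test, nc, tc)
      predict_risk(fit_cox_fixed_clusters(train), test),
    deepsurv = function(train, test, nc, tc)
      predict_risk(deepsurv_equivalent(train, nc, tc), test),
    proposed = function(train, test, nc, tc)
      predict_risk(fit_frailty_net(train, nc, tc), test),
    true_model = function(train, test, nc, tc)
      true_model_oracle(test)
  )
}

# interaction-expanded frailty fit stores renamed features; rebuild them
predict_risk_interactions <- function(fit, newdata) {
  X <- expand_interactions(feature_matrix(newdata, fit$base_features))
  nd <- cbind(newdata[, c("cluster", "time", "status")], as.data.frame(X))
  names(nd) <- c("cluster", "time", "status", fit$feature_names)
  predict_risk(fit, nd)
}

#' Registered benchmark method names
#' @return Character vector of method names accepted by
#'   \code{\link{run_benchmark}} and the command-line interface.
#' @export
benchmark_methods <- function() names(method_registry())
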