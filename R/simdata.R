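#' Scenario configuration for the clustered-survival simulator
#'
#' Describes one simulation scenario: a number of clusters whose sizes are
#' drawn uniformly from an integer range, a Gaussian cluster-level frailty
#' with variance \code{theta}, an exponential (unit) baseline hazard, a
#' scenario-specific nonlinear map from raw covariates \code{M} to the
#' effective covariates \code{X}, and independent \code{Uniform(0, censor_upper)}
#' right censoring.
#'
#' Scenario 1 draws five standard-normal covariates and squares them
#' (\code{X = M^2}, \code{beta = 0.5}, risk \code{r = X'beta - 3 + b}); with
#' \code{censor_upper = 0.5} around 70\% of subjects are censored.
#' Scenario 2 draws fifteen normal covariates with means
#' (1,1,1,2,2,3,3,3,0,...,0), binarizes the eighth as \code{I(M8 < 1)}, and
#' builds four nonlinear/interactive components (see
#' \code{\link{transform_covariates_s2}}); \code{beta = 1}, risk
#' \code{r = X'beta - 4 + b}, censoring \code{Uniform(0, 15)}.
#'
#' @param scenario 1 or 2.
#' @param n_clusters Number of clusters \code{s} (default 200).
#' @param cluster_size_range Integer pair; cluster sizes are drawn uniformly
#'   on \code{cluster_size_range[1]:cluster_size_range[2]} (default 20--100).
#' @param theta Frailty variance, \code{>= 0}.
#' @param censor_upper Upper bound of the uniform censoring law; defaults to
#'   0.5 for scenario 1 and 15 for scenario 2. May be \code{Inf} for no
#'   censoring.
#' @param seed Optional integer seed.
#' @return An object of class \code{"scenario_config"}.
#' @export
scenario_config <- function(scenario, n_clusters = 200L,
                            cluster_size_range = c(20L, 100L),
                            theta = 0, censor_upper = NULL, seed = NULL) {
  if (!scenario %in% c(1L, 2L))
    stop("unknown scenario id: ", scenario, " (must be 1 or 2)")
  if (theta < 0) stop("theta must be >= 0, got ", theta)
  cluster_size_range <- as.integer(round(cluster_size_range))
  if (length(cluster_size_range) != 2L ||
      cluster_size_range[1] > cluster_size_range[2] ||
      cluster_size_range[1] < 1L)
    stop("cluster_size_range must be an increasing integer pair with low >= 1")
  if (is.null(censor_upper))
    censor_upper <- if (scenario == 1L) 0.5 else 15
  if (censor_upper <= 0) stop("censor_upper must be > 0")
  structure(list(scenario = as.integer(scenario),
                 n_clusters = as.integer(n_clusters),
                 cluster_size_range = cluster_size_range,
                 theta = theta, censor_upper = censor_upper,
                 seed = seed),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario %d: s = %d clusters, sizes %d-%d, theta = %g, C ~ U(0, %g)\n",
              x$scenario, x$n_clusters, x$cluster_size_range[1],
              x$cluster_size_range[2], x$theta, x$censor_upper))
  invisible(x)
}

#' Square the scenario-1 raw covariates
#'
#' Element-wise square, mapping the five raw covariates \code{M} to the
#' effective covariates \code{X} of scenario 1.
#'
#' @param M Numeric vector of length 5, or a matrix with 5 columns
#'   (rows are subjects).
#' @return Object of the same shape as \code{M}.
#' @export
transform_covariates_s1 <- function(M) {
  p <- if (is.matrix(M)) ncol(M) else length(M)
  if (p != 5L) stop("scenario-1 covariates must have length 5, got ", p)
  M^2
}

#' Nonlinear covariate map of scenario 2
#'
#' Maps the fifteen raw covariates (with \code{M8} already binarized) to the
#' four effective covariates used by the scenario-2 risk score:
#' \deqn{X_1 = 0.1 e^{M_1}(1 + M_2 - M_3 M_4 M_5)/(2 M_5 + 0.2) - 0.01 M_9 M_{10}}
#' \deqn{X_2 = M_5 (M_3 M_4 - 0.3)/(|2 M_3 M_4 M_6 - 1 + 0.01 M_{11} M_{12}| + 1)}
#' \deqn{X_3 = 2 \sin(M_1 M_2 M_5)(M_2 M_5 M_6 - 0.6) - 0.01 M_{13} M_{14}}
#' \deqn{X_4 = \log(|M_1 M_2 M_6| + |M_5 M_7 M_8| + 0.01 |M_{15}| + 10^{-8})}
#' The covariates \code{M9..M15} enter only through 0.01-scaled nuisance
#' terms.  The compact inline notation these expressions originate from
#' admits more than one grouping; this parse is fixed here, in one pure
#' function, so it can be revised in a single place.
#'
#' @param M Numeric vector of length 15, or a matrix with 15 columns.
#' @return A 4-vector, or a matrix with 4 columns named \code{x1..x4}.
#' @export
transform_covariates_s2 <- function(M) {
  vec <- !is.matrix(M)
  if (vec) M <- matrix(M, nrow = 1L)
  if (ncol(M) != 15L)
    stop("scenario-2 covariates must have length 15, got ", ncol(M))
  m <- function(k) M[, k]
  x1 <- 0.1 * exp(m(1)) * (1 + m(2) - m(3) * m(4) * m(5)) /
    (2 * m(5) + 0.2) - 0.01 * m(9) * m(10)
  x2 <- m(5) * (m(3) * m(4) - 0.3) /
    (abs(2 * m(3) * m(4) * m(6) - 1 + 0.01 * m(11) * m(12)) + 1)
  x3 <- 2 * sin(m(1) * m(2) * m(5)) * (m(2) * m(5) * m(6) - 0.6) -
    0.01 * m(13) * m(14)
  x4 <- log(abs(m(1) * m(2) * m(6)) + abs(m(5) * m(7) * m(8)) +
              0.01 * abs(m(15)) + 1e-8)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3, x4 = x4)
  if (any(!is.finite(X)))
    stop("non-finite scenario-2 covariate value (domain problem in the map)")
  if (vec) drop(X) else X
}

#' Simulate clustered right-censored survival data
#'
#' Draws cluster sizes, Gaussian frailties \code{b_i ~ N(0, theta)}, raw
#' covariates \code{M}, effective covariates \code{X} through the
#' scenario map, risk scores \code{r = X'beta + intercept + b}, event times
#' by inverse transform under the unit exponential baseline
#' (\code{T = -log(V) exp(-r)}, \code{V ~ U(0,1)}) and censoring times
#' \code{C ~ Uniform(0, censor_upper)}.  Ties between \code{T} and \code{C}
#' (measure zero) resolve to an event.
#'
#' The returned table carries the columns every fitted model sees
#' (\code{cluster}, \code{time}, \code{status}, \code{m1..mp}) plus
#' oracle columns available only because the data are simulated:
#' \code{risk} (the true risk score), \code{frailty} (the cluster's
#' \code{b_i}), \code{x1..xq} (the effective covariates) and
#' \code{true_time} (the latent event time).  Fitted models observe the raw
#' \code{M}; \code{X} exists only for the true-model oracle.
#'
#' @param config A \code{\link{scenario_config}}.
#' @return A \code{data.frame} of class \code{"clustered_survival"}.
#' @export
simulate_clusters <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  s <- config$n_clusters
  size_rng <- config$cluster_size_range[1]:config$cluster_size_range[2]
  sizes <- size_rng[sample.int(length(size_rng), s, replace = TRUE)]
  n <- sum(sizes)
  cluster <- rep.int(seq_len(s), sizes)
  b <- if (config$theta > 0) rnorm(s, 0, sqrt(config$theta)) else numeric(s)

  if (config$scenario == 1L) {
    p <- 5L
    M <- matrix(rnorm(n * p), n, p)
    X <- transform_covariates_s1(M)
    r <- drop(X %*% rep(0.5, 5L)) - 3 + b[cluster]
  } else {
    p <- 15L
    mu <- c(1, 1, 1, 2, 2, 3, 3, 3, rep(0, 7))
    M <- matrix(rnorm(n * p), n, p) + matrix(mu, n, p, byrow = TRUE)
    M[, 8] <- as.numeric(M[, 8] < 1)
    X <- transform_covariates_s2(M)
    r <- drop(X %*% rep(1, 4L)) - 4 + b[cluster]
  }

  T_ev <- -log(runif(n)) * exp(-r)
  C <- if (is.finite(config$censor_upper))
    runif(n, 0, config$censor_upper) else rep(Inf, n)
  U <- pmin(T_ev, C)
  status <- as.integer(T_ev <= C)

  colnames(M) <- paste0("m", seq_len(p))
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- data.frame(cluster = cluster, time = U, status = status, M,
                    risk = r, frailty = b[cluster], X, true_time = T_ev)
  class(out) <- c("clustered_survival", "data.frame")
  out
}

#' Split a clustered dataset within each cluster
#'
#' Randomly assigns \code{round(train_fraction * n_i)} subjects of every
#' cluster to the training half (at least one subject on each side), so both
#' halves contain every cluster.  This mirrors the within-cluster prediction
#' setting: test subjects belong to clusters whose frailty estimate is
#' available from training.
#'
#' @param data A clustered survival \code{data.frame} with a \code{cluster}
#'   column.
#' @param train_fraction Fraction in (0,1); 0.5 gives the 50/50 split used by
#'   the simulation benchmark, 0.8 the 80/20 split used for registry-style
#'   analyses.
#' @param seed Optional integer seed.
#' @return A list with components \code{train} and \code{test}.
#' @export
split_within_cluster <- function(data, train_fraction = 0.5, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0,1)")
  if (!is.null(seed)) set.seed(seed)
  sizes <- table(data$cluster)
  if (any(sizes < 2L))
    stop("cluster(s) of size 1 cannot be split within-cluster: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  idx <- seq_len(nrow(data))
  train_idx <- unlist(lapply(split(idx, data$cluster), function(ii) {
    k <- round(train_fraction * length(ii))
    k <- min(max(k, 1L), length(ii) - 1L)
    sample(ii, k)
  }), use.names = FALSE)
  train_sel <- idx %in% train_idx
  out <- list(train = data[train_sel, , drop = FALSE],
              test = data[!train_sel, , drop = FALSE])
  out$train <- `rownames<-`(out$train, NULL)
  out$test <- `rownames<-`(out$test, NULL)
  out
}

#' Realized censoring fraction of a dataset
#'
#' @param data A clustered survival data.frame with a \code{status} column.
#' @return Fraction of rows with \code{status == 0}.
#' @export
censoring_rate <- function(data) mean(data$status == 0)
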