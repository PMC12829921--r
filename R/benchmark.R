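#' Replicated simulation benchmark
#'
#' For each replicate: simulate a clustered dataset, split every cluster
#' 50/50 (configurable) into train and test, fit each requested method on
#' the training half, and score the test half with Harrell's concordance
#' index.  Per-replicate seeds are derived from the master seed so any
#' replicate is reproducible in isolation, and every method within a
#' replicate sees the identical split (paired comparisons).  A method
#' failure yields an \code{NA} cell, not an aborted sweep.
#'
#' @param scenario 1 or 2.
#' @param theta Frailty variance.
#' @param n_replicates Number of simulation replicates.
#' @param methods Character vector from \code{\link{benchmark_methods}}.
#' @param seed Master seed.
#' @param net_config,tr_config Configurations passed to the network-based
#'   methods (defaults: the benchmark protocol).
#' @param train_fraction Within-cluster training fraction.
#' @param n_clusters,cluster_size_range Generator geometry.
#' @return A \code{"benchmark_report"} data.frame with columns
#'   \code{scenario}, \code{theta}, \code{method}, \code{replicate},
#'   \code{c_index} (on [0, 1]); \code{summary()} reports mean and sd on
#'   the conventional x100 scale.
#' @export
run_benchmark <- function(scenario, theta, n_replicates = 10L,
                          methods = c("cox", "true_model"), seed = 1L,
                          net_config = NULL, tr_config = NULL,
                          train_fraction = 0.5, n_clusters = 200L,
                          cluster_size_range = c(20L, 100L)) {
  reg <- method_registry()
  unknown <- setdiff(methods, names(reg))
  if (length(unknown))
    stop("unknown method(s): ", paste(unknown, collapse = ", "),
         "; valid: ", paste(names(reg), collapse = ", "))
  rows <- list()
  for (k in seq_len(n_replicates)) {
    rs <- as.integer(seed + 9973L * k)
    cfg <- scenario_config(scenario, n_clusters = n_clusters,
                           cluster_size_range = cluster_size_range,
                           theta = theta, seed = rs)
    dat <- simulate_clusters(cfg)
    sp <- split_within_cluster(dat, train_fraction, seed = rs + 1L)
    for (m in methods) {
      tc <- if (is.null(tr_config)) train_config(seed = rs + 2L)
      else { t2 <- tr_config; t2$seed <- rs + 2L; t2 }
      ci <- tryCatch({
        scores <- reg[[m]](sp$train, sp$test, net_config, tc)
        c_index(sp$test$time, sp$test$status, scores)$c_index
      }, error = function(e) {
        warning("method '", m, "' failed in replicate ", k, ": ",
                conditionMessage(e))
        NA_real_
      })
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = scenario, theta = theta, method = m,
                   replicate = k, c_index = ci)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_report", "data.frame")
  out
}

#' @export
summary.benchmark_report <- function(object, ...) {
  agg <- do.call(rbind, lapply(split(object, object$method), function(d)
    data.frame(scenario = d$scenario[1], theta = d$theta[1],
               method = d$method[1], n_replicates = nrow(d),
               mean_c_index = 100 * mean(d$c_index, na.rm = TRUE),
               sd_c_index = 100 * stats::sd(d$c_index, na.rm = TRUE),
               n_failed = sum(is.na(d$c_index)))))
  agg <- agg[order(match(agg$method, unique(object$method))), ]
  rownames(agg) <- NULL
  agg
}

#' @export
print.benchmark_report <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Benchmark: scenario %d, theta = %g, %d replicate(s)\n",
              s$scenario[1], s$theta[1], max(x$replicate)))
  cat("Mean C-index (x100, sd in brackets):\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-16s %6.2f (%.2f)%s\n", s$method[i], s$mean_c_index[i],
                s$sd_c_index[i],
                if (s$n_failed[i]) sprintf("  [%d failed]", s$n_failed[i])
                else ""))
  invisible(x)
}
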