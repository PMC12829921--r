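#' Write a clustered survival dataset to CSV
#'
#' Schema: \code{cluster,time,status,m1..mp} plus, for simulated data, the
#' oracle columns \code{risk,frailty,x1..xq}.
#'
#' @param data Clustered survival data.frame.
#' @param path Output path.
#' @export
write_dataset <- function(data, path) {
  keep <- intersect(c("cluster", "time", "status",
                      grep("^m[0-9]+$", names(data), value = TRUE),
                      "risk", "frailty",
                      grep("^x[0-9]+$", names(data), value = TRUE)),
                    names(data))
  utils::write.csv(data[, keep], path, row.names = FALSE)
}

#' Read a clustered survival dataset from CSV
#'
#' @param path CSV path with the schema of \code{\link{write_dataset}}.
#' @return A \code{"clustered_survival"} data.frame.
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path)
  need <- c("cluster", "time", "status")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("dataset is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!all(d$status %in% c(0L, 1L))) stop("status must be 0/1")
  if (any(d$time < 0)) stop("negative observed times")
  class(d) <- c("clustered_survival", "data.frame")
  d
}

#' Read a plain-text key: value configuration file
#'
#' @param path Path to a YAML-compatible "key: value" file.
#' @param allowed Optional character vector; unknown keys raise an error
#'   naming the offending key.
#' @return Named list.
#' @export
read_config <- function(path, allowed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(allowed)) {
    bad <- setdiff(names(cfg), allowed)
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(allowed, collapse = ", "))
  }
  cfg
}

#' Write a plain-text key: value configuration file
#' @param cfg Named list of scalar values.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) yaml::write_yaml(cfg, path)

#' Save / load a fitted-model checkpoint
#'
#' The checkpoint stores the full fitted object: network configuration,
#' weights and biases, output and per-cluster weights, frailty state,
#' Breslow baseline, preprocessing statistics and the cluster-id mapping.
#'
#' @param model A fitted model object.
#' @param path Checkpoint path.
#' @export
save_checkpoint <- function(model, path) saveRDS(model, path)

#' @rdname save_checkpoint
#' @return \code{load_checkpoint}: the fitted model object.
#' @export
load_checkpoint <- function(path) readRDS(path)
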