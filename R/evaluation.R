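#' Harrell's concordance index
#'
#' Rank agreement between predicted risk scores and observed survival:
#' usable pairs are those where the subject with the smaller observed time
#' has an event (pairs tied on time are usable only when exactly one is an
#' event); a pair is concordant when the earlier event carries the higher
#' risk score, and score ties count one half.  0.5 is random ranking, 1
#' perfect.  Computed through the concordance machinery of the survival
#' package, which implements exactly these (Harrell) conventions.
#'
#' @param time Observed times.
#' @param status Event indicators (0/1).
#' @param scores Predicted risk scores (higher = earlier failure expected).
#' @return List with \code{c_index} and \code{n_usable_pairs}.
#' @export
c_index <- function(time, status, scores) {
  stopifnot(length(time) == length(status), length(time) == length(scores))
  cc <- survival::concordance(survival::Surv(time, status) ~ scores,
                              reverse = TRUE)
  cnt <- cc$count
  usable <- sum(cnt[c("concordant", "discordant", "tied.x")])
  if (usable == 0) stop("no usable pairs for the concordance index")
  list(c_index = unname(cc$concordance), n_usable_pairs = unname(usable))
}

#' Kaplan-Meier estimator of the censoring distribution
#'
#' \eqn{\hat G(t) = \hat P(C > t)}: the Kaplan-Meier estimator applied with
#' the censoring indicator \eqn{1 - \Delta} as the event.  Supports
#' left-limit evaluation \eqn{\hat G(t^-)} as needed by the inverse
#' probability of censoring weights.
#'
#' @inheritParams c_index
#' @return Object of class \code{"censor_survfit"}.
#' @export
km_censoring_survival <- function(time, status) {
  stopifnot(length(time) == length(status))
  fit <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  structure(list(times = fit$time, surv = fit$surv), class = "censor_survfit")
}

#' Evaluate the censoring-survival estimator
#'
#' @param G A \code{"censor_survfit"}.
#' @param t Evaluation times.
#' @param left \code{TRUE} evaluates the left limit \eqn{\hat G(t^-)}.
#' @return Numeric vector of survival probabilities.
#' @export
censor_survival_at <- function(G, t, left = FALSE) {
  stopifnot(inherits(G, "censor_survfit"))
  idx <- if (left) findInterval(t, G$times, left.open = TRUE)
  else findInterval(t, G$times)
  c(1, G$surv)[idx + 1L]
}

#' IPCW time-dependent Brier score
#'
#' Mean squared error between the survival status \eqn{Y_i(t) = I(U_i > t)}
#' and the predicted survival probability at \eqn{t}, reweighted for
#' censoring by inverse probability weights
#' \deqn{\hat W_i(t) = \frac{(1 - Y_i(t))\,\delta_i}{\hat G(U_i^-)} +
#'   \frac{Y_i(t)}{\hat G(t)}.}
#' Subjects censored before \eqn{t} receive weight zero.  0 is perfect
#' prediction.
#'
#' @param t Evaluation time.
#' @param S_hat Predicted survival probabilities at \eqn{t}, one per
#'   subject, in [0, 1].
#' @param time,status Observed test times and event indicators.
#' @param G Censoring-survival estimator
#'   (\code{\link{km_censoring_survival}}); defaults to the estimator from
#'   \code{time}, \code{status} themselves.
#' @return Scalar Brier score.
#' @export
brier_score <- function(t, S_hat, time, status, G = NULL) {
  stopifnot(length(S_hat) == length(time), length(time) == length(status))
  if (any(S_hat < 0 | S_hat > 1)) stop("S_hat must lie in [0, 1]")
  if (is.null(G)) G <- km_censoring_survival(time, status)
  Gt <- censor_survival_at(G, t)
  if (Gt <= 0)
    stop("censoring-survival estimate is zero at t = ", t,
         "; the Brier score is undefined there")
  Y <- as.numeric(time > t)
  Gu <- censor_survival_at(G, time, left = TRUE)
  w_event <- (1 - Y) * status / pmax(Gu, .Machine$double.eps)
  w_alive <- Y / Gt
  mean((w_event + w_alive) * (Y - S_hat)^2)
}

#' Discrimination and calibration metrics for one method
#'
#' Computes the concordance index of the risk scores on the test set and,
#' when a fitted model with survival predictions is supplied, the IPCW
#' Brier curve on a time grid (default: deciles of observed test event
#' times, truncated where the censoring-survival estimate drops below
#' 0.05).  The censoring distribution is estimated on the test set.
#'
#' @param x Either a numeric risk-score vector aligned with \code{test}, or
#'   a fitted model with \code{\link{predict_risk}} (and, for the Brier
#'   curve, \code{\link{predict_survival}}) methods.
#' @param test Test data.
#' @param times Optional Brier time grid.
#' @param label Method label stored in the result.
#' @return Object of class \code{"eval_result"}: \code{c_index},
#'   \code{n_usable_pairs}, \code{brier} (data.frame time/score or NULL),
#'   \code{label}.
#' @export
evaluate_method <- function(x, test, times = NULL, label = NULL) {
  scores <- if (is.numeric(x)) x else predict_risk(x, test)
  ci <- c_index(test$time, test$status, scores)
  brier <- NULL
  if (!is.numeric(x) && !is.null(x$baseline)) {
    G <- km_censoring_survival(test$time, test$status)
    if (is.null(times)) {
      ev <- test$time[test$status == 1]
      times <- unname(stats::quantile(ev, probs = seq(0.1, 0.9, by = 0.1)))
      times <- times[censor_survival_at(G, times) >= 0.05]
    }
    if (length(times)) {
      S <- predict_survival(x, test, times)
      brier <- data.frame(time = times,
                          score = vapply(seq_along(times), function(j)
                            brier_score(times[j], S[, j], test$time,
                                        test$status, G), numeric(1)))
    }
  }
  structure(list(c_index = ci$c_index,
                 n_usable_pairs = ci$n_usable_pairs,
                 brier = brier,
                 label = if (is.null(label) && !is.numeric(x))
                   x$label else label),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("C-index: %.4f (%d usable pairs)\n", x$c_index,
              x$n_usable_pairs))
  if (!is.null(x$brier)) {
    cat("IPCW Brier score:\n")
    print(x$brier, row.names = FALSE)
  }
  invisible(x)
}
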