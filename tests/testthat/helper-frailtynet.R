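# Shared helpers: independent oracles and small data builders.

# O(n^2) enumeration of Harrell's concordance with the package's tie
# conventions: usable pairs have the earlier subject as an event (tied
# times usable only when exactly one is an event); score ties count 0.5.
brute_force_cindex <- function(time, status, scores) {
  conc <- 0; usable <- 0
  n <- length(time)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (time[i] == time[j]) {
      if (status[i] + status[j] != 1L) next
      e <- if (status[i] == 1L) i else j
      o <- if (status[i] == 1L) j else i
    } else {
      e <- if (time[i] < time[j]) i else j
      o <- if (time[i] < time[j]) j else i
      if (status[e] != 1L) next
    }
    usable <- usable + 1
    conc <- conc + (scores[e] > scores[o]) + 0.5 * (scores[e] == scores[o])
  }
  list(c_index = conc / usable, n_usable_pairs = usable)
}

# clustered data from a *linear* frailty Cox model (unit exponential
# baseline), for recovery and equivalence checks
sim_linear_clustered <- function(s, size, beta, theta, cens_upper,
                                 seed, mnames = TRUE) {
  set.seed(seed)
  n <- s * size
  cl <- rep(seq_len(s), each = size)
  b <- if (theta > 0) rnorm(s, 0, sqrt(theta)) else numeric(s)
  M <- matrix(rnorm(n * length(beta)), n, length(beta))
  colnames(M) <- paste0("m", seq_along(beta))
  r <- drop(M %*% beta) + b[cl]
  T_ev <- -log(runif(n)) * exp(-r)
  C <- runif(n, 0, cens_upper)
  d <- data.frame(cluster = cl, time = pmin(T_ev, C),
                  status = as.integer(T_ev <= C), M,
                  risk = r, frailty = b[cl])
  d
}

# central finite differences of a scalar function of a parameter list
fd_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

small_train_config <- function(seed = 1L, epochs = 20L, ...) {
  train_config(epochs = epochs, batch_size = 64L, theta_burnin = 8L,
               seed = seed, ...)
}
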