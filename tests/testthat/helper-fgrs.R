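# Shared fixture builders (everything is generated in code).

# A tiny uniform fingerprint axis.
toy_axis <- function(n = 141, lo = 400, hi = 1800) {
  seq(lo, hi, length.out = n)
}

# One spectrum from a numeric vector.
toy_spectrum <- function(y, wn = seq_along(y), id = "s1", label = NA) {
  spectra_from_matrix(matrix(y, ncol = 1), wn, sample_id = id, label = label)
}

# A small two-class set of Gaussian-band spectra with noise.
toy_set <- function(n_per_class = 4, n_chan = 101, noise_sd = 0.02,
                    delta = 0, seed = 1) {
  wn <- seq(400, 1800, length.out = n_chan)
  base <- 0.2 + 0.8 * exp(-0.5 * ((wn - 1655) / 40)^2) +
    exp(-0.5 * ((wn - 1449) / 40)^2)
  withr::with_seed(seed, {
    mk <- function(extra, n) {
      vapply(seq_len(n), function(i) base + extra + rnorm(n_chan, 0, noise_sd),
             numeric(n_chan))
    }
    bump <- delta * exp(-0.5 * ((wn - 1003) / 10)^2)
    m <- cbind(mk(bump, n_per_class), mk(0, n_per_class))
  })
  spectra_from_matrix(
    m, wn,
    sample_id = sprintf("s%02d", seq_len(2 * n_per_class)),
    label = rep(c("high", "low"), each = n_per_class)
  )
}

# Small-scale generator config for fast tests.
toy_synth_config <- function(...) {
  synth_config(n_per_class = 12, seed = 7, ...)
}

# Exhaustive prominence oracle: for each strict/plateau-leftmost local
# maximum, scan outward for the nearest higher terrain on each side and take
# the minima in between; prominence is height above the higher of the two.
oracle_peaks <- function(y, prominence_min) {
  n <- length(y)
  out <- list()
  i <- 2L
  while (i < n) {
    # leftmost channel of a plateau local maximum
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1L
    if (j < n && y[i] > y[i - 1] && y[i] > y[j + 1]) {
      left <- y[seq_len(i - 1)]
      higher_l <- which(left > y[i])
      lmin <- min(left[seq(from = if (length(higher_l)) max(higher_l) + 1 else 1,
                           to = i - 1)])
      right <- y[(j + 1):n]
      higher_r <- which(right > y[i])
      rmin <- min(right[seq_len(if (length(higher_r)) min(higher_r) - 1 else length(right))])
      prom <- y[i] - max(lmin, rmin)
      if (prom >= prominence_min) {
        out[[length(out) + 1L]] <- c(channel = i, prominence = prom)
      }
    }
    i <- j + 1L
  }
  if (length(out) == 0) {
    matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("channel", "prominence")))
  } else {
    do.call(rbind, out)
  }
}

# Exact Mann-Whitney two-sided p by full enumeration of group assignments.
oracle_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Dense reference solver for the AsLS normal equations, independent of the
# banded C++ path: explicit solve of (W + lam * t(D) %*% D) z = W y with the
# same asymmetric weight iteration.
dense_asls <- function(y, lam, p, max_iter = 20, tol = 1e-6) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lam * crossprod(D)
  w <- rep(1, n)
  for (it in seq_len(max_iter)) {
    z <- solve(diag(w) + P, w * y)
    w_new <- ifelse(y > z, p, 1 - p)
    if (max(abs(w_new - w)) <= tol) break
    w <- w_new
  }
  z
}
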