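# Preprocessing: fingerprint crop, AsLS baseline, cosmic-ray rejection,
# max-intensity normalization.

#' Preprocessing configuration
#'
#' Bundles the parameters of the preprocessing chain, applied in fixed order:
#' crop to the fingerprint region, asymmetric-least-squares (AsLS) baseline
#' subtraction, cosmic-ray rejection against the Amide I reference intensity,
#' and normalization. Cosmic rays are judged on the baseline-corrected,
#' pre-normalization scale.
#'
#' @param crop_lo,crop_hi Fingerprint region limits in cm^-1.
#' @param lam AsLS smoothness penalty weight (> 0) on squared second
#'   differences of the baseline.
#' @param asym_p AsLS asymmetry weight in (0, 1): residuals above the
#'   baseline get weight `asym_p`, residuals below get `1 - asym_p`.
#' @param max_iter,tol AsLS weight-iteration cap and convergence tolerance
#'   (maximum absolute weight change).
#' @param amide_lo,amide_hi Window (cm^-1) defining the Amide I reference
#'   intensity for cosmic-ray rejection.
#' @param spike_max_width Maximum full width (in channels, at half
#'   prominence) for a peak to count as a cosmic-ray spike.
#' @param despike Whether to run cosmic-ray rejection.
#' @param normalize `"max"` (divide by the greatest spectral intensity, the
#'   default), `"l2"` (unit Euclidean norm) or `"none"`.
#' @return A list of class `fgrs_preprocess_config`.
#' @export
preprocess_config <- function(crop_lo = 400, crop_hi = 1800,
                              lam = 1e5, asym_p = 0.01,
                              max_iter = 20, tol = 1e-6,
                              amide_lo = 1640, amide_hi = 1680,
                              spike_max_width = 3, despike = TRUE,
                              normalize = c("max", "l2", "none")) {
  normalize <- match.arg(normalize)
  .assert_scalar_number(lam, "lam", lower = 0, strict_lower = TRUE)
  .assert_scalar_number(asym_p, "asym_p", lower = 0, upper = 1, strict_lower = TRUE)
  if (asym_p >= 1) abort("`asym_p` must be in (0, 1)")
  .assert_scalar_number(max_iter, "max_iter", lower = 1)
  .assert_scalar_number(tol, "tol", lower = 0)
  .assert_scalar_number(spike_max_width, "spike_max_width", lower = 1)
  if (crop_lo >= crop_hi) abort("`crop_lo` must be < `crop_hi`")
  if (amide_lo >= amide_hi) abort("`amide_lo` must be < `amide_hi`")
  structure(
    list(crop_lo = crop_lo, crop_hi = crop_hi, lam = lam, asym_p = asym_p,
         max_iter = max_iter, tol = tol, amide_lo = amide_lo,
         amide_hi = amide_hi, spike_max_width = spike_max_width,
         despike = despike, normalize = normalize),
    class = "fgrs_preprocess_config"
  )
}

#' Crop spectra to the fingerprint region
#'
#' @param x An `fgrs_spectra` tibble.
#' @param lo,hi Inclusive wavenumber limits in cm^-1.
#' @return Spectra restricted to channels with `lo <= wavenumber <= hi`.
#' @export
crop_fingerprint <- function(x, lo = 400, hi = 1800) {
  if (lo >= hi) abort("`lo` must be < `hi`")
  x <- as_spectra(x)
  keep <- x$wavenumber >= lo & x$wavenumber <= hi
  if (!any(keep)) {
    abort(sprintf("empty crop: no channels in [%g, %g] cm^-1", lo, hi))
  }
  as_spectra(x[keep, ])
}

#' Asymmetric least squares baseline correction
#'
#' Estimates a smooth baseline z minimizing
#' `sum_i w_i (y_i - z_i)^2 + lam * sum_j (d2 z_j)^2` where `d2` is the
#' second difference, iterating the asymmetric weights
#' `w_i <- asym_p` if `y_i > z_i` else `1 - asym_p` until they stop changing
#' (or `max_iter`). Large positive excursions (Raman bands) are thereby
#' ignored while the broad fluorescence background is tracked.
#'
#' @inheritParams preprocess_config
#' @param x An `fgrs_spectra` tibble.
#' @return The spectra with `intensity` replaced by the baseline-corrected
#'   signal and an added `baseline` column; per-sample iteration counts are
#'   in `attr(, "iterations")`.
#' @export
asls_correct <- function(x, lam = 1e5, asym_p = 0.01, max_iter = 20,
                         tol = 1e-6) {
  x <- as_spectra(x)
  if (any(!is.finite(x$intensity))) abort("non-finite intensities in input")
  m <- spectra_matrix(x)
  fit <- .asls_baseline_mat_cpp(unclass(m)[, , drop = FALSE], lam, asym_p,
                                as.integer(max_iter), tol)
  out <- x
  out$baseline <- as.numeric(fit$baseline)
  out$intensity <- x$intensity - out$baseline
  attr(out, "iterations") <- setNames(fit$iterations, colnames(m))
  out
}

# --- internal vector/matrix machinery -------------------------------------

# Leftmost channel of every (plateau) local maximum.
.local_maxima <- function(y) {
  r <- rle(y)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  inner <- 2:(k - 1)
  is_max <- r$values[inner] > r$values[inner - 1] &
    r$values[inner] > r$values[inner + 1]
  starts[inner][is_max]
}

# Topographic prominence of the local maximum at channel i, plus its bases
# (positions of the minima between the peak and the nearest higher terrain
# or signal end on each side).
.peak_prominence <- function(y, i) {
  n <- length(y)
  h <- y[[i]]
  lmin <- Inf; lbase <- i
  j <- i - 1L
  while (j >= 1L && y[[j]] <= h) {
    if (y[[j]] < lmin) { lmin <- y[[j]]; lbase <- j }
    j <- j - 1L
  }
  rmin <- Inf; rbase <- i
  j <- i + 1L
  while (j <= n && y[[j]] <= h) {
    if (y[[j]] < rmin) { rmin <- y[[j]]; rbase <- j }
    j <- j + 1L
  }
  # an axis-boundary peak (despiking only) is bounded by its one real side
  if (i == 1L) lmin <- -Inf
  if (i == n) rmin <- -Inf
  list(prominence = h - max(lmin, rmin), left_base = lbase, right_base = rbase)
}

# Contiguous channel span around peak i with y >= (h - prominence / 2).
.half_prominence_span <- function(y, i, prominence) {
  level <- y[[i]] - prominence / 2
  n <- length(y)
  kl <- i
  while (kl > 1L && y[[kl - 1L]] >= level) kl <- kl - 1L
  kr <- i
  while (kr < n && y[[kr + 1L]] >= level) kr <- kr + 1L
  c(kl, kr)
}

# Cosmic-ray rejection on one baseline-corrected spectrum. A spike is a
# local maximum that is sharp (half-prominence span <= max_width channels)
# and whose height AND prominence both exceed the Amide I reference
# intensity; the reference is the window maximum computed with all sharp
# candidate spans interpolated out, so spikes landing inside the window do
# not mask themselves. Spikes are replaced by linear interpolation across
# their span; the scan repeats until no spike remains (idempotent).
.despike_vec <- function(y, amide_idx, max_width) {
  removed <- integer(0)
  repeat {
    ref0 <- max(y[amide_idx])
    n_chan <- length(y)
    cand <- c(if (y[[1]] > y[[2]]) 1L,
              .local_maxima(y),
              if (y[[n_chan]] > y[[n_chan - 1L]]) n_chan)
    cand <- cand[y[cand] >= ref0]
    if (length(cand) == 0) break
    info <- lapply(cand, function(i) {
      pk <- .peak_prominence(y, i)
      span <- .half_prominence_span(y, i, pk$prominence)
      list(channel = i, prominence = pk$prominence, span = span,
           width = span[2] - span[1] + 1L)
    })
    sharp <- info[vapply(info, function(p) p$width <= max_width, logical(1))]
    excl <- unlist(lapply(sharp, function(p) p$span[1]:p$span[2]))
    keep <- setdiff(amide_idx, excl)
    ref <- if (length(keep) > 0) max(y[keep]) else ref0
    spikes <- sharp[vapply(
      sharp, function(p) y[[p$channel]] > ref && p$prominence > ref, logical(1)
    )]
    if (length(spikes) == 0) break
    for (p in spikes) {
      kl <- p$span[1]; kr <- p$span[2]
      l <- kl - 1L; r <- kr + 1L
      n <- length(y)
      if (l < 1L && r > n) next
      yl <- if (l >= 1L) y[[l]] else y[[r]]
      yr <- if (r <= n) y[[r]] else y[[l]]
      idx <- kl:kr
      y[idx] <- yl + (yr - yl) * (idx - l) / (r - l)
      removed <- c(removed, p$channel)
    }
  }
  list(y = y, removed = removed)
}

.despike_mat <- function(m, axis, amide_lo, amide_hi, max_width) {
  amide_idx <- which(axis >= amide_lo & axis <= amide_hi)
  if (length(amide_idx) == 0) {
    abort(sprintf("Amide window [%g, %g] cm^-1 is outside the axis",
                  amide_lo, amide_hi))
  }
  spikes <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    res <- .despike_vec(m[, j], amide_idx, max_width)
    m[, j] <- res$y
    spikes[[j]] <- res$removed
  }
  list(m = m, spikes = spikes)
}

#' Remove cosmic-ray spikes
#'
#' Cosmic rays are sharp peaks (at most `max_width` channels wide at half
#' prominence) whose height and topographic prominence both exceed the
#' Amide I reference intensity (the maximum within `amide_lo`--`amide_hi`,
#' computed with sharp candidate peaks excluded). Detected spikes are
#' replaced by linear interpolation across their span; the operation is
#' idempotent.
#'
#' @inheritParams preprocess_config
#' @param x An `fgrs_spectra` tibble (typically baseline corrected).
#' @param max_width Sharpness bound in channels.
#' @return Cleaned spectra; removed spike positions are reported in
#'   `attr(, "spikes")` (tibble: `sample_id`, `channel`, `wavenumber`) and
#'   counts in `attr(, "n_removed")`.
#' @export
remove_cosmic_rays <- function(x, amide_lo = 1640, amide_hi = 1680,
                               max_width = 3) {
  x <- as_spectra(x)
  m <- spectra_matrix(x)
  axis <- attr(m, "wavenumber")
  res <- .despike_mat(unclass(m)[, , drop = FALSE], axis, amide_lo, amide_hi,
                      max_width)
  out <- x
  out$intensity <- as.numeric(res$m)
  ids <- colnames(m)
  spikes <- tibble(
    sample_id = rep(ids, lengths(res$spikes)),
    channel = unlist(res$spikes) %||% integer(0),
    wavenumber = axis[unlist(res$spikes) %||% integer(0)]
  )
  attr(out, "spikes") <- spikes
  attr(out, "n_removed") <- setNames(lengths(res$spikes), ids)
  out
}

#' Normalize spectra
#'
#' The default divides each spectrum by its greatest intensity, so the
#' maximum of every normalized spectrum is exactly 1; `"l2"` divides by the
#' Euclidean norm instead.
#'
#' @param x An `fgrs_spectra` tibble.
#' @param method `"max"` or `"l2"`.
#' @return Normalized spectra; per-sample divisors in `attr(, "scale")`.
#' @export
normalize_spectra <- function(x, method = c("max", "l2")) {
  method <- match.arg(method)
  x <- as_spectra(x)
  m <- spectra_matrix(x)
  res <- .normalize_mat(unclass(m)[, , drop = FALSE], method)
  out <- x
  out$intensity <- as.numeric(res$m)
  attr(out, "scale") <- setNames(res$scale, colnames(m))
  out
}

.normalize_mat <- function(m, method) {
  s <- switch(method,
    max = apply(m, 2, max),
    l2 = sqrt(colSums(m^2))
  )
  bad <- which(s <= 0)
  if (length(bad) > 0) {
    abort(sprintf("normalization error: spectrum '%s' has non-positive %s",
                  colnames(m)[bad[1]] %||% bad[1],
                  if (method == "max") "maximum" else "norm"))
  }
  list(m = sweep(m, 2, s, "/"), scale = s)
}

# Full matrix-level preprocessing chain shared by preprocess_spectra() and
# the synthetic-data recovery loop.
.preprocess_matrix <- function(m, axis, config) {
  keep <- which(axis >= config$crop_lo & axis <= config$crop_hi)
  if (length(keep) == 0) {
    abort(sprintf("empty crop: no channels in [%g, %g] cm^-1",
                  config$crop_lo, config$crop_hi))
  }
  m <- m[keep, , drop = FALSE]
  axis <- axis[keep]
  fit <- .asls_baseline_mat_cpp(m, config$lam, config$asym_p,
                                as.integer(config$max_iter), config$tol)
  m <- m - fit$baseline
  if (isTRUE(config$despike)) {
    ds <- .despike_mat(m, axis, config$amide_lo, config$amide_hi,
                       config$spike_max_width)
    m <- ds$m
    spikes <- ds$spikes
  } else {
    spikes <- rep(list(integer(0)), ncol(m))
  }
  scale <- rep(NA_real_, ncol(m))
  if (config$normalize != "none") {
    nm <- .normalize_mat(m, config$normalize)
    m <- nm$m
    scale <- nm$scale
  }
  list(m = m, axis = axis, iterations = fit$iterations, spikes = spikes,
       scale = scale)
}

#' Preprocess a set of spectra
#'
#' Applies the full chain with one shared configuration: crop to the
#' fingerprint region, AsLS baseline subtraction, cosmic-ray rejection on
#' the baseline-corrected (pre-normalization) scale, then normalization.
#'
#' @param x An `fgrs_spectra` tibble.
#' @param config A [preprocess_config()].
#' @return Preprocessed spectra with a per-spectrum processing log in
#'   `attr(, "log")` (`sample_id`, `asls_iterations`, `n_cosmic_removed`,
#'   `norm_scale`).
#' @export
preprocess_spectra <- function(x, config = preprocess_config()) {
  stopifnot(inherits(config, "fgrs_preprocess_config"))
  x <- as_spectra(x)
  if (any(!is.finite(x$intensity))) {
    bad <- x$sample_id[which(!is.finite(x$intensity))[1]]
    abort(sprintf("non-finite intensity in spectrum '%s'", bad))
  }
  m <- spectra_matrix(x)
  res <- .preprocess_matrix(unclass(m)[, , drop = FALSE],
                            attr(m, "wavenumber"), config)
  ids <- colnames(m)
  out <- spectra_from_matrix(res$m, res$axis, sample_id = ids,
                             label = unname(attr(m, "labels")))
  attr(out, "log") <- tibble(
    sample_id = ids,
    asls_iterations = as.integer(res$iterations),
    n_cosmic_removed = lengths(res$spikes),
    norm_scale = unname(res$scale)
  )
  out
}
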