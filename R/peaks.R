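# Topographic-prominence peak detection and band-intensity extraction.

.find_peaks_vec <- function(y, wn, prominence_min) {
  if (length(y) < 3) abort("find_peaks needs at least 3 channels")
  .assert_scalar_number(prominence_min, "prominence_min", lower = 0,
                        strict_lower = TRUE)
  if (any(!is.finite(y))) abort("non-finite intensities in input")
  maxima <- .local_maxima(y)
  rows <- lapply(maxima, function(i) {
    pk <- .peak_prominence(y, i)
    tibble(channel = i, wavenumber = wn[[i]], height = y[[i]],
           prominence = pk$prominence, left_base = pk$left_base,
           right_base = pk$right_base)
  })
  out <- if (length(rows) == 0) {
    tibble(channel = integer(), wavenumber = double(), height = double(),
           prominence = double(), left_base = integer(), right_base = integer())
  } else {
    dplyr::bind_rows(rows)
  }
  out[out$prominence >= prominence_min, ]
}

#' Find peaks by topographic prominence
#'
#' Detects local maxima and keeps those whose topographic prominence (height
#' above the higher of the two lowest saddles separating the peak from
#' higher terrain, or from the signal ends) reaches `prominence_min`.
#' Plateau maxima are reported at their leftmost channel. Prominence is
#' invariant to adding a constant to the whole signal, and raising
#' `prominence_min` can only remove peaks.
#'
#' @param x A numeric intensity vector or an `fgrs_spectra` tibble
#'   (peaks are found per spectrum; spectra are typically max-normalized so
#'   prominence is on the normalized intensity scale).
#' @param prominence_min Minimum prominence (> 0), e.g. 0.01 for mean-spectrum
#'   comparisons or 0.05 for noisier cell-line spectra.
#' @param ... Passed between methods.
#' @return A tibble with one row per retained peak: `channel`, `wavenumber`,
#'   `height`, `prominence`, `left_base`, `right_base` (and `sample_id` for
#'   spectra input), ordered by wavenumber; the threshold used is stored in
#'   `attr(, "prominence_threshold")`.
#' @export
find_peaks <- function(x, prominence_min, ...) UseMethod("find_peaks")

#' @rdname find_peaks
#' @param wavenumber Axis values for vector input (defaults to channel index).
#' @export
find_peaks.numeric <- function(x, prominence_min, wavenumber = seq_along(x),
                               ...) {
  out <- .find_peaks_vec(x, wavenumber, prominence_min)
  attr(out, "prominence_threshold") <- prominence_min
  out
}

#' @rdname find_peaks
#' @export
find_peaks.data.frame <- function(x, prominence_min, ...) {
  x <- as_spectra(x)
  m <- spectra_matrix(x)
  wn <- attr(m, "wavenumber")
  out <- purrr::map_dfr(colnames(m), function(id) {
    dplyr::mutate(.find_peaks_vec(m[, id], wn, prominence_min),
                  sample_id = id, .before = 1)
  })
  attr(out, "prominence_threshold") <- prominence_min
  out
}

.band_window_idx <- function(axis, lo, hi, half_window, name = NULL) {
  if (lo == hi) {
    lo <- lo - half_window
    hi <- hi + half_window
  }
  idx <- which(axis >= lo & axis <= hi)
  if (length(idx) == 0) {
    abort(sprintf("band %s[%g, %g] cm^-1 lies outside the wavenumber axis",
                  if (is.null(name)) "" else paste0("'", name, "' "), lo, hi))
  }
  idx
}

.band_intensity_matrix <- function(m, axis, panel, half_window) {
  out <- matrix(NA_real_, nrow = nrow(panel), ncol = ncol(m),
                dimnames = list(panel$name, colnames(m)))
  for (b in seq_len(nrow(panel))) {
    idx <- .band_window_idx(axis, panel$lo[[b]], panel$hi[[b]], half_window,
                            panel$name[[b]])
    sub <- m[idx, , drop = FALSE]
    out[b, ] <- apply(sub, 2, max)
  }
  out
}

#' Extract band intensities
#'
#' For every spectrum and every band of the panel, returns the maximum
#' intensity over the band's channels. Point bands (`lo == hi`) are expanded
#' by `half_window` on each side; range bands use their printed range as is.
#'
#' @param x An `fgrs_spectra` tibble (typically preprocessed).
#' @param panel An [band_panel()]; defaults to the packaged panel.
#' @param half_window Extraction half-window in cm^-1 for point bands.
#' @return A tibble with columns `sample_id`, `label`, `band`, `assignment`,
#'   `intensity`.
#' @export
band_intensity <- function(x, panel = default_band_panel(), half_window = 4) {
  x <- as_spectra(x)
  m <- spectra_matrix(x)
  bm <- .band_intensity_matrix(unclass(m)[, , drop = FALSE],
                               attr(m, "wavenumber"), panel, half_window)
  labs <- attr(m, "labels")
  tibble(
    sample_id = rep(colnames(m), each = nrow(panel)),
    label = rep(unname(labs), each = nrow(panel)),
    band = rep(panel$name, times = ncol(m)),
    assignment = rep(panel$assignment, times = ncol(m)),
    intensity = as.numeric(bm)
  )
}

#' Compare peak presence between two mean spectra
#'
#' Finds peaks in both spectra at a common prominence threshold and flags
#' each peak position as `shared` (matched within `match_tol` cm^-1),
#' `unique_a`, or `unique_b`. Matching is greedy by increasing center
#' distance.
#'
#' @param a,b Single-spectrum `fgrs_spectra` tibbles on the same axis
#'   (typically group mean spectra).
#' @param prominence_min Prominence threshold applied to both spectra.
#' @param match_tol Maximum center distance (cm^-1) for two peaks to count
#'   as the same band.
#' @return A tibble with `wavenumber` (matched peaks: midpoint),
#'   `wavenumber_a`, `wavenumber_b`, `prominence_a`, `prominence_b`, `flag`.
#' @export
compare_peak_presence <- function(a, b, prominence_min, match_tol = 5) {
  a <- as_spectra(a); b <- as_spectra(b)
  if (length(unique(a$sample_id)) != 1 || length(unique(b$sample_id)) != 1) {
    abort("compare_peak_presence expects one (mean) spectrum per input")
  }
  if (!identical(spectra_axis(a), spectra_axis(b))) {
    abort("axis mismatch between the two spectra")
  }
  pa <- find_peaks(a, prominence_min)
  pb <- find_peaks(b, prominence_min)
  na <- nrow(pa); nb <- nrow(pb)
  matched_a <- rep(FALSE, na); matched_b <- rep(FALSE, nb)
  pairs <- list()
  if (na > 0 && nb > 0) {
    d <- abs(outer(pa$wavenumber, pb$wavenumber, "-"))
    repeat {
      d_open <- d
      d_open[matched_a, ] <- Inf
      d_open[, matched_b] <- Inf
      if (all(!is.finite(d_open)) || min(d_open) > match_tol) break
      ij <- which(d_open == min(d_open), arr.ind = TRUE)[1, ]
      matched_a[ij[1]] <- TRUE; matched_b[ij[2]] <- TRUE
      pairs[[length(pairs) + 1L]] <- tibble(
        wavenumber = (pa$wavenumber[[ij[1]]] + pb$wavenumber[[ij[2]]]) / 2,
        wavenumber_a = pa$wavenumber[[ij[1]]],
        wavenumber_b = pb$wavenumber[[ij[2]]],
        prominence_a = pa$prominence[[ij[1]]],
        prominence_b = pb$prominence[[ij[2]]],
        flag = "shared"
      )
    }
  }
  only_a <- tibble(
    wavenumber = pa$wavenumber[!matched_a],
    wavenumber_a = pa$wavenumber[!matched_a],
    wavenumber_b = NA_real_,
    prominence_a = pa$prominence[!matched_a],
    prominence_b = NA_real_,
    flag = if (any(!matched_a)) "unique_a" else character(0)
  )
  only_b <- tibble(
    wavenumber = pb$wavenumber[!matched_b],
    wavenumber_a = NA_real_,
    wavenumber_b = pb$wavenumber[!matched_b],
    prominence_a = NA_real_,
    prominence_b = pb$prominence[!matched_b],
    flag = if (any(!matched_b)) "unique_b" else character(0)
  )
  out <- dplyr::bind_rows(pairs, only_a, only_b)
  dplyr::arrange(out, .data$wavenumber)
}
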