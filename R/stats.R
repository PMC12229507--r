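# Group summaries, difference spectra, double-SD channel selection,
# Mann-Whitney tests and Cohen's d effect sizes.

#' Per-channel mean and standard deviation of one class
#'
#' @param x An `fgrs_spectra` tibble.
#' @param label Class label to summarize (needs at least 2 spectra).
#' @return A tibble of class `fgrs_group_summary` with columns `wavenumber`,
#'   `mean`, `sd` (sample SD, n - 1 denominator); the label and spectra
#'   count are stored as attributes `label` and `n`.
#' @export
group_mean_sd <- function(x, label) {
  x <- as_spectra(x)
  sub <- x[!is.na(x$label) & x$label == label, ]
  n <- length(unique(sub$sample_id))
  if (n < 2) {
    abort(sprintf("label '%s' has %d spectra; need at least 2", label, n))
  }
  m <- spectra_matrix(as_spectra(sub))
  out <- tibble(
    wavenumber = attr(m, "wavenumber"),
    mean = rowMeans(m),
    sd = apply(m, 1, sd)
  )
  attr(out, "label") <- label
  attr(out, "n") <- n
  class(out) <- unique(c("fgrs_group_summary", class(out)))
  out
}

#' Summaries for every class in a spectra set
#'
#' @param x An `fgrs_spectra` tibble.
#' @return Named list of [group_mean_sd()] results, one per label.
#' @export
group_summaries <- function(x) {
  labs <- unique(x$label[!is.na(x$label)])
  setNames(lapply(labs, function(l) group_mean_sd(x, l)), labs)
}

#' Absolute difference of two group mean spectra
#'
#' @param a,b [group_mean_sd()] summaries on the same axis.
#' @return A tibble with `wavenumber` and `intensity = |mean_a - mean_b|`.
#' @export
abs_diff_spectrum <- function(a, b) {
  if (!identical(a$wavenumber, b$wavenumber)) {
    abort("axis mismatch between group summaries")
  }
  tibble(wavenumber = a$wavenumber, intensity = abs(a$mean - b$mean))
}

#' Double-standard-deviation channel selection
#'
#' Selects the Raman shifts whose between-class absolute mean difference
#' exceeds a scalar threshold: `multiplier` times the across-channel SD of
#' the absolute-difference spectrum (a single horizontal cutoff). The
#' alternative `per_channel` rule compares each channel's difference to
#' `multiplier` times its pooled between-class SD instead.
#'
#' @param a,b [group_mean_sd()] summaries on the same axis.
#' @param multiplier Threshold multiplier (> 0), 2 for the double-SD rule.
#' @param method `"scalar"` (default) or `"per_channel"`.
#' @return A tibble of class `fgrs_feature_mask` with `wavenumber` and
#'   logical `selected`; `attr(, "threshold_value")` (scalar rule) and
#'   `attr(, "n_selected")` record the cutoff and count.
#' @export
double_sd_mask <- function(a, b, multiplier = 2,
                           method = c("scalar", "per_channel")) {
  method <- match.arg(method)
  .assert_scalar_number(multiplier, "multiplier", lower = 0, strict_lower = TRUE)
  diff <- abs_diff_spectrum(a, b)
  if (method == "scalar") {
    thr <- multiplier * sd(diff$intensity)
    selected <- diff$intensity > thr
  } else {
    na <- attr(a, "n"); nb <- attr(b, "n")
    pooled <- sqrt(((na - 1) * a$sd^2 + (nb - 1) * b$sd^2) / (na + nb - 2))
    thr <- multiplier * pooled
    selected <- diff$intensity > thr
  }
  out <- tibble(wavenumber = diff$wavenumber, selected = selected)
  attr(out, "threshold_value") <- thr
  attr(out, "n_selected") <- sum(selected)
  class(out) <- unique(c("fgrs_feature_mask", class(out)))
  out
}

#' Mann-Whitney U test (Wilcoxon rank sum) for two independent samples
#'
#' U is computed from midranks. For small samples (both sizes at most
#' `exact_max`) the two-sided p-value is obtained by exact enumeration of
#' all group assignments of the observed values (ties included); otherwise
#' a normal approximation with tie correction and continuity correction is
#' used. `U_x + U_y = n_x * n_y` always holds.
#'
#' @param x,y Numeric samples (band intensities of the two classes).
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`) exact
#'   enumeration.
#' @param exact_max Largest per-group size for automatic exact enumeration.
#' @return A list with `u` (U statistic of `x`), `u_y`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL, exact_max = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) abort("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) abort("samples must be finite")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u_y <- nx * ny - u_x
  if (is.null(exact)) exact <- nx <= exact_max && ny <= exact_max
  mu <- nx * ny / 2
  if (exact) {
    # Null distribution of U over all C(nx+ny, nx) assignments of the
    # observed (mid)ranks to group x; symmetric about nx*ny/2 by the
    # order-reversal bijection, so two-sided p doubles/reflects cleanly.
    combos <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_x - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_x - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation with tie correction"
  }
  list(u = u_x, u_y = u_y, p_value = p, method = method)
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with
#' `s_pooled^2 = ((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2)`.
#' The sign follows `x - y`; tables report the magnitude `|d|`.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @return Signed effect size (a single number).
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("need at least 2 values per sample")
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 <= 0) abort("undefined effect size: pooled SD is zero")
  (mean(x) - mean(y)) / sqrt(sp2)
}

.stars <- function(p) {
  dplyr::case_when(
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Band-wise statistics table
#'
#' For every band of the panel, extracts per-spectrum band intensities
#' ([band_intensity()]), then reports group means/SDs, the Mann-Whitney U
#' rank-sum test and the pooled-SD Cohen's d for `labels[1]` vs `labels[2]`.
#' Stars encode `* p < 0.05`, `** p <= 1e-2`, `*** p <= 1e-3` (no
#' multiple-testing correction, matching common practice for band panels).
#'
#' @param x A preprocessed `fgrs_spectra` tibble.
#' @param labels Character vector of the two class labels to compare;
#'   defaults to the two labels present.
#' @param panel An [band_panel()].
#' @param half_window Extraction half-window (cm^-1) for point bands.
#' @return A tibble of class `fgrs_band_stats`: `band`, `assignment`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `u_stat`, `p_value`, `d`, `d_abs`,
#'   `stars`.
#' @export
band_stats_table <- function(x, labels = NULL, panel = default_band_panel(),
                             half_window = 4) {
  x <- as_spectra(x)
  present <- unique(x$label[!is.na(x$label)])
  if (is.null(labels)) {
    if (length(present) != 2) {
      abort("`labels` must be given unless exactly two labels are present")
    }
    labels <- present
  }
  if (!all(labels %in% present)) {
    abort(sprintf("label '%s' not present in the data",
                  labels[!labels %in% present][1]))
  }
  bi <- band_intensity(x, panel, half_window)
  rows <- purrr::map_dfr(seq_len(nrow(panel)), function(b) {
    sub <- bi[bi$band == panel$name[[b]], ]
    ia <- sub$intensity[sub$label == labels[[1]]]
    ib <- sub$intensity[sub$label == labels[[2]]]
    mw <- mann_whitney_u(ia, ib)
    # A band whose window contains the normalization maximum has intensity
    # exactly 1 in every spectrum; d is then 0 (identical constants) rather
    # than an error, +/-Inf if the constants differ.
    sp2 <- ((length(ia) - 1) * var(ia) + (length(ib) - 1) * var(ib)) /
      (length(ia) + length(ib) - 2)
    d <- if (sp2 > 0) cohens_d(ia, ib) else
      sign(mean(ia) - mean(ib)) * c(0, Inf)[(mean(ia) != mean(ib)) + 1]
    tibble(
      band = panel$name[[b]], assignment = panel$assignment[[b]],
      mean_a = mean(ia), sd_a = sd(ia),
      mean_b = mean(ib), sd_b = sd(ib),
      u_stat = mw$u, p_value = mw$p_value,
      d = d, d_abs = abs(d), stars = .stars(mw$p_value)
    )
  })
  attr(rows, "labels") <- labels
  class(rows) <- unique(c("fgrs_band_stats", class(rows)))
  rows
}
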