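# Spectra container: a long-format tibble with one row per (sample, channel).

#' Build a spectra table from a long data frame
#'
#' The package represents a set of single-cell Raman spectra as a long tibble
#' with columns `sample_id`, `label`, `wavenumber` (Raman shift, cm^-1) and
#' `intensity` (arbitrary units). All spectra must share one strictly
#' increasing wavenumber axis; the constructor enforces this and orders rows
#' by sample (in first-appearance order) and wavenumber.
#'
#' @param x A data frame with columns `sample_id`, `wavenumber`, `intensity`
#'   and optionally `label`.
#' @return A tibble of class `fgrs_spectra`.
#' @export
as_spectra <- function(x) {
  x <- as_tibble(x)
  required <- c("sample_id", "wavenumber", "intensity")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("spectra table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"label" %in% names(x)) x$label <- NA_character_
  if (!is.numeric(x$wavenumber) || !is.numeric(x$intensity)) {
    abort("`wavenumber` and `intensity` must be numeric")
  }
  if (nrow(x) == 0) abort("spectra table is empty")
  x$sample_id <- as.character(x$sample_id)
  x$label <- as.character(x$label)

  ids <- unique(x$sample_id)
  x <- x[order(match(x$sample_id, ids), x$wavenumber),
         c("sample_id", "label", "wavenumber", "intensity")]
  n_per_id <- tabulate(match(x$sample_id, ids), nbins = length(ids))
  axis <- x$wavenumber[seq_len(n_per_id[[1]])]
  if (length(axis) < 2) abort("wavenumber axis must have at least 2 channels")
  if (any(!is.finite(axis)) || any(diff(axis) <= 0)) {
    abort("wavenumber axis must be finite and strictly increasing")
  }
  if (any(n_per_id != length(axis))) {
    bad <- ids[which(n_per_id != length(axis))[1]]
    abort(sprintf("axis mismatch: spectrum '%s' is not on the shared wavenumber axis", bad))
  }
  off <- which(x$wavenumber != rep(axis, times = length(ids)))
  if (length(off) > 0) {
    abort(sprintf("axis mismatch: spectrum '%s' is not on the shared wavenumber axis",
                  x$sample_id[[off[1]]]))
  }
  new_spectra(x)
}

new_spectra <- function(x) {
  class(x) <- unique(c("fgrs_spectra", class(as_tibble(x))))
  x
}

#' Assemble spectra from an intensity matrix
#'
#' @param m Numeric matrix, channels in rows, one spectrum per column.
#' @param wavenumber Strictly increasing numeric axis, one value per row of `m`.
#' @param sample_id Optional sample identifiers (defaults to column names or
#'   `spec_1 ...`).
#' @param label Optional class label per spectrum (recycled if length 1).
#' @return An [as_spectra()] tibble.
#' @export
spectra_from_matrix <- function(m, wavenumber, sample_id = NULL, label = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != length(wavenumber)) {
    abort("`wavenumber` must have one value per row of `m`")
  }
  if (is.null(sample_id)) {
    sample_id <- colnames(m) %||% sprintf("spec_%03d", seq_len(ncol(m)))
  }
  if (is.null(label)) label <- NA_character_
  label <- rep_len(as.character(label), ncol(m))
  out <- tibble(
    sample_id = rep(as.character(sample_id), each = nrow(m)),
    label = rep(label, each = nrow(m)),
    wavenumber = rep(as.numeric(wavenumber), times = ncol(m)),
    intensity = as.numeric(m)
  )
  as_spectra(out)
}

#' Extract the channels-by-samples intensity matrix of a spectra table
#'
#' @param x An `fgrs_spectra` tibble.
#' @return Numeric matrix (channels x samples) with the axis in
#'   `attr(, "wavenumber")` and per-sample labels in `attr(, "labels")`.
#' @export
spectra_matrix <- function(x) {
  x <- as_spectra(x)
  ids <- unique(x$sample_id)
  axis <- spectra_axis(x)
  m <- matrix(x$intensity, nrow = length(axis), ncol = length(ids),
              dimnames = list(NULL, ids))
  attr(m, "wavenumber") <- axis
  attr(m, "labels") <- setNames(
    x$label[!duplicated(x$sample_id)], ids
  )
  m
}

#' Shared wavenumber axis of a spectra table
#' @param x An `fgrs_spectra` tibble.
#' @return Strictly increasing numeric vector of Raman shifts (cm^-1).
#' @export
spectra_axis <- function(x) {
  sort(unique(x$wavenumber))
}

#' Per-sample class labels of a spectra table
#' @param x An `fgrs_spectra` tibble.
#' @return Named character vector (names are sample ids).
#' @export
spectra_labels <- function(x) {
  setNames(x$label[!duplicated(x$sample_id)], unique(x$sample_id))
}

#' Validate a spectra table without modifying it
#'
#' Reports per-spectrum violations: non-finite intensities, wavenumber axes
#' that differ from the first spectrum's axis, and (when `label_set` is
#' declared) missing labels or labels outside the declared set. An empty
#' report means the table is valid.
#'
#' @param x A data frame in the long spectra layout (it need not already be a
#'   valid `fgrs_spectra` object).
#' @param label_set Optional character vector of allowed class labels.
#' @return A tibble with columns `sample_id` and `issue`, one row per
#'   violation.
#' @export
validate_spectra <- function(x, label_set = NULL) {
  x <- as_tibble(x)
  if (!"label" %in% names(x)) x$label <- NA_character_
  issues <- list()
  ids <- unique(x$sample_id)
  ref_axis <- NULL
  for (id in ids) {
    rows <- x[x$sample_id == id, ]
    wn <- sort(rows$wavenumber)
    if (is.null(ref_axis)) ref_axis <- wn
    if (any(!is.finite(rows$intensity))) {
      issues[[length(issues) + 1L]] <-
        tibble(sample_id = id, issue = "non-finite intensity")
    }
    if (length(wn) != length(ref_axis) || any(wn != ref_axis)) {
      issues[[length(issues) + 1L]] <-
        tibble(sample_id = id, issue = "axis mismatch")
    }
    lab <- rows$label[[1]]
    if (!is.null(label_set)) {
      if (is.na(lab)) {
        issues[[length(issues) + 1L]] <-
          tibble(sample_id = id, issue = "missing label")
      } else if (!lab %in% label_set) {
        issues[[length(issues) + 1L]] <-
          tibble(sample_id = id, issue = sprintf("label '%s' outside declared set", lab))
      }
    }
  }
  if (length(issues) == 0) {
    tibble(sample_id = character(), issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Read spectra from a delimited text file
#'
#' Two CSV dialects are supported. `wide`: first column is the wavenumber
#' axis, each further column one spectrum (column order becomes spectrum
#' order; no labels). `long`: columns `sample_id`, `wavenumber`, `intensity`
#' and optionally `label`.
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator).
#' @param dialect `"wide"` or `"long"`.
#' @return An [as_spectra()] tibble.
#' @export
read_spectra_table <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "wide") {
    # parse problems are escalated to errors below; silence readr's warning
    raw <- suppressWarnings(
      readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                      progress = FALSE)
    )
    .stop_on_parse_problems(raw, path)
    if (ncol(raw) < 2) abort("wide spectra file needs a wavenumber column plus at least one spectrum")
    m <- as.matrix(raw[, -1, drop = FALSE])
    spectra_from_matrix(m, wavenumber = raw[[1]], sample_id = names(raw)[-1])
  } else {
    raw <- suppressWarnings(readr::read_csv(
      path,
      col_types = readr::cols(
        sample_id = readr::col_character(),
        wavenumber = readr::col_double(),
        intensity = readr::col_double(),
        .default = readr::col_character()
      ),
      progress = FALSE
    ))
    .stop_on_parse_problems(raw, path)
    as_spectra(raw)
  }
}

.stop_on_parse_problems <- function(raw, path) {
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("parse error in %s at row %d: expected %s, got '%s'",
                  path, probs$row[[1]], probs$expected[[1]], probs$actual[[1]]))
  }
  invisible(raw)
}

#' Write spectra to a delimited text file
#'
#' Numbers are written with shortest round-trip precision, so
#' `read_spectra_table(write_spectra_table(x))` reproduces intensities
#' exactly. Labels are only representable in the `long` dialect.
#'
#' @param x An `fgrs_spectra` tibble.
#' @inheritParams read_spectra_table
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  x <- as_spectra(x)
  if (dialect == "wide") {
    m <- spectra_matrix(x)
    out <- as_tibble(as.data.frame(m))
    out <- dplyr::bind_cols(tibble(wavenumber = attr(m, "wavenumber")), out)
    readr::write_csv(out, path, progress = FALSE)
  } else {
    readr::write_csv(x[, c("sample_id", "wavenumber", "intensity", "label")],
                     path, progress = FALSE)
  }
  invisible(path)
}

#' @export
print.fgrs_spectra <- function(x, ...) {
  ids <- unique(x$sample_id)
  axis <- spectra_axis(x)
  labs <- spectra_labels(x)
  cat(sprintf("<fgrs_spectra: %d spectra x %d channels (%.1f-%.1f cm^-1)>\n",
              length(ids), length(axis), min(axis), max(axis)))
  tab <- table(labs, useNA = "ifany")
  cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  NextMethod()
}
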