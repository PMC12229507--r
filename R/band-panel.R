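# Band panel: named Raman shifts with molecular assignments.

#' Load a band panel from a CSV file
#'
#' A band panel names the Raman shifts at which band intensities are
#' extracted. Each row is one band with columns `name`, `lo`, `hi`
#' (cm^-1; point bands have `lo == hi`) and `assignment` (one of
#' `protein`, `nucleic_acid`, `lipid`, `other`).
#'
#' @param path CSV file; defaults to the packaged fingerprint panel of 19
#'   bands (glycogen 480 through the amide I region 1654-1660 and the lipid
#'   C=C band at 1660).
#' @return A tibble of class `fgrs_band_panel`.
#' @export
load_band_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "band_panel.csv", package = "fgrs",
                        mustWork = TRUE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      name = readr::col_character(),
      lo = readr::col_double(),
      hi = readr::col_double(),
      assignment = readr::col_character()
    ),
    progress = FALSE
  )
  .stop_on_parse_problems(raw, path)
  band_panel(raw$name, raw$lo, raw$hi, raw$assignment)
}

#' Construct a band panel
#'
#' @param name Unique band names.
#' @param lo,hi Band limits in cm^-1; `lo == hi` encodes a point band.
#' @param assignment Molecular class per band: `protein`, `nucleic_acid`,
#'   `lipid` or `other`.
#' @return A tibble of class `fgrs_band_panel`.
#' @export
band_panel <- function(name, lo, hi = lo, assignment = "other") {
  out <- tibble(
    name = as.character(name),
    lo = as.numeric(lo),
    hi = as.numeric(hi),
    assignment = rep_len(as.character(assignment), length(name))
  )
  if (anyDuplicated(out$name)) {
    abort(sprintf("duplicate band name(s): %s",
                  paste(unique(out$name[duplicated(out$name)]), collapse = ", ")))
  }
  bad <- which(out$lo > out$hi)
  if (length(bad) > 0) {
    abort(sprintf("band '%s' has lo > hi (%g > %g)",
                  out$name[[bad[1]]], out$lo[[bad[1]]], out$hi[[bad[1]]]))
  }
  allowed <- c("protein", "nucleic_acid", "lipid", "other")
  if (!all(out$assignment %in% allowed)) {
    abort(sprintf("assignment must be one of: %s", paste(allowed, collapse = ", ")))
  }
  class(out) <- unique(c("fgrs_band_panel", class(out)))
  out
}

#' @rdname load_band_panel
#' @export
default_band_panel <- function() load_band_panel()
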