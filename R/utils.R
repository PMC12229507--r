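# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed, all < 2^31.
.child_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                  strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    abort(sprintf("`%s` = %g is outside its valid range", name, x))
  }
  invisible(x)
}

# Pseudo-Voigt profile: eta * Lorentzian + (1 - eta) * Gaussian, unit height,
# full width at half maximum `fwhm` (shared by both components).
.pseudo_voigt <- function(x, center, fwhm, eta = 0.5) {
  u <- (x - center) / (fwhm / 2)
  g <- exp(-log(2) * u^2)
  l <- 1 / (1 + u^2)
  eta * l + (1 - eta) * g
}
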