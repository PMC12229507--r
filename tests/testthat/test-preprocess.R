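test_that("AsLS reproduces a constant spectrum exactly (fixed point)", {
  x <- toy_spectrum(rep(3.7, 50))
  out <- asls_correct(x)
  expect_lt(max(abs(out$baseline - 3.7)), 1e-8)
  expect_lt(max(abs(out$intensity)), 1e-8)
})

test_that("AsLS with a vanishing penalty returns the signal itself", {
  set.seed(1)
  y <- runif(80)
  out <- asls_correct(toy_spectrum(y), lam = 1e-12)
  expect_lt(max(abs(out$baseline - y)), 1e-6)
})

test_that("banded AsLS solver agrees with a dense direct solve", {
  set.seed(7)
  for (k in 1:20) {
    n <- sample(30:120, 1)
    y <- cumsum(rnorm(n)) + 5 * exp(-0.5 * ((seq_len(n) - n / 2) / 3)^2)
    lam <- 10^runif(1, 0, 6)
    out <- asls_correct(toy_spectrum(y), lam = lam)
    ref <- dense_asls(y, lam, 0.01)
    expect_lt(max(abs(out$baseline - ref)) / max(abs(ref)), 1e-6)
  }
})

test_that("AsLS baseline is translation-equivariant", {
  set.seed(2)
  y <- runif(60) + seq(0, 2, length.out = 60)
  b0 <- asls_correct(toy_spectrum(y))$baseline
  b1 <- asls_correct(toy_spectrum(y + 11.5))$baseline
  expect_lt(max(abs(b1 - (b0 + 11.5))), 1e-8)
})

test_that("AsLS tracks a linear ramp under an isolated peak", {
  n <- 200
  ramp <- seq(0, 1, length.out = n)
  y <- ramp + 10 * exp(-0.5 * ((seq_len(n) - 100) / 4)^2)
  out <- asls_correct(toy_spectrum(y), lam = 1e4)
  off_peak <- c(1:70, 130:n)
  expect_lt(max(abs(out$baseline[off_peak] - ramp[off_peak])), 0.1)
  expect_gt(out$intensity[100], 9)
})

test_that("crop_fingerprint keeps exactly the in-range channels", {
  x <- toy_spectrum(rep(1, 291), wn = seq(100, 3000, by = 10))
  cropped <- crop_fingerprint(x, 400, 1800)
  expect_length(spectra_axis(cropped), 141)
  expect_equal(range(spectra_axis(cropped)), c(400, 1800))

  inside <- toy_spectrum(rep(1, 50), wn = seq(500, 1700, length.out = 50))
  expect_equal(spectra_axis(crop_fingerprint(inside, 400, 1800)),
               spectra_axis(inside))

  expect_error(crop_fingerprint(x, 5000, 6000), "empty crop")
})

make_despike_fixture <- function() {
  wn <- seq(400, 1800, length.out = 571)
  y <- 0.05 + 0.8 * exp(-0.5 * ((wn - 1655) / 12)^2) +
    0.5 * exp(-0.5 * ((wn - 1003) / 8)^2)
  list(wn = wn, y = y)
}

test_that("clean spectra pass through despiking unchanged", {
  f <- make_despike_fixture()
  x <- toy_spectrum(f$y, f$wn)
  out <- remove_cosmic_rays(x)
  expect_equal(out$intensity, x$intensity)
  expect_equal(unname(attr(out, "n_removed")), 0L)
})

test_that("a single-channel spike at twice Amide I is removed and interpolated", {
  f <- make_despike_fixture()
  y <- f$y
  amide_ref <- max(y[f$wn >= 1640 & f$wn <= 1680])
  spike_at <- 250
  y[spike_at] <- y[spike_at] + 2 * amide_ref
  out <- remove_cosmic_rays(toy_spectrum(y, f$wn))
  expect_equal(unname(attr(out, "n_removed")), 1L)
  expect_equal(attr(out, "spikes")$channel, spike_at)
  expect_equal(out$intensity[spike_at],
               (f$y[spike_at - 1] + f$y[spike_at + 1]) / 2, tolerance = 1e-8)
  # nothing else moved
  expect_equal(out$intensity[-spike_at], f$y[-spike_at])
})

test_that("broad peaks taller than Amide I are retained", {
  f <- make_despike_fixture()
  y <- f$y + 2 * exp(-0.5 * ((f$wn - 900) / 60)^2)  # ~20 channels at half height
  out <- remove_cosmic_rays(toy_spectrum(y, f$wn))
  expect_equal(unname(attr(out, "n_removed")), 0L)
})

test_that("despiking is idempotent and catches spikes inside the Amide window", {
  f <- make_despike_fixture()
  y <- f$y
  amide_ref <- max(y[f$wn >= 1640 & f$wn <= 1680])
  in_window <- which(f$wn >= 1644 & f$wn <= 1650)[1]
  y[c(100, in_window)] <- y[c(100, in_window)] + 2.5 * amide_ref
  once <- remove_cosmic_rays(toy_spectrum(y, f$wn))
  expect_equal(unname(attr(once, "n_removed")), 2L)
  twice <- remove_cosmic_rays(once)
  expect_equal(twice$intensity, once$intensity)
  expect_equal(unname(attr(twice, "n_removed")), 0L)
})

test_that("despiking errors when the Amide window misses the axis", {
  x <- toy_spectrum(rep(1, 30), wn = seq(400, 800, length.out = 30))
  expect_error(remove_cosmic_rays(x), "outside the axis")
})

test_that("max normalization yields unit maxima and is scale invariant", {
  set.seed(3)
  y <- runif(50, 0.1, 2)
  n1 <- normalize_spectra(toy_spectrum(y))
  expect_equal(max(n1$intensity), 1)
  n7 <- normalize_spectra(toy_spectrum(7 * y))
  expect_equal(n7$intensity, n1$intensity)

  l2 <- normalize_spectra(toy_spectrum(y), method = "l2")
  expect_equal(sum(l2$intensity^2), 1)

  expect_error(normalize_spectra(toy_spectrum(rep(0, 20))), "non-positive")
})

test_that("preprocess_spectra composes the chain with a per-spectrum log", {
  x <- toy_set(n_per_class = 5)
  pp <- preprocess_spectra(x)
  maxima <- tapply(pp$intensity, pp$sample_id, max)
  expect_true(all(abs(maxima - 1) < 1e-12))
  log <- attr(pp, "log")
  expect_equal(nrow(log), 10)
  expect_true(all(log$n_cosmic_removed == 0))
  expect_true(all(log$asls_iterations >= 1))
})

test_that("the processing log attributes spikes to the right sample", {
  x <- toy_set(n_per_class = 3, noise_sd = 0.001)
  inj <- inject_cosmic_rays(x, amp_factor = 2, seed = 5, n_spikes = c(1, 0, 0, 0, 0, 0))
  pp <- preprocess_spectra(inj$spectra)
  log <- attr(pp, "log")
  spiked <- inj$positions$sample_id
  expect_equal(log$n_cosmic_removed[log$sample_id == spiked], 1L)
  expect_true(all(log$n_cosmic_removed[log$sample_id != spiked] == 0L))
})

test_that("the Amide threshold is applied before normalization", {
  # a spike at 1.5x the corrected Amide I maximum is far below the
  # post-normalization ceiling of 1; it must still be detected because
  # despiking precedes normalization
  f <- make_despike_fixture()
  y <- f$y
  amide_ref <- max(y[f$wn >= 1640 & f$wn <= 1680])
  y[120] <- y[120] + 1.5 * amide_ref
  cfg <- preprocess_config(lam = 1e5)
  pp <- preprocess_spectra(toy_spectrum(y, f$wn), cfg)
  expect_equal(attr(pp, "log")$n_cosmic_removed, 1L)
  expect_equal(max(pp$intensity), 1)
})

test_that("preprocessing an empty set errors", {
  expect_error(preprocess_spectra(tibble::tibble(
    sample_id = character(), wavenumber = double(), intensity = double()
  )), "empty")
})
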