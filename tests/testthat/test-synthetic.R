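test_that("generation is bitwise deterministic given a seed", {
  cfg <- toy_synth_config()
  a <- generate_dataset(cfg, seed = 123)
  b <- generate_dataset(cfg, seed = 123)
  expect_identical(a, b)
  c <- generate_dataset(cfg, seed = 124)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("noise_sd scales the per-channel spread of the generated set", {
  cfg1 <- synth_config(n_per_class = 95, cosmic_rate = 0, noise_sd = 0.01)
  cfg10 <- synth_config(n_per_class = 95, cosmic_rate = 0, noise_sd = 0.1)
  m1 <- spectra_matrix(generate_dataset(cfg1, seed = 5))
  m10 <- spectra_matrix(generate_dataset(cfg10, seed = 5))
  # per-channel SD across the high class only (no between-class component)
  sd1 <- apply(unclass(m1)[, 1:95], 1, sd)
  sd10 <- apply(unclass(m10)[, 1:95], 1, sd)
  expect_lt(abs(median(sd10 / sd1) - 10), 1)
})

test_that("cosmic_rate 0 produces spectra with no despiking events", {
  cfg <- toy_synth_config(cosmic_rate = 0)
  x <- generate_dataset(cfg, seed = 9)
  expect_equal(nrow(attr(x, "truth")$spikes), 0)
  pp <- preprocess_spectra(x)
  expect_equal(sum(attr(pp, "log")$n_cosmic_removed), 0)
})

test_that("injected spikes are exactly recovered by despiking", {
  cfg <- toy_synth_config(cosmic_rate = 0)
  x <- generate_dataset(cfg, seed = 10)
  inj <- inject_cosmic_rays(x, amp_factor = 2, seed = 11, n_spikes = 1)
  expect_equal(nrow(inj$positions), length(unique(x$sample_id)))
  cleaned <- remove_cosmic_rays(asls_correct(inj$spectra)[, 1:4])
  found <- attr(cleaned, "spikes")
  merged <- dplyr::inner_join(inj$positions, found,
                              by = c("sample_id", "channel"))
  expect_equal(nrow(merged), nrow(inj$positions))
  expect_equal(nrow(found), nrow(inj$positions))
})

test_that("spikes always land inside the axis", {
  cfg <- toy_synth_config()
  x <- generate_dataset(cfg, seed = 12)
  inj <- inject_cosmic_rays(x, rate = 3, seed = 13)
  expect_true(all(inj$positions$channel >= 1))
  expect_true(all(inj$positions$channel <= length(spectra_axis(x))))
  none <- inject_cosmic_rays(x, rate = 0, seed = 14)
  expect_equal(nrow(none$positions), 0)
  expect_equal(none$spectra$intensity, x$intensity)
})

test_that("zero targets calibrate to zero deltas", {
  cfg <- toy_synth_config()
  cfg$bands$target_d <- 0
  cal <- calibrate_band_deltas(cfg, n_reps = c(2, 2), seed = 15)
  expect_true(all(cal$bands$delta == 0))
})

test_that("calibration recovers a programmed effect size end to end", {
  # one driven band at a modest replicate budget; the acceptance suite runs
  # the full-scale version
  cfg <- synth_config(n_per_class = 40, seed = 16)
  cfg$bands$target_d <- ifelse(cfg$bands$name == "1336", 1, 0)
  cal <- calibrate_band_deltas(cfg, n_reps = c(12, 24), seed = 17)
  rec <- recover_band_effects(cal, n_reps = 40, seed = 18)
  got <- rec$mean_d_abs[rec$band == "1336"]
  expect_lt(abs(got - 1), 0.15)
  expect_true(all(rec$mean_d_abs[!rec$band %in% c("1336")] < 0.35))
})

test_that("the delta ~ d * noise_sd limit holds for an isolated clean band", {
  # single Gaussian band, flat zero background, extraction at the center,
  # no normalization: the recovered d equals delta / noise_sd as n grows
  bands <- tibble::tibble(name = "solo", center = 1100, base_amplitude = 0.5,
                          width_fwhm = 30, eta = 0, target_d = 1,
                          delta = 0.02)
  cfg <- synth_config(
    n_per_class = 400, bands = bands,
    background = list(high = background_spec("flat", 0),
                      low = background_spec("flat", 0)),
    noise_sd = 0.02, cosmic_rate = 0
  )
  panel <- band_panel("solo", 1100)
  pre <- preprocess_config(despike = FALSE, normalize = "none")
  rec <- recover_band_effects(cfg, n_reps = 30, seed = 19, panel = panel,
                              preprocess = pre, half_window = 1)
  expect_lt(abs(rec$mean_d_abs - 1), 0.12)
})

test_that("cell line profiles emit the full seven-set suite", {
  cfg <- toy_synth_config()
  cfg$bands$delta <- ifelse(cfg$bands$target_d > 0, 0.03, 0)
  sets <- make_cell_line_profiles(cfg, seed = 20)
  expect_named(sets, c("transfected", "control", "wildtype", "U87MG", "T98G",
                       "Ln229", "Ln18"))
  labs <- vapply(sets, function(s) unique(s$label), character(1))
  expect_equal(unname(labs[c("transfected", "U87MG")]),
               rep("high_cx43", 2))
  expect_equal(unname(labs[c("control", "wildtype", "T98G", "Ln229", "Ln18")]),
               rep("low_cx43", 5))
  prof <- attr(sets, "profiles")
  expect_equal(nrow(prof), 7)
  # null perturbation makes the wildtype set distributionally identical to
  # control: same generator mean, checked via the class mean spectra
  cfg0 <- toy_synth_config(cosmic_rate = 0)  # spikes would shift single-channel means
  sets0 <- make_cell_line_profiles(cfg0, amp_jitter = 0, background_shift = 0,
                                   n_per_line = 60, seed = 21)
  mc <- colMeans(t(spectra_matrix(sets0$control)))
  mw <- colMeans(t(spectra_matrix(sets0$wildtype)))
  noise_floor <- cfg0$noise_sd / sqrt(60)
  expect_lt(max(abs(mc - mw)), 6 * sqrt(2) * noise_floor)
})

test_that("a high-like cell line keeps the programmed amide contrast", {
  cfg <- synth_config(n_per_class = 60, seed = 22)
  cfg$bands$delta <- ifelse(cfg$bands$target_d > 0,
                            0.015 * cfg$bands$target_d, 0)
  sets <- make_cell_line_profiles(cfg, seed = 23)
  joint_tr <- as_spectra(dplyr::bind_rows(sets$transfected, sets$control))
  joint_t2 <- as_spectra(dplyr::bind_rows(sets$U87MG, sets$T98G))
  d_tr <- band_stats_table(preprocess_spectra(joint_tr),
                           labels = c("high_cx43", "low_cx43"))
  d_t2 <- band_stats_table(preprocess_spectra(joint_t2),
                           labels = c("high_cx43", "low_cx43"))
  amide_tr <- d_tr$d_abs[d_tr$band == "1654-1660"]
  amide_t2 <- d_t2$d_abs[d_t2$band == "1654-1660"]
  expect_gt(amide_t2, 0.3)
  expect_gt(amide_tr, 0.3)
})

test_that("generated sets validate and preprocess to unit maxima", {
  cfg <- toy_synth_config()
  x <- generate_dataset(cfg, seed = 24)
  expect_equal(nrow(validate_spectra(x, label_set = c("high_cx43", "low_cx43"))), 0)
  pp <- preprocess_spectra(x)
  expect_true(all(abs(tapply(pp$intensity, pp$sample_id, max) - 1) < 1e-12))
})
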