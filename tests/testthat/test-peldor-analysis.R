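study_timing <- function() peldor_timing(tau = 200, T2 = 1100, dt = 8,
                                         n_points = 148)

test_that("baseline correction annihilates an exact polynomial", {
  tm <- study_timing()
  t <- (0:147) * 8
  v <- 2 + 3e-3 * t - 1e-6 * t^2
  out <- correct_baseline(peldor_trace(tm, v), order = 2)
  expect_equal(out$v, rep(0, 148), tolerance = 1e-9)
  # corrected fit region has (numerically) zero mean
  expect_lt(abs(mean(out$v)), 1e-9 * diff(range(v)))
})

test_that("baseline correction removes exactly the least-squares polynomial part", {
  tm <- study_timing()
  t <- (0:147) * 8
  poly_part <- 1.5 - 2e-4 * t + 4e-7 * t^2
  cosine <- 0.3 * cos(2 * pi * 2.1 * (t - 200) * 1e-3)
  out <- correct_baseline(peldor_trace(tm, poly_part + cosine), order = 2)
  # independent normal-equations oracle on the summed signal
  expected <- (poly_part + cosine) -
    oracle_polyfit(t, poly_part + cosine, 2)
  expect_equal(out$v, expected, tolerance = 1e-8)
})

test_that("underdetermined baseline fits are refused", {
  tm <- peldor_timing(n_points = 8)
  tr <- peldor_trace(tm, rnorm(8))
  expect_error(correct_baseline(tr, order = 2, fit_start_fraction = 0.9),
               "fit region")
})

test_that("Hamming half-window keeps the first point and scales the last by 0.08", {
  tm <- study_timing()
  tr <- peldor_trace(tm, rep(1, 148))
  out <- apply_hamming(tr)
  expect_equal(out$v[1], 1.00)
  expect_equal(out$v[148], 0.08)
  # all-ones input returns the window itself
  k <- 0:147
  expect_equal(out$v, 0.54 + 0.46 * cos(pi * k / 147))
  # symmetric convention: both ends at 0.08, maximum at the centre
  full <- apply_hamming(tr, window = "full")
  expect_equal(full$v[1], 0.08)
  expect_equal(full$v[148], 0.08)
  expect_equal(which.max(full$v), 74, tolerance = 1)
})

test_that("zero filling appends zeros and preserves the acquired samples", {
  tm <- study_timing()
  v <- rnorm(148)
  tr <- peldor_trace(tm, v)
  out <- zero_fill(tr, 1024)
  expect_length(out$v, 1024)
  expect_identical(out$v[1:148], v)
  expect_identical(out$v[149:1024], rep(0, 876))
  expect_equal(diff(out$t), rep(8, 1023))
  expect_identical(zero_fill(tr, 148)$v, v)
  expect_error(zero_fill(tr, 100), "smaller")
})

test_that("cosine transform: resolution, peak position, zero input, linearity", {
  tm <- study_timing()
  t <- (0:147) * 8
  v <- cos(2 * pi * 2.1 * (t - 200) * 1e-3)
  spec <- cosine_transform(zero_fill(peldor_trace(tm, v), 1024))
  expect_equal(spec$resolution, 1e3 / (1024 * 8))
  expect_equal(round(spec$resolution, 4), 0.1221)
  # maximum lands on the grid frequency nearest 2.1 MHz
  expect_equal(spec$nu[which.max(spec$amp)], 2.1,
               tolerance = spec$resolution)
  # spot-check two bins against the loop-form direct summation oracle
  vz <- c(v, rep(0, 876)); tz <- (0:1023) * 8
  for (j in c(18, 40))
    expect_equal(spec$amp[j], oracle_cosine_amp(vz, tz, 200, spec$nu[j]),
                 tolerance = 1e-9)
  # all-zero trace -> all-zero spectrum
  z <- cosine_transform(peldor_trace(tm, rep(0, 148)))
  expect_true(all(z$amp == 0))
  # linearity
  v2 <- rnorm(148)
  sa <- cosine_transform(peldor_trace(tm, v))
  sb <- cosine_transform(peldor_trace(tm, v2))
  sab <- cosine_transform(peldor_trace(tm, 2 * v - 3 * v2))
  expect_equal(sab$amp, 2 * sa$amp - 3 * sb$amp, tolerance = 1e-9)
})

test_that("peak picking finds components and honours thresholds", {
  one <- analyze_peldor(
    simulate_peldor(data.frame(r_nm = 2.916, weight = 1),
                    collapse_theta = TRUE),
    baseline_order = 0)
  expect_equal(nrow(one$assignments), 1)
  expect_equal(one$assignments$nu_MHz, oracle_nu_perp(2.916),
               tolerance = one$spectrum$resolution)
  # flat spectrum yields nothing
  flat <- structure(list(nu = seq(0, 5, by = 0.1),
                         amp = rep(1, 51), amp_mag = rep(1, 51),
                         resolution = 0.1), class = "dipolar_spectrum")
  expect_equal(nrow(pick_peaks(flat)), 0)
  expect_error(pick_peaks(flat, min_rel_amplitude = 0), "min_rel_amplitude")
})

test_that("two-component resting-state emulation yields two peaks, slow one stronger", {
  tr <- simulate_peldor(data.frame(r_nm = c(4.703, 2.916),
                                   weight = c(0.75, 0.25)),
                        seed = 1, collapse_theta = TRUE)
  res <- analyze_peldor(tr, baseline_order = 0)
  expect_equal(nrow(res$assignments), 2)
  # sorted by descending amplitude: the slow (long-distance) component wins
  expect_gt(res$assignments$r_A[1], res$assignments$r_A[2])
  expect_equal(res$assignments$rel_amplitude[1], 1)
  # leakage-limited recovery bounds at a 1.18-us window (see vignette)
  expect_lt(abs(res$assignments$r_nm[1] * 10 - 47), 3)
  expect_lt(abs(res$assignments$r_nm[2] * 10 - 29), 1.5)
  # the sub-cycle flag marks only the slow component
  expect_identical(res$assignments$sub_cycle, c(TRUE, FALSE))
})

test_that("powder-kernel trace at the study acquisition timing recovers 29 A with the default chain", {
  tr <- simulate_peldor(data.frame(r_nm = 2.916, weight = 1), seed = 1)
  res <- analyze_peldor(tr)   # order-2 baseline default
  expect_equal(nrow(res$assignments), 1)
  expect_lt(abs(res$assignments$r_nm * 10 - 29.16), 1)
})

test_that("analysis is bit-reproducible and the all-zero trace yields no assignments", {
  tr <- simulate_peldor(noise_sd = 0.02, seed = 9)
  a <- analyze_peldor(tr, baseline_order = 0)
  b <- analyze_peldor(tr, baseline_order = 0)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$spectrum$amp, b$spectrum$amp)
  zero <- peldor_trace(study_timing(), rep(0, 148))
  expect_equal(nrow(analyze_peldor(zero)$assignments), 0)
})

test_that("spectral power grows monotonically with modulation depth", {
  power <- sapply(c(0.1, 0.3, 0.6), function(lam) {
    tr <- simulate_peldor(data.frame(r_nm = 2.916, weight = 1),
                          mod_depth = lam, collapse_theta = TRUE)
    sum(analyze_peldor(tr, baseline_order = 0)$spectrum$amp^2)
  })
  expect_true(all(diff(power) > 0))
})

test_that("simulate-analyze recovery stays within one resolution bin across distances", {
  # 2% noise, collapsed-orientation signal model, matched (order-0) baseline
  for (r_A in c(29, 42, 44, 47)) {
    bound <- max(1, bin_distance_error(r_A))
    errs <- sapply(1:20, function(s) {
      tr <- simulate_peldor(data.frame(r_nm = r_A / 10, weight = 1),
                            noise_sd = 0.02, seed = s,
                            collapse_theta = TRUE)
      a <- analyze_peldor(tr, baseline_order = 0)$assignments
      a$r_nm[1] * 10 - r_A
    })
    expect_lt(max(abs(errs)), bound)
  }
})

test_that("trace files round-trip through the CSV/JSON dialect", {
  dir <- withr::local_tempdir()
  tr <- simulate_peldor(noise_sd = 0.01, seed = 5)
  fs <- write_peldor_trace(tr, file.path(dir, "trace.csv"),
                           file.path(dir, "timing.json"))
  back <- read_peldor_trace(fs[1], fs[2])
  expect_equal(back$v, tr$v, tolerance = 1e-12)
  expect_equal(back$t, tr$t)
  expect_equal(back$timing$tau, 200)
  expect_equal(back$timing$dt, 8)
  expect_error(read_peldor_trace("nope.csv", fs[2]), "no such trace")
})
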