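test_that("local curvature: collinear, circle, and hand-computed triangle", {
  expect_equal(local_curvature(c(0, 0), c(1, 0), c(2, 0)), 0)
  # three points on a circle of radius 2
  th <- c(0.3, 1.1, 2.0)
  expect_equal(local_curvature(2 * c(cos(th[1]), sin(th[1])),
                               2 * c(cos(th[2]), sin(th[2])),
                               2 * c(cos(th[3]), sin(th[3]))),
               0.5, tolerance = 1e-12)
  # sides sqrt2, 2, sqrt2; area 1; R = abc/4A = 1
  expect_equal(local_curvature(c(0, 0), c(1, 1), c(2, 0)), 1, tolerance = 1e-12)
  expect_error(local_curvature(c(0, 0), c(0, 0), c(1, 1)),
               class = "shoalkin_invalid_input")
})

test_that("cycle detection delimits beats and flags non-oscillating input", {
  sq <- rigid_oscillation_seq(10, 1000, 0.3)  # 3 cycles, 301 frames
  cy <- detect_beat_cycles(sq)
  expect_equal(nrow(cy), 3L)
  expect_true(all(abs((cy$end - cy$start) - 100) <= 2))
  expect_error(detect_beat_cycles(straight_translating_seq()),
               class = "shoalkin_no_cycle")
  # the no-cycle condition is distinct from invalid input
  expect_false(inherits(tryCatch(detect_beat_cycles(straight_translating_seq()),
                                 error = function(e) e),
                        "shoalkin_invalid_input"))
})

test_that("TBF is frame rate over frames per cycle, averaged across cycles", {
  sq <- rigid_oscillation_seq(10, 1000, 0.3)
  expect_equal(tail_beat_frequency(sq), 10, tolerance = 0.01)
  sq2 <- rigid_oscillation_seq(20, 500, 0.2)   # 25-frame cycles at 500 fps
  expect_equal(tail_beat_frequency(sq2), 20, tolerance = 0.01)
  g <- generate_midline_sequence(wave_model_params(7.3, 0.95), n_cycles = 3)
  expect_lt(abs(tail_beat_frequency(g$seq) / 7.3 - 1), 0.02)
})

test_that("amplitudes recover generator truth and are translation invariant", {
  g <- generate_midline_sequence(
    wave_model_params(10, 0.95, head_amp_bl = 0.02, tail_amp_bl = 0.10),
    n_cycles = 3)
  a <- oscillation_amplitudes(g$seq)
  expect_lt(abs(a$head_amp_bl / 0.02 - 1), 0.03)
  expect_lt(abs(a$tail_amp_bl / 0.10 - 1), 0.03)
  expect_lt(abs(a$head_tail_ratio / 0.2 - 1), 0.03)

  # rigid translation of every frame leaves amplitudes unchanged
  sq2 <- g$seq
  sq2$x <- sq2$x + 5; sq2$y <- sq2$y + 3
  a2 <- oscillation_amplitudes(sq2)
  expect_equal(a2$head_amp_bl, a$head_amp_bl, tolerance = 1e-12)
  expect_equal(a2$tail_amp_bl, a$tail_amp_bl, tolerance = 1e-12)

  # zero-amplitude oscillation: (0, 0, missing) with a warning
  sq0 <- static_straight_seq()
  expect_warning(
    a0 <- oscillation_amplitudes(sq0, cycles = data.frame(start = 1, end = 51)),
    "ratio undefined")
  expect_equal(a0$head_amp_bl, 0)
  expect_equal(a0$tail_amp_bl, 0)
  expect_true(is.na(a0$head_tail_ratio))
})

test_that("peak amplitude estimator reads the raw extreme excursion", {
  sq <- rigid_oscillation_seq(10, 1000, 0.3, amp_mm = 1, bl_mm = 10)
  a <- oscillation_amplitudes(sq, method = "peak")
  expect_equal(a$tail_amp_bl, 0.1, tolerance = 1e-3)
  expect_equal(a$head_tail_ratio, 1, tolerance = 1e-6)
})

test_that("max body curvature: zero when straight, scale invariant, below truth", {
  expect_equal(max_body_curvature(straight_translating_seq(),
                                  cycles = data.frame(start = 1, end = 51)), 0)
  g <- generate_midline_sequence(wave_model_params(10, 0.95), n_cycles = 2)
  est <- max_body_curvature(g$seq)
  truth <- g$truth$max_curvature_per_bl
  expect_lte(est, truth * (1 + 1e-9))   # chord estimator never overshoots
  expect_gt(est, truth * 0.9)

  # co-scaling coordinates and BL leaves per-BL curvature unchanged
  sq2 <- g$seq
  sq2$x <- 2 * sq2$x; sq2$y <- 2 * sq2$y; sq2$body_length_mm <- 2 * sq2$body_length_mm
  expect_equal(max_body_curvature(sq2), est, tolerance = 1e-12)
})

test_that("kinematics are invariant under rigid rotation of every frame", {
  g <- generate_midline_sequence(wave_model_params(10, 0.95), n_cycles = 2)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sq2 <- g$seq
  xr <- g$seq$x * R[1, 1] + g$seq$y * R[1, 2]
  yr <- g$seq$x * R[2, 1] + g$seq$y * R[2, 2]
  sq2$x <- xr; sq2$y <- yr
  # curvature is rotation invariant as-is
  expect_equal(max_body_curvature(sq2), max_body_curvature(g$seq),
               tolerance = 1e-9)
})

test_that("wave speed and wavelength recover generator truth; degenerate input missing", {
  g <- generate_midline_sequence(wave_model_params(10, 0.95), n_cycles = 3)
  cy <- detect_beat_cycles(g$seq)
  tb <- tail_beat_frequency(g$seq, cy)
  w <- wave_speed_and_wavelength(g$seq, cy, tb)
  expect_lt(abs(w$wave_speed_bl_s / 9.5 - 1), 0.05)
  expect_lt(abs(w$wavelength_bl / 0.95 - 1), 0.05)
  # consistency by construction
  expect_equal(w$wavelength_bl * tb, w$wave_speed_bl_s, tolerance = 1e-12)

  expect_warning(
    w0 <- wave_speed_and_wavelength(straight_translating_seq(),
                                    cycles = data.frame(start = 1, end = 51),
                                    tbf_hz = 10),
    "missing")
  expect_true(is.na(w0$wave_speed_bl_s) && is.na(w0$wavelength_bl))
})

test_that("noisy wavelength recovery stays within tolerance in the median", {
  errs <- vapply(1:40, function(i) {
    g <- generate_midline_sequence(
      wave_model_params(5, 1.2, noise_sd_bl = 0.002, seed = i), n_cycles = 3)
    cy <- detect_beat_cycles(g$seq)
    w <- suppressWarnings(
      wave_speed_and_wavelength(g$seq, cy, tail_beat_frequency(g$seq, cy)))
    abs(w$wavelength_bl / 1.2 - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("analyze_midline_sequence returns an all-NA record without a cycle", {
  rec <- analyze_midline_sequence(straight_translating_seq())
  expect_equal(rec$n_cycles_used, 0L)
  expect_true(is.na(rec$tbf_hz))
})

test_that("shoal summary averages sequences within fish, then across fish", {
  rec <- function(fish, tbf, wl = 1) {
    data.frame(fish_id = fish, tbf_hz = tbf, head_amp_bl = 0.02,
               tail_amp_bl = 0.1, head_tail_ratio = 0.2, wave_speed_bl_s = 9,
               wavelength_bl = wl, max_curvature_per_bl = 4, n_cycles_used = 2L)
  }
  # five identical records: idempotent mean
  r5 <- do.call(rbind, lapply(paste0("f", 1:5), rec, tbf = 10))
  s5 <- summarize_shoal(r5)
  expect_equal(s5$tbf_hz, 10)
  expect_equal(s5$n_tbf_hz, 5L)

  # fish TBFs 8..12 average to 10
  r <- do.call(rbind, Map(rec, paste0("f", 1:5), 8:12))
  expect_equal(summarize_shoal(r)$tbf_hz, 10)

  # a fish's two sequences are averaged before the across-fish mean
  r2 <- rbind(rec("f1", 8), rec("f1", 12), rec("f2", 12))
  expect_equal(summarize_shoal(r2)$tbf_hz, 11)

  # one fish missing wavelength: mean over the rest, n flagged
  rm <- do.call(rbind, Map(rec, paste0("f", 1:5), 8:12,
                           wl = c(1, 1, NA, 1, 1)))
  sm <- summarize_shoal(rm)
  expect_equal(sm$wavelength_bl, 1)
  expect_equal(sm$n_wavelength_bl, 4L)
  expect_error(summarize_shoal(r5[0, ]), class = "shoalkin_invalid_input")
})
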