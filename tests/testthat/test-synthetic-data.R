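test_that("wave model parameters are validated", {
  expect_error(wave_model_params(tbf_hz = -1, wavelength_bl = 1),
               class = "shoalkin_invalid_input")
  expect_error(wave_model_params(10, 1, head_amp_bl = 0.2, tail_amp_bl = 0.1),
               class = "shoalkin_invalid_input")
  # Nyquist: frame rate must exceed twice the tail-beat frequency
  expect_error(wave_model_params(10, 1, frame_rate = 15),
               class = "shoalkin_invalid_input")
  expect_error(wave_model_params(10, 1, n_points = 9),
               class = "shoalkin_invalid_input")
})

test_that("midline generator frame count, wave-speed truth and amplitude extremes", {
  g <- generate_midline_sequence(wave_model_params(10, 0.95), n_cycles = 1)
  expect_equal(nrow(g$seq$x), 101L)               # frame_rate / f + 1
  expect_equal(diff(range(g$seq$time_s)), 0.1)
  expect_equal(g$truth$wave_speed_bl_s, 9.5)

  # zero amplitude: all frames identical straight midline
  g0 <- generate_midline_sequence(
    wave_model_params(10, 0.95, head_amp_bl = 0, tail_amp_bl = 0), n_cycles = 1)
  expect_true(all(g0$seq$y == 0))
  expect_equal(g0$seq$x[1, ], g0$seq$x[101, ])

  # noiseless sine attains its tail amplitude to machine precision
  # (phase chosen so the tail tip starts on an upward zero crossing and
  # therefore peaks exactly on a sampled frame)
  g1 <- generate_midline_sequence(
    wave_model_params(2.5, 0.95, head_amp_bl = 0.1, tail_amp_bl = 0.1,
                      envelope_exponent = 1, phase = 2 * pi / 0.95),
    n_cycles = 1)
  tip <- g1$seq$y[, 200] / g1$seq$body_length_mm
  expect_equal(max(tip), 0.1, tolerance = 1e-9)
  expect_equal(min(tip), -0.1, tolerance = 1e-9)
})

test_that("midline truth curvature matches a dense numeric evaluation", {
  for (pars in list(wave_model_params(10, 0.95),
                    wave_model_params(5, 1.3, head_amp_bl = 0.05,
                                      envelope_exponent = 1))) {
    g <- generate_midline_sequence(pars, n_cycles = 1)
    # numeric oracle: circumcircle curvature of the noiseless wave on a
    # dense arc-length grid at many phases
    s <- seq(0, 1, length.out = 4000)
    A <- pars$head_amp_bl +
      (pars$tail_amp_bl - pars$head_amp_bl) * s^pars$envelope_exponent
    h <- s[2] - s[1]
    kmax <- 0
    for (ph in seq(0, 2 * pi, length.out = 181)[-1]) {
      y <- A * sin(ph - 2 * pi * s / pars$wavelength_bl)
      y1 <- (y[-(1:2)] - y[1:3998]) / (2 * h)
      y2 <- diff(y, differences = 2) / h^2
      kmax <- max(kmax, max(abs(y2) / (1 + y1^2)^1.5))
    }
    expect_equal(g$truth$max_curvature_per_bl, kmax, tolerance = 1e-3)
  }
})

test_that("midline generation is deterministic given params and seed", {
  p <- wave_model_params(10, 0.95, noise_sd_bl = 0.005, seed = 11L)
  g1 <- generate_midline_sequence(p, 2)
  g2 <- generate_midline_sequence(p, 2)
  expect_identical(g1$seq$y, g2$seq$y)
  expect_identical(g1$seq$x, g2$seq$x)
})

test_that("shoal trajectory: separation template, zero-switch case, determinism", {
  p0 <- shoal_sim_params(n_fish = 5, mean_sep_bl = 2, switch_rate_per_s = 0,
                         jitter_sd_bl = 0, seed = 1)
  g <- generate_shoal_trajectory(p0)
  expect_equal(g$truth$n_switches, 0L)
  # five fish on a line at 0,1,2,3,4 BL: all-pairs mean = 2 BL
  expect_equal(mean_separation_distance(g$traj), 2, tolerance = 1e-12)
  # rank order constant
  rk <- t(apply(g$traj$x, 1, rank))
  expect_true(all(rk == rep(rk[1, ], each = nrow(rk))))

  p1 <- shoal_sim_params(seed = 5, switch_rate_per_s = 0.3)
  expect_identical(generate_shoal_trajectory(p1)$traj$x,
                   generate_shoal_trajectory(p1)$traj$x)
  expect_error(shoal_sim_params(n_fish = 1), class = "shoalkin_invalid_input")
  expect_error(shoal_sim_params(duration_s = 0.01, sample_hz = 10),
               class = "shoalkin_invalid_input")
})

test_that("realized switch counts are Poisson with mean rate x duration", {
  rate <- 0.2; dur <- 60
  counts <- vapply(1:500, function(i) {
    p <- shoal_sim_params(switch_rate_per_s = rate, duration_s = dur,
                          sample_hz = 5, jitter_sd_bl = 0, seed = i)
    generate_shoal_trajectory(p)$truth$n_switches
  }, integer(1))
  se <- sqrt(rate * dur / 500)
  expect_lt(abs(mean(counts) - rate * dur), 3 * se)
})

test_that("oxygen trace: linear rest, EPOC recovery law, floor resets", {
  p <- respo_sim_params(resting_slope = 1, peak_slope = 2.5,
                        recovery_decay_min = 15, o2_start = 8, noise_sd = 0)
  g <- generate_oxygen_trace(p)
  tr <- g$trace
  expect_equal(tr$o2[max(which(tr$phase == "rest"))], 7, tolerance = 1e-12)

  # peak = rest: recovery continues the same straight line
  p2 <- respo_sim_params(resting_slope = 1, peak_slope = 1, noise_sd = 0)
  o2 <- generate_oxygen_trace(p2)$trace$o2
  expect_equal(max(abs(diff(o2, differences = 2))), 0, tolerance = 1e-12)

  # instantaneous rate at t = tau equals rest + (peak-rest)/e: check via
  # the derivative of the closed-form law the generator integrates
  rate_at <- function(t_min) 1 + (2.5 - 1) * exp(-t_min / 15)
  expect_equal(rate_at(15), 1 + 1.5 * exp(-1), tolerance = 1e-12)
  d <- 1e-6
  num_rate <- -(epoc_o2(15 / 60 + d, 8, 1, 2.5, 15) -
                  epoc_o2(15 / 60 - d, 8, 1, 2.5, 15)) / (2 * d)
  expect_equal(num_rate, rate_at(15), tolerance = 1e-6)

  # concentration floor: labeled re-aeration resets, never negative O2
  p3 <- respo_sim_params(resting_slope = 8, peak_slope = 12, o2_start = 4,
                         noise_sd = 0, rest_duration_min = 60,
                         recovery_duration_min = 120)
  g3 <- generate_oxygen_trace(p3)
  expect_gt(g3$truth$n_resets, 0)
  expect_true(all(g3$trace$o2 > 0))
  expect_true(any(g3$trace$phase == "reset"))
})

test_that("study design mirrors the experimental layout", {
  d <- study_design()
  expect_equal(nrow(d$shoals), 29L)
  expect_equal(as.vector(table(d$shoals$stage)[c("larva", "juvenile", "adult")]),
               c(10L, 9L, 10L))
  expect_false("J9" %in% d$shoals$shoal_id)   # juvenile shoal 9 never run
  expect_error(study_design(shoals = rbind(d$shoals, d$shoals[1, ])),
               class = "shoalkin_invalid_input")
})

test_that("generated study bundles regenerate byte-identically", {
  sh <- study_design()$shoals
  tiny <- study_design(shoals = sh[sh$shoal_id %in% c("L1", "L2"), ],
                       noise = list(n_cycles = 2L, traj_duration_s = 10))
  d1 <- file.path(tempdir(), "bundle1"); d2 <- file.path(tempdir(), "bundle2")
  generate_study(tiny, d1, seed = 3L)
  generate_study(tiny, d2, seed = 3L)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1)); h2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(h1) == unname(h2)))
  expect_true("truth_manifest.json" %in% f1)
  unlink(c(d1, d2), recursive = TRUE)
})
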