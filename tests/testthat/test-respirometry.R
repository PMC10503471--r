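test_that("resting rate: exact on linear decline, zero on flat, clamped when rising", {
  g <- generate_oxygen_trace(respo_sim_params(1, 2.5, noise_sd = 0))
  r <- resting_mo2(g$trace)
  expect_equal(r$rate, 1, tolerance = 1e-9)
  expect_equal(r$r2, 1, tolerance = 1e-9)

  flat <- oxygen_trace(time_s = (0:60) * 60, o2 = rep(8, 61),
                       phase = rep("rest", 61), temperature_c = 28)
  expect_equal(resting_mo2(flat)$rate, 0)

  rising <- oxygen_trace(time_s = (0:60) * 60, o2 = 7 + (0:60) / 120,
                         phase = rep("rest", 61), temperature_c = 28)
  expect_warning(rr <- resting_mo2(rising), "clamped")
  expect_equal(rr$rate, 0)

  short <- oxygen_trace(time_s = (0:2) * 60, o2 = c(8, 7.9, 7.8),
                        phase = rep("recovery", 3), temperature_c = 28)
  expect_error(resting_mo2(short), class = "shoalkin_invalid_input")
})

test_that("noisy resting-rate recovery is unbiased", {
  ests <- vapply(1:100, function(i) {
    g <- generate_oxygen_trace(respo_sim_params(0.8, 2.5, noise_sd = 0.02,
                                                seed = i))
    resting_mo2(g$trace)$rate
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.8), 0.01)
  expect_lt(abs(mean(ests) - 0.8), 0.05)
})

test_that("peak recovery rate: window maximum matches the closed-form oracle", {
  g <- generate_oxygen_trace(respo_sim_params(1, 2.5, recovery_decay_min = 15,
                                              noise_sd = 0))
  p <- peak_recovery_mo2(g$trace)
  # oracle: concentration from the closed-form law on the same 60-s
  # grid; the maximal 10-min OLS window is the first one
  t_h <- (1:11) / 60
  o2 <- epoc_o2(t_h, 7, 1, 2.5, 15)
  oracle <- -unname(coef(lm(o2 ~ t_h))[2])
  expect_equal(p$rate, oracle, tolerance = 1e-9)
  # window averaging biases low, never high
  expect_lte(p$rate, 2.5)
  expect_gt(p$rate, 1)

  # recovery at the resting slope: peak equals resting rate
  g2 <- generate_oxygen_trace(respo_sim_params(1, 1, noise_sd = 0))
  expect_equal(peak_recovery_mo2(g2$trace)$rate, 1, tolerance = 1e-9)
})

test_that("reset-labeled samples are excluded from every peak window", {
  tr <- generate_oxygen_trace(respo_sim_params(1, 2.5, noise_sd = 0))$trace
  # poison three recovery samples with an artificial re-aeration jump
  k <- which(tr$phase == "recovery")[8:10]
  tr$phase[k] <- "reset"
  tr$o2[k] <- 8
  p <- peak_recovery_mo2(tr)
  # the chosen window must not span the reset
  expect_true(p$window_s[1] > max(tr$time_s[k]) ||
                p$window_s[2] < min(tr$time_s[k]))
  expect_lte(p$rate, 2.5)
})

test_that("factorial MO2 is the peak:rest ratio with guarded zero rest", {
  expect_equal(factorial_mo2(1, 1), 1)
  expect_equal(factorial_mo2(0.5, 1.25), 2.5)
  expect_warning(f0 <- factorial_mo2(0, 1), "undefined")
  expect_true(is.na(f0))
})

test_that("Q10: closed form, reciprocity, units invariance", {
  expect_equal(q10(1, 1, 28, 32), 1)
  expect_equal(q10(1, 2, 22, 32), 2)
  expect_equal(q10(0.5, 1, 28, 32), 2^2.5, tolerance = 1e-12)
  set.seed(5)
  for (r in 1:50) {
    k1 <- runif(1, 0.1, 5); k2 <- runif(1, 0.1, 5)
    t1 <- runif(1, 20, 30); t2 <- runif(1, 30.5, 40)
    # swapping the rates (same temperature contrast) inverts the quotient
    expect_equal(q10(k2, k1, t1, t2), 1 / q10(k1, k2, t1, t2),
                 tolerance = 1e-12)
    # relabeling both rates and temperatures together is an identity
    expect_equal(q10(k2, k1, t2, t1), q10(k1, k2, t1, t2),
                 tolerance = 1e-12)
    cc <- runif(1, 0.1, 10)
    expect_equal(q10(cc * k1, cc * k2, t1, t2), q10(k1, k2, t1, t2),
                 tolerance = 1e-12)
  }
  expect_error(q10(0, 1, 28, 32), class = "shoalkin_invalid_input")
  expect_error(q10(1, 1, 28, 28), class = "shoalkin_invalid_input")
})

test_that("per-stage Q10 table uses cell means and recorded temperatures", {
  rec <- expand.grid(stage = c("larva", "adult"), temperature_c = c(28, 32),
                     rep = 1:3, stringsAsFactors = FALSE)
  rec$mo2_rest <- 1; rec$mo2_peak <- 2
  tbl <- stage_q10_table(rec)
  expect_true(all(tbl$q10 == 1))

  # true 28->32 rate ratio of 2 recovers (2)^(10/4)
  rec2 <- rec
  rec2$mo2_rest <- ifelse(rec2$temperature_c == 32, 2, 1)
  tbl2 <- stage_q10_table(rec2)
  expect_equal(tbl2$q10[tbl2$rate_type == "rest"], rep(2^2.5, 2),
               tolerance = 1e-12)

  # recorded temperatures override nominal treatment labels
  rec3 <- rec2
  rec3$recorded_temp_c <- ifelse(rec3$temperature_c == 32, 32.5, 27.5)
  tbl3 <- stage_q10_table(rec3)
  expect_equal(tbl3$q10[tbl3$rate_type == "rest"], rep(2^2, 2),
               tolerance = 1e-12)

  # empty temperature cell: missing with one warning per rate type
  rec4 <- rec[!(rec$stage == "adult" & rec$temperature_c == 32), ]
  w <- capture_warnings(tbl4 <- stage_q10_table(rec4))
  expect_true(all(grepl("empty temperature cell", w)))
  expect_true(all(is.na(tbl4$q10[tbl4$stage == "adult"])))
})

test_that("estimated rates converge to generator truth as noise vanishes", {
  g <- generate_oxygen_trace(respo_sim_params(0.8, 2.5, noise_sd = 0))
  expect_equal(resting_mo2(g$trace)$rate, 0.8, tolerance = 1e-9)
  # the windowed peak is below truth but strictly above resting
  p <- peak_recovery_mo2(g$trace)$rate
  expect_true(p > 0.8 && p <= 2.5)
})
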