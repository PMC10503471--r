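test_that("one-way F matches hand computation and the aov cross-check", {
  y <- c(1, 2, 3, 4, 5, 6)
  a <- rep(c("g1", "g2"), each = 3)
  res <- anova_f(y, a)
  expect_equal(res$F, 13.5, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  # independent route: stats::aov on the same data
  ref <- summary(stats::aov(y ~ factor(a)))[[1]]
  expect_equal(res$F, ref$`F value`[1], tolerance = 1e-9)

  # all observations equal: F = 0
  expect_equal(anova_f(rep(2, 6), a)$F, 0)

  # balanced additive two-way with no noise: interaction F = 0,
  # main effects infinite (zero residual variance)
  d <- expand.grid(a = c("x", "y"), b = c("p", "q", "r"), rep = 1:2)
  d$y <- ifelse(d$a == "x", 1, 3) + as.integer(factor(d$b))
  res2 <- anova_f(d$y, d$a, d$b, model = "two_way_interaction")
  expect_equal(res2$F[res2$term == "a:b"], 0)
  expect_true(all(is.infinite(res2$F[res2$term %in% c("a", "b")])))
})

test_that("sequential F statistics match brute-force projection matrices", {
  set.seed(31)
  for (r in 1:15) {
    n_per <- sample(2:4, 1)
    d <- expand.grid(a = c("l", "j", "ad"), b = c("c", "w"), rep = 1:n_per)
    # unbalance it
    d <- d[-sample(nrow(d), 2), ]
    if (any(table(d$a, d$b) < 1)) next
    d$y <- rnorm(nrow(d))
    f_pkg <- anova_f(d$y, d$a, d$b, model = "two_way_interaction")$F
    f_ref <- projection_anova_f(d$y, d$a, d$b, interaction = TRUE)
    expect_equal(f_pkg, f_ref, tolerance = 1e-9)
    f1_pkg <- anova_f(d$y, d$a)$F
    expect_equal(f1_pkg, projection_anova_f(d$y, d$a), tolerance = 1e-9)
  }
})

test_that("permutation ANOVA is reproducible and respects p-value bounds", {
  set.seed(8)
  y <- rnorm(12)
  a <- rep(c("g1", "g2", "g3"), each = 4)
  r1 <- permutation_anova(y, a, m_permutations = 499, seed = 7)
  r2 <- permutation_anova(y, a, m_permutations = 499, seed = 7)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_gte(r1$p_perm, 1 / (r1$m + 1))
  expect_lte(r1$p_perm, 1)

  d <- expand.grid(a = c("l", "j"), b = c(28, 32), rep = 1:3)
  d$y <- rnorm(nrow(d))
  t1 <- permutation_anova(d$y, d$a, d$b, model = "two_way_interaction",
                          m_permutations = 199, seed = 3)
  t2 <- permutation_anova(d$y, d$a, d$b, model = "two_way_interaction",
                          m_permutations = 199, seed = 3)
  expect_identical(t1$p_perm, t2$p_perm)
  expect_error(permutation_anova(d$y, d$a, m_permutations = 50),
               class = "shoalkin_invalid_input")
})

test_that("a complete separation of groups gives the smallest attainable p", {
  y <- c(1, 2, 3, 2, 1, 11, 12, 13, 12, 11)
  a <- rep(c("g1", "g2"), each = 5)
  r <- permutation_anova(y, a, m_permutations = 999, seed = 2)
  expect_equal(r$method, "exact")     # C(10,5) = 252 <= 20,000
  expect_lte(r$p_perm, 0.01)
})

test_that("shifting one group's mean never increases the one-way p", {
  set.seed(13)
  y0 <- rnorm(10)
  a <- rep(c("g1", "g2"), each = 5)
  shifts <- c(0, 0.5, 1, 2, 4, 8)
  ps <- vapply(shifts, function(s) {
    y <- y0 + ifelse(a == "g2", s, 0)
    permutation_anova(y, a, m_permutations = 499, seed = 5)$p_perm
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("within-speed sweep tests each variable per speed and skips degenerate cells", {
  set.seed(21)
  tbl <- expand.grid(shoal = 1:4, stage = c("larva", "adult"),
                     temperature_c = c(28, 32), speed_bl_s = c(2, 3),
                     stringsAsFactors = FALSE)
  tbl$tbf_hz <- rnorm(nrow(tbl), 10) + ifelse(tbl$stage == "larva", 5, 0)
  # adult-only extra speed must be skipped with a message
  extra <- tbl[tbl$stage == "adult" & tbl$speed_bl_s == 2, ]
  extra$speed_bl_s <- 1
  tbl <- rbind(tbl, extra)
  expect_message(
    out <- within_speed_sweep(tbl, "tbf_hz", m_permutations = 199, seed = 1),
    "single stage")
  expect_setequal(unique(out$speed_bl_s), c(2, 3))
  expect_true(all(c("p_bh", "significant") %in% names(out)))
  # the injected stage effect is detected at both speeds
  expect_true(all(out$significant[out$term == "a"]))
})

test_that("null within-speed sweeps reject at about the nominal level", {
  set.seed(99)
  rej <- c()
  for (r in 1:25) {
    tbl <- expand.grid(shoal = 1:5, stage = c("l", "j", "ad"),
                       temperature_c = c(28, 32), speed_bl_s = c(3, 4),
                       stringsAsFactors = FALSE)
    tbl$v <- rnorm(nrow(tbl))
    out <- within_speed_sweep(tbl, "v", m_permutations = 199,
                              seed = 100 + r)
    rej <- c(rej, out$significant)
  }
  # 150 term-level null tests at alpha = 0.05
  expect_lt(mean(rej), 0.12)
  expect_gt(mean(rej), 0.005)
})
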