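# Independent oracles used across tests.

# Circle through three points by brute-force least squares (Kasa fit:
# minimize ||x - c||^2 - r^2 residuals, linear in (c, r^2 - |c|^2)).
# Exact circumcircle for three non-collinear points.
kasa_curvature <- function(p1, p2, p3) {
  P <- rbind(p1, p2, p3)
  A <- cbind(2 * P[, 1], 2 * P[, 2], 1)
  b <- P[, 1]^2 + P[, 2]^2
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(0)  # singular: collinear
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (r2 <= 0) return(0)
  1 / sqrt(r2)
}

# Brute-force sequential-SS F statistics via explicit projection
# matrices built column block by column block.
projection_anova_f <- function(response, a, b = NULL, interaction = FALSE) {
  df <- data.frame(a = factor(a))
  form <- ~a
  if (!is.null(b)) {
    df$b <- factor(b)
    form <- if (interaction) ~ a * b else ~ a + b
  }
  X <- stats::model.matrix(form, df)
  asn <- attr(X, "assign")
  n <- nrow(X)
  proj <- function(M) M %*% solve(t(M) %*% M) %*% t(M)
  terms <- sort(unique(asn[asn > 0]))
  ss <- df_t <- numeric(length(terms))
  P_prev <- proj(X[, asn <= 0, drop = FALSE])
  for (i in seq_along(terms)) {
    P_cur <- proj(X[, asn <= terms[i], drop = FALSE])
    ss[i] <- drop(t(response) %*% (P_cur - P_prev) %*% response)
    df_t[i] <- sum(asn == terms[i])
    P_prev <- P_cur
  }
  rss <- drop(t(response) %*% (diag(n) - P_prev) %*% response)
  df_res <- n - ncol(X)
  (ss / df_t) / (rss / df_res)
}

# A midline sequence whose every point shares one lateral oscillation
# (no traveling wave): convenient for cycle/TBF/amplitude tests.
rigid_oscillation_seq <- function(freq_hz, frame_rate = 1000, duration_s,
                                  amp_mm = 1, bl_mm = 10, n_points = 200,
                                  phase = 0) {
  t <- seq(0, duration_s, by = 1 / frame_rate)
  s <- seq(0, bl_mm, length.out = n_points)
  y <- matrix(amp_mm * sin(2 * pi * freq_hz * t + phase), length(t), n_points)
  x <- matrix(s, length(t), n_points, byrow = TRUE)
  midline_sequence(time_s = t, x = x, y = y, body_length_mm = bl_mm,
                   frame_rate = frame_rate)
}

# Static straight midline: every frame identical, no oscillation at all.
static_straight_seq <- function(n_frames = 51, bl_mm = 10, n_points = 200) {
  t <- (seq_len(n_frames) - 1) / 1000
  s <- seq(0, bl_mm, length.out = n_points)
  midline_sequence(time_s = t,
                   x = matrix(s, n_frames, n_points, byrow = TRUE),
                   y = matrix(0, n_frames, n_points),
                   body_length_mm = bl_mm, frame_rate = 1000)
}

# Straight midline translating rigidly (no undulation).
straight_translating_seq <- function(n_frames = 51, bl_mm = 10,
                                     n_points = 200) {
  t <- (seq_len(n_frames) - 1) / 1000
  s <- seq(0, bl_mm, length.out = n_points)
  x <- outer(0.05 * seq_len(n_frames), rep(1, n_points)) +
    matrix(s, n_frames, n_points, byrow = TRUE)
  y <- matrix(0.1 * seq_len(n_frames), n_frames, n_points)
  midline_sequence(time_s = t, x = x, y = y, body_length_mm = bl_mm,
                   frame_rate = 1000)
}

# Closed-form oxygen concentration (mg/L) of the EPOC recovery law at
# time t_h hours after recovery onset.
epoc_o2 <- function(t_h, c0, resting, peak, tau_min) {
  tau_h <- tau_min / 60
  c0 - (resting * t_h + (peak - resting) * tau_h * (1 - exp(-t_h / tau_h)))
}
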