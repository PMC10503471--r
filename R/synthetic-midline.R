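#' Parameters of the kinematic body-wave model
#'
#' Bundles the ground-truth parameters of the prescribed traveling-wave
#' swimmer used to generate synthetic midline sequences.  Lateral
#' displacement follows
#' \deqn{y(s, t) = A(s) \sin(2\pi (f t - s/\lambda) + \phi)}
#' with amplitude envelope
#' \eqn{A(s) = A_{head} + (A_{tail} - A_{head}) s^{p}} and \eqn{s \in [0, 1]}
#' the arc-length position along the body in body lengths (BL), head at
#' \eqn{s = 0}.  The wave travels head to tail at speed
#' \eqn{V = f \lambda} (BL/s).
#'
#' @param tbf_hz tail-beat frequency \eqn{f} (Hz), > 0.
#' @param wavelength_bl body wavelength \eqn{\lambda} (BL), > 0.
#' @param head_amp_bl lateral amplitude at the head (BL).
#' @param tail_amp_bl lateral amplitude at the tail tip (BL);
#'   must satisfy `0 <= head_amp_bl <= tail_amp_bl`.
#' @param envelope_exponent shape exponent \eqn{p > 0} of the head-to-tail
#'   amplitude growth.
#' @param body_length mm, > 0.
#' @param frame_rate frames per second; must exceed twice `tbf_hz`
#'   (Nyquist).
#' @param n_points midline points per frame (>= 11 so that three-point
#'   curvature at 5\% BL spacing has interior stations).
#' @param noise_sd_bl i.i.d. Gaussian positional jitter added to both
#'   coordinates of every point, in BL.
#' @param phase wave phase offset \eqn{\phi} (radians).  The default
#'   `NULL` aligns the tail-tip oscillation to start on an upward zero
#'   crossing, so a generated sequence of whole cycles begins and ends
#'   on a reversal through the midline, as digitized beat cycles do.
#' @param seed RNG seed used when jitter is drawn.
#'
#' @return An object of class `wave_model_params`.
#' @export
wave_model_params <- function(tbf_hz, wavelength_bl,
                              head_amp_bl = 0.02, tail_amp_bl = 0.10,
                              envelope_exponent = 2,
                              body_length = 10, frame_rate = 1000,
                              n_points = 200L, noise_sd_bl = 0,
                              phase = NULL, seed = NULL) {
  check_scalar(tbf_hz, "tbf_hz", positive = TRUE)
  check_scalar(wavelength_bl, "wavelength_bl", positive = TRUE)
  check_scalar(head_amp_bl, "head_amp_bl", nonneg = TRUE)
  check_scalar(tail_amp_bl, "tail_amp_bl", nonneg = TRUE)
  if (head_amp_bl > tail_amp_bl) {
    stop_invalid("head_amp_bl (%g) must not exceed tail_amp_bl (%g)",
                 head_amp_bl, tail_amp_bl)
  }
  check_scalar(envelope_exponent, "envelope_exponent", positive = TRUE)
  check_scalar(body_length, "body_length", positive = TRUE)
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  if (frame_rate <= 2 * tbf_hz) {
    stop_invalid(
      "frame_rate (%g fps) must exceed twice tbf_hz (%g Hz) to sample the wave",
      frame_rate, tbf_hz)
  }
  n_points <- as.integer(n_points)
  if (n_points < 11L) {
    stop_invalid("n_points must be >= 11 for interior curvature stations (got %d)",
                 n_points)
  }
  check_scalar(noise_sd_bl, "noise_sd_bl", nonneg = TRUE)
  structure(list(tbf_hz = tbf_hz, wavelength_bl = wavelength_bl,
                 head_amp_bl = head_amp_bl, tail_amp_bl = tail_amp_bl,
                 envelope_exponent = envelope_exponent,
                 body_length = body_length, frame_rate = frame_rate,
                 n_points = n_points, noise_sd_bl = noise_sd_bl,
                 phase = phase, seed = seed),
            class = "wave_model_params")
}

# amplitude envelope A(s), s in [0, 1], in BL
wave_envelope <- function(params, s) {
  params$head_amp_bl +
    (params$tail_amp_bl - params$head_amp_bl) * s^params$envelope_exponent
}

# Analytic maximum curvature (per BL) of the noiseless wave, from the
# closed-form first and second s-derivatives of y(s, t) evaluated on a
# dense (s, phase) grid.  With x = s the plane-curve curvature is
# kappa = |y''| / (1 + y'^2)^(3/2).
wave_max_curvature <- function(params, n_s = 2000L, n_phase = 720L) {
  p <- params
  k <- 2 * pi / p$wavelength_bl
  s <- seq(0, 1, length.out = n_s)
  dA <- (p$tail_amp_bl - p$head_amp_bl) * p$envelope_exponent *
    s^(p$envelope_exponent - 1)
  d2A <- (p$tail_amp_bl - p$head_amp_bl) * p$envelope_exponent *
    (p$envelope_exponent - 1) * ifelse(s > 0, s^(p$envelope_exponent - 2), 0)
  A <- wave_envelope(p, s)
  kap_max <- 0
  for (ph in seq(0, 2 * pi, length.out = n_phase + 1L)[-1L]) {
    arg <- ph - k * s
    sn <- sin(arg); cs <- cos(arg)
    y1 <- dA * sn - A * k * cs
    y2 <- d2A * sn - 2 * dA * k * cs - A * k^2 * sn
    kap_max <- max(kap_max, max(abs(y2) / (1 + y1^2)^1.5))
  }
  kap_max
}

#' Generate a synthetic midline sequence with known ground truth
#'
#' Produces a time-ordered sequence of body midlines (ordered 2-D point
#' sets, head to tail) for one fish following the prescribed traveling
#' wave of [wave_model_params()].  Frames span exactly
#' `n_cycles / tbf_hz` seconds at the model frame rate.
#'
#' @param params a [wave_model_params()] object.
#' @param n_cycles number of complete tail-beat cycles (>= 1).
#' @param fish_id identifier carried into the output.
#'
#' @return A list with components `seq`, a [midline_sequence()], and
#'   `truth`, a `synthetic_truth` record holding the parameters plus the
#'   derived truths `wave_speed_bl_s = tbf_hz * wavelength_bl` and
#'   `max_curvature_per_bl` (analytic maximum curvature of the noiseless
#'   wave).
#' @export
generate_midline_sequence <- function(params, n_cycles = 3L, fish_id = "f1") {
  stopifnot(inherits(params, "wave_model_params"))
  if (!is.numeric(n_cycles) || n_cycles < 1) {
    stop_invalid("n_cycles must be >= 1")
  }
  p <- params
  n_frames <- as.integer(round(p$frame_rate * n_cycles / p$tbf_hz)) + 1L
  t <- (seq_len(n_frames) - 1L) / p$frame_rate
  s <- seq(0, 1, length.out = p$n_points)
  A <- wave_envelope(p, s)
  if (is.null(p$phase)) {
    # start the tail-tip signal (mean of the last 5 points) at an
    # upward zero crossing
    p$phase <- 2 * pi * mean(s[(p$n_points - 4L):p$n_points]) / p$wavelength_bl
  }
  # frames x points matrices of lateral displacement (BL)
  phase_mat <- outer(2 * pi * p$tbf_hz * t, 2 * pi * s / p$wavelength_bl, "-") +
    p$phase
  y_bl <- sweep(sin(phase_mat), 2L, A, "*")
  x_bl <- matrix(s, n_frames, p$n_points, byrow = TRUE)
  if (p$noise_sd_bl > 0) {
    with_seed(p$seed, {
      x_bl <- x_bl + matrix(stats::rnorm(length(x_bl), 0, p$noise_sd_bl),
                            n_frames, p$n_points)
      y_bl <- y_bl + matrix(stats::rnorm(length(y_bl), 0, p$noise_sd_bl),
                            n_frames, p$n_points)
    })
  }
  seq_out <- midline_sequence(time_s = t,
                              x = x_bl * p$body_length,
                              y = y_bl * p$body_length,
                              body_length_mm = p$body_length,
                              frame_rate = p$frame_rate,
                              fish_id = fish_id)
  truth <- structure(
    c(unclass(p),
      list(n_cycles = n_cycles,
           wave_speed_bl_s = p$tbf_hz * p$wavelength_bl,
           max_curvature_per_bl = wave_max_curvature(p))),
    class = "synthetic_truth")
  list(seq = seq_out, truth = truth)
}

#' Construct a midline sequence
#'
#' Container for the digitized body axis of one fish: per-frame ordered
#' point lists, head first.
#'
#' @param time_s strictly increasing frame times (s).
#' @param x,y numeric matrices, frames in rows and the ordered midline
#'   points in columns (mm).
#' @param body_length_mm snout-to-tail body length (mm).
#' @param frame_rate recording frame rate (fps).
#' @param fish_id identifier.
#' @return An object of class `midline_sequence`.
#' @export
midline_sequence <- function(time_s, x, y, body_length_mm, frame_rate,
                             fish_id = "f1") {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop_invalid("x and y must have equal dimensions")
  if (length(time_s) != nrow(x)) {
    stop_invalid("length(time_s) must equal nrow(x)")
  }
  if (any(diff(time_s) <= 0)) stop_invalid("frame times must be strictly increasing")
  check_scalar(body_length_mm, "body_length_mm", positive = TRUE)
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  structure(list(time_s = as.numeric(time_s), x = x, y = y,
                 body_length_mm = body_length_mm, frame_rate = frame_rate,
                 fish_id = fish_id),
            class = "midline_sequence")
}

#' @export
print.midline_sequence <- function(x, ...) {
  cat(sprintf("<midline_sequence> fish %s: %d frames x %d points, BL %.2f mm, %g fps\n",
              x$fish_id, nrow(x$x), ncol(x$x), x$body_length_mm, x$frame_rate))
  invisible(x)
}
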