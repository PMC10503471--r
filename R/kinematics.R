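#' Three-point local curvature
#'
#' Curvature of the circle through three 2-D points, \eqn{\kappa = 1/R}
#' with \eqn{R = abc / (4 \cdot area)} the circumradius.  Collinear points
#' give zero curvature.
#'
#' @param p1,p2,p3 numeric length-2 vectors (same units, e.g. mm); the
#'   result is in inverse units (per mm).  Multiply by the body length to
#'   convert to per-BL curvature.
#' @param signed if `TRUE`, the sign of the turn (cross product of the
#'   two chords) is retained.
#' @return Curvature (1/R).
#' @export
#' @examples
#' local_curvature(c(0, 0), c(1, 1), c(2, 0))  # 1
local_curvature <- function(p1, p2, p3, signed = FALSE) {
  if (length(p1) != 2L || length(p2) != 2L || length(p3) != 2L) {
    stop_invalid("points must be length-2 numeric vectors")
  }
  a <- p2 - p1; b <- p3 - p2; c <- p3 - p1
  la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2)); lc <- sqrt(sum(c^2))
  if (la == 0 || lb == 0 || lc == 0) {
    stop_invalid("coincident points have no defined curvature")
  }
  cross <- a[1] * b[2] - a[2] * b[1]
  k <- 2 * cross / (la * lb * lc)
  if (signed) k else abs(k)
}

# Signed curvature profile for all frames at once.  Returns a
# frames x stations matrix (per mm); stations are midline indices
# (d + 1) .. (n_points - d) where d approximates 5% BL in index steps
# (nearest index, ties toward the head).
curvature_profile <- function(seq, frames = seq_len(nrow(seq$x)),
                              chord_frac = 0.05) {
  n <- ncol(seq$x)
  d <- max(1L, as.integer(floor(chord_frac * (n - 1) + 0.5)))
  j <- (d + 1L):(n - d)
  x1 <- seq$x[frames, j - d, drop = FALSE]; y1 <- seq$y[frames, j - d, drop = FALSE]
  x2 <- seq$x[frames, j, drop = FALSE];     y2 <- seq$y[frames, j, drop = FALSE]
  x3 <- seq$x[frames, j + d, drop = FALSE]; y3 <- seq$y[frames, j + d, drop = FALSE]
  ax <- x2 - x1; ay <- y2 - y1
  bx <- x3 - x2; by <- y3 - y2
  cx <- x3 - x1; cy <- y3 - y1
  la <- sqrt(ax^2 + ay^2); lb <- sqrt(bx^2 + by^2); lc <- sqrt(cx^2 + cy^2)
  denom <- la * lb * lc
  kap <- 2 * (ax * by - ay * bx) / denom
  kap[denom == 0] <- 0
  attr(kap, "stations") <- j
  attr(kap, "station_s_bl") <- (j - 1) / (n - 1)
  kap
}

# Mean lateral (y) position of the first / last five midline points.
head_signal <- function(seq) rowMeans(seq$y[, 1:5, drop = FALSE])
tail_signal <- function(seq) {
  n <- ncol(seq$y)
  rowMeans(seq$y[, (n - 4L):n, drop = FALSE])
}

#' Detect tail-beat cycles
#'
#' Cycles are delimited by every second zero crossing of the
#' mean-subtracted tail-tip lateral signal (the average of the last five
#' midline points), after light zero-phase smoothing; crossings closer
#' than three samples are merged (hysteresis against jitter).
#'
#' @param seq a [midline_sequence()].
#' @return A data.frame with columns `start` and `end` (frame indices);
#'   spans are contiguous and non-overlapping.  Signals with fewer than
#'   three qualifying zero crossings raise a `shoalkin_no_cycle` error,
#'   distinct from invalid-input errors.
#' @export
detect_beat_cycles <- function(seq) {
  stopifnot(inherits(seq, "midline_sequence"))
  sig <- tail_signal(seq)
  sig <- sig - mean(sig)
  if (stats::sd(sig) < 1e-9 * seq$body_length_mm) {
    stop_no_cycle("tail-tip signal shows no oscillation")
  }
  n <- length(sig)
  if (n >= 20L) sig <- running_mean(sig, max(3L, n %/% 100L))
  sgn <- sign(sig)
  # carry the previous non-zero sign through exact zeros
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1L) sgn[i] <- sgn[i - 1L]
  cross <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0) + 1L
  if (length(cross) >= 2L) {
    keep <- cross[1L]
    for (cc in cross[-1L]) {
      if (cc - keep[length(keep)] >= 3L) keep <- c(keep, cc)
    }
    cross <- keep
  }
  # a sequence boundary where the signal sits within 10% of its
  # amplitude of zero delimits a cycle as well: digitized sequences
  # conventionally start and end on a tail-beat reversal-to-midline
  amp <- max(abs(sig))
  if (abs(sig[1L]) <= 0.1 * amp &&
      (!length(cross) || cross[1L] >= 4L)) {
    cross <- c(1L, cross)
  }
  if (abs(sig[n]) <= 0.1 * amp &&
      (!length(cross) || n - cross[length(cross)] >= 3L)) {
    cross <- c(cross, n)
  }
  if (length(cross) < 3L) stop_no_cycle()
  n_cyc <- (length(cross) - 1L) %/% 2L
  starts <- cross[seq(1L, by = 2L, length.out = n_cyc)]
  ends <- cross[seq(3L, by = 2L, length.out = n_cyc)]
  data.frame(start = starts, end = ends)
}

#' Tail-beat frequency
#'
#' TBF is the frame rate divided by the number of frames spanning one
#' beat cycle; multi-cycle sequences return the per-cycle mean.
#'
#' @param seq a [midline_sequence()].
#' @param cycles cycle spans from [detect_beat_cycles()]; detected if
#'   missing.
#' @return TBF in Hz.
#' @export
tail_beat_frequency <- function(seq, cycles = detect_beat_cycles(seq)) {
  mean(seq$frame_rate / (cycles$end - cycles$start))
}

#' Head and tail oscillation amplitudes
#'
#' The head (tail) signal is the mean lateral position of the first
#' (last) five midline points.  The amplitude of each signal about its
#' time mean is estimated per cycle and averaged, then normalized by body
#' length; `head_tail_ratio = head_amp / tail_amp` (missing, with a
#' warning, when the tail amplitude is zero).
#'
#' Two estimators are available. `"harmonic"` (default) fits a sinusoid
#' at the cycle frequency by least squares and reports its amplitude —
#' for sinusoidal oscillation this equals the maximum lateral excursion
#' (half peak-to-peak), and it is essentially unbiased under digitizing
#' jitter.  `"peak"` reports the raw maximum |excursion| about the time
#' mean, which is upward-biased by noise on the extremes.
#'
#' @param seq a [midline_sequence()].
#' @param cycles cycle spans; detected if missing.
#' @param method `"harmonic"` or `"peak"`.
#' @return A list with `head_amp_bl`, `tail_amp_bl`, `head_tail_ratio`.
#' @export
oscillation_amplitudes <- function(seq, cycles = detect_beat_cycles(seq),
                                   method = c("harmonic", "peak")) {
  method <- match.arg(method)
  bl <- seq$body_length_mm
  amp_of <- function(sig) {
    per_cycle <- vapply(seq_len(nrow(cycles)), function(i) {
      idx <- cycles$start[i]:cycles$end[i]
      y <- sig[idx] - mean(sig[idx])
      if (method == "peak") return(max(abs(y)))
      f <- seq$frame_rate / (cycles$end[i] - cycles$start[i])
      wt <- 2 * pi * f * seq$time_s[idx]
      co <- stats::coef(stats::lm.fit(cbind(sin(wt), cos(wt)), y))
      sqrt(sum(co^2))
    }, numeric(1))
    mean(per_cycle) / bl
  }
  head_amp <- amp_of(head_signal(seq))
  tail_amp <- amp_of(tail_signal(seq))
  ratio <- if (tail_amp == 0) {
    warning("tail amplitude is zero; head:tail ratio undefined")
    NA_real_
  } else head_amp / tail_amp
  list(head_amp_bl = head_amp, tail_amp_bl = tail_amp,
       head_tail_ratio = ratio)
}

#' Maximum body curvature
#'
#' Three-point curvature is evaluated iteratively along the body with the
#' flanking points at 5\% BL from the central station (nearest midline
#' index), for every frame of the cycle; the maximum |curvature| is
#' returned in per-BL units.
#'
#' @param seq a [midline_sequence()].
#' @param cycles cycle spans; detected if missing.
#' @return Maximum curvature (per BL).
#' @export
max_body_curvature <- function(seq, cycles = detect_beat_cycles(seq)) {
  frames <- cycles$start[1L]:cycles$end[nrow(cycles)]
  kap <- curvature_profile(seq, frames)
  max(abs(kap)) * seq$body_length_mm
}

# Weighted least-squares slope of y on x.
wls_slope <- function(x, y, w) {
  xm <- sum(w * x) / sum(w); ym <- sum(w * y) / sum(w)
  sum(w * (x - xm) * (y - ym)) / sum(w * (x - xm)^2)
}

#' Body-wave speed and wavelength from local curvatures
#'
#' The rearward-traveling body wave is measured from the phase
#' propagation of the local-curvature wave.  At every arc-length station
#' of the posterior 50\% of the body (the near-straight head region
#' carries no usable curvature signal), the three-point curvature time
#' series over the cycle is harmonically fit at the tail-beat frequency,
#' giving a spatial phase profile \eqn{\varphi(s)}.  For a traveling
#' wave \eqn{y = A(s)\sin(\omega t - k s)}, the curvature phase is
#' \eqn{\varphi(s) = -k s + \psi(s)} where
#' \eqn{\psi = \arg[(A k^2 - A'') + 2 i A' k]} is the phase lead
#' contributed by the growing amplitude envelope (the curvature wave is
#' locally advected slower than the displacement wave).  \eqn{\psi} is
#' estimated from the measured lateral-amplitude envelope and removed,
#' and the wavenumber \eqn{k} is the weighted least-squares slope of the
#' corrected unwrapped phase (weights = squared curvature oscillation
#' amplitude), iterated once.  Wave speed is
#' \eqn{V = 2\pi f / k = f \lambda} (BL/s), so
#' `wavelength = wave_speed / tbf_hz` exactly.
#'
#' @param seq a [midline_sequence()].
#' @param cycles cycle spans; detected if missing.
#' @param tbf_hz tail-beat frequency; estimated if missing.
#' @return A list with `wave_speed_bl_s` and `wavelength_bl`; both `NA`
#'   (with a warning) when no coherent curvature wave is present (e.g.
#'   rigid translation) or fewer than 8 stations carry signal.
#' @export
wave_speed_and_wavelength <- function(seq, cycles = detect_beat_cycles(seq),
                                      tbf_hz = tail_beat_frequency(seq, cycles)) {
  frames <- cycles$start[1L]:cycles$end[nrow(cycles)]
  kap <- curvature_profile(seq, frames)
  s_bl <- attr(kap, "station_s_bl")
  bl <- seq$body_length_mm
  t_all <- seq$time_s[frames]
  w <- 2 * pi * tbf_hz
  X <- cbind(sin(w * t_all), cos(w * t_all))
  # harmonic fit of curvature and lateral displacement at every station
  co_k <- qr.coef(qr(cbind(1, X)), kap * bl)        # per-BL curvature
  co_y <- qr.coef(qr(cbind(1, X)), seq$y[frames, , drop = FALSE] / bl)
  zk <- complex(real = co_k[2L, ], imaginary = co_k[3L, ])  # phase of sin term
  amp_k <- Mod(zk)
  if (max(amp_k) <= 1e-6) {
    warning("no oscillating curvature signal; wave metrics missing")
    return(list(wave_speed_bl_s = NA_real_, wavelength_bl = NA_real_))
  }
  post <- which(s_bl >= 0.5)
  use <- post[amp_k[post] >= 0.2 * max(amp_k[post])]
  if (length(use) < 8L) {
    warning("fewer than 8 stations carry curvature signal; wave metrics missing")
    return(list(wave_speed_bl_s = NA_real_, wavelength_bl = NA_real_))
  }
  s_use <- s_bl[use]
  # kappa = a sin(wt) + b cos(wt) = M sin(wt + phi), phi = atan2(b, a)
  phi <- Arg(complex(real = co_k[2L, use], imaginary = co_k[3L, use]))
  phi <- cumsum(c(phi[1L], ((diff(phi) + pi) %% (2 * pi)) - pi))  # unwrap
  wts <- amp_k[use]^2
  k_hat <- -wls_slope(s_use, phi, wts)
  if (!is.finite(k_hat) || k_hat <= 0) {
    warning("curvature phase does not propagate rearward; wave metrics missing")
    return(list(wave_speed_bl_s = NA_real_, wavelength_bl = NA_real_))
  }
  # amplitude-envelope correction: psi from the measured y envelope.
  # The envelope and its derivatives come from a degree-4 polynomial
  # least-squares fit (pointwise finite differences would amplify
  # digitizing noise in the second derivative beyond use).
  n_pt <- ncol(seq$x)
  s_full <- (seq_len(n_pt) - 1) / (n_pt - 1)
  s_mid <- s_full[attr(kap, "stations")[use]]
  amp_y <- Mod(complex(real = co_y[2L, ], imaginary = co_y[3L, ]))
  V <- outer(s_full, 0:4, "^")
  cf <- qr.coef(qr(V), amp_y)
  env_a <- drop(outer(s_mid, 0:4, "^") %*% cf)
  env_d1 <- drop(outer(s_mid, 0:3, "^") %*% (cf[2:5] * (1:4)))
  env_d2 <- drop(outer(s_mid, 0:2, "^") %*% (cf[3:5] * c(2, 6, 12)))
  for (it in 1:2) {
    psi <- atan2(2 * env_d1 * k_hat, env_a * k_hat^2 - env_d2)
    k_new <- -wls_slope(s_use, phi - psi, wts)
    if (!is.finite(k_new) || k_new <= 0) break
    k_hat <- k_new
  }
  lambda <- 2 * pi / k_hat
  list(wave_speed_bl_s = tbf_hz * lambda, wavelength_bl = lambda)
}

#' Full kinematics record for one midline sequence
#'
#' Runs cycle detection and all kinematic estimators; a sequence without
#' a complete detected cycle contributes no kinematics (all-`NA` record
#' with `n_cycles_used = 0`).
#'
#' @param seq a [midline_sequence()].
#' @param min_cycles minimum number of detected cycles required.
#' @param amp_method amplitude estimator, see [oscillation_amplitudes()].
#' @return One-row data.frame with columns `fish_id`, `tbf_hz`,
#'   `head_amp_bl`, `tail_amp_bl`, `head_tail_ratio`, `wave_speed_bl_s`,
#'   `wavelength_bl`, `max_curvature_per_bl`, `n_cycles_used`.
#' @export
analyze_midline_sequence <- function(seq, min_cycles = 1L,
                                     amp_method = "harmonic") {
  empty <- data.frame(fish_id = seq$fish_id, tbf_hz = NA_real_,
                      head_amp_bl = NA_real_, tail_amp_bl = NA_real_,
                      head_tail_ratio = NA_real_, wave_speed_bl_s = NA_real_,
                      wavelength_bl = NA_real_, max_curvature_per_bl = NA_real_,
                      n_cycles_used = 0L, stringsAsFactors = FALSE)
  cycles <- tryCatch(detect_beat_cycles(seq),
                     shoalkin_no_cycle = function(e) NULL)
  if (is.null(cycles) || nrow(cycles) < min_cycles) return(empty)
  tbf <- tail_beat_frequency(seq, cycles)
  amps <- suppressWarnings(oscillation_amplitudes(seq, cycles, amp_method))
  wave <- suppressWarnings(wave_speed_and_wavelength(seq, cycles, tbf))
  data.frame(fish_id = seq$fish_id, tbf_hz = tbf,
             head_amp_bl = amps$head_amp_bl, tail_amp_bl = amps$tail_amp_bl,
             head_tail_ratio = amps$head_tail_ratio,
             wave_speed_bl_s = wave$wave_speed_bl_s,
             wavelength_bl = wave$wavelength_bl,
             max_curvature_per_bl = max_body_curvature(seq, cycles),
             n_cycles_used = nrow(cycles), stringsAsFactors = FALSE)
}

kinematics_metric_cols <- c("tbf_hz", "head_amp_bl", "tail_amp_bl",
                            "head_tail_ratio", "wave_speed_bl_s",
                            "wavelength_bl", "max_curvature_per_bl")

#' Average per-fish kinematics to one record per shoal
#'
#' Records from 1–2 independent sequences of the same fish are averaged
#' first; the shoal record is the unweighted mean across fish.  Missing
#' fields are excluded pairwise and the per-field count of contributing
#' fish is reported in `n_*` columns.
#'
#' @param records data.frame of per-sequence kinematics records with a
#'   `fish_id` column (e.g. rows from [analyze_midline_sequence()]).
#' @return One-row data.frame of shoal-mean metrics plus `n_*` counts.
#' @export
summarize_shoal <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop_invalid("no kinematics records to summarize")
  }
  per_fish <- do.call(rbind, lapply(split(records, records$fish_id), function(d) {
    out <- d[1L, , drop = FALSE]
    for (cl in kinematics_metric_cols) {
      v <- d[[cl]]
      out[[cl]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    out
  }))
  out <- per_fish[1L, setdiff(names(per_fish), "fish_id"), drop = FALSE]
  for (cl in kinematics_metric_cols) {
    v <- per_fish[[cl]]
    out[[cl]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    out[[paste0("n_", cl)]] <- sum(!is.na(v))
  }
  out$n_cycles_used <- sum(per_fish$n_cycles_used)
  rownames(out) <- NULL
  out
}
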