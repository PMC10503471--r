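#' Parameters of the station-keeping shoal simulator
#'
#' Fish hold noisy stations around a collinear template laid out along the
#' flow axis whose mean pairwise distance equals `mean_sep_bl`.
#' Streamwise-rank transpositions (adjacent fish exchanging stations)
#' occur at Poisson-distributed times with rate `switch_rate_per_s`; each
#' event completes within one sample step.
#'
#' @param n_fish number of shoal members (>= 2); the study design uses 5.
#' @param mean_sep_bl target mean pairwise separation distance (BL), > 0.
#' @param switch_rate_per_s Poisson rate of adjacent-rank transpositions
#'   (events per second), >= 0.
#' @param flow_speed_bl_s nominal flow speed (BL/s), metadata only — fish
#'   hold station in the flow-tank frame.
#' @param duration_s simulated duration (s).
#' @param sample_hz trajectory sampling rate (Hz).
#' @param jitter_sd_bl per-sample Gaussian positional noise (BL).
#' @param body_length_mm body length used to emit calibrated mm
#'   coordinates.
#' @param seed RNG seed.
#' @return An object of class `shoal_sim_params`.
#' @export
shoal_sim_params <- function(n_fish = 5L, mean_sep_bl = 2,
                             switch_rate_per_s = 0.1,
                             flow_speed_bl_s = 3, duration_s = 60,
                             sample_hz = 20, jitter_sd_bl = 0.02,
                             body_length_mm = 10, seed = NULL) {
  n_fish <- as.integer(n_fish)
  if (n_fish < 2L) stop_invalid("n_fish must be >= 2")
  check_scalar(mean_sep_bl, "mean_sep_bl", positive = TRUE)
  check_scalar(switch_rate_per_s, "switch_rate_per_s", nonneg = TRUE)
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(sample_hz, "sample_hz", positive = TRUE)
  if (duration_s * sample_hz < 2) {
    stop_invalid("duration_s * sample_hz must yield at least 2 samples")
  }
  check_scalar(jitter_sd_bl, "jitter_sd_bl", nonneg = TRUE)
  check_scalar(body_length_mm, "body_length_mm", positive = TRUE)
  structure(list(n_fish = n_fish, mean_sep_bl = mean_sep_bl,
                 switch_rate_per_s = switch_rate_per_s,
                 flow_speed_bl_s = flow_speed_bl_s,
                 duration_s = duration_s, sample_hz = sample_hz,
                 jitter_sd_bl = jitter_sd_bl,
                 body_length_mm = body_length_mm, seed = seed),
            class = "shoal_sim_params")
}

#' Generate a synthetic shoal trajectory
#'
#' For a collinear template with spacing \eqn{d} along the flow axis the
#' mean pairwise distance is \eqn{d (n+1)/3}, so spacing is chosen as
#' `mean_sep_bl * 3 / (n_fish + 1)`.
#'
#' @param params a [shoal_sim_params()] object.
#' @return A list with `traj`, a [shoal_trajectory()], and `truth`, the
#'   parameter set plus the realized number of switch events
#'   (`n_switches`) and their times.
#' @export
generate_shoal_trajectory <- function(params) {
  stopifnot(inherits(params, "shoal_sim_params"))
  p <- params
  n_samp <- as.integer(floor(p$duration_s * p$sample_hz)) + 1L
  t <- (seq_len(n_samp) - 1L) / p$sample_hz
  spacing <- p$mean_sep_bl * 3 / (p$n_fish + 1)
  stations <- (seq_len(p$n_fish) - 1L) * spacing   # BL, along flow axis (+x)

  with_seed(p$seed, {
    n_events <- stats::rpois(1L, p$switch_rate_per_s * p$duration_s)
    event_times <- sort(stats::runif(n_events, 0, p$duration_s))
    event_pairs <- if (n_events > 0) {
      sample.int(p$n_fish - 1L, n_events, replace = TRUE)
    } else integer(0)

    # assignment[i] = station index currently held by fish i
    assignment <- seq_len(p$n_fish)
    x <- matrix(0, n_samp, p$n_fish)
    y <- matrix(0, n_samp, p$n_fish)
    ev <- 1L
    for (k in seq_len(n_samp)) {
      while (ev <= n_events && event_times[ev] <= t[k]) {
        r <- event_pairs[ev]  # swap stations of rank r and r + 1
        i <- which(assignment == r); j <- which(assignment == r + 1L)
        assignment[c(i, j)] <- c(r + 1L, r)
        ev <- ev + 1L
      }
      x[k, ] <- stations[assignment]
      y[k, ] <- 0
    }
    if (p$jitter_sd_bl > 0) {
      x <- x + matrix(stats::rnorm(length(x), 0, p$jitter_sd_bl), n_samp)
      y <- y + matrix(stats::rnorm(length(y), 0, p$jitter_sd_bl), n_samp)
    }
  })

  traj <- shoal_trajectory(time_s = t,
                           x = x * p$body_length_mm,
                           y = y * p$body_length_mm,
                           body_length_mm = rep(p$body_length_mm, p$n_fish),
                           flow_axis = c(1, 0))
  truth <- structure(c(unclass(p),
                       list(n_switches = n_events,
                            switch_times = event_times)),
                     class = "synthetic_truth")
  list(traj = traj, truth = truth)
}

#' Construct a shoal trajectory
#'
#' Per-frame reference positions (body centroid or digitizer reference
#' point) of every shoal member, in calibrated coordinates.
#'
#' @param time_s strictly increasing sample times (s).
#' @param x,y numeric matrices, samples in rows and fish in columns (mm).
#' @param body_length_mm per-fish body lengths (mm).
#' @param flow_axis unit vector of the flow (streamwise) axis.
#' @param fish_ids fish identifiers.
#' @return An object of class `shoal_trajectory`.
#' @export
shoal_trajectory <- function(time_s, x, y, body_length_mm,
                             flow_axis = c(1, 0),
                             fish_ids = paste0("f", seq_len(ncol(as.matrix(x))))) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop_invalid("x and y must have equal dimensions")
  if (length(time_s) != nrow(x)) stop_invalid("length(time_s) must equal nrow(x)")
  if (any(diff(time_s) <= 0)) stop_invalid("times must be strictly increasing")
  if (length(body_length_mm) == 1L) {
    body_length_mm <- rep(body_length_mm, ncol(x))
  }
  if (length(body_length_mm) != ncol(x)) {
    stop_invalid("body_length_mm must have one value per fish")
  }
  if (any(body_length_mm <= 0)) stop_invalid("body lengths must be positive")
  flow_axis <- flow_axis / sqrt(sum(flow_axis^2))
  structure(list(time_s = as.numeric(time_s), x = x, y = y,
                 body_length_mm = as.numeric(body_length_mm),
                 flow_axis = flow_axis, fish_ids = fish_ids),
            class = "shoal_trajectory")
}

#' @export
print.shoal_trajectory <- function(x, ...) {
  cat(sprintf("<shoal_trajectory> %d fish, %d samples over %.1f s\n",
              ncol(x$x), nrow(x$x), diff(range(x$time_s))))
  invisible(x)
}
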