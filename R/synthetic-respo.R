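#' Parameters of the respirometry trace simulator
#'
#' Emulates closed-respirometry oxygen concentration series sampled every
#' `sample_period_s`: a rest phase declining linearly at `resting_slope`,
#' followed by a recovery phase whose instantaneous decline rate follows
#' an exponentially decaying excess post-exercise oxygen consumption
#' (EPOC) law,
#' \deqn{r(t) = r_{rest} + (r_{peak} - r_{rest}) e^{-t/\tau},}
#' so the maximal rate occurs at recovery onset.  If the concentration
#' would fall to the hypoxia floor (2 mg/L) the chamber is re-aerated to
#' `o2_start` and the sample labeled `reset`.
#'
#' @param resting_slope true resting O2 decline rate (mg O2 L^-1 h^-1), > 0.
#' @param peak_slope true maximal recovery decline rate (mg O2 L^-1 h^-1),
#'   >= `resting_slope`.
#' @param recovery_decay_min EPOC decay time constant \eqn{\tau} (min).
#' @param o2_start initial (and re-aeration) concentration (mg/L).
#' @param sample_period_s sampling period (s); the study design samples
#'   every 60 s.
#' @param rest_duration_min rest-phase duration (min).
#' @param recovery_duration_min recovery-phase duration (min), >= 120 in
#'   the study design.
#' @param noise_sd Gaussian measurement noise per sample (mg/L).
#' @param temperature_c treatment temperature (deg C).
#' @param seed RNG seed.
#' @return An object of class `respo_sim_params`.
#' @export
respo_sim_params <- function(resting_slope, peak_slope,
                             recovery_decay_min = 15, o2_start = 8,
                             sample_period_s = 60, rest_duration_min = 60,
                             recovery_duration_min = 120, noise_sd = 0.02,
                             temperature_c = 28, seed = NULL) {
  check_scalar(resting_slope, "resting_slope", positive = TRUE)
  check_scalar(peak_slope, "peak_slope", positive = TRUE)
  if (peak_slope < resting_slope) {
    stop_invalid("peak_slope (%g) must be >= resting_slope (%g)",
                 peak_slope, resting_slope)
  }
  check_scalar(recovery_decay_min, "recovery_decay_min", positive = TRUE)
  check_scalar(o2_start, "o2_start", positive = TRUE)
  if (o2_start <= 2) stop_invalid("o2_start must exceed the 2 mg/L floor")
  check_scalar(sample_period_s, "sample_period_s", positive = TRUE)
  check_scalar(rest_duration_min, "rest_duration_min", positive = TRUE)
  check_scalar(recovery_duration_min, "recovery_duration_min", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(resting_slope = resting_slope, peak_slope = peak_slope,
                 recovery_decay_min = recovery_decay_min, o2_start = o2_start,
                 sample_period_s = sample_period_s,
                 rest_duration_min = rest_duration_min,
                 recovery_duration_min = recovery_duration_min,
                 noise_sd = noise_sd, temperature_c = temperature_c,
                 seed = seed),
            class = "respo_sim_params")
}

# Cumulative O2 consumed (mg/L) from recovery onset to t hours:
# integral of resting + (peak - resting) exp(-t/tau).
epoc_consumed <- function(t_h, resting, peak, tau_h) {
  resting * t_h + (peak - resting) * tau_h * (1 - exp(-t_h / tau_h))
}

#' Generate a synthetic oxygen-concentration trace
#'
#' @param params a [respo_sim_params()] object.
#' @param shoal_id,stage identifiers carried into the trace.
#' @return A list with `trace`, an [oxygen_trace()], and `truth`, the
#'   parameter set plus the number of re-aeration resets.
#' @export
generate_oxygen_trace <- function(params, shoal_id = "s1", stage = "adult") {
  stopifnot(inherits(params, "respo_sim_params"))
  p <- params
  floor_mg <- 2
  dt_h <- p$sample_period_s / 3600
  n_rest <- as.integer(round(p$rest_duration_min * 60 / p$sample_period_s))
  n_rec <- as.integer(round(p$recovery_duration_min * 60 / p$sample_period_s))
  t_s <- (0:(n_rest + n_rec)) * p$sample_period_s
  phase <- c(rep("rest", n_rest + 1L), rep("recovery", n_rec))
  tau_h <- p$recovery_decay_min / 60
  t_rec_h <- (t_s - n_rest * p$sample_period_s) / 3600  # time since recovery onset

  # ideal per-step consumption (mg/L) between consecutive samples
  cons <- numeric(length(t_s))
  for (k in 2:length(t_s)) {
    if (phase[k] == "rest") {
      cons[k] <- p$resting_slope * dt_h
    } else {
      t0 <- max(t_rec_h[k - 1L], 0)
      cons[k] <- epoc_consumed(t_rec_h[k], p$resting_slope, p$peak_slope, tau_h) -
        epoc_consumed(t0, p$resting_slope, p$peak_slope, tau_h)
    }
  }

  o2 <- numeric(length(t_s))
  o2[1L] <- p$o2_start
  n_resets <- 0L
  for (k in 2:length(t_s)) {
    val <- o2[k - 1L] - cons[k]
    if (val <= floor_mg) {
      o2[k] <- p$o2_start
      phase[k] <- "reset"
      n_resets <- n_resets + 1L
    } else {
      o2[k] <- val
    }
  }
  if (p$noise_sd > 0) {
    with_seed(p$seed, {
      o2 <- o2 + stats::rnorm(length(o2), 0, p$noise_sd)
    })
    o2 <- pmax(o2, 0.01)  # measurement noise never produces non-positive O2
  }
  trace <- oxygen_trace(time_s = t_s, o2 = o2, phase = phase,
                        temperature_c = p$temperature_c,
                        shoal_id = shoal_id, stage = stage)
  truth <- structure(c(unclass(p), list(n_resets = n_resets)),
                     class = "synthetic_truth")
  list(trace = trace, truth = truth)
}

#' Construct an oxygen trace
#'
#' @param time_s sample times (s), strictly increasing.
#' @param o2 oxygen concentration (mg O2/L), > 0.
#' @param phase per-sample labels among `"rest"`, `"recovery"`, `"reset"`;
#'   rest precedes recovery.
#' @param temperature_c treatment temperature.
#' @param shoal_id,stage identifiers.
#' @return An object of class `oxygen_trace`.
#' @export
oxygen_trace <- function(time_s, o2, phase, temperature_c,
                         shoal_id = "s1", stage = "adult") {
  if (length(time_s) != length(o2) || length(o2) != length(phase)) {
    stop_invalid("time_s, o2 and phase must have equal length")
  }
  if (any(diff(time_s) <= 0)) stop_invalid("times must be strictly increasing")
  if (any(o2 <= 0)) stop_invalid("o2 concentrations must be positive")
  bad <- setdiff(unique(phase), c("rest", "recovery", "reset"))
  if (length(bad)) stop_invalid("unknown phase label(s): %s",
                                paste(bad, collapse = ", "))
  if (any(phase == "rest") && any(phase == "recovery") &&
      min(which(phase == "recovery")) < max(which(phase == "rest"))) {
    stop_invalid("rest phase must precede recovery phase")
  }
  structure(list(time_s = as.numeric(time_s), o2 = as.numeric(o2),
                 phase = as.character(phase), temperature_c = temperature_c,
                 shoal_id = shoal_id, stage = stage),
            class = "oxygen_trace")
}

#' @export
print.oxygen_trace <- function(x, ...) {
  cat(sprintf("<oxygen_trace> shoal %s (%s, %g degC): %d samples, %.0f min\n",
              x$shoal_id, x$stage, x$temperature_c, length(x$o2),
              diff(range(x$time_s)) / 60))
  invisible(x)
}
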