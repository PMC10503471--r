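# Ordinary least-squares slope of o2 (mg/L) vs time (h); returns slope
# and r^2.
ols_slope_h <- function(t_s, o2) {
  t_h <- t_s / 3600
  fit <- stats::lm.fit(cbind(1, t_h), o2)
  slope <- stats::coef(fit)[2L]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((o2 - mean(o2))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(slope = unname(slope), r2 = r2)
}

#' Resting routine metabolic rate
#'
#' Oxygen decline rate over the final `window_min` minutes of the rest
#' phase (the earlier rest samples absorb the handling/acclimation
#' transient), by ordinary least-squares slope.  Re-aeration (`reset`)
#' samples are excluded: the fit uses the trailing run of uninterrupted
#' rest samples.
#'
#' @param trace an [oxygen_trace()].
#' @param window_min fitting window (min).
#' @return A list with `rate` (mg O2 L^-1 h^-1, >= 0), `r2`, and the
#'   fitted `window_s` time span.  A rising O2 trend yields a warning and
#'   a rate clamped at 0.
#' @export
resting_mo2 <- function(trace, window_min = 30) {
  stopifnot(inherits(trace, "oxygen_trace"))
  idx <- which(trace$phase == "rest")
  if (!length(idx)) stop_invalid("trace has no rest phase")
  # trailing run of rest samples unbroken by resets
  resets <- which(trace$phase == "reset" & seq_along(trace$phase) < max(idx))
  if (length(resets)) idx <- idx[idx > max(resets)]
  t_end <- trace$time_s[max(idx)]
  idx <- idx[trace$time_s[idx] >= t_end - window_min * 60]
  if (length(idx) < 3L) {
    stop_invalid("insufficient rest-phase samples (%d) for a %g-min window",
                 length(idx), window_min)
  }
  fit <- ols_slope_h(trace$time_s[idx], trace$o2[idx])
  rate <- -fit$slope
  if (rate < 0) {
    if (rate < -1e-9 * max(abs(trace$o2))) {
      warning("O2 rising during rest window; resting rate clamped at 0")
    }
    rate <- 0
  }
  list(rate = rate, r2 = fit$r2,
       window_s = range(trace$time_s[idx]))
}

#' Peak metabolic rate during recovery
#'
#' A `window_min`-minute window slides sample-by-sample across the
#' recovery phase; the rate in each window is the magnitude of the
#' least-squares O2 slope, and the maximum across windows is returned.
#' Windows containing re-aeration (`reset`) samples are skipped.  Because
#' the window averages a monotonically decaying instantaneous rate, the
#' estimate is biased low, never high, relative to the true onset rate.
#'
#' @param trace an [oxygen_trace()].
#' @param window_min window length (min).
#' @return A list with `rate` (mg O2 L^-1 h^-1), `r2` of the maximal
#'   window, and its `window_s` time span.
#' @export
peak_recovery_mo2 <- function(trace, window_min = 10) {
  stopifnot(inherits(trace, "oxygen_trace"))
  rec <- which(trace$phase %in% c("recovery", "reset"))
  if (!length(rec)) stop_invalid("trace has no recovery phase")
  t <- trace$time_s[rec]
  if (max(t) - min(t) < window_min * 60) {
    stop_invalid("recovery phase shorter than the %g-min window", window_min)
  }
  is_reset <- trace$phase[rec] == "reset"
  best <- list(rate = -Inf, r2 = NA_real_, window_s = c(NA_real_, NA_real_))
  for (k in seq_along(rec)) {
    inw <- which(t >= t[k] & t <= t[k] + window_min * 60)
    if (length(inw) < 3L) next
    if (max(t[inw]) - t[k] < window_min * 60 - 1e-9) next  # truncated at end
    if (any(is_reset[inw])) next
    fit <- ols_slope_h(t[inw], trace$o2[rec][inw])
    rate <- -fit$slope
    if (rate > best$rate) {
      best <- list(rate = rate, r2 = fit$r2, window_s = range(t[inw]))
    }
  }
  if (!is.finite(best$rate)) {
    stop_invalid("no reset-free %g-min window available in recovery", window_min)
  }
  best$rate <- max(best$rate, 0)
  best
}

#' Factorial metabolic rate
#'
#' Ratio of the peak recovery rate to the resting routine rate, an
#' aerobic-scope proxy.
#'
#' @param rest,peak rates (mg O2 L^-1 h^-1).
#' @return `peak / rest`; `NA` with a warning when `rest` is 0.
#' @export
factorial_mo2 <- function(rest, peak) {
  if (is.na(rest) || is.na(peak)) return(NA_real_)
  if (rest < 0 || peak < 0) stop_invalid("rates must be non-negative")
  if (rest == 0) {
    warning("resting rate is zero; factorial MO2 undefined")
    return(NA_real_)
  }
  peak / rest
}

#' Temperature quotient Q10
#'
#' \deqn{Q_{10} = (K_2 / K_1)^{10 / (T_2 - T_1)}}
#' the factor by which a rate changes per 10 deg C.
#'
#' @param k1,k2 mean rates at temperatures `t1` and `t2`; must be > 0.
#' @param t1,t2 temperatures (deg C), `t1 != t2`.
#' @return The temperature quotient.
#' @export
#' @examples
#' q10(0.5, 1.0, 28, 32)  # 2^2.5
q10 <- function(k1, k2, t1, t2) {
  check_scalar(k1, "k1", positive = TRUE)
  check_scalar(k2, "k2", positive = TRUE)
  check_scalar(t1, "t1"); check_scalar(t2, "t2")
  if (t1 == t2) stop_invalid("t1 and t2 must differ")
  (k2 / k1)^(10 / (t2 - t1))
}

#' Per-shoal metabolic record from one oxygen trace
#'
#' @param trace an [oxygen_trace()].
#' @param rest_window_min,peak_window_min fitting windows (min).
#' @return One-row data.frame with `shoal_id`, `stage`, `temperature_c`,
#'   `mo2_rest`, `mo2_peak`, `factorial_mo2` and fit diagnostics.
#' @export
metabolic_record <- function(trace, rest_window_min = 30,
                             peak_window_min = 10) {
  rest <- resting_mo2(trace, rest_window_min)
  peak <- peak_recovery_mo2(trace, peak_window_min)
  data.frame(shoal_id = trace$shoal_id, stage = trace$stage,
             temperature_c = trace$temperature_c,
             mo2_rest = rest$rate, mo2_peak = peak$rate,
             factorial_mo2 = suppressWarnings(factorial_mo2(rest$rate,
                                                            peak$rate)),
             rest_r2 = rest$r2, peak_r2 = peak$r2,
             peak_window_start_s = peak$window_s[1L],
             stringsAsFactors = FALSE)
}

#' Per-stage Q10 table
#'
#' For every stage, K1 and K2 are the unweighted means of per-shoal rates
#' in the 28 deg C and 32 deg C cells; one Q10 is computed per stage for
#' resting and for peak rates.  T1 and T2 are the mean recorded treatment
#' temperatures of the contributing shoals (falling back to nominal
#' treatment temperatures when no recorded values exist).
#'
#' @param records data.frame of per-shoal metabolic records (columns
#'   `stage`, `temperature_c`, `mo2_rest`, `mo2_peak`; optional
#'   `recorded_temp_c` with per-shoal recorded means).
#' @return data.frame with one row per stage x rate-type: `stage`,
#'   `rate_type`, `k1`, `k2`, `t1`, `t2`, `q10`, `n1`, `n2`.  Empty
#'   temperature cells yield `NA` with a warning.
#' @export
stage_q10_table <- function(records) {
  stopifnot(is.data.frame(records))
  temps <- sort(unique(records$temperature_c))
  if (length(temps) != 2L) {
    stop_invalid("Q10 requires exactly two treatment temperatures (got %d)",
                 length(temps))
  }
  rows <- list()
  for (st in unique(records$stage)) {
    for (rt in c("rest", "peak")) {
      col <- paste0("mo2_", rt)
      lo <- records[records$stage == st & records$temperature_c == temps[1L], ]
      hi <- records[records$stage == st & records$temperature_c == temps[2L], ]
      if (!nrow(lo) || !nrow(hi)) {
        warning(sprintf("stage %s: empty temperature cell; Q10 missing", st))
        rows[[length(rows) + 1L]] <- data.frame(
          stage = st, rate_type = rt, k1 = NA_real_, k2 = NA_real_,
          t1 = temps[1L], t2 = temps[2L], q10 = NA_real_,
          n1 = nrow(lo), n2 = nrow(hi), stringsAsFactors = FALSE)
        next
      }
      t1 <- if (!is.null(lo$recorded_temp_c) && any(!is.na(lo$recorded_temp_c))) {
        mean(lo$recorded_temp_c, na.rm = TRUE)
      } else temps[1L]
      t2 <- if (!is.null(hi$recorded_temp_c) && any(!is.na(hi$recorded_temp_c))) {
        mean(hi$recorded_temp_c, na.rm = TRUE)
      } else temps[2L]
      k1 <- mean(lo[[col]]); k2 <- mean(hi[[col]])
      rows[[length(rows) + 1L]] <- data.frame(
        stage = st, rate_type = rt, k1 = k1, k2 = k2, t1 = t1, t2 = t2,
        q10 = q10(k1, k2, t1, t2), n1 = nrow(lo), n2 = nrow(hi),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
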