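# Recorded acclimation temperatures (mean, SD) per shoal and stage for
# the default study layout: 10 shoals alternating 32/28 deg C treatment,
# three stages, with juvenile shoal 9 never run.
default_shoal_table <- function() {
  temp_trt <- rep(c(32, 28), 5)
  rec <- list(
    larva    = cbind(c(32.0, 28.1, 32.1, 28.0, 32.0, 28.1, 32.0, 28.1, 32.1, 28.0),
                     c(0.7, 0.2, 0.2, 0.2, 0.6, 0.1, 0.3, 0.2, 0.2, 0.2)),
    juvenile = cbind(c(32.2, 28.1, 32.1, 27.9, 31.9, 28.1, 32.2, 28.1, NA, 27.9),
                     c(0.4, 0.1, 0.2, 0.4, 0.2, 0.1, 0.1, 0.0, NA, 0.4)),
    adult    = cbind(c(31.9, 28.0, 32.2, 28.1, 31.9, 28.1, 31.8, 28.1, 32.2, 28.0),
                     c(0.5, 0.2, 0.2, 0.3, 0.4, 0.1, 0.3, 0.2, 0.2, 0.2)))
  rows <- list()
  for (st in names(rec)) {
    pre <- toupper(substr(st, 1, 1))
    for (i in 1:10) {
      if (is.na(rec[[st]][i, 1])) next  # shoal never run
      rows[[length(rows) + 1L]] <- data.frame(
        shoal_id = paste0(pre, i), stage = st,
        treatment_temp_c = temp_trt[i],
        recorded_temp_mean_c = rec[[st]][i, 1],
        recorded_temp_sd_c = rec[[st]][i, 2],
        n_fish = 5L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Stage-level ground-truth parameters of the default synthetic study.
# TBF follows tbf = tbf_int + tbf_slope * speed (Hz), scaled by
# tbf_temp_fac at the warm treatment; kinematic amplitudes and
# wavelength are per-stage constants; metabolic thermal sensitivity is
# injected through true Q10 values applied over the nominal 28->32 degC
# contrast.
default_stage_params <- function() {
  data.frame(
    stage = c("larva", "juvenile", "adult"),
    tbf_int = c(15, 8, 2), tbf_slope = c(3, 2, 1.2),
    tbf_temp_fac = c(1.10, 1.05, 1.02),
    wavelength_bl = c(0.70, 0.95, 1.10),
    head_amp_bl = c(0.04, 0.03, 0.02), tail_amp_bl = c(0.10, 0.10, 0.10),
    mean_sep_bl = c(3.6, 2.4, 1.2),
    switch_rate_per_s = c(0.10, 0.15, 0.20),
    mo2_rest_28 = c(1.2, 0.8, 2.0),
    factorial_scope = c(3.5, 3.0, 5.0),
    q10_rest = c(1.96, 9.98, 2.19), q10_peak = c(1.03, 1.37, 2.53),
    body_length_28_mm = c(8.40, 14.32, 36.84),
    body_length_32_mm = c(8.00, 13.45, 36.04),
    stringsAsFactors = FALSE)
}

stage_speeds <- function(stage) {
  switch(stage,
         larva = c(1.5, 2.6, 3, 4, 5),
         juvenile = c(1.5, 2, 3, 4, 5),
         adult = c(1, 1.5, 2, 3, 4, 5),
         stop_invalid("unknown stage '%s'", stage))
}

#' Synthetic study design
#'
#' Experiment layout of the default synthetic study: 3 ontogenetic
#' stages x 2 acclimation temperatures, 9–10 shoals of 5 fish per stage
#' (29 shoals in total), each stage tested at its speed list (larvae
#' 1.5/2.6/3/4/5, juveniles 1.5/2/3/4/5, adults 1/1.5/2/3/4/5 BL/s).
#' Effect sizes on TBF, separation distance and metabolic rates are
#' injectable through `stage_params`; `effects = "null"` equalizes all
#' stage and temperature parameters (every cell drawn from one
#' population), for type-I-error studies.
#'
#' @param shoals shoal metadata table (default mirrors the study layout).
#' @param stage_params per-stage ground-truth parameter table.
#' @param effects `"default"` (ontogenetic + thermal effects injected)
#'   or `"null"` (no effects).
#' @param noise list of nuisance parameters: `shoal_cv` (between-shoal
#'   lognormal CV on kinematic/behavioral truths), `fish_cv`
#'   (between-fish CV on TBF), `midline_noise_sd_bl`, `traj_jitter_sd_bl`,
#'   `o2_noise_sd`, `n_cycles`, `frame_rate`, `traj_duration_s`,
#'   `traj_sample_hz`.
#' @return An object of class `study_design`.
#' @export
study_design <- function(shoals = default_shoal_table(),
                         stage_params = default_stage_params(),
                         effects = c("default", "null"),
                         noise = list()) {
  effects <- match.arg(effects)
  if (anyDuplicated(shoals$shoal_id)) {
    stop_invalid("duplicate shoal IDs in design: %s",
                 paste(unique(shoals$shoal_id[duplicated(shoals$shoal_id)]),
                       collapse = ", "))
  }
  if (effects == "null") {
    # one common parameter set: no stage or temperature effect anywhere
    for (cl in setdiff(names(stage_params), "stage")) {
      stage_params[[cl]] <- mean(stage_params[[cl]])
    }
    stage_params$tbf_temp_fac <- 1
    stage_params$q10_rest <- 1
    stage_params$q10_peak <- 1
  }
  defaults <- list(shoal_cv = 0.06, fish_cv = 0.03,
                   midline_noise_sd_bl = 0.003, traj_jitter_sd_bl = 0.02,
                   o2_noise_sd = 0.02, n_cycles = 3L, frame_rate = 1000,
                   traj_duration_s = 60, traj_sample_hz = 20)
  noise <- utils::modifyList(defaults, noise)
  structure(list(shoals = shoals, stage_params = stage_params,
                 effects = effects, noise = noise),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d shoals (%s), effects: %s\n",
              nrow(x$shoals),
              paste(sprintf("%d %s", table(x$shoals$stage)[unique(x$shoals$stage)],
                            unique(x$shoals$stage)), collapse = ", "),
              x$effects))
  invisible(x)
}

#' Simulate one shoal of the study design
#'
#' Generates everything measured for a single shoal: five midline
#' sequences (one per fish) and one shoal trajectory at every
#' stage-appropriate flow speed, plus one rest + recovery oxygen trace.
#' Deterministic given (design, seed).
#'
#' @param design a [study_design()].
#' @param shoal_row one row of `design$shoals`.
#' @param seed RNG seed for this shoal.
#' @return A list with elements `shoal` (the metadata row),
#'   `body_length_mm`, `speeds`, `per_speed` (per speed: `speed`, `fish`
#'   midline generator outputs, `traj` trajectory generator output),
#'   `oxygen` (oxygen generator output), and `truth` (the injected
#'   metabolic ground truth).
#' @export
simulate_shoal <- function(design, shoal_row, seed) {
  sp <- design$stage_params[design$stage_params$stage == shoal_row$stage, ]
  nz <- design$noise
  warm <- shoal_row$treatment_temp_c == 32
  bl <- if (warm) sp$body_length_32_mm else sp$body_length_28_mm
  speeds <- stage_speeds(shoal_row$stage)

  shoal_fac <- with_seed(derive_seed(seed, 1L), {
    exp(stats::rnorm(6, 0, nz$shoal_cv))  # tbf, sep, switch, rest, peak, amp
  })
  tbf_temp <- if (warm) sp$tbf_temp_fac else 1
  q_fac_rest <- if (warm) sp$q10_rest^((32 - 28) / 10) else 1
  q_fac_peak <- if (warm) sp$q10_peak^((32 - 28) / 10) else 1

  per_speed <- list()
  for (si in seq_along(speeds)) {
    v <- speeds[si]
    tbf_true <- (sp$tbf_int + sp$tbf_slope * v) * tbf_temp * shoal_fac[1]
    fish <- list()
    for (fi in 1:shoal_row$n_fish) {
      fseed <- derive_seed(seed, 10L + si * 10L + fi)
      fish_fac <- with_seed(fseed, exp(stats::rnorm(1, 0, nz$fish_cv)))
      wp <- wave_model_params(
        tbf_hz = tbf_true * fish_fac,
        wavelength_bl = sp$wavelength_bl,
        head_amp_bl = sp$head_amp_bl * shoal_fac[6],
        tail_amp_bl = sp$tail_amp_bl * shoal_fac[6],
        body_length = bl, frame_rate = nz$frame_rate,
        noise_sd_bl = nz$midline_noise_sd_bl,
        phase = 2 * pi * fi / shoal_row$n_fish,
        seed = derive_seed(fseed, 2L))
      fish[[fi]] <- generate_midline_sequence(wp, n_cycles = nz$n_cycles,
                                              fish_id = paste0("f", fi))
    }
    tp <- shoal_sim_params(
      n_fish = shoal_row$n_fish,
      mean_sep_bl = sp$mean_sep_bl * shoal_fac[2],
      switch_rate_per_s = sp$switch_rate_per_s * shoal_fac[3],
      flow_speed_bl_s = v, duration_s = nz$traj_duration_s,
      sample_hz = nz$traj_sample_hz, jitter_sd_bl = nz$traj_jitter_sd_bl,
      body_length_mm = bl, seed = derive_seed(seed, 900L + si))
    per_speed[[si]] <- list(speed = v, fish = fish,
                            traj = generate_shoal_trajectory(tp))
  }

  rest_true <- sp$mo2_rest_28 * q_fac_rest * shoal_fac[4]
  peak_true <- sp$mo2_rest_28 * sp$factorial_scope * q_fac_peak * shoal_fac[5]
  rp <- respo_sim_params(resting_slope = rest_true,
                         peak_slope = max(peak_true, rest_true),
                         o2_start = 8, noise_sd = nz$o2_noise_sd,
                         temperature_c = shoal_row$treatment_temp_c,
                         seed = derive_seed(seed, 999L))
  oxy <- generate_oxygen_trace(rp, shoal_id = shoal_row$shoal_id,
                               stage = shoal_row$stage)

  list(shoal = shoal_row, body_length_mm = bl, speeds = speeds,
       per_speed = per_speed, oxygen = oxy,
       truth = list(tbf_28_intercept = sp$tbf_int,
                    rest_true = rest_true, peak_true = peak_true))
}

#' Generate and write a full synthetic study bundle
#'
#' Simulates every shoal of the design and writes midline, trajectory
#' and oxygen files (synthetic-data formats), a `metadata.csv`, and a
#' structured truth manifest pairing every artifact with its generating
#' parameters.  Regeneration from the same (design, seed) is
#' byte-identical.
#'
#' @param design a [study_design()].
#' @param dir output directory (created if needed).
#' @param seed base RNG seed; per-shoal seeds are derived
#'   deterministically from it.
#' @return `dir`, invisibly.
#' @export
generate_study <- function(design, dir, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("midlines", "trajectories", "oxygen")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  truth <- list()
  meta <- design$shoals
  meta$recorded_temp <- sprintf("%.1f \u00b1 %.1f", meta$recorded_temp_mean_c,
                                meta$recorded_temp_sd_c)
  meta$body_length_mm <- NA_real_
  for (i in seq_len(nrow(design$shoals))) {
    row <- design$shoals[i, ]
    sim <- simulate_shoal(design, row, derive_seed(seed, i))
    meta$body_length_mm[i] <- sim$body_length_mm
    for (ps in sim$per_speed) {
      trial <- sprintf("%s_v%g", row$shoal_id, ps$speed)
      mpath <- file.path(dir, "midlines", paste0(trial, ".csv"))
      write_midline_file(lapply(ps$fish, `[[`, "seq"), mpath, trial_id = trial)
      tpath <- file.path(dir, "trajectories", paste0(trial, ".csv"))
      write_trajectory_file(ps$traj$traj, tpath, trial_id = trial)
      truth[[paste0("midlines/", trial)]] <-
        lapply(ps$fish, function(f) unclass(f$truth))
      truth[[paste0("trajectories/", trial)]] <- unclass(ps$traj$truth)
    }
    opath <- file.path(dir, "oxygen", paste0(row$shoal_id, ".csv"))
    write_oxygen_file(sim$oxygen$trace, opath, trial_id = row$shoal_id)
    truth[[paste0("oxygen/", row$shoal_id)]] <- unclass(sim$oxygen$truth)
  }
  utils::write.csv(meta[, c("shoal_id", "stage", "treatment_temp_c",
                            "recorded_temp", "body_length_mm", "n_fish")],
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}
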