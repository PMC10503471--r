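#' Pipeline configuration
#'
#' Defaults equal the documented module defaults.  `mode = "synthetic"`
#' simulates the study design and analyzes it; `mode = "provided"` reads
#' an existing data directory in the synthetic-data file formats
#' (`metadata.csv`, `midlines/`, `trajectories/`, `oxygen/`).
#'
#' @param out_dir output directory for result tables.
#' @param mode `"synthetic"` or `"provided"`.
#' @param seed base RNG seed for simulation and permutation tests.
#' @param design a [study_design()] (synthetic mode).
#' @param input_dir data directory (provided mode).
#' @param sample_hz,hysteresis_bl switch-rate parameters.
#' @param rest_window_min,peak_window_min respirometry slope windows.
#' @param m_permutations permutations per test.
#' @param min_cycles minimum detected cycles per contributing sequence.
#' @param amp_method amplitude estimator (see [oscillation_amplitudes()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, mode = c("synthetic", "provided"),
                            seed = 1L, design = study_design(),
                            input_dir = NULL, sample_hz = 10,
                            hysteresis_bl = 0.05, rest_window_min = 30,
                            peak_window_min = 10, m_permutations = 4999,
                            min_cycles = 1L, amp_method = "harmonic") {
  mode <- match.arg(mode)
  if (mode == "provided" && is.null(input_dir)) {
    stop_invalid("provided-data mode needs input_dir")
  }
  structure(list(out_dir = out_dir, mode = mode, seed = as.integer(seed),
                 design = design, input_dir = input_dir,
                 sample_hz = sample_hz, hysteresis_bl = hysteresis_bl,
                 rest_window_min = rest_window_min,
                 peak_window_min = peak_window_min,
                 m_permutations = m_permutations, min_cycles = min_cycles,
                 amp_method = amp_method),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error, omitted keys keep their defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file (e.g. from a caller).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop_invalid("unknown config key(s): %s",
                                paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

# Analyze one shoal's data (in-memory form produced by simulate_shoal or
# assembled by the provided-data reader).
analyze_shoal <- function(sim, config) {
  kin_rows <- list()
  for (ps in sim$per_speed) {
    recs <- do.call(rbind, lapply(ps$fish, function(f) {
      sq <- if (inherits(f, "midline_sequence")) f else f$seq
      analyze_midline_sequence(sq, min_cycles = config$min_cycles,
                               amp_method = config$amp_method)
    }))
    n_no_cycle <- sum(recs$n_cycles_used == 0L)
    if (n_no_cycle > 0) {
      warning(sprintf("shoal %s at %g BL/s: %d fish without a full cycle excluded",
                      sim$shoal$shoal_id, ps$speed, n_no_cycle))
    }
    row <- summarize_shoal(recs)
    traj <- if (inherits(ps$traj, "shoal_trajectory")) ps$traj else ps$traj$traj
    beh <- shoal_metrics(traj, config$sample_hz, config$hysteresis_bl)
    kin_rows[[length(kin_rows) + 1L]] <-
      cbind(data.frame(shoal_id = sim$shoal$shoal_id, stage = sim$shoal$stage,
                       temperature_c = sim$shoal$treatment_temp_c,
                       speed_bl_s = ps$speed, stringsAsFactors = FALSE),
            row, beh)
  }
  trace <- if (inherits(sim$oxygen, "oxygen_trace")) sim$oxygen else sim$oxygen$trace
  met <- metabolic_record(trace, config$rest_window_min, config$peak_window_min)
  met$recorded_temp_c <- sim$shoal$recorded_temp_mean_c
  list(kin = do.call(rbind, kin_rows), met = met)
}

# Read one shoal's files from a provided-data directory.
read_shoal_data <- function(input_dir, meta_row) {
  sid <- meta_row$shoal_id
  mfiles <- list.files(file.path(input_dir, "midlines"),
                       pattern = paste0("^", sid, "_v.*\\.csv$"),
                       full.names = TRUE)
  per_speed <- lapply(mfiles, function(mf) {
    trial <- sub("\\.csv$", "", basename(mf))
    speed <- as.numeric(sub(".*_v", "", trial))
    seqs <- read_midline_file(mf, body_length_mm = meta_row$body_length_mm)
    tf <- file.path(input_dir, "trajectories", paste0(trial, ".csv"))
    traj <- read_trajectory_file(tf, body_length_mm = meta_row$body_length_mm)
    list(speed = speed, fish = unname(seqs), traj = traj)
  })
  per_speed <- per_speed[order(vapply(per_speed, `[[`, numeric(1), "speed"))]
  trace <- read_oxygen_file(file.path(input_dir, "oxygen", paste0(sid, ".csv")),
                            shoal_id = sid, stage = meta_row$stage)
  list(shoal = meta_row, per_speed = per_speed, oxygen = trace)
}

kinematic_test_variables <- c("tbf_hz", "head_amp_bl", "tail_amp_bl",
                              "head_tail_ratio", "wave_speed_bl_s",
                              "wavelength_bl", "max_curvature_per_bl",
                              "mean_sep_bl", "switch_rate_per_s")

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the study, computes per-shoal kinematics and
#' behavior at every speed, per-shoal metabolic rates, the per-stage Q10
#' table, and the permutation-test tables; writes all result tables, a
#' plain-text summary of the headline ontogenetic/thermal contrasts, and
#' a manifest with content hashes.  Deterministic for a fixed
#' (config, seed).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the result tables (`kinematics`,
#'   `metabolic`, `q10`, `perm_tests`, `mo2_tests`, `summary_lines`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  if (config$mode == "provided") {
    meta_path <- file.path(config$input_dir, "metadata.csv")
    if (!file.exists(meta_path)) {
      stop_invalid("provided-data directory %s has no metadata.csv; aborting before any output",
                   config$input_dir %||% "<missing>")
    }
    meta <- load_metadata(meta_path)
  } else {
    meta <- config$design$shoals
  }

  kin_list <- list(); met_list <- list()
  for (i in seq_len(nrow(meta))) {
    row <- meta[i, ]
    sim <- if (config$mode == "synthetic") {
      simulate_shoal(config$design, row, derive_seed(config$seed, i))
    } else {
      read_shoal_data(config$input_dir, row)
    }
    res <- suppressWarnings(analyze_shoal(sim, config))
    kin_list[[i]] <- res$kin
    met_list[[i]] <- res$met
    say("analyzed shoal %s (%s, %g degC): %d speeds", row$shoal_id,
        row$stage, row$treatment_temp_c, nrow(res$kin))
  }
  kin <- do.call(rbind, kin_list)
  met <- do.call(rbind, met_list)
  q10_tbl <- suppressWarnings(stage_q10_table(met))

  say("running permutation tests (m = %d)", config$m_permutations)
  perm <- within_speed_sweep(kin, kinematic_test_variables,
                             model = "two_way_interaction",
                             m_permutations = config$m_permutations,
                             seed = derive_seed(config$seed, 5000L))
  mo2_rows <- list()
  for (st in unique(met$stage)) {
    d <- met[met$stage == st, ]
    if (length(unique(d$temperature_c)) < 2L) next
    for (v in c("mo2_rest", "mo2_peak")) {
      r <- permutation_anova(d[[v]], a = d$temperature_c, model = "one_way",
                             m_permutations = config$m_permutations,
                             seed = derive_seed(config$seed, 6000L))
      r$stage <- st; r$variable <- v
      mo2_rows[[length(mo2_rows) + 1L]] <- r
    }
  }
  if (length(unique(met$stage)) >= 2L &&
      length(unique(met$temperature_c)) >= 2L) {
    fact <- permutation_anova(met$factorial_mo2, a = met$stage,
                              b = met$temperature_c,
                              model = "two_way_interaction",
                              m_permutations = config$m_permutations,
                              seed = derive_seed(config$seed, 7000L))
    fact$stage <- "all"; fact$variable <- "factorial_mo2"
    mo2_rows <- c(mo2_rows, list(fact))
  }
  mo2_tests <- do.call(rbind, mo2_rows)

  summary_lines <- pipeline_summary(kin, met, q10_tbl, perm, mo2_tests)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(kinematics = "kinematics_by_shoal.csv",
             metabolic = "metabolic_rates.csv",
             q10 = "q10_by_stage.csv",
             perm_tests = "perm_tests.csv",
             mo2_tests = "mo2_tests.csv")
  tables <- list(kinematics = kin, metabolic = met, q10 = q10_tbl,
                 perm_tests = perm, mo2_tests = mo2_tests)
  for (nm in names(paths)) {
    utils::write.csv(tables[[nm]] %||% data.frame(),
                     file.path(config$out_dir, paths[nm]), row.names = FALSE)
  }
  writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))

  files <- c(unname(paths), "summary.txt")
  manifest <- list(
    seed = config$seed, mode = config$mode,
    parameters = config[c("sample_hz", "hysteresis_bl", "rest_window_min",
                          "peak_window_min", "m_permutations", "min_cycles",
                          "amp_method")],
    n_shoals = nrow(meta),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %s", config$out_dir)
  invisible(c(tables, list(summary_lines = summary_lines,
                           out_dir = config$out_dir)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Headline contrasts as plain-text summary lines.
pipeline_summary <- function(kin, met, q10_tbl, perm, mo2_tests) {
  stage_order <- c("larva", "juvenile", "adult")
  stages <- intersect(stage_order, unique(kin$stage))
  sep_means <- vapply(stages, function(st) {
    mean(kin$mean_sep_bl[kin$stage == st], na.rm = TRUE)
  }, numeric(1))
  tbf_means <- vapply(stages, function(st) {
    mean(kin$tbf_hz[kin$stage == st], na.rm = TRUE)
  }, numeric(1))
  lines <- c(
    sprintf("shoals analyzed: %d (%s)", length(unique(kin$shoal_id)),
            paste(sprintf("%s=%d", stages,
                          vapply(stages, function(st)
                            length(unique(kin$shoal_id[kin$stage == st])),
                            integer(1))), collapse = ", ")),
    sprintf("mean separation distance (BL): %s",
            paste(sprintf("%s %.2f", stages, sep_means), collapse = ", ")),
    sprintf("separation distance decreases with ontogeny: %s",
            !is.unsorted(rev(sep_means))),
    sprintf("mean TBF (Hz): %s",
            paste(sprintf("%s %.1f", stages, tbf_means), collapse = ", ")),
    sprintf("TBF decreases with ontogeny: %s", !is.unsorted(rev(tbf_means))))
  for (rt in c("rest", "peak")) {
    qs <- q10_tbl[q10_tbl$rate_type == rt, ]
    qs <- qs[match(stages, qs$stage), ]
    lines <- c(lines, sprintf("Q10 (%s): %s", rt,
                              paste(sprintf("%s %.2f", qs$stage, qs$q10),
                                    collapse = ", ")))
  }
  jr <- met[met$stage == "juvenile", ]
  if (nrow(jr) && length(unique(jr$temperature_c)) == 2L) {
    k <- tapply(jr$mo2_rest, jr$temperature_c, mean)
    lines <- c(lines, sprintf(
      "juvenile resting-rate warm:cool ratio: %.2f (elevated: %s)",
      k[2] / k[1], k[2] / k[1] > 1.5))
  }
  if (!is.null(perm) && nrow(perm)) {
    st_tests <- perm[perm$term == "a", ]
    lines <- c(lines, sprintf(
      "stage effect significant in %d / %d (variable, speed) permutation tests",
      sum(st_tests$significant), nrow(st_tests)))
  }
  lines
}
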