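# File formats: flat delimited tables with a one-line header.
#   midline:    trial_id, fish_id, frame, time_s, point_index, x_mm, y_mm
#   trajectory: trial_id, fish_id, time_s, x_mm, y_mm
#   oxygen:     trial_id, time_s, phase, o2_mg_per_l, temp_c
# Coordinates are stored in mm; BL normalization happens at computation
# time, never at storage time.

#' Write midline sequences to a delimited file
#'
#' @param seqs a [midline_sequence()] or list of them (one per fish).
#' @param path output file.
#' @param trial_id trial identifier stored with every row.
#' @return `path`, invisibly.
#' @export
write_midline_file <- function(seqs, path, trial_id = "t1") {
  if (inherits(seqs, "midline_sequence")) seqs <- list(seqs)
  rows <- lapply(seqs, function(sq) {
    n_f <- nrow(sq$x); n_p <- ncol(sq$x)
    data.frame(trial_id = trial_id, fish_id = sq$fish_id,
               frame = rep(seq_len(n_f), each = n_p),
               time_s = rep(sq$time_s, each = n_p),
               point_index = rep.int(0:(n_p - 1L), n_f),
               x_mm = as.vector(t(sq$x)), y_mm = as.vector(t(sq$y)),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read midline sequences from a delimited file
#'
#' @param path midline file (format of [write_midline_file()]).
#' @param body_length_mm single body length or named vector keyed by
#'   `fish_id` (the file format stores calibrated coordinates only).
#' @param frame_rate fps; inferred from the time stamps when `NULL`.
#' @return Named list of [midline_sequence()] objects, one per fish.
#' @export
read_midline_file <- function(path, body_length_mm, frame_rate = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "frame", "time_s", "point_index", "x_mm", "y_mm")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_invalid("midline file %s lacks required column(s): %s", path,
                 paste(miss, collapse = ", "))
  }
  out <- lapply(split(d, d$fish_id), function(df) {
    df <- df[order(df$frame, df$point_index), ]
    n_p <- length(unique(df$point_index))
    n_f <- nrow(df) / n_p
    if (n_f != round(n_f)) {
      stop_invalid("midline file %s: fish %s has ragged frames", path,
                   df$fish_id[1L])
    }
    t_s <- df$time_s[seq(1L, nrow(df), by = n_p)]
    fr <- if (is.null(frame_rate)) 1 / stats::median(diff(t_s)) else frame_rate
    bl <- if (length(body_length_mm) > 1L) {
      body_length_mm[[df$fish_id[1L]]]
    } else body_length_mm
    midline_sequence(time_s = t_s,
                     x = matrix(df$x_mm, n_f, n_p, byrow = TRUE),
                     y = matrix(df$y_mm, n_f, n_p, byrow = TRUE),
                     body_length_mm = bl, frame_rate = fr,
                     fish_id = df$fish_id[1L])
  })
  out
}

#' Write a shoal trajectory to a delimited file
#' @param traj a [shoal_trajectory()].
#' @param path output file.
#' @param trial_id trial identifier.
#' @return `path`, invisibly.
#' @export
write_trajectory_file <- function(traj, path, trial_id = "t1") {
  n <- ncol(traj$x)
  d <- data.frame(trial_id = trial_id,
                  fish_id = rep(traj$fish_ids, each = nrow(traj$x)),
                  time_s = rep(traj$time_s, n),
                  x_mm = as.vector(traj$x), y_mm = as.vector(traj$y),
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a shoal trajectory from a delimited file
#' @param path trajectory file.
#' @param body_length_mm per-fish body lengths (scalar, or named vector
#'   keyed by `fish_id`).
#' @param flow_axis flow-axis unit vector.
#' @return A [shoal_trajectory()].
#' @export
read_trajectory_file <- function(path, body_length_mm, flow_axis = c(1, 0)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "time_s", "x_mm", "y_mm")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_invalid("trajectory file %s lacks required column(s): %s", path,
                 paste(miss, collapse = ", "))
  }
  ids <- unique(d$fish_id)
  t_s <- sort(unique(d$time_s))
  x <- sapply(ids, function(f) d$x_mm[d$fish_id == f][order(d$time_s[d$fish_id == f])])
  y <- sapply(ids, function(f) d$y_mm[d$fish_id == f][order(d$time_s[d$fish_id == f])])
  bl <- if (length(body_length_mm) > 1L) {
    unname(body_length_mm[ids])
  } else body_length_mm
  shoal_trajectory(time_s = t_s, x = x, y = y, body_length_mm = bl,
                   flow_axis = flow_axis, fish_ids = ids)
}

#' Write an oxygen trace to a delimited file
#' @param trace an [oxygen_trace()].
#' @param path output file.
#' @param trial_id trial identifier.
#' @return `path`, invisibly.
#' @export
write_oxygen_file <- function(trace, path, trial_id = trace$shoal_id) {
  d <- data.frame(trial_id = trial_id, time_s = trace$time_s,
                  phase = trace$phase, o2_mg_per_l = trace$o2,
                  temp_c = trace$temperature_c, stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read an oxygen trace from a delimited file
#' @param path oxygen file.
#' @param shoal_id,stage identifiers (from trial metadata).
#' @return An [oxygen_trace()].
#' @export
read_oxygen_file <- function(path, shoal_id = NULL, stage = "unknown") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "phase", "o2_mg_per_l", "temp_c")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_invalid("oxygen file %s lacks required column(s): %s", path,
                 paste(miss, collapse = ", "))
  }
  if (is.null(shoal_id)) {
    shoal_id <- if ("trial_id" %in% names(d)) as.character(d$trial_id[1L]) else "s1"
  }
  oxygen_trace(time_s = d$time_s, o2 = d$o2_mg_per_l, phase = d$phase,
               temperature_c = d$temp_c[1L], shoal_id = shoal_id,
               stage = stage)
}

# parse "32.0 ± 0.7" (or "32.0 +/- 0.7") into c(mean, sd)
parse_mean_sd <- function(x) {
  x <- trimws(x)
  parts <- strsplit(x, "\u00b1|\\+/-")[[1]]
  if (length(parts) != 2L) {
    return(c(mean = suppressWarnings(as.numeric(x)), sd = NA_real_))
  }
  c(mean = as.numeric(trimws(parts[1])), sd = as.numeric(trimws(parts[2])))
}

#' Load trial metadata
#'
#' Reads a shoal metadata table (one row per shoal): columns `shoal_id`,
#' `stage` (larva/juvenile/adult), `treatment_temp_c` (28/32),
#' `recorded_temp` (a "mean ± SD" string, parsed into
#' `recorded_temp_mean_c` / `recorded_temp_sd_c`), `body_length_mm`, and
#' optionally `n_fish` and `mass_g`.  Rows whose `recorded_temp` is the
#' absence marker `–` (or `-`/`NA`) are dropped: those shoals were
#' not run.
#'
#' @param path CSV file.
#' @return Validated data.frame of trial metadata.
#' @export
load_metadata <- function(path) {
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) NULL)
  need <- c("shoal_id", "stage", "treatment_temp_c", "recorded_temp",
            "body_length_mm")
  if (is.null(d) || nrow(d) == 0L || !all(need %in% names(d))) {
    stop_invalid("metadata file %s is empty or lacks required columns: %s",
                 path, paste(need, collapse = ", "))
  }
  absent <- trimws(d$recorded_temp) %in% c("\u2013", "-", "", "NA")
  d <- d[!absent, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    if (!d$stage[i] %in% c("larva", "juvenile", "adult")) {
      stop_invalid("metadata row %d: unknown stage label '%s'", i, d$stage[i])
    }
    if (is.na(d$shoal_id[i]) || d$shoal_id[i] == "") {
      stop_invalid("metadata row %d: missing shoal_id", i)
    }
  }
  if (anyDuplicated(d$shoal_id)) {
    stop_invalid("duplicate shoal IDs in metadata: %s",
                 paste(d$shoal_id[duplicated(d$shoal_id)], collapse = ", "))
  }
  ms <- t(vapply(d$recorded_temp, parse_mean_sd, numeric(2)))
  d$recorded_temp_mean_c <- ms[, 1L]
  d$recorded_temp_sd_c <- ms[, 2L]
  if (!"n_fish" %in% names(d)) d$n_fish <- 5L
  rownames(d) <- NULL
  d
}
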