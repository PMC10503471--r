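# Internal engine: sequential (Type I) sums of squares via the QR
# decomposition of the model matrix.  The decomposition is computed once
# per design; permutations only re-project the response, which keeps
# large permutation runs cheap.
anova_engine <- function(X, assign) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop_invalid("degenerate design: model matrix is rank-deficient")
  }
  n <- nrow(X)
  p <- ncol(X)
  terms <- sort(unique(assign[assign > 0]))
  cols <- lapply(terms, function(tm) which(assign == tm))
  df_terms <- lengths(cols)
  df_res <- n - p
  if (df_res <= 0) stop_invalid("no residual degrees of freedom")
  list(qr = qr_x, n = n, p = p, cols = cols, terms = terms,
       df_terms = df_terms, df_res = df_res)
}

# F statistics per term for a response vector under a prepared engine.
# Sums of squares below a relative floor are treated as exact zeros so
# that noise-free designs report F = 0 (null term, zero residual) or an
# infinite marker (real effect, zero residual) rather than ratios of
# rounding error.
engine_f <- function(eng, y) {
  eff <- qr.qty(eng$qr, y)
  rss <- sum(eff[(eng$p + 1L):eng$n]^2)
  ss <- vapply(eng$cols, function(cl) sum(eff[cl]^2), numeric(1))
  tol <- 1e-12 * max(sum(eff[-1L]^2), .Machine$double.eps)
  ss[ss <= tol] <- 0
  if (rss <= tol) rss <- 0
  ms <- ss / eng$df_terms
  mse <- rss / eng$df_res
  f <- if (mse > 0) ms / mse else ifelse(ms > 0, Inf, 0)
  f[ms == 0] <- 0
  f
}

model_formula <- function(model) {
  switch(model,
         one_way = ~a,
         two_way_interaction = ~ a * b,
         stop_invalid("unknown model '%s'", model))
}

prepare_design <- function(response, a, b = NULL, model) {
  if (anyNA(response)) stop_invalid("response contains missing values")
  a <- factor(a)
  if (nlevels(a) < 2L) stop_invalid("factor A needs at least 2 levels")
  df <- data.frame(a = a)
  if (model == "two_way_interaction") {
    if (is.null(b)) stop_invalid("two-way model needs factor B")
    b <- factor(b)
    if (nlevels(b) < 2L) stop_invalid("factor B needs at least 2 levels")
    df$b <- b
    if (any(table(a, b) < 1L)) {
      stop_invalid("every factor-level combination needs at least one observation")
    }
  }
  X <- stats::model.matrix(model_formula(model), df)
  list(X = X, assign = attr(X, "assign"), data = df)
}

#' Classical ANOVA F statistics (sequential sums of squares)
#'
#' F statistics of the linear factorial model from sequential (Type I)
#' sums of squares, term order A, B, A:B.  With equal cell sizes this
#' matches Type III.  Zero residual variance yields `Inf` for terms with
#' positive effect sums of squares and 0 for null terms.
#'
#' @param response numeric response vector (one value per analysis unit,
#'   e.g. per shoal).
#' @param a factor A labels (e.g. ontogenetic stage).
#' @param b factor B labels (e.g. acclimation temperature); only for the
#'   two-way model.
#' @param model `"one_way"` or `"two_way_interaction"`.
#' @return data.frame with one row per term: `term`, `df`, `ss`, `F`.
#' @export
anova_f <- function(response, a, b = NULL,
                    model = c("one_way", "two_way_interaction")) {
  model <- match.arg(model)
  dsn <- prepare_design(response, a, b, model)
  eng <- anova_engine(dsn$X, dsn$assign)
  eff <- qr.qty(eng$qr, response)
  ss <- vapply(eng$cols, function(cl) sum(eff[cl]^2), numeric(1))
  f <- engine_f(eng, response)
  labels <- attr(stats::terms(model_formula(model)), "term.labels")
  data.frame(term = c("a", "b", "a:b")[eng$terms],
             label = labels[eng$terms],
             df = eng$df_terms, ss = ss, F = f,
             stringsAsFactors = FALSE)
}

# All distinct assignments of observations to groups with fixed group
# sizes, as a list of index permutations (the first is the identity-like
# canonical one).  Count must have been pre-checked against the cap.
enumerate_assignments <- function(group_sizes) {
  n <- sum(group_sizes)
  out <- list()
  recurse <- function(remaining, sizes) {
    if (!length(sizes)) {
      out[[length(out) + 1L]] <<- integer(0)
      return(invisible(NULL))
    }
    picks <- utils::combn(length(remaining), sizes[1L], simplify = FALSE)
    for (pk in picks) {
      chosen <- remaining[pk]
      rest <- remaining[-pk]
      before <- length(out)
      recurse(rest, sizes[-1L])
      for (i in (before + 1L):length(out)) {
        out[[i]] <<- c(chosen, out[[i]])
      }
    }
    invisible(NULL)
  }
  recurse(seq_len(n), group_sizes)
  out
}

n_distinct_assignments <- function(group_sizes) {
  exp(lgamma(sum(group_sizes) + 1) - sum(lgamma(group_sizes + 1)))
}

#' Permutation ANOVA
#'
#' One-way designs are tested by raw-label permutation: the permutation
#' distribution of the F statistic under reshuffling of the response
#' against the group labels, enumerated exhaustively when the number of
#' distinct assignments is at most `exact_cap`, otherwise by `m` random
#' permutations with \eqn{p = (\#\{F^* \ge F\} + 1)/(m + 1)}.
#'
#' Two-way designs use the Freedman–Lane scheme per term: residuals of
#' the reduced model excluding the tested term (main effects are reduced
#' against the other main effect; the interaction against both main
#' effects) are permuted, added back to the reduced fit, and the term's
#' sequential F recomputed from the full model.
#'
#' @inheritParams anova_f
#' @param m_permutations number of random permutations (>= 99).
#' @param seed RNG seed; results are reproducible for a fixed
#'   (data, seed, m) triple.
#' @param exact_cap exhaustive-enumeration threshold for one-way designs.
#' @return data.frame with one row per term: `term`, `df`, `F`,
#'   `p_perm`, `m` (permutations actually used), `method`, `seed`.
#' @export
permutation_anova <- function(response, a, b = NULL,
                              model = c("one_way", "two_way_interaction"),
                              m_permutations = 4999, seed = 1L,
                              exact_cap = 20000) {
  model <- match.arg(model)
  if (m_permutations < 99) stop_invalid("m_permutations must be >= 99")
  dsn <- prepare_design(response, a, b, model)
  eng <- anova_engine(dsn$X, dsn$assign)
  f_obs <- engine_f(eng, response)
  labels <- attr(stats::terms(model_formula(model)), "term.labels")

  if (model == "one_way") {
    sizes <- as.integer(table(dsn$data$a))
    if (n_distinct_assignments(sizes) <= exact_cap) {
      # enumerate distinct group assignments of the observed responses
      ord <- order(dsn$data$a)
      perms <- enumerate_assignments(sizes)
      count <- 0L
      for (pm in perms) {
        y_star <- response
        y_star[ord] <- response[pm]
        if (engine_f(eng, y_star)[1L] >= f_obs[1L] - 1e-12) count <- count + 1L
      }
      p <- count / length(perms)
      m_used <- length(perms) - 1L
      method <- "exact"
    } else {
      count <- 0L
      with_seed(seed, {
        for (i in seq_len(m_permutations)) {
          y_star <- response[sample.int(length(response))]
          if (engine_f(eng, y_star)[1L] >= f_obs[1L] - 1e-12) count <- count + 1L
        }
      })
      p <- (count + 1) / (m_permutations + 1)
      m_used <- m_permutations
      method <- "monte_carlo"
    }
    return(data.frame(term = "a", label = labels[1L], df = eng$df_terms[1L],
                      F = f_obs[1L], p_perm = p, m = m_used,
                      method = method, seed = seed, stringsAsFactors = FALSE))
  }

  # two-way with interaction, Freedman-Lane per term
  reduced <- list(a = ~b, b = ~a, `a:b` = ~ a + b)
  term_names <- c("a", "b", "a:b")
  p_vals <- numeric(3)
  with_seed(seed, {
    perm_idx <- replicate(m_permutations, sample.int(length(response)),
                          simplify = FALSE)
  })
  for (k in 1:3) {
    Xr <- stats::model.matrix(reduced[[term_names[k]]], dsn$data)
    fit_r <- stats::lm.fit(Xr, response)
    fitted_r <- response - fit_r$residuals
    resid_r <- fit_r$residuals
    count <- 0L
    for (pm in perm_idx) {
      y_star <- fitted_r + resid_r[pm]
      if (engine_f(eng, y_star)[k] >= f_obs[k] - 1e-12) count <- count + 1L
    }
    p_vals[k] <- (count + 1) / (m_permutations + 1)
  }
  data.frame(term = term_names, label = labels, df = eng$df_terms,
             F = f_obs, p_perm = p_vals, m = m_permutations,
             method = "freedman_lane", seed = seed, stringsAsFactors = FALSE)
}

#' Permutation tests for every variable within every speed
#'
#' The study design tests each shoal at several non-independent,
#' unequally replicated speeds, so stage and temperature effects are
#' tested within each speed.  No multiple-testing correction is applied
#' to the significance flags; a Benjamini–Hochberg column is emitted
#' alongside for transparency.
#'
#' @param tbl tidy per-shoal table with columns `speed_bl_s`, `stage`,
#'   `temperature_c` and the response variables.
#' @param variables character vector of response column names.
#' @param model passed to [permutation_anova()].
#' @param m_permutations,seed passed to [permutation_anova()].
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with one row per (variable, speed, term):
#'   `variable`, `speed_bl_s`, `term`, `df`, `F`, `p_perm`, `p_bh`, `m`,
#'   `seed`, `significant`.  Speeds at which a tested factor has a single
#'   level are skipped with a message.
#' @export
within_speed_sweep <- function(tbl, variables,
                               model = "two_way_interaction",
                               m_permutations = 4999, seed = 1L,
                               alpha = 0.05) {
  rows <- list()
  speeds <- sort(unique(tbl$speed_bl_s))
  for (v in variables) {
    for (sp in speeds) {
      d <- tbl[tbl$speed_bl_s == sp & !is.na(tbl[[v]]), ]
      if (length(unique(d$stage)) < 2L) {
        message(sprintf("skipping %s at %g BL/s: single stage present", v, sp))
        next
      }
      if (model == "two_way_interaction" && length(unique(d$temperature_c)) < 2L) {
        message(sprintf("skipping %s at %g BL/s: single temperature present",
                        v, sp))
        next
      }
      cell_n <- if (model == "two_way_interaction") {
        table(d$stage, d$temperature_c)
      } else table(d$stage)
      if (any(cell_n < 2L)) {
        message(sprintf("skipping %s at %g BL/s: a tested cell has < 2 shoals",
                        v, sp))
        next
      }
      res <- permutation_anova(d[[v]], a = d$stage, b = d$temperature_c,
                               model = model, m_permutations = m_permutations,
                               seed = derive_seed(seed, round(100 * sp)))
      res$variable <- v
      res$speed_bl_s <- sp
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) {
    return(data.frame(variable = character(), speed_bl_s = numeric(),
                      term = character(), label = character(),
                      df = integer(), F = numeric(), p_perm = numeric(),
                      p_bh = numeric(), m = integer(), method = character(),
                      seed = integer(), significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_perm, method = "BH")
  out$significant <- out$p_perm <= alpha
  out[, c("variable", "speed_bl_s", "term", "label", "df", "F",
          "p_perm", "p_bh", "m", "method", "seed", "significant")]
}
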