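# Session-level aggregation and the within-subject comparison workflow:
# training criteria, PRE/POST grouping around the learning criterion, the
# dPBS/iPBS merge gate, and the condition contrasts (repeated-measures
# ANOVA for scalar metrics, Watson-Williams/Kuiper for pooled angles).

#' Summarize a session's trial metrics
#'
#' @param session a `vr_session`, or a `trial_metrics` data.frame from
#'   [session_metrics()] (then `metrics` is ignored).
#' @param config the matching `arena_config`.
#' @param metrics optional precomputed [session_metrics()] table.
#' @return object of class `session_summary`: a list with visit
#'   percentages (both the all-trial and completed-trial denominators),
#'   mean speed, crossing counts, DD/PCD mean vectors and mean deviations,
#'   mean excess distance and the session duration (trial time plus reward
#'   and inter-trial intervals).
#' @export
summarize_session <- function(session, config, metrics = NULL) {
  if (inherits(session, "vr_session")) {
    m <- metrics %||% session_metrics(session, config)
    subject_id <- session$subject_id; condition <- session$condition
    day <- session$day
  } else {
    m <- session
    subject_id <- m$subject_id[1]; condition <- m$condition[1]
    day <- NA_integer_
  }
  if (!nrow(m)) stop("empty session")
  n <- nrow(m)
  n_completed <- sum(m$outcome != "timeout")
  n_high <- sum(m$outcome == "high")
  dd <- m$departing_direction[!is.na(m$departing_direction)]
  pcd <- m$perimeter_crossing_direction[!is.na(m$perimeter_crossing_direction)]
  completed <- m$outcome != "timeout"
  duration <- sum(m$latency) +
    config$reward_duration * n_completed + config$iti_still_duration * n
  structure(list(
    subject_id = subject_id, condition = condition, day = day,
    n_trials = n, n_completed = n_completed,
    high_visit_pct = 100 * n_high / n,
    low_visit_pct = 100 * sum(m$outcome == "low") / n,
    timeout_pct = 100 * sum(m$outcome == "timeout") / n,
    high_visit_pct_completed = if (n_completed > 0) 100 * n_high / n_completed else NA_real_,
    mean_speed = mean(m$mean_speed, na.rm = TRUE),
    mean_crossings = mean(m$n_perimeter_crossings),
    dd_mean_vector = if (length(dd)) mean_vector(dd) else NULL,
    pcd_mean_vector = if (length(pcd)) mean_vector(pcd) else NULL,
    mean_dd_deviation = mean(m$dd_deviation, na.rm = TRUE),
    mean_pcd_deviation = mean(m$pcd_deviation, na.rm = TRUE),
    mean_excess = mean(m$excess_travel_distance[completed]),
    mean_travel = mean(m$travel_distance),
    mean_latency = mean(m$latency[completed]),
    session_duration = duration
  ), class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary %s %s day %s: %d trials, %.1f%% high visits, %.2f crossings/trial>\n",
              x$subject_id, x$condition, x$day, x$n_trials,
              x$high_visit_pct, x$mean_crossings))
  invisible(x)
}

#' Flatten session summaries into a table of scalar metrics
#'
#' @param summaries list of `session_summary` objects.
#' @return data.frame, one row per session, with mean-vector lengths and
#'   directions expanded into scalar columns.
#' @export
summary_table <- function(summaries) {
  if (inherits(summaries, "session_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(subject_id = s$subject_id, condition = s$condition,
               day = s$day, n_trials = s$n_trials,
               high_visit_pct = s$high_visit_pct,
               high_visit_pct_completed = s$high_visit_pct_completed,
               mean_speed = s$mean_speed,
               mean_crossings = s$mean_crossings,
               dd_mean_length = if (!is.null(s$dd_mean_vector)) s$dd_mean_vector$length else NA_real_,
               dd_mean_direction = if (!is.null(s$dd_mean_vector)) s$dd_mean_vector$direction else NA_real_,
               pcd_mean_length = if (!is.null(s$pcd_mean_vector)) s$pcd_mean_vector$length else NA_real_,
               pcd_mean_direction = if (!is.null(s$pcd_mean_vector)) s$pcd_mean_vector$direction else NA_real_,
               mean_dd_deviation = s$mean_dd_deviation,
               mean_pcd_deviation = s$mean_pcd_deviation,
               mean_excess = s$mean_excess,
               mean_latency = s$mean_latency,
               session_duration = s$session_duration,
               stringsAsFactors = FALSE)
  }))
}

#' Evaluate phase-specific training criteria
#'
#' Thresholds: shaping, more than 60 completed trials; pre-training, 60
#' trials within 40 min, more than 75% high-value visits (completed-trial
#' denominator) and mean excess travel distance below 0.6 m;
#' post-training, 40 trials, the same visit criterion, mean excess below
#' 1 m; probe, 40 trials with mean excess below 0.1 m (strict
#' inequalities throughout).
#'
#' @param summary a `session_summary`.
#' @param phase `"shaping"`, `"pre_training"`, `"post_training"` or
#'   `"probe"`.
#' @return list with `phase`, `passed` and `reasons` (character vector of
#'   failed checks, empty when passed).
#' @export
evaluate_criteria <- function(summary,
                              phase = c("pre_training", "post_training",
                                        "shaping", "probe")) {
  phase <- match.arg(phase)
  reasons <- character(0)
  s <- summary
  add <- function(cond, why) if (!cond) reasons <<- c(reasons, why)
  if (phase == "shaping") {
    add(s$n_trials > 60, "trial count (need > 60 trials)")
  } else if (phase == "pre_training") {
    add(s$n_trials >= 60, "trial count (need 60 trials)")
    add(s$session_duration <= 40 * 60, "session duration (need 60 trials in 40 min)")
    add(s$high_visit_pct_completed > 75, "visit percentage (need > 75% high-value visits)")
    add(is.finite(s$mean_excess) && s$mean_excess < 0.6,
        "excess travel distance (need < 0.6 m)")
  } else if (phase == "post_training") {
    add(s$n_trials >= 40, "trial count (need 40 trials)")
    add(s$high_visit_pct_completed > 75, "visit percentage (need > 75% high-value visits)")
    add(is.finite(s$mean_excess) && s$mean_excess < 1, "excess travel distance (need < 1 m)")
  } else {
    add(s$n_trials >= 40, "trial count (need 40 trials)")
    add(is.finite(s$mean_excess) && s$mean_excess < 0.1,
        "excess travel distance (need < 0.1 m)")
  }
  list(phase = phase, passed = length(reasons) == 0, reasons = reasons)
}

#' Find the PRE/POST learning windows in a day series
#'
#' POST is the first pair of consecutive criterion-passing days; PRE is
#' the two days immediately preceding it. Errors if no qualifying pair
#' exists or if the first passing pair starts before day 3 (no PRE window
#' available).
#'
#' @param summaries chronologically ordered list of `session_summary`
#'   objects (daily sessions of one subject), or a logical vector of
#'   pass flags.
#' @param phase criterion phase passed to [evaluate_criteria()].
#' @return list with integer day indices `pre` and `post` (length 2 each).
#' @export
find_pre_post <- function(summaries, phase = "pre_training") {
  passed <- if (is.logical(summaries)) summaries
  else vapply(summaries, function(s) evaluate_criteria(s, phase)$passed,
              logical(1))
  n <- length(passed)
  if (n < 2) stop("need at least two daily sessions")
  i <- which(passed[-n] & passed[-1])[1]
  if (is.na(i)) stop("no pair of consecutive criterion-passing days found")
  if (i < 3) stop("criterion reached before day 3: no PRE window available")
  list(pre = c(i - 2L, i - 1L), post = c(i, i + 1L))
}

#' Merge dPBS and iPBS control sessions after a difference gate
#'
#' For each metric, the paired dPBS and iPBS values are first compared
#' with a Wilcoxon signed-rank test; if no significant difference is found
#' (p >= alpha, or a degenerate all-ties comparison) the per-subject
#' average is emitted as the merged PBS value. Metrics that do differ
#' significantly are left unmerged and flagged.
#'
#' @param dpbs,ipbs data.frames with a `subject_id` column and one column
#'   per metric, paired by subject.
#' @param metrics character vector of metric column names to gate and
#'   merge (default: all shared numeric columns).
#' @param alpha significance level of the gate (default 0.05).
#' @return list with `merged` (data.frame of merged metrics, `NA` where
#'   the merge was refused), `gate` (per-metric p-values and decisions)
#'   and `alpha`.
#' @export
merge_pbs <- function(dpbs, ipbs, metrics = NULL, alpha = 0.05) {
  if (!all(dpbs$subject_id == ipbs$subject_id)) {
    dpbs <- dpbs[order(dpbs$subject_id), , drop = FALSE]
    ipbs <- ipbs[order(ipbs$subject_id), , drop = FALSE]
    if (!identical(as.character(dpbs$subject_id), as.character(ipbs$subject_id)))
      stop("dPBS and iPBS sessions must be paired by subject")
  }
  if (is.null(metrics)) {
    shared <- intersect(names(dpbs), names(ipbs))
    metrics <- shared[vapply(shared, function(nm) is.numeric(dpbs[[nm]]),
                             logical(1))]
    metrics <- setdiff(metrics, c("day", "n_trials"))
  }
  merged <- data.frame(subject_id = dpbs$subject_id, condition = "PBS",
                       stringsAsFactors = FALSE)
  gate <- do.call(rbind, lapply(metrics, function(nm) {
    w <- wilcoxon_signed_rank(dpbs[[nm]], ipbs[[nm]])
    ok <- w$degenerate || w$p_value >= alpha
    merged[[nm]] <<- if (ok) (dpbs[[nm]] + ipbs[[nm]]) / 2 else NA_real_
    data.frame(metric = nm,
               p_value = if (w$degenerate) NA_real_ else w$p_value,
               degenerate = w$degenerate, merged = ok,
               stringsAsFactors = FALSE)
  }))
  list(merged = merged, gate = gate, alpha = alpha)
}

#' Compare behavioural conditions
#'
#' Scalar metrics (one value per subject and condition) are tested with a
#' one-way repeated-measures ANOVA (Greenhouse-Geisser correction
#' reported alongside) followed by Bonferroni-corrected pairwise paired
#' t-tests. Angular measures (trial-pooled DD or PCD samples per
#' condition) are tested with the Watson-Williams test across all
#' conditions, pairwise Watson-Williams contrasts under the 0.45
#' applicability gate, and pairwise Kuiper permutation tests.
#'
#' @param summaries data.frame from [summary_table()] with columns
#'   `subject_id`, `condition` and the scalar metrics; every subject must
#'   appear in every condition.
#' @param scalar_metrics character vector of metric columns to test.
#' @param angles optional named list of angular measures, each a named
#'   list mapping condition to a vector of pooled angles (degrees), e.g.
#'   `list(dd = list(PBS = ..., dMUS = ..., iMUS = ...))`.
#' @param n_perm,seed Kuiper permutation settings.
#' @param alpha significance level recorded in the report.
#' @return list with `scalar` (per-metric [rm_anova()] results plus a tidy
#'   `table` and `posthoc`), and `angular` (per-measure omnibus and
#'   pairwise results plus a tidy `table`).
#' @export
compare_conditions <- function(summaries, scalar_metrics = c(
                                 "high_visit_pct", "mean_speed",
                                 "mean_crossings", "dd_mean_length",
                                 "mean_dd_deviation"),
                               angles = NULL, n_perm = 2000, seed = 1,
                               alpha = 0.05) {
  conds <- unique(summaries$condition)
  if (length(conds) < 2) stop("need >= 2 conditions")
  subjects <- sort(unique(summaries$subject_id))
  scalar_metrics <- intersect(scalar_metrics, names(summaries))

  scalar <- list(); scalar_rows <- list(); posthoc_rows <- list()
  for (nm in scalar_metrics) {
    mat <- matrix(NA_real_, length(subjects), length(conds),
                  dimnames = list(subjects, conds))
    for (r in seq_len(nrow(summaries)))
      mat[as.character(summaries$subject_id[r]),
          as.character(summaries$condition[r])] <- summaries[[nm]][r]
    if (anyNA(mat)) stop("mismatched subjects: every subject needs a value in every condition (metric ", nm, ")")
    res <- rm_anova(mat)
    scalar[[nm]] <- res
    scalar_rows[[nm]] <- data.frame(metric = nm, F = res$F,
                                    df1 = res$df[1], df2 = res$df[2],
                                    p_value = res$p_value,
                                    gg_epsilon = res$gg_epsilon,
                                    p_value_gg = res$p_value_gg,
                                    stringsAsFactors = FALSE)
    ph <- res$posthoc; ph$metric <- nm
    posthoc_rows[[nm]] <- ph
  }

  angular <- list(); angular_rows <- list()
  for (nm in names(angles %||% list())) {
    groups <- angles[[nm]]
    omni <- watson_williams_quiet(groups)
    rows <- data.frame(measure = nm, test = "watson_williams",
                       contrast = "omnibus", statistic = omni$statistic,
                       p_value = omni$p_value, applicable = omni$applicable,
                       stringsAsFactors = FALSE)
    prs <- utils::combn(names(groups), 2)
    pair_res <- list()
    for (j in seq_len(ncol(prs))) {
      g1 <- prs[1, j]; g2 <- prs[2, j]
      lbl <- paste(g1, g2, sep = " vs ")
      ww <- watson_williams_quiet(groups[c(g1, g2)])
      ku <- kuiper_two_sample(groups[[g1]], groups[[g2]], n_perm = n_perm,
                              seed = seed + j)
      pair_res[[lbl]] <- list(watson_williams = ww, kuiper = ku)
      rows <- rbind(rows,
                    data.frame(measure = nm, test = "watson_williams",
                               contrast = lbl, statistic = ww$statistic,
                               p_value = ww$p_value,
                               applicable = ww$applicable,
                               stringsAsFactors = FALSE),
                    data.frame(measure = nm, test = "kuiper",
                               contrast = lbl, statistic = ku$statistic,
                               p_value = ku$p_value, applicable = TRUE,
                               stringsAsFactors = FALSE))
    }
    angular[[nm]] <- list(omnibus = omni, pairwise = pair_res)
    angular_rows[[nm]] <- rows
  }

  list(scalar = scalar,
       scalar_table = if (length(scalar_rows)) do.call(rbind, scalar_rows) else NULL,
       posthoc_table = if (length(posthoc_rows)) do.call(rbind, posthoc_rows) else NULL,
       angular = angular,
       angular_table = if (length(angular_rows)) do.call(rbind, angular_rows) else NULL,
       alpha = alpha)
}

watson_williams_quiet <- function(groups)
  suppressWarnings(watson_williams(groups))
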