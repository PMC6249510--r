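#' Intersect two hit sets
#'
#' Deterministic sorted intersection of the exercise-associated and
#' drinking-associated probe sets; a disjoint pair warns.
#'
#' @param exercise_hits,drinking_hits character vectors of probe ids.
#' @return sorted character vector.
#' @export
intersect_hits <- function(exercise_hits, drinking_hits) {
  out <- sort(intersect(exercise_hits, drinking_hits))
  if (length(out) == 0) warning("hit sets are disjoint; no overlapping markers")
  out
}

#' Classify the direction of a methylation difference
#'
#' Sign of `mean_b - mean_a`: `"hyper"` when the second mean is larger,
#' `"hypo"` when smaller, `"none"` on an exact tie (a tie can never be
#' opposite to anything — the conservative choice).  Vectorized.
#'
#' @param mean_a reference mean (control, or baseline).
#' @param mean_b comparison mean (drinker, or follow-up).
#' @return character vector in `{"hyper", "hypo", "none"}`.
#' @export
classify_direction <- function(mean_a, mean_b) {
  if (anyNA(mean_a) || anyNA(mean_b)) stop("means must be non-missing")
  if (any(c(mean_a, mean_b) < 0 | c(mean_a, mean_b) > 1))
    stop("means must lie in [0, 1]")
  d <- sign(mean_b - mean_a)
  c("hypo", "none", "hyper")[d + 2]
}

#' Join exercise and drinking results into per-probe marker calls
#'
#' For every probe in the intersection of the two hit sets, records both
#' effect directions (from group/timepoint means), the four means, both
#' p-values, and whether the directions are opposite.  The regression
#' coefficient sign is cross-checked against the mean-difference sign;
#' on disagreement (possible under covariate adjustment) the probe is
#' flagged and the coefficient sign is used.
#'
#' @param exercise_tab `assoc_table` from [paired_ttest()].
#' @param drinking_tab `assoc_table` from [group_diff_regression()].
#' @param exercise_hits,drinking_hits probe id vectors (defaults: the
#'   tables' Bonferroni flags).
#' @return data.frame of class `marker_calls`: one row per overlapping
#'   probe with directions, means, p-values, `opposite`, `sign_flagged`.
#' @export
marker_calls <- function(exercise_tab, drinking_tab,
                         exercise_hits = exercise_tab$probe_id[exercise_tab$significant],
                         drinking_hits = drinking_tab$probe_id[drinking_tab$significant]) {
  overlap <- intersect_hits(exercise_hits, drinking_hits)
  ei <- match(overlap, exercise_tab$probe_id)
  di <- match(overlap, drinking_tab$probe_id)
  if (anyNA(ei) || anyNA(di))
    stop("hit probes missing from the association tables")
  ex_mean_dir <- classify_direction(exercise_tab$mean_baseline[ei],
                                    exercise_tab$mean_followup[ei])
  dr_mean_dir <- classify_direction(drinking_tab$mean_control[di],
                                    drinking_tab$mean_drinker[di])
  ex_coef_dir <- c("hypo", "none", "hyper")[sign(exercise_tab$estimate[ei]) + 2]
  dr_coef_dir <- c("hypo", "none", "hyper")[sign(drinking_tab$estimate[di]) + 2]
  flagged <- (ex_mean_dir != ex_coef_dir) | (dr_mean_dir != dr_coef_dir)
  ex_dir <- ifelse(flagged, ex_coef_dir, ex_mean_dir)
  dr_dir <- ifelse(flagged, dr_coef_dir, dr_mean_dir)
  opposite <- (dr_dir == "hypo" & ex_dir == "hyper") |
    (dr_dir == "hyper" & ex_dir == "hypo")
  out <- data.frame(
    probe_id = overlap,
    drinking_direction = ifelse(dr_dir == "none", "none",
                                paste0(dr_dir, "_in_drinkers")),
    exercise_direction = ifelse(ex_dir == "none", "none",
                                paste0(ex_dir, "_after_exercise")),
    opposite = opposite,
    mean_control = drinking_tab$mean_control[di],
    mean_drinker = drinking_tab$mean_drinker[di],
    p_drinking = drinking_tab$p[di],
    mean_baseline = exercise_tab$mean_baseline[ei],
    mean_followup = exercise_tab$mean_followup[ei],
    p_exercise = exercise_tab$p[ei],
    sign_flagged = flagged,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("marker_calls", "data.frame")
  out
}

#' Extract opposite-direction markers
#'
#' Subset of marker calls whose exercise and drinking directions oppose,
#' sorted by drinking p-value.  Idempotent on its own output.
#'
#' @param markers a `marker_calls` data.frame.
#' @return the opposite-direction subset, same class.
#' @export
find_opposite <- function(markers) {
  out <- markers[markers$opposite, , drop = FALSE]
  out <- out[order(out$p_drinking), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_calls", "data.frame")
  out
}

#' Post-hoc cell-proportion-adjusted re-test of markers
#'
#' Re-tests each marker with estimated cell-type proportions as
#' covariates: in the exercise cohort a regression of methylation on the
#' timepoint factor replaces the paired test; in the drinking cohort the
#' group model gains the proportion covariates.  The last cell-type
#' column is dropped to avoid the simplex collinearity (proportions sum
#' to one).  Bonferroni control is over the marker set.
#'
#' @param beta a [beta_matrix].
#' @param sheet aligned sheet.
#' @param props `cell_proportions` (samples x types), aligned.
#' @param analysis `"exercise"` or `"drinking"`.
#' @param markers probe ids to test.
#' @param family_alpha family-wise alpha.
#' @return `assoc_table` on the markers.
#' @export
posthoc_cellprops <- function(beta, sheet, props,
                              analysis = c("exercise", "drinking"),
                              markers, family_alpha = 0.05) {
  analysis <- match.arg(analysis)
  stopifnot(nrow(props) == n_samples(beta))
  markers <- intersect(markers, probe_ids(beta))
  sub <- beta_matrix(beta$values[, markers, drop = FALSE])
  Wc <- props[, -ncol(props), drop = FALSE]  # drop last type: simplex
  ## constant proportion columns carry no information; drop to keep full rank
  keep <- apply(Wc, 2, function(x) stats::sd(x) > 0)
  Wc <- Wc[, keep, drop = FALSE]
  if (analysis == "exercise") {
    X <- cbind(`(Intercept)` = 1,
               group = as.numeric(sheet$timepoint == "followup"))
    if (ncol(Wc) > 0) X <- cbind(X, Wc)
    fit <- ols_by_column(sub$values, X, coef = "group")
    m0 <- colMeans(sub$values[sheet$timepoint == "baseline", , drop = FALSE], na.rm = TRUE)
    m1 <- colMeans(sub$values[sheet$timepoint == "followup", , drop = FALSE], na.rm = TRUE)
    mean_names <- c("mean_baseline", "mean_followup")
  } else {
    X <- cbind(`(Intercept)` = 1,
               group = as.numeric(sheet$group == "drinker"),
               dummy_code(sheet$race))
    if (ncol(Wc) > 0) X <- cbind(X, Wc)
    fit <- ols_by_column(sub$values, X, coef = "group")
    m0 <- colMeans(sub$values[sheet$group == "control", , drop = FALSE], na.rm = TRUE)
    m1 <- colMeans(sub$values[sheet$group == "drinker", , drop = FALSE], na.rm = TRUE)
    mean_names <- c("mean_control", "mean_drinker")
  }
  n_tests <- sum(!is.na(fit$p))
  out <- data.frame(probe_id = rownames(fit), estimate = fit$estimate,
                    statistic = fit$statistic, p = fit$p,
                    significant = !is.na(fit$p) & fit$p < family_alpha / n_tests,
                    m0, m1, n = fit$n, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[6:7] <- mean_names
  attr(out, "n_tests") <- n_tests
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Greedy race-then-age matching of drinkers and controls
#'
#' Within each race level, pairs every drinker with the age-nearest
#' unused control (exact race match first, then nearest-neighbor age),
#' until one group is exhausted.
#'
#' @param sheet case-control sample sheet.
#' @return character vector of matched sample ids (both groups).
#' @export
race_match <- function(sheet) {
  ids <- character(0)
  for (r in unique(sheet$race)) {
    d <- sheet[sheet$race == r & sheet$group == "drinker", ]
    c_ <- sheet[sheet$race == r & sheet$group == "control", ]
    if (nrow(d) == 0 || nrow(c_) == 0) next
    d <- d[order(d$age), ]
    used <- rep(FALSE, nrow(c_))
    for (i in seq_len(min(nrow(d), nrow(c_)))) {
      j <- which.min(ifelse(used, Inf, abs(c_$age - d$age[i])))
      used[j] <- TRUE
      ids <- c(ids, d$sample_id[i], c_$sample_id[j])
    }
  }
  ids
}

#' Subgroup confirmation of markers
#'
#' Re-runs the primary analysis on a restricted subsample: the exercise
#' subjects who objectively increased their VO2 max (paired test), or a
#' race-matched drinker/control subset (group regression).  Reports a
#' per-marker direction-consistency flag against a primary table when
#' one is supplied.
#'
#' @param beta a [beta_matrix].
#' @param sheet aligned sheet.
#' @param markers probe ids to test.
#' @param subset `"vo2_increased"` or `"race_matched"`.
#' @param primary optional primary `assoc_table` for consistency
#'   checking.
#' @param family_alpha family-wise alpha over the marker set.
#' @return `assoc_table` on the markers with a `direction_consistent`
#'   column when `primary` is given.
#' @export
subgroup_confirm <- function(beta, sheet, markers,
                             subset = c("vo2_increased", "race_matched"),
                             primary = NULL, family_alpha = 0.05) {
  subset <- match.arg(subset)
  markers <- intersect(markers, probe_ids(beta))
  if (subset == "vo2_increased") {
    keep <- which(sheet$vo2_increased %in% TRUE)
    if (length(unique(sheet$subject_id[keep])) < 10)
      stop("fewer than 10 pairs in the VO2-increased subset")
    sub <- beta_matrix(beta$values[keep, markers, drop = FALSE])
    out <- paired_ttest(sub, sheet[keep, , drop = FALSE],
                        family_alpha = family_alpha)
  } else {
    ids <- race_match(sheet)
    keep <- match(ids, sheet$sample_id)
    if (length(keep) < 10) stop("fewer than 10 samples after race matching")
    op_log("markers", sprintf("race matching kept %d + %d samples",
                              sum(sheet$group[keep] == "drinker"),
                              sum(sheet$group[keep] == "control")))
    sub <- beta_matrix(beta$values[keep, markers, drop = FALSE])
    out <- group_diff_regression(sub, sheet[keep, , drop = FALSE],
                                 family_alpha = family_alpha)
  }
  if (!is.null(primary)) {
    pi <- match(out$probe_id, primary$probe_id)
    out$direction_consistent <- sign(out$estimate) == sign(primary$estimate[pi])
  }
  out
}
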