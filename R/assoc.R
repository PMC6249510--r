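#' Paired longitudinal test per probe
#'
#' Per probe, follow-up minus baseline differences over complete pairs:
#' t = mean(d) / (sd(d)/sqrt(n)), two-sided p on n - 1 degrees of
#' freedom.  The Bonferroni flag uses the number of probes actually
#' tested.  Probes with fewer than 3 complete pairs are skipped and
#' logged.  Zero-variance differences are degenerate: p is set to 0 when
#' the mean difference is non-zero (a perfectly reproducible shift) and
#' to 1 when it is zero.
#'
#' @param beta a [beta_matrix] covering both timepoints.
#' @param sheet aligned sample sheet with `subject_id` and `timepoint`
#'   (`baseline` / `followup`).
#' @param family_alpha family-wise alpha for the Bonferroni flag.
#' @return data.frame of class `assoc_table`: one row per tested probe
#'   with `estimate` (mean paired difference), `statistic`, `p`,
#'   `significant`, `mean_baseline`, `mean_followup`, `n`; attribute
#'   `n_tests` carries the Bonferroni denominator.
#' @export
paired_ttest <- function(beta, sheet, family_alpha = 0.05) {
  stopifnot(nrow(sheet) == n_samples(beta))
  subj <- unique(sheet$subject_id)
  i0 <- match(paste0(subj, ".baseline"),
              paste0(sheet$subject_id, ".", sheet$timepoint))
  i1 <- match(paste0(subj, ".followup"),
              paste0(sheet$subject_id, ".", sheet$timepoint))
  if (anyNA(i0) || anyNA(i1))
    stop("every subject must appear at both timepoints")
  B0 <- beta$values[i0, , drop = FALSE]
  B1 <- beta$values[i1, , drop = FALSE]
  D <- B1 - B0
  n <- colSums(!is.na(D))
  tested <- n >= 3L
  if (any(!tested))
    op_log("assoc", sprintf("paired test: skipped %d probe(s) with < 3 complete pairs",
                            sum(!tested)))
  D <- D[, tested, drop = FALSE]
  n <- n[tested]
  m <- colMeans(D, na.rm = TRUE)
  s <- col_sds(D)
  tt <- m / (s / sqrt(n))
  p <- 2 * stats::pt(abs(tt), n - 1, lower.tail = FALSE)
  degen <- !is.na(s) & s == 0
  p[degen] <- ifelse(m[degen] != 0, 0, 1)
  tt[degen] <- ifelse(m[degen] != 0, Inf * sign(m[degen]), 0)
  if (any(degen)) op_log("assoc", sprintf("%d zero-variance probe(s) handled as degenerate",
                                          sum(degen)))
  n_tests <- sum(tested)
  out <- data.frame(
    probe_id = colnames(D),
    estimate = m, statistic = tt, p = p,
    significant = p < family_alpha / n_tests,
    mean_baseline = colMeans(B0[, tested, drop = FALSE], na.rm = TRUE),
    mean_followup = colMeans(B1[, tested, drop = FALSE], na.rm = TRUE),
    n = n, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_tests") <- n_tests
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Group-difference regression per probe
#'
#' Ordinary least squares of methylation on the group indicator adjusted
#' for dummy-coded race (reference: most frequent level), two-sided t
#' test of the group coefficient, Bonferroni flag over the probes tested.
#' Group means are reported unadjusted.
#'
#' @param beta a [beta_matrix].
#' @param sheet aligned sheet with `group` (`drinker` / `control`) and
#'   `race`.
#' @param family_alpha family-wise alpha.
#' @param adjust_race include race dummies (default TRUE).
#' @param extra_covariates optional numeric matrix of additional
#'   covariates (e.g. cell-type proportions), aligned with samples.
#' @return `assoc_table` with `estimate` (drinker-minus-control
#'   coefficient), `statistic`, `p`, `significant`, `mean_control`,
#'   `mean_drinker`, `n`; attribute `n_tests`.
#' @export
group_diff_regression <- function(beta, sheet, family_alpha = 0.05,
                                  adjust_race = TRUE,
                                  extra_covariates = NULL) {
  stopifnot(nrow(sheet) == n_samples(beta))
  g <- sheet$group
  if (length(unique(g)) < 2L) stop("group label is constant")
  gnum <- as.numeric(g == "drinker")
  X <- cbind(`(Intercept)` = 1, group = gnum)
  if (adjust_race) X <- cbind(X, dummy_code(sheet$race))
  if (!is.null(extra_covariates)) X <- cbind(X, extra_covariates)
  fit <- ols_by_column(beta$values, X, coef = "group")
  tested <- !is.na(fit$p)
  n_tests <- sum(tested)
  out <- data.frame(
    probe_id = rownames(fit),
    estimate = fit$estimate, statistic = fit$statistic, p = fit$p,
    significant = !is.na(fit$p) & fit$p < family_alpha / n_tests,
    mean_control = colMeans(beta$values[gnum == 0, , drop = FALSE], na.rm = TRUE),
    mean_drinker = colMeans(beta$values[gnum == 1, , drop = FALSE], na.rm = TRUE),
    n = fit$n, row.names = NULL, stringsAsFactors = FALSE)
  out <- out[tested, , drop = FALSE]
  attr(out, "n_tests") <- n_tests
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Principal components of the behavioral battery
#'
#' The 13 measures are standardized to zero mean and unit variance
#' (their ranges are heterogeneous, so the correlation scale prevents
#' any one scale from dominating) and the correlation matrix is
#' eigendecomposed.  k is the smallest number of components whose
#' cumulative variance reaches `variance_target`.
#'
#' @param behavior numeric matrix (samples x 13 measures), no missing
#'   values.
#' @param variance_target cumulative variance to capture (default 0.90).
#' @return list of class `behavior_pcs`: `loadings` (measures x k),
#'   `scores` (samples x k), `variance_fraction` (all components), `k`.
#' @export
behavior_pca <- function(behavior, variance_target = 0.90) {
  if (anyNA(behavior)) stop("behavior matrix must be complete")
  sds <- apply(behavior, 2, stats::sd)
  if (any(sds == 0))
    stop("constant behavioral measure: ",
         paste(colnames(behavior)[sds == 0], collapse = ", "))
  Z <- scale(behavior)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(vf) >= variance_target)[1]
  structure(list(loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 scores = pc$x[, seq_len(k), drop = FALSE],
                 variance_fraction = vf, k = k,
                 variance_target = variance_target),
            class = "behavior_pcs")
}

#' Per-probe association with behavioral principal components
#'
#' For each probe and each PC, methylation is modeled on the PC score
#' adjusted for age, sex and dummy-coded race; a probe passes when
#' (under the default `"any"` rule) its minimum PC p-value is below
#' `step2_alpha`, uncorrected — this verification step deliberately
#' trades false negatives for sensitivity because its inputs are already
#' Bonferroni-controlled.  `"all"` requires every PC to pass; an integer
#' selects one specific PC.
#'
#' @param beta a [beta_matrix] restricted to the step-1 hits.
#' @param pcs a `behavior_pcs` on the same samples.
#' @param sheet aligned sheet with `age`, `sex`, `race`.
#' @param step2_alpha uncorrected alpha (default 0.05).
#' @param rule `"any"`, `"all"`, or a PC index.
#' @return data.frame: `probe_id`, `min_p`, `best_pc`, `pass`, plus one
#'   `p_PCi` column per component.
#' @export
pc_association <- function(beta, pcs, sheet, step2_alpha = 0.05, rule = "any") {
  stopifnot(nrow(sheet) == n_samples(beta))
  S <- pcs$scores
  if (nrow(S) != n_samples(beta)) stop("PC scores and beta matrix disagree on samples")
  if (any(apply(S, 2, stats::sd) == 0)) stop("zero-variance principal component")
  base <- cbind(`(Intercept)` = 1, age = sheet$age,
                sexM = as.numeric(sheet$sex == "M"), dummy_code(sheet$race))
  P <- matrix(NA_real_, n_probes(beta), ncol(S),
              dimnames = list(probe_ids(beta), paste0("p_PC", seq_len(ncol(S)))))
  for (j in seq_len(ncol(S))) {
    X <- cbind(base[, 1, drop = FALSE], pc = S[, j], base[, -1, drop = FALSE])
    P[, j] <- ols_by_column(beta$values, X, coef = "pc")$p
  }
  min_p <- apply(P, 1, function(r)
    if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
  best <- apply(P, 1, function(r)
    if (all(is.na(r))) NA_integer_ else unname(which.min(r)))
  pass <- switch(as.character(rule),
                 any = min_p < step2_alpha,
                 all = apply(P < step2_alpha, 1, all),
                 P[, as.integer(rule)] < step2_alpha)
  pass <- !is.na(pass) & pass
  data.frame(probe_id = rownames(P), min_p = min_p, best_pc = best,
             pass = pass, P, row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-step drinking association
#'
#' Step 1 identifies Bonferroni-significant group-difference probes in
#' the case-control cohort (race-adjusted regression).  Step 2 verifies
#' each of those probes against the behavioral principal components in
#' the all-drinker cohort (uncorrected, per-PC models adjusted for age,
#' sex, race).  A probe is drinking-associated when it passes both
#' steps; its direction is the sign of the group coefficient.
#'
#' @param beta_cc,sheet_cc case-control cohort.
#' @param beta_dr,sheet_dr drinking cohort with the 13 behavior columns.
#' @param config a [run_config].
#' @param rule step-2 pass rule (see [pc_association()]).
#' @return list of class `two_step_result`: `step1` (assoc_table), `pcs`,
#'   `step2` (verdicts), `hits` (drinking-associated probe ids),
#'   `direction` (named +1/-1).
#' @export
two_step_drinking <- function(beta_cc, sheet_cc, beta_dr, sheet_dr,
                              config = run_config(), rule = "any") {
  common <- intersect(probe_ids(beta_cc), probe_ids(beta_dr))
  if (length(common) == 0) stop("cohort probe sets do not intersect")
  cc <- beta_matrix(beta_cc$values[, common, drop = FALSE])
  step1 <- group_diff_regression(cc, sheet_cc, family_alpha = config$family_alpha)
  s1_hits <- step1$probe_id[step1$significant]
  op_log("assoc", sprintf("step 1: %d of %d probes Bonferroni-significant",
                          length(s1_hits), attr(step1, "n_tests")))
  if (length(s1_hits) == 0) {
    warning("no step-1 hits; drinking-associated set is empty")
    return(structure(list(step1 = step1, pcs = NULL, step2 = NULL,
                          hits = character(0), direction = numeric(0)),
                     class = "two_step_result"))
  }
  bm <- as.matrix(sheet_dr[, behavior_measures(), drop = FALSE])
  pcs <- behavior_pca(bm, config$pca_variance_target)
  op_log("assoc", sprintf("behavior PCA: %d components capture %.1f%% variance",
                          pcs$k, 100 * cumsum(pcs$variance_fraction)[pcs$k]))
  sub <- beta_matrix(beta_dr$values[, s1_hits, drop = FALSE])
  step2 <- pc_association(sub, pcs, sheet_dr, config$step2_alpha, rule = rule)
  hits <- step2$probe_id[step2$pass]
  dir <- sign(step1$estimate[match(hits, step1$probe_id)])
  names(dir) <- hits
  op_log("assoc", sprintf("step 2: %d of %d probes verified (%d hypo, %d hyper in drinkers)",
                          length(hits), length(s1_hits), sum(dir < 0), sum(dir > 0)))
  structure(list(step1 = step1, pcs = pcs, step2 = step2,
                 hits = hits, direction = dir),
            class = "two_step_result")
}
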