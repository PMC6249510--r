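#' Run configuration
#'
#' Collects every analysis threshold in one validated object.  Defaults
#' follow the study design the pipeline implements: strict detection-p
#' masking at 0.05, 5% missing-rate filters, a single inter-subject SD
#' retention threshold of 0.06 beta (the larger of the two cohort
#' replicate-error SDs, applied to both studies to standardize filtering),
#' an uncorrected p < 0.01 age screen, family-wise alpha 0.05 with
#' Bonferroni control, an uncorrected 0.05 behavioral verification step,
#' a 90% PCA variance target, and a |z| > 1.5 contributor threshold.
#'
#' @param detect_p_max detection p-value above which a measurement is set
#'   missing.
#' @param max_missing_rate maximum tolerated missing fraction per sample
#'   and per probe.
#' @param sd_threshold inter-subject SD (beta scale) a probe must exceed
#'   to be retained.
#' @param replicate_sd named expectation for the per-cohort replicate
#'   error SDs (informational; the pipeline estimates these from data).
#' @param age_screen_p uncorrected p threshold of the age screen.
#' @param family_alpha family-wise alpha for Bonferroni-corrected tests.
#' @param step2_alpha uncorrected alpha of the behavioral verification
#'   step.
#' @param pca_variance_target cumulative variance the behavioral PCs must
#'   reach.
#' @param z_contrib_threshold |z| cutoff defining top contributors of an
#'   independent component.
#' @param rng_seed root seed; all stage seeds are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(detect_p_max = 0.05,
                       max_missing_rate = 0.05,
                       sd_threshold = 0.06,
                       replicate_sd = c(exercise = 0.045, drinking = 0.06),
                       age_screen_p = 0.01,
                       family_alpha = 0.05,
                       step2_alpha = 0.05,
                       pca_variance_target = 0.90,
                       z_contrib_threshold = 1.5,
                       rng_seed = 1L) {
  probs <- c(detect_p_max = detect_p_max, max_missing_rate = max_missing_rate,
             age_screen_p = age_screen_p, family_alpha = family_alpha,
             step2_alpha = step2_alpha)
  ## family_alpha = 0 is allowed as an explicit "no hits" degenerate run
  if (any(probs < 0 | probs > 1))
    stop("probability thresholds must lie in [0, 1]")
  if (pca_variance_target <= 0 || pca_variance_target > 1)
    stop("pca_variance_target must lie in (0, 1]")
  if (sd_threshold < 0) stop("sd_threshold must be >= 0")
  if (z_contrib_threshold < 0) stop("z_contrib_threshold must be >= 0")
  structure(list(detect_p_max = detect_p_max,
                 max_missing_rate = max_missing_rate,
                 sd_threshold = sd_threshold,
                 replicate_sd = replicate_sd,
                 age_screen_p = age_screen_p,
                 family_alpha = family_alpha,
                 step2_alpha = step2_alpha,
                 pca_variance_target = pca_variance_target,
                 z_contrib_threshold = z_contrib_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys raise an error rather than being silently ignored.
#'
#' @param path YAML file path.
#' @return A [run_config].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(y), known)
  if (length(extra) > 0)
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (!is.null(y$replicate_sd)) y$replicate_sd <- unlist(y$replicate_sd)
  do.call(run_config, y)
}

#' Validate a multi-cohort run
#'
#' Cross-checks sample sheets against beta matrices: per-cohort sample
#' counts, longitudinal pairing completeness in the exercise cohort,
#' covariate completeness, and completeness of the 13 behavioral scores
#' in the drinking cohort.  Violations of pairing are hard errors;
#' incomplete behavior vectors flag samples for exclusion (they are
#' reported, not dropped here).  Validation never mutates its inputs.
#'
#' @param config a [run_config].
#' @param sheets named list of sample sheets (names are cohort labels
#'   `exercise`, `case_control`, `drinking`).
#' @param betas named list of [beta_matrix] objects, same names.
#' @return A list of class `validation_report` with per-cohort counts,
#'   flagged samples, and a `violations` character vector (empty when the
#'   run is fully consistent).
#' @export
validate_run <- function(config, sheets, betas) {
  stopifnot(inherits(config, "run_config"))
  if (!identical(sort(names(sheets)), sort(names(betas))))
    stop("sheets and betas must cover the same cohorts")
  violations <- character(0)
  cohorts <- list()
  for (nm in names(sheets)) {
    sh <- sheets[[nm]]
    bm <- betas[[nm]]
    missing_in_beta <- setdiff(sh$sample_id, sample_ids(bm))
    if (length(missing_in_beta) > 0)
      violations <- c(violations,
                      sprintf("cohort %s: %d sheet sample(s) absent from beta matrix (%s)",
                              nm, length(missing_in_beta),
                              paste(utils::head(missing_in_beta, 3), collapse = ", ")))
    flagged <- character(0)
    if (nm == "exercise") {
      tab <- table(sh$subject_id)
      bad <- names(tab)[tab != 2L]
      bad_tp <- unlist(lapply(split(sh$timepoint, sh$subject_id), function(tp)
        !setequal(tp, c("baseline", "followup"))))
      bad <- union(bad, names(bad_tp)[bad_tp])
      if (length(bad) > 0)
        stop("unpaired exercise subject(s): ", paste(sort(bad), collapse = ", "))
    }
    n_analyzable <- nrow(sh)
    if (nm == "drinking") {
      bm_cols <- intersect(behavior_measures(), names(sh))
      if (length(bm_cols) != 13L)
        stop(sprintf("drinking cohort sheet has %d of the 13 behavioral measures",
                     length(bm_cols)))
      complete <- stats::complete.cases(sh[, bm_cols, drop = FALSE])
      flagged <- sh$sample_id[!complete]
      n_analyzable <- sum(complete)
      op_log("validate", sprintf(
        "drinking cohort: %d of %d samples have complete behavior vectors",
        n_analyzable, nrow(sh)))
    }
    covs <- c("age", "sex", "race")
    inc <- !stats::complete.cases(sh[, covs, drop = FALSE])
    if (any(inc))
      violations <- c(violations,
                      sprintf("cohort %s: %d sample(s) with incomplete demographics",
                              nm, sum(inc)))
    cohorts[[nm]] <- list(n_samples = nrow(sh),
                          n_analyzable = n_analyzable,
                          flagged_samples = flagged,
                          n_probes = n_probes(bm))
  }
  structure(list(cohorts = cohorts, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  for (nm in names(x$cohorts)) {
    co <- x$cohorts[[nm]]
    cat(sprintf("%-12s %4d samples (%d analyzable), %d probes\n",
                nm, co$n_samples, co$n_analyzable, co$n_probes))
  }
  if (length(x$violations) == 0) cat("no violations\n")
  else cat("violations:\n", paste(" -", x$violations, collapse = "\n"), "\n")
  invisible(x)
}
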