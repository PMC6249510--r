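#' Run the full discovery pipeline on a study
#'
#' Executes, in order: per-cohort preprocessing (detection-p mask,
#' missing-rate filters, listed-probe removal, batch adjustment, SD
#' filter, and the age screen in the exercise cohort), the paired
#' exercise test, the two-step drinking association, marker intersection
#' and opposite-direction extraction, optional post-hoc confirmations
#' (cell-proportion-adjusted models, VO2 and race-matched subgroups),
#' and the optional ICA fusion.  Every stage count lands in the run
#' report; a fixed seed and config give a byte-identical report.
#'
#' @param config a [run_config].
#' @param study a study list as from [simulate_study()]; when NULL one is
#'   simulated with `config$rng_seed`.
#' @param exclude_probes externally supplied probe exclusion list (e.g.
#'   cross-hybridizing probes, published age-predictor sites).
#' @param run_posthoc,run_fusion toggle the post-hoc confirmations and
#'   the fusion stage.
#' @param outdir optional directory for stage artifacts (TSV/JSON).
#' @return list of class `run_report` (see fields in the implementation:
#'   counts, hit sets, marker tables, fusion summary, config echo).
#' @export
run_all <- function(config = run_config(), study = NULL,
                    exclude_probes = character(0),
                    run_posthoc = TRUE, run_fusion = TRUE,
                    outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(study)) study <- simulate_study(seed = config$rng_seed)

  pp_ex <- preprocess_cohort(study$exercise$beta, study$exercise$sheet,
                             config, exclude_probes, age_screen = TRUE)
  pp_cc <- preprocess_cohort(study$case_control$beta, study$case_control$sheet,
                             config, exclude_probes)
  pp_dr <- preprocess_cohort(study$drinking$beta, study$drinking$sheet,
                             config, exclude_probes)

  err_sd <- vapply(study$replicates, estimate_error_sd, numeric(1))

  ex_tab <- paired_ttest(pp_ex$beta, pp_ex$sheet, config$family_alpha)
  ex_hits <- ex_tab$probe_id[ex_tab$significant]
  ex_dir <- sign(ex_tab$estimate[match(ex_hits, ex_tab$probe_id)])

  ts <- two_step_drinking(pp_cc$beta, pp_cc$sheet, pp_dr$beta, pp_dr$sheet,
                          config)

  calls <- marker_calls(ex_tab, ts$step1,
                        exercise_hits = ex_hits, drinking_hits = ts$hits)
  opp <- find_opposite(calls)

  posthoc <- NULL
  if (run_posthoc && nrow(opp) > 0) {
    props_ex <- estimate_cell_props(pp_ex$beta, study$panel)
    props_cc <- estimate_cell_props(pp_cc$beta, study$panel)
    posthoc <- list(
      exercise_cellprops = posthoc_cellprops(pp_ex$beta, pp_ex$sheet, props_ex,
                                             "exercise", opp$probe_id,
                                             config$family_alpha),
      drinking_cellprops = posthoc_cellprops(pp_cc$beta, pp_cc$sheet, props_cc,
                                             "drinking", opp$probe_id,
                                             config$family_alpha),
      vo2 = subgroup_confirm(pp_ex$beta, pp_ex$sheet, opp$probe_id,
                             "vo2_increased", primary = ex_tab,
                             family_alpha = config$family_alpha),
      race_matched = subgroup_confirm(pp_cc$beta, pp_cc$sheet, opp$probe_id,
                                      "race_matched", primary = ts$step1,
                                      family_alpha = config$family_alpha))
  }

  fusion <- NULL
  if (run_fusion && nrow(opp) >= 3) {
    mv <- pp_dr$beta$values[, intersect(opp$probe_id, probe_ids(pp_dr$beta)),
                            drop = FALSE]
    if (anyNA(mv)) {
      ## the few detection-masked entries left are mean-imputed per probe
      ## so the decomposition sees a complete matrix
      op_log("fusion", sprintf("mean-imputing %d missing marker value(s)",
                               sum(is.na(mv))))
      for (j in seq_len(ncol(mv)))
        mv[is.na(mv[, j]), j] <- mean(mv[, j], na.rm = TRUE)
    }
    bm <- beta_matrix(mv)
    fusion <- fuse_modalities(bm, pp_dr$sheet, config,
                              seed = fan_seed(config$rng_seed, "fusion"))
  }

  report <- structure(list(
    config = unclass(config),
    error_sd = err_sd,
    preprocess = list(exercise = pp_ex$report, case_control = pp_cc$report,
                      drinking = pp_dr$report),
    counts = list(
      exercise_tested = attr(ex_tab, "n_tests"),
      exercise_hits = length(ex_hits),
      exercise_hyper = sum(ex_dir > 0), exercise_hypo = sum(ex_dir < 0),
      drinking_tested = attr(ts$step1, "n_tests"),
      drinking_step1_hits = sum(ts$step1$significant),
      drinking_hits = length(ts$hits),
      drinking_hyper = sum(ts$direction > 0),
      drinking_hypo = sum(ts$direction < 0),
      behavior_pcs = if (is.null(ts$pcs)) NA_integer_ else ts$pcs$k,
      overlap = nrow(calls),
      opposite = nrow(opp)),
    exercise = ex_tab, drinking = ts,
    markers = calls, opposite = opp,
    posthoc = posthoc, fusion = fusion),
    class = "run_report")
  if (!is.null(outdir)) write_artifacts(report, outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  co <- x$counts
  cat(sprintf("exercise: %d hits / %d tested (%d hyper, %d hypo in follow-up)\n",
              co$exercise_hits, co$exercise_tested, co$exercise_hyper,
              co$exercise_hypo))
  cat(sprintf("drinking: %d hits (%d step-1) / %d tested, %d behavior PCs\n",
              co$drinking_hits, co$drinking_step1_hits, co$drinking_tested,
              co$behavior_pcs))
  cat(sprintf("overlap: %d, opposite-direction: %d\n", co$overlap, co$opposite))
  if (!is.null(x$fusion)) {
    sig <- x$fusion$fusion$pairs
    cat(sprintf("fusion: %d of %d loading pairs Bonferroni-significant\n",
                sum(sig$significant), x$fusion$fusion$n_pairs))
  }
  invisible(x)
}

write_artifacts <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, nm) utils::write.table(
    df, file.path(outdir, nm), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$exercise, "exercise_assoc.tsv")
  wt(report$drinking$step1, "drinking_step1.tsv")
  if (!is.null(report$drinking$step2)) wt(report$drinking$step2, "drinking_step2.tsv")
  wt(report$markers, "marker_calls.tsv")
  render_table3(report$opposite, path = file.path(outdir, "opposite_markers.tsv"))
  jsonlite::write_json(
    list(counts = report$counts, error_sd = as.list(report$error_sd),
         config = report$config),
    file.path(outdir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Render an opposite-marker table in the standard column layout
#'
#' Columns: `CpG_site`, `Gene`, `Mean_control`, `Mean_drinker`,
#' `P-value (drinking)`, `Mean_baseline`, `Mean_followup`,
#' `P-value (exercise)`; means to 4 decimals, p-values in scientific
#' notation.  An empty marker set yields a header-only table.
#'
#' @param markers a `marker_calls` data.frame.
#' @param gene_map optional named character vector probe -> gene.
#' @param path optional output TSV path.
#' @return the rendered data.frame (character columns), invisibly when
#'   `path` is given.
#' @export
render_table3 <- function(markers, gene_map = NULL, path = NULL) {
  fm <- function(x) sprintf("%.4f", x)
  fp <- function(x) toupper(sprintf("%.2e", x))
  out <- data.frame(
    CpG_site = markers$probe_id,
    Gene = if (is.null(gene_map)) rep("", nrow(markers)) else
      unname(gene_map[markers$probe_id]),
    Mean_control = fm(markers$mean_control),
    Mean_drinker = fm(markers$mean_drinker),
    `P-value (drinking)` = fp(markers$p_drinking),
    Mean_baseline = fm(markers$mean_baseline),
    Mean_followup = fm(markers$mean_followup),
    `P-value (exercise)` = fp(markers$p_exercise),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(markers) == 0) out <- out[0, , drop = FALSE]
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Packaged worked-example marker table
#'
#' The published 15-row opposite-direction marker table (four group /
#' timepoint means and two p-values per CpG), shipped as a plain-text
#' fixture for the direction-classification worked example.
#'
#' @return data.frame with 15 rows.
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "opposite_markers_published.tsv",
                      package = "oppomark", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Packaged pathway-enrichment fixture
#'
#' Static canonical-pathway enrichment results for the 15 opposite
#' markers (produced by a proprietary pathway tool; shipped for
#' documentation only, never recomputed).
#'
#' @return data.frame with pathway, molecules and p-value columns.
#' @export
ipa_fixture <- function() {
  path <- system.file("extdata", "pathway_enrichment_static.tsv",
                      package = "oppomark", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
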