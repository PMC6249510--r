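# Shared synthetic fixtures, built once per test run.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# a compact study used by several files (500 probes keeps it quick)
small_manifest <- function(seed = 42) {
  truth_manifest(n_probes = 500,
                 n_exercise_only = 15, n_drinking_only = 15,
                 n_overlap_concordant = 6, n_overlap_opposite = 8,
                 n_opposite_hypo = 5,
                 n_age_driven = 8, n_batch_driven = 8, n_race_driven = 8,
                 seed = seed)
}

null_manifest <- function(seed, n_probes = 1500) {
  truth_manifest(n_probes = n_probes,
                 n_exercise_only = 0, n_drinking_only = 0,
                 n_overlap_concordant = 0, n_overlap_opposite = 0,
                 n_age_driven = 0, n_batch_driven = 0, n_race_driven = 0,
                 seed = seed)
}

.small_study_cache <- new.env(parent = emptyenv())
small_study <- function(seed = 42) {
  key <- as.character(seed)
  if (is.null(.small_study_cache[[key]])) {
    .small_study_cache[[key]] <- quiet(
      simulate_study(seed = seed, manifest = small_manifest(seed)))
  }
  .small_study_cache[[key]]
}

# minimal hand-built beta matrix
tiny_beta <- function(n = 3, p = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("cg%08d", seq_len(p))))
  beta_matrix(m)
}

# a minimal consistent sample-sheet pair for validate_run tests
tiny_sheets <- function() {
  ex <- data.frame(
    sample_id = c("a_T0", "a_T1", "b_T0", "b_T1"),
    subject_id = c("a", "a", "b", "b"),
    cohort = "exercise",
    timepoint = c("baseline", "followup", "baseline", "followup"),
    group = NA_character_, age = c(30, 30, 40, 40),
    sex = c("F", "F", "M", "M"), race = "Caucasian", batch = "B1",
    stringsAsFactors = FALSE)
  ex
}
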