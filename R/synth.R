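#' Ground-truth manifest for synthetic cohorts
#'
#' Assigns every probe to one effect class and records the signed effect
#' sizes the generators plant, so downstream recovery can be scored
#' against known truth.  Classes: `null`, `exercise_only`,
#' `drinking_only`, `overlap_concordant`, `overlap_opposite`,
#' `age_driven`, `batch_driven`, `race_driven`.  Opposite-class probes
#' have sign(exercise delta) = -sign(drinking delta), both non-zero; by
#' default 9 of the 15 opposite probes are hypomethylated in drinkers and
#' 6 hypermethylated, mirroring the observed direction split.
#'
#' Drinking-affected probes are additionally linked to the latent shared
#' drinking-severity factor (loading sign equal to the sign of the
#' drinking shift); two designated opposite-class probes are instead
#' linked, more strongly, to the impaired-control factor and act as the
#' planted top contributors of the fusion analysis.
#'
#' @param n_probes total number of probes.
#' @param n_exercise_only,n_drinking_only,n_overlap_concordant
#'   class sizes.
#' @param n_overlap_opposite number of opposite-direction probes.
#' @param n_opposite_hypo how many opposite probes are hypomethylated in
#'   drinkers (default 9 of 15).
#' @param n_age_driven,n_batch_driven,n_race_driven nuisance class sizes.
#' @param delta_beta planted absolute beta shift (default 0.08, chosen to
#'   exceed the 0.06 SD retention threshold so planted probes survive
#'   filtering).
#' @param link_r target correlation of drinking-affected probes with the
#'   latent severity factor.
#' @param top_link_r stronger linkage of the two designated fusion
#'   probes.  The default makes the impaired-control factor the dominant
#'   variance source of the two probes (r^2 > 0.5) and keeps the
#'   two-probe component's leading eigenvalue (sigma^2 + 2 c^2) well
#'   above the sample-covariance noise-bulk edge
#'   sigma^2 (1 + sqrt(p/n))^2 at the default cohort size, so the
#'   planted fusion component is recoverable by construction rather than
#'   sitting at the detection boundary.
#' @param subject_sd inter-subject SD planted at effect probes.
#' @param age_slope beta/year slope of age-driven probes.
#' @param batch_delta,race_delta nuisance shift sizes.
#' @param seed integer seed.
#' @return list of class `truth_manifest` with elements `probes` (one row
#'   per probe), `top_linked` (probe ids), and `mixture_alpha` (Dirichlet
#'   parameters of the cell mixture).
#' @export
truth_manifest <- function(n_probes = 1500,
                           n_exercise_only = 40,
                           n_drinking_only = 40,
                           n_overlap_concordant = 17,
                           n_overlap_opposite = 15,
                           n_opposite_hypo = min(9L, n_overlap_opposite),
                           n_age_driven = 25,
                           n_batch_driven = 25,
                           n_race_driven = 25,
                           delta_beta = 0.08,
                           link_r = 0.3,
                           top_link_r = 0.75,
                           subject_sd = 0.07,
                           age_slope = 0.004,
                           batch_delta = 0.05,
                           race_delta = 0.08,
                           seed = 1L) {
  n_eff <- n_exercise_only + n_drinking_only + n_overlap_concordant +
    n_overlap_opposite + n_age_driven + n_batch_driven + n_race_driven
  if (n_eff > n_probes) stop("class sizes exceed n_probes")
  if (n_opposite_hypo > n_overlap_opposite)
    stop("n_opposite_hypo cannot exceed n_overlap_opposite")
  set.seed(fan_seed(seed, "manifest"))
  probe_id <- sprintf("cg%08d", seq_len(n_probes))
  cls <- rep("null", n_probes)
  idx <- sample.int(n_probes, n_eff)
  take <- function(k) {
    out <- idx[seq_len(k)]
    idx <<- idx[-seq_len(k)]
    out
  }
  i_ex <- take(n_exercise_only)
  i_dr <- take(n_drinking_only)
  i_oc <- take(n_overlap_concordant)
  i_oo <- take(n_overlap_opposite)
  i_ag <- take(n_age_driven)
  i_ba <- take(n_batch_driven)
  i_ra <- take(n_race_driven)
  cls[i_ex] <- "exercise_only"; cls[i_dr] <- "drinking_only"
  cls[i_oc] <- "overlap_concordant"; cls[i_oo] <- "overlap_opposite"
  cls[i_ag] <- "age_driven"; cls[i_ba] <- "batch_driven"
  cls[i_ra] <- "race_driven"

  ex_d <- dr_d <- rep(0, n_probes)
  rs <- function(k) sample(c(-1, 1), k, replace = TRUE)
  ex_d[i_ex] <- rs(n_exercise_only) * delta_beta
  dr_d[i_dr] <- rs(n_drinking_only) * delta_beta
  s_oc <- rs(n_overlap_concordant)
  ex_d[i_oc] <- s_oc * delta_beta
  dr_d[i_oc] <- s_oc * delta_beta
  s_oo <- c(rep(-1, n_opposite_hypo),
            rep(1, n_overlap_opposite - n_opposite_hypo))
  dr_d[i_oo] <- s_oo * delta_beta     # negative = hypomethylated in drinkers
  ex_d[i_oo] <- -s_oo * delta_beta    # exercise shifts the opposite way

  age_s <- rep(0, n_probes); age_s[i_ag] <- age_slope * rs(n_age_driven)
  bat_d <- rep(0, n_probes); bat_d[i_ba] <- batch_delta
  rac_d <- rep(0, n_probes); rac_d[i_ra] <- race_delta * rs(n_race_driven)

  ## behavioral linkage: drinking-affected probes covary with the shared
  ## severity factor; the two designated fusion probes covary with the
  ## impaired-control factor instead (the planted fusion scenario:
  ## 2 linked probes + 1 dominant linked measure)
  lr <- rep(0, n_probes)
  lf <- rep("none", n_probes)
  linked <- c(i_dr, i_oc, i_oo)
  lr[linked] <- link_r
  lf[linked] <- "shared"
  top <- i_oo[seq_len(min(2L, n_overlap_opposite))]
  lr[top] <- top_link_r
  lf[top] <- "link"
  link_sign <- sign(dr_d)

  sub_sd <- rep(NA_real_, n_probes)
  sub_sd[cls == "null"] <- stats::runif(sum(cls == "null"), 0.015, 0.12)
  sub_sd[cls %in% c("exercise_only", "drinking_only", "overlap_concordant",
                    "overlap_opposite", "batch_driven", "race_driven")] <- subject_sd
  sub_sd[cls == "age_driven"] <- 0.03

  probes <- data.frame(probe_id = probe_id, class = cls,
                       exercise_delta = ex_d, drinking_delta = dr_d,
                       age_slope = age_s, batch_delta = bat_d,
                       race_delta = rac_d, link_r = lr,
                       link_factor = lf,
                       link_sign = link_sign, subject_sd = sub_sd,
                       stringsAsFactors = FALSE)
  structure(list(probes = probes,
                 top_linked = probe_id[top],
                 delta_beta = delta_beta,
                 mixture_alpha = c(buccal = 5, leukocyte = 2)),
            class = "truth_manifest")
}

#' Probe ids of a manifest class
#' @param manifest a [truth_manifest].
#' @param class character class label(s).
#' @return character vector of probe ids.
#' @export
manifest_probes <- function(manifest, class) {
  manifest$probes$probe_id[manifest$probes$class %in% class]
}

#' Generate a cell-type reference panel
#'
#' Mean beta profiles for `n_types` constituent cell types (default a
#' buccal-epithelial-like and a leukocyte-like type, the two dominant
#' saliva fractions).  A designated subset of discriminating probes has a
#' between-type profile difference of at least 0.2 beta so the mixture is
#' identifiable.
#'
#' @param n_types number of cell types (>= 2).
#' @param n_probes number of probes.
#' @param seed integer seed.
#' @param frac_discriminating fraction of probes made discriminating.
#' @param min_diff minimum between-type difference at discriminating
#'   probes.
#' @return list of class `reference_panel` with `profiles` (types x
#'   probes matrix) and `discriminating` (probe ids).
#' @export
gen_reference_panel <- function(n_types = 2, n_probes = 1500, seed = 1L,
                                frac_discriminating = 0.1, min_diff = 0.25) {
  if (n_types < 2) stop("n_types must be >= 2")
  set.seed(fan_seed(seed, "panel"))
  probe_id <- sprintf("cg%08d", seq_len(n_probes))
  base <- stats::rbeta(n_probes, 2, 2) * 0.7 + 0.15
  profiles <- matrix(rep(base, each = n_types), nrow = n_types,
                     dimnames = list(paste0("type", seq_len(n_types)), probe_id))
  n_disc <- max(20L, round(frac_discriminating * n_probes))
  disc <- sort(sample.int(n_probes, n_disc))
  for (t in seq_len(n_types)[-1]) {
    dir <- ifelse(base[disc] > 0.5, -1, 1)  # push toward the interior
    profiles[t, disc] <- pmin(pmax(base[disc] + dir * (min_diff + 0.02 * (t - 1)), 0), 1)
    jitter_idx <- setdiff(seq_len(n_probes), disc)
    profiles[t, jitter_idx] <- pmin(pmax(
      profiles[t, jitter_idx] + stats::rnorm(length(jitter_idx), 0, 0.01), 0), 1)
  }
  structure(list(profiles = profiles, discriminating = probe_id[disc]),
            class = "reference_panel")
}

## Dirichlet sampler via normalized gammas.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

## Per-sample mixed baseline profile: convex combination of panel profiles
## by Dirichlet proportions, plus per-subject deviations at the manifest's
## subject SD.  Returns list(values, props, subject_dev).
mixed_baseline <- function(n_subjects, manifest, panel) {
  pr <- manifest$probes
  np <- nrow(pr)
  if (!identical(pr$probe_id, colnames(panel$profiles)))
    stop("manifest and panel must be defined on the same probe set")
  props <- rdirichlet(n_subjects, manifest$mixture_alpha)
  colnames(props) <- rownames(panel$profiles)
  mix <- props %*% panel$profiles
  dev <- matrix(stats::rnorm(n_subjects * np, 0, rep(pr$subject_sd, each = n_subjects)),
                nrow = n_subjects)
  list(values = mix + dev, props = props)
}

clip01 <- function(m, stage) {
  n_clip <- sum(m < 0 | m > 1, na.rm = TRUE)
  rate <- n_clip / length(m)
  op_log(stage, sprintf("clipped %d values (%.2f%%) into [0,1]", n_clip, 100 * rate))
  if (rate > 0.10)
    warning(sprintf("%s: clipping rate %.1f%% exceeds 10%%", stage, 100 * rate))
  attr_m <- pmin(pmax(m, 0), 1)
  attr(attr_m, "clip_rate") <- rate
  attr_m
}

## Detection p-values: mostly confident calls, a small fraction failed.
gen_detection_p <- function(dim, fail_rate = 0.005) {
  p <- matrix(stats::runif(prod(dim), 0, 0.03), nrow = dim[1])
  n_fail <- round(fail_rate * length(p))
  if (n_fail > 0) {
    idx <- sample.int(length(p), n_fail)
    p[idx] <- stats::runif(n_fail, 0.051, 1)
  }
  p
}

sample_race <- function(n, freq) {
  sample(names(freq), n, replace = TRUE, prob = freq / sum(freq))
}

#' Generate the longitudinal exercise cohort
#'
#' `n_subjects` healthy participants measured at baseline and after a
#' twelve-month moderate-exercise intervention (2 x n_subjects samples).
#' Follow-up values at exercise-affected probes are shifted by the
#' manifest's signed delta; subject-level profiles persist across
#' timepoints so paired differences cancel them.  Values are clipped to
#' \[0, 1\] only after noise addition, with the clipping rate logged.
#'
#' @param n_subjects number of paired participants (default 53).
#' @param manifest a [truth_manifest].
#' @param panel a `reference_panel` on the same probes.
#' @param noise_sd per-measurement technical noise SD (default 0.02).
#' @param seed integer seed.
#' @param n_vo2_increased how many subjects objectively increased their
#'   VO2 max (default 29).
#' @return list with `beta` ([beta_matrix]), `sheet` (data.frame,
#'   2 x n_subjects rows) and `cell_props` (true mixing proportions).
#' @export
gen_exercise_cohort <- function(n_subjects = 53, manifest, panel,
                                noise_sd = 0.02, seed = 1L,
                                n_vo2_increased = 29) {
  set.seed(fan_seed(seed, "exercise"))
  pr <- manifest$probes
  np <- nrow(pr)
  age <- round(pmin(pmax(stats::rnorm(n_subjects, 28.45, 7.94), 18), 44))
  sex <- sample(c("F", "M"), n_subjects, replace = TRUE, prob = c(42, 11))
  race <- sample_race(n_subjects,
                      c(Caucasian = 35, AfricanAmerican = 2, AsianAmerican = 7,
                        Hispanic = 6, Native = 3, Multiracial = 1))
  vo2 <- rep(FALSE, n_subjects)
  vo2[sample.int(n_subjects, min(n_vo2_increased, n_subjects))] <- TRUE
  base <- mixed_baseline(n_subjects, manifest, panel)
  age_eff <- outer(age - 30, pr$age_slope)
  signal <- base$values + age_eff
  b0 <- signal + matrix(stats::rnorm(n_subjects * np, 0, noise_sd), n_subjects)
  b1 <- signal + matrix(pr$exercise_delta, n_subjects, np, byrow = TRUE) +
    matrix(stats::rnorm(n_subjects * np, 0, noise_sd), n_subjects)
  vals <- rbind(b0, b1)
  vals <- clip01(vals, "gen_exercise")
  subj <- sprintf("EX%03d", seq_len(n_subjects))
  sid <- c(paste0(subj, "_T0"), paste0(subj, "_T1"))
  dimnames(vals) <- list(sid, pr$probe_id)
  batch <- sample(c("B1", "B2"), n_subjects, replace = TRUE)
  sheet <- data.frame(
    sample_id = sid,
    subject_id = rep(subj, 2),
    cohort = "exercise",
    timepoint = rep(c("baseline", "followup"), each = n_subjects),
    group = NA_character_,
    age = rep(age, 2), sex = rep(sex, 2), race = rep(race, 2),
    batch = rep(batch, 2),
    vo2_increased = rep(vo2, 2),
    stringsAsFactors = FALSE)
  dp <- gen_detection_p(dim(vals))
  dimnames(dp) <- dimnames(vals)
  list(beta = beta_matrix(vals, detection_p = dp), sheet = sheet,
       cell_props = base$props)
}

#' Generate the case-control drinking cohort
#'
#' `n_per_group` hazardous drinkers and `n_per_group` controls matched in
#' age and sex (each drinker's age and sex are reused for one control)
#' but deliberately imbalanced in race, mirroring the demographic
#' structure the race-adjusted model must handle.  Drinking-affected
#' probes are shifted in drinkers by the manifest delta; race-driven
#' probes are shifted by race membership, not by group.
#'
#' @param n_per_group samples per group (default 81).
#' @param manifest a [truth_manifest].
#' @param panel a `reference_panel`.
#' @param race_confound list with per-group race frequency vectors
#'   `drinker` and `control` (defaults mirror the study's imbalance,
#'   e.g. Asian American 0 vs 23).
#' @param noise_sd technical noise SD.
#' @param seed integer seed.
#' @return list with `beta`, `sheet`, `cell_props`.
#' @export
gen_casecontrol_cohort <- function(n_per_group = 81, manifest, panel,
                                   race_confound = NULL,
                                   noise_sd = 0.02, seed = 1L) {
  set.seed(fan_seed(seed, "casecontrol"))
  if (is.null(race_confound)) {
    race_confound <- list(
      drinker = c(Caucasian = 40, AfricanAmerican = 1, AsianAmerican = 0,
                  Hispanic = 23, Native = 3, Multiracial = 14),
      control = c(Caucasian = 36, AfricanAmerican = 3, AsianAmerican = 23,
                  Hispanic = 7, Native = 0, Multiracial = 12))
  }
  pr <- manifest$probes
  np <- nrow(pr)
  n <- 2 * n_per_group
  age1 <- round(pmin(pmax(stats::rnorm(n_per_group, 32, 10.5), 20), 56))
  sex1 <- sample(c("F", "M"), n_per_group, replace = TRUE, prob = c(53, 28))
  age <- c(age1, age1)           # matched by construction
  sex <- c(sex1, sex1)
  group <- rep(c("drinker", "control"), each = n_per_group)
  race <- c(sample_race(n_per_group, race_confound$drinker),
            sample_race(n_per_group, race_confound$control))
  base <- mixed_baseline(n, manifest, panel)
  vals <- base$values
  is_drinker <- group == "drinker"
  vals[is_drinker, ] <- vals[is_drinker, ] +
    matrix(pr$drinking_delta, sum(is_drinker), np, byrow = TRUE)
  is_shifted_race <- race == "AsianAmerican"
  if (any(is_shifted_race))
    vals[is_shifted_race, ] <- vals[is_shifted_race, ] +
      matrix(pr$race_delta, sum(is_shifted_race), np, byrow = TRUE)
  batch <- sample(c("B1", "B2"), n, replace = TRUE)
  vals <- vals + matrix(pr$batch_delta, n, np, byrow = TRUE) * (batch == "B2")
  vals <- vals + matrix(stats::rnorm(n * np, 0, noise_sd), n)
  vals <- clip01(vals, "gen_casecontrol")
  sid <- sprintf("CC%03d", seq_len(n))
  dimnames(vals) <- list(sid, pr$probe_id)
  sheet <- data.frame(
    sample_id = sid, subject_id = sid, cohort = "case_control",
    timepoint = NA_character_, group = group,
    age = age, sex = sex, race = race, batch = batch,
    vo2_increased = NA, stringsAsFactors = FALSE)
  dp <- gen_detection_p(dim(vals))
  dimnames(dp) <- dimnames(vals)
  list(beta = beta_matrix(vals, detection_p = dp), sheet = sheet,
       cell_props = base$props)
}

#' Default behavior model for the binge-drinking cohort
#'
#' Two latent factors: a shared drinking-severity factor loading all 13
#' measures (the source of their strong mutual correlation) and an
#' impaired-control factor loading the ICS measures, with ICS-total
#' loading strongest.  The impaired-control factor also drives the
#' manifest's behavior-linked probes.
#'
#' @param shared_loading loading of every measure on the shared factor.
#' @param link_loadings named loadings on the impaired-control factor.
#' @param noise_sd unique noise SD of each measure.
#' @return list describing the model.
#' @export
behavior_model_default <- function(shared_loading = 0.6,
                                   link_loadings = c(ICS_total = 0.7,
                                                     ICS_ac = 0.35,
                                                     ICS_fc = 0.35,
                                                     ICS_pc = 0.35),
                                   noise_sd = 0.5) {
  lv <- stats::setNames(rep(0, 13), behavior_measures())
  lv[names(link_loadings)] <- link_loadings
  list(shared_loading = rep(shared_loading, 13), link_loadings = lv,
       noise_sd = noise_sd)
}

## Model-implied mean off-diagonal correlation of the 13 measures.
behavior_model_mean_cor <- function(model) {
  s <- model$shared_loading
  l <- model$link_loadings
  v <- s^2 + l^2 + model$noise_sd^2
  cm <- (outer(s, s) + outer(l, l)) / sqrt(outer(v, v))
  mean(cm[upper.tri(cm)])
}

#' Generate the binge-drinking cohort with behavioral scores
#'
#' `n` drinkers with a complete 13-measure behavior vector generated from
#' the latent-factor model, and methylation in which the manifest's
#' behavior-linked probes covary with the impaired-control factor at
#' their stated signed strength (correlation scale).
#'
#' @param n number of drinkers (default 281).
#' @param manifest a [truth_manifest].
#' @param panel a `reference_panel`.
#' @param behavior_model a model from [behavior_model_default()].
#' @param noise_sd technical noise SD.
#' @param seed integer seed.
#' @return list with `beta`, `sheet` (including the 13 behavior columns),
#'   `cell_props`, and `latent` (the per-sample factor scores).
#' @export
gen_drinking_cohort <- function(n = 281, manifest, panel,
                                behavior_model = behavior_model_default(),
                                noise_sd = 0.02, seed = 1L) {
  set.seed(fan_seed(seed, "drinking"))
  if (length(behavior_model$shared_loading) != 13L ||
      length(behavior_model$link_loadings) != 13L)
    stop("behavior model loadings must have length 13")
  pr <- manifest$probes
  np <- nrow(pr)
  ## latent severity factors are unit-variance Laplace: drinking-severity
  ## scores are heavy-tailed in practice, and super-Gaussian factors make
  ## the planted independent components identifiable for Infomax
  rlaplace <- function(n) stats::rexp(n) * sample(c(-1, 1), n, TRUE) / sqrt(2)
  f_shared <- rlaplace(n)
  f_link <- rlaplace(n)
  scores <- outer(f_shared, behavior_model$shared_loading) +
    outer(f_link, behavior_model$link_loadings) +
    matrix(stats::rnorm(n * 13, 0, behavior_model$noise_sd), n)
  colnames(scores) <- behavior_measures()
  base <- mixed_baseline(n, manifest, panel)
  vals <- base$values
  ## probe linkage: target correlation r with the impaired-control factor;
  ## contribution c chosen so that c / sqrt(c^2 + subject_sd^2) = r.
  linked <- which(pr$link_r > 0)
  if (length(linked) > 0) {
    r <- pr$link_r[linked]
    c_amp <- r * pr$subject_sd[linked] / sqrt(1 - r^2)
    F <- cbind(shared = f_shared, link = f_link)[, pr$link_factor[linked],
                                                 drop = FALSE]
    vals[, linked] <- vals[, linked] +
      F * matrix(c_amp * pr$link_sign[linked], n, length(linked), byrow = TRUE)
  }
  vals <- vals + matrix(stats::rnorm(n * np, 0, noise_sd), n)
  vals <- clip01(vals, "gen_drinking")
  sid <- sprintf("DR%03d", seq_len(n))
  dimnames(vals) <- list(sid, pr$probe_id)
  age <- round(pmin(pmax(stats::rnorm(n, 31.8, 9.9), 21), 56))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(86, 195))
  race <- sample_race(n, c(Caucasian = 128, AfricanAmerican = 6,
                           AsianAmerican = 2, Hispanic = 72, Native = 17,
                           Multiracial = 56))
  sheet <- data.frame(
    sample_id = sid, subject_id = sid, cohort = "drinking",
    timepoint = NA_character_, group = "drinker",
    age = age, sex = sex, race = race,
    batch = sample(c("B1", "B2"), n, replace = TRUE),
    vo2_increased = NA, stringsAsFactors = FALSE)
  sheet <- cbind(sheet, as.data.frame(scores))
  dp <- gen_detection_p(dim(vals))
  dimnames(dp) <- dimnames(vals)
  list(beta = beta_matrix(vals, detection_p = dp), sheet = sheet,
       cell_props = base$props,
       latent = data.frame(sample_id = sid, shared = f_shared, link = f_link))
}

#' Generate technical replicate pairs
#'
#' For `n_replicated` randomly chosen samples, two technical measurements
#' are simulated as the sample's stored value plus independent
#' Normal(0, error_sd) noise (each measurement carries its own error, the
#' assumption under which the paired-difference estimator recovers the
#' per-measurement SD), clipped to \[0, 1\].
#'
#' @param beta a [beta_matrix].
#' @param error_sd per-measurement error SD (>= 0).
#' @param n_replicated number of replicated samples.
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `probe_id`, `meas1`,
#'   `meas2`.
#' @export
gen_replicates <- function(beta, error_sd, n_replicated = 5, seed = 1L) {
  if (error_sd < 0) stop("error_sd must be >= 0")
  if (n_replicated > n_samples(beta))
    stop("n_replicated exceeds sample count")
  set.seed(fan_seed(seed, "replicates"))
  pick <- sort(sample.int(n_samples(beta), n_replicated))
  v <- beta$values[pick, , drop = FALSE]
  noise <- function() matrix(stats::rnorm(length(v), 0, error_sd), nrow(v))
  m1 <- pmin(pmax(v + noise(), 0), 1)
  m2 <- pmin(pmax(v + noise(), 0), 1)
  data.frame(
    sample_id = rep(rownames(v), times = ncol(v)),
    probe_id = rep(colnames(v), each = nrow(v)),
    meas1 = as.vector(m1), meas2 = as.vector(m2),
    stringsAsFactors = FALSE)
}

#' Generate all three cohorts plus replicates and panel in one call
#'
#' Convenience wrapper used by the end-to-end pipeline and tests.  All
#' stage seeds derive from `seed`.
#'
#' @param manifest a [truth_manifest] (default: [truth_manifest()] with
#'   the same seed).
#' @param seed root seed.
#' @param n_exercise,n_per_group,n_drinking cohort sizes.
#' @param error_sd named per-cohort replicate error SDs.
#' @return list with `manifest`, `panel`, `exercise`, `case_control`,
#'   `drinking`, `replicates` (list of two replicate tables).
#' @export
simulate_study <- function(seed = 1L, manifest = NULL,
                           n_exercise = 53, n_per_group = 81,
                           n_drinking = 281,
                           error_sd = c(exercise = 0.045, drinking = 0.06)) {
  if (is.null(manifest)) manifest <- truth_manifest(seed = seed)
  panel <- gen_reference_panel(n_probes = nrow(manifest$probes), seed = seed)
  ex <- gen_exercise_cohort(n_exercise, manifest, panel, seed = seed)
  cc <- gen_casecontrol_cohort(n_per_group, manifest, panel, seed = seed)
  dr <- gen_drinking_cohort(n_drinking, manifest, panel, seed = seed)
  reps <- list(
    exercise = gen_replicates(ex$beta, error_sd[["exercise"]],
                              n_replicated = 5, seed = fan_seed(seed, "rep_ex")),
    drinking = gen_replicates(cc$beta, error_sd[["drinking"]],
                              n_replicated = 5, seed = fan_seed(seed, "rep_dr")))
  list(manifest = manifest, panel = panel, exercise = ex,
       case_control = cc, drinking = dr, replicates = reps)
}
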