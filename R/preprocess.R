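#' Mask measurements by detection p-value
#'
#' Measurements whose detection p-value exceeds `p_max` (strict
#' inequality; p equal to the threshold is retained) are set missing.
#' Without detection p-values the matrix is returned unchanged with a
#' warning.
#'
#' @param beta a [beta_matrix].
#' @param p_max detection p-value threshold (default 0.05).
#' @return A [beta_matrix] with failed measurements set to `NA`.
#' @export
mask_detection <- function(beta, p_max = 0.05) {
  if (is.null(beta$detection_p)) {
    warning("no detection p-values present; mask_detection is a no-op")
    return(beta)
  }
  v <- beta$values
  fail <- !is.na(beta$detection_p) & beta$detection_p > p_max
  v[fail] <- NA_real_
  op_log("preprocess", sprintf("detection-p mask: %d measurement(s) set missing",
                               sum(fail)))
  beta_matrix(v, detection_p = beta$detection_p)
}

#' Filter samples or probes by missing rate
#'
#' Rows (samples) or columns (probes) whose missing fraction strictly
#' exceeds `max_rate` are removed; a missing rate exactly equal to the
#' threshold is retained.  Order of the remaining entries is preserved.
#'
#' @param beta a [beta_matrix].
#' @param max_rate maximum tolerated missing fraction (default 0.05).
#' @param axis `"probes"` or `"samples"`.
#' @return list with `beta` (filtered) and `removed` (identifiers).
#' @export
filter_missing <- function(beta, max_rate = 0.05, axis = c("probes", "samples")) {
  axis <- match.arg(axis)
  if (max_rate < 0 || max_rate > 1) stop("max_rate must lie in [0, 1]")
  miss <- is.na(beta$values)
  if (axis == "samples") {
    rate <- rowMeans(miss)
    keep <- rate <= max_rate
    removed <- rownames(beta$values)[!keep]
    v <- beta$values[keep, , drop = FALSE]
    dp <- if (!is.null(beta$detection_p)) beta$detection_p[keep, , drop = FALSE]
  } else {
    rate <- colMeans(miss)
    keep <- rate <= max_rate
    removed <- colnames(beta$values)[!keep]
    v <- beta$values[, keep, drop = FALSE]
    dp <- if (!is.null(beta$detection_p)) beta$detection_p[, keep, drop = FALSE]
  }
  if (length(v) == 0) stop("missing-rate filter removed everything")
  op_log("preprocess", sprintf("missing-rate filter (%s): removed %d of %d",
                               axis, length(removed), length(rate)))
  list(beta = beta_matrix(v, detection_p = dp), removed = removed)
}

#' Remove probes by identifier
#'
#' Drops an externally supplied probe list (e.g. cross-hybridizing
#' probes, or a published age-predictor exclusion list) from the matrix.
#'
#' @param beta a [beta_matrix].
#' @param probes character vector of probe ids to drop.
#' @return A [beta_matrix] without those probes.
#' @export
drop_probes <- function(beta, probes) {
  keep <- !(colnames(beta$values) %in% probes)
  op_log("preprocess", sprintf("dropped %d listed probe(s)", sum(!keep)))
  dp <- if (!is.null(beta$detection_p)) beta$detection_p[, keep, drop = FALSE]
  beta_matrix(beta$values[, keep, drop = FALSE], detection_p = dp)
}

#' Regress batch effects out of each probe
#'
#' Per probe, batch indicator dummies are regressed out on complete cases
#' and the residuals plus the probe's grand mean are returned, so
#' batch-balanced data keep their per-probe means.  Missing entries stay
#' missing.  Output is clipped to \[0, 1\] with the clip count logged.
#' With a single batch the input is returned unchanged.
#'
#' @param beta a [beta_matrix].
#' @param batch factor-like batch label per sample, aligned with the
#'   matrix rows.
#' @return A [beta_matrix].
#' @export
adjust_batch <- function(beta, batch) {
  if (length(batch) != n_samples(beta))
    stop("batch length must equal the sample count")
  batch <- droplevels(as.factor(batch))
  if (nlevels(batch) < 2L) {
    op_log("preprocess", "single batch; no adjustment applied")
    return(beta)
  }
  if (any(table(batch) < 2L)) stop("every batch needs >= 2 samples")
  v <- beta$values
  B <- stats::model.matrix(~batch)
  out <- v
  complete <- !colAnyNA(v)
  adjust_block <- function(vals, design) {
    q <- qr(design)
    res <- qr.resid(q, vals)
    sweep(res, 2, colMeans(vals), "+")
  }
  if (any(complete))
    out[, complete] <- adjust_block(v[, complete, drop = FALSE], B)
  flagged <- character(0)
  for (j in which(!complete)) {
    ok <- !is.na(v[, j])
    bj <- droplevels(batch[ok])
    if (nlevels(bj) < 2L) {
      flagged <- c(flagged, colnames(v)[j])
      next  # only one batch observed for this probe; left unadjusted
    }
    Bj <- stats::model.matrix(~bj)
    out[ok, j] <- qr.resid(qr(Bj), v[ok, j]) + mean(v[ok, j])
  }
  if (length(flagged) > 0)
    op_log("preprocess", sprintf("%d probe(s) observed in one batch only, unadjusted: %s",
                                 length(flagged),
                                 paste(utils::head(flagged, 3), collapse = ", ")))
  n_clip <- sum(out < 0 | out > 1, na.rm = TRUE)
  if (n_clip > 0)
    op_log("preprocess", sprintf("batch adjustment clipped %d value(s)", n_clip))
  out <- pmin(pmax(out, 0), 1)
  beta_matrix(out, detection_p = beta$detection_p)
}

#' Estimate the per-measurement replicate error SD
#'
#' Pooled SD of paired replicate differences divided by sqrt(2): when
#' both technical measurements carry independent error of SD sigma, the
#' difference has SD sigma * sqrt(2), so the quotient estimates the
#' per-measurement error.  Pooled over probes and replicate pairs.
#'
#' @param replicates data.frame with columns `meas1`, `meas2` (one row
#'   per sample x probe), as from [gen_replicates()].
#' @return scalar SD estimate.
#' @export
estimate_error_sd <- function(replicates) {
  if (!all(c("meas1", "meas2") %in% names(replicates)))
    stop("replicate table needs columns meas1 and meas2")
  d <- replicates$meas2 - replicates$meas1
  d <- d[!is.na(d)]
  if (length(d) < 2L) stop("need at least 2 replicate pairs")
  ## pooled about zero: technical error has mean zero by construction
  sqrt(mean(d^2) / 2)
}

#' Retain probes whose inter-subject SD exceeds a threshold
#'
#' Probes varying less across subjects than the measurement error carry
#' no usable biological signal; only probes with complete-case SD
#' strictly greater than `sd_threshold` are retained.
#'
#' @param beta a [beta_matrix].
#' @param sd_threshold SD threshold on the beta scale (default 0.06).
#' @return character vector of retained probe ids.
#' @export
sd_filter <- function(beta, sd_threshold = 0.06) {
  if (sd_threshold < 0) stop("sd_threshold must be >= 0")
  s <- col_sds(beta$values)
  keep <- !is.na(s) & s > sd_threshold
  op_log("preprocess", sprintf("SD filter (> %.3f): retained %d of %d probes",
                               sd_threshold, sum(keep), length(s)))
  colnames(beta$values)[keep]
}

#' Screen probes for age association
#'
#' Per probe, a linear model of methylation on age adjusted for sex and
#' dummy-coded race (complete cases); probes whose age coefficient is
#' significant at `p_threshold` (uncorrected) are returned for exclusion.
#'
#' @param beta a [beta_matrix].
#' @param sheet sample sheet aligned with the matrix rows (columns `age`,
#'   `sex`, `race`).
#' @param p_threshold uncorrected p threshold (default 0.01).
#' @return character vector of age-associated probe ids.
#' @export
screen_age_probes <- function(beta, sheet, p_threshold = 0.01) {
  stopifnot(nrow(sheet) == n_samples(beta))
  X <- cbind(`(Intercept)` = 1, age = sheet$age,
             sexM = as.numeric(sheet$sex == "M"),
             dummy_code(sheet$race))
  fit <- ols_by_column(beta$values, X, coef = "age")
  excl <- rownames(fit)[!is.na(fit$p) & fit$p < p_threshold]
  op_log("preprocess", sprintf("age screen (p < %g): excluding %d probe(s)",
                               p_threshold, length(excl)))
  excl
}

#' Reference-based cell-type proportion estimation
#'
#' Constrained projection of each sample's methylation profile onto the
#' reference panel: minimize ||profile - t(panel) w||^2 subject to w on
#' the probability simplex (non-negative, sum to one), solved by
#' projected gradient descent with step 1/L (L the largest eigenvalue of
#' the Gram matrix), which decreases the residual monotonically.
#'
#' @param beta a [beta_matrix].
#' @param panel a `reference_panel`.
#' @param min_overlap minimum probes shared between matrix and panel.
#' @param max_iter,tol solver controls.
#' @return matrix (samples x cell types) of class `cell_proportions`,
#'   rows on the simplex, with attribute `residual_norm`.
#' @export
estimate_cell_props <- function(beta, panel, min_overlap = 20,
                                max_iter = 2000, tol = 1e-13) {
  common <- intersect(probe_ids(beta), colnames(panel$profiles))
  if (length(common) < min_overlap)
    stop(sprintf("only %d probes overlap the reference panel (need >= %d)",
                 length(common), min_overlap))
  P <- t(panel$profiles[, common, drop = FALSE])   # probes x types
  if (max(apply(P, 1, function(r) diff(range(r)))) < 1e-8)
    stop("degenerate reference panel: cell-type profiles are identical")
  G <- crossprod(P)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  k <- ncol(P)
  n <- n_samples(beta)
  W <- matrix(NA_real_, n, k,
              dimnames = list(sample_ids(beta), rownames(panel$profiles)))
  resid_norm <- numeric(n)
  for (i in seq_len(n)) {
    y <- beta$values[i, common]
    ok <- !is.na(y)
    Pi <- P[ok, , drop = FALSE]
    yi <- y[ok]
    Gi <- crossprod(Pi); gi <- crossprod(Pi, yi)
    Li <- max(eigen(Gi, symmetric = TRUE, only.values = TRUE)$values)
    w <- rep(1 / k, k)
    obj <- function(w) sum((Pi %*% w - yi)^2)
    last <- obj(w)
    for (it in seq_len(max_iter)) {
      w <- project_simplex(w - as.vector(Gi %*% w - gi) / Li)
      cur <- obj(w)
      if (last - cur < tol) break
      last <- cur
    }
    W[i, ] <- w
    resid_norm[i] <- sqrt(obj(w))
  }
  structure(W, residual_norm = resid_norm, class = c("cell_proportions", "matrix"))
}

## Euclidean projection onto the probability simplex (sorted-threshold
## algorithm).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Run the full preprocessing chain on one cohort
#'
#' Fixed, logged order: detection-p mask, sample missing-rate filter,
#' probe missing-rate filter, listed-probe removal (cross-hybridizing
#' plus, for the exercise cohort, the published age-predictor list),
#' batch adjustment, SD filter, and (exercise cohort only) the age
#' screen.  Batch adjustment precedes the SD filter so retention is
#' decided on analysis-ready values.
#'
#' @param beta a [beta_matrix].
#' @param sheet aligned sample sheet.
#' @param config a [run_config].
#' @param exclude_probes externally supplied probe ids to drop.
#' @param age_screen run the age screen (TRUE for the exercise cohort).
#' @return list with `beta` (filtered, adjusted matrix restricted to
#'   retained probes), `sheet` (rows matching the matrix), and `report`
#'   (per-stage counts of class `preprocess_report`).
#' @export
preprocess_cohort <- function(beta, sheet, config = run_config(),
                              exclude_probes = character(0),
                              age_screen = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- list()
  n0 <- c(samples = n_samples(beta), probes = n_probes(beta))
  b <- mask_detection(beta, config$detect_p_max)
  fs <- filter_missing(b, config$max_missing_rate, axis = "samples")
  stages$samples_missing <- fs$removed
  fp <- filter_missing(fs$beta, config$max_missing_rate, axis = "probes")
  stages$probes_missing <- fp$removed
  b <- fp$beta
  listed <- intersect(probe_ids(b), exclude_probes)
  stages$probes_listed <- listed
  b <- drop_probes(b, exclude_probes)
  sheet <- sheet[match(sample_ids(b), sheet$sample_id), , drop = FALSE]
  b <- adjust_batch(b, sheet$batch)
  retained <- sd_filter(b, config$sd_threshold)
  stages$probes_low_sd <- setdiff(probe_ids(b), retained)
  keep <- probe_ids(b) %in% retained
  dp <- if (!is.null(b$detection_p)) b$detection_p[, keep, drop = FALSE]
  b <- beta_matrix(b$values[, keep, drop = FALSE], detection_p = dp)
  age_excl <- character(0)
  if (age_screen) {
    base_rows <- if (all(is.na(sheet$timepoint))) seq_len(nrow(sheet)) else
      which(sheet$timepoint == "baseline")
    sub <- beta_matrix(b$values[base_rows, , drop = FALSE])
    age_excl <- screen_age_probes(sub, sheet[base_rows, , drop = FALSE],
                                  config$age_screen_p)
    b <- drop_probes(b, age_excl)
    stages$probes_age <- age_excl
  }
  report <- structure(list(
    input = n0,
    removed = lapply(stages, length),
    removed_ids = stages,
    retained_probes = probe_ids(b),
    n_retained = n_probes(b)), class = "preprocess_report")
  list(beta = b, sheet = sheet, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("input: %d samples x %d probes\n", x$input["samples"], x$input["probes"]))
  for (nm in names(x$removed))
    cat(sprintf("  removed %-16s %d\n", nm, x$removed[[nm]]))
  cat(sprintf("retained probes: %d\n", x$n_retained))
  invisible(x)
}
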