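#' Residualize methylation on demographic covariates
#'
#' Per probe, ordinary least-squares residuals of methylation on age,
#' sex and dummy-coded race, so downstream decompositions cannot be
#' driven by demographic structure.  Residual columns are mean-zero.
#'
#' @param beta a [beta_matrix] (typically restricted to the marker set).
#' @param sheet aligned sheet with `age`, `sex`, `race`.
#' @return numeric matrix (samples x probes) of residuals.
#' @export
residualize <- function(beta, sheet) {
  stopifnot(nrow(sheet) == n_samples(beta))
  X <- cbind(`(Intercept)` = 1, age = sheet$age,
             sexM = as.numeric(sheet$sex == "M"), dummy_code(sheet$race))
  q <- qr(X)
  if (q$rank < ncol(X))
    stop("rank-deficient covariate design in residualize")
  if (anyNA(beta$values)) stop("residualize requires complete marker data")
  R <- qr.resid(q, beta$values)
  dimnames(R) <- dimnames(beta$values)
  R
}

#' Infomax independent component analysis
#'
#' Decomposes `X = A S`: columns (features) are centered, the matrix is
#' whitened by PCA to exactly `k` dimensions (square ICA in whitened
#' space), and the unmixing matrix is estimated by natural-gradient
#' Infomax updates with the logistic nonlinearity.  The learning rate is
#' a fixed step halved on divergence.  `A` (samples x k) holds the
#' component loadings, `S` (k x features) the source scores.  Each
#' component's sign is fixed so its largest-magnitude source score is
#' positive; the fit is deterministic for a fixed seed.
#'
#' @param X numeric matrix, samples x features, finite.
#' @param k number of components (<= min(dim(X)) and <= rank).
#' @param seed integer seed for the random orthogonal initialisation.
#' @param max_iter maximum iterations (default 10000).
#' @param tol convergence tolerance on the unmixing-matrix update
#'   (default 1e-7).
#' @param lr initial learning rate.
#' @return list of class `ica_model`: `A`, `S`, `W` (unmixing in
#'   whitened space), `whitening` (n x k pre-whitening mixing),
#'   `converged`, `iterations`, `k`, `seed`, `center`.
#' @export
infomax_ica <- function(X, k, seed = 1L, max_iter = 10000, tol = 1e-7,
                        lr = 0.1) {
  if (!all(is.finite(X))) stop("X must be finite")
  n <- nrow(X); p <- ncol(X)
  if (k > min(n, p)) stop("k must be <= min(dim(X))")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = k, nv = k)
  if (sv$d[k] < 1e-10 * sv$d[1]) stop("k exceeds the numerical rank of X")
  ## whitened feature-space representation: Z (k x p) with unit row scale;
  ## Xc = M Z with M = U_k D_k / sqrt(p)
  Z <- sqrt(p) * t(sv$v[, seq_len(k), drop = FALSE])
  M <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)] / sqrt(p), k)
  set.seed(seed)
  init <- function() {
    Q <- qr.Q(qr(matrix(stats::rnorm(k * k), k)))
    Q
  }
  W <- init()
  I_k <- diag(k)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    U <- W %*% Z
    Y <- 1 / (1 + exp(-U))
    dW <- lr * (I_k + (1 - 2 * Y) %*% t(U) / p) %*% W
    if (!all(is.finite(dW)) || max(abs(dW)) > 1e6) {
      lr <- lr / 2          # divergence: halve the step and restart
      W <- init()
      next
    }
    W <- W + dW
    if (max(abs(dW)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    op_log("fusion", sprintf("infomax did not converge in %d iterations", max_iter))
  S <- W %*% Z
  A <- M %*% solve(W)
  ## sign convention: largest-|score| feature of each component positive
  for (i in seq_len(k)) {
    j <- which.max(abs(S[i, ]))
    if (S[i, j] < 0) {
      S[i, ] <- -S[i, ]
      A[, i] <- -A[, i]
    }
  }
  rownames(A) <- rownames(X)
  colnames(S) <- colnames(X)
  structure(list(A = A, S = S, W = W, whitening = M, converged = converged,
                 iterations = it, k = k, seed = seed, center = ctr),
            class = "ica_model")
}

#' Stability-based selection of the component number
#'
#' For each candidate k, the decomposition is repeated `n_restarts`
#' times from different random initialisations, each repeat fitted on a
#' bootstrap resample of the samples (restart-only repeats are
#' degenerate for this purpose: a deterministic algorithm reproduces
#' every order almost perfectly on fixed data, so resampling is what
#' exposes spurious components).  The pooled components are clustered by
#' absolute source-score correlation (average-linkage hierarchical
#' clustering cut at k clusters) and each cluster scores mean
#' within-cluster |r| minus mean between-cluster |r| — an ICASSO-style
#' cluster-quality index.  The chosen k is the largest candidate whose
#' mean index exceeds `stability_threshold`: underestimated orders are
#' trivially stable (merged components reproduce too), so the largest
#' stable order is the informative one.  If no candidate is stable a
#' warning is issued and the smallest candidate returned.
#'
#' @param X samples x features matrix.
#' @param k_candidates integer vector of candidate orders.
#' @param n_restarts repeats per candidate (>= 5; fewer make the index
#'   degenerate).
#' @param seed integer seed.
#' @param stability_threshold minimum mean quality index (default 0.8).
#' @param bootstrap resample rows across repeats (default TRUE).
#' @return list: `k` (chosen), `profile` (data.frame of k vs index),
#'   `stable` (logical per candidate).
#' @export
stability_select <- function(X, k_candidates = 1:5, n_restarts = 10,
                             seed = 1L, stability_threshold = 0.8,
                             bootstrap = TRUE) {
  if (n_restarts < 5) stop("n_restarts must be >= 5 for a meaningful index")
  k_candidates <- sort(unique(k_candidates))
  if (max(k_candidates) > min(dim(X)))
    stop("candidate k exceeds the matrix rank bound")
  idx <- numeric(length(k_candidates))
  for (ki in seq_along(k_candidates)) {
    k <- k_candidates[ki]
    comps <- NULL
    for (r in seq_len(n_restarts)) {
      sd_r <- fan_seed(seed, sprintf("stab_k%d_r%d", k, r))
      Xr <- X
      if (bootstrap && r > 1) {      # first repeat on the full data
        set.seed(sd_r)
        Xr <- X[sample.int(nrow(X), replace = TRUE), , drop = FALSE]
      }
      fit <- infomax_ica(Xr, k, seed = sd_r, max_iter = 2000, tol = 1e-6)
      comps <- rbind(comps, fit$S)
    }
    R <- abs(stats::cor(t(comps)))
    cl <- if (k == 1) rep(1L, nrow(comps)) else
      stats::cutree(stats::hclust(stats::as.dist(1 - R), method = "average"), k = k)
    qual <- vapply(seq_len(max(cl)), function(g) {
      inside <- which(cl == g); outside <- which(cl != g)
      w <- if (length(inside) > 1) mean(R[inside, inside][upper.tri(R[inside, inside])]) else 1
      b <- if (length(outside) > 0) mean(R[inside, outside]) else 0
      w - b
    }, numeric(1))
    idx[ki] <- mean(qual)
  }
  stable <- idx > stability_threshold
  if (any(stable)) {
    k_chosen <- max(k_candidates[stable])
  } else {
    warning("no candidate component number is stable; using the smallest")
    k_chosen <- min(k_candidates)
  }
  list(k = k_chosen,
       profile = data.frame(k = k_candidates, quality = idx),
       stable = stable)
}

#' Correlate component loadings across modalities
#'
#' Pearson correlation of every methylation-loading /
#' behavior-loading column pair, two-sided p from the exact t transform
#' on n - 2 degrees of freedom (or a permutation p with
#' `n_permutations` shuffles), Bonferroni threshold
#' `family_alpha / (k1 * k2)`.
#'
#' @param A1 loadings of modality 1 (samples x k1).
#' @param A2 loadings of modality 2 (same samples, samples x k2).
#' @param family_alpha family-wise alpha.
#' @param n_permutations if > 0, permutation p-values instead of the t
#'   transform.
#' @param seed seed for the permutation option.
#' @return list of class `fusion_result`: `r` and `p` matrices
#'   (k1 x k2), `pairs` data.frame sorted by p, `alpha_bonferroni`,
#'   `n`.
#' @export
loading_correlation <- function(A1, A2, family_alpha = 0.05,
                                n_permutations = 0, seed = 1L) {
  if (nrow(A1) != nrow(A2)) stop("loading matrices must share samples")
  n <- nrow(A1)
  if (n < 4) stop("need at least 4 samples")
  r <- stats::cor(A1, A2)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  if (n_permutations > 0) {
    set.seed(seed)
    exceed <- matrix(0, nrow(r), ncol(r))
    for (b in seq_len(n_permutations)) {
      rp <- stats::cor(A1[sample.int(n), , drop = FALSE], A2)
      exceed <- exceed + (abs(rp) >= abs(r))
    }
    p <- (exceed + 1) / (n_permutations + 1)
  }
  k1 <- ncol(A1); k2 <- ncol(A2)
  thr <- family_alpha / (k1 * k2)
  pairs <- data.frame(
    comp1 = rep(seq_len(k1), times = k2),
    comp2 = rep(seq_len(k2), each = k1),
    r = as.vector(r), p = as.vector(p),
    significant = as.vector(p) < thr)
  pairs <- pairs[order(pairs$p), ]
  rownames(pairs) <- NULL
  structure(list(r = r, p = p, pairs = pairs, n_pairs = k1 * k2,
                 alpha_bonferroni = thr, n = n),
            class = "fusion_result")
}

#' Top contributing features of a component
#'
#' Source scores are standardized to mean 0, SD 1 (population SD, i.e.
#' the root mean squared deviation); features whose |z| exceeds the
#' threshold are returned with their signed z.
#'
#' @param s numeric vector of source scores (named by feature).
#' @param z_threshold |z| cutoff (default 1.5).
#' @return data.frame `feature`, `z`, sorted by |z| descending.
#' @export
top_contributors <- function(s, z_threshold = 1.5) {
  if (length(s) < 2) stop("need at least 2 features")
  sdv <- sqrt(mean((s - mean(s))^2))
  if (sdv == 0) stop("zero-variance source scores")
  z <- (s - mean(s)) / sdv
  sel <- which(abs(z) > z_threshold)
  if (length(sel) == 0)
    warning("no feature exceeds |z| > ", z_threshold)
  out <- data.frame(feature = names(s)[sel], z = z[sel],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-abs(out$z)), , drop = FALSE]
}

#' Multivariate methylation-behavior fusion
#'
#' Residualizes the marker methylation on age, sex and race, standardizes
#' the 13-measure behavior matrix, selects the component number of each
#' modality by stability (unless fixed), runs Infomax ICA per modality,
#' correlates the loading columns with Bonferroni control, and extracts
#' the |z| > threshold contributors of every significant pair.
#'
#' @param beta_markers a [beta_matrix] restricted to the marker probes.
#' @param sheet aligned drinking-cohort sheet with behavior columns.
#' @param config a [run_config].
#' @param k_meth,k_behav fixed component numbers (NULL: select by
#'   stability).
#' @param k_candidates_meth,k_candidates_behav candidate orders.
#' @param n_restarts stability restarts.
#' @param seed integer seed.
#' @return list of class `fusion_analysis`: `fusion`
#'   ([loading_correlation()] result), `ica_meth`, `ica_behav`,
#'   `k_meth`, `k_behav`, `contributors` (per significant pair: probes
#'   and measures), `stability` profiles.
#' @export
fuse_modalities <- function(beta_markers, sheet, config = run_config(),
                            k_meth = NULL, k_behav = NULL,
                            k_candidates_meth = 1:4,
                            k_candidates_behav = 1:8,
                            n_restarts = 10, seed = 1L) {
  Rm <- residualize(beta_markers, sheet)
  Bz <- scale(as.matrix(sheet[, behavior_measures(), drop = FALSE]))
  stab <- list()
  if (is.null(k_meth)) {
    stab$meth <- stability_select(Rm, k_candidates_meth, n_restarts,
                                  seed = fan_seed(seed, "stab_meth"))
    k_meth <- stab$meth$k
  }
  if (is.null(k_behav)) {
    stab$behav <- stability_select(Bz, k_candidates_behav, n_restarts,
                                   seed = fan_seed(seed, "stab_behav"))
    k_behav <- stab$behav$k
  }
  op_log("fusion", sprintf("component numbers: %d (methylation), %d (behavior)",
                           k_meth, k_behav))
  im <- infomax_ica(Rm, k_meth, seed = fan_seed(seed, "ica_meth"))
  ib <- infomax_ica(Bz, k_behav, seed = fan_seed(seed, "ica_behav"))
  fr <- loading_correlation(im$A, ib$A, family_alpha = config$family_alpha)
  sig <- fr$pairs[fr$pairs$significant, , drop = FALSE]
  contribs <- lapply(seq_len(nrow(sig)), function(i) {
    list(pair = sig[i, ],
         probes = top_contributors(im$S[sig$comp1[i], ],
                                   config$z_contrib_threshold),
         measures = top_contributors(ib$S[sig$comp2[i], ],
                                     config$z_contrib_threshold))
  })
  structure(list(fusion = fr, ica_meth = im, ica_behav = ib,
                 k_meth = k_meth, k_behav = k_behav,
                 contributors = contribs, stability = stab),
            class = "fusion_analysis")
}
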