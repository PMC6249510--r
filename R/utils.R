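#' @keywords internal
"_PACKAGE"

## Column-wise sd with complete-case handling (probes are columns).
col_sds <- function(x) {
  n <- colSums(!is.na(x))
  mu <- colMeans(x, na.rm = TRUE)
  ss <- colSums(sweep(x, 2, mu, "-")^2, na.rm = TRUE)
  out <- sqrt(ss / pmax(n - 1, 1))
  out[n < 2] <- NA_real_
  out
}

col_means_na <- function(x) colMeans(x, na.rm = TRUE)

#' Deterministic per-stage seed derivation
#'
#' Fans a single root seed out to independent stage seeds so that each
#' pipeline stage is reproducible in isolation.  Kept below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param stage character stage label.
#' @return integer seed.
#' @keywords internal
fan_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

## Vectorised per-column OLS of Y (n x p, NA allowed) on design X (n x q).
## Returns estimate / se / t / p / df / n for the coefficient in column
## `coef` of X, using complete cases per response column.  Columns with no
## missing data share one QR decomposition; the rest are fit individually.
ols_by_column <- function(Y, X, coef) {
  stopifnot(nrow(Y) == nrow(X))
  if (is.character(coef)) {
    coef <- match(coef, colnames(X))
    if (is.na(coef)) stop("coefficient not found in design")
  }
  p <- ncol(Y)
  est <- se <- tt <- pv <- df <- rep(NA_real_, p)
  nn <- integer(p)
  qX <- qr(X)
  if (qX$rank < ncol(X)) {
    bad <- colnames(X)[qX$pivot[seq.int(qX$rank + 1L, ncol(X))]]
    stop("rank-deficient design; aliased columns: ", paste(bad, collapse = ", "))
  }
  complete <- !colAnyNA(Y)
  if (any(complete)) {
    Yc <- Y[, complete, drop = FALSE]
    beta <- qr.coef(qX, Yc)
    res <- qr.resid(qX, Yc)
    dfr <- nrow(X) - ncol(X)
    sigma2 <- colSums(res^2) / dfr
    XtXinv <- chol2inv(qr.R(qX))
    ## account for pivoting in qr
    piv <- qX$pivot
    XtXinv <- XtXinv[order(piv), order(piv), drop = FALSE]
    v <- XtXinv[coef, coef]
    est[complete] <- beta[coef, ]
    se[complete] <- sqrt(sigma2 * v)
    df[complete] <- dfr
    nn[complete] <- nrow(X)
  }
  for (j in which(!complete)) {
    ok <- !is.na(Y[, j])
    if (sum(ok) <= ncol(X)) next
    Xo <- X[ok, , drop = FALSE]
    qo <- qr(Xo)
    if (qo$rank < ncol(Xo)) next
    b <- qr.coef(qo, Y[ok, j])
    r <- qr.resid(qo, Y[ok, j])
    dfr <- sum(ok) - ncol(Xo)
    XtXinv <- chol2inv(qr.R(qo))
    XtXinv <- XtXinv[order(qo$pivot), order(qo$pivot), drop = FALSE]
    est[j] <- b[coef]
    se[j] <- sqrt(sum(r^2) / dfr * XtXinv[coef, coef])
    df[j] <- dfr
    nn[j] <- sum(ok)
  }
  tt <- est / se
  pv <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  data.frame(estimate = est, se = se, statistic = tt, p = pv,
             df = df, n = nn, row.names = colnames(Y))
}

colAnyNA <- function(x) colSums(is.na(x)) > 0L

## Dummy-code a factor against its most frequent level (reference), the
## variance-maximising conventional choice when the reference is unstated.
dummy_code <- function(f, prefix = "race") {
  f <- droplevels(as.factor(f))
  ref <- names(sort(table(f), decreasing = TRUE))[1]
  f <- stats::relevel(f, ref = ref)
  lev <- levels(f)
  if (length(lev) < 2L) {
    return(matrix(numeric(0), nrow = length(f), ncol = 0))
  }
  m <- sapply(lev[-1], function(l) as.numeric(f == l))
  m <- matrix(m, nrow = length(f),
              dimnames = list(NULL, paste0(prefix, "_", lev[-1])))
  m
}

## Structured stage log: message() so it can be suppressed, prefixed.
op_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}
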