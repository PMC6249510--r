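test_that("paired t statistics match an independent long-hand computation", {
  st <- small_study()
  ex <- st$exercise
  tab <- quiet(paired_ttest(ex$beta, ex$sheet))
  set.seed(1)
  pick <- sample(nrow(tab), 100)
  sh <- ex$sheet
  subj <- unique(sh$subject_id)
  for (i in pick) {
    pid <- tab$probe_id[i]
    b0 <- ex$beta$values[match(paste0(subj, ".baseline"),
                               paste0(sh$subject_id, ".", sh$timepoint)), pid]
    b1 <- ex$beta$values[match(paste0(subj, ".followup"),
                               paste0(sh$subject_id, ".", sh$timepoint)), pid]
    d <- (b1 - b0)[!is.na(b1 - b0)]
    tt <- mean(d) / (sd(d) / sqrt(length(d)))
    pp <- 2 * pt(abs(tt), length(d) - 1, lower.tail = FALSE)
    expect_equal(tab$statistic[i], tt, tolerance = 1e-12)
    expect_equal(tab$p[i], pp, tolerance = 1e-12)
  }
})

test_that("paired t handles zero-variance differences as degenerate", {
  subj <- c("a", "b", "c", "d")
  sheet <- data.frame(sample_id = c(paste0(subj, "_0"), paste0(subj, "_1")),
                      subject_id = rep(subj, 2),
                      timepoint = rep(c("baseline", "followup"), each = 4))
  v <- cbind(shift = c(rep(0.2, 4), rep(0.3, 4)),  # d == 0.1 exactly
             flat = rep(0.5, 8))
  colnames(v) <- c("cg00000001", "cg00000002")
  rownames(v) <- sheet$sample_id
  tab <- quiet(paired_ttest(beta_matrix(v), sheet))
  expect_equal(tab$p[tab$probe_id == "cg00000001"], 0)
  expect_true(tab$significant[tab$probe_id == "cg00000001"])
  expect_equal(tab$p[tab$probe_id == "cg00000002"], 1)
})

test_that("paired t is invariant to subject ordering and holds its size", {
  st <- small_study()
  ex <- st$exercise
  tab <- quiet(paired_ttest(ex$beta, ex$sheet))
  set.seed(2)
  perm <- sample(nrow(ex$sheet))
  b_perm <- beta_matrix(ex$beta$values[perm, ])
  tab_perm <- quiet(paired_ttest(b_perm, ex$sheet[perm, ]))
  expect_equal(tab$statistic, tab_perm$statistic[match(tab$probe_id, tab_perm$probe_id)],
               tolerance = 1e-12)

  # type-I calibration at nominal alpha on pure-noise differences
  rej <- sapply(1:20, function(sd) {
    set.seed(sd)
    d <- matrix(rnorm(53 * 50, 0, 0.05), 53, 50)
    tt <- colMeans(d) / (apply(d, 2, sd) / sqrt(53))
    mean(2 * pt(abs(tt), 52, lower.tail = FALSE) < 0.05)
  })
  ci <- qbinom(c(0.025, 0.975), 20 * 50, 0.05) / (20 * 50)
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("group regression matches a brute-force normal-equations solve", {
  st <- small_study()
  cc <- st$case_control
  tab <- quiet(group_diff_regression(cc$beta, cc$sheet))
  g <- as.numeric(cc$sheet$group == "drinker")
  rc <- as.factor(cc$sheet$race)
  ref <- names(sort(table(rc), decreasing = TRUE))[1]
  rc <- relevel(rc, ref)
  X <- cbind(1, g, sapply(levels(rc)[-1], function(l) as.numeric(rc == l)))
  set.seed(3)
  for (i in sample(nrow(tab), 100)) {
    y <- cc$beta$values[, tab$probe_id[i]]
    ok <- !is.na(y)
    Xo <- X[ok, , drop = FALSE]
    beta_hat <- solve(t(Xo) %*% Xo, t(Xo) %*% y[ok])
    res <- y[ok] - Xo %*% beta_hat
    s2 <- sum(res^2) / (sum(ok) - ncol(Xo))
    se <- sqrt(s2 * solve(t(Xo) %*% Xo)[2, 2])
    expect_equal(tab$estimate[i], beta_hat[2], tolerance = 1e-10)
    expect_equal(tab$statistic[i], beta_hat[2] / se, tolerance = 1e-10)
  }
})

test_that("group regression is mean-equivariant and rejects bad designs", {
  set.seed(4)
  n <- 30
  sheet <- data.frame(group = rep(c("drinker", "control"), each = n / 2),
                      race = "Caucasian", stringsAsFactors = FALSE)
  m <- matrix(rnorm(n * 5, 0.4, 0.05), n, 5,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%08d", 1:5)))
  t1 <- quiet(group_diff_regression(beta_matrix(m), sheet))
  t2 <- quiet(group_diff_regression(beta_matrix(m + 0.2), sheet))
  expect_equal(t1$statistic, t2$statistic, tolerance = 1e-10)
  expect_equal(t2$mean_control - t1$mean_control, rep(0.2, 5), tolerance = 1e-12)

  sheet$group <- "drinker"
  expect_error(group_diff_regression(beta_matrix(m), sheet), "constant")
})

test_that("group regression flags planted shifts at epigenome-scale Bonferroni", {
  hit <- sapply(1:10, function(sd) {
    set.seed(sd)
    n <- 162
    g <- rep(c(1, 0), each = 81)
    y <- 0.4 + 0.08 * g + rnorm(n, 0, 0.05)
    m <- matrix(pmin(pmax(y, 0), 1), n, 1,
                dimnames = list(sprintf("s%03d", 1:n), "cg00000001"))
    sheet <- data.frame(group = ifelse(g == 1, "drinker", "control"),
                        race = sample(c("Caucasian", "Hispanic"), n, TRUE))
    tab <- quiet(group_diff_regression(beta_matrix(m), sheet))
    tab$p[1] < 0.05 / 5153
  })
  expect_gte(mean(hit), 0.9)
})

test_that("behavior PCA standardizes, orders variance and picks minimal k", {
  # exactly isotropic construction: orthonormal columns have identity
  # correlation, so every PC explains 1/13 and k = 12 at the 0.90 target
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(40 * 13), 40)))[, 1:13]
  colnames(Q) <- behavior_measures()
  iso <- behavior_pca(Q, 0.90)
  expect_equal(iso$k, 12)
  expect_true(all(diff(iso$variance_fraction) <= 1e-12))
  expect_equal(sum(iso$variance_fraction), 1, tolerance = 1e-10)

  # one dominant factor with little unique noise: few components suffice,
  # and k agrees with a direct eigendecomposition of the correlation matrix
  set.seed(6)
  f <- rnorm(281)
  beh <- outer(f, rep(0.9, 13)) + matrix(rnorm(281 * 13, 0, 0.2), 281)
  colnames(beh) <- behavior_measures()
  dom <- behavior_pca(beh, 0.90)
  ev <- eigen(cor(beh), symmetric = TRUE, only.values = TRUE)$values
  k_oracle <- which(cumsum(ev) / sum(ev) >= 0.90)[1]
  expect_equal(dom$k, k_oracle)
  expect_lte(dom$k, 3)
  expect_gte(cumsum(dom$variance_fraction)[dom$k], 0.90)
  if (dom$k > 1)
    expect_lt(cumsum(dom$variance_fraction)[dom$k - 1], 0.90)

  beh[, 1] <- 1
  expect_error(behavior_pca(beh), "constant.*ADS_con")
})

test_that("PC association passes linked probes and calibrates on nulls", {
  set.seed(7)
  n <- 281
  sheet <- data.frame(age = round(runif(n, 21, 56)),
                      sex = sample(c("F", "M"), n, TRUE),
                      race = sample(c("Caucasian", "Hispanic", "Native"), n, TRUE),
                      stringsAsFactors = FALSE)
  f <- rnorm(n)
  beh <- outer(f, rep(0.7, 13)) + matrix(rnorm(n * 13, 0, 0.7), n)
  colnames(beh) <- behavior_measures()
  pcs <- behavior_pca(beh, 0.90)

  pass_linked <- sapply(1:10, function(sd) {
    set.seed(sd + 100)
    y <- 0.5 + 0.25 * 0.07 / sqrt(1 - 0.25^2) * f + rnorm(n, 0, 0.07)
    m <- matrix(pmin(pmax(y, 0), 1), n, 1,
                dimnames = list(NULL, "cg00000001"))
    rownames(m) <- sprintf("s%03d", 1:n)
    out <- pc_association(beta_matrix(m), pcs, sheet)
    out$pass[1]
  })
  expect_gte(mean(pass_linked), 0.9)

  # independent probes: pass rate near the 1 - 0.95^k union bound
  set.seed(8)
  m0 <- matrix(runif(n * 300, 0.3, 0.7), n, 300,
               dimnames = list(sprintf("s%03d", 1:n), sprintf("cg%08d", 1:300)))
  out0 <- pc_association(beta_matrix(m0), pcs, sheet)
  expected <- 1 - 0.95^pcs$k
  expect_lt(abs(mean(out0$pass) - expected), 0.12)

  bad <- pcs
  bad$scores[, 1] <- 0
  expect_error(pc_association(beta_matrix(m0), bad, sheet), "zero-variance")
})

test_that("two-step drinking composes, is monotone and tracks direction", {
  st <- small_study()
  cfg <- run_config()
  ts <- quiet(two_step_drinking(st$case_control$beta, st$case_control$sheet,
                                st$drinking$beta, st$drinking$sheet, cfg))
  s1_hits <- ts$step1$probe_id[ts$step1$significant]
  expect_true(all(ts$hits %in% s1_hits))
  expect_equal(cumsum(ts$pcs$variance_fraction)[ts$pcs$k] >= 0.90, TRUE)

  # sign bookkeeping: planted drinker-hypomethylated probes report hypo
  pr <- st$manifest$probes
  neg <- pr$probe_id[pr$drinking_delta < 0]
  rec <- intersect(ts$hits, neg)
  expect_gt(length(rec), 0)
  expect_true(all(ts$direction[rec] < 0))

  # empty step 1 gives an empty, warned result
  cfg0 <- run_config(family_alpha = 0)
  expect_warning(
    ts0 <- suppressMessages(
      two_step_drinking(st$case_control$beta, st$case_control$sheet,
                        st$drinking$beta, st$drinking$sheet, cfg0)),
    "no step-1 hits")
  expect_length(ts0$hits, 0)
})
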