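test_that("detection-p masking uses a strict threshold", {
  b <- tiny_beta(3, 2)
  dp <- matrix(0.01, 3, 2, dimnames = dimnames(b$values))
  dp[1, 1] <- 0.06
  dp[2, 2] <- 0.05          # boundary: retained
  bm <- beta_matrix(b$values, detection_p = dp)
  out <- quiet(mask_detection(bm, 0.05))
  expect_true(is.na(out$values[1, 1]))
  expect_false(is.na(out$values[2, 2]))
  expect_equal(out$values[-1, ], bm$values[-1, ])
  expect_warning(mask_detection(b), "no-op")
})

test_that("missing-rate filter removes strictly above the threshold", {
  set.seed(1)
  m <- matrix(runif(100 * 10), 100, 10,
              dimnames = list(sprintf("s%03d", 1:100), sprintf("cg%08d", 1:10)))
  m[1:6, 1] <- NA            # 6% missing -> removed
  m[1:5, 2] <- NA            # exactly 5% -> retained
  b <- beta_matrix(m)
  out <- quiet(filter_missing(b, 0.05, axis = "probes"))
  expect_identical(out$removed, "cg00000001")
  expect_true("cg00000002" %in% probe_ids(out$beta))

  clean <- quiet(filter_missing(tiny_beta(5, 4), 0.05, axis = "probes"))
  expect_length(clean$removed, 0)
  expect_identical(clean$beta$values, tiny_beta(5, 4)$values)

  all_na <- beta_matrix(matrix(NA_real_, 2, 2,
                               dimnames = list(c("a", "b"), c("cg01", "cg02"))))
  expect_error(quiet(filter_missing(all_na, 0, axis = "probes")), "everything")
})

test_that("batch adjustment removes planted offsets and keeps means", {
  set.seed(2)
  n <- 40
  batch <- rep(c("B1", "B2"), each = n / 2)
  m <- matrix(rnorm(n * 50, 0.5, 0.05), n, 50,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%08d", 1:50)))
  m_off <- m
  m_off[batch == "B2", ] <- m_off[batch == "B2", ] + 0.05
  b <- quiet(adjust_batch(beta_matrix(pmin(pmax(m_off, 0), 1)), batch))
  bd <- colMeans(b$values[batch == "B2", ]) - colMeans(b$values[batch == "B1", ])
  expect_true(all(abs(bd) < 1e-10))

  # balanced null data: per-probe means preserved
  b2 <- quiet(adjust_batch(beta_matrix(m), batch))
  expect_true(all(abs(colMeans(b2$values) - colMeans(m)) < 1e-10))

  # single batch: identity
  one <- quiet(adjust_batch(beta_matrix(m), rep("B1", n)))
  expect_identical(one$values, m)
})

test_that("batch adjustment then group regression matches unadjusted on balanced data", {
  set.seed(3)
  n <- 40
  sheet <- data.frame(group = rep(rep(c("drinker", "control"), each = 2), n / 4),
                      race = "Caucasian", stringsAsFactors = FALSE)
  batch <- rep(c("B1", "B2"), n / 2)   # balanced across groups
  m <- matrix(rnorm(n * 30, 0.5, 0.05), n, 30,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%08d", 1:30)))
  b_raw <- beta_matrix(m)
  b_adj <- quiet(adjust_batch(b_raw, batch))
  t_raw <- quiet(group_diff_regression(b_raw, sheet, adjust_race = FALSE))
  t_adj <- quiet(group_diff_regression(b_adj, sheet, adjust_race = FALSE))
  expect_true(all(abs(t_raw$estimate - t_adj$estimate) < 1e-8))
})

test_that("replicate-error estimator is exact on identical replicates", {
  reps <- data.frame(meas1 = runif(100), meas2 = NA)
  reps$meas2 <- reps$meas1
  expect_equal(estimate_error_sd(reps), 0)
  expect_error(estimate_error_sd(data.frame(meas1 = 1, meas2 = 1)), "2 replicate")
})

test_that("SD filter retains strictly above the threshold", {
  set.seed(4)
  m <- cbind(const = rep(0.5, 50),
             low = 0.5 + rnorm(50, 0, 0.01),
             high = pmin(pmax(0.5 + rnorm(50, 0, 0.08), 0), 1))
  colnames(m) <- c("cg00000001", "cg00000002", "cg00000003")
  rownames(m) <- sprintf("s%02d", 1:50)
  b <- beta_matrix(m)
  kept <- quiet(sd_filter(b, 0.06))
  expect_false("cg00000001" %in% kept)
  expect_false("cg00000002" %in% kept)
  expect_true("cg00000003" %in% kept)
  expect_setequal(quiet(sd_filter(b, 0)),
                  c("cg00000002", "cg00000003"))
})

test_that("age screen has power at the planted slope and holds its size", {
  excl_rate <- sapply(1:10, function(sd) {
    set.seed(sd)
    n <- 100
    age <- round(runif(n, 18, 44))
    sheet <- data.frame(age = age, sex = sample(c("F", "M"), n, TRUE),
                        race = sample(c("Caucasian", "Hispanic"), n, TRUE),
                        stringsAsFactors = FALSE)
    m <- matrix(0.5 + 0.004 * (age - 30), n, 5) +
      matrix(rnorm(n * 5, 0, 0.03), n)
    dimnames(m) <- list(sprintf("s%03d", 1:n), sprintf("cg%08d", 1:5))
    excl <- quiet(screen_age_probes(beta_matrix(pmin(pmax(m, 0), 1)), sheet, 0.01))
    length(excl) / 5
  })
  expect_gte(mean(excl_rate), 0.9)

  # permuted age: exclusion close to the nominal 1%
  set.seed(11)
  n <- 100
  sheet <- data.frame(age = round(runif(n, 18, 44)),
                      sex = sample(c("F", "M"), n, TRUE),
                      race = sample(c("Caucasian", "Hispanic"), n, TRUE),
                      stringsAsFactors = FALSE)
  m <- matrix(runif(n * 800, 0.3, 0.7), n, 800,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("cg%08d", 1:800)))
  excl <- quiet(screen_age_probes(beta_matrix(m), sheet, 0.01))
  expect_lt(length(excl) / 800, 0.03)
})

test_that("cell-proportion estimation recovers mixtures on the simplex", {
  pan <- gen_reference_panel(2, 300, seed = 9)
  P <- pan$profiles

  # vertex case: a sample equal to a pure profile
  v <- rbind(P[1, ], P[1, ])
  dimnames(v) <- list(c("s1", "s2"), colnames(P))
  w <- estimate_cell_props(beta_matrix(v), pan)
  expect_equal(unname(w[1, ]), c(1, 0), tolerance = 1e-4)

  # noisy synthetic mixtures
  set.seed(10)
  mix <- c(0.7, 0.3)
  v2 <- matrix(rep(mix %*% P, 10), 10, ncol(P), byrow = TRUE) +
    matrix(rnorm(10 * ncol(P), 0, 0.02), 10)
  v2 <- pmin(pmax(v2, 0), 1)
  dimnames(v2) <- list(sprintf("s%02d", 1:10), colnames(P))
  w2 <- estimate_cell_props(beta_matrix(v2), pan)
  expect_true(all(abs(w2[, 1] - 0.7) < 0.05))
  expect_true(all(w2 >= 0))
  expect_true(all(abs(rowSums(w2) - 1) < 1e-8))

  # degenerate panel
  flat <- pan
  flat$profiles[2, ] <- flat$profiles[1, ]
  expect_error(estimate_cell_props(beta_matrix(v2), flat), "degenerate")

  # insufficient overlap
  small <- beta_matrix(v2[, 1:5])
  expect_error(estimate_cell_props(small, pan), "overlap")
})

test_that("preprocess_cohort runs the full chain and reports counts", {
  st <- small_study()
  out <- quiet(preprocess_cohort(st$exercise$beta, st$exercise$sheet,
                                 run_config(), age_screen = TRUE))
  rep <- out$report
  expect_s3_class(rep, "preprocess_report")
  expect_equal(rep$input[["probes"]], 500)
  expect_equal(rep$n_retained, length(rep$retained_probes))
  expect_lt(rep$n_retained, 500)
  # planted exercise probes survive the chain
  planted <- manifest_probes(st$manifest, c("exercise_only", "overlap_opposite"))
  expect_gt(mean(planted %in% rep$retained_probes), 0.95)
  # matrix rows align with the returned sheet
  expect_identical(sample_ids(out$beta), out$sheet$sample_id)

  # externally listed probes are dropped
  out2 <- quiet(preprocess_cohort(st$exercise$beta, st$exercise$sheet,
                                  run_config(),
                                  exclude_probes = probe_ids(st$exercise$beta)[1:10]))
  expect_false(any(probe_ids(st$exercise$beta)[1:10] %in% probe_ids(out2$beta)))
})
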