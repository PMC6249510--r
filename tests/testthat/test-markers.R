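test_that("hit-set intersection is sorted, warned when empty, and contained", {
  expect_identical(intersect_hits(c("a", "b", "c"), c("c", "b", "d")), c("b", "c"))
  expect_warning(empty <- intersect_hits("a", "b"), "disjoint")
  expect_length(empty, 0)
  set.seed(1)
  x <- sample(letters, 10); y <- sample(letters, 10)
  i <- suppressWarnings(intersect_hits(x, y))
  expect_true(all(i %in% x) && all(i %in% y))
})

test_that("direction classification follows the sign of the mean difference", {
  # worked examples from the published marker table
  expect_equal(classify_direction(0.2395, 0.1636), "hypo")
  expect_equal(classify_direction(0.1454, 0.0848), "hypo")
  expect_equal(classify_direction(0.2267, 0.3120), "hyper")
  expect_equal(classify_direction(0.5, 0.5), "none")
  expect_error(classify_direction(NA, 0.5), "non-missing")
  expect_error(classify_direction(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("published marker table classifies 15/15 opposite with 9 drinker-hypo", {
  t3 <- table3_fixture()
  expect_equal(nrow(t3), 15)
  dr <- classify_direction(t3$Mean_control, t3$Mean_drinker)
  ex <- classify_direction(t3$Mean_baseline, t3$Mean_followup)
  expect_true(all(dr != "none" & ex != "none"))
  expect_true(all((dr == "hypo") == (ex == "hyper")))
  expect_equal(sum(dr == "hypo"), 9)
  expect_equal(sum(dr == "hyper"), 6)
})

test_that("find_opposite extracts, sorts and is idempotent", {
  t3 <- table3_fixture()
  mk <- data.frame(
    probe_id = t3$CpG_site,
    drinking_direction = paste0(classify_direction(t3$Mean_control, t3$Mean_drinker),
                                "_in_drinkers"),
    exercise_direction = paste0(classify_direction(t3$Mean_baseline, t3$Mean_followup),
                                "_after_exercise"),
    opposite = TRUE,
    mean_control = t3$Mean_control, mean_drinker = t3$Mean_drinker,
    p_drinking = as.numeric(t3$`P-value (drinking)`),
    mean_baseline = t3$Mean_baseline, mean_followup = t3$Mean_followup,
    p_exercise = as.numeric(t3$`P-value (exercise)`),
    sign_flagged = FALSE, stringsAsFactors = FALSE)
  # add a concordant row: must be excluded
  conc <- mk[1, ]
  conc$probe_id <- "cg99999999"
  conc$exercise_direction <- "hypo_after_exercise"
  conc$opposite <- FALSE
  opp <- find_opposite(rbind(mk, conc))
  expect_equal(nrow(opp), 15)
  expect_false("cg99999999" %in% opp$probe_id)
  expect_true(!is.unsorted(opp$p_drinking))
  expect_identical(find_opposite(opp), opp)
})

test_that("marker_calls joins directions from both analyses", {
  st <- small_study()
  ex_tab <- quiet(paired_ttest(st$exercise$beta, st$exercise$sheet))
  dr_tab <- quiet(group_diff_regression(st$case_control$beta, st$case_control$sheet))
  calls <- quiet(marker_calls(ex_tab, dr_tab))
  expect_true(all(calls$probe_id %in% ex_tab$probe_id))
  # the opposite flag matches its defining invariant
  expect_identical(calls$opposite,
                   (calls$drinking_direction == "hypo_in_drinkers" &
                      calls$exercise_direction == "hyper_after_exercise") |
                     (calls$drinking_direction == "hyper_in_drinkers" &
                        calls$exercise_direction == "hypo_after_exercise"))
  # opposite markers are a subset of the overlap, itself within each hit set
  opp <- find_opposite(calls)
  expect_true(all(opp$probe_id %in% calls$probe_id))
  # with no planted confounding, mean- and coefficient-based directions agree
  expect_false(any(calls$sign_flagged))
  # planted opposite probes carry the right split of directions
  pr <- st$manifest$probes
  oo <- pr[pr$class == "overlap_opposite" & pr$probe_id %in% opp$probe_id, ]
  got <- opp$drinking_direction[match(oo$probe_id, opp$probe_id)]
  expect_identical(got == "hypo_in_drinkers", oo$drinking_delta < 0)
})

test_that("cell-proportion adjustment is inert for constant proportions", {
  st <- small_study()
  cc <- st$case_control
  markers <- manifest_probes(st$manifest, "overlap_opposite")
  props <- matrix(0.5, nrow(cc$sheet), 2,
                  dimnames = list(cc$sheet$sample_id, c("type1", "type2")))
  class(props) <- c("cell_proportions", "matrix")
  adj <- quiet(posthoc_cellprops(cc$beta, cc$sheet, props, "drinking", markers))
  raw <- quiet(group_diff_regression(
    beta_matrix(cc$beta$values[, intersect(markers, probe_ids(cc$beta))]),
    cc$sheet))
  expect_equal(adj$statistic, raw$statistic[match(adj$probe_id, raw$probe_id)],
               tolerance = 1e-10)
})

test_that("cell-proportion adjustment keeps real effects and kills mixture artifacts", {
  st <- small_study()
  cc <- st$case_control
  props <- quiet(estimate_cell_props(cc$beta, st$panel))
  markers <- intersect(manifest_probes(st$manifest, "overlap_opposite"),
                       probe_ids(cc$beta))
  prim <- quiet(group_diff_regression(beta_matrix(cc$beta$values[, markers]),
                                      cc$sheet))
  adj <- quiet(posthoc_cellprops(cc$beta, cc$sheet, props, "drinking", markers))
  keep <- prim$significant
  expect_gt(mean(adj$significant[keep]), 0.8)
  expect_identical(sign(adj$estimate), sign(prim$estimate))

  # a purely mixture-driven group difference disappears after adjustment
  set.seed(9)
  n <- 120
  pan <- gen_reference_panel(2, 200, seed = 3)
  w1 <- cbind(rbeta(n / 2, 8, 2), NA); w1[, 2] <- 1 - w1[, 1]
  w2 <- cbind(rbeta(n / 2, 2, 8), NA); w2[, 2] <- 1 - w2[, 1]
  W <- rbind(w1, w2)
  v <- W %*% pan$profiles + matrix(rnorm(n * 200, 0, 0.02), n)
  v <- pmin(pmax(v, 0), 1)
  dimnames(v) <- list(sprintf("s%03d", 1:n), colnames(pan$profiles))
  sheet <- data.frame(sample_id = rownames(v),
                      group = rep(c("drinker", "control"), each = n / 2),
                      race = "Caucasian", stringsAsFactors = FALSE)
  target <- pan$discriminating[1:10]
  b <- beta_matrix(v)
  naive <- quiet(group_diff_regression(beta_matrix(v[, target]), sheet))
  props2 <- quiet(estimate_cell_props(b, pan))
  adj2 <- quiet(posthoc_cellprops(b, sheet, props2, "drinking", target))
  expect_gt(sum(naive$significant), 5)
  expect_lt(sum(adj2$significant), sum(naive$significant) / 2)
})

test_that("subgroup confirmations keep directions and reduce to the primary", {
  st <- small_study()
  ex <- st$exercise
  markers <- intersect(manifest_probes(st$manifest, "overlap_opposite"),
                       probe_ids(ex$beta))
  prim <- quiet(paired_ttest(ex$beta, ex$sheet))

  vo2 <- quiet(subgroup_confirm(ex$beta, ex$sheet, markers, "vo2_increased",
                                primary = prim))
  expect_true(all(vo2$direction_consistent))

  # subset == full cohort: identical to the primary analysis
  sheet_all <- ex$sheet
  sheet_all$vo2_increased <- TRUE
  full <- quiet(subgroup_confirm(ex$beta, sheet_all, markers, "vo2_increased",
                                 primary = prim))
  expect_equal(full$statistic,
               prim$statistic[match(full$probe_id, prim$probe_id)],
               tolerance = 1e-12)

  cc <- st$case_control
  prim_cc <- quiet(group_diff_regression(cc$beta, cc$sheet))
  rm_tab <- quiet(subgroup_confirm(cc$beta, cc$sheet, markers, "race_matched",
                                   primary = prim_cc))
  expect_gt(mean(rm_tab$direction_consistent), 0.9)
})

test_that("race matching balances groups within race", {
  st <- small_study()
  sh <- st$case_control$sheet
  ids <- race_match(sh)
  sub <- sh[match(ids, sh$sample_id), ]
  tab <- table(sub$race, sub$group)
  expect_true(all(tab[, "drinker"] == tab[, "control"]))
})
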