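test_that("overlap metrics agree with set-counting oracles on toys", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE     # |A| = 8
  b <- array(FALSE, c(4, 4, 4)); b[2:3, 1:2, 1:2] <- TRUE     # |B| = 8
  expect_equal(dsc(a, b), 0.5)        # intersection 4
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(iou(a, b), dsc(a, b) / (2 - dsc(a, b)))
  expect_equal(dsc(a, a), 1)
  expect_equal(iou(a, a), 1)
  disj <- array(FALSE, c(4, 4, 4)); disj[4, 4, 4] <- TRUE
  expect_equal(dsc(a, disj), 0)
  expect_equal(iou(a, disj), 0)
  empty <- array(FALSE, c(4, 4, 4))
  expect_true(is.na(dsc(empty, empty)))
  expect_error(dsc(a, array(FALSE, c(3, 3, 3))), "differ")
})

test_that("Hausdorff distance handles points, symmetry and empty masks", {
  a <- array(FALSE, c(6, 6, 6)); a[1, 1, 1] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[4, 5, 1] <- TRUE
  expect_equal(hausdorff(a, b), 5)            # 3-4-5 triangle
  expect_equal(hausdorff(a, a), 0)
  expect_true(is.na(hausdorff(a, array(FALSE, c(6, 6, 6)))))
  # anisotropic spacing in mm
  expect_equal(hausdorff(a, b, spacing = c(2, 1, 1)), sqrt(36 + 16))
  # symmetry on random masks
  for (s in 1:5) {
    pr <- random_small_mask_pair(s)
    if (sum(pr$a) == 0 || sum(pr$b) == 0) next
    expect_equal(hausdorff(pr$a, pr$b, pr$spacing),
                 hausdorff(pr$b, pr$a, pr$spacing))
  }
})

test_that("volumetric difference follows its formula", {
  expect_equal(volumetric_difference(100, 80), 0.2)
  expect_equal(volumetric_difference(50, 50), 0)
  expect_equal(volumetric_difference(10, 0), 1)
  expect_true(is.na(volumetric_difference(0, 5)))
})

test_that("per-region metrics match brute-force voxel-set computations", {
  sch <- default_scheme()
  labs_ref <- array(0L, c(6, 6, 6))
  labs_ref[1:3, 1:3, 1:3] <- 1L
  labs_ref[4:6, 4:6, 4:6] <- 35L
  labs_cmp <- array(0L, c(6, 6, 6))
  labs_cmp[2:4, 1:3, 1:3] <- 1L
  labs_cmp[4:5, 4:5, 4:6] <- 35L
  ref <- as_label_mask(labs_ref, sch)
  cmp <- as_label_mask(labs_cmp, sch)
  rows <- per_region_metrics(ref, cmp)
  expect_equal(nrow(rows), 2)
  for (i in seq_len(nrow(rows))) {
    id <- rows$region_id[i]
    a <- labs_ref == id; b <- labs_cmp == id
    expect_equal(rows$dsc[i], oracle_dsc(a, b))
    expect_equal(rows$iou[i], oracle_iou(a, b))
    expect_equal(rows$vd[i], oracle_vd(a, b))
    expect_equal(rows$hd_mm[i], oracle_hausdorff(a, b))
  }
  # identical masks: perfect rows
  self <- per_region_metrics(ref, ref)
  expect_true(all(self$dsc == 1 & self$iou == 1 & self$hd_mm == 0 &
                    self$vd == 0))
  # region present in ref but absent in cmp
  labs_cmp2 <- labs_cmp; labs_cmp2[labs_cmp2 == 35L] <- 0L
  rows2 <- per_region_metrics(ref, as_label_mask(labs_cmp2, sch))
  r35 <- rows2[rows2$region_id == 35, ]
  expect_equal(r35$dsc, 0)
  expect_equal(r35$vd, 1)
  expect_true(is.na(r35$hd_mm))
  # geometry consistency is enforced
  cmp_bad <- as_label_mask(labs_cmp, sch, spacing = c(2, 1, 1))
  expect_error(per_region_metrics(ref, cmp_bad), "co-register")
})

test_that("head-motion pairing keeps HM1-referenced subjects only", {
  roster <- expand.grid(subject = c("s1", "s2", "s3"),
                        condition = c("CONV", "MOVE1", "MOVE2"),
                        stringsAsFactors = FALSE)
  roster$method <- "m"
  roster$session <- match(roster$condition, c("CONV", "MOVE1", "MOVE2"))
  roster$tier <- ifelse(roster$condition == "CONV", "HM1",
                        ifelse(roster$condition == "MOVE1", "HM2", "HM3"))
  roster$mask <- paste0(roster$subject, "_", roster$condition, ".nii.gz")
  prs <- build_pairs(roster, "head_motion")
  expect_equal(nrow(prs), 6)
  expect_equal(sum(prs$pairing_type == "HM1-HM2"), 3)
  expect_equal(sum(prs$pairing_type == "HM1-HM3"), 3)
  # a subject whose CONV record is HM2 contributes nothing
  roster$tier[roster$subject == "s1" & roster$condition == "CONV"] <- "HM2"
  expect_message(prs2 <- build_pairs(roster, "head_motion"), "excluded")
  expect_equal(nrow(prs2), 4)
  expect_false("s1" %in% prs2$subject)
})

test_that("test-retest pairing enumerates all within-subject pairs", {
  roster <- data.frame(subject = "s1", method = "m", condition = "RETEST",
                       session = 1:4, tier = "HM1",
                       mask = paste0("r", 1:4, ".nii.gz"),
                       stringsAsFactors = FALSE)
  prs <- build_pairs(roster, "test_retest")
  expect_equal(nrow(prs), 6)   # C(4,2)
  expect_true(all(prs$pairing_type == "TR"))
  # the earlier record is always the reference
  sess_of <- function(x) as.integer(sub("r(\\d)\\.nii\\.gz", "\\1", x))
  expect_true(all(sess_of(prs$ref_mask) < sess_of(prs$cmp_mask)))
})

test_that("aggregation averages regions and counts undefined values", {
  rows <- data.frame(
    pair_id = 1, subject = "s1", method = "m", pairing_type = "HM1-HM2",
    region_id = c(1, 2, 35), region = c("a", "b", "c"),
    macro_region = c("cortical", "cortical", "subcortical"),
    n_ref = 10, n_cmp = 10,
    dsc = c(0.8, 0.6, 0.9), iou = c(0.7, 0.5, 0.8),
    hd_mm = c(1, NA, 2), vd = c(0.1, 0.2, NA),
    stringsAsFactors = FALSE)
  sm <- aggregate_metrics(rows)
  cort <- sm[sm$macro_region == "cortical", ]
  expect_equal(cort$dsc, 0.7)
  expect_equal(cort$hd_mm, 1)       # the NA is excluded from the mean
  expect_equal(cort$hd_excluded, 1)
  sub <- sm[sm$macro_region == "subcortical", ]
  expect_equal(sub$dsc, 0.9)        # single region: summary equals the row
  expect_equal(sub$vd_excluded, 1)
})

test_that("method comparison selects the right test and flags degeneracy", {
  mk_summary <- function(vals_a, vals_b, subj_b = NULL) {
    n <- length(vals_a)
    subj_a <- paste0("s", seq_len(n))
    if (is.null(subj_b)) subj_b <- subj_a
    rbind(
      data.frame(subject = subj_a, method = "A", macro_region = "cortical",
                 pairing_type = "HM1-HM2", dsc = vals_a, iou = vals_a,
                 hd_mm = vals_a, vd = vals_a, stringsAsFactors = FALSE),
      data.frame(subject = subj_b, method = "B", macro_region = "cortical",
                 pairing_type = "HM1-HM2", dsc = vals_b, iou = vals_b,
                 hd_mm = vals_b, vd = vals_b, stringsAsFactors = FALSE))
  }
  # identical samples -> degenerate, not tested
  s0 <- mk_summary(c(0.9, 0.8, 0.7), c(0.9, 0.8, 0.7))
  r0 <- compare_methods(s0, "A", "B", "dsc", "cortical", "HM1-HM2")
  expect_true(r0$degenerate)
  expect_true(is.na(r0$p_raw))
  # all-positive shifts, n = 6: exact two-sided signed-rank p = 0.03125
  y <- c(0.70, 0.72, 0.74, 0.76, 0.78, 0.80)
  shift <- c(0.050, 0.041, 0.033, 0.026, 0.020, 0.015)
  s1 <- mk_summary(y + shift, y)
  r1 <- compare_methods(s1, "A", "B", "dsc", "cortical", "HM1-HM2")
  expect_equal(r1$test_name, "wilcoxon")
  expect_equal(r1$p_raw, 0.03125)
  expect_equal(r1$p_raw, oracle_wilcoxon_exact(y + shift, y))
  # unequal subject sets -> Mann-Whitney
  s2 <- mk_summary(y + shift, y[1:5], subj_b = paste0("t", 1:5))
  r2 <- compare_methods(s2, "A", "B", "dsc", "cortical", "HM1-HM2")
  expect_equal(r2$test_name, "mannwhitney")
  expect_error(compare_methods(s2[1:4, ], "A", "B", "dsc", "cortical",
                               "HM1-HM2"), "at least 3")
})

test_that("BH correction is per-metric, monotone and never decreases p", {
  res <- data.frame(
    comparison = "A vs B", macro_region = "cortical", pairing_type = "x",
    metric = c(rep("dsc", 4), "vd"),
    test_name = "wilcoxon", statistic = 1,
    p_raw = c(0.01, 0.02, 0.03, 0.04, 0.01),
    degenerate = FALSE, n_a = 6, n_b = 6, stringsAsFactors = FALSE)
  adj <- bh_adjust(res)
  # the step-up worked example: family (0.01,0.02,0.03,0.04) -> all 0.04
  expect_equal(adj$p_adjusted[adj$metric == "dsc"], rep(0.04, 4))
  # a single p in its own family is unchanged
  expect_equal(adj$p_adjusted[adj$metric == "vd"], 0.01)
  expect_true(all(adj$p_adjusted >= adj$p_raw))
  expect_true(all(adj$significant == (adj$p_adjusted < 0.05)))
  # random families: monotone in sorted order, superset of Bonferroni
  set.seed(3)
  p <- runif(12)
  fake <- data.frame(metric = "dsc", p_raw = p)
  fake$p_adjusted <- stats::p.adjust(p, "BH")
  bh_sig <- fake$p_adjusted < 0.05
  bonf_sig <- stats::p.adjust(p, "bonferroni") < 0.05
  expect_true(all(bh_sig[bonf_sig]))
  o <- order(p)
  expect_true(all(diff(fake$p_adjusted[o]) >= -1e-12))
})
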