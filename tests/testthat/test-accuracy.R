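# build a detections table like detect_regions() returns
mk_det <- function(regions, hemis, L_r = NULL, threshold = 2) {
  lt <- region_lobe_table()
  L_r <- if (is.null(L_r)) seq(5, by = -0.5, length.out = length(regions))
         else L_r
  d <- data.frame(region = regions, hemisphere = hemis,
                  lobe = lt$lobe[match(regions, lt$region)],
                  L_r = L_r, n_contributing = 9,
                  stringsAsFactors = FALSE)
  d <- d[order(-d$L_r, d$region), ]
  d$detected <- d$L_r >= threshold
  structure(d, threshold = threshold,
            class = c("region_scores", "data.frame"))
}

mk_gt <- function(expert = "", eeg = NA, res_h = NA, res_l = NA, res_r = NA,
                  engel = NA, fu = NA, id = "D1", subtype = "MTLE-HS-left") {
  data.frame(dataset_id = id, subject_id = "P1", subtype = subtype,
             expert_regions = expert, eeg_lateralization = eeg,
             resection_hemisphere = res_h, resection_lobe = res_l,
             resection_regions = res_r, engel_class = engel,
             followup_months = fu, stringsAsFactors = FALSE)
}

test_that("the lobe lookup covers the whole schema", {
  lt <- region_lobe_table()
  expect_setequal(lt$region, unique(mn_schema()$region))
  expect_equal(lt$lobe[lt$region == "Hippocampus"], "temporal")
  expect_equal(lt$lobe[lt$region == "G_temporal_inf"], "temporal")
  expect_equal(lt$lobe[lt$region == "precentral"], "frontal")
  expect_equal(sum(lt$lobe == "subcortical"), 13)
})

test_that("dataset sensitivity matches detections to ground truth", {
  det <- mk_det(c("Hippocampus", "superiorfrontal"), c("left", "right"))
  gt_surg <- mk_gt(res_h = "left", res_l = "temporal",
                   res_r = "Hippocampus;Amygdala;entorhinal",
                   engel = "I", fu = 12)
  expect_equal(dataset_sensitivity(det, gt_surg, "surgery", "sublobar"), 1)
  expect_equal(dataset_sensitivity(det, gt_surg, "surgery", "lobar"), 1)
  # all detections on the wrong hemisphere
  det_r <- mk_det("Hippocampus", "right")
  expect_equal(dataset_sensitivity(det_r, gt_surg, "surgery", "sublobar"), 0)
  expect_equal(dataset_sensitivity(det_r, gt_surg, "surgery",
                                   "hemispheric"), 0)
  # expert-MRI annotations at the three granularities
  gt_mri <- mk_gt(expert = "entorhinal:left;Hippocampus:left")
  expect_equal(dataset_sensitivity(det, gt_mri, "expert_mri", "sublobar"), 1)
  det_tmp <- mk_det("middletemporal", "left")
  expect_equal(dataset_sensitivity(det_tmp, gt_mri, "expert_mri",
                                   "sublobar"), 0)
  expect_equal(dataset_sensitivity(det_tmp, gt_mri, "expert_mri", "lobar"), 1)
  # EEG is hemispheric; diffuse EEG is not applicable
  expect_equal(dataset_sensitivity(det, mk_gt(eeg = "left"), "eeg"), 1)
  expect_equal(dataset_sensitivity(det_r, mk_gt(eeg = "left"), "eeg"), 0)
  expect_true(is.na(dataset_sensitivity(det, mk_gt(eeg = "diffuse"), "eeg")))
  # non-lesional expert MRI -> not applicable
  expect_true(is.na(dataset_sensitivity(det, mk_gt(expert = ""),
                                        "expert_mri")))
})

test_that("surgery comparisons require favorable outcome and follow-up", {
  det <- mk_det("Hippocampus", "left")
  gt3 <- mk_gt(res_h = "left", res_l = "temporal", res_r = "Hippocampus",
               engel = "III", fu = 12)
  expect_true(is.na(dataset_sensitivity(det, gt3, "surgery")))
  gt_short <- mk_gt(res_h = "left", res_l = "temporal",
                    res_r = "Hippocampus", engel = "I", fu = 3)
  expect_true(is.na(dataset_sensitivity(det, gt_short, "surgery")))
  gt_ok <- mk_gt(res_h = "left", res_l = "temporal", res_r = "Hippocampus",
                 engel = "II", fu = 6)
  expect_equal(dataset_sensitivity(det, gt_ok, "surgery"), 1)
})

test_that("specificity restricts matching to the top-3 detections", {
  det <- mk_det(c("cuneus", "precentral", "lingual", "Hippocampus"),
                c("left", "left", "left", "left"),
                L_r = c(5, 4.5, 4, 3))
  gt <- mk_gt(expert = "Hippocampus:left")
  expect_equal(dataset_sensitivity(det, gt, "expert_mri"), 1)  # rank-4 hit
  expect_equal(dataset_specificity(det, gt, "expert_mri"), 0)
  # no detections at all: 0 for lesional ground truth
  none <- mk_det("Hippocampus", "left", L_r = 1)
  expect_equal(dataset_sensitivity(none, gt, "expert_mri"), 0)
})

test_that("aggregate fractions equal hand counts", {
  mt <- data.frame(sens_expert_mri = c(1, 0, 1, NA, 1))
  a <- aggregate_matches(mt, "sens_expert_mri")
  expect_equal(a$fraction, 3 / 4)
  expect_equal(a$consistent, 3)
  expect_equal(a$evaluable, 4)
  expect_equal(aggregate_matches(mt, "sens_expert_mri",
                                 subset = c(TRUE, TRUE, FALSE, FALSE,
                                            FALSE))$fraction, 0.5)
  expect_error(aggregate_matches(mt, "nope"), "no column")
  set.seed(40)
  x <- sample(c(0, 1, NA), 200, replace = TRUE)
  mt2 <- data.frame(v = x)
  expect_equal(aggregate_matches(mt2, "v")$fraction,
               sum(x == 1, na.rm = TRUE) / sum(!is.na(x)))
})

test_that("diagnostic odds ratio matches its closed form", {
  expect_equal(diagnostic_odds_ratio(1, 1, 1, 1)$dor, 1)
  r <- diagnostic_odds_ratio(9, 1, 1, 9)
  expect_equal(r$dor, 81)
  expect_equal(r$sensitivity, 0.9)
  expect_equal(r$specificity, 0.9)
  expect_equal(r$lr_pos / r$lr_neg, r$dor)
  # prevalence invariance: scaling the diseased row leaves DOR unchanged
  set.seed(41)
  for (b in 1:20) {
    tp <- sample(1:30, 1); fn <- sample(1:30, 1)
    fp <- sample(1:30, 1); tn <- sample(1:30, 1)
    d1 <- diagnostic_odds_ratio(tp, fp, fn, tn)$dor
    d2 <- diagnostic_odds_ratio(2 * tp, fp, 2 * fn, tn)$dor
    expect_equal(d1, d2, tolerance = 1e-10)
    expect_equal(d1, (tp * tn) / (fp * fn), tolerance = 1e-10)
  }
  # continuity correction keeps log(DOR) finite with empty cells
  r0 <- diagnostic_odds_ratio(5, 0, 2, 10)
  expect_true(is.finite(log(r0$dor)) && r0$dor > 0)
  expect_error(diagnostic_odds_ratio(0, 0, 0, 0), "empty")
})

test_that("predictive values follow their definitions", {
  r <- predictive_values(10, 0, 0, 10)
  expect_equal(r$ppv, 1)
  expect_equal(r$npv, 1)
  expect_equal(predictive_values(0, 5, 3, 2)$ppv, 0)
  expect_true(is.na(predictive_values(0, 0, 3, 2)$ppv))
  set.seed(42)
  tp <- 7; fp <- 13; fn <- 2; tn <- 40
  r <- predictive_values(tp, fp, fn, tn)
  expect_equal(r$ppv, tp / (tp + fp))
  expect_equal(r$npv, tn / (tn + fn))
})

test_that("regional accuracy counts TP/FP/FN/TN across datasets", {
  mk_all <- function(detected_regions) {
    regs <- c("Hippocampus", "cuneus", "precentral")
    d <- mk_det(regs, "left",
                L_r = ifelse(regs %in% detected_regions, 4, 0))
    d
  }
  dets <- list(D1 = mk_all("Hippocampus"), D2 = mk_all("cuneus"))
  gt <- rbind(mk_gt(expert = "Hippocampus:left", id = "D1"),
              mk_gt(expert = "Hippocampus:left", id = "D2"))
  acc <- regional_accuracy(dets, gt)
  hip <- acc[acc$region == "Hippocampus", ]
  expect_equal(c(hip$tp, hip$fp, hip$fn, hip$tn), c(1, 0, 1, 0))
  cun <- acc[acc$region == "cuneus", ]
  expect_equal(c(cun$tp, cun$fp, cun$fn, cun$tn), c(0, 1, 0, 1))
  expect_true(all(acc$tp + acc$fp + acc$fn + acc$tn == 2))
})

test_that("randomization test has the +1 convention and fixed-seed identity", {
  x <- c(rep(1, 10), rep(1, 10))
  g <- rep(c("a", "b"), each = 10)
  expect_equal(randomization_test(x, g, n_resamples = 200)$p_value, 1)
  # fully separated binary groups
  x2 <- c(rep(1, 20), rep(0, 20))
  g2 <- rep(c("a", "b"), each = 20)
  r <- randomization_test(x2, g2, n_resamples = 10000, seed = 7)
  expect_lte(r$p_value, 0.001)
  r2 <- randomization_test(x2, g2, n_resamples = 10000, seed = 7)
  expect_identical(r$p_value, r2$p_value)
  # null uniformity-ish: p never zero, at least 1/(N+1)
  expect_gte(r$p_value, 1 / 10001)
  expect_error(randomization_test(1:4, rep("a", 4)), ">= 2 groups")
})

test_that("exact and binomial tests match brute-force computations", {
  expect_equal(exact_test_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  # binomial upper tail vs direct summation
  set.seed(43)
  for (b in 1:20) {
    n <- sample(20:200, 1)
    p0 <- runif(1, 0.005, 0.2)
    k <- sample(0:n, 1)
    oracle <- sum(stats::dbinom(k:n, n, p0))
    expect_equal(binomial_rate_test(k, n, p0), oracle, tolerance = 1e-12)
  }
  # count at expectation sits near the distribution centre
  p_mid <- binomial_rate_test(10, 1000, 0.01)
  expect_gt(p_mid, 0.4)
  expect_lt(p_mid, 0.65)
  # extreme count: p ~ p0^n
  p_ext <- binomial_rate_test(100, 100, 0.01)
  expect_equal(log(p_ext), 100 * log(0.01), tolerance = 1e-6)
  expect_lt(p_ext, 1e-100)
})

test_that("sequential testing gates pairwise tests on the first level", {
  set.seed(44)
  x_same <- rnorm(60)
  g <- rep(c("a", "b", "c"), each = 20)
  r <- sequential_group_test(x_same, g)
  if (r$kw_p >= 0.05) expect_null(r$pairwise)
  # one clearly shifted group
  x_shift <- x_same + (g == "c") * 3
  r2 <- sequential_group_test(x_shift, g)
  expect_lt(r2$kw_p, 0.01)
  expect_equal(r2$kw_label, "significant")
  pw <- r2$pairwise
  expect_true(all(pw$label[pw$group_1 == "c" | pw$group_2 == "c"] ==
                    "significant"))
  expect_true(all(pw$p >= 0 & pw$p <= 1))
  # undersized groups are dropped with a warning; nothing left is an error
  expect_error(expect_warning(
    sequential_group_test(c(1, 2, 3, 1), c("a", "a", "a", "b")),
    "excluded"), ">= 2 groups")
})
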