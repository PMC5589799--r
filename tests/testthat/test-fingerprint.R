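test_that("signed log-p fingerprint values follow the sign convention", {
  expect_equal(signed_log_feature(0.01, 1), 2)     # positive residual
  expect_equal(signed_log_feature(0.001, -1), -3)  # negative residual
  expect_equal(signed_log_feature(1, 1), 0)
  expect_equal(signed_log_feature(1, -1), 0)
  expect_warning(l <- signed_log_feature(0, 1), "clipped")
  expect_equal(l, 16)
  expect_equal(signed_log_feature(c(0.1, 0.1), c(1, -1)), c(1, -1))
})

test_that("regional condensation matches the direct odds^2-weighted formula", {
  # single entry collapses to |L|
  expect_equal(condense_region(-3, 7), 3)
  # equal odds and weights: root-mean-square
  L <- c(1, 2, 3)
  expect_equal(condense_region(L, rep(5, 3)), sqrt(mean(L^2)))
  # a huge-odds null entry swamps a low-odds signal
  expect_equal(condense_region(c(4, 0), c(1, 100)),
               sqrt(16 * 1 / (1 + 100^2)), tolerance = 1e-12)
  expect_equal(condense_region(c(4, 0), c(1, 100)), 0.04, tolerance = 1e-3)
  # direct-formula oracle on random draws, with weights
  set.seed(20)
  for (b in 1:50) {
    k <- sample(2:18, 1)
    L <- rnorm(k, sd = 2)
    o <- runif(k, 0.5, 200)
    w <- sample(c(1, 0.5), k, replace = TRUE)
    direct <- sqrt(sum(w * L^2 * o^2) / sum(w * o^2))
    expect_equal(condense_region(L, o, w), direct, tolerance = 1e-12)
    # weighted-RMS bound
    expect_gte(condense_region(L, o, w), min(abs(L)) - 1e-12)
    expect_lte(condense_region(L, o, w), max(abs(L)) + 1e-12)
  }
  expect_true(is.na(condense_region(numeric(0), numeric(0))))
  expect_error(condense_region(1, 0), "positive")
})

test_that("down-weighting a contributor's odds removes its influence", {
  L <- c(5, 1)
  without <- condense_region(L[2], 10)
  eps_path <- sapply(c(1, 0.1, 0.01, 0.001), function(o1) {
    condense_region(L, c(o1, 10))
  })
  expect_true(all(diff(abs(eps_path - without)) < 0))
  expect_equal(eps_path[4], without, tolerance = 1e-3)
})

test_that("detections pool hemisphere and asymmetry entries as specified", {
  m <- mn_model()
  # all p = 1 -> no detections
  flat <- mn_flat_profile(m)
  expect_equal(nrow(detect_regions(flat, m)), 0)

  # one cortical region with all 9 left parameters at p = 0.01 (positive):
  # oracle = brute-force pool of 9 x L=2 (weight 1) + 9 x L=0 asym (weight .5)
  reg <- "superiortemporal"
  feats <- feature_id(reg, surface_parameters(), "left")
  prof <- mn_flat_profile(m, data.frame(feature = feats, p = 0.01, sign = 1))
  det <- detect_regions(prof, m, all = TRUE)
  row <- det[det$region == reg & det$hemisphere == "left", ]
  o_meas <- m$blocks$normalized$odds[match(feats,
                                           m$blocks$normalized$features)]
  a_feats <- feature_id(reg, surface_parameters(), "asymmetry")
  o_asym <- m$blocks$asymmetry$odds[match(a_feats,
                                          m$blocks$asymmetry$features)]
  oracle <- sqrt(sum(1 * 4 * o_meas^2) /
                   (sum(o_meas^2) + sum(0.5 * o_asym^2)))
  expect_equal(row$L_r, oracle, tolerance = 1e-12)
  expect_false(row$detected)   # diluted below 2 by the null asymmetry pool

  # scores table is sorted by L_r descending
  expect_true(all(diff(det$L_r) <= 1e-12))
})

test_that("volume regions use the volume + half-asymmetry pool", {
  m <- mn_model()
  f_v <- "Hippocampus|volume|left"
  f_a <- "Hippocampus|volume|asymmetry"
  prof <- mn_flat_profile(m, data.frame(feature = c(f_v, f_a),
                                        p = c(1e-4, 1e-3), sign = 1))
  det <- detect_regions(prof, m)
  expect_equal(det$region[1], "Hippocampus")
  expect_equal(det$hemisphere[1], "left")
  o_v <- m$blocks$normalized$odds[match(f_v, m$blocks$normalized$features)]
  o_a <- m$blocks$asymmetry$odds[match(f_a, m$blocks$asymmetry$features)]
  oracle <- sqrt((16 * o_v^2 + 0.5 * 9 * o_a^2) / (o_v^2 + 0.5 * o_a^2))
  expect_equal(det$L_r[1], oracle, tolerance = 1e-12)
  expect_true(det$detected[1])
})

test_that("top-k keeps the most prominent detections with stable ties", {
  sc <- structure(
    data.frame(region = c("b", "a", "c", "d"),
               hemisphere = c("left", "left", "right", "left"),
               lobe = "temporal", L_r = c(5, 3, 3, 1.5),
               n_contributing = 9,
               detected = c(TRUE, TRUE, TRUE, FALSE)),
    class = c("region_scores", "data.frame"), threshold = 2)
  expect_equal(nrow(top_k(sc, 3)), 3)
  expect_equal(top_k(sc, 3)$region, c("b", "a", "c"))
  expect_equal(nrow(top_k(sc[FALSE, ], 3)), 0)
  # two detections, k = 3 -> both
  expect_equal(nrow(top_k(sc[1:2, ], 3)), 2)

  # rank ties in detect_regions break lexicographically by region label
  m <- mn_model()
  regs <- c("cuneus", "lingual")
  set <- do.call(rbind, lapply(regs, function(r) {
    data.frame(feature = feature_id(r, surface_parameters(), "left"),
               p = 1e-6, sign = 1)
  }))
  prof <- mn_flat_profile(m, set)
  det <- detect_regions(prof, m, all = TRUE)
  near <- det[det$region %in% regs & det$hemisphere == "left", ]
  if (abs(diff(near$L_r)) < 1e-9) {
    expect_equal(near$region, sort(near$region))
  }
})

test_that("fingerprint vectors extract the full family in schema order", {
  m <- mn_model()
  prof <- score_scan(m, mn_null_scan())
  v <- feature_vector(prof)
  expect_equal(length(v), 2976)
  expect_identical(names(v), m$schema$feature)
  expect_equal(unname(v["Hippocampus|volume|left"]),
               prof$L[prof$feature == "Hippocampus|volume|left" &
                        prof$variant == "normalized"])
})

test_that("an injected mesiotemporal lesion dominates the detections", {
  m <- mn_model()
  pat <- generate_patients(mn_world(), "MTLE-HS-left", n_patients = 15,
                           seed = 202)
  hits <- 0
  for (i in 1:15) {
    prof <- score_scan(m, pat$cohort[i, , drop = FALSE])
    t3 <- top_k(detect_regions(prof, m), 3)
    if (any(t3$region == "Hippocampus" & t3$hemisphere == "left")) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 11)
})
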