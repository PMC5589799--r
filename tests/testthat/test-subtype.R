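test_that("correlation matrices behave like Pearson correlation", {
  v <- rnorm(100)
  C <- correlation_matrix(rbind(v, v))
  expect_equal(C[1, 2], 1)
  C <- correlation_matrix(rbind(v, -v))
  expect_equal(C[1, 2], -1)
  set.seed(30)
  L <- matrix(rnorm(10 * 2976), 10)
  C <- correlation_matrix(L)
  expect_equal(diag(C), rep(1, 10))
  expect_equal(C, t(C))
  expect_lt(max(abs(C[upper.tri(C)])), 0.15)  # ~N(0, 1/sqrt(2976))
  expect_warning(Cz <- correlation_matrix(rbind(rep(1, 5), rnorm(5))),
                 "zero-variance")
  expect_true(is.na(Cz[1, 2]))
})

test_that("median comparison separates shifted element sets", {
  same <- rnorm(100)
  r <- group_median_compare(same, same)
  expect_gt(r$p_value, 0.99)
  expect_equal(r$median_within, r$median_between)
  set.seed(31)
  r2 <- group_median_compare(rnorm(50, 1), rnorm(50, 0))
  expect_lt(r2$p_value, 0.01)
  expect_gt(r2$median_within, r2$median_between)
  expect_length(r2$ci_within, 2)
  expect_true(r2$ci_within[1] <= r2$median_within &&
                r2$median_within <= r2$ci_within[2])
})

test_that("correlation splitting pairs by label", {
  C <- matrix(c(1, .9, .1,
                .9, 1, .2,
                .1, .2, 1), 3, byrow = TRUE)
  sp <- split_correlations(C, c("p1", "p1", "p2"))
  expect_equal(sp$within, 0.9)
  expect_equal(sort(sp$between), c(0.1, 0.2))
})

test_that("reproducible-feature selection applies Tukey fences to t = mean/sd", {
  set.seed(32)
  L <- matrix(rnorm(40 * 2976), 40, dimnames = list(NULL, paste0("f", 1:2976)))
  sel <- select_reproducible(L)
  frac <- length(sel$selected) / 2976
  # expected fence-exceedance rate for a near-normal t population (~0.7%)
  expect_gt(frac, 0.0005)
  expect_lt(frac, 0.025)
  # one feature with a huge mean in SD units is always flagged
  L[, 7] <- rnorm(40, mean = 5, sd = 0.1)
  sel <- select_reproducible(L)
  expect_true("f7" %in% sel$selected)
  # negating the data negates t and preserves the flagged set
  sel_neg <- select_reproducible(-L)
  expect_setequal(sel$selected, sel_neg$selected)
  expect_equal(sel$t, -sel_neg$t)
  # degenerate sd = 0 features get capped t and are reported
  L[, 9] <- 2
  sel <- select_reproducible(L)
  expect_true("f9" %in% sel$degenerate)
  expect_true("f9" %in% sel$selected)
  expect_error(select_reproducible(L[1:2, ]), ">= 3")
})

test_that("unique-feature selection requires difference from every subtype", {
  set.seed(33)
  mk <- function(n, shift = 0, cols = 50) {
    matrix(rnorm(n * cols), n, dimnames = list(NULL, paste0("f", 1:cols))) +
      matrix(shift, n, cols, byrow = TRUE)
  }
  shift_a <- c(5, rep(0, 49))         # f1 shifted in A only
  shift_b <- c(5, 5, rep(0, 48))      # f1 and f2 shifted in B
  Ls <- list(A = mk(10, shift_a), B = mk(10, shift_b), C = mk(10))
  sel <- select_unique(Ls, "A")
  # f1 is equal between A and B -> not unique for A; f2 differs from both
  expect_false("f1" %in% sel$selected)
  selB <- select_unique(Ls, "B")
  expect_true("f2" %in% selB$selected)
  expect_false("f1" %in% selB$selected)
  # identical distributions: almost nothing selected
  L0 <- list(A = mk(10), B = mk(10), C = mk(10))
  expect_lte(length(select_unique(L0, "A")$selected), 2)
  # pooled mode and wilcoxon variant run
  expect_true("f2" %in% select_unique(Ls, "B", pooled = TRUE)$selected)
  expect_true("f2" %in% select_unique(Ls, "B", method = "wilcoxon",
                                      alpha = 0.05)$selected)
  # a subtype with < 2 datasets is excluded with a warning
  Ls$D <- mk(1)
  expect_warning(select_unique(Ls, "A"), "excluded")
})

test_that("feature importances are normalized mean |L| weights", {
  L <- matrix(c(1, 3, 2, 2, -2, 0), 2,
              dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(feature_importance(L, "a")), 1)
  w <- feature_importance(L, c("a", "b"))
  expect_equal(sum(w), 1)
  expect_equal(unname(w), c(2, 2) / 4)
  w3 <- feature_importance(L, c("a", "b", "c"))
  expect_equal(sum(w3), 1, tolerance = 1e-12)
})

test_that("subtype selection intersects both criteria and weights them", {
  set.seed(34)
  cols <- 200
  mk <- function(shift) {
    matrix(rnorm(12 * cols, sd = 1), 12,
           dimnames = list(NULL, paste0("f", 1:cols))) +
      matrix(rep(shift, each = 12), 12)
  }
  shift <- rep(0, cols)
  shift[5] <- 6            # reproducible and unique for A
  Ls <- list(A = mk(shift), B = mk(rep(0, cols)), C = mk(rep(0, cols)))
  sel <- select_subtype_features(Ls, "A")
  expect_true("f5" %in% sel$selected)
  expect_true(all(sel$selected %in% sel$reproducible))
  expect_true(all(sel$selected %in% sel$unique))
  expect_equal(sum(sel$importance), 1, tolerance = 1e-12)
  expect_output(print(sel), "selected")
})
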