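# Reproducibility analysis of fingerprint vectors and heuristic selection of
# subtype-representative features (reproducible within subtype AND unique to
# it).

#' Pearson correlation matrix of fingerprint vectors
#'
#' @param L Matrix `datasets x features` of fingerprint values (rows are
#'   vectors to correlate).
#' @return Symmetric correlation matrix with unit diagonal; entries involving
#'   a zero-variance vector are `NA` (with a warning).
#' @export
correlation_matrix <- function(L) {
  L <- as.matrix(L)
  if (nrow(L) < 2) stop("need at least two vectors")
  v <- apply(L, 1, stats::var)
  if (any(v == 0, na.rm = TRUE)) {
    warning("zero-variance fingerprint vector(s); correlations set to NA")
  }
  suppressWarnings(C <- stats::cor(t(L)))
  diag(C) <- 1
  C
}

#' Compare within- vs. between-group correlation elements
#'
#' Medians, 2.5-97.5 element-percentile intervals and the two-sided
#' Mann-Whitney-Wilcoxon p-value for two sets of correlation-matrix elements
#' (e.g. within-patient vs. between-patient).
#'
#' @param within,between Numeric vectors of matrix elements.
#' @return List with `median_within`, `median_between`, `ci_within`,
#'   `ci_between` (percentile ranges) and `p_value`.
#' @export
group_median_compare <- function(within, between) {
  stopifnot(length(within) > 0, length(between) > 0)
  p <- suppressWarnings(
    stats::wilcox.test(within, between, exact = FALSE)$p.value)
  list(
    median_within = stats::median(within, na.rm = TRUE),
    median_between = stats::median(between, na.rm = TRUE),
    ci_within = stats::quantile(within, c(0.025, 0.975), na.rm = TRUE,
                                names = FALSE),
    ci_between = stats::quantile(between, c(0.025, 0.975), na.rm = TRUE,
                                 names = FALSE),
    p_value = p
  )
}

# off-diagonal elements of C grouped by a pairing predicate on labels
#' Split correlation-matrix elements by a pairing label
#'
#' Convenience for reproducibility analyses: returns the upper-triangle
#' elements of `C` split into pairs whose `labels` agree and pairs whose
#' labels differ.
#'
#' @param C Correlation matrix.
#' @param labels One label per row (e.g. patient id, or subtype).
#' @return List with `within` and `between` element vectors.
#' @export
split_correlations <- function(C, labels) {
  stopifnot(nrow(C) == length(labels))
  ut <- upper.tri(C)
  same <- outer(labels, labels, "==")
  list(within = C[ut & same], between = C[ut & !same])
}

#' Reproducible features of one subtype (Tukey-fence rule)
#'
#' For every feature computes `t_f = mean_f / sd_f` over the subtype's
#' fingerprint vectors (a signal-to-noise score of the subtype-wise mean in SD
#' units) and flags features whose `t_f` lies outside the Tukey fences of the
#' pooled `t` distribution over all features: above `Q3 + 1.5 IQR` or below
#' `Q1 - 1.5 IQR`.
#'
#' @param L Matrix `datasets x features` of one subtype's fingerprints (>= 3
#'   rows).
#' @param cap Surrogate magnitude assigned when `sd_f = 0` (flagged as
#'   degenerate).
#' @return List with `selected` (feature names), `t` (named scores), `fences`
#'   (lower/upper) and `degenerate` (features with zero SD).
#' @export
select_reproducible <- function(L, cap = 1e6) {
  L <- as.matrix(L)
  if (nrow(L) < 3) stop("need >= 3 datasets in the subtype")
  m <- colMeans(L)
  s <- apply(L, 2, stats::sd)
  degen <- s == 0
  t_f <- m / s
  t_f[degen] <- sign(m[degen]) * cap
  qs <- stats::quantile(t_f, c(0.25, 0.75), names = FALSE)
  iqr <- qs[2] - qs[1]
  fences <- c(lower = qs[1] - 1.5 * iqr, upper = qs[2] + 1.5 * iqr)
  sel <- t_f > fences["upper"] | t_f < fences["lower"]
  list(selected = colnames(L)[sel], t = t_f, fences = fences,
       degenerate = colnames(L)[degen])
}

#' Unique features of one subtype
#'
#' Features whose mean in the subtype of interest differs from *each* other
#' subtype (pairwise two-sided Welch t-tests, all `p < alpha`; a pooled
#' comparison against all other subtypes merged, or Mann-Whitney-Wilcoxon
#' tests, are available as options).
#'
#' @param L_by_subtype Named list of fingerprint matrices (`datasets x
#'   features`), one per subtype.
#' @param subtype Name of the subtype of interest.
#' @param alpha Significance level (default 0.01).
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @param pooled Compare against all other subtypes pooled into one group
#'   instead of pairwise.
#' @return List with `selected` (feature names) and `p` (features x
#'   comparisons matrix of p-values).
#' @export
select_unique <- function(L_by_subtype, subtype, alpha = 0.01,
                          method = c("welch", "wilcoxon"), pooled = FALSE) {
  method <- match.arg(method)
  stopifnot(subtype %in% names(L_by_subtype), length(L_by_subtype) >= 2)
  ns <- vapply(L_by_subtype, nrow, 0L)
  small <- names(ns)[ns < 2]
  if (length(small)) {
    warning("subtype(s) with < 2 datasets excluded: ",
            paste(small, collapse = ", "))
    L_by_subtype <- L_by_subtype[ns >= 2]
    if (!subtype %in% names(L_by_subtype)) {
      stop("subtype of interest has < 2 datasets")
    }
  }
  A <- as.matrix(L_by_subtype[[subtype]])
  others <- setdiff(names(L_by_subtype), subtype)
  if (pooled) {
    comparisons <- list(pooled = do.call(rbind, L_by_subtype[others]))
  } else {
    comparisons <- lapply(L_by_subtype[others], as.matrix)
  }
  pmat <- sapply(comparisons, function(B) {
    if (method == "welch") {
      .welch_p(A, B)
    } else {
      vapply(seq_len(ncol(A)), function(j) {
        suppressWarnings(stats::wilcox.test(A[, j], B[, j],
                                            exact = FALSE)$p.value)
      }, 0)
    }
  })
  pmat <- matrix(pmat, ncol = length(comparisons),
                 dimnames = list(colnames(A), names(comparisons)))
  sel <- rowSums(pmat < alpha, na.rm = TRUE) == ncol(pmat) &
    rowSums(is.na(pmat)) == 0
  list(selected = colnames(A)[sel], p = pmat)
}

# vectorized two-sided Welch t-test p-values per column
.welch_p <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- apply(A, 2, stats::var); v2 <- apply(B, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate: both groups constant
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  p
}

#' Relative feature importances
#'
#' Importance of a selected feature is the mean |L| over the subtype's
#' datasets, normalized so the importances of all selected features add up to
#' one.
#'
#' @param L Fingerprint matrix `datasets x features` of the subtype.
#' @param selected Feature names to weight.
#' @return Named numeric vector summing to 1.
#' @export
feature_importance <- function(L, selected) {
  stopifnot(length(selected) > 0)
  w <- colMeans(abs(as.matrix(L)[, selected, drop = FALSE]))
  w / sum(w)
}

#' Heuristic selection of subtype-representative features
#'
#' Intersects the reproducible set ([select_reproducible()]) with the unique
#' set ([select_unique()]) and attaches normalized importances.
#'
#' @inheritParams select_unique
#' @param ... Passed on to [select_unique()].
#' @return List of class `subtype_selection`: `subtype`, `reproducible`,
#'   `unique`, `selected` (intersection), `importance`.
#' @export
select_subtype_features <- function(L_by_subtype, subtype, alpha = 0.01,
                                    ...) {
  rep_set <- select_reproducible(L_by_subtype[[subtype]])
  unq <- select_unique(L_by_subtype, subtype, alpha = alpha, ...)
  sel <- intersect(rep_set$selected, unq$selected)
  imp <- if (length(sel)) {
    feature_importance(L_by_subtype[[subtype]], sel)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(list(subtype = subtype, reproducible = rep_set$selected,
                 unique = unq$selected, selected = sel, importance = imp,
                 t = rep_set$t, fences = rep_set$fences),
            class = "subtype_selection")
}

#' @export
print.subtype_selection <- function(x, ...) {
  cat("Subtype-representative features for", x$subtype, "\n")
  cat("  reproducible:", length(x$reproducible),
      " unique:", length(x$unique),
      " selected (intersection):", length(x$selected), "\n")
  if (length(x$selected)) {
    top <- utils::head(sort(x$importance, decreasing = TRUE), 5)
    cat("  top importances:\n")
    for (f in names(top)) cat(sprintf("    %-45s %.3f\n", f, top[f]))
  }
  invisible(x)
}
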