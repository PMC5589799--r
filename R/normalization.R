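# Head-size (eTIV) normalization, scanner contrast matching and asymmetry indices.

#' Isometric eTIV scaling exponents per surface parameter
#'
#' Head-size correction rescales each measure by `(reference_etiv / etiv)^n`
#' with the exponent fixed by dimensional analysis of an isometric scaling:
#' `n = 1` for volumes, `2/3` for areas, `1/3` for thicknesses, `-1/3` for mean
#' curvature (units 1/length), `-2/3` for Gaussian curvature (1/length^2) and
#' `0` for the dimensionless curvature and folding indices. Grey-white percent
#' contrast (`pctmean`) is `NA` here: it is sequence-dependent and handled by
#' scanner-wise mean matching ([contrast_normalize()]), not by eTIV.
#'
#' @return Named numeric vector over `c("volume", surface_parameters())`.
#' @export
etiv_exponents <- function() {
  c(volume = 1, grayvol = 1, surfarea = 2 / 3, thickavg = 1 / 3,
    thickstd = 1 / 3, meancurv = -1 / 3, gauscurv = -2 / 3,
    curvind = 0, foldind = 0, pctmean = NA_real_)
}

#' Normalize a measure to a reference head size
#'
#' Returns `value * (reference_etiv / etiv)^n`. Multiplying by the ratio (rather
#' than dividing by `etiv^n`) keeps physical units, so normalized values remain
#' directly comparable to raw ones in reports.
#'
#' @param value Numeric vector of raw measures.
#' @param etiv Estimated total intracranial volume of the scan (ml), > 0.
#' @param n Scaling exponent (see [etiv_exponents()]).
#' @param reference_etiv Reference head size (ml), > 0; conventionally the
#'   geometric mean eTIV of the normative cohort.
#' @return Normalized values, same units as `value`.
#' @export
normalize_to_etiv <- function(value, etiv, n, reference_etiv) {
  if (any(!is.finite(etiv)) || any(etiv <= 0)) {
    stop("'etiv' must be positive and finite")
  }
  if (any(!is.finite(reference_etiv)) || any(reference_etiv <= 0)) {
    stop("'reference_etiv' must be positive and finite")
  }
  value * (reference_etiv / etiv)^n
}

#' Hemispheric asymmetry index
#'
#' `AI = (right - left) / (right + left)`, in `[-1, +1]`: `-1` for extremely
#' left-dominated structures, `+1` for extremely right-dominated ones, `0` under
#' complete morphological symmetry. Antisymmetric under swapping the
#' hemispheres. Undefined (NA) when both sides are zero.
#'
#' @param left,right Non-negative measures of the left/right homologue.
#' @return Numeric vector of asymmetry indices.
#' @export
asymmetry_index <- function(left, right) {
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE)) {
    stop("asymmetry_index() expects non-negative inputs")
  }
  s <- left + right
  out <- (right - left) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

#' Scanner-sequence mean matching for grey-white contrast
#'
#' Percent contrast depends mainly on the MR sequence, so instead of eTIV
#' scaling it is regionally rescaled so that every scanner-sequence group has
#' the same mean as the grand regional mean. Reference means are learned from
#' the normative cohort and re-applied to patient scans.
#'
#' @param values Numeric vector of contrast values for one feature.
#' @param groups Scanner-sequence label per value.
#' @param reference Optional reference as returned in the `reference` element:
#'   a list with `group_means` (named) and `grand_mean`, learned from a
#'   normative cohort. When `NULL`, both are estimated from `values` itself.
#' @return List with `values` (adjusted, `v * grand_mean / group_mean`) and
#'   `reference`.
#' @export
contrast_normalize <- function(values, groups, reference = NULL) {
  groups <- as.character(groups)
  if (is.null(reference)) {
    gm <- tapply(values, groups, mean, na.rm = TRUE)
    reference <- list(group_means = stats::setNames(as.numeric(gm),
                                                    names(gm)),
                      grand_mean = mean(values, na.rm = TRUE))
  }
  unseen <- setdiff(unique(groups), names(reference$group_means))
  if (length(unseen)) {
    stop("unseen scanner_sequence group(s) at scoring time: ",
         paste(unseen, collapse = ", "),
         "; re-fit the reference or map the scan to the closest known group")
  }
  adj <- values * reference$grand_mean /
    as.numeric(reference$group_means[groups])
  list(values = adj, reference = reference)
}

# ---- cohort-level derivations -------------------------------------------------

# split a cohort data.frame into metadata and the measured-feature matrix
cohort_matrix <- function(cohort, schema) {
  mf <- measured_features(schema)
  missing <- setdiff(mf, names(cohort))
  if (length(missing)) {
    stop("cohort is missing ", length(missing),
         " schema feature column(s), e.g. ", missing[1])
  }
  X <- as.matrix(cohort[, mf, drop = FALSE])
  storage.mode(X) <- "double"
  meta_cols <- setdiff(names(cohort), mf)
  list(meta = cohort[, meta_cols, drop = FALSE], X = X)
}

# eTIV + contrast normalization of a measured-feature matrix.
# contrast_refs: named list per pctmean feature (NULL -> learn from data).
normalize_matrix <- function(X, etiv, scanner, schema, reference_etiv,
                             contrast_refs = NULL) {
  mf_schema <- schema[schema$measured, , drop = FALSE]
  stopifnot(identical(colnames(X), mf_schema$feature))
  expo <- etiv_exponents()
  n_by_col <- ifelse(mf_schema$kind == "volume", expo[["volume"]],
                     expo[mf_schema$parameter])
  Xn <- X
  scale_cols <- which(!is.na(n_by_col))
  # outer product: scan-wise ratio^n, column-wise exponent
  ratio <- reference_etiv / etiv
  for (j in scale_cols) {
    if (n_by_col[j] != 0) Xn[, j] <- X[, j] * ratio^n_by_col[j]
  }
  pct_cols <- which(mf_schema$parameter == "pctmean")
  learned <- vector("list", length(pct_cols))
  names(learned) <- mf_schema$feature[pct_cols]
  for (j in seq_along(pct_cols)) {
    cn <- mf_schema$feature[pct_cols[j]]
    ref <- if (is.null(contrast_refs)) NULL else contrast_refs[[cn]]
    res <- contrast_normalize(X[, pct_cols[j]], scanner, ref)
    Xn[, pct_cols[j]] <- res$values
    learned[[cn]] <- res$reference
  }
  list(X = Xn, contrast_refs = learned)
}

# asymmetry-index matrix from the raw measured matrix
asymmetry_matrix <- function(X, schema) {
  am <- asymmetry_map(schema)
  A <- asymmetry_index(X[, am$left, drop = FALSE], X[, am$right, drop = FALSE])
  colnames(A) <- am$feature
  A
}

# complete 2,976-long variant matrix in schema order
full_variant <- function(X_measured, A, schema) {
  V <- cbind(X_measured, A)[, schema$feature, drop = FALSE]
  V
}
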