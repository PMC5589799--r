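# Abnormality fingerprints: signed decadic log-p feature vectors and their
# odds^2-weighted condensation into one detection score per brain region.

#' Signed decadic log-p fingerprint value
#'
#' `L = -log10(p)` when the fit residual is positive (observation larger than
#' expected), `L = +log10(p)` when it is negative, and `0` at `p = 1`. Thus
#' positive L means a positive deviation and |L| grows with significance.
#' p-values of 0 (or below `p_min`) are clipped to `p_min` with a warning.
#'
#' @param p Two-sided abnormality p-values in (0, 1].
#' @param sign Sign of the fit residual (-1, 0, +1).
#' @param p_min Floor applied before taking the log (default 1e-16).
#' @return Numeric vector of signed log-p values.
#' @export
signed_log_feature <- function(p, sign, p_min = 1e-16) {
  if (any(p < p_min, na.rm = TRUE)) {
    warning("p-values below ", p_min, " clipped")
  }
  p <- pmax(p, p_min)
  ifelse(sign >= 0, -log10(p), log10(p))
}

#' Odds-weighted regional condensation of fingerprint values
#'
#' Pools the per-parameter fingerprint magnitudes of one region into a single
#' non-negative score, weighting by the squared validity odds so that
#' potentially artifactual measurements lose influence:
#' `L_r = sqrt( sum(w * L^2 * odds^2) / sum(w * odds^2) )`.
#' Asymmetry entries conventionally enter with weight 1/2 in each hemisphere's
#' pool.
#'
#' @param L Fingerprint values of the contributing features.
#' @param odds Validity odds (> 0) of the contributing features.
#' @param weights Pooling weights (default 1; use 0.5 for asymmetry entries).
#' @return The regional score `L_r >= 0` (`NA` for empty input).
#' @export
condense_region <- function(L, odds, weights = 1) {
  ok <- is.finite(L) & is.finite(odds)
  L <- L[ok]
  odds <- rep_len(odds, length(ok))[ok]
  weights <- rep_len(weights, length(ok))[ok]
  if (!length(L)) return(NA_real_)
  if (any(odds <= 0)) stop("odds must be positive")
  sqrt(sum(weights * L^2 * odds^2) / sum(weights * odds^2))
}

#' Extract the 2,976-long fingerprint vector of a profile
#'
#' @param profile An `abnormality_profile` from [score_scan()].
#' @param variant `"normalized"` (default) or `"raw"`.
#' @return Named numeric vector of signed log-p values in schema order.
#' @export
feature_vector <- function(profile, variant = "normalized") {
  pv <- profile[profile$variant == variant, ]
  stats::setNames(pv$L, pv$feature)
}

# per-region contributor table: features, odds and weights for each
# (region, hemisphere) pool and each global region
.region_pools <- function(model, variant = "normalized") {
  sch <- model$schema
  odds_measured <- stats::setNames(model$blocks[[variant]]$odds,
                                   model$blocks[[variant]]$features)
  odds_asym <- stats::setNames(model$blocks$asymmetry$odds,
                               model$blocks$asymmetry$features)
  odds <- c(odds_measured, odds_asym)

  pools <- list()
  bilat <- unique(sch$region[sch$side == "asymmetry"])
  for (reg in bilat) {
    rs <- sch[sch$region == reg, , drop = FALSE]
    for (h in c("left", "right")) {
      f_h <- rs$feature[rs$side == h]
      f_a <- rs$feature[rs$side == "asymmetry"]
      pools[[paste(reg, h, sep = "|")]] <- list(
        region = reg, hemisphere = h,
        features = c(f_h, f_a),
        weights = c(rep(1, length(f_h)), rep(0.5, length(f_a))),
        odds = unname(odds[c(f_h, f_a)])
      )
    }
  }
  for (reg in sch$region[sch$side == "global"]) {
    f <- sch$feature[sch$region == reg]
    pools[[paste(reg, "global", sep = "|")]] <- list(
      region = reg, hemisphere = NA_character_, features = f,
      weights = rep(1, length(f)), odds = unname(odds[f])
    )
  }
  pools
}

#' Regional detection scores of a scored scan
#'
#' Condenses the fingerprint of each brain region and hemisphere with
#' [condense_region()]: cortical parcellations pool their 9 hemisphere
#' parameters (weight 1) plus the 9 asymmetry parameters (weight 1/2);
#' bilateral volume segmentations pool volume (weight 1) plus asymmetry
#' (weight 1/2); global volumes stand alone. Regions reaching
#' `L_r >= threshold` count as detections.
#'
#' @param profile An `abnormality_profile`.
#' @param model The `normative_model` that produced it (source of the validity
#'   odds).
#' @param threshold Detection threshold on `L_r` (default 2).
#' @param variant Which p-value variant feeds the scores (default
#'   `"normalized"`).
#' @param all Return all regional scores (`TRUE`) or only detections
#'   (default).
#' @return data.frame of class `region_scores` with columns `region`,
#'   `hemisphere`, `lobe`, `L_r`, `n_contributing`, `detected`, sorted by
#'   decreasing `L_r` (ties broken lexicographically by region label, then
#'   hemisphere).
#' @export
detect_regions <- function(profile, model, threshold = 2,
                           variant = "normalized", all = FALSE) {
  pools <- .region_pools(model, variant)
  Lv <- feature_vector(profile, variant)
  lobes <- region_lobe_table()
  lobe_of <- stats::setNames(lobes$lobe, lobes$region)
  rows <- lapply(pools, function(p) {
    L <- unname(Lv[p$features])
    data.frame(region = p$region, hemisphere = p$hemisphere,
               lobe = unname(lobe_of[p$region]),
               L_r = condense_region(L, p$odds, p$weights),
               n_contributing = sum(is.finite(L)),
               stringsAsFactors = FALSE)
  })
  sc <- do.call(rbind, rows)
  sc <- sc[order(-sc$L_r, sc$region, sc$hemisphere), , drop = FALSE]
  sc$detected <- !is.na(sc$L_r) & sc$L_r >= threshold
  if (!all) sc <- sc[sc$detected, , drop = FALSE]
  rownames(sc) <- NULL
  structure(sc, dataset_id = attr(profile, "dataset_id"),
            threshold = threshold, variant = variant,
            class = c("region_scores", "data.frame"))
}

#' @export
print.region_scores <- function(x, n = 10, ...) {
  cat("Regional detection scores for dataset", attr(x, "dataset_id"),
      "(threshold L_r >=", attr(x, "threshold"), ")\n")
  cat(" ", sum(x$detected), "detection(s)\n")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 3)
  invisible(x)
}

#' The k most prominent detections
#'
#' @param scores A `region_scores` table (already sorted by `L_r`).
#' @param k How many to keep (default 3, the convention used for
#'   specificity).
#' @return The first `min(k, nrow)` detected rows.
#' @export
top_k <- function(scores, k = 3) {
  det <- scores[scores$detected, , drop = FALSE]
  utils::head(det, k)
}
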