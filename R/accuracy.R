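# Agreement of automated detections with ground truth (expert MRI reading,
# resection site, EEG lateralization): per-dataset match indicators, aggregate
# sensitivity/specificity, regional DOR/PPV/NPV, and the statistical tests
# used alongside them.

#' Static parcellation-to-lobe lookup
#'
#' Fixed lobar assignment of every schema region (Desikan-Killiany, Destrieux
#' and volume segmentations). Regions on lobar boundaries follow a documented
#' convention (e.g. paracentral with frontal, parieto-occipital sulcus with
#' occipital); hippocampus and amygdala count as temporal, remaining
#' segmentations as subcortical, whole-brain partial volumes as global.
#'
#' @return data.frame with columns `region`, `lobe`.
#' @export
region_lobe_table <- function() {
  dk <- list(
    frontal = c("caudalmiddlefrontal", "frontalpole", "lateralorbitofrontal",
                "medialorbitofrontal", "paracentral", "parsopercularis",
                "parsorbitalis", "parstriangularis", "precentral",
                "rostralmiddlefrontal", "superiorfrontal"),
    temporal = c("bankssts", "entorhinal", "fusiform", "inferiortemporal",
                 "middletemporal", "parahippocampal", "superiortemporal",
                 "temporalpole", "transversetemporal"),
    parietal = c("inferiorparietal", "postcentral", "precuneus",
                 "superiorparietal", "supramarginal"),
    occipital = c("cuneus", "lateraloccipital", "lingual", "pericalcarine"),
    cingulate = c("caudalanteriorcingulate", "isthmuscingulate",
                  "posteriorcingulate", "rostralanteriorcingulate"),
    insula = "insula"
  )
  dx <- list(
    frontal = c("G_and_S_frontomargin", "G_and_S_paracentral",
                "G_and_S_transv_frontopol", "G_front_inf-Opercular",
                "G_front_inf-Orbital", "G_front_inf-Triangul",
                "G_front_middle", "G_front_sup", "G_orbital", "G_precentral",
                "G_rectus", "Lat_Fis-ant-Horizont", "Lat_Fis-ant-Vertical",
                "S_central", "S_front_inf", "S_front_middle", "S_front_sup",
                "S_orbital_lateral", "S_orbital_med-olfact",
                "S_orbital-H_Shaped", "S_precentral-inf-part",
                "S_precentral-sup-part", "S_suborbital"),
    temporal = c("G_oc-temp_lat-fusifor", "G_oc-temp_med-Parahip",
                 "G_temp_sup-G_T_transv", "G_temp_sup-Lateral",
                 "G_temp_sup-Plan_polar", "G_temp_sup-Plan_tempo",
                 "G_temporal_inf", "G_temporal_middle", "Pole_temporal",
                 "S_collat_transv_ant", "S_oc-temp_lat",
                 "S_oc-temp_med_and_Lingual", "S_temporal_inf",
                 "S_temporal_sup", "S_temporal_transverse", "Lat_Fis-post"),
    parietal = c("G_and_S_subcentral", "G_pariet_inf-Angular",
                 "G_pariet_inf-Supramar", "G_parietal_sup", "G_postcentral",
                 "G_precuneus", "S_interm_prim-Jensen",
                 "S_intrapariet_and_P_trans", "S_postcentral",
                 "S_subparietal"),
    occipital = c("G_and_S_occipital_inf", "G_cuneus", "G_occipital_middle",
                  "G_occipital_sup", "G_oc-temp_med-Lingual",
                  "Pole_occipital", "S_calcarine", "S_collat_transv_post",
                  "S_oc_middle_and_Lunatus", "S_oc_sup_and_transversal",
                  "S_occipital_ant", "S_parieto_occipital"),
    cingulate = c("G_and_S_cingul-Ant", "G_and_S_cingul-Mid-Ant",
                  "G_and_S_cingul-Mid-Post", "G_cingul-Post-dorsal",
                  "G_cingul-Post-ventral", "G_subcallosal", "S_pericallosal",
                  "S_cingul-Marginalis"),
    insula = c("G_Ins_lg_and_S_cent_ins", "G_insular_short",
               "S_circular_insula_ant", "S_circular_insula_inf",
               "S_circular_insula_sup")
  )
  cortex <- do.call(rbind, lapply(names(dk), function(l) {
    data.frame(region = c(dk[[l]], dx[[l]]), lobe = l,
               stringsAsFactors = FALSE)
  }))
  vols <- data.frame(region = volume_bilateral_regions(),
                     lobe = "subcortical", stringsAsFactors = FALSE)
  vols$lobe[vols$region %in% c("Hippocampus", "Amygdala")] <- "temporal"
  glob <- data.frame(region = volume_global_regions(), lobe = "global",
                     stringsAsFactors = FALSE)
  out <- rbind(cortex, vols, glob)
  stopifnot(!anyDuplicated(out$region),
            setequal(out$region, unique(mn_schema()$region)))
  out
}

# parse "region:hemisphere;region:hemisphere" ground-truth strings
.parse_regions <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(region = character(0), hemisphere = character(0)))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(region = vapply(parts, `[`, "", 1),
             hemisphere = vapply(parts, function(p) {
               if (length(p) > 1) p[2] else NA_character_
             }, ""),
             stringsAsFactors = FALSE)
}

# is the surgery ground truth of this row evaluable (favorable outcome)?
.surgery_evaluable <- function(gt) {
  !is.na(gt$resection_hemisphere) &&
    !is.na(gt$engel_class) && gt$engel_class %in% c("I", "II") &&
    !is.na(gt$followup_months) && gt$followup_months >= 6
}

# match one detection table against one GT source at a granularity level
.match_gt <- function(det, gt, source, level) {
  det <- det[det$detected & !is.na(det$hemisphere), , drop = FALSE]
  if (source == "expert_mri") {
    er <- .parse_regions(gt$expert_regions)
    if (!nrow(er)) return(NA_integer_)
    hit <- switch(level,
      sublobar = any(paste(det$region, det$hemisphere) %in%
                       paste(er$region, er$hemisphere)),
      lobar = {
        lt <- region_lobe_table()
        er$lobe <- lt$lobe[match(er$region, lt$region)]
        any(paste(det$lobe, det$hemisphere) %in%
              paste(er$lobe, er$hemisphere))
      },
      hemispheric = any(det$hemisphere %in% er$hemisphere)
    )
    return(as.integer(hit))
  }
  if (source == "surgery") {
    if (!.surgery_evaluable(gt)) return(NA_integer_)
    det_h <- det[det$hemisphere == gt$resection_hemisphere, , drop = FALSE]
    hit <- switch(level,
      sublobar = any(det_h$region %in%
                       strsplit(gt$resection_regions, ";")[[1]]),
      lobar = any(det_h$lobe == gt$resection_lobe),
      hemispheric = nrow(det_h) > 0
    )
    return(as.integer(hit))
  }
  if (source == "eeg") {
    if (is.na(gt$eeg_lateralization) ||
        !gt$eeg_lateralization %in% c("left", "right")) {
      return(NA_integer_)
    }
    return(as.integer(any(det$hemisphere == gt$eeg_lateralization)))
  }
  stop("unknown source: ", source)
}

#' Per-dataset sensitivity indicator
#'
#' A dataset counts as *sensitive* for a ground-truth source if at least one
#' detection (`L_r >=` threshold) is consistent with it at the requested
#' granularity: the annotated region set (sublobar), its lobe (lobar) or its
#' hemisphere (hemispheric). Surgery comparisons require a favorable outcome
#' (Engel class I-II, follow-up >= 6 months); non-lesional expert readings,
#' non-focal EEG and non-evaluable surgery give `NA` (not applicable).
#'
#' @param detections A `region_scores` table from [detect_regions()].
#' @param gt One ground-truth row (see [read_ground_truth()]).
#' @param source `"expert_mri"`, `"surgery"` or `"eeg"`.
#' @param level `"sublobar"`, `"lobar"` or `"hemispheric"` (EEG is always
#'   hemispheric).
#' @return 1, 0 or `NA`.
#' @export
dataset_sensitivity <- function(detections, gt,
                                source = c("expert_mri", "surgery", "eeg"),
                                level = c("sublobar", "lobar",
                                          "hemispheric")) {
  source <- match.arg(source)
  level <- if (source == "eeg") "hemispheric" else match.arg(level)
  .match_gt(detections, gt, source, level)
}

#' Per-dataset specificity indicator
#'
#' The stricter criterion: consistency must hold for one of the *three most
#' prominent* detections.
#'
#' @inheritParams dataset_sensitivity
#' @param k Number of most prominent detections considered (default 3).
#' @return 1, 0 or `NA`.
#' @export
dataset_specificity <- function(detections, gt,
                                source = c("expert_mri", "surgery", "eeg"),
                                level = c("sublobar", "lobar",
                                          "hemispheric"), k = 3) {
  source <- match.arg(source)
  level <- if (source == "eeg") "hemispheric" else match.arg(level)
  .match_gt(top_k(detections, k), gt, source, level)
}

#' Match table over a set of datasets
#'
#' One row per dataset with the sensitivity/specificity indicators against
#' expert MRI (sublobar), surgery (sublobar) and EEG (hemispheric), plus the
#' expert-MRI-vs-EEG agreement derived from the ground truth itself.
#'
#' @param detections_list Named list of `region_scores`, one per dataset id.
#' @param gt Ground-truth data.frame (one row per dataset id).
#' @param level Granularity for the MRI and surgery comparisons.
#' @return data.frame with columns `dataset_id`, `subtype`, `sens_expert_mri`,
#'   `sens_surgery`, `sens_eeg`, `spec_expert_mri`, `spec_surgery`,
#'   `spec_eeg`, `agreement_mri_eeg`.
#' @export
build_match_table <- function(detections_list, gt, level = "sublobar") {
  rows <- lapply(seq_len(nrow(gt)), function(i) {
    g <- gt[i, , drop = FALSE]
    det <- detections_list[[g$dataset_id]]
    if (is.null(det)) stop("no detections for dataset ", g$dataset_id)
    er <- .parse_regions(g$expert_regions)
    agree <- if (!nrow(er) ||
                 !g$eeg_lateralization %in% c("left", "right")) {
      NA_integer_
    } else {
      as.integer(g$eeg_lateralization %in% er$hemisphere)
    }
    data.frame(
      dataset_id = g$dataset_id,
      subtype = if ("subtype" %in% names(g)) g$subtype else NA_character_,
      sens_expert_mri = dataset_sensitivity(det, g, "expert_mri", level),
      sens_surgery = dataset_sensitivity(det, g, "surgery", level),
      sens_eeg = dataset_sensitivity(det, g, "eeg"),
      spec_expert_mri = dataset_specificity(det, g, "expert_mri", level),
      spec_surgery = dataset_specificity(det, g, "surgery", level),
      spec_eeg = dataset_specificity(det, g, "eeg"),
      agreement_mri_eeg = agree,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Aggregate match indicators into an overall fraction
#'
#' Overall sensitivities/specificities are the fraction of consistent datasets
#' among all evaluable ones (indicators 1/0, `NA` dropped).
#'
#' @param match_table A [build_match_table()] table (or any data.frame).
#' @param column Indicator column name.
#' @param subset Optional logical vector restricting the rows.
#' @return List with `fraction`, `consistent` and `evaluable`.
#' @export
aggregate_matches <- function(match_table, column, subset = NULL) {
  x <- match_table[[column]]
  if (is.null(x)) stop("no column '", column, "'")
  if (!is.null(subset)) x <- x[subset]
  x <- x[!is.na(x)]
  if (!length(x)) stop("no evaluable dataset for ", column)
  list(fraction = mean(x), consistent = sum(x), evaluable = length(x))
}

#' Diagnostic odds ratio and likelihood ratios of a 2x2 detection table
#'
#' `LR+ = sens / (1 - spec)`, `LR- = (1 - sens) / spec`, and
#' `DOR = LR+ / LR- = (tp * tn) / (fp * fn)`; a +1/2 continuity correction is
#' applied to all cells when any cell is zero, so log(DOR) stays finite. The
#' DOR is prevalence-independent.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return List with `sensitivity`, `specificity`, `lr_pos`, `lr_neg`, `dor`.
#' @export
diagnostic_odds_ratio <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  if (tp + fp + fn + tn == 0) stop("empty 2x2 table")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  cc <- if (any(c(tp, fp, fn, tn) == 0)) 0.5 else 0
  a <- tp + cc; b <- fp + cc; c <- fn + cc; d <- tn + cc
  sens_c <- a / (a + c); spec_c <- d / (d + b)
  list(sensitivity = sens, specificity = spec,
       lr_pos = sens_c / (1 - spec_c), lr_neg = (1 - sens_c) / spec_c,
       dor = (a * d) / (b * c))
}

#' Positive and negative predictive values
#'
#' Prevalence-dependent fractions of correctly classified abnormal
#' (`PPV = tp / (tp + fp)`) and normal (`NPV = tn / (tn + fn)`) regions;
#' undefined cells give `NA`.
#'
#' @inheritParams diagnostic_odds_ratio
#' @return List with `ppv` and `npv`.
#' @export
predictive_values <- function(tp, fp, fn, tn) {
  list(ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Regional accuracy against expert annotations
#'
#' Counts, per (region, hemisphere), true/false positives/negatives of the
#' detections across datasets with lesional expert ground truth, and derives
#' DOR, PPV and NPV per region.
#'
#' @param detections_list Named list of *full* regional score tables
#'   (`detect_regions(..., all = TRUE)`).
#' @param gt Ground-truth data.frame.
#' @return data.frame with per-region counts and accuracy statistics.
#' @export
regional_accuracy <- function(detections_list, gt) {
  use <- which(vapply(seq_len(nrow(gt)), function(i) {
    nrow(.parse_regions(gt$expert_regions[i])) > 0
  }, TRUE))
  if (!length(use)) stop("no dataset with expert annotations")
  first <- detections_list[[gt$dataset_id[use[1]]]]
  key <- paste(first$region, first$hemisphere)
  keep <- !is.na(first$hemisphere)
  acc <- data.frame(region = first$region[keep],
                    hemisphere = first$hemisphere[keep],
                    tp = 0L, fp = 0L, fn = 0L, tn = 0L,
                    stringsAsFactors = FALSE)
  akey <- paste(acc$region, acc$hemisphere)
  for (i in use) {
    det <- detections_list[[gt$dataset_id[i]]]
    er <- .parse_regions(gt$expert_regions[i])
    pos <- akey %in% paste(er$region, er$hemisphere)
    dkey <- paste(det$region, det$hemisphere)[det$detected]
    found <- akey %in% dkey
    acc$tp <- acc$tp + (found & pos)
    acc$fp <- acc$fp + (found & !pos)
    acc$fn <- acc$fn + (!found & pos)
    acc$tn <- acc$tn + (!found & !pos)
  }
  stats <- lapply(seq_len(nrow(acc)), function(j) {
    d <- diagnostic_odds_ratio(acc$tp[j], acc$fp[j], acc$fn[j], acc$tn[j])
    pv <- predictive_values(acc$tp[j], acc$fp[j], acc$fn[j], acc$tn[j])
    c(dor = d$dor, ppv = pv$ppv, npv = pv$npv)
  })
  cbind(acc, do.call(rbind, stats))
}

#' Randomization (permutation) test for group differences
#'
#' Recomputes the statistic under `n_resamples` random relabelings of the
#' group assignment; two-sided by comparing symmetrized (absolute) statistics,
#' with the +1 convention `p = (1 + #(|s*| >= |s|)) / (n_resamples + 1)` so
#' p is never zero.
#'
#' @param x Numeric responses (e.g. 0/1 match indicators).
#' @param g Group labels (>= 2 groups).
#' @param statistic Function `(x, g) -> scalar`; default: difference of group
#'   means for two groups, variance of group means otherwise.
#' @param n_resamples Number of resamplings (default 10,000).
#' @param seed Optional seed for reproducibility.
#' @return List with `p_value`, `observed`, `n_resamples`.
#' @export
randomization_test <- function(x, g, statistic = NULL, n_resamples = 10000,
                               seed = NULL) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok])
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (is.null(statistic)) {
    statistic <- if (nlevels(g) == 2) {
      function(x, g) diff(tapply(x, g, mean))
    } else {
      function(x, g) stats::var(tapply(x, g, mean))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- abs(statistic(x, g))
  if (!is.finite(obs) || stats::var(x) == 0) {
    return(list(p_value = 1, observed = obs, n_resamples = n_resamples))
  }
  cnt <- 0L
  for (b in seq_len(n_resamples)) {
    s <- abs(statistic(x, sample(g)))
    if (s >= obs) cnt <- cnt + 1L
  }
  list(p_value = (1 + cnt) / (n_resamples + 1), observed = obs,
       n_resamples = n_resamples)
}

#' Fisher's exact test of a 2x2 table
#'
#' @param tab 2x2 matrix of counts.
#' @return Two-sided exact p-value.
#' @export
exact_test_2x2 <- function(tab) {
  stats::fisher.test(tab)$p.value
}

#' Exact binomial tail test of a detection rate
#'
#' Probability of observing at least `count` events in `n` trials under a
#' reference rate `p0` (e.g. the expectation in healthy controls).
#'
#' @param count Observed event count.
#' @param n Number of trials.
#' @param p0 Reference rate.
#' @return Upper-tail p-value `P(X >= count)`.
#' @export
binomial_rate_test <- function(count, n, p0) {
  stopifnot(count >= 0, n >= count, p0 >= 0, p0 <= 1)
  stats::pbinom(count - 1, n, p0, lower.tail = FALSE)
}

#' Sequential nonparametric group comparison
#'
#' First-level Kruskal-Wallis test of the group medians; when at least
#' marginally significant (`p < trend_alpha`), second-level pairwise
#' Mann-Whitney-Wilcoxon tests reveal which groups differ. p-values are
#' labelled `"significant"` below `alpha` (0.01), `"trend"` in
#' `[alpha, trend_alpha)` and `"ns"` otherwise.
#'
#' @param x Numeric responses.
#' @param g Group labels.
#' @param alpha Significance level (default 0.01).
#' @param trend_alpha Marginal-significance band limit (default 0.05).
#' @return List with `kw_p`, `kw_label`, and `pairwise` (data.frame, or
#'   `NULL` when the first level is not at least marginal).
#' @export
sequential_group_test <- function(x, g, alpha = 0.01, trend_alpha = 0.05) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok])
  small <- names(which(table(g) < 2))
  if (length(small)) {
    warning("group(s) with < 2 observations excluded: ",
            paste(small, collapse = ", "))
    keep <- !g %in% small
    x <- x[keep]; g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) stop("need >= 2 groups with >= 2 observations")
  lab <- function(p) {
    if (p < alpha) "significant" else if (p < trend_alpha) "trend" else "ns"
  }
  kw <- stats::kruskal.test(x, g)$p.value
  pw <- NULL
  if (kw < trend_alpha) {
    prs <- utils::combn(levels(g), 2)
    pw <- data.frame(
      group_1 = prs[1, ], group_2 = prs[2, ],
      p = apply(prs, 2, function(pr) {
        suppressWarnings(stats::wilcox.test(
          x[g == pr[1]], x[g == pr[2]], exact = FALSE)$p.value)
      }),
      stringsAsFactors = FALSE
    )
    pw$label <- vapply(pw$p, lab, "")
  }
  list(kw_p = kw, kw_label = lab(kw), pairwise = pw)
}
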