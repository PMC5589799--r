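# Fixed feature schema: 60 volume features + (34 DK + 74 Destrieux) parcellations
# x {left, right, asymmetry} x 9 surface parameters = 2,976 features in total.

#' The nine cortical surface parameters
#'
#' Per-parcellation measures produced by surface-based morphometry: grey-matter
#' volume, surface area, mean and standard deviation of cortical thickness, mean
#' (extrinsic) curvature, Gaussian (intrinsic) curvature, curvature index,
#' folding index, and mean grey-white percent contrast.
#'
#' @return Character vector of length 9 with the parameter codes.
#' @export
surface_parameters <- function() {
  c("grayvol", "surfarea", "thickavg", "thickstd",
    "meancurv", "gauscurv", "curvind", "foldind", "pctmean")
}

#' Desikan-Killiany cortical parcellation labels (34 per hemisphere)
#' @return Character vector of length 34.
#' @export
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula")
}

#' Destrieux cortical parcellation labels (74 per hemisphere)
#' @return Character vector of length 74.
#' @export
destrieux_regions <- function() {
  c("G_and_S_frontomargin", "G_and_S_occipital_inf", "G_and_S_paracentral",
    "G_and_S_subcentral", "G_and_S_transv_frontopol", "G_and_S_cingul-Ant",
    "G_and_S_cingul-Mid-Ant", "G_and_S_cingul-Mid-Post", "G_cingul-Post-dorsal",
    "G_cingul-Post-ventral", "G_cuneus", "G_front_inf-Opercular",
    "G_front_inf-Orbital", "G_front_inf-Triangul", "G_front_middle",
    "G_front_sup", "G_Ins_lg_and_S_cent_ins", "G_insular_short",
    "G_occipital_middle", "G_occipital_sup", "G_oc-temp_lat-fusifor",
    "G_oc-temp_med-Lingual", "G_oc-temp_med-Parahip", "G_orbital",
    "G_pariet_inf-Angular", "G_pariet_inf-Supramar", "G_parietal_sup",
    "G_postcentral", "G_precentral", "G_precuneus", "G_rectus", "G_subcallosal",
    "G_temp_sup-G_T_transv", "G_temp_sup-Lateral", "G_temp_sup-Plan_polar",
    "G_temp_sup-Plan_tempo", "G_temporal_inf", "G_temporal_middle",
    "Lat_Fis-ant-Horizont", "Lat_Fis-ant-Vertical", "Lat_Fis-post",
    "Pole_occipital", "Pole_temporal", "S_calcarine", "S_central",
    "S_cingul-Marginalis", "S_circular_insula_ant", "S_circular_insula_inf",
    "S_circular_insula_sup", "S_collat_transv_ant", "S_collat_transv_post",
    "S_front_inf", "S_front_middle", "S_front_sup", "S_interm_prim-Jensen",
    "S_intrapariet_and_P_trans", "S_oc_middle_and_Lunatus",
    "S_oc_sup_and_transversal", "S_occipital_ant", "S_oc-temp_lat",
    "S_oc-temp_med_and_Lingual", "S_orbital_lateral", "S_orbital_med-olfact",
    "S_orbital-H_Shaped", "S_parieto_occipital", "S_pericallosal",
    "S_postcentral", "S_precentral-inf-part", "S_precentral-sup-part",
    "S_suborbital", "S_subparietal", "S_temporal_inf", "S_temporal_sup",
    "S_temporal_transverse")
}

#' Bilateral volume segmentations (15 structures)
#'
#' Each contributes a left, a right and an asymmetry feature. Together with the
#' 15 global volumes of [volume_global_regions()] this fixes the 60-feature
#' volume block (15 x 3 + 15 = 60). The composition is a documented convention
#' of this package (typical subcortical and cerebellar segmentations plus
#' hemispheric tissue compartments).
#'
#' @return Character vector of length 15.
#' @export
volume_bilateral_regions <- function() {
  c("Lateral-Ventricle", "Inf-Lat-Vent", "Cerebellum-White-Matter",
    "Cerebellum-Cortex", "Thalamus", "Caudate", "Putamen", "Pallidum",
    "Hippocampus", "Amygdala", "Accumbens-area", "VentralDC", "Choroid-Plexus",
    "Cerebral-White-Matter", "Cerebral-Cortex")
}

#' Global (unpaired) volume features (15 entries)
#'
#' Midline structures, corpus callosum subsegments and whole-brain partial
#' volumes; these carry side `"global"` and have no asymmetry entry.
#'
#' @return Character vector of length 15.
#' @export
volume_global_regions <- function() {
  c("3rd-Ventricle", "4th-Ventricle", "Brain-Stem", "CSF", "Optic-Chiasm",
    "CC_Posterior", "CC_Mid_Posterior", "CC_Central", "CC_Mid_Anterior",
    "CC_Anterior", "BrainSegVol", "TotalGrayVol", "SubCortGrayVol",
    "SupraTentorialVol", "CerebralWhiteMatterVol")
}

#' Canonical feature identifier
#'
#' Feature identifiers are `"region|parameter|side"`; the `|` separator never
#' occurs inside atlas labels.
#'
#' @param region Atlas label.
#' @param parameter Morphometric parameter code.
#' @param side One of `"left"`, `"right"`, `"asymmetry"`, `"global"`.
#' @return Character vector of identifiers.
#' @export
feature_id <- function(region, parameter, side) {
  paste(region, parameter, side, sep = "|")
}

#' Assemble the fixed 2,976-feature schema
#'
#' Deterministic, ordered catalog of every (region, parameter, side) feature:
#' the 60-entry volume block first (bilateral structures as
#' left/right/asymmetry triples, then global volumes), followed by the surface
#' block (DK then Destrieux regions, each with the 9 parameters of
#' [surface_parameters()] on left, right and asymmetry). Two calls always yield
#' identical ordering.
#'
#' @return A `data.frame` of class `mn_schema` with columns `feature`, `region`,
#'   `parameter`, `side`, `atlas` (`"aseg"`, `"global"`, `"DK"`, `"Destrieux"`),
#'   `kind` (`"volume"`/`"surface"`) and `measured` (`FALSE` for derived
#'   asymmetry entries).
#' @examples
#' sch <- mn_schema()
#' nrow(sch)                         # 2976
#' sum(sch$kind == "surface")        # 2916
#' @export
mn_schema <- function() {
  sides <- c("left", "right", "asymmetry")

  vb <- volume_bilateral_regions()
  vol_bi <- data.frame(
    region = rep(vb, each = 3L),
    parameter = "volume",
    side = rep(sides, length(vb)),
    atlas = "aseg", kind = "volume",
    stringsAsFactors = FALSE
  )
  vol_gl <- data.frame(
    region = volume_global_regions(),
    parameter = "volume", side = "global",
    atlas = "global", kind = "volume",
    stringsAsFactors = FALSE
  )

  surf_block <- function(regions, atlas) {
    pars <- surface_parameters()
    data.frame(
      region = rep(regions, each = length(pars) * 3L),
      parameter = rep(rep(pars, each = 3L), length(regions)),
      side = rep(sides, length(pars) * length(regions)),
      atlas = atlas, kind = "surface",
      stringsAsFactors = FALSE
    )
  }

  sch <- rbind(vol_bi, vol_gl,
               surf_block(dk_regions(), "DK"),
               surf_block(destrieux_regions(), "Destrieux"))
  sch$feature <- feature_id(sch$region, sch$parameter, sch$side)
  sch$measured <- sch$side != "asymmetry"
  sch <- sch[, c("feature", "region", "parameter", "side", "atlas", "kind",
                 "measured")]
  rownames(sch) <- NULL
  stopifnot(nrow(sch) == 2976L, !anyDuplicated(sch$feature))
  class(sch) <- c("mn_schema", "data.frame")
  sch
}

#' @export
print.mn_schema <- function(x, ...) {
  cat("Morphometric feature schema:", nrow(x), "features\n")
  cat("  volume:", sum(x$kind == "volume"),
      " surface:", sum(x$kind == "surface"),
      " (asymmetry entries:", sum(x$side == "asymmetry"), ")\n")
  NextMethod()
}

# measured feature ids in schema order (the columns of a cohort table)
measured_features <- function(schema = mn_schema()) {
  schema$feature[schema$measured]
}

# asymmetry feature ids together with their left/right source ids
asymmetry_map <- function(schema = mn_schema()) {
  a <- schema[schema$side == "asymmetry", , drop = FALSE]
  data.frame(
    feature = a$feature,
    left = feature_id(a$region, a$parameter, "left"),
    right = feature_id(a$region, a$parameter, "right"),
    stringsAsFactors = FALSE
  )
}
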