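# Standardized per-patient result presentation: flag-coloured feature tables,
# regional detections and reproducible provenance.

# tiny deterministic polynomial hash for provenance config fingerprints
.cfg_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 4294967296
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Format a measurement with its uncertainty
#'
#' Clinical-report style `"2.1 +/- 0.2 ml"`: the value rounded to the
#' precision suggested by the uncertainty (one significant digit of the SD).
#'
#' @param value Measured value.
#' @param sd Measurement uncertainty (same units).
#' @param unit Unit string (optional).
#' @return Character vector.
#' @export
format_measurement <- function(value, sd, unit = "") {
  digits <- ifelse(sd > 0, pmax(0, -floor(log10(sd))), 2)
  sd_r <- signif(sd, 1)
  out <- sprintf("%.*f ± %.*f", digits, round(value, digits), digits,
                 sd_r)
  if (nzchar(unit)) out <- paste(out, unit)
  out
}

# flag -> report colour per the standardized display convention
.flag_colour <- function(flag) {
  c(none = "none", uncorrected = "yellow", fdr = "red")[flag]
}

#' Render a standardized morphometry report
#'
#' Writes, for one scored scan: `report.tsv` (one row per feature with raw and
#' normalized values, measurement uncertainty, normative prediction at the
#' patient's age, p-values and yellow/red flag colours), `detections.tsv`
#' (regional scores sorted by L_r), and `report.json` (both plus provenance:
#' package and model version, thresholds, config hash). Optionally renders
#' per-feature age-trend plots of the flagged features into a PDF.
#'
#' @param profile An `abnormality_profile`.
#' @param model The `normative_model`.
#' @param dir Output directory (created if needed).
#' @param detections Optional precomputed [detect_regions()] table.
#' @param plots Render `trends.pdf` with the top flagged features.
#' @param max_plots Cap on plotted features.
#' @return Invisibly, the list of files written.
#' @export
render_report <- function(profile, model, dir, detections = NULL,
                          plots = FALSE, max_plots = 12) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory ", dir)
  }
  if (is.null(detections)) detections <- detect_regions(profile, model)

  raw <- profile[profile$variant == "raw", ]
  nrm <- profile[profile$variant == "normalized", ]
  stopifnot(identical(raw$feature, nrm$feature))
  meas_sd <- stats::setNames(
    c(model$blocks$raw$measurement_sd, model$blocks$asymmetry$measurement_sd),
    c(model$blocks$raw$features, model$blocks$asymmetry$features))
  unit_of <- function(parameter, kind) {
    u <- c(volume = "ml", grayvol = "ml", surfarea = "cm^2", thickavg = "mm",
           thickstd = "mm", meancurv = "1/mm", gauscurv = "1/mm^2",
           curvind = "", foldind = "", pctmean = "%")
    ifelse(kind == "volume", "ml", u[parameter])
  }
  sch <- model$schema
  units <- unit_of(sch$parameter, sch$kind)
  units[sch$side == "asymmetry"] <- ""
  tab <- data.frame(
    feature = raw$feature, region = raw$region, parameter = raw$parameter,
    side = raw$side,
    value = format_measurement(raw$value, unname(meas_sd[raw$feature]),
                               ""),
    unit = units,
    predicted = signif(nrm$predicted, 5),
    p_raw = raw$p, p_normalized = nrm$p,
    L_raw = raw$L, L_normalized = nrm$L,
    flag_raw = .flag_colour(raw$flag),
    flag_normalized = .flag_colour(nrm$flag),
    stringsAsFactors = FALSE
  )
  files <- character(0)
  f_tab <- file.path(dir, "report.tsv")
  utils::write.table(tab, f_tab, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_det <- file.path(dir, "detections.tsv")
  utils::write.table(as.data.frame(detections), f_det, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  provenance <- list(
    package = "morphonorm",
    package_version = as.character(utils::packageVersion("morphonorm")),
    model_version = model$version,
    model_cohort = c(scans = model$n_scans, subjects = model$n_subjects),
    dataset_id = attr(profile, "dataset_id"),
    age = attr(profile, "age"),
    extrapolated = attr(profile, "extrapolated"),
    alpha = attr(profile, "alpha"), q = attr(profile, "q"),
    lr_threshold = attr(detections, "threshold"),
    config_hash = .cfg_hash(paste(attr(profile, "alpha"), attr(profile, "q"),
                                 attr(detections, "threshold"),
                                 model$max_order, model$artifact_z,
                                 model$n_scans, sep = "|"))
  )
  f_json <- file.path(dir, "report.json")
  jsonlite::write_json(list(provenance = provenance, features = tab,
                            detections = as.data.frame(detections)),
                       f_json, auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(f_tab, f_det, f_json)

  if (plots) {
    flagged <- nrm[nrm$flag != "none" & nrm$side != "asymmetry", ]
    flagged <- flagged[order(flagged$p), , drop = FALSE]
    f_pdf <- file.path(dir, "trends.pdf")
    grDevices::pdf(f_pdf, width = 6, height = 4.5)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (f in utils::head(flagged$feature, max_plots)) {
      plot(model, f, block = "normalized",
           scan = list(age = attr(profile, "age"),
                       value = nrm$value[nrm$feature == f]),
           main = f)
    }
    files <- c(files, f_pdf)
  }
  invisible(files)
}
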