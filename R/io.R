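# Reading and writing the tabular artifacts: morphometry stats tables
# (FreeSurfer-style dialects and a generic TSV interchange format), wide
# normative cohort tables, ground truth, profiles and fitted models.

#' Construct a morphometric record for one scan
#'
#' @param subject_id,session_id Identifiers.
#' @param age Age in years (> 0).
#' @param sex `"m"`/`"f"`.
#' @param scanner_sequence Scanner-sequence group label.
#' @param etiv Estimated total intracranial volume (ml, > 0).
#' @param values Named numeric vector keyed by measured feature identifiers
#'   (see [feature_id()]); asymmetry entries are computed later, absent
#'   features may be missing.
#' @return List of class `morphometric_record`.
#' @export
morphometric_record <- function(subject_id, session_id = subject_id, age,
                                sex = NA_character_,
                                scanner_sequence = "default", etiv,
                                values = numeric(0)) {
  if (!is.na(age) && age <= 0) stop("age must be positive")
  if (!is.na(etiv) && etiv <= 0) stop("etiv must be positive")
  if (any(values < 0, na.rm = TRUE)) {
    stop("raw morphometric values must be non-negative")
  }
  structure(list(subject_id = subject_id, session_id = session_id,
                 age = age, sex = sex, scanner_sequence = scanner_sequence,
                 etiv = etiv, values = values),
            class = "morphometric_record")
}

#' @export
print.morphometric_record <- function(x, ...) {
  cat("Morphometric record", x$session_id, "(subject", x$subject_id, ")\n")
  cat("  age", round(x$age, 1), "y, sex", x$sex, ", eTIV",
      round(x$etiv), "ml,", length(x$values), "feature values\n")
  invisible(x)
}

#' Convert a record to a one-row cohort data.frame
#'
#' @param record A [morphometric_record()].
#' @param schema Feature schema.
#' @return One-row data.frame with metadata and all measured feature columns
#'   (absent features `NA`).
#' @export
record_to_row <- function(record, schema = mn_schema()) {
  mf <- measured_features(schema)
  v <- stats::setNames(rep(NA_real_, length(mf)), mf)
  known <- intersect(names(record$values), mf)
  v[known] <- record$values[known]
  cbind(data.frame(subject_id = record$subject_id,
                   session_id = record$session_id, age = record$age,
                   sex = record$sex,
                   scanner_sequence = record$scanner_sequence,
                   etiv = record$etiv, stringsAsFactors = FALSE),
        as.data.frame(as.list(v), check.names = FALSE))
}

#' Write a record as a generic TSV stats table
#'
#' The canonical interchange format: `#`-prefixed `key<TAB>value` metadata
#' lines followed by a four-column table `region`, `parameter`, `side`,
#' `value`.
#'
#' @param record A `morphometric_record`.
#' @param path Output path.
#' @export
write_record <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in c("subject_id", "session_id", "age", "sex", "scanner_sequence",
              "etiv")) {
    cat(sprintf("#%s\t%s\n", k, format(record[[k]], digits = 17)),
        file = con)
  }
  parts <- strsplit(names(record$values), "|", fixed = TRUE)
  df <- data.frame(region = vapply(parts, `[`, "", 1),
                   parameter = vapply(parts, `[`, "", 2),
                   side = vapply(parts, `[`, "", 3),
                   value = unname(record$values))
  cat("region\tparameter\tside\tvalue\n", file = con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a morphometry stats table
#'
#' Supported dialects: the package's `generic_tsv` interchange format
#' ([write_record()]), FreeSurfer-style `freesurfer_aseg` segmentation tables
#' (`# Measure` header lines plus a whitespace table with a `# ColHeaders`
#' line; volumes converted mm^3 -> ml) and `freesurfer_aparc` parcellation
#' tables (one hemisphere per file; areas converted mm^2 -> cm^2, grey-matter
#' volumes mm^3 -> ml). Rows whose labels are not in the schema are skipped
#' with one warning; duplicate rows are an error.
#'
#' @param path File path.
#' @param dialect One of `"generic_tsv"`, `"freesurfer_aseg"`,
#'   `"freesurfer_aparc"`.
#' @param hemisphere For `freesurfer_aparc`: `"left"` or `"right"`.
#' @param schema Feature schema.
#' @return A `morphometric_record` (metadata fields may be `NA` for
#'   FreeSurfer dialects, which carry no demographics; merge via
#'   [morphometric_record()]).
#' @export
read_stats_table <- function(path,
                             dialect = c("generic_tsv", "freesurfer_aseg",
                                         "freesurfer_aparc"),
                             hemisphere = NULL, schema = mn_schema()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         generic_tsv = .read_generic_tsv(path, schema),
         freesurfer_aseg = .read_fs_aseg(path, schema),
         freesurfer_aparc = .read_fs_aparc(path, hemisphere, schema))
}

.keep_known <- function(ids, values, schema, path) {
  if (anyDuplicated(ids)) {
    stop("duplicate region row(s) in ", path, ": ",
         ids[duplicated(ids)][1])
  }
  known <- ids %in% schema$feature[schema$measured]
  if (any(!known)) {
    warning(sum(!known), " row(s) with labels not in the schema skipped ",
            "(e.g. ", ids[!known][1], ")")
  }
  stats::setNames(values[known], ids[known])
}

.read_generic_tsv <- function(path, schema) {
  lines <- readLines(path)
  meta_ln <- grep("^#", lines)
  meta <- list()
  for (i in meta_ln) {
    kv <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed header at line ", i, " of ", path)
    meta[[kv[1]]] <- kv[2]
  }
  body <- lines[setdiff(seq_along(lines), meta_ln)]
  if (!length(body) || !identical(strsplit(body[1], "\t")[[1]],
                                  c("region", "parameter", "side", "value"))) {
    stop("malformed column header at line ", length(meta_ln) + 1, " of ",
         path, " (expected region/parameter/side/value)")
  }
  df <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  ids <- feature_id(df$region, df$parameter, df$side)
  values <- .keep_known(ids, df$value, schema, path)
  morphometric_record(
    subject_id = meta$subject_id %||% NA_character_,
    session_id = meta$session_id %||% meta$subject_id %||% basename(path),
    age = as.numeric(meta$age %||% NA),
    sex = meta$sex %||% NA_character_,
    scanner_sequence = meta$scanner_sequence %||% "default",
    etiv = as.numeric(meta$etiv %||% NA),
    values = values
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FreeSurfer global-measure names -> schema global volume regions
.fs_measure_map <- c(
  BrainSeg = "BrainSegVol", TotalGray = "TotalGrayVol",
  SubCortGray = "SubCortGrayVol", SupraTentorial = "SupraTentorialVol",
  CerebralWhiteMatter = "CerebralWhiteMatterVol"
)

.read_fs_aseg <- function(path, schema) {
  lines <- readLines(path)
  etiv <- NA_real_
  values <- numeric(0)
  for (ln in grep("^# Measure", lines, value = TRUE)) {
    parts <- trimws(strsplit(sub("^# Measure ", "", ln), ",")[[1]])
    if (length(parts) < 4) stop("malformed Measure header line in ", path)
    val <- as.numeric(parts[length(parts) - 1]) / 1000  # mm^3 -> ml
    if (parts[1] == "EstimatedTotalIntraCranialVol") {
      etiv <- val
    } else if (parts[1] %in% names(.fs_measure_map)) {
      values[feature_id(.fs_measure_map[[parts[1]]], "volume", "global")] <-
        val
    }
  }
  ch <- grep("^# ColHeaders", lines, value = TRUE)
  if (length(ch) != 1) stop("missing ColHeaders line in ", path)
  cols <- strsplit(trimws(sub("^# ColHeaders", "", ch)), "\\s+")[[1]]
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  tab <- utils::read.table(text = body, col.names = cols,
                           stringsAsFactors = FALSE, check.names = FALSE)
  side <- ifelse(grepl("^Left-", tab$StructName), "left",
                 ifelse(grepl("^Right-", tab$StructName), "right", "global"))
  region <- sub("^(Left|Right)-", "", tab$StructName)
  ids <- feature_id(region, "volume", side)
  v2 <- .keep_known(ids, tab$Volume_mm3 / 1000, schema, path)
  morphometric_record(subject_id = basename(path), age = NA_real_,
                      etiv = etiv, values = c(values, v2))
}

.read_fs_aparc <- function(path, hemisphere, schema) {
  if (is.null(hemisphere) || !hemisphere %in% c("left", "right")) {
    stop("freesurfer_aparc requires hemisphere = 'left' or 'right'")
  }
  lines <- readLines(path)
  ch <- grep("^# ColHeaders", lines, value = TRUE)
  if (length(ch) != 1) stop("missing ColHeaders line in ", path)
  cols <- strsplit(trimws(sub("^# ColHeaders", "", ch)), "\\s+")[[1]]
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  tab <- utils::read.table(text = body, col.names = cols,
                           stringsAsFactors = FALSE, check.names = FALSE)
  par_map <- c(SurfArea = "surfarea", GrayVol = "grayvol",
               ThickAvg = "thickavg", ThickStd = "thickstd",
               MeanCurv = "meancurv", GausCurv = "gauscurv",
               FoldInd = "foldind", CurvInd = "curvind", PctMean = "pctmean")
  scale <- c(surfarea = 1 / 100, grayvol = 1 / 1000, thickavg = 1,
             thickstd = 1, meancurv = 1, gauscurv = 1, foldind = 1,
             curvind = 1, pctmean = 1)
  values <- numeric(0)
  for (cn in intersect(names(par_map), cols)) {
    p <- par_map[[cn]]
    values[feature_id(tab$StructName, p, hemisphere)] <-
      tab[[cn]] * scale[[p]]
  }
  values <- .keep_known(names(values), values, schema, path)
  morphometric_record(subject_id = basename(path), age = NA_real_,
                      etiv = NA_real_, values = values)
}

# ---- cohort tables ------------------------------------------------------------

#' Write / read a wide cohort table (one row per scan)
#'
#' TSV with the metadata columns followed by one column per measured feature.
#'
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @return `read_cohort` returns the data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# ---- ground truth -------------------------------------------------------------

.gt_columns <- c("dataset_id", "subject_id", "subtype", "expert_regions",
                 "eeg_lateralization", "resection_hemisphere",
                 "resection_lobe", "resection_regions", "engel_class",
                 "followup_months")

#' Read / write ground-truth annotation tables
#'
#' TSV with one row per dataset: expert-annotated lesion regions
#' (`region:hemisphere` joined by `;`), EEG lateralization (`left`, `right`,
#' `diffuse`, `none`), and the resection description with Engel class and
#' follow-up. Enumerated fields are validated on read.
#'
#' @param gt Ground-truth data.frame.
#' @param path File path.
#' @return `read_ground_truth` returns the validated data.frame (empty files
#'   give a zero-row table).
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  if (!length(first) || !nzchar(trimws(first))) {
    gt <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.gt_columns)), .gt_columns))
    gt$followup_months <- numeric(0)
    return(gt)
  }
  gt <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(.gt_columns, names(gt))
  if (length(missing)) {
    stop("ground truth lacks column(s): ", paste(missing, collapse = ", "))
  }
  gt$followup_months <- as.numeric(gt$followup_months)
  for (ch in c("expert_regions", "eeg_lateralization", "resection_hemisphere",
               "resection_lobe", "resection_regions", "engel_class")) {
    gt[[ch]] <- as.character(gt[[ch]])
    gt[[ch]][gt[[ch]] == ""] <- NA_character_
  }
  bad_eeg <- !is.na(gt$eeg_lateralization) &
    !gt$eeg_lateralization %in% c("left", "right", "diffuse", "none")
  if (any(bad_eeg)) {
    stop("invalid eeg_lateralization value(s): ",
         paste(unique(gt$eeg_lateralization[bad_eeg]), collapse = ", "))
  }
  bad_engel <- !is.na(gt$engel_class) &
    !gt$engel_class %in% c("I", "II", "III", "IV")
  if (any(bad_engel)) {
    stop("invalid engel_class value(s): ",
         paste(unique(gt$engel_class[bad_engel]), collapse = ", "))
  }
  bad_hemi <- !is.na(gt$resection_hemisphere) &
    !gt$resection_hemisphere %in% c("left", "right")
  if (any(bad_hemi)) stop("invalid resection_hemisphere value(s)")
  gt
}

#' @rdname read_ground_truth
#' @export
write_ground_truth <- function(gt, path) {
  utils::write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# ---- profiles, detections, reports --------------------------------------------

#' Serialize / restore an abnormality profile
#'
#' JSON (full precision, including the profile attributes) or plain TSV of the
#' table.
#'
#' @param profile An `abnormality_profile`.
#' @param path Output path; format chosen by extension (`.json` or `.tsv`).
#' @return `read_profile` restores the `abnormality_profile` from JSON.
#' @export
write_profile <- function(profile, path) {
  if (grepl("\\.json$", path)) {
    payload <- list(
      dataset_id = attr(profile, "dataset_id"), age = attr(profile, "age"),
      extrapolated = attr(profile, "extrapolated"),
      alpha = attr(profile, "alpha"), q = attr(profile, "q"),
      table = as.data.frame(profile)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    utils::write.table(as.data.frame(profile), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x$table, dataset_id = x$dataset_id, age = x$age,
            extrapolated = x$extrapolated, alpha = x$alpha, q = x$q,
            class = c("abnormality_profile", "data.frame"))
}

#' Write an accuracy report
#'
#' @param report A list (e.g. match table plus aggregates) or data.frame.
#' @param path Output path (`.json` or `.tsv`).
#' @export
write_accuracy <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    utils::write.table(as.data.frame(report), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---- model serialization ------------------------------------------------------

#' Serialize / restore a fitted normative model (JSON)
#'
#' @param model A `normative_model`.
#' @param path File path.
#' @return `read_normative` returns the restored `normative_model`.
#' @export
write_normative <- function(model, path) {
  ser_block <- function(b) {
    list(features = b$features, order = b$order,
         coef = b$coef, sigma = b$sigma, df = b$df,
         xtxinv = b$xtxinv, max_order = b$max_order, n_cov = b$n_cov,
         artifact_p = b$artifact_p, odds = b$odds,
         n_outliers = b$n_outliers, measurement_sd = b$measurement_sd,
         population_sd = b$population_sd, delta_cv = b$delta_cv)
  }
  ser_refs <- lapply(model$normalization$contrast_refs, function(r) {
    list(groups = names(r$group_means),
         means = unname(r$group_means),
         grand_mean = r$grand_mean)
  })
  payload <- list(
    version = model$version,
    blocks = lapply(model$blocks, ser_block),
    normalization = list(reference_etiv = model$normalization$reference_etiv,
                         contrast_refs = ser_refs),
    cov_info = model$cov_info,
    age_center = model$age_center, age_scale = model$age_scale,
    age_range = model$age_range, alpha = model$alpha, q = model$q,
    artifact_z = model$artifact_z, max_order = model$max_order,
    n_scans = model$n_scans, n_subjects = model$n_subjects,
    n_repeat_pairs = model$n_repeat_pairs
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_normative
#' @export
read_normative <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_block <- function(b) {
    b$coef <- as.matrix(b$coef)
    b$xtxinv <- lapply(b$xtxinv, as.matrix)
    b
  }
  x$blocks <- lapply(x$blocks, de_block)
  x$cov_info$levels <- lapply(x$cov_info$levels, unlist)
  x$cov_info$columns <- unlist(x$cov_info$columns)
  x$cov_info$means <- unlist(x$cov_info$means)
  if (is.null(x$cov_info$columns)) x$cov_info$columns <- character(0)
  if (is.null(x$cov_info$means)) x$cov_info$means <- numeric(0)
  x$normalization$contrast_refs <- lapply(
    x$normalization$contrast_refs, function(r) {
      list(group_means = stats::setNames(unlist(r$means),
                                         unlist(r$groups)),
           grand_mean = r$grand_mean)
    })
  x$normalization$exponents <- etiv_exponents()
  x$schema <- mn_schema()
  x$call <- quote(read_normative())
  class(x) <- "normative_model"
  x
}
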