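# Synthetic cohort generator: emulates the statistical structure of the
# MRI-derived normative database and TLE patient cohorts — polynomial age
# trends, region-specific population spread, subject-level biology shared
# across repeated scans, scanner offsets, head-size scaling, measurement noise,
# value-level artifact contamination, and subtype-specific injected effects.

# run expr with a private RNG stream, restoring the caller's .Random.seed
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# nominal volumes (ml) of the bilateral and global segmentations
.volume_baselines <- function() {
  bi <- c("Lateral-Ventricle" = 8, "Inf-Lat-Vent" = 0.4,
          "Cerebellum-White-Matter" = 14, "Cerebellum-Cortex" = 52,
          "Thalamus" = 7.4, "Caudate" = 3.6, "Putamen" = 5.2, "Pallidum" = 1.8,
          "Hippocampus" = 4.1, "Amygdala" = 1.7, "Accumbens-area" = 0.6,
          "VentralDC" = 4.0, "Choroid-Plexus" = 1.0,
          "Cerebral-White-Matter" = 230, "Cerebral-Cortex" = 240)
  gl <- c("3rd-Ventricle" = 1.1, "4th-Ventricle" = 1.8, "Brain-Stem" = 21,
          "CSF" = 320, "Optic-Chiasm" = 0.2, "CC_Posterior" = 1.0,
          "CC_Mid_Posterior" = 0.5, "CC_Central" = 0.5, "CC_Mid_Anterior" = 0.5,
          "CC_Anterior" = 0.9, "BrainSegVol" = 1150, "TotalGrayVol" = 640,
          "SubCortGrayVol" = 60, "SupraTentorialVol" = 1020,
          "CerebralWhiteMatterVol" = 460)
  list(bilateral = bi, global = gl)
}

# draw per-parameter baselines for one surface parcellation unit
.surface_baseline_ranges <- function() {
  list(grayvol = c(2, 25), surfarea = c(5, 40), thickavg = c(2.0, 3.2),
       thickstd = c(0.4, 0.7), meancurv = c(0.10, 0.20),
       gauscurv = c(0.02, 0.08), curvind = c(2, 20), foldind = c(10, 60),
       pctmean = c(15, 25))
}

#' Generator configuration for synthetic morphometry cohorts
#'
#' Fixes the "world": per-(region, parameter) baselines, polynomial age trends,
#' region-specific population spread, measurement error, scanner offsets and
#' grey-white-contrast sequence factors. The world is drawn once from
#' `world_seed` and is independent of the cohort seeds passed to
#' [generate_controls()]/[generate_patients()], so different cohorts live in
#' the same world. Cohort defaults mirror the scale of a single-centre
#' normative database (300 control scans of 260 subjects, 40 repeat pairs,
#' ages 7-79, three scanner-sequence groups).
#'
#' @param n_subjects Number of control subjects.
#' @param n_repeat_pairs Subjects with a second scan within the repeat window.
#' @param age_range Age span (years) of the cohort.
#' @param scanners Scanner-sequence labels.
#' @param scanner_probs Sampling probability per scanner.
#' @param artifact_rate Fraction of measured values replaced by gross artifacts
#'   in control scans (in `[0, 0.2]`).
#' @param lr_correlation Correlation of left/right subject-level effects of
#'   bilateral features.
#' @param measurement_frac Range of the measurement SD as a fraction of the
#'   biological (between-subject) SD.
#' @param population_cv Range of the biological SD as a fraction of baseline.
#' @param etiv_mean,etiv_sd Head-size distribution (ml).
#' @param world_seed Seed of the fixed world library.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 260, n_repeat_pairs = 40,
                       age_range = c(7, 79),
                       scanners = c("scannerA", "scannerB", "scannerC"),
                       scanner_probs = c(0.5, 0.3, 0.2),
                       artifact_rate = 0.01, lr_correlation = 0.6,
                       measurement_frac = c(0.3, 0.5),
                       population_cv = c(0.06, 0.12),
                       etiv_mean = 1450, etiv_sd = 120,
                       world_seed = 7979L) {
  stopifnot(artifact_rate >= 0, artifact_rate <= 0.2,
            n_repeat_pairs <= n_subjects, length(age_range) == 2)
  schema <- mn_schema()
  # one "unit" per (region, parameter); bilateral sides share a unit
  mf <- schema[schema$measured, , drop = FALSE]
  unit_key <- paste(mf$region, mf$parameter, sep = "|")
  units <- unique(unit_key)
  nu <- length(units)

  world <- with_seed(world_seed, {
    reg <- sub("\\|.*", "", units)
    par <- sub(".*\\|", "", units)
    vb <- .volume_baselines()
    baseline <- numeric(nu)
    vol <- par == "volume"
    baseline[vol] <- c(vb$bilateral, vb$global)[reg[vol]]
    rng <- .surface_baseline_ranges()
    for (p in names(rng)) {
      idx <- par == p
      baseline[idx] <- runif(sum(idx), rng[[p]][1], rng[[p]][2])
    }
    ord <- sample(0:2, nu, replace = TRUE, prob = c(0.35, 0.45, 0.20))
    c1 <- ifelse(ord >= 1, rnorm(nu, -1e-3, 1e-3), 0)
    c2 <- ifelse(ord >= 2, rnorm(nu, 0, 2e-5), 0)
    pop_cv <- runif(nu, population_cv[1], population_cv[2])
    meas_frac <- runif(nu, measurement_frac[1], measurement_frac[2])
    off <- matrix(rnorm(nu * length(scanners), 0, 0.25), nu,
                  length(scanners), dimnames = list(units, scanners))
    pct_factor <- matrix(runif(nu * length(scanners), 0.92, 1.08), nu,
                         length(scanners), dimnames = list(units, scanners))
    list(units = units, region = reg, parameter = par, baseline = baseline,
         trend_order = ord, c1 = c1, c2 = c2,
         pop_sd = pop_cv * baseline,
         meas_sd = meas_frac * pop_cv * baseline,
         scanner_offset = off,      # in units of pop_sd
         pct_factor = pct_factor)
  })

  structure(list(
    n_subjects = n_subjects, n_repeat_pairs = n_repeat_pairs,
    age_range = age_range, scanners = scanners,
    scanner_probs = scanner_probs, artifact_rate = artifact_rate,
    lr_correlation = lr_correlation, etiv_mean = etiv_mean,
    etiv_sd = etiv_sd, schema = schema, world = world,
    feature_unit = match(unit_key, units),
    measured = mf
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic morphometry world:", length(x$world$units),
      "(region, parameter) units,", nrow(x$measured), "measured features\n")
  cat("  controls:", x$n_subjects, "subjects,", x$n_repeat_pairs,
      "repeat pairs, ages", x$age_range[1], "-", x$age_range[2],
      ", artifact rate", x$artifact_rate, "\n")
  invisible(x)
}

# core scan synthesizer shared by controls and patients.
# subjects: data.frame(subject_id, age0, sex, etiv); sessions: data.frame
# (subject (index), session_id, age, scanner). Returns a cohort data.frame.
.synth_scans <- function(config, subjects, sessions, artifact_rate,
                         effects = NULL) {
  w <- config$world
  mf <- config$measured
  fu <- config$feature_unit
  nf <- nrow(mf)
  nsub <- nrow(subjects)
  n <- nrow(sessions)

  rho <- config$lr_correlation
  Zc <- matrix(rnorm(nsub * length(w$units)), nsub)        # shared L/R biology
  Zs <- matrix(rnorm(nsub * nf), nsub)                     # side-specific
  paired <- mf$side %in% c("left", "right")
  subj_z <- Zs
  subj_z[, paired] <- sqrt(rho) * Zc[, fu[paired], drop = FALSE] +
    sqrt(1 - rho) * Zs[, paired, drop = FALSE]

  a <- sessions$age - 40
  trend <- rep(w$baseline[fu], each = n) *
    (1 + outer(a, w$c1[fu]) + outer(a^2, w$c2[fu]))
  dev <- subj_z[sessions$subject, , drop = FALSE] +
    matrix(rnorm(n * nf), n) * rep(w$meas_sd[fu] / w$pop_sd[fu], each = n)
  # scanner offsets (in pop_sd units): O[i, j] = offset[unit(j), scanner(i)]
  off <- w$scanner_offset[cbind(rep(fu, each = n),
                                rep(match(sessions$scanner, config$scanners),
                                    nf))]
  dev <- dev + matrix(off, n, nf)
  X <- trend + dev * rep(w$pop_sd[fu], each = n)

  if (!is.null(effects) && nrow(effects)) {
    total_sd <- sqrt(w$pop_sd^2 + w$meas_sd^2)
    for (k in seq_len(nrow(effects))) {
      j <- which(mf$region == effects$region[k] &
                   mf$parameter == effects$parameter[k] &
                   mf$side == effects$side[k])
      if (!length(j)) stop("effect targets unknown feature: ",
                           effects$region[k], "|", effects$parameter[k], "|",
                           effects$side[k])
      X[, j] <- X[, j] + effects$size[k] * total_sd[fu[j]]
    }
  }

  if (artifact_rate > 0) {
    bad <- matrix(runif(n * nf) < artifact_rate, n)
    nb <- sum(bad)
    if (nb) {
      fac <- ifelse(runif(nb) < 0.5, runif(nb, 0.20, 0.55),
                    runif(nb, 1.8, 3.0))
      X[bad] <- X[bad] * fac
    }
  }

  # head-size scaling: isometric power law per parameter; contrast gets the
  # sequence factor instead
  expo <- etiv_exponents()
  nvec <- ifelse(mf$kind == "volume", expo[["volume"]], expo[mf$parameter])
  etiv <- subjects$etiv[sessions$subject]
  ratio <- etiv / config$etiv_mean
  for (j in which(!is.na(nvec) & nvec != 0)) {
    X[, j] <- X[, j] * ratio^nvec[j]
  }
  pct <- which(mf$parameter == "pctmean")
  pf <- w$pct_factor[cbind(rep(fu[pct], each = n),
                           rep(match(sessions$scanner, config$scanners),
                               length(pct)))]
  X[, pct] <- X[, pct] * matrix(pf, n, length(pct))
  X[X < 0] <- 0

  out <- data.frame(subject_id = subjects$subject_id[sessions$subject],
                    session_id = sessions$session_id,
                    age = sessions$age,
                    sex = subjects$sex[sessions$subject],
                    scanner_sequence = sessions$scanner,
                    etiv = etiv, stringsAsFactors = FALSE)
  X <- as.data.frame(X)
  names(X) <- mf$feature
  cbind(out, X)
}

.draw_subjects <- function(config, n, prefix) {
  data.frame(
    subject_id = sprintf("%s%03d", prefix, seq_len(n)),
    age0 = runif(n, config$age_range[1], config$age_range[2]),
    sex = sample(c("m", "f"), n, replace = TRUE, prob = c(0.47, 0.53)),
    etiv = pmax(1000, rnorm(n, config$etiv_mean, config$etiv_sd)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic normative control cohort
#'
#' Each scan's feature value is baseline age trend + subject-level biological
#' effect (shared across that subject's scans, correlated between hemispheres)
#' + scanner offset + measurement noise, scaled by the subject's head size;
#' a fraction `artifact_rate` of values is replaced by gross segmentation-like
#' artifacts. The designated repeat subjects receive a second scan within
#' three years.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; output is bitwise-reproducible given
#'   `(config, seed)`.
#' @return List with `cohort` (one row per scan: `subject_id`, `session_id`,
#'   `age`, `sex`, `scanner_sequence`, `etiv` and the 1,989 measured feature
#'   columns) and `repeat_pairs` (data.frame of session-id pairs).
#' @export
generate_controls <- function(config = sim_config(), seed = 1L) {
  with_seed(seed, {
    subjects <- .draw_subjects(config, config$n_subjects, "HC")
    rep_idx <- seq_len(config$n_repeat_pairs)
    ses <- data.frame(
      subject = c(seq_len(config$n_subjects), rep_idx),
      visit = c(rep(1L, config$n_subjects), rep(2L, length(rep_idx)))
    )
    ses$age <- subjects$age0[ses$subject] +
      ifelse(ses$visit == 2L, runif(nrow(ses), 0.3, 2.8), 0)
    ses$scanner <- sample(config$scanners, nrow(ses), replace = TRUE,
                          prob = config$scanner_probs)
    ses$session_id <- sprintf("%s_s%d", subjects$subject_id[ses$subject],
                              ses$visit)
    cohort <- .synth_scans(config, subjects, ses, config$artifact_rate)
    pairs <- data.frame(
      subject_id = subjects$subject_id[rep_idx],
      session_1 = sprintf("%s_s1", subjects$subject_id[rep_idx]),
      session_2 = sprintf("%s_s2", subjects$subject_id[rep_idx]),
      stringsAsFactors = FALSE
    )
    list(cohort = cohort, repeat_pairs = pairs)
  })
}

#' Default injected effect templates per TLE subtype
#'
#' Effect sizes are in units of the feature's total control SD
#' (biological + measurement). Mesial subtypes centre on unilateral
#' hippocampal atrophy with mesiotemporal involvement; lateral subtypes on
#' lateral temporal thinning and grey-matter loss. Right-sided subtypes mirror
#' the left templates.
#'
#' @param subtype One of `"MTLE-HS-left"`, `"MTLE-HS-right"`, `"LTLE-left"`,
#'   `"LTLE-right"`.
#' @return data.frame with columns `region`, `parameter`, `side`, `size`.
#' @export
default_subtype_effects <- function(subtype) {
  mtle <- data.frame(
    region = c("Hippocampus", "Amygdala", "entorhinal", "superiortemporal",
               "temporalpole"),
    parameter = c("volume", "volume", "thickavg", "thickavg", "thickavg"),
    side = "left",
    size = c(-4, -1.5, -2, -2, -1.5),
    stringsAsFactors = FALSE
  )
  ltle <- data.frame(
    region = c("superiortemporal", "middletemporal", "inferiortemporal",
               "superiortemporal", "middletemporal"),
    parameter = c("thickavg", "thickavg", "thickavg", "grayvol", "grayvol"),
    side = "left",
    size = c(-2.5, -2.5, -2, -2, -2),
    stringsAsFactors = FALSE
  )
  eff <- switch(subtype,
                "MTLE-HS-left" = mtle,
                "MTLE-HS-right" = transform(mtle, side = "right"),
                "LTLE-left" = ltle,
                "LTLE-right" = transform(ltle, side = "right"),
                stop("unknown subtype: ", subtype))
  eff
}

# mesiotemporal / lateral temporal label sets used for synthetic resections
.resection_regions <- function(subtype) {
  if (grepl("^MTLE", subtype)) {
    c("Hippocampus", "Amygdala", "entorhinal", "parahippocampal",
      "temporalpole")
  } else {
    c("superiortemporal", "middletemporal", "inferiortemporal")
  }
}

#' Generate a synthetic TLE patient cohort with ground truth
#'
#' Control-like scans with the subtype's effect template added (scaled by
#' `effect_scale`). Ground truth lists the injected regions as expert-annotated
#' lesions, an EEG lateralization equal to the injected hemisphere (flipped
#' with probability `eeg_discordance`), and for a `surgery_fraction` subset a
#' resection covering the subtype's temporal target with Engel class I and
#' 12-month follow-up. Patients are artifact-free by default, emulating
#' datasets that passed quality control.
#'
#' @param config A [sim_config()].
#' @param subtype See [default_subtype_effects()].
#' @param n_patients Number of patients.
#' @param seed Integer seed.
#' @param effects Effect template; defaults to the subtype's.
#' @param effect_scale Multiplier on all effect sizes (0 gives null patients).
#' @param n_repeat Patients receiving a second scan.
#' @param eeg_discordance Probability that the EEG lateralization contradicts
#'   the injected side.
#' @param surgery_fraction Fraction of patients with a favorable-outcome
#'   resection in the ground truth.
#' @param artifact_rate Artifact contamination of patient scans.
#' @param id_prefix Prefix of the generated subject identifiers.
#' @return List with `cohort` and `ground_truth` (one row per scan; columns
#'   `dataset_id`, `subject_id`, `subtype`, `expert_regions`
#'   (";"-separated `region:hemisphere`), `eeg_lateralization`,
#'   `resection_hemisphere`, `resection_lobe`, `resection_regions`,
#'   `engel_class`, `followup_months`).
#' @export
generate_patients <- function(config = sim_config(), subtype = "MTLE-HS-left",
                              n_patients = 20, seed = 1L,
                              effects = default_subtype_effects(subtype),
                              effect_scale = 1, n_repeat = 0,
                              eeg_discordance = 0, surgery_fraction = 0.5,
                              artifact_rate = 0, id_prefix = "PT") {
  eff <- effects
  eff$size <- eff$size * effect_scale
  side <- if (grepl("right$", subtype)) "right" else "left"
  with_seed(seed, {
    subjects <- .draw_subjects(config, n_patients, id_prefix)
    # patients skew adult
    subjects$age0 <- pmin(config$age_range[2] - 1,
                          pmax(18, subjects$age0))
    rep_idx <- seq_len(min(n_repeat, n_patients))
    ses <- data.frame(
      subject = c(seq_len(n_patients), rep_idx),
      visit = c(rep(1L, n_patients), rep(2L, length(rep_idx)))
    )
    ses$age <- subjects$age0[ses$subject] +
      ifelse(ses$visit == 2L, runif(nrow(ses), 0.3, 2.8), 0)
    ses$scanner <- sample(config$scanners, nrow(ses), replace = TRUE,
                          prob = config$scanner_probs)
    ses$session_id <- sprintf("%s_s%d", subjects$subject_id[ses$subject],
                              ses$visit)
    cohort <- .synth_scans(config, subjects, ses, artifact_rate, eff)

    eeg_subj <- ifelse(runif(n_patients) < eeg_discordance,
                       setdiff(c("left", "right"), side), side)
    n_surg <- round(surgery_fraction * n_patients)
    surg_subj <- seq_len(n_patients) %in%
      sample(seq_len(n_patients), n_surg)
    lesional <- any(eff$size != 0)
    gt <- data.frame(
      dataset_id = ses$session_id,
      subject_id = subjects$subject_id[ses$subject],
      subtype = subtype,
      expert_regions = if (lesional) {
        paste(paste(eff$region, eff$side, sep = ":"), collapse = ";")
      } else "",
      eeg_lateralization = eeg_subj[ses$subject],
      resection_hemisphere = ifelse(surg_subj[ses$subject], side, NA),
      resection_lobe = ifelse(surg_subj[ses$subject], "temporal", NA),
      resection_regions = ifelse(surg_subj[ses$subject],
                                 paste(.resection_regions(subtype),
                                       collapse = ";"), NA),
      engel_class = ifelse(surg_subj[ses$subject], "I", NA),
      followup_months = ifelse(surg_subj[ses$subject], 12, NA),
      stringsAsFactors = FALSE
    )
    list(cohort = cohort, ground_truth = gt)
  })
}
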