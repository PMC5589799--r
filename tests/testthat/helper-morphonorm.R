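# Shared fixtures, built once per test run. The normative model is fitted on
# the default study conditions (300 control scans of 260 subjects, 40 repeat
# pairs) and reused across files.

.mn_cache <- new.env(parent = emptyenv())

mn_world <- function() {
  if (is.null(.mn_cache$cfg)) .mn_cache$cfg <- sim_config()
  .mn_cache$cfg
}

mn_controls <- function() {
  if (is.null(.mn_cache$controls)) {
    .mn_cache$controls <- generate_controls(mn_world(), seed = 101)
  }
  .mn_cache$controls
}

mn_model <- function() {
  if (is.null(.mn_cache$model)) {
    .mn_cache$model <- fit_normative(mn_controls()$cohort)
  }
  .mn_cache$model
}

# one null (zero-effect, artifact-free) scan in cohort format
mn_null_scan <- function(seed = 555) {
  generate_patients(mn_world(), "MTLE-HS-left", n_patients = 1, seed = seed,
                    effect_scale = 0)$cohort
}

# a synthetic profile with chosen L/p entries, everything else null (p = 1)
mn_flat_profile <- function(model, set = NULL, variant = "normalized") {
  sch <- model$schema
  one <- data.frame(
    feature = sch$feature, region = sch$region, parameter = sch$parameter,
    side = sch$side, variant = variant, value = 0, predicted = 0, se = 1,
    z = 0, sign = 0, p = 1, L = 0, flag = "none", stringsAsFactors = FALSE
  )
  if (!is.null(set)) {
    i <- match(set$feature, one$feature)
    stopifnot(!anyNA(i))
    one$p[i] <- set$p
    one$sign[i] <- set$sign
    one$L[i] <- signed_log_feature(set$p, set$sign)
  }
  structure(one, dataset_id = "synthetic", age = 40, extrapolated = FALSE,
            alpha = 0.01, q = 0.01,
            class = c("abnormality_profile", "data.frame"))
}
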