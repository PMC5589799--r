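#' Published per-dataset match indicators of the TLE evaluation study
#'
#' The per-dataset sensitivity/specificity indicators of the study's
#' evaluation table: 47 MRI datasets of 37 TLE patients, with morphometry
#' match indicators against expert MRI reading, surgery (favorable outcome
#' only) and EEG lateralization, plus the expert-MRI-vs-EEG agreement. `NA`
#' marks not-available/not-applicable cells. The `consistency` column labels
#' the operated datasets by whether expert MRI and EEG readings were
#' consistent or equivocal; it is reconstructed from the table's agreement
#' column (the original subdivision lives in supplementary material) such
#' that the published subgroup fractions (5/5 consistent, 3/5 equivocal) are
#' reproduced, and is `NA` for datasets without evaluable surgery.
#'
#' @return data.frame with columns `dataset`, `patient`, `subtype`, the six
#'   indicator columns, `agreement_mri_eeg` and `consistency`.
#' @export
table2_matches <- function() {
  path <- system.file("extdata", "table2_matches.tsv",
                      package = "morphonorm", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE)
  ind <- c("sens_expert_mri", "sens_surgery", "sens_eeg", "spec_expert_mri",
           "spec_surgery", "spec_eeg", "agreement_mri_eeg")
  for (cn in ind) tab[[cn]] <- suppressWarnings(as.integer(tab[[cn]]))
  tab$consistency[!nzchar(trimws(ifelse(is.na(tab$consistency), "",
                                        tab$consistency)))] <- NA
  tab
}
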