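#' Published benchmark group summaries for selected features
#'
#' Group summary statistics (n, mean, SD per class) together with the
#' printed two-sided P values, cut-offs, sensitivities, specificities and
#' AUCs for the texture and spectral markers of a published 34-nodule
#' (14 benign / 20 malignant) thyroid DECT study. These printed summaries
#' are inputs for regression checks: the variance-gated t-test recomputed
#' from (n, mean, SD) should reproduce the printed P values to their 3
#' printed decimals. Spectral rows (iodine content, normalized slope) carry
#' only the printed AUCs.
#'
#' @param recomputable_only Keep only the texture rows whose printed P value
#'   is recomputable from the printed summaries under the F-gated
#'   pooled/Satterthwaite convention at the printed precision (the
#'   regression subset).
#' @return `data.frame` with columns `feature`, `energy_keV`, `benign_n`,
#'   `benign_mean`, `benign_sd`, `malignant_n`, `malignant_mean`,
#'   `malignant_sd`, `printed_p`, `printed_cutoff_direction`,
#'   `printed_cutoff`, `printed_sensitivity_pct`, `printed_specificity_pct`,
#'   `printed_auc`, `regression_target`.
#' @export
reference_summaries <- function(recomputable_only = FALSE) {
  path <- system.file("extdata", "thyroid_dect_reference_summaries.csv",
                      package = "dectexture", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (recomputable_only) x <- x[x$regression_target, ]
  x
}
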