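#' Reference predicted genotypic values (published study table)
#'
#' The printed per-progeny results of the RV-02 tropical maize
#' recurrent-selection evaluation: BLUPs and predicted additive genotypic
#' values for grain yield (kg/ha) together with BLUPs and predicted values
#' for inbreeding depression (%) of the ten top-ranked half-sib progenies,
#' plus the mean row over the 38 selected progenies
#' (`progeny = "selected_mean"`). Shipped as a plain-text CSV in
#' `inst/extdata`; used as worked-example input for the genotypic-value
#' identity `genotypic value = base mean + BLUP` (the base means implied by
#' the mean row are 4025 - 558 = 3467 kg/ha for grain yield and
#' 43.1 - (-7.9) = 51.0 for inbreeding depression).
#'
#' @return A data frame with columns `progeny`, `blup_gy`,
#'   `genotypic_value_gy`, `blup_id`, `genotypic_value_id`.
#' @examples
#' ref <- reference_genotypic_values()
#' mean_row <- ref[ref$progeny == "selected_mean", ]
#' mean_row$genotypic_value_gy - mean_row$blup_gy # implied base mean
#' @export
reference_genotypic_values <- function() {
  path <- system.file("extdata", "reference_genotypic_values.csv",
                      package = "recsel", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(progeny = "character"))
}
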