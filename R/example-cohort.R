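#' Example carrier table from a two-ancestry prostate cancer case cohort
#'
#' A curated table of germline potentially pathogenic SV carriers in a case
#' series of 113 African and 57 European prostate cancer patients, shipped
#' as a worked example for the reporting functions.  One row per
#' (patient, SV): the disrupted gene (or fusion), the final classification
#' (`PP_SV` or `cautionary`), whether the call rests on a known
#' pathogenic/likely-pathogenic archive entry (`clinvar` of `"P"`, `"LP"`
#' or `"none"`), the SV and impact type, the estimated variant allele
#' fraction, and the patient's ancestry, age (years), PSA (ng/mL), ISUP
#' grade group (`NA` = unknown), tumour LOH status and somatic second hit.
#'
#' @return `data.frame` with 24 carrier rows.
#' @seealso [example_cohort_patients()], [carrier_fraction()],
#'   [aggressive_fraction()]
#' @export
example_carriers <- function() {
  rows <- rbind(
    c("SLC3A1",        "PP_SV", "LP",   "N0001",   "DUP", "IED",  0.33, "AFR", 75, 22.9, 4,  "LOH_neg", "none"),
    c("SLC3A1",        "PP_SV", "LP",   "SMU094",  "DUP", "IED",  0.30, "AFR", 64, 15.0, 4,  "LOH_CNG", "CNL"),
    c("OCA2",          "PP_SV", "LP",   "N0059",   "DEL", "pLoF", 0.45, "AFR", 79, 153,  5,  "LOH_neg", "CNG"),
    c("PIGN",          "PP_SV", "P",    "SMU083",  "DEL", "pLoF", 0.51, "AFR", 86, 40.5, 3,  "LOH_CNL", "none"),
    c("SLC7A2",        "PP_SV", "none", "UP2035",  "DEL", "pLoF", 0.48, "AFR", 70, 680,  5,  "LOH_neg", "CNL"),
    c("SLC7A2",        "PP_SV", "none", "KAL0054", "DEL", "pLoF", 0.49, "AFR", 64, 42.9, 5,  "LOH_CNG", "none"),
    c("DNAJC15",       "PP_SV", "none", "17135",   "DEL", "pLoF", 0.48, "EUR", 63, 7.8,  5,  "LOH_neg", "none"),
    c("BCL2L11",       "PP_SV", "none", "KAL0101", "DEL", "pLoF", 0.45, "AFR", 71, 32.3, 5,  "LOH_CNN", "none"),
    c("BARD1",         "PP_SV", "none", "N0073",   "DEL", "pLoF", 0.49, "AFR", 62, NA,   NA, "LOH_CNN", "none"),
    c("COL4A2/COL4A1", "PP_SV", "none", "UP2039",  "DUP", "CG",   0.35, "AFR", 71, 319,  4,  "LOH_neg", "none"),
    c("SLC2A5",        "PP_SV", "none", "11099",   "DUP", "IED",  0.33, "EUR", 70, 9.9,  5,  "LOH_neg", "none"),
    c("FOXP1",         "PP_SV", "none", "UP2101",  "INV", "pLoF", 0.41, "AFR", 57, 75,   5,  "LOH_neg", "CNG"),
    c("FOXP1",         "PP_SV", "none", "N0084",   "INV", "pLoF", 0.41, "AFR", 65, 591,  4,  "LOH_neg", "none"),
    c("WASF1",         "PP_SV", "none", "N0048",   "INV", "pLoF", 0.32, "AFR", 70, 83.3, 5,  "LOH_neg", "CNG"),
    c("MLH1",          "PP_SV", "none", "SMU080",  "INV", "pLoF", 0.43, "AFR", 64, 23.3, 4,  "LOH_neg", "none"),
    c("RB1",           "PP_SV", "none", "SMU064",  "INV", "pLoF", 0.37, "AFR", 70, 13.7, 3,  "LOH_neg", "none"),
    c("CTNNA1",        "PP_SV", "none", "13179",   "TRA", "pLoF", 0.50, "EUR", 59, 8.4,  5,  "LOH_neg", "none"),
    c("AK8-DST",       "PP_SV", "none", "11452",   "TRA", "pLoF", 0.47, "EUR", 67, 11,   1,  "LOH_neg", "none"),
    c("LTBP1/BIRC6",   "cautionary", "none", "5287",   "DUP", "CG",   0.39, "EUR", 54, 4.3,  5, "LOH_neg", "CNG"),
    c("PHC3-PRKACA",   "cautionary", "none", "SMU061", "TRA", "pLoF", 0.49, "AFR", 65, 12.1, 3, "LOH_neg", "CNL"),
    c("KCTD3-DST",     "cautionary", "none", "UP2039", "TRA", "pLoF", 0.40, "AFR", 71, 319,  4, "LOH_neg", "CNL"),
    c("KCTD3-DST",     "cautionary", "none", "SMU101", "TRA", "pLoF", 0.42, "AFR", 70, 4.3,  3, "LOH_neg", "none"),
    c("PKHD1",         "cautionary", "none", "N0056",  "TRA", "pLoF", 0.36, "AFR", 70, 153,  5, "LOH_neg", "CNG"),
    c("PKHD1",         "cautionary", "none", "SMU196", "TRA", "pLoF", 0.39, "AFR", 47, 9.5,  1, "LOH_neg", "none")
  )
  out <- data.frame(
    gene = rows[, 1], final_class = rows[, 2], clinvar = rows[, 3],
    patient_id = rows[, 4], svtype = rows[, 5], impact = rows[, 6],
    vaf = as.numeric(rows[, 7]), ancestry = rows[, 8],
    age = as.integer(rows[, 9]), psa = as.numeric(rows[, 10]),
    isup_gg = as.integer(rows[, 11]), loh = rows[, 12],
    second_hit = rows[, 13], stringsAsFactors = FALSE
  )
  out$sv_id <- paste0("ex", seq_len(nrow(out)))
  out
}

#' Patient roster matching the example carrier table
#'
#' The 113 African and 57 European patients of the example cohort: carrier
#' patients keep their clinical columns from [example_carriers()];
#' non-carrier patients appear with anonymous ids and unknown clinical
#' values, which suffices for the denominator-based cohort statistics.
#'
#' @return `data.frame` with columns `patient_id`, `ancestry`, `isup_gg`.
#' @export
example_cohort_patients <- function() {
  carr <- example_carriers()
  seen <- !duplicated(carr$patient_id)
  known <- data.frame(patient_id = carr$patient_id[seen],
                      ancestry = carr$ancestry[seen],
                      isup_gg = carr$isup_gg[seen], stringsAsFactors = FALSE)
  n_afr <- 113 - sum(known$ancestry == "AFR")
  n_eur <- 57 - sum(known$ancestry == "EUR")
  filler <- data.frame(
    patient_id = c(sprintf("AFRX%03d", seq_len(n_afr)),
                   sprintf("EURX%03d", seq_len(n_eur))),
    ancestry = c(rep("AFR", n_afr), rep("EUR", n_eur)),
    isup_gg = NA_integer_, stringsAsFactors = FALSE)
  rbind(known, filler)
}
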