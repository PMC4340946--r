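#' The five urinary glucocorticoid analytes
#'
#' Column names used for the analyte panel summed into total uGC: cortisol
#' plus four of its major urinary metabolites (tetrahydrocortisol,
#' tetrahydrocortisone, 5beta-androstane, 11-oxoetiocholanolone). All are
#' concentrations in ng per ml urine.
#'
#' @format Character vector of length 5.
#' @export
ugc_analytes <- c("cortisol", "tetrahydrocortisol", "tetrahydrocortisone",
                  "androstane_5b", "oxoetiocholanolone_11")

## average composition of total uGC across the five analytes, used by the
## simulator to split totals into an analyte panel
ugc_composition <- c(cortisol = 0.09, tetrahydrocortisol = 0.37,
                     tetrahydrocortisone = 0.35, androstane_5b = 0.05,
                     oxoetiocholanolone_11 = 0.14)
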