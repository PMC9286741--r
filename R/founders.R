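#' Canonical founder order for the diversity outbred population
#'
#' The eight inbred founder strains of the DO population, in the standard
#' letter-code order A-H. All founder-probability arrays, founder-genotype
#' tables and founder allele pattern (FAP) labels produced by this package
#' use this order; FAP strings join founder names with `/` sorted in this
#' order, so labels are canonical and comparable across loci.
#'
#' @format Character vector of length 8:
#'   `AJ, B6, 129, NOD, NZO, CAST, PWK, WSB`.
#' @export
DO_FOUNDERS <- c("AJ", "B6", "129", "NOD", "NZO", "CAST", "PWK", "WSB")

#' The five dietary interventions
#'
#' Diet groups imposed at the intervention age: ad libitum (AL), 20% and 40%
#' daily calorie restriction, and 1- or 2-day-per-week intermittent fasting.
#'
#' @format Character vector of length 5.
#' @export
DO_DIETS <- c("AL", "20", "40", "1D", "2D")

# internal: stop with a classed validation error so callers/tests can
# distinguish bad data from bad code
stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dietqtl_validation_error", "error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dietqtl_format_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
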