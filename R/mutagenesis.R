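#' Template duplications of one PCR round
#'
#' The number of doublings a template pool underwent, computed from the
#' double-stranded DNA mass before (\code{input_mass}) and after
#' (\code{output_mass}) amplification: \code{D = ln(O / I) / ln 2}. Only the
#' mass ratio enters, so any common unit works.
#'
#' @param input_mass,output_mass positive DNA quantities in the same unit,
#'   with \code{output_mass >= input_mass}.
#' @return number of duplications (full precision; round to one decimal for
#'   reporting, see [round1()]).
#' @export
pcr_duplications <- function(input_mass, output_mass) {
  if (any(input_mass <= 0) || any(output_mass <= 0)) {
    stop("masses must be positive")
  }
  if (any(output_mass < input_mass)) {
    stop("output mass below input mass: no amplification")
  }
  log(output_mass / input_mass) / log(2)
}

#' Expected mutation load of an error-prone PCR protocol
#'
#' \code{Nmut = mu * D * L} with \code{mu} the polymerase error rate per
#' nucleotide per duplication, \code{D} the total number of template
#' duplications summed over the protocol's rounds, and \code{L} the amplicon
#' length in bp. A typical error-prone Taq under mutagenic conditions has
#' \code{mu} around 3e-5.
#'
#' @param mu error rate per nucleotide per duplication (>= 0).
#' @param amplicon_length amplicon length in bp (> 0).
#' @param rounds data frame with columns \code{input_mass} and
#'   \code{output_mass}, one row per PCR round.
#' @return list with \code{duplications} (per round), \code{total_duplications}
#'   and \code{n_mut}, all at full precision.
#' @export
expected_mutations <- function(mu, amplicon_length, rounds) {
  stopifnot(is.numeric(mu), mu >= 0, amplicon_length > 0,
            all(c("input_mass", "output_mass") %in% names(rounds)))
  d <- pcr_duplications(rounds$input_mass, rounds$output_mass)
  list(
    duplications = d,
    total_duplications = sum(d),
    n_mut = mu * sum(d) * amplicon_length
  )
}

#' Round to one decimal, the reporting precision for PCR mutation loads
#' @param x numeric.
#' @return \code{x} rounded to one decimal place.
#' @export
round1 <- function(x) round(x, 1)
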