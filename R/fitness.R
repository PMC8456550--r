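#' Number of generations from initial and final cell densities
#'
#' \code{log2(n_final / n_initial)}: the number of population doublings
#' during a growth interval, estimated from optical-density measurements.
#'
#' @param n_initial,n_final positive cell densities (any common unit).
#' @return generations of growth.
#' @export
estimate_generations <- function(n_initial, n_final) {
  if (any(n_initial <= 0) || any(n_final <= 0)) {
    stop("cell densities must be positive")
  }
  log2(n_final / n_initial)
}

#' Competitive fitness from two-fluorophore co-culture counts
#'
#' The fitness of the YFP-tagged strain relative to the GFP-tagged
#' competitor is the exponential of the slope of the ordinary least-squares
#' regression of \code{ln(yfp_count / gfp_count)} on cumulative generations
#' of co-growth. With exactly two timepoints this reduces to
#' \code{exp(delta ln-ratio / delta generations)}. Only the count ratio
#' matters: scaling both channels by a constant leaves the estimate
#' unchanged.
#'
#' @param generations cumulative generations at each timepoint (>= 2 distinct
#'   values).
#' @param yfp_count,gfp_count positive event counts per timepoint.
#' @return the fitness ratio (1 = neutral).
#' @export
competitive_fitness <- function(generations, yfp_count, gfp_count) {
  stopifnot(length(generations) == length(yfp_count),
            length(generations) == length(gfp_count))
  if (length(generations) < 2) stop("need at least two timepoints")
  if (any(yfp_count <= 0) || any(gfp_count <= 0)) {
    stop("counts must be positive at all used timepoints")
  }
  if (stats::var(generations) == 0) {
    stop("singular fit: all timepoints at the same generation count")
  }
  lr <- log(yfp_count / gfp_count)
  slope <- stats::cov(generations, lr) / stats::var(generations)
  exp(slope)
}

#' Fitness relative to the mean of a reference strain's replicates
#'
#' Divides each fitness value by the mean fitness of the reference
#' replicates, so the reference's own relative values average to 1.
#'
#' @param fitness_values fitness estimates to normalize.
#' @param reference_fitness_values fitness estimates of the reference strain
#'   replicates (positive mean).
#' @return relative fitness values.
#' @export
relative_fitness <- function(fitness_values, reference_fitness_values) {
  m <- mean(reference_fitness_values)
  if (!is.finite(m) || m <= 0) stop("reference mean fitness must be positive")
  fitness_values / m
}
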