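#' Signed bulk-segregant association test for one variant
#'
#' Tests whether the alternate-allele frequency differs between the low and
#' high fluorescence bulks with a 2x2 G-test on read counts, and attaches a
#' direction sign: \code{+1} if the alternate (mutant) allele is more frequent
#' in the high fluorescence bulk, \code{-1} if more frequent in the low bulk,
#' and \code{0} if the two bulk frequencies are equal.
#'
#' @param low_ref,low_alt reference and alternate read counts in the low
#'   fluorescence bulk.
#' @param high_ref,high_alt reference and alternate read counts in the high
#'   fluorescence bulk.
#' @return a \code{"g_test"} list with elements \code{G}, \code{df}, \code{p}
#'   and \code{sign}.
#' @export
signed_association <- function(low_ref, low_alt, high_ref, high_alt) {
  res <- g_test_2x2(low_ref, low_alt, high_ref, high_alt)
  f_low <- low_alt / (low_ref + low_alt)
  f_high <- high_alt / (high_ref + high_alt)
  res$sign <- as.integer(sign(f_high - f_low))
  res
}

#' Call variants associated with the phenotype from per-variant bulk counts
#'
#' Runs [signed_association()] on every row of a bulk-count table and calls a
#' variant associated with fluorescence (directly or through linkage) when the
#' G-test p-value falls below \code{alpha}. The expected number of false
#' positives, \code{nrow(counts) * alpha}, is attached as an attribute so the
#' type-I burden of a screen is always visible (e.g. 1.82 expected false
#' calls for 1819 variants at alpha = 0.001).
#'
#' @param counts a data frame with columns \code{low_ref}, \code{low_alt},
#'   \code{high_ref}, \code{high_alt} and optionally \code{variant_id}.
#' @param alpha per-test significance level, default 0.001.
#' @return the input data frame with added columns \code{G}, \code{p},
#'   \code{sign} and logical \code{associated}; attribute
#'   \code{"expected_false_positives"}.
#' @export
call_associations <- function(counts, alpha = 0.001) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  need <- c("low_ref", "low_alt", "high_ref", "high_alt")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "))
  }
  n <- nrow(counts)
  G <- p <- numeric(n)
  sgn <- integer(n)
  for (i in seq_len(n)) {
    r <- signed_association(counts$low_ref[i], counts$low_alt[i],
                            counts$high_ref[i], counts$high_alt[i])
    G[i] <- r$G; p[i] <- r$p; sgn[i] <- r$sign
  }
  out <- counts
  out$G <- G
  out$p <- p
  out$sign <- sgn
  out$associated <- p < alpha
  attr(out, "expected_false_positives") <- n * alpha
  out
}

#' G-test for association of a whole-chromosome aneuploidy
#'
#' Compares the proportion of reads mapping to the aneuploid chromosome
#' (versus the rest of the genome) between the low and high fluorescence
#' bulks. Identical to [g_test_2x2()] on the corresponding table; an
#' aneuploidy with \eqn{G > 10.828} (p < 0.001) is considered present at
#' different frequencies in the two bulks.
#'
#' @param chrom_low,rest_low read counts on the aneuploid chromosome and on
#'   the rest of the genome in the low fluorescence bulk.
#' @param chrom_high,rest_high the same counts in the high fluorescence bulk.
#' @return a \code{"g_test"} list.
#' @export
aneuploidy_g_test <- function(chrom_low, rest_low, chrom_high, rest_high) {
  g_test_2x2(chrom_low, rest_low, chrom_high, rest_high)
}

#' Flag candidate aneuploid chromosomes from mean coverage
#'
#' A chromosome is flagged when its mean sequencing coverage divided by the
#' median coverage of all other chromosomes reaches \code{ratio_threshold}.
#' Trisomic chromosomes in segregant pools from a disomic x euploid cross
#' show roughly 1.5-fold elevated coverage, hence the default of 1.4.
#'
#' @param coverage a data frame with columns \code{chrom} and
#'   \code{mean_coverage}, one row per chromosome (at least two rows).
#' @param ratio_threshold coverage ratio at or above which a chromosome is
#'   flagged; default 1.4.
#' @return the input with added columns \code{ratio} and logical
#'   \code{aneuploid}.
#' @export
detect_aneuploidy <- function(coverage, ratio_threshold = 1.4) {
  stopifnot(all(c("chrom", "mean_coverage") %in% names(coverage)))
  if (nrow(coverage) < 2) stop("need coverage for at least two chromosomes")
  n <- nrow(coverage)
  ratio <- vapply(seq_len(n), function(i) {
    coverage$mean_coverage[i] / stats::median(coverage$mean_coverage[-i])
  }, numeric(1))
  coverage$ratio <- ratio
  coverage$aneuploid <- ratio >= ratio_threshold
  coverage
}

#' Group associated mutations into linkage groups
#'
#' Single-linkage clustering of mutations within each chromosome: two
#' mutations are linked when their genetic distance is below
#' \code{threshold_cM}, and a group is any chain of such pairs. Mutations on
#' different chromosomes are never linked. On a line, single linkage reduces
#' to breaking the sorted positions wherever the gap to the next mutation
#' reaches the threshold.
#'
#' @param mutations a data frame with columns \code{chrom} and \code{cM}
#'   (genetic-map coordinate within the chromosome). Physical coordinates can
#'   be converted with a genome-average map density, e.g. 0.4 cM/kb for
#'   S. cerevisiae.
#' @param threshold_cM linkage threshold in centimorgans; default 25.
#' @return the input with an added integer column \code{linkage_group};
#'   groups are numbered in input order of first appearance.
#' @export
group_linked <- function(mutations, threshold_cM = 25) {
  stopifnot(all(c("chrom", "cM") %in% names(mutations)))
  if (any(!is.finite(mutations$cM))) {
    stop("every mutation needs a finite genetic-map coordinate (cM)")
  }
  n <- nrow(mutations)
  grp <- integer(n)
  next_id <- 1L
  for (ch in unique(mutations$chrom)) {
    idx <- which(mutations$chrom == ch)
    o <- idx[order(mutations$cM[idx])]
    gaps <- diff(mutations$cM[o])
    brk <- cumsum(c(0L, as.integer(gaps >= threshold_cM)))
    grp[o] <- next_id + brk
    next_id <- next_id + max(brk) + 1L
  }
  # renumber by first appearance in input order
  grp <- match(grp, unique(grp))
  mutations$linkage_group <- grp
  mutations
}

#' Parametric bootstrap comparing the association strength of linked variants
#'
#' When several linked mutations are all associated with the phenotype, only
#' one of them is usually causal. This test asks whether the variant with the
#' larger observed G statistic (\code{counts_a}) is significantly more
#' strongly associated than a linked competitor (\code{counts_b}). For each
#' resample, alternate read counts are redrawn for each variant and bulk as
#' Binomial(observed depth, observed alternate frequency) and both G
#' statistics are recomputed; the p-value is the fraction of resamples in
#' which the resampled G of variant a does not exceed that of variant b.
#' p < 0.05 declares variant a the stronger candidate.
#'
#' @param counts_a,counts_b named numeric vectors or one-row data frames with
#'   elements \code{low_ref}, \code{low_alt}, \code{high_ref},
#'   \code{high_alt}; \code{counts_a} must have the larger observed G.
#' @param n_resamples number of bootstrap resamples (at least 100).
#' @param seed optional integer seed for reproducibility.
#' @return the bootstrap p-value (raw resample fraction).
#' @export
compare_linked_g <- function(counts_a, counts_b, n_resamples = 10000,
                             seed = NULL) {
  if (n_resamples < 100) stop("n_resamples < 100 gives unstable p-values")
  if (!is.null(seed)) set.seed(seed)
  grab <- function(x) {
    x <- unlist(x)[c("low_ref", "low_alt", "high_ref", "high_alt")]
    if (any(is.na(x))) stop("counts need low_ref, low_alt, high_ref, high_alt")
    x
  }
  a <- grab(counts_a); b <- grab(counts_b)
  g_obs_a <- g_test_2x2(a[1], a[2], a[3], a[4])$G
  g_obs_b <- g_test_2x2(b[1], b[2], b[3], b[4])$G
  if (g_obs_a < g_obs_b) {
    stop("counts_a must be the variant with the larger observed G")
  }
  boot_g <- function(x) {
    d_low <- x[1] + x[2]; d_high <- x[3] + x[4]
    alt_low <- stats::rbinom(n_resamples, d_low, x[2] / d_low)
    alt_high <- stats::rbinom(n_resamples, d_high, x[4] / d_high)
    vapply(seq_len(n_resamples), function(i) {
      g_test_2x2(d_low - alt_low[i], alt_low[i],
                 d_high - alt_high[i], alt_high[i])$G
    }, numeric(1))
  }
  ga <- boot_g(a)
  gb <- boot_g(b)
  mean(ga <= gb)
}
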