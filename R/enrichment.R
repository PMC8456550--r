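#' Contrast a categorical property between two mutation sets
#'
#' Builds the 2 x k contingency table of set membership (trans-regulatory vs
#' non-regulatory) against the categories produced by
#' \code{property_extractor}, and applies the r x c G-test. Used for
#' spectrum classes, region classes, coding-effect classes, per-chromosome
#' distributions, or any user-supplied gene-category map.
#'
#' @param trans_set,nonreg_set data frames of mutations.
#' @param property_extractor function mapping a mutation data frame to a
#'   vector of category labels (one per row).
#' @return a list with the contingency \code{table} (rows \code{trans},
#'   \code{nonreg}), the \code{g_test} result, and the per-set category
#'   \code{proportions}.
#' @export
compare_mutation_property <- function(trans_set, nonreg_set,
                                      property_extractor) {
  pt <- property_extractor(trans_set)
  pn <- property_extractor(nonreg_set)
  lev <- sort(unique(c(pt, pn)))
  tab <- rbind(
    trans = table(factor(pt, levels = lev)),
    nonreg = table(factor(pn, levels = lev))
  )
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  list(
    table = tab,
    g_test = g_test_rxc(tab),
    proportions = sweep(tab, 1, rowSums(tab), "/")
  )
}

#' Amino-acid change frequency matrix of a coding mutation set
#'
#' Returns a 21 x 21 matrix (20 amino acids plus stop, one-letter codes) of
#' percentage frequencies: cell (i, j) is 100 times the fraction of the
#' set's mutations changing amino acid i into amino acid j. Cells for
#' changes not observed carry \code{NA} ("absent") rather than zero, and the
#' observed frequencies sum to 100.
#'
#' @param mutations data frame with \code{aa_from} and \code{aa_to} columns
#'   set on every row.
#' @return a 21 x 21 numeric matrix of percentages with \code{NA} for
#'   unobserved changes.
#' @export
aa_change_matrix <- function(mutations) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V", "*")
  if (any(is.na(mutations$aa_from)) || any(is.na(mutations$aa_to))) {
    stop("aa_from/aa_to must be set on all input mutations")
  }
  counts <- table(factor(mutations$aa_from, levels = aa),
                  factor(mutations$aa_to, levels = aa))
  m <- 100 * counts / sum(counts)
  m <- unclass(m)
  m[counts == 0] <- NA_real_
  m
}

#' Difference of amino-acid change frequencies between two sets
#'
#' Cell-wise \code{trans percentage - nonreg percentage}, treating absent
#' cells as 0 in the subtraction but returning \code{NA} where the change is
#' observed in neither set.
#'
#' @param trans_set,nonreg_set coding mutation data frames with
#'   \code{aa_from}/\code{aa_to}.
#' @return a 21 x 21 difference matrix in percentage points.
#' @export
aa_change_difference <- function(trans_set, nonreg_set) {
  mt <- aa_change_matrix(trans_set)
  mn <- aa_change_matrix(nonreg_set)
  both_na <- is.na(mt) & is.na(mn)
  mt[is.na(mt)] <- 0; mn[is.na(mn)] <- 0
  d <- mt - mn
  d[both_na] <- NA_real_
  d
}

#' Permutation test for enrichment of an amino-acid change category
#'
#' The statistic is the absolute difference between the proportion of
#' trans-regulatory and the proportion of non-regulatory coding mutations
#' falling in \code{target_category} - either a specific change
#' (\code{c(from = "G", to = "D")}) or all changes from one amino acid
#' (\code{c(from = "G")}). The null is built by permuting set labels over the
#' pooled mutations, holding set sizes fixed; the p-value is the raw
#' fraction of permuted statistics greater than or equal to the observed one
#' (it can be 0 at finite permutation counts).
#'
#' @param trans_set,nonreg_set coding mutation data frames with
#'   \code{aa_from}/\code{aa_to}.
#' @param target_category named character vector with element \code{from} and
#'   optionally \code{to}.
#' @param n_perm number of label permutations; default 10000.
#' @param seed optional integer seed.
#' @return a list with \code{observed} (absolute proportion difference) and
#'   \code{p}.
#' @export
aa_permutation_test <- function(trans_set, nonreg_set, target_category,
                                n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  in_cat <- function(from, to) {
    hit <- from == target_category[["from"]]
    if ("to" %in% names(target_category)) {
      hit <- hit & to == target_category[["to"]]
    }
    hit
  }
  x <- c(in_cat(trans_set$aa_from, trans_set$aa_to),
         in_cat(nonreg_set$aa_from, nonreg_set$aa_to))
  n1 <- nrow(trans_set); n <- length(x)
  stat <- function(lab1) abs(mean(x[lab1]) - mean(x[-lab1]))
  obs <- stat(seq_len(n1))
  perm <- vapply(seq_len(n_perm), function(i) {
    stat(sample.int(n, n1))
  }, numeric(1))
  list(observed = obs, p = mean(perm >= obs))
}

#' Resampling test for over-dispersion of per-strain mutation counts
#'
#' Mutation counts from a homogeneous mutagenesis process should be Poisson;
#' cell-to-cell heterogeneity (e.g. in DNA repair) produces more strains far
#' from the average than Poisson predicts. The statistic is the dispersion
#' index (sample variance / sample mean); the null distribution is obtained
#' by resampling count vectors of the same size from Poisson(sample mean).
#' The p-value is the raw fraction of null statistics greater than or equal
#' to the observed one.
#'
#' @param counts integer vector of per-strain mutation counts (at least 5).
#' @param n_resamples number of Poisson resamples; default 100000.
#' @param seed optional integer seed.
#' @return a list with \code{dispersion} and \code{p}.
#' @export
poisson_dispersion_test <- function(counts, n_resamples = 100000,
                                    seed = NULL) {
  if (length(counts) < 5) stop("need at least 5 strains")
  m <- mean(counts)
  if (m == 0) stop("mean count is zero; dispersion undefined")
  if (!is.null(seed)) set.seed(seed)
  obs <- stats::var(counts) / m
  n <- length(counts)
  sims <- matrix(stats::rpois(n * n_resamples, m), nrow = n)
  null_disp <- matrixVar(sims) / colMeans(sims)
  list(dispersion = obs, p = mean(null_disp >= obs))
}

# column variances without apply() overhead
matrixVar <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}

#' Enrichment of mutations in a set of genomic intervals
#'
#' Counts, for each mutation set, how many mutations fall inside the union
#' of the supplied intervals (1-based inclusive ends), tests the 2 x 2 table
#' of set x membership with a G-test, and reports the fraction of the genome
#' covered by the interval union. Typical use: testing whether
#' trans-regulatory mutations are over-represented in eQTL regions.
#'
#' @param trans_set,nonreg_set data frames with \code{chrom} and \code{pos}.
#' @param intervals data frame with \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive; overlaps allowed, the union is taken).
#' @param genome_size total genome length in bp; default 12.07e6.
#' @return list with the 2 x 2 \code{table}, \code{g_test},
#'   \code{proportions} (fraction of each set inside intervals) and
#'   \code{genome_fraction}.
#' @export
interval_overlap_enrichment <- function(trans_set, nonreg_set, intervals,
                                        genome_size = 12.07e6) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start > intervals$end)) stop("interval start > end")
  by_chr <- split(intervals, intervals$chrom)
  reduced <- lapply(by_chr, function(iv) {
    IRanges::reduce(IRanges::IRanges(start = iv$start, end = iv$end))
  })
  union_bp <- sum(vapply(reduced, function(r) sum(IRanges::width(r)),
                         numeric(1)))
  inside <- function(muts) {
    vapply(seq_len(nrow(muts)), function(i) {
      r <- reduced[[as.character(muts$chrom[i])]]
      if (is.null(r)) return(FALSE)
      any(muts$pos[i] >= IRanges::start(r) & muts$pos[i] <= IRanges::end(r))
    }, logical(1))
  }
  ti <- inside(trans_set); ni <- inside(nonreg_set)
  tab <- rbind(trans = c(inside = sum(ti), outside = sum(!ti)),
               nonreg = c(inside = sum(ni), outside = sum(!ni)))
  list(
    table = tab,
    g_test = g_test_rxc(tab),
    proportions = c(trans = mean(ti), nonreg = mean(ni)),
    genome_fraction = union_bp / genome_size
  )
}
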