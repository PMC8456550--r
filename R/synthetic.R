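#' Configuration for the synthetic-data generators
#'
#' Collects every parameter of the cohort, cross, plate and competition
#' generators with defaults matching the study conditions the pipeline is
#' designed for: a 16-chromosome 12.07-Mb genome, overdispersed per-strain
#' mutation counts averaging 23.9 (two-component Poisson mixture, modelling
#' cell-to-cell heterogeneity in DNA repair), an EMS-like spectrum (96.3%
#' G:C-to-A:T among SNVs, 2.7% indels), 69.4% coding genome, 2.5%
#' fluorescence tails, ~105x sequencing coverage, 8 x 12 plates with 20
#' control wells, a 146-position x 4-replicate reference panel whose
#' between-position variance is twice the within-position variance, and
#' two-fluorophore competitions mixed 17:3 and counted at 5000 events.
#'
#' \code{n_spores} defaults to 40000 so that the 2.5% tails hold 1000
#' spores: bulk allele frequencies then carry negligible spore-sampling
#' variance relative to read sampling, the regime of the real experiment's
#' 1.5e5-cell bulks (see the methods vignette).
#'
#' @param ... named overrides of any default listed above.
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(...) {
  chr_kb <- c(230, 813, 317, 1532, 577, 270, 1091, 563, 440, 746, 667,
              1078, 924, 784, 1091, 948)  # sums to 12.071 Mb
  cfg <- list(
    seed = NULL,
    genome = stats::setNames(chr_kb * 1000,
                             paste0("chr", as.character(utils::as.roman(1:16)))),
    n_strains = 76,
    count_means = c(15, 32.8),      # Poisson mixture components (mean 23.9)
    count_weights = c(0.5, 0.5),
    p_indel = 0.027,
    p_gc_at = 0.963,                # among SNVs
    p_other_ts = 0.012,             # among SNVs
    coding_fraction = 0.694,
    n_causal = 1,
    effect_size = 3,                # phenotypic SD per causal mutation
    cM_per_kb = 0.4,
    n_spores = 40000,
    bulk_fraction = 0.025,
    coverage = 105,
    plate_rows = 8, plate_cols = 12,
    n_controls = 20,
    n_replicates = 4,
    panel_positions = 146,
    row_gradient = 0.01,            # fractional change per row step
    col_gradient = 0.01,
    sigma_within = 0.01,            # lognormal sdlog, same-position replicates
    sigma_between = 0.01 * sqrt(2), # position-to-position sdlog
    autofluorescence = 0.02,        # baseline added to every well
    reference_level = 1,
    competition_generations = c(0, 10),
    competition_events = 5000,
    initial_ratio = 17 / 3
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown sim_config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  with(cfg, {
    stopifnot(all(genome > 0), n_spores > 0, coverage > 0,
              p_indel >= 0, p_indel <= 1, p_gc_at >= 0,
              p_gc_at + p_other_ts <= 1,
              coding_fraction >= 0, coding_fraction <= 1,
              all(count_weights >= 0), sum(count_weights) > 0)
    if (bulk_fraction <= 0 || bulk_fraction >= 0.5) {
      stop("bulk_fraction must be in (0, 0.5)")
    }
  })
  cfg$count_weights <- cfg$count_weights / sum(cfg$count_weights)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an EMS mutagenesis cohort with truth labels
#'
#' Draws a mutation table for each strain: per-strain counts from the
#' configured Poisson mixture, positions uniform over the genome (chromosome
#' chosen proportionally to length), classes from the EMS-like spectrum with
#' ref/alt alleles consistent with each class, a coding/non-coding label
#' drawn at the configured coding fraction, and \code{n_causal} causal
#' mutations per strain tagged with the configured effect size (in
#' phenotypic standard deviations). Everything is reproducible from
#' (config, seed).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return a data frame with one row per mutation: \code{strain}, \code{id},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{mtype},
#'   \code{region}, \code{causal}, \code{effect}.
#' @export
simulate_ems_cohort <- function(config = sim_config(), seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  g <- config$genome
  n_per_strain <- draw_mixture_counts(config$n_strains, config$count_means,
                                      config$count_weights)
  total <- sum(n_per_strain)
  strain <- rep(seq_len(config$n_strains), n_per_strain)
  chrom <- sample(names(g), total, replace = TRUE, prob = g)
  pos <- floor(stats::runif(total) * g[chrom]) + 1L

  u <- stats::runif(total)
  mtype <- ifelse(u < config$p_indel, "indel", "SNV")
  cls <- stats::runif(total)
  ref <- alt <- character(total)
  is_snv <- mtype == "SNV"
  p1 <- config$p_gc_at; p2 <- p1 + config$p_other_ts
  for (i in which(is_snv)) {
    if (cls[i] < p1) {            # G:C -> A:T
      if (stats::runif(1) < 0.5) { ref[i] <- "G"; alt[i] <- "A" }
      else { ref[i] <- "C"; alt[i] <- "T" }
    } else if (cls[i] < p2) {     # A:T -> G:C
      if (stats::runif(1) < 0.5) { ref[i] <- "A"; alt[i] <- "G" }
      else { ref[i] <- "T"; alt[i] <- "C" }
    } else {                      # transversion
      ref[i] <- sample(c("A", "C", "G", "T"), 1)
      tv <- switch(ref[i], A = c("C", "T"), G = c("C", "T"),
                   C = c("A", "G"), T = c("A", "G"))
      alt[i] <- sample(tv, 1)
    }
  }
  for (i in which(!is_snv)) {     # 1-bp insertion or deletion
    b <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
    if (stats::runif(1) < 0.5) { ref[i] <- b[1]; alt[i] <- paste0(b[1], b[2]) }
    else { ref[i] <- paste0(b[1], b[2]); alt[i] <- b[1] }
  }
  region <- ifelse(stats::runif(total) < config$coding_fraction,
                   "coding", "intergenic")

  causal <- rep(FALSE, total)
  effect <- rep(0, total)
  if (config$n_causal > 0) {
    for (s in seq_len(config$n_strains)) {
      idx <- which(strain == s & is_snv)
      if (length(idx) == 0) idx <- which(strain == s)
      if (length(idx) == 0) next
      pick <- sample(idx, min(config$n_causal, length(idx)))
      causal[pick] <- TRUE
      effect[pick] <- config$effect_size *
        sample(c(-1, 1), length(pick), replace = TRUE)
    }
  }
  data.frame(
    strain = strain,
    id = paste0("s", strain, "_m", sequence(n_per_strain)),
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    mtype = mtype, region = region, causal = causal, effect = effect,
    stringsAsFactors = FALSE
  )
}

# mixture-of-Poissons per-strain mutation counts
draw_mixture_counts <- function(n, means, weights) {
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  stats::rpois(n, means[comp])
}

#' Simulate a mapping cross and truncation-selected bulks for one strain
#'
#' Generates \code{n_spores} haploid segregants from a cross of the mutant
#' to an unmutagenized mapper: each chromosome is a Markov chain over the
#' strain's mutation sites ordered by position, with adjacent-site
#' recombination fractions from the Haldane map function
#' \eqn{r = (1 - e^{-2d/100})/2} (d in cM, from physical distance times
#' \code{cM_per_kb}). Spore phenotype is the sum of inherited causal effects
#' plus standard normal noise. The bottom and top \code{bulk_fraction} tails
#' form the low and high bulks; per-site read counts are drawn binomially
#' from each tail's mutant-allele frequency at a depth that is Poisson
#' around \code{coverage}.
#'
#' @param mutations one strain's mutation table (columns \code{id},
#'   \code{chrom}, \code{pos}, \code{effect}; e.g. one strain's rows from
#'   [simulate_ems_cohort()]).
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return a data frame with one row per mutation: \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{low_ref}, \code{low_alt},
#'   \code{high_ref}, \code{high_alt}, the underlying tail frequencies
#'   \code{freq_low}, \code{freq_high}, and \code{causal}.
#' @export
simulate_cross_and_bulks <- function(mutations, config = sim_config(),
                                     seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n_sp <- config$n_spores
  nb <- max(1L, round(config$bulk_fraction * n_sp))
  m <- nrow(mutations)
  geno <- matrix(0L, n_sp, m)
  ord_all <- integer(0)
  for (ch in unique(mutations$chrom)) {
    idx <- which(mutations$chrom == ch)
    idx <- idx[order(mutations$pos[idx])]
    ord_all <- c(ord_all, idx)
    d_cM <- diff(mutations$pos[idx]) / 1000 * config$cM_per_kb
    r <- (1 - exp(-2 * d_cM / 100)) / 2
    x <- stats::rbinom(n_sp, 1L, 0.5)
    geno[, idx[1]] <- x
    for (k in seq_along(r)) {
      flip <- stats::rbinom(n_sp, 1L, r[k])
      x <- ifelse(flip == 1L, 1L - x, x)
      geno[, idx[k + 1]] <- x
    }
  }
  phen <- as.vector(geno %*% mutations$effect) + stats::rnorm(n_sp)
  o <- order(phen)
  low_idx <- o[seq_len(nb)]
  high_idx <- o[seq.int(n_sp - nb + 1L, n_sp)]
  freq_low <- colMeans(geno[low_idx, , drop = FALSE])
  freq_high <- colMeans(geno[high_idx, , drop = FALSE])

  depth_low <- stats::rpois(m, config$coverage)
  depth_high <- stats::rpois(m, config$coverage)
  alt_low <- stats::rbinom(m, depth_low, freq_low)
  alt_high <- stats::rbinom(m, depth_high, freq_high)
  data.frame(
    variant_id = mutations$id,
    chrom = mutations$chrom, pos = mutations$pos,
    low_ref = depth_low - alt_low, low_alt = alt_low,
    high_ref = depth_high - alt_high, high_alt = alt_high,
    freq_low = freq_low, freq_high = freq_high,
    causal = if ("causal" %in% names(mutations)) mutations$causal
             else mutations$effect != 0,
    stringsAsFactors = FALSE
  )
}

#' Simulate a 96-well plate expression experiment and a reference panel
#'
#' Each test strain is measured in \code{n_replicates} wells at one fixed
#' plate position across replicate plates; 20 fixed positions per plate hold
#' the reference (control) strain and one holds the non-fluorescent strain.
#' A well's value is \code{true expression x (1 + row/column gradient) x
#' lognormal replicate noise + autofluorescence baseline}. The reference
#' panel (\code{panel_positions} x \code{n_replicates}) carries a lognormal
#' position effect with \code{sigma_between > sigma_within}, the nested
#' variance structure that motivates the two-level permutation test.
#'
#' @param strain_effects named vector of true relative expression levels
#'   (reference = 1).
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return a list with \code{wells} (plate_id, row, col, strain_id,
#'   replicate, value, is_control, is_autofluorescence) and \code{panel}
#'   (matrix, positions x replicates).
#' @export
simulate_plate_experiment <- function(strain_effects, config = sim_config(),
                                      seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  nr <- config$plate_rows; nc <- config$plate_cols
  n_wells <- nr * nc
  # controls at mirror-image position pairs so their mean plate coordinate
  # sits exactly at the plate centre (a balanced control layout)
  half <- round(seq(2, floor(n_wells / 2) - 1,
                    length.out = ceiling(config$n_controls / 2)))
  ctrl_pos <- sort(unique(c(half, n_wells + 1 - half)))[
    seq_len(config$n_controls)]
  autofl_pos <- n_wells  # last well
  free_pos <- setdiff(seq_len(n_wells), c(ctrl_pos, autofl_pos))
  n_strains <- length(strain_effects)
  if (n_strains > length(free_pos)) {
    stop("too many strains for one plate layout: at most ",
         length(free_pos))
  }
  strain_pos <- sample(free_pos, n_strains)
  ids <- names(strain_effects)
  if (is.null(ids)) ids <- paste0("strain", seq_len(n_strains))

  gradient <- function(row, col) {
    1 + config$row_gradient * (row - (nr + 1) / 2) +
      config$col_gradient * (col - (nc + 1) / 2)
  }
  make_wells <- function(pos, strain_id, true_level, is_ctrl, is_autofl, rep_i) {
    row <- (pos - 1L) %% nr + 1L
    col <- (pos - 1L) %/% nr + 1L
    value <- true_level * gradient(row, col) *
      exp(stats::rnorm(length(pos), 0, config$sigma_within)) +
      config$autofluorescence
    data.frame(plate_id = rep_i, row = row, col = col,
               strain_id = strain_id, replicate = rep_i, value = value,
               is_control = is_ctrl, is_autofluorescence = is_autofl,
               stringsAsFactors = FALSE)
  }
  wells <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
    rbind(
      make_wells(ctrl_pos, "reference", config$reference_level,
                 TRUE, FALSE, r),
      make_wells(autofl_pos, "autofluorescence", 0, FALSE, TRUE, r),
      make_wells(strain_pos, ids, config$reference_level * strain_effects,
                 FALSE, FALSE, r)
    )
  }))
  rownames(wells) <- NULL

  b <- stats::rnorm(config$panel_positions, 0, config$sigma_between)
  panel <- config$reference_level *
    exp(matrix(b, config$panel_positions, config$n_replicates) +
        matrix(stats::rnorm(config$panel_positions * config$n_replicates,
                            0, config$sigma_within),
               config$panel_positions, config$n_replicates))
  list(wells = wells, panel = panel)
}

#' Simulate a two-fluorophore competition assay
#'
#' Deterministic log-ratio dynamics \eqn{\ln(Y/G)_g = \ln(Y/G)_0 + g \ln w}
#' sampled with binomial counting noise at \code{competition_events} flow
#' events per timepoint (\code{Inf} gives noise-free fractional counts).
#' The starting ratio is the configured 17:3 YFP:GFP mix.
#'
#' @param true_fitness per-generation fitness of the YFP strain relative to
#'   the GFP competitor (> 0).
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return data frame with \code{generations}, \code{yfp_count},
#'   \code{gfp_count}.
#' @export
simulate_competition_assay <- function(true_fitness, config = sim_config(),
                                       seed = config$seed) {
  stopifnot(true_fitness > 0)
  if (!is.null(seed)) set.seed(seed)
  g <- config$competition_generations
  ratio <- config$initial_ratio * true_fitness^g
  frac <- ratio / (1 + ratio)
  n <- config$competition_events
  if (is.infinite(n)) {
    yfp <- frac; gfp <- 1 - frac
  } else {
    yfp <- stats::rbinom(length(g), n, frac)
    gfp <- n - yfp
  }
  data.frame(generations = g, yfp_count = yfp, gfp_count = gfp)
}
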