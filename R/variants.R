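#' Read a freebayes-dialect VCF into a per-ALT variant table
#'
#' Parses a VCF 4.x file produced by pooled-sample variant calling and
#' returns one row per ALT allele (multi-allelic records are decomposed
#' before any filtering). The freebayes INFO fields used by the downstream
#' filter (\code{MQM}, \code{DP}, \code{AO}, \code{RO}, \code{PAIRED},
#' \code{PAIREDR}, \code{SAP}, \code{EPP}, \code{RPP}) are extracted as
#' numeric columns; per-ALT fields are split on commas so each decomposed
#' row carries its own value. A field absent from a record yields \code{NA}
#' ("absent", never zero) and the corresponding filter rule passes for that
#' record. \code{FREQ.REF}, the pooled reference-allele frequency, is taken
#' from the INFO column when present and otherwise derived as
#' \code{RO / (RO + AO)}.
#'
#' When the file contains exactly two sample columns they are interpreted as
#' the low and high fluorescence bulks (in file order) and their per-sample
#' \code{RO}/\code{AO} FORMAT fields populate \code{low_ref}, \code{low_alt},
#' \code{high_ref}, \code{high_alt}.
#'
#' @param path path to an uncompressed or gzipped VCF file.
#' @return a data frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{qual}, the INFO fields above, \code{FREQ.REF}, and
#'   (two-sample files only) the four bulk count columns.
#' @export
read_freebayes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) stop("no variant records in ", path)

  alt_list <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec <- rep.int(seq_len(n_rec), n_alt)   # source record of each output row
  alt_idx <- sequence(n_alt)              # which ALT within its record

  per_alt_fields <- c("MQM", "AO", "PAIRED", "SAP", "EPP", "RPP")
  per_rec_fields <- c("DP", "RO", "PAIREDR")

  pull <- function(field, per_alt) {
    raw <- vcfR::extract.info(vcf, element = field)
    if (all(is.na(raw))) {
      message("INFO field ", field, " absent from all records; rule will pass")
      return(rep(NA_real_, length(rec)))
    }
    if (per_alt) {
      parts <- strsplit(raw, ",", fixed = TRUE)
      vapply(seq_along(rec), function(i) {
        v <- parts[[rec[i]]]
        if (length(v) == 0 || all(is.na(v))) return(NA_real_)
        k <- if (length(v) >= alt_idx[i]) alt_idx[i] else 1L
        suppressWarnings(as.numeric(v[k]))
      }, numeric(1))
    } else {
      suppressWarnings(as.numeric(raw))[rec]
    }
  }

  out <- data.frame(
    chrom = as.character(fix[, "CHROM"])[rec],
    pos = as.integer(fix[, "POS"])[rec],
    ref = as.character(fix[, "REF"])[rec],
    alt = unlist(alt_list),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"]))[rec],
    stringsAsFactors = FALSE
  )
  for (f in per_alt_fields) out[[f]] <- pull(f, per_alt = TRUE)
  for (f in per_rec_fields) out[[f]] <- pull(f, per_alt = FALSE)

  fr <- pull("FREQ.REF", per_alt = FALSE)
  derived <- out$RO / (out$RO + out$AO)
  out$FREQ.REF <- ifelse(is.na(fr), derived, fr)

  # per-bulk counts from the two pooled samples, when present
  gt <- vcf@gt
  if (!is.null(gt) && ncol(gt) == 3L) {  # FORMAT + 2 samples
    ro <- vcfR::extract.gt(vcf, element = "RO", as.numeric = TRUE)
    ao <- vcfR::extract.gt(vcf, element = "AO")
    ao_k <- function(col) {
      parts <- strsplit(ao[, col], ",", fixed = TRUE)
      vapply(seq_along(rec), function(i) {
        v <- parts[[rec[i]]]
        if (length(v) == 0 || all(is.na(v))) return(NA_real_)
        k <- if (length(v) >= alt_idx[i]) alt_idx[i] else 1L
        suppressWarnings(as.numeric(v[k]))
      }, numeric(1))
    }
    out$low_ref <- ro[rec, 1]
    out$low_alt <- ao_k(1)
    out$high_ref <- ro[rec, 2]
    out$high_alt <- ao_k(2)
  }
  rownames(out) <- NULL
  out
}

#' Default variant-filter thresholds
#'
#' The filtering rules applied to freebayes calls to remove false positives
#' while retaining Sanger-confirmed variants: QUAL > 200, MQM > 27, DP > 20,
#' AO > 3, RO > 3, FREQ.REF > 0.1, PAIRED > 0.8, PAIREDR > 0.8, SAP < 100,
#' EPP < 50, RPP < 50. All inequalities are strict.
#'
#' @return a named list with elements \code{lower} (fields that must exceed
#'   their threshold) and \code{upper} (fields that must fall below it).
#' @export
default_filter_thresholds <- function() {
  list(
    lower = c(qual = 200, MQM = 27, DP = 20, AO = 3, RO = 3,
              FREQ.REF = 0.1, PAIRED = 0.8, PAIREDR = 0.8),
    upper = c(SAP = 100, EPP = 50, RPP = 50)
  )
}

#' Filter variant records on freebayes quality annotations
#'
#' A record is retained iff every \emph{present} annotation satisfies its
#' strict inequality; a missing (NA) annotation passes its rule, so absence
#' of an annotation never discards a call. Row order is preserved. The number
#' of records failing each rule (among all input records, independently) is
#' attached as attribute \code{"removed_per_rule"}.
#'
#' @param records a data frame as returned by [read_freebayes_vcf()].
#' @param thresholds a list shaped like [default_filter_thresholds()].
#' @return the retained rows of \code{records}, with attribute
#'   \code{"removed_per_rule"}.
#' @export
filter_variants <- function(records, thresholds = default_filter_thresholds()) {
  if (!is.list(thresholds) ||
      !all(c("lower", "upper") %in% names(thresholds)) ||
      !is.numeric(thresholds$lower) || !is.numeric(thresholds$upper)) {
    stop("thresholds must be a list with numeric 'lower' and 'upper' vectors")
  }
  keep <- rep(TRUE, nrow(records))
  removed <- integer(0)
  apply_rule <- function(field, cut, lower) {
    if (!field %in% names(records)) return(rep(TRUE, nrow(records)))
    v <- records[[field]]
    ok <- if (lower) v > cut else v < cut
    ok[is.na(v)] <- TRUE   # absent annotation: rule passes
    ok
  }
  for (f in names(thresholds$lower)) {
    ok <- apply_rule(f, thresholds$lower[[f]], lower = TRUE)
    removed[paste0(f, ">", thresholds$lower[[f]])] <- sum(!ok)
    keep <- keep & ok
  }
  for (f in names(thresholds$upper)) {
    ok <- apply_rule(f, thresholds$upper[[f]], lower = FALSE)
    removed[paste0(f, "<", thresholds$upper[[f]])] <- sum(!ok)
    keep <- keep & ok
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_per_rule") <- removed
  out
}

#' Annotate point mutations with region, coding effect and amino-acid change
#'
#' Assigns each mutation to a genomic region (coding, intron, or intergenic)
#' by interval lookup against gene models, and for coding single-nucleotide
#' variants rewrites the affected codon on the annotated coding strand and
#' translates it with the standard genetic code to classify the change as
#' synonymous, nonsynonymous or nonsense. Positions between the CDS segments
#' of a gene (on the gene's strand-independent span) are introns; positions
#' outside every gene span are intergenic, and the two flanking genes are
#' recorded as \code{"left|right"} (\code{NA} at chromosome ends).
#'
#' @param mutations data frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}.
#' @param gene_models data frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{cds_start}, \code{cds_end}
#'   (1-based inclusive); one row per CDS segment, segments of a gene ordered
#'   5' to 3' on the coding strand.
#' @param genome named character vector or \code{Biostrings::DNAStringSet} of
#'   chromosome sequences.
#' @return \code{mutations} with added columns \code{mtype}, \code{region},
#'   \code{effect}, \code{aa_from}, \code{aa_to} (one-letter codes, \code{*}
#'   for stop) and \code{gene}.
#' @export
annotate_mutations <- function(mutations, gene_models, genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome), !is.null(names(genome)))
  n <- nrow(mutations)
  region <- character(n); effect <- rep(NA_character_, n)
  aa_from <- rep(NA_character_, n); aa_to <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  mtype <- ifelse(nchar(mutations$ref) == 1 & nchar(mutations$alt) == 1,
                  "SNV", "indel")

  spans <- do.call(rbind, lapply(split(gene_models, gene_models$gene_id),
    function(g) data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
                           strand = g$strand[1],
                           start = min(g$cds_start), end = max(g$cds_end),
                           stringsAsFactors = FALSE)))

  for (i in seq_len(n)) {
    ch <- mutations$chrom[i]; pos <- mutations$pos[i]
    if (mtype[i] == "SNV") {
      gbase <- substr(genome[[ch]], pos, pos)
      if (!identical(toupper(gbase), toupper(mutations$ref[i]))) {
        stop(sprintf("ref allele %s at %s:%d disagrees with genome base %s",
                     mutations$ref[i], ch, pos, gbase))
      }
    }
    seg <- gene_models[gene_models$chrom == ch &
                       gene_models$cds_start <= pos &
                       gene_models$cds_end >= pos, , drop = FALSE]
    if (nrow(seg) > 0) {
      region[i] <- "coding"
      gene[i] <- seg$gene_id[1]
      if (mtype[i] == "SNV") {
        eff <- codon_effect(pos, mutations$alt[i],
                            gene_models[gene_models$gene_id == seg$gene_id[1], ],
                            genome[[ch]])
        effect[i] <- eff$effect; aa_from[i] <- eff$aa_from; aa_to[i] <- eff$aa_to
      }
      next
    }
    sp <- spans[spans$chrom == ch & spans$start <= pos & spans$end >= pos, ,
                drop = FALSE]
    if (nrow(sp) > 0) {
      region[i] <- "intron"
      gene[i] <- sp$gene_id[1]
    } else {
      region[i] <- "intergenic"
      chr_sp <- spans[spans$chrom == ch, , drop = FALSE]
      left <- chr_sp[chr_sp$end < pos, , drop = FALSE]
      right <- chr_sp[chr_sp$start > pos, , drop = FALSE]
      lg <- if (nrow(left)) left$gene_id[which.max(left$end)] else NA
      rg <- if (nrow(right)) right$gene_id[which.min(right$start)] else NA
      gene[i] <- paste(lg, rg, sep = "|")
    }
  }
  mutations$mtype <- mtype
  mutations$region <- region
  mutations$effect <- effect
  mutations$aa_from <- aa_from
  mutations$aa_to <- aa_to
  mutations$gene <- gene
  mutations
}

# effect of a coding SNV: rebuild the codon on the coding strand, substitute,
# translate both with the standard genetic code.
codon_effect <- function(pos, alt, segs, chrom_seq) {
  segs <- segs[order(segs$cds_start), , drop = FALSE]
  cds_pos_list <- unlist(lapply(seq_len(nrow(segs)), function(j) {
    segs$cds_start[j]:segs$cds_end[j]
  }))
  minus <- segs$strand[1] == "-"
  if (minus) cds_pos_list <- rev(cds_pos_list)
  idx <- match(pos, cds_pos_list)          # 1-based index along the CDS
  if (is.na(idx)) stop("position not in CDS segments")
  codon_i <- (idx - 1L) %/% 3L
  codon_genomic <- cds_pos_list[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
  base_at <- function(p) substr(chrom_seq, p, p)
  raw <- toupper(vapply(codon_genomic, base_at, character(1)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  codon_ref <- if (minus) comp[raw] else raw
  within <- (idx - 1L) %% 3L + 1L
  codon_alt <- codon_ref
  codon_alt[within] <- if (minus) comp[[toupper(alt)]] else toupper(alt)
  tr <- function(cd) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(paste(cd, collapse = "")),
      genetic.code = Biostrings::GENETIC_CODE, no.init.codon = TRUE))
  }
  aa_from <- tr(codon_ref); aa_to <- tr(codon_alt)
  effect <- if (aa_from == aa_to) "synonymous"
            else if (aa_to == "*") "nonsense"
            else "nonsynonymous"
  list(effect = effect, aa_from = aa_from, aa_to = aa_to)
}

#' Tabulate the mutation spectrum
#'
#' Counts mutations in the five classes relevant to an EMS screen:
#' G:C to A:T transitions (the canonical EMS change, collapsed by strand so
#' G>A and C>T count as one class), other transitions (A:T to G:C),
#' transversions, indels, and aneuploidies. Counts always sum to the number
#' of input mutations.
#'
#' @param mutations data frame with columns \code{ref}, \code{alt} and
#'   \code{mtype} (\code{"SNV"}, \code{"indel"} or \code{"aneuploidy"}).
#' @return a named integer vector over the five classes.
#' @export
classify_spectrum <- function(mutations) {
  classes <- c("GC_to_AT", "other_transition", "transversion",
               "indel", "aneuploidy")
  out <- stats::setNames(integer(5), classes)
  for (i in seq_len(nrow(mutations))) {
    mt <- mutations$mtype[i]
    if (mt == "indel") { out["indel"] <- out["indel"] + 1L; next }
    if (mt == "aneuploidy") { out["aneuploidy"] <- out["aneuploidy"] + 1L; next }
    r <- toupper(mutations$ref[i]); a <- toupper(mutations$alt[i])
    key <- paste0(r, a)
    cls <- if (key %in% c("GA", "CT")) "GC_to_AT"
           else if (key %in% c("AG", "TC")) "other_transition"
           else "transversion"
    out[cls] <- out[cls] + 1L
  }
  out
}
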