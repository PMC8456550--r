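test_that("VCF parsing returns one row per ALT with the freebayes fields", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(f, c(
    toy_record(pos = 100, ref = "G", alt = "A"),
    toy_record(pos = 250, ref = "C", alt = "T", qual = 900, dp = 80,
               ao = 30, ro = 50, gt = "RO:AO\t25:15\t25:15")
  ))
  v <- suppressMessages(read_freebayes_vcf(f))
  expect_equal(nrow(v), 2L)
  expect_equal(v$pos, c(100L, 250L))
  expect_equal(v$ref, c("G", "C"))
  expect_equal(v$alt, c("A", "T"))
  expect_equal(v$qual, c(500, 900))
  expect_equal(v$DP, c(100, 80))
  expect_equal(v$low_ref, c(26, 25))
  expect_equal(v$high_alt, c(24, 15))
  # FREQ.REF derived from pooled counts when absent from INFO
  expect_equal(v$FREQ.REF, c(52 / 100, 50 / 80))
})

test_that("multi-allelic records decompose with per-ALT INFO values", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(f, toy_record(
    pos = 500, ref = "G", alt = "A,T",
    mqm = "60,42", ao = "30,10", paired = "0.99,0.95",
    sap = "3,8", epp = "4,9", rpp = "5,11",
    gt = "RO:AO\t30:15,5\t30:15,5"
  ))
  v <- suppressMessages(read_freebayes_vcf(f))
  expect_equal(nrow(v), 2L)
  expect_equal(v$pos, c(500L, 500L))
  expect_equal(v$alt, c("A", "T"))
  expect_equal(v$MQM, c(60, 42))
  expect_equal(v$AO, c(30, 10))
  expect_equal(v$low_alt, c(15, 5))
})

test_that("a record missing an INFO field carries NA and passes that rule", {
  f <- withr::local_tempfile(fileext = ".vcf")
  rec <- sub("SAP=[0-9.]+;", "", toy_record(pos = 10))
  suppressMessages(write_toy_vcf(f, c(rec, toy_record(pos = 20, sap = 250))))
  v <- suppressMessages(read_freebayes_vcf(f))
  expect_true(is.na(v$SAP[1]))
  kept <- filter_variants(v)
  # record 1 passes (SAP absent); record 2 fails SAP < 100
  expect_equal(kept$pos, 10L)
})

test_that("filtering applies every strict inequality and is idempotent", {
  rec <- function(...) {
    d <- data.frame(qual = 500, MQM = 60, DP = 100, AO = 48, RO = 52,
                    FREQ.REF = 0.52, PAIRED = 0.99, PAIREDR = 0.99,
                    SAP = 3, EPP = 4, RPP = 5)
    args <- list(...)
    d[names(args)] <- args
    d
  }
  # failing QUAL alone removes the record
  expect_equal(nrow(filter_variants(rec(qual = 150))), 0L)
  # exactly at a threshold is removed (strict inequality)
  expect_equal(nrow(filter_variants(rec(DP = 20))), 0L)
  expect_equal(nrow(filter_variants(rec(SAP = 100))), 0L)
  # toy set of 3: one failing MQM leaves 2
  three <- rbind(rec(), rec(MQM = 20), rec())
  kept <- filter_variants(three)
  expect_equal(nrow(kept), 2L)
  expect_equal(attr(kept, "removed_per_rule")[["MQM>27"]], 1L)
  # idempotence
  again <- filter_variants(kept)
  expect_equal(nrow(again), nrow(kept))
  expect_equal(again$MQM, kept$MQM)
  # malformed thresholds rejected
  expect_error(filter_variants(three, list(lower = "a", upper = 1)), "numeric")
})

test_that("annotation assigns regions, flanking genes and codon effects", {
  genome <- toy_genome()
  gm <- toy_gene_models()
  muts <- data.frame(
    chrom = "chrI",
    pos = c(50L, 22L, 21L, 85L),
    ref = c("A", "G", "C", "C"),
    alt = c("T", "A", "T", "T"),
    stringsAsFactors = FALSE
  )
  # pos 22: + strand codon GGA, position 2 G>A -> GAA, Gly->Glu
  # pos 21: + strand codon ... but 21 holds G of GGA; C>T needs ref C, so use
  #   the CAA codon start at 24 instead for the nonsense case below
  muts$pos[3] <- 24L; muts$ref[3] <- "C"; muts$alt[3] <- "T"
  ann <- annotate_mutations(muts, gm, genome)
  expect_equal(ann$region, c("intergenic", "coding", "coding", "coding"))
  expect_equal(ann$gene[1], "geneA|geneB")   # flanking pair
  expect_equal(ann$effect[2], "nonsynonymous")
  expect_equal(ann$aa_from[2], "G"); expect_equal(ann$aa_to[2], "E")
  # CAA -> TAA: Gln -> stop
  expect_equal(ann$effect[3], "nonsense")
  expect_equal(ann$aa_from[3], "Q"); expect_equal(ann$aa_to[3], "*")
  # minus strand: genomic C>T at pos 85 is codon GGA pos 2 on coding strand
  expect_equal(ann$effect[4], "nonsynonymous")
  expect_equal(ann$aa_from[4], "G"); expect_equal(ann$aa_to[4], "E")
  # disagreement with the genome base is a data error
  bad <- data.frame(chrom = "chrI", pos = 22L, ref = "T", alt = "C")
  expect_error(annotate_mutations(bad, gm, genome), "disagrees")
})

test_that("spectrum classes collapse by strand and sum to the input size", {
  m <- data.frame(
    ref = c("G", "C", "A", "G", "C", "AT"),
    alt = c("A", "T", "G", "T", "G", "A"),
    mtype = c(rep("SNV", 5), "indel"),
    stringsAsFactors = FALSE
  )
  s <- classify_spectrum(m)
  expect_equal(unname(s["GC_to_AT"]), 2L)        # G>A and C>T collapse
  expect_equal(unname(s["other_transition"]), 1L)
  expect_equal(unname(s["transversion"]), 2L)
  expect_equal(unname(s["indel"]), 1L)
  expect_equal(sum(s), nrow(m))
})

test_that("EMS-type nonsense mutations only arise from Arg, Gln or Trp codons", {
  # exhaustive enumeration: every codon placed as a one-codon gene, every
  # G>A and C>T substitution annotated through the package's codon machinery
  bases <- c("A", "C", "G", "T")
  gm <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                   cds_start = 1L, cds_end = 3L, stringsAsFactors = FALSE)
  origins <- character(0)
  n_checked <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codon <- c(b1, b2, b3)
    genome <- c(c = paste(codon, collapse = ""))
    for (k in 1:3) {
      alt <- switch(codon[k], G = "A", C = "T", NA)
      if (is.na(alt)) next
      mut <- data.frame(chrom = "c", pos = k, ref = codon[k], alt = alt,
                        stringsAsFactors = FALSE)
      ann <- annotate_mutations(mut, gm, genome)
      n_checked <- n_checked + 1L
      if (!is.na(ann$effect) && ann$effect == "nonsense") {
        origins <- c(origins, ann$aa_from)
      }
    }
  }
  expect_gt(n_checked, 60)
  expect_gt(length(origins), 0)
  expect_true(all(origins %in% c("R", "Q", "W")))
  # and all three origin amino acids are actually reachable
  expect_setequal(unique(origins), c("R", "Q", "W"))
})
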