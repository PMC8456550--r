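# fixtures built in code: a freebayes-style toy VCF and a two-gene toy genome

write_toy_vcf <- function(path, records, samples = TRUE) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQM,Number=A,Type=Float,Description=\"Mean mapping quality of alt\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alt observations\">",
    "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"Ref observations\">",
    "##INFO=<ID=PAIRED,Number=A,Type=Float,Description=\"Proportion paired alt\">",
    "##INFO=<ID=PAIREDR,Number=1,Type=Float,Description=\"Proportion paired ref\">",
    "##INFO=<ID=SAP,Number=A,Type=Float,Description=\"Strand balance P\">",
    "##INFO=<ID=EPP,Number=A,Type=Float,Description=\"End placement P\">",
    "##INFO=<ID=RPP,Number=A,Type=Float,Description=\"Read placement P\">",
    "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"Ref obs\">",
    "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alt obs\">",
    if (samples) "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tlow\thigh"
    else "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  writeLines(c(hdr, records), path)
  path
}

# one passing record with all INFO fields; tweak fields via sprintf in tests
toy_record <- function(chrom = "chrI", pos = 100, ref = "G", alt = "A",
                       qual = 500, mqm = 60, dp = 100, ao = 48, ro = 52,
                       paired = 0.99, pairedr = 0.99, sap = 3, epp = 4,
                       rpp = 5, gt = "RO:AO\t26:24\t26:24") {
  sprintf(
    "%s\t%d\t.\t%s\t%s\t%s\tPASS\tMQM=%s;DP=%s;AO=%s;RO=%s;PAIRED=%s;PAIREDR=%s;SAP=%s;EPP=%s;RPP=%s\t%s",
    chrom, pos, ref, alt, qual, mqm, dp, ao, ro, paired, pairedr, sap, epp,
    rpp, gt)
}

# two genes on a 120-bp chromosome:
#   geneA: + strand, CDS 21..26 (two codons)
#   geneB: - strand, CDS 81..86
toy_genome <- function() {
  base <- paste(rep("A", 120), collapse = "")
  s <- strsplit(base, "")[[1]]
  s[21:26] <- c("G", "G", "A", "C", "A", "A")  # codons GGA, CAA on + strand
  s[81:86] <- c("T", "T", "G", "T", "C", "C")  # reverse complement: GGA CAA
  c(chrI = paste(s, collapse = ""))
}

toy_gene_models <- function() {
  data.frame(
    gene_id = c("geneA", "geneB"),
    chrom = "chrI",
    strand = c("+", "-"),
    cds_start = c(21L, 81L),
    cds_end = c(26L, 86L),
    stringsAsFactors = FALSE
  )
}

# independent likelihood-ratio chi-square oracle (iterative proportional
# fitting / deviance path in MASS, not the 2*sum(O*ln(O/E)) closed form)
loglm_g <- function(tab) {
  fit <- MASS::loglm(~ 1 + 2, data = tab, fit = TRUE)
  unname(fit$lrt)
}

# brute-force enumeration oracle for the two-level test on a 1-position panel
enumerate_two_level_p <- function(test_values, panel_row) {
  pool <- c(test_values, panel_row)
  d_obs <- abs(mean(test_values) - mean(panel_row))
  splits <- utils::combn(8, 4)
  d <- apply(splits, 2, function(s) d_obs - abs(mean(pool[s]) - mean(pool[-s])))
  tol <- sqrt(.Machine$double.eps) * max(1, max(abs(pool)))
  if (all(abs(d) <= tol)) return(1)
  sum(d < -tol) / sum(abs(d) > tol)
}
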