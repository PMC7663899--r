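# Fixture builders shared across test files. Everything is generated in
# code at test time; nothing is stored on disk.

# Write a VCF 4.2 text file from a record table.
# records: data.frame(chrom, pos, ref, alt, gt [, filter]); one sample
# column per element of `samples` (gt recycled across samples unless a
# gt.<sample> column is present).
write_test_vcf <- function(records, path, samples = "S1") {
  if (is.null(records$filter)) records$filter <- "PASS"
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt_cols <- lapply(samples, function(s) {
    col <- paste0("gt.", s)
    if (col %in% names(records)) records[[col]] else records$gt
  })
  body <- do.call(paste, c(list(records$chrom, records$pos, ".", records$ref,
                                records$alt, ".", records$filter, ".", "GT"),
                           gt_cols, list(sep = "\t")))
  writeLines(c(hdr, body), path)
  path
}

# Deterministic mixed-record VCF: `n_het` phased biallelic SNP HETs plus
# a fixed assortment of records that must be excluded (indel, homozygote,
# multi-allelic, missing GT, non-PASS, unphased HETs if requested).
make_mixed_vcf <- function(path, n_het = 40, n_unphased = 0, step = 100L) {
  pos <- seq(1000L, by = step, length.out = n_het + n_unphased + 5L)
  het <- data.frame(chrom = "chr1", pos = pos[seq_len(n_het)],
                    ref = "A", alt = "G",
                    gt = rep(c("0|1", "1|0"), length.out = n_het),
                    filter = "PASS", stringsAsFactors = FALSE)
  unph <- if (n_unphased > 0)
    data.frame(chrom = "chr1", pos = pos[n_het + seq_len(n_unphased)],
               ref = "C", alt = "T", gt = "0/1", filter = "PASS",
               stringsAsFactors = FALSE)
  junk_pos <- pos[n_het + n_unphased + 1:5]
  junk <- data.frame(
    chrom = "chr1", pos = junk_pos,
    ref = c("A", "AT", "C", "G", "T"),
    alt = c("G,T", "A", "C,G", "A", "C"),
    gt = c("0|1", "0|1", "1|0", "1|1", "0|1"),
    filter = c("PASS", "PASS", "PASS", "PASS", "q10"),
    stringsAsFactors = FALSE)
  records <- rbind(het, unph, junk)
  records <- records[order(records$pos), ]
  write_test_vcf(records, path)
  list(path = path, n_het_phased = n_het, n_unphased = n_unphased)
}

# Phased-site table built directly (no VCF round trip).
make_sites <- function(n, chrom = "chr1", start = 1000L, step = 500L,
                       seed = 42L) {
  withr::with_seed(seed, {
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    data.frame(chrom = chrom, pos = seq(start, by = step, length.out = n),
               ref = ref, alt = alt,
               hap1_allele = ifelse(runif(n) < 0.5, ref, alt),
               stringsAsFactors = FALSE)
  })
}

# Counts table with prescribed per-unit VAF pattern: each element of
# `unit_vafs` becomes one unit of `unit_size` sites carrying
# `reads_per_unit` pooled reads split to match the VAF exactly.
make_units_counts <- function(unit_vafs, unit_size = 1L,
                              reads_per_unit = 30L) {
  n <- length(unit_vafs) * unit_size
  sites <- make_sites(n)
  h1_unit <- round(unit_vafs * reads_per_unit)
  sites$hap1_reads <- 0L
  sites$hap2_reads <- 0L
  first <- (seq_along(unit_vafs) - 1L) * unit_size + 1L
  sites$hap1_reads[first] <- as.integer(h1_unit)
  sites$hap2_reads[first] <- as.integer(reads_per_unit - h1_unit)
  sites$other_reads <- 0L
  sites
}

# Shared small simulated genome for metric-level tests (module scope, so
# it is built once per test file that uses it).
test_genome_sites <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_phased_hets(sim_genome_config(genome_length = 3e6,
                                                       het_spacing_mean = 1500,
                                                       seed = 11L))
    cache
  }
})
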