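# MDA-bias simulator: phased HETs, fragment-level amplification imbalance,
# haplotype dropout, Poisson read sampling, and fixture writers.

#' Configuration of a synthetic genome of phased HETs
#'
#' @param genome_length total genome size in bp (split evenly over
#'   chromosomes).
#' @param n_chroms number of chromosomes.
#' @param het_spacing_mean mean inter-HET distance in bp (spacings are
#'   exponential, i.e. HET positions form a Poisson process).
#' @param seed RNG seed; every generator is fully deterministic given it.
#' @return a `sim_genome_config` list.
#' @export
sim_genome_config <- function(genome_length = 3e6, n_chroms = 1L,
                              het_spacing_mean = 1500, seed = 1L) {
  stopifnot(genome_length > 0, n_chroms >= 1, het_spacing_mean > 0)
  structure(list(genome_length = genome_length, n_chroms = as.integer(n_chroms),
                 het_spacing_mean = het_spacing_mean, seed = as.integer(seed)),
            class = "sim_genome_config")
}

#' Configuration of one synthetic amplified cell
#'
#' The generative model mimics MDA: the genome is independently tiled, per
#' haplotype, into amplified fragments with lengths uniform on
#' `fragment_len_range` (default 50-70 kb, the typical MDA fragment size).
#' Each (fragment, haplotype) receives an amplification weight: zero with
#' probability `dropout_prob` (the haplotype copy failed to amplify), else
#' lognormal with log-scale standard deviation `bias_sigma`. Weights are
#' normalized to the cell's realized mean, so `coverage` keeps its meaning
#' as the sequenced depth whatever the amplification yield. All sites within
#' one fragment share the fragment's weight — consecutive SNPs are
#' amplified together — and per-site read counts are Poisson with rate
#' `coverage / 2 x weight` per haplotype.
#'
#' @param cell_id cell identifier.
#' @param bias_sigma log-scale SD of the per-(fragment, haplotype)
#'   amplification factor; 0 = perfectly uniform amplification, ~3 = very
#'   bad cell.
#' @param dropout_prob probability that a haplotype copy of a fragment is
#'   not amplified at all.
#' @param fragment_len_range amplified-fragment length range (bp).
#' @param coverage target mean sequencing depth (x).
#' @param read_length read length (bp), recorded for unit sizing.
#' @param seed RNG seed.
#' @param dropout_hap `"both"` (default) applies dropout independently to
#'   either haplotype; `"hap1"`/`"hap2"` restricts it to one haplotype
#'   (directional-dropout test mode).
#' @return a `sim_cell_config` list.
#' @export
sim_cell_config <- function(cell_id = "cell", bias_sigma = 0, dropout_prob = 0,
                            fragment_len_range = c(50000, 70000),
                            coverage = 0.3, read_length = 100L, seed = 1L,
                            dropout_hap = c("both", "hap1", "hap2")) {
  dropout_hap <- match.arg(dropout_hap)
  stopifnot(bias_sigma >= 0, dropout_prob >= 0, dropout_prob <= 1,
            length(fragment_len_range) == 2,
            fragment_len_range[1] <= fragment_len_range[2],
            fragment_len_range[1] > 0, coverage > 0, read_length >= 1)
  structure(list(cell_id = cell_id, bias_sigma = bias_sigma,
                 dropout_prob = dropout_prob,
                 fragment_len_range = fragment_len_range,
                 coverage = coverage, read_length = as.integer(read_length),
                 seed = as.integer(seed), dropout_hap = dropout_hap),
            class = "sim_cell_config")
}

#' Simulate phased heterozygous SNPs
#'
#' Lays down HET positions with exponential spacing on each chromosome,
#' draws ref/alt uniformly from distinct bases and assigns the haplotype-1
#' allele by a fair coin. Deterministic given the config seed.
#'
#' @param genome_cfg a [sim_genome_config()].
#' @return phased-site data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `hap1_allele`) sorted by `(chrom, pos)`.
#' @export
simulate_phased_hets <- function(genome_cfg) {
  stopifnot(inherits(genome_cfg, "sim_genome_config"))
  with_seed(genome_cfg$seed, {
    chrom_len <- genome_cfg$genome_length / genome_cfg$n_chroms
    per_chrom <- lapply(seq_len(genome_cfg$n_chroms), function(i) {
      n_guess <- ceiling(chrom_len / genome_cfg$het_spacing_mean +
                           4 * sqrt(chrom_len / genome_cfg$het_spacing_mean) + 10)
      pos <- cumsum(rexp(n_guess, rate = 1 / genome_cfg$het_spacing_mean))
      while (pos[length(pos)] <= chrom_len) {  # rare: extend until past the end
        pos <- c(pos, pos[length(pos)] +
                   cumsum(rexp(n_guess, rate = 1 / genome_cfg$het_spacing_mean)))
      }
      pos <- unique(pmax(1L, as.integer(floor(pos[pos <= chrom_len]))))
      n <- length(pos)
      if (n == 0L) return(NULL)
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
      data.frame(chrom = sprintf("chr%d", i), pos = pos, ref = ref, alt = alt,
                 hap1_allele = ifelse(runif(n) < 0.5, ref, alt),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(per_chrom, list(make.row.names = FALSE)))
    if (is.null(out))
      out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), hap1_allele = character(),
                        stringsAsFactors = FALSE)
    out
  })
}

# Per-site amplification weights (w1, w2): the genome is tiled into
# fragments independently per haplotype; every site inherits the weight of
# the fragment covering it on each haplotype. Weights are lognormal,
# zeroed by dropout, and normalized to the cell's realized mean so that
# the target coverage is met whatever the amplification yield (the
# library is sequenced to a chosen depth regardless of how unevenly the
# cell amplified).
sim_fragment_weights <- function(sites, cell_cfg) {
  n <- nrow(sites)
  w <- matrix(1, n, 2)
  if (n == 0L) return(w)
  fr <- cell_cfg$fragment_len_range
  for (ch in unique(sites$chrom)) {
    sel <- sites$chrom == ch
    pos <- sites$pos[sel]
    chrom_end <- max(pos)
    for (h in 1:2) {
      n_frag <- ceiling(chrom_end / fr[1]) + 2L
      lens <- runif(n_frag, fr[1], fr[2])
      while (sum(lens) <= chrom_end)
        lens <- c(lens, runif(n_frag, fr[1], fr[2]))
      breaks <- cumsum(lens)
      frag_idx <- findInterval(pos - 1, c(0, breaks), rightmost.closed = FALSE)
      n_used <- max(frag_idx)
      dropped <- switch(cell_cfg$dropout_hap,
        both = runif(n_used) < cell_cfg$dropout_prob,
        hap1 = if (h == 1L) runif(n_used) < cell_cfg$dropout_prob else {
          runif(n_used); rep(FALSE, n_used) },
        hap2 = if (h == 2L) runif(n_used) < cell_cfg$dropout_prob else {
          runif(n_used); rep(FALSE, n_used) }
      )
      amp <- exp(rnorm(n_used, 0, cell_cfg$bias_sigma) -
                   cell_cfg$bias_sigma^2 / 2)
      fw <- ifelse(dropped, 0, amp)
      w[sel, h] <- fw[frag_idx]
    }
  }
  if (mean(w) > 0) w <- w / mean(w)
  w
}

# Poisson read sampling at `coverage` given per-site haplotype weights.
sample_site_reads <- function(sites, w, coverage) {
  n <- nrow(sites)
  counts <- sites[, c("chrom", "pos", "ref", "alt", "hap1_allele")]
  counts$hap1_reads <- rpois(n, coverage / 2 * w[, 1])
  counts$hap2_reads <- rpois(n, coverage / 2 * w[, 2])
  counts$other_reads <- 0L
  counts
}

#' Simulate per-site allele counts for one amplified cell
#'
#' Draws fragment-level amplification weights (see [sim_cell_config()])
#' and Poisson read counts at the cell's coverage. Sites within one
#' amplified fragment share one haplotype-imbalance draw, so allelic
#' imbalance is locally correlated along the genome exactly as MDA bias
#' is.
#'
#' @param sites phased-site data.frame, sorted by `(chrom, pos)`.
#' @param cell_cfg a [sim_cell_config()].
#' @return counts data.frame (site columns plus `hap1_reads`,
#'   `hap2_reads`, `other_reads`).
#' @export
simulate_cell_counts <- function(sites, cell_cfg) {
  stopifnot(inherits(cell_cfg, "sim_cell_config"))
  w <- with_seed(derive_seed(cell_cfg$seed, 1L),
                 sim_fragment_weights(sites, cell_cfg))
  with_seed(derive_seed(cell_cfg$seed, 2L),
            sample_site_reads(sites, w, cell_cfg$coverage))
}

#' Paired shallow and deep sequencing of the same amplified cell
#'
#' Both count sets share one set of amplification weights (it is the same
#' physical cell) and differ only in Poisson read sampling at the two
#' depths; sub-seeds are split deterministically from the cell seed.
#'
#' @param sites phased-site data.frame.
#' @param cell_cfg a [sim_cell_config()]; its `coverage` is the shallow
#'   depth.
#' @param deep_coverage depth of the deep re-sequencing run (x).
#' @return list with elements `shallow` and `deep`, each a counts
#'   data.frame.
#' @export
paired_shallow_deep <- function(sites, cell_cfg, deep_coverage = 30) {
  stopifnot(inherits(cell_cfg, "sim_cell_config"), deep_coverage > 0)
  w <- with_seed(derive_seed(cell_cfg$seed, 1L),
                 sim_fragment_weights(sites, cell_cfg))
  list(
    shallow = with_seed(derive_seed(cell_cfg$seed, 2L),
                        sample_site_reads(sites, w, cell_cfg$coverage)),
    deep = with_seed(derive_seed(cell_cfg$seed, 3L),
                     sample_site_reads(sites, w, deep_coverage))
  )
}

#' Write a phased VCF for simulated sites
#'
#' Minimal single-sample VCF 4.2 with phased genotypes (`0|1` when the
#' reference allele is on haplotype 1, else `1|0`), readable back by
#' [read_phased_vcf()].
#'
#' @param sites phased-site data.frame.
#' @param path output `.vcf` path.
#' @param sample_name sample column name.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(sites, path, sample_name = "SIM") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=wgaqc-simulator",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (nrow(sites) > 0) {
    lens <- tapply(sites$pos, sites$chrom, max)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(lens),
                          as.integer(lens) + 1000L))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_name, sep = "\t"))
  body <- character(0)
  if (nrow(sites) > 0) {
    gt <- ifelse(sites$hap1_allele == sites$ref, "0|1", "1|0")
    body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                  "PASS", ".", "GT", gt, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a synthetic BAM from an explicit read table
#'
#' Builds a coordinate-sorted, indexed BAM (via an intermediate SAM) from
#' a table of synthetic alignments; used to exercise the pileup code path
#' on fully known input.
#'
#' @param reads data.frame with columns `chrom`, `pos` (1-based leftmost),
#'   `seq` (read bases) and optionally `mapq` (default 60).
#' @param chrom_lengths named vector of reference contig lengths.
#' @param out_prefix output path without extension; `<out_prefix>.bam` and
#'   its index are created.
#' @return the BAM path.
#' @export
write_sim_bam <- function(reads, chrom_lengths, out_prefix) {
  stopifnot(all(c("chrom", "pos", "seq") %in% names(reads)),
            !is.null(names(chrom_lengths)))
  if (is.null(reads$mapq)) reads$mapq <- 60L
  reads <- reads[order(match(reads$chrom, names(chrom_lengths)), reads$pos), ,
                 drop = FALSE]
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  if (nrow(reads) > 0) {
    len <- nchar(reads$seq)
    sam <- c(sam, paste(sprintf("r%06d", seq_len(nrow(reads))), 0L,
                        reads$chrom, reads$pos, reads$mapq,
                        paste0(len, "M"), "*", 0L, 0L, reads$seq,
                        strrep("I", len), sep = "\t"))
  }
  sam_path <- paste0(out_prefix, ".sam")
  writeLines(sam, sam_path)
  bam <- Rsamtools::asBam(sam_path, destination = out_prefix,
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam_path)
  bam
}

# One minimal single-base alignment per counted read, so that the pileup
# of the resulting BAM reproduces `counts` exactly. "Other" reads get a
# base distinct from both haplotype alleles.
counts_to_reads <- function(counts) {
  other_base <- function(a, b) {
    vapply(seq_along(a),
           function(i) setdiff(c("A", "C", "G", "T"), c(a[i], b[i]))[1],
           character(1))
  }
  h2 <- hap2_allele(counts)
  expand <- function(n_col, base) {
    n <- counts[[n_col]]
    data.frame(chrom = rep(counts$chrom, n), pos = rep(counts$pos, n),
               seq = rep(base, n), stringsAsFactors = FALSE)
  }
  rbind(expand("hap1_reads", counts$hap1_allele),
        expand("hap2_reads", h2),
        expand("other_reads", other_base(counts$hap1_allele, h2)))
}

#' Write fixture files for a simulated cell
#'
#' Emits the phased VCF for the sites, the per-site counts TSV, and
#' optionally a tiny synthetic BAM whose filtered pileup reproduces the
#' counts exactly (one single-base alignment per counted read), for
#' end-to-end tests of the BAM code path. All outputs are synthetic.
#'
#' @param sites phased-site data.frame.
#' @param counts counts data.frame for one cell.
#' @param out_dir output directory (created if needed).
#' @param cell_id basename for the per-cell files.
#' @param write_bam also write `<cell_id>.bam` (+ index).
#' @param coverage,read_length metadata recorded in the counts TSV.
#' @return named list of paths (`vcf`, `counts`, and `bam` if written).
#' @export
write_fixture_files <- function(sites, counts, out_dir, cell_id = "cell1",
                                write_bam = FALSE, coverage = NULL,
                                read_length = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(out_dir, "sites.vcf")
  write_phased_vcf(sites, vcf_path)
  counts_path <- file.path(out_dir, paste0(cell_id, ".counts.tsv"))
  write_counts_table(counts, counts_path, coverage = coverage,
                     read_length = read_length, cell_id = cell_id)
  out <- list(vcf = vcf_path, counts = counts_path)
  if (write_bam) {
    lens <- if (nrow(sites) > 0) {
      tapply(sites$pos, sites$chrom, max) + 1000L
    } else c(chr1 = 1000L)
    out$bam <- write_sim_bam(counts_to_reads(counts),
                             setNames(as.integer(lens), names(lens)),
                             file.path(out_dir, cell_id))
  }
  out
}
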