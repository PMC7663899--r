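# Per-cell coverage estimation and haplotype-resolved allele counting from BAM.

#' Read-filter configuration for pileup counting
#'
#' Defaults (MAPQ >= 20, base quality >= 20, duplicates and
#' secondary/supplementary alignments excluded) are the standard choices
#' for SNP allele counting; all are configurable.
#'
#' @param min_mapq minimum mapping quality.
#' @param min_baseq minimum base quality.
#' @param exclude_duplicates drop reads flagged as PCR/optical duplicates.
#' @param exclude_secondary_supplementary drop secondary and supplementary
#'   alignments.
#' @return a `read_filter_config` list.
#' @export
read_filter_config <- function(min_mapq = 20L, min_baseq = 20L,
                               exclude_duplicates = TRUE,
                               exclude_secondary_supplementary = TRUE) {
  stopifnot(min_mapq >= 0, min_baseq >= 0)
  structure(list(min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 exclude_duplicates = isTRUE(exclude_duplicates),
                 exclude_secondary_supplementary =
                   isTRUE(exclude_secondary_supplementary)),
            class = "read_filter_config")
}

filter_flag <- function(filters) {
  Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (filters$exclude_duplicates) FALSE else NA,
    isSecondaryAlignment = if (filters$exclude_secondary_supplementary) FALSE else NA,
    isSupplementaryAlignment = if (filters$exclude_secondary_supplementary) FALSE else NA
  )
}

bam_seqlengths <- function(bam_path) {
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]
  hdr$targets
}

check_bam <- function(bam_path) {
  if (!file.exists(bam_path))
    stop(sprintf("BAM file not found: %s", bam_path), call. = FALSE)
  idx <- paste0(bam_path, ".bai")
  idx2 <- sub("\\.bam$", ".bai", bam_path)
  if (!file.exists(idx) && !file.exists(idx2))
    stop(sprintf(
      "BAM index not found for '%s'; run `samtools index %s` first",
      bam_path, bam_path), call. = FALSE)
  invisible(TRUE)
}

#' Estimate genome-wide mean sequencing depth of a BAM
#'
#' The coverage drives the SNP-unit size, so it must be known per cell.
#' Depth is estimated as (number of passing primary alignments x modal read
#' length) / genome size rather than by full per-base traversal; at the
#' shallow depths this tool targets the two agree to well under a percent
#' and the count-based estimate is much faster.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param genome_size genome size in bp; default the sum of the reference
#'   contig lengths in the BAM header.
#' @param filters a [read_filter_config()].
#' @param n_sample_reads number of reads sampled to determine the modal
#'   read length.
#' @return list with `mean_depth` (x), `read_length` (modal, bp),
#'   `n_reads` (passing alignments counted), `n_reads_sampled`.
#' @export
estimate_coverage <- function(bam_path, genome_size = NULL,
                              filters = read_filter_config(),
                              n_sample_reads = 20000L) {
  check_bam(bam_path)
  if (is.null(genome_size)) genome_size <- sum(as.double(bam_seqlengths(bam_path)))
  stopifnot(genome_size > 0)
  param <- Rsamtools::ScanBamParam(flag = filter_flag(filters),
                                   mapqFilter = filters$min_mapq)
  n_reads <- Rsamtools::countBam(bam_path, param = param)$records
  if (n_reads == 0L)
    stop(sprintf("no passing alignments in '%s'; cannot estimate coverage",
                 bam_path), call. = FALSE)
  bf <- Rsamtools::BamFile(bam_path, yieldSize = as.integer(n_sample_reads))
  open(bf); on.exit(close(bf))
  qw <- Rsamtools::scanBam(
    bf, param = Rsamtools::ScanBamParam(flag = filter_flag(filters),
                                        mapqFilter = filters$min_mapq,
                                        what = "qwidth"))[[1]]$qwidth
  qw <- qw[!is.na(qw)]
  read_length <- as.integer(names(sort(table(qw), decreasing = TRUE))[1])
  list(mean_depth = n_reads * read_length / genome_size,
       read_length = read_length,
       n_reads = n_reads,
       n_reads_sampled = length(qw))
}

#' Count reads supporting each haplotype allele at phased HET sites
#'
#' Pileup-based counting at every phased HET: a base increments
#' `hap1_reads` if it equals the haplotype-1 allele, `hap2_reads` if it
#' equals the haplotype-2 allele, and `other_reads` otherwise; deletions
#' and reference skips spanning the site count as nothing. Sites on contigs
#' absent from the BAM header get zero counts with a warning. Every read
#' passing the filters contributes one base per site it covers; mates of a
#' pair overlapping the same site are counted independently.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param sites phased-site data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `hap1_allele`), sorted by `(chrom, pos)`.
#' @param filters a [read_filter_config()].
#' @param max_depth pileup depth cap per site.
#' @return data.frame with the site columns plus `hap1_reads`,
#'   `hap2_reads`, `other_reads` (one row per input site, zeros allowed).
#' @export
count_alleles_at_sites <- function(bam_path, sites,
                                   filters = read_filter_config(),
                                   max_depth = 100000L) {
  check_bam(bam_path)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "hap1_allele") %in% names(sites)))
  out <- sites[, c("chrom", "pos", "ref", "alt", "hap1_allele")]
  out$hap1_reads <- 0L; out$hap2_reads <- 0L; out$other_reads <- 0L
  if (nrow(sites) == 0L) return(out)

  known <- names(bam_seqlengths(bam_path))
  on_bam <- sites$chrom %in% known
  if (any(!on_bam))
    warning(sprintf(
      "%d site(s) on contigs absent from the BAM header (%s); zero counts reported",
      sum(!on_bam), paste(unique(sites$chrom[!on_bam]), collapse = ", ")),
      call. = FALSE)
  if (!any(on_bam)) return(out)

  gr <- GenomicRanges::GRanges(sites$chrom[on_bam],
                               IRanges::IRanges(sites$pos[on_bam], width = 1L))
  pp <- Rsamtools::PileupParam(
    max_depth = as.integer(max_depth),
    min_base_quality = filters$min_baseq,
    min_mapq = filters$min_mapq,
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE
  )
  sbp <- Rsamtools::ScanBamParam(flag = filter_flag(filters), which = gr)
  pu <- Rsamtools::pileup(bam_path, scanBamParam = sbp, pileupParam = pp)
  if (nrow(pu) == 0L) return(out)

  key <- paste(as.character(pu$seqnames), pu$pos, sep = ":")
  idx <- match(key, site_key(out))
  keep <- !is.na(idx)
  pu <- pu[keep, ]; idx <- idx[keep]
  nuc <- as.character(pu$nucleotide)
  h1 <- nuc == out$hap1_allele[idx]
  h2 <- nuc == hap2_allele(out)[idx]
  add <- function(which) {
    v <- integer(nrow(out))
    if (any(which)) {
      t <- tapply(pu$count[which], idx[which], sum)
      v[as.integer(names(t))] <- as.integer(t)
    }
    v
  }
  out$hap1_reads <- add(h1)
  out$hap2_reads <- add(h2)
  out$other_reads <- add(!h1 & !h2)
  out
}

COUNTS_COLS <- c("chrom", "pos", "ref", "alt", "hap1_allele",
                 "hap1_reads", "hap2_reads", "other_reads")

#' Write / read a per-site allele-counts table
#'
#' Tab-separated table (columns `chrom`, `pos`, `ref`, `alt`,
#' `hap1_allele`, `hap1_reads`, `hap2_reads`, `other_reads`) that
#' round-trips bit-exactly. Metadata such as the cell's estimated coverage
#' and read length are carried in `#key=value` comment lines before the
#' header and surface as attributes on reading.
#'
#' @param counts data.frame from [count_alleles_at_sites()] or
#'   [simulate_cell_counts()].
#' @param path file path.
#' @param coverage,read_length,cell_id optional metadata written as
#'   comments.
#' @return `write_counts_table`: `path` invisibly; `read_counts_table`:
#'   the counts data.frame with attributes `coverage`, `read_length`,
#'   `cell_id` when present in the file.
#' @export
write_counts_table <- function(counts, path, coverage = NULL,
                               read_length = NULL, cell_id = NULL) {
  stopifnot(all(COUNTS_COLS %in% names(counts)))
  con <- file(path, "w"); on.exit(close(con))
  meta <- c(coverage = coverage, read_length = read_length, cell_id = cell_id)
  if (length(meta))
    writeLines(paste0("#", names(meta), "=", unname(meta)), con)
  write.table(counts[, COUNTS_COLS], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_table
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("counts table not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta]
  body <- lines[!is_meta]
  if (length(body) == 0L)
    stop("counts table has no header line: ", path, call. = FALSE)
  tab <- read.delim(text = body, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
  if (!all(COUNTS_COLS %in% names(tab)))
    stop("counts table must have columns: ", paste(COUNTS_COLS, collapse = ", "),
         call. = FALSE)
  tab <- tab[, COUNTS_COLS]
  count_cols <- c("hap1_reads", "hap2_reads", "other_reads")
  for (cc in count_cols) {
    bad <- which(is.na(tab[[cc]]) | tab[[cc]] < 0 | tab[[cc]] != round(tab[[cc]]))
    if (length(bad))
      stop(sprintf("invalid %s at line %d of %s (must be a non-negative integer)",
                   cc, sum(is_meta) + 1L + bad[1], path), call. = FALSE)
    tab[[cc]] <- as.integer(tab[[cc]])
  }
  tab$pos <- as.integer(tab$pos)
  kv <- sub("^#", "", meta_lines)
  kv <- kv[grepl("=", kv)]
  keys <- sub("=.*$", "", kv); vals <- sub("^[^=]*=", "", kv)
  if ("coverage" %in% keys)
    attr(tab, "coverage") <- as.numeric(vals[keys == "coverage"][1])
  if ("read_length" %in% keys)
    attr(tab, "read_length") <- as.integer(vals[keys == "read_length"][1])
  if ("cell_id" %in% keys)
    attr(tab, "cell_id") <- vals[keys == "cell_id"][1]
  tab
}
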