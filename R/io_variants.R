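# Variant-site I/O: bulk VCF -> biallelic HETs -> catalog subset -> phased table.

HET_GENOTYPES      <- c("0/1", "1/0", "0|1", "1|0")
PHASED_GENOTYPES   <- c("0|1", "1|0")
UNPHASED_GENOTYPES <- c("0/1", "1/0")

# Chromosomes that violate the diploid-HET assumption (dropped by default).
is_autosome <- function(chrom) {
  !grepl("^(chr)?(X|Y|M|MT)$", chrom, ignore.case = TRUE)
}

# Pull the genotype matrix column for `sample`, defaulting to the first
# sample; fatal with the available names if the sample is absent.
select_sample_gt <- function(gt, sample) {
  if (is.null(dim(gt)) || ncol(gt) == 0L)
    stop("VCF has no sample genotype columns", call. = FALSE)
  if (is.null(sample)) return(gt[, 1L])
  if (!sample %in% colnames(gt))
    stop(sprintf("sample '%s' not found in VCF; available samples: %s",
                 sample, paste(colnames(gt), collapse = ", ")), call. = FALSE)
  gt[, sample]
}

# Read a VCF and return a site table with one row per record and a `gt`
# column holding the chosen sample's GT string (allele fields only).
read_vcf_sites <- function(vcf_path, sample = NULL) {
  if (!file.exists(vcf_path))
    stop(sprintf("VCF file not found: %s", vcf_path), call. = FALSE)
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stop(sprintf("failed to parse VCF '%s': %s",
                                     vcf_path, conditionMessage(e)), call. = FALSE)
  )
  fm <- vcfR::getFIX(vcf)
  if (is.null(dim(fm))) fm <- matrix(fm, nrow = 1, dimnames = list(NULL, names(fm)))
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), filter = character(), gt = character(),
                      stringsAsFactors = FALSE))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  data.frame(
    chrom  = fix$CHROM,
    pos    = as.integer(fix$POS),
    ref    = fix$REF,
    alt    = fix$ALT,
    filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
    gt     = select_sample_gt(gt, sample),
    stringsAsFactors = FALSE
  )
}

#' Extract biallelic heterozygous SNPs from a bulk VCF
#'
#' Reads a (multi-sample) VCF and returns the biallelic SNP records whose
#' genotype for the chosen sample is heterozygous (`0/1`, `1/0`, `0|1` or
#' `1|0`). Indels, multi-allelic records, missing and homozygous genotypes
#' are excluded. By default only records with FILTER `PASS` or `.` are kept
#' and sex chromosomes / mitochondria are dropped (the diploid-HET
#' assumption does not hold there).
#'
#' @param vcf_path path to a VCF 4.x file (plain or gzipped).
#' @param sample sample name; default the first sample column.
#' @param keep_filtered keep records whose FILTER is neither `PASS` nor `.`.
#' @param autosomes_only drop X/Y/MT records (default TRUE).
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   sorted by `(chrom, pos)`.
#' @export
parse_het_sites <- function(vcf_path, sample = NULL, keep_filtered = FALSE,
                            autosomes_only = TRUE) {
  tab <- read_vcf_sites(vcf_path, sample)
  keep <- !is.na(tab$gt) & tab$gt %in% HET_GENOTYPES &
    nchar(tab$ref) == 1L & nchar(tab$alt) == 1L &
    tab$ref %in% c("A", "C", "G", "T") & tab$alt %in% c("A", "C", "G", "T") &
    !grepl(",", tab$alt, fixed = TRUE)
  if (!keep_filtered) keep <- keep & tab$filter %in% c("PASS", ".")
  if (autosomes_only) keep <- keep & is_autosome(tab$chrom)
  out <- tab[keep, c("chrom", "pos", "ref", "alt")]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no biallelic heterozygous SNPs survive filtering in ", vcf_path,
            call. = FALSE)
  out
}

#' Read a site catalog of known SNP positions
#'
#' Accepts either a plain TSV with columns `chrom`, `pos` (1-based) and
#' optionally `ref`, `alt`, or a VCF (positions and alleles taken from the
#' fixed fields, genotypes ignored).
#'
#' @param path catalog file (`.tsv`/`.txt` or `.vcf`/`.vcf.gz`).
#' @return data.frame with columns `chrom`, `pos` and, when available,
#'   `ref`, `alt`; duplicate `(chrom, pos)` keys removed.
#' @export
read_site_catalog <- function(path) {
  if (!file.exists(path))
    stop(sprintf("site catalog not found: %s", path), call. = FALSE)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fm <- vcfR::getFIX(vcf)
    if (is.null(dim(fm))) fm <- matrix(fm, nrow = 1, dimnames = list(NULL, names(fm)))
    fix <- as.data.frame(fm, stringsAsFactors = FALSE)
    cat <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  } else {
    cat <- read.delim(path, stringsAsFactors = FALSE)
    names(cat) <- tolower(names(cat))
    if (!all(c("chrom", "pos") %in% names(cat)))
      stop("site catalog TSV must have columns 'chrom' and 'pos'", call. = FALSE)
    cat$pos <- as.integer(cat$pos)
  }
  cat[!duplicated(paste(cat$chrom, cat$pos)), , drop = FALSE]
}

site_key <- function(x) paste(x$chrom, x$pos, sep = ":")

#' Subset HET sites to a catalog of known positions
#'
#' Keeps sites whose `(chrom, pos)` appears in the catalog (e.g. the 1000
#' Genomes germline-variant positions). When the catalog carries `ref`/`alt`
#' columns, sites with mismatching alleles are dropped and counted. Input
#' order is preserved. A complete lack of overlap between non-empty inputs
#' usually signals a chromosome-naming mismatch ("chr1" vs "1") and is
#' reported as a warning naming the two conventions.
#'
#' @param sites data.frame from [parse_het_sites()].
#' @param catalog data.frame from [read_site_catalog()].
#' @return the subset of `sites`, with attribute `n_allele_mismatch`.
#' @export
intersect_with_catalog <- function(sites, catalog) {
  if (nrow(sites) == 0L || nrow(catalog) == 0L) {
    out <- sites[integer(0), , drop = FALSE]
    attr(out, "n_allele_mismatch") <- 0L
    return(out)
  }
  hit <- site_key(sites) %in% site_key(catalog)
  if (!any(hit)) {
    warning(sprintf(
      "no overlap between sites and catalog; chromosome naming may differ ('%s' vs '%s')",
      sites$chrom[1], catalog$chrom[1]), call. = FALSE)
  }
  out <- sites[hit, , drop = FALSE]
  n_mismatch <- 0L
  if (all(c("ref", "alt") %in% names(catalog)) && nrow(out) > 0L) {
    idx <- match(site_key(out), site_key(catalog))
    ok <- out$ref == catalog$ref[idx] & out$alt == catalog$alt[idx]
    n_mismatch <- sum(!ok)
    if (n_mismatch > 0L)
      wq_log(n_mismatch, " site(s) dropped: alleles disagree with catalog")
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_allele_mismatch") <- n_mismatch
  out
}

#' Read phased heterozygous SNPs from a phased VCF
#'
#' Retains biallelic SNP heterozygotes with a phased genotype separator
#' (`|`) and records which allele lies on haplotype 1: `0|1` puts the
#' reference allele on haplotype 1, `1|0` the alternate. The labels
#' "haplotype 1/2" are arbitrary (maternal/paternal origin unknown) but
#' consistent genome-wide within one file. Unphased (`/`) heterozygotes are
#' excluded and counted in the `n_unphased_skipped` attribute.
#'
#' @inheritParams parse_het_sites
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `hap1_allele` (the base on haplotype 1), sorted by `(chrom, pos)`;
#'   attribute `n_unphased_skipped`.
#' @export
read_phased_vcf <- function(vcf_path, sample = NULL, keep_filtered = FALSE,
                            autosomes_only = TRUE) {
  tab <- read_vcf_sites(vcf_path, sample)
  snp <- !is.na(tab$gt) &
    nchar(tab$ref) == 1L & nchar(tab$alt) == 1L &
    tab$ref %in% c("A", "C", "G", "T") & tab$alt %in% c("A", "C", "G", "T")
  if (!keep_filtered) snp <- snp & tab$filter %in% c("PASS", ".")
  if (autosomes_only) snp <- snp & is_autosome(tab$chrom)
  phased   <- snp & tab$gt %in% PHASED_GENOTYPES
  unphased <- snp & tab$gt %in% UNPHASED_GENOTYPES
  n_skipped <- sum(unphased)
  if (!any(phased))
    stop("no phased heterozygous SNPs in ", vcf_path,
         "; phase the VCF first (e.g. with SHAPEIT2) so heterozygous ",
         "genotypes use the '|' separator", call. = FALSE)
  if (n_skipped > 0L)
    wq_log(n_skipped, " unphased heterozygote(s) skipped")
  out <- tab[phased, c("chrom", "pos", "ref", "alt")]
  out$hap1_allele <- ifelse(tab$gt[phased] == "0|1", out$ref, out$alt)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unphased_skipped") <- n_skipped
  out
}

# The other haplotype's allele, given the hap1 assignment.
hap2_allele <- function(sites) {
  ifelse(sites$hap1_allele == sites$ref, sites$alt, sites$ref)
}

#' Write / read the phased-site table
#'
#' Tab-separated table with header and columns `chrom`, `pos`, `ref`,
#' `alt`, `hap1_allele`; round-trips losslessly.
#'
#' @param sites data.frame from [read_phased_vcf()].
#' @param path output (or input) file path.
#' @return `write_phased_sites`: `path` invisibly; `read_phased_sites`: the
#'   site data.frame.
#' @export
write_phased_sites <- function(sites, path) {
  cols <- c("chrom", "pos", "ref", "alt", "hap1_allele")
  stopifnot(all(cols %in% names(sites)))
  ok <- tryCatch({
    write.table(sites[, cols], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write phased-site table to '%s'", path),
                call. = FALSE)
  invisible(path)
}

#' @rdname write_phased_sites
#' @export
read_phased_sites <- function(path) {
  if (!file.exists(path))
    stop(sprintf("phased-site table not found: %s", path), call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
  cols <- c("chrom", "pos", "ref", "alt", "hap1_allele")
  if (!all(cols %in% names(tab)))
    stop("phased-site table must have columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  tab$pos <- as.integer(tab$pos)
  tab[, cols]
}
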