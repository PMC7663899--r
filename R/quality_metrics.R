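# Core metrics: SNP-unit construction, VAF dispersion, allelic dropout,
# classification, ranking, MAPD baseline, and the VAF histogram.

#' Metric configuration
#'
#' Thresholds and knobs for unit construction, dropout calling and
#' classification.
#'
#' @param min_reads_per_unit minimum pooled haplotype reads for a unit to
#'   be informative; a VAF from fewer than ~10 reads is dominated by
#'   sampling noise at any amplification quality.
#' @param ado_low,ado_high unit VAF at or below `ado_low` / at or above
#'   `ado_high` counts as an allelic-dropout unit.
#' @param sd_good_max cells with VAF standard deviation below this are
#'   "good" (uniformly amplified).
#' @param sd_moderate_max cells between `sd_good_max` and this (inclusive)
#'   are "moderate"; above, "bad".
#' @param unit_size_override force a SNP-unit size instead of deriving it
#'   from coverage.
#' @param min_informative_units minimum number of informative units for a
#'   cell's quality to be considered determinable; a standard deviation
#'   estimated from fewer unit VAFs has a relative standard error above
#'   ~25\% (roughly `1 / sqrt(2 (n - 1))`) and such cells should be
#'   re-sequenced slightly deeper rather than ranked.
#' @param bin_width VAF histogram bin width (fixed across cells for
#'   comparability).
#' @return a `metric_config` list.
#' @export
metric_config <- function(min_reads_per_unit = 10L, ado_low = 0.01,
                          ado_high = 0.99, sd_good_max = 0.26,
                          sd_moderate_max = 0.35, unit_size_override = NULL,
                          min_informative_units = 10L, bin_width = 0.02) {
  stopifnot(min_reads_per_unit >= 1, ado_low >= 0, ado_low < ado_high,
            ado_high <= 1, sd_good_max < sd_moderate_max,
            min_informative_units >= 1, bin_width > 0)
  structure(list(min_reads_per_unit = as.integer(min_reads_per_unit),
                 ado_low = ado_low, ado_high = ado_high,
                 sd_good_max = sd_good_max, sd_moderate_max = sd_moderate_max,
                 unit_size_override = unit_size_override,
                 min_informative_units = as.integer(min_informative_units),
                 bin_width = bin_width),
            class = "metric_config")
}

#' Coverage-scaled SNP-unit size
#'
#' The number of consecutive HETs pooled into one SNP unit is inversely
#' proportional to coverage: at ~30x with 100 bp reads each HET already
#' carries ~30 reads and is used on its own (unit size 1); at 0.3x, 100
#' HETs are pooled so the unit carries comparable read support (30 divided
#' by 0.3). For other read lengths the count scales by `100 / read_length`.
#'
#' @param coverage genome-wide mean depth (x); must be > 0.
#' @param read_length read length in bp.
#' @return integer unit size, >= 1; always 1 for coverage >= 30.
#' @export
compute_unit_size <- function(coverage, read_length = 100L) {
  if (!is.finite(coverage) || coverage <= 0)
    stop("coverage must be a positive number, got ", coverage, call. = FALSE)
  stopifnot(read_length > 0)
  if (coverage >= 30) return(1L)
  max(1L, as.integer(round((30 / coverage) * (100 / read_length))))
}

#' Merge consecutive phased HETs into SNP units
#'
#' Per chromosome, consecutive retained HETs (adjacent in the genome-wide
#' HET ordering, regardless of base-pair gap) are grouped into
#' non-overlapping blocks of exactly `unit_size` sites; haplotype read
#' counts are pooled over the block and the unit VAF is the haplotype-1
#' fraction `hap1 / (hap1 + hap2)` (bases matching neither allele are
#' excluded). A trailing remainder block with fewer than `unit_size` sites
#' is kept only if it has at least `ceiling(unit_size / 2)` sites;
#' otherwise it is discarded and counted. Units never span chromosomes. A
#' warning is emitted when any unit spans more than 1 Mb (a HET desert or
#' very low coverage: the unit then averages over many amplified
#' fragments).
#'
#' @param counts per-site counts data.frame (see [count_alleles_at_sites()]),
#'   sorted by `(chrom, pos)`.
#' @param unit_size number of HETs per unit, >= 1.
#' @param max_span_warn unit span (bp) above which the warning fires.
#' @return data.frame with one row per unit: `chrom`, `start_pos`,
#'   `end_pos`, `n_sites`, `hap1_reads`, `hap2_reads`, `unit_vaf` (NA when
#'   the unit has no haplotype reads); attribute `n_sites_discarded`.
#' @export
build_snp_units <- function(counts, unit_size, max_span_warn = 1e6) {
  if (length(unit_size) != 1L || !is.finite(unit_size) || unit_size < 1)
    stop("unit_size must be a single integer >= 1", call. = FALSE)
  unit_size <- as.integer(unit_size)
  stopifnot(all(c("chrom", "pos", "hap1_reads", "hap2_reads") %in% names(counts)))

  per_chrom <- split(counts, factor(counts$chrom, levels = unique(counts$chrom)))
  min_keep <- as.integer(ceiling(unit_size / 2))
  discarded <- 0L
  units <- lapply(per_chrom, function(cc) {
    n <- nrow(cc)
    grp <- (seq_len(n) - 1L) %/% unit_size
    sizes <- tabulate(grp + 1L)
    last <- length(sizes)
    if (sizes[last] < unit_size && sizes[last] < min_keep) {
      discarded <<- discarded + sizes[last]
      keep <- grp < (last - 1L)
      cc <- cc[keep, , drop = FALSE]
      grp <- grp[keep]
      if (nrow(cc) == 0L) return(NULL)
    }
    g <- factor(grp)
    data.frame(
      chrom = cc$chrom[1],
      start_pos = as.integer(tapply(cc$pos, g, min)),
      end_pos = as.integer(tapply(cc$pos, g, max)),
      n_sites = as.integer(tapply(cc$pos, g, length)),
      hap1_reads = as.integer(tapply(cc$hap1_reads, g, sum)),
      hap2_reads = as.integer(tapply(cc$hap2_reads, g, sum)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(units, list(make.row.names = FALSE)))
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(chrom = character(), start_pos = integer(),
                      end_pos = integer(), n_sites = integer(),
                      hap1_reads = integer(), hap2_reads = integer(),
                      unit_vaf = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_sites_discarded") <- discarded
    return(out)
  }
  tot <- out$hap1_reads + out$hap2_reads
  out$unit_vaf <- ifelse(tot > 0, out$hap1_reads / tot, NA_real_)
  span <- out$end_pos - out$start_pos
  if (any(span > max_span_warn))
    warning(sprintf("%d unit(s) span more than %.3g bp; at this HET density/coverage a unit averages over many amplified fragments",
                    sum(span > max_span_warn), max_span_warn), call. = FALSE)
  attr(out, "n_sites_discarded") <- discarded
  out
}

#' Per-cell amplification-quality metrics
#'
#' From the unit VAF distribution: `vaf_sd` is the sample standard
#' deviation of unit VAFs over informative units (pooled haplotype reads
#' >= `min_reads_per_unit`); `ado_rate` is the fraction of informative
#' units with extreme VAF (<= `ado_low` or >= `ado_high`), capturing
#' random, drastic overrepresentation of one allele; `combined_score` is
#' their (unweighted) sum. The class label follows [classify_cell()].
#' `determinable` records whether enough informative units support the
#' estimates (at least `min_informative_units`); an undeterminable cell —
#' typically one whose amplification concentrated the reads in few units —
#' still gets metrics and a label, but they should not be trusted for
#' selection.
#'
#' @param units data.frame from [build_snp_units()].
#' @param config a [metric_config()].
#' @param cell_id cell identifier carried into the report.
#' @param coverage,unit_size recorded in the report (not used in the
#'   computation).
#' @return one-row data.frame: `cell_id`, `coverage`, `unit_size`,
#'   `n_units_total`, `n_units_informative`, `vaf_sd`, `ado_rate`,
#'   `combined_score`, `label`, `determinable`.
#' @export
cell_metrics <- function(units, config = metric_config(), cell_id = "cell",
                         coverage = NA_real_, unit_size = NA_integer_) {
  stopifnot(inherits(config, "metric_config"))
  tot <- units$hap1_reads + units$hap2_reads
  informative <- !is.na(units$unit_vaf) & tot >= config$min_reads_per_unit
  if (!any(informative))
    stop(sprintf(
      "cell '%s': no informative SNP units (>= %d pooled reads); coverage may be too low or the sites do not match the alignment",
      cell_id, config$min_reads_per_unit), call. = FALSE)
  vaf <- units$unit_vaf[informative]
  vaf_sd <- if (length(vaf) > 1L) sd(vaf) else 0
  ado <- mean(vaf <= config$ado_low | vaf >= config$ado_high)
  data.frame(
    cell_id = cell_id,
    coverage = coverage,
    unit_size = as.integer(unit_size),
    n_units_total = nrow(units),
    n_units_informative = sum(informative),
    vaf_sd = vaf_sd,
    ado_rate = ado,
    combined_score = vaf_sd + ado,
    label = classify_cell(vaf_sd, config),
    determinable = sum(informative) >= config$min_informative_units,
    stringsAsFactors = FALSE
  )
}

#' Classify a cell from its VAF standard deviation
#'
#' Cells with unit-VAF standard deviation below 0.26 are uniformly
#' amplified ("good"); between 0.26 and 0.35 inclusive, "moderate"; above
#' 0.35, "bad".
#'
#' @param vaf_sd standard deviation of unit VAFs (>= 0).
#' @param config a [metric_config()] carrying the two thresholds.
#' @return `"good"`, `"moderate"` or `"bad"` (vectorised).
#' @export
classify_cell <- function(vaf_sd, config = metric_config()) {
  stopifnot(all(vaf_sd >= 0))
  ifelse(vaf_sd < config$sd_good_max, "good",
         ifelse(vaf_sd <= config$sd_moderate_max, "moderate", "bad"))
}

#' Rank cells by amplification quality
#'
#' Ascending by the chosen key (lower is better); ties broken by
#' `ado_rate`, then `cell_id`, for a deterministic order.
#'
#' @param reports data.frame of stacked [cell_metrics()] rows.
#' @param key `"sd"` (VAF standard deviation), `"ado"` (dropout rate) or
#'   `"combined"` (their sum).
#' @return `reports` reordered, with a `rank` column prepended.
#' @export
rank_cells <- function(reports, key = c("sd", "ado", "combined")) {
  key <- match.arg(key)
  stopifnot(nrow(reports) >= 1)
  val <- switch(key, sd = reports$vaf_sd, ado = reports$ado_rate,
                combined = reports$combined_score)
  ord <- order(val, reports$ado_rate, reports$cell_id)
  out <- reports[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Median absolute pairwise difference (MAPD) of bin counts
#'
#' Depth-uniformity baseline metric: bin counts are normalized by their
#' mean and the median absolute difference between adjacent bins is
#' returned. Unlike the haplotype VAF dispersion it is blind to allelic
#' imbalance that preserves total depth.
#'
#' @param bin_counts numeric vector (>= 2 bins) of non-negative read
#'   counts in consecutive genomic bins.
#' @return the MAPD value.
#' @export
compute_mapd <- function(bin_counts) {
  stopifnot(length(bin_counts) >= 2, all(bin_counts >= 0))
  m <- mean(bin_counts)
  if (m == 0) stop("all bins are zero; MAPD undefined", call. = FALSE)
  x <- bin_counts / m
  median(abs(diff(x)))
}

# Bin unit VAFs on [0,1] with fixed-width bins; shared by plot and TSV.
# Breaks are rounded so that common VAFs (e.g. exactly 0.5) land in the
# bin their value names, free of floating-point drift in seq().
bin_vaf <- function(vaf, bin_width) {
  breaks <- round(seq(0, 1, by = bin_width), 10)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- hist(vaf, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  data.frame(bin_start = head(breaks, -1), bin_end = breaks[-1],
             count = h$counts)
}

#' Plot the unit-VAF histogram for one cell
#'
#' Histogram of informative-unit VAFs on [0, 1] (bin width from the
#' config, default 0.02), annotated with the cell id, VAF standard
#' deviation, dropout rate and class label. The binned counts are also
#' written as a companion TSV (`<out>.bins.tsv`) so the plot content is
#' testable numerically.
#'
#' @param units data.frame from [build_snp_units()].
#' @param report one-row data.frame from [cell_metrics()].
#' @param out_path output image path (extension selects the device, e.g.
#'   `.png` or `.pdf`).
#' @param config a [metric_config()].
#' @return the bin-count data.frame, invisibly.
#' @export
plot_vaf_histogram <- function(units, report, out_path,
                               config = metric_config()) {
  tot <- units$hap1_reads + units$hap2_reads
  vaf <- units$unit_vaf[!is.na(units$unit_vaf) & tot >= config$min_reads_per_unit]
  if (length(vaf) == 0L)
    stop("no informative units to plot", call. = FALSE)
  bins <- bin_vaf(vaf, config$bin_width)
  bins_path <- paste0(tools::file_path_sans_ext(out_path), ".bins.tsv")
  write.table(bins, bins_path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- sprintf("%s  (cov %.2gx, unit %d)\nSD = %.3f   ADO = %.3f   %s",
                 report$cell_id, report$coverage, report$unit_size,
                 report$vaf_sd, report$ado_rate, report$label)
  p <- ggplot2::ggplot(data.frame(vaf = vaf), ggplot2::aes(x = vaf)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = config$bin_width),
                            closed = "left", fill = "grey35", colour = "white",
                            linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "SNP-unit haplotype-1 allele frequency",
                  y = "SNP units", title = lab) +
    ggplot2::theme_bw(base_size = 10)
  ok <- tryCatch({
    ggplot2::ggsave(out_path, p, width = 5, height = 3.5, dpi = 150)
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write histogram to '%s': %s", out_path,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(bins)
}
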