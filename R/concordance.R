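# Shallow-vs-deep validation experiment on simulated cells.

#' Shallow/deep concordance experiment on simulated cells
#'
#' Simulates a panel of cells spanning the amplification-quality spectrum
#' (bias and dropout increase together from perfectly uniform to very
#' bad), sequences each cell at shallow and deep coverage with shared
#' amplification weights, and compares the shallow SNP-unit VAF standard
#' deviation against the deep per-site one. The Spearman correlation
#' across cells measures how faithfully the shallow, unit-based estimate
#' reproduces the deep ranking; cells whose shallow run is undeterminable
#' (fewer than `min_informative_units` informative units, see
#' [metric_config()]) are excluded from the correlation, as they would be
#' from a real selection.
#'
#' @param sites phased-site data.frame (e.g. from
#'   [simulate_phased_hets()]).
#' @param n_cells number of simulated cells (evenly spaced over the
#'   parameter ranges).
#' @param bias_range range of `bias_sigma` across the panel.
#' @param dropout_range range of `dropout_prob` across the panel.
#' @param shallow_coverage,deep_coverage sequencing depths (x).
#' @param read_length read length (bp).
#' @param unit_size_shallow SNP-unit size for the shallow pass; default
#'   derived from `shallow_coverage` via [compute_unit_size()].
#' @param unit_size_deep unit size for the deep pass (default 1: per-site
#'   VAFs).
#' @param seed base seed; per-cell seeds are derived deterministically.
#' @param config a [metric_config()].
#' @return list with `cells` (per-cell data.frame: parameters, shallow
#'   and deep `vaf_sd` / `ado_rate`, `determinable`), `spearman_sd`,
#'   `spearman_ado`, `spearman_combined` (correlations over determinable
#'   cells) and `n_cells_used`.
#' @export
shallow_deep_concordance <- function(sites, n_cells = 24,
                                     bias_range = c(0, 3),
                                     dropout_range = c(0, 0.5),
                                     shallow_coverage = 0.3,
                                     deep_coverage = 30,
                                     read_length = 100L,
                                     unit_size_shallow = NULL,
                                     unit_size_deep = 1L,
                                     seed = 1L,
                                     config = metric_config()) {
  stopifnot(n_cells >= 2)
  if (is.null(unit_size_shallow))
    unit_size_shallow <- compute_unit_size(shallow_coverage, read_length)
  sigma <- seq(bias_range[1], bias_range[2], length.out = n_cells)
  dropout <- seq(dropout_range[1], dropout_range[2], length.out = n_cells)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cfg <- sim_cell_config(cell_id = sprintf("sim%02d", i),
                           bias_sigma = sigma[i], dropout_prob = dropout[i],
                           coverage = shallow_coverage,
                           read_length = read_length,
                           seed = derive_seed(seed, i))
    pair <- paired_shallow_deep(sites, cfg, deep_coverage = deep_coverage)
    rs <- cell_metrics(build_snp_units(pair$shallow, unit_size_shallow),
                       config, cell_id = cfg$cell_id,
                       coverage = shallow_coverage,
                       unit_size = unit_size_shallow)
    rd <- cell_metrics(build_snp_units(pair$deep, unit_size_deep),
                       config, cell_id = cfg$cell_id,
                       coverage = deep_coverage, unit_size = unit_size_deep)
    rows[[i]] <- data.frame(
      cell_id = cfg$cell_id, bias_sigma = sigma[i], dropout_prob = dropout[i],
      n_units_shallow = rs$n_units_informative,
      vaf_sd_shallow = rs$vaf_sd, vaf_sd_deep = rd$vaf_sd,
      ado_shallow = rs$ado_rate, ado_deep = rd$ado_rate,
      determinable = rs$determinable, stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  use <- cells$determinable
  sp <- function(a, b) cor(a[use], b[use], method = "spearman")
  list(cells = cells,
       spearman_sd = sp(cells$vaf_sd_shallow, cells$vaf_sd_deep),
       spearman_ado = sp(cells$ado_shallow, cells$ado_deep),
       spearman_combined = sp(cells$vaf_sd_shallow + cells$ado_shallow,
                              cells$vaf_sd_deep + cells$ado_deep),
       n_cells_used = sum(use))
}
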