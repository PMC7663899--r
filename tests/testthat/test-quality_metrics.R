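test_that("SNP-unit size scales inversely with coverage", {
  expect_identical(compute_unit_size(0.30, 100), 100L)
  expect_identical(compute_unit_size(30, 100), 1L)
  expect_identical(compute_unit_size(0.15, 100), 200L)
  # above 30x a single HET is always its own unit
  expect_identical(compute_unit_size(60, 100), 1L)
  # other read lengths scale by 100 / read_length
  expect_identical(compute_unit_size(0.30, 50), 200L)
  expect_error(compute_unit_size(0), "positive")
  expect_error(compute_unit_size(-1), "positive")

  # non-increasing in coverage
  grid <- c(0.05, 0.1, 0.2, 0.3, 0.5, 1, 5, 10, 29, 30, 40)
  sizes <- vapply(grid, compute_unit_size, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("build_snp_units blocks consecutive sites with the remainder rule", {
  counts <- make_units_counts(rep(0.5, 250), unit_size = 1L)
  u <- build_snp_units(counts, 100)
  expect_equal(nrow(u), 3L)  # 100 + 100 + 50 (= ceiling(100/2), kept)
  expect_equal(u$n_sites, c(100L, 100L, 50L))

  # remainder below half the unit size is discarded and counted
  u2 <- build_snp_units(counts[1:230, ], 100)
  expect_equal(nrow(u2), 2L)
  expect_equal(attr(u2, "n_sites_discarded"), 30L)

  # unit_size 1 reduces to per-site VAFs
  u3 <- build_snp_units(counts[1:10, ], 1)
  expect_equal(u3$n_sites, rep(1L, 10))
  expect_equal(u3$unit_vaf,
               counts$hap1_reads[1:10] /
                 (counts$hap1_reads[1:10] + counts$hap2_reads[1:10]))

  expect_error(build_snp_units(counts, 0), "unit_size")
})

test_that("units never span chromosomes", {
  a <- make_sites(100, chrom = "chr1")
  b <- make_sites(100, chrom = "chr2")
  counts <- rbind(a, b)
  counts$hap1_reads <- 1L; counts$hap2_reads <- 1L; counts$other_reads <- 0L
  u <- build_snp_units(counts, 100)
  expect_equal(nrow(u), 2L)
  expect_equal(u$chrom, c("chr1", "chr2"))
  expect_equal(u$n_sites, c(100L, 100L))
})

test_that("pooled unit reads conserve the per-site totals", {
  counts <- withr::with_seed(3L, {
    x <- make_sites(137)
    x$hap1_reads <- rpois(137, 1.3)
    x$hap2_reads <- rpois(137, 0.7)
    x$other_reads <- 0L
    x
  })
  for (us in c(1, 7, 30, 137)) {
    u <- build_snp_units(counts, us)
    kept <- sum(u$n_sites)
    expect_equal(sum(u$hap1_reads) + sum(u$hap2_reads),
                 sum(counts$hap1_reads[1:kept]) + sum(counts$hap2_reads[1:kept]))
  }
  # a unit with zero pooled reads has undefined VAF
  z <- counts[1:4, ]
  z$hap1_reads <- 0L; z$hap2_reads <- 0L
  expect_true(all(is.na(build_snp_units(z, 2)$unit_vaf)))
})

test_that("a unit spanning a HET desert triggers the span warning", {
  counts <- make_units_counts(rep(0.5, 4), unit_size = 1L)
  counts$pos <- c(1000L, 2000L, 2e6L, 3e6L)
  expect_warning(build_snp_units(counts, 4), "span")
})

test_that("cell metrics match closed-form values on fixed VAF patterns", {
  cfg <- metric_config()
  # perfectly balanced units
  u <- build_snp_units(make_units_counts(c(0.5, 0.5, 0.5)), 1)
  r <- cell_metrics(u, cfg, cell_id = "flat")
  expect_equal(r$vaf_sd, 0)
  expect_equal(r$ado_rate, 0)
  expect_equal(r$combined_score, 0)
  expect_equal(r$label, "good")
  expect_false(r$determinable)  # 3 units cannot support a trusted sd

  # total dropout alternating between haplotypes: sample sd of {0,1,0,1}
  u2 <- build_snp_units(make_units_counts(c(0, 1, 0, 1)), 1)
  r2 <- cell_metrics(u2, cfg, cell_id = "ado")
  expect_equal(r2$ado_rate, 1)
  expect_equal(r2$vaf_sd, sd(c(0, 1, 0, 1)))
  expect_equal(r2$vaf_sd, 0.5773503, tolerance = 1e-6)
  expect_equal(r2$combined_score, r2$vaf_sd + 1)

  # units below min_reads_per_unit are not informative
  u3 <- build_snp_units(make_units_counts(c(0.5, 0.5, 0.5, 0.5),
                                          reads_per_unit = 4L), 1)
  expect_error(cell_metrics(u3, cfg), "no informative")
  r3 <- cell_metrics(u3, metric_config(min_reads_per_unit = 2))
  expect_equal(r3$n_units_informative, 4L)
})

test_that("unbiased binomial counts reproduce the sqrt(0.25/m) dispersion", {
  m <- 30L
  vafs <- withr::with_seed(21L, rbinom(10000, m, 0.5) / m)
  counts <- make_units_counts(vafs, reads_per_unit = m)
  r <- cell_metrics(build_snp_units(counts, 1), cell_id = "binom")
  expect_equal(r$vaf_sd, sqrt(0.25 / m), tolerance = 0.03)
  expect_true(r$determinable)
})

test_that("vaf_sd is invariant under a global haplotype swap", {
  for (seed in 1:5) {
    counts <- withr::with_seed(seed, {
      x <- make_sites(300, seed = seed)
      x$hap1_reads <- rpois(300, 20)
      x$hap2_reads <- rpois(300, 5)
      x$other_reads <- 0L
      x
    })
    swapped <- counts
    swapped$hap1_reads <- counts$hap2_reads
    swapped$hap2_reads <- counts$hap1_reads
    r1 <- cell_metrics(build_snp_units(counts, 10), cell_id = "a")
    r2 <- cell_metrics(build_snp_units(swapped, 10), cell_id = "b")
    expect_equal(r1$vaf_sd, r2$vaf_sd, tolerance = 1e-12)
    expect_equal(r1$ado_rate, r2$ado_rate)
  }
})

test_that("classification thresholds split good / moderate / bad", {
  expect_equal(classify_cell(0.20), "good")
  expect_equal(classify_cell(0.30), "moderate")
  expect_equal(classify_cell(0.40), "bad")
  # boundaries are inclusive for "moderate"
  expect_equal(classify_cell(0.26), "moderate")
  expect_equal(classify_cell(0.35), "moderate")
  expect_equal(classify_cell(c(0, 0.5)), c("good", "bad"))
  expect_error(classify_cell(-0.1))
})

test_that("rank_cells orders ascending with deterministic tie-breaks", {
  reports <- data.frame(
    cell_id = c("A", "B", "C"),
    vaf_sd = c(0.3, 0.2, 0.4),
    ado_rate = c(0.0, 0.0, 0.0),
    combined_score = c(0.3, 0.2, 0.4),
    stringsAsFactors = FALSE)
  expect_equal(rank_cells(reports, "sd")$cell_id, c("B", "A", "C"))

  ties <- data.frame(cell_id = c("A", "B"), vaf_sd = c(0.3, 0.3),
                     ado_rate = c(0.2, 0.1), combined_score = c(0.5, 0.4),
                     stringsAsFactors = FALSE)
  expect_equal(rank_cells(ties, "sd")$cell_id, c("B", "A"))

  comb <- data.frame(cell_id = c("A", "B"), vaf_sd = c(0.2, 0.3),
                     ado_rate = c(0.3, 0.1), combined_score = c(0.5, 0.4),
                     stringsAsFactors = FALSE)
  expect_equal(rank_cells(comb, "combined")$cell_id, c("B", "A"))
  expect_equal(rank_cells(comb, "combined")$rank, c(1L, 2L))
})

test_that("MAPD matches hand-computed values", {
  expect_equal(compute_mapd(c(5, 5, 5, 5)), 0)
  expect_equal(compute_mapd(c(1, 3, 1, 3)), 1.0)
  expect_equal(compute_mapd(c(2, 2, 4)), 0.375)
  expect_error(compute_mapd(c(0, 0, 0)), "zero")
  expect_error(compute_mapd(5))
})

test_that("VAF histogram bins are written and conserve the unit count", {
  dir <- withr::local_tempdir()
  u <- build_snp_units(make_units_counts(rep(0.5, 1000)), 1)
  r <- cell_metrics(u, cell_id = "h")
  out <- file.path(dir, "h.png")
  bins <- plot_vaf_histogram(u, r, out)
  expect_true(file.exists(out))
  expect_true(file.exists(file.path(dir, "h.bins.tsv")))
  expect_equal(sum(bins$count), r$n_units_informative)
  # all mass in the [0.50, 0.52) bin
  expect_equal(bins$count[bins$bin_start == 0.5], 1000L)
  expect_true(all(bins$count[bins$bin_start != 0.5] == 0L))

  # histogram mode of a balanced simulated cell is within one bin of 0.5
  vafs <- withr::with_seed(5L, rbinom(2000, 30, 0.5) / 30)
  u2 <- build_snp_units(make_units_counts(vafs), 1)
  bins2 <- plot_vaf_histogram(u2, cell_metrics(u2, cell_id = "b"),
                              file.path(dir, "b.png"))
  expect_lte(abs(bins2$bin_start[which.max(bins2$count)] - 0.5), 0.02 + 1e-9)

  expect_error(plot_vaf_histogram(u[0, ], r, out), "no informative")
})
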