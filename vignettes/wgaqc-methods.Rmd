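---
title: "Ranking single-cell amplification quality from shallow sequencing: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking single-cell amplification quality from shallow sequencing: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Single-cell whole-genome sequencing requires amplifying one cell's ~6 pg of
DNA, usually by multiple displacement amplification (MDA). MDA amplifies the
genome in long fragments (roughly 50–70 kb) and does so unevenly: at a given
locus the two parental haplotypes may be amplified to very different final
copy numbers, up to complete allelic dropout (ADO), where one haplotype's
fragment is simply absent from the library. Since deep sequencing
(~30×) of every candidate cell is expensive, one wants to *triage* cells
from a shallow (0.1–0.4×) pass and deep-sequence only the well-amplified
ones.

At 30×, amplification balance is directly visible in the variant allele
frequency (VAF) of heterozygous germline SNPs (HETs): a balanced cell shows
a bell-shaped VAF distribution centred at 0.5; a biased cell shows wide
dispersion and mass near 0 and 1. At 0.3× an individual HET carries on
average 0.3 reads, so its VAF is meaningless. The method implemented here
restores the deep-coverage picture by *pooling* consecutive HETs.

## The SNP-unit model

HETs are first phased (externally — e.g. SHAPEIT2; this package consumes the
phased VCF), so that for every HET we know which allele lies on haplotype 1
and which on haplotype 2. Because MDA amplifies tens-of-kilobase fragments
as a whole, *consecutive* HETs share their amplification fate, and their
reads can be pooled coherently along haplotypes.

A **SNP unit** is a block of consecutive retained HETs on one chromosome.
Its VAF is

$$\mathrm{VAF}_u \;=\; \frac{r^{(1)}_u}{r^{(1)}_u + r^{(2)}_u},$$

where $r^{(h)}_u$ is the pooled count of reads supporting haplotype-$h$
alleles across the unit's sites (bases matching neither allele are
excluded; see *Open choices* below). The unit size is chosen so that a unit
at shallow coverage carries the read support a single HET has at 30×:

$$\text{unit size} = \frac{30}{\text{coverage}} \cdot \frac{100}{\text{read length}},$$

rounded to an integer and clamped to 1 for coverage ≥ 30×. At 0.3× with
100 bp reads this gives 100 HETs per unit (~30 pooled reads); at 30× each
HET is its own unit. `compute_unit_size()` implements exactly this;
`cmd_rank()` lets the user override it.

Per cell, over units with at least `min_reads_per_unit` (default 10) pooled
haplotype reads ("informative" units):

* `vaf_sd` — the sample standard deviation of unit VAFs. This is the primary
  dispersion metric.
* `ado_rate` — the fraction of informative units with VAF ≤ 0.01 or ≥ 0.99.
  The literature uses "allelic dropout rate" without a formula; we define it
  at unit granularity as the fraction of units where one haplotype is
  essentially unobserved, which captures "random and drastic
  overrepresentation of one allele".
* `combined_score = vaf_sd + ado_rate` — the simplest additive combination;
  the two addends are on comparable scales (both bounded by ~0.58 and 1)
  and no weighting is suggested by the data we simulate.

Cells are classified from `vaf_sd`: **good** below 0.26, **moderate** from
0.26 to 0.35 inclusive, **bad** above 0.35. The interval reading "between
0.26 and 0.35" is taken as inclusive on both ends, so exactly 0.26 and
exactly 0.35 are moderate. `rank_cells()` orders cells ascending by the
chosen metric with deterministic tie-breaks (then `ado_rate`, then
`cell_id`).

As a depth-uniformity baseline, `compute_mapd()` implements MAPD: bin
counts normalized by their mean, median absolute difference of adjacent
bins. MAPD sees only total-depth fluctuation; it is blind to allelic
imbalance that preserves depth, which is the key advantage of the
haplotype-based metric.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_mapq`, `min_baseq` | 20, 20 | phred | standard SNP-counting pileup filters; configurable because the original pipeline does not pin them |
| `min_reads_per_unit` | 10 | reads | a unit VAF from fewer reads is dominated by sampling noise at any amplification quality |
| `ado_low`, `ado_high` | 0.01, 0.99 | VAF | a unit is a dropout unit when ≤ 1% of its reads come from one haplotype |
| `sd_good_max`, `sd_moderate_max` | 0.26, 0.35 | VAF sd | the published classification thresholds |
| `min_informative_units` | 10 | units | below this the sd estimate has ≥ ~25% relative standard error (`1/sqrt(2(n-1))`); the cell is flagged not *determinable* rather than ranked — the same judgement the original study applied to a too-shallow cell |
| `bin_width` | 0.02 | VAF | fixed histogram binning for cross-cell comparability |
| `fragment_len_range` | 50–70 kb | bp | typical MDA amplified-fragment length |

## SNP-unit construction choices

Several details are not dictated by the published description and were
fixed as follows:

* **Consecutiveness is HET-index adjacency, not base-pair distance.** Units
  are blocks of adjacent *retained* HETs, which stays well-defined across
  HET deserts; a warning fires when a unit spans > 1 Mb, since such a unit
  averages many amplified fragments.
* **Units never cross chromosome boundaries.**
* **Remainder rule.** The trailing sub-unit at a chromosome end is kept if
  it has at least half the unit size (≥ `ceiling(unit_size/2)` sites), else
  discarded and counted. This keeps data without admitting tiny,
  high-variance units.
* **Sample (n−1) standard deviation** — conventional; negligible against
  the population form at realistic unit counts.
* **Boundary classification** — 0.26 and 0.35 are both "moderate" (see
  above).
* **Coverage estimation** multiplies passing-read count by modal read
  length instead of a per-base traversal; at < 1× the two agree to well
  under a percent.
* **Overlapping mate pairs are counted independently** in the pileup. At
  < 1× coverage, two mates of one fragment overlapping the same HET is a
  rare event; the counting layer inherits this behaviour from the
  underlying pileup engine.

## The simulator: what it emulates

`sim_cell_config()` / `simulate_cell_counts()` implement an explicit
generative model of MDA bias:

1. Each haplotype of each chromosome is independently tiled into fragments
   with lengths uniform on 50–70 kb (independent tilings reflect
   independent template fragmentation during lysis).
2. Each (fragment, haplotype) draws an amplification weight: 0 with
   probability `dropout_prob`, otherwise lognormal with log-scale sd
   `bias_sigma`. The lognormal is the standard multiplicative-noise model
   for exponential amplification; one dispersion knob spans the whole
   quality spectrum (σ = 0 perfectly uniform → σ ≈ 3 very bad).
3. Weights are normalized to the cell's realized mean: the sequencer is
   loaded to the target depth whatever the amplification yield, so
   `coverage` keeps its meaning for every cell. Without this, high-σ cells
   would collapse to near-zero depth and bias would be confounded with
   coverage.
4. Per-site haplotype read counts are Poisson with rate
   `coverage/2 × weight`, all sites of a fragment sharing the fragment's
   weight — consecutive SNPs are amplified together, which is precisely the
   correlation structure the SNP unit exploits.

`paired_shallow_deep()` reuses one weight draw for a shallow (0.3×) and a
deep (30×) sampling of the *same* cell, emulating re-sequencing selected
cells at depth.

**What the simulator does not emulate:** read sequences and sequencing
error, GC and mappability bias, chimeric reads, C→T deamination artifacts,
copy-number variation, mate-pair structure. Passing the validation suite
therefore demonstrates that the metrics recover *amplification imbalance
of the simulated kind* from shallow counts — not that the pileup layer is
robust to alignment pathology, which is upstream of this tool's scope.

Default problem sizes were chosen so the whole validation suite runs in
seconds: a 3 Mb toy genome with exponential HET spacing (mean 1.5 kb,
~2000 HETs, matching the ~1 HET per 1.5 kb density of a human genome), 24
cells per concordance panel with `bias_sigma` and `dropout_prob` rising
together over [0, 3] × [0, 0.5] (a cohort spanning good to bad, as a real
selection experiment would see). Two experiments use a 6 Mb genome
instead: the dropout-recovery sweep (a dropout unit at shallow granularity
requires every overlapping fragment of one haplotype to drop — a rare
event that needs more units for a stable mean) and the
oversized-unit check below.

## Validation properties

The test suite asserts, among others:

* **Binomial limit.** For an unbiased cell, unit VAFs are binomial splits
  of ~Poisson(30) reads, so `vaf_sd` must approach
  $\sqrt{0.25/30} \approx 0.091$; checked against this closed form at
  ~10 000 units.
* **Haplotype-swap invariance.** Relabelling haplotypes maps every VAF to
  1−VAF and must leave `vaf_sd` and `ado_rate` unchanged.
* **Parameter recovery.** Mean `vaf_sd` is strictly increasing in
  `bias_sigma`, and mean `ado_rate` in `dropout_prob`, over seeded
  replicate sweeps.
* **Shallow/deep concordance.** Across a 24-cell panel, Spearman
  correlation between shallow unit-based `vaf_sd` (0.3×, unit 100) and
  deep per-site `vaf_sd` (30×, unit 1) — computed over determinable cells,
  exactly as a real selection would use it.
* **Fragment averaging.** When the unit is forced to ~10× the per-fragment
  HET count (unit 400 at 1.5 kb spacing), a unit averages over many
  fragments and the shallow dispersion *under*-estimates the deep one for
  a biased cell — the known caveat of running this QC below ~0.3×
  coverage, and the reason `cmd_rank()` warns there.
* **Route equivalence.** The BAM pileup route and the counts-table fast
  route produce identical reports on fixtures constructed so the pileup is
  known exactly.

## Numerical and degenerate-input choices

* All generators are deterministic given their seed; sub-streams
  (weights vs shallow vs deep sampling) are derived from the cell seed with
  a fixed integer recurrence, so paired designs are reproducible
  element-wise.
* A unit with zero pooled haplotype reads has undefined VAF (`NA`), never
  0/0 → `NaN`; such units are excluded by the informativeness filter.
* A cell with *no* informative units is an error at the metrics level and
  a `FAILED` row (run continues) at the pipeline level.
* Histogram breaks are rounded to 10 decimals so exact VAFs (e.g. 0.5)
  land in the bin their value names.
* Multi-allelic VCF records are dropped whole, not decomposed: two-haplotype
  arithmetic assumes biallelic sites. Sex chromosomes and mitochondria are
  excluded by default (`autosomes_only = FALSE` re-admits them for known
  diploid cases).
* Ties in ranking are broken by `ado_rate`, then `cell_id`.

## Open choices, resolved

* **VAF denominator.** Reads matching neither haplotype allele
  ("other" bases: sequencing errors, contamination) are excluded from the
  unit VAF denominator. Including them would deflate both haplotype
  fractions with noise unrelated to amplification balance; they are still
  reported per site.
* **DP/GQ pre-filters on the bulk VCF.** None are applied by default — the
  bulk caller's FILTER column is trusted (only `PASS`/`.` records pass
  unless `keep_filtered`); exposing further thresholds belongs to the
  caller, not this tool.
* **Below 0.3× coverage** the tool warns (units span multiple fragments,
  bias averages out, a bad cell can look good) and proceeds; the
  `unit_size` override exists for users who prefer fixed-size units at a
  known cost in read support per unit.

## Limitations

* The haplotype metric needs phased HETs; phasing errors (switch errors)
  make consecutive sites disagree and inflate dispersion slightly. The
  simulator does not model switch errors.
* Thresholds 0.26/0.35 come from one experimental context; the package
  exposes them (`metric_config`) rather than asserting universality.
* The simulator's σ and dropout are calibration knobs, not estimates of a
  real MDA process; concordance numbers measured on it characterise the
  estimator, not any particular chemistry.

## Running the pieces together

```{r, eval = FALSE}
library(wgaqc)

# simulate a toy genome and a moderately biased cell
sites <- simulate_phased_hets(sim_genome_config(seed = 1))
counts <- simulate_cell_counts(
  sites, sim_cell_config(bias_sigma = 1.5, coverage = 0.3, seed = 2))

units <- build_snp_units(counts, compute_unit_size(0.3, 100))
cell_metrics(units, cell_id = "demo", coverage = 0.3, unit_size = 100)
```

For BAM input the same flow is `cmd_prepare_sites()` →
`cmd_count()` → `cmd_rank()`, or the `inst/cli/wgaqc` script with the
subcommands `prepare-sites`, `count`, `rank`, `simulate`.
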