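---
title: "Titrating oligo-conjugated antibody panels: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Titrating oligo-conjugated antibody panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtiter)
```

## Why titrate by sequencing cost

Antibody-derived tags (ADTs) report surface-protein abundance as UMI
counts, so signal intensity translates directly into sequencing cost. Two
consequences drive everything in this package. First, the optimum is not
the saturation plateau familiar from flow cytometry but the lowest
concentration that still separates positive from negative cells, with read
usage balanced across the panel. Second, the dominant background source is
free antibody left in suspension after washing: it partitions into the
enormous excess of empty droplets, where it is measurable — and into
cell-containing droplets, where it obscures signal. Empty droplets are
therefore not waste; they are the assay's built-in background control.

## The droplet partition

Cell-containing barcodes are separated from empty ones at the knee of the
RNA barcode-rank curve. `barcode_rank_curve()` sorts per-barcode UMI totals
descending (ties broken by barcode string, so the curve is deterministic);
`find_inflection()` returns the rank maximizing the negative derivative of
`log10(total)` against `log10(rank)`.

Three numerical choices matter here:

* **Run-length collapsing.** The deep tail of a UMI rank curve is almost
  entirely ties; per-rank discrete derivatives there produce arbitrarily
  large spurious spikes (a drop of one count across a tiny `log10(rank)`
  increment). The derivative is therefore evaluated between *distinct*
  totals, as is standard for knee detectors on these curves.
* **Smoothing with refinement.** The slope sequence is smoothed by a
  centred moving average (default window 11 distinct steps, shrinking at
  the ends) to find the descent region, then the steepest *unsmoothed*
  step within twice the window is returned — averaging over `w` steps can
  displace the argmin of an asymmetric descent by up to about `w`.
* **Guard rails.** The search is restricted to `[min_cells, max_cells]`
  (defaults 100 and unbounded; set `max_cells` to ~5x the expected cell
  count when the expected yield is known), and a curve whose steepest
  smoothed slope never falls below `slope_threshold` (default −2) is
  rejected with advice to set a manual cutoff, rather than silently
  returning a meaningless rank.

QC (default: at least 60 detected genes and mitochondrial fraction below
15%) runs *after* the partition. Failing barcodes sit above the knee but
are not intact cells, so by default they are labelled `removed` and join
neither pool — the empty-droplet background stays uncontaminated and the
cell pool stays viable. Counting them as empty instead is a documented
switch (`removed_to_empty`), since the partition definition alone would put
them there.

## Detection gates and the metric suite

The positive/negative gate for a marker is the 0.99 quantile (linear
interpolation) of its empty-droplet counts, floored at 1 UMI. Gating off
the ambient distribution rather than manual inspection is the package's
default because background level and usable cutoff are tightly coupled:
markers with high ambient load need proportionally higher cutoffs. A cell
is positive strictly above the gate.

Per marker and condition, `marker_metrics()` reports: total cell-UMIs; the
90th-percentile count within the expressing cell type (chosen as the type
with the highest per-cell *mean*, which tolerates bimodal clusters better
than the median; a panel-sheet override is available); positive fraction;
`snr`, the median positive count minus the median negative count (0 when
nothing is positive; an empty negative set contributes 0); UMIs per
positive cell as a share of all panel cell-UMIs (the marker-only
denominator is available via `per_positive_denominator`); the background
percentage `100 * empty / (empty + cells)`; and the marker's UMI frequency
in each compartment with their ratio. Frequencies sum to one per
compartment by construction. Dilution response uses a pseudocount of 1 on
both sides of the log-ratio — zeros are routine at realistic depth — so a
perfectly linear marker shows `log2(DF)` minus a small pseudocount bias.

## The five response categories

Classification thresholds that remain qualitative in practice are made
explicit in `classifier_config()`: `r_min = 0.5` log2 units is the minimal
response that counts as responding; `s_min = 5` UMIs is the minimal
separation (consistent with typical median positive signals of order 7–11
UMIs at optimized concentrations); `u_min = 0.90` positive fraction defines
ubiquity; `b_high = 50%` background marks background domination;
`e_max = 0.2%` of panel UMIs marks a functionally dead marker; `t_low = 3`
UMIs marks a gate with no headroom. The rules are evaluated in a fixed
order (D, E, A, B, C, then `review`), which resolves overlaps the way a
panel designer would: a ubiquitous marker that also responds linearly is
still D; a marker that separates in any tissue is not dead, so per-tissue
results reconcile by priority D > B > C > A > E
(`reconcile_categories()`). Near-boundary records fall through to
`review` rather than being forced into a letter.

Recommended multipliers (A 0.25x, B 0.5x, C 1x or 0.8x when the reference
gate is far above `t_low`, D 0.25x plus a drop suggestion, E 3x plus a
review flag) are starting points, all overridable; the rationale string on
every recommendation cites the metrics that triggered it.

## Fair cross-condition comparison

Comparisons between conditions are confounded by composition and depth.
`equalize_celltypes()` down-samples each condition to the per-type minimum
count (uniformly, seeded). `match_in_embedding()` implements greedy
nearest-neighbour pairing in a supplied integrated embedding: within each
cluster, every cell of the smaller sample takes its nearest unused
neighbour in the larger one, in a seed-shuffled order. Greedy matching (not
optimal assignment) is deliberate — it is what the procedure describes and
it is transparent; the tests verify it lands within 10% of a brute-force
greedy oracle's total distance.

`thin_counts()` equalizes sequencing depth at the UMI level: an exact
multivariate hypergeometric subsample, implemented as sequential
conditional `rhyper()` draws, so the thinned total is met exactly and no
entry grows. The original procedure thinned FASTQ reads; at the count-matrix
level the UMI-collapse nonlinearity is invisible, so a two-stage mode
(`mode = "reads"`) inflates each molecule to a Poisson number of reads,
thins reads, and re-collapses — use it when sequencing saturation itself is
under study. Saturation follows the 10x convention `1 − UMIs/reads`.

## The simulator

`simulate_lane()` generates droplet lanes with known truth from the
simplest mechanism that reproduces the four phenomena a titration
manipulates:

* **Equilibrium binding with depletion.** Free antibody solves the
  single-site mass-balance quadratic (closed form, cancellation-stable;
  conservation `C_free + R_tot·θ = C_tot` holds to 1e-9). Saturation
  plateau (`C ≫ Kd`), linear range (`θ ≈ C/Kd` for `C ≪ Kd` with antibody
  in excess), and depletion at high epitope load all emerge from it.
  Epitope copy numbers convert to concentration units via an IgG molecular
  weight of 150 kDa, so staining volume and cell number act through
  `R_tot` exactly as in the wet protocol.
* **A shared ambient pool.** Hashed conditions are pooled into one lane,
  so every droplet — cell or empty — draws ambient molecules
  `Poisson(ambient_scale · w · mean_j C_free_j)` from a single pool, `w`
  being the wash-retention fraction. This is why high-concentration
  markers show the same background in every condition and essentially no
  apparent dilution response: the mean over pooled conditions barely moves.
  Per-sample ambient pools are intentionally not modelled.
* **Finite depth.** Each molecule is observed with probability
  `1 − exp(−reads_per_umi)` (a Poisson-reads approximation; read-level
  simulation is available through the thinning module instead).
* **RNA and HTO as scaffolding.** RNA totals are a two-component mixture
  (negative-binomial cells over ~200 genes including `MT-` genes, Poisson
  ambient empties) — just enough structure to exercise rank-curve
  partitioning and QC, with no claim to realistic expression. HTO counts
  are own-sample Poisson signal over a weak ambient floor.

Defaults describe the study conditions this package targets: 50 uL
staining volume, 1e6 cells at staining, fourfold dilution between
conditions, 500 captured cells per condition against 5000 empty droplets,
capture efficiency 2e-3, wash retention 0.05, ambient scale 16,
`reads_per_umi = 1.5` (78% detection). `archetype_panel()` fixes ten
markers, two per category, whose Kd/epitope/concentration combinations
realize each category's defining behaviour under those conditions; its
parameters are documented in the function and were chosen from the binding
model, not fitted to any test outcome.

What passing simulator-based tests does **not** show: robustness to
Fc-receptor-mediated nonspecific binding, antibody aggregates, per-sample
ambient differences, doublet-driven artefacts, or real RNA structure. The
simulator validates the *logic* of the pipeline (partition, gating,
metrics, classification, cost accounting) under a mechanism that produces
the right qualitative phenomena — it is not a generative model of any real
dataset.

## Problem sizes and determinism

Every stochastic entry point takes a seed and restores the caller's RNG
state; one seed reproduces a full pipeline run bit-identically, and the
run log written by `run_pipeline()` (config echo plus seed) is sufficient
to do so. The bundled test and acceptance workloads use lanes of 10
markers with 300–1000 cells and 2000–6000 empty droplets, 10–20 replicate
simulations per property, and 1000 random parameter triples for the
solver-versus-bisection check; these sizes give stable means for every
property tested while keeping a full run in the tens of seconds on one
core.

## Known limitations

* Categories A and E can be genuinely ambiguous for a marker with no
  visible positives: distinguishing "obscured by background" from "no
  epitope" uses background share and panel share only, and borderline
  records are deliberately routed to `review`.
* The exact denominator for "UMIs used for background signal" admits more
  than one reading; the per-marker share-in-empty-droplets definition is
  used and flagged in the documentation.
* Cell-type labels and embeddings are *inputs*: clustering, annotation and
  integration live upstream of this package.
* Read-level effects (PCR duplication structure, saturation curvature) are
  approximated; use the two-stage thinning mode where they matter.
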