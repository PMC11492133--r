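---
title: "Calling and characterising TFBS clustered regions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterising TFBS clustered regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Transcription-factor binding sites (TFBSs) in accessible chromatin are not
spread evenly: they aggregate into clustered regions that behave like
cis-regulatory elements. `tfcrpipe` identifies such TFBS clustered regions
(TFCRs) and scores how many — and how tightly — transcription factors can
engage each one.

Given motif hits (FIMO-style scans of ATAC-seq peaks), every hit is reduced
to its interval midpoint and the per-chromosome intensity

$$f(x) \;=\; \sum_j \exp\!\left(-\frac{(x - m_j)^2}{2\sigma^2}\right)$$

is evaluated on a regular grid. Each local maximum of $f$ is a TFCR. The sum
is deliberately **unnormalised**: a single site at zero distance contributes
1.0, so the downstream contribution threshold has an absolute meaning that
does not drift with the number of sites, as it would for a probability
density.

A site *contributes* to a TFCR when its kernel weight at the peak is at
least $\theta = 0.1$; equivalently when it lies within the cutoff radius
$\sigma\sqrt{2\ln(1/\theta)} \approx 643.8$ bp at the default
$\sigma = 300$ bp. Per TFCR:

* **TC (complexity)** — the kernel-weight sum over contributing sites after
  family–locus deduplication: same-family sites whose intervals overlap
  (transitively) count once, keeping the group's maximum weight. Same-family
  sites at distinct loci, and different families anywhere, count separately.
  TC therefore reflects the diversity of factors that can co-occupy a
  region, not motif redundancy at one spot.
* **TW (width)** — the genomic span of the contributing site intervals
  (widened minimally to contain the peak base). Width reflects binding-site
  extent rather than a density level set.
* **cw** — unit-base complexity, TC/TW: a density of regulatory potential.
* **CAS** — mean score of ATAC peaks overlapping the TFCR by ≥ 1 bp. The
  accessibility score cited by the literature this package follows is not
  restated there; the overlapping-peak mean is this package's own
  definition, and is documented as such.

TFCRs are linked to genes by nearest TSS in both directions (all
exact-distance ties retained; distance is $|TSS - \mathrm{peak}|$, clamped
to 0 when the TSS lies inside the TFCR). Links are classified by absolute
distance $d$ into R1 ($d \le 2$ kb, proximal/promoter-like, "p-TFCR"),
R2 ($2$–$27$ kb), R3 ($27$–$50$ kb) and R4 ($d > 50$ kb, long-range
"LR-TFCR"), with boundaries belonging to the lower region.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `bandwidth_bp` | 300 | Gaussian kernel sd, in bp; sets the clustering scale. "Centered at 300 bp" is read as $\sigma = 300$: it is the only bandwidth-like constant available and yields a 0.1-cutoff radius of ~644 bp, a plausible cluster scale. |
| `grid_step_bp` | 10 | density evaluation grid; peaks are then polished to 1 bp (below) |
| `contribution_threshold` | 0.1 | minimum kernel weight for a site to count toward a TFCR |
| `truncation_sigmas` | 4 | kernel support radius in units of $\sigma$ |
| `n_tc_bins` | 10 | per-sample TC decile labels TC0..TC9 |
| thresholds `t1,t2,t3` | 2 kb, 27 kb, 50 kb | region cuts; the published values are authoritative, `derive_thresholds()` re-derives them diagnostically |
| `c`, `m` (trajectories) | 6, 2.0 | fuzzy c-means cluster count and fuzzifier; fixed `m` keeps runs deterministic |

## Numerical choices

**Coordinates.** Everything internal is 0-based half-open; FIMO input
(1-based inclusive) is shifted exactly once at the read boundary. Touching
intervals do not overlap.

**Continuous truncation.** Kernels are truncated at $4\sigma$ *and shifted
down by the edge value* $e^{-8}$ so the track stays continuous. A hard
cutoff leaves step discontinuities of ~$3.4\times 10^{-4}$ that plant
spurious micro-maxima near truncation edges whose presence depends on the
evaluation grid — the shifted kernel removes them at the same
approximation cost. Contribution weights are exact Gaussians, unaffected.

**Peak polish.** Each coarse-grid maximum is refined by a 1-bp argmax of
the same kernel sum within one grid step, so peak positions (and hence
contribution sets, which depend only on the peak) are independent of
`grid_step_bp`. Plateaus collapse to their center base; two equal-height
maxima separated by a strict dip remain distinct TFCRs. Candidate peaks
with no contributing site are discarded.

**Tie rules.** Quantile bins (TC deciles, E6/Q100 expression groups) use
nearest-rank cuts with equal values always sharing the lower bin. Top-cw
selection breaks ties by TC then id. In trajectories, a gene linked to two
equidistant TFCRs takes the larger TC.

**Degenerate inputs.** Constant vectors make Spearman's rho undefined (NA
with a warning, never silently 0); two constant equal samples give a Welch
p of 1; a zero-distance point in fuzzy c-means takes membership 1 at that
center (the $u_{ij} \propto d_{ij}^{-2/(m-1)}$ limit); the c-means
objective is checked to be non-increasing at every iteration.

**Threshold derivation.** `derive_thresholds()` estimates the density of
$\log_{10}(d+1)$, keeps prominent modes (≥ 5% of the maximum height, which
suppresses far-tail ripples), and reports: t1 = the density minimum between
the first two modes, t2 = the second mode snapped to its nearest percentile
of the 99-percentile grid, t3 = min(50 kb, 99th percentile) snapped
likewise. t1 is intentionally *not* snapped: the inter-mode valley holds
almost no data, so its nearest data percentile is unstable — the dense
density grid is the reliable locator there. Unimodal or data-poor inputs
fall back to the published 2/27/50 kb cuts with provenance `"default"`.

## What the synthetic generator emulates — and what it does not

`generate_bundle()` plants one TFBS cluster per gene with known ground
truth: TSS distances from a bimodal-plus-tail mixture (promoter mode
$|N(500, 300)|$, mid mode $N(27\,000, 8\,000)$ truncated above 2 kb, far
tail $U(50\,001, 300\,000)$ — the landmarks observed in real
embryonic-stage data), Poisson family counts (mean 6), Gaussian site
scatter (sd 150 bp), expression following
$\log_{10}\mathrm{FPKM} = a\log_{10}(TC_{true}+c)+b+\varepsilon$ with
$a=2, b=1, c=0.03, \sigma_\varepsilon=0.15$, ATAC peaks spanning each
cluster with score ∝ site count, 1 Mb tiling TADs, and a
phase-separation-flagged (PSTF) family subset that boosts cluster
complexity by 3 families for 35% of clusters. Genes are laid out sparsely
(650–850 kb spacing) so each cluster is unambiguously nearest to its own
gene even in the far tail — that is what makes planted distance categories
recoverable and is a deliberate idealisation.

`generate_stage_panel()` adds a five-stage layout with a planted
activation switch (default at stage 3, the 8Cell position): a planted
fraction of "ZGA" genes has single-family clusters before activation and
elevated (Poisson mean 10) complexity from it onward, and *expression is
pure noise before activation for every gene* (maternal transcripts),
coupling to complexity only from the activation stage. The
complexity–expression correlation therefore switches from ~0 to strongly
positive at activation — a directional property, not a numeric target.

What the generator does **not** emulate: sequence content and motif
scanning (sites are placed directly; a FIMO-dialect writer keeps the I/O
honest), overlapping clusters per gene, background (non-clustered) motif
hits, read-level ATAC noise, chromosome-scale accessibility trends, and
real TAD architecture. Passing the recovery tests therefore shows the
machinery is correct and calibrated on idealised data; it does not certify
performance on real embryonic ATAC-seq, where cluster separation and
signal-to-noise are far less generous.

## Open design points, resolved

* **Site anchor.** A hit is anchored at `floor((start+end)/2)`; no anchor
  convention is stated upstream, and the midpoint is symmetric.
* **Unknown families** bucket to `"UNKNOWN"` instead of being dropped —
  dropping would silently deflate TC.
* **Distance anchor** is the density peak (not an edge or midpoint of the
  interval), because complexity is peak-anchored.
* **TC deciles are per sample/stage**, not pooled, matching within-stage
  comparisons.
* **Cross-stage identity is positional** (≥ 1 bp interval overlap between
  independently called stages), never id-based; "overlaps more than 1 bp"
  is implemented as overlap ≥ 1 bp, since a strict `> 1` would drop
  single-base overlaps arbitrarily.
* **Gained at the first stage and lost at the last are undefined** (empty)
  rather than guessed.
* **Four-group correlation labels** (`TC`, `TW`, `TC&TW`, `nTC&TW`) come
  from the deterministic |cor| > 0.5 rule; k-means on the two correlations
  is an optional seeded diagnostic, because only the threshold rule is
  exactly reproducible.
* **PSTF matching** is by upper-cased TF name; the percentage denominator
  is the count of distinct TFs on the TFCR. TAD membership uses the TFCR
  peak, so a boundary-straddling TFCR gets its peak's TAD.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on
bundles of 500 genes across 5 chromosomes (~4,000 TFBSs per stage) and a
five-stage panel of the same size — large enough for stable rank
statistics, small enough to re-run in about a minute on one core. Every
stochastic step (generator, control sampling, k-means, fuzzy c-means) is
seeded explicitly; a fixed configuration reproduces byte-identical
outputs.

## A worked sketch

```r
library(tfcrpipe)

cfg <- synthetic_config(seed = 1)
b <- generate_bundle(cfg, "demo_bundle")

res <- run_single_stage(
  b$paths["tfbs"], b$paths["genes"],
  expr_path = b$paths["expr"], atac_path = b$paths["atac"],
  family_map_path = b$paths["family_map"],
  out_dir = "demo_out", stage = "demo")

head(res$tfcrs[, c("tfcr_id", "peak_pos", "TC", "TW", "cw", "tc_bin")])
res$region_proportions
derive_thresholds(res$links_t2g)[c("t1", "t2", "t3", "provenance")]
res$stats$spearman_tc[c("rho", "p_value", "stars")]
```

## Known limitations

CAS is a package-defined proxy, not the cited accessibility score. The
threshold derivation is one defensible reading of a procedure whose exact
recipe is unpublished; classification always uses the published cuts
unless the caller opts into derived ones. The complexity formula (kernel
weight sum with family–locus dedup) is this package's reading of
"number and proximity of contributing sites". Headline counts from the
original embryonic study (e.g. the number of stable LR-TFCRs) depend on
proprietary-scale inputs — a specific GEO accession, motif release and
scan threshold — and are out of reach of the synthetic conditions; the
package instead verifies every mechanism against oracles and planted
ground truth.
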