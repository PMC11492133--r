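# tfcrpipe

Transcription factors do not bind accessible chromatin uniformly: their
binding sites aggregate into **TFBS clustered regions (TFCRs)** that act
like cis-regulatory elements. `tfcrpipe` is an R package for calling TFCRs
from motif scans of chromatin-accessibility data and for quantifying what
each region can do — built for regulatory-genomics analyses of
developmental ATAC-seq panels (e.g. early embryonic stages), where the
questions are *where* the clustered regions are, *how complex* they are,
*which genes* they serve, and *how all of that shifts between stages*.

## The model in brief

TFBS midpoints $m_j$ define a per-chromosome, unnormalised Gaussian kernel
intensity

$$f(x) = \sum_j \exp\!\big(-(x-m_j)^2 / 2\sigma^2\big), \qquad \sigma = 300\ \mathrm{bp},$$

whose local maxima are the TFCRs. A site contributes to a TFCR when its
kernel weight at the peak is ≥ 0.1 (cutoff radius
$\sigma\sqrt{2\ln 10} \approx 644$ bp). Each TFCR is scored by:

* **TC** — complexity: the kernel-weight sum over contributing sites,
  counting same-family sites at the same locus once (family–locus
  deduplication);
* **TW** — width: the span of the contributing sites; **cw = TC/TW**, the
  unit-base complexity;
* **CAS** — mean score of overlapping ATAC peaks.

TFCRs are linked to genes by nearest TSS (ties all retained) and classified
by absolute distance into **R1** (≤ 2 kb, proximal "p-TFCRs"), **R2**
(2–27 kb), **R3** (27–50 kb) and **R4** (> 50 kb, long-range "LR-TFCRs").
Across an ordered stage panel the package tracks gained/lost/kept TFCRs and
stably occupied regions by interval overlap, clusters per-gene complexity
trajectories with fuzzy c-means, and annotates links with TAD
co-localisation and phase-separation-associated TF (PSTF) content. A
synthetic-data generator with full ground truth (planted cluster centers,
complexities, distance categories, expression law
$\log_{10}\mathrm{FPKM} = a\log_{10}(TC+c)+b+\varepsilon$) makes the whole
pipeline testable without any external download.

## Worked example

```r
library(tfcrpipe)

cfg <- synthetic_config(seed = 1)            # 500 genes, 5 chromosomes
b   <- generate_bundle(cfg, "demo_bundle")   # FIMO TSV, BEDs, expression, truth

res <- run_single_stage(
  b$paths["tfbs"], b$paths["genes"],
  expr_path = b$paths["expr"], atac_path = b$paths["atac"],
  family_map_path = b$paths["family_map"], stage = "demo")

head(res$tfcrs[, c("tfcr_id", "peak_pos", "TC", "TW", "cw", "tc_bin")], 4)
#>             tfcr_id peak_pos       TC  TW         cw tc_bin
#> 1 demo_chr1_1072290  1072290 7.223492 400 0.01805873    TC4
#> 2 demo_chr1_1826730  1826730 7.313727 492 0.01486530    TC4
#> 3 demo_chr1_2612249  2612249 4.958898 552 0.00898351    TC2
#> 4 demo_chr1_3400779  3400779 9.624631 536 0.01795640    TC7
```

`TC ≈ 7.2` means roughly seven distinct-family binding events can engage
near that peak (each weighted by proximity); `tc_bin` is the within-sample
complexity decile. Region proportions and the re-derived distance cuts:

```r
round(res$region_proportions, 3)
#>    R1    R2    R3    R4
#> 0.462 0.192 0.174 0.172

derive_thresholds(res$links_t2g)[c("t1", "t2", "t3", "provenance")]
#> $t1: 3845      $t2: 26982     $t3: 56356    $provenance: "derived"
```

The derived valley (~3.8 kb) and second mode (~27 kb) recover the planted
bimodal TSS-distance structure; classification itself uses the canonical
2/27/50 kb cuts unless you opt into the derived ones. Complexity predicts
expression under the saturating log law:

```r
res$stats$spearman_tc[c("rho", "stars")]   # rho = 0.872, "****"
res$stats$log_fit[c("a", "b", "c", "r_squared")]
#> a = 1.87, b = 1.01, c = 0.03, R2 = 0.80   (planted: a = 2, b = 1)
```

For a multi-stage panel, `generate_stage_panel()` + `run_panel()` add
gained/lost/stable TFCRs, long-range distance bins, trajectory clustering
and TAD/PSTF comparisons, and write per-stage tables plus one aggregated
JSON report.

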