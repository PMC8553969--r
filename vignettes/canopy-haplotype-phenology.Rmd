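---
title: "Haplotype-based phenology QTL mapping from remote-sensing canopy traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based phenology QTL mapping from remote-sensing canopy traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Time-course monitoring of a crop canopy from low-altitude RGB imagery turns
a single destructive end-of-season measurement into a phenology trait: when
a genetic factor acts, not only how much. **hapCanopy** implements the full
chain for a rice MAGIC (multi-parental advanced generation inter-cross)
population of 8 founders and ~165 inbred lines:

1. **imaging** — per-plot canopy height (CH, from differencing a digital
   surface model against its pre-transplant baseline), vegetation fraction
   (VF, Otsu segmentation of the CIELAB a\* channel) and leaf colour
   (mean −a\* over plant pixels);
2. **gwas** — a per-SNP Kruskal–Wallis scan over founder-haplotype classes,
   a two-season SNP selection rule, and 2-Mb merging into QTL calls with
   per-timepoint detection flags;
3. **effects** — haplotype-effect profiles at each QTL, quadratic
   time-course fits, correlation-based hierarchical clustering of QTLs,
   allele-class tests and top-vs-bottom haplotype contrasts on
   yield-allocation traits;
4. **simdata** — a founder-mosaic genome simulator, trait generator with
   stage-specific planted QTL effects, and a plot-scene renderer, so every
   stage above is testable without field data.

## The statistical model

### The scan

At every SNP the lines are grouped by founder-of-origin label (8 classes).
Association of a trait slice (one trait, year, timepoint) with the SNP is
tested with the tie-corrected Kruskal–Wallis statistic

$$H = \frac{\frac{12}{N(N+1)}\sum_i n_i\left(\bar r_i - \frac{N+1}{2}\right)^2}
          {1 - \sum_t (t^3 - t)/(N^3 - N)},$$

with $\bar r_i$ the mean rank of class $i$ and $t$ the tie-group sizes;
$p$ comes from the upper tail of $\chi^2_{k-1}$. Classes with fewer than 4
lines are excluded *before* ranking (see "Design choices"); lines with a
missing label are dropped per SNP, not listwise. No multiple-testing
correction is applied — replication across seasons is the error control:

- a SNP is **selected** for a timepoint pair iff $p_{y1} < 10^{-2}$ and
  $p_{y2} < 10^{-2}$ and $p_{y1} p_{y2} < 10^{-5}$;
- per chromosome, the union of SNPs selected at any timepoint is sorted by
  position and split wherever consecutive selected SNPs are more than 2 Mb
  apart; each run is one QTL, represented by the member with the smallest
  two-year $p$-product (ties broken by lower position).

Under independent uniform null $p$-values the selection region has exact
probability $t\,(1 + \ln(c^2/t)) = 10^{-5}(1+\ln 10) \approx 3.30\times
10^{-5}$ per SNP (with $c = 10^{-2}$, $t = 10^{-5}$); the acceptance suite
checks a $10^6$-draw Monte-Carlo estimate against this closed form.

### Phenology characterisation

The **haplotype effect** at a QTL is the mean trait value of the lines
carrying a founder label at the representative SNP; it is reported together
with its ratio to the population mean, where the denominator is the mean
over *all* lines (including lines in classes too small to report). Each
class's time course of means is summarised by an ordinary-least-squares
quadratic in DAT (days after transplanting); the leading coefficient
measures sharpness, so haplotypes with a stable, stage-independent effect
fit visibly flatter parabolas. QTLs are clustered by average-linkage
agglomeration on $1 - r$ over their effect vectors, founder haplotypes can
be collapsed into functional allele classes (omnibus Kruskal–Wallis plus
unadjusted pairwise Wilcoxon tests with a compact letter display), and
canopy-raising vs canopy-lowering haplotype groups are contrasted on PW,
SLW and PW/SLW (panicle vs stem-and-leaf weight) with Welch *t*-tests at
tiers 0.01 / 0.05 / 0.1.

## The synthetic world

The generator's defaults restate the study design and are not revisited:

| parameter | default | why |
|---|---|---|
| lines × founders | 165 × 8 | population size of the field experiment |
| SNP panel | 1,000 SNPs / 5 chromosomes of 30 Mb | desk-scale stand-in for a 13,603-SNP genotyping-by-sequencing panel |
| recombination | 3×10⁻⁷ breakpoints/bp | ~4 cM/Mb (rice average) × ~7 effective meioses of funnel crossing and selfing → ~3.3 Mb mean founder blocks |
| DAT grids | 2019: 40,56,69,83,97,111; 2018: 39,54,68,83,97,113 | the two seasons' observation days, paired columnwise, two pairs per stage (tillering, heading, maturation) |
| CH baseline | rise to 110 cm at 83 DAT, then −0.25 cm/day | canopy peaks at 83 DAT and droops moderately during maturation |
| CH noise | σ = 5 cm, Gaussian, independent per line and timepoint | the field design had no replicates, so line-level noise is a free parameter; 5 cm is the scale used throughout the acceptance criteria |
| planting geometry | 3 rows × 11 plants at 30 cm × 18 cm, 2 mm/px | the field plot layout and orthomosaic resolution |

The mosaic genomes are generated directly as a Markov founder-label process
(breakpoints Poisson along physical distance, labels resampled from the
founder frequencies), not as an explicit 8-way funnel pedigree: downstream
stages only consume the label matrix, and the Markov process reproduces the
block structure with the founder frequencies as its stationary
distribution. Endpoint traits are driven by each line's genetic CH value at
the peak timepoint — culm length is an affine function of it (reproducing
the strong CH–CL correlation) — and planted pleiotropy vectors put
opposite-sign effects on PW and SLW at trade-off QTLs, so that CH
correlates negatively with PW/SLW at the haplotype level.

The scene renderer places each plot's canopy as clustered regions around a
3 × 11 grid of plant centres: the closest-VF-percent of pixels (by distance
to the nearest centre) become plant, take a green colour matched to the
requested −a\* through the inverse sRGB transform, and raise the DSM by the
requested CH; the remainder take soil colour and baseline elevation.

**What the renderer does not emulate:** perspective and stitching artifacts,
shadows, specular water surfaces between rows, radiometric drift between
flights, mixed border pixels, lodging. A green imaging test therefore
establishes correctness of the extraction arithmetic and segmentation
logic, not robustness to real orthomosaic artifacts.

## Numerical choices

- **Otsu** quantises the observed range into 256 bins and breaks ties
  toward the lower threshold; constant input is an error, and the
  segmentation falls back to an absolute a\* cutoff (default −10) with a
  warning when the histogram is degenerate *or* when the two Otsu classes'
  mean a\* differ by less than 8 units — the latter guard stops the
  threshold from splitting quantisation noise inside a uniform (all-soil or
  full-canopy) plot. The plant class is always the lower-a\* (greener)
  side; if the below-threshold class is less green, the classes are
  swapped.
- **CH summary**: the source method differences whole DSMs but never states
  the per-plot aggregation; the default is the 95th percentile of
  within-plot differences (robust to soil gaps between plants without
  needing the plant mask), configurable to mean/median over the mask. The
  95th percentile is *not* antisymmetric under swapping the two DSMs; the
  mean is.
- **Quadratic fits** use `lm` on $(t, t^2)$ and interpolate exactly at 3
  points; fewer than 3 points give `NA`.
- **Clustering** uses average linkage; correlations on class means
  (ratios give the same $r$ by scale invariance, so the choice is
  cosmetic). Any QTL pair with fewer than 3 shared non-missing entries is
  an error naming the pair.
- **Determinism**: every stochastic function takes an explicit seed;
  pipeline stage seeds are small fixed offsets from the master seed.

## Design choices where the method description was open

- *Small classes in the scan.* The source states the n < 4 exclusion only
  for effect estimation; this package also applies it inside the scan, so
  that 1–3-line classes cannot dominate the ranks. Configurable via
  `min_class_size`; the divergence risk is that borderline associations
  driven by very small classes are not reproduced.
- *"Fewer than four haplotypes"* is read as fewer than four **lines per
  class** (not fewer than four classes), which matches the way class means
  are reported.
- *Representative SNP across two years.* "Lowest p-value" is ambiguous with
  two seasons; the two-year $p$-product is used, ties broken by position.
- *Otsu per plot*, not per mosaic: thresholds adapt to each plot's
  soil/canopy mixture, matching the per-plot extraction of the source
  workflow.
- *Effects per year*, not pooled: profiles, fits and correlations are
  computed within season and compared across seasons.
- *Ratio denominator* is the mean over all lines, not only over reported
  classes.

## Known limitations

- **Replicated background leakage limits "exact" QTL recovery.** With all
  genetic variance concentrated in a few strong planted QTLs
  (effect/noise = 2), every unlinked SNP carries a small *fixed* signal:
  the chance overlap between planted-founder carriers and that SNP's eight
  classes. Because genotypes do not change between seasons, this leak
  replicates across years, and the two-year $p$-product rule — which
  guards against season-specific noise — cannot suppress it. Its expected
  noncentrality is approximately $(\delta/\sigma)^2\,p(1-p)\,(k-1)$ per
  active QTL (~3.5 here), independent of population size. In the 20-seed
  recovery experiment the pipeline localises every planted QTL to within
  1 Mb and reproduces stage flags in >80 % of cases, but spurious extra
  calls (leak SNPs in the noncentrality tail) appear in roughly 40 % of
  seeds, so the "no extras in ≥90 % of seeds" acceptance clause fails and
  is deliberately left failing. A kinship or structure correction would
  remove the leak but is explicitly out of scope for this method, which
  thresholds raw p-values.
- Raster I/O uses plain-text formats (ASCII PPM for RGB, ESRI ASCII grid
  for elevation) rather than GeoTIFF: the deliverable is text-only and the
  runtime has no TIFF codec. Both formats round-trip exactly.
- Plot rectangles are axis-aligned in pixel coordinates; rotating a source
  mosaic into grid alignment is upstream of this package.
- No haplotype inference: founder-of-origin labels are an input (or
  simulated); no VCF/PLINK import, no mixed-model scan, no candidate-gene
  annotation.
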