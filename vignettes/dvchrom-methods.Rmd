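---
title: "Methods: comparative chromatin-conformation analysis in dvchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative chromatin-conformation analysis in dvchrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dvchrom` analyses binned chromatin contact matrices (Hi-C, Micro-C) and
compares them across conditions. This vignette describes the models and
procedures the package implements, the parameters that matter, the design
choices made where conventions diverge, and what the synthetic-data
validation does and does not demonstrate about real data.

## Data model and conventions

Intervals are `GRanges` (1-based, closed) throughout; conversion to and
from 0-based half-open conventions (BED, bedGraph, COO bin ids) happens
only at format boundaries, as does the 1-based-inclusive GFF3 convention.
A contact matrix couples a bin table (fixed-width tiling, short last bin
per chromosome) with a dense symmetric count matrix, a per-bin validity
mask, and — after balancing — per-bin biases and normalized values. Dense
storage is deliberate: at the bin counts this package targets (10² to
low 10⁴ bins) dense linear algebra is faster and considerably simpler than
sparse bookkeeping, while the on-disk format stays sparse
(upper-triangular COO text with a BED sidecar).

## Balancing

Matrix balancing removes multiplicative per-bin biases (mappability, GC,
fragment density) under the assumption that every locus should have equal
total visibility. Two equivalent solvers are provided:

- `kr_balance()`, the Knight–Ruiz inner–outer Newton iteration with a
  conjugate-gradient inner solver — fast and robust at moderate size;
- `ice_balance()`, Imakaev-style iterative correction — marginal division
  until the marginals are flat.

Both scale the valid submatrix so that every row of `b_i b_j c_ij` sums
to 1 (tolerance `tol`, default 1e-10). Row sum 1 rather than a
mean-preserving convention makes saddle and aggregate values directly
comparable across samples; any other convention is a global rescaling.
Because the doubly stochastic scaling of a fully supported symmetric
matrix is unique, the two methods agree to numerical precision, which the
tests assert against an independent Sinkhorn oracle. A valid bin whose
row is entirely zero makes the problem structurally unbalanceable and is
reported as an error; such bins should be masked by
`filter_low_coverage()` (marginal below 10% of the median marginal, the
conventional cutoff) first.

## Expected contacts, O/E and P(s)

The expected profile is the per-chromosome mean normalized contact at
each bin separation, over valid pixels only; pixels touching masked bins
are excluded from numerator and denominator alike (never zero-filled).
Observed/expected (O/E) divides each pixel by the expected value at its
separation, so the per-distance mean of every O/E matrix is exactly 1 —
an arithmetic identity the acceptance tests check to 1e-12. Distance
decay `P(s)` pools cis pixels into log-spaced bins (edge ratio 1.15 by
default; the binning is not critical and is exposed) and by default
total-sum normalizes the curve so samples of different depth are
comparable; the derivative `d log P / d log s` is computed by central
differences and equals −α in mid-range for a pure power law, which the
tests verify. Virtual 4C extracts the mean normalized row of the anchor
bins.

## Insulation, boundaries, domains

The insulation score of bin *i* with window *w* is the mean normalized
signal over the square `[i−w, i−1] × [i+1, i+w]`, reported as log2 of the
ratio to the chromosome mean. Values are undefined within *w* bins of a
chromosome edge and where more than half of the flanking bins are masked
(this guard avoids spurious minima at mask edges). Boundaries are called
at insulation minima where the delta vector (mean of the next
`delta_bins` values minus mean of the previous `delta_bins`, default 3)
crosses zero from negative to positive. The boundary score is
`max(delta after) − min(delta before)` within `delta_bins` of the
minimum — a depth measure chosen because the upstream tool chain's exact
score is not published; it is a plain function argument and can be
substituted. Boundaries below 0.7 are discarded.

Consensus boundaries combine calls across a parameter grid (2 resolutions
× 4 window sizes = 8 combinations in the reference configuration):
single-linkage clustering at the coarser resolution, keep clusters
supported by at least 4 distinct combinations, emit the median position
snapped to the finest resolution. Domains pair consecutive consensus
boundaries per chromosome and drop sizes outside [10 kb, 500 kb].
"Pairing" is interpreted as consecutive pairs only; all-pairs domain
construction would create nested domains the downstream analyses do not
use.

## Compartments and saddle plots

The pericentromeric-heterochromatin mask derives from two H3K9me3
enrichment tracks (two developmental stages, 10-kb bins, log-ratio > 0 =
enriched; the threshold is exposed): select bins enriched in both, merge
runs separated by gaps under 25 kb, remove regions under 20 kb, merge
survivors within 100 kb, and keep the largest region per chromosome —
the last rule stands in for a manual "clearly pericentromeric" judgement
and is documented as swappable.

The compartment eigenvector is computed per whole chromosome (no arm
splitting) from the Pearson correlation matrix of the masked O/E columns;
the eigenvector with the largest-magnitude eigenvalue is oriented so it
correlates positively with GC content (A/active = positive). Masked and
degenerate bins carry 0. Saddle plots rank bins by a reference
eigenvector, cut the nonzero bins into `n_quantiles` equal-count groups
(most negative first), and average O/E within group pairs; zero-valued
bins are removed before quantile cutting and collapsed into one trailing
row/column. Compartmentalization strength is
`(BB corner + AA corner) / (AB + BA corners)` with a configurable corner
block size (default a single cell).

## Aggregate analyses

Domain aggregates extract each domain window (domain ± `flank_fraction` ×
length), rescale it to a fixed grid by area-weighted interpolation
(constant-preserving, missing-aware) and average across domains. Loop
aggregates (APA) average fixed windows centered on anchor-pair pixels;
pairs closer to the diagonal than the window are excluded with a warning.
Loop strength is the center pixel over the mean of the 3 × 3 corner block
on the farther-from-diagonal side of the window, the corner least
contaminated by distance decay. Enhancer–promoter tables take the O/E
value at the (enhancer, promoter) pixel — the mean over spanned pixels
when a feature covers several bins — after dropping pairs separated by
less than 10 kb; a separate 5-kb exclusion is available at the
assignment stage because both cutoffs exist independently in the
reference workflow. Cross-condition comparison uses the two-sided
Wilcoxon rank-sum test (exact for tie-free samples of ≤ 10, normal
approximation with tie correction otherwise).

One interaction worth knowing about: balancing flattens marginals, which
slightly deflates O/E inside strong domains and inflates it between
domain-free bins, so aggregate contrasts on balanced synthetic maps are
somewhat weaker than the planted boosts would suggest. This mirrors real
balanced Hi-C data and does not affect recovery of feature *locations*.

## Windowed structural similarity

Two maps are compared window by window along the diagonal (500-kb
windows, 5-kb steps by default). Each O/E block is smoothed with a small
boxcar mean (`smooth_bins = 3`) and log2-transformed with a 1e-4
pseudocount, and the two blocks are scored with the structural similarity
index computed globally over the window's shared finite pixels
(`ssim = ((2μaμb + c1)(2cov + c2)) / ((μa² + μb² + c1)(σa² + σb² + c2))`,
`c1 = (0.01 L)²`, `c2 = (0.03 L)²`, `L` the joint dynamic range). The
boxcar plays the role the sliding Gaussian sub-window plays in standard
image ssim; without it, windows at realistic sequencing depth are
dominated by the zero/nonzero pattern of Poisson counts and even
replicate pairs score near zero.

Each window also receives a signal-to-noise ratio. The default
(`snr_method = "shot_noise"`) divides the mean absolute log-O/E signal of
the two blocks by the Poisson noise scale of the smoothed log values,
`1/(ln 2 · √(n + 1))` with `n` the pooled raw count under the smoothing
kernel: windows over sparse data score low, while windows whose maps
genuinely differ do not. An alternative definition — signal over the
standard deviation of the pixelwise difference — is retained as
`snr_method = "difference"`, but note that its denominator grows exactly
where a real structural difference exists, which suppresses the windows a
differential caller needs to keep; this was the reason the shot-noise
definition is the default.

Z-scores are taken genome-wide over finite windows (mean 0, sd 1 by
construction; a zero-variance track yields z = 0). Comparisons are made
specific by subtracting a reference track computed from a replicate pair
(`delta_ssim = query − reference`; negative = query pair less similar
than replicates), and regions are called where the delta z-score is below
−2 with signal-to-noise z ≥ 1, merging adjacent significant windows. For
gene-level association only every 100th window is kept so windows do not
overlap, windows are classed by whether they contain a differentially
expressed gene, and the classes are compared by rank-sum test.

## Enhancer-to-gene linking

Differential 150-bp windows (per pairwise genotype contrast, log-fold
change and FDR as produced by a windowed differential ChIP analysis) are
merged when gaps are ≤ 100 bp; runs longer than 5 kb are split
left-to-right into near-equal-count chunks, using the smallest chunk
count that satisfies the width cap (deterministic and order-free). The
region FDR is the Simes combination of member FDRs — the default
combination rule of the csaw framework this stage consumes — and regions
are kept when that FDR is < 0.05 and all member fold-changes share one
sign. Tissue-specific sets are the span intersections of the two
"this genotype up" contrasts, minus any region overlapping a promoter
window (± 500 bp around the TSS by default; the promoter extent is not
fixed by convention and is a parameter).

Candidate target genes exclude housekeeping-flagged genes and genes with
mean TPM < 1 across genotypes. Assignment applies four rules in order,
the first applicable winning: (1) enhancer overlaps transcripts of
exactly one candidate gene; (2) closest candidate promoter not separated
from the enhancer by a domain boundary, where a boundary separates when
its bin lies strictly inside the open interval between enhancer and
promoter; (3) closest promoter within the enhancer's domain; (4) closest
promoter unconstrained. Distances are enhancer-edge to TSS point, 0 for
overlap, ties broken toward the smaller start coordinate. "Closest" is
always restricted to candidate genes, since the expression filter
precedes assignment.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes.
The expected intensity of a cis pixel at separation `d` bp is

```
e(i,j) = (d + s0)^(-alpha)
         * (1 + tau)   [same planted domain]
         * (1 + lambda * exp(-(Δi² + Δj²)/(2σ²)))   [near a loop anchor]
         * exp(kappa * v_i * v_j)   [compartment profile v ∈ {−1, 0, +1}]
```

normalized to sum 1 over the upper triangle; counts are
`Poisson(depth · b_i b_j · e)` with log-normal biases `b`
(`sdlog = bias_sigma`, mean 1). Poisson noise (not negative-binomial) is
the deliberate default: at bin level Hi-C shot noise is well approximated
by Poisson, and the pipeline never relies on overdispersion. Balancer-like
rearrangements recompute the decay term with bin distances measured in
the rearranged genome (an inversion reverses bin order in its segment; a
reciprocal translocation exchanges chromosome tails), mix mutant and
reference intensities as `f·mutant + (1−f)·reference` to emulate a pooled
collection in which a fraction `f` of embryos carries the rearrangement,
and re-sample counts with the reference biases.

Defaults were chosen once as the realistic regime for this system:
`alpha = 0.8` (embryonic Hi-C decay in the sub-Mb range), `s0` = one bin,
`bias_sigma = 0.2`, depth 1e6–5e6 pairs per simulated region (pooled
replicates at kb-scale resolution), domains of 50–140 kb on a 10-kb grid
with `tau = 1`, 100-kb alternating compartment blocks, Gaussian loops of
width 1 bin. The differential-structure simulations tile the genome with
domains because a decay-only map has no structure for a similarity index
to compare — replicate ssim would be near zero everywhere, unlike any
real genome.

The matched regulatory annotation plants genes on a jittered ~25-kb grid
(30% flagged housekeeping with uniformly high expression), places
`n_enhancers` per genotype 2.5–10 kb from the TSS of a distinct,
expressed, non-housekeeping target gene in the same planted domain,
avoiding promoter windows, and verifying at placement time that the
target is the nearest candidate promoter — so the planted truth is
consistent with the assignment rules by construction. Null and decoy
windows (enriched versus only one genotype; enriched but overlapping a
promoter) exercise the negative branches of the selection rules; they
represent constitutive acetylated regions and are placed at least 1 kb
from planted enhancers, because a sign-inconsistent null window fused
into an enhancer run would make the planted truth unrecoverable by the
stated merging rules — a property of the annotation, not of the method.
Target genes receive a log-normal expression boost (median ~6-fold) in
the matching genotype.

## What the validation shows — and what it does not

The test suite and `scripts/acceptance.R` demonstrate, on synthetic data:
exact balancing conservation and KR/ICE agreement; exact O/E and
insulation identities against brute-force oracles; recovery of planted
boundaries (recall and precision ≥ 0.9 at ±1 coarse bin on a 1,000-bin
map at depth 1e6), compartment profiles (|r| ≥ 0.9 at κ = 0.4, saddle
strength monotone in κ), loops (APA ≥ 1.5 at λ = 1 versus ≈ 1 for
distance-matched random pairs), and 300-kb inversions at carrier fraction
0.5 (≥ 9/10 detected, ≤ 5% of called windows more than 1 Mb from a
breakpoint); ≥ 90% exact recovery of planted enhancer–gene links through
the full pipeline with significantly higher matching-genotype expression;
and uniform p-values under null simulations of both comparison
statistics.

The generator does not emulate several features of real data: restriction
fragment geometry and ligation artifacts, distance-dependent
overdispersion, copy-number variation, nested or hierarchical domains,
compartment transitions finer than the planted blocks, or trans
contacts beyond a flat level used for translocation tests. Passing these
tests therefore validates the implementation of each procedure and the
end-to-end plumbing, not the biological effect sizes one would estimate
from real embryo data. Problem sizes in the tests (0.2–5 Mb regions,
10³ bins, depths 1e5–5e6) were chosen as the smallest scales at which
each statistical property is comfortably identifiable.

## Known limitations

- KR balancing is dense; matrices beyond ~2×10⁴ bins should be balanced
  per chromosome or with iterative correction (the reason the Micro-C
  convention here defaults to `ice_balance()`).
- The boundary score is a stand-in for an unpublished definition;
  absolute score values are not comparable across tools, only the ≥ 0.7
  filtering behaviour is.
- The ssim is computed globally per window rather than with a sliding
  Gaussian; the boxcar pre-smoothing recovers most of the local weighting
  but window scores are not numerically interchangeable with other
  implementations.
- Trans expected values are chromosome-pair means; no distance model
  exists in trans, so trans O/E is only meaningful for coarse block-level
  questions such as translocation detection.
- The seed is a function argument (R convention) rather than a field of
  the simulation spec; reproducibility contracts are per call.
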