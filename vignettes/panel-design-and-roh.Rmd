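---
title: "Designing and validating reduced SNP panels: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating reduced SNP panels: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snppanel)
```

# The problem

Reduced SNP panels ("liquid chips", genotyping-by-target-sequencing kits)
genotype a few tens of thousands of markers chosen from millions of
whole-genome variants. A good panel must balance three demands: markers that
discriminate the breeds of interest, markers tied to traits of economic
interest, and an even physical coverage of the genome so that downstream
analyses — relationship estimation, runs of homozygosity (ROH), selection
scans — are not starved in any region. `snppanel` implements a complete
desk-scale workflow for this: candidate discovery from multi-breed genotype
data, hierarchical window-based panel construction, and the standard
validation battery (PCA, distance trees, LD decay, ROH and ROH islands).

# Candidate discovery: breed-differentiation statistics

For every site and every pair of breeds the package computes three
statistics from missing-excluded allele frequencies $p_1, p_2$:

* **Wright's Fst**, in the two-population heterozygosity form
  $F_{ST} = (H_T - H_S)/H_T$ with $H_T = 2\bar p(1-\bar p)$,
  $\bar p = (p_1+p_2)/2$ and $H_S = \tfrac12\{2p_1(1-p_1)+2p_2(1-p_2)\}$.
  No sample-size correction is applied; this is the plain frequency form,
  and both populations fixed for the same allele return 0 by convention.
* **delta**, the absolute frequency difference $|p_1 - p_2|$.
* **informativeness for assignment** ($I_n$, Rosenberg's entropy measure),
  over both alleles $j$:
  $I_n = \sum_j \big( -\bar p_j \ln \bar p_j + \tfrac1K \sum_i p_{ij}\ln p_{ij} \big)$,
  with $0\ln 0 = 0$ and natural logarithms, so the two-population maximum is
  $\ln 2$ at a fixed difference.

Which breed contrasts to score is genuinely open: the package scores **every
breed pair with every statistic** and pools the per-stratum top-$N$ lists by
union (`rank_top_sites()`). The union is deliberate — a marker highly
informative for even one contrast is worth carrying, and intersection-style
pooling would discard exactly the breed-specific markers the panel exists
for.

The pool size $N$ is chosen by a quantitative surrogate for "inspect the PCA
grouping": `select_candidate_pool()` evaluates each candidate size by the
mean silhouette width of breed labels in PC1–PC2 space and takes the
smallest $N$ within 0.02 of the best ("plateau rule"). The 0.02 margin is
roughly the replicate-to-replicate noise of silhouettes at these sample
sizes, so the rule prefers smaller pools unless a larger one is genuinely
better.

# Panel construction: priorities, windows and the SD² rule

Candidates carry a priority tier: breed-specific and trait-related sites are
tier 1, common sites from commercial chips tier 2, and generic polymorphic
WGS sites (MAF > 0.2, enforced) tier 3. A physical site in several
categories is kept once under its best tier.

Chromosomes are tiled into 50-kb windows (0-based half-open, last window
short). Per window:

* one candidate → kept;
* two or more → the pair $(N_i, N_j)$ minimising
  $SD^2 = \frac{(S-\bar X)^2 + (N_i-\bar X)^2 + (N_j-\bar X)^2 + (E-\bar X)^2}{4}$,
  where $S,E$ are the window bounds and
  $\bar X = (S + N_i + N_j + E)/4$ — i.e. the population variance of the
  four positions. $\bar X$ as the mean of the four positions is the only
  reading under which the expression is a variance; nothing else makes the
  formula well-defined.
* none → one site from the supplement pool of QC-passing, non-candidate
  sites in the window, ranked by priority tier, then MAF (higher first),
  then position. One site per empty window keeps the filled windows at the
  panel's typical density (below one site per window genome-wide).

Tie-breaks are deterministic everywhere: equal-SD² pairs prefer the higher
total priority, then the leftmost pair; ranking ties prefer the earlier
chromosome, then the smaller position. `build_panel()` is therefore a pure
function of its inputs, and the audit table records the rule applied in
every window.

One property of the SD² criterion deserves honesty: minimising the variance
of $\{S, N_i, N_j, E\}$ pulls the two retained SNPs toward the *window
centre* rather than spreading them at thirds. The criterion is implemented
exactly as defined; users wanting maximal spread should be aware the
even-distribution interpretation holds only loosely. A `cap_exempt_priority1`
flag optionally exempts tier-1 sites from the two-per-window cap (all tier-1
sites kept; the cap then applies to tiers 2–3 in windows without a tier-1
site). It is off by default, matching the literal two-per-window rule.

# ROH detection

Detection follows the PLINK sliding-window scheme with these defaults:
minimum run length 1 Mb; maximum inter-SNP gap 1 Mb; density at least 1 SNP
per 100 kb; 50-SNP windows tolerating 1 heterozygous and 5 missing calls;
per-SNP window hit threshold 0.01; and a minimum SNP count
$$L = \left\lceil \frac{\ln\!\big(\alpha/(n_s n_i)\big)}{\ln(1 - het)} \right\rceil$$
with $\alpha = 0.05$, $n_s$ SNPs per animal, $n_i$ animals and $het$ the
mean heterozygosity — the number of homozygous SNPs unlikely to occur in a
row by chance. The ceiling keeps the guarantee conservative; a $10^{-9}$
slack is subtracted first so exact integer ratios are not inflated by
floating-point representation (e.g. $n_s=n_i=1$, $het=0.95$ gives exactly 1).

Numerical and procedural choices:

* The window hit threshold defaults to **0.01** (the analysis this package
  operationalises uses that value; PLINK's own default is 0.05). It is a
  parameter, not a constant.
* The per-window missing allowance (5) is PLINK's default.
* Chromosomes with fewer than 50 SNPs are scored against the single
  truncated window instead of being dropped, so short scaffolds still
  contribute.
* Segment ends are trimmed to homozygous calls (`trim_ends = TRUE`): a run
  of homozygosity begins and ends on a homozygous genotype, as in PLINK's
  implementation. Interior heterozygous calls tolerated by the window rule
  remain inside the segment.
* Sex chromosomes and the mitochondrion are excluded by default; ROH
  statistics are autosomal quantities.

**Boundary resolution is intrinsically limited.** A window lying mostly
inside a long homozygous tract also covers a few SNPs beyond its edge;
because one heterozygous call per window is tolerated and a single passing
window flags a SNP (threshold 0.01 with ≤ 50 covering windows), the flagged
run extends past the true tract edge until two heterozygous calls fall
within one window span. With background heterozygosity $h$ the probability
that a tract edge is localised within one SNP is about $h^2(2-h)$ per side
(≈ 0.14 for both sides jointly at $h = 0.5$), and the median overshoot in
our simulations is 3–5 SNPs per side. Planted-tract experiments in the test
suite therefore validate *coverage* (every tract recovered in full, no
false segments in tract-free samples) and report boundary precision
separately; sub-SNP boundary accuracy is not achievable with this class of
detector and is not claimed.

# ROH incidence and islands

Per-SNP incidence is the fraction of individuals with at least one segment
covering the position (inclusive ends). The island threshold is the
empirical $1 - 0.01$ quantile (R's default type-7 interpolation) of the
incidence values; islands are maximal runs of consecutive panel SNPs
*strictly above* the threshold with at least 2 SNPs. Strictness matters: a
flat incidence profile produces no islands rather than declaring the whole
genome an island. Runs are defined over consecutive panel SNPs irrespective
of bp gaps — island width is a property of the panel's resolution — with an
optional `gap_split_bp` to split runs across large voids. Island bounds are
the first/last constituent SNP positions, and `annotate_intervals()`
reports overlapping genes/QTL from any GFF3/BED annotation by 1-based
inclusive intersection.

# Validation analyses

* **PCA**: sites centred by $2p$ and scaled by $\sqrt{2p(1-p)}$, missing
  calls mean-imputed, monomorphic sites dropped, eigendecomposition of the
  sample covariance. Signs are fixed by forcing each component's
  largest-magnitude coordinate positive, making results reproducible and
  sample-order invariant.
* **p-distance**: mean over jointly-called sites of $|g_i - g_j|/2$; pairs
  with no jointly-called site are an error unless explicitly allowed.
* **Neighbor joining**: classic Saitou–Nei agglomeration, implemented in
  the package. Negative branch estimates are clamped to zero with the
  deficit moved to the sister branch, preserving pairwise path lengths; on
  additive matrices the generating tree is recovered exactly (the test
  suite checks path-length reconstruction to $10^{-9}$ against an
  independent tree library).
* **LD decay**: genotype-correlation $r^2$ (squared Pearson correlation of
  dosage vectors, pairwise-complete) for same-chromosome pairs within a
  distance cap, averaged in distance bins; the reported decay distance is
  the linear interpolation of the first bin crossing below $r^2 = 0.2$.
  Genotype-based $r^2$ requires no phasing, which is why it is used here
  instead of haplotype $D'$-family measures.

# The synthetic-data generator

`sim_config()`/`simulate_frequencies()`/`simulate_genotypes()` implement
the Balding–Nichols model: ancestral frequencies $p \sim U(0.05, 0.95)$,
per-breed frequencies $\text{Beta}\big(p(1-F)/F,\ (1-p)(1-F)/F\big)$ so
that $\mathrm{Var}(p_i) = F\,p(1-p)$, genotypes $\text{Binomial}(2, p_i)$,
Bernoulli missingness. Defaults emulate a small multi-breed cattle study at
desk scale: 4 breeds × 25 animals, 2,000 sites on two chromosomes,
$F = 0.1$ (typical differentiation between related cattle breeds),
missingness 0.5% (panel-grade call rates above 99%). `plant_roh()` writes
ground-truth homozygous tracts for detector validation; `label_candidates()`
fabricates candidate categories.

One calibration fact matters when interpreting tests: for **two**
populations each at parameter $F$, the expected value of the
heterozygosity-based Fst above is **$F/(2-F)$, not $F$** — the total
heterozygosity is computed from the mean of only two population
frequencies, which itself varies with $F$. The simulator calibration checks
therefore compare the multi-locus estimator
$\sum(H_T - H_S)/\sum H_T$ against $F/(2-F)$ (0.026, 0.053, 0.111 at
$F = 0.05, 0.1, 0.2$), and the observed agreement is within a few $10^{-3}$
at 10,000 sites.

What the generator does *not* emulate: linkage disequilibrium (sites are
independent unless the copy-with-error `dup_fraction` mode is used, which
creates high-$r^2$ pairs only), demographic history (bottlenecks,
admixture, migration), allele-frequency spectra of real ascertained
panels, and genotyping-error structure. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under the model — not
performance on any particular livestock dataset.

# Problem sizes used by the test suite

The suite and the acceptance script run at sizes chosen to exercise every
code path while staying desk-scale: the full chip-composition bookkeeping
(42,686 candidates over 21,343 windows on 29 chromosomes), 1,000 random
windows for the SD² oracle comparison, 100 seeded replicates of 600-SNP/
12-Mb chromosomes for planted-tract recovery, 10,000 sites per setting for
Fst calibration, and 60-sample/2,000-site matrices for PCA separation.

# Known limitations

* ROH boundary overshoot, as analysed above.
* The SD² criterion centres pairs rather than spreading them.
* Genotype-correlation $r^2$ differs numerically from haplotype-based LD.
* The exact numeric output of external tools (PLINK PCA scaling, VCF2Dis
  rounding, PopLDdecay binning) is not reproduced; the methods are
  equivalent at the algorithm level, not bit level.
* Model-based ancestry estimation (ADMIXTURE-style) and HMM ROH callers
  are out of scope; the validation surface is PCA, distance trees and LD.
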