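---
title: "Linking regional homogeneity to spatial gene expression: methods"
author: "imgtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking regional homogeneity to spatial gene expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imgtx)
```

## The analysis in one paragraph

Regional homogeneity (ReHo) measures how synchronously a voxel's
resting-state BOLD signal fluctuates with its immediate neighbourhood; it
is a data-driven, highly reliable index of local spontaneous brain
activity.  Because spatially dense gene expression (the Allen Human Brain
Atlas) and group-level ReHo maps can be projected into the same anatomical
parcellation, one can ask which *coexpression modules* — clusters of genes
with similar spatial expression profiles — covary spatially with ReHo,
which cortical *cell types* those modules are specific to, and whether the
module genes carry *GWAS signal* for brain disorders.  `imgtx` implements
that entire chain as reusable, tested components, together with a
synthetic-data layer that plants known ground truth at every stage so the
chain can be validated end to end without any external download.

## Voxel-wise ReHo and regional zReHo

For each in-mask voxel, ReHo is Kendall's coefficient of concordance of
the voxel's time course with the in-mask members of its 3×3×3
neighbourhood (26-connectivity, so up to K = 27 series of length n):

$$W = \frac{12\sum_i (R_i - \bar R)^2}{K^2(n^3 - n) - K\sum_j T_j},$$

where $R_i$ is the rank sum at timepoint $i$ and $T_j$ the standard tie
correction of series $j$ (midranks throughout).  W lives in [0, 1] and is
invariant to any strictly monotone transform of each series, which is why
the synthetic generator can use Gaussian white noise without loss of
generality.  Design choices worth knowing:

* **Partial neighbourhoods.** At mask edges the KCC is computed over the
  available in-mask series (K < 27) rather than padding, so out-of-mask
  signal never contaminates the statistic; per-voxel K is stored for
  audit.  Isolated voxels (K = 1) and voxels whose neighbourhood series
  are all constant get an `NA` sentinel.
* **Standardisation.** zReHo subtracts the in-mask mean and divides by the
  in-mask *population* (1/N) standard deviation; the choice of SD
  convention is not dictated by the method and is recorded in the object.
* **Smoothing.** The zReHo map is smoothed with a separable Gaussian
  kernel, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis converted to
  voxels (8 mm FWHM on 3 mm voxels gives $\sigma \approx 1.132$ voxels);
  inside a mask the convolution is renormalised by the smoothed mask
  indicator so edge voxels are not diluted toward zero.  Smoothing is
  applied to the zReHo map (after standardisation), and the group map is
  the voxel-wise mean across subjects — regional means of that map are
  what feed the association stage.
* **Aggregation.** Regional zReHo is the arithmetic mean over each atlas
  label's in-mask voxels; labels with no usable voxels are dropped and
  reported.

## Expression preprocessing

The probe-level pipeline mirrors the standard atlas-expression workflow:

1. **Intensity filter** — keep probes above the array background in at
   least 50% of samples (the background calls are platform input; the
   synthetic generator plants them).
2. **Probe selection** — for multi-probe genes, keep the probe best
   correlated (Pearson) with the gene's RNA-seq reference profile across
   shared samples; ties break to the lowest probe id.  Genes absent from
   the reference fall back to the probe with the highest mean expression,
   the common fallback when a reference is incomplete.
3. **Sample assignment** — each tissue sample maps to the region of the
   nearest labelled voxel (Euclidean mm distance to voxel centres), with a
   2 mm default ceiling; samples whose annotated hemisphere contradicts
   the assigned voxel's hemisphere (sign of world x) are excluded.
   Distance is point-to-voxel-centre; a point-to-boundary variant is
   deliberately not offered.
4. **Aggregation and normalisation** — per-donor regional means are passed
   through a scaled robust sigmoid per gene within donor,
   $s = (1 + \exp(-(x - \mathrm{med})/( \mathrm{IQR}/1.35)))^{-1}$,
   min–max rescaled to [0, 1], then averaged across donors per region.
   The 1.35 divisor makes the IQR an SD-equivalent under normality.  The
   sigmoid is strictly monotone, so within-donor rank structure — all that
   downstream rank statistics use — is untouched.  Zero-IQR genes fall
   back to an SD-based sigmoid; fully constant genes map to 0.5.  The
   cross-donor combination (mean) is a documented choice; the per-donor
   normalisation itself is the standard step.

World coordinates use an identity-scaled affine with the origin at the
volume centre, so x < 0 is the left hemisphere, MNI-like; voxels are 3 mm
by default.

## Coexpression modules

An unsigned weighted network is built as $a_{ij} = |r_{ij}|^\beta$
(Pearson by default; the correlation flavour is configurable).  The soft
power $\beta$ is the smallest candidate whose signed scale-free fit
($R^2$ of $\log p(k)$ on $\log k$, negative-slope convention) reaches 0.9,
falling back to the best-fitting power when none saturates — on synthetic
data with a few planted modules the degree distribution is not scale-free
and the fallback is the norm.  Topological overlap

$$\mathrm{TOM}_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i,k_j) + 1 - a_{ij}},
\qquad l_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj},$$

is clustered by average linkage on $1-\mathrm{TOM}$.  The tree is cut with
a deliberately simplified dynamic procedure: a static cut at 99% of the
dendrogram height range, recursive sub-branch splitting whose required
height gap shrinks as `deepSplit` grows (0..4), a minimum module size of
50, a cohesion gate, and iterative merging of modules whose eigengene
dissimilarity $1 - \mathrm{cor}$ falls below 0.1.  Two of these pieces
deserve justification:

* **Cohesion gate.** A candidate cluster is kept only if its mean
  within-cluster |correlation| exceeds three times the null mean
  $\sqrt{2/\pi(n-1)}$ for $n$ regions.  Without it, average linkage on
  pure noise still produces one large branch below the static cut; with
  it, independent genes land entirely in the background ("grey") label
  while modules with within-correlation ≥ 0.6 pass with a wide margin.
  The factor 3 was fixed once from that separation argument.
* **Fidelity caveat.** The cut is *not* a re-implementation of the
  reference hybrid tree-cut heuristics; the package's validation target is
  planted-truth recovery (adjusted Rand index against planted membership),
  not label identity with any particular implementation.

Module eigengenes are the first principal component of the
column-standardised member genes across regions, sign-oriented to
correlate positively with the module's mean profile, with the explained
variance fraction reported.

## Spatial association and replication

Each eigengene is correlated with regional zReHo by Spearman's rho
(midrank ties), two-sided p from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$; an exact permutation mode
(`spearmanExactP`, n ≤ 12) exists as an oracle for the approximation.
P-values are Bonferroni-corrected over the number of modules, and a module
counts as *replicated* only if its corrected p is below alpha in the
discovery and in **every** replication dataset.  Sign agreement across
datasets is reported but not required — the replication criterion is
significance alone.  Under a global null this triple-significance rule has
a per-module replication probability of roughly $(0.05/30)^3$, which the
test suite verifies empirically.

## Cell-type specificity

Cell-type profiles are mean RPKM
($\mathrm{count}/(\mathrm{lib}/10^6)/(\mathrm{len}/10^3)$) over purified
replicates.  For a target type, genes are ranked by descending fold change
against each other type (pseudo-RPKM $\epsilon = 10^{-3}$ stabilises zero
expression), and the specificity index SI is the average rank; permutation
p-values (pSI) come from shuffling expression values across genes
independently within each type, counting per gene how often the null SI is
at least as extreme, with an add-one estimator over the default 10,000
permutations.  The within-type shuffling scheme preserves each type's
marginal distribution; it is the package's main fidelity caveat relative
to the reference pSI implementation, and correspondingly the validation is
calibration (uniform pSI under an exchangeable null) plus planted-marker
recovery, not numeric identity.  Genes with pSI strictly below 0.05 form
each type's enriched list, and module-versus-list overlap is tested by the
one-sided hypergeometric (Fisher) tail with a Bonferroni threshold of
$0.05/(\text{types} \times \text{modules})$.

## GWAS gene-set enrichment

With only summary statistics available, the gene model is the
mean-$\chi^2$ form: SNP p-values become 1-df chi-squares, the gene
statistic is their mean, and its null is the weighted sum of independent
chi-squares with weights the eigenvalues of the gene's reference-panel LD
matrix divided by the SNP count.  The tail is evaluated by Imhof's
numerical inversion of the characteristic function by default — the
two-moment Satterthwaite approximation is available as a fast mode, but
its mid-range error (up to ~0.03 in p around p ≈ 0.2 under strong LD)
makes it unsuitable as the default for a statistic that feeds a
regression.  Gene Z is $\Phi^{-1}(1-p)$, with p clamped away from 1 so Z
stays finite (clamp count reported).

The competitive test regresses Z on a set-membership indicator plus
log gene length, log SNP count, log SNP density and mean minor-allele
count, by GLS with the gene-gene correlation (normalised cross-gene mean
squared LD; zero across chromosomes) as the error correlation, one-sided
for a positive indicator coefficient and Bonferroni-corrected over the
number of sets.  Log density is an exact linear combination of the other
two size covariates, so it is dropped with a warning whenever density is
literally SNP count over length — the covariate list follows the stated
confounders, and the rank-deficiency handling makes that safe.  A singular
correlation matrix receives a $10^{-6}$ ridge before factorisation.
Within a significant set, genes are called at the Bonferroni threshold
alpha / set size.  Ontology-style enrichment of module genes against GMT
collections uses the same one-sided Fisher tail with Benjamini–Hochberg
correction at q < 0.05.

## What the synthetic data emulate — and what they do not

Every generator is a pure function of its seed, and every pipeline input
has a generator: BOLD series with per-region latent synchrony
($\sqrt{w}\,L + \sqrt{1-w}\,\epsilon$, so planted weight orders regional
ReHo), Voronoi parcellations, probe-level expression with planted modules
whose latents hit a target population Spearman correlation with a
phenotype (via the bivariate-normal inversion $\rho = 2\sin(\pi r_s/6)$),
negative-binomial cell-type counts with fold-change markers, and GWAS
genotypes under exchangeable within-gene LD with a planted enriched set.
Null settings (weight 0, fold change 1, effect 0) are exact nulls, which
is what the calibration tests rely on.

These scenarios are calibration instruments, not replicas: there is no
hemodynamic autocorrelation, no spatial smoothness beyond the planted
regional structure, no realistic allele-frequency spectrum, and donor
effects are a single scale/offset.  Passing tests therefore demonstrate
statistical correctness and planted-signal recovery of the machinery, not
that real-data effect sizes will match.

## Problem sizes and numerical choices

The demo scenario (`demoPipeline`, one command) uses a 14³ grid with a
spherical mask (~900 voxels), 48 regions, 120 timepoints, three datasets,
240 genes in three planted 60-gene modules (target correlations 0.75,
−0.6, 0), two donors, five cell types with planted astrocyte/microglia
markers, and ~1,500 SNPs with a 300-individual panel; it completes in well
under a minute and recovers all planted truths.  Module-recovery
validation uses 200 regions × 200 genes; calibration suites use 1,000–2,000
replicates at the sizes the property demands.  Other numerical choices:
Kendall's W is clipped only for floating error (≤ 1e−12); eigenvalues of
LD matrices are floored at zero; probe-selection ties break to the lowest
probe id; all randomness flows from one master seed through named
substreams so stages are independently reproducible.

## Known limitations

Surface-based parcellations, one-sample t group maps, spatial-
autocorrelation-preserving (spin) nulls, signed networks, biweight
midcorrelation defaults, and conditional/joint gene-set models are out of
scope.  The differential-stability filter is exposed but off by default
(no principled cutoff without donor-replication data).  The dynamic tree
cut is a simplification (above), and the pSI permutation scheme is a
stated approximation to the reference tool's unpublished details.
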