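---
title: "Linking environmental and dispersal filters to phylogenetic turnover"
author: "PhyloTurnover authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking environmental and dispersal filters to phylogenetic turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhyloTurnover)
```

# The question

When tree communities differ from plot to plot, two classes of process are
usually invoked: environmental filtering (species sort along climate, soil
and geomorphological gradients according to their niches) and dispersal
limitation (community similarity decays with distance because seeds do not
travel far, over ecological or evolutionary time). Taxonomic beta diversity
alone cannot separate the two well; phylogenetic beta diversity adds the
information of *which lineages* turn over, and null models separate the
part of that signal that mere richness and composition differences would
produce anyway.

`PhyloTurnover` implements this inference chain end to end: beta-diversity
decomposition, community-phylogenetic standardized effect sizes, spatial
eigenfunction analysis, constrained ordination with forward selection, and
variance partitioning — plus a metacommunity simulator in which the
strengths of filtering and dispersal limitation are set by the user, so
that every stage can be validated against known ground truth.

# Indices and conventions

## Incidence only

All indices are computed on presence/absence. The Sørensen family used here
is defined on species counts and shared branch lengths, not abundances;
`communityTable()` and the readers collapse any counts to incidence at
entry.

## Taxonomic and phylogenetic beta diversity

For plots $i, j$ with $a$ shared species and $b, c$ species unique to each:

$$\beta_{sor} = \frac{b + c}{2a + b + c}, \qquad
  \beta_{sim} = \frac{\min(b,c)}{a + \min(b,c)}, \qquad
  \beta_{nes} = \beta_{sor} - \beta_{sim}.$$

$\beta_{sim}$ (Simpson-based turnover) is insensitive to richness
differences; the nestedness component is non-negative by construction. The
phylogenetic family substitutes branch lengths for counts via root-inclusive
Faith's PD: $a_{pd} = PD_i + PD_j - PD_{tot}$,
$b_{pd} = PD_{tot} - PD_j$, $c_{pd} = PD_{tot} - PD_i$, where $PD_{tot}$ is
the PD of the pooled pair. Root-inclusive PD (the path to the tree root is
always counted) guarantees $a_{pd} \ge 0$ for any two non-empty
communities and makes the pooled-pair identity exact. On a star phylogeny
with equal branch lengths the phylogenetic indices reduce exactly to the
taxonomic ones — a property the test suite asserts at $10^{-12}$.

A separate statistic, `multiSiteSorensen()`, evaluates the across-all-plots
form
$$\frac{\sum \min(b_{ij}, b_{ji}) + \sum \max(b_{ij}, b_{ji})}
       {2(\sum S_i - S_T) + \sum \min(b_{ij}, b_{ji}) + \sum \max(b_{ij}, b_{ji})}$$
with sums over all plot pairs, $S_i$ plot richness and $S_T$ pooled
richness. It is a summary of the whole network, not a pairwise matrix, and
is deliberately kept separate from the pairwise workhorses.

One algebraic fact worth knowing when interpreting output: if all plots
share the same richness then $b = c$ for every pair and
$\beta_{sor} \equiv \beta_{sim}$ — the fixed-richness simulator produces
identical total and turnover matrices by construction, not by error.

## Null models and standardized effect sizes

Two randomizations are implemented, each matched to the inference it
serves:

* **Richness-preserving draws**: each plot keeps its observed richness and
  its species are drawn uniformly without replacement from the regional
  pool (all species of the table for taxonomic metrics; all tips of the
  regional tree for phylogenetic ones). This is the null for turnover
  metrics. The printed description of the taxonomic null in the source
  analysis also mentions preserving pairwise shared-species counts, which
  cannot hold simultaneously with equiprobable colonization; richness alone
  is enforced.
* **Tip shuffling**: tip labels are permuted across the regional phylogeny,
  leaving topology and branch lengths (hence the cophenetic-distance
  multiset) untouched. This is the null for between-community MPD
  (beta NRI, tree-wide depth) and MNTD (beta NTI, toward the tips).

SES is $({\rm obs} - \mu_{null})/\sigma_{null}$. The sign is stored so that
positive means phylogenetic evenness (observed exceeds the null mean) and
negative means clustering; this equals $-1\times$ Webb's NRI/NTI
convention. Between-community MNTD is made symmetric by averaging the two
directional means (the choice is immaterial for MPD). Envelopes are
$\mu \pm 1.96\sigma$ per pair. Degenerate pairs (null sd $= 0$, e.g. two
plots with identical species sets, whose inter-MNTD is zero under every
shuffle) are flagged and reported as NA rather than forced to a sign.

Defaults: 999 iterations for inference, reduced counts in the test profile;
a seed argument on every stochastic entry point makes runs bit-reproducible.

# Spatial eigenfunctions

`pcnmBasis()` follows the canonical PCNM construction: Euclidean plot
distances; truncation threshold $t$ = the longest edge of the minimum
spanning tree (the smallest value keeping the neighbor graph connected);
distances beyond $t$ replaced by $4t$; Gower double-centering of
$-d^2/2$; eigenvectors with positive eigenvalues retained, unit-normed
(they enter RDA as standardized predictors), in decreasing eigenvalue
order. Setting $t = \infty$ reduces the construction to classical PCoA of
the raw distances, and the implementation is numerically identical to the
reference implementation in `vegan::pcnm` (asserted in tests up to sign).

On a transect the leading eigenvector is a sinusoid whose wavelength equals
the transect extent — one interior zero crossing — and successive
eigenvectors halve the wavelength. The often-repeated description of the
first axis as "half a sine wave" does not survive contact with the
numbers: a phase-free half-period sine fit tops out near $|r| \approx
0.85$, while the full-period sinusoid fits at $|r| > 0.99$. Tests assert
the latter.

**Scale classification.** Each eigenvector is assigned a characteristic
wavelength: plots are ordered along a depth-first traversal of the minimum
spanning tree starting from one end of its diameter, and the wavelength is
$2 L_{path} / (\text{number of sign changes})$ along that ordering
($\infty$, i.e. broadest, when the centered vector never changes sign).
Two cutoffs bin the axes into broad/mid/fine. The defaults are the
geometric midpoints between $\sqrt{50}$, $\sqrt{5}$ and $\sqrt{0.5}$ km —
the side lengths of the 50, 5 and 0.5 km² reference areas used to label
broad, mid and fine structure in western-Amazonian plot networks — i.e.
about 3.98 and 1.26 km. Both cutoffs are user-settable; any analysis at a
different extent should set them to match its own design (the acceptance
script uses 60 and 25 km for a ~220 km extent). Classification is invariant
to eigenvector sign flips. Which PCNM *indices* end up significant is a
property of each dataset's geometry; no fixed index set is meaningful
across datasets.

# Ordination and testing

* **PCA** (`pcaOrdination`): eigen-decomposition of the correlation matrix
  by default — the right choice for environmental variables on
  heterogeneous scales; zero-variance columns are an error there, by name.
* **NMDS** (`nmdsOrdination`): Kruskal stress-1 with monotone regression —
  the engine is `vegan::monoMDS` — restarted from `nStarts` random
  configurations; the best solution is centered and principal-axis rotated.
  The analysis default is 1000 starts; convergence within one start is the
  engine's own (stress change $<10^{-6}$, max 300 iterations).
* **RDA** (`rdaFit`): least-squares projection of the centered response
  onto the predictor column space, SVD of the fitted values;
  $R^2 = SS_{fit}/SS_{tot}$, adjusted by Ezekiel's formula
  $1-(1-R^2)(n-1)/(n-m-1)$ with $m$ the predictor rank. Rank-deficient
  predictor matrices are an error naming the dependent columns.
* **db-RDA** (`dbRDA`): PCoA of the dissimilarity, axes with positive
  eigenvalues as the response, then RDA; constrained-axis proportions are
  relative to the retained-axes variance. Negative PCoA eigenvalues are
  discarded with a logged count (Lingoes/Cailliez corrections available as
  a toggle); on a Euclidean dissimilarity the result equals direct RDA on
  the underlying centered data to $10^{-8}$, a key internal consistency
  check.
* **Permutation pseudo-F** (`permutationPseudoF`):
  $F = (SS_{exp}/m)/(SS_{res}/(n-m-m_c-1))$ with
  $p = (1+\#\{F^\pi \ge F\})/(1+n_\pi)$. Without a condition matrix,
  response rows are permuted; with one, the Freedman–Lane scheme permutes
  reduced-model residuals — the choice that keeps partial tests type-I
  calibrated (asserted by simulation). Per-axis tests in `rdaFit`/`dbRDA`
  compare each constrained eigenvalue against its permutation distribution
  with whole-response row permutation — a simple marginal scheme, reported
  per axis.
* **Forward selection** (`forwardSelect`): greedy on added explained
  variance, with the double stopping rule — each entrant needs permutation
  $p \le \alpha$, and the cumulative adjusted $R^2$ may not exceed that of
  the all-candidates model — behind a global pre-test of all candidates at
  $\alpha$. Without the gate the procedure's type-I error is not held at
  $\alpha$; with it, pure-noise candidate sets admit a variable at a rate
  near (and bounded by) $\alpha$.

A genuine property of the double stopping rule deserves emphasis: when the
candidate set contains one strong predictor and many pure-noise columns,
the adjusted $R^2$ of the single true predictor exceeds the adjusted $R^2$
of the full model roughly half the time (the noise variables contribute
zero *expected* adjusted $R^2$, so the cap and the candidate estimate the
same quantity), and the rule then rejects even the true first entrant.
`vegan::ordiR2step`, which implements the same rule, behaves identically in
simulation. The rule buys strong protection against overfitting at a real
cost in power; users with a single-variable signal in a noisy candidate
pool should know the empty selection is a feature of the rule, not a bug
of the data.

# Variance partitioning

`partitionVariation()` computes every Venn cell of explained variation for
2–4 predictor sets by inclusion–exclusion over the adjusted $R^2$ of all
subset models: with $R(S)$ the adjusted $R^2$ of the union of sets $S$,
$h(S) = R({\rm all}) - R({\rm all}\setminus S)$ and cells recovered by
Möbius inversion, so cells sum to $R(\rm all)$ and fractions plus residual
sum to 1 exactly. Adjusted $R^2$ is used throughout — raw $R^2$ is not
comparable across sets of different sizes. Negative fractions are reported
as computed and flagged; `partitionFractions(x, clamp = TRUE)` offers the
conventional non-negative presentation. Unique fractions carry partial
permutation tests (condition = all other sets); shared fractions are
differences of fitted models and are not testable. The two-set and
three-set cells match `vegan::varpart` to $10^{-10}$ in the test suite.

`scaleStratifiedPartition()` re-runs the partition with the spatial set
restricted to the PCNM eigenvectors of one scale class, the per-scale
question ("is the spatially structured environment broad- or
fine-scaled?") asked directly. The default response matrix is the first
two NMDS axes of the chosen dissimilarity; PCoA axes are accepted anywhere
a response is, and are the deterministic choice the acceptance simulations
use.

# The synthetic metacommunity

`generateDataset()` chains four generators, all seeded:

1. **Phylogeny**: birth–death conditioned on the number of tips
   (`ape::rphylo`), hence ultrametric; internal edges shorter than a set
   fraction of tree depth can be collapsed into polytomies, mimicking
   genus-level lack of resolution. Defaults: birth 1, death 0.2, 1687 tips.
2. **Niche optima**: independent Brownian motion per axis along the tree
   (`ape::rTraitCont`); $\sigma^2 = 0$ gives identical optima. Two axes
   (climate, soil) by default.
3. **Landscape**: 41 plots placed uniformly over 223 × 167 km (the km
   equivalent of a 2° × 1.5° window at the equator). Each environmental
   variable mixes its class's shared gradient field (sinusoids along the
   west–east axis, fixed phase, weights $1/k$ over the configured
   wavelengths — 150, 30, 5 km by default) with an own random-orientation
   sinusoid field, in proportion `betweenClassCor` (0.6 by default,
   emulating correlated climate/soil gradients), plus white noise
   (sd 0.3). 19 climate, 9 soil and 4 geomorphology variables; values are
   shifted positive so the square-root transform applies. The class-level
   shared fields, z-scored, are returned as the *true* niche fields.
4. **Assembly**: each plot draws its target richness (250 by default)
   without replacement with probability
   $\propto \exp(-w \sum_a ({\rm env}_a - {\rm opt}_a)^2)\,
   \exp(-d_{\rm source}/\delta)$, with per-species seed sources uniform
   over the landscape. $w = 0$, $\delta = \infty$ reduces *exactly* to the
   richness-preserving null (the uniform weighted draw is the same
   algorithm), which is what makes the end-to-end calibration tests
   meaningful. Defaults $w = 2$, $\delta = 150$ km keep all three regimes
   (neutral, filtered, dispersal-limited) within reach of a single knob
   each. Optima are z-scored per axis before matching, so $w$ is in units
   of squared standardized mismatch.

Fixed richness is deliberate: it keeps every simulated community directly
comparable to the richness-preserving null. A consequence noted above is
that total and turnover Sørensen matrices coincide on simulated data.

What the generator does *not* emulate: abundances (everything is
incidence), interspecific competition, non-equilibrium dynamics,
raster-derived predictor construction, and — important for one documented
limitation — *recent habitat-driven divergence*, i.e. sister species
specializing into different habitats. Under Brownian niches with Gaussian
filtering, climatically similar plots recruit from the same clades, so
between-community MNTD sits far below the tip-shuffle null for similar
pairs and at or above it for distant pairs: beta NTI *increases* with
climatic distance in this generator. Empirical systems in which the same
regression slopes *downward* (clustering between climatically distant
communities) are exhibiting tip-level niche divergence that a BM-only
trait model cannot produce; the corresponding acceptance check is left
failing, with the mechanism documented here, rather than reproduced by a
generator change that the trait model cannot justify. Passing the other
calibration tests therefore says: the chain recovers what this generator
encodes — not that real data obey the generator.

# Numerical conventions and problem sizes

* All indices in double precision; test comparisons at $10^{-12}$ for
  algebraic identities, $10^{-8}$ for decomposition-level equalities.
* Permutation p-values are never zero: $p = (1+\#)/(1+n_\pi)$.
* Residual sums of squares are clamped at zero before F ratios (a perfect
  fit yields $F = \infty$ and the minimum attainable p, not a sign-flipped
  statistic); tests with no residual information return $p = 1$ flagged by
  $F = {\rm NaN}$.
* Ties in $\min/\max$ components need no tie-breaking (min = max).
* The test suite and acceptance script run everything at desk scale — a
  few hundred species, 20–41 plots, 199-draw nulls, 150–250 replicate
  simulations per calibration curve — sizes chosen so the whole suite
  completes in about a minute and the acceptance script in a few minutes
  on one CPU while keeping every statistical band at its stated width.
  The full-size defaults (41 × 1687, 999 iterations, 1000 NMDS starts,
  9999 selection permutations) are what `pipelineConfig(profile = "full")`
  runs on real data.

# Known limitations

* Geomorphology "standardize and add cubed values" is implemented as
  z-standardization plus a cubed companion column per variable — a
  polynomial augmentation allowing non-monotone responses. The construction
  in the methodological literature it gestures at is not fully specified;
  this interpretation is isolated in `applyTransforms()`.
* Coordinates must be planar km; `degreesToKm()` offers a local
  equirectangular conversion adequate for a few degrees of extent, not a
  geodesic projection.
* Per-axis db-RDA tests use marginal row permutation, not sequential
  conditioning on earlier axes.
* Abundance-weighted indices (Bray–Curtis, weighted UniFrac), fixed-fixed
  swap nulls (Curveball), Mantel tests and CCA are out of scope.
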