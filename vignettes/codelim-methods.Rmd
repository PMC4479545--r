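---
title: "Methods: congruence-based species delimitation across data types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: congruence-based species delimitation across data types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codelim)
```

## The question the package operationalizes

Species delimitation studies routinely stack genetic, phenotypic and
climatic evidence, treating the climatic envelope at specimen localities as
a surrogate for physiological tolerance and hence for lineage identity.
Whether climate actually carries taxonomic signal comparable to heritable
(intrinsic) characters is an empirical question, and it can only be asked
fairly if every data type is run through *one identical* statistical
procedure. codelim implements that procedure — ordination followed by
model-based clustering — together with the downstream machinery needed to
compare its outputs across data types: partition congruence, geographic
contiguity, a conservative delimitation rule, and four-taxon D-statistics
for introgression. A synthetic-data generator with known truth makes the
entire chain testable without any external download.

## The shared clustering procedure

Every dataset is reduced to a numeric specimen × feature matrix:

* **mtDNA**: biallelic variable sites of the alignment, coded 0/1 with the
  majority base as 0 (`extract_snps()`); gaps, `N` and IUPAC ambiguity
  codes count as missing. Ties in base frequency are broken alphabetically;
  the polarity is irrelevant to PCA beyond axis sign.
* **SNPs**: diploid 0/1/2 counts as supplied.
* **Phenotype**: 18 meristic counts untouched (bilateral characters are
  averaged, half-integers allowed; a one-sided count is used as is), and 9
  morphometric lengths replaced by residuals of a pooled ordinary
  least-squares regression of log10(length) on log10(body length). Body
  length itself is excluded, giving 27 features. The regression is pooled
  over all specimens, not per group: no grouping exists before clustering.
* **Climate**: 19 bioclim-style variables; the 8 precipitation-type columns
  are log10(x+1)-transformed (zero rainfall occurs in deserts, so the +1
  offset is used instead of a bare log), temperature-type columns pass
  through.

Missing genotypes are replaced by the locus mean of the observed codes
(`impute_missing()`); a locus with no observations is an error, not a
guess. Mean imputation is the documented behaviour of the standard
replacement routines for genotype PCA.

`pca_correlation()` standardizes the columns and computes the eigensystem
of the correlation matrix through an SVD of the standardized data, which is
stable when features outnumber specimens (SNP matrices). Axes whose
variance fraction strictly exceeds 5% are retained (`retain_axes()`); axis
1 is always kept so clustering has at least one dimension. For molecular
data, any retained axis whose scores correlate with the per-sample missing
fraction at |r| ≥ 0.7 is screened out (`screen_missingness_axes()`):
such an axis reflects data completeness, not population structure. The 0.7
default is deliberately conservative — it flags only the pathological,
near-deterministic case — and is exposed as an argument.

Clustering is Gaussian-mixture EM over six covariance families (spherical,
diagonal, full × equal, varying: EII, VII, EEI, VVI, EEE, VVV), a lattice
that spans differences in cluster volume, shape and orientation while
keeping every parameter-count formula auditable. For each component count
K = 1..12 and family, EM runs from a seeded k-means++ initialization with
10 restarts, and the fit with the highest BIC

\[ \mathrm{BIC} = 2\,\ell - m \log n \quad (\text{larger is better}) \]

is selected; ties go to smaller K, then fewer parameters. Specimens are
assigned to their maximum-posterior component, labels are renumbered by
descending cluster size, and classification uncertainty is one minus the
maximum posterior probability.

### Numerical safeguards in the EM engine

The mixture likelihood is unbounded: a component shrink-wrapped around a
handful of near-coincident points drives the log-likelihood to infinity.
With aggressive multi-restart EM these spurious maxima *are* found, and
BIC would happily select them. Three safeguards keep the search honest:

* covariance eigenvalues are floored at 1e-8, so duplicated specimens
  cannot crash a fit;
* a fit is reported *singular* — and skipped during model search — when a
  varying-covariance component (VII/VVI/VVV) holds fewer than d+1
  effective points (its covariance is unidentifiable), or when any
  covariance eigenvalue sits on the floor. Equal-covariance families pool
  their covariance across components and therefore may keep legitimate
  singleton clusters, which real datasets produce (island populations
  represented by one specimen);
* an EM iteration that *decreases* the log-likelihood (possible only when
  the floor has intervened, making the update no longer an exact M-step)
  terminates the fit as singular, so the ascent property of every reported
  fit is exact.

With these rules the engine's selections match mclust on shared scores
(identical BIC to 4 decimals in our cross-checks), while remaining robust
to restart-driven spurious maxima that mclust's single hierarchical
initialization simply never visits.

## Spatial thinning and consensus for climate

Occurrence records oversample accessible places, and climate values are
properties of places; a cluster analysis of raw records therefore weights
climate by collecting effort. `consensus_cluster()` corrects this by
overlaying a grid of 0.5 arc-minute cells (anchored at the minimum
longitude/latitude of the data; the anchor is recorded), sampling one
specimen per occupied cell uniformly at random, clustering the subsample
with the identical engine, and repeating (1000 replicates by default, each
with an independently derived RNG stream). Replicates are combined through
the histogram of selected K (modal K, ties toward smaller K) and a
specimen × specimen co-assignment frequency matrix; the final partition
cuts the average-linkage tree of (1 − co-assignment) into modal-K groups,
so thinned-out specimens also receive labels, and per-specimen uncertainty
is one minus its mean within-group co-assignment. How to combine
replicates is genuinely open; co-assignment consensus is standard
consensus-clustering practice and is isolated behind this one function.

## Congruence, contiguity, and the delimitation rule

`adjusted_rand()` quantifies agreement between partitions
(Hubert–Arabie). "Geographic contiguity" is used in the literature as a
visual criterion; codelim formalizes it: a Delaunay graph over all
specimen localities (duplicated coordinates collapse to one node), edges
longer than the 95th percentile pruned, and a cluster's score is
`1 − (components − 1)/max(1, members − 1)` on the induced subgraph, with a
flag at 0.9. Islands remain contiguous with the mainland whenever their
connecting edges survive pruning. The triangulation is an exact
brute-force construction (empty-circumcircle test in compiled code),
appropriate for the few hundred localities these analyses involve.

`merge_diffuse_clusters()` merges a cluster pair when the members' mean
classification uncertainty exceeds 0.25 *and* their range hulls overlap by
more than 20% of the smaller hull — the signature of one variable species
split in two — iterating to a fixed point and logging every merge. Both
thresholds are exposed arguments; the defaults reproduce the merge
behaviour on synthetic analogues of a species with two overlapping,
high-uncertainty mitochondrial clusters.

`delimit()` implements a conservative rule: species are the most inclusive
clusters congruent across at least two intrinsic datasets. Operationally,
specimens joined in the same cluster by ≥ 2 datasets form cores (connected
components of the co-assignment graph), and cores merge whenever one
dataset's cluster wholly contains them and that cluster is a union of
whole clusters in ≥ 2 datasets. This reproduces both limiting cases: two
identical partitions delimit their common clusters, and a dataset that
splits a group another dataset keeps whole does not inflate the species
count. Groups failing contiguity are flagged, never dissolved.

## D-statistics

`patterson_d()` computes the four-taxon ABBA–BABA statistic from
single-individual representatives. Sites with missing genotypes in the
quartet, or a heterozygous outgroup, are excluded; the outgroup's major
allele defines the ancestral state (with one individual, its genotype is
the only ancestral information available); genotype g becomes a derived
allele frequency g/ploidy; and

\[ D = \frac{\sum \mathrm{ABBA} - \sum \mathrm{BABA}}
           {\sum \mathrm{ABBA} + \sum \mathrm{BABA}},\qquad
   \mathrm{ABBA} = (1-p_1)p_2p_3(1-p_4),\ \
   \mathrm{BABA} = p_1(1-p_2)p_3(1-p_4). \]

Significance uses a delete-m_j block jackknife over 50 contiguous blocks
in locus order — the field-standard procedure for D — with Z = D/SE and a
two-sided normal p; `test_battery()` mirrors the usual supplementary-table
layout and flags p ≤ 0.001. Zero jackknife variance yields a ±Inf Z
sentinel with p = 0, and fewer informative sites than blocks reduces the
block count with a warning.

## Allometric slope heterogeneity

`slope_heterogeneity()` is the ANCOVA homogeneity-of-slopes test on
log10–log10 axes (allometry is linear there; the transform is a flag for
users whose variables are already log-scaled): full model with per-group
slopes and intercepts against a common-slope reduced model,
F = ((RSS_r − RSS_f)/(g−1)) / (RSS_f/(n−2g)). Which two morphometric
columns play "head size" and "rattle size" is the caller's choice — the
package does not hard-wire variable semantics.

## The synthetic world

`sim_world()` generates all five inputs from one seed with known truth.

* **SNPs**: per locus an ancestral frequency Uniform(0.05, 0.95) drifts
  down a user-supplied population tree under the Balding–Nichols model —
  along a branch with drift c, the child frequency is
  Beta(p(1−c)/c, (1−p)(1−c)/c) — then optional admixture edges replace the
  recipient's frequency by (1−γ)p_rec + γp_don, genotypes are
  Binomial(2, p), and cells are masked at the missing rate (default 5%).
  Balding–Nichols was chosen over coalescent simulation because its
  closed-form expectations (E[F_ST] = c for the Hudson ratio-of-sums
  estimator between two populations drifted at c) make the generator
  itself testable, and frequency-level admixture yields an analytically
  predictable direction for E[D].
* **mtDNA**: Jukes–Cantor substitutions, Poisson(rate × branch × length)
  per branch, down the same topology; individuals radiate from their
  population sequence as a star with tip rate 0.008 per site. The tip rate
  matters: far lower values make most conspecific individuals identical
  haplotypes, which is unrealistic for a rapidly evolving mitochondrial
  fragment and degenerate for Gaussian clustering (zero within-cluster
  variance). At 0.008 essentially every simulated individual is a distinct
  haplotype, as in real ATPase data.
* **Traits**: meristic counts are Poisson with per-lineage log-normal mean
  shifts; morphometrics follow log10 y = α_g + β_g log10(SVL) + ε with SVL
  drawn per ontogeny class (adults ~ N(850, 90) mm, subadults ~
  N(450, 70) mm, 75% adults) and residual σ = 0.02.
* **Localities**: uniform points in per-population range ellipses (default
  four ellipses of 0.9° × 0.75° spaced 2.5° apart along longitude).
* **Climate**: two latent fields evaluated at each locality. Temperature
  is a weak latitude gradient (0.5 per degree) plus a strong aspatial
  specimen-level disturbance (sd 2.0) shared by the 11 temperature-type
  variables — the analogue of elevation and microhabitat effects that make
  temperature variables covary without tracking region. Precipitation is a
  logistic "monsoon front" of amplitude 6: in the *crossing* scenario the
  front runs east–west (transition width 0.04° latitude) so the
  high-precipitation regime covers the northern part of *every* lineage's
  range; in the *aligned* scenario it sits in the gap between the two
  easternmost ranges, so the regime boundary coincides with one lineage
  boundary. The 8 precipitation-type variables load on this field through
  a softplus (non-negativity). The true climate-region label is the
  deterministic field thresholded at half its amplitude.

Two generator design points deserve emphasis. First, the front is
logistic, not a Gaussian bump: a Gaussian flank always holds about as many
specimens as the region core (the geometry is scale-invariant), which
manufactures an intermediate third cluster that any sound BIC procedure
will find — the wrong target. A sharp front with a transition width small
relative to the region produces the discrete two-regime landscape the
scenario is meant to encode. Second, cross-loadings between the blocks are
small (0.02–0.05) and the temperature block's shared disturbance is
strong, so correlation-matrix PCA yields axis 1 dominated by
temperature-type variables and axis 2 by precipitation-type variables —
the qualitative structure reported for real bioclim data — rather than a
single merged "latitude" axis.

What the generator does *not* emulate: linkage and coalescent genealogy
variance among SNPs (loci are independent), recombination, selection,
spatially explicit gene flow, intra-locus mtDNA rate variation, realistic
WorldClim covariance structure, or measurement error correlated across
traits. Passing tests therefore demonstrate that the *procedure* behaves
as designed on data satisfying its assumptions — not that any particular
empirical dataset will.

## Study conditions and problem sizes used by the checks

The package's property checks run at fixed, deliberately desk-scale sizes:
the headline contrast uses 20 "crossing" worlds (4 lineages, c = 0.25 on
every branch, 1000 SNP loci, 15 specimens per population) and compares
median adjusted Rand indices of SNP and climate partitions against the
true lineages and true climate regions; the climate partition uses the
same `model_select()` engine as the intrinsic data because synthetic
localities are uniform within each range ellipse, making grid thinning a
no-op in expectation (the thinning consensus has its own dedicated checks,
including invariance of modal K to tenfold oversampling of one cell over
50 replicates). D-statistic calibration uses a deeply diverged
pectinate quartet (drift 0.5/0.5 on the sister tips, 0.5 on their stem,
0.7 on P3, 0.8 on the outgroup — levels appropriate to long-isolated
species and island lineages) with 5000 loci and single-individual
representatives: 200 null simulations for |Z| < 3 calibration and 100
simulations at γ = 0.15 for power. Shallower quartets leave D
underpowered at 5000 loci, which is a property of the statistic, not of
the implementation.

## Known limitations

* The Delaunay construction is O(n³)–O(n⁴); beyond a few hundred unique
  localities the contiguity score becomes slow. The pruning quantile
  (0.95) and flag threshold (0.9) are heuristics exposed as arguments.
* Mean imputation shrinks high-missingness specimens toward the centroid;
  the missingness-axis screen catches the resulting artefactual axes but
  cannot restore lost signal.
* The most-inclusive delimitation rule is one formalization of a verbal
  criterion; `delimit()` exposes `min_support` and reports the full
  support and contiguity audit so alternatives can be compared.
* BIC model selection on small samples can wander by ±1 component around
  marginal optima (2-point BIC margins are common at n = 60); consensus
  and congruence layers are designed to absorb this.
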