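---
title: "Models and methods behind microhapgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microhapgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the design was genuinely open. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data model

A *microhaplotype locus* is a short sequenced fragment whose phased SNPs
define haplotype alleles; a locus may carry from 2 to dozens of alleles.
Genotypes are unordered pairs of allele indices per (individual, locus),
with explicit missing calls. Per-locus gene-copy counts are recomputed from
the calls everywhere they are needed rather than cached, so that filters
cannot desynchronise bookkeeping. The phased-VCF collapser recreates
haplotype collapsing only from already-phased input: read-backed phasing
needs BAMs and belongs upstream of this package. Individuals with any
unphased or missing site at a contig become missing at that locus (counted,
warned, never fatal).

Missing genotypes deserve one note: analyses use the observed
(missingness-reduced) gene-copy count per locus per group. Listwise
behaviours in other software can differ; recomputing n per locus preserves
the observed information content and is declared in the output rather than
hidden.

## Coalescent simulator

Time is measured in units of 2N generations (so the pairwise coalescence
rate within a deme is 1). The event loop treats coalescence and migration
as competing exponentials; with exponential growth at rate α (2N units) all
demes shrink backwards in time as `N(t) = N0 exp(-αt)` and the coalescence
candidate time is drawn exactly by inverting the integrated hazard
`C (e^{αt'} - e^{αt})/α = E`, so no time discretisation is involved.
Migration is a per-lineage backwards rate matrix; the strict island model
gives each lineage total out-rate M/2 with a uniformly chosen destination,
`M = 4Nm`. An event cap (10⁷) converts impossible parameterisations (for
example M = 0 with samples split across demes) into errors instead of
hangs.

Mutations fall uniformly on total branch length under infinite sites.
Fixed-S mode conditions only on the number of segregating sites, not on
tree shape — the natural matched-null construction when a null set "with
the same distribution of segregating sites" as an observed set is required.
θ mode draws `S ~ Poisson(θ T/2)`, giving `E[S] = θ a₁`. Consequences used
as test oracles: `E[T₂] = 1`, `E[T_total] = 2 Σ_{k=1}^{n-1} 1/k`, and under
an island model with d demes the within-deme pair coalescence time scales
with d — which is why per-locus θ values chosen to span observed
heterozygosities are divided by the simulated deme count.

The hot loops (genealogy construction, mutation dropping, the fixed-S
Tajima-D null engine) are C++ with per-deme lineage bookkeeping, driven by
R's RNG so `set.seed()` reproducibility holds end to end.

## Neutrality statistics

Per locus and group: S, mean pairwise difference k̂ (computed from per-site
allele counts, so identical for haplotype strings and binary site
matrices), `Θ_W = S/a₁`, `Θ_T = k̂`, each also per site (÷ fragment
length), and Tajima's
`D = (k̂ - S/a₁) / sqrt(e₁ S + e₂ S (S-1))`. D is undefined for
monomorphic loci; groups with fewer than 4 gene copies at a locus are
skipped (the variance constants degenerate below n = 4). The per-locus test
is the classical beta approximation: D is assumed to follow a scaled beta
on `[D_min, D_max]` with mean 0 and variance 1; the two-sided p doubles the
smaller tail. The test suite validates the closed-form `pbeta`
implementation against direct numerical quadrature of the density.

The genome-wide test matches every observed polymorphic locus with one
constant-size fixed-S coalescent locus of the same gene-copy count and the
same S, per replicate; replicate means and medians form the null. The
reported p-values are plain one-sided empirical proportions
(`p_mean_lower` = share of replicates with simulated mean ≤ observed); an
optional `(1 + count)/(R + 1)` variant sits behind the `add_one` flag, with
the literal proportion as the default. Monomorphic loci contribute no D and
are excluded from both sides (counted in the result). Note that the mean of
D under the fixed-S neutral null is itself slightly negative (about −0.09
at n = 40 over S ∈ [2, 30]) — a known property of the statistic, which is
exactly why the test compares against the simulated null rather than
against zero.

Mann–Whitney Θ comparisons default to per-locus Θ with a per-site switch;
both are exposed because pooling conventions differ across studies.

## AMOVA

Gene copies are the units; the distance between two copies is allele
identity (0 same allele, 1 different) — an F_ST-like analysis on
microhaplotype alleles. Sums of squares reduce to allele-count expressions
(`SSD = (n - Σ_a c_a²/n)/2` within any pool), partitioned into among-group
/ among-population-within-group / within-population levels with the
unequal-size coefficients n', n'', n'''. Everything is per locus with that
locus's observed gene copies; variance components are summed over loci and
F-statistics are formed from the summed components (ratio-of-sums, the
locus-by-locus convention). Negative components are retained — truncation
would bias pairwise estimates that are legitimately negative near zero
differentiation.

Permutation schemes per statistic: F_ST permutes individuals among
populations, F_SC permutes individuals among populations within groups,
F_CT permutes whole populations among groups;
`p = (#{permuted ≥ observed} + 1)/(n_perm + 1)` with ties counted.
A hierarchical design with a single group carries no among-group level and
collapses to the single-level analysis (with a message). The engine is
vectorised over loci via tabulation of (allele, population) keys; the test
suite proves it equal, to 1e-12, to a brute-force implementation that forms
full pairwise distance matrices and direct double sums.

## F_ST outlier scan

The scan asks, locus by locus, whether the observed F_ST is too high for a
neutral strict island model reproducing the data's global F_ST. The
migration rate starts at the closed form `M = (1/F - 1)((d-1)/d)²` and is
refined by log-scale bisection on the mean simulated F_ST over pilot
batches with common random numbers (tolerance ±0.005, 30-step cap with a
diagnostic error). Simulated loci use matched per-population gene-copy
counts, per-locus θ log-uniform over a range spanning the observed
heterozygosities (scaled by 1/d as above), and infinite-sites haplotypes
collapsed to allele identities — the same treatment the observed F_ST
applies to alleles, through the same per-locus count-matrix primitive.

Observed loci are compared with simulated loci in the same heterozygosity
stratum (equal-count bins, default 20, automatically widened below 100
simulated loci per bin) — a simpler, testable alternative to kernel
smoothing, declared in the scan metadata. Only the high tail is tested;
low-F_ST (balancing-type) outliers are out of scope for a low-background
F_ST marine system. p-values are BH-corrected and flags use q < 0.05. Under
the null the p-values are approximately uniform; with finitely many
simulated loci per stratum the smallest attainable p is 0, so the expected
number of BH flags on fully neutral data is about L/(stratum size) — which
is why the scan defaults to 20,000 simulations. The consensus step accepts
an external second flag list (one locus id per line) and intersects; a
second Bayesian scanner is a separate project-scale effort, and the default
empty list keeps the partition conservative.

## Diversity

Nei's unbiased gene diversity `H = n/(n-1)(1 - Σp²)`, hypergeometric
rarefied allele counts `E[A_g] = Σ_i [1 - C(N-N_i, g)/C(N, g)]` (computed
via `lchoose` for numerical safety), and E5 evenness
`((1/λ) - 1)/(e^{H'} - 1)`. The rarefaction depth defaults to the smallest
per-group gene-copy count at each locus across compared groups, reported in
the output — no study-wide constant is assumed. Monomorphic loci take E5 =
1 by convention (the 0/0 limit, flagged), so distribution comparisons are
not biased by asymmetric dropping. Group comparisons use Friedman tests
with loci as blocks and pairwise Wilcoxon signed-rank post hocs
(BH-corrected), on complete blocks only (dropped loci are counted).
Fixed-allele intersections use exclusive UpSet semantics.

## Redundancy analysis and variance partitioning

Allele dosages (0/1/2 per allele column, mean-imputed for missing calls,
centered) form the response. The fit is ordinary least squares onto the
constraint matrix followed by SVD of the fitted values; with a conditioning
matrix, response and constraints are first residualised on it. R² and
adjusted R² are reported against the *total* (unconditioned) response
variance so the variance-partition fractions are commensurable and the
inclusion–exclusion identities hold by construction to machine precision:
`[a] = [a+b+c] - [b+c]`, `[c] = [a+b+c] - [a+b]`,
`[b] = [a+b] + [b+c] - [a+b+c]`, residual `= 1 - [a+b+c]` (adjusted
fractions may be negative). Permutation tests shuffle rows of the
(residualised) response and recompute the pseudo-F; marginal, full and both
partial models are tested. The implementation is validated against vegan to
1e-10 on eigenvalues, R², adjusted R² and all four partition fractions —
vegan remains the cross-check, never the implementation.

Forward selection adds the candidate with the largest adjusted-R² gain,
subject to a permutation test (conditional on the current selection) at
α = 0.05 and to the cumulative adjusted R² not exceeding that of the
full-candidate model. The cap is applied from the second addition onward:
for a single informative candidate among noise, the full model's adjusted
R² is *expected* to fall slightly below the single-candidate model's by
degrees-of-freedom accounting alone, so a first-step cap would veto
legitimate selections at random. With the cap active from step two, noise
candidate pools still yield empty or near-empty selections at roughly the
familywise rate of the per-step test.

Environment-associated alleles are flagged by squared Mahalanobis distance
of their loadings on the first two canonical axes, with the plain empirical
mean and covariance (no robustification — only the distance and the
threshold, 25, are part of the method definition). Loadings are the
unscaled right singular vectors; site scores are weighted sums (scaling-1
style), both declared in the model object. Two caveats matter. First, a
χ²₂ tail calibration of the D² > 25 rule (tail mass 3.7×10⁻⁶) holds only
when loadings are approximately i.i.d. bivariate normal across columns;
rare-allele columns violate this badly and make raw loadings heavy-tailed.
`code_alleles(min_freq = )` therefore provides the standard
genotype–environment practice of dropping rare allele columns (the
calibration tests use `min_freq = 0.05`); with no filter the flag count on
null data is conservative in no sense and should be read as a ranking, not
a test. Second, spatial predictors are orthogonal polynomials of coastal
distance after per-individual Gaussian jitter (default sd 2 km — estuary
mates are otherwise exact ties); the jitter's influence on R² is bounded in
the test suite.

## The scenario generator

The generator emulates the study design: two basins with 9 + 6 estuaries at
coastline-like spacings and the study's per-estuary sample sizes (304
individuals; the per-estuary counts are the authoritative design input),
stepping-stone migration between coastal neighbours within basins
(M_within = 900 per edge), a single between-basin edge linking the closest
estuary pair (M_between = 23), exponential growth α = 5 in every deme, and
per-locus θ log-uniform on [0.2, 2.5] over 120-bp fragments. The migration
defaults were tuned once, by pilot simulation, so that hierarchical AMOVA
on the generated neutral loci recovers F_CT ≈ 0.04 between basins with
F_SC ≈ 0.002 within them — the divergence regime the package is designed
for — and then frozen; α = 5 is a realistic post-glacial expansion signal
that produces clearly negative genome-wide Tajima's D (mean near −1 per
estuary). Environmental structure: two latent axes across estuaries,
rotated into 39 correlated observables with noise, so that PCA is genuinely
needed to recover them. A configurable fraction of loci (default 5%) is
made environment-associated by weighted resampling of gene copies within
each deme with weights `exp(β · env · carrier)` on a tag site chosen
nearest frequency 0.5 — a selection surrogate that moves allele frequencies
along the axis without inventing alleles. Truth tables carry the planted
flags and exhaustively counted allele frequencies, and the realized
F_CT/F_SC of the neutral loci.

What the generator does *not* emulate: linkage between loci (loci are
independent coalescents; the linkage map is a uniform random annotation),
genotyping error and allelic dropout, within-locus recombination, age
structure and overlapping generations, and temporal variation in the
environment. Passing tests therefore validate the statistical machinery
under the stated model, not robustness to those real-data complications.

## Problem sizes and numerical choices

The default test and acceptance runs use deliberately scaled problem sizes,
chosen once as the smallest sizes at which the Monte-Carlo error is well
inside each tolerance: 10⁵ genealogies for coalescent moments, 10⁴ loci for
the fixed-S mean-D band, 200 meta-replicates (40 loci, R = 99) for
null-test calibration, 2,000 loci for island-model F_ST recovery at d = 10,
400 observed loci against 10,000 simulated loci for scan calibration at
d = 100, 600 generated loci for the scenario's realized F_CT/F_SC, and
300-locus Gulf scenarios for the flag-enrichment checks. The analysis
scripts default to 1,200 loci and 500–1,000 permutations, and state the
study-scale conventions (10,000 AMOVA permutations, 20,000 scan
simulations, 1,000 null replicates) in their headers.

Tie and degeneracy handling, in one place: permutation p-values always
count ties and the observed arrangement; all-tied rank tests return p = 1
with a warning; zero-variance environmental variables are dropped with a
warning; collinear constraint columns are pruned by rank-revealing QR with
a warning; saturated ordination models (zero residual df) report R² but NA
adjusted R², pseudo-F and p; D is NA at S = 0 and outside-support values in
the beta test are clamped with a warning.

## Known limitations

The fdist scan's heterozygosity conditioning is a binned empirical
approximation, validated by null calibration rather than by matching any
particular legacy implementation bit for bit. The AMOVA permutation engine
re-tabulates per permutation and is comfortable at thousands of loci and
permutations but not optimised for much larger designs. The RDA pathway
holds the full dosage matrix densely in memory (an n × columns double
matrix). The generator's selection surrogate changes allele frequencies by
resampling, which slightly perturbs within-deme haplotype correlations at
planted loci; planted-truth recovery tests are the intended use.
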