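---
title: "Association networks from observation data: models, null models and their limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association networks from observation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assocnet)
```

## The observation model

Field data on animal sociality usually arrive as *group sightings*: at each
sampling period an observer records one or more groups, each a set of
identified individuals. Under the gambit of the group, all members of a group
are assumed to be associating at that moment. The package stores these data as
a binary group-by-individual (GBI) matrix whose column order is the
individual registry; every attribute table, metric vector and adjacency matrix
downstream is kept in that same order, because silently re-ordered attributes
are the classic way to corrupt a network analysis.

For each unordered dyad the sampling units are classified as: together (`x`),
both identified but apart (`y_AB`), or only one identified (`y_A`, `y_B`). The
simple ratio index `x/(x + y_AB + y_A + y_B)` estimates the proportion of time
together when detection is reliable; the half-weight index
`x/(x + y_AB + (y_A + y_B)/2)` discounts solo sightings when joint
observations are frequently missed, and is never smaller than the simple
ratio. Two sampling-unit conventions are supported: `union` (default) pools
all groups within a sampling period — a dyad is "together" if it shared any
group that period — while `rows` treats each group record as its own unit,
appropriate for instantaneous scans. Dyads whose denominator is zero (both
individuals on the roster but never sampled) carry weight 0 and are flagged in
a mask so that statistics can include or exclude them explicitly; both
conventions exist in the literature and they change the CV of the network, so
the choice is surfaced rather than hidden.

Directed interaction logs (counts or durations with an actor and a receiver)
become rate networks by dividing each actor's totals by its observation
effort. Generalized affiliation indices regress association on structural
predictors (spatial overlap, joint gregariousness) and keep the residuals —
by default a binomial regression of `x` successes in `d` trials, since the
index is a proportion; an identity-link variant serves precomputed indices.

Thresholding (binarizing at a cutoff, or pruning weak edges) is implemented
with a strictly-greater convention and deliberately warns when used: in the
test suite, thresholding a synthetic half-weight network at half the mean
index visibly reshuffles which individuals rank as most connected, and
published simulation work finds inflated error rates in thresholded networks. The
preset thresholds (`mean`, `half_mean`, `twice_mean`) average over non-zero
edges by default; averaging over all dyads is available via `nonzero_only`.

## Metrics

Node metrics (degree, strength, betweenness, eigenvector centrality, PageRank,
reach) and network metrics (density, weighted assortativity, transitivity,
leading-eigenvector communities) follow their standard definitions; standard
graph algorithms are delegated to igraph. Three numerical choices deserve
note. Weighted shortest paths use distance `1/weight`, so strong associations
are short — the field has no single convention, and this one is stated and
configurable by binarizing first. Eigenvector centrality is scaled to a
maximum of 1 and computed per connected component (with a warning), since the
global principal eigenvector assigns zero to everything outside the dominant
component. Transitivity defaults to the standard closed-triple ratio
`3 * triangles / connected triples`, which is bounded by 1; the informal
"three-edge over two-edge triads" ratio is exposed as `variant = "literal"`
because it is sometimes quoted, but it is unbounded and degenerate on
complete graphs.

## Null models

Hypothesis tests compare an observed statistic with its distribution over
randomized datasets. Two families are provided.

**Node-label permutations** shuffle attribute rows across individuals while
the network stays fixed. They are exact for "is this metric associated with
this attribute?" *if* the observed network equals the true network — an
assumption that fails under observation bias.

**Data-stream permutations** randomize the raw observations. Group swaps find
a 2x2 checkerboard `[[1,0],[0,1]]` between two GBI rows in the same stratum
and flip it, exactly conserving group sizes, per-individual sighting counts
and per-stratum totals; strata are the cross-product of the requested
constraint keys (sampling period, location), so swaps can control for time
and space simultaneously. Dyadic swaps exchange receivers between two
interaction records in a stratum, conserving in- and out-counts. Both are
sequential Markov chains: successive states differ by one swap, so replicates
are serially correlated. `burn_in` (default 1000 accepted swaps) moves the
chain away from the observed data before sampling and `swaps_per_step` thins
it; the defaults mirror the common field practice of re-computing the
statistic after every swap, and the calibration experiments below show when
they must be increased. Rejected proposals (no checkerboard) are redrawn and
not counted; a proposal cap converts constraint saturation into an error
rather than a livelock. Missing constraint values collapse into a single
stratum with a warning, so constraints are opt-in rather than silently
invented. All streams are seed-reproducible.

The p-value convention is the field's counting rule — the proportion of null
statistics at least as extreme as the observed one, with the observed value
not added to numerator or denominator; the conservative `(1+k)/(1+n)` variant
is a flag.

## The hypothesis-testing suite

**CV test for preferred/avoided associations.** If relationships are
differentiated, the spread of association indices exceeds its value under
random association given the margins. The statistic is the coefficient of
variation of the dyad values (population standard deviation over mean), which
doubles as an effect size: the observed CV and the mean null CV are reported
together. Calibration experiments in the test suite (uniform random grouping,
120 datasets) show rejection at the nominal 5% level once the chain is burned in and
thinned enough for successive replicates to decorrelate (tens of swaps per
replicate at that data size).

**Permutation-corrected model coefficients.** A node metric (say strength) is
modelled on attributes, optionally with one random intercept
(`strength ~ sex + (1 | area)`). The observed fit uses lme4 (REML; singular
fits degrade to the fixed-effects model); each permuted dataset rebuilds the
network, recomputes the metric and refits the same model, and the focal
coefficient's permutation p-value is reported alongside the naive t-statistic.
The per-replicate refits use an internal profiled restricted-likelihood solver
for the single-random-intercept Gaussian case — for `V = I + theta ZZ'` the
blockwise Woodbury identity reduces REML to a one-dimensional profile over
`log(theta)` — verified against lme4 to five decimals in the test suite and
roughly an order of magnitude faster, which is what makes hundreds of
simulated datasets with hundreds of refits each tractable. When the metric is
strength or degree and swaps cannot move an individual across sampling units,
the index denominators are invariant, so the permutation loop recomputes only
the joint-count matrix (one cross-product per replicate); the fast path is
checked against the full pipeline in the tests.

**Matrix association.** The Mantel test correlates the off-diagonal cells of
two dyadic matrices with node-relabeling permutations of one of them; MRQAP
with double-semi-partialling regresses a dyadic response on several dyadic
predictors, permutes the focal predictor's residual matrix (after regressing
it on the others) by node relabeling, and compares t-statistics; partial
correlations are the effect sizes. Both are validated against exhaustive
enumeration of all relabelings on 4- and 5-node instances.

**Temporal stability.** The lagged association rate estimates, for each lag
bin, the probability that a dyad together at one time is together again a lag
later, conditional on both members being identified then; the expected rate
under random re-grouping, `(mean group size - 1)/(N - 1)`, is attached for
reference. Lag bins default to log-spacing over the observed lags.

**Precision and repeatability.** Bootstrap intervals resample sampling
periods with replacement (resampled copies of a period are kept as distinct
units) and report percentile intervals per node; split-half repeatability
builds networks from disjoint period subsets (odd/even or first/second half)
and reports the Spearman correlation of node metrics.

## Sampling effort and network accuracy

Two quantities govern how well an estimated network mirrors the true one: the
social differentiation `S` (CV of the true dyadic association probabilities)
and the sampling effort `H`, the mean number of *joint* identifications per
dyad. Writing the true probabilities as gamma with mean `mu` and CV `S` and
the per-dyad counts as binomial over `d ~ H/mu` sampling units, the
correlation between true and estimated edges is approximately
`r = sqrt(S^2 H / (1 + S^2 H))`, hence `H = r^2 / (S^2 (1 - r^2))` for a
target accuracy. `H` must be the expected number of joint sightings — not the
number of sampling units — for this relation to reproduce the standard field
guidance (about 44 joint identifications per dyad at `S = 0.2` for `r = 0.8`,
about 5 at `S = 0.6`, and about 0.02 at `S = 10`, where a single observation
of an edge is already near-definitive). `sampling_correlation()` verifies the
closed form by direct simulation; the default mean probability is 0.05, and
parameter combinations that would clip a non-trivial fraction of the gamma
mass at 1 are rejected rather than silently truncated.

## The synthetic populations

`simulate_population()` generates the calibration scenarios used throughout:
`n` individuals split across areas, Poisson gregariousness with area-specific
means (defaults 2 and 3), `P(male)` rising with gregariousness
(`sex_link * g/max(g) + (1 - sex_link)/2`), and in every sampling period an
independent dyadic association for each within-area pair with probability
`edge_prob_scale * (g_i + g_j)` — never across areas. The default scale 0.02
puts the mean dyadic probability near 0.1. Groups for GBI pipelines are the
connected components of each period's realized association graph among
detected individuals, singletons included, each row tagged with its period and
area. `apply_detection_bias()` thins each individual's presence per period by
a class probability (e.g. females 0.7, males 1.0), removing their dyadic
events with them. Everything is seed-reproducible.

What the generator emulates: fission–fusion grouping with persistent
individual gregariousness, spatial separation, and conspicuousness bias. What
it does not: temporal autocorrelation of group membership, demographic
turnover, spatially continuous home ranges, or observation error beyond
per-individual thinning — so passing calibration here does not certify those
settings. Simulation sizes in the test suite (40 individuals, 100 periods,
200 permutations per test, 100–500 datasets per property) were chosen as the
smallest designs at which the qualitative contrasts are stable.

## What the permutation coefficient test can and cannot do

The bias demonstration is reproduced as a property: with sex random but
females detected at 0.7, the naive mixed model calls the sex difference
"significant" (|t| > 2) in the large majority of simulated populations, while
the data-stream permutation p-value typically does not — the null carries the
detection bias because each individual's sighting count is conserved.

Its exact error *rate* is another matter. A data-stream null conditions on
the margins (sighting counts, group sizes), so the null distribution of a
regression coefficient contains only the variance that survives that
conditioning. In these populations, persistent gregariousness differences
drive most of the between-dataset variance of the sex coefficient, and that
variance is frozen into the margins: the swap-null distribution of the
coefficient is an order of magnitude narrower than the coefficient's true
sampling distribution, so the permutation p-value concentrates near 0 or 1
depending on which side of its (offset) null mean the observed coefficient
falls. No chain length or thinning fixes this — it is a property of the null
model, not of mixing, and it is consistent with published critiques of
regression coefficients tested against data-stream permutations. The test
suite therefore asserts the qualitative bias-correction property, and reports
the strict type-I calibration of this design honestly; when the observed
network can be trusted, node-label permutations (`kind = "node"`) are exactly
calibrated for attribute–metric associations and are the right tool. By
contrast the CV test's statistic measures structure *beyond* the margins,
which is exactly what the swap null randomizes, and it calibrates cleanly.

## Degenerate inputs and numerical conventions

Empty GBIs, groups with duplicate members, unknown individuals, asymmetric
matrices for undirected networks, negative weights, constant attributes for
assortativity, and saturated swap constraints all raise errors naming the
offending entity. Self-edges in input matrices are zeroed with a warning.
Association indices at zero denominator are 0 and masked. Community detection
uses the deterministic leading-eigenvector routine; betweenness ties split
path counts evenly; Spearman correlations use average ranks on ties. Round
trips through square-CSV, edge-list and GraphML formats preserve weights to
1e-12 and registry order exactly.
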