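---
title: "Models and methods behind ylineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ylineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ylineage)
```

ylineage is a pipeline for haploid (Y-chromosome) sequence analysis: it
filters jointly called haploid genotypes into a binary SNV matrix, builds a
rooted phylogeny from that matrix, dates its internal nodes with the ρ
statistic, assigns haplogroups from a marker tree, and interpolates
haplogroup frequencies into presence and combination maps. Because the
interesting properties of such a pipeline (does filtering remove exactly
what it claims? does tree building recover the true genealogy? is dating
unbiased?) can only be judged against a known truth, the package ships a
first-class synthetic-data generator and validates every stage against it.

## The coalescent generator

`simulate_genealogy()` draws a Kingman coalescent for `n_samples` haploid
lineages. Internally it works in generations — with `k` lineages the waiting
time to the next coalescence is exponential with rate `choose(k, 2) / Ne` —
and converts to years through `generation_time` (default 30 y/generation),
so that all user-facing ages are in years, matching the per-year mutation
rate. Under the default constant-size model the expected TMRCA is
`2 Ne (1 − 1/n)` generations; with the default haploid `Ne = 1000` and 30
y/generation a large sample coalesces around 60 ky, the timescale of
non-African Y-chromosome variation. The alternative `expansion` model keeps
`Ne` constant before `T_expand` years ago (default 54 ky) and multiplies it
by `growth` afterwards; it is illustrative — no published demographic fit is
claimed — and exists so that tests can exercise piecewise-constant
demographies. When `tmrca_target` is set, all node ages are rescaled so the
root age equals it exactly; this turns Monte-Carlo TMRCA variation off when
a test needs a known truth.

`drop_mutations()` places mutations under the infinite-sites model: each
edge receives a Poisson number with mean `mu * L * edge_length`, each
mutation occupies a fresh site among the `L` callable positions, and the
derived allele is carried by exactly the tips below the edge. Defaults are
the field's standard point estimate `mu = 0.76e-9` mutations/site/year and
an `L = 10.3` Mb callable region. The infinite-sites assumption is enforced
(an error if the expected mutation count exceeds `L`), which guarantees the
output matrix passes the four-gamete test and admits a perfect phylogeny —
the property the tree builder relies on.

`inject_artifacts()` adds what real short-read call sets suffer from:
per-sample mean depths drawn from Normal(`depth_mean = 30`,
`depth_sd = 8`) truncated at 1 with per-genotype Poisson DP (a standard
count model; the calling literature gives no reason for anything richer
here); contaminated genotypes at `allele_error_rate` whose called-allele
read fraction is forced to ≤ 0.8 by giving ⌈0.2 DP⌉ reads (DP floored at 5)
to a second allele, so every planted contamination is visible to — and
removable by — the 0.85 allele-balance rule; genotypes dropped at
`missing_rate`; and indel records placed within 5 bp of existing SNVs at
`indel_rate` per SNV site so the SnpGap filter has something to do. The
generator returns a truth mask of corrupted and dropped genotypes.

What the generator deliberately does not emulate: recombination (none on
the male-specific region anyway), back-mutation and recurrent mutation,
reference/mapping bias, batch effects between cohorts, and read-level data.
Passing tests therefore demonstrate correctness of the pipeline's logic
under its stated model, not robustness to homoplasy or mapping artifacts in
real data.

## The filter chain

`filter_calls()` applies, in a fixed order: removal of SNVs within 5 bp of
an indel and of indel records; genotype masking below a minimum depth (DP <
3 for samples with mean chrY depth ≥ 12×, DP < 2 below that, with
low-coverage samples exempt); genotype masking where reads support more
than one allele and the called allele holds < 0.85 of them; then removal of
samples with ≥ 5% missingness and, after that, of sites with ≥ 3%
missingness. All inequalities are closed bounds — removal happens at
exactly 5%, 3% and below 0.85 — and the two missingness cuts are applied in
sample-then-site order, with the site fraction computed over the retained
samples. The `FilterReport` attributes every removal to exactly one stage.

Invariant (non-variant) sites are never materialized: the call set carries
a callable-length scalar `L`, every removed record decrements it, and the
resulting `L_effective` is the denominator of all per-site divergences.
Missingness fractions are computed over the records present in the call
set; simulated invariant sites are treated as always called.

One consequence worth knowing: at small sample sizes the 3% site cut is
aggressive (with 20 samples, a single missing genotype already exceeds it),
and removing real variant sites while barely touching the ~10.3 Mb
denominator biases ρ ages downward. This mirrors the behaviour of the same
filters on real cohorts, where the effect is small because sample sizes are
in the hundreds; the dating-accuracy tests therefore run on noise-free
matrices, where the estimator's own properties are isolated from the
filter interaction.

## Tree building

`build_tree()` constructs the rooted perfect phylogeny directly from the
derived-carrier sets: identical carrier sets share an edge, the laminar
family of carrier sets is the clade hierarchy, and the ancestral state
roots the tree (so no outgroup is needed). Maximum-likelihood inference is
out of scope by design: on effectively homoplasy-free binary Y-SNV data the
ML, parsimony and perfect-phylogeny topologies coincide, and the
combinatorial construction is exactly testable — recovery can be asserted
as Robinson–Foulds distance 0, not "close".

Sites whose carriers conflict with the family (possible only with
genotyping error) are placed by greedy parsimony on the minimal set of
existing clades covering their carriers, reported per site in `conflicts`;
a recurrent placement reproduces the observed genotypes exactly. Missing
entries are resolved by "snapping": if every non-missing member of an
existing clade is derived at the site, the carrier set is promoted to the
largest such (non-root) clade and the missing members are imputed derived —
the right call when missingness is dropout, as in the generator; otherwise
missing entries are imputed ancestral. Ties anywhere (child ordering,
diameter pairs) are broken lexicographically on sample IDs so results are
order-independent.

`midpoint_root()` roots at the midpoint of the longest tip-to-tip path in
the mutation-count metric, with ties broken on the lexicographically
smallest tip pair; it is provided for trees that arrive unrooted (the
builder's own trees are already rooted by the ancestral state).
`flag_long_terminal_branches()` implements the standard terminal-branch QC:
tips whose terminal mutation count exceeds the median by more than 6 MADs
(the usual 1.4826-scaled MAD) are flagged, not removed — removal is the
analyst's decision.

## ρ dating

For an internal node, `clade_divergence()` averages pairwise divergences
over all cross-child pairs; `pairwise_divergence(i, j)` is the number of
sites where both samples are called and differ, divided by the comparable
length — `L_effective` minus the sites missing in either sample, so
invariant sites count in the denominator. A child clade with more than 100
descendants is first subsampled to ⌈n/3⌉, using a seed keyed to the clade's
sorted tip labels so that dating does not depend on traversal or sample
order.

`date_node()` converts divergence `d` to an age `d / (2 μ)`: a pairwise
divergence accrues along two lineages, so the per-lineage convention
divides by 2. The factor is exposed as
`dating_config(pair_divergence_factor=)` for anyone preferring the
one-lineage convention. The confidence interval propagates only the
mutation-rate uncertainty, `(d/(2 μ_high), d/(2 μ_low))` with defaults
`0.67e-9`–`0.86e-9`; it does not include coalescent or sampling variance,
so it should be read as rate uncertainty, not a full posterior.
`lineages_through_time()` counts the edges crossing a time horizon, with
the stem convention that any `t` at or above the (clade) root age returns 1.

## Haplogroup assignment

`call_haplogroup()` walks the haplogroup hierarchy from its root. At each
node it enters the child with the highest fraction of typed markers in the
derived state, requiring at least one derived marker and a fraction ≥ 0.5 —
a majority rule that tolerates isolated genotyping errors. A child whose
markers are all untyped can still be traversed when derived markers exist
deeper in its subtree: the assignment follows the most terminal derived
SNV, and an uncheckable intermediate node is listed under `missing` rather
than blocking the walk. Derived markers off the accepted path are surfaced
as `conflicts` and never retract an assignment. With no typed markers at
all the call is `"unresolved"`, not an error.

The planted-marker generator defaults to several markers per named clade;
the validation cohorts use 3 markers per branch with 15% marker dropout.
With 2 markers a branch has a 2–4% chance of being entirely untyped at
realistic dropout rates, which caps terminal-clade accuracy below 99%
regardless of the walk rule — redundancy, not cleverness, is what real
marker panels rely on, and the chosen panel reflects that.

## Cartography

`merge_populations()` agglomerates small neighbouring populations until the
mean sample size among populations carrying the focal haplogroup reaches
~50, merging the smallest carrier with its great-circle nearest neighbour
at the sample-weighted centroid; totals are conserved.
`shepard_interpolate()` is a generalized Shepard (inverse-distance)
interpolator with a 2000 km radius of influence and exponent 3. The exact
kernel of the historical GeneGeo "weight function 3" is not published, so
the kernel is pluggable: the default Franke–Little form
`((R − d)/(R d))^3` and a plain truncated `d^−3` differ only smoothly, and
every property asserted in tests (exactness at population coordinates,
convexity, truncation) holds for both. Distances are haversine on a
6371 km sphere. Nodes coinciding with a population take its value exactly;
nodes beyond the radius of every population are no-data. `presence_map()`
thresholds at frequency > 0 (the maps show presence/absence, not a
frequency cut), and `combine_presence()` sums presence layers nodewise,
treating a no-data layer as 0 but keeping all-no-data nodes as no-data, so
the three-haplogroup combination map has domain {0, 1, 2, 3}.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → filter → tree → date → haplogroup → map
(any contiguous subset; a fixture VCF can replace the simulate stage) and
writes a manifest of MD5 hashes. A single master seed drives every stage
through per-purpose derived seeds, so a rerun is byte-identical. All output
formats are plain text: VCF 4.2 with `GT:DP:AD`, Newick with node-age
labels, TSV tables, JSON reports.

## Validation problem sizes

The shipped validation suite uses: a 50 × 2000 call set with hand-placed
boundary artifacts for filter fidelity; 50 seeded genealogies of 20 tips at
TMRCAs of 50–60 ky for topology recovery (RF = 0 required) and dating
(mean root-age error < 5% observed at well under 1%, rate-CIs covering the
truth in every replicate); 1000 random (tree, time) queries for
lineage-through-time; 20 cohorts of 25 samples for haplogroup accuracy
(≥ 99%); and 10,000 random grid nodes for the interpolation invariants.
These sizes make the full suite run in about a minute while keeping every
Monte-Carlo tolerance derived from the corresponding analytic standard
error, never tuned to observed outcomes.

## Known limitations

Perfect phylogeny with greedy parsimony fallback is not an ML tree under a
substitution model; it is the right tool only while homoplasy is
negligible, which holds for Y-SNV matrices but not for, say, mtDNA
hypervariable sites. ρ confidence intervals understate total uncertainty
(no coalescent variance). The site-missingness cut biases ρ ages downward
at very small n (see above). The haplogroup walk assumes the marker tree is
correct; marker conflicts are reported, not arbitrated. The cartography
makes no landmass distinction and interpolates across water.
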