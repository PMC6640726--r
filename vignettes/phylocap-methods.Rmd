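---
title: "phylocap: models and methods for target-capture phylogenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phylocap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocap)
```

phylocap implements the analysis loop of a target-capture (Hyb-Seq)
phylogenomics project — variant filtering, per-locus alignments,
informativeness profiling, gene- and species-tree estimation — together
with the design loop — locus selection under a bait budget and
dual-index barcode construction. This vignette describes the models,
the estimators, the tunable parameters and their defaults, the
numerical choices, and the limits of what the synthetic data can show.

## The multispecies coalescent generator

Downstream methods are exercised on data from `simulate_species_tree()`
(a Yule tree: pure birth at rate `birth_rate`, default 1 per unit time,
ultrametric by construction) and `simulate_gene_trees()`, which runs the
multispecies coalescent (MSC) inside the species tree. Within a branch
of duration $t$ time units, $k$ gene lineages coalesce at rate
$\binom{k}{2}/\theta$, so the branch spans $d = t/\theta$ coalescent
units. This makes the classical quartet law exact: for a four-species
caterpillar tree whose single internal branch is $d$ coalescent units
long, a gene tree matches the species-tree quartet with probability
$1 - \tfrac{2}{3}e^{-d}$, and the two minor resolutions appear with
probability $\tfrac{1}{3}e^{-d}$ each. (For a balanced four-species
tree the exponent is the sum of the two internal branches.) The test
suite checks simulated frequencies against this law and against an
independent lineage-merge sampler.

Sequences evolve on gene trees under a reversible substitution model
(`substitution_model()`, JC or GTR) by `simulate_alignment()`. One unit
of branch length is one expected substitution per site at stationarity.
Among-site rate variation is continuous mean-one gamma with shape
$\alpha$ (values in the empirically common range 0.2–1 make rate
heterogeneity strong); per-gene rate multipliers model slow and fast
loci. The
simulator stores the true per-site rates, which the informativeness
tests use as recovery truth.

`simulate_variant_table()` turns alignments into all-sites variant
records: per-genotype depths are negative binomial (`mean` 30, `size`
10 by default — overdispersed, like capture data), site qualities are
rounded clamped Gaussians (mean 60, sd 15, max 99), a configurable
fraction of sites is flagged as indels, and genotypes go missing at a
configurable rate. Depth and quality distributions are free knobs of
the generator, not calibrated to any particular sequencing archive;
indels are simulated as site annotations only, because the downstream
filter needs nothing more than the flag.

Seeding: every generator is a pure function of its arguments; per-gene
(and per-bootstrap-replicate) streams derive from the master seed by an
exact integer congruential mix, so runs are reproducible and
order-independent.

What the generator does *not* emulate: read-level artefacts (mapping
error, PCR duplicates, reference bias), gene flow or hybridization,
linkage between adjacent loci, and realistic indel processes. Tests
that pass on these data therefore validate the estimators under their
own model assumptions, not robustness to violations of them.

## Site filtering and alignment extraction

`filter_sites()` applies the standard capture filters, with defaults
(site quality strictly > 20, no indels, per-sample depth ≥ 8×, ≤ 50%
missing genotypes per site) exposed in `filter_config()`. Two
comparisons are deliberately asymmetric: the quality rule is strict
(a site at exactly 20 is removed) while the depth rule is inclusive
(a genotype at exactly 8× survives), reading "minimum depth" as an
attained minimum. Rule order matters and is fixed: depth masking is the
only per-genotype rule, so it runs first and feeds the site-level
missingness computation; whether a published pipeline computed
missingness before or after depth masking is generally ambiguous, and
this order is the conservative choice (masking can only increase
missingness, so it removes more borderline sites). Filtering is
idempotent and monotone in each threshold; both properties are tested.

`variants_to_alignments()` reconstructs the full region span per
sample: reference base where no record or a homozygous-reference call
exists, alternate base for homozygous-alternate, IUPAC ambiguity code
for heterozygotes (a deterministic convention, preferred over random
allele sampling so repeated runs agree), and `N` for missing genotypes
and filtered sites. Multi-allelic heterozygotes map to the code of
their two alternate bases. Regions are BED-like 0-based half-open
internally; VCF I/O is 1-based.

## Phylogenetic informativeness

`estimate_site_rates()` estimates a scalar rate multiplier per site by
maximum likelihood on a fixed ultrametric reference tree whose depth is
normalized to 1 (absolute geological time is a user-supplied rescaling
of the profile axis). Because the likelihood depends only on the
product rate × time, rates are always optimized on the depth-1 tree and
rescaled — this makes the rate–time identifiability exact rather than a
numerical accident. The per-site likelihood surface can be multimodal
(saturated sites place mass at the upper bound), so the optimizer
first scans a 41-point log-spaced grid, vectorized over site patterns,
then refines the bracketed maximum by Brent search. Invariant columns
get rate 0 without optimization; columns with any non-ACGT character
are excluded and reported, since the rate model assumes complete data.
JC is the default substitution core — with topology and relative branch
lengths fixed, the per-site scalar rate is barely sensitive to the
exchangeabilities, and JC keeps the estimator testable against closed
forms; a GTR core is available.

The informativeness of a site with rate $\lambda$ at depth $t$ is the
four-state form
$$\rho(t) = 16\,\lambda^2\, t\, e^{-4\lambda t},$$
summed over sites for a gene profile (`pi_profile()`). Analytic
consequences used as test oracles: the single-site profile peaks at
$t = 1/(4\lambda)$, and the per-site integral over $[0, \infty)$ is
exactly 1 for every $\lambda > 0$, so the profile is scale-free.
`integrated_pi()` integrates epochs by composite trapezoid with grid
doubling to a relative tolerance of $10^{-6}$, recomputing the profile
from the stored rates so refinement is not limited to the display grid;
an infinite upper bound switches to the analytic tail
$e^{-4\lambda a}(4\lambda a + 1)$. Epoch boundaries are configuration,
not constants: which epoch should drive gene ranking depends on the
divergence depths a study targets, so `rank_genes()` takes the epoch as
an argument (ties break by gene id for stable output).

## Gene trees

`tree_log_likelihood()` is Felsenstein pruning over compressed site
patterns with per-node underflow rescaling; gaps, `N` and ambiguity
codes contribute partial likelihood 1 per compatible state. Discrete
gamma uses 4 equal-probability categories by default (field
convention); $\alpha$, when requested, is estimated by bounded 1-D
optimization in $[0.02, 100]$.

`estimate_gene_tree()` starts from neighbor joining on JC-corrected
distances (saturated pairs capped at 3 substitutions/site), optimizes
branch lengths by cycling per-branch Brent searches (relative tolerance
$10^{-6}$, cycles until the log-likelihood gains less than $10^{-4}$),
and hill-climbs with nearest-neighbor interchanges: candidates are
scanned in a fixed canonical order, screened with two cheap
branch-length cycles, and the first strict improvement is accepted and
then fully re-optimized. First-improvement with a fixed order makes the
search deterministic; an optional seeded jitter on the NJ distances
resolves ties on signal-free data (off by default). The NNI trajectory
never decreases the log-likelihood, which the tests assert.

`bootstrap_support()` is the plain nonparametric bootstrap: columns
resampled with replacement, the full estimator re-run per replicate,
and per-branch support the percentage of replicates containing the
bipartition. A fixed replicate count (default 100) replaces adaptive
stopping rules so runs are reproducible. The mean bootstrap — the
statistic consumed by gene selection — averages over internal branches
only; pendant branches appear in every resolved tree and would only
dilute the signal, but the set of branches averaged is an explicit
choice, kept configurable in reporting rather than buried.

`concatenate_alignments()` builds the partitioned supermatrix (missing
sample × gene blocks as `-`; RAxML-style partition lines, 1-based
inclusive) and `root_with_outgroup()` roots on the branch separating a
monophyly-checked outgroup — a non-monophyletic outgroup is an error,
never silently forced.

## Species tree

`quartet_score()` counts, over all species 4-subsets and gene trees
(and all individual choices under a multi-individual mapping), induced
gene-tree quartets that agree with the species tree. Induced quartet
topologies come from topological (unit-branch-length) path distances
and the four-point condition, which is exact on binary trees; ties mark
unresolved quartets, which are excluded from both numerator and
denominator so the per-branch frequencies $(q_1, q_2, q_3)$ remain a
proper distribution.

`estimate_species_tree()` maximizes the quartet score exactly — all
unrooted topologies, feasible to 8 species (10,395 trees) — after
tallying each 4-subset's gene-tree resolutions once, so scoring a
candidate topology is a table lookup. Above the exact cutoff, species
are inserted greedily in order of decreasing appearance frequency and
the result is polished by first-improvement NNI on the score;
enumeration order breaks ties deterministically. The dynamic-programming
constrained search of large-scale quartet methods is out of scope: at
desk scale the exact search doubles as its own certificate, and the
tests verify the returned score equals the enumerated maximum.

Per branch, `quartet_support()` tallies the three resolutions around
the branch's quadripartition, and `local_posterior()` converts counts
$(n_1, n_2, n_3)$ into posterior probabilities under the MSC multinomial
model — resolving quartets follow
$(1-\tfrac{2}{3}e^{-d},\ \tfrac{1}{3}e^{-d},\ \tfrac{1}{3}e^{-d})$ —
with an exponential prior on $d$ (rate `prior_lambda`, default 0.5, the
convention of the local-posterior literature). The integral over
$d \in (0, 20]$ is computed by adaptive quadrature with log-domain
likelihood evaluation (the likelihood underflows in double precision
already at a few hundred quartets); $d > 20$ contributes below machine
precision. Symmetric counts give exactly $(\frac13,\frac13,\frac13)$,
and $pp_1$ is monotone in $n_1$ — both tested, along with agreement to
a fine-grid trapezoid oracle at $10^{-6}$ absolute.

`annotate_species_tree()` serializes the tree with $pp_1$ as internal
node labels (17 significant digits, so parsing recovers them exactly)
and the $q$'s in bracketed comments, and reports the fraction of
branches with $pp_1 > 0.9$ — the headline support statistic of a
coalescent analysis.

## Locus selection and index design

`select_genes()` applies six criteria in a fixed order — single-copy;
on an allowed chromosome (default `chr1..chr16`, excluding unplaced
scaffolds); absent from the existing kit; in the top *k* (default 500)
by informativeness **or** by mean bootstrap ("and/or" read as set
union, the inclusive reading that retains the most signal); mean
bootstrap strictly greater than 60; at least 5 baits — and then
enforces the bait budget by dropping genes in order of worst composite
rank (the max of the two ranks, ties by informativeness rank, then gene
id). Every input gene is audited with the first criterion that removed
it, which makes the criterion order transparent and the whole selection
reproducible from the audit table. Whether a published kit applied its
budget before or after the bait-count criterion is usually not
recoverable from text; here the budget always runs last, and the audit
makes that visible.

`tile_baits()` places 120-nt baits (2× tiling, step 60) per exon with
the last bait right-aligned; exons shorter than a bait get one bait iff
they are at least half a bait long. Both geometry parameters are
configurable, and bait counts may instead be supplied directly in the
metadata. `export_kit()` extends short-exon baits symmetrically into
flanking reference sequence so every exported bait reaches full length.

`generate_indexes()` builds two disjoint sets of fixed-length indexes
whose pairwise Levenshtein distance meets a floor (default: 7 nt,
distance 4 — the edit-distance reading is literal, insertions and
deletions included, with a Hamming mode for fixed-length screening) and
whose per-position base composition is within ±0.15 of uniform.
Construction is a greedy scan of a seeded shuffle of all $4^7$
candidates followed by first-improvement swaps toward balance, with up
to 50 restarts; a greedy pass typically packs ~45–50 seven-mers at
distance 4, comfortably above the 30 needed per set. Balance is
enforced only for sets of at least 8 sequences (smaller sets cannot
approximate uniform composition by pigeonhole). The distance floor
applies within each set by default; a cross-set floor is optional,
since dual-index demultiplexing reads the two sides independently. The
emitted sets are re-verified by the package's own dynamic-programming
edit distance — the construction path uses a different routine, so
verification is independent.

## Problem sizes and degenerate inputs

The test suite runs the estimators at sizes where exhaustive oracles
exist and simulations stay tight: likelihoods are cross-checked by
interior-state enumeration at ≤ 5 taxa and ≤ 50 sites; quartet tallies
by brute force at ≤ 8 species and ≤ 50 genes; the exact species-tree
search against full enumeration at 5–7 species; the quartet law at
10,000 gene trees per branch length; site-rate recovery at 20 taxa and
2,000 sites; and the end-to-end identity-recovery run uses 6 species ×
16 genes × 600 bp. These sizes are the package's validation envelope —
large enough for Monte-Carlo error to be small against the tested
effect, small enough that every oracle is exact.

Degenerate inputs are defined rather than accidental: empty variant
tables filter to empty tables; an all-missing alignment column
contributes likelihood 1; invariant columns have rate 0; `m = 0`
resolving quartets is an explicit error for local posteriors (not a
NaN); zero-length branches are legal everywhere; infeasible index
parameters fail with the attempt count instead of looping.

## Known limitations

- The likelihood engine and tree searches are pure R and sized for
  desk-scale problems (tens of taxa, kilobase alignments), not for
  thousand-sample supermatrices.
- Gene-tree error is not propagated into the species-tree posteriors;
  quartet counts are taken at face value, as in standard two-step
  coalescent practice.
- The MSC generator assumes one constant `theta` across branches and no
  migration; the sequence simulator has no indel process.
- Substitution-model selection is out of scope by design: the model is
  configuration (GTR+Γ is adequate for tree estimation in practice),
  not a fitted choice.
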