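---
title: "Measuring the phylogenetic structure of regional extinctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the phylogenetic structure of regional extinctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarphylo)
```

`polarphylo` asks a single question of a dated higher-taxon phylogeny and
two regional faunal snapshots: were the taxa that disappeared between the
snapshots a random draw from the regional tree, or were they each other's
relatives? The answer matters because clustered extinction prunes whole
limbs of the tree and permanently restructures a regional fauna, while
random extinction of the same intensity thins the tree evenly and leaves
most deep history represented by surviving relatives. This vignette explains
the models behind each stage, the tunable parameters and defaults, the
numerical conventions, and what the synthetic-data tests do and do not
demonstrate.

## The data model and fossil calibration

The tree is an `ape::phylo` whose tips are families; polytomies are allowed
everywhere and never randomly resolved. Branch lengths are not taken from
the input newick: they are derived by **fossil calibration**
(`calibrate_ages()`), which assigns each internal node the first-appearance
age (Ma) of the oldest family it subtends, sets all tips to `tip_age`
(default 0 Ma = Recent), and defines every edge length as
`age(parent) − age(child)` in Myr. The rule is a maximum over descendants,
so it is idempotent, monotone in the input ages, and always yields
nonnegative edges; the calibrated tree is ultrametric at `tip_age`.

Tips are fixed at 0 Ma for *both* time bins, including the fossil one. The
alternative — truncating fossil-bin tips at the bin's closing age — would
make branch-length totals incomparable between bins; calibrating once and
reading both faunas off the same tree keeps the earlier/later comparison a
pure pruning comparison. This is a deliberate convention, not a claim that
the fossil families persisted to the Recent.

Pruning (`prune_to()`) suppresses unifurcations by merging their edge
lengths and **drops the root stem above the surviving most recent common
ancestor**: a branch with no surviving descendants in the region is not
retained history. Patristic distances among the kept tips are invariant
under pruning (property-tested against a path-walking oracle), which is why
SES results are identical whether distances come from the global matrix or
a regional subtree.

## Extinction clustering: MPD/MNTD standardized effect sizes

For the extinct set *E* with pairwise patristic distances `d(i, j)`:

* `MPD(E)` — mean over unordered pairs; sensitive to deep, tree-wide
  clustering.
* `MNTD(E)` — mean distance to the nearest other extinct family; sensitive
  to terminal clustering. `MNTD ≤ MPD` always.

The null model draws uniformly random subsets of the regional tree's tips
of size `|E|` — the exact set-valued equivalent of shuffling tip labels, and
the natural "richness" null when the only data are presences. We report
`SES = (obs − mean(null)) / sd(null)` with the sample (n−1) sd, the
one-tailed clustering p-value `p = (#{null ≤ obs} + 1) / (n_rand + 1)`
(the add-one correction keeps p > 0), and a two-tailed companion. The
observed value is never pooled into the null. Default `n_rand = 10000`;
1,000 randomizations already give p-values stable to ~0.01, so the default
is conservative.

Preconditions are enforced rather than patched: fewer than two extinct
families is an error (the metrics are undefined), and an all-extinct
labeling is a degenerate null (zero variance), also an error.

## Phylogenetic signal: the D statistic

The raw score d is the sum over edges of `|value(child) − value(parent)|`,
with internal node values estimated tips-to-root as the plain arithmetic
mean of each node's children. No branch-length weighting enters the
estimator — branch lengths act only through the Brownian null — and
polytomies contribute the mean over all their children, so the observed d is
deterministic. This estimator reproduces the documented limiting behaviour
that defines D's scale, which is the testable contract: under prevalence-
matched tip shuffles d averages to its "random" expectation (D = 1), under a
Brownian-threshold trait to its "clumped" expectation (D = 0), and

```
D = (d_obs − mean d_Brownian) / (mean d_random − mean d_Brownian).
```

The Brownian null simulates a continuous character edge-wise with variance
proportional to edge length and then marks exactly k tips as extinct by
rank, k being the observed count. Thresholding by rank rather than by a
fixed quantile of the normal keeps prevalence identical across both nulls,
which is what makes D invariant (to Monte-Carlo error) under swapping the
two state labels. Default `n_sims = 1000` per null; the spread of repeated
D estimates shrinks as `1/sqrt(n_sims)`.

D is reported alongside SES because it adds graded information: two regions
can both fail or both pass a significance test while sitting at very
different points on the random-to-Brownian axis.

## Diversity retention

`retention()` totals the regional tree in two currencies — branch length
(Myr) and node count after suppressing unifurcations — before and after
extinction, and reports retained and lost fractions of each. The two
metrics deliberately disagree when extinction is clustered: node count
falls roughly with the number of tips lost, while branch length collapses
only when *all* descendants of a deep branch are gone.

Two modes handle the asymmetry of fossil and modern sampling. The default
`survivors` mode prunes the earlier tree to the survivors of the earlier
fauna, treating later-bin additions as unverifiable at face value. The
`full_list` mode instead builds the later tree from the later faunal list
as given, so persisting or newly recorded sister families count toward
retained history. Both are computed by `run_all()`; which is appropriate
depends on how much one trusts later-bin additions, which is a data-curation
judgement the package does not make.

## Lyellian survivorship and the genus cascade

The Lyellian percentage — percent of an interval's genera surviving to the
Recent — gets an exact Clopper–Pearson binomial CI in closed beta-quantile
form (coverage ≥ 94% across an (n, p) grid is part of the test suite).

The **cascade null** tests whether family-level extinction patterns could
arise from independent genus-level turnover alone. Per replicate, exactly
`round((1 − s)·N)` genera (half-up; s is the survival fraction, typically a
Lyellian percentage / 100) are drawn without replacement and marked extinct;
a family dies only if all its genera are drawn. The fixed draw count, rather
than per-genus Bernoulli trials, matches the sampling-without-replacement
design and makes small-fauna enumeration exact. Per replicate we record the
family-extinction count, the MPD/MNTD of the extinct family set, and any
named co-extinction events (all families of a set, e.g. an order, extinct
together). Replicates with fewer than two extinct families on the tree have
undefined MPD/MNTD; they keep their counts, are excluded from the distance
summaries, and their number is reported. The summary interval is
`mean ± 1.96·sd` of the replicate counts.

## The synthetic-data generator

`simulate_polar_dataset()` provides the study conditions all stochastic
tests run under:

* **Tree.** A birth–death tree conditioned on `n_families = 67` tips
  (`birth = 0.06`, `death = 0.03` per Myr — a net diversification slow
  enough to spread nodes across the Phanerozoic), rescaled so the root sits
  at 520 Ma and with internal edges shorter than 1% of the root age
  collapsed into polytomies, mirroring the soft polytomies of composite
  family-level supertrees.
* **Ages.** Each family's first appearance is drawn uniformly within its
  subtending edge's age interval (floored at 5 Ma), so calibration is
  self-consistent by construction: no negative edges, node ages bounded by
  the true nodes.
* **Faunas.** Two regions of 40 and 35 families sharing 27 (the `overlap`
  fraction scales with tree size); per-family genus richness is geometric
  (`genus_p = 0.4`, mean ≈ 2.5 genera, many one-genus families — the
  right-skew that drives cascade behaviour); species counts are shifted
  Poisson and shell dimensions lognormal (median length 20 mm), purely as
  plausible magnitudes for the comparison wrappers.
* **Extinction regimes.** `random` draws a fixed-size uniform subset;
  `brownian_threshold` evolves a Brownian trait on the calibrated tree and
  extinguishes the top-k tips. The Brownian generator is *the same code* as
  the D statistic's Brownian null, on purpose: the parameter-recovery test
  (D ≈ 0 under the clustered regime at zero noise, D ≈ 1 under the random
  regime, SES centred on 0 under random labelings) is then exact by
  construction at noise 0 and degrades gracefully as `noise_sd` grows.
  Default prevalences are 0.5 and 12/35 for the two regions.

What the generator does **not** emulate: stratigraphic preservation and
sampling (every simulated family in a bin is observed), taxonomic synonymy,
within-family phylogenetic structure, genus-level survival heterogeneity
within surviving families, and any correlation of body size or richness
with extinction risk. Passing tests therefore demonstrate that the
estimators recover known generating processes on clean data of realistic
shape — not that real faunal lists are free of the sampling biases the
surrounding literature deals with upstream.

## Numerical conventions and problem sizes

* Zero-length edges (age ties under the oldest-descendant rule) are legal
  everywhere; they contribute nothing to distances and zero variance to
  Brownian increments, and rank thresholding breaks the resulting trait
  ties randomly under the stage seed.
* All Monte-Carlo stages take explicit seeds and record them, and
  `run_all()` expands one master seed into fixed per-region, per-stage
  seeds, so whole reports reproduce byte-for-byte.
* Degenerate inputs (constant traits, all-extinct faunas, single-tip
  regional trees, uncalibrated trees) raise typed errors rather than
  returning NaN.
* Test problem sizes were chosen to make oracles exact: pair-enumeration
  MPD/MNTD on 10-tip trees, exhaustive subset nulls on ≤ 8 tips, exhaustive
  cascade draws on ≤ 12 genera, 200 64-tip datasets at 1,000 simulations
  for the D calibration, and 1,000 random labelings at 199 randomizations
  for the SES type-I check — sizes at which the uniform-p granularity
  (1/200) still resolves the 0.05 level cleanly.

## Limitations

The method inherits the resolution of its inputs: family-level presence
data cannot see species-level selectivity, and calibrated branch lengths
are minimum estimates because extinct lineages are absent from the tree.
The tip-shuffle null conditions on the regional pool; it does not model
range shifts or recolonization, so "extinction" here is strictly regional
absence in the later bin. And D's absolute value depends on the nodal
estimator convention, so cross-study comparisons of D should check that the
same estimator was used; its two anchor points (0 and 1) are
implementation-independent, which is what the calibration tests pin down.
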