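# polarphylo

**Phylogenetic selectivity of regional extinctions, from fossil-calibrated
family trees and regional faunal lists.**

Regional extinction can erase evolutionary history in two very different
ways: losses scattered at random across a phylogeny leave the shape of the
regional tree intact, while losses concentrated within clades prune away
whole limbs of it. `polarphylo` quantifies which of the two happened, given

* a family-level phylogeny (newick) whose internal nodes can be dated by the
  first-appearance ages of the families they subtend,
* tidy occurrence tables of `(region, time_bin, family, genus, ...)` records
  for an earlier (fossil) and a later (modern) time bin.

It was built for the classic polar-bivalve setting — early Cenozoic versus
Recent faunas of the Arctic and Antarctic shelves — but applies to any
two-bin regional comparison on a dated higher-taxon tree. Everything is
tibble-first and pipe-friendly; trees are `ape::phylo` objects.

## What it computes

Let `d(i, j)` be the patristic distance (Myr) between families *i* and *j*
on the calibrated tree, and *E* the set of families that went regionally
extinct.

* **Extinction clustering (MPD / MNTD SES).** The mean pairwise distance
  `MPD(E) = mean over pairs of d(i, j)` and mean nearest-taxon distance
  `MNTD(E) = mean over i of min d(i, j)` of the extinct set, compared with a
  null of uniformly random same-size tip sets of the regional tree
  (equivalent to tip-label shuffling). Reported as
  `SES = (observed − null mean) / null sd`; negative SES means the extinct
  families are more closely related than chance — phylogenetic clumping.
* **Phylogenetic signal (Fritz–Purvis D).** The sum of sister-clade
  differences of the binary extinct/survivor trait, scaled between its
  expectation under tip shuffles (D = 1, random) and under a
  Brownian-threshold trait (D = 0, clade-structured extinction).
* **Diversity retention.** Total branch length (Myr) and node count of the
  regional tree before and after the extinctions — a phylogenetic-diversity
  (PD) accounting of how much of the tree each fauna keeps.
* **Lyellian survivorship & the genus cascade.** Percent of genera
  surviving to the Recent with exact (Clopper–Pearson) binomial CIs, and a
  randomization that extinguishes genera at the Lyellian rate to ask whether
  independent genus-level turnover alone could produce the observed
  family-level extinction pattern.
* **Supporting comparisons.** Spearman richness correlations, paired
  Wilcoxon tests, Kolmogorov–Smirnov and chi-square wrappers over the same
  data model, plus the shell body-size metric `log2(sqrt(L * H))`.

A synthetic-data module (`simulate_polar_dataset()`) generates birth–death
family trees with fossil first-appearance ages and two-region faunas under
a random or phylogenetically clustered extinction regime, so the entire
pipeline can be exercised and validated without any external data.

## Worked example

```r
library(polarphylo)

ds  <- simulate_polar_dataset(sim_config(seed = 1))   # 67-family synthetic world
lab <- label_extinctions(ds$occurrences, "RegionA", "Paleocene-Eocene", "Modern")
sum(lab$extinct)                                      # 20 of 40 families lost

ses_phylo(lab, ds$calibrated, n_rand = 10000, seed = 1)
#> Phylogenetic extinction selectivity (tip-shuffle null)
#> Extinct families: 20 of 40; 10000 randomizations
#>   metric observed null_mean null_sd    ses  p_low
#> 1 mpd       195.      211.     8.69 -1.79  0.0519
#> 2 mntd       75.2      69.1   13.0   0.472 0.682

phylo_d(lab, regional_tree(ds$calibrated, lab$family), n_sims = 1000, seed = 1)
#> Fritz-Purvis D statistic
#>   d observed      : 5.8594  (20 of 40 tips in state 1)
#>   D               : -0.6240  (1 = random, 0 = Brownian clumping)
#>   p (vs random)   : 0.0010   p (vs Brownian): 0.9311   n_sims: 1000

retention(ds$calibrated, lab$family, lab$family[!lab$extinct], region = "RegionA")
#>   branch length: 1700.81 -> 655.71 Myr  (loss 61.4%)
#>   node count   : 76 -> 38        (loss 50.0%)

lyellian(27, 120)
#>   22.5% of genera survive, 95% CI (15.4, 31.0)
```

RegionA was simulated under the clustered (Brownian-threshold) regime, and
the analysis recovers that: the extinct families are closer together than
the shuffle null expects (negative SES for MPD, here `p ≈ 0.05`), D sits
near 0 rather than 1, and more than half of the regional tree's branch
length is lost — random losses at the same intensity would have left far
more. `run_all()` chains all stages (labeling, retention in both modes,
SES, D, Lyellian, cascade, cross-region comparisons) from one seeded
configuration, and each result type has `tidy()`, `glance()` and
`autoplot()` methods.

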