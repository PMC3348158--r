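# divtime

Diversification-timing analysis on dated phylogenies of regional species
assemblages.

## The problem

When did the species of a regional assemblage — say, the teleost fishes of
the Mediterranean Sea — accumulate? Given an ultrametric chronogram (node
ages in Myr, tips at 0) and a table assigning each species to a
biogeographic status (*endemic*, *non-endemic native*, *exotic*,
*outgroup*), one can prune the tree to one status class, record the age of
every split that survives pruning, and ask whether those species
diversified earlier or later than a random set of species of the same size
would suggest.

`divtime` implements that analysis as a reusable, tested pipeline:

* **Split-age extraction.** Pruning a chronogram to a tip set *S* keeps
  each surviving internal node at its original age, which equals the age of
  the MRCA (in the full tree) of its retained descendants. The events of a
  tree are the multiset of internal-node ages, a polytomy of *k* children
  counting as *k − 1* collapsed splits, so total event weight is always
  *n* − 1 for *n* tips.
* **Randomization test.** The observed statistic is the weighted median
  split age of the status class, *m*<sub>obs</sub>. The null draws the same
  number of tips at random, without replacement, from the full tree (1000
  draws by default) and recomputes the median each time. The verdict is
  two-tailed: *m*<sub>obs</sub> outside the central 95% of the null medians
  is significantly *young* or *old*. Sensitivity reruns repeat the whole
  test reading the lower or upper bound of each node-age credibility
  interval instead of the point age.
* **Taxonomic grafting.** Species without sequence data are attached as
  polytomies at the MRCA of two or more congeners, the parent of a single
  congener, or the MRCA of their family's or order's members — the first
  level that applies — with tip branch length equal to the attachment
  node's age. Cumulative levels yield a series of chronograms of
  increasing taxonomic coverage.
* **Lineage-through-time curves and event histograms** for each tree and
  status class.
* **Supermatrix utilities.** Gblocks-style block filtering (minimum block
  length 10 sites, at most 5 contiguous non-conserved positions, at most
  50% gaps per column) and partitioned concatenation of per-locus
  alignments with missing-data accounting.
* **Synthetic data.** A seeded forward birth–death simulator, clade-
  structured status labelling, synthetic node-age intervals and alignment
  fixtures, so the full pipeline is testable without any empirical data.

## Worked example

Simulate a 200-tip chronogram of height 160 Myr, concentrate the endemic
status in clades originating in the last 50 Myr, and test it:

```r
library(divtime)
x <- simulate_bd_chronogram(n_tips = 200, birth = 0.08, death = 0.03, seed = 1)
x <- rescale_chronogram(x, 160)
x <- synthesize_age_intervals(x, 0.25, seed = 2)
taxa <- assign_categories(x, "clade_enriched", target = "endemic",
                          window = c(0, 50), strength = 1, seed = 3)
taxon_counts(taxa)
#>  endemic   native   exotic outgroup
#>       24      136       40        0

group_timing_test(x, taxa, "endemic", reps = 1000, seed = 4)
#> Median split-age test for status "endemic" (n = 24)
#>   mean  observed      30 Myr  null [52.5, 92.6]  significant_young
#>   lower observed    22.6 Myr  null [46.7, 74.2]  significant_young
#>   upper observed    34.9 Myr  null [58.7, 105]  significant_young
```

The 24 endemics' median split age (30 Myr at the point estimates) falls
below the central 95% of medians from 1000 random draws of 24 species, so
the endemics diversified significantly more recently than chance predicts —
and the verdict is stable whether node ages are read at their point
estimates or at either credibility bound.

The whole analysis — events, medians, histograms, LTT curves, tests for
every status at every bound, optional grafting series — runs from one
config:

```r
report <- run_analysis(list(seed = 7, reps = 1000), out_dir = "results/")
```

writing `report.json`, per-status event/histogram TSVs, per-tree LTT TSVs
and grafted trees. The same config always produces a byte-identical
report.

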