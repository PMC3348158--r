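---
title: "Timing diversification in a regional assemblage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing diversification in a regional assemblage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divtime)
```

## The model

`divtime` asks a deliberately simple question of a dated phylogeny: did the
species of one biogeographic class accumulate earlier or later than a
random set of species of the same size? The unit of analysis is the
*split*: an internal node of the chronogram pruned to the class of
interest, dated by its node age. Because pruning preserves original node
ages (each surviving node is the MRCA, in the full tree, of its retained
descendants), the split ages of a tip set are a deterministic function of
the full chronogram — no re-estimation is involved.

The test statistic is the weighted median split age. The null model is
plain tip resampling: draw the same number of tips uniformly at random
without replacement from the resampling pool, extract that draw's split
ages, take their median, and repeat (1000 draws by default). The verdict
is two-tailed at level $\alpha = 0.05$: an observed median strictly below
the empirical $\alpha/2$ quantile of the null medians is *significantly
young*, strictly above the $1-\alpha/2$ quantile *significantly old*.

Two design points deserve emphasis:

* **This is not rate estimation.** No birth or death rates are fitted to
  the empirical tree; the randomization sidesteps the strong assumptions
  of diversification-rate models and asks only whether the class's timing
  is exchangeable with a random class of equal size.
* **The null is phylogenetically naive by construction.** Random tip sets
  inherit the tree-wide age structure; a class concentrated in young
  clades will have young within-clade splits where a random class of the
  same size mostly coalesces deep. That contrast is exactly the signal
  the test is designed to detect.

Sensitivity reruns repeat the entire procedure — observed statistic *and*
null — reading the lower or the upper bound of each node's age
credibility interval instead of the point age. A conclusion that holds at
all three bounds does not depend on the dating uncertainty encoded in
those intervals.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `reps` | 1000 | draws | Resolves the 2.5% tails to ±0.5% Monte-Carlo error. |
| `alpha` | 0.05 | — | Conventional two-tailed level. |
| `bin_width` | 20 | Myr | Histogram granularity; coarse enough that bins are well-populated for classes of a few dozen species. |
| `pool` | `mediterranean_only` | — | Outgroup tips exist to root and calibrate, not to describe the assemblage; they are excluded from the resampling pool by default. `all_tips` is available since the alternative reading is defensible. |
| `tolerance` | 1e-6 | relative | Ultrametricity check: tip-depth spread over tree height. Catches real errors while admitting decimal round-off in Newick files. |
| `relative_halfwidth` | 0.25 | relative | Synthetic credibility intervals; dated-node posteriors commonly span roughly ±20–30% of the point age. |

## Numerical and procedural choices

* **Weighted median.** Event ages are conceptually expanded by weight;
  with an even total the midpoint (mean of the two central values) is
  used, matching `stats::median` on the expanded vector.
* **Polytomies.** A node with $k$ children contributes weight $k-1$, the
  number of bifurcations it collapses. This keeps total event weight at
  $n-1$ tips invariantly, makes grafted (polytomous) trees commensurable
  with binary ones, and reduces to weight 1 on binary trees.
* **Quantiles and ties.** Null quantiles use the inclusive empirical-CDF
  definition (type 1); observed values tied with the quantile value count
  as inside the central region. The test is therefore conservative under
  heavy ties (empirical size slightly below $\alpha$; the calibration
  checks in the test suite bound this).
* **Histogram bins** are half-open $[kw, (k+1)w)$ anchored at 0; an event
  exactly at the top edge is counted in the last bin so mass is conserved.
* **Pruning** recomputes nothing: ages, and credibility bounds, of
  surviving nodes are copied bitwise from the input tree via an MRCA
  lookup. The randomization inner loop uses an equivalent $O(\text{edges})$
  subset scan that never builds the pruned tree; the equivalence of the
  two routes is property-tested.
* **Seeding.** Every stochastic operation takes one integer seed; the
  randomization spawns per-replicate sub-seeds from a counter, so results
  are independent of evaluation order, and the pipeline derives all its
  stage seeds from the single config seed. Identical configs produce
  byte-identical reports.
* **Serialization.** Age intervals ride on Newick as
  `[&age_interval={lower,upper}]` node comments — no standard encoding
  exists, so the package defines one and accepts plain Newick without
  intervals; foreign comments and support labels are parsed and ignored.
  Branch lengths are written with the shortest decimal representation
  that round-trips the double, so write–parse is an identity.

## Grafting

Species lacking sequence data are placed at the first applicable level of
a four-step ladder: MRCA of $\ge 2$ congeners; parent node of a single
congener (the node joining it to its closest relative); MRCA of all
backbone members of the family; MRCA of all backbone members of the
order. The grafted tip's branch length equals the attachment node's age,
so the tree stays ultrametric and every backbone node age and
relationship is untouched — pruning the grafted tree back to the backbone
tips reproduces the backbone exactly, which the test suite asserts.

Two readings of the stepwise procedure are possible, and both are
provided. By default, attachment nodes are computed on the original
backbone only, which makes placement independent of request order. With
`sequential = TRUE`, each grafted species immediately joins the working
tree and can recruit later requests (as a congener, family or order
member), mimicking a manual curation pass; the outcome then depends on
request order, which is why it is not the default. Species no level can
place are reported as `unplaced` rather than raising: incomplete coverage
is an expected outcome, not an error.

`chronogram_series()` applies the cumulative prefixes of the ladder,
giving four trees of non-decreasing coverage whose lineage-through-time
curves can be compared to the backbone's to check that conclusions are
robust to sampling.

## What the synthetic data emulate — and what they do not

The generator exists so that every stage has a realistic, fully seeded
input of known structure.

* `simulate_bd_chronogram()` runs a forward birth–death process from a
  crown pair, with either a tip-count or a duration stopping rule, prunes
  extinct lineages, and retries on total extinction. Under tip-count
  stopping the present is placed just before the first post-target event,
  so terminal branches are positive. Piecewise rate epochs are tied to
  absolute ages and therefore require the duration rule (under tip-count
  stopping the final height is unknown in advance). Defaults
  (birth 0.08, death 0.03 per lineage per Myr, 200 tips, rescaled to
  160 Myr) give trees whose size and depth match a few-hundred-species
  marine assemblage whose deepest splits approach 160 Mya. The simulator
  is checked against the Yule expectation (per-lineage event rate) by
  Monte Carlo.
* `assign_categories()` produces either exchangeable labels (the
  calibration condition: any test should reject at rate $\alpha$) or a
  *clade-enriched* labelling that concentrates a target status in clades
  originating inside an age window — the age-structured signal the test
  is meant to detect. Candidate clades are the maximal clades whose root
  age lies in the window; they are selected in random order until they
  cover roughly the target status's overall proportion of tips (always at
  least one clade), tips inside them take the target status with
  probability `strength`, and all other tips draw from the remaining
  proportions with the target's mass removed. Removing the target's mass
  elsewhere is a deliberate choice: it makes the label pattern the pure
  clade signal, so power runs measure detection of clade structure and
  nothing else.
* The synthesized genus/family/order hierarchy is built by nested clade
  cuts with geometric size targets (genera of ~2 tips within families of
  ~5 genera within orders of ~5 families). Only containment and monophyly
  matter — they make MRCA grafting exercisable — no claim about real
  taxonomic practice is intended.
* Alignment fixtures are uniform random nucleotides with whole
  taxon-by-locus blocks replaced by `?`: the dominant missingness mode of
  multi-locus supermatrices (a taxon simply unsequenced for a locus).
  There is no substitution model, no rate variation, no alignment error.

Consequently, passing tests show that the *procedures* behave as
specified under controlled conditions; they do not validate any empirical
dating, nor show that real label/clade associations look like the
enrichment model.

## Block filtering and concatenation

The alignment filter applies three rules in order: drop maximal runs of
more than 5 contiguous non-conserved columns (columns with more than 50%
gaps are excluded outright and count as non-conserved); trim each
remaining segment to begin and end on a highly conserved column; drop
segments shorter than 10 sites. Conservation is judged by the modal
non-gap residue's frequency over all sequences — strictly above 0.5 is
conserved, strictly above 0.85 highly conserved; gaps never count toward
the mode. These thresholds are the canonical defaults of
conservation-based filtering; the three block parameters are exposed
alongside them in `block_filter_params()`. The filter is defined by these
rules and their property tests — bit-identity with any particular legacy
implementation (which applies additional iterative flank heuristics) is
not claimed.

Concatenation takes the sorted union of taxa, pads absent taxon-by-locus
blocks with `?`, and records a 0-based half-open partition map internally;
the partition file is written 1-based inclusive in the RAxML convention
for interoperability.

## Problem sizes used by the automated checks

The test suite and `scripts/acceptance.R` use sizes chosen to make
Monte-Carlo error small relative to the assertion bands while keeping a
laptop run comfortable: 100 random trees of up to 30 tips for the pruning
oracle (exact equality against all-pairs MRCA ages); 200 simulated
200-tip trees with 200-draw nulls for the type-I calibration (binomial
95% band around 0.05); 100 enrichment runs for power; 10,000 draws for
the exhaustively enumerable 3-tip null (true masses 1/3 and 2/3); 500
pure-birth replicates for the Yule rate check.

## Known limitations

* The null resamples tips independently of phylogeny; it answers "is this
  class's timing exchangeable with a random class?", not "which process
  generated it". Clade-autocorrelated sampling artefacts (e.g. one large
  young genus) will register as signal, which may or may not be the
  question of interest.
* Grafting pins species at MRCA nodes exactly; it adds no branch-length
  uncertainty and cannot discover placements finer than the taxonomy.
  Grafted-tree event sets are therefore biased toward the attachment
  node ages at high grafting fractions.
* Credibility-bound reruns treat each node's bound as if all nodes moved
  together; they bracket, but do not integrate over, dating uncertainty.
* The epoch-rate simulator conditions on survival by retry, which
  slightly enriches fast-diversifying histories at high extinction
  fractions; it is a data generator, not an inference tool.
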