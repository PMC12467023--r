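---
title: "Methods: classifying and counting turnover of sex-biased expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and counting turnover of sex-biased expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbgturnover)
```

## The problem

A sex-biased gene (SBG) is expressed at different levels in males and
females of the same species. Across insects, the *direction* of that bias
is evolutionarily labile: an orthologous gene can be female-biased in most
lineages yet male-biased in one, a reversal we call **turnover**. This
package implements the comparative workflow for quantifying that
phenomenon across a panel of species spanning several insect orders:

1. call a per-gene bias direction from sexed FPKM pairs;
2. aggregate calls to an order-level consensus per orthologous gene
   family;
3. classify single-copy families as consistently or non-consistently
   biased and attribute each reversal to a deviating species;
4. screen gene trees for lineage-specific branch-length acceleration in
   the reversal families.

The default panel is 13 species in four orders (one hemipteran, one
coleopteran, two lepidopterans, nine dipterans; see
`default_species_meta()`). The heavy imbalance toward Diptera is
deliberate: it is the sampling regime this kind of database-derived
comparative study actually faces, and it drives the consensus edge cases
the tests exercise.

## Bias calling

For a male/female FPKM pair $(m, f)$ the call is

* `unbiased` with `passed_floor = FALSE` if $\max(m, f) <$
  `min_fpkm_floor` (default 1 FPKM): genes essentially silent in both
  sexes carry no usable signal;
* `male` if $(m + \varepsilon)/(f + \varepsilon) \ge$ `fold_threshold`
  and $m > f$; `female` symmetrically; otherwise `unbiased`.

The pseudocount $\varepsilon = 0.01$ FPKM keeps ratios finite at zero
expression without ever flipping a direction at the default threshold.
The default `fold_threshold` is 1 — a pure sign rule above the floor.
That choice is forced by the data this pipeline consumes: upstream
sex-bias databases label genes with ratios as mild as 104.6 vs 123.0
(ratio 1.18) as biased, so any cutoff above 1.18 would contradict the
labels the analysis is meant to reproduce. The exact criterion those
databases used is not published; the sign-with-floor rule is a stand-in,
kept configurable, not a reconstruction.

When a gene has rows from several tissues, one row is selected by a
configurable priority list (whole body > gonad > carcass > head, then
other tissues alphabetically). Mixed-tissue input is a fact of the
upstream databases; a priority list makes the choice explicit and
deterministic.

## Order consensus and family classification

Within a family, each species is first reduced to one direction (its
genes' majority; single-copy families reduce to the single gene's call).
Each order then gets a consensus direction under one of two rules:

* **majority** (default): strict plurality of male vs female calls;
  unbiased calls are counted but never win; a male–female tie is
  `unbiased`; no calling species at all is `no_data`.
* **unanimity**: every calling species must agree, else `unbiased`.

Both rules are implemented because the aggregation rule behind published
order-level statements is typically unstated; majority is the default
because it is the weaker assumption and behaves sensibly for the
nine-species dipteran clade. With one species per order — the situation
for every non-dipteran order in the default panel — the rules coincide.

A single-copy family's order-direction pattern is then classified:

| pattern over the four orders | label |
|---|---|
| all male | `consistent_male` |
| all female | `consistent_female` |
| three male, one female | `non_consistent_male` |
| three female, one male | `non_consistent_female` |
| any order `unbiased` or `no_data` | `unclassified` |
| anything else (e.g. 2–2) | `mixed` |

Only fully-called families enter the four named classes; `unclassified`
and `mixed` hold the remainder explicitly rather than silently absorbing
it into either non-consistent class. This makes the bookkeeping
`total − consistent = everything else` exact and auditable, while leaving
visible how many families fall outside the published four-class taxonomy.

**Single-copy selection.** A family qualifies when every present species
has exactly one gene and the family covers at least one species in each
of the (default four) orders. An alternative presence criterion — at
least *k* species regardless of order — is exposed for tree-building
family sets, where taxon count matters more than order coverage.

## Turnover attribution

For the `female_biased` context, reversals are the
`non_consistent_female` families; the deviating species are those in the
deviating order whose own call matches that order's (male) direction.
Attribution is

* **strict** (default): only families with exactly one deviating species
  count, contributing 1 to that species; others are listed in a
  remainder report. Strict is the default because published per-species
  reversal counts sum exactly to the family total, which implies
  one-species attribution.
* **lenient**: every deviating species of every such family gets 1; kept
  for sensitivity analysis. Lenient totals are never smaller than strict.

Shares are `100 · count/total` rounded half away from zero to one
decimal; the excess of one class over the other is
`100 · (a − b)/b` rounded to the nearest integer. Half-away-from-zero
matches how such percentages are conventionally printed.

## The synthetic-data generator

Every downstream stage is tested against data with known ground truth,
generated by `simulate_dataset()` / `write_dataset()`:

* **Bias states** evolve on the species tree under a symmetric two-state
  (male ↔ female) Markov chain: over a branch of length $t$ the state
  flips with probability $(1 - e^{-2\mu t})/2$. There is no latent
  "unbiased" state — an unbiased observation arises only from the calling
  threshold. This is the minimal model that generates reversals; the real
  process may well be asymmetric (female→male reversals appear more
  common empirically), and an asymmetric-rate extension is left as
  future configuration.
* **Expression**: each sex's FPKM is an independent lognormal draw,
  $2^{\mathcal{N}(b, \sigma)}$ around baseline $b$ (default
  $\log_2 10$), with the biased sex's log2 mean shifted up by
  $\log_2(\text{fold})$ (default fold 4). Independence per sex is what
  lets noise flip calls: a call flips when a
  $\mathcal{N}(\log_2 \text{fold}, \sigma\sqrt{2})$ variate goes
  negative, so $\sigma \approx 1.1$ flips about 10% of calls at fold 4 —
  the regime used for the degradation tests.
* **Occupancy**: presence of each species in each family is
  Bernoulli(0.7 by default); present species carry a second copy with
  probability 0.05; empty families are redrawn.
* **Alignments** evolve site-independently under Jukes–Cantor from a
  uniform root, with an optional acceleration factor multiplying one
  focal terminal branch — the planted signal for the acceleration
  screen.

Default sizes (500 families, 1000 sites) keep a full simulated run in
seconds while leaving Monte-Carlo error well below the effects being
tested; the closed-form checks use 10,000 replicates/sites where the
analytic comparison needs them.

What the generator does **not** emulate: biological replicates and their
variance structure, tissue-dependent expression, gene duplication/loss
histories reconciled with the species tree, rate heterogeneity across
sites or lineages (other than the single planted acceleration), and any
correlation between expression bias and sequence evolution. Passing
recovery tests therefore show the pipeline's logic is correct under its
own assumptions, not that those assumptions hold for any real dataset.

## Tree machinery

The desk-scale tree path is distance-based: Jukes–Cantor distances
$d = -\tfrac34 \ln(1 - \tfrac43 p)$ from mismatch fractions, neighbor
joining, and Robinson–Foulds (RF) comparison on unrooted nontrivial
bipartitions. Distance NJ replaces likelihood inference deliberately: on
simulated JC data the quantity under test is topology/branch-length
recovery, for which NJ on near-additive matrices is sufficient and
exact in the additive limit; externally inferred Newick trees (e.g. from
a likelihood tool) drop into the same report path unchanged. Gene-tree
leaves are relabeled to species ids via the family membership before RF
comparison; families whose gene→species map is not a bijection are
skipped with a logged reason.

**Acceleration screen.** "Substantially longer terminal branch" is
operationalized as: ratio of the leaf's terminal length to the median of
the other terminal lengths (threshold 3), plus a robust z-score on log
lengths, $(\log \ell - \mathrm{median}) / (1.4826 \cdot \mathrm{MAD})$
(threshold 2), combined with AND by default. Two statistics are used
because neither alone is robust: the ratio ignores the spread of the
background, the z-score explodes when the background MAD is tiny. When
the MAD is zero the z criterion is undefined and the ratio decides
alone. Thresholds are configuration, not biology; the defaults give
>90% power against a 5× planted acceleration with <10% false flags at
8 taxa and 5000 sites in the packaged simulation test.

## Numerical and degenerate-input conventions

* JC saturation ($p \ge 0.75$): hard error by default, or a configurable
  cap (`on_saturation = "cap"`), since one saturated pair should not
  silently poison a distance matrix.
* NJ negative branch estimates are clamped to zero with the deficit
  moved to a sibling branch, preserving path lengths through the join;
  taxa are pre-sorted lexicographically so the result is independent of
  input row order.
* Newick: unquoted labels, decimal lengths, no comment/NHX support;
  missing branch lengths read as 0; malformed input fails with a
  character offset. RF is computed on unrooted topologies, so rooting
  differences between compared trees cannot manufacture discordance.
* All randomness flows through R's RNG seeded once per dataset; draw
  order is documented in each simulator function, so a config plus seed
  is a complete reproducibility artifact. Reports contain no timestamps
  and use fixed numeric formatting, so reruns are byte-identical.

## Known limitations

* The bias caller reconstructs an unpublished upstream criterion; the
  default sign-with-floor rule is the weakest rule consistent with the
  published example calls, not a validated reconstruction.
* Order consensus under heavy sampling imbalance effectively lets the
  nine dipterans vote while three orders are single-species delegates;
  `unanimity` is provided to probe that sensitivity.
* The acceleration screen is a descriptive outlier test, not a formal
  rate test (no relative-rate framework, no dN/dS); it is a screen for
  candidates, not evidence of selection.
* Genome-scale headline counts from real databases depend on the
  upstream corpus and clustering run and are outside what synthetic data
  can or should reproduce; the packaged benchmark reproduces the
  *published reversal table* and its derived percentages, which are
  functions of the pipeline logic alone.
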