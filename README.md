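# sbgturnover

Turnover of sex-biased gene expression across insect gene families.

## What this is for

Sex-biased genes (SBGs) — genes expressed at different levels in males
and females — frequently change the *direction* of their bias between
lineages: an ortholog female-biased in most species can be male-biased
in one. `sbgturnover` is for comparative genomicists quantifying that
phenomenon across a multi-order insect panel from three inputs: an
OrthoFinder-style orthogroup table, a per-gene sexed expression table
(male/female FPKM), and species metadata (order, sex-determination
system).

The core objects and statistics:

* **Bias call** per gene: `male` if $(m+\varepsilon)/(f+\varepsilon)\ge$
  threshold and $m > f$ (symmetrically `female`), `unbiased` otherwise
  or below an expression floor.
* **Order consensus** per family: majority (or unanimity) of the
  per-species directions within each insect order.
* **Family classification** over the four orders: `consistent_male` /
  `consistent_female` (same direction everywhere),
  `non_consistent_male` / `non_consistent_female` (three orders one way,
  one reversed), `mixed`, `unclassified`.
* **Turnover table**: each non-consistent family's reversal attributed
  to its deviating species; per-species counts, shares
  ($100\,c_s/\sum c$), and the excess of one reversal class over the
  other ($100\,(a-b)/b$).
* **Tree screens**: Jukes–Cantor distances
  ($d=-\tfrac34\ln(1-\tfrac43 p)$), neighbor-joining gene trees,
  Robinson–Foulds congruence with the species tree, and a
  terminal-branch acceleration screen (ratio-to-median ≥ 3 AND robust
  log-scale z ≥ 2).

A ground-truth-labeled synthetic generator (binary bias states evolving
on the species tree under a symmetric two-state Markov chain, lognormal
FPKM, Jukes–Cantor alignments with an optionally accelerated focal
branch) makes every stage testable without database downloads. See
`vignettes/sbg-turnover-methods.Rmd` for the models and the reasoning
behind each default.

## Worked example

The package ships the published FPKM table of a proteasome-activator
orthogroup in which six species are female-biased but the red flour
beetle is male-biased:

```r
library(sbgturnover)
expr  <- read_expression(sbg_example("og0001228_expression.tsv"))
calls <- call_bias_table(expr)
calls
#>           gene_id species_id     tissue direction fold_change passed_floor
#> 1      AALB006416       Aalb    carcass    female       1.175         TRUE
#> 2 AgaP_AGAP000308       Agam    carcass    female       3.047         TRUE
#> 3      Aste1435_g       Aste whole body    female       2.672         TRUE
#> 4   KWMTBOMO04424       Bmor       head    female       3.583         TRUE
#> 5    LOC100169004       Apis whole body    female       3.276         TRUE
#> 6      LOC4815668       Dpse whole body    female       3.898         TRUE
#> 7       LOC663373       Tcas      gonad      male      40.399         TRUE
```

Each row is one gene's call: the direction, the pseudocounted
fold-change between the sexes, and whether it cleared the 1-FPKM floor.
Aggregating to orders and classifying:

```r
meta <- default_species_meta()
og   <- list(list(og_id = "OG0001228",
                  membership = setNames(as.list(expr$gene_id),
                                        expr$species_id)))
cons <- build_consensus_table(og, calls, meta)
classify_families(cons, calls, og, meta)
#>       og_id                 label deviating_order deviating_species n_deviating
#> 1 OG0001228 non_consistent_female      Coleoptera              Tcas           1
```

The family is female-biased in three orders and male-biased in one —
a `non_consistent_female` family whose reversal is attributed to the
beetle, the pattern the turnover statistics count genome-wide.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and the packaged benchmark, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # labeled synthetic dataset
Rscript analysis/02_classify.R          # full pipeline + truth comparison
Rscript analysis/03_turnover_benchmark.R  # 44-family reversal benchmark
Rscript analysis/04_tree_screens.R      # NJ/RF + acceleration screen
```

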