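# ghostshift

Quantify how **ghost lineages** — extinct or unsampled lineages missing from
a species tree — distort the inferred *relative order* of horizontal gene
transfers into the stem lineage of eukaryotes.

## The problem

Timelines of eukaryogenesis are often reconstructed by dating gene
transfers from bacterial donors into the lineage running from FECA (the
divergence of eukaryotes from their closest sampled archaeal relatives,
the Asgard archaea) to LECA (the last eukaryotic common ancestor). When
the true donor is a ghost, the only measurable proxy for the transfer age
is the age at which the ghost diverged from its closest *sampled* sister —
which is always older than the transfer itself. For a **pair** of
transfers, the inferred early/late ordering can then be reversed relative
to the true ordering: a **conclusion shift**.

`ghostshift` measures how often this happens, by Monte Carlo simulation on
a dated (ultrametric, time-calibrated) species tree:

1. Place the acceptor window: `leca_age = age(MRCA(eukaryote tips))`,
   `feca_age = age(MRCA(eukaryote ∪ Asgard tips))`.
2. Build the **FECA–LECA branch space**: every bacterial branch
   `[death, birth]` that coexisted with the open window, i.e.
   `birth > leca` and `death < feca`.
3. For each pair member, pick a sister branch uniformly (with replacement)
   and draw the ghost birth `g ~ U(max(death, leca), birth]` and transfer
   age `τ ~ U(leca, min(g, feca))` — the transfer lies inside the window
   and cannot predate the ghost's origin.
4. A pair is **shifted** when the ordering by `τ` (true) and by the
   observed age (`g` for a ghost donor, `τ` for a sampled one) are
   strictly reversed. Shifted pairs with an observed age older than FECA
   would be discarded as artifactual in practice; the remainder are the
   truly **confounding** pairs:
   `confounding = shift × (1 − P(outside FECA | shift))`.

The package also stratifies shift risk by donor clade pair, sweeps the
Bernoulli proportion of ghost donors from 0 to 1, simulates dated
birth–death fixture trees, and ships an independent brute-force oracle
used to validate the simulator.

## Worked example

A fully synthetic, labelled dated tree of life (bacteria + Asgard +
eukaryotes + a prunable organellar clade, FECA–LECA at 2.42–1.89 Ga)
is generated by the package itself, so the example needs no downloads:

```r
library(ghostshift)

fx     <- simulate_study_tree(seed = 7)
tree   <- prune_tips(fx$tree, fx$prune)                 # drop organelles
window <- locate_window(tree, fx$euk_tips, fx$sister_tips)
space  <- build_branch_space(branch_records(tree, fx$clades), window)
space
#> FECA-LECA branch space: 12 eligible donor branches
#> Acceptor window: FECA 2.42 -> LECA 1.89 (span 0.53 time units)
#> Clades: Phylum01 (9), Phylum02 (3)

ex <- run_experiment(space, n_rounds = 200, n_pairs = 1000, seed = 42)
summary(ex)
#> Ghost-transfer shift experiment: 200 rounds x 1000 pairs (seed 42)
#>   shift proportion:        0.1749
#>   outside FECA | shift:    0.1458
#>   confounding proportion:  0.1494
#>
#> Across-round quantiles:
#>                          2.5%    25%    50%    75%  97.5%
#> shift_proportion       0.1530 0.1670 0.1740 0.1830 0.1960
#> outside_given_shift    0.0982 0.1237 0.1436 0.1669 0.1943
#> confounding_proportion 0.1299 0.1410 0.1485 0.1562 0.1730
```

Read: with every donor a ghost (the worst case), about 17.5% of transfer
pairs on this tree would be ordered incorrectly; about 15% of those
reversals produce an inferred age older than FECA and would be discarded,
leaving ~14.9% of pairs truly confounding.

Sensitivity to the actual proportion of ghost donors:

```r
sw <- ghost_fraction_sweep(space, c(0, 0.25, 0.5, 0.75, 1),
                           n_pairs = 50000, seed = 42)
sw$sweep
#>      p n_pairs shift_prop
#>   0.00   50000    0.00000
#>   0.25   50000    0.07732
#>   0.50   50000    0.13144
#>   0.75   50000    0.16356
#>   1.00   50000    0.17578
```

With no ghosts there are no shifts, by construction; the shift proportion
rises with the ghost fraction and saturates towards the all-ghost value.

### Command line

```sh
Rscript inst/exec/ghostshift.R fixture  --out-dir demo --seed 7
Rscript inst/exec/ghostshift.R simulate --tree demo/tree.nwk \
    --euk-tips demo/euk_tips.txt --sister-tips demo/sister_tips.txt \
    --domain-tips demo/domain_tips.txt --prune demo/prune_tips.txt \
    --clade-map demo/clades.tsv --seed 42 --out-dir demo/results
```

(After installation the script is at
`system.file("exec", "ghostshift.R", package = "ghostshift")`.)
Subcommands `sweep` and `matrix` write the ghost-proportion grid and the
long-format clade-pair shift matrix; exit codes are 0 (ok), 2 (input
error), 3 (empty branch space). To analyse an empirical dated tree of
life, supply your own Newick file plus tip-set and clade-map files in the
same formats.

## Documentation

The methods vignette (`vignettes/ghost-lineage-shifts.Rmd`) describes the
sampling model, its assumptions, the analytic 1/4 reference case, what the
synthetic generator does and does not emulate, and the package's numerical
conventions.
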