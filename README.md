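# ervsegmap

Detection and population analysis of **segregating endogenous retrovirus
(ERV) insertions** from pooled mate-pair re-sequencing, for researchers
studying transposable-element variation across related populations or
selection lines.

The package implements the full analysis chain for three pooled chicken
lines (high-growth **H**, low-growth **L**, white-leghorn outgroup **W**,
11 individuals per pool, 5.53× / 5.19× / 3.37× coverage):

1. **Junction calling** — reads hitting an independent ERV reference
   library (scores ≥ 425 on the 400–493 scale), uniquely anchored to
   chromosomes by their mates, are clustered into upstream/downstream
   ERV–host junctions (3,500 nt insert window, ≥ 2% union read footprint)
   and paired into candidate insertion loci (< 20 kb span, shared
   orientation and ERV targets); relaxed reads (≥ 400) are then appended.
2. **Differential presence testing** — per locus, the 2 × 3 table of
   supporting reads $k_l$ vs remaining line-wide ERV-host pairs
   $N_l - k_l$ is tested with the Freeman–Halton exact test when
   $\min_l k_l < 15$ and the Pearson chi-square (df = 2) otherwise;
   Bonferroni control at $\alpha/m$ (m = all candidate loci; 12,709 loci
   give $3.93\times10^{-6} \approx 4\times10^{-6}$). Loci get presence
   patterns (`H--` … `HLW`) and are polarized into gains/losses on the
   ((H,L),W) tree with the reference assembly as outgroup.
3. **Landscape annotation** — locus–gene relations within 150 kb (10 kb
   bins, sense/antisense orientation, intragenic antisense-bias binomial
   test) and selective-sweep overlap against a binomial expectation.
4. **Phylogeny association** — each locus is assigned to its best-matching
   reference ERV by summed read scores; a provided reference-ERV tree is
   annotated with per-line difference symbols and clade dispersion is
   summarized.
5. **Synthetic data** — a seeded generator of pooled mate-pair alignment
   records with known ground truth (segregating insertions, solo-LTR
   dominated forms, per-line allele frequencies, coverage imbalance), so
   the whole pipeline is testable end-to-end without any external data.

See `vignettes/ervsegmap-methods.Rmd` for the model, thresholds and design
decisions.

## Worked example

The `analysis/` directory holds the staged workflow (each script writes
under `results/` and prints what it found):

```sh
Rscript analysis/01_simulate.R   # synthetic pooled study, 300 insertions
Rscript analysis/02_cluster.R    # junctions -> candidate loci
Rscript analysis/03_difftest.R   # per-locus tests, patterns, polarity
Rscript analysis/04_landscape.R  # genes, orientation, sweeps
Rscript analysis/05_phylo.R      # best-ERV assignment, tree annotation
Rscript analysis/06_report.R     # single-call run + published-table totals
```

Stage 2 and 3 print, for the default seed:

```
strict pairs (>=425):      2967
junction clusters:         537 (261 up, 276 down)
candidate ERV loci:        247
...
loci tested: 247; Bonferroni threshold 0.000202 (reported 2e-04)
test dispatch: 247 exact, 0 chi-square
corrected-significant loci: 7
differential candidates: 173 of 247 (70%)
```

i.e. 300 planted insertions yield 247 recovered candidate loci (low-dosage
insertions drop below the footprint threshold, as intended for pooled
data); 173 show a nominal line difference and 7 survive Bonferroni
correction at this desk scale. The same run in one call:

```r
library(ervsegmap)
run <- run_pipeline(sim_config(seed = 20260920L, n_chromosomes = 4,
                               chromosome_length = 3e6, n_insertions = 300,
                               emit_sequences = TRUE),
                    outdir = "results/run")
run$summary$table          # per-pattern candidate/corrected/gene counts
run$sweep_test             # sweep overlap binomial test
run$tree_annotation$tips   # annotated reference-ERV tips
```

Stage 6 also reproduces the published study's headline totals from the
printed per-pattern table shipped with the package
(`published_locus_table()`), through the same summary arithmetic used for
synthetic runs:

```
candidate ERV loci:           12709
with a nominal difference:     8340 (66%)
Bonferroni threshold:        3.93e-06 (reported 4e-06)
corrected-significant loci:     369
ERVs adjacent to genes:         115
genes adjacent to ERVs:         229
```

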