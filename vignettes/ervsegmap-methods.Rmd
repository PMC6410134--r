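---
title: "Mapping segregating ERV insertions from pooled mate-pair data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping segregating ERV insertions from pooled mate-pair data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervsegmap)
```

## The problem

Endogenous retroviruses (ERVs) are retroviral proviruses fixed into the host
germline. Most loci in a genome are old and shared, but insertions still
segregate within populations: different individuals — and different closed
breeding lines derived from a common founder population — carry different
subsets. `ervsegmap` implements an analysis for detecting such segregating
ERV insertions from pooled mate-pair re-sequencing of three related chicken
lines (a high-growth line H, a low-growth line L, and a white-leghorn
outgroup W), without requiring the insertion to be present in the reference
assembly.

The detection principle: reads are mapped against an independent library of
reference-assembly ERV consensus sequences; a read that hits the library,
whose mate maps uniquely to chromosomal flanking DNA, marks an ERV–host DNA
junction near the mate's anchor. Because a mate-pair insert (~3,500 nt) far
exceeds the read length (50 nt), anchors accumulate within an insert-sized
window on each side of an integration.

## Junction calling

The junction module proceeds in four steps, each with an explicit threshold:

1. **Strict pair selection** (`select_strict_pairs`). ERV-side score ≥ 425 on
   the mapper's 400–493 score scale, plus a top-quality unique anchor for
   the mate. The anchor strand encodes the junction side: a `+` anchor reads
   toward the insertion from the 5′ flank (upstream), a `-` anchor from the
   3′ flank (downstream). The ERV-side read orientation equals the insertion
   orientation. This strand/side convention is the package's own (the four
   combinations are tabulated in the `select_strict_pairs` help); it matches
   the simulator's emission geometry and any real pipeline can remap its
   flags onto it.
2. **Clustering** (`cluster_junctions`). Single-linkage chaining of anchors
   per chromosome × side × orientation, where neighbouring anchor reads at
   a gap ≤ 3,500 nt (the insert size, hence the maximum flanking distance)
   join a cluster, and a greedy left-to-right cap keeps every cluster
   interval ≤ 3,500 nt. Sorting first makes the result independent of input
   order; on sorted equal-length reads the chain rule is exactly the
   transitive closure of the pairwise gap rule (tested against a brute-force
   union-find oracle). Clusters must have a union read footprint of at least
   2% of the window (70 bases), i.e. two reads overlapping by ≤ 30 nt
   suffice, a single 50-nt read never does. The 2% rule is applied per
   junction cluster, not per locus.
3. **Pairing** (`pair_junctions`). An upstream and a downstream cluster form
   a candidate locus when they share chromosome, inferred orientation, and
   at least one target ERV id, and their outer bounds span < 20 kb —
   room for a 7–11 kb provirus plus secondary insertions. Separation is
   measured between outer bounds. Matching is greedy nearest-first with
   deterministic tie-breaks (smaller span, then leftmost, then
   lexicographically smaller shared ERV id); each cluster joins at most one
   locus. The requirement of evidence for both the 5′ and the 3′ ERV flank
   is realized structurally — a locus needs one cluster on each side — since
   the alignment-record dialect does not carry within-ERV hit coordinates.
   Unpaired clusters are reported as half-supported records and excluded
   from testing: solo-LTR loci can be short, so only the 20 kb ceiling is
   enforced, with no floor on the span.
4. **Relaxed appending** (`append_relaxed_reads`). Reads scoring in
   [400, 425) whose anchors start inside an existing cluster interval, with
   matching side, orientation and consensus ERV, increment the relaxed
   counts. They never create loci and never change strict counts.

`tune_to_target` reproduces the threshold-tuning step: the strict score
cutoff is swept over the observed range and the value whose locus count is
closest to a target (~10,000 = 20 × the ~500 full-length library ERVs,
using the ~1:20 full-ERV:total ratio dominated by solo-LTRs) is chosen,
ties going to the more conservative threshold.

## Differential presence testing

For each locus the per-line supporting read counts are laid against the
line-wide totals of ERV-host read pairs in a 2 × 3 contingency table

$$\begin{pmatrix} k_H & k_L & k_W \\ N_H - k_H & N_L - k_L & N_W - k_W \end{pmatrix}$$

and tested for line differences. Conditioning on the line totals absorbs
the per-line coverage imbalance (5.53× / 5.19× / 3.37×). The table layout is
this package's interpretation of "read-mapping differences"; a
`mode = "normalized"` variant instead rescales counts to a common total
before testing, since whether counts were normalized up front is not
derivable from the study description — both modes are provided and the raw
(conditional) mode is the default.

When the minimum locus count is below 15 the **Freeman–Halton exact test**
is used: full enumeration of 2 × 3 tables with the observed margins under
multivariate hypergeometric weights, summing the probability of tables no
more probable than the observed one. The enumeration is authored here
(vectorized over the two free cells) and is cross-checked in the test suite
against both an independent enumeration oracle and `stats::fisher.test`, to
1e-9 on small tables. At or above 15, the Pearson chi-square statistic
(df = 2, expected counts proportional to line totals, upper tail) is used —
"comparison to the Chi distribution" is read as the standard Pearson test
for three groups. The boundary is asserted on both sides in the tests.
All-zero loci get p = 1 by convention. Tests are two-sided (probability
ordering for the exact test); sidedness is not otherwise specified by the
method description.

Significance uses Bonferroni control: threshold α/m with α = 0.05 and m =
the number of candidate loci tested — all of them, not only those with a
nominal difference (12,709 gives 3.93 × 10⁻⁶ ≈ the conventionally reported
4 × 10⁻⁶; using the 8,340 subset would give 6 × 10⁻⁶, which does not match
the reported threshold).

**Presence patterns.** Each line is called present or absent per locus; the
seven non-empty patterns are written `H--`, `-L-`, `--W`, `HL-`, `H-W`,
`-LW`, `HLW` (a letter marks presence; the all-present `HLW` class is
excluded from differential claims). "Near-absence" is quantified as: absent
when the count does not exceed `max(1, floor(0.02 × expected))`, where
`expected` is the locus total apportioned by line totals — stray reads
proportional to depth do not rescue a missing locus. The 2% tolerance is a
package choice (no number is stated in the study) and is exposed as
`absent_frac`.

**Polarization.** On the line tree ((H,L),W) with the reference assembly as
outgroup, a locus present in the reference is ancestrally present, so
absences are losses; a non-reference locus is ancestrally absent, so
presences are gains (with subsequent losses allowed, and at most
one-per-branch events). Patterns explained by a single event get that
branch; patterns needing ≥ 2 events (`H-W`/`-LW` as gains; `H--`/`-L-` as
losses) are flagged ambiguous and every minimal resolution is listed rather
than forcing one assignment — how the original figure resolved these is not
derivable from the text. The lookup table is verified in the tests against
an exhaustive enumeration of event placements on the tree.

## Landscape annotation

`intersect_genes` emits every locus–gene pair within 150 kb. Distance is
measured between nearest interval edges (inclusive at exactly 150,000), a
deliberate choice where the source mixes TSS-anchored and interval language;
a TSS-anchored mode sits behind `tss_mode = TRUE`. A locus overlapping the
transcript is intragenic at distance 0; otherwise upstream/downstream
follows the gene's strand. Relative orientation compares insertion
orientation with gene strand. Distances bin at 10 kb;
`orientation_profile` returns per-bin sense/antisense counts and per-bin
mean distances (both, since the figure's "average points" are underdefined),
plus the intragenic antisense fraction with an exact binomial test against
0.5 — intragenic insertions are expected antisense-biased under purifying
selection against splice interference, and an unbiased simulation must sit
inside the binomial interval around 0.5.

`sweep_overlap_test` merges the sweep intervals and compares the number of
significant loci whose span midpoint (the package's reference point; not
specified in the study) falls inside a sweep against Binomial(n, sweep
fraction of the genome), two-sided. `export_gene_lists` writes de-duplicated
per-pattern gene lists for external ontology services; enrichment itself is
out of scope.

## Phylogeny association

`assign_best_erv` scores each locus against every library ERV by the sum of
its member reads' alignment scores (summed support was chosen over
read-majority voting; the margin to the runner-up flags ambiguity, and exact
ties resolve to the lexicographically smaller id and are always flagged).
Tree inference itself is consumed, not computed — the tree arrives as
newick, already rooted. `annotate_tree` inserts `[&n=…,patterns=…]` comments
after assigned tip labels by string surgery, leaving every other byte of the
newick (topology, branch lengths, other tips) untouched.
`dispersion_summary` makes "spread across the phylogeny" quantitative:
per-clade annotated-tip counts and a chi-square test of proportionality to
clade sizes. This formalization is the package's own; the original
observation is qualitative.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes, under the study's conditions as defaults:

| parameter | default | rationale |
|---|---|---|
| pools | 3 lines × 11 diploid individuals | study pool sizes |
| coverage | 5.53× / 5.19× / 3.37× (H/L/W) | study per-line coverages |
| reads | 50 nt × 2, insert ~N(3500, 350) truncated to [100, 7000] | mate-pair geometry; only "about 3–4 kb" is stated, the sd is a package choice |
| ERV library | 20 consensi of 7–11 kb, 300 nt LTR | expected ERV lengths; library size scaled down for desk-scale runs |
| forms | 80% solo-LTR, 15% truncated, 5% full | keeps the ~20:1 total:full-length ratio |
| allele frequencies | Beta(0.5, 0.5) per line | U-shaped standing variation; fully configurable (`point` matrices for planted designs) |
| scores | 400 + 93·Beta(4, 1.5) true, Beta(1.5, 4) noise | hits the 400–493 scale with most true reads above 425 |
| noise rate | 1% | chimera/mis-anchor rate is not stated; exposed in config |
| detection rate | 2% | see below |

Pools are treated as a single DNA mixture: reads are drawn per haplotype in
proportion to carrier dosage, which is itself binomial in 2 × 11 trials on
the per-line allele frequency. Alignment records, not raw reads, are the
contract — scores are simulated directly, since colorspace alignment is out
of scope, and sequence emission (FASTA fixtures) is optional.

The expected number of *detected* junction-spanning pairs per junction,
line and insertion is

$$\lambda \;=\; d \cdot \frac{C}{2n} \cdot \frac{\mu - 2L}{2L} \cdot r$$

with dosage $d$, pool coverage $C$, pool haplotypes $2n = 22$, insert mean
$\mu$, read length $L$ and detection rate $r$: the first three factors are
the physical (clone) mate-pair coverage of one pooled haplotype restricted
to junction-spanning configurations; $r$ collapses every loss between a
physical junction-spanning fragment and a usable record (ERV-library
mappability at score ≥ 400, unique mate anchoring). The default $r = 0.02$
puts a fixed insertion at roughly 7–8 supporting pairs per line at 5×
coverage, matching the per-locus support scale implied by the study's
line-wide ERV-host pair totals (~10⁵ pairs over ~10⁴ loci). Counts are
Poisson around $\lambda$; this expectation is asserted against simulation
in the tests.

Insertion placement uses a fixed slot grid with bounded jitter so that
consecutive insertions stay ≥ 20 kb apart: planted loci can then never
merge or cross-pair (cross spans would exceed the 20 kb pairing ceiling),
which keeps ground-truth matching unambiguous. Configurations that cannot
place all insertions raise an error rather than silently overlapping.
Coordinates are 0-based half-open throughout; BED is written natively.

**What the generator does not emulate**: real colorspace error profiles,
reference-biased mappability, segmental duplications or reference gaps,
LTR-level sequence homology between families (ERV ids are emitted directly,
so cross-family mis-assignment exists only through the noise channel), and
linkage between loci. Passing tests therefore validate the pipeline's
statistical machinery and bookkeeping under the stated geometry — not
robustness to alignment artifacts of real SOLiD data.

## Numerical and calibration choices

* Exact-test enumeration compares log-probabilities with a 1e-7 relative
  slack when accumulating "as or less probable" tables, the usual guard
  against floating-point ties.
* The chi-square path is only dispatched at min count ≥ 15, where expected
  cells are large enough for the asymptotic null.
* Calibration checks that need *continuous* null p-values (KS uniformity)
  are run at high junction support (fixed loci, elevated detection rate) so
  the chi-square path dominates; exact-test p-values on few-read loci are
  discrete and conservative by construction, which a KS test against
  U(0,1) would flag as non-uniform for the wrong reason.
* The family-wise error check plants 10,000 fixed loci per replicate (three
  replicate seeds) under the study's coverage imbalance; with every line at
  dosage 22 the only cross-line differences are depth, absorbed by the
  conditional margins. The suite asserts that at most one of three
  replicate families shows any Bonferroni rejection.
* The recovery check (line-private fixed insertions, zero noise, fixed
  3,500 nt inserts, expected support ≥ 15 reads per carrier line) plants
  private insertions for all three lines over a shared fixed background, so
  every line keeps a realistic genome-wide read total — with a one-sided
  design the private line's inflated total would itself look like
  depletion at every shared locus, which is a real property of
  total-normalized testing, not an artifact. Fixed inserts bound the
  anchor-to-junction distance by the insert size, which is what makes the
  "span endpoints within 3,500 nt of truth" assertion exact rather than
  probabilistic.
* Desk-scale problem sizes (4–20 chromosomes of 2–13 Mb, 200–10,000
  insertions) were chosen so each property is estimated with adequate
  precision while a full suite run stays in the minutes range; they are
  stated in the tests and scripts alongside each check.

## Known limitations

* Breakpoints are insert-resolution (± the flanking distance); there is no
  split-read refinement, mirroring the mate-pair-only design.
* Loci closer than one insert size would merge; the generator avoids this
  by construction, real data need not.
* `annotate_tree`'s string surgery assumes unquoted newick labels.
* Polarization treats the reference-assembly flag as known; on real data it
  comes from reference ERV annotation and inherits its errors.
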