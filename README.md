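# mitocapture

Desk-scale phylogenomics for **reference-mapped mitochondrial
target-capture data** in conifers and other plants whose mitochondrial
genome evolves slowly and rearranges often. Plant mtDNA is maternally
inherited in Pinaceae and therefore tracks seed-mediated colonization
history, but the data that capture experiments produce — per-sample
consensus calls against a fragmented multi-contig reference, with read
depth that collapses in species distant from the bait donor — need a
dedicated cleaning and analysis path. `mitocapture` implements that path
end to end, together with a synthetic data generator so every stage can
be tested without any sequencing data.

## What it does

* **Alignment construction** (`mask_low_coverage()`,
  `clean_spurious_calls()`, `build_alignment()`): consensus calls below a
  read-depth threshold (default 20×) become missing (`?`); short called
  islands inside capture gaps are removed; per-sample calls are stacked
  into a reference-anchored taxa × columns alignment. Length variation is
  coded as a **binary 0/1 indel matrix** (simple indel coding): maximal
  gap runs with identical boundaries form one event, insertion blocks are
  keyed by (position, inserted sequence), and gap runs that overlap an
  event with different boundaries are ambiguous and resolved to missing.
* **Variant statistics** (`count_snps()`, `count_indel_events()`,
  `intraspecific_polymorphisms()`, `group_distances()`): SNP = a column
  with ≥ 2 nucleotide states; distances use pairwise deletion because
  scored fractions can be as low as ~27%.
* **Introgression** (`population_consensus()`, `abba_baba()`,
  `dstat_significance()`): each population is collapsed to a plurality
  consensus; ABBA/BABA site patterns are counted over pooled SNP columns
  and indel events with the outgroup consensus as the ancestral state,
  `D = (ABBA − BABA)/(ABBA + BABA)`, with an exact binomial sign test and
  a block bootstrap.
* **Phylogeny** (`jc_dist_matrix()`, `neighbor_joining()`,
  `fitch_score()`, `mp_search()`, `bootstrap_tree()`): deterministic
  Saitou–Nei NJ on Jukes–Cantor distances; vectorized Fitch parsimony
  (gaps are missing data, indel signal enters via the 0/1 events);
  heuristic MP search (random stepwise addition + NNI); bootstrap over
  the pooled column set.
* **Dating** (`date_tree()`, `select_lambda()`, `bootstrap_ages()`):
  penalized-likelihood rate smoothing on a fixed rooted topology — a
  Poisson likelihood of per-branch substitution counts minus
  λ × (squared rate changes between adjacent branches) under fossil
  min/max box constraints on node ages (`calibration()`,
  `pinaceae_calibrations()`), with branch-pruning cross-validation for λ
  and a bootstrap node-age summarizer.
* **Simulator** (`sim_params()`, `simulate_capture()`): multi-contig
  reference, substitutions + non-overlapping indels down a known tree
  whose root is the reference, regional coverage dropout growing with
  distance from the reference, optional introgression by column transfer.
  Truth is recorded exactly, so pipeline identity can be asserted.
* **Amplicon tiling** (`plan_amplicons()`, `write_bed()`): minimal
  10–12 kb long-range-PCR windows per contig, even overlap, BED output.

## Worked example

```r
library(mitocapture)
set.seed(42)
tree <- sim_default_tree(n_taxa = 8, depth = 0.05)
params <- sim_params(n_contigs = 3, total_ref_len = 30000, tree = tree,
                     rng_seed = 42, dropout_base = 0.08, dropout_slope = 8,
                     indel_rate = 0.3)
res <- simulate_capture(params)

samples <- lapply(res$samples, mask_low_coverage, threshold = 20)
samples <- lapply(samples, clean_spurious_calls, ref = res$refobj$index)
built <- build_alignment(samples, res$refobj$index)

variant_summary(built$aln, built$indels)
```

prints

```
alignment length: 32370
SNP sites: 3478  indel events: 1119
scored fractions:
   t2    t8    t4    t7    t3    t5    t6    t1   REF
0.314 0.428 0.480 0.482 0.503 0.659 0.662 0.681 1.000
```

The alignment is longer than the 30 kb reference because insertion
columns are kept; the reference taxon is fully scored while the other
taxa lose 30–70% of positions to simulated capture dropout — the same
27–92% scored-fraction band real capture experiments show, decreasing
with distance from the reference. Tree inference and dating:

```r
nj <- neighbor_joining(jc_dist_matrix(built$aln))
phangorn::RF.dist(ape::unroot(nj), ape::unroot(res$tree))   # 0 = truth
boot <- bootstrap_tree(built$aln, built$indels, B = 100, method = "nj",
                       seed = 1)
round(boot$support)
#>       t4|t5    t4|t5|t7 t4|t5|t6|t7 t1|t2|t3|t8    t2|t3|t8       t2|t3
#>         100          99         100         100         100          97

top <- ape::drop.tip(res$tree, "REF")
bootstrap_ages(built$aln, built$indels, top,
               list(calibration(top$tip.label, 10, 10)),
               B = 25, seed = 1)$summary
#>                     clade  mean  lo95  hi95
#> 1 t1|t2|t3|t4|t5|t6|t7|t8 10.00 10.00 10.00
#> 2                t4|t5|t7  0.98  0.78  1.15
#> 3                   t4|t5  0.48  0.35  0.67
#> 4             t1|t2|t3|t8  6.99  6.50  7.52
#> 5                t2|t3|t8  1.45  1.31  1.64
#> 6                   t2|t3  0.53  0.30  0.80
#> 7             t4|t5|t6|t7  1.35  1.21  1.48
```

Every bipartition of the generating tree is recovered with high bootstrap
support, and the node-age intervals (root calibrated to 10 Mya) bracket
the true clock ages.

A published aligned FASTA can be analyzed directly with
`alignment_from_fasta()` → `indels_from_alignment()` →
`supplementary_alignment_report()`, which returns the SNP/indel counts,
per-taxon scored fractions, intraspecific polymorphism counts and
ABBA-BABA counts for four named population roles.

## Command line

A thin CLI ships in `inst/cli/mitocapture`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","mitocapture",package="mitocapture"))') \
    simulate --seed 3 --ref-len 30000 --out-dir out/
# subcommands: simulate, tile, stats, groupdist, abbababa, tree, date
```

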