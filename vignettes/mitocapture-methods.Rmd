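---
title: "Models and methods behind mitocapture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitocapture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mitocapture` analyzes reference-mapped mitochondrial target-capture
data: per-sample consensus calls with read coverage against a
multi-contig reference, as produced when genomic libraries enriched for
mtDNA are sequenced and mapped back to the bait donor's assembly. This
vignette explains the models, the tunable parameters and their defaults,
the deliberately open design choices, and what the synthetic-data tests
do and do not establish.

## Coordinate and symbol conventions

All genomic coordinates are 0-based, half-open, on the concatenated
reference; conversion to 1-based happens only at display boundaries (BED
output is natively 0-based). The single missing-data symbol is `?`
everywhere — nucleotide matrix and indel matrix alike; `N` on FASTA
input is mapped to `?` on read. A gap (`-`) is *length information*, not
missingness, and never counts as a nucleotide state.

## Cleaning model

Two artifacts dominate mapped capture consensi: low-coverage noise and
isolated called islands inside capture gaps.

* `mask_low_coverage()` sets every call with depth below the threshold
  (default **20 reads**) to `?`. The threshold is the one knob every
  downstream count depends on; it is deliberately a plain argument, not
  hidden state.
* `clean_spurious_calls()` removes maximal called runs shorter than
  `min_island_len` (default **10 bp**). Published pipelines describe
  removing "spurious polymorphisms" without giving a rule; short islands
  flanked by missing data are the operationalization chosen here because
  they are the dominant artifact class in mapped consensus data — a
  10 bp island inside a kilobase capture gap is far more likely a
  mismapped read than genuine signal. Runs are bounded by contig edges,
  so a short island at a contig end is removed as well.

## Alignment and simple indel coding

`build_alignment()` stacks the cleaned calls over all reference
positions and adds one **insertion column block** per distinct
(position, inserted sequence) pair observed in any sample. Alignment
regions outside the reference are thus kept only as insertions, keyed by
content; two different inserted sequences at one position are distinct
events, which avoids having to align insertions against each other.

Length variation becomes a binary matrix with one character per event
(simple indel coding): maximal gap runs with identical boundaries across
taxa are one event; a taxon is `1` if it carries the event, `0` if it is
fully called across the event footprint, `?` otherwise. Gap runs that
overlap an event with *different* boundaries are **ambiguous**. The
default `to-missing` policy erases the conflicting run from the
nucleotide matrix (to `?`) and scores the taxon `?` for every overlapped
event — ambiguity is treated as non-information. The alternative
`split-events` policy keeps each distinct run as its own event with its
carrier scored `1`. Under `to-missing` the ambiguity resolution depends
on which gap runs survive coverage masking, so the *fraction* of scored
columns is not monotone in the coverage threshold (the scored-column
count at the masking step is); the test suite pins the monotone
quantities and this caveat is the reason.

Indel footprints are excluded from SNP calling: a gap is not a
nucleotide state, and the indel signal is carried once, by the 0/1
events — never double-counted.

## Variant statistics and group distances

A SNP is a column with at least two distinct nucleotide states in the
taxon subset, counted once regardless of allele count (site counts, not
allele counts). Distances between phylogenetic groups are means over all
cross pairs of per-pair difference counts, with **pairwise deletion**:
with scored fractions down to ~27%, complete-case analysis would discard
nearly everything. Raw counts are reported alongside per-site normalized
versions; raw counts are the primary surface because that is the
convention of the capture literature this package serves.

## ABBA-BABA on population consensuses

Populations are collapsed to plurality consensuses (ties → `?`), because
the capture design yields one consensus per sample and no within-
population allele frequencies — Patterson's frequency-based D is
deliberately out of scope. A pooled character (SNP column or indel
event) is informative when all four consensus states are determinate and
exactly two states occur; the outgroup consensus is the ancestral state.
With roles recipient (P1), sister (P2), donor (P3), outgroup (P4):
ABBA = P2,P3 share the derived state; BABA = P1,P3 share it. Note the
orientation: donor→recipient gene flow inflates *BABA* under these
labels. Roles are named explicitly rather than numbered because numbered
conventions are ambiguous in the literature. Significance comes from an
exact two-sided binomial sign test on (ABBA, BABA) and optionally a
block bootstrap over contiguous pooled columns (default block 1000),
which respects linkage along the mitochondrial genome.

## Phylogeny

Jukes–Cantor distances use pairwise deletion; saturated pairs
(p ≥ 0.75) are capped at d = 5 and flagged. Neighbor joining is the
standard Saitou–Nei agglomeration with a lexicographic tie-break on the
smallest tip label per cluster, so results are reproducible across
platforms; negative branch lengths are clamped to zero. Fitch parsimony
treats `-` and `?` as the universal state and scores indel events as
binary characters alongside nucleotide columns; the implementation is a
vectorized bitmask postorder pass, checked in the tests against an
independent implementation and against exhaustive topology enumeration.
The MP search uses random stepwise addition followed by NNI
hill-climbing; NNI (not TBR) is the default because at ≤ ~90 taxa
restarts are cheaper than deep swaps, and tied optima are collapsed to a
strict consensus. Bootstrap resamples the pooled column set (SNP columns
and indel events together) and annotates the best tree's bipartitions
with replicate frequencies. Maximum likelihood is intentionally not
reimplemented: externally produced ML trees enter via newick and can be
dated directly.

## Penalized-likelihood dating

On a fixed rooted topology with branch lengths in substitutions/site,
`date_tree()` minimizes

    score = − Σ_k [ x_k log(r_k t_k) − r_k t_k − log(x_k!) ]
            + λ [ Σ_nonroot (r_k − r_parent(k))² + Var(root-children rates) ]

where `x_k` = branch length × `n_sites` rounded to the nearest integer
(floored at 0), `t_k` = parent age − child age, and rates live on the
substitution-count scale (divide by `n_sites` for per-site rates).
Fossil calibrations are min/max boxes on MRCA ages; bounds propagate
(child minima push ancestors up, ancestor maxima cap descendants) and an
infeasible combination is a hard error naming the violating pair.

Numerical scheme: ages are initialized by proportional depth scaled into
the root calibration window and projected to feasibility; optimization
alternates a 1-D golden-section pass over node ages (each age boxed by
its children, parent and calibration) with exact coordinate updates for
rates — the stationarity condition in one rate is a quadratic with a
single positive root, iterated Gauss–Seidel within each sweep — until
the relative score change is < 1e-8 or 10,000 sweeps. There is no RNG
anywhere in the fit, so results are bit-reproducible. `x log(r t)` uses
the `0·log(0) = 0` convention with underflow protection.

λ is chosen by branch-pruning cross-validation over a grid (default
0.1–1000): each terminal branch not adjacent to the root is pruned, the
tree re-dated, and the branch's substitution count predicted from the
merged edge's fitted rate and the interpolated attachment age; the error
is chi-square-like, and λ values whose errors differ by less than 1% of
the error scale (well under one substitution) are treated as tied, with
ties resolved toward the smoother fit. Under a true clock this selects
the largest grid value; under genuine rate variation a finite interior
value wins.

`bootstrap_ages()` resamples pooled columns, re-fits branch lengths on
the *fixed* topology by non-negative least squares against the weighted
JC distance matrix, re-roots at the original root bipartition, and dates
each replicate. Distances cannot place the root along its edge, so the
root edge is split to equalize mean root-to-tip depth on both sides —
the clock-consistent choice; an even 50/50 split was measurably biased
in testing and is not used. Indel events participate in resampling but
not in the distance matrix (distances are nucleotide-only).

## The synthetic world

The generator emulates the statistical structure of a capture
experiment, with defaults stating that world:

| parameter | default | meaning |
|---|---|---|
| `n_contigs` / `total_ref_len` | 19 / 10⁶ bp | fragmented mitochondrial reference (tests scale the length down) |
| `subst_model`, `kappa` | JC (HKY optional) | base exchange on branches, Poisson(branch × sites) |
| `indel_rate` | 0.3 / substitution | indel events, geometric lengths, mean 4 bp |
| `dropout_base` | 0.08 | regional capture failure near the reference |
| `dropout_slope` | 12 per subs/site | extra dropout per unit divergence from the reference; with ~0.05 subs/site depth this spans the ~27–92% scored band |
| `dropout_window_mean` | 2000 bp | capture failures are regional, not per-base |
| coverage | NB, mean 100 (captured), mean 2 (dropout) | captured windows have a depth floor of 20 |

Design choices worth recording:

* The **root sequence is the reference** and the reference taxon is a
  leaf with a near-zero branch, mirroring reference-mapping geometry.
* **Indel footprints never overlap anywhere in the simulation** (1 bp
  margin). The weaker "no overlap within a lineage" would already keep
  per-lineage bookkeeping consistent, but cross-lineage overlaps merge
  gap runs in descendants and would break the exact event-level identity
  the pipeline tests assert; overlapping indels are exercised through
  hand-built fixtures instead.
* **Captured windows have a depth floor** (20, the default threshold):
  a captured position is by definition well covered. Without the floor,
  ~10⁻⁴ of captured positions fall under the threshold and the exact
  pipeline-identity property cannot hold.
* The default tree is a random coalescent whose node heights are floored
  at 5% of the depth (ultrametricity preserved). Raw coalescent trees
  contain arbitrarily short internal branches, making the default world
  statistically unidentifiable at desk scale — topology recovery and
  10%-age-recovery claims would fail for reasons that have nothing to do
  with the methods.
* Introgression transfers the **donor plurality state at
  reference-anchored nucleotide columns** polymorphic in the donor ∪
  recipient union; indel-state transfer is not simulated, keeping the
  consensus/insertion bookkeeping exact. Since SNP columns dominate the
  pooled ABBA-BABA character set, this does not change what the
  calibration tests establish.
* The negative-binomial depth model is a modeling convenience; no claim
  about real capture depth distributions is made.

What a green simulation test establishes: internal consistency (the
pipeline recovers exactly what the generator put in), correct
orientation and calibration of the ABBA-BABA test under the null, and
statistical power in an identifiable regime. What it does not establish:
performance under mapping error, chimeric reads, heteroplasmy,
recombination, or reference bias beyond coverage dropout — none of which
are simulated.

## Known limitations

* Consensus-based ABBA-BABA has no within-population sampling; weak
  gene flow that never flips a plurality consensus is invisible.
* `mp_search()` with NNI can stop in local optima on pathological flat
  landscapes; restarts mitigate but do not eliminate this (the tests
  budget 10 restarts for 6-taxon exhaustive agreement).
* The dating objective treats branch lengths as Poisson counts after
  rounding; for very short branches (< 1 expected substitution) ages are
  bounded by the calibration structure, not the data.
* Exact reproduction of externally produced published alignments is
  bounded by the unpublished cleaning conventions of their original
  pipelines; the convention knobs here (SNP = variable column, indel =
  variable event, ambiguity → missing) are explicit and documented.
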