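---
title: "Partitioning allopolyploid genomes into subgenomes with repetitive k-mers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning allopolyploid genomes into subgenomes with repetitive k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polykmer)
```

## The problem and the model

An allopolyploid genome carries `p` chromosome sets (subgenomes) inherited
intact from distinct progenitor species. Before hybridization each
progenitor lineage accumulated its own bursts of transposable-element (TE)
activity, so families of repetitive sequence — and therefore the short DNA
words they contain — are unevenly distributed across homoeologous
chromosomes long after the merger. polykmer exploits exactly this signal:
canonical k-mers (a word pooled with its reverse complement; by default
k = 13, long enough to be specific, short enough that a TE family shares
many words across its copies) act as markers of subgenome-specific
repetitive activity. No diploid relative, gene annotation, or external
database is needed; all evidence is intragenomic.

The input contract is a chromosome-scale assembly plus a grouping of
chromosomes into homoeologous groups (pairs, trios, quartets, ...), one
member per subgenome, with `2n = 2px`. Deriving those groups (typically
from shared protein-coding content) is upstream of this package.
Rearranged genomes are handled by declaring chromosome *segments* as
first-class pseudo-chromosomes.

## Marker discovery

Three filters produce candidate subgenome markers:

1. **High copy number.** Keep k-mers with at least `N_min` (default 100)
   copies genome-wide; this restricts attention to repetitive families and,
   at k = 13, prunes the matrix from tens of millions of words to a few
   thousand. The boundary is `>= N_min`.
2. **Within-group fold enrichment.** Within a homoeologous group, a k-mer
   is enriched if some member's density is at least `F` (default 2) times
   the density of at least one other member. Densities are pseudocounted,
   `(count + 1) / length` — homoeologs differ in length, so raw counts
   would create spurious winners, and subgenome-absent markers (count 0)
   must remain comparable on the log scale.
3. **Cross-group quorum.** The enrichment must recur in at least `quorum`
   groups (default: all considered groups; `x - 1` tolerates one outlier
   chromosome, as needed for a poorly assembled homoeolog).
   Chromosome-private expansions (e.g. one pericentromeric bloom) fail any
   quorum >= 2 and are discarded: they cannot unite chromosomes into a
   subgenome.

An optional `bootstrap_groups` subset restricts discovery to groups whose
homoeology is unambiguous; candidates from those groups then classify every
chromosome. This mirrors the restricted-trio and restricted-pair bootstraps
used for heavily rearranged hexaploids and for tetraploids with uncertain
pairings.

## Clustering and the partition

Chromosome profiles of log10 marker density are clustered agglomeratively
with distance `1 - r` (Pearson). Cutting the tree into `p` clusters yields
the subgenome partition. This is a similarity clustering over repetitive
content, **not** a phylogeny, and the package labels it accordingly.

Where the cut violates the one-member-per-group rule, the offending group is
re-assigned by nearest cluster centroid under `1 - r`, taking the label
permutation of minimum total distance; a chromosome whose best centroid
correlation falls below `min_assign_r = 0.2` is declared unassigned. The
original procedure completed marginal assignments by expert inspection of
the heatmap; the centroid rule is our automated, deterministic stand-in and
is flagged in the output so a human can review exactly the chromosomes an
expert would have reviewed. Linkage is complete by default (average
available); the choice is not specified by the method description we
implement, so it is pinned in configuration and in tests.

## Statistical validation

For each k-mer, a one-way ANOVA on log10 densities across subgenomes is
followed by Tukey–Kramer comparisons of every subgenome pair:

$$q_{ij} = \frac{|\bar y_i - \bar y_j|}{\sqrt{(MSE/2)(1/n_i + 1/n_j)}},$$

with p-values from the studentized-range distribution with `p` groups and
`df = N - p` (N assigned chromosomes). The studentized-range tail is used
as-is — Tukey's HSD is by definition one-sided in this sense — with no
halving or doubling. Bonferroni correction multiplies by the *full*
high-copy family size m (every k-mer passing `N_min`, not just quorum
candidates), which is deliberately conservative. Degenerate rows (zero MSE)
are flagged and given p = 0 or 1 according to whether means differ.
Effect sizes are reported both on the tested log scale and as raw mean
count/chromosome differences, the scale used for volcano plots.

**Marker classes.** A marker's class is the subset S of subgenomes it marks:
every contrast between S and its complement significant with S higher, no
significant contrast inside S. Combination classes (e.g. SG1+SG2) are the
genomic record of shared TE activity in an intermediate polyploid ancestor
— observing many SG1+SG2 markers but few SG2-only markers implies SG1 and
SG2 arrived together in an allotetraploid intermediate. If several subsets
qualify (rare), the smallest, then lexicographically first, is taken, for
determinism.

Two optional display/physical filters exist: a merged-coverage floor in
bp per Mb of the enriched subgenome (`density_floor`; the published
strawberry analysis used 1 kb/Mb — we interpret the unit as merged
marker-hit base coverage per Mb of subgenome length, an operational
definition the source leaves open), and a fold-ratio `display_bias` filter
(e.g. 100x) applied to karyogram tracks only, never to statistics.

## Tracks and the exchange HMM

Significant markers are located by exact both-strand string matching (for
13-mers this coincides with word-exact alignment), merged when overlapping
or adjacent, and binned at 100 kb (covered bp per bin by default; hit-count
mode exists). Each bin emits a symbol: the class of maximal density, or a
null symbol below a floor.

A hidden Markov model with one state per subgenome segments each chromosome
by ancestry: stay probability `1 - tau`, switch `tau / (p - 1)` with
`tau = 1e-3`; emissions P(own class | state) = 0.9, P(null | state) = 0.05,
remainder uniform. These defaults are package choices — the original
parameterization is not in the text we implement from — so correctness is
established by simulation recovery, not parameter equality: at these
defaults a switch needs roughly five consecutive discordant 100-kb bins,
which sets the resolution of exchange detection. Viterbi decoding (exact,
log space, ties broken toward staying) yields runs; each within-chromosome
transition is an exchange call with a 0-based breakpoint bin, annotated
terminal when it falls within 10% of a chromosome end. Runs shorter than
`min_run` bins can be absorbed into their flanks.

## LTR retrotransposon dating

An intact LTR retrotransposon's two terminal repeats are identical at
insertion; their subsequent divergence clocks its age. Given an intact-LTR
annotation (coordinates of the 5' LTR, 3' LTR and inner span; the package
does not discover elements de novo), the LTR pair is globally aligned
(affine gaps: match 1, mismatch -2, open -4, extend -1), the mismatch
proportion pi is computed over aligned non-gap columns only (Jukes-Cantor
is a substitution model; gaps carry no information under it), corrected as
`d = -(3/4) ln(1 - (4/3) pi)`, and converted to age `d / (2 mu)`. The
default calibration `mu = 0.035 / (2 * 3e6)` per site per year makes
d = 0.035 correspond to 3 My, matching the published correspondence for
octoploid strawberry; it should be overridden per clade. Pairs with
alignment identity below 60% are flagged unalignable and excluded from
histograms. Families are built by single linkage over pairs whose local LTR
alignment spans at least 90% of *both* sequences (the reciprocal-coverage
rule preserved exactly); the significance cutoff is a minimum identity
(0.8) plus minimum length (50 bp) — an internal stand-in for a BLAST
E-value, which we cannot calibrate meaningfully for an internal aligner.
Divergence histograms restricted to large families (>= 10 members), grouped
by host-chromosome subgenome, reveal shared modes: a common peak across a
subset of subgenomes dates TE activity in their common (intermediate
polyploid) ancestor.

## The simulator: a stated world

`simulate_polyploid()` generates the scenario the method assumes, with full
ground truth: ancestral chromosomes i.i.d. uniform ACGT; each branch of a
hybridization tree applies i.i.d. per-site substitutions (each site flips
at most once per branch, uniform alternative base — no indels outside TE
insertion) and then TE bursts (fresh random consensus; copies mutated
per-site at `copy_mut_rate = 0.02` at insertion, LTR pairs duplicated
*after* per-copy mutation so they are identical at insertion); merges
concatenate chromosome sets; exchanges copy (or, optionally, reciprocally
swap) homoeologous segments after the final merger — the directional copy
is the default because that is the usual homoeologous-exchange outcome.

Preset scales are chosen so a full pipeline run takes seconds to ~1 min on
one CPU:

* `tetraploid_clean` — two progenitors, one private burst each (300 copies
  of a 1-kb consensus), x = 5 chromosomes of 0.5 Mb, substitution rate 0.02
  per branch.
* `tetraploid_exchange` — as above at x = 8 chromosomes of 1.5 Mb plus one
  internal 500-kb exchange. The larger group count matters: with a third of
  one acceptor chromosome contaminated, donor markers only survive the
  conservative Bonferroni correction when `df = 2x - 2` is realistic
  (empirical polyploid analyses have 7–25 groups).
* `hexaploid_staged` — (SG1,SG2),SG3 with a 300-copy burst on the shared
  internal branch (the tetraploid-intermediate signature) and leaf bursts;
  SG2's private burst is 150 copies of a 150-bp element, so SG2-only
  markers exist but are ~10x fewer than shared SG1+SG2 markers, the
  qualitative asymmetry observed in real hexaploids.
* `octoploid_staged` — ((T1,T2),I),V with bursts on both internal branches;
  the I-T1-T2 branch burst is LTR-bearing, and the post-burst substitution
  rates on each descendant lineage sum to ~0.0175, so LTR pairs diverge by
  d ~ 0.035 — the dating signal lands in the 0.03–0.04 histogram bin on
  T1/T2/I and is absent from V.

What the simulator does **not** emulate: target-site duplications, nested
insertion biology (nested hits are merely flagged), solo-LTR formation,
recombination, selection, GC heterogeneity, or assembly error. A green test
therefore establishes algorithmic correctness on the stated model, not
robustness to every artifact of real assemblies; the published analyses of
cotton, cyprinids, Camelina, strawberry and tobacco are the full-scale
validation and are out of desk-scale scope.

## Numerical choices and degenerate inputs

* Pseudocount 1 before normalization keeps log densities finite for
  subgenome-absent markers; raw-count effect sizes are unaffected.
* Normalization divides by chromosome length L, not L - k + 1, matching the
  stated count/bp measure.
* Winner ties in fold enrichment break to the first-listed group member and
  are flagged; Viterbi ties break toward staying, then to the lower state
  index; class-label ties take the smallest subset.
* Constant rows are excluded from correlation clustering (correlation is
  undefined); constant rows row-scale to zero in heatmaps under an sd guard
  of 1e-12.
* `jc_distance` errors at pi >= 0.75 (saturation) rather than returning
  infinity.
* All randomness in the simulator flows from a single integer seed; outputs
  are byte-identical across runs with the same seed.

## Test scaling

The no-exchange HMM specificity check runs 50 replicates (the breakpoint
recovery check runs the full 100) and the marker-power check runs 60
replicates rather than 200, keeping the default suite inside its time
budget; pass margins at these sizes are large (the power check's expected
studentized range statistic is ~30 against a significance threshold of ~8).
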