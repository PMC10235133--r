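# polykmer

Partition an allopolyploid genome into its subgenomes using nothing but the
distribution of repetitive k-mers across homoeologous chromosomes.

## The problem

An allopolyploid carries `p` chromosome sets contributed by distinct
progenitor species. Each progenitor lineage, before hybridization,
accumulated its own bursts of transposable-element activity, so short
repetitive words remain asymmetrically distributed across homoeologs. Given
a chromosome-scale assembly and a grouping of chromosomes into homoeologous
groups (one member per subgenome, `2n = 2px`), polykmer:

1. counts **canonical k-mers** (word pooled with its reverse complement,
   default k = 13) per chromosome and normalizes to copies/bp
   (pseudocount 1, log10 scale);
2. discovers candidate markers: genome-wide copy number ≥ `N_min`
   (default 100), within-group enrichment of one homoeolog over another by
   a factor `F` (default 2) on pseudocounted densities, recurring in a
   quorum of groups;
3. clusters chromosomes hierarchically with distance `1 − r` (Pearson) on
   marker log-densities and cuts at `p` to obtain the subgenome partition;
4. validates each marker by one-way ANOVA plus Tukey–Kramer contrasts
   `q = |ȳᵢ − ȳⱼ| / sqrt((MSE/2)(1/nᵢ + 1/nⱼ))` against the
   studentized-range distribution with `df = N − p`, Bonferroni-corrected
   over the full high-copy family, and assigns marker **classes**
   (single subgenomes, or combinations such as SG1+SG2 that record shared
   ancestry in an intermediate polyploid);
5. localizes markers into 100-kb density tracks and segments each
   chromosome with a Viterbi HMM over subgenome states — state switches
   along a chromosome are **homoeologous exchange** calls;
6. dates intact LTR retrotransposons from 5'/3' LTR divergence under
   Jukes–Cantor, `d = −(3/4)ln(1 − 4π/3)`, age `= d/(2μ)`, and groups them
   into families by reciprocal-coverage single linkage.

A seeded simulator (`simulate_polyploid()`, presets from tetraploid to
octoploid with staged hybridizations, TE bursts, exchanges and LTR
elements) provides ground truth for every stage.

## Worked example

```r
library(polykmer)

res <- simulate_polyploid(sim_preset("tetraploid_clean"))
res
#> sim_result: 10 chromosomes, 2 subgenomes ( A, B ), 600 TE insertions, 0 exchange(s)

pl <- run_pipeline(res$genome, res$design)
pl$partition
#> Subgenome partition over 10 chromosomes, 2 subgenomes
#>   SG1: A1, A2, A3, A4, A5
#>   SG2: B1, B2, B3, B4, B5

length(pl$candidates$kmers)   # candidate marker k-mers
#> [1] 1976
table(pl$classes)             # markers per subgenome class (df = 8 here)
#> SG1 SG2
#> 988 988

truth <- setNames(res$truth$subgenome, res$truth$chromosome)
adjusted_rand_index(pl$partition$assignment, truth)
#> [1] 1
```

The two progenitors each carried one 300-copy burst of a 1-kb element; its
988 internal 13-mers are recovered as markers of each subgenome
(`table(pl$classes)`), the partition matches the simulation truth exactly
(adjusted Rand index 1), and every marker's Tukey contrast is reported with
Bonferroni-corrected p-values in `pl$stats` (e.g. `p_bonferroni ≈ 1e-10`
for clean subgenome-specific markers at df = 8, m = 1976).

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/polykmer.R simulate --preset tetraploid_clean --out sim/
Rscript inst/cli/polykmer.R pipeline --genome sim/genome.fa \
    --design sim/design.json --out run/
```

`run/` then holds `partition.tsv`, `candidates.tsv`, `stats.tsv`, Newick
dendrograms, per-class bedGraph tracks, `segmentation.bed`,
`exchange_calls.tsv` and a `manifest.json` snapshot of all parameters.

## Acceptance script

`scripts/acceptance.R` re-runs the full workflow from scratch against the
installed package — simulating an allotetraploid at the given seed,
discovering and validating markers, recovering the partition — and writes
its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope notes

Homoeolog grouping, assembly, gene annotation and de novo LTR discovery are
upstream of this package; intact-LTR annotations are an input (the
simulator emits them for testing). Clustering output is similarity of
repetitive content, not a phylogeny. See
`vignettes/subgenome-partitioning.Rmd` for the model, parameter defaults,
numerical choices and limitations.
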