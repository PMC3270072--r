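# grnevo

Simulation of development and evolution in transcriptional regulatory
networks with continuously varying expression levels.

## The problem

How do complex gene regulatory networks stay *developmentally stable* as they
evolve — through sex, through the gain and loss of genes? In the classic
Wagner framework, a network of `n` transcription factors is an `n × n` real
matrix `W` (entry `w_ij` is the effect of factor `j` on the production of
factor `i`, in `[-1, 1]`), and an individual's expression state is a vector
`S` that develops by iterating

```
S(t+1) = f(W · S(t)),      f(x) = 2 / (1 + exp(-a·x)) − 1
```

The sigmoid `f` bounds expression to `(-1, 1)`. With curvature `a = 1.5` the
stable expression levels are genuinely continuous (the COV regime); with
`a ≈ 100` the sigmoid saturates and expression is effectively ±1, recovering
the discrete on/off model (DOV). Development is *stable* when the windowed
convergence statistic

```
φ(S_t) = (1/τ) · Σ_{i=t−τ..t} D(S_i, S̄_t),      D(X,Y) = Σ(x_i − y_i)² / (4n)
```

falls below `σ = 1e-4` within `L_max = 100` steps (`τ = 10`). An individual is
**viable** when development converges *and* the stable state actually
expresses a pattern (variance of its expression levels ≥ 0.1 — otherwise the
ever-present fixed point at the origin would count every small network as
viable).

On top of this developmental core, the package implements the evolution
operators whose viability consequences are the object of study — **haploid
mating** (offspring rows copied whole from either parent), **diploid mating**
(offspring entries are parental means: additive gene action), **gene
insertion** (new random row/column), **gene duplication** (copied
row/column), and **gene deletion** — plus the measurement layer: Monte-Carlo
viability rates with Wilson intervals, the intraclass correlation of stable
states across viable individuals, pooled-output uniformity testing, and the
network-versus-initial-vector decomposition of viability.

It is intended for researchers studying network robustness, canalization,
and the evolution of regulatory complexity who want a fast, seeded, fully
reproducible implementation of this model family (the inner development loop
is compiled C++; everything returns tidy tibbles).

## A worked example

```r
library(grnevo)

set.seed(42)
ind <- find_viable_individual(10)   # rejection-sample a viable 10-gene individual
ind
#> <grn_individual> n = 10, path length 26, found in 1 attempts

develop(ind$network, ind$initial_state)
#> <grn_development> viable, n = 10, path length 26
#> stable state: -0.8949 -0.8765  0.2678 -0.9160 -0.4461 -0.8748 -0.6765  0.9443 -0.6488 -0.6832

# how likely is a RANDOM network to be viable at all?
cfg <- experiment_config(gene_sizes = c(5, 10, 15), trials_per_unit = 2000, seed = 1)
run_random_viability(cfg)
#> # A tibble: 3 × 7
#>       n regime successes trials  rate ci_low ci_high
#>   <int> <chr>      <int>  <int> <dbl>  <dbl>   <dbl>
#> 1     5 COV          249   2000 0.124 0.111    0.140
#> 2    10 COV          325   2000 0.162 0.147    0.179
#> 3    15 COV          204   2000 0.102 0.0895   0.116

# diploid mating: offspring entries are the means of the parents' entries
set.seed(42)
tidy(mate_diploid(ind, find_viable_individual(10)))
#> # A tibble: 1 × 5
#>   source      n viable path_length index
#>   <chr>   <int> <lgl>        <int> <int>
#> 1 diploid    10 TRUE            10    NA
```

A 15-gene random network is viable only ~10% of the time, yet diploid mating
between two viable 15-gene parents yields a viable offspring ~45% of the
time — sexual averaging of interaction strengths preserves complexity far
better than chance assembles it. `run_mating()`, `run_indels()`, `run_icc()`
and `run_decomposition()` regenerate the corresponding figure-level
experiments as tibbles with confidence intervals; `autoplot()` draws the
rate-versus-size curves.

A thin command-line shell covers the same operations
(`Rscript inst/cli/grn.R develop --network w.tsv --state s0.tsv`, `generate`,
`mate`, `mutate`, `stats`, `experiment ... --seed S --out dir/`), with
networks and individuals exchanged as TSV/JSON and every results directory
carrying a `manifest.json` (config, seed, digest) from which it can be
regenerated bit-identically.

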