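---
title: "The continuous-output network developmental model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The continuous-output network developmental model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnevo)
```

## The model

An individual is a pair: a regulatory network `W` (an `n × n` real matrix,
`w_ij ∈ [-1, 1]`, row `i` collecting the effects of every transcription
factor on the production of factor `i`) and an expression state `S`
(length-`n`, elements in `[-1, 1]`). Development iterates

$$S_{t+1} = f(W S_t), \qquad f(x) = \frac{2}{1 + e^{-ax}} - 1 .$$

`f` is applied element-wise; it is odd, strictly increasing, and maps the
real line into $(-1, 1)$, so expression levels can never run away. The
curvature `a` is the regime switch: between 1 and 2 the stable expression
levels spread over the whole interval (continuous-output, COV; the package
default is `a = 1.5`), while around 100 the sigmoid is effectively a step
function and expression saturates at ±1 (discrete-output, DOV,
`dov_params()`), recovering the classic on/off model as a special case.

Convergence is declared through a windowed, variance-like statistic. With
$D(X, Y) = \sum_i (x_i - y_i)^2 / (4n) \in [0, 1]$ the normalised squared
distance between states, the statistic over the last $\tau + 1$ states is

$$\varphi(S_t) = \frac{1}{\tau} \sum_{i = t-\tau}^{t} D(S_i, \bar S_t),$$

where $\bar S_t$ is the element-wise mean of the window. Development
*converges* at the first step $t \le L_{\max}$ with $\varphi < \sigma$;
reaching $L_{\max}$ without that is instability — this is also how networks
with persistently cyclic trajectories (e.g. complex dominant eigenvalues of
`W`) are discarded, behaviourally rather than by a spectral pre-filter, which
would require an arbitrary test of its own and would alter the measured
rates.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `a` | 1.5 | sigmoid curvature (unitless); 1.5 = continuous regime, 100 = discrete regime |
| `tau` | 10 | convergence window length, in developmental steps |
| `sigma` | 1e-4 | threshold on the windowed statistic (distance units, i.e. fraction of the maximal squared spread) |
| `l_max` | 100 | step cutoff after which a trajectory is declared unstable |
| `min_var` | 0.1 | minimum variance of the stable state's expression levels for viability |

All five live in one `model_params()` object that every operation takes
explicitly and that serialises to YAML/JSON with experiment configs.

### Viability and the variance floor

An individual is **viable** when development converges *and* the stable
state's expression levels have variance at least `min_var`. The second clause
deserves explanation, because it is the one genuinely open design decision in
the formulation. The origin is a fixed point of the map for every network
($f(0) = 0$), and it is locally attracting whenever the spectral radius of
$(a/2)\,W$ is below 1 — which, for uniform random matrices, happens extremely
often at small `n`. Bare convergence would therefore call the vast majority
of small random networks "viable" on the strength of a state that expresses
nothing, would concentrate stable states at a single point (breaking both the
near-zero intraclass correlation and the near-uniform pooled output
distribution that characterise this model), and would invert the documented
shape of the viability-versus-size curve, in which the continuous regime is
*rare* at small `n` and overtakes the discrete regime only around six genes.
With the floor in place the package reproduces all three signatures (the
acceptance suite checks them). We read the model's "minimum population
variance of 0.1" stability requirement as exactly this: a floor on the
variance of the population of gene products within an individual. Set
`min_var = 0` to study bare convergence; `develop()` always reports
`converged` and `viable` separately.

### When is the statistic first evaluated?

$\varphi$ needs $\tau + 1$ states. The package keeps a rolling window
(a ring buffer, so memory is $O(\tau n)$ regardless of `l_max`) that includes
the initial state $S_0$, and evaluates $\varphi$ from step index $t = \tau$
onwards — the earliest index at which the sum $i = t-\tau \dots t$ is
defined. Including $S_0$ gives the earliest possible detection of trivially
stable systems; path length `L` is the number of map applications executed
when $\varphi$ first drops below $\sigma$. A perfectly flat trajectory is
therefore detected at $t = \tau$, and one that flattens after the first step
at $t = \tau + 1$.

### Numerical choices

The exponent in `f` is clamped to ±700 before `exp()` — purely defensive,
since $|a x| \le a n$ stays far below that in any studied configuration.
The development loop is implemented in C++ (Rcpp) because the Monte-Carlo
designs require millions of develop calls; a pure-R scalar-loop reference
implementation lives in the test helpers and the suite asserts agreement to
1e-10 on random instances in both regimes, plus bit-for-bit determinism of
repeated calls. One numerical subtlety is inherited by the re-entry property:
the recorded stable state $S^*$ sits anywhere within the $\varphi$-window's
spread of the true fixed point (of order $\tau\sigma$ in distance units), so
redeveloping from $S^*$ reconverges and lands within that tolerance of
$S^*$ — not within machine precision. Individuals whose stable-state variance
sits exactly at the `min_var` boundary can flip viability on re-entry; the
tests assert re-entrant viability only away from the floor.

## Random genesis: what the generator emulates

Every experiment input is synthetic by construction — the study *is* a
Monte-Carlo study of the uniform ensemble. `random_network(n)` draws all
$n^2$ interaction strengths i.i.d. Uniform$[-1, 1]$ (dense: every pair of
genes interacts, however weakly), `random_state(n)` draws initial expression
levels the same way (interpretable as maternally provisioned gene products),
and `find_viable_individual()` rejection-samples pairs through `develop()`
with no enrichment or selection of any kind, recording the attempt count
(whose geometric-distribution consistency the tests check). What this
ensemble does *not* emulate about real regulatory networks: sparsity (real
networks are sparse and modular; here every entry is nonzero), degree
structure, signed motif enrichment, or any mutational correlation between
entries. Passing tests therefore validate the model's internal claims about
this ensemble, not claims about any empirical network.

## Evolution operators

All operators act on viable parents and develop the offspring immediately,
recording viability.

* **Haploid mating** — each offspring row is copied verbatim from the
  corresponding row of a parent chosen independently with probability 1/2
  (genes are inherited whole; no blending). The offspring's initial state is
  the stable state of a uniformly chosen parent, reflecting maternal
  provisioning.
* **Diploid mating** — every entry is the arithmetic mean of the parental
  entries: purely additive gene action, no dominance or epistasis. The mean
  tempers extreme interaction strengths, which is why this mode preserves
  viability in large networks so much better than haploid mating. The initial
  state convention is deliberately identical to the haploid one, so the two
  modes differ only in how `W` is formed.
* **Insertion** — a new gene at a uniformly random position with a fully
  random row, column and self-interaction; development starts from the
  parent's stable state extended by one random element. (Internally the
  position is a random index; the dynamics are equivariant under gene
  relabelling, so position cannot affect viability.)
* **Deletion** — strike a uniformly chosen gene's row, column and
  stable-state entry (`n = 1` refuses: there is no last-gene deletion).
* **Duplication** — a full copy of a uniformly chosen gene `g`'s row and
  column, with the copy's self-interaction and both copy–original couplings
  equal to `w_gg`, and the duplicated stable-state entry as the copy's
  starting level. Two placements are exposed. `mode = "append"` grows the
  network to `n + 1` — the most literal construction, and the one whose
  dimension algebra is exactly reversible (deleting the copy restores the
  parent bit-for-bit). `mode = "overwrite"` (the default, and what the
  runners use) writes the copy over a second uniformly chosen gene, keeping
  `n` fixed: duplication with turnover. The distinction matters empirically:
  appending a working gene's copy is much gentler than a random insertion and
  its success decays with size, whereas the overwrite form is the only
  reading whose success rate is approximately constant in network size and
  *below* insertion's — the two qualitative signatures reported for
  duplication in this model family. A `zero_coupling` flag additionally
  decouples copy and original (they stop regulating each other directly), as
  a documented variant; it is not the default because a "full copy" of the
  row/column pair includes those couplings.

Mating-rate experiments draw parent pairs uniformly *with replacement across
matings* but always as two distinct individuals — self-mating is excluded,
since clone mating is trivially viable (an identity the property tests
assert).

## The measurement layer

* `viability_rate()` — success counts with the 95% Wilson score interval
  (closed form; never escapes $[0, 1]$, well-behaved at the small success
  counts typical of large random networks). Cross-checked in the tests
  against `prop.test(correct = FALSE)` and by Monte-Carlo coverage.
* `icc()` — the intraclass correlation of stable states across viable
  individuals, asking whether independent viable individuals share expression
  patterns. The printed formula in the source literature is typographically
  unrecoverable, so two estimators are provided and anchored on the two
  degenerate cases that are unambiguous (a population of clones gives 1;
  i.i.d. values give ≈ 0): the classical one-way ANOVA estimator with *gene*
  as the grouping factor and individuals as replicates,
  $(MS_B - MS_W) / (MS_B + (n-1) MS_W)$, and the Fisher-style pairwise moment
  estimator $\frac{1}{n-1}\left[\frac{n}{k s^2} \sum_j (\bar x_j - \bar x)^2 - 1\right]$
  with $s^2$ the population variance of all $nk$ values. Gene must be the
  grouping factor for the clone anchor to sit at 1. Degenerate designs
  (fewer than two individuals or genes) error; exactly zero total variance
  returns 0 with a warning.
* `output_uniformity()` — a one-sample Kolmogorov–Smirnov test of pooled
  stable-state elements against Uniform$(-1, 1)$ at $\alpha = 0.01$. The
  choice of KS is ours (no test is named in the source); it is calibrated on
  true uniform draws and rejects overwhelmingly on saturated ±1 outputs. At
  large pooled counts the test is sensitive enough to reject mild endpoint
  enrichment in the continuous regime, so the experiment runners report the
  p-value rather than enforcing non-rejection.
* `decompose_stability()` — the two shuffling arms that locate where
  viability lives: retain the individual's initial vector and redraw the
  network (the fraction staying viable collapses toward the unconditional
  random-viability rate — the vector carries almost nothing), or retain the
  network and redraw the vector (in the discrete regime this fraction is
  large: the matrix decides). `population_variance_ok()` implements the
  population-level minimum-variance filter as an optional, off-by-default
  check for discrete-regime populations.

## Experiments, seeding, and scale

Each `run_*()` runner is a pure function of its `experiment_config()`:
reruns are bit-identical. A single master seed is expanded into independent
named streams — one per (experiment, regime, size) — by a polynomial string
hash modulo $2^{31}-1$ (`derive_seed()`), so adding an experiment or a size
never perturbs another's draws. Full scale (`scale_factor = 1`) reproduces
the reference design: populations of 1000 viable individuals, 1000 matings,
100 insertion/deletion/duplication attempts per member. The test suite runs
the same machinery at desk scale (populations of 100–500, a few hundred
matings, 40 indel attempts per parent; the discrete-regime decomposition uses
100 individuals × 200 redraws per size), sizes chosen so the whole suite
completes in well under a minute per file while leaving binomial error small
relative to the tolerances being asserted; the acceptance script uses
1000-member populations for the 15-gene mating rates and 200×100 indel
designs. Result tables always carry successes, trials and the interval —
never a bare rate — and `write_results()` adds a manifest (package version,
config, seed, digest) sufficient to regenerate any results file exactly.

## Known limitations

* The uniform dense ensemble is the object of study, not a model of any
  empirical network (no sparsity, no modularity, no degree structure).
* There is no fitness, selection, or population-genetic dynamics: mating and
  indel operators are applied to rejection-sampled viable parents only, one
  generation deep.
* The duplication protocol is the one genuinely under-determined operator;
  both placements are implemented and documented above, and results for it
  should be read with that ambiguity in mind.
* In the discrete regime the stability threshold interacts with saturated
  states: trajectories either pin to ±1 patterns quickly or cycle, so path
  lengths are short and the `min_var` floor mostly excludes all-equal ±1
  patterns.
* Stochastic gene expression, continuous-time dynamics, and Boolean-network
  semantics are out of scope; the map is deterministic and synchronous.
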