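---
title: "Modelling karyotype evolution: chromosome number, sex chromosome systems, and the SA-fusion test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling karyotype evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyevol)
```

## The model

karyevol treats a species' karyotype as a pair $(k, s)$: the haploid
autosome number $k$ and the sex chromosome system $s$. Evolution along a
phylogeny is a continuous-time Markov chain on the bounded state space
$\{k_{\min},\dots,k_{\max}\} \times \{\text{simple}, \text{neo}\}$ with four
moves:

* **fission** $(k,s) \to (k+1,s)$ at rate $\delta$ — a chromosome splits,
  raising the count by one;
* **autosomal fusion** $(k,s) \to (k-1,s)$ at rate $\phi$ — two autosomes
  fuse;
* **SA-fusion** $(k,\text{simple}) \to (k-1,\text{neo})$ at rate $\rho$ — a
  sex chromosome captures an autosome, creating a neo sex chromosome system
  and removing one autosome pair;
* **reversion** $(k,\text{neo}) \to (k,\text{simple})$ at rate $\sigma$ — a
  neo system degrades back to a simple one without changing the autosome
  count.

"Simple" covers both XY and XO observations (an XO complement is a simple
system that happens to have lost its Y; the model does not distinguish
them), "neo" covers neo-XY. Multi-sex-chromosome systems (X1X2Y, ...) are
outside the state space and rejected at parse time. A neo lineage cannot
undergo a second SA-fusion before reverting; the model deliberately does not
represent multi-sex-chromosome evolution.

The basic variant drops the system dimension entirely (moves $\delta$ and
$\phi$ only) and is the right tool when the question is purely the tempo of
chromosome-number change.

Branch lengths are in tree units of $10^8$ years. All internal rates are
per tree unit; summaries are also printed per million years (rate / 100),
the scale on which empirical estimates for scarab beetles fall in the range
0.003–0.038 per My.

### Likelihood and root treatment

Tip-data likelihoods use Felsenstein pruning with per-branch transition
matrices $P(t) = e^{Qt}$. The per-branch propagators are computed by
uniformization,
$P(t) = \sum_n \mathrm{Pois}(n;\Omega t)\, R^n$ with
$\Omega = \max_i(-q_{ii})$ and $R = I + Q/\Omega$, truncated when the
Poisson weight falls below $10^{-30}$ past its mode. Because every term is
non-negative there is no cancellation: even transition probabilities of
order $10^{-14}$ (many-jump paths) retain good relative accuracy. This
matters: an eigendecomposition fast path tried first had only *absolute*
accuracy ~$10^{-11}$ and silently corrupted likelihoods in exactly the
regime where the data force improbable multi-step transitions. The
test suite pins the pruning likelihood against an exhaustive enumeration
over internal-node states to $10^{-10}$.

The root state is handled by FitzJohn-style conditional weighting by
default (each root state weighted by its share of the conditional
likelihood), with flat and fixed-root options. The choice is exposed
because none of the options is canonical for non-reversible bounded chains.

### Priors and MCMC

Each active rate gets an independent exponential prior with rate
$r = 2$ (prior mean 0.5 per tree unit — "broad" relative to the
fractions-per-unit magnitudes typical of karyotype change). Sampling is
univariate slice sampling within Gibbs (stepping-out and shrinkage, initial
width 0.5, hard lower bound 0); one sample is recorded per full sweep, which
is what a "generation" means here. Slice sampling needs no tuning and mixes
fast on these 2–4 parameter posteriors, which is why chains of 100
generations with 50% burn-in — the protocol this package replicates — are
usable at all.

Phylogenetic and tip-state uncertainty are propagated by replication: the
chain is re-run on each tree of a posterior tree sample, with conflicting
multi-record tips re-resolved by a fresh uniform draw per tree, the first
half of each chain discarded, and the remainder pooled. 100 trees × 100
generations × 50% burn-in = 5,000 pooled samples. Per-tree seeds are split
deterministically from the master seed, so multi-tree runs are reproducible
end to end.

### Stochastic mapping

Event counts are not identified by tip data alone, so they are sampled:
node states by a backward (pruning) / forward pass, branch interiors by
endpoint-conditioned uniformization — the jump count is drawn from its
exact conditional distribution given the branch endpoints, intermediate
states by the forward–backward rule on the uniformized chain, jump times
uniformly. Unlike rejection sampling this cannot stall on long branches
with incompatible endpoints. One map is drawn per retained posterior sample
by default, so downstream event-count distributions integrate parameter
uncertainty rather than conditioning on a point estimate.

### The SA-fusion excess test

If fusions struck unordered chromosome pairs uniformly at random, the
chance that a fusion involves the sex chromosome in a karyotype with $k$
autosomes would be

$$ e(k) = \frac{k}{\binom{k+1}{2}} = \frac{2}{k+1} $$

under the default haploid-complement formulation ($k$ autosomes plus one
sex element; at $k = 9$, $e = 0.2$). A diploid-complement variant
($2k$ autosomes + X + Y, excluding homologous pairs and X–Y) is provided
and also gives 0.2 at $k = 9$; the two differ slightly elsewhere, and the
choice is a config switch because the equation the empirical work relies on
is not reprinted in it.

For each stochastic map the package computes the **observed** SA share
$n_{SA}/(n_{SA}+n_{AA})$ (maps with no fusions at all are excluded and
counted) and the **duration-weighted null**
$\sum_s T_s\, e(k_s) / \sum_s T_s$ over simple-system states, where $T_s$
is the time the map spends in state $s$. Neo-state durations are excluded
from both sums by default since the model permits no SA-fusion out of a neo
state (an `include_neo` switch exists). The two distributions over maps are
compared by 95% HPD intervals — shortest contiguous window containing
$\lceil 0.95 n \rceil$ sorted samples — and the verdict is *excess* iff the
observed interval lies entirely above the null interval, mirroring the
non-overlap significance convention. Per-tree verdicts across a posterior
tree sample provide the robustness count ("excess in $m$ of $n$ trees").

## The synthetic-data generator

`make_dataset()` builds a world with the statistical shape the analysis
assumes, so the whole pipeline is testable without any downloads:

* a birth–death tree conditioned on the extant tip count (`ape::rphylo`),
  rescaled to a chosen root depth — default 1.84 units ≈ 184 My, matching
  the calibrated root age of the empirical phylogeny;
* a karyotype history simulated forward by the Gillespie algorithm under
  the same bounded generator used for inference (boundary moves have rate
  zero in both, so recovery tests are coherent);
* a tip table derived from the terminal states, with a configurable
  fraction of tips (default 0.175, emulating 37/211) duplicated with a
  conflicting record whose count differs by ±1;
* a "posterior tree sample" emulated by lognormal branch-length jitter
  (sd 0.1) of the true tree. Real posterior samples vary in topology too;
  jitter keeps tip sets identical across trees, which is the property the
  multi-tree machinery actually consumes. A green multi-tree test therefore
  establishes correct pooling and seed-splitting, not robustness to
  topological conflict.

Default rates (fission 0.3, fusion 0.7, SA-fusion 0.6, reversion 0.2 per
tree unit = 0.002–0.007 per My) are the magnitudes estimated empirically
for these beetles. One caveat discovered while calibrating the acceptance
experiments and worth recording: with slow reversion ($\sigma = 0.2$),
lineages accumulate in neo states where SA-fusion is impossible, so the
*realized* share of SA-fusions among fusion events under these defaults is
~0.30, not $\rho/(\rho+\phi) = 0.46$. The power experiment for the excess
test therefore uses $\delta=0.3, \phi=0.45, \rho=0.55, \sigma=0.55$, which
realizes a true share of ≈ 0.45 (the empirically observed effect size)
while leaving ~44% neo tips as identifying signal; the calibration
experiment tunes the SA-fusion *rate* to the per-state null,
$\rho/(\rho+\phi) = 0.2$.

## Numerical and design choices

* **State-space bounds**: $k_{\min} = 1$, $k_{\max}$ = observed max + 10 by
  default. Padding limits boundary-truncation bias; widen `k_pad` to test
  sensitivity.
* **Uniformization truncation**: Poisson tail cut at $10^{-30}$ past the
  mode; `expmat` fallback when $\Omega t > 700$ (where $e^{-\Omega t}$
  underflows), which only occurs for the long-time stationary checks.
* **HPD ties**: among equal-width windows the first (lowest) is returned.
* **Zero-fusion maps**: the observed SA proportion is undefined (0/0);
  such maps are excluded from the observed distribution and their count
  reported, rather than imputed as 0 or 1.
* **Degenerate inputs**: probability-zero tip configurations give
  $-\infty$ log-likelihood (an error in mapping, where no history exists);
  groups with fewer than 3 species are skipped with a warning, matching the
  empirical protocol of dropping families with fewer than 3 sampled
  species.
* **Seeds**: every public sampler takes an integer seed; per-tree and
  per-map seeds are derived by a fixed integer-splitting rule kept below
  $2^{31}$.

## Limitations

* No polyploidy, translocations, or state-dependent diversification; rates
  are homogeneous across the tree within a run (group differences are
  assessed by running groups separately).
* The generator's tree-sample emulation does not vary topology (above).
* Convergence diagnostics beyond seed-replication are out of scope; the
  short-chain × many-trees design substitutes replication for long-chain
  diagnostics, and inherits that design's assumptions.
* X-autosome and Y-autosome fusions are not distinguished; sex-chromosome
  turnover is not modelled.

Every number quoted in this vignette is computed by the test suite
(`tests/testthat/`) or the acceptance script (`scripts/acceptance.R`), not
asserted from outside.
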