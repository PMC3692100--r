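---
title: "Detecting coevolving presence-absence characters: models and methods"
author: "phylocoev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coevolving presence-absence characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocoev)
```

## The problem

A phyletic pattern (phylogenetic profile) records the presence (1) or
absence (0) of binary characters — gene families, introns, restriction
sites, indels — across a set of species. The extant pattern is the outcome
of gain (0→1) and loss (1→0) events along the species phylogeny. Characters
whose gains and losses co-occur on the same branches more often than chance
allows are candidates for functional interaction: in prokaryotes,
co-gained and co-lost gene families frequently belong to the same pathway,
complex or phenotype module.

`phylocoev` detects such coevolving pairs. The pipeline is: fit a
probabilistic gain/loss model to the pattern on the tree; compute, for every
character and branch, the posterior expected numbers of gain and loss
events (stochastic mapping); score co-occurrence of mapped events between
character pairs; calibrate significance against simulations from the fitted
model; control the false discovery rate; and export the resulting network.
A phylogeny-naive alternative — correlating extant 0/1 columns directly —
confounds shared ancestry with interaction; mapping events onto branches is
what removes that confounding.

## The gain/loss model

Each character evolves by a two-state continuous-time Markov chain with
gain rate $g$ and loss rate $l$. The chain has eigenvalues $0$ and
$-(g+l)$, giving the closed form

$$P_{01}(t) = \pi_1\,(1 - e^{-(g+l)t}), \qquad
  P_{10}(t) = \pi_0\,(1 - e^{-(g+l)t}),$$

with stationary frequencies $(\pi_0, \pi_1) = (l, g)/(g+l)$. Three model
tiers describe among-character rate variation:

* **single** — one $(g, l)$ shared by all characters;
* **gamma_invariant** (default) — an overall rate multiplier follows a
  discretized gamma distribution (Yang-style mean-of-quantile-bin
  categories, default $K = 4$, equal weights) plus a zero-rate invariant
  category of proportion $p_\mathrm{inv}$; the multiplier scales $g$ and
  $l$ jointly;
* **mixture** — gain and loss multipliers vary independently, each with
  its own gamma shape, on a $K_g \times K_l$ product grid (default
  $3\times3$).

**Rate normalization.** Rates and branch lengths are confounded in any
such model. The mixture is rescaled once so that the expected number of
events per unit branch length at stationarity, averaged over categories
($\sum_c w_c\,(\pi_{0c} g_c + \pi_{1c} l_c)$), equals 1. Branch lengths are
then expressed in expected events per character, and the input tree's
branch lengths are used as given — only the model's free parameters are
estimated, with an optional single global branch-scale factor
(`fit_branch_scale`).

**Unobservable data.** A character absent from every genome never enters a
real dataset. With `correction = "no_absent"` (the default) every site
likelihood is divided by $1 - P(\text{all-absent})$, computed on the same
tree and mixture. All-present characters remain observable and are not
conditioned on. Two consequences ripple through the package:

* simulated data meant to emulate real input (`make_benchmark`, and null
  simulations compared against real data) reject all-absent draws
  (`condition_observable`), because the conditioned simulator's density is
  exactly the corrected likelihood — mixing an unconditioned simulator
  with a conditioned likelihood makes the estimator inconsistent;
* the corrected likelihood can be multimodal in the gain/loss ratio on
  heterogeneous data. The single-tier fit therefore scans a 33-point grid
  of $\log(g/l) \in [-8, 8]$ before Brent refinement; the multi-parameter
  tiers use Nelder-Mead from three fixed starts on transformed parameters
  ($\log$ ratio, $\log$ shapes, logit $p_\mathrm{inv}$), so all fits are
  deterministic.

Likelihoods are computed by Felsenstein pruning, vectorized over sites,
with per-node rescaling of partial likelihoods; the root prior of each
category is its stationary distribution (the invariant category carries
the base model's frequencies). Pruning is verified in the test suite
against exhaustive summation over interior states on small trees.

## Stochastic mapping

For each branch, rate category and endpoint-state pair $(a, b)$, the
conditional expected number of $i \to j$ transitions is the analytic
integral

$$E[N_{ij} \mid a, b] = \frac{q_{ij}}{P_{ab}(t)}
  \int_0^t P_{ai}(s)\, P_{jb}(t-s)\, ds,$$

evaluated in closed form from the two-eigenvalue structure (`expm1` keeps
small $(g+l)t$ accurate; the zero-rate category contributes exactly zero).
Endpoint-state posteriors per branch come from inside/outside partial
vectors; categories are mixed by their per-site posterior weights. Events
are attributed to branches of the rooted tree in root-to-tip direction —
rooting does not affect the likelihood (the chain is reversible) but fixes
the direction bookkeeping. The analytic expectations are validated against
adaptive quadrature and against million-trajectory Monte-Carlo simulation.

## Scoring and significance

The **coevolution score** of a character pair is the Pearson correlation of
their concatenated per-branch expected-gain and expected-loss vectors
(length $2 \times$ number of branches). Characters whose event vector is
constant carry no usable signal and are excluded with a warning.

The null distribution of this score depends strongly on event abundance:
two low-abundance characters whose single mapped event happens to fall on
the same branch correlate near 1 by chance. P-values therefore come from
**abundance-matched simulations**: `n_sims` independent characters are
simulated under the fitted model on the same tree, their events mapped
identically, and every disjoint simulated pair is scored. Null scores are
stratified on a grid of quantile bins (default $5 \times 5$) of per-site
total expected events, with bin edges taken from the real data; a real
pair is compared only against null pairs in its stratum. Strata below the
floor (100 samples) are pooled with nearest bins by growing Chebyshev
neighborhoods. The bank is computed block-wise, so tens of thousands of
simulated characters fit in memory.

The empirical p-value uses the add-one rule
$p = (1 + \#\{\text{null} \ge s\})/(N+1)$ — never zero, valid at finite
sample size, with an explicit floor of $1/(N+1)$. Benjamini-Hochberg
adjustment across all tested pairs gives q-values; the network keeps edges
with $q \le \alpha$ (default $\alpha = 0.01$).

**Simulation resolution.** The add-one floor interacts with multiplicity:
over $m$ pairs, BH at level $\alpha$ can only ever reject if some p-values
fall below $\alpha k/m$ at rank $k$. A null bank too small makes every
network empty regardless of signal. The package treats this as a sizing
rule: choose `n_sims` so the floor of the smallest stratum sits comfortably
(at least a factor of two) below the target threshold. This is why the
acceptance script uses larger banks for network construction than for
raw calibration checks.

## The synthetic-data generator

`simulate_independent_sites` draws a rate category per character, a root
state from that category's stationary frequencies, and then the full jump
process on every branch, recording actual event counts (so simulations can
serve as an oracle for the mapping). `simulate_coevolving_pair` evolves a
pair as one 4-state chain over $\{00, 01, 10, 11\}$ built from the two
marginal generators: every rate entering a concordant state (00 or 11) is
multiplied by the dependency factor $d$, every rate leaving one divided by
$d$. At $d = 1$ the generator is exactly the Kronecker sum of the
marginals (independence); at large $d$ the pair is held concordant and
each excursion of one character is rapidly followed by a compensating
event in the other — co-occurring gains and losses.

Default study conditions, chosen once:

* marginal rates $g : l = 1 : 2$, i.e. equilibrium presence $1/3$ —
  losses outpace gains, as is typical for accessory gene families;
* benchmark tree: 64 taxa, random topology, midpoint-rooted, total length
  16 expected events per character. The length is tied to the default
  $d = 16$: a coevolving pair leaves concordance at rate $\sim 2/d$ per
  unit length, so a total length of order $d$ yields roughly two
  excursions (about four co-occurring events) per true pair. On a much
  shorter tree the "coevolving" pairs freeze into constant columns with
  no events — a degenerate benchmark in which no event-based detector
  (and no biologist) could call coevolution;
* dependency $d = 16$; benchmark composition 50 coevolving pairs among
  400 independent characters; characters conditioned on observability.

What the generator does *not* emulate: real phylogeny shapes (it uses
random topologies with uniform branch lengths), branch-specific or
lineage-specific rate shifts, gene-to-gene rate correlation beyond the
designated pairs, copy-number variation, and annotation structure. Passing
benchmarks here therefore demonstrates internal statistical correctness —
calibration, FDR control, ranking — not performance on any particular
real dataset.

## Numerical and design choices

* Pairwise ML distances for NJ maximize the two-sequence likelihood of the
  reversible two-state chain with counted stationary frequencies; the
  divergence is split $t/2$ per branch (immaterial under reversibility),
  optimized by Brent to $10^{-8}$, and capped at 10 expected events per
  character (a saturation guard in the same spirit as infinite
  Jukes-Cantor distances). Degenerate all-constant matrices can fall back
  to frequencies $(0.5, 0.5)$.
* Neighbor joining is Saitou-Nei (via `ape::nj`); negative branch length
  estimates are clamped to zero and the unrooted result is midpoint-rooted
  (`phangorn::midpoint`).
* Trees with a basal multifurcation are accepted; the basal node serves as
  the root.
* Missing-data symbols are rejected rather than imputed: silently filling
  a `?` would change the likelihood in ways the user never sees.
* All stochastic steps take explicit integer seeds; identical
  configurations reproduce results byte-for-byte.

## Problem sizes used by the test suite

The test and acceptance experiments use 64-taxon trees with: 200
characters and 1000 null characters for p-value calibration; 2000
characters for rate-ratio recovery; 20 replicates of 300 characters (15
coevolving pairs, i.e. 10%, at $d = 16$) with 2000-character null banks
for FDR control; and the 50-pair / 400-independent benchmark for detector
comparison. These sizes give the relevant Monte-Carlo checks standard
errors well inside their tolerance bands while keeping a full run of the
suite to a few minutes.

## Known limitations

* Binary characters only; copy-number dynamics are out of scope.
* Scores are pairwise; triplet or higher-order dependencies are not
  modeled, and the network clustering offered is connected components.
* At stringent significance levels ($\alpha = 0.01$) over very many pairs,
  empirical p-value resolution — not signal — can dominate: the floor
  $1/(N+1)$ must clear $\alpha k / m$. The acceptance script reports the
  network at the level its bank can resolve, alongside the stricter level.
* The advantage of event-based scoring over extant correlation depends on
  the event regime: when coevolving pairs carry very few events, extant
  concordance is the only signal and the two detectors converge; the
  margin on the default benchmark is real but modest.
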