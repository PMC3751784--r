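---
title: "Inferring process-link networks from perturbed interactions: model and methods"
author: "mcmcbpn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring process-link networks from perturbed interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcmcbpn)
```

## The model

The inputs are an undirected gene interaction network \(G(V, E)\), a
catalog of processes \(P\) (gene sets), and a per-gene perturbation call
(differential-expression p-value at or below a threshold, default 0.05).
Genes absent from the p-value table are treated as unperturbed:
perturbation requires positive evidence. Before inference, processes are
screened to sizes 10–300 (removing overly-specific and overly-general
sets) and, when a per-process significance table is supplied, to q ≤ 0.1.

A pair of distinct processes cross-annotates an interaction when one
endpoint carries one process and the other endpoint the other process,
*unless* both endpoints carry both processes — such an interaction is
internal to the shared annotation, not an interface between the two
processes. The exclusion is applied per pair, not per edge: an edge whose
endpoints have identical annotation sets can still be cross-annotated by
pairs the endpoints do not fully share. The candidate links \(L\) are the
pairs with non-empty cross sets \(C_{ij}\); \(C\) is their union and
\(D \subseteq C\) the interactions with both endpoints perturbed.

A link set \(X\) explains the union of its cross sets. Classifying each
interaction of \(C\) by (perturbed?, explained?) gives the four counts
\(|I_{11}|, |I_{10}|, |I_{01}|, |I_{00}|\), and the posterior over states
\(m(\Phi, X)\), \(\Phi = (\lambda, \alpha, \beta)\), is proportional to

\[ \lambda^{|X|}(1-\lambda)^{|L\setminus X|}
   \alpha^{|I_{10}|}(1-\alpha)^{|I_{00}|}
   \beta^{|I_{01}|}(1-\beta)^{|I_{11}|}, \]

with a uniform (dropped) prior over parameter configurations. The three
parameters trade off against each other: a small \(\lambda\) favors few
links, a small \(\alpha\) favors explaining the perturbed interactions, a
small \(\beta\) penalizes explaining unperturbed ones.

### Parameter grids

Inference restricts the parameters to discrete grids:
\(\lambda \in \{10^{-5}, 5\cdot10^{-5}, 10^{-4}, 5\cdot10^{-4}, 10^{-3},
5\cdot10^{-3}, 0.01\} \cup \{0.05k\}_{k=1}^{10}\) (17 values, spanning
regimes from very sparse to dense link selection) and
\(\alpha, \beta \in \{0.05k\}_{k=1}^{19}\). Grid values are computed once
in `parameterGrids()` and reused everywhere, so equal parameters compare
exactly; user-supplied values are snapped to the grid within 1e-9 and
rejected otherwise.

## The sampler

States are explored by two move types: with probability ρ (default 0.9) a
link drawn uniformly from \(L\) is toggled — realizing the
one-more-or-one-fewer-link neighborhood with a constant neighbor count
\(|L|\) — and otherwise a (parameter, alternative grid value) pair is
drawn uniformly from all such pairs (16 + 18 + 18 = 52 under the default
grids). Because both neighbor counts are state-independent, the Hastings
correction cancels exactly and the acceptance probability is
\(\min(1, e^{\Delta})\) on the log-likelihood difference.

Each chain starts at \(X = \emptyset\) with each parameter drawn uniformly
from its grid, runs a burn-in (default \(10^7\) steps, contributing to no
counter), then records the current state once per step for the sampling
phase (default \(10^8\) steps), whether or not the proposal was accepted.
A link's posterior probability is its visit fraction; links at or above
θ = 0.7 form the BPN. Parameter posteriors are per-grid-value visit
fractions, with the reported mode breaking ties toward the smallest value
(deterministic reporting). Replicates derive their seeds as
`seed + run index`.

### Numerical and implementation choices

* All likelihood arithmetic is in log space. The state log-likelihood is
  always recomputed from the sufficient counts in O(1) — deltas are never
  accumulated — so there is no drift over \(10^8\)-step chains.
* The only mutated chain state is an integer per-interaction explanation
  counter; a link toggle costs time proportional to its cross set (only
  the 0↔1 transitions change the counts). The sampler kernel is compiled
  (Rcpp); the R-level `toggleDelta()`/`parameterDelta()` implement the
  same updates independently and the tests require the two routes to agree
  with full recomputation to 1e-9 over \(10^4\) random moves.
* Visit counters use run-length bookkeeping (a counter is flushed only
  when its entity changes), so recording is O(1) per step regardless of
  \(|L|\).
* The kernel draws from R's RNG stream; a chain is bit-reproducible from
  its `ChainConfig` seed.
* Interactions and links are stored as canonical (lexicographically
  sorted) unordered pairs, making all set operations orientation-stable.

### The link universe

By default \(|L|\) in the prior term counts the cross-annotating pairs:
a pair that cross-annotates nothing can never explain an interaction, and
including such pairs in the proposal space would only dilute it. A
`linkUniverse = "all"` mode counts all \(\binom{|P|}{2}\) pairs instead.
Proposals still toggle only cross-annotating links: a link with an empty
cross set touches no confusion count, so its posterior inclusion
probability factorizes to exactly \(\lambda\) independent of everything
else — restricting proposals while enlarging the prior denominator is
exact marginalization, not an approximation.

### The explain-nothing optimum and the β cap

The posterior is bimodal in a characteristic way: a chain can settle at
\(X = \emptyset\) with \(\alpha \approx |D|/|C|\), where β is
unidentified (no explained interactions) and drifts freely. While β sits
high, adding a true link gains almost nothing — at β = 0.8, α = 0.2 the
per-interaction terms cancel exactly — so escape requires β to random-walk
down first, which can exceed short chains. The standard remedy is capping
the β grid (`betaMax = 0.7`), which keeps every true link's inclusion gain
decisively positive; it is off by default and enabled in the packaged
recovery experiment.

## The BPLN baseline

For comparison, `computeBPLN()` implements the linkage-network baseline on
the subnetwork induced by \(D\): for each ordered pair (from, to), it
counts the genes of *to* adjacent to at least one gene of *from* and
applies a one-sided Fisher's exact test (hypergeometric upper tail) with
the subnetwork's genes as the universe. The 2×2 construction takes the
most literal reading of the neighbor-count definition: a gene annotated to
both processes counts toward the *to* margin and is adjacent only via
neighbors other than itself; pairs with no *to* gene in the universe are
untestable and skipped rather than assigned p = 1. BH correction is
applied across all directed tests as one family (the correction is for the
whole screen, not per source process), and an undirected link is reported
when either direction reaches q ≤ 0.05. `bplnThresholdSweep()` returns the
smallest p-value cutoff yielding at least a target number of undirected
links, for size-matched comparisons against a BPN.

## Redundancy and consistency metrics

Within a BPN, every link pair is compared by the Jaccard index of their
explained interactions, separately over perturbed and unperturbed ones;
each link's maximum JI is histogrammed in bins of width 0.2 (right-open
except the last, [0.8, 1]). The JI of two empty sets is defined as 0,
avoiding spurious perfect overlap between links that explain nothing in
the compared stratum; links whose comparison sets are all empty are
excluded from the histogram and counted separately. The
links-per-interaction distribution reports, for each k ≥ 1, the fraction
of explained interactions explained by exactly k links. Across replicate
runs, `bpnOverlap()` reports three JIs — link sets, explained perturbed,
explained unperturbed — and replicate averages are plain means over runs.

## The synthetic generator

`generateInstance()` inverts the observation model: it builds a catalog
(process sizes uniform in a range, each gene slot reusing an existing gene
with probability `overlapFraction`, which creates the multiply-annotated
genes that exercise the cross-annotation exclusion), an Erdős–Rényi
network over annotated plus background genes, plants
\(X^* \sim\) Bernoulli(\(\lambda^*\)) over the candidate links, and labels
interactions perturbed with probability \(1-\beta^*\) (explained) or
\(\alpha^*\) (unexplained).

Perturbation is assigned at the interaction level, matching the
likelihood. The default `"interaction"` mode keeps those exact labels in
the returned index, for exact likelihood and recovery tests. The `"gene"`
mode emits only a gene-level profile (endpoints of perturbed interactions
get p = 0.01, all other genes 0.5) and recomputes the index from it; this
exercises the full I/O path but can incidentally perturb extra
interactions whose endpoints were each perturbed via different
interactions, so the realized \(D\) is reported as the effective truth.

What the generator does *not* emulate: microarray intensities or the
upstream differential-expression analysis, scale-free or modular network
topology, and annotation biases of real gene-set catalogs. Passing tests
on synthetic instances therefore demonstrate correctness of the inference
machinery under the model's own assumptions, not robustness to their
violation on real data.

### The packaged recovery experiment

`recoveryExperiment()` is the standard validation run: 30 processes of
20–30 genes, 50 background genes, edge probability 0.1, overlap 0.1,
planted \(\Phi^* = (0.01, 0.2, 0.35)\), five replicate chains of \(10^6\)
recorded steps after \(10^5\) burn-in with the β grid capped at 0.7.
Two deliberate design choices make the experiment well-posed:

* **Sizing.** A planted link with cross set size \(m\) is recoverable only
  if its inclusion gain
  \(-\mathrm{logit}(\lambda) + m[0.65\ln\frac{1-\beta}{\alpha} +
  0.35\ln\frac{\beta}{1-\alpha}] \approx -4.6 + 0.48\,m\)
  is decisively positive, i.e. \(m \gtrsim 15\). The chosen process sizes
  and edge density give every planted link \(m \approx 40\text{–}95\)
  while keeping the instance around 20,000 cross-annotated interactions.
* **Conditioned realization.** At \(|L| = 435\) candidate links, an
  unconditioned Bernoulli draw of \(X^*\) and of the noise labels leaves
  the identifiable optimum one grid step away from the planted values for
  an appreciable fraction of instances (e.g. the λ mode is 0.01 only when
  \(|X^*| \in \{4, 5\}\)). The experiment therefore conditions the
  realization on its expectation: `fixedLinkCount` plants exactly
  \(\mathrm{round}(\lambda^* |L|)\) links and `balancedNoise` realizes
  exactly the rounded expected number of perturbed labels per stratum.
  The experiment then measures what it is meant to measure — whether the
  chain converges to the known optimum — rather than binomial noise in
  the instance. Both options are off by default in `generateInstance()`.

## Problem sizes in the test suite

The shipped tests run the worked six-gene example exactly; exhaustive
oracles (all \(2^{|L|}\) states, all 2×2 tables to universe 30, literal
triple-loop cross-annotation) on instances small enough to enumerate;
\(10^6\)-step chains for the stationarity and recovery checks; and
\(10^4\)-move incremental-likelihood audits. These sizes were chosen so
the full suite completes in about a minute while every check retains
sensible statistical power; the sampler itself is routinely run at the
\(10^7/10^8\)-step defaults.

## Known limitations

* The likelihood treats interactions as exchangeable given their
  explained/perturbed status; confidence scores are used only as a load
  filter, never as weights.
* Identifier matching is exact and case-sensitive; cross-namespace mapping
  must happen upstream.
* Links are undirected and the method does not model directionality of
  influence between processes.
* Very small cross sets are intrinsically unidentifiable (see the sizing
  bound above): absence of a weakly-supported link from a BPN is not
  evidence of absence.
* Convergence monitoring is limited to the stationarity diagnostics
  described here; no automatic restart or tempering is provided.
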