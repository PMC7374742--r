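---
title: "Methods: key-protein inference and MAPK kinetics in netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: key-protein inference and MAPK kinetics in netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

# The problem

A pleiotropic small molecule rewires a protein interaction network (PIN)
rather than hitting a single target. Given (i) an edge list of
confidence-scored protein associations, (ii) gene-set annotations of
pathways, and (iii) a kinetic model of the signalling cascade downstream of
the strongest candidate target, `netpharm` asks: *which proteins are the key
regulators of the compound's network effect, and what does inhibiting the
top one do to its cascade?*

The chain is: topology → dense-module detection → pathway enrichment →
prioritization → kinetics. This vignette documents the model behind each
stage, the tunable parameters, the numerical choices, and what the
synthetic test beds do and do not establish.

# Network topology

Networks are undirected simple graphs. Edge confidence scores (STRING's
0–1000 scale) gate which edges enter the network (`score_threshold`,
default 900 = "highest confidence"; 700 = "high confidence" is the other
conventional setting) but are ignored by all topology computations — the
metrics reported by the usual PIN tooling (Cytoscape's Network Analyzer and
cytoHubba) are unweighted, and we match their conventions so values are
comparable:

* **Degree distribution and power-law fit.** Scale-free behaviour is
  diagnosed by ordinary least squares of $\log_{10} n(k)$ on
  $\log_{10} k$, so $n(k) = a\,k^b$ with $a = 10^{\mathrm{intercept}}$ and
  $b$ the slope, $R^2$ on the log–log scale. Zero-degree and zero-count
  bins are excluded (they have no logarithm); nonlinear least squares is
  deliberately not used, again to match the convention of the tooling this
  mirrors. On noiseless power-law data the fit recovers $(a, b)$ to
  machine precision with $R^2 = 1$; for noiseless *constant* counts the
  total log-variance is zero and $R^2$ is defined as 1 by convention.
* **Clustering coefficient** $C(v) = 2 e_{N(v)} / (d_v (d_v - 1))$, zero
  for degree < 2; the network value is the mean over all nodes including
  isolates.
* **Characteristic path length**: mean shortest-path length over unordered
  *connected* pairs; unreachable pairs are excluded from numerator and
  denominator, so disconnected graphs are handled without an arbitrary
  penalty distance.
* **Betweenness**: Brandes shortest-path betweenness, undirected,
  unnormalized, endpoints excluded, each unordered pair counted once —
  the magnitudes cytoHubba prints (thousands on a few-hundred-node PIN)
  force the unnormalized convention.
* **Closeness**: the *harmonic* form
  $\mathrm{Clo}(v) = \sum_{u \ne v} 1/d(v, u)$ with unreachable nodes
  contributing zero. Published closeness columns with values far above 1
  (e.g. 155.83 on a 295-node network) imply a reciprocal-distance sum
  rather than the normalized inverse-average; this choice is recorded
  here as ours, since the original tables cannot arbitrate it exactly.

## BottleNeck centrality

The selection statistic for candidate regulators is the cytoHubba
*BottleNeck* score. For every root $s$, grow the BFS shortest-path tree
$T_s$; for a non-root $v$ let $p_s(v)$ be the number of tree nodes whose
root-path passes through $v$ (equivalently the size of $v$'s subtree,
counting $v$). Then

$$\mathrm{BN}(v) = \#\{s : p_s(v) > |V(T_s)|/4\}.$$

A protein scores highly when it is the trunk through which a quarter of
the tree flows from many vantage points — a bridge or tunnel in the
network's shortest-path traffic, empirically a stronger essentiality
signal than raw degree. The original description leaves tree construction
under-determined, so we pin it for determinism: BFS parents are chosen by
lexicographic node order among equally close candidates, every node serves
as a root, the root itself never scores, the inequality is strict, and
$v$ counts in its own $p_s(v)$. Tests verify the implementation against an
independently written tree-walker on batteries of small random graphs.

# MCODE module detection

Dense "molecular complexes" are detected with a from-scratch MCODE:

1. **Vertex weighting.** For each $v$, take the closed neighbourhood
   subgraph $G_v$, find its highest $k$-core, and set
   $w(v) = k_{\max} \times \mathrm{density}(k_{\max}\text{-core})$. The
   core-density product rewards locally dense, non-chained neighbourhoods.
2. **Complex prediction.** Seed at the highest-weight unvisited vertex and
   expand breadth-first, admitting unvisited neighbours with
   $w \ge w_{\mathrm{seed}} (1 - \texttt{node\_score\_cutoff})$
   (inclusive), to at most `max_depth` levels. Visited marking makes
   complexes disjoint.
3. **Post-processing.** *Haircut* iteratively removes members with fewer
   than two intra-complex links (leaf removal cannot disconnect a
   complex); optional *fluff* (off by default, as in the plugin) adds
   boundary nodes whose neighbourhood density exceeds
   `fluff_density_cutoff`. Complexes with no 2-core are discarded.
4. **Scoring.** $\mathrm{score} = \mathrm{density} \times |V|$; a higher
   score is a tighter module. Output is sorted by score, ties by seed
   name; every tie-break in the algorithm is lexicographic so results are
   bit-reproducible.

Defaults (`degree_cutoff = 2`, `node_score_cutoff = 0.2`,
`k_core_filter = 2`, `max_depth = 100`, haircut on, fluff off) are the
plugin's documented defaults. One direction note: because the admission
threshold is $w_{\mathrm{seed}}(1-c)$, *raising* `node_score_cutoff`
loosens admission; the monotone-inclusion property (tighter cutoff ⊆
looser cutoff, per complex) is tested in that direction.

# Enrichment and term grouping

For a query of $n$ genes against a term of $K$ genes in a universe of $N$,
with overlap $k$, the two-sided p-value is the doubled smaller tail of
$X \sim \mathrm{Hypergeom}(N, K, n)$, capped at one:
$p = \min(1,\, 2\min(P(X \ge k), P(X \le k)))$. "Two-sided" has no unique
definition for discrete distributions; the doubled-tail form is the one
compatible with the ClueGO-style tooling this mirrors and is pinned here.
Bonferroni correction multiplies by the number of *tested* terms (those
with $k \ge 1$) by default — a switch restores correction over all
annotation terms — and records with $p_{\mathrm{bonf}} < \alpha$
(default 0.05, strict) are retained.

Redundant terms are grouped by Cohen's kappa between their query-hit
membership vectors over the universe, with an edge at $\kappa \ge 0.4$ and
groups taken as connected components, numbered from 0 in descending size
(ties by lexicographic leading term). ClueGO's full iterative merge
(initial kappa groups merged at 50% overlap) is deliberately simplified to
components: the published group tables give no grouping parameters to
reconstruct, and components are deterministic and order-independent, which
the tests rely on. Kappa degenerates when both marginals are saturated
($p_e = 1$); identical sets then score 1.

# Prioritization cascade

The key-regulator selection composes four steps, each with a documented
convention forced by the published 22 → 12 reduction it reproduces:

1. **Top bottleneck**: keep nodes in the `k_levels = 10` largest
   *distinct* BottleNeck values with ties retained — the only reading
   under which a "10 best scores" table can hold 22 proteins (scores 52
   down to 5 with shared levels).
2. **Date-hub filter**: keep clustering coefficient strictly below
   `cc_threshold = 0.5`. Low-co-clustering hubs ("date hubs") bind
   partners sequentially and are the plausible regulatory bottlenecks;
   party hubs (≥ 0.5) are excluded at the boundary.
3. **Pathway coverage**: per candidate, the number of term groups whose
   associated genes contain it; proteins in no group count zero and stay
   in the sample.
4. **Median cutoff**: the standard sample median of all counts (even
   $n$: mean of the middle pair), selection at count ≥ median. On the
   transcribed tables the median is exactly 7 and the two proteins at 7
   (CREB1, CASP8) are selected, which forces ≥ rather than >.

Identifiers are matched literally, with no alias resolution: the candidate
table prints the legacy symbol IL8 while the pathway groups carry CXCL8,
so IL8 counts zero — consistent with the published treatment of that row.

# Mass-action kinetics

`kinetic_model` holds species (µM) and reactions with integer
stoichiometries, mass-action rate laws, and optional reverse constants;
`simulate_model` integrates $\dot c = S\,v(c)$ with `deSolve::lsoda`
(stiff-capable) at `rtol = 1e-8`, `atol = 1e-10`, reporting 1,501 uniform
points by default — pinned so trajectories are reproducible and converged
(tests show a 10× tolerance tightening moves 150 s concentrations by far
less than 1e-4 µM). SBML level-2 input is supported for the mass-action
subset (products of constants and reactant concentrations, optionally a
forward-minus-reverse difference); any other rate law is rejected naming
the offending reaction.

The shipped cascade (`mapk_cascade_model()`, also as SBML in
`inst/extdata/`) is an in-code transcription of the curated BioModels
entry BIOMD0000000009 — Huang & Ferrell's ultrasensitive MAPK cascade —
as 10 enzyme–substrate binding equilibria ($a = 1000\ \mu M^{-1}s^{-1}$,
$d = 150\ s^{-1}$) each followed by irreversible catalysis
($k = 150\ s^{-1}$), with initial concentrations MAPKKK $3\times10^{-3}$,
MAPKK 1.2, MAPK 1.2, E1 $3\times10^{-5}$, E2 $3\times10^{-4}$, MAPKK
phosphatase $3\times10^{-4}$, MAPK phosphatase 0.12 µM. The transcription
is validated by the tests: each kinase moiety is conserved to $10^{-6}$ µM
along the 150 s trajectory, and the simulated free and doubly
phosphorylated MAPK at 150 s match the values published for this model to
better than 0.1%.

**Inhibitor injection.** `add_inhibitor()` adds a free-inhibitor species
(default 20 µM, the concentration conventionally assigned to curcumin) and
one inert complex per target with reversible binding
$T + I \rightleftharpoons TI$. Binding is to unphosphorylated MAPK by
default; the target list is explicit, because which MAPK forms the
compound binds in vivo is not settled. The association/dissociation pair
is a *required* argument with no hidden default: the docking-derived
$K_i = 662.55$ nM suggests the illustrative pairing
$k_{on} = 1\ \mu M^{-1}s^{-1}$, $k_{off} = 6.6255\times10^{-4}\ s^{-1}$
used in examples and tests, but that is a reconstruction — published
inhibited-trajectory concentrations depend on unpublished rate constants
and are therefore documented, not targeted. What the package *does*
guarantee, and tests, is structural: inhibitor moiety conservation to
$10^{-6}$ µM, a null perturbation at $k_{on} = 0$, and depression of
activated MAPK under sequestration.

# Synthetic data: what it emulates, and what it does not

The generators are seeded and bit-reproducible:

* `scale_free_graph(n, m, seed)` — preferential attachment pinned to a
  deterministic variant (start from an $(m{+}1)$-star; each arrival
  attaches to $m$ distinct degree-weighted targets), so the edge count is
  exactly $(n-m)m$ and tests can assert it.
* `random_graph(n, p, seed)` — Erdős–Rényi, the null model against which
  scale-free fits are compared.
* `planted_modules_graph` — disjoint cliques bridged once into an ER
  background; the known membership makes MCODE recovery quantifiable
  (top-module Jaccard ≥ 0.8 across seeds at background density 0.03).
* `annotation_with_planted_term` — one term enriched by construction
  (defaults: universe 1,000, 50 terms of 40 genes, query 25 with 20
  planted), giving a power test bed where the planted term survives
  Bonferroni in ≥ 45/50 seeds.
* `toy_cascade_model` — a three-tier activation cascade with closed-form
  pieces and unit moiety totals for solver checks.

These beds establish *algorithmic correctness*: metrics equal brute-force
enumeration, planted structure is recovered, planted enrichment is
detected, solvers match closed forms. They do not establish that any
specific historical PIN is reproduced: global statistics of a published
network (node counts, degree exponent, path length, module count) depend
on the interaction-database version and retrieval settings and are
explicitly out of reach; the transcribed candidate and pathway tables are
the fixture of record for the downstream cascade instead. Test problem
sizes — ER oracles at ≤ 30 nodes, brute-force centrality batteries at
5–12 nodes, BA fits at 600 nodes, 20–50 seed replicates — were chosen as
the smallest sizes at which the checked properties are non-trivial.

# Known limitations

* No identifier mapping: IL8 vs CXCL8 and similar aliasing is the data
  author's responsibility.
* Enrichment grouping is components-at-$\kappa \ge 0.4$, not the full
  iterative ClueGO merge; with very dense term overlap the two can give
  different group counts.
* SBML support is intentionally the mass-action subset: no events, rules,
  function definitions, or Michaelis–Menten laws.
* No stochastic simulation and no parameter fitting; the kinetics module
  answers "what does this mass-action system do", not "what are its
  constants".
* Two cells of the transcribed candidate table (and the
  betweenness/closeness block of five further rows) are typographically
  ambiguous in the source and are flagged `ambiguous = TRUE`; nothing in
  the package asserts on them.
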