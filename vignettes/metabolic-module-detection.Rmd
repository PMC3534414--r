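---
title: "Detecting functional metabolic modules from time-course profiles and transcript evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting functional metabolic modules from time-course profiles and transcript evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamod)
```

## The problem

Organisms that survive complete desiccation — tardigrades are the canonical
example — shut their metabolism down during dehydration and restart it upon
rehydration. Time-resolved GC-MS metabolite profiles across such a
transition, together with state-specific transcript evidence (EST libraries
from the active and the inactive animal), carry complementary information:
the profiles say *which metabolites* change, the transcripts say *which
reactions* are catalysed and how their enzyme abundance differs between
states. `metamod` integrates both on a metabolic reaction network and
extracts a single connected, maximum-scoring subnetwork — a *functional
module* — of concerted metabolic change.

The pipeline has four stages, each usable on its own:

1. **Network construction** from KEGG KGML pathway files.
2. **Node scoring** from trend tests on the metabolite time courses, via a
   beta-uniform mixture (BUM) model of the p-value distribution.
3. **Edge scoring** from enzyme presence (EST-to-EC mappings) and
   differential EST counts.
4. **Module extraction** as a maximum-weight connected subgraph (MWCS),
   solved exactly by branch and bound, in a two-step
   enrichment-then-module procedure.

## Network construction

Each KGML pathway is converted to a graph with compounds as nodes and
reactions as edges; a reaction with several substrates and products
contributes one edge per substrate-product pair. Pathway graphs are merged
into one supergraph (union semantics: an edge present in two pathways keeps
both reaction identifiers), converted to an undirected graph, and cleaned in
two ways:

* **Anomer fusion.** α- and β-anomers of common carbohydrates are chemically
  distinct nodes in KEGG but indistinguishable to the profiling platform;
  they are fused to a canonical compound (e.g. α- and β-D-glucose to
  D-glucose), with all incident edges re-attached. The fusion table is
  configuration, not code (`default_fusion_table()`, or a two-column TSV);
  the shipped default covers the common hexoses.
* **Pool-metabolite removal.** Thirteen cofactor-like "currency" compounds
  (H+, H2O, orthophosphate, ATP, NAD+, NADH, ADP, CO2, CoA, NADP+, NADPH,
  NH3, diphosphate) connect otherwise unrelated reactions and would act as
  biologically meaningless shortcuts in a connectivity-driven search; they
  are removed with all incident edges. The listed names are resolved to
  KEGG compound IDs ("P" as orthophosphate C00009, "PP" as diphosphate
  C00013) because names are ambiguous and IDs are not.

Reversibility is recorded during parsing but plays no role after the
undirected conversion. Parallel edges are merged (annotations unioned)
rather than kept as a multigraph, because the scoring model assigns one
score per node pair.

```{r}
f <- system.file("extdata", "toy_glycolysis.xml", package = "metamod")
net <- build_reference_network(
  f,
  fusion_table = read_fusion_table(
    system.file("extdata", "anomer_fusion.tsv", package = "metamod")),
  pool = read_pool_list(
    system.file("extdata", "pool_metabolites.tsv", package = "metamod")))
igraph::V(net)$name
```

## Trend tests on time-course profiles

The experimental design is k ordered time points (default 20: ten
dehydration, ten rehydration) with technical replicates (default 4) per
point. Metabolism is expected to be minimal at the dehydration endpoint, so
the biologically interesting alternative is not a monotone trend but a
*peaked* one: a rise to the turning point followed by a fall (storage
metabolites, bioprotectants) or its mirror image (energy metabolism).

* `jt_test()` implements the Jonckheere-Terpstra test for monotone trends:
  the statistic is the sum of Mann-Whitney counts over ordered group pairs.
* `umbrella_test()` implements the Mack-Wolfe umbrella test with known peak
  `l`: Mann-Whitney counts run forward up to the peak and backward after
  it. With `peak = k` it reduces exactly to the JT statistic. The
  standardized statistic Z is signed: positive for an umbrella shape,
  negative for an inverse umbrella. Two-sided p-values are the default
  (both directions are biologically meaningful); one-sided tests are
  available by flag.

Ties are handled by midranks (a tied pair counts 0.5). Three p-value
methods are provided: the normal approximation with the closed-form null
moments (tie-corrected variance for JT; the Mack-Wolfe null moments for the
umbrella statistic) and a 0.5 continuity correction, exact enumeration over
all distinct group assignments (the reference method for small or heavily
tied samples), and seeded Monte-Carlo permutation (default 10,000 draws).
The closed-form moments are not taken on trust: the test suite checks them
against the exact permutation distribution, and the exact method against an
independent full-factorial enumeration oracle.

The peak defaults to time point 10 — the end of dehydration, where the
transition to the inactive state is complete. `wilcoxon_phase_test()`
provides the simpler two-phase location comparison (pooled dehydration vs
rehydration measurements, rank-sum test), which is useful as a baseline but
blind to peaked shapes.

`correspondence_analysis()` (backed by `vegan::cca`) gives a low-dimensional
view of the profile matrix; inertia fractions report how much structure the
leading axes capture. Normalized profiles may contain negative values, which
a correspondence table cannot; affected rows are shifted by their minimum to
nonnegativity (recorded in the result), since the analysis is used purely
descriptively here.

## Node scores from a beta-uniform mixture

Under the null, trend-test p-values are uniform; signal concentrates near
zero. The mixture
\[ f(x) = \lambda + (1 - \lambda)\, a\, x^{a-1}, \qquad 0 < a < 1 \]
captures this with a uniform noise component and a Beta(a, 1) signal
component. `fit_bum()` obtains maximum-likelihood estimates by
box-constrained optimization from a 25-point deterministic grid of starting
values. The quantity \(\pi = f(1) = \lambda + (1-\lambda)a\) bounds the
noise fraction from above; \(1 - \pi\) is a lower bound on the signal
fraction.

Node scores are the FDR-calibrated log likelihood ratio
\[ S(x) = (a - 1)\,(\log x - \log \tau(\mathrm{FDR})), \]
with natural logarithms and
\(\tau = \big(\frac{\pi - \mathrm{FDR}\,\pi}{\mathrm{FDR} - \mathrm{FDR}\,\pi}\big)^{1/(a-1)}\).
A node scores positive exactly when its p-value beats the threshold
\(\tau\); the module search FDR defaults to 0.2, which deliberately admits
moderate evidence — the connectivity requirement provides the additional
filtering. Unmeasured metabolites (most of a reference network) receive the
mean of the negative measured scores: a score drawn from the noise level of
the data, so that unmeasured nodes are mild connectors rather than free or
forbidden. p-values of exactly zero are clamped to 1e-12 before the
logarithm and the clamping is reported.

## Edge scores from transcript evidence

Two evidence layers, two orders of magnitude apart by design:

* **Presence** (`score_edges_presence()`): an edge whose EC annotation
  matches the EST-derived EC set scores +0.01, otherwise −0.01. Partial EC
  numbers ("2.2.1.-") match field-wise with "-" as a wildcard. These small
  weights bias the search toward reactions whose enzyme demonstrably exists
  in the organism without ever dominating a measured signal.
* **Differential abundance** (`score_edges_dest()`): for edges with
  KO-mapped differential-EST clusters,
  \( S_e = |\log_2((n_a + c)/(n_i + c))| - t \),
  where \(n_a, n_i\) are active/inactive counts, \(c\) a pseudocount
  (default 1; \(c = 0\) is allowed but rejects zero counts), and
  \(t \ge 0\) a sensitivity threshold (default 1) playing the same role for
  edges that the FDR plays for nodes. The score is bounded below by
  \(-t\), attained at equal counts. When several clusters map to one edge
  the maximum (most informative) score is used; when one KO maps to several
  edges, all of them receive the evidence — the data cannot distinguish
  among them. Edges without differential evidence fall back to their
  presence score. No clamping is applied by default; an optional symmetric
  clamp is available.

## Maximum-weight connected subgraph

A module is a connected subgraph; its score is the sum of selected node and
edge scores. Positive induced edges always belong to an optimal edge set;
negative edges enter only when needed for connectivity, chosen as a
maximum-weight spanning connection across the components formed by the
positive edges.

Three solvers share this definition:

* `brute_force_mwcs()` enumerates every connected induced subset (networks
  up to 15 nodes); it exists as the exactness oracle for the tests.
* `exact_mwcs()` is a depth-first branch and bound over connected subsets:
  minimum-index rooting visits each subset once; the admissible bound adds
  the positive node and edge mass still reachable from the current subset
  to its committed score; a heuristic warm start provides the initial
  incumbent. The returned status is "optimal", or "time-limit" with the
  best feasible solution when the optional wall-clock limit is hit. The
  connectivity structure is handled directly in the search rather than
  through flow constraints, since no integer-programming backend is
  required this way.
* `heuristic_mwcs()` groups positive nodes into seed components, connects
  seeds along cheapest paths (edge transit cost = negative part of the edge
  score plus half the negative parts of its endpoint scores) while the
  attachment gain is positive, and prunes score-decreasing leaves. It is
  feasible by construction and never reported as optimal.

Worst-case exactness is NP-hard: instances whose scores hover near zero
(e.g. a weak, unstable BUM fit on very few p-values) can make the exact
search expensive, which is why `time_limit` exists and why the heuristic is
the practical choice beyond a few hundred nodes. Equal-score optima are
disambiguated by an epsilon perturbation (−1e-9 × node-ID rank), making the
returned module reproducible; reported scores are recomputed unperturbed.
Top-K enumeration re-solves with previously found node sets excluded.

## The two-step module search

1. **Enrichment** (`enrich_network()`): measured metabolites score +1,
   unmeasured ones −0.001, edges ±0.01 by enzyme presence. The
   maximum-scoring subnetwork under these scores is the organism-specific
   subnetwork: it aggregates metabolites and reactions for which any
   evidence exists. The unmeasured-node score is deliberately small and
   negative — zero would admit arbitrary unmeasured appendages, a large
   penalty would forbid necessary connectors. By default the enriched
   network is the subgraph induced by the selected nodes; the
   solver-selected edge set can be requested instead
   (`edge_semantics = "selected"`).
2. **Module** (`find_functional_module()`): on the enriched network, BUM
   node scores (FDR 0.2) and differential-EST edge scores (t = 1) replace
   the enrichment scores, and the solver runs again. Differential edges
   score in [−1, 1] for typical counts — a hundredfold the presence
   weights, so abundance changes dominate mere existence. The module is
   annotated per node with the signed Z (umbrella vs inverse umbrella) and
   per edge with its evidence class (differential / present / absent).

`run_pipeline()` chains every stage; the `metamod` command-line script
exposes the same steps as subcommands (`simulate`, `build-network`,
`trend`, `fit-bum`, `score`, `module`, `run-all`) with a TOML-style config
file, CLI flags taking precedence, and the resolved configuration
serialized next to the outputs.

## What the synthetic data emulates — and what it does not

`simulate_profiles()` draws tent-shaped (umbrella), mirrored, linear and
constant time courses on the 20-point dehydration/rehydration grid with
Gaussian replicate noise; `simulate_network()` builds connected sparse
networks (random spanning tree plus extra edges); `plant_module()` embeds a
connected module whose nodes get peaked profiles and whose edges get
Poisson differential-EST counts with a planted fold change, while
everything else is null. Defaults — effect 1, noise SD 0.3, 4 replicates,
peak at time point 10, Poisson baseline 5 with fold change 4, 30-node
networks with mean degree 3 and 8-node planted modules — were chosen once
to represent a clearly detectable but noisy signal at the scale of the
motivating experiment (84 measured metabolites, 4 technical replicates),
and they are the conditions under which the recovery tests run.

What passing these tests shows: the statistics are calibrated (type-I error
at nominal level, BUM parameter recovery, exact solver agreement with
enumeration) and the pipeline recovers planted structure (median node
Jaccard ≥ 0.8 over 20 seeded replicates at the default signal). What it
does not show: robustness to the things real GC-MS and EST data add —
correlated replicate noise, batch and normalization artifacts, missing and
censored measurements, annotation errors in the EC/KO mappings, and a
reference network whose topology is itself incomplete. The generators make
no attempt to simulate spectra or sequence reads.

## Numerical choices and degenerate inputs

* Midranks for ties everywhere; the exact permutation method is the
  reference when ties make the closed-form variance approximate.
* Normal-approximation p-values carry a 0.5 continuity correction; on
  continuous six-observation inputs this keeps them within 0.05 of the
  exact permutation p-value. Heavily tied tiny samples have permutation
  distributions too coarse for any continuous approximation — use
  `method = "exact"` there.
* All-constant data: z = 0, p = 1 by convention.
* BUM fitting requires ≥ 20 p-values; with only dozens the fit is noisy
  and \(\tau\) unstable — module results from very few measured
  metabolites deserve skepticism regardless of solver exactness.
* `fdr_threshold()` clips \(\tau\) into (0, 1]; degenerate all-noise fits
  (\(\pi \to 1\)) drive \(\tau \to 0\) and all scores negative, so the
  empty module is returned rather than an artifact.
* CA refuses all-zero rows or columns by name; negative rows are shifted.
* Problem sizes in the test suite (2000-profile null calibrations,
  100 solver cross-checks at ≤ 12 nodes, 20 recovery replicates at 30
  nodes) are the package's chosen validation scale: large enough for the
  asserted tolerances, small enough to run routinely.

## Known limitations

* Network construction depends on the KGML snapshot used; node and edge
  counts are not comparable across KEGG releases, and the anomer fusion
  table is intentionally minimal.
* The Mack-Wolfe normal approximation has no closed-form tie correction;
  for replicate-heavy tied data prefer the permutation methods.
* Exact module optimality on thousands of nodes is not guaranteed within
  bounded time; status and the time limit make this explicit.
* EST counts are semi-quantitative; the pseudocount and threshold t shape
  the edge scores more strongly than any distributional assumption, and
  both are exposed as parameters.
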