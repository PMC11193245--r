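---
title: "Learning Synthea disease-module graphs from OMOP event histories"
author: "synthgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning Synthea disease-module graphs from OMOP event histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthgraph)
```

## The problem

Synthea generates lifelong synthetic electronic health records by sampling
hand-built *disease modules*: directed state graphs whose nodes are clinical
states and whose `distributed_transition` edges carry probabilities. Building
such modules by hand is expensive. This package learns candidate module
graphs directly from observational data in the OMOP Common Data Model: each
patient's diagnoses (`condition_occurrence`) and procedures
(`procedure_occurrence`) are flattened into one discrete event sequence, a
set of weighted temporal rules is learned from the sequence database, and
the rules are emitted as a valid Synthea module that can itself be sampled.

Throughout, a patient history is a discrete time series
$x_{n,t} \in \mathcal{C}^D$: the time axis is the *event index* (position in
the ordered sequence), not calendar time. Calendar dates are used only to
order events; same-day events are ordered by ascending concept id so that
the extraction is deterministic and permutation-invariant in the input rows.
Every sequence is framed by START/STOP sentinels (reserved ids −1/−2) so the
learners can model which observations open and close a history, and so the
mapped module has the `Initial` and `Terminal` states sampling requires.

## The three learners

**Markov chain.** Every observation (plus the sentinels) is a state and

$$P(\text{consequent}\mid\text{antecedent})
  = \frac{\#(\text{antecedent},\text{consequent})}
         {\#(\text{antecedent},\cdot)}$$

is the maximum-likelihood estimate from adjacent-pair counts pooled over all
patients. We deliberately pool counts rather than average per-patient
probabilities: the two readings agree when patients contribute equally, and
pooling is the MLE of the population chain. No smoothing is applied; with a
default probability threshold of 0 the extracted graph keeps every observed
transition, which is why Markov graphs *extract* (grow with the data) rather
than compress.

**Temporal association rule mining.** For ordered concepts $(X, Y)$ over the
sequence database $S$,

$$seqSup(X \to Y) = \frac{sup(X\,Y)}{|S|}, \qquad
  seqConf(X \to Y) = \frac{sup(X\,Y)}{sup(X)},$$

where $sup(X\,Y)$ counts sequences in which some occurrence of $X$ strictly
precedes some occurrence of $Y$ (each sequence contributes at most once; for
$X = Y$ two occurrences are required). Rules are restricted to singleton
antecedents/consequents because the downstream Synthea edge is pairwise;
mining is a brute-force scan over all $D^2$ ordered pairs, $O(N T + N k^2)$
per dataset with $k$ distinct concepts per sequence, which is entirely
adequate at the scales the package targets. Defaults are
`minSeqSup = 0.1`, `minSeqConf = 0.5`; rules out of START are exempt from
the confidence threshold so every mapped module keeps an entry
distribution. Output size is anti-monotone in both thresholds.

**DYNOTEARS.** Event sequences are one-hot encoded into pooled design
matrices: row $t$ of $X$ is the indicator of the event at index $t$, row $t$
of $Y$ stacks the indicators at lags $1..p$ (default $p = 1$, matching the
interpretation of inter-slice edges as $x_t \to x_{t+1}$); windows never
span two patients. The structural VAR
$X = XW + YA + E$ is estimated by minimizing

$$\tfrac{1}{2M}\lVert X - XW - YA\rVert_F^2
  + \lambda_W \lVert W\rVert_1 + \lambda_A \lVert A\rVert_1
  \quad \text{s.t.}\quad h(W) = \mathrm{tr}\,e^{W \circ W} - d = 0,$$

where $h$ is the smooth acyclicity function (zero exactly on DAGs). The
equality constraint is handled by an augmented Lagrangian: $\rho_0 = 1$,
$\rho \leftarrow 10\rho$ whenever $h$ fails to shrink by a factor of 4,
$\alpha \leftarrow \alpha + \rho h$, tolerance $h \le 10^{-8}$, at most 100
outer iterations; each inner problem is solved by L-BFGS-B over the
non-negative split $(W^+, W^-, A^+, A^-)$ with the diagonal of $W$ pinned to
zero. Initialization is $W = A = 0$, so the fit is deterministic.

### Numerical choices that matter

*Normalization.* Design columns are centered and divided by **one global
scale factor** — the smallest column standard deviation of $X$, a proxy for
the structural noise scale (a coordinate driven only by its own noise has
sd $\sigma$; every other column is at least as variable). Two alternatives
were considered and rejected. Fitting raw low-variance data makes the fixed
L1 weights dominate the least-squares term and zero out true effects.
Per-column standardization instead destroys the equal-noise-variance
structure through which the least-squares score identifies the direction of
contemporaneous edges, and we observed it reversing intra-slice edges on
simulated ground truth. A single common scalar changes neither the
coefficients nor the noise structure — it only moves the problem into the
unit-noise regime the penalty defaults assume.

*Penalty defaults.* $\lambda_W = \lambda_A = 0.02$, the order of the
standard lasso scaling $\sqrt{\log d / M} \approx 0.03$ at the benchmark
sizes ($d = 5$, $M = 2000$) under unit-noise normalization. Stronger
penalties (e.g. 0.1) measurably trade true lagged effects for spurious
sparse contemporaneous explanations on simulated ground truth: the
penalized objective at the generating model then exceeds the objective at a
wrong sparse estimate, so no optimizer could recover the truth. Both
penalties remain configurable.

*Edge extraction.* Coefficients with magnitude above 0.3 (configurable)
become rules: inter-slice entries are the temporal rules (provenance
`dynotears-inter`, lags beyond 1 collapsed by maximum magnitude);
intra-slice entries are same-encounter co-occurrence links kept with their
own provenance (`dynotears-intra`) so either subset can be selected
downstream. Edges into START or out of STOP are semantically void and
dropped. With $D$ large the fit is quadratic in dimension, so the encoder
caps the vocabulary at the `topK = 100` most frequent concepts by default.

## Mapping rules into Synthea modules

Each non-sentinel concept reachable from START becomes one `Encounter`
state (an observation can appear only once in a module, so state names are
deduplicated labels); START/STOP become `Initial`/`Terminal`. Design
choices where the mapping was genuinely open:

- outgoing rule weights are normalized **proportionally** into a
  distribution (the learners produce weights, not probabilities);
- dead-end states transition to `Terminal` with probability 1, since every
  Synthea path must terminate;
- states unreachable from `Initial` are pruned with a warning rather than
  an error — real learners produce disconnected fragments;
- cyclic rule sets are emitted as-is (Synthea expresses time through its
  hierarchy; the cycle load of a learned graph is visible in the
  flow-hierarchy metric rather than silently broken);
- probabilities are rounded to 6 decimals with the largest share absorbing
  the residue, so every written distribution sums to exactly 1;
- codes are recorded as `SNOMED-CT` with the OMOP concept id as code — a
  documented placeholder; true OMOP-to-SNOMED translation is out of scope.

`sampleModule()` walks a module `Initial → … → Terminal` and returns a
`SequenceDataset`, closing the loop: `fitMarkov(sampleModule(M, 10000))`
recovers every transition probability of `M` within sampling error (the
test suite asserts ±0.02 at 10000 walks).

## Graph evaluation

Six complexity measures per graph: node count, edge count (self-loops
included), density $m / (n(n-1))$, average clustering, number of strongly
connected components, and flow hierarchy (the fraction of edges not on any
directed cycle; an edge lies on a cycle exactly when its endpoints share a
strongly connected component, self-loops counting as cyclic). Directed
clustering uses the all-directed-triangle (Fagiolo) generalization by
default, matching common network-library behaviour; an undirected variant
is available behind a flag since the two can differ materially on dense
graphs. For graphs with at most one node the ratio metrics are defined
as 0. Pairwise comparison uses the asymmetric containment percentage
$100\,|E_1 \cap E_2| / |E_1|$ on unweighted directed pairs.

## The synthetic cohort generator

No public registry extract exists, so the generator emulates the *shape* of
a mid-sized cancer-registry cohort, not its semantics: defaults are 5000
patients, 135 distinct concepts, mean sequence length 5.5 (counted
including the sentinels — the same quantity the ETL reports). Ground truth
is a layered DAG of Encounter states: a walk is absorbed into Terminal with
a constant per-layer probability solved so that the expected number of
emitted events equals the target (clamped below at one event; a target
below that degenerates to minimal single-event walks). Synthetic calendar
dates exercise the ETL's tie-break: roughly 10% of steps share the previous
event's date, only where ascending concept ids make the (date, id) sort
reproduce the walk order, so a generated cohort written as OMOP CSVs
re-parses through the full ETL byte-identically.

A ubiquitous "blood-sampling-like" confounder can be inserted after any
event with configurable probability (default 0, since insertion inflates
walk length past the configured mean). At rate 0.5 it reproduces, at desk
scale, the qualitative contrast between the learners: the Markov graph
acquires confounder in-edges from essentially every concept, while the
DYNOTEARS graph, whose lagged coefficients for a uniformly-inserted event
carry little signal, stays far cleaner — and Markov graphs have strictly
more edges than mined rule graphs at default thresholds.

For DYNOTEARS benchmarks, `simulateSVAR()` draws an acyclic $W$ (permuted
upper-triangular support) and lagged $A$ with edge probability 0.3 and
magnitudes $\pm U(0.5, 1)$, rejects unstable reduced-form processes
(companion spectral radius ≥ 1), and simulates
$x_t = (I - W^\top)^{-1}(A^\top x_{t-1..t-p} + \varepsilon_t)$ after a
100-step burn-in.

### What passing tests do and do not show

The generator produces first-order walks over a modest vocabulary with
near-uniform branch weights and homoscedastic Gaussian SVAR noise. Passing
recovery tests therefore show the estimators are correctly implemented and
well-calibrated *for data matching their model class*. Real registry data
violate these assumptions in known ways — long-range dependence, heavily
skewed concept frequencies, coding artefacts, calendar-time effects — so
test results bound implementation correctness, not clinical fidelity.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
cohorts of 120–500 patients over 12–30 concepts for the pipeline checks,
10–20 replicates of the $d = 5$, $M = 2000$ SVAR benchmark, 10000-walk
round trips, and 50–200 randomized cases per brute-force oracle comparison.
These sizes were chosen so that every check is sharp (sampling error well
inside the asserted tolerances) while the whole suite stays comfortably
fast on one CPU.

## Known limitations

- Only `Initial`/`Terminal`/`Encounter` states and distributed transitions
  are emitted; Synthea's conditional, loop, delay and guard constructs are
  out of scope (no learner here could estimate them).
- Rules are pairwise; multi-item antecedents/consequents are not mined.
- The Markov and TARM learners are deterministic; DYNOTEARS is
  deterministic given its zero initialization but its augmented Lagrangian
  can stop at `converged = FALSE` on pathological inputs (reported via a
  warning and the model's `trace`).
- OMOP ingestion is CSV-first; only `condition_occurrence` and
  `procedure_occurrence` are read.
- Dimensionality above the `topK` cap is truncated by frequency for the
  SVAR learner; rare concepts then cannot appear in its graph.
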