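---
title: "Probabilistic Boolean modeling of gene module drug response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic Boolean modeling of gene module drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolmod)
```

## The problem

Drug-tolerant persister cells survive treatment without resistance
mutations, by shifting into a reversible transcriptional state. Given
steady-state RNAseq of a cell line under a handful of treatment
conditions (e.g. a kinase inhibitor, a glucocorticoid, their
combination, and vehicle control, each in triplicate), plus curated
interaction databases, `boolmod` builds a probabilistic Boolean model of
the regulatory network and asks a control question: which single-gene
knockouts (KO, node held OFF) or constitutive activations (CA, node held
ON) push a gene co-expression module up or down?

The package assumes the gene-to-module assignment is given (in practice
it comes from a co-expression clustering such as WGCNA, which is outside
this package's scope) and covers everything downstream: network
assembly, rule inference, attractor analysis, and intervention
simulation. A synthetic-data module generates ground-truth networks and
matching expression/interaction tables, so every stage can be exercised
and validated offline with known answers.

## Network assembly

Interaction resources disagree on gene naming, so names are first
canonicalized (uppercase; `"."`, `"-"`, `"_"` stripped) and then merged
through an alias graph: names connected by any path of alias pairs refer
to the same gene. Records from all resources are grouped by resolved
endpoint pair, and each merged edge is scored

$$\mathrm{score} = \left(N_\mathrm{references} + N_\mathrm{resources} +
10\,\bar{c}\right)\cdot TFMUL,$$

where $\bar c$ is the mean record confidence and $TFMUL = 2$ for
transcription-factor sources. Every edge has at least one reference and
one resource, so the minimum score is 2. One genuinely open reading in
this score is whether the confidence term is a sum or an average over
the merged records; we average, because a sum would let many
zero-confidence duplicates inflate an edge and because the floor of 2
only holds under the averaging reading.

Boolean rule inference degrades rapidly with in-degree (a rule over $N$
regulators has $2^N$ input configurations to constrain with a handful of
samples), so each target keeps its up-to-three highest-scoring in-edges
unconditionally, and each further edge only if its score exceeds the
number already retained minus one. Sink nodes are removed iteratively to
a fixed point — a node whose targets were all removed cannot drive the
dynamics either — and weakly connected components with fewer than 4
nodes are dropped. Module genes orphaned from the large components are
reconnected through shortest directed paths of at most 4 nodes (all
tying paths are added); we allow the path to run in either direction
because connection, not causal orientation, is what the reconnection
step restores.

## Rule inference

Expression is transformed as $\log(1+\mathrm{FPKM})$ and normalized per
gene to $[0,1]$: values at or below the 20th percentile become 0, values
at or above the 80th become 1, the middle interpolates linearly.
Percentiles use R's default linear-interpolation convention. A gene
whose two percentiles coincide carries no state information; it is set
to 0.5 everywhere with a warning rather than dividing by zero.

Edges from transcription factors are transcriptional; all others are
post-translational, with unannotated post-translational signs assumed
activating. A node with any post-translational input is split into a
transcript form `X_T` (carrying the transcriptional inputs) and an
active-protein form `X_A`; all outgoing regulation comes from `X_A`.
Activation is inhibitory-dominant: with activator set $A$ and inhibitor
set $I$,

$$X_A = X_T \cdot \min\Big(\sum_{j \in A} x_j,\, 1\Big) \cdot
\max\Big(1 - \sum_{j \in I} x_j,\, 0\Big),$$

with the activator factor dropped when $A$ is empty, so that
unactivated-but-uninhibited proteins stay active. Because regulators may
themselves be `_A` variables, this is a coupled nonlinear system per
sample; we solve it by damped fixed-point iteration (damping 0.5,
tolerance $10^{-9}$) started at $X_A = X_T$. The map sends the unit cube
into itself, and in practice convergence takes a few dozen iterations;
non-convergence raises an error naming the offending nodes. For the
Boolean dynamics, `X_A` keeps the deterministic restriction of the same
equation: `X_A = X_T AND (OR activators) AND NOT (OR inhibitors)`.

Each transcriptionally regulated node gets a probabilistic rule in the
BooleaBayes style. For a regulator configuration $c \in \{0,1\}^N$,
sample $s$ receives weight $w_{s,c} = \prod_i x_{i,s}^{c_i}(1 -
x_{i,s})^{1-c_i}$, and

$$f(c) = \frac{0.5\,w_0 + \sum_s w_{s,c}\, y_s}{w_0 + \sum_s w_{s,c}},$$

with $y_s$ the target's normalized value and a single pseudo-observation
of weight $w_0$ (`prior_weight`, default 1) at 0.5. The exact prior
strength is a design choice of this package: it reproduces the intended
limiting behavior — a configuration with no sample support returns
exactly 0.5 ("no data, coin flip"), and the estimate converges to the
empirical mean as support grows — while remaining a configuration knob.

Each regulator's significance is the largest change it can make to the
rule output across all configurations of the other regulators. While any
regulator falls below the 0.1 threshold, the least significant one is
removed (ties broken lexicographically, for determinism) and the rule is
re-inferred; a node that loses all regulators becomes a source node for
the later analyses.

## Pseudo-attractors

Rounding every rule probability at 0.5 yields the closest deterministic
system: in the probabilistic state transition system, transitions with
probability below 0.5 are exactly the ones more likely to be reversed
than taken, so the attractors of the rounded system are the
pseudo-attractors of the probabilistic one. Probabilities of exactly 0.5
round to 1 — "below 0.5 is absent" leaves ties present — but the
deterministic approximation is genuinely ill-defined there, so ties are
reported.

Source nodes are pinned per condition to their replicate-mean state
(mean normalized value above 0.5 is ON; an exact 0.5 tie pins OFF and is
reported), constants are propagated to a fixed point, and the remaining
free system is searched exhaustively: we build the general-asynchronous
state transition graph (one node updated per step, matching the
simulation dynamics; the update scheme is chosen for that consistency)
and report its terminal strongly connected components. Singletons are
steady states; larger components report their varying nodes as
oscillating. The exhaustive search is bounded (default 20 free nodes)
and asks for stronger pinning beyond that. Oscillating nodes count 0.5
in module-activation summaries and in the condition-average start state;
averages are thresholded at strictly 0.5, with ties resolving OFF.

## Interventions

The influence index ranks candidate interventions before any
simulation. For an edge with source ON-average
$\mathrm{avgON}$ and OFF-average $\mathrm{avgOFF}$ (unweighted means of
the target's rule over the co-regulator configurations), a positive edge
scores $NON = 1 - \mathrm{avgOFF}$, $SON = \mathrm{avgON}$ and a
negative edge $NOFF = \mathrm{avgOFF}$, $SOFF = 1 - \mathrm{avgON}$. An
exactly tied edge ($\mathrm{avgON} = \mathrm{avgOFF}$) has no net
direction and scores zero on all four. The index sums, over the node's
targets inside the module, `(NON - NOFF) + 0.5 (SON - SOFF)` for
KO/DOWN (and the analogous sign/weight patterns for the other
mode-goal pairs): necessity weighs double under KO, sufficiency under
CA.

Simulations start from the condition's average pseudo-attractor state
and update one uniformly chosen non-held node per step, turning it ON
with its rule probability. Held nodes — the intervention targets, on
both forms of a split gene, and the condition-pinned source nodes — are
never updated; sources are held because the condition defines their
state and no intervention can reach them. A module's activation is the
ON-fraction of its non-source nodes, banded as low ($< 1/4$),
intermediate ($1/4$ to $3/4$, boundaries inclusive) or high ($> 3/4$).
Per walk we record the first step at which a module leaves its start
band (low starts cross into intermediate, intermediate starts into low;
intermediate-to-high crossings are rare and not scored), censored at
`n_steps + 1` — by default 5001, after 100 walks of 5000 steps per
condition. Wild-type and intervention switching-time distributions are
compared with a two-sided Mann-Whitney U test (normal approximation
with tie correction; censored values simply tie at 5001, which a rank
test tolerates), all tests of a batch are Benjamini-Hochberg adjusted,
and significant shifts (adjusted $p < 0.05$) are classified: a module
that starts low and switches more slowly under intervention is being
held down (downregulating), faster means upregulating, and the
interpretation flips for intermediate starts. Walk $w$ of an experiment
uses seed `seed + w`, so runs are reproducible and walks independent.

## What the synthetic data emulates

`generate_ground_truth_network()` builds weakly connected Boolean
models with about 20% source nodes, at least one feedback loop, and
rules drawn from {identity, negation, two-input AND/OR with signed
literals, three-input inhibitory-dominant} — the forms the inference
stage must recover. `generate_expression()` pins sources per condition,
relaxes to a steady state and emits FPKM-like values (ON genes uniform
in [20, 200], OFF in [0, 2], multiplicative lognormal noise with
`noise_sd = 0.2` by default) in the six-condition, triplicate layout the
pipeline expects; the ON/OFF separation guarantees the 20/80
normalization can recover states whenever conditions actually differ.
`generate_interaction_databases()` scatters the true edges over
resources with case/punctuation variants and alias substitutions that
the assembly stage must undo, and plants reference-count-1,
zero-confidence decoy edges for the pruning stage to remove.

The generator does not emulate read-level noise, library-size or batch
effects, dosage, or realistic human gene symbols; passing tests
demonstrate that the pipeline's logic recovers planted structure under
its own assumptions, not that those assumptions hold for any particular
real dataset.

## Numerical choices and problem sizes

Defaults follow the study conditions: percentiles 20/80, significance
threshold 0.1, reconnecting paths of at most 4 nodes, minimum component
size 4, bands at 1/4 and 3/4, 100 walks of 5000 steps, alpha 0.05.
Deviations a run makes from these defaults are logged at startup by
`pipeline_config()`. The bundled demonstration (`run_demo()`) uses a
12-node model with 25 walks of 1500 steps and a module-core threshold of
3 — sizes chosen so the whole pipeline, including attractor search and
simulation, completes in about a second while still exercising every
stage; the test suite validates attractor detection against an
independent brute-force enumeration on systems of up to 12 free nodes
and intervention recovery at the full 100 x 5000 walk size.

```{r}
demo_dir <- file.path(tempdir(), "boolmod-demo")
manifest <- run_demo(demo_dir, seed = 7)
read.csv(file.path(demo_dir, "results", "intervention_results.csv"))
```

## Known limitations

* Attractor search is exhaustive over free nodes and therefore bounded;
  systems that remain large after pinning need external stable-motif
  style reduction, which this package does not implement.
* Rules with more than 6 regulators are inferable but warned against:
  with steady-state data of realistic size, most configurations have
  essentially no support and the rule is dominated by the prior.
* The influence index only looks one edge ahead; a high-influence node
  whose targets are themselves weakly coupled to the module can fail to
  produce a significant simulated effect.
* Mann-Whitney on heavily censored distributions loses power when both
  arms are mostly censored; the censoring value only needs to be ordinal
  for the test to remain valid.
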