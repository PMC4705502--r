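---
title: "DEMATEL, ANP and the hybrid DANP: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DEMATEL, ANP and the hybrid DANP: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(danpselect)
```

danpselect ranks a portfolio of improvement projects — the motivating case
is six-sigma project selection in a medical centre — over a decision
network of strategies, criteria clusters, sub-criteria and alternatives.
This vignette explains the three methods it implements, the assumptions
behind them, the tunable parameters, and the design decisions taken where
the methodology literature leaves the choice open.

## The decision network

A model consists of a goal, a strategy cluster, one or more criteria
clusters of sub-criteria, and the project alternatives. Clusters declare
dependency blocks: within-cluster dependence, and sub-criterion to
alternative priorities. Element ordering in the configuration is
authoritative; every matrix is read in that order and nothing is sorted.
Criteria clusters carry relative weights $RW^m$ that must sum to 1; when
they are not declared, equal weights are assumed. The bundled case-study
structure (`sixsigma_model()`) has four criteria clusters with
$RW^m = 0.25$ each, treated as fixed design weights rather than elicited
quantities.

## DEMATEL

Participants score the directed influence of element $i$ on element $j$ on
a five-point scale: none (0), low (1), medium (2), high (3), very high
(4). The group's direct-relation matrix $A$ (arithmetic mean of the
individual matrices, so real values are allowed) is normalised with

$$ M = k A, \qquad
   k = \min\!\left( \frac{1}{\max_i \sum_j |a_{ij}|},\;
                    \frac{1}{\max_j \sum_i |a_{ij}|} \right), $$

using the two-term minimum over the largest row and column sum exactly as
stated (some variants use the row maximum only; the two-term rule is what
the implementation follows, and it is what makes the bundled worked
example come out at $k = 1/8$). The total-relation matrix accumulates all
direct and indirect influence:

$$ S = M + M^2 + M^3 + \cdots = M (I - M)^{-1}, $$

defined whenever the spectral radius of $M$ is below 1, which the
normalisation guarantees except in degenerate cases (for instance a
two-element cluster with perfectly symmetric influence, which the package
reports as a non-convergence error rather than masking). The inverse
is obtained by a linear solve, with a warning when the reciprocal
condition estimate falls below $10^{-12}$.

Row sums $D$ and column sums $R$ of $S$ give the prominence $D + R$ (how
involved an element is) and the relation $D - R$ (its net causal
direction). Elements with $D - R$ above a tolerance of $10^{-9}$ are
*dispatchers* (net causes, prioritised in the analysis); below, they are
*receivers*. The tolerance creates an explicit *neutral* class because a
group-averaged matrix can produce an exactly balanced element, and such an
element is neither cause nor effect. By construction
$\sum_i (D_i - R_i) = 0$ within each cluster — a conservation identity the
test suite asserts on every computed output and that also holds for the
published case-study table to its printed precision.

Finally the *inner-dependence matrix* divides each column of $S$ by its
column sum. A zero column (an element receiving no influence at all) makes
this undefined and is reported as an error naming the element.

## ANP

Pairwise-comparison matrices on the Saaty 1–9 scale must be positive,
reciprocal ($a_{ji} = 1/a_{ij}$), unit-diagonal, with entries in
$[1/9, 9]$; `validate_reciprocal()` reports violations cell by cell. The
priority vector is the principal eigenvector, computed by power iteration
from a uniform start vector — deterministic and dependency-free — run to a
max-norm step below $10^{-12}$ (capped at 10,000 iterations, a guard that
positive matrices never reach) and then polished with a few extra
iterations so that the closed-form identities below hold to near machine
precision. The principal eigenvalue $\lambda_{\max}$ is the Rayleigh
quotient at convergence. Two identities serve as independent oracles in
the tests: for consistent matrices $a_{ij} = w_i / w_j$ the eigenvector
recovers $w$ exactly, and for every $3 \times 3$ reciprocal matrix it
equals the normalised row geometric means.

Consistency follows the standard index,

$$ CI = \frac{\lambda_{\max} - n}{n - 1}, \qquad CR = CI / RI, $$

with the random index $RI$ hard-coded for orders 2–10 (0, 0.58, 0.9,
1.12, 1.24, 1.32, 1.41, 1.45, 1.51). Orders above 10 are rejected rather
than extrapolated. $CR \le 0.1$ is acceptable; the pipelines warn and
continue on violations by default (consistency is conventionally reviewed
post hoc) and abort under `strict = TRUE`. For $n = 2$, $RI = 0$ and a
reciprocal matrix is always consistent, so $CR$ is defined as 0 — a
positive $CI$ at $n = 2$ can only be an upstream bug and errors.

The supermatrix is a partitioned matrix over all elements plus the
alternatives. Declared blocks are filled column-wise with priority
vectors; undeclared blocks are zero. Alternatives are modelled as
absorbing sinks (an identity block in their own columns), the standard
device that makes the limit of a hierarchical supermatrix reproduce
weighted-sum composition. The weighted supermatrix scales each block by a
cluster-level weight so every column sums to unity; when a cluster's
columns feed both its own inner block and the alternatives, the split is
controlled by `inner_weight` (default 0.5, an equal split — no
cluster-level comparisons exist to inform it, and with independent
within-cluster elements the absorbed priorities are provably invariant to
this split, which the tests verify). The limit supermatrix is computed by
repeated squaring to a max-norm tolerance of $10^{-10}$, capped at
$2^{40}$-equivalent powers. Cyclic structures whose powers oscillate with
period 2 converge under squaring to one phase of the cycle; the
implementation detects this (the one-step image of the candidate limit
moves it by more than $10^{-8}$) and returns the Cesàro average of the two
phases, recording which path was taken.

Block normalisation rescales stabilised masses cluster by cluster. Mode
`"unit"`, the default for new analyses, makes each block sum to 1. Mode
`"half"` makes each block sum to 0.5 — the reporting convention of the
bundled case study's published tables, in which each criteria cluster's
local-weight column and the alternatives' global weights each carry half a
unit of mass. The modes differ only by the factor 0.5 and never change a
ranking. Global weights multiply local by cluster weight,
$GW_i = LW_i^m \cdot RW^m$; for display the package rounds half away from
zero at 5 decimals, matching the published tables' precision (base R's
banker's rounding would disagree on exact ties). Rankings sort descending
by weight with exact ties kept in declaration order, so results are
deterministic.

## The hybrid DANP coupling

The methodology literature combines DEMATEL and ANP in several ways and
the combination equation is rarely written out. The package isolates its
coupling rule in one place (`danp_couple_weights()` plus the
inner-block substitution) so alternates can be swapped:

* each cluster's DEMATEL inner-dependence matrix replaces that cluster's
  within-cluster supermatrix block (plain ANP uses an identity block —
  the independence assumption);
* local weights are filtered through the same matrix,
  $LW^{danp} \propto B \cdot LW^{anp}$, so elements that receive more of
  the cluster's influence mass absorb more weight;
* cluster relative weights stay at their declared fixed values by default
  (`cluster_weights = "fixed"`, matching the case study's fixed 0.25
  convention); `cluster_weights = "dematel"` instead derives them by
  normalising each cluster's total-relation mass.

Two degeneracy properties anchor this design and are asserted in the test
suite: with an identity inner block the hybrid reduces exactly to plain
ANP (the coupling is the only difference between the two pipelines), and
with symmetric influence ($D = R$ everywhere, all elements neutral) both
methods agree on the top alternative in the regression fixtures.

## Group aggregation

Individual comparison matrices are combined with the element-wise
geometric mean — the standard aggregation of individual judgments, and the
only mean that preserves reciprocity exactly — and influence matrices with
the element-wise arithmetic mean, which keeps the bounded 0–4 scale's
interpretation. Both schemes are selectable; the defaults are used
whenever a list of participants is passed to a pipeline. Aggregation is
permutation-invariant over participants.

## The synthetic-data generator

No raw judgment matrices were published for the motivating case study, so
every stage is exercised against generated models with known ground truth
(`synthesis_spec()` / `synth_model()`). The defaults emulate the case
study's conditions: 3 strategies, criteria clusters of 5/4/3/3
sub-criteria, 6 alternatives, 6 participants, judgment noise 0.1.

The generator draws true local weights per context (Dirichlet), gives each
alternative a base log-quality shared across sub-criteria (projects that
are good tend to be good on most criteria — this correlation is what makes
composed scores separate; fifteen independent draws would average out to
near-uniform scores with no meaningful true ranking), and materialises
every context as a consistent matrix snapped to the Saaty scale. Snapping
happens in log space (nearest scale value by log distance), treating $x$
and $1/x$ symmetrically, and the upper triangle is snapped with the lower
filled as reciprocals so reciprocity is exact. The stored ground truth is
the exact solution of this snapped noise-free model — the model a
perfectly reliable respondent could actually express on the discrete
scale — so a zero-noise pipeline run recovers the true ranking exactly,
and the recovery property test (50 seeds) verifies the machinery rather
than the size of the discretisation error. Ground truths whose composed
scores sit closer than `min_gap` (default 0.02) are redrawn so the true
ranking is unambiguous.

Participant noise is multiplicative log-normal on comparisons (perturb,
re-snap, refill reciprocals) and additive Gaussian on influence scores
(default sd 0.5 — half a scale step of inter-rater disagreement — then
rounded and clipped to 0–4 with a clip-count warning). True influence
matrices are drawn uniformly on {0,…,4} with zero diagonal, and both they
and their noisy copies are deterministically repaired to stay analysable:
a zero column (an element receiving no influence) makes inner dependence
undefined, and a doubly balanced matrix — all row sums and all column
sums equal — normalises to spectral radius exactly 1 where the
total-relation series diverges. The repair restores a unit link into a
zeroed column and nudges one off-diagonal entry to break exact balance;
real group-averaged elicitation data essentially never sits on these
degenerate configurations, which is why the generator excludes them.

What the generator does **not** emulate: systematic rater bias (noise is
centred on truth), correlated errors across contexts within a
participant, incomplete or inattentive responding, and any dependence of
influence scores on the comparison judgments. Passing tests therefore
demonstrate that the machinery recovers well-separated ground truth under
honest independent noise — not that real elicitation data is this benign.

## Robustness harness

Adequacy-to-change tests clone an alternative (every alternatives matrix
gains a row/column copying the target, mutual comparison 1) or a
sub-criterion (within-cluster comparison and influence matrices gain a
duplicated row/column; the clone's alternatives matrix copies the
target's; the influence diagonal stays zero). `rank_stability()` compares
orders over the original items only: a preservation flag, Kendall's tau,
and per-item displacements.

Judgment counting (`count_judgments()`) treats a judgment as an ordered
off-diagonal matrix entry, $n(n-1)$ per elicited matrix, with alternatives
compared per sub-criterion only and cluster weights fixed (not elicited).
This is the only convention that reproduces the case study's published
totals — 500 for ANP and 550 for DANP on the 3 / 5-4-3-3 / 6 structure —
and its incremental figures (+12 per sub-criterion per added alternative;
+30 ANP and +36 DANP for a sub-criterion added to a 3-element cluster)
simultaneously. The published incremental accounting excludes the enlarged
within-cluster comparison matrix from both methods, which makes it
internally inconsistent with its own base totals (the difference of totals
before and after exceeds the published increment by $2c$ for a cluster of
size $c$). Both conventions are implemented —
`include_within_cluster = TRUE` gives the self-consistent count — and the
discrepancy is pinned down by an explicit known-deviation test rather than
smoothed over.

## Numerical choices and problem sizes

| Quantity | Value | Rationale |
|---|---|---|
| power-iteration step tolerance | $10^{-12}$ | plus polish iterations; supports $10^{-12}$ closed-form checks |
| limit squaring tolerance | $10^{-10}$ | max-norm between successive squared powers |
| Cesàro detection threshold | $10^{-8}$ | one-step drift of the candidate limit |
| role-classification tolerance | $10^{-9}$ | defines the neutral class |
| reciprocity validation tolerance | $10^{-9}$ | elicitation data is exact fractions |
| display rounding | half-up, 5 decimals | matches the published tables |
| RI table bound | $n \le 10$ | reject, never extrapolate |

The test suite exercises property loops at 5–20 replicates, the truncated
power-series oracle at 400 terms, the brute-force limit oracle at 600
multiplications on 6–10 node matrices, and end-to-end recovery on 50
seeds of the full 24-node structure; the complete suite runs in well under
a minute on a single CPU. These sizes were chosen to pin each numerical
claim at its stated tolerance while keeping the suite fast to iterate on.

## Known limitations

* Within-cluster dependence and sub-criterion-to-alternative blocks are
  the supported block structures; arbitrary cross-cluster blocks are
  accepted by the supermatrix assembler (keyed priorities) but not
  elicited by the judgment-set conventions.
* No benefits–opportunities–costs–risks multiplicative synthesis; the
  criteria clusters are plain weighted criteria.
* No completion methods for incomplete comparison matrices; every context
  must be fully elicited.
* The published case-study weight tables themselves are not exactly
  reproducible by anyone, because the underlying aggregated judgment
  matrices were never published; the package reproduces their structural
  identities (conservation, block sums, $GW = LW \cdot RW$, ranking) and
  embeds the two illustrative matrices that were printed.
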