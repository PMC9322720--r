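---
title: "Rooting species trees with DTL reconciliation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rooting species trees with DTL reconciliation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dtlroot)
```

This vignette is the package's own account of its model, its numerical
choices, and the limits of what its synthetic experiments can show. It
states no empirical result that the test suite does not itself compute.

## The undated DTL model

A gene family evolves inside a rooted species tree by four event types:
duplication, transfer, loss, and speciation. The rates `delta`, `tau`,
`lambda` are dimensionless weights relative to the unit speciation
weight; per opportunity, the event probabilities are `delta/W`, `tau/W`,
`lambda/W`, `1/W` with `W = delta + tau + lambda + 1`. "Undated" means
transfers may connect any ordered pair of distinct branches — no
time-consistency constraint — which is the standard machinery when the
species tree carries no calibrated node ages.

Branches are identified with nodes (the edge above each node), so a tree
on `L` species has `2L - 1` branches including a stem above the root;
gene families may originate on any of them, stem included (toggleable via
`orig_stem`). Allowing stem origination lets families predate the first
split, which matters for rooting because an origination below the root
would otherwise forbid one side of the tree.

Two coupled quantities drive the likelihood:

* **Extinction** `E_e`: the probability that a single copy entering
  branch `e` leaves no observed descendant — through loss, through
  duplication with both daughters vanishing, through a transfer whose
  donor and recipient copies both vanish, or (at the tips) through the
  per-species missing-gene fraction `m_s`. It is the fixed point of the
  map written in `src/dtl.cpp`, iterated from all zeros to `1e-12`.
* **Observation** `P(u, e)`: the probability that a copy entering branch
  `e` yields exactly the observed (pruned) gene subtree `u`. The
  recurrence couples a subtree's vector across branches through
  speciation-loss (walks down the species tree) and through
  transfer-with-donor-extinct (couples all branches through the mean
  `Pbar`). Given the children's vectors this system is *linear*: lower
  triangular in postorder plus a rank-one term in the branch mean, so the
  package solves it exactly (two triangular sweeps and a closed-form
  Sherman–Morrison step) instead of iterating — same fixed point, no
  iteration error.

The family likelihood sums `P(rho, e)` over all rootings `rho` of the
unrooted gene tree and all origination branches `e`, divides by the
number of origination branches (uniform origination prior), and
conditions on the family being observed at all (divide by one minus the
mean extinction over origination branches). Marginalising over gene-tree
rootings — rather than maximising, as some implementations do — keeps the
surface smooth in the rates; the two differ by at most the log of the
number of rootings and agree when one rooting dominates.

Combinatorial conventions (duplication split counted once; duplication
with one extinct daughter counted twice; both stay/move assignments of a
transfer counted) are pinned by an independent oracle in the test suite:
an exhaustive enumeration of event histories organised by the exact
number of duplication/transfer/loss events, which converges geometrically
onto the dynamic programme's value as the event budget grows. Per-subtree
log scaling keeps families with hundreds of leaves finite.

## Rate fitting and T:D policies

Free fits maximise the likelihood over `(delta, tau, lambda)` with a
Nelder–Mead simplex in log10-rate space, seeded at `delta = tau` (the 1:1
transfer:duplication seed that mirrors reconciliation software's default),
bounded to `[1e-10, 10]`, with one restart from the best point;
deterministic throughout. The upper bound deliberately clips the extreme
per-family rates such analyses occasionally report. Fixed-T:D fits hold
`delta` and `tau` and optimise only `lambda` (Brent).

A `rate_policy` fixes how scans set per-family rates:

* `free` — all rates re-fit per family per root (the "1:1 analysis");
* `fixed_ratio(rho)` — each family's transfer rate is taken from its free
  fit at a reference root and its duplication rate set to `tau / rho`, so
  the T:D ratio is exactly `rho`;
* `ratio_floor(rho)` — only families whose free T:D falls below `rho` are
  adjusted ("`rho`:1 or more").

Ratios are always written as T:D; the literal string form (`"50:1"`,
`"1:2"`) is accepted everywhere to prevent inversion bugs. Flux summaries
report mean/median/sample-sd (n−1) per rate, per-family gain
`delta + tau`, and the loss:gain ratio L:G computed from means; L:G above
one is genome reduction.

## Root scanning and the AU test

`root_scan()` evaluates every branch of the unrooted species tree
(`2L - 3` candidates) as a root. The reference root for free fits is the
first branch by default; `run_experiment()` derives the constrained
policies' transfer rates from free fits at the free scan's
maximum-likelihood root, since synthetic data have no published root to
condition on. For the free policy the default is a full per-root refit
(`refit = "full"`): each family's simplex is warm-started at its
reference-root optimum with a small initial step. The alternative
`refit = "lambda"` holds `(delta, tau)` at the reference fit; it is
faster per evaluation but anchors every family to one root, which adds a
small shared bias toward the reference branch — the full refit is the
default for exactly that reason.

`au_test()` resamples families with replacement at ten scales
(`sigma^2 = 0.5 ... 1.4` by default; `n' = round(N / sigma^2)`, and the
regression uses the realised `N / n'`), records the fraction of
replicates in which each root's summed log-likelihood is maximal (exact
ties split equally), and fits

```
z(sigma) = d / sigma + c * sigma,    z = qnorm(1 - BP)
```

by weighted least squares with weights `B * dnorm(z)^2 / (BP (1 - BP))`
(BP clipped to `[1/(2B), 1 - 1/(2B)]`). The signed distance `d`
multiplies `1/sigma` — at large resample sizes the boundary is seen from
distance `d` in rescaled units — and the curvature `c` grows with
`sigma`; the AU p-value is `1 - pnorm(d - c)`. Under the flat-boundary
null (two roots, iid per-family differences) this reduces to the
textbook one-sided normal p-value, and the test suite verifies the
rejection rate at `alpha = 0.05` is 5% ± 2% over 500 seeded trials.
Roots never (or always) maximal at any scale get p = 0 (or 1) and a flag
rather than an extrapolated fit. `root_set()` retains roots with
`p > alpha` plus, always, the maximum-likelihood root: a root cannot be
rejected against itself.

## The simulator

`simulate_dataset()` draws a pure-birth (Yule) species tree rescaled to
unit root-to-tip depth (stem length 0.2 by default), then evolves each
family forward: origination at the top of a uniformly drawn branch,
exponential waiting times per unit branch length, transfers to a uniform
contemporaneous recipient (a transfer with no living recipient — possible
only on the stem — cannot occur), bifurcation at speciations, and
observation of each surviving copy with probability `1 - m_s`. Families
with fewer than `min_leaves` (default 3) observed leaves are redrawn,
with the rejection count reported — the same conditioning as analysing
observed families. Ground-truth event counts are recorded both for the
full history and restricted to the observed history (duplications and
transfers with at least one observed descendant; losses that prune a
lineage whose parent has observed descendants).

Preset regimes state the study conditions:

* bacteria-like: `tau = 0.6`, `delta = tau / td` with `td = 50` by
  default (50–100 allowed), `lambda = 1.05 (delta + tau)` — transfers
  dominate and losses slightly exceed gains;
* eukaryote-like: `delta = 0.3`, `tau = 0.15` (T:D = 1:2, the
  duplication-rich average such datasets show), `lambda = 0.6`.

Only the ratios are dictated by the regimes; the absolute scales are
package choices picked so that observed families on a unit-depth tree
have a handful of copies — small enough to scan exhaustively, large
enough to carry events. With uniform origination a zero-rate family is
congruent with the *clade below its origination branch*; the
whole-tree congruence property holds under `origination = "stem"`.

The simulator is dated; the inference model is undated. That model
mismatch is deliberate — it mirrors the real situation, where no
reconciliation model matches the generating process — and is why
parameter-recovery checks are stated as order-of-magnitude/ratio
properties, not exact recovery.

## Experiment sizes

The packaged experiments run at desk scale: 16-species, 300-family
bacteria-like replicates for the policy comparison; 12-species,
300-family eukaryote-like replicates for root recovery; a 10-species,
1000-family mixed dataset (half duplication-rich, half transfer-rich at
matched gain rates) for the power analysis; AU tests at `B = 2000` in the
tests and `B = 10000` by default in the API. The methods scale linearly
in families and in candidate roots; nothing in the implementation is
specific to these sizes.

## What the synthetic experiments do and do not show

The simulator emulates the statistical structure the analysis assumes —
DTL events on a fixed species tree, species-incomplete and multi-copy
families, per-species sampling gaps — but **not** gene-tree
reconstruction error: every simulated gene tree is the true pruned
history. Two consequences, both visible in the acceptance suite, matter
for interpretation:

* On error-free gene trees the free fits do not systematically
  overestimate duplication rates: most transfer-dominated families fit
  `delta` near zero (fitted T:D far above 50:1), so a 50:1 floor adjusts
  only the minority of families with genuine or ambiguous duplication
  signal, and the free-versus-floored root-set comparison sits within one
  root of equality instead of showing the strong real-data effect, where
  spurious duplications inflate the free analysis's confidence.
* Several published effects that our experiments test do **not**
  reproduce on clean trees, and the corresponding acceptance checks are
  left failing rather than weakened. They share one mechanism. On
  error-free data a family's duplications sit at family-specific
  positions and favour family-specific alternative roots, so duplication
  signal *disagrees across families*: it inflates the bootstrap variance
  of the between-root likelihood differences and **widens** root sets.
  Consequently (i) the Spearman correlation between block mean
  duplication rate and retained-root count comes out positive, not
  negative; (ii) floored (duplication-penalised) scans come out slightly
  sharper, not flatter, than free scans; and (iii) forcing a
  transfer-dominated ratio onto duplication-rich data does not displace
  the true root — the inverted-policy root sets stay small and keep it.
  On real data, families with high fitted duplication rates are
  disproportionately those whose gene-tree reconstruction errors are
  read as root-informative events shared in their biases, which is the
  plausible source of the published signs. Reproducing them would
  require the gene-tree error injection the simulator deliberately
  omits.

## Numerical choices, degenerate inputs, limitations

* Extinction fixed point: from all zeros, Gauss–Seidel in postorder,
  tolerance `1e-12`, cap `1e4` sweeps (error on non-convergence).
* Closure denominators `1 - 2 p_D E_e - p_T Ebar` below `1e-12`, or a
  non-contractive mean coupling, signal an infeasible rate region: the
  likelihood is reported as zero (`-Inf` log), never silently clamped.
* A multi-copy family under `delta = tau = 0` has probability zero and
  is reported as such; optimizers treat it as `-1e300`.
* Two-leaf gene families are treated as rooted at their unique internal
  node (no rooting sum); one-leaf families are rejected as input.
* Polytomies are errors, never silently resolved — the DP assumes binary
  trees and silent resolution would change likelihoods.
* Exact AU ties are split equally, which keeps bootstrap proportions
  unbiased under exact symmetry (identical likelihood rows).
* Spearman p-values use the t approximation for `n >= 10` and the exact
  permutation distribution below that; ranking ties break by family id
  so blocks are deterministic.
* Leaf labels encode species as the prefix before the first underscore
  by default; an explicit two-column table overrides this. The
  convention is a package choice — reconciliation inputs in the wild
  carry no standard encoding.
* Known limitations: no conditional-clade amalgamation (fixed gene-tree
  topologies are reconciled), no dated/time-sliced reconciliation, no
  incomplete lineage sorting, no gene-tree error model, and no sampling
  of per-branch event histories (the analyses need event *rates*).
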