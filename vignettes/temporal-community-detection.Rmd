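---
title: "Detecting community-activity structure in temporal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting community-activity structure in temporal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model behind `tempocomm`, the assumptions it
makes, the parameters that matter, and the design choices taken where
more than one reasonable implementation exists. It is the reference for
*why* the package behaves as it does; the README shows *how* to use it.

## 1. From an event stream to a tensor

The raw input is a stream of undirected, time-stamped contact events
`(t, i, j)`. `build_tensor()` divides the timeline into consecutive
intervals of width Δ and sets entry `(i, j, m)` of an `N × N × S` tensor
to 1 when the pair had at least one contact during interval `m` (both
orientations are set; every slice is symmetric with zero diagonal).

Choices worth spelling out:

* **Half-open intervals** `[t0 + mΔ, t0 + (m+1)Δ)`. An event exactly on
  a boundary belongs to the later interval. This is the standard
  unambiguous binning for time series; the same rule is used for
  location fingerprints so that the two data streams stay aligned.
* **Node order** is the lexicographically sorted set of ids, frozen
  before the tensor is built. Tensors are therefore independent of the
  order of lines in the input file.
* **Binary slices by default.** Presence/absence per interval is the
  modelling unit; contact *counts* per interval are available behind
  `weighted = TRUE` but are not the default, and the time-aggregated
  network (`aggregate_time()`) deliberately refuses weighted tensors —
  its link weights are defined as counts of active intervals.
* **Δ defaults to 780 s** (13 minutes). School-day activity blocks are
  tens of minutes long; 13-minute aggregation resolves them without
  inflating `S`. Δ is a required modelling decision, not a tuning knob:
  results should be (and, on structured data, are) robust across a
  range of aggregation levels.
* **`t0` defaults to 0** and must not exceed the first event. All
  intervals in `[t0, t_max]` are kept, including empty ones (an
  overnight gap between recording days simply contributes all-zero
  slices); dropping them would desynchronize the time axis from wall
  time.
* Self-loops and exact duplicate events are dropped, with counts kept
  on the returned object.

## 2. The factorization model

The tensor is approximated as a sum of `R` non-negative rank-1
components, `T ≈ Σ_r a_r ∘ b_r ∘ c_r`, by minimizing the Frobenius
residual. Non-negativity buys interpretability: components only *add*
structure, so a column of `A` reads directly as membership weights and a
column of `C` as an activity timeline. Nothing constrains components to
be disjoint (overlap is expected: a node can sit in its class and in a
lunch group) or temporally contiguous (the time axis is treated as
unordered, which is what lets the method capture abrupt, recurring, or
disjoint activity).

For undirected input the model is fitted on the full symmetric tensor
with *independent* `A` and `B`; symmetry of the solution emerges rather
than being imposed. The solver reports the asymmetry
`‖A_n − B_n‖_F / ‖A_n‖_F` on column-normalized factors; in
well-converged runs on symmetric data it is near zero (typically below
1e-3 on the bundled benchmark), and a large value is a useful
convergence red flag. An optional post-hoc symmetrization (averaging
the normalized node factors) exists but is off by default.

## 3. The solver

Each sweep of `als_sweep()` updates one factor at a time from the
matricized problem `min_{F ≥ 0} ‖X(n) − F Kᵀ‖_F`, where `K` is the
Khatri–Rao product of the other two factors. The per-row NNLS problems
share one `R × R` Gram matrix, so each is solved exactly by **block
principal pivoting** on the normal equations; Murty's lowest-index
single-exchange rule is the anti-cycling fallback, and Lawson–Hanson
(`pracma::lsqnonneg`) backs both a user-selectable `"active-set"` route
and the last-resort path for pathological rows.

Numerical points that shaped the implementation:

* **Unfolding layout.** Mode-`n` matricization linearizes the remaining
  indices in increasing mode order (mode 1: columns `j + J·k`). Under
  this one convention, used everywhere, `X(1) = A (C ⊙ B)ᵀ` holds
  exactly, and the test suite checks the identity on random factors to
  1e-12 relative.
* **Initialization.** Each run draws i.i.d. uniform(0, 1) factors
  scaled by `mean(T)^(1/3)`, so the initial reconstruction has the
  tensor's magnitude. Runs are seeded as a deterministic function of
  `(master seed, run index)`: any single run can be reproduced without
  re-running the others.
* **Convergence** is declared when the relative objective change per
  sweep falls below `tol` (default 1e-7), with a sweep cap
  (`max_iter = 500`). These are implementation defaults — configurable,
  and reported on the fitted object.
* **Monotonicity.** With exact block solves the objective cannot
  increase. In floating point it can, marginally, when a redundant
  component makes the Gram matrix nearly singular (typical when `R`
  exceeds the data's true rank and the fit is nearly exact). Two
  safeguards keep the reported objective monotone: a row update is only
  accepted if it does not increase that row's quadratic objective
  (falling back to the previous, feasible row otherwise), and a
  residual uptick below `1e-8·(1 + ‖T‖_F)` leaves the previous iterate
  in place. A larger increase raises an error, because it would mean a
  genuine solver defect — the property is also asserted across random
  problems in the test suite.
* **Collapsed components.** A column that reaches all-zero is reseeded
  once from small uniform noise; if it collapses again it stays zero
  and is flagged on the model. Zero columns in a design matrix have
  their coefficients pinned at zero.

Because the objective is non-convex, `factorize()` runs a multi-start
protocol (default 20 runs; run counts are a practical choice, not a
statistical one). `select_best()` then ranks runs by core consistency,
keeps the top `keep_cc = 10`, re-ranks those by decomposition score and
keeps the top `keep_score = 5`, breaking ties deterministically by run
seed.

## 4. Model-order diagnostics

`core_consistency()` fits the least-squares Tucker core `G` for the
fixed CP factors (via SVD-based pseudoinverses with cutoff
`max(dim)·ε·σ_max`, so rank-deficient factors degrade gracefully and are
flagged) and returns `100·(1 − ‖G − I‖²/R)`. An exact CP model with
full-column-rank factors scores exactly 100; redundant or overfitted
models fall away sharply, and strongly negative values are reported
as-is — clamping them would hide exactly the signal the diagnostic
carries. On small noisy tensors the collapse below the crossover is
dramatic (large negative values are normal CORCONDIA behaviour, not an
error).

`consistency_sweep()` repeats the full multi-start protocol across a
range of `R` and tabulates the surviving runs, with both selection
stages visible (`stage` column), since either view of the curve can be
of interest. The package deliberately does **not** auto-select `R`:
the crossover in the curve (conventional reference line at 90) is a
guide, and different `R` below it expose different levels of structural
detail.

The per-component relevance is `r_k = ‖a_k‖·‖b_k‖·‖c_k‖` on the raw
factors — invariant under the CP scaling indeterminacy. A whole run is
scored by the **sum** of relevances by default; a product variant is
available (both appear in the literature; the sum degrades gracefully
when a component collapses to zero, which would zero out a product).

## 5. Interpreting factors

**Membership binarization.** Well-separated components produce a
membership-weight histogram with a spike at zero (non-members) and a
broad positive bulk (members). `binarize_membership()` splits the two
by scalar 2-means, made fully deterministic: centers initialized at the
column minimum and maximum, Lloyd iterations capped at 100, an
equidistant point joining the lower cluster, and an `eps = 1e-9` guard
sending an (effectively) all-zero column to the empty member set. The
split is invariant under positive rescaling of the column. Membership
uses factor `A`; `B`-based and averaged variants exist for checking.
On weakly structured data no clean two-population split need exist — in
that regime the binary matrix is a convenience and the weighted factor
column remains the primary output.

**Activity strength.** The strength of component `k` at interval `t`
combines the component's temporal profile with its total membership
weight: `s_k(t) = C[t, k] · Σ_i A[i, k]`. A normalized variant
(unit-norm node columns, scale absorbed into `C`) is selectable and
differs only by a per-component constant; the default keeps raw factor
scales so that strengths are comparable across components within one
model.

## 6. Validation against ground truth

* **Strict Jaccard matching**: a component matches a class iff exactly
  one class has overlap `> 0` — set overlap, no epsilon. One stray
  node from another class voids the match; this severity is the point,
  as it makes a reported match very strong evidence.
* **Students only** by default: teachers have no unambiguous class,
  so they are excluded from overlap and recall computations, while
  still appearing in component sizes.
* **Recall** is the fraction of students of the matched classes found
  inside their matching components; several components matching one
  class contribute the union of their members. With no matches, recall
  is reported as missing rather than zero.
* **Score matrices** `PᵀQ` (classes × communities student counts)
  accept any binary node-community matrix, so partitions from external
  community detectors can be scored identically.
* **Co-location** multiplies the members' location fingerprints
  element-wise, so it is non-zero at `(receiver, interval)` exactly
  when *every* member was there — deliberately strict. Raw products
  overflow for large components; the `log_domain = TRUE` variant
  returns the log-domain sum gated by the all-present condition and is
  the recommended form beyond ~20 members.

## 7. The planted benchmark: what it does and does not emulate

`school_spec()` plants the structure the method targets: disjoint
groups ("classes") with a shared schedule (activity probability 0.8 in
class time, 0.15 during a lunch block), within-group contacts with
probability 0.6 per pair per active interval, background noise at
0.001, and one lunch gathering mixing 4 classes (pair probability 0.5)
at a named receiver, with Poisson(5) fingerprint counts at the home or
event receiver. The canonical instance — 10 classes of 6 students, 40
intervals, generator seed 11 — is the fixed study condition of the
acceptance script; group activation is interval-wise independent
Bernoulli, the simplest model of a schedule that imposes no temporal
continuity.

What it does *not* emulate: heavy-tailed contact durations,
within-group degree heterogeneity, sensor dropout, or mobility between
receivers. Passing the recovery tests therefore demonstrates that the
pipeline — binning, factorization, selection, binarization, matching —
recovers planted block-with-schedule structure through Bernoulli noise;
it does not by itself bound performance on empirical data, where
membership distributions are messier and class sizes larger. The
bundled reference tables (`reference_recovery_table()`) document what
the same pipeline achieved at full empirical scale on a published
primary-school contact dataset; their arithmetic identities (recall as
covered/known counts; component size = class size + teachers − missing)
are recomputed by `scripts/acceptance.R`. Two rows of that table (6 and
7 components) print a recall inconsistent with their own counts; they
are carried verbatim but excluded from the identity checks.

## 8. Problem sizes and runtime

The test suite and acceptance script are sized for a laptop-class
single CPU: algebra and NNLS oracle suites run hundreds of randomized
cases on tensors up to `5 × 5 × 5` in seconds; the end-to-end benchmark
(60 × 60 × 40 tensor, `R = 11`, 10 restarts) completes in a few
seconds. Dense storage is used throughout — for the intended scale
(hundreds of nodes, `N²S` entries) memory is not a constraint, and
three-way dense algebra keeps every identity testable against
brute-force oracles. Larger `N` mainly costs time in the `N × (N·S)`
unfolding products.

## 9. Known limitations

* Three-way tensors only; no general N-way machinery.
* No missing-data masking: an unobserved interval is indistinguishable
  from an empty one.
* No projected-gradient solver; ANLS with block pivoting is the only
  optimizer (it is the faster of the two on this problem class).
* Directed networks are representable (A and B are already
  independent) but in/out membership reporting is not implemented.
* The temporal axis is unordered by design; when continuity is known
  to matter, a smoothness-aware method will extract more stable
  structure from noisy data.
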