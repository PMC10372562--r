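---
title: "Methods: exact-aggregation federated analysis in fedsilo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact-aggregation federated analysis in fedsilo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedsilo)
```

## The federation model

`fedsilo` simulates *horizontal cross-silo* federated learning: a small
number of organizations each hold the same variables for different
subjects, and a single coordinator aggregates. The topology is a star —
exactly one coordinator, N participants — because that is the natural
shape of an aggregate-then-broadcast scheme. The coordinator may itself
hold data (the default, `coordinator_has_data = TRUE`): dual role changes
nothing about the simulated message pattern, which is what the engine
audits.

Every federated application alternates two phases until it signals
completion: a *participant phase* run at each party against its local
state, producing an outbound payload, and a *coordinator phase* over the
gathered payloads, producing a broadcast or the final result. The engine
is barrier-synchronized: aggregation waits for every party. Real
platforms sometimes start aggregating as submissions arrive; for the
sum-based aggregators used here the result is identical either way, and
the barrier makes runs deterministic, so we chose it deliberately.

Execution is in-process on one machine. The transport of a production
system (containers, relay servers, sockets) is replaced by an in-memory
message bus with byte accounting — 8 bytes per float64 element for
numeric blocks, JSON length for structured payloads, native serialized
size for opaque model objects — because the algorithms, not the
transport, are the reusable content. The message log enforces the
communication pattern: participants may address only the coordinator
(the one exception being secret shares, which are relayed blind), and a
whitelist audit (`audit_message_log()`) checks that no payload kind
corresponding to raw features or labels ever appears.

## Why exact federation works

All the package's "identical to centralized" claims reduce to one
algebraic fact: the estimator depends on the data only through statistics
that are sums over subjects, and sums are partition-invariant.

* **Linear regression.** The normal equations need only `XᵀX`, `Xᵀy`,
  and `n`. Summing per-party Gram matrices gives the pooled ones exactly,
  so the coordinator's solve equals pooled OLS for *any* partition. A
  singular aggregate is solved by SVD pseudoinverse with a warning.
* **Logistic regression.** At a shared β, the pooled score
  `Xᵀ(y − p)` and observed information `Xᵀ diag(p(1−p)) X` are sums of the
  per-party versions, so each federated Newton step equals the centralized
  step, and the whole trajectory coincides. We iterate
  `β ← β + (ΣH)⁻¹(Σg)` until `max|Δβ| < tol` (default 1e−8) or `max_iter`
  rounds (default 25 — roughly 2–3× the ~10 rounds well-conditioned
  problems need, while bounding the worst case). Newton/IRLS was chosen
  as the update rule because gradient-plus-Hessian exchange per round
  implies it and it converges quadratically near the optimum. Convergence
  is declared on coefficient change rather than likelihood change — both
  are commonly used; coefficient change is what the broadcast carries
  anyway, and `tol` applies to the quantity users interpret.
* **Standardization.** Pooled mean and SD come from summed
  `(n, Σx, Σx²)` with Bessel's `n − 1` correction, matching the
  centralized sample-SD convention so the equivalence is exact rather
  than off by `n/(n−1)`. Zero-variance features get SD 1 with a warning
  and pass through centered.
* **Evaluation.** Confusion matrices and `(n, SSE, SAE)` are summable,
  so global F1 and RMSE equal the pooled computation; only counts cross
  the wire. F1 defaults to binary positive-class form (macro averaging is
  a flag), matching the binary tasks of the shipped workflows.
* **Survival.** The Kaplan–Meier product-limit estimator
  `S(t) = Π (1 − dᵢ/nᵢ)` and the log-rank statistic depend only on
  per-time counts of events and censorings. Parties ship event tables;
  the coordinator unions time points and sums counts, which reproduces
  the pooled table exactly. Ties follow the standard convention: subjects
  censored at `t` are still at risk for events at `t`. The log-rank test
  uses hypergeometric variances summed over event times, chi-square with
  k − 1 degrees of freedom.

The cross-validation app makes *local* splits: each party shuffles its
own rows into k balanced folds (default k = 10), unstratified — label
stratification is a plausible variant, but plain uniform shuffles are
the simpler default and the federated-equals-centralized comparisons
condition on the realized folds either way. Downstream apps then train
on folds ≠ f and evaluate on fold f, per fold, and the evaluation app
aggregates per-fold metrics into a median/quartile report.

## Additive secret sharing

Plain federation already hides raw data, but the coordinator still sees
each party's local statistics. With `secure_aggregation = TRUE`, every
sum-based app's payload is split into additive shares: party i encodes
its vector on a fixed-point ring, draws N − 1 uniformly random residue
vectors, and sets the last so all N sum to the encoded secret; each party
then sums the shares addressed to it and sends only that partial sum to
the coordinator, which adds the partials and decodes the global sum. Any
N − 1 shares are jointly uniform, so no proper subset — including the
coordinator's view — reveals a local vector. Below three parties the
scheme is pointless (the coordinator could subtract its own contribution
from the total), so it raises a protocol error.

Numerical choices: the scale is 10⁶ (one ring unit = 10⁻⁶ on the real
line), so reconstructed sums match plain sums to 1/scale per summand —
the 1e−5 agreement bound used in the tests for whole GLM fits. The
modulus is the largest prime below 2⁵², 4 503 599 627 370 449, chosen so
that the sum of any two residues stays below 2⁵³ and modular addition in
double-precision arithmetic is exact without big-integer support;
multiplication by public integer constants uses binary (double-and-add)
multiplication, which only ever adds residues. At this scale values up to
~10⁶ in magnitude encode to ~10¹², leaving room for sums over a few
thousand parties before wrapping — ample for cross-silo settings. The
scheme supports addition and public-scalar multiplication only; no
secret-by-secret products.

The cost is traffic: each party sends one share to every other party, so
share messages grow as n(n − 1) — quadratic — plus n partial sums.
Shares are relayed through the coordinator as an opaque blob (it cannot
decode without all partials), mirroring a relay-server deployment
without party-to-party sockets. The exact share choreography of
production systems varies (e.g. pairwise seeds instead of explicit
shares); we fixed the standard one-round explicit-share scheme and did
not guess further.

## Federated random forest

Forests federate by ensemble merging, in three steps: parties report
sample counts; the coordinator allocates trees proportionally and
broadcasts the allocation; parties train their shares on bootstrap
resamples (unpruned, √p features per split, via the randomForest
package) and the coordinator concatenates them. Two design points the
protocol's description leaves open:

* *Rounding rule.* "Proportional" allocation must preserve the fixed
  global size (default 100 trees), so we use Hamilton largest-remainder
  apportionment with ties broken by party id — the canonical fixed-total
  apportionment. Parties allocated zero trees trigger a warning.
* *Prediction combination.* Merged classification predicts by hard
  majority vote over all trees (ties broken deterministically by label
  order), regression by the mean of tree predictions. Probability
  averaging would need calibrated leaf distributions; hard voting needs
  only tree structures and is what a tree-serialization exchange
  supports. Votes are unweighted beyond the count-proportional
  allocation itself.

Unlike the GLMs, a merged forest is *not* bitwise equal to a centralized
forest — the bootstrap draws differ — so the tests compare
distributionally: median F1 over a 10-fold CV within 0.05 of the
centralized median, and the single-party case reduces exactly to one
centralized `randomForest` call. A party whose local data contain one
class yields a constant predictor with a warning — a valid degenerate
ensemble member. Trees can be exported as nested JSON split tables
(`export_forest_json()`) and applied elsewhere
(`predict_forest_json()`).

## FedAvg neural training

The deep-learning app trains a small multilayer perceptron — default one
hidden layer of 32 tanh units, linear (MSE) or sigmoid (cross-entropy)
output — by federated averaging: broadcast parameters, run
`local_epochs` of plain mini-batch SGD at each party (no momentum; the
optimizer is deliberately the simplest thing that demonstrates the
scheme), then average per tensor with weights `nᵢ/Σn`. Count weighting
makes the scheme exact in one limiting case that anchors the tests: with
one full-batch local step, the weighted mean of per-party mean gradients
*is* the pooled mean gradient, so one federated round equals one
centralized gradient step to machine precision, for any partition. The
default desk-scale architecture is a stand-in for arbitrary
framework-backed networks, and is implemented with plain matrix algebra
so the package carries no GPU dependency. Evaluation uses a 20% local
holdout rather than k-fold CV — the convention for larger datasets where
CV is wasteful. Divergence (non-finite or exploding loss) aborts with
the failing round identified.

## The synthetic-data generator

`synth_dataset()` produces the three task types with standard-Gaussian,
unit-variance features and a linear signal: regression
`y = Xβ + ε`, classification `P(y=1) = plogis(Xβ)` with Bernoulli draws,
and survival with exponential event times at rate `exp(Xβ)` plus
independent uniform censoring whose upper bound is calibrated by
root-finding so the expected censored fraction hits `censoring_rate`
(default 0.30, a typical clinical-cohort figure). Preset geometries
mirror common evaluation datasets: a 579 × 10 binary task, a 442 × 10
regression, and a large-n 12-feature regression down-sized to n = 5000
by default — the full 42 894 is only ever used for split *arithmetic*
(cheap), never for model fitting, to keep the test suite fast.
`partition_parties()` splits IID (shuffle, then cut to the
floor-allocation plan; default proportions 10/15/15/30/30 with the
remainder dropped, reproducing the canonical uneven five-party split) or
with *label skew*: party p's class mix is
`(1 − s)·global + s·onehot(dominant class)`, dominant classes assigned
round-robin. The acceptance checks use s = 0.8 — strongly but not
degenerately non-IID, so every party still holds some minority-class
samples while local-only models visibly stop generalizing.

What the generator does *not* emulate: real covariate correlation,
heavy tails, missingness, measurement error, or site-level distribution
shift beyond label skew. Passing tests therefore certify the
*federation algebra* — that distributed computation equals pooled
computation under these conditions — not clinical performance on any
real cohort.

## Numerical choices and degenerate inputs

* Newton damping: if the aggregated Hessian fails to solve (separable or
  collinear toy data), 1e−8 is added to its diagonal with a warning —
  invisible for well-posed problems at the 1e−6 comparison tolerance.
* Singular Gram aggregates: SVD pseudoinverse, singular values below
  1e−10 of the largest treated as zero.
* Fold assignment requires `n ≥ k`; fold sizes differ by at most one.
* Zero-variance features standardize to centered zeros (SD forced to 1).
* Constant-class forests, empty tree lists, all-censored survival data,
  and zero-event log-rank inputs are all handled explicitly (constant
  predictors, empty ensembles, `S ≡ 1`, and a clear error respectively).
* Seeds: every stochastic step derives its seed deterministically from
  the workflow seed, the step index, and the party id, so a config plus
  seed reproduces a run bit for bit; share randomness is seeded
  separately so enabling secure aggregation does not perturb model
  randomness.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: GLM
equivalence over hundreds of random datasets of 60–250 rows; forest
comparisons on the 579 × 10 preset with 100 trees and 10 folds; survival
cohorts around 150–230 subjects; FedAvg identities on 80–120 rows;
traffic sweeps over 2–8 parties at fixed pooled n. These sizes were
chosen because the properties being checked are scale-free algebraic
identities or, for forests, stable distributional comparisons — larger n
adds runtime, not information.

## Known limitations

* Honest-but-curious security model only: no differential privacy,
  no homomorphic encryption, no protection against a malicious
  coordinator forging aggregates.
* Exact per-time survival counts disclose small cells; binning or
  secure summation of counts is available but not the default.
* The one-hot app shares category *labels* with the coordinator — a
  documented trade-off (a rare category's presence at some site is
  revealed).
* Abort-and-rerun is the only failure policy; there is no dropout
  recovery mid-round.
* Cross-device scale (thousands of clients) is out of scope; the
  simulator targets a handful of silos.
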