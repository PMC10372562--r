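# fedsilo

Cross-silo federated learning, simulated honestly on one machine.

Clinical and biomedical datasets are scattered across institutions that
cannot pool raw records. In horizontal federated learning a handful of
sites (hospitals, registries, biobanks) each hold the same variables for
different patients; a coordinator orchestrates training by exchanging
**model parameters and sufficient statistics only**, never data. `fedsilo`
is an R package for methodologists and analysts who want to study, teach,
or prototype such analyses: it runs a complete star-topology workflow —
one coordinator, N participants, chained federated applications — entirely
in memory, while logging every simulated message with its byte size so the
communication pattern and traffic of a real deployment can be audited.

## What it computes

For sum-decomposable estimators, federation is *exact*, not approximate:

* **Linear regression** — each party ships its Gram statistics
  (XᵀX, Xᵀy, n); the coordinator solves
  `(Σᵢ XᵢᵀXᵢ) β = Σᵢ Xᵢᵀyᵢ`, which is identical to ordinary least squares
  on the pooled data for any partition.
* **Logistic regression** — iterated Newton–Raphson: parties return the
  local score `Xᵀ(y − p)` and information `Xᵀ diag(p(1−p)) X` at the
  broadcast β; summed, these reproduce the centralized ML trajectory round
  for round.
* **Normalization, evaluation** — pooled means/SDs from summed moments
  `(n, Σx, Σx²)`; global F1 from summed confusion counts; global RMSE from
  summed squared-error sums.
* **Kaplan–Meier and log-rank** — per-time event tables (at-risk, events,
  censorings) are summable, so federated survival curves and the
  hypergeometric log-rank statistic equal the pooled analysis exactly.
* **Random forest** — parties train unpruned trees on bootstrap resamples
  (√p feature sampling) and the coordinator merges them into a global
  ensemble of fixed size (100 trees by default), each party contributing
  proportionally to its sample count via largest-remainder apportionment.
  Here agreement with a centralized forest is distributional, not bitwise.
* **FedAvg neural training** — a small MLP trained by rounds of local
  mini-batch SGD and count-weighted parameter averaging
  `θ ← Σᵢ (nᵢ/n) θᵢ`.
* **Additive secret sharing** — any sum-based aggregation can be routed
  through fixed-point secret shares on a prime ring, so the coordinator
  learns only the global sum, never a local vector; exact to 1e−6 per
  summand at the default scale. Requires ≥ 3 parties.

## Worked example

Five parties hold an uneven 10/15/15/30/30 % split of a 442 × 10
regression cohort. The workflow chains 10-fold cross-validation,
federated standardization, federated linear regression, and federated
evaluation:

```r
library(fedsilo)

d <- synth_diabetes_like(seed = 1)
parties <- partition_parties(d, seed = 1)
sapply(parties, nrow)
#> [1]  44  66  66 132 132

cfg <- workflow_config(
  list(wf_step("cv", k = 10), wf_step("normalization"),
       wf_step("linear_regression"), wf_step("eval_regression")),
  n_parties = 5, seed = 1)
res <- run_workflow(cfg, parties)
res
#> Federated workflow result: 4 step(s), 5 part(ies), 40 message(s)
#> Steps: cv -> normalization -> linear_regression -> eval_regression

glance(res$per_step_reports$eval_regression)
#> # A tibble: 1 × 7
#>   metric median    q1    q3   min   max n_folds
#>   <chr>   <dbl> <dbl> <dbl> <dbl> <dbl>   <int>
#> 1 rmse    0.973 0.892  1.06 0.717  1.28      10
```

The per-fold RMSE distribution is exactly what a centralized pipeline
with the same folds would report (the generator's noise SD is 1, so an
RMSE near 1 means the model has recovered essentially all the signal).
The one-shot fit and its coefficients:

```r
fit <- fed_linear(parties)
head(tidy(fit), 4)
#> # A tibble: 4 × 2
#>   term        estimate
#>   <chr>          <dbl>
#> 1 (Intercept)   0.0154
#> 2 x1            0.976
#> 3 x2           -1.09
#> 4 x3            0.967
```

Estimates sit near the generating coefficients (±1 alternating), and are
equal — to ~1e−15 — to `lm()` on the pooled data. Every simulated message
is logged:

```r
traffic_summary(res)
#> # A tibble: ... round direction      payload_kind       messages bytes
#> 1 broadcast      report                    5  6050
#> 1 to_coordinator fold_counts               5   400
#> 2 broadcast      standardize_params        5 12400
#> 2 to_coordinator moment_stats              5  8480 ...
```

`audit_message_log(res)` verifies that only whitelisted payload kinds —
sufficient statistics, parameters, shares — ever crossed the wire.
`autoplot()` methods draw survival curves, per-fold box plots, and loss
histories; `plot_traffic()` charts bytes per round. A thin command-line
wrapper (`inst/cli/fedsilo`, subcommands `run`, `simulate`, `synth`,
`predict`) drives the same functions from YAML configs; examples live in
`inst/examples/`.

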