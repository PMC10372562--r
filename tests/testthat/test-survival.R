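test_that("local event tables enumerate events, censorings, and risk sets", {
  # all censored: no event times, full count at risk
  allc <- local_event_table(data.frame(time = c(1, 2, 3), event = 0))
  expect_equal(nrow(allc$events), 0)
  expect_equal(allc$n_total, 3)
  # hand enumeration for times 1, 2, 2, 3 all events
  tab <- local_event_table(data.frame(time = c(1, 2, 2, 3), event = 1))
  td <- tidy(tab)
  expect_equal(td$time, c(1, 2, 3))
  expect_equal(td$n_event, c(1L, 2L, 1L))
  expect_equal(td$n_risk, c(4, 3, 1))
  # a single event drives S to zero at its time
  one <- km_curve(local_event_table(data.frame(time = 5, event = 1)))
  expect_equal(one$survival, 0)
  expect_error(local_event_table(data.frame(time = -1, event = 1)),
               "validation error")
})

test_that("aggregating event tables equals pooling the records", {
  t1 <- local_event_table(data.frame(time = c(1, 3, 5), event = c(1, 0, 1)))
  expect_equal(tidy(aggregate_tables(list(t1))), tidy(t1))
  # duplicate table doubles every count
  dbl <- aggregate_tables(list(t1, t1))
  expect_equal(dbl$n_total, 2 * t1$n_total)
  expect_equal(dbl$events$d, 2 * t1$events$d)
  # disjoint-time tables interleave, counts match the pooled records
  a <- data.frame(time = c(1, 4), event = 1)
  b <- data.frame(time = c(2, 3), event = c(1, 0))
  agg <- aggregate_tables(list(local_event_table(a), local_event_table(b)))
  pooled <- local_event_table(rbind(a, b))
  expect_equal(tidy(agg), tidy(pooled))
})

test_that("km_curve implements the product-limit estimator", {
  # no events: S identically 1 (empty curve)
  none <- km_curve(local_event_table(data.frame(time = 1:3, event = 0)))
  expect_equal(nrow(none), 0)
  expect_equal(km_survival_at(none, c(0, 10)), c(1, 1))
  # one step: d=1 of n=2 at t=1 gives S(1) = 0.5
  half <- km_curve(local_event_table(
    data.frame(time = c(1, 2), event = c(1, 0))
  ))
  expect_equal(km_survival_at(half, 1), 0.5)
})

test_that("federated KM is identical to the centralized estimator", {
  skip_if_not_installed("survival")
  # lung-cancer-like synthetic cohort: n ~ 228, ~63% events
  d <- synth_dataset("survival", n_samples = 228, n_features = 3,
                     censoring_rate = 0.37, seed = 101)
  set.seed(101)
  parts <- random_partition(d, 3)
  fed <- fed_kaplan_meier(parts)$curves$overall
  sf <- survival::survfit(
    survival::Surv(time, event) ~ 1, data = dplyr::bind_rows(parts)
  )
  ev <- sf$n.event > 0
  expect_equal(fed$time, sf$time[ev], tolerance = 1e-12)
  expect_equal(fed$survival, sf$surv[ev], tolerance = 1e-12)
  expect_equal(fed$n_risk, sf$n.risk[ev])
  # S is a proper survival function
  expect_true(all(diff(fed$survival) <= 1e-15))
  expect_true(all(fed$survival >= 0 & fed$survival <= 1))
})

test_that("federation exactness holds over random partitions", {
  d <- synth_dataset("survival", 150, 2, censoring_rate = 0.3, seed = 102)
  pooled <- km_curve(local_event_table(d))
  set.seed(102)
  for (n_parties in c(1, 2, 4, 8)) {
    parts <- if (n_parties == 1) list(d) else random_partition(d, n_parties)
    fed <- km_curve(aggregate_tables(lapply(parts, local_event_table)))
    expect_equal(fed$survival, pooled$survival, tolerance = 1e-12)
    expect_equal(fed$n_risk, pooled$n_risk)
  }
})

test_that("log-rank test matches hand computation and the pooled oracle", {
  # two identical groups: statistic 0, p = 1
  g <- local_event_table(data.frame(time = c(1, 2, 3), event = c(1, 1, 0)))
  same <- logrank_test(list(A = g, B = g))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  # all of A's events precede B's: hand-computed hypergeometric sums give
  # O_A = 2, E_A = 5/6, Var = 1/4 + 2/9, so chi-square = 49/17
  a <- local_event_table(data.frame(time = c(1, 2), event = 1))
  b <- local_event_table(data.frame(time = c(3, 4), event = 1))
  lr <- logrank_test(list(A = a, B = b))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-12)
  expect_error(logrank_test(list(A = a)), "2 groups")
  expect_error(
    logrank_test(list(
      A = local_event_table(data.frame(time = 1, event = 0)),
      B = local_event_table(data.frame(time = 2, event = 0))
    )),
    "no events"
  )
})

test_that("log-rank statistic is invariant to the party partition", {
  skip_if_not_installed("survival")
  d <- synth_dataset("survival", 200, 3, censoring_rate = 0.3, seed = 103)
  d$group <- ifelse(d$x1 > 0, "A", "B")
  set.seed(103)
  pooled_fit <- fed_kaplan_meier(list(d), group = "group")
  oracle <- survival::survdiff(
    survival::Surv(time, event) ~ group, data = d
  )
  expect_equal(pooled_fit$logrank$statistic, oracle$chisq, tolerance = 1e-8)
  for (n_parties in c(2, 5)) {
    parts <- random_partition(d, n_parties)
    fed <- fed_kaplan_meier(parts, group = "group")
    expect_equal(fed$logrank$statistic, pooled_fit$logrank$statistic,
                 tolerance = 1e-12)
  }
})
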