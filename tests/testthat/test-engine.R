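test_that("gather orders payloads by party and enforces the barrier", {
  s <- fed_session(3)
  s$round <- 1L
  for (p in 1:3) party_send(s, p, 1.0, "ack", round = 1)
  expect_equal(gather(s, 1, "ack"), list(1.0, 1.0, 1.0))
  s$round <- 2L
  party_send(s, 1, c(1, 2), "model_params", round = 2)
  party_send(s, 2, c(3, 4), "model_params", round = 2)
  expect_error(gather(s, 2, "model_params"), "timeout waiting for party 3")
  party_send(s, 3, c(5, 6), "model_params", round = 2)
  expect_equal(gather(s, 2, "model_params"),
               list(c(1, 2), c(3, 4), c(5, 6)))
})

test_that("broadcast logs one message per recipient with byte accounting", {
  s <- fed_session(8)
  payload <- rnorm(100)  # 800 bytes as raw float64
  broadcast(s, 1, payload, "beta")
  log <- message_log(s)
  expect_equal(nrow(log), 8)
  expect_equal(sum(log$byte_size), 6400)
  expect_true(all(log$sender == 0))
  expect_error(broadcast(s, 1, payload, "beta", from = 1), "role violation")
})

test_that("participant traffic may only target the coordinator", {
  s <- fed_session(3)
  expect_error(party_send(s, 1, c(1), "beta", round = 1, recipient = 2),
               "forbidden")
  # the secure-aggregation exception
  expect_silent(party_send(s, 1, c(1), "secret_share", round = 1,
                           recipient = 2))
  expect_error(party_send(s, 1, c(1), "raw_data", round = 1),
               "unknown payload kind")
})

test_that("an identity workflow returns each party's data unchanged", {
  d <- synth_dataset("regression", 40, 3, seed = 141)
  cfg <- workflow_config(list(wf_step("identity")), n_parties = 1, seed = 1)
  res <- run_workflow(cfg, list(d))
  expect_identical(res$final_outputs[[1]], d)
  # one-shot app with N parties: N submissions and N broadcasts
  parts <- partition_parties(d, c(0.5, 0.5), seed = 1)
  cfg2 <- workflow_config(list(wf_step("identity")), n_parties = 2, seed = 1)
  log <- message_log(run_workflow(cfg2, parts))
  expect_equal(sum(log$recipient == 0), 2)
  expect_equal(sum(log$sender == 0), 2)
})

test_that("misconfigured workflows fail fast with configuration errors", {
  d <- synth_dataset("regression", 40, 3, seed = 142)
  expect_error(
    run_workflow(workflow_config(list(wf_step("cox")), 1, 1), list(d)),
    "unknown app"
  )
  # slot mismatch: eval consumes 'model' but cv produces 'folds'
  expect_error(
    run_workflow(workflow_config(
      list(wf_step("cv", k = 2), wf_step("eval_regression")), 1, 1
    ), list(d)),
    "configuration error"
  )
  expect_error(
    run_workflow(workflow_config(list(wf_step("identity")), 2, 1), list(d)),
    "one dataset per party"
  )
})

test_that("a failing app aborts the workflow naming the step", {
  register_app("exploding", list(
    consumes = "data", produces = "data",
    participant_phase = function(state, broadcast_in, params, ctx) {
      stop("boom")
    },
    coordinator_phase = function(cstate, payloads, params, ctx) {
      list(done = TRUE)
    }
  ))
  d <- synth_dataset("regression", 30, 2, seed = 143)
  err <- tryCatch(
    run_workflow(workflow_config(
      list(wf_step("identity"), wf_step("exploding")), 1, 1
    ), list(d)),
    error = function(e) e
  )
  expect_s3_class(err, "fedsilo_workflow_error")
  expect_match(conditionMessage(err), "step 2 \\('exploding'\\)")
})

test_that("the five-party evaluation chain produces ordered step reports", {
  d <- synth_dataset("classification", 250, 6, seed = 144)
  parts <- partition_parties(d, seed = 144)
  cfg <- workflow_config(
    list(wf_step("cv", k = 3), wf_step("normalization"),
         wf_step("random_forest", task = "classification", n_trees = 50),
         wf_step("eval_classification")),
    n_parties = 5, seed = 144
  )
  res <- run_workflow(cfg, parts)
  expect_equal(names(res$per_step_reports),
               c("cv", "normalization", "random_forest",
                 "eval_classification"))
  expect_length(res$per_step_reports, 4)
  expect_s3_class(res$per_step_reports$eval_classification, "fed_cv_report")
  audit_message_log(res)
})

test_that("the federated linear pipeline matches a centralized pipeline", {
  d <- synth_dataset("regression", 500, 6, seed = 145)
  parts <- partition_parties(d, c(0.10, 0.15, 0.15, 0.30, 0.30), seed = 145)
  cfg <- workflow_config(
    list(wf_step("cv", k = 5), wf_step("normalization"),
         wf_step("linear_regression"), wf_step("eval_regression")),
    n_parties = 5, seed = 146
  )
  res <- run_workflow(cfg, parts)
  fed_rmse <- res$per_step_reports$eval_regression$per_fold$metric
  expect_equal(fed_rmse, oracle_pipeline_rmse(res$party_states),
               tolerance = 1e-8)
})

test_that("workflows are deterministic under a fixed seed", {
  d <- synth_dataset("classification", 200, 4, seed = 147)
  parts <- partition_parties(d, c(0.4, 0.6), seed = 147)
  cfg <- workflow_config(
    list(wf_step("cv", k = 3), wf_step("normalization"),
         wf_step("logistic_regression"), wf_step("eval_classification")),
    n_parties = 2, seed = 148
  )
  r1 <- run_workflow(cfg, parts)
  r2 <- run_workflow(cfg, parts)
  expect_identical(message_log(r1), message_log(r2))
  expect_identical(r1$per_step_reports$eval_classification$per_fold,
                   r2$per_step_reports$eval_classification$per_fold)
  expect_identical(r1$party_states[[1]]$model$betas,
                   r2$party_states[[1]]$model$betas)
})

test_that("the message log passes the privacy whitelist audit", {
  d <- synth_dataset("regression", 150, 4, seed = 149)
  parts <- partition_parties(d, c(0.3, 0.3, 0.4), seed = 149)
  cfg <- workflow_config(
    list(wf_step("cv", k = 2), wf_step("normalization"),
         wf_step("linear_regression"), wf_step("eval_regression")),
    n_parties = 3, seed = 150, secure_aggregation = TRUE
  )
  res <- run_workflow(cfg, parts)
  expect_true(audit_message_log(res))
  expect_error(
    audit_message_log(tibble::tibble(sender = 1, recipient = 0, round = 1,
                                     payload_kind = "raw_labels",
                                     byte_size = 10)),
    "privacy audit failed"
  )
  # secure aggregation is refused below 3 parties
  cfg2 <- workflow_config(list(wf_step("identity")), n_parties = 2,
                          seed = 1, secure_aggregation = TRUE)
  expect_error(run_workflow(cfg2, parts[1:2]), "at least 3 parties")
})

test_that("secure share messages scale as n(n-1) per secure round", {
  d <- synth_dataset("regression", 200, 3, seed = 151)
  for (n in c(3, 4)) {
    props <- rep(1 / n, n)
    parts <- partition_parties(d, props, seed = 151)
    cfg <- workflow_config(
      list(wf_step("normalization", consumes = "data"),
           wf_step("linear_regression"), wf_step("eval_regression")),
      n_parties = n, seed = 152, secure_aggregation = TRUE
    )
    log <- message_log(run_workflow(cfg, parts))
    shares_per_round <- log |>
      dplyr::filter(.data$payload_kind == "secret_share") |>
      dplyr::count(.data$round)
    expect_true(all(shares_per_round$n == n * (n - 1)))
  }
})

test_that("one-hot workflow aligns encoded columns across parties", {
  d1 <- tibble::tibble(x1 = rnorm(5), site = c("A", "A", "B", "B", "A"),
                       y = rnorm(5))
  d2 <- tibble::tibble(x1 = rnorm(5), site = c("B", "C", "C", "B", "C"),
                       y = rnorm(5))
  cfg <- workflow_config(list(wf_step("one_hot")), n_parties = 2, seed = 1)
  res <- run_workflow(cfg, list(d1, d2))
  out1 <- res$final_outputs[[1]]
  out2 <- res$final_outputs[[2]]
  expect_true(all(c("site_A", "site_B", "site_C") %in% names(out1)))
  expect_identical(names(out1), names(out2))
  expect_equal(sum(out2$site_A), 0)  # absent category encodes all-zero
})

test_that("the kaplan_meier app reproduces the direct federated fit", {
  d <- synth_dataset("survival", 150, 3, censoring_rate = 0.3, seed = 153)
  d$group <- ifelse(d$x1 > 0, "A", "B")
  parts <- partition_parties(d, c(0.5, 0.5), label = "event", seed = 153)
  cfg <- workflow_config(list(wf_step("kaplan_meier", group = "group")),
                         n_parties = 2, seed = 1)
  res <- run_workflow(cfg, parts)
  direct <- fed_kaplan_meier(parts, group = "group")
  expect_equal(res$per_step_reports$kaplan_meier$logrank$statistic,
               direct$logrank$statistic, tolerance = 1e-12)
  expect_equal(res$final_outputs[[1]]$curves$A$survival,
               direct$curves$A$survival)
})
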