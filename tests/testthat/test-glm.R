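test_that("local Gram statistics match direct matrix products", {
  g <- local_gram(diag(2), c(1, 2))
  expect_equal(unname(g$xtx), diag(2))
  expect_equal(unname(g$xty), c(1, 2))
  # rank-1 single row
  g1 <- local_gram(matrix(c(3, 5), 1, 2), 2)
  expect_equal(unname(g1$xtx), matrix(c(9, 15, 15, 25), 2, 2))
  # random case against explicit t(X) %*% X
  set.seed(21)
  x <- matrix(rnorm(150), 50, 3)
  y <- rnorm(50)
  g2 <- local_gram(x, y)
  expect_equal(unname(g2$xtx), t(x) %*% x)
  expect_equal(unname(g2$xty), drop(t(x) %*% y))
})

test_that("federated linear regression equals pooled least squares", {
  # single party degenerates to local OLS
  d <- synth_dataset("regression", 80, 3, seed = 31)
  f1 <- fed_linear(list(d))
  expect_equal(unname(f1$beta), unname(oracle_ols(d)), tolerance = 1e-10)
  # noiseless data: exact recovery under any partition
  d0 <- synth_dataset("regression", 100, 4, noise_sd = 0, seed = 32)
  set.seed(32)
  for (n_parties in c(2, 5, 8)) {
    parts <- random_partition(d0, n_parties)
    fit <- fed_linear(parts, intercept = FALSE)
    expect_equal(unname(fit$beta), attr(d0, "beta"), tolerance = 1e-10)
  }
  # diabetes-like geometry with the uneven five-party split
  dd <- synth_diabetes_like(seed = 33)
  parts <- partition_parties(dd, seed = 33)
  fit <- fed_linear(parts)
  pooled <- dplyr::bind_rows(parts)
  expect_lt(max(abs(fit$beta - oracle_ols(pooled))), 1e-8)
})

test_that("singular aggregated Gram falls back to the pseudoinverse", {
  x <- cbind(1:4, (1:4) * 2)  # collinear
  g <- local_gram(x, c(1, 2, 3, 4))
  expect_warning(fit <- fit_linear(list(g)), "pseudoinverse")
  expect_true(fit$singular)
  expect_true(all(is.finite(fit$beta)))
})

test_that("local Newton rounds match closed forms and numeric gradients", {
  # beta = 0 on label-balanced data (every x appears once with each
  # label): residuals y - 1/2 cancel, so the gradient vanishes
  x <- rbind(c(1, 2), c(1, 2), c(-3, 1), c(-3, 1))
  y <- c(1, 0, 1, 0)
  r <- local_logistic_round(x, y, c(0, 0))
  expect_equal(unname(r$gradient), c(0, 0))
  # beta = 0: p = 1/2 everywhere, Hessian = X'X / 4
  set.seed(41)
  x2 <- matrix(rnorm(60), 20, 3)
  y2 <- rbinom(20, 1, 0.5)
  r2 <- local_logistic_round(x2, y2, rep(0, 3))
  expect_equal(r2$hessian, crossprod(x2) / 4)
  # random beta: gradient matches finite differences of the log-likelihood
  beta <- rnorm(3) / 2
  ll <- function(b) {
    eta <- drop(x2 %*% b)
    sum(y2 * eta - log1p(exp(eta)))
  }
  num_grad <- vapply(1:3, function(j) {
    h <- 1e-6
    e <- rep(0, 3); e[j] <- h
    (ll(beta + e) - ll(beta - e)) / (2 * h)
  }, numeric(1))
  r3 <- local_logistic_round(x2, y2, beta)
  expect_equal(unname(r3$gradient), num_grad, tolerance = 1e-5)
  # deviance equals -2 * log-likelihood
  expect_equal(r3$deviance, -2 * ll(beta), tolerance = 1e-10)
})

test_that("federated logistic Newton equals the centralized ML fit", {
  d <- synth_dataset("classification", 400, 5, seed = 51)
  # partitioned vs unpartitioned: identical because summed gradients and
  # Hessians are partition-invariant
  set.seed(51)
  parts <- random_partition(d, 3)
  f_part <- fed_logistic(parts)
  f_whole <- fed_logistic(list(d))
  expect_equal(f_part$beta, f_whole$beta, tolerance = 1e-10)
  expect_equal(f_part$iterations, f_whole$iterations)
  # against the centralized solver oracle
  expect_lt(max(abs(f_part$beta - oracle_logistic(d))), 1e-6)
  expect_true(f_part$converged)
  # ILPD-like geometry, uneven five-party split
  di <- synth_ilpd_like(seed = 52)
  pi5 <- partition_parties(di, seed = 52)
  fi <- fed_logistic(pi5)
  expect_lt(max(abs(fi$beta - oracle_logistic(dplyr::bind_rows(pi5)))), 1e-6)
})

test_that("logistic deviance decreases across Newton rounds", {
  d <- synth_dataset("classification", 300, 4, seed = 61)
  f <- fed_logistic(list(d))
  expect_true(all(diff(f$deviance_trace) <= 1e-8))
  expect_error(fed_logistic(list(dplyr::mutate(d, y = 1))), "both classes")
})

test_that("secure aggregation leaves GLM fits unchanged within codec scale", {
  d <- synth_dataset("regression", 200, 4, seed = 71)
  set.seed(71)
  parts <- random_partition(d, 3)
  plain <- fed_linear(parts)
  sec <- fed_linear(parts, secure = TRUE, seed = 72)
  expect_lt(max(abs(plain$beta - sec$beta)), 1e-5)
  dc <- synth_dataset("classification", 250, 3, seed = 73)
  set.seed(73)
  pc <- random_partition(dc, 4)
  plain_l <- fed_logistic(pc)
  sec_l <- fed_logistic(pc, secure = TRUE, seed = 74)
  expect_lt(max(abs(plain_l$beta - sec_l$beta)), 1e-5)
})

test_that("GLM fits tidy, glance, and export cleanly", {
  d <- synth_dataset("regression", 120, 3, seed = 81)
  fit <- fed_linear(list(d))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(glance(fit)), 1)
  path <- withr::local_tempfile(fileext = ".json")
  export_glm_json(fit, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$beta, unname(fit$beta), tolerance = 1e-12)
})
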