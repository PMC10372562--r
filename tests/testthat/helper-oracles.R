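# Independent oracles used across the suite.  These recompute expected
# results on pooled data with base R / established packages, never through
# the federated code paths they check.

# pooled ordinary least squares (intercept first), via QR
oracle_ols <- function(data, label = "y") {
  x <- cbind(1, as.matrix(data[setdiff(names(data), label)]))
  qr.solve(x, data[[label]])
}

# pooled unpenalized logistic ML fit via glm (the centralized solver)
oracle_logistic <- function(data, label = "y") {
  f <- stats::as.formula(paste(label, "~ ."))
  stats::coef(stats::glm(f, data = data, family = stats::binomial(),
                         control = stats::glm.control(epsilon = 1e-12,
                                                      maxit = 200)))
}

# random partition of a data frame into 1..max_parties contiguous shuffled
# blocks (every row kept)
random_partition <- function(data, n_parties) {
  idx <- sample(nrow(data))
  cuts <- sort(sample(seq_len(nrow(data) - 1), n_parties - 1))
  bounds <- c(0, cuts, nrow(data))
  lapply(seq_len(n_parties), function(p) {
    data[idx[(bounds[p] + 1):bounds[p + 1]], , drop = FALSE]
  })
}

# centralized per-fold RMSE oracle for the cv/normalization/linear/eval
# pipeline, reusing the parties' own fold assignments and standardized
# matrices (which are themselves checked against pooled standardization
# elsewhere) but fitting and scoring with base R on the pooled data
oracle_pipeline_rmse <- function(states) {
  k <- states[[1]]$standardized$k
  vapply(seq_len(k), function(f) {
    tr_x <- do.call(rbind, lapply(states, function(s) {
      s$standardized$x[[f]][s$standardized$folds != f, , drop = FALSE]
    }))
    tr_y <- unlist(lapply(states, function(s) {
      s$standardized$y[s$standardized$folds != f]
    }))
    te_x <- do.call(rbind, lapply(states, function(s) {
      s$standardized$x[[f]][s$standardized$folds == f, , drop = FALSE]
    }))
    te_y <- unlist(lapply(states, function(s) {
      s$standardized$y[s$standardized$folds == f]
    }))
    beta <- qr.solve(cbind(1, tr_x), tr_y)
    sqrt(mean((te_y - drop(cbind(1, te_x) %*% beta))^2))
  }, numeric(1))
}

# flatten mlp parameters for elementwise comparison
unlist_flat <- function(params) {
  unlist(lapply(params, function(l) c(as.vector(l$w), l$b)))
}

# F1 computed directly from pooled label vectors
oracle_f1 <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}
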