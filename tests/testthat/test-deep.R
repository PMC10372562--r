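test_that("local updates are deterministic and inert at zero learning rate", {
  set.seed(131)
  x <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  p0 <- mlp_init(c(3, 8, 1), seed = 1)
  cfg0 <- list(local_epochs = 2, batch_size = 5, learning_rate = 0,
               loss = "mse", seed = 3)
  expect_equal(local_update(p0, x, y, cfg0), p0)
  cfg <- list(local_epochs = 3, batch_size = 4, learning_rate = 0.05,
              loss = "mse", seed = 3)
  expect_identical(local_update(p0, x, y, cfg), local_update(p0, x, y, cfg))
})

test_that("a linear network's full-batch step matches the analytic gradient", {
  set.seed(132)
  x <- matrix(rnorm(80), 20, 4)
  y <- rnorm(20)
  p0 <- mlp_init(c(4, 1), seed = 2)
  lr <- 0.1
  cfg <- list(local_epochs = 1, batch_size = 20, learning_rate = lr,
              loss = "mse", seed = 1)
  upd <- local_update(p0, x, y, cfg)
  # closed form: L = mean((Xw + b - y)^2), dL/dw = 2 X'(Xw + b - y)/n
  resid <- drop(x %*% p0[[1]]$w) + p0[[1]]$b - y
  grad_w <- 2 * drop(t(x) %*% resid) / 20
  grad_b <- 2 * mean(resid)
  expect_equal(drop(upd[[1]]$w), drop(p0[[1]]$w) - lr * grad_w,
               tolerance = 1e-12)
  expect_equal(upd[[1]]$b, p0[[1]]$b - lr * grad_b, tolerance = 1e-12)
})

test_that("fedavg is a count-weighted mean with the expected algebra", {
  p <- mlp_init(c(2, 3, 1), seed = 4)
  # idempotence on identical inputs
  expect_equal(fedavg(list(p, p, p), c(10, 20, 30)), p)
  # symmetry: equal counts with params W and -W cancel
  neg <- p
  for (l in seq_along(neg)) {
    neg[[l]]$w <- -neg[[l]]$w
    neg[[l]]$b <- -neg[[l]]$b
  }
  avg <- fedavg(list(p, neg), c(5, 5))
  expect_equal(max(abs(unlist(lapply(avg, function(l) c(l$w, l$b))))), 0)
  # affine equivariance: fedavg(a * P + b) = a * fedavg(P) + b
  set.seed(133)
  ps <- lapply(1:3, function(i) mlp_init(c(2, 3, 1), seed = i))
  ns <- c(3, 9, 4)
  base <- fedavg(ps, ns)
  a <- 2.5; b <- -0.75
  shifted <- lapply(ps, function(pp) {
    for (l in seq_along(pp)) {
      pp[[l]]$w <- a * pp[[l]]$w + b
      pp[[l]]$b <- a * pp[[l]]$b + b
    }
    pp
  })
  got <- fedavg(shifted, ns)
  for (l in seq_along(base)) {
    expect_equal(got[[l]]$w, a * base[[l]]$w + b, tolerance = 1e-12)
    expect_equal(got[[l]]$b, a * base[[l]]$b + b, tolerance = 1e-12)
  }
  # convex hull: every averaged weight lies inside the per-party range
  lo <- pmin(unlist_flat(ps[[1]]), unlist_flat(ps[[2]]), unlist_flat(ps[[3]]))
  hi <- pmax(unlist_flat(ps[[1]]), unlist_flat(ps[[2]]), unlist_flat(ps[[3]]))
  m <- unlist_flat(base)
  expect_true(all(m >= lo - 1e-12 & m <= hi + 1e-12))
  expect_error(fedavg(list(p, mlp_init(c(2, 4, 1), seed = 1)), c(1, 1)),
               "protocol error")
})

test_that("one full-batch step federates exactly to the pooled step", {
  set.seed(134)
  x <- matrix(rnorm(180), 60, 3)
  y <- rnorm(60)
  p0 <- mlp_init(c(3, 5, 1), seed = 6)
  cfg <- list(local_epochs = 1, batch_size = 1e6, learning_rate = 0.1,
              loss = "mse", seed = 1)
  for (split in list(list(1:20, 21:60), list(1:10, 11:30, 31:60))) {
    locals <- lapply(split, function(i) {
      local_update(p0, x[i, , drop = FALSE], y[i], cfg)
    })
    avg <- fedavg(locals, lengths(split))
    pooled <- local_update(p0, x, y, cfg)
    expect_equal(unlist_flat(avg), unlist_flat(pooled), tolerance = 1e-10)
  }
})

test_that("IID full-batch federated training tracks centralized descent", {
  set.seed(135)
  d <- synth_dataset("regression", 120, 4, seed = 135)
  x <- as.matrix(d[paste0("x", 1:4)])
  y <- d$y
  cfg <- list(rounds = 5, local_epochs = 1, batch_size = 1e6,
              learning_rate = 0.05, loss = "mse", seed = 9)
  parties <- list(list(x = x[1:60, ], y = y[1:60]),
                  list(x = x[61:120, ], y = y[61:120]))
  fed <- train_federated(parties, c(4, 6, 1), cfg)
  # centralized oracle: full-batch descent on the pooled data
  p <- mlp_init(c(4, 6, 1), seed = cfg$seed)
  scfg <- list(local_epochs = 1, batch_size = 1e6, learning_rate = 0.05,
               loss = "mse", seed = 1)
  for (r in 1:5) p <- local_update(p, x, y, scfg)
  expect_equal(unlist_flat(fed$params), unlist_flat(p), tolerance = 1e-10)
  expect_equal(nrow(fed$history), 5)
  expect_true(all(diff(fed$history$loss) < 0))
})

test_that("single-party training equals centralized mini-batch training", {
  d <- synth_dataset("regression", 80, 3, seed = 136)
  cfg <- list(rounds = 3, local_epochs = 2, batch_size = 16,
              learning_rate = 0.02, loss = "mse", seed = 11)
  f1 <- train_federated(list(d), c(3, 4, 1), cfg)
  f2 <- train_federated(list(d), c(3, 4, 1), cfg)
  expect_identical(unlist_flat(f1$params), unlist_flat(f2$params))
})
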