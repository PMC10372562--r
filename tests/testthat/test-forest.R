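test_that("tree allocation is proportional with a fixed total", {
  expect_equal(allocate_trees(c(50, 50), 100)$n_trees, c(50L, 50L))
  # the uneven five-party split maps to the printed percentages
  expect_equal(allocate_trees(c(4289, 6434, 6434, 12868, 12868), 100)$n_trees,
               c(10L, 15L, 15L, 30L, 30L))
  # equal tiny counts: total preserved, near-even split
  a <- allocate_trees(c(1, 1, 1), 100)
  expect_equal(sum(a$n_trees), 100L)
  expect_lte(max(a$n_trees) - min(a$n_trees), 1L)
  # more parties than trees still sums correctly, warning on zero shares
  expect_warning(a2 <- allocate_trees(rep(1, 7), 5), "0 trees")
  expect_equal(sum(a2$n_trees), 5L)
})

test_that("the global ensemble always holds exactly 100 trees", {
  set.seed(121)
  for (n_parties in c(1, 7, 17, 30)) {
    counts <- sample(20:200, n_parties, replace = TRUE)
    expect_equal(sum(allocate_trees(counts, 100)$n_trees), 100L)
  }
  # and a fitted merge really contains that many trees
  d <- synth_dataset("classification", 120, 4, seed = 121)
  parts <- partition_parties(d, c(0.3, 0.3, 0.4), seed = 121)
  ens <- fed_random_forest(parts, n_trees_global = 100, seed = 1)
  expect_equal(ens$n_trees, 100)
  expect_equal(sum(tidy(ens)$n_trees), 100)
})

test_that("allocation is monotone in a party's sample count", {
  set.seed(122)
  for (trial in 1:25) {
    k <- sample(2:6, 1)
    counts <- sample(10:100, k, replace = TRUE)
    base <- allocate_trees(counts, 100)$n_trees
    bumped <- counts
    j <- sample(k, 1)
    bumped[j] <- bumped[j] + sample(1:20, 1)
    after <- allocate_trees(bumped, 100)$n_trees
    expect_gte(after[j], base[j])
  }
})

test_that("local training is seeded and handles degenerate parties", {
  d <- synth_dataset("classification", 80, 4, seed = 123)
  expect_length(train_local_trees(d, n_trees = 0), 0)
  t1 <- train_local_trees(d, n_trees = 5, labels = c("0", "1"), seed = 9)
  t2 <- train_local_trees(d, n_trees = 5, labels = c("0", "1"), seed = 9)
  expect_equal(randomForest::getTree(t1[[1]]$forest, 1),
               randomForest::getTree(t2[[1]]$forest, 1))
  # pure single-class party: constant predictor everywhere
  pure <- d[d$y == 1, ]
  expect_warning(tp <- train_local_trees(pure, n_trees = 3,
                                         labels = c("0", "1")),
                 "single-class")
  ens <- merge_forests(list(tp), labels = c("0", "1"))
  expect_true(all(predict(ens, d[paste0("x", 1:4)]) == "1"))
})

test_that("a single-party merge behaves like a centralized forest", {
  d <- synth_dataset("classification", 150, 5, seed = 124)
  parts <- partition_parties(d, 1.0, seed = 124)
  ens <- fed_random_forest(parts, n_trees_global = 100, seed = 77)
  # the same seed yields the same randomForest call as a central fit
  set.seed(fedsilo:::make_seed(77, 1))
  x <- as.data.frame(parts[[1]][paste0("x", 1:5)])
  central <- randomForest::randomForest(
    x = x, y = factor(as.character(parts[[1]]$y), levels = c("0", "1")),
    ntree = 100, mtry = 2, replace = TRUE, nodesize = 1
  )
  test_x <- d[paste0("x", 1:5)]
  fed_votes <- predict(ens, test_x, type = "votes")
  cen_votes <- predict(central, test_x, type = "vote", norm.votes = FALSE)
  expect_equal(unname(fed_votes), unname(cen_votes))
})

test_that("identical data copies give federated F1 near the centralized band", {
  d <- synth_dataset("classification", 200, 6, seed = 125)
  test_d <- synth_dataset("classification", 300, 6, seed = 126)
  test_x <- test_d[paste0("x", 1:6)]
  # centralized seed-to-seed F1 band over 20 seeds
  cen_f1 <- vapply(1:20, function(s) {
    set.seed(s)
    rf <- randomForest::randomForest(
      x = as.data.frame(d[paste0("x", 1:6)]),
      y = factor(as.character(d$y), levels = c("0", "1")),
      ntree = 100, mtry = 2, replace = TRUE, nodesize = 1
    )
    pred <- as.character(predict(rf, test_x))
    oracle_f1(as.character(test_d$y), pred, "1")
  }, numeric(1))
  ens <- fed_random_forest(list(d, d), n_trees_global = 100, seed = 300)
  fed_f1 <- oracle_f1(as.character(test_d$y),
                      predict(ens, test_x), "1")
  band <- range(cen_f1) + c(-1, 1) * stats::sd(cen_f1)
  expect_gte(fed_f1, band[1])
  expect_lte(fed_f1, band[2])
})

test_that("JSON forest export predicts like the in-memory ensemble", {
  d <- synth_dataset("classification", 100, 4, seed = 127)
  parts <- partition_parties(d, c(0.5, 0.5), seed = 127)
  ens <- fed_random_forest(parts, n_trees_global = 20, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  export_forest_json(ens, path)
  test_x <- d[paste0("x", 1:4)]
  expect_equal(predict_forest_json(path, test_x),
               unname(predict(ens, test_x)))
})
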