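#' Proportional tree allocation by largest-remainder apportionment
#'
#' The merged forest has a fixed global size; each party contributes a
#' number of trees proportional to its sample count.  "Proportional"
#' needs a rounding rule that preserves the fixed total, so Hamilton's
#' largest-remainder method is used: floor the exact quotas, then hand the
#' leftover trees to the largest fractional remainders (ties broken by
#' lower party id).
#'
#' @param sample_counts Per-party local sample counts (all >= 1).
#' @param n_trees_global Total ensemble size (default 100).
#' @return A tibble with `party`, `n_samples`, `n_trees`; `sum(n_trees)`
#'   always equals `n_trees_global`.  A warning is raised if any party is
#'   allocated zero trees.
#' @examples
#' allocate_trees(c(4289, 6434, 6434, 12868, 12868))
#' @export
allocate_trees <- function(sample_counts, n_trees_global = 100) {
  stopifnot(all(sample_counts >= 1), n_trees_global >= 1)
  quota <- n_trees_global * sample_counts / sum(sample_counts)
  base <- floor(quota)
  left <- n_trees_global - sum(base)
  if (left > 0) {
    extra <- order(-(quota - base), seq_along(quota))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  if (any(base == 0)) {
    warning("some parties are allocated 0 trees", call. = FALSE)
  }
  tibble::tibble(
    party = seq_along(sample_counts),
    n_samples = as.integer(sample_counts),
    n_trees = as.integer(base)
  )
}

#' Train a party's share of the global forest
#'
#' Fits `n_trees` unpruned decision trees on bootstrap resamples of the
#' local data with sqrt-of-features sampling per split, via the
#' randomForest package.  A party whose local data holds a single class
#' yields a constant predictor (with a warning) — a valid degenerate
#' ensemble member.
#'
#' @param data Local data frame (features plus label column).
#' @param label Label column name.
#' @param n_trees Trees to train (0 gives an empty list).
#' @param task `"classification"` or `"regression"`.
#' @param labels Global class label set (classification), so that vote
#'   matrices align across parties.
#' @param seed Integer seed (fixed seed reproduces identical trees).
#' @return A list of ensemble members, each
#'   `list(forest = , n_trees = , constant = )` where `forest` is a
#'   `randomForest` object or, for single-class data, the constant class.
#' @export
train_local_trees <- function(data, label = "y", n_trees,
                              task = c("classification", "regression"),
                              labels = NULL, seed = NULL) {
  task <- match.arg(task)
  if (n_trees == 0) return(list())
  stopifnot(nrow(data) >= 1)
  x <- as.data.frame(data[setdiff(names(data), label)])
  yv <- data[[label]]
  if (!is.null(seed)) set.seed(seed)
  mtry <- max(1, floor(sqrt(ncol(x))))
  if (task == "classification") {
    if (is.null(labels)) labels <- sort(unique(as.character(yv)))
    y <- factor(as.character(yv), levels = labels)
    if (length(unique(as.character(yv))) < 2) {
      warning("single-class local data; trees are constant predictors",
              call. = FALSE)
      return(list(list(forest = as.character(yv[1]), n_trees = n_trees,
                       constant = TRUE)))
    }
    fo <- randomForest::randomForest(
      x = x, y = y, ntree = n_trees, mtry = mtry,
      replace = TRUE, nodesize = 1
    )
  } else {
    fo <- randomForest::randomForest(
      x = x, y = as.numeric(yv), ntree = n_trees, mtry = mtry,
      replace = TRUE, nodesize = 1
    )
  }
  list(list(forest = fo, n_trees = n_trees, constant = FALSE))
}

#' Merge per-party tree lists into the global ensemble
#'
#' Concatenates each party's trees into one forest of exactly the global
#' size.  Classification predicts by majority (hard) vote over all trees;
#' regression averages tree predictions.  Per-tree provenance (the
#' contributing party) is retained.
#'
#' @param local_tree_lists List (per party) of [train_local_trees()]
#'   outputs.
#' @param task `"classification"` or `"regression"`.
#' @param labels Global class label set (classification).
#' @return Object of class `fed_forest`: `members` (each with `party`,
#'   `forest`, `n_trees`, `constant`), `n_trees`, `task`, `labels`.
#' @export
merge_forests <- function(local_tree_lists,
                          task = c("classification", "regression"),
                          labels = NULL) {
  task <- match.arg(task)
  members <- list()
  for (p in seq_along(local_tree_lists)) {
    for (m in local_tree_lists[[p]]) {
      m$party <- p
      members <- c(members, list(m))
    }
  }
  n_trees <- sum(vapply(members, function(m) m$n_trees, numeric(1)))
  structure(
    list(members = members, n_trees = n_trees, task = task, labels = labels),
    class = "fed_forest"
  )
}

#' Predict with a merged federated forest
#'
#' @param object A [merge_forests()] ensemble.
#' @param newdata Data frame of features.
#' @param type `"response"` for the voted class / mean prediction,
#'   `"votes"` for the per-class vote-count matrix (classification only).
#' @param ... Unused.
#' @return Predictions (character vector / numeric vector), or a vote
#'   matrix.
#' @export
predict.fed_forest <- function(object, newdata, type = c("response", "votes"),
                               ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  if (object$task == "classification") {
    labels <- object$labels
    votes <- matrix(0, nrow(newdata), length(labels),
                    dimnames = list(NULL, labels))
    for (m in object$members) {
      if (m$constant) {
        votes[, m$forest] <- votes[, m$forest] + m$n_trees
      } else {
        v <- stats::predict(m$forest, newdata, type = "vote",
                            norm.votes = FALSE)
        votes[, colnames(v)] <- votes[, colnames(v)] + v
      }
    }
    if (type == "votes") return(votes)
    # deterministic tie-break: first label in the global ordering wins
    labels[apply(votes, 1, which.max)]
  } else {
    tot <- rep(0, nrow(newdata))
    for (m in object$members) {
      ind <- stats::predict(m$forest, newdata, predict.all = TRUE)$individual
      tot <- tot + rowSums(ind)
    }
    tot / object$n_trees
  }
}

#' @export
print.fed_forest <- function(x, ...) {
  per_party <- table(vapply(x$members, function(m) m$party, numeric(1)))
  cat(sprintf("Federated %s forest: %d trees from %d part(ies)\n",
              x$task, x$n_trees, length(per_party)))
  invisible(x)
}

#' End-to-end federated random forest
#'
#' Runs the three-step protocol on a list of party training sets: parties
#' report sample counts, the coordinator allocates trees by
#' [allocate_trees()], parties train their shares, and the coordinator
#' merges them into the fixed-size global ensemble.
#'
#' @param data_list List of party data frames.
#' @param label Label column name.
#' @param task `"classification"` or `"regression"`.
#' @param n_trees_global Global ensemble size (default 100).
#' @param seed Integer seed; per-party training seeds are derived from it.
#' @return A `fed_forest` (with the allocation tibble as attribute
#'   `"allocation"`).
#' @export
fed_random_forest <- function(data_list, label = "y",
                              task = c("classification", "regression"),
                              n_trees_global = 100, seed = NULL) {
  task <- match.arg(task)
  alloc <- allocate_trees(vapply(data_list, nrow, integer(1)), n_trees_global)
  labels <- NULL
  if (task == "classification") {
    labels <- sort(unique(unlist(lapply(data_list, function(d) {
      as.character(d[[label]])
    }))))
  }
  tree_lists <- lapply(seq_along(data_list), function(p) {
    train_local_trees(
      data_list[[p]], label = label, n_trees = alloc$n_trees[p], task = task,
      labels = labels,
      seed = if (is.null(seed)) NULL else make_seed(seed, p)
    )
  })
  out <- merge_forests(tree_lists, task = task, labels = labels)
  attr(out, "allocation") <- alloc
  out
}

#' Export a merged forest as portable JSON
#'
#' Serializes every tree as a nested table of split nodes (feature,
#' threshold, children, leaf prediction), so the model can be inspected or
#' applied outside the training session.
#'
#' @param ensemble A `fed_forest`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
export_forest_json <- function(ensemble, path) {
  trees <- list()
  for (m in ensemble$members) {
    if (m$constant) {
      trees <- c(trees, rep(list(list(constant = m$forest, party = m$party)),
                            m$n_trees))
      next
    }
    for (t in seq_len(m$n_trees)) {
      tr <- randomForest::getTree(m$forest, t, labelVar = FALSE)
      trees <- c(trees, list(list(
        party = m$party,
        left = tr[, "left daughter"],
        right = tr[, "right daughter"],
        split_var = tr[, "split var"],
        split_point = tr[, "split point"],
        status = tr[, "status"],
        prediction = tr[, "prediction"]
      )))
    }
  }
  obj <- list(task = ensemble$task, labels = ensemble$labels,
              n_trees = ensemble$n_trees, trees = trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Predict from a JSON-exported forest
#'
#' Traverses the serialized split tables directly; numeric splits send
#' `x <= threshold` left.  Useful for applying an exported model to a CSV
#' without the original fit objects.
#'
#' @param path Path to a JSON file from [export_forest_json()].
#' @param newdata Data frame of features, columns in training order.
#' @return Predicted classes (character) or numeric values.
#' @export
predict_forest_json <- function(path, newdata) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  newdata <- as.matrix(as.data.frame(newdata))
  n <- nrow(newdata)
  classification <- identical(obj$task, "classification")
  trees <- obj$trees
  if (is.data.frame(trees)) trees <- split(trees, seq_len(nrow(trees)))
  if (classification) {
    votes <- matrix(0, n, length(obj$labels),
                    dimnames = list(NULL, obj$labels))
  } else {
    tot <- rep(0, n)
  }
  for (tr in trees) {
    if (!is.null(tr$constant) && !all(is.na(tr$constant))) {
      cst <- tr$constant[[1]]
      votes[, cst] <- votes[, cst] + 1
      next
    }
    left <- unlist(tr$left); right <- unlist(tr$right)
    svar <- unlist(tr$split_var); spt <- unlist(tr$split_point)
    status <- unlist(tr$status); pred <- unlist(tr$prediction)
    for (i in seq_len(n)) {
      node <- 1
      while (status[node] != -1) {
        node <- if (newdata[i, svar[node]] <= spt[node]) left[node] else right[node]
      }
      if (classification) {
        votes[i, pred[node]] <- votes[i, pred[node]] + 1
      } else {
        tot[i] <- tot[i] + pred[node]
      }
    }
  }
  if (classification) obj$labels[apply(votes, 1, which.max)]
  else tot / length(trees)
}
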