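# Built-in federated apps.
#
# Each app follows the registry contract (see register_app): a participant
# phase executed at every party against its local state environment, and a
# coordinator phase over the gathered payloads.  Apps whose aggregation is
# a plain elementwise sum mark secure_cap = TRUE and emit one flat numeric
# vector; with secure aggregation enabled the engine then routes that
# vector through additive secret sharing and the coordinator only ever
# sees the total.

feature_cols <- function(data, label) {
  setdiff(names(data), c(label, "time", "event", "group"))
}

# payloads is either a per-party list of numeric vectors or the secure
# aggregate; returns the elementwise sum either way
sum_payloads <- function(payloads) {
  if (is_secure_payloads(payloads)) payloads$sum
  else Reduce(`+`, payloads)
}

# ---- identity ---------------------------------------------------------------

app_identity <- list(
  consumes = "data", produces = "data",
  participant_phase = function(state, broadcast_in, params, ctx) {
    list(payload = NULL, kind = "ack")
  },
  coordinator_phase = function(cstate, payloads, params, ctx) {
    list(done = TRUE, report = list(app = "identity", parties = ctx$n_parties))
  }
)

# ---- cross-validation -------------------------------------------------------

app_cv <- list(
  consumes = "data", produces = "folds",
  participant_phase = function(state, broadcast_in, params, ctx) {
    k <- params$k %||% 10
    state$folds <- local_kfold(nrow(state$data), k, seed = ctx$seed)
    state$k <- k
    list(payload = as.numeric(table(state$folds)), kind = "fold_counts")
  },
  coordinator_phase = function(cstate, payloads, params, ctx) {
    sizes <- dplyr::bind_rows(lapply(seq_along(payloads), function(p) {
      tibble::tibble(party = p, fold = seq_along(payloads[[p]]),
                     n = payloads[[p]])
    }))
    list(done = TRUE,
         report = list(app = "cv", k = params$k %||% 10, fold_sizes = sizes))
  }
)

# ---- normalization ----------------------------------------------------------

# Secret layout: c(k, p, then per fold c(n, sum_1..p, sumsq_1..p)).
# k and p are identical at every party, so their sums divide back out by
# the party count.
app_normalization <- list(
  consumes = "folds", produces = "standardized", secure_cap = TRUE,
  participant_phase = function(state, broadcast_in, params, ctx) {
    label <- params$label
    feats <- feature_cols(state$data, label)
    k <- state$k %||% 1
    x <- as.matrix(state$data[feats])
    blocks <- unlist(lapply(seq_len(k), function(f) {
      rows <- if (k == 1) rep(TRUE, nrow(x)) else state$folds != f
      ms <- moment_stats(x[rows, , drop = FALSE])
      c(ms$n, ms$sum, ms$sumsq)
    }))
    list(payload = c(k, length(feats), blocks),
         kind = if (ctx$secure) "secure_aggregate" else "moment_stats")
  },
  coordinator_phase = function(cstate, payloads, params, ctx) {
    tot <- sum_payloads(payloads)
    k <- round(tot[1] / ctx$n_parties)
    p <- round(tot[2] / ctx$n_parties)
    per_fold <- lapply(seq_len(k), function(f) {
      off <- 2 + (f - 1) * (1 + 2 * p)
      st <- list(n = tot[off + 1],
                 sum = tot[off + 1 + seq_len(p)],
                 sumsq = tot[off + 1 + p + seq_len(p)])
      class(st) <- "moment_stats"
      federated_standardize(list(st))
    })
    list(done = TRUE, final = per_fold, kind = "standardize_params",
         report = list(app = "normalization", k = k, n_features = p,
                       pooled_n = per_fold[[1]]$n))
  },
  finalize = function(state, final, params, ctx) {
    label <- params$label
    feats <- feature_cols(state$data, label)
    x <- as.matrix(state$data[feats])
    state$standardized <- list(
      k = length(final),
      folds = state$folds %||% rep(1L, nrow(x)),
      x = lapply(final, function(prm) apply_standardize(x, prm)),
      y = state$data[[label]],
      features = feats
    )
    invisible(state)
  }
)

# ---- linear regression ------------------------------------------------------

# Secret layout: c(k, p, per fold c(n, vec(X'X), X'y)) with p the design
# width including the intercept column.
app_linear_regression <- list(
  consumes = "standardized", produces = "model", secure_cap = TRUE,
  participant_phase = function(state, broadcast_in, params, ctx) {
    std <- state$standardized
    k <- std$k
    blocks <- unlist(lapply(seq_len(k), function(f) {
      rows <- if (k == 1) rep(TRUE, length(std$y)) else std$folds != f
      g <- local_gram(std$x[[f]][rows, , drop = FALSE], std$y[rows],
                      intercept = TRUE)
      c(g$n, as.vector(g$xtx), g$xty)
    }))
    p <- length(std$features) + 1
    list(payload = c(k, p, blocks),
         kind = if (ctx$secure) "secure_aggregate" else "gram_stats")
  },
  coordinator_phase = function(cstate, payloads, params, ctx) {
    tot <- sum_payloads(payloads)
    k <- round(tot[1] / ctx$n_parties)
    p <- round(tot[2] / ctx$n_parties)
    blk <- 1 + p * p + p
    betas <- lapply(seq_len(k), function(f) {
      off <- 2 + (f - 1) * blk
      g <- structure(list(
        xtx = matrix(tot[off + 1 + seq_len(p * p)], p, p),
        xty = tot[off + 1 + p * p + seq_len(p)],
        n = tot[off + 1], feature_names = NULL
      ), class = "gram_stats")
      unname(fit_linear(list(g))$beta)
    })
    list(done = TRUE, final = list(kind = "glm", link = "identity",
                                   betas = betas),
         kind = "beta",
         report = list(app = "linear_regression", k = k,
                       beta = betas[[1]]))
  },
  finalize = function(state, final, params, ctx) {
    state$model <- list(type = "cv", kind = "glm", link = final$link,
                        betas = final$betas)
    invisible(state)
  }
)

# ---- logistic regression ----------------------------------------------------

# Iterative Newton: per round and fold the secret carries
# c(n, deviance, gradient, vec(Hessian)); the coordinator updates each
# fold's beta until every fold converges or max_iter rounds pass.
app_logistic_regression <- list(
  consumes = "standardized", produces = "model", secure_cap = TRUE,
  participant_phase = function(state, broadcast_in, params, ctx) {
    std <- state$standardized
    k <- std$k
    p <- length(std$features) + 1
    betas <- if (is.null(broadcast_in)) {
      lapply(seq_len(k), function(f) rep(0, p))
    } else {
      broadcast_in
    }
    blocks <- unlist(lapply(seq_len(k), function(f) {
      rows <- if (k == 1) rep(TRUE, length(std$y)) else std$folds != f
      x <- cbind(1, std$x[[f]][rows, , drop = FALSE])
      r <- local_logistic_round(x, std$y[rows], betas[[f]])
      c(r$n, r$deviance, r$gradient, as.vector(r$hessian))
    }))
    list(payload = c(k, p, blocks),
         kind = if (ctx$secure) "secure_aggregate" else "gradient_hessian")
  },
  coordinator_phase = function(cstate, payloads, params, ctx) {
    tot <- sum_payloads(payloads)
    k <- round(tot[1] / ctx$n_parties)
    p <- round(tot[2] / ctx$n_parties)
    blk <- 2 + p + p * p
    max_iter <- params$max_iter %||% 25
    tol <- params$tol %||% 1e-8
    betas <- cstate$betas %||% lapply(seq_len(k), function(f) rep(0, p))
    iter <- (cstate$iter %||% 0) + 1
    max_delta <- 0
    for (f in seq_len(k)) {
      off <- 2 + (f - 1) * blk
      g <- tot[off + 2 + seq_len(p)]
      h <- matrix(tot[off + 2 + p + seq_len(p * p)], p, p)
      delta <- tryCatch(
        drop(solve(h, g)),
        error = function(e) drop(solve(h + diag(1e-8, p), g))
      )
      betas[[f]] <- betas[[f]] + delta
      max_delta <- max(max_delta, max(abs(delta)))
    }
    done <- max_delta < tol || iter >= max_iter
    if (done) {
      list(done = TRUE,
           final = list(kind = "glm", link = "logit", betas = betas,
                        iterations = iter, converged = max_delta < tol),
           kind = "beta",
           report = list(app = "logistic_regression", k = k,
                         iterations = iter, converged = max_delta < tol))
    } else {
      list(state = list(betas = betas, iter = iter),
           broadcast = betas, kind = "beta", done = FALSE)
    }
  },
  finalize = function(state, final, params, ctx) {
    state$model <- list(type = "cv", kind = "glm", link = final$link,
                        betas = final$betas, labels = c("0", "1"))
    invisible(state)
  }
)

# ---- random forest ----------------------------------------------------------

app_random_forest <- list(
  consumes = "standardized", produces = "model",
  participant_phase = function(state, broadcast_in, params, ctx) {
    std <- state$standardized
    task <- params$task %||% "classification"
    if (is.null(broadcast_in)) {
      # step 1: announce sample count (and local label set)
      pay <- list(n = length(std$y),
                  labels = if (task == "classification") {
                    sort(unique(as.character(std$y)))
                  })
      return(list(payload = pay, kind = "sample_count"))
    }
    # step 2: train this party's share of trees, per fold
    alloc <- broadcast_in$allocation
    labels <- broadcast_in$labels
    n_trees <- alloc$n_trees[ctx$party_id]
    k <- std$k
    forests <- lapply(seq_len(k), function(f) {
      rows <- if (k == 1) rep(TRUE, length(std$y)) else std$folds != f
      d <- as.data.frame(std$x[[f]][rows, , drop = FALSE])
      d$y <- std$y[rows]
      train_local_trees(d, label = "y", n_trees = n_trees,
                        task = task, labels = labels,
                        seed = make_seed(ctx$seed, f))
    })
    list(payload = forests, kind = "tree_list")
  },
  coordinator_phase = function(cstate, payloads, params, ctx) {
    task <- params$task %||% "classification"
    if (is.null(cstate$allocation)) {
      counts <- vapply(payloads, function(p) p$n, numeric(1))
      alloc <- allocate_trees(counts, params$n_trees %||% 100)
      labels <- if (task == "classification") {
        sort(unique(unlist(lapply(payloads, function(p) p$labels))))
      }
      bc <- list(allocation = alloc, labels = labels,
                 total_n = sum(counts))
      return(list(state = list(allocation = alloc, labels = labels),
                  broadcast = bc, kind = "tree_allocation", done = FALSE))
    }
    # step 2/3: merge each fold's trees into a fixed-size global forest
    k <- length(payloads[[1]])
    forests <- lapply(seq_len(k), function(f) {
      merge_forests(lapply(payloads, function(p) p[[f]]),
                    task = task, labels = cstate$labels)
    })
    list(done = TRUE,
         final = list(kind = "forest", task = task, forests = forests,
                      labels = cstate$labels),
         kind = "global_model",
         report = list(app = "random_forest",
                       allocation = cstate$allocation,
                       n_trees = forests[[1]]$n_trees, k = k))
  },
  finalize = function(state, final, params, ctx) {
    state$model <- list(type = "cv", kind = "forest", task = final$task,
                        fits = final$forests, labels = final$labels)
    invisible(state)
  }
)

# ---- FedAvg neural network --------------------------------------------------

app_neural_network <- list(
  consumes = "data", produces = "model", secure_cap = TRUE,
  participant_phase = function(state, broadcast_in, params, ctx) {
    label <- params$label
    feats <- feature_cols(state$data, label)
    if (is.null(state$nn)) {
      n <- nrow(state$data)
      n_test <- max(1, floor((params$test_fraction %||% 0.2) * n))
      old <- get0(".Random.seed", envir = globalenv())
      set.seed(make_seed(ctx$seed, 999))
      test_idx <- sample(n, n_test)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      state$nn <- list(
        test_idx = test_idx,
        x = as.matrix(state$data[-test_idx, feats]),
        y = state$data[[label]][-test_idx]
      )
    }
    if (is.null(broadcast_in)) {
      # round 1: report training size and width so the coordinator can
      # initialize one shared model
      return(list(payload = c(nrow(state$nn$x), length(feats)),
                  kind = if (ctx$secure) "secure_aggregate" else "sample_count"))
    }
    cfg <- list(
      local_epochs = params$local_epochs %||% 1,
      batch_size = params$batch_size %||% 32,
      learning_rate = params$learning_rate %||% 0.05,
      loss = params$loss %||% "mse",
      seed = make_seed(ctx$seed, ctx$round)
    )
    upd <- local_update(broadcast_in, state$nn$x, state$nn$y, cfg)
    n <- nrow(state$nn$x)
    loss <- mlp_loss(upd, state$nn$x, state$nn$y, cfg$loss)
    # count-weighted layout: c(n, n * theta, n * loss); the weighted mean
    # of parameters falls out of the plain sum
    list(payload = c(n, n * unlist_params(upd), n * loss),
         kind = if (ctx$secure) "secure_aggregate" else "model_params")
  },
  coordinator_phase = function(cstate, payloads, params, ctx) {
    loss <- params$loss %||% "mse"
    if (is.null(cstate$params)) {
      tot <- sum_payloads(payloads)
      p_in <- round(tot[2] / ctx$n_parties)
      arch <- c(p_in, params$hidden %||% 32, 1)
      params0 <- mlp_init(arch, seed = ctx$seed)
      return(list(state = list(params = params0, arch = arch, r = 0,
                               history = numeric(0)),
                  broadcast = params0, kind = "model_params", done = FALSE))
    }
    tot <- sum_payloads(payloads)
    n_tot <- tot[1]
    len <- length(tot)
    avg <- relist_params(tot[2:(len - 1)] / n_tot, cstate$params)
    mean_loss <- tot[len] / n_tot
    r <- cstate$r + 1
    history <- c(cstate$history, mean_loss)
    if (r >= (params$rounds %||% 20)) {
      list(done = TRUE,
           final = list(kind = "mlp", params = avg, arch = cstate$arch,
                        loss = loss,
                        history = tibble::tibble(round = seq_along(history),
                                                 loss = history)),
           kind = "global_model",
           report = list(app = "neural_network", rounds = r,
                         final_loss = mean_loss,
                         history = tibble::tibble(round = seq_along(history),
                                                  loss = history)))
    } else {
      list(state = list(params = avg, arch = cstate$arch, r = r,
                        history = history),
           broadcast = avg, kind = "model_params", done = FALSE)
    }
  },
  finalize = function(state, final, params, ctx) {
    state$model <- list(type = "holdout", kind = "mlp", fit = final$params,
                        loss = final$loss, test_idx = state$nn$test_idx)
    invisible(state)
  }
)

unlist_params <- function(params) {
  unlist(lapply(params, function(l) c(as.vector(l$w), l$b)))
}

relist_params <- function(vec, template) {
  off <- 0
  for (l in seq_along(template)) {
    nw <- length(template[[l]]$w)
    nb <- length(template[[l]]$b)
    template[[l]]$w <- matrix(vec[off + seq_len(nw)],
                              nrow(template[[l]]$w), ncol(template[[l]]$w))
    template[[l]]$b <- vec[off + nw + seq_len(nb)]
    off <- off + nw + nb
  }
  template
}

# ---- evaluation -------------------------------------------------------------

# predictions of a trained model slot on a feature matrix
model_predict <- function(model, x, fold = 1) {
  if (model$kind == "glm") {
    eta <- drop(cbind(1, x) %*% model$betas[[fold]])
    if (identical(model$link, "logit")) stats::plogis(eta) else eta
  } else if (model$kind == "forest") {
    stats::predict(model$fits[[fold]], as.data.frame(x))
  } else if (model$kind == "mlp") {
    drop(predict.mlp_params(model$fit, x, loss = model$loss))
  } else {
    stop("unknown model kind", call. = FALSE)
  }
}

# test-set features/targets for fold f at one party
eval_split <- function(state, fold, label) {
  m <- state$model
  if (m$type == "holdout") {
    feats <- feature_cols(state$data, label)
    list(x = as.matrix(state$data[m$test_idx, feats]),
         y = state$data[[label]][m$test_idx])
  } else {
    std <- state$standardized
    rows <- if (std$k == 1) rep(TRUE, length(std$y)) else std$folds == fold
    list(x = std$x[[fold]][rows, , drop = FALSE], y = std$y[rows])
  }
}

eval_k <- function(state) {
  if (state$model$type == "holdout") 1 else state$standardized$k
}

app_eval_classification <- list(
  consumes = "model", produces = "metrics", secure_cap = TRUE,
  participant_phase = function(state, broadcast_in, params, ctx) {
    labels <- state$model$labels
    k <- eval_k(state)
    blocks <- unlist(lapply(seq_len(k), function(f) {
      sp <- eval_split(state, f, params$label)
      raw <- model_predict(state$model, sp$x, f)
      pred <- if (is.numeric(raw)) {
        labels[1 + (raw > 0.5)]
      } else {
        as.character(raw)
      }
      cm <- confusion_counts(as.character(sp$y), pred, labels = labels)
      as.vector(cm$counts)
    }))
    list(payload = c(k, length(labels), blocks),
         kind = if (ctx$secure) "secure_aggregate" else "confusion_counts")
  },
  coordinator_phase = function(cstate, payloads, params, ctx) {
    tot <- sum_payloads(payloads)
    k <- round(tot[1] / ctx$n_parties)
    nl <- round(tot[2] / ctx$n_parties)
    labels <- params$labels %||% as.character(seq_len(nl) - 1)
    f1 <- vapply(seq_len(k), function(f) {
      off <- 2 + (f - 1) * nl * nl
      cm <- structure(list(
        labels = labels,
        counts = matrix(tot[off + seq_len(nl * nl)], nl, nl,
                        dimnames = list(truth = labels, pred = labels)),
        n = sum(tot[off + seq_len(nl * nl)])
      ), class = "confusion_counts")
      f1_from_confusion(cm, positive = params$positive %||% labels[nl])
    }, numeric(1))
    rep <- cv_report(f1, metric_name = "f1")
    list(done = TRUE, final = rep, kind = "report", report = rep)
  },
  finalize = function(state, final, params, ctx) {
    state$metrics <- final
    invisible(state)
  }
)

app_eval_regression <- list(
  consumes = "model", produces = "metrics", secure_cap = TRUE,
  participant_phase = function(state, broadcast_in, params, ctx) {
    k <- eval_k(state)
    blocks <- unlist(lapply(seq_len(k), function(f) {
      sp <- eval_split(state, f, params$label)
      yhat <- model_predict(state$model, sp$x, f)
      es <- error_sums(sp$y, yhat)
      c(es$n, es$sse, es$sae)
    }))
    list(payload = c(k, blocks),
         kind = if (ctx$secure) "secure_aggregate" else "error_sums")
  },
  coordinator_phase = function(cstate, payloads, params, ctx) {
    tot <- sum_payloads(payloads)
    k <- round(tot[1] / ctx$n_parties)
    rmse <- vapply(seq_len(k), function(f) {
      off <- 1 + (f - 1) * 3
      es <- structure(list(n = tot[off + 1], sse = tot[off + 2],
                           sae = tot[off + 3]), class = "error_sums")
      rmse_from_sums(es)
    }, numeric(1))
    rep <- cv_report(rmse, metric_name = "rmse")
    list(done = TRUE, final = rep, kind = "report", report = rep)
  },
  finalize = function(state, final, params, ctx) {
    state$metrics <- final
    invisible(state)
  }
)

# ---- one-hot encoding -------------------------------------------------------

app_one_hot <- list(
  consumes = "data", produces = "data",
  participant_phase = function(state, broadcast_in, params, ctx) {
    cols <- params$columns %||%
      names(state$data)[!vapply(state$data, is.numeric, logical(1))]
    sets <- lapply(cols, function(cl) sort(unique(as.character(state$data[[cl]]))))
    names(sets) <- cols
    list(payload = sets, kind = "category_set")
  },
  coordinator_phase = function(cstate, payloads, params, ctx) {
    cols <- unique(unlist(lapply(payloads, names)))
    cats <- lapply(cols, function(cl) {
      federated_one_hot(lapply(payloads, function(p) p[[cl]]))
    })
    names(cats) <- cols
    list(done = TRUE, final = cats, kind = "category_list",
         report = list(app = "one_hot", categories = cats))
  },
  finalize = function(state, final, params, ctx) {
    for (cl in names(final)) {
      enc <- encode_one_hot(state$data[[cl]], final[[cl]])
      colnames(enc) <- paste(cl, final[[cl]], sep = "_")
      state$data[[cl]] <- NULL
      state$data <- dplyr::bind_cols(state$data, tibble::as_tibble(enc))
    }
    invisible(state)
  }
)

# ---- Kaplan-Meier -----------------------------------------------------------

app_kaplan_meier <- list(
  consumes = "data", produces = "survival",
  participant_phase = function(state, broadcast_in, params, ctx) {
    group <- params$group %||% if ("group" %in% names(state$data)) "group"
    if (is.null(group)) {
      pay <- list(overall = local_event_table(state$data))
    } else {
      levs <- sort(unique(state$data[[group]]))
      pay <- lapply(levs, function(g) {
        local_event_table(state$data[state$data[[group]] == g, , drop = FALSE])
      })
      names(pay) <- as.character(levs)
    }
    list(payload = pay, kind = "event_table")
  },
  coordinator_phase = function(cstate, payloads, params, ctx) {
    groups <- unique(unlist(lapply(payloads, names)))
    tables <- lapply(groups, function(g) {
      aggregate_tables(Filter(Negate(is.null),
                              lapply(payloads, function(p) p[[g]])))
    })
    names(tables) <- groups
    fit <- structure(
      list(curves = lapply(tables, km_curve), tables = tables,
           logrank = if (length(tables) >= 2) logrank_test(tables) else NULL),
      class = "fed_km_fit"
    )
    list(done = TRUE, final = fit, kind = "survival_result", report = fit)
  },
  finalize = function(state, final, params, ctx) {
    state$survival <- final
    invisible(state)
  }
)

register_builtin_apps <- function() {
  register_app("identity", app_identity)
  register_app("cv", app_cv)
  register_app("normalization", app_normalization)
  register_app("one_hot", app_one_hot)
  register_app("linear_regression", app_linear_regression)
  register_app("logistic_regression", app_logistic_regression)
  register_app("random_forest", app_random_forest)
  register_app("neural_network", app_neural_network)
  register_app("eval_classification", app_eval_classification)
  register_app("eval_regression", app_eval_regression)
  register_app("kaplan_meier", app_kaplan_meier)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_apps()
}
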