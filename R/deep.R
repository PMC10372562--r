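#' Initialize multilayer-perceptron parameters
#'
#' A small fully connected network with tanh hidden units and a linear
#' (regression / mse) or sigmoid (binary cross-entropy) output, held as
#' plain weight matrices and bias vectors so that federated averaging is
#' ordinary arithmetic on tensors.
#'
#' @param layer_sizes Integer vector `c(inputs, hidden..., outputs)`; e.g.
#'   `c(12, 32, 1)` is the default desk-scale architecture (one hidden
#'   layer of 32 tanh units).
#' @param seed Integer seed (same seed gives identical parameters).
#' @return Object of class `mlp_params`: list of layers, each
#'   `list(w = , b = )`, with the architecture as attribute.
#' @export
mlp_init <- function(layer_sizes, seed = NULL) {
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1))
  if (!is.null(seed)) set.seed(seed)
  layers <- lapply(seq_len(length(layer_sizes) - 1), function(l) {
    fan_in <- layer_sizes[l]
    fan_out <- layer_sizes[l + 1]
    s <- sqrt(6 / (fan_in + fan_out))  # Glorot uniform
    list(
      w = matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out),
      b = rep(0, fan_out)
    )
  })
  structure(layers, class = "mlp_params", layer_sizes = layer_sizes)
}

# forward pass; returns activations per layer for backprop
mlp_forward <- function(params, x, loss = "mse") {
  a <- list(as.matrix(x))
  n_layers <- length(params)
  for (l in seq_len(n_layers)) {
    z <- sweep(a[[l]] %*% params[[l]]$w, 2, params[[l]]$b, `+`)
    a[[l + 1]] <- if (l < n_layers) tanh(z)
    else if (loss == "cross_entropy") stats::plogis(z)
    else z
  }
  a
}

#' Predict with MLP parameters
#'
#' @param object An `mlp_params` object.
#' @param newdata Feature matrix or data frame.
#' @param loss `"mse"` (linear output) or `"cross_entropy"` (sigmoid
#'   probability output).
#' @param ... Unused.
#' @return Numeric matrix of network outputs (n x outputs).
#' @export
predict.mlp_params <- function(object, newdata, loss = "mse", ...) {
  acts <- mlp_forward(object, as.matrix(newdata), loss)
  acts[[length(acts)]]
}

#' Training loss of MLP parameters on a dataset
#'
#' `mse` is the mean over samples of the squared error summed over
#' outputs; `cross_entropy` is the mean binary negative log-likelihood.
#'
#' @param params An `mlp_params` object.
#' @param x Feature matrix.
#' @param y Target vector/matrix.
#' @param loss `"mse"` or `"cross_entropy"`.
#' @return Scalar loss.
#' @export
mlp_loss <- function(params, x, y, loss = "mse") {
  yhat <- predict.mlp_params(params, x, loss = loss)
  y <- as.matrix(y)
  if (loss == "cross_entropy") {
    eps <- 1e-12
    -mean(y * log(yhat + eps) + (1 - y) * log(1 - yhat + eps))
  } else {
    mean(rowSums((yhat - y)^2))
  }
}

# gradient of the mean loss over the given batch, by backpropagation
mlp_grad <- function(params, x, y, loss = "mse") {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  acts <- mlp_forward(params, x, loss)
  n_layers <- length(params)
  out <- acts[[n_layers + 1]]
  # both mse (linear out) and cross-entropy (sigmoid out) reduce to the
  # same output delta up to the mse factor 2
  delta <- if (loss == "cross_entropy") (out - y) / n else 2 * (out - y) / n
  grads <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    grads[[l]] <- list(
      w = crossprod(acts[[l]], delta),
      b = colSums(delta)
    )
    if (l > 1) {
      delta <- (delta %*% t(params[[l]]$w)) * (1 - acts[[l]]^2)
    }
  }
  grads
}

#' One party's local FedAvg update
#'
#' Runs `local_epochs` passes of mini-batch gradient descent (plain SGD)
#' over the local data, starting from the broadcast parameters.  Batch
#' order is reshuffled every epoch from the configured seed, so the update
#' is bitwise reproducible.
#'
#' @param params Starting `mlp_params` (the current global model).
#' @param x,y Local features and targets.
#' @param cfg List with `local_epochs`, `batch_size`, `learning_rate`,
#'   `loss` (`"mse"`/`"cross_entropy"`), and optional `seed`.
#' @return Updated `mlp_params`.
#' @export
local_update <- function(params, x, y, cfg) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  stopifnot(cfg$local_epochs >= 1, cfg$batch_size >= 1,
            cfg$learning_rate >= 0)
  for (epoch in seq_len(cfg$local_epochs)) {
    idx <- if (!is.null(cfg$seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      set.seed(make_seed(cfg$seed, epoch))
      i <- sample(n)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      i
    } else {
      sample(n)
    }
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    for (b in batches) {
      g <- mlp_grad(params, x[b, , drop = FALSE], y[b, , drop = FALSE],
                    cfg$loss %||% "mse")
      for (l in seq_along(params)) {
        params[[l]]$w <- params[[l]]$w - cfg$learning_rate * g[[l]]$w
        params[[l]]$b <- params[[l]]$b - cfg$learning_rate * g[[l]]$b
      }
      if (any(!vapply(params, function(p) all(is.finite(p$w)), logical(1)))) {
        stop("NaN/Inf in parameters during local update; lower the learning rate",
             call. = FALSE)
      }
    }
  }
  params
}

#' Federated averaging of model parameters
#'
#' Per-tensor weighted mean with weights `n_i / sum(n_i)`.  Count
#' weighting makes one full-batch local step on any partition equal one
#' centralized pooled-gradient step, because the weighted mean of
#' per-party mean gradients is the pooled mean gradient.
#'
#' @param param_list List of `mlp_params`, one per party, identical
#'   architectures.
#' @param sample_counts Per-party sample counts.
#' @return Averaged `mlp_params`.
#' @export
fedavg <- function(param_list, sample_counts) {
  stopifnot(length(param_list) == length(sample_counts),
            length(param_list) >= 1)
  archs <- lapply(param_list, attr, "layer_sizes")
  if (length(unique(archs)) != 1) {
    stop("protocol error: parameter shapes differ across parties",
         call. = FALSE)
  }
  w <- sample_counts / sum(sample_counts)
  out <- param_list[[1]]
  for (l in seq_along(out)) {
    out[[l]]$w <- Reduce(`+`, lapply(seq_along(param_list), function(i) {
      w[i] * param_list[[i]][[l]]$w
    }))
    out[[l]]$b <- Reduce(`+`, lapply(seq_along(param_list), function(i) {
      w[i] * param_list[[i]][[l]]$b
    }))
  }
  out
}

#' Federated MLP training loop
#'
#' Iterates `rounds` times: broadcast the current global parameters, let
#' every party run [local_update()], and average with [fedavg()].  The
#' per-round count-weighted training loss (evaluated at the freshly
#' averaged parameters) is recorded.
#'
#' @param parties List of `list(x = , y = )` per party, or data frames
#'   with a `label` column.
#' @param layer_sizes Architecture, `c(inputs, hidden..., outputs)`.
#' @param cfg List: `rounds`, `local_epochs`, `batch_size`,
#'   `learning_rate`, `loss`, `seed`.
#' @param label Label column for data-frame input.
#' @return Object of class `fed_mlp_fit`: `params`, `history` tibble
#'   (`round`, `loss`), `cfg`, `layer_sizes`.
#' @export
train_federated <- function(parties, layer_sizes, cfg, label = "y") {
  stopifnot(length(parties) >= 1, cfg$rounds >= 1)
  mats <- lapply(parties, function(p) {
    if (is.data.frame(p)) {
      list(x = as.matrix(p[setdiff(names(p), label)]), y = p[[label]])
    } else {
      list(x = as.matrix(p$x), y = p$y)
    }
  })
  ns <- vapply(mats, function(m) nrow(m$x), numeric(1))
  loss <- cfg$loss %||% "mse"
  params <- mlp_init(layer_sizes, seed = cfg$seed)
  history <- numeric(cfg$rounds)
  for (r in seq_len(cfg$rounds)) {
    locals <- lapply(seq_along(mats), function(i) {
      pcfg <- cfg
      pcfg$seed <- if (is.null(cfg$seed)) NULL else make_seed(cfg$seed, r, i)
      local_update(params, mats[[i]]$x, mats[[i]]$y, pcfg)
    })
    params <- fedavg(locals, ns)
    history[r] <- sum(ns * vapply(seq_along(mats), function(i) {
      mlp_loss(params, mats[[i]]$x, mats[[i]]$y, loss)
    }, numeric(1))) / sum(ns)
    if (!is.finite(history[r]) || history[r] > 1e6) {
      stop(sprintf("training diverged at round %d (loss %g)", r, history[r]),
           call. = FALSE)
    }
  }
  structure(
    list(params = params,
         history = tibble::tibble(round = seq_len(cfg$rounds), loss = history),
         cfg = cfg, layer_sizes = layer_sizes, n_parties = length(mats)),
    class = "fed_mlp_fit"
  )
}

#' @export
print.fed_mlp_fit <- function(x, ...) {
  cat(sprintf(
    "Federated MLP (%s): %d round(s), %d part(ies), final loss %.6f\n",
    paste(x$layer_sizes, collapse = "-"), nrow(x$history), x$n_parties,
    x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Export MLP parameters as JSON
#'
#' @param fit A `fed_mlp_fit` or `mlp_params`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
export_mlp_json <- function(fit, path) {
  params <- if (inherits(fit, "fed_mlp_fit")) fit$params else fit
  obj <- list(
    layer_sizes = attr(params, "layer_sizes"),
    layers = lapply(params, function(l) {
      list(w = unclass(l$w), b = l$b)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
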