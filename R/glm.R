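#' Local Gram statistics for one-shot federated linear regression
#'
#' The normal equations depend on the data only through `X'X`, `X'y`, and
#' `n` — all summable across parties.  Each party computes these locally;
#' only the aggregates reach the coordinator, which then solves for the
#' coefficients exactly as a centralized least-squares fit would.
#'
#' @param x Numeric matrix or data frame of features.
#' @param y Numeric response vector.
#' @param intercept Prepend a column of ones (shared convention across
#'   parties)?
#' @return An object of class `gram_stats`: list with `xtx`, `xty`, `n`,
#'   `feature_names`.
#' @export
local_gram <- function(x, y, intercept = FALSE) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), is.numeric(y), nrow(x) == length(y),
            !anyNA(x), !anyNA(y))
  if (intercept) {
    x <- cbind(`(Intercept)` = 1, x)
  }
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(x)))
  structure(
    list(xtx = crossprod(x), xty = drop(crossprod(x, y)), n = nrow(x),
         feature_names = nms),
    class = "gram_stats"
  )
}

# Moore-Penrose pseudoinverse solve used as singular fallback
pinv_solve <- function(a, b, tol = 1e-10) {
  sv <- svd(a)
  pos <- sv$d > tol * max(sv$d)
  drop(sv$v[, pos, drop = FALSE] %*%
         ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos]))
}

#' Solve the aggregated normal equations
#'
#' Sums the per-party Gram statistics and solves
#' `(sum X'X) beta = sum X'y`.  The result is identical to ordinary least
#' squares on the pooled data, for any partition of it, because summed
#' Gram matrices are partition-invariant.
#'
#' @param gram_list List of [local_gram()] outputs with matching dimension.
#' @return An object of class `fed_linear_fit` with `beta`, `n`, and a
#'   `singular` flag (pseudoinverse fallback used).
#' @export
fit_linear <- function(gram_list) {
  stopifnot(length(gram_list) >= 1)
  a <- Reduce(`+`, lapply(gram_list, function(g) g$xtx))
  b <- Reduce(`+`, lapply(gram_list, function(g) g$xty))
  n <- sum(vapply(gram_list, function(g) g$n, numeric(1)))
  singular <- FALSE
  beta <- tryCatch(
    drop(solve(a, b)),
    error = function(e) {
      warning("singular aggregated Gram matrix; using pseudoinverse",
              call. = FALSE)
      singular <<- TRUE
      pinv_solve(a, b)
    }
  )
  names(beta) <- gram_list[[1]]$feature_names
  structure(
    list(beta = beta, n = n, p = length(beta), singular = singular,
         n_parties = length(gram_list)),
    class = "fed_linear_fit"
  )
}

#' Federated linear regression on a list of party data frames
#'
#' High-level wrapper: builds each party's design matrix from all numeric
#' columns except the label, computes local Gram statistics, aggregates
#' (optionally through additive secret sharing so the coordinator sees only
#' the sums), and solves.
#'
#' @param data_list List of data frames, one per party, sharing columns.
#' @param label Name of the response column.
#' @param intercept Include an intercept?
#' @param secure Route the aggregation through [secure_sum()]?
#' @param codec Fixed-point codec used when `secure = TRUE`.
#' @param seed Seed for the share randomness.
#' @return A `fed_linear_fit`; see [fit_linear()].
#' @examples
#' d <- synth_dataset("regression", n_samples = 120, n_features = 3, seed = 1)
#' parts <- partition_parties(d, proportions = c(0.5, 0.5), seed = 1)
#' fed_linear(parts)$beta
#' @export
fed_linear <- function(data_list, label = "y", intercept = TRUE,
                       secure = FALSE, codec = fp_codec(), seed = NULL) {
  grams <- lapply(data_list, function(d) {
    local_gram(d[setdiff(names(d), label)], d[[label]], intercept = intercept)
  })
  if (secure) grams <- secure_gram_aggregate(grams, codec, seed)
  fit <- fit_linear(grams)
  fit$secure <- secure
  fit
}

# Sum gram stats through the secret-sharing path, returning a singleton
# list so fit_linear sees only the aggregate (as the coordinator would).
secure_gram_aggregate <- function(grams, codec, seed) {
  p <- ncol(grams[[1]]$xtx)
  secrets <- lapply(grams, function(g) c(g$n, as.vector(g$xtx), g$xty))
  tot <- secure_sum(secrets, codec, rng_seed = seed)
  list(structure(
    list(
      xtx = matrix(tot[2:(1 + p * p)], p, p),
      xty = tot[(2 + p * p):(1 + p * p + p)],
      n = tot[1],
      feature_names = grams[[1]]$feature_names
    ),
    class = "gram_stats"
  ))
}

#' One Newton round of federated logistic regression at a party
#'
#' With fitted probabilities `p_i = 1 / (1 + exp(-x_i' beta))`, the local
#' score and information are `X'(y - p)` and `X' diag(p (1 - p)) X`
#' (ascent convention: the Newton step adds `H^{-1} g`).  Both are summable
#' across parties, so the federated trajectory matches a centralized
#' Newton fit round for round.
#'
#' @param x Numeric design matrix (intercept column included if wanted).
#' @param y Binary 0/1 response.
#' @param beta Current coefficient vector.
#' @return List with `gradient`, `hessian`, `n`, `deviance` (local
#'   `-2 log L`), class `newton_round`.
#' @export
local_logistic_round <- function(x, y, beta) {
  x <- as.matrix(x)
  stopifnot(all(y %in% c(0, 1)), length(beta) == ncol(x))
  eta <- drop(x %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  # deviance via log1p for numerical stability at extreme eta
  dev <- -2 * sum(y * eta - log1p(exp(eta)))
  structure(
    list(
      gradient = drop(crossprod(x, y - p)),
      hessian = crossprod(x, x * w),
      n = nrow(x),
      deviance = dev
    ),
    class = "newton_round"
  )
}

#' Federated logistic regression by aggregated Newton-Raphson
#'
#' Iterates: the coordinator broadcasts the current coefficients, each
#' party returns its local gradient and Hessian, the coordinator sums them
#' and takes a Newton step, until the largest coefficient change falls
#' below `tol` or `max_iter` rounds pass.  Because summed gradients and
#' Hessians are partition-invariant, the fit equals an unpenalized
#' centralized maximum-likelihood fit.
#'
#' A near-singular aggregated Hessian (e.g. separable toy data) is damped
#' with a small ridge on the diagonal, with a warning.
#'
#' @param parties List of `list(x = , y = )` per party, or data frames when
#'   `label` is given (all non-label numeric columns become features).
#' @param max_iter Maximum federated rounds (default 25).
#' @param tol Convergence tolerance on `max(abs(delta beta))`.
#' @param intercept Prepend an intercept column (data-frame input only).
#' @param label Response column name for data-frame input.
#' @param secure Aggregate gradient/Hessian through [secure_sum()]?
#' @param codec Fixed-point codec for the secure path.
#' @param seed Seed for share randomness.
#' @param ridge Damping added to the Hessian diagonal on failure.
#' @return An object of class `fed_logistic_fit`: `beta`, `iterations`,
#'   `converged`, `deviance` (final pooled `-2 log L`), `deviance_trace`.
#' @export
fed_logistic <- function(parties, label = "y", intercept = TRUE,
                         max_iter = 25, tol = 1e-8,
                         secure = FALSE, codec = fp_codec(), seed = NULL,
                         ridge = 1e-8) {
  mats <- lapply(parties, function(p) {
    if (is.data.frame(p)) {
      x <- as.matrix(p[setdiff(names(p), label)])
      if (intercept) x <- cbind(`(Intercept)` = 1, x)
      list(x = x, y = p[[label]])
    } else {
      list(x = as.matrix(p$x), y = p$y)
    }
  })
  y_all <- unlist(lapply(mats, function(m) m$y))
  if (length(unique(y_all)) < 2) {
    stop("pooled data must contain both classes", call. = FALSE)
  }
  p <- ncol(mats[[1]]$x)
  beta <- rep(0, p)
  converged <- FALSE
  dev_trace <- numeric(0)
  iter <- 0
  damped <- FALSE
  for (iter in seq_len(max_iter)) {
    rounds <- lapply(mats, function(m) local_logistic_round(m$x, m$y, beta))
    if (secure) {
      secrets <- lapply(rounds, function(r) {
        c(r$n, r$deviance, r$gradient, as.vector(r$hessian))
      })
      tot <- secure_sum(secrets, codec,
                        rng_seed = if (is.null(seed)) NULL else make_seed(seed, iter))
      dev <- tot[2]
      g <- tot[3:(2 + p)]
      h <- matrix(tot[(3 + p):(2 + p + p * p)], p, p)
    } else {
      dev <- sum(vapply(rounds, function(r) r$deviance, numeric(1)))
      g <- Reduce(`+`, lapply(rounds, function(r) r$gradient))
      h <- Reduce(`+`, lapply(rounds, function(r) r$hessian))
    }
    dev_trace <- c(dev_trace, dev)
    delta <- tryCatch(
      drop(solve(h, g)),
      error = function(e) {
        if (!damped) {
          warning("ill-conditioned aggregated Hessian; ridge-damped Newton step",
                  call. = FALSE)
          damped <<- TRUE
        }
        drop(solve(h + diag(ridge, p), g))
      }
    )
    beta <- beta + delta
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  nms <- colnames(mats[[1]]$x)
  if (!is.null(nms)) names(beta) <- nms
  structure(
    list(beta = beta, iterations = iter, converged = converged,
         deviance = dev_trace[length(dev_trace)], deviance_trace = dev_trace,
         n = sum(vapply(mats, function(m) length(m$y), numeric(1))),
         n_parties = length(mats), secure = secure, damped = damped),
    class = "fed_logistic_fit"
  )
}

#' @export
print.fed_linear_fit <- function(x, ...) {
  cat(sprintf("Federated linear regression (%d parties, n = %g)\n",
              x$n_parties, x$n))
  print(x$beta)
  invisible(x)
}

#' @export
print.fed_logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Federated logistic regression (%d parties, n = %g)\n%d Newton rounds, %s; deviance %.4f\n",
    x$n_parties, x$n, x$iterations,
    if (x$converged) "converged" else "NOT converged", x$deviance))
  print(x$beta)
  invisible(x)
}

#' Export a fitted federated GLM as portable JSON
#'
#' @param fit A `fed_linear_fit` or `fed_logistic_fit`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
export_glm_json <- function(fit, path) {
  obj <- list(
    model = if (inherits(fit, "fed_logistic_fit")) "logistic" else "linear",
    feature_names = names(fit$beta),
    beta = unname(fit$beta),
    iterations = fit$iterations %||% 1L,
    converged = fit$converged %||% TRUE
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
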