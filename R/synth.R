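#' Generate a synthetic pooled dataset
#'
#' Emulates the statistical shape of typical cross-silo evaluation data:
#' standard-Gaussian features with a linear signal, so that the
#' normalization app has nontrivial but well-conditioned work and noiseless
#' settings admit exact recovery checks.
#'
#' * `regression`: `y = X beta + eps`, `eps ~ N(0, noise_sd^2)`.
#' * `classification`: `P(y = 1) = plogis(X beta)`, labels drawn Bernoulli.
#' * `survival`: event times exponential with rate `exp(X beta)`;
#'   independent uniform censoring on `(0, c_max)` with `c_max` calibrated
#'   by root-finding so the expected censored fraction hits
#'   `censoring_rate`.
#'
#' @param task `"regression"`, `"classification"`, or `"survival"`.
#' @param n_samples Number of rows (>= 2).
#' @param n_features Number of Gaussian features.
#' @param effect Coefficient vector (recycled/truncated to `n_features`),
#'   or a single class-separation scalar.  Default: alternating-sign
#'   coefficients of magnitude 1 (regression/classification) or 0.5
#'   (survival).
#' @param noise_sd Regression noise standard deviation (>= 0).
#' @param censoring_rate Target censored fraction in `[0, 1)` (survival).
#' @param seed Integer seed; same seed reproduces the dataset.
#' @return A tibble with features `x1..xp` and, by task, `y` or
#'   `time`/`event`; attributes `"beta"` and `"task"`.
#' @examples
#' d <- synth_dataset("classification", 200, 5, seed = 7)
#' table(d$y)
#' @export
synth_dataset <- function(task = c("regression", "classification", "survival"),
                          n_samples, n_features,
                          effect = NULL, noise_sd = 1,
                          censoring_rate = 0.3, seed = NULL) {
  task <- match.arg(task)
  stopifnot(n_samples >= 2, n_features >= 1, noise_sd >= 0,
            censoring_rate >= 0, censoring_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(effect)) {
    effect <- rep_len(c(1, -1), n_features) *
      if (task == "survival") 0.5 else 1
  }
  beta <- rep_len(effect, n_features)
  x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
  colnames(x) <- paste0("x", seq_len(n_features))
  lin <- drop(x %*% beta)
  out <- tibble::as_tibble(x)
  if (task == "regression") {
    out$y <- lin + stats::rnorm(n_samples, sd = noise_sd)
  } else if (task == "classification") {
    out$y <- stats::rbinom(n_samples, 1, stats::plogis(lin))
  } else {
    rate <- exp(pmin(lin, 20))
    t_event <- stats::rexp(n_samples, rate = rate)
    if (censoring_rate > 0) {
      # E[censored | c_max] = mean over i of (1 - exp(-rate_i c)) / (rate_i c)
      frac <- function(cmax) mean((1 - exp(-rate * cmax)) / (rate * cmax))
      cmax <- stats::uniroot(function(cm) frac(cm) - censoring_rate,
                             lower = 1e-8, upper = 1e8, tol = 1e-10)$root
      t_cens <- stats::runif(n_samples, 0, cmax)
      out$time <- pmin(t_event, t_cens)
      out$event <- as.integer(t_event <= t_cens)
    } else {
      out$time <- t_event
      out$event <- 1L
    }
  }
  attr(out, "beta") <- beta
  attr(out, "task") <- task
  out
}

#' Preset generators shaped like the evaluation datasets
#'
#' Convenience wrappers with the sample/feature geometry used throughout
#' the test bed: a 579 x 10 binary classification set, a 442 x 10
#' regression set, and a large-n 12-feature regression set (down-sized to
#' `n = 5000` by default; the full 42,894 is only ever needed for cheap
#' split arithmetic, not model fitting).
#'
#' @param seed Integer seed.
#' @param n Sample count for the large regression set.
#' @return A tibble as in [synth_dataset()].
#' @export
synth_ilpd_like <- function(seed = NULL) {
  synth_dataset("classification", n_samples = 579, n_features = 10,
                effect = rep_len(c(0.8, -0.8), 10), seed = seed)
}

#' @rdname synth_ilpd_like
#' @export
synth_diabetes_like <- function(seed = NULL) {
  synth_dataset("regression", n_samples = 442, n_features = 10,
                noise_sd = 1, seed = seed)
}

#' @rdname synth_ilpd_like
#' @export
synth_share_like <- function(seed = NULL, n = 5000) {
  synth_dataset("regression", n_samples = n, n_features = 12,
                noise_sd = 1, seed = seed)
}

#' Partition a pooled dataset into party datasets
#'
#' `mode = "iid"`: shuffle, then cut into contiguous blocks of the sizes
#' given by [plan_split()] (the default proportions reproduce the
#' 10/15/15/30/30 five-party split).  `mode = "label_skew"`: each party's
#' class mix interpolates between the global mix and a single dominant
#' class (round-robin over parties) with weight `skew_strength`, the
#' non-IID setting under which locally trained models stop generalizing.
#'
#' Pooling the partition recovers the pooled dataset as a multiset exactly,
#' minus any samples dropped by the remainder policy.
#'
#' @param data Pooled tibble (e.g. from [synth_dataset()]).
#' @param proportions Per-party fractions summing to 1.
#' @param mode `"iid"` or `"label_skew"`.
#' @param skew_strength In `[0, 1]`; 0 is IID, 1 is maximally skewed.
#' @param label Class column used for skewing.
#' @param remainder_policy Passed to [plan_split()].
#' @param seed Integer seed.
#' @return List of tibbles, one per party, each with attribute
#'   `"party_id"`.
#' @export
partition_parties <- function(data,
                              proportions = c(0.10, 0.15, 0.15, 0.30, 0.30),
                              mode = c("iid", "label_skew"),
                              skew_strength = 0, label = "y",
                              remainder_policy = c("drop", "assign_last"),
                              seed = NULL) {
  mode <- match.arg(mode)
  remainder_policy <- match.arg(remainder_policy)
  stopifnot(skew_strength >= 0, skew_strength <= 1)
  if (!is.null(seed)) set.seed(seed)
  plan <- plan_split(nrow(data), proportions, remainder_policy)
  counts <- plan$count
  if (any(counts == 0)) {
    stop("a party would receive 0 samples; adjust proportions or n",
         call. = FALSE)
  }
  n_parties <- length(counts)
  if (mode == "iid") {
    idx <- sample(nrow(data))
    starts <- cumsum(c(0, counts[-n_parties]))
    parts <- lapply(seq_len(n_parties), function(p) {
      idx[(starts[p] + 1):(starts[p] + counts[p])]
    })
  } else {
    parts <- skew_partition_idx(data[[label]], counts, skew_strength)
  }
  out <- lapply(seq_len(n_parties), function(p) {
    d <- data[parts[[p]], , drop = FALSE]
    attr(d, "party_id") <- p
    d
  })
  out
}

# Label-skew index allocation: party p's target class mix is
# (1 - s) * global + s * one_hot(dominant class of p), dominant classes
# assigned round-robin; draws honor availability, shortfalls filled from
# whatever classes remain.
skew_partition_idx <- function(labels, counts, s) {
  classes <- sort(unique(labels))
  k <- length(classes)
  n_parties <- length(counts)
  pools <- lapply(classes, function(cl) sample(which(labels == cl)))
  names(pools) <- as.character(classes)
  global_mix <- as.numeric(table(factor(labels, levels = classes))) / length(labels)
  parts <- vector("list", n_parties)
  for (p in seq_len(n_parties)) {
    dom <- ((p - 1) %% k) + 1
    mix <- (1 - s) * global_mix + s * (seq_len(k) == dom)
    want <- floor(mix * counts[p])
    # top up rounding shortfall, preferring the dominant class
    short <- counts[p] - sum(want)
    order_pref <- order(-(seq_len(k) == dom), -mix)
    for (j in order_pref) {
      if (short == 0) break
      want[j] <- want[j] + short
      short <- 0
    }
    take <- integer(0)
    for (j in seq_len(k)) {
      avail <- length(pools[[j]])
      m <- min(want[j], avail)
      if (m > 0) {
        take <- c(take, pools[[j]][seq_len(m)])
        pools[[j]] <- pools[[j]][-seq_len(m)]
      }
    }
    # fill any availability shortfall from remaining pools
    deficit <- counts[p] - length(take)
    j <- 1
    while (deficit > 0 && j <= k) {
      avail <- length(pools[[j]])
      m <- min(deficit, avail)
      if (m > 0) {
        take <- c(take, pools[[j]][seq_len(m)])
        pools[[j]] <- pools[[j]][-seq_len(m)]
        deficit <- deficit - m
      }
      j <- j + 1
    }
    parts[[p]] <- take
  }
  parts
}
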