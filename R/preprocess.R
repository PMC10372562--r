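#' Plan an uneven split of a pooled sample into parties
#'
#' Allocates `floor(p_i * n_total)` samples to party `i`.  Under the
#' default `"drop"` policy any remainder left by the floor rule is simply
#' not allocated (the printed evaluation split of 42,894 samples into
#' 10/15/15/30/30 percent leaves one sample unassigned); under
#' `"assign_last"` the remainder goes to the last party.
#'
#' @param n_total Total pooled sample count.
#' @param proportions Positive fractions summing to 1.
#' @param remainder_policy `"drop"` or `"assign_last"`.
#' @return A tibble with one row per party: `party`, `proportion`, `count`;
#'   attribute `"dropped"` holds the number of unallocated samples.
#' @examples
#' plan_split(42894, c(0.10, 0.15, 0.15, 0.30, 0.30))
#' @export
plan_split <- function(n_total,
                       proportions = c(0.10, 0.15, 0.15, 0.30, 0.30),
                       remainder_policy = c("drop", "assign_last")) {
  remainder_policy <- match.arg(remainder_policy)
  stopifnot(n_total >= 1, all(proportions > 0))
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  counts <- floor(proportions * n_total)
  if (remainder_policy == "assign_last") {
    counts[length(counts)] <- counts[length(counts)] + (n_total - sum(counts))
  }
  out <- tibble::tibble(
    party = seq_along(proportions),
    proportion = proportions,
    count = as.integer(counts)
  )
  attr(out, "dropped") <- as.integer(n_total - sum(counts))
  attr(out, "remainder_policy") <- remainder_policy
  out
}

#' Per-party moment statistics for federated standardization
#'
#' The sufficient statistics for a pooled mean and sample standard
#' deviation are the per-feature count, sum, and sum of squares — all
#' summable across parties, so standardization federates exactly.
#'
#' @param x Numeric matrix or data frame (samples x features).
#' @return A list with `n`, `sum`, `sumsq` (class `moment_stats`).
#' @export
moment_stats <- function(x) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), nrow(x) >= 1)
  structure(
    list(n = nrow(x), sum = colSums(x), sumsq = colSums(x^2)),
    class = "moment_stats"
  )
}

#' Pool moment statistics into global standardization parameters
#'
#' Computes the pooled mean and Bessel-corrected sample standard deviation
#' from summed moments: `mean = S1/n`, `var = (S2 - S1^2/n) / (n - 1)`.
#' The result is identical to standardizing the pooled data centrally.
#' Zero-variance features get `sd = 1` with a warning, so constant columns
#' pass through centered.
#'
#' @param local_stats List of [moment_stats()] objects with matching
#'   feature dimension.
#' @return A list with `mean`, `sd`, `n`, and logical `zero_variance`.
#' @export
federated_standardize <- function(local_stats) {
  stopifnot(length(local_stats) >= 1)
  n <- sum(vapply(local_stats, function(s) s$n, numeric(1)))
  if (n < 2) stop("need at least 2 pooled samples to standardize", call. = FALSE)
  s1 <- Reduce(`+`, lapply(local_stats, function(s) s$sum))
  s2 <- Reduce(`+`, lapply(local_stats, function(s) s$sumsq))
  mean <- s1 / n
  v <- (s2 - s1^2 / n) / (n - 1)
  v[v < 0] <- 0  # guard tiny negative round-off
  zero <- v < .Machine$double.eps * pmax(1, abs(s2 / n))
  sd <- sqrt(v)
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature(s); passing through centered",
                    sum(zero)), call. = FALSE)
    sd[zero] <- 1
  }
  list(mean = mean, sd = sd, n = n, zero_variance = zero)
}

#' Apply standardization parameters to a local matrix
#'
#' @param x Numeric matrix or data frame.
#' @param params Output of [federated_standardize()].
#' @return Standardized numeric matrix.
#' @export
apply_standardize <- function(x, params) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, params$mean, `-`), 2, params$sd, `/`)
}

#' Local fold assignment for k-fold cross-validation
#'
#' Each party shuffles its own samples into `k` folds whose sizes differ by
#' at most one; splits are local, so no indices cross party boundaries.
#'
#' @param n_local Local sample count.
#' @param k Number of folds.
#' @param seed Integer seed; the same seed reproduces the assignment.
#' @return Integer vector of length `n_local` with fold labels in `1..k`.
#' @export
local_kfold <- function(n_local, k, seed = NULL) {
  if (n_local < k) {
    stop("configuration error: fewer samples than folds", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  fold <- rep(seq_len(k), length.out = n_local)
  sample(fold)
}

#' Global one-hot category list from per-party category sets
#'
#' Parties share the category labels (not counts) they observe; the
#' coordinator returns the sorted union so that every party encodes with an
#' identical column order.  Categories absent at a party encode as all-zero
#' columns there.  Sharing labels is a documented privacy trade-off of this
#' app: a rare label's presence at some site is revealed.
#'
#' @param local_category_sets List of character vectors.
#' @return Sorted character vector of all distinct categories.
#' @export
federated_one_hot <- function(local_category_sets) {
  cats <- sort(unique(unlist(local_category_sets)))
  if (length(cats) == 0) stop("no categories observed", call. = FALSE)
  cats
}

#' Encode a categorical vector against a global category list
#'
#' @param values Character (or factor) vector.
#' @param categories Global ordered category list from
#'   [federated_one_hot()].
#' @return 0/1 integer matrix with one column per global category.
#' @export
encode_one_hot <- function(values, categories) {
  values <- as.character(values)
  out <- vapply(categories, function(cat) as.integer(values == cat),
                integer(length(values)))
  out <- matrix(out, nrow = length(values),
                dimnames = list(NULL, categories))
  out
}
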