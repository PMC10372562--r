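#' Fixed-point codec for secure aggregation
#'
#' Real-valued model parameters are mapped to residues of a prime ring so
#' that additive secret shares can be summed exactly in integer arithmetic.
#' Values are scaled by a power of ten, rounded, and reduced modulo a prime;
#' on decoding, residues above `modulus / 2` map back to negative numbers
#' (signed centering).
#'
#' The default modulus is the largest prime below 2^52
#' (4503599627370449), so the sum of any two residues stays below 2^53 and
#' modular addition in double-precision floats is exact.  At the default
#' scale of 10^6 a value of magnitude up to 10^6 encodes to roughly 10^12,
#' leaving headroom for sums over a few thousand parties before wrapping.
#'
#' @param scale Positive power of ten; one unit of the ring equals
#'   `1/scale` on the real line.  Default `1e6`.
#' @param modulus Prime ring size.  Must be below 2^52 so that share
#'   addition is exact in doubles.
#' @return An object of class `fp_codec`.
#' @examples
#' cdc <- fp_codec()
#' fp_decode(fp_encode(c(-1.5, 2.25), cdc), cdc)
#' @export
fp_codec <- function(scale = 1e6, modulus = 4503599627370449) {
  stopifnot(scale > 0, modulus > 2 * scale, modulus <= 2^52)
  structure(list(scale = scale, modulus = modulus), class = "fp_codec")
}

#' @export
print.fp_codec <- function(x, ...) {
  cat(sprintf("<fp_codec> scale = %g, modulus = %.0f (~2^%.1f)\n",
              x$scale, x$modulus, log2(x$modulus)))
  invisible(x)
}

# modular addition; exact because a + b < 2^53 for residues below 2^52
mod_add <- function(a, b, m) (a + b) %% m

# a * k mod m for a vector of residues and one nonnegative integer k,
# by binary (Russian-peasant) multiplication: only ever adds residues,
# so every intermediate stays exactly representable.
mod_mul_scalar <- function(a, k, m) {
  stopifnot(length(k) == 1, k == round(k))
  neg <- k < 0
  k <- abs(k)
  out <- rep(0, length(a))
  base <- a %% m
  while (k > 0) {
    if (k %% 2 == 1) out <- mod_add(out, base, m)
    base <- mod_add(base, base, m)
    k <- k %/% 2
  }
  if (neg) out <- (m - out) %% m
  out
}

#' Encode / decode real vectors on the fixed-point ring
#'
#' @param v Numeric vector to encode.
#' @param r Residue vector to decode.
#' @param codec An [fp_codec()].
#' @return `fp_encode()` returns a residue vector in `[0, modulus)`;
#'   `fp_decode()` returns a numeric vector (`round(v * scale) / scale`).
#' @export
fp_encode <- function(v, codec = fp_codec()) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  if (any(abs(v) * codec$scale >= codec$modulus / 2)) {
    stop("encoding error: value magnitude exceeds modulus/2 at this scale",
         call. = FALSE)
  }
  round(v * codec$scale) %% codec$modulus
}

#' @rdname fp_encode
#' @export
fp_decode <- function(r, codec = fp_codec()) {
  r <- r %% codec$modulus
  r[r > codec$modulus / 2] <- r[r > codec$modulus / 2] - codec$modulus
  r / codec$scale
}

# uniform residues in [0, modulus): two 26-bit draws glued together,
# rejection-sampled below m (rejection probability < 1e-4 at the default m)
draw_residues <- function(n, m) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    r <- floor(stats::runif(length(need)) * 2^26) * 2^26 +
      floor(stats::runif(length(need)) * 2^26)
    ok <- r < m
    out[need[ok]] <- r[ok]
    need <- need[!ok]
  }
  out
}

#' Split a secret vector into additive shares
#'
#' One party's real-valued vector is encoded on the fixed-point ring and
#' split into `n_parties` residue vectors whose modular sum equals the
#' encoded secret.  The first `n_parties - 1` shares are uniform on the
#' ring; the last is the difference.  Any `n_parties - 1` shares are
#' jointly uniform, so no proper subset reveals the secret.
#'
#' The scheme requires at least three parties: with two, the coordinator
#' could subtract its own contribution from the global sum and recover the
#' other party's vector, so the protocol is undefined below three.
#'
#' @param secret Numeric vector to protect.
#' @param n_parties Number of parties (>= 3).
#' @param codec An [fp_codec()].
#' @param rng_seed Optional integer seed for the share randomness.
#' @return An object of class `share_bundle`: a list with `shares` (an
#'   `n_parties` x `length(secret)` residue matrix, row `j` destined for
#'   party `j`), `length`, and `codec`.
#' @examples
#' b <- make_shares(c(1.5, -2), n_parties = 3, rng_seed = 1)
#' fp_decode(combine_received(asplit(b$shares, 1)), b$codec)
#' @export
make_shares <- function(secret, n_parties, codec = fp_codec(), rng_seed = NULL) {
  if (n_parties < 3) {
    stop("protocol error: additive secret sharing requires at least 3 parties",
         call. = FALSE)
  }
  if (!is.null(rng_seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(rng_seed)
  }
  enc <- fp_encode(secret, codec)
  len <- length(enc)
  shares <- matrix(0, nrow = n_parties, ncol = len)
  partial <- rep(0, len)
  for (j in seq_len(n_parties - 1)) {
    shares[j, ] <- draw_residues(len, codec$modulus)
    partial <- mod_add(partial, shares[j, ], codec$modulus)
  }
  shares[n_parties, ] <- (enc - partial) %% codec$modulus
  structure(list(shares = shares, length = len, codec = codec),
            class = "share_bundle")
}

#' Sum the shares a party has received
#'
#' Each party adds, on the ring, the one share addressed to it from every
#' other party's bundle, producing a partial sum that reveals nothing on
#' its own.
#'
#' @param received_shares List of residue vectors of equal length.
#' @param codec An [fp_codec()].
#' @return Residue vector: the elementwise modular sum.
#' @export
combine_received <- function(received_shares, codec = fp_codec()) {
  stopifnot(length(received_shares) >= 1)
  lens <- vapply(received_shares, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("protocol error: share vectors have mismatched lengths", call. = FALSE)
  }
  as.vector(Reduce(function(a, b) mod_add(a, b, codec$modulus),
                   received_shares))
}

#' Reconstruct the global sum from per-party partial sums
#'
#' The coordinator adds all partial sums on the ring and decodes.  The
#' result equals the plain sum of the original secrets up to `1/scale`
#' rounding per summand.  Multiplication of the reconstructed total by
#' public constants may equivalently be applied to shares before summation
#' via [mod_mul_scalar]; secret-by-secret products are not supported.
#'
#' @param partials List of residue vectors, one per party.
#' @param codec An [fp_codec()].
#' @return Numeric vector: the decoded global sum.
#' @export
reconstruct_sum <- function(partials, codec = fp_codec()) {
  if (length(partials) == 0 || any(vapply(partials, is.null, logical(1)))) {
    stop("protocol error: missing partial sum", call. = FALSE)
  }
  fp_decode(combine_received(partials, codec), codec)
}

#' Traffic cost of one secure summation
#'
#' Every party sends one share to each of the other `n - 1` parties, so
#' share messages grow quadratically in the number of parties — the price
#' of hiding local vectors from the coordinator.
#'
#' @param n_parties Number of parties (>= 3).
#' @param vector_len Length of the vector being summed.
#' @return A tibble with `share_messages` (`n(n-1)`), `partial_messages`
#'   (`n`), and `bytes` (8 bytes per float64 element over all share and
#'   partial messages).
#' @export
secure_sum_traffic <- function(n_parties, vector_len) {
  if (n_parties < 3) {
    stop("protocol error: additive secret sharing requires at least 3 parties",
         call. = FALSE)
  }
  share_msgs <- n_parties * (n_parties - 1)
  tibble::tibble(
    n_parties = n_parties,
    vector_len = vector_len,
    share_messages = share_msgs,
    partial_messages = n_parties,
    bytes = (share_msgs + n_parties) * vector_len * 8
  )
}

#' Securely sum a list of per-party vectors
#'
#' Runs the whole one-round additive scheme in one call: each party splits
#' its vector into shares, exchanges them (in the workflow engine the
#' exchange is routed through the coordinator as an opaque relay), combines
#' what it received, and the coordinator reconstructs the global sum.
#'
#' @param secrets List of numeric vectors of equal length, one per party.
#' @param codec An [fp_codec()].
#' @param rng_seed Optional integer seed.
#' @return Numeric vector: the global sum, exact to `1/scale` per summand.
#' @examples
#' secure_sum(list(c(1.5), c(2.25), c(-0.75)))
#' @export
secure_sum <- function(secrets, codec = fp_codec(), rng_seed = NULL) {
  n <- length(secrets)
  if (n < 3) {
    stop("protocol error: additive secret sharing requires at least 3 parties",
         call. = FALSE)
  }
  lens <- vapply(secrets, length, integer(1))
  stopifnot(length(unique(lens)) == 1)
  bundles <- lapply(seq_len(n), function(i) {
    make_shares(secrets[[i]], n, codec,
                rng_seed = if (is.null(rng_seed)) NULL else make_seed(rng_seed, i))
  })
  partials <- lapply(seq_len(n), function(j) {
    combine_received(lapply(bundles, function(b) b$shares[j, ]), codec)
  })
  reconstruct_sum(partials, codec)
}

# deterministic seed derivation; keeps derived seeds inside 32-bit range
make_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  acc <- 0
  for (p in parts) acc <- (acc * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(acc)
}
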