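#' Cyclic half-rotation of a 2k-bit word
#'
#' Rotates a 2k-bit integer by k bits (half its width), exchanging the
#' high and low halves.  Used inside the bijective hash transformations to
#' move the well-mixed inner bits of a canonical k-mer code to the outer
#' positions before multiplication.  Self-inverse.
#'
#' @param x numeric vector of values in `[0, 4^k)`.
#' @param k k-mer length (1..26).
#' @return numeric vector.
#' @export
rot_half <- function(x, k) {
  stopifnot(k >= 1, k <= 26)
  .cpp_rot_half(as.numeric(x), as.integer(k))
}

#' Bijective affine hash transformation and its inverse
#'
#' The bucket-address hash functions have the form
#' `f(x) = g(x) mod p` with `g(x) = (a * (rot_half(x) XOR b)) mod 4^k`.
#' Because `a` is odd, `g` is a bijection on `[0, 4^k)` and its inverse is
#' `x = rot_half(((a' * y) mod 4^k) XOR b)` where `a'` is the
#' multiplicative inverse of `a` modulo `4^k`.  Bijectivity is what makes
#' quotienting possible: the stored quotient plus the bucket address
#' reconstruct the key exactly.
#'
#' @param x,y numeric vector of keys / hashed values in `[0, 4^k)`.
#' @param a odd multiplier in `[1, 4^k)`.
#' @param b offset in `[0, 4^k)`.
#' @param k k-mer length (1..26).
#' @return numeric vector of transformed values.
#' @examples
#' g_inverse(g_forward(7, a = 3, b = 5, k = 2), a = 3, b = 5, k = 2)  # 7
#' @export
g_forward <- function(x, a, b, k) {
  stopifnot(k >= 1, k <= 26)
  if (a %% 2 == 0) stop("multiplier 'a' must be odd (bijectivity requires it)")
  stopifnot(a >= 1, a < 4^k, b >= 0, b < 4^k)
  .cpp_g_forward(as.numeric(x), as.numeric(a), as.numeric(b), as.integer(k))
}

#' @rdname g_forward
#' @export
g_inverse <- function(y, a, b, k) {
  stopifnot(k >= 1, k <= 26)
  if (a %% 2 == 0) stop("multiplier 'a' must be odd (bijectivity requires it)")
  stopifnot(a >= 1, a < 4^k, b >= 0, b < 4^k)
  .cpp_g_inverse(as.numeric(y), as.numeric(a), as.numeric(b), as.integer(k))
}

#' Random affine hash parameters
#'
#' Draws `n` distinct (a, b) pairs for the affine transformations, with
#' `a` uniform over odd values in `[1, 4^k)` and `b` uniform over
#' `[0, 4^k)`, from R's RNG after seeding with `seed`.  The store draws
#' its own parameters internally from its build seed; this helper exists
#' for experimentation and testing.
#'
#' @param k k-mer length (1..26).
#' @param n number of hash functions (default 3).
#' @param seed integer seed.
#' @return data.frame with columns `a` and `b`.
#' @export
hash_params <- function(k, n = 3, seed = 1) {
  stopifnot(k >= 1, k <= 26, n >= 1)
  with_preserved_seed(seed, {
    out <- data.frame(a = numeric(0), b = numeric(0))
    while (nrow(out) < n) {
      a <- floor(runif(1, 0, 4^k / 2)) * 2 + 1
      b <- floor(runif(1, 0, 4^k))
      if (!any(out$a == a & out$b == b)) out <- rbind(out, data.frame(a = a, b = b))
    }
    out
  })
}

#' Bucket address and quotient of a key
#'
#' Splits `g(x)` into the bucket address `f = g(x) mod p` and the
#' quotient `q = g(x) %/% p`.  Storing only q (plus a 2-bit hash-choice
#' tag) suffices to reconstruct the key, since `g(x) = p*q + f` and g is
#' bijective.
#'
#' @inheritParams g_forward
#' @param p number of buckets (1..4^k).
#' @return data.frame with columns `f` and `q`.
#' @export
bucket_and_quotient <- function(x, a, b, k, p) {
  stopifnot(p >= 1, p <= 4^k)
  g <- g_forward(x, a, b, k)
  data.frame(f = g %% p, q = g %/% p)
}

#' Quotient width in bits
#'
#' Number of bits needed for the quotient: `ceiling(2k - log2 p)`.  The
#' full slot then takes `2 + 3 + quotient_bits(k, p)` bits (hash-choice
#' tag, species value, quotient).
#'
#' @param k k-mer length (1..31).
#' @param p number of buckets; must satisfy `1 <= p <= 4^k`.
#' @return integer bit width.
#' @examples
#' quotient_bits(25, 1276595745)  # 20 -> 25-bit slots, 100-bit buckets
#' @export
quotient_bits <- function(k, p) {
  stopifnot(k >= 1, k <= 31)
  .cpp_quotient_bits(as.integer(k), as.numeric(p))
}

#' Bits per slot and per bucket for a store configuration
#'
#' @inheritParams quotient_bits
#' @param b slots per bucket (default 4).
#' @return list with `quotient_bits`, `slot_bits`, `bucket_bits`.
#' @export
slot_geometry <- function(k, p, b = 4) {
  qb <- quotient_bits(k, p)
  list(quotient_bits = qb, slot_bits = 2L + 3L + qb,
       bucket_bits = as.integer(b) * (2L + 3L + qb))
}
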