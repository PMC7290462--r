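# Internal helpers: seeded RNG scoping, intervals, arbitrary-precision integers.

#' Run code under a fixed RNG state, restoring the caller's state afterwards
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that results are pure functions of an integer seed,
#' independent of the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  old_kind <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(old_kind))
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  set.seed(as.integer(seed))
  force(code)
}

#' 0-based half-open interval constructor
#' @noRd
iv <- function(start, end) {
  stopifnot(length(start) == 1L, length(end) == 1L, start <= end)
  c(start = as.integer(start), end = as.integer(end))
}

iv_len <- function(x) unname(x["end"] - x["start"])

iv_overlap <- function(a, b) {
  max(0L, min(a["end"], b["end"]) - max(a["start"], b["start"]))
}

#' Fraction of interval `a` covered by interval `b`
#' @noRd
iv_overlap_frac <- function(a, b) {
  if (iv_len(a) == 0L) return(0)
  iv_overlap(a, b) / iv_len(a)
}

#' Round half away from zero to integer (used for percentages)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# ---- minimal exact big-integer arithmetic (non-negative) -------------------
# Values are little-endian numeric vectors of base-1e7 limbs.  Only the
# operations needed for exact diversity counts are provided: construction
# from a small integer, multiplication by a small integer, exponentiation,
# decimal rendering and log10.

BIG_BASE <- 1e7

big_from_int <- function(n) {
  stopifnot(n >= 0, n < 2^53)
  out <- numeric(0)
  n <- as.numeric(n)
  repeat {
    out <- c(out, n %% BIG_BASE)
    n <- floor(n / BIG_BASE)
    if (n == 0) break
  }
  out
}

big_mul_small <- function(b, m) {
  stopifnot(m >= 0, m < BIG_BASE)
  carry <- 0
  out <- numeric(length(b))
  for (i in seq_along(b)) {
    v <- b[i] * m + carry
    out[i] <- v %% BIG_BASE
    carry <- floor(v / BIG_BASE)
  }
  while (carry > 0) {
    out <- c(out, carry %% BIG_BASE)
    carry <- floor(carry / BIG_BASE)
  }
  # strip leading zero limbs (keep at least one)
  while (length(out) > 1L && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_pow_small <- function(base, exp) {
  stopifnot(exp >= 0)
  out <- big_from_int(1)
  if (exp == 0) return(out)
  for (i in seq_len(exp)) out <- big_mul_small(out, base)
  out
}

big_prod_small <- function(factors) {
  out <- big_from_int(1)
  for (f in factors) {
    if (f == 0) return(big_from_int(0))
    out <- big_mul_small(out, f)
  }
  out
}

big_to_string <- function(b) {
  n <- length(b)
  head <- format(b[n], scientific = FALSE, trim = TRUE)
  rest <- if (n > 1L) {
    vapply(rev(b[-n]), function(x) sprintf("%07d", as.integer(x)), character(1))
  } else character(0)
  paste0(head, paste0(rest, collapse = ""))
}

big_is_zero <- function(b) length(b) == 1L && b[1] == 0

big_log10 <- function(b) {
  if (big_is_zero(b)) return(-Inf)
  n <- length(b)
  lead <- b[n]
  if (n >= 2L) lead <- lead + b[n - 1L] / BIG_BASE
  log10(lead) + 7 * (n - 1L)
}

big_eq_string <- function(b, s) identical(big_to_string(b), s)

#' Validate a DNA string over {A,C,G,T,N}; returns position of first illegal
#' character or 0 when valid.
#' @noRd
first_illegal_base <- function(sequence) {
  m <- regexpr("[^ACGTN]", sequence)
  as.integer(m[1])
}
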