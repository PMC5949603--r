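# Minimal exact non-negative big-integer arithmetic (base-1e7 limb vectors,
# little-endian), sufficient for counting sequence spaces far beyond the
# 2^53 exact-double range. No arbitrary-precision package is required.

BI_BASE <- 1e7

big_int <- function(n = 0) {
  if (inherits(n, "bbp_bigint")) return(n)
  stopifnot(n >= 0, n == round(n), n < 2^53)
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, n %% BI_BASE)
    n <- n %/% BI_BASE
    if (n == 0) break
  }
  structure(limbs, class = "bbp_bigint")
}

bi_trim <- function(x) {
  while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]
  structure(x, class = "bbp_bigint")
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  x <- numeric(n); x[seq_along(a)] <- a; y <- numeric(n); y[seq_along(b)] <- b
  s <- x + y; carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% BI_BASE
    s[i] <- s[i] %% BI_BASE
  }
  if (carry > 0) s <- c(s, carry)
  bi_trim(s)
}

bi_mul_small <- function(a, k) {
  stopifnot(k >= 0, k < BI_BASE)
  if (k == 0) return(big_int(0))
  s <- unclass(a) * k; carry <- 0; out <- numeric(length(s))
  for (i in seq_along(s)) {
    v <- s[i] + carry
    out[i] <- v %% BI_BASE
    carry <- v %/% BI_BASE
  }
  while (carry > 0) {
    out <- c(out, carry %% BI_BASE)
    carry <- carry %/% BI_BASE
  }
  bi_trim(out)
}

bi_pow_small <- function(base, e) {
  stopifnot(e >= 0, e == round(e))
  out <- big_int(1)
  for (i in seq_len(e)) out <- bi_mul_small(out, base)
  out
}

# Exact division by a small integer (used for Burnside averaging; the sum is
# always divisible by the group order).
bi_div_small <- function(a, k) {
  stopifnot(k >= 1, k < BI_BASE)
  rem <- 0; out <- numeric(length(a))
  for (i in rev(seq_along(a))) {
    v <- rem * BI_BASE + a[i]
    out[i] <- v %/% k
    rem <- v %% k
  }
  if (rem != 0) stop("non-exact big-integer division")
  bi_trim(out)
}

#' @export
format.bbp_bigint <- function(x, ...) {
  n <- length(x)
  paste0(format(x[n], scientific = FALSE),
         paste(sprintf("%07d", rev(x[-n])), collapse = ""))
}

#' @export
print.bbp_bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.bbp_bigint <- function(x, ...) format(x)

#' @export
as.double.bbp_bigint <- function(x, ...) sum(unclass(x) * BI_BASE^(seq_along(x) - 1))
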