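# Exact non-negative big-integer arithmetic on base-1e7 digit vectors
# (little-endian doubles). Just enough for binomial sums whose magnitudes
# overflow doubles: add, multiply / exactly divide by a small integer.
# Multipliers must stay below ~9e8 so digit * m fits in the 2^53 exact
# range of a double.

BIG_BASE <- 1e7

big_from_int <- function(x) {
  stopifnot(x >= 0, x == floor(x))
  if (x == 0) return(0)
  d <- numeric(0)
  while (x > 0) { d <- c(d, x %% BIG_BASE); x <- x %/% BIG_BASE }
  d
}

big_trim <- function(a) {
  while (length(a) > 1L && a[length(a)] == 0) a <- a[-length(a)]
  a
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a))); b <- c(b, numeric(n - length(b)))
  s <- a + b; carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% BIG_BASE
    s[i] <- s[i] %% BIG_BASE
  }
  if (carry > 0) s <- c(s, big_from_int(carry))
  big_trim(s)
}

big_mul_small <- function(a, m) {
  stopifnot(m >= 0, m == floor(m), m < 9e8)
  if (m == 0) return(0)
  s <- a * m; carry <- 0
  for (i in seq_along(s)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% BIG_BASE
    s[i] <- s[i] %% BIG_BASE
  }
  while (carry > 0) { s <- c(s, carry %% BIG_BASE); carry <- carry %/% BIG_BASE }
  big_trim(s)
}

# exact division by a small integer (remainder must be 0)
big_div_small <- function(a, m) {
  stopifnot(m >= 1, m == floor(m), m < 9e8)
  q <- numeric(length(a)); rem <- 0
  for (i in rev(seq_along(a))) {
    cur <- rem * BIG_BASE + a[i]
    q[i] <- cur %/% m
    rem <- cur %% m
  }
  stopifnot(rem == 0)
  big_trim(q)
}

big_to_string <- function(a) {
  a <- big_trim(a)
  paste0(format(a[length(a)], scientific = FALSE),
         paste(rev(sprintf("%07d", a[-length(a)])), collapse = ""))
}

big_to_numeric <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1))

#' @export
print.ratiomics_bigint <- function(x, ...) {
  cat(big_to_string(unclass(x)), "\n")
  invisible(x)
}

#' @export
as.character.ratiomics_bigint <- function(x, ...) big_to_string(unclass(x))

#' @export
as.double.ratiomics_bigint <- function(x, ...) big_to_numeric(unclass(x))
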