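# Minimal exact big-integer arithmetic (non-negative), base 1e7, little-endian
# digit vectors. Only what the combinatorics of A^L-sized sequence spaces needs:
# add, multiply/divide by a small integer, compare, exponentiate, format.
# Doubles silently lose integer exactness above 2^53, which A^L exceeds for
# L >= 27 at A = 4 — hence this module.

BI_BASE <- 1e7

bi <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  d <- numeric(0)
  repeat {
    d <- c(d, x %% BI_BASE)
    x <- floor(x / BI_BASE)
    if (x == 0) break
  }
  structure(list(d = d), class = "pw_bigint")
}

bi_norm <- function(d) {
  carry <- 0
  for (i in seq_along(d)) {
    v <- d[i] + carry
    d[i] <- v %% BI_BASE
    carry <- floor(v / BI_BASE)
  }
  while (carry > 0) {
    d <- c(d, carry %% BI_BASE)
    carry <- floor(carry / BI_BASE)
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  structure(list(d = d), class = "pw_bigint")
}

bi_add <- function(a, b) {
  n <- max(length(a$d), length(b$d))
  da <- c(a$d, numeric(n - length(a$d)))
  db <- c(b$d, numeric(n - length(b$d)))
  bi_norm(da + db)
}

# multiplier m must keep digit * m below 2^53: m < 2^53 / 1e7 ~ 9e8
bi_mul_small <- function(a, m) {
  stopifnot(m >= 0, m == floor(m), m < 9e8)
  if (m == 0) return(bi(0))
  bi_norm(a$d * m)
}

# exact division by small integer; errors if not divisible
bi_div_small <- function(a, m) {
  stopifnot(m >= 1, m == floor(m), m < 9e8)
  d <- rev(a$d)
  out <- numeric(length(d))
  rem <- 0
  for (i in seq_along(d)) {
    cur <- rem * BI_BASE + d[i]
    out[i] <- floor(cur / m)
    rem <- cur - out[i] * m
  }
  if (rem != 0) stop("bi_div_small: not exactly divisible")
  bi_norm(rev(out))
}

bi_pow_small <- function(base, k) {
  out <- bi(1)
  for (i in seq_len(k)) out <- bi_mul_small(out, base)
  out
}

bi_cmp <- function(a, b) {
  if (length(a$d) != length(b$d)) return(sign(length(a$d) - length(b$d)))
  for (i in rev(seq_along(a$d))) {
    if (a$d[i] != b$d[i]) return(sign(a$d[i] - b$d[i]))
  }
  0L
}

#' @export
format.pw_bigint <- function(x, ...) {
  d <- rev(x$d)
  paste0(d[1], paste(sprintf("%07d", d[-1]), collapse = ""))
}

#' @export
print.pw_bigint <- function(x, ...) {
  cat("<exact integer> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.pw_bigint <- function(x, ...) format(x)

# lossy once past 2^53; callers needing exactness compare digits instead
# (as.numeric dispatches through as.double methods)
#' @export
as.double.pw_bigint <- function(x, ...) sum(x$d * BI_BASE^(seq_along(x$d) - 1))

# natural log, accurate from the leading digits (error < 1e-12 relative)
bi_log <- function(x) {
  n <- length(x$d)
  top <- x$d[n]
  if (n >= 2) top <- top + x$d[n - 1] / BI_BASE
  if (n >= 3) top <- top + x$d[n - 2] / BI_BASE^2
  if (n == 1L && x$d[1] == 0) return(-Inf)
  log(top) + (n - 1) * log(BI_BASE)
}
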