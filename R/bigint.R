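# Exact non-negative big integers for linear-extension counts.
#
# Counts of linear extensions grow factorially (an antichain of p elements has
# p! extensions), so 64-bit doubles overflow long before the downset DP does.
# Numbers are stored as little-endian digit vectors in base 1e6, held as
# doubles: every intermediate product is at most (1e6-1)^2 * length, far below
# 2^53 for any size this package can produce.

BIG_BASE <- 1e6
BIG_DIGITS <- 6L

new_bignat <- function(digits) {
  # strip leading (high-order) zeros; canonical zero is the single digit 0
  n <- length(digits)
  while (n > 1L && digits[n] == 0) n <- n - 1L
  structure(list(d = digits[seq_len(n)]), class = "bignat")
}

#' Exact non-negative integer
#'
#' Constructs an exact arbitrary-precision non-negative integer, the value
#' type returned by all counting functions in this package.  Supports `+`,
#' `*` and the comparison operators against other `bignat` objects or plain
#' non-negative integers, and converts to a decimal string with
#' [as.character()].
#'
#' @param x A single non-negative integer-valued number (must be below 2^53),
#'   or a decimal string.
#' @return An object of class `bignat`.
#' @examples
#' bignat(12) * bignat("1000000000000") + bignat(1)
#' big_factorial(25)
#' @export
bignat <- function(x) {
  if (inherits(x, "bignat")) return(x)
  if (is.character(x)) {
    if (length(x) != 1L || !grepl("^[0-9]+$", x)) {
      stop_input("bignat: string must be a single non-negative decimal integer")
    }
    x <- sub("^0+(?=.)", "", x, perl = TRUE)
    n <- nchar(x)
    starts <- rev(seq(n, 1L, by = -BIG_DIGITS))
    digits <- vapply(rev(starts), function(s) {
      as.numeric(substr(x, max(1L, s - BIG_DIGITS + 1L), s))
    }, numeric(1))
    return(new_bignat(digits))
  }
  if (length(x) != 1L || is.na(x) || x < 0 || x != trunc(x) || x >= 2^53) {
    stop_input("bignat: need a single exact non-negative integer below 2^53")
  }
  x <- as.numeric(x)
  digits <- numeric(0)
  repeat {
    digits <- c(digits, x %% BIG_BASE)
    x <- x %/% BIG_BASE
    if (x == 0) break
  }
  new_bignat(digits)
}

is_bignat <- function(x) inherits(x, "bignat")

big_carry <- function(d) {
  # propagate carries left-to-right; digits may exceed the base on entry
  i <- 1L
  while (i <= length(d)) {
    if (d[i] >= BIG_BASE) {
      q <- d[i] %/% BIG_BASE
      d[i] <- d[i] %% BIG_BASE
      if (i == length(d)) d <- c(d, 0)
      d[i + 1L] <- d[i + 1L] + q
    }
    i <- i + 1L
  }
  d
}

big_add <- function(a, b) {
  da <- a$d; db <- b$d
  n <- max(length(da), length(db))
  da <- c(da, numeric(n - length(da)))
  db <- c(db, numeric(n - length(db)))
  new_bignat(big_carry(da + db))
}

big_mul <- function(a, b) {
  da <- a$d; db <- b$d
  if ((length(da) == 1L && da == 0) || (length(db) == 1L && db == 0)) {
    return(bignat(0))
  }
  out <- numeric(length(da) + length(db))
  for (i in seq_along(da)) {
    idx <- i + seq_along(db) - 1L
    out[idx] <- out[idx] + da[i] * db
    out <- big_carry(out)
  }
  new_bignat(out)
}

# exact division by a small positive integer; errors if a remainder is left
big_div_small <- function(a, s) {
  if (s <= 0 || s != trunc(s) || s >= 2^26) {
    stop_input("big_div_small: divisor must be a positive integer below 2^26")
  }
  d <- a$d
  out <- numeric(length(d))
  rem <- 0
  for (i in rev(seq_along(d))) {
    cur <- rem * BIG_BASE + d[i]
    out[i] <- cur %/% s
    rem <- cur %% s
  }
  if (rem != 0) stop_domain("big_div_small: division is not exact")
  new_bignat(out)
}

big_cmp <- function(a, b) {
  da <- a$d; db <- b$d
  if (length(da) != length(db)) return(sign(length(da) - length(db)))
  for (i in rev(seq_along(da))) {
    if (da[i] != db[i]) return(sign(da[i] - db[i]))
  }
  0L
}

#' @export
as.character.bignat <- function(x, ...) {
  d <- rev(x$d)
  head <- format(d[1], scientific = FALSE)
  rest <- vapply(d[-1], function(v) {
    formatC(v, width = BIG_DIGITS, flag = "0", format = "d")
  }, character(1))
  paste0(head, paste(rest, collapse = ""))
}

#' @export
format.bignat <- function(x, ...) as.character(x)

#' @export
print.bignat <- function(x, ...) {
  cat(as.character(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.double.bignat <- function(x, ...) sum(x$d * BIG_BASE^(seq_along(x$d) - 1))

#' @export
Ops.bignat <- function(e1, e2) {
  if (nargs() == 1L) stop_input("unary operators are not defined for bignat")
  a <- bignat(e1)
  b <- bignat(e2)
  switch(.Generic,
    "+" = big_add(a, b),
    "*" = big_mul(a, b),
    "==" = big_cmp(a, b) == 0L,
    "!=" = big_cmp(a, b) != 0L,
    "<"  = big_cmp(a, b) < 0L,
    ">"  = big_cmp(a, b) > 0L,
    "<=" = big_cmp(a, b) <= 0L,
    ">=" = big_cmp(a, b) >= 0L,
    stop_input(sprintf("operator %s is not defined for bignat", .Generic))
  )
}

#' Exact factorial
#'
#' @param n Non-negative integer.
#' @return `n!` as a [bignat()].
#' @export
big_factorial <- function(n) {
  if (n < 0 || n != trunc(n)) stop_input("big_factorial: n must be a non-negative integer")
  out <- bignat(1)
  for (i in seq_len(n)) out <- big_mul(out, bignat(i))
  out
}

#' Exact binomial coefficient
#'
#' @param n,k Non-negative integers.
#' @return `choose(n, k)` as a [bignat()].
#' @export
big_binomial <- function(n, k) {
  if (k < 0 || k > n) return(bignat(0))
  k <- min(k, n - k)
  out <- bignat(1)
  for (i in seq_len(k)) {
    out <- big_div_small(big_mul(out, bignat(n - k + i)), i)
  }
  out
}

# multinomial(n1 + ... + nk; n1, ..., nk) as a product of binomials
big_multinomial <- function(sizes) {
  out <- bignat(1)
  acc <- 0
  for (s in sizes) {
    acc <- acc + s
    out <- big_mul(out, big_binomial(acc, s))
  }
  out
}
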