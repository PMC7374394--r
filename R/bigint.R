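# Minimal exact non-negative integer arithmetic used for search-space
# cardinality, which overflows 64-bit integers (e.g. 40^3 * 1009^3 * 3841^2).
# Numbers are stored little-endian in base 1e4 so per-limb products stay well
# inside the 2^53 exact-double range.

big_from_int <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(structure(list(limbs = 0), class = "hs_bigint"))
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% 1e4)
    x <- x %/% 1e4
  }
  structure(list(limbs = limbs), class = "hs_bigint")
}

big_mul_int <- function(big, m) {
  stopifnot(inherits(big, "hs_bigint"), m >= 0, m == floor(m), m < 2^40)
  if (m == 0) return(big_from_int(0))
  prod <- big$limbs * m
  carry <- 0
  out <- numeric(0)
  i <- 1L
  while (i <= length(prod) || carry > 0) {
    v <- carry + if (i <= length(prod)) prod[i] else 0
    out <- c(out, v %% 1e4)
    carry <- v %/% 1e4
    i <- i + 1L
  }
  structure(list(limbs = out), class = "hs_bigint")
}

#' @export
format.hs_bigint <- function(x, ...) {
  n <- length(x$limbs)
  head <- format(x$limbs[n], scientific = FALSE)
  rest <- if (n > 1L) sprintf("%04d", rev(x$limbs[-n])) else character(0)
  paste0(c(head, rest), collapse = "")
}

#' @export
print.hs_bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.hs_bigint <- function(x, ...) format(x)

#' @export
as.double.hs_bigint <- function(x, ...) {
  sum(x$limbs * 1e4^(seq_along(x$limbs) - 1))
}
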