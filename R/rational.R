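#' Exact rational numbers
#'
#' A minimal exact-fraction type used by the carrier-risk calculator, so that
#' textbook genetic-risk quantities (1/60, 1/3600, 1/240, ...) are reproduced
#' as identities rather than to floating-point tolerance. Numerator and
#' denominator are stored as doubles holding integer values (exact up to
#' 2^53), always gcd-reduced, with the sign carried on the numerator.
#'
#' Arithmetic (`+`, `-`, `*`, `/`), comparison (`==`, `<`, ...) and
#' `as.numeric()` are provided via group generics. Mixing a `rational` with a
#' plain numeric degrades gracefully to numeric.
#'
#' @param num integer-valued numerator.
#' @param den integer-valued denominator; must be non-zero.
#' @return An object of class `rational`.
#' @examples
#' rational(1, 30) / 2 == rational(1, 60)
#' rational(1, 60)^2
#' @export
rational <- function(num, den = 1) {
  if (length(num) != 1L || length(den) != 1L) {
    stop("rational() is scalar; got vector arguments", call. = FALSE)
  }
  if (!is.numeric(num) || !is.numeric(den) ||
      num != trunc(num) || den != trunc(den)) {
    stop("numerator and denominator must be integer-valued", call. = FALSE)
  }
  if (den == 0) stop("zero denominator", call. = FALSE)
  if (abs(num) > 2^53 || abs(den) > 2^53) {
    stop("rational components exceed exact integer range (2^53)", call. = FALSE)
  }
  if (den < 0) {
    num <- -num
    den <- -den
  }
  g <- gcd_int(abs(num), den)
  if (g > 1) {
    num <- num / g
    den <- den / g
  }
  structure(list(num = num, den = den), class = "rational")
}

gcd_int <- function(a, b) {
  while (b != 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  if (a == 0) 1 else a
}

#' @export
is_rational <- function(x) inherits(x, "rational")

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
format.rational <- function(x, ...) {
  if (x$den == 1) format(x$num) else paste0(format(x$num), "/", format(x$den))
}

#' @export
print.rational <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

rat_binop <- function(op, e1, e2) {
  # integer-valued numeric scalars (the 2s and 4s of the risk formulas) are
  # promoted to rational so exactness survives; true floats degrade the
  # whole expression to numeric
  promote <- function(x) {
    if (is_rational(x)) return(x)
    if (is.numeric(x) && length(x) == 1L && is.finite(x) &&
        x == trunc(x) && abs(x) <= 2^53) {
      return(rational(x))
    }
    NULL
  }
  p1 <- promote(e1)
  p2 <- promote(e2)
  if (is.null(p1) || is.null(p2)) {
    return(get(op)(
      if (is_rational(e1)) as.numeric(e1) else e1,
      if (is_rational(e2)) as.numeric(e2) else e2
    ))
  }
  e1 <- p1
  e2 <- p2
  switch(op,
    "+" = rational(e1$num * e2$den + e2$num * e1$den, e1$den * e2$den),
    "-" = rational(e1$num * e2$den - e2$num * e1$den, e1$den * e2$den),
    "*" = rational(e1$num * e2$num, e1$den * e2$den),
    "/" = {
      if (e2$num == 0) stop("division by zero rational", call. = FALSE)
      rational(e1$num * e2$den, e1$den * e2$num)
    },
    "^" = {
      k <- as.numeric(e2)
      if (k != trunc(k)) stop("rational power must be integer", call. = FALSE)
      if (k >= 0) rational(e1$num^k, e1$den^k) else rational(e1$den^-k, e1$num^-k)
    },
    stop("unsupported rational operation: ", op, call. = FALSE)
  )
}

#' @export
Ops.rational <- function(e1, e2) {
  if (.Generic %in% c("+", "-", "*", "/", "^")) {
    if (missing(e2)) { # unary
      if (.Generic == "-") return(rational(-e1$num, e1$den))
      return(e1)
    }
    return(rat_binop(.Generic, e1, e2))
  }
  # comparisons: cross-multiply when both rational (exact), else numeric
  a <- if (is_rational(e1)) e1 else NULL
  b <- if (is_rational(e2)) e2 else NULL
  if (!is.null(a) && !is.null(b)) {
    lhs <- a$num * b$den
    rhs <- b$num * a$den
  } else {
    lhs <- if (is.null(a)) e1 else as.numeric(a)
    rhs <- if (is.null(b)) e2 else as.numeric(b)
  }
  switch(.Generic,
    "==" = lhs == rhs, "!=" = lhs != rhs,
    "<" = lhs < rhs, ">" = lhs > rhs,
    "<=" = lhs <= rhs, ">=" = lhs >= rhs,
    stop("unsupported rational operation: ", .Generic, call. = FALSE)
  )
}

# Coerce a probability-like input to rational when possible, keep numeric
# otherwise. Used so risk operations honour the "rational in, rational out;
# float in, float out" contract.
as_prob <- function(x, what = "probability") {
  v <- if (is_rational(x)) as.numeric(x) else x
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
    stop(what, " must be a single value in [0, 1]", call. = FALSE)
  }
  x
}
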