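# Exact rational arithmetic.
#
# Rationals are stored as parallel numerator/denominator vectors of doubles
# holding integers. Doubles represent every integer up to 2^53 exactly and
# multiplication is correctly rounded, so a post-hoc magnitude check of
# |result| <= 2^52 guarantees the computed product/sum is the true integer.
# All entries are kept reduced (gcd 1, denominator positive); any operation
# that would leave the safe range aborts instead of rounding.

.INT_GUARD <- 2^52

.chk_int <- function(x) {
  if (any(abs(x) > .INT_GUARD))
    stop("exact integer overflow: intermediate value exceeds 2^52; ",
         "input coefficients are too large for the exact kernel",
         call. = FALSE)
  x
}

# gcd of two nonnegative scalars (Euclid)
.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# elementwise gcd of two vectors
rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  repeat {
    nz <- which(b != 0)
    if (!length(nz)) return(a)
    r <- numeric(length(a))
    r[nz] <- a[nz] %% b[nz]
    a[nz] <- b[nz]
    b <- r
  }
}

# gcd of all entries of a vector (0 for the all-zero vector)
vec_gcd <- function(v) {
  g <- 0
  for (x in v) {
    g <- .gcd2(g, x)
    if (g == 1) break
  }
  g
}

.lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  .chk_int(abs(a) / .gcd2(a, b) * abs(b))
}

# reduce num/den pairs: positive denominator, gcd 1
rat_norm <- function(num, den) {
  if (any(den == 0)) stop("zero denominator in rational", call. = FALSE)
  .chk_int(num); .chk_int(den)
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- rat_gcd(num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

rat_add <- function(n1, d1, n2, d2) {
  rat_norm(.chk_int(.chk_int(n1 * d2) + .chk_int(n2 * d1)), .chk_int(d1 * d2))
}

rat_sub <- function(n1, d1, n2, d2) rat_add(n1, d1, -n2, d2)

rat_mul <- function(n1, d1, n2, d2) {
  # cross-reduce first to limit growth
  g1 <- rat_gcd(n1, d2); g1[g1 == 0] <- 1
  g2 <- rat_gcd(n2, d1); g2[g2 == 0] <- 1
  rat_norm(.chk_int((n1 / g1) * (n2 / g2)), .chk_int((d1 / g2) * (d2 / g1)))
}

rat_div <- function(n1, d1, n2, d2) {
  if (any(n2 == 0)) stop("division by zero rational", call. = FALSE)
  rat_mul(n1, d1, d2 * sign(n2), abs(n2))
}

# sign of r1 - r2 (denominators assumed positive)
rat_cmp <- function(n1, d1, n2, d2) {
  sign(.chk_int(n1 * d2) - .chk_int(n2 * d1))
}

# exact dot product of two rational vectors -> scalar list(num, den)
rat_dot <- function(n1, d1, n2, d2) {
  acc_n <- 0; acc_d <- 1
  for (i in seq_along(n1)) {
    if (n1[i] == 0 || n2[i] == 0) next
    p <- rat_mul(n1[i], d1[i], n2[i], d2[i])
    r <- rat_add(acc_n, acc_d, p$num, p$den)
    acc_n <- r$num; acc_d <- r$den
  }
  list(num = unname(acc_n), den = unname(acc_d))
}

# render an integral double without scientific notation
int_chr <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Format exact rationals as "p/q" strings
#'
#' Integers are rendered without the "/1" suffix.
#'
#' @param num numerator vector (integral doubles).
#' @param den denominator vector (positive integral doubles).
#' @return character vector.
#' @export
format_rational <- function(num, den) {
  r <- rat_norm(num, den)
  out <- ifelse(r$den == 1, int_chr(r$num),
                paste0(int_chr(r$num), "/", int_chr(r$den)))
  unname(out)
}

#' Parse exact rationals from strings or numbers
#'
#' Accepts integer strings ("-3"), fraction strings ("p/q"), and decimal
#' strings ("0.25", parsed by decimal-string interpretation, i.e. 0.1 becomes
#' 1/10 and never the binary double value). Numeric input is routed through
#' its shortest decimal representation for the same reason.
#'
#' @param x character or numeric vector.
#' @return list with integral `num` and `den` vectors.
#' @export
parse_rational <- function(x) {
  if (is.numeric(x)) {
    x <- vapply(x, function(v) {
      if (!is.finite(v)) stop("non-finite value cannot be parsed as a rational",
                              call. = FALSE)
      format(v, digits = 15, scientific = FALSE)
    }, character(1))
  }
  x <- trimws(as.character(x))
  num <- den <- numeric(length(x))
  for (k in seq_along(x)) {
    s <- x[k]
    if (grepl("^[+-]?[0-9]+/[0-9]+$", s)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      num[k] <- as.numeric(parts[1])
      den[k] <- as.numeric(parts[2])
    } else if (grepl("^[+-]?[0-9]*\\.[0-9]+$", s)) {
      frac <- sub("^[^.]*\\.", "", s)
      num[k] <- as.numeric(sub(".", "", s, fixed = TRUE))
      den[k] <- 10^nchar(frac)
    } else if (grepl("^[+-]?[0-9]+$", s)) {
      num[k] <- as.numeric(s)
      den[k] <- 1
    } else {
      stop("cannot parse '", s, "' as an exact rational", call. = FALSE)
    }
  }
  rat_norm(num, den)
}

# scale a rational vector to its primitive integer representative
# (integer entries, gcd of absolute values 1, direction preserved)
rat_primitive <- function(num, den) {
  r <- rat_norm(num, den)
  L <- 1
  for (d in unique(r$den)) L <- .lcm2(L, d)
  v <- .chk_int(r$num * (L / r$den))
  g <- vec_gcd(v)
  if (g > 1) v <- v / g
  v
}
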