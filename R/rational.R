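# Minimal exact rational arithmetic on c(num, den) integer pairs.
# Doubles are used as integer carriers; all magnitudes here stay far below
# 2^53, where double arithmetic on integers is exact.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

rat <- function(num, den = 1) {
  num <- unname(num); den <- unname(den)
  if (den == 0) stop("rational with zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- .gcd2(num, den)
  if (g > 1) { num <- num / g; den <- den / g }
  c(num = num, den = den)
}

# continued-fraction conversion; exact for integers and small dyadic values
as_rat <- function(x, tol = 1e-9, max_den = 1e6) {
  if (length(x) != 1 || !is.finite(x)) stop("as_rat expects one finite value")
  if (abs(x - round(x)) < tol) return(rat(round(x)))
  sign <- if (x < 0) -1 else 1
  x0 <- abs(x)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; b <- x0
  repeat {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(x0 - h / k) < tol) break
    if (abs(b - a) < 1e-15) break
    b <- 1 / (b - a)
  }
  if (abs(x0 - h1 / k1) > tol) {
    stop("value ", x, " is not recognisably rational (tol = ", tol, ")")
  }
  rat(sign * h1, k1)
}

rat_add <- function(a, b) rat(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
rat_neg <- function(a) rat(-a[1], a[2])
rat_mul <- function(a, b) rat(a[1] * b[1], a[2] * b[2])
rat_div <- function(a, b) {
  if (b[1] == 0) stop("rational division by zero")
  rat(a[1] * b[2], a[2] * b[1])
}
# sign of a - b
rat_cmp <- function(a, b) sign(a[1] * b[2] - b[1] * a[2])
rat_num <- function(a) unname(a[1] / a[2])
rat_fmt <- function(a) if (a[2] == 1) format(a[1]) else paste0(a[1], "/", a[2])
rat_floor <- function(a) floor(a[1] / a[2])
rat_ceil <- function(a) ceiling(a[1] / a[2])

# least common multiple of denominators of a numeric vector
common_denominator <- function(x, tol = 1e-9) {
  dens <- vapply(x, function(v) as_rat(v, tol)[2], numeric(1))
  Reduce(function(a, b) a * b / .gcd2(a, b), dens, accumulate = FALSE, 1)
}
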