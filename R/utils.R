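# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Hann taper of n samples (0 at both ends for n > 1).
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Tukey (tapered cosine) window: flat plateau with cosine ramps covering
# alpha of the support (alpha = 1 reduces to Hann, 0 to rectangular).
tukey_window <- function(n, alpha = 0.5) {
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

# Deterministic 31-bit seed derived from a base seed plus stream indices,
# so each subject / classifier / permutation has an independent, reproducible
# RNG stream regardless of evaluation order.
derive_seed <- function(...) {
  v <- c(...)
  h <- 0
  for (x in v) h <- (h * 48271 + abs(as.numeric(x)) + 11) %% 2147483629
  as.integer(h) + 1L
}

#' Draw from the von Mises distribution
#'
#' Rejection sampler of Best and Fisher (1979). For `kappa = 0` the
#' distribution degenerates to the circular uniform.
#'
#' @param n number of draws.
#' @param mu preferred direction, radians.
#' @param kappa concentration parameter, `kappa >= 0`.
#' @return `n` angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(wrap_pi(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap_pi(mu + sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1)))
      i <- i + 1L
    }
  }
  out
}

#' Circular mean and resultant length
#'
#' @param x angles in radians.
#' @return `circ_mean`: mean direction in (-pi, pi]; `circ_r`: mean resultant
#'   length in `[0, 1]`.
#' @export
circ_mean <- function(x) Arg(sum(exp(1i * x)))

#' @rdname circ_mean
#' @export
circ_r <- function(x) Mod(mean(exp(1i * x)))

# Condition levels used throughout; order matters for reporting.
CONDITIONS <- c("control", "nonconfigural", "configural")
CATEGORIES <- c("indoor", "outdoor")

# Normalize a scalar or (partially) named per-condition value into a fully
# named vector over the three task conditions.
per_condition <- function(x, what = "value") {
  if (length(x) == 1 && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), 3), CONDITIONS))
  }
  if (is.null(names(x)) && length(x) == 3) {
    return(stats::setNames(as.numeric(x), CONDITIONS))
  }
  if (!all(names(x) %in% CONDITIONS)) {
    stop(sprintf("unknown condition name in %s: %s", what,
                 paste(setdiff(names(x), CONDITIONS), collapse = ", ")))
  }
  out <- stats::setNames(rep(0, 3), CONDITIONS)
  out[names(x)] <- as.numeric(x)
  out
}
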