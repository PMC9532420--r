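# Circular-error primitives: von Mises precision conversions, resultant
# lengths, error combination and sampling. Angles are degrees at the public
# interface and radians internally.

.rad <- function(x) x * (pi / 180)
.deg <- function(x) x * (180 / pi)

# wrap angle(s) to (-pi, pi]
.wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi)
  y[y <= 0] <- y[y <= 0] + 2 * pi
  y - pi
}

#' Convert angular deviation to von Mises concentration
#'
#' Orientation precision is quantified by the angular deviation
#' \eqn{\sigma = 1/\sqrt{\kappa}} (in radians), which closely resembles the
#' standard angular deviation for \eqn{\sigma \le 30}{sigma <= 30} degrees.
#'
#' @param sigma_deg angular deviation in degrees (> 0). A deviation of 0 is
#'   the deterministic limit and is represented by `kappa = Inf`; use
#'   [precision_spec()] rather than this converter for that case.
#' @return von Mises concentration parameter \eqn{\kappa = 1/\sigma^2}
#'   (with \eqn{\sigma} in radians).
#' @examples
#' sigma_to_kappa(20)  # ~ 8.2
#' sigma_to_kappa(2.5) # ~ 525
#' @seealso [kappa_to_sigma()], [circular_length()]
#' @export
sigma_to_kappa <- function(sigma_deg) {
  if (any(!is.finite(sigma_deg)) || any(sigma_deg <= 0)) {
    stop("`sigma_deg` must be finite and > 0 (0 encodes the deterministic limit)")
  }
  1 / .rad(sigma_deg)^2
}

#' @rdname sigma_to_kappa
#' @param kappa von Mises concentration (> 0; `Inf` maps to 0 degrees).
#' @export
kappa_to_sigma <- function(kappa) {
  if (any(kappa <= 0)) stop("`kappa` must be > 0")
  ifelse(is.infinite(kappa), 0, .deg(1 / sqrt(kappa)))
}

# internal: sigma in degrees (0 allowed) -> kappa with Inf sentinel
.kappa_of <- function(sigma_deg) {
  ifelse(sigma_deg <= 0, Inf, 1 / .rad(sigma_deg)^2)
}

#' Mean resultant length of a von Mises distribution
#'
#' The circular (mean resultant) length \eqn{I_1(\kappa)/I_0(\kappa)}, the
#' standard concentration measure in \eqn{[0, 1)}. Exponentially scaled
#' Bessel functions are used so that large concentrations do not overflow.
#'
#' @param kappa von Mises concentration (>= 0; `Inf` allowed).
#' @return mean resultant length in \eqn{[0, 1]}.
#' @examples
#' circular_length(8.2)  # ~ 0.94
#' circular_length(0)    # 0 (circular uniform)
#' @export
circular_length <- function(kappa) {
  if (any(kappa < 0)) stop("`kappa` must be >= 0")
  out <- numeric(length(kappa))
  inf <- is.infinite(kappa)
  out[inf] <- 1
  f <- !inf
  out[f] <- besselI(kappa[f], 1, expon.scaled = TRUE) /
    besselI(kappa[f], 0, expon.scaled = TRUE)
  out
}

#' Combine independent angular deviations
#'
#' Root-sum-square combination \eqn{\sigma_{A+B} = \sqrt{\sigma_A^2 + \sigma_B^2}},
#' the normal approximation for stacking independent circular errors. The
#' approximation degrades for combined deviations beyond about 30 degrees;
#' a `"valid_normal"` attribute flags this.
#'
#' @param sigmas_deg numeric vector of angular deviations in degrees (all >= 0).
#' @return combined deviation in degrees, with attribute `valid_normal`
#'   (`TRUE` when the result is within the ~30 degree regime).
#' @examples
#' combine_precisions(c(15, 15, 2.5)) # ~ 21.4
#' @export
combine_precisions <- function(sigmas_deg) {
  if (any(sigmas_deg < 0)) stop("angular deviations must be >= 0")
  out <- sqrt(sum(sigmas_deg^2))
  attr(out, "valid_normal") <- out <= 30
  out
}

#' Sample headings from a von Mises distribution
#'
#' Draws use the Best & Fisher (1979) wrapped-Cauchy rejection scheme.
#' `kappa = Inf` is the deterministic sentinel and returns the mean exactly
#' (bit-reproducible error-free runs); `kappa = 0` is circular uniform.
#' Randomness comes from the R session RNG, so callers control streams via
#' `set.seed()`.
#'
#' @param n number of draws.
#' @param mean_deg mean direction in degrees.
#' @param kappa concentration (>= 0, `Inf` allowed).
#' @return headings in degrees, wrapped to (-180, 180].
#' @export
rvonmises <- function(n, mean_deg = 0, kappa = 1) {
  if (length(kappa) == 1 && is.infinite(kappa)) {
    # deterministic sentinel: return the mean exactly (no radian round-trip)
    y <- (mean_deg + 180) %% 360
    y[y <= 0] <- y[y <= 0] + 360
    return(rep_len(y - 180, n))
  }
  .deg(.rvm_rad(n, .rad(mean_deg), kappa))
}

# internal radian sampler
.rvm_rad <- function(n, mu = 0, kappa = 1) {
  if (n == 0) return(numeric(0))
  if (is.infinite(kappa)) return(.wrap_pi(rep_len(mu, n)))
  if (kappa == 0) return(.wrap_pi(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      out[got + seq_len(k)] <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      got <- got + k
    }
  }
  .wrap_pi(mu + out)
}

#' Standard deviation of the along-axis step component
#'
#' For a von Mises heading error about the preferred direction, the
#' projection of a unit flight-step onto that direction is \eqn{\cos\Theta}.
#' Its standard deviation follows from the circular moments
#' \eqn{E[\cos\Theta] = I_1(\kappa)/I_0(\kappa)} and
#' \eqn{E[\cos 2\Theta] = I_2(\kappa)/I_0(\kappa)}:
#' \deqn{\sigma_C = \sqrt{\tfrac12\left(1 + I_2/I_0\right) - (I_1/I_0)^2}.}
#' Used by [timely_arrival()] to bound latitudinal progress.
#'
#' @param kappa von Mises concentration (> 0; `Inf` gives 0, `0` gives
#'   \eqn{\sqrt{1/2}}).
#' @return standard deviation of \eqn{\cos\Theta} (dimensionless).
#' @export
cosine_dispersion <- function(kappa) {
  if (any(kappa < 0)) stop("`kappa` must be >= 0")
  out <- numeric(length(kappa))
  inf <- is.infinite(kappa)
  f <- !inf
  i0 <- besselI(kappa[f], 0, expon.scaled = TRUE)
  r1 <- besselI(kappa[f], 1, expon.scaled = TRUE) / i0
  r2 <- besselI(kappa[f], 2, expon.scaled = TRUE) / i0
  out[f] <- sqrt(pmax(0, 0.5 * (1 + r2) - r1^2))
  out
}
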