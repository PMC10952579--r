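# Circular-statistics utilities used by the synthetic generators and the
# recovery analyses. Angles are degrees at the API boundary.

#' Circular mean of angles in degrees
#'
#' @param x angles, degrees.
#' @return mean direction in degrees in \code{(-180, 180]}.
#' @export
circular_mean <- function(x) {
  r <- deg2rad(x)
  wrap180(rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

#' Mean resultant length of angles in degrees
#' @param x angles, degrees.
#' @return R-bar in \code{[0, 1]}.
#' @export
circular_rbar <- function(x) {
  r <- deg2rad(x)
  sqrt(mean(sin(r))^2 + mean(cos(r))^2)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. Uses R's global RNG stream, so
#' results are reproducible under \code{set.seed()}.
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration (> 0).
#' @return angles in degrees in \code{(-180, 180]}.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa > 0)
  mu_r <- deg2rad(mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- mu_r + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap180(rad2deg(out))
}

#' Sample from a mixture of von Mises components
#'
#' @param n number of draws.
#' @param means component mean directions, degrees.
#' @param kappas component concentrations (> 0).
#' @param weights component weights (sum to 1); default uniform.
#' @return list with \code{values} (degrees) and integer \code{labels}.
#' @export
rvonmises_mixture <- function(n, means, kappas,
                              weights = rep(1 / length(means), length(means))) {
  stopifnot(length(means) == length(kappas), length(means) == length(weights),
            all(kappas > 0), abs(sum(weights) - 1) < 1e-8)
  lab <- sample.int(length(means), n, replace = TRUE, prob = weights)
  val <- numeric(n)
  for (k in seq_along(means)) {
    idx <- which(lab == k)
    if (length(idx)) val[idx] <- rvonmises(length(idx), means[k], kappas[k])
  }
  list(values = val, labels = lab)
}

#' Sample from a wrapped normal distribution
#'
#' Gaussian draws wrapped into \code{(-180, 180]}.
#'
#' @param n number of draws.
#' @param mu mean, degrees.
#' @param sigma standard deviation, degrees (>= 0).
#' @return angles in degrees.
#' @export
rwrappednorm <- function(n, mu, sigma) {
  stopifnot(sigma >= 0)
  wrap180(stats::rnorm(n, mu, sigma))
}
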