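#' Negative-binomial log probability mass, mean/shape parameterization
#'
#' The count likelihood used by the disparity model:
#' \deqn{P(y \mid \mu, \phi) = \frac{\Gamma(y+\phi)}{\Gamma(\phi)\, y!}
#'   \left(\frac{\phi}{\phi+\mu}\right)^{\phi}
#'   \left(\frac{\mu}{\phi+\mu}\right)^{y}}
#' with mean \eqn{\mu} and shape \eqn{\phi}, so the variance is
#' \eqn{\mu + \mu^2/\phi}; \eqn{\phi \to \infty} recovers the Poisson.
#'
#' @param y Non-negative integer count(s).
#' @param mu Positive mean(s).
#' @param phi Positive shape(s).
#' @return Log pmf value(s), vectorized with recycling.
#' @examples
#' nb_log_pmf(0, mu = 1, phi = 1)  # log(1/2)
#' @export
nb_log_pmf <- function(y, mu, phi) {
  if (any(y < 0) || any(y != floor(y))) {
    stop("y must be a non-negative integer", call. = FALSE)
  }
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  if (any(phi <= 0)) stop("phi must be > 0", call. = FALSE)
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    phi * (log(phi) - log(phi + mu)) +
    y * (log(mu) - log(phi + mu))
}
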