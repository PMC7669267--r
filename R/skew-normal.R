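# Maximum-likelihood skew-normal fitting and mode extraction.
#
# Distributions of substitution effects pile up against the assay's
# sensitivity limits and are therefore skewed; the skew-normal
# f(x) = (2/omega) phi(z) Phi(alpha z), z = (x - xi)/omega, generalises the
# normal (alpha = 0) to capture this, and its mode serves as the typical
# effect of a substitution.

#' Skew-normal density
#'
#' @param x Numeric vector of evaluation points.
#' @param xi Location.
#' @param omega Scale (> 0).
#' @param alpha Shape; `alpha = 0` recovers the normal distribution.
#' @param log Return log density?
#' @return Density values at `x`.
#' @export
dSkewNormal <- function(x, xi = 0, omega = 1, alpha = 0, log = FALSE) {
  stopifnot(omega > 0)
  z <- (x - xi) / omega
  lf <- log(2) - log(omega) + dnorm(z, log = TRUE) +
    pnorm(alpha * z, log.p = TRUE)
  if (log) lf else exp(lf)
}

# inverse Mills ratio phi(t)/Phi(t), numerically stable in the left tail
zetaIM <- function(t) exp(dnorm(t, log = TRUE) - pnorm(t, log.p = TRUE))

# Method-of-moments start: solve the skewness equation for delta.
snMomStart <- function(x) {
  m <- mean(x); s <- sd(x)
  g1 <- mean((x - m)^3) / s^3
  gmax <- 0.9952717  # supremum of skew-normal skewness
  g1 <- sign(g1) * min(abs(g1), 0.985 * gmax)
  a23 <- abs(g1)^(2 / 3)
  delta <- sign(g1) * sqrt((pi / 2) * a23 / (a23 + ((4 - pi) / 2)^(2 / 3)))
  delta <- sign(delta) * min(abs(delta), 0.995)
  alpha <- delta / sqrt(1 - delta^2)
  omega <- s / sqrt(1 - 2 * delta^2 / pi)
  xi <- m - omega * delta * sqrt(2 / pi)
  c(xi, log(omega), max(-50, min(50, alpha)))
}

snNll <- function(par, x) {
  xi <- par[1]; omega <- exp(par[2]); alpha <- par[3]
  z <- (x - xi) / omega
  -sum(log(2) - par[2] + dnorm(z, log = TRUE) +
         pnorm(alpha * z, log.p = TRUE))
}

snNllGrad <- function(par, x) {
  xi <- par[1]; omega <- exp(par[2]); alpha <- par[3]
  z <- (x - xi) / omega
  zt <- zetaIM(alpha * z)
  c(sum(-z + alpha * zt) / omega,
    length(x) - sum(z^2) + alpha * sum(z * zt),
    -sum(z * zt))
}

#' Fit a skew-normal distribution by maximum likelihood
#'
#' Quasi-Newton optimisation over (location, log scale, shape) from a
#' method-of-moments start, with the shape bounded at |alpha| <= 50 to
#' keep the fit away from the half-normal boundary. On failure a second
#' attempt starts from the normal fit (alpha = 0).
#'
#' @param values Numeric vector of observations.
#' @param minN Minimum number of finite values required to fit
#'   (default 20).
#' @return List with `xi`, `omega`, `alpha`, `mode`, `converged`, `n`.
#'   Degenerate input (constant values, or fewer than `minN`) returns
#'   `converged = FALSE` with `NA` parameters.
#' @export
#' @examples
#' x <- rnorm(361)
#' fitSkewNormal(x)$alpha  # near 0
fitSkewNormal <- function(values, minN = 20L) {
  x <- values[is.finite(values)]
  bad <- list(xi = NA_real_, omega = NA_real_, alpha = NA_real_,
              mode = NA_real_, converged = FALSE, n = length(x))
  if (length(x) < max(3L, minN) || sd(x) == 0) return(bad)
  # fit on standardised data for conditioning; back-transform after
  m <- mean(x); s <- sd(x)
  z <- (x - m) / s
  tryFit <- function(start) {
    suppressWarnings(
      optim(start, .snNllCpp, .snNllGradCpp, x = z, method = "L-BFGS-B",
            lower = c(-10, -10, -50), upper = c(10, 10, 50),
            control = list(maxit = 300L)))
  }
  fit <- tryFit(snMomStart(z))
  if (!is.finite(fit$value) || fit$convergence != 0) {
    fit2 <- tryFit(c(0, 0, 0))
    if (is.finite(fit2$value) &&
        (!is.finite(fit$value) || fit2$value <= fit$value)) fit <- fit2
  }
  if (!is.finite(fit$value)) return(bad)
  xi <- m + s * fit$par[1]
  omega <- s * exp(fit$par[2])
  alpha <- fit$par[3]
  list(xi = xi, omega = omega, alpha = alpha,
       mode = skewNormalMode(xi, omega, alpha),
       converged = fit$convergence == 0, n = length(x))
}

#' Mode of a skew-normal distribution
#'
#' The density is log-concave, so the mode is the unique root of the
#' derivative of the log density, solved to high precision by bracketed
#' root finding; `alpha = 0` gives `xi` exactly, and the mode is
#' location-scale equivariant.
#'
#' @inheritParams dSkewNormal
#' @return The argmax of the density.
#' @export
#' @examples
#' skewNormalMode(0, 1, 0)  # 0
skewNormalMode <- function(xi, omega, alpha) {
  stopifnot(omega > 0)
  if (alpha == 0) return(xi)
  a <- abs(alpha)
  # root of g(z) = -z + a*zeta(a z) (d/dz log density, strictly decreasing)
  # by Newton with bisection safeguard
  lo <- 0
  hi <- 1
  while (-hi + a * zetaIM(a * hi) > 0) {
    lo <- hi
    hi <- hi * 2
  }
  delta <- a / sqrt(1 + a^2)
  z <- min(max(delta * sqrt(2 / pi), lo), hi)  # start at the SN mean
  for (it in 1:50) {
    zt <- zetaIM(a * z)
    g <- -z + a * zt
    if (g > 0) lo <- z else hi <- z
    gp <- -1 - a^2 * zt * (a * z + zt)
    zNew <- z - g / gp
    if (zNew <= lo || zNew >= hi) zNew <- (lo + hi) / 2
    if (abs(zNew - z) < 1e-12 * max(1, z)) {
      z <- zNew
      break
    }
    z <- zNew
  }
  xi + sign(alpha) * omega * z
}
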