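#' @include AllClasses.R
NULL

# Deterministic per-stage seed stream: a single global seed plus a stage name
# yields an integer seed < 2^31, so stages can be rerun in isolation.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Project y orthogonal to the columns of X (always including an intercept).
projectOut <- function(y, X) {
  X <- cbind(1, X)
  qr.resid(qr(X), y)
}

# Rescale a centred vector to an exact sample variance.
rescaleVar <- function(x, targetVar) {
  v <- stats::var(x)
  if (v <= 0) return(x * 0)
  x * sqrt(targetVar / v)
}

#' Genotypic effects from genotype-class means
#'
#' Converts the three genotype-class means (hom-ref, het, hom-alt) into the
#' genotypic additive effect \eqn{a = (\mu_2 - \mu_0)/2} (half the homozygote
#' difference) and the genotypic dominance effect
#' \eqn{d = \mu_1 - (\mu_0 + \mu_2)/2} (heterozygote deviation from the
#' homozygote midpoint).
#'
#' @param mu0,mu1,mu2 class means for dosages 0, 1 and 2. Alternatively
#'   \code{mu0} may be a length-3 vector.
#' @return named numeric vector with elements \code{a}, \code{d} and \code{k}
#'   (the dominance coefficient \eqn{d/|a|}, \code{NA} when \eqn{a = 0}).
#' @examples
#' genotypicEffects(0, -1.44, -11.21)   # a mostly recessive pattern, k ~ 0.74
#' @export
genotypicEffects <- function(mu0, mu1 = NULL, mu2 = NULL) {
  if (is.null(mu1)) { mu2 <- mu0[3]; mu1 <- mu0[2]; mu0 <- mu0[1] }
  a <- (mu2 - mu0) / 2
  d <- mu1 - (mu0 + mu2) / 2
  c(a = a, d = d, k = dominanceCoefficient(a, d))
}

#' Dominance coefficient k = d / |a|
#'
#' \eqn{k \approx 0} marks an additive locus, \eqn{k \approx 1} a fully
#' recessive minor allele, and \eqn{k > 1} over-dominance.
#'
#' @param a genotypic additive effect (half the homozygote difference).
#' @param d genotypic dominance effect.
#' @return \code{d / abs(a)}; \code{NA} where \code{a == 0}.
#' @examples
#' dominanceCoefficient(-129.181, 109.644)
#' @export
dominanceCoefficient <- function(a, d) {
  k <- d / abs(a)
  k[a == 0] <- NA_real_
  k
}

#' Two-sided normal p-value from an estimate and its standard deviation
#'
#' The z-statistic \code{estimate / sd} is referred to the standard normal
#' distribution, as in a posterior-summary Z-test.
#'
#' @param estimate posterior mean (or any estimate).
#' @param sd its posterior standard deviation (or standard error).
#' @return list with \code{z} and two-sided \code{p}.
#' @examples
#' zTestP(-129.181, 23.604)
#' @export
zTestP <- function(estimate, sd) {
  z <- estimate / sd
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
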