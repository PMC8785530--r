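#' @include AllClasses.R
NULL

#' Sample genotype-class effects for one variant
#'
#' Reference (single-variant) implementation of the association sampler:
#' for every retained posterior sample \eqn{t}, the weighted least-squares
#' genotype-class means \eqn{\hat b^{(t)}} of the LOSO-adjusted phenotype
#' are computed and a draw
#' \eqn{b^{(t)} \sim N(\hat b^{(t)}, (T'R^{-1}T)^{-1}\sigma_e^{2(t)})}
#' is taken (\eqn{T'R^{-1}T} is diagonal for class indicators, so classes
#' are drawn independently). Empty classes yield \code{NA} effects.
#'
#' @param ytilde numeric matrix animals x samples of adjusted phenotypes.
#' @param x integer genotype vector (0/1/2, \code{NA} allowed).
#' @param w record-count weights.
#' @param varE residual-variance chain (one value per sample).
#' @param draw add the conditional-normal draw (set \code{FALSE} for the
#'   plain WLS class means).
#' @return matrix samples x 3 of class effects \code{b0}, \code{b1},
#'   \code{b2}.
#' @export
sampleClassEffects <- function(ytilde, x, w = rep(1, length(x)),
                               varE = rep(0, ncol(ytilde)), draw = TRUE) {
  stopifnot(nrow(ytilde) == length(x), length(w) == length(x),
            length(varE) == ncol(ytilde))
  occ <- sum(vapply(0:2, function(g) any(x == g, na.rm = TRUE), logical(1)))
  if (occ < 2) stop("variant must have at least 2 occupied genotype classes")
  b <- sapply(0:2, function(g) {
    idx <- which(x == g)
    if (!length(idx)) return(rep(NA_real_, ncol(ytilde)))
    sw <- sum(w[idx])
    bhat <- as.numeric(crossprod(w[idx], ytilde[idx, , drop = FALSE])) / sw
    if (draw) bhat + stats::rnorm(length(bhat)) * sqrt(varE / sw) else bhat
  })
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  colnames(b) <- c("b0", "b1", "b2")
  b
}

#' Summarise contrast chains from a class-effect chain
#'
#' Per sample: the genotypic additive contrast \eqn{a = (b_2 - b_0)/2},
#' the dominance contrast \eqn{d = b_1 - (b_0 + b_2)/2}, and the
#' standard-additive effect as the weighted regression slope of the class
#' effects on dosage. Summaries are the chain means and SDs, z = mean/SD,
#' two-sided normal p, and the dominance coefficient \eqn{k = d/|a|}
#' computed from the posterior means.
#'
#' @param b chain matrix samples x 3 from \code{\link{sampleClassEffects}}.
#' @param classWeights total WLS weight of each genotype class (sums of
#'   \code{w} per class; used for the dosage-slope contrast).
#' @return one-row data.frame with \code{aMean}, \code{aSd}, \code{aZ},
#'   \code{aP}, the same for \code{d} and \code{alpha}, and \code{k}.
#' @export
summarizeContrasts <- function(b, classWeights = c(1, 1, 1)) {
  a <- (b[, 3] - b[, 1]) / 2
  d <- b[, 2] - (b[, 1] + b[, 3]) / 2
  W <- classWeights
  has <- !is.na(b[1, ]) & W > 0
  al <- rep(NA_real_, nrow(b))
  if (sum(has) >= 2) {
    xg <- 0:2
    xbar <- sum(W[has] * xg[has]) / sum(W[has])
    Sxx <- sum(W[has] * (xg[has] - xbar)^2)
    al <- as.numeric(b[, has, drop = FALSE] %*%
                       (W[has] * (xg[has] - xbar))) / Sxx
  }
  s <- function(v, nm) {
    m <- mean(v); sd <- stats::sd(v)
    z <- if (is.na(sd) || sd == 0) NA_real_ else m / sd
    stats::setNames(data.frame(m, sd, z, 2 * stats::pnorm(-abs(z))),
                    paste0(nm, c("Mean", "Sd", "Z", "P")))
  }
  out <- cbind(s(a, "a"), s(d, "d"), s(al, "alpha"))
  out$k <- dominanceCoefficient(mean(a), mean(d))
  out
}

#' Genome scan of genotype-class contrasts over LOSO-adjusted phenotypes
#'
#' For each test variant, builds the MCMC chain of genotype-class effects
#' against the adjusted phenotypes of the variant's own LOSO segment and
#' summarises the additive, dominance and standard-additive contrasts
#' (see \code{\link{summarizeContrasts}}). Variants with an empty
#' heterozygote or homozygote class keep their defined contrasts and are
#' excluded from dominance calling downstream.
#'
#' @param geno a \linkS4class{GenotypeData} containing the test variants.
#' @param loso a \linkS4class{LOSOPhenotypes} whose plan covers
#'   \code{geno}'s map.
#' @param variants integer indices of the variants to test (default: all
#'   non-structure variants when the map is flagged, otherwise all).
#' @param extraAdjust optional animals x samples matrix subtracted from every
#'   adjusted phenotype (used by the iterative conditional scan).
#' @param seed integer seed for the class-effect draws.
#' @return data.frame with one row per tested variant: map columns,
#'   \code{maf}, class counts, contrast summaries, and \code{k}.
#' @export
scanAssociation <- function(geno, loso, variants = NULL, extraAdjust = NULL,
                            seed = 1L) {
  stopifnot(is(loso, "LOSOPhenotypes"))
  map <- variantMap(geno)
  mc <- S4Vectors::mcols(map)
  if (is.null(variants)) {
    variants <- if ("isStructure" %in% colnames(mc))
      which(!mc$isStructure) else seq_len(nVariants(geno))
  }
  variants <- sort(unique(variants))  # draws consumed in map order, so
                                      # results are input-order invariant
  plan <- loso@plan
  stopifnot(length(plan@assignment) == nVariants(geno))
  seg <- plan@assignment[variants]
  w <- loso@w
  set.seed(stageSeed(seed, "assoc"))
  out <- vector("list", length(unique(seg)))
  k <- 0
  for (s in sort(unique(seg))) {
    vs <- variants[seg == s]
    Y <- adjustedPhenotypes(loso, s)
    if (!is.null(extraAdjust)) Y <- Y - extraAdjust
    res <- cpp_scan_class_effects(dosages(geno), as.integer(vs - 1L),
                                  t(Y), w, loso@samples@varE)
    colnames(res) <- c("n0", "n1", "n2", "nMissing", "aMean", "aSd",
                       "dMean", "dSd", "alphaMean", "alphaSd")
    k <- k + 1
    out[[k]] <- cbind(data.frame(variant = vs, segment = s), res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$variant), ]
  ch <- as.character(GenomicRanges::seqnames(map))[res$variant]
  pos <- GenomicRanges::start(map)[res$variant]
  nObs <- res$n0 + res$n1 + res$n2
  altFreq <- (res$n1 + 2 * res$n2) / (2 * nObs)
  zp <- function(m, s) {
    z <- ifelse(is.na(s) | s == 0, NA_real_, m / s)
    list(z = z, p = 2 * stats::pnorm(-abs(z)))
  }
  za <- zp(res$aMean, res$aSd)
  zd <- zp(res$dMean, res$dSd)
  zal <- zp(res$alphaMean, res$alphaSd)
  data.frame(variant = res$variant, chrom = ch, pos = pos,
             ref = mc$ref[res$variant], alt = mc$alt[res$variant],
             segment = res$segment, maf = pmin(altFreq, 1 - altFreq),
             n0 = res$n0, n1 = res$n1, n2 = res$n2, nMissing = res$nMissing,
             aMean = res$aMean, aSd = res$aSd, aZ = za$z, aP = za$p,
             dMean = res$dMean, dSd = res$dSd, dZ = zd$z, dP = zd$p,
             alphaMean = res$alphaMean, alphaSd = res$alphaSd,
             alphaZ = zal$z, alphaP = zal$p,
             k = dominanceCoefficient(res$aMean, res$dMean),
             stringsAsFactors = FALSE)
}

#' Storey q-values
#'
#' \eqn{\hat\pi_0} is estimated on the grid
#' \eqn{\lambda \in \{0.05, \dots, 0.95\}} from
#' \eqn{\#\{p > \lambda\}/(m(1-\lambda))} with a df-3 spline smoother
#' evaluated at the largest \eqn{\lambda} (clamped to (0, 1]); then
#' \eqn{q_{(i)} = \min_{j \ge i}\ \hat\pi_0\, m\, p_{(j)} / j}, so q is
#' monotone in p and ties share a q-value. With fewer than 100 p-values
#' \eqn{\hat\pi_0} is fixed at 1 with a warning.
#'
#' @param p p-values in (0, 1] (\code{NA}s are passed through).
#' @param lambda tuning grid for \eqn{\hat\pi_0}.
#' @return list: \code{q} (same order as \code{p}) and \code{pi0}.
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv <= 0 | pv > 1)) stop("p-values must lie in (0, 1]")
  m <- length(pv)
  if (m < 100) {
    warning("fewer than 100 p-values: pi0 fixed at 1")
    pi0 <- 1
  } else {
    pi0l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    pi0 <- tryCatch({
      fit <- stats::smooth.spline(lambda, pi0l, df = 3)
      stats::predict(fit, x = max(lambda))$y
    }, error = function(e) min(pi0l))
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  ord <- order(pv)
  qo <- pi0 * m * pv[ord] / seq_len(m)
  qo <- rev(cummin(rev(qo)))
  qo <- pmin(qo, 1)
  q <- rep(NA_real_, length(p))
  qq <- numeric(m)
  qq[ord] <- qo
  q[ok] <- qq
  list(q = q, pi0 = pi0)
}

#' Classify the mode of dominance from k
#'
#' Bins the absolute dominance coefficient: \eqn{|k| \le 0.1} additive,
#' \eqn{0.1 < |k| < 0.7} partial-dominant, \eqn{0.7 < |k| < 1.3} the
#' recessive window, \eqn{|k| \ge 1.3} over-dominant (negative k mirrored;
#' the boundary 0.7 falls in the recessive window).
#'
#' @param k dominance coefficients (signed; the absolute value is binned).
#' @param edges bin edges \code{c(additive, recessive, over)}.
#' @return character vector of class labels.
#' @export
classifyDominance <- function(k, edges = c(0.1, 0.7, 1.3)) {
  ka <- abs(k)
  out <- rep(NA_character_, length(k))
  out[ka <= edges[1]] <- "additive"
  out[ka > edges[1] & ka < edges[2]] <- "partial-dominant"
  out[ka >= edges[2] & ka < edges[3]] <- "recessive-window"
  out[ka >= edges[3]] <- "over-dominant"
  out
}

#' Call and classify QTL from association results
#'
#' A variant is significant when the q-value of its dominance contrast
#' falls below \code{fdr} (computed per trait over all tested variants with
#' a defined dominance contrast) and is retained as a QTL when additionally
#' \eqn{\max(|a|, |d|)} exceeds \code{effectFrac} of the phenotypic SD.
#'
#' @param results data.frame from \code{\link{scanAssociation}}.
#' @param phenotypicSd phenotypic standard deviation of the trait.
#' @param fdr q-value threshold (default 1e-3).
#' @param effectFrac minimum effect size as a fraction of the phenotypic SD
#'   (default 0.05).
#' @param edges dominance-class bin edges, see
#'   \code{\link{classifyDominance}}.
#' @return the results with added \code{qD}, \code{passesFdr},
#'   \code{passesEffect}, \code{called} and \code{class} columns, ordered as
#'   input; attribute \code{"pi0"} carries the Storey estimate.
#' @export
callAndClassify <- function(results, phenotypicSd, fdr = 1e-3,
                            effectFrac = 0.05, edges = c(0.1, 0.7, 1.3)) {
  qv <- qvalues(results$dP)
  results$qD <- qv$q
  results$passesFdr <- !is.na(results$qD) & results$qD < fdr
  results$passesEffect <-
    pmax(abs(results$aMean), abs(results$dMean), na.rm = TRUE) >
    effectFrac * phenotypicSd
  results$called <- results$passesFdr & results$passesEffect
  results$class <- classifyDominance(results$k, edges)
  attr(results, "pi0") <- qv$pi0
  results
}
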