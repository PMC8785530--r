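#' @include AllClasses.R
NULL

#' Gibbs sampler configuration
#'
#' Defaults retain 500 post-burn-in, thinned samples of plausible SNP
#' effects. Priors on the three variance components are scaled
#' inverse-chi-squared with \code{priorDf} degrees of freedom; prior scales
#' default to an assumed 50/45/5 split of the phenotypic variance into
#' residual / additive / dominance, translated to per-SNP effect scales at
#' run time (all overridable).
#'
#' @param nRetained retained samples (>= 2).
#' @param burnIn discarded initial sweeps.
#' @param thin keep every \code{thin}-th post-burn-in sweep.
#' @param priorDf length-3 degrees of freedom for the additive-effect,
#'   dominance-effect and residual variances.
#' @param priorSplit assumed split of phenotypic variance into
#'   (additive, dominance, residual) used to set the prior scales.
#' @param seed integer seed.
#' @return list of class \code{GibbsConfig}.
#' @export
gibbsConfig <- function(nRetained = 500, burnIn = 1000, thin = 10,
                        priorDf = c(4, 4, 4),
                        priorSplit = c(alpha = 0.45, delta = 0.05, e = 0.5),
                        seed = 1L) {
  stopifnot(nRetained >= 2, thin >= 1, burnIn >= 0, all(priorDf > 0),
            length(priorSplit) == 3, all(priorSplit > 0))
  structure(list(nRetained = as.integer(nRetained),
                 burnIn = as.integer(burnIn), thin = as.integer(thin),
                 priorDf = priorDf,
                 priorSplit = priorSplit / sum(priorSplit),
                 seed = as.integer(seed)),
            class = "GibbsConfig")
}

#' BayesC0 Gibbs sampling of genome-wide SNP effects
#'
#' Samples the model \eqn{y = 1\mu + M_\alpha\alpha + M_\delta\delta + e}
#' with every SNP fitted, common effect variances
#' \eqn{\alpha_j \sim N(0, \sigma^2_\alpha)},
#' \eqn{\delta_j \sim N(0, \sigma^2_\delta)}, and weighted residuals
#' \eqn{e_i \sim N(0, \sigma^2_e / w_i)} (the diagonal of R varies with the
#' number of test-day records). \eqn{M_\alpha} holds dosage codes [0, 1, 2]
#' and \eqn{M_\delta} the heterozygote indicator [0, 1, 0], derived from the
#' same matrix. Single-site Gibbs updates draw each effect from its normal
#' full conditional and the variances from scaled inverse-chi-squared full
#' conditionals. Zero-variance SNP columns are pinned to effect 0.
#'
#' @param y numeric phenotypes (no missing values).
#' @param w positive record-count weights.
#' @param M integer dosage matrix (animals x structure SNPs).
#' @param config a \code{\link{gibbsConfig}}.
#' @param snpIds optional SNP identifiers.
#' @param fitDominance fit the dominance effects (\code{FALSE} pins every
#'   \eqn{\delta_j} to zero, leaving a plain additive BayesC0).
#' @param updateVariances draw the variance components (\code{FALSE} keeps
#'   them fixed at their initial values, making the effect posterior exactly
#'   Gaussian -- useful for closed-form cross-checks).
#' @param init optional named list overriding the initial/fixed variance
#'   values \code{varAlpha}, \code{varDelta}, \code{varE}.
#' @return a \linkS4class{PosteriorSampleSet}.
#' @export
gibbsBayesC0 <- function(y, w = rep(1, length(y)), M, config = gibbsConfig(),
                         snpIds = colnames(M), fitDominance = TRUE,
                         updateVariances = TRUE, init = list()) {
  stopifnot(inherits(config, "GibbsConfig"))
  if (any(!is.finite(y))) stop("non-finite phenotype")
  stopifnot(length(w) == length(y), nrow(M) == length(y), all(w > 0))
  storage.mode(M) <- "integer"
  if (anyNA(M)) {
    # mean impute to the nearest hard call at model-fitting time
    for (j in which(colSums(is.na(M)) > 0)) {
      mj <- M[, j]
      M[is.na(mj), j] <- as.integer(round(mean(mj, na.rm = TRUE)))
    }
  }
  vy <- stats::var(y)
  if (vy <= 0) stop("phenotype has zero variance")
  p <- colMeans(M) / 2
  het <- 2 * p * (1 - p)
  split <- config$priorSplit
  s2aInit <- split[["alpha"]] * vy / max(sum(het), 1)
  s2dInit <- split[["delta"]] * vy / max(sum(het * (1 - het)), 1)
  s2eInit <- split[["e"]] * vy
  if (!is.null(init$varAlpha)) s2aInit <- init$varAlpha
  if (!is.null(init$varDelta)) s2dInit <- init$varDelta
  if (!is.null(init$varE)) s2eInit <- init$varE
  set.seed(stageSeed(config$seed, "gibbs"))
  res <- cpp_gibbs_c0(y, w, M, config$burnIn, config$thin, config$nRetained,
                      as.numeric(config$priorDf),
                      c(s2aInit, s2dInit, s2eInit),
                      s2aInit, s2dInit, s2eInit, fitDominance,
                      updateVariances)
  if (is.null(snpIds)) snpIds <- sprintf("snp%06d", seq_len(ncol(M)))
  new("PosteriorSampleSet", mu = res$mu, alpha = res$alpha, delta = res$delta,
      varAlpha = res$varAlpha, varDelta = res$varDelta, varE = res$varE,
      snpIds = snpIds)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first 10\% of a chain against the mean of the
#' last 50\%:
#' \eqn{z = (\bar x_A - \bar x_B) / \sqrt{\hat S_A(0)/n_A + \hat S_B(0)/n_B}}
#' with spectral density at frequency zero estimated in each window from an
#' AIC-selected autoregressive fit. \eqn{|z| > 2} flags non-convergence.
#' Constant chains return \eqn{z = 0} with a degenerate flag.
#'
#' @param chain numeric chain (length >= 50).
#' @param fracA,fracB window fractions (defaults 0.1 and 0.5).
#' @return list: \code{z}, \code{converged} (\eqn{|z| \le 2}),
#'   \code{degenerate}.
#' @export
gewekeDiagnostic <- function(chain, fracA = 0.1, fracB = 0.5) {
  n <- length(chain)
  if (n < 50) stop("chain too short for the Geweke diagnostic (need >= 50)")
  if (stats::var(chain) == 0)
    return(list(z = 0, converged = TRUE, degenerate = TRUE))
  a <- chain[seq_len(max(2, floor(fracA * n)))]
  b <- chain[seq.int(n - floor(fracB * n) + 1, n)]
  spec0 <- function(x) {
    if (stats::var(x) == 0) return(0)
    fit <- tryCatch(stats::ar(x, aic = TRUE,
                              order.max = min(20, length(x) - 1)),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$ar) == 0) return(stats::var(x))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  se <- sqrt(spec0(a) / length(a) + spec0(b) / length(b))
  z <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  list(z = z, converged = abs(z) <= 2, degenerate = FALSE)
}

#' Partition a variant map into LOSO segments
#'
#' Tiles each chromosome into half-open intervals of \code{segmentBp}
#' (default 10 Mb) on 0-based coordinates: a 1-based position \eqn{p} belongs
#' to within-chromosome tile \eqn{\lfloor (p-1)/L \rfloor}. The last tile of
#' a chromosome is truncated at the largest observed position.
#'
#' @param chrom,pos per-variant chromosome and 1-based position (or a
#'   \linkS4class{GenotypeData} as \code{chrom}).
#' @param segmentBp segment width in bp.
#' @param chromLength optional named vector of chromosome lengths used to
#'   truncate the last tile (defaults to the largest variant position).
#' @return a \linkS4class{SegmentPlan}.
#' @export
partitionSegments <- function(chrom, pos = NULL, segmentBp = 1e7,
                              chromLength = NULL) {
  if (is(chrom, "GenotypeData")) {
    g <- chrom
    map <- variantMap(g)
    chrom <- as.character(GenomicRanges::seqnames(map))
    pos <- GenomicRanges::start(map)
    vids <- variantIds(g)
  } else {
    chrom <- as.character(chrom)
    vids <- paste(chrom, pos, sep = ":")
  }
  stopifnot(length(chrom) == length(pos), segmentBp > 0)
  tile <- (pos - 1) %/% segmentBp
  key <- paste(chrom, tile, sep = "_")
  segs <- unique(data.frame(chrom = chrom, tile = tile, key = key,
                            stringsAsFactors = FALSE))
  segs <- segs[order(segs$chrom, segs$tile), ]
  segs$segId <- seq_len(nrow(segs))
  segs$startBp <- segs$tile * segmentBp
  endOf <- if (is.null(chromLength))
    tapply(pos, chrom, max) else chromLength
  segs$endBp <- pmin(segs$startBp + segmentBp,
                     as.numeric(endOf[segs$chrom]))
  assignment <- segs$segId[match(key, segs$key)]
  new("SegmentPlan",
      segments = segs[, c("segId", "chrom", "startBp", "endBp")],
      assignment = as.integer(assignment), variantIds = vids)
}

#' Leave-one-segment-out adjusted phenotypes
#'
#' For every retained posterior sample \eqn{t}, the fully adjusted residual
#' \eqn{y - 1\mu^{(t)} - M_\alpha\alpha^{(t)} - M_\delta\delta^{(t)}} is
#' cached; the adjusted phenotype of segment \eqn{s} is obtained lazily by
#' adding back the fitted contribution of the structure SNPs inside \eqn{s}.
#' This is algebraically identical to summing over SNPs outside \eqn{s}
#' while never storing segments x samples vectors.
#'
#' @param y numeric phenotypes.
#' @param samples a \linkS4class{PosteriorSampleSet}.
#' @param plan a \linkS4class{SegmentPlan} covering the test variants.
#' @param structDosage integer dosage matrix of the structure SNPs
#'   (animals x SNPs, column order matching \code{samples}).
#' @param structChrom,structPos map of the structure SNPs, used to place
#'   them into segments of \code{plan}.
#' @param w record-count weights carried along for downstream WLS.
#' @return a \linkS4class{LOSOPhenotypes}.
#' @export
losoAdjust <- function(y, samples, plan, structDosage, structChrom,
                       structPos, w = rep(1, length(y))) {
  stopifnot(is(samples, "PosteriorSampleSet"), is(plan, "SegmentPlan"),
            nrow(structDosage) == length(y),
            ncol(structDosage) == nrow(samples@alpha))
  M <- structDosage
  storage.mode(M) <- "integer"
  if (anyNA(M)) {
    # mean-impute to the nearest hard call, consistently with the sampler
    for (j in which(colSums(is.na(M)) > 0)) {
      mj <- M[, j]
      M[is.na(mj), j] <- as.integer(round(mean(mj, na.rm = TRUE)))
    }
  }
  structDosage <- M
  storage.mode(M) <- "double"
  H <- (M == 1) * 1.0
  fit <- M %*% samples@alpha + H %*% samples@delta
  yAdj <- matrix(y, length(y), nSamples(samples)) -
    matrix(samples@mu, length(y), nSamples(samples), byrow = TRUE) - fit
  dimnames(yAdj) <- NULL
  dimnames(structDosage) <- NULL
  # place structure SNPs into the plan's segments
  segs <- plan@segments
  segBp <- max(segs$endBp - segs$startBp)
  tile <- (structPos - 1) %/% segBp
  key <- paste(structChrom, tile, sep = "_")
  segKey <- paste(segs$chrom, segs$startBp %/% segBp, sep = "_")
  segIdx <- segs$segId[match(key, segKey)]
  segIdx[is.na(segIdx)] <- 0L  # outside every test segment: never added back
  storage.mode(structDosage) <- "integer"
  new("LOSOPhenotypes", yAdjFull = yAdj, samples = samples,
      structDosage = structDosage, structSegment = as.integer(segIdx),
      plan = plan, w = as.numeric(w))
}

#' @rdname adjustedPhenotypes
#' @export
setMethod("adjustedPhenotypes", "LOSOPhenotypes", function(x, segment, ...) {
  if (is.na(segment)) return(x@yAdjFull)
  if (!segment %in% x@plan@segments$segId)
    stop("unknown segment id: ", segment)
  j <- which(x@structSegment == segment)
  if (!length(j)) return(x@yAdjFull)
  Ms <- x@structDosage[, j, drop = FALSE]
  storage.mode(Ms) <- "double"
  Hs <- (Ms == 1) * 1.0
  x@yAdjFull + Ms %*% x@samples@alpha[j, , drop = FALSE] +
    Hs %*% x@samples@delta[j, , drop = FALSE]
})
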