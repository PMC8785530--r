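#' @include AllGenerics.R
NULL

#' GenotypeData: dosage genotypes with a variant map
#'
#' Container for biallelic allele-dosage genotypes of a set of animals.
#' Dosages count copies of the alternate allele (0/1/2, \code{NA} for a
#' missing call) and are stored animals-by-variants so that each variant is a
#' contiguous column, which is the access pattern of all per-variant scans.
#' The variant map is a \link[GenomicRanges]{GRanges} (width-1 ranges,
#' 1-based positions) whose metadata columns carry the \code{ref} and
#' \code{alt} alleles and the per-variant imputation dosage R-squared
#' (\code{dr2}). Optional per-animal metadata (breed fractions) live in
#' \code{animalData}.
#'
#' @slot dosage integer matrix, animals x variants.
#' @slot map \code{GRanges} with mcols \code{ref}, \code{alt}, \code{dr2}.
#' @slot animalData \code{DataFrame} with one row per animal (may have zero
#'   columns); column \code{breedFracA} holds the ancestral fraction of pool A
#'   when known.
#'
#' @param dosage integer matrix of alternate-allele dosages (animals x
#'   variants); row names, when present, become animal identifiers.
#' @param chrom,pos,ref,alt per-variant map columns (recycled \code{ref}/
#'   \code{alt} default to "A"/"B" for simulated data).
#' @param dr2 per-variant imputation quality in [0, 1]; defaults to 1.
#' @param animalData optional \code{DataFrame}/\code{data.frame} of per-animal
#'   covariates (e.g. \code{breedFracA}).
#' @return a \code{GenotypeData} object.
#'
#' @examples
#' g <- GenotypeData(matrix(c(0L, 1L, 2L, 0L), 2, 2),
#'                   chrom = c("1", "1"), pos = c(100L, 200L))
#' variantStats(g)
#' @aliases dosages variantMap dr2 animalIds variantIds breedFractions
#'   nAnimals nVariants
#' @export GenotypeData
#' @exportClass GenotypeData
GenotypeData <- setClass("GenotypeData",
  slots = c(dosage = "matrix", map = "GRanges", animalData = "DataFrame"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!is.integer(object@dosage))
    msg <- c(msg, "dosage must be an integer matrix")
  if (ncol(object@dosage) != length(object@map))
    msg <- c(msg, "ncol(dosage) must equal length(map)")
  if (nrow(object@animalData) != nrow(object@dosage))
    msg <- c(msg, "animalData must have one row per animal")
  mc <- S4Vectors::mcols(object@map)
  if (!all(c("ref", "alt", "dr2") %in% colnames(mc)))
    msg <- c(msg, "map mcols must contain ref, alt, dr2")
  else {
    d <- mc$dr2
    if (any(d < 0 | d > 1, na.rm = TRUE))
      msg <- c(msg, "dr2 must lie in [0, 1]")
  }
  if (length(object@dosage)) {
    # min/max are allocation-free even on multi-GB matrices (range() copies)
    lo <- suppressWarnings(min(object@dosage, na.rm = TRUE))
    hi <- suppressWarnings(max(object@dosage, na.rm = TRUE))
    if (is.finite(lo) && (lo < 0L || hi > 2L))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  # positions strictly increasing within chromosome
  ch <- as.character(GenomicRanges::seqnames(object@map))
  pos <- GenomicRanges::start(object@map)
  if (length(pos) > 1) {
    same <- ch[-1] == ch[-length(ch)]
    if (any(same & diff(pos) <= 0))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GenotypeData-class construct from dosage matrix and map columns.
#' @export
GenotypeData <- function(dosage, chrom, pos, ref = "A", alt = "B", dr2 = 1,
                         animalData = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  if (storage.mode(dosage) != "integer") storage.mode(dosage) <- "integer"
  nv <- ncol(dosage)
  map <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L),
    ref = rep_len(as.character(ref), nv),
    alt = rep_len(as.character(alt), nv),
    dr2 = rep_len(as.numeric(dr2), nv))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("animal%05d", seq_len(nrow(dosage)))
  ad <- if (is.null(animalData)) {
    S4Vectors::DataFrame(row.names = rownames(dosage))
  } else S4Vectors::DataFrame(animalData, row.names = rownames(dosage))
  new("GenotypeData", dosage = dosage, map = map, animalData = ad)
}

#' @rdname GenotypeData-class
#' @export
setMethod("dosages", "GenotypeData", function(x, ...) x@dosage)

#' @rdname GenotypeData-class
#' @export
setMethod("variantMap", "GenotypeData", function(x, ...) x@map)

#' @rdname GenotypeData-class
#' @export
setMethod("dr2", "GenotypeData", function(x, ...) S4Vectors::mcols(x@map)$dr2)

#' @rdname GenotypeData-class
#' @export
setMethod("animalIds", "GenotypeData", function(x, ...) rownames(x@dosage))

#' @rdname GenotypeData-class
#' @export
setMethod("variantIds", "GenotypeData", function(x, ...) {
  mc <- S4Vectors::mcols(x@map)
  paste(as.character(GenomicRanges::seqnames(x@map)),
        GenomicRanges::start(x@map), mc$ref, mc$alt, sep = ":")
})

#' @rdname GenotypeData-class
#' @export
setMethod("breedFractions", "GenotypeData", function(x, ...) {
  ad <- x@animalData
  if ("breedFracA" %in% colnames(ad)) ad$breedFracA
  else rep(NA_real_, nrow(ad))
})

#' @rdname GenotypeData-class
#' @export
setMethod("nAnimals", "GenotypeData", function(x) nrow(x@dosage))

#' @rdname GenotypeData-class
#' @export
setMethod("nVariants", "GenotypeData", function(x) ncol(x@dosage))

#' @rdname GenotypeData-class
#' @param i,j,drop animal and variant indices (any standard subscript form);
#'   \code{drop} is ignored.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  if (is.character(j)) j <- match(j, variantIds(x))
  new("GenotypeData", dosage = x@dosage[i, j, drop = FALSE],
      map = x@map[j], animalData = x@animalData[i, , drop = FALSE])
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nAnimals(object), "animals x", nVariants(object),
      "variants on",
      length(unique(as.character(GenomicRanges::seqnames(object@map)))),
      "chromosome(s)\n")
  cat("  missing calls:", if (anyNA(object@dosage)) "present" else "none",
      "\n")
  invisible(NULL)
})

#' PosteriorSampleSet: retained Gibbs draws of genome-wide SNP effects
#'
#' Retained (post burn-in, thinned) draws from the BayesC0 Gibbs sampler of
#' \code{\link{gibbsBayesC0}}: the overall mean, the additive and dominance
#' effect vectors of every structure SNP, and the three variance components.
#'
#' @slot mu numeric chain of the overall mean.
#' @slot alpha,delta numeric matrices (SNPs x retained samples) of additive
#'   and dominance SNP effects.
#' @slot varAlpha,varDelta,varE numeric chains of the SNP-additive, SNP-
#'   dominance and residual variances.
#' @slot snpIds character identifiers of the structure SNPs (row order of
#'   \code{alpha}/\code{delta}).
#' @aliases nSamples
#' @export
#' @exportClass PosteriorSampleSet
PosteriorSampleSet <- setClass("PosteriorSampleSet",
  slots = c(mu = "numeric", alpha = "matrix", delta = "matrix",
            varAlpha = "numeric", varDelta = "numeric", varE = "numeric",
            snpIds = "character"))

setValidity("PosteriorSampleSet", function(object) {
  nT <- length(object@mu)
  msg <- character()
  if (nT < 2) msg <- c(msg, "at least 2 retained samples are required")
  if (ncol(object@alpha) != nT || ncol(object@delta) != nT)
    msg <- c(msg, "alpha/delta must have one column per retained sample")
  if (length(object@varAlpha) != nT || length(object@varDelta) != nT ||
      length(object@varE) != nT)
    msg <- c(msg, "variance chains must match the retained sample count")
  if (any(c(object@varAlpha, object@varDelta, object@varE) <= 0))
    msg <- c(msg, "variance draws must be positive")
  if (nrow(object@alpha) != length(object@snpIds))
    msg <- c(msg, "snpIds must match the SNP dimension")
  if (length(msg)) msg else TRUE
})

#' @rdname PosteriorSampleSet-class
#' @param x a \code{PosteriorSampleSet}.
#' @export
setMethod("nSamples", "PosteriorSampleSet", function(x) length(x@mu))

setMethod("show", "PosteriorSampleSet", function(object) {
  cat("PosteriorSampleSet:", length(object@mu), "retained samples,",
      nrow(object@alpha), "SNPs\n")
  cat(sprintf("  posterior means: var_alpha %.4g, var_delta %.4g, var_e %.4g\n",
              mean(object@varAlpha), mean(object@varDelta), mean(object@varE)))
  invisible(NULL)
})

#' SegmentPlan: 10-Mb leave-one-segment-out tiling
#'
#' Half-open genomic intervals tiling each chromosome (default width 10 Mb)
#' plus the assignment of every variant to exactly one segment. A 1-based
#' position \eqn{p} on a chromosome belongs to segment
#' \eqn{\lfloor (p-1)/L \rfloor} of that chromosome, i.e. the tiling is
#' half-open on 0-based coordinates.
#'
#' @slot segments data.frame with columns \code{segId}, \code{chrom},
#'   \code{startBp}, \code{endBp} (half-open, 0-based start).
#' @slot assignment integer vector: segment id of every variant.
#' @slot variantIds character ids matching \code{assignment}.
#' @aliases segments segmentOf
#' @export
#' @exportClass SegmentPlan
SegmentPlan <- setClass("SegmentPlan",
  slots = c(segments = "data.frame", assignment = "integer",
            variantIds = "character"))

setValidity("SegmentPlan", function(object) {
  msg <- character()
  if (length(object@assignment) != length(object@variantIds))
    msg <- c(msg, "one assignment per variant is required")
  if (length(object@assignment) &&
      !all(object@assignment %in% object@segments$segId))
    msg <- c(msg, "every variant must map to a declared segment")
  if (length(msg)) msg else TRUE
})

#' @rdname SegmentPlan-class
#' @param x a \code{SegmentPlan}.
#' @param ... unused.
#' @export
setMethod("segments", "SegmentPlan", function(x, ...) x@segments)

#' @rdname SegmentPlan-class
#' @export
setMethod("segmentOf", "SegmentPlan", function(x, ...) x@assignment)

setMethod("show", "SegmentPlan", function(object) {
  cat("SegmentPlan:", nrow(object@segments), "segments over",
      length(unique(object@segments$chrom)), "chromosome(s);",
      length(object@assignment), "variants assigned\n")
  invisible(NULL)
})

#' LOSOPhenotypes: lazily materialised LOSO-adjusted phenotypes
#'
#' Stores the fully adjusted phenotype per posterior sample,
#' \eqn{y - 1\mu^{(t)} - M_\alpha \alpha^{(t)} - M_\delta \delta^{(t)}},
#' together with everything needed to add back the contribution of one
#' segment on demand, so the \eqn{n \times T} matrix of each of the
#' \eqn{S} segments is never stored at once. Use
#' \code{\link{adjustedPhenotypes}} to materialise one segment.
#'
#' @slot yAdjFull numeric matrix, animals x samples: fully adjusted residuals.
#' @slot samples the \linkS4class{PosteriorSampleSet} used.
#' @slot structDosage integer matrix, animals x structure SNPs.
#' @slot structSegment integer vector: segment id of each structure SNP.
#' @slot plan the \linkS4class{SegmentPlan}.
#' @slot w numeric record-count weights (carried for downstream WLS).
#' @export
#' @exportClass LOSOPhenotypes
LOSOPhenotypes <- setClass("LOSOPhenotypes",
  slots = c(yAdjFull = "matrix", samples = "PosteriorSampleSet",
            structDosage = "matrix", structSegment = "integer",
            plan = "SegmentPlan", w = "numeric"))

setValidity("LOSOPhenotypes", function(object) {
  msg <- character()
  if (ncol(object@yAdjFull) != nSamples(object@samples))
    msg <- c(msg, "yAdjFull must have one column per retained sample")
  if (nrow(object@structDosage) != nrow(object@yAdjFull))
    msg <- c(msg, "structure dosages must cover the same animals")
  if (ncol(object@structDosage) != length(object@structSegment))
    msg <- c(msg, "one segment id per structure SNP is required")
  if (length(object@w) != nrow(object@yAdjFull))
    msg <- c(msg, "one weight per animal is required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LOSOPhenotypes", function(object) {
  cat("LOSOPhenotypes:", nrow(object@yAdjFull), "animals x",
      ncol(object@yAdjFull), "posterior samples;",
      nrow(object@plan@segments), "LOSO segments\n")
  invisible(NULL)
})

#' VarianceComponents: additive + dominance GREML estimates
#'
#' Result of \code{\link{remlAD}}: REML estimates of the additive, dominance
#' and residual variances under
#' \eqn{y \sim N(1\mu,\; G_a\sigma^2_a + G_d\sigma^2_d + I\sigma^2_e)},
#' with the derived heritabilities \eqn{h^2 = \sigma^2_a/\sigma^2_p} and
#' \eqn{\delta^2 = \sigma^2_d/\sigma^2_p} and their delta-method standard
#' errors from the inverse average-information matrix.
#'
#' @slot sigma2 named numeric: \code{a}, \code{d}, \code{e}.
#' @slot se named numeric standard errors of the variance components.
#' @slot h2,delta2 heritability ratios.
#' @slot seH2,seDelta2 approximate standard errors of the ratios.
#' @slot logLik restricted log-likelihood at convergence.
#' @slot converged logical.
#' @slot trace data.frame iteration trace (logLik and components).
#' @export
#' @exportClass VarianceComponents
VarianceComponents <- setClass("VarianceComponents",
  slots = c(sigma2 = "numeric", se = "numeric", h2 = "numeric",
            delta2 = "numeric", seH2 = "numeric", seDelta2 = "numeric",
            logLik = "numeric", converged = "logical", trace = "data.frame"))

setValidity("VarianceComponents", function(object) {
  msg <- character()
  if (any(object@sigma2 < 0)) msg <- c(msg, "variances must be non-negative")
  if (object@h2 + object@delta2 > 1 + 1e-8)
    msg <- c(msg, "h2 + delta2 cannot exceed 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (REML",
      if (object@converged) "converged" else "NOT converged", ")\n")
  cat(sprintf("  sigma2_a = %.4g, sigma2_d = %.4g, sigma2_e = %.4g\n",
              object@sigma2["a"], object@sigma2["d"], object@sigma2["e"]))
  cat(sprintf("  h2 = %.4f (SE %.4f), delta2 = %.4f (SE %.4f)\n",
              object@h2, object@seH2, object@delta2, object@seDelta2))
  invisible(NULL)
})
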