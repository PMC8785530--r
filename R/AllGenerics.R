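#' @include RcppExports.R
NULL

#' @rdname GenotypeData-class
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname GenotypeData-class
#' @export
setGeneric("variantMap", function(x, ...) standardGeneric("variantMap"))

#' @rdname GenotypeData-class
#' @export
setGeneric("dr2", function(x, ...) standardGeneric("dr2"))

#' @rdname GenotypeData-class
#' @export
setGeneric("animalIds", function(x, ...) standardGeneric("animalIds"))

#' @rdname GenotypeData-class
#' @export
setGeneric("variantIds", function(x, ...) standardGeneric("variantIds"))

#' @rdname GenotypeData-class
#' @export
setGeneric("breedFractions", function(x, ...) standardGeneric("breedFractions"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname SegmentPlan-class
#' @export
setGeneric("segments", function(x, ...) standardGeneric("segments"))

#' @rdname SegmentPlan-class
#' @export
setGeneric("segmentOf", function(x, ...) standardGeneric("segmentOf"))

#' @rdname PosteriorSampleSet-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Adjusted phenotypes for one LOSO segment
#'
#' Retrieve the leave-one-segment-out adjusted phenotype matrix
#' \eqn{\tilde{y}^{(s,t)}} for segment \code{segment}: one column per retained
#' posterior sample.
#'
#' @param x a \linkS4class{LOSOPhenotypes} object.
#' @param segment integer segment identifier (a row of the plan's segment
#'   table), or \code{NA} for the fully adjusted phenotype (nothing added
#'   back).
#' @param ... unused.
#' @return numeric matrix, animals by retained samples.
#' @export
setGeneric("adjustedPhenotypes", function(x, segment, ...)
  standardGeneric("adjustedPhenotypes"))
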