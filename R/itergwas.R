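#' @include assoc.R
NULL

#' Fitted effects of conditioned variants
#'
#' Joint weighted least-squares fit of the conditioned variants to each
#' posterior sample of the fully adjusted phenotype; returns the fitted
#' contribution (without the intercept) as an animals x samples matrix to be
#' subtracted before re-scanning. With \code{coding = "class"} each variant
#' contributes its heterozygote and hom-alt indicators (genotype-class
#' conditioning, used by the dominance iteration); with \code{"dosage"} it
#' contributes its 0/1/2 dosage (additive conditioning, used by stepwise tag
#' selection). Indicator columns of empty classes are dropped silently;
#' genuinely collinear columns across conditioned variants are dropped with
#' a warning (QR pivoting).
#'
#' @param loso a \linkS4class{LOSOPhenotypes}.
#' @param geno a \linkS4class{GenotypeData}.
#' @param variants integer indices of the conditioned variants.
#' @param coding \code{"class"} or \code{"dosage"}.
#' @return animals x samples numeric matrix of fitted effects.
#' @export
conditionClassEffects <- function(loso, geno, variants,
                                  coding = c("class", "dosage")) {
  coding <- match.arg(coding)
  stopifnot(length(variants) >= 1)
  m <- dosages(geno)[, variants, drop = FALSE]
  if (anyNA(m)) stop("conditioned variants must be genotyped in all animals")
  X <- if (coding == "class") {
    do.call(cbind, lapply(seq_along(variants), function(k)
      cbind(het = (m[, k] == 1L) * 1.0, hom = (m[, k] == 2L) * 1.0)))
  } else {
    storage.mode(m) <- "double"
    m
  }
  X <- X[, colSums(X != 0) > 0, drop = FALSE]   # empty classes carry nothing
  Y <- adjustedPhenotypes(loso, NA)
  w <- loso@w
  Xf <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xf * sqrt(w))
  if (qrx$rank < ncol(Xf))
    warning("collinear columns among conditioned variants; ",
            ncol(Xf) - qrx$rank, " dropped by pivoting")
  coef <- qr.coef(qrx, Y * sqrt(w))
  coef[is.na(coef)] <- 0
  X %*% coef[-1, , drop = FALSE]
}

#' Iterative conditional dominance scan of one chromosome
#'
#' Repeatedly scans the chromosome, calls the most significant dominance
#' variant passing the FDR and effect-size thresholds (or the next
#' user-supplied candidate), conditions the phenotypes on the genotype-class
#' effects of all variants conditioned so far, and re-scans, until no
#' significant QTL remains or \code{maxRounds} is reached. Used to separate
#' co-locating QTL whose tag variants are in linkage equilibrium.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param loso a \linkS4class{LOSOPhenotypes}.
#' @param chrom chromosome to scan.
#' @param phenotypicSd phenotypic SD of the trait (for the effect filter).
#' @param fdr,effectFrac calling thresholds, see
#'   \code{\link{callAndClassify}}.
#' @param candidates optional integer vector of candidate causal variants:
#'   conditioning then follows this order instead of the top-variant rule.
#' @param maxRounds safety bound on the number of iterations.
#' @param seed integer seed for the scan draws.
#' @return list: \code{calls} (one row per conditioned QTL with its
#'   iteration index and association summaries), \code{log} (per-round
#'   bookkeeping), \code{final} (last scan's results).
#' @export
iterateChromosome <- function(geno, loso, chrom, phenotypicSd, fdr = 1e-3,
                              effectFrac = 0.05, candidates = NULL,
                              maxRounds = 10, seed = 1L) {
  map <- variantMap(geno)
  mc <- S4Vectors::mcols(map)
  onChrom <- which(as.character(GenomicRanges::seqnames(map)) == chrom)
  if ("isStructure" %in% colnames(mc))
    onChrom <- setdiff(onChrom, which(mc$isStructure))
  if (!length(onChrom)) stop("no test variants on chromosome ", chrom)
  conditioned <- integer(0)
  calls <- list()
  logRows <- list()
  extra <- NULL
  res <- NULL
  for (round in seq_len(maxRounds)) {
    res <- scanAssociation(geno, loso, variants = onChrom,
                           extraAdjust = extra,
                           seed = seed + round - 1L)
    res <- callAndClassify(res, phenotypicSd, fdr = fdr,
                           effectFrac = effectFrac)
    sig <- res[res$called & !res$variant %in% conditioned, , drop = FALSE]
    logRows[[round]] <- data.frame(round = round,
                                   nSignificant = sum(res$called,
                                                      na.rm = TRUE),
                                   nNewSignificant = nrow(sig))
    pickFromCandidates <- !is.null(candidates) &&
      length(conditioned) < length(candidates)
    if (!pickFromCandidates && nrow(sig) == 0) break
    top <- if (pickFromCandidates) {
      candidates[length(conditioned) + 1L]
    } else sig$variant[which.min(sig$dP)]
    if (top %in% conditioned)
      stop("oscillation detected: variant ", top, " re-entered the model")
    conditioned <- c(conditioned, top)
    row <- res[res$variant == top, , drop = FALSE]
    row$iteration <- round
    calls[[round]] <- row
    extra <- conditionClassEffects(loso, geno, conditioned)
  }
  list(calls = if (length(calls)) do.call(rbind, calls) else NULL,
       log = do.call(rbind, logRows), final = res,
       conditioned = conditioned)
}

#' Stepwise selection of additive tag variants
#'
#' Greedy forward selection on the standard-additive (dosage-slope) signal:
#' each round re-scans all candidates with the dosages of the selected tags
#' conditioned out of every posterior sample, computes Storey q-values of
#' the chain-based standard-additive p-values, and adds the most significant
#' candidate until none passes the FDR threshold. Using the per-sample
#' chains keeps the between-sample adjustment uncertainty in the test, so
#' ancestry-proxy variants are not over-called. Candidates nearly collinear
#' with a selected tag (dosage \eqn{R^2 >} \code{collinearR2}) are skipped.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param loso a \linkS4class{LOSOPhenotypes}.
#' @param variants candidate variant indices (default: all non-structure).
#' @param fdr q-value threshold for adding a tag.
#' @param collinearR2 collinearity guard.
#' @param maxTags safety bound.
#' @param seed integer seed for the scan draws.
#' @return list: \code{tags} (selected variant indices in selection order),
#'   \code{trace} (per-round data.frame of the best candidate and its q).
#' @export
stepwiseAdditiveTags <- function(geno, loso, variants = NULL, fdr = 1e-3,
                                 collinearR2 = 0.99, maxTags = 50,
                                 seed = 1L) {
  map <- variantMap(geno)
  mc <- S4Vectors::mcols(map)
  if (is.null(variants)) {
    variants <- if ("isStructure" %in% colnames(mc))
      which(!mc$isStructure) else seq_len(nVariants(geno))
  }
  tags <- integer(0)
  trace <- list()
  extra <- NULL
  for (round in seq_len(maxTags)) {
    res <- scanAssociation(geno, loso, variants = variants,
                           extraAdjust = extra, seed = seed + round - 1L)
    p <- res$alphaP
    p[res$variant %in% tags] <- NA
    if (length(tags)) {
      skip <- vapply(res$variant, function(v) {
        if (v %in% tags) return(FALSE)
        any(vapply(tags, function(t) {
          r <- suppressWarnings(stats::cor(dosages(geno)[, v],
                                           dosages(geno)[, t]))
          !is.na(r) && r^2 > collinearR2
        }, logical(1)))
      }, logical(1))
      p[skip] <- NA
    }
    q <- suppressWarnings(qvalues(p)$q)
    best <- which.min(q)
    if (!length(best) || is.na(q[best]) || q[best] >= fdr) break
    tags <- c(tags, res$variant[best])
    trace[[round]] <- data.frame(round = round, variant = res$variant[best],
                                 z = res$alphaZ[best], q = q[best])
    extra <- conditionClassEffects(loso, geno, tags, coding = "dosage")
  }
  list(tags = tags,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}
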