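#' @include AllClasses.R
NULL

#' Read genotypes from VCF or dosage TSV
#'
#' VCF input (via \pkg{vcfR}) uses the \code{DS} FORMAT field when present
#' (configurable), otherwise hard \code{GT} calls; fractional dosages are
#' rounded to the nearest hard call for analysis, with the fractional values
#' retained for output. The per-variant imputation quality is taken from the
#' \code{DR2} INFO key (1 when absent). The TSV dialect is a rectangular
#' dosage matrix: header row of variant ids \code{chrom:pos:ref:alt}, one
#' animal per line with its id in the first column.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"vcf"} or \code{"tsv"}.
#' @param preferDS use DS over GT when both are present (default TRUE).
#' @return a \linkS4class{GenotypeData}; fractional dosages, when read, are
#'   attached as metadata column \code{ds} is not used — they are stored in
#'   the object's metadata environment via \code{attr(, "fractional")}.
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv"),
                          preferDS = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") readGenotypesVcf(path, preferDS) else
    readGenotypesTsv(path)
}

readGenotypesVcf <- function(path, preferDS = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic records are not supported: line(s) ",
         paste(which(grepl(",", fix[, "ALT"], fixed = TRUE)), collapse = ", "))
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos))
    stop("malformed record: non-numeric POS at record ",
         paste(which(is.na(pos)), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  hard <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  hard[clean %in% c("0/0", "0")] <- 0L
  hard[clean %in% c("0/1", "1/0")] <- 1L
  hard[clean %in% c("1/1", "1")] <- 2L
  frac <- NULL
  fmt <- unique(unlist(v@gt[, 1]))
  if (preferDS && any(grepl("DS", fmt))) {
    ds <- suppressWarnings(
      vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
    if (!all(is.na(ds))) {
      frac <- ds
      hardDs <- round(ds)
      keep <- !is.na(hardDs)
      hard[keep] <- as.integer(pmin(2, pmax(0, hardDs[keep])))
    }
  }
  dr2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DR2")))
  dr2[is.na(dr2)] <- 1
  dos <- t(hard)  # vcfR is variants x samples
  rownames(dos) <- colnames(gt)
  gd <- GenotypeData(dos, chrom = fix[, "CHROM"], pos = pos,
                     ref = fix[, "REF"], alt = fix[, "ALT"], dr2 = dr2)
  if (!is.null(frac)) attr(gd, "fractional") <- t(frac)
  gd
}

readGenotypesTsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  parts <- strsplit(colnames(m), ":", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad))
    stop("malformed variant id in header column ", bad[1] + 1,
         " (expected chrom:pos:ref:alt)")
  GenotypeData(m, chrom = vapply(parts, `[`, "", 1),
               pos = as.integer(vapply(parts, `[`, "", 2)),
               ref = vapply(parts, `[`, "", 3),
               alt = vapply(parts, `[`, "", 4))
}

#' Write genotypes
#'
#' \code{writeGenotypesTsv} writes the rectangular dosage dialect read by
#' \code{\link{readGenotypes}}. \code{writeGenotypesVcf} writes a VCF 4.2
#' file with \code{GT} and \code{DS} per sample and \code{DR2} as an INFO
#' field (gzip-compressed when the path ends in \code{.gz}, via \pkg{vcfR}).
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param path output path (VCF paths are given a \code{.gz} suffix by
#'   \pkg{vcfR} when not already present).
#' @return the path written, invisibly.
#' @export
writeGenotypesTsv <- function(geno, path) {
  m <- dosages(geno)
  dt <- data.table::data.table(animalId = animalIds(geno))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::setnames(dt, c("animalId", variantIds(geno)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname writeGenotypesTsv
#' @export
writeGenotypesVcf <- function(geno, path) {
  m <- dosages(geno)
  map <- variantMap(geno)
  mc <- S4Vectors::mcols(map)
  gtStr <- c("0/0", "0/1", "1/1")
  gt <- matrix(".", ncol(m), nrow(m))
  ok <- !is.na(t(m))
  gt[ok] <- paste0(gtStr[t(m)[ok] + 1L], ":", t(m)[ok])
  gt[!ok] <- "./.:."
  colnames(gt) <- animalIds(geno)
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"Imputation dosage R-squared\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">",
            paste0("##contig=<ID=",
                   unique(as.character(GenomicRanges::seqnames(map))), ">"))
  fix <- cbind(CHROM = as.character(GenomicRanges::seqnames(map)),
               POS = as.character(GenomicRanges::start(map)),
               ID = variantIds(geno), REF = mc$ref, ALT = mc$alt,
               QUAL = ".", FILTER = "PASS",
               INFO = sprintf("DR2=%.4g", mc$dr2))
  obj <- new("vcfR", meta = meta, fix = fix,
             gt = cbind(FORMAT = "GT:DS", gt))
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Per-variant summary statistics
#'
#' Frequencies are computed over non-missing calls. The Hardy-Weinberg
#' deviation is the absolute difference between the observed heterozygote
#' frequency and its expectation \eqn{2pq}; when breed strata are supplied
#' it is computed within each stratum and the maximum over strata is
#' reported ("calculated within breed").
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param strata optional factor of breed labels (one per animal).
#' @return data.frame with one row per variant: \code{maf}, \code{callRate},
#'   \code{hetFreq}, \code{homAltCount}, \code{hweDev}, \code{dr2},
#'   \code{allMissing}.
#' @export
variantStats <- function(geno, strata = NULL) {
  m <- dosages(geno)
  n <- nrow(m)
  nonMiss <- n - colSums(is.na(m))
  altFreq <- colMeans(m, na.rm = TRUE) / 2
  hetFreq <- colMeans(m == 1L, na.rm = TRUE)
  homAlt <- colSums(m == 2L, na.rm = TRUE)
  hweDevStratum <- function(idx) {
    p <- colMeans(m[idx, , drop = FALSE], na.rm = TRUE) / 2
    h <- colMeans(m[idx, , drop = FALSE] == 1L, na.rm = TRUE)
    abs(h - 2 * p * (1 - p))
  }
  hwe <- if (is.null(strata)) {
    abs(hetFreq - 2 * altFreq * (1 - altFreq))
  } else {
    strata <- as.factor(strata)
    do.call(pmax, c(lapply(levels(strata), function(l)
      hweDevStratum(which(strata == l))), na.rm = TRUE))
  }
  data.frame(variant = variantIds(geno),
             maf = pmin(altFreq, 1 - altFreq),
             callRate = nonMiss / n,
             hetFreq = hetFreq,
             homAltCount = as.integer(homAlt),
             hweDev = hwe,
             dr2 = dr2(geno),
             allMissing = nonMiss == 0L,
             stringsAsFactors = FALSE)
}

#' Expected rare-homozygote count under Hardy-Weinberg
#'
#' With \eqn{p^2 + 2pq + q^2 = 1}, the expected number of minor-allele
#' homozygotes among \eqn{n} individuals is \eqn{q^2 n}; it shrinks
#' quadratically as the allele frequency drops, which is why recessive
#' mapping needs very large samples.
#'
#' @param maf minor allele frequency in [0, 0.5].
#' @param n number of individuals.
#' @return expected homozygote count \eqn{q^2 n}.
#' @examples
#' expectedHomCount(0.01, 10000)   # a single expected homozygote
#' @export
expectedHomCount <- function(maf, n) {
  stopifnot(all(maf >= 0), all(maf <= 0.5))
  maf^2 * n
}

#' Pairwise LD (squared allelic correlation) within a window
#'
#' \eqn{R^2} is the squared Pearson correlation of dosage vectors over the
#' animals non-missing at both variants. Pairs containing a zero-variance
#' variant are skipped.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param windowBp only pairs within this many bp on the same chromosome.
#' @return data.frame: \code{i}, \code{j} (variant column indices),
#'   \code{r2}.
#' @export
ldR2 <- function(geno, windowBp = 1e6) {
  stopifnot(windowBp > 0)
  m <- dosages(geno)
  map <- variantMap(geno)
  ch <- as.character(GenomicRanges::seqnames(map))
  pos <- GenomicRanges::start(map)
  out <- vector("list", ncol(m))
  for (i in seq_len(ncol(m))) {
    j <- which(ch == ch[i] & pos > pos[i] & pos - pos[i] <= windowBp)
    if (!length(j)) next
    r2 <- vapply(j, function(jj) {
      ok <- !is.na(m[, i]) & !is.na(m[, jj])
      xi <- m[ok, i]; xj <- m[ok, jj]
      if (stats::var(xi) == 0 || stats::var(xj) == 0) return(NA_real_)
      stats::cor(xi, xj)^2
    }, numeric(1))
    out[[i]] <- data.frame(i = i, j = j, r2 = r2)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(i = integer(), j = integer(),
                                      r2 = numeric())
  res[!is.na(res$r2), , drop = FALSE]
}

#' Structure-adjustment panel filter cascade
#'
#' Removes variants with call rate below \code{1 - maxMissing}, folded MAF
#' below \code{minMaf}, within-stratum Hardy-Weinberg heterozygote-frequency
#' deviation above \code{maxHweDev}, or DR2 below \code{minDr2}; the
#' survivors are then greedily LD-pruned left-to-right: of any pair within
#' \code{pruneWindowBp} with \eqn{R^2} above \code{pruneR2}, the lower-MAF
#' member is dropped. Thresholds are strict inequalities as stated
#' (missing > 0.01, MAF < 0.02, HWE deviation > 0.15, DR2 < 0.9,
#' R2 > 0.9). Each removed variant carries exactly one first-failure reason.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param strata optional breed labels for the within-breed HWE deviation.
#' @param maxMissing,minMaf,maxHweDev,minDr2,pruneR2,pruneWindowBp thresholds;
#'   set \code{pruneR2 = NULL} to disable pruning.
#' @return list: \code{keep} (integer variant indices retained) and
#'   \code{report} (per-variant data.frame with stats and
#'   \code{firstFailure}, \code{NA} for retained variants).
#' @export
structurePanelFilter <- function(geno, strata = NULL, maxMissing = 0.01,
                                 minMaf = 0.02, maxHweDev = 0.15,
                                 minDr2 = 0.9, pruneR2 = 0.9,
                                 pruneWindowBp = 1e6) {
  st <- variantStats(geno, strata)
  fail <- rep(NA_character_, nrow(st))
  fail[is.na(fail) & (1 - st$callRate) > maxMissing] <- "missing_rate"
  fail[is.na(fail) & st$maf < minMaf] <- "low_maf"
  fail[is.na(fail) & st$hweDev > maxHweDev] <- "hwe_deviation"
  fail[is.na(fail) & st$dr2 < minDr2] <- "low_dr2"
  keep <- which(is.na(fail))
  if (!is.null(pruneR2) && length(keep) > 1) {
    sub <- geno[, keep]
    ld <- ldR2(sub, pruneWindowBp)
    ld <- ld[ld$r2 > pruneR2, , drop = FALSE]
    drop <- logical(length(keep))
    if (nrow(ld)) {
      mafs <- st$maf[keep]
      for (r in seq_len(nrow(ld))) {
        i <- ld$i[r]; j <- ld$j[r]
        if (drop[i] || drop[j]) next
        # keep the higher-MAF member; position order breaks ties
        if (mafs[j] > mafs[i]) drop[i] <- TRUE else drop[j] <- TRUE
      }
    }
    fail[keep[drop]] <- "ld_prune"
    keep <- keep[!drop]
  }
  if (!length(keep)) stop("no variants survive the structure-panel filter")
  st$firstFailure <- fail
  list(keep = keep, report = st)
}

#' Imputed-sequence panel filter
#'
#' Removes very rare variants (homozygous-alternate count \eqn{\le}
#' \code{maxHomAlt}) and poorly imputed variants (DR2 strictly below
#' \code{minDr2}).
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param maxHomAlt variants with \code{homAltCount <= maxHomAlt} are removed.
#' @param minDr2 variants with \code{dr2 < minDr2} are removed.
#' @return list: \code{keep} indices and \code{report} as in
#'   \code{\link{structurePanelFilter}}.
#' @export
sequencePanelFilter <- function(geno, maxHomAlt = 5, minDr2 = 0.7) {
  st <- variantStats(geno)
  fail <- rep(NA_character_, nrow(st))
  fail[is.na(fail) & st$homAltCount <= maxHomAlt] <- "rare_hom_alt"
  fail[is.na(fail) & st$dr2 < minDr2] <- "low_dr2"
  keep <- which(is.na(fail))
  if (!length(keep)) stop("no variants survive the sequence-panel filter")
  st$firstFailure <- fail
  list(keep = keep, report = st)
}
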