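#' @include utils.R
NULL

#' Configuration of the synthetic mixed-breed population
#'
#' Collects and validates every knob of the genotype simulator. The simulated
#' population mirrors the structure the downstream analysis assumes: two
#' ancestral breed pools (A and B, emulating Holstein-Friesian and Jersey)
#' plus crossbreds, a medium-density structure-adjustment SNP panel and a
#' dense panel of imputed-sequence-like test variants, linkage disequilibrium
#' generated by haplotype copying from a finite founder panel, and per-variant
#' imputation quality (DR2) drawn independently of the genotypes.
#'
#' @param nAnimals number of diploid animals.
#' @param breedMix proportions of pure-A, pure-B and crossbred animals;
#'   must sum to 1.
#' @param nStructureSnps size of the structure-adjustment panel.
#' @param nDenseVariants number of dense test variants.
#' @param nChromosomes,chromLengthBp genome layout (equal-length chromosomes).
#' @param recombRate per-bp crossover probability per meiosis used by the
#'   gamete copier (cattle-like default 1e-8, i.e. 1 cM/Mb).
#' @param founderHaps founder haplotypes per breed pool. Smaller panels give
#'   stronger drift and more rare-variant structure.
#' @param ldDepth per-site probability that the haplotype copier redraws the
#'   allele from the base frequency instead of copying its template; smaller
#'   values give deeper shared ancestry and stronger LD.
#' @param panelSwitchRate per-bp template-switch rate when building founder
#'   haplotypes; controls how fast LD decays with distance.
#' @param divergence Balding-Nichols F(ST)-like divergence of the two breed
#'   pools' allele frequencies (0 = identical pools).
#' @param crossFractions possible pool-A ancestry fractions of crossbred
#'   animals, sampled with \code{crossWeights}.
#' @param crossWeights sampling weights for \code{crossFractions}.
#' @param fracDr2Below07,fracDr2Below09 fractions of variants whose simulated
#'   DR2 falls below 0.7 and below 0.9 (the two filter thresholds used
#'   downstream); \code{fracDr2Below07 <= fracDr2Below09}.
#' @param seed integer seed making the whole dataset reproducible.
#' @return a validated list of class \code{PopulationConfig}.
#' @examples
#' cfg <- populationConfig(nAnimals = 200, nStructureSnps = 50,
#'                         nDenseVariants = 200, seed = 1)
#' @export
populationConfig <- function(nAnimals = 2000,
                             breedMix = c(pureA = 0.25, pureB = 0.25, cross = 0.5),
                             nStructureSnps = 1000,
                             nDenseVariants = 5000,
                             nChromosomes = 2,
                             chromLengthBp = 5e7,
                             recombRate = 1e-8,
                             founderHaps = 100,
                             ldDepth = 0.08,
                             panelSwitchRate = 2e-6,
                             divergence = 0.05,
                             crossFractions = c(0.25, 0.5, 0.75),
                             crossWeights = c(0.25, 0.5, 0.25),
                             fracDr2Below07 = 0.03,
                             fracDr2Below09 = 0.10,
                             seed = 1L) {
  stopifnot(nAnimals > 0, nStructureSnps > 0, nDenseVariants > 0,
            nChromosomes > 0, chromLengthBp > 0, founderHaps >= 2,
            recombRate >= 0, divergence >= 0, divergence < 1,
            fracDr2Below07 <= fracDr2Below09, fracDr2Below09 <= 1)
  if (abs(sum(breedMix) - 1) > 1e-12)
    stop("breedMix proportions must sum to 1")
  if (chromLengthBp < 2e7)
    stop("chromLengthBp must be at least two LOSO segment widths (20 Mb)")
  nV <- nStructureSnps + nDenseVariants
  if (nV > nChromosomes * chromLengthBp)
    stop("more variants requested than positions available on the map")
  cfg <- list(nAnimals = as.integer(nAnimals), breedMix = breedMix,
              nStructureSnps = as.integer(nStructureSnps),
              nDenseVariants = as.integer(nDenseVariants),
              nChromosomes = as.integer(nChromosomes),
              chromLengthBp = chromLengthBp, recombRate = recombRate,
              founderHaps = as.integer(founderHaps), ldDepth = ldDepth,
              panelSwitchRate = panelSwitchRate, divergence = divergence,
              crossFractions = crossFractions, crossWeights = crossWeights,
              fracDr2Below07 = fracDr2Below07, fracDr2Below09 = fracDr2Below09,
              seed = as.integer(seed))
  class(cfg) <- "PopulationConfig"
  cfg
}

#' Specification of a planted QTL
#'
#' Describes one biallelic causal variant to plant into the simulated
#' genotypes: its position, target minor allele frequency, and genotypic
#' additive and dominance effects in trait units, with class deviations
#' (hom-ref, het, hom-alt) = (-a, d, +a) about the homozygote midpoint.
#' A fully recessive minor-allele deficit of \eqn{D} trait units is
#' \code{aTrue = -D, dTrue = +D} (k = 1).
#'
#' @param chrom,pos chromosome and 1-based position (snapped to the nearest
#'   simulated dense variant when no variant exists there).
#' @param mafTarget target minor allele frequency in (0, 0.5].
#' @param aTrue,dTrue genotypic additive and dominance effects (trait units).
#' @param breedRestricted optionally \code{"A"} or \code{"B"}: the minor
#'   allele then segregates only in that breed pool.
#' @return a list of class \code{QTLSpec}.
#' @export
qtlSpec <- function(chrom, pos, mafTarget, aTrue, dTrue, breedRestricted = NA) {
  stopifnot(mafTarget > 0, mafTarget <= 0.5)
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 mafTarget = mafTarget, aTrue = aTrue, dTrue = dTrue,
                 breedRestricted = breedRestricted),
            class = "QTLSpec")
}

#' Simulate founder haplotype pools for the two breeds
#'
#' Builds the variant map (structure panel interleaved with dense variants)
#' and one founder haplotype panel per breed pool. Pool allele frequencies
#' diverge by a Balding-Nichols perturbation of shared base frequencies;
#' within-pool LD arises from sequential copy-with-switch haplotype
#' construction. Variants named in \code{qtl} get their founder allele counts
#' fixed exactly to the target frequency so the realised population MAF is
#' binomial around the target.
#'
#' @param config a \code{\link{populationConfig}}.
#' @param qtl optional list of \code{\link{qtlSpec}} objects.
#' @return list of class \code{HaplotypePools}: integer 0/1 matrices
#'   \code{A}, \code{B} (variants x founder haplotypes), the \code{map}
#'   data.frame (\code{chrom}, \code{pos}, \code{isStructure},
#'   \code{isPlanted}), base and pool frequencies, and the config.
#' @export
simulateHaplotypePools <- function(config, qtl = NULL) {
  stopifnot(inherits(config, "PopulationConfig"))
  set.seed(stageSeed(config$seed, "haplotypes"))
  nV <- config$nStructureSnps + config$nDenseVariants
  perChrom <- diff(round(seq(0, nV, length.out = config$nChromosomes + 1)))
  map <- do.call(rbind, lapply(seq_len(config$nChromosomes), function(c) {
    pos <- sort(sample.int(config$chromLengthBp, perChrom[c]))
    data.frame(chrom = as.character(c), pos = pos)
  }))
  # spread the structure panel evenly across the map, chip-like
  sidx <- round(seq(1, nV, length.out = config$nStructureSnps))
  map$isStructure <- seq_len(nV) %in% sidx
  map$isPlanted <- FALSE

  # base frequencies: chip-like common alleles for the structure panel,
  # rare-skewed spectrum for dense sequence-like variants
  base <- numeric(nV)
  base[map$isStructure] <- 0.05 + 0.45 * stats::rbeta(config$nStructureSnps, 1.2, 1.2)
  base[!map$isStructure] <- pmin(0.999, pmax(0.001,
    0.5 * stats::rbeta(config$nDenseVariants, 0.45, 1.4)))
  poolFreq <- function(q) {
    if (config$divergence == 0) return(q)
    Fst <- config$divergence
    a <- q * (1 - Fst) / Fst
    b <- (1 - q) * (1 - Fst) / Fst
    pmin(0.999, pmax(0.001, stats::rbeta(length(q), a, b)))
  }
  qA <- poolFreq(base)
  qB <- poolFreq(base)

  planted <- integer(0)
  if (length(qtl)) {
    shareA <- config$breedMix[1] +
      sum(config$crossFractions * config$crossWeights) * config$breedMix[3]
    for (s in qtl) {
      stopifnot(inherits(s, "QTLSpec"))
      cand <- which(map$chrom == s$chrom & !map$isStructure)
      if (!length(cand)) stop("QTL chromosome not on the simulated map")
      v <- cand[which.min(abs(map$pos[cand] - s$pos))]
      F <- config$founderHaps
      if (is.na(s$breedRestricted)) {
        qA[v] <- qB[v] <- round(s$mafTarget * F) / F
      } else if (s$breedRestricted == "A") {
        qA[v] <- round(s$mafTarget / shareA * F) / F; qB[v] <- 0
      } else {
        qB[v] <- round(s$mafTarget / (1 - shareA) * F) / F; qA[v] <- 0
      }
      map$isPlanted[v] <- TRUE
      planted <- c(planted, v)
    }
  }
  gap <- c(0, pmax(0, diff(map$pos)))
  gap[c(0, which(diff(as.integer(factor(map$chrom, levels = unique(map$chrom)))) != 0)) + 1] <- NA
  gapSwitch <- 1 - exp(-config$panelSwitchRate * gap[-1])
  gapSwitch[is.na(gapSwitch)] <- 1  # new chromosome: independent template
  A <- cpp_sim_pool(qA, config$founderHaps, gapSwitch, config$ldDepth)
  B <- cpp_sim_pool(qB, config$founderHaps, gapSwitch, config$ldDepth)
  # planted variants: exact founder carrier counts, random carriers
  for (v in planted) {
    for (pool in c("A", "B")) {
      q <- if (pool == "A") qA[v] else qB[v]
      k <- round(q * config$founderHaps)
      col <- integer(config$founderHaps)
      if (k > 0) col[sample.int(config$founderHaps, k)] <- 1L
      if (pool == "A") A[v, ] <- col else B[v, ] <- col
    }
  }
  structure(list(A = A, B = B, map = map, baseFreq = base,
                 poolFreqA = qA, poolFreqB = qB, config = config),
            class = "HaplotypePools")
}

#' Simulate crossbred dosage genotypes from founder pools
#'
#' Each animal is assigned a breed class by \code{breedMix}; pure animals
#' draw both gametes from their pool, crossbreds draw each gamete from pool A
#' with their ancestry fraction as probability. Gametes are founder mosaics
#' with crossovers at \code{recombRate}. Per-variant DR2 values are simulated
#' independently of the genotypes with the configured fractions below 0.7
#' and 0.9.
#'
#' @param pools a \code{HaplotypePools} object.
#' @param config the same \code{\link{populationConfig}} (defaults to the one
#'   stored in \code{pools}).
#' @return a \linkS4class{GenotypeData} with \code{breedFracA} in its animal
#'   metadata and \code{isStructure}/\code{isPlanted} flags on the variant map.
#' @export
simulateCrossbredGenotypes <- function(pools, config = pools$config) {
  stopifnot(inherits(pools, "HaplotypePools"))
  set.seed(stageSeed(config$seed, "genotypes"))
  n <- config$nAnimals
  cls <- sample(c("A", "B", "X"), n, replace = TRUE, prob = config$breedMix)
  probA <- ifelse(cls == "A", 1, ifelse(cls == "B", 0,
    sample(config$crossFractions, n, replace = TRUE, prob = config$crossWeights)))
  map <- pools$map
  chromStart <- c(0L, cumsum(rle(map$chrom)$lengths))
  chromStart <- chromStart[-length(chromStart)]
  G <- cpp_sim_genotypes(pools$A, pools$B, probA, as.numeric(map$pos),
                         as.integer(chromStart), config$recombRate)
  # refcount is 1 here: attach names in place, sparing a 4-byte-per-cell copy
  rownames(G) <- sprintf("animal%05d", seq_len(n))
  nV <- ncol(G)
  u <- stats::runif(nV)
  dr2 <- ifelse(u < config$fracDr2Below07, stats::runif(nV, 0.2, 0.7),
         ifelse(u < config$fracDr2Below09, stats::runif(nV, 0.7, 0.9),
                stats::runif(nV, 0.9, 1.0)))
  gd <- GenotypeData(G, chrom = map$chrom, pos = map$pos, dr2 = dr2,
                     animalData = S4Vectors::DataFrame(
                       breedFracA = probA, breedClass = cls))
  S4Vectors::mcols(gd@map)$isStructure <- map$isStructure
  S4Vectors::mcols(gd@map)$isPlanted <- map$isPlanted
  gd
}

#' Plant QTL effects and return the genetic-value vector
#'
#' The genetic value of animal \eqn{i} is
#' \eqn{g_i = \sum_l a_l (x_{il} - 1) + d_l 1\{x_{il} = 1\}}, i.e. genotype
#' class deviations (hom-ref, het, hom-alt) = (-a, d, +a) about the class
#' midpoint. Specs pointing at a monomorphic simulated variant contribute 0
#' with a warning.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param specs list of \code{\link{qtlSpec}} objects.
#' @return list with \code{g} (numeric genetic values) and \code{truth}
#'   (data.frame: variant index, realised MAF, a, d, k, class means).
#' @export
plantQTL <- function(geno, specs) {
  if (inherits(specs, "QTLSpec")) specs <- list(specs)
  n <- nAnimals(geno)
  g <- numeric(n)
  map <- variantMap(geno)
  ch <- as.character(GenomicRanges::seqnames(map))
  pos <- GenomicRanges::start(map)
  mc <- S4Vectors::mcols(map)
  dense <- if ("isStructure" %in% colnames(mc)) !mc$isStructure
           else rep(TRUE, length(pos))
  rows <- lapply(specs, function(s) {
    cand <- which(ch == s$chrom & dense)
    if (!length(cand)) stop("QTL chromosome not present in genotype map")
    v <- cand[which.min(abs(pos[cand] - s$pos))]
    x <- dosages(geno)[, v]
    p <- mean(x, na.rm = TRUE) / 2
    if (p <= 0 || p >= 1) {
      warning("planted QTL variant is monomorphic; contributes 0")
      return(data.frame(variant = v, chrom = s$chrom, pos = pos[v],
                        maf = min(p, 1 - p), a = s$aTrue, d = s$dTrue,
                        k = dominanceCoefficient(s$aTrue, s$dTrue),
                        mu0 = 0, mu1 = 0, mu2 = 0, monomorphic = TRUE))
    }
    dev <- c(-s$aTrue, s$dTrue, s$aTrue)
    xi <- x; xi[is.na(xi)] <- round(2 * p)
    g <<- g + dev[xi + 1L]
    data.frame(variant = v, chrom = s$chrom, pos = pos[v],
               maf = min(p, 1 - p), a = s$aTrue, d = s$dTrue,
               k = dominanceCoefficient(s$aTrue, s$dTrue),
               mu0 = dev[1], mu1 = dev[2], mu2 = dev[3], monomorphic = FALSE)
  })
  list(g = g, truth = do.call(rbind, rows))
}

#' Simulate weighted yield-deviation phenotypes
#'
#' Phenotypes emulate pre-adjusted first-lactation yield deviations:
#' \eqn{y_i = g_i + u_i + v_i + \bar e_i}, where the additive polygenic value
#' \eqn{u_i} and the dominance polygenic value \eqn{v_i} are built from the
#' structure SNPs (dosage and heterozygosity codes with i.i.d. normal
#' effects), and \eqn{\bar e_i} is the mean of \eqn{w_i} independent
#' test-day residuals so that \eqn{Var(\bar e_i) = \sigma^2_e / w_i}. Record
#' counts are shifted Poisson (minimum 1). Components are orthogonalised
#' against each other and exactly rescaled, so the realised variance
#' fractions match the targets and, for constant \eqn{w}, the component
#' variances add exactly to the phenotypic variance.
#'
#' @param geno a \linkS4class{GenotypeData} (its structure-panel variants are
#'   used for the polygenic values; all variants are used if the map carries
#'   no \code{isStructure} flag).
#' @param g genetic values from \code{\link{plantQTL}} (default all zero).
#' @param h2,delta2 target additive and dominance polygenic variance
#'   fractions.
#' @param phenVar target total phenotypic variance (trait units squared),
#'   excluding the planted-QTL variance.
#' @param wLambda Poisson rate of the shifted record-count distribution
#'   (mean records per animal = 1 + wLambda).
#' @param w optional explicit record counts (positive integers, length n).
#' @param seed integer seed.
#' @return data.frame of class \code{PhenotypeTable}: \code{animalId},
#'   \code{y}, \code{w}, \code{breedFracA}; simulated components are attached
#'   as attribute \code{"components"} and \eqn{\sigma^2_e} as
#'   \code{"sigmaE2"}.
#' @export
simulateYieldDeviations <- function(geno, g = NULL, h2 = 0.296,
                                    delta2 = 0.044, phenVar = 1,
                                    wLambda = 8, w = NULL, seed = 1L) {
  stopifnot(h2 >= 0, delta2 >= 0, h2 + delta2 <= 1, phenVar >= 0)
  set.seed(stageSeed(seed, "phenotypes"))
  n <- nAnimals(geno)
  if (is.null(g)) g <- numeric(n)
  if (is.null(w)) w <- 1L + stats::rpois(n, wLambda)
  if (any(w < 1)) stop("record counts w must be >= 1")
  mc <- S4Vectors::mcols(variantMap(geno))
  sidx <- if ("isStructure" %in% colnames(mc)) which(mc$isStructure)
          else seq_len(nVariants(geno))
  M <- dosages(geno)[, sidx, drop = FALSE]
  M[is.na(M)] <- 1L
  storage.mode(M) <- "double"
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  # standardised additive codes and raw orthogonal dominance class codes:
  # i.i.d. effects on these columns make Var(u) proportional to the additive
  # GRM and Var(v) proportional to the dominance GRM, exactly the
  # architecture GREMLd models
  Za <- sweep(sweep(M, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  u <- as.numeric(Za %*% stats::rnorm(ncol(Za)))
  rm(Za)                                    # keep the peak to one Z matrix
  Zd <- matrix(0, nrow(M), ncol(M))
  cls <- col(M)
  Zd[M == 0] <- (-2 * p^2)[cls[M == 0]]
  Zd[M == 1] <- (2 * p * (1 - p))[cls[M == 1]]
  Zd[M == 2] <- (-2 * (1 - p)^2)[cls[M == 2]]
  v <- as.numeric(Zd %*% stats::rnorm(ncol(Zd)))
  rm(Zd, cls, M)
  gc(FALSE)
  u <- rescaleVar(projectOut(u, cbind(g)), h2 * phenVar)
  v <- rescaleVar(projectOut(v, cbind(g, u)), delta2 * phenVar)
  residVar <- (1 - h2 - delta2) * phenVar      # mean residual variance
  sigmaE2 <- residVar / mean(1 / w)
  if (sigmaE2 > 0) {
    e <- stats::rnorm(n, 0, sqrt(sigmaE2 / w))
    e <- projectOut(e, cbind(g, u, v))
    # exact weighted rescale: sample variance of sqrt(w)-scaled residuals
    # equals sigmaE2, so Var(e_i) = sigmaE2 / w_i holds in the weighted sense
    e <- e * sqrt(sigmaE2 / stats::var(e * sqrt(w)))
  } else e <- numeric(n)
  y <- g + u + v + e
  out <- data.frame(animalId = animalIds(geno), y = y, w = as.integer(w),
                    breedFracA = breedFractions(geno),
                    stringsAsFactors = FALSE)
  class(out) <- c("PhenotypeTable", "data.frame")
  attr(out, "components") <- list(g = g, u = u, v = v, e = e)
  attr(out, "sigmaE2") <- sigmaE2
  out
}

#' One-call synthetic dataset
#'
#' Convenience wrapper chaining \code{\link{simulateHaplotypePools}},
#' \code{\link{simulateCrossbredGenotypes}}, \code{\link{plantQTL}} and
#' \code{\link{simulateYieldDeviations}}.
#'
#' @param config a \code{\link{populationConfig}}.
#' @param qtl optional list of \code{\link{qtlSpec}} objects.
#' @param ... passed to \code{\link{simulateYieldDeviations}}.
#' @return list: \code{geno}, \code{pheno}, \code{truth}, \code{structureIdx}.
#' @export
simulateDataset <- function(config, qtl = NULL, ...) {
  pools <- simulateHaplotypePools(config, qtl)
  geno <- simulateCrossbredGenotypes(pools, config)
  pq <- if (length(qtl)) plantQTL(geno, qtl) else
    list(g = numeric(nAnimals(geno)), truth = NULL)
  pheno <- simulateYieldDeviations(geno, g = pq$g, seed = config$seed, ...)
  sidx <- which(S4Vectors::mcols(variantMap(geno))$isStructure)
  list(geno = geno, pheno = pheno, truth = pq$truth, structureIdx = sidx)
}

#' Causal variant plus tags at chosen allelic R-squared
#'
#' Generates Hardy-Weinberg genotypes for one causal variant and companion
#' tag variants whose haplotype-level allelic correlation with the causal
#' variant is controlled exactly: a tag carries the causal allele with
#' probability \eqn{\beta = r^2 / (1 - q(1 - r^2))} (and never carries it on
#' non-causal haplotypes), which yields allelic
#' \eqn{R^2 = \beta(1-q)/(1-q\beta)}. Used to exercise the LD tagging law
#' (additive variance captured scales with \eqn{R^2}, dominance variance
#' with \eqn{R^4}).
#'
#' @param n number of diploid individuals.
#' @param maf causal minor allele frequency.
#' @param r2 vector of target allelic R-squared values for the tags.
#' @param seed integer seed.
#' @return list: \code{G} integer dosage matrix (columns: causal then tags),
#'   \code{r2Target} and realised \code{r2}.
#' @export
simulateTaggedVariants <- function(n, maf, r2 = c(1, 0.8, 0.5), seed = 1L) {
  set.seed(stageSeed(seed, "tags"))
  q <- maf
  hap <- matrix(stats::rbinom(2 * n, 1, q), ncol = 1)
  beta <- r2 / (1 - q * (1 - r2))
  tags <- sapply(beta, function(b) hap[, 1] * stats::rbinom(2 * n, 1, b))
  H <- cbind(hap, tags)
  G <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
  storage.mode(G) <- "integer"
  colnames(G) <- c("causal", sprintf("tag_r2_%g", r2))
  real <- apply(H[, -1, drop = FALSE], 2, function(h) stats::cor(h, H[, 1])^2)
  list(G = G, r2Target = r2, r2 = real)
}
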