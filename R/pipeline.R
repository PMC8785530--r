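#' @include itergwas.R
NULL

#' Pipeline run configuration
#'
#' A single configuration object (optionally read from a YAML file) driving
#' the whole pipeline: simulation parameters, stage toggles, thresholds,
#' Gibbs settings, segment size, dominance-class bin edges, output
#' directory and the global seed. Per-stage seeds are streamed
#' deterministically from the global seed, so stages can be rerun in
#' isolation.
#'
#' @param outDir output directory (created if missing).
#' @param seed global integer seed.
#' @param stages character vector of stages to run, a subset of
#'   \code{c("simulate", "qc", "greml", "adjust", "assoc", "iterate",
#'   "report")}.
#' @param population a \code{\link{populationConfig}}.
#' @param qtl optional list of \code{\link{qtlSpec}}s to plant.
#' @param h2,delta2 simulated variance fractions.
#' @param wLambda record-count Poisson rate (mean records = 1 + wLambda).
#' @param gibbs a \code{\link{gibbsConfig}}.
#' @param segmentBp LOSO segment width.
#' @param fdr,effectFrac,kEdges calling thresholds.
#' @param genotypes,phenotypes optional input paths; when given, the
#'   simulate stage is skipped and data are read instead.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(outDir = tempfile("domqtl_run_"), seed = 1L,
                      stages = c("simulate", "qc", "greml", "adjust",
                                 "assoc", "iterate", "report"),
                      population = populationConfig(seed = seed),
                      qtl = NULL, h2 = 0.296, delta2 = 0.044, wLambda = 8,
                      gibbs = gibbsConfig(seed = seed), segmentBp = 1e7,
                      fdr = 1e-3, effectFrac = 0.05,
                      kEdges = c(0.1, 0.7, 1.3),
                      genotypes = NULL, phenotypes = NULL) {
  cfg <- list(outDir = outDir, seed = as.integer(seed), stages = stages,
              population = population, qtl = qtl, h2 = h2, delta2 = delta2,
              wLambda = wLambda, gibbs = gibbs, segmentBp = segmentBp,
              fdr = fdr, effectFrac = effectFrac, kEdges = kEdges,
              genotypes = genotypes, phenotypes = phenotypes)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' Scalar keys map one-to-one onto \code{\link{runConfig}} arguments;
#' \code{population} and \code{gibbs} sub-maps onto
#' \code{\link{populationConfig}} and \code{\link{gibbsConfig}}; \code{qtl}
#' is a list of \code{\link{qtlSpec}} maps.
#'
#' @param path YAML file path.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  yml <- yaml::read_yaml(path)
  args <- yml[setdiff(names(yml), c("population", "gibbs", "qtl"))]
  if (!is.null(yml$population))
    args$population <- do.call(populationConfig,
                               c(yml$population,
                                 list(seed = yml$seed %||% 1L)))
  if (!is.null(yml$gibbs))
    args$gibbs <- do.call(gibbsConfig,
                          c(yml$gibbs, list(seed = yml$seed %||% 1L)))
  if (!is.null(yml$qtl))
    args$qtl <- lapply(yml$qtl, function(q) do.call(qtlSpec, q))
  do.call(runConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "outDir")], f)
  unname(tools::md5sum(f))
}

writeStamped <- function(df, path, hash, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s  seed: %d", hash, seed), con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Run the full non-additive QTL mapping pipeline
#'
#' Executes the enabled stages in dependency order:
#' simulate (or read inputs) -> structure-panel QC -> GREML variance
#' components -> BayesC0 + LOSO adjustment -> association scan -> iterative
#' conditional scan per significant chromosome -> report tables. Every
#' output TSV is stamped with the config hash and seed; identical config and
#' seed give identical outputs.
#'
#' @param config a \code{\link{runConfig}} (or a YAML path).
#' @return (invisibly) a list with the in-memory stage artifacts:
#'   \code{geno}, \code{pheno}, \code{truth}, \code{qc}, \code{greml},
#'   \code{samples}, \code{loso}, \code{assoc}, \code{iterate},
#'   \code{reportFiles}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  seed <- config$seed
  msg <- function(...) message("[domQTL] ", ...)
  state <- list()
  run <- function(stage) stage %in% config$stages

  # --- simulate (or read) -------------------------------------------------
  if (!is.null(config$genotypes)) {
    state$geno <- readGenotypes(config$genotypes)
    ph <- data.table::fread(config$phenotypes)
    state$pheno <- as.data.frame(ph)
    state$truth <- NULL
  } else if (run("simulate")) {
    msg("simulate: ", config$population$nAnimals, " animals")
    sim <- simulateDataset(config$population, config$qtl, h2 = config$h2,
                           delta2 = config$delta2, wLambda = config$wLambda)
    state$geno <- sim$geno
    state$pheno <- sim$pheno
    state$truth <- sim$truth
    if (!is.null(sim$truth))
      writeStamped(sim$truth, file.path(config$outDir, "truth.tsv"),
                   hash, seed)
    writeStamped(state$pheno, file.path(config$outDir, "phenotypes.tsv"),
                 hash, seed)
  } else stop("no genotype input: enable the simulate stage or give paths")

  geno <- state$geno
  pheno <- state$pheno
  mc <- S4Vectors::mcols(variantMap(geno))
  sidx <- if ("isStructure" %in% colnames(mc)) which(mc$isStructure)
          else seq_len(nVariants(geno))

  # --- qc -----------------------------------------------------------------
  if (run("qc")) {
    msg("qc: structure panel filter on ", length(sidx), " SNPs")
    strata <- if ("breedClass" %in% colnames(geno@animalData))
      geno@animalData$breedClass else NULL
    qc <- structurePanelFilter(geno[, sidx], strata = strata)
    state$qc <- qc
    writeStamped(qc$report, file.path(config$outDir, "qc_structure.tsv"),
                 hash, seed)
    sidx <- sidx[qc$keep]
  }

  # --- greml --------------------------------------------------------------
  if (run("greml")) {
    msg("greml: ", length(sidx), " SNPs, ", nAnimals(geno), " animals")
    grms <- buildGRMs(geno[, sidx])
    state$greml <- remlAD(pheno$y, grms)
    writeVarianceReport(list(trait = state$greml),
                        file.path(config$outDir, "variance_components.tsv"))
  }

  # --- adjust -------------------------------------------------------------
  if (run("adjust")) {
    msg("adjust: BayesC0 on ", length(sidx), " SNPs, ",
        config$gibbs$nRetained, " retained samples")
    Ms <- dosages(geno)[, sidx, drop = FALSE]
    state$samples <- gibbsBayesC0(pheno$y, pheno$w, Ms, config$gibbs,
                                  snpIds = variantIds(geno)[sidx])
    gew <- vapply(list(state$samples@varAlpha, state$samples@varDelta,
                       state$samples@varE),
                  function(ch) if (length(ch) >= 50)
                    gewekeDiagnostic(ch)$z else NA_real_, numeric(1))
    state$geweke <- stats::setNames(gew, c("varAlpha", "varDelta", "varE"))
    msg("adjust: Geweke z = ",
        paste(sprintf("%.2f", gew), collapse = ", "))
    plan <- partitionSegments(geno, segmentBp = config$segmentBp)
    map <- variantMap(geno)
    state$loso <- losoAdjust(pheno$y, state$samples, plan,
                             dosages(geno)[, sidx, drop = FALSE],
                             as.character(GenomicRanges::seqnames(map))[sidx],
                             GenomicRanges::start(map)[sidx],
                             w = pheno$w)
  }

  # --- assoc --------------------------------------------------------------
  if (run("assoc")) {
    stopifnot(!is.null(state$loso))
    msg("assoc: scanning test variants")
    res <- scanAssociation(geno, state$loso,
                           seed = stageSeed(seed, "scan"))
    res <- callAndClassify(res, phenotypicSd = stats::sd(pheno$y),
                           fdr = config$fdr,
                           effectFrac = config$effectFrac,
                           edges = config$kEdges)
    state$assoc <- res
    writeStamped(res, file.path(config$outDir, "association.tsv"),
                 hash, seed)
  }

  # --- iterate ------------------------------------------------------------
  if (run("iterate")) {
    stopifnot(!is.null(state$assoc))
    sigChrom <- unique(state$assoc$chrom[state$assoc$called])
    state$iterate <- lapply(sigChrom, function(ch) {
      msg("iterate: chromosome ", ch)
      iterateChromosome(geno, state$loso, ch,
                        phenotypicSd = stats::sd(pheno$y),
                        fdr = config$fdr, effectFrac = config$effectFrac,
                        seed = stageSeed(seed, paste0("iter", ch)))
    })
    names(state$iterate) <- sigChrom
    calls <- do.call(rbind, lapply(state$iterate, `[[`, "calls"))
    if (!is.null(calls) && nrow(calls))
      writeStamped(calls, file.path(config$outDir, "qtl_calls.tsv"),
                   hash, seed)
    state$calls <- calls
  }

  # --- report -------------------------------------------------------------
  if (run("report")) {
    state$reportFiles <- makeReport(state, config, hash)
  }
  invisible(state)
}

#' Report tables from pipeline outputs
#'
#' Emits Manhattan-ready per-variant tables (-log10 p for the additive and
#' dominance contrasts), a MAF-versus-effect table for called QTL, and an
#' additive-versus-dominance architecture summary. Regeneration is
#' idempotent; an empty call set yields report files with empty tables.
#'
#' @param state pipeline state list holding at least \code{assoc}.
#' @param config the \code{RunConfig} used.
#' @param hash config hash to stamp into the files (recomputed if missing).
#' @return character vector of written paths.
#' @export
makeReport <- function(state, config, hash = NULL) {
  stopifnot(!is.null(state$assoc))
  if (is.null(hash)) hash <- configHash(config)
  res <- state$assoc
  out <- character(0)
  manh <- data.frame(chrom = res$chrom, pos = res$pos,
                     negLog10PAdd = -log10(pmax(res$aP, 1e-300)),
                     negLog10PDom = -log10(pmax(res$dP, 1e-300)),
                     negLog10PStd = -log10(pmax(res$alphaP, 1e-300)))
  manh[is.na(manh)] <- 0
  f <- file.path(config$outDir, "manhattan.tsv")
  writeStamped(manh, f, hash, config$seed)
  out <- c(out, f)
  called <- res[!is.na(res$called) & res$called, , drop = FALSE]
  mafEff <- data.frame(chrom = called$chrom, pos = called$pos,
                       maf = called$maf, a = called$aMean, d = called$dMean,
                       absK = abs(called$k), class = called$class)
  f <- file.path(config$outDir, "maf_vs_effect.tsv")
  writeStamped(mafEff, f, hash, config$seed)
  out <- c(out, f)
  arch <- data.frame(
    nTested = nrow(res),
    nCalledDominance = nrow(called),
    nRecessiveWindow = sum(called$class == "recessive-window", na.rm = TRUE),
    nPartialDominant = sum(called$class == "partial-dominant", na.rm = TRUE),
    nOverDominant = sum(called$class == "over-dominant", na.rm = TRUE),
    medianMafCalled = stats::median(called$maf),
    medianAbsDCalled = stats::median(abs(called$dMean)))
  f <- file.path(config$outDir, "architecture.tsv")
  writeStamped(arch, f, hash, config$seed)
  out <- c(out, f)
  out
}
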