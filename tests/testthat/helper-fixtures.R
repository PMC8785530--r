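# Small shared fixtures built in code. The medium simulation feeds several
# association/iteration tests; building it once keeps the suite fast.

smallConfig <- function(seed = 3, ...) {
  populationConfig(nAnimals = 400, nStructureSnps = 80, nDenseVariants = 320,
                   nChromosomes = 2, chromLengthBp = 3e7, seed = seed, ...)
}

# run BayesC0 + LOSO on a simulated dataset with reduced chain settings
fitLoso <- function(sim, nRetained = 50, burnIn = 100, seed = 7,
                    segmentBp = 1e7) {
  Ms <- dosages(sim$geno)[, sim$structureIdx, drop = FALSE]
  smp <- gibbsBayesC0(sim$pheno$y, sim$pheno$w, Ms,
                      gibbsConfig(nRetained = nRetained, burnIn = burnIn,
                                  thin = 1, seed = seed))
  plan <- partitionSegments(sim$geno, segmentBp = segmentBp)
  map <- variantMap(sim$geno)
  loso <- losoAdjust(sim$pheno$y, smp, plan, Ms,
                     as.character(GenomicRanges::seqnames(map))[sim$structureIdx],
                     GenomicRanges::start(map)[sim$structureIdx],
                     w = sim$pheno$w)
  list(samples = smp, plan = plan, loso = loso)
}

# hand-rolled weighted class means, independent of the package path
oracleClassMeans <- function(y, x, w) {
  vapply(0:2, function(g) {
    idx <- which(x == g)
    if (!length(idx)) return(NA_real_)
    sum(w[idx] * y[idx]) / sum(w[idx])
  }, numeric(1))
}
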