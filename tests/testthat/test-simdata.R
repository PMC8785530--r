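test_that("population config validates its invariants", {
  expect_error(populationConfig(breedMix = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(populationConfig(nAnimals = 0))
  expect_error(populationConfig(nStructureSnps = 1e7, nDenseVariants = 1e8,
                                nChromosomes = 1, chromLengthBp = 2e7),
               "more variants")
  expect_error(populationConfig(chromLengthBp = 1e6), "20 Mb")
})

test_that("zero recombination copies founder haplotypes exactly", {
  cfg <- populationConfig(nAnimals = 60, nStructureSnps = 10,
                          nDenseVariants = 40, nChromosomes = 1,
                          chromLengthBp = 2e7, recombRate = 0,
                          breedMix = c(1, 0, 0), founderHaps = 6, seed = 4)
  pools <- simulateHaplotypePools(cfg)
  geno <- simulateCrossbredGenotypes(pools, cfg)
  # every animal must be the sum of two founder columns of pool A
  founders <- t(pools$A)                       # haplotypes x variants
  sums <- apply(expand.grid(1:6, 1:6), 1, function(ij)
    paste(founders[ij[1], ] + founders[ij[2], ], collapse = ""))
  obs <- apply(dosages(geno), 1, paste, collapse = "")
  expect_true(all(obs %in% sums))
  expect_true(all(breedFractions(geno) == 1))
})

test_that("pool divergence matches a beta-resampling oracle", {
  nv <- 2000
  cfg0 <- populationConfig(nAnimals = 10, nStructureSnps = 100,
                           nDenseVariants = nv - 100, nChromosomes = 1,
                           chromLengthBp = 3e7, divergence = 0, seed = 9)
  p0 <- simulateHaplotypePools(cfg0)
  expect_lt(mean(abs(p0$poolFreqA - p0$poolFreqB)), 1e-12)

  cfg <- populationConfig(nAnimals = 10, nStructureSnps = 100,
                          nDenseVariants = nv - 100, nChromosomes = 1,
                          chromLengthBp = 3e7, divergence = 0.1, seed = 9)
  pools <- simulateHaplotypePools(cfg)
  # the generator's target frequencies are the Balding-Nichols draws;
  # oracle: independent beta resampling at the same base frequencies
  realized <- mean(abs(pools$poolFreqA - pools$poolFreqB))
  set.seed(42)
  Fst <- 0.1
  reps <- vapply(1:200, function(r) {
    q <- pools$baseFreq
    qa <- rbeta(nv, q * (1 - Fst) / Fst, (1 - q) * (1 - Fst) / Fst)
    qb <- rbeta(nv, q * (1 - Fst) / Fst, (1 - q) * (1 - Fst) / Fst)
    mean(abs(qa - qb))
  }, numeric(1))
  expect_lt(abs(realized - mean(reps)), 3 * sd(reps) + 3 * sd(reps) / sqrt(200))
  # founder-panel drift rides on top of the target divergence, so panel
  # frequencies must diverge more under Fst = 0.1 than under Fst = 0
  pd0 <- mean(abs(colMeans(t(p0$A)) - colMeans(t(p0$B))))
  pd1 <- mean(abs(colMeans(t(pools$A)) - colMeans(t(pools$B))))
  expect_gt(pd1, pd0)
})

test_that("genotype bounds hold and planted MAF is binomial around target", {
  cfg <- populationConfig(nAnimals = 10000, nStructureSnps = 50,
                          nDenseVariants = 450, nChromosomes = 1,
                          chromLengthBp = 2.5e7, seed = 12)
  qtl <- list(qtlSpec("1", 1.2e7, 0.03, -1, 1))
  pools <- simulateHaplotypePools(cfg, qtl)
  geno <- simulateCrossbredGenotypes(pools, cfg)
  st <- variantStats(geno)
  expect_true(all(st$maf >= 0 & st$maf <= 0.5))
  expect_true(all(st$homAltCount >= 0 & st$homAltCount <= nAnimals(geno)))
  v <- which(S4Vectors::mcols(variantMap(geno))$isPlanted)
  se <- sqrt(0.03 * 0.97 / (2 * 10000))
  expect_lt(abs(mean(dosages(geno)[, v]) / 2 - 0.03), 3 * se)
})

test_that("plantQTL encodes class deviations (-a, d, +a)", {
  cfg <- smallConfig()
  pools <- simulateHaplotypePools(cfg, list(qtlSpec("1", 5e6, 0.2, -5, 5)))
  geno <- simulateCrossbredGenotypes(pools, cfg)
  pq <- plantQTL(geno, list(qtlSpec("1", 5e6, 0.2, -5, 5)))
  x <- dosages(geno)[, pq$truth$variant]
  # fully recessive: het equals hom-ref, hom-alt 2|a| below
  expect_equal(unique(pq$g[x == 0]), 5)
  expect_equal(unique(pq$g[x == 1]), 5)
  expect_equal(unique(pq$g[x == 2]), -5)
  expect_equal(pq$truth$k, 1)
  # perfectly additive spec: k = 0
  pq2 <- plantQTL(geno, list(qtlSpec("1", 5e6, 0.2, -5, 0)))
  expect_equal(unique(pq2$g[x == 1]), 0)
  expect_equal(pq2$truth$k, 0)
})

test_that("class-mean arithmetic matches the stop-gain worked example", {
  eff <- genotypicEffects(c(0, -1.44, -11.21))
  # independent arithmetic oracle
  a <- (-11.21 - 0) / 2
  d <- -1.44 - (0 + -11.21) / 2
  expect_equal(unname(eff["a"]), a)
  expect_equal(unname(eff["d"]), d)
  expect_equal(unname(eff["a"]), -5.605)
  expect_equal(unname(eff["d"]), 4.165)
  expect_equal(round(unname(eff["k"]), 2), 0.74)
})

test_that("a spec at a monomorphic variant warns and contributes zero", {
  g <- GenotypeData(matrix(0L, 10, 2), chrom = c("1", "1"),
                    pos = c(100L, 2e6L))
  expect_warning(pq <- plantQTL(g, list(qtlSpec("1", 100, 0.1, -2, 2))),
                 "monomorphic")
  expect_equal(pq$g, rep(0, 10))
})

test_that("yield deviations obey the noise-free limit and variance targets", {
  cfg <- smallConfig(seed = 5)
  sim0 <- simulateDataset(cfg, qtl = list(qtlSpec("1", 5e6, 0.2, -1, 1)),
                          h2 = 0, delta2 = 0, phenVar = 0)
  comp <- attr(sim0$pheno, "components")
  expect_equal(sim0$pheno$y, comp$g)   # y == g exactly with no noise

  # constant weights: exact component scaling and additive decomposition
  cfg2 <- smallConfig(seed = 6)
  pools <- simulateHaplotypePools(cfg2)
  geno <- simulateCrossbredGenotypes(pools, cfg2)
  ph <- simulateYieldDeviations(geno, h2 = 0.3, delta2 = 0.05,
                                w = rep(5L, nAnimals(geno)), seed = 11)
  comp <- attr(ph, "components")
  expect_equal(var(comp$u), 0.3, tolerance = 1e-10)
  expect_equal(var(comp$v), 0.05, tolerance = 1e-10)
  sigmaE2 <- attr(ph, "sigmaE2")
  expect_equal(var(comp$e), sigmaE2 / 5, tolerance = 1e-10)
  expect_equal(var(ph$y), var(comp$g) + 0.3 + 0.05 + sigmaE2 / 5,
               tolerance = 1e-8)
  expect_error(simulateYieldDeviations(geno, w = rep(0L, nAnimals(geno))),
               "w must be")
})

test_that("a fixed seed reproduces the dataset byte-for-byte", {
  cfg <- smallConfig(seed = 17)
  s1 <- simulateDataset(cfg, qtl = list(qtlSpec("2", 1e7, 0.1, -1, 0.5)))
  s2 <- simulateDataset(cfg, qtl = list(qtlSpec("2", 1e7, 0.1, -1, 0.5)))
  expect_identical(dosages(s1$geno), dosages(s2$geno))
  expect_identical(s1$pheno$y, s2$pheno$y)
  expect_identical(s1$pheno$w, s2$pheno$w)
  expect_identical(dr2(s1$geno), dr2(s2$geno))
})

test_that("noise-free class means reproduce the planted (a, d) exactly", {
  cfg <- smallConfig(seed = 19)
  qtl <- list(qtlSpec("1", 8e6, 0.25, -2.5, 1.75))
  sim <- simulateDataset(cfg, qtl, h2 = 0, delta2 = 0, phenVar = 0)
  x <- dosages(sim$geno)[, sim$truth$variant]
  mu <- vapply(0:2, function(g) mean(sim$pheno$y[x == g]), numeric(1))
  eff <- genotypicEffects(mu)
  expect_equal(unname(eff["a"]), -2.5, tolerance = 1e-12)
  expect_equal(unname(eff["d"]), 1.75, tolerance = 1e-12)
})

test_that("tagged-variant generator hits its target allelic R2", {
  tv <- simulateTaggedVariants(30000, maf = 0.05, r2 = c(1, 0.8, 0.5),
                               seed = 3)
  expect_equal(tv$r2[1], 1)
  expect_equal(tv$r2[2], 0.8, tolerance = 0.05)
  expect_equal(tv$r2[3], 0.5, tolerance = 0.05)
  expect_true(all(tv$G %in% 0:2))
})
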