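test_that("class-effect chains collapse to the truth without noise", {
  mu <- c(1, 1, -1)
  x <- rep(c(0L, 1L, 2L), times = c(50, 30, 20))
  yt <- matrix(mu[x + 1], length(x), 8)    # identical across samples
  b <- sampleClassEffects(yt, x, varE = rep(0, 8))
  expect_equal(unname(b[, "b0"]), rep(1, 8))
  expect_equal(unname(b[, "b1"]), rep(1, 8))
  expect_equal(unname(b[, "b2"]), rep(-1, 8))
  expect_error(sampleClassEffects(yt, rep(1L, length(x))), "2 occupied")
})

test_that("WLS class means match hand-computed oracles", {
  set.seed(3)
  x <- rep(c(0L, 1L, 2L), each = 3)
  w <- rep(c(1, 2, 4), times = 3)
  yt <- matrix(rnorm(9 * 5), 9, 5)
  b <- sampleClassEffects(yt, x, w = w, draw = FALSE)
  for (t in 1:5)
    expect_equal(unname(b[t, ]), oracleClassMeans(yt[, t], x, w),
                 tolerance = 1e-12)
  # equal weights reduce to plain group means
  b1 <- sampleClassEffects(yt, x, draw = FALSE)
  for (t in 1:5)
    expect_equal(unname(b1[t, ]),
                 vapply(0:2, function(g) mean(yt[x == g, t]), numeric(1)),
                 tolerance = 1e-12)
})

test_that("contrast summaries reproduce the printed worked examples", {
  # class means from the premature-stop locus on chromosome 25
  b <- matrix(rep(c(0, -1.44, -11.21), each = 4), 4, 3)
  s <- summarizeContrasts(b, classWeights = c(100, 20, 5))
  expect_equal(s$aMean, -5.605)
  expect_equal(s$dMean, 4.165)
  expect_equal(round(s$k, 2), 0.74)
  # perfect additivity: d = 0, k = 0
  b2 <- cbind(0, 1.3, 2.6)[rep(1, 4), ]
  s2 <- summarizeContrasts(b2, classWeights = c(10, 10, 10))
  expect_equal(s2$dMean, 0)
  expect_equal(s2$k, 0)
  # z-test arithmetic against the printed milk-volume additive row
  zt <- zTestP(-129.181, 23.604)
  expect_equal(zt$z, -129.181 / 23.604)
  # independent tail oracle via erfc
  erfcOracle <- function(z) {
    t <- 1 / (1 + 0.5 * abs(z) / sqrt(2))
    # Numerical Recipes erfc approximation, accurate to ~1e-7 relative
    tau <- t * exp(-(z / sqrt(2))^2 - 1.26551223 + t * (1.00002368 +
      t * (0.37409196 + t * (0.09678418 + t * (-0.18628806 + t * (0.27886807 +
      t * (-1.13520398 + t * (1.48851587 + t * (-0.82215223 +
      t * 0.17087277)))))))))
    tau
  }
  expect_equal(zt$p, erfcOracle(zt$z), tolerance = 1e-4)
})

test_that("q-values follow the Storey formula and stay monotone", {
  expect_equal(qvalues(rep(1, 200))$q, rep(1, 200))
  p <- c(1e-5, rep(1, 99))
  q <- qvalues(p)                          # m = 100: pi0 estimated, clamps at 1
  expect_equal(q$pi0, 1)
  expect_equal(q$q[1], 1e-5 * 100 / 1)     # pi0 * m * p(1) / 1 = 1e-3
  expect_warning(qvalues(runif(50)), "fewer than 100")
  expect_error(qvalues(c(0, 0.5)), "lie in")
  set.seed(5)
  pu <- runif(5000)
  qq <- qvalues(pu)$q
  ord <- order(pu)
  expect_true(all(diff(qq[ord]) >= -1e-12))  # monotone in p
  # ties share a q-value
  pt <- c(0.01, 0.01, runif(200, 0.4, 1))
  qt <- qvalues(pt)$q
  expect_equal(qt[1], qt[2])
})

test_that("uniform p-values essentially never clear the dominance FDR", {
  set.seed(7)
  hits <- vapply(1:20, function(r) sum(qvalues(runif(10000))$q < 1e-3),
                 numeric(1))
  expect_lte(sum(hits), 5)
})

test_that("dominance classification bins match the printed coefficients", {
  expect_equal(classifyDominance(dominanceCoefficient(-129.181, 109.644)),
               "recessive-window")    # k = 0.849
  expect_equal(classifyDominance(dominanceCoefficient(-5.170, 5.546)),
               "recessive-window")    # k = 1.073 < 1.3
  expect_equal(classifyDominance(dominanceCoefficient(-1, 0)), "additive")
  expect_equal(classifyDominance(c(0.05, 0.4, -0.95, 1.5)),
               c("additive", "partial-dominant", "recessive-window",
                 "over-dominant"))
})

test_that("calling requires both the FDR and the effect-size gate", {
  res <- data.frame(dP = c(1e-10, 1e-10, 0.5), aMean = c(1, 0.01, 1),
                    dMean = c(0.9, 0.01, 0.9), k = c(0.9, 1, 0.9))
  res <- suppressWarnings(callAndClassify(res, phenotypicSd = 1,
                                          fdr = 1e-3, effectFrac = 0.05))
  expect_true(res$called[1])
  expect_false(res$called[2])   # significant but tiny effect
  expect_false(res$called[3])   # large effect but not significant
})

test_that("scan results are order invariant and internally consistent", {
  cfg <- smallConfig(seed = 41)
  sim <- simulateDataset(cfg, qtl = list(qtlSpec("1", 6e6, 0.15, -1, 1)))
  fit <- fitLoso(sim, nRetained = 30, burnIn = 60)
  vs <- which(!S4Vectors::mcols(variantMap(sim$geno))$isStructure)
  r1 <- scanAssociation(sim$geno, fit$loso, variants = vs, seed = 2)
  r2 <- scanAssociation(sim$geno, fit$loso, variants = rev(vs), seed = 2)
  expect_equal(r1, r2)
  expect_true(all(r1$maf <= 0.5 + 1e-12))
  expect_true(all(r1$n0 + r1$n1 + r1$n2 + r1$nMissing == nAnimals(sim$geno)))
  # linearity: k recomputed from posterior-mean contrasts matches column
  expect_equal(r1$k, r1$dMean / abs(r1$aMean))
  # z and p columns agree with their definitions
  expect_equal(r1$dZ, r1$dMean / r1$dSd)
  expect_equal(r1$dP, 2 * pnorm(-abs(r1$dZ)))
})

test_that("single-variant chains agree with the vectorised scan", {
  cfg <- smallConfig(seed = 43)
  sim <- simulateDataset(cfg, qtl = list(qtlSpec("1", 6e6, 0.2, -1, 1)))
  fit <- fitLoso(sim, nRetained = 200, burnIn = 60)
  v <- sim$truth$variant
  res <- scanAssociation(sim$geno, fit$loso, variants = v, seed = 2)
  s <- segmentOf(fit$plan)[v]
  yt <- adjustedPhenotypes(fit$loso, s)
  set.seed(99)
  b <- sampleClassEffects(yt, dosages(sim$geno)[, v], w = sim$pheno$w,
                          varE = fit$samples@varE)
  sc <- summarizeContrasts(b, classWeights = vapply(0:2, function(g)
    sum(sim$pheno$w[dosages(sim$geno)[, v] == g]), numeric(1)))
  # same estimator, independent draw noise: agreement within chain MC error
  expect_lt(abs(res$aMean - sc$aMean), 4 * sc$aSd / sqrt(200))
  expect_lt(abs(res$dMean - sc$dMean), 4 * sc$dSd / sqrt(200))
  expect_lt(abs(res$alphaMean - sc$alphaMean), 5 * sc$alphaSd / sqrt(200))
})

test_that("variants with an empty class keep the defined contrasts", {
  set.seed(47)
  n <- 120
  x <- c(rep(0L, 100), rep(1L, 20))          # no hom-alt
  yt <- matrix(rnorm(n * 6), n, 6)
  g <- GenotypeData(cbind(x), chrom = "1", pos = 5L)
  plan <- partitionSegments(g)
  smp <- new("PosteriorSampleSet", mu = rep(0, 6),
             alpha = matrix(0, 1, 6), delta = matrix(0, 1, 6),
             varAlpha = rep(1e-4, 6), varDelta = rep(1e-4, 6),
             varE = rep(1, 6), snpIds = "s1")
  loso <- losoAdjust(yt[, 1], smp, plan, matrix(0L, n, 1), "1", 5L)
  res <- scanAssociation(g, loso, variants = 1L, seed = 3)
  expect_true(is.na(res$aMean))              # needs both homozygote classes
  expect_true(is.na(res$dMean))
  expect_false(is.na(res$alphaMean))         # slope over 2 classes remains
})
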