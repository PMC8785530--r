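test_that("Gibbs sampler config and inputs are validated", {
  expect_error(gibbsConfig(nRetained = 1), "nRetained")
  expect_error(gibbsConfig(thin = 0))
  M <- matrix(c(0L, 1L, 2L, 1L), 4, 1)
  expect_error(gibbsBayesC0(c(1, NA, 2, 1), M = M,
                            config = gibbsConfig(10, 10, 1)), "non-finite")
  expect_error(gibbsBayesC0(rep(2, 4), M = M,
                            config = gibbsConfig(10, 10, 1)), "zero variance")
})

test_that("near-constant phenotypes give null SNP effects", {
  set.seed(3)
  n <- 300
  M <- vapply(runif(60, 0.1, 0.5), function(p) rbinom(n, 2L, p), integer(n))
  y <- rep(3, n) + rnorm(n, 0, 0.01)
  smp <- gibbsBayesC0(y, rep(1, n), M, gibbsConfig(200, 200, 1, seed = 5))
  aM <- rowMeans(smp@alpha); aS <- apply(smp@alpha, 1, sd)
  dM <- rowMeans(smp@delta); dS <- apply(smp@delta, 1, sd)
  expect_true(all(abs(aM) < 3 * aS + 1e-8))
  expect_true(all(abs(dM) < 3 * dS + 1e-8))
  # and the overall mean is recovered
  expect_equal(mean(smp@mu), 3, tolerance = 0.01)
})

test_that("generative variance recovery and zero-variance pinning", {
  set.seed(7)
  n <- 1000; p <- 500
  s2a <- 4e-4; s2d <- 2e-4; s2e <- 0.8
  M <- vapply(runif(p, 0.1, 0.5), function(pp) rbinom(n, 2L, pp), integer(n))
  M[, 1] <- 1L                              # zero-variance column
  H <- (M == 1L) * 1
  y <- as.numeric(M %*% rnorm(p, 0, sqrt(s2a)) +
                  H %*% rnorm(p, 0, sqrt(s2d))) + rnorm(n, 0, sqrt(s2e))
  smp <- gibbsBayesC0(y, rep(1, n), M, gibbsConfig(300, 300, 1, seed = 9))
  expect_true(all(smp@alpha[1, ] == 0))     # pinned
  expect_true(all(smp@delta[1, ] == 0))
  mcse <- function(ch) sd(ch) / sqrt(length(ch) / 10)  # conservative ESS
  expect_lt(abs(mean(smp@varE) - s2e), 3 * mcse(smp@varE) + 0.05)
  expect_lt(abs(mean(smp@varAlpha) - s2a),
            3 * mcse(smp@varAlpha) + 3 * sd(smp@varAlpha))
  expect_lt(abs(mean(smp@varDelta) - s2d),
            3 * mcse(smp@varDelta) + 3 * sd(smp@varDelta))
})

test_that("with dominance off and fixed variances the sampler solves ridge", {
  set.seed(5)
  n <- 400; p <- 50
  M <- vapply(runif(p, 0.2, 0.5), function(pp) rbinom(n, 2L, pp), integer(n))
  y <- as.numeric(M %*% rnorm(p, 0, 0.3)) + rnorm(n)
  smp <- gibbsBayesC0(y, rep(1, n), M,
                      gibbsConfig(800, 300, 2, seed = 9),
                      fitDominance = FALSE, updateVariances = FALSE,
                      init = list(varAlpha = 0.09, varE = 1))
  expect_true(all(smp@delta == 0))
  abar <- rowMeans(smp@alpha)
  # the exact posterior mean profiles out mu, i.e. ridge on centred codes
  Mc <- scale(M, scale = FALSE)
  sol <- solve(crossprod(Mc) + diag(1 / 0.09, p), crossprod(Mc, y - mean(y)))
  expect_lt(max(abs(abar - sol)), 0.02)
  expect_gt(cor(abar, sol), 0.999)
})

test_that("Geweke diagnostic is calibrated and flags non-stationarity", {
  set.seed(11)
  zs <- replicate(200, gewekeDiagnostic(rnorm(2000))$z)
  expect_gte(mean(abs(zs) < 2), 0.95)
  expect_gt(abs(gewekeDiagnostic(seq_len(1000) / 10)$z), 5)
  gd <- gewekeDiagnostic(rep(1, 100))
  expect_equal(gd$z, 0)
  expect_true(gd$degenerate)
  expect_error(gewekeDiagnostic(rnorm(10)), "chain too short")
})

test_that("segment tiling follows floor((pos - 1) / L)", {
  pos <- c(1, 9999999, 1e7, 1e7 + 1, 2e7, 2.4e7)
  plan <- partitionSegments(rep("5", 6), pos)
  expect_equal(nrow(segments(plan)), 3)   # [0,10M), [10M,20M), [20M,25M)
  expect_equal(segments(plan)$startBp, c(0, 1e7, 2e7))
  expect_equal(segments(plan)$endBp, c(1e7, 2e7, 2.4e7))
  # 1-based 1e7 is the last position of the first tile; 1e7+1 starts the next
  expect_equal(segmentOf(plan), c(1L, 1L, 1L, 2L, 2L, 3L))
})

test_that("every variant lands in exactly one segment", {
  set.seed(13)
  chrom <- sample(c("1", "2", "3"), 500, replace = TRUE)
  pos <- sample.int(4.3e7, 500)
  ord <- order(chrom, pos)
  plan <- partitionSegments(chrom[ord], pos[ord])
  expect_equal(length(segmentOf(plan)), 500)
  expect_false(anyNA(segmentOf(plan)))
  segs <- segments(plan)
  # assignments agree with the interval definitions
  for (i in sample(500, 50)) {
    s <- segs[segs$segId == segmentOf(plan)[i], ]
    expect_equal(s$chrom, chrom[ord][i])
    expect_true(pos[ord][i] - 1 >= s$startBp && pos[ord][i] - 1 < s$endBp)
  }
})

test_that("LOSO add-back is an exact algebraic identity", {
  cfg <- smallConfig(seed = 31)
  sim <- simulateDataset(cfg, h2 = 0.3, delta2 = 0.05)
  fit <- fitLoso(sim, nRetained = 20, burnIn = 40)
  loso <- fit$loso
  smp <- fit$samples
  Ms <- dosages(sim$geno)[, sim$structureIdx]
  storage.mode(Ms) <- "double"
  dimnames(Ms) <- NULL
  Hs <- (Ms == 1) * 1
  n <- nAnimals(sim$geno)
  full <- matrix(sim$pheno$y, n, nSamples(smp)) -
    matrix(smp@mu, n, nSamples(smp), byrow = TRUE) -
    Ms %*% smp@alpha - Hs %*% smp@delta
  expect_equal(adjustedPhenotypes(loso, NA), full, tolerance = 1e-12)
  for (s in segments(fit$plan)$segId) {
    j <- which(loso@structSegment == s)
    direct <- matrix(sim$pheno$y, n, nSamples(smp)) -
      matrix(smp@mu, n, nSamples(smp), byrow = TRUE) -
      Ms[, -j, drop = FALSE] %*% smp@alpha[-j, , drop = FALSE] -
      Hs[, -j, drop = FALSE] %*% smp@delta[-j, , drop = FALSE]
    expect_equal(adjustedPhenotypes(loso, s), direct, tolerance = 1e-12)
  }
  expect_error(adjustedPhenotypes(loso, 999L), "unknown segment")
})

test_that("a single genome-wide segment leaves y - mu untouched", {
  cfg <- populationConfig(nAnimals = 200, nStructureSnps = 40,
                          nDenseVariants = 100, nChromosomes = 1,
                          chromLengthBp = 2e7, seed = 33)
  sim <- simulateDataset(cfg)
  fit <- fitLoso(sim, nRetained = 10, burnIn = 20, segmentBp = 1e9)
  expect_equal(nrow(segments(fit$plan)), 1)
  yt <- adjustedPhenotypes(fit$loso, 1L)
  expected <- matrix(sim$pheno$y, 200, 10) -
    matrix(fit$samples@mu, 200, 10, byrow = TRUE)
  expect_equal(yt, expected, tolerance = 1e-12)
})

test_that("LOSO avoids shrinking a QTL that sits on a structure SNP", {
  set.seed(37)
  n <- 3000; p <- 150
  M <- vapply(runif(p, 0.2, 0.5), function(pp) rbinom(n, 2L, pp), integer(n))
  beta <- 0.25
  qsnp <- 75
  y <- beta * M[, qsnp] + rnorm(n, 0, 1)
  smp <- gibbsBayesC0(y, rep(1, n), M, gibbsConfig(60, 120, 1, seed = 5))
  # SNPs spread over 3 segments of one chromosome; the QTL SNP in segment 2
  pos <- seq(1e5, 2.95e7, length.out = p)
  plan <- partitionSegments(rep("1", p), pos)
  loso <- losoAdjust(y, smp, plan, M, rep("1", p), pos)
  s <- segmentOf(plan)[qsnp]
  ytS <- rowMeans(adjustedPhenotypes(loso, s))
  ytF <- rowMeans(adjustedPhenotypes(loso, NA))
  bS <- coef(lm(ytS ~ M[, qsnp]))[2]
  bF <- coef(lm(ytF ~ M[, qsnp]))[2]
  se <- summary(lm(y ~ M[, qsnp]))$coefficients[2, 2]
  expect_lt(abs(bS - beta), 3 * se)      # LOSO recovers the planted slope
  expect_lt(bF, bS - 2 * se)             # full adjustment attenuates it
})
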