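vcfHeader <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"dosage R2\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
  "##contig=<ID=1>")

writeVcfLines <- function(records, samples = "s1") {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(vcfHeader,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               records), f)
  f
}

test_that("VCF reading honours GT, DS preference and hard-call rounding", {
  f <- writeVcfLines(c(
    "1\t100\t.\tA\tC\t.\tPASS\tDR2=0.95\tGT\t0/1",
    "1\t200\t.\tG\tT\t.\tPASS\tDR2=0.80\tGT:DS\t1/1:1.7",
    "1\t300\t.\tT\tA\t.\tPASS\tDR2=0.50\tGT:DS\t0/0:0.1"))
  g <- readGenotypes(f)
  expect_equal(unname(dosages(g)[1, ]), c(1L, 2L, 0L))
  expect_equal(dr2(g), c(0.95, 0.80, 0.50))
  # fractional doses retained alongside the hard calls
  expect_equal(unname(attr(g, "fractional")[1, 2]), 1.7)
  # GT wins when DS preference is off
  g2 <- readGenotypes(f, preferDS = FALSE)
  expect_equal(unname(dosages(g2)[1, ]), c(1L, 2L, 0L))
})

test_that("malformed and multi-allelic records are rejected with context", {
  f <- writeVcfLines("1\t100\t.\tA\tC,G\t.\tPASS\t.\tGT\t0/1")
  expect_error(readGenotypes(f), "multi-allelic")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("animalId\t1:100:A\tx", "a1\t0\t1"), f2)
  expect_error(readGenotypes(f2), "malformed variant id")
  expect_error(readGenotypes(tempfile(fileext = ".vcf")), "not found")
})

test_that("write-then-read round trips are identity for VCF and TSV", {
  cfg <- smallConfig(seed = 8)
  sim <- simulateDataset(cfg)
  fv <- tempfile(fileext = ".vcf.gz")
  writeGenotypesVcf(sim$geno, fv)
  gv <- readGenotypes(fv)
  expect_identical(unname(dosages(gv)), unname(dosages(sim$geno)))
  expect_equal(dr2(gv), dr2(sim$geno), tolerance = 1e-3)
  ft <- tempfile(fileext = ".tsv")
  writeGenotypesTsv(sim$geno, ft)
  gt <- readGenotypes(ft)
  expect_identical(unname(dosages(gt)), unname(dosages(sim$geno)))
  expect_equal(GenomicRanges::start(variantMap(gt)),
               GenomicRanges::start(variantMap(sim$geno)))
})

test_that("variant statistics match hand arithmetic", {
  g <- GenotypeData(cbind(c(0L, 0L, 1L, 2L)), chrom = "1", pos = 100L)
  st <- variantStats(g)
  expect_equal(st$maf, 0.375)
  expect_equal(st$callRate, 1)

  counts <- c(rep(0L, 81), rep(1L, 18), rep(2L, 1))
  g2 <- GenotypeData(cbind(counts), chrom = "1", pos = 100L)
  st2 <- variantStats(g2)
  expect_equal(st2$maf, 0.10)
  expect_equal(st2$hetFreq, 0.18)
  expect_equal(st2$hweDev, 0)          # exactly at HWE

  counts3 <- c(rep(0L, 45), rep(1L, 10), rep(2L, 45))
  g3 <- GenotypeData(cbind(counts3), chrom = "1", pos = 100L)
  expect_equal(variantStats(g3)$hweDev, 0.4)   # |0.1 - 0.5|
})

test_that("MAF is invariant to allele swapping", {
  cfg <- smallConfig(seed = 23)
  sim <- simulateDataset(cfg)
  st <- variantStats(sim$geno)
  swapped <- GenotypeData(2L - dosages(sim$geno),
                          chrom = as.character(
                            GenomicRanges::seqnames(variantMap(sim$geno))),
                          pos = GenomicRanges::start(variantMap(sim$geno)))
  expect_equal(variantStats(swapped)$maf, st$maf)
})

test_that("expected homozygote counts reproduce the quoted arithmetic", {
  expect_equal(expectedHomCount(0.01, 10000), 1)
  expect_equal(expectedHomCount(0.001, 1e6), 1)
  expect_equal(expectedHomCount(0, 12345), 0)
  expect_error(expectedHomCount(0.6, 10))
})

test_that("LD R2 matches an independent correlation computation", {
  x <- c(0L, 0L, 1L, 1L, 2L, 2L)
  y <- c(0L, 1L, 1L, 1L, 1L, 2L)
  g <- GenotypeData(cbind(x, y, x), chrom = "1", pos = c(100L, 200L, 300L))
  ld <- ldR2(g, windowBp = 1e6)
  # arithmetic oracle: explicit covariance formula
  n <- 6
  oracle <- (sum(x * y) - sum(x) * sum(y) / n)^2 /
    ((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  expect_equal(ld$r2[ld$i == 1 & ld$j == 2], oracle)
  expect_equal(ld$r2[ld$i == 1 & ld$j == 3], 1)  # duplicated column
  # zero-variance column is skipped
  g0 <- GenotypeData(cbind(x, rep(1L, 6)), chrom = "1",
                     pos = c(100L, 200L))
  expect_equal(nrow(ldR2(g0, 1e6)), 0)
})

test_that("independent variants have mean R2 near 1/n (permutation oracle)", {
  set.seed(31)
  n <- 10000
  G <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4), rbinom(n, 2, 0.25))
  storage.mode(G) <- "integer"
  g <- GenotypeData(G, chrom = "1", pos = c(100L, 200L, 300L))
  obs <- mean(ldR2(g, 1e6)$r2)
  perm <- replicate(60, {
    xp <- sample(G[, 1])
    c(cor(xp, G[, 2])^2, cor(xp, G[, 3])^2)
  })
  expect_lt(abs(obs - mean(perm)), 3 * sd(perm) / sqrt(length(perm)) +
              3 * sd(perm))
})

test_that("structure-panel filter applies each rule once, with reasons", {
  set.seed(7)
  n <- 200
  mk <- function(p) rbinom(n, 2, p)
  G <- cbind(
    good1 = mk(0.3),
    miss  = mk(0.3),        # high missingness
    rare  = rbinom(n, 2, 0.005),  # low MAF
    hwe   = c(rep(0L, 100), rep(2L, 100)),  # het deficit
    good2 = mk(0.4),
    lowdr = mk(0.3),        # DR2 below 0.9
    good3 = mk(0.25),
    good4 = mk(0.45),
    good5 = mk(0.35),
    good6 = mk(0.2))
  G[sample(n, 10), "miss"] <- NA
  G <- cbind(G, prune = G[, "good5"])   # R2 = 1 with good5, lower MAF loses
  storage.mode(G) <- "integer"
  g <- GenotypeData(G, chrom = "1", pos = seq(1e5, by = 1e5,
                                              length.out = ncol(G)),
                    dr2 = c(1, 1, 1, 1, 1, 0.85, 1, 1, 1, 1, 1))
  fl <- structurePanelFilter(g)
  expect_equal(sort(fl$report$firstFailure[!is.na(fl$report$firstFailure)]),
               sort(c("missing_rate", "low_maf", "hwe_deviation",
                      "low_dr2", "ld_prune")))
  expect_equal(length(fl$keep), ncol(G) - 5)
  # exactly one first-failure reason per removed variant
  expect_true(all(table(is.na(fl$report$firstFailure))[["FALSE"]] == 5))
  # idempotence: filtering the survivors removes nothing
  fl2 <- structurePanelFilter(g[, fl$keep])
  expect_equal(length(fl2$keep), length(fl$keep))
  # disabled thresholds pass everything through
  fl3 <- structurePanelFilter(g, maxMissing = 1, minMaf = 0, maxHweDev = 1,
                              minDr2 = 0, pruneR2 = NULL)
  expect_equal(fl3$keep, seq_len(ncol(G)))
})

test_that("sequence-panel filter applies the quoted strict boundaries", {
  mk <- function(nHom) c(rep(2L, nHom), rep(1L, 30), rep(0L, 170 - nHom))
  G <- cbind(five = mk(5), six = mk(6), dr2lo = mk(20), dr2eq = mk(20))
  g <- GenotypeData(G, chrom = "1",
                    pos = c(100L, 200L, 300L, 400L),
                    dr2 = c(1, 1, 0.69, 0.7))
  fl <- sequencePanelFilter(g)
  expect_false(1 %in% fl$keep)   # hom-alt count 5 removed
  expect_true(2 %in% fl$keep)    # 6 retained
  expect_false(3 %in% fl$keep)   # DR2 < 0.7 removed
  expect_true(4 %in% fl$keep)    # DR2 = 0.7 retained (strict inequality)
})

test_that("sequence filter counts match the generator's bookkeeping", {
  cfg <- populationConfig(nAnimals = 600, nStructureSnps = 60,
                          nDenseVariants = 600, nChromosomes = 1,
                          chromLengthBp = 2.5e7, fracDr2Below07 = 0.1,
                          fracDr2Below09 = 0.2, seed = 44)
  sim <- simulateDataset(cfg)
  fl <- sequencePanelFilter(sim$geno)
  st <- variantStats(sim$geno)
  expected <- which(st$homAltCount > 5 & dr2(sim$geno) >= 0.7)
  expect_equal(fl$keep, expected)
})
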