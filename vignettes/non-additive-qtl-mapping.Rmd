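---
title: "Mapping recessive and dominance QTL for lactation traits with domQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive and dominance QTL for lactation traits with domQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domQTL)
```

## The problem

Most genome-wide association studies of quantitative traits fit an additive
model, yet deleterious recessive alleles segregating at low frequency can
have large phenotypic impacts that an additive scan dilutes or misses.
In dairy cattle, lactation phenotypes (milk volume, fat and protein yield)
are recorded at population scale and act as proxies of whole-animal health,
which makes them attractive substrates for screening recessive defects:
a homozygous animal that produces a hundred litres less milk per lactation
is flagging something biological, whether or not a veterinary diagnosis
exists.

domQTL implements a complete non-additive QTL mapping workflow for this
setting:

1. **Marker QC** — the filter cascades for a medium-density
   structure-adjustment panel (missingness, MAF, within-breed
   Hardy–Weinberg deviation, imputation quality, LD pruning) and for a
   dense imputed-sequence panel (rare hom-alt count, DR²).
2. **GREMLd** — joint REML estimation of additive and dominance variance
   components from genomic relationship matrices, giving \(h^2\) and
   \(\delta^2\).
3. **Structure adjustment** — BayesC0 Gibbs sampling of genome-wide
   additive *and* dominance SNP effects, retaining a set of plausible
   posterior samples, with leave-one-segment-out (LOSO) adjusted
   phenotypes per 10-Mb interval.
4. **Association** — per-variant MCMC chains of genotype-class effects over
   the LOSO samples, summarised as genotypic additive (\(a\)), dominance
   (\(d\)) and standard-additive (dosage slope, \(\alpha\)) contrasts with
   z-statistics, two-sided normal p-values and Storey q-values; calling and
   classification by the dominance coefficient \(k = d/|a|\).
5. **Iterative conditioning** — repeated scanning of a chromosome with the
   genotype-class effects of already-called variants fitted out, to
   separate co-locating but uncorrelated QTL, plus stepwise selection of
   additive tag variants.
6. **Synthetic data** — a mixed-breed genotype/phenotype simulator that
   reproduces the statistical structure every stage assumes, so the whole
   pipeline is testable without animal data.

## The model

For one test variant the underlying linear model is

\[
y = 1\mu + Tb + M_\alpha\alpha + M_\delta\delta + e ,
\]

where \(b\) holds the three genotype-class effects of the variant of
interest (design \(T\)), \(\alpha\) and \(\delta\) are random additive and
dominance effects of all structure SNPs with
\(\alpha_j \sim N(0, \sigma^2_\alpha)\),
\(\delta_j \sim N(0, \sigma^2_\delta)\) (columns of \(M_\alpha\) are
dosages 0/1/2, columns of \(M_\delta\) the heterozygote indicator 0/1/0),
and \(e_i \sim N(0, \sigma^2_e / w_i)\). The weight \(w_i\) is the number
of test-day records aggregated into animal \(i\)'s yield deviation, so the
residual covariance is heteroscedastic by information content.

Fitting this jointly for millions of variants is infeasible, so the
two-step strategy samples the nuisance terms once: the model without
\(Tb\) is sampled by single-site Gibbs (BayesC0: every SNP fitted, common
effect variances, scaled-inverse-\(\chi^2\) updates for the three
variances), and a configurable number of retained draws
\((\mu, \alpha, \delta, \sigma^2_e)^{(t)}\) defines, for each 10-Mb
segment \(s\), adjusted phenotypes

\[
\tilde y^{(s,t)} = y - 1\mu^{(t)}
  - \sum_{j \notin s} \bigl( m_{\alpha j}\alpha_j^{(t)}
  + m_{\delta j}\delta_j^{(t)} \bigr).
\]

Leaving the focal segment out keeps a local QTL's signal from being
absorbed (shrunk) by the genome-wide adjustment; `test-adjust.R`
demonstrates that property directly. For each test variant the weighted
class means of \(\tilde y^{(s(v),t)}\) are computed per sample and a draw
\(b^{(t)} \sim N(\hat b^{(t)}, (T'R^{-1}T)^{-1}\sigma_e^{2(t)})\) taken;
the contrast chains

\[
a^{(t)} = \tfrac12 (b_2 - b_0)^{(t)}, \qquad
d^{(t)} = b_1^{(t)} - \tfrac12 (b_0 + b_2)^{(t)},
\]

plus the weighted dosage-slope contrast, are summarised by their means and
SDs; \(z = \text{mean}/\text{SD}\) is referred to the standard normal.
Because each draw combines within-sample estimation error with
between-sample adjustment uncertainty, the chain SD is an honest (slightly
conservative) standard error — on a pure-noise simulation the observed
dominance z-scores have SD \(\approx 0.91\).

Significance is controlled per trait by Storey q-values at FDR
\(10^{-3}\); called loci additionally need \(\max(|a|, |d|)\) above 5% of
the phenotypic SD. The dominance coefficient \(k = d/|a|\) classifies the
mode of action: \(|k| \le 0.1\) additive, \(0.1 < |k| < 0.7\) partial
dominance, \(0.7 < |k| < 1.3\) the recessive window, \(|k| \ge 1.3\)
over-dominance (negative \(k\) is mirrored; all edges configurable).

### Why dominance mapping needs dense, well-imputed variants

If a tag variant has allelic correlation \(R^2\) with a causal variant,
the additive variance it captures shrinks by \(R^2\) but the dominance
variance shrinks by \(R^4\); and under Hardy–Weinberg the expected number
of rare-allele homozygotes is \(q^2 N\) (one homozygote among 10,000
animals at 1% MAF). Both facts are exercised as tests
(`expectedHomCount()`, the LD-law block in `test-acceptance.R`): recessive
scans need both very large samples and tags in near-perfect LD with the
causal alleles.

## A small worked run

```{r smoke, eval = FALSE}
cfg <- runConfig(
  outDir = "run1", seed = 1,
  population = populationConfig(nAnimals = 2000, nStructureSnps = 300,
                                nDenseVariants = 1500, nChromosomes = 2,
                                chromLengthBp = 4e7, seed = 1),
  qtl = list(qtlSpec("1", 5e6, mafTarget = 0.1, aTrue = -1, dTrue = 1)),
  gibbs = gibbsConfig(nRetained = 50, burnIn = 100, thin = 1, seed = 1))
state <- runPipeline(cfg)
subset(state$assoc, called)
```

## The synthetic-data generator

The generator emulates the population structure the method assumes, not
any particular herd:

* **Two breed pools plus crossbreds.** Founder haplotype panels (default
  100 per pool) are built by sequential copy-with-switch: each new
  haplotype copies a random earlier one, switching template at a per-bp
  rate and re-drawing alleles from the base frequency with probability
  `ldDepth`. Small `ldDepth` gives deep shared ancestry, blocky LD and a
  rare-skewed frequency spectrum. Pool frequencies diverge by a
  Balding–Nichols perturbation (`divergence`, an \(F_{ST}\) analogue,
  default 0.05 — typical of Holstein–Friesian vs Jersey). Animals draw two
  founder-mosaic gametes with crossovers at 1 cM/Mb; crossbreds draw each
  gamete from pool A with their ancestry fraction (¼, ½ or ¾) as the
  probability.
* **Planted QTL** fix their founder allele counts exactly, so the realised
  population MAF is binomial around the target; genetic values use class
  deviations \((-a, d, +a)\), i.e. a fully recessive deficit \(D\) is
  \(a = -D, d = +D\) (\(k = 1\)).
* **Phenotypes** are yield deviations \(y = g + u + v + \bar e\): additive
  (\(u\)) and dominance (\(v\)) polygenic values built from the structure
  SNPs — i.i.d. effects on standardised additive codes and on the raw
  orthogonal dominance class codes, so \(\mathrm{Var}(u) \propto G_a\) and
  \(\mathrm{Var}(v) \propto G_d\), the architecture GREMLd models — and
  \(\bar e\) the mean of \(w\) test-day residuals with
  \(\mathrm{Var}(\bar e_i) = \sigma^2_e / w_i\); record counts are shifted
  Poisson (default mean 9, about one herd test per month of a 268-day
  lactation). Components are orthogonalised and exactly rescaled so the
  realised variance fractions equal the targets (defaults
  \(h^2 = 0.296\), \(\delta^2 = 0.044\), the Holstein–Friesian milk-volume
  point of the heritability analysis); with constant \(w\) the component
  variances add exactly to the phenotypic variance.

### What the simulator does *not* reproduce

Real data differ in ways that matter for interpretation: genotyping error
and imputation error correlated with allele frequency (DR² is simulated
independently of the genotypes because only the filter behaviour is in
scope), pedigree and herd structure beyond two pools, selection, multi-trait
correlations, and a polygenic architecture spread over millions of causal
variants. Passing tests demonstrate the statistical machinery is correct
under the stated model, not that any particular field dataset will behave
identically.

### Polygenic leakage through the LOSO window

One property of the simulated architecture deserves emphasis because it
shaped the validation design. The generator concentrates *all* polygenic
variance on the structure SNPs, and the dense panel tags local ancestry
almost perfectly. Since LOSO deliberately leaves each segment's own
polygenic contribution unadjusted, dense variants that proxy local
ancestry show genuine association — including genuine dominance signal
where breed structure makes genotype classes nonlinear in ancestry. At
n = 10,000 with the default \(\delta^2 = 0.044\) background and *no*
planted QTL, on the order of a hundred variants reach
\(q_d < 10^{-3}\) — and they are true signals of that architecture, not
false positives. Calibration of the test statistics and of the q-value
machinery is therefore checked on a genetic-signal-free null
(\(h^2 = \delta^2 = 0\)), where the dominance z-scores are near-standard
(SD ≈ 0.91) and essentially nothing clears the FDR; planted-QTL recovery
runs keep the full polygenic background. The same separation is used for
the conditioning tests, which count planted loci exactly.

## Numerical choices

* **Gibbs sampler.** Priors are scaled inverse-\(\chi^2\) with 4 df;
  scales derive from an assumed 45/5/50 split of phenotypic variance into
  SNP-additive/SNP-dominance/residual, translated to per-SNP scales via
  the panel heterozygosity. Defaults retain 500 thinned draws (burn-in
  1,000, thin 10); the large validation runs in the test suite use 50
  retained draws after 100 burn-in sweeps, which at z ≈ 10 for the planted
  loci leaves chain-length noise immaterial. Convergence of the three
  variance chains is monitored by the Geweke diagnostic (first 10% vs last
  50%, AR-spectral variance at frequency zero, |z| > 2 flags).
* **Zero-variance SNPs** are pinned to effect 0; missing dosages are
  mean-imputed to the nearest hard call at model-fitting time only, never
  during QC.
* **Segments.** A 1-based position \(p\) belongs to the tile
  \(\lfloor (p-1)/10^7 \rfloor\) of its chromosome (half-open tiling on
  0-based coordinates); the last tile is truncated.
* **REML.** Average-information iterations with an active-set treatment of
  boundary components, step-halving, and an EM fallback (monotone in the
  restricted likelihood) whenever the AI proposal fails; components are
  constrained non-negative by projection onto a small positive boundary,
  which is how a zero heritability estimate is reported. SEs come from the
  inverse AI matrix with the delta method for \(h^2\) and \(\delta^2\).
* **Filters** use strict inequalities exactly as stated (missingness
  > 0.01, MAF < 0.02, HWE deviation > 0.15, DR² < 0.9 / < 0.7, prune
  R² > 0.9, hom-alt count ≤ 5). The Hardy–Weinberg filter is a
  heterozygote-frequency deviation (|observed − 2pq| per breed stratum,
  maximum over strata), not a test p-value: 0.15 is far too large for a
  p-value at these sample sizes and sits naturally on the frequency scale.
* **LD pruning** is greedy left-to-right by position, keeping the
  higher-MAF member of each offending pair.
* **Empty genotype classes.** Variants missing a homozygote (or the
  heterozygote) class keep whatever contrasts remain defined — the dosage
  slope survives with two classes — and are excluded from dominance
  calling.
* **Conditioning** (iterative scan) fits the genotype-class indicators of
  all conditioned variants jointly by WLS per posterior sample and
  subtracts the fitted values; stepwise additive tagging conditions on tag
  dosages instead, and its test statistic comes from the per-sample chains
  — a mean-phenotype shortcut would ignore between-sample adjustment
  uncertainty and over-call ancestry-proxy variants.

## Design decisions taken where the method left room

* The standard-additive effect is the weighted regression slope of the
  class effects on dosage, evaluated per posterior sample as a linear
  contrast of \(b^{(t)}\).
* Iterations of the conditional scan re-run only the association step; the
  genome-wide adjustment is not re-sampled.
* GREML ignores the record-count weights (homoscedastic residual), and
  heritability estimation is intended for within-breed subsets: across
  breeds, Wahlund excess homozygosity inflates the GRM diagonals (mean
  diagonal ≈ 1.14 in the default mixed simulation) and biases both ratios
  downward, which is presumably why the original analysis estimated
  within pure breeds.
* Additive tag selection is genotype-level stepwise conditioning: with
  genotypes in hand there is no reason to approximate joint fits through
  summary statistics and an external LD reference.
* The q-value \(\hat\pi_0\) smoother is a df-3 spline over
  \(\lambda \in \{0.05, \dots, 0.95\}\) evaluated at \(\lambda = 0.95\),
  clamped to (0, 1]; with fewer than 100 p-values \(\hat\pi_0\) is fixed
  at 1.
* The report's MAF-versus-effect table lists *called* (dominance-FDR)
  QTL; purely additive planted loci have \(d \approx 0\) and by
  construction cannot enter a table gated on the dominance FDR.

## Known limitations

* The association sampler treats the retained Gibbs draws as exchangeable
  plausible adjustments; it does not propagate uncertainty in the segment
  plan or in marker QC.
* The chain SD slightly over-estimates the sampling SE (conservative
  p-values) because adjustment noise enters twice for variants in strong
  LD with structure SNPs.
* GREMLd is dense linear algebra: practical to a few thousand animals per
  fit, which matches its role here (validating variance components on
  subsets), not national-scale evaluation.
* Only biallelic variants are handled; multi-allelic records are rejected
  at input.

## Problem sizes used by the validation suite

Parameter recovery runs at n = 20,000 animals (2,000 structure SNPs,
20,000 test variants, 20 replicates), null calibration at n = 10,000
(10,000 variants, 20 replicates), heritability recovery at n = 2,000 with
5,000 SNPs, and the LD-law checks at n = 50,000 haplotype-level
simulations. These sizes were chosen so the planted effects sit well above
their detection thresholds while a full suite remains runnable on a single
CPU.
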