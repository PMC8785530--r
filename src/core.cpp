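#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Founder haplotype panel by sequential copy-with-switch ("copying with error").
// Haplotype 0 is drawn site-wise Bernoulli(baseFreq); haplotype k copies a
// uniformly chosen earlier haplotype, switching template with probability
// gapSwitch[v-1] between adjacent sites (1 at chromosome starts) and redrawing
// the allele from Bernoulli(baseFreq[v]) with probability redraw. Small
// redraw => deep coalescence => strong blocky LD.
// Returns V x F 0/1 integer matrix (sites in rows, haplotypes in columns).
// [[Rcpp::export]]
IntegerMatrix cpp_sim_pool(NumericVector baseFreq, int nHap,
                           NumericVector gapSwitch, double redraw) {
  const int V = baseFreq.size();
  IntegerMatrix H(V, nHap);
  for (int v = 0; v < V; ++v)
    H(v, 0) = (unif_rand() < baseFreq[v]) ? 1 : 0;
  for (int k = 1; k < nHap; ++k) {
    int tmpl = (int)(unif_rand() * k);
    if (tmpl >= k) tmpl = k - 1;
    for (int v = 0; v < V; ++v) {
      if (v > 0 && unif_rand() < gapSwitch[v - 1]) {
        tmpl = (int)(unif_rand() * k);
        if (tmpl >= k) tmpl = k - 1;
      }
      if (unif_rand() < redraw)
        H(v, k) = (unif_rand() < baseFreq[v]) ? 1 : 0;
      else
        H(v, k) = H(v, tmpl);
    }
  }
  return H;
}

// One gamete: mosaic of pool haplotypes with crossovers as an exponential
// process along bp. Writes alleles into out[0..V-1].
static void mosaic_gamete(const int *pool, int V, int F,
                          const double *pos, const int *chromStart, int nChrom,
                          double recRate, int *out) {
  for (int c = 0; c < nChrom; ++c) {
    int lo = chromStart[c];
    int hi = (c + 1 < nChrom) ? chromStart[c + 1] : V;
    int f = (int)(unif_rand() * F); if (f >= F) f = F - 1;
    if (recRate <= 0.0) {
      for (int v = lo; v < hi; ++v) out[v] = pool[v + (size_t)V * f];
      continue;
    }
    double nextX = pos[lo] + exp_rand() / recRate;
    for (int v = lo; v < hi; ++v) {
      while (pos[v] >= nextX) {
        int fn = (int)(unif_rand() * F); if (fn >= F) fn = F - 1;
        f = fn;
        nextX += exp_rand() / recRate;
      }
      out[v] = pool[v + (size_t)V * f];
    }
  }
}

// Diploid dosage genotypes for n animals. Each animal draws two gametes;
// each gamete comes from pool A with probability probA[i], else pool B.
// Gametes are built variant-contiguously into a small block buffer and
// scattered into the animals x variants output in cache-friendly tiles.
// Returns animals x variants integer dosage matrix (0/1/2).
// [[Rcpp::export]]
IntegerMatrix cpp_sim_genotypes(IntegerMatrix poolA, IntegerMatrix poolB,
                                NumericVector probA, NumericVector pos,
                                IntegerVector chromStart, double recRate) {
  const int V = poolA.nrow(), FA = poolA.ncol(), FB = poolB.ncol();
  const int n = probA.size(), nChrom = chromStart.size();
  const int B = 32;
  IntegerMatrix G(n, V);
  int *g = G.begin();
  std::vector<int> g1(V), g2(V);
  std::vector<int> buf((size_t)V * B);
  std::vector<int> cs(chromStart.begin(), chromStart.end());
  const int *pa = poolA.begin(); const int *pb = poolB.begin();
  for (int i0 = 0; i0 < n; i0 += B) {
    int nb = std::min(B, n - i0);
    for (int b = 0; b < nb; ++b) {
      int i = i0 + b;
      bool a1 = unif_rand() < probA[i];
      bool a2 = unif_rand() < probA[i];
      mosaic_gamete(a1 ? pa : pb, V, a1 ? FA : FB, pos.begin(), cs.data(),
                    nChrom, recRate, g1.data());
      mosaic_gamete(a2 ? pa : pb, V, a2 ? FA : FB, pos.begin(), cs.data(),
                    nChrom, recRate, g2.data());
      int *col = buf.data() + (size_t)V * b;
      for (int v = 0; v < V; ++v) col[v] = g1[v] + g2[v];
    }
    for (int v = 0; v < V; ++v) {
      int *dst = g + i0 + (size_t)n * v;
      const int *src = buf.data() + v;
      for (int b = 0; b < nb; ++b) dst[b] = src[(size_t)V * b];
    }
  }
  return G;
}

// BayesC0 single-site Gibbs sampler for y = 1*mu + Ma*alpha + Md*delta + e,
// alpha_j ~ N(0, s2a), delta_j ~ N(0, s2d) (all effects fitted, common
// variances), e_i ~ N(0, s2e / w_i). Variances get scaled-inverse-chi-square
// updates with prior (df0, scale0). M holds 0/1/2 dosages; the dominance
// covariate is the heterozygote indicator derived from M (het animals are
// pre-indexed per SNP so the dominance pass touches only heterozygotes).
// [[Rcpp::export]]
List cpp_gibbs_c0(NumericVector y, NumericVector w, IntegerMatrix M,
                  int burnin, int thin, int nRetain,
                  NumericVector df0, NumericVector scale0,
                  double s2aInit, double s2dInit, double s2eInit,
                  bool fitDominance = true, bool updateVariances = true) {
  const int n = y.size(), p = M.ncol();
  const int nIter = burnin + thin * nRetain;
  std::vector<double> e(n), alpha(p, 0.0), delta(p, 0.0);
  std::vector<double> xd(std::size_t(n) * p);   // dosages as doubles
  std::vector<double> cxa(p), cxd(p);
  std::vector<bool> pinned(p, false);
  std::vector<int> hetStart(p + 1, 0);
  double mu = 0.0, sw = 0.0, swy = 0.0;
  for (int i = 0; i < n; ++i) { sw += w[i]; swy += w[i] * y[i]; }
  mu = swy / sw;
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  int pEffA = 0, pEffD = 0;
  std::vector<int> hetIdx;
  hetIdx.reserve((size_t)n * p / 3);
  for (int j = 0; j < p; ++j) {
    const int *x = &M(0, j);
    double *xj = xd.data() + (size_t)n * j;
    double ca = 0.0, cd = 0.0, swj = 0.0;
    int first = x[0]; bool novar = true;
    for (int i = 0; i < n; ++i) {
      xj[i] = (double)x[i];
      ca += w[i] * xj[i] * xj[i];
      if (x[i] == 1) { cd += w[i]; hetIdx.push_back(i); }
      swj += w[i];
      if (x[i] != first) novar = false;
    }
    hetStart[j + 1] = (int)hetIdx.size();
    pinned[j] = novar;
    cxa[j] = ca; cxd[j] = cd;
    if (!novar) { ++pEffA; if (cd > 0 && cd < swj) ++pEffD; }
  }
  double s2a = s2aInit, s2d = s2dInit, s2e = s2eInit;

  NumericVector muChain(nRetain), vaChain(nRetain), vdChain(nRetain), veChain(nRetain);
  NumericMatrix aChain(p, nRetain), dChain(p, nRetain);
  const double *wp = w.begin();

  int kept = 0;
  for (int it = 0; it < nIter; ++it) {
    // mean
    double r = 0.0;
    for (int i = 0; i < n; ++i) r += wp[i] * e[i];
    double muNew = mu + r / sw + norm_rand() * std::sqrt(s2e / sw);
    double dmu = muNew - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = muNew;
    // SNP effects
    for (int j = 0; j < p; ++j) {
      if (pinned[j]) continue;
      const double *xj = xd.data() + (size_t)n * j;
      // additive: branch-free weighted dot and axpy, auto-vectorisable
      {
        double rhs = 0.0;
        for (int i = 0; i < n; ++i) rhs += wp[i] * xj[i] * e[i];
        rhs += cxa[j] * alpha[j];
        double lhs = cxa[j] + s2e / s2a;
        double anew = rhs / lhs + std::sqrt(s2e / lhs) * norm_rand();
        double da = anew - alpha[j];
        for (int i = 0; i < n; ++i) e[i] -= da * xj[i];
        alpha[j] = anew;
      }
      // dominance: only heterozygotes enter
      if (fitDominance && cxd[j] > 0.0) {
        const int *hi = hetIdx.data() + hetStart[j];
        const int nh = hetStart[j + 1] - hetStart[j];
        double rhs = 0.0;
        for (int k = 0; k < nh; ++k) rhs += wp[hi[k]] * e[hi[k]];
        rhs += cxd[j] * delta[j];
        double lhs = cxd[j] + s2e / s2d;
        double dnew = rhs / lhs + std::sqrt(s2e / lhs) * norm_rand();
        double dd = dnew - delta[j];
        for (int k = 0; k < nh; ++k) e[hi[k]] -= dd;
        delta[j] = dnew;
      }
    }
    // variances (scaled inverse chi-square full conditionals)
    if (updateVariances) {
      double ssa = 0.0, ssd = 0.0, sse = 0.0;
      for (int j = 0; j < p; ++j) { ssa += alpha[j] * alpha[j]; ssd += delta[j] * delta[j]; }
      for (int i = 0; i < n; ++i) sse += wp[i] * e[i] * e[i];
      s2a = (ssa + df0[0] * scale0[0]) / Rf_rchisq(df0[0] + pEffA);
      s2d = (ssd + df0[1] * scale0[1]) / Rf_rchisq(df0[1] + pEffD);
      s2e = (sse + df0[2] * scale0[2]) / Rf_rchisq(df0[2] + n);
    }

    if (it >= burnin && ((it - burnin + 1) % thin) == 0 && kept < nRetain) {
      muChain[kept] = mu; vaChain[kept] = s2a; vdChain[kept] = s2d; veChain[kept] = s2e;
      std::memcpy(&aChain(0, kept), alpha.data(), sizeof(double) * p);
      std::memcpy(&dChain(0, kept), delta.data(), sizeof(double) * p);
      ++kept;
    }
  }
  return List::create(_["mu"] = muChain, _["alpha"] = aChain, _["delta"] = dChain,
                      _["varAlpha"] = vaChain, _["varDelta"] = vdChain,
                      _["varE"] = veChain);
}

// Genotype-class effect chains for a set of variants against one LOSO-adjusted
// phenotype matrix. Yt is T x n (posterior samples in rows, animals in
// columns). For each variant and each sample t the weighted class means
// bhat_g are computed and b_g drawn from N(bhat_g, varE[t] / sum_{i in g} w_i);
// contrasts a = (b2-b0)/2, d = b1-(b0+b2)/2 and the weighted dosage-slope
// contrast alpha are accumulated into chain means/SDs.
// Returns one row per variant:
// n0 n1 n2 nmiss aMean aSd dMean dSd alMean alSd
// [[Rcpp::export]]
NumericMatrix cpp_scan_class_effects(IntegerMatrix G, IntegerVector cols,
                                     NumericMatrix Yt, NumericVector w,
                                     NumericVector varE) {
  const int n = G.nrow(), T = Yt.nrow(), nv = cols.size();
  if (Yt.ncol() != n) stop("Yt must be T x n");
  // weighted totals over all animals
  std::vector<double> tot(T, 0.0);
  double totw = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *yc = &Yt(0, i);
    double wi = w[i];
    totw += wi;
    for (int t = 0; t < T; ++t) tot[t] += wi * yc[t];
  }
  NumericMatrix out(nv, 10);
  std::vector<int> idx1, idx2, idxm;
  idx1.reserve(n); idx2.reserve(n); idxm.reserve(n);
  std::vector<double> S1(T), S2(T), Sm(T);
  for (int vi = 0; vi < nv; ++vi) {
    int j = cols[vi];
    const int *x = &G(0, j);
    idx1.clear(); idx2.clear(); idxm.clear();
    double sw1 = 0.0, sw2 = 0.0, swm = 0.0;
    for (int i = 0; i < n; ++i) {
      int g = x[i];
      if (g == NA_INTEGER) { idxm.push_back(i); swm += w[i]; }
      else if (g == 1) { idx1.push_back(i); sw1 += w[i]; }
      else if (g == 2) { idx2.push_back(i); sw2 += w[i]; }
    }
    std::fill(S1.begin(), S1.end(), 0.0);
    std::fill(S2.begin(), S2.end(), 0.0);
    std::fill(Sm.begin(), Sm.end(), 0.0);
    for (size_t k = 0; k < idx1.size(); ++k) {
      int i = idx1[k]; const double *yc = &Yt(0, i); double wi = w[i];
      for (int t = 0; t < T; ++t) S1[t] += wi * yc[t];
    }
    for (size_t k = 0; k < idx2.size(); ++k) {
      int i = idx2[k]; const double *yc = &Yt(0, i); double wi = w[i];
      for (int t = 0; t < T; ++t) S2[t] += wi * yc[t];
    }
    for (size_t k = 0; k < idxm.size(); ++k) {
      int i = idxm[k]; const double *yc = &Yt(0, i); double wi = w[i];
      for (int t = 0; t < T; ++t) Sm[t] += wi * yc[t];
    }
    int n1 = idx1.size(), n2 = idx2.size(), nm = idxm.size();
    int n0 = n - n1 - n2 - nm;
    double sw0 = totw - sw1 - sw2 - swm;
    bool has0 = n0 > 0, has1 = n1 > 0, has2 = n2 > 0;
    int nocc = (int)has0 + (int)has1 + (int)has2;
    double sa = 0, ssa = 0, sd_ = 0, ssd = 0, sal = 0, ssal = 0;
    bool aOk = has0 && has2, dOk = has0 && has1 && has2, alOk = nocc >= 2;
    for (int t = 0; t < T; ++t) {
      double ve = varE[t];
      double b0 = NA_REAL, b1 = NA_REAL, b2 = NA_REAL;
      if (has0) b0 = (tot[t] - S1[t] - S2[t] - Sm[t]) / sw0 +
        norm_rand() * std::sqrt(ve / sw0);
      if (has1) b1 = S1[t] / sw1 + norm_rand() * std::sqrt(ve / sw1);
      if (has2) b2 = S2[t] / sw2 + norm_rand() * std::sqrt(ve / sw2);
      if (aOk) { double a = 0.5 * (b2 - b0); sa += a; ssa += a * a; }
      if (dOk) { double d = b1 - 0.5 * (b0 + b2); sd_ += d; ssd += d * d; }
      if (alOk) {
        double W[3] = { has0 ? sw0 : 0.0, has1 ? sw1 : 0.0, has2 ? sw2 : 0.0 };
        double b[3] = { b0, b1, b2 };
        double Wt = W[0] + W[1] + W[2];
        double xbar = (W[1] + 2.0 * W[2]) / Wt;
        double Sxx = 0.0, num = 0.0;
        for (int g = 0; g < 3; ++g) if (W[g] > 0) {
          double xc = g - xbar;
          Sxx += W[g] * xc * xc;
          num += W[g] * xc * b[g];
        }
        double al = num / Sxx;
        sal += al; ssal += al * al;
      }
    }
    double Td = (double)T;
    double aM = aOk ? sa / Td : NA_REAL;
    double aS = aOk ? std::sqrt(std::max(0.0, (ssa - Td * aM * aM) / (Td - 1))) : NA_REAL;
    double dM = dOk ? sd_ / Td : NA_REAL;
    double dS = dOk ? std::sqrt(std::max(0.0, (ssd - Td * dM * dM) / (Td - 1))) : NA_REAL;
    double alM = alOk ? sal / Td : NA_REAL;
    double alS = alOk ? std::sqrt(std::max(0.0, (ssal - Td * alM * alM) / (Td - 1))) : NA_REAL;
    out(vi, 0) = n0; out(vi, 1) = n1; out(vi, 2) = n2; out(vi, 3) = nm;
    out(vi, 4) = aM; out(vi, 5) = aS; out(vi, 6) = dM; out(vi, 7) = dS;
    out(vi, 8) = alM; out(vi, 9) = alS;
  }
  return out;
}
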