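// Gibbs kernels for the tree-guided latent factor model, its flat variant,
// the LDA baseline, held-out topic-weight inference, and the Monte-Carlo
// predictive likelihood.  Randomness comes from an embedded PCG32 stream so
// chains are reproducible from a single integer seed, independent of R's
// generator state.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// PCG32 (O'Neill): 64-bit state, 32-bit output
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  double unif() {               // in (0, 1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
  double normal() {             // Box-Muller
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  double gammaDraw(double a) {  // Marsaglia-Tsang; boost for a < 1
    if (a < 1.0) {
      double u = unif();
      return gammaDraw(a + 1.0) * std::pow(u, 1.0 / a);
    }
    double d = a - 1.0 / 3.0, c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = normal();
      double v = 1.0 + c * x;
      if (v <= 0.0) continue;
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v)))
        return d * v;
    }
  }
  double betaDraw(double a, double b) {
    double x = gammaDraw(a), y = gammaDraw(b);
    return x / (x + y);
  }
};

static const double PHI_EPS = 1e-12;

static inline double clampProb(double p) {
  if (p < PHI_EPS) return PHI_EPS;
  if (p > 1.0 - PHI_EPS) return 1.0 - PHI_EPS;
  return p;
}

// ---------------------------------------------------------------------------
// Full systematic-scan sampler.  Tree encoding: nodes 0..M-1 topological,
// node 0 the root; parent[n] is the parent index (-1 for root); children in
// CSR (childStart, childList); codeIdx[n] is the W column of node n or -1.
// State matrices: Z (D x S), I (K x (M-1), column n-1 for node n),
// phi (K x S).  Update order within a sweep: Z -> I -> phi -> rho.
// Samples are collected after the sweeps listed in collectAt (1-based);
// collectFull = false stores only the count tables N (for EM E-steps).
// [[Rcpp::export]]
List cpp_gibbs_run(IntegerMatrix W,
                   IntegerVector parent, IntegerVector childStart,
                   IntegerVector childList, IntegerVector codeIdx,
                   NumericVector alpha,
                   NumericVector betaA, NumericVector betaI,
                   NumericVector rho01Prior, NumericVector rho11Prior,
                   IntegerMatrix Z0, IntegerMatrix I0, NumericMatrix phi0,
                   double rho01_0, double rho11_0,
                   int nSweeps, IntegerVector collectAt, bool collectFull,
                   int seed, bool collectZ = false) {
  const int D = W.nrow(), S = W.ncol(), K = alpha.size();
  const int M = parent.size();            // nodes incl. root
  const int NR = M - 1;                   // non-root nodes
  Pcg32 rng((uint64_t)seed);

  std::vector<int> Z(Z0.begin(), Z0.end());          // D x S, 0-based topics
  std::vector<int> I(I0.begin(), I0.end());          // K x NR
  std::vector<double> phi(phi0.begin(), phi0.end()); // K x S
  double rho01 = rho01_0, rho11 = rho11_0;
  for (int i = 0; i < K * S; ++i) phi[i] = clampProb(phi[i]);

  // code node -> column lookup and reverse
  std::vector<int> codeNode(S, -1);
  for (int n = 0; n < M; ++n)
    if (codeIdx[n] >= 0) codeNode[codeIdx[n]] = n;

  // count tables; Ad holds N_dk + alpha_k as doubles (K x D)
  std::vector<double> Ad((size_t)K * D);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) Ad[k + (size_t)K * d] = alpha[k];
  std::vector<int> Nks(K * S, 0);        // K x S assignments per (topic,code)
  std::vector<int> C1(K * S, 0);         // of which W == 1
  const int *Wp = W.begin();
  for (int s = 0; s < S; ++s)
    for (int d = 0; d < D; ++d) {
      int k = Z[d + (size_t)D * s];
      Ad[k + (size_t)K * d] += 1.0;
      Nks[k + (size_t)K * s]++;
      C1[k + (size_t)K * s] += Wp[d + (size_t)D * s];
    }

  const double aA = betaA[0], bA = betaA[1], aI = betaI[0], bI = betaI[1];
  const double lbA = R::lbeta(aA, bA), lbI = R::lbeta(aI, bI);

  std::vector<double> tab1(K * S), tab0(K * S); // phi, 1 - phi
  std::vector<double> cum(K);

  List samples(collectAt.size());
  int nextCollect = 0;

  for (int sweep = 1; sweep <= nSweeps; ++sweep) {
    // --- Z: partially collapsed conditional.  Ad caches N_dk + alpha_k
    // as doubles; Nks/C1 are rebuilt in one pass after the scan.
    for (int i = 0; i < K * S; ++i) { tab1[i] = phi[i]; tab0[i] = 1.0 - phi[i]; }
    for (int s = 0; s < S; ++s) {
      const double *t1 = &tab1[(size_t)K * s], *t0 = &tab0[(size_t)K * s];
      const int *Wcol = &Wp[(size_t)D * s];
      int *Zcol = &Z[(size_t)D * s];
      if (K == 4) {               // unrolled fast path (simulation studies)
        for (int d = 0; d < D; ++d) {
          int kOld = Zcol[d];
          double *ad = &Ad[4 * (size_t)d];
          ad[kOld] -= 1.0;
          const double *tab = Wcol[d] ? t1 : t0;
          double c0 = ad[0] * tab[0];
          double c1 = c0 + ad[1] * tab[1];
          double c2 = c1 + ad[2] * tab[2];
          double tot = c2 + ad[3] * tab[3];
          if (!(tot > 0.0))
            stop("all-zero topic weights in the Z conditional; phi must be "
                 "clamped away from {0,1}");
          double u = rng.unif() * tot;
          int kNew = (u >= c0) + (u >= c1) + (u >= c2);
          Zcol[d] = kNew;
          ad[kNew] += 1.0;
        }
      } else {
        for (int d = 0; d < D; ++d) {
          int kOld = Zcol[d];
          double *ad = &Ad[(size_t)K * d];
          ad[kOld] -= 1.0;
          const double *tab = Wcol[d] ? t1 : t0;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            tot += ad[k] * tab[k];
            cum[k] = tot;
          }
          if (!(tot > 0.0))
            stop("all-zero topic weights in the Z conditional; phi must be "
                 "clamped away from {0,1}");
          double u = rng.unif() * tot;
          int kNew = 0;
          while (kNew < K - 1 && cum[kNew] < u) ++kNew;
          Zcol[d] = kNew;
          ad[kNew] += 1.0;
        }
      }
    }
    // rebuild per-(topic, code) assignment counts for the phi update
    std::fill(Nks.begin(), Nks.end(), 0);
    std::fill(C1.begin(), C1.end(), 0);
    for (int s = 0; s < S; ++s) {
      const int *Wcol = &Wp[(size_t)D * s];
      const int *Zcol = &Z[(size_t)D * s];
      int *NksS = &Nks[(size_t)K * s];
      int *C1S = &C1[(size_t)K * s];
      for (int d = 0; d < D; ++d) {
        NksS[Zcol[d]]++;
        C1S[Zcol[d]] += Wcol[d];
      }
    }

    // --- I: single-site Gibbs in topological order
    const double l11 = std::log(rho11), l10 = std::log1p(-rho11);
    const double l01 = std::log(rho01), l00 = std::log1p(-rho01);
    for (int k = 0; k < K; ++k) {
      for (int n = 1; n < M; ++n) {
        double lw1 = 0.0, lw0 = 0.0;
        int s = codeIdx[n];
        if (s >= 0) {
          double x = phi[k + (size_t)K * s];
          double lx = std::log(x), l1x = std::log1p(-x);
          lw1 += (aA - 1.0) * lx + (bA - 1.0) * l1x - lbA;
          lw0 += (aI - 1.0) * lx + (bI - 1.0) * l1x - lbI;
        }
        int pn = parent[n];
        int ps = (pn == 0) ? 0 : I[k + (size_t)K * (pn - 1)];
        if (ps == 1) { lw1 += l11; lw0 += l10; }
        else         { lw1 += l01; lw0 += l00; }
        for (int ci = childStart[n]; ci < childStart[n + 1]; ++ci) {
          int c = childList[ci];
          int cs = I[k + (size_t)K * (c - 1)];
          lw1 += (cs ? l11 : l10);
          lw0 += (cs ? l01 : l00);
        }
        double p1 = 1.0 / (1.0 + std::exp(lw0 - lw1));
        I[k + (size_t)K * (n - 1)] = (rng.unif() < p1) ? 1 : 0;
      }
    }

    // --- phi: Beta conjugate update per (topic, code)
    for (int s = 0; s < S; ++s) {
      int n = codeNode[s];
      for (int k = 0; k < K; ++k) {
        int act = I[k + (size_t)K * (n - 1)];
        int c1 = C1[k + (size_t)K * s];
        int c0 = Nks[k + (size_t)K * s] - c1;
        double a = (act ? aA : aI) + c1;
        double b = (act ? bA : bI) + c0;
        phi[k + (size_t)K * s] = clampProb(rng.betaDraw(a, b));
      }
    }

    // --- rho: pooled edge counts over all topics (root treated as state 0)
    {
      long n00 = 0, n01 = 0, n10 = 0, n11 = 0;
      for (int k = 0; k < K; ++k)
        for (int n = 1; n < M; ++n) {
          int pn = parent[n];
          int ps = (pn == 0) ? 0 : I[k + (size_t)K * (pn - 1)];
          int cs = I[k + (size_t)K * (n - 1)];
          if (ps == 0) { if (cs) ++n01; else ++n00; }
          else         { if (cs) ++n11; else ++n10; }
        }
      rho01 = rng.betaDraw(rho01Prior[0] + n01, rho01Prior[1] + n00);
      rho11 = rng.betaDraw(rho11Prior[0] + n11, rho11Prior[1] + n10);
      rho01 = clampProb(rho01);
      rho11 = clampProb(rho11);
    }

    // --- collection
    if (nextCollect < collectAt.size() && sweep == collectAt[nextCollect]) {
      IntegerMatrix Nout(D, K);
      for (int d = 0; d < D; ++d)
        for (int k = 0; k < K; ++k)
          Nout(d, k) = (int)std::lround(Ad[k + (size_t)K * d] - alpha[k]);
      if (collectFull) {
        NumericMatrix phiOut(K, S);
        std::copy(phi.begin(), phi.end(), phiOut.begin());
        IntegerMatrix Iout(K, NR);
        std::copy(I.begin(), I.end(), Iout.begin());
        List smp = List::create(
          _["phi"] = phiOut, _["I"] = Iout,
          _["rho"] = NumericVector::create(rho01, rho11),
          _["N"] = Nout);
        if (collectZ) {
          IntegerMatrix Zs(D, S);
          std::copy(Z.begin(), Z.end(), Zs.begin());
          smp["Z"] = Zs;
        }
        samples[nextCollect] = smp;
      } else {
        samples[nextCollect] = List::create(_["N"] = Nout);
      }
      ++nextCollect;
    }
  }

  IntegerMatrix Zout(D, S);
  std::copy(Z.begin(), Z.end(), Zout.begin());
  IntegerMatrix Iout(K, NR);
  std::copy(I.begin(), I.end(), Iout.begin());
  NumericMatrix phiOut(K, S);
  std::copy(phi.begin(), phi.end(), phiOut.begin());
  return List::create(_["Z"] = Zout, _["I"] = Iout, _["phi"] = phiOut,
                      _["rho01"] = rho01, _["rho11"] = rho11,
                      _["samples"] = samples);
}

// ---------------------------------------------------------------------------
// Held-out topic weights: Gibbs over Z only with phi and alpha fixed; theta
// computed from the count tables at each collected sample and averaged.
// [[Rcpp::export]]
NumericMatrix cpp_theta_infer(IntegerMatrix W, NumericMatrix phiFix,
                              NumericVector alpha,
                              int burnIn, int nSamples, int thin, int seed) {
  const int D = W.nrow(), S = W.ncol(), K = alpha.size();
  Pcg32 rng((uint64_t)seed);
  std::vector<double> phi(phiFix.begin(), phiFix.end());
  for (int i = 0; i < K * S; ++i) phi[i] = clampProb(phi[i]);
  const int *Wp = W.begin();

  std::vector<int> Z(D * S);
  std::vector<int> Ndk(K * D, 0);
  for (int s = 0; s < S; ++s)
    for (int d = 0; d < D; ++d) {
      int k = (int)(rng.unif() * K); if (k == K) k = K - 1;
      Z[d + (size_t)D * s] = k;
      Ndk[k + (size_t)K * d]++;
    }

  double sumAlpha = 0.0;
  for (int k = 0; k < K; ++k) sumAlpha += alpha[k];
  NumericMatrix thetaAcc(D, K);
  std::fill(thetaAcc.begin(), thetaAcc.end(), 0.0);
  std::vector<double> cum(K);

  int total = burnIn + (nSamples > 0 ? nSamples * thin : 0);
  int collected = 0;
  for (int sweep = 1; sweep <= total; ++sweep) {
    for (int s = 0; s < S; ++s)
      for (int d = 0; d < D; ++d) {
        size_t zi = d + (size_t)D * s;
        int kOld = Z[zi], w = Wp[zi];
        int *nd = &Ndk[(size_t)K * d];
        nd[kOld]--;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double f = w ? phi[k + (size_t)K * s] : 1.0 - phi[k + (size_t)K * s];
          tot += (nd[k] + alpha[k]) * f;
          cum[k] = tot;
        }
        double u = rng.unif() * tot;
        int kNew = 0;
        while (kNew < K - 1 && cum[kNew] < u) ++kNew;
        Z[zi] = kNew;
        nd[kNew]++;
      }
    if (sweep > burnIn && thin > 0 && (sweep - burnIn) % thin == 0) {
      for (int k = 0; k < K; ++k)
        for (int d = 0; d < D; ++d)
          thetaAcc(d, k) += (Ndk[k + (size_t)K * d] + alpha[k]) /
                            (S + sumAlpha);
      ++collected;
    }
  }
  if (collected > 0)
    for (int i = 0; i < D * K; ++i) thetaAcc[i] /= collected;
  return thetaAcc;
}

// ---------------------------------------------------------------------------
// Collapsed-Gibbs LDA over the bag of diagnosed codes.  Documents in CSR
// form: tokens[docStart[d]..docStart[d+1]) are 0-based code indices.
// [[Rcpp::export]]
List cpp_lda_chain(IntegerVector docStart, IntegerVector tokens,
                   int D, int S, int K,
                   NumericVector alpha, double eta,
                   int burnIn, int nSamples, int thin, int seed) {
  Pcg32 rng((uint64_t)seed);
  const int T = tokens.size();
  std::vector<int> z(T);
  std::vector<int> Ndk(D * K, 0), Mks(K * S, 0), Mk(K, 0);
  for (int d = 0; d < D; ++d)
    for (int t = docStart[d]; t < docStart[d + 1]; ++t) {
      int k = (int)(rng.unif() * K); if (k == K) k = K - 1;
      z[t] = k;
      Ndk[d + (size_t)D * k]++;
      Mks[k + (size_t)K * tokens[t]]++;
      Mk[k]++;
    }
  std::vector<double> cum(K);
  const double Seta = S * eta;
  int total = burnIn + (nSamples > 0 ? nSamples * thin : 0);
  List samples(nSamples);
  int collected = 0;
  for (int sweep = 1; sweep <= total; ++sweep) {
    for (int d = 0; d < D; ++d)
      for (int t = docStart[d]; t < docStart[d + 1]; ++t) {
        int s = tokens[t], kOld = z[t];
        Ndk[d + (size_t)D * kOld]--;
        Mks[kOld + (size_t)K * s]--;
        Mk[kOld]--;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          tot += (Ndk[d + (size_t)D * k] + alpha[k]) *
                 (Mks[k + (size_t)K * s] + eta) / (Mk[k] + Seta);
          cum[k] = tot;
        }
        double u = rng.unif() * tot;
        int kNew = 0;
        while (kNew < K - 1 && cum[kNew] < u) ++kNew;
        z[t] = kNew;
        Ndk[d + (size_t)D * kNew]++;
        Mks[kNew + (size_t)K * s]++;
        Mk[kNew]++;
      }
    if (sweep > burnIn && thin > 0 && (sweep - burnIn) % thin == 0 &&
        collected < nSamples) {
      NumericMatrix phiOut(K, S);
      for (int k = 0; k < K; ++k)
        for (int s = 0; s < S; ++s)
          phiOut(k, s) = (Mks[k + (size_t)K * s] + eta) / (Mk[k] + Seta);
      IntegerMatrix Nout(D, K);
      std::copy(Ndk.begin(), Ndk.end(), Nout.begin());
      samples[collected] = List::create(_["phi"] = phiOut, _["N"] = Nout);
      ++collected;
    }
  }
  return List::create(_["samples"] = samples);
}

// ---------------------------------------------------------------------------
// Monte-Carlo predictive likelihood: for each posterior sample of phi, M
// topic-weight draws theta ~ Dirichlet(alpha) approximate
//   p(W_d | phi, alpha) = E_theta [ prod_s Bern(W_ds | (theta . phi)_s) ],
// log-sum-exp stabilised; the per-individual log-likelihood is averaged
// over the phi samples.
// [[Rcpp::export]]
NumericVector cpp_predictive_loglik(IntegerMatrix W, List phiSamples,
                                    NumericVector alpha, int M, int seed) {
  const int D = W.nrow(), S = W.ncol(), K = alpha.size();
  const int nPhi = phiSamples.size();
  Pcg32 rng((uint64_t)seed);
  const int *Wp = W.begin();
  NumericVector out(D);
  std::vector<double> theta(M * K), L1(M * S), L0(M * S), ll(M);

  for (int ps = 0; ps < nPhi; ++ps) {
    NumericMatrix phi = phiSamples[ps];
    for (int m = 0; m < M; ++m) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = rng.gammaDraw(alpha[k]);
        theta[m + (size_t)M * k] = g;
        tot += g;
      }
      for (int k = 0; k < K; ++k) theta[m + (size_t)M * k] /= tot;
    }
    for (int s = 0; s < S; ++s)
      for (int m = 0; m < M; ++m) {
        double p = 0.0;
        for (int k = 0; k < K; ++k)
          p += theta[m + (size_t)M * k] * phi(k, s);
        p = clampProb(p);
        L1[m + (size_t)M * s] = std::log(p);
        L0[m + (size_t)M * s] = std::log1p(-p);
      }
    for (int d = 0; d < D; ++d) {
      std::fill(ll.begin(), ll.end(), 0.0);
      for (int s = 0; s < S; ++s) {
        const double *col = Wp[d + (size_t)D * s] ? &L1[(size_t)M * s]
                                                  : &L0[(size_t)M * s];
        for (int m = 0; m < M; ++m) ll[m] += col[m];
      }
      double mx = ll[0];
      for (int m = 1; m < M; ++m) if (ll[m] > mx) mx = ll[m];
      double sum = 0.0;
      for (int m = 0; m < M; ++m) sum += std::exp(ll[m] - mx);
      out[d] += mx + std::log(sum) - std::log((double)M);
    }
  }
  for (int d = 0; d < D; ++d) out[d] /= nPhi;
  return out;
}
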