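#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the admixture model with uncorrelated cluster allele
// frequencies: each individual i has membership vector Q_i over K
// clusters; each gene copy's cluster-of-origin Z is latent; cluster k
// carries per-locus allele frequencies P_kl. Conjugate updates throughout:
//   Z_{ilc} | Q,P  ~ Cat( Q_ik * P_kl[a_ilc] )
//   P_kl    | Z    ~ Dirichlet(lambda + origin-partitioned allele counts)
//   Q_i     | Z    ~ Dirichlet(alpha + per-individual origin counts)
// Missing calls (allele code 0) are skipped. Uses R's RNG, so a set.seed()
// in the calling R session makes the whole run deterministic.

static void rdirichlet_inplace(std::vector<double>& out,
                               const std::vector<double>& shape) {
  double s = 0.0;
  for (size_t a = 0; a < shape.size(); ++a) {
    out[a] = R::rgamma(shape[a], 1.0);
    s += out[a];
  }
  if (s <= 0) { // pathological underflow: fall back to uniform
    for (size_t a = 0; a < shape.size(); ++a) out[a] = 1.0 / shape.size();
    return;
  }
  for (size_t a = 0; a < shape.size(); ++a) out[a] /= s;
}

// [[Rcpp::export(name = ".gibbs_admixture_cpp")]]
List gibbs_admixture_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                         int K, double alpha, double lambda,
                         int burn_in, int iterations) {
  const int n = geno.nrow();
  const int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("geno must have 2 columns per locus");
  if (K < 1) stop("K must be >= 1");

  GetRNGstate();

  // P[k][l][a], Q[i][k], Z[i][2l+c]
  // P chains start at the empirical allele frequencies with Dirichlet
  // jitter: over-dispersed starts straight from the prior often strand
  // replicate chains in distinct modes within short desk-scale runs.
  std::vector<std::vector<std::vector<double>>> P(K);
  std::vector<std::vector<double>> emp(L);
  for (int l = 0; l < L; ++l) {
    emp[l].assign(n_alleles[l], 0.0);
    double tot = 0.0;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 2; ++c) {
        int a = geno(i, 2 * l + c);
        if (a > 0) { emp[l][a - 1] += 1.0; tot += 1.0; }
      }
    for (int a = 0; a < n_alleles[l]; ++a)
      emp[l][a] = (emp[l][a] + lambda) / (tot + lambda * n_alleles[l]);
  }
  for (int k = 0; k < K; ++k) {
    P[k].resize(L);
    for (int l = 0; l < L; ++l) {
      P[k][l].assign(n_alleles[l], 1.0 / n_alleles[l]);
      std::vector<double> shape(n_alleles[l]);
      for (int a = 0; a < n_alleles[l]; ++a)
        shape[a] = lambda + 10.0 * emp[l][a];
      rdirichlet_inplace(P[k][l], shape);
    }
  }
  std::vector<std::vector<double>> Q(n, std::vector<double>(K, 1.0 / K));
  std::vector<int> Z(n * 2 * L, 0);

  std::vector<std::vector<std::vector<double>>> Pcnt(K);
  for (int k = 0; k < K; ++k) {
    Pcnt[k].resize(L);
    for (int l = 0; l < L; ++l) Pcnt[k][l].assign(n_alleles[l], 0.0);
  }

  std::vector<double> Qsum(n * K, 0.0);
  std::vector<std::vector<std::vector<double>>> Psum(K);
  for (int k = 0; k < K; ++k) {
    Psum[k].resize(L);
    for (int l = 0; l < L; ++l) Psum[k][l].assign(n_alleles[l], 0.0);
  }
  NumericVector trace(iterations);

  std::vector<double> prob(K), qshape(K), qdraw(K);

  for (int t = 0; t < burn_in + iterations; ++t) {
    // --- Z given Q, P; accumulate allele counts and origin counts
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        std::fill(Pcnt[k][l].begin(), Pcnt[k][l].end(), 0.0);

    for (int i = 0; i < n; ++i) {
      std::vector<double> ocnt(K, 0.0);
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a <= 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q[i][k] * P[k][l][a - 1];
            s += prob[k];
          }
          int z = K - 1;
          if (s > 0) {
            double u = unif_rand() * s, acc = 0.0;
            for (int k = 0; k < K; ++k) {
              acc += prob[k];
              if (u <= acc) { z = k; break; }
            }
          } else {
            z = (int)(unif_rand() * K); if (z >= K) z = K - 1;
          }
          Z[(i * L + l) * 2 + c] = z;
          Pcnt[z][l][a - 1] += 1.0;
          ocnt[z] += 1.0;
        }
      }
      // --- Q_i given origin counts
      for (int k = 0; k < K; ++k) qshape[k] = alpha + ocnt[k];
      rdirichlet_inplace(qdraw, qshape);
      for (int k = 0; k < K; ++k) Q[i][k] = qdraw[k];
    }

    // --- P given Z
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        std::vector<double> shape(n_alleles[l]);
        for (int a = 0; a < n_alleles[l]; ++a)
          shape[a] = lambda + Pcnt[k][l][a];
        rdirichlet_inplace(P[k][l], shape);
      }
    }

    if (t >= burn_in) {
      // observed-data log-likelihood at the current (P, Q)
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        for (int l = 0; l < L; ++l) {
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a <= 0) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k) s += Q[i][k] * P[k][l][a - 1];
            ll += std::log(s > 0 ? s : 1e-300);
          }
        }
      }
      trace[t - burn_in] = ll;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum[i * K + k] += Q[i][k];
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
          for (int a = 0; a < n_alleles[l]; ++a)
            Psum[k][l][a] += P[k][l][a];
    }
  }

  // complete-data log-likelihood at the final state (for invariant checks)
  double cll = 0.0;
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l)
      for (int c = 0; c < 2; ++c) {
        int a = geno(i, 2 * l + c);
        if (a <= 0) continue;
        int z = Z[(i * L + l) * 2 + c];
        cll += std::log(Q[i][z] > 0 ? Q[i][z] : 1e-300) +
               std::log(P[z][l][a - 1] > 0 ? P[z][l][a - 1] : 1e-300);
      }

  PutRNGstate();

  NumericMatrix Qmean(n, K), Qfin(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) {
      Qmean(i, k) = Qsum[i * K + k] / iterations;
      Qfin(i, k) = Q[i][k];
    }
  List Pmean(K), Pfin(K);
  for (int k = 0; k < K; ++k) {
    List pk(L), pkf(L);
    for (int l = 0; l < L; ++l) {
      NumericVector v(n_alleles[l]), vf(n_alleles[l]);
      for (int a = 0; a < n_alleles[l]; ++a) {
        v[a] = Psum[k][l][a] / iterations;
        vf[a] = P[k][l][a];
      }
      pk[l] = v; pkf[l] = vf;
    }
    Pmean[k] = pk; Pfin[k] = pkf;
  }
  IntegerMatrix Zfin(n, 2 * L);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 2 * L; ++j) Zfin(i, j) = Z[(i * L + j / 2) * 2 + j % 2] + 1;
  // note: column order of Zfin is (l1c1, l1c2, l2c1, ...), matching geno

  return List::create(_["Q"] = Qmean, _["P"] = Pmean, _["trace"] = trace,
                      _["Q_final"] = Qfin, _["P_final"] = Pfin,
                      _["Z_final"] = Zfin,
                      _["complete_loglik_final"] = cll);
}
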