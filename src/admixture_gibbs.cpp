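// Gibbs sampler for the admixture model with population inbreeding.
//
// Data: N diploid individuals typed at L microsatellite loci; alleles are
// coded as 0-based indices per locus. Each population (cluster) k has its
// own allele frequencies p[k][l][.] and inbreeding coefficient f[k]; each
// individual i has membership proportions q[i][.] (Dirichlet(alpha) prior)
// and a per-locus origin z[i][l].
//
// Genotype probability given origin k at locus l:
//   homozygote aa:   f_k * p_a + (1 - f_k) * p_a^2
//   heterozygote ab: (1 - f_k) * 2 * p_a * p_b
//
// The f_k * p_a term is handled by data augmentation: each homozygous
// locus-genotype assigned to k carries an identity-by-descent indicator;
// conditional on the indicators every update is conjugate (categorical z,
// Dirichlet q and p, Beta f), so no proposal tuning is needed.
//
// All randomness goes through R's RNG, so set.seed() in R makes a chain
// exactly reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static const double P_FLOOR = 1e-9;

// one Dirichlet draw via gammas, with floor + renormalisation
static void rdirichlet_into(const std::vector<double> &shape, std::vector<double> &out) {
  double s = 0.0;
  for (size_t i = 0; i < shape.size(); ++i) {
    out[i] = R::rgamma(shape[i], 1.0);
    s += out[i];
  }
  if (s <= 0.0) s = 1.0;
  double s2 = 0.0;
  for (size_t i = 0; i < shape.size(); ++i) {
    out[i] = out[i] / s;
    if (out[i] < P_FLOOR) out[i] = P_FLOOR;
    s2 += out[i];
  }
  for (size_t i = 0; i < shape.size(); ++i) out[i] /= s2;
}

// [[Rcpp::export(name = ".admixture_gibbs")]]
List admixture_gibbs(IntegerMatrix a1, IntegerMatrix a2, IntegerVector n_alleles,
                     int K, int iterations, int burn_in, int thin,
                     double alpha, double freq_prior) {
  const int N = a1.nrow(), L = a1.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > N) stop("K exceeds the number of individuals");
  if (iterations <= burn_in) stop("iterations must exceed burn_in");

  RNGScope scope;

  // state
  std::vector<std::vector<std::vector<double> > > p(K);  // p[k][l][a]
  for (int k = 0; k < K; ++k) {
    p[k].resize(L);
    for (int l = 0; l < L; ++l) {
      std::vector<double> shape(n_alleles[l], 1.0);
      p[k][l].resize(n_alleles[l]);
      rdirichlet_into(shape, p[k][l]);
    }
  }
  std::vector<double> f(K);
  for (int k = 0; k < K; ++k) f[k] = R::runif(0.0, 1.0);
  NumericMatrix q(N, K);
  for (int i = 0; i < N; ++i) {
    std::vector<double> shape(K, alpha), row(K);
    rdirichlet_into(shape, row);
    for (int k = 0; k < K; ++k) q(i, k) = (K == 1) ? 1.0 : row[k];
  }
  IntegerMatrix z(N, L);
  IntegerMatrix ibd(N, L);  // meaningful only at homozygous locus-genotypes

  // accumulators
  NumericMatrix q_sum(N, K);
  std::vector<double> f_sum(K, 0.0);
  std::vector<std::vector<std::vector<double> > > p_sum(K);
  for (int k = 0; k < K; ++k) {
    p_sum[k].resize(L);
    for (int l = 0; l < L; ++l) p_sum[k][l].assign(n_alleles[l], 0.0);
  }
  std::vector<double> deviances;
  int n_saved = 0;

  std::vector<double> lik(K), zcnt(K), qshape(K), qrow(K);

  for (int it = 1; it <= iterations; ++it) {
    // --- z (and IBD indicator) per individual x locus ---
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        const int x = a1(i, l), y = a2(i, l);
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          const double pa = p[k][l][x];
          double g;
          if (x == y) g = f[k] * pa + (1.0 - f[k]) * pa * pa;
          else        g = (1.0 - f[k]) * 2.0 * pa * p[k][l][y];
          lik[k] = q(i, k) * (g > 0 ? g : 0.0);
          tot += lik[k];
        }
        int kk = K - 1;
        if (tot > 0) {
          double u = R::unif_rand() * tot, c = 0.0;
          for (int k = 0; k < K; ++k) { c += lik[k]; if (u <= c) { kk = k; break; } }
        } else {
          kk = (int)std::floor(R::unif_rand() * K);
          if (kk == K) kk = K - 1;
        }
        z(i, l) = kk;
        if (x == y) {
          const double pa = p[kk][l][x];
          const double pr_ibd = f[kk] * pa / (f[kk] * pa + (1.0 - f[kk]) * pa * pa);
          ibd(i, l) = (R::unif_rand() < pr_ibd) ? 1 : 0;
        } else {
          ibd(i, l) = 0;
        }
      }
    }

    // --- q per individual ---
    if (K > 1) {
      for (int i = 0; i < N; ++i) {
        std::fill(zcnt.begin(), zcnt.end(), 0.0);
        for (int l = 0; l < L; ++l) zcnt[z(i, l)] += 1.0;
        for (int k = 0; k < K; ++k) qshape[k] = alpha + zcnt[k];
        rdirichlet_into(qshape, qrow);
        for (int k = 0; k < K; ++k) q(i, k) = qrow[k];
      }
    }

    // --- p per cluster x locus, f per cluster ---
    for (int k = 0; k < K; ++k) {
      double n_ibd = 0.0, n_out = 0.0;
      for (int l = 0; l < L; ++l) {
        std::vector<double> shape(n_alleles[l], freq_prior);
        for (int i = 0; i < N; ++i) {
          if (z(i, l) != k) continue;
          const int x = a1(i, l), y = a2(i, l);
          if (x == y) {
            if (ibd(i, l)) { shape[x] += 1.0; n_ibd += 1.0; }
            else           { shape[x] += 2.0; n_out += 1.0; }
          } else {
            shape[x] += 1.0; shape[y] += 1.0; n_out += 1.0;
          }
        }
        rdirichlet_into(shape, p[k][l]);
      }
      f[k] = R::rbeta(1.0 + n_ibd, 1.0 + n_out);
    }

    // --- record ---
    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      double dev = 0.0;
      for (int i = 0; i < N; ++i) {
        for (int l = 0; l < L; ++l) {
          const int x = a1(i, l), y = a2(i, l);
          double m = 0.0;
          for (int k = 0; k < K; ++k) {
            const double pa = p[k][l][x];
            double g;
            if (x == y) g = f[k] * pa + (1.0 - f[k]) * pa * pa;
            else        g = (1.0 - f[k]) * 2.0 * pa * p[k][l][y];
            m += q(i, k) * g;
          }
          dev += std::log(m > P_FLOOR ? m : P_FLOOR);
        }
      }
      deviances.push_back(-2.0 * dev);
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) q_sum(i, k) += q(i, k);
      for (int k = 0; k < K; ++k) {
        f_sum[k] += f[k];
        for (int l = 0; l < L; ++l)
          for (int a = 0; a < n_alleles[l]; ++a) p_sum[k][l][a] += p[k][l][a];
      }
      ++n_saved;
    }
  }

  if (n_saved == 0) stop("no post-burn-in samples recorded");

  NumericMatrix q_mean(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) q_mean(i, k) = q_sum(i, k) / n_saved;
  NumericVector f_mean(K);
  for (int k = 0; k < K; ++k) f_mean[k] = f_sum[k] / n_saved;
  List p_mean(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pm(K, n_alleles[l]);
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < n_alleles[l]; ++a) pm(k, a) = p_sum[k][l][a] / n_saved;
    p_mean[l] = pm;
  }

  // deviance at the posterior means (for p_D / DIC)
  double dev_hat = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int l = 0; l < L; ++l) {
      const int x = a1(i, l), y = a2(i, l);
      double m = 0.0;
      NumericMatrix pm = p_mean[l];
      for (int k = 0; k < K; ++k) {
        const double pa = pm(k, x);
        double g;
        if (x == y) g = f_mean[k] * pa + (1.0 - f_mean[k]) * pa * pa;
        else        g = (1.0 - f_mean[k]) * 2.0 * pa * pm(k, y);
        m += q_mean(i, k) * g;
      }
      dev_hat += std::log(m > P_FLOOR ? m : P_FLOOR);
    }
  }
  dev_hat *= -2.0;

  return List::create(_["q_mean"] = q_mean, _["f_mean"] = f_mean,
                      _["p_mean"] = p_mean,
                      _["deviance_samples"] = NumericVector(deviances.begin(), deviances.end()),
                      _["deviance_at_mean"] = dev_hat,
                      _["n_saved"] = n_saved);
}
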