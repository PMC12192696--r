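// Li-Stephens-style diploid forward-backward over ordered haplotype pairs.
//
// State space: ordered pairs (a, b) of reference-panel haplotypes, held as
// an H x H matrix. The switch kernel t(a -> a') = (1-s) * delta + s/H
// factorises over the two copied haplotypes, and the genotype emission is a
// rank-<=2 outer product of per-haplotype allele-emission vectors, so each
// marker step costs O(H^2). The recursions below are written as fused raw
// loops with no per-marker allocations; this is the package's hot path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// emission factor for genotype g given per-haplotype allele-1 probabilities
static inline double emit(int g, double p1a, double p1b) {
  if (g == 0) return (1.0 - p1a) * (1.0 - p1b);
  if (g == 2) return p1a * p1b;
  return (1.0 - p1a) * p1b + p1a * (1.0 - p1b);
}

// panel: H x M 0/1 integer matrix; geno: length-M vector with 0/1/2, NA = -1
// want_post: length-M 0/1; posteriors are computed where it is 1.
// Returns genotype posteriors (3 x M) and the forward log-likelihood.
// [[Rcpp::export(name = ".ls_forward_backward")]]
Rcpp::List ls_forward_backward(const arma::imat& panel,
                               const arma::ivec& geno,
                               double switch_prob,
                               double mismatch_prob,
                               const arma::ivec& want_post) {
  const int H = panel.n_rows, M = panel.n_cols;
  if (H < 1) Rcpp::stop("empty haplotype panel");
  if ((int)geno.n_elem != M) Rcpp::stop("genotype length != panel markers");
  const double e = mismatch_prob, s = switch_prob;
  const double stay = 1.0 - s, jump = s / H;
  const double st2 = stay * stay, stj = stay * jump, j2 = jump * jump;

  // per-marker allele-1 emission probability for each haplotype
  mat P1(H, M);
  for (int m = 0; m < M; ++m)
    for (int a = 0; a < H; ++a)
      P1(a, m) = e + (1.0 - 2.0 * e) * panel(a, m);

  // store normalised forward matrices only where posteriors are requested
  std::vector<int> store_at(M, -1);
  int n_req = 0;
  for (int m = 0; m < M; ++m) if (want_post[m]) store_at[m] = n_req++;
  std::vector<mat> Fstore(n_req);

  mat F(H, H);
  F.fill(1.0 / (double(H) * H));
  vec rs(H);
  vec csv(H);
  double loglik = 0.0;

  for (int m = 0; m < M; ++m) {
    const double* p1 = P1.colptr(m);
    const int g = geno[m];
    double z = 0.0;
    if (m == 0) {
      if (g >= 0) {
        for (int b = 0; b < H; ++b) {
          double* col = F.colptr(b);
          for (int a = 0; a < H; ++a) {
            col[a] *= emit(g, p1[a], p1[b]);
            z += col[a];
          }
        }
      } else {
        z = 1.0;
      }
    } else {
      // row/col sums and total of the incoming forward matrix
      double S = 0.0;
      rs.zeros(); csv.zeros();
      for (int b = 0; b < H; ++b) {
        const double* col = F.colptr(b);
        double cb = 0.0;
        for (int a = 0; a < H; ++a) {
          rs[a] += col[a];
          cb += col[a];
        }
        csv[b] = cb;
        S += cb;
      }
      const double j2S = j2 * S;
      for (int b = 0; b < H; ++b) {
        double* col = F.colptr(b);
        const double tb = stj * csv[b] + j2S;
        if (g >= 0) {
          const double p1b = p1[b];
          for (int a = 0; a < H; ++a) {
            double v = (st2 * col[a] + stj * rs[a] + tb) * emit(g, p1[a], p1b);
            col[a] = v;
            z += v;
          }
        } else {
          for (int a = 0; a < H; ++a) {
            double v = st2 * col[a] + stj * rs[a] + tb;
            col[a] = v;
            z += v;
          }
        }
      }
    }
    if (!(z > 0)) Rcpp::stop("forward pass underflow at marker %d", m + 1);
    F *= 1.0 / z;
    loglik += std::log(z);
    if (store_at[m] >= 0) Fstore[store_at[m]] = F;
  }

  // backward pass: B_m(z) = sum_{z'} T(z -> z') e_{m+1}(z') B_{m+1}(z');
  // the switch kernel is symmetric, so the same fused update applies
  mat post(3, M, fill::zeros);
  mat B(H, H, fill::ones);
  mat C(H, H);
  for (int m = M - 1; m >= 0; --m) {
    if (store_at[m] >= 0) {
      const mat& Fm = Fstore[store_at[m]];
      const double* p1 = P1.colptr(m);
      double q0 = 0.0, q1 = 0.0, q2 = 0.0;
      for (int b = 0; b < H; ++b) {
        const double* fc = Fm.colptr(b);
        const double* bc = B.colptr(b);
        const double p1b = p1[b];
        for (int a = 0; a < H; ++a) {
          const double w = fc[a] * bc[a];
          const double p1a = p1[a];
          q0 += w * (1.0 - p1a) * (1.0 - p1b);
          q1 += w * ((1.0 - p1a) * p1b + p1a * (1.0 - p1b));
          q2 += w * p1a * p1b;
        }
      }
      const double qz = q0 + q1 + q2;
      post(0, m) = q0 / qz;
      post(1, m) = q1 / qz;
      post(2, m) = q2 / qz;
    }
    if (m > 0) {
      const double* p1 = P1.colptr(m);
      const int g = geno[m];
      // C = e_m .* B, with running row/col sums
      double S = 0.0;
      rs.zeros(); csv.zeros();
      for (int b = 0; b < H; ++b) {
        const double* bc = B.colptr(b);
        double* cc = C.colptr(b);
        const double p1b = (g >= 0) ? p1[b] : 0.0;
        double cb = 0.0;
        for (int a = 0; a < H; ++a) {
          double v = (g >= 0) ? bc[a] * emit(g, p1[a], p1b) : bc[a];
          cc[a] = v;
          rs[a] += v;
          cb += v;
        }
        csv[b] = cb;
        S += cb;
      }
      const double j2S = j2 * S;
      double z = 0.0;
      for (int b = 0; b < H; ++b) {
        const double* cc = C.colptr(b);
        double* bc = B.colptr(b);
        const double tb = stj * csv[b] + j2S;
        for (int a = 0; a < H; ++a) {
          double v = st2 * cc[a] + stj * rs[a] + tb;
          bc[a] = v;
          z += v;
        }
      }
      if (!(z > 0)) Rcpp::stop("backward pass underflow at marker %d", m);
      B *= (double(H) * H) / z;  // rescale to avoid under/overflow
    }
  }

  return Rcpp::List::create(Rcpp::Named("post") = post,
                            Rcpp::Named("loglik") = loglik);
}
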