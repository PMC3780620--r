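// Rao-Blackwellized particle filter for the CRP mixture observer.
//
// Each particle carries a partition of the trials seen so far (since the
// last block reset) as per-category sufficient statistics; category
// means/variances and color multinomials are marginalized analytically
// (normal-inverse-gamma and Dirichlet conjugacy). Per trial the filter
// first forms the pre-feedback estimate of the true count from the
// sensory signal y_t, then, once feedback x_t is observed, samples each
// particle's assignment z_t from its conditional posterior and reweights
// by the marginal likelihood of (x_t, c_t). Systematic resampling is
// triggered when the effective sample size drops below half the particle
// count. Uses R's RNG, so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Particle {
  std::vector<int> M;                 // trials per category
  std::vector<double> mean_x, sse_x;  // running moments per category
  std::vector<std::vector<int> > N_c; // color counts per category
  double log_w;
  int K() const { return static_cast<int>(M.size()); }
  void reset() { M.clear(); mean_x.clear(); sse_x.clear(); N_c.clear(); }
};

// Student-t predictive variance with Gaussian moment matching: for
// dof <= 2 the t variance is undefined/infinite, fall back to the
// squared scale.
inline double matched_var(double beta, double df) {
  return df > 2.0 ? beta * df / (df - 2.0) : beta;
}

}  // namespace

// [[Rcpp::export(name = ".filter_session_cpp")]]
List filter_session_cpp(NumericVector x, IntegerVector color,
                        IntegerVector block, List hp, int n_particles,
                        bool reset_per_block, bool force_new) {
  const int T = x.size();
  const double alpha = as<double>(hp["alpha"]);
  const double a0 = as<double>(hp["a0"]);
  const double b0 = as<double>(hp["b0"]);
  const double eta0 = as<double>(hp["eta0"]);
  const double mu0 = as<double>(hp["mu0"]);
  const double lam = as<double>(hp["lam"]);
  const double sigma_y = as<double>(hp["sigma_y"]);
  const int C = as<int>(hp["n_colors"]);
  const double sy2 = sigma_y * sigma_y;
  const int N = n_particles;

  std::vector<Particle> part(N);
  for (int i = 0; i < N; ++i) part[i].log_w = 0.0;

  NumericVector estimate(T), expected_K(T), map_K(T);
  std::vector<double> block_modal_K;
  std::vector<int> block_ids;

  std::vector<double> W(N), wbuf, gbuf, mbuf;
  int trials_in_stream = 0;  // trials since last reset

  for (int t = 0; t < T; ++t) {
    if (t == 0 || (reset_per_block && block[t] != block[t - 1])) {
      if (reset_per_block && t > 0) {
        for (int i = 0; i < N; ++i) { part[i].reset(); part[i].log_w = 0.0; }
      }
      trials_in_stream = 0;
    }

    // normalized particle weights before feedback
    double maxlw = part[0].log_w;
    for (int i = 1; i < N; ++i) maxlw = std::max(maxlw, part[i].log_w);
    double sw = 0.0;
    for (int i = 0; i < N; ++i) { W[i] = std::exp(part[i].log_w - maxlw); sw += W[i]; }
    for (int i = 0; i < N; ++i) W[i] /= sw;

    const double xt = x[t];
    const double yt = xt;  // sensory signal pinned to the true count
    const int ct = color[t] - 1;
    const double denom = trials_in_stream + alpha;

    double est = 0.0;
    for (int i = 0; i < N; ++i) {
      Particle &p = part[i];
      const int K = p.K();
      wbuf.assign(K + 1, 0.0);
      gbuf.assign(K + 1, 0.0);
      mbuf.assign(K + 1, 0.0);
      double totw = 0.0, totg = 0.0;
      for (int k = 0; k <= K; ++k) {
        const bool isnew = (k == K);
        const double M = isnew ? 0.0 : p.M[k];
        double prior;
        if (trials_in_stream == 0) {
          prior = isnew ? 1.0 : 0.0;
        } else {
          prior = (isnew ? alpha : M) / denom;
        }
        const int nck = isnew ? 0 : p.N_c[k][ct];
        const double colp = (lam + nck) / (C * lam + M);
        const double mx = isnew ? 0.0 : p.mean_x[k];
        const double sse = isnew ? 0.0 : p.sse_x[k];
        const double eta = M + eta0;
        const double mu = (eta0 * mu0 + M * mx) / eta;
        const double a = (M + a0) / 2.0;
        const double b = b0 + sse / 2.0 +
          M * eta0 * (mu0 - mx) * (mu0 - mx) / (2.0 * eta);
        const double beta = b * (1.0 + eta) / (a * eta);
        const double df = 2.0 * a;
        const double v = matched_var(beta, df);
        // pre-feedback: y-likelihood via the Gaussian moment match
        const double liky = R::dnorm(yt, mu, std::sqrt(v + sy2), 0);
        const double w = prior * colp * liky;
        wbuf[k] = w; totw += w;
        mbuf[k] = (sy2 * mu + v * yt) / (v + sy2);
        // feedback: exact Student-t marginal of x_t
        const double s = std::sqrt(beta);
        const double likx = R::dt((xt - mu) / s, df, 0) / s;
        const double g = prior * colp * likx;
        gbuf[k] = g; totg += g;
      }
      double pred = yt;
      if (totw > 0.0) {
        pred = 0.0;
        for (int k = 0; k <= K; ++k) pred += wbuf[k] * mbuf[k] / totw;
      }
      est += W[i] * pred;

      // sample the assignment from the conditional posterior
      int z;
      if (force_new) {
        z = K;
      } else if (totg <= 0.0) {
        z = K;  // degenerate underflow: open a new category
        totg = 1e-300;
      } else {
        const double u = unif_rand() * totg;
        double acc = 0.0;
        z = K;
        for (int k = 0; k <= K; ++k) {
          acc += gbuf[k];
          if (u <= acc) { z = k; break; }
        }
      }
      p.log_w += std::log(totg);

      if (z == K) {
        p.M.push_back(0);
        p.mean_x.push_back(0.0);
        p.sse_x.push_back(0.0);
        p.N_c.push_back(std::vector<int>(C, 0));
      }
      const int Mnew = p.M[z] + 1;
      const double delta = xt - p.mean_x[z];
      p.mean_x[z] += delta / Mnew;
      p.sse_x[z] += delta * (xt - p.mean_x[z]);
      p.M[z] = Mnew;
      p.N_c[z][ct] += 1;
    }
    estimate[t] = est;
    ++trials_in_stream;

    // post-feedback weights, expected / modal category counts
    maxlw = part[0].log_w;
    for (int i = 1; i < N; ++i) maxlw = std::max(maxlw, part[i].log_w);
    sw = 0.0;
    for (int i = 0; i < N; ++i) { W[i] = std::exp(part[i].log_w - maxlw); sw += W[i]; }
    double ek = 0.0, ess = 0.0;
    int kmax_seen = 0;
    for (int i = 0; i < N; ++i) {
      W[i] /= sw;
      ek += W[i] * part[i].K();
      ess += W[i] * W[i];
      kmax_seen = std::max(kmax_seen, part[i].K());
    }
    expected_K[t] = ek;
    std::vector<double> khist(kmax_seen + 1, 0.0);
    for (int i = 0; i < N; ++i) khist[part[i].K()] += W[i];
    int kmode = 0;
    for (int k = 1; k <= kmax_seen; ++k) if (khist[k] > khist[kmode]) kmode = k;
    map_K[t] = kmode;

    if (t == T - 1 || block[t + 1] != block[t]) {
      block_modal_K.push_back(kmode);
      block_ids.push_back(block[t]);
    }

    // systematic resampling when the ESS falls below N/2
    if (1.0 / ess < N / 2.0 && N > 1) {
      const double u0 = unif_rand() / N;
      std::vector<Particle> newp;
      newp.reserve(N);
      double acc = 0.0;
      int i = 0;
      for (int j = 0; j < N; ++j) {
        const double uj = u0 + static_cast<double>(j) / N;
        while (acc + W[i] < uj && i < N - 1) { acc += W[i]; ++i; }
        newp.push_back(part[i]);
        newp.back().log_w = 0.0;
      }
      part.swap(newp);
    }
  }

  return List::create(_["estimate"] = estimate,
                      _["expected_n_categories"] = expected_K,
                      _["map_n_categories"] = map_K,
                      _["block_end_modal_K"] = wrap(block_modal_K),
                      _["block_id"] = wrap(block_ids));
}
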