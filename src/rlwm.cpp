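#include <Rcpp.h>
using namespace Rcpp;

// Shared per-trial engine for the RL-WM model. State resets at block
// boundaries; trial order within a call: (optional) WM decay, policy,
// latent recording, WM update, RL update, (optional) post decay.
// Stimulus and action indices are 1-based on entry.

namespace {

struct Engine {
  int n_a;
  double alpha, gamma, phi, rho, eps, beta;
  int capacity;
  bool decay_before;
  std::vector<double> q_rl, q_wm;  // ss x n_a, row-major by stimulus
  int ss;
  double omega;

  void reset_block(int ss_, double rho_) {
    ss = ss_;
    q_rl.assign((size_t)ss * n_a, 1.0 / n_a);
    q_wm.assign((size_t)ss * n_a, 1.0 / n_a);
    double cap_ratio = (double)capacity / ss;
    omega = rho_ * (cap_ratio < 1.0 ? cap_ratio : 1.0);
  }

  void decay() {
    const double q0 = 1.0 / n_a;
    for (double &q : q_wm) q += phi * (q0 - q);
  }

  // softmax with max-subtraction over one stimulus row
  void policy(const double *q, double *p) const {
    double m = q[0];
    for (int i = 1; i < n_a; ++i) if (q[i] > m) m = q[i];
    double sum = 0.0;
    for (int i = 0; i < n_a; ++i) { p[i] = std::exp(beta * (q[i] - m)); sum += p[i]; }
    for (int i = 0; i < n_a; ++i) p[i] /= sum;
  }

  void update(int s, int a, int r) {
    size_t k = (size_t)s * n_a + a;
    if (r == 1) {
      q_wm[k] = 1.0;
      q_rl[k] += alpha * (1.0 - q_rl[k]);
    } else {
      q_wm[k] += gamma * (0.0 - q_wm[k]);
      q_rl[k] += alpha * gamma * (0.0 - q_rl[k]);
    }
  }
};

} // namespace

// [[Rcpp::export]]
double rlwm_nll_cpp(IntegerVector block_id, IntegerVector set_size,
                    IntegerVector stim, IntegerVector action,
                    IntegerVector correct, int n_a,
                    double alpha, double gamma, double phi, double rho,
                    int capacity, double epsilon, double beta,
                    bool decay_before) {
  const int n = block_id.size();
  Engine e;
  e.n_a = n_a; e.alpha = alpha; e.gamma = gamma; e.phi = phi;
  e.rho = rho; e.eps = epsilon; e.beta = beta; e.capacity = capacity;
  e.decay_before = decay_before;
  std::vector<double> prl(n_a), pwm(n_a);
  int cur_block = -1;
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (block_id[t] != cur_block) {
      cur_block = block_id[t];
      e.reset_block(set_size[t], rho);
    }
    if (decay_before) e.decay();
    int s = stim[t] - 1, a = action[t] - 1;
    e.policy(&e.q_rl[(size_t)s * n_a], prl.data());
    e.policy(&e.q_wm[(size_t)s * n_a], pwm.data());
    double pmix = (1.0 - e.omega) * prl[a] + e.omega * pwm[a];
    double pfin = (1.0 - epsilon) * pmix + epsilon / n_a;
    nll -= std::log(pfin);
    e.update(s, a, correct[t]);
    if (!decay_before) e.decay();
  }
  return nll;
}

// [[Rcpp::export]]
NumericMatrix rlwm_latents_cpp(IntegerVector block_id, IntegerVector set_size,
                               IntegerVector stim, IntegerVector action,
                               IntegerVector correct, int n_a,
                               double alpha, double gamma, double phi,
                               double rho, int capacity, double epsilon,
                               double beta, bool decay_before,
                               bool rpe_cooperative) {
  const int n = block_id.size();
  Engine e;
  e.n_a = n_a; e.alpha = alpha; e.gamma = gamma; e.phi = phi;
  e.rho = rho; e.eps = epsilon; e.beta = beta; e.capacity = capacity;
  e.decay_before = decay_before;
  std::vector<double> prl(n_a), pwm(n_a);
  NumericMatrix out(n, 6);  // q_rl, q_wm, q_mix, omega, rpe, choice_prob
  int cur_block = -1;
  for (int t = 0; t < n; ++t) {
    if (block_id[t] != cur_block) {
      cur_block = block_id[t];
      e.reset_block(set_size[t], rho);
    }
    if (decay_before) e.decay();
    int s = stim[t] - 1, a = action[t] - 1;
    size_t k = (size_t)s * n_a + a;
    e.policy(&e.q_rl[(size_t)s * n_a], prl.data());
    e.policy(&e.q_wm[(size_t)s * n_a], pwm.data());
    double pmix = (1.0 - e.omega) * prl[a] + e.omega * pwm[a];
    double pfin = (1.0 - epsilon) * pmix + epsilon / n_a;
    double qmix = e.omega * e.q_wm[k] + (1.0 - e.omega) * e.q_rl[k];
    out(t, 0) = e.q_rl[k];
    out(t, 1) = e.q_wm[k];
    out(t, 2) = qmix;
    out(t, 3) = e.omega;
    out(t, 4) = correct[t] - (rpe_cooperative ? qmix : e.q_rl[k]);
    out(t, 5) = pfin;
    e.update(s, a, correct[t]);
    if (!decay_before) e.decay();
  }
  return out;
}

// Generative pass: sample actions from the final policy, score correctness
// against the designated correct action per (block, stimulus). Uses R's
// RNG (unif_rand) so results are reproducible under set.seed(). The
// per-trial order matches the likelihood engine exactly.
// [[Rcpp::export]]
IntegerMatrix rlwm_simulate_cpp(IntegerVector block_id,
                                IntegerVector set_size, IntegerVector stim,
                                IntegerVector correct_action, int n_a,
                                double alpha, double gamma, double phi,
                                double rho, int capacity, double epsilon,
                                double beta, bool decay_before) {
  const int n = block_id.size();
  Engine e;
  e.n_a = n_a; e.alpha = alpha; e.gamma = gamma; e.phi = phi;
  e.rho = rho; e.eps = epsilon; e.beta = beta; e.capacity = capacity;
  e.decay_before = decay_before;
  std::vector<double> prl(n_a), pwm(n_a), pfin(n_a);
  IntegerMatrix out(n, 2);  // action (1-based), correct
  int cur_block = -1;
  RNGScope scope;
  for (int t = 0; t < n; ++t) {
    if (block_id[t] != cur_block) {
      cur_block = block_id[t];
      e.reset_block(set_size[t], rho);
    }
    if (decay_before) e.decay();
    int s = stim[t] - 1;
    e.policy(&e.q_rl[(size_t)s * n_a], prl.data());
    e.policy(&e.q_wm[(size_t)s * n_a], pwm.data());
    for (int i = 0; i < n_a; ++i)
      pfin[i] = (1.0 - epsilon) *
                  ((1.0 - e.omega) * prl[i] + e.omega * pwm[i]) +
                epsilon / n_a;
    double u = unif_rand(), acc = 0.0;
    int a = n_a - 1;
    for (int i = 0; i < n_a; ++i) {
      acc += pfin[i];
      if (u <= acc) { a = i; break; }
    }
    int r = (a + 1 == correct_action[t]) ? 1 : 0;
    out(t, 0) = a + 1;
    out(t, 1) = r;
    e.update(s, a, r);
    if (!decay_before) e.decay();
  }
  return out;
}
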