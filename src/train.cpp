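#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// activation codes shared with R: 0 purelin, 1 tansig, 2 logsig_standard,
// 3 logsig_paper (two-scaled logistic as printed in the source tables)

static inline double act(int kind, double x) {
  switch (kind) {
  case 0: return x;
  case 1: return 2.0 / (1.0 + std::exp(-2.0 * x)) - 1.0;
  case 2: return 1.0 / (1.0 + std::exp(-x));
  default: return 2.0 / (1.0 + std::exp(-x));
  }
}

// derivative expressed through the activation value f
static inline double dact(int kind, double f) {
  switch (kind) {
  case 0: return 1.0;
  case 1: return 1.0 - f * f;
  case 2: return f * (1.0 - f);
  default: return f * (1.0 - f / 2.0);
  }
}

struct Net {
  std::vector<double> w1, bi, lw;
  double bj;
  int hact; // hidden activation code; output is purelin during training
};

static double net_mse(const Net &net, const std::vector<double> &cs,
                      const std::vector<double> &ys) {
  const size_t n = cs.size(), H = net.w1.size();
  double sse = 0.0;
  for (size_t k = 0; k < n; ++k) {
    double yhat = net.bj;
    for (size_t i = 0; i < H; ++i) {
      yhat += act(net.hact, cs[k] * net.w1[i] + net.bi[i]) * net.lw[i];
    }
    const double r = yhat - ys[k];
    sse += r * r;
  }
  return sse / static_cast<double>(n);
}

// batch-MSE gradient; parameter order: w1[0..H), bi[0..H), lw[0..H), bj
static void net_grad(const Net &net, const std::vector<double> &cs,
                     const std::vector<double> &ys, std::vector<double> &g) {
  const size_t n = cs.size(), H = net.w1.size();
  std::fill(g.begin(), g.end(), 0.0);
  std::vector<double> f(H);
  for (size_t k = 0; k < n; ++k) {
    double yhat = net.bj;
    for (size_t i = 0; i < H; ++i) {
      f[i] = act(net.hact, cs[k] * net.w1[i] + net.bi[i]);
      yhat += f[i] * net.lw[i];
    }
    const double e = 2.0 * (yhat - ys[k]) / static_cast<double>(n);
    for (size_t i = 0; i < H; ++i) {
      const double d = e * net.lw[i] * dact(net.hact, f[i]);
      g[i] += d * cs[k];
      g[H + i] += d;
      g[2 * H + i] += e * f[i];
    }
    g[3 * H] += e;
  }
}

static inline double get_param(const Net &net, size_t p, size_t H) {
  if (p < H) return net.w1[p];
  if (p < 2 * H) return net.bi[p - H];
  if (p < 3 * H) return net.lw[p - 2 * H];
  return net.bj;
}

static inline void add_param(Net &net, size_t p, size_t H, double delta) {
  if (p < H) net.w1[p] += delta;
  else if (p < 2 * H) net.bi[p - H] += delta;
  else if (p < 3 * H) net.lw[p - 2 * H] += delta;
  else net.bj += delta;
}

static List result_list(const Net &net, int epochs,
                        const std::vector<double> &history, double goal) {
  const double final_mse = history.empty() ? NA_REAL : history.back();
  return List::create(
      _["input_weights"] = wrap(net.w1), _["hidden_biases"] = wrap(net.bi),
      _["output_weights"] = wrap(net.lw), _["output_bias"] = net.bj,
      _["epochs_run"] = epochs, _["mse_history"] = wrap(history),
      _["final_mse"] = final_mse, _["converged"] = (final_mse <= goal));
}

// [[Rcpp::export(name = ".train_cpp")]]
List train_cpp(std::string algorithm, NumericVector w1, NumericVector bi,
               NumericVector lw, double bj, int hidden_act, NumericVector cs,
               NumericVector ys, List config) {
  Net net;
  net.w1 = as<std::vector<double>>(w1);
  net.bi = as<std::vector<double>>(bi);
  net.lw = as<std::vector<double>>(lw);
  net.bj = bj;
  net.hact = hidden_act;
  const size_t H = net.w1.size();
  const size_t P = 3 * H + 1;
  const std::vector<double> c = as<std::vector<double>>(cs);
  const std::vector<double> y = as<std::vector<double>>(ys);

  const int max_epochs = as<int>(config["max_epochs"]);
  const double goal = as<double>(config["goal_mse"]);
  std::vector<double> history;
  history.reserve(max_epochs);
  std::vector<double> g(P);
  int epochs = 0;

  if (algorithm == "gda") {
    double lr = as<double>(config["lr0"]);
    const double lr_inc = as<double>(config["lr_inc"]);
    const double lr_dec = as<double>(config["lr_dec"]);
    const double max_perf_inc = as<double>(config["max_perf_inc"]);
    double mse = net_mse(net, c, y);
    if (!std::isfinite(mse)) stop("training diverged at epoch 0");
    for (int ep = 1; ep <= max_epochs; ++ep) {
      net_grad(net, c, y, g);
      Net cand = net;
      for (size_t p = 0; p < P; ++p) add_param(cand, p, H, -lr * g[p]);
      const double new_mse = net_mse(cand, c, y);
      if (!std::isfinite(new_mse) || new_mse > max_perf_inc * mse) {
        lr *= lr_dec; // discard the step
      } else {
        if (new_mse < mse) lr *= lr_inc;
        net = cand;
        mse = new_mse;
      }
      history.push_back(mse);
      epochs = ep;
      if (mse <= goal) break;
    }
  } else if (algorithm == "rp") {
    const double delta_inc = as<double>(config["delta_inc"]);
    const double delta_dec = as<double>(config["delta_dec"]);
    const double delta_max = as<double>(config["delta_max"]);
    std::vector<double> delta(P, as<double>(config["delta0"]));
    std::vector<double> prev_g(P, 0.0), prev_step(P, 0.0);
    for (int ep = 1; ep <= max_epochs; ++ep) {
      net_grad(net, c, y, g);
      for (size_t p = 0; p < P; ++p) {
        const double s = g[p] * prev_g[p];
        if (s > 0.0) {
          delta[p] = std::min(delta[p] * delta_inc, delta_max);
          const double step = (g[p] > 0.0 ? -delta[p] : delta[p]);
          add_param(net, p, H, step);
          prev_step[p] = step;
          prev_g[p] = g[p];
        } else if (s < 0.0) {
          // sign flip: retract the previous step, shrink, skip this epoch
          delta[p] *= delta_dec;
          add_param(net, p, H, -prev_step[p]);
          prev_step[p] = 0.0;
          prev_g[p] = 0.0;
        } else {
          const double step =
              (g[p] > 0.0 ? -delta[p] : (g[p] < 0.0 ? delta[p] : 0.0));
          add_param(net, p, H, step);
          prev_step[p] = step;
          prev_g[p] = g[p];
        }
      }
      const double mse = net_mse(net, c, y);
      if (!std::isfinite(mse)) stop("training diverged at epoch %d", ep);
      history.push_back(mse);
      epochs = ep;
      if (mse <= goal) break;
    }
  } else if (algorithm == "seq") {
    const double lr = as<double>(config["lr0"]);
    const size_t n = c.size();
    std::vector<double> f(H);
    for (int ep = 1; ep <= max_epochs; ++ep) {
      for (size_t k = 0; k < n; ++k) { // dataset presentation order
        double yhat = net.bj;
        for (size_t i = 0; i < H; ++i) {
          f[i] = act(net.hact, c[k] * net.w1[i] + net.bi[i]);
          yhat += f[i] * net.lw[i];
        }
        const double e = 2.0 * (yhat - y[k]); // single-sample MSE gradient
        for (size_t i = 0; i < H; ++i) {
          const double d = e * net.lw[i] * dact(net.hact, f[i]);
          net.lw[i] -= lr * e * f[i];
          net.w1[i] -= lr * d * c[k];
          net.bi[i] -= lr * d;
        }
        net.bj -= lr * e;
      }
      const double mse = net_mse(net, c, y);
      if (!std::isfinite(mse)) stop("training diverged at epoch %d", ep);
      history.push_back(mse);
      epochs = ep;
      if (mse <= goal) break;
    }
  } else {
    stop("unknown training algorithm '%s'", algorithm.c_str());
  }
  (void)get_param; // silence unused warning on some compilers
  return result_list(net, epochs, history, goal);
}
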