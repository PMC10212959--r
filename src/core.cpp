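#include <Rcpp.h>
using namespace Rcpp;

// Direct form II transposed IIR filter with initial conditions.
// b, a already normalised so a[0] == 1; zi has length max(nb, na) - 1.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int n = x.size();
  int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  std::vector<double> z(nf - 1, 0.0);
  for (int i = 0; i < zi.size() && i < nf - 1; ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int k = 0; k < nf - 2; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    z[nf - 2] = bb[nf - 1] * xt - aa[nf - 1] * yt;
    y[t] = yt;
  }
  return y;
}

// Full-batch gradient descent for a 2-in / H-hidden(tanh) / 1-out MLP.
// Parameter vector theta = [W (H x 2, column-major), b (H), v (H), c].
// Minimises mean squared error; adaptive step (halve on increase, grow
// 1.1x on acceptance); stops on gradient norm, step collapse, loss
// plateau (relative decrease < plateau_tol over 25 epochs), or epochs.
// [[Rcpp::export(name = ".mlp_gd")]]
List mlp_gd(NumericMatrix X, NumericVector y, NumericVector theta0,
            int max_epochs, double grad_tol, double step0,
            double plateau_tol) {
  int n = X.nrow();
  int H = (theta0.size() - 1) / 4;
  int np = 4 * H + 1;
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> g(np), th_try(np), a(H), t(H);

  auto loss_grad = [&](const std::vector<double> &p, std::vector<double> *gr) {
    const double *W = &p[0];        // H x 2 column-major
    const double *b = &p[2 * H];
    const double *v = &p[3 * H];
    double c = p[4 * H];
    double L = 0.0;
    if (gr) std::fill(gr->begin(), gr->end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double x1 = X(i, 0), x2 = X(i, 1);
      double yhat = c;
      for (int j = 0; j < H; ++j) {
        a[j] = b[j] + W[j] * x1 + W[H + j] * x2;
        t[j] = std::tanh(a[j]);
        yhat += v[j] * t[j];
      }
      double e = yhat - y[i];
      L += e * e;
      if (gr) {
        double s = 2.0 * e / n;
        std::vector<double> &G = *gr;
        G[4 * H] += s;
        for (int j = 0; j < H; ++j) {
          double dt = s * v[j] * (1.0 - t[j] * t[j]);
          G[3 * H + j] += s * t[j];
          G[2 * H + j] += dt;
          G[j] += dt * x1;
          G[H + j] += dt * x2;
        }
      }
    }
    return L / n;
  };

  double step = step0;
  std::vector<double> g_try(np);
  double L = loss_grad(th, &g);
  int epoch = 0;
  bool converged = false;
  const int plateau_window = 25;
  double L_window = L;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    double gnorm = 0.0;
    for (int k = 0; k < np; ++k) gnorm += g[k] * g[k];
    gnorm = std::sqrt(gnorm);
    if (!std::isfinite(L)) stop("non-finite training loss at epoch %d", epoch);
    if (gnorm < grad_tol) { converged = true; break; }
    // backtracking: halve until the step decreases the loss; the gradient
    // of the candidate point is computed in the same pass so an accepted
    // step costs one evaluation
    bool accepted = false;
    while (step > 1e-15) {
      for (int k = 0; k < np; ++k) th_try[k] = th[k] - step * g[k];
      double Lt = loss_grad(th_try, &g_try);
      if (std::isfinite(Lt) && Lt <= L) {
        th = th_try;
        L = Lt;
        g = g_try;
        step *= 1.1;
        accepted = true;
        break;
      }
      step *= 0.5;
    }
    if (!accepted) { converged = true; break; }  // step collapsed: local min
    if (plateau_tol > 0 && (epoch + 1) % plateau_window == 0) {
      if (L_window - L < plateau_tol * std::max(L_window, 1e-30)) {
        converged = true;
        ++epoch;
        break;
      }
      L_window = L;
    }
  }
  return List::create(_["theta"] = NumericVector(th.begin(), th.end()),
                      _["loss"] = L, _["epochs"] = epoch,
                      _["converged"] = converged);
}
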