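// Online training loop for the three-layer microcircuit.
//
// One timestep = forward pass (L4 delay, attenuated L2/3->L5 drive, direct
// thalamic L5 input), manually specified weight updates with reconstruction
// gradient blocking, and an SGD or Adam step. Kept in compiled code because
// the model learns online (one update per stream element), which defeats
// batching at the R level; every gradient here is a rank-one outer product,
// so the optimizer update is fused with the product to keep the loop within
// memory bandwidth. Semantics are pinned to the R reference implementation
// (forward_step + gradient_set) by the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec sigm(const arma::vec& u) {
  return 1.0 / (1.0 + arma::exp(-u));
}

struct AdamState {
  arma::mat m, v;
  AdamState(arma::uword r, arma::uword c)
      : m(r, c, arma::fill::zeros), v(r, c, arma::fill::zeros) {}
};

// W -= eta * step(d x^T) with the rank-one gradient formed on the fly
static void update_outer(arma::mat& W, AdamState& st, const arma::vec& d,
                         const arma::vec& x, double eta, int optimizer,
                         double b1, double b2, double eps, double bc1,
                         double bc2) {
  const arma::uword R = W.n_rows, C = W.n_cols;
  double* w = W.memptr();
  if (optimizer == 0) {  // plain SGD; zero columns (e.g. one-hot context)
    for (arma::uword j = 0; j < C; ++j) {
      const double xj = x[j];
      if (xj == 0.0) continue;
      const double exj = eta * xj;
      double* wc = w + j * R;
      for (arma::uword i = 0; i < R; ++i) wc[i] -= exj * d[i];
    }
  } else {  // Adam with bias correction
    double* m = st.m.memptr();
    double* v = st.v.memptr();
    for (arma::uword j = 0; j < C; ++j) {
      const double xj = x[j];
      double* wc = w + j * R;
      double* mc = m + j * R;
      double* vc = v + j * R;
      for (arma::uword i = 0; i < R; ++i) {
        const double g = d[i] * xj;
        mc[i] = b1 * mc[i] + (1.0 - b1) * g;
        vc[i] = b2 * vc[i] + (1.0 - b2) * g * g;
        wc[i] -= eta * (mc[i] / bc1) / (std::sqrt(vc[i] / bc2) + eps);
      }
    }
  }
}

// [[Rcpp::export]]
List train_loop_cpp(arma::mat W1, arma::mat W2, arma::mat Wtd, arma::mat W3,
                    arma::mat W4, arma::mat Wd, const arma::mat& Xprev,
                    const arma::mat& Xt, const arma::mat& TD, double alpha,
                    double lambda_p, double lambda_r, double eta,
                    int optimizer, double beta1, double beta2,
                    double adam_eps, int fb_mode, const arma::mat& fb_random,
                    const arma::mat& fb_mask, bool use_mask, bool ko_l23_l5,
                    bool ko_thal_l5, bool ko_topdown, bool ko_delay,
                    bool ko_l4_l23, bool literal_eq9) {
  const arma::uword T = Xt.n_rows;
  arma::mat costs(T, 2, arma::fill::zeros);

  // knocking out L2/3->L5 disables the self-supervised cost during learning
  const double lp = ko_l23_l5 ? 0.0 : lambda_p;

  AdamState a1(W1.n_rows, W1.n_cols), a2(W2.n_rows, W2.n_cols),
      atd(Wtd.n_rows, Wtd.n_cols), a3(W3.n_rows, W3.n_cols),
      a4(W4.n_rows, W4.n_cols), ad(Wd.n_rows, Wd.n_cols);

  double bc1 = 1.0, bc2 = 1.0;
  for (arma::uword t = 0; t < T; ++t) {
    if (optimizer == 1) {
      bc1 = 1.0 - std::pow(beta1, double(t + 1));
      bc2 = 1.0 - std::pow(beta2, double(t + 1));
    }
    const arma::vec xt = Xt.row(t).t();
    const arma::vec xl4 = ko_delay ? xt : arma::vec(Xprev.row(t).t());
    const arma::vec itd =
        ko_topdown ? arma::vec(TD.n_cols, arma::fill::zeros)
                   : arma::vec(TD.row(t).t());

    const arma::vec z4 = sigm(W1 * xl4);
    arma::vec u23 = Wtd * itd;
    if (!ko_l4_l23) u23 += W2 * z4;
    const arma::vec z23 = sigm(u23);
    const arma::vec zhat = W3 * z23;
    arma::vec u5(W3.n_rows, arma::fill::zeros);
    if (!ko_l23_l5) u5 += alpha * zhat;
    if (!ko_thal_l5) u5 += W4 * xt;
    const arma::vec z5 = sigm(u5);
    const arma::vec xhat = Wd * z5;

    const arma::vec e = zhat - z5;
    const arma::vec rres = xt - xhat;
    const double c_pred = 0.5 * arma::dot(e, e);
    const double c_recon = 0.5 * arma::dot(rres, rres);
    costs(t, 0) = c_pred;
    costs(t, 1) = c_recon;
    if (!std::isfinite(c_pred) || !std::isfinite(c_recon)) {
      stop("training diverged at step %d (non-finite cost)", (int)(t + 1));
    }

    const arma::vec sp5 = z5 % (1.0 - z5);
    const arma::vec ef = e % (1.0 - alpha * sp5);

    // error carried back to L2/3 through the feedback pathway (computed
    // before W3 is updated, like the simultaneous rules it mirrors)
    arma::vec d23(z23.n_elem, arma::fill::zeros);
    bool have_d23 = false;
    if (fb_mode != 2 && lp != 0.0) {
      arma::vec back;
      if (fb_mode == 0) {  // symmetric: live transpose of W3
        back = use_mask ? arma::vec((fb_mask % W3.t()) * (lp * ef))
                        : arma::vec(W3.t() * (lp * ef));
      } else {  // random fixed matrix
        back = use_mask ? arma::vec((fb_mask % fb_random) * (lp * ef))
                        : arma::vec(fb_random * (lp * ef));
      }
      d23 = back % (z23 % (1.0 - z23));
      have_d23 = true;
    }

    // L2/3-to-L5 prediction weights (predictive cost only)
    if (!ko_l23_l5 && lp != 0.0) {
      update_outer(W3, a3, lp * ef, z23, eta, optimizer, beta1, beta2,
                   adam_eps, bc1, bc2);
    }

    if (!ko_l4_l23 && have_d23) {
      const arma::vec d4 = (W2.t() * d23) % (z4 % (1.0 - z4));
      update_outer(W2, a2, d23, z4, eta, optimizer, beta1, beta2, adam_eps,
                   bc1, bc2);
      update_outer(W1, a1, d4, xl4, eta, optimizer, beta1, beta2, adam_eps,
                   bc1, bc2);
    }
    if (!ko_topdown && have_d23) {
      update_outer(Wtd, atd, d23, itd, eta, optimizer, beta1, beta2,
                   adam_eps, bc1, bc2);
    }

    // thalamus-to-L5: both cost components reach this matrix
    if (!ko_thal_l5) {
      arma::vec e5 = -lp * e - lambda_r * (Wd.t() * rres);
      if (!literal_eq9) e5 %= sp5;
      update_outer(W4, a4, e5, xt, eta, optimizer, beta1, beta2, adam_eps,
                   bc1, bc2);
    }

    // decoder: reconstruction cost only
    if (lambda_r != 0.0) {
      update_outer(Wd, ad, -lambda_r * rres, z5, eta, optimizer, beta1,
                   beta2, adam_eps, bc1, bc2);
    }
  }

  return List::create(_["W_thal_l4"] = W1, _["W_l4_l23"] = W2,
                      _["W_td_l23"] = Wtd, _["W_l23_l5"] = W3,
                      _["W_thal_l5"] = W4, _["W_decoder"] = Wd,
                      _["costs"] = costs);
}
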