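// Likelihood and gradient kernels for the bandit model family.
//
// Data layout: trials x blocks matrices. `actions` holds 0-based arm
// indices with -1 marking invalid (missed) trials; `rewards` holds scaled
// rewards in [0.01, 1]. Missed trials contribute no loss and leave all
// latent state unchanged. Losses are summed over blocks and valid trials
// (negative log-likelihood of the observed action under the model's
// softmax policy). Gradients are exact reverse-mode accumulation through
// the full recurrence (backpropagation through time).

#include <RcppArmadillo.h>
#include <numeric>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec softmax_stable(const arma::vec& z) {
  arma::vec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// ---------------------------------------------------------------------------
// Tabular Q-learning family
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_tabular_nll(const IntegerMatrix& actions, const NumericMatrix& rewards,
                     const List& params) {
  const int T = actions.nrow(), B = actions.ncol(), K = 4;
  const double alpha = params["alpha"], beta = params["beta"],
               b = params["b"], kappa = params["kappa"], f = params["f"],
               q_init = params["q_init"], alpha_init = params["alpha_init"],
               w = params["w"];
  const bool var_lr = params["variable_lr"], persev = params["perseveration"];
  const int forget = params["forgetting"]; // 0 off, 1 unchosen, 2 all

  NumericVector per_block(B);
  for (int blk = 0; blk < B; ++blk) {
    arma::vec q(K, arma::fill::value(q_init));
    arma::vec cv(K, arma::fill::zeros);
    double at = var_lr ? alpha_init : alpha;
    double nll = 0.0;
    for (int t = 0; t < T; ++t) {
      int a = actions(t, blk);
      if (a < 0) continue;
      arma::vec p = softmax_stable(beta * (q + cv));
      nll -= std::log(p(a));
      double r = rewards(t, blk);
      if (forget == 1) {
        for (int i = 0; i < K; ++i)
          if (i != a) q(i) = (1 - f) * q(i) + f * q_init;
      } else if (forget == 2) {
        q = (1 - f) * q + f * q_init;
      }
      double delta = r - q(a);
      q(a) += (var_lr ? at : alpha) * delta + b;
      if (var_lr) at = w * std::fabs(delta) + (1 - w) * at;
      cv.zeros();
      if (persev) cv(a) = kappa;
    }
    per_block[blk] = nll;
  }
  return List::create(_["total"] = std::accumulate(per_block.begin(), per_block.end(), 0.0), _["per_block"] = per_block);
}

// ---------------------------------------------------------------------------
// Two-module architectures: RL-ANN (arch 0), Context-ANN (1), Memory-ANN (2)
// ---------------------------------------------------------------------------
//
// Reward module MLP: h = tanh(W1r x + b1r), qa = W2r h + b2r (scalar).
// Action module MLP: h = tanh(W1a x + b1a), c = W2a h + b2a (4-vector).
// Inputs per architecture (a, r from the previous trial):
//   rl_ann:      x_r = [Q(a), r],            x_a = [a]
//   context_ann: x_r = [Q(a), r, Q (all 4)], x_a = [a, c (all 4)]
//   memory_ann:  x_r = [r, s_r],             x_a = [a, s_a]
// After the reward module runs, unchosen values decay towards q_init with
// rate sigmoid(f_raw) and the chosen arm is overwritten by the module
// output. Logits are Q + c; the softmax has no inverse temperature.
// Before any (action, reward) has been observed, Q = q_init, c = 0 and the
// memory states are zero; trial 1 is predicted from this initial state and
// is included in the loss.

// [[Rcpp::export]]
List cpp_modular_nll_grad(const List& w, const IntegerMatrix& actions,
                          const NumericMatrix& rewards, int arch,
                          bool want_grad) {
  const int T = actions.nrow(), B = actions.ncol(), K = 4;
  const arma::mat W1r = w["W1r"], W2r = w["W2r"], W1a = w["W1a"], W2a = w["W2a"];
  const arma::vec b1r = w["b1r"], b1a = w["b1a"], b2a = w["b2a"];
  const double b2r = as<NumericVector>(w["b2r"])[0];
  const double f_raw = w["f_raw"], q_init = w["q_init"];
  const double f = sigmoid(f_raw);
  const int H = W1r.n_rows;
  const int nin_r = W1r.n_cols, nin_a = W1a.n_cols;

  arma::mat gW1r(arma::size(W1r), arma::fill::zeros), gW2r(arma::size(W2r), arma::fill::zeros);
  arma::mat gW1a(arma::size(W1a), arma::fill::zeros), gW2a(arma::size(W2a), arma::fill::zeros);
  arma::vec gb1r(H, arma::fill::zeros), gb1a(H, arma::fill::zeros), gb2a(K, arma::fill::zeros);
  double gb2r = 0.0, gf = 0.0, gqinit = 0.0;

  NumericVector per_block(B);

  // per-trial storage (one block at a time)
  arma::mat Qs(K, T + 1), Cs(K, T + 1), Ps(K, T);
  arma::mat Hr(H, T), Ha(H, T), Xr(nin_r, T), Xa(nin_a, T);
  arma::mat Sr, Sa;
  if (arch == 2) { Sr.set_size(H, T + 1); Sa.set_size(H, T + 1); }
  std::vector<int> ran(T); // whether the modules ran going *into* trial t

  for (int blk = 0; blk < B; ++blk) {
    // ---------------- forward ----------------
    Qs.col(0).fill(q_init);
    Cs.col(0).zeros();
    if (arch == 2) { Sr.col(0).zeros(); Sa.col(0).zeros(); }
    double nll = 0.0;
    for (int t = 0; t < T; ++t) {
      if (t > 0) {
        int ap = actions(t - 1, blk);
        if (ap >= 0) {
          ran[t] = 1;
          double rp = rewards(t - 1, blk);
          arma::vec xr(nin_r), xa(nin_a);
          if (arch == 0) {
            xr = { Qs(ap, t - 1), rp };
            xa = { (double)ap };
          } else if (arch == 1) {
            xr(0) = Qs(ap, t - 1); xr(1) = rp;
            xr.subvec(2, 1 + K) = Qs.col(t - 1);
            xa(0) = (double)ap;
            xa.subvec(1, K) = Cs.col(t - 1);
          } else {
            xr(0) = rp; xr.subvec(1, H) = Sr.col(t - 1);
            xa(0) = (double)ap; xa.subvec(1, H) = Sa.col(t - 1);
          }
          arma::vec hr = arma::tanh(W1r * xr + b1r);
          double qa = arma::as_scalar(W2r * hr) + b2r;
          arma::vec ha = arma::tanh(W1a * xa + b1a);
          arma::vec cv = W2a * ha + b2a;
          arma::vec q = (1 - f) * Qs.col(t - 1) + f * q_init;
          q(ap) = qa;
          Qs.col(t) = q; Cs.col(t) = cv;
          Hr.col(t) = hr; Ha.col(t) = ha; Xr.col(t) = xr; Xa.col(t) = xa;
          if (arch == 2) { Sr.col(t) = hr; Sa.col(t) = ha; }
        } else {
          ran[t] = 0;
          Qs.col(t) = Qs.col(t - 1); Cs.col(t) = Cs.col(t - 1);
          if (arch == 2) { Sr.col(t) = Sr.col(t - 1); Sa.col(t) = Sa.col(t - 1); }
        }
      } else {
        ran[t] = 0;
      }
      int a = actions(t, blk);
      if (a >= 0) {
        arma::vec p = softmax_stable(Qs.col(t) + Cs.col(t));
        Ps.col(t) = p;
        nll -= std::log(p(a));
      }
    }
    per_block[blk] = nll;

    if (!want_grad) continue;

    // ---------------- backward ----------------
    arma::vec gq(K, arma::fill::zeros), gc(K, arma::fill::zeros);
    arma::vec gsr(H, arma::fill::zeros), gsa(H, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      int a = actions(t, blk);
      if (a >= 0) {
        arma::vec gl = Ps.col(t);
        gl(a) -= 1.0;
        gq += gl; gc += gl;
      }
      if (t == 0) break;
      if (ran[t]) {
        int ap = actions(t - 1, blk);
        arma::vec gq_prev(K, arma::fill::zeros), gc_prev(K, arma::fill::zeros);
        // decay of unchosen arms
        for (int i = 0; i < K; ++i) {
          if (i == ap) continue;
          gq_prev(i) += (1 - f) * gq(i);
          gf += (q_init - Qs(i, t - 1)) * gq(i);
          gqinit += f * gq(i);
        }
        double gqa = gq(ap);
        // reward module backward
        arma::vec ghr = W2r.t() * gqa;
        if (arch == 2) ghr += gsr;              // state reused as next input
        arma::vec hr = Hr.col(t);
        arma::vec gzr = ghr % (1 - hr % hr);
        gW2r += gqa * hr.t();
        gb2r += gqa;
        gW1r += gzr * Xr.col(t).t();
        gb1r += gzr;
        arma::vec gxr = W1r.t() * gzr;
        // action module backward
        arma::vec gha = W2a.t() * gc;
        if (arch == 2) gha += gsa;
        arma::vec ha = Ha.col(t);
        arma::vec gza = gha % (1 - ha % ha);
        gW2a += gc * ha.t();
        gb2a += gc;
        gW1a += gza * Xa.col(t).t();
        gb1a += gza;
        arma::vec gxa = W1a.t() * gza;
        // route input gradients to the previous state
        if (arch == 0) {
          gq_prev(ap) += gxr(0);
        } else if (arch == 1) {
          gq_prev(ap) += gxr(0);
          gq_prev += gxr.subvec(2, 1 + K);
          gc_prev += gxa.subvec(1, K);
        } else {
          gsr = gxr.subvec(1, H);
          gsa = gxa.subvec(1, H);
        }
        gq = gq_prev; gc = gc_prev;
      }
      // invalid previous trial: identity transition, gradients pass through
    }
    gqinit += arma::accu(gq); // Q_1 = q_init * ones
  }

  List out = List::create(_["total"] = std::accumulate(per_block.begin(), per_block.end(), 0.0), _["per_block"] = per_block);
  if (want_grad) {
    out["grads"] = List::create(
      _["W1r"] = gW1r, _["b1r"] = gb1r, _["W2r"] = gW2r,
      _["b2r"] = NumericVector::create(gb2r),
      _["W1a"] = gW1a, _["b1a"] = gb1a, _["W2a"] = gW2a, _["b2a"] = gb2a,
      _["f_raw"] = gf * f * (1 - f), _["q_init"] = gqinit);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Vanilla RNN
// ---------------------------------------------------------------------------
//
// s_t = tanh(W1 [onehot(a_{t-1}), r_{t-1}, s_{t-1}] + b1); h_t = W2 s_t + b2.
// Trial 1 runs with the all-zero one-hot and mid-scale reward 0.5. Invalid
// previous trials consume no input: state and logits carry forward.

// [[Rcpp::export]]
List cpp_rnn_nll_grad(const List& w, const IntegerMatrix& actions,
                      const NumericMatrix& rewards, bool want_grad) {
  const int T = actions.nrow(), B = actions.ncol(), K = 4;
  const arma::mat W1 = w["W1"], W2 = w["W2"];
  const arma::vec b1 = w["b1"], b2 = w["b2"];
  const int H = W1.n_rows, nin = W1.n_cols; // nin = K + 1 + H

  arma::mat gW1(arma::size(W1), arma::fill::zeros), gW2(arma::size(W2), arma::fill::zeros);
  arma::vec gb1(H, arma::fill::zeros), gb2(K, arma::fill::zeros);

  NumericVector per_block(B);
  arma::mat Ss(H, T + 1), Ps(K, T), Xs(nin, T), Ls(K, T);
  std::vector<int> ran(T);

  for (int blk = 0; blk < B; ++blk) {
    Ss.col(0).zeros();
    arma::vec logits(K, arma::fill::zeros);
    double nll = 0.0;
    for (int t = 0; t < T; ++t) {
      bool run = (t == 0) || (actions(t - 1, blk) >= 0);
      ran[t] = run ? 1 : 0;
      if (run) {
        arma::vec x(nin, arma::fill::zeros);
        if (t == 0) {
          x(K) = 0.5;
        } else {
          x(actions(t - 1, blk)) = 1.0;
          x(K) = rewards(t - 1, blk);
        }
        x.subvec(K + 1, nin - 1) = Ss.col(t); // previous state
        arma::vec s = arma::tanh(W1 * x + b1);
        logits = W2 * s + b2;
        Ss.col(t + 1) = s; Xs.col(t) = x;
      } else {
        Ss.col(t + 1) = Ss.col(t);
      }
      Ls.col(t) = logits;
      int a = actions(t, blk);
      if (a >= 0) {
        arma::vec p = softmax_stable(logits);
        Ps.col(t) = p;
        nll -= std::log(p(a));
      }
    }
    per_block[blk] = nll;

    if (!want_grad) continue;

    arma::vec gs(H, arma::fill::zeros);
    arma::vec glog(K, arma::fill::zeros); // gradient on carried logits
    for (int t = T - 1; t >= 0; --t) {
      int a = actions(t, blk);
      if (a >= 0) {
        arma::vec gl = Ps.col(t);
        gl(a) -= 1.0;
        glog += gl;
      }
      if (ran[t]) {
        arma::vec s = Ss.col(t + 1);
        gW2 += glog * s.t();
        gb2 += glog;
        arma::vec gstot = gs + W2.t() * glog;
        arma::vec gz = gstot % (1 - s % s);
        gW1 += gz * Xs.col(t).t();
        gb1 += gz;
        arma::vec gx = W1.t() * gz;
        gs = gx.subvec(K + 1, nin - 1);
        glog.zeros();
      }
      // carried (not-run) trials: glog and gs keep accumulating backwards
    }
  }

  List out = List::create(_["total"] = std::accumulate(per_block.begin(), per_block.end(), 0.0), _["per_block"] = per_block);
  if (want_grad) {
    out["grads"] = List::create(_["W1"] = gW1, _["b1"] = gb1,
                                _["W2"] = gW2, _["b2"] = gb2);
  }
  return out;
}
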