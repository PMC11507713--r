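// Compact profile+quantity CNN: forward pass, multiscale loss, and exact
// analytic gradients, all in Armadillo. The architecture family is fixed
// (two conv layers, a dilated residual tower, max pools, two dense heads);
// only the filter counts / lengths vary via `arch`.
//
// Layout conventions:
//   activations: cube (channels, length, batch)
//   dense inputs: mat (batch, features)
//   conv weights: mat (filters, kernel * in_channels), column k*Cin + c
//   dense weights: mat (out, in)
//
// Gradients are verified against central finite differences in the test
// suite (tests/testthat/test-model.R), which is the independent oracle for
// this file.
//
// Internals compute in single precision (the network engine is memory-
// bandwidth bound on CPU and float halves the traffic); parameters and the
// optimizer live in double on the R side, and the standalone multiscale
// loss below is double so analytic checks retain full precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using cube = arma::fcube;
using mat = arma::fmat;
using vec = arma::fvec;
using arma::uword;

namespace {

mat to_f(const arma::mat& x) { return arma::conv_to<mat>::from(x); }
vec to_fv(const arma::vec& x) { return arma::conv_to<vec>::from(x); }
arma::mat to_d(const mat& x) { return arma::conv_to<arma::mat>::from(x); }
arma::vec to_dv(const vec& x) { return arma::conv_to<arma::vec>::from(x); }

struct ConvCache {
  mat cols;               // concatenated im2col: (Cin*K, L*B)
  cube z;                 // pre-BN conv output
  cube xhat;              // BN normalized
  vec bmean, bvar;        // batch statistics
  cube a;                 // post-activation
  cube pooled;            // after max pool (may be empty)
  arma::ucube argmax;     // pool selector
};

int pad_left(int kernel, int dil) { return ((kernel - 1) * dil) / 2; }

// One GEMM over the whole batch: columns of the im2col matrix are laid out
// slice-major (slice s occupies columns [s*L, (s+1)*L)).
cube conv1d_forward(const cube& x, const mat& w, const vec& b, int kernel,
                    int dil, mat& cols) {
  const uword cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const uword F = w.n_rows;
  const int pl = pad_left(kernel, dil);
  cols.zeros(cin * kernel, L * B);
  for (uword s = 0; s < B; ++s) {
    for (int k = 0; k < kernel; ++k) {
      const int off = k * dil - pl;
      // source column range [lo, hi) maps to target columns t = src - off
      int lo = std::max(0, off), hi = std::min((int)L, (int)L + off);
      if (lo < hi) {
        cols.submat((uword)(k * cin), s * L + (uword)(lo - off),
                    (uword)((k + 1) * cin - 1),
                    s * L + (uword)(hi - off - 1)) =
            x.slice(s).cols((uword)lo, (uword)(hi - 1));
      }
    }
  }
  mat out_all = w * cols;        // (F, L*B)
  out_all.each_col() += b;
  cube out(F, L, B);
  for (uword s = 0; s < B; ++s) out.slice(s) = out_all.cols(s * L,
                                                            (s + 1) * L - 1);
  return out;
}

// accumulates dW/db, returns dX
cube conv1d_backward(const cube& dy, const mat& cols, const mat& w,
                     int kernel, int dil, uword cin, mat& dW, vec& db) {
  const uword F = dy.n_rows, L = dy.n_cols, B = dy.n_slices;
  const int pl = pad_left(kernel, dil);
  mat dy_all(F, L * B);
  for (uword s = 0; s < B; ++s) dy_all.cols(s * L, (s + 1) * L - 1) =
      dy.slice(s);
  dW = dy_all * cols.t();
  db = arma::sum(dy_all, 1);
  mat dcol = w.t() * dy_all;     // (Cin*K, L*B)
  cube dx(cin, L, B, arma::fill::zeros);
  for (uword s = 0; s < B; ++s) {
    for (int k = 0; k < kernel; ++k) {
      const int off = k * dil - pl;
      int lo = std::max(0, off), hi = std::min((int)L, (int)L + off);
      if (lo < hi) {
        dx.slice(s).cols((uword)lo, (uword)(hi - 1)) +=
            dcol.submat((uword)(k * cin), s * L + (uword)(lo - off),
                        (uword)((k + 1) * cin - 1),
                        s * L + (uword)(hi - off - 1));
      }
    }
  }
  return dx;
}

// Batch norm over (length, batch) per channel.
cube bn_conv_forward(const cube& z, const vec& gamma, const vec& beta,
                     bool training, vec& run_mean, vec& run_var,
                     float momentum, float eps, cube& xhat, vec& bmean,
                     vec& bvar) {
  const uword F = z.n_rows, L = z.n_cols, B = z.n_slices;
  const double N = (double)(L * B);
  vec m(F), v(F);
  if (training) {
    m.zeros(); v.zeros();
    for (uword s = 0; s < B; ++s) m += arma::sum(z.slice(s), 1);
    m /= N;
    for (uword s = 0; s < B; ++s) {
      mat c = z.slice(s);
      c.each_col() -= m;
      v += arma::sum(arma::square(c), 1);
    }
    v /= N;
    run_mean = momentum * run_mean + (1.0f - momentum) * m;
    run_var = momentum * run_var + (1.0f - momentum) * v;
  } else {
    m = run_mean; v = run_var;
  }
  bmean = m; bvar = v;
  vec invstd = 1.0f / arma::sqrt(v + eps);
  xhat.set_size(F, L, B);
  cube out(F, L, B);
  for (uword s = 0; s < B; ++s) {
    mat c = z.slice(s);
    c.each_col() -= m;
    c.each_col() %= invstd;
    xhat.slice(s) = c;
    c.each_col() %= gamma;
    c.each_col() += beta;
    out.slice(s) = c;
  }
  return out;
}

cube bn_conv_backward(const cube& dy, const cube& xhat, const vec& gamma,
                      const vec& bvar, float eps, vec& dgamma, vec& dbeta) {
  const uword F = dy.n_rows, L = dy.n_cols, B = dy.n_slices;
  const double N = (double)(L * B);
  dgamma.zeros(F); dbeta.zeros(F);
  vec sum_dxhat(F, arma::fill::zeros), sum_dxhat_xhat(F, arma::fill::zeros);
  for (uword s = 0; s < B; ++s) {
    dgamma += arma::sum(dy.slice(s) % xhat.slice(s), 1);
    dbeta += arma::sum(dy.slice(s), 1);
  }
  // dxhat = dy * gamma (per channel)
  for (uword s = 0; s < B; ++s) {
    mat dxh = dy.slice(s);
    dxh.each_col() %= gamma;
    sum_dxhat += arma::sum(dxh, 1);
    sum_dxhat_xhat += arma::sum(dxh % xhat.slice(s), 1);
  }
  vec invstd = 1.0f / arma::sqrt(bvar + eps);
  cube dz(F, L, B);
  for (uword s = 0; s < B; ++s) {
    mat dxh = dy.slice(s);
    dxh.each_col() %= gamma;
    mat t = N * dxh;
    t.each_col() -= sum_dxhat;
    t -= xhat.slice(s).each_col() % sum_dxhat_xhat;
    t.each_col() %= (invstd / N);
    dz.slice(s) = t;
  }
  return dz;
}

// Batch norm over batch rows per feature column; x is (B, D).
mat bn_dense_forward(const mat& x, const vec& gamma, const vec& beta,
                     bool training, vec& run_mean, vec& run_var,
                     float momentum, float eps, mat& xhat, vec& bvar) {
  const double N = (double)x.n_rows;
  vec m, v;
  if (training) {
    m = arma::mean(x, 0).t();
    mat c = x.each_row() - m.t();
    v = (arma::sum(arma::square(c), 0) / N).t();
    run_mean = momentum * run_mean + (1.0f - momentum) * m;
    run_var = momentum * run_var + (1.0f - momentum) * v;
  } else {
    m = run_mean; v = run_var;
  }
  bvar = v;
  vec invstd = 1.0f / arma::sqrt(v + eps);
  xhat = (x.each_row() - m.t());
  xhat.each_row() %= invstd.t();
  mat out = xhat.each_row() % gamma.t();
  out.each_row() += beta.t();
  return out;
}

mat bn_dense_backward(const mat& dy, const mat& xhat, const vec& gamma,
                      const vec& bvar, float eps, vec& dgamma, vec& dbeta) {
  const double N = (double)dy.n_rows;
  dgamma = arma::sum(dy % xhat, 0).t();
  dbeta = arma::sum(dy, 0).t();
  mat dxh = dy.each_row() % gamma.t();
  arma::frowvec s1 = arma::sum(dxh, 0);
  arma::frowvec s2 = arma::sum(dxh % xhat, 0);
  mat t = N * dxh;
  t.each_row() -= s1;
  t -= xhat.each_row() % s2;
  arma::frowvec invstd = (1.0f / arma::sqrt(bvar + eps)).t();
  t.each_row() %= (invstd / N);
  return t;
}

cube elu(const cube& x) {
  cube y = x;
  y.transform([](float v) { return v > 0 ? v : (float)std::expm1((double)v); });
  return y;
}

cube relu_c(const cube& x) { return arma::clamp(x, 0.0f, arma::fdatum::inf); }

cube maxpool2(const cube& x, arma::ucube& sel) {
  const uword F = x.n_rows, L = x.n_cols / 2, B = x.n_slices;
  const arma::uvec even = arma::regspace<arma::uvec>(0, 2, 2 * L - 2);
  const arma::uvec odd = even + 1;
  cube out(F, L, B);
  sel.set_size(F, L, B);
  for (uword s = 0; s < B; ++s) {
    mat a = x.slice(s).cols(even), b = x.slice(s).cols(odd);
    arma::umat pick = (b > a);  // ties resolve to the left element
    out.slice(s) = a % (1.0f - arma::conv_to<mat>::from(pick)) +
                   b % arma::conv_to<mat>::from(pick);
    sel.slice(s) = pick;
  }
  return out;
}

cube maxpool2_backward(const cube& dy, const arma::ucube& sel, uword Lin) {
  const uword F = dy.n_rows, L = dy.n_cols, B = dy.n_slices;
  cube dx(F, Lin, B, arma::fill::zeros);
  for (uword s = 0; s < B; ++s) {
    mat pick = arma::conv_to<mat>::from(sel.slice(s));
    for (uword t = 0; t < L; ++t) {
      dx.slice(s).col(2 * t) = dy.slice(s).col(t) % (1.0f - pick.col(t));
      dx.slice(s).col(2 * t + 1) = dy.slice(s).col(t) % pick.col(t);
    }
  }
  return dx;
}

mat getm(const List& p, const std::string& nm) { return to_f(as<arma::mat>(p[nm])); }
vec getv(const List& p, const std::string& nm) { return to_fv(as<arma::vec>(p[nm])); }

struct Arch {
  int L, P, F1, F2, Fd, K1, K2, Kt, n_tower;
  double eps, momentum;
};

Arch read_arch(const List& arch) {
  Arch a;
  a.L = as<int>(arch["input_length"]);
  a.P = 2 * as<int>(arch["output_length"]);
  a.F1 = as<int>(arch["n_filters1"]);
  a.F2 = as<int>(arch["n_filters2"]);
  a.Fd = as<int>(arch["n_filters_tower"]);
  a.K1 = as<int>(arch["kernel1"]);
  a.K2 = as<int>(arch["kernel2"]);
  a.Kt = as<int>(arch["kernel_tower"]);
  a.n_tower = as<int>(arch["n_tower"]);
  a.eps = as<double>(arch["bn_eps"]);
  a.momentum = as<double>(arch["bn_momentum"]);
  return a;
}

struct ForwardState {
  ConvCache c1, c2;
  std::vector<ConvCache> tower;
  std::vector<cube> tower_in;  // input to each tower conv
  cube trunk;                  // pooled tower output
  arma::ucube trunk_sel;
  cube pre_pool_trunk;
  mat flat;       // (B, Fd*L3)
  mat prof_lin;   // dense out pre BN
  mat prof_xhat;  // BN cache
  vec prof_bvar;
  mat prof_bn;    // post BN
  mat profile;    // post ReLU (B, P)
  mat gap;        // (B, Fd)
  mat q_lin, q_xhat;
  vec q_bvar;
  mat q_bn;
  vec quantity;   // (B)
};

// Full forward pass; updates running stats in `state_out` when training.
void forward_pass(const List& params, const Arch& a, const cube& X,
                  bool training, ForwardState& fs, List& state_out) {
  const uword B = X.n_slices;
  // conv block 1: conv -> BN -> ELU -> pool
  vec rm1 = getv(params, "bn1_mean"), rv1 = getv(params, "bn1_var");
  fs.c1.z = conv1d_forward(X, getm(params, "conv1_W"), getv(params, "conv1_b"),
                           a.K1, 1, fs.c1.cols);
  cube u1 = bn_conv_forward(fs.c1.z, getv(params, "bn1_gamma"),
                            getv(params, "bn1_beta"), training, rm1, rv1,
                            a.momentum, a.eps, fs.c1.xhat, fs.c1.bmean,
                            fs.c1.bvar);
  fs.c1.a = elu(u1);
  cube p1 = maxpool2(fs.c1.a, fs.c1.argmax);
  fs.c1.pooled = p1;

  // conv block 2: conv -> BN -> ReLU -> pool
  vec rm2 = getv(params, "bn2_mean"), rv2 = getv(params, "bn2_var");
  fs.c2.z = conv1d_forward(p1, getm(params, "conv2_W"), getv(params, "conv2_b"),
                           a.K2, 1, fs.c2.cols);
  cube u2 = bn_conv_forward(fs.c2.z, getv(params, "bn2_gamma"),
                            getv(params, "bn2_beta"), training, rm2, rv2,
                            a.momentum, a.eps, fs.c2.xhat, fs.c2.bmean,
                            fs.c2.bvar);
  fs.c2.a = relu_c(u2);
  cube h = maxpool2(fs.c2.a, fs.c2.argmax);
  fs.c2.pooled = h;

  // dilated residual tower
  fs.tower.resize(a.n_tower);
  fs.tower_in.resize(a.n_tower);
  std::vector<vec> rmt(a.n_tower), rvt(a.n_tower);
  for (int i = 0; i < a.n_tower; ++i) {
    const std::string tag = "tw" + std::to_string(i + 1);
    const int dil = 1 << i;
    fs.tower_in[i] = h;
    rmt[i] = getv(params, tag + "_bn_mean");
    rvt[i] = getv(params, tag + "_bn_var");
    fs.tower[i].z = conv1d_forward(h, getm(params, tag + "_W"),
                                   getv(params, tag + "_b"), a.Kt, dil,
                                   fs.tower[i].cols);
    cube ut = bn_conv_forward(fs.tower[i].z, getv(params, tag + "_bn_gamma"),
                              getv(params, tag + "_bn_beta"), training, rmt[i],
                              rvt[i], a.momentum, a.eps, fs.tower[i].xhat,
                              fs.tower[i].bmean, fs.tower[i].bvar);
    fs.tower[i].a = relu_c(ut);
    if (fs.tower[i].a.n_rows == h.n_rows) h = fs.tower[i].a + h;  // skip
    else h = fs.tower[i].a;
  }
  fs.pre_pool_trunk = h;
  fs.trunk = maxpool2(h, fs.trunk_sel);

  // profile head: flatten -> dense -> BN -> ReLU
  const uword L3 = fs.trunk.n_cols, Fd = fs.trunk.n_rows;
  fs.flat.set_size(B, Fd * L3);
  for (uword s = 0; s < B; ++s)
    fs.flat.row(s) = arma::vectorise(fs.trunk.slice(s)).t();
  mat Wp = getm(params, "prof_W");
  vec bp = getv(params, "prof_b");
  fs.prof_lin = fs.flat * Wp.t();
  fs.prof_lin.each_row() += bp.t();
  vec rmp = getv(params, "bnp_mean"), rvp = getv(params, "bnp_var");
  fs.prof_bn = bn_dense_forward(fs.prof_lin, getv(params, "bnp_gamma"),
                                getv(params, "bnp_beta"), training, rmp, rvp,
                                a.momentum, a.eps, fs.prof_xhat, fs.prof_bvar);
  fs.profile = arma::clamp(fs.prof_bn, 0.0f, arma::fdatum::inf);

  // quantity head: global average pool -> dense -> BN -> ReLU
  fs.gap.set_size(B, Fd);
  for (uword s = 0; s < B; ++s)
    fs.gap.row(s) = arma::mean(fs.trunk.slice(s), 1).t();
  mat Wq = getm(params, "quant_W");
  vec bq = getv(params, "quant_b");
  fs.q_lin = fs.gap * Wq.t();
  fs.q_lin.each_row() += bq.t();
  vec rmq = getv(params, "bnq_mean"), rvq = getv(params, "bnq_var");
  fs.q_bn = bn_dense_forward(fs.q_lin, getv(params, "bnq_gamma"),
                             getv(params, "bnq_beta"), training, rmq, rvq,
                             a.momentum, a.eps, fs.q_xhat, fs.q_bvar);
  fs.quantity = arma::clamp(fs.q_bn.col(0), 0.0f, arma::fdatum::inf);

  if (training) {
    state_out = List::create(
        Named("bn1_mean") = to_dv(rm1), Named("bn1_var") = to_dv(rv1),
        Named("bn2_mean") = to_dv(rm2), Named("bn2_var") = to_dv(rv2),
        Named("bnp_mean") = to_dv(rmp), Named("bnp_var") = to_dv(rvp),
        Named("bnq_mean") = to_dv(rmq), Named("bnq_var") = to_dv(rvq));
    for (int i = 0; i < a.n_tower; ++i) {
      const std::string tag = "tw" + std::to_string(i + 1);
      state_out[tag + "_bn_mean"] = to_dv(rmt[i]);
      state_out[tag + "_bn_var"] = to_dv(rvt[i]);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List nn_forward_cpp(List params, List arch, arma::cube X, bool training) {
  Arch a = read_arch(arch);
  if ((int)X.n_cols != a.L) stop("input length %d != expected %d", X.n_cols, a.L);
  cube Xf = arma::conv_to<cube>::from(X);
  ForwardState fs;
  List state;
  forward_pass(params, a, Xf, training, fs, state);
  List out = List::create(Named("profile") = to_d(fs.profile),
                          Named("quantity") = to_dv(fs.quantity));
  if (training) out["state"] = state;
  return out;
}

// Pooled trunk features (global average over length), inference mode.
// Used for closed-form calibration of the quantity head.
// [[Rcpp::export]]
arma::mat nn_gap_cpp(List params, List arch, arma::cube X) {
  Arch a = read_arch(arch);
  cube Xf = arma::conv_to<cube>::from(X);
  ForwardState fs;
  List state;
  forward_pass(params, a, Xf, false, fs, state);
  return to_d(fs.gap);
}

// [[Rcpp::export]]
double multiscale_loss_cpp(arma::mat p_obs, arma::mat y_profile,
                           arma::vec y_quantity, double lambda, double alpha) {
  const uword B = p_obs.n_rows;
  double total = 0.0;
  for (uword s = 0; s < B; ++s) {
    double np = arma::norm(p_obs.row(s), 2), ny = arma::norm(y_profile.row(s), 2);
    double cosv = (np > 0 && ny > 0)
                      ? arma::dot(p_obs.row(s), y_profile.row(s)) / (np * ny)
                      : 0.0;
    double d = std::log(arma::accu(p_obs.row(s)) + alpha) -
               std::log(y_quantity(s) + alpha);
    total += -cosv + lambda * d * d;
  }
  return total / (double)B;
}

// One fused forward+backward over a batch (training mode). Returns the mean
// multiscale loss, gradients for every trainable parameter, and updated
// batch-norm running statistics.
// [[Rcpp::export]]
List nn_loss_grad_cpp(List params, List arch, arma::cube X, arma::mat p_obs,
                      double lambda, double alpha) {
  Arch a = read_arch(arch);
  const uword B = X.n_slices;
  if (p_obs.n_rows != B) stop("batch size mismatch");
  if ((int)p_obs.n_cols != a.P) stop("observed profile length mismatch");
  cube Xf = arma::conv_to<cube>::from(X);
  mat pf = to_f(p_obs);
  ForwardState fs;
  List state;
  forward_pass(params, a, Xf, true, fs, state);

  // ----- loss and gradient wrt heads -----
  double total = 0.0;
  mat dprofile(B, a.P, arma::fill::zeros);
  vec dquant(B, arma::fill::zeros);
  for (uword s = 0; s < B; ++s) {
    arma::frowvec po = pf.row(s), yp = fs.profile.row(s);
    double np = arma::norm(po, 2), ny = arma::norm(yp, 2);
    double cosv = 0.0;
    if (np > 0 && ny > 0) {
      cosv = arma::dot(po, yp) / (np * ny);
      dprofile.row(s) = -(po / (np * ny) - cosv * yp / (ny * ny));
    }
    double q = fs.quantity(s);
    double d = std::log(arma::accu(po) + alpha) - std::log(q + alpha);
    total += -cosv + lambda * d * d;
    dquant(s) = -2.0 * lambda * d / (q + alpha);
  }
  total /= (double)B;
  dprofile /= (double)B;
  dquant /= (double)B;

  List grads;

  // ----- profile head backward -----
  mat d_prof_bn = dprofile % arma::conv_to<mat>::from(fs.prof_bn > 0);
  vec dgp, dbp_;
  mat d_prof_lin = bn_dense_backward(d_prof_bn, fs.prof_xhat,
                                     getv(params, "bnp_gamma"), fs.prof_bvar,
                                     a.eps, dgp, dbp_);
  grads["bnp_gamma"] = to_dv(dgp); grads["bnp_beta"] = to_dv(dbp_);
  mat Wp = getm(params, "prof_W");
  grads["prof_W"] = to_d(d_prof_lin.t() * fs.flat);
  grads["prof_b"] = to_dv(arma::sum(d_prof_lin, 0).t());
  mat dflat = d_prof_lin * Wp;  // (B, Fd*L3)

  // ----- quantity head backward -----
  mat d_q_bn(B, 1);
  d_q_bn.col(0) = dquant % arma::conv_to<vec>::from(fs.q_bn.col(0) > 0);
  vec dgq, dbq_;
  mat d_q_lin = bn_dense_backward(d_q_bn, fs.q_xhat, getv(params, "bnq_gamma"),
                                  fs.q_bvar, a.eps, dgq, dbq_);
  grads["bnq_gamma"] = to_dv(dgq); grads["bnq_beta"] = to_dv(dbq_);
  mat Wq = getm(params, "quant_W");
  grads["quant_W"] = to_d(d_q_lin.t() * fs.gap);
  grads["quant_b"] = to_dv(arma::sum(d_q_lin, 0).t());
  mat dgap = d_q_lin * Wq;  // (B, Fd)

  // ----- merge head gradients into trunk -----
  const uword L3 = fs.trunk.n_cols, Fd = fs.trunk.n_rows;
  cube dtrunk(Fd, L3, B, arma::fill::zeros);
  for (uword s = 0; s < B; ++s) {
    dtrunk.slice(s) = arma::reshape(dflat.row(s).t(), Fd, L3);
    dtrunk.slice(s).each_col() += dgap.row(s).t() / (double)L3;
  }
  cube dh = maxpool2_backward(dtrunk, fs.trunk_sel, fs.pre_pool_trunk.n_cols);

  // ----- tower backward -----
  for (int i = a.n_tower - 1; i >= 0; --i) {
    const std::string tag = "tw" + std::to_string(i + 1);
    const int dil = 1 << i;
    bool skip = (fs.tower[i].a.n_rows == fs.tower_in[i].n_rows);
    cube da = dh;  // gradient into the activation branch
    cube du = da % arma::conv_to<cube>::from(fs.tower[i].a > 0);
    vec dg, db2;
    cube dz = bn_conv_backward(du, fs.tower[i].xhat,
                               getv(params, tag + "_bn_gamma"),
                               fs.tower[i].bvar, a.eps, dg, db2);
    grads[tag + "_bn_gamma"] = to_dv(dg); grads[tag + "_bn_beta"] = to_dv(db2);
    mat dW; vec db;
    cube dxi = conv1d_backward(dz, fs.tower[i].cols, getm(params, tag + "_W"),
                               a.Kt, dil, fs.tower_in[i].n_rows, dW, db);
    grads[tag + "_W"] = to_d(dW); grads[tag + "_b"] = to_dv(db);
    if (skip) dh = dxi + dh;  // identity branch
    else dh = dxi;
  }

  // ----- conv block 2 backward -----
  cube dp2 = maxpool2_backward(dh, fs.c2.argmax, fs.c2.a.n_cols);
  cube du2 = dp2 % arma::conv_to<cube>::from(fs.c2.a > 0);
  {
    vec dg, db2;
    cube dz2 = bn_conv_backward(du2, fs.c2.xhat, getv(params, "bn2_gamma"),
                                fs.c2.bvar, a.eps, dg, db2);
    grads["bn2_gamma"] = to_dv(dg); grads["bn2_beta"] = to_dv(db2);
    mat dW; vec db;
    cube dp1 = conv1d_backward(dz2, fs.c2.cols, getm(params, "conv2_W"), a.K2,
                               1, fs.c1.pooled.n_rows, dW, db);
    grads["conv2_W"] = to_d(dW); grads["conv2_b"] = to_dv(db);

    // ----- conv block 1 backward -----
    cube da1 = maxpool2_backward(dp1, fs.c1.argmax, fs.c1.a.n_cols);
    // ELU'(u) = 1 for u > 0 else exp(u) = a + 1
    cube du1 = da1;
    for (uword s = 0; s < du1.n_slices; ++s)
      for (uword t = 0; t < du1.n_cols; ++t)
        for (uword f = 0; f < du1.n_rows; ++f)
          if (fs.c1.a(f, t, s) <= 0) du1(f, t, s) *= fs.c1.a(f, t, s) + 1.0;
    vec dg1, db1;
    cube dz1 = bn_conv_backward(du1, fs.c1.xhat, getv(params, "bn1_gamma"),
                                fs.c1.bvar, a.eps, dg1, db1);
    grads["bn1_gamma"] = to_dv(dg1); grads["bn1_beta"] = to_dv(db1);
    mat dW1; vec db1b;
    conv1d_backward(dz1, fs.c1.cols, getm(params, "conv1_W"), a.K1, 1, 4, dW1,
                    db1b);
    grads["conv1_W"] = to_d(dW1); grads["conv1_b"] = to_dv(db1b);
  }

  return List::create(Named("loss") = total, Named("grads") = grads,
                      Named("state") = state,
                      Named("profile") = to_d(fs.profile),
                      Named("quantity") = to_dv(fs.quantity));
}
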