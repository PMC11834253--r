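// Full-batch training loop for the two-branch graph model: forward pass with
// inverted dropout, hand-derived reverse-mode gradients, Adam with classic L2
// weight decay, per-epoch validation and early stopping with best-weights
// restoration. Mirrors the R reference implementation (R/gnn_core.R,
// R/backprop.R) operation for operation; the two paths are cross-checked in
// the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::sp_mat;

namespace {

inline mat relu(const mat& x) { return x % (x > 0); }

inline mat elu(const mat& x) {
  mat r = x;
  double* p = r.memptr();
  const arma::uword ne = r.n_elem;
  for (arma::uword k = 0; k < ne; ++k)
    if (p[k] <= 0) p[k] = std::expm1(p[k]);
  return r;
}

// inverted dropout mask drawn from R's RNG (respects set.seed)
mat dropout_mask(int n, int d, double rate) {
  mat m(n, d);
  const double scale = 1.0 / (1.0 - rate);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      m(i, j) = (unif_rand() >= rate) ? scale : 0.0;
  return m;
}

struct AttCache {
  mat zt;  // transposed transformed features (F' x n): contiguous per node
  vec alpha, pre;
};

// one attention head forward: logits, neighborhood softmax, aggregation
mat att_forward(const mat& hin, const mat& w, const vec& a,
                const arma::ivec& ei, const arma::ivec& ej,
                const arma::ivec& ends_i, double slope, AttCache& cache) {
  const int m = ei.n_elem, n = hin.n_rows, f = w.n_cols;
  cache.zt = (hin * w).t();
  vec s = cache.zt.t() * a.subvec(0, f - 1);
  vec t = cache.zt.t() * a.subvec(f, 2 * f - 1);
  cache.pre.set_size(m);
  vec logit(m);
  for (int k = 0; k < m; ++k) {
    double v = s[ei[k] - 1] + t[ej[k] - 1];
    cache.pre[k] = v;
    logit[k] = v > 0 ? v : slope * v;
  }
  cache.alpha.set_size(m);
  int start = 0;
  for (int i = 0; i < n; ++i) {
    int end = ends_i[i];
    if (end > start) {
      double mx = logit[start];
      for (int k = start + 1; k < end; ++k)
        if (logit[k] > mx) mx = logit[k];
      double denom = 0.0;
      for (int k = start; k < end; ++k) {
        cache.alpha[k] = std::exp(logit[k] - mx);
        denom += cache.alpha[k];
      }
      for (int k = start; k < end; ++k) cache.alpha[k] /= denom;
    }
    start = end;
  }
  mat out_t(f, n, arma::fill::zeros);
  for (int k = 0; k < m; ++k)
    out_t.col(ei[k] - 1) += cache.alpha[k] * cache.zt.col(ej[k] - 1);
  return out_t.t();
}

// one attention head backward; returns gradient w.r.t. the head input when
// need_dh is set
void att_backward(const AttCache& cache, const mat& g, const mat& hin,
                  const mat& w, const vec& a, const arma::ivec& ei,
                  const arma::ivec& ej, const arma::ivec& ends_i, double slope,
                  mat& dw, vec& da, mat* dh) {
  const int m = ei.n_elem, n = g.n_rows, f = w.n_cols;
  const mat gt = g.t();
  mat dzt(f, n, arma::fill::zeros);
  vec dalpha(m);
  for (int k = 0; k < m; ++k) {
    const int i = ei[k] - 1, j = ej[k] - 1;
    dzt.col(j) += cache.alpha[k] * gt.col(i);
    dalpha[k] = arma::dot(gt.col(i), cache.zt.col(j));
  }
  vec ds(n, arma::fill::zeros), dt(n, arma::fill::zeros);
  int start = 0;
  for (int i = 0; i < n; ++i) {
    int end = ends_i[i];
    double sdot = 0.0;
    for (int k = start; k < end; ++k) sdot += cache.alpha[k] * dalpha[k];
    for (int k = start; k < end; ++k) {
      double de = cache.alpha[k] * (dalpha[k] - sdot);
      double beta = de * (cache.pre[k] > 0 ? 1.0 : slope);
      ds[i] += beta;
      dt[ej[k] - 1] += beta;
    }
    start = end;
  }
  vec a_src = a.subvec(0, f - 1), a_dst = a.subvec(f, 2 * f - 1);
  mat dz = dzt.t() + ds * a_src.t() + dt * a_dst.t();
  dw = hin.t() * dz;
  da = arma::join_cols(cache.zt * ds, cache.zt * dt);
  if (dh) *dh = dz * w.t();
}

struct Model {
  // branches: 0 = both, 1 = gcn only, 2 = gat only
  int branches, kh, ko;
  double slope;
  std::vector<mat> gcnW;
  std::vector<mat> gathW, gatoW;
  std::vector<vec> gatha, gatoa;
  mat mlpW1, mlpW2;
  vec mlpb1, mlpb2;

  std::vector<mat*> mats;
  std::vector<vec*> vecs;
  void index() {
    mats.clear(); vecs.clear();
    for (auto& w : gcnW) mats.push_back(&w);
    for (auto& w : gathW) mats.push_back(&w);
    for (auto& w : gatoW) mats.push_back(&w);
    mats.push_back(&mlpW1); mats.push_back(&mlpW2);
    for (auto& v : gatha) vecs.push_back(&v);
    for (auto& v : gatoa) vecs.push_back(&v);
    vecs.push_back(&mlpb1); vecs.push_back(&mlpb2);
  }
};

struct Cache {
  std::vector<mat> gcn_in, gcn_z;
  mat gat_in, hcat_pre, gat_out_in;
  std::vector<AttCache> att_h, att_o;
  mat gef, mlp_in1, mlp_a1, mlp_in2;
  vec logits, probs;
};

struct Masks {
  std::vector<mat> gcn;
  mat gat_in, gat_out_in, mlp1, mlp2;
  bool active = false;
};

vec forward(const Model& mdl, const mat& x, const sp_mat& adjn,
            const arma::ivec& ei, const arma::ivec& ej,
            const arma::ivec& ends_i, const Masks& mk, Cache& c) {
  const int n = x.n_rows;
  mat e_gcn, e_gat;
  if (mdl.branches != 2) {
    const int L = mdl.gcnW.size();
    c.gcn_in.resize(L); c.gcn_z.resize(L);
    mat h = x;
    for (int l = 0; l < L; ++l) {
      c.gcn_in[l] = mk.active ? mat(h % mk.gcn[l]) : h;
      c.gcn_z[l] = adjn * (c.gcn_in[l] * mdl.gcnW[l]);
      h = (l < L - 1) ? relu(c.gcn_z[l]) : c.gcn_z[l];
    }
    e_gcn = h;
  }
  if (mdl.branches != 1) {
    c.gat_in = mk.active ? mat(x % mk.gat_in) : x;
    c.att_h.resize(mdl.kh);
    const int fh = mdl.gathW[0].n_cols;
    mat hcat(n, fh * mdl.kh);
    for (int k = 0; k < mdl.kh; ++k) {
      hcat.cols(k * fh, (k + 1) * fh - 1) =
        att_forward(c.gat_in, mdl.gathW[k], mdl.gatha[k], ei, ej, ends_i,
                    mdl.slope, c.att_h[k]);
    }
    c.hcat_pre = hcat;
    mat hact = elu(hcat);
    c.gat_out_in = mk.active ? mat(hact % mk.gat_out_in) : hact;
    c.att_o.resize(mdl.ko);
    e_gat.zeros(n, mdl.gatoW[0].n_cols);
    for (int k = 0; k < mdl.ko; ++k) {
      e_gat += att_forward(c.gat_out_in, mdl.gatoW[k], mdl.gatoa[k], ei, ej,
                           ends_i, mdl.slope, c.att_o[k]) / mdl.ko;
    }
  }
  c.gef = (mdl.branches == 0) ? mat(arma::join_rows(e_gcn, e_gat))
          : (mdl.branches == 1 ? e_gcn : e_gat);
  c.mlp_in1 = mk.active ? mat(c.gef % mk.mlp1) : c.gef;
  c.mlp_a1 = c.mlp_in1 * mdl.mlpW1;
  c.mlp_a1.each_row() += mdl.mlpb1.t();
  mat h1 = relu(c.mlp_a1);
  c.mlp_in2 = mk.active ? mat(h1 % mk.mlp2) : h1;
  c.logits = c.mlp_in2 * mdl.mlpW2 + mdl.mlpb2[0];
  c.probs = 1.0 / (1.0 + arma::exp(-c.logits));
  return c.probs;
}

void backward(const Model& mdl, Model& grad, const mat& x, const sp_mat& adjn,
              const arma::ivec& ei, const arma::ivec& ej,
              const arma::ivec& ends_i, const Masks& mk, const Cache& c,
              const vec& dlogits) {
  grad.mlpW2 = c.mlp_in2.t() * dlogits;
  grad.mlpb2 = vec{arma::accu(dlogits)};
  mat dh1 = dlogits * mdl.mlpW2.t();
  if (mk.active) dh1 %= mk.mlp2;
  mat da1 = dh1 % (c.mlp_a1 > 0);
  grad.mlpW1 = c.mlp_in1.t() * da1;
  grad.mlpb1 = arma::sum(da1, 0).t();
  mat dgef = da1 * mdl.mlpW1.t();
  if (mk.active) dgef %= mk.mlp1;

  mat de_gcn, de_gat;
  if (mdl.branches == 0) {
    const int dg = mdl.gcnW.back().n_cols;
    de_gcn = dgef.cols(0, dg - 1);
    de_gat = dgef.cols(dg, dgef.n_cols - 1);
  } else if (mdl.branches == 1) {
    de_gcn = dgef;
  } else {
    de_gat = dgef;
  }

  if (mdl.branches != 2) {
    const int L = mdl.gcnW.size();
    mat delta = de_gcn;  // linear output embedding
    for (int l = L - 1; l >= 0; --l) {
      mat du = adjn * delta;  // adjn is symmetric
      grad.gcnW[l] = c.gcn_in[l].t() * du;
      if (l > 0) {
        mat dh = du * mdl.gcnW[l].t();
        if (mk.active) dh %= mk.gcn[l];
        delta = dh % (c.gcn_z[l - 1] > 0);
      }
    }
  }

  if (mdl.branches != 1) {
    mat dhd(c.gat_out_in.n_rows, c.gat_out_in.n_cols, arma::fill::zeros);
    for (int k = 0; k < mdl.ko; ++k) {
      mat dh_k;
      att_backward(c.att_o[k], de_gat / mdl.ko, c.gat_out_in, mdl.gatoW[k],
                   mdl.gatoa[k], ei, ej, ends_i, mdl.slope,
                   grad.gatoW[k], grad.gatoa[k], &dh_k);
      dhd += dh_k;
    }
    if (mk.active) dhd %= mk.gat_out_in;
    // ELU'(pre) = 1 for pre > 0, exp(pre) otherwise
    mat dhcat = dhd;
    const arma::uword nel = c.hcat_pre.n_elem;
    for (arma::uword t = 0; t < nel; ++t)
      if (c.hcat_pre[t] <= 0) dhcat[t] *= std::exp(c.hcat_pre[t]);
    const int fh = mdl.gathW[0].n_cols;
    for (int k = 0; k < mdl.kh; ++k) {
      mat gk = dhcat.cols(k * fh, (k + 1) * fh - 1);
      att_backward(c.att_h[k], gk, c.gat_in, mdl.gathW[k], mdl.gatha[k],
                   ei, ej, ends_i, mdl.slope, grad.gathW[k], grad.gatha[k],
                   nullptr);
    }
  }
}

struct Adam {
  std::vector<mat> m_mat, v_mat;
  std::vector<vec> m_vec, v_vec;
  long t = 0;
  void init(const Model& mdl) {
    for (auto* w : mdl.mats) {
      m_mat.push_back(mat(w->n_rows, w->n_cols, arma::fill::zeros));
      v_mat.push_back(mat(w->n_rows, w->n_cols, arma::fill::zeros));
    }
    for (auto* v : mdl.vecs) {
      m_vec.push_back(vec(v->n_elem, arma::fill::zeros));
      v_vec.push_back(vec(v->n_elem, arma::fill::zeros));
    }
  }
  void step(Model& mdl, const Model& grad, double lr, double wd) {
    ++t;
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    const double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
    for (size_t i = 0; i < mdl.mats.size(); ++i) {
      mat g = *grad.mats[i] + wd * (*mdl.mats[i]);
      m_mat[i] = b1 * m_mat[i] + (1 - b1) * g;
      v_mat[i] = b2 * v_mat[i] + (1 - b2) * (g % g);
      *mdl.mats[i] -= lr * (m_mat[i] / bc1) / (arma::sqrt(v_mat[i] / bc2) + eps);
    }
    for (size_t i = 0; i < mdl.vecs.size(); ++i) {
      vec g = *grad.vecs[i] + wd * (*mdl.vecs[i]);
      m_vec[i] = b1 * m_vec[i] + (1 - b1) * g;
      v_vec[i] = b2 * v_vec[i] + (1 - b2) * (g % g);
      *mdl.vecs[i] -= lr * (m_vec[i] / bc1) / (arma::sqrt(v_vec[i] / bc2) + eps);
    }
  }
};

double masked_loss(const vec& probs, const vec& y01, const arma::ivec& idx,
                   double cw) {
  double s = 0.0;
  for (arma::uword k = 0; k < idx.n_elem; ++k) {
    const int i = idx[k] - 1;
    double p = std::min(std::max(probs[i], 1e-12), 1.0 - 1e-12);
    s += y01[i] > 0.5 ? -cw * std::log(p) : -std::log1p(-p);
  }
  return s / idx.n_elem;
}

Model model_from_list(const List& params, int branches, int kh, int ko,
                      double slope) {
  Model mdl;
  mdl.branches = branches; mdl.kh = kh; mdl.ko = ko; mdl.slope = slope;
  if (branches != 2) {
    for (int l = 1; ; ++l) {
      std::string nm = "gcn.W" + std::to_string(l);
      if (!params.containsElementNamed(nm.c_str())) break;
      mdl.gcnW.push_back(as<mat>(params[nm]));
    }
  }
  if (branches != 1) {
    for (int k = 1; k <= kh; ++k) {
      mdl.gathW.push_back(as<mat>(params["gat.h" + std::to_string(k) + ".W"]));
      mdl.gatha.push_back(as<vec>(params["gat.h" + std::to_string(k) + ".a"]));
    }
    for (int k = 1; k <= ko; ++k) {
      mdl.gatoW.push_back(as<mat>(params["gat.o" + std::to_string(k) + ".W"]));
      mdl.gatoa.push_back(as<vec>(params["gat.o" + std::to_string(k) + ".a"]));
    }
  }
  mdl.mlpW1 = as<mat>(params["mlp.W1"]);
  mdl.mlpb1 = as<vec>(params["mlp.b1"]);
  mdl.mlpW2 = as<mat>(params["mlp.W2"]);
  mdl.mlpb2 = as<vec>(params["mlp.b2"]);
  mdl.index();
  return mdl;
}

List model_to_list(const Model& mdl) {
  List out;
  for (size_t l = 0; l < mdl.gcnW.size(); ++l)
    out["gcn.W" + std::to_string(l + 1)] = mdl.gcnW[l];
  for (int k = 0; k < (int)mdl.gathW.size(); ++k) {
    out["gat.h" + std::to_string(k + 1) + ".W"] = mdl.gathW[k];
    out["gat.h" + std::to_string(k + 1) + ".a"] =
      NumericVector(mdl.gatha[k].begin(), mdl.gatha[k].end());
  }
  for (int k = 0; k < (int)mdl.gatoW.size(); ++k) {
    out["gat.o" + std::to_string(k + 1) + ".W"] = mdl.gatoW[k];
    out["gat.o" + std::to_string(k + 1) + ".a"] =
      NumericVector(mdl.gatoa[k].begin(), mdl.gatoa[k].end());
  }
  out["mlp.W1"] = mdl.mlpW1;
  out["mlp.b1"] = NumericVector(mdl.mlpb1.begin(), mdl.mlpb1.end());
  out["mlp.W2"] = mdl.mlpW2;
  out["mlp.b2"] = NumericVector(mdl.mlpb2.begin(), mdl.mlpb2.end());
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".train_loop_cpp")]]
List train_loop_cpp(const arma::mat& x, const arma::sp_mat& adjn,
                    const arma::ivec& ei, const arma::ivec& ej,
                    const arma::ivec& ends_i, List params_init,
                    const arma::vec& y01, const arma::ivec& train_idx,
                    const arma::ivec& val_idx, double class_weight,
                    int branches, int kh, int ko, double slope,
                    double dropout, double lr, double weight_decay,
                    int max_epochs, int patience) {
  const int n = x.n_rows, d = x.n_cols;
  Model mdl = model_from_list(params_init, branches, kh, ko, slope);
  Model grad = mdl;  // same shapes; values overwritten each epoch
  grad.index();
  Adam opt;
  opt.init(mdl);

  Model best = mdl;
  double best_loss = R_PosInf;
  int best_epoch = 0, wait = 0, epoch = 0;
  Cache c;
  Masks mk;
  mk.active = dropout > 0;

  while (epoch < max_epochs) {
    ++epoch;
    if (mk.active) {
      if (branches != 2) {
        mk.gcn.clear();
        int din = d;
        for (size_t l = 0; l < mdl.gcnW.size(); ++l) {
          mk.gcn.push_back(dropout_mask(n, din, dropout));
          din = mdl.gcnW[l].n_cols;
        }
      }
      if (branches != 1) {
        mk.gat_in = dropout_mask(n, d, dropout);
        mk.gat_out_in = dropout_mask(n, mdl.gathW[0].n_cols * kh, dropout);
      }
      mk.mlp1 = dropout_mask(n, (branches == 0)
                                  ? mdl.gcnW.back().n_cols + mdl.gatoW[0].n_cols
                                  : (branches == 1 ? mdl.gcnW.back().n_cols
                                                   : mdl.gatoW[0].n_cols),
                             dropout);
      mk.mlp2 = dropout_mask(n, mdl.mlpW1.n_cols, dropout);
    }
    vec probs = forward(mdl, x, adjn, ei, ej, ends_i, mk, c);
    if (!probs.is_finite())
      stop("training diverged (non-finite probabilities) at epoch %d", epoch);
    vec dl(n, arma::fill::zeros);
    for (arma::uword k = 0; k < train_idx.n_elem; ++k) {
      const int i = train_idx[k] - 1;
      dl[i] = (y01[i] > 0.5 ? -class_weight * (1.0 - probs[i]) : probs[i]) /
              train_idx.n_elem;
    }
    backward(mdl, grad, x, adjn, ei, ej, ends_i, mk, c, dl);
    opt.step(mdl, grad, lr, weight_decay);

    Masks off;
    Cache ce;
    vec pe = forward(mdl, x, adjn, ei, ej, ends_i, off, ce);
    double val_loss = masked_loss(pe, y01, val_idx, class_weight);
    if (!std::isfinite(val_loss))
      stop("training diverged (non-finite validation loss) at epoch %d", epoch);
    if (val_loss < best_loss - 1e-9) {
      best_loss = val_loss;
      best = mdl;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }

  best.index();
  Masks off;
  Cache cf;
  vec probs = forward(best, x, adjn, ei, ej, ends_i, off, cf);
  return List::create(_["params"] = model_to_list(best),
                      _["probs"] = NumericVector(probs.begin(), probs.end()),
                      _["epochs_run"] = epoch, _["best_epoch"] = best_epoch,
                      _["best_val_loss"] = best_loss);
}
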