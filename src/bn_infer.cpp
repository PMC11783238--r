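// Discrete Bayesian network inference core.
//
// Networks arrive flattened: per-node cardinalities, 0-based parent index
// vectors, and CPTs as flat vectors laid out row-major over parent
// configurations (first parent most significant, node state varying
// fastest): cpt[j * r + k] = P(node = k | parent config j).
//
// Evidence / data use -1 for unobserved cells, otherwise 0-based states.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <functional>
using namespace Rcpp;

namespace {

struct Net {
  int V;
  std::vector<int> cards;
  std::vector<std::vector<int>> parents;
  std::vector<std::vector<double>> cpts;
};

Net make_net(const IntegerVector& cards, const List& parents, const List& cpts) {
  Net net;
  net.V = cards.size();
  net.cards.assign(cards.begin(), cards.end());
  net.parents.resize(net.V);
  net.cpts.resize(net.V);
  for (int v = 0; v < net.V; ++v) {
    IntegerVector p = parents[v];
    net.parents[v].assign(p.begin(), p.end());
    NumericVector c = cpts[v];
    net.cpts[v].assign(c.begin(), c.end());
  }
  return net;
}

struct Factor {
  std::vector<int> vars;   // ascending variable ids
  std::vector<double> val; // last var varies fastest
};

// CPT of `node` reduced on observed evidence; result over unobserved family
// members, sorted by variable id.
Factor reduce_cpt(const Net& net, int node, const std::vector<int>& ev) {
  const std::vector<int>& P = net.parents[node];
  std::vector<int> full(P);
  full.push_back(node);
  const int m = (int)full.size();
  std::vector<long> stride(m);
  long s = 1;
  for (int t = m - 1; t >= 0; --t) { stride[t] = s; s *= net.cards[full[t]]; }
  long base = 0;
  std::vector<int> keptPos;
  for (int t = 0; t < m; ++t) {
    if (ev[full[t]] >= 0) base += (long)ev[full[t]] * stride[t];
    else keptPos.push_back(t);
  }
  std::sort(keptPos.begin(), keptPos.end(),
            [&](int a, int b) { return full[a] < full[b]; });
  Factor f;
  for (int t : keptPos) f.vars.push_back(full[t]);
  long n = 1;
  for (int v : f.vars) n *= net.cards[v];
  f.val.resize(n);
  const int kk = (int)f.vars.size();
  std::vector<int> digit(kk, 0);
  for (long i = 0; i < n; ++i) {
    long idx = base;
    for (int t = 0; t < kk; ++t) idx += (long)digit[t] * stride[keptPos[t]];
    f.val[i] = net.cpts[node][idx];
    for (int t = kk - 1; t >= 0; --t) {
      if (++digit[t] < net.cards[f.vars[t]]) break;
      digit[t] = 0;
    }
  }
  return f;
}

// Sum `v` out of the product of all factors containing it. Rescales the new
// factor to max 1 and accumulates the log scale in `logc`. Returns false when
// the new factor is identically zero (impossible evidence).
bool eliminate_var(std::vector<Factor>& fs, int v, const Net& net, double& logc) {
  std::vector<Factor> touching, rest;
  for (Factor& f : fs) {
    if (std::binary_search(f.vars.begin(), f.vars.end(), v))
      touching.push_back(std::move(f));
    else
      rest.push_back(std::move(f));
  }
  std::vector<int> U;
  for (const Factor& f : touching)
    for (int x : f.vars) U.push_back(x);
  std::sort(U.begin(), U.end());
  U.erase(std::unique(U.begin(), U.end()), U.end());
  const int mu = (int)U.size();
  long nU = 1;
  for (int x : U) nU *= net.cards[x];
  std::vector<std::vector<long>> fstr(touching.size(), std::vector<long>(mu, 0));
  for (size_t fi = 0; fi < touching.size(); ++fi) {
    const Factor& f = touching[fi];
    const int mf = (int)f.vars.size();
    std::vector<long> str(mf);
    long s = 1;
    for (int t = mf - 1; t >= 0; --t) { str[t] = s; s *= net.cards[f.vars[t]]; }
    for (int t = 0; t < mu; ++t) {
      auto it = std::lower_bound(f.vars.begin(), f.vars.end(), U[t]);
      if (it != f.vars.end() && *it == U[t]) fstr[fi][t] = str[it - f.vars.begin()];
    }
  }
  const int posv = (int)(std::lower_bound(U.begin(), U.end(), v) - U.begin());
  Factor res;
  for (int x : U)
    if (x != v) res.vars.push_back(x);
  res.val.assign(nU / net.cards[v], 0.0);
  std::vector<long> rstr(mu, 0);
  {
    long s = 1;
    for (int t = mu - 1; t >= 0; --t) {
      if (t == posv) continue;
      rstr[t] = s;
      s *= net.cards[U[t]];
    }
  }
  std::vector<int> dg(mu, 0);
  for (long i = 0; i < nU; ++i) {
    double p = 1.0;
    for (size_t fi = 0; fi < touching.size(); ++fi) {
      long idx = 0;
      for (int t = 0; t < mu; ++t) idx += fstr[fi][t] * dg[t];
      p *= touching[fi].val[idx];
    }
    long ridx = 0;
    for (int t = 0; t < mu; ++t) ridx += rstr[t] * dg[t];
    res.val[ridx] += p;
    for (int t = mu - 1; t >= 0; --t) {
      if (++dg[t] < net.cards[U[t]]) break;
      dg[t] = 0;
    }
  }
  double mx = 0.0;
  for (double x : res.val) mx = std::max(mx, x);
  if (mx <= 0.0) return false;
  for (double& x : res.val) x /= mx;
  logc += std::log(mx);
  fs = std::move(rest);
  fs.push_back(std::move(res));
  return true;
}

// Product of all remaining factors, over the (sorted) union of their vars.
Factor multiply_all(const std::vector<Factor>& fs, const Net& net) {
  std::vector<int> U;
  for (const Factor& f : fs)
    for (int x : f.vars) U.push_back(x);
  std::sort(U.begin(), U.end());
  U.erase(std::unique(U.begin(), U.end()), U.end());
  const int mu = (int)U.size();
  long nU = 1;
  for (int x : U) nU *= net.cards[x];
  std::vector<std::vector<long>> fstr(fs.size(), std::vector<long>(mu, 0));
  for (size_t fi = 0; fi < fs.size(); ++fi) {
    const Factor& f = fs[fi];
    const int mf = (int)f.vars.size();
    std::vector<long> str(mf);
    long s = 1;
    for (int t = mf - 1; t >= 0; --t) { str[t] = s; s *= net.cards[f.vars[t]]; }
    for (int t = 0; t < mu; ++t) {
      auto it = std::lower_bound(f.vars.begin(), f.vars.end(), U[t]);
      if (it != f.vars.end() && *it == U[t]) fstr[fi][t] = str[it - f.vars.begin()];
    }
  }
  Factor res;
  res.vars = U;
  res.val.assign(nU, 0.0);
  std::vector<int> dg(mu, 0);
  for (long i = 0; i < nU; ++i) {
    double p = 1.0;
    for (size_t fi = 0; fi < fs.size(); ++fi) {
      long idx = 0;
      for (int t = 0; t < mu; ++t) idx += fstr[fi][t] * dg[t];
      p *= fs[fi].val[idx];
    }
    res.val[i] = p;
    for (int t = mu - 1; t >= 0; --t) {
      if (++dg[t] < net.cards[U[t]]) break;
      dg[t] = 0;
    }
  }
  return res;
}

// Min-degree choice among remaining elimination candidates; ties broken by
// smallest variable id (registry order).
int pick_min_degree(const std::vector<Factor>& fs, const std::vector<int>& elim) {
  int best = -1, bestdeg = -1;
  for (int v : elim) {
    std::vector<int> nb;
    for (const Factor& f : fs)
      if (std::binary_search(f.vars.begin(), f.vars.end(), v))
        for (int x : f.vars) nb.push_back(x);
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    int deg = (int)nb.size() - 1;
    if (best < 0 || deg < bestdeg || (deg == bestdeg && v < best)) {
      best = v;
      bestdeg = deg;
    }
  }
  return best;
}

// Variable elimination over the CPT factors of `fams`. Returns the
// unnormalized joint over `keep` (sorted); log of the summed-out mass is
// logZ + log(sum of returned values). `ok` is false when the evidence has
// probability zero under these factors.
Factor ve_marginal_fams(const Net& net, const std::vector<int>& ev,
                        const std::vector<int>& fams,
                        const std::vector<int>& keep, double& logZ, bool& ok) {
  std::vector<Factor> fs;
  fs.reserve(fams.size());
  std::vector<int> seen;
  for (int v : fams) {
    Factor f = reduce_cpt(net, v, ev);
    for (int x : f.vars) seen.push_back(x);
    fs.push_back(std::move(f));
  }
  std::sort(seen.begin(), seen.end());
  seen.erase(std::unique(seen.begin(), seen.end()), seen.end());
  std::vector<bool> keepmask(net.V, false);
  for (int k : keep) keepmask[k] = true;
  std::vector<int> elim;
  for (int v : seen)
    if (!keepmask[v]) elim.push_back(v);
  logZ = 0.0;
  ok = true;
  while (!elim.empty()) {
    int v = pick_min_degree(fs, elim);
    elim.erase(std::find(elim.begin(), elim.end(), v));
    if (!eliminate_var(fs, v, net, logZ)) { ok = false; return Factor(); }
  }
  return multiply_all(fs, net);
}

// Variable elimination over the full network.
Factor ve_marginal(const Net& net, const std::vector<int>& ev,
                   const std::vector<int>& keep, double& logZ, bool& ok) {
  std::vector<int> fams(net.V);
  for (int v = 0; v < net.V; ++v) fams[v] = v;
  return ve_marginal_fams(net, ev, fams, keep, logZ, ok);
}

std::vector<int> row_evidence(const IntegerMatrix& data, int i) {
  std::vector<int> ev(data.ncol());
  for (int v = 0; v < data.ncol(); ++v) {
    int x = data(i, v);
    ev[v] = (x == NA_INTEGER || x < 0) ? -1 : x;
  }
  return ev;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_posterior(IntegerVector cards, List parents, List cpts,
                            IntegerVector evidence, int target) {
  Net net = make_net(cards, parents, cpts);
  std::vector<int> ev(evidence.begin(), evidence.end());
  for (int v = 0; v < net.V; ++v)
    if (ev[v] == NA_INTEGER) ev[v] = -1;
  ev[target] = -1;
  double logZ;
  bool ok;
  Factor f = ve_marginal(net, ev, std::vector<int>{target}, logZ, ok);
  NumericVector out(net.cards[target]);
  if (!ok) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  double s = 0.0;
  for (double x : f.val) s += x;
  if (s <= 0.0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  for (int k = 0; k < net.cards[target]; ++k) out[k] = f.val[k] / s;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_predict(IntegerVector cards, List parents, List cpts,
                          IntegerMatrix data, int target) {
  Net net = make_net(cards, parents, cpts);
  const int n = data.nrow();
  NumericMatrix out(n, net.cards[target]);
  for (int i = 0; i < n; ++i) {
    std::vector<int> ev = row_evidence(data, i);
    ev[target] = -1;
    double logZ;
    bool ok;
    Factor f = ve_marginal(net, ev, std::vector<int>{target}, logZ, ok);
    double s = 0.0;
    if (ok)
      for (double x : f.val) s += x;
    for (int k = 0; k < net.cards[target]; ++k)
      out(i, k) = (ok && s > 0.0) ? f.val[k] / s : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_loglik(IntegerVector cards, List parents, List cpts,
                         IntegerMatrix data) {
  Net net = make_net(cards, parents, cpts);
  const int n = data.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> ev = row_evidence(data, i);
    double logZ;
    bool ok;
    Factor f = ve_marginal(net, ev, std::vector<int>(), logZ, ok);
    if (!ok) {
      out[i] = R_NegInf;
      continue;
    }
    double s = 0.0;
    for (double x : f.val) s += x;
    out[i] = logZ + std::log(s);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_counts(IntegerMatrix data, IntegerVector cards, int node,
                         IntegerVector parents) {
  const int r = cards[node];
  const int m = parents.size();
  long q = 1;
  for (int t = 0; t < m; ++t) q *= cards[parents[t]];
  NumericMatrix out(q, r);
  std::vector<long> stride(m);
  long s = 1;
  for (int t = m - 1; t >= 0; --t) { stride[t] = s; s *= cards[parents[t]]; }
  for (int i = 0; i < data.nrow(); ++i) {
    int k = data(i, node);
    if (k == NA_INTEGER || k < 0) continue;
    long j = 0;
    bool okrow = true;
    for (int t = 0; t < m; ++t) {
      int x = data(i, parents[t]);
      if (x == NA_INTEGER || x < 0) { okrow = false; break; }
      j += stride[t] * x;
    }
    if (okrow) out(j, k) += 1.0;
  }
  return out;
}

// Expectation-maximization for CPT parameters under arbitrary missingness.
//
// The E-step decomposes per record into (a) fully observed families, whose
// unit counts and CPT cell indices never change across iterations, and
// (b) connected components of unobserved variables in the family (moral)
// graph, whose joint posterior is enumerated exactly. Both parts are
// precompiled once into an index program before iterating, so an EM
// iteration is pure gather-multiply-scatter. Components whose state table
// exceeds `comp_limit` fall back to per-family variable elimination, which
// exploits conditional independence inside large components. The
// observed-data log-likelihood comes from the component normalizers.
// [[Rcpp::export]]
List cpp_em(IntegerVector cards, List parents, List cpts_init,
            IntegerMatrix data, double alpha, double tol, int max_iter,
            double comp_limit = 2187) {
  Net net = make_net(cards, parents, cpts_init);
  const int V = net.V;
  const int n = data.nrow();

  // family layout: full var list (parents..node), strides, q
  std::vector<std::vector<int>> ffull(V);
  std::vector<std::vector<long>> fstride(V);
  std::vector<long> fq(V);
  for (int v = 0; v < V; ++v) {
    ffull[v] = net.parents[v];
    ffull[v].push_back(v);
    const int m = (int)ffull[v].size();
    fstride[v].resize(m);
    long s = 1;
    for (int t = m - 1; t >= 0; --t) { fstride[v][t] = s; s *= net.cards[ffull[v][t]]; }
    fq[v] = s / net.cards[v];
  }

  // ---- precompile the E-step program ----
  // base counts from fully observed families (constant across iterations)
  std::vector<std::vector<double>> EN_base(V);
  for (int v = 0; v < V; ++v) EN_base[v].assign(net.cpts[v].size(), 0.0);

  // enumerable components: flattened storage
  struct Comp {
    int nfam, ncfg;
    size_t fam_off;  // into comp_fam (node ids)
    size_t idx_off;  // into comp_idx (ncfg * nfam CPT indices)
  };
  std::vector<Comp> comps;
  std::vector<int> comp_fam;
  std::vector<int> comp_idx;
  // oversized components: handled by VE each iteration
  struct BigComp {
    std::vector<int> ev;
    std::vector<int> fams;
    std::vector<std::vector<int>> funobs;
  };
  std::vector<BigComp> bigs;

  std::vector<int> uf(V);
  std::function<int(int)> find = [&](int x) {
    while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
    return x;
  };

  for (int i = 0; i < n; ++i) {
    std::vector<int> ev = row_evidence(data, i);
    for (int v = 0; v < V; ++v) uf[v] = v;
    std::vector<std::vector<int>> funobs(V);
    for (int v = 0; v < V; ++v) {
      for (int x : ffull[v])
        if (ev[x] < 0) funobs[v].push_back(x);
      for (size_t t = 1; t < funobs[v].size(); ++t)
        uf[find(funobs[v][t])] = find(funobs[v][0]);
    }
    for (int v = 0; v < V; ++v) {
      if (!funobs[v].empty()) continue;
      long idx = 0;
      const int m = (int)ffull[v].size();
      for (int t = 0; t < m; ++t) idx += fstride[v][t] * ev[ffull[v][t]];
      EN_base[v][idx] += 1.0;
    }
    std::vector<std::vector<int>> comp_fams(V);
    for (int v = 0; v < V; ++v)
      if (!funobs[v].empty()) comp_fams[find(funobs[v][0])].push_back(v);
    for (int root = 0; root < V; ++root) {
      if (comp_fams[root].empty()) continue;
      const std::vector<int>& fams = comp_fams[root];
      std::vector<int> cvars;
      for (int v : fams)
        for (int x : funobs[v]) cvars.push_back(x);
      std::sort(cvars.begin(), cvars.end());
      cvars.erase(std::unique(cvars.begin(), cvars.end()), cvars.end());
      double tbl = 1.0;
      for (int x : cvars) tbl *= net.cards[x];
      if (tbl > comp_limit) {
        BigComp b;
        b.ev = ev;
        b.fams = fams;
        for (int v : fams) b.funobs.push_back(funobs[v]);
        bigs.push_back(std::move(b));
        continue;
      }
      const int mu = (int)cvars.size();
      const long ncfg = (long)tbl;
      Comp c;
      c.nfam = (int)fams.size();
      c.ncfg = (int)ncfg;
      c.fam_off = comp_fam.size();
      c.idx_off = comp_idx.size();
      for (int v : fams) comp_fam.push_back(v);
      // per-family base index over observed members + per-cvar strides
      std::vector<long> fbase(fams.size(), 0);
      std::vector<std::vector<long>> fcstr(fams.size(), std::vector<long>(mu, 0));
      for (size_t fi = 0; fi < fams.size(); ++fi) {
        const int v = fams[fi];
        const int fm = (int)ffull[v].size();
        for (int t = 0; t < fm; ++t) {
          int var = ffull[v][t];
          if (ev[var] >= 0)
            fbase[fi] += fstride[v][t] * ev[var];
          else {
            int pos = (int)(std::lower_bound(cvars.begin(), cvars.end(), var) - cvars.begin());
            fcstr[fi][pos] += fstride[v][t];
          }
        }
      }
      std::vector<int> dg(mu, 0);
      for (long g = 0; g < ncfg; ++g) {
        for (size_t fi = 0; fi < fams.size(); ++fi) {
          long idx = fbase[fi];
          for (int t = 0; t < mu; ++t) idx += fcstr[fi][t] * dg[t];
          comp_idx.push_back((int)idx);
        }
        for (int t = mu - 1; t >= 0; --t) {
          if (++dg[t] < net.cards[cvars[t]]) break;
          dg[t] = 0;
        }
      }
      comps.push_back(c);
    }
  }

  // ---- iterate ----
  std::vector<std::vector<double>> EN(V);
  std::vector<double> trace;
  std::vector<double> w;
  double ll_prev = R_NegInf;
  bool converged = false;
  int iters = 0;

  for (int iter = 0; iter < max_iter; ++iter) {
    iters = iter + 1;
    for (int v = 0; v < V; ++v) EN[v] = EN_base[v];
    double ll = 0.0;
    // fully observed families: sum of base-count-weighted log CPT cells
    for (int v = 0; v < V; ++v)
      for (size_t c = 0; c < EN_base[v].size(); ++c)
        if (EN_base[v][c] > 0.0) ll += EN_base[v][c] * std::log(net.cpts[v][c]);
    // enumerable components
    for (const Comp& c : comps) {
      const int* fams = comp_fam.data() + c.fam_off;
      const int* idx = comp_idx.data() + c.idx_off;
      w.resize(c.ncfg);
      double Z = 0.0;
      const int* ip = idx;
      for (int g = 0; g < c.ncfg; ++g) {
        double p = 1.0;
        for (int f = 0; f < c.nfam; ++f) p *= net.cpts[fams[f]][ip[f]];
        w[g] = p;
        Z += p;
        ip += c.nfam;
      }
      if (Z <= 0.0) { ll = R_NegInf; continue; }
      ll += std::log(Z);
      ip = idx;
      for (int g = 0; g < c.ncfg; ++g) {
        if (w[g] > 0.0) {
          const double ww = w[g] / Z;
          for (int f = 0; f < c.nfam; ++f) EN[fams[f]][ip[f]] += ww;
        }
        ip += c.nfam;
      }
    }
    // oversized components: exact per-family marginals by VE
    for (const BigComp& b : bigs) {
      double logZ;
      bool ok;
      Factor z = ve_marginal_fams(net, b.ev, b.fams, std::vector<int>(), logZ, ok);
      double zs = 0.0;
      for (double x : z.val) zs += x;
      if (!ok || zs <= 0.0) { ll = R_NegInf; continue; }
      ll += logZ + std::log(zs);
      for (size_t fi = 0; fi < b.fams.size(); ++fi) {
        const int v = b.fams[fi];
        double lz2;
        bool ok2;
        Factor m = ve_marginal_fams(net, b.ev, b.fams, b.funobs[fi], lz2, ok2);
        double ms = 0.0;
        for (double x : m.val) ms += x;
        if (!ok2 || ms <= 0.0) continue;
        const std::vector<int>& uv = m.vars;
        const int mu = (int)uv.size();
        std::vector<int> dg(mu, 0);
        for (size_t li = 0; li < m.val.size(); ++li) {
          long idx = 0;
          const int fm = (int)ffull[v].size();
          for (int t = 0; t < fm; ++t) {
            int var = ffull[v][t];
            int st = b.ev[var];
            if (st < 0) {
              int pos = (int)(std::lower_bound(uv.begin(), uv.end(), var) - uv.begin());
              st = dg[pos];
            }
            idx += fstride[v][t] * st;
          }
          EN[v][idx] += m.val[li] / ms;
          for (int t = mu - 1; t >= 0; --t) {
            if (++dg[t] < net.cards[uv[t]]) break;
            dg[t] = 0;
          }
        }
      }
    }

    trace.push_back(ll);
    // M-step
    double maxdiff = 0.0;
    for (int v = 0; v < V; ++v) {
      const int r = net.cards[v];
      for (long j = 0; j < fq[v]; ++j) {
        double Nj = 0.0;
        for (int k = 0; k < r; ++k) Nj += EN[v][j * r + k];
        for (int k = 0; k < r; ++k) {
          double p;
          if (Nj + r * alpha > 0.0)
            p = (EN[v][j * r + k] + alpha) / (Nj + r * alpha);
          else
            p = 1.0 / r;  // unvisited row with alpha 0: keep uniform
          maxdiff = std::max(maxdiff, std::fabs(p - net.cpts[v][j * r + k]));
          net.cpts[v][j * r + k] = p;
        }
      }
    }
    if (maxdiff < 1e-12) { converged = true; break; }
    if (iter >= 1 && std::isfinite(ll) && std::isfinite(ll_prev) &&
        (ll - ll_prev) <= tol * std::fabs(ll_prev)) {
      converged = true;
      break;
    }
    ll_prev = ll;
  }

  List out_cpts(V);
  for (int v = 0; v < V; ++v)
    out_cpts[v] = NumericVector(net.cpts[v].begin(), net.cpts[v].end());
  return List::create(_["cpts"] = out_cpts,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged,
                      _["iterations"] = iters);
}
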