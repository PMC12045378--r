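#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Off-lattice biofilm agent model. Cells live in 2 or 3 dimensions; the last
// coordinate is height above the substrate (z >= 0, reflective). Substrate
// anchors sit at z = 0. Pairwise pseudo-force magnitude between p and q is
//   H / d^6  -  ((G_p + G_q)/2) / d^2      (positive = repulsive)
// and a cell-anchor term replaces (G_p + G_q)/2 by G_p / 2. Cells move a
// fixed distance D per step along the normalized blend of the unit net-force
// vector and a random unit vector, weighted (1-F) : F.

namespace {

struct Vec3 { double x[3]; };

inline double runif_sym(double j) { return (2.0 * unif_rand() - 1.0) * j; }

void random_unit(int dim, double* u) {
  if (dim == 2) {
    double th = 2.0 * M_PI * unif_rand();
    u[0] = std::cos(th); u[1] = std::sin(th); u[2] = 0.0;
  } else {
    double n2 = 0.0;
    do {
      for (int k = 0; k < 3; ++k) u[k] = norm_rand();
      n2 = u[0]*u[0] + u[1]*u[1] + u[2]*u[2];
    } while (n2 < 1e-12);
    double inv = 1.0 / std::sqrt(n2);
    for (int k = 0; k < 3; ++k) u[k] *= inv;
  }
}

// net pseudo-forces on every cell (cell-cell plus cell-anchor terms);
// the anchor term uses Gaa/Gas for asocial/social cells, so the substrate
// attraction can either follow the cell's own constant or stay at the
// calibrated baseline
void net_forces(const std::vector<Vec3>& pos, const std::vector<char>& soc,
                const std::vector<Vec3>& anch, int dim,
                double H, double Ga, double Gs, double Gaa, double Gas,
                std::vector<Vec3>& f) {
  int N = (int)pos.size(), A = (int)anch.size();
  f.assign(N, Vec3{{0.0, 0.0, 0.0}});
  for (int p = 0; p < N; ++p) {
    double Gp = soc[p] ? Gs : Ga;
    double Gp_anchor = soc[p] ? Gas : Gaa;
    for (int q = p + 1; q < N; ++q) {
      double d2 = 0.0, dx[3];
      for (int k = 0; k < dim; ++k) {
        dx[k] = pos[p].x[k] - pos[q].x[k];
        d2 += dx[k] * dx[k];
      }
      if (d2 < 1e-300) continue;
      double inv2 = 1.0 / d2;
      double Gq = soc[q] ? Gs : Ga;
      double s = H * inv2 * inv2 * inv2 - 0.5 * (Gp + Gq) * inv2;
      double sd = s * std::sqrt(inv2);
      for (int k = 0; k < dim; ++k) {
        f[p].x[k] += sd * dx[k];
        f[q].x[k] -= sd * dx[k];
      }
    }
    for (int aidx = 0; aidx < A; ++aidx) {
      double d2 = 0.0, dx[3];
      for (int k = 0; k < dim; ++k) {
        dx[k] = pos[p].x[k] - anch[aidx].x[k];
        d2 += dx[k] * dx[k];
      }
      if (d2 < 1e-300) continue;
      double inv2 = 1.0 / d2;
      double s = H * inv2 * inv2 * inv2 - 0.5 * Gp_anchor * inv2;
      double sd = s * std::sqrt(inv2);
      for (int k = 0; k < dim; ++k) f[p].x[k] += sd * dx[k];
    }
  }
}

// predation interface: highest cell within each occupied tangent window of
// width D (the single cell in 2-D windows along x; (x, y) windows in 3-D)
void interface_cells(const std::vector<Vec3>& pos, int dim, double D,
                     std::vector<int>& out) {
  out.clear();
  std::unordered_map<long long, int> top;
  int N = (int)pos.size();
  for (int p = 0; p < N; ++p) {
    long long ix = (long long)std::floor(pos[p].x[0] / D);
    long long key = ix;
    if (dim == 3) {
      long long iy = (long long)std::floor(pos[p].x[1] / D);
      key = ix * 2000003LL + iy;
    }
    auto it = top.find(key);
    if (it == top.end() || pos[p].x[dim - 1] > pos[it->second].x[dim - 1])
      top[key] = p;
  }
  for (auto& kv : top) out.push_back(kv.second);
  std::sort(out.begin(), out.end());
}

// k distinct uniform picks from idx (partial Fisher-Yates, in place)
void pick_distinct(std::vector<int>& idx, int k, std::vector<int>& out) {
  out.clear();
  int n = (int)idx.size();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(idx[i], idx[j]);
    out.push_back(idx[i]);
  }
}

void to_vecs(const NumericMatrix& m, int dim, std::vector<Vec3>& v) {
  v.resize(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) {
    v[i] = Vec3{{0.0, 0.0, 0.0}};
    for (int k = 0; k < dim; ++k) v[i].x[k] = m(i, k);
  }
}

NumericMatrix from_vecs(const std::vector<Vec3>& v, int dim) {
  NumericMatrix m((int)v.size(), dim);
  for (int i = 0; i < (int)v.size(); ++i)
    for (int k = 0; k < dim; ++k) m(i, k) = v[i].x[k];
  return m;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_bf_forces(NumericMatrix pos, LogicalVector social,
                            NumericMatrix anchors, double H, double G_asoc,
                            double G_soc, double G_anchor_asoc,
                            double G_anchor_soc) {
  int dim = pos.ncol();
  std::vector<Vec3> p, a, f;
  to_vecs(pos, dim, p);
  to_vecs(anchors, dim, a);
  std::vector<char> soc(social.begin(), social.end());
  net_forces(p, soc, a, dim, H, G_asoc, G_soc, G_anchor_asoc, G_anchor_soc, f);
  return from_vecs(f, dim);
}

// [[Rcpp::export]]
IntegerVector cpp_bf_interface(NumericMatrix pos, double D) {
  int dim = pos.ncol();
  std::vector<Vec3> p;
  to_vecs(pos, dim, p);
  std::vector<int> idx;
  interface_cells(p, dim, D, idx);
  IntegerVector out((int)idx.size());
  for (int i = 0; i < (int)idx.size(); ++i) out[i] = idx[i] + 1;
  return out;
}

// outcome codes: 0 horizon, 1 population exceeded stop_size, 2 extinct,
// 3 homogenized social, 4 homogenized asocial
// [[Rcpp::export]]
List cpp_biofilm_run(NumericMatrix pos0, LogicalVector social0,
                     NumericMatrix anchors, double H, double G_asoc,
                     double G_soc, double G_anchor_asoc, double G_anchor_soc,
                     double F, double r_asoc, double r_soc,
                     double K_BF, double L, double dt, double D,
                     double jitter_pos, double jitter_div, int n_steps,
                     bool move, bool divide, bool remove, int stop_size,
                     bool stop_homog, int record_every) {
  int dim = pos0.ncol();
  std::vector<Vec3> pos, anch, f;
  to_vecs(pos0, dim, pos);
  to_vecs(anchors, dim, anch);
  std::vector<char> soc(social0.begin(), social0.end());

  std::vector<double> rec_t, rec_n, rec_s;
  int outcome = 0, steps_done = 0;

  for (int step = 1; step <= n_steps; ++step) {
    int N = (int)pos.size();
    if (N == 0) { outcome = 2; break; }

    // --- motion ---
    if (move) {
    net_forces(pos, soc, anch, dim, H, G_asoc, G_soc, G_anchor_asoc,
               G_anchor_soc, f);
    for (int p = 0; p < N; ++p) {
      double fn = 0.0;
      for (int k = 0; k < dim; ++k) fn += f[p].x[k] * f[p].x[k];
      fn = std::sqrt(fn);
      double uf[3] = {0.0, 0.0, 0.0}, ur[3] = {0.0, 0.0, 0.0};
      if (fn > 1e-300)
        for (int k = 0; k < dim; ++k) uf[k] = f[p].x[k] / fn;
      if (F > 0.0) random_unit(dim, ur);
      double dir[3], dn = 0.0;
      for (int k = 0; k < dim; ++k) {
        dir[k] = (1.0 - F) * uf[k] + F * ur[k];
        dn += dir[k] * dir[k];
      }
      dn = std::sqrt(dn);
      if (dn > 1e-300)
        for (int k = 0; k < dim; ++k) pos[p].x[k] += D * dir[k] / dn;
      if (pos[p].x[dim - 1] < 0.0) pos[p].x[dim - 1] = -pos[p].x[dim - 1];
      for (int k = 0; k < dim; ++k) pos[p].x[k] += runif_sym(jitter_pos);
      if (pos[p].x[dim - 1] < 0.0) pos[p].x[dim - 1] = -pos[p].x[dim - 1];
    }
    }

    // --- division (both rates use the pre-division total) ---
    if (divide) {
      double logistic = 1.0 - (double)N / K_BF;
      if (logistic < 0.0) logistic = 0.0;
      std::vector<int> idx_a, idx_s;
      for (int p = 0; p < N; ++p) (soc[p] ? idx_s : idx_a).push_back(p);
      for (int type = 0; type < 2; ++type) {
        std::vector<int>& idx = (type == 0) ? idx_a : idx_s;
        double r = (type == 0) ? r_asoc : r_soc;
        int nt = (int)idx.size();
        if (nt == 0) continue;
        int k = (int)R::rpois(nt * r * logistic * dt);
        if (k > nt) k = nt;
        if (k == 0) continue;
        std::vector<int> chosen;
        pick_distinct(idx, k, chosen);
        for (int c : chosen) {
          Vec3 np = pos[c];
          for (int kk = 0; kk < dim; ++kk) np.x[kk] += runif_sym(jitter_div);
          if (np.x[dim - 1] < 0.0) np.x[dim - 1] = -np.x[dim - 1];
          pos.push_back(np);
          soc.push_back(type == 1);
        }
      }
    }

    // --- removal from the predation interface ---
    if (remove && !pos.empty()) {
      std::vector<int> iface;
      interface_cells(pos, dim, D, iface);
      int m = (int)iface.size();
      int k = (int)R::rpois(m * L * dt);
      if (k > m) k = m;
      if (k > 0) {
        std::vector<int> chosen;
        pick_distinct(iface, k, chosen);
        std::sort(chosen.begin(), chosen.end(), std::greater<int>());
        for (int c : chosen) {
          pos.erase(pos.begin() + c);
          soc.erase(soc.begin() + c);
        }
      }
    }

    steps_done = step;
    int N2 = (int)pos.size(), ns = 0;
    for (char s : soc) if (s) ++ns;
    if (record_every > 0 && (step % record_every == 0)) {
      rec_t.push_back(step); rec_n.push_back(N2); rec_s.push_back(ns);
    }
    if (N2 == 0) { outcome = 2; break; }
    if (stop_size > 0 && N2 > stop_size) { outcome = 1; break; }
    if (stop_homog && ns == N2) { outcome = 3; break; }
    if (stop_homog && ns == 0) { outcome = 4; break; }
    if ((step & 255) == 0) Rcpp::checkUserInterrupt();
  }

  int N = (int)pos.size(), ns = 0;
  for (char s : soc) if (s) ++ns;
  NumericMatrix rec((int)rec_t.size(), 3);
  for (int i = 0; i < (int)rec_t.size(); ++i) {
    rec(i, 0) = rec_t[i]; rec(i, 1) = rec_n[i]; rec(i, 2) = rec_s[i];
  }
  colnames(rec) = CharacterVector::create("step", "n_cells", "n_social");
  return List::create(_["positions"] = from_vecs(pos, dim),
                      _["social"] = LogicalVector(soc.begin(), soc.end()),
                      _["steps_done"] = steps_done,
                      _["outcome"] = outcome,
                      _["n_cells"] = N, _["n_social"] = ns,
                      _["record"] = rec);
}
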