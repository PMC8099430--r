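#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis Monte Carlo sweeps over bead / segment / pivot / rigid-body
// moves with incremental delta scoring of the flat-bottom crosslink,
// excluded-volume and connectivity restraints.  Only score *differences*
// are evaluated here; full per-snapshot score breakdowns are recomputed in
// R from the recorded coordinates.  All randomness comes from R's RNG, so
// a set.seed() on the R side makes the trajectory bit-reproducible.

struct Links {
  // ambiguity combos flattened: for link l, combos [start[l], start[l+1])
  std::vector<int> a, b;      // particle indices (0-based) per combo
  std::vector<int> start;
  std::vector<double> L;
  std::vector<double> d;      // current min distance per link
};

static inline double dist3(const double* x, const double* y, const double* z,
                           int i, int j) {
  const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static double link_min(const Links& lk, int l, const double* x,
                       const double* y, const double* z) {
  double m = R_PosInf;
  for (int c = lk.start[l]; c < lk.start[l + 1]; ++c) {
    const double d = dist3(x, y, z, lk.a[c], lk.b[c]);
    if (d < m) m = d;
  }
  return m;
}

// Doubly-linked cell list over a fixed box (outside positions clamp to the
// boundary cells), giving O(1) membership updates on accepted moves and
// ~constant-size neighbor queries for the short-ranged overlap term.
struct CellGrid {
  double x0, y0, z0, cell;
  int nx, ny, nz;
  std::vector<int> head, nxt, prv, cell_of;

  void init(int n, const double* x, const double* y, const double* z,
            double cell_size, double pad) {
    cell = cell_size;
    double xl = x[0], xh = x[0], yl = y[0], yh = y[0], zl = z[0], zh = z[0];
    for (int i = 1; i < n; ++i) {
      xl = std::min(xl, x[i]); xh = std::max(xh, x[i]);
      yl = std::min(yl, y[i]); yh = std::max(yh, y[i]);
      zl = std::min(zl, z[i]); zh = std::max(zh, z[i]);
    }
    x0 = xl - pad; y0 = yl - pad; z0 = zl - pad;
    nx = (int)((xh + pad - x0) / cell) + 1;
    ny = (int)((yh + pad - y0) / cell) + 1;
    nz = (int)((zh + pad - z0) / cell) + 1;
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(n, -1);
    prv.assign(n, -1);
    cell_of.assign(n, -1);
    for (int i = 0; i < n; ++i) insert(i, x[i], y[i], z[i]);
  }
  inline int cidx(double xi, double yi, double zi) const {
    int a = (int)((xi - x0) / cell); a = a < 0 ? 0 : (a >= nx ? nx - 1 : a);
    int b = (int)((yi - y0) / cell); b = b < 0 ? 0 : (b >= ny ? ny - 1 : b);
    int c = (int)((zi - z0) / cell); c = c < 0 ? 0 : (c >= nz ? nz - 1 : c);
    return (c * ny + b) * nx + a;
  }
  void insert(int i, double xi, double yi, double zi) {
    const int c = cidx(xi, yi, zi);
    cell_of[i] = c;
    prv[i] = -1;
    nxt[i] = head[c];
    if (head[c] >= 0) prv[head[c]] = i;
    head[c] = i;
  }
  void remove(int i) {
    const int c = cell_of[i];
    if (prv[i] >= 0) nxt[prv[i]] = nxt[i]; else head[c] = nxt[i];
    if (nxt[i] >= 0) prv[nxt[i]] = prv[i];
  }
  void move(int i, double xi, double yi, double zi) {
    const int c = cidx(xi, yi, zi);
    if (c == cell_of[i]) return;
    remove(i);
    insert(i, xi, yi, zi);
  }
};

// excluded-volume terms of particle i (at its coordinates in x/y/z)
// against all non-exempt, non-marked particles found via the grid
static double ev_one(int i, const CellGrid& g, const double* x,
                     const double* y, const double* z, const double* rad,
                     const std::vector<char>& mark, double k_ev) {
  double s = 0.0;
  const double xi = x[i], yi = y[i], zi = z[i], ri = rad[i];
  int a0 = (int)((xi - g.x0) / g.cell);
  a0 = a0 < 0 ? 0 : (a0 >= g.nx ? g.nx - 1 : a0);
  int b0 = (int)((yi - g.y0) / g.cell);
  b0 = b0 < 0 ? 0 : (b0 >= g.ny ? g.ny - 1 : b0);
  int c0 = (int)((zi - g.z0) / g.cell);
  c0 = c0 < 0 ? 0 : (c0 >= g.nz ? g.nz - 1 : c0);
  const int alo = a0 > 0 ? a0 - 1 : 0, ahi = a0 < g.nx - 1 ? a0 + 1 : g.nx - 1;
  const int blo = b0 > 0 ? b0 - 1 : 0, bhi = b0 < g.ny - 1 ? b0 + 1 : g.ny - 1;
  const int clo = c0 > 0 ? c0 - 1 : 0, chi = c0 < g.nz - 1 ? c0 + 1 : g.nz - 1;
  for (int c = clo; c <= chi; ++c) {
    for (int b = blo; b <= bhi; ++b) {
      for (int a = alo; a <= ahi; ++a) {
        for (int j = g.head[((size_t)c * g.ny + b) * g.nx + a]; j >= 0; j = g.nxt[j]) {
          if (mark[j]) continue;
          const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
          const double d2 = dx * dx + dy * dy + dz * dz;
          const double rr = ri + rad[j];
          if (d2 < rr * rr) {
            const double ov = rr - std::sqrt(d2);
            s += ov * ov;
          }
        }
      }
    }
  }
  return k_ev * s;
}

// [[Rcpp::export(name = ".mc_core")]]
List mc_core(NumericMatrix coords_in, NumericVector radius,
             List exempt,            // per particle: 1-based exempt indices
             IntegerVector conn_i, IntegerVector conn_j, NumericVector conn_u,
             List conn_touch,        // per particle: 1-based conn pair ids
             List link_combo_a, List link_combo_b, NumericVector link_L,
             List link_of,           // per particle: 1-based link ids
             IntegerVector bead_idx, // 1-based mobile bead indices
             List chains,            // per chain: 1-based ordered bead idx
             List bodies,            // per mobile body: 1-based indices
             NumericVector temps,    // temperature per sweep
             int record_every,
             double bead_sigma, double trans_sigma, double rot_sigma_deg,
             double k_xl, double xl_max_excess, double k_ev, double k_conn,
             double w_xl, double w_ev, double w_conn) {
  const int n = coords_in.nrow();
  NumericMatrix coords = clone(coords_in);
  double* x = &coords(0, 0);
  double* y = &coords(0, 1);
  double* z = &coords(0, 2);
  const double* rad = radius.begin();

  // exemption marks are set/unset around each particle's EV pass
  std::vector<std::vector<int> > ex(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = exempt[i];
    ex[i].assign(v.begin(), v.end());
    for (size_t k = 0; k < ex[i].size(); ++k) ex[i][k]--;
  }
  std::vector<char> mark(n, 0);

  const int n_conn = conn_i.size();
  std::vector<int> ci(conn_i.begin(), conn_i.end());
  std::vector<int> cj(conn_j.begin(), conn_j.end());
  for (int k = 0; k < n_conn; ++k) { ci[k]--; cj[k]--; }
  std::vector<std::vector<int> > ctouch(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = conn_touch[i];
    ctouch[i].assign(v.begin(), v.end());
    for (size_t k = 0; k < ctouch[i].size(); ++k) ctouch[i][k]--;
  }

  Links lk;
  const int n_links = link_L.size();
  lk.L.assign(link_L.begin(), link_L.end());
  lk.start.push_back(0);
  for (int l = 0; l < n_links; ++l) {
    IntegerVector a = link_combo_a[l], b = link_combo_b[l];
    for (int c = 0; c < a.size(); ++c) {
      lk.a.push_back(a[c] - 1);
      lk.b.push_back(b[c] - 1);
    }
    lk.start.push_back((int)lk.a.size());
  }
  lk.d.resize(n_links);
  for (int l = 0; l < n_links; ++l) lk.d[l] = link_min(lk, l, x, y, z);
  std::vector<std::vector<int> > lof(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = link_of[i];
    lof[i].assign(v.begin(), v.end());
    for (size_t k = 0; k < lof[i].size(); ++k) lof[i][k]--;
  }

  const int nb = bead_idx.size();
  std::vector<int> beads(bead_idx.begin(), bead_idx.end());
  for (int k = 0; k < nb; ++k) beads[k]--;
  const int n_chains = chains.size();
  std::vector<std::vector<int> > chain(n_chains);
  for (int c = 0; c < n_chains; ++c) {
    IntegerVector v = chains[c];
    chain[c].assign(v.begin(), v.end());
    for (size_t k = 0; k < chain[c].size(); ++k) chain[c][k]--;
  }
  const int n_bodies = bodies.size();
  std::vector<std::vector<int> > body(n_bodies);
  for (int c = 0; c < n_bodies; ++c) {
    IntegerVector v = bodies[c];
    body[c].assign(v.begin(), v.end());
    for (size_t k = 0; k < body[c].size(); ++k) body[c][k]--;
  }

  // move mix mirrors the documented sampler design
  const bool has_beads = nb > 0, has_bodies = n_bodies > 0;
  double p_bead = 0, p_seg = 0, p_piv = 0, p_body = 0;
  if (has_beads && has_bodies) { p_bead = .5; p_seg = .25; p_piv = .25; p_body = .25; }
  else if (has_beads) { p_bead = .5; p_seg = .25; p_piv = .25; }
  else if (has_bodies) { p_body = 1; }
  const double psum = p_bead + p_seg + p_piv + p_body;
  p_bead /= psum; p_seg /= psum; p_piv /= psum; p_body /= psum;

  const int steps = temps.size();
  const int n_prop = nb + n_bodies;
  double n_accept = 0;

  // scratch: moved set, saved coordinates, touched conn pairs / links
  std::vector<int> idx; idx.reserve(n);
  std::vector<double> sx(n), sy(n), sz(n);
  std::vector<int> tconn; tconn.reserve(64);
  std::vector<int> tlink; tlink.reserve(64);
  std::vector<int> stamp_conn(n_conn, -1), stamp_link(n_links, -1);
  std::vector<double> new_d; new_d.reserve(64);
  std::vector<int> tmp_marked; tmp_marked.reserve(256);
  int stamp = 0;

  // neighbor grid for the short-ranged overlap term
  double rmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, rad[i]);
  CellGrid grid;
  grid.init(n, x, y, z, 2 * rmax + 0.1, 30.0);

  List snapshots;
  IntegerVector snap_sweep;

  for (int s = 0; s < steps; ++s) {
    const double temp = temps[s];
    for (int prop = 0; prop < n_prop; ++prop) {
      ++stamp;
      idx.clear();
      // --- choose move ---------------------------------------------------
      const double u = unif_rand();
      bool rigid_rot = false;
      double Rm[9]; double pivx = 0, pivy = 0, pivz = 0;
      double tx = 0, ty = 0, tz = 0;
      if (u < p_bead) {
        idx.push_back(beads[(int)(unif_rand() * nb) % nb]);
        tx = norm_rand() * bead_sigma;
        ty = norm_rand() * bead_sigma;
        tz = norm_rand() * bead_sigma;
      } else if (u < p_bead + p_seg) {
        const std::vector<int>& ch = chain[(int)(unif_rand() * n_chains) % n_chains];
        const int len = (int)ch.size();
        int w = 2 + (int)(unif_rand() * 15); if (w > len) w = len;
        const int a0 = (int)(unif_rand() * (len - w + 1));
        for (int k = 0; k < w; ++k) idx.push_back(ch[a0 + k]);
        tx = norm_rand() * bead_sigma;
        ty = norm_rand() * bead_sigma;
        tz = norm_rand() * bead_sigma;
      } else if (u < p_bead + p_seg + p_piv) {
        const std::vector<int>& ch = chain[(int)(unif_rand() * n_chains) % n_chains];
        const int len = (int)ch.size();
        const int pv = 1 + (int)(unif_rand() * len);  // 1-based position
        if (2 * pv <= len) {
          const int cnt = pv > 1 ? pv - 1 : 1;
          for (int k = 0; k < cnt; ++k) idx.push_back(ch[k]);
          const int anchor = ch[pv - 1];
          pivx = x[anchor]; pivy = y[anchor]; pivz = z[anchor];
        } else {
          for (int k = pv - 1; k < len; ++k) idx.push_back(ch[k]);
          const int anchor = ch[pv - 1];
          pivx = x[anchor]; pivy = y[anchor]; pivz = z[anchor];
        }
        rigid_rot = true;
        // random axis, N(0, 4*rot_sigma) angle (degrees)
        double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
        double an = std::sqrt(ax * ax + ay * ay + az * az);
        if (an < 1e-12) { ax = 1; ay = 0; az = 0; an = 1; }
        ax /= an; ay /= an; az /= an;
        const double th = norm_rand() * 4.0 * rot_sigma_deg * M_PI / 180.0;
        const double c = std::cos(th), sn = std::sin(th), C = 1 - c;
        Rm[0] = c + ax * ax * C;      Rm[1] = ax * ay * C - az * sn; Rm[2] = ax * az * C + ay * sn;
        Rm[3] = ay * ax * C + az * sn; Rm[4] = c + ay * ay * C;      Rm[5] = ay * az * C - ax * sn;
        Rm[6] = az * ax * C - ay * sn; Rm[7] = az * ay * C + ax * sn; Rm[8] = c + az * az * C;
      } else {
        const std::vector<int>& bd = body[(int)(unif_rand() * n_bodies) % n_bodies];
        for (size_t k = 0; k < bd.size(); ++k) idx.push_back(bd[k]);
        rigid_rot = true;
        double cx = 0, cy = 0, cz = 0;
        for (size_t k = 0; k < bd.size(); ++k) { cx += x[bd[k]]; cy += y[bd[k]]; cz += z[bd[k]]; }
        pivx = cx / bd.size(); pivy = cy / bd.size(); pivz = cz / bd.size();
        double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
        double an = std::sqrt(ax * ax + ay * ay + az * az);
        if (an < 1e-12) { ax = 1; ay = 0; az = 0; an = 1; }
        ax /= an; ay /= an; az /= an;
        const double th = norm_rand() * rot_sigma_deg * M_PI / 180.0;
        const double c = std::cos(th), sn = std::sin(th), C = 1 - c;
        Rm[0] = c + ax * ax * C;      Rm[1] = ax * ay * C - az * sn; Rm[2] = ax * az * C + ay * sn;
        Rm[3] = ay * ax * C + az * sn; Rm[4] = c + ay * ay * C;      Rm[5] = ay * az * C - ax * sn;
        Rm[6] = az * ax * C - ay * sn; Rm[7] = az * ay * C + ax * sn; Rm[8] = c + az * az * C;
        tx = norm_rand() * trans_sigma;
        ty = norm_rand() * trans_sigma;
        tz = norm_rand() * trans_sigma;
      }
      const int m = (int)idx.size();

      // --- touched restraints -------------------------------------------
      tconn.clear(); tlink.clear();
      for (int k = 0; k < m; ++k) {
        const int i = idx[k];
        for (size_t q = 0; q < ctouch[i].size(); ++q) {
          const int pid = ctouch[i][q];
          if (stamp_conn[pid] != stamp) { stamp_conn[pid] = stamp; tconn.push_back(pid); }
        }
        for (size_t q = 0; q < lof[i].size(); ++q) {
          const int lid = lof[i][q];
          if (stamp_link[lid] != stamp) { stamp_link[lid] = stamp; tlink.push_back(lid); }
        }
      }

      // --- old local terms ----------------------------------------------
      // intra-set pairs are excluded from both passes (rigid subset moves
      // preserve them, so they cancel in the delta exactly)
      for (int k = 0; k < m; ++k) mark[idx[k]] = 2;
      double ev_old = 0, conn_old = 0, xl_old = 0;
      for (int k = 0; k < m; ++k) {
        const int i = idx[k];
        tmp_marked.clear();
        for (size_t q = 0; q < ex[i].size(); ++q) {
          const int e = ex[i][q];
          if (!mark[e]) { mark[e] = 1; tmp_marked.push_back(e); }
        }
        ev_old += ev_one(i, grid, x, y, z, rad, mark, k_ev);
        for (size_t q = 0; q < tmp_marked.size(); ++q) mark[tmp_marked[q]] = 0;
      }
      for (size_t q = 0; q < tconn.size(); ++q) {
        const int pid = tconn[q];
        const double d = dist3(x, y, z, ci[pid], cj[pid]);
        if (d > conn_u[pid]) { const double e = d - conn_u[pid]; conn_old += k_conn * e * e; }
      }
      for (size_t q = 0; q < tlink.size(); ++q) {
        const int l = tlink[q];
        if (lk.d[l] > lk.L[l]) {
          const double e = std::min(lk.d[l] - lk.L[l], xl_max_excess);
          xl_old += k_xl * e * e;
        }
      }

      // --- apply move ----------------------------------------------------
      for (int k = 0; k < m; ++k) {
        const int i = idx[k];
        sx[k] = x[i]; sy[k] = y[i]; sz[k] = z[i];
        if (rigid_rot) {
          const double vx = x[i] - pivx, vy = y[i] - pivy, vz = z[i] - pivz;
          x[i] = Rm[0] * vx + Rm[1] * vy + Rm[2] * vz + pivx + tx;
          y[i] = Rm[3] * vx + Rm[4] * vy + Rm[5] * vz + pivy + ty;
          z[i] = Rm[6] * vx + Rm[7] * vy + Rm[8] * vz + pivz + tz;
        } else {
          x[i] += tx; y[i] += ty; z[i] += tz;
        }
      }

      // --- new local terms ----------------------------------------------
      double ev_new = 0, conn_new = 0, xl_new = 0;
      for (int k = 0; k < m; ++k) {
        const int i = idx[k];
        tmp_marked.clear();
        for (size_t q = 0; q < ex[i].size(); ++q) {
          const int e = ex[i][q];
          if (!mark[e]) { mark[e] = 1; tmp_marked.push_back(e); }
        }
        ev_new += ev_one(i, grid, x, y, z, rad, mark, k_ev);
        for (size_t q = 0; q < tmp_marked.size(); ++q) mark[tmp_marked[q]] = 0;
      }
      for (int k = 0; k < m; ++k) mark[idx[k]] = 0;
      for (size_t q = 0; q < tconn.size(); ++q) {
        const int pid = tconn[q];
        const double d = dist3(x, y, z, ci[pid], cj[pid]);
        if (d > conn_u[pid]) { const double e = d - conn_u[pid]; conn_new += k_conn * e * e; }
      }
      new_d.resize(tlink.size());
      for (size_t q = 0; q < tlink.size(); ++q) {
        const int l = tlink[q];
        new_d[q] = link_min(lk, l, x, y, z);
        if (new_d[q] > lk.L[l]) {
          const double e = std::min(new_d[q] - lk.L[l], xl_max_excess);
          xl_new += k_xl * e * e;
        }
      }

      const double dE = w_xl * (xl_new - xl_old) + w_ev * (ev_new - ev_old) +
        w_conn * (conn_new - conn_old);
      if (!R_finite(dE)) stop("non-finite score delta during sampling");
      if (dE <= 0 || unif_rand() < std::exp(-dE / temp)) {
        n_accept += 1;
        for (size_t q = 0; q < tlink.size(); ++q) lk.d[tlink[q]] = new_d[q];
        for (int k = 0; k < m; ++k)
          grid.move(idx[k], x[idx[k]], y[idx[k]], z[idx[k]]);
      } else {
        for (int k = 0; k < m; ++k) {
          const int i = idx[k];
          x[i] = sx[k]; y[i] = sy[k]; z[i] = sz[k];
        }
      }
    }
    if ((s + 1) % record_every == 0) {
      snapshots.push_back(clone(coords));
      snap_sweep.push_back(s + 1);
    }
  }

  return List::create(_["snapshots"] = snapshots,
                      _["snap_sweep"] = snap_sweep,
                      _["n_accept"] = n_accept,
                      _["n_proposals"] = (double)steps * n_prop);
}
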