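#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <deque>
using namespace Rcpp;

// Five-node Laplacian on the conductive subset with no-flux boundaries:
// a neighbour that is off-grid or non-conductive is mirrored to the centre
// value, which makes its contribution to (sum - 4*u_c) vanish. The addends
// are grouped as (up+down) + (left+right) so the floating-point result is
// invariant under the grid's reflections and rotations (pair sums only
// commute, they never reassociate).
static inline double lap_at(const double* u, const int* mask,
                            int i, int j, int nr, int nc, double inv_dx2) {
  const double uc = u[i + (R_xlen_t)j * nr];
  const double up = (i > 0      && mask[(i - 1) + (R_xlen_t)j * nr]) ? u[(i - 1) + (R_xlen_t)j * nr] : uc;
  const double dn = (i < nr - 1 && mask[(i + 1) + (R_xlen_t)j * nr]) ? u[(i + 1) + (R_xlen_t)j * nr] : uc;
  const double lf = (j > 0      && mask[i + (R_xlen_t)(j - 1) * nr]) ? u[i + (R_xlen_t)(j - 1) * nr] : uc;
  const double rt = (j < nc - 1 && mask[i + (R_xlen_t)(j + 1) * nr]) ? u[i + (R_xlen_t)(j + 1) * nr] : uc;
  return ((up + dn) + (lf + rt) - 4.0 * uc) * inv_dx2;
}

// [[Rcpp::export]]
NumericMatrix masked_laplacian_cpp(NumericMatrix u, IntegerMatrix mask, double dx) {
  const int nr = u.nrow(), nc = u.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("field and template dimensions differ");
  NumericMatrix out(nr, nc);
  const double inv_dx2 = 1.0 / (dx * dx);
  const double* up = REAL(u);
  const int* mp = INTEGER(mask);
  double* op = REAL(out);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mp[i + (R_xlen_t)j * nr])
        op[i + (R_xlen_t)j * nr] = lap_at(up, mp, i, j, nr, nc, inv_dx2);
  return out;
}

// One synchronous explicit-Euler step; reads pre-step u, v throughout.
// Returns the iteration (1-based within this call) at which a non-finite
// value first appeared, or 0 if the step completed.
static int step_once(std::vector<double>& u, std::vector<double>& v,
                     std::vector<double>& unew, const int* mask,
                     const std::vector<int>& idx_i, const std::vector<int>& idx_j,
                     int nr, int nc,
                     double du, double a, double b, double c1, double c2,
                     double I, double dt, double inv_dx2) {
  const size_t n = idx_i.size();
  const double* up = u.data();
  for (size_t k = 0; k < n; ++k) {
    const int i = idx_i[k], j = idx_j[k];
    const R_xlen_t p = i + (R_xlen_t)j * nr;
    const double uc = up[p], vc = v[p];
    const double lap = lap_at(up, mask, i, j, nr, nc, inv_dx2);
    const double un = uc + dt * (c1 * uc * (uc - a) * (1.0 - uc) - c2 * uc * vc + I + du * lap);
    const double vn = vc + dt * (b * (uc - vc));
    if (!std::isfinite(un) || !std::isfinite(vn)) return 1;
    unew[p] = un;
    v[p] = vn;
  }
  u.swap(unew);
  return 0;
}

// [[Rcpp::export]]
List euler_step_cpp(NumericMatrix u, NumericMatrix v, IntegerMatrix mask,
                    double du, double a, double b, double c1, double c2,
                    double I, double dt, double dx) {
  const int nr = u.nrow(), nc = u.ncol();
  if (v.nrow() != nr || v.ncol() != nc || mask.nrow() != nr || mask.ncol() != nc)
    stop("field and template dimensions differ");
  std::vector<double> uu(REAL(u), REAL(u) + (R_xlen_t)nr * nc);
  std::vector<double> vv(REAL(v), REAL(v) + (R_xlen_t)nr * nc);
  std::vector<double> un(uu);
  std::vector<int> idx_i, idx_j;
  const int* mp = INTEGER(mask);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mp[i + (R_xlen_t)j * nr]) { idx_i.push_back(i); idx_j.push_back(j); }
  if (step_once(uu, vv, un, mp, idx_i, idx_j, nr, nc,
                du, a, b, c1, c2, I, dt, 1.0 / (dx * dx)))
    stop("non-finite field value at iteration 1");
  NumericMatrix uo(nr, nc), vo(nr, nc);
  std::copy(uu.begin(), uu.end(), REAL(uo));
  std::copy(vv.begin(), vv.end(), REAL(vo));
  return List::create(_["u"] = uo, _["v"] = vo);
}

// Full integration loop with in-loop recorders.
//
// stim_iter / stim_idx / stim_val : schedule of instantaneous perturbations;
//   stim_idx holds 0-based flat (column-major) indices, conductive only.
// elec_idx : per electrode, flat indices of the conductive nodes within its
//   sampling neighbourhood; elec_centre / elec_n support the literal
//   centre-field reading of the electrode sum.
// Records (potentials, activity, extents) are taken after every
// `record_every`-th step and also for the initial state (iteration 0, after
// iteration-0 stimuli). Coverage and max-u are accumulated every step.
// [[Rcpp::export]]
List fhn_simulate_cpp(IntegerMatrix mask, NumericMatrix u0, NumericMatrix v0,
                      double du, double a, double b, double c1, double c2,
                      double I, double dt, double dx,
                      int n_iter,
                      IntegerVector stim_iter, List stim_idx, NumericVector stim_val,
                      List elec_idx, IntegerVector elec_centre, IntegerVector elec_n,
                      bool summand_centre,
                      int record_every,
                      double activity_threshold,
                      bool track_coverage, bool track_max,
                      int snapshot_every, double snapshot_threshold,
                      bool record_fields) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const R_xlen_t nn = (R_xlen_t)nr * nc;
  if (u0.nrow() != nr || u0.ncol() != nc || v0.nrow() != nr || v0.ncol() != nc)
    stop("field and template dimensions differ");
  if (n_iter < 1) stop("n_iter must be >= 1");
  if (record_every < 1) stop("record_every must be >= 1");

  std::vector<double> u(REAL(u0), REAL(u0) + nn);
  std::vector<double> v(REAL(v0), REAL(v0) + nn);
  std::vector<double> un(u);
  const int* mp = INTEGER(mask);
  std::vector<int> idx_i, idx_j;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mp[i + (R_xlen_t)j * nr]) { idx_i.push_back(i); idx_j.push_back(j); }
  if (idx_i.empty()) stop("template has no conductive nodes");
  const double inv_dx2 = 1.0 / (dx * dx);
  const size_t ncond = idx_i.size();

  const int n_elec = elec_idx.size();
  std::vector< std::vector<R_xlen_t> > eidx(n_elec);
  for (int e = 0; e < n_elec; ++e) {
    IntegerVector iv = elec_idx[e];
    eidx[e].assign(iv.begin(), iv.end());
  }

  const int n_rec = n_iter / record_every + 1;  // includes iteration 0
  NumericMatrix potentials(n_rec, n_elec);
  IntegerVector rec_iter(n_rec);
  IntegerVector activity(n_rec);
  IntegerMatrix extents(n_rec, 4);  // min_i, max_i, min_j, max_j (-1 if none)
  std::vector<int> coverage;
  if (track_coverage) coverage.assign(nn, 0);
  NumericVector max_u(track_max ? (n_iter + 1) : 0);
  List snapshots;
  List fields;
  List fields_v;

  int rec_row = 0;
  auto do_record = [&](int t) {
    rec_iter[rec_row] = t;
    for (int e = 0; e < n_elec; ++e) {
      double s = 0.0;
      if (summand_centre) {
        const R_xlen_t c = elec_centre[e];
        s = (u[c] - v[c]) * (double)elec_n[e];
      } else {
        for (size_t k = 0; k < eidx[e].size(); ++k) {
          const R_xlen_t p = eidx[e][k];
          s += u[p] - v[p];
        }
      }
      potentials(rec_row, e) = s;
    }
    int act = 0, mi = -1, Mi = -1, mj = -1, Mj = -1;
    for (size_t k = 0; k < ncond; ++k) {
      const R_xlen_t p = idx_i[k] + (R_xlen_t)idx_j[k] * nr;
      if (u[p] > activity_threshold) {
        ++act;
        const int i = idx_i[k], j = idx_j[k];
        if (mi < 0 || i < mi) mi = i;
        if (Mi < 0 || i > Mi) Mi = i;
        if (mj < 0 || j < mj) mj = j;
        if (Mj < 0 || j > Mj) Mj = j;
      }
    }
    activity[rec_row] = act;
    extents(rec_row, 0) = mi; extents(rec_row, 1) = Mi;
    extents(rec_row, 2) = mj; extents(rec_row, 3) = Mj;
    if (record_fields) {
      NumericMatrix f(nr, nc), fv(nr, nc);
      std::copy(u.begin(), u.end(), REAL(f));
      std::copy(v.begin(), v.end(), REAL(fv));
      fields.push_back(f);
      fields_v.push_back(fv);
    }
    ++rec_row;
  };
  auto do_snapshot = [&]() {
    LogicalMatrix f(nr, nc);
    for (size_t k = 0; k < ncond; ++k) {
      const R_xlen_t p = idx_i[k] + (R_xlen_t)idx_j[k] * nr;
      if (u[p] > snapshot_threshold) f[p] = TRUE;
    }
    snapshots.push_back(f);
  };

  // iteration counter t: stimuli scheduled at t are applied before the step
  // that advances t -> t+1
  int t = 0;
  auto apply_stims = [&](int at) {
    for (int s = 0; s < stim_iter.size(); ++s) {
      if (stim_iter[s] == at) {
        IntegerVector iv = stim_idx[s];
        for (int k = 0; k < iv.size(); ++k) u[iv[k]] = stim_val[s];
      }
    }
  };
  apply_stims(0);
  if (track_max) {
    double m = 0.0;
    for (size_t k = 0; k < ncond; ++k) {
      const R_xlen_t p = idx_i[k] + (R_xlen_t)idx_j[k] * nr;
      if (u[p] > m) m = u[p];
    }
    max_u[0] = m;
  }
  do_record(0);
  if (snapshot_every > 0) do_snapshot();

  for (t = 0; t < n_iter; ++t) {
    if (t > 0) apply_stims(t);
    if (step_once(u, v, un, mp, idx_i, idx_j, nr, nc,
                  du, a, b, c1, c2, I, dt, inv_dx2))
      stop("non-finite field value at iteration %d", t + 1);
    const int tc = t + 1;
    if (track_coverage) {
      for (size_t k = 0; k < ncond; ++k) {
        const R_xlen_t p = idx_i[k] + (R_xlen_t)idx_j[k] * nr;
        if (u[p] > activity_threshold) ++coverage[p];
      }
    }
    if (track_max) {
      double m = 0.0;
      for (size_t k = 0; k < ncond; ++k) {
        const R_xlen_t p = idx_i[k] + (R_xlen_t)idx_j[k] * nr;
        if (u[p] > m) m = u[p];
      }
      max_u[tc] = m;
    }
    if (tc % record_every == 0) do_record(tc);
    if (snapshot_every > 0 && tc % snapshot_every == 0) do_snapshot();
    if (tc % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix uo(nr, nc), vo(nr, nc);
  std::copy(u.begin(), u.end(), REAL(uo));
  std::copy(v.begin(), v.end(), REAL(vo));
  List out = List::create(
    _["u"] = uo, _["v"] = vo, _["t"] = n_iter,
    _["rec_iter"] = rec_iter, _["potentials"] = potentials,
    _["activity"] = activity, _["extents"] = extents,
    _["snapshots"] = snapshots, _["fields"] = fields,
    _["fields_v"] = fields_v);
  if (track_coverage) {
    IntegerMatrix cov(nr, nc);
    std::copy(coverage.begin(), coverage.end(), INTEGER(cov));
    out["coverage"] = cov;
  } else {
    out["coverage"] = R_NilValue;
  }
  out["max_u"] = track_max ? (SEXP)max_u : R_NilValue;
  return out;
}

// 8-connected component labelling (BFS); labels 1..k, background 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int* mp = INTEGER(mask);
  int* lp = INTEGER(lab);
  int next = 0;
  std::deque<R_xlen_t> q;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      const R_xlen_t p0 = i0 + (R_xlen_t)j0 * nr;
      if (!mp[p0] || lp[p0]) continue;
      lp[p0] = ++next;
      q.push_back(p0);
      while (!q.empty()) {
        const R_xlen_t p = q.front(); q.pop_front();
        const int i = (int)(p % nr), j = (int)(p / nr);
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            const int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            const R_xlen_t pp = ii + (R_xlen_t)jj * nr;
            if (mp[pp] && !lp[pp]) { lp[pp] = next; q.push_back(pp); }
          }
        }
      }
    }
  }
  return lab;
}
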