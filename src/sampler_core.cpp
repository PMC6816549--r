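// Core Metropolis-Hastings kernel for the track-partition sampler.
//
// The partition state lives here during a sweep: tracks are vectors of
// 0-based observation indices, everything else (clutter membership, count
// statistics, cached per-track Kalman log-likelihoods, the running
// unnormalised log posterior) is maintained incrementally. All randomness
// is drawn from R's RNG so a single R-level seed reproduces a run exactly.
//
// Nine proposal move types are implemented as descents of a sampling tree;
// each descent multiplies the probability of every branch taken into the
// forward proposal mass Q(w*|w), and the probability of the unique inverse
// path is evaluated exactly in the proposed state to give Q(w|w*).

#include <RcppArmadillo.h>
#include <deque>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

typedef arma::mat::fixed<4, 2> mat42;

inline int runif_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

struct Edit {
  std::vector<int> rm;                    // track indices to remove
  std::vector<std::vector<int>> add;      // new tracks (0-based obs)
  double lq = 0.0, lrev = 0.0;
  bool identity = true;
  int mtype = 0;
};

struct Core {
  // observations
  int N = 0, Tn = 0;
  std::vector<int> t;
  std::vector<double> x, y;
  double W = 1, H = 1, aratio = 1;

  // configuration
  double max_speed = 16.0, stopp = 0.5;
  int gate = 4;

  // parameters and motion model
  double lb = 0.5, lc = 0.5, po = 0.8, ps = 0.9;
  arma::mat22 Robs;
  double qpos = 1.0, qvel = 0.1, s0v = 100.0, svv = 4.0;

  // static geometry indices
  std::vector<std::vector<int>> fwd, bwd, by_frame;

  // partition state
  std::vector<std::vector<int>> tracks;
  std::vector<double> trll;
  std::vector<int> track_of;              // -1 = clutter
  std::vector<int> clutter, cpos;         // cpos: index into clutter or -1

  // sufficient counts
  std::vector<int> n_births, n_clutter;
  long n_observed = 0, n_dark = 0, n_survive = 0, n_die = 0;

  double cur_lp = 0.0;                    // log P(Y|w,th) + log P(w|th)

  inline double dist2(int a, int b) const {
    double dx = x[a] - x[b], dy = y[a] - y[b];
    return dx * dx + dy * dy;
  }
  inline bool link_ok(int a, int b) const {
    int dt = t[b] - t[a];
    if (dt < 1 || dt > gate) return false;
    double v = max_speed * dt;
    return dist2(a, b) <= v * v;
  }

  void build_indices() {
    by_frame.assign(Tn, {});
    for (int i = 0; i < N; ++i) by_frame[t[i]].push_back(i);
    fwd.assign(N, {});
    bwd.assign(N, {});
    for (int i = 0; i < N; ++i) {
      for (int dt = 1; dt <= gate; ++dt) {
        int f = t[i] + dt;
        if (f >= Tn) break;
        for (int j : by_frame[f])
          if (link_ok(i, j)) { fwd[i].push_back(j); bwd[j].push_back(i); }
      }
    }
  }

  // ---- Kalman track log-likelihood (4-state near-constant-velocity) ----
  //
  // Hand-rolled arithmetic on the symmetric 4x4 state covariance stored as
  // 10 doubles (x, vx, y, vy ordering):
  //   [ p0 p1 p2 p3 ]
  //   [    p4 p5 p6 ]
  //   [       p7 p8 ]
  //   [          p9 ]
  struct KState {
    double X[4];
    double p[10];
  };

  inline void ks_init(KState& s, double ox, double oy) const {
    s.X[0] = ox; s.X[1] = 0.0; s.X[2] = oy; s.X[3] = 0.0;
    for (int i = 0; i < 10; ++i) s.p[i] = 0.0;
    s.p[0] = s0v; s.p[4] = svv; s.p[7] = s0v; s.p[9] = svv;
  }

  // one frame of F X, F P F' + Q with F: x += vx, y += vy
  inline void ks_predict(KState& s) const {
    double* p = s.p;
    double n0 = p[0] + 2.0 * p[1] + p[4] + qpos;
    double n1 = p[1] + p[4];
    double n2 = p[2] + p[5] + p[3] + p[6];
    double n3 = p[3] + p[6];
    double n4 = p[4] + qvel;
    double n5 = p[5] + p[6];
    double n6 = p[6];
    double n7 = p[7] + 2.0 * p[8] + p[9] + qpos;
    double n8 = p[8] + p[9];
    double n9 = p[9] + qvel;
    p[0] = n0; p[1] = n1; p[2] = n2; p[3] = n3; p[4] = n4;
    p[5] = n5; p[6] = n6; p[7] = n7; p[8] = n8; p[9] = n9;
    s.X[0] += s.X[1];
    s.X[2] += s.X[3];
  }

  // measurement update at (zx, zy); returns the innovation log-density
  inline double ks_update(KState& s, double zx, double zy) const {
    double* p = s.p;
    double S00 = p[0] + Robs(0, 0), S01 = p[2] + Robs(0, 1),
           S11 = p[7] + Robs(1, 1);
    double det = S00 * S11 - S01 * S01;
    if (!(det > 0.0) || !std::isfinite(det))
      stop("innovation covariance not positive definite (det = %f)", det);
    double i00 = S11 / det, i01 = -S01 / det, i11 = S00 / det;
    double rx = zx - s.X[0], ry = zy - s.X[2];
    double ll = -std::log(2.0 * M_PI) - 0.5 * std::log(det) -
                0.5 * (i00 * rx * rx + 2.0 * i01 * rx * ry + i11 * ry * ry);
    // u = P e_x, v = P e_y (columns of P H')
    double u[4] = {p[0], p[1], p[2], p[3]};
    double v[4] = {p[2], p[5], p[7], p[8]};
    double K0[4], K1[4];
    for (int a = 0; a < 4; ++a) {
      K0[a] = u[a] * i00 + v[a] * i01;
      K1[a] = u[a] * i01 + v[a] * i11;
      s.X[a] += K0[a] * rx + K1[a] * ry;
    }
    // P <- P - K (H P); rows of H P are u and v
    p[0] -= K0[0] * u[0] + K1[0] * v[0];
    p[1] -= K0[0] * u[1] + K1[0] * v[1];
    p[2] -= K0[0] * u[2] + K1[0] * v[2];
    p[3] -= K0[0] * u[3] + K1[0] * v[3];
    p[4] -= K0[1] * u[1] + K1[1] * v[1];
    p[5] -= K0[1] * u[2] + K1[1] * v[2];
    p[6] -= K0[1] * u[3] + K1[1] * v[3];
    p[7] -= K0[2] * u[2] + K1[2] * v[2];
    p[8] -= K0[2] * u[3] + K1[2] * v[3];
    p[9] -= K0[3] * u[3] + K1[3] * v[3];
    return ll;
  }

  double kalman_ll(const std::vector<int>& tr) const {
    KState s;
    ks_init(s, x[tr[0]], y[tr[0]]);
    double ll = 0.0;
    int prev_t = t[tr[0]];
    for (size_t k = 0; k < tr.size(); ++k) {
      int o = tr[k];
      for (int f = prev_t; f < t[o]; ++f) ks_predict(s);
      prev_t = t[o];
      ll += ks_update(s, x[o], y[o]);
    }
    return ll;
  }

  // Cholesky (lower) of a symmetric 4x4 in 10-double storage; false if not
  // positive definite after jitter.
  static bool chol4(const double* p, double L[4][4], double jitter) {
    double a[4][4] = {{p[0] + jitter, p[1], p[2], p[3]},
                      {p[1], p[4] + jitter, p[5], p[6]},
                      {p[2], p[5], p[7] + jitter, p[8]},
                      {p[3], p[6], p[8], p[9] + jitter}};
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) L[i][j] = 0.0;
    for (int i = 0; i < 4; ++i) {
      for (int j = 0; j <= i; ++j) {
        double s = a[i][j];
        for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
        if (i == j) {
          if (!(s > 0.0)) return false;
          L[i][i] = std::sqrt(s);
        } else {
          L[i][j] = s / L[j][j];
        }
      }
    }
    return true;
  }

  // draw z ~ N(mean, P) with P in 10-double storage
  static void mvn4(const double* mean, const double* p, double* out) {
    double L[4][4];
    double jit = 1e-12;
    while (!chol4(p, L, jit)) {
      jit *= 100.0;
      if (jit > 1.0) {  // degenerate: fall back to the mean
        for (int i = 0; i < 4; ++i) out[i] = mean[i];
        return;
      }
    }
    double z[4];
    for (int i = 0; i < 4; ++i) z[i] = norm_rand();
    for (int i = 0; i < 4; ++i) {
      double s = mean[i];
      for (int k = 0; k <= i; ++k) s += L[i][k] * z[k];
      out[i] = s;
    }
  }

  // Residuals about a backward-sampled state trajectory (forward filter,
  // backward sampling), pooled into sum of r r' and a count. Sampling the
  // states rather than using the smoothed means keeps the inverse-Wishart
  // update of R exactly conjugate.
  void accumulate_residuals(arma::mat22& rsum, long& rn) const {
    for (const auto& tr : tracks) {
      int span = t[tr.back()] - t[tr[0]] + 1;
      std::vector<KState> pred(span), filt(span);
      std::vector<int> obs_at(span, -1);
      for (int o : tr) obs_at[t[o] - t[tr[0]]] = o;
      KState s;
      ks_init(s, x[tr[0]], y[tr[0]]);
      for (int i = 0; i < span; ++i) {
        if (i > 0) ks_predict(s);
        pred[i] = s;
        int o = obs_at[i];
        if (o >= 0) ks_update(s, x[o], y[o]);
        filt[i] = s;
      }
      double xs[4];
      mvn4(filt[span - 1].X, filt[span - 1].p, xs);
      for (int i = span - 1; i >= 0; --i) {
        if (i < span - 1) {
          // G = Pf F' inv(Pp_next): solve Pp_next G' = F Pf
          const double* pf = filt[i].p;
          // B = F Pf (rows: r0 = pf row0 + row1, r1 = row1, r2 = row2+row3,
          // r3 = row3), full 4x4 from symmetric storage
          double Pfm[4][4] = {{pf[0], pf[1], pf[2], pf[3]},
                              {pf[1], pf[4], pf[5], pf[6]},
                              {pf[2], pf[5], pf[7], pf[8]},
                              {pf[3], pf[6], pf[8], pf[9]}};
          double B[4][4];
          for (int c = 0; c < 4; ++c) {
            B[0][c] = Pfm[0][c] + Pfm[1][c];
            B[1][c] = Pfm[1][c];
            B[2][c] = Pfm[2][c] + Pfm[3][c];
            B[3][c] = Pfm[3][c];
          }
          double L[4][4];
          if (!chol4(pred[i + 1].p, L, 1e-12)) {
            // singular prediction covariance: fall back to a filtered draw
            mvn4(filt[i].X, filt[i].p, xs);
            int oo = obs_at[i];
            if (oo >= 0) {
              double rx = x[oo] - xs[0], ry = y[oo] - xs[2];
              rsum(0, 0) += rx * rx;
              rsum(0, 1) += rx * ry;
              rsum(1, 0) += rx * ry;
              rsum(1, 1) += ry * ry;
              rn += 1;
            }
            continue;
          }
          // solve (L L') Gt = B column-wise; Gt[.][c] = G'_{.c} = G_{c.}
          double G[4][4];
          for (int c = 0; c < 4; ++c) {
            double w[4];
            for (int r = 0; r < 4; ++r) {  // forward: L w = B[.][c]
              double sum = B[r][c];
              for (int k = 0; k < r; ++k) sum -= L[r][k] * w[k];
              w[r] = sum / L[r][r];
            }
            for (int r = 3; r >= 0; --r) {  // backward: L' g = w
              double sum = w[r];
              for (int k = r + 1; k < 4; ++k) sum -= L[k][r] * G[c][k];
              G[c][r] = sum / L[r][r];
            }
          }
          // conditional mean and covariance
          const double* pp = pred[i + 1].p;
          double Ppm[4][4] = {{pp[0], pp[1], pp[2], pp[3]},
                              {pp[1], pp[4], pp[5], pp[6]},
                              {pp[2], pp[5], pp[7], pp[8]},
                              {pp[3], pp[6], pp[8], pp[9]}};
          double cm[4];
          for (int r = 0; r < 4; ++r) {
            double sum = filt[i].X[r];
            for (int k = 0; k < 4; ++k)
              sum += G[r][k] * (xs[k] - pred[i + 1].X[k]);
            cm[r] = sum;
          }
          double GP[4][4];
          for (int r = 0; r < 4; ++r)
            for (int c = 0; c < 4; ++c) {
              double sum = 0.0;
              for (int k = 0; k < 4; ++k) sum += G[r][k] * Ppm[k][c];
              GP[r][c] = sum;
            }
          double cc[10];
          int idx = 0;
          for (int r = 0; r < 4; ++r)
            for (int c = r; c < 4; ++c) {
              double sum = Pfm[r][c];
              for (int k = 0; k < 4; ++k) sum -= GP[r][k] * G[c][k];
              cc[idx++] = sum;
            }
          mvn4(cm, cc, xs);
        }
        int o = obs_at[i];
        if (o >= 0) {
          double rx = x[o] - xs[0], ry = y[o] - xs[2];
          rsum(0, 0) += rx * rx;
          rsum(0, 1) += rx * ry;
          rsum(1, 0) += rx * ry;
          rsum(1, 1) += ry * ry;
          rn += 1;
        }
      }
    }
  }

  // ---- count statistics ----
  void recount_stats() {
    n_births.assign(Tn, 0);
    n_clutter.assign(Tn, 0);
    n_observed = n_dark = n_survive = n_die = 0;
    for (const auto& tr : tracks) {
      int tb = t[tr[0]], td = t[tr.back()];
      n_births[tb] += 1;
      int span = td - tb + 1;
      n_observed += (long)tr.size();
      n_dark += span - (long)tr.size();
      n_survive += span - 1;
      if (td < Tn - 1) n_die += 1;
    }
    for (int o : clutter) n_clutter[t[o]] += 1;
  }

  double prior_total() const {
    double mub = lb * aratio, muc = lc * aratio, out = 0.0;
    for (int f = 0; f < Tn; ++f) {
      out += R::dpois(n_births[f], mub, 1);
      out += R::dpois(n_clutter[f], muc, 1);
    }
    out += n_survive * std::log(ps) + n_die * std::log1p(-ps);
    out += n_observed * std::log(po) + n_dark * std::log1p(-po);
    out += -((double)clutter.size()) * std::log(W * H);
    return out;
  }

  void init_posterior() {
    recount_stats();
    trll.resize(tracks.size());
    for (size_t i = 0; i < tracks.size(); ++i) trll[i] = kalman_ll(tracks[i]);
    cur_lp = prior_total();
    for (double v : trll) cur_lp += v;
  }

  // ---- candidate helpers ----
  inline bool in_small(const std::vector<int>& v, int o, size_t upto) const {
    for (size_t i = 0; i < upto; ++i) if (v[i] == o) return true;
    return false;
  }

  // clutter neighbours of `o` in direction dir (true = forward), excluding
  // the first `upto` entries of `ex`
  int clutter_cands(int o, bool fwd_dir, const std::vector<int>& ex,
                    size_t upto, std::vector<int>* out) const {
    const std::vector<int>& nb = fwd_dir ? fwd[o] : bwd[o];
    int n = 0;
    for (int b : nb) {
      if (track_of[b] >= 0) continue;
      if (in_small(ex, b, upto)) continue;
      ++n;
      if (out) out->push_back(b);
    }
    return n;
  }

  // ---- move implementations ----

  // birth-style chain probability of appending `seq` (in append order) to a
  // growing end starting at `cur`, in a virtual state where the members of
  // `virt_clutter_extra` count as clutter. Returns the log-probability of
  // the append branches and the final stop branch.
  double chain_log_prob(int cur, const std::vector<int>& seq, bool fwd_dir,
                        const std::vector<int>& virt_extra) const {
    double lp = 0.0;
    for (size_t k = 0; k < seq.size(); ++k) {
      const std::vector<int>& nb = fwd_dir ? fwd[cur] : bwd[cur];
      int cnt = 0;
      for (int b : nb) {
        bool cl = track_of[b] < 0 || in_small(virt_extra, b, virt_extra.size());
        if (!cl) continue;
        if (in_small(seq, b, k)) continue;  // already appended
        ++cnt;
      }
      lp += std::log1p(-stopp) - std::log((double)cnt);
      cur = seq[k];
    }
    // final stop factor: 0.5 if any candidate remains, else 1
    const std::vector<int>& nb = fwd_dir ? fwd[cur] : bwd[cur];
    int cnt = 0;
    for (int b : nb) {
      bool cl = track_of[b] < 0 || in_small(virt_extra, b, virt_extra.size());
      if (!cl) continue;
      if (in_small(seq, b, seq.size())) continue;
      ++cnt;
    }
    if (cnt > 0) lp += std::log(stopp);
    return lp;
  }

  void mv_birth(Edit& e) {
    int Nc = (int)clutter.size();
    if (Nc == 0) return;
    std::vector<int> chain;
    chain.push_back(clutter[runif_int(Nc)]);
    double lq = -std::log((double)Nc);
    for (;;) {
      std::vector<int> cands;
      clutter_cands(chain.back(), true, chain, chain.size(), &cands);
      if (cands.empty()) break;
      if (unif_rand() < stopp) { lq += std::log(stopp); break; }
      lq += std::log1p(-stopp) - std::log((double)cands.size());
      chain.push_back(cands[runif_int((int)cands.size())]);
    }
    if (chain.size() < 2) return;
    e.identity = false;
    e.add.push_back(chain);
    e.lq = lq;
    e.lrev = -std::log((double)tracks.size() + 1.0);
  }

  void mv_death(Edit& e) {
    int K = (int)tracks.size();
    if (K == 0) return;
    int i = runif_int(K);
    const std::vector<int>& tr = tracks[i];
    e.identity = false;
    e.rm.push_back(i);
    e.lq = -std::log((double)K);
    // reverse: birth of exactly this chain once its members are clutter
    int Ncp = (int)clutter.size() + (int)tr.size();
    double lrev = -std::log((double)Ncp);
    for (size_t k = 1; k < tr.size(); ++k) {
      int cnt = 0;
      for (int b : fwd[tr[k - 1]]) {
        bool cl = track_of[b] < 0 || track_of[b] == i;
        if (!cl || in_small(tr, b, k)) continue;
        ++cnt;
      }
      lrev += std::log1p(-stopp) - std::log((double)cnt);
    }
    int cnt = 0;
    for (int b : fwd[tr.back()]) {
      bool cl = track_of[b] < 0 || track_of[b] == i;
      if (!cl || in_small(tr, b, tr.size())) continue;
      ++cnt;
    }
    if (cnt > 0) lrev += std::log(stopp);
    e.lrev = lrev;
  }

  void mv_extend(Edit& e) {
    int K = (int)tracks.size();
    if (K == 0) return;
    int i = runif_int(K);
    bool back = unif_rand() < 0.5;
    double lq = -std::log((double)K) - std::log(2.0);
    const std::vector<int>& tr = tracks[i];
    int cur = back ? tr.back() : tr.front();
    std::vector<int> added;
    for (;;) {
      std::vector<int> cands;
      clutter_cands(cur, back, added, added.size(), &cands);
      if (cands.empty()) break;
      if (unif_rand() < stopp) { lq += std::log(stopp); break; }
      lq += std::log1p(-stopp) - std::log((double)cands.size());
      int pick = cands[runif_int((int)cands.size())];
      added.push_back(pick);
      cur = pick;
    }
    if (added.empty()) return;
    e.identity = false;
    std::vector<int> nt;
    if (back) {
      nt = tr;
      nt.insert(nt.end(), added.begin(), added.end());
    } else {
      nt.assign(added.rbegin(), added.rend());
      nt.insert(nt.end(), tr.begin(), tr.end());
    }
    e.rm.push_back(i);
    e.add.push_back(nt);
    e.lq = lq;
    e.lrev = -std::log((double)K) - std::log(2.0) -
             std::log((double)nt.size() - 2.0);
  }

  void mv_reduce(Edit& e) {
    int K = (int)tracks.size();
    if (K == 0) return;
    int i = runif_int(K);
    bool back = unif_rand() < 0.5;
    const std::vector<int>& tr = tracks[i];
    int len = (int)tr.size();
    int c = len - 2;
    if (c <= 0) return;
    int j = 1 + runif_int(c);
    e.identity = false;
    e.lq = -std::log((double)K) - std::log(2.0) - std::log((double)c);
    std::vector<int> kept, removed;  // removed in re-append order
    if (back) {
      kept.assign(tr.begin(), tr.end() - j);
      for (int k = len - j; k < len; ++k) removed.push_back(tr[k]);
    } else {
      kept.assign(tr.begin() + j, tr.end());
      for (int k = j - 1; k >= 0; --k) removed.push_back(tr[k]);
    }
    e.rm.push_back(i);
    e.add.push_back(kept);
    int cur = back ? kept.back() : kept.front();
    e.lrev = -std::log((double)K) - std::log(2.0) +
             chain_log_prob(cur, removed, back, removed);
  }

  void count_merge_pairs(const std::vector<const std::vector<int>*>& trs,
                         std::vector<std::pair<int, int>>* out) const {
    int K = (int)trs.size();
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        if (i == j) continue;
        int a = trs[i]->back(), b = trs[j]->front();
        if (link_ok(a, b)) out->push_back({i, j});
      }
  }

  std::vector<const std::vector<int>*> track_ptrs() const {
    std::vector<const std::vector<int>*> p;
    p.reserve(tracks.size());
    for (const auto& tr : tracks) p.push_back(&tr);
    return p;
  }

  void mv_split(Edit& e) {
    std::vector<int> elig;
    for (size_t i = 0; i < tracks.size(); ++i)
      if (tracks[i].size() >= 4) elig.push_back((int)i);
    if (elig.empty()) return;
    int i = elig[runif_int((int)elig.size())];
    const std::vector<int>& tr = tracks[i];
    int len = (int)tr.size();
    int a = 2 + runif_int(len - 3);  // prefix length in 2..len-2
    e.identity = false;
    e.lq = -std::log((double)elig.size()) - std::log((double)(len - 3));
    std::vector<int> t1(tr.begin(), tr.begin() + a),
        t2(tr.begin() + a, tr.end());
    e.rm.push_back(i);
    e.add.push_back(t1);
    e.add.push_back(t2);
    // reverse: merge pair count in the proposed state
    auto trs = track_ptrs();
    trs[i] = &e.add[0];
    trs.push_back(&e.add[1]);
    std::vector<std::pair<int, int>> pairs;
    count_merge_pairs(trs, &pairs);
    e.lrev = -std::log((double)pairs.size());
  }

  void mv_merge(Edit& e) {
    auto trs = track_ptrs();
    std::vector<std::pair<int, int>> pairs;
    count_merge_pairs(trs, &pairs);
    if (pairs.empty()) return;
    auto pr = pairs[runif_int((int)pairs.size())];
    e.identity = false;
    e.lq = -std::log((double)pairs.size());
    const std::vector<int>& u = tracks[pr.first];
    const std::vector<int>& v = tracks[pr.second];
    std::vector<int> merged = u;
    merged.insert(merged.end(), v.begin(), v.end());
    e.rm.push_back(pr.first);
    e.rm.push_back(pr.second);
    e.add.push_back(merged);
    // reverse: split in the proposed state
    int elig = 0;
    for (size_t k = 0; k < tracks.size(); ++k) {
      if ((int)k == pr.first || (int)k == pr.second) continue;
      if (tracks[k].size() >= 4) ++elig;
    }
    ++elig;  // the merged track itself (always >= 4)
    e.lrev = -std::log((double)elig) -
             std::log((double)merged.size() - 3.0);
  }

  void mv_update(Edit& e) {
    int K = (int)tracks.size();
    if (K == 0) return;
    int i = runif_int(K);
    const std::vector<int>& tr = tracks[i];
    int len = (int)tr.size();
    int pos = runif_int(len);
    int o = tr[pos];
    int prev = pos > 0 ? tr[pos - 1] : -1;
    int next = pos < len - 1 ? tr[pos + 1] : -1;
    std::vector<int> cands;
    for (int b : by_frame[t[o]]) {
      if (track_of[b] >= 0) continue;
      if (prev >= 0 && !link_ok(prev, b)) continue;
      if (next >= 0 && !link_ok(b, next)) continue;
      cands.push_back(b);
    }
    if (cands.empty()) return;
    int c = cands[runif_int((int)cands.size())];
    e.identity = false;
    e.lq = -std::log((double)K) - std::log((double)len) -
           std::log((double)cands.size());
    std::vector<int> nt = tr;
    nt[pos] = c;
    e.rm.push_back(i);
    e.add.push_back(nt);
    // reverse candidates: clutter minus c plus o, same neighbours
    int m = 0;
    for (int b : by_frame[t[o]]) {
      bool cl = (b == o) || (track_of[b] < 0 && b != c);
      if (!cl) continue;
      if (prev >= 0 && !link_ok(prev, b)) continue;
      if (next >= 0 && !link_ok(b, next)) continue;
      ++m;
    }
    e.lrev = -std::log((double)K) - std::log((double)len) -
             std::log((double)m);
  }

  // interior insertion slot of `o` into track tr; returns slot index k
  // (insert before position k) or -1 if no strictly interior valid slot
  int interior_slot(const std::vector<int>& tr, int o) const {
    int to = t[o];
    if (to <= t[tr.front()] || to >= t[tr.back()]) return -1;
    for (size_t k = 1; k < tr.size(); ++k) {
      if (t[tr[k]] > to) {
        if (t[tr[k - 1]] == to) return -1;  // frame occupied
        if (link_ok(tr[k - 1], o) && link_ok(o, tr[k])) return (int)k;
        return -1;
      }
    }
    return -1;
  }

  void mv_transfer(Edit& e) {
    int K = (int)tracks.size();
    if (K < 2) return;
    int src = runif_int(K);
    const std::vector<int>& tr = tracks[src];
    int len = (int)tr.size();
    if (len < 3) return;
    int pos = 1 + runif_int(len - 2);
    int o = tr[pos];
    if (!link_ok(tr[pos - 1], tr[pos + 1])) return;  // bridge must be legal
    std::vector<int> targets;
    for (int j = 0; j < K; ++j) {
      if (j == src) continue;
      if (interior_slot(tracks[j], o) >= 0) targets.push_back(j);
    }
    if (targets.empty()) return;
    int tgt = targets[runif_int((int)targets.size())];
    e.identity = false;
    e.lq = -std::log((double)K) - std::log((double)(len - 2)) -
           std::log((double)targets.size());
    std::vector<int> ns = tr;
    ns.erase(ns.begin() + pos);
    std::vector<int> ntg = tracks[tgt];
    int slot = interior_slot(ntg, o);
    ntg.insert(ntg.begin() + slot, o);
    e.rm.push_back(src);
    e.rm.push_back(tgt);
    e.add.push_back(ns);
    e.add.push_back(ntg);
    // reverse: transfer o from the enlarged target back; count its targets
    std::vector<const std::vector<int>*> trs = track_ptrs();
    trs[src] = &e.add[0];
    trs[tgt] = &e.add[1];
    int ntp = 0;
    for (int j = 0; j < K; ++j) {
      if (j == tgt) continue;
      if (interior_slot(*trs[j], o) >= 0) ++ntp;
    }
    e.lrev = -std::log((double)K) -
             std::log((double)(ntg.size() - 2)) - std::log((double)ntp);
  }

  int count_cross_cuts(const std::vector<int>& A, const std::vector<int>& B,
                       std::vector<std::pair<int, int>>* out) const {
    int n = 0;
    for (size_t a = 1; a < A.size(); ++a)
      for (size_t b = 1; b < B.size(); ++b) {
        int lo = std::max(t[A[a - 1]], t[B[b - 1]]);
        int hi = std::min(t[A[a]], t[B[b]]);
        if (lo >= hi) continue;
        if (!link_ok(A[a - 1], B[b]) || !link_ok(B[b - 1], A[a])) continue;
        ++n;
        if (out) out->push_back({(int)a, (int)b});
      }
    return n;
  }

  void mv_cross(Edit& e) {
    int K = (int)tracks.size();
    if (K < 2) return;
    long npair = (long)K * (K - 1) / 2;
    long r = runif_int((int)npair);
    int i = 0;
    while (r >= K - 1 - i) { r -= K - 1 - i; ++i; }
    int j = i + 1 + (int)r;
    const std::vector<int>& A = tracks[i];
    const std::vector<int>& B = tracks[j];
    std::vector<std::pair<int, int>> cuts;
    count_cross_cuts(A, B, &cuts);
    if (cuts.empty()) return;
    auto cut = cuts[runif_int((int)cuts.size())];
    e.identity = false;
    e.lq = -std::log((double)npair) - std::log((double)cuts.size());
    int a = cut.first, b = cut.second;
    std::vector<int> n1(A.begin(), A.begin() + a);
    n1.insert(n1.end(), B.begin() + b, B.end());
    std::vector<int> n2(B.begin(), B.begin() + b);
    n2.insert(n2.end(), A.begin() + a, A.end());
    e.rm.push_back(i);
    e.rm.push_back(j);
    e.add.push_back(n1);
    e.add.push_back(n2);
    int nrev = count_cross_cuts(n1, n2, nullptr);
    e.lrev = -std::log((double)npair) - std::log((double)nrev);
  }

  Edit propose(int force_move) {
    Edit e;
    int mt = force_move >= 0 ? force_move : runif_int(9);
    e.mtype = mt;
    const double l9 = -std::log(9.0);
    switch (mt) {
      case 0: mv_birth(e); break;
      case 1: mv_death(e); break;
      case 2: mv_extend(e); break;
      case 3: mv_reduce(e); break;
      case 4: mv_split(e); break;
      case 5: mv_merge(e); break;
      case 6: mv_update(e); break;
      case 7: mv_transfer(e); break;
      case 8: mv_cross(e); break;
    }
    if (!e.identity) {
      e.lq += l9;
      e.lrev += l9;
    }
    return e;
  }

  // ---- evaluating and applying edits ----

  // delta of the unnormalised log posterior (likelihood + partition prior)
  double edit_delta(const Edit& e, std::vector<double>* add_ll) const {
    double d = 0.0;
    for (const auto& tr : e.add) {
      double v = kalman_ll(tr);
      if (add_ll) add_ll->push_back(v);
      d += v;
    }
    for (int i : e.rm) d -= trll[i];

    double mub = lb * aratio, muc = lc * aratio;
    std::map<int, int> db, dc;
    long dobs = 0, ddark = 0, dsurv = 0, ddie = 0, dclut = 0;
    for (int i : e.rm) {
      const std::vector<int>& tr = tracks[i];
      int tb = t[tr[0]], td = t[tr.back()], span = td - tb + 1;
      db[tb] -= 1;
      dobs -= (long)tr.size();
      ddark -= span - (long)tr.size();
      dsurv -= span - 1;
      if (td < Tn - 1) ddie -= 1;
      for (int o : tr) dc[t[o]] += 1;
      dclut += (long)tr.size();
    }
    for (const auto& tr : e.add) {
      int tb = t[tr[0]], td = t[tr.back()], span = td - tb + 1;
      db[tb] += 1;
      dobs += (long)tr.size();
      ddark += span - (long)tr.size();
      dsurv += span - 1;
      if (td < Tn - 1) ddie += 1;
      for (int o : tr) dc[t[o]] -= 1;
      dclut -= (long)tr.size();
    }
    auto lpois_d = [](int k_new, int k_old, double mu) {
      // difference of Poisson log-pmfs at fixed mean
      double out = (k_new - k_old) * (mu > 0 ? std::log(mu) : R_NegInf);
      return out - std::lgamma(k_new + 1.0) + std::lgamma(k_old + 1.0);
    };
    for (auto& kv : db)
      if (kv.second != 0)
        d += lpois_d(n_births[kv.first] + kv.second, n_births[kv.first], mub);
    for (auto& kv : dc)
      if (kv.second != 0)
        d += lpois_d(n_clutter[kv.first] + kv.second, n_clutter[kv.first], muc);
    d += dsurv * std::log(ps) + ddie * std::log1p(-ps);
    d += dobs * std::log(po) + ddark * std::log1p(-po);
    d += -((double)dclut) * std::log(W * H);
    return d;
  }

  void clutter_insert(int o) {
    cpos[o] = (int)clutter.size();
    clutter.push_back(o);
    track_of[o] = -1;
  }
  void clutter_remove(int o) {
    int p = cpos[o];
    int last = clutter.back();
    clutter[p] = last;
    cpos[last] = p;
    clutter.pop_back();
    cpos[o] = -1;
  }

  void apply_edit(const Edit& e, const std::vector<double>& add_ll,
                  double delta) {
    // release removed tracks' observations to clutter
    for (int i : e.rm) {
      for (int o : tracks[i]) clutter_insert(o);
      int tb = t[tracks[i][0]], td = t[tracks[i].back()];
      n_births[tb] -= 1;
      int span = td - tb + 1;
      n_observed -= (long)tracks[i].size();
      n_dark -= span - (long)tracks[i].size();
      n_survive -= span - 1;
      if (td < Tn - 1) n_die -= 1;
      for (int o : tracks[i]) n_clutter[t[o]] += 1;
    }
    // drop removed track slots (highest index first keeps indices valid)
    std::vector<int> rm = e.rm;
    std::sort(rm.begin(), rm.end(), std::greater<int>());
    for (int i : rm) {
      int last = (int)tracks.size() - 1;
      if (i != last) {
        tracks[i] = std::move(tracks[last]);
        trll[i] = trll[last];
        for (int o : tracks[i]) track_of[o] = i;
      }
      tracks.pop_back();
      trll.pop_back();
    }
    // add new tracks
    for (size_t k = 0; k < e.add.size(); ++k) {
      const std::vector<int>& tr = e.add[k];
      int idx = (int)tracks.size();
      for (int o : tr) clutter_remove(o);
      tracks.push_back(tr);
      trll.push_back(add_ll[k]);
      for (int o : tr) track_of[o] = idx;
      int tb = t[tr[0]], td = t[tr.back()], span = td - tb + 1;
      n_births[tb] += 1;
      n_observed += (long)tr.size();
      n_dark += span - (long)tr.size();
      n_survive += span - 1;
      if (td < Tn - 1) n_die += 1;
      for (int o : tr) n_clutter[t[o]] -= 1;
    }
    cur_lp += delta;
  }

  long edit_ged(const Edit& e) const {
    std::vector<long long> la, lb2;
    for (int i : e.rm)
      for (size_t k = 1; k < tracks[i].size(); ++k)
        la.push_back((long long)tracks[i][k - 1] * (N + 1) + tracks[i][k]);
    for (const auto& tr : e.add)
      for (size_t k = 1; k < tr.size(); ++k)
        lb2.push_back((long long)tr[k - 1] * (N + 1) + tr[k]);
    std::sort(la.begin(), la.end());
    std::sort(lb2.begin(), lb2.end());
    std::vector<long long> sym;
    std::set_symmetric_difference(la.begin(), la.end(), lb2.begin(),
                                  lb2.end(), std::back_inserter(sym));
    return (long)sym.size();
  }
};

static void setup_core(Core& C, IntegerVector& obs_t, NumericVector& obs_x,
                       NumericVector& obs_y, int n_frames_,
                       NumericVector& fov_, double area_unit, List& tracks_,
                       IntegerVector& clutter_, List& theta_, List& model_,
                       List& cfg_) {
  C.N = obs_t.size();
  C.Tn = n_frames_;
  C.t.assign(obs_t.begin(), obs_t.end());
  C.x.assign(obs_x.begin(), obs_x.end());
  C.y.assign(obs_y.begin(), obs_y.end());
  C.W = fov_[0];
  C.H = fov_[1];
  C.aratio = C.W * C.H / area_unit;
  C.max_speed = as<double>(cfg_["max_speed"]);
  C.gate = as<int>(cfg_["gate_frames"]);
  C.stopp = as<double>(cfg_["birth_stop"]);
  C.lb = as<double>(theta_["lambda_b"]);
  C.lc = as<double>(theta_["lambda_c"]);
  C.po = as<double>(theta_["p_o"]);
  C.ps = as<double>(theta_["p_s"]);
  NumericMatrix R_(as<NumericMatrix>(theta_["R"]));
  C.Robs = {{R_(0, 0), R_(0, 1)}, {R_(1, 0), R_(1, 1)}};
  C.qpos = as<double>(model_["q_pos"]);
  C.qvel = as<double>(model_["q_vel"]);
  double s0 = as<double>(model_["prior_sigma0"]);
  double sv = as<double>(model_["prior_sigmav"]);
  C.s0v = s0 * s0;
  C.svv = sv * sv;

  C.build_indices();
  C.track_of.assign(C.N, -1);
  C.cpos.assign(C.N, -1);
  for (int k = 0; k < tracks_.size(); ++k) {
    IntegerVector tr = tracks_[k];
    std::vector<int> v(tr.size());
    for (int u = 0; u < tr.size(); ++u) v[u] = tr[u] - 1;
    for (size_t u = 1; u < v.size(); ++u)
      if (!C.link_ok(v[u - 1], v[u]))
        stop("track %d contains a link outside the speed/frame gate", k + 1);
    for (int o : v) C.track_of[o] = k;
    C.tracks.push_back(std::move(v));
  }
  for (int u = 0; u < clutter_.size(); ++u) {
    int o = clutter_[u] - 1;
    C.cpos[o] = (int)C.clutter.size();
    C.clutter.push_back(o);
  }
  C.init_posterior();
}

}  // namespace

// [[Rcpp::export(name = ".bgl_run")]]
List bgl_run(IntegerVector obs_t, NumericVector obs_x, NumericVector obs_y,
             int n_frames_, NumericVector fov_, double area_unit,
             List tracks_, IntegerVector clutter_,
             List theta_, List model_, List cfg_,
             int n_steps, int force_move, bool propose_only,
             int record_every, int record_offset, int record_max,
             int record_mode) {
  Core C;
  setup_core(C, obs_t, obs_x, obs_y, n_frames_, fov_, area_unit, tracks_,
             clutter_, theta_, model_, cfg_);

  // link universe for mask recording (small problems only)
  std::vector<long long> link_index_key;
  std::map<long long, int> link_bit;
  if (record_mode == 2) {
    for (int a = 0; a < C.N; ++a)
      for (int b : C.fwd[a]) {
        long long key = (long long)a * (C.N + 1) + b;
        link_bit[key] = (int)link_index_key.size();
        link_index_key.push_back(key);
      }
    if (link_index_key.size() > 62)
      stop("mask recording supports at most 62 candidate links");
  }
  auto current_mask = [&]() {
    double m = 0;
    for (const auto& tr : C.tracks)
      for (size_t k = 1; k < tr.size(); ++k) {
        long long key = (long long)tr[k - 1] * (C.N + 1) + tr[k];
        m += std::ldexp(1.0, link_bit[key]);
      }
    return m;
  };

  IntegerMatrix move_stats(9, 3);  // rejected, identity, accepted
  std::vector<std::vector<std::vector<int>>> records;
  std::vector<double> masks;
  IntegerVector p_move(propose_only ? n_steps : 0);
  LogicalVector p_ident(propose_only ? n_steps : 0);
  IntegerVector p_ged(propose_only ? n_steps : 0);
  NumericVector p_lq(propose_only ? n_steps : 0);
  NumericVector p_lrev(propose_only ? n_steps : 0);
  NumericVector p_mask(propose_only && record_mode == 2 ? n_steps : 0);
  List p_first;

  int until_record = record_offset;
  for (int step = 0; step < n_steps; ++step) {
    Edit e = C.propose(force_move);
    if (propose_only) {
      p_move[step] = e.mtype + 1;
      p_ident[step] = e.identity;
      p_ged[step] = e.identity ? 0 : (int)C.edit_ged(e);
      p_lq[step] = e.identity ? NA_REAL : e.lq;
      p_lrev[step] = e.identity ? NA_REAL : e.lrev;
      if (record_mode == 2) {
        double m = current_mask();
        if (!e.identity) {
          for (int i : e.rm)
            for (size_t k = 1; k < C.tracks[i].size(); ++k)
              m -= std::ldexp(1.0, link_bit[(long long)C.tracks[i][k - 1] *
                                                (C.N + 1) +
                                            C.tracks[i][k]]);
          for (const auto& tr : e.add)
            for (size_t k = 1; k < tr.size(); ++k)
              m += std::ldexp(1.0,
                              link_bit[(long long)tr[k - 1] * (C.N + 1) +
                                       tr[k]]);
        }
        p_mask[step] = m;
      }
      if (step == 0) {
        // expose the first proposal as an explicit partition
        List ptr(e.identity ? (int)C.tracks.size()
                            : (int)(C.tracks.size() - e.rm.size() +
                                    e.add.size()));
        int w = 0;
        std::set<int> rmset(e.rm.begin(), e.rm.end());
        for (size_t i = 0; i < C.tracks.size(); ++i) {
          if (!e.identity && rmset.count((int)i)) continue;
          IntegerVector tv((int)C.tracks[i].size());
          for (size_t u = 0; u < C.tracks[i].size(); ++u)
            tv[u] = C.tracks[i][u] + 1;
          ptr[w++] = tv;
        }
        if (!e.identity)
          for (const auto& tr : e.add) {
            IntegerVector tv((int)tr.size());
            for (size_t u = 0; u < tr.size(); ++u) tv[u] = tr[u] + 1;
            ptr[w++] = tv;
          }
        p_first = ptr;
      }
      continue;
    }
    if (e.identity) {
      move_stats(e.mtype, 1) += 1;
    } else {
      std::vector<double> add_ll;
      double delta = C.edit_delta(e, &add_ll);
      double logr = delta + e.lrev - e.lq;
      if (std::log(unif_rand()) < logr) {
        C.apply_edit(e, add_ll, delta);
        move_stats(e.mtype, 2) += 1;
      } else {
        move_stats(e.mtype, 0) += 1;
      }
    }
    if (record_mode == 2) {
      masks.push_back(current_mask());
    } else if (record_mode == 1 && record_every > 0 &&
               (int)records.size() < record_max) {
      if (until_record == 0) {
        records.push_back(C.tracks);
        until_record = record_every - 1;
      } else {
        --until_record;
      }
    }
  }

  arma::mat22 rsum(arma::fill::zeros);
  long rn = 0;
  if (!propose_only && C.N > 0) C.accumulate_residuals(rsum, rn);

  List rtracks((int)C.tracks.size());
  for (size_t i = 0; i < C.tracks.size(); ++i) {
    IntegerVector tv((int)C.tracks[i].size());
    for (size_t u = 0; u < C.tracks[i].size(); ++u) tv[u] = C.tracks[i][u] + 1;
    rtracks[i] = tv;
  }
  IntegerVector rclut((int)C.clutter.size());
  for (size_t i = 0; i < C.clutter.size(); ++i) rclut[i] = C.clutter[i] + 1;

  List rrec(records.size());
  for (size_t s = 0; s < records.size(); ++s) {
    List snap((int)records[s].size());
    for (size_t i = 0; i < records[s].size(); ++i) {
      IntegerVector tv((int)records[s][i].size());
      for (size_t u = 0; u < records[s][i].size(); ++u)
        tv[u] = records[s][i][u] + 1;
      snap[i] = tv;
    }
    rrec[s] = snap;
  }

  NumericVector tll((int)C.trll.size());
  for (size_t i = 0; i < C.trll.size(); ++i) tll[i] = C.trll[i];

  return List::create(
      _["tracks"] = rtracks, _["clutter"] = rclut,
      _["log_posterior_omega"] = C.cur_lp, _["track_logliks"] = tll,
      _["move_stats"] = move_stats, _["records"] = rrec,
      _["masks"] = NumericVector(masks.begin(), masks.end()),
      _["record_offset"] = until_record,
      _["resid_sum"] = NumericMatrix(2, 2, arma::mat(rsum).memptr()),
      _["resid_n"] = (double)rn,
      _["stats"] = List::create(
          _["n_births"] = IntegerVector(C.n_births.begin(), C.n_births.end()),
          _["n_clutter"] =
              IntegerVector(C.n_clutter.begin(), C.n_clutter.end()),
          _["n_observed"] = (double)C.n_observed,
          _["n_dark"] = (double)C.n_dark,
          _["n_survive"] = (double)C.n_survive,
          _["n_die"] = (double)C.n_die),
      _["prop_move"] = p_move, _["prop_identity"] = p_ident,
      _["prop_ged"] = p_ged, _["prop_log_q_fwd"] = p_lq,
      _["prop_log_q_rev"] = p_lrev, _["prop_mask"] = p_mask,
      _["prop_first"] = p_first);
}

// Multi-sweep Gibbs driver: alternates `steps_per_sweep` Metropolis-Hastings
// partition steps with one conjugate parameter draw per sweep, entirely in
// compiled code. All randomness flows from R's RNG. Optionally records
// thinned partition samples (record_mode 1) and always returns the
// parameter trace plus a trailing window of per-sweep link-key snapshots
// for the convergence diagnostics.
// [[Rcpp::export(name = ".bgl_gibbs")]]
List bgl_gibbs(IntegerVector obs_t, NumericVector obs_x, NumericVector obs_y,
               int n_frames_, NumericVector fov_, double area_unit,
               List tracks_, IntegerVector clutter_,
               List theta_, List model_, List cfg_,
               int n_sweeps, int steps_per_sweep,
               double prior_phi, double prior_dof,
               int record_every, int record_offset, int record_max,
               int snap_window) {
  Core C;
  setup_core(C, obs_t, obs_x, obs_y, n_frames_, fov_, area_unit, tracks_,
             clutter_, theta_, model_, cfg_);

  IntegerMatrix move_stats(9, 3);
  std::vector<std::vector<std::vector<int>>> records;
  std::deque<std::vector<double>> snaps;
  NumericMatrix theta_trace(n_sweeps, 7);
  int until_record = record_offset;
  int sweeps_done = 0;

  double exposure = (double)C.Tn * C.aratio;
  if (exposure <= 0) exposure = 1.0;

  for (int s = 0; s < n_sweeps; ++s) {
    // ---- partition sweep under the current theta ----
    for (int step = 0; step < steps_per_sweep; ++step) {
      Edit e = C.propose(-1);
      if (e.identity) {
        move_stats(e.mtype, 1) += 1;
      } else {
        std::vector<double> add_ll;
        double delta = C.edit_delta(e, &add_ll);
        double logr = delta + e.lrev - e.lq;
        if (std::log(unif_rand()) < logr) {
          C.apply_edit(e, add_ll, delta);
          move_stats(e.mtype, 2) += 1;
        } else {
          move_stats(e.mtype, 0) += 1;
        }
      }
      if (record_every > 0 && (int)records.size() < record_max) {
        if (until_record == 0) {
          records.push_back(C.tracks);
          until_record = record_every - 1;
        } else {
          --until_record;
        }
      }
    }

    // ---- conjugate parameter draw given the partition ----
    arma::mat22 rsum(arma::fill::zeros);
    long rn = 0;
    if (C.N > 0) C.accumulate_residuals(rsum, rn);
    long sb = 0, sc = 0;
    for (int f = 0; f < C.Tn; ++f) {
      sb += C.n_births[f];
      sc += C.n_clutter[f];
    }
    C.lb = R::rgamma((double)sb + 1.0, 1.0 / exposure);
    C.lc = R::rgamma((double)sc + 1.0, 1.0 / exposure);
    C.po = R::rbeta((double)C.n_observed + 1.0, (double)C.n_dark + 1.0);
    C.ps = R::rbeta((double)C.n_survive + 1.0, (double)C.n_die + 1.0);
    const double eps = 1e-12;
    C.po = std::min(std::max(C.po, eps), 1.0 - eps);
    C.ps = std::min(std::max(C.ps, eps), 1.0 - eps);
    // R ~ IW(Psi, nu) via the Bartlett decomposition of W(nu, Psi^{-1})
    double nu = prior_dof + (double)rn;
    double s00 = prior_phi + rsum(0, 0), s01 = rsum(0, 1),
           s11 = prior_phi + rsum(1, 1);
    double detp = s00 * s11 - s01 * s01;
    double g00 = s11 / detp, g01 = -s01 / detp, g11 = s00 / detp;
    double l00 = std::sqrt(g00);
    double l10 = g01 / l00;
    double l11 = std::sqrt(std::max(g11 - l10 * l10, 1e-300));
    double a11 = std::sqrt(R::rchisq(nu));
    double a21 = norm_rand();
    double a22 = std::sqrt(R::rchisq(nu - 1.0));
    // M = L A (both lower triangular); W = M M'
    double m00 = l00 * a11;
    double m10 = l10 * a11 + l11 * a21;
    double m11 = l11 * a22;
    double w00 = m00 * m00;
    double w01 = m00 * m10;
    double w11 = m10 * m10 + m11 * m11;
    double detw = w00 * w11 - w01 * w01;
    C.Robs = {{w11 / detw, -w01 / detw}, {-w01 / detw, w00 / detw}};

    theta_trace(s, 0) = C.lb;
    theta_trace(s, 1) = C.lc;
    theta_trace(s, 2) = C.po;
    theta_trace(s, 3) = C.ps;
    theta_trace(s, 4) = C.Robs(0, 0);
    theta_trace(s, 5) = C.Robs(0, 1);
    theta_trace(s, 6) = C.Robs(1, 1);

    // refresh cached likelihoods and the posterior under the new theta
    C.init_posterior();

    // per-sweep link-key snapshot for the convergence window
    std::vector<double> keys;
    for (const auto& tr : C.tracks)
      for (size_t k = 1; k < tr.size(); ++k)
        keys.push_back((double)(tr[k - 1] + 1) * (C.N + 1) +
                       (double)(tr[k] + 1));
    snaps.push_back(std::move(keys));
    if ((int)snaps.size() > snap_window) snaps.pop_front();

    sweeps_done = s + 1;
    if (record_every > 0 && (int)records.size() >= record_max) break;
  }

  List rtracks((int)C.tracks.size());
  for (size_t i = 0; i < C.tracks.size(); ++i) {
    IntegerVector tv((int)C.tracks[i].size());
    for (size_t u = 0; u < C.tracks[i].size(); ++u) tv[u] = C.tracks[i][u] + 1;
    rtracks[i] = tv;
  }
  IntegerVector rclut((int)C.clutter.size());
  for (size_t i = 0; i < C.clutter.size(); ++i) rclut[i] = C.clutter[i] + 1;

  List rrec((int)records.size());
  for (size_t s = 0; s < records.size(); ++s) {
    List snap((int)records[s].size());
    for (size_t i = 0; i < records[s].size(); ++i) {
      IntegerVector tv((int)records[s][i].size());
      for (size_t u = 0; u < records[s][i].size(); ++u)
        tv[u] = records[s][i][u] + 1;
      snap[i] = tv;
    }
    rrec[s] = snap;
  }

  List rsnaps((int)snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i)
    rsnaps[i] = NumericVector(snaps[i].begin(), snaps[i].end());

  NumericMatrix Rout(2, 2);
  Rout(0, 0) = C.Robs(0, 0);
  Rout(0, 1) = C.Robs(0, 1);
  Rout(1, 0) = C.Robs(1, 0);
  Rout(1, 1) = C.Robs(1, 1);

  return List::create(
      _["tracks"] = rtracks, _["clutter"] = rclut,
      _["theta"] = List::create(_["lambda_b"] = C.lb, _["lambda_c"] = C.lc,
                                _["p_o"] = C.po, _["p_s"] = C.ps,
                                _["R"] = Rout),
      _["theta_trace"] = theta_trace, _["move_stats"] = move_stats,
      _["snapshots"] = rsnaps, _["records"] = rrec,
      _["record_offset"] = until_record, _["sweeps_done"] = sweeps_done);
}
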