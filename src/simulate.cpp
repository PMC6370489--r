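#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Balloon-Windkessel state for one ROI: vasodilatory signal s, inflow f,
// volume v, deoxyhemoglobin q. Euler update at dt; returns BOLD observation.
struct Balloon {
  int n;
  std::vector<double> s, f, v, q;
  double kappa, gamma, tau, alpha, E0, V0, k1, k2, k3, ialpha;
  Balloon(int n_, const NumericVector& bp) : n(n_), s(n_, 0.0), f(n_, 1.0),
      v(n_, 1.0), q(n_, 1.0) {
    kappa = bp[0]; gamma = bp[1]; tau = bp[2]; alpha = bp[3];
    E0 = bp[4]; V0 = bp[5]; k1 = bp[6]; k2 = bp[7]; k3 = bp[8];
    ialpha = 1.0 / alpha;
  }
  // advance one step driven by x (length n); bold written in place
  void step(const double* x, double dt, double* bold, int step_idx) {
    for (int i = 0; i < n; ++i) {
      double fi = f[i];
      if (fi <= 1e-6)
        stop("balloon integration failure: inflow f <= 0 at ROI %d, step %d (dt too large?)",
             i + 1, step_idx);
      double fv = std::pow(v[i], ialpha);
      double E = 1.0 - std::pow(1.0 - E0, 1.0 / fi);
      double ds = x[i] - kappa * s[i] - gamma * (fi - 1.0);
      double df = s[i];
      double dv = (fi - fv) / tau;
      double dq = (fi * E / E0 - fv * q[i] / v[i]) / tau;
      s[i] += dt * ds;
      f[i] += dt * df;
      v[i] += dt * dv;
      q[i] += dt * dq;
      bold[i] = V0 * (k1 * (1.0 - q[i]) + k2 * (1.0 - q[i] / v[i]) +
                      k3 * (1.0 - v[i]));
    }
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_balloon(NumericMatrix x, double dt, NumericVector bp,
                          double gain) {
  int n = x.nrow(), T = x.ncol();
  Balloon bw(n, bp);
  NumericMatrix out(n, T);
  std::vector<double> drive(n), y(n);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) drive[i] = gain * x(i, t);
    bw.step(drive.data(), dt, y.data(), t + 1);
    for (int i = 0; i < n; ++i) out(i, t) = y[i];
  }
  return out;
}

// sparse adjacency: per target node, the contiguous range of incoming edges
// (source node, weight, delay in steps)
struct EdgeList {
  std::vector<int> start;           // n+1 offsets
  std::vector<int> src;
  std::vector<double> w;
  std::vector<int> dly;
  int max_delay;
  EdgeList(const NumericMatrix& C, const IntegerMatrix& dsteps) {
    int n = C.nrow();
    start.assign(n + 1, 0);
    max_delay = 0;
    for (int i = 0; i < n; ++i)
      for (int p = 0; p < n; ++p)
        if (C(p, i) != 0.0) ++start[i + 1];
    for (int i = 0; i < n; ++i) start[i + 1] += start[i];
    src.resize(start[n]);
    w.resize(start[n]);
    dly.resize(start[n]);
    std::vector<int> pos(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i)
      for (int p = 0; p < n; ++p)
        if (C(p, i) != 0.0) {
          int e = pos[i]++;
          src[e] = p;
          w[e] = C(p, i);
          dly[e] = dsteps(p, i);
          if (dly[e] > max_delay) max_delay = dly[e];
        }
  }
};

// Firing-rate model with pairwise conduction delays:
//   tau0 dr_n/dt = -r_n + (k/c1) sum_p C_np r_p(t - tau_np) + sigma n(t)
// Euler-Maruyama, noise sigma*sqrt(dt)*N(0,1) per step. Delayed states are
// read from a ring buffer of width max(delay)+1 initialized to the initial
// state (constant history).
// [[Rcpp::export]]
List cpp_sim_fr(NumericMatrix C, IntegerMatrix dsteps, double k, double c1,
                double tau0, double sigma, double dt, int total_steps,
                int discard_steps, NumericVector init, int thin,
                bool record_neural, bool record_bold, NumericVector bp,
                double gain) {
  int n = C.nrow();
  EdgeList el(C, dsteps);
  int B = el.max_delay + 1;
  std::vector<double> buf((size_t)n * B);
  for (int c = 0; c < B; ++c)
    for (int i = 0; i < n; ++i) buf[(size_t)c * n + i] = init[i];
  std::vector<double> r(init.begin(), init.end()), rnew(n);
  int n_rec = (total_steps - discard_steps) / thin;
  NumericMatrix neural, bold;
  if (record_neural) neural = NumericMatrix(n, n_rec);
  if (record_bold) bold = NumericMatrix(n, n_rec);
  Balloon bw(n, bp);
  std::vector<double> y(n), drive(n);
  double kc = k / c1, sq = sigma * std::sqrt(dt);
  int cur = 0, rec = 0;
  RNGScope scope;
  for (int step = 1; step <= total_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int e = el.start[i]; e < el.start[i + 1]; ++e) {
        int c = cur - el.dly[e];
        if (c < 0) c += B;
        acc += el.w[e] * buf[(size_t)c * n + el.src[e]];
      }
      double noise = (sigma > 0.0) ? sq * norm_rand() : 0.0;
      rnew[i] = r[i] + dt / tau0 * (-r[i] + kc * acc) + noise;
      if (!std::isfinite(rnew[i]))
        stop("integration failure: non-finite firing rate at ROI %d, step %d",
             i + 1, step);
    }
    cur = (cur + 1) % B;
    for (int i = 0; i < n; ++i) {
      r[i] = rnew[i];
      buf[(size_t)cur * n + i] = r[i];
    }
    if (step > discard_steps) {
      if (record_bold) {
        for (int i = 0; i < n; ++i) drive[i] = gain * r[i];
        bw.step(drive.data(), dt, y.data(), step);
      }
      if ((step - discard_steps) % thin == 0 && rec < n_rec) {
        if (record_neural)
          for (int i = 0; i < n; ++i) neural(i, rec) = r[i];
        if (record_bold)
          for (int i = 0; i < n; ++i) bold(i, rec) = y[i];
        ++rec;
      }
    }
  }
  List out = List::create(Named("n_rec") = rec);
  if (record_neural) out["neural"] = neural;
  if (record_bold) out["bold"] = bold;
  return out;
}

// Kuramoto model with pairwise conduction delays:
//   dtheta_n/dt = omega_n + k sum_p C_np sin(theta_p(t - tau_np) - theta_n)
// sin/cos of delayed phases kept in ring buffers so the coupling is two
// delayed gathers per pair (sin(a-b) expansion). Phases wrapped to [0, 2pi).
// [[Rcpp::export]]
List cpp_sim_km(NumericMatrix C, IntegerMatrix dsteps, double k,
                NumericVector omega, double sigma, double dt, int total_steps,
                int discard_steps, NumericVector init, int thin,
                bool record_neural, bool record_bold, NumericVector bp,
                double gain) {
  int n = C.nrow();
  const double TWOPI = 2.0 * M_PI;
  EdgeList el(C, dsteps);
  int B = el.max_delay + 1;
  std::vector<double> sbuf((size_t)n * B), cbuf((size_t)n * B);
  std::vector<double> th(init.begin(), init.end()), thnew(n), sth(n), cth(n);
  for (int i = 0; i < n; ++i) { sth[i] = std::sin(th[i]); cth[i] = std::cos(th[i]); }
  for (int c = 0; c < B; ++c)
    for (int i = 0; i < n; ++i) {
      sbuf[(size_t)c * n + i] = sth[i];
      cbuf[(size_t)c * n + i] = cth[i];
    }
  int n_rec = (total_steps - discard_steps) / thin;
  NumericMatrix neural, bold;
  if (record_neural) neural = NumericMatrix(n, n_rec);
  if (record_bold) bold = NumericMatrix(n, n_rec);
  Balloon bw(n, bp);
  std::vector<double> y(n), drive(n);
  double sq = sigma * std::sqrt(dt);
  int cur = 0, rec = 0;
  RNGScope scope;
  for (int step = 1; step <= total_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double accs = 0.0, accc = 0.0;
      for (int e = el.start[i]; e < el.start[i + 1]; ++e) {
        int c = cur - el.dly[e];
        if (c < 0) c += B;
        size_t at = (size_t)c * n + el.src[e];
        accs += el.w[e] * sbuf[at];
        accc += el.w[e] * cbuf[at];
      }
      // sum_p C_np sin(theta_p(t-tau) - theta_n)
      double coup = cth[i] * accs - sth[i] * accc;
      double noise = (sigma > 0.0) ? sq * norm_rand() : 0.0;
      double t2 = th[i] + dt * (omega[i] + k * coup) + noise;
      if (!std::isfinite(t2))
        stop("integration failure: non-finite phase at ROI %d, step %d",
             i + 1, step);
      t2 -= TWOPI * std::floor(t2 / TWOPI); // wrap to [0, 2pi)
      thnew[i] = t2;
    }
    cur = (cur + 1) % B;
    for (int i = 0; i < n; ++i) {
      th[i] = thnew[i];
      sth[i] = std::sin(th[i]);
      cth[i] = std::cos(th[i]);
      sbuf[(size_t)cur * n + i] = sth[i];
      cbuf[(size_t)cur * n + i] = cth[i];
    }
    if (step > discard_steps) {
      if (record_bold) {
        for (int i = 0; i < n; ++i) drive[i] = gain * sth[i];
        bw.step(drive.data(), dt, y.data(), step);
      }
      if ((step - discard_steps) % thin == 0 && rec < n_rec) {
        if (record_neural)
          for (int i = 0; i < n; ++i) neural(i, rec) = th[i];
        if (record_bold)
          for (int i = 0; i < n; ++i) bold(i, rec) = y[i];
        ++rec;
      }
    }
  }
  List out = List::create(Named("n_rec") = rec);
  if (record_neural) out["neural"] = neural;
  if (record_bold) out["bold"] = bold;
  return out;
}

// k-means with Manhattan (L1) distance and componentwise-median centroid
// updates; best of the supplied initializations (rows of init_idx are
// 1-based row indices into X) by total within-cluster L1 distance.
// [[Rcpp::export]]
List cpp_kmeans_l1(NumericMatrix X, int k, int max_iter,
                   IntegerMatrix init_idx) {
  int m = X.nrow(), d = X.ncol(), n_init = init_idx.nrow();
  // row-major copy so each observation is contiguous
  std::vector<double> xt((size_t)m * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < m; ++i) xt[(size_t)i * d + j] = X(i, j);
  std::vector<double> best_centers;
  std::vector<int> best_labels;
  double best_inertia = R_PosInf;
  int best_iters = 0;
  std::vector<double> centers((size_t)k * d), newc((size_t)k * d);
  std::vector<int> labels(m), counts(k);
  std::vector<double> gather;
  std::vector<int> members;
  for (int ini = 0; ini < n_init; ++ini) {
    for (int c = 0; c < k; ++c) {
      int r = init_idx(ini, c) - 1;
      for (int j = 0; j < d; ++j)
        centers[(size_t)c * d + j] = xt[(size_t)r * d + j];
    }
    int it = 0;
    bool changed = true;
    double inertia = 0.0;
    std::fill(labels.begin(), labels.end(), -1);
    while (changed && it < max_iter) {
      changed = false;
      inertia = 0.0;
      std::fill(counts.begin(), counts.end(), 0);
      for (int i = 0; i < m; ++i) {
        const double* xi = &xt[(size_t)i * d];
        double bestd = R_PosInf;
        int bestc = 0;
        for (int c = 0; c < k; ++c) {
          double dist = 0.0;
          const double* cc = &centers[(size_t)c * d];
          for (int j = 0; j < d; ++j) {
            dist += std::fabs(xi[j] - cc[j]);
            if (dist >= bestd) break;
          }
          if (dist < bestd) { bestd = dist; bestc = c; }
        }
        if (labels[i] != bestc) { labels[i] = bestc; changed = true; }
        counts[bestc]++;
        inertia += bestd;
      }
      // empty cluster: seize the point farthest (L1) from its centroid
      for (int c = 0; c < k; ++c) {
        if (counts[c] == 0) {
          double worst = -1.0;
          int wi = 0;
          for (int i = 0; i < m; ++i) {
            if (counts[labels[i]] <= 1) continue;
            double dist = 0.0;
            const double* cc = &centers[(size_t)labels[i] * d];
            const double* xi = &xt[(size_t)i * d];
            for (int j = 0; j < d; ++j) dist += std::fabs(xi[j] - cc[j]);
            if (dist > worst) { worst = dist; wi = i; }
          }
          counts[labels[wi]]--;
          labels[wi] = c;
          counts[c] = 1;
          changed = true;
        }
      }
      // median update: gather each cluster into a dim-major block so every
      // nth_element works on contiguous memory
      for (int c = 0; c < k; ++c) {
        members.clear();
        for (int i = 0; i < m; ++i)
          if (labels[i] == c) members.push_back(i);
        size_t sz = members.size();
        gather.assign(sz * (size_t)d, 0.0);
        for (size_t p = 0; p < sz; ++p) {
          const double* xi = &xt[(size_t)members[p] * d];
          for (int j = 0; j < d; ++j) gather[(size_t)j * sz + p] = xi[j];
        }
        size_t h = sz / 2;
        for (int j = 0; j < d; ++j) {
          double* col = &gather[(size_t)j * sz];
          std::nth_element(col, col + h, col + sz);
          double med = col[h];
          if (sz % 2 == 0) {
            std::nth_element(col, col + h - 1, col + h);
            med = 0.5 * (med + col[h - 1]);
          }
          newc[(size_t)c * d + j] = med;
        }
      }
      centers.swap(newc);
      ++it;
    }
    // final inertia under final centers
    inertia = 0.0;
    for (int i = 0; i < m; ++i) {
      double dist = 0.0;
      const double* cc = &centers[(size_t)labels[i] * d];
      const double* xi = &xt[(size_t)i * d];
      for (int j = 0; j < d; ++j) dist += std::fabs(xi[j] - cc[j]);
      inertia += dist;
    }
    if (inertia < best_inertia) {
      best_inertia = inertia;
      best_centers = centers;
      best_labels = labels;
      best_iters = it;
    }
  }
  NumericMatrix cen(k, d);
  for (int c = 0; c < k; ++c)
    for (int j = 0; j < d; ++j) cen(c, j) = best_centers[(size_t)c * d + j];
  IntegerVector lab(m);
  for (int i = 0; i < m; ++i) lab[i] = best_labels[i] + 1;
  return List::create(Named("centers") = cen, Named("labels") = lab,
                      Named("inertia") = best_inertia,
                      Named("iterations") = best_iters);
}
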