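// Compiled kernels: DPSS taper computation via the Slepian tridiagonal
// eigenproblem (LAPACK dstebz/dstein), and Euler-Maruyama integration of the
// delayed corticothalamic rate equations.
#include <Rcpp.h>
#define USE_FC_LEN_T
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// top m eigenpairs of a symmetric tridiagonal matrix (descending order)
static void top_eigs_tridiag(std::vector<double>& d, std::vector<double>& e,
                             int m, std::vector<double>& vals,
                             std::vector<std::vector<double> >& vecs) {
  int n = (int)d.size();
  if (m > n) stop("internal: too many eigenpairs requested");
  int il = n - m + 1, iu = n, found = 0, nsplit = 0, info = 0;
  double vl = 0, vu = 0, abstol = 0;
  std::vector<double> wv(n), work(4 * n);
  std::vector<int> iblock(n), isplit(n), iwork(3 * n);
  F77_CALL(dstebz)("I", "B", &n, &vl, &vu, &il, &iu, &abstol, d.data(),
                   e.data(), &found, &nsplit, wv.data(), iblock.data(),
                   isplit.data(), work.data(), iwork.data(), &info FCONE FCONE);
  if (info != 0 || found != m) stop("tridiagonal eigenvalue computation failed");
  std::vector<double> z((size_t)n * m), work2(5 * n);
  std::vector<int> iwork2(n), ifail(m);
  F77_CALL(dstein)(&n, d.data(), e.data(), &found, wv.data(), iblock.data(),
                   isplit.data(), z.data(), &n, work2.data(), iwork2.data(),
                   ifail.data(), &info);
  if (info != 0) stop("tridiagonal eigenvector computation failed");
  vals.resize(m);
  vecs.assign(m, std::vector<double>(n));
  for (int j = 0; j < m; ++j) {   // reverse into descending order
    int src = m - 1 - j;
    vals[j] = wv[src];
    for (int t = 0; t < n; ++t) vecs[j][t] = z[(size_t)src * n + t];
  }
}

// First k discrete prolate spheroidal sequences of length n at
// time-half-bandwidth product nw, as columns in decreasing concentration
// order, each unit-norm with positive polarity (positive mean, or positive
// leading lobe for the antisymmetric tapers). Uses the Slepian tridiagonal
// formulation. Because the tridiagonal matrix is persymmetric its spectrum
// splits into symmetric and antisymmetric halves that become degenerate to
// machine precision at large n; the problem is therefore folded into two
// half-size problems (where eigenvalues are well separated) and the
// eigenvectors unfolded, which keeps inverse iteration well conditioned for
// epoch lengths in the 10^5-10^6 sample range.
// [[Rcpp::export]]
NumericMatrix dpss_tapers_cpp(int n, double nw, int k) {
  if (n < 2 || k < 1 || k > n) stop("invalid DPSS request");
  std::vector<double> d(n), e(n - 1);
  double w = nw / n, c = std::cos(2.0 * M_PI * w);
  for (int t = 0; t < n; ++t) {
    double h = (n - 1 - 2.0 * t) / 2.0;
    d[t] = h * h * c;
  }
  for (int t = 1; t < n; ++t)
    e[t - 1] = (double)t * ((double)n - t) / 2.0;
  int m = n / 2;
  bool odd = (n % 2 == 1);
  // symmetric (even-about-midpoint) half problem
  int ns = odd ? m + 1 : m;
  std::vector<double> ds(d.begin(), d.begin() + ns);
  std::vector<double> es(e.begin(), e.begin() + (ns - 1));
  if (odd) {
    es[ns - 2] = std::sqrt(2.0) * e[m - 1];  // similarity-scaled middle link
  } else {
    ds[ns - 1] += e[m - 1];                  // v[m] = v[m-1]
  }
  // antisymmetric half problem
  int na = m;
  std::vector<double> da(d.begin(), d.begin() + na);
  std::vector<double> ea(e.begin(), e.begin() + (na - 1));
  if (!odd) da[na - 1] -= e[m - 1];          // v[m] = -v[m-1]
  int k_s = (k + 2) / 2, k_a = (k + 1) / 2;  // enough of each parity
  std::vector<double> val_s, val_a;
  std::vector<std::vector<double> > vec_s, vec_a;
  top_eigs_tridiag(ds, es, std::min(k_s, ns), val_s, vec_s);
  top_eigs_tridiag(da, ea, std::min(k_a, na), val_a, vec_a);
  NumericMatrix out(n, k);
  const double inv_sqrt2 = 1.0 / std::sqrt(2.0);
  int is = 0, ia = 0;
  for (int j = 0; j < k; ++j) {
    bool take_sym;
    if (is < (int)val_s.size() && ia < (int)val_a.size())
      take_sym = val_s[is] >= val_a[ia];
    else take_sym = is < (int)val_s.size();
    if (take_sym) {
      const std::vector<double>& u = vec_s[is++];
      if (odd) {
        for (int t = 0; t < m; ++t) out(t, j) = u[t] * inv_sqrt2;
        out(m, j) = u[m];                     // undo similarity scaling
        for (int t = 0; t < m; ++t) out(n - 1 - t, j) = u[t] * inv_sqrt2;
        // renormalize: ||(u_0..u_{m-1}, sqrt(2) u_m)|| = 1 already in
        // half-problem coordinates => full vector norm is 1 by construction
      } else {
        for (int t = 0; t < m; ++t) {
          out(t, j) = u[t] * inv_sqrt2;
          out(n - 1 - t, j) = u[t] * inv_sqrt2;
        }
      }
      double s = 0;
      for (int t = 0; t < n; ++t) s += out(t, j);
      if (s < 0) for (int t = 0; t < n; ++t) out(t, j) = -out(t, j);
    } else {
      const std::vector<double>& u = vec_a[ia++];
      for (int t = 0; t < m; ++t) {
        out(t, j) = u[t] * inv_sqrt2;
        out(n - 1 - t, j) = -u[t] * inv_sqrt2;
      }
      if (odd) out(m, j) = 0.0;
      // polarity: positive first major lobe
      double mx = 0.0;
      for (int t = 0; t < m; ++t)
        if (std::fabs(out(t, j)) > std::fabs(mx)) mx = out(t, j);
      if (mx < 0) for (int t = 0; t < n; ++t) out(t, j) = -out(t, j);
    }
  }
  return out;
}

static inline double sigmoid_rate(double v, double qmax, double theta,
                                  double sigma) {
  return qmax / (1.0 + std::exp(-M_PI * (v - theta) / (sigma * std::sqrt(3.0))));
}

// Euler-Maruyama integration of the four-population corticothalamic model
// (global mode). Couplings in order: ee, ei, es, se, sr, sn, re, rs. The
// inhibitory cortical population receives the same afferents as the
// excitatory one (random-connectivity assumption). Delay of n_delay steps on
// the e->{r,s} and s->{e,i} projections. Noise (per-sample sd) drives the
// relay through nu_sn. Uses R's RNG, so set.seed() upstream gives
// reproducible paths.
// [[Rcpp::export]]
List simulate_ct_cpp(NumericVector nu, double qmax, double theta, double sigma,
                     double alpha, double beta, double gamma, double dt,
                     int n_steps, int n_delay, double noise_mean,
                     double noise_sd, NumericVector v0, double phi_e0,
                     double q_s0, int keep_from, bool keep_all,
                     double guard) {
  const double nu_ee = nu[0], nu_ei = nu[1], nu_es = nu[2], nu_se = nu[3],
               nu_sr = nu[4], nu_sn = nu[5], nu_re = nu[6], nu_rs = nu[7];
  double Ve = v0[0], Vi = v0[1], Vr = v0[2], Vs = v0[3];
  double We = 0, Wi = 0, Wr = 0, Ws = 0;       // dV/dt states
  double phie = phi_e0, Pe = 0;                 // wave states
  std::vector<double> buf_e(n_delay, phi_e0), buf_s(n_delay, q_s0);
  int pos = 0;
  const int n_keep = n_steps - keep_from;
  NumericVector tr_ve(n_keep), tr_phie(n_keep);
  NumericVector tr_vi, tr_vr, tr_vs;
  if (keep_all) {
    tr_vi = NumericVector(n_keep);
    tr_vr = NumericVector(n_keep);
    tr_vs = NumericVector(n_keep);
  }
  const double ab = alpha * beta, apb = alpha + beta, g2 = gamma * gamma;
  bool diverged = false;
  NumericVector noise = rnorm(n_steps, noise_mean, noise_sd);
  for (int t = 0; t < n_steps; ++t) {
    double phie_d = buf_e[pos], qs_d = buf_s[pos];
    double Qe = sigmoid_rate(Ve, qmax, theta, sigma);
    double Qi = sigmoid_rate(Vi, qmax, theta, sigma);
    double Qr = sigmoid_rate(Vr, qmax, theta, sigma);
    double Qs = sigmoid_rate(Vs, qmax, theta, sigma);
    buf_e[pos] = phie;
    buf_s[pos] = Qs;
    pos = (pos + 1) % n_delay;
    double u_e = nu_ee * phie + nu_ei * Qi + nu_es * qs_d;
    double u_i = u_e;
    double u_r = nu_re * phie_d + nu_rs * Qs;
    double u_s = nu_se * phie_d + nu_sr * Qr + nu_sn * noise[t];
    if (t >= keep_from) {
      int j = t - keep_from;
      tr_ve[j] = Ve;
      tr_phie[j] = phie;
      if (keep_all) {
        tr_vi[j] = Vi;
        tr_vr[j] = Vr;
        tr_vs[j] = Vs;
      }
    }
    double We_n = We + dt * (ab * (u_e - Ve) - apb * We);
    double Wi_n = Wi + dt * (ab * (u_i - Vi) - apb * Wi);
    double Wr_n = Wr + dt * (ab * (u_r - Vr) - apb * Wr);
    double Ws_n = Ws + dt * (ab * (u_s - Vs) - apb * Ws);
    double Pe_n = Pe + dt * (g2 * (Qe - phie) - 2.0 * gamma * Pe);
    Ve += dt * We; Vi += dt * Wi; Vr += dt * Wr; Vs += dt * Ws;
    phie += dt * Pe;
    We = We_n; Wi = Wi_n; Wr = Wr_n; Ws = Ws_n; Pe = Pe_n;
    if (!(std::fabs(Ve) < guard) || !(std::fabs(Vs) < guard) ||
        !(std::fabs(Vr) < guard) || !(std::fabs(phie) < guard)) {
      diverged = true;
      break;
    }
  }
  List out = List::create(_["v_e"] = tr_ve, _["phi_e"] = tr_phie,
                          _["diverged"] = diverged);
  if (keep_all) {
    out["v_i"] = tr_vi;
    out["v_r"] = tr_vr;
    out["v_s"] = tr_vs;
  }
  return out;
}
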