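#include <Rcpp.h>
using namespace Rcpp;

// Single-accumulator first-passage machinery for the linear ballistic
// accumulator: start point ~ U(0, A), drift ~ N(v, sv) truncated below at 0,
// threshold b.  Closed forms are the classic untruncated expressions divided
// by P(drift > 0) = pnorm(v / sv), so each node's finishing-time density
// integrates to one.

static const double INV_SQRT_2PI = 0.3989422804014327;

static inline double phi(double z) { return INV_SQRT_2PI * std::exp(-0.5 * z * z); }
static inline double Phi(double z) { return 0.5 * std::erfc(-z * M_SQRT1_2); }

static inline double trunc_mass(double v, double sv) { return Phi(v / sv); }

// untruncated-density kernels; callers divide by trunc_mass(v, sv)
static double node_pdf_raw(double t, double A, double b, double v, double sv) {
  if (t <= 0.0) return 0.0;
  const double ts = t * sv;
  double out;
  if (A < 1e-10) {
    // degenerate start point at 0: b / d <= t  <=>  d >= b / t
    out = (b / (t * ts)) * phi((b - t * v) / ts);
  } else {
    const double z1 = (b - A - t * v) / ts;
    const double z2 = (b - t * v) / ts;
    out = (-v * Phi(z1) + sv * phi(z1) + v * Phi(z2) - sv * phi(z2)) / A;
  }
  return out > 0.0 ? out : 0.0;
}

static double node_cdf_raw(double t, double A, double b, double v, double sv) {
  if (t <= 0.0) return 0.0;
  const double ts = t * sv;
  double out;
  if (A < 1e-10) {
    out = Phi((t * v - b) / ts);
  } else {
    const double z1 = (b - A - t * v) / ts;
    const double z2 = (b - t * v) / ts;
    out = 1.0 + ((b - A - t * v) / A) * Phi(z1)
              - ((b - t * v) / A) * Phi(z2)
              + (ts / A) * (phi(z1) - phi(z2));
  }
  return out > 0.0 ? out : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_node_density(NumericVector t, double A, double b,
                               double v, double sv) {
  const int n = t.size();
  const double im = 1.0 / trunc_mass(v, sv);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = node_pdf_raw(t[i], A, b, v, sv) * im;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_node_cdf(NumericVector t, double A, double b,
                           double v, double sv) {
  const int n = t.size();
  const double im = 1.0 / trunc_mass(v, sv);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p = node_cdf_raw(t[i], A, b, v, sv) * im;
    out[i] = p > 1.0 ? 1.0 : p;
  }
  return out;
}

// one condition's parameters with precomputed truncation normalizers
struct CondPar {
  double v_c, v_e, sv_c, sv_e, A, b, t0, im_c, im_e;
  void set(const double *p) {
    v_c = p[0]; v_e = p[1]; sv_c = p[2]; sv_e = p[3];
    A = p[4]; b = p[5]; t0 = p[6];
    im_c = 1.0 / trunc_mass(v_c, sv_c);
    im_e = 1.0 / trunc_mass(v_e, sv_e);
  }
};

// defective density of one trial: winner's density times loser's survivor,
// floored before the log so single outlier trials cannot yield -Inf
static inline double trial_logdens(double rt, int correct, const CondPar &cp,
                                   double floor_dens) {
  const double t = rt - cp.t0;
  double dens = 0.0;
  if (t > 0.0) {
    if (correct) {
      double surv = 1.0 - node_cdf_raw(t, cp.A, cp.b, cp.v_e, cp.sv_e) * cp.im_e;
      if (surv < 0.0) surv = 0.0;
      dens = node_pdf_raw(t, cp.A, cp.b, cp.v_c, cp.sv_c) * cp.im_c * surv;
    } else {
      double surv = 1.0 - node_cdf_raw(t, cp.A, cp.b, cp.v_c, cp.sv_c) * cp.im_c;
      if (surv < 0.0) surv = 0.0;
      dens = node_pdf_raw(t, cp.A, cp.b, cp.v_e, cp.sv_e) * cp.im_e * surv;
    }
  }
  if (!(dens > floor_dens)) dens = floor_dens;
  return std::log(dens);
}

// [[Rcpp::export]]
NumericVector cpp_lba_loglik(NumericVector rt, IntegerVector correct,
                             IntegerVector cond, NumericMatrix par1,
                             NumericMatrix par2, double floor_dens) {
  const int n = rt.size(), m = par1.nrow();
  NumericVector out(m);
  double row[7];
  CondPar c1, c2;
  for (int j = 0; j < m; ++j) {
    for (int c = 0; c < 7; ++c) row[c] = par1(j, c);
    c1.set(row);
    for (int c = 0; c < 7; ++c) row[c] = par2(j, c);
    c2.set(row);
    double ll = 0.0;
    for (int i = 0; i < n; ++i)
      ll += trial_logdens(rt[i], correct[i], cond[i] == 1 ? c1 : c2,
                          floor_dens);
    out[j] = ll;
  }
  return out;
}

// per-draw x per-trial log-likelihood matrix (for WAIC)
// [[Rcpp::export]]
NumericMatrix cpp_lba_trial_loglik(NumericVector rt, IntegerVector correct,
                                   IntegerVector cond, NumericMatrix par1,
                                   NumericMatrix par2, double floor_dens) {
  const int n = rt.size(), m = par1.nrow();
  NumericMatrix out(m, n);
  double row[7];
  CondPar c1, c2;
  for (int j = 0; j < m; ++j) {
    for (int c = 0; c < 7; ++c) row[c] = par1(j, c);
    c1.set(row);
    for (int c = 0; c < 7; ++c) row[c] = par2(j, c);
    c2.set(row);
    for (int i = 0; i < n; ++i)
      out(j, i) = trial_logdens(rt[i], correct[i], cond[i] == 1 ? c1 : c2,
                                floor_dens);
  }
  return out;
}

// inverse-CDF draw from N(v, sv) truncated below at 0; uses R's RNG stream
static inline double rtnorm_pos(double v, double sv) {
  const double lo = R::pnorm(-v / sv, 0.0, 1.0, 1, 0);
  double u = lo + unif_rand() * (1.0 - lo);
  if (u >= 1.0) u = 1.0 - 1e-16;
  return v + sv * R::qnorm(u, 0.0, 1.0, 1, 0);
}

// simulate n race trials; returns rt and correctness indicator
// [[Rcpp::export]]
List cpp_simulate_lba(int n, double v_c, double v_e, double sv_c, double sv_e,
                      double A, double b, double t0) {
  NumericVector rt(n);
  IntegerVector correct(n);
  for (int i = 0; i < n; ++i) {
    const double dc = rtnorm_pos(v_c, sv_c);
    const double de = rtnorm_pos(v_e, sv_e);
    const double tc = (b - A * unif_rand()) / dc;
    const double te = (b - A * unif_rand()) / de;
    if (tc <= te) { rt[i] = t0 + tc; correct[i] = 1; }
    else          { rt[i] = t0 + te; correct[i] = 0; }
  }
  return List::create(_["rt"] = rt, _["correct"] = correct);
}
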