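#include <Rcpp.h>
#include <cmath>
#include <cfloat>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Scalar sampling primitives.  These are the single source of truth: the
// vectorised R-level samplers and both simulators call the same inline code.
// ---------------------------------------------------------------------------

static inline double safe_uniform() {
  double u = unif_rand();
  if (u <= 0.0) u = DBL_MIN;          // guard against -log(0)
  if (u >= 1.0) u = 1.0 - DBL_EPSILON;
  return u;
}

static inline double free_path(double mus, double u) {
  return -std::log(u) / mus;
}

// Henyey-Greenstein inverse CDF for the scattering cosine.
static inline double hg_cosine(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Rayleigh scattering cosine: CDF F(mu) = (3 mu + mu^3 + 4)/8 inverted in
// closed form (Cardano).  The depressed cubic mu^3 + 3 mu - 2w = 0 with
// w = 4u - 2 has discriminant w^2 + 1 >= 1, hence a single real root and a
// numerically safe closed form.
static inline double rayleigh_cosine(double u) {
  double w = 4.0 * u - 2.0;
  double r = std::sqrt(w * w + 1.0);
  double mu = std::cbrt(w + r) + std::cbrt(w - r);
  if (mu > 1.0) mu = 1.0;
  if (mu < -1.0) mu = -1.0;
  return mu;
}

// Rotate a unit direction by polar cosine ct and azimuth phi about itself.
// Degenerate branch when the direction is within 1e-12 of +/- z.
static inline void rotate_direction(double &ux, double &uy, double &uz,
                                    double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 1.0 - 1e-12) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0.0) ? ct : -ct;
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double n2 = ux * ux + uy * uy + uz * uz;
  if (std::fabs(n2 - 1.0) > 1e-12) {
    double inv = 1.0 / std::sqrt(n2);
    ux *= inv; uy *= inv; uz *= inv;
  }
}

// Unpolarised Fresnel reflectance for incidence cosine cos_i, indices
// ni -> nt.  Returns 1 under total internal reflection.
static inline double fresnel_R(double ni, double nt, double cos_i) {
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = ni / nt * sin_i;
  if (sin_t >= 1.0) return 1.0;
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (ni * cos_i - nt * cos_t) / (ni * cos_i + nt * cos_t);
  double rp = (nt * cos_i - ni * cos_t) / (nt * cos_i + ni * cos_t);
  return 0.5 * (rs * rs + rp * rp);
}

// ---------------------------------------------------------------------------
// Vectorised exports used by the R-level sampling API and its tests.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_free_path(double mus, NumericVector u) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = free_path(mus, u[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hg_cosine(double g, NumericVector u) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cosine(g, u[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rayleigh_cosine(NumericVector u) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rayleigh_cosine(u[i]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_scatter_direction(NumericMatrix dir, NumericVector ct,
                                    NumericVector phi) {
  int n = dir.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double ux = dir(i, 0), uy = dir(i, 1), uz = dir(i, 2);
    rotate_direction(ux, uy, uz, ct[i], phi[i]);
    out(i, 0) = ux; out(i, 1) = uy; out(i, 2) = uz;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fresnel(double ni, double nt, NumericVector cos_i) {
  int n = cos_i.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fresnel_R(ni, nt, cos_i[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Step 1: pencil beam at the origin of an infinite non-absorbing medium;
// per-order tallies of the event coordinates and cumulative path lengths.
// Quantities, in row order: x, y, z, x^2, y^2, z^2, rho^2, d^2, l, l^2.
// ---------------------------------------------------------------------------

// phase_kind: 0 = HG, 1 = Rayleigh.
// defect: 0 none, 1 = HG asymmetry biased by +0.005 (verification fixture).

// [[Rcpp::export]]
List cpp_run_step1(double n_photons, int k_max, double mus, int phase_kind,
                   double g, int defect) {
  const int NQ = 10;
  double g_eff = (defect == 1) ? g + 0.005 : g;
  std::vector<double> sum(NQ * k_max, 0.0), ssq(NQ * k_max, 0.0);
  std::vector<double> csum(NQ * k_max, 0.0), cssq(NQ * k_max, 0.0);
  const double CHUNK = 65536.0;  // pairwise-ish accumulation for long runs
  double in_chunk = 0.0;
  double N = n_photons;
  for (double i = 0.0; i < N; i += 1.0) {
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double x = 0.0, y = 0.0, z = 0.0, l = 0.0;
    for (int k = 0; k < k_max; ++k) {
      double step = free_path(mus, safe_uniform());
      x += ux * step; y += uy * step; z += uz * step; l += step;
      double x2 = x * x, y2 = y * y, z2 = z * z;
      double rho2 = x2 + y2, d2 = rho2 + z2, l2 = l * l;
      double q[NQ] = {x, y, z, x2, y2, z2, rho2, d2, l, l2};
      double *cs = &csum[(size_t)NQ * k], *cq = &cssq[(size_t)NQ * k];
      for (int j = 0; j < NQ; ++j) {
        cs[j] += q[j];
        cq[j] += q[j] * q[j];
      }
      if (k + 1 < k_max) {
        double ct = (phase_kind == 1) ? rayleigh_cosine(safe_uniform())
                                      : hg_cosine(g_eff, safe_uniform());
        double phi = 2.0 * M_PI * safe_uniform();
        rotate_direction(ux, uy, uz, ct, phi);
      }
    }
    if (++in_chunk >= CHUNK) {
      for (size_t j = 0; j < sum.size(); ++j) {
        sum[j] += csum[j]; csum[j] = 0.0;
        ssq[j] += cssq[j]; cssq[j] = 0.0;
      }
      in_chunk = 0.0;
    }
  }
  for (size_t j = 0; j < sum.size(); ++j) {
    sum[j] += csum[j];
    ssq[j] += cssq[j];
  }
  NumericMatrix S(NQ, k_max), Q(NQ, k_max);
  for (int k = 0; k < k_max; ++k)
    for (int j = 0; j < NQ; ++j) {
      S(j, k) = sum[(size_t)NQ * k + j];
      Q(j, k) = ssq[(size_t)NQ * k + j];
    }
  return List::create(_["sum"] = S, _["sumsq"] = Q, _["n"] = n_photons);
}

// ---------------------------------------------------------------------------
// Step 2: laterally infinite layered slab, Lambertian illumination realised
// by reciprocity as alternating-face cosine-weighted point injection.
// Track-length tallies per layer (path lengths) and per (layer, theta bin)
// (radiance); per-photon reduction gives exact standard errors.
// ---------------------------------------------------------------------------

// defect: 0 none, 2 = index order swapped inside the reflectance formula
// (reflectance evaluated for nt -> ni while refraction stays correct, a
// reciprocity-breaking bug), 3 = missing total-internal-reflection branch
// (transmits undeviated).  Synthetic-bug fixtures for sensitivity tests.

static inline double fresnel_R_defect(double ni, double nt, double cos_i,
                                      int defect, bool &tir) {
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = ni / nt * sin_i;
  tir = (sin_t >= 1.0);
  if (tir && defect != 2) return (defect == 3) ? 0.0 : 1.0;
  if (defect == 2) return fresnel_R(nt, ni, cos_i);
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (ni * cos_i - nt * cos_t) / (ni * cos_i + nt * cos_t);
  double rp = (nt * cos_i - ni * cos_t) / (nt * cos_i + ni * cos_t);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
List cpp_run_step2(double n_photons, NumericVector s, NumericVector n_layer,
                   NumericVector mus, IntegerVector phase_kind,
                   NumericVector g, double ne, int n_bins, int defect,
                   double event_cap) {
  int M = s.size();
  int B = n_bins;
  std::vector<double> zb(M + 1, 0.0);
  for (int j = 0; j < M; ++j) zb[j + 1] = zb[j] + s[j];

  std::vector<double> L_sum(M, 0.0), L_ssq(M, 0.0);
  std::vector<double> R_sum((size_t)M * B, 0.0), R_ssq((size_t)M * B, 0.0);
  // per-photon scratch
  std::vector<double> Lp(M, 0.0);
  std::vector<int> Ltouch; Ltouch.reserve(M);
  std::vector<double> Rp((size_t)M * B, 0.0);
  std::vector<int> Rtouch; Rtouch.reserve(256);

  double n_refl = 0.0, n_trans = 0.0, n_abort = 0.0;
  double Lt_sum = 0.0, Lt_ssq = 0.0;
  double N = n_photons;

  for (double i = 0.0; i < N; i += 1.0) {
    int parity = ((long long)i) & 1;  // 0: inject at z = 0, 1: at z = Z
    // cosine-weighted external direction, Fresnel entry
    double cos_e = std::sqrt(safe_uniform());
    int j0 = parity ? M - 1 : 0;
    bool tir;
    double Rentry = fresnel_R_defect(ne, n_layer[j0], cos_e, defect, tir);
    bool inside = (unif_rand() >= Rentry);
    if (!inside) {
      // specular entry rejection: zero internal path, still counted in N
      if (parity == 0) n_refl += 1.0; else n_trans += 1.0;
    }
    if (inside) {
      double sin_e = std::sqrt(std::max(0.0, 1.0 - cos_e * cos_e));
      double sin_t, cos_t;
      if (tir && defect == 3) {  // missing-TIR fixture: enter undeviated
        sin_t = sin_e; cos_t = cos_e;
      } else {
        sin_t = ne / n_layer[j0] * sin_e;
        cos_t = std::sqrt(std::max(0.0, 1.0 - sin_t * sin_t));
      }
      double phi = 2.0 * M_PI * safe_uniform();
      double ux = sin_t * std::cos(phi), uy = sin_t * std::sin(phi);
      double uz = parity ? -cos_t : cos_t;
      double z = parity ? zb[M] : 0.0;
      int j = j0;
      double tau = -std::log(safe_uniform());  // residual optical depth
      double events = 0.0;
      bool alive = true;
      while (alive) {
        if (++events > event_cap) { n_abort += 1.0; alive = false; break; }
        double d_scat = (mus[j] > 0.0) ? tau / mus[j] : R_PosInf;
        double d_bound;
        if (uz > 0.0) d_bound = (zb[j + 1] - z) / uz;
        else if (uz < 0.0) d_bound = (zb[j] - z) / uz;
        else d_bound = R_PosInf;
        double seg = (d_scat < d_bound) ? d_scat : d_bound;
        if (!(seg < R_PosInf)) {  // stuck (uz = 0 in a void layer): abort
          n_abort += 1.0; alive = false; break;
        }
        // tally the segment
        if (seg > 0.0) {
          if (Lp[j] == 0.0) Ltouch.push_back(j);
          Lp[j] += seg;
          double th = std::acos(std::max(-1.0, std::min(1.0, uz)));
          int b = (int)(th / M_PI * B);
          if (b >= B) b = B - 1;
          size_t idx = (size_t)j * B + b;
          if (Rp[idx] == 0.0) Rtouch.push_back((int)idx);
          Rp[idx] += seg;
        }
        if (d_scat < d_bound) {
          z += uz * d_scat;
          double ct = (phase_kind[j] == 1) ? rayleigh_cosine(safe_uniform())
                                           : hg_cosine(g[j], safe_uniform());
          double ph = 2.0 * M_PI * safe_uniform();
          rotate_direction(ux, uy, uz, ct, ph);
          tau = -std::log(safe_uniform());
        } else {
          tau -= d_bound * mus[j];
          if (tau < 0.0) tau = 0.0;
          bool up = (uz > 0.0);
          z = up ? zb[j + 1] : zb[j];
          bool to_external = up ? (j == M - 1) : (j == 0);
          double ni = n_layer[j];
          double nt = to_external ? ne : n_layer[up ? j + 1 : j - 1];
          double cos_i = std::fabs(uz);
          double R = fresnel_R_defect(ni, nt, cos_i, defect, tir);
          if (unif_rand() < R) {
            uz = -uz;  // reflect (includes TIR)
          } else if (tir && defect == 3) {
            // missing-TIR bug fixture: transmit undeviated
            if (to_external) {
              alive = false;
              if (up == (parity == 0)) n_trans += 1.0; else n_refl += 1.0;
            } else {
              j = up ? j + 1 : j - 1;
            }
          } else {
            double scale = ni / nt;
            double st2 = scale * scale * (1.0 - uz * uz);
            double czn = std::sqrt(std::max(0.0, 1.0 - st2));
            ux *= scale; uy *= scale;
            uz = up ? czn : -czn;
            double n2 = ux * ux + uy * uy + uz * uz;
            if (std::fabs(n2 - 1.0) > 1e-12) {
              double inv = 1.0 / std::sqrt(n2);
              ux *= inv; uy *= inv; uz *= inv;
            }
            if (to_external) {
              alive = false;
              if (up == (parity == 0)) n_trans += 1.0; else n_refl += 1.0;
            } else {
              j = up ? j + 1 : j - 1;
            }
          }
        }
      }
    }
    // reduce per-photon scratch into the global sums
    double ltot = 0.0;
    for (size_t t = 0; t < Ltouch.size(); ++t) {
      int j = Ltouch[t];
      L_sum[j] += Lp[j];
      L_ssq[j] += Lp[j] * Lp[j];
      ltot += Lp[j];
      Lp[j] = 0.0;
    }
    Lt_sum += ltot;
    Lt_ssq += ltot * ltot;
    Ltouch.clear();
    for (size_t t = 0; t < Rtouch.size(); ++t) {
      size_t idx = (size_t)Rtouch[t];
      R_sum[idx] += Rp[idx];
      R_ssq[idx] += Rp[idx] * Rp[idx];
      Rp[idx] = 0.0;
    }
    Rtouch.clear();
  }

  NumericVector Ls(M), Lq(M);
  for (int j = 0; j < M; ++j) { Ls[j] = L_sum[j]; Lq[j] = L_ssq[j]; }
  NumericMatrix Rs(M, B), Rq(M, B);
  for (int j = 0; j < M; ++j)
    for (int b = 0; b < B; ++b) {
      Rs(j, b) = R_sum[(size_t)j * B + b];
      Rq(j, b) = R_ssq[(size_t)j * B + b];
    }
  return List::create(_["L_sum"] = Ls, _["L_sumsq"] = Lq,
                      _["Ltot_sum"] = Lt_sum, _["Ltot_sumsq"] = Lt_ssq,
                      _["rad_sum"] = Rs, _["rad_sumsq"] = Rq,
                      _["n"] = n_photons, _["n_reflected"] = n_refl,
                      _["n_transmitted"] = n_trans, _["n_aborted"] = n_abort);
}
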