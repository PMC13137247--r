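#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.0083144621; // kJ mol^-1 K^-1
static const double DEG = M_PI / 180.0;

// ---- forward kinematics -------------------------------------------------
// Beads are placed sequentially with fixed bond length `ell`, bond angle
// thetas[k-2] at bead k (k = 2..n-1), and dihedral phis[k-4] for bead k
// (k = 4..n), all angles in degrees.  Dihedrals follow the IUPAC sign
// convention (trans = 180).
static void build_coords(const std::vector<double> &phis_deg, double ell,
                         const NumericVector &thetas_deg, int n,
                         std::vector<double> &X) {
  X.assign(3 * n, 0.0);
  double th0 = thetas_deg[0] * DEG;
  X[3 * 1 + 0] = ell;
  X[3 * 2 + 0] = ell + ell * std::cos(M_PI - th0);
  X[3 * 2 + 1] = ell * std::sin(M_PI - th0);
  for (int k = 3; k < n; ++k) { // 0-based bead index
    double theta = thetas_deg[k - 2] * DEG;
    double phi = phis_deg[k - 3] * DEG;
    const double *a = &X[3 * (k - 3)], *b = &X[3 * (k - 2)], *c = &X[3 * (k - 1)];
    double bc[3], ab[3], nv[3], mv[3];
    double nrm = 0.0;
    for (int j = 0; j < 3; ++j) { bc[j] = c[j] - b[j]; nrm += bc[j] * bc[j]; }
    nrm = std::sqrt(nrm);
    for (int j = 0; j < 3; ++j) bc[j] /= nrm;
    for (int j = 0; j < 3; ++j) ab[j] = b[j] - a[j];
    double dot = ab[0] * bc[0] + ab[1] * bc[1] + ab[2] * bc[2];
    nrm = 0.0;
    for (int j = 0; j < 3; ++j) { nv[j] = ab[j] - dot * bc[j]; nrm += nv[j] * nv[j]; }
    nrm = std::sqrt(nrm);
    for (int j = 0; j < 3; ++j) nv[j] /= nrm;
    mv[0] = bc[1] * nv[2] - bc[2] * nv[1];
    mv[1] = bc[2] * nv[0] - bc[0] * nv[2];
    mv[2] = bc[0] * nv[1] - bc[1] * nv[0];
    double ct = std::cos(theta), st = std::sin(theta);
    double cp = std::cos(phi), sp = std::sin(phi);
    for (int j = 0; j < 3; ++j)
      X[3 * k + j] = c[j] + ell * (-ct * bc[j] - st * (cp * nv[j] - sp * mv[j]));
  }
}

static double min_pair_dist(const std::vector<double> &X,
                            const IntegerVector &ia, const IntegerVector &ib) {
  double best = R_PosInf;
  for (int u = 0; u < ia.size(); ++u)
    for (int v = 0; v < ib.size(); ++v) {
      const double *p = &X[3 * (ia[u] - 1)], *q = &X[3 * (ib[v] - 1)];
      double d = 0.0;
      for (int j = 0; j < 3; ++j) d += (p[j] - q[j]) * (p[j] - q[j]);
      d = std::sqrt(d);
      if (d < best) best = d;
    }
  return best;
}

// [[Rcpp::export]]
NumericMatrix chain_coords_cpp(NumericVector psi, double ell,
                               NumericVector thetas, IntegerVector tors_bonds,
                               int n_beads) {
  std::vector<double> phis(n_beads - 3, 180.0);
  for (int i = 0; i < tors_bonds.size(); ++i)
    phis[tors_bonds[i] - 2] = psi[i]; // dihedral about bond m -> phi index m-2
  std::vector<double> X;
  build_coords(phis, ell, thetas, n_beads, X);
  NumericMatrix out(n_beads, 3);
  for (int k = 0; k < n_beads; ++k)
    for (int j = 0; j < 3; ++j) out(k, j) = X[3 * k + j];
  return out;
}

// ---- energy helpers -----------------------------------------------------
static double torsion_energy_one(double psi_deg, const NumericVector &coefs) {
  double p = psi_deg * DEG, e = 0.0;
  for (int k = 0; k < coefs.size(); ++k) e += coefs[k] * std::cos((k + 1) * p);
  return e;
}

static double wall_energy_c(double v, double limit, double k, int side, int expo) {
  double viol = (side > 0) ? (limit - v) : (v - limit); // side>0: lower wall
  if (viol <= 0.0 || k <= 0.0) return 0.0;
  double e = k;
  for (int i = 0; i < expo; ++i) e *= viol;
  return e;
}

// linear interpolation on a uniform grid, clamped at the edges
static double grid_eval(const std::vector<double> &g, double gmin, double dx,
                        double x) {
  int n = (int)g.size();
  double t = (x - gmin) / dx;
  if (t <= 0.0) return g[0];
  if (t >= n - 1) return g[n - 1];
  int i = (int)t;
  double f = t - i;
  return g[i] * (1.0 - f) + g[i + 1] * f;
}

static void grid_add_gaussian(std::vector<double> &g, double gmin, double dx,
                              double c, double h, double sigma) {
  for (size_t i = 0; i < g.size(); ++i) {
    double x = gmin + dx * i, z = (x - c) / sigma;
    g[i] += h * std::exp(-0.5 * z * z);
  }
}

static double kernels_eval(const std::vector<double> &centers,
                           const std::vector<double> &heights, double sigma,
                           double x) {
  double v = 0.0;
  for (size_t j = 0; j < centers.size(); ++j) {
    double z = (x - centers[j]) / sigma;
    v += heights[j] * std::exp(-0.5 * z * z);
  }
  return v;
}

// ---- chain Monte Carlo --------------------------------------------------
// Torsion-space Metropolis MC of the coarse-grained oligomer.  Energy:
//   lambda * sum_i U(psi_i)  +  wall(d1)  +  V_bias(d1)
// Optional well-tempered metadynamics deposits on d1.  Uses R's RNG.
// [[Rcpp::export]]
List chain_mc_cpp(NumericVector psi0, int n_sweeps, int thin, double ell,
                  NumericVector thetas, IntegerVector tors_bonds, int n_beads,
                  IntegerVector term_a, IntegerVector term_b,
                  NumericVector coefs, double lambda, bool wall_on,
                  double wall_limit, double wall_k, int wall_side, int wall_exp,
                  bool metad_on, bool metad_deposit, NumericVector centers0,
                  NumericVector heights0, double msigma, double mgamma,
                  double mw0, int mpace, double gmin, double gmax, int ngrid,
                  double temperature) {
  const int nt = psi0.size();
  const double kT = KB * temperature;
  std::vector<double> psi(psi0.begin(), psi0.end());
  std::vector<double> phis(n_beads - 3, 180.0);
  std::vector<int> pidx(nt);
  for (int i = 0; i < nt; ++i) pidx[i] = tors_bonds[i] - 2;
  for (int i = 0; i < nt; ++i) phis[pidx[i]] = psi[i];

  std::vector<double> X;
  build_coords(phis, ell, thetas, n_beads, X);
  double d1 = min_pair_dist(X, term_a, term_b);

  std::vector<double> centers(centers0.begin(), centers0.end());
  std::vector<double> heights(heights0.begin(), heights0.end());
  const double dx = (gmax - gmin) / (ngrid - 1);
  std::vector<double> bias_grid(metad_on ? ngrid : 1, 0.0);
  if (metad_on)
    for (size_t j = 0; j < centers.size(); ++j)
      grid_add_gaussian(bias_grid, gmin, dx, centers[j], heights[j], msigma);

  double e_wall = wall_on ? wall_energy_c(d1, wall_limit, wall_k, wall_side, wall_exp) : 0.0;
  double e_bias = metad_on ? grid_eval(bias_grid, gmin, dx, d1) : 0.0;

  int n_frames = n_sweeps / thin;
  NumericMatrix psi_out(n_frames, nt);
  NumericVector d1_out(n_frames), bias_out(n_frames);
  long accepted = 0, attempted = 0;
  int frame = 0;

  for (int sw = 1; sw <= n_sweeps; ++sw) {
    for (int i = 0; i < nt; ++i) {
      double old = psi[i];
      double cand = R::runif(-180.0, 180.0);
      double de_t = lambda * (torsion_energy_one(cand, coefs) -
                              torsion_energy_one(old, coefs));
      phis[pidx[i]] = cand;
      build_coords(phis, ell, thetas, n_beads, X);
      double d1_new = min_pair_dist(X, term_a, term_b);
      double e_wall_new = wall_on ? wall_energy_c(d1_new, wall_limit, wall_k, wall_side, wall_exp) : 0.0;
      double e_bias_new = metad_on ? grid_eval(bias_grid, gmin, dx, d1_new) : 0.0;
      double dE = de_t + (e_wall_new - e_wall) + (e_bias_new - e_bias);
      ++attempted;
      if (dE <= 0.0 || R::runif(0.0, 1.0) < std::exp(-dE / kT)) {
        psi[i] = cand;
        d1 = d1_new;
        e_wall = e_wall_new;
        e_bias = e_bias_new;
        ++accepted;
      } else {
        phis[pidx[i]] = old;
      }
    }
    if (metad_on && metad_deposit && mpace > 0 && sw % mpace == 0) {
      double v_here = kernels_eval(centers, heights, msigma, d1);
      double h = mw0 * std::exp(-v_here / (KB * (mgamma - 1.0) * temperature));
      centers.push_back(d1);
      heights.push_back(h);
      grid_add_gaussian(bias_grid, gmin, dx, d1, h, msigma);
      e_bias = grid_eval(bias_grid, gmin, dx, d1);
    }
    if (sw % thin == 0 && frame < n_frames) {
      for (int i = 0; i < nt; ++i) psi_out(frame, i) = psi[i];
      d1_out[frame] = d1;
      bias_out[frame] = e_bias;
      ++frame;
    }
  }

  return List::create(
      _["psi"] = psi_out, _["d1"] = d1_out, _["bias"] = bias_out,
      _["psi_final"] = NumericVector(psi.begin(), psi.end()),
      _["acceptance"] = attempted ? (double)accepted / attempted : NA_REAL,
      _["centers"] = NumericVector(centers.begin(), centers.end()),
      _["heights"] = NumericVector(heights.begin(), heights.end()));
}

// ---- 1-D double-well Monte Carlo ---------------------------------------
// Metropolis random walk on V(s) = lambda * sum_k poly[k] s^k with optional
// wall and well-tempered metadynamics on s.  Validation workhorse for the
// sampling engines.
// [[Rcpp::export]]
List dw_mc_cpp(double s0, int n_steps, int thin, NumericVector poly,
               double lambda, double step_sd, bool wall_on, double wall_limit,
               double wall_k, int wall_side, int wall_exp, bool metad_on,
               bool metad_deposit, NumericVector centers0,
               NumericVector heights0, double msigma, double mgamma,
               double mw0, int mpace, double gmin, double gmax, int ngrid,
               double temperature) {
  const double kT = KB * temperature;
  double s = s0;
  std::vector<double> centers(centers0.begin(), centers0.end());
  std::vector<double> heights(heights0.begin(), heights0.end());
  const double dx = (gmax - gmin) / (ngrid - 1);
  std::vector<double> bias_grid(metad_on ? ngrid : 1, 0.0);
  if (metad_on)
    for (size_t j = 0; j < centers.size(); ++j)
      grid_add_gaussian(bias_grid, gmin, dx, centers[j], heights[j], msigma);

  auto poly_e = [&](double x) {
    double e = 0.0, xp = 1.0;
    for (int k = 0; k < poly.size(); ++k) { e += poly[k] * xp; xp *= x; }
    return lambda * e;
  };
  double e_pot = poly_e(s);
  double e_wall = wall_on ? wall_energy_c(s, wall_limit, wall_k, wall_side, wall_exp) : 0.0;
  double e_bias = metad_on ? grid_eval(bias_grid, gmin, dx, s) : 0.0;

  int n_frames = n_steps / thin;
  NumericVector s_out(n_frames), bias_out(n_frames);
  long accepted = 0;
  int frame = 0;
  for (int st = 1; st <= n_steps; ++st) {
    double cand = s + R::rnorm(0.0, step_sd);
    double ep = poly_e(cand);
    double ew = wall_on ? wall_energy_c(cand, wall_limit, wall_k, wall_side, wall_exp) : 0.0;
    double eb = metad_on ? grid_eval(bias_grid, gmin, dx, cand) : 0.0;
    double dE = (ep + ew + eb) - (e_pot + e_wall + e_bias);
    if (dE <= 0.0 || R::runif(0.0, 1.0) < std::exp(-dE / kT)) {
      s = cand; e_pot = ep; e_wall = ew; e_bias = eb;
      ++accepted;
    }
    if (metad_on && metad_deposit && mpace > 0 && st % mpace == 0) {
      double v_here = kernels_eval(centers, heights, msigma, s);
      double h = mw0 * std::exp(-v_here / (KB * (mgamma - 1.0) * temperature));
      centers.push_back(s);
      heights.push_back(h);
      grid_add_gaussian(bias_grid, gmin, dx, s, h, msigma);
      e_bias = grid_eval(bias_grid, gmin, dx, s);
    }
    if (st % thin == 0 && frame < n_frames) {
      s_out[frame] = s;
      bias_out[frame] = e_bias;
      ++frame;
    }
  }
  return List::create(
      _["s"] = s_out, _["bias"] = bias_out, _["s_final"] = s,
      _["acceptance"] = (double)accepted / n_steps,
      _["centers"] = NumericVector(centers.begin(), centers.end()),
      _["heights"] = NumericVector(heights.begin(), heights.end()));
}
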