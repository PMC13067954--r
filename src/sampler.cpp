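#include <Rcpp.h>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// Basin-mixture torsional energy of one residue (kcal/mol).
// U = -eps * log( sum_k w_k exp(kappa_k (cos(phi-phi0k) - 1))
//                         * exp(kappa_k (cos(psi-psi0k) - 1)) )
// The exp(kappa (cos d - 1)) kernel is a von Mises bell rescaled to peak
// at 1, so the log argument is bounded and the energy finite.
static double residue_energy(double phi, double psi, int res,
                             const NumericMatrix &w,
                             const NumericMatrix &centers,
                             const NumericVector &kappa,
                             double eps) {
  double s = 0.0;
  const int nb = centers.nrow();
  for (int k = 0; k < nb; ++k) {
    double wk = w(res, k);
    if (wk <= 0.0) continue;
    double e = kappa[k] * (std::cos((phi - centers(k, 0)) * DEG) - 1.0) +
               kappa[k] * (std::cos((psi - centers(k, 1)) * DEG) - 1.0);
    s += wk * std::exp(e);
  }
  if (s <= 0.0) return R_PosInf;
  return -eps * std::log(s);
}

// [[Rcpp::export]]
NumericVector cpp_residue_energies(NumericVector phi, NumericVector psi,
                                   NumericMatrix weights,
                                   NumericMatrix centers,
                                   NumericVector kappa, double epsilon) {
  const int n = phi.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = residue_energy(phi[i], psi[i], i, weights, centers, kappa,
                            epsilon);
  return out;
}

static inline double wrap_deg(double x) {
  x -= 360.0 * std::floor((x + 180.0) / 360.0); // [-180, 180)
  if (x <= -180.0) x += 360.0;                  // domain is (-180, 180]
  return x;
}

// One Metropolis sweep over a replica: every phi then psi of each residue
// is proposed once with a uniform +/- step perturbation. Consumes exactly
// 2 uniforms per angle (proposal, acceptance) so RNG streams are
// reproducible independent of acceptance outcomes.
static void sweep_replica(std::vector<double> &phi, std::vector<double> &psi,
                          std::vector<double> &eres, double &etot,
                          double kbt, double step,
                          const NumericMatrix &w, const NumericMatrix &centers,
                          const NumericVector &kappa, double eps) {
  const int n = (int)phi.size();
  for (int i = 0; i < n; ++i) {
    for (int ang = 0; ang < 2; ++ang) {
      double delta = (2.0 * unif_rand() - 1.0) * step;
      double nphi = phi[i], npsi = psi[i];
      if (ang == 0) nphi = wrap_deg(nphi + delta);
      else npsi = wrap_deg(npsi + delta);
      double enew = residue_energy(nphi, npsi, i, w, centers, kappa, eps);
      if (!R_finite(enew)) stop("non-finite energy in Metropolis sweep");
      double du = enew - eres[i];
      double u = unif_rand();
      if (u < std::exp(-du / kbt)) {
        phi[i] = nphi;
        psi[i] = npsi;
        etot += du;
        eres[i] = enew;
      }
    }
  }
}

// Replica-exchange torsional Monte Carlo.
// phi0/psi0: K x n_res initial angles (degrees), one row per replica.
// Returns recorded per-temperature trajectories (configuration swaps
// applied, so row k of every recorded frame is the configuration
// currently at temperature temps[k]), per-frame energies, and exchange
// bookkeeping per neighbouring pair.
// [[Rcpp::export]]
List cpp_remd(NumericMatrix weights, NumericMatrix centers,
              NumericVector kappa, double epsilon,
              NumericVector temps, NumericMatrix phi0, NumericMatrix psi0,
              int n_sweeps, double step, int exchange_every,
              int record_every, double kb) {
  const int K = temps.size();
  const int n = weights.nrow();
  if (phi0.nrow() != K || phi0.ncol() != n)
    stop("initial state must be n_replicas x n_residues");

  std::vector<std::vector<double> > phi(K), psi(K), eres(K);
  std::vector<double> etot(K, 0.0);
  for (int k = 0; k < K; ++k) {
    phi[k].resize(n); psi[k].resize(n); eres[k].resize(n);
    for (int i = 0; i < n; ++i) {
      phi[k][i] = phi0(k, i);
      psi[k][i] = psi0(k, i);
      eres[k][i] = residue_energy(phi[k][i], psi[k][i], i, weights, centers,
                                  kappa, epsilon);
      etot[k] += eres[k][i];
    }
  }

  const int nrec = record_every > 0 ? n_sweeps / record_every : 0;
  NumericVector rec_phi(Dimension(nrec, K, n));
  NumericVector rec_psi(Dimension(nrec, K, n));
  NumericMatrix rec_e(nrec, K);
  IntegerVector ex_att(K > 1 ? K - 1 : 0), ex_acc(K > 1 ? K - 1 : 0);

  RNGScope scope;
  int rec = 0;
  long exchange_event = 0;
  for (int s = 1; s <= n_sweeps; ++s) {
    for (int k = 0; k < K; ++k)
      sweep_replica(phi[k], psi[k], eres[k], etot[k], kb * temps[k], step,
                    weights, centers, kappa, epsilon);
    if (K > 1 && exchange_every > 0 && s % exchange_every == 0) {
      ++exchange_event;
      int start = (exchange_event % 2 == 1) ? 0 : 1; // odd/even alternation
      for (int p = start; p + 1 < K; p += 2) {
        ++ex_att[p];
        double d = (1.0 / (kb * temps[p]) - 1.0 / (kb * temps[p + 1])) *
                   (etot[p] - etot[p + 1]);
        double u = unif_rand();
        if (u < std::exp(d)) {
          ++ex_acc[p];
          std::swap(phi[p], phi[p + 1]);
          std::swap(psi[p], psi[p + 1]);
          std::swap(eres[p], eres[p + 1]);
          std::swap(etot[p], etot[p + 1]);
        }
      }
    }
    if (record_every > 0 && s % record_every == 0) {
      for (int k = 0; k < K; ++k) {
        for (int i = 0; i < n; ++i) {
          rec_phi[rec + nrec * (k + K * i)] = phi[k][i];
          rec_psi[rec + nrec * (k + K * i)] = psi[k][i];
        }
        rec_e(rec, k) = etot[k];
      }
      ++rec;
    }
  }

  NumericMatrix fphi(K, n), fpsi(K, n);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) {
      fphi(k, i) = phi[k][i];
      fpsi(k, i) = psi[k][i];
    }
  return List::create(_["phi"] = rec_phi, _["psi"] = rec_psi,
                      _["energy"] = rec_e,
                      _["final_phi"] = fphi, _["final_psi"] = fpsi,
                      _["exchange_attempts"] = ex_att,
                      _["exchange_accepts"] = ex_acc);
}

// Per-frame radius of gyration of idealised N/CA/C backbones rebuilt from
// dihedrals (equal atom masses). Mirrors the R backbone builder; the two
// are cross-checked in the test suite.
// [[Rcpp::export]]
NumericVector cpp_backbone_rg(NumericMatrix phi, NumericMatrix psi,
                              NumericVector lens, NumericVector angs,
                              double omega) {
  const int nf = phi.nrow(), n = phi.ncol();
  if (n < 2) stop("need at least 2 residues");
  NumericVector rg(nf);
  const double b_n_ca = lens[0], b_ca_c = lens[1], b_c_n = lens[2];
  const double a_n_ca_c = angs[0], a_ca_c_n = angs[1], a_c_n_ca = angs[2];
  std::vector<double> X(3 * n * 3);
  for (int f = 0; f < nf; ++f) {
    double *N0 = &X[0], *CA0 = &X[3], *C0 = &X[6];
    N0[0] = N0[1] = N0[2] = 0.0;
    CA0[0] = b_n_ca; CA0[1] = 0.0; CA0[2] = 0.0;
    double th = a_n_ca_c * DEG;
    C0[0] = CA0[0] - b_ca_c * std::cos(th);
    C0[1] = b_ca_c * std::sin(th);
    C0[2] = 0.0;
    for (int i = 1; i < n; ++i) {
      double *pN = &X[9 * i], *pCA = &X[9 * i + 3], *pC = &X[9 * i + 6];
      double *qN = &X[9 * (i - 1)], *qCA = &X[9 * (i - 1) + 3],
             *qC = &X[9 * (i - 1) + 6];
      // place: N(i) from psi(i-1), CA(i) from omega, C(i) from phi(i)
      auto place = [](const double *a, const double *b, const double *c,
                      double r, double theta, double tau, double *d) {
        double thr = theta * DEG, tar = tau * DEG;
        double dl0 = -r * std::cos(thr);
        double dl1 = r * std::sin(thr) * std::cos(tar);
        double dl2 = r * std::sin(thr) * std::sin(tar);
        double bc[3] = {c[0] - b[0], c[1] - b[1], c[2] - b[2]};
        double nb = std::sqrt(bc[0] * bc[0] + bc[1] * bc[1] + bc[2] * bc[2]);
        bc[0] /= nb; bc[1] /= nb; bc[2] /= nb;
        double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
        double nn[3] = {ab[1] * bc[2] - ab[2] * bc[1],
                        ab[2] * bc[0] - ab[0] * bc[2],
                        ab[0] * bc[1] - ab[1] * bc[0]};
        double nm = std::sqrt(nn[0] * nn[0] + nn[1] * nn[1] + nn[2] * nn[2]);
        nn[0] /= nm; nn[1] /= nm; nn[2] /= nm;
        double mm[3] = {nn[1] * bc[2] - nn[2] * bc[1],
                        nn[2] * bc[0] - nn[0] * bc[2],
                        nn[0] * bc[1] - nn[1] * bc[0]};
        for (int t = 0; t < 3; ++t)
          d[t] = c[t] + dl0 * bc[t] + dl1 * mm[t] + dl2 * nn[t];
      };
      place(qN, qCA, qC, b_c_n, a_ca_c_n, psi(f, i - 1), pN);
      place(qCA, qC, pN, b_n_ca, a_c_n_ca, omega, pCA);
      place(qC, pN, pCA, b_ca_c, a_n_ca_c, phi(f, i), pC);
    }
    const int na = 3 * n;
    double cx = 0, cy = 0, cz = 0;
    for (int a = 0; a < na; ++a) {
      cx += X[3 * a]; cy += X[3 * a + 1]; cz += X[3 * a + 2];
    }
    cx /= na; cy /= na; cz /= na;
    double ss = 0;
    for (int a = 0; a < na; ++a) {
      double dx = X[3 * a] - cx, dy = X[3 * a + 1] - cy,
             dz = X[3 * a + 2] - cz;
      ss += dx * dx + dy * dy + dz * dz;
    }
    rg[f] = std::sqrt(ss / na);
  }
  return rg;
}
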