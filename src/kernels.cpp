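#include <Rcpp.h>
using namespace Rcpp;

// Minimum-image squared distance in an orthorhombic box.
static inline double min_image_r2(const double* xi, const double* xj,
                                  const double* box) {
  double r2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = xi[k] - xj[k];
    d -= box[k] * std::round(d / box[k]);
    r2 += d * d;
  }
  return r2;
}

// Histogram of minimum-image distances between two index sets.
// idx_a / idx_b are 0-based atom indices; when same_set is true they must be
// identical and each unordered pair is counted once. Pairs sharing molid are
// skipped when exclude_intra is set. Distances >= nbins*bin_width are ignored.
// [[Rcpp::export]]
NumericVector cpp_pair_hist(const NumericMatrix& coords,
                            const NumericVector& box,
                            const IntegerVector& idx_a,
                            const IntegerVector& idx_b,
                            bool same_set,
                            const IntegerVector& molid,
                            bool exclude_intra,
                            double bin_width, int nbins) {
  const int n = coords.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  const double b[3] = {box[0], box[1], box[2]};
  const double rmax = bin_width * nbins;
  const double rmax2 = rmax * rmax;
  NumericVector counts(nbins);
  const int na = idx_a.size(), nb = idx_b.size();
  for (int ii = 0; ii < na; ++ii) {
    const int i = idx_a[ii];
    const int j0 = same_set ? ii + 1 : 0;
    for (int jj = j0; jj < nb; ++jj) {
      const int j = idx_b[jj];
      if (i == j) continue;
      if (exclude_intra && molid[i] == molid[j]) continue;
      double r2 = min_image_r2(&x[3 * i], &x[3 * j], b);
      if (r2 >= rmax2) continue;
      int bin = (int)(std::sqrt(r2) / bin_width);
      if (bin >= 0 && bin < nbins) counts[bin] += 1.0;
    }
  }
  return counts;
}

// Species-pair-resolved truncated pair-energy sums (the brute-force oracle).
// sp: 0-based species index per atom; eps/sig: nsp x nsp matrices of combined
// LJ parameters; kqq: nsp x nsp matrix of k_e*q_a*q_b (added when
// include_coulomb). Returns an nsp x nsp matrix with each unordered pair's
// sum stored symmetrically (u[a][b] == u[b][a]; diagonal holds self-pair sums).
// [[Rcpp::export]]
NumericMatrix cpp_pair_energy_sums(const NumericMatrix& coords,
                                   const NumericVector& box,
                                   const IntegerVector& sp, int nsp,
                                   const IntegerVector& molid,
                                   bool exclude_intra,
                                   const NumericMatrix& eps,
                                   const NumericMatrix& sig,
                                   const NumericMatrix& kqq,
                                   bool include_coulomb,
                                   double r_cut) {
  const int n = coords.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  const double b[3] = {box[0], box[1], box[2]};
  const double rc2 = r_cut * r_cut;
  NumericMatrix u(nsp, nsp);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (exclude_intra && molid[i] == molid[j]) continue;
      double r2 = min_image_r2(&x[3 * i], &x[3 * j], b);
      if (r2 > rc2) continue;
      const int a = sp[i], c = sp[j];
      double s2 = sig(a, c) * sig(a, c) / r2;
      double s6 = s2 * s2 * s2;
      double e = 4.0 * eps(a, c) * (s6 * s6 - s6);
      if (include_coulomb) e += kqq(a, c) / std::sqrt(r2);
      u(a, c) += e;
      if (a != c) u(c, a) += e;
    }
  }
  return u;
}

// Energy of particle i against all others (truncated, unshifted LJ).
static double particle_energy(const std::vector<double>& x, int n, int i,
                              const double* pos_i, const double* b,
                              const int* sp, const double* eps,
                              const double* sig, int nsp, double rc2) {
  double e = 0.0;
  const int a = sp[i];
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double r2 = min_image_r2(pos_i, &x[3 * j], b);
    if (r2 > rc2) continue;
    const int c = sp[j];
    double s = sig[a + nsp * c];
    double s2 = s * s / r2;
    double s6 = s2 * s2 * s2;
    e += 4.0 * eps[a + nsp * c] * (s6 * s6 - s6);
  }
  return e;
}

static double total_energy(const std::vector<double>& x, int n, const double* b,
                           const int* sp, const double* eps, const double* sig,
                           int nsp, double rc2) {
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double r2 = min_image_r2(&x[3 * i], &x[3 * j], b);
      if (r2 > rc2) continue;
      const int a = sp[i], c = sp[j];
      double s = sig[a + nsp * c];
      double s2 = s * s / r2;
      double s6 = s2 * s2 * s2;
      e += 4.0 * eps[a + nsp * c] * (s6 * s6 - s6);
    }
  return e;
}

// Metropolis single-particle-displacement Monte Carlo on a truncated
// (unshifted) LJ mixture. One sweep = n attempted moves, each picking a
// uniformly random particle. Uses R's RNG (seed with set.seed() in R).
// Snapshots are collected every snapshot_interval sweeps after burn_in_sweeps.
// Returns coordinates of each snapshot, the incrementally tracked energy at
// each snapshot, the final tracked and recomputed energies, and the
// acceptance fraction.
// [[Rcpp::export]]
List cpp_run_metropolis(const NumericMatrix& coords0,
                        const NumericVector& box,
                        const IntegerVector& sp_in, int nsp,
                        const NumericMatrix& eps_in,
                        const NumericMatrix& sig_in,
                        double r_cut, double temperature, double k_B,
                        int n_sweeps, double max_displacement,
                        int snapshot_interval, int burn_in_sweeps) {
  RNGScope scope;
  const int n = coords0.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords0(i, k);
  const double b[3] = {box[0], box[1], box[2]};
  std::vector<int> sp(sp_in.begin(), sp_in.end());
  std::vector<double> eps(eps_in.begin(), eps_in.end());
  std::vector<double> sig(sig_in.begin(), sig_in.end());
  const double rc2 = r_cut * r_cut;
  const double beta = (temperature > 0) ? 1.0 / (k_B * temperature) : R_PosInf;

  double e_tot = total_energy(x, n, b, sp.data(), eps.data(), sig.data(),
                              nsp, rc2);
  long accepted = 0, attempted = 0;
  List snapshots;
  std::vector<double> snap_energy;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int m = 0; m < n; ++m) {
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      double trial[3];
      double e_old = particle_energy(x, n, i, &x[3 * i], b, sp.data(),
                                     eps.data(), sig.data(), nsp, rc2);
      for (int k = 0; k < 3; ++k) {
        double xi = x[3 * i + k] + max_displacement * (2.0 * unif_rand() - 1.0);
        xi -= b[k] * std::floor(xi / b[k]);  // wrap into [0, L)
        trial[k] = xi;
      }
      double e_new = particle_energy(x, n, i, trial, b, sp.data(),
                                     eps.data(), sig.data(), nsp, rc2);
      double dE = e_new - e_old;
      ++attempted;
      bool accept = (dE <= 0.0) || (unif_rand() < std::exp(-beta * dE));
      if (accept) {
        for (int k = 0; k < 3; ++k) x[3 * i + k] = trial[k];
        e_tot += dE;
        ++accepted;
      }
    }
    if (sweep > burn_in_sweeps &&
        ((sweep - burn_in_sweeps) % snapshot_interval) == 0) {
      NumericMatrix snap(n, 3);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) snap(i, k) = x[3 * i + k];
      snapshots.push_back(snap);
      snap_energy.push_back(e_tot);
    }
  }

  double e_recomputed = total_energy(x, n, b, sp.data(), eps.data(),
                                     sig.data(), nsp, rc2);
  return List::create(
    _["snapshots"] = snapshots,
    _["snapshot_energy"] = NumericVector(snap_energy.begin(), snap_energy.end()),
    _["energy_tracked"] = e_tot,
    _["energy_recomputed"] = e_recomputed,
    _["acceptance_fraction"] =
        attempted > 0 ? (double)accepted / (double)attempted : NA_REAL);
}
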