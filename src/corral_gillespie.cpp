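#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven simulation of the kinase-phosphatase composition
// reaction in a single membrane corral.
//
// State: nP  = number of product (PI(4,5)P2) lipids out of n_lipid;
//        nE  = kinase copy number on the corral.
// Events and propensities (x = nP / n_lipid):
//   kinase arrival       a1 = arrival_rate * (1 + recruit_coupling * x)
//   kinase departure     a2 = departure_rate * nE
//   phosphorylation      a3 = k(x) * (1 - x) * n_lipid * (nE / e_mean)
//   dephosphorylation    a4 = (p0 + p1 * (1 - x)) * x * n_lipid
// e_mean > 0 enables the explicit kinase copy-number channel; e_mean == 0
// means no kinase reaches the corral (phosphorylation silent); e_mean < 0
// is the mean-field sentinel (no copy fluctuations, full k(x) rate).
// Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export]]
List corral_gillespie_cpp(int n_lipid, int n_p0,
                          NumericVector k, NumericVector p,
                          double arrival_rate, double departure_rate,
                          double e_mean, double recruit_coupling,
                          double t_end, double dt_record) {
  const double k0 = k[0], k1 = k[1], k2 = k[2];
  const double p0 = p[0], p1 = p[1];
  const bool copy_dynamics = e_mean > 0.0;
  const bool no_kinase = e_mean == 0.0;

  int nP = n_p0;
  // start the kinase channel at its mean occupancy (rounded)
  int nE = copy_dynamics ? (int)std::lround(e_mean) : 0;

  const int n_rec = (int)std::floor(t_end / dt_record + 1e-9) + 1;
  NumericVector xs(n_rec), nEs(n_rec);

  double t = 0.0;
  int irec = 0;
  const double inv_n = 1.0 / (double)n_lipid;

  while (true) {
    double x = nP * inv_n;
    double a1 = copy_dynamics ?
      arrival_rate * (1.0 + recruit_coupling * x) : 0.0;
    double a2 = copy_dynamics ? departure_rate * nE : 0.0;
    double kx = k0 + k1 * x + k2 * x * x;
    double a3 = no_kinase ? 0.0 : kx * (1.0 - x) * (double)n_lipid;
    if (copy_dynamics) a3 *= (double)nE / e_mean;
    double a4 = (p0 + p1 * (1.0 - x)) * x * (double)n_lipid;
    double a0 = a1 + a2 + a3 + a4;

    double t_next = (a0 > 0.0) ? t + R::rexp(1.0 / a0) : R_PosInf;

    // record all grid points passed before the next event
    while (irec < n_rec && irec * dt_record <= t_next) {
      xs[irec] = x;
      nEs[irec] = nE;
      ++irec;
    }
    if (irec >= n_rec || t_next > t_end) break;
    t = t_next;

    double u = unif_rand() * a0;
    if (u < a1) {
      ++nE;
    } else if (u < a1 + a2) {
      if (nE > 0) --nE;
    } else if (u < a1 + a2 + a3) {
      if (nP < n_lipid) ++nP;
    } else {
      if (nP > 0) --nP;
    }
  }
  // fill any remaining grid points with the final state
  double x = nP * inv_n;
  while (irec < n_rec) { xs[irec] = x; nEs[irec] = nE; ++irec; }

  return List::create(_["x"] = xs, _["n_kinase"] = nEs);
}
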