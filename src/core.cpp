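// Forward-Euler core loop for the Cdc42 reaction-diffusion system.
// The sparse Laplace-Beltrami operator is passed in dgCMatrix (CSC) slot
// form; it is symmetric with zero row sums applied as (W f)_i / a_i.
// Uses R's RNG so set.seed() in R controls the stochastic noise stream.

#include <Rcpp.h>
using namespace Rcpp;

// Fused sparse matvec over the five dynamic fields (one pass over nnz).
static void lap5(const IntegerVector& Wp, const IntegerVector& Wi,
                 const NumericVector& Wx, int n,
                 const std::vector<double>& cd, const std::vector<double>& ct,
                 const std::vector<double>& gi, const std::vector<double>& gf,
                 const std::vector<double>& gs,
                 std::vector<double>& lcd, std::vector<double>& lct,
                 std::vector<double>& lgi, std::vector<double>& lgf,
                 std::vector<double>& lgs) {
  std::fill(lcd.begin(), lcd.end(), 0.0);
  std::fill(lct.begin(), lct.end(), 0.0);
  std::fill(lgi.begin(), lgi.end(), 0.0);
  std::fill(lgf.begin(), lgf.end(), 0.0);
  std::fill(lgs.begin(), lgs.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    const double xcd = cd[j], xct = ct[j], xgi = gi[j], xgf = gf[j], xgs = gs[j];
    for (int k = Wp[j]; k < Wp[j + 1]; ++k) {
      const int i = Wi[k];
      const double w = Wx[k];
      lcd[i] += w * xcd;
      lct[i] += w * xct;
      lgi[i] += w * xgi;
      lgf[i] += w * xgf;
      lgs[i] += w * xgs;
    }
  }
}

// [[Rcpp::export]]
List simulate_core(IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
                   NumericVector areas, NumericVector bias,
                   IntegerVector tip1_idx, IntegerVector tip2_idx,
                   List par, List init,
                   int nsteps, int trace_stride,
                   int snap_stride, int snap_start) {
  const int n = areas.size();
  const double DT = par["DT"], DD = par["DD"], DGI = par["DGAPI"],
               DGF = par["DGAPIIfast"], DGS = par["DGAPIIslow"],
               k1n = par["k1n"], k2n = par["k2n"], k3n = par["k3n"],
               k4n = par["k4n"], k5n = par["k5n"], k6n = par["k6n"],
               k7n = par["k7n"], k8n = par["k8n"], ksat = par["ksat"],
               hexp = par["h"], k0p = par["k0p"], k1p = par["k1p"],
               k2p = par["k2p"], Ectot = par["Ectot"], jDp = par["jDp"],
               rT = par["rT"], rD = par["rD"], rGI = par["rGAPI"],
               rGF = par["rGAPIIfast"], rGS = par["rGAPIIslow"],
               rnoise = par["rnoise"], V = par["V"], dt = par["dt"],
               t0 = par["t0"];
  const int noise_mode = par["noise_mode_int"];  // 0 off, 1 deterministic, 2 stochastic
  const double ksat_h = std::pow(ksat, hexp);
  const bool h_is_2 = std::fabs(hexp - 2.0) < 1e-12;

  std::vector<double> CD(n), CT(n), GI(n), GF(n), GS(n), CGEF(n);
  {
    NumericVector v;
    v = init["CD"]; std::copy(v.begin(), v.end(), CD.begin());
    v = init["CT"]; std::copy(v.begin(), v.end(), CT.begin());
    v = init["CGAPI"]; std::copy(v.begin(), v.end(), GI.begin());
    v = init["CGAPIIfast"]; std::copy(v.begin(), v.end(), GF.begin());
    v = init["CGAPIIslow"]; std::copy(v.begin(), v.end(), GS.begin());
  }
  std::vector<double> lcd(n), lct(n), lgi(n), lgf(n), lgs(n);

  // tip-region area weights
  double a_tip1 = 0.0, a_tip2 = 0.0;
  for (int k = 0; k < tip1_idx.size(); ++k) a_tip1 += areas[tip1_idx[k]];
  for (int k = 0; k < tip2_idx.size(); ++k) a_tip2 += areas[tip2_idx[k]];

  const int ntrace = nsteps / trace_stride + 1;
  NumericVector tr_t(ntrace), tr_tip1(ntrace), tr_tip2(ntrace), tr_Ec(ntrace);
  NumericMatrix tr_mass(ntrace, 5);

  int nsnap = 0;
  if (snap_stride > 0 && snap_start <= nsteps)
    nsnap = (nsteps - snap_start) / snap_stride + 1;
  NumericVector snap_t(nsnap);
  NumericMatrix sCD(nsnap > 0 ? n : 1, std::max(nsnap, 1)),
      sCT(nsnap > 0 ? n : 1, std::max(nsnap, 1)),
      sGI(nsnap > 0 ? n : 1, std::max(nsnap, 1)),
      sGF(nsnap > 0 ? n : 1, std::max(nsnap, 1)),
      sGS(nsnap > 0 ? n : 1, std::max(nsnap, 1)),
      sGEF(nsnap > 0 ? n : 1, std::max(nsnap, 1));

  RNGScope rng;
  double Ec = Ectot;

  auto refresh_gef = [&]() {
    double S = 0.0;
    for (int i = 0; i < n; ++i) {
      const double g = (k1p * CT[i] + k2p * CT[i] * CT[i]) / V;
      CGEF[i] = g;            // temporarily the unscaled weight
      S += g * areas[i];
    }
    Ec = Ectot / (1.0 + S);
    for (int i = 0; i < n; ++i) CGEF[i] *= Ec;
  };

  auto record_trace = [&](int slot, double t) {
    tr_t[slot] = t;
    double s1 = 0.0, s2 = 0.0, mcd = 0.0, mct = 0.0, mgi = 0.0, mgf = 0.0, mgs = 0.0;
    for (int k = 0; k < tip1_idx.size(); ++k) s1 += CT[tip1_idx[k]] * areas[tip1_idx[k]];
    for (int k = 0; k < tip2_idx.size(); ++k) s2 += CT[tip2_idx[k]] * areas[tip2_idx[k]];
    tr_tip1[slot] = s1 / a_tip1;
    tr_tip2[slot] = s2 / a_tip2;
    tr_Ec[slot] = Ec;
    for (int i = 0; i < n; ++i) {
      mcd += CD[i] * areas[i]; mct += CT[i] * areas[i]; mgi += GI[i] * areas[i];
      mgf += GF[i] * areas[i]; mgs += GS[i] * areas[i];
    }
    tr_mass(slot, 0) = mcd; tr_mass(slot, 1) = mct; tr_mass(slot, 2) = mgi;
    tr_mass(slot, 3) = mgf; tr_mass(slot, 4) = mgs;
  };

  auto record_snap = [&](int slot, double t) {
    snap_t[slot] = t;
    for (int i = 0; i < n; ++i) {
      sCD(i, slot) = CD[i]; sCT(i, slot) = CT[i]; sGI(i, slot) = GI[i];
      sGF(i, slot) = GF[i]; sGS(i, slot) = GS[i]; sGEF(i, slot) = CGEF[i];
    }
  };

  refresh_gef();
  record_trace(0, t0);
  int snap_slot = 0;
  if (nsnap > 0 && snap_start == 0) record_snap(snap_slot++, t0);

  for (int step = 1; step <= nsteps; ++step) {
    lap5(Wp, Wi, Wx, n, CD, CT, GI, GF, GS, lcd, lct, lgi, lgf, lgs);

    for (int i = 0; i < n; ++i) {
      const double inv_a = 1.0 / areas[i];
      const double cd = CD[i], ct = CT[i], gi = GI[i], gf = GF[i], gs = GS[i];
      const double hyd = (k1n + k2n * gi + k3n * gf + k8n * gs) * ct;
      const double act = k0p * bias[i] * CGEF[i] * cd;
      double dcd = DD * lcd[i] * inv_a + jDp + hyd - act - rD * cd;
      double dct = DT * lct[i] * inv_a + act - hyd - rT * ct;
      if (noise_mode == 1) {
        dcd -= rnoise * cd;
        dct += rnoise * cd;
      }
      const double cth = h_is_2 ? ct * ct : std::pow(ct, hexp);
      const double dgi = DGI * lgi[i] * inv_a + k4n * cth / (ksat_h + cth) - rGI * gi;
      const double conv = k6n * gf - k7n * gs * ct;
      const double dgf = DGF * lgf[i] * inv_a + k5n * ct - conv - rGF * gf;
      const double dgs = DGS * lgs[i] * inv_a + conv - rGS * gs;
      CD[i] = cd + dt * dcd;
      CT[i] = ct + dt * dct;
      GI[i] = gi + dt * dgi;
      GF[i] = gf + dt * dgf;
      GS[i] = gs + dt * dgs;
    }

    // roundoff clamp vs. instability abort
    for (int i = 0; i < n; ++i) {
      if (CD[i] < 0 || CT[i] < 0 || GI[i] < 0 || GF[i] < 0 || GS[i] < 0) {
        const char* nm = CD[i] < 0 ? "CD" : CT[i] < 0 ? "CT" : GI[i] < 0 ? "CGAPI"
                          : GF[i] < 0 ? "CGAPIIfast" : "CGAPIIslow";
        double v = std::min(std::min(CD[i], CT[i]), std::min(GI[i], std::min(GF[i], GS[i])));
        if (v < -1e-9)
          stop("numerical instability: field %s reached %.3e at t = %.2f s",
               nm, v, t0 + step * dt);
        if (CD[i] < 0) CD[i] = 0;
        if (CT[i] < 0) CT[i] = 0;
        if (GI[i] < 0) GI[i] = 0;
        if (GF[i] < 0) GF[i] = 0;
        if (GS[i] < 0) GS[i] = 0;
      }
    }

    if (noise_mode == 2 && rnoise > 0) {
      // superposition of per-node Poisson events: total count is Poisson
      // with the summed mean, nodes assigned by mass-weighted inverse CDF
      double S = 0.0;
      for (int i = 0; i < n; ++i) S += CD[i] * areas[i];
      const int nev = (int) R::rpois(rnoise * dt * S);
      for (int e = 0; e < nev; ++e) {
        double u = unif_rand() * S, acc = 0.0;
        int i = n - 1;
        for (int k = 0; k < n; ++k) {
          acc += CD[k] * areas[k];
          if (u <= acc) { i = k; break; }
        }
        const double conv = std::min(1.0, CD[i] * areas[i]) / areas[i];
        CD[i] -= conv;
        CT[i] += conv;
      }
    }

    refresh_gef();

    if (step % trace_stride == 0) record_trace(step / trace_stride, t0 + step * dt);
    if (nsnap > 0 && step >= snap_start && (step - snap_start) % snap_stride == 0)
      record_snap(snap_slot++, t0 + step * dt);
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  List snaps = R_NilValue;
  if (nsnap > 0)
    snaps = List::create(_["t"] = snap_t, _["CD"] = sCD, _["CT"] = sCT,
                         _["CGAPI"] = sGI, _["CGAPIIfast"] = sGF,
                         _["CGAPIIslow"] = sGS, _["CGEF"] = sGEF);

  List fin = List::create(
      _["CD"] = NumericVector(CD.begin(), CD.end()),
      _["CT"] = NumericVector(CT.begin(), CT.end()),
      _["CGAPI"] = NumericVector(GI.begin(), GI.end()),
      _["CGAPIIfast"] = NumericVector(GF.begin(), GF.end()),
      _["CGAPIIslow"] = NumericVector(GS.begin(), GS.end()),
      _["CGEF"] = NumericVector(CGEF.begin(), CGEF.end()),
      _["Ec"] = Ec, _["t"] = t0 + nsteps * dt);

  return List::create(
      _["times"] = tr_t, _["tip1"] = tr_tip1, _["tip2"] = tr_tip2,
      _["Ec"] = tr_Ec, _["mass"] = tr_mass, _["snapshots"] = snaps,
      _["final"] = fin);
}
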