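// Core simulation engine: sparse synapse sampling, the synchronous
// membrane/spike/trace update, and the two-threshold Hebbian rule.
// All randomness goes through R's RNG so runs are reproducible from
// set.seed() and (where a noise matrix is supplied) bit-comparable to
// the scalar R reference used in the tests.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Engine {
  // layout
  int nC = 0;              // total cells (e then i)
  int nE = 0;              // excitatory cells, indices [0, nE)
  int nAreas = 0;
  std::vector<int> area;   // area id per cell (0-based)
  std::vector<int> eCount; // e-cells per area

  // weights, CSC over all cells: column = presynaptic cell
  std::vector<int> p, ri;
  std::vector<double> x;
  // CSR index over plastic (e->e) entries, rows = postsynaptic e-cell
  std::vector<int> rp, rc, rx;

  // parameters
  double tau_e, tau_i, k1, k2, kG, thresh, alpha, alpha_adapt;
  double tau_adapt, tau_glob, theta_plus, theta_minus, theta_pre;
  double theta_zero, delta_w, w_max;

  // state
  std::vector<double> V, wAdapt, wE, wG, phiPrev, phiNew, synIn;
  std::vector<int> areaSpk;

  void resetState(bool full) {
    std::fill(V.begin(), V.end(), 0.0);
    std::fill(phiPrev.begin(), phiPrev.end(), 0.0);
    if (full) {
      std::fill(wAdapt.begin(), wAdapt.end(), 0.0);
      std::fill(wE.begin(), wE.end(), 0.0);
      std::fill(wG.begin(), wG.end(), 0.0);
    }
  }

  void plasticityPass() {
    // LTP + homosynaptic LTD: active presynaptic columns
    for (int pre = 0; pre < nE; ++pre) {
      if (wE[pre] < theta_pre) continue;
      for (int k = p[pre]; k < p[pre + 1]; ++k) {
        int post = ri[k];
        if (post >= nE) continue;           // e->i links are not plastic
        double v = V[post];
        if (v >= theta_plus) {
          x[k] += delta_w;
          if (x[k] > w_max) x[k] = w_max;
        } else if (v >= theta_minus) {
          x[k] -= delta_w;
          if (x[k] < 0.0) x[k] = 0.0;
        }
      }
    }
    // heterosynaptic LTD: strongly depolarized posts whose presynaptic
    // input is truly silent (rate estimate below theta_zero); pres in the
    // neutral band [theta_zero, theta_pre) are neither potentiated nor
    // depressed
    for (int post = 0; post < nE; ++post) {
      if (V[post] < theta_plus) continue;
      for (int k = rp[post]; k < rp[post + 1]; ++k) {
        int pre = rc[k];
        if (wE[pre] >= theta_zero) continue;
        int xi = rx[k];
        x[xi] -= delta_w;
        if (x[xi] < 0.0) x[xi] = 0.0;
      }
    }
  }

  // One synchronous step. stim: external drive per e-cell (raw units, added
  // into the net input before k1 rescaling). noise: pointer to nE noise
  // values in [-0.5, 0.5], or nullptr to draw from R's RNG (noiseOn) /
  // disable (!noiseOn). Returns max fraction of an area's e-cells firing.
  double step(const double* stim, const double* noise, bool noiseOn,
              bool learn, double tau_favg) {
    // (1) synaptic input from previous outputs
    std::fill(synIn.begin(), synIn.end(), 0.0);
    for (int y = 0; y < nC; ++y) {
      double o = phiPrev[y];
      if (o == 0.0) continue;
      for (int k = p[y]; k < p[y + 1]; ++k) synIn[ri[k]] += x[k] * o;
    }
    // (2) membrane integration (Euler, dt = 1). Weights are effective
    // couplings: k1 rescales the external drive, global inhibition and
    // noise, while the synaptic sum enters directly (see the package
    // vignette on the input-scaling convention).
    for (int c = 0; c < nE; ++c) {
      double eta = noise ? noise[c] : (noiseOn ? (unif_rand() - 0.5) : 0.0);
      double vin = synIn[c] +
        k1 * ((stim ? stim[c] : 0.0) - kG * wG[area[c]] + k2 * eta);
      V[c] += (-V[c] + vin) / tau_e;
    }
    for (int c = nE; c < nC; ++c)
      V[c] += (-V[c] + synIn[c]) / tau_i;
    for (int c = 0; c < nC; ++c)
      if (!std::isfinite(V[c]))
        stop("non-finite membrane potential at cell %d (membrane stage)", c + 1);
    // (3) outputs
    std::fill(areaSpk.begin(), areaSpk.end(), 0);
    for (int c = 0; c < nE; ++c) {
      double f = (V[c] - alpha * wAdapt[c]) > thresh ? 1.0 : 0.0;
      phiNew[c] = f;
      if (f != 0.0) ++areaSpk[area[c]];
    }
    for (int c = nE; c < nC; ++c) phiNew[c] = V[c] > 0.0 ? V[c] : 0.0;
    // (4) trace updates
    for (int c = 0; c < nE; ++c) {
      wAdapt[c] += (-wAdapt[c] + alpha_adapt * phiNew[c]) / tau_adapt;
      wE[c] += (-wE[c] + phiNew[c]) / tau_favg;
    }
    double maxFrac = 0.0;
    for (int a = 0; a < nAreas; ++a) {
      wG[a] += (-wG[a] + (double)areaSpk[a]) / tau_glob;
      double frac = (double)areaSpk[a] / (double)eCount[a];
      if (frac > maxFrac) maxFrac = frac;
    }
    if (learn) plasticityPass();
    std::copy(phiNew.begin(), phiNew.end(), phiPrev.begin());
    return maxFrac;
  }
};

double getPar(const List& pars, const char* nm) {
  if (!pars.containsElementNamed(nm)) stop("missing engine parameter '%s'", nm);
  return as<double>(pars[nm]);
}

} // namespace

// [[Rcpp::export]]
List cpp_sample_network(int nAreas, int g, IntegerVector edgeFrom,
                        IntegerVector edgeTo, List kernels,
                        double wInitMax, double wInhibMax, bool torus) {
  List kw = kernels["ee_within"], kb = kernels["ee_between"], ki = kernels["ie"];
  double cpw = kw["center_prob"], sw = kw["sigma"];
  double cpb = kb["center_prob"], sb = kb["sigma"];
  double cpi = ki["center_prob"], si = ki["sigma"];
  int nbw = kw["neighborhood"], nbb = kb["neighborhood"], nbi = ki["neighborhood"];
  int nPerArea = g * g, nE = nAreas * nPerArea;

  std::vector<int> outI, outJ;
  std::vector<double> outX;
  outI.reserve(1 << 20); outJ.reserve(1 << 20); outX.reserve(1 << 20);

  auto sampleKernel = [&](int preBase, int postBase, double cp, double sigma,
                          int nb, bool skipSelf, double sign) {
    int h = nb / 2;
    double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    for (int pre = 0; pre < nPerArea; ++pre) {
      int pr = pre / g, pc = pre % g;
      for (int dy = -h; dy <= h; ++dy) {
        for (int dx = -h; dx <= h; ++dx) {
          int r = pr + dy, c = pc + dx;
          if (torus) {
            r = ((r % g) + g) % g;
            c = ((c % g) + g) % g;
          } else if (r < 0 || r >= g || c < 0 || c >= g) {
            continue;
          }
          int post = r * g + c;
          if (skipSelf && post == pre && preBase == postBase) continue;
          double pr2 = cp * std::exp(-(double)(dx * dx + dy * dy) * inv2s2);
          if (unif_rand() < pr2) {
            outI.push_back(postBase + post);
            outJ.push_back(preBase + pre);
            outX.push_back(sign * unif_rand() * wInitMax);
          }
        }
      }
    }
  };

  double rho = wInitMax > 0 ? wInhibMax / wInitMax : 0.0;
  for (int a = 0; a < nAreas; ++a) {
    int eb = a * nPerArea, ib = nE + a * nPerArea;
    sampleKernel(eb, eb, cpw, sw, nbw, true, 1.0);    // e -> e within area
    sampleKernel(eb, ib, cpi, si, nbi, false, rho);   // e -> i (mirrored kernel)
    sampleKernel(ib, eb, cpi, si, nbi, false, -rho);  // i -> e (negative sign)
  }
  for (int k = 0; k < edgeFrom.size(); ++k) {        // between-area e -> e
    int ea = edgeFrom[k] * nPerArea, ebb = edgeTo[k] * nPerArea;
    sampleKernel(ea, ebb, cpb, sb, nbb, false, 1.0);
  }
  return List::create(_["i"] = Rcpp::wrap(outI), _["j"] = Rcpp::wrap(outJ),
                      _["x"] = Rcpp::wrap(outX));
}

// [[Rcpp::export]]
SEXP cpp_engine_create(IntegerVector p, IntegerVector ri, NumericVector x,
                       int nE, IntegerVector areaOf, IntegerVector eCount,
                       List pars) {
  Engine* e = new Engine();
  e->nC = p.size() - 1;
  e->nE = nE;
  e->nAreas = eCount.size();
  e->area.assign(areaOf.begin(), areaOf.end());
  e->eCount.assign(eCount.begin(), eCount.end());
  e->p.assign(p.begin(), p.end());
  e->ri.assign(ri.begin(), ri.end());
  e->x.assign(x.begin(), x.end());

  e->tau_e = getPar(pars, "tau_e");       e->tau_i = getPar(pars, "tau_i");
  e->k1 = getPar(pars, "k1");             e->k2 = getPar(pars, "k2");
  e->kG = getPar(pars, "k_G");            e->thresh = getPar(pars, "thresh");
  e->alpha = getPar(pars, "alpha");       e->alpha_adapt = getPar(pars, "alpha_adapt");
  e->tau_adapt = getPar(pars, "tau_adapt"); e->tau_glob = getPar(pars, "tau_glob");
  e->theta_plus = getPar(pars, "theta_plus");
  e->theta_minus = getPar(pars, "theta_minus");
  e->theta_pre = getPar(pars, "theta_pre");
  e->theta_zero = getPar(pars, "theta_zero");
  e->delta_w = getPar(pars, "delta_w");   e->w_max = getPar(pars, "w_max");

  // CSR index over plastic e->e entries for the heterosynaptic pass
  std::vector<int> rowCnt(nE, 0);
  for (int col = 0; col < nE; ++col)
    for (int k = e->p[col]; k < e->p[col + 1]; ++k)
      if (e->ri[k] < nE) ++rowCnt[e->ri[k]];
  e->rp.assign(nE + 1, 0);
  for (int r = 0; r < nE; ++r) e->rp[r + 1] = e->rp[r] + rowCnt[r];
  e->rc.assign(e->rp[nE], 0);
  e->rx.assign(e->rp[nE], 0);
  std::vector<int> cur(e->rp.begin(), e->rp.end() - 1);
  for (int col = 0; col < nE; ++col)
    for (int k = e->p[col]; k < e->p[col + 1]; ++k) {
      int r = e->ri[k];
      if (r < nE) { e->rc[cur[r]] = col; e->rx[cur[r]] = k; ++cur[r]; }
    }

  e->V.assign(e->nC, 0.0);
  e->wAdapt.assign(nE, 0.0);
  e->wE.assign(nE, 0.0);
  e->wG.assign(e->nAreas, 0.0);
  e->phiPrev.assign(e->nC, 0.0);
  e->phiNew.assign(e->nC, 0.0);
  e->synIn.assign(e->nC, 0.0);
  e->areaSpk.assign(e->nAreas, 0);

  XPtr<Engine> ptr(e, true);
  return ptr;
}

// [[Rcpp::export]]
void cpp_engine_reset(SEXP eng, bool full) {
  XPtr<Engine> e(eng);
  e->resetState(full);
}

// [[Rcpp::export]]
NumericVector cpp_engine_weights(SEXP eng) {
  XPtr<Engine> e(eng);
  return NumericVector(e->x.begin(), e->x.end());
}

// [[Rcpp::export]]
void cpp_engine_set_weights(SEXP eng, NumericVector x) {
  XPtr<Engine> e(eng);
  if ((int)e->x.size() != x.size()) stop("weight vector length mismatch");
  std::copy(x.begin(), x.end(), e->x.begin());
}

// [[Rcpp::export]]
List cpp_engine_state(SEXP eng) {
  XPtr<Engine> e(eng);
  return List::create(
    _["V"] = NumericVector(e->V.begin(), e->V.end()),
    _["adapt"] = NumericVector(e->wAdapt.begin(), e->wAdapt.end()),
    _["rate"] = NumericVector(e->wE.begin(), e->wE.end()),
    _["glob"] = NumericVector(e->wG.begin(), e->wG.end()),
    _["phi"] = NumericVector(e->phiPrev.begin(), e->phiPrev.end()));
}

// [[Rcpp::export]]
void cpp_engine_set_state(SEXP eng, NumericVector V, NumericVector adapt,
                          NumericVector rate, NumericVector glob,
                          NumericVector phi) {
  XPtr<Engine> e(eng);
  if (V.size() != (int)e->V.size() || phi.size() != (int)e->phiPrev.size() ||
      adapt.size() != (int)e->wAdapt.size() || rate.size() != (int)e->wE.size() ||
      glob.size() != (int)e->wG.size())
    stop("state vector length mismatch");
  std::copy(V.begin(), V.end(), e->V.begin());
  std::copy(adapt.begin(), adapt.end(), e->wAdapt.begin());
  std::copy(rate.begin(), rate.end(), e->wE.begin());
  std::copy(glob.begin(), glob.end(), e->wG.begin());
  std::copy(phi.begin(), phi.end(), e->phiPrev.begin());
}

// [[Rcpp::export]]
void cpp_engine_plasticity(SEXP eng) {
  XPtr<Engine> e(eng);
  e->plasticityPass();
}

// Run nsteps. stim: length-nE drive (or NULL). noiseMat: nE x nsteps matrix
// of eta values (or NULL: draw fresh noise when noiseOn). record: 0 none,
// 1 rate estimates, 2 spikes. gateThr/gateAreas: stop early once the global
// inhibition of every gate area falls below gateThr (NA thr = no gate).
// [[Rcpp::export]]
List cpp_engine_run(SEXP eng, int nsteps, Nullable<NumericVector> stim,
                    bool learn, double tau_favg, bool noiseOn,
                    Nullable<NumericMatrix> noiseMat, int record,
                    double gateThr, IntegerVector gateAreas) {
  XPtr<Engine> e(eng);
  const double* stimPtr = nullptr;
  NumericVector stimV;
  if (stim.isNotNull()) {
    stimV = stim.get();
    if (stimV.size() != e->nE) stop("stim must have one entry per e-cell");
    stimPtr = REAL(stimV);
  }
  NumericMatrix nm;
  bool haveNoise = noiseMat.isNotNull();
  if (haveNoise) {
    nm = noiseMat.get();
    if (nm.nrow() != e->nE || nm.ncol() < nsteps)
      stop("noise matrix must be nE x nsteps");
  }
  NumericMatrix recRate;
  IntegerMatrix recSpk;
  if (record == 1) recRate = NumericMatrix(e->nE, nsteps);
  if (record == 2) recSpk = IntegerMatrix(e->nE, nsteps);
  bool gate = R_finite(gateThr);

  int done = 0, hotSteps = 0;
  for (int t = 0; t < nsteps; ++t) {
    const double* noisePtr = haveNoise ? &nm(0, t) : nullptr;
    double frac = e->step(stimPtr, noisePtr, noiseOn, learn, tau_favg);
    if (frac > 0.9) ++hotSteps;
    if (record == 1)
      for (int c = 0; c < e->nE; ++c) recRate(c, t) = e->wE[c];
    if (record == 2)
      for (int c = 0; c < e->nE; ++c) recSpk(c, t) = (int)e->phiPrev[c];
    ++done;
    if (gate) {
      bool quiet = true;
      for (int k = 0; k < gateAreas.size(); ++k)
        if (e->wG[gateAreas[k]] >= gateThr) { quiet = false; break; }
      if (quiet) break;
    }
  }
  List out = List::create(_["steps"] = done, _["hot_steps"] = hotSteps);
  if (record == 1) out["rates"] = recRate;
  if (record == 2) out["spikes"] = recSpk;
  return out;
}
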