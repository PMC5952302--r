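// Core integration engine: adaptive Dormand-Prince RK45 for the coupled
// Hodgkin-Huxley ring with event-based STDP and alpha-function stimulation.
// All randomness lives on the R side; this code is fully deterministic.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double SINGULARITY_EPS = 1e-7;

// u/(1 - exp(-u)) with its removable singularity at u = 0.
static inline double expm1_ratio(double u) {
  if (std::fabs(u) < SINGULARITY_EPS) return 1.0;
  return u / (1.0 - std::exp(-u));
}

struct Rates {
  double am, bm, ah, bh, an, bn;
};

static inline Rates hh_rates(double V) {
  Rates r;
  r.am = expm1_ratio(0.1 * V + 4.0);
  r.bm = 4.0 * std::exp((-V - 65.0) / 18.0);
  r.ah = 0.07 * std::exp((-V - 65.0) / 20.0);
  r.bh = 1.0 / (1.0 + std::exp(-0.1 * V - 3.5));
  r.an = 0.1 * expm1_ratio(0.1 * V + 5.5);
  r.bn = 0.125 * std::exp((-V - 65.0) / 80.0);
  return r;
}

// Exported for cross-checking against the plain-R reference implementation.
// [[Rcpp::export]]
NumericVector hh_rates_cpp(double V) {
  Rates r = hh_rates(V);
  return NumericVector::create(
    _["alpha_m"] = r.am, _["beta_m"] = r.bm,
    _["alpha_h"] = r.ah, _["beta_h"] = r.bh,
    _["alpha_n"] = r.an, _["beta_n"] = r.bn);
}

struct NetConst {
  int N;
  double C, gNa, gK, gl, VNa, VK, Vl, Vr_exc;
};

// Right-hand side of the coupled system. y is laid out [V | m | h | n | s].
// stim_pf[i] = K * sum_k D(i, x_k) * G_k(t) is supplied by the caller so the
// same routine serves both the integrator and the exported test hook.
static void rhs(const NetConst& nc,
                const double* y, double* dy,
                const double* Iinj,
                const double* c, const double* absM, const double* Vr,
                const double* stim_pf) {
  const int N = nc.N;
  const double* V = y;
  const double* m = y + N;
  const double* h = y + 2 * N;
  const double* n = y + 3 * N;
  const double* s = y + 4 * N;

  std::vector<double> accVr(N, 0.0), acc(N, 0.0);
  for (int j = 0; j < N; ++j) {
    const double sj = s[j];
    if (sj == 0.0) continue;
    const double* cj = c + (size_t)N * j;
    const double* aj = absM + (size_t)N * j;
    const double* vj = Vr + (size_t)N * j;
    for (int i = 0; i < N; ++i) {
      const double w = cj[i] * aj[i] * sj;
      accVr[i] += w * vj[i];
      acc[i] += w;
    }
  }

  for (int i = 0; i < N; ++i) {
    const double Vi = V[i];
    const double S = (accVr[i] - Vi * acc[i]) / N;
    const double F = (nc.Vr_exc - Vi) * stim_pf[i];
    const double INa = nc.gNa * m[i] * m[i] * m[i] * h[i] * (Vi - nc.VNa);
    const double IK = nc.gK * n[i] * n[i] * n[i] * n[i] * (Vi - nc.VK);
    const double Il = nc.gl * (Vi - nc.Vl);
    dy[i] = (Iinj[i] - INa - IK - Il + S + F) / nc.C;
    Rates r = hh_rates(Vi);
    dy[N + i] = r.am * (1.0 - m[i]) - r.bm * m[i];
    dy[2 * N + i] = r.ah * (1.0 - h[i]) - r.bh * h[i];
    dy[3 * N + i] = r.an * (1.0 - n[i]) - r.bn * n[i];
    dy[4 * N + i] = 0.5 * (1.0 - s[i]) / (1.0 + std::exp(-(Vi + 5.0) / 12.0))
      - 2.0 * s[i];
  }
}

// [[Rcpp::export]]
NumericMatrix hh_rhs_cpp(NumericVector V, NumericVector m, NumericVector h,
                         NumericVector n, NumericVector s, NumericVector Iinj,
                         NumericMatrix c, NumericMatrix absM, NumericMatrix Vr,
                         NumericVector F_current, List net) {
  NetConst nc;
  nc.N = V.size();
  nc.C = as<double>(net["C"]);
  nc.gNa = as<double>(net["g_Na"]);
  nc.gK = as<double>(net["g_K"]);
  nc.gl = as<double>(net["g_l"]);
  nc.VNa = as<double>(net["V_Na"]);
  nc.VK = as<double>(net["V_K"]);
  nc.Vl = as<double>(net["V_l"]);
  nc.Vr_exc = as<double>(net["V_r_exc"]);
  const int N = nc.N;
  std::vector<double> y(5 * N), dy(5 * N), pf(N);
  for (int i = 0; i < N; ++i) {
    y[i] = V[i]; y[N + i] = m[i]; y[2 * N + i] = h[i];
    y[3 * N + i] = n[i]; y[4 * N + i] = s[i];
    // caller supplies the full stimulation current; fold it into the
    // driving-force form used internally: F = (Vr_exc - V) * pf
    double drive = nc.Vr_exc - V[i];
    pf[i] = (std::fabs(drive) > 1e-12) ? F_current[i] / drive : 0.0;
  }
  rhs(nc, y.data(), dy.data(), REAL(Iinj), REAL(c), REAL(absM), REAL(Vr),
      pf.data());
  NumericMatrix out(N, 5);
  for (int i = 0; i < N; ++i)
    for (int q = 0; q < 5; ++q) out(i, q) = dy[q * N + i];
  colnames(out) = CharacterVector::create("V", "m", "h", "n", "s");
  return out;
}

// Dormand-Prince 5(4) tableau.
static const double A21 = 1.0 / 5.0;
static const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
static const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
static const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
  A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
static const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
  A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0, A65 = -5103.0 / 18656.0;
static const double B1 = 35.0 / 384.0, B3 = 500.0 / 1113.0,
  B4 = 125.0 / 192.0, B5 = -2187.0 / 6784.0, B6 = 11.0 / 84.0;
static const double E1 = 71.0 / 57600.0, E3 = -71.0 / 16695.0,
  E4 = 71.0 / 1920.0, E5 = -17253.0 / 339200.0, E6 = 22.0 / 525.0,
  E7 = -1.0 / 40.0;

struct SpikeEvent {
  double t;
  int neuron;
};

// [[Rcpp::export]]
List sim_period_cpp(List state, List net, List stdp,
                    double duration_ms, bool stdp_enabled,
                    NumericVector onset_times, IntegerVector onset_sites,
                    NumericMatrix site_profile, double K,
                    double Ts, double tau_alpha,
                    double rtol, double atol, double hmax,
                    double metric_dt, double lockout_ms) {
  NetConst nc;
  NumericVector V0 = state["V"], m0 = state["m"], h0 = state["h"],
    n0 = state["n"], s0 = state["s"], Iinj = state["I"],
    last_spike0 = state["last_spike"];
  NumericMatrix c0 = state["c"];
  double t0 = as<double>(state["t"]);
  nc.N = V0.size();
  const int N = nc.N;
  nc.C = as<double>(net["C"]);
  nc.gNa = as<double>(net["g_Na"]);
  nc.gK = as<double>(net["g_K"]);
  nc.gl = as<double>(net["g_l"]);
  nc.VNa = as<double>(net["V_Na"]);
  nc.VK = as<double>(net["V_K"]);
  nc.Vl = as<double>(net["V_l"]);
  nc.Vr_exc = as<double>(net["V_r_exc"]);
  const double Vr_inh = as<double>(net["V_r_inh"]);

  NumericMatrix absM_in = net["abs_M"];
  IntegerMatrix Msign_in = net["sign_M"];
  const int Ns = site_profile.ncol();

  const double beta1 = as<double>(stdp["beta1"]);
  const double beta2 = as<double>(stdp["beta2"]);
  const double gamma1 = as<double>(stdp["gamma1"]);
  const double gamma2 = as<double>(stdp["gamma2"]);
  const double tau = as<double>(stdp["tau"]);
  const double delta = as<double>(stdp["delta"]);
  const double c_min = as<double>(stdp["c_min"]);
  const double c_max = as<double>(stdp["c_max"]);

  // working copies
  std::vector<double> y(5 * N);
  for (int i = 0; i < N; ++i) {
    y[i] = V0[i]; y[N + i] = m0[i]; y[2 * N + i] = h0[i];
    y[3 * N + i] = n0[i]; y[4 * N + i] = s0[i];
  }
  std::vector<double> c(c0.begin(), c0.end());
  std::vector<double> absM(absM_in.begin(), absM_in.end());
  std::vector<int> Msign(Msign_in.begin(), Msign_in.end());
  std::vector<double> Vr((size_t)N * N);
  for (size_t q = 0; q < Vr.size(); ++q)
    Vr[q] = (Msign[q] > 0) ? nc.Vr_exc : Vr_inh;
  std::vector<double> last_spike(last_spike0.begin(), last_spike0.end());

  // synapse-type bookkeeping for O(1) connectivity metrics
  long nEE = 0, nII = 0;
  double sumE = 0.0, sumI = 0.0;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      if (i == j) continue;
      const size_t q = (size_t)i + (size_t)N * j;
      if (Msign[q] > 0) { ++nEE; sumE += c[q]; }
      else if (Msign[q] < 0) { ++nII; sumI += c[q]; }
    }
  const double N2 = (double)N * (double)N;
  const double NEE2 = (double)nEE * (double)nEE;
  const double NII2 = (double)nII * (double)nII;

  // per-site onset lists (times already sorted ascending overall)
  std::vector<std::vector<double>> site_onsets(Ns);
  for (int q = 0; q < onset_times.size(); ++q) {
    int k = onset_sites[q] - 1;
    if (k < 0 || k >= Ns) stop("onset site index out of range");
    site_onsets[k].push_back(onset_times[q]);
  }
  for (int k = 0; k < Ns; ++k)
    if (!std::is_sorted(site_onsets[k].begin(), site_onsets[k].end()))
      stop("per-site onsets must be sorted ascending");
  std::vector<size_t> site_ptr(Ns, 0); // index of first onset > t

  // integration segment boundaries: every onset plus the period end
  const double t_end = t0 + duration_ms;
  std::vector<double> boundaries;
  for (int q = 0; q < onset_times.size(); ++q)
    if (onset_times[q] > t0 && onset_times[q] < t_end)
      boundaries.push_back(onset_times[q]);
  boundaries.push_back(t_end);
  std::sort(boundaries.begin(), boundaries.end());
  boundaries.erase(std::unique(boundaries.begin(), boundaries.end()),
                   boundaries.end());

  const double alpha_cutoff = Ts / 2.0;
  std::vector<double> pf(N), gk(Ns);
  auto stim_profile = [&](double t) {
    if (K == 0.0 || onset_times.size() == 0) {
      std::fill(pf.begin(), pf.end(), 0.0);
      return;
    }
    bool any = false;
    for (int k = 0; k < Ns; ++k) {
      // advance pointer: site_ptr[k] = count of onsets <= t
      const std::vector<double>& on = site_onsets[k];
      size_t& p = site_ptr[k];
      while (p < on.size() && on[p] <= t) ++p;
      double g = 0.0;
      // at most the two most recent onsets can overlap within Ts/2
      for (int back = 1; back <= 2; ++back) {
        if (p < (size_t)back) break;
        double dt = t - on[p - back];
        if (dt >= 0.0 && dt <= alpha_cutoff) {
          double u = dt / tau_alpha;
          g += u * std::exp(-u);
        }
      }
      gk[k] = g;
      if (g > 0.0) any = true;
    }
    if (!any) { std::fill(pf.begin(), pf.end(), 0.0); return; }
    for (int i = 0; i < N; ++i) {
      double acc = 0.0;
      for (int k = 0; k < Ns; ++k)
        if (gk[k] > 0.0) acc += site_profile(i, k) * gk[k];
      pf[i] = K * acc;
    }
  };

  // NOTE: site_ptr advances monotonically; RK stages sample t within the
  // current segment, which contains no onset, so re-evaluating the profile
  // at stage times never needs to rewind the pointer.

  // outputs
  std::vector<int> raster_neuron;
  std::vector<double> raster_time;
  std::vector<double> met_t, met_cav, met_cee, met_cii;
  long n_steps = 0, n_rejected = 0, n_spikes = 0;

  double next_mark = t0 + metric_dt;
  auto record_marks_upto = [&](double tlim) {
    while (next_mark <= tlim + 1e-12 && next_mark <= t_end + 1e-12) {
      met_t.push_back(next_mark);
      met_cav.push_back((sumE - sumI) / N2);
      met_cee.push_back(nEE > 0 ? sumE / NEE2 : 0.0);
      met_cii.push_back(nII > 0 ? sumI / NII2 : 0.0);
      next_mark += metric_dt;
    }
  };

  auto apply_stdp_event = [&](int i, double ts) {
    // pair neuron i's new spike with every partner's most recent spike
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      const double lj = last_spike[j];
      if (ISNAN(lj)) continue;
      {
        // incoming synapse j -> i, post = i spikes now: dt >= 0 branch
        const size_t q = (size_t)i + (size_t)N * j;
        const int sg = Msign[q];
        if (sg != 0) {
          const double dt = ts - lj;
          const double dc = beta1 * std::exp(-dt / (gamma1 * tau));
          double w = c[q] + (sg > 0 ? delta * dc : -delta * dc);
          w = std::min(c_max, std::max(c_min, w));
          const double dW = w - c[q];
          if (sg > 0) sumE += dW; else sumI += dW;
          c[q] = w;
        }
      }
      {
        // outgoing synapse i -> j, post = j spiked earlier: dt <= 0 branch
        const size_t q = (size_t)j + (size_t)N * i;
        const int sg = Msign[q];
        if (sg != 0) {
          const double dt = lj - ts;
          double dc;
          if (dt >= 0.0) dc = beta1 * std::exp(-dt / (gamma1 * tau));
          else dc = beta2 * (dt / tau) * std::exp(dt / (gamma2 * tau));
          double w = c[q] + (sg > 0 ? delta * dc : -delta * dc);
          w = std::min(c_max, std::max(c_min, w));
          const double dW = w - c[q];
          if (sg > 0) sumE += dW; else sumI += dW;
          c[q] = w;
        }
      }
    }
    last_spike[i] = ts;
  };

  const int nvar = 5 * N;
  std::vector<double> k1(nvar), k2(nvar), k3(nvar), k4(nvar), k5(nvar),
    k6(nvar), k7(nvar), ytmp(nvar), ynew(nvar), yerr(nvar);
  std::vector<double> Vold(N);
  std::vector<SpikeEvent> events;

  double t = t0;
  double hstep = std::min(0.01, hmax);
  bool have_k1 = false;

  for (size_t bseg = 0; bseg < boundaries.size(); ++bseg) {
    const double seg_end = boundaries[bseg];
    have_k1 = false; // restart at every stimulation onset (waveform kink)
    while (t < seg_end - 1e-12) {
      double hcur = std::min(hstep, seg_end - t);
      hcur = std::min(hcur, hmax);
      if (!have_k1) {
        stim_profile(t);
        rhs(nc, y.data(), k1.data(), REAL(Iinj), c.data(), absM.data(),
            Vr.data(), pf.data());
        have_k1 = true;
      }
      bool accepted = false;
      while (!accepted) {
        // stages
        for (int q = 0; q < nvar; ++q)
          ytmp[q] = y[q] + hcur * A21 * k1[q];
        stim_profile(t + 0.2 * hcur);
        rhs(nc, ytmp.data(), k2.data(), REAL(Iinj), c.data(), absM.data(),
            Vr.data(), pf.data());
        for (int q = 0; q < nvar; ++q)
          ytmp[q] = y[q] + hcur * (A31 * k1[q] + A32 * k2[q]);
        stim_profile(t + 0.3 * hcur);
        rhs(nc, ytmp.data(), k3.data(), REAL(Iinj), c.data(), absM.data(),
            Vr.data(), pf.data());
        for (int q = 0; q < nvar; ++q)
          ytmp[q] = y[q] + hcur * (A41 * k1[q] + A42 * k2[q] + A43 * k3[q]);
        stim_profile(t + 0.8 * hcur);
        rhs(nc, ytmp.data(), k4.data(), REAL(Iinj), c.data(), absM.data(),
            Vr.data(), pf.data());
        for (int q = 0; q < nvar; ++q)
          ytmp[q] = y[q] + hcur * (A51 * k1[q] + A52 * k2[q] + A53 * k3[q]
                                     + A54 * k4[q]);
        stim_profile(t + 8.0 / 9.0 * hcur);
        rhs(nc, ytmp.data(), k5.data(), REAL(Iinj), c.data(), absM.data(),
            Vr.data(), pf.data());
        for (int q = 0; q < nvar; ++q)
          ytmp[q] = y[q] + hcur * (A61 * k1[q] + A62 * k2[q] + A63 * k3[q]
                                     + A64 * k4[q] + A65 * k5[q]);
        stim_profile(t + hcur);
        rhs(nc, ytmp.data(), k6.data(), REAL(Iinj), c.data(), absM.data(),
            Vr.data(), pf.data());
        for (int q = 0; q < nvar; ++q)
          ynew[q] = y[q] + hcur * (B1 * k1[q] + B3 * k3[q] + B4 * k4[q]
                                     + B5 * k5[q] + B6 * k6[q]);
        rhs(nc, ynew.data(), k7.data(), REAL(Iinj), c.data(), absM.data(),
            Vr.data(), pf.data());

        double errnorm = 0.0;
        for (int q = 0; q < nvar; ++q) {
          const double e = hcur * (E1 * k1[q] + E3 * k3[q] + E4 * k4[q]
                                     + E5 * k5[q] + E6 * k6[q] + E7 * k7[q]);
          const double sc = atol + rtol * std::max(std::fabs(y[q]),
                                                   std::fabs(ynew[q]));
          const double r = e / sc;
          errnorm += r * r;
        }
        errnorm = std::sqrt(errnorm / nvar);

        if (errnorm <= 1.0 || hcur <= 1e-10) {
          accepted = true;
          double fac = (errnorm > 0.0)
            ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
          fac = std::min(5.0, std::max(0.2, fac));
          hstep = std::min(hmax, hcur * fac);
        } else {
          ++n_rejected;
          double fac = 0.9 * std::pow(errnorm, -0.2);
          fac = std::max(0.1, fac);
          hcur *= fac;
          if (hcur < 1e-12)
            stop("integrator step size underflow at t = %f ms", t);
        }
      }

      // spike detection on the accepted step (0 mV upward crossing,
      // linear interpolation, refractory lockout)
      events.clear();
      for (int i = 0; i < N; ++i) {
        Vold[i] = y[i];
        if (y[i] < 0.0 && ynew[i] >= 0.0) {
          const double frac = (0.0 - y[i]) / (ynew[i] - y[i]);
          const double ts = t + frac * hcur;
          const double li = last_spike[i];
          if (ISNAN(li) || ts - li >= lockout_ms) {
            SpikeEvent ev; ev.t = ts; ev.neuron = i;
            events.push_back(ev);
          }
        }
      }
      if (!events.empty()) {
        std::sort(events.begin(), events.end(),
                  [](const SpikeEvent& a, const SpikeEvent& b) {
                    if (a.t != b.t) return a.t < b.t;
                    return a.neuron < b.neuron;
                  });
        for (const SpikeEvent& ev : events) {
          record_marks_upto(ev.t);
          raster_neuron.push_back(ev.neuron + 1);
          raster_time.push_back(ev.t);
          ++n_spikes;
          if (stdp_enabled) apply_stdp_event(ev.neuron, ev.t);
          else last_spike[ev.neuron] = ev.t;
        }
      }
      t += hcur;
      record_marks_upto(t);
      std::swap(y, ynew);
      std::swap(k1, k7); // FSAL
      // weight updates invalidate the FSAL derivative (c enters S_i)
      if (stdp_enabled && !events.empty()) have_k1 = false;
      ++n_steps;
    }
    t = seg_end;
  }
  record_marks_upto(t_end);

  NumericVector Vout(N), mout(N), hout(N), nout(N), sout(N), lsout(N);
  for (int i = 0; i < N; ++i) {
    Vout[i] = y[i]; mout[i] = y[N + i]; hout[i] = y[2 * N + i];
    nout[i] = y[3 * N + i]; sout[i] = y[4 * N + i];
    lsout[i] = last_spike[i];
  }
  NumericMatrix cout_(N, N);
  std::copy(c.begin(), c.end(), cout_.begin());

  List newstate = List::create(
    _["V"] = Vout, _["m"] = mout, _["h"] = hout, _["n"] = nout,
    _["s"] = sout, _["I"] = Iinj, _["c"] = cout_,
    _["last_spike"] = lsout, _["t"] = t_end);

  return List::create(
    _["state"] = newstate,
    _["raster_neuron"] = wrap(raster_neuron),
    _["raster_time"] = wrap(raster_time),
    _["metric_time"] = wrap(met_t),
    _["c_av"] = wrap(met_cav),
    _["c_ee"] = wrap(met_cee),
    _["c_ii"] = wrap(met_cii),
    _["n_steps"] = (double)n_steps,
    _["n_rejected"] = (double)n_rejected,
    _["n_spikes"] = (double)n_spikes,
    _["n_EE"] = (double)nEE,
    _["n_II"] = (double)nII);
}
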