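// Compiled core of the Potts latching simulator.
//
// Storage convention for the tensor couplings: for receiving unit i
// (0-based), source slot n (0..c_m-1), active states k, l (0-based), the
// coupling sits at J[((i*c_m + n)*S + k)*S + l]. Activations sigma are
// unit-major with the background state first: sigma[i*(S+1) + k], k = 0..S.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Hebbian covariance rule on the dilute graph. xi is p x N with entries
// 0..S; jidx is N x c_m, 1-based source units.
// [[Rcpp::export]]
NumericVector build_weights_cpp(IntegerMatrix xi, IntegerMatrix jidx,
                                int S, double a) {
  const int p = xi.nrow(), N = xi.ncol(), cm = jidx.ncol();
  const double q = a / S;
  const double norm = cm * a * (1.0 - q);
  NumericVector J(static_cast<R_xlen_t>(N) * cm * S * S);

  // per-unit active-state counts over patterns: cnt[i*S + k-1]
  std::vector<int> cnt(static_cast<size_t>(N) * S, 0);
  for (int i = 0; i < N; ++i)
    for (int mu = 0; mu < p; ++mu) {
      int k = xi(mu, i);
      if (k > 0) cnt[static_cast<size_t>(i) * S + (k - 1)]++;
    }

  std::vector<int> nn(static_cast<size_t>(S) * S);
  for (int i = 0; i < N; ++i) {
    for (int n = 0; n < cm; ++n) {
      int j = jidx(i, n) - 1;
      std::fill(nn.begin(), nn.end(), 0);
      for (int mu = 0; mu < p; ++mu) {
        int ki = xi(mu, i), lj = xi(mu, j);
        if (ki > 0 && lj > 0) nn[static_cast<size_t>(ki - 1) * S + (lj - 1)]++;
      }
      double *blk = &J[(static_cast<R_xlen_t>(i) * cm + n) * S * S];
      const int *ci = &cnt[static_cast<size_t>(i) * S];
      const int *cj = &cnt[static_cast<size_t>(j) * S];
      for (int k = 0; k < S; ++k)
        for (int l = 0; l < S; ++l)
          blk[k * S + l] =
            (nn[static_cast<size_t>(k) * S + l] - q * ci[k] - q * cj[l] +
             q * q * p) / norm;
    }
  }
  return J;
}

// STM boosts on the tensor (Models 3a / 3b). The boost is applied at most
// once per coupling (Heaviside of a membership count).
// [[Rcpp::export]]
NumericVector boost_weights_cpp(NumericVector J, IntegerMatrix jidx,
                                IntegerMatrix xi, int S, IntegerVector stm,
                                double deltaJ, bool pairwise) {
  const int N = jidx.nrow(), cm = jidx.ncol(), L = stm.size();
  NumericVector out = clone(J);
  if (L == 0 || deltaJ == 0.0) return out;
  std::vector<char> mark(static_cast<size_t>(S) * S);
  std::vector<char> ki_set(S), lj_set(S);
  for (int i = 0; i < N; ++i) {
    for (int n = 0; n < cm; ++n) {
      int j = jidx(i, n) - 1;
      std::fill(mark.begin(), mark.end(), 0);
      if (!pairwise) {
        for (int m = 0; m < L; ++m) {
          int mu = stm[m] - 1;
          int k = xi(mu, i), l = xi(mu, j);
          if (k > 0 && l > 0) mark[static_cast<size_t>(k - 1) * S + (l - 1)] = 1;
        }
      } else {
        std::fill(ki_set.begin(), ki_set.end(), 0);
        std::fill(lj_set.begin(), lj_set.end(), 0);
        for (int m = 0; m < L; ++m) {
          int mu = stm[m] - 1;
          int k = xi(mu, i), l = xi(mu, j);
          if (k > 0) ki_set[k - 1] = 1;
          if (l > 0) lj_set[l - 1] = 1;
        }
        for (int k = 0; k < S; ++k)
          if (ki_set[k])
            for (int l = 0; l < S; ++l)
              if (lj_set[l]) mark[static_cast<size_t>(k) * S + l] = 1;
      }
      double *blk = &out[(static_cast<R_xlen_t>(i) * cm + n) * S * S];
      for (int kl = 0; kl < S * S; ++kl)
        if (mark[kl]) blk[kl] += deltaJ;
    }
  }
  return out;
}

// Compressed index of the nonzero heteroassociative couplings for an
// instruction I_1..I_L: the coupling into (unit i, state k) from
// (unit j, state l) is lambda iff k = xi_i^{I_{mu+1}} and l = xi_j^{I_mu}
// for some transition mu (both active), j != i, counted once.
// [[Rcpp::export]]
List het_index_cpp(IntegerMatrix xi, IntegerVector instr, int S) {
  const int N = xi.ncol(), L = instr.size();
  // predecessor patterns feeding each (i, k) target
  std::vector<std::vector<int> > preds(static_cast<size_t>(N) * S);
  for (int m = 0; m + 1 < L; ++m) {
    int nu = instr[m] - 1, succ = instr[m + 1] - 1;
    for (int i = 0; i < N; ++i) {
      int k = xi(succ, i);
      if (k > 0) preds[static_cast<size_t>(i) * S + (k - 1)].push_back(nu);
    }
  }
  std::vector<int> unit, state, ptr, src_unit, src_state;
  ptr.push_back(0);
  std::vector<char> seen(S);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < S; ++k) {
      std::vector<int> &pv = preds[static_cast<size_t>(i) * S + k];
      if (pv.empty()) continue;
      unit.push_back(i + 1);
      state.push_back(k + 1);
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        std::fill(seen.begin(), seen.end(), 0);
        for (size_t t = 0; t < pv.size(); ++t) {
          int l = xi(pv[t], j);
          if (l > 0 && !seen[l - 1]) {
            seen[l - 1] = 1;
            src_unit.push_back(j + 1);
            src_state.push_back(l);
          }
        }
      }
      ptr.push_back(static_cast<int>(src_unit.size()));
    }
  return List::create(_["unit"] = wrap(unit), _["state"] = wrap(state),
                      _["ptr"] = wrap(ptr), _["src_unit"] = wrap(src_unit),
                      _["src_state"] = wrap(src_state));
}

// Synchronous explicit-Euler integration of the Potts equations with online
// overlap sampling, null-attractor detection and (optional) early stopping
// once enough digitized retrieval events have been seen.
// [[Rcpp::export]]
List run_potts_cpp(IntegerMatrix xi, IntegerMatrix jidx, NumericVector J,
                   int S, double a, NumericVector wvec,
                   IntegerMatrix theta_mask, double delta_theta,
                   List het, double lambda,
                   double beta, double U,
                   double tau1, double tau2, double tauA, double tauB,
                   double gammaA, double dt,
                   int max_steps, int sample_every,
                   int cue_pattern, double cue_strength, int cue_steps,
                   double m_null, double act_null, int null_window,
                   double m_star, int min_dwell, int max_events,
                   IntegerVector stm_whitelist, bool stop_on_violation) {
  const int p = xi.nrow(), N = xi.ncol(), cm = jidx.ncol();
  const double q = a / S;
  const int Sp1 = S + 1;

  // internal copy of the couplings, transposed (l outer, k inner) with the
  // k dimension padded to a multiple of 4 so the hot loop is contiguous and
  // vectorizable; the canonical k-major layout of J is unchanged outside.
  const int Kp = ((S + 3) / 4) * 4;
  std::vector<double> Jt(static_cast<size_t>(N) * cm * S * Kp, 0.0);
  std::vector<int> jsrc(static_cast<size_t>(N) * cm);
  for (int i = 0; i < N; ++i)
    for (int n = 0; n < cm; ++n) {
      jsrc[static_cast<size_t>(i) * cm + n] = jidx(i, n) - 1;
      const double *blk = &J[(static_cast<R_xlen_t>(i) * cm + n) * S * S];
      double *tblk = &Jt[(static_cast<size_t>(i) * cm + n) * S * Kp];
      for (int k = 0; k < S; ++k)
        for (int l = 0; l < S; ++l)
          tblk[static_cast<size_t>(l) * Kp + k] = blk[k * S + l];
    }

  std::vector<double> sigma(static_cast<size_t>(N) * Sp1);
  std::vector<double> r(static_cast<size_t>(N) * S, 0.0);
  std::vector<double> th(static_cast<size_t>(N) * S, 0.0);
  std::vector<double> thA(N, 0.0), thB(N, 0.0);
  std::vector<double> h(static_cast<size_t>(N) * S);
  std::vector<double> act(N);

  const bool use_mask = theta_mask.nrow() == N && delta_theta != 0.0;
  const bool use_het = het.size() > 0 && lambda > 0.0;
  IntegerVector h_unit, h_state, h_ptr, h_sj, h_sl;
  if (use_het) {
    h_unit = het["unit"]; h_state = het["state"]; h_ptr = het["ptr"];
    h_sj = het["src_unit"]; h_sl = het["src_state"];
  }

  // pattern states transposed for overlap locality: xiT[mu*N + i]
  std::vector<int> xiT(static_cast<size_t>(p) * N);
  for (int mu = 0; mu < p; ++mu)
    for (int i = 0; i < N; ++i) xiT[static_cast<size_t>(mu) * N + i] = xi(mu, i);

  // softmax from current potentials and inhibitory thresholds
  auto update_sigma = [&](void) {
    for (int i = 0; i < N; ++i) {
      double e0 = beta * (U + thA[i] + thB[i]);
      double mx = e0;
      const double *ri = &r[static_cast<size_t>(i) * S];
      for (int k = 0; k < S; ++k) if (beta * ri[k] > mx) mx = beta * ri[k];
      double z = std::exp(e0 - mx), zsum = z;
      double *si = &sigma[static_cast<size_t>(i) * Sp1];
      si[0] = z;
      for (int k = 0; k < S; ++k) {
        double e = std::exp(beta * ri[k] - mx);
        si[k + 1] = e;
        zsum += e;
      }
      for (int k = 0; k <= S; ++k) si[k] /= zsum;
    }
  };
  update_sigma(); // initial condition: r = theta = 0, background-biased softmax

  const double m_norm = 1.0 / (N * a * (1.0 - q));
  std::vector<double> m_buf, act_buf, t_buf;
  int term = 0; // 0 step_cap, 1 null_attractor, 2 event_cap
  int null_run = 0;
  int cand = -1, cand_run = 0, last_event = -1, n_events = 0;
  // first repeat-or-intrusion detection for error-limited recall scoring
  std::vector<char> is_stm(p, 0), seen(p, 0);
  for (int t = 0; t < stm_whitelist.size(); ++t)
    is_stm[stm_whitelist[t] - 1] = 1;
  int step = 0;

  for (step = 1; step <= max_steps; ++step) {
    // activity per unit (current sigma)
    for (int i = 0; i < N; ++i) {
      const double *si = &sigma[static_cast<size_t>(i) * Sp1];
      double s = 0.0;
      for (int k = 1; k <= S; ++k) s += si[k];
      act[i] = s;
    }
    // fields
    std::vector<double> hacc(Kp);
    for (int i = 0; i < N; ++i) {
      double *ha = hacc.data();
      std::memset(ha, 0, sizeof(double) * Kp);
      const size_t base = static_cast<size_t>(i) * cm;
      for (int n = 0; n < cm; ++n) {
        const int j = jsrc[base + n];
        const double *sj = &sigma[static_cast<size_t>(j) * Sp1 + 1];
        const double *tblk = &Jt[(base + n) * S * Kp];
        for (int l = 0; l < S; ++l) {
          const double s = sj[l];
          const double *col = tblk + static_cast<size_t>(l) * Kp;
          for (int k = 0; k < Kp; ++k) ha[k] += col[k] * s;
        }
      }
      double *hi = &h[static_cast<size_t>(i) * S];
      const double *si = &sigma[static_cast<size_t>(i) * Sp1 + 1];
      const double wi = wvec[i], mean_act = act[i] / S;
      for (int k = 0; k < S; ++k) hi[k] = ha[k] + wi * (si[k] - mean_act);
    }
    if (cue_pattern > 0 && step <= cue_steps) {
      const int mu = cue_pattern - 1;
      for (int i = 0; i < N; ++i) {
        const int k0 = xiT[static_cast<size_t>(mu) * N + i];
        double *hi = &h[static_cast<size_t>(i) * S];
        for (int k = 0; k < S; ++k)
          hi[k] += cue_strength * (((k + 1) == k0 ? 1.0 : 0.0) - q);
      }
    }
    if (use_het) {
      const int nE = h_unit.size();
      for (int e = 0; e < nE; ++e) {
        const int i = h_unit[e] - 1, k = h_state[e] - 1;
        double acc = 0.0;
        for (int t = h_ptr[e]; t < h_ptr[e + 1]; ++t)
          acc += th[static_cast<size_t>(h_sj[t] - 1) * S + (h_sl[t] - 1)];
        h[static_cast<size_t>(i) * S + k] += lambda * acc;
      }
    }
    // Euler updates of r, theta, thA, thB using current sigma
    const double g1 = dt / tau1, g2 = dt / tau2, gA = dt / tauA, gB = dt / tauB;
    for (int i = 0; i < N; ++i) {
      double *ri = &r[static_cast<size_t>(i) * S];
      double *ti = &th[static_cast<size_t>(i) * S];
      const double *hi = &h[static_cast<size_t>(i) * S];
      const double *si = &sigma[static_cast<size_t>(i) * Sp1 + 1];
      for (int k = 0; k < S; ++k) {
        ri[k] += g1 * (hi[k] - ti[k] - ri[k]);
        double drive = si[k] - ti[k];
        if (use_mask && theta_mask(i, k) != 0) drive -= delta_theta;
        ti[k] += g2 * drive;
      }
      thA[i] += gA * (gammaA * act[i] - thA[i]);
      thB[i] += gB * ((1.0 - gammaA) * act[i] - thB[i]);
    }
    update_sigma();

    if (step % sample_every == 0) {
      // overlaps and mean activity from the fresh sigma
      double act_sum = 0.0;
      for (int i = 0; i < N; ++i) {
        const double *si = &sigma[static_cast<size_t>(i) * Sp1];
        act_sum += 1.0 - si[0];
      }
      const double mean_act = act_sum / N;
      double max_m = -2.0;
      int arg_m = -1;
      for (int mu = 0; mu < p; ++mu) {
        const int *xm = &xiT[static_cast<size_t>(mu) * N];
        double s = 0.0;
        for (int i = 0; i < N; ++i) {
          const int k0 = xm[i];
          const double *si = &sigma[static_cast<size_t>(i) * Sp1];
          double ai = 1.0 - si[0];
          s += (k0 > 0 ? si[k0] : 0.0) - q * ai;
        }
        const double m = s * m_norm;
        m_buf.push_back(m);
        if (m > max_m) { max_m = m; arg_m = mu; }
      }
      act_buf.push_back(mean_act);
      t_buf.push_back(step * dt);
      if (!std::isfinite(max_m) || !std::isfinite(mean_act))
        stop("non-finite state encountered at t = %f", step * dt);

      // null-attractor detection
      if (max_m < m_null && mean_act < act_null) {
        if (++null_run >= null_window) { term = 1; break; }
      } else null_run = 0;

      // online digitizer (same rule as digitize_trajectory) for early stop
      if (max_events > 0 || stop_on_violation) {
        if (max_m > m_star) {
          if (arg_m == cand) ++cand_run; else { cand = arg_m; cand_run = 1; }
          if (cand_run == min_dwell && cand != last_event) {
            ++n_events;
            last_event = cand;
            if (max_events > 0 && n_events > max_events) { term = 2; break; }
            if (stop_on_violation && (!is_stm[cand] || seen[cand])) {
              term = 2; // the offending event is recorded, then the run stops
              break;
            }
            seen[cand] = 1;
          }
        } else { cand = -1; cand_run = 0; }
      }
    }
  }

  const int ns = static_cast<int>(t_buf.size());
  NumericMatrix m(ns, p);
  for (int s = 0; s < ns; ++s)
    for (int mu = 0; mu < p; ++mu)
      m(s, mu) = m_buf[static_cast<size_t>(s) * p + mu];
  std::string reason = term == 1 ? "null_attractor"
                     : term == 2 ? "event_cap" : "step_cap";
  return List::create(
    _["times"] = wrap(t_buf), _["m"] = m, _["activity"] = wrap(act_buf),
    _["terminated_by"] = reason,
    _["steps"] = (step > max_steps ? max_steps : step),
    _["n_events_engine"] = n_events);
}

// Equal-probability random-walk null over L items with one of the recall
// stopping rules. Returns the distinct-item count per run (the event that
// triggers the stop is excluded, as in the sequence metrics). Uses R's RNG.
// stop_rule: 0 first_revisit, 1 repeated_transition, 2 third_occurrence,
// 3 budget (2L - h automaton). mode: 0 i.i.d. draws, 1 no immediate repeats.
// [[Rcpp::export]]
IntegerVector random_walk_cpp(int L, int n_runs, int mode, int stop_rule) {
  RNGScope scope;
  IntegerVector out(n_runs);
  std::vector<char> visited(L);
  std::vector<int> occ(L);
  std::vector<char> trans(stop_rule == 1 ? static_cast<size_t>(L) * L : 0);
  for (int run = 0; run < n_runs; ++run) {
    std::fill(visited.begin(), visited.end(), 0);
    std::fill(occ.begin(), occ.end(), 0);
    if (stop_rule == 1) std::fill(trans.begin(), trans.end(), 0);
    int prev = -1, distinct = 0, consumed = 0, h = 0;
    const int hard_cap = 100 * L + 1000; // safety for non-terminating rules
    for (int t = 0; t < hard_cap; ++t) {
      int item;
      if (mode == 1 && prev >= 0) {
        item = static_cast<int>(unif_rand() * (L - 1));
        if (item >= L - 1) item = L - 2;
        if (item >= prev) ++item; // uniform over the L-1 others
      } else {
        item = static_cast<int>(unif_rand() * L);
        if (item >= L) item = L - 1;
      }
      bool stop_now = false;
      switch (stop_rule) {
      case 0:
        if (visited[item]) stop_now = true;
        break;
      case 1:
        if (prev >= 0) {
          char &tr = trans[static_cast<size_t>(prev) * L + item];
          if (tr) stop_now = true; else tr = 1;
        }
        break;
      case 2:
        if (occ[item] >= 2) stop_now = true;
        break;
      case 3:
        if (consumed >= 2 * L - h) stop_now = true;
        break;
      }
      if (stop_now) break;
      ++consumed;
      if (!visited[item]) { visited[item] = 1; ++distinct; ++h; }
      ++occ[item];
      prev = item;
    }
    out[run] = distinct;
  }
  return out;
}
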