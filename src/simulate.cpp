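#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-timestep colony update for the trophallaxis model.
//
// Phase order within one timestep t:
//   1. ongoing trophallactic pairs: separation check (prob phi), otherwise
//      one transfer of transfer_rate food units donor -> receiver (the pair
//      also separates immediately when the donor's crop reaches zero);
//   2. departures: each unpaired ant in the nest, in random order, leaves
//      for the source with probability alpha_max * k^n/(k^n + Q^n); the
//      first visit promotes the ant to forager (absorbing);
//   3. source: each ant at the source ingests intake_rate units, then
//      returns with probability beta (optionally via a fixed-length
//      transit state);
//   4. pairing: each unpaired nest ant, in random order, draws one
//      uniformly random unpaired nest partner and becomes its donor with
//      probability theta_i(Q_i) * gamma_j(Q_j); a freshly formed pair
//      exchanges its first transfer_rate units at formation.
//
// A pair formed at t_start that survives m-1 separation checks makes m
// transfers at steps t_start, ..., t_start + m - 1, so the exchanged
// amount is transfer_rate * (t_end - t_start + 1) with t_end the last
// transfer step, unless the donor empties first. All randomness comes
// from R's RNG, so set.seed() in R makes runs exactly reproducible.

static inline double hill_inc(double Q, double k, double n) {
  double r = std::pow(Q / k, n);
  return r / (1.0 + r);
}

static void shuffle_order(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

struct ActivePair {
  int donor, receiver, t_start, d_caste, r_caste;
  double amount;
  int last_transfer;
};

// [[Rcpp::export]]
List simulate_colony_cpp(int n_steps,
                         NumericVector theta0_nf, NumericVector gamma0_nf,
                         NumericVector theta0_f, NumericVector gamma0_f,
                         NumericVector alpha0, NumericVector alpha0_forager,
                         double k, double hill_n,
                         double beta, double phi,
                         double intake_rate, double transfer_rate,
                         int return_delay,
                         int traj_every,
                         bool check_conservation,
                         bool pairing_before_departures,
                         bool dual_initiation) {
  const int N = theta0_nf.size();
  // locations: 0 = in nest, 1 = at source, 2 = returning (transit)
  std::vector<int> loc(N, 0), caste(N, 0), partner(N, -1), timer(N, 0);
  std::vector<int> first_visit(N, -1), cur_stay(N, 0), max_stay(N, 0);
  std::vector<double> crop(N, 0.0), th(N), ga(N), al(N);
  for (int i = 0; i < N; ++i) {
    th[i] = theta0_nf[i]; ga[i] = gamma0_nf[i]; al[i] = alpha0[i];
  }
  double withdrawn = 0.0, max_dev = 0.0;

  std::vector<ActivePair> pairs;
  // event log accumulators
  std::vector<int> ev_donor, ev_receiver, ev_start, ev_end, ev_dc, ev_rc;
  std::vector<double> ev_amount;

  int n_snap = (traj_every > 0) ? n_steps / traj_every : 0;
  NumericMatrix traj(n_snap > 0 ? N : 0, n_snap);

  std::vector<int> order; order.reserve(N);
  std::vector<int> avail; avail.reserve(N);
  std::vector<int> pos(N, -1);

  auto finalize = [&](const ActivePair &p, int t_end) {
    ev_donor.push_back(p.donor + 1);
    ev_receiver.push_back(p.receiver + 1);
    ev_start.push_back(p.t_start);
    ev_end.push_back(t_end);
    ev_amount.push_back(p.amount);
    ev_dc.push_back(p.d_caste);
    ev_rc.push_back(p.r_caste);
    partner[p.donor] = -1;
    partner[p.receiver] = -1;
  };

  auto promote = [&](int i, int t) {
    if (first_visit[i] < 0) {
      first_visit[i] = t;
      caste[i] = 1;
      th[i] = theta0_f[i];
      ga[i] = gamma0_f[i];
      al[i] = alpha0_forager[i];
    }
  };

  auto departures = [&](int t) {
    order.clear();
    for (int i = 0; i < N; ++i)
      if (loc[i] == 0 && partner[i] < 0) order.push_back(i);
    shuffle_order(order);
    for (int i : order) {
      double p = al[i] * (1.0 - hill_inc(crop[i], k, hill_n));
      if (unif_rand() < p) {
        loc[i] = 1;
        cur_stay[i] = 0;
        promote(i, t);
      }
    }
  };

  auto pairing = [&](int t, bool dual) {
    avail.clear();
    for (int i = 0; i < N; ++i) {
      if (loc[i] == 0 && partner[i] < 0) { pos[i] = (int)avail.size(); avail.push_back(i); }
      else pos[i] = -1;
    }
    order = avail;
    shuffle_order(order);
    for (int i : order) {
      if (pos[i] < 0) continue;           // already paired this step
      int m = (int)avail.size();
      if (m < 2) break;
      // draw a uniformly random other available ant
      auto draw_partner = [&](int self) {
        int mm = (int)avail.size();
        int r = (int)std::floor(unif_rand() * (mm - 1));
        if (r >= mm - 1) r = mm - 2;
        if (r >= pos[self]) ++r;          // uniform over avail \ {self}
        return avail[r];
      };
      // encounter initiated by i as donor; in dual-initiation mode a
      // failed donor attempt is followed by an attempt as receiver
      int donor = -1, recv = -1;
      int j = draw_partner(i);
      double p = th[i] * hill_inc(crop[i], k, hill_n) *
                 ga[j] * (1.0 - hill_inc(crop[j], k, hill_n));
      if (crop[i] > 0.0 && unif_rand() < p) {
        donor = i; recv = j;
      } else if (dual) {
        int d = draw_partner(i);
        double p2 = th[d] * hill_inc(crop[d], k, hill_n) *
                    ga[i] * (1.0 - hill_inc(crop[i], k, hill_n));
        if (crop[d] > 0.0 && unif_rand() < p2) { donor = d; recv = i; }
      }
      if (donor >= 0) {
        int i = donor, j = recv;
        // remove both from the available pool (swap with last)
        for (int who : {i, j}) {
          int q = pos[who];
          int last = avail.back();
          avail[q] = last; pos[last] = q;
          avail.pop_back(); pos[who] = -1;
        }
        ActivePair ap;
        ap.donor = i; ap.receiver = j; ap.t_start = t;
        ap.d_caste = caste[i]; ap.r_caste = caste[j];
        double x = std::min(transfer_rate, crop[i]);
        crop[i] -= x; crop[j] += x;
        ap.amount = x; ap.last_transfer = t;
        if (crop[i] <= 0.0) {
          crop[i] = 0.0;
          finalize(ap, t);               // donor emptied at formation
        } else {
          partner[i] = j; partner[j] = i;
          pairs.push_back(ap);
        }
      }
    }
  };

  for (int t = 1; t <= n_steps; ++t) {
    // --- phase 1: ongoing exchanges ---------------------------------
    for (size_t pi = 0; pi < pairs.size();) {
      ActivePair &p = pairs[pi];
      if (unif_rand() < phi) {
        finalize(p, p.last_transfer);
        pairs[pi] = pairs.back(); pairs.pop_back();
        continue;
      }
      double x = std::min(transfer_rate, crop[p.donor]);
      crop[p.donor] -= x; crop[p.receiver] += x;
      p.amount += x; p.last_transfer = t;
      if (crop[p.donor] <= 0.0) {
        crop[p.donor] = 0.0;
        finalize(p, t);
        pairs[pi] = pairs.back(); pairs.pop_back();
        continue;
      }
      ++pi;
    }

    // --- phases 2 & 4 (order switchable), phase 3 in between --------
    if (!pairing_before_departures) departures(t);
    else pairing(t, dual_initiation);

    // --- phase 3: transit, then the food source ---------------------
    for (int i = 0; i < N; ++i) {
      if (loc[i] == 2) {
        if (--timer[i] <= 0) loc[i] = 0;
      }
    }
    for (int i = 0; i < N; ++i) {
      if (loc[i] == 1) {
        crop[i] += intake_rate;
        withdrawn += intake_rate;
        ++cur_stay[i];
        if (cur_stay[i] > max_stay[i]) max_stay[i] = cur_stay[i];
        if (unif_rand() < beta) {
          if (return_delay > 0) { loc[i] = 2; timer[i] = return_delay; }
          else loc[i] = 0;
        }
      }
    }

    if (!pairing_before_departures) pairing(t, dual_initiation);
    else departures(t);

    if (check_conservation) {
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += crop[i];
      double dev = std::fabs(s - withdrawn);
      if (dev > max_dev) max_dev = dev;
    }
    if (traj_every > 0 && t % traj_every == 0) {
      int col = t / traj_every - 1;
      for (int i = 0; i < N; ++i) traj(i, col) = crop[i];
    }
  }

  // close exchanges still in progress at the horizon
  for (const ActivePair &p : pairs) finalize(p, p.last_transfer);
  pairs.clear();

  IntegerVector fv(N), ms(N), cst(N);
  NumericVector cr(N);
  for (int i = 0; i < N; ++i) {
    fv[i] = (first_visit[i] < 0) ? NA_INTEGER : first_visit[i];
    ms[i] = max_stay[i];
    cst[i] = caste[i];
    cr[i] = crop[i];
  }

  return List::create(
    _["donor"] = wrap(ev_donor), _["receiver"] = wrap(ev_receiver),
    _["t_start"] = wrap(ev_start), _["t_end"] = wrap(ev_end),
    _["amount"] = wrap(ev_amount),
    _["donor_caste"] = wrap(ev_dc), _["receiver_caste"] = wrap(ev_rc),
    _["first_visit"] = fv, _["max_stay"] = ms, _["caste"] = cst,
    _["crop"] = cr, _["withdrawn"] = withdrawn,
    _["max_conservation_dev"] = max_dev,
    _["traj"] = traj);
}
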