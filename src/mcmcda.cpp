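// MCMC data association for microbubble tracking.
//
// Detections (frame, axial, lateral positions in micrometres) are
// partitioned into tracks and false alarms.  A partition omega is scored by
// log P(Y|omega) + log P(omega): the likelihood comes from a
// constant-velocity Kalman filter evaluated per axis (axial and lateral
// dynamics are independent), the prior from Poisson birth/false-alarm
// intensities, a binomial detect/miss factor and a geometric survival
// factor.  Association-independent normalising constants are dropped
// throughout, so scores are comparable only across partitions of the same
// detection set.
//
// All randomness is drawn from R's RNG so results are reproducible under
// set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Pars {
  double q2;         // process noise variance (white accel., um^2/frame^3)
  double r2;         // measurement noise variance, um^2
  double v02;        // initial velocity variance, um^2/frame^2
  double gate_speed; // um/frame
  double gate_slack; // um
  int max_gap;       // max allowed frame difference for one link
  double log_pd, log_qd;   // log p_detect, log(1 - p_detect)
  double log_pz, log_qz;   // log p_terminate, log(1 - p_terminate)
  double log_lb;           // log birth intensity (tracks per frame)
  double log_lf;           // log false-alarm intensity (per frame)
  double log_area;         // log field-of-view area, um^2
};

Pars read_pars(const List& p) {
  Pars P;
  double q = as<double>(p["process_noise_sigma"]);
  double r = as<double>(p["measurement_noise_sigma"]);
  double v0 = as<double>(p["init_velocity_sigma"]);
  P.q2 = q * q;
  P.r2 = r * r;
  P.v02 = v0 * v0;
  P.gate_speed = as<double>(p["gate_speed"]);
  P.gate_slack = as<double>(p["gate_slack"]);
  P.max_gap = as<int>(p["max_gap"]);
  double pd = as<double>(p["p_detect"]);
  double pz = as<double>(p["p_terminate"]);
  P.log_pd = std::log(pd);
  P.log_qd = std::log1p(-pd);
  P.log_pz = std::log(pz);
  P.log_qz = std::log1p(-pz);
  P.log_lb = std::log(as<double>(p["birth_rate"]));
  P.log_lf = std::log(as<double>(p["false_alarm_rate"]));
  P.log_area = std::log(as<double>(p["area"]));
  return P;
}

struct Problem {
  int n;
  std::vector<int> f;        // frame index per detection (1-based)
  std::vector<double> ax, lat;
  Pars P;

  bool gated(int i, int j) const { // link i -> j, f[j] > f[i]
    int g = f[j] - f[i];
    if (g < 1 || g > P.max_gap) return false;
    double da = ax[j] - ax[i], dl = lat[j] - lat[i];
    double lim = P.gate_speed * g + P.gate_slack;
    return da * da + dl * dl <= lim * lim;
  }

  // Kalman innovation log-likelihood of one axis of one track.
  double axis_loglik(const std::vector<int>& tr,
                     const std::vector<double>& y) const {
    double p = y[tr[0]], v = 0.0;
    double P00 = P.r2, P01 = 0.0, P11 = P.v02;
    double ll = 0.0;
    for (size_t k = 1; k < tr.size(); ++k) {
      int g = f[tr[k]] - f[tr[k - 1]];
      for (int s = 0; s < g; ++s) {
        double n00 = P00 + 2.0 * P01 + P11 + P.q2 / 3.0;
        double n01 = P01 + P11 + 0.5 * P.q2;
        double n11 = P11 + P.q2;
        P00 = n00; P01 = n01; P11 = n11;
        p += v;
      }
      double S = P00 + P.r2;
      double innov = y[tr[k]] - p;
      ll += -0.5 * (std::log(2.0 * M_PI * S) + innov * innov / S);
      double K0 = P00 / S, K1 = P01 / S;
      p += K0 * innov;
      v += K1 * innov;
      double n00 = (1.0 - K0) * P00;
      double n01 = (1.0 - K0) * P01;
      double n11 = P11 - K1 * P01;
      P00 = n00; P01 = n01; P11 = n11;
    }
    return ll;
  }

  double track_loglik(const std::vector<int>& tr) const {
    // First detection scored uniformly over the field of view; the rest by
    // the Kalman innovations.
    return -P.log_area + axis_loglik(tr, ax) + axis_loglik(tr, lat);
  }

  double track_logprior(const std::vector<int>& tr) const {
    int k = (int)tr.size();
    int span = f[tr[k - 1]] - f[tr[0]];
    return P.log_lb + (k - 1) * P.log_pd + (span - k + 1) * P.log_qd +
           span * P.log_qz + P.log_pz;
  }

  double track_score(const std::vector<int>& tr) const {
    return track_loglik(tr) + track_logprior(tr);
  }

  double fa_term() const { return P.log_lf - P.log_area; }
};

Problem make_problem(const IntegerVector& frame, const NumericVector& ax,
                     const NumericVector& lat, const List& params) {
  Problem pr;
  pr.n = frame.size();
  pr.f.assign(frame.begin(), frame.end());
  pr.ax.assign(ax.begin(), ax.end());
  pr.lat.assign(lat.begin(), lat.end());
  pr.P = read_pars(params);
  return pr;
}

std::vector<std::vector<int>> read_tracks(const List& tracks) {
  std::vector<std::vector<int>> out;
  for (int t = 0; t < tracks.size(); ++t) {
    IntegerVector tr = tracks[t];
    std::vector<int> v(tr.size());
    for (int i = 0; i < tr.size(); ++i) v[i] = tr[i] - 1; // to 0-based
    out.push_back(v);
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
double assoc_loglik_cpp(IntegerVector frame, NumericVector ax,
                        NumericVector lat, List tracks, List params) {
  Problem pr = make_problem(frame, ax, lat, params);
  std::vector<std::vector<int>> trs = read_tracks(tracks);
  int in_tracks = 0;
  double ll = 0.0;
  for (auto& tr : trs) {
    ll += pr.track_loglik(tr);
    in_tracks += (int)tr.size();
  }
  ll += -(pr.n - in_tracks) * pr.P.log_area; // false alarms uniform in FOV
  return ll;
}

// [[Rcpp::export]]
double assoc_logprior_cpp(IntegerVector frame, NumericVector ax,
                          NumericVector lat, List tracks, List params) {
  Problem pr = make_problem(frame, ax, lat, params);
  std::vector<std::vector<int>> trs = read_tracks(tracks);
  int in_tracks = 0;
  double lp = 0.0;
  for (auto& tr : trs) {
    lp += pr.track_logprior(tr);
    in_tracks += (int)tr.size();
  }
  lp += (pr.n - in_tracks) * pr.P.log_lf;
  return lp;
}

// ---------------------------------------------------------------------------
// Exhaustive MAP over all valid partitions (test oracle, tiny instances only)
// ---------------------------------------------------------------------------

namespace {

struct Exhaustive {
  const Problem& pr;
  std::vector<int> order;                 // detections sorted by frame
  std::vector<std::vector<int>> seqs;     // open sequences (0-based det ids)
  double best = R_NegInf;
  int best_ntracks = 0;
  std::vector<std::vector<int>> best_tracks;
  long long leaves = 0;

  explicit Exhaustive(const Problem& p) : pr(p) {
    order.resize(pr.n);
    for (int i = 0; i < pr.n; ++i) order[i] = i;
    std::stable_sort(order.begin(), order.end(),
                     [&](int a, int b) { return pr.f[a] < pr.f[b]; });
  }

  void leaf() {
    ++leaves;
    int in_tracks = 0;
    double sc = 0.0;
    for (auto& s : seqs) {
      if (s.size() < 2) return; // singleton "track": invalid partition
      sc += pr.track_score(s);
      in_tracks += (int)s.size();
    }
    sc += (pr.n - in_tracks) * pr.fa_term();
    bool better = sc > best + 1e-9;
    if (!better && sc > best - 1e-9) { // tie: fewer tracks, then lexicographic
      if ((int)seqs.size() < best_ntracks) better = true;
      else if ((int)seqs.size() == best_ntracks && seqs < best_tracks)
        better = true;
    }
    if (better) {
      best = sc;
      best_ntracks = (int)seqs.size();
      best_tracks = seqs;
    }
  }

  void recurse(int idx) {
    if (idx == pr.n) { leaf(); return; }
    int d = order[idx];
    // false alarm
    recurse(idx + 1);
    // append to an open sequence
    for (auto& s : seqs) {
      if (pr.gated(s.back(), d)) {
        s.push_back(d);
        recurse(idx + 1);
        s.pop_back();
      }
    }
    // start a new sequence
    seqs.push_back({d});
    recurse(idx + 1);
    seqs.pop_back();
  }
};

} // namespace

// [[Rcpp::export]]
List exhaustive_map_cpp(IntegerVector frame, NumericVector ax,
                        NumericVector lat, List params) {
  Problem pr = make_problem(frame, ax, lat, params);
  Exhaustive ex(pr);
  if (pr.n > 0) ex.recurse(0);
  else ex.best = 0.0;
  List tr(ex.best_tracks.size());
  for (size_t t = 0; t < ex.best_tracks.size(); ++t) {
    IntegerVector v(ex.best_tracks[t].size());
    for (size_t i = 0; i < ex.best_tracks[t].size(); ++i)
      v[i] = ex.best_tracks[t][i] + 1;
    tr[t] = v;
  }
  return List::create(_["tracks"] = tr, _["log_posterior"] = ex.best,
                      _["n_evaluated"] = (double)ex.leaves);
}

// ---------------------------------------------------------------------------
// Metropolis sampler over associations
// ---------------------------------------------------------------------------

namespace {

struct Chain {
  const Problem& pr;
  std::vector<std::vector<int>> succ; // gated successors per detection
  std::vector<std::vector<int>> tracks;
  std::vector<double> tscore;
  std::vector<int> assign; // track index or -1 (false alarm)
  double total;
  double best;
  int best_ntracks;
  std::vector<std::vector<int>> best_tracks;

  explicit Chain(const Problem& p) : pr(p) {
    succ.resize(pr.n);
    for (int i = 0; i < pr.n; ++i)
      for (int j = 0; j < pr.n; ++j)
        if (pr.gated(i, j)) succ[i].push_back(j);
    assign.assign(pr.n, -1);
    total = pr.n * pr.fa_term(); // cold start: everything a false alarm
    best = total;
    best_ntracks = 0;
  }

  int runi(int n) { return (int)std::floor(unif_rand() * n) % n; }

  bool debug = false;

  // partition invariant: every detection in exactly one track or a false
  // alarm, tracks sorted in strictly increasing frames, all links gated
  void check_partition() const {
    std::vector<int> seen(pr.n, -1);
    for (int t = 0; t < (int)tracks.size(); ++t) {
      if (tracks[t].size() < 2) Rcpp::stop("internal: track shorter than 2");
      for (size_t k = 0; k < tracks[t].size(); ++k) {
        int d = tracks[t][k];
        if (seen[d] != -1) Rcpp::stop("internal: detection in two tracks");
        seen[d] = t;
        if (assign[d] != t) Rcpp::stop("internal: assignment out of sync");
        if (k > 0 && !pr.gated(tracks[t][k - 1], d))
          Rcpp::stop("internal: ungated link");
      }
    }
    for (int d = 0; d < pr.n; ++d)
      if (seen[d] == -1 && assign[d] != -1)
        Rcpp::stop("internal: stale assignment");
  }

  void snapshot_if_best() {
    bool better = total > best + 1e-9;
    if (!better && total > best - 1e-9) {
      if ((int)tracks.size() < best_ntracks) better = true;
    }
    if (better) {
      best = total;
      best_ntracks = (int)tracks.size();
      best_tracks = tracks;
    }
  }

  bool accept(double delta) {
    if (delta >= 0) return true;
    return std::log(unif_rand()) < delta;
  }

  void install_track(std::vector<int> tr, double sc) {
    tracks.push_back(std::move(tr));
    tscore.push_back(sc);
    int id = (int)tracks.size() - 1;
    for (int d : tracks[id]) assign[d] = id;
  }

  void remove_track(int id) {
    for (int d : tracks[id]) assign[d] = -1;
    int last = (int)tracks.size() - 1;
    if (id != last) {
      tracks[id] = std::move(tracks[last]);
      tscore[id] = tscore[last];
      for (int d : tracks[id]) assign[d] = id;
    }
    tracks.pop_back();
    tscore.pop_back();
  }

  void replace_track(int id, std::vector<int> tr, double sc) {
    for (int d : tracks[id]) assign[d] = -1;
    tracks[id] = std::move(tr);
    tscore[id] = sc;
    for (int d : tracks[id]) assign[d] = id;
  }

  // free (false-alarm) gated successors of detection d at the smallest
  // available frame gap; preferring contiguous continuations keeps the
  // proposals from assembling frame-skipping tracks when an unbroken one
  // exists
  std::vector<int> free_succ_min_gap(int d) {
    std::vector<int> cand;
    int best_gap = INT_MAX;
    for (int j : succ[d]) {
      if (assign[j] != -1) continue;
      int g = pr.f[j] - pr.f[d];
      if (g < best_gap) { best_gap = g; cand.clear(); }
      if (g == best_gap) cand.push_back(j);
    }
    return cand;
  }

  // --- moves ------------------------------------------------------------
  void move_birth() {
    if (pr.n == 0) return;
    int start = runi(pr.n);
    if (assign[start] != -1) return;
    std::vector<int> seq = {start};
    int cur = start;
    for (;;) {
      std::vector<int> cand = free_succ_min_gap(cur);
      if (cand.empty()) break;
      if (seq.size() >= 2 && unif_rand() < 0.35) break;
      cur = cand[runi((int)cand.size())];
      seq.push_back(cur);
    }
    if (seq.size() < 2) return;
    double sc = pr.track_score(seq);
    double delta = sc - (double)seq.size() * pr.fa_term();
    if (accept(delta)) {
      install_track(std::move(seq), sc);
      total += delta;
      snapshot_if_best();
    }
  }

  void move_death() {
    if (tracks.empty()) return;
    int id = runi((int)tracks.size());
    double delta = (double)tracks[id].size() * pr.fa_term() - tscore[id];
    if (accept(delta)) {
      remove_track(id);
      total += delta;
      snapshot_if_best();
    }
  }

  void move_extend() {
    if (tracks.empty()) return;
    int id = runi((int)tracks.size());
    bool fwd = unif_rand() < 0.5;
    std::vector<int> cand;
    if (fwd) {
      cand = free_succ_min_gap(tracks[id].back());
    } else {
      int head = tracks[id].front();
      int best_gap = INT_MAX;
      for (int j = 0; j < pr.n; ++j) {
        if (assign[j] != -1 || !pr.gated(j, head)) continue;
        int g = pr.f[head] - pr.f[j];
        if (g < best_gap) { best_gap = g; cand.clear(); }
        if (g == best_gap) cand.push_back(j);
      }
    }
    if (cand.empty()) return;
    int d = cand[runi((int)cand.size())];
    std::vector<int> tr = tracks[id];
    if (fwd) tr.push_back(d);
    else tr.insert(tr.begin(), d);
    double sc = pr.track_score(tr);
    double delta = sc - tscore[id] - pr.fa_term();
    if (accept(delta)) {
      replace_track(id, std::move(tr), sc);
      total += delta;
      snapshot_if_best();
    }
  }

  void move_reduce() {
    if (tracks.empty()) return;
    int id = runi((int)tracks.size());
    if (tracks[id].size() < 3) return; // length-2 reduction == death
    std::vector<int> tr = tracks[id];
    if (unif_rand() < 0.5) tr.pop_back();
    else tr.erase(tr.begin());
    double sc = pr.track_score(tr);
    double delta = sc - tscore[id] + pr.fa_term();
    if (accept(delta)) {
      replace_track(id, std::move(tr), sc);
      total += delta;
      snapshot_if_best();
    }
  }

  void move_split() {
    if (tracks.empty()) return;
    int id = runi((int)tracks.size());
    int len = (int)tracks[id].size();
    if (len < 4) return;
    int cut = 2 + runi(len - 3); // first part gets `cut` detections (>= 2)
    std::vector<int> a(tracks[id].begin(), tracks[id].begin() + cut);
    std::vector<int> b(tracks[id].begin() + cut, tracks[id].end());
    double sa = pr.track_score(a), sb = pr.track_score(b);
    double delta = sa + sb - tscore[id];
    if (accept(delta)) {
      double dummy = tscore[id];
      (void)dummy;
      replace_track(id, std::move(a), sa);
      install_track(std::move(b), sb);
      total += delta;
      snapshot_if_best();
    }
  }

  void move_merge() {
    if (tracks.size() < 2) return;
    int i = runi((int)tracks.size());
    std::vector<int> cand; // partners whose head is gated to i's tail
    for (int k = 0; k < (int)tracks.size(); ++k)
      if (k != i && pr.gated(tracks[i].back(), tracks[k].front()))
        cand.push_back(k);
    if (cand.empty()) return;
    int j = cand[runi((int)cand.size())];
    std::vector<int> tr = tracks[i];
    tr.insert(tr.end(), tracks[j].begin(), tracks[j].end());
    double sc = pr.track_score(tr);
    double delta = sc - tscore[i] - tscore[j];
    if (accept(delta)) {
      std::vector<int> keep = std::move(tr);
      // remove j first (careful with index invalidation from swap-pop)
      remove_track(j);
      if (i == (int)tracks.size()) i = j; // i was the swapped-in last slot
      replace_track(i, std::move(keep), sc);
      total += delta;
      snapshot_if_best();
    }
  }

  void move_switch() {
    if (tracks.size() < 2) return;
    int i = runi((int)tracks.size());
    int j = runi((int)tracks.size());
    if (i == j) return;
    const std::vector<int>& a = tracks[i];
    const std::vector<int>& b = tracks[j];
    int pi = runi((int)a.size() - 1);      // swap point: keep a[0..pi]
    int pj = runi((int)b.size() - 1);
    if (!pr.gated(a[pi], b[pj + 1]) || !pr.gated(b[pj], a[pi + 1])) return;
    std::vector<int> na(a.begin(), a.begin() + pi + 1);
    na.insert(na.end(), b.begin() + pj + 1, b.end());
    std::vector<int> nb(b.begin(), b.begin() + pj + 1);
    nb.insert(nb.end(), a.begin() + pi + 1, a.end());
    double sa = pr.track_score(na), sb = pr.track_score(nb);
    double delta = sa + sb - tscore[i] - tscore[j];
    if (accept(delta)) {
      // clear both old assignments before writing either new track:
      // detections swap owners, so a per-track replace would clobber the
      // other track's fresh assignments
      for (int d : tracks[i]) assign[d] = -1;
      for (int d : tracks[j]) assign[d] = -1;
      tracks[i] = std::move(na); tscore[i] = sa;
      tracks[j] = std::move(nb); tscore[j] = sb;
      for (int d : tracks[i]) assign[d] = i;
      for (int d : tracks[j]) assign[d] = j;
      total += delta;
      snapshot_if_best();
    }
  }

  // zip: merge two tracks whose detections interleave in time into one
  // time-ordered track; rescues the chain from the frame-skipping local
  // optimum where two tracks alternate over one bubble's detections
  void move_zip() {
    if (tracks.size() < 2) return;
    int i = runi((int)tracks.size());
    int j = runi((int)tracks.size());
    if (i == j) return;
    std::vector<int> merged(tracks[i].size() + tracks[j].size());
    std::merge(tracks[i].begin(), tracks[i].end(), tracks[j].begin(),
               tracks[j].end(), merged.begin(),
               [&](int a, int b) { return pr.f[a] < pr.f[b]; });
    for (size_t k = 1; k < merged.size(); ++k) {
      if (pr.f[merged[k]] == pr.f[merged[k - 1]]) return; // frame clash
      if (!pr.gated(merged[k - 1], merged[k])) return;
    }
    double sc = pr.track_score(merged);
    double delta = sc - tscore[i] - tscore[j];
    if (accept(delta)) {
      std::vector<int> keep = std::move(merged);
      remove_track(j);
      if (i == (int)tracks.size()) i = j;
      replace_track(i, std::move(keep), sc);
      total += delta;
      snapshot_if_best();
    }
  }

  void move_point_swap() {
    if (tracks.empty() || pr.n == 0) return;
    int id = runi((int)tracks.size());
    int pos = runi((int)tracks[id].size());
    int old = tracks[id][pos];
    std::vector<int> cand;
    for (int j = 0; j < pr.n; ++j)
      if (assign[j] == -1 && pr.f[j] == pr.f[old]) cand.push_back(j);
    if (cand.empty()) return;
    int d = cand[runi((int)cand.size())];
    std::vector<int> tr = tracks[id];
    tr[pos] = d;
    if (pos > 0 && !pr.gated(tr[pos - 1], tr[pos])) return;
    if (pos + 1 < (int)tr.size() && !pr.gated(tr[pos], tr[pos + 1])) return;
    double sc = pr.track_score(tr);
    double delta = sc - tscore[id];
    if (accept(delta)) {
      assign[old] = -1;
      replace_track(id, std::move(tr), sc);
      total += delta;
      snapshot_if_best();
    }
  }

  void step() {
    switch (runi(9)) {
      case 0: move_birth(); break;
      case 1: move_death(); break;
      case 2: move_extend(); break;
      case 3: move_reduce(); break;
      case 4: move_split(); break;
      case 5: move_merge(); break;
      case 6: move_switch(); break;
      case 7: move_point_swap(); break;
      case 8: move_zip(); break;
    }
    if (debug) check_partition();
  }
};

} // namespace

// [[Rcpp::export]]
List run_mcmcda_cpp(IntegerVector frame, NumericVector ax, NumericVector lat,
                    List params, int n_iterations, bool debug = false) {
  Problem pr = make_problem(frame, ax, lat, params);
  Chain ch(pr);
  ch.debug = debug;
  double initial = ch.total;
  ch.snapshot_if_best();
  for (int it = 0; it < n_iterations; ++it) ch.step();
  List tr(ch.best_tracks.size());
  for (size_t t = 0; t < ch.best_tracks.size(); ++t) {
    IntegerVector v(ch.best_tracks[t].size());
    for (size_t i = 0; i < ch.best_tracks[t].size(); ++i)
      v[i] = ch.best_tracks[t][i] + 1;
    tr[t] = v;
  }
  return List::create(_["tracks"] = tr, _["log_posterior"] = ch.best,
                      _["initial_log_posterior"] = initial,
                      _["final_log_posterior"] = ch.total);
}
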