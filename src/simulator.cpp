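#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Rightward deletion scan with skip/block semantics.
// chrom: 1 deletes on g, 2 deletes on h. Positions already 0 on the target
// chromosome are skipped without counting toward a; the first position whose
// copy on the other chromosome is 0 blocks the event. If dry == true the
// sequences are not modified (used for event-type classification).
static void scan_delete(int* g, int* h, int* eg, int* eh, int n,
                        int chrom, int anchor, int a, int id, bool dry,
                        std::vector<int>& del, bool& blocked, int& skipped,
                        bool& clipped) {
  int* s = (chrom == 1) ? g : h;
  int* o = (chrom == 1) ? h : g;
  int* es = (chrom == 1) ? eg : eh;
  del.clear();
  blocked = false;
  clipped = false;
  skipped = 0;
  int converted = 0;
  int pos = anchor;
  while (converted < a && pos < n) {
    if (s[pos] == 0) {
      ++skipped;                       // skippable collision
    } else if (o[pos] == 0) {
      blocked = true;                  // blocking collision
      break;
    } else {
      if (!dry) { s[pos] = 0; es[pos] = id; }
      del.push_back(pos);
      ++converted;
    }
    ++pos;
  }
  if (!blocked && converted < a) clipped = true;  // ran off the interval
}

// [[Rcpp::export]]
List cpp_apply_deletion(IntegerVector g_, IntegerVector h_,
                        IntegerVector eg_, IntegerVector eh_,
                        int chrom, int anchor, int a, int id) {
  IntegerVector g = clone(g_), h = clone(h_), eg = clone(eg_),
                eh = clone(eh_);
  int n = g.size();
  if (anchor < 0 || anchor >= n)
    stop("anchor out of range");
  if (g[anchor] != 1 || h[anchor] != 1)
    stop("anchor is not a duplicate position");
  std::vector<int> del;
  bool blocked, clipped;
  int skipped;
  scan_delete(g.begin(), h.begin(), eg.begin(), eh.begin(), n,
              chrom, anchor, a, id, false, del, blocked, skipped, clipped);
  return List::create(_["g"] = g, _["h"] = h, _["eg"] = eg, _["eh"] = eh,
                      _["deleted"] = wrap(del), _["blocked"] = blocked,
                      _["skipped"] = skipped, _["clipped"] = clipped);
}

// Classify an event by the number of pre-existing single-copy runs its
// consolidated run absorbs: 0 -> A, 1 -> B (left) / C (right),
// 2 -> E (touches left) / D (reaches over to the right), >=3 -> other.
// sc[] is single-copy status *before* the event; [anchor, last] are the
// positions the event converted or skipped.
static int classify_event(const std::vector<char>& sc, int n,
                          int anchor, int last) {
  int L = anchor;
  while (L - 1 >= 0 && sc[L - 1]) --L;
  int Rt = last;
  while (Rt + 1 < n && sc[Rt + 1]) ++Rt;
  int k = 0;
  bool in_block = false;
  for (int p = L; p <= Rt; ++p) {
    if (sc[p] && !in_block) { ++k; in_block = true; }
    else if (!sc[p]) in_block = false;
  }
  bool touch_left = (anchor - 1 >= 0 && sc[anchor - 1]);
  if (k == 0) return 0;                      // A
  if (k == 1) return touch_left ? 1 : 2;     // B : C
  if (k == 2) return touch_left ? 4 : 3;     // E : D
  return 5;                                  // other (>= 3 runs merged)
}

// Consolidated run statistics of the current state.
static List state_stats(const int* g, const int* h,
                        const int* eg, const int* eh, int n) {
  std::vector<int> rs, rl, rr, rboth, rsl, rsr;
  std::vector<int> dup_lens;
  int ndup = 0, ng0 = 0, nh0 = 0;
  int i = 0;
  while (i < n) {
    int sc = (g[i] + h[i] == 1);
    int j = i;
    while (j < n && ((g[j] + h[j] == 1) == (sc == 1))) ++j;
    if (sc) {
      std::vector<int> ids;
      bool any_g = false, any_h = false;
      for (int p = i; p < j; ++p) {
        if (g[p] == 0) { any_g = true; ids.push_back(eg[p]); ++ng0; }
        else           { any_h = true; ids.push_back(eh[p]); ++nh0; }
      }
      std::sort(ids.begin(), ids.end());
      int r = (int)(std::unique(ids.begin(), ids.end()) - ids.begin());
      rs.push_back(i);
      rl.push_back(j - i);
      rr.push_back(r);
      rboth.push_back(any_g && any_h);
      rsl.push_back(g[i] == 0 ? 1 : 2);
      rsr.push_back(g[j - 1] == 0 ? 1 : 2);
    } else {
      dup_lens.push_back(j - i);
      ndup += j - i;
    }
    i = j;
  }
  return List::create(
    _["run_start"] = wrap(rs), _["run_length"] = wrap(rl),
    _["run_r"] = wrap(rr), _["run_both"] = wrap(rboth),
    _["side_left"] = wrap(rsl), _["side_right"] = wrap(rsr),
    _["dup_run_lengths"] = wrap(dup_lens),
    _["theta"] = (double)ndup / n,
    _["n_deleted_g"] = ng0, _["n_deleted_h"] = nh0);
}

// [[Rcpp::export]]
List cpp_state_stats(IntegerVector g, IntegerVector h,
                     IntegerVector eg, IntegerVector eh) {
  return state_stats(g.begin(), h.begin(), eg.begin(), eh.begin(), g.size());
}

// Discrete-time simulation of the fractionation process. Checkpoints are
// theta values (decreasing); statistics and the event-type tallies
// accumulated since the previous checkpoint are recorded at each.
// Per event the RNG is consumed in fixed order: chromosome, anchor
// (rejection draws), length.
// [[Rcpp::export]]
List cpp_simulate(int n, double mu, double phi, double stop_theta,
                  NumericVector checkpoints, bool keep_state) {
  std::vector<int> g(n, 1), h(n, 1), eg(n, 0), eh(n, 0);
  std::vector<char> sc(n, 0);   // single-copy status, kept incrementally
  int ndup = n;
  int event_id = 0;
  long tally[6] = {0, 0, 0, 0, 0, 0};
  long window_events = 0;
  int n_blocked = 0, n_clipped = 0;
  int cp_idx = 0;
  int ncp = checkpoints.size();
  List records(ncp);
  bool saturated = false;
  std::vector<int> del;

  while (true) {
    double theta = (double)ndup / n;
    while (cp_idx < ncp && theta <= checkpoints[cp_idx] + 1e-12) {
      List st = state_stats(g.data(), h.data(), eg.data(), eh.data(), n);
      st["checkpoint"] = checkpoints[cp_idx];
      st["events_total"] = event_id;
      st["window_events"] = (double)window_events;
      st["tally_A"] = (double)tally[0];
      st["tally_B"] = (double)tally[1];
      st["tally_C"] = (double)tally[2];
      st["tally_D"] = (double)tally[3];
      st["tally_E"] = (double)tally[4];
      st["tally_other"] = (double)tally[5];
      records[cp_idx] = st;
      for (int t = 0; t < 6; ++t) tally[t] = 0;
      window_events = 0;
      ++cp_idx;
    }
    if (theta <= stop_theta || cp_idx >= ncp) break;
    if (ndup == 0) { saturated = true; break; }

    int chrom = (unif_rand() < phi) ? 1 : 2;
    int anchor;
    do {
      anchor = (int)(unif_rand() * n);
      if (anchor >= n) anchor = n - 1;
    } while (!(g[anchor] == 1 && h[anchor] == 1));
    int a = 1 + (int)R::rgeom(1.0 / mu);

    bool blocked, clipped;
    int skipped;
    // dry pass for classification, then apply
    scan_delete(g.data(), h.data(), eg.data(), eh.data(), n,
                chrom, anchor, a, 0, true, del, blocked, skipped, clipped);
    int last = del.back();
    int type = classify_event(sc, n, anchor, last);
    ++event_id;
    scan_delete(g.data(), h.data(), eg.data(), eh.data(), n,
                chrom, anchor, a, event_id, false, del, blocked, skipped,
                clipped);
    for (size_t d = 0; d < del.size(); ++d) sc[del[d]] = 1;
    ndup -= (int)del.size();
    ++tally[type];
    ++window_events;
    if (blocked) ++n_blocked;
    if (clipped) ++n_clipped;
  }

  List out = List::create(
    _["records"] = records,
    _["n_checkpoints_done"] = cp_idx,
    _["events_total"] = event_id,
    _["n_blocked"] = n_blocked,
    _["n_clipped"] = n_clipped,
    _["saturated"] = saturated);
  if (keep_state) {
    out["g"] = wrap(g); out["h"] = wrap(h);
    out["eg"] = wrap(eg); out["eh"] = wrap(eh);
  }
  return out;
}
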