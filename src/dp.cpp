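// Banded dynamic programming extension of a seed into a glocal or overlap
// alignment of an experimental map against a reference map.
//
// A state (s, t) is the best partial alignment whose last match ends with
// experimental fragment s and reference fragment t.  Partial alignments are
// ordered lexicographically by (cut errors, chi-square, #matches); both
// components are additive over matches, so prefix dominance holds and one
// state per (s, t) suffices.  The band restricts a single match to at most
// `max_false` false cuts and `max_miss` missing cuts, which is what keeps a
// level's state set small.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct State {
  int t;            // reference index the last match ends at
  int ce;           // total cut errors so far
  double chi2;      // total chi-square so far
  int nmatch;
  int parent;       // state index of predecessor, -1 for origin
  // match that created this state (side-local 1-based coordinates)
  int k, l;         // match covers query k..s, reference l..t
  uint32_t gapmask; // bit b set => reference fragment l+1+b treated missing
  int trunc;        // 0 none, 1 query-end one-sided, 2 reference-end one-sided
};

struct SideResult {
  bool found = false;
  int term_state = -1;
  int term_s = 0;
  std::vector<State> states;
};

struct Params {
  double C;
  int max_false, max_miss, f_min;
  double small_bp;
  int gap_max_run;
  bool overlap_mode;
  bool trunc_chi2;
};

inline bool lex_better(int ce1, double chi1, int nm1,
                       int ce2, double chi2, int nm2) {
  if (ce1 != ce2) return ce1 < ce2;
  if (chi1 != chi2) return chi1 < chi2;
  return nm1 < nm2;
}

// Evaluate the best admissible variant (gap subsets, truncation fallback) of
// the match covering query k..s / reference l..t.  Returns false if no
// variant is feasible.
bool eval_match(const std::vector<double>& OP, const std::vector<double>& RP,
                const std::vector<double>& VP, const NumericVector& rL,
                int k, int s, int l, int t, int mm, int nn, const Params& par,
                double& chi2_out, uint32_t& gap_out, int& ngap_out,
                int& trunc_out) {
  const double o_sum = OP[s] - OP[k - 1];
  const double r_sum0 = RP[t] - RP[l - 1];
  const double var0 = VP[t] - VP[l - 1];
  if (var0 <= 0) return false;
  const double d0 = o_sum - r_sum0;
  const double lim0 = par.C * std::sqrt(var0);
  const bool feas_base = std::fabs(d0) <= lim0;
  const double chi2_base = d0 * d0 / var0;

  // interior small fragments eligible as gaps
  int smalls[12];
  int g = 0;
  for (int p = l + 1; p <= t - 1 && g < 12; ++p) {
    if (rL[p - 1] <= par.small_bp) smalls[g++] = p;
  }

  bool have = false;
  double best_chi2 = 0.0;
  uint32_t best_mask = 0;
  int best_ngap = 0;
  if (feas_base) {
    have = true;
    best_chi2 = chi2_base;
  }
  if (g > 0) {
    const int nsub = 1 << g;
    for (int mask = 1; mask < nsub; ++mask) {
      // check run-length constraint on consecutive reference positions
      int run = 0, prev = -10;
      bool ok = true;
      double gs = 0, gv = 0;
      int cnt = 0;
      for (int b = 0; b < g; ++b) {
        if (!(mask & (1 << b))) continue;
        int p = smalls[b];
        run = (p == prev + 1) ? run + 1 : 1;
        if (run > par.gap_max_run) { ok = false; break; }
        prev = p;
        gs += rL[p - 1];
        gv += VP[p] - VP[p - 1];
        ++cnt;
      }
      if (!ok) continue;
      const double var_g = var0 - gv;
      if (var_g <= 0) continue;
      const double d = o_sum - (r_sum0 - gs);
      if (std::fabs(d) > par.C * std::sqrt(var_g)) continue;
      const double chi2_g = d * d / var_g;
      // a fragment may only be called missing when it halves the local
      // chi-square, or when keeping it is infeasible
      if (feas_base && chi2_g > 0.5 * chi2_base) continue;
      if (!have || chi2_g < best_chi2) {
        have = true;
        best_chi2 = chi2_g;
        best_mask = 0;
        for (int b = 0; b < g; ++b)
          if (mask & (1 << b)) best_mask |= (1u << (smalls[b] - l - 1));
        best_ngap = cnt;
      }
    }
  }
  if (have) {
    chi2_out = best_chi2;
    gap_out = best_mask;
    ngap_out = best_ngap;
    trunc_out = 0;
    return true;
  }
  // truncation fallbacks, one-sided tests, only at map ends
  if (s == mm && d0 <= lim0) {
    chi2_out = par.trunc_chi2 ? chi2_base : 0.0;
    gap_out = 0; ngap_out = 0; trunc_out = 1;
    return true;
  }
  if (par.overlap_mode && t == nn && d0 >= -lim0) {
    chi2_out = par.trunc_chi2 ? chi2_base : 0.0;
    gap_out = 0; ngap_out = 0; trunc_out = 2;
    return true;
  }
  return false;
}

// Extend rightwards over side-local query fragments oL (length mm) and
// reference fragments rL/vL (length nn), starting from the boundary state
// (0, 0).  In glocal mode the extension must consume the whole query; in
// overlap mode it may instead consume the reference to its end.
SideResult side_extend(const NumericVector& oL, const NumericVector& rL,
                       const NumericVector& vL, const Params& par) {
  const int mm = oL.size(), nn = rL.size();
  SideResult res;
  res.states.push_back(State{0, 0, 0.0, 0, -1, 0, 0, 0u, 0});
  std::vector<std::map<int, int>> level(mm + 1);
  level[0][0] = 0;

  std::vector<double> OP(mm + 1, 0.0), RP(nn + 1, 0.0), VP(nn + 1, 0.0);
  for (int i = 1; i <= mm; ++i) OP[i] = OP[i - 1] + oL[i - 1];
  for (int j = 1; j <= nn; ++j) {
    RP[j] = RP[j - 1] + rL[j - 1];
    VP[j] = VP[j - 1] + vL[j - 1];
  }

  int last_nonempty = 0;
  for (int s = 1; s <= mm; ++s) {
    if (s - last_nonempty > par.max_false + 1) break;       // unreachable
    if (last_nonempty == 0 && s > par.f_min) break;         // early stop
    const int kmin = std::max(1, s - par.max_false);
    for (int k = kmin; k <= s; ++k) {
      for (const auto& kv : level[k - 1]) {
        // copy: res.states may reallocate while new states are appended
        const State st = res.states[kv.second];
        const int t0 = st.t;
        const int tmax = std::min(nn, t0 + 1 + par.max_miss);
        for (int t = t0 + 1; t <= tmax; ++t) {
          double chi2_m; uint32_t gaps; int ngap, trunc;
          if (!eval_match(OP, RP, VP, rL, k, s, t0 + 1, t, mm, nn, par,
                          chi2_m, gaps, ngap, trunc))
            continue;
          const int ce = st.ce + (s - k) + (t - t0 - 1);
          const double chi2 = st.chi2 + chi2_m;
          const int nm = st.nmatch + 1;
          auto it = level[s].find(t);
          if (it != level[s].end()) {
            State& cur = res.states[it->second];
            if (!lex_better(ce, chi2, nm, cur.ce, cur.chi2, cur.nmatch))
              continue;
            cur = State{t, ce, chi2, nm, kv.second, k, t0 + 1, gaps, trunc};
          } else {
            res.states.push_back(
                State{t, ce, chi2, nm, kv.second, k, t0 + 1, gaps, trunc});
            level[s][t] = (int)res.states.size() - 1;
          }
        }
      }
    }
    if (!level[s].empty()) last_nonempty = s;
  }

  // terminal selection
  int best = -1, best_s = -1;
  auto consider = [&](int idx, int s) {
    const State& st = res.states[idx];
    if (best < 0 || s > best_s ||
        (s == best_s && lex_better(st.ce, st.chi2, st.nmatch,
                                   res.states[best].ce, res.states[best].chi2,
                                   res.states[best].nmatch))) {
      best = idx;
      best_s = s;
    }
  };
  for (const auto& kv : level[mm]) consider(kv.second, mm);
  if (par.overlap_mode && best < 0) {
    for (int s = 0; s <= mm; ++s)
      for (const auto& kv : level[s])
        if (res.states[kv.second].t == nn) consider(kv.second, s);
  }
  if (best >= 0) {
    res.found = true;
    res.term_state = best;
    res.term_s = best_s;
  }
  return res;
}

} // namespace

static List extend_impl(const NumericVector& o, const NumericVector& r,
                        const NumericVector& rvar, const IntegerMatrix& seed,
                        const Params& par) {
  const int m = o.size(), n = r.size();
  const double C_sigma = par.C;

  // seed matches: rows (qs, qe, rs, re), 1-based inclusive, ordered
  std::vector<double> RP(n + 1, 0.0), VP(n + 1, 0.0), OPf(m + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    RP[j] = RP[j - 1] + r[j - 1];
    VP[j] = VP[j - 1] + rvar[j - 1];
  }
  for (int i = 1; i <= m; ++i) OPf[i] = OPf[i - 1] + o[i - 1];

  int ce = 0, nmatch = 0;
  double chi2 = 0.0;
  const int nseed = seed.nrow();
  for (int i = 0; i < nseed; ++i) {
    const int qs = seed(i, 0), qe = seed(i, 1), rs = seed(i, 2), re = seed(i, 3);
    const double os = OPf[qe] - OPf[qs - 1];
    const double rsum = RP[re] - RP[rs - 1];
    const double var = VP[re] - VP[rs - 1];
    if (var <= 0 || std::fabs(os - rsum) > C_sigma * std::sqrt(var))
      return List::create(Named("found") = false);
    ce += (qe - qs) + (re - rs);
    chi2 += (os - rsum) * (os - rsum) / var;
    ++nmatch;
  }
  const int q0 = seed(0, 0), q1 = seed(nseed - 1, 1);
  const int r0 = seed(0, 2), r1 = seed(nseed - 1, 3);

  // right side
  NumericVector oR(std::max(0, m - q1)), rR(std::max(0, n - r1)),
      vR(std::max(0, n - r1));
  for (int i = 0; i < oR.size(); ++i) oR[i] = o[q1 + i];
  for (int j = 0; j < rR.size(); ++j) {
    rR[j] = r[r1 + j];
    vR[j] = rvar[r1 + j];
  }
  SideResult right = side_extend(oR, rR, vR, par);
  if (!right.found) return List::create(Named("found") = false);

  // left side (mirrored)
  NumericVector oLv(q0 - 1), rLv(r0 - 1), vLv(r0 - 1);
  for (int i = 0; i < q0 - 1; ++i) oLv[i] = o[q0 - 2 - i];
  for (int j = 0; j < r0 - 1; ++j) {
    rLv[j] = r[r0 - 2 - j];
    vLv[j] = rvar[r0 - 2 - j];
  }
  SideResult left = side_extend(oLv, rLv, vLv, par);
  if (!left.found) return List::create(Named("found") = false);

  // assemble matches in global coordinates
  std::vector<std::array<int, 7>> rows; // qs qe rs re ngaps trunc side
  std::vector<int> gap_idx;

  // left: backtracking from the terminal visits the global-leftmost match
  // first, so the collected order is already leftmost-first
  {
    int s_cur = left.term_s;
    for (int idx = left.term_state; idx > 0;) {
      const State& st = left.states[idx];
      const int k = st.k, l = st.l, t = st.t;
      // local match k..s_cur, l..t ; map to global: query q0 - s_cur .. q0 - k
      // reference r0 - t .. r0 - l
      std::array<int, 7> row{q0 - s_cur, q0 - k, r0 - t, r0 - l, 0, st.trunc, 0};
      int ng = 0;
      for (int b = 0; b < 30; ++b)
        if (st.gapmask & (1u << b)) {
          gap_idx.push_back(r0 - (l + 1 + b));
          ++ng;
        }
      row[4] = ng;
      rows.push_back(row);
      s_cur = k - 1;
      idx = st.parent;
    }
  }
  for (int i = 0; i < nseed; ++i)
    rows.push_back({seed(i, 0), seed(i, 1), seed(i, 2), seed(i, 3), 0, 0, 1});
  {
    std::vector<std::array<int, 7>> tmp;
    int s_cur = right.term_s;
    for (int idx = right.term_state; idx > 0;) {
      const State& st = right.states[idx];
      const int k = st.k, l = st.l, t = st.t;
      std::array<int, 7> row{q1 + k, q1 + s_cur, r1 + l, r1 + t, 0, st.trunc, 2};
      int ng = 0;
      for (int b = 0; b < 30; ++b)
        if (st.gapmask & (1u << b)) {
          gap_idx.push_back(r1 + l + 1 + b);
          ++ng;
        }
      row[4] = ng;
      tmp.push_back(row);
      s_cur = k - 1;
      idx = st.parent;
    }
    for (auto it = tmp.rbegin(); it != tmp.rend(); ++it) rows.push_back(*it);
  }

  const State& Ls = left.states[left.term_state];
  const State& Rs = right.states[right.term_state];
  const int tot_ce = ce + Ls.ce + Rs.ce;
  const double tot_chi2 = chi2 + Ls.chi2 + Rs.chi2;
  const int tot_nm = nmatch + Ls.nmatch + Rs.nmatch;

  IntegerMatrix M(rows.size(), 7);
  int miss_cuts = 0, false_cuts = 0, miss_frag = 0;
  for (size_t i = 0; i < rows.size(); ++i) {
    for (int jj = 0; jj < 7; ++jj) M(i, jj) = rows[i][jj];
    false_cuts += rows[i][1] - rows[i][0];
    miss_cuts += rows[i][3] - rows[i][2] - rows[i][4];
    miss_frag += rows[i][4];
  }
  colnames(M) = CharacterVector::create("q_start", "q_end", "r_start", "r_end",
                                        "n_gaps", "truncated", "part");
  const double C_ce = C_sigma * C_sigma * m + 1.0;
  return List::create(
      Named("found") = true, Named("matches") = M,
      Named("gap_ref_idx") = IntegerVector(gap_idx.begin(), gap_idx.end()),
      Named("cut_errors") = tot_ce, Named("missing_cuts") = miss_cuts,
      Named("false_cuts") = false_cuts, Named("missing_fragments") = miss_frag,
      Named("chi2") = tot_chi2, Named("n_matches") = tot_nm,
      Named("score") = C_ce * tot_ce + tot_chi2,
      Named("q_aligned_start") = q0 - left.term_s,
      Named("q_aligned_end") = q1 + right.term_s,
      Named("r_start") = rows.front()[2], Named("r_end") = rows.back()[3]);
}

// [[Rcpp::export]]
List dp_extend_cpp(NumericVector o, NumericVector r, NumericVector rvar,
                   IntegerMatrix seed, double C_sigma, int max_false,
                   int max_miss, int f_min, double small_bp, int gap_max_run,
                   bool overlap_mode, bool trunc_chi2) {
  Params par{C_sigma, max_false, max_miss, f_min, small_bp, gap_max_run,
             overlap_mode, trunc_chi2};
  return extend_impl(o, r, rvar, seed, par);
}

// Batched extension of many seed hits of one query against one reference.
// `hits` columns: q_pos, r_pos, variant (1 plain / 2 merge12 / 3 merge23),
// q_merged (0/1).  Returns one result (or NULL) per hit.
// [[Rcpp::export]]
List dp_extend_batch_cpp(NumericVector o, NumericVector r, NumericVector rvar,
                         IntegerMatrix hits, double C_sigma, int max_false,
                         int max_miss, int f_min, double small_bp,
                         int gap_max_run, bool overlap_mode, bool trunc_chi2) {
  Params par{C_sigma, max_false, max_miss, f_min, small_bp, gap_max_run,
             overlap_mode, trunc_chi2};
  const int m = o.size(), n = r.size();
  const int nh = hits.nrow();
  List out(nh);
  IntegerMatrix seed(2, 4);
  for (int h = 0; h < nh; ++h) {
    const int i = hits(h, 0), j = hits(h, 1);
    const int variant = hits(h, 2);
    const bool qm = hits(h, 3) != 0;
    // first anchor match
    seed(0, 0) = i;
    seed(0, 1) = qm ? i + 1 : i;
    seed(0, 2) = j;
    seed(0, 3) = (variant == 2) ? j + 1 : j;
    // second anchor match
    seed(1, 0) = qm ? i + 2 : i + 1;
    seed(1, 1) = seed(1, 0);
    seed(1, 2) = (variant == 2) ? j + 2 : j + 1;
    seed(1, 3) = (variant == 1) ? j + 1 : j + 2;
    if (seed(1, 1) > m || seed(1, 3) > n) {
      out[h] = R_NilValue;
      continue;
    }
    out[h] = extend_impl(o, r, rvar, seed, par);
  }
  return out;
}
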