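#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive enumeration of intrinsic-terminator decompositions:
// stem5 + loop + stem3 (+ optional 1-nt bulge per arm) + spacer + 12-nt tail.
// Hairpin free energy is computed per decomposition from the supplied
// nearest-neighbor tables so that weak hairpins can be rejected in place.

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// pair types in table order: CG GC GU UG AU UA (DNA T stands for U)
static inline int pair_idx(int x, int y, bool allow_gu) {
  if (x < 0 || y < 0) return -1;
  if (x == 1 && y == 2) return 0;                 // C-G
  if (x == 2 && y == 1) return 1;                 // G-C
  if (x == 2 && y == 3) return allow_gu ? 2 : -1; // G-U
  if (x == 3 && y == 2) return allow_gu ? 3 : -1; // U-G
  if (x == 0 && y == 3) return 4;                 // A-U
  if (x == 3 && y == 0) return 5;                 // U-A
  return -1;
}

static const int REV_PAIR[6] = {1, 0, 3, 2, 5, 4};

struct Collector {
  std::vector<int> s5, s5e, ll, s3, s3e, sp, ts, sl, nb;
  std::vector<double> dg;
  void add(int s5_, int s5e_, int ll_, int s3_, int s3e_, int sp_, int ts_,
           int sl_, int nb_, double dg_) {
    s5.push_back(s5_); s5e.push_back(s5e_); ll.push_back(ll_);
    s3.push_back(s3_); s3e.push_back(s3e_); sp.push_back(sp_);
    ts.push_back(ts_); sl.push_back(sl_); nb.push_back(nb_);
    dg.push_back(dg_);
  }
};

// [[Rcpp::export]]
DataFrame cpp_scan_decomps(std::string seq, int stem_min, int stem_max,
                           int loop_min, int loop_max, int spacer_min,
                           int spacer_max, int tail_len, int tail_min_t,
                           int tail_head_min_t, bool allow_gu, bool allow_bulge,
                           NumericMatrix stack, NumericVector hloop,
                           double term_au, double bulge_dg, double dg_max) {
  int n = seq.size();
  std::vector<int> b(n);
  std::vector<int> tcum(n + 1, 0); // prefix count of T
  for (int i = 0; i < n; ++i) {
    b[i] = base_idx(seq[i]);
    tcum[i + 1] = tcum[i] + (b[i] == 3 ? 1 : 0);
  }
  // tail_ok[t] (0-based tail start): T-content rule holds and window fits
  std::vector<char> tail_ok(n, 0);
  for (int t = 0; t + tail_len <= n; ++t) {
    if (tcum[t + tail_len] - tcum[t] >= tail_min_t &&
        tcum[t + 5] - tcum[t] >= tail_head_min_t)
      tail_ok[t] = 1;
  }
  Collector out;
  int ptypes[32];

  double hl[31];
  for (int l = 3; l <= 30; ++l) hl[l] = hloop[l - 3];

  // fast path: no bulges
  for (int s = 0; s < n; ++s) {
    for (int L = stem_min; L <= stem_max; ++L) {
      if (s + 2 * L + loop_min + spacer_min + tail_len > n) break;
      for (int ll = loop_min; ll <= loop_max; ++ll) {
        int s3 = s + L + ll;          // 0-based stem3 start
        int tail0 = s3 + L;           // first position after stem3
        if (tail0 + spacer_min + tail_len > n) break;
        bool anytail = false;
        for (int sp = spacer_min; sp <= spacer_max; ++sp) {
          int ts = tail0 + sp;
          if (ts + tail_len > n) break;
          if (tail_ok[ts]) { anytail = true; break; }
        }
        if (!anytail) continue;
        bool ok = true;
        for (int k = 0; k < L; ++k) {
          int pi = pair_idx(b[s + k], b[s3 + L - 1 - k], allow_gu);
          if (pi < 0) { ok = false; break; }
          ptypes[k] = pi;
        }
        if (!ok) continue;
        double dg = hl[ll > 30 ? 30 : ll];
        for (int k = 0; k + 1 < L; ++k)
          dg += stack(ptypes[k], REV_PAIR[ptypes[k + 1]]);
        if (ptypes[0] >= 2) dg += term_au;
        if (dg > dg_max) continue;
        for (int sp = spacer_min; sp <= spacer_max; ++sp) {
          int ts = tail0 + sp;
          if (ts + tail_len > n) break;
          if (!tail_ok[ts]) continue;
          out.add(s + 1, s + L, ll, s3 + 1, s3 + L, sp, ts + 1, L, 0, dg);
        }
      }
    }
  }

  // bulge path: at most one single-nt bulge per arm (b5/b3), excluded from
  // the no-bulge enumeration above by requiring b5 + b3 >= 1
  if (allow_bulge) {
    std::vector<int> arm5(32), arm3(32);
    for (int s = 0; s < n; ++s)
      for (int L = stem_min; L <= stem_max; ++L)
        for (int b5 = 0; b5 <= 1; ++b5)
          for (int p5 = 1; p5 <= (b5 ? L - 1 : 1); ++p5) {
            if (!b5 && p5 > 1) break;
            for (int ll = loop_min; ll <= loop_max; ++ll)
              for (int b3 = 0; b3 <= 1; ++b3) {
                if (b5 + b3 == 0) continue;
                for (int p3 = 1; p3 <= (b3 ? L - 1 : 1); ++p3) {
                  if (!b3 && p3 > 1) break;
                  int len5 = L + b5, len3 = L + b3;
                  int loop_start = s + len5;
                  int s3 = loop_start + ll;
                  int tail0 = s3 + len3;
                  if (tail0 + spacer_min + tail_len > n) continue;
                  for (int k = 0; k < L; ++k)
                    arm5[k] = s + (b5 && k >= p5 ? k + 1 : k);
                  // p3 counts pairs from the outer end: the bulge sits
                  // after the first (L - p3) inner-side bases
                  for (int k = 0; k < L; ++k)
                    arm3[k] = s3 + (b3 && k >= L - p3 ? k + 1 : k);
                  bool ok = true;
                  for (int k = 0; k < L; ++k) {
                    int pi = pair_idx(b[arm5[k]], b[arm3[L - 1 - k]],
                                      allow_gu);
                    if (pi < 0) { ok = false; break; }
                    ptypes[k] = pi;
                  }
                  if (!ok) continue;
                  double dg = hl[ll > 30 ? 30 : ll];
                  for (int k = 0; k + 1 < L; ++k)
                    dg += stack(ptypes[k], REV_PAIR[ptypes[k + 1]]);
                  if (ptypes[0] >= 2) dg += term_au;
                  dg += bulge_dg * (b5 + b3);
                  if (dg > dg_max) continue;
                  for (int sp = spacer_min; sp <= spacer_max; ++sp) {
                    int ts = tail0 + sp;
                    if (ts + tail_len > n) break;
                    if (!tail_ok[ts]) continue;
                    out.add(s + 1, s + len5, ll, s3 + 1, s3 + len3, sp,
                            ts + 1, L, b5 + b3, dg);
                  }
                }
              }
          }
  }

  return DataFrame::create(
      _["stem5_start"] = out.s5, _["stem5_end"] = out.s5e,
      _["loop_len"] = out.ll, _["stem3_start"] = out.s3,
      _["stem3_end"] = out.s3e, _["spacer_len"] = out.sp,
      _["tail_start"] = out.ts, _["stem_len"] = out.sl,
      _["n_bulge"] = out.nb, _["delta_g"] = out.dg);
}
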