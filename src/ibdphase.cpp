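#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// State order: 0 = NONIBD, 1 = S11, 2 = S12, 3 = S21, 4 = S22.
// Diplotype codes d = 2*a1 + a2 (allele 1 = minor); pair code c = 4*da + db.
// Genotype codes 0,1,2 dosage; 3 = missing.

// ---------------------------------------------------------------------------
// Simulator: recombine two parental mosaics into one gamete.
// Mosaics are piece end positions (genetic scale, last == L) plus labels.
// [[Rcpp::export]]
List cpp_recombine(NumericVector br1, IntegerVector lab1,
                   NumericVector br2, IntegerVector lab2,
                   NumericVector cuts, int start) {
  std::vector<double> obr;
  std::vector<int> olab;
  const double L = br1[br1.size() - 1];
  int cur = start - 1;  // 0 -> haplotype 1, 1 -> haplotype 2
  double pos = 0.0;
  int nc = cuts.size();
  for (int seg = 0; seg <= nc; ++seg) {
    double hi = (seg < nc) ? cuts[seg] : L;
    if (hi > pos) {
      const NumericVector& br = cur == 0 ? br1 : br2;
      const IntegerVector& lab = cur == 0 ? lab1 : lab2;
      // pieces of the active haplotype overlapping (pos, hi]
      int i = std::lower_bound(br.begin(), br.end(), pos) - br.begin();
      if (i < br.size() && br[i] == pos) ++i;  // piece ending exactly at pos
      for (; i < br.size() && br[i] < hi; ++i) {
        obr.push_back(br[i]);
        olab.push_back(lab[i]);
      }
      int last = std::min<int>(i, lab.size() - 1);
      obr.push_back(hi);
      olab.push_back(lab[last]);
    }
    cur = 1 - cur;
    pos = hi;
  }
  // merge adjacent pieces with identical labels
  std::vector<double> mbr;
  std::vector<int> mlab;
  for (size_t i = 0; i < obr.size(); ++i) {
    if (!mlab.empty() && mlab.back() == olab[i])
      mbr.back() = obr[i];
    else {
      mbr.push_back(obr[i]);
      mlab.push_back(olab[i]);
    }
  }
  mbr.back() = L;
  return List::create(_["br"] = mbr, _["lab"] = mlab);
}

// ---------------------------------------------------------------------------
// Prescan: scaled Forward-Backward over the 5-state pair HMM.
//
// obs: m x 80 matrix, column c*5 + s = P(observed genotype pair combo c |
// state s) at that marker, c = 4*ga' + gb' with missing coded 3.
// trans: (m-1) x 25, column-major 5x5 per interval.  pi0: prior 5-vector.

static void pair_fb(const int* ga, const int* gb, int m,
                    const NumericMatrix& obs, const NumericMatrix& trans,
                    const NumericVector& pi0, double* post /* 5*m */) {
  std::vector<double> alpha(5 * m), beta(5 * m);
  double tmp[5];
  // forward
  {
    int c = ga[0] * 4 + gb[0];
    double z = 0;
    for (int s = 0; s < 5; ++s) {
      alpha[s] = pi0[s] * obs(0, c * 5 + s);
      z += alpha[s];
    }
    for (int s = 0; s < 5; ++s) alpha[s] /= z;
  }
  for (int j = 1; j < m; ++j) {
    int c = ga[j] * 4 + gb[j];
    const double* aprev = &alpha[5 * (j - 1)];
    double z = 0;
    for (int p = 0; p < 5; ++p) {
      double acc = 0;
      for (int q = 0; q < 5; ++q) acc += aprev[q] * trans(j - 1, p * 5 + q);
      tmp[p] = acc * obs(j, c * 5 + p);
      z += tmp[p];
    }
    for (int p = 0; p < 5; ++p) alpha[5 * j + p] = tmp[p] / z;
  }
  // backward
  for (int s = 0; s < 5; ++s) beta[5 * (m - 1) + s] = 1.0;
  for (int j = m - 2; j >= 0; --j) {
    int c = ga[j + 1] * 4 + gb[j + 1];
    const double* bnext = &beta[5 * (j + 1)];
    double z = 0;
    for (int q = 0; q < 5; ++q) {
      double acc = 0;
      for (int p = 0; p < 5; ++p)
        acc += trans(j, p * 5 + q) * obs(j + 1, c * 5 + p) * bnext[p];
      tmp[q] = acc;
      z += acc;
    }
    for (int q = 0; q < 5; ++q) beta[5 * j + q] = tmp[q] / z;
  }
  for (int j = 0; j < m; ++j) {
    double z = 0;
    for (int s = 0; s < 5; ++s) {
      post[5 * j + s] = alpha[5 * j + s] * beta[5 * j + s];
      z += post[5 * j + s];
    }
    for (int s = 0; s < 5; ++s) post[5 * j + s] /= z;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_posteriors(IntegerVector ga, IntegerVector gb,
                                  NumericMatrix obs, NumericMatrix trans,
                                  NumericVector pi0) {
  int m = ga.size();
  NumericMatrix post(5, m);
  pair_fb(ga.begin(), gb.begin(), m, obs, trans, pi0, post.begin());
  return post;
}

// Call maximal runs with combined IBD posterior above threshold, merging
// runs separated by fewer than gap_merge markers and dropping runs shorter
// than min_markers.  Returns rows (start, end, peak) with 0-based half-open
// marker intervals.
static void call_runs(const double* post, int m, double threshold,
                      int gap_merge, int min_markers,
                      std::vector<std::array<double, 3> >& out) {
  std::vector<int> starts, ends;
  std::vector<double> peaks;
  int run_start = -1;
  double peak = 0;
  for (int j = 0; j <= m; ++j) {
    double pibd = -1;
    if (j < m)
      pibd = post[5 * j + 1] + post[5 * j + 2] + post[5 * j + 3] +
             post[5 * j + 4];
    if (j < m && pibd > threshold) {
      if (run_start < 0) { run_start = j; peak = pibd; }
      else peak = std::max(peak, pibd);
    } else if (run_start >= 0) {
      starts.push_back(run_start);
      ends.push_back(j);
      peaks.push_back(peak);
      run_start = -1;
    }
  }
  // merge runs separated by fewer than gap_merge markers
  std::vector<int> ms, me;
  std::vector<double> mp;
  for (size_t i = 0; i < starts.size(); ++i) {
    if (!ms.empty() && starts[i] - me.back() < gap_merge) {
      me.back() = ends[i];
      mp.back() = std::max(mp.back(), peaks[i]);
    } else {
      ms.push_back(starts[i]);
      me.push_back(ends[i]);
      mp.push_back(peaks[i]);
    }
  }
  for (size_t i = 0; i < ms.size(); ++i)
    if (me[i] - ms[i] >= min_markers)
      out.push_back({(double)ms[i], (double)me[i], mp[i]});
}

// [[Rcpp::export]]
NumericMatrix cpp_scan_pairs(IntegerMatrix gcode, NumericMatrix obs,
                             NumericMatrix trans, NumericVector pi0,
                             double threshold, int gap_merge,
                             int min_markers, bool progress) {
  int n = gcode.nrow(), m = gcode.ncol();
  std::vector<double> post(5 * m);
  std::vector<int> ga(m), gb(m);
  std::vector<std::array<double, 5> > segs;
  for (int a = 0; a < n - 1; ++a) {
    for (int j = 0; j < m; ++j) ga[j] = gcode(a, j);
    for (int b = a + 1; b < n; ++b) {
      for (int j = 0; j < m; ++j) gb[j] = gcode(b, j);
      pair_fb(ga.data(), gb.data(), m, obs, trans, pi0, post.data());
      std::vector<std::array<double, 3> > runs;
      call_runs(post.data(), m, threshold, gap_merge, min_markers, runs);
      for (auto& r : runs)
        segs.push_back({(double)(a + 1), (double)(b + 1), r[0], r[1], r[2]});
    }
    if (progress && (a % 25 == 0))
      Rcpp::Rcout << "prescan: individual " << a + 1 << "/" << n
                  << ", segments so far: " << segs.size() << std::endl;
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(segs.size(), 5);
  for (size_t i = 0; i < segs.size(); ++i)
    for (int k = 0; k < 5; ++k) out(i, k) = segs[i][k];
  colnames(out) = CharacterVector::create("a", "b", "start", "end", "peak");
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_call_runs(NumericMatrix post, double threshold,
                            int gap_merge, int min_markers) {
  std::vector<std::array<double, 3> > runs;
  call_runs(post.begin(), post.ncol(), threshold, gap_merge, min_markers,
            runs);
  NumericMatrix out(runs.size(), 3);
  for (size_t i = 0; i < runs.size(); ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = runs[i][k];
  colnames(out) = CharacterVector::create("start", "end", "peak");
  return out;
}

// ---------------------------------------------------------------------------
// Min-Sum engine over the Bayesian network restricted to plausible segments.
//
// Factors per segment chain (pair a, b over markers js..je-1):
//   F_js(da, db, p)          = -log[ pi0(p) E(p; da,db) / Z0 ]
//   F_j (da, db, q, p)       = -log[ T_{j-1}(q,p) E_j(p; da,db) / Z(q,da,db) ]
// plus genotype unaries on each diplotype variable h.  Messages live in the
// negative-log domain; factor-to-h messages are damped, chain messages
// (alpha forward, beta backward) are recomputed exactly each sweep.

struct Seg {
  int a, b, start, len;
  std::vector<double> Ma, Mb;      // factor -> h messages, 4 * len
  std::vector<double> alpha, beta; // chain messages, 5 * len
  std::vector<int> ha, hb;         // h-variable column per marker
};

static inline double neglog(double x, double big) {
  return x > 0 ? std::min(-std::log(x), big) : big;
}

static void norm_min(double* v, int k) {
  double mn = v[0];
  for (int i = 1; i < k; ++i) mn = std::min(mn, v[i]);
  for (int i = 0; i < k; ++i) v[i] -= mn;
}

// [[Rcpp::export]]
List cpp_min_sum(IntegerMatrix gcode, NumericVector f, double epsilon,
                 NumericMatrix trans, NumericVector pi0,
                 IntegerMatrix segdef, IntegerVector anchors,
                 double damping, int max_iters, double tol, double big) {
  const int n = gcode.nrow(), m = gcode.ncol(), nseg = segdef.nrow();

  // --- per-marker tables -----------------------------------------------
  // emission E(p, c) with c = 4*da + db; lE = -log E; lZ(q, c) = +log Z.
  std::vector<double> lE(m * 80), lZ(m * 80), lZ0(m * 16);
  std::vector<double> lT(std::max(m - 1, 0) * 25);
  {
    std::vector<double> E(80);
    for (int j = 0; j < m; ++j) {
      double fr = f[j];
      double w[4] = {1 - fr, fr, 1 - fr, fr};  // allele weight by allele
      for (int da = 0; da < 4; ++da) {
        int a1 = da >> 1, a2 = da & 1;
        for (int db = 0; db < 4; ++db) {
          int b1 = db >> 1, b2 = db & 1;
          double full = w[a1] * w[a2] * w[b1] * w[b2];
          int c = 4 * da + db;
          E[c * 5 + 0] = full;
          int aa[2] = {a1, a2}, bb[2] = {b1, b2};
          for (int s = 1; s < 5; ++s) {
            int i = (s - 1) >> 1, jj = (s - 1) & 1;  // S(i+1)(jj+1)
            E[c * 5 + s] =
                (aa[i] == bb[jj]) ? full / w[aa[i]] : 0.0;
          }
        }
      }
      for (int k = 0; k < 80; ++k) lE[j * 80 + k] = neglog(E[k], big);
      for (int c = 0; c < 16; ++c) {
        double z0 = 0;
        for (int p = 0; p < 5; ++p) z0 += pi0[p] * E[c * 5 + p];
        lZ0[j * 16 + c] = std::log(z0);
        if (j > 0) {
          for (int q = 0; q < 5; ++q) {
            double z = 0;
            for (int p = 0; p < 5; ++p)
              z += trans(j - 1, p * 5 + q) * E[c * 5 + p];
            lZ[j * 80 + c * 5 + q] = std::log(z);
          }
        }
      }
      if (j > 0)
        for (int k = 0; k < 25; ++k)
          lT[(j - 1) * 25 + k] = neglog(trans(j - 1, k), big);
    }
  }

  // --- h variables: cells covered by at least one segment ---------------
  IntegerMatrix hidx(n, m);
  std::fill(hidx.begin(), hidx.end(), -1);
  std::vector<Seg> segs(nseg);
  int nH = 0;
  for (int s = 0; s < nseg; ++s) {
    Seg& S = segs[s];
    S.a = segdef(s, 0); S.b = segdef(s, 1);
    S.start = segdef(s, 2);
    S.len = segdef(s, 3) - segdef(s, 2);
    S.Ma.assign(4 * S.len, 0.0);
    S.Mb.assign(4 * S.len, 0.0);
    S.alpha.assign(5 * S.len, 0.0);
    S.beta.assign(5 * S.len, 0.0);
    S.ha.resize(S.len);
    S.hb.resize(S.len);
    for (int j = 0; j < S.len; ++j) {
      int gj = S.start + j;
      if (hidx(S.a, gj) < 0) hidx(S.a, gj) = nH++;
      if (hidx(S.b, gj) < 0) hidx(S.b, gj) = nH++;
      S.ha[j] = hidx(S.a, gj);
      S.hb[j] = hidx(S.b, gj);
    }
  }

  // unary potentials (genotype factors, plus per-individual anchors)
  std::vector<double> unary(4 * (size_t)nH, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      int h = hidx(i, j);
      if (h < 0) continue;
      int g = gcode(i, j);
      for (int d = 0; d < 4; ++d) {
        int dose = (d >> 1) + (d & 1);
        double u = 0;
        if (g != 3) u = (g == dose) ? neglog(1 - epsilon, big)
                                    : neglog(epsilon / 2, big);
        if (anchors[i] == j && d != 2) u += big;  // fix (minor, major)
        unary[4 * (size_t)h + d] = u;
      }
    }
  std::vector<double> S_sum(4 * (size_t)nH, 0.0);  // sum of factor->h msgs

  // --- damped Min-Sum sweeps --------------------------------------------
  double delta = 0;
  int it = 0;
  bool converged = false;
  std::vector<double> nua, nub, A(80), D(25);
  double newmsg[4];
  for (it = 1; it <= max_iters; ++it) {
    delta = 0;
    for (int s = 0; s < nseg; ++s) {
      Seg& S = segs[s];
      const int len = S.len;
      nua.assign(4 * len, 0.0);
      nub.assign(4 * len, 0.0);
      for (int j = 0; j < len; ++j) {
        for (int d = 0; d < 4; ++d) {
          nua[4 * j + d] = unary[4 * (size_t)S.ha[j] + d] +
                           S_sum[4 * (size_t)S.ha[j] + d] - S.Ma[4 * j + d];
          nub[4 * j + d] = unary[4 * (size_t)S.hb[j] + d] +
                           S_sum[4 * (size_t)S.hb[j] + d] - S.Mb[4 * j + d];
        }
        norm_min(&nua[4 * j], 4);
        norm_min(&nub[4 * j], 4);
      }
      // forward chain messages alpha_j = msg F_j -> p_j
      for (int j = 0; j < len; ++j) {
        int gj = S.start + j;
        const double* e = &lE[gj * 80];
        double* al = &S.alpha[5 * j];
        for (int p = 0; p < 5; ++p) al[p] = big * 8;
        if (j == 0) {
          for (int da = 0; da < 4; ++da)
            for (int db = 0; db < 4; ++db) {
              int c = 4 * da + db;
              double w = nua[da] + nub[db] + lZ0[gj * 16 + c];
              for (int p = 0; p < 5; ++p) {
                double v = w + neglog(pi0[p], big) + e[c * 5 + p];
                if (v < al[p]) al[p] = v;
              }
            }
        } else {
          const double* ap = &S.alpha[5 * (j - 1)];
          const double* t = &lT[(gj - 1) * 25];
          const double* z = &lZ[gj * 80];
          for (int da = 0; da < 4; ++da)
            for (int db = 0; db < 4; ++db) {
              int c = 4 * da + db;
              double w = nua[4 * j + da] + nub[4 * j + db];
              for (int q = 0; q < 5; ++q)
                A[c * 5 + q] = w + ap[q] + z[c * 5 + q];
            }
          for (int c = 0; c < 16; ++c)
            for (int q = 0; q < 5; ++q) {
              double base = A[c * 5 + q];
              for (int p = 0; p < 5; ++p) {
                double v = base + t[p * 5 + q] + e[c * 5 + p];
                if (v < al[p]) al[p] = v;
              }
            }
        }
        norm_min(al, 5);
      }
      // backward chain messages beta_{j-1} = msg F_j -> p_{j-1}
      for (int p = 0; p < 5; ++p) S.beta[5 * (len - 1) + p] = 0;
      for (int j = len - 1; j >= 1; --j) {
        int gj = S.start + j;
        const double* e = &lE[gj * 80];
        const double* t = &lT[(gj - 1) * 25];
        const double* z = &lZ[gj * 80];
        const double* bn = &S.beta[5 * j];
        double* bp = &S.beta[5 * (j - 1)];
        for (int q = 0; q < 5; ++q) bp[q] = big * 8;
        for (int da = 0; da < 4; ++da)
          for (int db = 0; db < 4; ++db) {
            int c = 4 * da + db;
            double w = nua[4 * j + da] + nub[4 * j + db];
            for (int p = 0; p < 5; ++p) {
              double base = w + bn[p] + e[c * 5 + p];
              for (int q = 0; q < 5; ++q) {
                double v = base + t[p * 5 + q] + z[c * 5 + q];
                if (v < bp[q]) bp[q] = v;
              }
            }
          }
        norm_min(bp, 5);
      }
      // factor -> h messages, damped
      for (int j = 0; j < len; ++j) {
        int gj = S.start + j;
        const double* e = &lE[gj * 80];
        const double* bn = &S.beta[5 * j];
        for (int side = 0; side < 2; ++side) {
          double* M = side == 0 ? &S.Ma[4 * j] : &S.Mb[4 * j];
          const double* nuo = side == 0 ? &nub[4 * j] : &nua[4 * j];
          int hcol = side == 0 ? S.ha[j] : S.hb[j];
          for (int d = 0; d < 4; ++d) newmsg[d] = big * 8;
          if (j == 0) {
            for (int da = 0; da < 4; ++da)
              for (int db = 0; db < 4; ++db) {
                int c = 4 * da + db;
                int dme = side == 0 ? da : db;
                int doth = side == 0 ? db : da;
                double w = nuo[doth] + lZ0[gj * 16 + c];
                for (int p = 0; p < 5; ++p) {
                  double v = w + neglog(pi0[p], big) + e[c * 5 + p] + bn[p];
                  if (v < newmsg[dme]) newmsg[dme] = v;
                }
              }
          } else {
            const double* ap = &S.alpha[5 * (j - 1)];
            const double* t = &lT[(gj - 1) * 25];
            const double* z = &lZ[gj * 80];
            for (int q = 0; q < 5; ++q)
              for (int p = 0; p < 5; ++p)
                D[q * 5 + p] = ap[q] + t[p * 5 + q] + bn[p];
            for (int da = 0; da < 4; ++da)
              for (int db = 0; db < 4; ++db) {
                int c = 4 * da + db;
                int dme = side == 0 ? da : db;
                int doth = side == 0 ? db : da;
                double w = nuo[doth];
                for (int q = 0; q < 5; ++q) {
                  double base = w + z[c * 5 + q];
                  for (int p = 0; p < 5; ++p) {
                    double v = base + D[q * 5 + p] + e[c * 5 + p];
                    if (v < newmsg[dme]) newmsg[dme] = v;
                  }
                }
              }
          }
          norm_min(newmsg, 4);
          for (int d = 0; d < 4; ++d) {
            double upd = damping * M[d] + (1 - damping) * newmsg[d];
            double ch = std::fabs(upd - M[d]);
            if (ch > delta) delta = ch;
            S_sum[4 * (size_t)hcol + d] += upd - M[d];
            M[d] = upd;
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
    if (delta < tol) { converged = true; break; }
  }
  if (it > max_iters) it = max_iters;

  // --- outputs -----------------------------------------------------------
  NumericMatrix belief(4, nH);
  for (int h = 0; h < nH; ++h)
    for (int d = 0; d < 4; ++d)
      belief(d, h) = unary[4 * (size_t)h + d] + S_sum[4 * (size_t)h + d];
  List seg_states(nseg), seg_margin(nseg), seg_mm(nseg);
  for (int s = 0; s < nseg; ++s) {
    Seg& S = segs[s];
    NumericMatrix mmz(5, S.len), almat(5, S.len), bemat(5, S.len);
    for (int j = 0; j < S.len; ++j)
      for (int pp = 0; pp < 5; ++pp) {
        mmz(pp, j) = S.alpha[5 * j + pp] + S.beta[5 * j + pp];
        almat(pp, j) = S.alpha[5 * j + pp];
        bemat(pp, j) = S.beta[5 * j + pp];
      }
    seg_mm[s] = List::create(_["mm"] = mmz, _["alpha"] = almat,
                             _["beta"] = bemat);
    IntegerVector st(S.len);
    NumericVector mg(S.len);
    for (int j = 0; j < S.len; ++j) {
      double mm[5];
      for (int p = 0; p < 5; ++p)
        mm[p] = S.alpha[5 * j + p] + S.beta[5 * j + p];
      int best = 0;
      for (int p = 1; p < 5; ++p)
        if (mm[p] < mm[best]) best = p;  // ties -> lower-numbered state
      double second = R_PosInf;
      for (int p = 0; p < 5; ++p)
        if (p != best && mm[p] < second) second = mm[p];
      st[j] = best + 1;
      mg[j] = second - mm[best];
    }
    seg_states[s] = st;
    seg_margin[s] = mg;
  }
  return List::create(_["hidx"] = hidx, _["belief"] = belief,
                      _["seg_states"] = seg_states,
                      _["seg_margin"] = seg_margin,
                      _["seg_maxmarg"] = seg_mm,
                      _["converged"] = converged, _["iters"] = it,
                      _["delta"] = delta);
}
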