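#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh) over integer-encoded residues.
// Residue codes are 1-based indices into the substitution matrix. A gap of
// length k costs gap_open + (k-1) * gap_extend; switching gap direction
// opens a new gap.
//
// States: H = best ending in a residue-residue column or overall,
//         P = gap in target (consumes query), Q = gap in query (consumes
//         target).

static const int NEG = INT_MIN / 4;

// trace codes for H: 0 = origin/stop, 1 = diagonal, 2 = from P, 3 = from Q
// trace codes for P/Q: 1 = opened from H, 0 = extended

// [[Rcpp::export]]
List align_pair_cpp(IntegerVector q, IntegerVector t, IntegerMatrix sub,
                    IntegerMatrix eq, int gap_open, int gap_extend,
                    bool local) {
  const int n = q.size(), m = t.size();
  const int W = m + 1;
  std::vector<int> H((n + 1) * W, 0), P((n + 1) * W, NEG), Q((n + 1) * W, NEG);
  std::vector<unsigned char> trH((n + 1) * W, 0), trP((n + 1) * W, 0),
      trQ((n + 1) * W, 0);

  if (!local) {
    for (int i = 1; i <= n; i++) {
      P[i * W] = gap_open + (i - 1) * gap_extend;
      H[i * W] = P[i * W];
      trH[i * W] = 2;
      trP[i * W] = (i == 1) ? 1 : 0;
    }
    for (int j = 1; j <= m; j++) {
      Q[j] = gap_open + (j - 1) * gap_extend;
      H[j] = Q[j];
      trH[j] = 3;
      trQ[j] = (j == 1) ? 1 : 0;
    }
  }

  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      const int up = (i - 1) * W + j, left = i * W + (j - 1),
                diag = (i - 1) * W + (j - 1), cur = i * W + j;
      int popen = (H[up] == NEG) ? NEG : H[up] + gap_open;
      int pext = (P[up] == NEG) ? NEG : P[up] + gap_extend;
      if (popen >= pext) {
        P[cur] = popen;
        trP[cur] = 1;
      } else {
        P[cur] = pext;
        trP[cur] = 0;
      }
      int qopen = (H[left] == NEG) ? NEG : H[left] + gap_open;
      int qext = (Q[left] == NEG) ? NEG : Q[left] + gap_extend;
      if (qopen >= qext) {
        Q[cur] = qopen;
        trQ[cur] = 1;
      } else {
        Q[cur] = qext;
        trQ[cur] = 0;
      }
      int best = NEG;
      unsigned char tr = 0;
      if (H[diag] != NEG) {
        best = H[diag] + sub(q[i - 1] - 1, t[j - 1] - 1);
        tr = 1;
      }
      if (P[cur] > best) {
        best = P[cur];
        tr = 2;
      }
      if (Q[cur] > best) {
        best = Q[cur];
        tr = 3;
      }
      if (local && best < 0) {
        best = 0;
        tr = 0;
      }
      H[cur] = best;
      trH[cur] = tr;
    }
  }

  // endpoint
  int ei = n, ej = m, score;
  if (local) {
    score = 0;
    ei = 0;
    ej = 0;
    for (int i = 1; i <= n; i++) {
      for (int j = 1; j <= m; j++) {
        int s = H[i * W + j];
        // ties: prefer longer span (larger i + j), then smaller template end
        if (s > score || (s == score && s > 0 &&
                          (i + j > ei + ej || (i + j == ei + ej && j < ej)))) {
          score = s;
          ei = i;
          ej = j;
        }
      }
    }
  } else {
    score = H[n * W + m];
  }

  // traceback
  std::string ops;
  int i = ei, j = ej;
  int state = 0; // 0 = H, 1 = P, 2 = Q
  while (true) {
    if (state == 0) {
      if (i == 0 && j == 0) break;
      unsigned char c = trH[i * W + j];
      if (c == 0) break; // local origin
      if (c == 1) {
        ops.push_back(eq(q[i - 1] - 1, t[j - 1] - 1) ? 'M' : 'S');
        i--;
        j--;
      } else if (c == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      unsigned char c = trP[i * W + j];
      ops.push_back('I');
      i--;
      state = (c == 1) ? 0 : 1;
    } else {
      unsigned char c = trQ[i * W + j];
      ops.push_back('D');
      j--;
      state = (c == 1) ? 0 : 2;
    }
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(
      _["score"] = score, _["ops"] = ops, _["q_start"] = i + 1,
      _["q_end"] = ei, _["t_start"] = j + 1, _["t_end"] = ej);
}

// Score-only local alignment of many reads against many templates.
// qs, ts: lists of 1-based integer residue vectors. Returns a matrix
// (length(qs) x length(ts)) of local alignment scores.
// [[Rcpp::export]]
IntegerMatrix score_many_cpp(List qs, List ts, IntegerMatrix sub, int gap_open,
                             int gap_extend) {
  const int nq = qs.size(), nt = ts.size();
  IntegerMatrix out(nq, nt);
  std::vector<std::vector<int>> tv(nt);
  for (int k = 0; k < nt; k++) tv[k] = as<std::vector<int>>(ts[k]);
  for (int r = 0; r < nq; r++) {
    std::vector<int> qv = as<std::vector<int>>(qs[r]);
    const int n = qv.size();
    for (int k = 0; k < nt; k++) {
      const std::vector<int>& tvk = tv[k];
      const int m = tvk.size();
      std::vector<int> H(m + 1, 0), Pp(m + 1, NEG), Qq(m + 1, NEG);
      int best = 0;
      for (int i = 1; i <= n; i++) {
        int diagH = H[0]; // H[i-1][0]
        H[0] = 0;
        int qrow = NEG;
        for (int j = 1; j <= m; j++) {
          int pr = std::max(H[j] + gap_open,
                            Pp[j] == NEG ? NEG : Pp[j] + gap_extend);
          int ql = std::max(H[j - 1] + gap_open,
                            qrow == NEG ? NEG : qrow + gap_extend);
          int d = diagH + sub(qv[i - 1] - 1, tvk[j - 1] - 1);
          int h = d;
          if (pr > h) h = pr;
          if (ql > h) h = ql;
          if (h < 0) h = 0;
          diagH = H[j];
          H[j] = h;
          Pp[j] = pr;
          qrow = ql;
          if (h > best) best = h;
        }
      }
      out(r, k) = best;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exhaustive path-enumeration oracles (test use). These enumerate every
// alignment path explicitly (no tabulation), so they are an independent
// route to the optimal score. Feasible only for short sequences.

struct Enum {
  const int *q, *t;
  int n, m;
  const int* sub;
  int nrow;
  int go, ge;
  int s(int i, int j) const { return sub[(q[i] - 1) + nrow * (t[j] - 1)]; }

  int global(int i, int j, int state) const {
    if (i == n && j == m) return 0;
    int best = NEG;
    if (i < n && j < m) {
      int v = s(i, j) + global(i + 1, j + 1, 0);
      if (v > best) best = v;
    }
    if (i < n) {
      int v = (state == 1 ? ge : go) + global(i + 1, j, 1);
      if (v > best) best = v;
    }
    if (j < m) {
      int v = (state == 2 ? ge : go) + global(i, j + 1, 2);
      if (v > best) best = v;
    }
    return best;
  }

  int local(int i, int j, int state) const {
    int best = 0; // may stop anywhere
    if (i < n && j < m) {
      int v = s(i, j) + local(i + 1, j + 1, 0);
      if (v > best) best = v;
    }
    if (i < n) {
      int v = (state == 1 ? ge : go) + local(i + 1, j, 1);
      if (v > best) best = v;
    }
    if (j < m) {
      int v = (state == 2 ? ge : go) + local(i, j + 1, 2);
      if (v > best) best = v;
    }
    return best;
  }
};

// [[Rcpp::export]]
int oracle_global_cpp(IntegerVector q, IntegerVector t, IntegerMatrix sub,
                      int gap_open, int gap_extend) {
  Enum e{INTEGER(q), INTEGER(t), (int)q.size(), (int)t.size(),
         INTEGER(sub), sub.nrow(), gap_open, gap_extend};
  return e.global(0, 0, 0);
}

// [[Rcpp::export]]
int oracle_local_cpp(IntegerVector q, IntegerVector t, IntegerMatrix sub,
                     int gap_open, int gap_extend) {
  Enum e{INTEGER(q), INTEGER(t), (int)q.size(), (int)t.size(),
         INTEGER(sub), sub.nrow(), gap_open, gap_extend};
  int best = 0;
  for (int i = 0; i <= e.n; i++)
    for (int j = 0; j <= e.m; j++) {
      int v = e.local(i, j, 0);
      if (v > best) best = v;
    }
  return best;
}
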