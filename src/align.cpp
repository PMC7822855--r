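#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Alphabet {A,C,G,T,N}; N never matches.
// A gap of length L costs gap_open + L * gap_extend (both <= 0).
// Co-optimal ties: smallest (query start, ref start), then smallest
// (query end, ref end); traceback prefers the match state.
// All reported coordinates are 0-based half-open.

static inline int sub_score(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string ref,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int)query.size(), n = (int)ref.size();
  const int W = n + 1;
  const long long NEG = -1000000000LL;
  const long long OB = (long long)n + 2;  // origin pack base: qs*OB + rs

  std::vector<int> H((size_t)(m + 1) * W, 0);
  std::vector<long long> E((size_t)(m + 1) * W, NEG), F((size_t)(m + 1) * W, NEG);
  std::vector<long long> oH((size_t)(m + 1) * W, 0), oE((size_t)(m + 1) * W, 0),
      oF((size_t)(m + 1) * W, 0);
  // a cell with no (positive-score) path through it owns origin (i, j):
  // "an alignment would start here"; keeps origin comparisons consistent
  // at the borders and at score-0 cells
  for (int i = 0; i <= m; ++i)
    for (int j = 0; j <= n; ++j)
      oH[(size_t)i * W + j] = oE[(size_t)i * W + j] = oF[(size_t)i * W + j] =
          (long long)i * ((long long)n + 2) + j;

  const int ge = gap_extend, go_ge = gap_open + gap_extend;

  int best = 0, bi = 0, bj = 0;
  long long best_o = 0;

  for (int i = 1; i <= m; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= n; ++j) {
      const size_t idx = (size_t)i * W + j;
      const size_t up = idx - W, left = idx - 1, diag = idx - W - 1;

      // E: gap in ref (op I, consumes query base i)
      {
        long long a = (long long)H[up] + go_ge;
        long long b = E[up] + ge;
        if (a > b || (a == b && oH[up] <= oE[up])) {
          E[idx] = a; oE[idx] = oH[up];
        } else {
          E[idx] = b; oE[idx] = oE[up];
        }
      }
      // F: gap in query (op D, consumes ref base j)
      {
        long long a = (long long)H[left] + go_ge;
        long long b = F[left] + ge;
        if (a > b || (a == b && oH[left] <= oF[left])) {
          F[idx] = a; oF[idx] = oH[left];
        } else {
          F[idx] = b; oF[idx] = oF[left];
        }
      }
      // H: match/mismatch column
      const int s = sub_score(qc, ref[j - 1], match, mismatch);
      long long prev = 0;
      long long prev_o = (long long)(i - 1) * OB + (j - 1);  // fresh start
      if ((long long)H[diag] > prev ||
          ((long long)H[diag] == prev && oH[diag] < prev_o)) {
        prev = H[diag]; prev_o = oH[diag];
      }
      if (E[diag] > prev || (E[diag] == prev && oE[diag] < prev_o)) {
        prev = E[diag]; prev_o = oE[diag];
      }
      if (F[diag] > prev || (F[diag] == prev && oF[diag] < prev_o)) {
        prev = F[diag]; prev_o = oF[diag];
      }
      long long h = prev + s;
      if (h <= 0) {
        H[idx] = 0; oH[idx] = (long long)i * OB + j;
      } else {
        H[idx] = (int)h; oH[idx] = prev_o;
        if ((int)h > best || ((int)h == best && prev_o < best_o)) {
          best = (int)h; best_o = prev_o; bi = i; bj = j;
        }
      }
    }
  }

  if (best <= 0) {
    return List::create(
        _["score"] = 0, _["query_interval"] = IntegerVector::create(0, 0),
        _["ref_interval"] = IntegerVector::create(0, 0),
        _["ops"] = DataFrame::create(_["op"] = CharacterVector(0),
                                     _["length"] = IntegerVector(0),
                                     _["stringsAsFactors"] = false),
        _["mismatch_positions"] = IntegerVector(0));
  }

  // traceback
  std::vector<char> ops_rev;
  std::vector<int> mism_rev;
  int i = bi, j = bj;
  char state = 'H';
  for (;;) {
    const size_t idx = (size_t)i * W + j;
    if (state == 'H') {
      ops_rev.push_back('M');
      const int s = sub_score(query[i - 1], ref[j - 1], match, mismatch);
      if (!(query[i - 1] == ref[j - 1] && query[i - 1] != 'N'))
        mism_rev.push_back(i - 1);
      const long long prev = (long long)H[idx] - s;
      const long long o = oH[idx];
      const size_t diag = idx - W - 1;
      if (prev == 0 && o == (long long)(i - 1) * OB + (j - 1)) {
        --i; --j;
        break;  // alignment starts here
      }
      if ((long long)H[diag] == prev && oH[diag] == o) state = 'H';
      else if (E[diag] == prev && oE[diag] == o) state = 'E';
      else state = 'F';
      --i; --j;
    } else if (state == 'E') {
      ops_rev.push_back('I');
      const long long val = E[idx];
      const long long o = oE[idx];
      const size_t up = idx - W;
      if ((long long)H[up] + go_ge == val && oH[up] == o) state = 'H';
      else state = 'E';
      --i;
    } else {  // F
      ops_rev.push_back('D');
      const long long val = F[idx];
      const long long o = oF[idx];
      const size_t left = idx - 1;
      if ((long long)H[left] + go_ge == val && oH[left] == o) state = 'H';
      else state = 'F';
      --j;
    }
  }

  const int qs = i, rs = j;
  std::reverse(ops_rev.begin(), ops_rev.end());
  std::reverse(mism_rev.begin(), mism_rev.end());

  // run-length encode the op string
  std::vector<std::string> op_out;
  std::vector<int> len_out;
  for (size_t k = 0; k < ops_rev.size();) {
    size_t k2 = k;
    while (k2 < ops_rev.size() && ops_rev[k2] == ops_rev[k]) ++k2;
    op_out.push_back(std::string(1, ops_rev[k]));
    len_out.push_back((int)(k2 - k));
    k = k2;
  }

  return List::create(
      _["score"] = best,
      _["query_interval"] = IntegerVector::create(qs, bi),
      _["ref_interval"] = IntegerVector::create(rs, bj),
      _["ops"] = DataFrame::create(_["op"] = wrap(op_out),
                                   _["length"] = wrap(len_out),
                                   _["stringsAsFactors"] = false),
      _["mismatch_positions"] = wrap(mism_rev));
}
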