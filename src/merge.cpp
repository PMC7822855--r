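#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Gap-free end-free overlap of r1's 3' end with (already reverse-complemented)
// r2's 5' end. For every overlap length o in [1, min(l1, l2)] the overlap is
// scored as matches - mismatches (N is always a mismatch); the best-scoring
// offset (ties -> fewer mismatches, then longer overlap) decides the outcome:
//   status 0: perfect overlap of length >= min_overlap -> merged
//   status 1: best overlap contains a mismatch          -> discard "mismatch"
//   status 2: best overlap perfect but too short (or no offset) -> "short_overlap"

// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector r2rc, int min_overlap) {
  const int np = r1.size();
  CharacterVector merged(np);
  IntegerVector overlap_len(np), status(np);

  for (int p = 0; p < np; ++p) {
    const std::string a = as<std::string>(r1[p]);
    const std::string b = as<std::string>(r2rc[p]);
    const int l1 = (int)a.size(), l2 = (int)b.size();
    const int omax = std::min(l1, l2);

    int best_score = -2147483647, best_o = 0, best_mism = -1;
    for (int o = 1; o <= omax; ++o) {
      int mism = 0;
      const char *pa = a.data() + (l1 - o);
      for (int k = 0; k < o; ++k) {
        const char ca = pa[k], cb = b[k];
        if (ca != cb || ca == 'N') ++mism;
      }
      const int score = o - 2 * mism;
      if (score > best_score ||
          (score == best_score && (mism < best_mism ||
                                   (mism == best_mism && o > best_o)))) {
        best_score = score; best_o = o; best_mism = mism;
      }
    }

    if (omax < 1) {
      merged[p] = NA_STRING; overlap_len[p] = 0; status[p] = 2;
    } else if (best_mism == 0 && best_o >= min_overlap) {
      merged[p] = a + b.substr(best_o);
      overlap_len[p] = best_o; status[p] = 0;
    } else if (best_mism > 0) {
      merged[p] = NA_STRING; overlap_len[p] = best_o; status[p] = 1;
    } else {
      merged[p] = NA_STRING; overlap_len[p] = best_o; status[p] = 2;
    }
  }
  return List::create(_["merged"] = merged, _["overlap_length"] = overlap_len,
                      _["status"] = status);
}
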