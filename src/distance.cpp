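#include <Rcpp.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Levenshtein distance between a[0..na) and b[0..nb), two-row DP.
static int levenshtein(const char *a, int na, const char *b, int nb) {
  if (na == 0) return nb;
  if (nb == 0) return na;
  std::vector<int> prev(nb + 1), cur(nb + 1);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    for (int j = 1; j <= nb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int m = sub < del ? sub : del;
      cur[j] = m < ins ? m : ins;
    }
    prev.swap(cur);
  }
  return prev[nb];
}

// Hamming distance for equal-length windows (config alternative to Levenshtein).
static int hamming(const char *a, const char *b, int n) {
  int d = 0;
  for (int i = 0; i < n; ++i) d += (a[i] != b[i]);
  return d;
}

//' @title Sliding-window subsequence distance (C++ kernel)
//' @description For each target string, the minimum string distance between
//'   \code{s} and any contiguous window of the target of length
//'   \code{nchar(s)}; when the target is shorter than \code{s}, the distance
//'   of \code{s} to the whole target. \code{NA} targets give \code{NA}.
//' @param s candidate subsequence (non-empty single string)
//' @param targets character vector of symbolic records (\code{NA} = empty)
//' @param hamming_dist use Hamming instead of Levenshtein window distance
//' @return integer vector of distances, one per target
//' @keywords internal
// [[Rcpp::export]]
IntegerVector subseq_distance_cpp(std::string s, CharacterVector targets,
                                  bool hamming_dist = false) {
  int ns = s.size();
  if (ns == 0) stop("candidate subsequence must be non-empty");
  int n = targets.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(targets[i])) {
      out[i] = NA_INTEGER;
      continue;
    }
    const char *t = CHAR(STRING_ELT(targets, i));
    int nt = std::strlen(t);
    if (nt == 0) {
      out[i] = NA_INTEGER;  // zero-length record == empty marker
      continue;
    }
    if (nt < ns) {
      out[i] = levenshtein(s.c_str(), ns, t, nt);
      continue;
    }
    int best = ns + 1;
    for (int off = 0; off + ns <= nt; ++off) {
      int d = hamming_dist ? hamming(s.c_str(), t + off, ns)
                           : levenshtein(s.c_str(), ns, t + off, ns);
      if (d < best) best = d;
      if (best == 0) break;
    }
    out[i] = best;
  }
  return out;
}
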