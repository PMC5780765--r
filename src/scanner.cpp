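#include <Rcpp.h>
using namespace Rcpp;

// PWM scanning over integer-encoded sequences (A=0, C=1, G=2, T=3, N/other=-1).
// Scores are log-odds sums; any window touching an ambiguous base scores -Inf
// and can never be a hit. Both strands are scanned at every offset; a minus
// strand match at offset o scores the reverse complement of seq[o, o+W) under
// the PWM, i.e. the forward window under the reverse-complemented matrix.

static inline double window_score(const double* lod, int width,
                                  const int* seq, int offset) {
  double s = 0.0;
  for (int i = 0; i < width; ++i) {
    int b = seq[offset + i];
    if (b < 0) return R_NegInf;
    s += lod[i + width * b]; // column-major W x 4
  }
  return s;
}

// reverse-complement the W x 4 log-odds matrix once per scan
static NumericMatrix revcomp_lod(const NumericMatrix& lod) {
  int w = lod.nrow();
  NumericMatrix rc(w, 4);
  for (int i = 0; i < w; ++i)
    for (int b = 0; b < 4; ++b)
      rc(i, b) = lod(w - 1 - i, 3 - b);
  return rc;
}

// [[Rcpp::export]]
double cpp_score_at(NumericMatrix lod, IntegerVector seq, int offset0,
                    bool minus_strand) {
  int w = lod.nrow();
  if (offset0 < 0 || offset0 + w > seq.size())
    stop("offset out of range for motif width %d", w);
  if (minus_strand) {
    NumericMatrix rc = revcomp_lod(lod);
    return window_score(REAL(rc), w, INTEGER(seq), offset0);
  }
  return window_score(REAL(lod), w, INTEGER(seq), offset0);
}

// [[Rcpp::export]]
int cpp_count_hits(NumericMatrix lod, double threshold, IntegerVector seq) {
  int w = lod.nrow(), n = seq.size();
  if (n < w) return 0;
  NumericMatrix rc = revcomp_lod(lod);
  const double* fwd = REAL(lod);
  const double* rev = REAL(rc);
  const int* s = INTEGER(seq);
  int count = 0;
  for (int o = 0; o <= n - w; ++o) {
    if (window_score(fwd, w, s, o) >= threshold) ++count;
    if (window_score(rev, w, s, o) >= threshold) ++count;
  }
  return count;
}

// counts for a list of sequences x a database of motifs
// [[Rcpp::export]]
IntegerMatrix cpp_count_matrix(List seqs, List lods, NumericVector thresholds) {
  int n = seqs.size(), m = lods.size();
  IntegerMatrix out(n, m);
  std::vector<NumericMatrix> fwd, rev;
  fwd.reserve(m); rev.reserve(m);
  for (int j = 0; j < m; ++j) {
    NumericMatrix lod = lods[j];
    fwd.push_back(lod);
    rev.push_back(revcomp_lod(lod));
  }
  for (int i = 0; i < n; ++i) {
    IntegerVector sv = seqs[i];
    const int* s = INTEGER(sv);
    int len = sv.size();
    for (int j = 0; j < m; ++j) {
      int w = fwd[j].nrow();
      if (len < w) { out(i, j) = 0; continue; }
      const double* f = REAL(fwd[j]);
      const double* r = REAL(rev[j]);
      double thr = thresholds[j];
      int count = 0;
      for (int o = 0; o <= len - w; ++o) {
        if (window_score(f, w, s, o) >= thr) ++count;
        if (window_score(r, w, s, o) >= thr) ++count;
      }
      out(i, j) = count;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
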