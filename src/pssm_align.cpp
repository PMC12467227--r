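#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Local alignment of amino-acid sequences against a position-specific
// log2-odds score matrix (columns = profile match states, 20 residues).
//
// Two stages, mirroring the shape of a profile-search pipeline:
//   1. an ungapped best-diagonal scan over every sequence (cheap filter);
//   2. full affine-gap Smith-Waterman with traceback, run only for
//      sequences whose ungapped best reaches `prefilter_bits`, iterated
//      with masking to pull out additional non-overlapping domains until
//      the next domain falls below `domain_floor` bits.
//
// Scores are bits throughout; gap penalties are positive bit costs.

static const char AA[] = "ACDEFGHIKLMNPQRSTVWY";

static inline int aa_code(char c) {
  switch (c) {
    case 'A': return 0;  case 'C': return 1;  case 'D': return 2;
    case 'E': return 3;  case 'F': return 4;  case 'G': return 5;
    case 'H': return 6;  case 'I': return 7;  case 'K': return 8;
    case 'L': return 9;  case 'M': return 10; case 'N': return 11;
    case 'P': return 12; case 'Q': return 13; case 'R': return 14;
    case 'S': return 15; case 'T': return 16; case 'V': return 17;
    case 'W': return 18; case 'Y': return 19;
    default:  return -1; // unknowns (X, B, Z, ...) score as background = 0 bits
  }
}

struct Domain {
  int seq_start, seq_end;   // 0-based half-open on the sequence
  int prof_start, prof_end; // 0-based half-open on profile columns
  double bits;
  int naligned;             // aligned (residue-column) pairs
  double identity;          // fraction of aligned pairs matching consensus
};

// Ungapped Kadane scan over all diagonals; returns best run.
// prof is L x 20 column-major (NumericMatrix with L rows); the inner loop
// only tracks the best run's end — its start is recovered afterwards by
// re-walking the single best diagonal, keeping the hot loop minimal.
static Domain ungapped_best(const double *prof, int L,
                            const std::vector<int> &seq,
                            const std::vector<char> &mask,
                            const int *consensus) {
  int n = (int)seq.size();
  std::vector<double> H(L + 1, 0.0);
  Domain best; best.bits = 0; best.seq_start = best.seq_end = 0;
  best.prof_start = best.prof_end = 0; best.naligned = 0; best.identity = 0;
  double bv = 0.0; int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    if (mask[i]) { std::fill(H.begin(), H.end(), 0.0); continue; }
    int a = seq[i];
    double diag = 0.0;
    if (a >= 0) {
      const double *row = prof + (size_t)a * L;
      for (int j = 0; j < L; ++j) {
        double keep = H[j + 1];
        double h = diag + row[j];
        if (h <= 0) h = 0;
        H[j + 1] = h;
        if (h > bv) { bv = h; bi = i; bj = j; }
        diag = keep;
      }
    } else { // unknown residue scores 0: runs carry through unchanged
      for (int j = 0; j < L; ++j) {
        double keep = H[j + 1];
        H[j + 1] = diag;
        diag = keep;
      }
    }
  }
  if (bi < 0) return best;
  // recover the run start along the best diagonal
  int off = bi - bj;
  int i0 = off > 0 ? off : 0;
  double run = 0.0; int start_i = i0;
  for (int i = i0; i <= bi; ++i) {
    int j = i - off;
    if (mask[i]) { run = 0.0; start_i = i + 1; continue; }
    int a = seq[i];
    double s = a >= 0 ? prof[j + (size_t)a * L] : 0.0;
    run += s;
    if (run <= 0) { run = 0.0; start_i = i + 1; }
  }
  int b0i = start_i, b0j = start_i - off;
  best.bits = bv;
  best.seq_start = b0i; best.seq_end = bi + 1;
  best.prof_start = b0j; best.prof_end = bj + 1;
  int len = bi - b0i + 1, matches = 0;
  for (int k = 0; k < len; ++k)
    if (seq[b0i + k] == consensus[b0j + k]) ++matches;
  best.naligned = len;
  best.identity = len > 0 ? (double)matches / len : 0.0;
  return best;
}

// Full affine-gap local alignment with traceback; respects mask.
static Domain affine_best(const double *prof, int L,
                          const std::vector<int> &seq,
                          const std::vector<char> &mask,
                          const int *consensus,
                          double gap_open, double gap_extend) {
  int n = (int)seq.size();
  size_t W = (size_t)L + 1;
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, -1e18), F((n + 1) * W, -1e18);
  double bestv = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int a = seq[i - 1];
    bool blocked = mask[i - 1] != 0;
    for (int j = 1; j <= L; ++j) {
      size_t c = i * W + j;
      double e = std::max(H[c - 1] - gap_open, E[c - 1] - gap_extend);
      double f = std::max(H[c - W] - gap_open, F[c - W] - gap_extend);
      double s = blocked ? -1e9 : (a >= 0 ? prof[(j - 1) + (size_t)a * L] : 0.0);
      double m = H[c - W - 1] + s;
      double h = m;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      H[c] = h; E[c] = e; F[c] = f;
      if (h > bestv) { bestv = h; bi = i; bj = j; }
    }
  }
  Domain d; d.bits = bestv; d.naligned = 0; d.identity = 0;
  d.seq_start = d.seq_end = d.prof_start = d.prof_end = 0;
  if (bestv <= 0) return d;
  // traceback on values
  int i = bi, j = bj, matches = 0, npair = 0;
  int state = 0; // 0 = H, 1 = E (gap in seq row: j moves), 2 = F (i moves)
  const double eps = 1e-9;
  while (i > 0 && j > 0) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      if (H[c] <= eps) break;
      int a = seq[i - 1];
      double s = mask[i - 1] ? -1e9 : (a >= 0 ? prof[(j - 1) + (size_t)a * L] : 0.0);
      if (std::abs(H[c] - (H[c - W - 1] + s)) < eps) {
        ++npair;
        if (a == consensus[j - 1]) ++matches;
        --i; --j;
      } else if (std::abs(H[c] - E[c]) < eps) state = 1;
      else if (std::abs(H[c] - F[c]) < eps) state = 2;
      else break; // started at 0
    } else if (state == 1) {
      size_t cl = c - 1;
      if (std::abs(E[c] - (H[cl] - gap_open)) < eps) state = 0;
      --j;
      (void)cl;
    } else {
      size_t cu = c - W;
      if (std::abs(F[c] - (H[cu] - gap_open)) < eps) state = 0;
      --i;
      (void)cu;
    }
  }
  d.seq_start = i; d.seq_end = bi;
  d.prof_start = j; d.prof_end = bj;
  d.naligned = npair;
  d.identity = npair > 0 ? (double)matches / npair : 0.0;
  return d;
}

// [[Rcpp::export(name = ".pssm_scan")]]
DataFrame pssm_scan(NumericMatrix prof, IntegerVector consensus,
                    CharacterVector seqs,
                    double gap_open, double gap_extend,
                    double domain_floor, double prefilter_bits,
                    int max_domains) {
  int L = prof.nrow();
  if (prof.ncol() != 20) stop("profile score matrix must have 20 residue columns");
  const double *P = prof.begin();
  std::vector<int> cons(L);
  for (int j = 0; j < L; ++j) cons[j] = consensus[j];

  std::vector<int> out_seq;
  std::vector<int> v_ss, v_se, v_ps, v_pe, v_na;
  std::vector<double> v_bits, v_id;
  std::vector<int> v_stage; // 1 ungapped-only, 2 affine

  for (int k = 0; k < seqs.size(); ++k) {
    const char *cs = CHAR(STRING_ELT(seqs, k));
    int n = (int)std::strlen(cs);
    std::vector<int> seq(n);
    for (int i = 0; i < n; ++i) seq[i] = aa_code(cs[i]);
    if (n == 0) continue;
    std::vector<char> mask(n, 0);
    Domain u = ungapped_best(P, L, seq, mask, cons.data());
    if (u.bits < prefilter_bits) {
      if (u.bits >= domain_floor) {
        out_seq.push_back(k + 1);
        v_ss.push_back(u.seq_start); v_se.push_back(u.seq_end);
        v_ps.push_back(u.prof_start); v_pe.push_back(u.prof_end);
        v_bits.push_back(u.bits); v_na.push_back(u.naligned);
        v_id.push_back(u.identity); v_stage.push_back(1);
      }
      continue;
    }
    for (int d = 0; d < max_domains; ++d) {
      Domain a = affine_best(P, L, seq, mask, cons.data(), gap_open, gap_extend);
      if (a.bits < domain_floor) break;
      out_seq.push_back(k + 1);
      v_ss.push_back(a.seq_start); v_se.push_back(a.seq_end);
      v_ps.push_back(a.prof_start); v_pe.push_back(a.prof_end);
      v_bits.push_back(a.bits); v_na.push_back(a.naligned);
      v_id.push_back(a.identity); v_stage.push_back(2);
      for (int i = a.seq_start; i < a.seq_end; ++i) mask[i] = 1;
    }
  }
  return DataFrame::create(
    _["seq"] = out_seq,
    _["seq_start"] = v_ss, _["seq_end"] = v_se,
    _["prof_start"] = v_ps, _["prof_end"] = v_pe,
    _["bits"] = v_bits, _["naligned"] = v_na,
    _["identity"] = v_id, _["stage"] = v_stage);
}

// [[Rcpp::export(name = ".aa_alphabet")]]
CharacterVector aa_alphabet() {
  CharacterVector out(20);
  for (int i = 0; i < 20; ++i) out[i] = std::string(1, AA[i]);
  return out;
}
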