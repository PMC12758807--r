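#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh) with full traceback.
// A gap of length L costs gap_open + L * gap_ext (opening charged once,
// extension per gapped column), matching the package's documented scheme
// and the convention of Biostrings::pairwiseAlignment.
//
// States: H = best alignment ending in a match/mismatch column,
//         E = ending with a gap in the query (consumes subject -> 'D'),
//         F = ending with a gap in the subject (consumes query -> 'I').
// Ties resolved deterministically: the best cell is the first encountered
// in row-major order under strict improvement, i.e. smallest query end,
// then smallest subject end.

// [[Rcpp::export]]
List cpp_sw_align(std::string query, std::string subject,
                  int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int) query.size();
  const int m = (int) subject.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");
  if ((double)(n + 1) * (double)(m + 1) > 8e7)
    stop("alignment matrix too large (%d x %d)", n, m);

  const int NEG = -1000000000;
  const size_t W = (size_t) m + 1;
  std::vector<int> H((size_t)(n + 1) * W, 0);
  std::vector<int> E((size_t)(n + 1) * W, NEG);
  std::vector<int> F((size_t)(n + 1) * W, NEG);
  // traceback: dirH 0=stop 1=diag 2=fromE 3=fromF; dirE/dirF 0=open(from H) 1=extend
  std::vector<uint8_t> dH((size_t)(n + 1) * W, 0);
  std::vector<uint8_t> dE((size_t)(n + 1) * W, 0);
  std::vector<uint8_t> dF((size_t)(n + 1) * W, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = query[(size_t) i - 1];
    const size_t row = (size_t) i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      // E: gap in query (deletion of subject base j)
      int e_open = H[row + j - 1] - gap_open - gap_ext;
      int e_ext  = E[row + j - 1] - gap_ext;
      if (e_open >= e_ext) { E[row + j] = e_open; dE[row + j] = 0; }
      else                 { E[row + j] = e_ext;  dE[row + j] = 1; }
      // F: gap in subject (insertion of query base i)
      int f_open = H[prow + j] - gap_open - gap_ext;
      int f_ext  = F[prow + j] - gap_ext;
      if (f_open >= f_ext) { F[row + j] = f_open; dF[row + j] = 0; }
      else                 { F[row + j] = f_ext;  dF[row + j] = 1; }
      // H
      int s = (qc == subject[(size_t) j - 1]) ? match : mismatch;
      int diag = H[prow + j - 1] + s;
      int h = 0; uint8_t d = 0;
      if (diag > h) { h = diag; d = 1; }
      if (E[row + j] > h) { h = E[row + j]; d = 2; }
      if (F[row + j] > h) { h = F[row + j]; d = 3; }
      H[row + j] = h; dH[row + j] = d;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj)
  std::string ops;             // reversed op string, one char per column
  int i = bi, j = bj;
  int nmatch = 0, nmis = 0, nins = 0, ndel = 0;
  int state = 0;               // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    const size_t row = (size_t) i * W;
    if (state == 0) {
      uint8_t d = dH[row + j];
      if (d == 0) break;
      if (d == 1) {
        bool eq = (query[(size_t) i - 1] == subject[(size_t) j - 1]);
        ops.push_back(eq ? '=' : 'X');
        if (eq) ++nmatch; else ++nmis;
        --i; --j;
      } else if (d == 2) state = 1;
      else state = 2;
    } else if (state == 1) {   // E: 'D' consumes subject
      uint8_t d = dE[row + j];
      ops.push_back('D'); ++ndel;
      --j;
      if (d == 0) state = 0;
    } else {                   // F: 'I' consumes query
      uint8_t d = dF[row + j];
      ops.push_back('I'); ++nins;
      --i;
      if (d == 0) state = 0;
    }
  }
  const int q_start = i, s_start = j;

  // compress reversed ops into a CIGAR-like string
  std::string cigar;
  for (size_t k = ops.size(); k > 0;) {
    char op = ops[k - 1];
    size_t run = 0;
    while (k > 0 && ops[k - 1] == op) { ++run; --k; }
    cigar += std::to_string(run);
    cigar.push_back(op);
  }

  return List::create(
    _["score"] = best,
    _["q_start"] = q_start, _["q_end"] = bi,
    _["s_start"] = s_start, _["s_end"] = bj,
    _["n_match"] = nmatch, _["n_mismatch"] = nmis,
    _["n_ins"] = nins, _["n_del"] = ndel,
    _["cigar"] = cigar);
}

static inline int base_index(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Pileup of alignment records on one reference.
// depth[p] counts '=' and 'X' columns covering p (deletion columns do not
// cover, insertions add no reference columns). counts is L x 6
// (A, C, G, T, ins, del); insertions are attributed to the reference
// position left of the insertion point.

// [[Rcpp::export]]
List cpp_pileup(int ref_len, IntegerVector ref_start, IntegerVector read_start,
                CharacterVector cigar, CharacterVector seq) {
  const int nrec = ref_start.size();
  if (read_start.size() != nrec || cigar.size() != nrec || seq.size() != nrec)
    stop("pileup inputs must have equal length");
  IntegerVector depth(ref_len);
  IntegerMatrix counts(ref_len, 6);

  for (int r = 0; r < nrec; ++r) {
    std::string cg = as<std::string>(cigar[r]);
    std::string sq = as<std::string>(seq[r]);
    int rp = ref_start[r];
    int qp = read_start[r];
    if (rp < 0) stop("negative ref_start in record %d", r + 1);
    size_t k = 0;
    while (k < cg.size()) {
      size_t num = 0;
      while (k < cg.size() && isdigit(cg[k])) { num = num * 10 + (cg[k] - '0'); ++k; }
      if (k >= cg.size() || num == 0) stop("malformed cigar '%s'", cg.c_str());
      char op = cg[k++];
      if (op == '=' || op == 'X' || op == 'M') {
        if (rp + (int) num > ref_len) stop("alignment exceeds reference bounds");
        if (qp + (int) num > (int) sq.size()) stop("alignment exceeds read bounds");
        for (size_t t = 0; t < num; ++t) {
          depth[rp]++;
          int b = base_index(sq[(size_t) qp]);
          if (b >= 0) counts(rp, b)++;
          ++rp; ++qp;
        }
      } else if (op == 'D') {
        if (rp + (int) num > ref_len) stop("alignment exceeds reference bounds");
        for (size_t t = 0; t < num; ++t) { counts(rp, 5)++; ++rp; }
      } else if (op == 'I') {
        int at = rp - 1;
        if (at >= 0 && at < ref_len) counts(at, 4)++;
        qp += (int) num;
      } else if (op == 'S') {
        qp += (int) num;
      } else {
        stop("unsupported cigar op '%c'", op);
      }
    }
  }
  return List::create(_["depth"] = depth, _["counts"] = counts);
}
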