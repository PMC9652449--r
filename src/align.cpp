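// Semiglobal (fitting) alignment of a read against a reference amplicon with
// affine gaps (Gotoh). The read is consumed end to end; unaligned reference
// prefix/suffix is free. A gap of length L costs gap_open + L * gap_extend.
// Tie-breaking in the traceback prefers aligned columns over gaps; indel
// placement is then canonicalised by left-alignment, so equal-scoring indel
// placements always come out at the lowest reference coordinate.

#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// op codes shared with the R side
enum { OP_MATCH = 1, OP_MISMATCH = 2, OP_INS = 3, OP_DEL = 4 };

static inline bool base_match(char a, char b) {
  return a == b && a != 'N';
}

struct Aln {
  int score;
  int ref_start;               // 0-based first reference index consumed
  std::vector<int> ops;        // per-column op codes
};

static Aln align_core(const std::string& read, const std::string& ref,
                      int ma, int mm, int go, int ge) {
  const int n = (int) read.size(), m = (int) ref.size();
  const int W = m + 1;
  std::vector<int> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
                   Y((n + 1) * W, NEG);
  // row 0: free leading reference gap -> alignment may start at any column
  for (int j = 0; j <= m; ++j) M[j] = 0;

  for (int i = 1; i <= n; ++i) {
    const char rc = read[i - 1];
    // j == 0: read overhang before the reference
    {
      int openv = std::max(M[(i - 1) * W], Y[(i - 1) * W]);
      int ext = X[(i - 1) * W];
      X[i * W] = std::max(openv == NEG ? NEG : openv + go + ge,
                          ext == NEG ? NEG : ext + ge);
    }
    for (int j = 1; j <= m; ++j) {
      const int dg = (i - 1) * W + (j - 1), up = (i - 1) * W + j,
                lf = i * W + (j - 1), cur = i * W + j;
      int s = base_match(rc, ref[j - 1]) ? ma : mm;
      int prev = std::max(M[dg], std::max(X[dg], Y[dg]));
      M[cur] = prev == NEG ? NEG : prev + s;
      int xo = std::max(M[up], Y[up]);
      X[cur] = std::max(xo == NEG ? NEG : xo + go + ge,
                        X[up] == NEG ? NEG : X[up] + ge);
      int yo = std::max(M[lf], X[lf]);
      Y[cur] = std::max(yo == NEG ? NEG : yo + go + ge,
                        Y[lf] == NEG ? NEG : Y[lf] + ge);
    }
  }

  // end: free trailing reference gap; never end in a deletion
  int best = NEG, bj = 0, bstate = 0; // state 0 = M, 1 = X
  for (int j = 0; j <= m; ++j) {
    int cur = n * W + j;
    if (M[cur] > best) { best = M[cur]; bj = j; bstate = 0; }
    if (X[cur] > best) { best = X[cur]; bj = j; bstate = 1; }
  }

  Aln out; out.score = best;
  std::vector<int>& ops = out.ops;
  int i = n, j = bj, state = bstate;
  while (i > 0) {
    if (state == 0) { // M
      int cur = i * W + j;
      int s = base_match(read[i - 1], ref[j - 1]) ? ma : mm;
      ops.push_back(base_match(read[i - 1], ref[j - 1]) ? OP_MATCH
                                                        : OP_MISMATCH);
      int target = M[cur] - s;
      int dg = (i - 1) * W + (j - 1);
      if (M[dg] == target) state = 0;
      else if (Y[dg] == target) state = 2;
      else state = 1;
      --i; --j;
    } else if (state == 1) { // X: insertion, consumes read
      int cur = i * W + j, up = (i - 1) * W + j;
      ops.push_back(OP_INS);
      int target = X[cur];
      if (M[up] != NEG && M[up] + go + ge == target) state = 0;
      else if (X[up] != NEG && X[up] + ge == target) state = 1;
      else state = 2;
      --i;
    } else { // Y: deletion, consumes reference
      int cur = i * W + j, lf = i * W + (j - 1);
      ops.push_back(OP_DEL);
      int target = Y[cur];
      if (M[lf] != NEG && M[lf] + go + ge == target) state = 0;
      else if (Y[lf] != NEG && Y[lf] + ge == target) state = 2;
      else state = 1;
      --j;
    }
  }
  out.ref_start = j;
  std::reverse(ops.begin(), ops.end());
  return out;
}

// Shift every insertion/deletion run to its minimal reference coordinate
// among sequence-equivalent placements. Swapping an indel run with the
// aligned column on its left preserves the read, the consumed reference
// span and the score whenever the flanking base condition holds.
static void left_align_ops(std::vector<int>& ops, int ref_start,
                           const std::string& read, const std::string& ref) {
  bool moved = true;
  while (moved) {
    moved = false;
    int ri = 0, rj = ref_start;
    size_t k = 0;
    while (k < ops.size()) {
      int op = ops[k];
      if (op == OP_MATCH || op == OP_MISMATCH) { ++ri; ++rj; ++k; continue; }
      size_t c0 = k;
      while (k < ops.size() && ops[k] == op) ++k;
      size_t c1 = k;
      int L = (int) (c1 - c0);
      bool shifted = false;
      if (op == OP_DEL) {
        int rs = rj; // first deleted reference index
        while (c0 > 0 && (ops[c0 - 1] == OP_MATCH || ops[c0 - 1] == OP_MISMATCH)
               && rs > 0 && ref[rs - 1] == ref[rs + L - 1]) {
          std::swap(ops[c0 - 1], ops[c1 - 1]);
          --c0; --c1; --rs; shifted = true;
        }
      } else { // OP_INS
        int as = ri; // first inserted read index
        while (c0 > 0 && (ops[c0 - 1] == OP_MATCH || ops[c0 - 1] == OP_MISMATCH)
               && as > 0 && read[as - 1] == read[as + L - 1]) {
          std::swap(ops[c0 - 1], ops[c1 - 1]);
          --c0; --c1; --as; shifted = true;
        }
      }
      if (shifted) { moved = true; break; } // rescan with fresh coordinates
      if (op == OP_DEL) rj += L; else ri += L;
    }
  }
}

static std::string revcomp_cpp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (char& c : out) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return out;
}

static bool valid_seq(const std::string& s) {
  for (char c : s)
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'N') return false;
  return !s.empty();
}

// [[Rcpp::export(name = ".cq_align_one")]]
List cq_align_one(std::string read, std::string ref, int match, int mismatch,
                  int gap_open, int gap_extend, bool left_align = true) {
  if (!valid_seq(read) || !valid_seq(ref))
    stop("sequences must be non-empty and contain only ACGTN");
  Aln a = align_core(read, ref, match, mismatch, gap_open, gap_extend);
  if (left_align) left_align_ops(a.ops, a.ref_start, read, ref);
  return List::create(_["score"] = a.score, _["ref_start"] = a.ref_start,
                      _["ops"] = IntegerVector(a.ops.begin(), a.ops.end()));
}

// [[Rcpp::export(name = ".cq_left_align")]]
IntegerVector cq_left_align(IntegerVector ops, int ref_start,
                            std::string read, std::string ref) {
  std::vector<int> v(ops.begin(), ops.end());
  left_align_ops(v, ref_start, read, ref);
  return IntegerVector(v.begin(), v.end());
}

static int prefix_hamming(const std::string& read, const std::string& ref,
                          int k) {
  int n = std::min((int) read.size(), std::min((int) ref.size(), k));
  int h = 0;
  for (int i = 0; i < n; ++i) if (read[i] != ref[i]) ++h;
  return h + (k - n);
}

// Batch alignment against one reference. Orientation is decided by alignment
// score of the two orientations; a prefix-identity screen skips the second
// DP when the orientation is unambiguous. Returns flat per-read vectors plus
// a flat table of indel segments across all reads.
// [[Rcpp::export(name = ".cq_align_batch")]]
List cq_align_batch(CharacterVector reads, std::string ref, int match,
                    int mismatch, int gap_open, int gap_extend,
                    int prefix_len, IntegerVector proto_idx) {
  const int n = reads.size();
  IntegerVector score(n), ref_start(n), prefix_matches(n), n_mismatch(n);
  LogicalVector valid(n), is_rev(n), has_indel(n);
  CharacterVector oriented(n), proto(n);
  std::vector<int> seg_read, seg_op, seg_ref, seg_len, seg_readpos;
  std::vector<std::string> seg_seq;

  const int np = proto_idx.size();
  std::string protobuf(np, '.');

  for (int r = 0; r < n; ++r) {
    std::string rd = as<std::string>(reads[r]);
    for (char& c : rd) c = (char) toupper((unsigned char) c);
    if (!valid_seq(rd)) {
      valid[r] = false; score[r] = NA_INTEGER; ref_start[r] = NA_INTEGER;
      prefix_matches[r] = NA_INTEGER; n_mismatch[r] = NA_INTEGER;
      oriented[r] = NA_STRING;
      proto[r] = NA_STRING; is_rev[r] = false; has_indel[r] = false;
      continue;
    }
    valid[r] = true;
    std::string rc = revcomp_cpp(rd);
    int hf = prefix_hamming(rd, ref, 24), hr = prefix_hamming(rc, ref, 24);
    Aln a; bool rev;
    if (hf + 6 <= hr) {
      a = align_core(rd, ref, match, mismatch, gap_open, gap_extend);
      rev = false;
    } else if (hr + 6 <= hf) {
      a = align_core(rc, ref, match, mismatch, gap_open, gap_extend);
      rev = true;
    } else {
      Aln af = align_core(rd, ref, match, mismatch, gap_open, gap_extend);
      Aln ar = align_core(rc, ref, match, mismatch, gap_open, gap_extend);
      if (ar.score > af.score) { a = ar; rev = true; }
      else { a = af; rev = false; }
    }
    const std::string& rs = rev ? rc : rd;
    left_align_ops(a.ops, a.ref_start, rs, ref);
    score[r] = a.score; ref_start[r] = a.ref_start;
    is_rev[r] = rev; oriented[r] = rs;

    // walk columns once: prefix matches, protospacer bases, indel segments
    std::fill(protobuf.begin(), protobuf.end(), '.');
    int pm = 0, nmm = 0, ri = 0, rj = a.ref_start;
    bool anyindel = false;
    size_t k = 0;
    while (k < a.ops.size()) {
      int op = a.ops[k];
      if (op == OP_MATCH || op == OP_MISMATCH) {
        if (op == OP_MATCH && rj < prefix_len) ++pm;
        if (op == OP_MISMATCH) ++nmm;
        for (int p = 0; p < np; ++p)
          if (proto_idx[p] == rj) protobuf[p] = rs[ri];
        ++ri; ++rj; ++k;
      } else {
        size_t c0 = k;
        while (k < a.ops.size() && a.ops[k] == op) ++k;
        int L = (int) (k - c0);
        anyindel = true;
        seg_read.push_back(r + 1);
        seg_op.push_back(op);
        seg_len.push_back(L);
        if (op == OP_INS) {
          seg_ref.push_back(rj);          // inter-base insertion point
          seg_readpos.push_back(ri);
          seg_seq.push_back(rs.substr(ri, L));
          ri += L;
        } else {
          seg_ref.push_back(rj);          // first deleted base
          seg_readpos.push_back(ri);
          seg_seq.push_back("");
          for (int d = 0; d < L; ++d, ++rj)
            for (int p = 0; p < np; ++p)
              if (proto_idx[p] == rj) protobuf[p] = '-';
        }
      }
    }
    prefix_matches[r] = pm;
    n_mismatch[r] = nmm;
    has_indel[r] = anyindel;
    proto[r] = np ? protobuf : std::string("");
  }

  return List::create(
    _["valid"] = valid, _["score"] = score, _["ref_start"] = ref_start,
    _["is_rev"] = is_rev, _["prefix_matches"] = prefix_matches,
    _["n_mismatch"] = n_mismatch,
    _["has_indel"] = has_indel, _["oriented"] = oriented, _["proto"] = proto,
    _["seg_read"] = IntegerVector(seg_read.begin(), seg_read.end()),
    _["seg_op"] = IntegerVector(seg_op.begin(), seg_op.end()),
    _["seg_ref_start"] = IntegerVector(seg_ref.begin(), seg_ref.end()),
    _["seg_read_start"] = IntegerVector(seg_readpos.begin(), seg_readpos.end()),
    _["seg_len"] = IntegerVector(seg_len.begin(), seg_len.end()),
    _["seg_seq"] = CharacterVector(seg_seq.begin(), seg_seq.end()));
}
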