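#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Six-base block matchers for the four telomeric repeat dialects of a
// directional WGBS library.  Read 1 reports the bisulfite-converted original
// strand: a C-strand repeat CCCTAA appears as [CT][CT][CT]TAA (each cytosine
// independently converted to T or left as C), while a G-strand repeat has no
// cytosines and appears verbatim as TTAGGG.  Read 2 is the complement, so the
// patterns are reverse-complemented: TTA[AG][AG][AG] and CCCTAA.

static inline bool is_ct(char c) { return c == 'C' || c == 'T'; }
static inline bool is_ag(char c) { return c == 'A' || c == 'G'; }

static inline bool block_c1(const char* s) {
  return is_ct(s[0]) && is_ct(s[1]) && is_ct(s[2]) &&
         s[3] == 'T' && s[4] == 'A' && s[5] == 'A';
}
static inline bool block_g1(const char* s) {
  return s[0] == 'T' && s[1] == 'T' && s[2] == 'A' &&
         s[3] == 'G' && s[4] == 'G' && s[5] == 'G';
}
static inline bool block_c2(const char* s) {
  return s[0] == 'T' && s[1] == 'T' && s[2] == 'A' &&
         is_ag(s[3]) && is_ag(s[4]) && is_ag(s[5]);
}
static inline bool block_g2(const char* s) {
  return s[0] == 'C' && s[1] == 'C' && s[2] == 'C' &&
         s[3] == 'T' && s[4] == 'A' && s[5] == 'A';
}

// Site code of a C-strand block: bit 0 = site1, bit 1 = site2, bit 2 = site3
// unconverted.  Sites are indexed 5'->3' on the C strand (CCCTAA); on read 2
// the block is reverse-complemented so its positions 4..6 carry 'G' for an
// unconverted site3, site2, site1 respectively.
static inline int site_code_c1(const char* s) {
  return (s[0] == 'C' ? 1 : 0) | (s[1] == 'C' ? 2 : 0) | (s[2] == 'C' ? 4 : 0);
}
static inline int site_code_c2(const char* s) {
  return (s[5] == 'G' ? 1 : 0) | (s[4] == 'G' ? 2 : 0) | (s[3] == 'G' ? 4 : 0);
}

// Longest run of consecutive, non-overlapping matching blocks at any phase
// offset, via the backwards recurrence run[i] = match(i) ? 1 + run[i+6] : 0.
// Exact: a greedy left-to-right regex can consume a short run whose tail
// overlaps a longer run in a different phase.  Ties go to the leftmost start.
static void longest_run(const char* s, int L, bool (*match)(const char*),
                        int& best_start, int& best_len) {
  best_start = -1;
  best_len = 0;
  int n = L - 5;
  if (n <= 0) return;
  std::vector<int> run(n, 0);
  for (int i = n - 1; i >= 0; --i) {
    if (match(s + i)) run[i] = 1 + (i + 6 < n ? run[i + 6] : 0);
  }
  for (int i = 0; i < n; ++i) {
    if (run[i] > best_len) { best_len = run[i]; best_start = i; }
  }
}

// [[Rcpp::export]]
List scan_reads_cpp(CharacterVector seqs, int dialect, int min_blocks,
                    bool keep_blocks) {
  if (dialect != 1 && dialect != 2) stop("dialect must be 1 or 2");
  if (min_blocks < 1) stop("min_blocks must be >= 1");
  const int n = seqs.size();

  bool (*cmatch)(const char*) = dialect == 1 ? block_c1 : block_c2;
  bool (*gmatch)(const char*) = dialect == 1 ? block_g1 : block_g2;
  int (*scode)(const char*) = dialect == 1 ? site_code_c1 : site_code_c2;

  IntegerVector strand(n), start(n), nblocks(n);
  IntegerVector n0(n), n1(n), n2(n), n3(n), s1(n), s2(n), s3(n);
  List blocks = keep_blocks ? List(n) : List(0);

  for (int r = 0; r < n; ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    int L = LENGTH(STRING_ELT(seqs, r));

    int cs, cl, gs, gl;
    longest_run(s, L, cmatch, cs, cl);
    longest_run(s, L, gmatch, gs, gl);

    // longer run decides strand origin; ties prefer the C strand so that
    // conversion information is never discarded
    int st = 0, bs = -1, bl = 0;
    if (cl >= gl && cl >= min_blocks) {
      st = 1; bs = cs; bl = cl;
    } else if (gl > cl && gl >= min_blocks) {
      st = 2; bs = gs; bl = gl;
    }

    strand[r] = st;
    start[r] = st ? bs : NA_INTEGER;
    nblocks[r] = bl;
    if (st == 1) {
      IntegerVector codes(keep_blocks ? bl : 0);
      int c0 = 0, c1 = 0, c2 = 0, c3 = 0, u1 = 0, u2 = 0, u3 = 0;
      for (int b = 0; b < bl; ++b) {
        int code = scode(s + bs + 6 * b);
        if (keep_blocks) codes[b] = code;
        int k = (code & 1) + ((code >> 1) & 1) + ((code >> 2) & 1);
        if (k == 0) ++c0; else if (k == 1) ++c1; else if (k == 2) ++c2; else ++c3;
        u1 += code & 1; u2 += (code >> 1) & 1; u3 += (code >> 2) & 1;
      }
      n0[r] = c0; n1[r] = c1; n2[r] = c2; n3[r] = c3;
      s1[r] = u1; s2[r] = u2; s3[r] = u3;
      if (keep_blocks) blocks[r] = codes;
    } else if (keep_blocks) {
      blocks[r] = IntegerVector(0);
    }
  }

  List out = List::create(
      _["strand"] = strand, _["start"] = start, _["nblocks"] = nblocks,
      _["n0"] = n0, _["n1"] = n1, _["n2"] = n2, _["n3"] = n3,
      _["s1"] = s1, _["s2"] = s2, _["s3"] = s3);
  if (keep_blocks) out["blocks"] = blocks;
  return out;
}
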