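#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman) of a read against the
// reference region, with deterministic tie-breaking: among equal-scoring
// optimal alignments the traceback minimizes the number of gap openings,
// then prefers gap extension / diagonal moves so that residual placement
// ambiguity is pushed leftward (and canonicalized downstream by VCF
// left-normalization).
//
// States: M = read base aligned to region base;
//         I = insertion (read base against a gap in the region);
//         D = deletion (region base against a gap in the read).
// A gap of length L costs gap_open + L * gap_extend.

static const int NEG = INT_MIN / 4;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp_one(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t k = 0; k < s.size(); ++k)
    out[k] = comp_base(s[s.size() - 1 - k]);
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp_one(as<std::string>(x[i]));
  }
  return out;
}

struct Cand { int score; int opens; int ptr; };

// pick the best candidate: max score, then min gap openings, then the
// order in which candidates were supplied (caller lists preferred first)
static inline void consider(Cand& best, int score, int opens, int ptr) {
  if (score > best.score ||
      (score == best.score && opens < best.opens)) {
    best.score = score; best.opens = opens; best.ptr = ptr;
  }
}

// [[Rcpp::export]]
List cpp_sw_align(std::string read, std::string region,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int) read.size();
  const int m = (int) region.size();
  const int W = m + 1;

  // per-state score, gap-open count, traceback pointer
  std::vector<int> Ms((size_t)(n + 1) * W, 0),  Mo((size_t)(n + 1) * W, 0);
  std::vector<int> Is((size_t)(n + 1) * W, NEG), Io((size_t)(n + 1) * W, 0);
  std::vector<int> Ds((size_t)(n + 1) * W, NEG), Do((size_t)(n + 1) * W, 0);
  std::vector<unsigned char> Mp((size_t)(n + 1) * W, 0),
      Ip((size_t)(n + 1) * W, 0), Dp((size_t)(n + 1) * W, 0);

  int best = 0, best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    const char rc = read[i - 1];
    const size_t row = (size_t) i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const char gc = region[j - 1];
      const int sub = (rc == gc && rc != 'N' && rc != 'n') ? match : mismatch;

      // M: diagonal from M, D, I, or a fresh local start (score 0)
      {
        Cand c = {0, 0, 0};  // ptr 0 = start
        const size_t d = prow + (j - 1);
        consider(c, Ms[d] + sub, Mo[d], 1);
        if (Ds[d] > NEG / 2) consider(c, Ds[d] + sub, Do[d], 3);
        if (Is[d] > NEG / 2) consider(c, Is[d] + sub, Io[d], 2);
        if (c.score <= 0) { c.score = 0; c.opens = 0; c.ptr = 0; }
        Ms[row + j] = c.score; Mo[row + j] = c.opens; Mp[row + j] = (unsigned char) c.ptr;
        if (c.score > best ||
            (c.score == best && (j < best_j || (j == best_j && i < best_i)))) {
          if (c.score > 0) { best = c.score; best_i = i; best_j = j; }
        }
      }

      // I: consume read[i] against a gap; extend preferred on ties
      {
        Cand c = {NEG, 0, 0};
        const size_t u = prow + j;
        if (Is[u] > NEG / 2) consider(c, Is[u] - gap_extend, Io[u], 2);
        consider(c, Ms[u] - gap_open - gap_extend, Mo[u] + 1, 1);
        if (Ds[u] > NEG / 2) consider(c, Ds[u] - gap_open - gap_extend, Do[u] + 1, 3);
        Is[row + j] = c.score; Io[row + j] = c.opens; Ip[row + j] = (unsigned char) c.ptr;
      }

      // D: consume region[j] against a gap
      {
        Cand c = {NEG, 0, 0};
        const size_t l = row + (j - 1);
        if (Ds[l] > NEG / 2) consider(c, Ds[l] - gap_extend, Do[l], 3);
        consider(c, Ms[l] - gap_open - gap_extend, Mo[l] + 1, 1);
        if (Is[l] > NEG / 2) consider(c, Is[l] - gap_open - gap_extend, Io[l] + 1, 2);
        Ds[row + j] = c.score; Do[row + j] = c.opens; Dp[row + j] = (unsigned char) c.ptr;
      }
    }
  }

  if (best <= 0) {
    IntegerMatrix empty_ops(0, 4);
    colnames(empty_ops) = CharacterVector::create("kind", "length",
                                                  "read_off", "region_off");
    return List::create(_["score"] = 0,
                        _["ops"] = empty_ops,
                        _["read_span"] = IntegerVector::create(0, 0),
                        _["region_span"] = IntegerVector::create(0, 0),
                        _["n_match"] = 0, _["n_mismatch"] = 0,
                        _["n_gap_opens"] = 0);
  }

  // traceback from the best-scoring M cell
  std::vector<int> kinds, lens, roffs, goffs;  // reversed during collection
  int i = best_i, j = best_j, state = 0;       // 0=M,1=I,2=D
  int n_match = 0, n_mismatch = 0, n_opens = 0;
  int end_i = best_i, end_j = best_j;

  auto push_col = [&](int kind, int roff, int goff) {
    if (!kinds.empty() && kinds.back() == kind) {
      lens.back() += 1; roffs.back() = roff; goffs.back() = goff;
    } else {
      kinds.push_back(kind); lens.push_back(1);
      roffs.push_back(roff); goffs.push_back(goff);
    }
  };

  while (true) {
    // boundary rows/columns are implicit local starts (score 0)
    if (state == 0 && (i == 0 || j == 0)) break;
    if (state == 1 && i == 0) break;
    if (state == 2 && j == 0) break;
    const size_t idx = (size_t) i * W + j;
    // a zero-scoring M cell is where the local alignment (re)starts
    if (state == 0 && Ms[idx] <= 0) break;
    if (state == 0) {
      const int ptr = Mp[idx];
      const bool is_match = (read[i - 1] == region[j - 1] &&
                             read[i - 1] != 'N' && read[i - 1] != 'n');
      push_col(is_match ? 1 : 2, i, j);
      if (is_match) ++n_match; else ++n_mismatch;
      --i; --j;
      if (ptr == 0) break;            // local start reached
      state = (ptr == 1) ? 0 : (ptr == 2 ? 1 : 2);
    } else if (state == 1) {          // insertion: consumes read
      const int ptr = Ip[idx];
      push_col(3, i, j);              // goff = last consumed region base
      --i;
      if (ptr != 2) ++n_opens;
      state = (ptr == 1) ? 0 : (ptr == 2 ? 1 : 2);
    } else {                          // deletion: consumes region
      const int ptr = Dp[idx];
      push_col(4, i, j);              // roff = last consumed read base
      --j;
      if (ptr != 3) ++n_opens;
      state = (ptr == 1) ? 0 : (ptr == 2 ? 1 : 2);
    }
  }
  const int start_i = i + 1, start_j = j + 1;  // first consumed positions

  const int K = (int) kinds.size();
  IntegerMatrix ops(K, 4);
  for (int k = 0; k < K; ++k) {
    const int src = K - 1 - k;       // reverse into left-to-right order
    ops(k, 0) = kinds[src];
    ops(k, 1) = lens[src];
    int roff = roffs[src], goff = goffs[src];
    if (kinds[src] == 3) {           // insertion: roff = first inserted base,
      ops(k, 2) = roff;              // goff = region base left of insertion
      ops(k, 3) = goff;
    } else if (kinds[src] == 4) {    // deletion: goff = first deleted base,
      ops(k, 2) = roff;              // roff = read base left of deletion
      ops(k, 3) = goff;
    } else {
      ops(k, 2) = roff;              // first read base of the run
      ops(k, 3) = goff;              // first region base of the run
    }
  }
  colnames(ops) = CharacterVector::create("kind", "length", "read_off", "region_off");

  return List::create(_["score"] = best,
                      _["ops"] = ops,
                      _["read_span"] = IntegerVector::create(start_i, end_i),
                      _["region_span"] = IntegerVector::create(start_j, end_j),
                      _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
                      _["n_gap_opens"] = n_opens);
}

// Overlap-join paired-end mates: mate 2 is reverse-complemented, all
// overlap lengths >= min_overlap are scanned, and the overlap with the
// lowest mismatch fraction (ties -> longest) is accepted when its mismatch
// fraction is <= max_mismatch_frac. Overlap mismatches take the
// higher-quality base (mate 1 on ties or when qualities are absent).
// [[Rcpp::export]]
List cpp_join_pairs(CharacterVector s1, CharacterVector q1,
                    CharacterVector s2, CharacterVector q2,
                    int min_overlap, double max_mismatch_frac) {
  const R_xlen_t np = s1.size();
  CharacterVector seq(np), qual(np);
  LogicalVector joined(np);

  for (R_xlen_t p = 0; p < np; ++p) {
    const std::string a  = as<std::string>(s1[p]);
    const std::string b  = revcomp_one(as<std::string>(s2[p]));
    std::string qa = CharacterVector::is_na(q1[p]) ? std::string() : as<std::string>(q1[p]);
    std::string qb = CharacterVector::is_na(q2[p]) ? std::string() : as<std::string>(q2[p]);
    std::reverse(qb.begin(), qb.end());
    const int l1 = (int) a.size(), l2 = (int) b.size();
    const int omax = std::min(l1, l2);

    double best_frac = 2.0; int best_o = -1;
    for (int o = min_overlap; o <= omax; ++o) {
      int mm = 0;
      const int lim = (int) std::floor(max_mismatch_frac * o + 1e-9);
      for (int k = 0; k < o; ++k) {
        if (a[l1 - o + k] != b[k] && ++mm > lim) break;
      }
      if (mm > lim) continue;
      const double frac = (double) mm / o;
      if (frac < best_frac - 1e-12 ||
          (std::abs(frac - best_frac) <= 1e-12 && o > best_o)) {
        best_frac = frac; best_o = o;
      }
    }

    if (best_o < 0) {
      seq[p] = NA_STRING; qual[p] = NA_STRING; joined[p] = false;
      continue;
    }
    const int o = best_o;
    std::string ms = a.substr(0, l1 - o);
    std::string mq = qa.empty() ? std::string(l1 - o, 'I') : qa.substr(0, l1 - o);
    for (int k = 0; k < o; ++k) {
      const char ca = a[l1 - o + k], cb = b[k];
      const char fa = qa.empty() ? 'I' : qa[l1 - o + k];
      const char fb = qb.empty() ? 'I' : qb[k];
      if (ca == cb) { ms.push_back(ca); }
      else if (!qa.empty() && !qb.empty() && fb > fa) { ms.push_back(cb); }
      else { ms.push_back(ca); }
      mq.push_back(std::max(fa, fb));
    }
    ms += b.substr(o);
    mq += qb.empty() ? std::string(l2 - o, 'I') : qb.substr(o);
    seq[p] = ms; qual[p] = mq; joined[p] = true;
  }
  return List::create(_["sequence"] = seq, _["quality"] = qual,
                      _["joined"] = joined);
}
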