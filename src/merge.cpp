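#include <Rcpp.h>
using namespace Rcpp;

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'N': return 'N'; default: return 'N';
  }
}

// Merge one read pair: scan overlap lengths between r1's 3' end and
// revcomp(r2)'s 5' end, keep the overlap minimising the mismatch fraction
// (ties -> longer overlap), consensus by higher base quality (ties -> r1).
// [[Rcpp::export(name = ".mergePairsCpp")]]
List mergePairsCpp(CharacterVector r1, CharacterVector q1,
                   CharacterVector r2, CharacterVector q2,
                   int minOverlap, double maxMismatchFrac) {
  int n = r1.size();
  CharacterVector seqOut(n), qualOut(n);
  IntegerVector overlapLen(n), mismatches(n);
  LogicalVector merged(n);

  for (int i = 0; i < n; ++i) {
    std::string a(r1[i]), qa(q1[i]);
    std::string b(r2[i]), qb(q2[i]);
    // reverse-complement read 2 (and reverse its qualities)
    std::string brc(b.rbegin(), b.rend());
    for (size_t k = 0; k < brc.size(); ++k) brc[k] = complement(brc[k]);
    std::string qbr(qb.rbegin(), qb.rend());

    int na = (int)a.size(), nb = (int)brc.size();
    int maxOv = std::min(na, nb);
    int bestOv = -1, bestMm = 0;
    double bestFrac = 1.0;
    for (int ov = minOverlap; ov <= maxOv; ++ov) {
      int mm = 0;
      const char* pa = a.data() + (na - ov);
      const char* pb = brc.data();
      for (int k = 0; k < ov; ++k) if (pa[k] != pb[k]) ++mm;
      double frac = (double)mm / ov;
      if (frac <= maxMismatchFrac &&
          (frac < bestFrac || (frac == bestFrac && ov > bestOv))) {
        bestFrac = frac; bestOv = ov; bestMm = mm;
      }
    }
    if (bestOv < 0) {
      merged[i] = false;
      seqOut[i] = NA_STRING; qualOut[i] = NA_STRING;
      overlapLen[i] = 0; mismatches[i] = NA_INTEGER;
      continue;
    }
    std::string cons = a.substr(0, na - bestOv);
    std::string consQ = qa.substr(0, na - bestOv);
    for (int k = 0; k < bestOv; ++k) {
      char ca = a[na - bestOv + k], cb = brc[k];
      char qca = qa[na - bestOv + k], qcb = qbr[k];
      if (ca == cb) {
        cons += ca; consQ += std::max(qca, qcb);
      } else if (qcb > qca) {
        cons += cb; consQ += qcb;
      } else {
        cons += ca; consQ += qca;
      }
    }
    cons += brc.substr(bestOv);
    consQ += qbr.substr(bestOv);
    merged[i] = true;
    seqOut[i] = cons; qualOut[i] = consQ;
    overlapLen[i] = bestOv; mismatches[i] = bestMm;
  }
  return List::create(_["merged"] = merged, _["sequence"] = seqOut,
                      _["quality"] = qualOut, _["overlap_len"] = overlapLen,
                      _["mismatches"] = mismatches);
}

// Run-length encode gapped alignment strings into CIGARs: '-' in the pattern
// (read) is a deletion from the reference, '-' in the subject (reference) is
// an insertion, anything else an alignment match (M covers mismatches).
// [[Rcpp::export(name = ".cigarFromGappedCpp")]]
CharacterVector cigarFromGappedCpp(CharacterVector pattern,
                                   CharacterVector subject) {
  int n = pattern.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string p(pattern[i]), s(subject[i]);
    if (p.size() != s.size())
      stop("gapped pattern/subject length mismatch at record %d", i + 1);
    std::string cigar;
    char cur = 0;
    int run = 0;
    for (size_t k = 0; k < p.size(); ++k) {
      char op;
      if (p[k] == '-' && s[k] == '-')
        stop("double gap column at record %d", i + 1);
      else if (p[k] == '-') op = 'D';
      else if (s[k] == '-') op = 'I';
      else op = 'M';
      if (op == cur) { ++run; }
      else {
        if (run > 0) { cigar += std::to_string(run); cigar += cur; }
        cur = op; run = 1;
      }
    }
    if (run > 0) { cigar += std::to_string(run); cigar += cur; }
    out[i] = cigar;
  }
  return out;
}
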