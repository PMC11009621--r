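#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <set>
#include <algorithm>
using namespace Rcpp;

// 2-bit base codes; -1 for anything outside ACGT (N never seeds, always
// counts as a mismatch during extension).
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: break;
    }
  }
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > KmerIndex;

// Index every k-mer of every reference (k <= 31).
static KmerIndex build_index(const std::vector<std::string>& refs, int k) {
  KmerIndex idx;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < (int)refs.size(); ++r) {
    const std::string& s = refs[r];
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) idx[h].emplace_back(r, i - k + 1);
    }
  }
  return idx;
}

// Semi-global ungapped placement of each read over all references and both
// strands: exact k-mer seeding, full-containment mismatch count, score
// len - 2*mismatches. Ties across >=2 references are emitted once per tied
// reference with ambiguous = TRUE.
// [[Rcpp::export(name = ".cpp_align_reads")]]
DataFrame cpp_align_reads(CharacterVector reads, CharacterVector ref_names,
                          CharacterVector ref_seqs, int k, double min_identity) {
  int nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(ref_seqs[i]);
  KmerIndex idx = build_index(refs, k);
  const uint64_t mask = (1ULL << (2 * k)) - 1;

  std::vector<int> out_read, out_ref, out_start, out_mm, out_len;
  std::vector<int> out_strand;          // 0 = '+', 1 = '-'
  std::vector<bool> out_amb;
  std::vector<std::string> out_seq;

  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int L = fwd.size();
    if (L < k) continue;
    std::string rc = revcomp(fwd);
    int best_mm = L + 1;
    // placement = (ref, strand, offset)
    std::set<std::tuple<int,int,int> > seen;
    std::vector<std::tuple<int,int,int> > best;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = strand == 0 ? fwd : rc;
      uint64_t h = 0; int run = 0;
      for (int i = 0; i < L; ++i) {
        int c = base_code(rd[i]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++run < k) continue;
        auto it = idx.find(h);
        if (it == idx.end()) continue;
        int rpos = i - k + 1;
        for (auto& hit : it->second) {
          int ref = hit.first;
          int off = hit.second - rpos;
          if (off < 0 || off + L > (int)refs[ref].size()) continue;
          auto key = std::make_tuple(ref, strand, off);
          if (!seen.insert(key).second) continue;
          const std::string& rs = refs[ref];
          int mm = 0;
          for (int p = 0; p < L && mm <= best_mm; ++p)
            if (rd[p] != rs[off + p]) ++mm;
          if (mm < best_mm) { best_mm = mm; best.clear(); }
          if (mm == best_mm) best.push_back(key);
        }
      }
    }
    if (best.empty()) continue;
    double ident = 1.0 - (double)best_mm / L;
    if (ident < min_identity) continue;

    // one placement per tied reference: smallest (strand, offset)
    std::sort(best.begin(), best.end());
    std::vector<std::tuple<int,int,int> > per_ref;
    std::set<int> refs_hit;
    for (auto& b : best)
      if (refs_hit.insert(std::get<0>(b)).second) per_ref.push_back(b);
    bool amb = per_ref.size() >= 2;
    for (auto& b : per_ref) {
      out_read.push_back(ri + 1);
      out_ref.push_back(std::get<0>(b) + 1);
      out_strand.push_back(std::get<1>(b));
      out_start.push_back(std::get<2>(b));
      out_mm.push_back(best_mm);
      out_len.push_back(L);
      out_amb.push_back(amb);
      out_seq.push_back(std::get<1>(b) == 0 ? fwd : rc);
    }
  }

  int n = out_read.size();
  CharacterVector fam(n), strand(n), seq(n);
  for (int i = 0; i < n; ++i) {
    fam[i] = ref_names[out_ref[i] - 1];
    strand[i] = out_strand[i] == 0 ? "+" : "-";
    seq[i] = out_seq[i];
  }
  return DataFrame::create(
    _["read"] = wrap(out_read), _["family_id"] = fam,
    _["start"] = wrap(out_start), _["strand"] = strand,
    _["mismatches"] = wrap(out_mm), _["aligned_len"] = wrap(out_len),
    _["is_ambiguous"] = wrap(out_amb), _["seq"] = seq,
    _["stringsAsFactors"] = false);
}

// Accumulate one family's pileup: unambiguous reads add full coverage and
// base counts; ambiguous reads add fractional coverage only.
// [[Rcpp::export(name = ".cpp_pileup")]]
NumericMatrix cpp_pileup(int ref_len, IntegerVector starts, CharacterVector seqs,
                         LogicalVector ambiguous, NumericVector weights) {
  NumericMatrix m(ref_len, 6);   // covU covA A C G T
  for (int i = 0; i < starts.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int st = starts[i];
    for (int p = 0; p < (int)s.size(); ++p) {
      int pos = st + p;
      if (pos < 0 || pos >= ref_len) continue;
      if (ambiguous[i]) {
        m(pos, 1) += weights[i];
      } else {
        int c = base_code(s[p]);
        if (c >= 0) { m(pos, 0) += 1.0; m(pos, 2 + c) += 1.0; }
      }
    }
  }
  return m;
}

struct Hit {
  int cstart, cend, fstart, fend, score, mm;
};

// Gapless local alignment of one family consensus (already oriented) against
// a contig: exact k-mer seeds, x-drop extension, match +1 / mismatch -1.
static std::vector<Hit> scan_oriented(const std::string& contig,
                                      const std::string& fam,
                                      int k, int min_score, int xdrop) {
  std::vector<Hit> hits;
  // diagonal -> contig end already covered (skip redundant seeds)
  std::unordered_map<int,int> diag_cov;
  // index family k-mers
  std::unordered_map<uint64_t, std::vector<int> > fidx;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  {
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < (int)fam.size(); ++i) {
      int c = base_code(fam[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) fidx[h].push_back(i - k + 1);
    }
  }
  uint64_t h = 0; int run = 0;
  int CL = contig.size(), FL = fam.size();
  for (int i = 0; i < CL; ++i) {
    int c = base_code(contig[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run < k) continue;
    auto it = fidx.find(h);
    if (it == fidx.end()) continue;
    int cpos = i - k + 1;
    for (int fpos : it->second) {
      int d = cpos - fpos;
      auto dc = diag_cov.find(d);
      if (dc != diag_cov.end() && cpos < dc->second) continue;
      // extend right from seed end
      int score = k, best = k, mm = 0, best_mm = 0;
      int cr = cpos + k, fr = fpos + k, best_cr = cr;
      while (cr < CL && fr < FL) {
        if (contig[cr] == fam[fr] && base_code(contig[cr]) >= 0) ++score;
        else { --score; ++mm; }
        ++cr; ++fr;
        if (score > best) { best = score; best_cr = cr; best_mm = mm; }
        if (best - score > xdrop) break;
      }
      // extend left from seed start
      score = best; mm = best_mm;
      int cl = cpos, fl = fpos, best_cl = cl;
      int best2 = best, best2_mm = mm;
      while (cl > 0 && fl > 0) {
        --cl; --fl;
        if (contig[cl] == fam[fl] && base_code(contig[cl]) >= 0) ++score;
        else { --score; ++mm; }
        if (score > best2) { best2 = score; best_cl = cl; best2_mm = mm; }
        if (best2 - score > xdrop) break;
      }
      if (best2 >= min_score) {
        Hit ht;
        ht.cstart = best_cl; ht.cend = best_cr;
        ht.fstart = fpos - (cpos - best_cl); ht.fend = fpos + k + (best_cr - cpos - k);
        ht.score = best2; ht.mm = best2_mm;
        hits.push_back(ht);
        int& cov = diag_cov[d];
        cov = std::max(cov, best_cr);
      }
    }
  }
  return hits;
}

// [[Rcpp::export(name = ".cpp_find_hits")]]
DataFrame cpp_find_hits(std::string contig, CharacterVector fam_names,
                        CharacterVector fam_seqs, int k, int min_score,
                        int xdrop) {
  std::vector<int> o_start, o_end, o_qs, o_qe, o_score;
  std::vector<double> o_div;
  std::vector<std::string> o_fam, o_strand;
  for (int f = 0; f < fam_seqs.size(); ++f) {
    std::string fam = as<std::string>(fam_seqs[f]);
    std::string name = as<std::string>(fam_names[f]);
    int FL = fam.size();
    for (int strand = 0; strand < 2; ++strand) {
      std::string oriented = strand == 0 ? fam : revcomp(fam);
      std::vector<Hit> hits = scan_oriented(contig, oriented, k, min_score, xdrop);
      // greedy overlap filter: keep best-scoring, drop hits overlapping a
      // kept hit by >= 50% of their length
      std::sort(hits.begin(), hits.end(),
                [](const Hit& a, const Hit& b) { return a.score > b.score; });
      std::vector<Hit> kept;
      for (auto& ht : hits) {
        bool redundant = false;
        for (auto& kp : kept) {
          int ov = std::min(ht.cend, kp.cend) - std::max(ht.cstart, kp.cstart);
          if (ov > 0 && 2 * ov >= (ht.cend - ht.cstart)) { redundant = true; break; }
        }
        if (!redundant) kept.push_back(ht);
      }
      for (auto& ht : kept) {
        int qs = ht.fstart, qe = ht.fend;
        if (strand == 1) { qs = FL - ht.fend; qe = FL - ht.fstart; }
        int alen = ht.cend - ht.cstart;
        o_start.push_back(ht.cstart); o_end.push_back(ht.cend);
        o_qs.push_back(qs); o_qe.push_back(qe);
        o_score.push_back(ht.score);
        o_div.push_back(alen > 0 ? (double)ht.mm / alen : 0.0);
        o_fam.push_back(name);
        o_strand.push_back(strand == 0 ? "+" : "-");
      }
    }
  }
  return DataFrame::create(
    _["family_id"] = wrap(o_fam), _["start"] = wrap(o_start),
    _["end"] = wrap(o_end), _["strand"] = wrap(o_strand),
    _["score"] = wrap(o_score), _["divergence"] = wrap(o_div),
    _["qstart"] = wrap(o_qs), _["qend"] = wrap(o_qe),
    _["stringsAsFactors"] = false);
}
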