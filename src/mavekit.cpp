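#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Hamming distance; strings of unequal length are incomparable (NA upstream).
static inline int hamming(const std::string &a, const std::string &b) {
    int d = 0;
    for (size_t i = 0; i < a.size(); ++i)
        if (a[i] != b[i]) ++d;
    return d;
}

// [[Rcpp::export]]
IntegerMatrix cpp_hamming_matrix(CharacterVector seqs, CharacterVector refs) {
    int n = seqs.size(), m = refs.size();
    IntegerMatrix out(n, m);
    std::vector<std::string> rf(m);
    for (int j = 0; j < m; ++j) rf[j] = as<std::string>(refs[j]);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        for (int j = 0; j < m; ++j) {
            if (s.size() != rf[j].size())
                out(i, j) = NA_INTEGER;
            else
                out(i, j) = hamming(s, rf[j]);
        }
    }
    return out;
}

// 1-based positions at which seq differs from ref (equal lengths required).
// [[Rcpp::export]]
IntegerVector cpp_diff_positions(std::string seq, std::string ref) {
    if (seq.size() != ref.size())
        stop("sequences must have equal length");
    std::vector<int> pos;
    for (size_t i = 0; i < seq.size(); ++i)
        if (seq[i] != ref[i]) pos.push_back((int)i + 1);
    return wrap(pos);
}

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return c;  // N and other IUPAC left as-is
    }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    int n = seqs.size();
    CharacterVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::string r(s.size(), ' ');
        for (size_t k = 0; k < s.size(); ++k)
            r[k] = comp(s[s.size() - 1 - k]);
        out[i] = r;
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_reverse_strings(CharacterVector x) {
    int n = x.size();
    CharacterVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(x[i]);
        std::reverse(s.begin(), s.end());
        out[i] = s;
    }
    return out;
}

// Mean Phred score (ASCII offset 33) per quality string; NaN for empty.
// [[Rcpp::export]]
NumericVector cpp_phred_means(CharacterVector quals) {
    int n = quals.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string q = as<std::string>(quals[i]);
        if (q.empty()) { out[i] = R_NaN; continue; }
        double s = 0;
        for (size_t k = 0; k < q.size(); ++k) s += (double)q[k] - 33.0;
        out[i] = s / (double)q.size();
    }
    return out;
}

// [[Rcpp::export]]
IntegerVector cpp_count_char(CharacterVector seqs, char what) {
    int n = seqs.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        out[i] = (int)std::count(s.begin(), s.end(), what);
    }
    return out;
}

// Overlap-merge read pairs. The reverse sequence must already be
// reverse-complemented (and its qualities reversed) so both mates are in
// forward orientation. Overlaps are scanned from the longest allowed width
// down to the shortest; the first width whose mismatch fraction is within
// max_mismatch_fraction and whose merged length lies in
// [min_merged_length, max_merged_length] wins. Within the overlap,
// discordant bases are resolved towards the higher quality (tie: forward
// base); the retained quality is the maximum of the two.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fwd, CharacterVector fwd_qual,
                     CharacterVector rev, CharacterVector rev_qual,
                     int min_overlap, int max_overlap,
                     int min_merged_length, int max_merged_length,
                     double max_mismatch_fraction) {
    int n = fwd.size();
    CharacterVector mseq(n), mqual(n);
    LogicalVector ok(n);
    for (int i = 0; i < n; ++i) {
        std::string f = as<std::string>(fwd[i]);
        std::string fq = as<std::string>(fwd_qual[i]);
        std::string r = as<std::string>(rev[i]);
        std::string rq = as<std::string>(rev_qual[i]);
        int lf = (int)f.size(), lr = (int)r.size();
        int hi = std::min(std::min(lf, lr), max_overlap);
        int lo = std::max(1, min_overlap);
        bool found = false;
        for (int o = hi; o >= lo && !found; --o) {
            int mlen = lf + lr - o;
            if (mlen < min_merged_length || mlen > max_merged_length) continue;
            int mm = 0;
            for (int k = 0; k < o; ++k)
                if (f[lf - o + k] != r[k]) ++mm;
            if ((double)mm / (double)o > max_mismatch_fraction) continue;
            std::string ms = f.substr(0, lf - o);
            std::string mq = fq.substr(0, lf - o);
            for (int k = 0; k < o; ++k) {
                char fb = f[lf - o + k], rb = r[k];
                char fqc = fq[lf - o + k], rqc = rq[k];
                if (fb == rb) {
                    ms.push_back(fb);
                    mq.push_back(std::max(fqc, rqc));
                } else if (rqc > fqc) {
                    ms.push_back(rb);
                    mq.push_back(rqc);
                } else {
                    ms.push_back(fb);
                    mq.push_back(fqc);
                }
            }
            ms += r.substr(o);
            mq += rq.substr(o);
            mseq[i] = ms;
            mqual[i] = mq;
            found = true;
        }
        ok[i] = found;
        if (!found) { mseq[i] = NA_STRING; mqual[i] = NA_STRING; }
    }
    return List::create(_["seq"] = mseq, _["qual"] = mqual, _["ok"] = ok);
}

// Constant-region check against one or more references: nearest reference by
// Hamming distance among equal-length references; fail on tie, on distance
// above max_mismatch, or when no reference has a compatible length.
// Per-quality match/mismatch counts (vs the nearest reference) are
// accumulated for every inspected read, pass or fail.
// [[Rcpp::export]]
List cpp_constant_check(CharacterVector cseqs, CharacterVector cquals,
                        CharacterVector refs, double max_mismatch) {
    int n = cseqs.size(), m = refs.size();
    std::vector<std::string> rf(m);
    for (int j = 0; j < m; ++j) rf[j] = as<std::string>(refs[j]);
    LogicalVector pass(n);
    IntegerMatrix tally(94, 2);  // columns: nMatch, nMismatch by quality 0..93
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(cseqs[i]);
        std::string q = as<std::string>(cquals[i]);
        int best = -1, bestd = 0, nbest = 0;
        for (int j = 0; j < m; ++j) {
            if (rf[j].size() != s.size()) continue;
            int d = hamming(s, rf[j]);
            if (best < 0 || d < bestd) { best = j; bestd = d; nbest = 1; }
            else if (d == bestd) ++nbest;
        }
        if (best < 0) { pass[i] = false; continue; }
        const std::string &r = rf[best];
        for (size_t k = 0; k < s.size(); ++k) {
            int qv = (int)q[k] - 33;
            if (qv < 0) qv = 0;
            if (qv > 93) qv = 93;
            if (s[k] == r[k]) tally(qv, 0) += 1; else tally(qv, 1) += 1;
        }
        pass[i] = (nbest == 1) && ((double)bestd <= max_mismatch);
    }
    return List::create(_["pass"] = pass, _["tally"] = tally);
}

// Greedy absorption sweep. Sequences must be pre-sorted by decreasing count
// (ties broken lexicographically). Returns, for each sequence, the 1-based
// index of the seed it belongs to (its own index if it seeds a cluster).
// A sequence is absorbed into the earliest seed with equal length, Hamming
// distance <= max_distance, seed count >= min_abundance and
// seed count / own count >= min_ratio; counts are the original (pre-sweep)
// counts. Absorbed sequences never absorb others.
// [[Rcpp::export]]
IntegerVector cpp_greedy_collapse(CharacterVector seqs, NumericVector counts,
                                  int max_distance, double min_abundance,
                                  double min_ratio) {
    int n = seqs.size();
    IntegerVector assign(n);
    std::vector<std::string> ss(n);
    for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
    std::vector<int> seeds;
    for (int i = 0; i < n; ++i) {
        int home = -1;
        for (size_t k = 0; k < seeds.size(); ++k) {
            int j = seeds[k];
            if (ss[j].size() != ss[i].size()) continue;
            if (counts[j] < min_abundance) continue;
            if (counts[i] > 0 && counts[j] / counts[i] < min_ratio) continue;
            if (hamming(ss[i], ss[j]) <= max_distance) { home = j; break; }
        }
        if (home < 0) { seeds.push_back(i); assign[i] = i + 1; }
        else assign[i] = home + 1;
    }
    return assign;
}

// Substitution errors injected per base with probability given by rate[i]
// for read i; the replacement base is drawn uniformly from the other three.
// u supplies pre-drawn uniforms (consumed sequentially) so that the caller
// controls the random stream.
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector seqs, NumericVector rate,
                                  NumericVector u, NumericVector upick) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    int n = seqs.size();
    CharacterVector out(n);
    R_xlen_t ui = 0, pi = 0;
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        for (size_t k = 0; k < s.size(); ++k) {
            double uu = u[ui++];
            if (uu < rate[i]) {
                char cur = s[k];
                int off = 1 + (int)(upick[pi++] * 3.0);
                if (off > 3) off = 3;
                int idx = 0;
                switch (cur) {
                case 'A': idx = 0; break; case 'C': idx = 1; break;
                case 'G': idx = 2; break; case 'T': idx = 3; break;
                default:  idx = 0; break;
                }
                s[k] = bases[(idx + off) % 4];
            }
        }
        out[i] = s;
    }
    return out;
}
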