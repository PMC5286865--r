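// Online suffix automaton over the separator-joined reference concatenation.
// Alphabet codes: A=0 C=1 G=2 T=3, separator/ambiguous(ref)=4; ambiguous
// query characters (N etc.) take no transition, so matches never cross a
// reference boundary and N never matches on either side.
#include <Rcpp.h>
#include <array>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

struct SuffixAutomaton {
  std::vector<int> len, link;
  std::vector<std::array<int, 5>> nxt;
  int last;

  SuffixAutomaton() {
    len.assign(1, 0);
    link.assign(1, -1);
    nxt.assign(1, blank());
    last = 0;
  }

  static std::array<int, 5> blank() {
    return std::array<int, 5>{{-1, -1, -1, -1, -1}};
  }

  void reserve(size_t n_chars) {
    size_t n = 2 * n_chars + 4;
    len.reserve(n);
    link.reserve(n);
    nxt.reserve(n);
  }

  int node(int l, int lk, const std::array<int, 5>& tr) {
    len.push_back(l);
    link.push_back(lk);
    nxt.push_back(tr);
    return static_cast<int>(len.size()) - 1;
  }

  void extend(int c) {
    int cur = node(len[last] + 1, -1, blank());
    int p = last;
    while (p != -1 && nxt[p][c] == -1) {
      nxt[p][c] = cur;
      p = link[p];
    }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = nxt[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = node(len[p] + 1, link[q], nxt[q]);
        while (p != -1 && nxt[p][c] == q) {
          nxt[p][c] = clone;
          p = link[p];
        }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  }

  static int code_ref(char ch) {
    switch (ch) {
      case 'A': return 0;
      case 'C': return 1;
      case 'G': return 2;
      case 'T': return 3;
      default:  return 4;  // separator; never reachable from a query
    }
  }

  static int code_query(char ch) {
    switch (ch) {
      case 'A': return 0;
      case 'C': return 1;
      case 'G': return 2;
      case 'T': return 3;
      default:  return -1;  // N and friends: match nothing
    }
  }

  void add_sequence(const std::string& s, bool separator_before) {
    if (separator_before) extend(4);
    for (char ch : s) extend(code_ref(ch));
  }

  // E[j] = length of the longest suffix of q[0..j] occurring in the text.
  std::vector<int> suffix_match(const std::string& q) const {
    std::vector<int> E(q.size(), 0);
    int v = 0, l = 0;
    for (size_t j = 0; j < q.size(); ++j) {
      int c = code_query(q[j]);
      if (c < 0) {
        v = 0;
        l = 0;
        E[j] = 0;
        continue;
      }
      while (v != 0 && nxt[v][c] == -1) {
        v = link[v];
        l = len[v];
      }
      if (nxt[v][c] != -1) {
        v = nxt[v][c];
        ++l;
      } else {
        l = 0;
      }
      E[j] = l;
    }
    return E;
  }
};

// Convert end-anchored match lengths E to start-anchored lengths L:
// L[i] = max { j - i + 1 : j >= i, E[j] >= j - i + 1 }.  The match start
// j - E[j] + 1 is non-decreasing in j (E grows by at most 1), so a single
// forward pointer suffices.
std::vector<int> starts_to_lengths(const std::vector<int>& E) {
  int n = static_cast<int>(E.size());
  std::vector<int> L(n, 0);
  int t = 0;
  for (int i = 0; i < n; ++i) {
    while (t < n && t - E[t] + 1 <= i) ++t;
    int j = t - 1;
    L[i] = (j >= i) ? (j - i + 1) : 0;
  }
  return L;
}

IntegerVector to_iv(const std::vector<int>& x) {
  return IntegerVector(x.begin(), x.end());
}

}  // namespace

// [[Rcpp::export(name = ".sam_build")]]
SEXP sam_build(CharacterVector seqs) {
  SuffixAutomaton* sam = new SuffixAutomaton();
  size_t total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) total += LENGTH(STRING_ELT(seqs, i)) + 1;
  sam->reserve(total);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    sam->add_sequence(as<std::string>(seqs[i]), i > 0);
  }
  XPtr<SuffixAutomaton> ptr(sam, true);
  return ptr;
}

// [[Rcpp::export(name = ".sam_match_profile")]]
IntegerVector sam_match_profile(SEXP xp, std::string query) {
  XPtr<SuffixAutomaton> sam(xp);
  return to_iv(starts_to_lengths(sam->suffix_match(query)));
}

// [[Rcpp::export(name = ".sam_node_count")]]
int sam_node_count(SEXP xp) {
  XPtr<SuffixAutomaton> sam(xp);
  return static_cast<int>(sam->len.size());
}

// Leave-one-out match profiles.  `group` must be non-decreasing; elements of
// one group are excluded together.  Two linear passes: each element is
// matched against an automaton over all preceding groups, then against one
// over all following groups; the per-position maximum is the exact
// leave-group-out answer.
// [[Rcpp::export(name = ".sam_loo_profiles")]]
List sam_loo_profiles(CharacterVector seqs, IntegerVector group) {
  int m = static_cast<int>(seqs.size());
  if (group.size() != m) stop("group must parallel seqs");
  std::vector<std::string> s(m);
  size_t total = 0;
  for (int i = 0; i < m; ++i) {
    s[i] = as<std::string>(seqs[i]);
    total += s[i].size() + 1;
  }
  std::vector<std::vector<int>> best(m);
  {
    SuffixAutomaton fwd;
    fwd.reserve(total);
    int i = 0;
    bool any_added = false;
    while (i < m) {
      int j = i;
      while (j < m && group[j] == group[i]) ++j;
      for (int k = i; k < j; ++k) best[k] = fwd.suffix_match(s[k]);
      for (int k = i; k < j; ++k) {
        fwd.add_sequence(s[k], any_added);
        any_added = true;
      }
      i = j;
    }
  }
  {
    SuffixAutomaton bwd;
    bwd.reserve(total);
    int i = m - 1;
    bool any_added = false;
    while (i >= 0) {
      int j = i;
      while (j >= 0 && group[j] == group[i]) --j;
      for (int k = j + 1; k <= i; ++k) {
        std::vector<int> e = bwd.suffix_match(s[k]);
        for (size_t p = 0; p < e.size(); ++p) {
          if (e[p] > best[k][p]) best[k][p] = e[p];
        }
      }
      for (int k = j + 1; k <= i; ++k) {
        bwd.add_sequence(s[k], any_added);
        any_added = true;
      }
      i = j;
    }
  }
  List out(m);
  for (int k = 0; k < m; ++k) out[k] = to_iv(starts_to_lengths(best[k]));
  return out;
}
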