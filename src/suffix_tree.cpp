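// Suffix tree built by naive successive insertion of suffixes into a
// character trie with string tails.  A node stores single characters on its
// child edges plus, optionally, the uncompared remainder ("tail") of one
// inserted suffix; the tail is split into nodes the moment a second suffix
// shares its prefix.  Lookup of a word of length m walks at most m child
// edges plus one tail comparison.

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  std::map<char, int> children;
  std::string tail;          // uncompared remainder of one suffix, "" if none
  int tail_pos;              // 1-based start of the suffix carried by tail
  std::vector<int> end_pos;  // suffixes terminating exactly at this node
  Node() : tail_pos(-1) {}
};

class SuffixTree {
 public:
  explicit SuffixTree(const std::string& s) : seq_(s) {
    nodes_.reserve(2 * s.size() + 1);
    nodes_.emplace_back();  // root
    for (std::size_t p = 0; p < s.size(); ++p) insert(p);
  }

  std::size_t seq_length() const { return seq_.size(); }
  std::size_t node_count() const { return nodes_.size(); }

  // All start positions (1-based, ascending) where `w` occurs.
  // path_chars / tail_cmps, when non-null, receive the number of child-edge
  // descents and tail comparisons performed (the O(m) walk, instrumented).
  std::vector<int> find(const std::string& w, int* path_chars,
                        int* tail_cmps) const {
    std::vector<int> out;
    if (w.empty()) return out;
    int v = 0;
    std::size_t i = 0;
    while (i < w.size()) {
      std::map<char, int>::const_iterator it = nodes_[v].children.find(w[i]);
      if (it != nodes_[v].children.end()) {
        v = it->second;
        ++i;
        if (path_chars) ++*path_chars;
        continue;
      }
      // The remainder, if present at all, lies inside this node's tail.
      if (!nodes_[v].tail.empty()) {
        if (tail_cmps) ++*tail_cmps;
        const std::string& t = nodes_[v].tail;
        std::size_t rem = w.size() - i;
        if (rem <= t.size() && t.compare(0, rem, w, i, rem) == 0)
          out.push_back(nodes_[v].tail_pos);
      }
      return out;
    }
    // Word fully matched along a path: every suffix below starts with it.
    collect(v, out);
    std::sort(out.begin(), out.end());
    return out;
  }

  bool contains(const std::string& w) const {
    if (w.empty()) return false;
    int v = 0;
    std::size_t i = 0;
    while (i < w.size()) {
      std::map<char, int>::const_iterator it = nodes_[v].children.find(w[i]);
      if (it != nodes_[v].children.end()) {
        v = it->second;
        ++i;
        continue;
      }
      const std::string& t = nodes_[v].tail;
      std::size_t rem = w.size() - i;
      return !t.empty() && rem <= t.size() && t.compare(0, rem, w, i, rem) == 0;
    }
    return true;
  }

  // Spell every stored suffix (root-to-terminal concatenation) with its
  // 1-based start position; used to verify the suffix-set invariant.
  void suffixes(std::vector<int>* pos, std::vector<std::string>* str) const {
    std::string cur;
    spell(0, cur, pos, str);
  }

 private:
  void insert(std::size_t p) {
    int v = 0;
    std::size_t i = p;
    while (true) {
      if (i == seq_.size()) {
        nodes_[v].end_pos.push_back(static_cast<int>(p) + 1);
        return;
      }
      char c = seq_[i];
      std::map<char, int>::iterator it = nodes_[v].children.find(c);
      if (it != nodes_[v].children.end()) {
        v = it->second;
        ++i;
        continue;
      }
      if (!nodes_[v].tail.empty() && nodes_[v].tail[0] == c) {
        pop_tail(v);  // split: the tail's first char becomes a child node
        continue;
      }
      // No shared path: store the remainder as the tail of a fresh child.
      nodes_.emplace_back();
      int u = static_cast<int>(nodes_.size()) - 1;
      nodes_[v].children[c] = u;
      if (i + 1 < seq_.size()) {
        nodes_[u].tail = seq_.substr(i + 1);
        nodes_[u].tail_pos = static_cast<int>(p) + 1;
      } else {
        nodes_[u].end_pos.push_back(static_cast<int>(p) + 1);
      }
      return;
    }
  }

  // Move the first tail character of node v into a child node, so a second
  // suffix sharing that character can continue the walk below it.
  void pop_tail(int v) {
    std::string t;
    t.swap(nodes_[v].tail);
    int tp = nodes_[v].tail_pos;
    nodes_[v].tail_pos = -1;
    nodes_.emplace_back();
    int u = static_cast<int>(nodes_.size()) - 1;
    nodes_[v].children[t[0]] = u;
    if (t.size() > 1) {
      nodes_[u].tail = t.substr(1);
      nodes_[u].tail_pos = tp;
    } else {
      nodes_[u].end_pos.push_back(tp);
    }
  }

  void collect(int v, std::vector<int>& out) const {
    for (std::size_t j = 0; j < nodes_[v].end_pos.size(); ++j)
      out.push_back(nodes_[v].end_pos[j]);
    if (nodes_[v].tail_pos >= 0) out.push_back(nodes_[v].tail_pos);
    for (std::map<char, int>::const_iterator it = nodes_[v].children.begin();
         it != nodes_[v].children.end(); ++it)
      collect(it->second, out);
  }

  void spell(int v, std::string& cur, std::vector<int>* pos,
             std::vector<std::string>* str) const {
    for (std::size_t j = 0; j < nodes_[v].end_pos.size(); ++j) {
      pos->push_back(nodes_[v].end_pos[j]);
      str->push_back(cur);
    }
    if (nodes_[v].tail_pos >= 0) {
      pos->push_back(nodes_[v].tail_pos);
      str->push_back(cur + nodes_[v].tail);
    }
    for (std::map<char, int>::const_iterator it = nodes_[v].children.begin();
         it != nodes_[v].children.end(); ++it) {
      cur.push_back(it->first);
      spell(it->second, cur, pos, str);
      cur.pop_back();
    }
  }

  std::string seq_;
  std::vector<Node> nodes_;
};

SuffixTree* get_tree(SEXP xp) {
  XPtr<SuffixTree> p(xp);
  if (!p) stop("invalid suffix index handle");
  return p.get();
}

}  // namespace

// [[Rcpp::export(name = ".st_build")]]
SEXP st_build(std::string sequence) {
  if (sequence.empty()) stop("empty sequence");
  XPtr<SuffixTree> p(new SuffixTree(sequence), true);
  return p;
}

// [[Rcpp::export(name = ".st_length")]]
int st_length(SEXP xp) {
  return static_cast<int>(get_tree(xp)->seq_length());
}

// [[Rcpp::export(name = ".st_node_count")]]
int st_node_count(SEXP xp) {
  return static_cast<int>(get_tree(xp)->node_count());
}

// [[Rcpp::export(name = ".st_find")]]
IntegerVector st_find(SEXP xp, std::string word) {
  std::vector<int> v = get_tree(xp)->find(word, NULL, NULL);
  return wrap(v);
}

// [[Rcpp::export(name = ".st_find_many")]]
List st_find_many(SEXP xp, CharacterVector words) {
  SuffixTree* t = get_tree(xp);
  List out(words.size());
  for (R_xlen_t i = 0; i < words.size(); ++i) {
    std::vector<int> v = t->find(as<std::string>(words[i]), NULL, NULL);
    out[i] = wrap(v);
  }
  return out;
}

// [[Rcpp::export(name = ".st_find_profiled")]]
List st_find_profiled(SEXP xp, std::string word) {
  int path_chars = 0, tail_cmps = 0;
  std::vector<int> v = get_tree(xp)->find(word, &path_chars, &tail_cmps);
  return List::create(_["positions"] = wrap(v),
                      _["path_chars"] = path_chars,
                      _["tail_comparisons"] = tail_cmps);
}

// [[Rcpp::export(name = ".st_contains")]]
bool st_contains(SEXP xp, std::string word) {
  return get_tree(xp)->contains(word);
}

// [[Rcpp::export(name = ".st_suffixes")]]
DataFrame st_suffixes(SEXP xp) {
  std::vector<int> pos;
  std::vector<std::string> str;
  get_tree(xp)->suffixes(&pos, &str);
  return DataFrame::create(_["position"] = wrap(pos),
                           _["suffix"] = wrap(str),
                           _["stringsAsFactors"] = false);
}
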