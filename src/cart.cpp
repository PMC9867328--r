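// Compiled core of the RUS-boosted CART ensemble.
//
// A boosting run makes hundreds of small tree fits; formula-interface tree
// fitters pay a fixed per-call model-frame cost that dominates at these
// sizes. This implementation keeps rpart's splitting semantics (binary Gini
// splits, minimum bucket/split sizes, complexity threshold) but fits each
// tree from feature orders presorted once per ensemble and partitioned down
// the tree, and runs the full boosting loop (weighted balanced
// undersampling, AdaBoost weight updates) without leaving C++. All
// randomness comes from R's RNG, so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature;       // -1 for leaf
  double threshold;  // go left if x <= threshold
  int left, right;
  double prob1;
};

struct Tree {
  std::vector<Node> nodes;
};

typedef std::vector<std::vector<int> > SortedIdx;  // per-feature row order

double giniCost(int n1, int n) {
  if (n == 0) return 0.0;
  double p = (double)n1 / n;
  return 2.0 * p * (1.0 - p) * n;
}

void grow(const NumericMatrix& X, const IntegerVector& y,
          const SortedIdx& sorted, int depth, int maxdepth, int minbucket,
          int minsplit, double cpScaled, Tree& tree, int me) {
  int p = sorted.size();
  int n = sorted[0].size();
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += y[sorted[0][i]];
  tree.nodes[me].feature = -1;
  tree.nodes[me].prob1 = n == 0 ? 0.0 : (double)n1 / n;
  if (n < minsplit || n1 == 0 || n1 == n || depth >= maxdepth) return;

  double parentCost = giniCost(n1, n);
  double bestGain = cpScaled;
  int bestF = -1;
  double bestThr = 0.0;
  for (int f = 0; f < p; ++f) {
    const std::vector<int>& ord = sorted[f];
    int l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      l1 += y[ord[i]];
      int nl = i + 1, nr = n - nl;
      if (nl < minbucket || nr < minbucket) continue;
      double v = X(ord[i], f), vn = X(ord[i + 1], f);
      if (v == vn) continue;  // no cut between tied values
      double gain = parentCost - giniCost(l1, nl) - giniCost(n1 - l1, nr);
      if (gain > bestGain + 1e-12) {
        bestGain = gain;
        bestF = f;
        bestThr = 0.5 * (v + vn);
      }
    }
  }
  if (bestF < 0) return;

  SortedIdx ls(p), rs(p);
  for (int f = 0; f < p; ++f) {
    ls[f].reserve(n); rs[f].reserve(n);
    for (int i = 0; i < n; ++i) {
      int r = sorted[f][i];
      if (X(r, bestF) <= bestThr) ls[f].push_back(r);
      else rs[f].push_back(r);
    }
  }
  tree.nodes[me].feature = bestF;
  tree.nodes[me].threshold = bestThr;
  tree.nodes.push_back(Node());
  int lid = tree.nodes.size() - 1;
  tree.nodes.push_back(Node());
  int rid = tree.nodes.size() - 1;
  tree.nodes[me].left = lid;
  tree.nodes[me].right = rid;
  grow(X, y, ls, depth + 1, maxdepth, minbucket, minsplit, cpScaled,
       tree, lid);
  grow(X, y, rs, depth + 1, maxdepth, minbucket, minsplit, cpScaled,
       tree, rid);
}

Tree fitTree(const NumericMatrix& X, const IntegerVector& y,
             const SortedIdx& globalOrder, const std::vector<char>& member,
             int minbucket, int minsplit, double cp, int maxdepth) {
  int p = globalOrder.size();
  SortedIdx sorted(p);
  for (int f = 0; f < p; ++f) {
    sorted[f].reserve(X.nrow());
    for (size_t i = 0; i < globalOrder[f].size(); ++i) {
      int r = globalOrder[f][i];
      if (member[r]) sorted[f].push_back(r);
    }
  }
  int n = sorted[0].size(), n1 = 0;
  for (int i = 0; i < n; ++i) n1 += y[sorted[0][i]];
  Tree tree;
  tree.nodes.push_back(Node());
  grow(X, y, sorted, 0, maxdepth, minbucket, minsplit,
       cp * giniCost(n1, n), tree, 0);
  return tree;
}

int treeClass(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.nodes[node].feature >= 0) {
    node = X(row, t.nodes[node].feature) <= t.nodes[node].threshold
             ? t.nodes[node].left : t.nodes[node].right;
  }
  return t.nodes[node].prob1 > 0.5 ? 1 : 0;
}

// weighted sampling without replacement (Efraimidis-Spirakis keys);
// returns `size` indices from `cand` with probability proportional to w
std::vector<int> sampleWeighted(const std::vector<int>& cand, int size,
                                const std::vector<double>& w) {
  int m = cand.size();
  if (size >= m) return cand;
  std::vector<std::pair<double, int> > keys(m);
  for (int i = 0; i < m; ++i) {
    double u = unif_rand();
    keys[i] = std::make_pair(std::pow(u, 1.0 / std::max(w[cand[i]], 1e-300)),
                             cand[i]);
  }
  std::partial_sort(keys.begin(), keys.begin() + size, keys.end(),
                    std::greater<std::pair<double, int> >());
  std::vector<int> out(size);
  for (int i = 0; i < size; ++i) out[i] = keys[i].second;
  return out;
}

List treeToList(const Tree& t) {
  int m = t.nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), prob1(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = t.nodes[i].feature;
    threshold[i] = t.nodes[i].feature < 0 ? NA_REAL : t.nodes[i].threshold;
    left[i] = t.nodes[i].feature < 0 ? -1 : t.nodes[i].left;
    right[i] = t.nodes[i].feature < 0 ? -1 : t.nodes[i].right;
    prob1[i] = t.nodes[i].prob1;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["prob1"] = prob1);
}

Tree treeFromList(List tl) {
  IntegerVector feature = tl["feature"], left = tl["left"],
                right = tl["right"];
  NumericVector threshold = tl["threshold"], prob1 = tl["prob1"];
  Tree t;
  t.nodes.resize(feature.size());
  for (int i = 0; i < feature.size(); ++i) {
    t.nodes[i].feature = feature[i];
    t.nodes[i].threshold = threshold[i];
    t.nodes[i].left = left[i];
    t.nodes[i].right = right[i];
    t.nodes[i].prob1 = prob1[i];
  }
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".rusBoost")]]
List rusBoost(NumericMatrix X, IntegerVector y, int nCycles,
              double learnRate, int minbucket, int minsplit, double cp,
              int maxdepth) {
  RNGScope rng;
  int n = X.nrow(), p = X.ncol();
  SortedIdx globalOrder(p);
  for (int f = 0; f < p; ++f) {
    std::vector<std::pair<double, int> > v(n);
    for (int i = 0; i < n; ++i) v[i] = std::make_pair(X(i, f), i);
    std::sort(v.begin(), v.end());
    globalOrder[f].resize(n);
    for (int i = 0; i < n; ++i) globalOrder[f][i] = v[i].second;
  }
  std::vector<int> i0, i1;
  for (int i = 0; i < n; ++i) (y[i] == 0 ? i0 : i1).push_back(i);
  int nTake = std::min(i0.size(), i1.size());
  std::vector<double> w(n, 1.0 / n);
  List trees;
  std::vector<double> alphas;

  std::vector<char> member(n);
  for (int m = 0; m < nCycles; ++m) {
    std::fill(member.begin(), member.end(), 0);
    std::vector<int> t0 = sampleWeighted(i0, nTake, w);
    std::vector<int> t1 = sampleWeighted(i1, nTake, w);
    for (size_t i = 0; i < t0.size(); ++i) member[t0[i]] = 1;
    for (size_t i = 0; i < t1.size(); ++i) member[t1[i]] = 1;
    Tree tree = fitTree(X, y, globalOrder, member, minbucket, minsplit,
                        cp, maxdepth);
    double err = 0.0;
    std::vector<char> mis(n);
    for (int i = 0; i < n; ++i) {
      mis[i] = treeClass(tree, X, i) != y[i];
      if (mis[i]) err += w[i];
    }
    if (err >= 0.5) continue;  // weak learner no better than chance
    if (err < 1e-10) err = 1e-10;
    double a = learnRate * 0.5 * std::log((1.0 - err) / err);
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      w[i] *= std::exp(mis[i] ? a : -a);
      tot += w[i];
    }
    for (int i = 0; i < n; ++i) w[i] /= tot;
    trees.push_back(treeToList(tree));
    alphas.push_back(a);
  }
  if (trees.size() == 0) {  // fall back to one undersampled tree
    std::fill(member.begin(), member.end(), 0);
    std::vector<int> t0 = sampleWeighted(i0, nTake, w);
    std::vector<int> t1 = sampleWeighted(i1, nTake, w);
    for (size_t i = 0; i < t0.size(); ++i) member[t0[i]] = 1;
    for (size_t i = 0; i < t1.size(); ++i) member[t1[i]] = 1;
    trees.push_back(treeToList(fitTree(X, y, globalOrder, member, minbucket,
                                       minsplit, cp, maxdepth)));
    alphas.push_back(1.0);
  }
  return List::create(_["trees"] = trees,
                      _["alphas"] = NumericVector(alphas.begin(),
                                                  alphas.end()));
}

// [[Rcpp::export(name = ".ensemblePredict")]]
IntegerVector ensemblePredict(List trees, NumericVector alphas,
                              NumericMatrix X) {
  int n = X.nrow();
  std::vector<double> score(n, 0.0);
  for (int k = 0; k < trees.size(); ++k) {
    Tree t = treeFromList(trees[k]);
    for (int i = 0; i < n; ++i)
      score[i] += alphas[k] * (treeClass(t, X, i) == 1 ? 1.0 : -1.0);
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = score[i] > 0 ? 1 : 0;
  return out;
}
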