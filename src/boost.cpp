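// Stage-wise gradient boosting of shallow regression trees.
//
// Each stage fits a best-first regression tree with a fixed number of
// internal splits (tree complexity) to the current loss gradient on a
// bagged row subsample, then adds it with shrinkage. Terminal-node values
// are loss-specific one-step estimates on the in-bag rows (mean residual
// for Gaussian; log(sum y / sum exp(f)) for Poisson, clamped). Split
// improvements (squared-error reduction in gradient space) are accumulated
// per predictor for relative-influence accounting. All randomness flows
// through R's RNG so a set.seed() on the R side fixes the fit bit-for-bit.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Leaf {
  std::vector<int> rows;  // positions into the bag arrays
  double bestImp;
  int bestVar;            // 0-based; -1 = no valid split
  double bestSplit;
  int nodeIndex;          // index into the node table
};

struct NodeTable {
  // parallel arrays; var = 0 marks a leaf, otherwise 1-based predictor
  std::vector<int> var;
  std::vector<double> split;
  std::vector<int> left, right;  // 1-based node indices, 0 for leaves
  std::vector<double> value;
  int addLeaf() {
    var.push_back(0);
    split.push_back(0.0);
    left.push_back(0);
    right.push_back(0);
    value.push_back(0.0);
    return (int)var.size() - 1;
  }
};

void bestSplitForLeaf(const NumericMatrix& X, const std::vector<int>& bagRows,
                      const std::vector<double>& g, Leaf& lf, int minObs) {
  lf.bestImp = -1.0;
  lf.bestVar = -1;
  const int nr = (int)lf.rows.size();
  if (nr < 2 * minObs) return;
  double S = 0.0;
  for (int i : lf.rows) S += g[i];
  const int p = X.ncol();
  std::vector<std::pair<double, double> > xv(nr);
  for (int v = 0; v < p; ++v) {
    for (int k = 0; k < nr; ++k) {
      const int i = lf.rows[k];
      xv[k] = std::make_pair(X(bagRows[i], v), g[i]);
    }
    std::sort(xv.begin(), xv.end());
    double SL = 0.0;
    for (int k = 0; k < nr - 1; ++k) {
      SL += xv[k].second;
      if (xv[k].first == xv[k + 1].first) continue;
      const int nL = k + 1, nR = nr - nL;
      if (nL < minObs || nR < minObs) continue;
      const double SR = S - SL;
      const double imp =
          SL * SL / nL + SR * SR / nR - S * S / nr;
      if (imp > lf.bestImp + 1e-12) {
        lf.bestImp = imp;
        lf.bestVar = v;
        lf.bestSplit = 0.5 * (xv[k].first + xv[k + 1].first);
      }
    }
  }
}

double routeValue(const NodeTable& t, const NumericMatrix& X, int row) {
  int cur = 0;
  while (t.var[cur] != 0) {
    cur = (X(row, t.var[cur] - 1) <= t.split[cur]) ? t.left[cur] - 1
                                                   : t.right[cur] - 1;
  }
  return t.value[cur];
}

double meanDeviance(const NumericVector& y, const std::vector<double>& f,
                    bool poisson) {
  const int n = y.size();
  double dev = 0.0;
  for (int i = 0; i < n; ++i) {
    if (poisson) {
      const double mu = std::exp(f[i]);
      double t = (y[i] > 0) ? y[i] * std::log(y[i] / mu) : 0.0;
      dev += 2.0 * (t - (y[i] - mu));
    } else {
      const double r = y[i] - f[i];
      dev += r * r;
    }
  }
  return dev / n;
}

}  // namespace

// [[Rcpp::export(name = ".cppBoost")]]
List cppBoost(NumericMatrix X, NumericVector y, std::string loss,
              int nTrees, double lr, int tc, double bagFrac, int minObs,
              NumericMatrix Xtest, int stepSize, bool keepTrees) {
  const int n = X.nrow(), p = X.ncol(), nTest = Xtest.nrow();
  const bool poisson = (loss == "poisson");

  double init;
  if (poisson) {
    double my = mean(y);
    init = std::log(std::max(my, 1e-8));
  } else {
    init = mean(y);
  }
  std::vector<double> f(n, init), fTest(nTest, init);

  std::vector<int> checkpoints;
  for (int t = stepSize; t <= nTrees; t += stepSize) checkpoints.push_back(t);
  if (checkpoints.empty() || checkpoints.back() != nTrees)
    checkpoints.push_back(nTrees);
  const int nCheck = (int)checkpoints.size();
  NumericMatrix testCheck(nCheck, nTest);
  NumericVector trainDev(nCheck);
  int checkIdx = 0;

  NumericVector varImp(p);
  List trees(keepTrees ? nTrees : 0);

  const int bagSize = std::max(1, (int)std::lround(bagFrac * n));
  std::vector<int> bagRows(bagSize);
  std::vector<double> g(bagSize);

  for (int t = 0; t < nTrees; ++t) {
    // bag: sample without replacement via R's RNG
    IntegerVector pick = Rcpp::sample(n, bagSize, false);
    for (int k = 0; k < bagSize; ++k) bagRows[k] = pick[k] - 1;
    for (int k = 0; k < bagSize; ++k) {
      const int i = bagRows[k];
      g[k] = poisson ? (y[i] - std::exp(f[i])) : (y[i] - f[i]);
    }

    NodeTable nt;
    std::vector<Leaf> leaves(1);
    leaves[0].rows.resize(bagSize);
    for (int k = 0; k < bagSize; ++k) leaves[0].rows[k] = k;
    leaves[0].nodeIndex = nt.addLeaf();
    bestSplitForLeaf(X, bagRows, g, leaves[0], minObs);

    for (int s = 0; s < tc; ++s) {
      int best = -1;
      double bestImp = 1e-12;
      for (size_t l = 0; l < leaves.size(); ++l) {
        if (leaves[l].bestVar >= 0 && leaves[l].bestImp > bestImp) {
          bestImp = leaves[l].bestImp;
          best = (int)l;
        }
      }
      if (best < 0) break;
      Leaf& parent = leaves[best];
      varImp[parent.bestVar] += parent.bestImp;

      Leaf lchild, rchild;
      for (int i : parent.rows) {
        if (X(bagRows[i], parent.bestVar) <= parent.bestSplit)
          lchild.rows.push_back(i);
        else
          rchild.rows.push_back(i);
      }
      const int ni = parent.nodeIndex;
      nt.var[ni] = parent.bestVar + 1;
      nt.split[ni] = parent.bestSplit;
      lchild.nodeIndex = nt.addLeaf();
      rchild.nodeIndex = nt.addLeaf();
      nt.left[ni] = lchild.nodeIndex + 1;
      nt.right[ni] = rchild.nodeIndex + 1;
      bestSplitForLeaf(X, bagRows, g, lchild, minObs);
      bestSplitForLeaf(X, bagRows, g, rchild, minObs);
      leaves[best] = lchild;
      leaves.push_back(rchild);
    }

    // terminal-node values from the in-bag rows
    for (const Leaf& lf : leaves) {
      double val;
      if (poisson) {
        double sy = 0.0, sm = 0.0;
        for (int i : lf.rows) {
          sy += y[bagRows[i]];
          sm += std::exp(f[bagRows[i]]);
        }
        val = (sy > 0) ? std::log(sy / sm) : -19.0;
        val = std::max(-19.0, std::min(19.0, val));
      } else {
        double sg = 0.0;
        for (int i : lf.rows) sg += g[i];
        val = lf.rows.empty() ? 0.0 : sg / lf.rows.size();
      }
      nt.value[lf.nodeIndex] = val;
    }

    for (int i = 0; i < n; ++i) f[i] += lr * routeValue(nt, X, i);
    for (int i = 0; i < nTest; ++i)
      fTest[i] += lr * routeValue(nt, Xtest, i);

    if (keepTrees) {
      const int nn = (int)nt.var.size();
      NumericMatrix tm(nn, 5);
      for (int j = 0; j < nn; ++j) {
        tm(j, 0) = nt.var[j];
        tm(j, 1) = nt.split[j];
        tm(j, 2) = nt.left[j];
        tm(j, 3) = nt.right[j];
        tm(j, 4) = nt.value[j];
      }
      trees[t] = tm;
    }

    if (checkIdx < nCheck && t + 1 == checkpoints[checkIdx]) {
      trainDev[checkIdx] = meanDeviance(y, f, poisson);
      for (int i = 0; i < nTest; ++i) testCheck(checkIdx, i) = fTest[i];
      ++checkIdx;
    }
  }

  return List::create(
      _["init"] = init, _["fTrain"] = NumericVector(f.begin(), f.end()),
      _["checkpointTrees"] =
          IntegerVector(checkpoints.begin(), checkpoints.end()),
      _["testCheckpoints"] = testCheck, _["trainDeviance"] = trainDev,
      _["varImprovement"] = varImp, _["trees"] = trees);
}

// [[Rcpp::export(name = ".cppPredict")]]
NumericVector cppPredict(List trees, double init, double lr,
                         NumericMatrix X, int nTrees) {
  const int n = X.nrow();
  NumericVector f(n, init);
  for (int t = 0; t < nTrees; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int cur = 0;
      while ((int)tm(cur, 0) != 0) {
        cur = (X(i, (int)tm(cur, 0) - 1) <= tm(cur, 1)) ? (int)tm(cur, 2) - 1
                                                        : (int)tm(cur, 3) - 1;
      }
      f[i] += lr * tm(cur, 4);
    }
  }
  return f;
}
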