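// Felsenstein pruning under a reversible (GTR) substitution model, with
// coordinate-descent optimizers for branch lengths (free trees) and node
// heights (clock trees). Transition probabilities come from the symmetric
// eigendecomposition of the rate matrix, precomputed in R and passed as
// A exp(Lambda t) Ainv.

#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <vector>

using namespace Rcpp;

static const double BL_MIN = 1e-9;
static const double BL_MAX = 12.0;

struct Model {
  double A[16], Ainv[16], lam[4], pi[4];
};

static Model makeModel(const NumericMatrix& A, const NumericMatrix& Ainv,
                       const NumericVector& lam, const NumericVector& pi) {
  Model m;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      m.A[4 * i + j] = A(i, j);
      m.Ainv[4 * i + j] = Ainv(i, j);
    }
  for (int i = 0; i < 4; ++i) { m.lam[i] = lam[i]; m.pi[i] = pi[i]; }
  return m;
}

// P(t) = A diag(exp(lam t)) Ainv
static inline void pmat(const Model& m, double t, double* P) {
  double e[4];
  for (int k = 0; k < 4; ++k) e[k] = std::exp(m.lam[k] * t);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += m.A[4 * i + k] * e[k] * m.Ainv[4 * k + j];
      P[4 * i + j] = s;
    }
}

struct Pruner {
  int ntip, nnode, nedge, npat;
  std::vector<int> parent, child;     // postorder edges, 0-based node ids
  std::vector<int> tipStates;         // ntip x npat, column-major by pattern
  std::vector<double> weights;
  Model model;
  std::vector<double> partials;       // nnode x 4 x npat

  double lnl(const std::vector<double>& bl) {
    std::fill(partials.begin(), partials.end(), 1.0);
    double P[16];
    for (int e = 0; e < nedge; ++e) {
      pmat(model, bl[e], P);
      int pa = parent[e], ch = child[e];
      double* pp = &partials[(size_t)pa * 4 * npat];
      if (ch < ntip) {
        for (int s = 0; s < npat; ++s) {
          int st = tipStates[(size_t)ch * npat + s];
          if (st < 0) continue;       // gap/ambiguous: contributes 1
          for (int x = 0; x < 4; ++x) pp[4 * s + x] *= P[4 * x + st];
        }
      } else {
        const double* cp = &partials[(size_t)ch * 4 * npat];
        for (int s = 0; s < npat; ++s)
          for (int x = 0; x < 4; ++x) {
            double v = 0.0;
            for (int y = 0; y < 4; ++y) v += P[4 * x + y] * cp[4 * s + y];
            pp[4 * s + x] *= v;
          }
      }
    }
    int root = ntip;                 // ape convention: root = ntip + 1 (1-based)
    const double* rp = &partials[(size_t)root * 4 * npat];
    double ll = 0.0;
    for (int s = 0; s < npat; ++s) {
      double sl = 0.0;
      for (int x = 0; x < 4; ++x) sl += model.pi[x] * rp[4 * s + x];
      if (sl <= 0.0 || !std::isfinite(sl)) return -1e100;
      ll += weights[s] * std::log(sl);
    }
    return ll;
  }
};

static Pruner makePruner(const IntegerMatrix& edge, int ntip,
                         const IntegerMatrix& tipStates,
                         const NumericVector& weights,
                         const NumericMatrix& A, const NumericMatrix& Ainv,
                         const NumericVector& lam, const NumericVector& pi) {
  Pruner pr;
  pr.ntip = ntip;
  pr.nedge = edge.nrow();
  pr.npat = tipStates.ncol();
  if (tipStates.nrow() < ntip)
    stop("tip state matrix has fewer rows than tips");
  int mx = 0;
  for (int e = 0; e < pr.nedge; ++e) {
    if (edge(e, 0) > mx) mx = edge(e, 0);
    if (edge(e, 1) > mx) mx = edge(e, 1);
  }
  pr.nnode = mx;
  pr.parent.resize(pr.nedge);
  pr.child.resize(pr.nedge);
  for (int e = 0; e < pr.nedge; ++e) {
    pr.parent[e] = edge(e, 0) - 1;
    pr.child[e] = edge(e, 1) - 1;
  }
  pr.tipStates.resize((size_t)ntip * pr.npat);
  for (int i = 0; i < ntip; ++i)
    for (int s = 0; s < pr.npat; ++s)
      pr.tipStates[(size_t)i * pr.npat + s] = tipStates(i, s);
  pr.weights.assign(weights.begin(), weights.end());
  pr.model = makeModel(A, Ainv, lam, pi);
  pr.partials.resize((size_t)pr.nnode * 4 * pr.npat);
  return pr;
}

// Brent 1-D maximization of f on [a, b]
static double brentMax(const std::function<double(double)>& f, double a,
                       double b, double tol, double* xbest) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 60; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-12, tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool useGolden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etmp = e; e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etmp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        useGolden = false;
      }
    }
    if (useGolden) {
      e = (x >= xm) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu >= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu >= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *xbest = x;
  return fx;
}

// [[Rcpp::export]]
double cppGtrLnl(IntegerMatrix edge, int ntip, NumericVector bl,
                 IntegerMatrix tipStates, NumericVector weights,
                 NumericMatrix A, NumericMatrix Ainv, NumericVector lam,
                 NumericVector pi) {
  Pruner pr = makePruner(edge, ntip, tipStates, weights, A, Ainv, lam, pi);
  std::vector<double> b(bl.begin(), bl.end());
  return pr.lnl(b);
}

// coordinate-descent branch-length optimization (free tree)
// [[Rcpp::export]]
List cppOptimBl(IntegerMatrix edge, int ntip, NumericVector bl0,
                IntegerMatrix tipStates, NumericVector weights,
                NumericMatrix A, NumericMatrix Ainv, NumericVector lam,
                NumericVector pi, double tol, int maxCycles,
                double brentTol) {
  Pruner pr = makePruner(edge, ntip, tipStates, weights, A, Ainv, lam, pi);
  std::vector<double> bl(bl0.begin(), bl0.end());
  for (size_t e = 0; e < bl.size(); ++e) {
    if (bl[e] < BL_MIN) bl[e] = BL_MIN;
    if (bl[e] > BL_MAX) bl[e] = BL_MAX;
  }
  double cur = pr.lnl(bl);
  for (int cyc = 0; cyc < maxCycles; ++cyc) {
    double prev = cur;
    for (int e = 0; e < pr.nedge; ++e) {
      double xb;
      double fb = brentMax([&](double x) {
        bl[e] = x;
        return pr.lnl(bl);
      }, BL_MIN, BL_MAX, brentTol, &xb);
      if (fb >= cur) { bl[e] = xb; cur = fb; }
      else bl[e] = xb;  // brent returns best found; keep consistent
    }
    cur = pr.lnl(bl);
    if (cur - prev < tol) break;
  }
  return List::create(_["bl"] = NumericVector(bl.begin(), bl.end()),
                      _["lnl"] = cur);
}

// clock tree: parameters are root height then, for each non-root internal
// node in preorder, the fraction of its parent's height
// [[Rcpp::export]]
List cppOptimClock(IntegerMatrix edge, int ntip, IntegerVector preorderInt,
                   IntegerVector parentOf, NumericVector par0,
                   IntegerMatrix tipStates, NumericVector weights,
                   NumericMatrix A, NumericMatrix Ainv, NumericVector lam,
                   NumericVector pi, double tol, int maxCycles,
                   double brentTol) {
  Pruner pr = makePruner(edge, ntip, tipStates, weights, A, Ainv, lam, pi);
  int nPar = par0.size();
  std::vector<double> par(par0.begin(), par0.end());
  std::vector<double> heights(pr.nnode, 0.0);
  std::vector<double> bl(pr.nedge);

  auto computeBl = [&]() {
    int root = ntip;                // 0-based
    heights[root] = par[0];
    for (int k = 1; k < nPar; ++k) {
      int v = preorderInt[k] - 1;
      heights[v] = heights[parentOf[v] - 1] * par[k];
    }
    for (int i = 0; i < ntip; ++i) heights[i] = 0.0;
    for (int e = 0; e < pr.nedge; ++e)
      bl[e] = heights[pr.parent[e]] - heights[pr.child[e]];
  };

  auto obj = [&]() { computeBl(); return pr.lnl(bl); };

  double cur = obj();
  for (int cyc = 0; cyc < maxCycles; ++cyc) {
    double prev = cur;
    for (int k = 0; k < nPar; ++k) {
      double lo = (k == 0) ? 1e-8 : 1e-6;
      double hi = (k == 0) ? BL_MAX : 1.0 - 1e-6;
      double xb;
      double fb = brentMax([&](double x) {
        par[k] = x;
        return obj();
      }, lo, hi, brentTol, &xb);
      par[k] = xb;
      cur = fb;
    }
    cur = obj();
    if (cur - prev < tol) break;
  }
  computeBl();
  return List::create(_["par"] = NumericVector(par.begin(), par.end()),
                      _["bl"] = NumericVector(bl.begin(), bl.end()),
                      _["lnl"] = cur);
}
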