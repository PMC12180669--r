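// Core engines for generalized cophenetic L_p distances on rooted binary
// trees: the quadratic reference algorithm and the median-vertex
// divide-and-conquer (GetCntr / SeqPrd, the odd- and even-p single-mixed
// sweeps, and the unified recursion), plus an L-infinity (max-monoid)
// variant of the same decomposition.
//
// All power sums are evaluated either in double precision (real-valued,
// i.e. branch-length-weighted, contributions) or in exact signed
// arbitrary-precision integers (integer-valued contributions).  Exactness
// is not a luxury: the alternating binomial expansions used by SeqPrd and
// the single-mixed sweeps cancel catastrophically in 64-bit floats for
// large p, and the package contract is bit-exact agreement between the
// fast and the naive path up to at least p = 100.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <cstdlib>
#include <vector>
#include <map>
#include <string>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// BigInt: compact signed arbitrary-precision integer, base 2^32 limbs.
// Only the operations the algorithms need: + - * , small exact division
// (for binomials), powers of machine integers, decimal rendering, log.
// ---------------------------------------------------------------------------

typedef std::vector<uint32_t> Mag;

static void trimMag(Mag &a) {
  while (!a.empty() && a.back() == 0u) a.pop_back();
}

static int cmpMag(const Mag &a, const Mag &b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (size_t i = a.size(); i-- > 0;)
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  return 0;
}

static Mag addMag(const Mag &a, const Mag &b) {
  const Mag &x = a.size() >= b.size() ? a : b;
  const Mag &y = a.size() >= b.size() ? b : a;
  Mag r(x.size());
  uint64_t carry = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    uint64_t cur = carry + x[i] + (i < y.size() ? y[i] : 0u);
    r[i] = (uint32_t)cur;
    carry = cur >> 32;
  }
  if (carry) r.push_back((uint32_t)carry);
  return r;
}

// requires |a| >= |b|
static Mag subMag(const Mag &a, const Mag &b) {
  Mag r(a.size());
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t cur = (int64_t)a[i] - borrow - (i < b.size() ? (int64_t)b[i] : 0);
    if (cur < 0) { cur += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
    r[i] = (uint32_t)cur;
  }
  trimMag(r);
  return r;
}

static Mag mulMag(const Mag &a, const Mag &b) {
  if (a.empty() || b.empty()) return Mag();
  Mag r(a.size() + b.size(), 0u);
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t carry = 0;
    for (size_t j = 0; j < b.size(); ++j) {
      uint64_t cur = (uint64_t)r[i + j] + (uint64_t)a[i] * b[j] + carry;
      r[i + j] = (uint32_t)cur;
      carry = cur >> 32;
    }
    size_t k = i + b.size();
    while (carry) {
      uint64_t cur = (uint64_t)r[k] + carry;
      r[k] = (uint32_t)cur;
      carry = cur >> 32;
      ++k;
    }
  }
  trimMag(r);
  return r;
}

struct BigInt {
  int sign;  // -1, 0, +1
  Mag d;     // little-endian magnitude; empty iff sign == 0

  BigInt() : sign(0) {}
  explicit BigInt(long long v) : sign(0) {
    unsigned long long m;
    if (v < 0) { sign = -1; m = (unsigned long long)(-(v + 1)) + 1ull; }
    else if (v > 0) { sign = 1; m = (unsigned long long)v; }
    else m = 0;
    while (m) { d.push_back((uint32_t)m); m >>= 32; }
  }

  bool isZero() const { return sign == 0; }

  BigInt operator+(const BigInt &o) const {
    if (sign == 0) return o;
    if (o.sign == 0) return *this;
    BigInt r;
    if (sign == o.sign) { r.sign = sign; r.d = addMag(d, o.d); return r; }
    int c = cmpMag(d, o.d);
    if (c == 0) return BigInt();
    if (c > 0) { r.sign = sign; r.d = subMag(d, o.d); }
    else { r.sign = o.sign; r.d = subMag(o.d, d); }
    return r;
  }
  BigInt operator-() const { BigInt r(*this); r.sign = -r.sign; return r; }
  BigInt operator-(const BigInt &o) const { return *this + (-o); }
  BigInt operator*(const BigInt &o) const {
    BigInt r;
    if (sign == 0 || o.sign == 0) return r;
    r.sign = sign * o.sign;
    r.d = mulMag(d, o.d);
    return r;
  }
  BigInt &operator+=(const BigInt &o) { *this = *this + o; return *this; }
  BigInt &operator-=(const BigInt &o) { *this = *this - o; return *this; }

  // exact division by a small positive integer (used for binomials)
  BigInt divExact(uint32_t m) const {
    BigInt r(*this);
    uint64_t rem = 0;
    for (size_t i = r.d.size(); i-- > 0;) {
      uint64_t cur = (rem << 32) | r.d[i];
      r.d[i] = (uint32_t)(cur / m);
      rem = cur % m;
    }
    trimMag(r.d);
    if (r.d.empty()) r.sign = 0;
    return r;
  }

  double toDouble() const {
    double v = 0.0;
    for (size_t i = d.size(); i-- > 0;) {
      v = v * 4294967296.0 + (double)d[i];
      if (!std::isfinite(v)) return sign < 0 ? -INFINITY : INFINITY;
    }
    return sign < 0 ? -v : v;
  }

  // natural log of |value|; -inf for zero
  double logAbs() const {
    if (sign == 0) return -INFINITY;
    size_t k = d.size();
    size_t take = k < 3 ? k : 3;
    double m = 0.0;
    for (size_t i = 0; i < take; ++i)
      m = m * 4294967296.0 + (double)d[k - 1 - i];
    return std::log(m) + (double)(k - take) * 32.0 * M_LN2;
  }

  std::string toString() const {
    if (sign == 0) return "0";
    Mag tmp = d;
    std::vector<uint32_t> chunks;  // base 1e9
    while (!tmp.empty()) {
      uint64_t rem = 0;
      for (size_t i = tmp.size(); i-- > 0;) {
        uint64_t cur = (rem << 32) | tmp[i];
        tmp[i] = (uint32_t)(cur / 1000000000u);
        rem = cur % 1000000000u;
      }
      trimMag(tmp);
      chunks.push_back((uint32_t)rem);
    }
    std::string s = sign < 0 ? "-" : "";
    char buf[16];
    snprintf(buf, sizeof(buf), "%u", chunks.back());
    s += buf;
    for (size_t i = chunks.size() - 1; i-- > 0;) {
      snprintf(buf, sizeof(buf), "%09u", chunks[i]);
      s += buf;
    }
    return s;
  }
};

// ---------------------------------------------------------------------------
// Numeric policy: the algorithms are templated over Num in {double, BigInt}.
// Contribution values themselves always fit in a double / long long; only
// accumulated power sums need arbitrary precision.
// ---------------------------------------------------------------------------

template <typename Num> struct NumOps;

template <> struct NumOps<double> {
  static double zero() { return 0.0; }
  static double one() { return 1.0; }
  static double fromCount(long long c) { return (double)c; }
  static double scalar(double x) { return x; }
  static bool isZero(const double &x) { return x == 0.0; }
  static double toD(const double &x) { return x; }
  static double logAbs(const double &x) { return std::log(std::fabs(x)); }
};

template <> struct NumOps<BigInt> {
  static BigInt zero() { return BigInt(); }
  static BigInt one() { return BigInt(1); }
  static BigInt fromCount(long long c) { return BigInt(c); }
  static BigInt scalar(double x) { return BigInt((long long)llround(x)); }
  static bool isZero(const BigInt &x) { return x.isZero(); }
  static double toD(const BigInt &x) { return x.toDouble(); }
  static double logAbs(const BigInt &x) { return x.logAbs(); }
};

// powers 0..p of a contribution value
template <typename Num>
static std::vector<Num> powersOf(double x, int p) {
  std::vector<Num> r(p + 1);
  Num b = NumOps<Num>::scalar(x);
  r[0] = NumOps<Num>::one();
  for (int l = 1; l <= p; ++l) r[l] = r[l - 1] * b;
  return r;
}
template <>
std::vector<double> powersOf<double>(double x, int p) {
  std::vector<double> r(p + 1);
  r[0] = 1.0;
  for (int l = 1; l <= p; ++l) r[l] = r[l - 1] * x;
  return r;
}

template <typename Num>
static Num powNum(double x, int p) {
  Num r = NumOps<Num>::one();
  Num b = NumOps<Num>::scalar(x);
  for (int l = 0; l < p; ++l) r = r * b;
  return r;
}

// binomial coefficients C(p, i) via the multiplicative recurrence
// a_i = a_{i-1} (p - i + 1) / i  (exact in BigInt, double for real mode)
static std::vector<BigInt> binomBig(int p) {
  std::vector<BigInt> a(p + 1);
  a[0] = BigInt(1);
  for (int i = 1; i <= p; ++i)
    a[i] = (a[i - 1] * BigInt(p - i + 1)).divExact((uint32_t)i);
  return a;
}
static std::vector<double> binomDbl(int p) {
  std::vector<double> a(p + 1);
  a[0] = 1.0;
  for (int i = 1; i <= p; ++i) a[i] = a[i - 1] * (double)(p - i + 1) / (double)i;
  return a;
}
template <typename Num> static std::vector<Num> binomFor(int p);
template <> std::vector<BigInt> binomFor<BigInt>(int p) { return binomBig(p); }
template <> std::vector<double> binomFor<double>(int p) { return binomDbl(p); }

// ---------------------------------------------------------------------------
// Tree representation.  Vertices 0..nv-1; leaf[v] is a *global* leaf index
// (stable across contractions) or -1 for internal vertices.  Contribution
// values xi are stored per vertex, already normalized to the descending
// convention by the caller.
// ---------------------------------------------------------------------------

struct Tree {
  int nv = 0;
  int root = -1;
  std::vector<int> par, lft, rgh, leaf;
  std::vector<double> xi;
  std::vector<int> post;  // postorder (children before parents)
  int nLeaves = 0;

  bool isLeaf(int v) const { return leaf[v] >= 0; }
  int sibling(int v) const {
    int p = par[v];
    return lft[p] == v ? rgh[p] : lft[p];
  }

  void buildPost() {
    post.clear();
    nLeaves = 0;
    if (root < 0) return;
    std::vector<int> st;
    st.push_back(root);
    while (!st.empty()) {
      int v = st.back();
      st.pop_back();
      post.push_back(v);
      if (!isLeaf(v)) { st.push_back(lft[v]); st.push_back(rgh[v]); }
      else ++nLeaves;
    }
    std::reverse(post.begin(), post.end());
  }
};

static Tree treeFromList(const List &x) {
  Tree T;
  IntegerVector par = x["parent"], lft = x["left"], rgh = x["right"],
                leaf = x["leaf"];
  NumericVector xi = x["xi"];
  T.nv = par.size();
  T.par.assign(par.begin(), par.end());
  T.lft.assign(lft.begin(), lft.end());
  T.rgh.assign(rgh.begin(), rgh.end());
  T.leaf.assign(leaf.begin(), leaf.end());
  T.xi.assign(xi.begin(), xi.end());
  for (int v = 0; v < T.nv; ++v)
    if (T.par[v] < 0) T.root = v;
  T.buildPost();
  return T;
}

// Descent from the root toward the larger-subtree child (left on ties)
// until the subtree holds at most half of the leaves.
static int medianVertexC(const Tree &T) {
  std::vector<int> cnt(T.nv, 0);
  for (int v : T.post)
    cnt[v] = T.isLeaf(v) ? 1 : cnt[T.lft[v]] + cnt[T.rgh[v]];
  int n = cnt[T.root];
  int t = T.root;
  while (2 * cnt[t] > n) {
    int l = T.lft[t], r = T.rgh[t];
    t = cnt[l] >= cnt[r] ? l : r;
  }
  return t;
}

// median path root -> t
static std::vector<int> medianPath(const Tree &T, int t) {
  std::vector<int> path;
  for (int v = t; v >= 0; v = T.par[v]) path.push_back(v);
  std::reverse(path.begin(), path.end());
  return path;
}

// anchorVert[g] = lca(leaf g, t): the deepest median-path vertex that is an
// ancestor of the leaf.  Filled for every leaf of T.
static void computeAnchors(const Tree &T, const std::vector<int> &path,
                           std::vector<int> &anchorVert) {
  std::vector<char> onPath(T.nv, 0);
  for (int v : path) onPath[v] = 1;
  // preorder walk carrying the current anchor
  std::vector<std::pair<int, int> > st;  // (vertex, anchor)
  st.push_back(std::make_pair(T.root, T.root));
  while (!st.empty()) {
    int v = st.back().first, a = st.back().second;
    st.pop_back();
    if (onPath[v]) a = v;
    if (T.isLeaf(v)) anchorVert[T.leaf[v]] = a;
    else {
      st.push_back(std::make_pair(T.lft[v], a));
      st.push_back(std::make_pair(T.rgh[v], a));
    }
  }
}

// leaves below t (global ids) -> mask
static void lowerLeafMask(const Tree &T, int t, std::vector<char> &mask) {
  std::vector<int> st;
  st.push_back(t);
  while (!st.empty()) {
    int v = st.back();
    st.pop_back();
    if (T.isLeaf(v)) mask[T.leaf[v]] = 1;
    else { st.push_back(T.lft[v]); st.push_back(T.rgh[v]); }
  }
}

// Restriction of T to the kept leaves: induced topology with degree-2
// vertices suppressed; every surviving vertex keeps the xi value of the
// original vertex it corresponds to (the original lca of its leaf set).
static Tree contractC(const Tree &T, const std::vector<char> &keep) {
  Tree R;
  std::vector<int> map(T.nv, -1);
  for (int v : T.post) {
    if (T.isLeaf(v)) {
      if (keep[T.leaf[v]]) {
        int id = R.nv++;
        R.par.push_back(-1);
        R.lft.push_back(-1);
        R.rgh.push_back(-1);
        R.leaf.push_back(T.leaf[v]);
        R.xi.push_back(T.xi[v]);
        map[v] = id;
      }
    } else {
      int a = map[T.lft[v]], b = map[T.rgh[v]];
      if (a >= 0 && b >= 0) {
        int id = R.nv++;
        R.par.push_back(-1);
        R.lft.push_back(a);
        R.rgh.push_back(b);
        R.leaf.push_back(-1);
        R.xi.push_back(T.xi[v]);
        R.par[a] = id;
        R.par[b] = id;
        map[v] = id;
      } else {
        map[v] = a >= 0 ? a : b;
      }
    }
  }
  R.root = map[T.root];
  R.buildPost();
  return R;
}

// ---------------------------------------------------------------------------
// Naive reference: fill the per-pair lca-contribution differences by a
// direct double loop over subtree leaf lists, then accumulate |diff|^p.
// Theta(p n^2); deliberately simple.
// ---------------------------------------------------------------------------

// local leaf index mapping for dense matrices
static void localIndex(const Tree &T, std::vector<int> &glb2loc,
                       std::vector<int> &loc2glb) {
  loc2glb.clear();
  for (int v : T.post)
    if (T.isLeaf(v)) loc2glb.push_back(T.leaf[v]);
  std::sort(loc2glb.begin(), loc2glb.end());
  for (size_t i = 0; i < loc2glb.size(); ++i) glb2loc[loc2glb[i]] = (int)i;
}

// M[i*n+j] += sgn * xi(lca_T(i,j)) for all i<=j (symmetric fill)
static void accumulateLca(const Tree &T, const std::vector<int> &glb2loc,
                          int n, double sgn, std::vector<double> &M) {
  std::vector<std::vector<int> > under(T.nv);
  for (int v : T.post) {
    if (T.isLeaf(v)) {
      int i = glb2loc[T.leaf[v]];
      under[v].push_back(i);
      M[(size_t)i * n + i] += sgn * T.xi[v];
    } else {
      std::vector<int> &L = under[T.lft[v]];
      std::vector<int> &R = under[T.rgh[v]];
      for (int a : L)
        for (int b : R) {
          M[(size_t)a * n + b] += sgn * T.xi[v];
          M[(size_t)b * n + a] += sgn * T.xi[v];
        }
      under[v].swap(L);
      under[v].insert(under[v].end(), R.begin(), R.end());
      R.clear();
      R.shrink_to_fit();
    }
  }
}

template <typename Num>
static Num naivePS(const Tree &A, const Tree &B, int p, int globalN) {
  int n = A.nLeaves;
  if (n == 0) return NumOps<Num>::zero();
  std::vector<int> glb2loc(globalN, -1), loc2glb;
  localIndex(A, glb2loc, loc2glb);
  std::vector<double> M((size_t)n * n, 0.0);
  accumulateLca(A, glb2loc, n, 1.0, M);
  accumulateLca(B, glb2loc, n, -1.0, M);
  Num tot = NumOps<Num>::zero();
  // group identical |diff| values so exact powers are computed once each
  std::map<double, long long> cnt;
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) cnt[std::fabs(M[(size_t)i * n + j])] += 1;
  for (std::map<double, long long>::const_iterator it = cnt.begin();
       it != cnt.end(); ++it) {
    if (it->first == 0.0) continue;
    tot += powNum<Num>(it->first, p) * NumOps<Num>::fromCount(it->second);
  }
  return tot;
}

static double naiveMax(const Tree &A, const Tree &B, int globalN) {
  int n = A.nLeaves;
  if (n == 0) return -INFINITY;
  std::vector<int> glb2loc(globalN, -1), loc2glb;
  localIndex(A, glb2loc, loc2glb);
  std::vector<double> M((size_t)n * n, 0.0);
  accumulateLca(A, glb2loc, n, 1.0, M);
  accumulateLca(B, glb2loc, n, -1.0, M);
  double mx = -INFINITY;
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      mx = std::max(mx, std::fabs(M[(size_t)i * n + j]));
  return mx;
}

// ---------------------------------------------------------------------------
// SeqPrd: sum_{i,j} |alpha_i - beta_j|^p for sorted
// sequences, via streaming prefix power sums and a binomial expansion.
// ---------------------------------------------------------------------------

template <typename Num>
static Num seqPrdT(int p, std::vector<double> a, std::vector<double> b,
                   const std::vector<Num> &binom) {
  if (a.empty() || b.empty()) return NumOps<Num>::zero();
  if (a.back() > b.back()) std::swap(a, b);
  int k = (int)a.size(), m = (int)b.size();
  std::vector<std::vector<Num> > sig(m);
  {
    std::vector<Num> run(p + 1, NumOps<Num>::zero());
    int i = 0;
    for (int j = 0; j < m; ++j) {
      while (i < k && a[i] <= b[j]) {
        std::vector<Num> pw = powersOf<Num>(a[i], p);
        for (int l = 0; l <= p; ++l) run[l] += pw[l];
        ++i;
      }
      sig[j] = run;
    }
  }
  const std::vector<Num> &sigAll = sig[m - 1];
  Num tot = NumOps<Num>::zero();
  for (int j = 0; j < m; ++j) {
    std::vector<Num> bp = powersOf<Num>(b[j], p);
    for (int l = 0; l <= p; ++l) {
      Num term = binom[l] * (bp[l] * sig[j][p - l] +
                             bp[p - l] * (sigAll[l] - sig[j][l]));
      if ((p - l) % 2) tot -= term; else tot += term;
    }
  }
  return tot;
}

// ---------------------------------------------------------------------------
// GetCntr: contribution values xi(lca(x, t)) for x in X,
// emitted in median-path order (root -> t), hence non-decreasing for a
// descending contribution.
// ---------------------------------------------------------------------------

static std::vector<double> getCntrC(const Tree &T, const std::vector<int> &path,
                                    const std::vector<int> &anchorVert,
                                    const std::vector<char> &X) {
  std::vector<int> pos(T.nv, -1);
  for (size_t i = 0; i < path.size(); ++i) pos[path[i]] = (int)i;
  std::vector<long long> c(path.size(), 0);
  for (int v : T.post)
    if (T.isLeaf(v) && X[T.leaf[v]]) c[pos[anchorVert[T.leaf[v]]]] += 1;
  std::vector<double> gamma;
  for (size_t i = 0; i < path.size(); ++i)
    for (long long r = 0; r < c[i]; ++r) gamma.push_back(T.xi[path[i]]);
  return gamma;
}

// ---------------------------------------------------------------------------
// Single-mixed sweep over one tree G (upper part: r = root, stop at the
// median vertex; lower part: r = median vertex).  X1 is the x-leaf set
// (contributes beta power sums), Ym the y-leaf set (counted in siblings),
// beta[g] = xi'(lca_{G'}(x, t')) computed on the partner tree.
// Odd p uses the sigma+/sigma-/delta machinery with the binary search over
// the sorted ancestor array; even p uses the single-sigma sweep.
// ---------------------------------------------------------------------------

struct EffSubtree {
  std::vector<int> order;   // postorder of effective subtree
  std::vector<char> inEff;  // vertex included
};

static EffSubtree effSubtree(const Tree &T, int r, int stopv) {
  EffSubtree E;
  E.inEff.assign(T.nv, 0);
  std::vector<int> st;
  st.push_back(r);
  while (!st.empty()) {
    int v = st.back();
    st.pop_back();
    E.order.push_back(v);
    E.inEff[v] = 1;
    if (!T.isLeaf(v) && v != stopv) {
      st.push_back(T.lft[v]);
      st.push_back(T.rgh[v]);
    }
  }
  std::reverse(E.order.begin(), E.order.end());
  return E;
}

template <typename Num>
static Num singleMixedT(const Tree &T, int r, int stopv,
                        const std::vector<char> &X1,
                        const std::vector<char> &Ym,
                        const std::vector<double> &beta, int p,
                        const std::vector<Num> &binom) {
  EffSubtree E = effSubtree(T, r, stopv);
  if (E.order.size() <= 1) return NumOps<Num>::zero();
  std::vector<long long> ycnt(T.nv, 0);
  for (int v : E.order) {
    bool effLeaf = T.isLeaf(v) || v == stopv;
    if (effLeaf)
      ycnt[v] = (T.isLeaf(v) && Ym[T.leaf[v]]) ? 1 : 0;
    else
      ycnt[v] = ycnt[T.lft[v]] + ycnt[T.rgh[v]];
  }

  bool oddp = (p % 2) == 1;
  std::vector<std::vector<Num> > sigP(T.nv), sigM(T.nv), del(T.nv);
  std::vector<Num> zeroVec(p + 1, NumOps<Num>::zero());

  if (oddp) {
    // preprocessing: DFS from r keeping the (sorted) root-to-vertex path,
    // binary search for omega_x = the ancestor closest to r with
    // xi(w) >= x.beta
    std::vector<int> pathv;
    std::vector<double> pathxi;
    // explicit DFS with enter/exit events
    std::vector<std::pair<int, int> > st;  // (vertex, state 0=enter,1=exit)
    st.push_back(std::make_pair(r, 0));
    while (!st.empty()) {
      int v = st.back().first, state = st.back().second;
      st.pop_back();
      if (state == 1) { pathv.pop_back(); pathxi.pop_back(); continue; }
      pathv.push_back(v);
      pathxi.push_back(T.xi[v]);
      st.push_back(std::make_pair(v, 1));
      bool effLeaf = T.isLeaf(v) || v == stopv;
      if (effLeaf) {
        if (T.isLeaf(v) && X1[T.leaf[v]]) {
          double b = beta[T.leaf[v]];
          if (b <= T.xi[v]) {
            // first path position with xi >= b (path xi non-decreasing)
            size_t lo = std::lower_bound(pathxi.begin(), pathxi.end(), b) -
                        pathxi.begin();
            int w = pathv[lo];
            if (del[w].empty()) del[w] = zeroVec;
            std::vector<Num> pw = powersOf<Num>(b, p);
            for (int l = 0; l <= p; ++l) del[w][l] += pw[l];
          }
          if (v != r) {
            if (b <= T.xi[T.par[v]]) sigP[v] = powersOf<Num>(b, p);
            else sigM[v] = powersOf<Num>(b, p);
          }
        }
      } else {
        st.push_back(std::make_pair(T.lft[v], 0));
        st.push_back(std::make_pair(T.rgh[v], 0));
      }
    }
  } else {
    for (int v : E.order) {
      bool effLeaf = T.isLeaf(v) || v == stopv;
      if (effLeaf && T.isLeaf(v) && X1[T.leaf[v]])
        sigP[v] = powersOf<Num>(beta[T.leaf[v]], p);
    }
  }

  Num tot = NumOps<Num>::zero();
  for (int v : E.order) {
    bool effLeaf = T.isLeaf(v) || v == stopv;
    if (!effLeaf) {
      int a = T.lft[v], b = T.rgh[v];
      // sigma_v = sigma_lft + sigma_rgh (- delta for +, + delta for -)
      std::vector<Num> sp = sigP[a].empty() ? zeroVec : sigP[a];
      if (!sigP[b].empty())
        for (int l = 0; l <= p; ++l) sp[l] += sigP[b][l];
      if (oddp) {
        std::vector<Num> sm = sigM[a].empty() ? zeroVec : sigM[a];
        if (!sigM[b].empty())
          for (int l = 0; l <= p; ++l) sm[l] += sigM[b][l];
        if (!del[v].empty())
          for (int l = 0; l <= p; ++l) { sp[l] -= del[v][l]; sm[l] += del[v][l]; }
        sigM[v] = sm;
      }
      sigP[v] = sp;
      sigM[a].clear(); sigM[b].clear();
      // children sigma+ no longer needed after combination
      sigP[a].clear(); sigP[b].clear();
    }
    if (v != r) {
      long long y = ycnt[T.sibling(v)];
      bool haveP = !sigP[v].empty();
      bool haveM = oddp && !sigM[v].empty();
      // entry 0 of each power vector is the element count: skip empty sets
      bool any = (haveP && !NumOps<Num>::isZero(sigP[v][0])) ||
                 (haveM && !NumOps<Num>::isZero(sigM[v][0]));
      if (y > 0 && any) {
        std::vector<Num> pp = powersOf<Num>(T.xi[T.par[v]], p);
        Num s = NumOps<Num>::zero();
        for (int l = 0; l <= p; ++l) {
          Num spv = haveP ? sigP[v][p - l] : NumOps<Num>::zero();
          Num term;
          if (oddp) {
            Num sm = haveM ? sigM[v][l] : NumOps<Num>::zero();
            term = binom[l] * (pp[l] * spv + pp[p - l] * sm);
          } else {
            term = binom[l] * (pp[p - l] * (haveP ? sigP[v][l]
                                                  : NumOps<Num>::zero()));
          }
          if ((p - l) % 2) s -= term; else s += term;
        }
        tot += s * NumOps<Num>::fromCount(y);
      }
    }
  }
  return tot;
}

// L-infinity single-mixed: max |xi(v.parent) - beta| via min/max of beta
// over X1 leaves in each subtree.
static double singleMixedMax(const Tree &T, int r, int stopv,
                             const std::vector<char> &X1,
                             const std::vector<char> &Ym,
                             const std::vector<double> &beta) {
  EffSubtree E = effSubtree(T, r, stopv);
  if (E.order.size() <= 1) return -INFINITY;
  std::vector<long long> ycnt(T.nv, 0);
  std::vector<double> mn(T.nv, INFINITY), mx(T.nv, -INFINITY);
  for (int v : E.order) {
    bool effLeaf = T.isLeaf(v) || v == stopv;
    if (effLeaf) {
      ycnt[v] = (T.isLeaf(v) && Ym[T.leaf[v]]) ? 1 : 0;
      if (T.isLeaf(v) && X1[T.leaf[v]]) mn[v] = mx[v] = beta[T.leaf[v]];
    } else {
      int a = T.lft[v], b = T.rgh[v];
      ycnt[v] = ycnt[a] + ycnt[b];
      mn[v] = std::min(mn[a], mn[b]);
      mx[v] = std::max(mx[a], mx[b]);
    }
  }
  double tot = -INFINITY;
  for (int v : E.order) {
    if (v != r && ycnt[T.sibling(v)] > 0 && mn[v] <= mx[v]) {
      double xp = T.xi[T.par[v]];
      tot = std::max(tot, std::max(xp - mn[v], mx[v] - xp));
    }
  }
  return tot;
}

// ---------------------------------------------------------------------------
// Partial-distance assembly and the unified divide-and-conquer recursion.
// ---------------------------------------------------------------------------

struct SplitInfo {
  int t;
  std::vector<int> path;
  std::vector<int> anchorVert;  // by global leaf id
  std::vector<char> inB;        // by global leaf id
};

static SplitInfo makeSplit(const Tree &T, int globalN) {
  SplitInfo S;
  S.t = medianVertexC(T);
  S.path = medianPath(T, S.t);
  S.anchorVert.assign(globalN, -1);
  computeAnchors(T, S.path, S.anchorVert);
  S.inB.assign(globalN, 0);
  lowerLeafMask(T, S.t, S.inB);
  return S;
}

struct Masks {
  std::vector<char> cAA, cAB, cBA, cBB;  // x in A/B (tree 1) x A'/B' (tree 2)
  long long nAA = 0, nAB = 0, nBA = 0, nBB = 0;
};

static Masks makeMasks(const Tree &A, const SplitInfo &S1, const SplitInfo &S2,
                       int globalN) {
  Masks M;
  M.cAA.assign(globalN, 0);
  M.cAB.assign(globalN, 0);
  M.cBA.assign(globalN, 0);
  M.cBB.assign(globalN, 0);
  for (int v : A.post) {
    if (!A.isLeaf(v)) continue;
    int g = A.leaf[v];
    bool b1 = S1.inB[g], b2 = S2.inB[g];
    if (!b1 && !b2) { M.cAA[g] = 1; ++M.nAA; }
    else if (!b1 && b2) { M.cAB[g] = 1; ++M.nAB; }
    else if (b1 && !b2) { M.cBA[g] = 1; ++M.nBA; }
    else { M.cBB[g] = 1; ++M.nBB; }
  }
  return M;
}

template <typename Num>
static Num alignedPartialT(const Tree &A, const Tree &B, const SplitInfo &S1,
                           const SplitInfo &S2, const Masks &M, int p) {
  if (M.nBB == 0 || M.nAA == 0) return NumOps<Num>::zero();
  Num s = NumOps<Num>::zero();
  for (int v : A.post) {
    if (!A.isLeaf(v)) continue;
    int g = A.leaf[v];
    if (!M.cAA[g]) continue;
    double d = std::fabs(A.xi[S1.anchorVert[g]] - B.xi[S2.anchorVert[g]]);
    s += powNum<Num>(d, p);
  }
  return s * NumOps<Num>::fromCount(M.nBB);
}

static double alignedPartialMax(const Tree &A, const Tree &B,
                                const SplitInfo &S1, const SplitInfo &S2,
                                const Masks &M) {
  if (M.nBB == 0 || M.nAA == 0) return -INFINITY;
  double mx = -INFINITY;
  for (int v : A.post) {
    if (!A.isLeaf(v)) continue;
    int g = A.leaf[v];
    if (!M.cAA[g]) continue;
    mx = std::max(mx,
                  std::fabs(A.xi[S1.anchorVert[g]] - B.xi[S2.anchorVert[g]]));
  }
  return mx;
}

template <typename Num>
static Num diagTerm(const Tree &A, const Tree &B, int p) {
  // single shared leaf: only the diagonal pair remains
  int va = A.post[0], vb = B.post[0];
  for (int v : A.post) if (A.isLeaf(v)) va = v;
  for (int v : B.post) if (B.isLeaf(v)) vb = v;
  return powNum<Num>(std::fabs(A.xi[va] - B.xi[vb]), p);
}

template <typename Num>
static Num partDistT(const Tree &A, const Tree &B, int p,
                     const std::vector<Num> &binom, int thresh, int globalN) {
  int n = A.nLeaves;
  if (n == 0) return NumOps<Num>::zero();
  if (n == 1) return diagTerm<Num>(A, B, p);
  if (n <= thresh) return naivePS<Num>(A, B, p, globalN);

  SplitInfo S1 = makeSplit(A, globalN), S2 = makeSplit(B, globalN);
  Masks M = makeMasks(A, S1, S2, globalN);

  Num s = NumOps<Num>::zero();

  // non-mixed: contract both trees to each cell and recurse
  const std::vector<char> *cells[4] = {&M.cAA, &M.cAB, &M.cBA, &M.cBB};
  for (int c = 0; c < 4; ++c) {
    Tree CA = contractC(A, *cells[c]);
    Tree CB = contractC(B, *cells[c]);
    s += partDistT<Num>(CA, CB, p, binom, thresh, globalN);
  }

  // double-mixed aligned (AB|A'B'): one anchored sum scaled by |B n B'|
  s += alignedPartialT<Num>(A, B, S1, S2, M, p);

  // double-mixed crossed (AB|B'A'), GetCntr + SeqPrd
  {
    std::vector<double> g1 = getCntrC(A, S1.path, S1.anchorVert, M.cAB);
    std::vector<double> g2 = getCntrC(B, S2.path, S2.anchorVert, M.cBA);
    s += seqPrdT<Num>(p, g1, g2, binom);
  }

  // beta arrays: anchor contribution on the partner tree
  std::vector<double> beta2(globalN, 0.0), beta1(globalN, 0.0);
  for (int v : A.post)
    if (A.isLeaf(v)) {
      int g = A.leaf[v];
      beta1[g] = A.xi[S1.anchorVert[g]];
      beta2[g] = B.xi[S2.anchorVert[g]];
    }

  // single-mixed, all four categories
  s += singleMixedT<Num>(A, A.root, S1.t, M.cAA, M.cAB, beta2, p, binom);  // AA|A'B'
  s += singleMixedT<Num>(A, S1.t, -1, M.cBA, M.cBB, beta2, p, binom);      // BB|A'B'
  s += singleMixedT<Num>(B, B.root, S2.t, M.cAA, M.cBA, beta1, p, binom);  // AB|A'A' (swapped)
  s += singleMixedT<Num>(B, S2.t, -1, M.cAB, M.cBB, beta1, p, binom);      // AB|B'B' (swapped)

  return s;
}

static double partDistMax(const Tree &A, const Tree &B, int thresh,
                          int globalN) {
  int n = A.nLeaves;
  if (n == 0) return -INFINITY;
  if (n == 1) {
    int va = -1, vb = -1;
    for (int v : A.post) if (A.isLeaf(v)) va = v;
    for (int v : B.post) if (B.isLeaf(v)) vb = v;
    return std::fabs(A.xi[va] - B.xi[vb]);
  }
  if (n <= thresh) return naiveMax(A, B, globalN);

  SplitInfo S1 = makeSplit(A, globalN), S2 = makeSplit(B, globalN);
  Masks M = makeMasks(A, S1, S2, globalN);

  double s = -INFINITY;
  const std::vector<char> *cells[4] = {&M.cAA, &M.cAB, &M.cBA, &M.cBB};
  for (int c = 0; c < 4; ++c) {
    Tree CA = contractC(A, *cells[c]);
    Tree CB = contractC(B, *cells[c]);
    s = std::max(s, partDistMax(CA, CB, thresh, globalN));
  }

  s = std::max(s, alignedPartialMax(A, B, S1, S2, M));
  {
    std::vector<double> g1 = getCntrC(A, S1.path, S1.anchorVert, M.cAB);
    std::vector<double> g2 = getCntrC(B, S2.path, S2.anchorVert, M.cBA);
    if (!g1.empty() && !g2.empty()) {
      s = std::max(s, std::fabs(g1.front() - g2.back()));
      s = std::max(s, std::fabs(g1.back() - g2.front()));
    }
  }
  std::vector<double> beta2(globalN, 0.0), beta1(globalN, 0.0);
  for (int v : A.post)
    if (A.isLeaf(v)) {
      int g = A.leaf[v];
      beta1[g] = A.xi[S1.anchorVert[g]];
      beta2[g] = B.xi[S2.anchorVert[g]];
    }
  s = std::max(s, singleMixedMax(A, A.root, S1.t, M.cAA, M.cAB, beta2));
  s = std::max(s, singleMixedMax(A, S1.t, -1, M.cBA, M.cBB, beta2));
  s = std::max(s, singleMixedMax(B, B.root, S2.t, M.cAA, M.cBA, beta1));
  s = std::max(s, singleMixedMax(B, S2.t, -1, M.cAB, M.cBB, beta1));
  return s;
}

// ---------------------------------------------------------------------------
// Rcpp interface
// ---------------------------------------------------------------------------

template <typename Num>
static List resultList(const Num &ps) {
  double v = NumOps<Num>::toD(ps);
  double lg = NumOps<Num>::logAbs(ps);
  return List::create(_["value"] = v, _["log"] = lg);
}

// [[Rcpp::export(name = ".cppCophDist")]]
List cppCophDist(List tree1, List tree2, int p, bool integerMode,
                 int baseThreshold, int globalN) {
  Tree A = treeFromList(tree1), B = treeFromList(tree2);
  if (integerMode) {
    std::vector<BigInt> binom = binomBig(p);
    BigInt ps = partDistT<BigInt>(A, B, p, binom, baseThreshold, globalN);
    List r = resultList(ps);
    r["exact"] = ps.toString();
    return r;
  } else {
    std::vector<double> binom = binomDbl(p);
    double ps = partDistT<double>(A, B, p, binom, baseThreshold, globalN);
    List r = resultList(ps);
    r["exact"] = R_NilValue;
    return r;
  }
}

// [[Rcpp::export(name = ".cppCophDistInf")]]
double cppCophDistInf(List tree1, List tree2, int baseThreshold, int globalN) {
  Tree A = treeFromList(tree1), B = treeFromList(tree2);
  return partDistMax(A, B, baseThreshold, globalN);
}

// [[Rcpp::export(name = ".cppNaiveDist")]]
List cppNaiveDist(List tree1, List tree2, int p, bool integerMode,
                  int globalN) {
  Tree A = treeFromList(tree1), B = treeFromList(tree2);
  if (integerMode) {
    BigInt ps = naivePS<BigInt>(A, B, p, globalN);
    List r = resultList(ps);
    r["exact"] = ps.toString();
    return r;
  } else {
    double ps = naivePS<double>(A, B, p, globalN);
    List r = resultList(ps);
    r["exact"] = R_NilValue;
    return r;
  }
}

// [[Rcpp::export(name = ".cppNaiveDistInf")]]
double cppNaiveDistInf(List tree1, List tree2, int globalN) {
  Tree A = treeFromList(tree1), B = treeFromList(tree2);
  return naiveMax(A, B, globalN);
}

// [[Rcpp::export(name = ".cppSeqPrd")]]
List cppSeqPrd(NumericVector alpha, NumericVector beta, int p,
               bool integerMode) {
  std::vector<double> a(alpha.begin(), alpha.end()),
      b(beta.begin(), beta.end());
  if (integerMode) {
    std::vector<BigInt> binom = binomBig(p);
    BigInt s = seqPrdT<BigInt>(p, a, b, binom);
    List r = resultList(s);
    r["exact"] = s.toString();
    return r;
  } else {
    std::vector<double> binom = binomDbl(p);
    double s = seqPrdT<double>(p, a, b, binom);
    List r = resultList(s);
    r["exact"] = R_NilValue;
    return r;
  }
}

// [[Rcpp::export(name = ".cppMedianVertex")]]
int cppMedianVertex(List tree) {
  Tree T = treeFromList(tree);
  return medianVertexC(T);  // 0-based vertex index
}

// [[Rcpp::export(name = ".cppContract")]]
List cppContract(List tree, LogicalVector keepMask) {
  Tree T = treeFromList(tree);
  std::vector<char> keep(keepMask.size());
  for (int i = 0; i < keepMask.size(); ++i) keep[i] = keepMask[i] ? 1 : 0;
  Tree R = contractC(T, keep);
  return List::create(
      _["parent"] = IntegerVector(R.par.begin(), R.par.end()),
      _["left"] = IntegerVector(R.lft.begin(), R.lft.end()),
      _["right"] = IntegerVector(R.rgh.begin(), R.rgh.end()),
      _["leaf"] = IntegerVector(R.leaf.begin(), R.leaf.end()),
      _["xi"] = NumericVector(R.xi.begin(), R.xi.end()));
}

// [[Rcpp::export(name = ".cppBinom")]]
CharacterVector cppBinom(int p) {
  std::vector<BigInt> a = binomBig(p);
  CharacterVector out(p + 1);
  for (int i = 0; i <= p; ++i) out[i] = a[i].toString();
  return out;
}

// L-infinity analogue of the above: the ten partial maxima.
// [[Rcpp::export(name = ".cppTopPartialsInf")]]
NumericVector cppTopPartialsInf(List tree1, List tree2, int globalN) {
  Tree A = treeFromList(tree1), B = treeFromList(tree2);
  SplitInfo S1 = makeSplit(A, globalN), S2 = makeSplit(B, globalN);
  Masks M = makeMasks(A, S1, S2, globalN);
  NumericVector out(10);
  out.names() = CharacterVector::create("N1", "N2", "N3", "N4", "S1", "S2",
                                        "S3", "S4", "D1", "D2");
  const std::vector<char> *cells[4] = {&M.cAA, &M.cAB, &M.cBA, &M.cBB};
  const char *nNames[4] = {"N1", "N2", "N3", "N4"};
  for (int c = 0; c < 4; ++c) {
    Tree CA = contractC(A, *cells[c]);
    Tree CB = contractC(B, *cells[c]);
    out[nNames[c]] = naiveMax(CA, CB, globalN);
  }
  out["D1"] = alignedPartialMax(A, B, S1, S2, M);
  {
    std::vector<double> g1 = getCntrC(A, S1.path, S1.anchorVert, M.cAB);
    std::vector<double> g2 = getCntrC(B, S2.path, S2.anchorVert, M.cBA);
    double mx = -INFINITY;
    if (!g1.empty() && !g2.empty()) {
      mx = std::max(std::fabs(g1.front() - g2.back()),
                    std::fabs(g1.back() - g2.front()));
    }
    out["D2"] = mx;
  }
  std::vector<double> beta2(globalN, 0.0), beta1(globalN, 0.0);
  for (int v : A.post)
    if (A.isLeaf(v)) {
      int g = A.leaf[v];
      beta1[g] = A.xi[S1.anchorVert[g]];
      beta2[g] = B.xi[S2.anchorVert[g]];
    }
  out["S3"] = singleMixedMax(A, A.root, S1.t, M.cAA, M.cAB, beta2);
  out["S4"] = singleMixedMax(A, S1.t, -1, M.cBA, M.cBB, beta2);
  out["S1"] = singleMixedMax(B, B.root, S2.t, M.cAA, M.cBA, beta1);
  out["S2"] = singleMixedMax(B, S2.t, -1, M.cAB, M.cBB, beta1);
  return out;
}

// Top-level partial distances for the ten categories, for component-level
// validation against restricted oracles.  Non-mixed partials are computed
// by the naive sum on the contracted trees (the recursion's first step),
// mixed partials by the fast routines.
// [[Rcpp::export(name = ".cppTopPartials")]]
NumericVector cppTopPartials(List tree1, List tree2, int p, bool integerMode,
                             int globalN) {
  Tree A = treeFromList(tree1), B = treeFromList(tree2);
  SplitInfo S1 = makeSplit(A, globalN), S2 = makeSplit(B, globalN);
  Masks M = makeMasks(A, S1, S2, globalN);
  NumericVector out(10);
  out.names() = CharacterVector::create("N1", "N2", "N3", "N4", "S1", "S2",
                                        "S3", "S4", "D1", "D2");
  const std::vector<char> *cells[4] = {&M.cAA, &M.cAB, &M.cBA, &M.cBB};
  // N1 = AA|A'A', N2 = AA|B'B', N3 = BB|A'A', N4 = BB|B'B'
  int cellOfN[4] = {0, 1, 2, 3};
  const char *nNames[4] = {"N1", "N2", "N3", "N4"};
  std::vector<double> beta2(globalN, 0.0), beta1(globalN, 0.0);
  for (int v : A.post)
    if (A.isLeaf(v)) {
      int g = A.leaf[v];
      beta1[g] = A.xi[S1.anchorVert[g]];
      beta2[g] = B.xi[S2.anchorVert[g]];
    }
  if (integerMode) {
    std::vector<BigInt> binom = binomBig(p);
    for (int c = 0; c < 4; ++c) {
      Tree CA = contractC(A, *cells[cellOfN[c]]);
      Tree CB = contractC(B, *cells[cellOfN[c]]);
      out[nNames[c]] = NumOps<BigInt>::toD(naivePS<BigInt>(CA, CB, p, globalN));
    }
    out["D1"] = NumOps<BigInt>::toD(alignedPartialT<BigInt>(A, B, S1, S2, M, p));
    {
      std::vector<double> g1 = getCntrC(A, S1.path, S1.anchorVert, M.cAB);
      std::vector<double> g2 = getCntrC(B, S2.path, S2.anchorVert, M.cBA);
      out["D2"] = NumOps<BigInt>::toD(seqPrdT<BigInt>(p, g1, g2, binom));
    }
    out["S3"] = NumOps<BigInt>::toD(
        singleMixedT<BigInt>(A, A.root, S1.t, M.cAA, M.cAB, beta2, p, binom));
    out["S4"] = NumOps<BigInt>::toD(
        singleMixedT<BigInt>(A, S1.t, -1, M.cBA, M.cBB, beta2, p, binom));
    out["S1"] = NumOps<BigInt>::toD(
        singleMixedT<BigInt>(B, B.root, S2.t, M.cAA, M.cBA, beta1, p, binom));
    out["S2"] = NumOps<BigInt>::toD(
        singleMixedT<BigInt>(B, S2.t, -1, M.cAB, M.cBB, beta1, p, binom));
  } else {
    std::vector<double> binom = binomDbl(p);
    for (int c = 0; c < 4; ++c) {
      Tree CA = contractC(A, *cells[cellOfN[c]]);
      Tree CB = contractC(B, *cells[cellOfN[c]]);
      out[nNames[c]] = naivePS<double>(CA, CB, p, globalN);
    }
    out["D1"] = alignedPartialT<double>(A, B, S1, S2, M, p);
    {
      std::vector<double> g1 = getCntrC(A, S1.path, S1.anchorVert, M.cAB);
      std::vector<double> g2 = getCntrC(B, S2.path, S2.anchorVert, M.cBA);
      out["D2"] = seqPrdT<double>(p, g1, g2, binom);
    }
    out["S3"] = singleMixedT<double>(A, A.root, S1.t, M.cAA, M.cAB, beta2, p, binom);
    out["S4"] = singleMixedT<double>(A, S1.t, -1, M.cBA, M.cBB, beta2, p, binom);
    out["S1"] = singleMixedT<double>(B, B.root, S2.t, M.cAA, M.cBA, beta1, p, binom);
    out["S2"] = singleMixedT<double>(B, S2.t, -1, M.cAB, M.cBB, beta1, p, binom);
  }
  return out;
}
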