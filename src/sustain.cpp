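#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Piecewise-linear trajectory and marginal stage likelihoods for the
// Z-score event-sequence model.  Stage k (k = 0..N) occupies [k, k+1] on
// the [0, N+1] model timeline; the stage integral is approximated by a
// midpoint evaluation at t = k + 0.5.

static const double LOG_2PI = 1.8378770664093454836;

// g_i(t) for all biomarkers at the N+1 stage midpoints.
// positions: length-N, positions[e] = 1-based timeline position of event e
// eventBio:  length-N, 0-based biomarker index of event e
// eventZ:    length-N, Z-score threshold of event e
// Returns I x (N+1) matrix, column k = stage k midpoint t = k + 0.5.
static void traj_matrix(const std::vector<int> &positions,
                        const IntegerVector &eventBio,
                        const NumericVector &eventZ,
                        const NumericVector &zmax,
                        int I, int N,
                        std::vector<double> &G) {
  // anchors per biomarker: (0,0), (p_r, z_r) sorted by position, (N+1, zmax)
  std::vector<std::vector<std::pair<int, double>>> anchors(I);
  for (int e = 0; e < N; ++e)
    anchors[eventBio[e]].push_back(std::make_pair(positions[e], eventZ[e]));
  for (int i = 0; i < I; ++i) {
    std::sort(anchors[i].begin(), anchors[i].end());
    // walk the stage midpoints through the anchor segments
    size_t seg = 0;
    double t0 = 0.0, z0 = 0.0;
    double t1, z1;
    if (anchors[i].empty()) {
      t1 = N + 1.0; z1 = zmax[i];
    } else {
      t1 = anchors[i][0].first; z1 = anchors[i][0].second;
    }
    for (int k = 0; k <= N; ++k) {
      double t = k + 0.5;
      while (t > t1 && seg <= anchors[i].size()) {
        ++seg;
        t0 = t1; z0 = z1;
        if (seg < anchors[i].size()) {
          t1 = anchors[i][seg].first; z1 = anchors[i][seg].second;
        } else {
          t1 = N + 1.0; z1 = zmax[i];
        }
      }
      G[i + (size_t)k * I] = z0 + (z1 - z0) * (t - t0) / (t1 - t0);
    }
  }
}

// [[Rcpp::export(name = ".cppTrajMatrix")]]
NumericMatrix cppTrajMatrix(IntegerVector positions, IntegerVector eventBio,
                            NumericVector eventZ, NumericVector zmax) {
  int N = positions.size();
  int I = zmax.size();
  std::vector<int> pos(N);
  for (int e = 0; e < N; ++e) pos[e] = positions[e];
  std::vector<double> G((size_t)I * (N + 1));
  traj_matrix(pos, eventBio, eventZ, zmax, I, N, G);
  NumericMatrix out(I, N + 1);
  std::copy(G.begin(), G.end(), out.begin());
  return out;
}

// Per-subject, per-stage log likelihood for one sequence.
// X: J x I with NA = missing; logu[i] = log uniform density for biomarker i
// (used for missing entries when useUniform, otherwise missing is an error
// caught on the R side).  Returns J x (N+1).
static void stage_loglik(const NumericMatrix &X,
                         const std::vector<double> &G,
                         const NumericVector &sigma,
                         const NumericVector &logu,
                         int N, NumericMatrix &S) {
  int J = X.nrow(), I = X.ncol();
  std::vector<double> logsig(I), inv2s2(I);
  for (int i = 0; i < I; ++i) {
    logsig[i] = std::log(sigma[i]);
    inv2s2[i] = 0.5 / (sigma[i] * sigma[i]);
  }
  for (int j = 0; j < J; ++j) {
    double missConst = 0.0;
    for (int i = 0; i < I; ++i)
      if (NumericMatrix::is_na(X(j, i))) missConst += logu[i];
    for (int k = 0; k <= N; ++k) {
      double s = missConst;
      for (int i = 0; i < I; ++i) {
        double x = X(j, i);
        if (!NumericMatrix::is_na(x)) {
          double d = x - G[i + (size_t)k * I];
          s += -0.5 * LOG_2PI - logsig[i] - d * d * inv2s2[i];
        }
      }
      S(j, k) = s;
    }
  }
}

// [[Rcpp::export(name = ".cppStageLogLik")]]
NumericMatrix cppStageLogLik(NumericMatrix X, IntegerVector positions,
                             IntegerVector eventBio, NumericVector eventZ,
                             NumericVector zmax, NumericVector sigma,
                             NumericVector logu) {
  int N = positions.size();
  int I = zmax.size();
  std::vector<int> pos(N);
  for (int e = 0; e < N; ++e) pos[e] = positions[e];
  std::vector<double> G((size_t)I * (N + 1));
  traj_matrix(pos, eventBio, eventZ, zmax, I, N, G);
  NumericMatrix S(X.nrow(), N + 1);
  stage_loglik(X, G, sigma, logu, N, S);
  return S;
}

// weighted marginal log likelihood of one sequence:
//   sum_j w_j * logsumexp_k(logPrior_k + S_jk)
static double seq_loglik(const NumericMatrix &X,
                         const std::vector<int> &positions,
                         const IntegerVector &eventBio,
                         const NumericVector &eventZ,
                         const NumericVector &zmax,
                         const NumericVector &sigma,
                         const NumericVector &logu,
                         const NumericVector &logPrior,
                         const NumericVector &w) {
  int J = X.nrow(), I = X.ncol(), N = positions.size();
  std::vector<double> G((size_t)I * (N + 1));
  traj_matrix(positions, eventBio, eventZ, zmax, I, N, G);
  std::vector<double> logsig(I), inv2s2(I);
  for (int i = 0; i < I; ++i) {
    logsig[i] = std::log(sigma[i]);
    inv2s2[i] = 0.5 / (sigma[i] * sigma[i]);
  }
  double total = 0.0;
  std::vector<double> sk(N + 1);
  for (int j = 0; j < J; ++j) {
    if (w[j] == 0.0) continue;
    double missConst = 0.0;
    for (int i = 0; i < I; ++i)
      if (NumericMatrix::is_na(X(j, i))) missConst += logu[i];
    double m = R_NegInf;
    for (int k = 0; k <= N; ++k) {
      double s = missConst + logPrior[k];
      for (int i = 0; i < I; ++i) {
        double x = X(j, i);
        if (!NumericMatrix::is_na(x)) {
          double d = x - G[i + (size_t)k * I];
          s += -0.5 * LOG_2PI - logsig[i] - d * d * inv2s2[i];
        }
      }
      sk[k] = s;
      if (s > m) m = s;
    }
    double acc = 0.0;
    for (int k = 0; k <= N; ++k) acc += std::exp(sk[k] - m);
    total += w[j] * (m + std::log(acc));
  }
  return total;
}

// [[Rcpp::export(name = ".cppSeqLogLik")]]
double cppSeqLogLik(NumericMatrix X, IntegerVector positions,
                    IntegerVector eventBio, NumericVector eventZ,
                    NumericVector zmax, NumericVector sigma,
                    NumericVector logu, NumericVector logPrior,
                    NumericVector w) {
  int N = positions.size();
  std::vector<int> pos(N);
  for (int e = 0; e < N; ++e) pos[e] = positions[e];
  return seq_loglik(X, pos, eventBio, eventZ, zmax, sigma, logu, logPrior, w);
}

// ordering (event index at each position, 0-based events) -> positions[e]
static void ordering_to_positions(const std::vector<int> &ordering,
                                  std::vector<int> &positions) {
  int N = ordering.size();
  for (int p = 0; p < N; ++p) positions[ordering[p]] = p + 1;
}

// Greedy remove-and-reinsert hill climb over event orderings under the
// within-biomarker monotonicity constraint.  ordering0: 1-based event
// indices.  Deterministic given its inputs: events are scanned in event-
// index order, candidate slots in increasing order, strict improvement only.
// [[Rcpp::export(name = ".cppGreedyClimb")]]
List cppGreedyClimb(NumericMatrix X, NumericVector w, IntegerVector ordering0,
                    IntegerVector eventBio, NumericVector eventZ,
                    NumericVector zmax, NumericVector sigma,
                    NumericVector logu, NumericVector logPrior,
                    int maxPass) {
  int N = ordering0.size();
  std::vector<int> ordering(N), positions(N);
  for (int p = 0; p < N; ++p) ordering[p] = ordering0[p] - 1;
  ordering_to_positions(ordering, positions);
  double best = seq_loglik(X, positions, eventBio, eventZ, zmax, sigma,
                           logu, logPrior, w);
  std::vector<int> reduced(N - 1), cand(N), candPos(N);
  for (int pass = 0; pass < maxPass; ++pass) {
    bool improved = false;
    for (int e = 0; e < N; ++e) {
      int cur = positions[e] - 1;  // 0-based slot of event e
      // reduced ordering without e
      int idx = 0;
      for (int p = 0; p < N; ++p)
        if (ordering[p] != e) reduced[idx++] = ordering[p];
      // allowed slot range: after the previous same-biomarker event (lower
      // level) and before the next one (higher level) in the reduced list
      int lo = 0, hi = N - 1;  // insertion slots 0..N-1
      for (int p = 0; p < N - 1; ++p) {
        if (eventBio[reduced[p]] == eventBio[e]) {
          if (eventZ[reduced[p]] < eventZ[e]) lo = std::max(lo, p + 1);
          else hi = std::min(hi, p);
        }
      }
      double bestLL = best;
      int bestSlot = cur;
      for (int q = lo; q <= hi; ++q) {
        if (q == cur) continue;
        for (int p = 0; p < q; ++p) cand[p] = reduced[p];
        cand[q] = e;
        for (int p = q; p < N - 1; ++p) cand[p + 1] = reduced[p];
        ordering_to_positions(cand, candPos);
        double ll = seq_loglik(X, candPos, eventBio, eventZ, zmax, sigma,
                               logu, logPrior, w);
        if (ll > bestLL) { bestLL = ll; bestSlot = q; }
      }
      if (bestSlot != cur) {
        improved = true;
        best = bestLL;
        for (int p = 0; p < bestSlot; ++p) ordering[p] = reduced[p];
        ordering[bestSlot] = e;
        for (int p = bestSlot; p < N - 1; ++p) ordering[p + 1] = reduced[p];
        ordering_to_positions(ordering, positions);
      }
    }
    if (!improved) break;
  }
  IntegerVector out(N);
  for (int p = 0; p < N; ++p) out[p] = ordering[p] + 1;
  return List::create(_["ordering"] = out, _["logLik"] = best);
}

// per-subject stage-marginalised log likelihood under one sequence:
//   a_j = logsumexp_k(logPrior_k + S_jk)
static void subject_seq_loglik(const NumericMatrix &X,
                               const std::vector<int> &positions,
                               const IntegerVector &eventBio,
                               const NumericVector &eventZ,
                               const NumericVector &zmax,
                               const NumericVector &sigma,
                               const NumericVector &logu,
                               const NumericVector &logPrior,
                               std::vector<double> &a) {
  int J = X.nrow(), I = X.ncol(), N = positions.size();
  std::vector<double> G((size_t)I * (N + 1));
  traj_matrix(positions, eventBio, eventZ, zmax, I, N, G);
  std::vector<double> logsig(I), inv2s2(I);
  for (int i = 0; i < I; ++i) {
    logsig[i] = std::log(sigma[i]);
    inv2s2[i] = 0.5 / (sigma[i] * sigma[i]);
  }
  std::vector<double> sk(N + 1);
  for (int j = 0; j < J; ++j) {
    double missConst = 0.0;
    for (int i = 0; i < I; ++i)
      if (NumericMatrix::is_na(X(j, i))) missConst += logu[i];
    double m = R_NegInf;
    for (int k = 0; k <= N; ++k) {
      double s = missConst + logPrior[k];
      for (int i = 0; i < I; ++i) {
        double x = X(j, i);
        if (!NumericMatrix::is_na(x)) {
          double d = x - G[i + (size_t)k * I];
          s += -0.5 * LOG_2PI - logsig[i] - d * d * inv2s2[i];
        }
      }
      sk[k] = s;
      if (s > m) m = s;
    }
    double acc = 0.0;
    for (int k = 0; k <= N; ++k) acc += std::exp(sk[k] - m);
    a[j] = m + std::log(acc);
  }
}

static double mixture_loglik(const std::vector<std::vector<double>> &a,
                             const std::vector<double> &logf, int J) {
  int C = a.size();
  double total = 0.0;
  for (int j = 0; j < J; ++j) {
    double m = R_NegInf;
    for (int c = 0; c < C; ++c)
      m = std::max(m, logf[c] + a[c][j]);
    double acc = 0.0;
    for (int c = 0; c < C; ++c) acc += std::exp(logf[c] + a[c][j] - m);
    total += m + std::log(acc);
  }
  return total;
}

// Metropolis-Hastings over event orderings (one event moved to a random
// valid position in one random subtype per iteration) with a joint
// Gaussian perturb-clip-renormalise proposal on the mixture fractions.
// Uses R's RNG so results follow set.seed().
// orderings: C x N matrix of 1-based event indices.
// Returns acceptance count, per-iteration log lik and fractions, event x
// position occupancy counts per subtype, and thinned sequence samples.
// [[Rcpp::export(name = ".cppMCMC")]]
List cppMCMC(NumericMatrix X, IntegerMatrix orderings, NumericVector fractions,
             IntegerVector eventBio, NumericVector eventZ, NumericVector zmax,
             NumericVector sigma, NumericVector logu, NumericVector logPrior,
             int nIter, double fracSd, int thin) {
  int C = orderings.nrow(), N = orderings.ncol(), J = X.nrow();
  std::vector<std::vector<int>> ord(C, std::vector<int>(N));
  std::vector<std::vector<int>> pos(C, std::vector<int>(N));
  for (int c = 0; c < C; ++c) {
    for (int p = 0; p < N; ++p) ord[c][p] = orderings(c, p) - 1;
    ordering_to_positions(ord[c], pos[c]);
  }
  std::vector<double> f(C), logf(C);
  for (int c = 0; c < C; ++c) { f[c] = fractions[c]; logf[c] = std::log(f[c]); }
  std::vector<std::vector<double>> a(C, std::vector<double>(J));
  for (int c = 0; c < C; ++c)
    subject_seq_loglik(X, pos[c], eventBio, eventZ, zmax, sigma, logu,
                       logPrior, a[c]);
  double ll = mixture_loglik(a, logf, J);

  NumericVector llTrace(nIter);
  NumericMatrix fTrace(nIter, C);
  // posCount[c](e, p): samples with event e at position p+1 in subtype c
  std::vector<IntegerMatrix> posCount;
  for (int c = 0; c < C; ++c) posCount.push_back(IntegerMatrix(N, N));
  int nKeep = (thin > 0) ? nIter / thin : 0;
  IntegerVector seqSamples(Dimension(std::max(nKeep, 1), C, N));
  int accepted = 0, kept = 0;
  double bestLL = ll;
  std::vector<std::vector<int>> bestOrd = ord;
  std::vector<double> bestF = f;

  std::vector<int> reduced(N - 1), candOrd(N), candPos(N);
  std::vector<double> aCand(J), fCand(C), logfCand(C);
  for (int it = 0; it < nIter; ++it) {
    int c = (int)std::floor(unif_rand() * C);
    if (c == C) c = C - 1;
    int e = (int)std::floor(unif_rand() * N);
    if (e == N) e = N - 1;
    int cur = pos[c][e] - 1;
    int idx = 0;
    for (int p = 0; p < N; ++p)
      if (ord[c][p] != e) reduced[idx++] = ord[c][p];
    int lo = 0, hi = N - 1;
    for (int p = 0; p < N - 1; ++p) {
      if (eventBio[reduced[p]] == eventBio[e]) {
        if (eventZ[reduced[p]] < eventZ[e]) lo = std::max(lo, p + 1);
        else hi = std::min(hi, p);
      }
    }
    int q = lo + (int)std::floor(unif_rand() * (hi - lo + 1));
    if (q > hi) q = hi;
    for (int p = 0; p < q; ++p) candOrd[p] = reduced[p];
    candOrd[q] = e;
    for (int p = q; p < N - 1; ++p) candOrd[p + 1] = reduced[p];
    ordering_to_positions(candOrd, candPos);
    // fraction proposal: perturb, clip at 0, renormalise
    double fsum = 0.0;
    for (int cc = 0; cc < C; ++cc) {
      fCand[cc] = f[cc] + norm_rand() * fracSd;
      if (fCand[cc] < 0.0) fCand[cc] = 0.0;
      fsum += fCand[cc];
    }
    for (int cc = 0; cc < C; ++cc) {
      fCand[cc] /= fsum;
      logfCand[cc] = std::log(fCand[cc]);
    }
    bool seqChanged = (q != cur);
    if (seqChanged)
      subject_seq_loglik(X, candPos, eventBio, eventZ, zmax, sigma, logu,
                         logPrior, aCand);
    const std::vector<double> &aUse = seqChanged ? aCand : a[c];
    std::vector<const std::vector<double> *> aAll(C);
    for (int cc = 0; cc < C; ++cc) aAll[cc] = (cc == c) ? &aUse : &a[cc];
    double llNew = 0.0;
    for (int j = 0; j < J; ++j) {
      double m = R_NegInf;
      for (int cc = 0; cc < C; ++cc)
        m = std::max(m, logfCand[cc] + (*aAll[cc])[j]);
      double acc2 = 0.0;
      for (int cc = 0; cc < C; ++cc)
        acc2 += std::exp(logfCand[cc] + (*aAll[cc])[j] - m);
      llNew += m + std::log(acc2);
    }
    double u = unif_rand();
    if (llNew >= ll || u < std::exp(llNew - ll)) {
      ++accepted;
      ll = llNew;
      if (seqChanged) {
        ord[c] = candOrd;
        pos[c] = candPos;
        a[c] = aCand;
      }
      f = fCand;
      logf = logfCand;
      if (ll > bestLL) { bestLL = ll; bestOrd = ord; bestF = f; }
    }
    llTrace[it] = ll;
    for (int cc = 0; cc < C; ++cc) fTrace(it, cc) = f[cc];
    for (int cc = 0; cc < C; ++cc)
      for (int ee = 0; ee < N; ++ee)
        posCount[cc](ee, pos[cc][ee] - 1) += 1;
    if (thin > 0 && (it + 1) % thin == 0 && kept < nKeep) {
      for (int cc = 0; cc < C; ++cc)
        for (int p = 0; p < N; ++p)
          seqSamples[kept + (size_t)nKeep * (cc + (size_t)C * p)] =
            ord[cc][p] + 1;
      ++kept;
    }
  }
  List pc(C);
  for (int c = 0; c < C; ++c) pc[c] = posCount[c];
  IntegerMatrix bestOrderings(C, N);
  for (int c = 0; c < C; ++c)
    for (int p = 0; p < N; ++p) bestOrderings(c, p) = bestOrd[c][p] + 1;
  return List::create(_["accepted"] = accepted, _["logLik"] = llTrace,
                      _["fractions"] = fTrace, _["posCount"] = pc,
                      _["seqSamples"] = seqSamples, _["nKept"] = kept,
                      _["bestLogLik"] = bestLL,
                      _["bestOrderings"] = bestOrderings,
                      _["bestFractions"] = NumericVector(bestF.begin(),
                                                         bestF.end()));
}
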