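#include <Rcpp.h>
using namespace Rcpp;

// Mean nearest-taxon distances between all sample pairs under a tip-label
// permutation.  D is the full patristic matrix over the taxon pool (tip
// positions); comm holds 0-based taxon indices present in each sample; wts
// the matching within-sample weights (relative abundances, or 1/richness
// when unweighted).  perm maps taxon -> tip position; the identity
// permutation gives the observed values.
//
// For speed, the nearest-taxon scan runs over contiguous columns of D:
// minPos[s][pos] = min over taxa u in sample s of D(pos, perm[u]) is a
// sequential fold over whole columns, and pair accumulation then reads
// minPos[j][perm[t]] for the taxa t of sample i.
static void bmntd_all_pairs(const NumericMatrix& D,
                            const std::vector<std::vector<int> >& comm,
                            const std::vector<std::vector<double> >& wts,
                            const IntegerMatrix& pairs,
                            const int* perm,
                            std::vector<std::vector<double> >& minPos,
                            double* out) {
  const int T = D.nrow();
  const int S = (int) comm.size();
  for (int s = 0; s < S; ++s) {
    const std::vector<int>& cs = comm[s];
    std::vector<double>& ms = minPos[s];
    std::fill(ms.begin(), ms.end(), R_PosInf);
    for (size_t a = 0; a < cs.size(); ++a) {
      const double* col = &D(0, perm[cs[a]]);
      for (int pos = 0; pos < T; ++pos) {
        if (col[pos] < ms[pos]) ms[pos] = col[pos];
      }
    }
  }
  const int npairs = pairs.nrow();
  for (int p = 0; p < npairs; ++p) {
    const int i = pairs(p, 0), j = pairs(p, 1);
    const std::vector<int>& ci = comm[i];
    const std::vector<int>& cj = comm[j];
    const std::vector<double>& wi = wts[i];
    const std::vector<double>& wj = wts[j];
    const std::vector<double>& mj = minPos[j];
    const std::vector<double>& mi = minPos[i];
    double acc = 0.0;
    for (size_t a = 0; a < ci.size(); ++a) acc += wi[a] * mj[perm[ci[a]]];
    for (size_t b = 0; b < cj.size(); ++b) acc += wj[b] * mi[perm[cj[b]]];
    out[p] = 0.5 * acc;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_bnti(NumericMatrix D, List comm_r, List wts_r,
                       IntegerMatrix pairs, IntegerMatrix perms) {
  const int T = D.nrow();
  const int S = comm_r.size();
  const int npairs = pairs.nrow();
  const int n_null = perms.nrow();

  std::vector<std::vector<int> > comm(S);
  std::vector<std::vector<double> > wts(S);
  for (int s = 0; s < S; ++s) {
    comm[s] = as<std::vector<int> >(comm_r[s]);
    wts[s] = as<std::vector<double> >(wts_r[s]);
  }
  std::vector<std::vector<double> > minPos(S, std::vector<double>(T));

  std::vector<int> ident(T);
  for (int t = 0; t < T; ++t) ident[t] = t;
  std::vector<double> obs(npairs), nul(npairs);
  std::vector<double> sum(npairs, 0.0), sumsq(npairs, 0.0);

  bmntd_all_pairs(D, comm, wts, pairs, ident.data(), minPos, obs.data());

  std::vector<int> perm(T);
  for (int k = 0; k < n_null; ++k) {
    for (int t = 0; t < T; ++t) perm[t] = perms(k, t);
    bmntd_all_pairs(D, comm, wts, pairs, perm.data(), minPos, nul.data());
    for (int p = 0; p < npairs; ++p) {
      sum[p] += nul[p];
      sumsq[p] += nul[p] * nul[p];
    }
    if (k % 50 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix res(npairs, 3);
  for (int p = 0; p < npairs; ++p) {
    const double mean = sum[p] / n_null;
    double var = (sumsq[p] - n_null * mean * mean) / (n_null - 1.0);
    if (var < 0) var = 0;
    res(p, 0) = obs[p];
    res(p, 1) = mean;
    res(p, 2) = std::sqrt(var);
  }
  return res;
}
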