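#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Chromosome states, shared with the R level:
//   0 = none, 1 = parent-A monosome, 2 = parent-B monosome, 3 = heterodisome (A+B)
// A spore never carries more than one chromatid per homolog, so 3 is the maximum.

namespace {

// Per-spore loss outcome from a disomic MII entry, drawn with a single
// uniform against precomputed cumulative thresholds:
//   per_copy: both copies lost (pb^2) -> 0; A lost -> 2; B lost -> 1; keep -> 3
//   lose_one: one uniformly chosen copy lost w.p. pb
struct LossThresholds {
  double t_none, t_monoB, t_monoA; // cumulative
  double pa;
  bool has_pa, has_pb;
  LossThresholds(double pa_, double pb, bool per_copy) {
    pa = pa_;
    has_pa = pa_ > 0.0;
    has_pb = pb > 0.0;
    if (per_copy) {
      t_none = pb * pb;
      t_monoB = t_none + pb * (1.0 - pb);
      t_monoA = t_monoB + pb * (1.0 - pb);
    } else {
      t_none = 0.0;
      t_monoB = pb / 2.0;
      t_monoA = pb;
    }
  }
  inline int mii_state(int comp) const {
    // losses are evaluated once, on the MII-entry state: a pb-created
    // monosome is not re-exposed to pa
    if (comp == 3) {
      if (!has_pb) return 3;
      double u = unif_rand();
      if (u < t_none) return 0;
      if (u < t_monoB) return 2;
      if (u < t_monoA) return 1;
      return 3;
    }
    if (comp == 0) return 0;
    if (has_pa && unif_rand() < pa) return 0;
    return comp;
  }
};

} // namespace

// Bulk tetrad simulator.
//
// same_pole: per-chromosome probability that both homologs move to the same
//   pole at MI (c_N).  conditional = TRUE simulates only the two spores of a
//   designated full MI daughter, drawing its composition from the exact
//   conditional distribution (disome w.p. (c/2)/(1-c/2), else A/B monosome).
//
// Categories are indexed 0 copies, 1 altered_copies, 2 single, 3 mii_dead,
// 4 mi_dead, 5 multi.
//
// [[Rcpp::export]]
List cpp_simulate_tetrads(double n, NumericVector same_pole, double pa, double pb,
                          bool conditional, bool per_copy_loss,
                          int max_karyotypes) {
  const int K = same_pole.size();
  const long long N = (long long) n;
  const LossThresholds loss(pa, pb, per_copy_loss);

  // cumulative thresholds for the single-uniform composition draws
  std::vector<double> cond_dis(K), cond_monoA(K); // conditional daughter
  std::vector<double> mi_d1AB(K), mi_d2AB(K), mi_d1A(K); // unconditional MI
  for (int c = 0; c < K; ++c) {
    double cn = same_pole[c];
    double h = cn / 2.0;
    double p = h / (1.0 - h);
    cond_dis[c] = p;
    cond_monoA[c] = p + (1.0 - p) / 2.0;
    mi_d1AB[c] = h;
    mi_d2AB[c] = cn;
    mi_d1A[c] = cn + (1.0 - cn) / 2.0;
  }

  std::vector<long long> cat(6, 0);
  std::vector<long long> hist(K + 1, 0);
  std::vector<long long> n_monoA(K, 0), n_monoB(K, 0), n_disome(K, 0);
  long long n_viable = 0;

  IntegerMatrix karyo(max_karyotypes > 0 ? max_karyotypes : 1, K);
  int stored = 0;

  std::vector<int> comp1(K), comp2(K);
  std::vector<int> sp(4 * K); // spore states, spores 0..3
  bool viable[4];

  for (long long t = 0; t < N; ++t) {
    bool full1 = true, full2 = true;
    int n_daughters = conditional ? 1 : 2;

    if (conditional) {
      for (int c = 0; c < K; ++c) {
        double u = unif_rand();
        comp1[c] = (u < cond_dis[c]) ? 3 : (u < cond_monoA[c] ? 1 : 2);
      }
    } else {
      for (int c = 0; c < K; ++c) {
        double u = unif_rand();
        if (u < mi_d1AB[c])      { comp1[c] = 3; comp2[c] = 0; full2 = false; }
        else if (u < mi_d2AB[c]) { comp1[c] = 0; comp2[c] = 3; full1 = false; }
        else if (u < mi_d1A[c])  { comp1[c] = 1; comp2[c] = 2; }
        else                     { comp1[c] = 2; comp2[c] = 1; }
      }
    }

    int n_spores = 2 * n_daughters;
    for (int s = 0; s < 4; ++s) viable[s] = false;

    for (int d = 0; d < n_daughters; ++d) {
      bool full = (d == 0) ? full1 : full2;
      const std::vector<int>& comp = (d == 0) ? comp1 : comp2;
      for (int s = 2 * d; s < 2 * d + 2; ++s) {
        if (!full) { // a missing chromosome already kills both spores
          for (int c = 0; c < K; ++c) sp[s * K + c] = 0;
          continue;
        }
        bool ok = true;
        for (int c = 0; c < K; ++c) {
          int st = loss.mii_state(comp[c]);
          sp[s * K + c] = st;
          if (st == 0) ok = false;
        }
        viable[s] = ok;
      }
    }

    int nv = 0;
    for (int s = 0; s < n_spores; ++s) if (viable[s]) ++nv;

    // per-spore tallies
    for (int s = 0; s < n_spores; ++s) {
      if (!viable[s]) continue;
      ++n_viable;
      int nd = 0;
      for (int c = 0; c < K; ++c) {
        int st = sp[s * K + c];
        if (st == 3) { ++nd; ++n_disome[c]; }
        else if (st == 1) ++n_monoA[c];
        else ++n_monoB[c];
      }
      ++hist[nd];
      if (stored < max_karyotypes) {
        for (int c = 0; c < K; ++c) karyo(stored, c) = sp[s * K + c];
        ++stored;
      }
    }

    // ascus category
    if (nv == 0) {
      cat[(full1 || full2) ? 3 : 4] += 1;
    } else if (nv == 1) {
      cat[2] += 1;
    } else if (nv >= 3) {
      cat[5] += 1;
    } else {
      int a = -1, b = -1;
      for (int s = 0; s < n_spores; ++s) if (viable[s]) { if (a < 0) a = s; else b = s; }
      bool same = true;
      for (int c = 0; c < K; ++c)
        if (sp[a * K + c] != sp[b * K + c]) { same = false; break; }
      cat[same ? 0 : 1] += 1;
    }
  }

  NumericVector categories = NumericVector::create(
    _["copies"] = (double) cat[0], _["altered_copies"] = (double) cat[1],
    _["single"] = (double) cat[2], _["mii_dead"] = (double) cat[3],
    _["mi_dead"] = (double) cat[4], _["multi"] = (double) cat[5]);

  NumericVector disomy_hist(K + 1);
  for (int i = 0; i <= K; ++i) disomy_hist[i] = (double) hist[i];

  NumericMatrix chrom_counts(K, 3);
  for (int c = 0; c < K; ++c) {
    chrom_counts(c, 0) = (double) n_monoA[c];
    chrom_counts(c, 1) = (double) n_monoB[c];
    chrom_counts(c, 2) = (double) n_disome[c];
  }
  colnames(chrom_counts) = CharacterVector::create("monoA", "monoB", "disomyAB");

  List out = List::create(
    _["categories"] = categories,
    _["disomy_hist"] = disomy_hist,
    _["chrom_counts"] = chrom_counts,
    _["n_viable_spores"] = (double) n_viable,
    _["n_tetrads"] = (double) N);
  if (max_karyotypes > 0) {
    out["karyotypes"] = karyo(Range(0, std::max(stored - 1, 0)), _);
    out["n_karyotypes"] = stored;
  }
  return out;
}

// Harvest viable spore karyotypes from conditional tetrads until n_spores are
// collected; errors out if viability is too low to fill the request.
//
// [[Rcpp::export]]
IntegerMatrix cpp_sample_viable_spores(int n_spores, NumericVector same_pole,
                                       double pa, double pb, bool per_copy_loss) {
  const int K = same_pole.size();
  const LossThresholds loss(pa, pb, per_copy_loss);
  std::vector<double> cond_dis(K), cond_monoA(K);
  for (int c = 0; c < K; ++c) {
    double h = same_pole[c] / 2.0;
    double p = h / (1.0 - h);
    cond_dis[c] = p;
    cond_monoA[c] = p + (1.0 - p) / 2.0;
  }

  IntegerMatrix out(n_spores, K);
  int stored = 0;
  long long tries = 0;
  const long long max_tries = 1000LL * n_spores + 1000000LL;
  std::vector<int> comp(K), st(K);

  while (stored < n_spores && tries < max_tries) {
    ++tries;
    for (int c = 0; c < K; ++c) {
      double u = unif_rand();
      comp[c] = (u < cond_dis[c]) ? 3 : (u < cond_monoA[c] ? 1 : 2);
    }
    for (int s = 0; s < 2 && stored < n_spores; ++s) {
      bool ok = true;
      for (int c = 0; c < K; ++c) {
        st[c] = loss.mii_state(comp[c]);
        if (st[c] == 0) ok = false;
      }
      if (ok) {
        for (int c = 0; c < K; ++c) out(stored, c) = st[c];
        ++stored;
      }
    }
  }
  if (stored < n_spores)
    stop("could not collect %d viable spores (viability too low)", n_spores);
  return out;
}
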