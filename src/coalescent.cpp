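#include <Rcpp.h>
#include <vector>
#include <map>
#include <string>
using namespace Rcpp;

// Hudson-style structured coalescent, time in units of 2N generations.
// Demes have equal size; exponential growth alpha means the population
// (every deme) shrinks backwards in time as N(t) = N0 * exp(-alpha t), so the
// pairwise coalescence rate at time t is exp(alpha t) per 2N0 generations.
// Backwards migration rates are per lineage per 2N0 generations (a lineage
// currently in deme i moves to deme j at rate mig(i, j)).

struct Genealogy {
  std::vector<int> parent;      // 0-based, -1 for root
  std::vector<double> ntime;    // node times
  std::vector<int> tipcount;    // tips below each node (tips: 1)
  int ntips;
  double total_length;
  int n_migrations;
};

static Genealogy build_tree(const IntegerVector& sample_sizes,
                            const NumericMatrix& mig,
                            double alpha,
                            double max_events) {
  const int d = sample_sizes.size();
  int n = 0;
  for (int i = 0; i < d; ++i) n += sample_sizes[i];
  if (n < 2) stop("need at least 2 gene copies");

  const int n_nodes = 2 * n - 1;
  Genealogy g;
  g.parent.assign(n_nodes, -1);
  g.ntime.assign(n_nodes, 0.0);
  g.tipcount.assign(n_nodes, 0);
  g.ntips = n;
  g.n_migrations = 0;

  // active lineages kept as per-deme member lists (node ids) for O(1)
  // sampling within a deme and O(d) event dispatch
  std::vector<std::vector<int> > members(d);
  std::vector<int> k(d, 0); // lineages per deme
  {
    int idx = 0;
    for (int i = 0; i < d; ++i) {
      members[i].reserve(sample_sizes[i] + 8);
      for (int s = 0; s < sample_sizes[i]; ++s) members[i].push_back(idx++);
    }
  }
  for (int i = 0; i < d; ++i) k[i] = sample_sizes[i];
  for (int v = 0; v < n; ++v) g.tipcount[v] = 1;

  // per-deme total out-migration rate per lineage
  std::vector<double> outrate(d, 0.0);
  for (int i = 0; i < d; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) if (j != i) s += mig(i, j);
    outrate[i] = s;
  }

  double t = 0.0;
  int next_node = n;
  int active = n;
  double events = 0.0;

  while (active > 1) {
    events += 1.0;
    if (events > max_events)
      stop("coalescent event cap exceeded (%.0f events); check migration rates", max_events);

    double coal_rate = 0.0;
    for (int i = 0; i < d; ++i)
      coal_rate += 0.5 * (double)k[i] * (k[i] - 1);
    double mig_rate = 0.0;
    for (int i = 0; i < d; ++i) mig_rate += k[i] * outrate[i];

    if (coal_rate <= 0.0 && mig_rate <= 0.0)
      stop("no possible events: lineages isolated in separate demes with zero migration");

    // candidate coalescence time (time-inhomogeneous if alpha != 0)
    double tc = R_PosInf;
    if (coal_rate > 0.0) {
      double e = R::exp_rand();
      if (alpha == 0.0) {
        tc = t + e / coal_rate;
      } else {
        // integrated hazard from t to tc: coal_rate * (exp(a tc) - exp(a t))/a = e
        double z = std::exp(alpha * t) + alpha * e / coal_rate;
        tc = (z > 0.0) ? std::log(z) / alpha : R_PosInf;
      }
    }
    double tm = R_PosInf;
    if (mig_rate > 0.0) tm = t + R::exp_rand() / mig_rate;

    if (tc <= tm) {
      t = tc;
      // choose deme proportional to k_i (k_i - 1) / 2
      double u = unif_rand() * coal_rate, acc = 0.0;
      int deme = -1;
      for (int i = 0; i < d; ++i) {
        acc += 0.5 * (double)k[i] * (k[i] - 1);
        if (u <= acc) { deme = i; break; }
      }
      if (deme < 0) deme = d - 1;
      // choose an unordered pair uniformly within the deme's member list
      int ki = k[deme];
      int ia = (int)std::floor(unif_rand() * ki);
      int ib = (int)std::floor(unif_rand() * (ki - 1));
      if (ia >= ki) ia = ki - 1;
      if (ib >= ia) ib += 1;
      int node = next_node++;
      int va = members[deme][ia], vb = members[deme][ib];
      g.ntime[node] = t;
      g.parent[va] = node;
      g.parent[vb] = node;
      g.tipcount[node] = g.tipcount[va] + g.tipcount[vb];
      // replace a with merged node, drop b (swap-with-last)
      members[deme][ia] = node;
      members[deme][ib] = members[deme].back();
      members[deme].pop_back();
      k[deme] -= 1;
      active -= 1;
    } else {
      t = tm;
      // choose source deme proportional to k_i * outrate_i, member uniform
      double u = unif_rand() * mig_rate, acc = 0.0;
      int from = -1;
      for (int i = 0; i < d; ++i) {
        acc += k[i] * outrate[i];
        if (u <= acc) { from = i; break; }
      }
      if (from < 0) { for (int i = d - 1; i >= 0; --i) if (k[i] > 0) { from = i; break; } }
      int im = (int)std::floor(unif_rand() * k[from]);
      if (im >= k[from]) im = k[from] - 1;
      double u2 = unif_rand() * outrate[from], acc2 = 0.0;
      int to = -1;
      for (int j = 0; j < d; ++j) {
        if (j == from) continue;
        acc2 += mig(from, j);
        if (u2 <= acc2) { to = j; break; }
      }
      if (to < 0) { for (int j = d - 1; j >= 0; --j) if (j != from) { to = j; break; } }
      int v = members[from][im];
      members[from][im] = members[from].back();
      members[from].pop_back();
      members[to].push_back(v);
      k[from] -= 1; k[to] += 1;
      g.n_migrations += 1;
    }
  }

  double tot = 0.0;
  for (int v = 0; v < n_nodes - 1; ++v)
    tot += g.ntime[g.parent[v]] - g.ntime[v];
  g.total_length = tot;
  return g;
}

// [[Rcpp::export]]
List coal_genealogy_cpp(IntegerVector sample_sizes, NumericMatrix mig,
                        double alpha, double max_events) {
  Genealogy g = build_tree(sample_sizes, mig, alpha, max_events);
  const int d = sample_sizes.size();
  int n = g.ntips;
  IntegerVector par(2 * n - 1);
  for (int v = 0; v < 2 * n - 1; ++v) par[v] = g.parent[v] + 1; // 1-based, 0 = root
  IntegerVector deme(n);
  {
    int idx = 0;
    for (int i = 0; i < d; ++i)
      for (int s = 0; s < sample_sizes[i]; ++s) deme[idx++] = i + 1;
  }
  return List::create(_["parent"] = par,
                      _["node_time"] = NumericVector(g.ntime.begin(), g.ntime.end()),
                      _["tip_count"] = IntegerVector(g.tipcount.begin(), g.tipcount.end()),
                      _["deme_of_sample"] = deme,
                      _["n_tips"] = n,
                      _["total_branch_length"] = g.total_length,
                      _["n_migrations"] = g.n_migrations);
}

// Place S mutations uniformly on total branch length; return n x S 0/1 matrix.
// parent is 1-based with 0 marking the root.
// [[Rcpp::export]]
IntegerMatrix drop_mutations_cpp(IntegerVector parent, NumericVector node_time,
                                 int n_tips, int S) {
  const int n_nodes = parent.size();
  std::vector<double> bl(n_nodes, 0.0);
  double tot = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] > 0) {
      bl[v] = node_time[parent[v] - 1] - node_time[v];
      tot += bl[v];
    }
  }
  IntegerMatrix out(n_tips, S);
  if (S == 0) return out;
  if (tot <= 0.0) stop("degenerate genealogy: zero total branch length");

  // children lists for descent
  std::vector<std::vector<int> > children(n_nodes);
  for (int v = 0; v < n_nodes; ++v)
    if (parent[v] > 0) children[parent[v] - 1].push_back(v);

  for (int s = 0; s < S; ++s) {
    double u = unif_rand() * tot, acc = 0.0;
    int branch = -1;
    for (int v = 0; v < n_nodes; ++v) {
      acc += bl[v];
      if (u <= acc) { branch = v; break; }
    }
    if (branch < 0) branch = n_nodes - 2;
    // mark all tips below `branch`
    std::vector<int> stack;
    stack.push_back(branch);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v < n_tips) out(v, s) = 1;
      for (size_t c = 0; c < children[v].size(); ++c) stack.push_back(children[v][c]);
    }
  }
  return out;
}

// Fast engine for genome-wide fixed-S null distributions of Tajima's D:
// for each locus l simulate a constant-size single-deme genealogy with
// n_vec[l] tips, drop exactly S_vec[l] mutations (carrier counts only) and
// return the matrix of D values (reps x loci).
// [[Rcpp::export]]
NumericMatrix null_tajima_D_cpp(IntegerVector n_vec, IntegerVector S_vec, int reps,
                                double max_events) {
  const int L = n_vec.size();
  NumericMatrix out(reps, L);
  NumericMatrix mig(1, 1);
  for (int l = 0; l < L; ++l) {
    int n = n_vec[l], S = S_vec[l];
    // Tajima constants
    double a1 = 0.0, a2 = 0.0;
    for (int i = 1; i <= n - 1; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
    double b1 = (n + 1.0) / (3.0 * (n - 1.0));
    double b2 = 2.0 * (n * (double)n + n + 3.0) / (9.0 * n * (n - 1.0));
    double c1 = b1 - 1.0 / a1;
    double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
    double e1 = c1 / a1;
    double e2 = c2 / (a1 * a1 + a2);
    double denom = std::sqrt(e1 * S + e2 * (double)S * (S - 1.0));
    double pairs = 0.5 * (double)n * (n - 1.0);
    IntegerVector ss(1); ss[0] = n;
    for (int r = 0; r < reps; ++r) {
      if (S == 0) { out(r, l) = NA_REAL; continue; }
      Genealogy g = build_tree(ss, mig, 0.0, max_events);
      // pick S branches proportional to length, accumulate pairwise diffs
      const int n_nodes = 2 * n - 1;
      double khat_num = 0.0;
      for (int s = 0; s < S; ++s) {
        double u = unif_rand() * g.total_length, acc = 0.0;
        int branch = n_nodes - 2;
        for (int v = 0; v < n_nodes - 1; ++v) {
          double blv = (g.parent[v] >= 0) ? g.ntime[g.parent[v]] - g.ntime[v] : 0.0;
          acc += blv;
          if (u <= acc) { branch = v; break; }
        }
        double c = (double)g.tipcount[branch];
        khat_num += c * (n - c);
      }
      double khat = khat_num / pairs;
      out(r, l) = (khat - S / a1) / denom;
    }
  }
  return out;
}

// Simulate one island-model locus and return allele identities per sample:
// S >= 0 places exactly S mutations; S < 0 draws S ~ Poisson(theta * T / 2).
// Identical mutation patterns collapse to one allele.
// [[Rcpp::export]]
IntegerVector sim_locus_alleles_cpp(IntegerVector sample_sizes, NumericMatrix mig,
                                    double alpha, int S, double theta,
                                    double max_events) {
  Genealogy g = build_tree(sample_sizes, mig, alpha, max_events);
  int n = g.ntips;
  if (S < 0) S = (int)R::rpois(theta * g.total_length / 2.0);
  IntegerMatrix sites = drop_mutations_cpp(
      IntegerVector::import_transform(g.parent.begin(), g.parent.end(),
                                      [](int p) { return p + 1; }),
      NumericVector(g.ntime.begin(), g.ntime.end()), n, S);
  std::map<std::string, int> catalog;
  IntegerVector allele(n);
  for (int i = 0; i < n; ++i) {
    std::string key;
    key.reserve(S);
    for (int s = 0; s < S; ++s) key.push_back(sites(i, s) ? '1' : '0');
    std::map<std::string, int>::iterator it = catalog.find(key);
    int id;
    if (it == catalog.end()) {
      id = (int)catalog.size() + 1;
      catalog[key] = id;
    } else id = it->second;
    allele[i] = id;
  }
  return allele;
}
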