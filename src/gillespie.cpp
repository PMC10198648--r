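// Exact continuous-time (Gillespie) simulation of a clade from its crown age
// under a combined examined x concealed trait state system: per-state
// speciation/extinction, one-step trait transitions at rates Q(i,j).
// Uses R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List gillespie_clade_cpp(NumericVector lambda, NumericVector mu,
                         NumericMatrix Q, int root_state, double crown_age,
                         int max_lineages) {
  const int S = lambda.size();
  std::vector<std::vector<int> > nbr(S);
  std::vector<std::vector<double> > nbr_rate(S);
  std::vector<double> qtot(S, 0.0), evr(S);
  for (int i = 0; i < S; ++i) {
    for (int j = 0; j < S; ++j) {
      if (j != i && Q(i, j) > 0.0) {
        nbr[i].push_back(j);
        nbr_rate[i].push_back(Q(i, j));
        qtot[i] += Q(i, j);
      }
    }
    evr[i] = lambda[i] + mu[i] + qtot[i];
  }

  // lineage records (1-based ids; ids 1 and 2 are the crown lineages)
  std::vector<int> parent, state, end_type;  // end_type 0 extant 1 ext 2 spec
  std::vector<double> t_birth, t_end;
  // transition log
  std::vector<int> ev_lineage, ev_from, ev_to;
  std::vector<double> ev_time;

  parent.push_back(0); parent.push_back(0);
  state.push_back(root_state - 1); state.push_back(root_state - 1);
  end_type.push_back(0); end_type.push_back(0);
  t_birth.push_back(0.0); t_birth.push_back(0.0);
  t_end.push_back(NA_REAL); t_end.push_back(NA_REAL);

  std::vector<int> alive;  // 0-based indices into the record vectors
  alive.push_back(0);
  alive.push_back(1);

  double t = 0.0;
  bool overflow = false;
  while (!alive.empty()) {
    double R = 0.0;
    for (size_t a = 0; a < alive.size(); ++a) R += evr[state[alive[a]]];
    if (R <= 0.0) break;  // no further events possible
    t += R::exp_rand() / R;
    if (t >= crown_age) break;
    double u = unif_rand() * R;
    size_t pick = 0;
    double acc = 0.0;
    for (size_t a = 0; a < alive.size(); ++a) {
      acc += evr[state[alive[a]]];
      if (u < acc) { pick = a; break; }
    }
    int l = alive[pick];
    int s = state[l];
    double v = u - (acc - evr[s]);
    if (v < lambda[s]) {
      // speciation: lineage l ends, two daughters inherit its state
      end_type[l] = 2;
      t_end[l] = t;
      if ((int)parent.size() + 2 > max_lineages) { overflow = true; break; }
      for (int d = 0; d < 2; ++d) {
        parent.push_back(l + 1);
        state.push_back(s);
        end_type.push_back(0);
        t_birth.push_back(t);
        t_end.push_back(NA_REAL);
      }
      alive[pick] = (int)parent.size() - 2;
      alive.push_back((int)parent.size() - 1);
    } else if (v < lambda[s] + mu[s]) {
      end_type[l] = 1;
      t_end[l] = t;
      alive.erase(alive.begin() + pick);
    } else {
      double w = v - lambda[s] - mu[s];
      int to = nbr[s].back();
      for (size_t k = 0; k < nbr[s].size(); ++k) {
        w -= nbr_rate[s][k];
        if (w < 0.0) { to = nbr[s][k]; break; }
      }
      state[l] = to;
      ev_lineage.push_back(l + 1);
      ev_time.push_back(t);
      ev_from.push_back(s + 1);
      ev_to.push_back(to + 1);
    }
  }
  int n = parent.size();
  int n_extant = 0;
  for (int i = 0; i < n; ++i) {
    if (end_type[i] == 0) {
      t_end[i] = crown_age;
      ++n_extant;
    }
    state[i] += 1;  // back to 1-based states
  }
  return List::create(
      _["parent"] = IntegerVector(parent.begin(), parent.end()),
      _["state"] = IntegerVector(state.begin(), state.end()),
      _["end_type"] = IntegerVector(end_type.begin(), end_type.end()),
      _["t_birth"] = NumericVector(t_birth.begin(), t_birth.end()),
      _["t_end"] = NumericVector(t_end.begin(), t_end.end()),
      _["ev_lineage"] = IntegerVector(ev_lineage.begin(), ev_lineage.end()),
      _["ev_time"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["ev_from"] = IntegerVector(ev_from.begin(), ev_from.end()),
      _["ev_to"] = IntegerVector(ev_to.begin(), ev_to.end()),
      _["n_extant"] = n_extant, _["overflow"] = overflow);
}
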