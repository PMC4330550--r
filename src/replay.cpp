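#include <Rcpp.h>
using namespace Rcpp;

// Deterministic replay of an observed choice/outcome sequence through the
// generic five-parameter value-update rule (both simpler models are obtained
// by tying parameters: RW has ac_pos == ac_neg and zero unchosen rates, the
// risk-sensitive model has zero unchosen rates).
//
// choice is 1 (stimulus A) or 2 (stimulus B); outcome is the reinforcement
// signal on the unit scale (+1 reward, -1 punishment); missed trials carry no
// term and no value update. The switch/stay likelihood term at trial t is the
// softmax probability of the observed action given values updated through the
// previous non-missed trial; the first non-missed trial of the session has no
// predecessor and contributes no term. An RPE of exactly zero takes the
// positive-rate branch.
//
// unchosen_rule 0: the printed difference equation V_u -= a_u * RPE (unbounded
// in general); 1: the bounded fictive form V_u += a_u * (-R - V_u), identical
// to rule 0 whenever V_u == -V_c. Probabilities are clamped away from 0/1 so
// saturated logistics cannot emit -Inf log terms.
//
// [[Rcpp::export]]
List replay_cpp(IntegerVector choice, NumericVector outcome, LogicalVector missed,
                double ac_pos, double ac_neg, double au_pos, double au_neg,
                double tau, double v0a, double v0b, int unchosen_rule = 0) {
  int n = choice.size();
  NumericVector rpe(n, NA_REAL), vch(n, NA_REAL), pch(n, NA_REAL), pstay(n, NA_REAL);
  double V[2] = {v0a, v0b};
  bool has_prev = false;
  int prevc = 0;
  double sum_ll = 0.0;
  int n_eval = 0;
  for (int t = 0; t < n; ++t) {
    if (missed[t]) continue;
    int c = choice[t] - 1;
    if (c != 0 && c != 1) stop("choice must be coded 1 (A) or 2 (B)");
    double pa = 1.0 / (1.0 + std::exp(-(V[0] - V[1]) / tau));
    if (pa < 1e-15) pa = 1e-15;
    if (pa > 1.0 - 1e-15) pa = 1.0 - 1e-15;
    double p_c = (c == 0) ? pa : 1.0 - pa;
    pch[t] = p_c;
    if (has_prev) {
      double ps = (prevc == 0) ? pa : 1.0 - pa;
      pstay[t] = ps;
      sum_ll += std::log((c == prevc) ? ps : 1.0 - ps);
      ++n_eval;
    }
    double d = outcome[t] - V[c];
    rpe[t] = d;
    vch[t] = V[c];
    double a_c = (d >= 0.0) ? ac_pos : ac_neg;
    double a_u = (d >= 0.0) ? au_pos : au_neg;
    V[c] += a_c * d;
    if (unchosen_rule == 0) {
      V[1 - c] -= a_u * d;
    } else {
      V[1 - c] += a_u * (-outcome[t] - V[1 - c]);
    }
    prevc = c;
    has_prev = true;
  }
  return List::create(_["rpe"] = rpe, _["chosen_value"] = vch,
                      _["choice_prob"] = pch, _["p_stay"] = pstay,
                      _["loglik_sum"] = sum_ll, _["n_eval"] = n_eval,
                      _["v_final"] = NumericVector::create(V[0], V[1]));
}
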