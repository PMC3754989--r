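#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)) without overflow for large x
static inline double softplus(double x) {
  if (x > 35.0) return x;
  return log1p(exp(x));
}

// Log-likelihood of one observed session under one parameter combination.
// stim: 0-based stimulus index per trial; resp: 0 (A) or 1 (B);
// fb: feedback code per trial (+1 reward, -1 punishment, 0 none).
// Replays the session: softmax probability of the observed response from the
// current Q values, then a Rescorla-Wagner update of the chosen (response,
// stimulus) entry with learning rate alpha_gain for positive prediction
// errors and alpha_loss for negative ones. beta == 0 takes the greedy limit
// (probability 1 for the larger Q, 0.5 on ties), so a single inconsistent
// trial yields -Inf.
// [[Rcpp::export]]
double session_loglik_cpp(IntegerVector stim, IntegerVector resp,
                          IntegerVector fb, double alpha_gain,
                          double alpha_loss, double beta, double r0,
                          double r_plus = 1.0, double r_minus = -1.0) {
  const int n = stim.size();
  double q[2][8] = {{0.0}};
  double lle = 0.0;
  const double log_half = log(0.5);
  for (int t = 0; t < n; ++t) {
    const int s = stim[t], r = resp[t];
    const double q_c = q[r][s], q_o = q[1 - r][s];
    const double dq = q_o - q_c;
    if (beta > 0.0) {
      lle -= softplus(dq / beta);
    } else if (dq == 0.0) {
      lle += log_half;
    } else if (dq > 0.0) {
      return R_NegInf;
    } // dq < 0: probability 1, contributes 0
    const double R = (fb[t] == 0) ? r0 : (fb[t] > 0 ? r_plus : r_minus);
    const double pe = R - q_c;
    if (pe > 0.0) q[r][s] += alpha_gain * pe;
    else if (pe < 0.0) q[r][s] += alpha_loss * pe;
  }
  return lle;
}

// Log-likelihood at every point of the Cartesian grid, in ascending
// lexicographic order over (alpha_gain, alpha_loss, beta, r0) with r0
// varying fastest. The Q trajectory does not depend on beta (updates use the
// observed response and feedback only), so each (alpha_gain, alpha_loss, r0)
// replay is shared across all beta values.
// [[Rcpp::export]]
NumericVector grid_loglik_cpp(IntegerVector stim, IntegerVector resp,
                              IntegerVector fb, NumericVector alpha_gain,
                              NumericVector alpha_loss, NumericVector beta,
                              NumericVector r0, double r_plus = 1.0,
                              double r_minus = -1.0) {
  const int n = stim.size();
  const int nG = alpha_gain.size(), nL = alpha_loss.size();
  const int nB = beta.size(), nR = r0.size();
  NumericVector out((R_xlen_t)nG * nL * nB * nR);
  std::vector<double> dq(n);
  const double log_half = log(0.5);

  for (int iG = 0; iG < nG; ++iG) {
    const double aG = alpha_gain[iG];
    for (int iL = 0; iL < nL; ++iL) {
      const double aL = alpha_loss[iL];
      for (int iR = 0; iR < nR; ++iR) {
        const double v0 = r0[iR];
        // replay once, record Q[other] - Q[chosen] before each update
        double q[2][8] = {{0.0}};
        for (int t = 0; t < n; ++t) {
          const int s = stim[t], r = resp[t];
          const double q_c = q[r][s];
          dq[t] = q[1 - r][s] - q_c;
          const double R = (fb[t] == 0) ? v0 : (fb[t] > 0 ? r_plus : r_minus);
          const double pe = R - q_c;
          if (pe > 0.0) q[r][s] += aG * pe;
          else if (pe < 0.0) q[r][s] += aL * pe;
        }
        for (int iB = 0; iB < nB; ++iB) {
          const double b = beta[iB];
          double lle = 0.0;
          if (b > 0.0) {
            const double inv_b = 1.0 / b;
            for (int t = 0; t < n; ++t) lle -= softplus(dq[t] * inv_b);
          } else {
            for (int t = 0; t < n; ++t) {
              if (dq[t] == 0.0) lle += log_half;
              else if (dq[t] > 0.0) { lle = R_NegInf; break; }
            }
          }
          out[(((R_xlen_t)iG * nL + iL) * nB + iB) * nR + iR] = lle;
        }
      }
    }
  }
  return out;
}
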