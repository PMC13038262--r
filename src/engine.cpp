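#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial engine shared by likelihood evaluation, latent extraction
// and generative simulation.  Models are numbered as in the registry:
//   1 baseline, 2 WSLS, 3 reward RL, 4 inequality aversion, 5 social reward,
//   6 social reward + RL belief, 7 + influence (second-order) update,
//   8 + asymmetric RL belief update.
// Actions are coded 1 = cooperate, 0 = defect.  Parameters arrive in the
// fixed per-model order defined in R/models.R.

static const double P_CLIP = 1e-3;     // belief clip, influence model only
static const double Q_CLIP = 1e-10;    // likelihood guard

static double softmax_c(double Uc, double Ud, double beta) {
  // branch keeps the complement identity exact under role swap
  if (Ud >= Uc) return 1.0 / (1.0 + std::exp(beta * (Ud - Uc)));
  return 1.0 - 1.0 / (1.0 + std::exp(beta * (Uc - Ud)));
}

struct EngineState {
  double p;        // partner-cooperation expectation
  double Vc, Vd;   // option values (model 3)
};

// Pre-choice cooperation probability and latents for trial t (0-based).
// prev_own / prev_pay are the previous trial's own action and payoff
// (-1 when t == 0).
static void trial_forward(int model, const double* par, const EngineState& s,
                          int prev_own, double prev_pay,
                          double& q, double& Uc, double& Ud) {
  Uc = NA_REAL; Ud = NA_REAL;
  switch (model) {
  case 1:
    q = par[0];
    break;
  case 2: {
    if (prev_own < 0) { q = 0.5; break; }
    double eps = par[0];
    bool won = (prev_pay == 4.0 || prev_pay == 6.0);
    double rep = won ? 1.0 - eps / 2.0 : eps / 2.0;
    q = (prev_own == 1) ? rep : 1.0 - rep;
    break;
  }
  case 3: {
    double beta = par[1];
    Uc = s.Vc; Ud = s.Vd;
    q = softmax_c(Uc, Ud, beta);
    break;
  }
  case 4: {
    double phi = par[0], nu = par[1], beta = par[2];
    double p = s.p;
    double cs = 4.0 * p, co = 6.0 - 2.0 * p;
    double ds = 4.0 * p + 2.0, dd = 2.0 - 2.0 * p;
    Uc = cs - phi * std::max(co - cs, 0.0) - nu * std::max(cs - co, 0.0);
    Ud = ds - phi * std::max(dd - ds, 0.0) - nu * std::max(ds - dd, 0.0);
    q = softmax_c(Uc, Ud, beta);
    break;
  }
  case 5: case 6: case 7: case 8: {
    // omega, beta are the last two parameters for all social-reward models
    int np = (model == 5) ? 2 : (model == 6) ? 3 : 4;
    double omega = par[np - 2], beta = par[np - 1];
    Uc = s.p * (4.0 + omega);
    Ud = 4.0 * s.p + 2.0;
    q = softmax_c(Uc, Ud, beta);
    break;
  }
  default:
    stop("unknown model code");
  }
}

// Post-choice state update from the observed/realised trial.
static void trial_update(int model, const double* par, EngineState& s,
                         int own, int partner, double pay, double q) {
  switch (model) {
  case 3: {
    double alpha = par[0];
    if (own == 1) s.Vc += alpha * (pay - s.Vc);
    else          s.Vd += alpha * (pay - s.Vd);
    break;
  }
  case 6: {
    double alpha = par[0];
    s.p += alpha * ((double)partner - s.p);
    break;
  }
  case 7: {
    double alpha = par[0], kappa = par[1];
    s.p += alpha * ((double)partner - s.p) + kappa * ((double)own - q);
    if (s.p < P_CLIP) s.p = P_CLIP;
    if (s.p > 1.0 - P_CLIP) s.p = 1.0 - P_CLIP;
    break;
  }
  case 8: {
    double ap = par[0], am = par[1];
    double pe = (double)partner - s.p;
    if (pe > 0)      s.p += ap * pe;
    else if (pe < 0) s.p += am * pe;
    break;
  }
  default: break; // models 1, 2, 4, 5 carry no evolving state
  }
}

static EngineState init_state(double p0, double v0) {
  EngineState s; s.p = p0; s.Vc = v0; s.Vd = v0; return s;
}

// Full latent trace for an observed session (fitting / replay mode).
// [[Rcpp::export]]
List cpp_trace(int model, NumericVector par, IntegerVector own,
               IntegerVector partner, NumericVector payoff,
               double p0 = 0.5, double v0 = 3.0) {
  int T = own.size();
  NumericVector q(T), p(T), Uc(T), Ud(T), Vc(T), Vd(T), pe(T);
  EngineState s = init_state(p0, v0);
  for (int t = 0; t < T; ++t) {
    int po = (t == 0) ? -1 : own[t - 1];
    double pp = (t == 0) ? -1.0 : payoff[t - 1];
    p[t] = s.p; Vc[t] = s.Vc; Vd[t] = s.Vd;
    trial_forward(model, par.begin(), s, po, pp, q[t], Uc[t], Ud[t]);
    pe[t] = (double)partner[t] - s.p;
    trial_update(model, par.begin(), s, own[t], partner[t], payoff[t], q[t]);
  }
  return List::create(_["q"] = q, _["p"] = p, _["U_c"] = Uc, _["U_d"] = Ud,
                      _["V_c"] = Vc, _["V_d"] = Vd, _["pe"] = pe);
}

// Negative log-likelihood of the observed choices under one model.
// [[Rcpp::export]]
double cpp_nll(int model, NumericVector par, IntegerVector own,
               IntegerVector partner, NumericVector payoff,
               double p0 = 0.5, double v0 = 3.0) {
  int T = own.size();
  EngineState s = init_state(p0, v0);
  double nll = 0.0, q, Uc, Ud;
  for (int t = 0; t < T; ++t) {
    int po = (t == 0) ? -1 : own[t - 1];
    double pp = (t == 0) ? -1.0 : payoff[t - 1];
    trial_forward(model, par.begin(), s, po, pp, q, Uc, Ud);
    // evaluate the observed choice's probability straight from the
    // utilities for the softmax models: accurate deep in the tails,
    // where the complement 1 - q underflows
    double qc;
    if (model >= 3) {
      double beta = par[par.size() - 1];
      qc = (own[t] == 1) ? softmax_c(Uc, Ud, beta) : softmax_c(Ud, Uc, beta);
    } else {
      qc = (own[t] == 1) ? q : 1.0 - q;
    }
    if (qc < Q_CLIP) qc = Q_CLIP;
    if (qc > 1.0 - Q_CLIP) qc = 1.0 - Q_CLIP;
    nll -= std::log(qc);
    trial_update(model, par.begin(), s, own[t], partner[t], payoff[t], q);
  }
  return nll;
}

// Generative simulation against a scheduled partner.  u holds pre-drawn
// U(0,1) variates (one per trial) so all randomness stays under R's RNG.
// pay = c(CC, CD, DC, DD) own-payoff entries.
// [[Rcpp::export]]
List cpp_simulate(int model, NumericVector par, IntegerVector partner,
                  NumericVector u, NumericVector pay,
                  double p0 = 0.5, double v0 = 3.0) {
  int T = partner.size();
  IntegerVector own(T);
  NumericVector payoff(T), partner_payoff(T);
  NumericVector q(T), p(T), Uc(T), Ud(T), Vc(T), Vd(T), pe(T);
  EngineState s = init_state(p0, v0);
  for (int t = 0; t < T; ++t) {
    int po = (t == 0) ? -1 : own[t - 1];
    double pp = (t == 0) ? -1.0 : payoff[t - 1];
    p[t] = s.p; Vc[t] = s.Vc; Vd[t] = s.Vd;
    trial_forward(model, par.begin(), s, po, pp, q[t], Uc[t], Ud[t]);
    own[t] = (u[t] < q[t]) ? 1 : 0;
    if (own[t] == 1) { payoff[t] = partner[t] ? pay[0] : pay[1];
                       partner_payoff[t] = partner[t] ? pay[0] : pay[2]; }
    else             { payoff[t] = partner[t] ? pay[2] : pay[3];
                       partner_payoff[t] = partner[t] ? pay[1] : pay[3]; }
    pe[t] = (double)partner[t] - s.p;
    trial_update(model, par.begin(), s, own[t], partner[t], payoff[t], q[t]);
  }
  return List::create(_["own"] = own, _["own_payoff"] = payoff,
                      _["partner_payoff"] = partner_payoff,
                      _["q"] = q, _["p"] = p, _["U_c"] = Uc, _["U_d"] = Ud,
                      _["V_c"] = Vc, _["V_d"] = Vd, _["pe"] = pe);
}
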