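// Rate dynamics of competing cortico-striato-thalamic loops.
//
// Each schema (channel) i in a competing set owns seven units -- CTX,
// STR-D1, STR-D2, STN, GPe, GPi, THAL -- updated synchronously with leaky
// blending toward the logistic of their weighted input.  Connectivity:
// CTX excites STR-D1, STR-D2 and STN; STR-D1 inhibits GPi; STR-D2
// inhibits GPe; GPe inhibits STN and GPi; STN diffusely excites the GPi
// of ALL channels in the set; GPi inhibits THAL; THAL re-excites CTX.
// The diffuse STN -> GPi projection implements the off-channel surround
// that yields selective disinhibition of the most active channel.
//
// All randomness draws from R's RNG stream so that set.seed() at the R
// level fully determines a run.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// state-matrix rows
enum { CTX = 0, D1, D2, STN, GPE, GPI, THAL, NROW };

struct BgCfg {
  double w_tc, w_cs, w_cstn, w_ge_stn, w_d2_gpe, w_d1_gpi, w_ge_gpi,
         w_stn_gpi, w_gpi_thal, w_td;
  double t_gpe, t_gpi, t_thal;
  double a_str, a_stn, a_gpe, a_gpi, a_thal;
  double b_ctx, b_stn, b_gpe, b_gpi, b_thal;
  double b_str0, b_str_scale;
  double lambda;
};

static BgCfg read_cfg(const List& cfg) {
  BgCfg c;
  c.w_tc = cfg["w_tc"]; c.w_cs = cfg["w_cs"]; c.w_cstn = cfg["w_cstn"];
  c.w_ge_stn = cfg["w_ge_stn"]; c.w_d2_gpe = cfg["w_d2_gpe"];
  c.w_d1_gpi = cfg["w_d1_gpi"]; c.w_ge_gpi = cfg["w_ge_gpi"];
  c.w_stn_gpi = cfg["w_stn_gpi"]; c.w_gpi_thal = cfg["w_gpi_thal"];
  c.w_td = cfg["w_td"];
  c.t_gpe = cfg["t_gpe"]; c.t_gpi = cfg["t_gpi"]; c.t_thal = cfg["t_thal"];
  c.a_str = cfg["a_str"]; c.a_stn = cfg["a_stn"]; c.a_gpe = cfg["a_gpe"];
  c.a_gpi = cfg["a_gpi"]; c.a_thal = cfg["a_thal"];
  c.b_ctx = cfg["b_ctx"]; c.b_stn = cfg["b_stn"]; c.b_gpe = cfg["b_gpe"];
  c.b_gpi = cfg["b_gpi"]; c.b_thal = cfg["b_thal"];
  c.b_str0 = cfg["b_str0"]; c.b_str_scale = cfg["b_str_scale"];
  c.lambda = cfg["lambda"];
  return c;
}

static inline double sig(double alpha, double beta, double x) {
  double z = -alpha * (x - beta);
  if (z > 40.0) return 0.0;
  if (z < -40.0) return 1.0;
  return 1.0 / (1.0 + std::exp(z));
}

// one synchronous cycle of a loop set; xin = total external CTX input
static void cycle_set(NumericMatrix& S, const std::vector<double>& xin,
                      const NumericVector& beta_str, double a_ctx,
                      const BgCfg& c) {
  const int n = S.ncol();
  double stn_sum = 0.0;
  for (int i = 0; i < n; ++i) stn_sum += S(STN, i);
  std::vector<double> nu(NROW * n);
  for (int i = 0; i < n; ++i) {
    nu[CTX * n + i]  = sig(a_ctx, c.b_ctx, xin[i] + c.w_tc * S(THAL, i));
    // learned threshold in [0,1] mapped affinely into the striatal
    // unit's useful input range (keeps contrast when beta clips at 0/1)
    double bstr = c.b_str0 + c.b_str_scale * beta_str[i];
    nu[D1 * n + i]   = sig(c.a_str, bstr, c.w_cs * S(CTX, i));
    nu[D2 * n + i]   = sig(c.a_str, bstr, c.w_cs * S(CTX, i));
    nu[STN * n + i]  = sig(c.a_stn, c.b_stn,
                           c.w_cstn * S(CTX, i) - c.w_ge_stn * S(GPE, i));
    nu[GPE * n + i]  = sig(c.a_gpe, c.b_gpe, c.t_gpe - c.w_d2_gpe * S(D2, i));
    nu[GPI * n + i]  = sig(c.a_gpi, c.b_gpi,
                           c.t_gpi - c.w_d1_gpi * S(D1, i)
                           - c.w_ge_gpi * S(GPE, i) + c.w_stn_gpi * stn_sum);
    nu[THAL * n + i] = sig(c.a_thal, c.b_thal,
                           c.t_thal - c.w_gpi_thal * S(GPI, i));
  }
  for (int r = 0; r < NROW; ++r)
    for (int i = 0; i < n; ++i)
      S(r, i) = (1.0 - c.lambda) * S(r, i) + c.lambda * nu[r * n + i];
}

// [[Rcpp::export(name = ".bg_cycle_cpp")]]
NumericMatrix bg_cycle_cpp(NumericMatrix state, NumericVector input,
                           NumericVector beta_str, double alpha_ctx,
                           List cfg) {
  BgCfg c = read_cfg(cfg);
  NumericMatrix S = clone(state);
  std::vector<double> xin(input.begin(), input.end());
  cycle_set(S, xin, beta_str, alpha_ctx, c);
  return S;
}

static double median_of(std::vector<double>& v) {
  const size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Run coupled cognitive and sensorimotor loop sets until one sensorimotor
// schema's CTX activation exceeds theta_sel for k_sel consecutive cycles,
// or cycle_cap is reached (then: highest activation wins, ties broken
// uniformly at random, and the trial is flagged as capped).
// [[Rcpp::export(name = ".bg_trial_cpp")]]
List bg_trial_cpp(NumericMatrix cog, NumericMatrix sma,
                  NumericVector beta_cog, NumericVector beta_sma,
                  NumericVector cog_in, NumericVector sma_in,
                  IntegerVector td_map,   // 1-based sma target per cog schema
                  double alpha_cog, double alpha_sma,
                  double noise_cog, double noise_sma,
                  double theta_sel, int k_sel, int cycle_cap,
                  int sel_onset, List cfg) {
  BgCfg c = read_cfg(cfg);
  RNGScope scope;
  const int nc = cog.ncol(), ns = sma.ncol();
  NumericMatrix C = clone(cog), S = clone(sma);
  std::vector<std::vector<double> > ctx_hist(nc);

  std::vector<double> xc(nc), xs(ns);
  int winner = -1, sustain = 0, cycles = 0;
  bool capped = false;

  for (cycles = 1; cycles <= cycle_cap; ++cycles) {
    for (int i = 0; i < nc; ++i)
      xc[i] = cog_in[i] + R::runif(-noise_cog, noise_cog);
    for (int j = 0; j < ns; ++j)
      xs[j] = sma_in[j] + R::runif(-noise_sma, noise_sma);
    for (int i = 0; i < nc; ++i)
      xs[td_map[i] - 1] += c.w_td * C(CTX, i);

    cycle_set(C, xc, beta_cog, alpha_cog, c);
    cycle_set(S, xs, beta_sma, alpha_sma, c);
    for (int i = 0; i < nc; ++i) ctx_hist[i].push_back(C(CTX, i));

    // sustained-threshold selection on the sensorimotor set (armed only
    // after sel_onset cycles, so top-down drive can settle first)
    if (cycles < sel_onset) continue;
    int best = 0;
    for (int j = 1; j < ns; ++j) if (S(CTX, j) > S(CTX, best)) best = j;
    if (S(CTX, best) > theta_sel) {
      if (best == winner) {
        if (++sustain >= k_sel) break;
      } else {
        winner = best;
        sustain = 1;
      }
    } else {
      winner = -1;
      sustain = 0;
    }
  }

  if (cycles > cycle_cap) {           // cap hit without sustained winner
    cycles = cycle_cap;
    capped = true;
    double mx = S(CTX, 0);
    for (int j = 1; j < ns; ++j) if (S(CTX, j) > mx) mx = S(CTX, j);
    std::vector<int> top;
    for (int j = 0; j < ns; ++j) if (S(CTX, j) >= mx - 1e-12) top.push_back(j);
    winner = top[(int)std::floor(R::runif(0.0, 1.0) * top.size()) % top.size()];
  }

  NumericVector a_med(nc), sma_out(ns), cog_out(nc);
  for (int i = 0; i < nc; ++i) {
    a_med[i] = median_of(ctx_hist[i]);
    cog_out[i] = C(CTX, i);
  }
  for (int j = 0; j < ns; ++j) sma_out[j] = S(CTX, j);

  return List::create(
    _["response"] = winner + 1, _["cycles"] = cycles, _["capped"] = capped,
    _["cog"] = C, _["sma"] = S, _["a_med"] = a_med,
    _["cog_out"] = cog_out, _["sma_out"] = sma_out);
}
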