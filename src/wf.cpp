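// Lineage-tracking Wright-Fisher simulator with frequency-dependent mutant
// fitness. Each generation: (1) mutation - ancestors mutate with probability
// mu, each new mutant founding a lineage of size 1 with fresh (fi, fe) draws;
// (2) selection - one multinomial resampling of N individuals with weights
// count * fitness, where the mutant fitness is fi + (fe - fi) * x at ancestor
// fraction x (evaluated after mutation). Uses R's RNG throughout, so results
// are reproducible under set.seed().
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Dist {
  int kind; // 0 uniform, 1 truncated gaussian, 2 tabulated
  double lo, hi, mean, sd;
  std::vector<double> edges, cum;
};

static Dist make_dist(List spec) {
  Dist d;
  d.kind = as<int>(spec["kind"]);
  d.lo = as<double>(spec["lo"]);
  d.hi = as<double>(spec["hi"]);
  d.mean = as<double>(spec["mean"]);
  d.sd = as<double>(spec["sd"]);
  d.edges = as<std::vector<double> >(spec["edges"]);
  d.cum = as<std::vector<double> >(spec["cum"]);
  return d;
}

static double draw_dist(const Dist& d) {
  switch (d.kind) {
  case 0:
    return d.lo + unif_rand() * (d.hi - d.lo);
  case 1:
    for (;;) { // exact rejection sampling of the truncated normal
      double v = norm_rand() * d.sd + d.mean;
      if (v >= d.lo && v <= d.hi) return v;
    }
  default: {
    double u = unif_rand();
    size_t k = std::lower_bound(d.cum.begin(), d.cum.end(), u) - d.cum.begin();
    if (k + 1 >= d.edges.size()) k = d.edges.size() - 2;
    return d.edges[k] + unif_rand() * (d.edges[k + 1] - d.edges[k]);
  }
  }
}

static int bin_index(double x, const NumericVector& breaks) {
  // index of half-open bin [breaks[i], breaks[i+1]); -1 if outside
  int nb = breaks.size() - 1;
  if (nb < 1 || x < breaks[0] || x >= breaks[nb]) return -1;
  int k = std::upper_bound(breaks.begin(), breaks.end(), x) - breaks.begin() - 1;
  if (k >= nb) k = nb - 1;
  return k;
}

// [[Rcpp::export]]
List wf_sim_cpp(int N, double mu, int generations, int burn_in,
                List dfe_spec, List dee_spec,
                NumericVector fe_breaks, NumericVector fi_breaks,
                bool record_lineages, int totals_every,
                int init_count, double init_fi, double init_fe,
                bool stop_on_absorption) {
  if (N < 1) stop("N must be >= 1");
  if (mu < 0 || mu >= 1) stop("mu must lie in [0, 1)");
  if (burn_in >= generations) stop("burn_in must be smaller than generations");
  Dist dfe = make_dist(dfe_spec), dee = make_dist(dee_spec);
  RNGScope rng;

  std::vector<double> cnt, lfi, lfe;
  std::vector<int> birth, id;
  std::vector<double> rec_fi, rec_fe, rec_tau;
  std::vector<int> rec_birth, rec_id;
  int next_id = 1;

  int anc = N;
  if (init_count > 0) {
    if (init_count > N) stop("initial mutant count exceeds N");
    cnt.push_back((double)init_count);
    lfi.push_back(init_fi);
    lfe.push_back(init_fe);
    birth.push_back(0);
    id.push_back(next_id++);
    anc -= init_count;
  }

  int n_fe_bins = std::max(0, (int)fe_breaks.size() - 1);
  int n_fi_bins = std::max(0, (int)fi_breaks.size() - 1);
  std::vector<double> fe_hist(n_fe_bins, 0.0), fi_hist(n_fi_bins, 0.0);
  double sum_mut = 0.0, sumsq_mut = 0.0;
  double h1_sum = 0.0, h2_sum = 0.0;
  long h1_n = 0, h2_n = 0, n_post = 0;
  int T_post = generations - burn_in;

  std::vector<int> tot_gen;
  std::vector<int> tot_anc, tot_mut;
  if (totals_every > 0) {
    int cap = generations / totals_every + 2;
    tot_gen.reserve(cap); tot_anc.reserve(cap); tot_mut.reserve(cap);
  }

  int g = 0;
  for (g = 1; g <= generations; ++g) {
    // --- mutation step: only ancestors mutate ---
    if (mu > 0.0 && anc > 0) {
      int nm = (int)R::rbinom((double)anc, mu);
      for (int m = 0; m < nm; ++m) {
        cnt.push_back(1.0);
        lfi.push_back(draw_dist(dfe));
        lfe.push_back(draw_dist(dee));
        birth.push_back(g);
        id.push_back(next_id++);
      }
      anc -= nm;
    }
    double x = (double)anc / (double)N; // ancestor fraction after mutation

    // --- selection step: one multinomial draw over ancestor + lineages ---
    size_t K = cnt.size();
    double wa = (double)anc; // ancestor fitness is the constant 1
    double wsum = wa;
    std::vector<double> w(K);
    for (size_t j = 0; j < K; ++j) {
      double f = lfi[j] + (lfe[j] - lfi[j]) * x;
      w[j] = cnt[j] * f;
      wsum += w[j];
    }
    if (!(wsum > 0.0))
      stop("all selection weights vanished at generation %d", g);

    int remaining = N;
    double wrem = wsum;
    // ancestor category first, then lineages; conditional binomials
    {
      double p = (wrem > 0.0) ? wa / wrem : 0.0;
      if (p > 1.0) p = 1.0;
      anc = (int)R::rbinom((double)remaining, p);
      remaining -= anc;
      wrem -= wa;
    }
    size_t keep = 0;
    for (size_t j = 0; j < K; ++j) {
      int nj;
      if (j + 1 == K) {
        nj = remaining;
      } else if (remaining == 0 || wrem <= 0.0) {
        nj = 0;
      } else {
        double p = w[j] / wrem;
        if (p > 1.0) p = 1.0;
        if (p < 0.0) p = 0.0;
        nj = (int)R::rbinom((double)remaining, p);
      }
      remaining -= nj;
      wrem -= w[j];
      if (nj > 0) { // lineage survives; compact in place
        cnt[keep] = (double)nj;
        lfi[keep] = lfi[j];
        lfe[keep] = lfe[j];
        birth[keep] = birth[j];
        id[keep] = id[j];
        ++keep;
      } else if (record_lineages) { // extinct: tau = generations survived
        rec_fi.push_back(lfi[j]);
        rec_fe.push_back(lfe[j]);
        rec_birth.push_back(birth[j]);
        rec_tau.push_back((double)(g - birth[j]));
        rec_id.push_back(id[j]);
      }
    }
    cnt.resize(keep); lfi.resize(keep); lfe.resize(keep);
    birth.resize(keep); id.resize(keep);
    int mut_total = N - anc;

    // --- recorders ---
    if (totals_every > 0 && (g % totals_every == 0 || g == generations)) {
      tot_gen.push_back(g); tot_anc.push_back(anc); tot_mut.push_back(mut_total);
    }
    if (g > burn_in) {
      ++n_post;
      sum_mut += mut_total;
      sumsq_mut += (double)mut_total * mut_total;
      if (g - burn_in <= T_post / 2) { h1_sum += mut_total; ++h1_n; }
      else { h2_sum += mut_total; ++h2_n; }
      if (n_fe_bins > 0) {
        for (size_t j = 0; j < keep; ++j) {
          int kb = bin_index(lfe[j], fe_breaks);
          if (kb >= 0) fe_hist[kb] += cnt[j];
        }
      }
      if (n_fi_bins > 0) {
        for (size_t j = 0; j < keep; ++j) {
          int kb = bin_index(lfi[j], fi_breaks);
          if (kb >= 0) fi_hist[kb] += cnt[j];
        }
      }
    }
    if (stop_on_absorption && mu == 0.0 && (mut_total == 0 || anc == 0)) break;
  }
  int gens_run = std::min(g, generations);

  // lineages still alive at the end are censored (tau = NA)
  int n_censored = (int)cnt.size();
  std::vector<double> cens_cnt(cnt);
  if (record_lineages) {
    for (size_t j = 0; j < cnt.size(); ++j) {
      rec_fi.push_back(lfi[j]);
      rec_fe.push_back(lfe[j]);
      rec_birth.push_back(birth[j]);
      rec_tau.push_back(NA_REAL);
      rec_id.push_back(id[j]);
    }
  }

  return List::create(
    _["lineage_id"] = rec_id, _["fi"] = rec_fi, _["fe"] = rec_fe,
    _["birth"] = rec_birth, _["tau"] = rec_tau,
    _["n_lineages_total"] = next_id - 1,
    _["n_censored"] = n_censored,
    _["final_ancestor"] = anc,
    _["final_counts"] = cens_cnt,
    _["gens_run"] = gens_run,
    _["totals_gen"] = tot_gen, _["totals_anc"] = tot_anc,
    _["totals_mut"] = tot_mut,
    _["fe_hist"] = fe_hist, _["fi_hist"] = fi_hist,
    _["n_post"] = (double)n_post,
    _["sum_mut"] = sum_mut, _["sumsq_mut"] = sumsq_mut,
    _["h1_mean"] = h1_n > 0 ? h1_sum / h1_n : NA_REAL,
    _["h2_mean"] = h2_n > 0 ? h2_sum / h2_n : NA_REAL,
    _["h1_n"] = (double)h1_n, _["h2_n"] = (double)h2_n
  );
}

// Replicated two-type Wright-Fisher runs (no mutation) until absorption;
// used for fixation-probability checks against Moran/diffusion results.
// [[Rcpp::export]]
List wf_two_type_cpp(int N, double fi, double fe, int s0, int reps,
                     int max_gen) {
  if (s0 < 0 || s0 > N) stop("s0 must lie in 0..N");
  RNGScope rng;
  int n_fix = 0, n_ext = 0, n_cens = 0;
  for (int r = 0; r < reps; ++r) {
    int s = s0;
    int g = 0;
    while (s > 0 && s < N && g < max_gen) {
      double x = (double)(N - s) / (double)N;
      double wm = s * (fi + (fe - fi) * x);
      double wa = (double)(N - s);
      double p = wm / (wm + wa);
      if (p > 1.0) p = 1.0;
      s = (int)R::rbinom((double)N, p);
      ++g;
    }
    if (s == 0) ++n_ext;
    else if (s == N) ++n_fix;
    else ++n_cens;
  }
  return List::create(_["n_fix"] = n_fix, _["n_ext"] = n_ext,
                      _["n_censored"] = n_cens);
}
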