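#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs for the hierarchical Poisson-lognormal group model:
//   y_i | lambda_i ~ Poisson(lambda_i),  log lambda_i ~ Normal(mu, sigma)
//   mu ~ Normal(mu0, mu_sd),  sigma ~ Uniform(0, sigma_upper)
// mu is drawn from its conjugate normal full conditional; sigma by random walk
// on log(sigma) (with Jacobian); each latent log-mean by an independent
// random-walk Metropolis step.  Uses R's RNG, so set.seed() in R makes a run
// fully reproducible.

// log full conditional of t = log(sigma), including the change-of-variable
// Jacobian: p(sigma | ...) ~ sigma^-n exp(-ssq / 2 sigma^2) on (0, upper)
static inline double log_sigma_target(double t, int n, double ssq) {
  return -(double)(n - 1) * t - ssq / (2.0 * std::exp(2.0 * t));
}

// [[Rcpp::export]]
List pln_chain_cpp(IntegerVector counts,
                   int n_iter, int burn_in, int thin,
                   double mu0, double mu_sd, double sigma_upper,
                   double prop_sd_latent, double prop_sd_logsigma,
                   double init_mu, double init_sigma,
                   NumericVector init_latent,
                   bool adapt, bool track_latent) {
  const int n = counts.size();
  const double mu_prior_prec = 1.0 / (mu_sd * mu_sd);
  const int n_keep = (n_iter - burn_in) / thin;

  NumericVector mu_draws(n_keep), sigma_draws(n_keep);
  NumericVector latent_mean_draws(track_latent ? n_keep : 0);
  NumericVector latent_post_mean(n);      // running mean of l_i over kept draws
  double mu = init_mu, sigma = init_sigma;
  std::vector<double> l(init_latent.begin(), init_latent.end());
  std::vector<double> el(n);
  for (int i = 0; i < n; ++i) el[i] = std::exp(l[i]);

  double sd_l = prop_sd_latent, sd_ls = prop_sd_logsigma;
  long acc_l = 0, try_l = 0, acc_s = 0, try_s = 0;
  long batch_acc_l = 0, batch_try_l = 0, batch_acc_s = 0, batch_try_s = 0;
  int batch = 0, kept = 0;
  const int batch_len = 50;
  const double target_rate = 0.44;

  RNGScope scope;

  for (int it = 1; it <= n_iter; ++it) {
    // --- mu | l, sigma: conjugate normal draw
    double sum_l = 0.0;
    for (int i = 0; i < n; ++i) sum_l += l[i];
    double lik_prec = (double)n / (sigma * sigma);
    double prec = lik_prec + mu_prior_prec;
    double mean = (sum_l / (sigma * sigma) + mu0 * mu_prior_prec) / prec;
    mu = R::rnorm(mean, 1.0 / std::sqrt(prec));

    // --- sigma | l, mu: random walk on log sigma, bounded support
    double ssq = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = l[i] - mu;
      ssq += d * d;
    }
    double t_cur = std::log(sigma);
    double t_prop = t_cur + R::rnorm(0.0, sd_ls);
    ++try_s; ++batch_try_s;
    if (std::exp(t_prop) < sigma_upper) {
      double logr = log_sigma_target(t_prop, n, ssq) -
                    log_sigma_target(t_cur, n, ssq);
      if (logr >= 0.0 || R::unif_rand() < std::exp(logr)) {
        sigma = std::exp(t_prop);
        ++acc_s; ++batch_acc_s;
      }
    }

    // --- latent log-means: one RW-Metropolis step each
    double sig2 = sigma * sigma;
    for (int i = 0; i < n; ++i) {
      double lp = l[i] + R::rnorm(0.0, sd_l);
      double elp = std::exp(lp);
      double logr = counts[i] * (lp - l[i]) - (elp - el[i]) -
                    ((lp - mu) * (lp - mu) - (l[i] - mu) * (l[i] - mu)) /
                        (2.0 * sig2);
      ++try_l; ++batch_try_l;
      if (logr >= 0.0 || R::unif_rand() < std::exp(logr)) {
        l[i] = lp;
        el[i] = elp;
        ++acc_l; ++batch_acc_l;
      }
    }

    // --- proposal adaptation, burn-in only (Robbins-Monro style batches)
    if (adapt && it <= burn_in && it % batch_len == 0) {
      ++batch;
      double step = 1.0 / std::sqrt((double)batch);
      double r_l = batch_try_l ? (double)batch_acc_l / batch_try_l : target_rate;
      double r_s = batch_try_s ? (double)batch_acc_s / batch_try_s : target_rate;
      sd_l *= std::exp(step * (r_l - target_rate));
      sd_ls *= std::exp(step * (r_s - target_rate));
      sd_l = std::min(std::max(sd_l, 1e-3), 10.0);
      sd_ls = std::min(std::max(sd_ls, 1e-3), 10.0);
      batch_acc_l = batch_try_l = batch_acc_s = batch_try_s = 0;
    }

    // --- retain
    if (it > burn_in && (it - burn_in) % thin == 0) {
      mu_draws[kept] = mu;
      sigma_draws[kept] = sigma;
      if (track_latent) {
        double m = 0.0;
        for (int i = 0; i < n; ++i) m += el[i];
        latent_mean_draws[kept] = m / n;
      }
      for (int i = 0; i < n; ++i) latent_post_mean[i] += l[i];
      ++kept;
    }
  }
  if (kept > 0)
    for (int i = 0; i < n; ++i) latent_post_mean[i] /= kept;

  return List::create(
      _["mu"] = mu_draws, _["sigma"] = sigma_draws,
      _["latent_mean"] = latent_mean_draws,
      _["latent_post_mean"] = latent_post_mean,
      _["accept_latent"] = try_l ? (double)acc_l / try_l : NA_REAL,
      _["accept_sigma"] = try_s ? (double)acc_s / try_s : NA_REAL,
      _["prop_sd_latent"] = sd_l, _["prop_sd_logsigma"] = sd_ls);
}
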