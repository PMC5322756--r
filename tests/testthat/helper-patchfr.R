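# Shared fixtures, all generated in code.

# Independent negative-binomial log-probability oracle (mean/dispersion
# parametrization, written out from the probability mass function).
nb_logpmf_oracle <- function(y, mu, k) {
  lgamma(y + k) - lgamma(k) - lfactorial(y) +
    k * log(k / (k + mu)) + y * log(mu / (k + mu))
}

# Small synthetic feeding table used by the fitting-layer tests.
small_synth <- function(seed = 11, reps = 2L, k = 6) {
  truth <- fr_params(ln_c_n0 = 4.6, b_n0 = 1.7, ln_c_h = 0.25,
                     ln_fmax = log(6.7))
  make_synthetic_feeding_table(truth, k = k, reps = reps,
                               areas = c(0.04, 0.36, 2.56),
                               refuge_fractions = c(0.1, 0.4, 0.7),
                               ladder_max = 10L, seed = seed)
}

# The desk-scale pipeline stages are expensive; compute them once per test
# run and share across acceptance tests.
.desk_cache <- new.env(parent = emptyenv())

desk_pipeline <- function() {
  if (!is.null(.desk_cache$run)) return(.desk_cache$run)
  set.seed(20260301)
  counts <- max_feeding_counts(50L)
  mf <- fit_max_feeding(counts)
  trials <- run_experiment(c(0.04, 0.16, 0.64, 1.44, 2.56),
                           seq(0.05, 0.75, by = 0.10), reps = 5L,
                           fmax_mean = mean(counts), seed = 20260302)
  sel <- select_scaling_model(trials, mf$ln_fmax)
  table2_fit <- fr_fit(trials,
                       scaling_spec(area = TRUE, refuge = TRUE),
                       scaling_spec(), mf$ln_fmax)
  .desk_cache$run <- list(counts = counts, mf = mf, trials = trials,
                          selection = sel, table2_fit = table2_fit)
  .desk_cache$run
}
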