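# Shared fixtures, generated in code. The small reference fit is computed
# once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# compact design: 2 urbanization classes x 2 populations x 2 clones x
# 2 x 2 treatments x 2 replicates = 64 units
small_spec <- function() design_spec(n_populations_per_class = 2,
                                     n_clones_per_population = 2)

small_dataset <- function(seed = 42) {
  simulate_dataset(small_spec(), "paper_like", seed = seed, n_oversized = 2)
}

small_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    .fixture_cache$units <- small_dataset()
    .fixture_cache$fit <- sample_posterior(
      .fixture_cache$units,
      config = sampler_config(n_chains = 4, n_iterations = 800,
                              n_warmup = 400, seed = 42))
  }
  .fixture_cache$fit
}

small_fit_units <- function() {
  small_fit()
  .fixture_cache$units
}

# hand-built draws object with known values, for summary/diagnostic tests
fake_fit <- function(draws_list, divergent = NULL) {
  n_kept <- nrow(draws_list[[1]])
  n_chains <- ncol(draws_list[[1]])
  pn <- names(draws_list)
  arr <- array(NA_real_, c(n_kept, n_chains, length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (p in pn) arr[, , p] <- draws_list[[p]]
  structure(list(draws = arr, divergent = divergent, param_names = pn,
                 config = NULL, priors = prior_spec(),
                 terms = toxglmm:::MODEL_TERMS[toxglmm:::BETA_NAMES %in% pn],
                 re_coding = "signed",
                 data_info = list(), sampler_info = list()),
            class = "toxglmm_draws")
}

# parameters with all random effects zero, for closed-form predictor checks
zero_params <- function(beta = rep(0, 8), pops = "r1", clones = "r1.1",
                        sigma_pop = 1, sigma_clone = 1, nu = 10) {
  names(beta) <- toxglmm:::BETA_NAMES
  model_params(beta,
               b_pop = stats::setNames(rep(0, length(pops)), pops),
               b_clone = stats::setNames(rep(0, length(clones)), clones),
               sigma_pop = sigma_pop, sigma_clone = sigma_clone, nu = nu)
}

# a unit row built by hand
one_unit <- function(pesticide = "control", urbanization = "rural",
                     temperature = 20L, n_start = 5L, n_surviving = NA_integer_,
                     population_id = "r1", clone_id = "r1.1", replicate = 1L) {
  data.frame(population_id = population_id, clone_id = clone_id,
             urbanization = urbanization, temperature = temperature,
             pesticide = pesticide, replicate = replicate,
             n_start = n_start, n_surviving = n_surviving,
             stringsAsFactors = FALSE)
}
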