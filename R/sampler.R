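#' Sampler configuration
#'
#' Defaults reproduce the published sampling scheme: 4 chains of 10,000
#' iterations each with the first 5,000 discarded as warmup, leaving 20,000
#' retained draws. The target acceptance rate defaults to 0.9 —
#' deliberately conservative, which helps the funnel-like geometry of the
#' hierarchical scale parameters.
#'
#' @param n_chains number of chains (>= 2, so split-chain diagnostics are
#'   defined).
#' @param n_iterations iterations per chain, warmup included.
#' @param n_warmup warmup (adaptation) iterations, discarded.
#' @param seed integer seed; each chain runs on an independently derived
#'   substream.
#' @param target_accept dual-averaging target acceptance statistic.
#' @param max_treedepth cap on trajectory doublings per iteration.
#' @param init `"random"` (unconstrained values uniform on \[-2, 2\]) or
#'   `"zero"` (fixed effects and random effects at 0, scales at 1, `nu` at
#'   its prior mode of 10).
#' @return an object of class `toxglmm_sampler_config`.
#' @export
sampler_config <- function(n_chains = 4, n_iterations = 10000,
                           n_warmup = 5000, seed = 1,
                           target_accept = 0.9, max_treedepth = 10,
                           init = "random") {
  if (n_warmup >= n_iterations)
    tox_error("n_warmup must be smaller than n_iterations",
              "toxglmm_config_error")
  if (n_chains < 2)
    tox_error("n_chains must be >= 2", "toxglmm_config_error")
  if (!init %in% c("random", "zero"))
    tox_error(paste0("unknown init strategy: ", init), "toxglmm_config_error")
  if (target_accept <= 0 || target_accept >= 1)
    tox_error("target_accept must be in (0, 1)", "toxglmm_config_error")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup), seed = as.integer(seed),
                 target_accept = target_accept,
                 max_treedepth = as.integer(max_treedepth), init = init),
            class = "toxglmm_sampler_config")
}

initial_theta <- function(strategy, D, i_lnu) {
  theta <- switch(strategy,
                  random = runif(D, -2, 2),
                  zero = rep(0, D))
  if (strategy == "zero" && i_lnu > 0) theta[i_lnu] <- log(10)
  theta
}

#' Draw posterior samples with dynamic Hamiltonian Monte Carlo
#'
#' Runs the built-in no-U-turn sampler on the unconstrained parameterization
#' of the robust binomial GLMM (non-centered random effects, log-transformed
#' scales and degrees of freedom) and returns retained draws on the
#' constrained scale, with per-draw divergence flags.
#'
#' @param units a validated unit table with outcomes.
#' @param priors a [prior_spec()].
#' @param config a [sampler_config()].
#' @param terms fixed-effect terms to include (default: all 8). Reduced
#'   models (e.g. `terms = "intercept"`) are mainly useful for oracle
#'   checks.
#' @param include_random_effects set `FALSE` to fit the fixed-effects-only
#'   model (no population/clone terms, no scales, no `nu`).
#' @param re_coding see [simulate_outcomes()].
#' @return an object of class `toxglmm_draws`: a list with `draws` (array
#'   `iterations x chains x parameters`), `divergent`
#'   (`iterations x chains` logical matrix), `param_names`, `config`,
#'   `priors`, `data_info` and per-chain `sampler_info`.
#' @export
sample_posterior <- function(units, priors = prior_spec(),
                             config = sampler_config(),
                             terms = MODEL_TERMS,
                             include_random_effects = TRUE,
                             re_coding = "signed") {
  stopifnot(inherits(priors, "toxglmm_priors"),
            inherits(config, "toxglmm_sampler_config"))
  prep <- prepare_model_data(units, terms, include_random_effects, re_coding)
  K <- ncol(prep$X); P <- prep$npop; C <- prep$nclone
  D <- K + P + C + (P > 0) + 2 * (C > 0)
  i_lnu <- if (C > 0) D else -1L

  beta_names <- BETA_NAMES[match(prep$terms, MODEL_TERMS)]
  param_names <- c(beta_names,
                   if (P > 0) paste0("b_pop[", prep$pop_levels, "]"),
                   if (C > 0) paste0("b_clone[", prep$clone_levels, "]"),
                   if (P > 0) "sigma_pop",
                   if (C > 0) c("sigma_clone", "nu"))

  chain_seeds <- derive_subseeds(config$seed, config$n_chains)
  n_kept <- config$n_iterations - config$n_warmup
  draws <- array(NA_real_,
                 dim = c(n_kept, config$n_chains, length(param_names)),
                 dimnames = list(NULL, NULL, param_names))
  divergent <- matrix(NA, n_kept, config$n_chains)
  sampler_info <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    theta <- NULL
    for (try in 1:100) {
      cand <- initial_theta(config$init, D, i_lnu)
      lp <- cpp_lp_grad(cand, prep$y, prep$N, prep$X, prep$pop0, prep$npop,
                        prep$clone0, prep$nclone, prep$cre,
                        unclass(priors))$lp
      if (is.finite(lp)) { theta <- cand; break }
    }
    if (is.null(theta))
      tox_error("failed to find an initial point with finite log-posterior",
                "toxglmm_init_error")
    res <- cpp_sample_chain(prep$y, prep$N, prep$X, prep$pop0, prep$npop,
                            prep$clone0, prep$nclone, prep$cre,
                            unclass(priors), theta,
                            config$n_iterations, config$n_warmup,
                            config$target_accept, config$max_treedepth)
    # back-transform to the constrained scale
    unc <- res$draws
    con <- unc[, seq_len(K), drop = FALSE]
    if (P > 0 || C > 0) {
      sp <- if (P > 0) exp(unc[, K + P + C + 1]) else NULL
      sc <- if (C > 0) exp(unc[, K + P + C + 1 + (P > 0)]) else NULL
      nu <- if (C > 0) exp(unc[, D]) else NULL
      if (P > 0)
        con <- cbind(con, unc[, K + seq_len(P), drop = FALSE] * sp)
      if (C > 0)
        con <- cbind(con, unc[, K + P + seq_len(C), drop = FALSE] * sc)
      if (P > 0) con <- cbind(con, sp)
      if (C > 0) con <- cbind(con, sc, nu)
    }
    draws[, ch, ] <- con
    divergent[, ch] <- res$divergent
    sampler_info[[ch]] <- list(step_size = res$step_size,
                               accept_stat = res$accept_stat,
                               n_leapfrog = res$n_leapfrog,
                               divergent_warmup = res$divergent_warmup,
                               seed = chain_seeds[ch])
  }

  structure(list(draws = draws, divergent = divergent,
                 param_names = param_names, config = config, priors = priors,
                 terms = prep$terms, re_coding = re_coding,
                 data_info = list(n_units = length(prep$y),
                                  pop_levels = prep$pop_levels,
                                  clone_levels = prep$clone_levels),
                 sampler_info = sampler_info),
            class = "toxglmm_draws")
}

#' @export
print.toxglmm_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("toxglmm posterior draws:", d[1], "iterations x", d[2], "chains x",
      d[3], "parameters\n")
  ndiv <- if (is.null(x$divergent)) NA else sum(x$divergent)
  cat("divergent transitions:",
      if (is.na(ndiv)) "not recorded" else ndiv, "\n")
  fixed <- intersect(x$param_names,
                     c(BETA_NAMES, "sigma_pop", "sigma_clone", "nu"))
  med <- vapply(fixed, function(p) median(x$draws[, , p]), numeric(1))
  print(round(med, 3))
  invisible(x)
}

# iterations x chains matrix for one parameter
draws_matrix <- function(fit, parameter) {
  if (!parameter %in% fit$param_names)
    tox_error(paste0("unknown parameter: ", parameter),
              "toxglmm_parameter_error")
  fit$draws[, , parameter, drop = TRUE]
}

# all retained draws for one parameter, pooled across chains
pooled_draws <- function(fit, parameter) as.numeric(draws_matrix(fit, parameter))

#' Persist and restore posterior draws
#'
#' `write_draws()` stores a fit as plain text in a directory: `draws.csv`
#' (chain, iteration, divergence flag, one column per parameter) plus
#' `meta.json` (parameter names, config, priors, data dimensions, per-chain
#' sampler info). `read_draws()` restores a `toxglmm_draws` object
#' losslessly (values round-trip at full double precision).
#'
#' @param fit a `toxglmm_draws` object.
#' @param dir directory to create/use.
#' @return `write_draws()`: `dir` invisibly; `read_draws()`: the restored
#'   object.
#' @export
write_draws <- function(fit, dir) {
  stopifnot(inherits(fit, "toxglmm_draws"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(fit$draws)
  flat <- do.call(rbind, lapply(seq_len(d[2]), function(ch) {
    cbind(data.frame(chain = ch, iteration = seq_len(d[1]),
                     divergent = as.integer(fit$divergent[, ch])),
          as.data.frame(fit$draws[, ch, , drop = TRUE]))
  }))
  names(flat) <- c("chain", "iteration", "divergent", fit$param_names)
  utils::write.csv(format(flat, digits = 17, trim = TRUE, scientific = TRUE),
                   file.path(dir, "draws.csv"), row.names = FALSE, quote = TRUE)
  meta <- list(param_names = fit$param_names,
               config = unclass(fit$config), priors = unclass(fit$priors),
               terms = fit$terms, re_coding = fit$re_coding,
               data_info = fit$data_info, sampler_info = fit$sampler_info)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_draws
#' @export
read_draws <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  flat <- utils::read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  chains <- sort(unique(flat$chain))
  n_kept <- max(flat$iteration)
  pn <- meta$param_names
  draws <- array(NA_real_, dim = c(n_kept, length(chains), length(pn)),
                 dimnames = list(NULL, NULL, pn))
  divergent <- matrix(NA, n_kept, length(chains))
  for (ch in chains) {
    sub <- flat[flat$chain == ch, ]
    sub <- sub[order(sub$iteration), ]
    draws[, ch, ] <- as.matrix(sub[, pn, drop = FALSE])
    divergent[, ch] <- as.logical(sub$divergent)
  }
  cfg <- meta$config
  config <- sampler_config(cfg$n_chains, cfg$n_iterations, cfg$n_warmup,
                           cfg$seed, cfg$target_accept, cfg$max_treedepth,
                           cfg$init)
  priors <- do.call(prior_spec, meta$priors)
  structure(list(draws = draws, divergent = divergent, param_names = pn,
                 config = config, priors = priors, terms = meta$terms,
                 re_coding = meta$re_coding,
                 data_info = meta$data_info,
                 sampler_info = meta$sampler_info),
            class = "toxglmm_draws")
}
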