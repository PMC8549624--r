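#' Numerically stable inverse-logit
#'
#' @param eta numeric vector on the logit scale.
#' @return probabilities `1 / (1 + exp(-eta))`, computed without overflow
#'   for large `|eta|`.
#' @examples
#' inv_logit(0)          # 0.5
#' inv_logit(log(999))   # 0.999
#' @export
inv_logit <- function(eta) {
  p <- ifelse(eta >= 0, 1 / (1 + exp(-eta)), exp(eta) / (1 + exp(eta)))
  as.numeric(p)
}

#' Prior hyperparameters
#'
#' Defaults are the weakly informative priors of the published analysis:
#' `StudentT(3, 0, 5)` on every fixed effect, half-`StudentT(3, 0, 5)` on
#' both random-effect scales, and a shape-rate `Gamma(2, 0.1)` (mean 20) on
#' the Student-t degrees of freedom, following the Juarez-Steel
#' recommendation for estimating t tails. Note the Gamma is shape-RATE: a
#' shape-scale reading would silently put the prior mean at 0.2 instead
#' of 20.
#'
#' @param beta_df,beta_loc,beta_scale Student-t hyperparameters for the
#'   fixed-effect priors.
#' @param sd_df,sd_scale half-Student-t hyperparameters for `sigma_pop` and
#'   `sigma_clone` (location fixed at 0).
#' @param nu_shape,nu_rate Gamma hyperparameters for `nu`.
#' @return an object of class `toxglmm_priors`.
#' @export
prior_spec <- function(beta_df = 3, beta_loc = 0, beta_scale = 5,
                       sd_df = 3, sd_scale = 5,
                       nu_shape = 2, nu_rate = 0.1) {
  if (any(c(beta_df, beta_scale, sd_df, sd_scale, nu_shape, nu_rate) <= 0))
    tox_error("all prior df, scale, shape and rate hyperparameters must be > 0",
              "toxglmm_prior_error")
  structure(list(beta_df = beta_df, beta_loc = beta_loc,
                 beta_scale = beta_scale, sd_df = sd_df, sd_scale = sd_scale,
                 nu_shape = nu_shape, nu_rate = nu_rate),
            class = "toxglmm_priors")
}

#' Full parameter vector of the model
#'
#' @param beta named 8-vector of fixed effects (see [design_matrix()] term
#'   order).
#' @param b_pop,b_clone named random-effect vectors (one entry per
#'   population / retained clone).
#' @param sigma_pop,sigma_clone positive scales.
#' @param nu positive Student-t degrees of freedom.
#' @return an object of class `toxglmm_params`.
#' @export
model_params <- function(beta, b_pop, b_clone, sigma_pop, sigma_clone, nu) {
  if (is.null(names(beta))) names(beta) <- BETA_NAMES
  beta <- beta[BETA_NAMES]
  if (anyNA(beta))
    tox_error("beta must supply all 8 named fixed effects",
              "toxglmm_params_error")
  if (sigma_pop <= 0 || sigma_clone <= 0 || nu <= 0)
    tox_error("sigma_pop, sigma_clone and nu must be > 0",
              "toxglmm_params_error")
  structure(list(beta = beta, b_pop = b_pop, b_clone = b_clone,
                 sigma_pop = sigma_pop, sigma_clone = sigma_clone, nu = nu),
            class = "toxglmm_params")
}

#' Linear predictor on the logit scale
#'
#' \eqn{\eta_i = x_i'\beta + c_i (b_{pop(i)} + b_{clone(i)})} where
#' \eqn{c_i} is the signed pesticide code (so a clone's effect raises
#' survival in one arm and lowers it in the other by equal logit amounts),
#' or a 0/1 indicator under `re_coding = "indicator"`.
#'
#' @param params a [model_params()].
#' @param units a unit table; population and clone labels index the
#'   random-effect vectors by name.
#' @param re_coding see [simulate_outcomes()].
#' @return numeric vector of per-unit logits.
#' @export
linear_predictor <- function(params, units, re_coding = "signed") {
  stopifnot(inherits(params, "toxglmm_params"))
  X <- design_matrix(units)
  missing_pop <- setdiff(unique(units$population_id), names(params$b_pop))
  missing_clone <- setdiff(unique(units$clone_id), names(params$b_clone))
  if (length(missing_pop) || length(missing_clone))
    tox_error(paste0("random-effect entries missing for: ",
                     paste(c(missing_pop, missing_clone), collapse = ", ")),
              "toxglmm_params_error")
  cre <- re_multiplier(units, re_coding)
  unname(drop(X %*% params$beta) +
           cre * (params$b_pop[units$population_id] +
                    params$b_clone[units$clone_id]))
}

#' Binomial log-likelihood
#'
#' Sum over units of the full binomial log-pmf (combinatorial constant
#' included) at the model survival probabilities.
#'
#' @inheritParams linear_predictor
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(params, units, re_coding = "signed") {
  units <- validate_units(units, require_outcomes = TRUE)
  eta <- linear_predictor(params, units, re_coding)
  sum(dbinom(units$n_surviving, units$n_start, inv_logit(eta), log = TRUE))
}

# scaled Student-t log-density
dt_scaled_log <- function(x, df, loc = 0, scale = 1) {
  dt((x - loc) / scale, df = df, log = TRUE) - log(scale)
}

#' Joint log-prior density
#'
#' Student-t on each fixed effect, half-Student-t on the scales, Gamma on
#' `nu`, Normal(0, `sigma_pop`) on each population effect and
#' Student-t(`nu`, 0, `sigma_clone`) on each clone effect.
#'
#' @param params a [model_params()].
#' @param priors a [prior_spec()].
#' @return scalar log-density; `-Inf` outside the support.
#' @export
log_prior <- function(params, priors = prior_spec()) {
  stopifnot(inherits(params, "toxglmm_params"), inherits(priors, "toxglmm_priors"))
  if (params$sigma_pop <= 0 || params$sigma_clone <= 0 || params$nu <= 0)
    return(-Inf)
  sum(dt_scaled_log(params$beta, priors$beta_df, priors$beta_loc,
                    priors$beta_scale)) +
    log(2) + dt_scaled_log(params$sigma_pop, priors$sd_df, 0, priors$sd_scale) +
    log(2) + dt_scaled_log(params$sigma_clone, priors$sd_df, 0, priors$sd_scale) +
    dgamma(params$nu, shape = priors$nu_shape, rate = priors$nu_rate,
           log = TRUE) +
    sum(dnorm(params$b_pop, 0, params$sigma_pop, log = TRUE)) +
    sum(dt_scaled_log(params$b_clone, params$nu, 0, params$sigma_clone))
}

#' Joint log-posterior (up to a constant)
#'
#' @inheritParams log_likelihood
#' @inheritParams log_prior
#' @return `log_likelihood(params, units) + log_prior(params, priors)`.
#' @export
log_posterior <- function(params, units, priors = prior_spec(),
                          re_coding = "signed") {
  log_likelihood(params, units, re_coding) + log_prior(params, priors)
}

#' Map between constrained parameters and the sampler's unconstrained vector
#'
#' The sampler works on `(beta, z_pop, z_clone, log sigma_pop,
#' log sigma_clone, log nu)` with non-centered random effects
#' (`b = sigma * z`). `par_transform()` produces that vector;
#' `par_untransform()` inverts it.
#'
#' @param params a [model_params()].
#' @return `par_transform()`: named numeric vector.
#' @export
par_transform <- function(params) {
  stopifnot(inherits(params, "toxglmm_params"))
  theta <- c(params$beta,
             params$b_pop / params$sigma_pop,
             params$b_clone / params$sigma_clone,
             log(params$sigma_pop), log(params$sigma_clone), log(params$nu))
  names(theta) <- c(BETA_NAMES,
                    paste0("z_pop[", names(params$b_pop), "]"),
                    paste0("z_clone[", names(params$b_clone), "]"),
                    "log_sigma_pop", "log_sigma_clone", "log_nu")
  theta
}

#' @rdname par_transform
#' @param theta unconstrained vector laid out as produced by
#'   `par_transform()`.
#' @param pop_levels,clone_levels group labels giving the random-effect
#'   dimensions.
#' @return `par_untransform()`: a [model_params()].
#' @export
par_untransform <- function(theta, pop_levels, clone_levels) {
  P <- length(pop_levels); C <- length(clone_levels)
  if (length(theta) != 8 + P + C + 3)
    tox_error("theta length does not match the group structure",
              "toxglmm_params_error")
  if (any(!is.finite(theta)))
    tox_error("non-finite values in theta", "toxglmm_params_error")
  theta <- unname(theta)
  beta <- theta[1:8]
  names(beta) <- BETA_NAMES
  sigma_pop <- exp(theta[8 + P + C + 1])
  sigma_clone <- exp(theta[8 + P + C + 2])
  nu <- exp(theta[8 + P + C + 3])
  b_pop <- sigma_pop * theta[8 + seq_len(P)]
  b_clone <- sigma_clone * theta[8 + P + seq_len(C)]
  names(b_pop) <- pop_levels
  names(b_clone) <- clone_levels
  model_params(beta, b_pop, b_clone, sigma_pop, sigma_clone, nu)
}

# Log-posterior and gradient on the unconstrained scale (C++ backend); used
# by the sampler and exposed internally for finite-difference checks. The
# value differs from log_posterior() by the change-of-variables terms
# (P log sigma_pop + C log sigma_clone from non-centering, plus the three
# log-Jacobians of the log transforms).
unconstrained_lp <- function(theta, units, priors = prior_spec(),
                             terms = MODEL_TERMS, include_random_effects = TRUE,
                             re_coding = "signed") {
  prep <- prepare_model_data(units, terms, include_random_effects, re_coding)
  cpp_lp_grad(theta, prep$y, prep$N, prep$X, prep$pop0, prep$npop,
              prep$clone0, prep$nclone, prep$cre, unclass(priors))
}

# shared R -> C++ data marshalling
prepare_model_data <- function(units, terms = MODEL_TERMS,
                               include_random_effects = TRUE,
                               re_coding = "signed") {
  units <- validate_units(units, require_outcomes = TRUE)
  X <- design_matrix(units, terms)
  if (include_random_effects) {
    g <- group_indices(units)
    pop0 <- g$pop - 1L; clone0 <- g$clone - 1L
    npop <- length(g$pop_levels); nclone <- length(g$clone_levels)
    pop_levels <- g$pop_levels; clone_levels <- g$clone_levels
  } else {
    pop0 <- clone0 <- integer(nrow(units))
    npop <- nclone <- 0L
    pop_levels <- clone_levels <- character()
  }
  list(y = as.numeric(units$n_surviving), N = as.numeric(units$n_start),
       X = X, pop0 = pop0, clone0 = clone0, npop = npop, nclone = nclone,
       cre = re_multiplier(units, re_coding),
       pop_levels = pop_levels, clone_levels = clone_levels,
       terms = colnames(X))
}
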