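# --- convergence diagnostics -------------------------------------------------
#
# Rank-normalized split-chain formulations (the modern recommendation the
# published analysis follows): chains are split in half, all draws are
# jointly rank-transformed to normal scores, and R-hat / ESS are computed on
# the scores. R-hat additionally takes the maximum with the same statistic on
# folded draws (|x - median|), so both location and scale mismatches between
# chains are caught. The plain Gelman-Rubin variant is deliberately not
# offered.

as_chain_matrix <- function(x, parameter = NULL) {
  if (inherits(x, "toxglmm_draws")) {
    if (is.null(parameter))
      tox_error("parameter must be named for a toxglmm_draws object",
                "toxglmm_parameter_error")
    return(draws_matrix(x, parameter))
  }
  as.matrix(x)
}

split_chains <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  cbind(m[seq_len(half), , drop = FALSE],
        m[seq.int(n - half + 1, n), , drop = FALSE])
}

rank_normalize <- function(m) {
  r <- rank(m, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

check_degenerate <- function(m) {
  if (all(m == m[1]))
    tox_error("parameter has zero variance across all draws",
              "toxglmm_degenerate_error")
}

basic_rhat <- function(m) {
  n <- nrow(m)
  means <- colMeans(m)
  vars <- apply(m, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Rank-normalized split R-hat
#'
#' @param x a `toxglmm_draws` object, or an iterations-by-chains numeric
#'   matrix.
#' @param parameter parameter name (required when `x` is a fit object). When
#'   `x` is a fit and `parameter` is `NULL`... must be supplied; use
#'   [diagnostics_report()] for all parameters at once.
#' @return scalar R-hat (values below ~1.01 indicate convergence).
#' @export
split_rhat <- function(x, parameter = NULL) {
  m <- as_chain_matrix(x, parameter)
  if (ncol(m) < 2) tox_error("at least 2 chains required", "toxglmm_config_error")
  if (nrow(m) < 4) tox_error("at least 4 draws per chain required",
                             "toxglmm_config_error")
  check_degenerate(m)
  s <- split_chains(m)
  bulk <- basic_rhat(rank_normalize(s))
  folded <- basic_rhat(rank_normalize(abs(s - median(s))))
  max(bulk, folded)
}

# combined-chain autocorrelation ESS (Geyer initial monotone sequence)
ess_mean <- function(m) {
  n <- nrow(m); nc <- ncol(m)
  vars <- apply(m, 2, var)
  W <- mean(vars)
  B <- n * var(colMeans(m))
  var_plus <- (n - 1) / n * W + B / n
  acov <- vapply(seq_len(nc), function(c) {
    a <- acf(m[, c], lag.max = n - 1, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * vars[c] * (n - 1) / n
  }, numeric(n))
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer paired sums Gamma_k = rho_{2k} + rho_{2k+1}: keep the initial
  # positive sequence, enforce monotone non-increase, tau = -1 + 2 sum Gamma
  gamma_sums <- numeric(0)
  k <- 0
  while (2 * k + 2 <= n) {
    gk <- rho[2 * k + 1] + rho[2 * k + 2]
    if (!is.finite(gk) || gk <= 0) break
    gamma_sums <- c(gamma_sums, gk)
    k <- k + 1
  }
  gamma_sums <- cummin(gamma_sums)
  tau <- -1 + 2 * sum(gamma_sums)
  total <- n * nc
  tau <- max(tau, 1 / log10(max(total, 10)))  # cap super-efficiency gently
  total / tau
}

#' Rank-normalized bulk effective sample size
#'
#' @inheritParams split_rhat
#' @return scalar bulk ESS estimate.
#' @export
effective_sample_size <- function(x, parameter = NULL) {
  m <- as_chain_matrix(x, parameter)
  if (ncol(m) < 2) tox_error("at least 2 chains required", "toxglmm_config_error")
  if (nrow(m) < 4) tox_error("at least 4 draws per chain required",
                             "toxglmm_config_error")
  check_degenerate(m)
  ess_mean(rank_normalize(split_chains(m)))
}

#' Divergent-transition counts per chain
#'
#' @param fit a `toxglmm_draws` object.
#' @return integer vector of per-chain counts, or an object of class
#'   `toxglmm_not_applicable` when the draws carry no divergence flags
#'   (e.g. imported from a sampler that does not define them) — never a
#'   silent 0.
#' @export
divergence_count <- function(fit) {
  stopifnot(inherits(fit, "toxglmm_draws"))
  if (is.null(fit$divergent) || all(is.na(fit$divergent)))
    return(structure(list(message = "divergence flags not recorded"),
                     class = "toxglmm_not_applicable"))
  counts <- colSums(fit$divergent)
  names(counts) <- paste0("chain_", seq_along(counts))
  counts
}

#' @export
print.toxglmm_not_applicable <- function(x, ...) {
  cat("not applicable:", x$message, "\n")
  invisible(x)
}

#' Convergence report for all parameters
#'
#' @param fit a `toxglmm_draws` object.
#' @param rhat_threshold pass/fail cutoff (default 1.01, the published
#'   criterion).
#' @param parameters parameters to report (default: all).
#' @return list with a per-parameter `table` (R-hat, bulk ESS), per-chain
#'   `divergences`, and a logical `converged` flag (all reported R-hat below
#'   the threshold). Serializable with `jsonlite`.
#' @export
diagnostics_report <- function(fit, rhat_threshold = 1.01,
                               parameters = fit$param_names) {
  tab <- data.frame(parameter = parameters,
                    rhat = vapply(parameters, function(p)
                      split_rhat(fit, p), numeric(1)),
                    ess_bulk = vapply(parameters, function(p)
                      effective_sample_size(fit, p), numeric(1)),
                    row.names = NULL)
  div <- divergence_count(fit)
  list(table = tab,
       divergences = if (inherits(div, "toxglmm_not_applicable"))
         "not applicable" else as.list(div),
       rhat_threshold = rhat_threshold,
       max_rhat = max(tab$rhat),
       converged = all(tab$rhat < rhat_threshold))
}

# --- posterior predictive checks --------------------------------------------

#' Posterior predictive replication and goodness-of-fit summary
#'
#' Thins the retained draws to `n_replicates`, simulates a replicated
#' outcome vector from each draw's full parameter set (fixed effects plus
#' the draw's own random effects), and compares observed and replicated
#' data through (a) the distribution of per-unit survivor counts and (b)
#' arm-wise discrepancy statistics: mean and variance of the per-unit
#' survival fraction within the control and exposed arms. Tail probabilities
#' are `Pr(T(y_rep) >= T(y_obs))` with ties counted as half.
#'
#' @param fit a `toxglmm_draws` object from a full-model fit.
#' @param units the unit table the model was fitted to.
#' @param n_replicates number of replicated datasets (0 gives an empty
#'   summary).
#' @param seed integer seed for the binomial replication noise.
#' @return an object of class `toxglmm_ppc`: list with `y_rep` (matrix
#'   units x replicates), `count_table` (observed vs expected replicated
#'   frequencies of survivor counts) and `arm_stats` (per arm and statistic:
#'   observed value, replicated mean, tail probability).
#' @export
posterior_predictive <- function(fit, units, n_replicates = 200, seed = 1) {
  stopifnot(inherits(fit, "toxglmm_draws"))
  units <- validate_units(units, require_outcomes = TRUE)
  d <- dim(fit$draws)
  total <- d[1] * d[2]
  if (n_replicates > total)
    tox_error("n_replicates exceeds the number of retained draws",
              "toxglmm_ppc_error")
  empty <- n_replicates == 0
  X <- design_matrix(units, fit$terms)
  cre <- re_multiplier(units, fit$re_coding)
  flat <- matrix(fit$draws, nrow = total, ncol = d[3])
  colnames(flat) <- fit$param_names
  idx <- if (empty) integer() else
    unique(round(seq(1, total, length.out = n_replicates)))
  beta_cols <- BETA_NAMES[match(fit$terms, MODEL_TERMS)]
  pop_cols <- paste0("b_pop[", units$population_id, "]")
  clone_cols <- paste0("b_clone[", units$clone_id, "]")
  has_re <- all(c(pop_cols, clone_cols) %in% colnames(flat))
  set.seed(seed)
  y_rep <- matrix(NA_integer_, nrow(units), length(idx))
  for (j in seq_along(idx)) {
    row <- flat[idx[j], ]
    eta <- drop(X %*% row[beta_cols])
    if (has_re) eta <- eta + cre * (row[pop_cols] + row[clone_cols])
    y_rep[, j] <- rbinom(nrow(units), units$n_start, inv_logit(eta))
  }

  if (empty) {
    return(structure(list(y_rep = y_rep,
                          count_table = data.frame(),
                          arm_stats = data.frame()),
                     class = "toxglmm_ppc"))
  }
  counts <- 0:max(units$n_start)
  count_table <- data.frame(
    n_surviving = counts,
    observed = vapply(counts, function(k) sum(units$n_surviving == k),
                      numeric(1)),
    replicated_mean = vapply(counts, function(k) mean(colSums(y_rep == k)),
                             numeric(1)))
  arms <- list(control = units$pesticide == "control",
               chlorpyrifos = units$pesticide == "chlorpyrifos")
  arms <- arms[vapply(arms, any, logical(1))]
  stat_fns <- list(mean_survival = function(y, sel)
                     mean(y[sel] / units$n_start[sel]),
                   var_survival = function(y, sel)
                     var(y[sel] / units$n_start[sel]))
  rows <- list()
  for (a in names(arms)) for (s in names(stat_fns)) {
    obs <- stat_fns[[s]](units$n_surviving, arms[[a]])
    rep_vals <- apply(y_rep, 2, function(y) stat_fns[[s]](y, arms[[a]]))
    tail_p <- (sum(rep_vals > obs) + 0.5 * sum(rep_vals == obs)) /
      length(rep_vals)
    rows[[paste(a, s)]] <- data.frame(arm = a, statistic = s, observed = obs,
                                      replicated_mean = mean(rep_vals),
                                      tail_prob = tail_p)
  }
  structure(list(y_rep = y_rep, count_table = count_table,
                 arm_stats = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "toxglmm_ppc")
}

#' @export
print.toxglmm_ppc <- function(x, ...) {
  cat("posterior predictive check,", ncol(x$y_rep), "replicated datasets\n")
  if (nrow(x$arm_stats)) print(x$arm_stats, row.names = FALSE)
  invisible(x)
}
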