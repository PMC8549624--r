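# Quantile convention: linear interpolation between order statistics
# (stats::quantile type 7). Small-sample equal-tailed interval endpoints
# depend on this choice, so it is fixed and documented here.
eti <- function(x, level) {
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a), type = 7, names = FALSE))
}

pr_positive <- function(x) (sum(x > 0) + 0.5 * sum(x == 0)) / length(x)

#' Posterior summary table
#'
#' Per parameter: posterior median, equal-tailed credible intervals at the
#' requested levels (default 80% and 95%, bounded by the corresponding
#' sample quantiles), and the posterior probability of being positive (draws
#' exactly at zero count as half).
#'
#' @param fit a `toxglmm_draws` object.
#' @param parameters parameters to summarize (default: all).
#' @param levels credible-interval levels.
#' @return a `data.frame` with one row per parameter.
#' @export
summarize_parameters <- function(fit, parameters = fit$param_names,
                                 levels = c(0.8, 0.95)) {
  stopifnot(inherits(fit, "toxglmm_draws"), length(parameters) > 0)
  rows <- lapply(parameters, function(p) {
    x <- pooled_draws(fit, p)
    out <- data.frame(parameter = p, median = median(x))
    for (lv in sort(levels)) {
      q <- eti(x, lv)
      out[[paste0("lower_", round(100 * lv))]] <- q[1]
      out[[paste0("upper_", round(100 * lv))]] <- q[2]
    }
    out$pr_positive <- pr_positive(x)
    out
  })
  do.call(rbind, rows)
}

#' Posterior sign probability
#'
#' Fraction of retained draws with the stated sign (ties at zero count as
#' half).
#'
#' @param fit a `toxglmm_draws` object.
#' @param parameter parameter name.
#' @param direction `"positive"` or `"negative"`.
#' @return probability in \[0, 1\].
#' @export
sign_probability <- function(fit, parameter,
                             direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  x <- pooled_draws(fit, parameter)
  p <- pr_positive(x)
  if (direction == "positive") p else 1 - p
}

marginal_eta <- function(fit, cpf, urb, temp) {
  d <- dim(fit$draws)
  flat <- matrix(fit$draws, nrow = d[1] * d[2], ncol = d[3])
  colnames(flat) <- fit$param_names
  codes <- c(intercept = 1, cpf = cpf, urb = urb, temp = temp,
             `cpf:urb` = cpf * urb, `cpf:temp` = cpf * temp,
             `urb:temp` = urb * temp, `cpf:urb:temp` = cpf * urb * temp)
  needed <- names(codes)[codes != 0]
  missing_terms <- setdiff(needed, fit$terms)
  if (length(missing_terms))
    tox_error(paste0("condition needs model term(s) absent from the fit: ",
                     paste(missing_terms, collapse = ", ")),
              "toxglmm_condition_error")
  beta_cols <- BETA_NAMES[match(fit$terms, MODEL_TERMS)]
  drop(flat[, beta_cols, drop = FALSE] %*% codes[fit$terms])
}

#' Marginal survival probability for a treatment condition
#'
#' Per-draw survival probability with the stated treatment codes, the
#' remaining centered covariates fixed at 0 (their mean, i.e. averaged over
#' the design), and the random effects fixed at 0 — the "average condition,
#' population and clone". Codes are on the model's centered scale:
#' `-0.5` / `+0.5` select a level, `0` averages over it.
#'
#' @param fit a `toxglmm_draws` object.
#' @param cpf,urb,temp condition codes in `c(-0.5, 0, 0.5)`.
#' @param level credible level (default 0.95).
#' @return list of class `toxglmm_marginal` with the condition, the
#'   posterior `median`, `lower`/`upper` interval bounds, and the per-draw
#'   probabilities in `draws`.
#' @examples \donttest{
#' # control-arm survival at average urbanization/temperature:
#' # marginal_survival(fit, cpf = -0.5)
#' }
#' @export
marginal_survival <- function(fit, cpf = 0, urb = 0, temp = 0, level = 0.95) {
  p <- inv_logit(marginal_eta(fit, cpf, urb, temp))
  q <- eti(p, level)
  structure(list(condition = c(cpf = cpf, urb = urb, temp = temp),
                 median = median(p), lower = q[1], upper = q[2],
                 level = level, draws = p),
            class = "toxglmm_marginal")
}

#' Probability-scale contrast for one variable
#'
#' Per-draw difference in survival probability between the two levels of
#' `variable` (`+0.5` minus `-0.5`), at the stated base condition for the
#' other variables. The contrast is summarized draw-wise — never as a
#' difference of summaries — and is reported both in percentage points and
#' on the proportion scale.
#'
#' @param fit a `toxglmm_draws` object.
#' @param variable `"cpf"`, `"urb"` or `"temp"`.
#' @param cpf,urb,temp base condition codes for the variables not being
#'   contrasted (the entry for `variable` itself is ignored).
#' @param level credible level.
#' @return list of class `toxglmm_contrast` with medians and intervals on
#'   both scales and the per-draw differences (proportion scale) in `draws`.
#' @export
marginal_effect_pp <- function(fit, variable = c("cpf", "urb", "temp"),
                               cpf = 0, urb = 0, temp = 0, level = 0.95) {
  variable <- match.arg(variable)
  base <- list(cpf = cpf, urb = urb, temp = temp)
  hi <- lo <- base
  hi[[variable]] <- 0.5
  lo[[variable]] <- -0.5
  p_hi <- inv_logit(marginal_eta(fit, hi$cpf, hi$urb, hi$temp))
  p_lo <- inv_logit(marginal_eta(fit, lo$cpf, lo$urb, lo$temp))
  delta <- p_hi - p_lo
  q <- eti(delta, level)
  structure(list(variable = variable, base = unlist(base), level = level,
                 median_pp = 100 * median(delta),
                 lower_pp = 100 * q[1], upper_pp = 100 * q[2],
                 median_prop = median(delta), lower_prop = q[1],
                 upper_prop = q[2], draws = delta),
            class = "toxglmm_contrast")
}

#' @export
print.toxglmm_marginal <- function(x, ...) {
  cat(sprintf("marginal survival at (cpf=%g, urb=%g, temp=%g): %.4f [%.4f, %.4f] (%d%% CrI)\n",
              x$condition[1], x$condition[2], x$condition[3],
              x$median, x$lower, x$upper, round(100 * x$level)))
  invisible(x)
}

#' @export
print.toxglmm_contrast <- function(x, ...) {
  cat(sprintf("marginal effect of %s: %.2f pp [%.2f, %.2f] (%d%% CrI)\n",
              x$variable, x$median_pp, x$lower_pp, x$upper_pp,
              round(100 * x$level)))
  invisible(x)
}

#' Prior sensitivity analysis
#'
#' Refits the model once per prior specification (same data, same sampler
#' configuration and seed policy) and tabulates each fixed effect's
#' posterior median and 95% interval side by side, together with the
#' maximum absolute median shift across specifications. Individual fit
#' failures are reported per specification; the remaining fits are still
#' returned.
#'
#' @param units a unit table with outcomes.
#' @param prior_specs named list of at least two [prior_spec()] objects.
#' @param config a [sampler_config()].
#' @param parameters parameters to compare (default: the fixed effects and
#'   scales).
#' @param ... passed to [sample_posterior()].
#' @return list of class `toxglmm_sensitivity`: `table` (long data.frame:
#'   spec, parameter, median, lower_95, upper_95), `max_shift` (named
#'   vector per parameter), `failures` (named character vector of error
#'   messages, possibly empty), and the individual `fits`.
#' @export
prior_sensitivity <- function(units, prior_specs, config = sampler_config(),
                              parameters = NULL, ...) {
  if (length(prior_specs) < 2)
    tox_error("need at least two prior specifications",
              "toxglmm_config_error")
  if (is.null(names(prior_specs)))
    names(prior_specs) <- paste0("spec_", seq_along(prior_specs))
  fits <- list(); failures <- character()
  for (nm in names(prior_specs)) {
    fits[[nm]] <- tryCatch(
      sample_posterior(units, prior_specs[[nm]], config, ...),
      error = function(e) {
        failures[[nm]] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  rows <- lapply(names(fits)[ok], function(nm) {
    pars <- parameters
    if (is.null(pars))
      pars <- intersect(fits[[nm]]$param_names,
                        c(BETA_NAMES, "sigma_pop", "sigma_clone", "nu"))
    s <- summarize_parameters(fits[[nm]], pars, levels = 0.95)
    data.frame(spec = nm, parameter = s$parameter, median = s$median,
               lower_95 = s$lower_95, upper_95 = s$upper_95)
  })
  table <- do.call(rbind, rows)
  max_shift <- if (sum(ok) >= 2) {
    vapply(split(table$median, table$parameter),
           function(v) diff(range(v)), numeric(1))
  } else numeric(0)
  structure(list(table = table, max_shift = max_shift, failures = failures,
                 fits = fits[ok]),
            class = "toxglmm_sensitivity")
}
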