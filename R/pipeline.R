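#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> fit -> diagnose -> summarize -> ppc ->
#' prior sensitivity (optional), writing every artifact plus a manifest to
#' `out_dir`. The configuration is a nested list (or a path to a YAML/JSON
#' file) with sections mirroring the package's building blocks:
#'
#' * `data`: either `list(path = "units.csv", mapping = ...)` to load a
#'   dataset, or `list(simulate = list(truth = "paper_like", seed = 1,
#'   n_oversized = 4, design = list(...)))` to generate one.
#' * `priors`: arguments for [prior_spec()] (optional).
#' * `sampler`: arguments for [sampler_config()] (optional).
#' * `ppc`: `list(n_replicates = 200, seed = 1)` (optional).
#' * `sensitivity`: named list of prior-spec argument lists (optional).
#' * `rhat_threshold`: convergence cutoff for the manifest flag
#'   (default 1.01).
#'
#' @param config nested list or file path.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the fit, the diagnostics report, the
#'   summary table, marginal estimates, the PPC, the sensitivity result (or
#'   `NULL`) and the manifest. The manifest's `converged` field is `FALSE`
#'   if any reported R-hat meets or exceeds the threshold.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- load_config_file(config)
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("toxglmm")),
                   config = config, stages = list(), files = character())
  log_stage <- function(stage, ...) {
    message(sprintf("[toxglmm] %s: %s", stage, paste0(..., collapse = " ")))
    manifest$stages[[stage]] <<- "done"
  }

  # data
  if (!is.null(config$data$path)) {
    units <- read_units(config$data$path, config$data$mapping)
    log_stage("data", "loaded ", nrow(units), " units from ", config$data$path)
  } else {
    sim <- config$data$simulate
    spec <- do.call(design_spec, sim$design %||% list())
    units <- simulate_dataset(spec, sim$truth %||% "paper_like",
                              seed = sim$seed %||% 1,
                              n_oversized = sim$n_oversized %||% 4)
    log_stage("data", "simulated ", nrow(units), " units (seed ",
              sim$seed %||% 1, ")")
  }
  data_path <- file.path(out_dir, "units.csv")
  write_units(units, data_path)

  priors <- do.call(prior_spec, config$priors %||% list())
  scfg <- do.call(sampler_config, config$sampler %||% list())

  fit <- sample_posterior(units, priors, scfg)
  log_stage("fit", "4+ dims: ", length(fit$param_names), " parameters, seed ",
            scfg$seed)
  draws_dir <- file.path(out_dir, "draws")
  write_draws(fit, draws_dir)

  report <- diagnostics_report(fit, config$rhat_threshold %||% 1.01)
  jsonlite::write_json(report, file.path(out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_stage("diagnose", "max R-hat ", round(report$max_rhat, 4))

  summary_tab <- summarize_parameters(
    fit, intersect(fit$param_names, c(BETA_NAMES, "sigma_pop", "sigma_clone",
                                      "nu")))
  utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  marginals <- list(
    control = marginal_survival(fit, cpf = -0.5),
    exposed = marginal_survival(fit, cpf = 0.5),
    exposed_urban = marginal_survival(fit, cpf = 0.5, urb = 0.5),
    exposed_rural = marginal_survival(fit, cpf = 0.5, urb = -0.5),
    cpf_effect = marginal_effect_pp(fit, "cpf"),
    urb_effect = marginal_effect_pp(fit, "urb"),
    temp_effect = marginal_effect_pp(fit, "temp"))
  jsonlite::write_json(lapply(marginals, function(m)
    m[setdiff(names(m), "draws")]), file.path(out_dir, "marginals.json"),
    auto_unbox = TRUE, digits = NA)
  log_stage("summarize", "summary.csv + marginals.json")

  ppc <- NULL
  if (!is.null(config$ppc)) {
    ppc <- posterior_predictive(fit, units,
                                n_replicates = config$ppc$n_replicates %||% 200,
                                seed = config$ppc$seed %||% 1)
    jsonlite::write_json(list(count_table = ppc$count_table,
                              arm_stats = ppc$arm_stats),
                         file.path(out_dir, "ppc.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    log_stage("ppc", nrow(ppc$arm_stats), " discrepancy statistics")
  }

  sensitivity <- NULL
  if (!is.null(config$sensitivity)) {
    specs <- lapply(config$sensitivity, function(a) do.call(prior_spec, a))
    sensitivity <- prior_sensitivity(units, specs, scfg)
    jsonlite::write_json(list(table = sensitivity$table,
                              max_shift = as.list(sensitivity$max_shift),
                              failures = as.list(sensitivity$failures)),
                         file.path(out_dir, "sensitivity.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    log_stage("sensitivity", length(specs), " prior specifications")
  }

  manifest$files <- list.files(out_dir, recursive = TRUE)
  manifest$seed <- scfg$seed
  manifest$converged <- report$converged
  manifest$max_rhat <- report$max_rhat
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(units = units, fit = fit, diagnostics = report,
                 summary = summary_tab, marginals = marginals, ppc = ppc,
                 sensitivity = sensitivity, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_pipeline_config <- function(config) {
  if (!is.list(config))
    tox_error("config must be a list or a path to a YAML/JSON file",
              "toxglmm_config_error")
  if (is.null(config$data))
    tox_error("config$data is required (path or simulate section)",
              "toxglmm_config_error")
  s <- config$sampler
  if (!is.null(s$n_warmup) && !is.null(s$n_iterations) &&
      s$n_warmup >= s$n_iterations)
    tox_error("config$sampler$n_warmup must be smaller than config$sampler$n_iterations",
              "toxglmm_config_error")
  config
}

#' Simulation-based parameter-recovery experiment
#'
#' Simulates `n_replicates` datasets from a truth, fits each one, and
#' reports per-parameter recovery metrics: mean posterior-median bias,
#' empirical coverage of the 95% equal-tailed interval, and mean interval
#' width. Per-replicate fit failures are logged, excluded, and counted.
#'
#' @param truth a [simulation_truth()] or preset name.
#' @param spec a [design_spec()].
#' @param n_replicates number of simulated datasets (0 gives an empty
#'   report).
#' @param config a [sampler_config()]; replicate `r` simulates with seed
#'   `seed + r` and samples with a chain substream of the same seed.
#' @param parameters parameters to score (default: the 8 fixed effects plus
#'   the scales and `nu`).
#' @param n_oversized oversized units per simulated dataset.
#' @return a `data.frame` with one row per parameter (`true_value`,
#'   `mean_bias`, `coverage_95`, `mean_ci_width`, `n_fits`); failed
#'   replicates are recorded in the `failures` attribute. The per-replicate
#'   posterior medians are attached as attribute `medians`.
#' @export
recovery_experiment <- function(truth, spec = design_spec(excluded_clones = "u2.5"),
                                n_replicates = 25,
                                config = sampler_config(n_iterations = 1500,
                                                        n_warmup = 750),
                                parameters = c(BETA_NAMES, "sigma_pop",
                                               "sigma_clone", "nu"),
                                n_oversized = 4) {
  if (is.character(truth)) truth <- truth_preset(truth)
  true_vals <- c(truth$beta, sigma_pop = truth$sigma_pop,
                 sigma_clone = truth$sigma_clone, nu = truth$nu)
  if (n_replicates == 0) {
    out <- data.frame(parameter = character(), true_value = numeric(),
                      mean_bias = numeric(), coverage_95 = numeric(),
                      mean_ci_width = numeric(), n_fits = integer())
    attr(out, "failures") <- character()
    return(out)
  }
  med <- lo <- hi <- matrix(NA_real_, n_replicates, length(parameters),
                            dimnames = list(NULL, parameters))
  rhat_max <- rep(NA_real_, n_replicates)
  failures <- character()
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      units <- simulate_dataset(spec, truth, seed = config$seed + r,
                                n_oversized = n_oversized)
      cfg <- config
      cfg$seed <- as.integer(config$seed + 10000L + r)
      fit <- sample_posterior(units, prior_spec(), cfg)
      s <- summarize_parameters(fit, parameters, levels = 0.95)
      list(s = s,
           rhat = max(vapply(parameters, function(p) split_rhat(fit, p),
                             numeric(1))))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(res)))
      next
    }
    med[r, ] <- res$s$median
    lo[r, ] <- res$s$lower_95
    hi[r, ] <- res$s$upper_95
    rhat_max[r] <- res$rhat
  }
  ok <- !is.na(med[, 1])
  out <- data.frame(
    parameter = parameters,
    true_value = unname(true_vals[parameters]),
    mean_bias = colMeans(med[ok, , drop = FALSE]) - true_vals[parameters],
    coverage_95 = colMeans(lo[ok, , drop = FALSE] <=
                             rep(true_vals[parameters], each = sum(ok)) &
                           hi[ok, , drop = FALSE] >=
                             rep(true_vals[parameters], each = sum(ok))),
    mean_ci_width = colMeans(hi[ok, , drop = FALSE] - lo[ok, , drop = FALSE]),
    n_fits = sum(ok), row.names = NULL)
  attr(out, "failures") <- failures
  attr(out, "medians") <- med
  attr(out, "rhat_max") <- rhat_max
  out
}
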