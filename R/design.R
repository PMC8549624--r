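#' Specify a factorial acute-toxicity design
#'
#' Describes a balanced design of the form: 2 urbanization classes (rural,
#' urban) x `n_populations_per_class` populations x `n_clones_per_population`
#' clones x 2 pesticide treatments (control, chlorpyrifos) x 2 temperatures
#' (20, 24 degrees C) x `n_replicates` replicate jars. Clones can be excluded
#' wholesale (e.g. a clone lost to parasitic infection), and individual units
#' can be flagged as having started with `oversized_n_start` instead of
#' `n_start` individuals.
#'
#' Population labels are `r1..` / `u1..`; clone labels are globally unique in
#' the `u2.5` style (population label, dot, clone number).
#'
#' @param n_populations_per_class populations per urbanization class
#'   (default 5).
#' @param n_clones_per_population clones per population (default 5).
#' @param n_replicates replicate jars per clone x treatment cell (default 2).
#' @param excluded_clones character vector of clone labels dropped from the
#'   design entirely (all their units).
#' @param oversized_units integer indices (in the deterministic design order)
#'   of units that start with `oversized_n_start` individuals.
#' @param n_start individuals per jar at the start (default 5).
#' @param oversized_n_start count for the oversized units (default 6).
#' @return an object of class `toxglmm_design_spec`.
#' @seealso [build_design()]
#' @export
design_spec <- function(n_populations_per_class = 5,
                        n_clones_per_population = 5,
                        n_replicates = 2,
                        excluded_clones = character(),
                        oversized_units = integer(),
                        n_start = 5,
                        oversized_n_start = 6) {
  stopifnot(n_populations_per_class >= 1, n_clones_per_population >= 1,
            n_replicates >= 1, n_start >= 1, oversized_n_start >= 1)
  structure(
    list(n_populations_per_class = as.integer(n_populations_per_class),
         n_clones_per_population = as.integer(n_clones_per_population),
         n_replicates = as.integer(n_replicates),
         excluded_clones = as.character(excluded_clones),
         oversized_units = as.integer(oversized_units),
         n_start = as.integer(n_start),
         oversized_n_start = as.integer(oversized_n_start)),
    class = "toxglmm_design_spec")
}

#' Build the experimental-unit table for a design
#'
#' Expands a [design_spec()] into one row per experimental unit (replicate
#' jar), in a deterministic order: sorted by population, clone, pesticide
#' (control before chlorpyrifos), temperature (20 before 24), replicate.
#' Outcomes (`n_surviving`) are `NA` until observed or simulated.
#'
#' The default spec mirrors the motivating study: 400 units, or 392 after excluding
#' one clone (each fully excluded clone removes
#' 2 pesticide x 2 temperature x `n_replicates` units).
#'
#' @param spec a [design_spec()].
#' @return a `data.frame` with columns `population_id`, `clone_id`,
#'   `urbanization`, `temperature`, `pesticide`, `replicate`, `n_start`,
#'   `n_surviving`.
#' @examples
#' nrow(build_design(design_spec()))                                  # 400
#' nrow(build_design(design_spec(excluded_clones = "u2.5")))          # 392
#' @export
build_design <- function(spec) {
  stopifnot(inherits(spec, "toxglmm_design_spec"))
  pops <- c(paste0("r", seq_len(spec$n_populations_per_class)),
            paste0("u", seq_len(spec$n_populations_per_class)))
  urb_of_pop <- rep(c("rural", "urban"), each = spec$n_populations_per_class)
  clones <- unlist(lapply(pops, function(p)
    paste0(p, ".", seq_len(spec$n_clones_per_population))))
  if (anyDuplicated(clones))
    tox_error("duplicate clone labels in the constructed design",
              "toxglmm_design_error")
  missing_ex <- setdiff(spec$excluded_clones, clones)
  if (length(missing_ex))
    tox_error(paste0("excluded clone(s) not present in the design: ",
                     paste(missing_ex, collapse = ", ")),
              "toxglmm_design_error")
  keep <- setdiff(clones, spec$excluded_clones)
  pop_of_clone <- sub("\\.[0-9]+$", "", keep)
  units <- expand.grid(replicate = seq_len(spec$n_replicates),
                       temperature = c(20L, 24L),
                       pesticide = c("control", "chlorpyrifos"),
                       clone_id = keep,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  units$population_id <- pop_of_clone[match(units$clone_id, keep)]
  units$urbanization <- urb_of_pop[match(units$population_id, pops)]
  # deterministic ordering: population, clone, pesticide, temperature, replicate
  ord <- order(match(units$population_id, pops),
               match(units$clone_id, clones),
               match(units$pesticide, c("control", "chlorpyrifos")),
               units$temperature, units$replicate)
  units <- units[ord, c("population_id", "clone_id", "urbanization",
                        "temperature", "pesticide", "replicate")]
  rownames(units) <- NULL
  units$n_start <- rep(spec$n_start, nrow(units))
  if (length(spec$oversized_units)) {
    bad <- spec$oversized_units[spec$oversized_units < 1 |
                                  spec$oversized_units > nrow(units)]
    if (length(bad))
      tox_error(paste0("oversized unit index out of range: ",
                       paste(bad, collapse = ", ")), "toxglmm_design_error")
    units$n_start[spec$oversized_units] <- spec$oversized_n_start
  }
  units$n_surviving <- NA_integer_
  units
}

UNIT_COLUMNS <- c("population_id", "clone_id", "urbanization", "temperature",
                  "pesticide", "replicate", "n_start", "n_surviving")

#' Validate an experimental-unit table
#'
#' Checks the schema and the invariants: counts are non-negative integers,
#' `n_surviving <= n_start` wherever observed, `n_start` within the allowed
#' bound, enum columns have valid levels, and every clone maps to a single
#' population and urbanization class. Violations raise classed errors
#' (`toxglmm_validation_error`) naming the offending rows.
#'
#' @param units a unit `data.frame` as produced by [build_design()] or read
#'   with [read_units()].
#' @param max_n_start upper bound on `n_start` (default 6; raise for
#'   non-standard assays).
#' @param require_outcomes error when any `n_surviving` is missing.
#' @return `units`, invisibly, with normalized column types.
#' @export
validate_units <- function(units, max_n_start = 6, require_outcomes = FALSE) {
  missing_cols <- setdiff(UNIT_COLUMNS, names(units))
  if (length(missing_cols))
    tox_error(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
              "toxglmm_validation_error")
  units <- units[, UNIT_COLUMNS]
  fail_rows <- function(what, rows) {
    tox_error(paste0(what, " (row ", paste(rows, collapse = ", "), ")"),
              "toxglmm_validation_error")
  }
  chk_int <- function(col) {
    v <- units[[col]]
    bad <- which(!is.na(v) & (!is.finite(suppressWarnings(as.numeric(v))) |
                                as.numeric(v) != round(as.numeric(v))))
    if (length(bad)) fail_rows(paste0("non-integer value in '", col, "'"), bad)
    as.integer(v)
  }
  units$replicate <- chk_int("replicate")
  units$n_start <- chk_int("n_start")
  units$n_surviving <- chk_int("n_surviving")
  units$temperature <- chk_int("temperature")
  bad <- which(is.na(units$n_start) | units$n_start < 1 |
                 units$n_start > max_n_start)
  if (length(bad)) fail_rows(paste0("n_start outside [1, ", max_n_start, "]"), bad)
  bad <- which(!is.na(units$n_surviving) &
                 (units$n_surviving < 0 | units$n_surviving > units$n_start))
  if (length(bad)) fail_rows("n_surviving outside [0, n_start]", bad)
  if (require_outcomes && anyNA(units$n_surviving))
    fail_rows("missing n_surviving", which(is.na(units$n_surviving)))
  bad <- which(!units$urbanization %in% c("rural", "urban"))
  if (length(bad)) fail_rows("urbanization must be 'rural' or 'urban'", bad)
  bad <- which(!units$pesticide %in% c("control", "chlorpyrifos"))
  if (length(bad)) fail_rows("pesticide must be 'control' or 'chlorpyrifos'", bad)
  bad <- which(!units$temperature %in% c(20L, 24L))
  if (length(bad)) fail_rows("temperature must be 20 or 24", bad)
  bad <- which(is.na(units$replicate) | units$replicate < 1)
  if (length(bad)) fail_rows("replicate must be a positive integer", bad)
  # clone nested in exactly one population/urbanization
  map <- unique(units[, c("clone_id", "population_id", "urbanization")])
  dup <- map$clone_id[duplicated(map$clone_id)]
  if (length(dup)) {
    rows <- which(units$clone_id %in% dup)
    fail_rows(paste0("clone(s) mapped to multiple populations: ",
                     paste(unique(dup), collapse = ", ")), rows)
  }
  invisible(units)
}

#' Encode units as centered treatment covariates
#'
#' Maps the treatment enums to the signed half-unit codes the model equation
#' uses (control/rural/20C -> -0.5; chlorpyrifos/urban/24C -> +0.5) and fills
#' in the three pairwise products and the triple product. Because the codes
#' are centered, each code column sums to zero over a balanced design and the
#' intercept represents the average condition.
#'
#' @param units a validated unit table.
#' @return a `data.frame` with columns `cpf`, `urb`, `temp`, `cpf_urb`,
#'   `cpf_temp`, `urb_temp`, `cpf_urb_temp`.
#' @examples
#' u <- build_design(design_spec(1, 1, 1))
#' encode_units(u)
#' @export
encode_units <- function(units) {
  cpf <- ifelse(units$pesticide == "chlorpyrifos", 0.5, -0.5)
  urb <- ifelse(units$urbanization == "urban", 0.5, -0.5)
  temp <- ifelse(units$temperature == 24L, 0.5, -0.5)
  data.frame(cpf = cpf, urb = urb, temp = temp,
             cpf_urb = cpf * urb, cpf_temp = cpf * temp,
             urb_temp = urb * temp, cpf_urb_temp = cpf * urb * temp)
}

# canonical model-term names, in design-matrix column order
MODEL_TERMS <- c("intercept", "cpf", "urb", "temp",
                 "cpf:urb", "cpf:temp", "urb:temp", "cpf:urb:temp")
BETA_NAMES <- c("beta_0", "beta_cpf", "beta_urb", "beta_temp",
                "beta_cpf_urb", "beta_cpf_temp", "beta_urb_temp",
                "beta_cpf_urb_temp")

#' Fixed-effects design matrix
#'
#' @param units a unit table.
#' @param terms subset of the model terms to include, in the canonical
#'   order `c("intercept", "cpf", "urb", "temp", "cpf:urb", "cpf:temp",
#'   "urb:temp", "cpf:urb:temp")`.
#' @return numeric matrix with one column per term.
#' @export
design_matrix <- function(units, terms = MODEL_TERMS) {
  bad <- setdiff(terms, MODEL_TERMS)
  if (length(bad))
    tox_error(paste0("unknown model term(s): ", paste(bad, collapse = ", ")),
              "toxglmm_design_error")
  terms <- MODEL_TERMS[MODEL_TERMS %in% terms]
  codes <- encode_units(units)
  cols <- list(intercept = rep(1, nrow(units)), cpf = codes$cpf,
               urb = codes$urb, temp = codes$temp, `cpf:urb` = codes$cpf_urb,
               `cpf:temp` = codes$cpf_temp, `urb:temp` = codes$urb_temp,
               `cpf:urb:temp` = codes$cpf_urb_temp)
  X <- do.call(cbind, cols[terms])
  colnames(X) <- terms
  X
}

# population/clone index vectors (1-based) plus level vectors, in first-seen
# (design) order
group_indices <- function(units) {
  pop_levels <- unique(units$population_id)
  clone_levels <- unique(units$clone_id)
  list(pop = match(units$population_id, pop_levels),
       clone = match(units$clone_id, clone_levels),
       pop_levels = pop_levels, clone_levels = clone_levels)
}

# per-unit multiplier for the random effects: the signed pesticide code
# (as the model equation is written), or a 0/1 exposure indicator
re_multiplier <- function(units, re_coding = c("signed", "indicator")) {
  re_coding <- match.arg(re_coding)
  cpf <- ifelse(units$pesticide == "chlorpyrifos", 0.5, -0.5)
  if (re_coding == "signed") cpf else cpf + 0.5
}

#' Read / write unit tables as CSV
#'
#' The canonical file format is comma-separated UTF-8 text with a header row
#' and columns `population_id, clone_id, urbanization, temperature,
#' pesticide, replicate, n_start, n_surviving`. `read_units()` can ingest
#' files with different column names through `mapping`, a named character
#' vector (or a YAML/JSON file containing one) from canonical names to the
#' file's names. Validation runs on every read.
#'
#' @param path file path.
#' @param mapping optional column mapping: named character vector
#'   `c(canonical = "file_column", ...)`, or path to a YAML/JSON file with
#'   those pairs. Unmapped canonical names are looked up verbatim.
#' @param max_n_start passed to [validate_units()].
#' @return `read_units()`: a validated unit `data.frame`.
#' @export
read_units <- function(path, mapping = NULL, max_n_start = 6) {
  if (!file.exists(path))
    tox_error(paste0("file not found: ", path), "toxglmm_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping))
      mapping <- unlist(load_config_file(mapping))
    mapping <- mapping[intersect(names(mapping), UNIT_COLUMNS)]
    missing_src <- setdiff(unname(mapping), names(raw))
    if (length(missing_src))
      tox_error(paste0("mapped column(s) absent from file: ",
                       paste(missing_src, collapse = ", ")), "toxglmm_io_error")
    for (canon in names(mapping)) raw[[canon]] <- raw[[mapping[[canon]]]]
  }
  validate_units(raw, max_n_start = max_n_start)
}

#' @rdname read_units
#' @param units a unit table to write.
#' @return `write_units()`: `path`, invisibly.
#' @export
write_units <- function(units, path) {
  units <- validate_units(units)
  utils::write.csv(units, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# YAML or JSON config reader (extension-dispatched; YAML needs the yaml package)
load_config_file <- function(path) {
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      tox_error("reading YAML configs requires the 'yaml' package",
                "toxglmm_io_error")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
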