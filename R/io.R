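#' Load a scenario configuration from a YAML file
#'
#' Reads a flat key-value YAML file whose keys mirror the model's parameter
#' names and returns a validated [scenario_config()].  Omitted keys take the
#' baseline values (`eta = 0.2`, `W = 0.8`, `e0 = 75`, `j = 75`, `n = 50`,
#' `el_plus = en_plus = 5`, `c = 0.67`, `review_error = 0`,
#' `mistake_prob = 0.25`), so an empty file yields the full baseline audit
#' scenario.  Unknown keys and out-of-range values raise an error naming the
#' offending key.
#'
#' Recognized keys: `eta`, `W`, `e0`, `psi_sd`, `truth_prior`,
#' `mistake_prob`, `publish_negatives`, `population_size`, `audits` (logical), `j`, `n`,
#' `el_plus`, `en_plus`, `c`, `review_error`, `statistic`, `burn_in`,
#' `cutoff_floor`, `annual_salary`, `cost_mode`, `papers_per_auditor`,
#' `total_cycles`, `record_every`, `n_replicates`, `master_seed`, `label`.
#'
#' @param path Path to the YAML file, or `NULL` for the pure baseline.
#' @param overrides Named list applied on top of the file's values (used by
#'   the command line's flags).
#' @return A [scenario_config()] object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("j: 50\nlabel: fast audits", f)
#' load_config(f)$policy$cycles_per_audit
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("Config file not found: %s", path))
    }
    # keep boolean-like scalars (notably the key `n`) as literal strings;
    # logical values are re-typed below
    keep <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
    vals <- yaml::yaml.load(paste(readLines(path), collapse = "\n"),
                            handlers = keep)
    if (is.null(vals)) vals <- list()
  }
  vals <- modifyList(vals, overrides)
  known <- c("eta", "W", "e0", "psi_sd", "truth_prior", "mistake_prob",
             "publish_negatives", "population_size", "audits", "j", "n",
             "el_plus", "en_plus",
             "c", "review_error", "statistic", "burn_in", "cutoff_floor",
             "annual_salary", "cost_mode", "papers_per_auditor",
             "total_cycles", "record_every", "n_replicates", "master_seed",
             "label")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (key in c("audits", "publish_negatives")) {
    if (is.character(vals[[key]])) {
      vals[[key]] <- tolower(vals[[key]]) %in% c("yes", "true", "on", "y")
    }
  }
  g <- function(key, default) vals[[key]] %||% default
  with_key <- function(key, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Invalid value for config key `%s`: %s", key,
                    conditionMessage(e)))
    })
  }
  params <- with_key("eta/W/e0/psi_sd", world_params(
    population_size = g("population_size", 100L),
    eta = g("eta", 0.2),
    truth_prior = g("truth_prior", 0.1),
    power = g("W", 0.8),
    initial_effort = g("e0", 75),
    mutation_sd = g("psi_sd", 1),
    mistake_prob = g("mistake_prob", 0.25),
    publish_negatives = g("publish_negatives", TRUE)
  ))
  policy <- with_key("j/n/c/el_plus/en_plus/review_error", audit_policy(
    enabled = g("audits", TRUE),
    cycles_per_audit = g("j", 75L),
    burn_in = g("burn_in", 100L),
    min_papers = g("n", 50L),
    statistic = g("statistic", "false_positive_proportion"),
    cutoff_percentile = g("c", 0.67),
    cutoff_floor = vals[["cutoff_floor"]],
    review_error_pct = g("review_error", 0),
    effort_boost_audited = g("el_plus", 5),
    effort_boost_network = g("en_plus", 5)
  ))
  cost <- with_key("annual_salary/cost_mode", cost_model(
    annual_salary = g("annual_salary", 105000),
    papers_per_auditor = g("papers_per_auditor", 10L),
    cost_mode = g("cost_mode", "results_consistent")
  ))
  scenario_config(
    params = params, policy = policy, cost = cost,
    total_cycles = g("total_cycles", 800000L),
    record_every = g("record_every", 8000L),
    n_replicates = g("n_replicates", 500L),
    master_seed = g("master_seed", 42L),
    label = g("label", "scenario")
  )
}

#' Flatten a scenario configuration to config-file keys
#'
#' The inverse of [load_config()]: a flat named list that, written as YAML
#' and loaded again, reproduces the configuration exactly.  Used by the run
#' manifest.
#'
#' @param config A [scenario_config()] object.
#' @return A named list.
#' @export
as_config_list <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  p <- config$params; a <- config$policy; cm <- config$cost
  list(
    eta = p$eta, W = p$power, e0 = p$initial_effort, psi_sd = p$mutation_sd,
    truth_prior = p$truth_prior, mistake_prob = p$mistake_prob,
    publish_negatives = p$publish_negatives,
    population_size = p$population_size,
    audits = a$enabled, j = a$cycles_per_audit, n = a$min_papers,
    el_plus = a$effort_boost_audited, en_plus = a$effort_boost_network,
    c = a$cutoff_percentile, review_error = a$review_error_pct,
    statistic = a$statistic, burn_in = a$burn_in,
    cutoff_floor = a$cutoff_floor,
    annual_salary = cm$annual_salary, cost_mode = cm$cost_mode,
    papers_per_auditor = cm$papers_per_auditor,
    total_cycles = config$total_cycles, record_every = config$record_every,
    n_replicates = config$n_replicates, master_seed = config$master_seed,
    label = config$label
  )
}

#' Write and read trajectory records
#'
#' Records are stored as plain CSV with one row per recorded cycle per
#' replicate and columns `replicate`, `cycle`, `mean_effort`, `mean_alpha`,
#' `cum_papers`, `cum_false_positives`, `cum_mistakes`, `cum_audits`,
#' `cum_removals`, `cum_audited_papers`, `cum_cost`.
#'
#' @param x A records tibble with a `replicate` column, an `auditsim_run`
#'   (written as replicate 1), or an `auditsim_scenario` run with
#'   `keep_records = TRUE`.
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_records`); the records tibble
#'   (`read_records`).
#' @export
write_records <- function(x, path) {
  if (inherits(x, "auditsim_run")) {
    x <- dplyr::bind_cols(tibble::tibble(replicate = 1L), x$records)
  } else if (inherits(x, "auditsim_scenario")) {
    if (is.null(x$records)) {
      abort("This scenario was run without `keep_records = TRUE`.")
    }
    x <- x$records
  }
  if (!is.data.frame(x) || !"replicate" %in% names(x)) {
    abort("`x` must be a records table with a `replicate` column.")
  }
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write and read a scenario summary
#'
#' The one-row scenario summary (see [run_scenario()]) as structured YAML.
#'
#' @param summary A summary tibble (`glance()` of an `auditsim_scenario`),
#'   or the scenario object itself.
#' @param path Output YAML path.
#' @return `path`, invisibly (`write_summary`); a one-row tibble
#'   (`read_summary`).
#' @export
write_summary <- function(summary, path) {
  if (inherits(summary, "auditsim_scenario")) summary <- glance(summary)
  stopifnot(is.data.frame(summary), nrow(summary) == 1)
  yaml::write_yaml(as.list(summary), path, precision = 15)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  tibble::as_tibble(yaml::read_yaml(path))
}

#' Write a run manifest
#'
#' A YAML manifest sufficient to reproduce a run bit-for-bit: the fully
#' resolved configuration, package version, master seed, the derived
#' per-replicate seeds, and a timestamp.
#'
#' @param config A [scenario_config()] object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  manifest <- list(
    package = "auditsim",
    version = as.character(utils::packageVersion("auditsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = config$master_seed,
    replicate_seeds = replicate_seeds(config$master_seed, config$n_replicates),
    config = as_config_list(config)
  )
  yaml::write_yaml(manifest, path, precision = 15)
  invisible(path)
}
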