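#' Detect the competitive spiral in a trajectory
#'
#' The competitive spiral is the runaway selection for quantity that drives
#' effort to its minimum and the population mean false-positive probability
#' to its ceiling (0.6667 at power 0.8).  End states are strongly bimodal
#' (near the starting 0.05 or near the ceiling), so a replicate is
#' classified as having spiralled when the final record's mean alpha is at
#' or above `threshold`.
#'
#' @param records A trajectory tibble (from [run_simulation()], its
#'   `$records`, or [tidy()]) with `mean_alpha`; an `auditsim_run` is also
#'   accepted.
#' @param threshold Classification threshold on the final mean alpha
#'   (default 0.6, separating the two end-state modes).
#' @return `TRUE` if the trajectory ended in the spiral.
#' @examples
#' detect_spiral(tibble::tibble(mean_alpha = c(0.05, 0.05)))
#' detect_spiral(tibble::tibble(mean_alpha = c(0.05, 0.667)))
#' @export
detect_spiral <- function(records, threshold = 0.6) {
  if (inherits(records, "auditsim_run")) records <- records$records
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must be a non-empty trajectory data frame.")
  }
  check_number(threshold, "threshold", lower = 0, upper = 1)
  records$mean_alpha[nrow(records)] >= threshold
}

#' Non-parametric percentile confidence interval
#'
#' The `(1 - level)/2` and `(1 + level)/2` inverse-ECDF (type-1) empirical
#' quantiles of a sample of replicate-level statistics: the across-run
#' uncertainty interval used in the scenario summaries.
#'
#' @param x Numeric sample (one value per replicate).
#' @param level Coverage level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' nonparametric_ci(1:100)
#' @export
nonparametric_ci <- function(x, level = 0.95) {
  if (length(x) == 0 || !is.numeric(x)) abort("`x` must be a non-empty numeric sample.")
  check_number(level, "level", lower = 0, upper = 1)
  probs <- c((1 - level) / 2, (1 + level) / 2)
  c(lower = quantile_type1(x, probs[1]), upper = quantile_type1(x, probs[2]))
}

# Inverse-ECDF (type 1) quantile with a small fuzz on n*p so that values of
# n*p within float error of an integer resolve to that order statistic; the
# compiled engine uses the identical rule for the audit cut-off.
quantile_type1 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  s[min(n, max(1L, as.integer(ceiling(n * p - 1e-9))))]
}

# Deterministic per-replicate seeds derived from the master seed.
replicate_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a replicated scenario
#'
#' Runs `n_replicates` independent simulations of a scenario (each with a
#' seed derived deterministically from the scenario's master seed) and
#' aggregates them into the scenario summary: the percentage of replicates
#' avoiding the competitive spiral, and means with non-parametric 95%
#' confidence intervals for the percent of papers audited, cost per paper,
#' and false positives and mistakes per 100 papers.
#'
#' @param config A [scenario_config()] object (`n_replicates` and
#'   `master_seed` live there).
#' @param spiral_threshold Threshold passed to [detect_spiral()].
#' @param engine Engine passed to [run_simulation()].
#' @param quiet Suppress per-replicate progress messages?
#' @param keep_records Also keep every replicate's trajectory records (as
#'   `$records`, with a `replicate` column)?  Off by default to save memory.
#' @return An object of class `auditsim_scenario`: a list with `replicates`
#'   (one-row-per-replicate tibble of statistics), `summary` (one-row
#'   tibble), and the `config`.  [tidy()] returns the replicate table,
#'   [glance()] the summary row.
#' @examples
#' cfg <- scenario_config(policy = no_audit_policy(), total_cycles = 4000L,
#'                        record_every = 2000L, n_replicates = 3L,
#'                        master_seed = 1L)
#' glance(run_scenario(cfg))
#' @export
run_scenario <- function(config, spiral_threshold = 0.6,
                         engine = c("cpp", "r"), quiet = TRUE,
                         keep_records = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  engine <- match.arg(engine)
  seeds <- replicate_seeds(config$master_seed, config$n_replicates)
  all_records <- if (keep_records) vector("list", config$n_replicates)
  reps <- purrr::map(seq_len(config$n_replicates), function(r) {
    if (!quiet) {
      message(sprintf("[%s] replicate %d/%d (seed %d)",
                      config$label, r, config$n_replicates, seeds[r]))
    }
    run <- run_simulation(config, seed = seeds[r], engine = engine)
    if (keep_records) {
      all_records[[r]] <<- dplyr::bind_cols(tibble::tibble(replicate = r),
                                            run$records)
    }
    g <- glance(run)
    g$spiral <- detect_spiral(run$records, spiral_threshold)
    dplyr::bind_cols(tibble::tibble(replicate = r, seed = seeds[r]), g)
  })
  replicates <- dplyr::bind_rows(reps)
  structure(list(
    replicates = replicates,
    summary = summarise_replicates(replicates, config$label),
    records = if (keep_records) dplyr::bind_rows(all_records),
    config = config,
    spiral_threshold = spiral_threshold
  ), class = "auditsim_scenario")
}

mean_ci_cols <- function(x, prefix) {
  ci <- nonparametric_ci(x)
  out <- tibble::tibble(mean(x), ci[["lower"]], ci[["upper"]])
  names(out) <- paste0(prefix, c("", "_lower", "_upper"))
  out
}

summarise_replicates <- function(replicates, label) {
  dplyr::bind_cols(
    tibble::tibble(
      label = label,
      n_replicates = nrow(replicates),
      pct_avoiding_spiral = 100 * mean(!replicates$spiral)
    ),
    mean_ci_cols(replicates$pct_papers_audited, "pct_papers_audited"),
    mean_ci_cols(replicates$cost_per_paper, "cost_per_paper"),
    mean_ci_cols(replicates$fp_per_100, "fp_per_100"),
    mean_ci_cols(replicates$mistakes_per_100, "mistakes_per_100")
  )
}

#' @export
print.auditsim_scenario <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<auditsim_scenario> %s: %d replicates of %s cycles\n",
              s$label, s$n_replicates,
              format(x$config$total_cycles, big.mark = ",")))
  cat(sprintf("  avoiding spiral: %.1f%%\n", s$pct_avoiding_spiral))
  cat(sprintf("  papers audited: %.2f%% (%.2f, %.2f); cost/paper: $%.0f (%.0f, %.0f)\n",
              s$pct_papers_audited, s$pct_papers_audited_lower,
              s$pct_papers_audited_upper, s$cost_per_paper,
              s$cost_per_paper_lower, s$cost_per_paper_upper))
  cat(sprintf("  per 100 papers: %.1f false positives, %.1f mistakes\n",
              s$fp_per_100, s$mistakes_per_100))
  invisible(x)
}

#' @describeIn run_scenario `tidy()` returns the per-replicate statistics.
#' @param x An `auditsim_scenario`.
#' @param ... Unused.
#' @export
tidy.auditsim_scenario <- function(x, ...) x$replicates

#' @describeIn run_scenario `glance()` returns the one-row scenario summary.
#' @export
glance.auditsim_scenario <- function(x, ...) x$summary

#' Run a grid of scenarios
#'
#' Runs [run_scenario()] over a list of configurations and binds the
#' summaries into one table, ordered by the percentage of replicates
#' avoiding the competitive spiral (best first).
#'
#' @param configs List of [scenario_config()] objects.
#' @inheritParams run_scenario
#' @return A tibble with one row per scenario.
#' @seealso [table3_scenarios()] for the published 16-scenario sensitivity
#'   grid.
#' @export
sensitivity_grid <- function(configs, spiral_threshold = 0.6,
                             engine = c("cpp", "r"), quiet = TRUE) {
  engine <- match.arg(engine)
  purrr::map(configs, function(cfg) {
    if (!quiet) message(sprintf("scenario: %s", cfg$label))
    glance(run_scenario(cfg, spiral_threshold, engine, quiet = TRUE))
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(dplyr::desc(.data$pct_avoiding_spiral))
}

#' The published 16-scenario sensitivity grid
#'
#' Builds the configurations of the sensitivity analysis: the baseline audit
#' world (`j = 75`, `e0 = 75`, `el+ = en+ = 5`, `n = 50`, `c = 0.67`, no
#' review error, false-positive audits) and its one-at-a-time variations —
#' audit spacing `j` in \{50, 150\}, starting efforts 10 and 50, cut-offs
#' 0.95 and 1.0, boost levels \{0, 1, 10\} and the two asymmetric boost
#' settings, eligibility at 25 papers, 20% review error, the mistake-audit
#' scenario (`j = 200`, `el+ = 1`, `en+ = 0.5`), and the no-audit world.
#'
#' @param n_replicates Replicates per scenario.
#' @param total_cycles,record_every Run plan shared by all scenarios.
#' @param master_seed Master seed shared by all scenarios.
#' @return A named list of [scenario_config()] objects (16 entries).
#' @examples
#' names(table3_scenarios())
#' @export
table3_scenarios <- function(n_replicates = 500L, total_cycles = 800000L,
                             record_every = 8000L, master_seed = 42L) {
  base <- function(label, policy, params = world_params()) {
    scenario_config(params = params, policy = policy,
                    total_cycles = total_cycles, record_every = record_every,
                    n_replicates = n_replicates, master_seed = master_seed,
                    label = label)
  }
  fp <- function(...) audit_policy(...)
  configs <- list(
    base("j=75 el+=1 en+=1", fp(effort_boost_audited = 1, effort_boost_network = 1)),
    base("j=50 baseline", fp(cycles_per_audit = 50L)),
    base("j=75 c=1.00", fp(cutoff_percentile = 1)),
    base("j=75 c=0.95", fp(cutoff_percentile = 0.95)),
    base("j=75 review error 20%", fp(review_error_pct = 20)),
    base("j=75 baseline", fp()),
    base("j=200 mistakes el+=1 en+=0.5",
         audit_policy(cycles_per_audit = 200L, statistic = "mistake_proportion",
                      effort_boost_audited = 1, effort_boost_network = 0.5)),
    base("j=75 el+=0 en+=5", fp(effort_boost_audited = 0)),
    base("j=75 n=25", fp(min_papers = 25L)),
    base("j=150", fp(cycles_per_audit = 150L)),
    base("j=75 el+=10 en+=10", fp(effort_boost_audited = 10, effort_boost_network = 10)),
    base("j=75 el+=5 en+=0", fp(effort_boost_network = 0)),
    base("j=75 el+=0 en+=0", fp(effort_boost_audited = 0, effort_boost_network = 0)),
    base("no audits", no_audit_policy()),
    base("j=75 e0=10", fp(), params = world_params(initial_effort = 10)),
    base("j=75 e0=50", fp(), params = world_params(initial_effort = 50))
  )
  names(configs) <- vapply(configs, function(cfg) cfg$label, character(1))
  configs
}
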