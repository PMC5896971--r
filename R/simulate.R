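#' Run one replicate simulation
#'
#' Executes `total_cycles` research cycles from a fresh population of labs
#' all at the starting effort, recording the world every `record_every`
#' cycles.  The default engine is compiled C++; `engine = "r"` runs the pure
#' R reference implementation ([run_cycle()] in a loop), which draws from
#' R's RNG in exactly the same order and therefore produces bit-identical
#' trajectories under the same seed (it is orders of magnitude slower and
#' meant for verification at small cycle counts).
#'
#' @param config A [scenario_config()] object.
#' @param seed Optional integer seed (`set.seed()` is called when supplied;
#'   otherwise the current RNG state is consumed).
#' @param engine `"cpp"` (default) or `"r"`.
#' @return An object of class `auditsim_run`: a list with
#'   \describe{
#'     \item{records}{tibble of per-record world summaries (`cycle`,
#'       `mean_effort`, `mean_alpha`, and cumulative papers, false
#'       positives, mistakes, audits, removals, audited papers, cost).}
#'     \item{audits}{tibble with one row per conducted audit.}
#'     \item{labs}{tibble of the final population.}
#'     \item{totals}{list of cumulative world totals.}
#'     \item{config, seed, engine}{provenance.}
#'   }
#' @examples
#' cfg <- scenario_config(total_cycles = 4000L, record_every = 1000L)
#' run <- run_simulation(cfg, seed = 1)
#' run$records
#' @export
run_simulation <- function(config, seed = NULL, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "scenario_config"))
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  res <- if (engine == "cpp") {
    run_engine_cpp(config)
  } else {
    run_engine_r(config)
  }
  structure(
    list(records = res$records, audits = res$audits, labs = res$labs,
         totals = res$totals, config = config, seed = seed, engine = engine),
    class = "auditsim_run"
  )
}

statistic_code <- c(false_positive_proportion = 0L, alpha = 1L,
                    mistake_proportion = 2L)

run_engine_cpp <- function(config) {
  p <- config$params; a <- config$policy; cm <- config$cost
  raw <- sim_run_cpp(
    n_cycles = config$total_cycles, record_every = config$record_every,
    pop_size = p$population_size, eta = p$eta, truth_prior = p$truth_prior,
    W = p$power, e0 = p$initial_effort, mutation_prob = p$mutation_prob,
    mutation_sd = p$mutation_sd, mistake_prob = p$mistake_prob,
    publish_negatives = p$publish_negatives,
    death_sample = p$death_sample, birth_sample = p$birth_sample,
    audit_enabled = a$enabled, cycles_per_audit = a$cycles_per_audit,
    burn_in = a$burn_in, min_papers = a$min_papers,
    statistic = statistic_code[[a$statistic]],
    cutoff_percentile = a$cutoff_percentile, cutoff_floor = a$cutoff_floor,
    review_error_pct = a$review_error_pct,
    el_plus = a$effort_boost_audited, en_plus = a$effort_boost_network,
    annual_salary = cm$annual_salary * cm$months_per_auditor,
    papers_per_auditor = cm$papers_per_auditor,
    cost_mode = if (cm$cost_mode == "results_consistent") 0L else 1L
  )
  list(
    records = tibble::as_tibble(raw$records),
    audits = tibble::as_tibble(lapply(raw$audits, unlist_or_empty)) |>
      dplyr::mutate(removed = as.logical(.data$removed)),
    labs = tibble::as_tibble(raw$labs) |>
      dplyr::mutate(audited = as.logical(.data$audited)),
    totals = raw$totals
  )
}

unlist_or_empty <- function(x) if (length(x) == 0) numeric(0) else as.numeric(x)

run_engine_r <- function(config) {
  p <- config$params; a <- config$policy; cm <- config$cost
  world <- new_world(p)
  n_rec <- config$total_cycles %/% config$record_every
  rec <- vector("list", n_rec)
  k <- 0L
  for (cycle in seq_len(config$total_cycles)) {
    world <- run_cycle(world, p, a, cm)
    if (cycle %% config$record_every == 0L) {
      k <- k + 1L
      rec[[k]] <- tibble::tibble(
        cycle = as.numeric(cycle),
        mean_effort = mean(world$labs$effort),
        mean_alpha = mean(false_positive_prob(world$labs$power,
                                              world$labs$effort)),
        cum_papers = world$totals$papers,
        cum_false_positives = world$totals$false_positives,
        cum_mistakes = world$totals$mistakes,
        cum_audits = world$totals$audits,
        cum_removals = world$totals$removals,
        cum_audited_papers = world$totals$audited_papers,
        cum_cost = world$totals$cost
      )
    }
  }
  audits <- if (length(world$audit_log) > 0) {
    dplyr::bind_rows(world$audit_log)
  } else {
    tibble::tibble(cycle = numeric(0), lab_id = numeric(0),
                   papers_at_audit = numeric(0), statistic = numeric(0),
                   statistic_observed = numeric(0), cutoff = numeric(0),
                   removed = logical(0), cost = numeric(0))
  }
  labs <- tibble::as_tibble(world$labs)
  list(records = dplyr::bind_rows(rec), audits = audits, labs = labs,
       totals = world$totals)
}

#' @export
print.auditsim_run <- function(x, ...) {
  final <- x$records[nrow(x$records), ]
  cat(sprintf("<auditsim_run> %s cycles (%s engine)\n",
              format(x$config$total_cycles, big.mark = ","), x$engine))
  cat(sprintf("  final mean effort %.2f, mean alpha %.4f\n",
              final$mean_effort, final$mean_alpha))
  cat(sprintf("  %s papers, %s false positives, %s audits (%s removals)\n",
              format(x$totals$papers, big.mark = ","),
              format(x$totals$false_positives, big.mark = ","),
              format(x$totals$audits, big.mark = ","),
              format(x$totals$removals, big.mark = ",")))
  invisible(x)
}

#' @describeIn run_simulation `tidy()` returns the per-record trajectory
#'   tibble.
#' @param x An `auditsim_run`.
#' @param ... Unused.
#' @export
tidy.auditsim_run <- function(x, ...) x$records

#' @describeIn run_simulation `glance()` returns a one-row tibble of
#'   replicate-level statistics (final effort and alpha, spiral flag at the
#'   default threshold, percent of papers audited, cost per paper, false
#'   positives and mistakes per 100 papers).
#' @export
glance.auditsim_run <- function(x, ...) {
  final <- x$records[nrow(x$records), ]
  t <- x$totals
  tibble::tibble(
    final_mean_effort = final$mean_effort,
    final_mean_alpha = final$mean_alpha,
    spiral = detect_spiral(x$records),
    pct_papers_audited = if (t$papers > 0) 100 * t$audited_papers / t$papers else 0,
    cost_per_paper = if (t$papers > 0) t$cost / t$papers else 0,
    fp_per_100 = if (t$papers > 0) 100 * t$false_positives / t$papers else 0,
    mistakes_per_100 = if (t$papers > 0) 100 * t$mistakes / t$papers else 0,
    papers = t$papers, audits = t$audits, removals = t$removals
  )
}
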