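#' Is a given cycle an audit cycle?
#'
#' Audits start after the burn-in and then recur every `cycles_per_audit`
#' cycles, so the first audit falls at `burn_in + cycles_per_audit`.
#'
#' @param cycle Cycle number (scalar or vector).
#' @param policy An [audit_policy()] object.
#' @return Logical.
#' @examples
#' is_audit_cycle(c(100, 175, 250), audit_policy(cycles_per_audit = 75))
#' @export
is_audit_cycle <- function(cycle, policy) {
  stopifnot(inherits(policy, "audit_policy"))
  policy$enabled & cycle > policy$burn_in &
    (cycle - policy$burn_in) %% policy$cycles_per_audit == 0
}

#' Labs eligible for an audit
#'
#' A lab can be audited if it has never been audited before (a lifetime
#' restriction) and has published at least `min_papers` papers, so that the
#' auditors have enough data to judge it.
#'
#' @param world An `audit_world`.
#' @param policy An [audit_policy()] object.
#' @return The ids of the eligible labs (possibly empty), in storage order.
#' @export
eligible_labs <- function(world, policy) {
  stopifnot(inherits(world, "audit_world"))
  labs <- world$labs
  labs$id[!labs$audited & labs$papers >= policy$min_papers]
}

#' Reviewer noise on an audited count
#'
#' Simulates imperfect peer review: the observed count is the true count
#' plus a rounded Normal error with standard deviation
#' `(error_pct / 100 * count) / 1.96`, clamped to `[0, papers]`.  With this
#' scaling about 95% of observed counts fall within +/- `error_pct`% of the
#' truth.  A zero count or a zero error percentage is returned unchanged
#' (and consumes no random draw).
#'
#' @param count True count of false positives (or mistakes).
#' @param error_pct Reviewer error in percent.
#' @param papers Upper clamp: the lab's paper count.
#' @return The observed non-negative integer count.
#' @examples
#' set.seed(1)
#' apply_reviewer_noise(98, 20, papers = 200)
#' @export
apply_reviewer_noise <- function(count, error_pct, papers = Inf) {
  check_number(count, "count", lower = 0)
  check_number(error_pct, "error_pct", lower = 0)
  if (error_pct == 0 || count == 0) return(count)
  sd <- (error_pct / 100) * count / 1.96
  min(papers, max(0, count + round(rnorm(1, 0, sd))))
}

#' Audit statistic of a lab
#'
#' What the auditors measure, depending on the policy: the lab's realized
#' false-positive proportion (`false_positives / papers`), its current
#' false-positive probability `alpha` implied by its effort
#' ([false_positive_prob()]), or its cumulative mistake proportion
#' (`mistakes / papers`).  Reviewer noise, when enabled and requested,
#' perturbs the count-based statistics via [apply_reviewer_noise()].
#'
#' @param lab A lab as a named list or one-row data frame.
#' @param policy An [audit_policy()] object.
#' @param noised Apply reviewer noise (when the policy has a positive
#'   `review_error_pct`)?  The population distribution used for the removal
#'   cut-off is always computed un-noised.
#' @return The statistic, in `[0, 1]`.
#' @examples
#' lab <- list(effort = 75, power = 0.8, papers = 50L, false_positives = 10L,
#'             mistakes = 2L)
#' audit_statistic(lab, audit_policy())
#' audit_statistic(lab, audit_policy(statistic = "alpha"))
#' @export
audit_statistic <- function(lab, policy, noised = TRUE) {
  stopifnot(inherits(policy, "audit_policy"))
  if (is.data.frame(lab)) lab <- as.list(lab[1, ])
  if (policy$statistic == "alpha") {
    return(false_positive_prob(lab$power, lab$effort))
  }
  if (is.null(lab$papers) || lab$papers < 1) {
    abort("The audit statistic is undefined for a lab with no papers.")
  }
  count <- if (policy$statistic == "false_positive_proportion") {
    lab$false_positives
  } else {
    lab$mistakes
  }
  if (noised && policy$review_error_pct > 0) {
    count <- apply_reviewer_noise(count, policy$review_error_pct, lab$papers)
  }
  min(1, max(0, count / lab$papers))
}

#' Removal cut-off from the population's statistics
#'
#' The cut-off is the `percentile` inverse-ECDF (type-1) empirical quantile
#' of the current labs' audit statistics, floored at `floor` so that labs
#' with a low false-positive probability are never removed just for being in
#' a good population.  A percentile of 1 disables removal (the cut-off is
#' `Inf`).
#'
#' @param statistics Numeric vector of all current labs' statistics.
#' @param percentile Cut-off percentile in `(0, 1]`.
#' @param floor Minimum cut-off value.
#' @return The cut-off.
#' @examples
#' compute_cutoff(seq(0.01, 1, by = 0.01), 0.67, 0.05)
#' @export
compute_cutoff <- function(statistics, percentile, floor = 0.05) {
  if (length(statistics) == 0) abort("`statistics` must be non-empty.")
  if (percentile <= 0 || percentile > 1) abort("`percentile` must be in (0, 1].")
  if (percentile >= 1) return(Inf)
  max(quantile_type1(statistics, percentile), floor)
}

#' Conduct one audit
#'
#' Selects one lab uniformly at random from the eligible set (never-audited
#' labs with enough papers; if none, the audit is skipped).  The lab's
#' observed statistic ([audit_statistic()], possibly reviewer-noised) is
#' compared against the cut-off computed from all current labs' un-noised
#' statistics ([compute_cutoff()]).  A lab above the cut-off is removed and
#' replaced through the ordinary birth step; a surviving lab is marked
#' audited and raises its effort by `effort_boost_audited`.  Either way the
#' audited lab's living parent and children raise theirs by
#' `effort_boost_network` (all boosts clamped to `[1, 100]`).  The audit is
#' costed via [audit_cost()] at the lab's paper count at audit time.
#'
#' Audits never alter paper, false-positive or mistake counts.
#'
#' @param world An `audit_world`.
#' @param policy An [audit_policy()] object.
#' @param params A [world_params()] object.
#' @param cost A [cost_model()] object.
#' @return A list with the updated `world` and a one-row `record` tibble
#'   (`cycle`, `lab_id`, `papers_at_audit`, `statistic`,
#'   `statistic_observed`, `cutoff`, `removed`, `cost`), or `record = NULL`
#'   when no lab was eligible.
#' @export
conduct_audit <- function(world, policy, params = world_params(),
                          cost = cost_model()) {
  stopifnot(inherits(world, "audit_world"), inherits(policy, "audit_policy"))
  labs <- world$labs
  n <- length(labs$id)
  eligible <- which(!labs$audited & labs$papers >= policy$min_papers)
  if (length(eligible) == 0L) {
    return(list(world = world, record = NULL))
  }
  sel <- eligible[1L + floor(runif(1) * length(eligible))]

  # labs with no papers yet contribute a zero proportion to the distribution
  stats_all <- vapply(seq_len(n), function(i) {
    if (policy$statistic != "alpha" && labs$papers[[i]] < 1) return(0)
    audit_statistic(lab_at(labs, i), policy, noised = FALSE)
  }, numeric(1))
  cutoff <- compute_cutoff(stats_all, policy$cutoff_percentile,
                           policy$cutoff_floor)
  stat_true <- stats_all[sel]
  stat_obs <- audit_statistic(lab_at(labs, sel), policy, noised = TRUE)

  papers_at_audit <- labs$papers[[sel]]
  this_cost <- audit_cost(papers_at_audit, cost)
  audited_id <- labs$id[[sel]]
  audited_parent <- labs$parent_id[[sel]]
  removed <- stat_obs > cutoff

  if (removed) {
    world$labs <- labs_remove(labs, sel)
    world <- birth_replacement(world, params)
    world$totals$removals <- world$totals$removals + 1
  } else {
    world$labs$audited[[sel]] <- TRUE
    world$labs$effort[[sel]] <-
      clamp_effort(world$labs$effort[[sel]] + policy$effort_boost_audited)
  }
  # network effect: the audited lab's direct parent and children still alive
  labs <- world$labs
  network <- (!is.na(audited_parent) & labs$id == audited_parent) |
    (!is.na(labs$parent_id) & labs$parent_id == audited_id)
  labs$effort[network] <-
    clamp_effort(labs$effort[network] + policy$effort_boost_network)
  world$labs <- labs

  world$totals$audits <- world$totals$audits + 1
  world$totals$audited_papers <- world$totals$audited_papers + papers_at_audit
  world$totals$cost <- world$totals$cost + this_cost

  record <- tibble::tibble(
    cycle = world$cycle, lab_id = audited_id,
    papers_at_audit = papers_at_audit, statistic = stat_true,
    statistic_observed = stat_obs, cutoff = cutoff,
    removed = removed, cost = this_cost
  )
  list(world = world, record = record)
}
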