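#' World parameters for the lab-competition model
#'
#' Constants governing the research world: the population of competing labs,
#' the effort/output trade-off, the prior probability that a tackled
#' hypothesis is true, statistical power, and the inheritance (mutation)
#' process of the death-birth step.
#'
#' Each research cycle every lab tackles a new hypothesis with probability
#' `1 - eta * log10(e)` (effort `e` in `[1, 100]`), the hypothesis is true
#' with probability `truth_prior`, a true hypothesis is detected with
#' probability `power`, and a false one is mistakenly declared positive with
#' probability `power / (1 + (1 - power) * e)`.  Every tested hypothesis is
#' written up as a paper, but only positive results earn the unit pay-off
#' that drives selection; published false positives contain a detectable
#' mistake with probability `mistake_prob`.  After the
#' research phase, `death_sample` labs are sampled and the oldest removed,
#' then `birth_sample` survivors are sampled and the one with the highest
#' cumulative pay-off spawns a child that inherits its effort, perturbed with
#' probability `mutation_prob` by a Normal(0, `mutation_sd`) offset.
#'
#' @param population_size Number of labs, held constant (default 100).
#' @param eta Strength of the association between effort and the probability
#'   of tackling a new hypothesis (default 0.2).
#' @param truth_prior Probability that a tackled hypothesis is true
#'   (default 0.1).
#' @param power Statistical power of every lab, `W` in `[0, 1]`
#'   (default 0.8).
#' @param initial_effort Starting effort `e0` for all labs (default 75,
#'   which with `power = 0.8` gives the textbook type-I error of 0.05).
#' @param mutation_prob Probability that inheritance mutates (default 0.01).
#' @param mutation_sd Standard deviation of the Normal mutation offset
#'   (default 1).
#' @param mistake_prob Probability that a published false positive contains a
#'   detectable mistake (default 0.25).
#' @param publish_negatives Are negative results written up as (unrewarded)
#'   papers?  Default `TRUE`; they then count towards audit eligibility and
#'   every per-paper denominator.  `FALSE` restricts the published record to
#'   positive results.
#' @param death_sample,birth_sample Sizes of the random samples used in the
#'   death and birth steps (default 10 each).
#'
#' @return A validated list of class `world_params`.
#' @examples
#' world_params()
#' world_params(initial_effort = 10)
#' @export
world_params <- function(population_size = 100L,
                         eta = 0.2,
                         truth_prior = 0.1,
                         power = 0.8,
                         initial_effort = 75,
                         mutation_prob = 0.01,
                         mutation_sd = 1,
                         mistake_prob = 0.25,
                         publish_negatives = TRUE,
                         death_sample = 10L,
                         birth_sample = 10L) {
  p <- list(
    population_size = as.integer(population_size), eta = eta,
    truth_prior = truth_prior, power = power,
    initial_effort = initial_effort, mutation_prob = mutation_prob,
    mutation_sd = mutation_sd, mistake_prob = mistake_prob,
    publish_negatives = isTRUE(publish_negatives),
    death_sample = as.integer(death_sample),
    birth_sample = as.integer(birth_sample)
  )
  check_number(p$eta, "eta", lower = 0)
  check_prob(p$truth_prior, "truth_prior")
  check_prob(p$power, "power")
  check_prob(p$mutation_prob, "mutation_prob")
  check_prob(p$mistake_prob, "mistake_prob")
  check_number(p$mutation_sd, "mutation_sd", lower = 0)
  check_effort(p$initial_effort, "initial_effort")
  if (p$eta * log10(100) > 1) {
    abort("`eta` must satisfy eta * log10(100) <= 1 so tackling stays a probability.")
  }
  if (p$population_size < p$death_sample ||
      p$population_size < p$birth_sample + 1L) {
    abort("`population_size` must be at least `death_sample` and `birth_sample` + 1.")
  }
  structure(p, class = "world_params")
}

#' Audit policy
#'
#' Settings for the random-audit intervention: schedule, eligibility, the
#' audited statistic, the removal cut-off, reviewer noise, and the post-audit
#' effort boosts for the audited lab and its parent/child network.
#'
#' After `burn_in` research cycles, an audit runs every `cycles_per_audit`
#' cycles.  One lab is drawn uniformly from those never audited before with
#' at least `min_papers` papers (if none qualifies the audit is skipped).
#' The lab is removed when its observed statistic exceeds the cut-off, the
#' `cutoff_percentile` empirical quantile of the current population's
#' un-noised statistics, floored at `cutoff_floor`; `cutoff_percentile = 1`
#' disables removal entirely.  A surviving audited lab raises its effort by
#' `effort_boost_audited`, and its direct parent and children (if alive)
#' raise theirs by `effort_boost_network`, all clamped to `[1, 100]`.
#'
#' `statistic` selects what auditors measure: the realized false-positive
#' proportion (`false_positives / papers`, the default), the lab's current
#' false-positive probability `alpha` implied by its effort, or its
#' cumulative mistake proportion (`mistakes / papers`).  `review_error_pct`
#' simulates imperfect peer review by perturbing the audited lab's observed
#' count with a Normal error of standard deviation
#' `(review_error_pct/100 * count) / 1.96`, so that about 95% of audits see
#' a count within +/- `review_error_pct`% of the truth.
#'
#' @param enabled Run audits at all? `no_audit_policy()` is shorthand for
#'   `audit_policy(enabled = FALSE)`.
#' @param cycles_per_audit Cycles between audits, `j` (default 75).
#' @param burn_in Cycles before the first audit can occur (default 100); the
#'   first audit falls at `burn_in + cycles_per_audit`.
#' @param min_papers Papers needed for a lab to be auditable, `n`
#'   (default 50).
#' @param statistic One of `"false_positive_proportion"`, `"alpha"`,
#'   `"mistake_proportion"`.
#' @param cutoff_percentile Removal cut-off `c` in the empirical CDF of the
#'   population's statistics (default 0.67; 1 means never remove).
#' @param cutoff_floor Lower bound for the cut-off.  Defaults to 0.05 for
#'   the false-positive statistics and 0 for the mistake statistic.
#' @param review_error_pct Reviewer error in percent (default 0; the paper
#'   world's sensitivity setting is 20).
#' @param effort_boost_audited Effort increase `el+` for a surviving audited
#'   lab (default 5).
#' @param effort_boost_network Effort increase `en+` for the audited lab's
#'   living parent and children (default 5).
#'
#' @return A validated list of class `audit_policy`.
#' @examples
#' audit_policy(cycles_per_audit = 50)
#' no_audit_policy()
#' @export
audit_policy <- function(enabled = TRUE,
                         cycles_per_audit = 75L,
                         burn_in = 100L,
                         min_papers = 50L,
                         statistic = c("false_positive_proportion", "alpha",
                                       "mistake_proportion"),
                         cutoff_percentile = 0.67,
                         cutoff_floor = NULL,
                         review_error_pct = 0,
                         effort_boost_audited = 5,
                         effort_boost_network = 5) {
  statistic <- match.arg(statistic)
  if (is.null(cutoff_floor)) {
    cutoff_floor <- if (statistic == "mistake_proportion") 0 else 0.05
  }
  p <- list(
    enabled = isTRUE(enabled),
    cycles_per_audit = as.integer(cycles_per_audit),
    burn_in = as.integer(burn_in),
    min_papers = as.integer(min_papers),
    statistic = statistic,
    cutoff_percentile = cutoff_percentile,
    cutoff_floor = cutoff_floor,
    review_error_pct = review_error_pct,
    effort_boost_audited = effort_boost_audited,
    effort_boost_network = effort_boost_network
  )
  if (p$cycles_per_audit < 1L) abort("`cycles_per_audit` must be >= 1.")
  if (p$burn_in < 0L) abort("`burn_in` must be >= 0.")
  if (p$min_papers < 1L) abort("`min_papers` must be >= 1.")
  if (!is.numeric(p$cutoff_percentile) || p$cutoff_percentile <= 0 ||
      p$cutoff_percentile > 1) {
    abort("`cutoff_percentile` must be in (0, 1].")
  }
  check_number(p$cutoff_floor, "cutoff_floor", lower = 0)
  check_number(p$review_error_pct, "review_error_pct", lower = 0)
  check_number(p$effort_boost_audited, "effort_boost_audited", lower = 0)
  check_number(p$effort_boost_network, "effort_boost_network", lower = 0)
  structure(p, class = "audit_policy")
}

#' @rdname audit_policy
#' @export
no_audit_policy <- function() audit_policy(enabled = FALSE)

#' Audit cost model
#'
#' Auditor staffing and salary assumptions used to price each audit.  Every
#' audit of a lab with `p` papers costs, in `"results_consistent"` mode, one
#' auditor-month per paper (`p * annual_salary / 12`), and in
#' `"text_literal"` mode one auditor-month per started group of
#' `papers_per_auditor` papers (`ceiling(p / papers_per_auditor) *
#' annual_salary / 12`).  The two modes differ by a factor of
#' `papers_per_auditor`; the default reproduces the published cost-per-paper
#' figures (about USD 8,750 per audited paper).
#'
#' @param annual_salary Auditor annual salary in USD (default 105,000, the
#'   2016 average of professor and associate-professor salaries).
#' @param months_per_auditor Months each auditor is employed per audit
#'   (default 1).
#' @param papers_per_auditor Papers covered by one auditor in
#'   `"text_literal"` mode (default 10).
#' @param cost_mode `"results_consistent"` (default) or `"text_literal"`.
#'
#' @return A validated list of class `cost_model`.
#' @examples
#' audit_cost(50, cost_model())
#' audit_cost(50, cost_model(cost_mode = "text_literal"))
#' @export
cost_model <- function(annual_salary = 105000,
                       months_per_auditor = 1,
                       papers_per_auditor = 10L,
                       cost_mode = c("results_consistent", "text_literal")) {
  cost_mode <- match.arg(cost_mode)
  p <- list(
    annual_salary = annual_salary,
    months_per_auditor = months_per_auditor,
    papers_per_auditor = as.integer(papers_per_auditor),
    cost_mode = cost_mode
  )
  check_number(p$annual_salary, "annual_salary", lower = 1e-9)
  check_number(p$months_per_auditor, "months_per_auditor", lower = 1e-9)
  if (p$papers_per_auditor < 1L) abort("`papers_per_auditor` must be >= 1.")
  structure(p, class = "cost_model")
}

#' Scenario configuration
#'
#' Bundles world parameters, an audit policy, a cost model and the run plan
#' (cycle count, recording cadence, replicate count and master seed) into a
#' single object consumed by [run_simulation()], [run_scenario()] and
#' [sensitivity_grid()].
#'
#' @param params A [world_params()] object.
#' @param policy An [audit_policy()] object (use [no_audit_policy()] for the
#'   audit-free world).
#' @param cost A [cost_model()] object.
#' @param total_cycles Research cycles per replicate (default 800,000).
#' @param record_every Recording cadence in cycles (default 8,000, giving
#'   100 records per replicate); must divide `total_cycles`.
#' @param n_replicates Replicates run by [run_scenario()] (default 500).
#' @param master_seed Seed from which per-replicate seeds are derived.
#' @param label Scenario label carried through summaries.
#'
#' @return A validated list of class `scenario_config`.
#' @examples
#' scenario_config(policy = no_audit_policy(), n_replicates = 10)
#' @export
scenario_config <- function(params = world_params(),
                            policy = audit_policy(),
                            cost = cost_model(),
                            total_cycles = 800000L,
                            record_every = 8000L,
                            n_replicates = 500L,
                            master_seed = 42L,
                            label = "scenario") {
  stopifnot(inherits(params, "world_params"), inherits(policy, "audit_policy"),
            inherits(cost, "cost_model"))
  cfg <- list(
    params = params, policy = policy, cost = cost,
    total_cycles = as.integer(total_cycles),
    record_every = as.integer(record_every),
    n_replicates = as.integer(n_replicates),
    master_seed = as.integer(master_seed),
    label = as.character(label)
  )
  if (cfg$total_cycles < 1L) abort("`total_cycles` must be >= 1.")
  if (cfg$record_every < 1L) abort("`record_every` must be >= 1.")
  if (cfg$total_cycles %% cfg$record_every != 0L) {
    abort("`total_cycles` must be divisible by `record_every`.")
  }
  if (cfg$n_replicates < 1L) abort("`n_replicates` must be >= 1.")
  structure(cfg, class = "scenario_config")
}

# --- internal validators ---------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

check_prob <- function(x, name) check_number(x, name, lower = 0, upper = 1)

check_effort <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 1) || any(x > 100)) {
    abort(sprintf("`%s` must lie in the effort range [1, 100].", name))
  }
  invisible(x)
}
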