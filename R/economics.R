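#' Cost of a single audit
#'
#' Prices an audit of a lab holding `papers_at_audit` papers.  In
#' `"results_consistent"` mode (the default) each audited paper costs one
#' auditor-month; in `"text_literal"` mode one auditor covers
#' `papers_per_auditor` papers, so the audit costs one auditor-month per
#' started group of that size.  An auditor-month is
#' `annual_salary / 12 * months_per_auditor`.
#'
#' @param papers_at_audit Papers held by the audited lab (>= 1); vectorized.
#' @param model A [cost_model()] object.
#' @return Cost in USD.
#' @examples
#' audit_cost(50, cost_model())                              # 437,500
#' audit_cost(50, cost_model(cost_mode = "text_literal"))    # 43,750
#' @export
audit_cost <- function(papers_at_audit, model = cost_model()) {
  stopifnot(inherits(model, "cost_model"))
  if (!is.numeric(papers_at_audit) || any(is.na(papers_at_audit)) ||
      any(papers_at_audit < 1)) {
    abort("`papers_at_audit` must be >= 1.")
  }
  auditor_month <- model$annual_salary / 12 * model$months_per_auditor
  if (model$cost_mode == "results_consistent") {
    papers_at_audit * auditor_month
  } else {
    ceiling(papers_at_audit / model$papers_per_auditor) * auditor_month
  }
}

# Accept an auditsim_run, an audit_world, or a plain totals list.
as_world_totals <- function(x) {
  if (inherits(x, "auditsim_run") || inherits(x, "audit_world")) x$totals
  else if (is.list(x)) x
  else abort("Expected a simulation run, a world, or a totals list.")
}

#' Percentage of all published papers that were audited
#'
#' The audited share of the literature: 100 times the papers held by audited
#' labs at their audit times, divided by the cumulative papers produced by
#' all labs over the whole run (including labs later removed).
#'
#' @param x A simulation run ([run_simulation()]), an `audit_world`, or a
#'   totals list with `audited_papers` and `papers`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_papers_audited <- function(x) {
  t <- as_world_totals(x)
  if (is.null(t$papers) || t$papers <= 0) abort("No papers were produced.")
  100 * t$audited_papers / t$papers
}

#' Audit cost per published paper
#'
#' Total audit costs spread over every published paper (audited or not): the
#' surcharge each paper would carry to fund the audit system.
#'
#' @inheritParams percent_papers_audited
#' @return USD per paper.
#' @export
cost_per_paper <- function(x) {
  t <- as_world_totals(x)
  if (is.null(t$papers) || t$papers <= 0) abort("No papers were produced.")
  t$cost / t$papers
}

#' False positives (or mistakes) per 100 published papers
#'
#' Literature-quality summaries: cumulative false positives, or papers with
#' detectable mistakes, scaled to per 100 papers over a whole run, including
#' the output of labs that were later removed.
#'
#' @inheritParams percent_papers_audited
#' @return Rate per 100 papers.
#' @export
fp_per_100_papers <- function(x) {
  t <- as_world_totals(x)
  if (is.null(t$papers) || t$papers <= 0) abort("No papers were produced.")
  100 * t$false_positives / t$papers
}

#' @rdname fp_per_100_papers
#' @export
mistakes_per_100_papers <- function(x) {
  t <- as_world_totals(x)
  if (is.null(t$papers) || t$papers <= 0) abort("No papers were produced.")
  100 * t$mistakes / t$papers
}

#' Scale audit costs up to a national research system
#'
#' Applies a simulated audit coverage and per-paper cost to a national
#' annual paper count: how many papers would be audited each year, and what
#' the annual bill would be.
#'
#' @param annual_papers Papers the national system produces per year.
#' @param percent_audited Percentage of papers audited (e.g. 1.94).
#' @param cost_per_paper Audit cost per published paper in USD (e.g. 169).
#' @return A one-row tibble with `annual_papers`, `percent_audited`,
#'   `cost_per_paper`, `audited_papers` (rounded to the nearest paper) and
#'   `annual_cost` (USD).
#' @examples
#' national_scaleup(94000, 1.94, 169)   # NIH-funded output
#' national_scaleup(4138, 1.94, 169)    # NHMRC-funded output
#' @export
national_scaleup <- function(annual_papers, percent_audited, cost_per_paper) {
  check_number(annual_papers, "annual_papers", lower = 0)
  check_number(percent_audited, "percent_audited", lower = 0, upper = 100)
  check_number(cost_per_paper, "cost_per_paper", lower = 0)
  tibble::tibble(
    annual_papers = annual_papers,
    percent_audited = percent_audited,
    cost_per_paper = cost_per_paper,
    audited_papers = round(annual_papers * percent_audited / 100),
    annual_cost = annual_papers * cost_per_paper
  )
}
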