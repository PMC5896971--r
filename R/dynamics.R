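#' Probability of tackling a new hypothesis
#'
#' A lab with effort `e` takes on a new hypothesis in a given research cycle
#' with probability `1 - eta * log10(e)`: the less effort a lab spends per
#' hypothesis, the more hypotheses it has time to tackle.  At the default
#' `eta = 0.2` this gives 1 at the minimum effort of 1, 0.625 at the starting
#' effort of 75, and 0.6 at the maximum effort of 100.
#'
#' @param e Effort, in `[1, 100]`; vectorized.
#' @param eta Effort/output trade-off strength (default 0.2).
#' @return Tackling probability in `(0, 1]`.
#' @examples
#' prob_new_hypothesis(c(1, 75, 100))
#' @export
prob_new_hypothesis <- function(e, eta = 0.2) {
  check_effort(e, "e")
  check_number(eta, "eta", lower = 0)
  if (eta * log10(100) > 1) {
    abort("`eta` must satisfy eta * log10(100) <= 1.")
  }
  1 - eta * log10(e)
}

#' False-positive probability of a lab
#'
#' The probability that a lab declares a false hypothesis to be true:
#' `alpha = W / (1 + (1 - W) * e)` for power `W` and effort `e`.  It is
#' strictly decreasing in effort whenever `W < 1`: at `W = 0.8` it spans
#' 0.6667 (effort 1, the competitive-spiral ceiling) down to 0.0381
#' (effort 100), and equals the conventional 0.05 at the starting effort
#' of 75.
#'
#' @param W Power in `[0, 1]`; vectorized.
#' @param e Effort, at least 1; vectorized.
#' @return False-positive probability in `[0, 1)`.
#' @examples
#' false_positive_prob(0.8, c(1, 75, 100))
#' @export
false_positive_prob <- function(W, e) {
  if (!is.numeric(W) || any(is.na(W)) || any(W < 0) || any(W > 1)) {
    abort("`W` must lie in [0, 1].")
  }
  if (!is.numeric(e) || any(is.na(e)) || any(e < 1)) {
    abort("`e` must be >= 1.")
  }
  W / (1 + (1 - W) * e)
}

# --- world state -----------------------------------------------------------

#' Create a fresh research world
#'
#' Initializes `population_size` labs, all at the starting effort, with no
#' publication history and no lineage (founders have no parent).
#'
#' @param params A [world_params()] object.
#' @return An object of class `audit_world`: cycle counter, lab attribute
#'   vectors, cumulative world totals (which keep the output of labs that
#'   are later removed), and the audit log.
#' @examples
#' w <- new_world(world_params())
#' world_labs(w)
#' @export
new_world <- function(params = world_params()) {
  n <- params$population_size
  structure(list(
    cycle = 0L,
    labs = list(
      id = as.double(seq_len(n)),
      effort = rep(params$initial_effort, n),
      power = rep(params$power, n),
      birth_cycle = rep(0L, n),
      payoff = rep(0, n),
      papers = rep(0L, n),
      false_positives = rep(0L, n),
      mistakes = rep(0L, n),
      parent_id = rep(NA_real_, n),
      audited = rep(FALSE, n)
    ),
    next_id = n + 1,
    totals = list(papers = 0, false_positives = 0, mistakes = 0, audits = 0,
                  removals = 0, audited_papers = 0, cost = 0),
    audit_log = list()
  ), class = "audit_world")
}

#' Labs of a world as a tibble
#'
#' @param world An `audit_world`.
#' @return A tibble with one row per living lab.
#' @export
world_labs <- function(world) {
  stopifnot(inherits(world, "audit_world"))
  tibble::as_tibble(world$labs)
}

#' @export
print.audit_world <- function(x, ...) {
  cat(sprintf(
    "<audit_world> cycle %d, %d labs, mean effort %.2f, mean alpha %.4f\n",
    x$cycle, length(x$labs$id), mean(x$labs$effort),
    mean(false_positive_prob(x$labs$power, x$labs$effort))))
  cat(sprintf("  cumulative: %d papers, %d false positives, %d mistakes, %d audits\n",
              as.integer(x$totals$papers), as.integer(x$totals$false_positives),
              as.integer(x$totals$mistakes), as.integer(x$totals$audits)))
  invisible(x)
}

# Remove lab at position i from the attribute vectors.
labs_remove <- function(labs, i) {
  lapply(labs, function(v) v[-i])
}

lab_at <- function(labs, i) {
  lapply(labs, function(v) v[[i]])
}

# --- per-lab research step -------------------------------------------------

# Shared stochastic kernel: draws in the order tackle, truth, result,
# mistake (the last only for published false positives).  The C++ engine
# consumes the RNG stream in exactly this order.
lab_cycle_kernel <- function(effort, power, params) {
  out <- list(tackled = FALSE, hypothesis_true = NA, positive = NA,
              published = FALSE, false_positive = FALSE, mistake = FALSE)
  if (runif(1) >= prob_new_hypothesis(effort, params$eta)) return(out)
  out$tackled <- TRUE
  out$hypothesis_true <- runif(1) < params$truth_prior
  p_pos <- if (out$hypothesis_true) power else false_positive_prob(power, effort)
  out$positive <- runif(1) < p_pos
  out$published <- out$positive || params$publish_negatives
  if (!out$positive) return(out)
  if (!out$hypothesis_true) {
    out$false_positive <- TRUE
    out$mistake <- runif(1) < params$mistake_prob
  }
  out
}

#' Simulate one research cycle for a single lab
#'
#' Runs the per-lab stochastic sequence: tackle a new hypothesis (probability
#' [prob_new_hypothesis()]), draw its truth (probability `truth_prior`), and
#' test it (a true hypothesis is detected with probability `power`; a false
#' one is declared positive with probability [false_positive_prob()]).  The
#' result is written up as a paper (negative results too, unless
#' `publish_negatives` is off), but only a positive result earns the unit
#' pay-off that drives selection; a published false positive additionally
#' carries a detectable mistake with probability `mistake_prob`.
#'
#' @param lab A lab as a named list or one-row data frame with at least
#'   `effort`, `power`, `payoff`, `papers`, `false_positives`, `mistakes`.
#' @param params A [world_params()] object.
#' @return A list with the updated `lab` and an `outcome` list of logicals
#'   (`tackled`, `hypothesis_true`, `positive`, `published`,
#'   `false_positive`, `mistake`).
#' @examples
#' set.seed(1)
#' lab <- list(effort = 75, power = 0.8, payoff = 0, papers = 0L,
#'             false_positives = 0L, mistakes = 0L)
#' simulate_lab_cycle(lab, world_params())$outcome
#' @export
simulate_lab_cycle <- function(lab, params = world_params()) {
  if (is.data.frame(lab)) lab <- as.list(lab[1, ])
  outcome <- lab_cycle_kernel(lab$effort, lab$power, params)
  if (outcome$published) lab$papers <- lab$papers + 1L
  if (isTRUE(outcome$positive)) {
    lab$payoff <- lab$payoff + 1
    if (outcome$false_positive) {
      lab$false_positives <- lab$false_positives + 1L
      if (outcome$mistake) lab$mistakes <- lab$mistakes + 1L
    }
  }
  list(lab = lab, outcome = outcome)
}

# Research phase for the whole population (internal; updates world totals).
research_phase <- function(world, params) {
  labs <- world$labs
  n <- length(labs$id)
  for (i in seq_len(n)) {
    o <- lab_cycle_kernel(labs$effort[[i]], labs$power[[i]], params)
    if (o$published) {
      labs$papers[[i]] <- labs$papers[[i]] + 1L
      world$totals$papers <- world$totals$papers + 1
    }
    if (isTRUE(o$positive)) {
      labs$payoff[[i]] <- labs$payoff[[i]] + 1
      if (o$false_positive) {
        labs$false_positives[[i]] <- labs$false_positives[[i]] + 1L
        world$totals$false_positives <- world$totals$false_positives + 1
        if (o$mistake) {
          labs$mistakes[[i]] <- labs$mistakes[[i]] + 1L
          world$totals$mistakes <- world$totals$mistakes + 1
        }
      }
    }
  }
  world$labs <- labs
  world
}

# --- death-birth step ------------------------------------------------------

# Partial Fisher-Yates sample of k indices from 1..n, matching the C++
# engine's draw order.
fy_sample <- function(n, k) {
  pool <- seq_len(n)
  for (i in seq_len(k)) {
    j <- i + floor(runif(1) * (n - i + 1))
    tmp <- pool[i]; pool[i] <- pool[j]; pool[j] <- tmp
  }
  pool[seq_len(k)]
}

# Position (within vals) of the extreme value; ties broken uniformly with a
# single extra uniform draw only when there is more than one tied entry.
extreme_tie_uniform <- function(vals, maximize = TRUE) {
  best <- if (maximize) max(vals) else min(vals)
  tied <- which(vals == best)
  if (length(tied) == 1L) return(tied)
  tied[1L + floor(runif(1) * length(tied))]
}

#' Create a child lab
#'
#' The child inherits the parent's effort exactly, except that with
#' probability `mutation_prob` the inherited effort is perturbed by a
#' Normal(0, `mutation_sd`) offset; the result is clamped to `[1, 100]`.
#' The child starts with no papers, pay-off, false positives or mistakes,
#' is born in the given cycle, and records the parent's id.
#'
#' @param parent A lab as a named list (see [simulate_lab_cycle()]).
#' @param params A [world_params()] object.
#' @param cycle Birth cycle of the child.
#' @param id Id to assign to the child.
#' @return The child lab as a named list.
#' @examples
#' set.seed(1)
#' make_child(list(id = 7, effort = 75, power = 0.8), world_params())$effort
#' @export
make_child <- function(parent, params = world_params(), cycle = 0L, id = NA_real_) {
  if (is.data.frame(parent)) parent <- as.list(parent[1, ])
  e <- parent$effort
  if (runif(1) < params$mutation_prob) {
    e <- clamp_effort(e + rnorm(1, 0, params$mutation_sd))
  }
  list(id = id, effort = e, power = parent$power, birth_cycle = as.integer(cycle),
       payoff = 0, papers = 0L, false_positives = 0L, mistakes = 0L,
       parent_id = parent$id, audited = FALSE)
}

labs_append <- function(labs, child) {
  for (f in names(labs)) labs[[f]] <- c(labs[[f]], child[[f]])
  labs
}

# Birth step shared by the death-birth cycle and audit-removal replacement:
# sample birth_sample survivors, the richest (ties uniform) has one child.
birth_replacement <- function(world, params) {
  labs <- world$labs
  sampled <- fy_sample(length(labs$id), params$birth_sample)
  par_idx <- sampled[extreme_tie_uniform(labs$payoff[sampled], maximize = TRUE)]
  child <- make_child(lab_at(labs, par_idx), params, cycle = world$cycle,
                      id = world$next_id)
  world$next_id <- world$next_id + 1
  world$labs <- labs_append(labs, child)
  world
}

#' Death-birth replacement step
#'
#' Samples `death_sample` labs uniformly without replacement and removes the
#' oldest of them (age ties broken uniformly at random); then samples
#' `birth_sample` of the survivors and the one with the highest cumulative
#' pay-off (ties uniform) produces one child via [make_child()].  Population
#' size is conserved.
#'
#' @param world An `audit_world`.
#' @param params A [world_params()] object.
#' @return The updated world.
#' @examples
#' set.seed(1)
#' w <- new_world(world_params())
#' w$cycle <- 1L
#' w <- evolve_population(w, world_params())
#' nrow(world_labs(w))
#' @export
evolve_population <- function(world, params = world_params()) {
  stopifnot(inherits(world, "audit_world"))
  labs <- world$labs
  sampled <- fy_sample(length(labs$id), params$death_sample)
  dead_idx <- sampled[extreme_tie_uniform(labs$birth_cycle[sampled],
                                          maximize = FALSE)]
  world$labs <- labs_remove(labs, dead_idx)
  birth_replacement(world, params)
}

#' Run one complete research cycle
#'
#' Advances the world by one cycle: every lab runs its research step
#' ([simulate_lab_cycle()]), the death-birth step replaces one lab
#' ([evolve_population()]), and, when the cycle is a scheduled audit cycle
#' ([is_audit_cycle()]), one audit is conducted ([conduct_audit()]).
#'
#' This is the reference (pure-R) implementation of the engine;
#' [run_simulation()] uses a compiled equivalent for full-length runs and
#' both consume the RNG stream identically, so trajectories agree exactly
#' under the same seed.
#'
#' @param world An `audit_world`.
#' @param params A [world_params()] object.
#' @param policy An [audit_policy()] object.
#' @param cost A [cost_model()] object.
#' @return The updated world, with its cycle counter incremented.
#' @examples
#' set.seed(1)
#' w <- new_world(world_params())
#' w <- run_cycle(w, world_params(), no_audit_policy(), cost_model())
#' w$cycle
#' @export
run_cycle <- function(world, params = world_params(), policy = audit_policy(),
                      cost = cost_model()) {
  stopifnot(inherits(world, "audit_world"))
  world$cycle <- world$cycle + 1L
  world <- research_phase(world, params)
  world <- evolve_population(world, params)
  if (is_audit_cycle(world$cycle, policy)) {
    res <- conduct_audit(world, policy, params, cost)
    world <- res$world
    if (!is.null(res$record)) {
      world$audit_log[[length(world$audit_log) + 1L]] <- res$record
    }
  }
  world
}

clamp_effort <- function(e) pmin(100, pmax(1, e))
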