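# Shared fixtures: small configs and memoised full-length scenario runs used
# by the acceptance suite (each scenario is expensive, so run it once).

small_config <- function(total_cycles = 600L, record_every = 100L,
                         policy = audit_policy(cycles_per_audit = 20L,
                                               burn_in = 10L,
                                               min_papers = 5L),
                         params = world_params(), ...) {
  scenario_config(params = params, policy = policy,
                  total_cycles = total_cycles, record_every = record_every,
                  n_replicates = 1L, ...)
}

# A world where every lab already has a publication history, for audit tests.
seeded_world <- function(n = 100L, papers = 100L, fps = NULL, effort = 75) {
  w <- new_world(world_params(population_size = n,
                              death_sample = min(10L, n),
                              birth_sample = min(10L, n - 1L)))
  w$cycle <- 1000L
  w$labs$effort <- rep(effort, length.out = n)
  w$labs$papers <- rep(as.integer(papers), length.out = n)
  if (is.null(fps)) fps <- round(seq(0, 0.6, length.out = n) * papers)
  w$labs$false_positives <- as.integer(rep(fps, length.out = n))
  w$labs$mistakes <- as.integer(round(w$labs$false_positives * 0.25))
  w$labs$payoff <- as.numeric(w$labs$papers - w$labs$false_positives)
  w
}

.scenario_cache <- new.env(parent = emptyenv())

# Full-length (800,000-cycle) scenario runs at 12 replicates, master seed
# fixed up front; shared across the acceptance tests.
acceptance_scenario <- function(name) {
  if (!is.null(.scenario_cache[[name]])) return(.scenario_cache[[name]])
  n_rep <- 12L
  seed <- 101L
  cfg <- switch(name,
    none = scenario_config(policy = no_audit_policy(), n_replicates = n_rep,
                           master_seed = seed, label = "no audits"),
    j50 = scenario_config(policy = audit_policy(cycles_per_audit = 50L),
                          n_replicates = n_rep, master_seed = seed,
                          label = "j=50"),
    j75 = scenario_config(policy = audit_policy(cycles_per_audit = 75L),
                          n_replicates = n_rep, master_seed = seed,
                          label = "j=75"),
    mist200 = scenario_config(
      policy = audit_policy(cycles_per_audit = 200L,
                            statistic = "mistake_proportion",
                            effort_boost_audited = 1,
                            effort_boost_network = 0.5),
      n_replicates = n_rep, master_seed = seed, label = "mistake audits"),
    stop("unknown scenario: ", name)
  )
  .scenario_cache[[name]] <- run_scenario(cfg)
  .scenario_cache[[name]]
}

# Independent inverse-ECDF oracle: smallest sorted value whose empirical CDF
# reaches p, found by scanning (with the same float fuzz on n*p as the
# implementations under test).
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  for (i in seq_len(n)) {
    if (i >= n * p - 1e-9) return(s[i])
  }
  s[n]
}
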