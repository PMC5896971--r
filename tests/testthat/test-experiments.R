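test_that("spiral detection classifies the final record against the threshold", {
  expect_false(detect_spiral(tibble::tibble(mean_alpha = c(0.05, 0.05))))
  expect_true(detect_spiral(tibble::tibble(mean_alpha = c(0.05, 0.6667))))
  expect_true(detect_spiral(tibble::tibble(mean_alpha = c(0.9, 0.6))))   # inclusive
  expect_false(detect_spiral(tibble::tibble(mean_alpha = c(0.6667, 0.05))))
  expect_error(detect_spiral(tibble::tibble(mean_alpha = numeric(0))), "non-empty")
})

test_that("non-parametric CIs match a brute-force inverse-ECDF oracle", {
  expect_equal(nonparametric_ci(1:100), c(lower = 3, upper = 98))
  expect_equal(nonparametric_ci(rep(7, 10)), c(lower = 7, upper = 7))
  set.seed(40)
  for (i in 1:20) {
    s <- rnorm(sample(3:500, 1))
    ci <- nonparametric_ci(s)
    expect_equal(ci[["lower"]], oracle_quantile(s, 0.025))
    expect_equal(ci[["upper"]], oracle_quantile(s, 0.975))
    expect_lte(ci[["lower"]], stats::median(s))
    expect_gte(ci[["upper"]], stats::median(s))
  }
})

test_that("runs record at the requested cadence and are seed-deterministic", {
  cfg <- small_config(total_cycles = 8000L, record_every = 8000L)
  run <- run_simulation(cfg, seed = 41)
  expect_equal(nrow(run$records), 1L)
  cfg2 <- small_config(total_cycles = 2000L, record_every = 100L)
  expect_equal(nrow(run_simulation(cfg2, seed = 41)$records), 20L)
  a <- run_simulation(cfg2, seed = 42)
  b <- run_simulation(cfg2, seed = 42)
  expect_identical(a$records, b$records)
  expect_identical(a$labs, b$labs)
  expect_identical(a$audits, b$audits)
  # cumulative fields never decrease
  for (col in grep("^cum_", names(a$records), value = TRUE)) {
    expect_true(all(diff(a$records[[col]]) >= 0))
  }
})

test_that("without mutation or audits mean alpha stays at its closed form", {
  params <- world_params(mutation_prob = 0)
  cfg <- scenario_config(params = params, policy = no_audit_policy(),
                         total_cycles = 5000L, record_every = 500L)
  run <- run_simulation(cfg, seed = 43)
  expect_equal(run$records$mean_alpha, rep(0.05, 10))
  expect_equal(run$records$mean_effort, rep(75, 10))
})

test_that("scenario summaries aggregate replicates reproducibly", {
  cfg <- scenario_config(policy = no_audit_policy(), total_cycles = 2000L,
                         record_every = 1000L, n_replicates = 4L,
                         master_seed = 7L)
  s1 <- run_scenario(cfg)
  s2 <- run_scenario(cfg)
  expect_identical(s1$summary, s2$summary)
  expect_equal(nrow(tidy(s1)), 4L)
  g <- glance(s1)
  expect_lte(g$fp_per_100_lower, g$fp_per_100)
  expect_lte(g$fp_per_100, g$fp_per_100_upper)
  # single replicate: degenerate CIs equal to the replicate value
  cfg1 <- scenario_config(policy = no_audit_policy(), total_cycles = 2000L,
                          record_every = 1000L, n_replicates = 1L,
                          master_seed = 8L)
  g1 <- glance(run_scenario(cfg1))
  expect_equal(g1$fp_per_100_lower, g1$fp_per_100)
  expect_equal(g1$fp_per_100_upper, g1$fp_per_100)
})

test_that("the sensitivity grid covers the published 16 scenarios", {
  configs <- table3_scenarios(n_replicates = 2L, total_cycles = 1000L,
                              record_every = 500L)
  expect_length(configs, 16L)
  labels <- names(configs)
  expect_true("no audits" %in% labels)
  expect_false(configs[["no audits"]]$policy$enabled)
  expect_equal(configs[["j=50 baseline"]]$policy$cycles_per_audit, 50L)
  expect_equal(configs[["j=75 e0=10"]]$params$initial_effort, 10)
  m <- configs[["j=200 mistakes el+=1 en+=0.5"]]
  expect_equal(m$policy$statistic, "mistake_proportion")
  expect_equal(m$policy$effort_boost_audited, 1)
  expect_equal(m$policy$effort_boost_network, 0.5)
  grid <- sensitivity_grid(configs[c("no audits", "j=75 baseline")])
  expect_equal(nrow(grid), 2L)
  expect_true(all(diff(grid$pct_avoiding_spiral) <= 0))  # sorted best-first
})

test_that("tidy and glance expose replicate trajectories and statistics", {
  cfg <- small_config(total_cycles = 1000L, record_every = 100L)
  run <- run_simulation(cfg, seed = 44)
  expect_identical(tidy(run), run$records)
  g <- glance(run)
  expect_equal(g$papers, run$totals$papers)
  expect_equal(g$fp_per_100, 100 * run$totals$false_positives / run$totals$papers)
})
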