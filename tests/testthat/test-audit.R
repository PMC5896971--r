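test_that("audit scheduling starts after the burn-in, then every j cycles", {
  pol <- audit_policy(cycles_per_audit = 75L, burn_in = 100L)
  expect_false(is_audit_cycle(100, pol))
  expect_true(is_audit_cycle(175, pol))
  expect_false(is_audit_cycle(176, pol))
  expect_true(is_audit_cycle(250, pol))
  expect_false(any(is_audit_cycle(0:100, pol)))
  off <- no_audit_policy()
  expect_false(any(is_audit_cycle(c(150, 175, 1000), off)))
})

test_that("eligibility requires an unaudited lab with enough papers", {
  pol <- audit_policy(min_papers = 50L)
  w <- seeded_world(n = 4L, papers = c(49L, 50L, 51L, 200L))
  expect_setequal(eligible_labs(w, pol), c(2, 3, 4))  # boundary: "or more"
  w$labs$audited <- rep(TRUE, 4)
  expect_length(eligible_labs(w, pol), 0)
})

test_that("audit statistics measure what the policy asks for", {
  lab <- list(effort = 75, power = 0.8, papers = 50L, false_positives = 10L,
              mistakes = 2L)
  expect_equal(audit_statistic(lab, audit_policy()), 0.20)
  expect_equal(audit_statistic(lab, audit_policy(statistic = "alpha")), 0.05)
  expect_equal(
    audit_statistic(lab, audit_policy(statistic = "mistake_proportion")),
    0.04)
  # zero false positives observe zero even under reviewer noise
  clean <- modifyList(lab, list(false_positives = 0L))
  set.seed(5)
  expect_equal(audit_statistic(clean, audit_policy(review_error_pct = 20)), 0)
  nopapers <- modifyList(lab, list(papers = 0L))
  expect_error(audit_statistic(nopapers, audit_policy()), "no papers")
})

test_that("reviewer noise has the documented standard deviation and clamps", {
  expect_equal(apply_reviewer_noise(98, 0), 98)
  set.seed(6)
  expect_equal(apply_reviewer_noise(0, 20), 0)
  set.seed(7)
  obs <- replicate(4000, apply_reviewer_noise(98, 20, papers = 10000))
  expect_equal(sd(obs), 0.2 * 98 / 1.96, tolerance = 0.1)  # sd = 10
  expect_equal(mean(obs), 98, tolerance = 1)
  expect_true(all(obs == round(obs)))
  set.seed(8)
  capped <- replicate(500, apply_reviewer_noise(98, 400, papers = 100))
  expect_true(all(capped >= 0 & capped <= 100))
})

test_that("the removal cut-off is the empirical quantile, floored", {
  x <- seq(0.01, 1, by = 0.01)
  expect_equal(compute_cutoff(x, 0.67, 0.05), 0.67)
  expect_equal(compute_cutoff(rep(0.01, 100), 0.67, 0.05), 0.05)
  expect_equal(compute_cutoff(x, 1.0, 0.05), Inf)
  expect_error(compute_cutoff(numeric(0), 0.67), "non-empty")
  # oracle comparison on irregular samples
  set.seed(9)
  for (i in 1:20) {
    s <- runif(sample(5:200, 1))
    p <- runif(1, 0.01, 0.99)
    expect_equal(compute_cutoff(s, p, 0), oracle_quantile(s, p))
  }
})

test_that("a no-op audit policy only flags the audited lab", {
  pol <- audit_policy(cutoff_percentile = 1, effort_boost_audited = 0,
                      effort_boost_network = 0)
  w <- seeded_world()
  set.seed(30)
  res <- conduct_audit(w, pol, world_params(), cost_model())
  w2 <- res$world
  expect_false(res$record$removed)
  expect_equal(w2$labs$effort, w$labs$effort)
  expect_equal(w2$labs$papers, w$labs$papers)
  expect_equal(w2$labs$false_positives, w$labs$false_positives)
  expect_equal(w2$labs$mistakes, w$labs$mistakes)
  expect_equal(sum(w2$labs$audited), 1L)
  expect_equal(w2$labs$id[w2$labs$audited], res$record$lab_id)
})

test_that("a lab above the cut-off is removed and replaced", {
  # exactly one eligible lab, and its statistic tops the distribution
  w <- seeded_world()
  w$labs$audited <- rep(TRUE, 100)
  w$labs$audited[100] <- FALSE          # the dirtiest lab (fp prop 0.6)
  pol <- audit_policy(min_papers = 50L)
  set.seed(31)
  res <- conduct_audit(w, pol, world_params(), cost_model())
  expect_true(res$record$removed)
  expect_equal(res$record$lab_id, w$labs$id[100])
  expect_equal(length(res$world$labs$id), 100L)
  expect_false(w$labs$id[100] %in% res$world$labs$id)
  # replacement is a fresh child
  new_lab <- which(!res$world$labs$id %in% w$labs$id)
  expect_equal(res$world$labs$papers[new_lab], 0L)
})

test_that("audits never alter publication histories, only effort and flags", {
  pol <- audit_policy(min_papers = 50L, cutoff_percentile = 1)
  w <- seeded_world()
  set.seed(32)
  res <- conduct_audit(w, pol, world_params(), cost_model())
  expect_equal(res$world$labs$papers, w$labs$papers)
  expect_equal(res$world$labs$false_positives, w$labs$false_positives)
  expect_equal(res$world$labs$mistakes, w$labs$mistakes)
  expect_equal(res$world$labs$payoff, w$labs$payoff)
})

test_that("the effort boosts reach the audited lab and its living network", {
  params <- world_params()
  pol <- audit_policy(min_papers = 50L, cutoff_percentile = 1,
                      effort_boost_audited = 5, effort_boost_network = 2)
  w <- seeded_world(n = 6L, papers = c(100L, 10L, 10L, 10L, 10L, 10L))
  # lab 1 is the only eligible lab; labs 2 is its parent; 3, 4 its children
  w$labs$parent_id <- c(2, NA, 1, 1, NA, 6)
  w$labs$effort <- rep(50, 6)
  set.seed(33)
  res <- conduct_audit(w, pol, params, cost_model())
  expect_equal(res$world$labs$effort, c(55, 52, 52, 52, 50, 50))
  # boosts clamp at the effort ceiling
  w$labs$effort <- rep(99, 6)
  set.seed(34)
  res <- conduct_audit(w, pol, params, cost_model())
  expect_equal(res$world$labs$effort, c(100, 100, 100, 100, 99, 99))
})

test_that("about a third of audits remove the lab in a spread population", {
  # statistics evenly spread well above the floor: removal happens exactly
  # when the audited lab sits above the 67th percentile
  params <- world_params()
  pol <- audit_policy(min_papers = 50L, cutoff_percentile = 0.67)
  w <- seeded_world(fps = round(seq(0.1, 0.6, length.out = 100) * 100))
  set.seed(35)
  removed <- replicate(2000, {
    conduct_audit(w, pol, params, cost_model())$record$removed
  })
  expect_equal(mean(removed), 1 / 3, tolerance = 0.12)
})

test_that("no lab is ever audited twice over a whole run", {
  cfg <- scenario_config(
    policy = audit_policy(cycles_per_audit = 10L, burn_in = 10L,
                          min_papers = 5L),
    total_cycles = 3000L, record_every = 1000L)
  run <- run_simulation(cfg, seed = 36)
  expect_gt(nrow(run$audits), 50)
  survivors <- run$audits$lab_id[!run$audits$removed]
  expect_false(any(duplicated(survivors)))
  # audited survivors that are still alive carry the flag
  alive_flagged <- run$labs$id[run$labs$audited]
  expect_true(all(alive_flagged %in% survivors))
})
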