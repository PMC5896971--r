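test_that("tackling probability follows 1 - eta*log10(e)", {
  expect_equal(prob_new_hypothesis(100, 0.2), 0.6)
  expect_equal(prob_new_hypothesis(1, 0.2), 1.0)
  expect_equal(prob_new_hypothesis(75, 0.2), 1 - 0.2 * log10(75))
  expect_equal(round(prob_new_hypothesis(75, 0.2), 3), 0.625)
  # the formula, not the rounded prose value, is authoritative at e = 20
  expect_equal(prob_new_hypothesis(20, 0.2), 1 - 0.2 * log10(20),
               tolerance = 1e-12)
  expect_equal(round(prob_new_hypothesis(20, 0.2), 5), 0.73979)
  # strictly decreasing in effort
  e <- seq(1, 100, by = 0.5)
  expect_true(all(diff(prob_new_hypothesis(e)) < 0))
  expect_error(prob_new_hypothesis(0.5), "effort range")
  expect_error(prob_new_hypothesis(101), "effort range")
})

test_that("false-positive probability follows W/(1+(1-W)e)", {
  expect_equal(false_positive_prob(0.8, 75), 0.05)
  expect_equal(round(false_positive_prob(0.8, 1), 4), 0.6667)
  expect_equal(false_positive_prob(0, 10), 0)
  expect_equal(false_positive_prob(0.8, 100), 0.8 / 21)
  expect_equal(round(false_positive_prob(0.8, 100), 4), 0.0381)
  # strictly decreasing in effort for W < 1, and bounded on [1, 100]
  e <- seq(1, 100, by = 0.5)
  a <- false_positive_prob(0.8, e)
  expect_true(all(diff(a) < 0))
  expect_true(all(a >= 0.8 / 21 & a <= 0.8 / 1.2))
  expect_error(false_positive_prob(1.2, 10), "W")
  expect_error(false_positive_prob(0.8, 0), "e")
})

test_that("a published positive updates papers, pay-off and error counts together", {
  # truth_prior = 0 and mistake_prob = 1 force every positive to be a
  # false positive carrying a mistake
  params <- world_params(truth_prior = 0, mistake_prob = 1)
  lab <- list(effort = 1, power = 0.8, payoff = 0, papers = 0L,
              false_positives = 0L, mistakes = 0L)
  set.seed(421)
  for (i in 1:200) {
    res <- simulate_lab_cycle(lab, params)
    o <- res$outcome
    expect_true(o$tackled)            # e = 1 tackles with probability 1
    expect_false(o$hypothesis_true)
    d_papers <- res$lab$papers - lab$papers
    expect_equal(d_papers, 1L)        # every tested hypothesis is a paper
    if (o$positive) {
      expect_equal(res$lab$payoff - lab$payoff, 1)
      expect_equal(res$lab$false_positives - lab$false_positives, 1L)
      expect_equal(res$lab$mistakes - lab$mistakes, 1L)
    } else {
      expect_equal(res$lab$payoff, lab$payoff)
      expect_equal(res$lab$false_positives, lab$false_positives)
    }
    lab <- res$lab
  }
  # about 2/3 of hypotheses positive at e = 1, W = 0.8
  expect_gt(lab$payoff / lab$papers, 0.52)
  expect_lt(lab$payoff / lab$papers, 0.80)
})

test_that("per-cycle rates match their closed forms at e0 = 75", {
  # papers per lab-cycle = tackle prob 0.625; positives = 0.625 * (0.1*0.8
  # + 0.9*0.05) = 0.0781; false-positive share of positives = 0.36
  params <- world_params(mutation_prob = 0)
  cfg <- scenario_config(params = params, policy = no_audit_policy(),
                         total_cycles = 20000L, record_every = 20000L)
  run <- run_simulation(cfg, seed = 99)
  lab_cycles <- 100 * 20000
  expect_equal(run$totals$papers / lab_cycles, 1 - 0.2 * log10(75),
               tolerance = 0.01)
  expected_fp_rate <- 0.625 * 0.9 * 0.05
  expect_equal(run$totals$false_positives / lab_cycles, expected_fp_rate,
               tolerance = 0.03)
  # every tackled hypothesis is a paper, so the FP share of all papers is
  # P(false) * alpha = 0.9 * 0.05
  expect_equal(run$totals$false_positives / run$totals$papers, 0.045,
               tolerance = 0.03)
  # mistakes are a quarter of false positives
  expect_equal(run$totals$mistakes / run$totals$false_positives, 0.25,
               tolerance = 0.03)
})

test_that("children inherit effort exactly unless mutation fires", {
  parent <- list(id = 7, effort = 75, power = 0.8)
  set.seed(1)
  kids <- replicate(200, make_child(parent, world_params(mutation_prob = 0))$effort)
  expect_true(all(kids == 75))
  # clamping at the lower bound
  set.seed(2)
  low <- replicate(500, make_child(list(id = 1, effort = 1, power = 0.8),
                                   world_params(mutation_prob = 1))$effort)
  expect_true(all(low >= 1))
  expect_true(any(low == 1))  # negative offsets clamp to 1
  # mutation frequency and offset moments
  set.seed(3)
  kids <- replicate(20000, make_child(parent, world_params())$effort)
  mutated <- kids[kids != 75]
  expect_equal(length(mutated) / length(kids), 0.01, tolerance = 0.35)
  offsets <- mutated - 75
  expect_lt(abs(mean(offsets)), 0.2)
  expect_equal(sd(offsets), 1, tolerance = 0.25)
})

test_that("death-birth conserves population and breaks ties uniformly", {
  params <- world_params()
  set.seed(10)
  w0 <- new_world(params)
  w0$cycle <- 1L
  w1 <- evolve_population(w0, params)
  expect_equal(length(w1$labs$id), 100L)
  expect_equal(sum(!w1$labs$id %in% w0$labs$id), 1L)  # one new lab

  # all founders share age 0 and pay-off 0: the removed lab is uniform over
  # the population by symmetry of sampling + uniform tie-breaking
  set.seed(11)
  removed <- integer(4000)
  for (i in seq_along(removed)) {
    w <- evolve_population(w0, params)
    removed[i] <- setdiff(w0$labs$id, w$labs$id)
  }
  counts <- tabulate(removed, nbins = 100)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-4)
})

test_that("a strictly richest lab in the birth sample always reproduces", {
  # 11 labs, birth_sample = 10: after the death the whole survivor set is
  # sampled, so the unique pay-off maximum must be the parent whenever it
  # survives -- and it always survives because it is the unique youngest.
  params <- world_params(population_size = 11L, death_sample = 10L,
                         birth_sample = 10L)
  w <- new_world(params)
  w$cycle <- 10L
  w$labs$payoff[5] <- 1e9
  w$labs$birth_cycle <- c(rep(0L, 4), 9L, rep(0L, 6))
  set.seed(12)
  for (i in 1:50) {
    w2 <- evolve_population(w, params)
    new_lab <- which(!w2$labs$id %in% w$labs$id)
    expect_equal(w2$labs$parent_id[new_lab], w$labs$id[5])
  }
})

test_that("run_cycle increments the cycle and conserves the counters", {
  params <- world_params()
  set.seed(20)
  w <- new_world(params)
  for (i in 1:30) {
    w <- run_cycle(w, params, no_audit_policy(), cost_model())
    expect_equal(w$cycle, i)
    expect_equal(length(w$labs$id), 100L)
    expect_true(all(w$labs$false_positives <= w$labs$payoff))
    expect_true(all(w$labs$payoff <= w$labs$papers))
    expect_true(all(w$labs$mistakes <= w$labs$false_positives))
  }
  expect_gte(w$totals$papers, sum(w$labs$papers))  # removed labs count too
})
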