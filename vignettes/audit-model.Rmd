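---
title: "Random audits in a publish-or-perish research world: the model behind auditsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random audits in a publish-or-perish research world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auditsim)
```

# The model

`auditsim` simulates a research world of 100 competing labs in which career
rewards flow from the *quantity* of published positive results, and asks
whether randomly auditing a small share of the literature can stop the
resulting erosion of quality.

## Labs and the research cycle

Each lab $i$ carries a heritable effort $e_i \in [1, 100]$ and a fixed
statistical power $W = 0.8$. One *research cycle* consists of, for every
lab:

1. **Tackling.** The lab takes on a new hypothesis with probability
   $1 - \eta \log_{10} e_i$ (with $\eta = 0.2$): low-effort labs have time
   for more hypotheses. At the extremes, effort 1 tackles every cycle and
   effort 100 tackles with probability 0.6.
2. **Truth.** A tackled hypothesis is true with probability 0.1 — most
   novel hypotheses in the biomedical world are false.
3. **Testing.** A true hypothesis is detected positive with probability
   $W$; a false one is *falsely* declared positive with probability
   $$\alpha_i = \frac{W}{1 + (1 - W)\,e_i},$$
   which decreases from $0.67$ at effort 1 to $0.038$ at effort 100 and
   equals the conventional $0.05$ at the starting effort $e_0 = 75$.
4. **Publication and pay-off.** The result is written up as a paper.
   Only *positive* papers earn the unit pay-off that drives selection.
   A published false positive carries a detectable *mistake* with
   probability 0.25.

After the research phase comes a death–birth step: 10 labs are sampled
uniformly and the oldest dies (ties uniform at random); 10 of the survivors
are sampled and the one with the highest cumulative pay-off produces a
child, which inherits its effort exactly except that with probability 0.01
a Normal$(0, 1)$ mutation is added (clamped to $[1, 100]$).

Because pay-off counts positive papers, selection favours low effort —
more hypotheses per cycle *and* a higher positive rate on false hypotheses.
Left alone, the population drifts and then collapses into the
**competitive spiral**: effort pinned at 1, mean $\alpha$ at its ceiling of
$0.67$. The end states are strongly bimodal (mean $\alpha$ near 0.05 or
near 0.67), so we classify a replicate as spiralled when its final recorded
mean $\alpha$ is at least 0.6; the threshold sits in the empty region
between the modes and results are insensitive to its exact placement —
`detect_spiral()` exposes it as an argument so that sensitivity is easy to
check.

## Publication of negative results

Negative results are written up and counted as papers, but earn no pay-off.
This matters for every per-paper quantity: the steady-state share of false
positives among *all* papers at effort 75 is $0.9 \times 0.05 = 4.5$ per
100 papers, rising to 60 per 100 deep in the spiral, and the cumulative
no-audit average lands near 30 per 100 papers — bracketed by how early each
replicate spirals. Counting only positive papers would both bound the
false-positive rate below at about 30 per 100 (its value at effort 100) and
starve the audit system of eligible labs (a lab would need several hundred
cycles to accumulate 50 positive papers, far beyond typical lab lifespans),
neither of which matches the behaviour this model family reports. A
`publish_negatives = FALSE` switch in `world_params()` restricts the
published record to positive results for exploration.

## Audits

After a 100-cycle burn-in, an audit runs every $j$ cycles. One lab is
selected uniformly from those that were never audited before and hold at
least $n = 50$ papers (with no eligible lab the audit is skipped, not
deferred). The auditors measure one of three statistics, set by
`audit_policy(statistic = ...)`:

* `false_positive_proportion` (default): the lab's realized
  $\mathrm{FP}_i / \mathrm{papers}_i$. The default because the reviewer-noise
  model perturbs a *count* of false positives, which only a count-based
  statistic can absorb.
* `alpha`: the lab's current $\alpha_i$ implied by its effort — the
  idealized "perfect view" reading of the audit.
* `mistake_proportion`: cumulative mistakes over papers, the practical
  proxy used when false positives cannot be observed directly.

The lab is **removed** when its observed statistic exceeds the cut-off
$c$: the 67th-percentile (configurable) inverse-ECDF quantile of the
*current* 100 labs' un-noised statistics, floored at 0.05 for the
false-positive statistics so that labs are never removed from an already
clean population (no floor by default for the mistake statistic, which has
no natural 0.05 scale). A removed lab is replaced through the ordinary
birth step. `cutoff_percentile = 1` disables removal entirely.

A surviving audited lab raises its effort by $el^+$ (default 5), and —
whether or not the lab is removed — its direct parent and children still
alive raise theirs by $en^+$ (default 5), all clamped to $[1, 100]$. This
*network effect* is the main channel through which audits work: a single
audit improves several labs at once.

Reviewer error (`review_error_pct = 20`) replaces the audited lab's
false-positive count $F$ by $F + \mathrm{round}(\varepsilon)$,
$\varepsilon \sim N(0, (0.2 F / 1.96)^2)$, clamped to $[0,
\mathrm{papers}]$, so roughly 95% of observed counts fall within $\pm$20%
of the truth. The cut-off distribution always uses un-noised values: noise
models the audit of one lab, not the auditors' background knowledge.

## Costs

Each audit is priced at one auditor-month — an annual salary of USD
105,000 over 12 — per audited paper (`cost_mode = "results_consistent"`).
A stricter reading of the staffing assumption (one auditor per started
group of 10 papers, one month each) is available as
`cost_mode = "text_literal"`; the two differ by exactly the factor
`papers_per_auditor = 10`. The default mode is the one under which the
cost per published paper equals the auditor-month rate times the audited
fraction of the literature (about USD 169 per paper when 1.94% of papers
are audited), which is the arithmetic the reported national scale-ups
(`national_scaleup()`) follow. Costs of establishing and governing the
audit system are out of scope.

# Numerical choices

* **Quantiles.** The removal cut-off and the scenario summaries' 95%
  intervals both use the inverse-ECDF (type-1) empirical quantile
  $x_{(\lceil np \rceil)}$, computed with a $10^{-9}$ fuzz on $np$ so that
  floating-point noise around integer $np$ (e.g. $0.025 \times 440$)
  resolves to the same order statistic in R and in C++.
* **Ties.** Age ties in the death step and pay-off ties in the birth step
  are broken uniformly at random, consuming one extra uniform draw only
  when a tie actually occurs.
* **Clamping.** Effort is clamped to $[1, 100]$ after mutation and after
  every audit boost; the bounds themselves are attainable states.
* **Spiral classification** is inclusive at the threshold
  (`mean_alpha >= threshold`).
* **Degenerate inputs.** Labs with zero papers contribute a zero
  proportion to the cut-off distribution; the audit statistic of a single
  zero-paper lab is an error; an empty eligible set skips the audit.

# Determinism and the two engines

All randomness flows through R's global RNG. The production engine is
compiled C++; a pure-R reference engine (`run_simulation(engine = "r")`)
performs the same loop drawing from the RNG in a documented identical
order, and the test suite asserts *bit-identical* trajectories, audit logs
and final populations between the two under the same seed — an end-to-end
check that the compiled code implements exactly the model described here.
Replicate seeds are derived from a scenario master seed via `sample.int()`,
so whole scenario summaries are reproducible from one integer and
independent of execution order.

# Scenario runs and problem sizes

The published experimental design — 800,000 research cycles recorded every
8,000th cycle (100 records), 500 replicates per scenario — is the package
default (`scenario_config()`). The package's own test suite and the
bundled acceptance script run the same full-length worlds at 12 and 30
replicates respectively: spiral-avoidance percentages are then subject to
binomial sampling error (about $\pm 8$ points at 30 replicates for a rate
near 71%), which is the right yardstick when comparing them to the
500-replicate values. Cycle counts are never shortened for these checks,
because spiral onset times span the whole 800,000-cycle horizon and a
shorter world would misclassify late spirals.

# What the simulator does and does not show

The generator *is* the study object here — there is no external data — but
it remains a deliberately naive picture of research: one hypothesis per lab
per cycle, a single scalar quality knob, perfectly observable publication
histories, mistakes only inside false-positive papers, no grace periods or
repeat audits, no strategic reaction to the audit rule beyond the fixed
effort boosts, and a linear effort response regardless of a lab's current
effort. Conclusions about real audit policy would need a trial; what the
package supports is reasoning about the *model*: which audit parameters
($j$, $n$, $c$, $el^+$, $en^+$) preserve quality in this world, at what
simulated cost.

Known limitations worth keeping in mind when reading results:

* The audited statistic and the selection pressure both derive from the
  same publication process; audits that remove labs reshape the cut-off
  distribution itself over time.
* Spiral-avoidance rates for intermediate audit intensities (e.g. the
  mistake-audit scenario) are sensitive to fine details of audit
  book-keeping — the phase of the audit schedule, the handling of the
  removed lab's replacement, the exact eligibility pool — that the model
  family fixes by convention; such percentages carry more model
  uncertainty than the coverage and cost quantities, which are governed by
  robust steady-state arithmetic.
* With `cutoff_percentile = 1` audits never remove anyone, yet still
  confer effort boosts; this is the configuration that isolates the
  behavioural channel from the punitive one.

# A worked example

```{r example, eval = FALSE}
library(auditsim)

cfg <- scenario_config(
  policy = audit_policy(cycles_per_audit = 50),
  n_replicates = 30, master_seed = 1, label = "j = 50"
)
sc <- run_scenario(cfg)
glance(sc)[, c("pct_avoiding_spiral", "pct_papers_audited", "cost_per_paper")]
```

At 30 replicates this reports roughly 95–100% of replicates avoiding the
spiral, about 1.9% of all papers audited, and an audit surcharge of about
USD 170 per published paper; `tidy(sc)` exposes the replicate-level values
behind the interval columns, and `run_scenario(..., keep_records = TRUE)`
keeps the trajectories for `plot_trajectories()`.
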