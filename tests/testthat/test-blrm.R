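test_that("dlt_probability matches the closed-form logistic and is monotone", {
  expect_equal(dlt_probability(0, 0.7, 720, 720), 0.5)
  expect_equal(dlt_probability(0, -3, 720, 720), 0.5)
  expect_equal(dlt_probability(qlogis(0.2), 0, 500, 500), 0.2)
  # dose = e * ref with unit slope adds exactly 1 on the logit scale
  expect_equal(dlt_probability(-1.3862944, 0, exp(1) * 180, 180),
               plogis(-1.3862944 + 1), tolerance = 1e-12)

  doses <- c(10, 40, 120, 360, 720, 1000, 5000)
  for (lb in c(-2, 0, 1.5)) {
    p <- dlt_probability(-1, lb, doses, 720)
    expect_true(all(diff(p) > 0))
    expect_true(all(p > 0 & p < 1))
  }
  expect_error(dlt_probability(0, 0, -5, 720), "positive")
  expect_error(dlt_probability(0, 0, 100, 0), "positive")
})

test_that("cohort_records validates its invariants", {
  expect_error(cohort_records(40, 3, 4), "exceed")
  expect_error(cohort_records(-1, 3, 0), "positive")
  expect_error(cohort_records(40, 0, 0), ">= 1")
  expect_silent(cohort_records(numeric(), integer(), integer()))
})

test_that("posterior weights are normalised and the prior is recovered", {
  pr <- blrm_prior(720)
  post0 <- fit_posterior(pr)
  expect_lt(abs(sum(post0$weights) - 1), 1e-10)

  # zero cohorts: grid summaries match the prior Monte-Carlo within 0.005
  mc <- mc_posterior_oracle(pr, cohort_records(numeric(), integer(),
                                               integer()), 720)
  ip <- interval_probabilities(post0, 720)
  expect_true(all(abs(ip - mc) < 0.005))

  # and after data, for several <=3-cohort cases and doses
  cases <- list(
    cohort_records(c(40, 120), c(3, 3), c(0, 1)),
    cohort_records(c(120, 360, 720), c(3, 3, 3), c(0, 1, 2)),
    cohort_records(1000, 5, 1))
  for (ch in cases) {
    post <- fit_posterior(pr, ch)
    expect_lt(abs(sum(post$weights) - 1), 1e-10)
    for (d in c(120, 720, 1000)) {
      mc <- mc_posterior_oracle(pr, ch, d)
      ip <- interval_probabilities(post, d)
      expect_true(all(abs(ip - mc) < 0.005),
                  label = sprintf("grid vs MC at dose %g", d))
    }
  }
})

test_that("slope-degenerate posterior matches 1-D quadrature", {
  # log_beta pinned at -20: slope ~ 2e-9, all doses share one p
  pr <- blrm_prior(720, mean_log_alpha = qlogis(0.2), sd_log_alpha = 2,
                   mean_log_beta = -20, sd_log_beta = 1e-8)
  # a fine alpha grid: interval probabilities pay an O(h) boundary cut
  post <- fit_posterior(pr, cohort_records(360, 10, 2),
                        grid = grid_spec(n_alpha = 200001, n_beta = 3))
  oracle <- quad1d_interval_probs(qlogis(0.2), 2, x = 2, n = 10)
  got <- interval_probabilities(post, 360)
  expect_true(all(abs(got - oracle) < 1e-4))
  # and the shared-p property itself
  expect_equal(interval_probabilities(post, 40), got, tolerance = 1e-9)
})

test_that("grid truncation warns; interval probabilities partition to 1", {
  pr <- blrm_prior(720)
  expect_warning(fit_posterior(pr, grid = grid_spec(alpha_bounds = c(-2, 2))),
                 "truncate")
  post <- suppressWarnings(
    fit_posterior(pr, cohort_records(720, 3, 1),
                  grid = grid_spec(n_alpha = 101, n_beta = 101)))
  for (d in c(40, 720, 1000)) {
    ip <- interval_probabilities(post, d)
    expect_lt(abs(sum(ip) - 1), 1e-9)
    expect_true(all(ip >= 0))
  }
})

test_that("degenerate posteriors give the textbook interval summaries", {
  p05 <- degenerate_posterior(0.05)
  expect_equal(unname(interval_probabilities(p05, 720)), c(1, 0, 0))
  p40 <- degenerate_posterior(0.40)
  expect_equal(unname(interval_probabilities(p40, 720)), c(0, 0, 1))
  rules <- escalation_rules(cap_threshold_mg = 120)
  a <- ewoc_admissible(degenerate_posterior(0.10), 500, rules)
  expect_true(a$admissible)
  expect_equal(a$overdose_prob, 0)
  b <- ewoc_admissible(degenerate_posterior(0.50), 500, rules)
  expect_false(b$admissible)
  expect_equal(b$overdose_prob, 1)
})

test_that("escalation caps follow the two studies' step rules", {
  q3w <- escalation_rules(cap_threshold_mg = 120)
  qw <- escalation_rules(cap_threshold_mg = 40)
  expect_equal(escalation_cap(40, q3w), 120)   # the study's actual step
  expect_equal(escalation_cap(120, q3w), 360)
  expect_equal(escalation_cap(360, q3w), 720)  # +100% above threshold
  expect_equal(escalation_cap(120, qw), 240)
  expect_error(escalation_cap(0, q3w), "range")
})

test_that("EWOC admissibility is monotone in dose", {
  pr <- blrm_prior(720)
  rules <- escalation_rules(cap_threshold_mg = 120)
  doses <- c(40, 120, 360, 720, 1000, 1500)
  datasets <- list(
    cohort_records(numeric(), integer(), integer()),
    cohort_records(c(40, 120), c(3, 3), c(0, 2)),
    cohort_records(c(360, 720), c(3, 6), c(1, 3)),
    cohort_records(1000, 3, 3))
  for (ch in datasets) {
    post <- fit_posterior(pr, ch)
    op <- vapply(doses, function(d)
      ewoc_admissible(post, d, rules)$overdose_prob, numeric(1))
    # overdose probability is nondecreasing in dose, so inadmissibility
    # propagates upward
    expect_true(all(diff(op) >= -1e-12))
  }
})

test_that("adding a DLT never decreases the overdose probability above it", {
  pr <- blrm_prior(720)
  rules <- escalation_rules(cap_threshold_mg = 120)
  base <- cohort_records(c(120, 360, 720), c(3, 3, 6), c(0, 1, 1))
  bumped <- base
  bumped$n_dlt_patients[2] <- bumped$n_dlt_patients[2] + 1L  # extra DLT @360
  p0 <- fit_posterior(pr, base)
  p1 <- fit_posterior(pr, bumped)
  for (d in c(360, 720, 1000)) {
    expect_gte(ewoc_admissible(p1, d, rules)$overdose_prob,
               ewoc_admissible(p0, d, rules)$overdose_prob - 1e-12)
  }
})

test_that("next-dose recommendation filters and maximises correctly", {
  levels <- c(40, 120, 360, 720, 1000)
  rules <- escalation_rules(cap_threshold_mg = 120)
  pr <- blrm_prior(720)

  # all levels inadmissible -> stop
  rec <- recommend_next_dose(degenerate_posterior(0.9), tested_doses = 40,
                             provisional_levels = levels, rules = rules)
  expect_true(rec$stop)
  expect_true(is.na(rec$dose))

  # trial start -> lowest level
  post <- fit_posterior(pr)
  rec0 <- recommend_next_dose(post, numeric(), levels, rules)
  expect_equal(rec0$dose, 40)

  # the study's early path: 0/3@40, 0/2@120, 0/2@360. The cap from 360
  # allows 720; no-skip also forbids 1000. 720 maximises p_target among
  # the admissible candidates.
  seen <- cohort_records(c(40, 120, 360), c(3, 2, 2), c(0, 0, 0))
  post <- fit_posterior(pr, seen)
  rec <- recommend_next_dose(post, seen$dose_mg, levels, rules)
  expect_false(rec$stop)
  expect_equal(rec$dose, 720)
  expect_true(all(rec$table$admissible[rec$table$dose_mg <= 720]))
  # cross-check the p_target ordering on candidates with the MC oracle
  mc720 <- mc_posterior_oracle(pr, seen, 720)
  mc360 <- mc_posterior_oracle(pr, seen, 360)
  expect_gt(mc720[["target"]], mc360[["target"]])

  # single admissible level -> that level
  rec1 <- recommend_next_dose(post, tested_doses = 40,
                              provisional_levels = c(40), rules = rules)
  expect_equal(rec1$dose, 40)
  expect_error(recommend_next_dose(post, 40, numeric(), rules), "nonempty")
})

test_that("p_target ties break toward the higher dose", {
  # flat-in-dose posterior: every level has identical p_target
  post <- degenerate_posterior(0.20)
  rules <- escalation_rules(cap_threshold_mg = 120, allow_skipping = TRUE)
  rec <- recommend_next_dose(post, tested_doses = c(40, 120),
                             provisional_levels = c(40, 120, 240),
                             rules = rules)
  expect_equal(rec$dose, 240)
})

test_that("no-skip constraint holds untested intermediate levels", {
  pr <- blrm_prior(720)
  rules <- escalation_rules(cap_threshold_mg = 120)  # 360 -> cap 720
  seen <- cohort_records(c(40, 120), c(3, 3), c(0, 0))
  post <- fit_posterior(pr, seen)
  rec <- recommend_next_dose(post, seen$dose_mg, c(40, 120, 360, 720, 1000),
                             rules)
  expect_equal(rec$dose, 360)  # 360 is the lowest untested level
})

test_that("MTD declaration honours admissibility and patient minimum", {
  pr <- blrm_prior(720)
  rules <- escalation_rules(cap_threshold_mg = 120)

  # 0/3 at 40 mg cannot trip overdose control under the reference prior
  ch <- cohort_records(40, 3, 0)
  post <- fit_posterior(pr, ch)
  expect_true(ewoc_admissible(post, 40, rules)$admissible)
  decl <- declare_mtd(post, ch, rules, mtd_rule(min_patients_at_mtd = 3))
  expect_true(decl$determined)
  expect_equal(decl$mtd_mg, 40)

  # with the default 6-patient minimum the same data give "not determined"
  decl6 <- declare_mtd(post, ch, rules, mtd_rule())
  expect_false(decl6$determined)

  # uniformly toxic posterior -> not determined regardless
  decl_tox <- declare_mtd(degenerate_posterior(0.9), ch, rules, mtd_rule())
  expect_false(decl_tox$determined)
  expect_true(is.na(decl_tox$mtd_mg))
})
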