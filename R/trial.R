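#' Assumed true dose-toxicity scenario
#'
#' The "truth" object for design evaluation: a DLT probability for every
#' provisional dose, nondecreasing in dose.
#'
#' @param doses_mg strictly increasing provisional doses (mg).
#' @param prob_dlt true DLT probabilities in \[0, 1\], nondecreasing.
#' @return A data.frame of class `"tox_scenario"`.
#' @export
tox_scenario <- function(doses_mg, prob_dlt) {
  if (length(doses_mg) != length(prob_dlt))
    stop("`doses_mg` and `prob_dlt` must have equal length", call. = FALSE)
  if (is.unsorted(doses_mg, strictly = TRUE))
    stop("`doses_mg` must be strictly increasing", call. = FALSE)
  if (any(prob_dlt < 0 | prob_dlt > 1))
    stop("`prob_dlt` must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(prob_dlt))
    stop("`prob_dlt` must be nondecreasing in dose", call. = FALSE)
  structure(data.frame(dose_mg = doses_mg, prob_dlt = prob_dlt),
            class = c("tox_scenario", "data.frame"))
}

#' Complete design configuration for a BLRM-EWOC trial
#'
#' Bundles the prior, escalation rules, MTD rule, toxicity intervals,
#' provisional dose ladder and operational constants. Defaults follow
#' common phase-I practice where the studies are silent: cohorts of 3,
#' at most 30 patients, DLT window of 21 days, expansion at the declared
#' MTD until the patient budget is spent.
#'
#' @param prior a [blrm_prior()].
#' @param rules an [escalation_rules()].
#' @param provisional_levels strictly increasing dose ladder (mg).
#' @param start_dose starting dose; must be a provisional level.
#' @param mtd a [mtd_rule()].
#' @param intervals a [toxicity_intervals()].
#' @param cohort_size patients per escalation cohort.
#' @param max_patients total patient budget.
#' @param schedule label, `"Q3W"` or `"QW"`.
#' @param dlt_window_days DLT evaluation window (first cycle).
#' @param expand_at_mtd enroll remaining patients at the declared MTD?
#' @param grid a [grid_spec()] used for every interim fit.
#' @return A list of class `"design_config"`.
#' @export
design_config <- function(prior, rules, provisional_levels,
                          start_dose = min(provisional_levels),
                          mtd = mtd_rule(), intervals = toxicity_intervals(),
                          cohort_size = 3L, max_patients = 30L,
                          schedule = c("Q3W", "QW"), dlt_window_days = 21,
                          expand_at_mtd = TRUE, grid = grid_spec()) {
  stopifnot(inherits(prior, "blrm_prior"), inherits(rules, "escalation_rules"),
            inherits(mtd, "mtd_rule"))
  if (is.unsorted(provisional_levels, strictly = TRUE))
    stop("`provisional_levels` must be strictly increasing", call. = FALSE)
  if (!start_dose %in% provisional_levels)
    stop("`start_dose` must be a provisional level", call. = FALSE)
  check_number(cohort_size, "cohort_size", lower = 1)
  check_number(max_patients, "max_patients", lower = 1)
  structure(list(prior = prior, rules = rules, mtd = mtd,
                 intervals = intervals,
                 provisional_levels = provisional_levels,
                 start_dose = start_dose,
                 cohort_size = as.integer(cohort_size),
                 max_patients = as.integer(max_patients),
                 schedule = match.arg(schedule),
                 dlt_window_days = dlt_window_days,
                 expand_at_mtd = expand_at_mtd, grid = grid),
            class = "design_config")
}

# Precomputed machinery for repeated fits under one design: node lattice,
# prior log-density, and per-dose log(p) / log1p(-p) vectors so that each
# interim posterior is a pure vector-arithmetic update. Functionally
# identical to fit_posterior(); the equivalence is asserted in the tests.
design_engine <- function(design) {
  g <- make_grid(design$prior, design$grid)
  slope <- exp(g$lb_vec)
  doses <- design$provisional_levels
  lp <- lapply(doses, function(d) {
    p <- plogis(g$la_vec + slope * log(d / design$prior$ref_dose_mg))
    list(p = p, logp = log(p), log1mp = log1p(-p),
         over = p >= design$rules$overdose_cutoff,
         under = p < design$intervals$under_upper,
         target = p >= design$intervals$under_upper &
                  p < design$intervals$target_upper)
  })
  names(lp) <- as.character(doses)
  list(grid = g, per_dose = lp, design = design)
}

engine_fit <- function(eng, cohorts) {
  lw <- eng$grid$log_prior
  for (i in seq_len(nrow(cohorts))) {
    pd <- eng$per_dose[[as.character(cohorts$dose_mg[i])]]
    x <- cohorts$n_dlt_patients[i]; n <- cohorts$n_patients[i]
    # guard the x = 0 / x = n cases: p saturates to 0/1 at extreme nodes
    # and 0 * -Inf would poison the lattice with NaN
    if (x > 0) lw <- lw + x * pd$logp
    if (n - x > 0) lw <- lw + (n - x) * pd$log1mp
  }
  w <- exp(lw - max(lw))
  w / sum(w)
}

engine_summary <- function(eng, w) {
  design <- eng$design
  doses <- design$provisional_levels
  tab <- do.call(rbind, lapply(seq_along(doses), function(i) {
    pd <- eng$per_dose[[i]]
    data.frame(dose_mg = doses[i],
               p_under = sum(w[pd$under]), p_target = sum(w[pd$target]),
               p_over = sum(w[pd$over]), overdose_prob = sum(w[pd$over]))
  }))
  tab$admissible <- tab$overdose_prob < design$rules$ewoc_feasibility
  tab
}

# next-dose logic shared by replay and simulation; mirrors
# recommend_next_dose() but on a precomputed summary table
engine_recommend <- function(eng, tab, tested_doses) {
  design <- eng$design
  if (!length(tested_doses))
    return(list(dose = design$start_dose, stop = FALSE))
  cap <- escalation_cap(max(tested_doses), design$rules)
  tab$cap_ok <- tab$dose_mg <= cap
  if (design$rules$allow_skipping) {
    tab$skip_ok <- TRUE
  } else {
    untested <- setdiff(design$provisional_levels, tested_doses)
    tab$skip_ok <- tab$dose_mg <=
      (if (length(untested)) min(untested) else Inf)
  }
  ok <- tab$admissible & tab$cap_ok & tab$skip_ok
  if (!any(ok)) return(list(dose = NA_real_, stop = TRUE))
  cand <- tab[ok, ]
  best <- cand[cand$p_target >= max(cand$p_target) - 1e-12, ]
  list(dose = max(best$dose_mg), stop = FALSE)
}

new_trial_result <- function(decisions, mtd, cohorts, design) {
  structure(list(decisions = decisions, mtd = mtd, cohorts = cohorts,
                 n_patients = sum(cohorts$n_patients),
                 n_dlt_patients = sum(cohorts$n_dlt_patients),
                 design = design),
            class = "trial_result")
}

#' Replay a completed escalation from per-dose cohort data
#'
#' Walks the administered cohorts in enrollment order, refitting the
#' posterior after each and recording the model's interval summaries,
#' admissibility flags and next-dose recommendation, then applies the MTD
#' rule to the final posterior. Entirely deterministic.
#'
#' @param cohorts a [cohort_records()] table in enrollment order; every
#'   dose must be a provisional level.
#' @param design a [design_config()].
#' @return A `"trial_result"`: per-step `decisions` (each with the cohort
#'   seen, the per-dose summary table and the recommendation), the final
#'   `mtd` declaration, and pooled `cohorts`.
#' @examples
#' fx <- make_study_fixtures()
#' res <- replay(fx$qw$cohorts, fx$qw$design)
#' res$mtd$mtd_mg  # 180
#' @export
replay <- function(cohorts, design) {
  stopifnot(inherits(design, "design_config"))
  cohorts <- as_cohort_records(cohorts)
  if (!all(cohorts$dose_mg %in% design$provisional_levels))
    stop("replay cohorts contain a non-provisional dose", call. = FALSE)
  eng <- design_engine(design)
  if (!nrow(cohorts)) {
    # trial start: the prior recommends the starting dose, no MTD yet
    w <- engine_fit(eng, cohorts)
    tab <- engine_summary(eng, w)
    decisions <- list(list(cohort = NULL, summary = tab,
                           recommendation = engine_recommend(eng, tab,
                                                             numeric())))
    return(new_trial_result(decisions,
                            list(determined = FALSE, mtd_mg = NA_real_),
                            cohorts, design))
  }
  decisions <- vector("list", nrow(cohorts))
  for (k in seq_len(nrow(cohorts))) {
    seen <- cohorts[seq_len(k), , drop = FALSE]
    w <- engine_fit(eng, seen)
    tab <- engine_summary(eng, w)
    rec <- engine_recommend(eng, tab, unique(seen$dose_mg))
    decisions[[k]] <- list(cohort = cohorts[k, ], summary = tab,
                           recommendation = rec)
  }
  post <- fit_posterior(design$prior, cohorts, design$grid)
  mtd <- declare_mtd(post, cohorts, design$rules, design$mtd,
                     design$intervals)
  new_trial_result(decisions, mtd, cohorts, design)
}

#' Simulate one BLRM-EWOC trial under an assumed truth
#'
#' Cohort DLT counts are drawn binomially from the scenario; escalation
#' follows the model recommendation under the cap and no-skip constraints.
#' The trial ends when (a) no dose is admissible (MTD not determined),
#' (b) the recommended dose already has at least `min_patients_at_mtd`
#' treated patients (that dose is declared the MTD, and with
#' `expand_at_mtd` the remaining budget enrolls there), or (c) the patient
#' budget is exhausted (the MTD rule is applied to the final posterior).
#'
#' @param scenario a [tox_scenario()] on the design's provisional ladder.
#' @param design a [design_config()].
#' @param seed integer seed; runs are bit-reproducible.
#' @return A `"trial_result"` as in [replay()].
#' @export
simulate_trial <- function(scenario, design, seed) {
  stopifnot(inherits(scenario, "tox_scenario"),
            inherits(design, "design_config"))
  if (!all(design$provisional_levels %in% scenario$dose_mg))
    stop("scenario must cover every provisional level", call. = FALSE)
  eng <- design_engine(design)
  with_seed(seed, simulate_trial_impl(scenario, design, eng))
}

simulate_trial_impl <- function(scenario, design, eng) {
  p_true <- setNames(scenario$prob_dlt, as.character(scenario$dose_mg))
  cohorts <- cohort_records(numeric(), integer(), integer())
  decisions <- list()
  current <- design$start_dose
  mtd <- NULL
  repeat {
    n_enroll <- min(design$cohort_size,
                    design$max_patients - sum(cohorts$n_patients))
    x <- rbinom(1L, n_enroll, p_true[[as.character(current)]])
    cohorts <- rbind(cohorts,
                     cohort_records(current, n_enroll, x))
    class(cohorts) <- c("cohort_records", "data.frame")
    w <- engine_fit(eng, cohorts)
    tab <- engine_summary(eng, w)
    rec <- engine_recommend(eng, tab, unique(cohorts$dose_mg))
    decisions[[length(decisions) + 1L]] <-
      list(cohort = cohorts[nrow(cohorts), ], summary = tab,
           recommendation = rec)
    if (rec$stop) {
      mtd <- list(determined = FALSE, mtd_mg = NA_real_)
      break
    }
    treated_at_rec <- sum(cohorts$n_patients[cohorts$dose_mg == rec$dose])
    if (treated_at_rec >= design$mtd$min_patients_at_mtd) {
      mtd <- list(determined = TRUE, mtd_mg = rec$dose)
      remaining <- design$max_patients - sum(cohorts$n_patients)
      if (design$expand_at_mtd && remaining > 0) {
        x <- rbinom(1L, remaining, p_true[[as.character(rec$dose)]])
        cohorts <- rbind(cohorts, cohort_records(rec$dose, remaining, x))
        class(cohorts) <- c("cohort_records", "data.frame")
      }
      break
    }
    if (sum(cohorts$n_patients) >= design$max_patients) {
      post <- fit_posterior(design$prior, cohorts, design$grid)
      decl <- declare_mtd(post, cohorts, design$rules, design$mtd,
                          design$intervals)
      mtd <- list(determined = decl$determined, mtd_mg = decl$mtd_mg)
      break
    }
    current <- rec$dose
  }
  new_trial_result(decisions, mtd, cohorts, design)
}

#' Operating characteristics of a design under an assumed truth
#'
#' Repeats [simulate_trial()] `n_sims` times (seeds `seed`, `seed + 1`,
#' ...) and tabulates per-dose MTD selection frequencies, the
#' "not determined" frequency, and mean patient/DLT counts.
#'
#' @param scenario a [tox_scenario()].
#' @param design a [design_config()].
#' @param n_sims number of simulated trials (>= 1).
#' @param seed base seed.
#' @return A list: `selection` (data.frame of dose and frequency),
#'   `prop_not_determined`, `mean_patients`, `mean_dlt_patients`,
#'   `mtds` (per-trial declared MTD, NA when not determined).
#' @export
operating_characteristics <- function(scenario, design, n_sims, seed) {
  check_number(n_sims, "n_sims", lower = 1)
  eng <- design_engine(design)
  mtds <- numeric(n_sims)
  npat <- numeric(n_sims)
  ndlt <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    res <- with_seed(seed + i - 1,
                     simulate_trial_impl(scenario, design, eng))
    mtds[i] <- if (res$mtd$determined) res$mtd$mtd_mg else NA_real_
    npat[i] <- res$n_patients
    ndlt[i] <- res$n_dlt_patients
  }
  sel <- vapply(design$provisional_levels,
                function(d) sum(mtds == d, na.rm = TRUE) / n_sims, numeric(1))
  list(selection = data.frame(dose_mg = design$provisional_levels,
                              frequency = sel),
       prop_not_determined = mean(is.na(mtds)),
       mean_patients = mean(npat), mean_dlt_patients = mean(ndlt),
       mtds = mtds)
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("BLRM-EWOC trial: %d decision step(s), %d patients, %d DLT patient(s)\n",
              length(x$decisions), x$n_patients, x$n_dlt_patients))
  if (isTRUE(x$mtd$determined))
    cat(sprintf("Declared MTD: %g mg\n", x$mtd$mtd_mg))
  else cat("MTD not determined\n")
  invisible(x)
}
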