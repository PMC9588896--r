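#' Built-in study fixtures: the two dose-escalation tables
#'
#' The per-dose first-cycle outcomes of the two escalation studies of the
#' bispecific VEGF/Ang-2 nanobody, as published: five dose levels each,
#' with one DLT patient at 1000 mg on the every-3-weeks schedule and four
#' DLT patients (one at 120 mg, one at 180 mg, two at 240 mg) on the
#' weekly schedule. Each fixture bundles the cohort table, the provisional
#' ladder, a ready-made [design_config()] with the reference prior
#' (reference dose = the declared MTD of the schedule), and the published
#' decisions for assertion in tests.
#'
#' @return A list with elements `q3w` and `qw`; each contains `schedule`,
#'   `cohorts`, `provisional_levels`, `ref_dose_mg`, `design`, and
#'   `decisions` (list: `mtd_mg`, `top_dose_admissible`, `n_patients`,
#'   `n_dlt_patients`).
#' @examples
#' fx <- make_study_fixtures()
#' sum(fx$q3w$cohorts$n_patients)  # 29
#' @export
make_study_fixtures <- function() {
  q3w_cohorts <- cohort_records(c(40, 120, 360, 720, 1000),
                                c(3L, 2L, 2L, 17L, 5L),
                                c(0L, 0L, 0L, 0L, 1L))
  qw_cohorts <- cohort_records(c(40, 120, 150, 180, 240),
                               c(2L, 5L, 3L, 11L, 3L),
                               c(0L, 1L, 0L, 1L, 2L))
  q3w <- list(
    schedule = "Q3W",
    cohorts = q3w_cohorts,
    provisional_levels = c(40, 120, 360, 720, 1000),
    ref_dose_mg = 720,
    design = design_config(
      prior = blrm_prior(ref_dose_mg = 720),
      rules = escalation_rules(cap_threshold_mg = 120),
      provisional_levels = c(40, 120, 360, 720, 1000),
      schedule = "Q3W"),
    decisions = list(mtd_mg = 720, top_dose_admissible = TRUE,
                     n_patients = 29L, n_dlt_patients = 1L))
  qw <- list(
    schedule = "QW",
    cohorts = qw_cohorts,
    provisional_levels = c(40, 120, 150, 180, 240),
    ref_dose_mg = 180,
    design = design_config(
      prior = blrm_prior(ref_dose_mg = 180),
      rules = escalation_rules(cap_threshold_mg = 40),
      provisional_levels = c(40, 120, 150, 180, 240),
      schedule = "QW"),
    decisions = list(mtd_mg = 180, top_dose_admissible = FALSE,
                     n_patients = 24L, n_dlt_patients = 4L))
  list(q3w = q3w, qw = qw)
}

#' Draw binomial DLT outcomes under an assumed truth
#'
#' @param scenario a [tox_scenario()].
#' @param n_per_dose patients per dose (recycled to the ladder length).
#' @param seed integer seed.
#' @return A [cohort_records()] table with `n_dlt ~ Binomial(n, p_dose)`.
#' @export
gen_tox_outcomes <- function(scenario, n_per_dose, seed) {
  stopifnot(inherits(scenario, "tox_scenario"))
  n <- rep_len(as.integer(n_per_dose), nrow(scenario))
  x <- with_seed(seed, rbinom(nrow(scenario), n, scenario$prob_dlt))
  cohort_records(scenario$dose_mg, n, x)
}

#' Draw a lognormal population of PK/PD parameter sets
#'
#' Each subject's parameter is `base * exp(N(0, omega))`; parameters
#' without a named omega are copied unchanged, so draws are always
#' positive and `omega = 0` reproduces the typical subject.
#'
#' @param base named list/vector of typical parameter values (> 0).
#' @param omega named numeric vector of lognormal sds (>= 0); names must
#'   be a subset of `names(base)`.
#' @param n number of subjects.
#' @param seed integer seed.
#' @return A data.frame, one row per subject, one column per parameter.
#' @export
gen_pk_population <- function(base, omega, n, seed) {
  base <- unlist(base)
  if (is.null(names(base)) || !all(nzchar(names(base))))
    stop("`base` must be fully named", call. = FALSE)
  if (length(omega)) {
    if (is.null(names(omega)) || !all(names(omega) %in% names(base)))
      stop("`omega` names must match `base`", call. = FALSE)
    if (any(omega < 0)) stop("`omega` must be nonnegative", call. = FALSE)
  }
  check_number(n, "n", lower = 1)
  n <- as.integer(n)
  draws <- with_seed(seed, {
    cols <- lapply(names(base), function(nm) {
      om <- if (nm %in% names(omega)) omega[[nm]] else 0
      # one rnorm call per parameter even when omega is 0, so that adding
      # or zeroing an omega never shifts the draws of other parameters
      base[[nm]] * exp(rnorm(n, 0, 1) * om)
    })
    names(cols) <- names(base)
    cols
  })
  as.data.frame(draws)
}

#' Observed concentration datasets from a simulated profile
#'
#' Proportional-error observation model on the central drug concentration:
#' `obs = truth * (1 + N(0, sd))`, floored at zero, flagged BLQ below
#' `lloq`. One independent replicate per subject.
#'
#' @param profile a [simulate_regimen()] result.
#' @param prop_sd proportional error sd (>= 0).
#' @param lloq lower limit of quantification (nM).
#' @param seed integer seed.
#' @param n_subjects number of replicate subjects.
#' @return A list of [conc_series()], one per subject.
#' @export
gen_conc_dataset <- function(profile, prop_sd, lloq, seed, n_subjects = 1L) {
  stopifnot(inherits(profile, "sim_profile"))
  check_number(prop_sd, "prop_sd", lower = 0)
  check_number(lloq, "lloq", lower = 0)
  check_number(n_subjects, "n_subjects", lower = 1)
  truth <- profile$drug_central
  with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    obs <- pmax(0, truth * (1 + rnorm(length(truth), 0, prop_sd)))
    conc_series(s, profile$times, obs, lloq = lloq)
  }))
}

#' Synthetic target-lesion trajectories by outcome class
#'
#' Three stylised natural histories on a 6-weekly imaging schedule:
#' responders shrink exponentially to about -45% of baseline by the third
#' scan (reaching the -30% PR boundary with a confirming scan),
#' progressors grow 30% per scan (crossing +20% over nadir at the first),
#' and stable disease drifts within +/-5%. Gaussian measurement
#' noise with sd `noise_sd` mm is added to every post-baseline sum.
#'
#' @param class one of `"responder"`, `"stable"`, `"progressor"`.
#' @param noise_sd measurement noise sd in mm (>= 0).
#' @param seed integer seed.
#' @param subject subject identifier.
#' @param baseline_mm baseline target-lesion sum (default 60 mm).
#' @param weeks assessment schedule (default 6, 12, 18, 24).
#' @return A [lesion_series()].
#' @export
gen_lesion_series <- function(class = c("responder", "stable", "progressor"),
                              noise_sd, seed, subject = 1L,
                              baseline_mm = 60, weeks = seq(6, 24, by = 6)) {
  class <- match.arg(class)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_positive(baseline_mm, "baseline_mm")
  k <- seq_along(weeks)
  mult <- switch(class,
    responder = 1 - 0.45 * (1 - exp(-1.2 * k)),
    stable = 1 + 0.05 * sin(k),
    progressor = 1.3^k)
  sums <- with_seed(seed,
                    pmax(0, baseline_mm * mult + rnorm(length(k), 0, noise_sd)))
  lesion_series(subject, weeks, sums, baseline_mm)
}
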