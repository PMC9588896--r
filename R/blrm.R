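#' Cohort records: per-dose first-cycle DLT outcomes
#'
#' One row per dose level actually administered: the dose in mg, the number
#' of patients treated during the DLT evaluation window, and the number of
#' patients with at least one dose-limiting toxicity. A patient with several
#' DLTs counts once — escalation decisions operate on patients, not events.
#'
#' @param dose_mg numeric vector of positive doses (mg).
#' @param n_patients integer vector, patients treated at each dose (>= 1).
#' @param n_dlt_patients integer vector, patients with >= 1 first-cycle DLT.
#' @return A `data.frame` of class `"cohort_records"` with columns
#'   `dose_mg`, `n_patients`, `n_dlt_patients`.
#' @examples
#' cohort_records(c(40, 120), c(3, 3), c(0, 1))
#' @export
cohort_records <- function(dose_mg, n_patients, n_dlt_patients) {
  if (length(dose_mg) != length(n_patients) ||
      length(dose_mg) != length(n_dlt_patients))
    stop("cohort columns must have equal length", call. = FALSE)
  if (length(dose_mg)) {
    if (any(!is.finite(dose_mg)) || any(dose_mg <= 0))
      stop("`dose_mg` must be positive", call. = FALSE)
    if (any(n_patients < 1) || any(n_patients != round(n_patients)))
      stop("`n_patients` must be integers >= 1", call. = FALSE)
    if (any(n_dlt_patients < 0) || any(n_dlt_patients != round(n_dlt_patients)))
      stop("`n_dlt_patients` must be nonnegative integers", call. = FALSE)
    if (any(n_dlt_patients > n_patients))
      stop("`n_dlt_patients` cannot exceed `n_patients`", call. = FALSE)
  }
  out <- data.frame(dose_mg = as.numeric(dose_mg),
                    n_patients = as.integer(n_patients),
                    n_dlt_patients = as.integer(n_dlt_patients))
  class(out) <- c("cohort_records", "data.frame")
  out
}

as_cohort_records <- function(x) {
  if (inherits(x, "cohort_records")) return(x)
  if (is.data.frame(x) &&
      all(c("dose_mg", "n_patients", "n_dlt_patients") %in% names(x)))
    return(cohort_records(x$dose_mg, x$n_patients, x$n_dlt_patients))
  stop("expected a cohort_records object or a data.frame with columns ",
       "dose_mg, n_patients, n_dlt_patients", call. = FALSE)
}

#' Toxicity intervals for DLT-rate summaries
#'
#' Partition of the DLT probability scale into under-toxicity
#' \eqn{[0, 0.16)}, targeted toxicity \eqn{[0.16, 0.33)} and excessive
#' toxicity \eqn{[0.33, 1]}. The upper-interval side is half-open at 0.33
#' because overdose control tests \eqn{P(p \ge 0.33)}.
#'
#' @param under_upper upper bound of the under-toxicity interval.
#' @param target_upper upper bound of the target interval (= overdose cutoff).
#' @return A list of class `"toxicity_intervals"`.
#' @export
toxicity_intervals <- function(under_upper = 0.16, target_upper = 0.33) {
  check_number(under_upper, "under_upper", 0, 1, TRUE, TRUE)
  check_number(target_upper, "target_upper", 0, 1, TRUE, TRUE)
  if (under_upper >= target_upper)
    stop("`under_upper` must be below `target_upper`", call. = FALSE)
  structure(list(under_upper = under_upper, target_upper = target_upper),
            class = "toxicity_intervals")
}

#' Bivariate normal prior for the two-parameter BLRM
#'
#' The dose-toxicity model is
#' \deqn{\mathrm{logit}\, p(d) = \log\alpha + e^{\log\beta}
#'       \log(d/d_{\mathrm{ref}}),}
#' so \eqn{\mathrm{logistic}(\log\alpha)} is the DLT probability at the
#' reference dose and \eqn{e^{\log\beta} > 0} enforces monotonicity in dose.
#' The prior is bivariate normal on \eqn{(\log\alpha, \log\beta)}.
#'
#' The default hyperparameters are a weakly-informative choice common in
#' BLRM practice: \eqn{\log\alpha \sim N(\mathrm{logit}(0.2), 2^2)} centres
#' the reference dose on a 20% DLT rate with wide uncertainty, and
#' \eqn{\log\beta \sim N(0, 1)} centres the slope on 1.
#'
#' @param ref_dose_mg reference dose \eqn{d_{\mathrm{ref}}} in mg.
#' @param mean_log_alpha,sd_log_alpha prior mean / sd of \eqn{\log\alpha}.
#' @param mean_log_beta,sd_log_beta prior mean / sd of \eqn{\log\beta}.
#' @param correlation prior correlation in (-1, 1).
#' @return A list of class `"blrm_prior"`.
#' @examples
#' blrm_prior(ref_dose_mg = 720)
#' @export
blrm_prior <- function(ref_dose_mg,
                       mean_log_alpha = qlogis(0.2), sd_log_alpha = 2,
                       mean_log_beta = 0, sd_log_beta = 1,
                       correlation = 0) {
  check_positive(ref_dose_mg, "ref_dose_mg")
  check_number(mean_log_alpha, "mean_log_alpha")
  check_number(mean_log_beta, "mean_log_beta")
  check_positive(sd_log_alpha, "sd_log_alpha")
  check_positive(sd_log_beta, "sd_log_beta")
  check_number(correlation, "correlation", -1, 1, TRUE, TRUE)
  structure(list(ref_dose_mg = ref_dose_mg,
                 mean_log_alpha = mean_log_alpha,
                 sd_log_alpha = sd_log_alpha,
                 mean_log_beta = mean_log_beta,
                 sd_log_beta = sd_log_beta,
                 correlation = correlation),
            class = "blrm_prior")
}

#' Escalation rules: overdose control and step caps
#'
#' EWOC declares a dose admissible when the posterior probability that its
#' DLT rate reaches `overdose_cutoff` is below `ewoc_feasibility`. Step caps
#' limit the next dose to +200% of the current dose while the current dose
#' is at or below `cap_threshold_mg`, and to +100% above it (the thresholds
#' used by the two studies are 120 mg for the every-3-weeks schedule and
#' 40 mg for the weekly schedule).
#'
#' @param cap_threshold_mg dose (mg) up to which the larger increment applies.
#' @param ewoc_feasibility EWOC feasibility bound (default 0.25).
#' @param overdose_cutoff DLT-rate cutoff defining overdose (default 0.33).
#' @param max_increment_low fractional increment at/below the threshold
#'   (2 means +200%).
#' @param max_increment_high fractional increment above the threshold.
#' @param allow_skipping may untested provisional levels be skipped?
#' @return A list of class `"escalation_rules"`.
#' @examples
#' escalation_rules(cap_threshold_mg = 120)   # Q3W study rules
#' escalation_rules(cap_threshold_mg = 40)    # QW study rules
#' @export
escalation_rules <- function(cap_threshold_mg,
                             ewoc_feasibility = 0.25,
                             overdose_cutoff = 0.33,
                             max_increment_low = 2.0,
                             max_increment_high = 1.0,
                             allow_skipping = FALSE) {
  check_positive(cap_threshold_mg, "cap_threshold_mg")
  check_number(ewoc_feasibility, "ewoc_feasibility", 0, 1, TRUE, TRUE)
  check_number(overdose_cutoff, "overdose_cutoff", 0, 1, TRUE, TRUE)
  check_positive(max_increment_low, "max_increment_low")
  check_positive(max_increment_high, "max_increment_high")
  stopifnot(is.logical(allow_skipping), length(allow_skipping) == 1L)
  structure(list(cap_threshold_mg = cap_threshold_mg,
                 ewoc_feasibility = ewoc_feasibility,
                 overdose_cutoff = overdose_cutoff,
                 max_increment_low = max_increment_low,
                 max_increment_high = max_increment_high,
                 allow_skipping = allow_skipping),
            class = "escalation_rules")
}

#' MTD declaration rule
#'
#' The MTD is the highest administered dose that passes EWOC; a minimum
#' number of patients treated there (default 6) and, optionally, a minimum
#' posterior target-interval probability can additionally be required.
#' `min_target_interval_prob = 0` leaves admissibility + highest-dose as the
#' binding rule.
#'
#' @param min_target_interval_prob minimum posterior probability that the
#'   DLT rate lies in the target interval at the declared MTD.
#' @param min_patients_at_mtd minimum patients treated at the declared MTD.
#' @return A list of class `"mtd_rule"`.
#' @export
mtd_rule <- function(min_target_interval_prob = 0, min_patients_at_mtd = 6L) {
  check_number(min_target_interval_prob, "min_target_interval_prob", 0, 1)
  check_number(min_patients_at_mtd, "min_patients_at_mtd", 0)
  structure(list(min_target_interval_prob = min_target_interval_prob,
                 min_patients_at_mtd = as.integer(min_patients_at_mtd)),
            class = "mtd_rule")
}

#' Grid specification for the deterministic posterior
#'
#' The posterior over \eqn{(\log\alpha, \log\beta)} is computed by
#' tensor-product quadrature on a regular lattice spanning
#' `span` prior standard deviations around each prior mean (explicit bounds
#' may be given instead). 401 nodes per axis makes decisions
#' bit-reproducible while keeping interval probabilities accurate to well
#' under the Monte-Carlo comparison tolerance used in the tests.
#'
#' @param n_alpha,n_beta number of nodes per axis.
#' @param span half-width of each axis in prior standard deviations.
#' @param alpha_bounds,beta_bounds optional explicit `c(lo, hi)` bounds.
#' @return A list of class `"grid_spec"`.
#' @export
grid_spec <- function(n_alpha = 401L, n_beta = 401L, span = 6,
                      alpha_bounds = NULL, beta_bounds = NULL) {
  check_number(n_alpha, "n_alpha", 2)
  check_number(n_beta, "n_beta", 2)
  check_positive(span, "span")
  structure(list(n_alpha = as.integer(n_alpha), n_beta = as.integer(n_beta),
                 span = span, alpha_bounds = alpha_bounds,
                 beta_bounds = beta_bounds),
            class = "grid_spec")
}

#' DLT probability under the two-parameter logistic model
#'
#' \eqn{p(d) = \mathrm{logistic}(\log\alpha + e^{\log\beta}
#' \log(d/d_{\mathrm{ref}}))}. Strictly increasing in dose for any
#' parameter values because the slope \eqn{e^{\log\beta}} is positive.
#'
#' @param log_alpha,log_beta model parameters (vectorised).
#' @param dose_mg dose in mg, > 0.
#' @param ref_dose_mg reference dose in mg, > 0.
#' @return DLT probability in (0, 1).
#' @examples
#' dlt_probability(qlogis(0.2), 0, dose_mg = 720, ref_dose_mg = 720)  # 0.2
#' @export
dlt_probability <- function(log_alpha, log_beta, dose_mg, ref_dose_mg) {
  if (any(!is.finite(dose_mg)) || any(dose_mg <= 0))
    stop("`dose_mg` must be positive", call. = FALSE)
  if (any(!is.finite(ref_dose_mg)) || any(ref_dose_mg <= 0))
    stop("`ref_dose_mg` must be positive", call. = FALSE)
  plogis(log_alpha + exp(log_beta) * log(dose_mg / ref_dose_mg))
}

# Node lattice + prior log-density for a prior/grid pair. Warns when the
# requested bounds leave out more than 1e-6 of prior mass per axis.
make_grid <- function(prior, grid = grid_spec()) {
  ab <- grid$alpha_bounds %||%
    (prior$mean_log_alpha + c(-1, 1) * grid$span * prior$sd_log_alpha)
  bb <- grid$beta_bounds %||%
    (prior$mean_log_beta + c(-1, 1) * grid$span * prior$sd_log_beta)
  miss_a <- 1 - diff(pnorm(ab, prior$mean_log_alpha, prior$sd_log_alpha))
  miss_b <- 1 - diff(pnorm(bb, prior$mean_log_beta, prior$sd_log_beta))
  if (miss_a > 1e-6 || miss_b > 1e-6)
    warning(sprintf(
      "grid bounds truncate prior mass (log_alpha: %.2g, log_beta: %.2g)",
      miss_a, miss_b), call. = FALSE)
  la <- seq(ab[1], ab[2], length.out = grid$n_alpha)
  lb <- seq(bb[1], bb[2], length.out = grid$n_beta)
  # bivariate normal log-density on the lattice (alpha varies fastest)
  za <- (la - prior$mean_log_alpha) / prior$sd_log_alpha
  zb <- (lb - prior$mean_log_beta) / prior$sd_log_beta
  rho <- prior$correlation
  ZA <- matrix(za, grid$n_alpha, grid$n_beta)
  ZB <- matrix(zb, grid$n_alpha, grid$n_beta, byrow = TRUE)
  lp <- -(ZA^2 - 2 * rho * ZA * ZB + ZB^2) / (2 * (1 - rho^2))
  list(log_alpha = la, log_beta = lb, log_prior = as.vector(lp),
       la_vec = as.vector(ZA) * prior$sd_log_alpha + prior$mean_log_alpha,
       lb_vec = as.vector(ZB) * prior$sd_log_beta + prior$mean_log_beta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the BLRM posterior by deterministic grid quadrature
#'
#' Computes, on a regular \eqn{(\log\alpha, \log\beta)} lattice, weights
#' proportional to prior density times the binomial likelihood of the
#' observed per-dose DLT counts, normalised to sum to one. With zero
#' cohorts this is the discretised prior. Entirely deterministic for a
#' fixed grid, so escalation decisions are bit-reproducible.
#'
#' @param prior a [blrm_prior()].
#' @param cohorts a [cohort_records()] table (may have zero rows).
#' @param grid a [grid_spec()].
#' @return An object of class `"blrm_posterior"`: node vectors
#'   `log_alpha`, `log_beta` (flattened lattice), normalised `weights`,
#'   and the originating `prior`.
#' @examples
#' pr <- blrm_prior(720)
#' post <- fit_posterior(pr, cohort_records(c(40, 120), c(3, 3), c(0, 0)))
#' interval_probabilities(post, 360)
#' @export
fit_posterior <- function(prior, cohorts = cohort_records(numeric(), integer(),
                                                          integer()),
                          grid = grid_spec()) {
  stopifnot(inherits(prior, "blrm_prior"))
  cohorts <- as_cohort_records(cohorts)
  g <- make_grid(prior, grid)
  lw <- g$log_prior
  if (nrow(cohorts)) {
    slope <- exp(g$lb_vec)
    for (i in seq_len(nrow(cohorts))) {
      p <- plogis(g$la_vec + slope * log(cohorts$dose_mg[i] / prior$ref_dose_mg))
      lw <- lw + dbinom(cohorts$n_dlt_patients[i], cohorts$n_patients[i], p,
                        log = TRUE)
    }
  }
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  structure(list(log_alpha = g$la_vec, log_beta = g$lb_vec, weights = w,
                 prior = prior, n_cohorts = nrow(cohorts)),
            class = "blrm_posterior")
}

# internal: DLT probabilities at every posterior node for one dose
node_probs <- function(post, dose_mg) {
  dlt_probability(post$log_alpha, post$log_beta, dose_mg,
                  post$prior$ref_dose_mg)
}

#' Posterior toxicity-interval probabilities at a dose
#'
#' @param post a [fit_posterior()] result.
#' @param dose_mg dose in mg.
#' @param intervals a [toxicity_intervals()].
#' @return Named numeric vector `c(under, target, over)` summing to 1.
#' @export
interval_probabilities <- function(post, dose_mg,
                                   intervals = toxicity_intervals()) {
  stopifnot(inherits(post, "blrm_posterior"),
            inherits(intervals, "toxicity_intervals"))
  check_positive(dose_mg, "dose_mg")
  p <- node_probs(post, dose_mg)
  w <- post$weights
  over <- sum(w[p >= intervals$target_upper])
  under <- sum(w[p < intervals$under_upper])
  c(under = under, target = 1 - under - over, over = over)
}

#' EWOC admissibility of a dose
#'
#' A dose is admissible when the posterior probability that its DLT rate is
#' at least `rules$overdose_cutoff` falls below `rules$ewoc_feasibility`
#' (default: P(p >= 0.33) < 0.25).
#'
#' @param post a [fit_posterior()] result.
#' @param dose_mg dose in mg.
#' @param rules an [escalation_rules()].
#' @return A list with `admissible` (logical) and `overdose_prob`.
#' @export
ewoc_admissible <- function(post, dose_mg, rules) {
  stopifnot(inherits(post, "blrm_posterior"),
            inherits(rules, "escalation_rules"))
  check_positive(dose_mg, "dose_mg")
  p <- node_probs(post, dose_mg)
  op <- sum(post$weights[p >= rules$overdose_cutoff])
  list(admissible = op < rules$ewoc_feasibility, overdose_prob = op)
}

#' Maximum next dose under the escalation cap
#'
#' +200% of the current dose while the current dose is at or below the cap
#' threshold, +100% above it.
#'
#' @param current_dose_mg the highest dose administered so far (mg).
#' @param rules an [escalation_rules()].
#' @return The maximum permissible next dose in mg.
#' @examples
#' q3w <- escalation_rules(cap_threshold_mg = 120)
#' escalation_cap(40, q3w)    # 120
#' escalation_cap(360, q3w)   # 720
#' @export
escalation_cap <- function(current_dose_mg, rules) {
  stopifnot(inherits(rules, "escalation_rules"))
  check_positive(current_dose_mg, "current_dose_mg")
  inc <- if (current_dose_mg <= rules$cap_threshold_mg)
    rules$max_increment_low else rules$max_increment_high
  current_dose_mg * (1 + inc)
}

#' Recommend the next dose
#'
#' Among provisional levels that (a) pass EWOC, (b) do not exceed the
#' escalation cap relative to the highest tested dose, and (c) do not skip
#' an untested provisional level when skipping is disallowed, returns the
#' level with the highest posterior target-interval probability. Ties break
#' toward the higher dose (escalation intent). When no level survives the
#' filters the trial has no admissible dose and a stop signal is returned.
#'
#' @param post a [fit_posterior()] result.
#' @param tested_doses doses (mg) with at least one treated patient; may be
#'   empty at trial start, in which case the lowest provisional level is
#'   recommended.
#' @param provisional_levels strictly increasing vector of candidate doses.
#' @param rules an [escalation_rules()].
#' @param intervals a [toxicity_intervals()].
#' @return A list of class `"dose_recommendation"`: `dose` (NA on stop),
#'   `stop` (logical), and `table` — one row per provisional level with
#'   interval probabilities, overdose probability and the filter flags.
#' @export
recommend_next_dose <- function(post, tested_doses, provisional_levels,
                                rules, intervals = toxicity_intervals()) {
  stopifnot(inherits(post, "blrm_posterior"))
  if (!length(provisional_levels))
    stop("`provisional_levels` must be nonempty", call. = FALSE)
  if (is.unsorted(provisional_levels, strictly = TRUE))
    stop("`provisional_levels` must be strictly increasing", call. = FALSE)

  tab <- summarise_levels(post, provisional_levels, rules, intervals)

  if (!length(tested_doses)) {
    res <- list(dose = provisional_levels[1], stop = FALSE, table = tab)
    class(res) <- "dose_recommendation"
    return(res)
  }

  cap <- escalation_cap(max(tested_doses), rules)
  tab$cap_ok <- tab$dose_mg <= cap
  if (rules$allow_skipping) {
    tab$skip_ok <- TRUE
  } else {
    untested <- setdiff(provisional_levels, tested_doses)
    ceiling_dose <- if (length(untested)) min(untested) else Inf
    tab$skip_ok <- tab$dose_mg <= ceiling_dose
  }
  ok <- tab$admissible & tab$cap_ok & tab$skip_ok
  if (!any(ok)) {
    res <- list(dose = NA_real_, stop = TRUE, table = tab)
  } else {
    cand <- tab[ok, ]
    best <- cand[cand$p_target >= max(cand$p_target) - 1e-12, ]
    res <- list(dose = max(best$dose_mg), stop = FALSE, table = tab)
  }
  class(res) <- "dose_recommendation"
  res
}

summarise_levels <- function(post, levels, rules, intervals) {
  ip <- t(vapply(levels, function(d) interval_probabilities(post, d, intervals),
                 numeric(3)))
  op <- vapply(levels, function(d) ewoc_admissible(post, d, rules)$overdose_prob,
               numeric(1))
  data.frame(dose_mg = levels,
             p_under = ip[, "under"], p_target = ip[, "target"],
             p_over = ip[, "over"], overdose_prob = op,
             admissible = op < rules$ewoc_feasibility,
             cap_ok = NA, skip_ok = NA)
}

#' Declare the maximum tolerated dose
#'
#' The MTD is the highest administered dose that passes EWOC under the
#' final posterior, subject to a minimum number of patients treated there
#' and (optionally) a minimum target-interval probability. Returns
#' "not determined" when no tested dose qualifies.
#'
#' @param post the final [fit_posterior()].
#' @param tested_cohorts a [cohort_records()] table of all administered
#'   doses.
#' @param rules an [escalation_rules()].
#' @param rule an [mtd_rule()].
#' @param intervals a [toxicity_intervals()].
#' @return A list of class `"mtd_declaration"`: `determined` (logical),
#'   `mtd_mg` (NA when not determined), `p_target` at the MTD, and the
#'   per-dose summary `table`.
#' @export
declare_mtd <- function(post, tested_cohorts, rules, rule = mtd_rule(),
                        intervals = toxicity_intervals()) {
  tested_cohorts <- as_cohort_records(tested_cohorts)
  if (!nrow(tested_cohorts))
    stop("at least one cohort is required to declare an MTD", call. = FALSE)
  agg <- aggregate(cbind(n_patients, n_dlt_patients) ~ dose_mg,
                   data = tested_cohorts, FUN = sum)
  agg <- agg[order(agg$dose_mg), ]
  tab <- summarise_levels(post, agg$dose_mg, rules, intervals)
  tab$n_patients <- agg$n_patients
  tab$qualifies <- tab$admissible &
    tab$n_patients >= rule$min_patients_at_mtd &
    tab$p_target >= rule$min_target_interval_prob
  if (any(tab$qualifies)) {
    mtd <- max(tab$dose_mg[tab$qualifies])
    res <- list(determined = TRUE, mtd_mg = mtd,
                p_target = tab$p_target[tab$dose_mg == mtd], table = tab)
  } else {
    res <- list(determined = FALSE, mtd_mg = NA_real_, p_target = NA_real_,
                table = tab)
  }
  class(res) <- "mtd_declaration"
  res
}

#' @export
print.blrm_posterior <- function(x, ...) {
  cat(sprintf(
    "BLRM grid posterior: %d nodes, %d cohort(s), ref dose %g mg\n",
    length(x$weights), x$n_cohorts, x$prior$ref_dose_mg))
  invisible(x)
}

#' @export
print.dose_recommendation <- function(x, ...) {
  if (x$stop) cat("No admissible dose: stop signal\n")
  else cat(sprintf("Recommended next dose: %g mg\n", x$dose))
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
print.mtd_declaration <- function(x, ...) {
  if (x$determined)
    cat(sprintf("MTD: %g mg (posterior target-interval probability %.3f)\n",
                x$mtd_mg, x$p_target))
  else cat("MTD not determined\n")
  print(x$table, digits = 3)
  invisible(x)
}
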