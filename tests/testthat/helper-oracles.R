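# Independent oracles used across the suite. These deliberately avoid the
# package's grid/ODE code paths: Monte-Carlo importance sampling for the
# posterior, matrix exponentials via eigendecomposition for the linear PK
# system, and 1-D quadrature for the slope-degenerate model.

# Importance-sampled posterior summaries: draw from the prior, weight by
# the binomial likelihood. Returns interval probabilities and the overdose
# probability at `dose`.
mc_posterior_oracle <- function(prior, cohorts, dose, n_draws = 1e6,
                                seed = 421, under = 0.16, over = 0.33) {
  set.seed(seed)
  la <- rnorm(n_draws, prior$mean_log_alpha, prior$sd_log_alpha)
  lb <- rnorm(n_draws, prior$mean_log_beta, prior$sd_log_beta)
  lw <- numeric(n_draws)
  for (i in seq_len(nrow(cohorts))) {
    p <- plogis(la + exp(lb) * log(cohorts$dose_mg[i] / prior$ref_dose_mg))
    lw <- lw + dbinom(cohorts$n_dlt_patients[i], cohorts$n_patients[i], p,
                      log = TRUE)
  }
  w <- exp(lw - max(lw)); w <- w / sum(w)
  p <- plogis(la + exp(lb) * log(dose / prior$ref_dose_mg))
  c(under = sum(w[p < under]),
    target = sum(w[p >= under & p < over]),
    over = sum(w[p >= over]))
}

# 1-D quadrature oracle for the slope-degenerate case (log_beta pinned far
# negative so every dose shares one DLT probability p = logistic(log_alpha)).
quad1d_interval_probs <- function(mean_log_alpha, sd_log_alpha, x, n,
                                  under = 0.16, over = 0.33) {
  dens <- function(la) dnorm(la, mean_log_alpha, sd_log_alpha) *
    plogis(la)^x * (1 - plogis(la))^(n - x)
  Z <- integrate(dens, -Inf, Inf, rel.tol = 1e-12)$value
  pr <- function(lo, hi) integrate(dens, lo, hi, rel.tol = 1e-12)$value / Z
  c(under = pr(-Inf, qlogis(under)),
    target = pr(qlogis(under), qlogis(over)),
    over = pr(qlogis(over), Inf))
}

# Closed-form central/peripheral concentrations of the linear two-compartment
# model under superposed constant-rate infusions, by eigendecomposition of
#   d/dt (C, P) = A (C, P) + (rate/V1, 0).
two_cpt_infusion_oracle <- function(pk, dose_nmol, dur_days, start_times,
                                    times) {
  A <- matrix(c(-(pk$clearance + pk$intercompartmental_clearance) /
                  pk$central_volume,
                pk$intercompartmental_clearance / pk$peripheral_volume,
                pk$intercompartmental_clearance / pk$central_volume,
                -pk$intercompartmental_clearance / pk$peripheral_volume),
              2, 2)
  eg <- eigen(A)
  V <- eg$vectors; Vi <- solve(V); lam <- eg$values
  b <- c(dose_nmol / dur_days / pk$central_volume, 0)
  one_infusion <- function(t) {
    # response at time t (>= 0) to one infusion starting at 0
    if (t <= 0) return(c(0, 0))
    tt <- min(t, dur_days)
    # y(dur) from zero initial state under constant input
    phi <- V %*% diag((exp(lam * tt) - 1) / lam) %*% Vi %*% b
    if (t > dur_days)
      phi <- V %*% diag(exp(lam * (t - dur_days))) %*% Vi %*% phi
    as.vector(Re(phi))
  }
  out <- vapply(times, function(t) {
    Reduce(`+`, lapply(start_times, function(s) one_infusion(t - s)),
           accumulate = FALSE)
  }, numeric(2))
  list(central = out[1, ], peripheral = out[2, ])
}

# slowest (terminal) eigenvalue of the linear two-compartment system
two_cpt_terminal_lambda <- function(pk) {
  A <- matrix(c(-(pk$clearance + pk$intercompartmental_clearance) /
                  pk$central_volume,
                pk$intercompartmental_clearance / pk$peripheral_volume,
                pk$intercompartmental_clearance / pk$central_volume,
                -pk$intercompartmental_clearance / pk$peripheral_volume),
              2, 2)
  min(abs(Re(eigen(A)$values)))
}

# quasi-steady-state free ligand at a pinned drug concentration C:
# the root of 0 = ksyn - kdeg L - kon C L + koff X with X at its own
# steady state X = kon C L / (koff + kint).
free_ligand_qss <- function(lig, C) {
  lig$k_syn / (lig$k_deg +
                 lig$k_on * C * lig$k_int / (lig$k_off + lig$k_int))
}

# a small standard parameter kit for PK/PD tests
test_pk <- function() two_compartment_params(0.45, 3, 0.5, 2.5)
test_ang2 <- function(k_on = 1)
  binding_params(k_on, 1, 5, 5, 0.5, name = "Ang-2")
test_regimen <- function(dose = 360, n = 1, interval = 21)
  regimen(dose, 40000, 1, interval, n)

# near-point-mass posterior at a chosen DLT probability, flat in dose
degenerate_posterior <- function(p_flat, ref_dose = 720) {
  fit_posterior(
    blrm_prior(ref_dose, mean_log_alpha = qlogis(p_flat),
               sd_log_alpha = 1e-7, mean_log_beta = -20, sd_log_beta = 1e-7),
    grid = grid_spec(n_alpha = 3, n_beta = 3))
}
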