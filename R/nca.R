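#' Concentration-time series for one subject
#'
#' Observations below the lower limit of quantification are flagged, never
#' imputed: the NCA operations apply the standard convention (BLQ before
#' Tmax treated as zero, BLQ after Tmax excluded).
#'
#' @param subject subject identifier.
#' @param time numeric, strictly increasing sampling times.
#' @param conc numeric, nonnegative concentrations.
#' @param lloq lower limit of quantification (same unit as `conc`).
#' @param time_unit,conc_unit unit labels carried along (default days / nM).
#' @return A data.frame of class `"conc_series"` with a logical `blq`
#'   column and unit attributes.
#' @export
conc_series <- function(subject, time, conc, lloq = 0,
                        time_unit = "days", conc_unit = "nM") {
  if (length(time) != length(conc))
    stop("`time` and `conc` must have equal length", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("`time` must be strictly increasing", call. = FALSE)
  if (any(conc < 0)) stop("`conc` must be nonnegative", call. = FALSE)
  check_number(lloq, "lloq", lower = 0)
  out <- data.frame(subject = subject, time = time, conc = conc,
                    blq = conc < lloq)
  attr(out, "lloq") <- lloq
  attr(out, "time_unit") <- time_unit
  attr(out, "conc_unit") <- conc_unit
  class(out) <- c("conc_series", "data.frame")
  out
}

# quantifiable view with the BLQ convention applied: BLQ before Tmax -> 0,
# BLQ after Tmax -> dropped. Returns NULL when nothing is quantifiable.
blq_adjusted <- function(series) {
  stopifnot(inherits(series, "conc_series"))
  if (all(series$blq)) return(NULL)
  q <- which(!series$blq)
  tmax_idx <- q[which.max(series$conc[q])]
  keep <- !series$blq | seq_len(nrow(series)) < tmax_idx
  s <- series[keep, ]
  s$conc[s$blq] <- 0
  s
}

#' AUC from time zero to the last quantifiable concentration
#'
#' Trapezoidal integration up to the last quantifiable time point. With
#' `method = "linuplogdown"` the logarithmic trapezoid is used between
#' strictly positive, strictly decreasing neighbours; the linear trapezoid
#' elsewhere.
#'
#' @param series a [conc_series()].
#' @param method `"linuplogdown"` (default) or `"linear"`.
#' @return The AUC (conc x time), or `NA_real_` when fewer than two
#'   quantifiable points exist ("not evaluable").
#' @examples
#' s <- conc_series(1, c(0, 1, 2), c(0, 2, 0))
#' auc_0_tz(s, method = "linear")  # 2
#' @export
auc_0_tz <- function(series, method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  s <- blq_adjusted(series)
  if (is.null(s) || sum(!s$blq) < 2) return(NA_real_)
  last_q <- max(which(!s$blq))
  t <- s$time[seq_len(last_q)]
  c_ <- s$conc[seq_len(last_q)]
  auc <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    c1 <- c_[i]; c2 <- c_[i + 1]
    if (method == "linuplogdown" && c1 > c2 && c2 > 0) {
      auc <- auc + dt * (c1 - c2) / log(c1 / c2)
    } else {
      auc <- auc + dt * (c1 + c2) / 2
    }
  }
  auc
}

#' Maximum observed concentration and its time
#'
#' @param series a [conc_series()].
#' @return A list `cmax`, `tmax` (first occurrence on ties); both `NA`
#'   when no point is quantifiable.
#' @export
cmax_tmax <- function(series) {
  stopifnot(inherits(series, "conc_series"))
  q <- which(!series$blq)
  if (!length(q)) return(list(cmax = NA_real_, tmax = NA_real_))
  i <- q[which.max(series$conc[q])]   # which.max -> first occurrence
  list(cmax = series$conc[i], tmax = series$time[i])
}

#' Terminal half-life by best-adjusted-R2 log-linear regression
#'
#' Standard NCA terminal-slope selection: among contiguous terminal windows
#' of at least `min_points` quantifiable positive concentrations after
#' (and excluding) Tmax, fit `log(conc) ~ time` and keep the window with
#' the highest adjusted R2, breaking ties toward more points. The half-life
#' is `log(2) / lambda_z` with `lambda_z` the negated slope.
#'
#' @param series a [conc_series()].
#' @param min_points minimum points in the terminal fit (default 3).
#' @return A list `t_half`, `lambda_z`, `n_points`, `adj_r2`; all `NA`
#'   when not evaluable (insufficient points or nonnegative slope).
#' @export
terminal_half_life <- function(series, min_points = 3L) {
  stopifnot(inherits(series, "conc_series"))
  check_number(min_points, "min_points", lower = 2)
  ne <- list(t_half = NA_real_, lambda_z = NA_real_, n_points = NA_integer_,
             adj_r2 = NA_real_)
  q <- which(!series$blq & series$conc > 0)
  if (length(q) < 2) return(ne)
  tmax_idx <- q[which.max(series$conc[q])]
  cand <- q[q > tmax_idx]
  if (length(cand) < min_points) return(ne)
  t <- series$time[cand]; lc <- log(series$conc[cand])
  best <- NULL
  for (start in seq_len(length(cand) - min_points + 1)) {
    idx <- start:length(cand)
    # explicit least squares: summary.lm() warns on the exact fits that
    # mono-exponential profiles legitimately produce
    n <- length(idx)
    x <- t[idx]; y <- lc[idx]
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    if (!is.finite(slope) || slope >= 0) next
    sst <- sum((y - mean(y))^2)
    sse <- sst - slope^2 * sxx
    r2 <- 1 - max(sse, 0) / sst
    adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
    # tie-break toward more points: earlier (longer) windows win ties
    if (is.null(best) || adj > best$adj_r2 + 1e-10) {
      best <- list(t_half = log(2) / (-slope), lambda_z = -slope,
                   n_points = n, adj_r2 = adj)
    }
  }
  if (is.null(best)) return(ne)
  best
}

#' Full noncompartmental summary for one subject
#'
#' @param series a [conc_series()].
#' @param method AUC method, see [auc_0_tz()].
#' @return One-row data.frame: `subject`, `c_max`, `t_max`, `auc_0_tz`,
#'   `t_half`, `n_terminal_points`, `terminal_fit_r2`.
#' @export
nca_summary <- function(series, method = c("linuplogdown", "linear")) {
  ct <- cmax_tmax(series)
  th <- terminal_half_life(series)
  data.frame(subject = series$subject[1],
             c_max = ct$cmax, t_max = ct$tmax,
             auc_0_tz = auc_0_tz(series, method),
             t_half = th$t_half,
             n_terminal_points = th$n_points,
             terminal_fit_r2 = th$adj_r2)
}

#' NCA over a long-format dataset
#'
#' @param data data.frame with columns `subject, time, conc` and optionally
#'   `lloq` (constant per subject).
#' @param method AUC method.
#' @return Per-subject [nca_summary()] rows, one data.frame.
#' @export
run_nca <- function(data, method = c("linuplogdown", "linear")) {
  stopifnot(all(c("subject", "time", "conc") %in% names(data)))
  method <- match.arg(method)
  out <- lapply(split(data, data$subject), function(d) {
    d <- d[order(d$time), ]
    lloq <- if ("lloq" %in% names(d)) d$lloq[1] else 0
    nca_summary(conc_series(d$subject[1], d$time, d$conc, lloq), method)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dose-proportionality by the power model
#'
#' Regresses `log(AUC)` on `log(dose)` and reports the slope with its 90%
#' confidence interval; exposure is flagged dose-proportional when the
#' interval contains 1.
#'
#' @param auc_table data.frame with columns `dose_mg` and `auc`
#'   (one row per subject or per dose).
#' @param conf_level confidence level for the slope interval (default 0.90).
#' @return A list: `slope`, `ci` (length 2), `proportional` (logical).
#' @export
dose_proportionality <- function(auc_table, conf_level = 0.90) {
  stopifnot(all(c("dose_mg", "auc") %in% names(auc_table)))
  if (length(unique(auc_table$dose_mg)) < 3)
    stop("at least three distinct doses are required", call. = FALSE)
  x <- log(auc_table$dose_mg); y <- log(auc_table$auc)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  sse <- max(sum((y - mean(y))^2) - slope^2 * sxx, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  ci <- if (is.finite(se) && se > 0)
    slope + c(-1, 1) * qt(1 - (1 - conf_level) / 2, n - 2) * se
  else c(slope, slope)
  list(slope = slope, ci = ci, proportional = ci[1] <= 1 && 1 <= ci[2])
}
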