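#' Target-lesion measurement series for one subject
#'
#' Sums of target-lesion diameters (mm) at scheduled assessments, with the
#' pre-treatment baseline sum. An optional per-assessment flag records
#' unequivocal progression by new or non-target lesions, which triggers PD
#' regardless of the target-lesion sum.
#'
#' @param subject subject identifier.
#' @param week assessment times in weeks, strictly increasing, > 0.
#' @param target_sum_mm sum of target-lesion diameters per assessment (mm).
#' @param baseline_mm baseline sum (> 0).
#' @param new_lesion logical per assessment (default all `FALSE`).
#' @return A list of class `"lesion_series"`.
#' @export
lesion_series <- function(subject, week, target_sum_mm, baseline_mm,
                          new_lesion = rep(FALSE, length(week))) {
  check_positive(baseline_mm, "baseline_mm")
  if (length(week) != length(target_sum_mm) ||
      length(week) != length(new_lesion))
    stop("assessment columns must have equal length", call. = FALSE)
  if (length(week) && (is.unsorted(week, strictly = TRUE) || any(week <= 0)))
    stop("`week` must be strictly increasing and positive", call. = FALSE)
  if (any(target_sum_mm < 0))
    stop("`target_sum_mm` must be nonnegative", call. = FALSE)
  structure(list(subject = subject, week = as.numeric(week),
                 target_sum_mm = as.numeric(target_sum_mm),
                 baseline_mm = baseline_mm,
                 new_lesion = as.logical(new_lesion)),
            class = "lesion_series")
}

#' Percent change from baseline in target-lesion sum
#'
#' @param series a [lesion_series()].
#' @return A list: `percent_change` per assessment
#'   (100 x (sum - baseline) / baseline) and `best` (the most negative
#'   value; `NA` with zero assessments).
#' @examples
#' s <- lesion_series(1, c(6, 12), c(44, 30), baseline_mm = 40)
#' percent_change_from_baseline(s)$best  # -25
#' @export
percent_change_from_baseline <- function(series) {
  stopifnot(inherits(series, "lesion_series"))
  pc <- 100 * (series$target_sum_mm - series$baseline_mm) / series$baseline_mm
  list(percent_change = pc,
       best = if (length(pc)) min(pc) else NA_real_)
}

# per-assessment RECIST-style category trace on target-lesion sums.
# Nadir at assessment k is the smallest sum among baseline and assessments
# 1..k-1 (progression is judged against what was best before).
assessment_trace <- function(series, pd_threshold = 0.20,
                             pr_threshold = -0.30) {
  n <- length(series$week)
  cat <- character(n)
  nadir <- series$baseline_mm
  for (k in seq_len(n)) {
    s <- series$target_sum_mm[k]
    if (series$new_lesion[k] || s >= (1 + pd_threshold) * nadir) {
      cat[k] <- "PD"
    } else if (s == 0) {
      cat[k] <- "CR"
    } else if ((s - series$baseline_mm) / series$baseline_mm <= pr_threshold) {
      cat[k] <- "PR"
    } else {
      cat[k] <- "SD"
    }
    nadir <- min(nadir, s)
  }
  cat
}

#' Best overall response (RECIST 1.1-style, target lesions only)
#'
#' Per-assessment categories: PD when the sum grows by at least 20% over
#' the nadir (smallest sum so far, baseline included) or a new lesion is
#' flagged; CR when the sum reaches zero; PR when the change from baseline
#' is at most -30%; SD otherwise. Assessments after the first PD do not
#' improve the best response. PR/CR is `confirmed` when a second
#' qualifying assessment occurs at least `confirmation_window_weeks`
#' later. SD counts as best response only when observed at or after
#' `min_sd_duration_weeks`; an early SD followed by PD yields PD, an early
#' SD with no later information yields NE, matching usual practice.
#'
#' @param series a [lesion_series()].
#' @param confirmation_window_weeks minimum spacing for confirmation
#'   (default 4).
#' @param min_sd_duration_weeks minimum time on study for SD to count
#'   (default 6, the assessment cadence).
#' @return A list: `category` in `c("CR","PR","SD","PD","NE")` and
#'   `confirmed` (logical; only meaningful for PR/CR).
#' @export
best_overall_response <- function(series, confirmation_window_weeks = 4,
                                  min_sd_duration_weeks = 6) {
  stopifnot(inherits(series, "lesion_series"))
  n <- length(series$week)
  if (n == 0) return(list(category = "NE", confirmed = FALSE))
  trace <- assessment_trace(series)
  pd_idx <- which(trace == "PD")
  upto <- if (length(pd_idx)) pd_idx[1] else n
  pre <- trace[seq_len(upto)]
  wk <- series$week[seq_len(upto)]

  resp_idx <- which(pre %in% c("CR", "PR"))
  confirmed <- FALSE
  if (length(resp_idx) >= 2)
    confirmed <- (max(wk[resp_idx]) - min(wk[resp_idx])) >=
      confirmation_window_weeks
  category <-
    if (any(pre == "CR")) "CR"
    else if (any(pre == "PR")) "PR"
    else if (any(pre == "SD" & wk >= min_sd_duration_weeks)) "SD"
    else if (length(pd_idx)) "PD"
    else "NE"
  list(category = category, confirmed = confirmed)
}

#' Duration of response
#'
#' Time from the first assessment qualifying as PR or CR to progression.
#' Without a PD the duration is censored at the last assessment; when the
#' response occurred at the last assessment there is no follow-up at all
#' and the duration is reported as not available.
#'
#' @param series a [lesion_series()].
#' @return A list with `status` in `c("event", "censored",
#'   "not_available", "not_applicable")` and `weeks` (`NA` unless an event
#'   or censoring time exists).
#' @export
duration_of_response <- function(series) {
  stopifnot(inherits(series, "lesion_series"))
  trace <- assessment_trace(series)
  resp <- which(trace %in% c("CR", "PR"))
  if (!length(resp))
    return(list(status = "not_applicable", weeks = NA_real_))
  onset <- series$week[resp[1]]
  pd <- which(trace == "PD" & series$week > onset)
  if (length(pd))
    return(list(status = "event", weeks = series$week[pd[1]] - onset))
  last <- max(series$week)
  if (last <= onset)
    return(list(status = "not_available", weeks = NA_real_))
  list(status = "censored", weeks = last - onset)
}

#' Waterfall table of best change per subject
#'
#' @param series_list list of [lesion_series()].
#' @return data.frame `subject, best_percent_change, category, confirmed`,
#'   one row per subject, sorted for waterfall plotting (worst first).
#' @export
waterfall_table <- function(series_list) {
  rows <- lapply(series_list, function(s) {
    bor <- best_overall_response(s)
    data.frame(subject = s$subject,
               best_percent_change = percent_change_from_baseline(s)$best,
               category = bor$category, confirmed = bor$confirmed)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$best_percent_change), ]
  rownames(out) <- NULL
  out
}
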