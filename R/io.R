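#' Read / write cohort tables
#'
#' CSV with header `dose_mg,n_patients,n_dlt_patients`, one row per dose
#' level in enrollment order.
#'
#' @param path file path.
#' @return [read_cohorts_csv()]: a [cohort_records()] table.
#' @export
read_cohorts_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  as_cohort_records(d)
}

#' @rdname read_cohorts_csv
#' @param cohorts a [cohort_records()] table.
#' @export
write_cohorts_csv <- function(cohorts, path) {
  cohorts <- as_cohort_records(cohorts)
  write.csv(as.data.frame(cohorts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a design configuration as JSON
#'
#' The JSON mirrors [design_config()]: objects `prior`, `rules`, `mtd`,
#' `intervals` (each optional beyond the required prior/rules fields),
#' plus `provisional_levels`, `start_dose`, `cohort_size`, `max_patients`,
#' `schedule`, `dlt_window_days`.
#'
#' @param path file path.
#' @return A [design_config()].
#' @export
read_design_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  prior <- do.call(blrm_prior, as.list(j$prior))
  rules <- do.call(escalation_rules, as.list(j$rules))
  args <- list(prior = prior, rules = rules,
               provisional_levels = j$provisional_levels)
  if (!is.null(j$mtd)) args$mtd <- do.call(mtd_rule, as.list(j$mtd))
  if (!is.null(j$intervals))
    args$intervals <- do.call(toxicity_intervals, as.list(j$intervals))
  for (nm in c("start_dose", "cohort_size", "max_patients", "schedule",
               "dlt_window_days", "expand_at_mtd"))
    if (!is.null(j[[nm]])) args[[nm]] <- j[[nm]]
  do.call(design_config, args)
}

#' @rdname read_design_json
#' @param design a [design_config()].
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "design_config"))
  j <- list(prior = unclass(design$prior), rules = unclass(design$rules),
            mtd = unclass(design$mtd), intervals = unclass(design$intervals),
            provisional_levels = design$provisional_levels,
            start_dose = design$start_dose, cohort_size = design$cohort_size,
            max_patients = design$max_patients, schedule = design$schedule,
            dlt_window_days = design$dlt_window_days,
            expand_at_mtd = design$expand_at_mtd)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write long-format concentration data
#'
#' CSV with header `subject,time,conc,lloq` (lloq constant per subject).
#'
#' @param path file path.
#' @return [read_conc_csv()]: a list of [conc_series()], one per subject.
#' @export
read_conc_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "time", "conc") %in% names(d)))
  lapply(split(d, d$subject), function(s) {
    s <- s[order(s$time), ]
    conc_series(s$subject[1], s$time, s$conc,
                lloq = if ("lloq" %in% names(s)) s$lloq[1] else 0)
  })
}

#' @rdname read_conc_csv
#' @param series_list list of [conc_series()].
#' @export
write_conc_csv <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s)
    data.frame(subject = s$subject, time = s$time, conc = s$conc,
               lloq = attr(s, "lloq"))))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read lesion measurement data
#'
#' CSV with header `subject,week,target_sum_mm,new_lesion_flag`; the
#' baseline sum is the row at `week = 0`.
#'
#' @param path file path.
#' @return A list of [lesion_series()], one per subject.
#' @export
read_lesions_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "week", "target_sum_mm") %in% names(d)))
  if (!"new_lesion_flag" %in% names(d)) d$new_lesion_flag <- FALSE
  lapply(split(d, d$subject), function(s) {
    s <- s[order(s$week), ]
    base <- s$target_sum_mm[s$week == 0]
    if (length(base) != 1)
      stop("subject ", s$subject[1], ": exactly one week-0 baseline row ",
           "is required", call. = FALSE)
    post <- s[s$week > 0, ]
    lesion_series(s$subject[1], post$week, post$target_sum_mm, base,
                  as.logical(post$new_lesion_flag))
  })
}

#' BLRM fit report as JSON
#'
#' Emits per-dose interval probabilities, overdose probabilities and
#' admissibility flags, the recommended next dose and the MTD declaration
#' for a cohort table under a design — the machine-readable companion to
#' [replay()].
#'
#' @param cohorts a [cohort_records()] table.
#' @param design a [design_config()].
#' @param path output path.
#' @return The report list, invisibly (also written to `path` when given).
#' @export
blrm_fit_report <- function(cohorts, design, path = NULL) {
  res <- replay(cohorts, design)
  final <- res$decisions[[length(res$decisions)]]
  report <- list(
    schedule = design$schedule,
    doses = final$summary,
    recommended_next_dose =
      if (final$recommendation$stop) "stop" else final$recommendation$dose,
    mtd = if (res$mtd$determined) res$mtd$mtd_mg else "not determined",
    n_patients = res$n_patients, n_dlt_patients = res$n_dlt_patients)
  if (!is.null(path))
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  invisible(report)
}
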