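#' Season of a calendar date
#'
#' Fixed astronomical boundaries: Dec 21 - Mar 20 winter, Mar 21 - Jun 20
#' spring, Jun 21 - Sep 20 summer, Sep 21 - Dec 20 autumn (so e.g. 25
#' September maps to autumn).
#'
#' @param date A `Date` vector (or strings parseable as ISO dates).
#' @return Factor with levels `winter`, `autumn`, `spring`, `summer`.
#' @export
season_of <- function(date) {
  d <- as.Date(date)
  if (anyNA(d)) stop("invalid date passed to season_of")
  md <- as.integer(format(d, "%m")) * 100L + as.integer(format(d, "%d"))
  s <- ifelse(md >= 1221 | md <= 320, "winter",
       ifelse(md <= 620, "spring",
       ifelse(md <= 920, "summer", "autumn")))
  factor(s, levels = c("winter", "autumn", "spring", "summer"))
}

#' Collapse 5-second epochs to minute records
#'
#' Each minute value is the sum of its twelve 5-second epochs; a minute is
#' marked unobserved if any constituent epoch is missing (absent row or `NA`
#' activity).
#'
#' @param epoch_records data.frame with `subject_id`, `date`,
#'   `second_of_day` (multiples of 5 in 0-86395) and `activity`.
#' @return Minute-record `data.table` (`subject_id`, `date`, `minute_of_day`,
#'   `activity`, `observed`); unobserved minutes have `NA` activity. Minutes
#'   with no epochs at all are omitted (treated as unobserved downstream).
#' @export
aggregate_epochs_to_minutes <- function(epoch_records) {
  er <- data.table::as.data.table(epoch_records)
  need <- c("subject_id", "date", "second_of_day", "activity")
  if (!all(need %in% names(er)))
    stop("epoch records must have columns: ", paste(need, collapse = ", "))
  if (any(er$second_of_day %% 5 != 0 | er$second_of_day < 0 |
          er$second_of_day >= 86400))
    stop("epoch timestamps must align to 5-second boundaries within the day")
  if (anyDuplicated(er, by = c("subject_id", "date", "second_of_day")))
    stop("data integrity error: duplicate epochs for one timestamp")
  second_of_day <- activity <- NULL  # data.table NSE
  er[, minute_of_day := second_of_day %/% 60L]
  out <- er[, .(activity = sum(activity),
                observed = sum(!is.na(activity)) == 12L),
            by = .(subject_id, date, minute_of_day)]
  out[observed == FALSE, activity := NA_real_]
  data.table::setorder(out, subject_id, date, minute_of_day)
  out[]
}

#' Assemble day curves from minute records
#'
#' Pivots long-format minute records into one 1440-value curve per
#' subject-day (the day is the local-clock 24-hour interval), with an
#' observed-minute mask and day-level metadata: weekend (Saturday/Sunday),
#' work/school-day flag joined from `day_covariates` if given, and season of
#' the date. Minutes absent from the input are unobserved.
#'
#' @param minute_records Table with `subject_id`, `date`, `minute_of_day`
#'   (0-1439), `activity`, and optionally `observed`.
#' @param day_covariates Optional table with `subject_id`, `date`, `workday`.
#' @return A `day_curves` object: list with numeric matrix `values`
#'   (subject-days by 1440, `NA` where unobserved), logical matrix
#'   `observed`, and data.frame `meta` (`subject_id`, `date`, `weekend`,
#'   `workday`, `season`, `n_observed`, `valid`).
#' @export
build_day_curves <- function(minute_records, day_covariates = NULL) {
  mr <- data.table::as.data.table(minute_records)
  if (!all(c("subject_id", "date", "minute_of_day", "activity") %in%
           names(mr)))
    stop("minute records must have subject_id, date, minute_of_day, activity")
  if (any(mr$minute_of_day < 0L | mr$minute_of_day > 1439L))
    stop("minute_of_day outside [0, 1439]")
  if (!"observed" %in% names(mr)) mr$observed <- !is.na(mr$activity)
  mr$date <- as.Date(mr$date)
  data.table::setorder(mr, subject_id, date, minute_of_day)
  key <- paste(mr$subject_id, mr$date)
  days <- !duplicated(key)
  meta <- data.frame(subject_id = mr$subject_id[days], date = mr$date[days],
                     stringsAsFactors = FALSE)
  D <- nrow(meta)
  values <- matrix(NA_real_, D, 1440L)
  observed <- matrix(FALSE, D, 1440L)
  row_of <- match(key, key[days])
  idx <- cbind(row_of, mr$minute_of_day + 1L)
  ok <- mr$observed & !is.na(mr$activity)
  values[idx[ok, , drop = FALSE]] <- mr$activity[ok]
  observed[idx[ok, , drop = FALSE]] <- TRUE
  meta$weekend <- format(meta$date, "%u") %in% c("6", "7")
  meta$workday <- NA
  if (!is.null(day_covariates)) {
    dc <- as.data.frame(day_covariates)
    j <- match(paste(meta$subject_id, meta$date),
               paste(dc$subject_id, as.Date(dc$date)))
    meta$workday <- as.logical(dc$workday[j])
  }
  meta$season <- season_of(meta$date)
  meta$n_observed <- rowSums(observed)
  meta$valid <- NA
  structure(list(values = values, observed = observed, meta = meta),
            class = "day_curves")
}

#' @export
print.day_curves <- function(x, ...) {
  cat(sprintf(paste0("Day curves: %d subject-days from %d subjects; ",
                     "median observed minutes %d; valid days %s\n"),
              nrow(x$meta), length(unique(x$meta$subject_id)),
              as.integer(stats::median(x$meta$n_observed)),
              if (all(is.na(x$meta$valid))) "not yet flagged"
              else sprintf("%d", sum(x$meta$valid))))
  invisible(x)
}

#' Flag valid recording days
#'
#' A day is valid when at least `min_minutes` minutes were observed; the
#' default 960 implements the 16-recorded-hours wear-time rule (the boundary
#' is inclusive). Invalid days are kept but excluded from all downstream
#' statistics.
#'
#' @param day_curves A `day_curves` object.
#' @param min_minutes Validity threshold in observed minutes.
#' @return The `day_curves` with `meta$valid` filled.
#' @export
flag_valid_days <- function(day_curves, min_minutes = 960L) {
  stopifnot(inherits(day_curves, "day_curves"))
  day_curves$meta$valid <- day_curves$meta$n_observed >= min_minutes
  day_curves
}

#' Apply the weekday + weekend inclusion rule
#'
#' A subject is included when at least one valid weekday and at least one
#' valid weekend day are available. Excluded subjects are dropped from the
#' curves with a per-subject reason in the returned log.
#'
#' @param day_curves A `day_curves` object with valid flags set.
#' @return List: `day_curves` restricted to included subjects, and
#'   `inclusion` data.frame (`subject_id`, `n_valid_weekday`,
#'   `n_valid_weekend`, `included`, `reason`).
#' @export
check_inclusion <- function(day_curves) {
  stopifnot(inherits(day_curves, "day_curves"))
  m <- day_curves$meta
  if (anyNA(m$valid)) stop("run flag_valid_days() before check_inclusion()")
  agg <- stats::aggregate(cbind(n_valid_weekday = m$valid & !m$weekend,
                                n_valid_weekend = m$valid & m$weekend),
                          by = list(subject_id = m$subject_id), FUN = sum)
  agg$included <- agg$n_valid_weekday >= 1L & agg$n_valid_weekend >= 1L
  agg$reason <- ifelse(agg$included, "",
                ifelse(agg$n_valid_weekday < 1L & agg$n_valid_weekend < 1L,
                       "no valid days",
                ifelse(agg$n_valid_weekday < 1L, "no valid weekday",
                       "no valid weekend day")))
  keep <- m$subject_id %in% agg$subject_id[agg$included]
  out <- day_curves
  out$values <- out$values[keep, , drop = FALSE]
  out$observed <- out$observed[keep, , drop = FALSE]
  out$meta <- m[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  list(day_curves = out, inclusion = agg)
}

# Circular linear interpolation over the 1440-minute grid for positions
# where a profile is undefined.
interpolate_circular <- function(profile) {
  n <- length(profile)
  known <- which(!is.na(profile))
  if (length(known) == 0L) stop("cannot interpolate an all-missing profile")
  if (length(known) == n) return(profile)
  x <- c(known[length(known)] - n, known, known[1] + n)
  y <- profile[c(known[length(known)], known, known[1])]
  miss <- which(is.na(profile))
  profile[miss] <- stats::approx(x, y, xout = miss)$y
  profile
}

#' Impute unobserved minutes on valid days
#'
#' Each unobserved minute of a valid day is replaced by the subject's
#' activity at the same time of day, averaged across the subject's other
#' valid days (only observed values donate). If a minute is unobserved on
#' every valid day of a subject, the value is filled by linear interpolation
#' across the daily grid of the subject's mean profile (circularly, so
#' midnight-spanning gaps interpolate correctly) and a warning is issued.
#' Observed values are never altered; invalid days are left untouched. The
#' operation is idempotent.
#'
#' @param day_curves A `day_curves` object with valid flags set.
#' @return The `day_curves` with valid days fully imputed.
#' @export
impute_missing <- function(day_curves) {
  stopifnot(inherits(day_curves, "day_curves"))
  m <- day_curves$meta
  if (anyNA(m$valid)) stop("run flag_valid_days() before impute_missing()")
  V <- day_curves$values
  O <- day_curves$observed
  fallback_subjects <- character(0)
  for (sid in unique(m$subject_id)) {
    rows <- which(m$subject_id == sid & m$valid)
    if (length(rows) == 0L) next
    Ov <- O[rows, , drop = FALSE]
    Vv <- V[rows, , drop = FALSE]
    Vv[!Ov] <- 0
    donor_sum <- colSums(Vv)
    donor_n <- colSums(Ov)
    profile <- ifelse(donor_n > 0L, donor_sum / pmax(donor_n, 1L), NA_real_)
    if (anyNA(profile)) {
      profile_filled <- interpolate_circular(profile)
      fallback_subjects <- c(fallback_subjects, sid)
    } else profile_filled <- profile
    for (d in rows) {
      miss <- which(!O[d, ])
      if (length(miss) == 0L) next
      # donors are the OTHER valid days; day d contributes nothing at its
      # own unobserved minutes, so the pooled mean already excludes it
      fill <- ifelse(donor_n[miss] > 0L,
                     donor_sum[miss] / pmax(donor_n[miss], 1L),
                     profile_filled[miss])
      V[d, miss] <- fill
    }
  }
  if (length(fallback_subjects))
    warning("minutes unobserved on all valid days for subject(s) ",
            paste(unique(fallback_subjects), collapse = ", "),
            "; filled by interpolation across the daily grid")
  day_curves$values <- V
  day_curves
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: build day curves, flag validity, apply the inclusion
#' rule, and impute valid days.
#'
#' @inheritParams build_day_curves
#' @param min_minutes Validity threshold in observed minutes (default 960).
#' @return List with the imputed `day_curves` (included subjects only) and
#'   the `inclusion` log.
#' @export
preprocess_actigraphy <- function(minute_records, day_covariates = NULL,
                                  min_minutes = 960L) {
  dc <- build_day_curves(minute_records, day_covariates)
  dc <- flag_valid_days(dc, min_minutes)
  inc <- check_inclusion(dc)
  dc <- impute_missing(inc$day_curves)
  list(day_curves = dc, inclusion = inc$inclusion)
}
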