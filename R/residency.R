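#' Study configuration
#'
#' Fixed constants of a monitoring campaign: nominal tag life, study window,
#' array size, and the cut-off through which monthly residency is summarised.
#' Defaults describe the Lighthouse Reef Atoll deployment: V16 coded tags
#' with an estimated 1877-day life, 18 receivers moored continuously from
#' 2007-04-23 to 2014-05-09, and monthly summaries truncated at the end of
#' 2012 because most tags expired before the array was recovered.
#'
#' @param tag_life_days nominal acoustic tag life in days.
#' @param study_start,study_end deployment window (Date or ISO string).
#' @param n_stations number of receivers in the array.
#' @param monthly_summary_end last date included in monthly residency
#'   summaries.
#' @return Object of class `"study_config"`.
#' @export
study_config <- function(tag_life_days = 1877,
                         study_start = "2007-04-23",
                         study_end = "2014-05-09",
                         n_stations = 18,
                         monthly_summary_end = "2012-12-31") {
  stopifnot(tag_life_days > 0, n_stations > 0)
  cfg <- list(tag_life_days = as.integer(tag_life_days),
              study_start = as.Date(study_start),
              study_end = as.Date(study_end),
              n_stations = as.integer(n_stations),
              monthly_summary_end = as.Date(monthly_summary_end))
  if (cfg$study_start >= cfg$study_end) stop("study_start must precede study_end")
  structure(cfg, class = "study_config")
}

# inclusive day span between two dates: tagging day and last day both count
.span_days <- function(from, to) as.numeric(to - from) + 1

#' Residency index on the nominal tag life
#'
#' RI = days detected / expected days at liberty. The denominator is the
#' nominal tag life (1877 d) except in two cases: (a) the animal was reported
#' captured by fishers, in which case the capture date is the last expected
#' day; (b) the tag outperformed its rating — detections span more than the
#' nominal life — in which case expected days run from tagging to the last
#' detection or the end of the study, whichever came first. The result is
#' clamped to [0, 1].
#'
#' @param days_detected days on which the animal was detected (daily
#'   occurrence: at least two detections that day).
#' @param date_tagged,last_detection_date,study_end Dates (vectors recycle).
#' @param capture_date Date of reported capture, `NA` when not captured.
#' @param tag_life nominal tag life in days.
#' @return Numeric vector of residency indices in [0, 1].
#' @export
compute_residency_index <- function(days_detected, date_tagged,
                                    last_detection_date, study_end,
                                    capture_date = NULL, tag_life = 1877) {
  stopifnot(all(days_detected >= 0))
  if (tag_life <= 0) stop("tag_life must be positive")
  date_tagged <- as.Date(date_tagged)
  last_detection_date <- as.Date(last_detection_date)
  study_end <- as.Date(study_end)
  n <- max(length(days_detected), length(date_tagged))
  denom <- rep(as.numeric(tag_life), n)
  span <- .span_days(date_tagged, last_detection_date)
  overrun <- !is.na(span) & span > tag_life
  if (any(overrun)) {
    capped <- pmin(last_detection_date, study_end)
    denom[overrun] <- .span_days(date_tagged, capped)[overrun]
  }
  if (!is.null(capture_date)) {
    capture_date <- as.Date(capture_date)
    cap <- !is.na(capture_date)
    denom[cap] <- .span_days(date_tagged, capture_date)[cap]
  }
  if (any(denom <= 0)) stop("non-positive expected-days denominator")
  pmin(1, days_detected / denom)
}

#' Residency index on the detection span
#'
#' RI_max = days detected / days between tagging and last detection
#' (inclusive of both endpoints). A less conservative residency measure than
#' [compute_residency_index()]: it asks how resident the animal was while it
#' was demonstrably alive and carrying a working tag. An animal detected on
#' its tagging day only has a one-day span and RI_max 1.
#'
#' @inheritParams compute_residency_index
#' @return Numeric vector in [0, 1].
#' @export
compute_max_residency_index <- function(days_detected, date_tagged,
                                        last_detection_date) {
  date_tagged <- as.Date(date_tagged)
  last_detection_date <- as.Date(last_detection_date)
  if (any(last_detection_date < date_tagged, na.rm = TRUE))
    stop("last detection precedes tagging")
  span <- .span_days(date_tagged, last_detection_date)
  pmin(1, days_detected / span)
}

#' Roaming index
#'
#' Fraction of the array's receivers at which an animal was ever detected;
#' 1 means the animal used the entire array, values near 1/n a single site.
#'
#' @param receivers_visited distinct receivers (stations, not merged nodes)
#'   with at least one retained detection.
#' @param n_stations receivers in the array (default 18).
#' @return Numeric vector in (0, 1].
#' @export
compute_roaming_index <- function(receivers_visited, n_stations = 18) {
  if (any(receivers_visited <= 0) || any(receivers_visited > n_stations))
    stop("receivers_visited must be in 1..n_stations")
  receivers_visited / n_stations
}

#' Monthly residency series
#'
#' For one animal, days detected in each calendar month divided by the days
#' in that month. Every month from the tagging month through the earlier of
#' tag death and the monthly summary cut-off is present; months without
#' detections score 0.
#'
#' @param ds a cleaned `"detection_set"`.
#' @param shark_id animal to summarise.
#' @param cfg a [study_config()].
#' @param tz_offset_hours day-boundary offset.
#' @return data.frame with `year`, `month`, `days_in_month`, `days_detected`,
#'   `monthly_ri`.
#' @export
compute_monthly_series <- function(ds, shark_id, cfg = study_config(),
                                   tz_offset_hours = 0) {
  stopifnot(inherits(ds, "detection_set"))
  sh <- ds$sharks[as.character(ds$sharks$shark_id) == as.character(shark_id), , drop = FALSE]
  if (!nrow(sh)) stop("unknown shark: ", shark_id)
  tagged <- as.Date(sh$date_tagged[1])
  tag_death <- tagged + cfg$tag_life_days - 1
  end <- min(tag_death, cfg$monthly_summary_end, cfg$study_end)
  first_month <- as.Date(format(tagged, "%Y-%m-01"))
  months <- seq(first_month, as.Date(format(end, "%Y-%m-01")), by = "month")
  ev <- ds$events[ds$events$transmitter_id == as.character(shark_id), , drop = FALSE]
  days <- unique(.calendar_day(ev$timestamp, tz_offset_hours))
  days <- days[days <= end]
  day_month <- format(days, "%Y-%m")
  counts <- table(day_month)
  ym <- format(months, "%Y-%m")
  days_in_month <- as.numeric(seq(first_month, by = "month",
                                  length.out = length(months) + 1)[-1] - months)
  got <- as.integer(counts[ym])
  got[is.na(got)] <- 0L
  data.frame(year = as.integer(format(months, "%Y")),
             month = as.integer(format(months, "%m")),
             days_in_month = days_in_month,
             days_detected = got,
             monthly_ri = got / days_in_month)
}

#' Per-animal residency summary from detections
#'
#' Builds the per-shark metric table (days detected, receivers visited, RI,
#' RI_max, roaming index) from a cleaned detection set.
#'
#' @param ds a cleaned `"detection_set"` (after [remove_false_detections()]
#'   and [apply_minimum_days_filter()]).
#' @param cfg a [study_config()].
#' @param tz_offset_hours day-boundary offset.
#' @return data.frame, one row per retained animal, Table-1-shaped: metadata
#'   plus `days_detected`, `receivers_visited`, `ri`, `ri_max`,
#'   `roaming_index`, `first_detection`, `last_detection`.
#' @export
residency_summary <- function(ds, cfg = study_config(), tz_offset_hours = 0) {
  stopifnot(inherits(ds, "detection_set"))
  ev <- ds$events
  ids <- as.character(ds$sharks$shark_id)
  ids <- ids[ids %in% unique(ev$transmitter_id)]
  rows <- lapply(ids, function(id) {
    e <- ev[ev$transmitter_id == id, , drop = FALSE]
    day <- .calendar_day(e$timestamp, tz_offset_hours)
    data.frame(shark_id = id,
               days_detected = length(unique(day)),
               receivers_visited = length(unique(e$receiver_id)),
               first_detection = min(day), last_detection = max(day),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  meta <- ds$sharks[match(out$shark_id, as.character(ds$sharks$shark_id)), , drop = FALSE]
  out <- cbind(meta[setdiff(names(meta), "shark_id")], out)
  cap <- if ("capture_date" %in% names(meta)) meta$capture_date else NULL
  out$ri <- compute_residency_index(out$days_detected, meta$date_tagged,
                                    out$last_detection, cfg$study_end,
                                    capture_date = cap,
                                    tag_life = cfg$tag_life_days)
  out$ri_max <- compute_max_residency_index(out$days_detected, meta$date_tagged,
                                            out$last_detection)
  out$roaming_index <- compute_roaming_index(out$receivers_visited, cfg$n_stations)
  rownames(out) <- NULL
  out
}

#' Cohort-level residency summary
#'
#' Summarises a per-shark metric table: means and standard deviations of the
#' residency indices, the proportion of low-residency animals, the count and
#' composition of "site- and array-faithful" animals (RI_max strictly above
#' 0.5 with roaming index strictly below 0.5), the maturity composition of
#' low-roaming animals, and size-class counts by sex.
#'
#' @param tbl data.frame with columns `ri`, `ri_max`, `roaming_index`, `sex`,
#'   `size_class` (e.g. [residency_summary()] output joined to metadata, or
#'   [lighthouse_table1()]).
#' @return Object of class `"cohort_summary"` (a list).
#' @export
summarize_cohort <- function(tbl) {
  if (!nrow(tbl)) stop("empty cohort table")
  need <- c("ri", "ri_max", "roaming_index", "sex", "size_class")
  if (!all(need %in% names(tbl)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  faithful <- tbl$ri_max > 0.5 & tbl$roaming_index < 0.5
  low_roam <- tbl$roaming_index < 0.5
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  out <- list(
    n = nrow(tbl),
    mean_ri = mean(tbl$ri), sd_ri = sd0(tbl$ri),
    mean_ri_max = mean(tbl$ri_max), sd_ri_max = sd0(tbl$ri_max),
    prop_ri_below_half = mean(tbl$ri < 0.5),
    n_ri_max_above_half = sum(tbl$ri_max > 0.5),
    prop_roaming_at_most_half = mean(tbl$roaming_index <= 0.5),
    n_site_array_faithful = sum(faithful),
    prop_faithful_mature_female =
      if (any(faithful)) mean(tbl$sex[faithful] == "F" & tbl$size_class[faithful] == "C") else NA_real_,
    prop_low_roaming_mature =
      if (any(low_roam)) mean(tbl$size_class[low_roam] == "C") else NA_real_,
    size_class_by_sex = table(size_class = tbl$size_class, sex = tbl$sex)
  )
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 2, ...) {
  cat("Cohort residency summary (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  RI      mean %.2f +/- %.2f sd; %.0f%% below 0.50\n",
              x$mean_ri, x$sd_ri, 100 * x$prop_ri_below_half))
  cat(sprintf("  RI_max  mean %.2f +/- %.2f sd; %d animals above 0.50\n",
              x$mean_ri_max, x$sd_ri_max, x$n_ri_max_above_half))
  cat(sprintf("  site- and array-faithful (RI_max > 0.5, roaming < 0.5): %d (%.0f%% mature F)\n",
              x$n_site_array_faithful, 100 * x$prop_faithful_mature_female))
  cat(sprintf("  of animals with roaming < 0.5, %.0f%% are mature\n",
              100 * x$prop_low_roaming_mature))
  cat("  size classes by sex:\n")
  print(x$size_class_by_sex)
  invisible(x)
}
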