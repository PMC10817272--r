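#' Cohort construction configuration
#'
#' Code sets and window lengths for the case/control definition: the index
#' date is an encounter after the first PTSD diagnosis and before the first
#' substance-use-disorder (ASUD) diagnosis; a case has an ASUD code within
#' \code{outcome_window_days} after the index date; eligibility requires no
#' ASUD record within \code{washout_days} before the index date. Exposure
#' data are restricted to \code{lookback_days} before the index date.
#'
#' "3 months" is fixed as 90 days and "one year" as 365 days. The outcome
#' interval is half-open on the left and closed on the right,
#' \code{(index, index + 90]}; the washout interval is closed,
#' \code{[index - 365, index]}.
#'
#' @param ptsd_codes diagnosis codes defining the condition of interest.
#' @param asud_codes diagnosis codes defining the outcome (editable;
#'   the default is a documented placeholder list).
#' @param outcome_window_days prediction window length (days).
#' @param washout_days outcome-free period required before the index date.
#' @param lookback_days exposure window length (days).
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(ptsd_codes = c("309.81", "F43.10", "F43.11", "F43.12"),
                          asud_codes = default_asud_codes(),
                          outcome_window_days = 90L,
                          washout_days = 365L,
                          lookback_days = 365L) {
  if (!length(ptsd_codes)) stop_config("ptsd_codes", "must be non-empty")
  if (!length(asud_codes)) stop_config("asud_codes", "must be non-empty")
  for (w in c(outcome_window_days, washout_days, lookback_days))
    if (!is_count(w) || w <= 0)
      stop_config("windows", "all window lengths must be positive counts")
  structure(list(ptsd_codes = as.character(ptsd_codes),
                 asud_codes = as.character(asud_codes),
                 outcome_window_days = as.integer(outcome_window_days),
                 washout_days = as.integer(washout_days),
                 lookback_days = as.integer(lookback_days)),
            class = "cohort_config")
}

encounter_dates <- function(timeline) {
  as.Date(vapply(timeline$encounters, function(e) as.numeric(e$date),
                 numeric(1)), origin = "1970-01-01")
}

dates_with_code <- function(timeline, codes) {
  hit <- vapply(timeline$encounters,
                function(e) any(e$dx %in% codes), logical(1))
  encounter_dates(timeline)[hit]
}

timeline_span_end <- function(timeline) {
  ds <- as.numeric(encounter_dates(timeline))
  if (length(timeline$notes))
    ds <- c(ds, vapply(timeline$notes, function(n) as.numeric(n$date), numeric(1)))
  as.Date(max(ds), origin = "1970-01-01")
}

#' Eligible index dates for one patient
#'
#' Returns the encounter dates that satisfy the eligibility rules: strictly
#' after the first PTSD diagnosis, strictly before the first ASUD diagnosis
#' (if any), and with no ASUD record within the washout period before the
#' candidate date. Patients whose PTSD and ASUD first occur on the same day,
#' or whose ASUD precedes PTSD, have no eligible dates.
#'
#' @param timeline a \code{patient_timeline}.
#' @param config a [cohort_config()].
#' @return vector of \code{Date}s (possibly empty), sorted ascending.
#' @export
eligible_index_dates <- function(timeline, config) {
  enc <- encounter_dates(timeline)
  ptsd <- dates_with_code(timeline, config$ptsd_codes)
  if (!length(ptsd)) return(enc[0])
  first_ptsd <- min(ptsd)
  asud <- dates_with_code(timeline, config$asud_codes)
  first_asud <- if (length(asud)) min(asud) else as.Date(Inf, origin = "1970-01-01")
  if (first_asud <= first_ptsd) return(enc[0])  # same-day or prior ASUD
  cand <- enc[enc > first_ptsd & enc < first_asud]
  if (!length(cand)) return(enc[0])
  # washout: no ASUD within [index - washout_days, index]
  ok <- vapply(cand, function(d)
    !any(asud >= d - config$washout_days & asud <= d), logical(1))
  sort(unique(cand[ok]))
}

#' Select the index date from a set of eligible dates
#'
#' Takes the latest eligible encounter date (mimicking the patient's most
#' recent status) among those whose outcome window is observable: either
#' the data span extends at least \code{outcome_window_days} past the date,
#' or an ASUD event falls inside the window.
#'
#' @param dates vector of eligible \code{Date}s (from
#'   [eligible_index_dates()]).
#' @param timeline the patient's timeline, used to determine the data span
#'   and outcome events; if \code{NULL}, all dates count as observable.
#' @param config a [cohort_config()].
#' @return a single \code{Date}, or \code{NULL} if no eligible date has an
#'   observable outcome window (no-sample signal).
#' @export
select_index_date <- function(dates, timeline = NULL, config = cohort_config()) {
  if (!length(dates)) return(NULL)
  dates <- sort(dates)
  if (is.null(timeline)) return(dates[length(dates)])
  span_end <- timeline_span_end(timeline)
  asud <- dates_with_code(timeline, config$asud_codes)
  observable <- vapply(dates, function(d) {
    span_end >= d + config$outcome_window_days ||
      any(asud > d & asud <= d + config$outcome_window_days)
  }, logical(1))
  if (!any(observable)) return(NULL)
  max(dates[observable])
}

#' Label one patient at a given index date
#'
#' Builds a \code{cohort_sample}: label is \code{"case"} iff an ASUD code
#' occurs in \code{(index, index + outcome_window_days]}; the visit list is
#' restricted to \code{[index - lookback_days, index]} with offsets in whole
#' days before the index date (oldest first); notes after the index date are
#' dropped.
#'
#' @param timeline a \code{patient_timeline}.
#' @param index_date an encounter date of the timeline.
#' @param config a [cohort_config()].
#' @return object of class \code{cohort_sample} with fields
#'   \code{patient_id}, \code{label}, \code{index_date}, \code{visits}
#'   (list of \code{list(days_before, dx, rx, lab)}), \code{static}
#'   (demographics) and \code{notes}.
#' @export
label_sample <- function(timeline, index_date, config) {
  enc <- encounter_dates(timeline)
  if (!index_date %in% enc)
    stop(sprintf("index_date %s is not an encounter date of patient %s",
                 format(index_date), timeline$patient_id), call. = FALSE)
  asud <- dates_with_code(timeline, config$asud_codes)
  is_case <- any(asud > index_date &
                   asud <= index_date + config$outcome_window_days)
  keep <- which(enc >= index_date - config$lookback_days & enc <= index_date)
  keep <- keep[order(enc[keep])]
  visits <- lapply(keep, function(v) {
    e <- timeline$encounters[[v]]
    list(days_before = days_between(e$date, index_date),
         dx = e$dx, rx = e$rx, lab = e$lab)
  })
  notes <- Filter(function(n) n$date <= index_date, timeline$notes)
  structure(list(
    patient_id = timeline$patient_id,
    label = if (is_case) "case" else "control",
    index_date = index_date,
    visits = visits,
    static = list(sex = timeline$sex, race = timeline$race,
                  birth_year = timeline$birth_year, zip5 = timeline$zip5),
    notes = notes
  ), class = "cohort_sample")
}

#' Build a labeled cohort from patient timelines
#'
#' Applies [eligible_index_dates()], [select_index_date()] and
#' [label_sample()] to every patient. Every input patient becomes exactly
#' one of: a case sample, a control sample, or an excluded patient with a
#' recorded reason.
#'
#' @param timelines list of \code{patient_timeline} objects.
#' @param config a [cohort_config()].
#' @return object of class \code{ehr_cohort}: list with \code{samples}
#'   (list of \code{cohort_sample}) and \code{exclusions} (data frame with
#'   \code{patient_id}, \code{reason}).
#' @export
build_cohort <- function(timelines, config = cohort_config()) {
  ids <- vapply(timelines, function(t) t$patient_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate patient_id: %s", ids[duplicated(ids)][1]),
         call. = FALSE)
  samples <- list()
  excl <- list()
  for (tl in timelines) {
    ptsd <- dates_with_code(tl, config$ptsd_codes)
    if (!length(ptsd)) {
      excl[[length(excl) + 1L]] <- c(tl$patient_id, "no PTSD diagnosis")
      next
    }
    elig <- eligible_index_dates(tl, config)
    if (!length(elig)) {
      asud <- dates_with_code(tl, config$asud_codes)
      reason <- if (length(asud) && min(asud) < min(ptsd))
        "ASUD before PTSD diagnosis"
      else if (length(asud) && min(asud) == min(ptsd))
        "PTSD and ASUD on the same day"
      else "no eligible index encounter"
      excl[[length(excl) + 1L]] <- c(tl$patient_id, reason)
      next
    }
    idx <- select_index_date(elig, tl, config)
    if (is.null(idx)) {
      excl[[length(excl) + 1L]] <- c(tl$patient_id, "insufficient follow-up")
      next
    }
    samples[[length(samples) + 1L]] <- label_sample(tl, idx, config)
  }
  exclusions <- if (length(excl)) {
    m <- do.call(rbind, excl)
    data.frame(patient_id = m[, 1], reason = m[, 2], stringsAsFactors = FALSE)
  } else data.frame(patient_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  structure(list(samples = samples, exclusions = exclusions, config = config),
            class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  labs <- vapply(x$samples, function(s) s$label, character(1))
  cat(sprintf("EHR cohort: %d samples (%d cases, %d controls), %d excluded\n",
              length(labs), sum(labs == "case"), sum(labs == "control"),
              nrow(x$exclusions)))
  invisible(x)
}
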