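#' Simulation configuration for synthetic EHR cohorts
#'
#' Defines the generative model for synthetic patient timelines: a
#' homogeneous Poisson visit process per patient, sparse per-visit token
#' occurrence (diagnosis codes, medication names, flagged lab results), a
#' logistic outcome model over planted risk/protective token exposures and
#' zip-level social-determinant (SDoH) covariates, and clinical notes
#' carrying psychotherapy keyword sentences.
#'
#' The outcome event (a substance-use-disorder diagnosis code) is drawn per
#' patient from \code{plogis(base_logit + sum(planted effects present in the
#' one-year lookback of the index encounter) + SDoH terms + psychotherapy
#' terms)}; when positive, the event is placed uniformly within
#' \code{outcome_window_days} after the index encounter.
#'
#' Default planted effects emulate a strong-signal EMR regime: one strong
#' risk token (log-odds +2), one strong protective token (-2), twelve
#' moderate tokens (+/-1.5), four null tokens (0), a continuous
#' neighborhood-SES coefficient of -1.2, a vegetation-index coefficient of
#' -0.4, and protective psychotherapy effects (-0.8 trauma-focused, -0.4
#' CBT).
#'
#' @param n_patients number of patients to simulate (>= 2).
#' @param seed integer master seed; all randomness derives from it.
#' @param visit_rate mean encounters per patient-year (> 0).
#' @param study_span_days length of the simulated observation span in days.
#' @param vocab_spec list with data frames \code{dx} (code, p), \code{rx}
#'   (name, p) and \code{lab} (name, p_abnormal, p_normal): per-visit
#'   occurrence probabilities for each synthetic token.
#' @param planted_effects named numeric vector of log-odds contributions to
#'   the outcome, keyed by encoded token name (e.g. \code{"LAB:HGB"},
#'   \code{"RX:DB00584"}, \code{"DX:K21"}, \code{"THX:TF"}).
#' @param base_logit intercept of the outcome model.
#' @param sdoh_spec named list of zip-level features, each a list with
#'   \code{type} ("continuous"), \code{dist} ("normal" or "uniform_pm1") and
#'   \code{coef} (planted logistic coefficient on the standardized value).
#' @param psychotherapy_rate probability a patient has an active
#'   trauma-focused therapy note before the index date.
#' @param cbt_rate probability of an active CBT note (independent).
#' @param outcome_window_days prediction window after the index date (days).
#' @param lookback_days exposure window before the index date (days).
#' @param n_zips number of distinct 5-digit zip codes in the SDoH table.
#' @param missing_zip_rate fraction of patients whose zip is absent from the
#'   SDoH table (exercises missing-SDoH handling; those patients get no
#'   SDoH contribution to the outcome).
#'
#' @return an object of class \code{sim_config}.
#' @seealso [generate_cohort()], [write_fixtures()]
#' @export
sim_config <- function(n_patients = 1000,
                       seed = 1L,
                       visit_rate = 10,
                       study_span_days = 1095L,
                       vocab_spec = default_vocab_spec(),
                       planted_effects = default_planted_effects(),
                       base_logit = 0.4,
                       sdoh_spec = default_sdoh_spec(),
                       psychotherapy_rate = 0.35,
                       cbt_rate = 0.30,
                       outcome_window_days = 90L,
                       lookback_days = 365L,
                       n_zips = 60L,
                       missing_zip_rate = 0.01) {
  if (!is_count(n_patients) || n_patients < 2)
    stop_config("n_patients", "must be an integer >= 2")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop_config("seed", "must be a single integer")
  if (!is.numeric(visit_rate) || visit_rate <= 0)
    stop_config("visit_rate", "must be > 0")
  if (!is_count(study_span_days) || study_span_days <= 0)
    stop_config("study_span_days", "must be a positive count")
  if (!is_count(outcome_window_days) || outcome_window_days <= 0)
    stop_config("outcome_window_days", "must be a positive count")
  if (!is_count(lookback_days) || lookback_days <= 0)
    stop_config("lookback_days", "must be a positive count")
  for (p in c(psychotherapy_rate, cbt_rate, missing_zip_rate))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop_config("psychotherapy_rate/cbt_rate/missing_zip_rate",
                  "probabilities must lie in [0, 1]")
  probs <- c(vocab_spec$dx$p, vocab_spec$rx$p,
             vocab_spec$lab$p_abnormal, vocab_spec$lab$p_normal)
  if (any(probs < 0 | probs > 1))
    stop_config("vocab_spec", "all occurrence probabilities must lie in [0, 1]")
  if (!is.numeric(planted_effects) || is.null(names(planted_effects)))
    stop_config("planted_effects", "must be a named numeric vector")
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    visit_rate = visit_rate, study_span_days = as.integer(study_span_days),
    vocab_spec = vocab_spec, planted_effects = planted_effects,
    base_logit = base_logit, sdoh_spec = sdoh_spec,
    psychotherapy_rate = psychotherapy_rate, cbt_rate = cbt_rate,
    outcome_window_days = as.integer(outcome_window_days),
    lookback_days = as.integer(lookback_days),
    n_zips = as.integer(n_zips), missing_zip_rate = missing_zip_rate,
    start_date = as.Date("2015-01-01")
  ), class = "sim_config")
}

#' Default synthetic token vocabulary
#'
#' Small diagnosis / medication / lab vocabularies with per-visit occurrence
#' probabilities. Token names echo real clinical concepts but the
#' vocabulary, probabilities and drug-ID mapping are synthetic.
#'
#' @return list with data frames \code{dx}, \code{rx}, \code{lab}.
#' @export
default_vocab_spec <- function() {
  list(
    dx = data.frame(
      code = c("F43.10", "K21.9", "J45.909", "R52.2", "Z00.00", "Z23",
               "M54.5", "Z12.4", "I10", "E78.5"),
      p    = c(0.042, 0.042, 0.042, 0.042, 0.042, 0.042,
               0.042, 0.042, 0.03, 0.03),
      stringsAsFactors = FALSE
    ),
    rx = data.frame(
      name = c("enalapril", "acetaminophen", "oxycodone", "clindamycin",
               "valacyclovir", "moxifloxacin", "diphenoxylate", "ibuprofen",
               "herbalsupplement"),
      p    = c(0.06, 0.042, 0.042, 0.042, 0.042, 0.042, 0.042, 0.042, 0.01),
      stringsAsFactors = FALSE
    ),
    lab = data.frame(
      name       = c("HGB", "GLUCOSE", "K", "RARELAB"),
      p_abnormal = c(0.06, 0.042, 0.042, 0.0005),
      p_normal   = c(0.05, 0.05, 0.05, 0.0005),
      stringsAsFactors = FALSE
    )
  )
}

#' Default planted outcome effects (log-odds per encoded token)
#' @return named numeric vector.
#' @export
default_planted_effects <- function() {
  c("DX:F43" = 1.25, "LAB:HGB" = 2, "RX:DB00584" = -2,
    "RX:DB00316" = 1.5, "RX:DB00497" = 1.5, "LAB:GLUCOSE" = 1.5,
    "DX:K21" = 1.5, "DX:J45" = 1.5, "DX:R52" = 1.5,
    "DX:Z00" = -1.5, "DX:Z23" = -1.5, "RX:DB01190" = -1.5,
    "RX:DB00577" = -1.5, "RX:DB00218" = -1.5, "RX:DB01081" = -1.5,
    "DX:M54" = 0, "DX:Z12" = 0, "LAB:K" = 0, "RX:DB01050" = 0,
    "THX:TF" = -0.8, "THX:CBT" = -0.4)
}

#' Default zip-level SDoH feature specification
#' @return named list of feature specs (type, dist, coef).
#' @export
default_sdoh_spec <- function() {
  list(
    nses     = list(type = "continuous", dist = "normal",      coef = -1.2),
    ndvi     = list(type = "continuous", dist = "normal",      coef = -0.4),
    ice_race = list(type = "continuous", dist = "uniform_pm1", coef = 0),
    gini     = list(type = "continuous", dist = "normal",      coef = 0)
  )
}

#' Default synthetic medication-name to DrugBank-ID mapping table
#'
#' Small lookup used by both the simulator and the encoder. The name/ID
#' pairs follow public DrugBank identifiers but the table is a synthetic
#' fixture, not an extract of the DrugBank database.
#'
#' @return data frame with columns \code{name}, \code{drugbank_id}.
#' @export
default_drug_map <- function() {
  data.frame(
    name = c("enalapril", "acetaminophen", "oxycodone", "clindamycin",
             "valacyclovir", "moxifloxacin", "diphenoxylate", "ibuprofen"),
    drugbank_id = c("DB00584", "DB00316", "DB00497", "DB01190",
                    "DB00577", "DB00218", "DB01081", "DB01050"),
    stringsAsFactors = FALSE
  )
}

#' Default substance-use-disorder diagnosis code set
#'
#' Editable placeholder list of alcohol/substance-use-disorder ICD-9/10
#' codes used to mark outcome events. Replace with a full curated list for
#' real analyses.
#' @return character vector of diagnosis codes.
#' @export
default_asud_codes <- function() {
  c("F10.10", "F10.20", "F11.10", "F11.20", "F12.10",
    "303.90", "304.00", "305.00")
}

asud_group_tokens <- function(codes = default_asud_codes()) {
  unique(vapply(codes, group_diagnosis, character(1), USE.NAMES = FALSE))
}

# ---------------------------------------------------------------------------

#' Generate a synthetic EHR cohort
#'
#' Simulates patient timelines (dated encounters with diagnosis, medication
#' and lab tokens; clinical notes; demographics; zip code) together with a
#' ground-truth table recording, per patient, the generator's index
#' encounter, the linear predictor of the outcome model, the outcome event
#' date (if any) and the planted-feature exposures. Ground truth is kept in
#' a separate table so downstream stages cannot leak labels.
#'
#' @param config a [sim_config()] object.
#' @return object of class \code{ehr_sim}: list with \code{timelines} (list
#'   of \code{patient_timeline}), \code{truth} (data frame), \code{sdoh}
#'   (zip-level SDoH table), \code{drug_map} and \code{config}.
#' @examples
#' sim <- generate_cohort(sim_config(n_patients = 20, seed = 42))
#' length(sim$timelines)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_config("config", "must be a sim_config object")
  cfg <- config
  set.seed(cfg$seed)

  # zip-level SDoH table
  zips <- sprintf("%05d", 15201 + seq_len(cfg$n_zips) - 1)
  sdoh <- data.frame(zip5 = zips, stringsAsFactors = FALSE)
  for (nm in names(cfg$sdoh_spec)) {
    spec <- cfg$sdoh_spec[[nm]]
    sdoh[[nm]] <- switch(spec$dist,
      normal = rnorm(cfg$n_zips),
      uniform_pm1 = runif(cfg$n_zips, -1, 1),
      stop_config("sdoh_spec", sprintf("unknown dist '%s'", spec$dist)))
  }

  drug_map <- default_drug_map()
  rx_to_token <- setNames(paste0("RX:", drug_map$drugbank_id), drug_map$name)

  timelines <- vector("list", cfg$n_patients)
  truth <- vector("list", cfg$n_patients)
  eff_tokens <- names(cfg$planted_effects)

  for (i in seq_len(cfg$n_patients)) {
    set.seed(child_seed(cfg$seed, i))
    pt <- simulate_patient(i, cfg, sdoh, rx_to_token, eff_tokens)
    timelines[[i]] <- pt$timeline
    truth[[i]] <- pt$truth
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  structure(list(timelines = timelines, truth = truth, sdoh = sdoh,
                 drug_map = drug_map, config = cfg),
            class = "ehr_sim")
}

# one patient: visits, tokens, notes, outcome draw
simulate_patient <- function(i, cfg, sdoh, rx_to_token, eff_tokens) {
  pid <- sprintf("P%06d", i)
  birth_year <- sample(1945:2000, 1)
  sex <- sample(c("F", "M"), 1)
  race <- sample(c("WHITE", "BLACK", "ASIAN", "OTHER"), 1,
                 prob = c(0.6, 0.25, 0.05, 0.1))
  missing_zip <- runif(1) < cfg$missing_zip_rate
  zip5 <- if (missing_zip) "00000" else sample(sdoh$zip5, 1)

  n_visits <- max(1L, rpois(1, cfg$visit_rate * cfg$study_span_days / 365))
  day_offsets <- sort(sample.int(cfg$study_span_days, n_visits, replace = TRUE) - 1L)
  dates <- cfg$start_date + day_offsets

  vs <- cfg$vocab_spec
  encounters <- vector("list", n_visits)
  for (v in seq_len(n_visits)) {
    dx <- vs$dx$code[runif(nrow(vs$dx)) < vs$dx$p]
    if (v == 1L) dx <- unique(c("F43.10", dx))  # diagnosis onset at first visit
    rx <- vs$rx$name[runif(nrow(vs$rx)) < vs$rx$p]
    ab <- runif(nrow(vs$lab)) < vs$lab$p_abnormal
    no <- runif(nrow(vs$lab)) < vs$lab$p_normal
    lab <- data.frame(name = character(0), flag = character(0),
                      stringsAsFactors = FALSE)
    if (any(ab))
      lab <- rbind(lab, data.frame(
        name = vs$lab$name[ab],
        flag = sample(c("ABNORMAL", "HIGH", "LOW"), sum(ab), replace = TRUE),
        stringsAsFactors = FALSE))
    if (any(no))
      lab <- rbind(lab, data.frame(name = vs$lab$name[no], flag = "NORMAL",
                                   stringsAsFactors = FALSE))
    encounters[[v]] <- list(date = dates[v], dx = dx, rx = rx, lab = lab)
  }

  # generator's index: latest encounter strictly after the first (onset)
  # visit that still leaves the outcome window inside the visit span
  last_day <- day_offsets[n_visits]
  cand <- which(day_offsets > day_offsets[1] &
                  day_offsets + cfg$outcome_window_days <= last_day)
  index_v <- if (length(cand)) cand[length(cand)] else NA_integer_

  # psychotherapy notes
  tf_active <- runif(1) < cfg$psychotherapy_rate
  cbt_active <- runif(1) < cfg$cbt_rate
  notes <- list()
  note_day <- function() {
    upto <- if (is.na(index_v)) last_day else day_offsets[index_v]
    cfg$start_date + sample.int(max(1L, upto + 1L), 1) - 1L
  }
  if (tf_active) {
    kind <- sample(c("CPT", "PE", "EMDR"), 1)
    notes[[length(notes) + 1L]] <- list(
      date = note_day(),
      text = generate_note(TRUE, kind, seed = child_seed(cfg$seed, i * 7L + 1L)))
  }
  if (cbt_active)
    notes[[length(notes) + 1L]] <- list(
      date = note_day(),
      text = generate_note(TRUE, "CBT", seed = child_seed(cfg$seed, i * 7L + 2L)))
  if (!tf_active && !cbt_active && runif(1) < 0.3) {
    kind <- sample(c("CPT", "PE", "EMDR", "CBT", "none"), 1)
    notes[[length(notes) + 1L]] <- list(
      date = note_day(),
      text = generate_note(FALSE, kind, seed = child_seed(cfg$seed, i * 7L + 3L)))
  }
  # occasional active-phrased note after the index date: must be ignored by
  # any leakage-safe extractor
  if (!tf_active && !is.na(index_v) && runif(1) < 0.05)
    notes[[length(notes) + 1L]] <- list(
      date = dates[index_v] + cfg$outcome_window_days %/% 3L,
      text = generate_note(TRUE, "CPT", seed = child_seed(cfg$seed, i * 7L + 4L)))

  # exposures within the lookback window of the generator index
  exposure <- setNames(rep(FALSE, length(eff_tokens)), eff_tokens)
  eta <- NA_real_
  outcome <- NA_integer_
  outcome_day <- NA_integer_
  if (!is.na(index_v)) {
    lb_lo <- day_offsets[index_v] - cfg$lookback_days
    in_lb <- which(day_offsets >= lb_lo & day_offsets <= day_offsets[index_v])
    toks <- character(0)
    for (v in in_lb) {
      e <- encounters[[v]]
      ab_names <- e$lab$name[e$lab$flag %in% c("ABNORMAL", "HIGH", "LOW")]
      toks <- c(toks,
                vapply(e$dx, group_diagnosis, character(1), USE.NAMES = FALSE),
                unname(rx_to_token[e$rx[e$rx %in% names(rx_to_token)]]),
                if (length(ab_names)) paste0("LAB:", ab_names))
    }
    toks <- unique(toks)
    exposure[] <- eff_tokens %in% toks
    exposure["THX:TF"] <- if ("THX:TF" %in% eff_tokens) tf_active else FALSE
    exposure["THX:CBT"] <- if ("THX:CBT" %in% eff_tokens) cbt_active else FALSE

    eta <- cfg$base_logit + sum(cfg$planted_effects[exposure])
    if (!missing_zip) {
      zrow <- sdoh[sdoh$zip5 == zip5, , drop = FALSE]
      for (nm in names(cfg$sdoh_spec))
        eta <- eta + cfg$sdoh_spec[[nm]]$coef * zrow[[nm]]
    }
    outcome <- rbinom(1, 1, plogis(eta))
    if (outcome == 1L) {
      outcome_day <- day_offsets[index_v] + sample.int(cfg$outcome_window_days, 1)
      code <- sample(default_asud_codes(), 1)
      encounters[[length(encounters) + 1L]] <- list(
        date = cfg$start_date + outcome_day, dx = code, rx = character(0),
        lab = data.frame(name = character(0), flag = character(0),
                         stringsAsFactors = FALSE))
      # keep encounters date-ordered
      ord <- order(vapply(encounters, function(e) as.numeric(e$date), numeric(1)))
      encounters <- encounters[ord]
    }
  }

  timeline <- structure(list(
    patient_id = pid, birth_year = birth_year, sex = sex, race = race,
    zip5 = zip5, encounters = encounters, notes = notes
  ), class = "patient_timeline")

  tr <- data.frame(patient_id = pid,
                   index_day = if (is.na(index_v)) NA_integer_ else day_offsets[index_v],
                   eta = eta, outcome = outcome, outcome_day = outcome_day,
                   tf_active = tf_active, cbt_active = cbt_active,
                   zip5 = zip5, stringsAsFactors = FALSE)
  for (tok in eff_tokens) tr[[paste0("exp_", tok)]] <- unname(exposure[tok])
  list(timeline = timeline, truth = tr)
}

# ---------------------------------------------------------------------------

.note_phrases <- c(
  CPT = "cognitive processing therapy",
  PE = "prolonged exposure",
  EMDR = "eye movement desensitization and reprocessing",
  CBT = "cognitive behavioral therapy"
)

#' Generate a synthetic clinical note snippet
#'
#' Produces a short free-text note. With \code{active_therapy = TRUE} the
#' note contains at least one sentence describing the given psychotherapy as
#' ongoing treatment; otherwise any keyword mention is phrased as declined
#' or historical (so that a sentence classifier, not mere keyword matching,
#' is required to determine active status).
#'
#' @param active_therapy logical; is the therapy currently active?
#' @param therapy_kind one of \code{"CPT"}, \code{"PE"}, \code{"EMDR"},
#'   \code{"CBT"}, \code{"none"}.
#' @param seed integer seed for template selection.
#' @return a single string.
#' @examples
#' generate_note(TRUE, "CPT", seed = 1)
#' @export
generate_note <- function(active_therapy, therapy_kind, seed = 1L) {
  if (!therapy_kind %in% c(names(.note_phrases), "none"))
    stop(sprintf("unknown therapy_kind '%s'", therapy_kind), call. = FALSE)
  if (active_therapy && therapy_kind == "none")
    stop("active_therapy = TRUE requires a specific therapy_kind", call. = FALSE)
  set.seed(seed)
  filler <- sample(c(
    "Patient seen for routine follow-up today.",
    "Vitals stable and reviewed.",
    "Medication reconciliation completed."), 1)
  if (therapy_kind == "none") {
    body <- sample(c("No therapy discussed.",
                     "Plan: continue current medications."), 1)
    return(paste(filler, body))
  }
  phrase <- .note_phrases[[therapy_kind]]
  body <- if (active_therapy) {
    sample(c(
      sprintf("Patient continues %s sessions weekly and reports steady progress.", phrase),
      sprintf("Currently undergoing %s with good engagement.", phrase),
      sprintf("Patient is attending %s and tolerating sessions well.", phrase)), 1)
  } else {
    sample(c(
      sprintf("Patient declined %s at this time.", phrase),
      sprintf("Completed a course of %s two years ago; not currently in treatment.", phrase),
      sprintf("Discussed referral for %s but patient is not interested.", phrase)), 1)
  }
  paste(filler, body)
}
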