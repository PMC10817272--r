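#' Group a diagnosis code into its 3-character disease category
#'
#' Diagnosis codes are clustered by their first three characters (the
#' ICD-10 category; ICD-9 codes are grouped by the same prefix rule). The
#' result is namespaced with \code{"DX:"} and the operation is idempotent on
#' the 3-character core.
#'
#' @param code a non-empty diagnosis code string (e.g. \code{"F43.10"}).
#' @return a group token such as \code{"DX:F43"}.
#' @examples
#' group_diagnosis("F43.10")  # "DX:F43"
#' group_diagnosis("309.81")  # "DX:309"
#' @export
group_diagnosis <- function(code) {
  if (!is.character(code) || length(code) != 1 || is.na(code))
    stop("code must be a single string", call. = FALSE)
  core <- sub("^DX:", "", code)
  if (nchar(core) < 3)
    stop(sprintf("diagnosis code '%s' is shorter than 3 characters", code),
         call. = FALSE)
  paste0("DX:", toupper(substr(core, 1, 3)))
}

#' Map a medication name to its DrugBank-ID token
#'
#' Case-insensitive lookup in a name-to-DrugBank-ID table. Unmapped names
#' return \code{NA} so callers can drop them and count the drops.
#'
#' @param name medication name.
#' @param mapping data frame with columns \code{name}, \code{drugbank_id}.
#' @return token \code{"RX:<DrugBankID>"}, or \code{NA_character_} if the
#'   name is not in the mapping.
#' @examples
#' map_drug("Enalapril", default_drug_map())  # "RX:DB00584"
#' @export
map_drug <- function(name, mapping) {
  i <- match(tolower(name), tolower(mapping$name))
  ifelse(is.na(i), NA_character_, paste0("RX:", mapping$drugbank_id[i]))
}

#' Retain abnormal-lab tokens that clear a cohort-wide frequency threshold
#'
#' Only lab events flagged \code{ABNORMAL}, \code{HIGH} or \code{LOW} are
#' tokenized (as \code{"LAB:<analyte>"}); an analyte is retained only if its
#' cohort-wide abnormal-event count is at least \code{min_freq}. The
#' threshold is computed once over the whole cohort, before any dataset
#' split, so the vocabulary is split-independent.
#'
#' @param samples list of \code{cohort_sample} objects.
#' @param min_freq minimum cohort-wide abnormal-event count (default 100).
#' @return list with \code{retained} (character vector of analyte names)
#'   and \code{counts} (named abnormal-event counts for all analytes).
#' @export
filter_labs <- function(samples, min_freq = 100) {
  nm <- character(0)
  for (s in samples) for (v in s$visits) {
    if (!NROW(v$lab)) next
    nm <- c(nm, v$lab$name[v$lab$flag %in% c("ABNORMAL", "HIGH", "LOW")])
  }
  tab <- table(nm)
  counts <- setNames(as.integer(tab), names(tab))
  list(retained = names(counts)[counts >= min_freq], counts = counts)
}

# quintile bin by rank; ties share the rank of their first occurrence
# (rank-then-first-bin), so an all-equal feature puts everyone in Q1
quintile_bin <- function(x) {
  r <- rank(x, ties.method = "min")
  pmin(5L, pmax(1L, ceiling(5 * r / length(x))))
}

#' Encode SDoH and demographic features for a cohort
#'
#' Continuous zip-level features are z-scored over the cohort and binned
#' into quintile tokens \code{"SDOH:<name>:Q1".."Q5"}; demographics become
#' tokens (\code{"SEX:F"}, \code{"RACE:WHITE"}, age binned by decade as
#' \code{"AGE:40"}). Patients whose zip is absent from the table receive a
#' single \code{"SDOH:MISSING"} token and \code{NA} covariates. The raw
#' z-scored covariate matrix is returned alongside the tokens for the
#' regression-coefficient analysis.
#'
#' @param samples list of \code{cohort_sample} objects.
#' @param sdoh_table data frame from [read_sdoh()] (column \code{zip5} plus
#'   one numeric column per feature).
#' @return list with \code{tokens} (list of character vectors, one per
#'   sample) and \code{covariates} (numeric matrix, one row per sample,
#'   \code{NA} for missing zips).
#' @export
encode_sdoh <- function(samples, sdoh_table) {
  feat <- setdiff(names(sdoh_table), "zip5")
  zips <- vapply(samples, function(s) s$static$zip5, character(1))
  row <- match(zips, sdoh_table$zip5)
  n <- length(samples)
  cov <- matrix(NA_real_, n, length(feat), dimnames = list(NULL, feat))
  for (f in feat) {
    v <- sdoh_table[[f]][row]
    mu <- mean(v, na.rm = TRUE)
    sdv <- sd(v, na.rm = TRUE)
    cov[, f] <- if (is.na(sdv) || sdv == 0) ifelse(is.na(v), NA, 0) else (v - mu) / sdv
  }
  tokens <- vector("list", n)
  bins <- matrix(NA_integer_, n, length(feat), dimnames = list(NULL, feat))
  present <- !is.na(row)
  for (f in feat) if (any(present))
    bins[present, f] <- quintile_bin(cov[present, f])
  for (i in seq_len(n)) {
    s <- samples[[i]]
    age <- as.integer(format(s$index_date, "%Y")) - s$static$birth_year
    tk <- c(paste0("SEX:", s$static$sex),
            paste0("RACE:", s$static$race),
            paste0("AGE:", (age %/% 10) * 10))
    tk <- c(tk, if (present[i])
      paste0("SDOH:", feat, ":Q", bins[i, feat]) else "SDOH:MISSING")
    tokens[[i]] <- tk
  }
  list(tokens = tokens, covariates = cov)
}

#' Build a token vocabulary from tokenized samples
#'
#' Tokens are ranked by cohort frequency and truncated to
#' \code{max_vocab - 1} entries (integer index 0 is reserved for padding;
#' assigned indices start at 1). The reference token (the grouped PTSD
#' diagnosis token) is force-retained whenever observed.
#'
#' @param token_lists list (one element per sample) of lists of character
#'   vectors (one per visit), or of flat character vectors.
#' @param max_vocab maximum vocabulary size including the padding slot
#'   (default 30000).
#' @param reference_token token that must survive truncation (default
#'   \code{"DX:F43"}).
#' @return object of class \code{vocab_map}: list with \code{index}
#'   (named integer vector token -> index), \code{tokens} (index -> token),
#'   \code{freq}, \code{reference_token}.
#' @export
build_vocab <- function(token_lists, max_vocab = 30000,
                        reference_token = "DX:F43") {
  all_tokens <- unlist(token_lists, use.names = FALSE)
  freq <- sort(table(all_tokens), decreasing = TRUE)
  toks <- names(freq)
  keep_n <- min(length(toks), max_vocab - 1L)
  kept <- toks[seq_len(keep_n)]
  if (reference_token %in% toks && !reference_token %in% kept)
    kept <- c(kept[-keep_n], reference_token)
  idx <- seq_along(kept)
  structure(list(index = setNames(idx, kept), tokens = kept,
                 freq = as.integer(freq[kept]),
                 reference_token = reference_token),
            class = "vocab_map")
}

#' @export
print.vocab_map <- function(x, ...) {
  cat(sprintf("vocab_map: %d tokens (+ padding index 0), reference '%s'\n",
              length(x$tokens), x$reference_token))
  invisible(x)
}

vocab_lookup <- function(vocab, tokens) {
  unname(vocab$index[tokens])
}

vocab_decode <- function(vocab, idx) {
  vocab$tokens[idx]
}

# tokenize one cohort_sample's visits: grouped dx + mapped rx + retained labs
tokenize_visits <- function(sample, drug_map, retained_labs) {
  dropped_rx <- 0L
  visits <- lapply(sample$visits, function(v) {
    dx <- vapply(v$dx, group_diagnosis, character(1), USE.NAMES = FALSE)
    rx <- map_drug(v$rx, drug_map)
    dropped_rx <<- dropped_rx + sum(is.na(rx))
    rx <- rx[!is.na(rx)]
    lab <- character(0)
    if (NROW(v$lab)) {
      ab <- v$lab$flag %in% c("ABNORMAL", "HIGH", "LOW") &
        v$lab$name %in% retained_labs
      if (any(ab)) lab <- paste0("LAB:", v$lab$name[ab])
    }
    list(days_before = v$days_before, tokens = c(dx, rx, lab))
  })
  list(visits = visits, dropped_rx = dropped_rx)
}

#' Encode one tokenized sample against a vocabulary
#'
#' Maps per-visit token lists to integer index lists and computes elapsed
#' days between consecutive retained visits (first visit has elapsed 0).
#' Tokens absent from the vocabulary are dropped; visits whose tokens are
#' all out-of-vocabulary are omitted and elapsed times recomputed over the
#' remaining visits.
#'
#' @param visit_tokens list of \code{list(days_before, tokens)}, oldest
#'   visit first.
#' @param vocab a [build_vocab()] result.
#' @return list with \code{visits} (list of integer vectors),
#'   \code{elapsed} (numeric vector of day gaps, first 0) and
#'   \code{days_before} (retained visits' offsets).
#' @export
encode_sample <- function(visit_tokens, vocab) {
  idx_lists <- lapply(visit_tokens, function(v) {
    ix <- vocab_lookup(vocab, v$tokens)
    ix[!is.na(ix)]
  })
  keep <- lengths(idx_lists) > 0
  idx_lists <- idx_lists[keep]
  db <- vapply(visit_tokens, function(v) as.numeric(v$days_before),
               numeric(1))[keep]
  elapsed <- if (length(db)) c(0, -diff(db)) else numeric(0)
  list(visits = idx_lists, elapsed = elapsed, days_before = db)
}

#' Encode a cohort end-to-end
#'
#' Runs lab filtering, visit tokenization (diagnosis grouping, drug
#' mapping), SDoH/demographic coding, optional psychotherapy-status
#' extraction from notes, vocabulary construction and integer encoding.
#' Static tokens (demographics, SDoH quintiles, therapy flags) are appended
#' as a final visit at the index date (elapsed 0), mirroring how static
#' context enters visit-sequence models.
#'
#' @param cohort an \code{ehr_cohort} from [build_cohort()].
#' @param sdoh_table zip-level SDoH data frame (see [read_sdoh()]).
#' @param drug_map medication mapping data frame (see [read_drug_map()]).
#' @param nlp optional psychotherapy-extraction configuration from
#'   [nlp_config()]; \code{NULL} skips therapy flags.
#' @param min_lab_freq cohort-wide abnormal-event threshold for lab tokens.
#' @param max_vocab maximum vocabulary size (default 30000).
#' @param reference_token force-retained reference token (default
#'   \code{"DX:F43"}, the grouped PTSD diagnosis).
#' @return object of class \code{encoded_cohort}: list with
#'   \code{samples} (each with \code{patient_id}, \code{label} (0/1),
#'   \code{visits}, \code{elapsed}, \code{static_tokens}), \code{vocab},
#'   \code{covariates} (z-scored SDoH matrix plus therapy-flag columns),
#'   \code{labels}, \code{dropped_rx} (unmapped-drug count),
#'   \code{reference_token}.
#' @export
encode_cohort <- function(cohort, sdoh_table, drug_map = default_drug_map(),
                          nlp = NULL, min_lab_freq = 100, max_vocab = 30000,
                          reference_token = "DX:F43") {
  samples <- cohort$samples
  if (!length(samples)) stop("cohort has no samples", call. = FALSE)
  labs <- filter_labs(samples, min_freq = min_lab_freq)
  sd_enc <- encode_sdoh(samples, sdoh_table)

  therapy <- NULL
  if (!is.null(nlp)) {
    therapy <- lapply(samples, function(s)
      patient_therapy_flags(s$notes, nlp$keywords, nlp$anchors, nlp$embedder,
                            threshold = nlp$threshold, margin = nlp$margin))
  }

  dropped_rx <- 0L
  tokenized <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    tv <- tokenize_visits(samples[[i]], drug_map, labs$retained)
    dropped_rx <- dropped_rx + tv$dropped_rx
    static <- sd_enc$tokens[[i]]
    if (!is.null(therapy)) {
      if (therapy[[i]]$cbt_active) static <- c(static, "THX:CBT")
      if (therapy[[i]]$trauma_focused_active) static <- c(static, "THX:TF")
    }
    tokenized[[i]] <- list(
      visits = c(tv$visits, list(list(days_before = 0, tokens = static))),
      static = static)
  }

  vocab <- build_vocab(lapply(tokenized, function(t)
    lapply(t$visits, `[[`, "tokens")), max_vocab = max_vocab,
    reference_token = reference_token)

  enc_samples <- vector("list", length(samples))
  labels <- integer(length(samples))
  for (i in seq_along(samples)) {
    enc <- encode_sample(tokenized[[i]]$visits, vocab)
    labels[i] <- as.integer(samples[[i]]$label == "case")
    enc_samples[[i]] <- list(
      patient_id = samples[[i]]$patient_id,
      label = labels[i],
      visits = enc$visits, elapsed = enc$elapsed,
      days_before = enc$days_before,
      static_tokens = tokenized[[i]]$static)
  }

  cov <- sd_enc$covariates
  if (!is.null(therapy)) {
    cov <- cbind(cov,
      thx_cbt = vapply(therapy, function(t) as.numeric(t$cbt_active), numeric(1)),
      thx_tf = vapply(therapy, function(t) as.numeric(t$trauma_focused_active),
                      numeric(1)))
  }

  structure(list(samples = enc_samples, vocab = vocab, covariates = cov,
                 labels = labels, dropped_rx = dropped_rx,
                 reference_token = reference_token),
            class = "encoded_cohort")
}

#' @export
print.encoded_cohort <- function(x, ...) {
  cat(sprintf(paste0("encoded cohort: %d samples (%d cases), vocab %d tokens,",
                     " %d covariates, %d unmapped drug events dropped\n"),
              length(x$samples), sum(x$labels), length(x$vocab$tokens),
              ncol(x$covariates), x$dropped_rx))
  invisible(x)
}
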