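#' Default psychotherapy keyword dictionary
#'
#' Maps each therapy class to its lowercase keyword phrases: CPT, PE and
#' EMDR together form the trauma-focused class; CBT is reported separately.
#' @return named list of character vectors.
#' @export
default_keyword_dictionary <- function() {
  list(
    CPT = "cognitive processing therapy",
    PE = "prolonged exposure",
    EMDR = "eye movement desensitization and reprocessing",
    CBT = "cognitive behavioral therapy"
  )
}

#' Default sentence dictionary (active / inactive exemplars)
#'
#' Exemplar sentences used as similarity anchors when deciding whether a
#' keyword mention describes ongoing treatment (active) or a declined,
#' historical or merely discussed one (inactive).
#' @return list with character vectors \code{active} and \code{inactive}.
#' @export
default_sentence_dictionary <- function() {
  list(
    active = c(
      "Patient continues cognitive processing therapy sessions weekly and reports steady progress.",
      "Currently undergoing prolonged exposure with good engagement.",
      "Patient is attending cognitive behavioral therapy and tolerating sessions well."
    ),
    inactive = c(
      "Patient declined cognitive processing therapy at this time.",
      "Completed a course of prolonged exposure two years ago; not currently in treatment.",
      "Discussed referral for cognitive behavioral therapy but patient is not interested."
    )
  )
}

#' Deterministic character-trigram hashing sentence embedder
#'
#' Maps text to a fixed-length vector by hashing lowercase character
#' trigrams into signed buckets. Deterministic (equal inputs give equal
#' vectors) and requires no trained weights, which makes the classification
#' pipeline reproducible bit-exactly. Any embedding function with the same
#' contract (text in, fixed-length numeric vector out, deterministic) can
#' be plugged in instead, e.g. a pre-trained transformer sentence encoder
#' with output dimension 768.
#'
#' @param dim embedding dimension (default 768).
#' @return a function \code{character(1) -> numeric(dim)}.
#' @export
hash_embedder <- function(dim = 768) {
  force(dim)
  function(text) {
    s <- tolower(text)
    s <- gsub("[^a-z ]+", " ", s)
    s <- gsub(" +", " ", trimws(s))
    v <- numeric(dim)
    ch <- if (nzchar(s)) utf8ToInt(s) else integer(0)
    n <- length(ch)
    if (n >= 3) {
      h <- (ch[1:(n - 2)] * 31 + ch[2:(n - 1)]) * 31 + ch[3:n]
      d <- (h %% dim) + 1
      sgn <- 1 - 2 * ((h %/% dim) %% 2)
      for (k in seq_along(d)) v[d[k]] <- v[d[k]] + sgn[k]
    }
    v
  }
}

#' Psychotherapy-extraction configuration
#'
#' Bundles the keyword dictionary, sentence anchors, embedder and decision
#' parameters used by [patient_therapy_flags()] and [encode_cohort()].
#'
#' @param keywords keyword dictionary (see [default_keyword_dictionary()]).
#' @param anchors sentence dictionary (see [default_sentence_dictionary()]).
#' @param embedder deterministic text-embedding function.
#' @param threshold minimum cosine similarity to the nearest active anchor.
#' @param margin required excess of active over inactive similarity.
#' @return object of class \code{nlp_config}.
#' @export
nlp_config <- function(keywords = default_keyword_dictionary(),
                       anchors = default_sentence_dictionary(),
                       embedder = hash_embedder(768),
                       threshold = 0.5, margin = 0) {
  stopifnot(length(anchors$active) >= 1, length(anchors$inactive) >= 1)
  structure(list(keywords = keywords, anchors = anchors, embedder = embedder,
                 threshold = threshold, margin = margin),
            class = "nlp_config")
}

#' Read keyword and sentence dictionaries from a YAML file
#'
#' The YAML file may define \code{keywords} (map of class to phrase list),
#' \code{anchors} (\code{active} / \code{inactive} sentence lists),
#' \code{threshold} and \code{margin}; missing entries fall back to the
#' package defaults.
#'
#' @param path YAML file path.
#' @param embedder embedding function (defaults to [hash_embedder()]).
#' @return an [nlp_config()] object.
#' @export
read_nlp_config <- function(path, embedder = hash_embedder(768)) {
  y <- yaml::read_yaml(path)
  kw <- if (!is.null(y$keywords)) lapply(y$keywords, unlist)
        else default_keyword_dictionary()
  an <- if (!is.null(y$anchors))
    list(active = unlist(y$anchors$active), inactive = unlist(y$anchors$inactive))
  else default_sentence_dictionary()
  nlp_config(keywords = kw, anchors = an, embedder = embedder,
             threshold = y$threshold %||% 0.5, margin = y$margin %||% 0)
}

split_sentences <- function(note) {
  s <- unlist(strsplit(note, "(?<=[.!?])\\s+", perl = TRUE))
  s <- trimws(s)
  s[nzchar(s)]
}

#' Extract keyword-bearing candidate sentences from a note
#'
#' Splits the note on terminal punctuation and returns every sentence that
#' contains (case-insensitively) a keyword phrase, paired with the therapy
#' class of the matched phrase. A sentence containing phrases of several
#' classes yields one pair per class.
#'
#' @param note free-text note.
#' @param dict keyword dictionary (class -> phrases).
#' @return data frame with columns \code{sentence}, \code{class}.
#' @export
extract_candidate_sentences <- function(note, dict = default_keyword_dictionary()) {
  sentences <- split_sentences(note)
  out <- list()
  for (s in sentences) {
    low <- tolower(s)
    for (cl in names(dict)) {
      if (any(vapply(dict[[cl]], function(p) grepl(p, low, fixed = TRUE),
                     logical(1))))
        out[[length(out) + 1L]] <- c(s, cl)
    }
  }
  if (!length(out))
    return(data.frame(sentence = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  data.frame(sentence = m[, 1], class = m[, 2], stringsAsFactors = FALSE)
}

cosine <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    stop("zero-norm embedding: cannot compute cosine similarity", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Classify a candidate sentence as active or inactive therapy
#'
#' Embeds the sentence and compares its cosine similarity to the nearest
#' active anchor against the nearest inactive anchor. The sentence is
#' \code{"active"} iff the active similarity exceeds the inactive one by
#' more than \code{margin} and reaches \code{threshold}; ties are resolved
#' conservatively as inactive.
#'
#' @param sentence a single sentence.
#' @param anchors sentence dictionary with \code{active}/\code{inactive}.
#' @param embedder deterministic embedding function.
#' @param threshold minimum active-anchor similarity (default 0.5).
#' @param margin required similarity gap (default 0).
#' @return \code{"active"} or \code{"inactive"}.
#' @export
classify_active <- function(sentence, anchors = default_sentence_dictionary(),
                            embedder = hash_embedder(768),
                            threshold = 0.5, margin = 0) {
  v <- embedder(sentence)
  if (sqrt(sum(v * v)) == 0)
    stop("zero-norm embedding for input sentence", call. = FALSE)
  sim_a <- max(vapply(anchors$active, function(a) cosine(v, embedder(a)),
                      numeric(1)))
  sim_i <- max(vapply(anchors$inactive, function(a) cosine(v, embedder(a)),
                      numeric(1)))
  if (sim_a - sim_i > margin && sim_a >= threshold) "active" else "inactive"
}

#' Per-patient psychotherapy status flags
#'
#' Scans a patient's notes for keyword-bearing sentences and classifies
#' each; a flag is set iff at least one sentence of the class is classified
#' active. CPT, PE and EMDR mentions set the trauma-focused flag; CBT
#' mentions set the CBT flag. Notes dated after \code{index_date} are
#' ignored (leakage control).
#'
#' @param notes list of \code{list(date, text)} (or bare strings).
#' @param dict keyword dictionary.
#' @param anchors sentence dictionary.
#' @param embedder embedding function.
#' @param threshold,margin decision parameters (see [classify_active()]).
#' @param index_date optional cutoff \code{Date}.
#' @return list with logical \code{cbt_active} and
#'   \code{trauma_focused_active}.
#' @export
patient_therapy_flags <- function(notes, dict = default_keyword_dictionary(),
                                  anchors = default_sentence_dictionary(),
                                  embedder = hash_embedder(768),
                                  threshold = 0.5, margin = 0,
                                  index_date = NULL) {
  cbt <- FALSE; tf <- FALSE
  for (n in notes) {
    if (is.character(n)) n <- list(date = NULL, text = n)
    if (!is.null(index_date) && !is.null(n$date) && n$date > index_date) next
    cand <- extract_candidate_sentences(n$text, dict)
    for (j in seq_len(nrow(cand))) {
      if (classify_active(cand$sentence[j], anchors, embedder,
                          threshold, margin) == "active") {
        if (cand$class[j] == "CBT") cbt <- TRUE else tf <- TRUE
      }
    }
  }
  list(cbt_active = cbt, trauma_focused_active = tf)
}
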