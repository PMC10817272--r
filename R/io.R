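# serialization of timelines and tables
#
# Timelines: JSON Lines, one patient per line with fields patient_id,
# birth_year, sex, race, zip5, encounters [{date, dx[], rx[],
# lab[{name,flag}]}], notes [{date, text}]. Dates as "YYYY-MM-DD". SDoH and
# drug-map tables: headered CSV.

timeline_to_list <- function(tl) {
  list(
    patient_id = tl$patient_id,
    birth_year = tl$birth_year,
    sex = tl$sex, race = tl$race, zip5 = tl$zip5,
    encounters = lapply(tl$encounters, function(e) list(
      date = format(e$date, "%Y-%m-%d"),
      dx = as.character(e$dx), rx = as.character(e$rx),
      lab = if (NROW(e$lab)) {
        lapply(seq_len(nrow(e$lab)), function(j)
          list(name = e$lab$name[j], flag = e$lab$flag[j]))
      } else list()
    )),
    notes = lapply(tl$notes, function(n) list(
      date = format(n$date, "%Y-%m-%d"), text = n$text))
  )
}

list_to_timeline <- function(x) {
  structure(list(
    patient_id = x$patient_id,
    birth_year = as.integer(x$birth_year),
    sex = x$sex, race = x$race, zip5 = x$zip5,
    encounters = lapply(x$encounters, function(e) list(
      date = as.Date(e$date),
      dx = as.character(unlist(e$dx)),
      rx = as.character(unlist(e$rx)),
      lab = if (length(e$lab)) {
        data.frame(
          name = vapply(e$lab, function(l) l$name, character(1)),
          flag = vapply(e$lab, function(l) l$flag, character(1)),
          stringsAsFactors = FALSE)
      } else data.frame(name = character(0), flag = character(0),
                        stringsAsFactors = FALSE)
    )),
    notes = lapply(x$notes, function(n) list(date = as.Date(n$date),
                                             text = n$text))
  ), class = "patient_timeline")
}

#' Write simulated cohort fixtures to disk
#'
#' Writes \code{timelines.jsonl} (one patient per line), \code{sdoh.csv},
#' \code{drug_map.csv} and \code{truth.csv} (generator ground truth, kept in
#' a separate file so that no modelling stage needs to touch it). All files
#' round-trip losslessly through [read_timelines()], [read_sdoh()] and
#' [read_drug_map()].
#'
#' @param sim an \code{ehr_sim} object from [generate_cohort()], or a bare
#'   list of \code{patient_timeline} objects (then only timelines are
#'   written).
#' @param path output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_fixtures <- function(sim, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path))
    stop(sprintf("cannot create output directory '%s'", path), call. = FALSE)
  timelines <- if (inherits(sim, "ehr_sim")) sim$timelines else sim
  tl_path <- file.path(path, "timelines.jsonl")
  con <- file(tl_path, open = "wb")  # binary mode: byte-exact unicode round trips
  on.exit(close(con), add = TRUE)
  for (tl in timelines) {
    json <- jsonlite::toJSON(timeline_to_list(tl), auto_unbox = TRUE,
                             null = "null")
    writeLines(json, con, useBytes = TRUE)
  }
  written <- tl_path
  if (inherits(sim, "ehr_sim")) {
    p1 <- file.path(path, "sdoh.csv")
    p2 <- file.path(path, "drug_map.csv")
    p3 <- file.path(path, "truth.csv")
    write.csv(sim$sdoh, p1, row.names = FALSE)
    write.csv(sim$drug_map, p2, row.names = FALSE)
    write.csv(sim$truth, p3, row.names = FALSE)
    written <- c(written, p1, p2, p3)
  }
  invisible(written)
}

#' Read patient timelines from a JSONL file
#' @param path path to a \code{timelines.jsonl} file.
#' @return list of \code{patient_timeline} objects.
#' @export
read_timelines <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l)
    list_to_timeline(jsonlite::fromJSON(l, simplifyVector = FALSE)))
}

#' Read a zip-level SDoH table from CSV
#' @param path CSV path with a \code{zip5} column plus one column per feature.
#' @return data frame with character \code{zip5}.
#' @export
read_sdoh <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(zip5 = "character"))
  if (!"zip5" %in% names(x)) stop("SDoH table must have a 'zip5' column", call. = FALSE)
  x
}

#' Read a medication-name to DrugBank-ID mapping table from CSV
#' @param path CSV path with columns \code{name}, \code{drugbank_id}.
#' @return data frame.
#' @export
read_drug_map <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "drugbank_id") %in% names(x)))
    stop("drug map must have columns 'name' and 'drugbank_id'", call. = FALSE)
  x
}
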