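## ETL from OMOP CDM v5 occurrence tables into per-patient event sequences.
## Time axis downstream is the event index; calendar dates only order events.

.OMOP_DEFAULTS <- list(
  condition = c(person_id = "person_id",
                concept_id = "condition_concept_id",
                event_date = "condition_start_date"),
  procedure = c(person_id = "person_id",
                concept_id = "procedure_concept_id",
                event_date = "procedure_date")
)

#' Read an OMOP occurrence table
#'
#' Reads a CSV export of an OMOP CDM v5 `condition_occurrence` or
#' `procedure_occurrence` table and returns one event record per usable row.
#' Rows with `concept_id = 0` (OMOP's "no matching concept") and rows whose
#' date does not parse are dropped and counted in a message.
#'
#' @param path path to the CSV file (header row, comma separated).
#' @param tableKind `"condition"` or `"procedure"`; selects the default OMOP
#'   column names (`condition_concept_id`/`condition_start_date` vs
#'   `procedure_concept_id`/`procedure_date`).
#' @param columnMap optional named character vector overriding any of the
#'   logical columns `person_id`, `concept_id`, `event_date` with the actual
#'   column names in the file.
#' @return data.frame with columns `person_id` (character), `concept_id`
#'   (integer), `event_date` (Date) and `domain` (the `tableKind`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("person_id,condition_concept_id,condition_start_date",
#'              "p1,4115276,2016-03-01", "p1,0,2016-03-02"), f)
#' readOccurrenceTable(f, "condition")  # one record; concept 0 dropped
#' @export
readOccurrenceTable <- function(path, tableKind = c("condition", "procedure"),
                                columnMap = NULL) {
  tableKind <- match.arg(tableKind)
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- .OMOP_DEFAULTS[[tableKind]]
  if (!is.null(columnMap)) {
    unknown <- setdiff(names(columnMap), names(cols))
    if (length(unknown))
      stop("columnMap names must be among: ", paste(names(cols), collapse = ", "))
    cols[names(columnMap)] <- unlist(columnMap)
  }
  dt <- data.table::fread(path, colClasses = "character", sep = ",",
                          header = TRUE, showProgress = FALSE)
  if (nrow(dt) == 0L) {
    warning("empty occurrence table: ", path)
    return(data.frame(person_id = character(), concept_id = integer(),
                      event_date = as.Date(character()),
                      domain = character(), stringsAsFactors = FALSE))
  }
  missing_cols <- setdiff(unname(cols), names(dt))
  if (length(missing_cols))
    stop("required column(s) not found in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "))
  rec <- data.frame(
    person_id = as.character(dt[[cols["person_id"]]]),
    concept_id = suppressWarnings(as.integer(dt[[cols["concept_id"]]])),
    event_date = as.Date(dt[[cols["event_date"]]], format = "%Y-%m-%d"),
    domain = tableKind,
    stringsAsFactors = FALSE
  )
  n0 <- sum(rec$concept_id == 0L, na.rm = TRUE) + sum(is.na(rec$concept_id))
  nd <- sum(is.na(rec$event_date) & !is.na(rec$concept_id) & rec$concept_id != 0L)
  keep <- !is.na(rec$concept_id) & rec$concept_id != 0L & !is.na(rec$event_date)
  if (n0 + nd > 0)
    message(sprintf("%s: dropped %d unmapped-concept and %d unparseable-date rows",
                    basename(path), n0, nd))
  rec[keep, , drop = FALSE]
}

#' Build per-patient event sequences from occurrence records
#'
#' Groups records by patient, orders events by `(event_date, concept_id)`
#' (the concept-id tie-break makes same-day ordering deterministic), attaches
#' the START/STOP sentinels, and assembles the vocabulary from all distinct
#' concept ids plus the sentinels. The result is permutation-invariant in the
#' input row order.
#'
#' @param records data.frame as returned by [readOccurrenceTable()] (several
#'   tables may be row-bound first); must be non-empty.
#' @param dedupe drop duplicate (person, concept, date) records before
#'   sequencing (default FALSE: duplicates are retained and learners decide
#'   how to treat repeats).
#' @param provenance free-text source tag stored on the dataset.
#' @return A [SequenceDataset-class].
#' @export
buildSequences <- function(records, dedupe = FALSE, provenance = "omop_etl") {
  if (is.null(records) || nrow(records) == 0L)
    stop("records must be non-empty")
  if (dedupe)
    records <- records[!duplicated(records[, c("person_id", "concept_id",
                                               "event_date")]), , drop = FALSE]
  ord <- order(records$person_id, records$event_date, records$concept_id)
  records <- records[ord, , drop = FALSE]
  by_person <- split(seq_len(nrow(records)), records$person_id)
  pids <- names(by_person)  # sorted by person_id
  seqs <- vector("list", length(pids))
  dates <- vector("list", length(pids))
  for (k in seq_along(pids)) {
    idx <- by_person[[k]]
    seqs[[k]] <- c(START_ID, records$concept_id[idx], STOP_ID)
    dates[[k]] <- c(as.Date(NA), records$event_date[idx], as.Date(NA))
  }
  dom <- records$domain
  if (is.null(dom)) dom <- rep("condition", nrow(records))
  vocab_ids <- !duplicated(records$concept_id)
  voc <- rbind(
    .SENTINELS(),
    data.frame(concept_id = records$concept_id[vocab_ids],
               label = paste0("concept_", records$concept_id[vocab_ids]),
               domain = dom[vocab_ids], stringsAsFactors = FALSE)
  )
  voc <- voc[order(voc$concept_id), , drop = FALSE]
  rownames(voc) <- NULL
  new("SequenceDataset", sequences = seqs, personIds = pids, dates = dates,
      vocabulary = voc, provenance = provenance)
}

#' Subsample a dataset of patient sequences
#'
#' Draws a uniform random sample of `n` sequences without replacement and
#' recomputes the vocabulary from the retained sequences (plus sentinels).
#' Deterministic for a fixed `seed`.
#'
#' @param dataset a [SequenceDataset-class].
#' @param n number of sequences to keep (`n <= nSequences(dataset)`).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return A [SequenceDataset-class] with `n` sequences.
#' @export
subsampleDataset <- function(dataset, n, seed = NULL) {
  N <- length(dataset@sequences)
  if (n > N) stop("cannot subsample ", n, " from ", N, " sequences")
  if (n < 1L) stop("n must be >= 1")
  keep <- sort(.withSeed(seed, sample.int(N, n)))
  seqs <- dataset@sequences[keep]
  ids <- unique(unlist(seqs, use.names = FALSE))
  voc <- dataset@vocabulary
  voc <- voc[voc$concept_id %in% c(ids, START_ID, STOP_ID), , drop = FALSE]
  rownames(voc) <- NULL
  new("SequenceDataset",
      sequences = seqs,
      personIds = dataset@personIds[keep],
      dates = if (length(dataset@dates)) dataset@dates[keep] else list(),
      vocabulary = voc,
      provenance = sprintf("%s; subsample n=%d", dataset@provenance, n))
}

#' Attach human-readable concept labels from a vocabulary export
#'
#' Maps concept ids back to free-text names using an Athena-style vocabulary
#' file with columns `concept_id` and `concept_name` (tab- or comma-separated,
#' auto-detected). Ids not found keep the fallback label `concept_<id>` (with
#' a warning); the sentinels always keep "START"/"STOP".
#'
#' @param dataset a [SequenceDataset-class].
#' @param vocabularyPath path to the concept vocabulary file.
#' @return The dataset with labels attached.
#' @export
mapConceptLabels <- function(dataset, vocabularyPath) {
  if (!file.exists(vocabularyPath)) stop("file not found: ", vocabularyPath)
  dt <- data.table::fread(vocabularyPath, colClasses = "character",
                          header = TRUE, showProgress = FALSE)
  if (!all(c("concept_id", "concept_name") %in% names(dt)))
    stop("vocabulary file must have columns concept_id, concept_name")
  voc <- dataset@vocabulary
  lookup <- stats::setNames(as.character(dt$concept_name),
                            as.character(dt$concept_id))
  nonsent <- voc$domain != "sentinel"
  found <- as.character(voc$concept_id[nonsent]) %in% names(lookup)
  voc$label[nonsent][found] <-
    unname(lookup[as.character(voc$concept_id[nonsent][found])])
  voc$label[nonsent][!found] <-
    paste0("concept_", voc$concept_id[nonsent][!found])
  if (any(!found))
    warning(sum(!found), " concept id(s) not in vocabulary file; ",
            "fallback labels used")
  dataset@vocabulary <- voc
  dataset
}

#' Write/read the intermediate sequence file
#'
#' The canonical exchange format between the ETL and the learners: one line
#' per patient, `person_id TAB comma-separated concept ids` (sentinels
#' included). Calendar dates and labels are not part of the format; reading
#' reconstructs default labels.
#'
#' @param dataset a [SequenceDataset-class].
#' @param path output (input) file path.
#' @return `writeSequences` returns `path` invisibly; `readSequences` returns
#'   a [SequenceDataset-class].
#' @export
writeSequences <- function(dataset, path) {
  lines <- vapply(seq_along(dataset@sequences), function(k) {
    paste0(dataset@personIds[k], "\t",
           paste(dataset@sequences[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSequences
#' @export
readSequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty sequence file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pids <- vapply(parts, `[[`, character(1), 1L)
  seqs <- lapply(parts, function(p)
    as.integer(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]]))
  ids <- sort(unique(unlist(seqs, use.names = FALSE)))
  ids <- setdiff(ids, c(START_ID, STOP_ID))
  voc <- rbind(.SENTINELS(),
               data.frame(concept_id = ids, label = paste0("concept_", ids),
                          domain = "condition", stringsAsFactors = FALSE))
  voc <- voc[order(voc$concept_id), , drop = FALSE]
  rownames(voc) <- NULL
  new("SequenceDataset", sequences = seqs, personIds = pids, dates = list(),
      vocabulary = voc, provenance = paste0("file:", path))
}
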