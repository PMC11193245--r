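# ETL from OMOP occurrence CSVs into sentinel-framed event sequences

writeCsv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("occurrence reader parses OMOP defaults and filters bad rows", {
  f <- writeCsv(c("person_id,condition_concept_id,condition_start_date",
                  "p1,4115276,2016-03-01",
                  "p1,0,2016-03-02"))
  rec <- suppressMessages(readOccurrenceTable(f, "condition"))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$concept_id, 4115276L)
  expect_s3_class(rec$event_date, "Date")

  f3 <- writeCsv(c("person_id,condition_concept_id,condition_start_date",
                   "p1,101,2016-03-01", "p1,102,2016-03-05",
                   "p2,101,2017-01-01"))
  expect_equal(nrow(readOccurrenceTable(f3, "condition")), 3L)

  fp <- writeCsv(c("person_id,procedure_concept_id,procedure_date",
                   "p1,201,2016-06-01"))
  recp <- readOccurrenceTable(fp, "procedure")
  expect_equal(recp$domain, "procedure")

  fbad <- writeCsv(c("person_id,condition_concept_id,condition_start_date",
                     "p1,101,not-a-date", "p1,102,2016-01-01"))
  expect_equal(nrow(suppressMessages(readOccurrenceTable(fbad, "condition"))),
               1L)
})

test_that("missing columns and empty files are reported", {
  f <- writeCsv(c("person_id,concept,start", "p1,1,2016-01-01"))
  expect_error(readOccurrenceTable(f, "condition"), "condition_concept_id")
  expect_error(readOccurrenceTable(tempfile(), "condition"), "not found")
  fe <- writeCsv("person_id,condition_concept_id,condition_start_date")
  expect_warning(rec <- readOccurrenceTable(fe, "condition"), "empty")
  expect_equal(nrow(rec), 0L)
})

test_that("columnMap overrides default OMOP names", {
  f <- writeCsv(c("pid,code,when", "p1,55,2019-05-05"))
  rec <- readOccurrenceTable(f, "condition",
                             columnMap = c(person_id = "pid",
                                           concept_id = "code",
                                           event_date = "when"))
  expect_equal(rec$concept_id, 55L)
})

recordsDf <- function(pid, cid, dt) {
  data.frame(person_id = pid, concept_id = as.integer(cid),
             event_date = as.Date(dt), domain = "condition",
             stringsAsFactors = FALSE)
}

test_that("sequences are ordered by date with concept-id tie-break and framed", {
  rec <- recordsDf(c("p1", "p1"), c(10, 20), c("2016-01-01", "2016-01-02"))
  ds <- buildSequences(rec)
  expect_equal(sequences(ds)[[1]], c(START_ID, 10L, 20L, STOP_ID))

  rec2 <- recordsDf(c("p1", "p1"), c(20, 10), c("2016-01-01", "2016-01-01"))
  ds2 <- buildSequences(rec2)
  expect_equal(sequences(ds2)[[1]], c(START_ID, 10L, 20L, STOP_ID))

  rec3 <- recordsDf(c("p1", "p1", "p1", "p2", "p2"), c(1, 2, 3, 1, 2),
                    c("2016-01-01", "2016-01-02", "2016-01-03",
                      "2016-01-01", "2016-01-02"))
  ds3 <- buildSequences(rec3)
  expect_equal(nSequences(ds3), 2L)
  expect_equal(meanSequenceLength(ds3), 4.5)
})

test_that("sequence building is permutation-invariant and length-conserving", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    rec <- recordsDf(paste0("p", sample.int(8, n, replace = TRUE)),
                     sample.int(5, n, replace = TRUE),
                     as.character(as.Date("2016-01-01") +
                                    sample.int(30, n, replace = TRUE)))
    ds <- buildSequences(rec)
    shuf <- rec[sample.int(n), ]
    expect_identical(sequences(buildSequences(shuf)), sequences(ds))
    expect_equal(sum(lengths(sequences(ds))), n + 2 * nSequences(ds))
    expect_true(all(vapply(sequences(ds), function(s)
      s[1] == START_ID && s[length(s)] == STOP_ID, logical(1))))
  }
})

test_that("subsampling is uniform-without-replacement and deterministic", {
  ds <- makeDataset(replicate(20, sample.int(4, 3, replace = TRUE),
                              simplify = FALSE))
  expect_identical(sequences(subsampleDataset(ds, 20, seed = 1)),
                   sequences(ds))
  expect_equal(nSequences(subsampleDataset(ds, 1, seed = 3)), 1L)
  s1 <- subsampleDataset(ds, 7, seed = 5)
  s2 <- subsampleDataset(ds, 7, seed = 5)
  expect_identical(personIds(s1), personIds(s2))
  expect_error(subsampleDataset(ds, 21), "cannot subsample")
  # vocabulary recomputed from retained sequences
  expect_true(all(unlist(sequences(s1)) %in% vocabulary(s1)$concept_id))
})

test_that("label mapping uses the vocabulary file with stated fallbacks", {
  ds <- makeDataset(list(c(4115276L, 7L)))
  vf <- writeCsv(c("concept_id,concept_name",
                   "4115276,Chronic obstructive lung disease"))
  ds2 <- suppressWarnings(mapConceptLabels(ds, vf))
  voc <- vocabulary(ds2)
  expect_equal(voc$label[voc$concept_id == 4115276],
               "Chronic obstructive lung disease")
  expect_equal(voc$label[voc$concept_id == 7], "concept_7")
  expect_equal(voc$label[voc$concept_id == START_ID], "START")
  bad <- writeCsv(c("id,name", "1,x"))
  expect_error(mapConceptLabels(ds, bad), "concept_id")
})

test_that("the intermediate sequence file round-trips exactly", {
  ds <- makeDataset(list(c(3L, 1L, 2L), c(2L, 2L), 5L))
  f <- tempfile()
  writeSequences(ds, f)
  ds2 <- readSequences(f)
  expect_identical(sequences(ds2), sequences(ds))
  expect_identical(personIds(ds2), personIds(ds))
  f2 <- tempfile()
  writeSequences(ds2, f2)
  expect_identical(readLines(f), readLines(f2))
})
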