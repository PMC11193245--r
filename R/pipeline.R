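## End-to-end experiment: ETL (or synthetic cohort) -> subsampling ladder ->
## learners -> Synthea modules -> complexity/overlap reports with runtimes.

#' Configuration for a full experiment run
#'
#' @param input either a `"synthetic"` flag with `generator` set, or a named
#'   list of paths `list(condition = ..., procedure = ..., vocabulary = ...)`
#'   (vocabulary optional) pointing at OMOP CSV exports.
#' @param generator a [generatorConfig()] used when `input = "synthetic"`.
#' @param sizes descending integer vector of subsample sizes (the first entry
#'   may equal the full cohort size).
#' @param learners subset of `c("markov", "tarm", "dynotears")`.
#' @param hyper named list of per-learner hyperparameter lists, e.g.
#'   `list(tarm = list(minSeqSup = 0.1, minSeqConf = 0.5))`.
#' @param outDir output directory for all artifacts.
#' @param seed integer seed; drives subsampling (and nothing else: the
#'   learners are deterministic).
#' @param nested draw each smaller subsample from the next larger one
#'   (default TRUE) so graph-growth comparisons are not confounded by
#'   resampling noise; FALSE draws every size independently from the full
#'   dataset.
#' @return A validated list of class `"ExperimentConfig"`.
#' @export
experimentConfig <- function(input = "synthetic",
                             generator = generatorConfig(),
                             sizes = NULL,
                             learners = c("markov", "tarm", "dynotears"),
                             hyper = list(),
                             outDir = tempfile("synthgraph_experiment_"),
                             seed = 1L,
                             nested = TRUE) {
  learners <- match.arg(learners, c("markov", "tarm", "dynotears"),
                        several.ok = TRUE)
  if (!length(learners)) stop("learner set must be non-empty")
  if (!is.null(sizes)) {
    sizes <- as.integer(sizes)
    if (any(diff(sizes) > 0)) sizes <- sort(sizes, decreasing = TRUE)
  }
  structure(list(input = input, generator = generator, sizes = sizes,
                 learners = learners, hyper = hyper, outDir = outDir,
                 seed = as.integer(seed), nested = nested),
            class = "ExperimentConfig")
}

.fitLearner <- function(learner, dataset, hyper, tag) {
  h <- hyper[[learner]] %||% list()
  switch(learner,
    markov = {
      model <- fitMarkov(dataset)
      markovToRules(model, minProb = h$minProb %||% 0, datasetTag = tag)
    },
    tarm = mineTemporalRules(dataset,
                             minSeqSup = h$minSeqSup %||% 0.1,
                             minSeqConf = h$minSeqConf %||% 0.5,
                             datasetTag = tag),
    dynotears = {
      dm <- encodeBinaryPanel(dataset, topK = h$topK %||% 100,
                              p = h$p %||% 1L)
      model <- fitDynotears(dm,
                            lambdaW = h$lambdaW %||% 0.02,
                            lambdaA = h$lambdaA %||% 0.02)
      g <- svarToRules(model, threshold = h$threshold %||% 0.3,
                       datasetTag = tag)
      g
    },
    stop("unknown learner: ", learner))
}

#' Run the full experiment
#'
#' For each (learner, dataset size) cell: fits the learner with wall-clock
#' timing, writes the rule graph TSV and the mapped Synthea module JSON, and
#' records the six complexity measures. Afterwards the pairwise edge-overlap
#' matrix over all learner-by-size graphs is written. A failing cell is
#' recorded in the manifest and the remaining cells still run; the exit
#' manifest marks overall success. All artifacts land under
#' `config$outDir`.
#'
#' @param config an [experimentConfig()].
#' @return Invisibly, a list with `complexity` (data.frame, one row per cell
#'   incl. `fit_seconds`), `overlap` (matrix), `graphs` (named list of
#'   [RuleGraph-class]), and `manifest`.
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "ExperimentConfig"))
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (identical(config$input, "synthetic")) {
    cohort <- generateCohort(config$generator,
                             outDir = file.path(outDir, "input"))
    dataset <- cohort$dataset
  } else {
    recs <- list()
    if (!is.null(config$input$condition))
      recs$cond <- readOccurrenceTable(config$input$condition, "condition")
    if (!is.null(config$input$procedure))
      recs$proc <- readOccurrenceTable(config$input$procedure, "procedure")
    dataset <- buildSequences(do.call(rbind, recs))
    if (!is.null(config$input$vocabulary))
      dataset <- mapConceptLabels(dataset, config$input$vocabulary)
  }
  N <- nSequences(dataset)
  sizes <- config$sizes %||% N
  if (any(sizes > N)) stop("subsample sizes must be <= ", N)
  sizes <- sort(unique(as.integer(sizes)), decreasing = TRUE)
  datasets <- list()
  cur <- dataset
  for (i in seq_along(sizes)) {
    src <- if (config$nested) cur else dataset
    cur <- if (sizes[i] == nSequences(src)) src else
      subsampleDataset(src, sizes[i], seed = config$seed + i)
    datasets[[as.character(sizes[i])]] <- cur
  }
  graphs <- list()
  rows <- list()
  manifest <- list()
  for (sz in names(datasets)) {
    for (learner in config$learners) {
      tag <- sprintf("%s_n%s", learner, sz)
      cell <- list(learner = learner, size = as.integer(sz), status = "ok",
                   artifacts = character(0))
      t0 <- proc.time()["elapsed"]
      g <- tryCatch(
        .fitLearner(learner, datasets[[sz]], config$hyper, tag),
        error = function(e) e)
      secs <- unname(proc.time()["elapsed"] - t0)
      if (inherits(g, "error")) {
        cell$status <- "failed"
        cell$error <- conditionMessage(g)
        warning("cell ", tag, " failed: ", cell$error)
      } else {
        graphs[[tag]] <- g
        rules_path <- file.path(outDir, paste0(tag, "_rules.tsv"))
        writeRuleTable(g, rules_path)
        cell$artifacts <- rules_path
        mod <- tryCatch(rulesToModule(g, moduleName = tag),
                        error = function(e) e)
        if (inherits(mod, "error")) {
          cell$module_error <- conditionMessage(mod)
        } else {
          mod_path <- file.path(outDir, paste0(tag, "_module.json"))
          writeSyntheaModule(mod, mod_path)
          cell$artifacts <- c(cell$artifacts, mod_path)
        }
        rows[[tag]] <- cbind(
          data.frame(learner = learner, size = as.integer(sz),
                     stringsAsFactors = FALSE),
          graphComplexity(g),
          data.frame(fit_seconds = secs))
      }
      manifest[[tag]] <- cell
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(report)) {
    rownames(report) <- NULL
    data.table::fwrite(report, file.path(outDir, "complexity_report.tsv"),
                       sep = "\t")
  }
  ov <- NULL
  if (length(graphs)) {
    ov <- overlapMatrix(graphs)
    data.table::fwrite(data.frame(graph = rownames(ov), ov,
                                  check.names = FALSE),
                       file.path(outDir, "overlap_matrix.tsv"), sep = "\t")
  }
  ok <- all(vapply(manifest, function(x) x$status == "ok", logical(1)))
  manifest_doc <- list(success = ok, seed = config$seed,
                       n_sequences = N, sizes = as.integer(names(datasets)),
                       learners = config$learners, cells = manifest)
  jsonlite::write_json(manifest_doc, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(complexity = report, overlap = ov, graphs = graphs,
                 manifest = manifest_doc))
}
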