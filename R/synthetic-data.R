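## Synthetic fixtures with known ground truth: (a) patient cohorts sampled
## from a generated transition-graph module, optionally contaminated with a
## ubiquitous "blood-sampling-like" confounder event and written back out as
## OMOP-style CSVs so the full ETL path is exercised; (b) stable SVAR
## processes for DYNOTEARS recovery benchmarks.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the shape (not the semantics) of a mid-sized registry
#' extract: 5000 patients, 135 distinct medical observations, mean sequence
#' length 5.5 including the START/STOP sentinels. `confounderRate` is the
#' probability of inserting a ubiquitous confounder event (emulating
#' disease-independent observations such as blood sampling) after any
#' clinical event; the default 0 leaves walk lengths at the target.
#'
#' @param nPatients number of patients.
#' @param vocabSize number of distinct non-sentinel concepts.
#' @param meanLength target mean sequence length including sentinels (>= 2).
#' @param seed integer seed driving all generator randomness.
#' @param confounderRate probability in \[0, 1\].
#' @return A validated configuration list of class `"GeneratorConfig"`.
#' @export
generatorConfig <- function(nPatients = 5000L, vocabSize = 135L,
                            meanLength = 5.5, seed = 1L,
                            confounderRate = 0) {
  stopifnot(nPatients >= 1, vocabSize >= 2, meanLength >= 2,
            confounderRate >= 0, confounderRate <= 1)
  structure(list(nPatients = as.integer(nPatients),
                 vocabSize = as.integer(vocabSize),
                 meanLength = meanLength, seed = as.integer(seed),
                 confounderRate = confounderRate),
            class = "GeneratorConfig")
}

.CONFOUNDER_ID <- 999999L

#' Generate a random ground-truth Synthea module
#'
#' Builds a layered DAG of Encounter states with random distributed
#' transitions whose expected walk length matches `meanLength`: from each
#' layer the walk is absorbed into Terminal with a constant probability
#' solved so that the expected number of emitted events equals
#' `meanLength - 2` (clamped below at 1, since every walk emits at least one
#' event). Deterministic for a fixed seed; the output always validates.
#'
#' @param config a [generatorConfig()].
#' @return A [SyntheaModule-class]. Concept ids are synthetic (`1000 + k`)
#'   with synthetic labels.
#' @export
randomGroundTruth <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  E <- max(config$meanLength - 2, 1)
  if (E >= config$vocabSize)
    stop("infeasible meanLength for vocabSize: expected events (",
         E, ") must be below the number of layers (<= vocabSize)")
  L <- min(config$vocabSize, max(ceiling(E) + 2L, 2L))
  ## absorption probability q: E[events] = (1 - (1-q)^L) / q = E
  q <- if (E <= 1) 1 else
    stats::uniroot(function(qq) (1 - (1 - qq)^L) / qq - E,
                   c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  .withSeed(config$seed, {
    ids <- 1000L + seq_len(config$vocabSize)
    labels <- sprintf("synthetic observation %d", ids)
    layer <- rep(seq_len(L), length.out = config$vocabSize)
    layer <- sample(layer)                      # shuffle assignment
    states <- list()
    layer_ids <- split(ids, layer)
    rand_dist <- function(k) {
      w <- stats::runif(k, 0.2, 1)
      w / sum(w)
    }
    name_of <- stats::setNames(sprintf("synthetic observation %d", ids),
                               ids)
    states[["Initial"]] <- list(
      type = "Initial",
      distributed_transition = .distTransition(
        unname(name_of[as.character(layer_ids[[1L]])]),
        rand_dist(length(layer_ids[[1L]]))))
    for (li in seq_len(L)) {
      for (cid in layer_ids[[li]]) {
        if (li == L) {
          dt <- list(list(distribution = 1, transition = "Terminal"))
        } else {
          nxt <- layer_ids[[li + 1L]]
          w <- rand_dist(length(nxt)) * (1 - q)
          dt <- .distTransition(c(unname(name_of[as.character(nxt)]),
                                  "Terminal"),
                                c(w, q))
        }
        states[[name_of[[as.character(cid)]]]] <- list(
          type = "Encounter",
          encounter_class = "ambulatory",
          codes = list(list(system = "SNOMED-CT", code = as.character(cid),
                            display = name_of[[as.character(cid)]])),
          distributed_transition = dt)
      }
    }
    states[["Terminal"]] <- list(type = "Terminal")
    new("SyntheaModule", name = "synthetic_ground_truth", states = states)
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Samples `nPatients` walks from a [randomGroundTruth()] module, optionally
#' inserts the ubiquitous confounder event after each clinical event with
#' probability `confounderRate`, and synthesizes calendar dates (a random
#' start date plus day increments; about 10% of steps share the previous
#' event's date, only where the ETL's (date, concept id) tie-break preserves
#' the walk order). When `outDir` is given the cohort is also written out as
#' OMOP-style `condition_occurrence.csv` / `procedure_occurrence.csv` plus a
#' `vocabulary.csv`, so the full ETL path can be exercised and must
#' reproduce the returned dataset exactly.
#'
#' @param config a [generatorConfig()].
#' @param outDir optional directory for the OMOP-style CSV export.
#' @return A list with elements `dataset` (a [SequenceDataset-class]),
#'   `module` (the ground truth [SyntheaModule-class]) and, when `outDir` is
#'   given, `paths` (named character vector of the written files).
#' @export
generateCohort <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "GeneratorConfig"))
  module <- randomGroundTruth(config)
  ds <- sampleModule(module, config$nPatients, seed = config$seed + 1L)
  voc <- ds@vocabulary
  seqs <- ds@sequences
  .withSeed(config$seed + 2L, {
    if (config$confounderRate > 0) {
      seqs <- lapply(seqs, function(s) {
        body <- s[-c(1L, length(s))]
        if (!length(body)) return(s)
        out <- integer(0)
        for (ev in body) {
          out <- c(out, ev)
          if (stats::runif(1) < config$confounderRate)
            out <- c(out, .CONFOUNDER_ID)
        }
        c(START_ID, out, STOP_ID)
      })
      voc <- rbind(voc, data.frame(
        concept_id = .CONFOUNDER_ID,
        label = "blood sampling (synthetic confounder)",
        domain = "procedure", stringsAsFactors = FALSE))
      voc <- voc[order(voc$concept_id), , drop = FALSE]
      rownames(voc) <- NULL
    }
    ## synthetic domains: even ids are conditions, odd ids procedures
    nonsent <- voc$domain != "sentinel"
    voc$domain[nonsent] <- ifelse(voc$concept_id[nonsent] %% 2L == 0L,
                                  "condition", "procedure")
    voc$domain[voc$concept_id == .CONFOUNDER_ID] <- "procedure"
    ## dates: non-decreasing; a same-day tie is only allowed when the next
    ## concept id is larger, so the ETL sort reproduces the walk order
    dates <- lapply(seqs, function(s) {
      body <- s[-c(1L, length(s))]
      d0 <- as.Date("2015-01-01") + sample.int(2000L, 1L)
      dd <- d0
      if (length(body) > 1L) {
        for (k in 2:length(body)) {
          tie <- stats::runif(1) < 0.1 && body[k] > body[k - 1L]
          dd <- c(dd, dd[k - 1L] + if (tie) 0L else sample.int(30L, 1L))
        }
      }
      c(as.Date(NA), dd, as.Date(NA))
    })
    dataset <- new("SequenceDataset", sequences = seqs,
                   personIds = ds@personIds, dates = dates,
                   vocabulary = voc,
                   provenance = sprintf(
                     "synthetic cohort (n=%d, D=%d, confounder=%.2f, seed=%d)",
                     config$nPatients, config$vocabSize,
                     config$confounderRate, config$seed))
    out <- list(dataset = dataset, module = module)
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      out$paths <- .writeOmopCsvs(dataset, outDir)
      mp <- file.path(outDir, "ground_truth_module.json")
      writeSyntheaModule(module, mp)
      out$paths <- c(out$paths, module = mp)
    }
    out
  })
}

## flatten a dataset into OMOP-style occurrence CSVs split by domain
.writeOmopCsvs <- function(dataset, outDir) {
  voc <- dataset@vocabulary
  dom <- stats::setNames(voc$domain, voc$concept_id)
  rows <- lapply(seq_along(dataset@sequences), function(k) {
    s <- dataset@sequences[[k]]
    body <- seq_along(s)[-c(1L, length(s))]
    if (!length(body)) return(NULL)
    data.frame(person_id = dataset@personIds[k],
               concept_id = s[body],
               event_date = dataset@dates[[k]][body],
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  cond <- rec[dom[as.character(rec$concept_id)] == "condition", , drop = FALSE]
  proc <- rec[dom[as.character(rec$concept_id)] == "procedure", , drop = FALSE]
  cpath <- file.path(outDir, "condition_occurrence.csv")
  ppath <- file.path(outDir, "procedure_occurrence.csv")
  vpath <- file.path(outDir, "vocabulary.csv")
  data.table::fwrite(data.frame(person_id = cond$person_id,
                                condition_concept_id = cond$concept_id,
                                condition_start_date = cond$event_date),
                     cpath)
  data.table::fwrite(data.frame(person_id = proc$person_id,
                                procedure_concept_id = proc$concept_id,
                                procedure_date = proc$event_date),
                     ppath)
  nonsent <- voc$domain != "sentinel"
  data.table::fwrite(data.frame(concept_id = voc$concept_id[nonsent],
                                concept_name = voc$label[nonsent]),
                     vpath)
  c(condition = cpath, procedure = ppath, vocabulary = vpath)
}

#' Simulate a stable SVAR process with known structure
#'
#' Draws an acyclic intra-slice matrix `W` (random DAG via a permuted
#' upper-triangular support) and a lagged matrix `A`, each entry present with
#' probability `edgeProb` and magnitude uniform in `coefRange` with random
#' sign; the draw is rejected unless the implied reduced-form VAR is stable
#' (companion-matrix spectral radius < 1). The panel is generated as
#' `x_t = (I - W')^{-1} (sum_k A_k' x_{t-k} + eps_t)` with Gaussian noise,
#' after a burn-in of 100 steps.
#'
#' @param d number of coordinates.
#' @param p lag order (default 1).
#' @param edgeProb edge probability (default 0.3).
#' @param coefRange magnitude range, default `c(0.5, 1.0)`.
#' @param noiseSd Gaussian noise standard deviation (default 0.1).
#' @param M number of usable (x_t, lags) rows (default 2000).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @param maxTries rejection-sampling cap (default 1000; exceeding it is an
#'   error).
#' @return A list with `panel` (a [DesignMatrices-class]) and `truth` (an
#'   [SVARModel-class] holding the generating `W` and `A`).
#' @export
simulateSVAR <- function(d, p = 1L, edgeProb = 0.3, coefRange = c(0.5, 1.0),
                         noiseSd = 0.1, M = 2000L, seed = NULL,
                         maxTries = 1000L) {
  p <- as.integer(p)
  stopifnot(d >= 2, p >= 1, edgeProb >= 0, edgeProb <= 1, noiseSd > 0)
  .withSeed(seed, {
    draw <- NULL
    for (try in seq_len(maxTries)) {
      perm <- sample.int(d)
      W <- matrix(0, d, d)
      for (i in seq_len(d - 1L)) {
        for (j in (i + 1L):d) {
          if (stats::runif(1) < edgeProb) {
            W[perm[i], perm[j]] <- sample(c(-1, 1), 1) *
              stats::runif(1, coefRange[1], coefRange[2])
          }
        }
      }
      A <- matrix(0, d * p, d)
      nz <- stats::runif(d * p * d) < edgeProb
      A[nz] <- sample(c(-1, 1), sum(nz), replace = TRUE) *
        stats::runif(sum(nz), coefRange[1], coefRange[2])
      ## reduced-form lag matrices B_k = (I - W')^{-1} A_k'
      Binv <- solve(diag(d) - t(W))
      Bs <- lapply(seq_len(p), function(k)
        Binv %*% t(A[(k - 1L) * d + seq_len(d), , drop = FALSE]))
      comp <- matrix(0, d * p, d * p)
      comp[seq_len(d), ] <- do.call(cbind, Bs)
      if (p > 1L)
        comp[d + seq_len(d * (p - 1L)), seq_len(d * (p - 1L))] <-
          diag(d * (p - 1L))
      sr <- max(Mod(eigen(comp, only.values = TRUE)$values))
      if (sr < 1 && hAcyclicity(W) < 1e-10) {
        draw <- list(W = W, A = A, Binv = Binv, Bs = Bs)
        break
      }
    }
    if (is.null(draw))
      stop("no stable acyclic SVAR found after ", maxTries, " draws")
    burn <- 100L
    Tt <- M + p + burn
    xs <- matrix(0, Tt, d)
    for (t in (p + 1L):Tt) {
      lagpart <- numeric(d)
      for (k in seq_len(p)) lagpart <- lagpart + draw$Bs[[k]] %*% xs[t - k, ]
      xs[t, ] <- lagpart + draw$Binv %*% stats::rnorm(d, sd = noiseSd)
    }
    rows <- (burn + p + 1L):Tt
    X <- xs[rows, , drop = FALSE]
    Y <- do.call(cbind, lapply(seq_len(p), function(k)
      xs[rows - k, , drop = FALSE]))
    concepts <- seq_len(d)
    labels <- sprintf("x%d", concepts)
    panel <- new("DesignMatrices", X = X, Y = Y, p = p,
                 concepts = as.integer(concepts), labels = labels)
    truth <- new("SVARModel", W = draw$W, A = draw$A, p = p,
                 concepts = as.integer(concepts), labels = labels,
                 lambdaW = NA_real_, lambdaA = NA_real_, threshold = 0,
                 converged = TRUE, h = hAcyclicity(draw$W),
                 trace = data.frame())
    list(panel = panel, truth = truth)
  })
}
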