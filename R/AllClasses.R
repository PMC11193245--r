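## Central S4 data containers. Validity methods enforce the structural
## invariants every downstream learner relies on (sentinel framing, vocabulary
## closure, row-stochasticity, edge/endpoint consistency).

#' SequenceDataset: per-patient ordered discrete event sequences
#'
#' The canonical container for extracted patient histories: one integer vector
#' of OMOP concept ids per patient, framed by the [START_ID]/[STOP_ID]
#' sentinels, together with the concept vocabulary the sequences draw from.
#' Event time is the position in the sequence (event index), not calendar
#' time; the original event dates are retained alongside for provenance.
#'
#' @slot sequences list of integer vectors; each begins with `START_ID` and
#'   ends with `STOP_ID` and has length >= 2.
#' @slot personIds character vector of patient identifiers, parallel to
#'   `sequences`.
#' @slot dates list of `Date` vectors parallel to `sequences` (NA at sentinel
#'   positions), or an empty list when no calendar dates exist (e.g. sequences
#'   sampled from a module).
#' @slot vocabulary data.frame with columns `concept_id`, `label`, `domain`;
#'   closed over every concept id appearing in any sequence.
#' @slot provenance free-text description of where the data came from.
#'
#' @seealso [buildSequences()], [subsampleDataset()], [sampleModule()]
#' @export
setClass("SequenceDataset",
  representation(
    sequences = "list",
    personIds = "character",
    dates = "list",
    vocabulary = "data.frame",
    provenance = "character"
  )
)

setValidity("SequenceDataset", function(object) {
  seqs <- object@sequences
  if (length(seqs) < 1L) return("dataset must contain at least one sequence")
  if (length(object@personIds) != length(seqs))
    return("personIds and sequences lengths differ")
  if (length(object@dates) > 0L && length(object@dates) != length(seqs))
    return("dates, when present, must parallel sequences")
  voc <- object@vocabulary
  need <- c("concept_id", "label", "domain")
  if (!all(need %in% names(voc)))
    return("vocabulary must have columns concept_id, label, domain")
  if (anyDuplicated(voc$concept_id))
    return("vocabulary concept_id values must be unique")
  for (s in seqs) {
    if (!is.integer(s) || length(s) < 2L)
      return("each sequence must be an integer vector of length >= 2")
    if (s[1L] != START_ID) return("every sequence must begin with START_ID")
    if (s[length(s)] != STOP_ID) return("every sequence must end with STOP_ID")
  }
  ids <- unique(unlist(seqs, use.names = FALSE))
  if (!all(ids %in% voc$concept_id))
    return("sequence concept ids missing from vocabulary")
  TRUE
})

#' TransitionModel: first-order Markov chain over medical observations
#'
#' Pooled adjacent-pair counts and the row-normalized conditional transition
#' probabilities P(consequent | antecedent) over the vocabulary including the
#' START/STOP sentinels. The STOP state has no outgoing counts; rows with zero
#' count are all-zero in `probs`.
#'
#' @slot states integer vector of concept ids (ordered; includes sentinels).
#' @slot labels character labels parallel to `states`.
#' @slot counts non-negative integer matrix of observed consecutive pairs.
#' @slot probs row-stochastic matrix (rows with nonzero counts sum to 1).
#'
#' @seealso [fitMarkov()], [markovToRules()]
#' @export
setClass("TransitionModel",
  representation(
    states = "integer",
    labels = "character",
    counts = "matrix",
    probs = "matrix"
  )
)

setValidity("TransitionModel", function(object) {
  d <- length(object@states)
  if (length(object@labels) != d) return("labels must parallel states")
  if (!all(dim(object@counts) == c(d, d)) || !all(dim(object@probs) == c(d, d)))
    return("counts and probs must be square over states")
  if (any(object@counts < 0)) return("counts must be non-negative")
  rs <- rowSums(object@counts)
  ps <- rowSums(object@probs)
  bad <- rs > 0 & abs(ps - 1) > 1e-12
  if (any(bad)) return("rows with observed counts must sum to 1 in probs")
  if (any(rs == 0 & ps != 0)) return("zero-count rows must be all-zero in probs")
  stop_row <- which(object@states == STOP_ID)
  if (length(stop_row) == 1L && rs[stop_row] != 0)
    return("STOP state must have no outgoing counts")
  TRUE
})

#' RuleGraph: a learned directed graph of weighted temporal rules
#'
#' Each edge is a temporal rule antecedent -> consequent with a weight and the
#' provenance of the algorithm that produced it (`markov`, `tarm`,
#' `dynotears-inter`, `dynotears-intra`). Sequential support/confidence are
#' carried where the miner computed them (NA otherwise). Self-loops are kept
#' but flagged so downstream consumers can drop them.
#'
#' @slot nodes data.frame with columns `concept_id`, `label`: the union of
#'   edge endpoints.
#' @slot edges data.frame with columns `antecedent`, `consequent`, `weight`,
#'   `seq_sup`, `seq_conf`, `provenance`, `self_loop`.
#' @slot algorithm provenance tag for the whole graph.
#' @slot datasetTag free-text tag of the dataset the graph was learned from.
#'
#' @seealso [markovToRules()], [mineTemporalRules()], [svarToRules()],
#'   [graphComplexity()]
#' @export
setClass("RuleGraph",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    algorithm = "character",
    datasetTag = "character"
  )
)

setValidity("RuleGraph", function(object) {
  ed <- object@edges
  need <- c("antecedent", "consequent", "weight", "seq_sup", "seq_conf",
            "provenance", "self_loop")
  if (!all(need %in% names(ed))) return("edges missing required columns")
  if (!all(c("concept_id", "label") %in% names(object@nodes)))
    return("nodes must have columns concept_id, label")
  if (nrow(ed) > 0L) {
    if (anyDuplicated(ed[, c("antecedent", "consequent")]))
      return("duplicate (antecedent, consequent) pairs")
    if (!all(c(ed$antecedent, ed$consequent) %in% object@nodes$concept_id))
      return("edge endpoints missing from nodes")
    if (any(ed$antecedent == STOP_ID)) return("STOP cannot be an antecedent")
    if (any(ed$consequent == START_ID)) return("START cannot be a consequent")
    both <- !is.na(ed$seq_sup) & !is.na(ed$seq_conf)
    if (any(ed$seq_conf[both] < ed$seq_sup[both] - 1e-12))
      return("seq_conf must be >= seq_sup where both are present")
  }
  TRUE
})

#' DesignMatrices: pooled lagged design for SVAR structure learning
#'
#' Current-slice matrix `X` (M x d) and lagged matrix `Y` (M x d*p, lag-1
#' block first), pooled over patients so that no window spans two patients.
#' For event sequences the rows are one-hot indicators
#' ([encodeBinaryPanel()]); for simulated SVAR processes they are continuous
#' ([simulateSVAR()]).
#'
#' @slot X numeric matrix, M x d.
#' @slot Y numeric matrix, M x (d*p).
#' @slot p integer lag order (>= 1).
#' @slot concepts integer concept ids of the d modelled coordinates.
#' @slot labels character labels parallel to `concepts`.
#' @export
setClass("DesignMatrices",
  representation(
    X = "matrix",
    Y = "matrix",
    p = "integer",
    concepts = "integer",
    labels = "character"
  )
)

setValidity("DesignMatrices", function(object) {
  d <- ncol(object@X)
  if (object@p < 1L) return("lag order p must be >= 1")
  if (nrow(object@X) != nrow(object@Y)) return("X and Y row counts differ")
  if (ncol(object@Y) != d * object@p) return("Y must have d*p columns")
  if (length(object@concepts) != d || length(object@labels) != d)
    return("concepts/labels must parallel X columns")
  TRUE
})

#' SVARModel: intra- and inter-slice coefficient matrices
#'
#' The structural vector autoregressive model underlying DYNOTEARS: `W` (d x
#' d) holds contemporaneous (intra-slice) coefficients with zero diagonal,
#' `A` (d*p x d) holds lagged (inter-slice) coefficients, where entry (i, j)
#' is the effect of coordinate i (at the corresponding lag) on coordinate j.
#' After fitting, `h` records the acyclicity residual of `W`.
#'
#' @slot W numeric d x d matrix (zero diagonal).
#' @slot A numeric (d*p) x d matrix.
#' @slot p integer lag order.
#' @slot concepts integer ids of the modelled coordinates.
#' @slot labels character labels parallel to `concepts`.
#' @slot lambdaW,lambdaA L1 penalty weights used in fitting (NA for ground
#'   truth models).
#' @slot threshold default edge-pruning magnitude for rule extraction.
#' @slot converged logical: did the augmented Lagrangian reach its acyclicity
#'   tolerance.
#' @slot h numeric acyclicity residual of the fitted `W`.
#' @slot trace data.frame per-outer-iteration trace of the optimization.
#'
#' @seealso [fitDynotears()], [svarToRules()], [simulateSVAR()]
#' @export
setClass("SVARModel",
  representation(
    W = "matrix",
    A = "matrix",
    p = "integer",
    concepts = "integer",
    labels = "character",
    lambdaW = "numeric",
    lambdaA = "numeric",
    threshold = "numeric",
    converged = "logical",
    h = "numeric",
    trace = "data.frame"
  )
)

setValidity("SVARModel", function(object) {
  d <- ncol(object@W)
  if (nrow(object@W) != d) return("W must be square")
  if (any(abs(diag(object@W)) > 0)) return("diagonal of W must be zero")
  if (ncol(object@A) != d || nrow(object@A) != d * object@p)
    return("A must be (d*p) x d")
  if (length(object@concepts) != d) return("concepts must parallel W")
  TRUE
})

#' SyntheaModule: a Synthea generic-module document
#'
#' A directed state graph in the Synthea generic module dialect restricted to
#' the state types a learned rule graph can express: exactly one `Initial`
#' state, at least one `Terminal` state, and `Encounter` states carrying a
#' coded observation, connected by `distributed_transition` edges whose
#' probabilities sum to one. Constructed by [rulesToModule()] and by the
#' ground-truth generator [randomGroundTruth()]; sampled by [sampleModule()].
#'
#' @slot name module name.
#' @slot states named list of state records, keyed by state name, in
#'   insertion order (`Initial` first, `Terminal` last).
#'
#' @seealso [validateModule()], [writeSyntheaModule()]
#' @export
setClass("SyntheaModule",
  representation(name = "character", states = "list")
)

setValidity("SyntheaModule", function(object) {
  v <- validateModule(list(name = object@name, states = object@states))
  if (length(v) == 0L) TRUE else paste(v, collapse = "; ")
})
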