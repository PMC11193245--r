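#' @name accessors
#' @title Accessors for synthgraph containers
#'
#' @description Slot access for the S4 containers: patient sequences, person
#' ids, vocabularies, rule edges/nodes, transition counts and probabilities,
#' SVAR coefficient matrices, and module states.
#'
#' @param x a synthgraph S4 object.
#' @return The corresponding component; see each method.
NULL

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("personIds", function(x) standardGeneric("personIds"))
#' @rdname accessors
#' @export
setGeneric("eventDates", function(x) standardGeneric("eventDates"))
#' @rdname accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))
#' @rdname accessors
#' @export
setGeneric("meanSequenceLength", function(x) standardGeneric("meanSequenceLength"))
#' @rdname accessors
#' @export
setGeneric("ruleEdges", function(x) standardGeneric("ruleEdges"))
#' @rdname accessors
#' @export
setGeneric("ruleNodes", function(x) standardGeneric("ruleNodes"))
#' @rdname accessors
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))
#' @rdname accessors
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))
#' @rdname accessors
#' @export
setGeneric("intraSlice", function(x) standardGeneric("intraSlice"))
#' @rdname accessors
#' @export
setGeneric("interSlice", function(x) standardGeneric("interSlice"))
#' @rdname accessors
#' @export
setGeneric("moduleStates", function(x) standardGeneric("moduleStates"))
#' @rdname accessors
#' @export
setGeneric("moduleName", function(x) standardGeneric("moduleName"))

#' @rdname accessors
setMethod("sequences", "SequenceDataset", function(x) x@sequences)
#' @rdname accessors
setMethod("personIds", "SequenceDataset", function(x) x@personIds)
#' @rdname accessors
setMethod("eventDates", "SequenceDataset", function(x) x@dates)
#' @rdname accessors
setMethod("vocabulary", "SequenceDataset", function(x) x@vocabulary)
#' @rdname accessors
setMethod("provenance", "SequenceDataset", function(x) x@provenance)
#' @rdname accessors
setMethod("nSequences", "SequenceDataset", function(x) length(x@sequences))
#' @rdname accessors
setMethod("meanSequenceLength", "SequenceDataset",
  function(x) mean(lengths(x@sequences)))

#' @rdname accessors
setMethod("ruleEdges", "RuleGraph", function(x) x@edges)
#' @rdname accessors
setMethod("ruleNodes", "RuleGraph", function(x) x@nodes)

#' @rdname accessors
setMethod("transitionCounts", "TransitionModel", function(x) x@counts)
#' @rdname accessors
setMethod("transitionProbs", "TransitionModel", function(x) x@probs)

#' @rdname accessors
setMethod("intraSlice", "SVARModel", function(x) x@W)
#' @rdname accessors
setMethod("interSlice", "SVARModel", function(x) x@A)

#' @rdname accessors
setMethod("moduleStates", "SyntheaModule", function(x) x@states)
#' @rdname accessors
setMethod("moduleName", "SyntheaModule", function(x) x@name)

setMethod("show", "SequenceDataset", function(object) {
  cat(sprintf(
    "SequenceDataset: %d sequences, %d concepts (incl. sentinels)\n",
    length(object@sequences), nrow(object@vocabulary)))
  cat(sprintf("  mean length (incl. sentinels): %.2f\n",
              mean(lengths(object@sequences))))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "TransitionModel", function(object) {
  cat(sprintf("TransitionModel: %d states, %d observed transitions\n",
              length(object@states), sum(object@counts > 0)))
})

setMethod("show", "RuleGraph", function(object) {
  cat(sprintf("RuleGraph [%s]: %d nodes, %d edges",
              object@algorithm, nrow(object@nodes), nrow(object@edges)))
  sl <- sum(object@edges$self_loop)
  if (sl > 0) cat(sprintf(" (%d self-loops)", sl))
  cat("\n")
  if (nzchar(object@datasetTag)) cat("  dataset:", object@datasetTag, "\n")
})

setMethod("show", "SVARModel", function(object) {
  d <- ncol(object@W)
  cat(sprintf("SVARModel: d = %d, p = %d, h(W) = %.3g, converged = %s\n",
              d, object@p, object@h, object@converged))
})

setMethod("show", "DesignMatrices", function(object) {
  cat(sprintf("DesignMatrices: M = %d windows, d = %d coordinates, p = %d\n",
              nrow(object@X), ncol(object@X), object@p))
})

setMethod("show", "SyntheaModule", function(object) {
  types <- vapply(object@states, function(s) s$type, character(1))
  cat(sprintf("SyntheaModule '%s': %d states (%d Encounter)\n",
              object@name, length(object@states), sum(types == "Encounter")))
})
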