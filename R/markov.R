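## First-order Markov chain over medical observations: pooled adjacent-pair
## counts across the patient population, row-normalized into conditional
## transition probabilities P(consequent | antecedent).

#' Fit a first-order Markov chain to a sequence dataset
#'
#' Every medical observation (plus the START/STOP sentinels) is a state; the
#' conditional probability of observing each next state given the current one
#' is the maximum-likelihood estimate from adjacent-pair counts pooled over
#' all patients: `P(c | a) = count(a, c) / count(a, .)`. No smoothing or
#' pseudocounts are applied; rows never observed as antecedents are all-zero.
#'
#' @param dataset a [SequenceDataset-class] (non-empty).
#' @return A [TransitionModel-class]. State order is START, the non-sentinel
#'   concepts in ascending id order, STOP.
#' @export
fitMarkov <- function(dataset) {
  stopifnot(is(dataset, "SequenceDataset"))
  voc <- dataset@vocabulary
  concepts <- sort(voc$concept_id[voc$domain != "sentinel"])
  states <- c(START_ID, concepts, STOP_ID)
  d <- length(states)
  idx <- stats::setNames(seq_len(d), states)
  counts <- matrix(0L, d, d, dimnames = list(states, states))
  ants <- unlist(lapply(dataset@sequences, function(s) s[-length(s)]),
                 use.names = FALSE)
  cons <- unlist(lapply(dataset@sequences, function(s) s[-1L]),
                 use.names = FALSE)
  flat <- (idx[as.character(ants)] - 1L) * d + idx[as.character(cons)]
  tab <- tabulate(flat, nbins = d * d)
  counts <- matrix(as.integer(tab), d, d, byrow = TRUE,
                   dimnames = list(states, states))
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  probs[rs == 0, ] <- 0
  lab <- voc$label[match(states, voc$concept_id)]
  new("TransitionModel", states = as.integer(states), labels = lab,
      counts = counts, probs = probs)
}

#' Extract a rule graph from a fitted Markov chain
#'
#' Emits one temporal rule per transition with probability strictly above
#' `minProb`, weighted by the transition probability. All observed
#' transitions are kept at the default threshold of 0; self-loops are
#' retained but flagged.
#'
#' @param model a [TransitionModel-class].
#' @param minProb keep transitions with `P(c | a) > minProb` (default 0).
#' @param datasetTag free-text tag recorded on the graph.
#' @return A [RuleGraph-class] with provenance `"markov"`.
#' @export
markovToRules <- function(model, minProb = 0, datasetTag = "") {
  stopifnot(is(model, "TransitionModel"))
  hits <- which(model@probs > minProb & model@counts > 0, arr.ind = TRUE)
  edges <- data.frame(
    antecedent = model@states[hits[, 1L]],
    consequent = model@states[hits[, 2L]],
    weight = model@probs[hits],
    seq_sup = NA_real_,
    seq_conf = NA_real_,
    provenance = if (nrow(hits)) "markov" else character(0),
    self_loop = model@states[hits[, 1L]] == model@states[hits[, 2L]],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$antecedent, edges$consequent), , drop = FALSE]
  rownames(edges) <- NULL
  .makeRuleGraph(edges, model@states, model@labels, "markov", datasetTag)
}

## shared RuleGraph assembly: nodes are the union of edge endpoints
.makeRuleGraph <- function(edges, ids, labels, algorithm, datasetTag) {
  used <- unique(c(edges$antecedent, edges$consequent))
  nodes <- data.frame(concept_id = as.integer(used),
                      label = labels[match(used, ids)],
                      stringsAsFactors = FALSE)
  nodes$label[is.na(nodes$label)] <- paste0("concept_", nodes$concept_id[is.na(nodes$label)])
  nodes <- nodes[order(nodes$concept_id), , drop = FALSE]
  rownames(nodes) <- NULL
  new("RuleGraph", nodes = nodes, edges = edges,
      algorithm = algorithm, datasetTag = datasetTag)
}

#' Dump a transition matrix as TSV
#'
#' Writes one row per observed transition: antecedent label, consequent
#' label, pair count, and conditional probability.
#'
#' @param model a [TransitionModel-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeTransitionMatrix <- function(model, path) {
  hits <- which(model@counts > 0, arr.ind = TRUE)
  out <- data.frame(
    antecedent_label = model@labels[hits[, 1L]],
    consequent_label = model@labels[hits[, 2L]],
    count = model@counts[hits],
    probability = model@probs[hits],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$antecedent_label, out$consequent_label), , drop = FALSE]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
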