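## Temporal association rule mining over the sequence database, restricted to
## singleton antecedent/consequent (the downstream Synthea edge is pairwise).
## seqSup(X -> Y) = sup(X before Y) / |S|; seqConf(X -> Y) = sup(X before Y) / sup(X).
## Brute force over D^2 ordered pairs: O(N * T + N * k^2) with k distinct
## concepts per sequence, which suffices at the scales this package targets.

#' Sequential support of an ordered concept pair
#'
#' Counts the sequences containing at least one occurrence of `x` at some
#' index i and of `y` at some later index j > i; each sequence contributes at
#' most 1. For `x == y` this requires two occurrences.
#'
#' @param dataset a [SequenceDataset-class].
#' @param x,y concept ids (must be in the vocabulary).
#' @return integer count.
#' @export
sequenceSupport <- function(dataset, x, y) {
  voc <- dataset@vocabulary$concept_id
  if (!(x %in% voc) || !(y %in% voc))
    stop("unknown concept id: ", paste(setdiff(c(x, y), voc), collapse = ", "))
  n <- 0L
  for (s in dataset@sequences) {
    i <- match(x, s)                      # first occurrence
    if (is.na(i)) next
    j <- length(s) + 1L - match(y, rev(s))  # last occurrence
    if (!is.na(j) && i < j) n <- n + 1L
  }
  n
}

#' Mine pairwise temporal association rules
#'
#' For every ordered concept pair (x, y) with x != STOP and y != START,
#' computes sequential support `sup(x before y) / |S|` and sequential
#' confidence `sup(x before y) / sup(x)` over the sequence database and emits
#' a rule when both thresholds are met. The rule weight is the sequential
#' confidence. Rules out of the START sentinel are exempt from the confidence
#' threshold so that every mapped module retains an entry distribution
#' (Synthea sampling needs outgoing transitions from the initial state).
#'
#' @param dataset a [SequenceDataset-class].
#' @param minSeqSup minimum sequential support in \[0, 1\] (default 0.1).
#' @param minSeqConf minimum sequential confidence in \[0, 1\] (default 0.5).
#' @param datasetTag free-text tag recorded on the graph.
#' @return A [RuleGraph-class] with provenance `"tarm"`.
#' @export
mineTemporalRules <- function(dataset, minSeqSup = 0.1, minSeqConf = 0.5,
                              datasetTag = "") {
  stopifnot(minSeqSup >= 0, minSeqSup <= 1, minSeqConf >= 0, minSeqConf <= 1)
  voc <- dataset@vocabulary
  ids <- sort(voc$concept_id)
  d <- length(ids)
  pos <- stats::setNames(seq_len(d), ids)
  nS <- length(dataset@sequences)
  pair_sup <- matrix(0L, d, d)   # [x, y] = #sequences with x before y
  item_sup <- integer(d)         # #sequences containing x
  for (s in dataset@sequences) {
    u <- unique(s)
    k <- pos[as.character(u)]
    first <- vapply(u, function(cid) match(cid, s), integer(1))
    last <- vapply(u, function(cid) length(s) + 1L - match(cid, rev(s)),
                   integer(1))
    item_sup[k] <- item_sup[k] + 1L
    prec <- outer(first, last, `<`)  # x strictly before y
    pair_sup[k, k] <- pair_sup[k, k] + prec
  }
  ant <- rep(ids, times = d)
  con <- rep(ids, each = d)
  sup_xy <- as.vector(pair_sup)           # column-major: (x varies fastest)
  sup_x <- rep(item_sup, times = d)
  seq_sup <- sup_xy / nS
  seq_conf <- ifelse(sup_x > 0, sup_xy / sup_x, NA_real_)
  keep <- sup_xy > 0 & sup_x > 0 &
    ant != STOP_ID & con != START_ID &
    seq_sup >= minSeqSup &
    (ant == START_ID | seq_conf >= minSeqConf)
  edges <- data.frame(
    antecedent = as.integer(ant[keep]),
    consequent = as.integer(con[keep]),
    weight = seq_conf[keep],
    seq_sup = seq_sup[keep],
    seq_conf = seq_conf[keep],
    provenance = if (any(keep)) "tarm" else character(0),
    self_loop = ant[keep] == con[keep],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$antecedent, edges$consequent), , drop = FALSE]
  rownames(edges) <- NULL
  .makeRuleGraph(edges, voc$concept_id, voc$label, "tarm", datasetTag)
}

#' Write a mined rule list as TSV
#'
#' @param graph a [RuleGraph-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeRuleTable <- function(graph, path) {
  ed <- graph@edges
  lab <- stats::setNames(graph@nodes$label, graph@nodes$concept_id)
  out <- data.frame(
    antecedent_label = unname(lab[as.character(ed$antecedent)]),
    consequent_label = unname(lab[as.character(ed$consequent)]),
    weight = ed$weight,
    seq_sup = ed$seq_sup,
    seq_conf = ed$seq_conf,
    provenance = ed$provenance,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
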