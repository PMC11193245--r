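# Fixture builders and independent brute-force oracles. Oracles deliberately
# use naive nested loops so they share no code path with the implementation.

# wrap bodies (integer vectors of concept ids, no sentinels) into a dataset;
# extraIds adds never-observed concepts to the vocabulary
makeDataset <- function(bodies, extraIds = integer(0)) {
  seqs <- lapply(bodies, function(b) c(START_ID, as.integer(b), STOP_ID))
  ids <- sort(unique(c(unlist(bodies), extraIds)))
  voc <- rbind(
    data.frame(concept_id = c(START_ID, STOP_ID), label = c("START", "STOP"),
               domain = "sentinel", stringsAsFactors = FALSE),
    if (length(ids)) data.frame(concept_id = as.integer(ids),
                                label = paste0("concept_", ids),
                                domain = "condition",
                                stringsAsFactors = FALSE)
  )
  voc <- voc[order(voc$concept_id), ]
  rownames(voc) <- NULL
  new("SequenceDataset", sequences = seqs,
      personIds = paste0("p", seq_along(seqs)), dates = list(),
      vocabulary = voc, provenance = "fixture")
}

randomSmallDataset <- function(nseq = 10, nconcepts = 4, maxlen = 6) {
  bodies <- lapply(seq_len(nseq), function(i)
    sample.int(nconcepts, sample.int(maxlen, 1), replace = TRUE))
  makeDataset(bodies)
}

# brute-force Markov: nested loop over every adjacent pair in every sequence
bruteMarkov <- function(dataset) {
  states <- sort(vocabulary(dataset)$concept_id)
  d <- length(states)
  counts <- matrix(0L, d, d, dimnames = list(states, states))
  for (s in sequences(dataset)) {
    if (length(s) < 2) next
    for (t in seq_len(length(s) - 1)) {
      a <- as.character(s[t]); b <- as.character(s[t + 1])
      counts[a, b] <- counts[a, b] + 1L
    }
  }
  probs <- counts * 0
  for (i in seq_len(d)) if (sum(counts[i, ]) > 0)
    probs[i, ] <- counts[i, ] / sum(counts[i, ])
  list(counts = counts, probs = probs)
}

# brute-force precedence support: triple loop over index pairs
bruteSeqSup <- function(dataset, x, y) {
  n <- 0L
  for (s in sequences(dataset)) {
    hit <- FALSE
    for (i in seq_along(s)) {
      if (s[i] != x) next
      for (j in seq_along(s)) {
        if (j > i && s[j] == y) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) n <- n + 1L
  }
  n
}

# brute-force rule miner mirroring the declared semantics (START edges exempt
# from the confidence threshold)
bruteMineRules <- function(dataset, minSup, minConf) {
  ids <- sort(vocabulary(dataset)$concept_id)
  nS <- length(sequences(dataset))
  out <- list()
  for (x in ids) {
    if (x == STOP_ID) next
    supx <- sum(vapply(sequences(dataset), function(s) x %in% s, logical(1)))
    if (supx == 0) next
    for (y in ids) {
      if (y == START_ID) next
      supxy <- bruteSeqSup(dataset, x, y)
      if (supxy == 0) next
      ssup <- supxy / nS
      sconf <- supxy / supx
      if (ssup >= minSup && (x == START_ID || sconf >= minConf))
        out[[length(out) + 1L]] <- data.frame(
          antecedent = x, consequent = y, seq_sup = ssup, seq_conf = sconf)
    }
  }
  if (!length(out))
    return(data.frame(antecedent = integer(), consequent = integer(),
                      seq_sup = numeric(), seq_conf = numeric()))
  df <- do.call(rbind, out)
  df[order(df$antecedent, df$consequent), ]
}

# DFS cycle detector on the support of a matrix (|w| > tol edges)
bruteHasCycle <- function(W, tol = 1e-8) {
  d <- nrow(W)
  adj <- abs(W) > tol
  if (any(diag(adj))) return(TRUE)
  color <- integer(d)  # 0 white, 1 grey, 2 black
  visit <- function(u) {
    color[u] <<- 1L
    for (v in which(adj[u, ])) {
      if (color[v] == 1L) return(TRUE)
      if (color[v] == 0L && visit(v)) return(TRUE)
    }
    color[u] <<- 2L
    FALSE
  }
  for (u in seq_len(d)) if (color[u] == 0L && visit(u)) return(TRUE)
  FALSE
}

# brute-force complexity metrics from an edge data.frame over node ids
bruteComplexity <- function(nodes, edges) {
  n <- length(nodes)
  m <- nrow(edges)
  reach <- function(a, b) {  # directed path a -> b through >= 1 edge
    frontier <- edges$consequent[edges$antecedent == a]
    seen <- frontier
    while (length(frontier)) {
      if (b %in% frontier) return(TRUE)
      nxt <- unique(edges$consequent[edges$antecedent %in% frontier])
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    b %in% seen
  }
  # SCCs via mutual reachability (a node reaches itself trivially)
  same <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    if (i == j) return(TRUE)
    reach(nodes[i], nodes[j]) && reach(nodes[j], nodes[i])
  }))
  comp <- rep(NA_integer_, n)
  cc <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cc <- cc + 1L
      comp[same[i, ]] <- cc
    }
  }
  # an edge is cyclic iff it lies on some directed cycle
  cyclic <- vapply(seq_len(m), function(k) {
    a <- edges$antecedent[k]; b <- edges$consequent[k]
    if (a == b) TRUE else reach(b, a)
  }, logical(1))
  list(
    density = if (n > 1) m / (n * (n - 1)) else 0,
    n_scc = max(comp),
    flow_hierarchy = if (n > 1 && m > 0) 1 - sum(cyclic) / m else 0
  )
}

# brute-force directed (all-triangle) clustering: enumerate ordered triples
bruteDirectedClustering <- function(nodes, edges) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  keep <- edges$antecedent != edges$consequent
  A[cbind(as.character(edges$antecedent[keep]),
          as.character(edges$consequent[keep]))] <- 1
  cl <- numeric(n)
  for (i in seq_len(n)) {
    tri <- 0
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (j == i || k == i || j == k) next
        # triangle i-j-k with each undirected side present in some direction,
        # weighted by the number of directed edge combinations
        tri <- tri + (A[i, j] + A[j, i]) * (A[i, k] + A[k, i]) *
          (A[j, k] + A[k, j])
      }
    }
    tri <- tri / 2
    dtot <- sum(A[i, ]) + sum(A[, i])
    dbi <- sum(A[i, ] * A[, i])
    denom <- dtot * (dtot - 1) - 2 * dbi
    cl[i] <- if (denom > 0) tri / denom else 0
  }
  mean(cl)
}

# a random RuleGraph guaranteed to carry a START-anchored entry edge
randomRuleGraph <- function(nconcepts = 6, edgeProb = 0.3) {
  ids <- seq_len(nconcepts)
  pairs <- expand.grid(antecedent = c(START_ID, ids),
                       consequent = c(ids, STOP_ID))
  pairs <- pairs[runif(nrow(pairs)) < edgeProb, ]
  entry <- data.frame(antecedent = START_ID, consequent = sample(ids, 1))
  pairs <- unique(rbind(pairs, entry))
  edges <- data.frame(
    antecedent = as.integer(pairs$antecedent),
    consequent = as.integer(pairs$consequent),
    weight = runif(nrow(pairs), 0.05, 1),
    seq_sup = NA_real_, seq_conf = NA_real_,
    provenance = "fixture",
    self_loop = pairs$antecedent == pairs$consequent,
    stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL
  used <- unique(c(edges$antecedent, edges$consequent))
  nodes <- data.frame(concept_id = as.integer(used),
                      label = paste0("c", used), stringsAsFactors = FALSE)
  new("RuleGraph", nodes = nodes, edges = edges,
      algorithm = "fixture", datasetTag = "")
}

# RuleGraph straight from an edge list (weights optional)
edgeListGraph <- function(antecedent, consequent, weight = NULL) {
  edges <- data.frame(
    antecedent = as.integer(antecedent),
    consequent = as.integer(consequent),
    weight = if (is.null(weight)) rep(1, length(antecedent)) else weight,
    seq_sup = NA_real_, seq_conf = NA_real_,
    provenance = "fixture",
    self_loop = antecedent == consequent,
    stringsAsFactors = FALSE
  )
  used <- unique(c(edges$antecedent, edges$consequent))
  nodes <- data.frame(concept_id = as.integer(used),
                      label = paste0("c", used), stringsAsFactors = FALSE)
  new("RuleGraph", nodes = nodes, edges = edges,
      algorithm = "fixture", datasetTag = "")
}

emptyRuleGraph <- function() {
  new("RuleGraph",
      nodes = data.frame(concept_id = integer(), label = character(),
                         stringsAsFactors = FALSE),
      edges = data.frame(antecedent = integer(), consequent = integer(),
                         weight = numeric(), seq_sup = numeric(),
                         seq_conf = numeric(), provenance = character(),
                         self_loop = logical(), stringsAsFactors = FALSE),
      algorithm = "fixture", datasetTag = "")
}
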