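## Mapping learned rule graphs into Synthea generic-module documents and
## sampling them back into event sequences. Only the state types a pairwise
## rule graph can express are used: Initial, Terminal, and Encounter states
## connected by distributed transitions.

## round probabilities to 6 decimals, largest share absorbing the residue so
## the distribution sums to 1 exactly (within fp)
.roundDistribution <- function(p) {
  r <- round(p, 6)
  r[which.max(r)] <- r[which.max(r)] + (1 - sum(r))
  r
}

.distTransition <- function(targets, probs) {
  probs <- .roundDistribution(probs / sum(probs))
  mapply(function(tg, pr) list(distribution = pr, transition = tg),
         targets, probs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Convert a rule graph into a Synthea module
#'
#' Each non-sentinel concept reachable from START becomes one `Encounter`
#' state (any medical observation can occur only once in a Synthea graph, so
#' state names are deduplicated labels); START maps to `Initial` and STOP to
#' `Terminal`. Each state's outgoing rule weights are normalized
#' proportionally into a distributed transition summing to 1; dead-end states
#' transition to Terminal with probability 1; states unreachable from Initial
#' are pruned with a warning.
#'
#' @param graph a non-empty [RuleGraph-class] containing at least one
#'   START-anchored edge.
#' @param moduleName name recorded in the module document.
#' @param dropSelfLoops drop self-loop rules before mapping (default TRUE).
#' @return A [SyntheaModule-class]; always passes [validateModule()].
#' @export
rulesToModule <- function(graph, moduleName = "learned_module",
                          dropSelfLoops = TRUE) {
  ed <- graph@edges
  if (nrow(ed) == 0L) stop("rule graph has no edges")
  if (any(ed$weight < 0)) stop("negative rule weight")
  if (dropSelfLoops) ed <- ed[!ed$self_loop, , drop = FALSE]
  if (!any(ed$antecedent == START_ID))
    stop("no entry distribution: graph has no START-anchored edges")
  ## reachability from START over the retained edges
  reach <- START_ID
  frontier <- START_ID
  while (length(frontier)) {
    nxt <- unique(ed$consequent[ed$antecedent %in% frontier])
    frontier <- setdiff(nxt, reach)
    reach <- c(reach, frontier)
  }
  all_nodes <- unique(c(ed$antecedent, ed$consequent))
  pruned <- setdiff(all_nodes, c(reach, STOP_ID))
  if (length(pruned))
    warning(length(pruned), " state(s) unreachable from Initial pruned")
  concepts <- sort(setdiff(reach, c(START_ID, STOP_ID)))
  lab <- graph@nodes$label[match(concepts, graph@nodes$concept_id)]
  lab[is.na(lab)] <- paste0("concept_", concepts[is.na(lab)])
  state_name <- lab
  clash <- duplicated(state_name) | duplicated(state_name, fromLast = TRUE) |
    state_name %in% c("Initial", "Terminal")
  state_name[clash] <- paste0(state_name[clash], "_", concepts[clash])
  names(state_name) <- concepts
  target_of <- function(cid) {
    if (cid == STOP_ID) "Terminal" else unname(state_name[as.character(cid)])
  }
  states <- list()
  se <- ed[ed$antecedent == START_ID & ed$consequent %in% reach, , drop = FALSE]
  states[["Initial"]] <- list(
    type = "Initial",
    distributed_transition = .distTransition(
      vapply(se$consequent, target_of, character(1)), se$weight))
  for (k in seq_along(concepts)) {
    cid <- concepts[k]
    out <- ed[ed$antecedent == cid &
                (ed$consequent %in% reach | ed$consequent == STOP_ID), ,
              drop = FALSE]
    dt <- if (nrow(out) == 0L) {
      list(list(distribution = 1, transition = "Terminal"))
    } else {
      .distTransition(vapply(out$consequent, target_of, character(1)),
                      out$weight)
    }
    states[[state_name[k]]] <- list(
      type = "Encounter",
      encounter_class = "ambulatory",
      codes = list(list(system = "SNOMED-CT", code = as.character(cid),
                        display = lab[k])),
      distributed_transition = dt)
  }
  states[["Terminal"]] <- list(type = "Terminal")
  new("SyntheaModule", name = moduleName, states = states)
}

#' Validate a Synthea module document
#'
#' Checks the invariants the Synthea engine relies on: exactly one Initial
#' state and at least one Terminal state; every distributed transition sums
#' to 1 (within 1e-9) with non-negative probabilities; every transition
#' target names an existing state; every non-Terminal state has a transition.
#'
#' @param x a [SyntheaModule-class] or a plain list with `name` and `states`
#'   (e.g. parsed JSON).
#' @return Character vector of violations; empty when the module is valid.
#' @export
validateModule <- function(x) {
  if (is(x, "SyntheaModule")) x <- list(name = x@name, states = x@states)
  if (!is.list(x) || is.null(x$states) || !is.list(x$states) ||
      is.null(names(x$states)))
    stop("not a parseable module document (need named 'states' list)")
  st <- x$states
  v <- character(0)
  types <- vapply(st, function(s) as.character(s$type %||% ""), character(1))
  if (sum(types == "Initial") != 1L)
    v <- c(v, sprintf("expected exactly one Initial state, found %d",
                      sum(types == "Initial")))
  if (sum(types == "Terminal") < 1L)
    v <- c(v, "no Terminal state")
  for (nm in names(st)) {
    s <- st[[nm]]
    if (identical(s$type, "Terminal")) next
    dt <- s$distributed_transition
    if (is.null(dt) || length(dt) == 0L) {
      v <- c(v, sprintf("state '%s' has no transition", nm))
      next
    }
    probs <- vapply(dt, function(e) as.numeric(e$distribution), numeric(1))
    targets <- vapply(dt, function(e) as.character(e$transition), character(1))
    if (any(probs < 0))
      v <- c(v, sprintf("state '%s' has a negative transition probability", nm))
    if (abs(sum(probs) - 1) > 1e-9)
      v <- c(v, sprintf("state '%s' distribution sums to %.10f, not 1",
                        nm, sum(probs)))
    missing <- setdiff(targets, names(st))
    if (length(missing))
      v <- c(v, sprintf("state '%s' transitions to nonexistent state '%s'",
                        nm, missing))
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample patient sequences from a Synthea module
#'
#' Walks the module from Initial to Terminal `n` times, choosing successors
#' according to the distributed-transition probabilities, and returns the
#' sampled walks as a [SequenceDataset-class] (Initial and Terminal map to
#' the START/STOP sentinels; Encounter states emit their coded concept).
#' Walks exceeding `maxSteps` states are truncated with a warning (the STOP
#' sentinel is still appended so the dataset stays well-formed).
#'
#' @param module a valid [SyntheaModule-class].
#' @param n number of sequences to sample.
#' @param seed integer seed; NULL uses the current RNG stream.
#' @param maxSteps walk-length cap (default 1000).
#' @return A [SequenceDataset-class].
#' @export
sampleModule <- function(module, n, seed = NULL, maxSteps = 1000L) {
  viol <- validateModule(module)
  if (length(viol))
    stop("refusing to sample an invalid module: ", paste(viol, collapse = "; "))
  st <- module@states
  types <- vapply(st, function(s) s$type, character(1))
  init <- names(st)[types == "Initial"]
  codes <- vapply(st, function(s) {
    if (identical(s$type, "Encounter"))
      as.integer(s$codes[[1L]]$code) else NA_integer_
  }, integer(1))
  displays <- vapply(st, function(s) {
    if (identical(s$type, "Encounter"))
      as.character(s$codes[[1L]]$display) else NA_character_
  }, character(1))
  trans <- lapply(st, function(s) {
    dt <- s$distributed_transition
    if (is.null(dt)) return(NULL)
    list(targets = vapply(dt, function(e) as.character(e$transition),
                          character(1)),
         probs = vapply(dt, function(e) as.numeric(e$distribution),
                        numeric(1)))
  })
  truncated <- 0L
  seqs <- .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      cur <- init
      out <- START_ID
      steps <- 0L
      repeat {
        tr <- trans[[cur]]
        if (is.null(tr)) break           # Terminal
        cur <- if (length(tr$targets) == 1L) tr$targets else
          sample(tr$targets, 1L, prob = tr$probs)
        steps <- steps + 1L
        if (identical(types[[cur]], "Terminal")) break
        out <- c(out, codes[[cur]])
        if (steps >= maxSteps) {
          truncated <<- truncated + 1L
          break
        }
      }
      c(out, STOP_ID)
    })
  })
  if (truncated > 0L)
    warning(truncated, " walk(s) truncated at maxSteps = ", maxSteps)
  enc <- !is.na(codes)
  voc <- rbind(.SENTINELS(),
               data.frame(concept_id = unname(codes[enc]),
                          label = unname(displays[enc]),
                          domain = "condition", stringsAsFactors = FALSE))
  voc <- voc[order(voc$concept_id), , drop = FALSE]
  rownames(voc) <- NULL
  new("SequenceDataset", sequences = seqs,
      personIds = sprintf("S%05d", seq_len(n)), dates = list(),
      vocabulary = voc,
      provenance = sprintf("sampled from module '%s'", module@name))
}

#' Write/read a Synthea module JSON document
#'
#' The GitHub module-builder dialect: top-level `name` and `states`, states
#' keyed by name in insertion order, written UTF-8 with 2-space indent.
#'
#' @param module a [SyntheaModule-class].
#' @param path output (input) JSON path.
#' @param validate check invariants on read (default TRUE); with
#'   `validate = FALSE` the parsed list is returned so that defective
#'   documents can be inspected with [validateModule()].
#' @return `writeSyntheaModule` returns `path` invisibly;
#'   `readSyntheaModule` a [SyntheaModule-class] (or list).
#' @export
writeSyntheaModule <- function(module, path) {
  doc <- list(name = module@name, states = module@states)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeSyntheaModule
#' @export
readSyntheaModule <- function(path, validate = TRUE) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!validate) return(doc)
  new("SyntheaModule", name = as.character(doc$name %||% ""),
      states = doc$states)
}
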