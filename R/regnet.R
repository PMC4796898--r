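VALID_STATES <- c("up", "down", "undetermined")
VALID_TIERS <- c("qrt_confirmed", "array_reported", "predicted", "unanchored")

# evidence weights: known misregulation counts double a prediction
TIER_WEIGHTS <- c(qrt_confirmed = 2, array_reported = 2,
                  predicted = 1, unanchored = 0)

#' RegulatoryNetwork: a signed, directed, evidence-annotated gene network
#'
#' Container for a manually curated regulatory network: directed edges with a
#' sign (+1 activation, -1 repression), a directness flag (direct protein-to-
#' promoter binding versus indirect regulation) and a provenance string; and
#' per-gene node states recording observed or predicted misregulation
#' (`up`/`down`/`undetermined`) with an evidence tier (`qrt_confirmed`,
#' `array_reported`, `predicted`, `unanchored`). Anchored nodes (the two
#' known tiers) are held fixed during state inference.
#'
#' @slot edges data.frame with columns `source`, `target`, `sign`,
#'   `directness`, `provenance`.
#' @slot nodes data.frame with columns `gene`, `state`, `tier`.
#' @slot root optional gene id of the microRNA root node (character(0) if
#'   none).
#' @seealso [regulatoryNetwork()], [predictStates()], [pruneInconsistent()]
#' @export
setClass("RegulatoryNetwork",
         slots = c(edges = "data.frame", nodes = "data.frame",
                   root = "character"))

setValidity("RegulatoryNetwork", function(object) {
  e <- object@edges
  n <- object@nodes
  msgs <- character(0L)
  needE <- c("source", "target", "sign", "directness", "provenance")
  if (!all(needE %in% names(e))) {
    msgs <- c(msgs, sprintf("edges must have columns: %s",
                            paste(needE, collapse = ", ")))
  } else {
    if (any(e$source == e$target)) msgs <- c(msgs, "self-loop edges present")
    if (!all(e$sign %in% c(-1L, 1L))) msgs <- c(msgs, "edge sign must be +1 or -1")
    if (anyDuplicated(e[, c("source", "target", "sign")])) {
      msgs <- c(msgs, "duplicate (source, target, sign) edges")
    }
  }
  needN <- c("gene", "state", "tier")
  if (!all(needN %in% names(n))) {
    msgs <- c(msgs, sprintf("nodes must have columns: %s",
                            paste(needN, collapse = ", ")))
  } else {
    if (anyDuplicated(n$gene)) msgs <- c(msgs, "duplicate node gene ids")
    if (!all(n$state %in% VALID_STATES)) {
      msgs <- c(msgs, sprintf("node states must be one of: %s",
                              paste(VALID_STATES, collapse = ", ")))
    }
    if (!all(n$tier %in% VALID_TIERS)) {
      msgs <- c(msgs, sprintf("node tiers must be one of: %s",
                              paste(VALID_TIERS, collapse = ", ")))
    }
    known <- n$tier %in% c("qrt_confirmed", "array_reported")
    if (any(known & n$state == "undetermined")) {
      msgs <- c(msgs, "anchored (known-tier) nodes must have a determined state")
    }
    if (all(needE %in% names(e)) &&
        !all(c(e$source, e$target) %in% n$gene)) {
      msgs <- c(msgs, "every edge endpoint must be a node")
    }
  }
  if (length(object@root) > 1L ||
      (length(object@root) == 1L && all(needN %in% names(n)) &&
       !object@root %in% n$gene)) {
    msgs <- c(msgs, "root must be a single existing gene id (or absent)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RegulatoryNetwork
#'
#' @param edges data.frame of directed signed edges. Requires `source`,
#'   `target` and `sign` (+1/-1); `directness` (default `"direct"`) and
#'   `provenance` (default `""`) are filled in if absent. Duplicate
#'   (source, target, sign) rows are removed with a warning; a pair of
#'   parallel edges with opposite signs (a literature conflict) is kept and
#'   reported with a message.
#' @param anchors optional data.frame of observed/pre-assigned node states:
#'   columns `gene`, `state` (`up`/`down`), `tier`. Genes appearing in edges
#'   but not here become `undetermined`/`unanchored`.
#' @param root optional gene id flagged as the microRNA root.
#' @return A validated [RegulatoryNetwork-class] object.
#' @export
regulatoryNetwork <- function(edges, anchors = NULL, root = character(0L)) {
  stopIfNot1(is.data.frame(edges) && all(c("source", "target", "sign") %in%
                                           names(edges)),
             "edges must be a data.frame with source, target, sign columns")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  if (is.null(edges$directness)) edges$directness <- "direct"
  if (is.null(edges$provenance)) edges$provenance <- ""
  edges <- edges[, c("source", "target", "sign", "directness", "provenance")]
  dup <- duplicated(edges[, c("source", "target", "sign")])
  if (any(dup)) {
    warning(sprintf("removed %d duplicate edge(s)", sum(dup)), call. = FALSE)
    edges <- edges[!dup, , drop = FALSE]
  }
  pairKey <- paste(edges$source, edges$target, sep = "\r")
  conflict <- pairKey[duplicated(pairKey)]
  if (length(conflict)) {
    message(sprintf("note: %d gene pair(s) carry parallel edges of opposite sign",
                    length(unique(conflict))))
  }
  edges <- edges[order(edges$source, edges$target, edges$sign), , drop = FALSE]
  rownames(edges) <- NULL

  genes <- sort(unique(c(edges$source, edges$target,
                         if (!is.null(anchors)) as.character(anchors$gene))))
  nodes <- data.frame(gene = genes, state = "undetermined",
                      tier = "unanchored", stringsAsFactors = FALSE)
  if (!is.null(anchors)) {
    stopIfNot1(all(c("gene", "state", "tier") %in% names(anchors)),
               "anchors must have columns gene, state, tier")
    i <- match(as.character(anchors$gene), nodes$gene)
    nodes$state[i] <- as.character(anchors$state)
    nodes$tier[i] <- as.character(anchors$tier)
  }
  new("RegulatoryNetwork", edges = edges, nodes = nodes,
      root = as.character(root))
}

#' @describeIn RegulatoryNetwork-class edge table accessor
#' @param x a `RegulatoryNetwork`
#' @export
setGeneric("regEdges", function(x) standardGeneric("regEdges"))

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("regEdges", "RegulatoryNetwork", function(x) x@edges)

#' @describeIn RegulatoryNetwork-class node-state table accessor
#' @export
setGeneric("nodeStates", function(x) standardGeneric("nodeStates"))

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("nodeStates", "RegulatoryNetwork", function(x) x@nodes)

setMethod("show", "RegulatoryNetwork", function(object) {
  n <- object@nodes
  cat(sprintf("RegulatoryNetwork: %d nodes, %d signed edges\n",
              nrow(n), nrow(object@edges)))
  cat(sprintf("  states: %d up, %d down, %d undetermined\n",
              sum(n$state == "up"), sum(n$state == "down"),
              sum(n$state == "undetermined")))
  cat(sprintf("  tiers: %d qRT-confirmed, %d array-reported, %d predicted, %d unanchored\n",
              sum(n$tier == "qrt_confirmed"), sum(n$tier == "array_reported"),
              sum(n$tier == "predicted"), sum(n$tier == "unanchored")))
  if (length(object@root)) cat(sprintf("  microRNA root: %s\n", object@root))
  invisible(NULL)
})

stateToSign <- function(state) {
  out <- ifelse(state == "up", 1L, ifelse(state == "down", -1L, 0L))
  as.integer(out)
}

signToState <- function(s) c("down", "undetermined", "up")[s + 2L]

#' Sign consistency of one regulatory edge
#'
#' An edge `u -> v` with sign s is consistent with observed states when the
#' target's state equals the sign times the source's state: activation
#' preserves the direction of misregulation, repression inverts it (a
#' downregulated repressor therefore explains an upregulated target).
#'
#' @param sourceState,targetState node states as +1 (up) / -1 (down).
#' @param sign edge sign, +1 activation / -1 repression.
#' @return Logical vector.
#' @export
edgeConsistent <- function(sourceState, sign, targetState) {
  v <- cbind(sourceState, sign, targetState)
  if (!all(v %in% c(-1L, 1L))) {
    stop("states and signs must be +1 or -1 (filter undetermined nodes first)",
         call. = FALSE)
  }
  unname(v[, 3L] == v[, 2L] * v[, 1L])
}

# Incident-edge view used by the scorer: one row per (node, partner) incidence
# with the hypothesis the edge would support if the partner's state is `up`.
# For an outgoing edge node->partner, consistency requires
# state(partner) = sign * h, i.e. the edge supports h = sign * state(partner);
# an incoming edge partner->node supports h = sign * state(partner) likewise.
incidenceTable <- function(network) {
  e <- regEdges(network)
  data.frame(
    node = c(e$source, e$target),
    partner = c(e$target, e$source),
    sign = c(e$sign, e$sign),
    edge = rep(seq_len(nrow(e)), 2L),
    stringsAsFactors = FALSE)
}

scoreAllNodes <- function(inc, states, weights) {
  pState <- stateToSign(states[inc$partner])
  w <- weights[inc$partner]
  support <- inc$sign * pState           # hypothesis supported; 0 if partner undetermined
  up <- rowsum(w * (support == 1L), inc$node)
  down <- rowsum(w * (support == -1L), inc$node)
  list(up = setNames(up[, 1L], rownames(up)),
       down = setNames(down[, 1L], rownames(down)))
}

#' Score one misregulation hypothesis for a node
#'
#' Implements the tiered weighting used to decide whether an intermediate
#' gene is up- or downregulated: every incident edge (upstream and
#' downstream) whose other endpoint has a determined state contributes that
#' endpoint's evidence weight if the edge is sign-consistent under the
#' hypothesis, and nothing otherwise. Known misregulation (qRT-confirmed or
#' array-reported) weighs 2, predicted misregulation weighs 1, unanchored or
#' undetermined neighbours weigh 0.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param node gene id to score.
#' @param hypothesis `"up"` or `"down"` (or +1/-1).
#' @return List with `score` (non-negative integer) and `contributions`, a
#'   data.frame of the consistent edges with the partner gene and its weight.
#' @seealso [predictionScore()] for both hypotheses plus the decision.
#' @export
scoreHypothesis <- function(network, node, hypothesis) {
  n <- nodeStates(network)
  stopIfNot1(node %in% n$gene, sprintf("node '%s' not in network", node))
  if (is.character(hypothesis)) hypothesis <- stateToSign(hypothesis)
  stopIfNot1(hypothesis %in% c(-1L, 1L), "hypothesis must be up/down (+1/-1)")
  inc <- incidenceTable(network)
  inc <- inc[inc$node == node, , drop = FALSE]
  states <- setNames(n$state, n$gene)
  weights <- setNames(TIER_WEIGHTS[n$tier] * (stateToSign(n$state) != 0L),
                      n$gene)
  support <- inc$sign * stateToSign(states[inc$partner])
  hit <- support == hypothesis & weights[inc$partner] > 0
  contributions <- data.frame(
    partner = inc$partner[hit],
    sign = inc$sign[hit],
    weight = unname(weights[inc$partner[hit]]),
    stringsAsFactors = FALSE)
  list(score = sum(contributions$weight), contributions = contributions)
}

#' Both hypothesis scores and the decision for a node
#'
#' @inheritParams scoreHypothesis
#' @return List with `score_up`, `score_down` and `decision`
#'   (`up`/`down`/`undetermined`; ties are never broken by chance).
#' @export
predictionScore <- function(network, node) {
  up <- scoreHypothesis(network, node, "up")
  down <- scoreHypothesis(network, node, "down")
  decision <- if (up$score > down$score) "up"
  else if (down$score > up$score) "down"
  else "undetermined"
  list(score_up = up$score, score_down = down$score, decision = decision,
       contributions_up = up$contributions,
       contributions_down = down$contributions)
}

#' Predict misregulation states for unanchored network genes
#'
#' Iterative tiered-evidence inference. Round 1 scores every unanchored
#' node against its anchored (known-tier) neighbours only; later rounds
#' re-score with predicted neighbours contributing weight 1 as well.
#' Nodes that enter with tier `predicted` carry a state assigned by an
#' earlier pass: they are held fixed like anchors and contribute weight 1
#' from round 2 onwards. Each round is synchronous, so the result
#' is independent of edge or node input order. A node whose up and down
#' scores tie stays `undetermined` and contributes no weight to its
#' neighbours. Iteration stops at a fixed point or after `maxRounds`;
#' oscillating nodes (detected by a repeat of a full state vector) are
#' frozen as `undetermined` and reported.
#'
#' Anchored nodes never change state or tier.
#'
#' @param network a [RegulatoryNetwork-class] with at least one known-tier
#'   (anchored) node.
#' @param maxRounds maximum number of synchronous update rounds (default 25).
#' @return List with `assignments` (data.frame: `gene`, `state`, `tier`,
#'   `score_up`, `score_down`), `rounds` used, `converged` flag, and
#'   `oscillating` gene ids frozen as undetermined.
#' @export
predictStates <- function(network, maxRounds = 25L) {
  n <- nodeStates(network)
  known <- n$tier %in% c("qrt_confirmed", "array_reported")
  if (!any(known)) stop("nothing to propagate: no anchored nodes", call. = FALSE)

  states <- setNames(n$state, n$gene)
  tiers <- setNames(n$tier, n$gene)
  # pre-assigned predicted states are evidence from an earlier pass: kept
  # fixed, like anchors, but contributing weight 1 from round 2 onwards
  mutable <- sort(n$gene[n$tier == "unanchored"])
  inc <- incidenceTable(network)
  scoreUp <- scoreDown <- setNames(rep(NA_real_, nrow(n)), n$gene)
  frozen <- character(0L)
  history <- list(states)
  converged <- FALSE
  rounds <- 0L

  for (r in seq_len(maxRounds)) {
    rounds <- r
    w <- TIER_WEIGHTS[tiers] * (stateToSign(states) != 0L)
    if (r == 1L) w[!known[match(names(states), n$gene)]] <- 0  # known evidence only
    names(w) <- names(states)
    sc <- scoreAllNodes(inc, states, w)
    newStates <- states
    active <- setdiff(mutable, frozen)
    su <- ifelse(active %in% names(sc$up), sc$up[active], 0)
    sd2 <- ifelse(active %in% names(sc$down), sc$down[active], 0)
    su[is.na(su)] <- 0; sd2[is.na(sd2)] <- 0
    newStates[active] <- ifelse(su > sd2, "up",
                                ifelse(sd2 > su, "down", "undetermined"))
    scoreUp[active] <- su
    scoreDown[active] <- sd2
    tiers[active] <- ifelse(newStates[active] == "undetermined",
                            "unanchored", "predicted")

    if (identical(newStates, states) && r > 1L) {
      converged <- TRUE
      rounds <- r - 1L  # the final round confirmed the fixed point
      break
    }
    # oscillation: the full state vector revisits an earlier configuration
    rep_i <- which(vapply(history, identical, logical(1L), y = newStates))
    if (length(rep_i)) {
      cyc <- c(history[rep_i[1L]:length(history)], list(newStates))
      varying <- names(states)[vapply(names(states), function(g) {
        length(unique(vapply(cyc, `[[`, character(1L), g))) > 1L
      }, logical(1L))]
      frozen <- sort(union(frozen, intersect(varying, mutable)))
      newStates[frozen] <- "undetermined"
      tiers[frozen] <- "unanchored"
    }
    history <- c(history, list(newStates))
    states <- newStates
  }
  states <- if (exists("newStates")) newStates else states

  assignments <- data.frame(
    gene = n$gene,
    state = unname(states[n$gene]),
    tier = unname(tiers[n$gene]),
    score_up = unname(scoreUp[n$gene]),
    score_down = unname(scoreDown[n$gene]),
    stringsAsFactors = FALSE)
  list(assignments = assignments, rounds = rounds, converged = converged,
       oscillating = frozen)
}

#' Prune sign-inconsistent edges
#'
#' Removes every edge whose two endpoints both have determined states
#' (observed or predicted) and which fails the sign-consistency check; edges
#' touching an undetermined node are retained because they cannot be judged.
#' Removed edges are logged with their provenance.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param assignments result of [predictStates()] (or its `assignments`
#'   data.frame); defaults to the network's stored node states.
#' @return List with `network` (pruned, states updated from `assignments`)
#'   and `removed` (data.frame of dropped edges).
#' @export
pruneInconsistent <- function(network, assignments = NULL) {
  if (is.null(assignments)) assignments <- nodeStates(network)
  if (is.list(assignments) && !is.data.frame(assignments)) {
    assignments <- assignments$assignments
  }
  states <- setNames(stateToSign(assignments$state), assignments$gene)
  e <- regEdges(network)
  s <- states[e$source]
  t <- states[e$target]
  judged <- s != 0L & t != 0L
  bad <- judged & (t != e$sign * s)
  removed <- e[bad, , drop = FALSE]
  rownames(removed) <- NULL
  nodes <- nodeStates(network)
  i <- match(assignments$gene, nodes$gene)
  nodes$state[i[!is.na(i)]] <- assignments$state[!is.na(i)]
  nodes$tier[i[!is.na(i)]] <- assignments$tier[!is.na(i)]
  pruned <- new("RegulatoryNetwork", edges = e[!bad, , drop = FALSE],
                nodes = nodes, root = network@root)
  validObject(pruned)
  list(network = pruned, removed = removed)
}

#' Downstream-connection summary and hub genes
#'
#' Counts each gene's distinct downstream target genes (parallel edges to
#' the same target count once), tabulates the distribution, and reports hub
#' genes: nodes with at least `hubThreshold` downstream connections.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param hubThreshold minimum distinct-target count for a hub (default 7).
#' @return List with `out_degree` (data.frame `gene`, `n_targets`, all nodes),
#'   `histogram` (named integer vector: degree -> node count) and `hubs`
#'   (subset with `n_targets >= hubThreshold`, sorted decreasing).
#' @export
hubSummary <- function(network, hubThreshold = 7L) {
  n <- nodeStates(network)
  stopIfNot1(nrow(n) > 0L, "network has no nodes")
  e <- unique(regEdges(network)[, c("source", "target")])
  counts <- table(factor(e$source, levels = n$gene))
  od <- data.frame(gene = n$gene, n_targets = as.integer(counts),
                   stringsAsFactors = FALSE)
  hist <- table(od$n_targets)
  hubs <- od[od$n_targets >= hubThreshold, , drop = FALSE]
  hubs <- hubs[order(-hubs$n_targets, hubs$gene), , drop = FALSE]
  rownames(hubs) <- NULL
  list(out_degree = od,
       histogram = setNames(as.integer(hist), names(hist)),
       hubs = hubs)
}
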