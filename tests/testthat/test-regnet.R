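fig4b <- fig4bNetwork()

test_that("edge consistency is plain sign arithmetic", {
  expect_true(edgeConsistent(-1L, -1L, 1L))   # lost repressor -> target up
  expect_true(edgeConsistent(1L, 1L, 1L))
  expect_false(edgeConsistent(1L, 1L, -1L))
  expect_equal(edgeConsistent(c(1L, 1L), c(1L, -1L), c(1L, 1L)),
               c(TRUE, FALSE))
  expect_error(edgeConsistent(0L, 1L, 1L), "undetermined")
})

test_that("the worked intermediate-gene example scores 4 vs 3 and prunes two links", {
  down <- scoreHypothesis(fig4b, "Myod1", "down")
  up <- scoreHypothesis(fig4b, "Myod1", "up")
  expect_equal(down$score, 4)
  expect_equal(up$score, 3)
  # downstream evidence alone ties 2 vs 2
  downstreamOnly <- regulatoryNetwork(
    regEdges(fig4b)[regEdges(fig4b)$source == "Myod1", ],
    anchors = nodeStates(fig4b)[nodeStates(fig4b)$tier != "unanchored", ])
  expect_equal(scoreHypothesis(downstreamOnly, "Myod1", "down")$score, 2)
  expect_equal(scoreHypothesis(downstreamOnly, "Myod1", "up")$score, 2)

  pred <- predictStates(fig4b)
  a <- pred$assignments
  expect_equal(a$state[a$gene == "Myod1"], "down")
  expect_equal(a$tier[a$gene == "Myod1"], "predicted")

  pruned <- pruneInconsistent(fig4b, pred)
  rem <- pruned$removed[order(pruned$removed$source), ]
  expect_equal(nrow(rem), 2L)
  expect_equal(rem$source, c("Gpc1", "Myod1"))
  expect_equal(rem$target, c("Myod1", "Igll1"))
})

test_that("states propagate along a chain of activations", {
  net <- regulatoryNetwork(
    data.frame(source = c("A", "B"), target = c("B", "C"), sign = 1L),
    anchors = data.frame(gene = "A", state = "up", tier = "qrt_confirmed"))
  pred <- predictStates(net)
  st <- setNames(pred$assignments$state, pred$assignments$gene)
  expect_equal(unname(st[c("B", "C")]), c("up", "up"))
  expect_equal(pred$rounds, 2L)
  expect_true(pred$converged)
})

test_that("anchored nodes never change and inference needs an anchor", {
  pred <- predictStates(fig4b)
  a <- pred$assignments
  orig <- nodeStates(fig4b)
  anchored <- orig$tier %in% c("qrt_confirmed", "array_reported")
  expect_equal(a$state[match(orig$gene[anchored], a$gene)],
               orig$state[anchored])
  expect_equal(a$tier[match(orig$gene[anchored], a$gene)],
               orig$tier[anchored])
  bare <- regulatoryNetwork(
    data.frame(source = "A", target = "B", sign = 1L))
  expect_error(predictStates(bare), "nothing to propagate")
})

test_that("ties stay undetermined and contribute nothing", {
  net <- regulatoryNetwork(
    data.frame(source = c("U1", "U2", "M"), target = c("M", "M", "T"),
               sign = c(1L, -1L, 1L)),
    anchors = data.frame(gene = c("U1", "U2"), state = c("up", "up"),
                         tier = "qrt_confirmed"))
  pred <- predictStates(net)
  a <- pred$assignments
  expect_equal(a$state[a$gene == "M"], "undetermined")
  expect_equal(a$state[a$gene == "T"], "undetermined")
})

test_that("inference is invariant to edge input order", {
  g <- generateRegnet(synthNetworkSpec(n_nodes = 40, edge_probability = 0.06,
                                       anchor_fraction = 0.3, seed = 21))
  e <- regEdges(g$network)
  set.seed(1)
  shuffled <- regulatoryNetwork(e[sample(nrow(e)), ], anchors = g$anchors,
                                root = "miR96")
  p1 <- predictStates(g$network)
  p2 <- predictStates(shuffled)
  expect_equal(p1$assignments, p2$assignments)
  expect_equal(pruneInconsistent(g$network, p1)$removed,
               pruneInconsistent(shuffled, p2)$removed)
})

test_that("noise-free acyclic networks are fully recovered where reachable", {
  for (seed in 1:5) {
    g <- generateRegnet(synthNetworkSpec(
      n_nodes = 100, edge_probability = 0.03, anchor_fraction = 0.3,
      anchor_flip_probability = 0, acyclic = TRUE, seed = seed))
    pred <- predictStates(g$network)
    a <- pred$assignments
    st <- setNames(a$state, a$gene)
    e <- regEdges(g$network)
    comp <- igraph::components(igraph::graph_from_data_frame(
      e[, c("source", "target")], directed = FALSE,
      vertices = a$gene))$membership
    reachable <- names(comp)[comp %in% unique(comp[g$anchors$gene])]
    free <- setdiff(reachable, g$anchors$gene)
    expect_equal(mean(st[free] == g$truth[free]), 1,
                 info = sprintf("seed %d", seed))
  }
})

test_that("iterative decisions match the exhaustive consistency optimum", {
  set.seed(17)
  checked <- 0L
  for (rep in 1:30) {
    g <- generateRegnet(synthNetworkSpec(
      n_nodes = sample(6:10, 1L), edge_probability = 0.25,
      anchor_fraction = 0.5, acyclic = TRUE, seed = 100 + rep))
    a <- nodeStates(g$network)
    free <- a$gene[a$tier == "unanchored"]
    if (length(free) == 0L || length(free) > 10L) next
    fixed <- setNames(ifelse(a$state == "up", 1L,
                             ifelse(a$state == "down", -1L, NA_integer_)),
                      a$gene)
    oracle <- oracleJointStates(regEdges(g$network), fixed, free)
    pred <- predictStates(g$network)
    st <- setNames(pred$assignments$state, pred$assignments$gene)
    for (gn in free) {
      if (is.na(oracle$states[[gn]]) || st[[gn]] == "undetermined") next
      expect_equal(unname(ifelse(st[[gn]] == "up", 1L, -1L)),
                   oracle$states[[gn]],
                   info = sprintf("rep %d node %s", rep, gn))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20L)  # the comparison actually exercised nodes
})

test_that("pruning is sound and exact on planted inconsistencies", {
  # fully consistent network: nothing removed
  g <- generateRegnet(synthNetworkSpec(n_nodes = 30, edge_probability = 0.1,
                                       anchor_fraction = 1, seed = 2))
  stClean <- nodeStates(g$network)
  expect_equal(nrow(pruneInconsistent(g$network, stClean)$removed), 0L)

  # flip k planted edge signs -> exactly k removals
  e <- regEdges(g$network)
  set.seed(4)
  k <- 5L
  flip <- sample(nrow(e), k)
  e$sign[flip] <- -e$sign[flip]
  noisy <- regulatoryNetwork(e, anchors = stClean)
  res <- pruneInconsistent(noisy, stClean)
  expect_equal(nrow(res$removed), k)
  # post-condition: every surviving edge between determined nodes consistent
  st <- setNames(ifelse(stClean$state == "up", 1L, -1L), stClean$gene)
  e2 <- regEdges(res$network)
  expect_true(all(st[e2$target] == e2$sign * st[e2$source]))
})

test_that("hub summary counts distinct downstream targets", {
  e <- data.frame(source = c(rep("c", 4), "c"), target = c(paste0("l", 1:4), "l1"),
                  sign = c(rep(1L, 4), -1L))
  hs <- hubSummary(regulatoryNetwork(e), hubThreshold = 4)
  od <- setNames(hs$out_degree$n_targets, hs$out_degree$gene)
  expect_equal(unname(od["c"]), 4L)  # parallel edges to l1 count once
  expect_equal(unname(od["l2"]), 0L)
  expect_equal(hs$histogram, c("0" = 4L, "4" = 1L))
  expect_equal(hs$hubs$gene, "c")

  # the microRNA root with the packaged 31 direct targets
  targets <- compileDirectTargets(directTargetEvidence())
  root <- regulatoryNetwork(
    data.frame(source = "miR96", target = targets$gene, sign = -1L))
  hsRoot <- hubSummary(root)
  expect_equal(hsRoot$hubs$gene[1L], "miR96")
  expect_equal(hsRoot$hubs$n_targets[1L], 31L)
})
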