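test_that("spec constructors validate their parameters", {
  expect_error(synthNetworkSpec(n_nodes = 1), "n_nodes")
  expect_error(synthNetworkSpec(edge_probability = 0), "\\(0, 1\\]")
  expect_error(synthNetworkSpec(anchor_fraction = 1.2), "anchor_fraction")
  expect_error(synthUtrSpec(utr_length = 6), "utr_length")
  expect_error(synthUtrSpec(planted_word = "GTGCCA"), "7-mer")
  expect_error(synthUtrSpec(n_genes = 10, n_leading = 11), "cannot exceed")
  expect_error(synthQpcrSpec(n_pairs = 2), "n_pairs")
  expect_error(synthQpcrSpec(genes = c(Fos = -1)), "positive")
})

test_that("generators are deterministic and leave the global RNG untouched", {
  spec <- synthNetworkSpec(n_nodes = 50, seed = 42)
  a <- generateRegnet(spec)
  set.seed(999)
  before <- .Random.seed
  b <- generateRegnet(spec)
  expect_identical(.Random.seed, before)  # withSeed restores RNG state
  expect_identical(regEdges(a$network), regEdges(b$network))
  expect_identical(a$truth, b$truth)
  expect_identical(a$anchors, b$anchors)
  c <- generateRegnet(synthNetworkSpec(n_nodes = 50, seed = 43))
  expect_false(identical(regEdges(a$network), regEdges(c$network)))

  u1 <- generateRankedUtrs(synthUtrSpec(n_genes = 30, seed = 7))
  u2 <- generateRankedUtrs(synthUtrSpec(n_genes = 30, seed = 7))
  expect_identical(as.character(utrSequences(u1)),
                   as.character(utrSequences(u2)))
  q1 <- generateQpcrTable(synthQpcrSpec(seed = 7))
  q2 <- generateQpcrTable(synthQpcrSpec(seed = 7))
  expect_identical(q1, q2)
})

test_that("planted networks are exactly sign-consistent with the truth", {
  for (acyclic in c(TRUE, FALSE)) {
    g <- generateRegnet(synthNetworkSpec(n_nodes = 80, edge_probability = 0.04,
                                         acyclic = acyclic, seed = 13))
    e <- regEdges(g$network)
    st <- setNames(stateToSign(g$truth), names(g$truth))
    expect_true(all(st[e$target] == e$sign * st[e$source]))
    # the root is a pure repressor planted down, its targets up
    expect_true(all(e$sign[e$source == "miR96"] == -1L))
    expect_false(any(e$target == "miR96"))
    expect_equal(unname(g$truth["miR96"]), "down")
    expect_true(all(g$truth[e$target[e$source == "miR96"]] == "up"))
    if (acyclic) {
      ig <- igraph::graph_from_data_frame(e[, c("source", "target")])
      expect_true(igraph::is_dag(ig))
    }
  }
})

test_that("edge counts match the requested density in expectation", {
  p <- 0.03
  n <- 100L
  for (acyclic in c(TRUE, FALSE)) {
    counts <- vapply(1:20, function(s) {
      g <- generateRegnet(synthNetworkSpec(n_nodes = n, edge_probability = p,
                                           acyclic = acyclic,
                                           seed = 1000L + s))
      nrow(regEdges(g$network))
    }, numeric(1L))
    # expected n(n-1)p minus the (tiny) deficit from forbidden in-edges to
    # the root in the cyclic case; test within 4 binomial SDs of the mean
    expected <- n * (n - 1L) * p * if (acyclic) 1 else (1 - 1 / n)
    se <- sqrt(expected * (1 - p) / 20)
    expect_lt(abs(mean(counts) - expected), 4 * se)
  }
})

test_that("anchors report the truth and respect the tier split", {
  g <- generateRegnet(synthNetworkSpec(n_nodes = 100, anchor_fraction = 0.3,
                                       qrt_fraction = 0.5,
                                       anchor_flip_probability = 0, seed = 5))
  a <- g$anchors
  expect_equal(nrow(a), 30L)
  expect_true("miR96" %in% a$gene)
  expect_equal(sum(a$tier == "qrt_confirmed"), 15L)
  expect_equal(sum(a$tier == "array_reported"), 15L)
  expect_equal(a$state, unname(g$truth[a$gene]))
  # flips contradict the truth at roughly the requested rate
  flips <- vapply(1:10, function(s) {
    g <- generateRegnet(synthNetworkSpec(n_nodes = 100, anchor_fraction = 0.5,
                                         anchor_flip_probability = 0.2,
                                         seed = 50L + s))
    mean(g$anchors$state != g$truth[g$anchors$gene])
  }, numeric(1L))
  expect_gt(mean(flips), 0.1)
  expect_lt(mean(flips), 0.3)
  # zero anchors is a valid (if unusable) condition
  g0 <- generateRegnet(synthNetworkSpec(n_nodes = 50, anchor_fraction = 0,
                                        seed = 1))
  expect_equal(nrow(g0$anchors), 0L)
  # all network nodes exist even if isolated
  expect_equal(nrow(nodeStates(g0$network)), 50L)
})

test_that("UTR generator plants the word where and as often as requested", {
  spec <- synthUtrSpec(n_genes = 100, utr_length = 150, planted_word = "GTGCCAA",
                       planted_fraction = 0.8, n_leading = 20, seed = 2)
  ranked <- generateRankedUtrs(spec)
  seqs <- as.character(utrSequences(ranked))
  hasWord <- grepl("GTGCCAA", seqs, fixed = TRUE)
  expect_true(all(hasWord[1:16]))          # ceiling(0.8 * 20) planted
  expect_equal(length(ranked), 100L)
  expect_true(all(nchar(seqs) == 150L))
  # background occurrence beyond the planted block stays near the binomial
  # expectation for a random 7-mer: 1 - (1 - 4^-7)^(L - 6) per gene
  pBg <- 1 - (1 - 4^-7)^(150 - 6)
  nBg <- sum(hasWord[17:100])
  expect_lt(nBg, qbinom(0.9999, 84, pBg) + 1)
  # GC content steers composition
  gcRich <- generateRankedUtrs(synthUtrSpec(n_genes = 50, utr_length = 300,
                                            planted_fraction = 0,
                                            background_gc = 0.8, seed = 3))
  frac <- mean(Biostrings::letterFrequency(utrSequences(gcRich), "GC",
                                           as.prob = TRUE))
  expect_gt(frac, 0.75)
  expect_lt(frac, 0.85)
})

test_that("Ct tables encode the planted ratios exactly at zero noise", {
  tab <- generateQpcrTable(synthQpcrSpec(
    n_pairs = 4, genes = c(Ga = 0.25, Gb = 4), ct_noise_sd = 0, seed = 1))
  expect_setequal(unique(tab$gene), c("Hprt", "Jag1", "Ga", "Gb"))
  # per pair: reference and QC wells in both genotypes plus 2 genes x 2
  expect_equal(nrow(tab), 4L * (4L + 2L * 2L))
  w <- function(g, gt) tab$Ct[tab$gene == g & tab$genotype == gt]
  # ddCt arithmetic: ratio 0.25 -> hom Ct 2 cycles above wt
  expect_equal(unique(w("Ga", "hom") - w("Ga", "wt")), 2)
  expect_equal(unique(w("Gb", "hom") - w("Gb", "wt")), -2)
  expect_true(all(w("Hprt", "wt") == w("Hprt", "hom")))
  # violating pairs carry a QC ratio of exactly 1.5
  tabV <- generateQpcrTable(synthQpcrSpec(
    n_pairs = 5, genes = c(G = 1), qc_violation_fraction = 0.4, seed = 2))
  qc <- relativeExpression(
    tabV$Ct[tabV$gene == "Jag1" & tabV$genotype == "hom"],
    tabV$Ct[tabV$gene == "Hprt" & tabV$genotype == "hom"],
    tabV$Ct[tabV$gene == "Jag1" & tabV$genotype == "wt"],
    tabV$Ct[tabV$gene == "Hprt" & tabV$genotype == "wt"])
  expect_equal(sum(abs(qc - 1) > 0.30), 2L)
  expect_equal(sort(unique(round(qc, 10))), c(1, 1.5))
})
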