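#' Specification for a synthetic signed regulatory network
#'
#' Parameters of the planted-truth network generator. Defaults match the
#' study conditions the package's network tests assume: a 200-gene network
#' with 30% of nodes anchored by observed misregulation, half of the anchors
#' at the qRT-confirmed tier, and clean (unflipped) anchor states.
#'
#' @param n_nodes number of genes (>= 2), one of which plays the microRNA
#'   root.
#' @param edge_probability per ordered-pair edge probability in (0, 1].
#' @param repression_fraction target fraction of repression (-1) edges.
#' @param anchor_fraction fraction of nodes given observed states.
#' @param qrt_fraction fraction of anchors at the qRT-confirmed tier (the
#'   rest are array-reported).
#' @param anchor_flip_probability per-anchor probability that the observed
#'   state contradicts the planted truth (observation noise).
#' @param acyclic generate a directed acyclic network (default TRUE).
#' @param seed RNG seed; identical specs give byte-identical output.
#' @return A validated list of class `SynthNetworkSpec`.
#' @export
synthNetworkSpec <- function(n_nodes = 200L, edge_probability = 0.02,
                             repression_fraction = 0.4,
                             anchor_fraction = 0.3, qrt_fraction = 0.5,
                             anchor_flip_probability = 0,
                             acyclic = TRUE, seed = 1L) {
  checkCount(n_nodes, "n_nodes", min = 2L)
  checkFraction(edge_probability, "edge_probability")
  stopIfNot1(edge_probability > 0, "'edge_probability' must be in (0, 1]")
  checkFraction(repression_fraction, "repression_fraction")
  checkFraction(anchor_fraction, "anchor_fraction")
  checkFraction(qrt_fraction, "qrt_fraction")
  checkFraction(anchor_flip_probability, "anchor_flip_probability")
  stopIfNot1(is.logical(acyclic) && length(acyclic) == 1L,
             "'acyclic' must be a single logical")
  checkCount(seed, "seed")
  structure(list(n_nodes = as.integer(n_nodes),
                 edge_probability = edge_probability,
                 repression_fraction = repression_fraction,
                 anchor_fraction = anchor_fraction,
                 qrt_fraction = qrt_fraction,
                 anchor_flip_probability = anchor_flip_probability,
                 acyclic = acyclic, seed = as.integer(seed)),
            class = "SynthNetworkSpec")
}

#' Generate a synthetic signed network with planted misregulation states
#'
#' Builds a directed signed network whose edges are exactly consistent with
#' a planted ground-truth up/down state per gene, plus a set of anchors
#' reporting those states (possibly with flips). A designated root node
#' plays the microRNA: it is planted "down" (loss of wild-type function),
#' carries only outgoing repression edges, and its direct targets are
#' therefore planted "up".
#'
#' Truth states are assigned by propagation over a spanning forest of the
#' edge structure: root states are random, forest-edge signs are drawn with
#' the requested repression fraction and determine the child's state, and
#' every remaining edge's sign is then forced to `truth(u) * truth(v)` so
#' that the planted network is fully sign-consistent (the signal the
#' inference stage is meant to recover). With `acyclic = TRUE`, edges only
#' run forward along a random topological order and the per-pair inclusion
#' probability is doubled (capped at 1) to preserve the expected edge count
#' `n_nodes * (n_nodes - 1) * edge_probability`.
#'
#' @param spec a [synthNetworkSpec()].
#' @return List with `network` (a [RegulatoryNetwork-class] including the
#'   anchors), `truth` (named character vector, `up`/`down` per gene) and
#'   `anchors` (data.frame `gene`, `state`, `tier`).
#' @export
generateRegnet <- function(spec) {
  stopIfNot1(inherits(spec, "SynthNetworkSpec"),
             "spec must come from synthNetworkSpec()")
  withSeed(spec$seed, {
    nN <- spec$n_nodes
    genes <- c("miR96", sprintf("G%03d", seq_len(nN - 1L)))

    # edge sampling; the microRNA root never receives incoming edges
    if (spec$acyclic) {
      topo <- c("miR96", sample(genes[-1L]))
      pairs <- which(upper.tri(matrix(0, nN, nN)), arr.ind = TRUE)
      keep <- runif(nrow(pairs)) < min(1, 2 * spec$edge_probability)
      src <- topo[pairs[keep, 1L]]
      tgt <- topo[pairs[keep, 2L]]
    } else {
      pairs <- expand.grid(s = seq_len(nN), t = seq_len(nN))
      pairs <- pairs[pairs$s != pairs$t & pairs$t != 1L, ]  # no self loops, no in-edges to root
      keep <- runif(nrow(pairs)) < spec$edge_probability
      src <- genes[pairs$s[keep]]
      tgt <- genes[pairs$t[keep]]
    }
    edges <- data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]

    truth <- setNames(rep(NA_integer_, nN), genes)
    sign <- rep(NA_integer_, nrow(edges))

    # the microRNA root and its direct targets are fixed first
    truth["miR96"] <- -1L
    rootOut <- edges$source == "miR96"
    sign[rootOut] <- -1L
    truth[unique(edges$target[rootOut])] <- 1L

    # breadth-first propagation over the undirected constraint structure
    adj <- split(seq_len(nrow(edges)) * 2L - 1L, edges$source)
    adjIn <- split(seq_len(nrow(edges)) * 2L, edges$target)
    neighbours <- function(g) {
      ei <- c(adj[[g]], adjIn[[g]])
      if (is.null(ei)) integer(0L) else ei
    }
    queue <- names(truth)[!is.na(truth)]
    while (TRUE) {
      while (length(queue)) {
        g <- queue[[1L]]
        queue <- queue[-1L]
        for (code in neighbours(g)) {
          ei <- (code + 1L) %/% 2L
          other <- if (code %% 2L == 1L) edges$target[ei] else edges$source[ei]
          if (is.na(truth[other])) {
            s <- if (runif(1L) < spec$repression_fraction) -1L else 1L
            sign[ei] <- s
            truth[other] <- s * truth[g]
            queue <- c(queue, other)
          }
        }
      }
      rest <- names(truth)[is.na(truth)]
      if (!length(rest)) break
      # start a new component from a random root state
      seedNode <- rest[[1L]]
      truth[seedNode] <- sample(c(-1L, 1L), 1L)
      queue <- seedNode
    }
    # non-forest edges: sign forced by the planted states (consistency)
    na <- is.na(sign)
    sign[na] <- truth[edges$source[na]] * truth[edges$target[na]]

    edges$sign <- as.integer(sign)
    edges$directness <- sample(c("direct", "indirect"), nrow(edges),
                               replace = TRUE)
    edges$provenance <- "synthetic"

    # anchors: a sample of nodes reporting (possibly flipped) truth
    nAnchor <- round(spec$anchor_fraction * nN)
    anchors <- data.frame(gene = character(0L), state = character(0L),
                          tier = character(0L), stringsAsFactors = FALSE)
    if (nAnchor > 0L) {
      picked <- c("miR96", sample(setdiff(genes, "miR96"), nAnchor - 1L))
      nQrt <- round(spec$qrt_fraction * nAnchor)
      tier <- c(rep("qrt_confirmed", nQrt),
                rep("array_reported", nAnchor - nQrt))
      flips <- runif(nAnchor) < spec$anchor_flip_probability
      observed <- truth[picked] * ifelse(flips, -1L, 1L)
      anchors <- data.frame(gene = picked,
                            state = signToState(as.integer(observed)),
                            tier = tier, stringsAsFactors = FALSE)
      anchors <- anchors[order(anchors$gene), , drop = FALSE]
      rownames(anchors) <- NULL
    }
    # pad the anchor frame with unanchored placeholders so every spec gene
    # (isolated ones and the root included) exists in the network nodes
    unanchored <- setdiff(genes, anchors$gene)
    placeholders <- data.frame(gene = unanchored,
                               state = rep("undetermined", length(unanchored)),
                               tier = rep("unanchored", length(unanchored)),
                               stringsAsFactors = FALSE)
    net <- regulatoryNetwork(edges, anchors = rbind(anchors, placeholders),
                             root = "miR96")
    list(network = net,
         truth = setNames(signToState(unname(truth)), names(truth)),
         anchors = anchors)
  })
}

#' Specification for a synthetic ranked 3'UTR set
#'
#' @param n_genes number of genes in the ranking.
#' @param utr_length UTR length in bases (>= 7).
#' @param planted_word DNA 7-mer planted into leading genes (default the
#'   wild-type miR-96 seed match GTGCCAA).
#' @param planted_fraction fraction of the leading bin carrying at least one
#'   planted occurrence.
#' @param n_leading size of the leading bin that receives plantings
#'   (default `ceiling(n_genes / 5)`).
#' @param background_gc background GC content in \[0, 1\].
#' @param seed RNG seed.
#' @return A validated list of class `SynthUtrSpec`.
#' @export
synthUtrSpec <- function(n_genes = 500L, utr_length = 300L,
                         planted_word = "GTGCCAA", planted_fraction = 0.8,
                         n_leading = ceiling(n_genes / 5),
                         background_gc = 0.5, seed = 1L) {
  checkCount(n_genes, "n_genes", min = 1L)
  checkCount(utr_length, "utr_length", min = 7L)
  stopIfNot1(is.character(planted_word) && nchar(planted_word) == 7L &&
               grepl("^[ACGT]{7}$", planted_word),
             "'planted_word' must be a DNA 7-mer over {A,C,G,T}")
  checkFraction(planted_fraction, "planted_fraction")
  checkCount(n_leading, "n_leading", min = 0L)
  stopIfNot1(n_leading <= n_genes, "'n_leading' cannot exceed 'n_genes'")
  checkFraction(background_gc, "background_gc")
  checkCount(seed, "seed")
  structure(list(n_genes = as.integer(n_genes),
                 utr_length = as.integer(utr_length),
                 planted_word = planted_word,
                 planted_fraction = planted_fraction,
                 n_leading = as.integer(n_leading),
                 background_gc = background_gc, seed = as.integer(seed)),
            class = "SynthUtrSpec")
}

#' Generate a ranked UTR set with a planted heptamer
#'
#' Simulates the substrate of the word-enrichment landscape: genes ordered
#' most-upregulated first, each with an i.i.d. random 3'UTR at the requested
#' GC content, and the planted word written at a uniform random position
#' into the first `ceiling(planted_fraction * n_leading)` genes.
#'
#' @param spec a [synthUtrSpec()].
#' @return A [RankedUtrSet-class].
#' @export
generateRankedUtrs <- function(spec) {
  stopIfNot1(inherits(spec, "SynthUtrSpec"),
             "spec must come from synthUtrSpec()")
  withSeed(spec$seed, {
    gc <- spec$background_gc
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    mat <- matrix(sample(names(probs), spec$n_genes * spec$utr_length,
                         replace = TRUE, prob = probs),
                  nrow = spec$n_genes)
    seqs <- apply(mat, 1L, paste0, collapse = "")
    nPlant <- ceiling(spec$planted_fraction * spec$n_leading)
    if (nPlant > 0L) {
      pos <- sample.int(spec$utr_length - 6L, nPlant, replace = TRUE)
      for (i in seq_len(nPlant)) {
        substr(seqs[i], pos[i], pos[i] + 6L) <- spec$planted_word
      }
    }
    names(seqs) <- sprintf("gene%04d", seq_len(spec$n_genes))
    rankedUtrSet(Biostrings::DNAStringSet(seqs))
  })
}

#' Specification for a synthetic littermate-pair Ct table
#'
#' @param n_pairs number of wildtype/homozygote littermate pairs (>= 3).
#' @param genes named numeric vector of target genes and their true
#'   mutant/wildtype expression ratios (all > 0).
#' @param ct_noise_sd Gaussian noise SD on target-gene Ct values (cycles).
#' @param qc_violation_fraction fraction of pairs constructed to violate the
#'   30% QC rule (their QC-gene ratio is set to 1.5).
#' @param seed RNG seed.
#' @return A validated list of class `SynthQpcrSpec`.
#' @export
synthQpcrSpec <- function(n_pairs = 5L, genes = c(Fos = 0.67),
                          ct_noise_sd = 0.1, qc_violation_fraction = 0,
                          seed = 1L) {
  checkCount(n_pairs, "n_pairs", min = 3L)
  stopIfNot1(is.numeric(genes) && length(genes) >= 1L &&
               !is.null(names(genes)) && all(genes > 0),
             "'genes' must be a named vector of positive true ratios")
  stopIfNot1(is.numeric(ct_noise_sd) && length(ct_noise_sd) == 1L &&
               ct_noise_sd >= 0, "'ct_noise_sd' must be a single sd >= 0")
  checkFraction(qc_violation_fraction, "qc_violation_fraction")
  checkCount(seed, "seed")
  structure(list(n_pairs = as.integer(n_pairs), genes = genes,
                 ct_noise_sd = ct_noise_sd,
                 qc_violation_fraction = qc_violation_fraction,
                 seed = as.integer(seed)),
            class = "SynthQpcrSpec")
}

#' Generate a littermate-pair Ct table
#'
#' Simulates raw qRT-PCR cycle thresholds for target genes, the reference
#' gene (`Hprt`) and the tissue-QC gene (`Jag1`), per littermate pair and
#' genotype. Target Ct values are Gaussian around gene-specific means, with
#' the mutant mean shifted by `-log2(true ratio)` so the expected 2^-ddCt
#' equals the specified ratio; reference and QC wells are deterministic, so
#' exactly `round(qc_violation_fraction * n_pairs)` pairs violate the 30%
#' QC rule (their QC ratio is 1.5) at any noise level.
#'
#' @param spec a [synthQpcrSpec()].
#' @return Long-format data.frame with columns `pair_id`, `genotype`
#'   (`wt`/`hom`), `gene`, `Ct`.
#' @export
generateQpcrTable <- function(spec) {
  stopIfNot1(inherits(spec, "SynthQpcrSpec"),
             "spec must come from synthQpcrSpec()")
  withSeed(spec$seed, {
    pairs <- sprintf("P%02d", seq_len(spec$n_pairs))
    nViol <- round(spec$qc_violation_fraction * spec$n_pairs)
    violating <- if (nViol > 0L) sample(pairs, nViol) else character(0L)

    rows <- list()
    addRow <- function(pair, genotype, gene, ct) {
      rows[[length(rows) + 1L]] <<- data.frame(
        pair_id = pair, genotype = genotype, gene = gene, Ct = ct,
        stringsAsFactors = FALSE)
    }
    refCt <- 20
    qcWtCt <- 22
    targetWtMean <- 25
    for (p in pairs) {
      addRow(p, "wt", "Hprt", refCt)
      addRow(p, "hom", "Hprt", refCt)
      addRow(p, "wt", "Jag1", qcWtCt)
      qcRatio <- if (p %in% violating) 1.5 else 1.0
      addRow(p, "hom", "Jag1", qcWtCt - log2(qcRatio))
      for (g in names(spec$genes)) {
        wtCt <- targetWtMean + rnorm(1L, 0, spec$ct_noise_sd)
        homCt <- targetWtMean - log2(spec$genes[[g]]) +
          rnorm(1L, 0, spec$ct_noise_sd)
        addRow(p, "wt", g, wtCt)
        addRow(p, "hom", g, homCt)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
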