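SIGN_TOKENS <- c("+1" = 1L, "1" = 1L, "-1" = -1L,
                 "activates" = 1L, "represses" = -1L)

# full-precision TSV writers so tables round-trip bit-exactly
formatFull <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  } else {
    as.character(x)
  }
}

#' Write a data.frame as a full-precision TSV
#'
#' Doubles are serialised with 17 significant digits so that
#' write-then-read round trips preserve every field bit-exactly.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  out <- as.data.frame(lapply(x, formatFull), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(x)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a TSV written by [writeTsv()] (or any headered TSV)
#'
#' @param path input path.
#' @return data.frame with character columns converted to numeric where the
#'   whole column parses as numbers.
#' @export
readTsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character", na.strings = "NA")
  for (j in seq_along(x)) {
    v <- x[[j]]
    parsed <- suppressWarnings(as.numeric(v))
    if (!any(is.na(parsed) & !is.na(v))) x[[j]] <- parsed
  }
  x
}

#' Read a signed regulatory edge table
#'
#' Expects a TSV with header columns `source`, `target`, `sign` and
#' optionally `directness` and `provenance`. Sign accepts `+1`, `-1`,
#' `activates`, `represses`. Errors name the offending file line; duplicate
#' (source, target, sign) rows are removed with a warning.
#'
#' @param path TSV path.
#' @return Validated edge data.frame suitable for [regulatoryNetwork()].
#' @export
readEdgeTable <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  need <- c("source", "target", "sign")
  stopIfNot1(all(need %in% names(raw)),
             sprintf("%s: edge table must have columns %s", path,
                     paste(need, collapse = ", ")))
  sign <- SIGN_TOKENS[raw$sign]
  if (anyNA(sign)) {
    bad <- which(is.na(sign))[1L]
    stop(sprintf("%s: unknown sign token '%s' on line %d", path,
                 raw$sign[bad], bad + 1L), call. = FALSE)
  }
  loops <- which(raw$source == raw$target)
  if (length(loops)) {
    stop(sprintf("%s: self-loop edge on line %d", path, loops[1L] + 1L),
         call. = FALSE)
  }
  edges <- data.frame(
    source = raw$source, target = raw$target, sign = unname(sign),
    directness = if (is.null(raw$directness)) "direct" else raw$directness,
    provenance = if (is.null(raw$provenance)) "" else raw$provenance,
    stringsAsFactors = FALSE)
  dup <- duplicated(edges[, c("source", "target", "sign")])
  if (any(dup)) {
    warning(sprintf("%s: removed %d duplicate edge(s)", path, sum(dup)),
            call. = FALSE)
    edges <- edges[!dup, , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges
}

#' Write a regulatory edge table
#'
#' @param edges edge data.frame (or a [RegulatoryNetwork-class]).
#' @param path output TSV path.
#' @export
writeEdgeTable <- function(edges, path) {
  if (is(edges, "RegulatoryNetwork")) edges <- regEdges(edges)
  e <- edges
  e$sign <- ifelse(e$sign > 0, "+1", "-1")
  writeTsv(e, path)
}

#' Read an anchor (observed node state) table
#'
#' TSV with columns `gene`, `state` (`up`/`down`), `tier`.
#'
#' @param path TSV path.
#' @return data.frame for the `anchors` argument of [regulatoryNetwork()].
#' @export
readAnchorTable <- function(path) {
  a <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  stopIfNot1(all(c("gene", "state", "tier") %in% names(a)),
             sprintf("%s: anchor table must have columns gene, state, tier",
                     path))
  bad <- which(!a$state %in% VALID_STATES)
  if (length(bad)) {
    stop(sprintf("%s: invalid state '%s' on line %d", path, a$state[bad[1L]],
                 bad[1L] + 1L), call. = FALSE)
  }
  bad <- which(!a$tier %in% VALID_TIERS)
  if (length(bad)) {
    stop(sprintf("%s: invalid tier '%s' on line %d", path, a$tier[bad[1L]],
                 bad[1L] + 1L), call. = FALSE)
  }
  a
}

#' Read a littermate-pair Ct table
#'
#' TSV with columns `pair_id`, `genotype` (`wt`/`hom`), `gene`, `Ct`.
#'
#' @param path TSV path.
#' @return data.frame for [qpcrTest()].
#' @export
readCtTable <- function(path) {
  ct <- readTsv(path)
  need <- c("pair_id", "genotype", "gene", "Ct")
  stopIfNot1(all(need %in% names(ct)),
             sprintf("%s: Ct table must have columns %s", path,
                     paste(need, collapse = ", ")))
  bad <- which(!ct$genotype %in% c("wt", "hom"))
  if (length(bad)) {
    stop(sprintf("%s: genotype must be wt/hom (line %d)", path, bad[1L] + 1L),
         call. = FALSE)
  }
  ct$Ct <- as.numeric(ct$Ct)
  ct
}

#' Read gene sets in GMT format
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path GMT path.
#' @return Named list of character vectors; descriptions in attribute
#'   `"description"`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1L)) < 3L
  if (any(short)) {
    stop(sprintf("%s: malformed GMT record on line %d (need name, description, genes)",
                 path, which(short)[1L]), call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1L), 2L)
  sets
}

#' Read 3'UTR sequences plus a gene ranking
#'
#' Combines a FASTA of UTRs with a two-column ranking TSV (`gene`, `rank`;
#' rank 1 = most upregulated). Genes present in the FASTA but missing from
#' the ranking are dropped with a warning; ranked genes lacking a sequence
#' are reported and dropped with a warning.
#'
#' @param fastaPath FASTA of 3'UTR sequences named by gene id.
#' @param rankingPath ranking TSV.
#' @return A [RankedUtrSet-class] in ranking order.
#' @export
readFastaWithRanking <- function(fastaPath, rankingPath) {
  utrs <- Biostrings::readDNAStringSet(fastaPath)
  names(utrs) <- sub("\\s.*$", "", names(utrs))
  if (anyDuplicated(names(utrs))) {
    stop(sprintf("%s: duplicate FASTA id '%s'", fastaPath,
                 names(utrs)[duplicated(names(utrs))][1L]), call. = FALSE)
  }
  rk <- readTsv(rankingPath)
  stopIfNot1(all(c("gene", "rank") %in% names(rk)),
             sprintf("%s: ranking must have columns gene, rank", rankingPath))
  stopIfNot1(nrow(rk) > 0L, sprintf("%s: ranking is empty", rankingPath))
  rk <- rk[order(rk$rank), , drop = FALSE]
  noSeq <- setdiff(rk$gene, names(utrs))
  if (length(noSeq)) {
    warning(sprintf("ranked gene(s) without a UTR sequence, dropped: %s",
                    paste(noSeq, collapse = ", ")), call. = FALSE)
    rk <- rk[!rk$gene %in% noSeq, , drop = FALSE]
  }
  unranked <- setdiff(names(utrs), rk$gene)
  if (length(unranked)) {
    warning(sprintf("%d FASTA sequence(s) not in the ranking, dropped",
                    length(unranked)), call. = FALSE)
  }
  stopIfNot1(nrow(rk) > 0L, "no gene has both a rank and a sequence")
  rankedUtrSet(utrs[rk$gene])
}

#' Write a RankedUtrSet as FASTA plus ranking TSV
#'
#' @param ranked a [RankedUtrSet-class].
#' @param fastaPath,rankingPath output paths.
#' @export
writeRankedUtrs <- function(ranked, fastaPath, rankingPath) {
  Biostrings::writeXStringSet(utrSequences(ranked), fastaPath)
  writeTsv(data.frame(gene = geneRanking(ranked),
                      rank = seq_len(length(ranked))), rankingPath)
  invisible(fastaPath)
}

#' Export a network in SIF format
#'
#' One line per edge: `source  relation  target`, with relation `activates`
#' or `represses`, for use in graph viewers.
#'
#' @param network a [RegulatoryNetwork-class] or edge data.frame.
#' @param path output path.
#' @export
writeSif <- function(network, path) {
  e <- if (is(network, "RegulatoryNetwork")) regEdges(network) else network
  rel <- ifelse(e$sign > 0, "activates", "represses")
  writeLines(paste(e$source, rel, e$target, sep = "\t"), path)
  invisible(path)
}

# ---- packaged fixtures -----------------------------------------------------

fixturePath <- function(name) {
  p <- system.file("extdata", name, package = "regsign", mustWork = FALSE)
  stopIfNot1(nzchar(p), sprintf("packaged fixture '%s' not found", name))
  p
}

#' The worked intermediate-gene scoring neighbourhood
#'
#' A five-node fixture reproducing the published worked example of the
#' tiered weighting scheme: the intermediate gene Myod1 with two known
#' downstream genes (one consistent with each hypothesis), one
#' qRT-confirmed upstream regulator favouring downregulation, and one
#' predicted upstream regulator (Gpc1) favouring upregulation. Downstream
#' evidence alone ties 2 vs 2; with the regulators the down hypothesis
#' scores 4 against 3, so Myod1 is predicted down and the two
#' up-supporting links (Myod1 to Igll1, Gpc1 to Myod1) are pruned. Only
#' Myod1, Igll1 and Gpc1 are published gene names; the other two
#' neighbours are synthetic placeholders (`TargetB_syn`, `RegulatorA_syn`)
#' standing in for nodes whose identity is not recoverable from the figure
#' caption.
#'
#' @return A [RegulatoryNetwork-class].
#' @export
fig4bNetwork <- function() {
  edges <- readEdgeTable(fixturePath("myod1_neighbourhood_edges.tsv"))
  anchors <- readAnchorTable(fixturePath("myod1_neighbourhood_anchors.tsv"))
  regulatoryNetwork(edges, anchors = anchors)
}

#' Direct-target evidence table
#'
#' The packaged evidence table for the 31 direct targets of miR-96:
#' 19 literature-confirmed genes, 3 luciferase-confirmed genes, 7 genes
#' upregulated in mutants with a seed match in their 3'UTR, and 2
#' predicted-and-expressed genes (Zic2, Osbpl2).
#'
#' @return data.frame `gene`, `category`, `citation`.
#' @export
directTargetEvidence <- function() {
  readTsv(fixturePath("mir96_direct_target_evidence.tsv"))
}

#' Published high-degree PPI node table
#'
#' The packaged table of PPI-network nodes reported with degree above 75,
#' with their normalised betweenness and closeness centralities and, where
#' known, misregulation fold change and adjusted p-value.
#'
#' @return data.frame `node`, `degree`, `betweenness`, `closeness`,
#'   `fold_change`, `adj_p`.
#' @export
ppiDegreeTable <- function() {
  readTsv(fixturePath("ppi_high_degree_nodes.tsv"))
}

#' Published qRT-PCR panel summary statistics
#'
#' Packaged per-gene summaries (group sizes, means, SDs and rank-sum
#' p-values) of the four qRT-PCR panels: `"array_confirmation"` (ten genes
#' tested to confirm microarray misregulation), `"intermediate_candidates"`
#' (nine candidate intermediate regulators), `"pulldown_targets"` (eight
#' candidate direct targets from the pulldown assay) and `"network_nodes"`
#' (eight network nodes including Fos).
#'
#' @param panel one of the four panel names.
#' @return data.frame `gene`, `n_wt`, `mean_wt`, `sd_wt`, `n_hom`,
#'   `mean_hom`, `sd_hom`, `p`.
#' @export
qpcrPanelStats <- function(panel = c("array_confirmation",
                                     "intermediate_candidates",
                                     "pulldown_targets", "network_nodes")) {
  panel <- match.arg(panel)
  x <- readTsv(fixturePath("qpcr_panel_stats.tsv"))
  out <- x[x$panel == panel, setdiff(names(x), "panel"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- pipeline --------------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Binds the stages end to end on file inputs: expression-evidence
#' compilation, network state prediction and pruning with hub summaries,
#' word-landscape scanning of ranked UTRs, and qRT-PCR testing. Stages
#' whose inputs are not supplied are skipped. All outputs are written as
#' full-precision TSVs plus a machine-readable JSON manifest recording the
#' package version, the configuration (with an md5 content hash) and the
#' seed, so a rerun with the same config is byte-identical.
#'
#' @param config named list: input paths (`edges`, `anchors`, `expression`,
#'   `targets`, `utr_fasta`, `utr_ranking`, `ct`), options (`word`,
#'   `reference`, `qc`, and the thresholds `array_alpha` 0.1, `qpcr_alpha`
#'   0.05, `fc_threshold` 0.10, `qc_tolerance` 0.30, `hub_threshold` 7,
#'   `degree_threshold` 75, `max_rounds` 25), `seed`, and `out_dir`.
#' @return The manifest list, invisibly; outputs under `config$out_dir`.
#' @export
runPipeline <- function(config) {
  defaults <- list(array_alpha = 0.1, qpcr_alpha = 0.05, fc_threshold = 0.10,
                   qc_tolerance = 0.30, hub_threshold = 7L,
                   degree_threshold = 75, max_rounds = 25L,
                   reference = "Hprt", qc = "Jag1", seed = 1L)
  config <- utils::modifyList(defaults, config)
  stopIfNot1(!is.null(config$out_dir), "config$out_dir is required")
  inputs <- intersect(names(config),
                      c("edges", "anchors", "expression", "targets",
                        "utr_fasta", "utr_ranking", "ct"))
  missing <- inputs[!vapply(config[inputs], file.exists, logical(1L))]
  if (length(missing)) {
    stop(sprintf("missing input path(s): %s",
                 paste(unlist(config[missing]), collapse = ", ")),
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outFile <- function(name) file.path(config$out_dir, name)
  counts <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 outFile("FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (!is.null(config$expression)) {
    stage("gene_lists", {
      records <- readTsv(config$expression)
      mis <- compileMisregulated(records, config$array_alpha,
                                 config$qpcr_alpha)
      writeTsv(mis, outFile("misregulated.tsv"))
      ranked <- gseaInput(collapseProbes(records), config$fc_threshold)
      writeTsv(ranked, outFile("gsea_input.rnk.tsv"))
      counts$n_misregulated <- nrow(mis)
      if (!is.null(config$targets)) {
        tg <- compileDirectTargets(readTsv(config$targets))
        writeTsv(tg, outFile("direct_targets.tsv"))
        counts$n_direct_targets <- nrow(tg)
      }
    })
  }

  if (!is.null(config$edges)) {
    stage("network", {
      anchors <- if (!is.null(config$anchors)) {
        readAnchorTable(config$anchors)
      }
      net <- regulatoryNetwork(readEdgeTable(config$edges), anchors = anchors)
      pred <- predictStates(net, maxRounds = config$max_rounds)
      writeTsv(pred$assignments, outFile("assignments.tsv"))
      pruned <- pruneInconsistent(net, pred)
      writeEdgeTable(pruned$network, outFile("pruned_edges.tsv"))
      writeTsv(pruned$removed, outFile("removed_edges.tsv"))
      writeSif(pruned$network, outFile("network.sif"))
      hubs <- hubSummary(pruned$network, config$hub_threshold)
      writeTsv(hubs$hubs, outFile("hubs.tsv"))
      st <- pred$assignments$state
      counts$n_anchored <-
        sum(nodeStates(net)$tier %in% c("qrt_confirmed", "array_reported"))
      counts$n_predicted_up <-
        sum(st == "up" & pred$assignments$tier == "predicted")
      counts$n_predicted_down <-
        sum(st == "down" & pred$assignments$tier == "predicted")
      counts$n_undetermined <- sum(st == "undetermined")
      counts$n_pruned_edges <- nrow(pruned$removed)
      counts$n_hubs <- nrow(hubs$hubs)
      counts$prediction_rounds <- pred$rounds
    })
  }

  if (!is.null(config$utr_fasta) && !is.null(config$utr_ranking)) {
    stage("seedscan", {
      ranked <- readFastaWithRanking(config$utr_fasta, config$utr_ranking)
      word <- if (is.null(config$word)) "GTGCCAA" else config$word
      land <- wordLandscape(ranked, word)
      writeTsv(land, outFile("word_landscape.tsv"))
      counts$landscape_peak_score <- max(abs(land$score))
      counts$landscape_word <- word
    })
  }

  if (!is.null(config$ct)) {
    stage("qpcr", {
      res <- qpcrTest(readCtTable(config$ct), reference = config$reference,
                      qc = config$qc, tolerance = config$qc_tolerance)
      writeTsv(res, outFile("qpcr_results.tsv"))
      excl <- attr(res, "excluded_pairs")
      writeTsv(excl, outFile("qpcr_excluded_pairs.tsv"))
      counts$n_qpcr_genes <- nrow(res)
      counts$n_qpcr_pairs_excluded <- nrow(excl)
    })
  }

  cfgForHash <- config[order(names(config))]
  cfgJson <- jsonlite::toJSON(cfgForHash, auto_unbox = TRUE, digits = NA)
  tmp <- outFile("config.json")
  writeLines(cfgJson, tmp)
  manifest <- list(
    package_version = as.character(packageVersion("regsign")),
    config = cfgForHash,
    config_md5 = unname(md5sum(tmp)),
    seed = config$seed,
    summary = counts)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             outFile("manifest.json"))
  invisible(manifest)
}
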