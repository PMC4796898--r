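ARRAY_SOURCES <- c("array_P0", "array_P4")
EXPR_SOURCES <- c(ARRAY_SOURCES, "qrtpcr")
TARGET_CATEGORIES <- c("literature_confirmed", "luciferase_confirmed",
                       "upregulated_with_seed_match", "predicted_and_expressed")

checkExpressionRecords <- function(records) {
  need <- c("gene", "source", "fold_change", "p", "adj_p")
  stopIfNot1(is.data.frame(records) && all(need %in% names(records)),
             sprintf("expression records need columns: %s",
                     paste(need, collapse = ", ")))
  stopIfNot1(all(records$source %in% EXPR_SOURCES),
             sprintf("record sources must be one of: %s",
                     paste(EXPR_SOURCES, collapse = ", ")))
  pv <- c(records$p, records$adj_p)
  stopIfNot1(all(is.na(pv) | (pv >= 0 & pv <= 1)), "p-values must lie in [0, 1]")
  stopIfNot1(all(abs(records$fold_change) >= 1),
             "signed fold changes must satisfy |fc| >= 1")
  invisible(records)
}

#' Compile the misregulated gene list
#'
#' Applies the evidence-combination rule used to assemble the network input:
#' a gene enters the list when any microarray record (P0 or P4) has adjusted
#' p below `arrayAlpha` (default 0.1, deliberately lenient to maximise
#' genes available for network construction) or any qRT-PCR record has
#' adjusted p below `qpcrAlpha` (default 0.05). The attached quantitative
#' value is the significant qRT-PCR fold change when one exists; otherwise
#' the significant microarray value is used (P4 preferred over P0 when both
#' are significant). Genes whose significant sources disagree in sign are
#' kept but flagged.
#'
#' @param records expression-record data.frame: `gene`, optional `probe`,
#'   `source` (one of `array_P0`, `array_P4`, `qrtpcr`), signed
#'   `fold_change`, `p`, `adj_p`.
#' @param arrayAlpha adjusted-p threshold for microarray evidence.
#' @param qpcrAlpha adjusted-p threshold for qRT-PCR evidence.
#' @return data.frame with one row per included gene: `gene`,
#'   `fold_change`, `source_used`, `sign_conflict`.
#' @export
compileMisregulated <- function(records, arrayAlpha = 0.1, qpcrAlpha = 0.05) {
  if (nrow(records) == 0L) {
    return(data.frame(gene = character(0L), fold_change = numeric(0L),
                      source_used = character(0L), sign_conflict = logical(0L)))
  }
  checkExpressionRecords(records)
  sig <- (records$source %in% ARRAY_SOURCES & records$adj_p < arrayAlpha) |
    (records$source == "qrtpcr" & records$adj_p < qpcrAlpha)
  sigRec <- records[sig & !is.na(sig), , drop = FALSE]
  if (nrow(sigRec) == 0L) {
    return(data.frame(gene = character(0L), fold_change = numeric(0L),
                      source_used = character(0L), sign_conflict = logical(0L)))
  }
  rows <- lapply(split(sigRec, sigRec$gene), function(g) {
    # prefer confirmed qRT-PCR values; among arrays prefer P4
    pref <- match(g$source, c("qrtpcr", "array_P4", "array_P0"))
    pick <- g[order(pref, g$adj_p), , drop = FALSE][1L, ]
    data.frame(gene = pick$gene, fold_change = pick$fold_change,
               source_used = pick$source,
               sign_conflict = length(unique(sign(g$fold_change))) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$sign_conflict)) {
    warning(sprintf("sign conflict between significant sources for: %s",
                    paste(out$gene[out$sign_conflict], collapse = ", ")),
            call. = FALSE)
  }
  out[order(out$gene), , drop = FALSE]
}

#' Compile the direct-target gene set
#'
#' Unions the four evidence categories for direct microRNA targets
#' (literature-confirmed, luciferase-confirmed, upregulated with a 3'UTR
#' seed match, predicted-and-expressed) into a deduplicated gene set,
#' retaining the category provenance of every gene.
#'
#' @param evidence data.frame with columns `gene`, `category` (one of the
#'   four above) and optionally `citation`.
#' @return data.frame with one row per unique gene: `gene`, `categories`
#'   (comma-joined), sorted by gene; row count is the size of the target
#'   set.
#' @export
compileDirectTargets <- function(evidence) {
  if (is.null(evidence) || nrow(evidence) == 0L) {
    return(data.frame(gene = character(0L), categories = character(0L)))
  }
  stopIfNot1(all(c("gene", "category") %in% names(evidence)),
             "evidence needs columns gene, category")
  bad <- setdiff(unique(evidence$category), TARGET_CATEGORIES)
  if (length(bad)) {
    stop(sprintf("unknown evidence category: %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(TARGET_CATEGORIES, collapse = ", ")), call. = FALSE)
  }
  stopIfNot1(all(nzchar(evidence$gene)), "empty gene id in evidence")
  byGene <- split(as.character(evidence$category), as.character(evidence$gene))
  out <- data.frame(
    gene = names(byGene),
    categories = vapply(byGene, function(x)
      paste(sort(unique(x)), collapse = ","), character(1L)),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse multiple probes to one record per gene
#'
#' Where several probes measure the same gene, the record with the lowest
#' raw p-value survives; ties are broken towards the larger absolute fold
#' change and logged in the `"ties"` attribute.
#'
#' @param records expression-record data.frame (see
#'   [compileMisregulated()]).
#' @return One record per gene, sorted by gene; attribute `"ties"` lists
#'   genes where a p-value tie was broken.
#' @export
collapseProbes <- function(records) {
  if (nrow(records) == 0L) return(records)
  checkExpressionRecords(records)
  ties <- character(0L)
  rows <- lapply(split(records, records$gene), function(g) {
    best <- g[g$p == min(g$p), , drop = FALSE]
    if (nrow(best) > 1L) {
      ties <<- c(ties, best$gene[1L])
      best <- best[order(-abs(best$fold_change)), , drop = FALSE]
    }
    best[1L, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ties") <- ties
  out
}

#' Build the ranked input table for gene set enrichment
#'
#' Retains genes whose expression changed by more than 10% — on the signed
#' fold-change scale, `|fc| >= 1 + fcThreshold` — and orders them by signed
#' fold change, most upregulated first. The input should already be
#' collapsed to one record per gene ([collapseProbes()]).
#'
#' @param records per-gene expression records.
#' @param fcThreshold minimum fractional change (default 0.10).
#' @return data.frame `gene`, `fold_change`, sorted decreasing.
#' @export
gseaInput <- function(records, fcThreshold = 0.10) {
  if (nrow(records) == 0L) {
    return(data.frame(gene = character(0L), fold_change = numeric(0L)))
  }
  checkExpressionRecords(records)
  stopIfNot1(!anyDuplicated(records$gene),
             "records must be collapsed to one row per gene first")
  keep <- abs(records$fold_change) >= 1 + fcThreshold
  out <- records[keep, c("gene", "fold_change"), drop = FALSE]
  out <- out[order(-out$fold_change, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query list against a
#' gene universe: the p-value is the upper hypergeometric tail
#' P(overlap >= observed) for drawing `|query|` genes from the universe,
#' and p-values are Benjamini-Hochberg adjusted across all tested sets.
#' Gene sets are intersected with the universe before testing.
#'
#' @param query character vector of query genes (must lie in `universe`).
#' @param geneSets named list of character vectors (e.g. from
#'   [readGmt()]).
#' @param universe character vector of all considered genes.
#' @return data.frame per set: `set`, `set_size` (within universe),
#'   `overlap`, `p`, `adj_p`, ordered by `p`.
#' @export
oraHypergeometric <- function(query, geneSets, universe) {
  universe <- unique(as.character(universe))
  stopIfNot1(length(universe) > 0L, "universe is empty")
  query <- unique(as.character(query))
  extra <- setdiff(query, universe)
  if (length(extra)) {
    stop(sprintf("query genes absent from universe: %s",
                 paste(head(extra, 5L), collapse = ", ")), call. = FALSE)
  }
  stopIfNot1(is.list(geneSets) && !is.null(names(geneSets)),
             "geneSets must be a named list")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(unique(as.character(geneSets[[nm]])), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (K == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bhAdjust(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine compiled lists and their overlap
#'
#' @param directTargets output of [compileDirectTargets()].
#' @param misregulated output of [compileMisregulated()].
#' @return List with `direct_targets`, `misregulated` and `overlap` (genes
#'   in both).
#' @export
compiledLists <- function(directTargets, misregulated) {
  list(direct_targets = directTargets,
       misregulated = misregulated,
       overlap = sort(intersect(directTargets$gene, misregulated$gene)))
}
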