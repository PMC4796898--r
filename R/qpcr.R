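#' Relative expression by the 2^-ddCt method
#'
#' Computes relative expression of a target gene in mutant versus wildtype
#' tissue from raw qRT-PCR cycle thresholds (Ct), normalising each genotype
#' by a reference gene (the `Hprt` role):
#' \deqn{2^{-[(Ct_{t,mut} - Ct_{ref,mut}) - (Ct_{t,wt} - Ct_{ref,wt})]}}
#' A value of 1 means no change; 0.5 means the target is at half the
#' wildtype level in the mutant.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param ctTargetMut,ctRefMut target and reference Ct in the mutant sample
#'   (cycles).
#' @param ctTargetWt,ctRefWt target and reference Ct in the wildtype sample.
#' @return Numeric vector of positive relative-expression ratios.
#' @examples
#' relativeExpression(21, 20, 20, 20)  # ddCt = 1 -> 0.5
#' @export
relativeExpression <- function(ctTargetMut, ctRefMut, ctTargetWt, ctRefWt) {
  ct <- cbind(ctTargetMut, ctRefMut, ctTargetWt, ctRefWt)
  if (any(!is.finite(ct)) || any(ct <= 0)) {
    bad <- which(apply(ct, 1L, function(r) any(!is.finite(r) | r <= 0)))
    stop(sprintf(
      "missing or non-positive Ct value(s) at observation(s): %s",
      paste(bad, collapse = ", ")), call. = FALSE)
  }
  ddct <- (ct[, 1L] - ct[, 2L]) - (ct[, 3L] - ct[, 4L])
  unname(2^(-ddct))
}

#' Littermate-pair quality-control filter
#'
#' A pair of littermates is informative only if the two dissections captured
#' comparable amounts of sensory tissue. Following the convention of checking
#' a supporting-cell marker (the `Jag1`/`Ngfr` role), a pair is retained when
#' the QC gene's mutant/wildtype relative expression stays within
#' `tolerance` of 1, i.e. `|ratio - 1| <= tolerance`.
#'
#' @param qcRatio named numeric vector of QC-gene relative expression, one
#'   value per littermate pair (names are pair ids).
#' @param tolerance allowed deviation from 1 (default 0.30, the 30% rule).
#' @return List with `retained` (pair ids) and `excluded` (data.frame of
#'   `pair_id` and offending `qc_ratio`).
#' @export
qcFilterPairs <- function(qcRatio, tolerance = 0.30) {
  if (length(qcRatio) == 0L) {
    warning("no littermate pairs supplied; nothing to filter", call. = FALSE)
    return(list(retained = character(0L),
                excluded = data.frame(pair_id = character(0L),
                                      qc_ratio = numeric(0L))))
  }
  if (is.null(names(qcRatio))) names(qcRatio) <- as.character(seq_along(qcRatio))
  # boundary ratios (e.g. 0.70 against the 30% rule) must pass despite
  # binary floating point, so compare with a square-root-eps slack
  ok <- abs(qcRatio - 1) <= tolerance + sqrt(.Machine$double.eps)
  list(
    retained = names(qcRatio)[ok],
    excluded = data.frame(pair_id = names(qcRatio)[!ok],
                          qc_ratio = unname(qcRatio[!ok]),
                          stringsAsFactors = FALSE)
  )
}

# Exact distribution of the rank-sum of group x under random relabelling,
# conditional on the pooled mid-ranks (so ties are handled exactly).
# Mid-ranks doubled are integers; a subset-sum DP over them gives the count
# of size-m subsets at every achievable doubled rank-sum.
rankSumTailProbs <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  n <- length(pooled)
  r2 <- as.integer(round(2 * rank(pooled)))
  sObs <- sum(r2[seq_len(m)])
  total <- sum(r2)
  # ways[j + 1, s + 1] = number of size-j subsets with doubled rank-sum s
  ways <- matrix(0, nrow = m + 1L, ncol = total + 1L)
  ways[1L, 1L] <- 1
  for (v in r2) {
    jmax <- m
    for (j in jmax:1L) {
      src <- ways[j, seq_len(total + 1L - v)]
      idx <- (v + 1L):(total + 1L)
      ways[j + 1L, idx] <- ways[j + 1L, idx] + src
    }
  }
  counts <- ways[m + 1L, ]
  nTot <- sum(counts)
  lower <- sum(counts[seq_len(sObs + 1L)]) / nTot
  upper <- sum(counts[(sObs + 1L):(total + 1L)]) / nTot
  c(lower = lower, upper = upper)
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' Two-sample rank-sum (Mann-Whitney) test suited to the very small group
#' sizes of littermate-pair designs. For group sizes up to 12 the p-value is
#' exact: it is computed from the full permutation distribution of the
#' rank-sum statistic conditional on the observed pooled values, with ties
#' handled by mid-ranks (so the test stays exact in the presence of ties,
#' including a constant group). Above 12 per group a normal approximation
#' with tie-corrected variance is used.
#'
#' The two-sided p-value is `min(1, 2 * min(lower tail, upper tail))`.
#'
#' @param x,y numeric vectors of the two groups' values (both non-empty).
#' @return Two-sided p-value in (0, 1].
#' @examples
#' wilcoxonExact(c(1, 2, 3), c(4, 5, 6))  # 0.1
#' @export
wilcoxonExact <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(x, y)))) stop("non-finite values in input", call. = FALSE)
  if (max(length(x), length(y)) <= 12L) {
    tails <- rankSumTailProbs(x, y)
    return(min(1, 2 * min(tails)))
  }
  # tie-corrected normal approximation for larger groups
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  s <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  tieTab <- table(r)
  tieCorr <- sum(tieTab^3 - tieTab) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - tieCorr)
  if (sigma2 <= 0) return(1)
  z <- (s - mu) / sqrt(sigma2)
  min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values (sort
#' ascending, multiply the k-th by n/k, enforce monotonicity from the top,
#' cap at 1), returned in the input order. Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0L))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must all lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Signed fold change from a relative-expression ratio
#'
#' Maps a positive expression ratio onto the signed fold-change convention
#' used in microarray reporting: ratios at or above 1 are kept as-is, ratios
#' below 1 become `-1/ratio`, so a gene at 67% of wildtype level reports a
#' fold change of about -1.5. No rounding is applied.
#'
#' @param ratio positive numeric vector of relative-expression ratios.
#' @return Signed fold changes with `|fc| >= 1`.
#' @seealso [foldChangeToRatio()] for the inverse map.
#' @export
toFoldChange <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("relative-expression ratios must be positive and finite",
         call. = FALSE)
  }
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Inverse of the signed fold-change transform
#'
#' @param fc signed fold changes with `|fc| >= 1`.
#' @return Positive relative-expression ratios.
#' @export
foldChangeToRatio <- function(fc) {
  if (any(!is.finite(fc)) || any(abs(fc) < 1)) {
    stop("signed fold changes must satisfy |fc| >= 1", call. = FALSE)
  }
  ifelse(fc >= 1, fc, -1 / fc)
}

#' Per-gene qRT-PCR testing pipeline
#'
#' Runs the full littermate-pair quantification for every target gene in a
#' long-format Ct table: computes per-pair 2^-ddCt relative expression
#' against the reference gene, applies the QC-gene pair filter, tests mutant
#' against wildtype values (wildtype is normalised to 1 within each pair) by
#' the exact Wilcoxon rank-sum test, adjusts p-values across the gene panel
#' by Benjamini-Hochberg, and reports signed fold changes from the mutant
#' group mean.
#'
#' The adjustment family is the set of genes in `ct` (one panel); callers
#' wanting a different family can set `adjust = FALSE` and pool p-values
#' themselves.
#'
#' @param ct data.frame with columns `pair_id`, `genotype` (`"wt"` or
#'   `"hom"`), `gene`, `Ct`, e.g. from [readCtTable()] or
#'   [generateQpcrTable()].
#' @param reference reference (normaliser) gene id, default `"Hprt"`.
#' @param qc tissue-amount QC gene id, default `"Jag1"`; set `NULL` to skip
#'   QC filtering.
#' @param tolerance QC tolerance passed to [qcFilterPairs()].
#' @param adjust adjust p-values across the panel (default `TRUE`).
#' @return data.frame with one row per target gene: `gene`, `n_wt`, `n_hom`,
#'   `mean_wt`, `sd_wt`, `mean_hom`, `sd_hom`, `p`, `adj_p`, `fold_change`;
#'   attribute `"excluded_pairs"` carries the QC exclusion log.
#' @export
qpcrTest <- function(ct, reference = "Hprt", qc = "Jag1", tolerance = 0.30,
                     adjust = TRUE) {
  need <- c("pair_id", "genotype", "gene", "Ct")
  stopIfNot1(all(need %in% names(ct)),
             sprintf("Ct table must have columns: %s",
                     paste(need, collapse = ", ")))
  stopIfNot1(all(ct$genotype %in% c("wt", "hom")),
             "genotype must be 'wt' or 'hom'")
  stopIfNot1(reference %in% ct$gene,
             sprintf("reference gene '%s' absent from Ct table", reference))

  ctOf <- function(gene, genotype, pairs) {
    sub <- ct[ct$gene == gene & ct$genotype == genotype, ]
    v <- sub$Ct[match(pairs, sub$pair_id)]
    if (anyNA(v)) {
      stop(sprintf("missing Ct for gene '%s' (%s) in pair(s): %s",
                   gene, genotype,
                   paste(pairs[is.na(v)], collapse = ", ")), call. = FALSE)
    }
    v
  }

  pairs <- sort(unique(ct$pair_id))
  excluded <- data.frame(pair_id = character(0L), qc_ratio = numeric(0L))
  if (!is.null(qc)) {
    stopIfNot1(qc %in% ct$gene,
               sprintf("QC gene '%s' absent from Ct table", qc))
    qcRatio <- relativeExpression(
      ctOf(qc, "hom", pairs), ctOf(reference, "hom", pairs),
      ctOf(qc, "wt", pairs), ctOf(reference, "wt", pairs))
    names(qcRatio) <- pairs
    flt <- qcFilterPairs(qcRatio, tolerance)
    pairs <- flt$retained
    excluded <- flt$excluded
  }
  stopIfNot1(length(pairs) > 0L, "no littermate pairs survive QC filtering")

  targets <- setdiff(sort(unique(ct$gene)), c(reference, qc))
  rows <- lapply(targets, function(g) {
    re <- relativeExpression(
      ctOf(g, "hom", pairs), ctOf(reference, "hom", pairs),
      ctOf(g, "wt", pairs), ctOf(reference, "wt", pairs))
    wt <- rep(1, length(pairs))  # each pair's wildtype is its own baseline
    data.frame(
      gene = g, n_wt = length(wt), n_hom = length(re),
      mean_wt = mean(wt), sd_wt = sd(wt),
      mean_hom = mean(re), sd_hom = sd(re),
      p = wilcoxonExact(wt, re),
      fold_change = toFoldChange(mean(re)),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- if (adjust) bhAdjust(res$p) else NA_real_
  res <- res[, c("gene", "n_wt", "n_hom", "mean_wt", "sd_wt", "mean_hom",
                 "sd_hom", "p", "adj_p", "fold_change")]
  attr(res, "excluded_pairs") <- excluded
  res
}
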