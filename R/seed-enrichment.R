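#' RankedUtrSet: 3'UTR sequences in expression-rank order
#'
#' Holds one 3'UTR per gene, ordered from the most upregulated gene (rank 1)
#' to the most downregulated. This ordering is the substrate of the
#' hypergeometric word-enrichment landscape: a word concentrated among the
#' leading (upregulated) genes is a candidate lost-repression signature of a
#' mutant microRNA. Genes with UTRs shorter than 7 bases are retained and
#' simply never carry a word (excluding them would silently change the
#' universe).
#'
#' @slot utrs a [Biostrings::DNAStringSet] with unique gene-id names, in
#'   rank order.
#' @seealso [rankedUtrSet()], [wordLandscape()], [topWords()]
#' @export
setClass("RankedUtrSet", slots = c(utrs = "DNAStringSet"))

setValidity("RankedUtrSet", function(object) {
  nm <- names(object@utrs)
  msgs <- character(0L)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    msgs <- c(msgs, "every UTR must be named by its gene id")
  } else if (anyDuplicated(nm)) {
    msgs <- c(msgs, "gene ids must be unique (ranking is a permutation)")
  }
  if (length(object@utrs) == 0L) msgs <- c(msgs, "UTR set is empty")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RankedUtrSet
#'
#' @param utrs named [Biostrings::DNAStringSet] (or named character vector
#'   of DNA sequences), already in rank order: first = most upregulated.
#' @return A validated [RankedUtrSet-class].
#' @export
rankedUtrSet <- function(utrs) {
  if (is.character(utrs)) utrs <- Biostrings::DNAStringSet(utrs)
  obj <- new("RankedUtrSet", utrs = utrs)
  validObject(obj)
  obj
}

#' @describeIn RankedUtrSet-class sequence accessor
#' @param x a `RankedUtrSet`
#' @export
setGeneric("utrSequences", function(x) standardGeneric("utrSequences"))

#' @rdname RankedUtrSet-class
#' @export
setMethod("utrSequences", "RankedUtrSet", function(x) x@utrs)

#' @describeIn RankedUtrSet-class gene ids in rank order
#' @export
setGeneric("geneRanking", function(x) standardGeneric("geneRanking"))

#' @rdname RankedUtrSet-class
#' @export
setMethod("geneRanking", "RankedUtrSet", function(x) names(x@utrs))

setMethod("show", "RankedUtrSet", function(object) {
  w <- width(object@utrs)
  cat(sprintf("RankedUtrSet: %d genes (rank 1 = most upregulated)\n",
              length(object@utrs)))
  cat(sprintf("  UTR length: median %d [%d-%d]; %d shorter than 7 bases\n",
              as.integer(stats::median(w)), min(w), max(w), sum(w < 7L)))
  invisible(NULL)
})

#' @describeIn RankedUtrSet-class number of genes
#' @export
setMethod("length", "RankedUtrSet", function(x) length(x@utrs))

#' Seed-match motif from a mature microRNA sequence
#'
#' The seed region of a mature microRNA is nucleotides 2-8; a canonical
#' seed match in a 3'UTR is the DNA reverse complement of that heptamer.
#' For wild-type miR-96 (`UUUGGCACUAGCACAUUUUUGCU`) this yields `GTGCCAA`.
#'
#' @param mature mature microRNA sequence, RNA alphabet (A, C, G, U),
#'   length >= 8.
#' @return The 7-base DNA match motif as a character string.
#' @export
seedToMatch <- function(mature) {
  stopIfNot1(is.character(mature) && length(mature) == 1L,
             "'mature' must be a single sequence string")
  mature <- toupper(mature)
  if (!grepl("^[ACGU]+$", mature)) {
    stop("mature sequence contains non-RNA characters (alphabet is A, C, G, U)",
         call. = FALSE)
  }
  if (nchar(mature) < 8L) {
    stop("mature sequence must be at least 8 nucleotides (seed is 2-8)",
         call. = FALSE)
  }
  seed <- Biostrings::RNAString(substr(mature, 2L, 8L))
  as.character(Biostrings::DNAString(Biostrings::reverseComplement(seed)))
}

#' Scan a 3'UTR for exact seed-match sites
#'
#' Text search for exact, possibly overlapping occurrences of a 7-base
#' motif on the forward strand (3'UTRs are supplied sense-strand).
#'
#' @param utr DNA sequence (character or [Biostrings::DNAString]).
#' @param motif DNA 7-mer over `{A, C, G, T}` (no ambiguity codes).
#' @return Integer vector of 0-based start positions (half-open
#'   coordinates).
#' @export
seedMatchSites <- function(utr, motif) {
  stopIfNot1(is.character(motif) && nchar(motif) == 7L,
             "'motif' must be a 7-base string")
  if (!grepl("^[ACGT]{7}$", motif)) {
    stop("motif contains ambiguity codes or non-DNA characters", call. = FALSE)
  }
  if (is.character(utr)) utr <- Biostrings::DNAString(utr)
  if (length(utr) < 7L) return(integer(0L))
  m <- Biostrings::matchPattern(motif, utr)
  as.integer(start(m)) - 1L
}

# per-gene presence/absence of every heptamer (or one word): the urn model
# counts a gene once no matter how many sites it carries
wordPresenceMatrix <- function(ranked) {
  counts <- Biostrings::oligonucleotideFrequency(utrSequences(ranked),
                                                 width = 7L)
  counts > 0L
}

# signed hypergeometric score at given leading-bin cutoffs.
# k: present-in-leading counts (cutoffs x words), K: total present per word,
# N: genes, cut: cutoffs. Enrichment (k >= expectation) scores -log10 of the
# upper tail, depletion scores +log10 of the lower tail; by the stored
# convention positive = enriched in upregulated genes.
signedLandscapeScores <- function(k, K, N, cut) {
  Km <- matrix(K, nrow = length(cut), ncol = length(K), byrow = TRUE)
  cm <- matrix(cut, nrow = length(cut), ncol = length(K))
  expect <- cm * Km / N
  enr <- k >= expect
  pEnr <- phyper(k - 1, Km, N - Km, cm, lower.tail = FALSE)
  pDep <- phyper(k, Km, N - Km, cm, lower.tail = TRUE)
  p <- ifelse(enr, pEnr, pDep)
  score <- ifelse(enr, -log10(pmax(pEnr, .Machine$double.xmin)),
                  log10(pmax(pDep, .Machine$double.xmin)))
  list(p = p, score = score, enriched = enr)
}

#' Hypergeometric word-enrichment landscape along a ranked gene list
#'
#' For each leading-bin cutoff c (multiples of `binStep`), genes are marked
#' word-present or word-absent (presence/absence, not site counts) and the
#' hypergeometric tail probability of the observed present-count among the
#' leading c genes versus the whole set is computed. The score is signed:
#' `-log10(p)` of the upper (enrichment) tail when the leading bin holds at
#' least the expected number of word-present genes, `+log10(p)` of the
#' lower (depletion) tail otherwise — so peaks above zero mean the word is
#' concentrated in upregulated genes.
#'
#' @param ranked a [RankedUtrSet-class].
#' @param word DNA 7-mer to score.
#' @param binStep cutoff spacing in genes; default `max(1, floor(n/50))`,
#'   giving about 50 landscape points.
#' @return data.frame with one row per cutoff: `word`, `cutoff`,
#'   `n_present_leading`, `n_present_total`, `p`, `direction`
#'   (`enriched`/`depleted`), `score`.
#' @export
wordLandscape <- function(ranked, word, binStep = NULL) {
  stopIfNot1(is(ranked, "RankedUtrSet"), "'ranked' must be a RankedUtrSet")
  if (!is.character(word) || nchar(word) != 7L || !grepl("^[ACGT]{7}$", word)) {
    stop("'word' must be a DNA 7-mer over {A,C,G,T}", call. = FALSE)
  }
  N <- length(ranked)
  if (is.null(binStep)) binStep <- max(1L, floor(N / 50))
  checkCount(binStep, "binStep", min = 1L)
  cut <- seq.int(binStep, N, by = binStep)
  present <- as.integer(wordPresenceMatrix(ranked)[, word])
  k <- matrix(cumsum(present)[cut], ncol = 1L)
  K <- sum(present)
  sc <- signedLandscapeScores(k, K, N, cut)
  data.frame(
    word = word, cutoff = cut,
    n_present_leading = k[, 1L], n_present_total = K,
    p = sc$p[, 1L],
    direction = ifelse(sc$enriched[, 1L], "enriched", "depleted"),
    score = sc$score[, 1L],
    stringsAsFactors = FALSE)
}

#' Rank heptamers by their peak landscape score
#'
#' Evaluates the word-enrichment landscape for every DNA heptamer (all
#' 4^7 = 16384 by default, or a user-restricted set) and returns the words
#' with the largest peak absolute score together with the cutoff where the
#' peak occurs. A microRNA's seed match planted among upregulated genes is
#' expected to surface at the top.
#'
#' @param ranked a [RankedUtrSet-class].
#' @param nWords number of top words to return.
#' @param binStep cutoff spacing, as in [wordLandscape()].
#' @param words optional character vector restricting the candidate
#'   heptamers.
#' @return data.frame sorted by decreasing `|peak_score|` (ties broken
#'   alphabetically): `word`, `peak_score` (signed), `peak_cutoff`,
#'   `n_present_total`.
#' @export
topWords <- function(ranked, nWords = 10L, binStep = NULL, words = NULL) {
  stopIfNot1(is(ranked, "RankedUtrSet"), "'ranked' must be a RankedUtrSet")
  checkCount(nWords, "nWords", min = 0L)
  if (nWords == 0L) {
    return(data.frame(word = character(0L), peak_score = numeric(0L),
                      peak_cutoff = integer(0L),
                      n_present_total = integer(0L)))
  }
  N <- length(ranked)
  if (is.null(binStep)) binStep <- max(1L, floor(N / 50))
  checkCount(binStep, "binStep", min = 1L)
  cut <- seq.int(binStep, N, by = binStep)

  presence <- wordPresenceMatrix(ranked)
  if (!is.null(words)) {
    stopIfNot1(all(words %in% colnames(presence)),
               "'words' must be DNA 7-mers")
    presence <- presence[, words, drop = FALSE]
  }
  storage.mode(presence) <- "integer"
  cum <- apply(presence, 2L, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1L)  # single-gene set
  k <- cum[cut, , drop = FALSE]
  K <- colSums(presence)
  sc <- signedLandscapeScores(k, K, N, cut)
  peakIdx <- apply(abs(sc$score), 2L, which.max)
  peak <- sc$score[cbind(peakIdx, seq_along(K))]
  out <- data.frame(
    word = colnames(presence),
    peak_score = peak,
    peak_cutoff = cut[peakIdx],
    n_present_total = as.integer(K),
    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$peak_score), out$word), , drop = FALSE]
  rownames(out) <- NULL
  head(out, nWords)
}
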