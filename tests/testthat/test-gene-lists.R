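mkRecords <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("misregulated compilation applies the dual-threshold rule", {
  rec <- mkRecords(
    gene = c("Dynlrb2", "Dynlrb2", "Slc26a5", "Grk1", "Nofx"),
    source = c("array_P4", "qrtpcr", "array_P0", "array_P4", "qrtpcr"),
    fold_change = c(-1.8, -2.1, -3.0, 1.4, 1.2),
    p = c(0.001, 0.004, 0.0005, 0.03, 0.2),
    adj_p = c(0.04, 0.01, 0.02, 0.09, 0.4))
  mis <- compileMisregulated(rec)
  expect_setequal(mis$gene, c("Dynlrb2", "Slc26a5", "Grk1"))
  # the confirmed qRT-PCR value wins over the array value
  expect_equal(mis$fold_change[mis$gene == "Dynlrb2"], -2.1)
  expect_equal(mis$source_used[mis$gene == "Dynlrb2"], "qrtpcr")
  # array-only gene passes at the lenient 0.1 but not the strict 0.05
  expect_equal(mis$source_used[mis$gene == "Grk1"], "array_P4")
  expect_false(any(mis$sign_conflict))
  # tightening the array threshold drops the 0.09 record
  mis2 <- compileMisregulated(rec, arrayAlpha = 0.05)
  expect_false("Grk1" %in% mis2$gene)
  # qRT record at 0.4 never enters under defaults
  expect_false("Nofx" %in% mis$gene)
})

test_that("sign conflicts between significant sources are flagged", {
  rec <- mkRecords(
    gene = c("X", "X"), source = c("array_P4", "qrtpcr"),
    fold_change = c(1.5, -1.5), p = c(0.01, 0.01), adj_p = c(0.02, 0.02))
  expect_warning(mis <- compileMisregulated(rec), "sign conflict.*X")
  expect_true(mis$sign_conflict)
  expect_equal(mis$fold_change, -1.5)  # qRT-PCR value still preferred
})

test_that("P4 is preferred over P0 when both arrays are significant", {
  rec <- mkRecords(
    gene = c("Y", "Y"), source = c("array_P0", "array_P4"),
    fold_change = c(-2.0, -1.6), p = c(0.001, 0.002), adj_p = c(0.01, 0.02))
  mis <- compileMisregulated(rec)
  expect_equal(mis$source_used, "array_P4")
  expect_equal(mis$fold_change, -1.6)
})

test_that("direct-target compilation unions the packaged evidence to 31 genes", {
  ev <- directTargetEvidence()
  tg <- compileDirectTargets(ev)
  expect_equal(nrow(tg), 31L)
  expect_false(anyDuplicated(tg$gene) > 0L)
  expect_equal(tg$gene, sort(tg$gene))
  expect_equal(sum(grepl("literature_confirmed", tg$categories)), 19L)
  expect_equal(sum(grepl("luciferase_confirmed", tg$categories)), 3L)
  expect_equal(sum(grepl("upregulated_with_seed_match", tg$categories)), 7L)
  expect_setequal(tg$gene[grepl("predicted_and_expressed", tg$categories)],
                  c("Zic2", "Osbpl2"))
  # a gene in two categories keeps both, still one row
  ev2 <- rbind(ev, data.frame(gene = "Foxo1",
                              category = "luciferase_confirmed",
                              citation = "extra"))
  tg2 <- compileDirectTargets(ev2)
  expect_equal(nrow(tg2), 31L)
  expect_equal(tg2$categories[tg2$gene == "Foxo1"],
               "literature_confirmed,luciferase_confirmed")
  expect_error(compileDirectTargets(
    data.frame(gene = "A", category = "guessed")), "unknown evidence category")
})

test_that("probe collapse keeps lowest p, ties broken by |fold change|", {
  rec <- mkRecords(
    gene = c("A", "A", "B", "B"),
    probe = c("A_1", "A_2", "B_1", "B_2"),
    source = "array_P4",
    fold_change = c(1.2, -3.0, 1.5, -1.4),
    p = c(0.01, 0.05, 0.02, 0.02),
    adj_p = c(0.05, 0.2, 0.08, 0.08))
  out <- collapseProbes(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$probe[out$gene == "A"], "A_1")    # lower p wins
  expect_equal(out$probe[out$gene == "B"], "B_1")    # tie -> larger |fc|
  expect_equal(attr(out, "ties"), "B")
})

test_that("GSEA input applies the 10% change filter and sorts by fold change", {
  rec <- mkRecords(
    gene = c("U", "V", "W", "Z"), source = "array_P4",
    fold_change = c(2.0, 1.05, -1.05, -1.2),
    p = 0.5, adj_p = 0.9)
  out <- gseaInput(rec)
  expect_equal(out$gene, c("U", "Z"))                # 1.05s fall under 1.1
  expect_equal(out$fold_change, c(2.0, -1.2))        # most upregulated first
  out2 <- gseaInput(rec, fcThreshold = 0.04)
  expect_equal(nrow(out2), 4L)
  expect_error(gseaInput(rbind(rec, rec)), "one row per gene")
})

test_that("hypergeometric ORA matches closed forms and the enumeration oracle", {
  # overlap 2 of query 2, set 3 in universe 18: 3/153
  res <- oraHypergeometric(c("a", "b"), list(S = c("a", "b", "c")), letters[1:18])
  expect_equal(res$p, choose(3, 2) / choose(18, 2))
  expect_equal(res$adj_p, res$p)

  set.seed(12)
  universe <- paste0("g", 1:12)
  for (rep in 1:15) {
    q <- sample(universe, sample(2:5, 1L))
    s <- sample(universe, sample(2:6, 1L))
    res <- oraHypergeometric(q, list(S = s), universe)
    expect_equal(res$p, oracleOra(q, s, universe), tolerance = 1e-12,
                 info = sprintf("rep %d", rep))
  }
  # genes outside the universe never silently inflate significance
  expect_error(oraHypergeometric(c("a", "zz"), list(S = "a"), letters[1:5]),
               "absent from universe")
  # set members outside the universe are clipped before testing
  res <- oraHypergeometric("a", list(S = c("a", "zz")), letters[1:5])
  expect_equal(res$set_size, 1L)
  # multiple sets get BH-adjusted jointly
  res <- oraHypergeometric(letters[1:3],
                           list(S1 = letters[1:3], S2 = letters[10:12]),
                           letters[1:20])
  expect_equal(res$adj_p, bhAdjust(res$p))
})

test_that("compiled lists expose the overlap between targets and misregulated", {
  tg <- compileDirectTargets(directTargetEvidence())
  mis <- data.frame(gene = c("Foxo1", "Aqp5", "NotATarget"),
                    fold_change = c(1.5, 1.3, -2), source_used = "qrtpcr",
                    sign_conflict = FALSE)
  both <- compiledLists(tg, mis)
  expect_equal(both$overlap, c("Aqp5", "Foxo1"))
})

test_that("record validation catches malformed inputs", {
  good <- mkRecords(gene = "A", source = "qrtpcr", fold_change = 1.5,
                    p = 0.1, adj_p = 0.2)
  expect_silent(checkExpressionRecords(good))
  bad <- good; bad$source <- "rnaseq"
  expect_error(compileMisregulated(bad), "sources must be one of")
  bad <- good; bad$fold_change <- 0.5   # ratios must be converted first
  expect_error(compileMisregulated(bad), "\\|fc\\| >= 1")
  bad <- good; bad$p <- 1.5
  expect_error(compileMisregulated(bad), "\\[0, 1\\]")
})
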