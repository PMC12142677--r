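# Database matching, isobar adjudication, candidate filtering, reports.

test_that("database matching respects tolerance modes and inclusive bounds", {
  db <- toyDatabase()
  hits <- dbMatch(501.0076, db, adducts = "[M+H]+", tol = 5, tolMode = "ppm")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$name, "toy500")
  expect_identical(nrow(dbMatch(501.0076, db, adducts = "[M+H]+",
                                tol = 0.1, tolMode = "ppm")), 0L)
  # a query at the edge of the Da window is a hit (inclusive bounds)
  theo <- adductMz(500, "[M+H]+")
  expect_identical(nrow(dbMatch(theo + 0.005, db, adducts = "[M+H]+",
                                tol = 0.005, tolMode = "da")), 1L)
  expect_error(dbMatch(500, db[0, ]), "empty database")
})

test_that("database matching is invariant to row order and sorted by error", {
  db <- toyDatabase()
  mz <- adductMz(db$mass[1], "[M+H]+") + 0.001
  h1 <- dbMatch(mz, db, tol = 0.005, tolMode = "da")
  h2 <- dbMatch(mz, db[rev(seq_len(nrow(db))), ], tol = 0.005, tolMode = "da")
  expect_identical(h1, h2)
  if (nrow(h1) > 1) expect_true(!is.unsorted(abs(h1$errorDa)))
})

test_that("isobar adjudication picks the smaller CCS difference and flags ties", {
  cand <- data.frame(name = c("A", "B"), percentDiff = c(0.4, 2.1))
  adj <- adjudicateIsobars(280, cand)
  expect_false(adj$ambiguous)
  expect_identical(adj$winner$name, "A")
  tie <- data.frame(name = c("A", "B"), percentDiff = c(1.0, -1.0))
  adjT <- adjudicateIsobars(280, tie)
  expect_true(adjT$ambiguous)
  expect_null(adjT$winner)
  expect_error(adjudicateIsobars(280, cand[1, , drop = FALSE]), "at least 2")
  # winner never has a larger |diff| than any other candidate
  set.seed(23)
  for (i in 1:20) {
    cc <- data.frame(name = letters[1:5],
                     predictedCcs = 280 * (1 + rnorm(5, 0, 0.02)))
    adj <- adjudicateIsobars(280, cc)
    expect_true(all(abs(adj$ranked$percentDiff[1]) <=
                    abs(adj$ranked$percentDiff)))
  }
})

test_that("adjudication on simulated isobar pairs always selects the truth", {
  pairs <- simulateIsobarPairs(nPairs = 5, seed = 31)
  wins <- vapply(pairs, function(p) {
    adj <- adjudicateIsobars(p$experimentalCcs, p$candidates)
    !adj$ambiguous && adj$winner$isTruth
  }, logical(1))
  expect_identical(sum(wins), 5L)
  # the sodiated species is the winner in each pair, as constructed
  for (p in pairs) {
    expect_identical(adjudicateIsobars(p$experimentalCcs,
                                       p$candidates)$winner$adduct, "[M+Na]+")
  }
})

test_that("candidate filtering partitions the list and counts are threshold-monotone", {
  cand <- data.frame(percentDiff = c(0.4, -0.5, 2.4, 3.1))
  res <- filterCandidates(cand, 1.0)
  expect_identical(unname(res$counts), c(4L, 2L, 2L))
  empty <- filterCandidates(cand[0, , drop = FALSE])
  expect_identical(unname(empty$counts), c(0L, 0L, 0L))
  set.seed(7)
  for (i in 1:100) {
    cc <- data.frame(percentDiff = rnorm(40, 0, 1.5))
    a <- filterCandidates(cc, 0.5); b <- filterCandidates(cc, 1.0)
    expect_identical(nrow(a$kept) + nrow(a$removed), 40L)
    expect_length(intersect(rownames(a$kept), rownames(a$removed)), 0)
    expect_true(all(rownames(b$removed) %in% rownames(a$removed)))
  }
})

test_that("sum-composition check requires both formula and adduct to agree", {
  expect_true(sumCompositionCheck("C39H76NO8P", "[M+H]+", "C39H76NO8P", "[M+H]+"))
  expect_false(sumCompositionCheck("C40H78NO8P", "[M+H]+", "C39H76NO8P", "[M+H]+"))
  expect_false(sumCompositionCheck("C39H76NO8P", "[M+H]+", "C39H76NO8P", "[M+K]+"))
  # equivalent formula spellings compare equal
  expect_true(sumCompositionCheck("CH3CH3", "[M+H]+", "C2H6", "[M+H]+"))
})

test_that("candidate ingestion validates columns, ranks and truncates to top k", {
  cand <- simulateCandidates(nDecoys = 24, seed = 2)
  f <- tempfile(fileext = ".csv")
  write.csv(cand, f, row.names = FALSE)
  got <- ingestCandidates(f, topK = 20)
  expect_identical(nrow(got), 20L)
  expect_identical(got$rank, 1:20)
  write.csv(cand[setdiff(names(cand), "structure")], f, row.names = FALSE)
  expect_error(ingestCandidates(f), "structure")
  bad <- cand; bad$rank[2] <- 1
  write.csv(bad, f, row.names = FALSE)
  expect_error(ingestCandidates(f), "duplicate ranks")
})

test_that("feature annotation composes matching, filtering and adjudication", {
  db <- toyDatabase()
  cand <- simulateCandidates(nDecoys = 9, trueOffset = 0.3, seed = 4)
  rep <- annotateFeature(501.0076, 280, db, cand, tol = 5, tolMode = "ppm")
  expect_s3_class(rep, "AnnotationReport")
  expect_identical(unname(rep$counts["total"]), 10L)
  expect_identical(unname(rep$counts["kept"] + rep$counts["removed"]),
                   rep$counts[["total"]])
  expect_identical(rep$status, "annotated")
  # the truth candidate survives the 1% filter
  expect_true("kept" %in% rep$candidates$disposition[rep$candidates$isTruth])
  # no database hit and no candidates -> unknown
  rep2 <- annotateFeature(123.456, 150, db, tol = 5, tolMode = "ppm")
  expect_identical(rep2$status, "unknown")
  expect_identical(nrow(rep2$putativeMatches), 0L)
})

test_that("end-to-end annotation recovers the planted truth across seeds", {
  db <- toyDatabase()
  ok <- vapply(1:50, function(s) {
    cand <- simulateCandidates(nDecoys = 14, trueOffset = 0.3, seed = s)
    rep <- annotateFeature(501.0076, 280, db, cand, tol = 5, tolMode = "ppm")
    kept <- rep$candidates[rep$candidates$disposition == "kept", ]
    any(kept$isTruth)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
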