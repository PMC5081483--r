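test_that("edge construction collapses duplicates and rejects bad labels", {
  expect_message(
    net <- PDINetwork(mkEdges(c("A:p1", "A:p2", "A:p2"))),
    "collapsed 1 duplicate")
  expect_equal(nEdges(net), 2L)
  expect_error(PDINetwork(mkEdges("A:p1"),
                          baitQuality = c(p1 = "shiny")),
               "unknown bait quality")

  f <- tempfile(fileext = ".tsv")
  writeLines(c("tf_id\tpromoter_id\tgene_id\tbait_quality",
               "A\tp1\tg1\tclean",
               "A\tp1\tg1\tclean",
               "B\tp2\tg2\tmoderate_background"), f)
  net2 <- suppressMessages(loadEdgeList(f))
  expect_equal(nEdges(net2), 2L)
  expect_equal(unname(baitQuality(net2)["p2"]), "moderate_background")

  writeLines(c("tf_id\tpromoter_id\tgene_id\tbait_quality",
               "A\tp1\tg1\tglowing"), f)
  expect_error(suppressMessages(loadEdgeList(f)), "glowing.*row 1")
  writeLines("tf_id\tpromoter_id", f)
  expect_error(loadEdgeList(f), "empty")
  writeLines(c("x\ty", "1\t2"), f)
  expect_error(loadEdgeList(f), "missing required column")
})

test_that("edge lists round-trip through save and load", {
  net <- randNet(seed = 3)
  f <- tempfile(fileext = ".tsv")
  writeEdgeList(net, f)
  net2 <- suppressMessages(loadEdgeList(f))
  key <- function(n) sort(with(pdiEdges(n), paste(tf, promoter)))
  expect_identical(key(net2), key(net))
  expect_identical(baitQuality(net2)[promoterIds(net)],
                   baitQuality(net)[promoterIds(net)])
})

test_that("bait filtering keeps exactly the allowed qualities", {
  edges <- mkEdges(c("A:p1", "A:p2", "B:p2", "B:p3"))
  bq <- c(p1 = "clean", p2 = "high_background", p3 = "clean")
  net <- qNet(edges, baitQuality = bq)
  f <- filterBaits(net, "clean")
  expect_setequal(pdiEdges(f)$promoter, c("p1", "p3"))
  ## subset of input and idempotent
  expect_true(all(with(pdiEdges(f), paste(tf, promoter)) %in%
                  with(pdiEdges(net), paste(tf, promoter))))
  expect_identical(pdiEdges(filterBaits(f, "clean")), pdiEdges(f))
  ## all clean -> identity
  allClean <- qNet(edges)
  expect_identical(pdiEdges(filterBaits(allClean, "clean")),
                   pdiEdges(allClean))
  ## no label matches -> empty network
  expect_equal(nEdges(filterBaits(net, "moderate_background")), 0L)
  ## tested space preserved through filtering
  expect_equal(nTestedPromoters(f), nTestedPromoters(net))
})

test_that("degree summary is consistent with the degree maps", {
  net1 <- qNet(mkEdges(c("A:p1", "A:p2")))
  ds1 <- degreeSummary(net1)
  expect_equal(ds1$meanInDegree, 1)
  expect_equal(unname(ds1$outDegree["A"]), 2L)

  ## k disjoint single edges: mean = median = 1
  k <- 7
  netk <- qNet(data.frame(tf = paste0("T", 1:k),
                          promoter = paste0("p", 1:k)))
  dsk <- degreeSummary(netk)
  expect_equal(dsk$meanInDegree, 1)
  expect_equal(dsk$medianInDegree, 1)

  ## totals: sum of in-degrees = sum of out-degrees = |E|
  net <- randNet(seed = 11)
  ds <- degreeSummary(net)
  expect_equal(sum(ds$inDegree), nEdges(net))
  expect_equal(sum(ds$outDegree), nEdges(net))
  ## out-degree fractions use the tested denominator
  expect_equal(ds$meanOutFraction,
               mean(ds$outDegree / nTestedPromoters(net)))
  expect_error(degreeSummary(filterBaits(net, "no_interactions")), "empty")
})

test_that("density matrix matches a brute-force recount", {
  ## single edge: one occupied cell with density 1
  dm1 <- densityMatrix(qNet(mkEdges("A:p1")))
  expect_equal(sum(dm1$edgeCount), 1)
  expect_equal(dm1$density[dm1$edgeCount > 0], 1)

  ## complete bipartite 2x2: every occupied cell has density 1
  dm2 <- densityMatrix(qNet(mkEdges(c("A:p1", "A:p2", "B:p1", "B:p2"))))
  expect_true(all(dm2$density[dm2$edgeCount > 0] == 1))

  ## heavy-tailed synthetic network vs direct enumeration
  net <- randNet(nT = 25, nP = 50, nE = 200, seed = 5)
  dm <- densityMatrix(net)
  e <- pdiEdges(net)
  outDeg <- table(e$tf); inDeg <- table(e$promoter)
  for (i in seq_len(nrow(dm$density))) {
    for (j in seq_len(ncol(dm$density))) {
      tfsIn <- names(outDeg)[floor(log2(outDeg)) + 1 == i]
      promsIn <- names(inDeg)[floor(log2(inDeg)) + 1 == j]
      nEdge <- sum(e$tf %in% tfsIn & e$promoter %in% promsIn)
      if (length(tfsIn) && length(promsIn))
        expect_equal(dm$density[i, j],
                     nEdge / (length(tfsIn) * length(promsIn)))
    }
  }
  ## density x pairs-per-cell sums back to |E|
  denom <- outer(dm$tfCounts, dm$promoterCounts)
  expect_equal(sum(dm$density * denom, na.rm = TRUE), nEdges(net))
})

test_that("profile similarities are Jaccard indices with NA on empty sets", {
  net <- qNet(mkEdges(c("A:p1", "A:p2", "A:p3", "B:p2", "B:p3", "B:p4",
                        "C:p1", "C:p2", "C:p3", "D:p3", "E:p5")))
  expect_equal(targetProfileSimilarity(net, "A", "B"), 0.5)
  expect_equal(targetProfileSimilarity(net, "A", "A"), 1)
  ## promoter profiles: {A,C} vs {A,B,C,D} etc.
  expect_equal(tfProfileSimilarity(net, "p1", "p1"), 1)
  expect_equal(tfProfileSimilarity(net, "p1", "p5"), 0)
  ## {A,B,C} vs {C,D}: p2 bound by A,B,C; p3 by A,B,C,D -> 3/4
  expect_equal(tfProfileSimilarity(net, "p2", "p3"), 0.75)
  ## spec 1/4 case
  net2 <- qNet(mkEdges(c("A:x", "B:x", "C:x", "C:y", "D:y")))
  expect_equal(tfProfileSimilarity(net2, "x", "y"), 0.25)
  ## symmetry and bounds over random pairs
  net3 <- randNet(seed = 21)
  tfs <- sample(unique(pdiEdges(net3)$tf), 6)
  for (i in 1:5) {
    s1 <- targetProfileSimilarity(net3, tfs[i], tfs[i + 1])
    s2 <- targetProfileSimilarity(net3, tfs[i + 1], tfs[i])
    expect_equal(s1, s2)
    expect_gte(s1, 0); expect_lte(s1, 1)
  }
})

test_that("peaks are assigned to promoters by midpoint, half-open", {
  promTsv <- tempfile(fileext = ".tsv")
  writeLines(c("promoter_id\tchrom\tstart\tend\tstrand",
               "prA\tchr1\t0\t500\t+",
               "prB\tchr1\t500\t900\t+"), promTsv)
  proms <- readPromoterIntervals(promTsv)

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tTF1",      # midpoint 150 -> prA
               "chr1\t400\t600\tTF2",      # midpoint 500 -> prB (not prA)
               "chr1\t10\t20\tTF3",        # three TF3 peaks in prA
               "chr1\t30\t40\tTF3",
               "chr1\t50\t60\tTF3",
               "chr1\t850\t950\tTF4"), bed) # midpoint 900 -> outside both
  peaks <- readPeaksBED(bed)
  net <- assignPeaks(peaks, proms)
  e <- pdiEdges(net)
  expect_equal(e$promoter[e$tf == "TF1"], "prA")
  ## midpoint exactly at prA's end (500) falls in prB under half-open
  expect_equal(e$promoter[e$tf == "TF2"], "prB")
  ## multiple peaks of one TF on one promoter collapse to one edge
  expect_equal(sum(e$tf == "TF3"), 1L)
  ## midpoint at prB's end (900) is assigned nowhere
  expect_false("TF4" %in% e$tf)

  writeLines(c("chr1\t200\t100\tTF1"), bed)
  expect_error(readPeaksBED(bed), "malformed interval")
})

test_that("headline statistics report filtered counts and shared targets", {
  edges <- rbind(mkEdges(c(paste0("DAF:q", 1:5), "X:q1", "X:q2", "Y:q2")),
                 mkEdges("Z:bad1"))
  bq <- c(setNames(rep("clean", 5), paste0("q", 1:5)),
          bad1 = "high_background")
  net <- qNet(edges, baitQuality = bq)
  hs <- networkHeadlineStats(net, tfsOfInterest = "DAF",
                             tfPairs = cbind("X", "Y"), minTargets = 5)
  expect_equal(hs$nEdges, 8L)
  expect_equal(unname(hs$outDegree["DAF"]), 5L)
  expect_equal(unname(hs$sharedTargets["shared", 1]), 1L)
  expect_equal(unname(hs$sharedTargets["union", 1]), 2L)
  expect_equal(hs$nTFsWithMinTargets, 1L)
})
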