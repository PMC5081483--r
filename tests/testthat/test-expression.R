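test_that("co-expression integration matches a hand-computed oracle", {
  ## three datasets; expected pair score computed independently below
  set.seed(10)
  mk <- function(n, genes = paste0("g", 1:4)) {
    m <- matrix(2^rnorm(length(genes) * n, mean = 8), length(genes), n)
    rownames(m) <- genes
    m
  }
  ds <- list(d1 = mk(5), d2 = mk(7), d3 = mk(4))
  comp <- ExpressionCompendium(ds)
  cx <- buildCoexpression(comp, minDatasets = 1, lowExprQuantile = 0)
  ## oracle: per-dataset Pearson of log2(x+1), Fisher z, weights n - 3
  for (pair in list(c("g1", "g2"), c("g2", "g4"))) {
    zs <- ws <- numeric(0)
    for (m in ds) {
      r <- cor(log2(m[pair[1], ] + 1), log2(m[pair[2], ] + 1))
      zs <- c(zs, atanh(r)); ws <- c(ws, ncol(m) - 3)
    }
    expect_equal(coexScores(cx)[pair[1], pair[2]],
                 tanh(sum(ws * zs) / sum(ws)), tolerance = 1e-10)
  }
  ## symmetry
  expect_equal(coexScores(cx), t(coexScores(cx)))

  ## perfectly correlated pair clamps near 1
  g <- matrix(2^c(1:6, 2 * (1:6)), 2, 6, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  cx2 <- buildCoexpression(ExpressionCompendium(list(d = g)),
                           minDatasets = 1, lowExprQuantile = 0)
  expect_gt(coexScores(cx2)["a", "b"], 0.99)
})

test_that("coverage and noise-floor filters drop the right genes", {
  set.seed(11)
  mk <- function(genes, n = 6) {
    m <- matrix(2^rnorm(length(genes) * n, 8), length(genes), n,
                dimnames = list(genes, NULL))
    m
  }
  ## gRare present in 2 of 3 high-confidence datasets, threshold 3
  ds <- list(d1 = mk(c(paste0("g", 1:9), "gRare")),
             d2 = mk(c(paste0("g", 1:9), "gRare")),
             d3 = mk(paste0("g", 1:9)))
  cx <- buildCoexpression(ExpressionCompendium(ds), minDatasets = 3,
                          lowExprQuantile = 0)
  expect_true("gRare" %in% cx@dropped$lowCoverage)
  expect_false("gRare" %in% rownames(coexScores(cx)))

  ## a systematically bottom-decile gene is removed by the noise-floor rule
  ds2 <- lapply(1:4, function(i) {
    m <- mk(paste0("g", 1:20))
    m["g20", ] <- 2^rnorm(ncol(m), 1)   # far below the rest
    m
  })
  names(ds2) <- paste0("d", 1:4)
  cx2 <- buildCoexpression(ExpressionCompendium(ds2), minDatasets = 1)
  expect_true("g20" %in% cx2@dropped$lowExpression)
  expect_false("g20" %in% rownames(coexScores(cx2)))
})

test_that("rank-sum test matches wilcox and handles ties", {
  set.seed(12)
  ## tie-free exact case agrees with wilcox.test exact p
  x <- rnorm(6); y <- rnorm(7)
  expect_equal(rankSumTest(x, y)$p.value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-10)
  ## large-sample path agrees with normal-approximation wilcox.test
  x2 <- rnorm(40); y2 <- rnorm(60)
  expect_equal(rankSumTest(x2, y2)$p.value,
               wilcox.test(x2, y2, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
  ## ties do not break either path
  xt <- c(1, 1, 2, 3); yt <- c(1, 2, 2, 4)
  expect_true(is.finite(rankSumTest(xt, yt)$p.value))
  ## direction is read from the rank sum
  expect_equal(rankSumTest(c(5, 6, 7), c(1, 2, 3))$direction, "greater")
  expect_equal(rankSumTest(c(1, 2, 3), c(5, 6, 7))$direction, "less")
})

test_that("sign predictions respond to separation and the target minimum", {
  w <- standardWorld()
  net <- standardNet()
  coex <- standardCoex()
  tr <- worldTruth(w)
  ## planted activator and repressor are recovered
  ds <- degreeSummary(net)
  act <- names(tr$sign)[tr$sign == "activator"]
  act <- act[which.max(ds$outDegree[act])]
  rep_ <- names(tr$sign)[tr$sign == "repressor"]
  rep_ <- rep_[which.max(ds$outDegree[rep_])]
  pa <- predictSign(net, coex, act)
  pr <- predictSign(net, coex, rep_)
  expect_equal(pa$call, "activator")
  expect_equal(pr$call, "repressor")
  expect_lt(pa$p, 0.05)
  ## median-ratio display statistics
  mr <- medianRatio(net, coex, act)
  expect_equal(mr$ratio, mr$medianTargets / mr$medianNonTargets)
  ## a TF below the target minimum is not called
  few <- names(ds$outDegree)[ds$outDegree < 10][1]
  pf <- predictSign(net, coex, few)
  expect_equal(pf$call, "none")
  expect_match(pf$reason, "below minimum")
  ## extreme separation: all target scores above all non-target scores
  netX <- qNet(data.frame(tf = "X", promoter = paste0("q", 1:20)),
               promoterGene = setNames(paste0("h", 1:20), paste0("q", 1:20)))
  genes <- c("X", paste0("h", 1:20), paste0("z", 1:30))
  sc <- matrix(0, length(genes), length(genes),
               dimnames = list(genes, genes))
  sc["X", paste0("h", 1:20)] <- sc[paste0("h", 1:20), "X"] <- 0.9
  sc["X", paste0("z", 1:30)] <- sc[paste0("z", 1:30), "X"] <- -0.2
  cxX <- new("CoexpressionScores", scores = sc,
             coverage = setNames(rep(30L, length(genes)), genes),
             dropped = list(lowCoverage = character(0),
                            lowExpression = character(0)))
  ## non-target universe is scored network genes; add z genes to network
  netX2 <- qNet(rbind(pdiEdges(netX),
                      data.frame(tf = "Y", promoter = paste0("r", 1:30))),
                promoterGene = c(setNames(paste0("h", 1:20), paste0("q", 1:20)),
                                 setNames(paste0("z", 1:30), paste0("r", 1:30))))
  px <- predictSign(netX2, cxX, "X")
  expect_equal(px$call, "activator")
  expect_lt(px$p, 1e-6)
  ## zero non-target median: ratio withheld with a flag
  sc0 <- sc
  sc0["X", paste0("z", 1:30)] <- sc0[paste0("z", 1:30), "X"] <- 0
  cx0 <- new("CoexpressionScores", scores = sc0,
             coverage = setNames(rep(30L, length(genes)), genes),
             dropped = list(lowCoverage = character(0),
                            lowExpression = character(0)))
  mr0 <- medianRatio(netX2, cx0, "X")
  expect_true(is.na(mr0$ratio))
  expect_equal(mr0$flag, "zero denominator")
})

test_that("shuffle null separates planted signal from noise", {
  w <- standardWorld()
  net <- standardNet()
  coex <- standardCoex()
  sn <- shuffleNull(net, coex, config = randomizationConfig(100, seed = 3))
  expect_gt(sn$z[["activator"]], 3)
  expect_gt(sn$z[["repressor"]], 3)
  expect_gt(sn$nEligible, 10)
  ## observed counts dominate the null mean
  expect_gt(sum(sn$observed), sum(sn$nullMean) * 3)
  ## single-repetition null flags its degenerate SD
  sn1 <- shuffleNull(net, coex, config = randomizationConfig(2, seed = 4))
  ## (2 reps can tie; just check the flag is consistent with the SD)
  expect_equal(sn1$degenerate, any(sn1$nullSd == 0))
})

test_that("shared-TF-profile co-expression enrichment behaves at its anchors", {
  w <- standardWorld()
  net <- standardNet()
  coex <- standardCoex()
  en <- sharedTFCoexpressionEnrichment(net, coex, maxOutFraction = 0.15)
  ## threshold-0 stratum contains all pairs: enrichment exactly 1
  base <- en[en$jaccard == 0, ]
  expect_true(all(abs(base$enrichment - 1) < 1e-12))
  ## planted co-regulation: top-5% enrichment grows with the Jaccard cut
  e5 <- en[en$topFraction == 0.05 & en$flag == "", ]
  expect_gt(e5$enrichment[e5$jaccard == 0.3],
            e5$enrichment[e5$jaccard == 0])
  expect_lt(e5$p[e5$jaccard == 0.3], 0.01)
})

test_that("spatiotemporal overlap separates activators from repressors", {
  w <- standardWorld()
  net <- standardNet()
  tis <- worldData(w)$tissue
  tr <- worldTruth(w)
  st <- spatiotemporalOverlap(net, tis)
  ## odds ratio recomputes from its own table
  tab <- st$table
  expect_equal(st$oddsRatio,
               (tab[1, 1] / tab[1, 2]) / (tab[2, 1] / tab[2, 2]))
  expect_gt(st$oddsRatio, 1)    # interacting pairs overlap more
  expect_lt(st$p, 0.01)
  ## cutoff is a data quantile, not a constant
  expect_equal(st$cutoff, quantile(st$pcc, 0.75, names = FALSE))
  ## per-TF classes follow the planted signs
  act <- names(tr$sign)[tr$sign == "activator"][1]
  rep_ <- names(tr$sign)[tr$sign == "repressor"][1]
  expect_equal(perTFOverlapClass(net, tis, act)$label, "targets-overlap")
  expect_equal(perTFOverlapClass(net, tis, rep_)$label,
               "non-targets-overlap")
})
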