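test_that("edge switching preserves degrees exactly and is seed-deterministic", {
  ## no legal swap: single edge and complete bipartite 2x2 stay unchanged
  net1 <- qNet(mkEdges("A:p1"))
  expect_identical(pdiEdges(edgeSwitch(net1, randomizationConfig(1, seed = 1))),
                   pdiEdges(net1))
  netC <- qNet(mkEdges(c("A:p1", "A:p2", "B:p1", "B:p2")))
  sw <- edgeSwitch(netC, randomizationConfig(1, seed = 1))
  key <- function(n) sort(with(pdiEdges(n), paste(tf, promoter)))
  expect_identical(key(sw), key(netC))

  ## 100-edge network: degree maps identical pre/post, no duplicate edges
  net <- randNet(nT = 20, nP = 40, nE = 100, seed = 2)
  for (s in c(1, 17, 99)) {
    rn <- edgeSwitch(net, randomizationConfig(1, seed = s))
    expect_equal(table(pdiEdges(rn)$tf), table(pdiEdges(net)$tf))
    expect_equal(table(pdiEdges(rn)$promoter), table(pdiEdges(net)$promoter))
    expect_false(any(duplicated(with(pdiEdges(rn), paste(tf, promoter)))))
  }
  ## same seed -> identical network; different seed -> (generically) different
  a <- edgeSwitch(net, randomizationConfig(1, seed = 5))
  b <- edgeSwitch(net, randomizationConfig(1, seed = 5))
  expect_identical(pdiEdges(a), pdiEdges(b))
  c <- edgeSwitch(net, randomizationConfig(1, seed = 6))
  expect_false(identical(key(a), key(c)))
})

test_that("network overlap counts shared edges on the common node sets", {
  net <- randNet(seed = 4)
  expect_equal(networkOverlap(net, net), nEdges(net))
  other <- qNet(data.frame(tf = "ZZZ", promoter = "P01"))
  expect_error(networkOverlap(net, other), "no TFs in common")
  ## planted 50% overlap
  a <- qNet(mkEdges(c("A:p1", "A:p2", "B:p3", "B:p4")))
  b <- qNet(mkEdges(c("A:p1", "B:p3", "A:p5", "B:p6")))
  expect_equal(networkOverlap(a, b), 2L)
})

test_that("edge-switch null mean matches exhaustive enumeration on tiny networks", {
  ## all 0-1 matrices with fixed margins, enumerated by brute force
  enumerateMargins <- function(rs, cs) {
    nR <- length(rs); nC <- length(cs)
    out <- list()
    recurse <- function(rows, i, colLeft) {
      if (i > nR) { out[[length(out) + 1L]] <<- do.call(rbind, rows); return() }
      for (cols in utils::combn(nC, rs[i], simplify = FALSE)) {
        v <- integer(nC); v[cols] <- 1L
        if (all(colLeft - v >= 0)) {
          recurse(c(rows, list(v)), i + 1L, colLeft - v)
        }
      }
    }
    recurse(list(), 1L, cs)
    Filter(function(m) all(colSums(m) == cs), out)
  }
  rs <- c(2L, 1L, 1L); cs <- c(1L, 1L, 1L, 1L)
  mats <- enumerateMargins(rs, cs)
  ## reference network on the same node space
  ref <- matrix(0L, 3, 4); ref[1, 1] <- ref[1, 2] <- ref[2, 3] <- ref[3, 4] <- 1L
  expOverlap <- mean(vapply(mats, function(m) sum(m * ref), numeric(1)))

  toNet <- function(m) {
    idx <- which(m == 1L, arr.ind = TRUE)
    qNet(data.frame(tf = paste0("T", idx[, 1]),
                    promoter = paste0("P", idx[, 2]),
                    stringsAsFactors = FALSE))
  }
  start <- toNet(mats[[1]])
  refNet <- toNet(ref)
  nulls <- vapply(1:2000, function(s)
    networkOverlap(edgeSwitch(start, randomizationConfig(1, seed = s)),
                   refNet), numeric(1))
  se <- sd(vapply(mats, function(m) sum(m * ref), numeric(1))) / sqrt(2000)
  expect_lt(abs(mean(nulls) - expOverlap), 4 * se + 1e-9)
})

test_that("overlap significance reports z, normal and empirical p", {
  net <- randNet(nT = 20, nP = 40, nE = 120, seed = 9)
  ## reference = the network itself: strong enrichment
  ov <- overlapSignificance(net, net, randomizationConfig(50, seed = 2))
  expect_gt(ov$z, 5)
  expect_lt(ov$pNormal, 1e-6)
  expect_equal(ov$observed, nEdges(net))
  expect_equal(ov$pEmpirical, 1 / 51)
  expect_equal(ov$z, (ov$observed - ov$nullMean) / ov$nullSd)

  ## degenerate null (no legal swap) is flagged instead of a z
  netC <- qNet(mkEdges(c("A:p1", "A:p2", "B:p1", "B:p2")))
  ovC <- overlapSignificance(netC, netC, randomizationConfig(30, seed = 3))
  expect_true(ovC$degenerate)
  expect_true(is.na(ovC$z))

  ## reference sharing no edges: observed 0, empirical p = 1
  ref0 <- qNet(mkEdges(c("T01:P39", "T02:P40")))
  ## (constructed so the common space is non-empty but overlap impossible)
  e <- pdiEdges(net)
  if (!any(paste(e$tf, e$promoter) %in% c("T01 P39", "T02 P40"))) {
    ov0 <- overlapSignificance(net, ref0, randomizationConfig(30, seed = 4))
    expect_equal(ov0$observed, 0L)
    expect_gte(ov0$pEmpirical, 0.5)
  }
  expect_error(overlapSignificance(net, net, randomizationConfig(10)),
               "nRandomizations")
})

test_that("overlap reports serialize with their null samples", {
  net <- randNet(nT = 10, nP = 20, nE = 40, seed = 12)
  ov <- overlapSignificance(net, net, randomizationConfig(30, seed = 1))
  f <- tempfile(); fn <- tempfile()
  writeOverlapResult(ov, f, fn)
  rep <- read.delim(f)
  expect_equal(rep$observed, ov$observed)
  expect_equal(nrow(read.delim(fn)), 30)
})
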