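test_that("energy score is 0.5 on the consensus and falls with mismatches", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(runif(4 * 8, 0.05, 1), 4, 8)
    pwm <- PWMotif(m)
    expect_equal(pwmEnergyScore(pwm, consensusSeq(pwm)), 0.5)
  }
  ## uniform PWM scores every word 0.5
  uni <- PWMotif(matrix(0.25, 4, 6), pseudocount = 0)
  expect_equal(pwmEnergyScore(uni, "ACGTAC"), 0.5)
  expect_equal(pwmEnergyScore(uni, "TTTTTT"), 0.5)

  ## hand computation: three uniform columns contribute zero energy, one
  ## sharp column (0.97, 0.01, 0.01, 0.01); a mismatch there costs ln 97
  sharp <- cbind(rep(0.25, 4), rep(0.25, 4), c(0.97, 0.01, 0.01, 0.01),
                 rep(0.25, 4))
  pwm <- PWMotif(sharp, pseudocount = 0)
  expect_equal(pwmEnergyScore(pwm, "AAAA"), 0.5)        # consensus (A at col 3)
  expect_equal(pwmEnergyScore(pwm, "AACA"), 1 / 98, tolerance = 1e-12)
  ## brute-force scorer agreement on random words
  brute <- function(pwm, word) {
    mm <- motifMatrix(pwm)
    b <- match(strsplit(word, "")[[1]], rownames(mm))
    pr <- prod(mm[cbind(b, seq_along(b))] / apply(mm, 2, max))
    pr / (1 + pr)
  }
  set.seed(7)
  pwm2 <- PWMotif(matrix(runif(4 * 8, 0.05, 1), 4, 8))
  for (i in 1:10) {
    word <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
    expect_equal(pwmEnergyScore(pwm2, word), brute(pwm2, word),
                 tolerance = 1e-10)
  }
  ## monotone: substituting toward a lower-probability base never raises it
  word <- consensusSeq(pwm2)
  for (pos in c(1, 4, 8)) {
    col <- motifMatrix(pwm2)[, pos]
    ord <- names(sort(col, decreasing = TRUE))
    scores <- vapply(ord, function(bb) {
      w <- strsplit(word, "")[[1]]; w[pos] <- bb
      pwmEnergyScore(pwm2, paste(w, collapse = ""))
    }, numeric(1))
    expect_true(all(diff(scores) <= 1e-12))
  }
  expect_error(pwmEnergyScore(pwm2, "ACGTNCGT"), "non-ACGT")
  expect_error(pwmEnergyScore(pwm2, "ACGT"), "length")
})

test_that("promoter scan respects window, strands, and binary binding", {
  cons <- "AACGTGGT"            # non-palindromic, so strands are distinct
  pwm <- PWMotif(local({
    m <- matrix(0.02, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(strsplit(cons, "")[[1]], rownames(m)), 1:8)] <- 0.94
    m
  }))
  bg <- function(n) paste(sample(c("A", "C"), n, TRUE), collapse = "")
  set.seed(1)
  ## consensus inside the proximal window -> bound
  s1 <- paste0(bg(1500), cons, bg(200))
  expect_true(scanPromoter(pwm, s1)$bound)
  ## consensus only in the distal part of a 2 kb promoter -> not bound
  s2 <- paste0(bg(100), cons, bg(1892))
  expect_false(scanPromoter(pwm, s2)$bound)
  ## reverse complement in the window is found iff both strands scanned
  s3 <- paste0(bg(1700), rcKmer(cons), bg(100))
  expect_true(scanPromoter(pwm, s3)$bound)
  expect_false(scanPromoter(pwm, s3,
                            scanConfig(bothStrands = FALSE))$bound)
  ## multiple matches still yield a single binary flag
  s4 <- paste0(bg(100), cons, bg(50), cons, bg(50))
  r4 <- scanPromoter(pwm, s4)
  expect_true(r4$bound)
  expect_gte(length(r4$hits), 2L)
  ## sequence shorter than the motif: warned, not bound
  expect_warning(r5 <- scanPromoter(pwm, "ACGT"), "shorter")
  expect_false(r5$bound)
})

test_that("predicted networks drop non-specific TFs and shrink monotonically", {
  cons <- "GGATCCGA"
  mkPwm <- function(cons, tf) PWMotif(local({
    m <- matrix(0.02, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(strsplit(cons, "")[[1]], rownames(m)), 1:8)] <- 0.94
    m
  }), tfId = tf)
  set.seed(2)
  bg <- function(n) paste(sample(c("A", "C", "T"), n, TRUE), collapse = "")
  proms <- setNames(vapply(1:10, function(i) bg(600), ""), paste0("p", 1:10))
  ## motif planted everywhere -> TF removed, empty network
  withAll <- vapply(proms, function(s) paste0(s, cons, bg(20)), "")
  names(withAll) <- names(proms)
  r1 <- predictedNetwork(list(mkPwm(cons, "TFX")), withAll)
  expect_equal(r1$removed, "TFX")
  expect_equal(nEdges(r1$network), 0L)
  ## motif in exactly one promoter -> one edge
  one <- proms
  one["p3"] <- paste0(substr(one["p3"], 1, 500), cons,
                      substr(one["p3"], 509, 600))
  r2 <- predictedNetwork(list(mkPwm(cons, "TFX")), one)
  expect_equal(pdiEdges(r2$network),
               data.frame(tf = "TFX", promoter = "p3",
                          stringsAsFactors = FALSE))

  ## raising the threshold never adds edges (standard world subset)
  w <- standardWorld()
  pwms <- worldTruth(w)$pwms[1:8]
  seqs <- worldData(w)$promoters[1:80]
  keys <- lapply(c(0.05, 0.09, 0.2), function(th) {
    net <- predictedNetwork(pwms, seqs, scanConfig(threshold = th))$network
    with(pdiEdges(net), paste(tf, promoter))
  })
  expect_true(all(keys[[2]] %in% keys[[1]]))
  expect_true(all(keys[[3]] %in% keys[[2]]))
})

test_that("elementary-motif discovery recovers a planted word", {
  w <- standardWorld()
  net <- standardNet()
  tr <- worldTruth(w)
  proms <- worldData(w)$promoters
  ds <- degreeSummary(net)
  tf <- names(sort(ds$outDegree, decreasing = TRUE))[1]
  pos <- unique(pdiEdges(net)$promoter[pdiEdges(net)$tf == tf])
  neg <- setdiff(names(proms), pos)
  disc <- discoverMotifs(proms[pos], proms[neg])
  expect_gt(nrow(disc$kmers), 0)
  expect_lte(motifDistance(disc$kmers$kmer[1], tr$consensus[tf]), 1)
  expect_true(all(disc$kmers$fdr < 0.05))
  expect_true(all(disc$kmers$enrichment > 2))

  ## positives identical to negatives: nothing is enriched
  same <- proms[sample(names(proms), 60)]
  disc0 <- discoverMotifs(same, same)
  expect_equal(nrow(disc0$kmers), 0L)
  expect_length(disc0$motifs, 0)

  ## below the minimum positive-set size: refusal with message
  expect_error(discoverMotifs(proms[1:40], proms[41:80]),
               "at least 50 bound promoters")
})

test_that("MEME minimal files round-trip", {
  set.seed(3)
  pwms <- lapply(1:3, function(i)
    PWMotif(matrix(runif(4 * 8, 0.05, 1), 4, 8),
            motifId = paste0("m", i), tfId = paste0("TF", i)))
  f <- tempfile(fileext = ".meme")
  writeMEME(pwms, f)
  ## written matrices already carry their pseudocount; read without one
  back <- readMEME(f, pseudocount = 0)
  expect_named(back, c("m1", "m2", "m3"))
  for (i in 1:3) {
    expect_equal(back[[i]]@tfId, paste0("TF", i))
    expect_equal(motifMatrix(back[[i]]), motifMatrix(pwms[[i]]),
                 tolerance = 1e-4)
  }
})
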