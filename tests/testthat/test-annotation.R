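test_that("cofactor classification partitions TFs by partner roles", {
  roles <- c(taf1 = "co-activator", med1 = "co-activator",
             gro1 = "co-repressor", hda1 = "co-repressor",
             misc = "other")
  ppi <- cofactorPPI(data.frame(
    tf = c("A", "B", "B", "C", "D", "E", "E"),
    cofactor = c("taf1", "taf1", "gro1", "misc", "hda1", "med1", "misc")),
    roles)
  expect_equal(classifyByCofactors(ppi, "A"), "activator")
  expect_equal(classifyByCofactors(ppi, "B"), "bifunctional")
  expect_equal(classifyByCofactors(ppi, "C"), "unclassified")
  expect_equal(classifyByCofactors(ppi, "D"), "repressor")
  expect_equal(classifyByCofactors(ppi, "E"), "activator")
  ## invariant to edge order
  ppi2 <- cofactorPPI(ppi$edges[rev(seq_len(nrow(ppi$edges))), ], roles)
  for (tf in c("A", "B", "C", "D", "E"))
    expect_equal(classifyByCofactors(ppi2, tf), classifyByCofactors(ppi, tf))
  ## exactly one label each
  labs <- vapply(c("A", "B", "C", "D", "E"),
                 function(tf) classifyByCofactors(ppi, tf), character(1))
  expect_true(all(labs %in% c("activator", "repressor", "bifunctional",
                              "unclassified")))
})

test_that("cofactor fractions separate planted activators from repressors", {
  roles <- c(a1 = "co-activator", a2 = "co-activator",
             r1 = "co-repressor", r2 = "co-repressor")
  ## maximal separation
  ppi <- cofactorPPI(data.frame(
    tf = c("A1", "A1", "A2", "R1", "R1", "R2"),
    cofactor = c("a1", "a2", "a1", "r1", "r2", "r2")), roles)
  pred <- data.frame(tf = c("A1", "A2", "R1", "R2"),
                     call = c("activator", "activator",
                              "repressor", "repressor"))
  st <- cofactorFractionStats(ppi, pred)
  expect_equal(st$fractions$coactivatorFraction,
               c(1, 1, 0, 0))
  expect_lt(st$pCoactivator, 0.05)
  ## identical groups: no separation
  ppiSame <- cofactorPPI(data.frame(
    tf = c("A1", "A2", "R1", "R2"), cofactor = rep("a1", 4)), roles)
  stSame <- cofactorFractionStats(ppiSame, pred)
  expect_equal(stSame$pCoactivator, 1)

  ## planted synthetic signs: activator group higher co-activator fraction
  w <- standardWorld()
  tr <- worldTruth(w)
  ppiW <- worldData(w)$cofactorPPI
  predW <- data.frame(tf = names(tr$sign), call = unname(tr$sign))
  stW <- cofactorFractionStats(ppiW, predW)
  aMean <- mean(stW$fractions$coactivatorFraction[
    stW$fractions$call == "activator"])
  rMean <- mean(stW$fractions$coactivatorFraction[
    stW$fractions$call == "repressor"])
  expect_gt(aMean, rMean)
  expect_lt(stW$pCoactivator, 0.01)
})

test_that("sign-evidence concordance tolerates bifunctional labels", {
  ev <- data.frame(
    tf = c("A", "A", "B", "B", "C", "C", "D"),
    source = c("coexpression", "cofactor", "coexpression", "cofactor",
               "cofactor", "literature", "literature"),
    call = c("activator", "activator", "activator", "repressor",
             "bifunctional", "activator", "repressor"))
  sc <- signConcordance(ev)
  expect_equal(sc$nMultiSource, 3L)          # D has a single source
  perTF <- setNames(sc$perTF$concordant, sc$perTF$tf)
  expect_true(perTF[["A"]])
  expect_false(perTF[["B"]])
  expect_true(perTF[["C"]])                   # bifunctional is compatible
  expect_equal(sc$fraction, 2 / 3)
})

test_that("Fisher enrichment matches exhaustive enumeration", {
  ## spec-style worked example: universe 20, term 5, targets 5, overlap 4
  proms <- paste0("p", 1:20)
  genes <- setNames(paste0("g", 1:20), proms)
  edges <- rbind(data.frame(tf = "X", promoter = proms[1:5]),
                 data.frame(tf = "Y", promoter = proms))  # Y covers universe
  net <- qNet(edges, promoterGene = genes)
  ann <- list(termGenes = list(T1 = paste0("g", c(1:4, 20)),  # overlap 4
                               T0 = paste0("g", 19:20),       # overlap 0
                               TX = paste0("g", 1:5)))        # = target set
  r <- tfGoEnrichment(net, ann, "X", "T1")
  expect_equal(r$overlap, 4L)
  oracle <- (choose(5, 4) * choose(15, 1) + choose(5, 5)) / choose(20, 5)
  expect_equal(r$p, oracle, tolerance = 1e-12)
  expect_equal(r$fold, 4 / (5 * 5 / 20))
  ## zero overlap with a tiny term: p close to 1
  expect_gt(tfGoEnrichment(net, ann, "X", "T0")$p, 0.4)
  ## term equal to the target set: minimal attainable p for the margins
  pmin_ <- choose(5, 5) * choose(15, 0) / choose(20, 5)
  expect_equal(tfGoEnrichment(net, ann, "X", "TX")$p, pmin_,
               tolerance = 1e-12)
  expect_error(tfGoEnrichment(net, ann, "X", "missing"), "no genes")
  ## cross-check the p machinery against fisher.test on random tables
  set.seed(20)
  for (i in 1:20) {
    N <- sample(10:30, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    if (any(tab < 0)) next
    expect_equal(fisherUpperTail(k, K, n, N),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("association scan applies the filter cascade and dedup rule", {
  w <- standardWorld()
  net <- standardNet()
  go <- worldData(w)$go
  scan <- associationScan(net, go)
  ## out-degree bounds: no surviving TF outside [10, 150]
  outDeg <- table(pdiEdges(net)$tf)
  lowTF <- names(outDeg)[outDeg < 10]
  expect_false(any(scan$associations$tf %in% lowTF))
  ## term-size bounds hold on the annotated network universe
  expect_true(all(scan$associations$termSize >= 10 &
                  scan$associations$termSize <= 200))
  ## duplicate annotated sets: only one of the twin terms is ever tested
  dup <- names(go$termGenes)[duplicated(lapply(go$termGenes, sort)) |
    duplicated(lapply(go$termGenes, sort), fromLast = TRUE)]
  expect_gte(length(dup), 2)
  expect_lt(sum(dup %in% scan$associations$term), length(dup))
  ## the association count is invariant to which duplicate is kept
  n1 <- nrow(associationScan(net, go,
                             config = randomizationConfig(0, seed = 1))$associations)
  n2 <- nrow(associationScan(net, go,
                             config = randomizationConfig(0, seed = 99))$associations)
  expect_equal(n1, n2)
})

test_that("gene-set membership enrichment flags the planted NHR driver", {
  w <- standardWorld()
  net <- standardNet()
  tr <- worldTruth(w)
  fams <- setNames(tr$family, names(tr$family))
  en <- geneSetEnrichment(net, tr$enzymeFamilies[["CYP-like"]])
  nhrs <- names(fams)[fams == "NHR"]
  ## the donor NHR whose targets seeded the family is strongly enriched
  expect_lt(min(en$p[en$tf %in% nhrs]), 0.01)
  ## family-composition comparison runs and reports pooled-z output
  fb <- familyBindingEnrichment(net, tr$enzymeFamilies[["CYP-like"]],
                                fams, "NHR")
  expect_true(is.finite(fb$z))
  expect_equal(fb$p1, fb$familySetEdges / fb$setEdges)
})
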