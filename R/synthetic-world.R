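#' Parameters of the synthetic world
#'
#' Validated parameter list for [generateWorld()]. The defaults define the
#' standard desk-scale world used throughout the test suite: a 50 TF x 400
#' promoter screen whose TF out-degrees follow a rank^(-tailExponent) tail
#' capped at `maxOutFraction` of promoters (so a few hub TFs carry most
#' edges, as gene-centered screens observe); 8 activators and 8 repressors
#' planted with at least 30 targets each and a TF-target expression
#' correlation of 0.5 across 50 profiling datasets; 4 paralog pairs with
#' perturbed copies of one motif and largely shared targets, marked
#' non-essential; GO modules over-sampling the targets of 4 coherent TFs;
#' and bait-quality artifacts (a fraction of promoters with inflated
#' spurious in-degree) so that bait filtering measurably changes network
#' statistics.
#'
#' @param nTFs,nPromoters,promoterLength screen dimensions.
#' @param totalEdges pre-cap intended edge count.
#' @param tailExponent out-degree tail exponent (rank law).
#' @param maxOutFraction cap on a TF's out-degree as a fraction of
#'   promoters.
#' @param motifLength,motifDominance planted motif length and per-column
#'   probability of the consensus base (0.92 gives ~12 bits over 8 bp).
#' @param insertionRate probability a planted edge's motif is inserted.
#' @param dropoutRate probability a placed edge is missed by the screen.
#' @param falsePositiveRate false edges added, as a fraction of placed
#'   edges.
#' @param baitQualityMix named probabilities over `clean`,
#'   `moderate_background`, `high_background`.
#' @param spuriousInDegree Poisson mean of extra spurious edges per
#'   high-background bait.
#' @param activatorFraction,repressorFraction fractions of TFs planted as
#'   activators / repressors.
#' @param signTargetMin minimum intended targets for a signed TF.
#' @param effectCorrelation TF-target expression correlation magnitude.
#' @param nDatasets,samplesRange expression compendium size and per-dataset
#'   sample-count range.
#' @param missingGeneFrac fraction of genes absent from each dataset.
#' @param lowExpressionGeneFrac fraction of genes planted at the noise
#'   floor (exercises the bottom-decile filter).
#' @param nTissueConditions,tissueEffect tissue matrix width and TF-target
#'   tissue correlation.
#' @param nGoTerms,goTermSize,nPlantedGoTFs,plantedGoOverlap GO structure.
#' @param nParalogPairs,paralogReplaceFrac redundancy structure: pairs and
#'   the fraction of a partner's targets resampled.
#' @param cofactorFidelity probability a signed TF's cofactor partner has
#'   the matching role.
#' @param essentialRateBackground,essentialRateRedundant essentiality
#'   probabilities outside / inside the redundant (NHR-like + paralog)
#'   group.
#' @param gcContent background base composition (0.5 = uniform).
#' @param seed root seed; all randomness derives from it.
#' @return validated list with class `"WorldParams"`.
#' @export
worldParams <- function(nTFs = 50, nPromoters = 400, promoterLength = 1000,
                        totalEdges = 2500, tailExponent = 1.4,
                        maxOutFraction = 0.6, motifLength = 8,
                        motifDominance = 0.92, insertionRate = 0.85,
                        dropoutRate = 0.05, falsePositiveRate = 0.05,
                        baitQualityMix = c(clean = 0.85,
                                           moderate_background = 0.08,
                                           high_background = 0.07),
                        spuriousInDegree = 8,
                        activatorFraction = 0.16, repressorFraction = 0.16,
                        signTargetMin = 30, effectCorrelation = 0.5,
                        nDatasets = 50, samplesRange = c(3, 8),
                        missingGeneFrac = 0.1,
                        lowExpressionGeneFrac = 0.05,
                        nTissueConditions = 11, tissueEffect = 0.8,
                        nGoTerms = 40, goTermSize = c(10, 50),
                        nPlantedGoTFs = 4, plantedGoOverlap = 0.7,
                        nParalogPairs = 4, paralogReplaceFrac = 0.3,
                        cofactorFidelity = 0.9,
                        essentialRateBackground = 0.45,
                        essentialRateRedundant = 0.1,
                        gcContent = 0.5, seed = 1L) {
  p <- as.list(environment())
  violations <- character()
  chkFrac <- function(name) {
    v <- p[[name]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1))
      violations <<- c(violations, sprintf("%s must lie in [0, 1]", name))
  }
  for (f in c("maxOutFraction", "motifDominance", "insertionRate",
              "dropoutRate", "falsePositiveRate", "activatorFraction",
              "repressorFraction", "missingGeneFrac",
              "lowExpressionGeneFrac", "plantedGoOverlap",
              "paralogReplaceFrac", "cofactorFidelity",
              "essentialRateBackground", "essentialRateRedundant",
              "gcContent", "baitQualityMix")) chkFrac(f)
  if (p$activatorFraction + p$repressorFraction > 1)
    violations <- c(violations,
                    "activatorFraction + repressorFraction must be <= 1")
  if (abs(sum(p$baitQualityMix) - 1) > 1e-9)
    violations <- c(violations, "baitQualityMix must sum to 1")
  if (!all(c("clean", "moderate_background", "high_background") %in%
           names(p$baitQualityMix)))
    violations <- c(violations,
                    "baitQualityMix must name clean/moderate/high labels")
  if (p$nTFs < 8) violations <- c(violations, "nTFs must be >= 8")
  if (p$nPromoters < 20)
    violations <- c(violations, "nPromoters must be >= 20")
  if (p$promoterLength < p$motifLength)
    violations <- c(violations, "promoterLength must be >= motifLength")
  if (p$motifLength < 6 || p$motifLength > 10)
    violations <- c(violations, "motifLength must be in [6, 10]")
  if (p$effectCorrelation <= 0 || p$effectCorrelation >= 1)
    violations <- c(violations, "effectCorrelation must be in (0, 1)")
  if (p$tissueEffect <= 0 || p$tissueEffect >= 1)
    violations <- c(violations, "tissueEffect must be in (0, 1)")
  if (2 * p$nParalogPairs >
      round((p$activatorFraction + p$repressorFraction) * p$nTFs))
    violations <- c(violations,
                    "nParalogPairs exceeds available signed TFs")
  if (p$samplesRange[1] < 2 || p$samplesRange[2] < p$samplesRange[1])
    violations <- c(violations, "samplesRange must be increasing and >= 2")
  if (p$goTermSize[1] < 1 || p$goTermSize[2] < p$goTermSize[1] ||
      p$goTermSize[2] > p$nPromoters)
    violations <- c(violations,
                    "goTermSize must be increasing and fit the gene count")
  if (length(violations))
    stop("invalid world parameters:\n  ",
         paste(violations, collapse = "\n  "))
  structure(p, class = "WorldParams")
}

.mutateConsensus <- function(cons, nChanges) {
  b <- strsplit(cons, "")[[1]]
  pos <- sample(length(b), nChanges)
  for (i in pos)
    b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

.pwmFromConsensus <- function(cons, dominance, motifId, tfId) {
  b <- strsplit(cons, "")[[1]]
  m <- matrix((1 - dominance) / 3, 4, length(b),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(b, rownames(m)), seq_along(b))] <- dominance
  PWMotif(m, motifId = motifId, tfId = tfId)
}

#' Generate a synthetic world
#'
#' Builds the complete set of synthetic pipeline inputs with planted ground
#' truth; see [worldParams()] for what is planted. Generation is a
#' deterministic function of the parameter list: the root seed fans out to
#' per-component child seeds so each stage's draws are independent of the
#' others.
#'
#' @param params a [worldParams()] list.
#' @return a [SyntheticWorld].
#' @export
generateWorld <- function(params = worldParams()) {
  p <- params
  set.seed(p$seed)
  childSeed <- sample.int(2^31 - 2, 12)

  tfs <- sprintf("TF%02d", seq_len(p$nTFs))
  proms <- sprintf("P%03d", seq_len(p$nPromoters))
  genes <- setNames(sprintf("G%03d", seq_len(p$nPromoters)), proms)

  ## ---- out-degrees: rank law, capped, signed TFs bumped -----------------
  set.seed(childSeed[1])
  raw <- seq_len(p$nTFs)^(-p$tailExponent)
  d <- pmin(round(raw * p$totalEdges / sum(raw)),
            floor(p$maxOutFraction * p$nPromoters))
  d <- pmax(d, 1L)
  nAct <- round(p$activatorFraction * p$nTFs)
  nRep <- round(p$repressorFraction * p$nTFs)
  signedIdx <- seq_len(nAct + nRep)        # highest-degree TFs carry signs
  d[signedIdx] <- pmax(d[signedIdx], p$signTargetMin)
  sign <- setNames(rep("none", p$nTFs), tfs)
  actIdx <- sample(signedIdx, nAct)
  sign[actIdx] <- "activator"
  sign[setdiff(signedIdx, actIdx)] <- "repressor"

  ## ---- paralog pairs, families ------------------------------------------
  set.seed(childSeed[2])
  ## pair TFs of adjacent out-degree so partners have comparable target
  ## counts (paralogs of wildly different degree would not share profiles)
  pairUp <- function(idx, nPairs) {
    if (nPairs == 0 || length(idx) < 2) return(NULL)
    idx <- idx[order(-d[idx])]
    matrix(idx[seq_len(2 * nPairs)], ncol = 2, byrow = TRUE)
  }
  nPairAct <- p$nParalogPairs %/% 2
  nPairRep <- p$nParalogPairs - nPairAct
  pairs <- rbind(pairUp(which(sign == "activator"), nPairAct),
                 pairUp(which(sign == "repressor"), nPairRep))
  paralogIdx <- as.integer(pairs)
  family <- setNames(rep(NA_character_, p$nTFs), tfs)
  family[paralogIdx] <- "NHR"
  rest <- setdiff(seq_len(p$nTFs), paralogIdx)
  nhrExtra <- sample(rest, min(4, length(rest)))
  family[nhrExtra] <- "NHR"
  rest <- setdiff(rest, nhrExtra)
  zf <- sample(rest, min(8, length(rest)))
  family[zf] <- "ZF-C2H2"
  rest <- setdiff(rest, zf)
  family[rest] <- sample(c("HD", "bHLH", "bZIP", "WH-ETS"),
                         length(rest), replace = TRUE)
  nhrIdx <- which(family == "NHR")

  ## ---- motifs: shared base within NHR, near-copies within pairs ---------
  set.seed(childSeed[3])
  randCons <- function()
    paste(sample(c("A", "C", "G", "T"), p$motifLength, TRUE), collapse = "")
  consensus <- setNames(vapply(seq_len(p$nTFs), function(i) randCons(),
                               character(1)), tfs)
  nhrBase <- randCons()
  for (i in nhrIdx) consensus[i] <- .mutateConsensus(nhrBase, 2)
  if (!is.null(pairs))
    for (r in seq_len(nrow(pairs)))
      consensus[pairs[r, 2]] <- .mutateConsensus(consensus[pairs[r, 1]], 1)
  pwms <- lapply(seq_len(p$nTFs), function(i)
    .pwmFromConsensus(consensus[i], p$motifDominance,
                      motifId = paste0("M_", tfs[i]), tfId = tfs[i]))
  names(pwms) <- tfs

  ## ---- intended target sets ---------------------------------------------
  set.seed(childSeed[4])
  ## NHR shared target pool: a minority of promoters, so non-pool draws
  ## always have room
  pool <- sample(p$nPromoters, min(round(0.4 * p$nPromoters), 150))
  drawTargets <- function(i) {
    k <- d[i]
    if (i %in% nhrIdx) {
      fromPool <- min(k, round(0.8 * k), length(pool))
      c(sample(pool, fromPool),
        sample(setdiff(seq_len(p$nPromoters), pool), k - fromPool))
    } else sample(p$nPromoters, k)
  }
  targets <- lapply(seq_len(p$nTFs), drawTargets)
  if (!is.null(pairs))
    for (r in seq_len(nrow(pairs))) {
      m1 <- pairs[r, 1]; m2 <- pairs[r, 2]
      base <- targets[[m1]]
      nKeep <- min(round((1 - p$paralogReplaceFrac) * d[m2]), length(base))
      keep <- sample(base, nKeep)
      fresh <- sample(setdiff(seq_len(p$nPromoters), keep),
                      max(0L, d[m2] - nKeep))
      targets[[m2]] <- c(keep, fresh)
    }
  intended <- do.call(rbind, lapply(seq_len(p$nTFs), function(i)
    data.frame(tf = tfs[i], promoter = proms[targets[[i]]],
               stringsAsFactors = FALSE)))

  ## ---- promoter sequences with planted motifs ---------------------------
  set.seed(childSeed[5])
  baseProb <- c(A = (1 - p$gcContent) / 2, C = p$gcContent / 2,
                G = p$gcContent / 2, T = (1 - p$gcContent) / 2)
  seqs <- vapply(seq_len(p$nPromoters), function(i)
    paste(sample(names(baseProb), p$promoterLength, TRUE, baseProb),
          collapse = ""), character(1))
  names(seqs) <- proms
  window <- min(500L, p$promoterLength)
  placedFlag <- logical(nrow(intended))
  sampleInstance <- function(pwm) {
    m <- motifMatrix(pwm)
    paste(vapply(seq_len(ncol(m)), function(j)
      sample(rownames(m), 1, prob = m[, j]), character(1)), collapse = "")
  }
  lo <- p$promoterLength - window + 1L
  hi <- p$promoterLength - p$motifLength + 1L
  for (r in seq_len(nrow(intended))) {
    if (runif(1) > p$insertionRate) next
    placedFlag[r] <- TRUE
    inst <- sampleInstance(pwms[[intended$tf[r]]])
    pos <- sample(lo:hi, 1)
    s <- seqs[[intended$promoter[r]]]
    substr(s, pos, pos + p$motifLength - 1L) <- inst
    seqs[[intended$promoter[r]]] <- s
  }
  placements <- intended[placedFlag, , drop = FALSE]

  ## ---- emitted network: dropout, false positives, bait artifacts --------
  set.seed(childSeed[6])
  keep <- runif(nrow(placements)) > p$dropoutRate
  emitted <- placements[keep, , drop = FALSE]
  edgeKey <- function(df) paste(df$tf, df$promoter, sep = "\r")
  nFP <- round(p$falsePositiveRate * nrow(placements))
  falseEdges <- data.frame(tf = character(0), promoter = character(0),
                           stringsAsFactors = FALSE)
  if (nFP > 0) {
    cand <- data.frame(tf = tfs[sample.int(p$nTFs, 4 * nFP, TRUE)],
                       promoter = proms[sample.int(p$nPromoters, 4 * nFP,
                                                   TRUE)],
                       stringsAsFactors = FALSE)
    cand <- cand[!edgeKey(cand) %in% edgeKey(intended) &
                 !duplicated(edgeKey(cand)), , drop = FALSE]
    falseEdges <- head(cand, nFP)
  }
  quality <- setNames(sample(names(p$baitQualityMix), p$nPromoters,
                             TRUE, p$baitQualityMix), proms)
  spurious <- data.frame(tf = character(0), promoter = character(0),
                         stringsAsFactors = FALSE)
  for (pr in proms[quality == "high_background"]) {
    nSp <- rpois(1, p$spuriousInDegree)
    if (nSp > 0)
      spurious <- rbind(spurious,
        data.frame(tf = tfs[sample.int(p$nTFs, min(nSp, p$nTFs))],
                   promoter = pr, stringsAsFactors = FALSE))
  }
  allEdges <- rbind(emitted, falseEdges, spurious)
  allEdges <- allEdges[!duplicated(edgeKey(allEdges)), , drop = FALSE]
  lone <- setdiff(proms, unique(allEdges$promoter))
  quality[lone] <- "no_interactions"
  net <- suppressMessages(PDINetwork(
    allEdges, promoterGene = genes, baitQuality = quality,
    nTestedTFs = p$nTFs, nTestedPromoters = p$nPromoters))

  ## ---- expression compendium --------------------------------------------
  set.seed(childSeed[7])
  allGenes <- c(unname(genes), tfs)     # TFs are genes too
  ## a gene regulated by k signed TFs gets an additive effect rho/sqrt(k)
  ## from each, keeping unit variance (the per-regulator correlation decays
  ## with sqrt(k), as shared regulation dilutes attribution)
  regulators <- setNames(vector("list", length(genes)), unname(genes))
  for (i in signedIdx) {
    g <- unname(genes[proms[targets[[i]]]])
    for (gi in g) regulators[[gi]] <- c(regulators[[gi]], tfs[i])
  }
  regulated <- names(regulators)[lengths(regulators) > 0]
  lowGenes <- sample(setdiff(unname(genes), regulated),
                     round(p$lowExpressionGeneFrac * length(genes)))
  rho <- p$effectCorrelation
  signOf <- ifelse(sign == "activator", 1, -1)
  coupleRows <- function(m, tfExpr, rowsPresent, effect) {
    hit <- intersect(rowsPresent, regulated)
    for (g in hit) {
      reg <- regulators[[g]]
      k <- length(reg)
      beta <- effect / sqrt(k)
      drive <- colSums(matrix(signOf[reg] * beta, k, ncol(m)) *
                         tfExpr[reg, , drop = FALSE])
      m[g, ] <- drive + sqrt(max(0, 1 - k * beta^2)) * rnorm(ncol(m))
    }
    m
  }
  dsList <- list()
  for (k in seq_len(p$nDatasets)) {
    nk <- sample(p$samplesRange[1]:p$samplesRange[2], 1)
    presentG <- sample(unname(genes),
                       round((1 - p$missingGeneFrac) * length(genes)))
    rows <- c(presentG, tfs)
    tfExpr <- matrix(rnorm(p$nTFs * nk), p$nTFs, nk,
                     dimnames = list(tfs, NULL))
    m <- matrix(rnorm(length(rows) * nk), length(rows), nk,
                dimnames = list(rows, NULL))
    m[tfs, ] <- tfExpr
    m <- coupleRows(m, tfExpr, presentG, rho)
    baseline <- ifelse(rows %in% lowGenes, 3, 8)
    dsList[[sprintf("DS%03d", k)]] <- round(2^(baseline + m), 4)
  }
  compendium <- ExpressionCompendium(dsList)

  ## ---- tissue x stage matrix --------------------------------------------
  set.seed(childSeed[8])
  nc <- p$nTissueConditions
  condNames <- sprintf("cond%02d", seq_len(nc))
  tissue <- matrix(rnorm(length(allGenes) * nc), length(allGenes), nc,
                   dimnames = list(allGenes, condNames))
  tissue <- coupleRows(tissue, tissue[tfs, , drop = FALSE], unname(genes),
                       p$tissueEffect)

  ## ---- cofactor PPIs -----------------------------------------------------
  set.seed(childSeed[9])
  coact <- sprintf("COA%02d", 1:6)
  corep <- sprintf("COR%02d", 1:6)
  other <- sprintf("COF%02d", 1:4)
  roles <- c(setNames(rep("co-activator", 6), coact),
             setNames(rep("co-repressor", 6), corep),
             setNames(rep("other", 4), other))
  ppiRows <- list()
  for (i in seq_len(p$nTFs)) {
    if (sign[i] != "none") {
      nPart <- 1 + rpois(1, 1)
      match_ <- runif(nPart) < p$cofactorFidelity
      pools <- if (sign[i] == "activator") list(coact, corep)
               else list(corep, coact)
      partners <- unique(vapply(match_, function(ok)
        sample(if (ok) pools[[1]] else pools[[2]], 1), character(1)))
    } else if (runif(1) < 0.5) {
      partners <- sample(other, sample(1:2, 1))
    } else next
    ppiRows[[length(ppiRows) + 1L]] <-
      data.frame(tf = tfs[i], cofactor = partners, stringsAsFactors = FALSE)
  }
  ppi <- cofactorPPI(do.call(rbind, ppiRows), roles)

  ## ---- essentiality ------------------------------------------------------
  set.seed(childSeed[10])
  redundant <- union(paralogIdx, nhrIdx)
  essential <- setNames(
    runif(p$nTFs) < ifelse(seq_len(p$nTFs) %in% redundant,
                           p$essentialRateRedundant,
                           p$essentialRateBackground), tfs)

  ## ---- GO annotation -----------------------------------------------------
  set.seed(childSeed[11])
  geneIds <- unname(genes)
  degIntended <- vapply(targets, length, integer(1))
  goCand <- which(degIntended >= 15 & degIntended <= 150)
  goTFidx <- sample(goCand, min(p$nPlantedGoTFs, length(goCand)))
  termGenes <- list()
  termNames <- character(0)
  plantedGo <- data.frame(tf = character(0), term = character(0),
                          stringsAsFactors = FALSE)
  tcount <- 0L
  for (i in goTFidx) {
    tcount <- tcount + 1L
    id <- sprintf("GO:S%04d", tcount)
    tg <- unname(genes[proms[targets[[i]]]])
    core <- sample(tg, round(p$plantedGoOverlap * min(length(tg), 40)))
    filler <- sample(setdiff(geneIds, core), 8)
    termGenes[[id]] <- sort(c(core, filler))
    termNames[id] <- sprintf("planted process of %s", tfs[i])
    plantedGo <- rbind(plantedGo, data.frame(tf = tfs[i], term = id,
                                             stringsAsFactors = FALSE))
  }
  while (tcount < p$nGoTerms) {
    tcount <- tcount + 1L
    id <- sprintf("GO:S%04d", tcount)
    sz <- sample(p$goTermSize[1]:p$goTermSize[2], 1)
    termGenes[[id]] <- sort(sample(geneIds, sz))
    termNames[id] <- sprintf("random process %d", tcount)
  }
  ## a duplicated annotation set exercises the dedup rule
  dupId <- sprintf("GO:S%04d", tcount + 1L)
  termGenes[[dupId]] <- termGenes[[length(goTFidx) + 1L]]
  termNames[dupId] <- "duplicate of a random process"
  go <- list(termGenes = termGenes, termNames = termNames)

  ## ---- enzyme-like gene families ----------------------------------------
  set.seed(childSeed[12])
  famNames <- c("CYP-like", "GST-like", "UGT-like", "SDR-like")
  enzymeFamilies <- lapply(famNames, function(f) sample(geneIds, 25))
  names(enzymeFamilies) <- famNames
  if (length(nhrIdx)) {
    donor <- nhrIdx[which.max(degIntended[nhrIdx])]
    tg <- unname(genes[proms[targets[[donor]]]])
    enzymeFamilies[["CYP-like"]] <- sort(unique(c(
      sample(tg, min(15, length(tg))),
      sample(geneIds, 10))))
  }

  labels <- data.frame(tf = tfs, family = unname(family),
                       essential = unname(essential),
                       sign = unname(sign), stringsAsFactors = FALSE)
  truth <- list(
    outDegreeIntended = setNames(degIntended, tfs),
    sign = sign, family = family, essential = essential,
    paralogPairs = if (is.null(pairs)) data.frame() else
      data.frame(a = tfs[pairs[, 1]], b = tfs[pairs[, 2]],
                 stringsAsFactors = FALSE),
    consensus = consensus, pwms = pwms,
    intendedEdges = intended, placements = placements,
    falseEdges = falseEdges, spuriousEdges = spurious,
    regulators = regulators, plantedGo = plantedGo,
    nhrPool = proms[pool], enzymeFamilies = enzymeFamilies)
  data <- list(
    network = net,
    promoters = Biostrings::DNAStringSet(seqs),
    compendium = compendium, tissue = tissue, cofactorPPI = ppi,
    go = go, labels = labels)
  new("SyntheticWorld", params = unclass(p), truth = truth, data = data)
}

#' Accessors for SyntheticWorld objects
#'
#' @param x a [SyntheticWorld].
#' @return `worldTruth`: the planted ground truth list; `worldData`: the
#'   emitted datasets list; `worldParamsOf`: the parameter list.
#' @name SyntheticWorld-accessors
NULL

#' @rdname SyntheticWorld-accessors
#' @export
setMethod("worldTruth", "SyntheticWorld", function(x) x@truth)
#' @rdname SyntheticWorld-accessors
#' @export
setMethod("worldData", "SyntheticWorld", function(x) x@data)
#' @rdname SyntheticWorld-accessors
#' @export
setMethod("worldParamsOf", "SyntheticWorld", function(x) x@params)

setMethod("show", "SyntheticWorld", function(object) {
  p <- object@params
  cat("SyntheticWorld:", p$nTFs, "TFs x", p$nPromoters, "promoters,",
      nEdges(object@data$network), "emitted PDIs,",
      p$nDatasets, "expression datasets (seed", p$seed, ")\n")
})

#' Write a world's datasets to standard-format files
#'
#' Emits every dataset consumed by the pipeline — edge-list TSV, promoter
#' FASTA, truth motifs in MEME format, per-dataset expression TSVs with a
#' manifest, tissue TSV, cofactor PPI TSV, GO term-gene TSV, gene-family
#' TSV, TF label TSV — plus a ground-truth JSON and a checksum manifest.
#' All files re-load losslessly with the package's readers.
#'
#' @param world a [SyntheticWorld].
#' @param dir output directory (created if needed).
#' @return data.frame manifest: `file`, `md5`.
#' @export
emitDatasets <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- worldData(world); tr <- worldTruth(world)
  writeEdgeList(d$network, file.path(dir, "network.tsv"))
  Biostrings::writeXStringSet(d$promoters, file.path(dir, "promoters.fa"))
  writeMEME(tr$pwms, file.path(dir, "motifs.meme"))
  writeCompendium(d$compendium, file.path(dir, "compendium"))
  tis <- data.frame(gene_id = rownames(d$tissue), d$tissue,
                    check.names = FALSE)
  write.table(tis, file.path(dir, "tissue.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ppi <- d$cofactorPPI
  write.table(data.frame(tf_id = ppi$edges$tf,
                         cofactor_id = ppi$edges$cofactor,
                         role = unname(ppi$roles[ppi$edges$cofactor])),
              file.path(dir, "cofactor_ppi.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  goDf <- do.call(rbind, lapply(names(d$go$termGenes), function(t)
    data.frame(term_id = t, gene_id = d$go$termGenes[[t]],
               term_name = unname(d$go$termNames[t]),
               stringsAsFactors = FALSE)))
  write.table(goDf, file.path(dir, "go_annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  famDf <- do.call(rbind, lapply(names(tr$enzymeFamilies), function(f)
    data.frame(family = f, gene_id = tr$enzymeFamilies[[f]],
               stringsAsFactors = FALSE)))
  write.table(famDf, file.path(dir, "gene_families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(d$labels, file.path(dir, "tf_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt <- list(seed = world@params$seed,
             sign = as.list(tr$sign),
             essential = as.list(tr$essential),
             family = as.list(tr$family),
             paralogPairs = tr$paralogPairs,
             plantedGo = tr$plantedGo,
             consensus = as.list(tr$consensus))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c("network.tsv", "promoters.fa", "motifs.meme",
             file.path("compendium", "manifest.tsv"), "tissue.tsv",
             "cofactor_ppi.tsv", "go_annotations.tsv", "gene_families.tsv",
             "tf_labels.tsv", "ground_truth.json")
  data.frame(file = files,
             md5 = unname(tools::md5sum(file.path(dir, files))),
             stringsAsFactors = FALSE)
}
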