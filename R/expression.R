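#' Construct an expression compendium
#'
#' @param datasets named list of numeric gene x sample matrices with gene
#'   rownames.
#' @param highConfidenceMin minimum number of experiments (sample columns)
#'   for a dataset to count as high-confidence (default 4).
#' @return an [ExpressionCompendium].
#' @export
ExpressionCompendium <- function(datasets, highConfidenceMin = 4L) {
  stopifnot(is.list(datasets), length(datasets) >= 1,
            !is.null(names(datasets)))
  datasets <- lapply(datasets, as.matrix)
  new("ExpressionCompendium", datasets = datasets,
      nExperiments = vapply(datasets, ncol, integer(1)),
      highConfidenceMin = as.integer(highConfidenceMin))
}

#' Accessors for ExpressionCompendium objects
#'
#' @param x an [ExpressionCompendium].
#' @return `datasets`: named list of matrices; `nExperiments`: named
#'   integer; `highConfidence`: named logical (`nExperiments >=
#'   highConfidenceMin`); `geneUniverse`: union of gene ids.
#' @name ExpressionCompendium-accessors
NULL

#' @rdname ExpressionCompendium-accessors
#' @export
setMethod("datasets", "ExpressionCompendium", function(x) x@datasets)
#' @rdname ExpressionCompendium-accessors
#' @export
setMethod("nExperiments", "ExpressionCompendium", function(x) x@nExperiments)
#' @rdname ExpressionCompendium-accessors
#' @export
setMethod("highConfidence", "ExpressionCompendium", function(x)
  x@nExperiments >= x@highConfidenceMin)
#' @rdname ExpressionCompendium-accessors
#' @export
setMethod("geneUniverse", "ExpressionCompendium", function(x)
  sort(unique(unlist(lapply(x@datasets, rownames), use.names = FALSE))))

setMethod("show", "ExpressionCompendium", function(object) {
  cat("ExpressionCompendium:", length(object@datasets), "datasets (",
      sum(highConfidence(object)), "high-confidence ),",
      length(geneUniverse(object)), "genes\n")
})

#' Read / write a compendium from per-dataset TSVs
#'
#' A compendium directory holds one `genes x samples` TSV per dataset (first
#' column `gene_id`) plus a `manifest.tsv` with columns `dataset_id`,
#' `file`, `n_experiments`.
#'
#' @param dir compendium directory.
#' @return [readCompendium()]: an [ExpressionCompendium].
#' @export
readCompendium <- function(dir) {
  man <- read.delim(file.path(dir, "manifest.tsv"), stringsAsFactors = FALSE)
  ds <- lapply(seq_len(nrow(man)), function(i) {
    d <- read.delim(file.path(dir, man$file[i]), stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
  })
  names(ds) <- man$dataset_id
  ExpressionCompendium(ds)
}

#' @rdname readCompendium
#' @param comp an [ExpressionCompendium] to serialize.
#' @export
writeCompendium <- function(comp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(datasets(comp))
  files <- sprintf("%s.tsv", ids)
  for (i in seq_along(ids)) {
    m <- datasets(comp)[[i]]
    d <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write.table(d, file.path(dir, files[i]), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write.table(data.frame(dataset_id = ids, file = files,
                         n_experiments = unname(nExperiments(comp))),
              file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Integrated co-expression scores
#'
#' Computes a co-expression score for every gene pair by integrating the
#' high-confidence datasets of the compendium: per dataset, the Pearson
#' correlation of `log2(x + 1)` expression across samples; per pair, the
#' Fisher-z transformed correlations are averaged across the datasets that
#' contain both genes, weighted by `n_experiments - 3` (the inverse variance
#' of Fisher z), and back-transformed. Genes present in fewer than
#' `minDatasets` high-confidence datasets are removed, as are genes ranking
#' in the lowest `lowExprQuantile` of mean expression in more than
#' `lowExprDatasetFrac` of the high-confidence datasets containing them
#' (noise floor).
#'
#' @param comp an [ExpressionCompendium] with at least one high-confidence
#'   dataset.
#' @param minDatasets coverage threshold (default 25).
#' @param lowExprQuantile bottom expression quantile (default 0.1).
#' @param lowExprDatasetFrac fraction of datasets in which a gene may sit in
#'   the bottom quantile before removal (default 0.5).
#' @return a [CoexpressionScores].
#' @export
buildCoexpression <- function(comp, minDatasets = 25, lowExprQuantile = 0.1,
                              lowExprDatasetFrac = 0.5) {
  hc <- names(datasets(comp))[highConfidence(comp)]
  if (!length(hc)) stop("no high-confidence datasets")
  ds <- datasets(comp)[hc]
  genes <- sort(unique(unlist(lapply(ds, rownames), use.names = FALSE)))
  coverage <- setNames(integer(length(genes)), genes)
  lowCount <- setNames(integer(length(genes)), genes)
  for (m in ds) {
    g <- rownames(m)
    coverage[g] <- coverage[g] + 1L
    if (lowExprQuantile > 0) {       # 0 disables the noise-floor filter
      mu <- rowMeans(log2(m + 1))
      low <- g[mu <= quantile(mu, lowExprQuantile)]
      lowCount[low] <- lowCount[low] + 1L
    }
  }
  lowCoverage <- genes[coverage < minDatasets]
  lowExpression <- setdiff(
    genes[lowCount > lowExprDatasetFrac * coverage], lowCoverage)
  keep <- setdiff(genes, c(lowCoverage, lowExpression))
  if (!length(keep)) stop("no genes survive the coverage/expression filters")
  n <- length(keep)
  zsum <- matrix(0, n, n, dimnames = list(keep, keep))
  wsum <- matrix(0, n, n, dimnames = list(keep, keep))
  for (i in seq_along(ds)) {
    m <- ds[[i]]
    g <- intersect(rownames(m), keep)
    if (length(g) < 2) next
    r <- suppressWarnings(cor(t(log2(m[g, , drop = FALSE] + 1))))
    r[!is.finite(r)] <- 0              # zero-variance rows contribute z = 0
    z <- atanh(pmin(pmax(r, -0.999999), 0.999999))
    w <- ncol(m) - 3
    if (w <= 0) next                    # 3 samples carry no Fisher-z weight
    zsum[g, g] <- zsum[g, g] + w * z
    wsum[g, g] <- wsum[g, g] + w
  }
  scores <- ifelse(wsum > 0, tanh(zsum / pmax(wsum, 1e-12)), NA_real_)
  diag(scores) <- 1
  dimnames(scores) <- list(keep, keep)
  new("CoexpressionScores", scores = scores, coverage = coverage[keep],
      dropped = list(lowCoverage = lowCoverage,
                     lowExpression = lowExpression))
}

#' Accessors for CoexpressionScores objects
#'
#' @param x a [CoexpressionScores].
#' @return `coexScores`: the symmetric score matrix; `geneCoverage`: named
#'   integer of high-confidence dataset counts.
#' @name CoexpressionScores-accessors
NULL

#' @rdname CoexpressionScores-accessors
#' @export
setMethod("coexScores", "CoexpressionScores", function(x) x@scores)
#' @rdname CoexpressionScores-accessors
#' @export
setMethod("geneCoverage", "CoexpressionScores", function(x) x@coverage)

setMethod("show", "CoexpressionScores", function(object) {
  cat("CoexpressionScores:", nrow(object@scores), "genes;",
      length(object@dropped$lowCoverage), "dropped by coverage,",
      length(object@dropped$lowExpression), "by low expression\n")
})

## target genes (gene ids) of a TF in a network, and the scored universe
.signContext <- function(net, coex, tf, tfGene = tf) {
  scored <- rownames(coexScores(coex))
  netGenes <- unique(unname(promoterGene(net)[unique(pdiEdges(net)$promoter)]))
  universe <- setdiff(intersect(scored, netGenes), tfGene)
  e <- pdiEdges(net)
  targets <- intersect(
    unique(unname(promoterGene(net)[e$promoter[e$tf == tf]])), universe)
  list(universe = universe, targets = targets,
       nonTargets = setdiff(universe, targets),
       tfScored = tfGene %in% scored, tfGene = tfGene)
}

#' Activator/repressor prediction for one TF
#'
#' Compares the TF's co-expression scores with its network targets against
#' its scores with the scored non-target genes by a two-sided Mann-Whitney
#' U test. The TF is called an activator when targets are stochastically
#' higher and `p < alpha`, a repressor when lower, and `none` otherwise. The
#' non-target universe is the scored genes that appear as promoter genes in
#' the network (the TF itself excluded).
#'
#' @param net a [PDINetwork].
#' @param coex a [CoexpressionScores].
#' @param tf TF id; its expression row is looked up as `tfGene`.
#' @param tfGene gene id of the TF in the expression data (default: the TF
#'   id itself).
#' @param minTargets minimum scored targets for a call (default 10).
#' @param alpha significance level (default 0.05).
#' @return list with `tf`, `call` (`"activator"`, `"repressor"`, `"none"`),
#'   `p`, `medianRatio`, `nTargets`, `reason` (why no call, if `none`).
#' @export
predictSign <- function(net, coex, tf, tfGene = tf, minTargets = 10,
                        alpha = 0.05) {
  ctx <- .signContext(net, coex, tf, tfGene)
  if (!ctx$tfScored)
    return(list(tf = tf, call = "none", p = NA_real_,
                medianRatio = NA_real_, nTargets = length(ctx$targets),
                reason = "TF not in co-expression data"))
  if (length(ctx$targets) < minTargets)
    return(list(tf = tf, call = "none", p = NA_real_,
                medianRatio = NA_real_, nTargets = length(ctx$targets),
                reason = "below minimum targets"))
  s <- coexScores(coex)[ctx$tfGene, ]
  xs <- s[ctx$targets]; ys <- s[ctx$nonTargets]
  rt <- rankSumTest(xs, ys)
  call <- "none"
  if (is.finite(rt$p.value) && rt$p.value < alpha)
    call <- if (rt$direction == "greater") "activator" else
            if (rt$direction == "less") "repressor" else "none"
  mr <- if (abs(median(ys, na.rm = TRUE)) < .Machine$double.eps) NA_real_
        else median(xs, na.rm = TRUE) / median(ys, na.rm = TRUE)
  list(tf = tf, call = call, p = rt$p.value, medianRatio = mr,
       nTargets = length(xs), reason = if (call == "none") "not significant"
       else "")
}

#' Sign predictions for all eligible TFs
#'
#' @inheritParams predictSign
#' @param tfGeneMap optional named character mapping TF ids to gene ids.
#' @return data.frame with one row per TF in the network: `tf`, `call`,
#'   `p`, `medianRatio`, `nTargets`, `reason`.
#' @export
predictAllSigns <- function(net, coex, minTargets = 10, alpha = 0.05,
                            tfGeneMap = NULL) {
  tfs <- sort(unique(pdiEdges(net)$tf))
  rows <- lapply(tfs, function(tf) {
    tg <- if (!is.null(tfGeneMap) && tf %in% names(tfGeneMap))
      tfGeneMap[[tf]] else tf
    as.data.frame(predictSign(net, coex, tf, tg, minTargets, alpha),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shuffle null for sign-prediction counts
#'
#' For each eligible TF, the assignment of its co-expression scores to
#' target vs non-target genes is permuted and the activator/repressor call
#' repeated; over `nRandomizations` permutations this yields the null
#' distribution of prediction counts, against which the observed counts are
#' expressed as z-scores. The permutation is implemented by resampling the
#' target index set, which is equivalent to permuting the score vector over
#' the gene universe, using the same midrank statistic as [predictSign()].
#'
#' @inheritParams predictAllSigns
#' @param config a [randomizationConfig()].
#' @return list with `observed` (named counts), `nullCounts` (matrix
#'   n x 2), `nullMean`, `nullSd`, `z` (named, activator and repressor), and
#'   `degenerate` flag when the null SD is zero.
#' @export
shuffleNull <- function(net, coex, minTargets = 10, alpha = 0.05,
                        tfGeneMap = NULL,
                        config = randomizationConfig(1000)) {
  tfs <- sort(unique(pdiEdges(net)$tf))
  ctxs <- list()
  for (tf in tfs) {
    tg <- if (!is.null(tfGeneMap) && tf %in% names(tfGeneMap))
      tfGeneMap[[tf]] else tf
    ctx <- .signContext(net, coex, tf, tg)
    if (!ctx$tfScored || length(ctx$targets) < minTargets) next
    s <- coexScores(coex)[ctx$tfGene, c(ctx$targets, ctx$nonTargets)]
    r <- rank(s)
    n <- length(r); n1 <- length(ctx$targets)
    ties <- table(r)
    sig2 <- n1 * (n - n1) / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    ctxs[[tf]] <- list(r = r, n = n, n1 = n1, sig2 = sig2)
  }
  callCounts <- function(pick) {
    act <- 0L; rep_ <- 0L
    for (cx in ctxs) {
      W <- sum(cx$r[pick(cx)])
      mu <- cx$n1 * (cx$n + 1) / 2
      if (cx$sig2 <= 0) next
      z <- (W - mu) / sqrt(cx$sig2)
      p <- 2 * pnorm(-abs(z))
      if (p < alpha) {
        if (z > 0) act <- act + 1L else rep_ <- rep_ + 1L
      }
    }
    c(activator = act, repressor = rep_)
  }
  observed <- callCounts(function(cx) seq_len(cx$n1))
  set.seed(config$seed)
  nulls <- t(vapply(seq_len(config$nRandomizations), function(i)
    callCounts(function(cx) sample.int(cx$n, cx$n1)), numeric(2)))
  mu <- colMeans(nulls); sdv <- apply(nulls, 2, sd)
  degenerate <- any(!is.finite(sdv)) || any(sdv == 0)
  z <- if (degenerate) setNames(rep(NA_real_, 2), names(observed))
       else (observed - mu) / sdv
  list(observed = observed, nullCounts = nulls, nullMean = mu,
       nullSd = sdv, z = z, degenerate = degenerate,
       nEligible = length(ctxs))
}

#' Median co-expression ratio of targets to non-targets
#'
#' Display statistic accompanying sign calls: the ratio of the TF's median
#' co-expression score with its targets to that with its non-targets.
#'
#' @inheritParams predictSign
#' @return list with `ratio` (NA with `flag = "zero denominator"` when the
#'   non-target median is 0), `medianTargets`, `medianNonTargets`.
#' @export
medianRatio <- function(net, coex, tf, tfGene = tf) {
  ctx <- .signContext(net, coex, tf, tfGene)
  if (!ctx$tfScored) stop("TF not in co-expression data: ", tf)
  s <- coexScores(coex)[ctx$tfGene, ]
  mt <- median(s[ctx$targets], na.rm = TRUE)
  mn <- median(s[ctx$nonTargets], na.rm = TRUE)
  if (!is.finite(mn) || abs(mn) < .Machine$double.eps)
    return(list(ratio = NA_real_, flag = "zero denominator",
                medianTargets = mt, medianNonTargets = mn))
  list(ratio = mt / mn, flag = "", medianTargets = mt, medianNonTargets = mn)
}

#' Co-expression enrichment among genes with shared TF profiles
#'
#' Tests whether gene pairs whose promoters are bound by similar TF sets are
#' enriched among the most co-expressed pairs. Promoters bound by fewer than
#' `minInDegree` TFs are excluded, as are TFs binding at least
#' `maxOutFraction` of tested promoters (hubs would dominate the profiles).
#' For each TF-profile Jaccard threshold and each top co-expression
#' fraction, the fold enrichment of top pairs among threshold-passing pairs
#' relative to all eligible pairs is reported with a one-sided Fisher p.
#'
#' @param net a [PDINetwork].
#' @param coex a [CoexpressionScores].
#' @param jaccardThresholds numeric vector of profile-similarity thresholds.
#' @param topFractions numeric vector of top co-expression fractions.
#' @param minInDegree minimum promoter in-degree (default 3).
#' @param maxOutFraction TF out-degree fraction cutoff (default 0.05).
#' @return data.frame: `jaccard`, `topFraction`, `nPairs`, `nTop`,
#'   `enrichment`, `p`, `flag` (non-empty when a stratum is empty).
#' @export
sharedTFCoexpressionEnrichment <- function(net, coex,
    jaccardThresholds = c(0, 0.1, 0.2, 0.3),
    topFractions = c(0.01, 0.05, 0.10),
    minInDegree = 3, maxOutFraction = 0.05) {
  e <- pdiEdges(net)
  outDeg <- table(e$tf)
  okTF <- names(outDeg)[outDeg < maxOutFraction * nTestedPromoters(net)]
  e <- e[e$tf %in% okTF, , drop = FALSE]
  inDeg <- table(e$promoter)
  okProm <- names(inDeg)[inDeg >= minInDegree]
  e <- e[e$promoter %in% okProm, , drop = FALSE]
  proms <- sort(unique(e$promoter))
  scored <- rownames(coexScores(coex))
  genes <- promoterGene(net)[proms]
  keep <- genes %in% scored
  proms <- proms[keep]; genes <- genes[keep]
  if (length(proms) < 2) stop("fewer than two eligible scored promoters")
  ## promoter x TF incidence -> pairwise Jaccard
  tfs <- sort(unique(e$tf))
  M <- matrix(0L, length(proms), length(tfs),
              dimnames = list(proms, tfs))
  ee <- e[e$promoter %in% proms, , drop = FALSE]
  M[cbind(ee$promoter, ee$tf)] <- 1L
  inter <- tcrossprod(M)
  deg <- rowSums(M)
  uni <- outer(deg, deg, "+") - inter
  J <- ifelse(uni > 0, inter / uni, NA_real_)
  ut <- upper.tri(J)
  sc <- coexScores(coex)[genes, genes]
  sameGene <- outer(genes, genes, "==")
  ok <- ut & !sameGene & is.finite(sc)
  jv <- J[ok]; sv <- sc[ok]
  rows <- list()
  for (f in topFractions) {
    cutoff <- quantile(sv, 1 - f, names = FALSE)
    isTop <- sv >= cutoff
    baseRate <- mean(isTop)
    for (jt in jaccardThresholds) {
      inStr <- jv >= jt
      if (!any(inStr)) {
        rows[[length(rows) + 1L]] <- data.frame(
          jaccard = jt, topFraction = f, nPairs = 0L, nTop = 0L,
          enrichment = NA_real_, p = NA_real_, flag = "empty stratum",
          stringsAsFactors = FALSE)
        next
      }
      a <- sum(isTop & inStr)
      p <- fisherUpperTail(a, sum(isTop), sum(inStr), length(sv))
      rows[[length(rows) + 1L]] <- data.frame(
        jaccard = jt, topFraction = f, nPairs = sum(inStr), nTop = a,
        enrichment = (a / sum(inStr)) / baseRate, p = p, flag = "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read a tissue x stage expression matrix
#'
#' TSV with a `gene_id` first column and one column per tissue-stage
#' condition.
#'
#' @param path file path.
#' @return numeric matrix, genes x conditions.
#' @export
readTissueMatrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Spatiotemporal expression overlap of interacting pairs
#'
#' For every TF-gene pair with tissue data, the Pearson correlation of their
#' expression across the tissue-stage conditions is computed; pairs above
#' the given percentile of all pair correlations are classified as
#' overlapping. The odds of overlap among interacting pairs are compared to
#' those among non-interacting pairs (odds ratio, chi-square test without
#' continuity correction). Zero-variance expression vectors are skipped and
#' counted.
#'
#' @param net a [PDINetwork].
#' @param tissue numeric matrix, genes x conditions (TFs are rows too).
#' @param percentile overlap percentile (default 0.75).
#' @return list with `cutoff`, `table` (2 x 2), `oddsRatio`, `p`,
#'   `nSkipped`, and the per-pair correlation matrix `pcc` (TFs x genes).
#' @export
spatiotemporalOverlap <- function(net, tissue, percentile = 0.75) {
  e <- pdiEdges(net)
  tfs <- intersect(unique(e$tf), rownames(tissue))
  genes <- intersect(unique(unname(promoterGene(net)[unique(e$promoter)])),
                     rownames(tissue))
  genes <- setdiff(genes, tfs)
  if (!length(tfs) || !length(genes))
    stop("no TF or gene rows present in the tissue matrix")
  tvar <- apply(tissue, 1, sd)
  skipTF <- tfs[tvar[tfs] == 0]; skipG <- genes[tvar[genes] == 0]
  nSkipped <- length(skipTF) * length(genes) +
    length(setdiff(tfs, skipTF)) * length(skipG)
  tfs <- setdiff(tfs, skipTF); genes <- setdiff(genes, skipG)
  pcc <- cor(t(tissue[tfs, , drop = FALSE]),
             t(tissue[genes, , drop = FALSE]))
  cutoff <- quantile(pcc, percentile, names = FALSE)
  overlap <- pcc >= cutoff
  interacting <- matrix(FALSE, length(tfs), length(genes),
                        dimnames = dimnames(pcc))
  eg <- data.frame(tf = e$tf, gene = unname(promoterGene(net)[e$promoter]),
                   stringsAsFactors = FALSE)
  eg <- eg[eg$tf %in% tfs & eg$gene %in% genes, , drop = FALSE]
  interacting[cbind(eg$tf, eg$gene)] <- TRUE
  tab <- table(interacting = factor(interacting, c(TRUE, FALSE)),
               overlap = factor(overlap, c(TRUE, FALSE)))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  or <- (a / b) / (cc / d)
  p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  list(cutoff = cutoff, table = tab, oddsRatio = or, p = p,
       nSkipped = nSkipped, pcc = pcc)
}

#' Per-TF spatiotemporal overlap class
#'
#' Compares the odds of tissue-expression overlap among a TF's targets
#' against its non-targets. An odds ratio above 1 labels the TF
#' `targets-overlap`, below 1 `non-targets-overlap`; at exactly 1 the label
#' is withheld (`NA`). A zero cell triggers the Haldane-Anscombe 0.5
#' correction, flagged in the result.
#'
#' @inheritParams spatiotemporalOverlap
#' @param tf TF id (must have at least one target with tissue data).
#' @param cutoff overlap cutoff; when `NULL` (default) it is recomputed from
#'   all pairs at `percentile`, matching [spatiotemporalOverlap()].
#' @return list with `tf`, `label`, `oddsRatio`, `corrected`, `table`.
#' @export
perTFOverlapClass <- function(net, tissue, tf, percentile = 0.75,
                              cutoff = NULL) {
  st <- spatiotemporalOverlap(net, tissue, percentile)
  if (is.null(cutoff)) cutoff <- st$cutoff
  if (!tf %in% rownames(st$pcc)) stop("TF has no tissue data: ", tf)
  e <- pdiEdges(net)
  targets <- intersect(
    unique(unname(promoterGene(net)[e$promoter[e$tf == tf]])),
    colnames(st$pcc))
  if (!length(targets)) stop("TF has no targets with tissue data: ", tf)
  nonTargets <- setdiff(colnames(st$pcc), targets)
  ovT <- st$pcc[tf, targets] >= cutoff
  ovN <- st$pcc[tf, nonTargets] >= cutoff
  tab <- matrix(c(sum(ovT), sum(!ovT), sum(ovN), sum(!ovN)), 2,
                dimnames = list(c("overlap", "no"), c("targets", "non")))
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[1, 1] / t2[2, 1]) / (t2[1, 2] / t2[2, 2])
  label <- if (or > 1) "targets-overlap" else
           if (or < 1) "non-targets-overlap" else NA_character_
  list(tf = tf, label = label, oddsRatio = or, corrected = corrected,
       table = tab)
}
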