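#' Construct a PDI network
#'
#' Builds a [PDINetwork] from an edge table. Repeated detections of the same
#' TF-promoter pair are collapsed to a single binary edge (the number
#' collapsed is reported via a message and the `"collapsed"` attribute).
#'
#' @param edges data.frame with character columns `tf` and `promoter`.
#' @param promoterGene named character mapping promoter ids to gene ids.
#'   Promoters absent from the map default to their own id.
#' @param baitQuality named character mapping promoter ids to a quality
#'   label; unmapped promoters default to `"clean"`. Unknown labels are an
#'   error.
#' @param nTestedTFs,nTestedPromoters size of the tested screen space;
#'   default to the number of ids present.
#' @return A [PDINetwork].
#' @export
PDINetwork <- function(edges, promoterGene = NULL, baitQuality = NULL,
                       nTestedTFs = NA_integer_,
                       nTestedPromoters = NA_integer_) {
  stopifnot(is.data.frame(edges), all(c("tf", "promoter") %in% names(edges)))
  edges <- data.frame(tf = as.character(edges$tf),
                      promoter = as.character(edges$promoter),
                      stringsAsFactors = FALSE)
  key <- paste(edges$tf, edges$promoter, sep = "\r")
  ndup <- sum(duplicated(key))
  if (ndup > 0) {
    edges <- edges[!duplicated(key), , drop = FALSE]
    message(sprintf("collapsed %d duplicate edge(s)", ndup))
  }
  rownames(edges) <- NULL
  tfs <- sort(unique(edges$tf))
  proms <- sort(unique(c(edges$promoter, names(baitQuality),
                         names(promoterGene))))
  pg <- setNames(proms, proms)
  if (!is.null(promoterGene)) pg[names(promoterGene)] <- promoterGene
  bq <- setNames(rep("clean", length(proms)), proms)
  if (!is.null(baitQuality)) {
    bad <- setdiff(unique(baitQuality), .BAIT_QUALITIES)
    if (length(bad))
      stop("unknown bait quality label(s): ", paste(bad, collapse = ", "))
    bq[names(baitQuality)] <- baitQuality
  }
  if (is.na(nTestedTFs)) nTestedTFs <- length(tfs)
  if (is.na(nTestedPromoters)) nTestedPromoters <- length(proms)
  out <- new("PDINetwork", edges = edges, tfIds = tfs, promoterIds = proms,
             promoterGene = pg[proms], baitQuality = bq[proms],
             nTestedTFs = as.integer(nTestedTFs),
             nTestedPromoters = as.integer(nTestedPromoters))
  attr(out, "collapsed") <- ndup
  out
}

#' Accessors for PDINetwork objects
#'
#' @param x a [PDINetwork].
#' @return `pdiEdges`: the edge data.frame; `tfIds`/`promoterIds`: id
#'   vectors; `promoterGene`/`baitQuality`: named maps; `nTestedTFs`,
#'   `nTestedPromoters`, `nEdges`: counts; `testSpace`: number of
#'   TF-promoter combinations tested in the screen
#'   (`nTestedTFs * nTestedPromoters`).
#' @name PDINetwork-accessors
NULL

#' @rdname PDINetwork-accessors
#' @export
setMethod("pdiEdges", "PDINetwork", function(x) x@edges)
#' @rdname PDINetwork-accessors
#' @export
setMethod("tfIds", "PDINetwork", function(x) x@tfIds)
#' @rdname PDINetwork-accessors
#' @export
setMethod("promoterIds", "PDINetwork", function(x) x@promoterIds)
#' @rdname PDINetwork-accessors
#' @export
setMethod("promoterGene", "PDINetwork", function(x) x@promoterGene)
#' @rdname PDINetwork-accessors
#' @export
setMethod("baitQuality", "PDINetwork", function(x) x@baitQuality)
#' @rdname PDINetwork-accessors
#' @export
setMethod("nTestedTFs", "PDINetwork", function(x) x@nTestedTFs)
#' @rdname PDINetwork-accessors
#' @export
setMethod("nTestedPromoters", "PDINetwork", function(x) x@nTestedPromoters)
#' @rdname PDINetwork-accessors
#' @export
setMethod("nEdges", "PDINetwork", function(x) nrow(x@edges))
#' @rdname PDINetwork-accessors
#' @export
setMethod("testSpace", "PDINetwork", function(x)
  as.numeric(x@nTestedTFs) * as.numeric(x@nTestedPromoters))

setMethod("show", "PDINetwork", function(object) {
  cat("PDINetwork:", nrow(object@edges), "PDIs between",
      length(unique(object@promoterGene[unique(object@edges$promoter)])),
      "genes (", length(unique(object@edges$promoter)), "promoters ) and",
      length(unique(object@edges$tf)), "TFs\n")
  cat("  tested space:", object@nTestedTFs, "TFs x",
      object@nTestedPromoters, "promoters\n")
  qt <- table(factor(object@baitQuality, levels = .BAIT_QUALITIES))
  cat("  bait quality:", paste(names(qt), qt, sep = "=", collapse = ", "),
      "\n")
})

#' Read / write a PDI edge list
#'
#' The edge-list TSV has a header and columns for TF, promoter, gene and
#' bait quality (default names `tf_id`, `promoter_id`, `gene_id`,
#' `bait_quality`; remappable through `dialect`). Duplicate rows collapse to
#' one edge.
#'
#' @param path file path.
#' @param dialect named character remapping the canonical column names, e.g.
#'   `c(tf_id = "TF")` if the file calls its TF column "TF".
#' @param nTestedTFs,nTestedPromoters optional tested-space sizes.
#' @return [loadEdgeList()]: a [PDINetwork]. [writeEdgeList()]: the path,
#'   invisibly. Promoters with the quality label `no_interactions` are kept
#'   in the bait table even though they contribute no edges.
#' @export
loadEdgeList <- function(path, dialect = character(),
                         nTestedTFs = NA_integer_,
                         nTestedPromoters = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(d) == 0L) stop("empty edge list: ", path)
  cols <- c(tf_id = "tf_id", promoter_id = "promoter_id",
            gene_id = "gene_id", bait_quality = "bait_quality")
  cols[names(dialect)] <- dialect
  missing <- setdiff(unname(cols[c("tf_id", "promoter_id")]), names(d))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  tf <- d[[cols["tf_id"]]]
  prom <- d[[cols["promoter_id"]]]
  pg <- NULL
  if (cols["gene_id"] %in% names(d))
    pg <- setNames(as.character(d[[cols["gene_id"]]]), prom)
  bq <- NULL
  if (cols["bait_quality"] %in% names(d)) {
    q <- as.character(d[[cols["bait_quality"]]])
    bad <- which(!q %in% .BAIT_QUALITIES)
    if (length(bad))
      stop(sprintf("unknown bait quality label '%s' in row %d",
                   q[bad[1]], bad[1]))
    bq <- setNames(q, prom)
  }
  edges <- data.frame(tf = tf, promoter = prom, stringsAsFactors = FALSE)
  ## baits flagged as producing no interactions carry no edges
  keep <- if (is.null(bq)) rep(TRUE, nrow(edges)) else
    bq[edges$promoter] != "no_interactions"
  PDINetwork(edges[keep, , drop = FALSE], promoterGene = pg,
             baitQuality = bq, nTestedTFs = nTestedTFs,
             nTestedPromoters = nTestedPromoters)
}

#' @rdname loadEdgeList
#' @param net a [PDINetwork] to serialize.
#' @export
writeEdgeList <- function(net, path) {
  e <- pdiEdges(net)
  out <- data.frame(tf_id = e$tf, promoter_id = e$promoter,
                    gene_id = unname(promoterGene(net)[e$promoter]),
                    bait_quality = unname(baitQuality(net)[e$promoter]),
                    stringsAsFactors = FALSE)
  ## edge-less baits (e.g. no_interactions) are serialized with a blank TF
  ## so the bait table round-trips
  lone <- setdiff(promoterIds(net), e$promoter)
  if (length(lone))
    out <- rbind(out, data.frame(tf_id = "", promoter_id = lone,
                                 gene_id = unname(promoterGene(net)[lone]),
                                 bait_quality = unname(baitQuality(net)[lone]),
                                 stringsAsFactors = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a network by bait quality
#'
#' Keeps exactly the edges whose promoter has a quality label in `allowed`,
#' then prunes TF and promoter ids to those with at least one remaining edge.
#' Tested-space counts are preserved. Idempotent.
#'
#' @param net a [PDINetwork].
#' @param allowed non-empty character vector of quality labels.
#' @return filtered [PDINetwork].
#' @export
filterBaits <- function(net, allowed = "clean") {
  stopifnot(length(allowed) >= 1)
  bad <- setdiff(allowed, .BAIT_QUALITIES)
  if (length(bad))
    stop("unknown bait quality label(s): ", paste(bad, collapse = ", "))
  e <- pdiEdges(net)
  keep <- baitQuality(net)[e$promoter] %in% allowed
  e <- e[keep, , drop = FALSE]
  proms <- sort(unique(e$promoter))
  tfs <- sort(unique(e$tf))
  new("PDINetwork", edges = e, tfIds = tfs, promoterIds = proms,
      promoterGene = promoterGene(net)[proms],
      baitQuality = baitQuality(net)[proms],
      nTestedTFs = nTestedTFs(net),
      nTestedPromoters = nTestedPromoters(net))
}

#' Degree statistics of a PDI network
#'
#' Promoter in-degree is the number of distinct TFs bound; TF out-degree is
#' the number of promoters bound, reported both as counts and as fractions of
#' the promoters *tested* (the screen denominator, not promoters with edges).
#'
#' @param net non-empty [PDINetwork].
#' @param lowFractionThreshold fraction below which a TF counts as
#'   low-out-degree (default 0.01, i.e. "binds fewer than 1% of promoters").
#' @return list with `inDegree`, `outDegree` (named integer maps),
#'   `meanInDegree`, `medianInDegree`, `meanOutFraction`,
#'   `medianOutFraction`, and `fractionLowOutDegree`.
#' @export
degreeSummary <- function(net, lowFractionThreshold = 0.01) {
  e <- pdiEdges(net)
  if (nrow(e) == 0L) stop("empty network")
  inDeg <- table(e$promoter)
  outDeg <- table(e$tf)
  inDeg <- setNames(as.integer(inDeg), names(inDeg))
  outDeg <- setNames(as.integer(outDeg), names(outDeg))
  outFrac <- outDeg / nTestedPromoters(net)
  list(
    inDegree = inDeg,
    outDegree = outDeg,
    meanInDegree = mean(inDeg),
    medianInDegree = median(inDeg),
    meanOutFraction = mean(outFrac),
    medianOutFraction = median(outFrac),
    fractionLowOutDegree = mean(outFrac < lowFractionThreshold)
  )
}

#' PDI density matrix over log2 degree bins
#'
#' Bins TFs by out-degree and promoters by in-degree on a log2 scale
#' (bin k holds degrees in `[2^(k-1), 2^k)`), and reports for each bin pair
#' the density of PDIs: edges observed in the cell divided by the number of
#' TF-promoter pairs in the cell (TFs in bin times promoters in bin).
#' Marginal node counts per bin are returned alongside.
#'
#' @param net non-empty [PDINetwork].
#' @return list with `density` (matrix, TF bins x promoter bins), `edgeCount`
#'   (same shape), `tfCounts`, `promoterCounts` (bin marginals), and the bin
#'   assignment maps `tfBin`, `promoterBin`.
#' @export
densityMatrix <- function(net) {
  e <- pdiEdges(net)
  if (nrow(e) == 0L) stop("empty network")
  ds <- degreeSummary(net)
  binOf <- function(d) floor(log2(d)) + 1L
  tfBin <- binOf(ds$outDegree)
  promBin <- binOf(ds$inDegree)
  nbT <- max(tfBin); nbP <- max(promBin)
  tfCounts <- tabulate(tfBin, nbT)
  promCounts <- tabulate(promBin, nbP)
  cnt <- matrix(0, nbT, nbP)
  bt <- tfBin[e$tf]; bp <- promBin[e$promoter]
  for (i in seq_len(nrow(e))) cnt[bt[i], bp[i]] <- cnt[bt[i], bp[i]] + 1
  denom <- outer(tfCounts, promCounts)
  dens <- ifelse(denom > 0, cnt / denom, NA_real_)
  binLab <- function(n) sprintf("[%d,%d)", 2^(seq_len(n) - 1), 2^seq_len(n))
  dimnames(dens) <- dimnames(cnt) <- list(binLab(nbT), binLab(nbP))
  list(density = dens, edgeCount = cnt, tfCounts = tfCounts,
       promoterCounts = promCounts, tfBin = tfBin, promoterBin = promBin)
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Interaction-profile similarities
#'
#' `targetProfileSimilarity` is the Jaccard index of the bound-promoter
#' (bait) sets of two TFs; `tfProfileSimilarity` is the Jaccard index of the
#' bound-TF sets of two promoters. Both are symmetric, lie in `[0, 1]`, and
#' return `NA` when both profiles are empty.
#'
#' @param net a [PDINetwork].
#' @param a,b TF ids (or promoter ids for `tfProfileSimilarity`).
#' @return numeric similarity in `[0, 1]`, or `NA`.
#' @export
targetProfileSimilarity <- function(net, a, b) {
  stopifnot(a %in% tfIds(net), b %in% tfIds(net))
  e <- pdiEdges(net)
  .jaccard(e$promoter[e$tf == a], e$promoter[e$tf == b])
}

#' @rdname targetProfileSimilarity
#' @export
tfProfileSimilarity <- function(net, a, b) {
  stopifnot(a %in% promoterIds(net), b %in% promoterIds(net))
  e <- pdiEdges(net)
  .jaccard(e$tf[e$promoter == a], e$tf[e$promoter == b])
}

#' Read peak and promoter interval files
#'
#' Peaks come as BED 3+1 (chrom, start, end, tf_id; 0-based half-open, no
#' header); promoter intervals as a TSV with header
#' `promoter_id, chrom, start, end, strand` (same convention). Both are
#' returned as `GRanges` (1-based) with the 0-based coordinates preserved in
#' metadata-compatible form.
#'
#' @param path file path.
#' @return a [GenomicRanges::GRanges]; peaks carry a `tf` metadata column,
#'   promoters are named by promoter id.
#' @export
readPeaksBED <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 4) stop("BED 3+1 requires 4 columns")
  names(d)[1:4] <- c("chrom", "start", "end", "tf")
  .intervalsToGRanges(d, mcols = d["tf"])
}

#' @rdname readPeaksBED
#' @export
readPromoterIntervals <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("promoter_id", "chrom", "start", "end")
  if (!all(need %in% names(d)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  gr <- .intervalsToGRanges(d, strand = d$strand)
  names(gr) <- d$promoter_id
  gr
}

.intervalsToGRanges <- function(d, mcols = NULL, strand = NULL) {
  if (any(!is.finite(d$start)) || any(!is.finite(d$end)) ||
      any(d$start < 0) || any(d$start >= d$end))
    stop("malformed interval: require 0 <= start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start + 1L, end = d$end),
    strand = if (is.null(strand)) "*" else
      ifelse(strand %in% c("+", "-"), strand, "*"))
  if (!is.null(mcols)) S4Vectors::mcols(gr) <- mcols
  gr
}

#' Assign ChIP-style peaks to promoters by midpoint
#'
#' A peak is assigned to a promoter when the midpoint of the peak falls
#' inside the promoter interval. Coordinates follow the 0-based half-open
#' convention of the input files, with midpoint `floor((start + end) / 2)`;
#' a midpoint exactly at the promoter end is outside. Multiple peaks of one
#' TF on one promoter collapse to a single interaction.
#'
#' @param peaks `GRanges` with a `tf` metadata column (see [readPeaksBED()]).
#' @param promoters named `GRanges` of promoter intervals.
#' @param promoterGene optional promoter-to-gene map.
#' @return a [PDINetwork] of peak-supported interactions.
#' @export
assignPeaks <- function(peaks, promoters, promoterGene = NULL) {
  stopifnot(methods::is(peaks, "GRanges"), methods::is(promoters, "GRanges"))
  if (is.null(names(promoters))) stop("promoters must be named")
  if (is.null(peaks$tf)) stop("peaks must carry a 'tf' metadata column")
  ## back to 0-based half-open: start0 = start1 - 1, end0 = end1
  mid0 <- floor((GenomicRanges::start(peaks) - 1 +
                 GenomicRanges::end(peaks)) / 2)
  midGR <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                  IRanges::IRanges(mid0 + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(midGR, promoters, ignore.strand = TRUE)
  edges <- data.frame(
    tf = peaks$tf[S4Vectors::queryHits(hits)],
    promoter = names(promoters)[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  suppressMessages(PDINetwork(edges, promoterGene = promoterGene))
}

#' Headline statistics of a screen network
#'
#' Reproduction hook for a screen edge list: applies the bait filter and
#' reports the counts a study of this design headlines — edges, TFs, genes,
#' mean/median in-degree, selected TF out-degrees and shared-target counts.
#' Intended to be pointed at a supplementary interaction table when one is
#' available; works on any [PDINetwork].
#'
#' @param net a [PDINetwork] (unfiltered).
#' @param allowed bait-quality labels retained (default `"clean"`).
#' @param tfsOfInterest optional character vector of TF ids whose out-degree
#'   to report.
#' @param tfPairs optional 2-column matrix/data.frame of TF id pairs whose
#'   shared/union target counts to report.
#' @param minTargets target count threshold for `nTFsWithMinTargets`
#'   (default 50, the motif-discovery eligibility rule).
#' @return list of headline statistics.
#' @export
networkHeadlineStats <- function(net, allowed = "clean",
                                 tfsOfInterest = character(),
                                 tfPairs = NULL, minTargets = 50) {
  f <- filterBaits(net, allowed)
  ds <- degreeSummary(f)
  out <- list(
    nEdges = nEdges(f),
    nTFs = length(unique(pdiEdges(f)$tf)),
    nPromoters = length(unique(pdiEdges(f)$promoter)),
    nGenes = length(unique(promoterGene(f)[unique(pdiEdges(f)$promoter)])),
    meanInDegree = ds$meanInDegree,
    medianInDegree = ds$medianInDegree,
    nTFsWithMinTargets = sum(ds$outDegree >= minTargets)
  )
  if (length(tfsOfInterest))
    out$outDegree <- ds$outDegree[tfsOfInterest]
  if (!is.null(tfPairs)) {
    tfPairs <- as.matrix(tfPairs)
    e <- pdiEdges(f)
    out$sharedTargets <- apply(tfPairs, 1, function(p) {
      ta <- e$promoter[e$tf == p[1]]; tb <- e$promoter[e$tf == p[2]]
      c(shared = length(intersect(ta, tb)), union = length(union(ta, tb)))
    })
  }
  out
}
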