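#' Build the TF association (shared-target) network
#'
#' Nodes are TFs with PDI out-degree at least `minOutDegree`; an undirected
#' edge connects two TFs whose target-profile Jaccard similarity is at least
#' `threshold` (inclusive). Family and essentiality annotations may be
#' attached to the nodes.
#'
#' @param net a non-empty [PDINetwork].
#' @param minOutDegree minimum PDI out-degree for node inclusion (default 3).
#' @param threshold similarity threshold, inclusive (default 0.2).
#' @param family optional named character: family per TF.
#' @param essential optional named logical: essentiality per TF.
#' @return a [TFAssociationNetwork].
#' @export
buildAssociationNetwork <- function(net, minOutDegree = 3, threshold = 0.2,
                                    family = NULL, essential = NULL) {
  e <- pdiEdges(net)
  if (nrow(e) == 0L) stop("empty network")
  outDeg <- table(e$tf)
  tfs <- sort(names(outDeg)[outDeg >= minOutDegree])
  edges <- data.frame(a = character(0), b = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (length(tfs) >= 2) {
    proms <- sort(unique(e$promoter))
    M <- matrix(0L, length(tfs), length(proms),
                dimnames = list(tfs, proms))
    ee <- e[e$tf %in% tfs, , drop = FALSE]
    M[cbind(ee$tf, ee$promoter)] <- 1L
    inter <- tcrossprod(M)
    deg <- rowSums(M)
    uni <- outer(deg, deg, "+") - inter
    J <- inter / uni
    idx <- which(upper.tri(J) & J >= threshold, arr.ind = TRUE)
    if (nrow(idx))
      edges <- data.frame(a = tfs[idx[, 1]], b = tfs[idx[, 2]],
                          similarity = J[idx], stringsAsFactors = FALSE)
  }
  degree <- setNames(integer(length(tfs)), tfs)
  if (nrow(edges)) {
    t1 <- table(edges$a); t2 <- table(edges$b)
    degree[names(t1)] <- degree[names(t1)] + as.integer(t1)
    degree[names(t2)] <- degree[names(t2)] + as.integer(t2)
  }
  nodes <- data.frame(
    tf = tfs,
    outDegree = as.integer(outDeg[tfs]),
    degree = as.integer(degree),
    family = if (is.null(family)) NA_character_ else
      unname(family[tfs]),
    essential = if (is.null(essential)) NA else unname(essential[tfs]),
    stringsAsFactors = FALSE)
  new("TFAssociationNetwork", nodes = nodes, edges = edges,
      threshold = threshold, minOutDegree = as.integer(minOutDegree))
}

#' Accessors for TFAssociationNetwork objects
#'
#' @param x a [TFAssociationNetwork].
#' @return `assocNodes`: node attribute data.frame; `assocEdges`: edge
#'   data.frame with similarities.
#' @name TFAssociationNetwork-accessors
NULL

#' @rdname TFAssociationNetwork-accessors
#' @export
setMethod("assocNodes", "TFAssociationNetwork", function(x) x@nodes)
#' @rdname TFAssociationNetwork-accessors
#' @export
setMethod("assocEdges", "TFAssociationNetwork", function(x) x@edges)

setMethod("show", "TFAssociationNetwork", function(object) {
  cat("TFAssociationNetwork:", nrow(object@nodes), "TFs,",
      nrow(object@edges), "edges (similarity >=", object@threshold,
      ", PDI out-degree >=", object@minOutDegree, ")\n")
})

#' Essentiality versus association-network connectivity
#'
#' Compares the proportion of highly connected TFs (association degree at
#' least `degreeCut`; the default 1 contrasts connected with isolated TFs)
#' between essential and non-essential TFs by a pooled two-proportion
#' z-test; full degree distributions are returned. With one class empty
#' only the descriptive output is produced.
#'
#' @param assoc a [TFAssociationNetwork] with essentiality annotations.
#' @param degreeCut high-connectivity boundary (default 1).
#' @return list with `degreesByClass`, `proportions`, and (when both
#'   classes are non-empty) `z`, `p`, `p.fisher`.
#' @export
essentialityConnectivity <- function(assoc, degreeCut = 1) {
  n <- assocNodes(assoc)
  if (all(is.na(n$essential))) stop("no essentiality annotations")
  ess <- n[n$essential %in% TRUE, ]
  non <- n[n$essential %in% FALSE, ]
  out <- list(degreesByClass = list(essential = ess$degree,
                                    nonEssential = non$degree))
  if (nrow(ess) == 0 || nrow(non) == 0) {
    out$note <- "one essentiality class empty; descriptive output only"
    return(out)
  }
  x1 <- sum(non$degree >= degreeCut); n1 <- nrow(non)
  x2 <- sum(ess$degree >= degreeCut); n2 <- nrow(ess)
  pt <- proportionTest(x1, n1, x2, n2)
  out$proportions <- c(nonEssential = pt$p1, essential = pt$p2)
  out$z <- pt$z
  out$p <- pt$p.value
  out$p.fisher <- pt$p.fisher
  out
}

#' Per-family connectivity and essentiality statistics
#'
#' Each family with at least `minFamilySize` members is compared against
#' all other TFs: association degree by a Mann-Whitney rank test and
#' essential fraction by a pooled two-proportion z-test. Smaller families
#' are skipped (listed in the result).
#'
#' @param assoc a [TFAssociationNetwork] with family annotations.
#' @param minFamilySize minimum family size to test (default 3).
#' @return list with `stats` (data.frame: family, n, medianDegree,
#'   medianDegreeOthers, pDegree, essentialFraction,
#'   essentialFractionOthers, zEssential, pEssential) and `skipped`.
#' @export
familyStats <- function(assoc, minFamilySize = 3) {
  n <- assocNodes(assoc)
  if (all(is.na(n$family))) stop("no family annotations")
  fams <- table(n$family)
  test <- names(fams)[fams >= minFamilySize]
  skipped <- setdiff(names(fams), test)
  rows <- lapply(test, function(f) {
    inF <- n$family == f
    dIn <- n$degree[inF]; dOut <- n$degree[!inF]
    pD <- if (length(dOut) >= 1) rankSumTest(dIn, dOut)$p.value else NA_real_
    eIn <- n$essential[inF]; eOut <- n$essential[!inF]
    hasEss <- !all(is.na(c(eIn, eOut)))
    pt <- if (hasEss)
      proportionTest(sum(eIn, na.rm = TRUE), sum(!is.na(eIn)),
                     sum(eOut, na.rm = TRUE), sum(!is.na(eOut)))
      else NULL
    data.frame(family = f, n = sum(inF),
               medianDegree = median(dIn),
               medianDegreeOthers = median(dOut),
               pDegree = pD,
               essentialFraction = if (hasEss) pt$p1 else NA_real_,
               essentialFractionOthers = if (hasEss) pt$p2 else NA_real_,
               zEssential = if (hasEss) pt$z else NA_real_,
               pEssential = if (hasEss) pt$p.value else NA_real_,
               stringsAsFactors = FALSE)
  })
  list(stats = do.call(rbind, rows), skipped = skipped)
}

#' Export an association network
#'
#' Writes the edge list (tf_a, tf_b, similarity) and the node attribute
#' table as TSVs.
#'
#' @param assoc a [TFAssociationNetwork].
#' @param edgePath,nodePath output paths.
#' @return `edgePath`, invisibly.
#' @export
writeAssociationNetwork <- function(assoc, edgePath, nodePath) {
  e <- assocEdges(assoc)
  write.table(data.frame(tf_a = e$a, tf_b = e$b, similarity = e$similarity),
              edgePath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(assocNodes(assoc), nodePath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(edgePath)
}
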