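#' @import methods
#' @importFrom stats cor median quantile sd setNames rnorm runif rpois
#'   pnorm phyper p.adjust t.test wilcox.test chisq.test complete.cases
#' @importFrom utils read.delim write.table combn head
#' @useDynLib pdinet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Bait quality vocabulary is fixed: unknown labels are rejected, not coerced.
.BAIT_QUALITIES <- c("clean", "moderate_background", "high_background",
                     "no_interactions")

#' Bipartite protein-DNA interaction network
#'
#' A binary bipartite network of TF-to-promoter interactions, as produced by a
#' gene-centered screen such as enhanced yeast one-hybrid. Edges are
#' unweighted and unique; repeated detections of the same pair collapse to a
#' single edge. Each promoter (DNA bait) carries a quality label describing
#' its background reporter activity in the screen, and maps to the gene whose
#' promoter it is. The number of TFs and promoters *tested* in the screen is
#' stored separately from the ids present, because several statistics (e.g.
#' TF out-degree as a fraction of promoters tested) use the tested space as
#' denominator.
#'
#' @slot edges data.frame with character columns `tf` and `promoter`, one row
#'   per unique interaction.
#' @slot tfIds character vector of TF identifiers known to the network.
#' @slot promoterIds character vector of promoter (bait) identifiers.
#' @slot promoterGene named character; maps every promoter id to a gene id.
#' @slot baitQuality named character; maps every promoter id to one of
#'   `"clean"`, `"moderate_background"`, `"high_background"`,
#'   `"no_interactions"`.
#' @slot nTestedTFs integer; TFs assayed in the screen (>= TFs present).
#' @slot nTestedPromoters integer; promoters assayed (>= promoters present).
#' @export
setClass("PDINetwork",
  representation(
    edges = "data.frame",
    tfIds = "character",
    promoterIds = "character",
    promoterGene = "character",
    baitQuality = "character",
    nTestedTFs = "integer",
    nTestedPromoters = "integer"
  )
)

setValidity("PDINetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("tf", "promoter") %in% names(e)))
    msg <- c(msg, "edges must have columns 'tf' and 'promoter'")
  else {
    if (anyDuplicated(paste(e$tf, e$promoter, sep = "\r")))
      msg <- c(msg, "duplicate edges present")
    if (!all(e$tf %in% object@tfIds))
      msg <- c(msg, "edge references unknown tf id")
    if (!all(e$promoter %in% object@promoterIds))
      msg <- c(msg, "edge references unknown promoter id")
  }
  if (!all(object@promoterIds %in% names(object@baitQuality)))
    msg <- c(msg, "baitQuality must be defined for every promoter id")
  if (!all(object@baitQuality %in% .BAIT_QUALITIES))
    msg <- c(msg, sprintf("unknown bait quality label(s): %s",
      paste(unique(setdiff(object@baitQuality, .BAIT_QUALITIES)),
            collapse = ", ")))
  if (!all(object@promoterIds %in% names(object@promoterGene)))
    msg <- c(msg, "promoterGene must be defined for every promoter id")
  if (length(object@nTestedTFs) != 1L || is.na(object@nTestedTFs) ||
      object@nTestedTFs < length(object@tfIds))
    msg <- c(msg, "nTestedTFs must be a single value >= number of TF ids")
  if (length(object@nTestedPromoters) != 1L || is.na(object@nTestedPromoters) ||
      object@nTestedPromoters < length(object@promoterIds))
    msg <- c(msg, "nTestedPromoters must be >= number of promoter ids")
  if (length(msg)) msg else TRUE
})

#' Position weight matrix with energy-based scoring
#'
#' Base-probability matrix (4 x L, rows A/C/G/T) used for energy scoring of
#' promoter windows. A pseudocount is added to every cell at construction and
#' columns are renormalized, so all stored probabilities are strictly
#' positive; the pseudocount used is recorded.
#'
#' @slot motifId character motif identifier.
#' @slot tfId character id of the TF the motif belongs to ("" if unknown).
#' @slot mat 4 x L numeric matrix of base probabilities, columns sum to 1.
#' @slot pseudocount numeric pseudocount added per cell before renormalizing.
#' @export
setClass("PWMotif",
  representation(
    motifId = "character",
    tfId = "character",
    mat = "matrix",
    pseudocount = "numeric"
  )
)

setValidity("PWMotif", function(object) {
  msg <- character()
  m <- object@mat
  if (nrow(m) != 4L || !identical(rownames(m), c("A", "C", "G", "T")))
    msg <- c(msg, "matrix must have 4 rows named A, C, G, T")
  if (ncol(m) < 4L)
    msg <- c(msg, "motif length must be >= 4")
  if (any(m <= 0))
    msg <- c(msg, "probabilities must be > 0 after pseudocount")
  if (any(abs(colSums(m) - 1) > 1e-9))
    msg <- c(msg, "columns must sum to 1 within 1e-9")
  if (length(msg)) msg else TRUE
})

#' Collection of expression profiling datasets
#'
#' Holds per-dataset gene x sample expression tables together with the number
#' of experiments (samples) in each dataset. Datasets with at least
#' `highConfidenceMin` experiments are flagged high-confidence; only those are
#' used when integrating co-expression scores.
#'
#' @slot datasets named list of numeric matrices (genes x samples).
#' @slot nExperiments named integer; samples per dataset.
#' @slot highConfidenceMin integer; minimum experiments for high confidence.
#' @export
setClass("ExpressionCompendium",
  representation(
    datasets = "list",
    nExperiments = "integer",
    highConfidenceMin = "integer"
  )
)

setValidity("ExpressionCompendium", function(object) {
  msg <- character()
  if (length(object@datasets) != length(object@nExperiments))
    msg <- c(msg, "one nExperiments entry per dataset required")
  if (!identical(names(object@datasets), names(object@nExperiments)))
    msg <- c(msg, "dataset names and nExperiments names must match")
  bad <- vapply(object@datasets, function(m)
    !is.matrix(m) || !is.numeric(m) || any(!is.finite(m)), logical(1))
  if (any(bad))
    msg <- c(msg, "all datasets must be finite numeric matrices")
  ok <- vapply(object@datasets, ncol, integer(1)) == object@nExperiments
  if (!all(ok))
    msg <- c(msg, "nExperiments must equal the number of sample columns")
  if (length(msg)) msg else TRUE
})

#' Integrated gene-pair co-expression scores
#'
#' Symmetric gene x gene matrix of integrated co-expression scores (weighted
#' Fisher-z averaged Pearson correlations across high-confidence datasets),
#' plus the per-gene coverage (number of high-confidence datasets containing
#' the gene) for the retained genes.
#'
#' @slot scores symmetric numeric matrix, NA where a pair shares no dataset.
#' @slot coverage named integer per retained gene.
#' @slot dropped list with character vectors `lowCoverage` and
#'   `lowExpression` of genes removed by the coverage and the bottom-decile
#'   expression filters.
#' @export
setClass("CoexpressionScores",
  representation(
    scores = "matrix",
    coverage = "integer",
    dropped = "list"
  )
)

setValidity("CoexpressionScores", function(object) {
  msg <- character()
  s <- object@scores
  if (nrow(s) != ncol(s) || !identical(rownames(s), colnames(s)))
    msg <- c(msg, "scores must be square with matching dimnames")
  if (!identical(sort(names(object@coverage)), sort(rownames(s))))
    msg <- c(msg, "coverage must be named by the score matrix genes")
  if (length(msg)) msg else TRUE
})

#' TF association (shared-target) network
#'
#' Undirected network over TFs in which two TFs are connected when the
#' Jaccard similarity of their bound-promoter sets meets a threshold
#' (inclusive). Nodes are restricted to TFs with at least a minimum
#' out-degree in the underlying PDI network, and carry family and
#' essentiality annotations plus their association degree.
#'
#' @slot nodes data.frame: `tf`, `outDegree`, `degree`, `family`, `essential`.
#' @slot edges data.frame: `a`, `b`, `similarity` with a < b lexicographic.
#' @slot threshold numeric similarity threshold used (inclusive).
#' @slot minOutDegree integer minimum PDI out-degree for inclusion.
#' @export
setClass("TFAssociationNetwork",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    threshold = "numeric",
    minOutDegree = "integer"
  )
)

setValidity("TFAssociationNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$a == e$b)) msg <- c(msg, "self-edges are not allowed")
    if (any(e$similarity < object@threshold))
      msg <- c(msg, "edge below similarity threshold")
    if (!all(c(e$a, e$b) %in% object@nodes$tf))
      msg <- c(msg, "edge references unknown node")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic world with planted ground truth
#'
#' Complete set of synthetic inputs for the pipeline, generated from a single
#' seed, together with the ground truth that was planted: per-TF motifs,
#' regulatory signs, families, essentiality, paralog (redundant) pairs,
#' planted GO associations, and the provenance of every emitted edge.
#'
#' @slot params validated parameter list (see [worldParams()]).
#' @slot truth list of ground-truth objects.
#' @slot data list of emitted datasets (network, promoter sequences, motifs,
#'   expression compendium, tissue matrix, cofactor PPIs, GO annotation,
#'   label table).
#' @export
setClass("SyntheticWorld",
  representation(
    params = "list",
    truth = "list",
    data = "list"
  )
)
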