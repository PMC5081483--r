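#' @rdname PDINetwork-accessors
#' @export
setGeneric("pdiEdges", function(x) standardGeneric("pdiEdges"))

#' @rdname PDINetwork-accessors
#' @export
setGeneric("tfIds", function(x) standardGeneric("tfIds"))

#' @rdname PDINetwork-accessors
#' @export
setGeneric("promoterIds", function(x) standardGeneric("promoterIds"))

#' @rdname PDINetwork-accessors
#' @export
setGeneric("promoterGene", function(x) standardGeneric("promoterGene"))

#' @rdname PDINetwork-accessors
#' @export
setGeneric("baitQuality", function(x) standardGeneric("baitQuality"))

#' @rdname PDINetwork-accessors
#' @export
setGeneric("nTestedTFs", function(x) standardGeneric("nTestedTFs"))

#' @rdname PDINetwork-accessors
#' @export
setGeneric("nTestedPromoters", function(x) standardGeneric("nTestedPromoters"))

#' @rdname PDINetwork-accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname PDINetwork-accessors
#' @export
setGeneric("testSpace", function(x) standardGeneric("testSpace"))

#' @rdname PWMotif-accessors
#' @export
setGeneric("motifMatrix", function(x) standardGeneric("motifMatrix"))

#' @rdname PWMotif-accessors
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))

#' @rdname ExpressionCompendium-accessors
#' @export
setGeneric("datasets", function(x) standardGeneric("datasets"))

#' @rdname ExpressionCompendium-accessors
#' @export
setGeneric("nExperiments", function(x) standardGeneric("nExperiments"))

#' @rdname ExpressionCompendium-accessors
#' @export
setGeneric("highConfidence", function(x) standardGeneric("highConfidence"))

#' @rdname ExpressionCompendium-accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname CoexpressionScores-accessors
#' @export
setGeneric("coexScores", function(x) standardGeneric("coexScores"))

#' @rdname CoexpressionScores-accessors
#' @export
setGeneric("geneCoverage", function(x) standardGeneric("geneCoverage"))

#' @rdname TFAssociationNetwork-accessors
#' @export
setGeneric("assocNodes", function(x) standardGeneric("assocNodes"))

#' @rdname TFAssociationNetwork-accessors
#' @export
setGeneric("assocEdges", function(x) standardGeneric("assocEdges"))

#' @rdname SyntheticWorld-accessors
#' @export
setGeneric("worldTruth", function(x) standardGeneric("worldTruth"))

#' @rdname SyntheticWorld-accessors
#' @export
setGeneric("worldData", function(x) standardGeneric("worldData"))

#' @rdname SyntheticWorld-accessors
#' @export
setGeneric("worldParamsOf", function(x) standardGeneric("worldParamsOf"))
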