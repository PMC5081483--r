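#' Read TF-cofactor protein-protein interactions
#'
#' TSV with header columns `tf_id`, `cofactor_id`, `role`, where role is one
#' of `co-activator`, `co-repressor`, `other`.
#'
#' @param path file path.
#' @return list with `edges` (data.frame `tf`, `cofactor`) and `roles`
#'   (named character per cofactor).
#' @export
readCofactorPPI <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf_id", "cofactor_id", "role")
  if (!all(need %in% names(d)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  bad <- setdiff(unique(d$role), c("co-activator", "co-repressor", "other"))
  if (length(bad))
    stop("unknown cofactor role(s): ", paste(bad, collapse = ", "))
  cofactorPPI(data.frame(tf = d$tf_id, cofactor = d$cofactor_id,
                         stringsAsFactors = FALSE),
              setNames(d$role, d$cofactor_id))
}

#' @rdname readCofactorPPI
#' @param edges data.frame with columns `tf`, `cofactor`.
#' @param roles named character mapping every cofactor id to its role.
#' @export
cofactorPPI <- function(edges, roles) {
  stopifnot(all(c("tf", "cofactor") %in% names(edges)))
  miss <- setdiff(unique(edges$cofactor), names(roles))
  if (length(miss))
    stop("cofactor(s) without role entry: ", paste(miss, collapse = ", "))
  key <- paste(edges$tf, edges$cofactor, sep = "\r")
  edges <- edges[!duplicated(key), c("tf", "cofactor"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, roles = roles), class = "CofactorPPI")
}

#' Regulatory-sign classification from cofactor interactions
#'
#' A TF is classified as an activator when it interacts with at least one
#' co-activator and no co-repressor, a repressor in the converse case,
#' bifunctional when it interacts with both, and unclassified when it has
#' neither kind of partner. The labels partition the TFs and do not depend
#' on edge order.
#'
#' @param ppi a [cofactorPPI()] object.
#' @param tf TF id.
#' @return one of `"activator"`, `"repressor"`, `"bifunctional"`,
#'   `"unclassified"`.
#' @export
classifyByCofactors <- function(ppi, tf) {
  partners <- ppi$edges$cofactor[ppi$edges$tf == tf]
  roles <- ppi$roles[partners]
  hasAct <- any(roles == "co-activator")
  hasRep <- any(roles == "co-repressor")
  if (hasAct && hasRep) "bifunctional"
  else if (hasAct) "activator"
  else if (hasRep) "repressor"
  else "unclassified"
}

#' Cofactor-partner fractions for predicted activators and repressors
#'
#' For each TF with at least one cofactor PPI, the fraction of its partners
#' that are co-activators (and co-repressors) is computed; the co-activator
#' fractions of the predicted-activator group are compared to those of the
#' predicted-repressor group by an unpaired two-tailed Student's t-test.
#'
#' @param ppi a [cofactorPPI()] object.
#' @param predictions data.frame with columns `tf` and `call`
#'   (`"activator"` / `"repressor"`; other calls are ignored).
#' @return list with `fractions` (data.frame: tf, call, nPartners,
#'   coactivatorFraction, corepressorFraction), `pCoactivator`,
#'   `pCorepressor` (NA when a group is empty).
#' @export
cofactorFractionStats <- function(ppi, predictions) {
  predictions <- predictions[predictions$call %in%
                               c("activator", "repressor"), , drop = FALSE]
  rows <- lapply(seq_len(nrow(predictions)), function(i) {
    tf <- predictions$tf[i]
    partners <- ppi$edges$cofactor[ppi$edges$tf == tf]
    if (!length(partners)) return(NULL)
    roles <- ppi$roles[partners]
    data.frame(tf = tf, call = predictions$call[i],
               nPartners = length(partners),
               coactivatorFraction = mean(roles == "co-activator"),
               corepressorFraction = mean(roles == "co-repressor"),
               stringsAsFactors = FALSE)
  })
  fr <- do.call(rbind, rows)
  tPval <- function(col) {
    a <- fr[[col]][fr$call == "activator"]
    r <- fr[[col]][fr$call == "repressor"]
    if (length(a) < 2 || length(r) < 2) return(NA_real_)
    if (sd(a) == 0 && sd(r) == 0)    # degenerate: pooled variance is zero
      return(if (mean(a) == mean(r)) 1 else 0)
    t.test(a, r, var.equal = TRUE)$p.value
  }
  list(fractions = fr,
       pCoactivator = tPval("coactivatorFraction"),
       pCorepressor = tPval("corepressorFraction"))
}

#' Concordance of sign evidence across sources
#'
#' A TF with evidence from two or more sources (co-expression, cofactor
#' PPIs, literature/experiment) is concordant when no two sources give
#' strictly opposite signs; a bifunctional label is compatible with either
#' sign. The fraction of concordant TFs among those with >= 2 sources is
#' reported.
#'
#' @param evidence data.frame with columns `tf`, `source`, `call` (one of
#'   `activator`, `repressor`, `bifunctional`).
#' @return list with `fraction`, `nMultiSource`, and `perTF` (data.frame:
#'   tf, nSources, concordant).
#' @export
signConcordance <- function(evidence) {
  stopifnot(all(c("tf", "source", "call") %in% names(evidence)))
  sp <- split(evidence$call, evidence$tf)
  sp <- sp[vapply(sp, length, integer(1)) >= 2]
  if (!length(sp)) stop("no TF with evidence from >= 2 sources")
  conc <- vapply(sp, function(calls)
    !("activator" %in% calls && "repressor" %in% calls), logical(1))
  list(fraction = mean(conc), nMultiSource = length(sp),
       perTF = data.frame(tf = names(sp),
                          nSources = vapply(sp, length, integer(1)),
                          concordant = conc, row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Read GO biological-process annotations
#'
#' Accepts either a two-column TSV (`term_id`, `gene_id`, optional
#' `term_name`) or a GAF 2.x file (comment lines starting with `!`; the
#' gene symbol in column 3, term in column 5, aspect in column 9 of which
#' only `P` rows are kept).
#'
#' @param path file path.
#' @return list with `termGenes` (named list of gene-id vectors) and
#'   `termNames` (named character, possibly empty).
#' @export
readGOAnnotations <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "!") ||
      length(strsplit(first, "\t")[[1]]) >= 15) {
    d <- read.delim(path, header = FALSE, comment.char = "!",
                    stringsAsFactors = FALSE)
    d <- d[d$V9 == "P", , drop = FALSE]
    termGenes <- lapply(split(d$V3, d$V5), unique)
    return(list(termGenes = termGenes,
                termNames = setNames(character(0), character(0))))
  }
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("term_id", "gene_id")
  if (!all(need %in% names(d)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  termGenes <- lapply(split(d$gene_id, d$term_id), unique)
  termNames <- if ("term_name" %in% names(d))
    setNames(d$term_name, d$term_id)[!duplicated(d$term_id)]
  else setNames(character(0), character(0))
  list(termGenes = termGenes, termNames = termNames)
}

#' TF-GO term enrichment for one pair
#'
#' One-sided Fisher (upper-tail hypergeometric) test of whether a TF's
#' target genes are enriched in a GO term, over the universe of genes whose
#' promoters appear in the network (not the whole genome: this avoids
#' annotation-coverage bias).
#'
#' @param net a [PDINetwork].
#' @param annotations result of [readGOAnnotations()] or a compatible list.
#' @param tf TF id.
#' @param term term id; must overlap the network's gene universe.
#' @return list with `p`, `fold` (observed / expected overlap), `overlap`,
#'   `termSize`, `nTargets`, `universe`.
#' @export
tfGoEnrichment <- function(net, annotations, tf, term) {
  e <- pdiEdges(net)
  universe <- unique(unname(promoterGene(net)[unique(e$promoter)]))
  termGenes <- intersect(annotations$termGenes[[term]], universe)
  if (!length(termGenes))
    stop("term has no genes in the network universe: ", term)
  targets <- unique(unname(promoterGene(net)[e$promoter[e$tf == tf]]))
  k <- length(intersect(targets, termGenes))
  K <- length(termGenes); n <- length(targets); N <- length(universe)
  expected <- K * n / N
  list(p = fisherUpperTail(k, K, n, N),
       fold = if (expected > 0) k / expected else NA_real_,
       overlap = k, termSize = K, nTargets = n, universe = N)
}

## filter cascade shared by the scan and its randomization null
.goScanSetup <- function(net, annotations, minOutDegree, maxOutDegree,
                         minTermSize, maxTermSize, dedupSeed) {
  e <- pdiEdges(net)
  universe <- unique(unname(promoterGene(net)[unique(e$promoter)]))
  outDeg <- table(e$tf)
  tfs <- names(outDeg)[outDeg >= minOutDegree & outDeg <= maxOutDegree]
  termGenes <- lapply(annotations$termGenes, function(g)
    sort(intersect(g, universe)))
  sizes <- vapply(termGenes, length, integer(1))
  termGenes <- termGenes[sizes >= minTermSize & sizes <= maxTermSize]
  ## identical annotated target sets: keep one term, chosen by seeded draw
  if (length(termGenes) > 1) {
    key <- vapply(termGenes, paste, character(1), collapse = "\r")
    set.seed(dedupSeed)
    keep <- unlist(lapply(split(names(termGenes), key), function(ids)
      if (length(ids) == 1) ids else sample(ids, 1)), use.names = FALSE)
    termGenes <- termGenes[sort(keep)]
  }
  list(universe = universe, tfs = tfs, termGenes = termGenes)
}

.goScanCount <- function(edges, promoterGeneMap, setup, pCutoff,
                         collect = FALSE) {
  N <- length(setup$universe)
  rows <- if (collect) list() else NULL
  count <- 0L
  memb <- lapply(setup$termGenes, function(g) setup$universe %in% g)
  uni <- setup$universe
  for (tf in setup$tfs) {
    targets <- unique(unname(promoterGeneMap[edges$promoter[edges$tf == tf]]))
    targets <- intersect(targets, uni)
    n <- length(targets)
    if (n == 0) next
    tIn <- uni %in% targets
    for (term in names(setup$termGenes)) {
      K <- sum(memb[[term]])
      k <- sum(tIn & memb[[term]])
      p <- fisherUpperTail(k, K, n, N)
      if (p < pCutoff) {
        count <- count + 1L
        if (collect)
          rows[[length(rows) + 1L]] <- data.frame(
            tf = tf, term = term, overlap = k, termSize = K, nTargets = n,
            fold = k / (K * n / N), p = p, stringsAsFactors = FALSE)
      }
    }
  }
  if (collect) {
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(tf = character(0), term = character(0),
                 overlap = integer(0), termSize = integer(0),
                 nTargets = integer(0), fold = numeric(0), p = numeric(0))
    if (nrow(df)) df$p_adj <- p.adjust(df$p, method = "BH")
    else df$p_adj <- numeric(0)
    df[order(df$p), , drop = FALSE]
  } else count
}

#' Scan for TF-GO term associations with a randomized-network null
#'
#' Applies the filter cascade — TFs with out-degree below `minOutDegree` or
#' above `maxOutDegree` dropped; terms with fewer than `minTermSize` or more
#' than `maxTermSize` annotated network genes dropped; among terms
#' annotating identical target sets one kept by a seeded random draw — then
#' tests every surviving TF-term pair by a one-sided Fisher test and
#' reports pairs with `p < pCutoff`. The same count is recomputed on
#' degree-preserving edge-switched copies of the network to give the
#' expected-by-chance null.
#'
#' @param net a [PDINetwork].
#' @param annotations GO annotation list (see [readGOAnnotations()]).
#' @param minOutDegree,maxOutDegree TF out-degree bounds (defaults 10, 150).
#' @param minTermSize,maxTermSize annotated-target bounds (defaults 10, 200).
#' @param pCutoff association p cutoff (default 0.001; the framework
#'   controls multiplicity by this hard cutoff plus the randomization null;
#'   a Benjamini-Hochberg column is emitted alongside).
#' @param config a [randomizationConfig()]; set `nRandomizations = 0` to
#'   skip the null.
#' @return list with `associations` (data.frame: tf, term, overlap,
#'   termSize, nTargets, fold, p, p_adj), `nTFs`, `nTerms` (surviving
#'   counts), `nullCounts`, `nullMean`, `nullSd`, `z`.
#' @export
associationScan <- function(net, annotations, minOutDegree = 10,
                            maxOutDegree = 150, minTermSize = 10,
                            maxTermSize = 200, pCutoff = 0.001,
                            config = randomizationConfig(0, seed = 1L)) {
  setup <- .goScanSetup(net, annotations, minOutDegree, maxOutDegree,
                        minTermSize, maxTermSize, config$seed)
  if (!length(setup$tfs) || !length(setup$termGenes)) {
    message("no TFs or terms survive the filter cascade")
    return(list(associations = data.frame(), nTFs = length(setup$tfs),
                nTerms = length(setup$termGenes), nullCounts = numeric(0),
                nullMean = NA_real_, nullSd = NA_real_, z = NA_real_))
  }
  pg <- promoterGene(net)
  assoc <- .goScanCount(pdiEdges(net), pg, setup, pCutoff, collect = TRUE)
  nullCounts <- numeric(0)
  if (config$nRandomizations > 0) {
    set.seed(config$seed)
    seeds <- sample.int(.Machine$integer.max - 1L, config$nRandomizations)
    nullCounts <- vapply(seeds, function(s) {
      rn <- edgeSwitch(net, randomizationConfig(1,
                       config$swapAttemptsFactor, s))
      .goScanCount(pdiEdges(rn), pg, setup, pCutoff)
    }, numeric(1))
  }
  mu <- if (length(nullCounts)) mean(nullCounts) else NA_real_
  sdv <- if (length(nullCounts) > 1) sd(nullCounts) else NA_real_
  z <- if (is.finite(sdv) && sdv > 0) (nrow(assoc) - mu) / sdv else NA_real_
  list(associations = assoc, nTFs = length(setup$tfs),
       nTerms = length(setup$termGenes), nullCounts = nullCounts,
       nullMean = mu, nullSd = sdv, z = z)
}

#' Gene-set membership enrichment per TF
#'
#' Generic gene-set enrichment over user-supplied family sets (e.g. phase
#' I/II detoxifying-enzyme families): for each TF, a one-sided Fisher test
#' of its targets' membership in the set against the network gene universe.
#'
#' @param net a [PDINetwork].
#' @param geneSet character vector of gene ids (the family).
#' @param tfs TFs to test (default: all TFs with edges).
#' @return data.frame: `tf`, `overlap`, `nTargets`, `setSize`, `fold`, `p`,
#'   `p_adj`.
#' @export
geneSetEnrichment <- function(net, geneSet, tfs = NULL) {
  e <- pdiEdges(net)
  universe <- unique(unname(promoterGene(net)[unique(e$promoter)]))
  set <- intersect(geneSet, universe)
  if (!length(set)) stop("gene set has no genes in the network universe")
  if (is.null(tfs)) tfs <- sort(unique(e$tf))
  rows <- lapply(tfs, function(tf) {
    targets <- intersect(
      unique(unname(promoterGene(net)[e$promoter[e$tf == tf]])), universe)
    k <- length(intersect(targets, set))
    n <- length(targets)
    data.frame(tf = tf, overlap = k, nTargets = n, setSize = length(set),
               fold = if (n > 0) k / (length(set) * n / length(universe))
                      else NA_real_,
               p = fisherUpperTail(k, length(set), n, length(universe)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Family composition among set-binding TFs
#'
#' Two-proportion comparison of how often members of a TF family bind a
#' gene set's promoters, relative to the family's overall share of binding
#' in the network (the family-expansion enrichment display).
#'
#' @param net a [PDINetwork].
#' @param geneSet character vector of gene ids.
#' @param families named character: family per TF.
#' @param family family label to test.
#' @return list from [proportionTest()] plus the underlying counts.
#' @export
familyBindingEnrichment <- function(net, geneSet, families, family) {
  e <- pdiEdges(net)
  genes <- unname(promoterGene(net)[e$promoter])
  inSet <- genes %in% geneSet
  fam <- families[e$tf] == family
  x1 <- sum(fam & inSet); n1 <- sum(inSet)
  x2 <- sum(fam); n2 <- length(fam)
  c(proportionTest(x1, n1, x2, n2),
    list(setEdges = n1, familySetEdges = x1, totalEdges = n2,
         familyEdges = x2))
}
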