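#' Pipeline configuration
#'
#' All thresholds of the analysis framework with their standard defaults:
#' PWM scan threshold 0.09 on the (0, 0.5] energy-score scale, 500 bp
#' proximal window, 50% non-specific-TF cutoff; minimum 10 targets and
#' alpha 0.05 for sign calls; GO scan out-degree bounds [10, 150],
#' annotated-term-size bounds [10, 200], association p < 0.001; TF
#' association similarity 0.2 with minimum out-degree 3; spatiotemporal
#' overlap percentile 0.75; 20,000 randomizations for overlap significance
#' and 1,000 for the GO and sign nulls. Input paths may point at files
#' emitted by [emitDatasets()]; with `synthetic = TRUE` the pipeline
#' generates its own world instead.
#'
#' @param inputDir directory of input files (layout of [emitDatasets()]),
#'   or `NULL` with `synthetic = TRUE`.
#' @param synthetic generate a synthetic world instead of reading inputs.
#' @param params [worldParams()] for synthetic mode.
#' @param scanThreshold,scanWindow,nonSpecificFraction PWM scan settings.
#' @param minTargets,signAlpha sign-call settings.
#' @param minCoexpressionDatasets coverage threshold for co-expression.
#' @param goMinOutDegree,goMaxOutDegree,goMinTermSize,goMaxTermSize,goPCutoff
#'   GO scan filter cascade.
#' @param assocSimilarity,assocMinOutDegree association-network settings.
#' @param overlapPercentile spatiotemporal overlap percentile.
#' @param nRandomizationsOverlap,nRandomizationsNull randomization counts
#'   for overlap significance and for the GO / sign nulls.
#' @param seed master seed.
#' @return list with class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(inputDir = NULL, synthetic = is.null(inputDir),
                           params = worldParams(),
                           scanThreshold = 0.09, scanWindow = 500,
                           nonSpecificFraction = 0.5,
                           minTargets = 10, signAlpha = 0.05,
                           minCoexpressionDatasets = 25,
                           goMinOutDegree = 10, goMaxOutDegree = 150,
                           goMinTermSize = 10, goMaxTermSize = 200,
                           goPCutoff = 0.001,
                           assocSimilarity = 0.2, assocMinOutDegree = 3,
                           overlapPercentile = 0.75,
                           nRandomizationsOverlap = 20000,
                           nRandomizationsNull = 1000,
                           seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config a [pipelineConfig()] list.
#' @return character vector of violations; empty when the configuration is
#'   legal.
#' @export
validateConfig <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(config$scanThreshold > 0 && config$scanThreshold <= 0.5,
      "scanThreshold must lie in (0, 0.5]")
  chk(config$scanWindow >= 1, "scanWindow must be >= 1")
  chk(config$nonSpecificFraction > 0 && config$nonSpecificFraction <= 1,
      "nonSpecificFraction must lie in (0, 1]")
  chk(config$minTargets >= 1, "minTargets must be >= 1")
  chk(config$signAlpha > 0 && config$signAlpha < 1,
      "signAlpha must lie in (0, 1)")
  chk(config$minCoexpressionDatasets >= 1,
      "minCoexpressionDatasets must be >= 1")
  chk(config$goMinOutDegree >= 1 &&
        config$goMaxOutDegree >= config$goMinOutDegree,
      "GO out-degree bounds must satisfy 1 <= min <= max")
  chk(config$goMinTermSize >= 1 &&
        config$goMaxTermSize >= config$goMinTermSize,
      "GO term-size bounds must satisfy 1 <= min <= max")
  chk(config$goPCutoff > 0 && config$goPCutoff < 1,
      "goPCutoff must lie in (0, 1)")
  chk(config$assocSimilarity >= 0 && config$assocSimilarity <= 1,
      "assocSimilarity must lie in [0, 1]")
  chk(config$assocMinOutDegree >= 1, "assocMinOutDegree must be >= 1")
  chk(config$overlapPercentile > 0 && config$overlapPercentile < 1,
      "overlapPercentile must lie in (0, 1)")
  chk(config$nRandomizationsOverlap >= 0,
      "nRandomizationsOverlap must be >= 0")
  chk(config$nRandomizationsNull >= 0, "nRandomizationsNull must be >= 0")
  chk(isTRUE(config$synthetic) || !is.null(config$inputDir),
      "either synthetic mode or an inputDir is required")
  v
}

.md5OfObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — network loading and bait
#' filtering, degree statistics and density matrix, motif scan and
#' motif-predicted-network overlap significance, motif discovery, sign
#' predictions with shuffle null, spatiotemporal overlap, cofactor
#' classification and concordance, GO association scan with randomized
#' null, association network with essentiality and family statistics — and
#' returns a per-stage report. A failed stage is recorded and downstream
#' stages with satisfied inputs still run. Reports are reproducible: the
#' same configuration and inputs give the same report.
#'
#' @param config a [pipelineConfig()].
#' @return list with class `"RunReport"`: `stages` (each with `status` and
#'   a `summary`), `provenance` (config hash, seed), `warnings`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  violations <- validateConfig(config)
  if (length(violations))
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  report <- list(stages = list(),
                 provenance = list(configHash = .md5OfObject(
                   config[setdiff(names(config), "params")]),
                   seed = config$seed),
                 warnings = character())
  stage <- function(name, fun) {
    res <- tryCatch(list(status = "ok", summary = fun()),
                    error = function(e)
                      list(status = "failed", summary = conditionMessage(e)))
    report$stages[[name]] <<- res
    res$status == "ok"
  }
  env <- new.env()

  stage("inputs", function() {
    if (isTRUE(config$synthetic)) {
      p <- config$params
      p$seed <- config$seed
      env$world <- generateWorld(do.call(worldParams, unclass(p)))
      env$net0 <- worldData(env$world)$network
      env$promoters <- worldData(env$world)$promoters
      env$pwms <- worldTruth(env$world)$pwms
      env$compendium <- worldData(env$world)$compendium
      env$tissue <- worldData(env$world)$tissue
      env$ppi <- worldData(env$world)$cofactorPPI
      env$go <- worldData(env$world)$go
      env$labels <- worldData(env$world)$labels
      "synthetic world generated"
    } else {
      dir <- config$inputDir
      env$net0 <- loadEdgeList(file.path(dir, "network.tsv"))
      f <- function(x) file.path(dir, x)
      if (file.exists(f("promoters.fa")))
        env$promoters <- Biostrings::readDNAStringSet(f("promoters.fa"))
      if (file.exists(f("motifs.meme")))
        env$pwms <- readMEME(f("motifs.meme"))
      if (dir.exists(f("compendium")))
        env$compendium <- readCompendium(f("compendium"))
      if (file.exists(f("tissue.tsv")))
        env$tissue <- readTissueMatrix(f("tissue.tsv"))
      if (file.exists(f("cofactor_ppi.tsv")))
        env$ppi <- readCofactorPPI(f("cofactor_ppi.tsv"))
      if (file.exists(f("go_annotations.tsv")))
        env$go <- readGOAnnotations(f("go_annotations.tsv"))
      if (file.exists(f("tf_labels.tsv")))
        env$labels <- read.delim(f("tf_labels.tsv"),
                                 stringsAsFactors = FALSE)
      sprintf("inputs read from %s", dir)
    }
  })

  stage("network", function() {
    env$net <- filterBaits(env$net0, "clean")
    ds <- degreeSummary(env$net)
    dm <- densityMatrix(env$net)
    list(nEdges = nEdges(env$net),
         nTFs = length(unique(pdiEdges(env$net)$tf)),
         nPromoters = length(unique(pdiEdges(env$net)$promoter)),
         meanInDegree = ds$meanInDegree,
         medianInDegree = ds$medianInDegree,
         meanOutFraction = ds$meanOutFraction,
         fractionLowOutDegree = ds$fractionLowOutDegree,
         densityBins = dim(dm$density))
  })

  stage("motif_scan", function() {
    if (is.null(env$pwms) || is.null(env$promoters))
      stop("no motifs/promoters supplied")
    sc <- scanConfig(config$scanThreshold, config$scanWindow,
                     config$nonSpecificFraction)
    pred <- predictedNetwork(env$pwms, env$promoters, sc,
                             promoterGene = promoterGene(env$net0))
    env$predicted <- pred$network
    ov <- overlapSignificance(env$net, pred$network,
      randomizationConfig(max(30, config$nRandomizationsOverlap),
                          seed = config$seed + 1L))
    list(nPredictedEdges = nEdges(pred$network),
         nRemovedNonSpecific = length(pred$removed),
         overlapObserved = ov$observed, overlapNullMean = ov$nullMean,
         overlapZ = ov$z, overlapP = ov$pNormal)
  })

  stage("motif_discovery", function() {
    if (is.null(env$promoters)) stop("no promoters supplied")
    ds <- degreeSummary(env$net)
    eligible <- names(ds$outDegree)[ds$outDegree >= 50]
    if (!length(eligible)) stop("no TF with >= 50 targets")
    e <- pdiEdges(env$net)
    out <- lapply(eligible[seq_len(min(3, length(eligible)))], function(tf) {
      pos <- unique(e$promoter[e$tf == tf])
      neg <- setdiff(names(env$promoters), pos)
      disc <- discoverMotifs(env$promoters[pos], env$promoters[neg],
                             window = config$scanWindow)
      list(tf = tf, nKmers = nrow(disc$kmers),
           topConsensus = if (length(disc$motifs))
             consensusSeq(disc$motifs[[1]]) else NA_character_)
    })
    out
  })

  stage("signs", function() {
    if (is.null(env$compendium)) stop("no expression compendium supplied")
    env$coex <- buildCoexpression(env$compendium,
                                  minDatasets = config$minCoexpressionDatasets)
    env$signs <- predictAllSigns(env$net, env$coex,
                                 minTargets = config$minTargets,
                                 alpha = config$signAlpha)
    sn <- shuffleNull(env$net, env$coex, minTargets = config$minTargets,
                      alpha = config$signAlpha,
                      config = randomizationConfig(
                        max(config$nRandomizationsNull, 2),
                        seed = config$seed + 2L))
    list(nActivators = sum(env$signs$call == "activator"),
         nRepressors = sum(env$signs$call == "repressor"),
         nEligible = sn$nEligible, nullMean = sn$nullMean, z = sn$z)
  })

  stage("spatiotemporal", function() {
    if (is.null(env$tissue)) stop("no tissue matrix supplied")
    st <- spatiotemporalOverlap(env$net, env$tissue,
                                config$overlapPercentile)
    list(cutoff = st$cutoff, oddsRatio = st$oddsRatio, p = st$p)
  })

  stage("cofactors", function() {
    if (is.null(env$ppi)) stop("no cofactor PPIs supplied")
    tfs <- sort(unique(env$ppi$edges$tf))
    calls <- vapply(tfs, function(tf) classifyByCofactors(env$ppi, tf),
                    character(1))
    ev <- data.frame(tf = tfs, source = "cofactor", call = calls,
                     stringsAsFactors = FALSE)
    ev <- ev[ev$call != "unclassified", , drop = FALSE]
    conc <- NA_real_
    if (!is.null(env$signs)) {
      ev2 <- env$signs[env$signs$call != "none", c("tf", "call")]
      if (nrow(ev2)) {
        ev2$source <- "coexpression"
        both <- rbind(ev, ev2[, c("tf", "source", "call")])
        if (any(table(both$tf) >= 2))
          conc <- signConcordance(both)$fraction
      }
    }
    list(nActivators = sum(calls == "activator"),
         nRepressors = sum(calls == "repressor"),
         nBifunctional = sum(calls == "bifunctional"),
         concordance = conc)
  })

  stage("go", function() {
    if (is.null(env$go)) stop("no GO annotations supplied")
    scan <- associationScan(env$net, env$go,
      minOutDegree = config$goMinOutDegree,
      maxOutDegree = config$goMaxOutDegree,
      minTermSize = config$goMinTermSize,
      maxTermSize = config$goMaxTermSize,
      pCutoff = config$goPCutoff,
      config = randomizationConfig(max(config$nRandomizationsNull, 1),
                                   seed = config$seed + 3L))
    list(nAssociations = nrow(scan$associations),
         nTFs = length(unique(scan$associations$tf)),
         nullMean = scan$nullMean, z = scan$z)
  })

  stage("association", function() {
    fam <- ess <- NULL
    if (!is.null(env$labels)) {
      fam <- setNames(env$labels$family, env$labels$tf)
      ess <- setNames(env$labels$essential, env$labels$tf)
    }
    env$assoc <- buildAssociationNetwork(env$net,
      minOutDegree = config$assocMinOutDegree,
      threshold = config$assocSimilarity, family = fam, essential = ess)
    out <- list(nNodes = nrow(assocNodes(env$assoc)),
                nEdges = nrow(assocEdges(env$assoc)))
    if (!is.null(ess) && !all(is.na(ess))) {
      ec <- essentialityConnectivity(env$assoc)
      out$connectedFractionNonEssential <- ec$proportions[["nonEssential"]]
      out$connectedFractionEssential <- ec$proportions[["essential"]]
      out$pEssentiality <- ec$p
    }
    out
  })

  report$results <- as.list(env)
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Pipeline run (seed", x$provenance$seed, ", config",
      substr(x$provenance$configHash, 1, 8), ")\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-16s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}
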