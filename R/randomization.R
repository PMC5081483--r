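#' Randomization configuration
#'
#' Bundles the parameters of the degree-preserving randomization null:
#' number of randomized networks, swap-attempt multiplier, and seed. The
#' studies this framework models use 20,000 randomizations for overlap
#' significance and 1,000 for GO and sign nulls; no mixing schedule is
#' standard, so the number of swap attempts per randomization defaults to
#' 100 times the edge count.
#'
#' @param nRandomizations number of randomized copies (0 disables a null).
#' @param swapAttemptsFactor swap attempts per randomization, as a multiple
#'   of the edge count (>= 1).
#' @param seed integer seed; every source of randomness is derived from it.
#' @return list with class `"RandomizationConfig"`.
#' @export
randomizationConfig <- function(nRandomizations = 1000,
                                swapAttemptsFactor = 100, seed = 1L) {
  stopifnot(nRandomizations >= 0, swapAttemptsFactor >= 1)
  structure(list(nRandomizations = as.integer(nRandomizations),
                 swapAttemptsFactor = swapAttemptsFactor,
                 seed = as.integer(seed)),
            class = "RandomizationConfig")
}

#' Degree-preserving edge switching
#'
#' Randomizes a bipartite PDI network by repeated edge switching: two
#' distinct edges (t1, p1), (t2, p2) are drawn uniformly and rewired to
#' (t1, p2), (t2, p1) iff neither rewired edge already exists. Every TF
#' keeps its out-degree and every promoter its in-degree exactly, and the
#' network stays simple (no duplicate edges). The result is a deterministic
#' function of the network and the seed.
#'
#' @param net a [PDINetwork] with >= 2 edges (smaller networks are returned
#'   unchanged: no legal swap exists).
#' @param config a [randomizationConfig()] (only `swapAttemptsFactor` and
#'   `seed` are used).
#' @return a randomized [PDINetwork] with identical degree maps.
#' @export
edgeSwitch <- function(net, config = randomizationConfig()) {
  e <- pdiEdges(net)
  if (nrow(e) < 2L) return(net)
  tfs <- tfIds(net); proms <- promoterIds(net)
  ti <- match(e$tf, tfs); pi <- match(e$promoter, proms)
  attempts <- as.integer(ceiling(config$swapAttemptsFactor * nrow(e)))
  set.seed(config$seed)
  sw <- edge_switch_cpp(ti, pi, length(proms), attempts)
  out <- net
  out@edges <- data.frame(tf = tfs[sw[, 1]], promoter = proms[sw[, 2]],
                          stringsAsFactors = FALSE)
  out
}

#' Shared-edge count between two PDI networks
#'
#' Counts edges present in both networks, restricted to the TFs and
#' promoters present in both (overlap statistics are only meaningful on the
#' common test space).
#'
#' @param netA,netB [PDINetwork] objects.
#' @return integer shared-edge count.
#' @export
networkOverlap <- function(netA, netB) {
  tfs <- intersect(unique(pdiEdges(netA)$tf), unique(pdiEdges(netB)$tf))
  if (length(tfs) == 0L)
    stop("no TFs in common between the two networks")
  proms <- intersect(unique(pdiEdges(netA)$promoter),
                     unique(pdiEdges(netB)$promoter))
  if (length(proms) == 0L)
    stop("no promoters in common between the two networks")
  keyA <- with(pdiEdges(netA), paste(tf, promoter, sep = "\r"))
  keyB <- with(pdiEdges(netB), paste(tf, promoter, sep = "\r"))
  inA <- pdiEdges(netA)$tf %in% tfs & pdiEdges(netA)$promoter %in% proms
  sum(keyA[inA] %in% keyB)
}

#' Overlap significance against a reference network
#'
#' Compares the observed shared-edge count between `net` and `reference`
#' with the distribution of counts obtained from degree-preserving
#' edge-switched copies of `net`. Reports the null mean and SD, the z-score,
#' a one-sided upper-tail p-value assuming a normal null (the enrichment
#' direction), and the empirical p-value `(1 + #null >= obs) / (1 + n)`.
#'
#' @param net [PDINetwork] to randomize.
#' @param reference [PDINetwork] of reference interactions.
#' @param config a [randomizationConfig()]; `nRandomizations >= 30` is
#'   required for the normal-tail p to be reported.
#' @return list with `observed`, `nullMean`, `nullSd`, `z`, `pNormal`,
#'   `pEmpirical`, `degenerate` (TRUE when the null SD is 0, in which case
#'   `z`/`pNormal` are NA), and `nullSamples`.
#' @export
overlapSignificance <- function(net, reference,
                                config = randomizationConfig(1000)) {
  stopifnot(config$nRandomizations >= 30)
  obs <- networkOverlap(net, reference)
  ## child seeds keep each randomization independently reproducible
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$nRandomizations)
  nulls <- vapply(seeds, function(s) {
    rc <- randomizationConfig(1, config$swapAttemptsFactor, s)
    networkOverlap(edgeSwitch(net, rc), reference)
  }, numeric(1))
  mu <- mean(nulls); sdv <- sd(nulls)
  degenerate <- !is.finite(sdv) || sdv == 0
  z <- if (degenerate) NA_real_ else (obs - mu) / sdv
  list(observed = obs, nullMean = mu, nullSd = sdv, z = z,
       pNormal = if (degenerate) NA_real_ else pnorm(z, lower.tail = FALSE),
       pEmpirical = (1 + sum(nulls >= obs)) / (1 + length(nulls)),
       degenerate = degenerate, nullSamples = nulls)
}

#' Export an overlap result
#'
#' Writes the overlap report (observed, mean, sd, z, p_normal, p_empirical)
#' as a one-row TSV and, optionally, the null samples as a one-column TSV
#' for audit.
#'
#' @param res result of [overlapSignificance()].
#' @param path report path.
#' @param nullPath optional path for the null samples.
#' @return `path`, invisibly.
#' @export
writeOverlapResult <- function(res, path, nullPath = NULL) {
  df <- data.frame(observed = res$observed, mean = res$nullMean,
                   sd = res$nullSd, z = res$z, p_normal = res$pNormal,
                   p_empirical = res$pEmpirical)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nullPath))
    write.table(data.frame(overlap = res$nullSamples), nullPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}
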