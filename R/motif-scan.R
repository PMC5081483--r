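#' Construct a position weight matrix
#'
#' Normalizes the supplied base-count or base-probability matrix, adds the
#' pseudocount to every cell and renormalizes columns, so the stored
#' probabilities are strictly positive.
#'
#' @param mat 4 x L numeric matrix; rows A, C, G, T (rownames optional, this
#'   order assumed).
#' @param motifId,tfId identifiers.
#' @param pseudocount per-cell pseudocount (default 0.001; it avoids
#'   minus-infinite log-probabilities on zero entries and is negligible
#'   elsewhere).
#' @return a [PWMotif].
#' @export
PWMotif <- function(mat, motifId = "motif", tfId = "",
                    pseudocount = 0.001) {
  stopifnot(is.matrix(mat), nrow(mat) == 4)
  mat <- sweep(mat, 2, colSums(mat), "/")
  mat <- mat + pseudocount
  mat <- sweep(mat, 2, colSums(mat), "/")
  rownames(mat) <- c("A", "C", "G", "T")
  new("PWMotif", motifId = motifId, tfId = tfId, mat = mat,
      pseudocount = pseudocount)
}

#' Accessors for PWMotif objects
#'
#' @param x a [PWMotif].
#' @return `motifMatrix`: the 4 x L probability matrix; `consensusSeq`: the
#'   consensus (per-column argmax) as a character string.
#' @name PWMotif-accessors
NULL

#' @rdname PWMotif-accessors
#' @export
setMethod("motifMatrix", "PWMotif", function(x) x@mat)
#' @rdname PWMotif-accessors
#' @export
setMethod("consensusSeq", "PWMotif", function(x)
  paste(rownames(x@mat)[apply(x@mat, 2, which.max)], collapse = ""))

setMethod("show", "PWMotif", function(object) {
  cat("PWMotif", object@motifId,
      if (nzchar(object@tfId)) paste0("(", object@tfId, ")") else "",
      "length", ncol(object@mat), "consensus", consensusSeq(object), "\n")
})

#' Scan configuration
#'
#' Parameters of the energy-based promoter scan: the score threshold above
#' which a window counts as a binding site (0.09 in the framework's standard
#' calibration; scores live in (0, 0.5] with 0.5 a perfect match), the
#' proximal window length (500 bp: most in vivo binding in compact genomes
#' lies in the proximal promoter), the fraction of promoters above which a
#' TF's motif is deemed non-specific (0.5), and whether both strands are
#' scanned.
#'
#' @param threshold score cutoff in (0, 0.5].
#' @param window proximal window length in bp (>= 1).
#' @param nonSpecificFraction fraction of promoters bound above which a TF
#'   is removed as non-specific.
#' @param bothStrands scan the reverse complement as well (default TRUE).
#' @return list with class `"ScanConfig"`.
#' @export
scanConfig <- function(threshold = 0.09, window = 500,
                       nonSpecificFraction = 0.5, bothStrands = TRUE) {
  stopifnot(threshold > 0, threshold <= 0.5, window >= 1,
            nonSpecificFraction > 0, nonSpecificFraction <= 1)
  structure(list(threshold = threshold, window = as.integer(window),
                 nonSpecificFraction = nonSpecificFraction,
                 bothStrands = isTRUE(bothStrands)),
            class = "ScanConfig")
}

#' Energy-based PWM score of a k-mer
#'
#' Scores how well a k-mer matches a PWM on a (0, 0.5] scale with 0.5 a
#' perfect match. The mismatch energy of the word is the summed log-ratio of
#' the per-position maximal probability to the probability of the observed
#' base, `dE = sum_i [ln p_i,max - ln p_i,base]` (>= 0, and 0 exactly on the
#' consensus); the score is the logistic transform `1 / (1 + exp(dE))`.
#'
#' @param pwm a [PWMotif].
#' @param kmer character string over A/C/G/T of the motif length.
#' @return numeric score in (0, 0.5].
#' @export
pwmEnergyScore <- function(pwm, kmer) {
  m <- motifMatrix(pwm)
  b <- strsplit(toupper(kmer), "")[[1]]
  if (length(b) != ncol(m))
    stop("k-mer length must equal motif length")
  idx <- match(b, rownames(m))
  if (anyNA(idx))
    stop("ambiguous or non-ACGT base in k-mer: ", kmer)
  lp <- log(m)
  dE <- sum(apply(lp, 2, max) - lp[cbind(idx, seq_along(idx))])
  1 / (1 + exp(dE))
}

## integer encoding (A=1, C=2, G=3, T=4); NA for anything else
.encodeDNA <- function(seqchar) {
  match(strsplit(toupper(seqchar), "")[[1]], c("A", "C", "G", "T"))
}

.revcompCode <- function(code) rev(5L - code)

## all window scores of an encoded sequence against a log-probability matrix
.scanScores <- function(code, lp) {
  L <- ncol(lp); n <- length(code) - L + 1L
  if (n < 1L) return(numeric(0))
  colmax <- apply(lp, 2, max)
  dE <- rep(sum(colmax), n)
  for (i in seq_len(L)) {
    p <- lp[cbind(code[i:(i + n - 1L)], i)]
    p[is.na(p)] <- -Inf                   # ambiguous base never matches
    dE <- dE - p
  }
  1 / (1 + exp(dE))
}

#' Scan a promoter for a motif
#'
#' Scores every window of the proximal promoter region against the PWM and
#' reports whether any window reaches the threshold. The promoter sequence
#' is expected 5'->3' ending at the translation/transcription start (the
#' promoterome convention), so the proximal window is the 3'-most
#' `min(window, length)` bases. Multiple matches count as a single
#' interaction: the bound flag is binary.
#'
#' @param pwm a [PWMotif].
#' @param promoter a character string or [Biostrings::DNAString].
#' @param config a [scanConfig()].
#' @return list with `bound` (logical), `bestScore`, and `hits` (1-based
#'   start positions within the proximal window, forward strand coordinates;
#'   strand recorded alongside).
#' @export
scanPromoter <- function(pwm, promoter, config = scanConfig()) {
  s <- as.character(promoter)
  n <- nchar(s)
  L <- ncol(motifMatrix(pwm))
  if (n < L) {
    warning("sequence shorter than motif; not bound")
    return(list(bound = FALSE, bestScore = NA_real_,
                hits = integer(0), strand = character(0)))
  }
  win <- substr(s, max(1L, n - config$window + 1L), n)
  code <- .encodeDNA(win)
  lp <- log(motifMatrix(pwm))
  fw <- .scanScores(code, lp)
  rv <- if (config$bothStrands) .scanScores(.revcompCode(code), lp)
        else numeric(0)
  hitsF <- which(fw >= config$threshold)
  hitsRraw <- which(rv >= config$threshold)
  ## reverse-strand window j corresponds to forward start n - L + 2 - j
  nw <- length(code)
  hitsR <- if (length(hitsRraw)) nw - L + 2L - hitsRraw else integer(0)
  best <- suppressWarnings(max(c(fw, rv, -Inf)))
  list(bound = length(hitsF) + length(hitsR) > 0,
       bestScore = if (is.finite(best)) best else NA_real_,
       hits = c(hitsF, hitsR),
       strand = c(rep("+", length(hitsF)), rep("-", length(hitsR))))
}

#' Motif-predicted PDI network
#'
#' Scans every promoter with every PWM and assembles the binary network of
#' predicted binding. TFs whose motif hits more than
#' `config$nonSpecificFraction` of the promoters are considered non-specific
#' and removed; they are reported alongside the network.
#'
#' @param pwms list of [PWMotif] (the `tfId` slot names the TF; falls back
#'   to `motifId`).
#' @param promoters named [Biostrings::DNAStringSet] or named character
#'   vector of promoter sequences.
#' @param config a [scanConfig()].
#' @param promoterGene optional promoter-to-gene map.
#' @return list with `network` (a [PDINetwork] over the retained TFs) and
#'   `removed` (ids of non-specific TFs).
#' @export
predictedNetwork <- function(pwms, promoters, config = scanConfig(),
                             promoterGene = NULL) {
  stopifnot(length(pwms) >= 1, length(promoters) >= 1)
  seqs <- as.character(promoters)
  if (is.null(names(seqs))) names(seqs) <- names(promoters)
  if (is.null(names(seqs))) stop("promoters must be named")
  hits <- lapply(pwms, function(pwm) {
    names(seqs)[vapply(seqs, function(s)
      scanPromoter(pwm, s, config)$bound, logical(1))]
  })
  tfOf <- vapply(pwms, function(p)
    if (nzchar(p@tfId)) p@tfId else p@motifId, character(1))
  names(hits) <- tfOf
  frac <- vapply(hits, length, integer(1)) / length(seqs)
  removed <- names(hits)[frac > config$nonSpecificFraction]
  kept <- setdiff(names(hits), removed)
  edges <- do.call(rbind, c(list(
    data.frame(tf = character(0), promoter = character(0))),
    lapply(kept, function(tf)
      if (length(hits[[tf]]))
        data.frame(tf = tf, promoter = hits[[tf]],
                   stringsAsFactors = FALSE))))
  net <- suppressMessages(PDINetwork(edges, promoterGene = promoterGene))
  list(network = net, removed = removed)
}

#' Discover elementary motifs from bound vs unbound promoters
#'
#' Counts the presence (both strands) of every k-mer in the proximal windows
#' of the positive (bound) and negative (unbound) promoter sets, tests each
#' k-mer's presence counts with a one-sided hypergeometric test, adjusts by
#' Benjamini-Hochberg, and retains k-mers with FDR below `fdrCutoff` and
#' positive/negative frequency ratio above `enrCutoff`. Retained k-mers are
#' greedily aligned (best ungapped overlap of length >= k - 2, both
#' orientations) and stacked, weighted by their positive counts, into
#' probability matrices; discovery requires at least `minPositives` bound
#' promoters to avoid low-quality motifs from small positive sets.
#'
#' @param positives,negatives named sequence sets (character or
#'   `DNAStringSet`) of bound and unbound promoters.
#' @param k word length (default 8; 6-10 supported).
#' @param fdrCutoff FDR threshold (default 0.05).
#' @param enrCutoff enrichment threshold (default 2).
#' @param window proximal window length (default 500).
#' @param minPositives minimum number of bound promoters (default 50).
#' @return list with `kmers` (data.frame: kmer, posCount, negCount,
#'   posFreq, negFreq, enrichment, p, fdr for retained k-mers, ordered by
#'   p), and `motifs` (list of [PWMotif] built from the aligned clusters,
#'   ordered by total supporting count).
#' @export
discoverMotifs <- function(positives, negatives, k = 8, fdrCutoff = 0.05,
                           enrCutoff = 2, window = 500, minPositives = 50) {
  stopifnot(k >= 6, k <= 10)
  if (length(positives) < minPositives)
    stop(sprintf("motif discovery requires at least %d bound promoters, got %d",
                 minPositives, length(positives)))
  posW <- .proximalWindows(positives, window)
  negW <- .proximalWindows(negatives, window)
  posPres <- .kmerPresence(posW, k)
  negPres <- .kmerPresence(negW, k)
  all_kmers <- union(names(posPres), names(negPres))
  pos <- setNames(integer(length(all_kmers)), all_kmers)
  pos[names(posPres)] <- posPres
  neg <- setNames(integer(length(all_kmers)), all_kmers)
  neg[names(negPres)] <- negPres
  npos <- length(positives); nneg <- length(negatives)
  p <- fisherUpperTail(pos, pos + neg, npos, npos + nneg)
  fdr <- p.adjust(p, method = "BH")
  posFreq <- pos / npos
  negFreq <- neg / nneg
  ## pseudo-frequency guard keeps the ratio finite on zero negative counts
  enr <- posFreq / ((neg + 0.5) / (nneg + 0.5))
  keep <- fdr < fdrCutoff & enr > enrCutoff
  df <- data.frame(kmer = all_kmers, posCount = pos, negCount = neg,
                   posFreq = posFreq, negFreq = negFreq, enrichment = enr,
                   p = p, fdr = fdr, row.names = NULL,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  df <- df[order(df$p, -df$posCount), , drop = FALSE]
  rownames(df) <- NULL
  motifs <- .clusterKmers(df, k)
  list(kmers = df, motifs = motifs)
}

.proximalWindows <- function(seqs, window) {
  s <- as.character(seqs)
  n <- nchar(s)
  substr(s, pmax(1L, n - window + 1L), n)
}

## per-k-mer number of sequences containing the word on either strand
.kmerPresence <- function(seqs, k) {
  ss <- Biostrings::DNAStringSet(seqs)
  fw <- Biostrings::oligonucleotideFrequency(ss, width = k)
  rc <- Biostrings::oligonucleotideFrequency(
    Biostrings::reverseComplement(ss), width = k)
  pres <- colSums(fw > 0 | rc > 0)
  pres[pres > 0]
}

.revcompChar <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1)))
}

## greedy ungapped alignment of retained k-mers into probability matrices
.clusterKmers <- function(df, k) {
  if (nrow(df) == 0L) return(list())
  clusters <- list()
  for (i in seq_len(nrow(df))) {
    km <- df$kmer[i]; w <- df$posCount[i]
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      hit <- .bestOverlap(clusters[[ci]]$seed, km, k)
      if (!is.null(hit)) {
        clusters[[ci]]$members <- rbind(clusters[[ci]]$members,
          data.frame(kmer = hit$kmer, offset = hit$offset, weight = w,
                     stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <- list(
        seed = km,
        members = data.frame(kmer = km, offset = 0L, weight = w,
                             stringsAsFactors = FALSE))
  }
  ord <- order(vapply(clusters, function(cl) -sum(cl$members$weight),
                      numeric(1)))
  lapply(seq_along(ord), function(j) {
    cl <- clusters[[ord[j]]]
    .stackKmers(cl$members, sprintf("elementary_%d", j))
  })
}

## best offset aligning km (either orientation) to the seed with overlap
## >= k - 2 and at most one mismatch in the overlap; NULL if none
.bestOverlap <- function(seed, km, k) {
  best <- NULL
  for (cand in c(km, .revcompChar(km))) {
    for (off in seq(-(2L), 2L)) {
      a <- strsplit(seed, "")[[1]]; b <- strsplit(cand, "")[[1]]
      ia <- max(1L, 1L + off); ib <- max(1L, 1L - off)
      len <- min(k - ia + 1L, k - ib + 1L)
      if (len < k - 2L) next
      matches <- sum(a[ia:(ia + len - 1L)] == b[ib:(ib + len - 1L)])
      if (matches >= len - 1L &&
          (is.null(best) || matches > best$matches)) {
        best <- list(kmer = cand, offset = off, matches = matches)
      }
    }
  }
  best
}

.stackKmers <- function(members, id) {
  lo <- min(members$offset); hi <- max(members$offset)
  width <- hi - lo + max(nchar(members$kmer))
  counts <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(members))) {
    b <- strsplit(members$kmer[i], "")[[1]]
    start <- members$offset[i] - lo + 1L
    for (j in seq_along(b)) {
      bi <- match(b[j], rownames(counts))
      counts[bi, start + j - 1L] <-
        counts[bi, start + j - 1L] + members$weight[i]
    }
  }
  occupied <- colSums(counts) > 0
  PWMotif(counts[, occupied, drop = FALSE], motifId = id)
}

#' Read and write MEME minimal motif files
#'
#' Minimal MEME motif format: a version line, optional alphabet/strands/
#' background lines, then one `MOTIF` block per motif with a
#' `letter-probability matrix` header and one line of 4 probabilities per
#' position. `readMEME` returns a list of [PWMotif]; `writeMEME` serializes
#' one.
#'
#' @param path file path.
#' @param pseudocount pseudocount applied to matrices on read.
#' @return `readMEME`: named list of [PWMotif].
#' @export
readMEME <- function(path, pseudocount = 0.001) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    hdr <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    motifId <- if (length(hdr) >= 2) hdr[2] else "motif"
    tfId <- if (length(hdr) >= 3) hdr[3] else ""
    mline <- s + grep("letter-probability matrix",
                      lines[(s + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mline]))
    rows <- lines[(mline + 1):(mline + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4),
      USE.NAMES = FALSE))
    out[[motifId]] <- PWMotif(t(m), motifId = motifId, tfId = tfId,
                              pseudocount = pseudocount)
  }
  out
}

#' @rdname readMEME
#' @param pwms a [PWMotif] or list of them.
#' @export
writeMEME <- function(pwms, path) {
  if (methods::is(pwms, "PWMotif")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    m <- motifMatrix(p)
    writeLines(sprintf("MOTIF %s %s", p@motifId, p@tfId), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(m)), con)
    writeLines(apply(m, 2, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Export a discovered-motif summary table
#'
#' @param discovery result of [discoverMotifs()].
#' @param tsvPath path for the k-mer summary TSV (consensus, counts,
#'   enrichment, FDR).
#' @param memePath optional path for the clustered motifs in MEME format.
#' @return `tsvPath`, invisibly.
#' @export
writeMotifSummary <- function(discovery, tsvPath, memePath = NULL) {
  write.table(discovery$kmers, tsvPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(memePath) && length(discovery$motifs))
    writeMEME(discovery$motifs, memePath)
  invisible(tsvPath)
}
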