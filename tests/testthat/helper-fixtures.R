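# shared fixtures: all built in code, no stored data

## quiet constructor (duplicate-collapse messages are tested explicitly)
qNet <- function(...) suppressMessages(PDINetwork(...))

## edge data.frame from "tf:promoter" strings
mkEdges <- function(pairs) {
  parts <- strsplit(pairs, ":", fixed = TRUE)
  data.frame(tf = vapply(parts, `[`, "", 1),
             promoter = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

## random bipartite network with a heavy-ish degree tail
randNet <- function(nT = 30, nP = 60, nE = 150, seed = 1,
                    alpha = 1.2, minDeg = 1) {
  set.seed(seed)
  d <- pmax(minDeg, round((seq_len(nT))^(-alpha) * nE /
                            sum((seq_len(nT))^(-alpha))))
  edges <- do.call(rbind, lapply(seq_len(nT), function(i)
    data.frame(tf = sprintf("T%02d", i),
               promoter = sprintf("P%02d", sample(nP, min(d[i], nP))),
               stringsAsFactors = FALSE)))
  qNet(edges)
}

## the standard synthetic world, generated once per test run
.worldCache <- new.env(parent = emptyenv())
standardWorld <- function(seed = 1) {
  key <- paste0("w", seed)
  if (is.null(.worldCache[[key]]))
    .worldCache[[key]] <- generateWorld(worldParams(seed = seed))
  .worldCache[[key]]
}
standardNet <- function(seed = 1)
  filterBaits(worldData(standardWorld(seed))$network, "clean")
standardCoex <- function(seed = 1) {
  key <- paste0("c", seed)
  if (is.null(.worldCache[[key]]))
    .worldCache[[key]] <-
      buildCoexpression(worldData(standardWorld(seed))$compendium)
  .worldCache[[key]]
}

## reverse complement of a character k-mer
rcKmer <- function(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## minimal Hamming distance of `kmer` to `target` over both orientations
motifDistance <- function(kmer, target)
  min(hamming(kmer, target), hamming(rcKmer(kmer), target))
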