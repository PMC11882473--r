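# Independent reference implementations used to cross-check the package's
# optimised code paths.  These deliberately use exhaustive enumeration and
# closed forms, never the code they check.

# Exhaustive peak assembly: test every possible opening run and, once open,
# every possible terminating run, recomputing the running maximum from
# scratch each time.
refAssemblePeaks <- function(w, bg, sf = 2.5, rl = 8, mf = 50, ef = 0.04) {
  W <- length(w)
  res <- list()
  pos <- 1L
  qualifies <- function(i)
    all(w[i:(i + rl - 1)] >= sf * bg) || median(w[i:(i + rl - 1)]) > mf
  repeat {
    open <- NA
    if (pos + rl - 1 <= W)
      for (i in pos:(W - rl + 1)) if (qualifies(i)) { open <- i; break }
    if (is.na(open)) break
    close <- W; nxt <- W + 1
    t <- open + 1
    while (t + rl - 1 <= W) {
      M <- max(w[open:(t - 1)])
      if (all(w[t:(t + rl - 1)] < ef * M)) { close <- t - 1; nxt <- t + rl; break }
      t <- t + 1
    }
    res[[length(res) + 1]] <- c(open, close)
    pos <- nxt
  }
  if (!length(res)) return(matrix(numeric(), ncol = 2))
  m <- do.call(rbind, res)
  keep <- m[1, , drop = FALSE]
  if (nrow(m) > 1) for (r in 2:nrow(m)) {
    if (m[r, 1] <= keep[nrow(keep), 2] + 1)
      keep[nrow(keep), 2] <- max(keep[nrow(keep), 2], m[r, 2])
    else keep <- rbind(keep, m[r, , drop = FALSE])
  }
  keep
}

# Brute-force hypergeometric upper tail by explicit binomial-coefficient
# summation.
refHyperTail <- function(N, K, n, x) {
  if (x == 0) return(1)
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Brute-force gene counting: per read, loop over every gene and every block
# with plain interval arithmetic, no index structures.
refCountGenes <- function(reads, annotation, stranded = TRUE) {
  eu <- ripintegrate::exonUnion(annotation)
  g <- ripintegrate::genes(annotation)
  gid <- ripintegrate::geneIds(annotation)
  counts <- setNames(rep(0L, length(gid)), gid)
  ambiguous <- 0L
  for (i in seq_along(reads)) {
    if (!S4Vectors::mcols(reads)$unique[i]) next
    bl <- S4Vectors::mcols(reads)$blocks[[i]]
    compatible <- character()
    for (k in seq_along(gid)) {
      if (as.character(GenomicRanges::seqnames(reads)[i]) !=
          as.character(GenomicRanges::seqnames(g)[k])) next
      if (stranded && as.character(GenomicRanges::strand(reads)[i]) !=
          as.character(GenomicRanges::strand(g)[k])) next
      ex <- eu[[gid[k]]]
      allhit <- TRUE
      for (b in seq_along(bl)) {
        hit <- FALSE
        for (e in seq_along(ex)) {
          if (IRanges::start(bl)[b] <= IRanges::end(ex)[e] &&
              IRanges::end(bl)[b] >= IRanges::start(ex)[e]) { hit <- TRUE; break }
        }
        if (!hit) { allhit <- FALSE; break }
      }
      if (allhit) compatible <- c(compatible, gid[k])
    }
    if (length(compatible) == 1) counts[compatible] <- counts[compatible] + 1L
    if (length(compatible) > 1) ambiguous <- ambiguous + 1L
  }
  list(counts = counts, ambiguous = ambiguous)
}

# Brute-force junction enumeration read by read.
refJunctions <- function(reads) {
  out <- list()
  for (i in seq_along(reads)) {
    if (!S4Vectors::mcols(reads)$unique[i]) next
    bl <- S4Vectors::mcols(reads)$blocks[[i]]
    if (length(bl) < 2) next
    for (b in seq_len(length(bl) - 1)) {
      key <- paste(as.character(GenomicRanges::seqnames(reads)[i]),
                   as.character(GenomicRanges::strand(reads)[i]),
                   IRanges::end(bl)[b], IRanges::start(bl)[b + 1] - 1L)
      out[[key]] <- (out[[key]] %||% 0L) + 1L
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Median-of-ratios size factors computed the long way.
refSizeFactors <- function(counts) {
  keep <- apply(counts > 0, 1, all)
  m <- counts[keep, , drop = FALSE]
  geo <- apply(m, 1, function(r) exp(mean(log(r))))
  sf <- apply(m, 2, function(col) median(col / geo))
  sf / exp(mean(log(sf)))
}
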