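#' Mean per-base depth of sliding windows
#'
#' Scans a per-base depth vector with windows of `window` bp advancing by
#' `step` bp; each window's value is its mean per-base depth, and a trailing
#' partial window is kept with its actual width, so the number of windows is
#' `ceiling(length(depth) / step)`.
#'
#' @param depth numeric per-base depth vector (gene-span coordinates).
#' @param window,step window width and stride in bp (default 5 and 5).
#' @return numeric vector of window mean depths.
#' @export
windowDepths <- function(depth, window = 5, step = 5) {
  if (!length(depth)) return(numeric())
  .cpp_window_means(as.numeric(depth), as.integer(window), as.integer(step))
}

#' Assemble candidate peaks from window depths
#'
#' Scanning left to right, a peak opens at the first window of any run of
#' `run_len` consecutive windows that each reach `start_factor` times the
#' background depth, or of any run whose median depth exceeds
#' `median_floor`.  An open peak extends until `run_len` consecutive windows
#' each drop below `end_fraction` of the running maximum window depth of the
#' peak, and closes just before that run (or at the end of the track).
#' Abutting peaks are merged.
#'
#' @param windows numeric window depths from [windowDepths()].
#' @param background_depth background per-base depth (e.g. the gene mean).
#' @param start_factor opening multiple of the background (default 2.5).
#' @param run_len run length, in windows, for opening and closing (default 8).
#' @param median_floor alternative opening rule: run median above this
#'   absolute depth (default 50).
#' @param end_fraction closing fraction of the peak's maximum window depth
#'   (default 0.04).
#' @return data.frame with one row per candidate: `start_win`, `end_win`
#'   (1-based window indices, inclusive) and `max_window_depth`,
#'   `open_run_median`.
#' @export
assemblePeaks <- function(windows, background_depth, start_factor = 2.5,
                          run_len = 8, median_floor = 50,
                          end_fraction = 0.04) {
  W <- length(windows)
  peaks <- list()
  thr <- start_factor * background_depth
  i <- 1L
  while (i + run_len - 1L <= W) {
    run <- windows[i:(i + run_len - 1L)]
    if (all(run >= thr) || median(run) > median_floor) {
      open <- i
      M <- windows[open]
      low <- 0L
      j <- open
      close_at <- NA_integer_
      while (j <= W) {
        if (windows[j] < end_fraction * M) {
          low <- low + 1L
          if (low == run_len) { close_at <- j - run_len; break }
        } else {
          low <- 0L
          if (windows[j] > M) M <- windows[j]
        }
        j <- j + 1L
      }
      closed_by_run <- !is.na(close_at)
      if (!closed_by_run) close_at <- W
      peaks[[length(peaks) + 1L]] <-
        c(start = open, end = close_at,
          maxw = max(windows[open:close_at]), med = median(run))
      i <- if (closed_by_run) j + 1L else W + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(peaks))
    return(data.frame(start_win = integer(), end_win = integer(),
                      max_window_depth = numeric(),
                      open_run_median = numeric()))
  m <- do.call(rbind, peaks)
  out <- data.frame(start_win = as.integer(m[, "start"]),
                    end_win = as.integer(m[, "end"]),
                    max_window_depth = m[, "maxw"],
                    open_run_median = m[, "med"])
  # merge abutting candidates (separated by less than one window)
  if (nrow(out) > 1) {
    keep <- out[1, , drop = FALSE]
    for (r in 2:nrow(out)) {
      last <- nrow(keep)
      if (out$start_win[r] <= keep$end_win[last] + 1L) {
        keep$end_win[last] <- max(keep$end_win[last], out$end_win[r])
        keep$max_window_depth[last] <- max(keep$max_window_depth[last],
                                           out$max_window_depth[r])
      } else keep <- rbind(keep, out[r, ])
    }
    out <- keep
  }
  rownames(out) <- NULL
  out
}

#' Within-gene read-shuffle permutation test for a peak
#'
#' Uniformly re-places each of the gene's IP reads within the gene span
#' `n_shuffles` times (lengths preserved, clipped at the right edge),
#' recomputes the maximum window depth over the gene for each shuffle, and
#' returns the add-one empirical p-value
#' `(1 + #\{shuffle maxima >= observed\}) / (1 + n_shuffles)`, which can
#' never be exactly zero.
#'
#' @param peak_stat observed maximum window depth of the peak.
#' @param read_lengths integer lengths of the gene's IP reads.
#' @param gene_length gene span length in bp (must exceed the read length).
#' @param window,step window scan parameters.
#' @param n_shuffles number of shuffles (default 500).
#' @param seed RNG seed (set internally for reproducibility).
#' @return list with `p` and the vector `shuffle_max`.
#' @export
permutationTest <- function(peak_stat, read_lengths, gene_length,
                            window = 5, step = 5, n_shuffles = 500,
                            seed = 1) {
  if (gene_length < max(read_lengths))
    stop("gene shorter than a read length")
  set.seed(seed)
  mx <- .cpp_perm_max_depth(as.integer(read_lengths),
                            as.integer(gene_length), as.integer(window),
                            as.integer(step), as.integer(n_shuffles))
  list(p = (1 + sum(mx >= peak_stat)) / (1 + n_shuffles), shuffle_max = mx)
}

# per-base depth of reads over a gene span [gstart, gend]
.geneDepthVector <- function(read_starts, read_ends, gstart, gend) {
  L <- gend - gstart + 1L
  s <- pmax(read_starts, gstart) - gstart + 1L
  e <- pmin(read_ends, gend) - gstart + 1L
  ok <- s <= e
  cov <- IRanges::coverage(IRanges(s[ok], e[ok]), width = L)
  as.numeric(cov)
}

#' Call RIP-seq binding peaks with a within-gene permutation null
#'
#' Per gene: per-base IP coverage is scanned with [windowDepths()];
#' candidates are assembled by [assemblePeaks()] against the gene's mean
#' per-base IP depth as background; the gene's shuffle distribution of
#' maximum window depths ([permutationTest()], `n_shuffles` re-placements)
#' gives each candidate an empirical p-value; and IP/input abundances in
#' each candidate are computed as mean per-base depth in the peak per
#' million mapped reads (one pseudo-read on the input, spread over the
#' peak width).  [filterPeaks()] applies the significance-or-depth rule
#' and the fold-enrichment filter.
#'
#' @param ip,input alignment `GRanges` of the IP and matched input library
#'   (see [readBED12()]).
#' @param annotation A [GenomeAnnotation].
#' @param window,step,start_factor,run_len,median_floor,end_fraction peak
#'   assembly parameters, see [assemblePeaks()].
#' @param n_shuffles permutation count (default 500).
#' @param seed RNG seed; each gene gets a derived child seed.
#' @param dedup collapse same-start, same-strand reads (PCR duplicates)
#'   before calling (default FALSE; assumed done upstream).
#' @param ignore_strand assign reads to genes irrespective of strand
#'   (default TRUE).
#' @return `GRanges` of candidate peaks with metadata: gene_id, max_depth
#'   (per-base), max_window_depth, open_run_median, perm_p, ip_count,
#'   input_count, ip_abundance, input_abundance, fold_enrichment.
#' @export
callPeaks <- function(ip, input, annotation, window = 5, step = 5,
                      start_factor = 2.5, run_len = 8, median_floor = 50,
                      end_fraction = 0.04, n_shuffles = 500, seed = 1,
                      pseudo = 1, dedup = FALSE, ignore_strand = TRUE) {
  if (missing(input) || is.null(input))
    stop("an input (control) library is required for the enrichment filter")
  if (dedup) {
    key <- paste(seqnames(ip), start(ip), strand(ip))
    ip <- ip[!duplicated(key)]
    key <- paste(seqnames(input), start(input), strand(input))
    input <- input[!duplicated(key)]
  }
  g <- genes(annotation)
  ip_total <- length(ip)
  in_total <- length(input)
  hits_ip <- GenomicRanges::findOverlaps(ip, g, ignore.strand = ignore_strand)
  hits_in <- GenomicRanges::findOverlaps(input, g,
                                         ignore.strand = ignore_strand)
  ip_by_gene <- split(S4Vectors::queryHits(hits_ip),
                      S4Vectors::subjectHits(hits_ip))
  in_by_gene <- split(S4Vectors::queryHits(hits_in),
                      S4Vectors::subjectHits(hits_in))
  rows <- list()
  for (gi_chr in names(ip_by_gene)) {
    gi <- as.integer(gi_chr)
    ridx <- ip_by_gene[[gi_chr]]
    gstart <- start(g)[gi]; gend <- end(g)[gi]
    L <- gend - gstart + 1L
    depth <- .geneDepthVector(start(ip)[ridx], end(ip)[ridx], gstart, gend)
    bg <- mean(depth)
    if (bg == 0) next
    wd <- windowDepths(depth, window, step)
    cand <- assemblePeaks(wd, bg, start_factor, run_len, median_floor,
                          end_fraction)
    if (!nrow(cand)) next
    pt <- permutationTest(Inf, width(ip)[ridx], L, window, step, n_shuffles,
                          seed = childSeed(seed, paste0("perm:", gi)))
    shuffle_max <- pt$shuffle_max
    ps <- gstart + (cand$start_win - 1L) * step
    pe <- pmin(gstart + cand$end_win * step - 1L, gend)
    iidx <- in_by_gene[[gi_chr]]
    in_depth <- if (length(iidx))
      .geneDepthVector(start(input)[iidx], end(input)[iidx], gstart, gend)
      else numeric(L)
    mean_rl_in <- if (length(iidx)) mean(width(input)[iidx]) else
      mean(width(ip)[ridx])
    for (r in seq_len(nrow(cand))) {
      base_lo <- ps[r] - gstart + 1L
      base_hi <- pe[r] - gstart + 1L
      pw <- base_hi - base_lo + 1L
      max_depth <- max(depth[base_lo:base_hi])
      perm_p <- (1 + sum(shuffle_max >= cand$max_window_depth[r])) /
        (1 + n_shuffles)
      ip_cnt <- sum(start(ip)[ridx] <= pe[r] & end(ip)[ridx] >= ps[r])
      in_cnt <- if (length(iidx))
        sum(start(input)[iidx] <= pe[r] & end(input)[iidx] >= ps[r]) else 0L
      # abundance = mean per-base depth per million mapped over the peak's
      # enriched core (the windows at or above the opening threshold; the
      # end rule deliberately tolerates long low-coverage tails which would
      # otherwise dilute the contrast); one input pseudo-read spread over
      # the core width
      wlo <- cand$start_win[r]; whi <- cand$end_win[r]
      wsel <- which(wd[wlo:whi] >= start_factor * bg) + wlo - 1L
      if (!length(wsel)) wsel <- wlo:whi
      core <- unlist(lapply(wsel, function(wk)
        ((wk - 1L) * step + 1L):min(wk * step, L)))
      core <- core[core >= base_lo & core <= base_hi]
      if (!length(core)) core <- base_lo:base_hi
      ip_ab <- mean(depth[core]) / ip_total * 1e6
      in_ab <- (mean(in_depth[core]) +
                pseudo * mean_rl_in / length(core)) / in_total * 1e6
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(seqnames(g))[gi], start = ps[r], end = pe[r],
        strand = as.character(strand(g))[gi],
        gene_id = mcols(g)$gene_id[gi], max_depth = max_depth,
        max_window_depth = cand$max_window_depth[r],
        open_run_median = cand$open_run_median[r], perm_p = perm_p,
        ip_count = ip_cnt, input_count = in_cnt, ip_abundance = ip_ab,
        input_abundance = in_ab, fold_enrichment = ip_ab / in_ab)
    }
  }
  if (!length(rows)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(gene_id = character(), max_depth = numeric(),
                           max_window_depth = numeric(),
                           open_run_median = numeric(), perm_p = numeric(),
                           ip_count = integer(), input_count = integer(),
                           ip_abundance = numeric(),
                           input_abundance = numeric(),
                           fold_enrichment = numeric())
    return(gr)
  }
  df <- do.call(rbind, rows)
  GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
          gene_id = df$gene_id, max_depth = df$max_depth,
          max_window_depth = df$max_window_depth,
          open_run_median = df$open_run_median, perm_p = df$perm_p,
          ip_count = df$ip_count, input_count = df$input_count,
          ip_abundance = df$ip_abundance,
          input_abundance = df$input_abundance,
          fold_enrichment = df$fold_enrichment)
}

#' Filter candidate peaks
#'
#' Stage 1 keeps candidates that are permutation-significant
#' (`perm_p < p_threshold`) OR reach an absolute maximum per-base depth of
#' `min_max_depth`.  Stage 2 keeps those whose IP abundance exceeds `fold`
#' times the (pseudo-counted) input abundance, both as mean in-peak depth
#' per million mapped reads.
#'
#' @param candidates `GRanges` from [callPeaks()].
#' @param p_threshold permutation p cut-off (default 0.05).
#' @param min_max_depth absolute depth rescue threshold (default 10).
#' @param fold required IP/input fold enrichment (default 4).
#' @return the filtered `GRanges`, with logical columns `pass_stage1` and
#'   `pass_fold` added to all candidates in the attribute-free sense (the
#'   returned object only contains passing peaks).
#' @export
filterPeaks <- function(candidates, p_threshold = 0.05, min_max_depth = 10,
                        fold = 4) {
  if (!length(candidates)) return(candidates)
  s1 <- mcols(candidates)$perm_p < p_threshold |
    mcols(candidates)$max_depth >= min_max_depth
  s2 <- mcols(candidates)$fold_enrichment > fold
  candidates[s1 & s2]
}

#' Collapse peaks to their target genes
#'
#' @param peaks `GRanges` with a `gene_id` column (from [filterPeaks()]).
#' @return list with `genes` (unique gene identifiers) and `counts`
#'   (data.frame gene_id, n_peaks).
#' @export
peaksToGenes <- function(peaks) {
  if (!length(peaks))
    return(list(genes = character(),
                counts = data.frame(gene_id = character(),
                                    n_peaks = integer())))
  tab <- table(mcols(peaks)$gene_id)
  list(genes = sort(names(tab)),
       counts = data.frame(gene_id = names(tab),
                           n_peaks = as.integer(tab), row.names = NULL))
}

#' Write peaks as BED6+ with extra columns
#'
#' Name is the target gene, score is `round(-10 * log10(perm_p))`, and
#' `max_depth`, `fold_enrichment` and `perm_p` follow as extra columns.
#' Intervals are written 0-based half-open.
#'
#' @param peaks `GRanges` of peaks.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeaksBED <- function(peaks, path) {
  if (!length(peaks)) { writeLines(character(), path); return(invisible(path)) }
  mc <- mcols(peaks)
  lines <- paste(as.character(seqnames(peaks)), start(peaks) - 1L,
                 end(peaks), mc$gene_id,
                 round(-10 * log10(mc$perm_p)),
                 as.character(strand(peaks)),
                 signif(mc$max_depth, 6), signif(mc$fold_enrichment, 6),
                 signif(mc$perm_p, 6), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
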