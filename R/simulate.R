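#' Derive a stage-specific child seed from a master seed
#'
#' Hashes a stage name into an integer offset so that each pipeline stage
#' draws from an independent, reproducible RNG stream; adding a stage never
#' perturbs the randomness of existing stages.
#'
#' @param seed master seed (integer).
#' @param stage character stage label.
#' @return An integer seed below 2^31.
#' @export
childSeed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480009
  as.integer((h + (as.numeric(seed) %% 2147480009) * 7919) %% 2147480009)
}

.AS_TYPES <- c("ES", "cassetteExon", "A5SS", "A3SS", "MXE", "5pMXE", "3pMXE",
               "IntronR", "A5SS&ES", "A3SS&ES")

# swap site-polarity labels when a plus-strand template lands on minus strand
.swapStrandLabel <- function(type, strand) {
  if (strand != "-") return(type)
  map <- c(A5SS = "A3SS", A3SS = "A5SS", `5pMXE` = "3pMXE", `3pMXE` = "5pMXE",
           `A5SS&ES` = "A3SS&ES", `A3SS&ES` = "A5SS&ES")
  if (type %in% names(map)) unname(map[type]) else type
}

# Build the two-transcript exon layout for one gene.  Coordinates are
# genome-forward; `type` is the plus-strand template name.  Returns a list
# of transcripts, each an integer matrix of (start, end) rows.
.geneTemplate <- function(type, gstart, glen, exon_range = c(2, 5)) {
  we <- max(80L, round(0.08 * glen))       # exon width
  dd <- max(30L, round(0.03 * glen))       # alt-site offset
  chain <- function(k) {
    if (k == 1) return(cbind(gstart, gstart + glen - 1L))
    wi <- max(80L, floor((glen - k * we) / max(1, k - 1)))
    s <- gstart + (seq_len(k) - 1L) * (we + wi)
    cbind(s, s + we - 1L)
  }
  if (is.na(type)) {
    k <- sample(seq(exon_range[1], exon_range[2]), 1)
    return(list(T1 = chain(k)))
  }
  switch(type,
    ES = { e <- chain(3); list(T1 = e, T2 = e[c(1, 3), , drop = FALSE]) },
    cassetteExon = { e <- chain(4); list(T1 = e, T2 = e[c(1, 4), , drop = FALSE]) },
    A5SS = { e <- chain(2); s <- e; s[1, 2] <- s[1, 2] - dd
             list(T1 = e, T2 = s) },
    A3SS = { e <- chain(2); s <- e; s[2, 1] <- s[2, 1] + dd
             list(T1 = e, T2 = s) },
    MXE = { e <- chain(4)
            list(T1 = e[c(1, 2, 4), ], T2 = e[c(1, 3, 4), ]) },
    `5pMXE` = { e <- chain(4)
            list(T1 = e[c(1, 3, 4), ], T2 = e[c(2, 3, 4), ]) },
    `3pMXE` = { e <- chain(4)
            list(T1 = e[c(1, 2, 3), ], T2 = e[c(1, 2, 4), ]) },
    IntronR = { e <- chain(2)
            list(T1 = e, T2 = matrix(c(e[1, 1], e[2, 2]), 1)) },
    `A5SS&ES` = { e <- chain(3); alt <- e[1, , drop = FALSE]
            alt[1, 2] <- alt[1, 2] - dd
            list(T1 = e, T2 = rbind(alt, e[3, , drop = FALSE])) },
    `A3SS&ES` = { e <- chain(3); alt <- e[3, , drop = FALSE]
            alt[1, 1] <- alt[1, 1] + dd
            list(T1 = e, T2 = rbind(e[1, , drop = FALSE], alt)) },
    stop("unknown template type: ", type))
}

#' Simulate a gene annotation with alternative transcript structures
#'
#' Places non-overlapping genes (separated by at least 500 bp spacers,
#' alternating strand) on one synthetic chromosome `chrS`.  A configurable
#' fraction of genes receives a second transcript realising one of the ten
#' alternative-splicing event classes, cycled in a fixed order so that every
#' class is represented once at least ten alternative-structure genes exist.
#'
#' @param config A [SimConfig].
#' @return A [GenomeAnnotation]; `mcols(genes(x))$as_type` records the
#'   planted event class (`NA` for constitutive genes).
#' @export
simulateAnnotation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(childSeed(config@seed, "annotation"))
  n <- config@n_genes
  glens <- round(runif(n, config@gene_length_range[1],
                       config@gene_length_range[2]))
  is_as <- runif(n) < config@as_structure_frac
  types <- rep(NA_character_, n)
  # each template class occupies two consecutive alternative-structure slots
  # so that (with alternating strands) every class is realised on both
  # strands, hence every strand-aware label is representable
  types[is_as] <- .AS_TYPES[(ceiling(seq_len(sum(is_as)) / 2) - 1) %% 10 + 1]
  starts <- integer(n)
  cur <- 1L
  exon_rows <- vector("list", n)
  gene_rows <- vector("list", n)
  for (i in seq_len(n)) {
    gstart <- cur + 500L + sample.int(200L, 1)
    strand <- if (i %% 2L == 1L) "+" else "-"
    gid <- sprintf("G%04d", i)
    txs <- .geneTemplate(types[i], gstart, glens[i],
                         config@exons_per_gene_range)
    ex <- do.call(rbind, lapply(seq_along(txs), function(j) {
      m <- txs[[j]]
      data.frame(start = m[, 1], end = m[, 2], gene_id = gid,
                 transcript_id = paste0(gid, ".T", j), strand = strand)
    }))
    exon_rows[[i]] <- ex
    gend <- max(ex$end)
    gene_rows[[i]] <- data.frame(start = gstart, end = gend, gene_id = gid,
                                 strand = strand,
                                 as_type = if (is.na(types[i])) NA_character_
                                           else .swapStrandLabel(types[i], strand))
    cur <- gend
  }
  gdf <- do.call(rbind, gene_rows)
  edf <- do.call(rbind, exon_rows)
  g <- GRanges("chrS", IRanges(gdf$start, gdf$end), strand = gdf$strand,
               gene_id = gdf$gene_id, symbol = gdf$gene_id,
               as_type = gdf$as_type)
  e <- GRanges("chrS", IRanges(edf$start, edf$end), strand = edf$strand,
               gene_id = edf$gene_id, transcript_id = edf$transcript_id)
  GenomeAnnotation(genes = g, exons = e)
}

#' Simulate a 3-vs-3 negative-binomial count matrix with planted DE
#'
#' Gene baselines follow a log-normal abundance profile scaled to the
#' configured library size; counts are negative binomial with
#' variance = mu + alpha mu^2.  A fraction `frac_de` of genes has the
#' second-group mean shifted by `de_log2fc` with random sign.
#'
#' @param annotation A [GenomeAnnotation].
#' @param config A [SimConfig].
#' @return list with `counts` (a [SummarizedExperiment::SummarizedExperiment]
#'   with assay `counts`, `rowData$exon_length`, `colData$total_mapped` and
#'   `colData$group`) and `truth` (data.frame `gene_id`, `log2fc`).
#' @export
simulateCounts <- function(annotation, config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(childSeed(config@seed, "counts"))
  gid <- geneIds(annotation)
  n <- length(gid)
  if (!n) stop("annotation is empty")
  nrep <- config@n_replicates_per_group
  w <- rlnorm(n, 0, 1)
  mu <- config@lib_size_mean * w / sum(w)
  nde <- round(config@frac_de * n)
  de_idx <- if (nde) sort(sample.int(n, nde)) else integer()
  sign <- sample(c(-1, 1), nde, replace = TRUE)
  lfc <- numeric(n)
  lfc[de_idx] <- sign * config@de_log2fc
  sf <- rlnorm(2 * nrep, 0, 0.1)
  size <- 1 / config@nb_dispersion
  cols <- c(paste0("ctrl_", seq_len(nrep)), paste0("kd_", seq_len(nrep)))
  cts <- matrix(0L, n, 2 * nrep, dimnames = list(gid, cols))
  for (s in seq_len(2 * nrep)) {
    m <- if (s <= nrep) mu else mu * 2^lfc
    cts[, s] <- rnbinom(n, mu = m * sf[s], size = size)
  }
  lens <- sum(width(exonUnion(annotation)))[gid]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cts),
    rowData = DataFrame(gene_id = gid, exon_length = as.integer(lens)),
    colData = DataFrame(sample = cols,
                        group = rep(c("ctrl", "kd"), each = nrep),
                        total_mapped = colSums(cts)))
  truth <- data.frame(gene_id = gid[de_idx], log2fc = lfc[de_idx])
  list(counts = se, truth = truth)
}

# Junction sets (keys "donor:acceptor", half-open exonic coordinates) of a
# transcript exon matrix ordered by start.
.txJunctions <- function(m) {
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) < 2) return(data.frame(donor = integer(), acceptor = integer()))
  data.frame(donor = m[-nrow(m), 2], acceptor = m[-1, 1] - 1L)
}

.jkey <- function(donor, acceptor) paste(donor, acceptor, sep = ":")

# Enumerate the planted event geometry of every alternative-structure gene:
# the two transcripts' junction sets, split into shared and isoform-unique.
.plannedEvents <- function(annotation) {
  e <- exons(annotation)
  g <- genes(annotation)
  as_type <- mcols(g)$as_type
  res <- list()
  for (i in which(!is.na(as_type))) {
    gid <- mcols(g)$gene_id[i]
    ge <- e[mcols(e)$gene_id == gid]
    txs <- split(data.frame(start = start(ge), end = end(ge)),
                 mcols(ge)$transcript_id)
    js <- lapply(txs, function(d) .txJunctions(as.matrix(d)))
    k1 <- .jkey(js[[1]]$donor, js[[1]]$acceptor)
    k2 <- if (length(js) > 1) .jkey(js[[2]]$donor, js[[2]]$acceptor) else character()
    res[[gid]] <- list(gene_id = gid, type = as_type[i],
                       chrom = as.character(seqnames(g))[i],
                       strand = as.character(strand(g))[i],
                       u1 = setdiff(k1, k2), u2 = setdiff(k2, k1),
                       shared = intersect(k1, k2))
  }
  res
}

#' Simulate per-sample junction and boundary counts with planted shifts
#'
#' For every alternative-structure gene, isoform-1 usage is drawn per
#' replicate as binomial given a fixed per-event junction depth; a fraction
#' of events receives a between-group inclusion-ratio shift of
#' `as_delta_ratio` with random sign.  Isoform reads are multinomially
#' distributed over that isoform's unique junctions, so summed
#' inclusion/exclusion counts recover the planted ratio.  Intron-retention
#' genes write their retention evidence to the boundary-count table.
#'
#' @param annotation A [GenomeAnnotation] from [simulateAnnotation()].
#' @param config A [SimConfig].
#' @return list with `junctions` and `boundaries` (data.tables keyed by
#'   chrom, strand, donor, acceptor with one count column per sample) and
#'   `truth` (one row per planted event: gene, type, isoform-1 junction
#'   keys, per-group isoform-1 ratios, shifted flag).
#' @export
simulateJunctions <- function(annotation, config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(childSeed(config@seed, "junctions"))
  nrep <- config@n_replicates_per_group
  samples <- c(paste0("ctrl_", seq_len(nrep)), paste0("kd_", seq_len(nrep)))
  depth <- config@junction_depth
  ev <- .plannedEvents(annotation)
  jrows <- list(); brows <- list(); trows <- list()
  addCounts <- function(env, chrom, strand, key, counts) {
    da <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
    data.table::data.table(chrom = chrom, strand = strand,
      donor = da[1], acceptor = da[2],
      sample = samples, count = as.integer(counts))
  }
  for (x in ev) {
    p1 <- runif(1, 0.35, 0.65)
    shifted <- runif(1) < config@frac_as_shifted
    d <- if (shifted) sample(c(-1, 1), 1) * config@as_delta_ratio else 0
    p2 <- min(0.95, max(0.05, p1 + d))
    p <- c(rep(p1, nrep), rep(p2, nrep))
    n1 <- rbinom(2 * nrep, depth, p)
    n2 <- depth - n1
    if (x$type == "IntronR") {
      # isoform 1 = spliced (junction reads); isoform 2 = retained
      # (intron-exon boundary reads); the quantifier's inclusion side is
      # retention, so truth ratios below are stored for the u1 side.
      jrows[[length(jrows) + 1L]] <-
        addCounts(NULL, x$chrom, x$strand, x$u1, n1)
      brows[[length(brows) + 1L]] <-
        addCounts(NULL, x$chrom, x$strand, x$u1, n2)
    } else {
      for (side in c("u1", "u2")) {
        ks <- x[[side]]
        tot <- if (side == "u1") n1 else n2
        if (!length(ks)) next
        split_counts <- vapply(tot, function(tt)
          as.vector(rmultinom(1, tt, rep(1 / length(ks), length(ks)))),
          integer(length(ks)))
        split_counts <- matrix(split_counts, nrow = length(ks))
        for (j in seq_along(ks))
          jrows[[length(jrows) + 1L]] <-
            addCounts(NULL, x$chrom, x$strand, ks[j], split_counts[j, ])
      }
      # shared junctions carry steady constitutive traffic
      for (k in x$shared)
        jrows[[length(jrows) + 1L]] <-
          addCounts(NULL, x$chrom, x$strand, k, rpois(2 * nrep, depth))
    }
    trows[[length(trows) + 1L]] <- data.frame(
      gene_id = x$gene_id, type = x$type,
      inclusion_keys = paste(x$u1, collapse = ";"),
      exclusion_keys = paste(x$u2, collapse = ";"),
      ratio_g1 = p1, ratio_g2 = p2, shifted = shifted)
  }
  # constitutive genes: plain junction traffic, no events
  g <- genes(annotation)
  const <- mcols(g)$gene_id[is.na(mcols(g)$as_type)]
  aj <- annotatedJunctions(annotation)
  cj <- aj[aj$gene_id %in% const]
  if (nrow(cj)) {
    for (i in seq_len(nrow(cj)))
      jrows[[length(jrows) + 1L]] <- addCounts(NULL, cj$chrom[i], cj$strand[i],
        .jkey(cj$donor[i], cj$acceptor[i]), rpois(2 * nrep, depth))
  }
  castTab <- function(rows) {
    if (!length(rows)) {
      out <- data.table::data.table(chrom = character(), strand = character(),
        donor = integer(), acceptor = integer())
      for (s in samples) out[[s]] <- integer()
      return(out)
    }
    long <- data.table::rbindlist(rows)
    long <- long[, list(count = sum(count)),
                 by = c("chrom", "strand", "donor", "acceptor", "sample")]
    out <- data.table::dcast(long, chrom + strand + donor + acceptor ~ sample,
                             value.var = "count", fill = 0L)
    data.table::setcolorder(out, c("chrom", "strand", "donor", "acceptor",
                                   samples))
    data.table::setorder(out, chrom, strand, donor, acceptor)
    out[]
  }
  list(junctions = castTab(jrows), boundaries = castTab(brows),
       truth = if (length(trows)) do.call(rbind, trows) else
         data.frame(gene_id = character(), type = character(),
                    inclusion_keys = character(), exclusion_keys = character(),
                    ratio_g1 = numeric(), ratio_g2 = numeric(),
                    shifted = logical()))
}

#' Simulate IP and input read placements with planted binding peaks
#'
#' Input reads are placed uniformly over each gene body.  IP libraries get
#' the same uniform background; a fraction of genes additionally receives
#' extra reads confined to one planted interval so that the per-base rate
#' inside it is `peak_enrichment` times the background rate.
#'
#' @param annotation A [GenomeAnnotation].
#' @param config A [SimConfig].
#' @return list with `ip` and `input` (alignment `GRanges`, see
#'   [readBED12()]) and `truth` (data.frame gene_id, peak_start, peak_end
#'   0-based half-open, enrichment).
#' @export
simulateRipReads <- function(annotation, config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(childSeed(config@seed, "rip"))
  g <- genes(annotation)
  rl <- config@read_length_bp
  w <- config@peak_width_bp
  if (any(width(g) < w)) stop("peak_width_bp exceeds a gene length")
  n <- length(g)
  npk <- round(config@peak_fraction * n)
  pk_idx <- if (npk) sort(sample.int(n, npk)) else integer()
  erange <- range(config@peak_enrichment)
  enr <- setNames(runif(npk, erange[1], erange[2]), pk_idx)
  placeUniform <- function(gr_i, count) {
    lo <- start(g)[gr_i]; hi <- end(g)[gr_i] - rl + 1L
    lo + floor(runif(count) * (hi - lo + 1L))
  }
  mkReads <- function(starts, gi, prefix) {
    GRanges("chrS", IRanges(starts, width = rl),
            strand = strand(g)[gi],
            name = paste0(prefix, seq_along(starts)),
            unique = TRUE, blocks = IRanges::IRangesList(
              lapply(starts, function(s) IRanges(s, width = rl))),
            sample_id = prefix)
  }
  ip_starts <- integer(); ip_gi <- integer()
  in_starts <- integer(); in_gi <- integer()
  truth <- list()
  for (i in seq_len(n)) {
    in_s <- placeUniform(i, config@reads_per_gene_input)
    in_starts <- c(in_starts, in_s); in_gi <- c(in_gi, rep(i, length(in_s)))
    bg <- placeUniform(i, config@reads_per_gene_ip)
    extra <- integer()
    if (i %in% pk_idx) {
      L <- width(g)[i]
      E <- enr[[as.character(i)]]
      ps <- start(g)[i] + sample.int(L - w + 1L, 1) - 1L
      rate <- config@reads_per_gene_ip / L
      nx <- rpois(1, (E - 1) * rate * w)
      if (nx > 0) extra <- ps + floor(runif(nx) * (w - rl + 1L))
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = mcols(g)$gene_id[i], peak_start = ps - 1L,
        peak_end = ps + w - 1L, enrichment = E)
    }
    ip_s <- c(bg, extra)
    ip_starts <- c(ip_starts, ip_s); ip_gi <- c(ip_gi, rep(i, length(ip_s)))
  }
  list(ip = mkReads(ip_starts, ip_gi, "IP"),
       input = mkReads(in_starts, in_gi, "Input"),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(gene_id = character(), peak_start = integer(),
                    peak_end = integer(), enrichment = numeric()))
}

#' Simulate raw reads for the QC filter
#'
#' Generates a labelled mixture of clean reads, reads carrying planted `N`
#' bases, and short reads, with per-read truth of which QC rule (if any)
#' should discard them.  Explicit `lengths`/`n_counts` vectors override the
#' mixture and give a fully deterministic fixture.
#'
#' @param n_reads number of reads when drawing a random mixture.
#' @param frac_n fraction of reads given 1-5 planted `N` bases.
#' @param frac_short fraction of reads made shorter than `min_len`.
#' @param read_length length of normal reads (bp).
#' @param min_len,max_n the QC thresholds the truth labels anticipate.
#' @param lengths,n_counts optional explicit per-read lengths and N counts.
#' @param seed RNG seed.
#' @return list with `reads` (`Biostrings::DNAStringSet`, named) and `truth`
#'   (data.frame `name`, `length`, `n_bases`, `keep`, `drop_rule`).
#' @export
simulateRawReads <- function(n_reads = 100, frac_n = 0.1, frac_short = 0.1,
                             read_length = 150, min_len = 16, max_n = 2,
                             lengths = NULL, n_counts = NULL, seed = 1) {
  set.seed(childSeed(seed, "rawreads"))
  if (is.null(lengths)) {
    lengths <- rep(read_length, n_reads)
    short <- runif(n_reads) < frac_short
    lengths[short] <- sample(5:(min_len - 1), sum(short), replace = TRUE)
    n_counts <- integer(n_reads)
    withn <- runif(n_reads) < frac_n
    n_counts[withn] <- sample.int(5, sum(withn), replace = TRUE)
    n_counts <- pmin(n_counts, lengths)
  } else {
    n_counts <- if (is.null(n_counts)) integer(length(lengths)) else n_counts
    stopifnot(length(n_counts) == length(lengths), all(n_counts <= lengths))
  }
  n <- length(lengths)
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), lengths[i], replace = TRUE)
    if (n_counts[i] > 0) s[sample.int(lengths[i], n_counts[i])] <- "N"
    paste(s, collapse = "")
  }, "")
  nm <- sprintf("read%04d", seq_len(n))
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- nm
  drop_rule <- ifelse(n_counts > max_n, "max_n",
                      ifelse(lengths < min_len, "min_len", NA_character_))
  truth <- data.frame(name = nm, length = lengths, n_bases = n_counts,
                      keep = is.na(drop_rule), drop_rule = drop_rule)
  list(reads = reads, truth = truth)
}

#' Write reads to FASTQ with constant qualities
#'
#' @param reads A named `DNAStringSet`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
writeFASTQ <- function(reads, path) {
  quals <- Biostrings::BStringSet(vapply(width(reads), function(w)
    paste(rep("I", w), collapse = ""), ""))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}
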