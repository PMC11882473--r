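#' Extract splice junctions from block-structured alignments
#'
#' Every gap between consecutive blocks of a uniquely mapped read yields one
#' junction count.  Junctions are keyed by chromosome, strand, donor (exonic
#' end, 0-based half-open) and acceptor (exonic start, 0-based).
#'
#' @param reads one alignment `GRanges` (see [readBED12()]) or a named
#'   list of them, one per sample.
#' @return data.table: chrom, strand, donor, acceptor, one count column per
#'   sample.
#' @export
extractJunctions <- function(reads) {
  if (is(reads, "GRanges")) reads <- list(sample1 = reads)
  if (is.null(names(reads))) names(reads) <- paste0("sample", seq_along(reads))
  rows <- lapply(names(reads), function(s) {
    r <- reads[[s]]
    uq <- mcols(r)$unique
    if (!is.null(uq)) r <- r[uq]
    bl <- mcols(r)$blocks
    if (is.null(bl) || !length(r)) return(NULL)
    multi <- lengths(bl) > 1
    if (!any(multi)) return(NULL)
    r <- r[multi]; bl <- bl[multi]
    nj <- lengths(bl) - 1L
    st <- start(bl); en <- end(bl)
    donors <- unlist(lapply(en, function(x) x[-length(x)]))
    acceptors <- unlist(lapply(st, function(x) x[-1] - 1L))
    data.table::data.table(
      chrom = rep(as.character(seqnames(r)), nj),
      strand = rep(as.character(strand(r)), nj),
      donor = donors, acceptor = acceptors, sample = s)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  samples <- names(reads)
  if (!length(rows)) {
    out <- data.table::data.table(chrom = character(), strand = character(),
                                  donor = integer(), acceptor = integer())
    for (s in samples) out[[s]] <- integer()
    return(out)
  }
  long <- data.table::rbindlist(rows)
  long <- long[, list(count = .N),
               by = c("chrom", "strand", "donor", "acceptor", "sample")]
  out <- data.table::dcast(long, chrom + strand + donor + acceptor ~ sample,
                           value.var = "count", fill = 0L)
  for (s in setdiff(samples, colnames(out))) out[[s]] <- 0L
  data.table::setcolorder(out, c("chrom", "strand", "donor", "acceptor",
                                 samples))
  data.table::setorder(out, chrom, strand, donor, acceptor)
  out[]
}

.sampleCols <- function(tab)
  setdiff(colnames(tab), c("chrom", "strand", "donor", "acceptor", "gene_id"))

# strand-aware geometric label: alternative-donor events are 5' events on
# the plus strand and 3' events on the minus strand, and vice versa
.siteLabel <- function(kind, strand) {
  plus <- strand != "-"
  switch(kind,
    altdonor = if (plus) "A5SS" else "A3SS",
    altacceptor = if (plus) "A3SS" else "A5SS",
    terminaldonor = if (plus) "5pMXE" else "3pMXE",
    terminalacceptor = if (plus) "3pMXE" else "5pMXE",
    `altdonor&ES` = if (plus) "A5SS&ES" else "A3SS&ES",
    `altacceptor&ES` = if (plus) "A3SS&ES" else "A5SS&ES",
    kind)
}

#' Detect alternative-splicing events from junction evidence
#'
#' Classifies observed junctions against the annotated exon model of each
#' gene into ten event classes: exon skipping (`ES`, one skipped exon, both
#' inclusion junctions annotated or observed), `cassetteExon` (two or more
#' skipped exons), alternative 5'/3' splice sites (`A5SS`/`A3SS`; two
#' junctions sharing an acceptor/donor whose alternative boundary exons
#' overlap), mutually exclusive internal exons (`MXE`; four junctions, two
#' never co-included exons), mutually exclusive first/last exons
#' (`5pMXE`/`3pMXE`; shared-site pairs whose alternative exons are
#' non-overlapping transcript termini), intron retention (`IntronR`;
#' annotated junctions with intron-exon boundary-spanning read support),
#' and the composite classes `A5SS&ES`/`A3SS&ES` (an alternative splice
#' site whose long-form junction additionally skips an exon).  Composite
#' classes take precedence over their components and every junction
#' supports at most one event class, so the ten strata are disjoint.
#' Events using at least one un-annotated junction are flagged `novel`.
#'
#' @param annotation A [GenomeAnnotation].
#' @param junctions junction table from [extractJunctions()] or
#'   [simulateJunctions()].
#' @param boundaries optional intron-exon boundary-read table in the same
#'   layout (required to emit `IntronR` events).
#' @return data.frame of events: event_id, gene_id, chrom, strand, type,
#'   inclusion/exclusion junction keys (`donor:acceptor`, `;`-separated),
#'   alt_start/alt_end (0-based half-open) and `novel`.
#' @export
detectEvents <- function(annotation, junctions, boundaries = NULL) {
  g <- genes(annotation)
  jx <- data.table::as.data.table(junctions)
  scols <- .sampleCols(jx)
  if (nrow(jx)) {
    jgr <- GRanges(jx$chrom, IRanges(jx$donor + 1L, jx$acceptor),
                   strand = jx$strand)
    hits <- GenomicRanges::findOverlaps(jgr, g, type = "within")
    gene_of <- rep(NA_integer_, nrow(jx))
    gene_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
    jx$gene <- gene_of
  } else jx$gene <- integer()
  n_dropped <- sum(is.na(jx$gene))
  aj <- annotatedJunctions(annotation)
  e <- exons(annotation)
  events <- list()
  for (gi in sort(unique(jx$gene[!is.na(jx$gene)]))) {
    gid <- mcols(g)$gene_id[gi]
    gstrand <- as.character(strand(g))[gi]
    gchrom <- as.character(seqnames(g))[gi]
    J <- jx[!is.na(gene) & gene == gi]
    obs_tot <- rowSums(J[, scols, with = FALSE])
    J <- J[obs_tot > 0]
    if (!nrow(J)) next
    A <- aj[aj$gene_id == gid]
    akeys <- .jkey(A$donor, A$acceptor)
    okeys <- .jkey(J$donor, J$acceptor)
    oa <- union(akeys, okeys)
    ge <- e[mcols(e)$gene_id == gid]
    edt <- unique(data.frame(start = start(ge), end = end(ge)))
    # terminal flags in genome order, per transcript
    lt <- rt <- rep(FALSE, nrow(edt))
    for (tx in split(data.frame(start = start(ge), end = end(ge)),
                     mcols(ge)$transcript_id)) {
      i1 <- which(edt$start == min(tx$start) &
                  edt$end == tx$end[which.min(tx$start)])
      i2 <- which(edt$end == max(tx$end) &
                  edt$start == tx$start[which.max(tx$end)])
      lt[i1] <- TRUE; rt[i2] <- TRUE
    }
    exonEndingAt <- function(d) which(edt$end == d)
    exonStartingAt <- function(a) which(edt$start == a + 1L)
    overlapIdx <- function(i, j)
      length(i) && length(j) &&
      any(outer(seq_along(i), seq_along(j), Vectorize(function(u, v)
        edt$start[i[u]] <= edt$end[j[v]] && edt$start[j[v]] <= edt$end[i[u]])))
    consumed <- character()
    addEvent <- function(type, inc, exc, a0, a1) {
      novel <- any(!c(inc, exc) %in% akeys)
      events[[length(events) + 1L]] <<- data.frame(
        event_id = paste0(gid, ":", type, ":", a0, "-", a1),
        gene_id = gid, chrom = gchrom, strand = gstrand, type = type,
        inclusion_keys = paste(inc, collapse = ";"),
        exclusion_keys = paste(exc, collapse = ";"),
        alt_start = a0, alt_end = a1, novel = novel)
    }
    ## 1. skipping family (pure and composite); composite precedence
    for (r in seq_len(nrow(J))) {
      d <- J$donor[r]; a <- J$acceptor[r]
      key <- .jkey(d, a)
      S <- which(edt$start - 1L > d & edt$end < a)
      if (!length(S)) next
      S <- S[order(edt$start[S])]
      s1 <- S[1]; sk <- S[length(S)]
      in_same <- .jkey(d, edt$start[s1] - 1L) %in% oa
      out_same <- .jkey(edt$end[sk], a) %in% oa
      if (in_same && out_same) {
        chainkeys <- if (length(S) > 1)
          .jkey(edt$end[S[-length(S)]], edt$start[S[-1]] - 1L) else character()
        inc <- c(.jkey(d, edt$start[s1] - 1L),
                 intersect(chainkeys, oa), .jkey(edt$end[sk], a))
        addEvent(if (length(S) == 1) "ES" else "cassetteExon",
                 inc, key, edt$start[s1] - 1L, edt$end[sk])
        consumed <- c(consumed, key)
        next
      }
      if (out_same) {
        alt_in <- A[A$acceptor == edt$start[s1] - 1L & A$donor != d, ]
        if (nrow(alt_in)) {
          d1 <- alt_in$donor[1]
          if (overlapIdx(exonEndingAt(d), exonEndingAt(d1))) {
            inc <- c(.jkey(d1, edt$start[s1] - 1L), .jkey(edt$end[sk], a))
            addEvent(.siteLabel("altdonor&ES", gstrand), inc, key,
                     min(d, d1), max(d, d1))
            consumed <- c(consumed, key)
            next
          }
        }
      }
      if (in_same) {
        alt_out <- A[A$donor == edt$end[sk] & A$acceptor != a, ]
        if (nrow(alt_out)) {
          a1 <- alt_out$acceptor[1]
          if (overlapIdx(exonStartingAt(a), exonStartingAt(a1))) {
            inc <- c(.jkey(d, edt$start[s1] - 1L), .jkey(edt$end[sk], a1))
            addEvent(.siteLabel("altacceptor&ES", gstrand), inc, key,
                     min(a, a1), max(a, a1))
            consumed <- c(consumed, key)
          }
        }
      }
    }
    ## 2. mutually exclusive internal exons
    internals <- which(!lt & !rt)
    if (length(internals) >= 2) {
      for (u in seq_along(internals)) for (v in seq_along(internals)) {
        X <- internals[u]; Y <- internals[v]
        if (edt$end[X] >= edt$start[Y]) next       # need X strictly left of Y
        dcand <- intersect(A$donor[A$acceptor == edt$start[X] - 1L],
                           A$donor[A$acceptor == edt$start[Y] - 1L])
        acand <- intersect(A$acceptor[A$donor == edt$end[X]],
                           A$acceptor[A$donor == edt$end[Y]])
        if (!length(dcand) || !length(acand)) next
        d <- dcand[1]; a <- acand[1]
        four <- c(.jkey(d, edt$start[X] - 1L), .jkey(edt$end[X], a),
                  .jkey(d, edt$start[Y] - 1L), .jkey(edt$end[Y], a))
        if (!all(four %in% oa) || !any(four %in% okeys)) next
        if (.jkey(edt$end[X], edt$start[Y] - 1L) %in% oa) next
        if (any(four %in% consumed)) next
        addEvent("MXE", four[1:2], four[3:4], edt$start[X] - 1L, edt$end[Y])
        consumed <- c(consumed, four)
      }
    }
    ## 3. alternative sites and terminal mutually exclusive exons
    Jleft <- J[!okeys %in% consumed]
    if (nrow(Jleft)) {
      byA <- split(seq_len(nrow(Jleft)), Jleft$acceptor)
      for (idx in byA) {
        dn <- sort(unique(Jleft$donor[idx]))
        if (length(dn) < 2) next
        a <- Jleft$acceptor[idx[1]]
        for (q in seq_len(length(dn) - 1)) {
          da <- dn[q]; db <- dn[q + 1]
          Ea <- exonEndingAt(da); Eb <- exonEndingAt(db)
          terminal <- length(Ea) && length(Eb) && !overlapIdx(Ea, Eb) &&
            any(lt[Ea]) && any(lt[Eb])
          if (length(Ea) && length(Eb) && !overlapIdx(Ea, Eb) && !terminal)
            next                                  # non-overlapping internals
          kind <- if (terminal) "terminaldonor" else "altdonor"
          addEvent(.siteLabel(kind, gstrand), .jkey(db, a), .jkey(da, a),
                   da, db)
        }
      }
      byD <- split(seq_len(nrow(Jleft)), Jleft$donor)
      for (idx in byD) {
        ac <- sort(unique(Jleft$acceptor[idx]))
        if (length(ac) < 2) next
        d <- Jleft$donor[idx[1]]
        for (q in seq_len(length(ac) - 1)) {
          aa <- ac[q]; ab <- ac[q + 1]
          Ea <- exonStartingAt(aa); Eb <- exonStartingAt(ab)
          terminal <- length(Ea) && length(Eb) && !overlapIdx(Ea, Eb) &&
            any(rt[Ea]) && any(rt[Eb])
          if (length(Ea) && length(Eb) && !overlapIdx(Ea, Eb) && !terminal)
            next
          kind <- if (terminal) "terminalacceptor" else "altacceptor"
          addEvent(.siteLabel(kind, gstrand), .jkey(d, aa), .jkey(d, ab),
                   aa, ab)
        }
      }
    }
    ## 4. intron retention: annotated junction + boundary-spanning reads
    if (!is.null(boundaries) && nrow(boundaries)) {
      bt <- data.table::as.data.table(boundaries)
      bs <- .sampleCols(bt)
      for (r in seq_len(nrow(A))) {
        key <- .jkey(A$donor[r], A$acceptor[r])
        if (key %in% consumed) next
        hit <- bt[chrom == gchrom & strand == gstrand &
                  donor == A$donor[r] & acceptor == A$acceptor[r]]
        if (!nrow(hit) || sum(hit[, bs, with = FALSE]) == 0) next
        if (!key %in% okeys) next
        addEvent("IntronR", key, key, A$donor[r], A$acceptor[r])
      }
    }
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = character(), gene_id = character(),
               chrom = character(), strand = character(), type = character(),
               inclusion_keys = character(), exclusion_keys = character(),
               alt_start = integer(), alt_end = integer(), novel = logical())
  out <- unique(out)
  attr(out, "dropped_junctions") <- n_dropped
  out[order(out$gene_id, out$alt_start, out$type), , drop = FALSE]
}

#' Quantify per-sample inclusion ratios of detected events
#'
#' For each event and sample, `inclusion` is the summed count of the
#' event's inclusion junctions and `exclusion` that of its exclusion
#' junctions; `ratio = inclusion / (inclusion + exclusion)`.  For
#' `IntronR`, inclusion (retention) evidence is the boundary-spanning read
#' count and exclusion is the spliced-junction count.  Samples with fewer
#' than `min_cov` supporting reads are flagged undefined (`NA` ratio).
#'
#' @param events data.frame from [detectEvents()].
#' @param junctions junction count table.
#' @param boundaries boundary count table (for IntronR).
#' @param min_cov minimum inclusion+exclusion reads per sample (default 10).
#' @return data.frame, one row per event x sample: event_id, sample,
#'   inclusion, exclusion, ratio, defined.
#' @export
quantifyEvents <- function(events, junctions, boundaries = NULL,
                           min_cov = 10) {
  jx <- data.table::as.data.table(junctions)
  scols <- .sampleCols(jx)
  jmap <- as.matrix(jx[, scols, with = FALSE])
  rownames(jmap) <- .jkey(jx$donor, jx$acceptor)
  bmap <- NULL
  if (!is.null(boundaries) && nrow(boundaries)) {
    bt <- data.table::as.data.table(boundaries)
    bmap <- as.matrix(bt[, .sampleCols(bt), with = FALSE])
    rownames(bmap) <- .jkey(bt$donor, bt$acceptor)
  }
  sumKeys <- function(map, keys) {
    keys <- keys[keys %in% rownames(map)]
    if (!length(keys)) return(numeric(ncol(map)))
    colSums(map[keys, , drop = FALSE])
  }
  rows <- lapply(seq_len(nrow(events)), function(i) {
    inc_keys <- strsplit(events$inclusion_keys[i], ";", fixed = TRUE)[[1]]
    exc_keys <- strsplit(events$exclusion_keys[i], ";", fixed = TRUE)[[1]]
    if (events$type[i] == "IntronR") {
      inc <- if (is.null(bmap)) numeric(length(scols)) else
        sumKeys(bmap, inc_keys)
      exc <- sumKeys(jmap, exc_keys)
    } else {
      inc <- sumKeys(jmap, inc_keys)
      exc <- sumKeys(jmap, exc_keys)
    }
    tot <- inc + exc
    data.frame(event_id = events$event_id[i], sample = scols,
               inclusion = as.numeric(inc), exclusion = as.numeric(exc),
               ratio = ifelse(tot > 0, inc / tot, NA_real_),
               defined = tot >= min_cov)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(), sample = character(),
               inclusion = numeric(), exclusion = numeric(),
               ratio = numeric(), defined = logical())
  out$ratio[!out$defined] <- NA_real_
  out
}

#' Test for regulated alternative-splicing events between two groups
#'
#' Per event, a two-sided equal-variance (Student) t-test compares the
#' per-sample inclusion ratios of the two groups; p-values are BH-adjusted
#' across all tested events and events are called significant at
#' `fdr <= fdr_threshold`.  Events with fewer than `min_samples` defined
#' ratios in either group are reported untested.  Degenerate events (zero
#' variance in both groups) get p = 1 when the group means agree and p = 0,
#' flagged, when they differ.
#'
#' @param quants data.frame from [quantifyEvents()].
#' @param design data.frame with columns `sample`, `group` (two groups).
#' @param fdr_threshold FDR cut-off (default 0.05).
#' @param min_samples minimum defined ratios per group (default 2).
#' @return data.frame: event_id, mean ratios, delta_ratio (group2 - group1),
#'   p_value, fdr, tested, degenerate, significant.
#' @export
testRase <- function(quants, design, fdr_threshold = 0.05, min_samples = 2) {
  grp <- unique(design$group)
  if (length(grp) != 2) stop("exactly two groups are required")
  s1 <- design$sample[design$group == grp[1]]
  s2 <- design$sample[design$group == grp[2]]
  ev <- unique(quants$event_id)
  res <- lapply(ev, function(eid) {
    q <- quants[quants$event_id == eid, ]
    r1 <- q$ratio[q$sample %in% s1 & q$defined]
    r2 <- q$ratio[q$sample %in% s2 & q$defined]
    tested <- length(r1) >= min_samples && length(r2) >= min_samples
    p <- NA_real_; degen <- FALSE
    if (tested) {
      if (var(r1) == 0 && var(r2) == 0) {
        p <- if (isTRUE(all.equal(mean(r1), mean(r2)))) 1 else 0
        degen <- p == 0
      } else {
        p <- stats::t.test(r1, r2, var.equal = TRUE)$p.value
      }
    }
    data.frame(event_id = eid,
               mean_ratio_g1 = if (length(r1)) mean(r1) else NA_real_,
               mean_ratio_g2 = if (length(r2)) mean(r2) else NA_real_,
               delta_ratio = if (length(r1) && length(r2))
                 mean(r2) - mean(r1) else NA_real_,
               p_value = p, tested = tested, degenerate = degen)
  })
  out <- do.call(rbind, res)
  out$fdr <- NA_real_
  out$fdr[out$tested] <- p.adjust(out$p_value[out$tested], "BH")
  out$significant <- out$tested & !is.na(out$fdr) & out$fdr <= fdr_threshold
  out
}
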