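#' QC-filter raw reads
#'
#' Applies the two raw-read rules in order: reads with more than `max_n`
#' ambiguous `N` bases are discarded first, then reads shorter than
#' `min_len` nt are dropped.  Quality/adapter trimming is assumed to have
#' been performed upstream.
#'
#' @param reads A `DNAStringSet` (e.g. from [readFASTQ()]).
#' @param max_n maximum tolerated number of `N` bases (default 2).
#' @param min_len minimum read length in nt (default 16).
#' @return list with `kept` (filtered `DNAStringSet`) and `report`
#'   (data.frame: input, dropped_n, dropped_short, kept).
#' @examples
#' rr <- simulateRawReads(lengths = c(150, 150, 15, 150, 150),
#'                        n_counts = c(0, 3, 0, 2, 0))
#' filterRawReads(rr$reads)$report
#' @export
filterRawReads <- function(reads, max_n = 2, min_len = 16) {
  nN <- Biostrings::letterFrequency(reads, "N")[, 1]
  pass_n <- nN <= max_n
  after_n <- reads[pass_n]
  pass_len <- width(after_n) >= min_len
  kept <- after_n[pass_len]
  list(kept = kept,
       report = data.frame(input = length(reads),
                           dropped_n = sum(!pass_n),
                           dropped_short = sum(!pass_len),
                           kept = length(kept)))
}

#' Read a FASTQ file
#'
#' @param path FASTQ path.
#' @return A named `DNAStringSet`.
#' @export
readFASTQ <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(x) <- sub("\\s.*", "", names(x))
  x
}

#' Count uniquely mapped fragments per gene
#'
#' A read contributes one count to a gene iff it is uniquely mapped,
#' strand-compatible (when `stranded = "forward"`), and every one of its
#' blocks intersects that gene's exon union.  Reads compatible with more
#' than one gene are ambiguous and counted for none; reads on chromosomes
#' absent from the annotation are skipped with a warning.  Both tallies are
#' reported per sample in `colData`.
#'
#' @param reads one alignment `GRanges` (see [readBED12()]) or a named list
#'   of them, one per sample.
#' @param annotation A [GenomeAnnotation].
#' @param stranded `"forward"` (read strand must equal gene strand) or
#'   `"none"`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `rowData$exon_length` (exon-union bp) and per-sample
#'   `colData` columns `total_mapped`, `ambiguous`, `skipped_chrom`.
#' @export
countGenes <- function(reads, annotation, stranded = c("forward", "none")) {
  stranded <- match.arg(stranded)
  if (is(reads, "GRanges")) reads <- list(sample1 = reads)
  if (is.null(names(reads))) names(reads) <- paste0("sample", seq_along(reads))
  eu <- exonUnion(annotation)
  gid <- geneIds(annotation)
  eu <- eu[gid]
  exon_flat <- unlist(eu)
  exon_gene <- rep(seq_along(eu), lengths(eu))
  gene_strand <- as.character(strand(genes(annotation)))
  cts <- matrix(0L, length(gid), length(reads),
                dimnames = list(gid, names(reads)))
  total <- ambig <- skipped <- integer(length(reads))
  for (s in seq_along(reads)) {
    r <- reads[[s]]
    known <- as.character(seqnames(r)) %in% seqlevels(genes(annotation))
    if (any(!known)) {
      warning(sum(!known), " alignments on chromosomes absent from the ",
              "annotation were skipped in sample ", names(reads)[s])
      skipped[s] <- sum(!known)
      r <- r[known]
    }
    uq <- mcols(r)$unique
    if (is.null(uq)) uq <- rep(TRUE, length(r))
    r <- r[uq]
    total[s] <- length(r)
    if (!length(r)) next
    bl <- mcols(r)$blocks
    if (is.null(bl)) bl <- IRanges::IRangesList(S4Vectors::split(ranges(r), seq_along(r)))
    nblk <- lengths(bl)
    bgr <- GRanges(rep(seqnames(r), nblk), unlist(bl),
                   strand = rep(strand(r), nblk))
    read_of_block <- rep(seq_along(r), nblk)
    hits <- GenomicRanges::findOverlaps(bgr, exon_flat, ignore.strand = TRUE)
    if (!length(hits)) next
    dt <- data.table::data.table(
      read = read_of_block[S4Vectors::queryHits(hits)],
      block = S4Vectors::queryHits(hits),
      gene = exon_gene[S4Vectors::subjectHits(hits)])
    if (stranded == "forward") {
      rs <- as.character(strand(r))[dt$read]
      dt <- dt[rs == gene_strand[dt$gene]]
    }
    if (!nrow(dt)) next
    cover <- dt[, list(nb = data.table::uniqueN(block)), by = c("read", "gene")]
    full <- cover[nb == nblk[read]]
    if (!nrow(full)) next
    ngene <- full[, list(k = .N, gene = gene[1]), by = "read"]
    uniq_assign <- ngene[k == 1]
    ambig[s] <- sum(ngene$k > 1)
    if (nrow(uniq_assign)) {
      tab <- table(uniq_assign$gene)
      cts[as.integer(names(tab)), s] <- cts[as.integer(names(tab)), s] +
        as.integer(tab)
    }
  }
  lens <- sum(width(eu))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cts),
    rowData = DataFrame(gene_id = gid, exon_length = as.integer(lens)),
    colData = DataFrame(sample = names(reads), total_mapped = total,
                        ambiguous = ambig, skipped_chrom = skipped))
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `fpkm[g, s] = count[g, s] * 1e9 / (exon_length_bp[g] * total_mapped[s])`.
#' Gene length is the exon-union length across transcripts.
#'
#' @param se A count `SummarizedExperiment` as returned by [countGenes()]
#'   or [simulateCounts()].
#' @return A numeric matrix of FPKM values.
#' @examples
#' se <- SummarizedExperiment::SummarizedExperiment(
#'   assays = list(counts = matrix(10, 1, 1, dimnames = list("G1", "s1"))),
#'   rowData = S4Vectors::DataFrame(exon_length = 1000L),
#'   colData = S4Vectors::DataFrame(total_mapped = 1e6))
#' computeFpkm(se)  # 10
#' @export
computeFpkm <- function(se) {
  cts <- SummarizedExperiment::assay(se, "counts")
  len <- SummarizedExperiment::rowData(se)$exon_length
  tot <- SummarizedExperiment::colData(se)$total_mapped
  if (is.null(len) || any(len <= 0))
    stop("non-positive exon_length for gene(s): ",
         paste(head(rownames(cts)[which(len <= 0)]), collapse = ", "))
  if (is.null(tot) || any(tot <= 0))
    stop("non-positive total_mapped for sample(s): ",
         paste(head(colnames(cts)[which(tot <= 0)]), collapse = ", "))
  sweep(sweep(cts * 1e9, 1, as.numeric(len), "/"), 2, as.numeric(tot), "/")
}
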