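#' Read block-structured alignments from BED12
#'
#' Each BED12 record is one aligned fragment; blocks encode the aligned
#' segments, and gaps between consecutive blocks are splice junctions.
#' Mapping uniqueness is carried in the BED score field (dialect: 1 =
#' uniquely mapped, 0 = multi-mapped).
#'
#' @param path BED12 (or BED6) file path.
#' @param sample_id Optional sample label stored on every read.
#' @return A `GRanges`, one range per read (the read span), with metadata
#'   columns `name`, `unique` (logical), `blocks` (absolute-coordinate
#'   `IRangesList`) and `sample_id`.
#' @export
readBED12 <- function(path, sample_id = NA_character_) {
  x <- rtracklayer::import(path, format = "bed")
  bl <- mcols(x)$blocks
  if (is.null(bl)) {
    bl <- IRanges::IRangesList(as.list(S4Vectors::split(IRanges(1L, width(x)),
                                             seq_along(x))))
    names(bl) <- NULL
  }
  abs_blocks <- IRanges::shift(bl, start(x) - 1L)
  score <- mcols(x)$score
  if (is.null(score)) score <- rep(1, length(x))
  gr <- granges(x)
  mcols(gr)$name <- mcols(x)$name
  mcols(gr)$unique <- !is.na(score) & score >= 1
  mcols(gr)$blocks <- abs_blocks
  mcols(gr)$sample_id <- sample_id
  gr
}

#' Write block-structured alignments to BED12
#'
#' Inverse of [readBED12()]: writes one BED12 line per read, with blocks,
#' and the uniqueness flag in the score field.
#'
#' @param reads `GRanges` as returned by [readBED12()] (or with plain
#'   single-block reads and no `blocks` column).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeBED12 <- function(reads, path) {
  n <- length(reads)
  if (!n) { writeLines(character(), path); return(invisible(path)) }
  bl <- mcols(reads)$blocks
  if (is.null(bl)) bl <- IRanges::IRangesList(S4Vectors::split(ranges(reads), seq_len(n)))
  nm <- mcols(reads)$name
  if (is.null(nm)) nm <- paste0("read", seq_len(n))
  uq <- mcols(reads)$unique
  score <- if (is.null(uq)) rep(1L, n) else as.integer(uq)
  starts0 <- start(reads) - 1L
  sizes <- vapply(width(bl), paste, "", collapse = ",")
  offs <- vapply(seq_len(n), function(i)
    paste(start(bl[[i]]) - start(reads)[i], collapse = ","), "")
  nblk <- lengths(bl)
  lines <- paste(as.character(seqnames(reads)), starts0, end(reads), nm,
                 score, as.character(strand(reads)), starts0, end(reads),
                 "0", nblk, sizes, offs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Construct an alignment GRanges from block coordinates
#'
#' Convenience constructor used by the simulator and by tests.
#'
#' @param chrom,strand per-read chromosome and strand (recycled).
#' @param blocks list of integer matrices or `IRanges`, absolute
#'   block coordinates (1-based closed) per read.
#' @param name,unique,sample_id per-read metadata (recycled).
#' @return `GRanges` in the layout of [readBED12()].
#' @export
alignedReads <- function(chrom, strand, blocks, name = NULL,
                         unique = TRUE, sample_id = NA_character_) {
  bl <- IRanges::IRangesList(lapply(blocks, function(b) {
    if (is(b, "IRanges")) b else IRanges(b[, 1], b[, 2])
  }))
  n <- length(bl)
  span_start <- vapply(start(bl), min, 1L)
  span_end <- vapply(end(bl), max, 1L)
  gr <- GRanges(rep_len(chrom, n), IRanges(span_start, span_end),
                strand = rep_len(strand, n))
  mcols(gr)$name <- if (is.null(name)) paste0("read", seq_len(n)) else name
  mcols(gr)$unique <- rep_len(unique, n)
  mcols(gr)$blocks <- bl
  mcols(gr)$sample_id <- rep_len(sample_id, n)
  gr
}
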