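#' @rdname annotation-accessors
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname annotation-accessors
#' @export
setMethod("exons", "GenomeAnnotation", function(x) x@exons)

#' @rdname annotation-accessors
#' @export
setMethod("geneIds", "GenomeAnnotation", function(x) mcols(x@genes)$gene_id)

#' @rdname annotation-accessors
#' @export
setMethod("exonUnion", "GenomeAnnotation", function(x) {
  sp <- S4Vectors::split(granges(x@exons), mcols(x@exons)$gene_id)
  reduce(sp)
})

#' @rdname annotation-accessors
#' @export
setMethod("annotatedJunctions", "GenomeAnnotation", function(x) {
  e <- x@exons
  dt <- data.table::data.table(
    chrom = as.character(seqnames(e)), strand = as.character(strand(e)),
    start = start(e), end = end(e),
    gene_id = mcols(e)$gene_id, transcript_id = mcols(e)$transcript_id)
  data.table::setorder(dt, transcript_id, start)
  jt <- dt[, if (.N > 1) list(
    chrom = chrom[-.N], strand = strand[-.N], gene_id = gene_id[-.N],
    donor = end[-.N], acceptor = start[-1] - 1L), by = transcript_id]
  if (!nrow(jt)) {
    return(data.table::data.table(chrom = character(), strand = character(),
      gene_id = character(), donor = integer(), acceptor = integer()))
  }
  unique(jt[, list(chrom, strand, gene_id, donor, acceptor)])
})

#' Read a gene model from GTF
#'
#' Parses a GTF file (via \pkg{rtracklayer}) into a [GenomeAnnotation].
#' `gene` rows are optional: gene spans are rebuilt from exons when absent.
#'
#' @param path GTF file path.
#' @return A [GenomeAnnotation].
#' @export
readGTF <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[mcols(gr)$type == "exon"]
  if (!length(ex)) stop("no exon records in GTF: ", path)
  gid <- mcols(ex)$gene_id
  if (is.null(gid) || anyNA(gid)) stop("GTF exons lack gene_id attributes")
  grow <- gr[mcols(gr)$type == "gene"]
  if (length(grow)) {
    genes <- granges(grow)
    mcols(genes)$gene_id <- mcols(grow)$gene_id
    sym <- mcols(grow)$gene_name
    mcols(genes)$symbol <- if (is.null(sym)) mcols(grow)$gene_id else
      ifelse(is.na(sym), mcols(grow)$gene_id, sym)
  } else {
    sp <- S4Vectors::split(granges(ex), gid)
    genes <- unlist(range(sp), use.names = FALSE)
    mcols(genes)$gene_id <- names(sp)
    mcols(genes)$symbol <- names(sp)
  }
  exo <- granges(ex)
  mcols(exo)$gene_id <- gid
  mcols(exo)$transcript_id <- mcols(ex)$transcript_id
  GenomeAnnotation(genes = genes, exons = exo)
}

#' Write a gene model to GTF
#'
#' Emits gene, transcript and exon rows.  Header comment lines are omitted
#' so that output is byte-identical for identical inputs.
#'
#' @param annotation A [GenomeAnnotation].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGTF <- function(annotation, path) {
  g <- genes(annotation)
  e <- exons(annotation)
  edt <- data.table::data.table(
    chrom = as.character(seqnames(e)), start = start(e), end = end(e),
    strand = as.character(strand(e)), gene_id = mcols(e)$gene_id,
    transcript_id = mcols(e)$transcript_id)
  data.table::setorder(edt, chrom, start, end, transcript_id)
  tdt <- edt[, list(start = min(start), end = max(end),
                    chrom = chrom[1], strand = strand[1],
                    gene_id = gene_id[1]), by = transcript_id]
  data.table::setorder(tdt, chrom, start, end, transcript_id)
  fmt <- function(chrom, feat, start, end, strand, attr)
    paste(chrom, "ripintegrate", feat, start, end, ".", strand, ".", attr,
          sep = "\t")
  go <- order(as.character(seqnames(g)), start(g), end(g))
  g <- g[go]
  lines <- c(
    fmt(as.character(seqnames(g)), "gene", start(g), end(g),
        as.character(strand(g)),
        sprintf('gene_id "%s"; gene_name "%s";',
                mcols(g)$gene_id, mcols(g)$symbol)),
    fmt(tdt$chrom, "transcript", tdt$start, tdt$end, tdt$strand,
        sprintf('gene_id "%s"; transcript_id "%s";',
                tdt$gene_id, tdt$transcript_id)),
    fmt(edt$chrom, "exon", edt$start, edt$end, edt$strand,
        sprintf('gene_id "%s"; transcript_id "%s";',
                edt$gene_id, edt$transcript_id)))
  writeLines(lines, path)
  invisible(path)
}
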