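#' Accessors for GenomeAnnotation
#'
#' `genes()` and `exons()` return the gene-level and exon-level
#' [GenomicRanges::GRanges] of a [GenomeAnnotation]; `geneIds()` the gene
#' identifiers; `exonUnion()` the per-gene union of exons across transcripts
#' (a `GRangesList`, used as the counting target and as the FPKM length);
#' `annotatedJunctions()` the introns implied by consecutive exons of each
#' transcript.
#'
#' @param x A [GenomeAnnotation].
#' @return See each description above.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname annotation-accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname annotation-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname annotation-accessors
#' @export
setGeneric("exonUnion", function(x) standardGeneric("exonUnion"))

#' @rdname annotation-accessors
#' @export
setGeneric("annotatedJunctions", function(x) standardGeneric("annotatedJunctions"))
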