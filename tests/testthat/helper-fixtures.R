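# Small hand-built fixtures shared across test files.

# three-exon plus-strand gene with a skippable middle exon
toyEsAnnotation <- function() {
  e <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(101, 301, 501, 101, 501), c(200, 400, 600, 200, 600)),
    strand = "+",
    gene_id = "TG1",
    transcript_id = c("TG1.T1", "TG1.T1", "TG1.T1", "TG1.T2", "TG1.T2"))
  g <- GenomicRanges::GRanges("chrT", IRanges::IRanges(101, 600), "+",
                              gene_id = "TG1", symbol = "TG1")
  GenomeAnnotation(genes = g, exons = e)
}

# two overlapping plus-strand single-exon genes (for ambiguity tests)
toyOverlapAnnotation <- function() {
  g <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(101, 151), c(300, 350)), "+",
    gene_id = c("OV1", "OV2"), symbol = c("OV1", "OV2"))
  e <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(101, 151), c(300, 350)), "+",
    gene_id = c("OV1", "OV2"), transcript_id = c("OV1.T1", "OV2.T1"))
  GenomeAnnotation(genes = g, exons = e)
}

# junction count table from explicit keys ("donor:acceptor") and a count
# matrix (events x samples)
toyJunctionTable <- function(keys, counts, chrom = "chrT", strand = "+") {
  da <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  out <- data.table::data.table(chrom = chrom, strand = strand,
                                donor = as.integer(da[, 1]),
                                acceptor = as.integer(da[, 2]))
  counts <- as.matrix(counts)
  for (j in seq_len(ncol(counts))) out[[colnames(counts)[j]]] <- counts[, j]
  out
}

toyDesign <- function(nrep = 3)
  data.frame(sample = c(paste0("ctrl_", seq_len(nrep)),
                        paste0("kd_", seq_len(nrep))),
             group = rep(c("ctrl", "kd"), each = nrep))
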