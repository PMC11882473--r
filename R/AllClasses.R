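#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges IRangesList ranges reduce width start end
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand granges
#' @importFrom GenomeInfoDb seqlevels
NULL

#' Gene-model container for the pipeline
#'
#' `GenomeAnnotation` holds a gene model as two parallel [GenomicRanges::GRanges]
#' objects: one range per gene (with `gene_id` and `symbol` metadata columns)
#' and one range per exon (with `gene_id` and `transcript_id`).  It is the
#' coordinate backbone for gene counting, junction classification and the
#' per-gene read shuffling used by the peak caller.
#'
#' Exon coordinates are stored 1-based closed (the native GRanges convention);
#' BED output is converted to 0-based half-open on write.
#'
#' @slot genes `GRanges`, one range per gene, names and `gene_id` set.
#' @slot exons `GRanges`, one range per exon with `gene_id`, `transcript_id`.
#'
#' @seealso [readGTF()], [genes()], [exons()], [exonUnion()]
#' @export
setClass("GenomeAnnotation",
  representation(genes = "GRanges", exons = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  g <- object@genes
  e <- object@exons
  if (is.null(mcols(g)$gene_id)) msg <- c(msg, "genes must carry a gene_id column")
  if (length(e)) {
    need <- c("gene_id", "transcript_id")
    if (!all(need %in% colnames(mcols(e))))
      msg <- c(msg, "exons must carry gene_id and transcript_id columns")
    else if (!all(mcols(e)$gene_id %in% mcols(g)$gene_id))
      msg <- c(msg, "exon gene_ids must be a subset of gene gene_ids")
  }
  if (anyDuplicated(mcols(g)$gene_id)) msg <- c(msg, "duplicated gene_id")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param genes `GRanges` with `gene_id` (and optionally `symbol`) metadata.
#' @param exons `GRanges` with `gene_id` and `transcript_id` metadata.
#' @return A [GenomeAnnotation] object.
#' @examples
#' g <- GenomicRanges::GRanges("chrS", IRanges::IRanges(1, 1000), "+",
#'                             gene_id = "G1", symbol = "G1")
#' e <- GenomicRanges::GRanges("chrS", IRanges::IRanges(c(1, 501), c(200, 1000)),
#'                             "+", gene_id = "G1", transcript_id = "G1.T1")
#' GenomeAnnotation(genes = g, exons = e)
#' @export
GenomeAnnotation <- function(genes, exons) {
  if (is.null(mcols(genes)$symbol)) mcols(genes)$symbol <- mcols(genes)$gene_id
  names(genes) <- mcols(genes)$gene_id
  o <- order(as.character(seqnames(exons)), start(exons), end(exons),
             mcols(exons)$transcript_id)
  new("GenomeAnnotation", genes = genes, exons = exons[o])
}

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", length(object@genes), "genes,",
      length(unique(mcols(object@exons)$transcript_id)), "transcripts,",
      length(object@exons), "exons on",
      paste(seqlevels(object@genes), collapse = ","), "\n")
})

#' Simulation configuration for the synthetic-data generator
#'
#' Holds every knob of the synthetic study: annotation geometry, the
#' 3-vs-3 negative-binomial expression design with planted log2
#' fold-changes, per-event junction depths with planted inclusion-ratio
#' shifts, and IP/input read placement with planted enriched intervals.
#' Defaults describe a small strand-specific study: two groups of three
#' replicates, mature transcripts of 1.5-3 kb, 30 bp reads, a quarter of
#' genes carrying one 100 bp binding site at four-fold enrichment.
#'
#' @slot seed integer; master RNG seed.
#' @slot n_genes number of simulated genes.
#' @slot gene_length_range bp range (min, max) of gene spans.
#' @slot exons_per_gene_range exon-count range for constitutive genes.
#' @slot n_replicates_per_group replicates per condition (default 3).
#' @slot lib_size_mean expected reads per RNA-seq library.
#' @slot nb_dispersion NB dispersion alpha in var = mu + alpha mu^2.
#' @slot frac_de fraction of genes with a planted expression change.
#' @slot de_log2fc magnitude of the planted log2 fold-change.
#' @slot frac_as_shifted fraction of events with a planted ratio shift.
#' @slot as_delta_ratio planted inclusion-ratio shift (0-1).
#' @slot as_structure_frac fraction of genes given alternative transcript
#'   structures (cycled over the ten event classes).
#' @slot junction_depth junction reads per event per sample.
#' @slot peak_fraction fraction of genes with a planted binding peak.
#' @slot peak_enrichment per-base rate multiplier inside the peak; a
#'   length-2 vector plants per-gene enrichments drawn uniformly from
#'   that range.
#' @slot peak_width_bp planted peak width.
#' @slot reads_per_gene_ip IP background reads per gene.
#' @slot reads_per_gene_input input reads per gene.
#' @slot read_length_bp RIP read length.
#' @export
setClass("SimConfig", representation(
  seed = "integer", n_genes = "integer",
  gene_length_range = "numeric", exons_per_gene_range = "numeric",
  n_replicates_per_group = "integer", lib_size_mean = "numeric",
  nb_dispersion = "numeric", frac_de = "numeric", de_log2fc = "numeric",
  frac_as_shifted = "numeric", as_delta_ratio = "numeric",
  as_structure_frac = "numeric", junction_depth = "integer",
  peak_fraction = "numeric", peak_enrichment = "numeric",
  peak_width_bp = "integer", reads_per_gene_ip = "integer",
  reads_per_gene_input = "integer", read_length_bp = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- c(frac_de = object@frac_de, frac_as_shifted = object@frac_as_shifted,
          peak_fraction = object@peak_fraction,
          as_structure_frac = object@as_structure_frac)
  bad <- names(fr)[fr < 0 | fr > 1]
  if (length(bad)) msg <- c(msg, paste("fractions outside [0,1]:",
                                       paste(bad, collapse = ", ")))
  if (object@as_delta_ratio < 0 || object@as_delta_ratio >= 1)
    msg <- c(msg, "as_delta_ratio must lie in [0,1)")
  if (diff(object@gene_length_range) < 0 || any(object@gene_length_range <= 0))
    msg <- c(msg, "gene_length_range must be positive and ordered")
  if (diff(object@exons_per_gene_range) < 0 ||
      any(object@exons_per_gene_range < 1))
    msg <- c(msg, "exons_per_gene_range must be >= 1 and ordered")
  if (object@nb_dispersion <= 0) msg <- c(msg, "nb_dispersion must be > 0")
  if (any(object@peak_enrichment <= 0) ||
      !length(object@peak_enrichment) %in% 1:2 ||
      diff(range(object@peak_enrichment)) < 0)
    msg <- c(msg, "peak_enrichment must be a positive value or ordered range")
  if (object@peak_width_bp > object@gene_length_range[1])
    msg <- c(msg, "peak_width_bp exceeds the minimum gene length")
  if (object@read_length_bp > object@gene_length_range[1])
    msg <- c(msg, "read_length_bp exceeds the minimum gene length")
  if (object@n_replicates_per_group < 2)
    msg <- c(msg, "need at least 2 replicates per group")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param seed master RNG seed (integer).
#' @param n_genes number of genes.
#' @param gene_length_range,exons_per_gene_range geometry of gene models.
#' @param n_replicates_per_group,lib_size_mean,nb_dispersion RNA-seq design.
#' @param frac_de,de_log2fc planted differential expression.
#' @param frac_as_shifted,as_delta_ratio,as_structure_frac,junction_depth
#'   planted alternative splicing.
#' @param peak_fraction,peak_enrichment,peak_width_bp,reads_per_gene_ip,
#'   reads_per_gene_input,read_length_bp planted RIP-seq binding.
#' @return A validated [SimConfig].
#' @examples
#' simConfig(seed = 1, n_genes = 20)
#' @export
simConfig <- function(seed = 1L, n_genes = 100L,
                      gene_length_range = c(1500, 3000),
                      exons_per_gene_range = c(2, 6),
                      n_replicates_per_group = 3L,
                      lib_size_mean = 2e5, nb_dispersion = 0.1,
                      frac_de = 0.1, de_log2fc = 1,
                      frac_as_shifted = 0.2, as_delta_ratio = 0.3,
                      as_structure_frac = 0.8, junction_depth = 200L,
                      peak_fraction = 0.25, peak_enrichment = 4,
                      peak_width_bp = 100L, reads_per_gene_ip = 50L,
                      reads_per_gene_input = 200L, read_length_bp = 30L) {
  new("SimConfig", seed = as.integer(seed), n_genes = as.integer(n_genes),
      gene_length_range = as.numeric(gene_length_range),
      exons_per_gene_range = as.numeric(exons_per_gene_range),
      n_replicates_per_group = as.integer(n_replicates_per_group),
      lib_size_mean = lib_size_mean, nb_dispersion = nb_dispersion,
      frac_de = frac_de, de_log2fc = de_log2fc,
      frac_as_shifted = frac_as_shifted, as_delta_ratio = as_delta_ratio,
      as_structure_frac = as_structure_frac,
      junction_depth = as.integer(junction_depth),
      peak_fraction = peak_fraction, peak_enrichment = peak_enrichment,
      peak_width_bp = as.integer(peak_width_bp),
      reads_per_gene_ip = as.integer(reads_per_gene_ip),
      reads_per_gene_input = as.integer(reads_per_gene_input),
      read_length_bp = as.integer(read_length_bp))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_genes, "genes,",
      object@n_replicates_per_group, "x2 replicates, seed", object@seed, "\n")
})
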