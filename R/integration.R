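#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether the overlap of two gene sets within a common universe is
#' larger than expected by chance: with `N` universe genes, `K` in set A,
#' `n` in set B and `x` overlapping, the upper-tail probability
#' `P[X >= x]` for `X ~ Hypergeometric(N, K, n)`.  Genes outside the
#' universe are dropped with a warning.  The test is symmetric in the two
#' sets.
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @param universe character vector, the background gene universe.
#' @return list: `universe_size`, `set_a_size`, `set_b_size`, `overlap`,
#'   `p_value`, `overlap_genes`.
#' @examples
#' hypergeomOverlap(letters[1:5], letters[1:5], letters[1:10])$p_value
#' # 1 / choose(10, 5)
#' @export
hypergeomOverlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  a <- unique(set_a); b <- unique(set_b)
  if (any(!a %in% universe) || any(!b %in% universe)) {
    warning("genes outside the universe were dropped")
    a <- a[a %in% universe]; b <- b[b %in% universe]
  }
  N <- length(universe); K <- length(a); n <- length(b)
  ov <- intersect(a, b)
  x <- length(ov)
  p <- if (x == 0) 1 else
    stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  list(universe_size = N, set_a_size = K, set_b_size = n, overlap = x,
       p_value = p, overlap_genes = sort(ov))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: `q_(i) = min_{j >= i} (m / j) p_(j)`, ties preserved
#' and the original order restored.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values in the input order.
#' @export
bhFdr <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (term, description, tab-separated genes).
#' @return named list of character vectors.
#' @export
readGMT <- function(path) fgsea::gmtPathways(path)

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-term description column (recycled).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list against a GMT collection
#'
#' One hypergeometric upper-tail test per term (term genes restricted to
#' the universe), BH-FDR across terms, ranked by p-value.
#'
#' @param genes character vector, the query gene list.
#' @param gmt named list of gene sets (see [readGMT()]).
#' @param universe character vector, the background universe.
#' @param fdr_threshold flag terms at this FDR (default 0.05).
#' @return data.frame: term, term_size, hits, p_value, fdr, significant,
#'   hit_genes (`;`-separated), ordered by p.
#' @export
ora <- function(genes, gmt, universe, fdr_threshold = 0.05) {
  if (!length(gmt)) stop("empty gene-set collection")
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  genes <- intersect(unique(genes), universe)
  rows <- lapply(names(gmt), function(term) {
    tg <- intersect(unique(gmt[[term]]), universe)
    ov <- intersect(genes, tg)
    p <- if (!length(tg) || !length(ov)) 1 else
      stats::phyper(length(ov) - 1, length(tg),
                    length(universe) - length(tg), length(genes),
                    lower.tail = FALSE)
    data.frame(term = term, term_size = length(tg), hits = length(ov),
               p_value = p, hit_genes = paste(sort(ov), collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhFdr(out$p_value)
  out$significant <- out$fdr <= fdr_threshold
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out[, c("term", "term_size", "hits", "p_value", "fdr", "significant",
          "hit_genes")]
}

#' Integrate expression, splicing and binding gene sets
#'
#' Overlaps the differentially expressed genes (DEGs) and the genes with
#' regulated splicing events (RASGs) against the peak target genes, testing
#' each overlap hypergeometrically within the supplied universe, and splits
#' the DEG overlap by direction.  Identifiers are harmonised by upper-casing
#' (or through an optional two-column ortholog map applied to the peak
#' targets first).
#'
#' @param deg_results data.frame from [nbTest()] (with `status`).
#' @param rase_results data.frame from [testRase()].
#' @param rase_genes data.frame mapping `event_id` to `gene_id` (e.g. the
#'   event table from [detectEvents()]).
#' @param peak_targets character vector of peak target genes
#'   (from [peaksToGenes()]).
#' @param universe background gene universe (recommended: all genes
#'   detected in the RNA-seq stage).
#' @param ortholog_map optional data.frame with columns `from`, `to`
#'   applied to `peak_targets`.
#' @return list with `deg_overlap` and `rasg_overlap`
#'   ([hypergeomOverlap()] results), `direction` (up/down counts within
#'   the DEG overlap) and the harmonised sets.
#' @export
integrateSets <- function(deg_results, rase_results, rase_genes,
                          peak_targets, universe, ortholog_map = NULL) {
  if (!length(universe)) stop("empty universe")
  if (!is.null(ortholog_map)) {
    m <- match(peak_targets, ortholog_map$from)
    peak_targets <- ifelse(is.na(m), peak_targets, ortholog_map$to[m])
  }
  up <- function(x) toupper(as.character(x))
  universe <- unique(up(universe))
  degs <- deg_results[deg_results$status != "ns", ]
  deg_set <- intersect(unique(up(degs$gene)), universe)
  sig_ev <- rase_results$event_id[rase_results$significant]
  rasg_set <- intersect(
    unique(up(rase_genes$gene_id[rase_genes$event_id %in% sig_ev])),
    universe)
  peak_set <- intersect(unique(up(peak_targets)), universe)
  deg_ov <- hypergeomOverlap(deg_set, peak_set, universe)
  rasg_ov <- hypergeomOverlap(rasg_set, peak_set, universe)
  ov_status <- degs$status[match(deg_ov$overlap_genes, up(degs$gene))]
  list(deg_overlap = deg_ov, rasg_overlap = rasg_ov,
       direction = c(up = sum(ov_status == "up"),
                     down = sum(ov_status == "down")),
       deg_set = deg_set, rasg_set = rasg_set, peak_set = peak_set)
}
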