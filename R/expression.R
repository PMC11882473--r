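#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across genes (restricted
#' to genes with non-zero counts in every sample) of the ratio between that
#' sample's count and the gene's geometric mean; factors are rescaled to
#' geometric mean 1.
#'
#' @param counts integer matrix, genes x samples (or a
#'   `SummarizedExperiment` with a `counts` assay).
#' @return named numeric vector of positive size factors.
#' @export
medianRatioSizeFactors <- function(counts) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no gene has non-zero counts in all samples; consider a ",
         "pseudo-reference on filtered genes")
  lg <- log(counts[ok, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, median))
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald screen for differential expression
#'
#' A minimal two-group NB screen: counts are normalised by
#' [medianRatioSizeFactors()]; the per-gene dispersion (variance =
#' mu + alpha mu^2) is estimated by method of moments on the normalised
#' counts with a floor of 1e-8; the Wald statistic on the log2 fold-change
#' (delta-method standard error from the NB variance of each group mean)
#' is referred to a Student-t distribution with `n1 + n2 - 2` degrees of
#' freedom, which keeps the type-I error near nominal at small replicate
#' numbers.  Group means carry a pseudo-count of 0.5 for fold-change
#' reporting and variance stabilisation at zero.  All-zero genes get
#' p = 1 and status `ns`.  P-values are BH-adjusted across genes.
#'
#' @param counts genes x samples matrix or `SummarizedExperiment`.
#' @param design data.frame with columns `sample` and `group` (exactly two
#'   groups, reference first unless `reference` is given).
#' @param reference the reference (denominator) group label.
#' @param fc_up,fc_down,p_threshold,use_fdr thresholds passed to
#'   [classifyDegs()].
#' @return data.frame: gene, base_mean, log2fc, p_value, fdr, status.
#' @export
nbTest <- function(counts, design, reference = NULL,
                   fc_up = 1.5, fc_down = 0.67, p_threshold = 0.05,
                   use_fdr = FALSE) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  stopifnot(all(c("sample", "group") %in% colnames(design)))
  design <- design[match(colnames(counts), design$sample), ]
  if (anyNA(design$sample)) stop("design does not cover all samples")
  grp <- unique(design$group)
  if (length(grp) != 2) stop("exactly two groups are required")
  if (!is.null(reference)) grp <- c(reference, setdiff(grp, reference))
  i1 <- which(design$group == grp[1]); i2 <- which(design$group == grp[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("need at least 2 replicates per group to estimate variance")
  sf <- medianRatioSizeFactors(counts)
  nc <- sweep(counts, 2, sf, "/")
  g1 <- nc[, i1, drop = FALSE]; g2 <- nc[, i2, drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1, var); v2 <- apply(g2, 1, var)
  mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  alpha <- pmax((pooled - mu) / mu^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8
  m1p <- m1 + 0.5; m2p <- m2 + 0.5
  lfc <- log2(m2p / m1p)
  se <- sqrt((m1p + alpha * m1p^2) / (n1 * m1p^2) +
             (m2p + alpha * m2p^2) / (n2 * m2p^2)) / log(2)
  W <- lfc / se
  p <- 2 * pt(-abs(W), df = n1 + n2 - 2)
  allzero <- rowSums(counts) == 0
  p[allzero] <- 1
  lfc[allzero] <- 0
  res <- data.frame(gene = rownames(counts), base_mean = mu, log2fc = lfc,
                    p_value = p, fdr = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  cls <- classifyDegs(res, fc_up = fc_up, fc_down = fc_down,
                      p_threshold = p_threshold, use_fdr = use_fdr)
  res$status <- "ns"
  res$status[res$gene %in% cls$up] <- "up"
  res$status[res$gene %in% cls$down] <- "down"
  res$status[allzero] <- "ns"
  res
}

#' Classify differentially expressed genes by fold-change and p thresholds
#'
#' Default thresholds: fold change above 1.5 or below 0.67 together with a
#' raw p below 0.05.  A stricter preset (two-fold change at 5% FDR) is
#' available through `fc_up = 2, fc_down = 0.5, use_fdr = TRUE`.
#'
#' @param results data.frame from [nbTest()] (columns `gene`, `log2fc`,
#'   `p_value`, `fdr`).
#' @param fc_up,fc_down fold-change thresholds on the natural scale;
#'   `fc_up` must exceed 1 and `fc_down` be below 1.
#' @param p_threshold significance threshold.
#' @param use_fdr use the BH-adjusted column instead of raw p.
#' @return list with character vectors `up` and `down` and a `counts`
#'   entry (`n_up`, `n_down`).
#' @export
classifyDegs <- function(results, fc_up = 1.5, fc_down = 0.67,
                         p_threshold = 0.05, use_fdr = FALSE) {
  if (!nrow(results)) stop("empty result table")
  if (fc_up <= 1 || fc_down >= 1)
    stop("fc_up must be > 1 and fc_down < 1")
  p <- if (use_fdr) results$fdr else results$p_value
  fc <- 2^results$log2fc
  up <- results$gene[fc > fc_up & p < p_threshold]
  down <- results$gene[fc < fc_down & p < p_threshold]
  list(up = up, down = down, counts = c(n_up = length(up),
                                        n_down = length(down)))
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((ct_target_treated - ct_ref_treated) -
#' (ct_target_control - ct_ref_control))`, i.e. target expression
#' normalised to a reference gene and to the control condition.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values (finite numerics, vectorised).
#' @return relative expression value(s).
#' @examples
#' deltaDeltaCt(20, 15, 18, 15)  # ddCt = 2 -> 0.25
#' @export
deltaDeltaCt <- function(ct_target_treated, ct_ref_treated,
                         ct_target_control, ct_ref_control) {
  stopifnot(is.finite(ct_target_treated), is.finite(ct_ref_treated),
            is.finite(ct_target_control), is.finite(ct_ref_control))
  2^-((ct_target_treated - ct_ref_treated) -
      (ct_target_control - ct_ref_control))
}

#' Cell proliferation rate from CCK-8 optical densities
#'
#' `(od_exp - od_blank) / (od_control - od_blank) * 100`, in percent.
#'
#' @param od_exp,od_control,od_blank optical densities of the treated
#'   wells, control wells and cell-free blanks.
#' @return proliferation rate in percent.
#' @examples
#' proliferationRate(0.45, 0.80, 0.10)  # 50
#' @export
proliferationRate <- function(od_exp, od_control, od_blank) {
  if (any(od_control <= od_blank))
    stop("control OD must exceed blank OD")
  (od_exp - od_blank) / (od_control - od_blank) * 100
}
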