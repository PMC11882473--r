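#' Write / read tabular pipeline artifacts
#'
#' Plain TSV readers and writers for count matrices (gene_id, exon_length,
#' one column per sample), design tables (sample, group) and generic
#' data.frames.  All output is deterministic (no timestamps, fixed column
#' order), so reruns with one seed are byte-identical.
#'
#' @param x object to write.
#' @param path file path.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writeTSV <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readTSV <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname pipeline-io
#' @export
writeCountsTSV <- function(x, path) {
  cts <- SummarizedExperiment::assay(x, "counts")
  df <- data.frame(gene_id = rownames(cts),
                   exon_length = SummarizedExperiment::rowData(x)$exon_length,
                   cts, check.names = FALSE)
  writeTSV(df, path)
}

#' @rdname pipeline-io
#' @export
readCountsTSV <- function(path) {
  df <- readTSV(path)
  cts <- as.matrix(df[, setdiff(colnames(df), c("gene_id", "exon_length")),
                      drop = FALSE])
  rownames(cts) <- df$gene_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cts),
    rowData = DataFrame(gene_id = df$gene_id,
                        exon_length = df$exon_length),
    colData = DataFrame(sample = colnames(cts),
                        total_mapped = colSums(cts)))
}

#' Generate a complete synthetic study on disk
#'
#' Runs every simulator stage of a [SimConfig] and writes the standard
#' file formats the pipeline consumes: `annotation.gtf`, `counts.tsv`,
#' `design.tsv`, `junctions.tsv`, `boundaries.tsv`, `ip.bed` /
#' `input.bed` (BED12), `reads.fastq`, and the planted-truth tables
#' (`truth_*.tsv`).
#'
#' @param config A [SimConfig].
#' @param outdir output directory (created).
#' @return named list of file paths, invisibly; the in-memory objects are
#'   returned in the `objects` element.
#' @export
simulateStudy <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  anno <- simulateAnnotation(config)
  writeGTF(anno, p("annotation.gtf"))
  cm <- simulateCounts(anno, config)
  writeCountsTSV(cm$counts, p("counts.tsv"))
  writeTSV(data.frame(
    sample = SummarizedExperiment::colData(cm$counts)$sample,
    group = SummarizedExperiment::colData(cm$counts)$group), p("design.tsv"))
  writeTSV(cm$truth, p("truth_de.tsv"))
  jx <- simulateJunctions(anno, config)
  writeTSV(jx$junctions, p("junctions.tsv"))
  writeTSV(jx$boundaries, p("boundaries.tsv"))
  writeTSV(jx$truth, p("truth_as.tsv"))
  rip <- simulateRipReads(anno, config)
  writeBED12(rip$ip, p("ip.bed"))
  writeBED12(rip$input, p("input.bed"))
  writeTSV(rip$truth, p("truth_peaks.tsv"))
  rr <- simulateRawReads(n_reads = 50, seed = config@seed)
  writeFASTQ(rr$reads, p("reads.fastq"))
  writeTSV(rr$truth, p("truth_reads.tsv"))
  files <- list(gtf = p("annotation.gtf"), counts = p("counts.tsv"),
                design = p("design.tsv"), junctions = p("junctions.tsv"),
                boundaries = p("boundaries.tsv"), ip_bed = p("ip.bed"),
                input_bed = p("input.bed"), fastq = p("reads.fastq"),
                truth_de = p("truth_de.tsv"), truth_as = p("truth_as.tsv"),
                truth_peaks = p("truth_peaks.tsv"),
                truth_reads = p("truth_reads.tsv"))
  invisible(c(files, list(objects = list(annotation = anno, counts = cm,
                                         junctions = jx, rip = rip,
                                         raw = rr))))
}

#' Resolve a run configuration
#'
#' Merges user settings (a named list, or a YAML file path) over the
#' documented defaults and validates threshold ranges.
#'
#' @param config named list or YAML file path.
#' @return validated configuration list.
#' @export
runConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    gtf = NULL, counts = NULL, design = NULL, junctions = NULL,
    boundaries = NULL, ip_bed = NULL, input_bed = NULL, fastq = NULL,
    gmt = NULL, outdir = "ripintegrate_out", seed = 1L,
    stranded = "forward",
    qc_max_n = 2, qc_min_len = 16,
    deg_fc_up = 1.5, deg_fc_down = 0.67, deg_p = 0.05, deg_use_fdr = FALSE,
    rase_fdr = 0.05, rase_min_cov = 10,
    peak_window = 5, peak_step = 5, peak_start_factor = 2.5,
    peak_run_len = 8, peak_median_floor = 50, peak_end_fraction = 0.04,
    peak_shuffles = 500, peak_p = 0.05, peak_min_depth = 10,
    peak_fold = 4, peak_pseudo = 1)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$deg_p > 0, cfg$deg_p <= 1, cfg$rase_fdr > 0,
            cfg$rase_fdr <= 1, cfg$peak_p > 0, cfg$peak_p <= 1,
            cfg$peak_fold > 0, cfg$peak_shuffles >= 1)
  cfg
}

#' Run the full integrative pipeline
#'
#' Executes, in order: raw-read QC (when a FASTQ is given), expression
#' (counts + FPKM + NB differential-expression screen), splicing (event
#' detection, quantification and ratio testing), peak calling (window scan,
#' permutation null, enrichment filter) and integration (set overlaps, and
#' over-representation when a GMT is given).  Every stage writes TSV/BED
#' outputs under `outdir` and a `manifest.json` echoing the resolved
#' configuration; reruns with the same seed are byte-identical.
#'
#' @param config list or YAML path, see [runConfig()].  Required entries:
#'   `gtf`, `counts`, `design`, `junctions`, `ip_bed`, `input_bed`.
#' @return invisible list of stage results.
#' @export
runAll <- function(config) {
  cfg <- runConfig(config)
  for (key in c("gtf", "counts", "design", "junctions", "ip_bed",
                "input_bed")) {
    if (is.null(cfg[[key]])) stop("missing required input: ", key)
    if (!file.exists(cfg[[key]]))
      stop("input file for '", key, "' not found: ", cfg[[key]])
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  manifest <- list(package = "ripintegrate",
                   version = as.character(utils::packageVersion("ripintegrate")),
                   config = cfg[!vapply(cfg, is.null, TRUE)], stages = list())

  ## 1. preprocess: QC + counts + FPKM
  res_pre <- stage("preprocess", function() {
    qc <- NULL
    if (!is.null(cfg$fastq)) {
      fq <- filterRawReads(readFASTQ(cfg$fastq), max_n = cfg$qc_max_n,
                           min_len = cfg$qc_min_len)
      writeTSV(fq$report, out("qc_report.tsv"))
      qc <- fq$report
    }
    anno <- readGTF(cfg$gtf)
    se <- readCountsTSV(cfg$counts)
    fpkm <- computeFpkm(se)
    writeTSV(data.frame(gene_id = rownames(fpkm), fpkm, check.names = FALSE),
             out("fpkm.tsv"))
    list(qc = qc, annotation = anno, counts = se)
  })
  manifest$stages$preprocess <- list(
    genes = nrow(res_pre$counts), samples = ncol(res_pre$counts),
    qc = res_pre$qc, outputs = c("fpkm.tsv",
      if (!is.null(res_pre$qc)) "qc_report.tsv"))

  ## 2. expression
  design <- readTSV(cfg$design)
  res_deg <- stage("expression", function() {
    deg <- nbTest(res_pre$counts, design, fc_up = cfg$deg_fc_up,
                  fc_down = cfg$deg_fc_down, p_threshold = cfg$deg_p,
                  use_fdr = cfg$deg_use_fdr)
    writeTSV(deg, out("deg.tsv"))
    deg
  })
  manifest$stages$expression <- list(
    tested = nrow(res_deg), up = sum(res_deg$status == "up"),
    down = sum(res_deg$status == "down"), outputs = "deg.tsv")

  ## 3. splicing
  res_spl <- stage("splicing", function() {
    anno <- res_pre$annotation
    jx <- data.table::as.data.table(readTSV(cfg$junctions))
    bd <- if (!is.null(cfg$boundaries))
      data.table::as.data.table(readTSV(cfg$boundaries)) else NULL
    ev <- detectEvents(anno, jx, bd)
    qu <- quantifyEvents(ev, jx, bd, min_cov = cfg$rase_min_cov)
    ra <- testRase(qu, design, fdr_threshold = cfg$rase_fdr)
    writeTSV(ev, out("events.tsv"))
    writeTSV(qu, out("event_quant.tsv"))
    writeTSV(ra, out("rase.tsv"))
    list(events = ev, quants = qu, rase = ra)
  })
  manifest$stages$splicing <- list(
    events = nrow(res_spl$events),
    significant = sum(res_spl$rase$significant),
    outputs = c("events.tsv", "event_quant.tsv", "rase.tsv"))

  ## 4. peak calling
  res_pk <- stage("peakcalling", function() {
    ip <- readBED12(cfg$ip_bed, sample_id = "IP")
    inp <- readBED12(cfg$input_bed, sample_id = "Input")
    cand <- callPeaks(ip, inp, res_pre$annotation,
                      window = cfg$peak_window, step = cfg$peak_step,
                      start_factor = cfg$peak_start_factor,
                      run_len = cfg$peak_run_len,
                      median_floor = cfg$peak_median_floor,
                      end_fraction = cfg$peak_end_fraction,
                      n_shuffles = cfg$peak_shuffles,
                      seed = childSeed(cfg$seed, "peakcalling"),
                      pseudo = cfg$peak_pseudo)
    final <- filterPeaks(cand, p_threshold = cfg$peak_p,
                         min_max_depth = cfg$peak_min_depth,
                         fold = cfg$peak_fold)
    writeTSV(as.data.frame(cand), out("peak_candidates.tsv"))
    writePeaksBED(final, out("peaks.bed"))
    list(candidates = cand, final = final,
         targets = peaksToGenes(final))
  })
  manifest$stages$peakcalling <- list(
    candidates = length(res_pk$candidates), final = length(res_pk$final),
    target_genes = length(res_pk$targets$genes),
    outputs = c("peak_candidates.tsv", "peaks.bed"))

  ## 5. integration
  res_int <- stage("integration", function() {
    universe <- rownames(res_pre$counts)[
      rowSums(SummarizedExperiment::assay(res_pre$counts, "counts")) > 0]
    ig <- integrateSets(res_deg, res_spl$rase, res_spl$events,
                        res_pk$targets$genes, universe)
    writeTSV(data.frame(
      comparison = c("DEG_vs_peaks", "RASG_vs_peaks"),
      universe = c(ig$deg_overlap$universe_size,
                   ig$rasg_overlap$universe_size),
      set_a = c(ig$deg_overlap$set_a_size, ig$rasg_overlap$set_a_size),
      set_b = c(ig$deg_overlap$set_b_size, ig$rasg_overlap$set_b_size),
      overlap = c(ig$deg_overlap$overlap, ig$rasg_overlap$overlap),
      p_value = c(ig$deg_overlap$p_value, ig$rasg_overlap$p_value)),
      out("integration.tsv"))
    writeLines(ig$deg_overlap$overlap_genes, out("deg_peak_genes.txt"))
    writeLines(ig$rasg_overlap$overlap_genes, out("rasg_peak_genes.txt"))
    enr <- NULL
    if (!is.null(cfg$gmt)) {
      enr <- ora(ig$deg_overlap$overlap_genes, readGMT(cfg$gmt), universe)
      writeTSV(enr, out("enrichment.tsv"))
    }
    list(integration = ig, enrichment = enr)
  })
  ig <- res_int$integration
  manifest$stages$integration <- list(
    deg_overlap = ig$deg_overlap$overlap,
    deg_overlap_p = ig$deg_overlap$p_value,
    rasg_overlap = ig$rasg_overlap$overlap,
    rasg_overlap_p = ig$rasg_overlap$p_value,
    direction = as.list(ig$direction),
    outputs = c("integration.tsv", "deg_peak_genes.txt",
                "rasg_peak_genes.txt", if (!is.null(cfg$gmt)) "enrichment.tsv"))

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(preprocess = res_pre, expression = res_deg,
                 splicing = res_spl, peakcalling = res_pk,
                 integration = res_int, manifest = manifest))
}
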