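test_that("fixed seed gives byte-identical annotation, counts and reads", {
  cfg <- simConfig(seed = 4, n_genes = 15)
  f1 <- tempfile(); f2 <- tempfile()
  writeGTF(simulateAnnotation(cfg), f1)
  writeGTF(simulateAnnotation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  anno <- simulateAnnotation(cfg)
  c1 <- simulateCounts(anno, cfg); c2 <- simulateCounts(anno, cfg)
  expect_identical(SummarizedExperiment::assay(c1$counts),
                   SummarizedExperiment::assay(c2$counts))

  r1 <- simulateRipReads(anno, cfg); r2 <- simulateRipReads(anno, cfg)
  b1 <- tempfile(); b2 <- tempfile()
  writeBED12(r1$ip, b1); writeBED12(r2$ip, b2)
  expect_identical(readLines(b1), readLines(b2))
})

test_that("single-exon genes yield no junctions and no events", {
  cfg <- simConfig(seed = 5, n_genes = 10, exons_per_gene_range = c(1, 1),
                   as_structure_frac = 0)
  anno <- simulateAnnotation(cfg)
  expect_equal(nrow(annotatedJunctions(anno)), 0)
  jx <- simulateJunctions(anno, cfg)
  expect_equal(nrow(jx$truth), 0)
})

test_that("full alternative-structure config realises all ten event classes,
           as verified by the classifier", {
  cfg <- simConfig(seed = 6, n_genes = 40, as_structure_frac = 1)
  anno <- simulateAnnotation(cfg)
  jx <- simulateJunctions(anno, cfg)
  ev <- detectEvents(anno, jx$junctions, jx$boundaries)
  expect_setequal(unique(ev$type),
                  c("ES", "cassetteExon", "A5SS", "A3SS", "MXE", "5pMXE",
                    "3pMXE", "IntronR", "A5SS&ES", "A3SS&ES"))
  # one planted event per gene, classified to the planted type
  m <- merge(ev[, c("gene_id", "type")], jx$truth[, c("gene_id", "type")],
             by = "gene_id")
  expect_true(all(m$type.x == m$type.y))
})

test_that("count generator is NB with the configured mean-dispersion form", {
  anno <- simulateAnnotation(simConfig(seed = 7, n_genes = 400,
                                       as_structure_frac = 0))
  # near-zero dispersion: Poisson limit, variance close to mean
  cfgP <- simConfig(seed = 7, n_genes = 400, nb_dispersion = 1e-6,
                    frac_de = 0, n_replicates_per_group = 50L,
                    lib_size_mean = 4e5)
  cts <- SummarizedExperiment::assay(simulateCounts(anno, cfgP)$counts)
  nc <- sweep(cts, 2, medianRatioSizeFactors(cts), "/")
  mu <- rowMeans(nc); v <- apply(nc, 1, var)
  keep <- mu > 50
  expect_lt(median(abs(v[keep] / mu[keep] - 1)), 0.25)

  # null config: group means agree within sampling noise (3 SE for >=93%)
  cfg0 <- simConfig(seed = 8, n_genes = 400, frac_de = 0,
                    n_replicates_per_group = 10L, lib_size_mean = 4e5,
                    nb_dispersion = 0.05)
  sim <- simulateCounts(anno, cfg0)
  cts <- SummarizedExperiment::assay(sim$counts)
  g1 <- cts[, 1:10]; g2 <- cts[, 11:20]
  se <- sqrt(apply(g1, 1, var) / 10 + apply(g2, 1, var) / 10)
  z <- abs(rowMeans(g1) - rowMeans(g2)) / pmax(se, 1e-9)
  expect_gt(mean(z[rowMeans(cts) > 5] < 3), 0.93)
})

test_that("junction generator recovers planted inclusion-ratio shifts", {
  cfg <- simConfig(seed = 9, n_genes = 100, as_structure_frac = 1,
                   frac_as_shifted = 0.5, as_delta_ratio = 0.3,
                   junction_depth = 200L)
  anno <- simulateAnnotation(cfg)
  jx <- simulateJunctions(anno, cfg)
  ev <- detectEvents(anno, jx$junctions, jx$boundaries)
  qu <- quantifyEvents(ev, jx$junctions, jx$boundaries)
  ra <- testRase(qu, toyDesign())
  m <- merge(merge(ra, ev[, c("event_id", "gene_id")], by = "event_id"),
             jx$truth, by = "gene_id")
  shifted <- m[m$shifted, ]
  # estimated |shift| within 0.05 of planted 0.3 for >= 90% of events
  expect_gt(mean(abs(abs(shifted$delta_ratio) - 0.3) <= 0.05), 0.9)
  # null events: small estimated shifts
  expect_lt(median(abs(m$delta_ratio[!m$shifted])), 0.05)
})

test_that("a planted interval at 8x enrichment shows an 8x-ish depth contrast", {
  cfg <- simConfig(seed = 10, n_genes = 6, as_structure_frac = 0,
                   gene_length_range = c(2000, 2000), peak_fraction = 1,
                   peak_enrichment = 8, reads_per_gene_ip = 2000L)
  anno <- simulateAnnotation(cfg)
  rip <- simulateRipReads(anno, cfg)
  g <- genes(anno)
  ratios <- vapply(seq_len(nrow(rip$truth)), function(i) {
    gid <- rip$truth$gene_id[i]
    k <- which(S4Vectors::mcols(g)$gene_id == gid)
    gr <- rip$ip[GenomicRanges::findOverlaps(rip$ip, g[k],
      select = "first", ignore.strand = TRUE) == 1 &
      !is.na(GenomicRanges::findOverlaps(rip$ip, g[k], select = "first",
                                         ignore.strand = TRUE))]
    d <- as.numeric(IRanges::coverage(
      IRanges::IRanges(pmax(GenomicRanges::start(gr), GenomicRanges::start(g)[k]) -
                         GenomicRanges::start(g)[k] + 1L,
                       pmin(GenomicRanges::end(gr), GenomicRanges::end(g)[k]) -
                         GenomicRanges::start(g)[k] + 1L),
      width = GenomicRanges::width(g)[k]))
    lo <- rip$truth$peak_start[i] - GenomicRanges::start(g)[k] + 2L
    hi <- rip$truth$peak_end[i] - GenomicRanges::start(g)[k] + 1L
    mean(d[lo:hi]) / mean(d[-(lo:hi)])
  }, 1)
  expect_true(all(ratios > 6 & ratios < 10))
})

test_that("peak-free IP placement is indistinguishable from input placement", {
  cfg <- simConfig(seed = 12, n_genes = 50, as_structure_frac = 0,
                   peak_fraction = 0, reads_per_gene_ip = 200L,
                   reads_per_gene_input = 200L)
  anno <- simulateAnnotation(cfg)
  rip <- simulateRipReads(anno, cfg)
  ks <- suppressWarnings(
    ks.test(GenomicRanges::start(rip$ip), GenomicRanges::start(rip$input)))
  expect_gt(ks$p.value, 0.01)
})

test_that("raw-read generator labels the QC fixture correctly", {
  rr <- simulateRawReads(lengths = c(150, 150, 15, 150, 150),
                         n_counts = c(0, 3, 0, 2, 0))
  expect_equal(sum(rr$truth$keep), 3)
  # empty config gives an empty but valid FASTQ
  r0 <- simulateRawReads(lengths = integer(), n_counts = integer())
  fq <- tempfile(fileext = ".fastq")
  writeFASTQ(r0$reads, fq)
  expect_equal(length(readFASTQ(fq)), 0)
})

test_that("generated GTF round-trips without loss", {
  cfg <- simConfig(seed = 13, n_genes = 25)
  anno <- simulateAnnotation(cfg)
  f <- tempfile(fileext = ".gtf")
  writeGTF(anno, f)
  back <- readGTF(f)
  expect_equal(length(genes(back)), length(genes(anno)))
  expect_equal(length(exons(back)), length(exons(anno)))
  expect_setequal(
    unique(S4Vectors::mcols(exons(back))$transcript_id),
    unique(S4Vectors::mcols(exons(anno))$transcript_id))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(frac_de = 1.5), "fractions")
  expect_error(simConfig(gene_length_range = c(3000, 1500)), "ordered")
  expect_error(simConfig(peak_width_bp = 5000), "gene length")
  expect_error(simConfig(nb_dispersion = 0), "nb_dispersion")
})
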