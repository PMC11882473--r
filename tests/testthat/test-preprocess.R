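test_that("raw-read filter applies the N rule first, then the length rule", {
  reads <- Biostrings::DNAStringSet(c(
    a = paste(rep("A", 150), collapse = ""),
    b = paste(c(rep("A", 147), "N", "N", "N"), collapse = ""),   # 3 Ns
    c = paste(rep("C", 15), collapse = ""),                      # short
    d = paste(c(rep("G", 148), "N", "N"), collapse = ""),        # 2 Ns ok
    e = paste(c(rep("T", 10), "N", "N", "N"), collapse = "")))   # short AND 3N
  out <- filterRawReads(reads)
  expect_setequal(names(out$kept), c("a", "d"))
  # N rule consumes read e before the length rule sees it
  expect_equal(out$report$dropped_n, 2)
  expect_equal(out$report$dropped_short, 1)
})

test_that("the five-read simulator fixture keeps exactly three reads", {
  rr <- simulateRawReads(lengths = c(150, 150, 15, 150, 150),
                         n_counts = c(0, 3, 0, 2, 0))
  out <- filterRawReads(rr$reads)
  expect_equal(out$report$kept, 3)
  expect_setequal(names(out$kept), rr$truth$name[rr$truth$keep])
})

test_that("gene counting follows the uniqueness, strand and ambiguity rules", {
  anno <- toyEsAnnotation()
  reads <- alignedReads(
    chrom = "chrT",
    strand = c("+", "+", "-", "+"),
    blocks = list(cbind(120, 149),          # inside exon 1 -> TG1
                  cbind(120, 149),          # multimapped -> nowhere
                  cbind(120, 149),          # wrong strand -> nowhere
                  cbind(650, 679)),         # outside gene -> nowhere
    unique = c(TRUE, FALSE, TRUE, TRUE))
  se <- countGenes(reads, anno, stranded = "forward")
  expect_equal(unname(SummarizedExperiment::assay(se)["TG1", 1]), 1L)
  # spliced read whose blocks both intersect the exon union counts once
  spl <- alignedReads("chrT", "+", list(cbind(c(180, 301), c(200, 320))))
  se2 <- countGenes(spl, anno)
  expect_equal(unname(SummarizedExperiment::assay(se2)["TG1", 1]), 1L)
  # a read with one block in an intron is incompatible
  intr <- alignedReads("chrT", "+", list(cbind(c(180, 220), c(200, 240))))
  se3 <- countGenes(intr, anno)
  expect_equal(unname(SummarizedExperiment::assay(se3)["TG1", 1]), 0L)
})

test_that("reads compatible with two genes are counted for neither", {
  anno <- toyOverlapAnnotation()
  reads <- alignedReads("chrT", "+", list(cbind(200, 229), cbind(310, 339)))
  se <- countGenes(reads, anno)
  cts <- SummarizedExperiment::assay(se)
  expect_equal(unname(cts["OV1", 1]), 0L)   # read 1 hits both genes
  expect_equal(unname(cts["OV2", 1]), 1L)   # read 2 only hits OV2
  expect_equal(SummarizedExperiment::colData(se)$ambiguous, 1L)
})

test_that("alignments on unknown chromosomes are skipped with a warning", {
  anno <- toyEsAnnotation()
  reads <- alignedReads(c("chrT", "chrX"), "+",
                        list(cbind(120, 149), cbind(120, 149)))
  expect_warning(se <- countGenes(reads, anno), "absent from the annotation")
  expect_equal(SummarizedExperiment::colData(se)$skipped_chrom, 1L)
})

test_that("gene counting agrees with the brute-force oracle on random
           instances", {
  cfg <- simConfig(seed = 20, n_genes = 20, as_structure_frac = 0.5)
  anno <- simulateAnnotation(cfg)
  g <- genes(anno)
  set.seed(21)
  n <- 500
  gi <- sample(length(g), n, replace = TRUE)
  starts <- GenomicRanges::start(g)[gi] +
    floor(runif(n) * (GenomicRanges::width(g)[gi] - 60))
  blocks <- lapply(seq_len(n), function(i) {
    if (runif(1) < 0.3)
      cbind(c(starts[i], starts[i] + 100), c(starts[i] + 29, starts[i] + 129))
    else cbind(starts[i], starts[i] + 49)
  })
  reads <- alignedReads("chrS", sample(c("+", "-"), n, TRUE), blocks,
                        unique = runif(n) > 0.1)
  se <- countGenes(reads, anno, stranded = "forward")
  ref <- refCountGenes(reads, anno, stranded = TRUE)
  expect_equal(unname(SummarizedExperiment::assay(se)[, 1]),
               unname(ref$counts))
  expect_equal(SummarizedExperiment::colData(se)$ambiguous[1], ref$ambiguous)
  # column sum never exceeds the number of kept unique alignments
  expect_lte(sum(SummarizedExperiment::assay(se)),
             sum(S4Vectors::mcols(reads)$unique))
})

test_that("FPKM follows its closed form and scaling identities", {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = matrix(c(10, 0), 2, 1,
                                  dimnames = list(c("G1", "G2"), "s1"))),
    rowData = S4Vectors::DataFrame(exon_length = c(1000L, 500L)),
    colData = S4Vectors::DataFrame(total_mapped = 1e6))
  f <- computeFpkm(se)
  expect_equal(unname(f["G1", 1]), 10)
  expect_equal(unname(f["G2", 1]), 0)
  # doubling the total halves every FPKM
  SummarizedExperiment::colData(se)$total_mapped <- 2e6
  expect_equal(unname(computeFpkm(se)["G1", 1]), 5)
  # permuting genes permutes rows identically
  se2 <- se[c(2, 1), ]
  expect_equal(computeFpkm(se2), computeFpkm(se)[c(2, 1), , drop = FALSE])
  # zero length or zero total are refused with the culprit named
  SummarizedExperiment::rowData(se)$exon_length <- c(0L, 500L)
  expect_error(computeFpkm(se), "G1")
})
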