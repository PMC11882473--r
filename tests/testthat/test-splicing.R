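test_that("junction extraction enumerates block gaps of unique reads", {
  # blocks [100,150) and [200,250) in half-open coordinates
  r <- alignedReads("chrT", "+", list(cbind(c(101, 201), c(150, 250))))
  jx <- extractJunctions(r)
  expect_equal(jx$donor, 150L)
  expect_equal(jx$acceptor, 200L)
  expect_equal(jx$sample1, 1L)
  # three blocks give two junctions; single-block reads give none
  r3 <- alignedReads("chrT", "+",
                     list(cbind(c(1, 101, 201), c(50, 150, 250)),
                          cbind(301, 350)))
  expect_equal(nrow(extractJunctions(r3)), 2)
  # random instances agree with per-read brute force
  cfg <- simConfig(seed = 40, n_genes = 10)
  anno <- simulateAnnotation(cfg)
  set.seed(41)
  n <- 300
  blocks <- lapply(1:n, function(i) {
    s <- sample(1e4, 1)
    k <- sample(1:3, 1)
    st <- s + cumsum(c(0, rep(150, k - 1)))
    cbind(st, st + 29)
  })
  reads <- alignedReads("chrS", sample(c("+", "-"), n, TRUE), blocks,
                        unique = runif(n) > 0.2)
  jx <- extractJunctions(reads)
  ref <- refJunctions(reads)
  expect_equal(nrow(jx), length(ref))
  for (i in seq_len(nrow(jx))) {
    key <- paste(jx$chrom[i], jx$strand[i], jx$donor[i], jx$acceptor[i])
    expect_equal(unname(jx$sample1[i]), ref[[key]])
  }
})

test_that("exon skipping is detected from the three-junction pattern", {
  anno <- toyEsAnnotation()
  jx <- toyJunctionTable(c("200:300", "400:500", "200:500"),
                         matrix(10, 3, 1, dimnames = list(NULL, "s1")))
  ev <- detectEvents(anno, jx)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "ES")
  expect_equal(ev$alt_start, 300L)
  expect_equal(ev$alt_end, 400L)
  expect_setequal(strsplit(ev$inclusion_keys, ";")[[1]],
                  c("200:300", "400:500"))
  expect_equal(ev$exclusion_keys, "200:500")
  expect_false(ev$novel)
})

test_that("alternative 5' splice sites are named strand-aware", {
  g <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 600), "+",
                              gene_id = "AG1", symbol = "AG1")
  e <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(1, 301, 1, 301), c(150, 400, 130, 400)), "+",
    gene_id = "AG1",
    transcript_id = c("AG1.T1", "AG1.T1", "AG1.T2", "AG1.T2"))
  anno <- GenomeAnnotation(genes = g, exons = e)
  jx <- toyJunctionTable(c("150:300", "130:300"),
                         matrix(c(12, 8), 2, 1,
                                dimnames = list(NULL, "s1")))
  ev <- detectEvents(anno, jx)
  expect_equal(ev$type, "A5SS")
  expect_equal(c(ev$alt_start, ev$alt_end), c(130L, 150L))
  # same geometry on the minus strand is an alternative 3' site
  GenomicRanges::strand(g) <- "-"
  GenomicRanges::strand(e) <- "-"
  anno2 <- GenomeAnnotation(genes = g, exons = e)
  jx2 <- toyJunctionTable(c("150:300", "130:300"),
                          matrix(c(12, 8), 2, 1,
                                 dimnames = list(NULL, "s1")),
                          strand = "-")
  expect_equal(detectEvents(anno2, jx2)$type, "A3SS")
})

test_that("a single-junction gene with no alternatives yields no events", {
  g <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 500), "+",
                              gene_id = "SG", symbol = "SG")
  e <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(1, 301), c(150, 500)),
                              "+", gene_id = "SG",
                              transcript_id = "SG.T1")
  anno <- GenomeAnnotation(genes = g, exons = e)
  jx <- toyJunctionTable("150:300", matrix(20, 1, 1,
                                           dimnames = list(NULL, "s1")))
  expect_equal(nrow(detectEvents(anno, jx)), 0)
})

test_that("event detection is order-independent and keeps strata disjoint", {
  cfg <- simConfig(seed = 42, n_genes = 30, as_structure_frac = 1)
  anno <- simulateAnnotation(cfg)
  jx <- simulateJunctions(anno, cfg)
  ev1 <- detectEvents(anno, jx$junctions, jx$boundaries)
  shuf <- jx$junctions[sample(nrow(jx$junctions)), ]
  ev2 <- detectEvents(anno, shuf, jx$boundaries)
  expect_equal(ev1, ev2)
  # no junction key is claimed as exclusion evidence by two event classes
  exc <- unlist(lapply(seq_len(nrow(ev1)), function(i)
    paste(ev1$gene_id[i], strsplit(ev1$exclusion_keys[i], ";")[[1]])))
  expect_false(anyDuplicated(exc) > 0)
  # one event per gene here: total equals the sum over type strata
  expect_equal(nrow(ev1), sum(table(ev1$type)))
})

test_that("quantification computes inclusion ratios with a coverage floor", {
  ev <- data.frame(event_id = "E1", gene_id = "G", chrom = "chrT",
                   strand = "+", type = "ES",
                   inclusion_keys = "200:300;400:500",
                   exclusion_keys = "200:500",
                   alt_start = 300L, alt_end = 400L, novel = FALSE)
  jx <- toyJunctionTable(c("200:300", "400:500", "200:500"),
    matrix(c(4, 6, 10,   12, 8, 0,   2, 1, 4), 3, 3,
           dimnames = list(NULL, c("s1", "s2", "s3"))))
  q <- quantifyEvents(ev, jx)
  expect_equal(q$ratio[q$sample == "s1"], 0.5)       # 10 vs 10
  expect_equal(q$ratio[q$sample == "s2"], 1.0)       # exc = 0, inc 20
  expect_true(is.na(q$ratio[q$sample == "s3"]))      # 7 reads < min_cov
  expect_false(q$defined[q$sample == "s3"])
})

test_that("the ratio t-test matches its closed form and its invariances", {
  q <- do.call(rbind, lapply(1:6, function(i) data.frame(
    event_id = "E1", sample = toyDesign()$sample[i], inclusion = 100,
    exclusion = 100,
    ratio = c(0.80, 0.82, 0.78, 0.50, 0.52, 0.48)[i], defined = TRUE)))
  ra <- testRase(q, toyDesign())
  r1 <- c(0.80, 0.82, 0.78); r2 <- c(0.50, 0.52, 0.48)
  sp <- sqrt((2 * var(r1) + 2 * var(r2)) / 4)
  tstat <- (mean(r1) - mean(r2)) / (sp * sqrt(2 / 3))
  expect_equal(ra$p_value, 2 * pt(-abs(tstat), df = 4))
  expect_lt(ra$p_value, 0.001)
  expect_equal(ra$delta_ratio, -0.3)
  # swapping the group roles flips the sign of delta and preserves p
  ds <- toyDesign()[c(4:6, 1:3), ]
  ra2 <- testRase(q, ds)
  expect_equal(ra2$delta_ratio, 0.3)
  expect_equal(ra2$p_value, ra$p_value)
  # degenerate cases
  qq <- q; qq$ratio <- rep(0.5, 6)
  expect_equal(testRase(qq, toyDesign())$p_value, 1)
  qq$ratio <- rep(c(0.2, 0.8), each = 3)
  rd <- testRase(qq, toyDesign())
  expect_equal(rd$p_value, 0)
  expect_true(rd$degenerate)
})

test_that("planted ratio shifts are recalled and nulls controlled at 5% FDR", {
  cfg <- simConfig(seed = 43, n_genes = 150, as_structure_frac = 1,
                   frac_as_shifted = 0.3, as_delta_ratio = 0.3,
                   junction_depth = 200L)
  anno <- simulateAnnotation(cfg)
  jx <- simulateJunctions(anno, cfg)
  ev <- detectEvents(anno, jx$junctions, jx$boundaries)
  qu <- quantifyEvents(ev, jx$junctions, jx$boundaries)
  ra <- testRase(qu, toyDesign())
  expect_true(all(qu$ratio >= 0 & qu$ratio <= 1, na.rm = TRUE))
  m <- merge(merge(ra, ev[, c("event_id", "gene_id")], by = "event_id"),
             jx$truth, by = "gene_id")
  expect_gt(mean(m$significant[m$shifted]), 0.8)
  expect_lt(mean(m$significant[!m$shifted]), 0.07)
})
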