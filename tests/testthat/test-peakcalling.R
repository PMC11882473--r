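test_that("window depths are means with a kept trailing partial window", {
  expect_equal(windowDepths(rep(3, 20)), rep(3, 4))
  expect_equal(windowDepths(c(rep(1, 5), rep(9, 5))), c(1, 9))
  # trailing partial window keeps its actual width
  expect_equal(windowDepths(c(rep(2, 5), rep(8, 3))), c(2, 8))
  expect_length(windowDepths(rep(0, 23)), ceiling(23 / 5))
  expect_length(windowDepths(numeric()), 0)
})

test_that("peak assembly obeys the opening and closing run rules", {
  # flat track at background: no candidates
  expect_equal(nrow(assemblePeaks(rep(2, 100), 2)), 0)
  # plateau of 20 qualifying windows over background 2 -> one candidate
  w <- rep(2, 200); w[81:100] <- 60; w[101:200] <- 0
  out <- assemblePeaks(w, 2)
  expect_equal(nrow(out), 1)
  expect_lte(out$start_win, 81)
  expect_gte(out$end_win, 100)
  expect_equal(out$max_window_depth, 60)
  # only run_len - 1 qualifying windows and median below the floor: nothing
  w2 <- rep(0, 100); w2[50:56] <- 40
  expect_equal(nrow(assemblePeaks(w2, 2, median_floor = 50)), 0)
  # but the median-floor route alone can open a peak
  w3 <- rep(0, 100); w3[50:57] <- 60
  expect_equal(nrow(assemblePeaks(w3, 1e9, median_floor = 50)), 1)
})

test_that("peak assembly matches the exhaustive run-enumeration reference", {
  set.seed(50)
  for (k in 1:80) {
    L <- sample(100:2000, 1)
    n <- sample(5:80, 1)
    starts <- sample.int(L, n, replace = TRUE)
    depth <- as.numeric(IRanges::coverage(
      IRanges::IRanges(starts, width = pmin(30, L - starts + 1)), width = L))
    w <- windowDepths(depth)
    a <- assemblePeaks(w, mean(depth))
    b <- refAssemblePeaks(w, mean(depth))
    am <- unname(as.matrix(a[, c("start_win", "end_win")]))
    storage.mode(am) <- "numeric"
    expect_equal(am, unname(b), info = paste("track", k))
  }
})

test_that("the permutation p-value respects the add-one convention and the
           seed", {
  p1 <- permutationTest(1e9, rep(30L, 50), 1000L, seed = 3)
  expect_equal(p1$p, 1 / 501)
  p0 <- permutationTest(0, rep(30L, 50), 1000L, seed = 3)
  expect_equal(p0$p, 1)
  p2 <- permutationTest(1e9, rep(30L, 50), 1000L, seed = 3)
  expect_identical(p1$shuffle_max, p2$shuffle_max)
  expect_error(permutationTest(1, 50L, 40L), "shorter")
})

test_that("peak filtering is monotone in its thresholds", {
  cfg <- simConfig(seed = 51, n_genes = 60, as_structure_frac = 0,
                   peak_fraction = 0.3, peak_enrichment = c(4, 8))
  anno <- simulateAnnotation(cfg)
  rip <- simulateRipReads(anno, cfg)
  cand <- callPeaks(rip$ip, rip$input, anno, n_shuffles = 100, seed = 52)
  f4 <- filterPeaks(cand, fold = 4)
  f8 <- filterPeaks(cand, fold = 8)
  expect_true(all(names(f8) %in% names(f4)) || length(f8) <= length(f4))
  expect_true(all(as.data.frame(f8)$start %in% as.data.frame(f4)$start))
  d10 <- filterPeaks(cand, min_max_depth = 10)
  d20 <- filterPeaks(cand, min_max_depth = 20)
  expect_true(all(as.data.frame(d20)$start %in% as.data.frame(d10)$start))
  # determinism: same seed, same candidate table
  cand2 <- callPeaks(rip$ip, rip$input, anno, n_shuffles = 100, seed = 52)
  expect_equal(as.data.frame(cand), as.data.frame(cand2))
  # missing input is refused
  expect_error(callPeaks(rip$ip, NULL, anno), "input")
})

test_that("planted peaks at strong enrichment are recovered gene-wise", {
  cfg <- simConfig(seed = 53, n_genes = 80, as_structure_frac = 0,
                   peak_fraction = 0.25, peak_enrichment = 8)
  anno <- simulateAnnotation(cfg)
  rip <- simulateRipReads(anno, cfg)
  cand <- callPeaks(rip$ip, rip$input, anno, n_shuffles = 200, seed = 54)
  fin <- filterPeaks(cand)
  tg <- peaksToGenes(fin)
  expect_gt(mean(rip$truth$gene_id %in% tg$genes), 0.8)
  expect_gt(mean(tg$genes %in% rip$truth$gene_id), 0.8)
})

test_that("peaks collapse to de-duplicated target genes", {
  gr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(c(1, 50, 100), width = 10),
                               gene_id = c("G1", "G1", "G1"),
                               perm_p = c(0.01, 0.01, 0.01))
  tg <- peaksToGenes(gr)
  expect_equal(tg$genes, "G1")
  expect_equal(tg$counts$n_peaks, 3L)
  e <- peaksToGenes(GenomicRanges::GRanges())
  expect_length(e$genes, 0)
})
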