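test_that("normalize_rpm rescales by 1e6/total_mapped and conserves shape", {
  cs <- c(chrI = 10)
  tr <- paint_track(cs, list(list(chrom = "chrI", start = 0, end = 10,
                                  value = 5)), total_mapped = 2e6)
  out <- normalize_rpm(tr)
  expect_equal(out$cov$chrI, rep(2.5, 10))
  id <- normalize_rpm(coverage_track(tr$cov, cs, total_mapped = 1e6))
  expect_equal(id$cov$chrI, tr$cov$chrI)
  expect_equal(track_total(out), track_total(tr) * 1e6 / 2e6)
  expect_error(normalize_rpm(coverage_track(tr$cov, cs, total_mapped = 0)),
               "total_mapped")
})

test_that("subtract_background reproduces the hand-computed ratio moments", {
  cs <- c(chrI = 4)
  input <- paint_track(cs, list(list(chrom = "chrI", start = 0, end = 4,
                                     value = 1)))
  chip <- coverage_track(list(chrI = c(1, 1, 1, 11)), cs)
  sg <- subtract_background(chip, input, k = 1.2)
  expect_equal(sg$ratio_mean, 3.5)
  expect_equal(sg$ratio_sd, 5)          # sample (n-1) standard deviation
  expect_equal(sg$background_B, 9.5)
  expect_equal(sg$cov$chrI, c(0, 0, 0, 1.5))
})

test_that("subtract_background handles degenerate and masked input", {
  cs <- c(chrI = 6)
  input <- paint_track(cs, list(list(chrom = "chrI", start = 0, end = 6,
                                     value = 2)))
  chip <- paint_track(cs, list(list(chrom = "chrI", start = 0, end = 6,
                                    value = 4)))
  # constant ratio: sd 0, B = mean, everything floored to zero
  sg <- subtract_background(chip, input)
  expect_equal(track_total(sg), 0)
  # zero-input positions are masked: excluded from moments, signal 0
  input2 <- coverage_track(list(chrI = c(1, 1, 0, 0, 1, 1)), cs)
  chip2 <- coverage_track(list(chrI = c(2, 2, 9, 9, 2, 2)), cs)
  sg2 <- subtract_background(chip2, input2)
  expect_equal(sg2$ratio_mean, 2)
  expect_equal(sg2$cov$chrI[3:4], c(0, 0))
  expect_error(subtract_background(chip2, empty_track(cs)), "no usable")
})

test_that("with k = 0 and symmetric noise about half the genome is zeroed", {
  cs <- c(chrI = 20000)
  set.seed(5)
  input <- paint_track(cs, list(list(chrom = "chrI", start = 0, end = 20000,
                                     value = 1)))
  chip <- coverage_track(list(chrI = pmax(rnorm(20000, 10, 1), 0.1)), cs)
  sg <- subtract_background(chip, input, k = 0)
  frac_zero <- mean(sg$cov$chrI == 0)
  expect_gt(frac_zero, 0.45)
  expect_lt(frac_zero, 0.55)
})

test_that("partition assigns every base once with 5' > 3' > cds > igr precedence", {
  cat <- toy_catalog()
  # all signal inside gA's TSS +/- 300 window
  sig <- paint_track(cat$chrom_sizes,
                     list(list(chrom = "chrI", start = 900, end = 1100,
                               value = 3)))
  part <- partition_signal(sig, cat, flank = 300)
  expect_equal(sum(part$percent), 100, tolerance = 1e-6)
  expect_equal(part$percent[part$category == "five_prime"], 100)
  # uniform signal on a gene-free chromosome is all igr
  cs <- c(chrI = 10000, chrEmpty = 5000)
  cat2 <- transcript_catalog(toy_catalog()$transcripts, cs)
  sig2 <- paint_track(cs, list(list(chrom = "chrEmpty", start = 0,
                                    end = 5000, value = 1)))
  part2 <- partition_signal(sig2, cat2, flank = 300)
  expect_equal(part2$percent[part2$category == "igr"], 100)
  expect_error(partition_signal(sig, transcript_catalog(
    data.frame(id = "n", chrom = "chrI", start = 0, end = 10, strand = "+",
               kind = "noncoding"), c(chrI = 10000))), "no coding")
})

test_that("partition recovers the programmed 3' share on simulations", {
  s <- small_sim(n_genes = 300, seed = 13)
  part <- partition_signal(s$signal, s$catalog, flank = 300)
  pc <- setNames(part$percent, part$category)
  # 3' peaks are planted on ~20% of genes at one-third the 5' peak count:
  # the 3' share must be substantial but subordinate to the 5' share
  expect_gt(pc[["three_prime"]], 5)
  expect_lt(pc[["three_prime"]], pc[["five_prime"]])
  expect_gt(pc[["five_prime"]], 50)
})

test_that("metagene profiles align strand-aware and average correctly", {
  cat <- toy_catalog()
  # delta spike at tss + 10 of gA
  sig <- paint_track(cat$chrom_sizes,
                     list(list(chrom = "chrI", start = 1010, end = 1011,
                               value = 7)))
  prof <- metagene_profile(sig, cat, "tss_aligned", span = 50, ids = "gA")
  expect_equal(prof$mean[prof$offset == 10], 7)
  expect_equal(sum(prof$mean), 7)
  # mirror-image signal on opposite strands gives identical profiles
  sigp <- paint_track(cat$chrom_sizes,
                      list(list(chrom = "chrI", start = 1000, end = 1020,
                                value = 2)))
  sigm <- paint_track(cat$chrom_sizes,
                      list(list(chrom = "chrI", start = 6180, end = 6200,
                                value = 2)))
  pp <- metagene_profile(sigp, cat, "tss_aligned", span = 30, ids = "gA")
  pm <- metagene_profile(sigm, cat, "tss_aligned", span = 30, ids = "gC")
  expect_equal(pp$mean, pm$mean)
  expect_error(metagene_profile(sigp, cat, "tss_aligned", ids = "nope"),
               "no eligible")
})

test_that("scaled_cds interpolation reproduces a linear ramp", {
  cs <- c(chrI = 20000)
  tx <- data.frame(id = c("r1", "r2"), chrom = "chrI",
                   start = c(1000, 10000), end = c(3000, 12600),
                   strand = c("+", "-"), kind = "coding")
  cat <- transcript_catalog(tx, cs)
  cov <- numeric(20000)
  for (i in seq_len(nrow(tx))) {
    core <- region_of(cat$transcripts[i, ], "cds_core", 300, cs)
    L <- core$end - core$start
    ramp <- (seq_len(L) - 0.5) / L          # 0 -> 1 in transcription direction
    if (tx$strand[i] == "-") ramp <- rev(ramp)
    cov[(core$start + 1):core$end] <- ramp
  }
  sig <- coverage_track(list(chrI = cov), cs)
  prof <- metagene_profile(sig, cat, "scaled_cds", n_bins = 10)
  expect_equal(prof$mean, seq(0.05, 0.95, by = 0.1), tolerance = 0.01)
  expect_true(all(prof$n == 2))
})

test_that("feature vectors index their 25 windows correctly", {
  cs <- c(chrI = 20000)
  cat <- transcript_catalog(
    data.frame(id = "g1", chrom = "chrI", start = 5000, end = 6000,
               strand = "+", kind = "coding"), cs)
  zero <- empty_track(cs)
  fv <- feature_vectors(zero, cat)
  expect_equal(dim(fv), c(1, 25))
  expect_true(all(fv == 0))
  const <- paint_track(cs, list(list(chrom = "chrI", start = 0, end = 20000,
                                     value = 3)))
  expect_true(all(abs(feature_vectors(const, cat) - 3) < 1e-12))
  # spike of mass m in [tes-150, tes-100) lands in entry 20 (first TES window)
  spike <- paint_track(cs, list(list(chrom = "chrI", start = 5850,
                                     end = 5851, value = 10)))
  fv <- feature_vectors(spike, cat)
  expect_equal(unname(fv[1, 20]), 10 / 50)
  expect_true(all(fv[1, -20] == 0))
  # transcripts too short for the core windows are excluded with a record
  cat2 <- transcript_catalog(
    data.frame(id = c("g1", "tiny"), chrom = "chrI",
               start = c(5000, 100), end = c(6000, 350),
               strand = "+", kind = "coding"), cs)
  fv2 <- feature_vectors(zero, cat2)
  expect_equal(attr(fv2, "excluded"), "tiny")
  expect_equal(rownames(fv2), "g1")
})

test_that("feature vectors agree with metagene values on a one-gene catalog", {
  cs <- c(chrI = 20000)
  cat <- transcript_catalog(
    data.frame(id = "g1", chrom = "chrI", start = 5000, end = 6000,
               strand = "-", kind = "coding"), cs)
  set.seed(3)
  sig <- coverage_track(list(chrI = runif(20000)), cs)
  fv <- feature_vectors(sig, cat)
  prof <- metagene_profile(sig, cat, "tss_aligned", span = 300)
  # each of the nine TSS windows is the mean of its 50 profile positions
  for (j in 1:9) {
    offs <- (-300 + 50 * (j - 1)):(-300 + 50 * j - 1)
    expect_equal(unname(fv[1, j]),
                 mean(prof$mean[prof$offset %in% offs]), tolerance = 1e-9)
  }
})

test_that("clustering recovers planted groups and ignores input order", {
  set.seed(8)
  g1 <- matrix(rnorm(150, 0, 0.05), 6, 25)   # 5'-only pattern
  g1[, 1:9] <- g1[, 1:9] + 5
  g2 <- matrix(rnorm(150, 0, 0.05), 6, 25)   # 3'-only pattern
  g2[, 20:25] <- g2[, 20:25] + 5
  vec <- rbind(g1, g2)
  rownames(vec) <- sprintf("t%02d", 1:12)
  res <- cluster_profiles(vec, 2)
  expect_equal(length(unique(res$labels[1:6])), 1)
  expect_equal(length(unique(res$labels[7:12])), 1)
  expect_true(res$labels[1] != res$labels[12])
  perm <- vec[sample(nrow(vec)), ]
  res2 <- cluster_profiles(perm, 2)
  expect_equal(res2$labels[names(res$labels)], res$labels)
  # identical vectors collapse at distance zero
  same <- matrix(1, 3, 25, dimnames = list(c("a", "b", "c"), NULL))
  res3 <- cluster_profiles(same, 1)
  expect_equal(max(res3$tree$height), 0)
  expect_error(cluster_profiles(same, 5), "exceeds")
})

test_that("end enrichment quantifies clipped strand-aware windows linearly", {
  cs <- c(chrI = 2000)
  cat <- transcript_catalog(
    data.frame(id = "g", chrom = "chrI", start = 0, end = 1000,
               strand = "+", kind = "coding"), cs)
  expect_equal(quantify_end_enrichment(empty_track(cs), cat)$three_prime_level, 0)
  sig <- paint_track(cs, list(list(chrom = "chrI", start = 850, end = 1000,
                                   value = 2)))
  ee <- quantify_end_enrichment(sig, cat, window = 150)
  expect_equal(ee$three_prime_level, 2)
  expect_equal(ee$five_prime_level, 0)
  # linearity: rescaling the signal rescales levels by the same scalar
  sig3 <- sig; sig3$cov$chrI <- sig3$cov$chrI * 3.7
  ee3 <- quantify_end_enrichment(sig3, cat, window = 150)
  expect_equal(ee3$three_prime_level, 3.7 * ee$three_prime_level)
})

test_that("occupancy calls follow the none/positive-mean rule and scale-invariance", {
  expect_equal(classify_occupancy(c(0, 0, 4, 4)),
               c("none", "none", "high", "high"))
  expect_equal(classify_occupancy(c(0, 1, 3, 8)),
               c("none", "intermediate", "intermediate", "high"))
  lv <- c(0, 0.2, 1, 5, 9)
  expect_equal(classify_occupancy(lv * 13), classify_occupancy(lv))
  expect_equal(classify_occupancy(c(0, 0)), c("none", "none"))
  expect_error(classify_occupancy(c(-1, 2)), ">= 0")
})

test_that("the high-3' class recovers planted peaks with high sensitivity and specificity", {
  s <- small_sim(n_genes = 400, seed = 21)
  ee <- add_occupancy_calls(quantify_end_enrichment(s$signal, s$catalog))
  truth <- s$truth
  call <- ee$three_call[match(truth$gene, ee$id)]
  sens <- mean(call[truth$has_3prime_peak] == "high")
  spec <- mean(call[!truth$has_3prime_peak] != "high")
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})
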