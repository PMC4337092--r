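test_that("the fold rule associates peaks by downstream/upstream signal", {
  cs <- c(chrI = 1000)
  # antisense direction '-': downstream is left of the peak
  peak <- list(chrom = "chrI", start = 400, end = 550, strand = "-")
  mk <- function(down, up) {
    minus <- paint_track(cs, list(
      list(chrom = "chrI", start = 250, end = 400, value = down),
      list(chrom = "chrI", start = 550, end = 700, value = up)),
      strand = "-")
    stranded_expression(empty_track(cs, "+"), minus)
  }
  a <- associate_peak(peak, mk(9, 2), window = 150)
  expect_equal(a$downstream_mean, 9)
  expect_equal(a$upstream_mean, 2)
  expect_equal(a$fold, 9.1 / 2.1)
  expect_true(a$associated)
  # equal signal on both sides: fold 1, not associated
  b <- associate_peak(peak, mk(4, 4), window = 150)
  expect_false(b$associated)
  # zero signal on both sides: pseudocount gives fold exactly 1
  z <- associate_peak(peak, mk(0, 0), window = 150)
  expect_equal(z$fold, 1)
  expect_false(z$associated)
  expect_error(associate_peak(list(chrom = "chrI", start = -5, end = 10,
                                   strand = "-"), mk(1, 1)), "outside")
  # invariance under joint rescaling of both strands
  e <- mk(9, 2)
  e$minus$cov$chrI <- e$minus$cov$chrI * 100
  e$plus$cov$chrI <- e$plus$cov$chrI * 100
  a2 <- associate_peak(peak, e, window = 150, pseudocount = 1e-9)
  a1 <- associate_peak(peak, mk(9, 2), window = 150, pseudocount = 1e-9)
  expect_equal(a2$associated, a1$associated)
  expect_equal(a2$fold, a1$fold, tolerance = 1e-6)
})

test_that("overlap contingency builds the high-vs-none table with expectations", {
  ee <- data.frame(id = sprintf("g%02d", 1:40),
                   three_call = rep(c("high", "none", "intermediate"),
                                    c(10, 25, 5)))
  as_set <- data.frame(id = paste0("AS_", ee$id[c(1:8, 11:12)]),
                       host = ee$id[c(1:8, 11:12)],
                       overlap_fraction = 1,
                       excluded_convergent = FALSE)
  res <- overlap_contingency(ee, as_set, "high_vs_none")
  expect_equal(as.vector(res$table), c(8, 2, 2, 23))
  expect_equal(res$expected[1, 1], 10 * 10 / 35, tolerance = 1e-12)
  # intermediate genes are excluded from the default table
  expect_equal(sum(res$table), 35)
  # perfectly confounded: infinite odds ratio, minimal p
  as2 <- as_set[1:8, ]
  ee2 <- ee[ee$three_call != "intermediate", ]
  ee2$three_call[!(ee2$id %in% as2$host)] <- "none"
  ee2$three_call[ee2$id %in% as2$host] <- "high"
  res2 <- overlap_contingency(ee2, as2)
  expect_true(res2$odds_ratio_infinite)
  expect_lt(res2$p_value, 1e-6)
  expect_error(overlap_contingency(
    data.frame(id = "g", three_call = "intermediate"), as_set), "empty")
})

test_that("contingency p-values are calibrated when antisense labels are random", {
  s <- small_sim(n_genes = 300, seed = 41)
  ee <- add_occupancy_calls(quantify_end_enrichment(s$signal, s$catalog))
  genes <- ee$id
  set.seed(17)
  ps <- replicate(60, {
    hosts <- sample(genes, 40)
    as_set <- data.frame(id = paste0("AS_", hosts), host = hosts,
                         overlap_fraction = 1, excluded_convergent = FALSE)
    overlap_contingency(ee, as_set)$p_value
  })
  # under random labelling, small p-values are no more frequent than nominal
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps > 0.2), 0.5)
})

test_that("randomisation nulls match hypergeometric sampling", {
  s <- small_sim(n_genes = 200, seed = 51)
  as_set <- classify_antisense(s$catalog)
  genes <- s$truth$gene
  rt <- randomization_test(s$catalog, as_set, observed_genes = genes[1:60],
                           n_regions = 60, iters = 400, seed = 9)
  # null mean equals the hypergeometric expectation n * K / N within 3 SE
  pool_n <- length(genes)
  K <- sum(s$truth$has_antisense)
  m_exp <- 60 * K / pool_n
  v_exp <- 60 * (K / pool_n) * (1 - K / pool_n) * (pool_n - 60) / (pool_n - 1)
  se <- sqrt(v_exp / 400)
  expect_lt(abs(mean(rt$null_counts) - m_exp), 3 * se + 0.5)
  expect_equal(length(rt$null_counts), 400)
  # add-one empirical p never returns zero and is reproducible by seed
  expect_gte(rt$empirical_p, 1 / 401)
  rt2 <- randomization_test(s$catalog, as_set, observed_genes = genes[1:60],
                            n_regions = 60, iters = 400, seed = 9)
  expect_identical(rt$null_counts, rt2$null_counts)
  expect_error(randomization_test(s$catalog, as_set, genes,
                                  n_regions = 10000), "exceeds")
})

test_that("saturated antisense coverage drives the empirical p to one", {
  cs <- c(chrI = 100000)
  n <- 20
  start <- seq(1000, by = 4000, length.out = n)
  genes <- data.frame(id = sprintf("g%02d", 1:n), chrom = "chrI",
                      start = start, end = start + 2000, strand = "+",
                      kind = "coding")
  # antisense first base (end - 1 on the minus strand) inside each 3' window
  as_tx <- data.frame(id = paste0("AS_", genes$id), chrom = "chrI",
                      start = genes$end - 450, end = genes$end - 50,
                      strand = "-", kind = "noncoding")
  cat <- transcript_catalog(rbind(genes, as_tx), cs)
  as_set <- data.frame(id = as_tx$id, host = genes$id,
                       overlap_fraction = 0.25, excluded_convergent = FALSE)
  rt <- randomization_test(cat, as_set, observed_genes = genes$id[1:10],
                           n_regions = 10, iters = 50, seed = 2)
  expect_true(all(rt$null_counts == 10))
  expect_equal(rt$observed_count, 10)
  expect_equal(rt$empirical_p, 1)
})
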