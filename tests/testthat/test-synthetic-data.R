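test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(fraction_tandem_close = 0.9), "sum to 1")
  expect_error(sim_config(p_5prime_peak = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(effect_down_as = -1), "fold")
  expect_error(sim_config(close_gap = c(100, 400),
                          fraction_tandem_close = 0.35), "< 300")
})

test_that("simulation is deterministic in the seed, stream by stream", {
  cfg <- sim_config(n_genes = 60)
  a <- simulate_genome(cfg, seed = 5)
  b <- simulate_genome(cfg, seed = 5)
  expect_identical(a, b)
  c_ <- simulate_genome(cfg, seed = 6)
  expect_false(identical(a$truth, c_$truth))
  ca <- simulate_chip(a$catalog, a$truth, cfg, seed = 5)
  cb <- simulate_chip(a$catalog, a$truth, cfg, seed = 5)
  expect_identical(ca, cb)
  cc <- simulate_chip(a$catalog, a$truth, cfg, seed = 6)
  expect_false(identical(ca$chip$cov, cc$chip$cov))
  ra <- simulate_rna(a$catalog, a$truth, cfg, seed = 5)
  rb <- simulate_rna(a$catalog, a$truth, cfg, seed = 5)
  expect_identical(ra$counts, rb$counts)
})

test_that("arrangement geometry follows the configuration", {
  cfg <- sim_config(n_genes = 80, fraction_tandem_close = 1,
                    fraction_tandem_far = 0, fraction_convergent_close = 0,
                    fraction_convergent_far = 0)
  sim <- simulate_genome(cfg, seed = 3)
  arr <- sim$truth$arrangement
  defined <- arr != "undefined"
  expect_true(all(arr[defined] == "tandem_close"))
  expect_true(all(sim$truth$gap[defined] < 300))
  # antisense tied exactly to the 3' flag when the conditionals are 1/0
  cfg2 <- sim_config(n_genes = 80, p_antisense_given_3peak = 1,
                     p_antisense_given_no3peak = 0)
  sim2 <- simulate_genome(cfg2, seed = 3)
  expect_identical(sim2$truth$has_antisense, sim2$truth$has_3prime_peak)
})

test_that("realised frequencies match the configured rates within binomial error", {
  cfg <- sim_config(n_genes = 2000)
  sim <- simulate_genome(cfg, seed = 19)
  tr <- sim$truth
  check_rate <- function(x, p) {
    se <- sqrt(p * (1 - p) / length(x))
    expect_lt(abs(mean(x) - p), 3 * se + 1e-9)
  }
  check_rate(tr$has_5prime_peak, 0.49)
  check_rate(tr$has_antisense[tr$has_3prime_peak], 0.52)
  check_rate(tr$has_antisense[!tr$has_3prime_peak], 0.05)
  check_rate(tr$has_3prime_peak[grepl("^tandem", tr$arrangement)], 0.30)
  # arrangement fractions over genes with a defined 3'-side neighbour
  def <- tr$arrangement != "undefined"
  frac_tandem <- mean(grepl("^tandem", tr$arrangement[def]))
  expect_lt(abs(frac_tandem - 0.6), 3 * sqrt(0.6 * 0.4 / sum(def)))
})

test_that("antisense transcripts initiate inside the host 3' window, opposite strand", {
  cfg <- sim_config(n_genes = 300)
  sim <- simulate_genome(cfg, seed = 23)
  tx <- sim$catalog$transcripts
  tr <- sim$truth[sim$truth$has_antisense, ]
  for (i in seq_len(nrow(tr))) {
    host <- tx[tr$gene[i], ]
    as_ <- tx[tr$as_id[i], ]
    expect_true(as_$strand != host$strand)
    first_base <- if (as_$strand == "+") as_$start else as_$end - 1
    reg <- region_of(host, "three_prime_inner", 150, sim$catalog$chrom_sizes)
    expect_gte(first_base, reg$start)
    expect_lt(first_base, reg$end)
    # contained in the host span (never spills onto a neighbour)
    expect_gte(as_$start, host$start)
    expect_lte(as_$end, host$end)
  }
})

test_that("planted ChIP peaks put the ratio maximum inside the 3' window", {
  cfg <- sim_config(n_genes = 2, chrom_length = 20000, p_5prime_peak = 0,
                    p_3prime_peak_tandem = 1, p_3prime_peak_convergent = 1,
                    p_5prime_weak = 0, p_3prime_weak = 0)
  sim <- simulate_genome(cfg, seed = 2)
  chip <- simulate_chip(sim$catalog, sim$truth, cfg, seed = 2)
  ratio <- chip$chip$cov[[1]] / pmax(chip$input$cov[[1]], 1e-9)
  amax <- which.max(ratio) - 1
  windows <- transcript_regions(sim$catalog, "three_prime_inner", 150,
                                kind = "coding")
  expect_true(any(amax >= windows$start & amax < windows$end))
})

test_that("zero peak height leaves chip and input exchangeable", {
  cfg <- sim_config(n_genes = 40, chip_peak_height = 0,
                    p_5prime_weak = 0, p_3prime_weak = 0)
  sim <- simulate_genome(cfg, seed = 4)
  chip <- simulate_chip(sim$catalog, sim$truth, cfg, seed = 4)
  sg <- subtract_background(normalize_rpm(chip$chip),
                            normalize_rpm(chip$input))
  # residual signal above background is a small noise tail, not peaks
  expect_lt(mean(unlist(sg$cov) > 0), 0.2)
  ee <- quantify_end_enrichment(sg, sim$catalog)
  expect_lt(mean(ee$three_prime_level), 0.05)
})

test_that("RNA counts follow the programmed means and strand placement", {
  cfg <- sim_config(n_genes = 60, dispersion = 1e-6, n_replicates = 50,
                    rna_lognormal_sd = 0)
  sim <- simulate_genome(cfg, seed = 30)
  rna <- simulate_rna(sim$catalog, sim$truth, cfg, seed = 30)
  cond1 <- rna$col_data$sample[rna$col_data$condition == "rrp6d"]
  m <- rowMeans(rna$counts[, cond1])
  # near-zero dispersion: every sample mean within 4 Poisson standard
  # errors of its programmed mean, and within ~2% on average
  se1 <- sqrt(rna$mu[, 1] / 50)
  expect_true(all(abs(m - rna$mu[, 1]) < 4 * se1))
  expect_lt(mean(abs(m - rna$mu[, 1]) / rna$mu[, 1]), 0.02)
  # condition 2 applies the programmed fold changes
  cond2 <- rna$col_data$sample[rna$col_data$condition != "rrp6d"]
  m2 <- rowMeans(rna$counts[, cond2])
  se2 <- sqrt(rna$mu[, 2] / 50)
  expect_true(all(abs(m2 - rna$mu[, 2]) < 4 * se2))
  expect_lt(mean(abs(m2 - rna$mu[, 2]) / rna$mu[, 2]), 0.02)
  # antisense counts appear only on the strand opposite the host
  expr <- expression_from_counts(sim$catalog, rna$counts[, 1])
  tx <- sim$catalog$transcripts
  as1 <- tx[tx$kind == "noncoding", ][1, ]
  host <- tx[sub("^AS_", "", as1$id), ]
  as_track <- if (as1$strand == "+") expr$plus else expr$minus
  expect_gt(region_sum(as_track, as1$chrom, as1$start, as1$end), 0)
  host_track <- if (host$strand == "+") expr$plus else expr$minus
  expect_gt(region_sum(host_track, host$chrom, host$start, host$end), 0)
  expect_true(as1$strand != host$strand)
})

test_that("a written simulation round-trips through the format readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 30)
  out <- write_simulation(cfg, seed = 33, dir)
  cat2 <- read_annotation(file.path(dir, "annotation.gff3"), "gff3",
                          chrom_sizes = file.path(dir, "chrom.sizes"))
  expect_equal(sort(cat2$transcripts$id), sort(out$catalog$transcripts$id))
  chip2 <- read_coverage(file.path(dir, "chip.bedGraph"),
                         file.path(dir, "chrom.sizes"))
  expect_equal(track_total(chip2), track_total(out$chip$chip),
               tolerance = 1e-6)
  counts <- read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  expect_equal(nrow(counts), nrow(out$rna$counts))
})
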