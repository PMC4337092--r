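# Small in-code fixtures shared across tests.

# A toy catalog: three coding genes and one antisense transcript on a
# single 10-kb chromosome.
toy_catalog <- function() {
  transcript_catalog(
    data.frame(
      id = c("gA", "gB", "gC", "AS_gA"),
      chrom = "chrI",
      start = c(1000, 3100, 5000, 1600),
      end = c(2000, 4100, 6200, 1950),
      strand = c("+", "+", "-", "-"),
      kind = c("coding", "coding", "coding", "noncoding"),
      stringsAsFactors = FALSE),
    chrom_sizes = c(chrI = 10000))
}

# A flat track with chosen values painted over [start, end).
paint_track <- function(chrom_sizes, spans, strand = "*",
                        total_mapped = NULL) {
  cov <- lapply(chrom_sizes, function(n) numeric(n))
  for (s in spans)
    cov[[s$chrom]][(s$start + 1):s$end] <- s$value
  coverage_track(cov, chrom_sizes, strand, total_mapped)
}

# A paper-like small simulation reused by several test files.
small_sim <- function(n_genes = 400, seed = 11, ...) {
  cfg <- sim_config(n_genes = n_genes, ...)
  sim <- simulate_genome(cfg, seed)
  chip <- simulate_chip(sim$catalog, sim$truth, cfg, seed)
  signal <- subtract_background(normalize_rpm(chip$chip),
                                normalize_rpm(chip$input))
  list(cfg = cfg, catalog = sim$catalog, truth = sim$truth,
       chip = chip, signal = signal, seed = seed)
}

# Brute-force two-sided Fisher p by direct hypergeometric enumeration with
# choose(); independent of the package's log-space path.
enum_fisher_p <- function(a, b, c, d) {
  N <- a + b + c + d; r1 <- a + b; c1 <- a + c
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- choose(c1, ks) * choose(N - c1, r1 - ks) / choose(N, r1)
  obs <- choose(c1, a) * choose(N - c1, r1 - a) / choose(N, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force BH step-up: sort, p * n / rank, cumulative min from the top.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
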