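# Synthetic-data generator: compact genome of tandem/convergent gene pairs,
# planted 5'/3' variant-histone peaks, antisense transcripts initiating in
# 3' peak windows, and two-condition stranded RNA counts with programmable
# effects -- so every pipeline stage has a recoverable ground truth.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline targets: a
#' 4000-gene compact genome; a ~52% antisense rate among genes with a 3'
#' occupancy peak versus ~5% without one; ~49% of genes carrying a 5' peak;
#' 3' peaks concentrated at tandem genes (30% tandem vs 8% convergent,
#' ~20% overall); and, in the variant-null condition, 4-fold
#' down-regulation of 3'-peak antisense transcripts with a reciprocal
#' 1.5-fold up-regulation of their host sense transcripts.  ChIP noise is
#' generated block-wise at nucleosome/fragment scale so that it is
#' spatially correlated, as fragment-based coverage is.
#'
#' @param n_genes number of protein-coding genes.
#' @param chrom_length chromosome length in bp; genes spill onto additional
#'   chromosomes as needed.
#' @param gene_length_range min/max gene length (bp).
#' @param fraction_tandem_close,fraction_tandem_far,fraction_convergent_close,fraction_convergent_far
#'   target proportions of the four 3'-side arrangement categories
#'   (must sum to 1).
#' @param close_gap,far_gap min/max of the intergenic gap draws for close
#'   (< 300 bp) and far (> 300 bp) pairs.
#' @param p_5prime_peak probability a gene carries a 5' peak.
#' @param p_3prime_peak_tandem,p_3prime_peak_convergent probability of a 3'
#'   peak given the gene's arrangement.
#' @param p_antisense_given_3peak,p_antisense_given_no3peak antisense
#'   presence probabilities conditional on the 3' peak flag.
#' @param chip_background_mean,chip_noise_sd,chip_block flat input coverage
#'   mean, block-noise SD and noise block size (bp).
#' @param chip_peak_height peak amplitude in coverage units (Gaussian bump,
#'   sd 50 bp, truncated at +/-100 bp).
#' @param p_5prime_weak,p_3prime_weak probability that a gene *without* a
#'   planted peak carries a weak sub-threshold mark at that end; occupancy
#'   in real chromatin is graded, and these weak marks populate the
#'   intermediate tier of the none/intermediate/high classification.
#' @param weak_height_range weak-mark amplitude as a fraction of
#'   `chip_peak_height` (uniform draw).
#' @param rna_mean_sense,rna_mean_antisense median raw counts per
#'   transcript in the baseline condition.
#' @param rna_lognormal_sd spread (log scale) of per-transcript baseline
#'   means around the medians; expression spans orders of magnitude in real
#'   transcriptomes, and this dynamic range is what makes replicate tracks
#'   correlate.
#' @param dispersion negative-binomial dispersion of the counts.
#' @param effect_down_as fold change applied to 3'-peak antisense
#'   transcripts in condition 2 (default 0.25 = 4-fold down).
#' @param effect_sense_coupling reciprocal fold change applied to their
#'   host sense transcripts in condition 2.
#' @param n_replicates replicates per condition.
#' @return validated list of class `SimulationConfig`.
#' @export
sim_config <- function(n_genes = 4000,
                       chrom_length = 2e6,
                       gene_length_range = c(800, 2000),
                       fraction_tandem_close = 0.35,
                       fraction_tandem_far = 0.25,
                       fraction_convergent_close = 0.25,
                       fraction_convergent_far = 0.15,
                       close_gap = c(100, 280),
                       far_gap = c(320, 900),
                       p_5prime_peak = 0.49,
                       p_3prime_peak_tandem = 0.30,
                       p_3prime_peak_convergent = 0.08,
                       p_antisense_given_3peak = 0.52,
                       p_antisense_given_no3peak = 0.05,
                       chip_background_mean = 50,
                       chip_noise_sd = 5,
                       chip_block = 150,
                       chip_peak_height = 150,
                       p_5prime_weak = 0.30,
                       p_3prime_weak = 0.30,
                       weak_height_range = c(0.30, 0.50),
                       rna_mean_sense = 200,
                       rna_mean_antisense = 60,
                       rna_lognormal_sd = 0.8,
                       dispersion = 0.05,
                       effect_down_as = 0.25,
                       effect_sense_coupling = 1.5,
                       n_replicates = 2) {
  cfg <- as.list(environment())
  fr <- c(cfg$fraction_tandem_close, cfg$fraction_tandem_far,
          cfg$fraction_convergent_close, cfg$fraction_convergent_far)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("arrangement fractions must sum to 1")
  probs <- c(cfg$p_5prime_peak, cfg$p_3prime_peak_tandem,
             cfg$p_3prime_peak_convergent, cfg$p_antisense_given_3peak,
             cfg$p_antisense_given_no3peak)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (cfg$effect_down_as <= 0 || cfg$effect_sense_coupling <= 0)
    stop("fold changes must be > 0")
  if (cfg$n_genes < 2) stop("need at least 2 genes")
  if (diff(cfg$close_gap) < 0 || cfg$close_gap[2] >= 300)
    stop("close gaps must be < 300 bp")
  if (cfg$far_gap[1] <= 300) stop("far gaps must be > 300 bp")
  structure(cfg, class = "SimulationConfig")
}

# Run fn() under a private RNG stream derived from (seed, offset), leaving
# the caller's RNG state untouched.  One stream per artifact, so
# regenerating one artifact never perturbs another.
.with_stream <- function(seed, offset, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  fn()
}

#' Simulate the gene catalogue and its ground truth
#'
#' Genes are placed left-to-right; consecutive strands follow a two-state
#' chain whose same-strand transition probability equals the target tandem
#' fraction, which makes the realised 3'-side arrangement categories match
#' the configured proportions in expectation.  Gaps are drawn from the
#' close/far ranges conditional on the pair type.  Peak and antisense flags
#' are Bernoulli with the configured conditional rates; each antisense
#' transcript initiates at a uniform position inside its host's last 150 bp
#' (the 3'-inner window) on the opposite strand and extends into the gene
#' body.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed; the catalogue uses stream `seed + 1`.
#' @return list with `catalog` (a `TranscriptCatalog` holding coding genes
#'   plus `AS_<gene>` non-coding transcripts) and `truth` (per-gene flags,
#'   arrangement, antisense TSS, and true condition-2 fold changes).
#' @export
simulate_genome <- function(config, seed = 1) {
  stopifnot(is(config, "SimulationConfig"))
  .with_stream(seed, 1L, function() .simulate_genome_impl(config))
}

.simulate_genome_impl <- function(cfg) {
  n <- cfg$n_genes
  f_t <- cfg$fraction_tandem_close + cfg$fraction_tandem_far
  p_close_t <- cfg$fraction_tandem_close / max(f_t, 1e-12)
  f_c <- cfg$fraction_convergent_close + cfg$fraction_convergent_far
  p_close_c <- cfg$fraction_convergent_close / max(f_c, 1e-12)
  len <- round(runif(n, cfg$gene_length_range[1], cfg$gene_length_range[2]))
  strand <- character(n)
  strand[1] <- sample(c("+", "-"), 1)
  same <- runif(n - 1) < f_t
  for (i in 2:n)
    strand[i] <- if (same[i - 1]) strand[i - 1] else setdiff(c("+", "-"), strand[i - 1])
  # gap between gene i and i+1, drawn conditional on the pair type
  gap <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    pair <- paste0(strand[i], strand[i + 1])
    close <- switch(pair,
                    "++" = , "--" = runif(1) < p_close_t,
                    "+-" = runif(1) < p_close_c,
                    "-+" = FALSE)              # divergent pairs kept far
    rng <- if (close) cfg$close_gap else cfg$far_gap
    gap[i] <- round(runif(1, rng[1], rng[2]))
  }
  margin <- 1000
  chrom_idx <- integer(n); start <- numeric(n)
  cursor <- margin; chrom <- 1L
  broken_after <- logical(n)                   # TRUE: i+1 starts a new chrom
  for (i in seq_len(n)) {
    if (cursor + len[i] + margin > cfg$chrom_length) {
      chrom <- chrom + 1L; cursor <- margin
      if (i > 1L) broken_after[i - 1L] <- TRUE
    }
    chrom_idx[i] <- chrom; start[i] <- cursor
    cursor <- cursor + len[i] + if (i < n) gap[i] else 0
  }
  end <- start + len
  chroms <- paste0("chr", seq_len(max(chrom_idx)))
  chrom_sizes <- setNames(rep(cfg$chrom_length, length(chroms)), chroms)
  gene_id <- sprintf("g%04d", seq_len(n))
  # 3'-side arrangement truth from the generative pair logic
  arrangement <- rep("undefined", n)
  neighbor <- rep(NA_character_, n)
  gapv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- if (strand[i] == "+") i + 1L else i - 1L
    if (j < 1L || j > n) next
    k <- min(i, j)                             # gap index of the pair
    if (broken_after[k] || chrom_idx[i] != chrom_idx[j]) next
    type <- if (strand[i] == strand[j]) "tandem" else "convergent"
    arrangement[i] <- paste0(type, if (gap[k] < 300) "_close" else "_far")
    neighbor[i] <- gene_id[j]
    gapv[i] <- gap[k]
  }
  p3 <- ifelse(grepl("^tandem", arrangement), cfg$p_3prime_peak_tandem,
        ifelse(grepl("^convergent", arrangement), cfg$p_3prime_peak_convergent,
               f_t * cfg$p_3prime_peak_tandem +
                 f_c * cfg$p_3prime_peak_convergent))
  has5 <- runif(n) < cfg$p_5prime_peak
  has3 <- runif(n) < p3
  p_as <- ifelse(has3, cfg$p_antisense_given_3peak,
                 cfg$p_antisense_given_no3peak)
  hasAS <- runif(n) < p_as
  # antisense transcripts: TSS uniform in the host's 3'-inner 150 bp window
  as_tss <- rep(NA_real_, n)
  as_rows <- NULL
  as_len_raw <- round(runif(n, 300, 650))
  as_off <- floor(runif(n, 0, 150))            # offset of AS TSS inside window
  for (i in which(hasAS)) {
    if (strand[i] == "+") {
      q <- end[i] - 150 + as_off[i]            # AS first base (on - strand)
      L <- min(as_len_raw[i], q + 1 - start[i])
      as_rows <- rbind(as_rows, data.frame(
        id = paste0("AS_", gene_id[i]), chrom = chroms[chrom_idx[i]],
        start = q + 1 - L, end = q + 1, strand = "-",
        kind = "noncoding", stringsAsFactors = FALSE))
      as_tss[i] <- q
    } else {
      q <- start[i] + 150 - 1 - as_off[i]      # AS first base (on + strand)
      L <- min(as_len_raw[i], end[i] - q)
      as_rows <- rbind(as_rows, data.frame(
        id = paste0("AS_", gene_id[i]), chrom = chroms[chrom_idx[i]],
        start = q, end = q + L, strand = "+",
        kind = "noncoding", stringsAsFactors = FALSE))
      as_tss[i] <- q
    }
  }
  genes <- data.frame(id = gene_id, chrom = chroms[chrom_idx],
                      start = start, end = end, strand = strand,
                      kind = "coding", stringsAsFactors = FALSE)
  catalog <- transcript_catalog(rbind(genes, as_rows), chrom_sizes)
  affected <- has3 & hasAS                     # antisense down + sense coupling
  truth <- data.frame(
    gene = gene_id, arrangement = arrangement, neighbor = neighbor,
    gap = gapv, has_5prime_peak = has5, has_3prime_peak = has3,
    has_antisense = hasAS,
    as_id = ifelse(hasAS, paste0("AS_", gene_id), NA_character_),
    as_tss = as_tss,
    fc_antisense = ifelse(affected, cfg$effect_down_as, 1),
    fc_sense = ifelse(affected, cfg$effect_sense_coupling, 1),
    stringsAsFactors = FALSE)
  list(catalog = catalog, truth = truth)
}

# Block-wise non-negative noise: piecewise-constant at `block` bp scale,
# mimicking the spatial autocorrelation of fragment-based coverage.
.block_noise <- function(n, mean, sd, block) {
  nb <- ceiling(n / block)
  rep(pmax(rnorm(nb, mean, sd), 0), each = block)[seq_len(n)]
}

# Truncated Gaussian bump (sd 50 bp, support +/-100 bp) added around a
# centre; returns modified vector.
.add_bump <- function(v, centre, height, sd = 50, halfwidth = 100) {
  lo <- max(floor(centre - halfwidth), 0)
  hi <- min(ceiling(centre + halfwidth), length(v) - 1)
  if (hi < lo) return(v)
  x <- lo:hi
  v[x + 1L] <- v[x + 1L] + height * exp(-((x - centre)^2) / (2 * sd^2))
  v
}

#' Simulate ChIP and input coverage
#'
#' The input track is flat mean coverage plus non-negative block noise; the
#' ChIP track is an independent draw of the same background plus truncated
#' Gaussian bumps (sd 50 bp) at the planted sites: 5' peaks at the -1/+1
#' nucleosome positions (60 bp either side of the TSS) and 3' peaks at the
#' centre of the 3'-inner 150 bp window.
#'
#' @param catalog,truth output of [simulate_genome()].
#' @param config a [sim_config()].
#' @param seed master seed; this stage uses stream `seed + 2`.
#' @return list with `chip` and `input` `CoverageTrack`s.
#' @export
simulate_chip <- function(catalog, truth, config, seed = 1) {
  stopifnot(is(config, "SimulationConfig"))
  if (!all(truth$gene %in% catalog$transcripts$id))
    stop("truth does not match catalog")
  .with_stream(seed, 2L, function() {
    cs <- catalog$chrom_sizes
    input <- lapply(cs, function(n)
      .block_noise(n, config$chip_background_mean, config$chip_noise_sd,
                   config$chip_block))
    chip <- lapply(cs, function(n)
      .block_noise(n, config$chip_background_mean, config$chip_noise_sd,
                   config$chip_block))
    tx <- catalog_transcripts(catalog, "coding")
    tx <- tx[match(truth$gene, tx$id), ]
    h <- config$chip_peak_height
    n <- nrow(tx)
    # graded occupancy: unflagged ends may carry a weak sub-threshold mark
    weak5 <- !truth$has_5prime_peak & runif(n) < config$p_5prime_weak
    weak3 <- !truth$has_3prime_peak & runif(n) < config$p_3prime_weak
    wh <- h * runif(n, config$weak_height_range[1],
                    config$weak_height_range[2])
    for (i in seq_len(n)) {
      ch <- tx$chrom[i]; s <- tx$strand[i]
      dirpos <- function(off) if (s == "+") tx$tss[i] + off else tx$tss[i] - 1 - off
      h5 <- if (truth$has_5prime_peak[i]) h else if (weak5[i]) wh[i] else 0
      if (h5 > 0) {
        chip[[ch]] <- .add_bump(chip[[ch]], dirpos(-60), h5)
        chip[[ch]] <- .add_bump(chip[[ch]], dirpos(60), h5)
      }
      h3 <- if (truth$has_3prime_peak[i]) h else if (weak3[i]) wh[i] else 0
      if (h3 > 0) {
        centre <- if (s == "+") tx$tes[i] - 75 else tx$tes[i] + 74
        chip[[ch]] <- .add_bump(chip[[ch]], centre, h3)
      }
    }
    list(chip = coverage_track(chip, cs, "*",
                               total_mapped = round(sum(unlist(lapply(chip, sum))))),
         input = coverage_track(input, cs, "*",
                                total_mapped = round(sum(unlist(lapply(input, sum))))))
  })
}

#' Simulate two-condition stranded RNA counts
#'
#' Per-transcript counts are negative binomial with mean = baseline
#' (`rna_mean_sense` / `rna_mean_antisense`) times the true fold change;
#' condition 2 applies `effect_down_as` to antisense transcripts of
#' 3'-peak genes and `effect_sense_coupling` to their hosts.
#'
#' @param catalog,truth output of [simulate_genome()].
#' @param config a [sim_config()].
#' @param seed master seed; this stage uses stream `seed + 3`.
#' @param conditions labels of the two conditions.
#' @return list with `counts` (transcripts x samples integer matrix),
#'   `col_data` (condition/replicate per column) and `mu` (programmed
#'   means).
#' @export
simulate_rna <- function(catalog, truth, config, seed = 1,
                         conditions = c("rrp6d", "rrp6d_htz1d")) {
  stopifnot(is(config, "SimulationConfig"))
  .with_stream(seed, 3L, function() {
    tx <- catalog$transcripts
    base <- ifelse(tx$kind == "coding", config$rna_mean_sense,
                   config$rna_mean_antisense) *
      exp(rnorm(nrow(tx), 0, config$rna_lognormal_sd))
    fc <- rep(1, nrow(tx))
    m_gene <- match(tx$id, truth$gene)
    m_as <- match(tx$id, truth$as_id)
    fc[!is.na(m_gene)] <- truth$fc_sense[m_gene[!is.na(m_gene)]]
    fc[!is.na(m_as)] <- truth$fc_antisense[m_as[!is.na(m_as)]]
    reps <- config$n_replicates
    cols <- c(paste0(conditions[1], "_rep", seq_len(reps)),
              paste0(conditions[2], "_rep", seq_len(reps)))
    mu <- cbind(matrix(base, nrow(tx), reps),
                matrix(base * fc, nrow(tx), reps))
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                     nrow(tx), dimnames = list(tx$id, cols))
    list(counts = counts,
         col_data = data.frame(sample = cols,
                               condition = rep(conditions, each = reps),
                               replicate = rep(seq_len(reps), 2),
                               stringsAsFactors = FALSE),
         mu = matrix(c(base, base * fc), nrow(tx),
                     dimnames = list(tx$id, conditions)))
  })
}

#' Spread per-transcript counts into stranded coverage tracks
#'
#' Each transcript's count is distributed uniformly over its span on its
#' own strand (per-bp value = count / length), and counts of overlapping
#' same-strand transcripts add.
#'
#' @param catalog a `TranscriptCatalog`.
#' @param counts named numeric vector (or one column of the count matrix)
#'   indexed by transcript id.
#' @param condition,replicate labels attached to the result.
#' @return a [stranded_expression()].
#' @export
expression_from_counts <- function(catalog, counts, condition = "c1",
                                   replicate = "r1") {
  cs <- catalog$chrom_sizes
  plus <- lapply(cs, function(n) numeric(n))
  minus <- lapply(cs, function(n) numeric(n))
  tx <- catalog$transcripts
  k <- counts[tx$id]
  if (any(is.na(k))) stop("counts missing for transcript(s): ",
                          paste(head(tx$id[is.na(k)], 5), collapse = ", "))
  for (i in seq_len(nrow(tx))) {
    dens <- k[[i]] / (tx$end[i] - tx$start[i])
    idx <- (tx$start[i] + 1L):tx$end[i]
    if (tx$strand[i] == "+") {
      plus[[tx$chrom[i]]][idx] <- plus[[tx$chrom[i]]][idx] + dens
    } else {
      minus[[tx$chrom[i]]][idx] <- minus[[tx$chrom[i]]][idx] + dens
    }
  }
  stranded_expression(coverage_track(plus, cs, "+"),
                      coverage_track(minus, cs, "-"),
                      condition, replicate)
}

#' Write a simulated dataset to disk
#'
#' Emits the same plain-text formats the readers consume: `annotation.gff3`,
#' `chrom.sizes`, `chip.bedGraph`, `input.bedGraph`, `counts.tsv` (with a
#' `sample_info.tsv` companion) and `truth.tsv`.
#'
#' @param config a [sim_config()].
#' @param seed master seed.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the list of generated objects.
#' @export
write_simulation <- function(config, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config, seed)
  chip <- simulate_chip(sim$catalog, sim$truth, config, seed)
  rna <- simulate_rna(sim$catalog, sim$truth, config, seed)
  write_annotation(sim$catalog, file.path(out_dir, "annotation.gff3"))
  write_chrom_sizes(sim$catalog$chrom_sizes, file.path(out_dir, "chrom.sizes"))
  write_coverage(chip$chip, file.path(out_dir, "chip.bedGraph"))
  write_coverage(chip$input, file.path(out_dir, "input.bedGraph"))
  write.table(data.frame(id = rownames(rna$counts), rna$counts,
                         check.names = FALSE),
              file.path(out_dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(rna$col_data, file.path(out_dir, "sample_info.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(catalog = sim$catalog, truth = sim$truth,
                 chip = chip, rna = rna))
}
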