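# ChIP-seq processing: RPM normalisation, ratio-based background
# subtraction, gene-anatomy partition, metagene profiles, 25-dimensional
# occupancy vectors, clustering and end-enrichment calls.

#' Reads-per-million normalisation
#'
#' Multiplies every per-bp value by `1e6 / total_mapped`.
#'
#' @param track a `CoverageTrack` with `total_mapped > 0`.
#' @param total_mapped optional override of the track's read count.
#' @return a `CoverageTrack` in RPM units (`total_mapped` is retained so
#'   repeated calls are explicit, not implicit).
#' @export
normalize_rpm <- function(track, total_mapped = track$total_mapped) {
  if (is.null(total_mapped) || is.na(total_mapped) || total_mapped <= 0)
    stop("total_mapped must be > 0")
  f <- 1e6 / total_mapped
  out <- track
  out$cov <- lapply(track$cov, function(v) v * f)
  out
}

#' Ratio-based background subtraction
#'
#' The per-bp ChIP:input ratio `r(x)` is formed at positions with positive
#' input; positions with zero input are masked (excluded from the moments,
#' and their output signal is 0).  The background threshold is
#' `B = mean(r) + k * sd(r)` (sample standard deviation), and the final
#' signal is `max(r(x) - B, 0)`: wherever the background exceeds the ratio
#' the value is floored at zero.  Both tracks should be RPM-normalised
#' first.
#'
#' @param chip,input `CoverageTrack`s over the same chromosomes.
#' @param k multiplier on the standard deviation (default 1.2).
#' @param per_chromosome compute the ratio moments per chromosome instead of
#'   genome-wide (default genome-wide).
#' @return a `SignalTrack` (a `CoverageTrack` carrying `background_B`,
#'   `ratio_mean`, `ratio_sd` and `k`).
#' @export
subtract_background <- function(chip, input, k = 1.2,
                                per_chromosome = FALSE) {
  stopifnot(setequal(names(chip$cov), names(input$cov)))
  chroms <- names(chip$cov)
  ratio <- lapply(chroms, function(ch) {
    ci <- input$cov[[ch]]
    cc <- chip$cov[[ch]]
    r <- rep(NA_real_, length(ci))
    ok <- ci > 0
    r[ok] <- cc[ok] / ci[ok]
    r
  })
  names(ratio) <- chroms
  moments <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) stop("no usable input coverage")
    c(mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0)
  }
  if (per_chromosome) {
    mom <- lapply(ratio, moments)
    sig <- lapply(chroms, function(ch) {
      B <- mom[[ch]][["mean"]] + k * mom[[ch]][["sd"]]
      s <- pmax(ratio[[ch]] - B, 0)
      s[is.na(s)] <- 0
      s
    })
    gm <- moments(unlist(ratio, use.names = FALSE))
    B <- gm[["mean"]] + k * gm[["sd"]]
    rm_ <- gm[["mean"]]; rs <- gm[["sd"]]
  } else {
    gm <- moments(unlist(ratio, use.names = FALSE))
    rm_ <- gm[["mean"]]; rs <- gm[["sd"]]
    B <- rm_ + k * rs
    sig <- lapply(ratio, function(r) {
      s <- pmax(r - B, 0)
      s[is.na(s)] <- 0
      s
    })
  }
  names(sig) <- chroms
  out <- coverage_track(sig, chip$chrom_sizes, strand = "*",
                        total_mapped = chip$total_mapped)
  out$background_B <- B
  out$ratio_mean <- rm_
  out$ratio_sd <- rs
  out$k <- k
  class(out) <- c("SignalTrack", class(out))
  out
}

#' Partition signal by gene anatomy
#'
#' Assigns every base pair to exactly one of four categories: `five_prime`
#' (TSS +/- flank), `three_prime` (TES +/- flank), `cds` (inside a gene,
#' outside both end windows) and `igr` (more than `flank` bp from any gene).
#' Where windows of different genes overlap, precedence is
#' five_prime > three_prime > cds > igr.  Reports, per category, the total
#' signal, percent of total, assigned length and the length-normalised
#' density in RPKM (`total * 1e9 / (length * genome_total)`).
#'
#' @param signal a `SignalTrack` (or any `CoverageTrack`).
#' @param catalog a `TranscriptCatalog`; only coding transcripts define the
#'   anatomy.
#' @param flank end-window half-width in bp (default 300).
#' @return data.frame with one row per category.
#' @export
partition_signal <- function(signal, catalog, flank = 300) {
  tx <- catalog_transcripts(catalog, "coding")
  if (nrow(tx) == 0L) stop("catalog contains no coding transcripts")
  cats <- c("five_prime", "cds", "three_prime", "igr")
  assign_chrom <- function(ch) {
    n <- signal$chrom_sizes[[ch]]
    lab <- rep.int(4L, n)                                  # igr
    g <- tx[tx$chrom == ch, , drop = FALSE]
    fill <- function(lab, s, e, code) {
      s <- max(floor(s), 0); e <- min(ceiling(e), n)
      if (e > s) lab[(s + 1L):e] <- code
      lab
    }
    for (i in seq_len(nrow(g)))                            # cds = gene body
      lab <- fill(lab, g$start[i], g$end[i], 2L)
    for (i in seq_len(nrow(g)))                            # three_prime
      lab <- fill(lab, g$tes[i] - flank, g$tes[i] + flank, 3L)
    for (i in seq_len(nrow(g)))                            # five_prime wins
      lab <- fill(lab, g$tss[i] - flank, g$tss[i] + flank, 1L)
    lab
  }
  totals <- numeric(4); lengths <- numeric(4)
  for (ch in names(signal$cov)) {
    lab <- assign_chrom(ch)
    v <- signal$cov[[ch]]
    for (cde in 1:4) {
      sel <- lab == cde
      totals[cde] <- totals[cde] + sum(v[sel])
      lengths[cde] <- lengths[cde] + sum(sel)
    }
  }
  grand <- sum(totals)
  codes <- c(1L, 2L, 3L, 4L)
  data.frame(category = cats[codes],
             total = totals,
             percent = if (grand > 0) 100 * totals / grand else rep(NA_real_, 4),
             length_bp = lengths,
             density_rpkm = ifelse(lengths > 0 & grand > 0,
                                   totals * 1e9 / (lengths * grand), 0),
             stringsAsFactors = FALSE)
}

#' Metagene profile
#'
#' Averages signal across genes after aligning them at a common anchor.
#' `tss_aligned` / `tes_aligned` average the signal at each strand-aware
#' offset in `[-span, span)` (offset 0 = first base at/after the anchor in
#' the direction of transcription).  `scaled_cds` linearly rescales each
#' transcript's `cds_core(flank)` onto `n_bins` bins and averages; genes
#' with degenerate cores are excluded from that mode.
#'
#' @param signal a `CoverageTrack`/`SignalTrack`.
#' @param catalog a `TranscriptCatalog`.
#' @param mode one of `"tss_aligned"`, `"tes_aligned"`, `"scaled_cds"`.
#' @param span half-window in bp for the aligned modes (default 300).
#' @param n_bins number of bins for `scaled_cds` (default 100).
#' @param flank core trimming for `scaled_cds` (default 300).
#' @param kind which transcripts to average (default coding).
#' @param ids optional subset of transcript ids.
#' @return data.frame `(offset|bin, mean, n)` where `n` counts genes
#'   contributing at each position.
#' @export
metagene_profile <- function(signal, catalog,
                             mode = c("tss_aligned", "tes_aligned",
                                      "scaled_cds"),
                             span = 300, n_bins = 100, flank = 300,
                             kind = "coding", ids = NULL) {
  mode <- match.arg(mode)
  tx <- catalog_transcripts(catalog, kind)
  if (!is.null(ids)) tx <- tx[tx$id %in% ids, , drop = FALSE]
  if (nrow(tx) == 0L) stop("no eligible transcripts")
  if (mode %in% c("tss_aligned", "tes_aligned")) {
    stopifnot(span > 0)
    offsets <- seq.int(-span, span - 1L)
    acc <- numeric(length(offsets)); nn <- integer(length(offsets))
    for (i in seq_len(nrow(tx))) {
      t <- tx[i, ]
      v <- signal$cov[[t$chrom]]
      anchor <- if (mode == "tss_aligned") t$tss else t$tes
      pos <- if (t$strand == "+") anchor + offsets else anchor - 1L - offsets
      ok <- pos >= 0 & pos < length(v)
      acc[ok] <- acc[ok] + v[pos[ok] + 1L]
      nn <- nn + ok
    }
    if (all(nn == 0L)) stop("no eligible positions")
    data.frame(offset = offsets,
               mean = ifelse(nn > 0, acc / pmax(nn, 1L), NA_real_),
               n = nn)
  } else {
    stopifnot(n_bins >= 1)
    acc <- numeric(n_bins); nn <- integer(n_bins)
    for (i in seq_len(nrow(tx))) {
      t <- tx[i, ]
      core <- region_of(t, "cds_core", flank, catalog$chrom_sizes)
      if (core$degenerate) next
      v <- signal$cov[[t$chrom]][(core$start + 1L):core$end]
      if (t$strand == "-") v <- rev(v)
      L <- length(v)
      # mean of the signal over each of n_bins equal fractions of the core
      edges <- round(seq_len(n_bins) * L / n_bins)
      lo <- c(0L, edges[-n_bins])
      good <- edges > lo
      bm <- rep(NA_real_, n_bins)
      bm[good] <- vapply(which(good), function(b)
        mean(v[(lo[b] + 1L):edges[b]]), 0)
      ok <- !is.na(bm)
      acc[ok] <- acc[ok] + bm[ok]
      nn <- nn + ok
    }
    if (all(nn == 0L)) stop("no transcripts with a non-degenerate core")
    data.frame(bin = seq_len(n_bins),
               mean = ifelse(nn > 0, acc / pmax(nn, 1L), NA_real_),
               n = nn)
  }
}

# Mean signal over a transcription-direction window [a, b) relative to an
# anchor, clipped to the chromosome (length-corrected mean).
.window_mean <- function(signal, chrom, anchor, a, b, strand) {
  w <- .direction_window(anchor, a, b, strand)
  region_mean(signal, chrom, w[1], w[2])
}

#' 25-dimensional occupancy vectors
#'
#' For each transcript, mean signal in 25 windows laid out in the direction
#' of transcription: nine 50-bp windows spanning `[tss - 300, tss + 150)`
#' (covering the -2/-1/+1 nucleosome region at canonical ~150-bp spacing),
#' ten equal-width windows over the CDS core (`[tss + 150, tes - 150)`),
#' and six 50-bp windows spanning `[tes - 150, tes + 150)`.  Transcripts
#' too short for ten non-empty core windows (length < 310 bp) are excluded;
#' their ids are recorded in the `"excluded"` attribute.
#'
#' @param signal a `SignalTrack`/`CoverageTrack`.
#' @param catalog a `TranscriptCatalog`.
#' @param kind transcripts to vectorise (default coding).
#' @return numeric matrix (transcripts x 25) with transcript ids as row
#'   names; attribute `excluded` lists skipped ids.
#' @export
feature_vectors <- function(signal, catalog, kind = "coding") {
  tx <- catalog_transcripts(catalog, kind)
  len <- abs(tx$tes - tx$tss)
  eligible <- len >= 310
  excluded <- tx$id[!eligible]
  tx <- tx[eligible, , drop = FALSE]
  out <- matrix(0, nrow(tx), 25,
                dimnames = list(tx$id,
                                c(paste0("tss_", 1:9),
                                  paste0("cds_", 1:10),
                                  paste0("tes_", 1:6))))
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    L <- abs(t$tes - t$tss)
    tssw <- vapply(1:9, function(j)
      .window_mean(signal, t$chrom, t$tss, -300 + 50 * (j - 1),
                   -300 + 50 * j, t$strand), 0)
    coreL <- L - 300
    cedg <- round(seq_len(10) * coreL / 10)
    clo <- c(0, cedg[-10])
    cdsw <- vapply(1:10, function(j)
      .window_mean(signal, t$chrom, t$tss, 150 + clo[j], 150 + cedg[j],
                   t$strand), 0)
    tesw <- vapply(1:6, function(j)
      .window_mean(signal, t$chrom, t$tes, -150 + 50 * (j - 1),
                   -150 + 50 * j, t$strand), 0)
    out[i, ] <- c(tssw, cdsw, tesw)
  }
  attr(out, "excluded") <- excluded
  out
}

#' Hierarchical clustering of occupancy vectors
#'
#' Agglomerative clustering with Euclidean distances and average linkage.
#' Rows are ordered by transcript id before clustering so the result does
#' not depend on input order.
#'
#' @param vectors matrix from [feature_vectors()] (rownames = ids).
#' @param n_clusters number of clusters to cut the tree into.
#' @return list with `labels` (named integer vector) and `tree` (an
#'   `hclust` object).
#' @export
cluster_profiles <- function(vectors, n_clusters) {
  if (nrow(vectors) < 2) stop("need at least 2 vectors")
  if (n_clusters > nrow(vectors))
    stop("n_clusters exceeds the number of vectors")
  vectors <- vectors[order(rownames(vectors)), , drop = FALSE]
  tree <- hclust(dist(vectors, method = "euclidean"), method = "average")
  labels <- cutree(tree, k = n_clusters)
  list(labels = labels, tree = tree)
}

#' 5'/3' end enrichment per transcript
#'
#' Mean signal over the first `window` bp downstream of the TSS
#' (`five_prime_inner`) and the last `window` bp upstream of the TES
#' (`three_prime_inner`).  Windows are clipped for short transcripts and
#' the mean is length-corrected.
#'
#' @param signal a `SignalTrack`/`CoverageTrack`.
#' @param catalog a `TranscriptCatalog`.
#' @param window window size in bp (default 150).
#' @param kind transcripts to quantify (default coding).
#' @return data.frame `(id, five_prime_level, three_prime_level)`.
#' @export
quantify_end_enrichment <- function(signal, catalog, window = 150,
                                    kind = "coding") {
  stopifnot(window > 0)
  tx <- catalog_transcripts(catalog, kind)
  five <- numeric(nrow(tx)); three <- numeric(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    L <- abs(t$tes - t$tss)
    w <- min(window, L)
    five[i] <- .window_mean(signal, t$chrom, t$tss, 0, w, t$strand)
    three[i] <- .window_mean(signal, t$chrom, t$tes, -w, 0, t$strand)
  }
  data.frame(id = tx$id, five_prime_level = five,
             three_prime_level = three, stringsAsFactors = FALSE)
}

#' Classify occupancy levels as none / intermediate / high
#'
#' Default rule: `none` iff the background-subtracted level is exactly 0;
#' `high` iff the level is at least the mean of all strictly positive
#' levels; `intermediate` otherwise.  The rule is scale-invariant.
#'
#' @param levels non-negative numeric vector.
#' @param high_threshold optional explicit threshold overriding the
#'   positive-mean rule.
#' @return character vector of calls.
#' @export
classify_occupancy <- function(levels, high_threshold = NULL) {
  if (any(levels < 0)) stop("levels must be >= 0")
  if (is.null(high_threshold)) {
    pos <- levels[levels > 0]
    high_threshold <- if (length(pos) > 0) mean(pos) else Inf
  }
  ifelse(levels == 0, "none",
         ifelse(levels >= high_threshold, "high", "intermediate"))
}

#' Attach occupancy calls to an end-enrichment table
#'
#' @param ee output of [quantify_end_enrichment()].
#' @param high_threshold_5,high_threshold_3 optional explicit thresholds
#'   (default: mean of the strictly positive levels at each end).
#' @return `ee` with `five_call` and `three_call` columns added.
#' @export
add_occupancy_calls <- function(ee, high_threshold_5 = NULL,
                                high_threshold_3 = NULL) {
  ee$five_call <- classify_occupancy(ee$five_prime_level, high_threshold_5)
  ee$three_call <- classify_occupancy(ee$three_prime_level, high_threshold_3)
  ee
}
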