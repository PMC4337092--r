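# Core inference: link 3' occupancy peaks to antisense initiation via the
# >3-fold downstream/upstream rule, contingency counting, and the
# gene-resampling randomisation null.

#' Associate a peak with a putative transcript by the fold rule
#'
#' A peak is associated with a transcript if the RNA signal in the `window`
#' bp downstream of the peak (in the putative transcription direction) is
#' more than `fold_threshold`-fold the signal in the `window` bp upstream.
#' For an antisense candidate at a gene's 3' end, the putative direction is
#' opposite the host gene.  A pseudocount keeps the 0/0 case well-defined
#' (fold 1, not associated).
#'
#' @param peak list/row with `chrom`, `start`, `end`, and `strand` = the
#'   putative transcription direction.
#' @param expr a `StrandedExpression` (normalised).
#' @param window flanking window size in bp (default 150).
#' @param fold_threshold association threshold (default 3; rule is strict
#'   `>`).
#' @param pseudocount added to both means (default 0.1 signal units).
#' @return list `(downstream_mean, upstream_mean, fold, associated)`.
#' @export
associate_peak <- function(peak, expr, window = 150, fold_threshold = 3,
                           pseudocount = 0.1) {
  chrom <- as.character(peak$chrom)
  lim <- expr$plus$chrom_sizes[[chrom]]
  if (is.null(lim) || peak$start < 0 || peak$end > lim)
    stop("peak outside chromosome bounds")
  track <- .strand_track(expr, as.character(peak$strand))
  if (peak$strand == "+") {
    dn <- c(peak$end, peak$end + window)
    up <- c(peak$start - window, peak$start)
  } else {
    dn <- c(peak$start - window, peak$start)
    up <- c(peak$end, peak$end + window)
  }
  dmean <- region_mean(track, chrom, dn[1], dn[2])
  umean <- region_mean(track, chrom, up[1], up[2])
  fold <- (dmean + pseudocount) / (umean + pseudocount)
  list(downstream_mean = dmean, upstream_mean = umean, fold = fold,
       associated = fold > fold_threshold)
}

#' Fold-rule association for every gene's 3' window
#'
#' Builds each coding gene's 3'-inner window as the peak region, takes the
#' antisense direction (opposite the gene), and applies
#' [associate_peak()] against the antisense-strand RNA signal.
#'
#' @param catalog a `TranscriptCatalog`.
#' @param expr a normalised `StrandedExpression`.
#' @param window peak/flank window size (default 150).
#' @inheritParams associate_peak
#' @return data.frame `(id, downstream_mean, upstream_mean, fold,
#'   associated)`.
#' @export
associate_three_prime_peaks <- function(catalog, expr, window = 150,
                                        fold_threshold = 3,
                                        pseudocount = 0.1) {
  tx <- catalog_transcripts(catalog, "coding")
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    t <- tx[i, ]
    reg <- region_of(t, "three_prime_inner", window, catalog$chrom_sizes)
    reg$strand <- if (t$strand == "+") "-" else "+"
    a <- associate_peak(reg, expr, window, fold_threshold, pseudocount)
    data.frame(id = t$id, downstream_mean = a$downstream_mean,
               upstream_mean = a$upstream_mean, fold = a$fold,
               associated = a$associated, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' 3'-occupancy x antisense contingency
#'
#' Cross-tabulates genes by 3' occupancy call against antisense status and
#' attaches the independence expectations, two-sided Fisher p and odds
#' ratio.  The default construction compares the `high` against the `none`
#' class, excluding `intermediate` genes; one-vs-rest constructions are
#' available.
#'
#' @param end_calls data.frame with `id` and `three_call` (see
#'   [add_occupancy_calls()]).
#' @param as_assignments output of [classify_antisense()]; a gene "has
#'   antisense" if it hosts a non-excluded assignment.
#' @param which table construction: `"high_vs_none"` (default),
#'   `"high_vs_rest"` or `"none_vs_rest"`.
#' @return a `ContingencyResult` (see [fisher_exact()]) with a
#'   `row_labels` field.
#' @export
overlap_contingency <- function(end_calls, as_assignments,
                                which = c("high_vs_none", "high_vs_rest",
                                          "none_vs_rest")) {
  which <- match.arg(which)
  hosts <- unique(as_assignments$host[!as_assignments$excluded_convergent])
  has_as <- end_calls$id %in% hosts
  call <- end_calls$three_call
  grp <- switch(which,
    high_vs_none = ifelse(call == "high", "row1",
                          ifelse(call == "none", "row2", NA)),
    high_vs_rest = ifelse(call == "high", "row1", "row2"),
    none_vs_rest = ifelse(call == "none", "row1", "row2"))
  keep <- !is.na(grp)
  grp <- grp[keep]; has_as <- has_as[keep]
  a <- sum(grp == "row1" & has_as); b <- sum(grp == "row1" & !has_as)
  c_ <- sum(grp == "row2" & has_as); d <- sum(grp == "row2" & !has_as)
  if ((a + b) == 0 || (c_ + d) == 0)
    stop("empty occupancy class; cannot form the 2x2 table")
  res <- fisher_exact(a, b, c_, d)
  res$row_labels <- switch(which,
    high_vs_none = c("three_high", "three_none"),
    high_vs_rest = c("three_high", "rest"),
    none_vs_rest = c("three_none", "rest"))
  res
}

#' Randomisation null for 3'-window / antisense co-localisation
#'
#' The observed statistic is the number of 3'-inner windows among
#' `observed_genes` that contain an antisense TSS.  Each of `iters` null
#' iterations draws `n_regions` genes uniformly without replacement from
#' all genes with a defined 3' window and counts windows containing an
#' antisense TSS.  The empirical p is the add-one estimator
#' `(1 + #\{null >= observed\}) / (iters + 1)`, which never returns a
#' literal zero.
#'
#' @param catalog a `TranscriptCatalog`.
#' @param as_assignments output of [classify_antisense()] (non-excluded
#'   antisense TSSs define co-localisation).
#' @param observed_genes ids of the genes whose windows form the observed
#'   set (e.g. the high-3' class).
#' @param n_regions regions drawn per iteration (default:
#'   `length(observed_genes)`).
#' @param width window width in bp (default 150).
#' @param iters null iterations (default 1000).
#' @param seed RNG seed for the resampling.
#' @param tolerance extra bp allowed on each side of the window when
#'   testing TSS containment (default 0: strictly inside).
#' @return object of class `RandomizationResult`: list with
#'   `observed_count`, `null_counts`, `empirical_p`, `fdr_estimate`
#'   (`mean(null)/observed`) and `seed`.
#' @export
randomization_test <- function(catalog, as_assignments, observed_genes,
                               n_regions = length(observed_genes),
                               width = 150, iters = 1000, seed = 1,
                               tolerance = 0) {
  tx <- catalog_transcripts(catalog, "coding")
  pool <- tx[abs(tx$tes - tx$tss) >= width, , drop = FALSE]
  if (n_regions > nrow(pool))
    stop("n_regions exceeds the number of genes with a defined 3' window")
  keep <- !as_assignments$excluded_convergent
  as_tx <- catalog_transcripts(catalog, "noncoding")
  as_tx <- as_tx[as_tx$id %in% as_assignments$id[keep], , drop = FALSE]
  tssb <- tss_base(as_tx)
  contains <- vapply(seq_len(nrow(pool)), function(i) {
    reg <- region_of(pool[i, ], "three_prime_inner", width,
                     catalog$chrom_sizes)
    any(as_tx$chrom == reg$chrom &
          tssb >= reg$start - tolerance &
          tssb < reg$end + tolerance)
  }, FALSE)
  names(contains) <- pool$id
  obs_ids <- intersect(observed_genes, pool$id)
  observed <- sum(contains[obs_ids])
  null_counts <- .with_stream(seed, 0L, function()
    vapply(seq_len(iters), function(it)
      sum(contains[sample.int(nrow(pool), n_regions)]), 0))
  structure(list(observed_count = observed,
                 null_counts = null_counts,
                 empirical_p = (1 + sum(null_counts >= observed)) / (iters + 1),
                 fdr_estimate = if (observed > 0) mean(null_counts) / observed
                                else NA_real_,
                 n_regions = n_regions, iters = iters, seed = seed),
            class = "RandomizationResult")
}

#' @export
print.RandomizationResult <- function(x, ...) {
  cat(sprintf(paste0("Randomisation: observed %d of %d windows with an ",
                     "antisense TSS;\n  null mean %.1f, empirical p = %.4g ",
                     "(%d iterations, add-one estimator)\n"),
              x$observed_count, x$n_regions, mean(x$null_counts),
              x$empirical_p, x$iters))
  invisible(x)
}
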