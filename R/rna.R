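# Strand-specific RNA normalisation, per-transcript quantification, and
# antisense classification against the coding catalogue.

#' Construct a stranded expression object
#'
#' Holds a pair of strand-separated coverage tracks for one
#' condition/replicate, plus the normalisation factor applied so far.
#'
#' @param plus,minus `CoverageTrack`s for the + and - strands.
#' @param condition,replicate labels.
#' @return object of class `StrandedExpression`.
#' @export
stranded_expression <- function(plus, minus, condition = "c1",
                                replicate = "r1") {
  stopifnot(is(plus, "CoverageTrack"), is(minus, "CoverageTrack"))
  structure(list(plus = plus, minus = minus,
                 condition = condition, replicate = replicate,
                 scale_factor = 1),
            class = "StrandedExpression")
}

.strand_track <- function(expr, strand) {
  if (strand == "+") expr$plus else expr$minus
}

# Total signal attributable to a set of transcripts, summed on each
# transcript's own strand over its interval.
.transcript_signal_total <- function(expr, tx) {
  if (nrow(tx) == 0L) return(0)
  sum(vapply(seq_len(nrow(tx)), function(i)
    region_sum(.strand_track(expr, tx$strand[i]), tx$chrom[i],
               tx$start[i], tx$end[i]), 0))
}

#' Normalise stranded RNA signal to a fixed sense-strand total
#'
#' Computes one factor so that the total sense (coding-transcript) signal
#' equals `target` arbitrary units, and applies the same factor to both
#' strands, so antisense levels are rescaled identically and
#' sense:antisense ratios are preserved.
#'
#' @param expr a `StrandedExpression`.
#' @param catalog a `TranscriptCatalog` (defines the sense transcripts).
#' @param target normalisation target (default `1e8` arbitrary units).
#' @param method `"annotated"` sums signal over annotated coding
#'   transcripts (default); `"whole_strand"` uses all strand-assigned
#'   signal, crediting each strand's total to the genes encoded on it.
#' @return the rescaled `StrandedExpression` with `scale_factor` updated.
#' @export
normalize_stranded <- function(expr, catalog, target = 1e8,
                               method = c("annotated", "whole_strand")) {
  method <- match.arg(method)
  total <- if (method == "annotated") {
    .transcript_signal_total(expr, catalog_transcripts(catalog, "coding"))
  } else {
    track_total(expr$plus) + track_total(expr$minus)
  }
  if (total <= 0) stop("zero sense-strand signal; cannot normalise")
  f <- target / total
  expr$plus$cov <- lapply(expr$plus$cov, function(v) v * f)
  expr$minus$cov <- lapply(expr$minus$cov, function(v) v * f)
  expr$scale_factor <- expr$scale_factor * f
  expr
}

#' Per-transcript expression levels
#'
#' Level = summed per-bp signal on the transcript's strand over its
#' interval, normalised per kilobase of transcript length.
#'
#' @param expr a (normalised) `StrandedExpression`.
#' @param catalog a `TranscriptCatalog`.
#' @param ids optional subset of transcript ids.
#' @return data.frame `(id, kind, strand, level)`.
#' @export
quantify_transcripts <- function(expr, catalog, ids = NULL) {
  tx <- catalog$transcripts
  if (!is.null(ids)) tx <- tx[tx$id %in% ids, , drop = FALSE]
  if (any(tx$end <= tx$start)) stop("zero-length transcript")
  level <- vapply(seq_len(nrow(tx)), function(i) {
    s <- region_sum(.strand_track(expr, tx$strand[i]), tx$chrom[i],
                    tx$start[i], tx$end[i])
    s / ((tx$end[i] - tx$start[i]) / 1000)
  }, 0)
  data.frame(id = tx$id, kind = tx$kind, strand = tx$strand,
             level = level, stringsAsFactors = FALSE)
}

#' Assign non-coding transcripts to host genes as antisense
#'
#' A non-coding transcript is antisense to the coding gene on the opposite
#' strand with which it has the largest overlap, provided the overlap
#' covers at least `min_overlap` of the non-coding transcript.  Candidates
#' whose interval also overlaps a coding gene on their *own* strand are
#' flagged `excluded_convergent` (such signal is indistinguishable from
#' convergent read-through) and dropped from antisense quantification.
#' Transcripts matching no opposite-strand gene are reported as orphans.
#'
#' @param catalog a `TranscriptCatalog` containing both coding and
#'   non-coding transcripts (or pass `noncoding` / `coding` data.frames).
#' @param min_overlap minimum overlap fraction of the non-coding transcript
#'   (default 0.5).
#' @return data.frame `(id, host, overlap_fraction, excluded_convergent)`;
#'   attribute `orphans` lists unassigned ids.
#' @export
classify_antisense <- function(catalog, min_overlap = 0.5) {
  nc <- catalog_transcripts(catalog, "noncoding")
  cd <- catalog_transcripts(catalog, "coding")
  empty <- data.frame(id = character(), host = character(),
                      overlap_fraction = numeric(),
                      excluded_convergent = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(nc) == 0L || nrow(cd) == 0L) {
    attr(empty, "orphans") <- nc$id
    return(empty)
  }
  gr_nc <- GenomicRanges::GRanges(nc$chrom,
                                  IRanges::IRanges(nc$start + 1, nc$end),
                                  strand = nc$strand)
  gr_cd <- GenomicRanges::GRanges(cd$chrom,
                                  IRanges::IRanges(cd$start + 1, cd$end),
                                  strand = cd$strand)
  hits <- GenomicRanges::findOverlaps(gr_nc, gr_cd, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_nc)[qi], IRanges::ranges(gr_cd)[si]))
  same <- nc$strand[qi] == cd$strand[si]
  # convergent exclusion: any same-strand coding overlap
  excl_ids <- unique(nc$id[qi[same]])
  # best opposite-strand host per candidate
  opp <- !same
  rows <- lapply(seq_len(nrow(nc)), function(i) {
    sel <- which(qi == i & opp)
    if (length(sel) == 0L) return(NULL)
    frac <- ov[sel] / (nc$end[i] - nc$start[i])
    best <- sel[order(-frac, cd$id[si[sel]])][1L]
    data.frame(id = nc$id[i], host = cd$id[si[best]],
               overlap_fraction = ov[best] / (nc$end[i] - nc$start[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty[, 1:3]
  out <- out[out$overlap_fraction >= min_overlap, , drop = FALSE]
  out$excluded_convergent <- out$id %in% excl_ids
  attr(out, "orphans") <- setdiff(nc$id, out$id)
  rownames(out) <- NULL
  out
}
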