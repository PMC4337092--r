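# Per-base-pair coverage tracks.  A track is a named list of numeric
# vectors, one per chromosome, length equal to the chromosome length.

#' Construct a coverage track
#'
#' @param cov named list of non-negative numeric vectors (one per
#'   chromosome, one value per base pair).
#' @param chrom_sizes named vector of chromosome lengths; must match the
#'   vector lengths in `cov`.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded).
#' @param total_mapped read count the track derives from; defaults to the
#'   summed coverage (one coverage unit ~ one read-bp equivalent).
#' @return object of class `CoverageTrack`.
#' @export
coverage_track <- function(cov, chrom_sizes, strand = "*",
                           total_mapped = NULL) {
  stopifnot(is.list(cov), !is.null(names(cov)))
  if (!setequal(names(cov), names(chrom_sizes)))
    stop("cov and chrom_sizes name different chromosomes")
  cov <- cov[names(chrom_sizes)]
  for (ch in names(cov)) {
    if (length(cov[[ch]]) != chrom_sizes[[ch]])
      stop("coverage length for ", ch, " (", length(cov[[ch]]),
           ") != chromosome length (", chrom_sizes[[ch]], ")")
    if (any(cov[[ch]] < 0)) stop("negative coverage on ", ch)
  }
  if (!strand %in% c("+", "-", "*")) stop("strand must be +, - or *")
  if (is.null(total_mapped))
    total_mapped <- sum(vapply(cov, sum, 0))
  structure(list(cov = cov,
                 chrom_sizes = setNames(as.numeric(chrom_sizes),
                                        names(chrom_sizes)),
                 strand = strand,
                 total_mapped = as.numeric(total_mapped)),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("%s: %d chromosome(s), %.0f bp, strand %s, total signal %.4g\n",
              class(x)[1L], length(x$cov), sum(x$chrom_sizes), x$strand,
              track_total(x)))
  invisible(x)
}

#' Total signal in a track
#' @param track a `CoverageTrack`
#' @return scalar sum over all base pairs
#' @export
track_total <- function(track) sum(vapply(track$cov, sum, 0))

#' Zero-filled track over a genome
#' @param chrom_sizes named vector
#' @param strand strand label
#' @export
empty_track <- function(chrom_sizes, strand = "*") {
  coverage_track(lapply(chrom_sizes, function(n) numeric(n)),
                 chrom_sizes, strand, total_mapped = 0)
}

# Sum / mean of a track over [start, end) on a chromosome, clipped to
# bounds; mean divides by the clipped length (length-corrected).
region_sum <- function(track, chrom, start, end) {
  v <- track$cov[[chrom]]
  if (is.null(v)) stop("chromosome not in track: ", chrom)
  s <- max(floor(start), 0); e <- min(ceiling(end), length(v))
  if (e <= s) return(0)
  sum(v[(s + 1L):e])
}

region_mean <- function(track, chrom, start, end) {
  v <- track$cov[[chrom]]
  if (is.null(v)) stop("chromosome not in track: ", chrom)
  s <- max(floor(start), 0); e <- min(ceiling(end), length(v))
  if (e <= s) return(0)
  mean(v[(s + 1L):e])
}

#' Read a bedGraph file into a coverage track
#'
#' Base pairs not covered by any bedGraph interval are 0.  Overlapping
#' intervals are rejected as ambiguous.
#'
#' @param path bedGraph file.
#' @param chrom_sizes named vector or path to a chrom.sizes TSV.
#' @param strand strand label to attach (`"+"`, `"-"`, `"*"`).
#' @param total_mapped optional read count; defaults to the summed coverage.
#' @return a [coverage_track()].
#' @export
read_coverage <- function(path, chrom_sizes, strand = "*",
                          total_mapped = NULL) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  chrom_sizes <- .read_chrom_sizes(chrom_sizes)
  cov <- lapply(chrom_sizes, function(n) numeric(n))
  info <- file.info(path)
  nonempty <- is.finite(info$size) && info$size > 0 &&
    any(nzchar(readLines(path, n = 5L, warn = FALSE)))
  if (nonempty) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) > 0L) {
      df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = BiocGenerics::start(gr) - 1L,
                       end = BiocGenerics::end(gr),
                       score = as.numeric(S4Vectors::mcols(gr)$score),
                       stringsAsFactors = FALSE)
      if (any(df$score < 0)) stop("negative value(s) in ", path)
      bad <- setdiff(df$chrom, names(chrom_sizes))
      if (length(bad) > 0L)
        stop("chromosome(s) not in chrom_sizes: ", paste(bad, collapse = ", "))
      for (ch in unique(df$chrom)) {
        d <- df[df$chrom == ch, ]
        d <- d[order(d$start), ]
        if (any(d$end > chrom_sizes[[ch]]))
          stop("interval beyond chromosome end on ", ch)
        if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
          stop("overlapping bedGraph intervals on ", ch,
               " (ambiguous per-bp value)")
        for (i in seq_len(nrow(d)))
          cov[[ch]][(d$start[i] + 1L):d$end[i]] <- d$score[i]
      }
    }
  }
  coverage_track(cov, chrom_sizes, strand, total_mapped)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are merged; zero runs are omitted, so writing and
#' re-reading a track is an identity.
#'
#' @param track a `CoverageTrack`.
#' @param path output file.
#' @export
write_coverage <- function(track, path) {
  rows <- lapply(names(track$cov), function(ch) {
    r <- rle(track$cov[[ch]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = start[keep], end = end[keep],
               score = r$values[keep], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    file.create(path)
  } else {
    write.table(format(df, scientific = FALSE, trim = TRUE), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Pearson correlation between two tracks
#'
#' Simple replicate-agreement QC: the per-base-pair Pearson correlation over
#' the genome shared by the two tracks.
#'
#' @param a,b `CoverageTrack`s over the same chromosomes.
#' @export
track_correlation <- function(a, b) {
  stopifnot(setequal(names(a$cov), names(b$cov)))
  x <- unlist(a$cov[names(a$cov)], use.names = FALSE)
  y <- unlist(b$cov[names(a$cov)], use.names = FALSE)
  cor(x, y)
}
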