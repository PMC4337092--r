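# Transcript catalog: the coordinate frame for every downstream operation.
# Internal coordinates are 0-based half-open everywhere; GFF3's 1-based
# closed convention is converted at I/O only.

#' Build a transcript catalog
#'
#' A `TranscriptCatalog` holds all annotated transcripts (sense ORF-Ts and
#' candidate non-coding transcripts) together with chromosome lengths.
#' Coordinates are 0-based half-open.  The transcription start site (TSS) and
#' end site (TES) are strand-aware: for a `+` transcript the TSS is the
#' `start` coordinate and the TES the `end` coordinate; for a `-` transcript
#' the roles are swapped, so `tss < tes` iff the strand is `+`.
#'
#' @param transcripts data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`) and `kind` (`"coding"` or `"noncoding"`).
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @return An object of class `TranscriptCatalog`.
#' @export
transcript_catalog <- function(transcripts, chrom_sizes) {
  required <- c("id", "chrom", "start", "end", "strand", "kind")
  missing <- setdiff(required, names(transcripts))
  if (length(missing) > 0L)
    stop("transcripts is missing column(s): ", paste(missing, collapse = ", "))
  tx <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  tx$id <- as.character(tx$id)
  tx$chrom <- as.character(tx$chrom)
  tx$start <- as.numeric(tx$start)
  tx$end <- as.numeric(tx$end)
  tx$strand <- as.character(tx$strand)
  tx$kind <- as.character(tx$kind)
  if (anyDuplicated(tx$id))
    stop("duplicate transcript id(s): ",
         paste(unique(tx$id[duplicated(tx$id)]), collapse = ", "))
  if (!all(tx$strand %in% c("+", "-")))
    stop("every transcript must be stranded ('+' or '-')")
  if (!all(tx$kind %in% c("coding", "noncoding")))
    stop("kind must be 'coding' or 'noncoding'")
  if (any(tx$start < 0) || any(tx$end <= tx$start))
    stop("invalid interval: need 0 <= start < end")
  if (!all(tx$chrom %in% names(chrom_sizes)))
    stop("transcript chromosome(s) absent from chrom_sizes: ",
         paste(setdiff(tx$chrom, names(chrom_sizes)), collapse = ", "))
  if (any(tx$end > chrom_sizes[tx$chrom]))
    stop("transcript(s) extend beyond chromosome length")
  tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  tx$tes <- ifelse(tx$strand == "+", tx$end, tx$start)
  rownames(tx) <- tx$id
  structure(list(transcripts = tx,
                 chrom_sizes = setNames(as.numeric(chrom_sizes),
                                        names(chrom_sizes))),
            class = "TranscriptCatalog")
}

#' @export
print.TranscriptCatalog <- function(x, ...) {
  tx <- x$transcripts
  cat(sprintf("TranscriptCatalog: %d transcripts (%d coding, %d noncoding) on %d chromosome(s)\n",
              nrow(tx), sum(tx$kind == "coding"), sum(tx$kind == "noncoding"),
              length(x$chrom_sizes)))
  invisible(x)
}

#' Subset a catalog by transcript kind
#' @param catalog a `TranscriptCatalog`
#' @param kind `"coding"` or `"noncoding"`
#' @return data.frame of transcripts of that kind
#' @export
catalog_transcripts <- function(catalog, kind = NULL) {
  tx <- catalog$transcripts
  if (!is.null(kind)) tx <- tx[tx$kind %in% kind, , drop = FALSE]
  tx
}

## -- strand-aware region arithmetic ---------------------------------------

# Genomic [start, end) for a window given in transcription-direction
# coordinates [a, b) relative to an anchor position (tss or tes, both in the
# 0-based half-open frame where a '-' transcript's anchor is its exclusive
# right coordinate).
.direction_window <- function(anchor, a, b, strand) {
  if (strand == "+") c(anchor + a, anchor + b) else c(anchor - b, anchor - a)
}

#' Strand-aware anatomical regions of a transcript
#'
#' Computes one of five regions in transcription-direction coordinates:
#' \describe{
#'   \item{five_prime_flank}{`[tss - flank, tss + flank)`}
#'   \item{five_prime_inner}{first `flank` bp downstream of the TSS, inside
#'     the transcript}
#'   \item{three_prime_inner}{last `flank` bp upstream of the TES, inside the
#'     transcript}
#'   \item{three_prime_flank}{`[tes - flank, tes + flank)`}
#'   \item{cds_core}{the transcript minus the two inner flanks}
#' }
#' Regions are clipped to chromosome bounds.  A transcript shorter than
#' `2 * flank` yields a degenerate (empty) `cds_core`, flagged rather than
#' raised as an error.
#'
#' @param t one-row data.frame (a row of `catalog$transcripts`) or a list
#'   with fields `chrom`, `start`, `end`, `strand`, `tss`, `tes`.
#' @param which region name, see above.
#' @param flank window size in bp (> 0).
#' @param chrom_sizes optional named vector used for clipping.
#' @return list with `chrom`, `start`, `end`, `strand`, `degenerate`.
#' @export
region_of <- function(t, which = c("five_prime_flank", "three_prime_flank",
                                   "five_prime_inner", "three_prime_inner",
                                   "cds_core"),
                      flank, chrom_sizes = NULL) {
  which <- match.arg(which)
  stopifnot(flank > 0)
  strand <- as.character(t$strand)
  tss <- as.numeric(t$tss); tes <- as.numeric(t$tes)
  len <- abs(tes - tss)
  win <- switch(which,
    five_prime_flank  = .direction_window(tss, -flank, flank, strand),
    five_prime_inner  = .direction_window(tss, 0, min(flank, len), strand),
    three_prime_inner = .direction_window(tes, -min(flank, len), 0, strand),
    three_prime_flank = .direction_window(tes, -flank, flank, strand),
    cds_core          = .direction_window(tss, flank, len - flank, strand))
  degenerate <- win[2] <= win[1]
  if (degenerate) win[2] <- win[1] <- max(win[1], 0)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[[as.character(t$chrom)]]
    win[1] <- max(win[1], 0); win[2] <- min(win[2], lim)
    if (win[2] < win[1]) { win[2] <- win[1]; degenerate <- TRUE }
  } else {
    win[1] <- max(win[1], 0)
    win[2] <- max(win[2], win[1])
  }
  list(chrom = as.character(t$chrom), start = win[1], end = win[2],
       strand = strand, degenerate = degenerate)
}

# Vectorised regions for a whole catalog; returns a data.frame aligned with
# catalog$transcripts rows.
transcript_regions <- function(catalog, which, flank, kind = NULL) {
  tx <- catalog_transcripts(catalog, kind)
  if (nrow(tx) == 0L)
    return(data.frame(id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), degenerate = logical()))
  out <- lapply(seq_len(nrow(tx)), function(i)
    region_of(tx[i, ], which, flank, catalog$chrom_sizes))
  data.frame(id = tx$id,
             chrom = vapply(out, `[[`, "", "chrom"),
             start = vapply(out, `[[`, 0, "start"),
             end = vapply(out, `[[`, 0, "end"),
             strand = vapply(out, `[[`, "", "strand"),
             degenerate = vapply(out, `[[`, FALSE, "degenerate"),
             stringsAsFactors = FALSE)
}

# First transcribed base of each transcript (genomic coordinate of the TSS
# base itself, which for '-' transcripts is end - 1).
tss_base <- function(tx) ifelse(tx$strand == "+", tx$start, tx$end - 1)

## -- annotation I/O --------------------------------------------------------

.read_chrom_sizes <- function(chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L &&
      file.exists(chrom_sizes)) {
    cs <- read.delim(chrom_sizes, header = FALSE,
                     col.names = c("chrom", "size"),
                     stringsAsFactors = FALSE)
    return(setNames(as.numeric(cs$size), cs$chrom))
  }
  chrom_sizes
}

#' Read transcript annotation from GFF3 or BED12
#'
#' GFF3 records use 1-based closed coordinates and are converted to the
#' internal 0-based half-open frame; BED is already 0-based half-open.
#' Unstranded records are rejected and duplicate ids raise an error.  The
#' transcript kind is taken from a `kind` attribute (GFF3) when present;
#' otherwise records whose id matches `noncoding_pattern` are called
#' noncoding.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed12"`.
#' @param chrom_sizes named vector, or path to a two-column chrom.sizes TSV;
#'   if `NULL`, sequence lengths embedded in the GFF3 header are used, and
#'   failing that the maximum end coordinate per chromosome.
#' @param noncoding_pattern regular expression on ids used to call kind when
#'   the file does not carry one.
#' @return a [transcript_catalog()].
#' @export
read_annotation <- function(path, format = c("gff3", "bed12"),
                            chrom_sizes = NULL,
                            noncoding_pattern = "^AS_") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gff3") .validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (length(gr) == 0L) stop("no records in ", path)
  md <- S4Vectors::mcols(gr)
  ids <- if (format == "gff3") {
    if (!is.null(md$ID)) as.character(md$ID) else as.character(md$Name)
  } else as.character(md$name)
  if (any(is.na(ids)) || any(ids == ""))
    stop("record(s) without an id in ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("unstranded record(s) rejected: ",
         paste(head(ids[strand == "*"], 5L), collapse = ", "))
  kind <- if (format == "gff3" && !is.null(md$kind)) {
    as.character(md$kind)
  } else if (format == "gff3" && !is.null(md$type)) {
    ifelse(as.character(md$type) %in% c("ncRNA", "antisense_RNA"),
           "noncoding", "coding")
  } else {
    ifelse(grepl(noncoding_pattern, ids), "noncoding", "coding")
  }
  kind[is.na(kind)] <- "coding"
  tx <- data.frame(id = ids,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1,
                   end = BiocGenerics::end(gr),
                   strand = strand, kind = kind,
                   stringsAsFactors = FALSE)
  if (is.null(chrom_sizes) && format == "gff3") {
    sr <- grep("^##sequence-region", readLines(path, warn = FALSE),
               value = TRUE)
    if (length(sr) > 0L) {
      f <- strsplit(sr, "\\s+")
      chrom_sizes <- setNames(vapply(f, function(x) as.numeric(x[4]), 0),
                              vapply(f, `[[`, "", 2))
    }
  }
  if (is.null(chrom_sizes)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (all(!is.na(sl)) && length(sl) > 0L) {
      chrom_sizes <- sl
    } else {
      chrom_sizes <- tapply(tx$end, tx$chrom, max)
      chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
    }
  } else {
    chrom_sizes <- .read_chrom_sizes(chrom_sizes)
  }
  transcript_catalog(tx, chrom_sizes)
}

.validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^(#|\\s*$)", lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 0L)
  bad <- body[nf != 9L]
  if (length(bad) > 0L)
    stop("malformed GFF3 record at line ", bad[1L], " of ", path,
         " (expected 9 tab-separated fields, found ", nf[which(nf != 9L)[1L]], ")")
  invisible(TRUE)
}

#' Write a transcript catalog as GFF3
#'
#' Chromosome lengths are recorded in the header so that
#' [read_annotation()] round-trips the catalog exactly.
#'
#' @param catalog a `TranscriptCatalog`.
#' @param path output file.
#' @export
write_annotation <- function(catalog, path) {
  tx <- catalog$transcripts
  gr <- GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$start + 1, end = tx$end),
    strand = tx$strand,
    type = ifelse(tx$kind == "coding", "transcript", "ncRNA"),
    source = "zedsense",
    ID = tx$id, Name = tx$id, kind = tx$kind,
    seqinfo = GenomeInfoDb::Seqinfo(names(catalog$chrom_sizes),
                                    as.integer(catalog$chrom_sizes)))
  rtracklayer::export(gr, path, format = "gff3")
  # record chromosome lengths in the header for lossless round-trips
  lines <- readLines(path, warn = FALSE)
  sr <- sprintf("##sequence-region %s 1 %d", names(catalog$chrom_sizes),
                as.integer(catalog$chrom_sizes))
  writeLines(append(lines, sr, after = 1L), path)
  invisible(path)
}

#' Write a chrom.sizes two-column TSV
#' @param chrom_sizes named vector
#' @param path output file
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), as.integer(chrom_sizes)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
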