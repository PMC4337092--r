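# Gene-arrangement typology (tandem/convergent x close/far at the 3' side)
# and the four-class 5'/3' occupancy-pattern scheme, with their enrichment
# statistics.

#' Classify gene arrangement at the 3' side
#'
#' For each coding gene, the nearest coding neighbour on its 3' side
#' determines the category: same transcription direction = tandem, facing
#' transcription = convergent; the gap is measured between the gene's TES
#' and the neighbour's proximal boundary, and gaps strictly below
#' `close_threshold` are "close" (a gap of exactly the threshold is far).
#' The last gene on a chromosome arm is `undefined`.
#'
#' @param catalog a `TranscriptCatalog`.
#' @param close_threshold close/far boundary in bp (default 300).
#' @return data.frame `(id, category, neighbor, gap)`.
#' @export
classify_arrangement <- function(catalog, close_threshold = 300) {
  tx <- catalog_transcripts(catalog, "coding")
  out <- data.frame(id = tx$id, category = "undefined",
                    neighbor = NA_character_, gap = NA_real_,
                    stringsAsFactors = FALSE)
  for (ch in unique(tx$chrom)) {
    g <- tx[tx$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), ]
    for (i in seq_len(nrow(g))) {
      row <- match(g$id[i], out$id)
      if (g$strand[i] == "+") {
        cand <- which(g$start >= g$end[i])
        if (length(cand) == 0L) next
        j <- cand[which.min(g$start[cand])]
        gap <- g$start[j] - g$end[i]
        type <- if (g$strand[j] == "+") "tandem" else "convergent"
      } else {
        cand <- which(g$end <= g$start[i])
        if (length(cand) == 0L) next
        j <- cand[which.max(g$end[cand])]
        gap <- g$start[i] - g$end[j]
        type <- if (g$strand[j] == "-") "tandem" else "convergent"
      }
      out$category[row] <- paste0(type,
                                  if (gap < close_threshold) "_close" else "_far")
      out$neighbor[row] <- g$id[j]
      out$gap[row] <- max(gap, 0)
    }
  }
  out
}

#' 3' signal by arrangement category
#'
#' Totals and per-gene means of the 3'-end occupancy level for each
#' arrangement category.
#'
#' @param end_enrichments output of [quantify_end_enrichment()].
#' @param calls output of [classify_arrangement()].
#' @return data.frame `(category, n, total_three_prime, mean_three_prime,
#'   percent_of_total)`.
#' @export
category_signal <- function(end_enrichments, calls) {
  m <- merge(end_enrichments, calls, by = "id")
  cats <- c("tandem_close", "tandem_far", "convergent_close",
            "convergent_far", "undefined")
  rows <- lapply(cats, function(cc) {
    v <- m$three_prime_level[m$category == cc]
    data.frame(category = cc, n = length(v),
               total_three_prime = sum(v),
               mean_three_prime = if (length(v) > 0) mean(v) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  grand <- sum(out$total_three_prime)
  out$percent_of_total <- if (grand > 0) 100 * out$total_three_prime / grand
                          else NA_real_
  out
}

#' Category enrichment of a gene set
#'
#' For each arrangement category, Fisher's exact test of membership in a
#' focal gene set (e.g. hosts of down-regulated antisense transcripts)
#' against the genome composition: 2x2 of (in/out of category) x
#' (in/out of set), over genes with a defined category.
#'
#' @param gene_set character vector of gene ids.
#' @param calls output of [classify_arrangement()].
#' @return data.frame `(category, n_category, n_set_in_category, expected,
#'   odds_ratio, p_value)`; full `ContingencyResult`s in the
#'   `"tests"` attribute.
#' @export
category_enrichment <- function(gene_set, calls) {
  calls <- calls[calls$category != "undefined", , drop = FALSE]
  in_set <- calls$id %in% gene_set
  cats <- setdiff(unique(calls$category), NA)
  tests <- list()
  rows <- lapply(sort(cats), function(cc) {
    in_cat <- calls$category == cc
    a <- sum(in_cat & in_set); b <- sum(in_cat & !in_set)
    c_ <- sum(!in_cat & in_set); d <- sum(!in_cat & !in_set)
    if (a + b == 0) {
      warning("empty category skipped: ", cc)
      return(NULL)
    }
    res <- fisher_exact(a, b, c_, d)
    tests[[cc]] <<- res
    data.frame(category = cc, n_category = a + b, n_set_in_category = a,
               expected = res$expected[1, 1],
               odds_ratio = res$odds_ratio, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "tests") <- tests
  out
}

#' Four-class 5'/3' occupancy pattern
#'
#' Thresholds are the arithmetic means of the 5' and 3' levels over the
#' classified universe; each gene's class is set by the two indicator bits
#' (level >= threshold): class 1 = 5' only, class 2 = both, class 3 =
#' neither, class 4 = 3' only.
#'
#' @param end_enrichments output of [quantify_end_enrichment()].
#' @param universe optional gene ids restricting both the thresholds and
#'   the classification (e.g. genes with a detected antisense transcript).
#' @param positive_only use the mean of strictly positive levels as the
#'   thresholds instead of the plain mean (default `FALSE`).
#' @return data.frame `(id, five_prime_level, three_prime_level, class)`
#'   with attributes `tau5`, `tau3`.
#' @export
classify_htz_pattern <- function(end_enrichments, universe = NULL,
                                 positive_only = FALSE) {
  ee <- end_enrichments
  if (!is.null(universe)) ee <- ee[ee$id %in% universe, , drop = FALSE]
  if (nrow(ee) == 0L) stop("no genes to classify")
  mfun <- function(v) if (positive_only) mean(v[v > 0]) else mean(v)
  tau5 <- mfun(ee$five_prime_level)
  tau3 <- mfun(ee$three_prime_level)
  hi5 <- ee$five_prime_level >= tau5
  hi3 <- ee$three_prime_level >= tau3
  cls <- ifelse(hi5 & !hi3, 1L, ifelse(hi5 & hi3, 2L,
                ifelse(!hi5 & !hi3, 3L, 4L)))
  out <- data.frame(id = ee$id, five_prime_level = ee$five_prime_level,
                    three_prime_level = ee$three_prime_level,
                    class = cls, stringsAsFactors = FALSE)
  attr(out, "tau5") <- tau5
  attr(out, "tau3") <- tau3
  out
}

#' Sense fold-change distributions by occupancy class
#'
#' Joins sense-transcript log2 fold changes onto the four occupancy-pattern
#' classes and summarises each class: median and quartiles, a one-sample
#' two-tailed t-test of mean log2FC != 0, and pairwise Welch tests between
#' classes.
#'
#' @param classes output of [classify_htz_pattern()].
#' @param de a `DEResult` table whose `id` column matches gene ids.
#' @return list with `summary` (per-class data.frame) and `pairwise`
#'   (matrix of Welch p-values).
#' @export
class_fold_change_comparison <- function(classes, de) {
  m <- merge(classes, as.data.frame(de)[, c("id", "log2FC")], by = "id")
  present <- sort(unique(m$class))
  rows <- lapply(present, function(cl) {
    x <- m$log2FC[m$class == cl]
    p <- if (length(x) >= 2 && var(x) > 0)
      t.test(x, mu = 0)$p.value else NA_real_
    data.frame(class = cl, n = length(x),
               mean_log2FC = mean(x), median_log2FC = median(x),
               q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)),
               p_vs_zero = p, stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  k <- length(present)
  pw <- matrix(NA_real_, k, k, dimnames = list(present, present))
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      x <- m$log2FC[m$class == present[i]]
      y <- m$log2FC[m$class == present[j]]
      if (length(x) >= 2 && length(y) >= 2 && (var(x) > 0 || var(y) > 0))
        pw[i, j] <- pw[j, i] <- welch_t_test(x, y)$p_value
    }
  }
  list(summary = summary, pairwise = pw)
}
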