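# Differential-expression stand-in: median-of-ratios size factors and a
# negative-binomial likelihood-ratio test with trended dispersion
# moderation.  Externally computed DE tables can be imported instead.

#' Median-of-ratios size factors
#'
#' For each sample, the median over transcripts (positive in all samples)
#' of the ratio of its count to the transcript's geometric mean across
#' samples; factors are rescaled to geometric mean 1.
#'
#' @param counts transcripts x samples numeric matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts <= 0) == 0
  if (!any(ok))
    stop("no transcript has positive counts in every sample; ",
         "consider pooled normalisation")
  lg <- log(counts[ok, , drop = FALSE])
  ref <- rowMeans(lg)
  f <- exp(apply(lg - ref, 2, median))
  f / exp(mean(log(f)))
}

# NB log-likelihood of counts k with per-sample means q * sf at fixed size
# (1/dispersion); q maximised on a log grid via 1-D optimisation.
.nb_loglik <- function(k, sf, q, size) {
  sum(dnbinom(k, size = size, mu = pmax(q * sf, 1e-12), log = TRUE))
}

.nb_fit_q <- function(k, sf, size) {
  q0 <- sum(k) / sum(sf)
  if (q0 <= 0) return(list(q = 0, ll = .nb_loglik(k, sf, 1e-12, size)))
  opt <- optimize(function(lq) -.nb_loglik(k, sf, exp(lq), size),
                  interval = log(c(q0 / 50 + 1e-12, q0 * 50 + 1)))
  list(q = exp(opt$minimum), ll = -opt$objective)
}

#' Negative-binomial differential-expression test
#'
#' Per transcript: counts are modelled as negative binomial with
#' sample-specific means `q * size_factor`, condition-specific `q` under
#' the alternative and a common `q` under the null; the likelihood-ratio
#' statistic is referred to chi-squared with 1 df.  The dispersion used for
#' testing is the maximum of the transcript's method-of-moments estimate
#' and a mean-dispersion trend fitted across transcripts
#' (`a0 + a1/mean`), floored at `dispersion_floor` -- taking the maximum
#' guards the asymptotic reference against the severe underestimation of
#' per-transcript dispersions at small replicate numbers.  P-values are
#' Benjamini-Hochberg adjusted and calls made at `adjusted p < alpha`.
#'
#' @param counts transcripts x samples matrix of raw counts (rownames =
#'   ids).
#' @param design character/factor of condition labels (two levels; the
#'   second level is the numerator of the fold change).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param dispersion_floor lower bound on the testing dispersion
#'   (default 0.01).
#' @param class optional per-transcript labels (e.g. sense/antisense)
#'   carried into the result.
#' @return data.frame of class `DEResult`: `(id, class, baseMean, log2FC,
#'   pvalue, padj, call)` with `call` in up/down/unchanged.
#' @export
test_differential <- function(counts, design, alpha = 0.05,
                              dispersion_floor = 0.01, class = NULL) {
  counts <- as.matrix(counts)
  design <- as.character(design)
  lev <- unique(design)
  if (length(lev) != 2) stop("design must have exactly two conditions")
  if (min(table(design)) < 2) stop("need >= 2 samples per condition")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("t", seq_len(nrow(counts)))
  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  i1 <- design == lev[1]; i2 <- design == lev[2]
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  base_mean <- rowMeans(norm)
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  # method-of-moments dispersion from pooled within-condition variance
  v_within <- (apply(norm[, i1, drop = FALSE], 1, var) +
               apply(norm[, i2, drop = FALSE], 1, var)) / 2
  mu_within <- (m1 + m2) / 2
  disp_mom <- pmax((v_within - mu_within) / pmax(mu_within^2, 1e-8), 0)
  # parametric trend a0 + a1/mean over transcripts with usable estimates
  use <- disp_mom > 0 & mu_within > 0
  trend <- if (sum(use) >= 10) {
    fit <- lm(disp_mom[use] ~ I(1 / mu_within[use]))
    a <- pmax(coef(fit), 0)
    a[1] + a[2] / pmax(mu_within, 1e-8)
  } else rep(dispersion_floor, length(disp_mom))
  disp <- pmax(disp_mom, trend, dispersion_floor)
  n <- nrow(counts)
  pvalue <- numeric(n)
  for (i in seq_len(n)) {
    k <- counts[i, ]
    if (all(k == 0)) { pvalue[i] <- 1; next }
    size <- 1 / disp[i]
    ll0 <- .nb_fit_q(k, sf, size)$ll
    ll1 <- .nb_fit_q(k[i1], sf[i1], size)$ll +
           .nb_fit_q(k[i2], sf[i2], size)$ll
    stat <- max(2 * (ll1 - ll0), 0)
    pvalue[i] <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  padj <- bh_adjust(pvalue)
  call <- ifelse(padj < alpha & log2fc > 0, "up",
                 ifelse(padj < alpha & log2fc < 0, "down", "unchanged"))
  out <- data.frame(id = rownames(counts),
                    class = if (is.null(class)) NA_character_ else class,
                    baseMean = base_mean, log2FC = log2fc,
                    pvalue = pvalue, padj = padj, call = call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("DEResult", "data.frame"), alpha = alpha)
}

#' Import an externally computed differential-expression table
#'
#' Accepts the output of any DE tool exported as TSV with columns `id`,
#' `log2FC`, `pvalue`, `padj` (extra columns are kept).  Validates that
#' adjusted p-values are not below raw p-values and recomputes calls at
#' `alpha`.
#'
#' @param path TSV file.
#' @param alpha significance level for the recomputed calls.
#' @return `DEResult` data.frame.
#' @export
load_de_table <- function(path, alpha = 0.05) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "log2FC", "pvalue", "padj")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("DE table is missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$pvalue < 0 | df$pvalue > 1, na.rm = TRUE))
    stop("pvalue outside [0, 1]")
  if (any(df$padj < df$pvalue - 1e-9, na.rm = TRUE))
    stop("adjusted p-value below raw p-value; table is inconsistent")
  df$call <- ifelse(!is.na(df$padj) & df$padj < alpha & df$log2FC > 0, "up",
                    ifelse(!is.na(df$padj) & df$padj < alpha & df$log2FC < 0,
                           "down", "unchanged"))
  if (is.null(df$class)) df$class <- NA_character_
  structure(df, class = c("DEResult", "data.frame"), alpha = alpha)
}

#' Write a differential-expression table as TSV
#' @param de a `DEResult` data.frame.
#' @param path output file.
#' @export
write_de_table <- function(de, path) {
  write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
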