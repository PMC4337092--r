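# Statistical kernel shared by the contingency, randomisation and
# differential-expression stages.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the probability-mass two-sided p-value: the sum of
#' hypergeometric probabilities, at the observed margins, of all tables no
#' more probable than the one observed (with a small relative slack for
#' floating-point ties).  Tail sums are accumulated in log space so that
#' p-values far below the double underflow of a naive product (down to
#' ~1e-300 and beyond in the log domain) are computed stably — the extreme
#' genome-scale tables this pipeline produces require it.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = occupancy class,
#'   columns = antisense status: `a` = (row1, col1), `b` = (row1, col2),
#'   `c` = (row2, col1), `d` = (row2, col2).
#' @return object of class `ContingencyResult`: list with `table` (2x2
#'   matrix), `expected` (independence expectations, margins conserved
#'   exactly), `p_value`, `odds_ratio` (`(a d)/(b c)`), and
#'   `odds_ratio_infinite` flag.
#' @examples
#' fisher_exact(537, 488, 155, 2855)$p_value
#' @export
fisher_exact <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-9))
    stop("cell counts must be non-negative integers")
  x <- round(x)
  a <- x[["a"]]; b <- x[["b"]]; c <- x[["c"]]; d <- x[["d"]]
  N <- a + b + c + d
  if (N < 1) stop("empty table")
  r1 <- a + b; c1 <- a + c
  k <- max(0, r1 + c1 - N):min(r1, c1)
  lp <- dhyper(k, c1, N - c1, r1, log = TRUE)
  lobs <- dhyper(a, c1, N - c1, r1, log = TRUE)
  sel <- lp <= lobs + 1e-7          # additive log slack ~ relative slack on p
  m <- max(lp[sel])
  p <- min(1, exp(m + log(sum(exp(lp[sel] - m)))))
  expected <- outer(c(r1, c + d), c(c1, b + d)) / N
  dimnames(expected) <- list(c("row1", "row2"), c("col1", "col2"))
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  structure(list(table = matrix(c(a, c, b, d), 2,
                                dimnames = dimnames(expected)),
                 expected = expected,
                 p_value = p,
                 odds_ratio = or,
                 odds_ratio_infinite = is.infinite(or)),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat("2x2 contingency (observed | expected):\n")
  print(cbind(x$table, x$expected))
  cat(sprintf("Fisher two-sided p = %.4g; odds ratio = %.4g%s\n",
              x$p_value, x$odds_ratio,
              if (isTRUE(x$odds_ratio_infinite)) " (infinite)" else ""))
  invisible(x)
}

#' Welch's two-sample t-test (two-tailed)
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#'
#' @param x,y numeric samples, each of size >= 2, with nonzero variance in
#'   at least one.
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs n >= 2")
  if (var(x) == 0 && var(y) == 0)
    stop("degenerate samples: both variances are zero")
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Quantile bins
#'
#' Assigns each value to one of `k` quantile bins (edges at the i/k
#' empirical quantiles), ordered low to high.  Values tied with a bin edge
#' go to the lower bin.
#'
#' @param values numeric vector, `length(values) >= k`.
#' @param k number of bins (>= 2); 7 matches the occupancy-vs-level binning
#'   used downstream.
#' @return integer bin index per value, 1 (lowest) .. k (highest).
#' @export
quantile_bins <- function(values, k = 7) {
  if (k < 2) stop("k must be >= 2")
  if (length(values) < k) stop("need at least k values")
  edges <- quantile(values, probs = seq_len(k - 1) / k, names = FALSE,
                    type = 7)
  if (length(unique(values)) == 1L)
    warning("all values identical; every observation falls in bin 1")
  findInterval(values, edges, left.open = TRUE) + 1L
}
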