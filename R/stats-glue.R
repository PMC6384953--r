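# Shared statistical utilities: the normality gate used throughout the
# analyses (Kolmogorov-Smirnov, then t-test or Wilcoxon), and Benjamini-
# Hochberg FDR masking for per-frequency comparisons.

#' Kolmogorov-Smirnov normality gate
#'
#' Tests a sample against a normal with moments estimated from the data
#' (Lilliefors-style; the estimated-parameter caveat is accepted as the
#' field's convention). Degenerate samples (zero variance) are non-normal
#' only in the trivial sense and are flagged.
#'
#' @param x numeric sample
#' @param alpha gate level
#' @return list(normal = logical, p = numeric)
#' @export
ks_normal <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || stats::sd(x) == 0)
    return(list(normal = FALSE, p = NA_real_, degenerate = TRUE))
  p <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  list(normal = p > alpha, p = p, degenerate = FALSE)
}

#' Paired two-sided comparison with normality gate
#'
#' Differences are gated through [ks_normal()]: paired t-test when normal,
#' Wilcoxon signed-rank otherwise (exact null for n <= 25, normal
#' approximation with continuity correction above). All-zero differences are
#' degenerate and reported as p = 1.
#'
#' @param a,b paired samples, equal length >= 3
#' @return a `test_report` list: `test_name`, `statistic`, `p`, `n`,
#'   `alternative`, `degenerate`
#' @export
paired_compare <- function(a, b) {
  if (length(a) != length(b)) stop("paired_compare: length mismatch")
  if (length(a) < 3) stop("paired_compare: need length >= 3")
  d <- a - b
  n <- length(d)
  if (all(d == 0))
    return(test_report("wilcoxon_signed_rank", statistic = 0, p = 1, n = n,
                       degenerate = TRUE))
  gate <- ks_normal(d)
  if (isTRUE(gate$normal)) {
    ht <- stats::t.test(a, b, paired = TRUE)
    test_report("paired_t", statistic = unname(ht$statistic), p = ht$p.value,
                n = n)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = n <= 25, correct = TRUE))
    test_report("wilcoxon_signed_rank", statistic = unname(ht$statistic),
                p = ht$p.value, n = n)
  }
}

#' Construct a test report record
#' @param test_name character
#' @param statistic test statistic
#' @param p p-value in [0, 1]
#' @param n sample size
#' @param alternative sidedness
#' @param degenerate flag for degenerate inputs
#' @param corrected_p optional multiplicity-corrected p
#' @return list of class `test_report`
#' @export
test_report <- function(test_name, statistic, p, n, alternative = "two.sided",
                        degenerate = FALSE, corrected_p = NULL) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(list(test_name = test_name, statistic = statistic, p = p, n = n,
                 alternative = alternative, degenerate = degenerate,
                 corrected_p = corrected_p),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s: statistic = %.4g, p = %.4g (n = %d)%s\n",
              x$test_name, x$statistic, x$p, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Benjamini-Hochberg FDR significance mask
#'
#' @param pvalues p-values in [0, 1]
#' @param q target false discovery rate, in (0, 1)
#' @return logical mask, TRUE where the step-up procedure rejects
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop("bh_fdr: p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("bh_fdr: q must lie in (0, 1)")
  adj <- stats::p.adjust(pvalues, method = "BH")
  !is.na(adj) & adj <= q
}
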