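#' Fisher r-to-z transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, mapping a correlation
#' coefficient onto an approximately normal scale with standard error
#' `1 / sqrt(n - 3)`.
#'
#' @param r Correlation(s), strictly inside (-1, 1).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    stop("|r| must be < 1 for the Fisher transformation", call. = FALSE)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Significance of a single correlation coefficient
#'
#' Two-tailed p-value for the null hypothesis of zero correlation, via the
#' exact t-statistic `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees
#' of freedom.
#'
#' @param r Correlation, strictly inside (-1, 1).
#' @param n Sample size, at least 4. For a mirror-tree result the convention
#'   is the pairing count n = (N^2-N)/2 (see [mirror_tree()]).
#' @return Two-tailed p-value in (0, 1].
#' @export
single_corr_p <- function(r, n) {
  if (n < 4L) stop("n must be at least 4", call. = FALSE)
  if (abs(r) >= 1) stop("|r| must be < 1", call. = FALSE)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Significance of the difference between two correlation coefficients
#'
#' Both correlations are Fisher-transformed; the standardized difference
#' `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` is referred to the standard
#' normal, two-tailed. This is the test used to decide whether one candidate
#' partner's mirror-tree correlation is significantly higher than another's.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes, at least 4 each (pairing counts under the
#'   default mirror-tree convention).
#' @return A `correlation_comparison`: list with `r1`, `r2`, `n1`, `n2`,
#'   `z1`, `z2`, `z_stat` and `p_two_tailed`.
#' @export
#' @examples
#' compare_correlations(0.9427, 1128, 0.9274, 1485)
compare_correlations <- function(r1, n1, r2, n2) {
  if (n1 < 4L || n2 < 4L) stop("sample sizes must be at least 4",
                               call. = FALSE)
  z1 <- fisher_z(r1)
  z2 <- fisher_z(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z_stat <- (z1 - z2) / se
  structure(
    list(r1 = r1, r2 = r2, n1 = n1, n2 = n2, z1 = z1, z2 = z2,
         z_stat = z_stat, p_two_tailed = 2 * pnorm(-abs(z_stat))),
    class = "correlation_comparison"
  )
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat("<correlation_comparison>\n")
  cat(sprintf("  r1 = %.4f (n = %d)  vs  r2 = %.4f (n = %d)\n",
              x$r1, x$n1, x$r2, x$n2))
  cat(sprintf("  z = %.4f, two-tailed p = %.4g (%.2g to 2 s.f.)\n",
              x$z_stat, x$p_two_tailed, x$p_two_tailed))
  invisible(x)
}

#' Rank candidate partners by mirror-tree correlation
#'
#' Sorts candidates by decreasing correlation and compares the top candidate
#' against every other with [compare_correlations()]. A comparison with
#' p > 0.05 is flagged as a statistical tie with the top candidate: the data
#' cannot distinguish the two.
#'
#' @param x Either a data frame with columns `label`, `r` and `n`, or a named
#'   list of `mirror_tree_result` objects.
#' @return A `partner_ranking` data frame sorted by decreasing `r`, with
#'   columns `label`, `r`, `n`, `p_single`, `p_vs_top` (NA for the top row)
#'   and `tied_with_top`.
#' @export
rank_partners <- function(x) {
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, TRUE, "mirror_tree_result"))) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("mirror-tree results must be named by candidate label",
           call. = FALSE)
    }
    x <- data.frame(
      label = names(x),
      r = vapply(x, `[[`, 0, "r_ab"),
      n = vapply(x, `[[`, 0L, "n"),
      p_single = vapply(x, `[[`, 0, "p_single"),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(x), all(c("label", "r", "n") %in% names(x)))
  if (nrow(x) < 2L) {
    stop("ranking needs at least 2 candidates", call. = FALSE)
  }
  if (anyDuplicated(x$label)) {
    stop("duplicate candidate labels", call. = FALSE)
  }
  if (!"p_single" %in% names(x)) {
    x$p_single <- mapply(single_corr_p, x$r, x$n)
  }
  ord <- order(-x$r, x$label)
  x <- x[ord, , drop = FALSE]
  top <- x[1L, ]
  p_vs_top <- c(NA_real_, vapply(seq_len(nrow(x) - 1L) + 1L, function(i) {
    compare_correlations(top$r, top$n, x$r[i], x$n[i])$p_two_tailed
  }, 0))
  x$p_vs_top <- p_vs_top
  x$tied_with_top <- !is.na(p_vs_top) & p_vs_top > 0.05
  rownames(x) <- NULL
  class(x) <- c("partner_ranking", "data.frame")
  x
}
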