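#' Number of organism pairings
#'
#' The number of distinct unordered pairs of N common organisms,
#' `n = (N^2 - N) / 2` — the length of the vectorized strict upper triangle
#' of an N x N distance matrix, and the sample size used by the Fisher tests
#' under the default pairing convention.
#'
#' @param N Integer count(s) of common organisms, each at least 2.
#' @return Integer pairing count(s).
#' @export
#' @examples
#' pairing_count(41)  # 820
pairing_count <- function(N) {
  if (any(N < 2L) || any(N != round(N))) {
    stop("N must be an integer >= 2", call. = FALSE)
  }
  as.integer(N * (N - 1L) / 2L)
}

#' Vectorize a distance matrix over an ordered species list
#'
#' Extracts the strict upper triangle of the species-sorted submatrix in
#' row-major order: (1,2), (1,3), ..., (1,N), (2,3), ... The order is fixed by
#' the sorted labels, so the same species set always yields the same vector
#' regardless of the matrix's storage order.
#'
#' @param m A `coev_distmat` (or labelled symmetric matrix).
#' @param species Species to include; default all of `m`'s labels.
#' @return Numeric vector of length `pairing_count(length(species))`.
#' @export
vectorize_dist <- function(m, species = NULL) {
  labels <- rownames(m)
  if (is.null(species)) species <- labels
  missing <- setdiff(species, labels)
  if (length(missing)) {
    stop("species not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  s <- sort(species)
  sub <- t(unclass(m)[s, s, drop = FALSE])
  sub[lower.tri(sub)]
}

#' Pearson product-moment correlation
#'
#' Two-pass (centered) evaluation of the standard Pearson correlation
#' coefficient; the workhorse behind the mirror-tree statistic. Either vector
#' being constant makes the correlation undefined and is an error.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    stop("vectors have unequal lengths", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("need at least 3 observations", call. = FALSE)
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  min(1, max(-1, r))
}

#' Mirror-tree coevolution statistic for two protein families
#'
#' The core analysis: both families are restricted to their common species,
#' a p-distance matrix is built for each on that shared species set, both
#' matrices are vectorized in the same fixed species order, and the Pearson
#' correlation `r_AB` between the two distance vectors is computed. A value of
#' `r_AB` near 1 indicates that rate variation across lineages is shared by
#' the two families — the signature of coevolution (subject to the shared
#' underlying species phylogeny, which inflates all such correlations; judge
#' `r_AB` against controls, not in isolation).
#'
#' @param a,b `coev_alignment` objects (or record data frames) for the two
#'   families.
#' @param min_overlap Minimum common-species count (default 5).
#' @param min_sites Per-pair usable-site minimum for distances (default 50).
#' @param gap_policy Passed to [distance_matrix()].
#' @param sample_size Convention for the significance test of `r_AB`:
#'   `"pairings"` (default) uses n = (N^2-N)/2, `"organisms"` uses N. The
#'   pairing entries of a distance matrix are not independent observations, so
#'   the pairing-based p-value is anti-conservative; it is reported because it
#'   is the field's convention for this method.
#' @return A `mirror_tree_result`: list with `r_ab`, `N`, `n`, `p_single`,
#'   `species`, and the vectorized distances `dist_a`, `dist_b`.
#' @export
mirror_tree <- function(a, b, min_overlap = 5L, min_sites = 50L,
                        gap_policy = c("pairwise", "complete"),
                        sample_size = c("pairings", "organisms")) {
  gap_policy <- match.arg(gap_policy)
  sample_size <- match.arg(sample_size)
  a <- validate_alignment(a)
  b <- validate_alignment(b)
  common <- common_species(a, b, min_overlap = min_overlap)
  da <- distance_matrix(a, species = common, min_sites = min_sites,
                        gap_policy = gap_policy)
  db <- distance_matrix(b, species = common, min_sites = min_sites,
                        gap_policy = gap_policy)
  va <- vectorize_dist(da, common)
  vb <- vectorize_dist(db, common)
  N <- length(common)
  n <- pairing_count(N)
  r <- pearson_r(va, vb)
  m <- if (sample_size == "pairings") n else N
  p <- if (abs(r) < 1) single_corr_p(r, m) else 0
  structure(
    list(r_ab = r, N = N, n = n, p_single = p, species = common,
         sample_size = sample_size, dist_a = va, dist_b = vb),
    class = "mirror_tree_result"
  )
}

#' @export
print.mirror_tree_result <- function(x, ...) {
  cat("<mirror_tree_result>\n")
  cat(sprintf("  r_AB = %.4f over N = %d common species (n = %d pairings)\n",
              x$r_ab, x$N, x$n))
  cat(sprintf("  p (no correlation, %s convention) = %.3g\n",
              x$sample_size, x$p_single))
  invisible(x)
}
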