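#' Uncorrected p-distance between two aligned sequences
#'
#' The proportion of differing residues: substitutions divided by the number
#' of compared sites. Under the default pairwise-deletion policy a site is
#' compared only when both sequences carry a canonical residue there (gaps and
#' X are skipped for that pair alone).
#'
#' @param x,y Aligned residue strings of equal length.
#' @param min_sites Minimum number of usable sites required (default 50, to
#'   guard against distances estimated from near-empty overlaps; set to 1 for
#'   toy examples).
#' @return The distance in `[0, 1]`, with attribute `usable_sites`.
#' @export
#' @examples
#' p_distance("ACDEF", "ACDEY", min_sites = 1)  # 1 mismatch / 5 sites
p_distance <- function(x, y, min_sites = 50L) {
  cx <- encode_residue_string(x)
  cy <- encode_residue_string(y)
  if (length(cx) != length(cy)) {
    stop("sequences have unequal lengths (", length(cx), " vs ",
         length(cy), ")", call. = FALSE)
  }
  usable <- !is.na(cx) & !is.na(cy)
  n <- sum(usable)
  if (n == 0L) {
    stop("undefined distance: zero usable sites after pairwise deletion",
         call. = FALSE)
  }
  if (n < min_sites) {
    stop("only ", n, " usable sites; minimum is ", min_sites, call. = FALSE)
  }
  d <- sum(cx[usable] != cy[usable]) / n
  structure(d, usable_sites = n)
}

encode_residue_string <- function(x) {
  if (is.integer(x)) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], AA_CANONICAL)
}

#' Pairwise p-distance matrix of an alignment
#'
#' Computes all pairwise p-distances over the alignment's species (or a
#' subset), returning a symmetric species-by-species matrix with zero diagonal
#' and lexicographically sorted labels.
#'
#' @param aln A `coev_alignment` (or record data frame).
#' @param species Optional subset of species labels; default all.
#' @param min_sites Per-pair minimum of usable sites (see [p_distance()]).
#' @param gap_policy `"pairwise"` (default) deletes gap/ambiguous sites per
#'   pair; `"complete"` drops any column containing a gap or X in any retained
#'   sequence before computing distances.
#' @return A `coev_distmat`: a numeric matrix with species dimnames.
#' @export
distance_matrix <- function(aln, species = NULL, min_sites = 50L,
                            gap_policy = c("pairwise", "complete")) {
  gap_policy <- match.arg(gap_policy)
  aln <- validate_alignment(aln)
  if (!is.null(species)) {
    aln <- subset_alignment(aln, species)
  }
  m <- encode_alignment(aln)
  if (gap_policy == "complete") {
    keep <- colSums(is.na(m)) == 0L
    if (!any(keep)) {
      stop("complete deletion removed every column", call. = FALSE)
    }
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  valid <- !is.na(m)
  for (i in seq_len(n - 1L)) {
    ri <- m[i, ]
    vi <- valid[i, ]
    for (j in (i + 1L):n) {
      ok <- vi & valid[j, ]
      ns <- sum(ok)
      if (ns == 0L) {
        stop("undefined distance for pair (", rownames(m)[i], ", ",
             rownames(m)[j], "): zero usable sites", call. = FALSE)
      }
      if (ns < min_sites) {
        stop("pair (", rownames(m)[i], ", ", rownames(m)[j], ") has only ",
             ns, " usable sites; minimum is ", min_sites, call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(ri[ok] != m[j, ok]) / ns
    }
  }
  structure(d, class = c("coev_distmat", "matrix"))
}

#' @export
print.coev_distmat <- function(x, ...) {
  cat("<coev_distmat> ", nrow(x), " species\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Write a distance matrix to a text file
#'
#' Full-precision, lossless export in either a labelled tab-separated square
#' layout (header row and column) or the square PHYLIP dialect.
#'
#' @param m A `coev_distmat` or plain labelled numeric matrix.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  labels <- rownames(m)
  vals <- apply(unclass(m), 1:2, function(v) sprintf("%.17g", v))
  if (format == "tsv") {
    lines <- c(
      paste(c("species", labels), collapse = "\t"),
      vapply(seq_along(labels), function(i) {
        paste(c(labels[i], vals[i, ]), collapse = "\t")
      }, "")
    )
  } else {
    lines <- c(
      sprintf("%d", nrow(m)),
      vapply(seq_along(labels), function(i) {
        paste(c(sprintf("%-12s", labels[i]), vals[i, ]), collapse = "  ")
      }, "")
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a distance matrix written by [write_dist_matrix()]
#'
#' Auto-detects the TSV and square-PHYLIP dialects. The matrix must be square
#' and symmetric to within `tol`; the symmetrized matrix is returned.
#'
#' @param path Input path.
#' @param tol Maximum tolerated asymmetry (default 1e-9).
#' @return A `coev_distmat`.
#' @export
read_dist_matrix <- function(path, tol = 1e-9) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix file: ", path, call. = FALSE)
  if (grepl("^\\s*\\d+\\s*$", lines[1L])) {
    n <- as.integer(trimws(lines[1L]))
    rows <- strsplit(trimws(lines[-1L]), "\\s+")
    if (length(rows) != n) {
      stop("PHYLIP matrix announces ", n, " taxa but has ", length(rows),
           " rows", call. = FALSE)
    }
    labels <- vapply(rows, `[[`, "", 1L)
    d <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  } else {
    cells <- strsplit(lines, "\t", fixed = TRUE)
    labels <- vapply(cells[-1L], `[[`, "", 1L)
    d <- do.call(rbind,
                 lapply(cells[-1L], function(r) as.numeric(r[-1L])))
  }
  if (ncol(d) != nrow(d)) {
    stop("distance matrix is not square: ", nrow(d), " x ", ncol(d),
         call. = FALSE)
  }
  dimnames(d) <- list(labels, labels)
  if (max(abs(d - t(d))) > tol) {
    stop("distance matrix is asymmetric beyond tolerance ", tol,
         call. = FALSE)
  }
  d <- (d + t(d)) / 2
  structure(d, class = c("coev_distmat", "matrix"))
}
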