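#' Run a mirror-tree panel analysis
#'
#' Orchestrates the full analysis: one query family is correlated against a
#' panel of candidate partner families, candidates are ranked, and
#' (optionally) positive/negative control pairs are analysed to set the
#' candidate band. Panel members whose species overlap is insufficient are
#' recorded as skipped with the reason and the run continues; if every member
#' is skipped the run errors.
#'
#' @param config A named list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{query}{path to the query family's aligned FASTA (or a
#'       `coev_alignment`).}
#'     \item{panel}{named list/vector mapping candidate labels to alignment
#'       paths (or `coev_alignment` objects); labels must be unique.}
#'     \item{controls}{optional list with `positive` and `negative`, each a
#'       named list of two-element lists/vectors `(a, b)` of alignment paths.}
#'     \item{min_overlap, min_sites, gap_policy, sample_size}{optional
#'       overrides of the [mirror_tree()] defaults.}
#'   }
#' @param out_dir Optional output directory; when given, `ranking.tsv` and
#'   `report.json` are written there deterministically (fixed ordering and
#'   float formatting, so identical inputs give byte-identical JSON).
#' @return A `panel_report`: list with `results` (per-label
#'   `mirror_tree_result`), `ranking` (a [rank_partners()] table with a
#'   `candidate` flag when controls are present), `skipped` (label -> reason),
#'   `controls`, and `band` (see [control_banding()]).
#' @export
run_panel <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$query), !is.null(config$panel))
  panel <- config$panel
  if (is.null(names(panel)) || any(!nzchar(names(panel)))) {
    stop("panel members must be labelled", call. = FALSE)
  }
  if (anyDuplicated(names(panel))) {
    stop("duplicate panel labels", call. = FALSE)
  }
  min_overlap <- config$min_overlap %||% 5L
  min_sites <- config$min_sites %||% 50L
  gap_policy <- config$gap_policy %||% "pairwise"
  sample_size <- config$sample_size %||% "pairings"
  load_aln <- function(x) {
    if (inherits(x, "coev_alignment")) x else validate_alignment(read_fasta(x))
  }
  query <- load_aln(config$query)
  results <- list()
  skipped <- character()
  for (label in names(panel)) {
    res <- tryCatch(
      mirror_tree(query, load_aln(panel[[label]]),
                  min_overlap = min_overlap, min_sites = min_sites,
                  gap_policy = gap_policy, sample_size = sample_size),
      error = function(e) conditionMessage(e)
    )
    if (inherits(res, "mirror_tree_result")) {
      results[[label]] <- res
      message(sprintf("panel '%s': N = %d, n = %d, r = %.4f, p = %.3g",
                      label, res$N, res$n, res$r_ab, res$p_single))
    } else {
      skipped[[label]] <- res
      message(sprintf("panel '%s': skipped (%s)", label, res))
    }
  }
  if (!length(results)) {
    stop("every panel member was skipped", call. = FALSE)
  }
  ranking <- if (length(results) >= 2L) rank_partners(results) else {
    data.frame(label = names(results),
               r = results[[1L]]$r_ab, n = results[[1L]]$n,
               p_single = results[[1L]]$p_single,
               p_vs_top = NA_real_, tied_with_top = FALSE,
               stringsAsFactors = FALSE)
  }
  controls <- list(positive = list(), negative = list())
  for (kind in c("positive", "negative")) {
    for (label in names(config$controls[[kind]])) {
      pair <- config$controls[[kind]][[label]]
      controls[[kind]][[label]] <- mirror_tree(
        load_aln(pair[[1L]]), load_aln(pair[[2L]]),
        min_overlap = min_overlap, min_sites = min_sites,
        gap_policy = gap_policy, sample_size = sample_size)
    }
  }
  band <- NULL
  pos_r <- vapply(controls$positive, `[[`, 0, "r_ab")
  neg_r <- vapply(controls$negative, `[[`, 0, "r_ab")
  if (length(pos_r) && length(neg_r)) {
    band <- control_banding(max(pos_r), neg_r)
    ranking$candidate <- ranking$r > band$lower
  } else if (length(config$controls)) {
    warning("both positive and negative controls are needed for banding; ",
            "banding omitted", call. = FALSE)
  }
  report <- structure(
    list(results = results, ranking = ranking, skipped = skipped,
         controls = controls, band = band),
    class = "panel_report"
  )
  if (!is.null(out_dir)) {
    write_panel_report(report, out_dir)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Candidate band from control correlations
#'
#' The control logic of a mirror-tree screen: a negative-control pair (two
#' families with no plausible interaction) still yields a sizeable
#' correlation because both families share the underlying species phylogeny,
#' so a candidate is only meaningful when its correlation exceeds every
#' negative control's. The band runs from the largest negative-control r to
#' the positive-control r.
#'
#' @param positive_r Correlation of the positive-control pair.
#' @param negative_rs Correlations of one or more negative-control pairs.
#' @return List with `lower` (max negative r — the candidate threshold,
#'   strict), `upper` (positive r) and `degenerate` (TRUE when the threshold
#'   is not below the positive control, with a warning).
#' @export
control_banding <- function(positive_r, negative_rs) {
  stopifnot(length(positive_r) == 1L, length(negative_rs) >= 1L)
  lower <- max(negative_rs)
  degenerate <- lower >= positive_r
  if (degenerate) {
    warning("negative-control correlation (", format(lower),
            ") is not below the positive control (", format(positive_r),
            "); band is degenerate", call. = FALSE)
  }
  list(lower = lower, upper = positive_r, degenerate = degenerate)
}

write_panel_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ranking <- report$ranking
  num <- vapply(ranking, is.numeric, TRUE)
  ranking[num] <- lapply(ranking[num], function(v) sprintf("%.10g", v))
  write.table(ranking, file.path(out_dir, "ranking.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  as_plain <- function(res) {
    list(r_AB = round(res$r_ab, 10), N = res$N, n = res$n,
         p_single = signif(res$p_single, 10))
  }
  json <- list(
    ranking = lapply(seq_len(nrow(report$ranking)), function(i) {
      row <- report$ranking[i, ]
      list(label = row$label, r_AB = round(row$r, 10), n = row$n,
           p_single = signif(row$p_single, 10),
           p_vs_top = if (is.na(row$p_vs_top)) NULL else
             signif(row$p_vs_top, 10),
           tied_with_top = row$tied_with_top,
           candidate = if ("candidate" %in% names(row)) row$candidate
                       else NULL)
    }),
    skipped = as.list(report$skipped),
    controls = list(
      positive = lapply(report$controls$positive, as_plain),
      negative = lapply(report$controls$negative, as_plain)
    ),
    band = if (is.null(report$band)) NULL else
      list(lower = round(report$band$lower, 10),
           upper = round(report$band$upper, 10),
           degenerate = report$band$degenerate)
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.panel_report <- function(x, ...) {
  cat("<panel_report> ", nrow(x$ranking), " ranked, ",
      length(x$skipped), " skipped\n", sep = "")
  print(as.data.frame(x$ranking))
  if (!is.null(x$band)) {
    cat(sprintf("candidate band: r > %.4f (positive control %.4f)\n",
                x$band$lower, x$band$upper))
  }
  invisible(x)
}
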