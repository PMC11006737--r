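#' Map alignment columns to reference-sequence positions
#'
#' Residue numbering in conservation reports follows a chosen reference
#' species (for vertebrate pump alignments, conventionally the human
#' sequence). Columns where the reference carries a residue get 1-based
#' positions; columns where the reference is gapped map to NA.
#'
#' @param aln A `coev_alignment`.
#' @param reference Normalized species label of the reference sequence.
#' @return Integer vector of length `aln$length`: reference position per
#'   column, NA for reference-gap columns. Attribute `reference` stores the
#'   label.
#' @export
map_reference_positions <- function(aln, reference) {
  aln <- validate_alignment(aln)
  if (!reference %in% aln$species) {
    stop("reference species '", reference, "' not in alignment",
         call. = FALSE)
  }
  chars <- strsplit(aln$seqs[[reference]], "", fixed = TRUE)[[1L]]
  nongap <- chars != "-"
  if (!any(nongap)) {
    stop("reference sequence is all gaps", call. = FALSE)
  }
  map <- rep(NA_integer_, length(chars))
  map[nongap] <- seq_len(sum(nongap))
  structure(map, reference = reference)
}

#' Per-position conservation profile of an alignment
#'
#' For every reference position, tallies the residues observed across species
#' (gaps excluded from the denominator), reports the modal residue and its
#' frequency — the conservation fraction — and, when a class grouping is
#' supplied, the per-class modal fractions.
#'
#' @param aln A `coev_alignment`.
#' @param reference Reference species label for position numbering.
#' @param groups Optional species-to-class map: a named character vector, a
#'   two-column data frame (`species`, `group`), or a path to a YAML file of
#'   `species: class` entries. Species without an assignment fall in
#'   `"ungrouped"`.
#' @return A `conservation_profile` data frame with columns `position`,
#'   `ref_residue`, `n_nongap`, `n_gap`, `modal_residue`, `conservation`, and
#'   one `grp_<class>` column per class (modal non-gap fraction within the
#'   class, NA when the class has only gaps there). Attributes: `counts` (per
#'   position residue tables), `groups`, `reference`.
#' @export
conservation_profile <- function(aln, reference, groups = NULL) {
  aln <- validate_alignment(aln)
  map <- map_reference_positions(aln, reference)
  groups <- resolve_groups(groups, aln$species)
  mat <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(mat) <- aln$species
  cols <- which(!is.na(map))
  profile_row <- function(col) {
    res <- mat[, col]
    nongap <- res[res != "-"]
    counts <- sort(table(nongap), decreasing = TRUE)
    list(
      position = map[col],
      ref_residue = mat[reference, col],
      n_nongap = length(nongap),
      n_gap = length(res) - length(nongap),
      modal_residue = if (length(counts)) names(counts)[1L] else NA_character_,
      conservation = if (length(counts)) counts[[1L]] / length(nongap)
                     else NA_real_,
      counts = counts
    )
  }
  rows <- lapply(cols, profile_row)
  out <- data.frame(
    position = vapply(rows, `[[`, 0L, "position"),
    ref_residue = vapply(rows, `[[`, "", "ref_residue"),
    n_nongap = vapply(rows, `[[`, 0L, "n_nongap"),
    n_gap = vapply(rows, `[[`, 0L, "n_gap"),
    modal_residue = vapply(rows, `[[`, "", "modal_residue"),
    conservation = vapply(rows, `[[`, 0, "conservation"),
    stringsAsFactors = FALSE
  )
  for (g in sort(unique(groups))) {
    members <- names(groups)[groups == g]
    out[[paste0("grp_", g)]] <- vapply(cols, function(col) {
      res <- mat[members, col]
      nongap <- res[res != "-"]
      if (!length(nongap)) return(NA_real_)
      max(table(nongap)) / length(nongap)
    }, 0)
  }
  attr(out, "counts") <- setNames(lapply(rows, `[[`, "counts"), out$position)
  attr(out, "groups") <- groups
  attr(out, "reference") <- reference
  class(out) <- c("conservation_profile", "data.frame")
  out
}

resolve_groups <- function(groups, species) {
  if (is.null(groups)) {
    g <- setNames(rep("ungrouped", length(species)), species)
    return(g)
  }
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    y <- yaml::read_yaml(groups)
    groups <- vapply(y, as.character, "")
  }
  if (is.data.frame(groups)) {
    stopifnot(all(c("species", "group") %in% names(groups)))
    groups <- setNames(as.character(groups$group), groups$species)
  }
  stopifnot(is.character(groups), !is.null(names(groups)))
  out <- setNames(rep("ungrouped", length(species)), species)
  known <- intersect(names(groups), species)
  out[known] <- groups[known]
  out
}

#' Reference positions conserved above a threshold
#'
#' @param profile A `conservation_profile`.
#' @param threshold Minimum modal non-gap residue fraction, in (0, 1];
#'   the default 1.0 returns positions conserved across every species with a
#'   residue there.
#' @return Integer vector of reference positions. Monotone in `threshold`:
#'   raising it never adds positions.
#' @export
find_conserved <- function(profile, threshold = 1.0) {
  stopifnot(threshold > 0, threshold <= 1)
  profile$position[!is.na(profile$conservation) &
                     profile$conservation >= threshold]
}

#' Kinase consensus context around a candidate phosphosite
#'
#' For a reference position carrying a tyrosine, serine or threonine,
#' extracts each species' own ungapped sequence neighbourhood around the
#' residue aligned to that position and counts acidic (D/E) and basic (K/R)
#' flanking residues. Verdicts operationalize the two kinase-family context
#' preferences: Src-family tyrosine kinases favour nearby acidic residues
#' (especially glutamate), so a tyrosine with at least one acidic neighbour in
#' the window is tagged `"src-context"`; protein kinase C favours basic
#' flanking residues, so a serine/threonine with a basic residue on each side,
#' or at least two in total, is tagged `"pkc-context"`. Anything else is
#' `"none"`. These are descriptive tags, not a trained phosphosite predictor.
#'
#' @param aln A `coev_alignment`.
#' @param position Reference position (1-based, reference numbering).
#' @param reference Reference species label.
#' @param window_size Residues considered on each side, in the species' own
#'   ungapped coordinates. Default: 3 when the reference residue is Y, 5 when
#'   it is S/T.
#' @return A `kinase_context` data frame, one row per species: `species`,
#'   `residue` (NA when the species is gapped at the position), `window`
#'   (flanking residues as a string, centre bracketed), `acidic`, `basic`,
#'   `basic_left`, `basic_right`, `truncated` (window hit a sequence end),
#'   `verdict`. Attribute `summary` holds the fraction of species per verdict.
#' @export
kinase_context <- function(aln, position, reference, window_size = NULL) {
  aln <- validate_alignment(aln)
  map <- map_reference_positions(aln, reference)
  col <- which(!is.na(map) & map == position)
  if (length(col) != 1L) {
    stop("reference position ", position, " is not mapped", call. = FALSE)
  }
  ref_res <- substr(aln$seqs[[reference]], col, col)
  if (is.null(window_size)) {
    window_size <- if (ref_res == "Y") 3L else 5L
  }
  stopifnot(window_size >= 1L)
  rows <- lapply(aln$species, function(sp) {
    chars <- strsplit(aln$seqs[[sp]], "", fixed = TRUE)[[1L]]
    if (chars[col] == "-") {
      return(data.frame(species = sp, residue = NA_character_,
                        window = NA_character_, acidic = NA_integer_,
                        basic = NA_integer_, basic_left = NA_integer_,
                        basic_right = NA_integer_, truncated = NA,
                        verdict = "gap", stringsAsFactors = FALSE))
    }
    ungapped <- chars[chars != "-"]
    idx <- sum(chars[seq_len(col)] != "-")
    lo <- max(1L, idx - window_size)
    hi <- min(length(ungapped), idx + window_size)
    left <- if (lo < idx) ungapped[lo:(idx - 1L)] else character()
    right <- if (hi > idx) ungapped[(idx + 1L):hi] else character()
    res <- ungapped[idx]
    acidic <- sum(c(left, right) %in% ACIDIC_RESIDUES)
    b_left <- sum(left %in% BASIC_RESIDUES)
    b_right <- sum(right %in% BASIC_RESIDUES)
    verdict <- if (res == "Y" && acidic >= 1L) {
      "src-context"
    } else if (res %in% c("S", "T") &&
               ((b_left >= 1L && b_right >= 1L) || b_left + b_right >= 2L)) {
      "pkc-context"
    } else {
      "none"
    }
    data.frame(
      species = sp, residue = res,
      window = paste0(paste(left, collapse = ""), "[", res, "]",
                      paste(right, collapse = "")),
      acidic = acidic, basic = b_left + b_right,
      basic_left = b_left, basic_right = b_right,
      truncated = (idx - lo < window_size) || (hi - idx < window_size),
      verdict = verdict, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  tallied <- table(factor(out$verdict,
                          levels = c("src-context", "pkc-context",
                                     "none", "gap")))
  attr(out, "summary") <- tallied / nrow(out)
  attr(out, "position") <- position
  attr(out, "window_size") <- window_size
  class(out) <- c("kinase_context", "data.frame")
  out
}
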