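#' Read protein sequences from a FASTA file
#'
#' Parses each FASTA header into an accession-like identifier and a normalized
#' species label. Two header dialects are recognized: UniProt-style `OS=Genus
#' species` fields and NCBI-style bracketed organism names `[Genus species]`.
#' When neither is present the last two whitespace-separated tokens of the
#' description are used; a header with no description falls back to the
#' identifier itself.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param species_from Header dialect: `"auto"` (default) tries `OS=`, then
#'   brackets, then the fallback; `"os"` and `"bracket"` force one dialect and
#'   error when the field is absent.
#' @return A data frame with columns `id`, `species` (normalized,
#'   `genus_species`) and `residues` (uppercase).
#' @seealso [validate_alignment()], [normalize_species()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P1|A_HUMAN OS=Homo sapiens", "MGKA"), fa)
#' read_fasta(fa)
read_fasta <- function(path, species_from = c("auto", "os", "bracket")) {
  species_from <- match.arg(species_from)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  if (!startsWith(trimws(first), ">")) {
    stop("malformed FASTA (first record does not start with '>'): ",
         path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  residues <- toupper(as.character(set))
  parsed <- lapply(headers, parse_fasta_header, species_from = species_from)
  data.frame(
    id = vapply(parsed, `[[`, "", "id"),
    species = vapply(parsed, `[[`, "", "species"),
    residues = unname(residues),
    stringsAsFactors = FALSE
  )
}

parse_fasta_header <- function(header, species_from = "auto") {
  header <- trimws(header)
  id <- strsplit(header, "\\s+")[[1L]][1L]
  desc <- trimws(sub("^\\S+\\s*", "", header))
  os <- regmatches(header,
                   regexpr("OS=.*?(?=\\s+[A-Z]{2}=|$)", header, perl = TRUE))
  os <- if (length(os)) trimws(sub("^OS=", "", os)) else NA_character_
  br <- regmatches(header, regexpr("\\[[^]]+\\]", header))
  br <- if (length(br)) gsub("\\[|\\]", "", br) else NA_character_
  raw <- switch(species_from,
    os = {
      if (is.na(os)) stop("no OS= field in header: ", header, call. = FALSE)
      os
    },
    bracket = {
      if (is.na(br)) {
        stop("no bracketed organism in header: ", header, call. = FALSE)
      }
      br
    },
    auto = {
      if (!is.na(os)) {
        os
      } else if (!is.na(br)) {
        br
      } else if (nzchar(desc)) {
        toks <- strsplit(desc, "\\s+")[[1L]]
        paste(utils::tail(toks, 2L), collapse = " ")
      } else {
        id
      }
    }
  )
  list(id = id, species = normalize_species(raw))
}

#' Normalize a free-text organism name to a binomial label
#'
#' Lowercases, trims, and joins the genus and species epithet with an
#' underscore; subspecies, strain and variety tokens are dropped. Single-token
#' names pass through lowercased with a warning, since they cannot be resolved
#' to a binomial.
#'
#' @param raw Character vector of organism names.
#' @return Character vector of labels such as `"homo_sapiens"`. Idempotent.
#' @export
#' @examples
#' normalize_species(c("Homo sapiens", "Canis lupus familiaris"))
normalize_species <- function(raw) {
  stopifnot(is.character(raw), all(nzchar(trimws(raw))))
  out <- vapply(raw, function(x) {
    toks <- strsplit(tolower(trimws(x)), "[\\s_]+", perl = TRUE)[[1L]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 1L) {
      warning("single-token species name passed through: '", x, "'",
              call. = FALSE)
      toks
    } else {
      paste(toks[1:2], collapse = "_")
    }
  }, "", USE.NAMES = FALSE)
  out
}

#' Validate sequence records as a multiple alignment
#'
#' Checks that all residue strings have equal length, restricts characters to
#' the working alphabet (B/Z/U/O are remapped to X with a warning; anything
#' else is an error), and collapses duplicate species, keeping the record with
#' the longest ungapped sequence (ties broken by lexicographically smallest
#' id). Records are stored sorted by species label so downstream output is
#' reproducible regardless of input order.
#'
#' @param records Data frame with columns `id`, `species`, `residues`
#'   (as returned by [read_fasta()]), or an existing `coev_alignment`.
#' @return An object of class `coev_alignment`: a list with elements
#'   `species`, `ids`, `seqs` (named by species) and `length` (columns).
#' @export
validate_alignment <- function(records) {
  if (inherits(records, "coev_alignment")) {
    return(records)
  }
  stopifnot(is.data.frame(records),
            all(c("id", "species", "residues") %in% names(records)))
  if (nrow(records) < 2L) {
    stop("an alignment needs at least 2 records", call. = FALSE)
  }
  res <- toupper(records$residues)
  for (bad in names(AA_REMAP)) {
    hit <- grepl(bad, res, fixed = TRUE)
    if (any(hit)) {
      warning("residue '", bad, "' remapped to X in ",
              sum(hit), " record(s)", call. = FALSE)
      res <- gsub(bad, "X", res, fixed = TRUE)
    }
  }
  illegal <- gsub(paste0("[", paste(AA_ALPHABET, collapse = ""), "]"), "", res)
  if (any(nzchar(illegal))) {
    i <- which(nzchar(illegal))[1L]
    stop("illegal residue character(s) '", illegal[i], "' in record '",
         records$id[i], "'", call. = FALSE)
  }
  lens <- nchar(res)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1L])[1L]
    stop("ragged alignment: record '", records$id[off], "' has length ",
         lens[off], ", expected ", lens[1L], call. = FALSE)
  }
  df <- data.frame(id = records$id, species = records$species,
                   residues = res, stringsAsFactors = FALSE)
  # de-duplicate per species: longest ungapped sequence, then smallest id
  df$ungapped <- nchar(gsub("-", "", df$residues, fixed = TRUE))
  df <- df[order(df$species, -df$ungapped, df$id), , drop = FALSE]
  df <- df[!duplicated(df$species), , drop = FALSE]
  structure(
    list(
      species = df$species,
      ids = setNames(df$id, df$species),
      seqs = setNames(df$residues, df$species),
      length = lens[1L]
    ),
    class = "coev_alignment"
  )
}

#' @export
print.coev_alignment <- function(x, ...) {
  cat("<coev_alignment> ", length(x$species), " species x ", x$length,
      " sites\n", sep = "")
  shown <- head(x$species, 5L)
  cat("  species: ", paste(shown, collapse = ", "),
      if (length(x$species) > 5L) ", ...", "\n", sep = "")
  invisible(x)
}

#' Write sequence records or an alignment to FASTA
#'
#' @param x A record data frame (`id`, `species`, `residues`) or a
#'   `coev_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "coev_alignment")) {
    x <- data.frame(id = unname(x$ids), species = x$species,
                    residues = unname(x$seqs), stringsAsFactors = FALSE)
  }
  seqs <- Biostrings::BStringSet(setNames(x$residues, x$id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Species common to two alignments
#'
#' Lexicographically sorted intersection of the normalized species labels of
#' two alignments — the organism set over which a mirror-tree correlation is
#' computed.
#'
#' @param a,b `coev_alignment` objects.
#' @param min_overlap Minimum acceptable intersection size (default 5); a
#'   smaller overlap is an error since the downstream correlation would be
#'   meaningless.
#' @return Sorted character vector of species labels.
#' @export
common_species <- function(a, b, min_overlap = 5L) {
  a <- validate_alignment(a)
  b <- validate_alignment(b)
  common <- sort(intersect(a$species, b$species))
  if (length(common) < min_overlap) {
    stop("insufficient species overlap: ", length(common), " common species (minimum ",
         min_overlap, ")", call. = FALSE)
  }
  common
}

#' Restrict an alignment to a subset of species
#'
#' @param aln A `coev_alignment`.
#' @param species Species labels to keep (all must be present).
#' @return A `coev_alignment` over `species`, sorted by label.
#' @export
subset_alignment <- function(aln, species) {
  aln <- validate_alignment(aln)
  missing <- setdiff(species, aln$species)
  if (length(missing)) {
    stop("species not in alignment: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keep <- sort(species)
  structure(
    list(species = keep, ids = aln$ids[keep], seqs = aln$seqs[keep],
         length = aln$length),
    class = "coev_alignment"
  )
}
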