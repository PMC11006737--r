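# Fixture builders shared across the suite. Everything is generated in code;
# no binary or downloaded data.

make_records <- function(seqs, ids = NULL) {
  species <- names(seqs)
  data.frame(
    id = ids %||% paste0("id_", species),
    species = species,
    residues = unname(seqs),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_alignment <- function(seqs, ...) {
  validate_alignment(make_records(seqs, ...))
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# Random equal-length residue strings over the full alphabet (with optional
# gaps/X), for oracle comparisons.
random_alignment <- function(n_species, length, gap_frac = 0, seed = 1) {
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_species), function(i) {
      chars <- sample(alphabet, length, replace = TRUE)
      if (gap_frac > 0) {
        bad <- runif(length) < gap_frac
        chars[bad] <- sample(c("-", "X"), sum(bad), replace = TRUE)
      }
      paste(chars, collapse = "")
    }, "")
    names(seqs) <- sprintf("taxon_%02d", seq_len(n_species))
    seqs
  })
}

# Independent character-level p-distance oracle (double loop over columns).
oracle_p_distance <- function(x, y) {
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  used <- 0L
  diff <- 0L
  for (k in seq_along(cx)) {
    a <- cx[k]; b <- cy[k]
    if (a %in% c("-", "X") || b %in% c("-", "X")) next
    used <- used + 1L
    if (a != b) diff <- diff + 1L
  }
  diff / used
}

# Two-pass Pearson oracle via explicit sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}
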