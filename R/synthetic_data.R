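#' Simulate a Yule species tree
#'
#' Pure-birth (Yule) topology with exponentially distributed waiting times,
#' rescaled so the mean root-to-tip path length is 1 expected substitution
#' per site at rate 1. Tip labels are normalized species-style names
#' (`species_001`, ...). Deterministic for a given seed.
#'
#' @param n_species Number of tips, at least 3.
#' @param birth_rate Speciation rate of the pure-birth process (default 1;
#'   only the topology/relative branch lengths matter after rescaling).
#' @param seed Integer seed.
#' @return An [ape::read.tree()]-style `phylo` object.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1L) {
  if (n_species < 3L) stop("n_species must be at least 3", call. = FALSE)
  tree <- with_seed(seed,
                    ape::rphylo(n_species, birth = birth_rate, death = 0))
  depths <- ape::node.depth.edgelength(tree)
  mean_tip_depth <- mean(depths[seq_len(n_species)])
  tree$edge.length <- tree$edge.length / mean_tip_depth
  tree$tip.label <- sprintf("species_%03d", seq_len(n_species))
  tree
}

#' Lognormal branch-rate multipliers
#'
#' Lineage-specific rate heterogeneity: each branch gets an independent
#' multiplier `exp(g)` with `g ~ Normal(-sigma^2/2, sigma^2)`, so the expected
#' multiplier is exactly 1 at every `sigma`. `sigma = 0` returns all ones.
#'
#' @param tree A `phylo` tree; one multiplier is drawn per edge, in
#'   `tree$edge` row order.
#' @param sigma Standard deviation of the log-rates, at least 0.
#' @param seed Integer seed.
#' @return Numeric vector of positive multipliers with attribute `log_rates`.
#' @export
assign_branch_rates <- function(tree, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  n <- nrow(tree$edge)
  g <- if (sigma == 0) rep(0, n) else {
    with_seed(seed, rnorm(n, mean = -sigma^2 / 2, sd = sigma))
  }
  structure(exp(g), log_rates = g)
}

#' Correlated branch rates for a second family
#'
#' Encodes the coevolution hypothesis: if one family's rate rises along a
#' branch, the partner's tends to rise along the same branch. Per branch,
#' `g_B = rho * g_A + sqrt(1 - rho^2) * eps` with `eps` normal, mean-shifted
#' so the expected multiplier stays 1 and `corr(g_A, g_B) = rho` in
#' expectation. `rho = 1` copies the rates exactly; `rho = 0` draws an
#' independent set.
#'
#' @param rates_a Multipliers from [assign_branch_rates()] (the `log_rates`
#'   attribute is used when present).
#' @param rho Coevolution coefficient in `[0, 1]`.
#' @param sigma Log-rate standard deviation used for `rates_a`.
#' @param seed Integer seed.
#' @return Multiplier vector for family B with attribute `log_rates`.
#' @export
correlate_rates <- function(rates_a, rho, sigma, seed = 1L) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  g_a <- attr(rates_a, "log_rates")
  if (is.null(g_a)) g_a <- log(rates_a)
  if (rho == 1) {
    return(structure(exp(g_a), log_rates = g_a))
  }
  # eps mean chosen so E[g_B] = -sigma^2/2 (unit-mean multipliers)
  m <- if (sigma == 0) 0 else -sigma^2 / 2 * sqrt((1 - rho) / (1 + rho))
  eps <- with_seed(seed, rnorm(length(g_a), mean = m, sd = sigma))
  g_b <- rho * g_a + sqrt(1 - rho^2) * eps
  structure(exp(g_b), log_rates = g_b)
}

#' Evolve an alignment along a tree
#'
#' A root sequence drawn i.i.d. uniform over the 20 canonical residues is
#' evolved along each branch under the uniform 20-state exchange (Poisson)
#' model: substitution events arrive as a Poisson process and each event
#' jumps uniformly to one of the other 19 residues. Each branch's effective
#' length is `edge.length * rate`. Sampling uses the model's exact finite-time
#' transition probability, under which the expected p-distance between two
#' tips joined by total path `b` is `(19/20) * (1 - exp(-(20/19) * b))`
#' (see [expected_p_distance()]). The model is indel-free, so tips form an
#' exactly aligned, gap-free alignment.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param rates Per-edge rate multipliers in `tree$edge` row order
#'   (default all 1).
#' @param length Number of sites, at least 1.
#' @param seed Integer seed.
#' @return A `coev_alignment` whose species are the tip labels.
#' @export
evolve_sequences <- function(tree, rates = NULL, length, seed = 1L) {
  stopifnot(length >= 1L)
  n_edge <- nrow(tree$edge)
  if (is.null(rates)) rates <- rep(1, n_edge)
  stopifnot(base::length(rates) == n_edge, all(rates > 0))
  n_tip <- base::length(tree$tip.label)
  root <- n_tip + 1L
  # parents-first edge ordering: reversed postorder
  edge_order <- rev(ape::postorder(tree))
  with_seed(seed, {
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- sample.int(20L, length, replace = TRUE)
    for (e in edge_order) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      b <- tree$edge.length[e] * rates[e]
      p_change <- (19 / 20) * (1 - exp(-(20 / 19) * b))
      s <- seqs[[parent]]
      hit <- which(runif(length) < p_change)
      if (base::length(hit)) {
        # uniform jump to one of the other 19 states
        shift <- sample.int(19L, base::length(hit), replace = TRUE)
        s[hit] <- ((s[hit] - 1L + shift) %% 20L) + 1L
      }
      seqs[[child]] <- s
    }
    tips <- vapply(seq_len(n_tip), function(i) {
      paste(AA_CANONICAL[seqs[[i]]], collapse = "")
    }, "")
  })
  validate_alignment(data.frame(
    id = tree$tip.label, species = tree$tip.label, residues = tips,
    stringsAsFactors = FALSE
  ))
}

#' Expected p-distance under the uniform-exchange model
#'
#' Closed-form expectation for two sequences separated by total path length
#' `b` (expected substitution events per site): the 20-state analogue of the
#' Jukes-Cantor saturation curve.
#'
#' @param b Total path branch length(s).
#' @return Expected p-distance(s), approaching 19/20 as `b` grows.
#' @export
expected_p_distance <- function(b) {
  (19 / 20) * (1 - exp(-(20 / 19) * b))
}

#' Generate a coevolving pair of protein-family alignments
#'
#' End-to-end ground-truth generator: one shared Yule phylogeny, family-A
#' branch rates, family-B rates correlated with A at coefficient `rho`, and
#' one alignment evolved per family. The master seed is split into named
#' substreams (tree / rates A / rates B / sequences A / sequences B) so each
#' component can be varied independently while keeping the rest fixed.
#'
#' @param n_species Number of shared species (tree tips), at least 3.
#' @param length Sites in family A's alignment (default 1000; family B uses
#'   `length_b`, default the same).
#' @param sigma Log-rate standard deviation (lineage rate heterogeneity).
#' @param rho Coevolution coefficient in `[0, 1]`.
#' @param seed Master integer seed.
#' @param length_b Sites in family B's alignment.
#' @param birth_rate Yule speciation rate for the shared tree.
#' @return A `simulated_pair`: list with `tree`, `rates_a`, `rates_b`, `rho`,
#'   `sigma`, `alignment_a`, `alignment_b`, `seed`, `length_a`, `length_b`.
#' @export
make_coevolving_pair <- function(n_species, length = 1000L, sigma = 0.5,
                                 rho = 1, seed = 1L, length_b = length,
                                 birth_rate = 1) {
  subseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 5L))
  tree <- simulate_tree(n_species, birth_rate = birth_rate,
                        seed = subseeds[1L])
  rates_a <- assign_branch_rates(tree, sigma, seed = subseeds[2L])
  rates_b <- correlate_rates(rates_a, rho, sigma, seed = subseeds[3L])
  aln_a <- evolve_sequences(tree, rates_a, length, seed = subseeds[4L])
  aln_b <- evolve_sequences(tree, rates_b, length_b, seed = subseeds[5L])
  structure(
    list(tree = tree, rates_a = rates_a, rates_b = rates_b, rho = rho,
         sigma = sigma, alignment_a = aln_a, alignment_b = aln_b,
         seed = seed, length_a = length, length_b = length_b),
    class = "simulated_pair"
  )
}

#' @export
print.simulated_pair <- function(x, ...) {
  cat("<simulated_pair> ", base::length(x$tree$tip.label),
      " species, lengths ", x$length_a, "/", x$length_b,
      ", sigma = ", x$sigma, ", rho = ", x$rho, ", seed = ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Export a simulated pair to FASTA and newick files
#'
#' @param pair A `simulated_pair`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
export_simulated_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "simulated_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tree = file.path(dir, "tree.nwk"),
    family_a = file.path(dir, "family_a.fasta"),
    family_b = file.path(dir, "family_b.fasta")
  )
  ape::write.tree(pair$tree, paths[["tree"]])
  write_fasta(pair$alignment_a, paths[["family_a"]])
  write_fasta(pair$alignment_b, paths[["family_b"]])
  invisible(paths)
}
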