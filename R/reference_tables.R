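#' Published mirror-tree panel: gastric proton pump vs PKC isoforms
#'
#' Reference panel of published mirror-tree correlations between the gastric
#' H+,K+-ATPase catalytic (alpha-1) subunit and the nine UniProt-resolvable
#' protein kinase C isoforms (the two beta splice variants are not
#' distinguished and appear as a single `beta` entry). `r` is the Pearson
#' correlation of the two families' pairwise-distance vectors, `N` the number
#' of common organisms, and `n` the printed pairing count. These values are
#' inputs for the Fisher-test ranking machinery; they cannot be recomputed
#' here because the underlying database retrievals are not distributed.
#'
#' @return Data frame with columns `label`, `r`, `N`, `n`.
#' @seealso [src_mirror_panel()], [control_correlations()], [rank_partners()]
#' @export
pkc_mirror_panel <- function() {
  data.frame(
    label = c("theta", "eta", "alpha", "gamma", "zeta", "epsilon",
              "delta", "lambda", "beta"),
    r = c(0.9427, 0.9274, 0.9240, 0.9132, 0.9053, 0.8421,
          0.7580, 0.6799, 0.1284),
    N = c(48L, 55L, 41L, 53L, 36L, 45L, 67L, 51L, 46L),
    n = c(1128L, 1485L, 820L, 1378L, 630L, 990L, 2211L, 1275L, 1035L),
    stringsAsFactors = FALSE
  )
}

#' Published mirror-tree panel: gastric proton pump vs Src-family kinases
#'
#' Reference panel of published mirror-tree correlations between the gastric
#' H+,K+-ATPase catalytic subunit and eight Src-family tyrosine kinases.
#' Columns as in [pkc_mirror_panel()]. Note the `Lyn` row's printed pairing
#' count (4075) does not satisfy n = (N^2-N)/2 for its N = 91 (which gives
#' 4095); the printed value is retained verbatim.
#'
#' @return Data frame with columns `label`, `r`, `N`, `n`.
#' @export
src_mirror_panel <- function() {
  data.frame(
    label = c("Lck", "Yes", "Lyn", "Fyn", "Hck", "Blk", "Src", "Fgr"),
    r = c(0.9512, 0.9468, 0.9384, 0.9384, 0.9358, 0.9187, 0.8070, 0.3143),
    N = c(94L, 85L, 91L, 97L, 61L, 87L, 83L, 89L),
    n = c(4371L, 3570L, 4075L, 4656L, 1830L, 3741L, 3403L, 3916L),
    stringsAsFactors = FALSE
  )
}

#' Published control correlations for the proton-pump screen
#'
#' The positive control is the pump's own alpha-1/beta-1 subunit pair (direct
#' physical contact, hence strong coevolution); the negative controls are the
#' alpha-1 subunit vs hexokinase (a carbohydrate, not protein, kinase) and
#' PKC-alpha vs EGFR (not a serine/threonine kinase substrate). The sizeable
#' negative-control correlations illustrate the shared-phylogeny confound:
#' only correlations above the largest negative control are candidate
#' evidence of coevolution.
#'
#' @return Data frame with columns `label`, `type` (`positive`/`negative`),
#'   `r`.
#' @export
control_correlations <- function() {
  data.frame(
    label = c("alpha1_beta1", "alpha1_hexokinase", "pkc_alpha_egfr"),
    type = c("positive", "negative", "negative"),
    r = c(0.9639, 0.9172, 0.7915),
    stringsAsFactors = FALSE
  )
}
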