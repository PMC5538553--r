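#' Minimal pair-additive RNA energy model
#'
#' A deliberately small thermodynamic model for equilibrium base-pair
#' probabilities: every structure's energy is the sum of its pair energies
#' (one value per pair type), there are no loop, stacking or dangle terms.
#' This keeps the partition function exactly verifiable by exhaustive
#' enumeration on short sequences while still ranking stable helices above
#' unstable ones.  A richer engine can be swapped in by supplying its pair
#' probabilities directly to the scoring functions.
#'
#' @param pair_energies named vector with energies (arbitrary units, more
#'   negative = more stable) for `GC`, `AU`, `GU`; each covers both
#'   orientations.  Default `c(GC = -3, AU = -2, GU = -1)`; the constructor
#'   enforces `e_GC <= e_AU <= e_GU < 0`.
#' @param h minimum hairpin size: a pair (i, j) requires `j - i > h`
#'   unpaired-capable positions between (default 3).
#' @param beta inverse temperature scale multiplying energies in the
#'   Boltzmann weight `exp(-beta * E)`.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(pair_energies = c(GC = -3, AU = -2, GU = -1),
                         h = 3, beta = 1) {
  need <- c("GC", "AU", "GU")
  if (!all(need %in% names(pair_energies)))
    stop("pair_energies must name GC, AU and GU")
  e <- pair_energies[need]
  if (!(e["GC"] <= e["AU"] && e["AU"] <= e["GU"] && e["GU"] < 0))
    stop("need e_GC <= e_AU <= e_GU < 0")
  if (h < 1) stop("h must be >= 1")
  structure(list(pair_energies = e, h = h, beta = beta),
            class = "energy_model")
}

# 4x4 Boltzmann weight matrix, 0 for non-canonical combinations
pair_weight_matrix <- function(em) {
  W <- matrix(0, 4, 4, dimnames = list(.nuc_states, .nuc_states))
  W["G", "C"] <- W["C", "G"] <- exp(-em$beta * em$pair_energies[["GC"]])
  W["A", "U"] <- W["U", "A"] <- exp(-em$beta * em$pair_energies[["AU"]])
  W["G", "U"] <- W["U", "G"] <- exp(-em$beta * em$pair_energies[["GU"]])
  W
}

#' Equilibrium base-pair probabilities of one sequence
#'
#' Inside/outside (McCaskill-style) recursion over all pseudoknot-free
#' secondary structures under the pair-additive [energy_model()].  The
#' probability of pair (i, j) is the Boltzmann-weighted fraction of structures
#' containing that pair.
#'
#' @param seq ungapped RNA string over A, C, G, U.
#' @param em an [energy_model()].
#' @return Upper-triangular n x n matrix `p` with `p[i, j]` the probability
#'   that positions i < j pair; zero when `j - i <= h` or the pair is
#'   non-canonical.  Row sums (over partners both ways) never exceed 1.
#' @examples
#' p <- basepair_probabilities("GGGAAACCC")
#' which(p == max(p), arr.ind = TRUE)   # closing pair of the hairpin
#' @export
basepair_probabilities <- function(seq, em = energy_model()) {
  chars <- strsplit(normalize_rna(seq), "")[[1]]
  if (length(chars) < 1L) stop("empty sequence")
  idx <- match(chars, .nuc_states)
  if (anyNA(idx)) stop("invalid character at position ", which(is.na(idx))[1])
  bpp_matrix_cpp(idx - 1L, pair_weight_matrix(em), as.integer(em$h))
}

# Per-row pair-probability matrices and column -> ungapped-position maps for
# an alignment; the cache consumed by alignment_pair_weight() and pscore().
row_bpp_cache <- function(aln, em) {
  lapply(aln$rows, function(s) {
    ch <- strsplit(s, "")[[1]]
    gap <- !(ch %in% .nuc_states)
    map <- ifelse(gap, NA_integer_, cumsum(!gap))
    ungapped <- paste(ch[!gap], collapse = "")
    p <- if (nchar(ungapped) > 0) basepair_probabilities(ungapped, em)
         else matrix(0, 0, 0)
    list(p = p, map = map)
  })
}

#' Thermodynamic weight of an alignment column pair
#'
#' For each row, alignment columns i and j are mapped to positions in that
#' row's ungapped sequence and the row contributes its equilibrium pairing
#' probability at those positions (0 if either column is gapped in that row).
#' The weight is the arithmetic mean over rows, a value in `[0, 1]` used to
#' emphasize base pairs in thermodynamically stable contexts.
#'
#' @param aln a [crs_alignment].
#' @param i,j alignment columns, `1 <= i < j <= L`.
#' @param em an [energy_model()].
#' @param cache optional precomputed `row_bpp_cache` (internal reuse).
#' @return Weight `w_ij` in `[0, 1]`.
#' @export
alignment_pair_weight <- function(aln, i, j, em = energy_model(),
                                  cache = NULL) {
  if (!(i >= 1 && i < j && j <= aln$L)) stop("need 1 <= i < j <= L")
  if (is.null(cache)) cache <- row_bpp_cache(aln, em)
  contrib <- vapply(cache, function(rc) {
    pi_ <- rc$map[i]; pj <- rc$map[j]
    if (is.na(pi_) || is.na(pj)) 0 else rc$p[pi_, pj]
  }, numeric(1))
  mean(contrib)
}
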