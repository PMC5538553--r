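#' Parse a dot-bracket consensus structure
#'
#' Converts a dot-bracket string into the set of base-paired column pairs P
#' and the set of unpaired columns U (1-based columns; P and U partition the
#' columns).  Brackets must be balanced and non-crossing, and every pair must
#' span more than `h` columns.
#'
#' @param dotbracket structure string over `(`, `)`, `.` (WUSS symbols are
#'   normalized first).
#' @param h minimum hairpin size (default 3).
#' @return A list of class `consensus_structure` with `pairs` (2-column
#'   matrix, i < j), `unpaired` (integer vector) and `L`.
#' @examples
#' parse_structure("((...))")
#' @export
parse_structure <- function(dotbracket, h = 3) {
  s <- normalize_structure(dotbracket)
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  # first pass: balance only, so imbalance is reported before span problems
  depth <- 0L
  for (k in seq_len(L)) {
    if (ch[k] == "(") depth <- depth + 1L
    else if (ch[k] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced structure at column ", k)
    }
  }
  if (depth > 0L) stop("unbalanced structure at column ", L)
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  for (k in seq_len(L)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (k - i <= h)
        stop("pair (", i, ",", k, ") spans <= h = ", h, " columns")
      pairs <- rbind(pairs, c(i, k))
    }
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  unpaired <- setdiff(seq_len(L), as.vector(pairs))
  structure(list(pairs = pairs, unpaired = unpaired, L = L),
            class = "consensus_structure")
}

# assemble per-column observation matrices and run batched pruning
single_column_loglik <- function(tree, aln, model) {
  mat <- do.call(rbind, strsplit(aln$rows, ""))
  rownames(mat) <- names(aln$rows)
  obs <- matrix(match(mat, model$states), nrow = nrow(mat),
                dimnames = list(rownames(mat), NULL))
  log2(prune_likelihoods(tree, obs, model))
}

pair_column_loglik <- function(tree, aln, pairs, model) {
  if (nrow(pairs) == 0L) return(numeric(0))
  mat <- do.call(rbind, strsplit(aln$rows, ""))
  rownames(mat) <- names(aln$rows)
  obs <- matrix(NA_integer_, nrow(mat), nrow(pairs),
                dimnames = list(rownames(mat), NULL))
  for (k in seq_len(nrow(pairs))) {
    sym <- paste0(mat[, pairs[k, 1]], mat[, pairs[k, 2]])
    obs[, k] <- match(sym, model$states)  # any gap/N -> NA (missing)
  }
  log2(prune_likelihoods(tree, obs, model))
}

#' Three-model log-odds of one base pair
#'
#' Log-likelihoods (bits) of alignment columns i and j under the structured
#' 16-state pair model and under the conserved and neutral single-nucleotide
#' models.  With an independence pair model the pair term equals the sum of
#' the two single-column conserved terms exactly.
#'
#' @param tree `phylo` tree.
#' @param aln a [crs_alignment].
#' @param i,j alignment columns.
#' @param models a [score_models()] set.
#' @return List with `l_pair`, `l_cons` (= l_cons_i + l_cons_j), `l_neut`
#'   (= l_neut_i + l_neut_j), all in bits.
#' @export
pair_log_odds <- function(tree, aln, i, j, models) {
  pr <- matrix(c(i, j), 1, 2)
  l_pair <- pair_column_loglik(tree, aln, pr, models$pair)
  lc <- single_column_loglik(tree, aln, models$cons)
  ln <- single_column_loglik(tree, aln, models$neut)
  list(l_pair = l_pair, l_cons = lc[i] + lc[j], l_neut = ln[i] + ln[j])
}

#' Phylogenetic structure score of an annotated alignment
#'
#' The ranking statistic for conserved RNA structure.  For every consensus
#' base pair (i, j) the structured pair model is compared against the two
#' unstructured alternatives, weighted by the thermodynamic pair weight
#' `w_ij` (see [alignment_pair_weight()]):
#' \deqn{\Delta_{cons} = \sum_{(i,j) \in P} w_{ij}\,(\ell_{pair} -
#'   \ell_{cons,i} - \ell_{cons,j})}
#' \deqn{\Delta_{neut} = \sum_{(i,j) \in P} w_{ij}\,(\ell_{pair} -
#'   \ell_{neut,i} - \ell_{neut,j}) + \sum_{i \in U}
#'   (\ell_{cons,i} - \ell_{neut,i})}
#' and `pscore = min(delta_cons, delta_neut)` in bits: the structured model
#' must outscore both the conserved-unstructured and the neutral/misaligned
#' alternative.  Unpaired columns contribute only to the neutral comparison
#' (they cancel exactly in the conserved one), so evidence for structure must
#' come from paired columns.  Pairs gapped in more than `gap_cap` of the rows
#' get weight 0 (explicit stand-in for a base-pair indel model).
#'
#' @param aln a [crs_alignment].
#' @param tree `phylo` tree; every alignment row must map to a leaf.
#' @param models a [score_models()] set.
#' @param em an [energy_model()] for the thermodynamic weights, or `NULL`
#'   for unit weights.
#' @param structure optional [parse_structure()] result; default parses
#'   `aln$structure`.
#' @param gap_cap per-pair gap-fraction cap above which the pair's weight is
#'   zeroed (default 0.5).
#' @return An object of class `pscore_result`: `per_pair` data frame
#'   (i, j, w, l_pair, l_cons, l_neut), `delta_cons`, `delta_neut`,
#'   `pscore`, `n_pairs`, `n_unpaired`.
#' @export
pscore <- function(aln, tree, models = score_models(), em = energy_model(),
                   structure = NULL, gap_cap = 0.5) {
  if (length(aln$rows) == 0L) stop("empty alignment")
  if (is.null(structure)) structure <- parse_structure(aln$structure)
  if (structure$L != aln$L) stop("structure length mismatch")
  P <- structure$pairs
  lc <- single_column_loglik(tree, aln, models$cons)
  ln <- single_column_loglik(tree, aln, models$neut)
  lp <- pair_column_loglik(tree, aln, P, models$pair)
  if (nrow(P) > 0L) {
    if (is.null(em)) {
      w <- rep(1, nrow(P))
    } else {
      cache <- row_bpp_cache(aln, em)
      w <- vapply(seq_len(nrow(P)), function(k)
        alignment_pair_weight(aln, P[k, 1], P[k, 2], em, cache = cache),
        numeric(1))
    }
    mat <- do.call(rbind, strsplit(aln$rows, ""))
    gapfrac <- vapply(seq_len(nrow(P)), function(k)
      mean(!(mat[, P[k, 1]] %in% .nuc_states) |
           !(mat[, P[k, 2]] %in% .nuc_states)), numeric(1))
    w[gapfrac > gap_cap] <- 0
    d_cons_terms <- w * (lp - lc[P[, 1]] - lc[P[, 2]])
    d_neut_terms <- w * (lp - ln[P[, 1]] - ln[P[, 2]])
  } else {
    w <- numeric(0)
    d_cons_terms <- d_neut_terms <- numeric(0)
  }
  delta_cons <- sum(d_cons_terms)
  delta_neut <- sum(d_neut_terms) +
    sum(lc[structure$unpaired] - ln[structure$unpaired])
  per_pair <- data.frame(i = P[, 1], j = P[, 2], w = w, l_pair = lp,
                         l_cons = lc[P[, 1]] + lc[P[, 2]],
                         l_neut = ln[P[, 1]] + ln[P[, 2]])
  res <- list(per_pair = per_pair, delta_cons = delta_cons,
              delta_neut = delta_neut,
              pscore = min(delta_cons, delta_neut),
              n_pairs = nrow(P), n_unpaired = length(structure$unpaired),
              id = aln$id)
  class(res) <- "pscore_result"
  res
}

#' @export
print.pscore_result <- function(x, ...) {
  cat(sprintf(
    "<pscore '%s'> %.3f bits (delta_cons %.3f, delta_neut %.3f; %d pairs, %d unpaired)\n",
    x$id, x$pscore, x$delta_cons, x$delta_neut, x$n_pairs, x$n_unpaired))
  invisible(x)
}

#' Classify a score against a threshold
#'
#' `TRUE` iff `pscore >= threshold` (closed inequality).
#'
#' @param result a `pscore_result` (or a bare numeric score).
#' @param threshold finite numeric threshold.
#' @return Logical call.
#' @export
classify <- function(result, threshold) {
  stopifnot(is.finite(threshold))
  s <- if (inherits(result, "pscore_result")) result$pscore else result
  s >= threshold
}
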