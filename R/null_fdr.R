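#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian shuffle: the output has exactly the same
#' mononucleotide and dinucleotide counts as the input (and hence the same
#' first and last character).  Given a seed the draw is reproducible; over
#' many draws all valid shuffles are reachable.
#'
#' @param seq character string (length >= 2 for a non-trivial shuffle).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return Shuffled string.
#' @examples
#' dinucleotide_shuffle("ACGCAUGC", seed = 1)
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 3L || length(unique(ch)) < 2L) return(seq)
  with_seed(seed, {
    verts <- unique(ch)
    from <- ch[-n]
    to <- ch[-1]
    sn <- ch[n]
    out_edges <- split(to, factor(from, verts))
    # choose a random "last edge" per non-terminal vertex such that the
    # chosen edges form an arborescence converging on the final vertex
    nonterm <- setdiff(names(out_edges)[lengths(out_edges) > 0], sn)
    repeat {
      last <- vapply(nonterm, function(v) sample(out_edges[[v]], 1L),
                     character(1))
      ok <- all(vapply(nonterm, function(v) {
        seen <- character(0)
        while (v != sn) {
          if (v %in% seen || !(v %in% names(last))) return(FALSE)
          seen <- c(seen, v)
          v <- last[[v]]
        }
        TRUE
      }, logical(1)))
      if (ok) break
    }
    # permute the remaining out-edges, append the reserved last edge
    ordered <- lapply(names(out_edges), function(v) {
      e <- out_edges[[v]]
      if (v %in% names(last)) {
        drop <- match(last[[v]], e)
        e <- e[-drop]
      }
      e <- if (length(e) > 1L) sample(e) else e
      if (v %in% names(last)) c(e, last[[v]]) else e
    })
    names(ordered) <- names(out_edges)
    ptr <- setNames(rep(1L, length(ordered)), names(ordered))
    res <- character(n)
    res[1] <- ch[1]
    cur <- ch[1]
    for (k in 2:n) {
      nxt <- ordered[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      res[k] <- nxt
      cur <- nxt
    }
    paste(res, collapse = "")
  })
}

#' Simulate a null alignment
#'
#' Two transparent null modes bracket a full dinucleotide/GC-fitting
#' simulator:
#' \describe{
#'   \item{`shuffle`}{jointly permutes alignment columns, preserving every
#'     column's conservation/gap pattern (and each row's gap and base counts)
#'     while destroying covariation between the structure's paired columns.}
#'   \item{`evolve`}{evolves fresh sequences down the tree under a
#'     single-nucleotide GTR whose stationary GC content matches the source
#'     alignment's GC, reusing the source per-row gap mask.}
#' }
#' The returned alignment keeps the source structure string so the null can
#' be scored at the same column positions (its annotation carries no
#' covariation signal by construction).
#'
#' @param aln source [crs_alignment].
#' @param tree `phylo` tree (used by mode `evolve`).
#' @param mode `"shuffle"` or `"evolve"`.
#' @param seed integer seed; same seed, same output.
#' @return A [crs_alignment] with `id` suffixed by the mode.
#' @export
simulate_null_alignment <- function(aln, tree, mode = c("shuffle", "evolve"),
                                    seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    mat <- do.call(rbind, strsplit(aln$rows, ""))
    rownames(mat) <- names(aln$rows)
    if (mode == "shuffle") {
      perm <- sample.int(aln$L)
      mat <- mat[, perm, drop = FALSE]
    } else {
      st <- suppressWarnings(alignment_stats(aln))
      gc <- if (is.na(st$gc)) 0.5 else min(max(st$gc, 0.02), 0.98)
      pi <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
      model <- build_gtr(pi = pi)
      sim <- evolve_columns(tree, model, aln$L)
      new <- sim[rownames(mat), , drop = FALSE]
      new[!(mat %in% .nuc_states)] <- "-"   # reuse source gap mask
      mat <- new
    }
    rows <- setNames(apply(mat, 1, paste, collapse = ""), rownames(mat))
    crs_alignment(rows, aln$structure, id = paste0(aln$id, "|", mode))
  })
}

# evolve ncol independent sites down the tree under `model`; returns a
# character matrix (leaves x ncol).  Uses the caller's RNG stream.
evolve_columns <- function(tree, model, ncol) {
  validate_tree(tree)
  S <- length(model$states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, ncol)
  root <- ntip + 1L
  states[root, ] <- sample.int(S, ncol, replace = TRUE, prob = model$pi)
  # preorder = reverse postorder edge traversal
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(tr$edge)))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    P <- transition_matrix(model, tr$edge.length[e])
    ps <- states[parent, ]
    cs <- integer(ncol)
    for (s in unique(ps)) {
      at <- which(ps == s)
      cs[at] <- sample.int(S, length(at), replace = TRUE, prob = P[s, ])
    }
    states[child, ] <- cs
  }
  out <- matrix(model$states[states[seq_len(ntip), , drop = FALSE]],
                nrow = ntip, dimnames = list(tree$tip.label, NULL))
  out
}

#' GC-binned FDR estimation from real and null score lists
#'
#' For every (GC bin, score threshold) cell the false-discovery rate is
#' estimated as
#' \deqn{FDR = \min\left(1, \frac{N_{null}(score \ge t, gc \in bin)}
#'   {N_{real}(score \ge t, gc \in bin)}\right)}
#' per null replicate, then summarized as mean and SD over replicates.  Real
#' and null lists are expected to come from equal numbers of source
#' alignments per replicate.  Cells with no real observation are `NA`.
#'
#' @param real data frame with columns `pscore` and `gc` (one row per scored
#'   source alignment).
#' @param null like `real`, optionally with a `replicate` column.
#' @param thresholds numeric vector of score cutoffs.
#' @param gc_bins bin boundaries over `[0, 1]`; default the five reporting
#'   bins `c(0, 0.2, 0.4, 0.65, 0.8, 1)` (the 0.2-0.65 range being the most
#'   common GC range of real predictions).
#' @return Data frame of class `fdr_table` with `gc_lo`, `gc_hi`,
#'   `threshold`, `fdr_mean`, `fdr_sd`, `n_real`, `n_null` (mean per
#'   replicate).
#' @export
estimate_fdr <- function(real, null, thresholds,
                         gc_bins = c(0, 0.2, 0.4, 0.65, 0.8, 1)) {
  stopifnot(all(c("pscore", "gc") %in% names(real)),
            all(c("pscore", "gc") %in% names(null)))
  if (is.null(null$replicate)) null$replicate <- 1L
  reps <- sort(unique(null$replicate))
  nb <- length(gc_bins) - 1L
  bin_of <- function(gc) {
    b <- findInterval(gc, gc_bins, rightmost.closed = TRUE, all.inside = TRUE)
    b
  }
  real_bin <- bin_of(real$gc)
  null_bin <- bin_of(null$gc)
  out <- expand.grid(bin = seq_len(nb), threshold = thresholds,
                     KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(out)), function(r) {
    b <- out$bin[r]; t <- out$threshold[r]
    n_real <- sum(real_bin == b & real$pscore >= t)
    fdr_r <- vapply(reps, function(rep) {
      n_null <- sum(null_bin == b & null$replicate == rep & null$pscore >= t)
      if (n_real == 0L) return(NA_real_)
      min(1, n_null / n_real)
    }, numeric(1))
    n_null_mean <- mean(vapply(reps, function(rep)
      sum(null_bin == b & null$replicate == rep & null$pscore >= t),
      numeric(1)))
    if (n_real == 0L)
      warning("no real scores in bin ", b, " at threshold ", t,
              "; FDR reported as NA", call. = FALSE)
    data.frame(gc_lo = gc_bins[b], gc_hi = gc_bins[b + 1L], threshold = t,
               fdr_mean = mean(fdr_r), fdr_sd = if (length(fdr_r) > 1L)
                 sd(fdr_r) else NA_real_,
               n_real = n_real, n_null = n_null_mean)
  })
  tbl <- do.call(rbind, res)
  class(tbl) <- c("fdr_table", "data.frame")
  tbl
}

#' Choose a score threshold at a target FDR
#'
#' Smallest threshold in the table whose mean estimated FDR (pooled across
#' the requested GC bins) is at or below `target_fdr`.
#'
#' @param tbl an `fdr_table` from [estimate_fdr()].
#' @param target_fdr target false-discovery rate.
#' @param gc_range optional `c(lo, hi)` restricting which bins are used.
#' @return The selected threshold, or `NA` if no threshold qualifies.
#' @export
calibrate_threshold <- function(tbl, target_fdr, gc_range = NULL) {
  if (!is.null(gc_range))
    tbl <- tbl[tbl$gc_lo >= gc_range[1] & tbl$gc_hi <= gc_range[2], ]
  ok <- vapply(sort(unique(tbl$threshold)), function(t) {
    cell <- tbl[tbl$threshold == t & !is.na(tbl$fdr_mean), ]
    if (nrow(cell) == 0L) return(FALSE)
    # pool bins weighted by their real counts
    sum(cell$fdr_mean * cell$n_real) / sum(cell$n_real) <= target_fdr
  }, logical(1))
  ths <- sort(unique(tbl$threshold))
  if (!any(ok)) return(NA_real_)
  ths[which(ok)[1]]
}
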