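# Independent oracles and shared fixtures for the test suite.  Everything in
# here is deliberately brute-force: oracles must not share code paths with
# the implementations they check.

# --- trees -----------------------------------------------------------------

tree2 <- function(t1 = 0.1, t2 = 0.2)
  read_newick(text = sprintf("(A:%g,B:%g);", t1, t2))

tree3 <- function(ta = 0.1, tb = 0.3, tab = 0.2, tc = 0.4)
  read_newick(text = sprintf("((A:%g,B:%g):%g,C:%g);", ta, tb, tab, tc))

tree8 <- function(bl = 0.25) {
  txt <- paste0("(((h:", bl, ",m:", bl, "):", bl, ",(c:", bl, ",d:", bl,
                "):", bl, "):", bl, ",((e:", bl, ",f:", bl, "):", bl,
                ",(g:", bl, ",i:", bl, "):", bl, "):", bl, ");")
  read_newick(text = txt)
}

random_tree <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, tip.label = LETTERS[seq_len(n_leaves)])
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  tr
}

# the default 60-column benchmark structure: two hairpins, 9 base pairs =
# 18 paired columns out of 60 (30% of columns paired)
bench_structure <- function() {
  db <- "....(((((....))))).......((((....))))......................."
  stopifnot(nchar(db) == 60)
  db
}

# --- brute-force pruning oracle --------------------------------------------

# Sum over all ancestral-state assignments (and unobserved-leaf states):
# P(obs) = sum_assign pi(root) * prod_edges P(t_e)[parent, child].
# Vectorized over the assignment grid.
brute_force_likelihood <- function(tree, obs, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  S <- length(model$states)
  allowed <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    o <- obs[[tr$tip.label[i]]]
    idx <- if (is.null(o) || is.na(o)) NA_integer_ else match(o, model$states)
    allowed[[i]] <- if (is.na(idx)) seq_len(S) else idx
  }
  for (i in (ntip + 1):nnode) allowed[[i]] <- seq_len(S)
  grid <- as.matrix(expand.grid(allowed, KEEP.OUT.ATTRS = FALSE))
  pr <- model$pi[grid[, ntip + 1]]
  for (e in seq_len(nrow(tr$edge))) {
    P <- transition_matrix(model, tr$edge.length[e])
    pr <- pr * P[cbind(grid[, tr$edge[e, 1]], grid[, tr$edge[e, 2]])]
  }
  sum(pr)
}

# --- exhaustive structure enumeration oracle -------------------------------

# All pseudoknot-free structures of `chars` with min hairpin h and pairing
# allowed where W > 0; returns list of pair-lists.
enumerate_structures <- function(chars, h, W) {
  rec <- function(i, j) {
    if (j - i < h + 1) return(list(list()))
    out <- rec(i, j - 1)
    for (k in i:(j - h - 1)) {
      if (W[chars[k], chars[j]] > 0) {
        left <- if (k > i) rec(i, k - 1) else list(list())
        inner <- rec(k + 1, j - 1)
        for (l in left) for (m in inner)
          out <- c(out, list(c(l, m, list(c(k, j)))))
      }
    }
    out
  }
  rec(1, length(chars))
}

# Boltzmann pair probabilities by full enumeration
enumeration_bpp <- function(seq, em) {
  chars <- strsplit(seq, "")[[1]]
  W <- crstool:::pair_weight_matrix(em)
  structs <- enumerate_structures(chars, em$h, W)
  wts <- vapply(structs, function(st)
    prod(vapply(st, function(p) W[chars[p[1]], chars[p[2]]], numeric(1))),
    numeric(1))
  Z <- sum(wts)
  n <- length(chars)
  pm <- matrix(0, n, n)
  for (si in seq_along(structs)) for (p in structs[[si]])
    pm[p[1], p[2]] <- pm[p[1], p[2]] + wts[si] / Z
  pm
}

# --- misc ------------------------------------------------------------------

random_rna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# rank-based AUC of scores for positives vs negatives
auc_score <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# score a batch of alignments, returning data.frame(pscore, gc)
score_batch <- function(alns, tree, models, em) {
  do.call(rbind, lapply(alns, function(a) {
    st <- suppressWarnings(alignment_stats(a))
    data.frame(pscore = pscore(a, tree, models, em)$pscore, gc = st$gc)
  }))
}
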