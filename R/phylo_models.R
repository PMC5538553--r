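#' Build a general time-reversible (GTR) substitution model
#'
#' Constructs the reversible 4-state rate matrix \eqn{Q_{ij} = r_{ij}\pi_j}
#' from stationary frequencies `pi` over (A, C, G, U) and six symmetric
#' exchangeabilities, normalized so the expected substitution rate at
#' stationarity is 1 (\eqn{-\sum_i \pi_i Q_{ii} = 1}).  Detailed balance
#' \eqn{\pi_i Q_{ij} = \pi_j Q_{ji}} holds by construction.
#'
#' @param pi stationary distribution over A, C, G, U; strictly positive, sums
#'   to 1 (tolerance 1e-9).
#' @param exch the 6 exchangeabilities in order AC, AG, AU, CG, CU, GU; all
#'   positive.  Default all 1 (Jukes-Cantor when `pi` is uniform).
#' @return An object of class `rate_model` with elements `pi`, `exch` (full
#'   symmetric matrix), `Q`, `states`, `rate` (branch-length multiplier,
#'   1 by default) and a cached spectral decomposition.
#' @examples
#' jc <- build_gtr()                      # Jukes-Cantor
#' transition_matrix(jc, 0.1)
#' @export
build_gtr <- function(pi = rep(0.25, 4), exch = rep(1, 6)) {
  if (length(pi) != 4L || any(pi <= 0) || abs(sum(pi) - 1) > 1e-9)
    stop("pi must be 4 strictly positive values summing to 1")
  if (length(exch) != 6L || any(exch <= 0))
    stop("exch must be 6 positive exchangeabilities")
  R <- matrix(0, 4, 4, dimnames = list(.nuc_states, .nuc_states))
  R["A", "C"] <- R["C", "A"] <- exch[1]
  R["A", "G"] <- R["G", "A"] <- exch[2]
  R["A", "U"] <- R["U", "A"] <- exch[3]
  R["C", "G"] <- R["G", "C"] <- exch[4]
  R["C", "U"] <- R["U", "C"] <- exch[5]
  R["G", "U"] <- R["U", "G"] <- exch[6]
  new_rate_model(pi = setNames(pi, .nuc_states), R = R, states = .nuc_states,
                 class = "rate_model")
}

# shared reversible-model assembly: Q_ij = R_ij pi_j, normalized to
# `target_rate` expected substitutions per unit time (1 for nucleotide
# models; 2 for pair models, i.e. rate 1 per nucleotide, which makes the
# independence pair model exactly the product of two single-site processes),
# with cached symmetric eigendecomposition for fast matrix exponentials
new_rate_model <- function(pi, R, states, class, extra = list(),
                           target_rate = 1) {
  Q <- R * rep(pi, each = length(pi))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix")
  Q <- Q * (target_rate / scale)
  dimnames(Q) <- list(states, states)
  d <- sqrt(pi)
  B <- Q * (d %o% (1 / d))          # diag(d) Q diag(1/d), symmetric
  B <- (B + t(B)) / 2               # numerical symmetrization
  e <- eigen(B, symmetric = TRUE)
  decomp <- list(V = e$vectors / d,        # diag(1/d) %*% eigenvectors
                 Vinv = t(e$vectors * d),  # t(eigenvectors) %*% diag(d)
                 lambda = e$values)
  obj <- c(list(pi = pi, exch = R, Q = Q, states = states, rate = 1,
                scale = scale, decomp = decomp), extra)
  structure(obj, class = class)
}

#' Build a 16-state base-pair substitution model
#'
#' The 16 ordered dinucleotide states model the joint evolution of the two
#' columns of a base pair.  The backbone is the independence model (Kronecker
#' sum of a 4-state model with itself: \eqn{Q_{16} = Q \oplus Q},
#' \eqn{\pi_{16} = \pi \otimes \pi}), which is then made structure-aware by
#' boosting the stationary mass of the six canonical pairs (Watson-Crick and
#' GU wobble) and, optionally, the exchange rates between canonical pairs
#' (which is what makes compensatory double substitutions likely).
#' Reversibility is preserved because the boosts act on the stationary
#' distribution and the symmetric exchangeability term separately.
#'
#' Pair models are normalized to an expected rate of 2 per unit time -- 1 per
#' nucleotide -- so that the independence model is exactly the product of two
#' single-site processes on the same branch-length scale.
#'
#' @param from_single a `rate_model` supplying the independence backbone.
#'   Alternatively pass `pi16` and `exch16` directly.
#' @param pi16,exch16 explicit 16-state stationary distribution and symmetric
#'   16x16 exchangeability matrix (used when `from_single` is `NULL`).
#' @param stacking_bias named vector `c(wc = ..., wobble = ...)` of stationary
#'   multipliers for Watson-Crick and GU/UG pairs, or `NULL` for the pure
#'   independence model.  Defaults `c(wc = 8, wobble = 3)`.
#' @param canonical_exchange_boost multiplier (>= 1) applied to exchange rates
#'   between two distinct canonical pairs; drives compensatory substitutions.
#' @return An object of class `c("pair_rate_model", "rate_model")` with the
#'   same fields as [build_gtr()] plus `independent` (logical).
#' @export
build_pair_model <- function(from_single = NULL, pi16 = NULL, exch16 = NULL,
                             stacking_bias = c(wc = 8, wobble = 3),
                             canonical_exchange_boost = 1) {
  if (!is.null(from_single)) {
    stopifnot(inherits(from_single, "rate_model"))
    I4 <- diag(4)
    Q16 <- kronecker(from_single$Q, I4) + kronecker(I4, from_single$Q)
    pi16 <- as.vector(kronecker(from_single$pi, from_single$pi))
    R16 <- Q16 / rep(pi16, each = 16)
    diag(R16) <- 0
  } else {
    if (is.null(pi16) || is.null(exch16))
      stop("need either from_single or both pi16 and exch16")
    if (length(pi16) != 16L || any(pi16 <= 0) || abs(sum(pi16) - 1) > 1e-9)
      stop("pi16 must be 16 strictly positive values summing to 1")
    R16 <- (exch16 + t(exch16)) / 2
    if (any(R16[upper.tri(R16)] < 0)) stop("exchangeabilities must be >= 0")
    diag(R16) <- 0
  }
  names(pi16) <- .pair_states
  canon <- .pair_states %in% .canonical_pairs
  independent <- TRUE
  if (!is.null(stacking_bias)) {
    if (any(stacking_bias <= 0)) stop("bias weights must be > 0")
    w <- rep(1, 16)
    w[.pair_states %in% c("AU", "UA", "GC", "CG")] <- stacking_bias[["wc"]]
    w[.pair_states %in% c("GU", "UG")] <- stacking_bias[["wobble"]]
    pi16 <- pi16 * w / sum(pi16 * w)
    independent <- all(w == 1)
  }
  if (canonical_exchange_boost != 1) {
    if (canonical_exchange_boost <= 0) stop("boost must be > 0")
    R16[canon, canon] <- R16[canon, canon] * canonical_exchange_boost
    independent <- FALSE
  }
  dimnames(R16) <- list(.pair_states, .pair_states)
  new_rate_model(pi = pi16, R = R16, states = .pair_states,
                 class = c("pair_rate_model", "rate_model"),
                 extra = list(independent = independent), target_rate = 2)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the cached spectral decomposition of the reversible rate
#' matrix.  Tiny negative entries from round-off (> -1e-12) are clipped to 0
#' and rows renormalized.  The model's `rate` multiplier scales `t` (used for
#' the neutral model).
#'
#' @param model a `rate_model` or `pair_rate_model`.
#' @param t branch length (expected substitutions per site), `t >= 0`.
#' @return Row-stochastic matrix of transition probabilities.
#' @export
transition_matrix <- function(model, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single non-negative number")
  t <- t * model$rate
  P <- model$decomp$V %*% (exp(model$decomp$lambda * t) * model$decomp$Vinv)
  if (any(P < -1e-12)) stop("matrix exponential produced negative probabilities")
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model$states, model$states)
  P
}

# Encode observed symbols as state indices; anything outside the model
# alphabet (gaps, N, absent leaves) becomes NA = missing data.
encode_obs <- function(obs, states) {
  idx <- match(obs, states)
  idx
}

# Batch Felsenstein pruning: obs_idx is an (ntips x ncols) integer matrix of
# state indices (NA = marginalize), rownames = tip labels.  Returns the
# likelihood of every column.  All per-node partials are (S x C) matrices so
# the whole computation is dense matrix algebra.
prune_likelihoods <- function(tree, obs_idx, model) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (is.null(rownames(obs_idx))) stop("obs_idx needs rownames (leaf names)")
  unknown <- setdiff(rownames(obs_idx), tree$tip.label)
  if (length(unknown))
    stop("leaf name not in tree: ", paste(unknown, collapse = ", "))
  S <- length(model$states)
  C <- ncol(obs_idx)
  tr <- ape::reorder.phylo(tree, "postorder")
  partials <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) {
    lab <- tr$tip.label[i]
    m <- matrix(1, S, C)
    if (lab %in% rownames(obs_idx)) {
      o <- obs_idx[lab, ]
      seen <- which(!is.na(o))
      if (length(seen)) {
        m[, seen] <- 0
        m[cbind(o[seen], seen)] <- 1
      }
    }
    partials[[i]] <- m
  }
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    P <- transition_matrix(model, tr$edge.length[e])
    contrib <- P %*% partials[[child]]
    partials[[parent]] <- if (is.null(partials[[parent]])) contrib
                          else partials[[parent]] * contrib
  }
  root <- ntip + 1L
  as.vector(colSums(model$pi * partials[[root]]))
}

#' Column likelihood by Felsenstein pruning
#'
#' Probability of the observed leaf states of one alignment column (or column
#' pair) given a tree and a substitution model, computed by post-order pruning
#' with transition matrices \eqn{P(t) = e^{Qt}}.  Leaves without an
#' observation, gaps and ambiguity codes are treated as missing data and
#' marginalized.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param observations named character vector mapping leaf names to states:
#'   single bases (`"A"`) for a 4-state model, ordered dinucleotides (`"GC"`)
#'   for a 16-state model.  Symbols outside the model alphabet are missing.
#' @param model a `rate_model` or `pair_rate_model`.
#' @return The likelihood, a probability in (0, 1].
#' @export
column_likelihood <- function(tree, observations, model) {
  obs <- encode_obs(unname(observations), model$states)
  m <- matrix(obs, ncol = 1, dimnames = list(names(observations), NULL))
  prune_likelihoods(tree, m, model)
}

#' Pairwise evolutionary distance under a GTR model
#'
#' Maximum-likelihood distance \eqn{\hat t} between two aligned sequences,
#' maximizing \eqn{\prod_k \pi_{x_k} P(t)_{x_k y_k}} over `t` in
#' `[1e-6, 20]`.  Columns gapped (or ambiguous) in either sequence are
#' dropped.  Under the Jukes-Cantor special case this matches the closed form
#' \eqn{-\frac{3}{4}\log(1 - \frac{4p}{3})}.  Saturated pairs (optimum at the
#' upper bracket) are reported as `Inf` with a warning.
#'
#' @param seq1,seq2 aligned sequences (strings or character vectors).
#' @param model a 4-state `rate_model`.
#' @return Estimated distance in expected substitutions per site.
#' @export
gtr_distance <- function(seq1, seq2, model = build_gtr()) {
  x <- if (length(seq1) == 1L) strsplit(normalize_rna(seq1), "")[[1]] else seq1
  y <- if (length(seq2) == 1L) strsplit(normalize_rna(seq2), "")[[1]] else seq2
  if (length(x) != length(y)) stop("sequences must have equal length")
  keep <- x %in% model$states & y %in% model$states
  if (!any(keep)) stop("no comparable (ungapped) columns")
  x <- x[keep]; y <- y[keep]
  if (all(x == y)) return(0)
  N <- table(factor(x, model$states), factor(y, model$states))
  negll <- function(t) {
    P <- transition_matrix(model, t)
    -sum(N * log(pmax(model$pi * P, 1e-300)))
  }
  opt <- optimize(negll, c(1e-6, 20), tol = 1e-8)
  if (opt$minimum > 19) {
    warning("distance saturated; reporting Inf")
    return(Inf)
  }
  opt$minimum
}

#' Estimate a GTR model from alignment columns on a fixed tree
#'
#' Maximum-likelihood fit of stationary frequencies and exchangeabilities by
#' numerical optimization of the summed column log-likelihood (pruning on the
#' given tree).  Stationary frequencies are initialized from empirical base
#' counts; exchangeabilities from 1.  Identical column patterns are collapsed
#' and weighted for speed.
#'
#' @param columns character matrix (leaves x columns) of observed bases, with
#'   rownames naming the leaves; or a list of named character vectors.
#' @param tree a `phylo` tree with branch lengths.
#' @param maxit iteration cap for [stats::optim()] (Nelder-Mead).
#' @return A fitted `rate_model`; its attribute `logLik` holds the final
#'   log-likelihood.
#' @export
estimate_gtr <- function(columns, tree, maxit = 400) {
  if (is.list(columns)) {
    leaves <- unique(unlist(lapply(columns, names)))
    m <- matrix(NA_character_, length(leaves), length(columns),
                dimnames = list(leaves, NULL))
    for (j in seq_along(columns)) m[names(columns[[j]]), j] <- columns[[j]]
    columns <- m
  }
  chars <- columns[columns %in% .nuc_states]
  if (length(unique(chars)) < 2L)
    stop("degenerate data: fewer than two observed states")
  cnt <- table(factor(chars, .nuc_states)) + 1  # add-one smoothing
  pi0 <- as.numeric(cnt / sum(cnt))
  # collapse duplicate column patterns
  pat <- apply(columns, 2, paste, collapse = "\r")
  wts <- table(pat)
  uniq <- columns[, match(names(wts), pat), drop = FALSE]
  w <- as.numeric(wts)
  obsmat <- matrix(match(uniq, .nuc_states), nrow = nrow(uniq),
                   dimnames = list(rownames(uniq), NULL))
  par0 <- c(log(pi0[1:3] / pi0[4]), rep(0, 5))
  unpack <- function(par) {
    epi <- exp(c(par[1:3], 0))
    list(pi = epi / sum(epi), exch = c(exp(par[4:8]), 1))
  }
  negll <- function(par) {
    p <- unpack(par)
    m <- build_gtr(p$pi, p$exch)
    lik <- prune_likelihoods(tree, obsmat, m)
    -sum(w * log(pmax(lik, 1e-300)))
  }
  fit <- optim(par0, negll, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
  p <- unpack(fit$par)
  out <- build_gtr(p$pi, p$exch)
  attr(out, "logLik") <- -fit$value
  out
}

#' Default three-model set for pscore
#'
#' The scoring statistic compares a structured base-pair model against a
#' conserved single-nucleotide model and a neutral (faster) single-nucleotide
#' model.  The defaults used here are a documented stand-in for a trained
#' parameterization: uniform-frequency GTR for the conserved model, the
#' canonical-pair-biased 16-state model (stationary bias 8 for Watson-Crick
#' pairs, 3 for GU/UG, exchange boost 4 between canonical pairs) for the
#' structured model, and the conserved model with branch lengths scaled by
#' `rho > 1` for the neutral model.
#'
#' @param cons conserved single-nucleotide `rate_model`.
#' @param pair structured `pair_rate_model`.
#' @param rho neutral rate multiplier (> 1), default 3.
#' @return A list of class `score_models` with elements `cons`, `pair`,
#'   `neut`.
#' @export
score_models <- function(cons = build_gtr(),
                         pair = build_pair_model(
                           from_single = cons,
                           stacking_bias = c(wc = 8, wobble = 3),
                           canonical_exchange_boost = 4),
                         rho = 3) {
  if (rho <= 1) stop("neutral rate multiplier rho must be > 1")
  neut <- cons
  neut$rate <- cons$rate * rho
  structure(list(cons = cons, pair = pair, neut = neut, rho = rho),
            class = "score_models")
}
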