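#' Simulation configuration
#'
#' Bundles the generative assumptions the scoring pipeline is designed to
#' detect: a phylogeny, a consensus structure, a structured pair model whose
#' canonical-pair bias and boosted canonical exchange rates produce
#' compensatory double substitutions at paired columns, a single-nucleotide
#' model for unpaired columns, negative-binomial read-count parameters, and a
#' probing noise level.  A seed is mandatory; every generator is a pure
#' function of its configuration.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param structure dot-bracket string or [parse_structure()] result.
#' @param pair_model 16-state `pair_rate_model` for paired columns.
#' @param single_model 4-state `rate_model` for unpaired columns.
#' @param nb_mean,nb_dispersion negative-binomial mean and size parameter for
#'   read counts (`var = mu + mu^2 / dispersion`); defaults 50 and 0.3.
#' @param probing_noise probability that a probing position's pairing call is
#'   flipped (default 0).
#' @param seed integer seed (mandatory).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(tree, structure,
                       pair_model = build_pair_model(
                         from_single = build_gtr(),
                         stacking_bias = c(wc = 8, wobble = 3),
                         canonical_exchange_boost = 4),
                       single_model = build_gtr(),
                       nb_mean = 50, nb_dispersion = 0.3,
                       probing_noise = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.character(structure)) structure <- parse_structure(structure)
  validate_tree(tree)
  if (probing_noise < 0 || probing_noise > 1)
    stop("probing_noise must lie in [0, 1]")
  if (nb_mean <= 0 || nb_dispersion <= 0)
    stop("nb_mean and nb_dispersion must be > 0")
  obj <- list(tree = tree, structure = structure, pair_model = pair_model,
              single_model = single_model, nb_mean = nb_mean,
              nb_dispersion = nb_dispersion, probing_noise = probing_noise,
              seed = as.integer(seed))
  class(obj) <- "sim_config"
  obj
}

#' Simulate a structure-annotated alignment on a tree
#'
#' Paired columns evolve jointly as one 16-state site under the pair model
#' (so compensatory substitutions arise from the substitution process
#' itself); unpaired columns evolve independently under the 4-state model.
#' The root is drawn from each model's stationary distribution and states are
#' propagated down the tree with exact transition probabilities.
#' Deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @return A [crs_alignment] with attribute `truth = "structured"`.
#' @export
simulate_structured_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    st <- cfg$structure
    L <- st$L
    npair <- nrow(st$pairs)
    ntip <- length(cfg$tree$tip.label)
    mat <- matrix(NA_character_, ntip, L,
                  dimnames = list(cfg$tree$tip.label, NULL))
    if (npair > 0L) {
      sim16 <- evolve_columns(cfg$tree, cfg$pair_model, npair)
      for (k in seq_len(npair)) {
        mat[, st$pairs[k, 1]] <- substr(sim16[, k], 1, 1)
        mat[, st$pairs[k, 2]] <- substr(sim16[, k], 2, 2)
      }
    }
    if (length(st$unpaired) > 0L) {
      sim4 <- evolve_columns(cfg$tree, cfg$single_model, length(st$unpaired))
      mat[, st$unpaired] <- sim4
    }
    db <- rep(".", L)
    db[st$pairs[, 1]] <- "("
    db[st$pairs[, 2]] <- ")"
    aln <- crs_alignment(setNames(apply(mat, 1, paste, collapse = ""),
                                  rownames(mat)),
                         paste(db, collapse = ""),
                         id = paste0("sim", cfg$seed))
    attr(aln, "truth") <- "structured"
    aln
  })
}

#' Simulate a negative-binomial count matrix
#'
#' Overdispersed read counts per window and sample with specified per-sample
#' scale factors; deterministic given the seed.
#'
#' @param n_features number of features (windows/regions).
#' @param size_factors per-sample scale factors (> 0); their length sets the
#'   number of samples.
#' @param cfg a [sim_config()] supplying `nb_mean`, `nb_dispersion`, `seed`;
#'   alternatively pass `nb_mean`, `nb_dispersion`, `seed` directly.
#' @param nb_mean,nb_dispersion,seed overrides when no `cfg` is given.
#' @return Integer matrix, features x samples.
#' @export
simulate_read_counts <- function(n_features, size_factors = c(1, 1),
                                 cfg = NULL, nb_mean = 50,
                                 nb_dispersion = 0.3, seed = NULL) {
  if (!is.null(cfg)) {
    nb_mean <- cfg$nb_mean; nb_dispersion <- cfg$nb_dispersion
    seed <- cfg$seed
  }
  if (is.null(seed)) stop("seed is mandatory")
  if (any(size_factors <= 0)) stop("size factors must be > 0")
  with_seed(seed, {
    m <- vapply(size_factors, function(sf)
      rnbinom(n_features, mu = nb_mean * sf, size = nb_dispersion),
      numeric(n_features))
    storage.mode(m) <- "integer"
    colnames(m) <- paste0("s", seq_along(size_factors))
    m
  })
}

#' Simulate structure-probing termination counts
#'
#' Emulates paired/unpaired contrast in a chemical-probing termination assay:
#' positions called "paired" receive denatured counts guaranteed to exceed
#' twice the pseudo-counted native level (so the log-fold-change rule fires),
#' unpaired-looking positions the converse.  With probability
#' `probing_noise` a position's call is flipped relative to the structure's
#' truth.  Deterministic given the seed.
#'
#' @param structure a [parse_structure()] result (or dot-bracket string).
#' @param length profile length (>= structure length; default the structure
#'   length).
#' @param depth mean sequencing depth per position (> 0).
#' @param probing_noise call-flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @param kappa pseudo-count the downstream lfc rule will use (default 5).
#' @return List with `native`, `denatured` (count vectors) and
#'   `paired_truth` (logical).
#' @export
simulate_probing_counts <- function(structure, length = NULL, depth = 100,
                                    probing_noise = 0, seed, kappa = 5) {
  if (is.character(structure)) structure <- parse_structure(structure)
  if (depth <= 0) stop("depth must be > 0")
  if (probing_noise < 0 || probing_noise > 1) stop("invalid noise")
  L <- if (is.null(length)) structure$L else length
  if (L < structure$L) stop("length shorter than structure")
  with_seed(seed, {
    truth <- rep(FALSE, L)
    truth[as.vector(structure$pairs)] <- TRUE
    flip <- runif(L) < probing_noise
    call <- xor(truth, flip)
    native <- integer(L)
    denatured <- integer(L)
    low <- pmax(rpois(L, 0.05 * depth), 0L)
    high <- rpois(L, depth)
    paired_idx <- which(call)
    unpaired_idx <- which(!call)
    # paired-looking: denatured' + kappa > 2 (native' + kappa) guaranteed
    native[paired_idx] <- low[paired_idx]
    denatured[paired_idx] <- pmax(high[paired_idx],
                                  4L * (low[paired_idx] + kappa))
    # unpaired-looking: denatured <= native guarantees lfc <= 0
    denatured[unpaired_idx] <- low[unpaired_idx]
    native[unpaired_idx] <- pmax(high[unpaired_idx], low[unpaired_idx])
    list(native = native, denatured = denatured, paired_truth = truth)
  })
}
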