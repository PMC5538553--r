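test_that("build_gtr yields normalized reversible rate matrices", {
  jc <- build_gtr()
  off <- jc$Q[row(jc$Q) != col(jc$Q)]
  expect_equal(unname(off), rep(1 / 3, 12))  # Jukes-Cantor
  expect_equal(rowSums(jc$Q), rep(0, 4), ignore_attr = TRUE)

  m <- build_gtr(pi = c(0.7, 0.1, 0.1, 0.1), exch = rep(1, 6))
  expect_equal(-sum(m$pi * diag(m$Q)), 1)
  # detailed balance on random valid inputs
  set.seed(5)
  for (k in 1:5) {
    pi <- runif(4, 0.05, 1); pi <- pi / sum(pi)
    g <- build_gtr(pi, runif(6, 0.2, 3))
    flux <- g$pi * g$Q
    expect_equal(flux, t(flux), tolerance = 1e-12)
    expect_equal(-sum(g$pi * diag(g$Q)), 1)
  }
  expect_error(build_gtr(pi = c(0.5, 0.5, 0.1, 0.1)), "summing to 1")
  expect_error(build_gtr(exch = c(1, 1, 1, 1, 1, -1)), "positive")
})

test_that("build_pair_model: independence, bias and detailed balance", {
  jc <- build_gtr()
  ind <- build_pair_model(from_single = jc, stacking_bias = NULL)
  expect_true(ind$independent)
  expect_equal(unname(ind$pi), rep(1 / 16, 16))

  def <- build_pair_model(from_single = jc)
  canon <- names(def$pi) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  expect_gt(sum(def$pi[canon]), 0.5)

  set.seed(7)
  pi <- runif(4, 0.05, 1); pi <- pi / sum(pi)
  g <- build_gtr(pi, runif(6, 0.2, 3))
  pm <- build_pair_model(from_single = g, canonical_exchange_boost = 3)
  flux <- pm$pi * pm$Q
  expect_equal(flux, t(flux), tolerance = 1e-12)
  # pair models run at rate 1 per nucleotide = 2 per pair state
  expect_equal(-sum(pm$pi * diag(pm$Q)), 2)
  expect_error(build_pair_model(from_single = jc,
                                stacking_bias = c(wc = -1, wobble = 1)),
               "> 0")
})

test_that("transition_matrix: identity, stochasticity, semigroup", {
  set.seed(9)
  g <- build_gtr(c(0.3, 0.25, 0.25, 0.2), runif(6, 0.3, 2))
  expect_equal(transition_matrix(g, 0), diag(4), ignore_attr = TRUE)
  expect_equal(rowSums(transition_matrix(g, 0.37)), rep(1, 4),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(transition_matrix(g, 0.2) %*% transition_matrix(g, 0.3),
               transition_matrix(g, 0.5), tolerance = 1e-8)
  expect_error(transition_matrix(g, -0.1), "non-negative")
})

test_that("column_likelihood limits and brute-force equivalence", {
  jc <- build_gtr()
  t0 <- tree2(0, 0)
  expect_equal(column_likelihood(t0, c(A = "A", B = "A"), jc), 0.25)
  tinf <- tree2(50, 50)
  expect_equal(column_likelihood(tinf, c(A = "A", B = "A"), jc), 0.25^2,
               tolerance = 1e-6)
  # gaps marginalize: all-missing column has likelihood 1
  expect_equal(column_likelihood(t0, c(A = "-", B = "-"), jc), 1)
  expect_error(column_likelihood(t0, c(A = "A", Z = "C"), jc), "not in tree")

  set.seed(21)
  for (k in 1:10) {
    tr <- random_tree(3, seed = 100 + k)
    obs <- setNames(sample(c("A", "C", "G", "U"), 3, TRUE), tr$tip.label)
    expect_equal(column_likelihood(tr, obs, jc),
                 brute_force_likelihood(tr, as.list(obs), jc),
                 tolerance = 1e-12)
  }
})

test_that("likelihoods sum to 1 over all leaf assignments (<= 3 leaves)", {
  tr <- tree3()
  jc <- build_gtr()
  combos <- expand.grid(a = crstool:::.nuc_states, b = crstool:::.nuc_states,
                        c = crstool:::.nuc_states, stringsAsFactors = FALSE)
  tot <- sum(apply(combos, 1, function(x)
    column_likelihood(tr, setNames(unname(x), c("A", "B", "C")), jc)))
  expect_equal(tot, 1, tolerance = 1e-10)

  pm <- build_pair_model(from_single = jc)  # 16-state, 2-leaf tree
  tr2 <- tree2(0.3, 0.7)
  combos2 <- expand.grid(a = crstool:::.pair_states,
                         b = crstool:::.pair_states, stringsAsFactors = FALSE)
  tot2 <- sum(apply(combos2, 1, function(x)
    column_likelihood(tr2, setNames(unname(x), c("A", "B")), pm)))
  expect_equal(tot2, 1, tolerance = 1e-10)
})

test_that("likelihood is invariant to leaf enumeration order", {
  jc <- build_gtr()
  tr <- tree3()
  obs <- c(A = "G", B = "G", C = "U")
  expect_equal(column_likelihood(tr, obs, jc),
               column_likelihood(tr, obs[c(3, 1, 2)], jc))
})

test_that("gtr_distance: identical, JC closed form, recovery", {
  jc <- build_gtr()
  s <- random_rna(100, seed = 2)
  expect_equal(gtr_distance(s, s, jc), 0)

  # 100 sites, 10 differences -> JC closed form -(3/4) log(1 - 4p/3)
  x <- strsplit(random_rna(100, seed = 4), "")[[1]]
  y <- x
  flip <- 1:10
  y[flip] <- vapply(x[flip], function(ch)
    sample(setdiff(c("A", "C", "G", "U"), ch), 1), character(1))
  expect_equal(gtr_distance(paste(x, collapse = ""), paste(y, collapse = ""),
                            jc),
               -3 / 4 * log(1 - 4 * 0.1 / 3), tolerance = 1e-4)

  # parameter recovery on a simulated 10-kb pair at t = 0.2
  set.seed(77)
  g <- build_gtr(c(0.3, 0.2, 0.3, 0.2), c(1, 2, 1, 1, 2, 1))
  P <- transition_matrix(g, 0.2)
  a_idx <- sample.int(4, 10000, TRUE, prob = g$pi)
  b_idx <- vapply(a_idx, function(i) sample.int(4, 1, prob = P[i, ]),
                  integer(1))
  d <- gtr_distance(crstool:::.nuc_states[a_idx],
                    crstool:::.nuc_states[b_idx], g)
  expect_lt(abs(d - 0.2), 0.02)

  expect_error(gtr_distance("----", "AAAA", jc), "no comparable")
})

test_that("estimate_gtr recovers the stationary distribution", {
  tr <- tree8(0.3)
  truth <- build_gtr(c(0.4, 0.15, 0.3, 0.15), rep(1, 6))
  set.seed(31)
  cols <- crstool:::evolve_columns(tr, truth, 3000)
  fit <- estimate_gtr(cols, tr, maxit = 300)
  expect_true(all(abs(fit$pi - truth$pi) < 0.03))
  # optimization contract: fitted log-likelihood >= JC start
  obsmat <- matrix(match(cols, crstool:::.nuc_states), nrow = nrow(cols),
                   dimnames = list(rownames(cols), NULL))
  ll_jc <- sum(log(crstool:::prune_likelihoods(tr, obsmat, build_gtr())))
  expect_gte(attr(fit, "logLik"), ll_jc)

  mono <- matrix("A", 8, 50, dimnames = list(tr$tip.label, NULL))
  expect_error(estimate_gtr(mono, tr), "degenerate")
})

test_that("independence pair model factorizes over columns", {
  set.seed(13)
  for (k in 1:10) {
    tr <- random_tree(sample(2:4, 1), seed = 300 + k)
    pi <- runif(4, 0.05, 1); pi <- pi / sum(pi)
    g <- build_gtr(pi, runif(6, 0.2, 3))
    ind <- build_pair_model(from_single = g, stacking_bias = NULL)
    n <- length(tr$tip.label)
    c1 <- setNames(sample(c("A", "C", "G", "U"), n, TRUE), tr$tip.label)
    c2 <- setNames(sample(c("A", "C", "G", "U"), n, TRUE), tr$tip.label)
    pair_obs <- setNames(paste0(c1, c2), tr$tip.label)
    expect_equal(column_likelihood(tr, pair_obs, ind),
                 column_likelihood(tr, c1, g) * column_likelihood(tr, c2, g),
                 tolerance = 1e-10)
  }
})
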