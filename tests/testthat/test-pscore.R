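test_that("parse_structure partitions columns into P and U", {
  st <- parse_structure("((...))")
  expect_equal(st$pairs, matrix(c(1L, 2L, 7L, 6L), 2, 2,
                                dimnames = list(NULL, c("i", "j"))))
  expect_equal(st$unpaired, 3:5)

  st2 <- parse_structure(".......")
  expect_equal(nrow(st2$pairs), 0L)
  expect_equal(st2$unpaired, 1:7)

  expect_error(parse_structure("(.)"), "spans <= h")
})

test_that("pair_log_odds factorizes under an independence pair model", {
  tr <- tree3()
  cons <- build_gtr()
  models <- score_models(cons = cons,
                         pair = build_pair_model(from_single = cons,
                                                 stacking_bias = NULL))
  aln <- crs_alignment(c(A = "GAACCUUC", B = "GAACCUUC", C = "CAACCUUG"),
                       "((....))")
  lo <- pair_log_odds(tr, aln, 1, 8, models)
  expect_equal(lo$l_pair, lo$l_cons, tolerance = 1e-10)
})

test_that("covariation scores positive under the default structured model", {
  # perfectly covarying closing pair across two clades: GC in one, AU in the
  # other; oracle = brute-force pruning likelihoods on the 4-leaf tree
  tr <- read_newick(text = "((A:0.3,B:0.3):0.3,(C:0.3,D:0.3):0.3);")
  aln <- crs_alignment(c(A = "GAAAAAC", B = "GAAAAAC",
                         C = "AAAAAAU", D = "AAAAAAU"), "(.....)")
  models <- score_models()
  lo <- pair_log_odds(tr, aln, 1, 7, models)
  expect_gt(lo$l_pair - lo$l_cons, 0)

  brute_pair <- brute_force_likelihood(
    tr, list(A = "GC", B = "GC", C = "AU", D = "AU"), models$pair)
  expect_equal(lo$l_pair, log2(brute_pair), tolerance = 1e-10)
})

test_that("all-gap column pairs are fully marginalized to 0 bits", {
  tr <- tree2()
  aln <- crs_alignment(c(A = "-AAAAA-", B = "-AAAAA-"), "(.....)")
  lo <- pair_log_odds(tr, aln, 1, 7, score_models())
  expect_equal(lo$l_pair, 0)
  expect_equal(lo$l_cons, 0)
  expect_equal(lo$l_neut, 0)
})

test_that("pscore definition: empty P, neut = cons symmetry, gap cap", {
  tr <- tree3()
  aln <- crs_alignment(c(A = "GGCAAUC", B = "GGCAAUC", C = "GGCAAUC"),
                       ".......")
  res <- pscore(aln, tr)
  expect_equal(res$delta_cons, 0)
  expect_lte(res$pscore, 0)
  expect_equal(res$n_pairs, 0L)

  # neutral model identical to conserved -> both deltas coincide
  models <- score_models()
  models$neut <- models$cons
  aln2 <- crs_alignment(c(A = "GGAAAACC", B = "GGAAAACC", C = "CGAAAACG"),
                        "((....))")
  res2 <- pscore(aln2, tr, models)
  expect_equal(res2$delta_cons, res2$delta_neut)
  expect_equal(res2$pscore, min(res2$delta_cons, res2$delta_neut))

  # a pair gapped in >50% of rows gets weight zero
  aln3 <- crs_alignment(c(A = "-GAAAAC-", B = "-GAAAAC-", C = "GGAAAACC"),
                        "((....))")
  res3 <- pscore(aln3, tr)
  expect_equal(res3$per_pair$w[res3$per_pair$i == 1], 0)
})

test_that("null neutrality: unit weights + independence model give 0", {
  tr <- tree8()
  cons <- build_gtr()
  models <- score_models(cons = cons,
                         pair = build_pair_model(from_single = cons,
                                                 stacking_bias = NULL))
  set.seed(99)
  for (k in 1:5) {
    rows <- setNames(replicate(8, random_rna(40)), tr$tip.label)
    aln <- crs_alignment(rows, paste0("((((((....))))))", strrep(".", 24)))
    res <- pscore(aln, tr, models, em = NULL)
    expect_equal(res$delta_cons, 0, tolerance = 1e-9)
  }
})

test_that("pscore is additive over pairs and invariant to row order", {
  tr <- tree8()
  cfg <- sim_config(tr, bench_structure(), seed = 41)
  aln <- simulate_structured_alignment(cfg)
  models <- score_models()
  em <- energy_model()
  res <- pscore(aln, tr, models, em)

  # row order invariance
  perm <- aln
  perm$rows <- perm$rows[sample(length(perm$rows))]
  res_p <- pscore(crs_alignment(perm$rows, aln$structure), tr, models, em)
  expect_equal(res_p$pscore, res$pscore, tolerance = 1e-9)

  # additivity: dropping one pair changes delta_cons by its contribution
  st <- parse_structure(aln$structure)
  drop <- 3L
  keep <- st$pairs[-drop, , drop = FALSE]
  db <- rep(".", aln$L)
  db[keep[, 1]] <- "("; db[keep[, 2]] <- ")"
  aln2 <- crs_alignment(aln$rows, paste(db, collapse = ""))
  res2 <- pscore(aln2, tr, models, em)
  contrib <- res$per_pair$w[drop] *
    (res$per_pair$l_pair[drop] - res$per_pair$l_cons[drop])
  expect_equal(res$delta_cons - res2$delta_cons, contrib, tolerance = 1e-9)
})

test_that("faster neutral models weakly increase delta_neut on conserved data", {
  tr <- tree8(0.15)
  cfg <- sim_config(tr, bench_structure(), seed = 17)
  aln <- simulate_structured_alignment(cfg)
  em <- energy_model()
  d <- vapply(c(1.5, 3, 6), function(rho)
    pscore(aln, tr, score_models(rho = rho), em)$delta_neut, numeric(1))
  expect_true(all(diff(d) >= 0))
})

test_that("classify uses a closed inequality", {
  expect_true(classify(5, 5))
  expect_false(classify(-1, 0))
  r <- list(pscore = 3.2)
  class(r) <- "pscore_result"
  expect_true(classify(r, 3.2))
})
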