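test_that("empirical_pvalue: add-one smoothing and monotonicity", {
  bg <- 1:999
  expect_equal(empirical_pvalue(1000, bg), 1 / 1000)
  expect_equal(empirical_pvalue(0, bg), 1)
  expect_equal(empirical_pvalue(500, bg), (1 + 500) / 1000)
  expect_error(empirical_pvalue(3, numeric(0)), "empty")
  # monotone non-increasing in the observed count
  p <- empirical_pvalue(0:1000, bg)
  expect_true(all(diff(p) <= 0))
})

test_that("expression_calls applies the p < 0.01 rule", {
  bg <- rep(c(0, 1, 2, 5), 250)   # 1000 background loci
  calls <- expression_calls(c(loA = 1, hiA = 50), bg)
  expect_false(calls$expressed[calls$feature == "loA"])
  expect_true(calls$expressed[calls$feature == "hiA"])
  expect_equal(calls$empirical_p[2], 1 / 1001)
})

test_that("cpm_rle_normalize: size factors and recovery", {
  m <- matrix(rep(c(10L, 20L, 30L), 2), ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  r <- cpm_rle_normalize(m)
  expect_equal(unname(r$size_factors), c(1, 1))
  m2 <- cbind(s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
  r2 <- cpm_rle_normalize(m2)
  expect_equal(unname(r2$size_factors[2] / r2$size_factors[1]), 2)

  truth <- c(1, 2, 0.5, 1)
  counts <- simulate_read_counts(500, size_factors = truth, nb_mean = 50,
                                 nb_dispersion = 5, seed = 303)
  est <- cpm_rle_normalize(counts)$size_factors
  est <- est / exp(mean(log(est)))
  ref <- truth / exp(mean(log(truth)))
  expect_true(all(abs(est / ref - 1) < 0.1))

  expect_error(cpm_rle_normalize(matrix(0L, 3, 2)), "positive")
})

test_that("coexpression returns Pearson r with a strong flag", {
  expect_equal(coexpression(1:5, 1:5)$r, 1)
  expect_equal(coexpression(1:5, -(1:5))$r, -1)
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  # textbook formula oracle
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(coexpression(a, b)$r, r_hand)
  expect_warning(z <- coexpression(c(1, 1, 1), 1:3), "zero-variance")
  expect_true(is.na(z$r))
})

test_that("call_islands: extension, merging, repeat filter, p-values", {
  reads <- interval_set("chr1", c(100, 180), c(150, 230), strand = "+")
  isl <- call_islands(reads, extension = 150)
  expect_equal(nrow(isl), 1L)
  expect_equal(c(isl$start, isl$end), c(100L, 330L))
  expect_equal(isl$read_count, 2L)

  far <- interval_set("chr1", c(100, 500), c(150, 550), strand = "+")
  isl2 <- call_islands(far, extension = 150)
  expect_equal(nrow(isl2), 2L)
  expect_equal(isl2$read_count, c(1L, 1L))

  # 100-nt read overlapping a repeat by 50 nt is removed (>= 50% rule)
  reads3 <- interval_set("chr1", c(0, 300), c(100, 400), strand = "+")
  reps <- interval_set("chr1", 50, 150)
  isl3 <- call_islands(reads3, repeats = reps, extension = 150)
  expect_equal(nrow(isl3), 1L)
  expect_equal(isl3$start, 300L)

  # minus-strand reads anchor at their 3' coordinate
  mr <- interval_set("chr1", 1000, 1050, strand = "-")
  mi <- call_islands(mr, extension = 150)
  expect_equal(c(mi$start, mi$end), c(900L, 1050L))

  # on-target flag and off-target-based empirical p
  set.seed(6)
  starts <- seq(0, 19000, 1000)
  counts <- c(40, rep(1, 19))
  rd <- do.call(rbind, lapply(seq_along(starts), function(i)
    interval_set("chr1", rep(starts[i], counts[i]),
                 rep(starts[i] + 50, counts[i]), strand = "+")))
  class(rd) <- c("interval_set", "data.frame")
  probes <- interval_set("chr1", 0, 200)
  isl4 <- call_islands(rd, probes = probes, extension = 150)
  expect_equal(sum(isl4$on_target), 1L)
  expect_equal(isl4$empirical_p[isl4$on_target], 1 / 20)
  expect_true(isl4$expressed[isl4$on_target])
  expect_error(call_islands(interval_set("chr1", 1, 5)), "strand")

  # order invariance and count conservation
  shuf <- rd[sample(nrow(rd)), ]
  class(shuf) <- c("interval_set", "data.frame")
  isl5 <- call_islands(shuf, probes = probes, extension = 150)
  expect_equal(isl5$read_count, isl4$read_count)
  expect_equal(sum(isl5$read_count), nrow(rd))
})

test_that("exosome_sensitivity formula, clipping and thresholds", {
  r <- exosome_sensitivity(c(8, 8, 8, 2, 0), c(2, 6, 10, 1, 5))
  expect_equal(r$s, c(0.75, 0.25, 0, 0.5, NA))
  expect_equal(r$klass, c("unstable", "stable", "stable", "intermediate", NA))
  # scale invariance
  expect_equal(exosome_sensitivity(16, 4)$s, exosome_sensitivity(8, 2)$s)
})

test_that("probing_lfc boundary behaviour and depth normalization", {
  p <- probing_lfc(11, 27)
  expect_equal(p$lfc, 1)
  expect_false(p$paired_call)   # strict > 1

  p2 <- probing_lfc(0, 59)
  expect_equal(p2$lfc, 6 - log2(5))
  expect_true(p2$paired_call)

  p3 <- probing_lfc(c(5, 9, 100), c(5, 9, 100))
  expect_true(all(p3$lfc == 0))
  expect_false(any(p3$paired_call))

  # doubling the denatured depth cancels doubled denatured counts
  p4 <- probing_lfc(10, 60, depth_native = 1, depth_denatured = 2)
  expect_equal(p4$lfc, probing_lfc(10, 30)$lfc)
  expect_error(probing_lfc(1:3, 1:4), "length mismatch")
})

test_that("probing_concordance counts paired positions", {
  st <- parse_structure("((((....))))")
  prof <- probing_lfc(rep(0L, 12), c(rep(59L, 4), rep(0L, 4), rep(59L, 4)))
  expect_equal(probing_concordance(st, prof), 1)
  flat <- probing_lfc(rep(10L, 12), rep(10L, 12))
  expect_equal(probing_concordance(st, flat), 0)
  expect_error(probing_concordance(parse_structure("............"), flat),
               "no paired positions")
})
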