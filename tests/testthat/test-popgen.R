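test_that("rarefaction matches exhaustive enumeration and the closed cases", {
  expect_equal(rarefied_allelic_richness(c(A = 3, B = 1), 2), 1.5)
  # g = N returns the observed allele count; g = 1 returns 1
  expect_equal(rarefied_allelic_richness(c(4, 3, 2), 9), 3)
  expect_equal(rarefied_allelic_richness(c(4, 3, 2), 1), 1)
  expect_error(rarefied_allelic_richness(c(2, 1), 4), "exceeds")
  # every allele configuration with N <= 12 gene copies, all g
  for (N in 2:12) {
    for (cfg in integer_partitions(N)) {
      for (g in unique(c(1L, 2L, N %/% 2L, N))) {
        if (g < 1) next
        expect_equal(rarefied_allelic_richness(cfg, g),
                     rarefaction_oracle(cfg, g), tolerance = 1e-10)
      }
    }
  }
})

test_that("unbiased heterozygosity matches direct evaluation and limits", {
  expect_equal(expected_heterozygosity(c(5, 5)), (10 / 9) * 0.5)
  expect_equal(expected_heterozygosity(c(7)), 0)
  # k equifrequent alleles at large n approach 1 - 1/k
  expect_lt(abs(expected_heterozygosity(rep(10000, 4)) - 0.75), 1e-4)
  expect_error(expected_heterozygosity(c(1)), "2 gene copies")
})

test_that("F_IS reproduces hand-computed and boundary cases", {
  # 4 individuals: AA, AA, AB, BB
  gm <- gm_from_calls(list(list(c(1, 1)), list(c(1, 1)), list(c(1, 2)),
                           list(c(2, 2))), rep("p", 4))
  res <- fis(gm)
  he <- (8 / 7) * (1 - 0.625^2 - 0.375^2)
  expect_equal(unname(res$per_locus[1]), 1 - 0.25 / he, tolerance = 1e-10)
  expect_equal(res$mean, 1 - 0.25 / he, tolerance = 1e-10)
  # all homozygotes at a polymorphic locus: F_IS = 1
  gm2 <- gm_from_calls(list(list(c(1, 1)), list(c(2, 2))), rep("p", 2))
  expect_equal(unname(fis(gm2)$per_locus[1]), 1)
  # Hardy-Weinberg genotypes in a large sample: F_IS near 0
  set.seed(61)
  gm3 <- simulate_balding_nichols(biallelic_freqs(20), 0, 500)
  expect_lt(abs(fis(gm3)$mean), 0.02)
})

test_that("Weir-Cockerham theta equals the scalar oracle on random instances", {
  set.seed(62)
  for (rep in 1:40) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    k <- sample(2:4, 1)
    calls <- c(lapply(seq_len(n1), function(i)
      list(sort(sample.int(k, 2, TRUE)))),
      lapply(seq_len(n2), function(i) list(sort(sample.int(k, 2, TRUE)))))
    gm <- gm_from_calls(calls, rep(c("p1", "p2"), c(n1, n2)))
    cnt <- fragdiv:::pooled_counts_locus(gm, 1)
    if (length(cnt) < 2) next
    th <- wc_fst(gm, filters = list(max_missing = 1, min_maf = 0))$theta
    expect_equal(th, wc_theta_oracle(gm), tolerance = 1e-10)
  }
})

test_that("theta behaves at the differentiation extremes", {
  set.seed(63)
  # two samples from one pool: theta near 0
  gm0 <- simulate_balding_nichols(biallelic_freqs(30), c(0, 0), c(500, 500))
  expect_lt(abs(wc_fst(gm0, filters = list(max_missing = 1,
                                           min_maf = 0))$theta), 0.01)
  # fixed for alternative alleles: theta = 1
  gm1 <- gm_from_calls(c(rep(list(list(c(1, 1))), 6),
                         rep(list(list(c(2, 2))), 6)),
                       rep(c("p1", "p2"), each = 6))
  expect_equal(wc_fst(gm1, filters = list(max_missing = 1,
                                          min_maf = 0))$theta, 1)
})

test_that("ratio-of-sums equals the single-locus formula for one locus", {
  set.seed(64)
  gm <- simulate_balding_nichols(biallelic_freqs(1), c(0.2, 0.05), c(12, 15))
  res <- wc_fst(gm, filters = list(max_missing = 1, min_maf = 0))
  expect_equal(res$theta, unname(res$per_locus[1]))
})

test_that("F_ST filters screen missingness, MAF and population presence", {
  calls <- list(list(c(1, 1), c(1, 1), c(1, 1)),
                list(c(1, 2), NA,      c(1, 1)),
                list(c(2, 2), NA,      c(1, 1)),
                list(c(1, 2), NA,      c(1, 2)))
  gm <- gm_from_calls(calls, c("p1", "p1", "p2", "p2"))
  # locus 2: 75% missing; locus 3: MAF = 1/8 but absent in p1? present; keep
  res <- wc_fst(gm, filters = list(max_missing = 0.25, min_maf = 0.05))
  expect_equal(res$n_loci_used, 2L)
  res2 <- wc_fst(gm, filters = list(max_missing = 0.25, min_maf = 0.2))
  expect_equal(res2$n_loci_used, 1L)
})

test_that("permutation p-value detects real structure", {
  set.seed(65)
  gm <- simulate_balding_nichols(biallelic_freqs(30), c(0.25, 0.25), c(25, 25))
  res <- wc_fst(gm, filters = list(max_missing = 1, min_maf = 0),
                n_perm = 99, seed = 1)
  expect_lt(res$p_value, 0.05)
})

test_that("pairwise theta matrix is symmetric with zero diagonal", {
  set.seed(66)
  gm <- simulate_balding_nichols(biallelic_freqs(25), c(0.1, 0.02, 0.3),
                                 c(15, 15, 15))
  m <- pairwise_fst(gm, filters = list(max_missing = 1, min_maf = 0))
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 3), rownames(m)))
  expect_gt(m["pop_1", "pop_3"], 0)
})

test_that("linearized F_ST matches its closed form and sentinels", {
  expect_equal(linearize_fst(0.5), 1)
  expect_equal(linearize_fst(1), 0)
  expect_equal(round(linearize_fst(0.021), 2), 46.62)
  expect_warning(m <- linearize_fst(-0.01), "Inf")
  expect_identical(m, Inf)
  expect_error(linearize_fst(1.2), "exceed")
})

test_that("great-circle distances match the antipodal arc and symmetry", {
  meta <- population_meta(c("a", "b", "c"), c(0, 0, 45), c(0, 180, 9),
                          rep("1-10", 3), rep("x", 3))
  d <- great_circle_distances(meta)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], pi * 6371, tolerance = 1e-6)
  expect_equal(d, t(d))
})

test_that("Mantel statistics hit +/-1 on exact correspondence", {
  set.seed(67)
  meta <- population_meta(paste0("p", 1:5), runif(5, 50, 60), runif(5, -5, 0),
                          rep("1-10", 5), rep("x", 5))
  dk <- great_circle_distances(meta)
  g <- log(dk); diag(g) <- 0
  expect_equal(mantel_test(g, dk, n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(-g, dk, n_perm = 99, seed = 1)$r, -1)
  expect_error(mantel_test(g[1:3, 1:3], dk[1:3, 1:3]), "too few")
  dk0 <- dk; dk0[1, 2] <- dk0[2, 1] <- 0
  expect_error(mantel_test(g, dk0), "zero or negative")
})

test_that("exhaustive Mantel p equals full permutation enumeration", {
  set.seed(68)
  meta <- population_meta(paste0("p", 1:5), runif(5, 50, 60), runif(5, -5, 0),
                          rep("1-10", 5), rep("x", 5))
  dk <- great_circle_distances(meta)
  g <- matrix(0, 5, 5)
  g[upper.tri(g)] <- runif(10, 1, 50)
  g <- g + t(g)
  res <- mantel_test(g, dk, exhaustive = TRUE)
  oracle <- mantel_exhaustive_oracle(g, log(dk))
  expect_equal(res$r, oracle$r)
  expect_equal(res$p, oracle$p)
  expect_equal(res$n_perm, 120L)
})

test_that("Mantel r agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(69)
  g <- matrix(0, 6, 6); g[upper.tri(g)] <- runif(15)
  g <- g + t(g)
  d <- matrix(0, 6, 6); d[upper.tri(d)] <- runif(15, 1, 10)
  d <- d + t(d)
  ours <- mantel_test(g, d, log_distance = FALSE, n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(g), as.dist(d), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("region summaries exclude populations below five individuals", {
  set.seed(70)
  freqs <- biallelic_freqs(12)
  regions <- setNames(c("brit", "brit", "brit"), paste0("pop_", 1:3))
  gm <- simulate_balding_nichols(freqs, c(0.05, 0.05, 0.3), c(20, 20, 2),
                                 regions = regions)
  dt <- diversity_table(gm, g_rarefy = 10, min_pop_size = 5)
  poprows <- dt[dt$unit == "population", ]
  expect_true(poprows$excluded[poprows$id == "pop_3"])
  regrow <- dt[dt$unit == "region", ]
  expect_equal(regrow$n_ind, 40L)  # pop_3 left out
  expect_true(is.finite(regrow$fst))
})

test_that("diversity table approaches truth on Balding-Nichols output", {
  set.seed(71)
  freqs <- biallelic_freqs(60)
  gm <- simulate_balding_nichols(freqs, rep(0.1, 6), rep(30, 6))
  res <- wc_fst(gm, filters = list(max_missing = 1, min_maf = 0))
  expect_lt(abs(res$theta - 0.1), 0.035)
})

test_that("the isolation-by-distance wrapper runs end to end", {
  set.seed(72)
  freqs <- biallelic_freqs(40)
  pops <- paste0("p", 1:5)
  regions <- setNames(rep("brit", 5), pops)
  gm <- simulate_balding_nichols(freqs, rep(0.08, 5), rep(15, 5),
                                 pop_ids = pops, regions = regions)
  meta <- population_meta(pops, runif(5, 55, 58), runif(5, -5, -2),
                          rep("10-100", 5), rep("brit", 5))
  res <- suppressWarnings(ibd_test(gm, meta, "brit", n_perm = 99, seed = 1))
  expect_true(is.finite(res$mantel$r))
  expect_true(res$mantel$p > 0 && res$mantel$p <= 1)
  expect_equal(dim(res$m_matrix), dim(res$distance_km))
})
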