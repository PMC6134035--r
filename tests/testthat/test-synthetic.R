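test_that("Balding-Nichols collapses to the regional mean at F = 0", {
  set.seed(21)
  freqs <- list(c(0.3, 0.7))
  gm <- simulate_balding_nichols(freqs, 0, 2000)
  p_hat <- mean(c(gm$a1[, 1], gm$a2[, 1]) == 1L)
  expect_lt(abs(p_hat - 0.3), 0.02)
})

test_that("across-population frequency variance matches F pi (1 - pi)", {
  set.seed(22)
  n <- 50
  gm <- simulate_balding_nichols(list(c(0.5, 0.5)), rep(0.2, 500), rep(n, 500))
  p_hat <- vapply(unique(gm$populations), function(p) {
    rows <- gm$populations == p
    mean(c(gm$a1[rows, 1], gm$a2[rows, 1]) == 1L)
  }, 0)
  # sampling of 2n copies adds E[p(1-p)]/(2n) = pi(1-pi)(1-F)/(2n)
  expected <- 0.2 * 0.25 + 0.25 * 0.8 / (2 * n)
  expect_lt(abs(var(p_hat) - expected), 0.012)
})

test_that("generators are reproducible under a fixed seed", {
  freqs <- biallelic_freqs(5)
  g1 <- simulate_balding_nichols(freqs, c(0.1, 0.2), c(5, 5), seed = 33)
  g2 <- simulate_balding_nichols(freqs, c(0.1, 0.2), c(5, 5), seed = 33)
  expect_true(fragdiv:::gm_equal(g1, g2))
  w1 <- simulate_wright_fisher_ld(20, 10, 5, 10, mu = 0.01, seed = 34)
  w2 <- simulate_wright_fisher_ld(20, 10, 5, 10, mu = 0.01, seed = 34)
  expect_true(fragdiv:::gm_equal(w1, w2))
})

test_that("BN rejects invalid frequencies and F", {
  expect_error(simulate_balding_nichols(list(c(0.5, 0.6)), 0.1, 5), "sum to 1")
  expect_error(simulate_balding_nichols(list(c(0.5, 0.5)), 1, 5), "degenerate")
})

test_that("Wright-Fisher drifts to fixation without mutation", {
  set.seed(23)
  gm <- simulate_wright_fisher_ld(10, 10, 100, generations = 200, mu = 0)
  het <- vapply(seq_len(100), function(j) {
    cnt <- fragdiv:::pooled_counts_locus(gm, j)
    length(cnt) > 1L
  }, TRUE)
  expect_lt(mean(het), 0.02)
})

test_that("heterozygosity decays at rate 1 - 1/(2Ne) under drift", {
  set.seed(24)
  ne <- 20; gens <- 30; L <- 400
  # track expected heterozygosity 2p(1-p) through time via repeated snapshots
  h <- numeric(gens)
  A1 <- matrix(rbinom(ne * L, 1, 0.5), ne, L)
  A2 <- matrix(rbinom(ne * L, 1, 0.5), ne, L)
  for (g in seq_len(gens)) {
    mo <- sample.int(ne, ne, TRUE); fa <- sample.int(ne, ne, TRUE)
    pm <- matrix(runif(ne * L) < 0.5, ne, L)
    pf <- matrix(runif(ne * L) < 0.5, ne, L)
    N1 <- ifelse(pm, A1[mo, ], A2[mo, ]); N2 <- ifelse(pf, A1[fa, ], A2[fa, ])
    A1 <- N1; A2 <- N2
    p <- colMeans(rbind(A1, A2))
    h[g] <- mean(2 * p * (1 - p))
  }
  fit <- lm(log(h) ~ seq_len(gens))
  slope <- unname(coef(fit)[2])
  expect_lt(abs(slope - log(1 - 1 / (2 * ne))), 0.01)
})

test_that("simulated read bundles respect coverage and allele split", {
  true <- gm_from_calls(list(list(c(1, 2))), "p1", marker_kind = "ssr_id")
  seqs <- list(c("ACGTACGTAC", "ACGTACGTAG"))
  # zero coverage: no bundles at all
  rb0 <- simulate_rad_reads(true, seqs, coverage_mean = 0, seed = 1)
  expect_equal(nrow(rb0), 0L)
  # heterozygote at high coverage, no error: both sequences, counts sum
  rb <- simulate_rad_reads(true, seqs, coverage_mean = 40, seed = 2)
  expect_setequal(rb$sequence, seqs[[1]])
  expect_gte(sum(rb$count), 1L)
  # unmapped allele errors out
  expect_error(simulate_rad_reads(true, list("ACGT"), 10), "sequence mapping")
})

test_that("poisson coverage mean is respected", {
  set.seed(25)
  true <- gm_from_calls(rep(list(list(c(1, 1))), 300), rep("p1", 300),
                        marker_kind = "ssr_id")
  seqs <- list(c("ACGTACGTAC"))
  rb <- simulate_rad_reads(true, seqs, coverage_mean = 12)
  per_ind <- tapply(rb$count, rb$individual, sum)
  totals <- rep(0, 300)
  totals[match(names(per_ind), true$individuals)] <- per_ind
  expect_lt(abs(mean(totals) - 12), 3.5 * sqrt(12 / 300))
})

test_that("a minimal study fixture feeds every downstream stage", {
  cfg <- synthetic_study_config(
    n_pop_fragmented = 2, n_pop_continuous = 2,
    n_ind_fragmented = c(8, 8), n_ind_continuous = c(8, 8),
    loci = c(ssr_length = 3, ssr_id = 3, snp_ti = 3, snp_tv = 3),
    bundle_loci = 2, seed = 99)
  fix <- make_study_fixture(cfg)
  expect_named(fix$genotypes, c("ssr_length", "ssr_id", "snp_ti", "snp_tv"))
  expect_equal(length(unique(fix$genotypes$ssr_length$populations)), 4L)
  expect_s3_class(fix$meta, "population_meta")
  expect_s3_class(fix$bundles, "read_bundle_set")
  # every stage accepts it
  dt <- diversity_table(fix$genotypes$ssr_length, g_rarefy = 8,
                        min_pop_size = 2)
  expect_true(all(c("population", "region") %in% dt$unit))
  called <- call_genotypes(trim_reads(fix$bundles, 0))
  expect_s3_class(called, "genotype_matrix")
  est <- ld_ne(fix$genotypes$snp_ti)
  expect_equal(nrow(est), length(unique(fix$genotypes$snp_ti$populations)))
})

test_that("the study-shaped fixture reproduces the sampling design", {
  cfg <- synthetic_study_config(
    loci = c(ssr_length = 4, ssr_id = 4, snp_ti = 4, snp_tv = 4),
    bundle_loci = 2, seed = 5)
  fix <- make_study_fixture(cfg)
  reg <- table(fix$meta$region)
  expect_equal(unname(reg[c("fragmented", "continuous")]),
               c(29L, 10L), ignore_attr = TRUE)
  # tiny exhaustively-sampled remnants present
  sizes <- table(fix$genotypes$ssr_length$populations)
  expect_gte(sum(sizes <= 2), 2L)
  # all four census categories represented
  expect_setequal(unique(fix$meta$census_category),
                  c("1-10", "10-100", "100-1000", "1000-10000"))
  # RAD sets live on a subset of the PCR individuals
  expect_lt(length(fix$genotypes$snp_ti$individuals),
            length(fix$genotypes$ssr_length$individuals))
  expect_true(all(fix$genotypes$snp_ti$individuals %in%
                    fix$genotypes$ssr_length$individuals))
  # fixed seed => identical fixture
  fix2 <- make_study_fixture(cfg)
  expect_identical(fix$meta, fix2$meta)
  expect_true(fragdiv:::gm_equal(fix$genotypes$ssr_id,
                                 fix2$genotypes$ssr_id))
  # fixture round-trips through the io layer
  d <- withr::local_tempdir()
  write_study_fixture(fix, d)
  back <- read_genotypes(file.path(d, "ssr_length.tsv"), "tsv")
  expect_true(fragdiv:::gm_equal(fix$genotypes$ssr_length, back))
})

test_that("YAML study configs are honoured", {
  f <- withr::local_tempfile(
    lines = c("n_pop_fragmented: 3", "n_pop_continuous: 2",
              "n_ind_fragmented: [4, 4, 4]", "n_ind_continuous: [4, 4]",
              "loci:", "  ssr_length: 2", "  ssr_id: 2",
              "  snp_ti: 2", "  snp_tv: 2", "seed: 3"),
    fileext = ".yaml")
  cfg <- read_study_config(f)
  expect_equal(cfg$n_pop_fragmented, 3L)
  expect_equal(unname(cfg$loci["ssr_id"]), 2L)
})
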