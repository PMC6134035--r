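test_that("regional means distinguish pooled and population-averaged modes", {
  # pop_1: 10 individuals at p = 0.2; pop_2: 90 individuals at p = 0.8
  calls1 <- lapply(seq_len(10), function(i)
    list(if (i <= 2) c(1, 1) else if (i <= 4) c(1, 2) else c(2, 2)))
  # pop_1 allele-1 copies: 2*2 + 2 = 6 of 20 -> 0.3; adjust to exact 0.2
  calls1 <- lapply(seq_len(10), function(i)
    list(if (i <= 2) c(1, 1) else c(2, 2)))           # 4/20 = 0.2
  calls2 <- lapply(seq_len(90), function(i)
    list(if (i <= 72) c(1, 1) else c(2, 2)))          # 144/180 = 0.8
  gm <- gm_from_calls(c(calls1, calls2), rep(c("a", "b"), c(10, 90)),
                      regions = c(a = "reg", b = "reg"))
  pooled <- regional_mean_frequencies(gm, "reg", mode = "pooled")
  popm <- regional_mean_frequencies(gm, "reg", mode = "pop_mean")
  expect_equal(unname(pooled$freqs[[1]][1]), 148 / 200)
  expect_equal(unname(popm$freqs[[1]][1]), 0.5)
  # equal sizes: both modes coincide
  gm2 <- gm_from_calls(c(calls1, calls1), rep(c("a", "b"), each = 10),
                       regions = c(a = "reg", b = "reg"))
  expect_equal(regional_mean_frequencies(gm2, "reg", "pooled")$freqs[[1]],
               regional_mean_frequencies(gm2, "reg", "pop_mean")$freqs[[1]])
  # monomorphic locus flagged
  gm3 <- gm_from_calls(rep(list(list(c(1, 1))), 4), rep(c("a", "b"), 2),
                       regions = c(a = "reg", b = "reg"))
  expect_true(regional_mean_frequencies(gm3, "reg")$monomorphic[1])
})

test_that("a single draw marginalizes to the mean frequency for any F", {
  for (f in c(0.01, 0.2, 0.7))
    expect_equal(dirichlet_multinomial_loglik(c(1, 0), c(0.5, 0.5), f),
                 log(0.5), tolerance = 1e-12)
})

test_that("the closed-form beta-binomial case evaluates exactly", {
  # counts (2,0), pi = (.5,.5), F = .5: likelihood = E[p^2], p ~ Beta(.5,.5)
  expect_equal(exp(dirichlet_multinomial_loglik(c(2, 0), c(0.5, 0.5), 0.5)),
               0.375, tolerance = 1e-12)
  # F -> 0 approaches the binomial limit p^2 = 0.25
  expect_equal(exp(dirichlet_multinomial_loglik(c(2, 0), c(0.5, 0.5), 1e-7)),
               0.25, tolerance = 1e-5)
  expect_error(dirichlet_multinomial_loglik(c(2, 0), c(0.5, 0.5), 0), "inside")
  expect_error(dirichlet_multinomial_loglik(c(2, 1), c(1, 0), 0.3),
               "zero regional frequency")
})

test_that("likelihood equals the numerical beta integral on biallelic loci", {
  set.seed(81)
  for (f in c(0.01, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9)) {
    for (rep in 1:3) {
      n <- sample(2:30, 1)
      k <- sample(0:n, 1)
      pi1 <- runif(1, 0.1, 0.9)
      lik <- exp(dirichlet_multinomial_loglik(c(k, n - k), c(pi1, 1 - pi1), f))
      expect_lt(abs(lik - beta_integral_lik(k, n, pi1, f)), 1e-8)
    }
  }
})

test_that("no divergence evidence drives F to the lower search bound", {
  fr <- regional_frequencies(list(c(0.5, 0.5)))
  gm <- gm_from_calls(rep(list(list(c(1, 2))), 5), rep("p1", 5))
  est <- estimate_mlfst(gm, "p1", fr)
  expect_true(est$boundary)
  expect_equal(est$f_hat, 1e-4, tolerance = 1e-2)
})

test_that("fixation on a rare allele drives F high", {
  L <- 40
  fr <- regional_frequencies(replicate(L, c(0.05, 0.95), simplify = FALSE))
  gm <- gm_from_calls(rep(list(rep(list(c(1, 1)), L)), 4), rep("p1", 4))
  est <- estimate_mlfst(gm, "p1", fr)
  expect_gt(est$f_hat, 0.5)
})

test_that("estimates recover the generating F on synthetic data", {
  set.seed(82)
  freqs <- biallelic_freqs(300)
  fr <- regional_frequencies(freqs)
  hits <- replicate(20, {
    gm <- simulate_balding_nichols(freqs, 0.1, 30)
    est <- estimate_mlfst(gm, "pop_1", fr)
    est$f_hat
  })
  expect_gte(mean(hits >= 0.07 & hits <= 0.13), 0.9)
})

test_that("increasing the generating F increases the estimate", {
  set.seed(83)
  freqs <- biallelic_freqs(200)
  fr <- regional_frequencies(freqs)
  med <- vapply(c(0.02, 0.1, 0.3), function(f) {
    median(replicate(5, {
      gm <- simulate_balding_nichols(freqs, f, 25)
      estimate_mlfst(gm, "pop_1", fr)$f_hat
    }))
  }, 0)
  expect_true(all(diff(med) > 0))
})

test_that("single-individual estimates are deterministic and informative", {
  set.seed(84)
  freqs <- biallelic_freqs(150)
  regions <- setNames(rep("reg", 8), paste0("pop_", 1:8))
  f_true <- seq(0.02, 0.35, length.out = 8)
  gm <- simulate_balding_nichols(freqs, f_true, rep(20, 8),
                                 regions = regions)
  s1 <- single_individual_mlfst(gm, "reg", choose = "random", seed = 9)
  s2 <- single_individual_mlfst(gm, "reg", choose = "random", seed = 9)
  expect_identical(s1, s2)
  full <- mlfst_by_population(gm, "reg")
  expect_gt(cor(full$f_hat, s1$f_hat[match(full$population,
                                           s1$population)]), 0)
  # heterozygous-at-pi individual: estimate at the lower bound
  fr <- regional_frequencies(list(c(0.5, 0.5)))
  gm1 <- gm_from_calls(list(list(c(1, 2)), list(c(1, 2))), c("a", "a"))
  cnts <- list(L1 = c(1L, 1L))
  est <- estimate_mlfst(gm1, "a", fr, counts_override = cnts)
  expect_true(est$boundary)
})

test_that("local F falls with the effective size of the focal population", {
  set.seed(85)
  freqs <- biallelic_freqs(150)
  regions <- setNames(rep("reg", 6), paste0("pop_", 1:6))
  # small fragments drift harder: F inversely tied to a census gradient
  census <- c(5, 20, 100, 500, 2000, 8000)
  f_true <- pmin(0.4, 0.08 * (1000 / census)^0.5)
  gm <- simulate_balding_nichols(freqs, f_true, rep(15, 6), regions = regions)
  res <- mlfst_by_population(gm, "reg")
  expect_lt(cor(log(census), res$f_hat, method = "spearman"), 0)
})
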