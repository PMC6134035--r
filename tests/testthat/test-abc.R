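test_that("summary statistics are permutation-invariant and cross-check", {
  set.seed(121)
  spec <- scenario_spec("1", c(B1 = 5, B2 = 5), 5, t1 = 100, t2 = 400,
                        tb1 = 20, ne_br = 500, ne_sc = 500, ne_cur = 50)
  gm <- simulate_scenario(spec, "ssr_length", 10, mu = 5e-4)
  sv <- summary_stats(gm, "ssr_length")
  expect_named(sv, c("mean_alleles", "mean_he", "fst_global", "fst_regions",
                     "var_size"))
  # permuting individuals leaves the vector unchanged
  perm <- sample(length(gm$individuals))
  gmp <- gm_subset(gm, ind = perm)
  expect_equal(summary_stats(gmp, "ssr_length"), sv)
  # values equal an independent recomputation from the same matrix
  he <- mean(vapply(seq_len(10), function(j)
    expected_heterozygosity(fragdiv:::pooled_counts_locus(gm, j)), 0))
  expect_equal(unname(sv["mean_he"]), he)
  expect_equal(unname(sv["fst_global"]),
               wc_fst(gm, filters = list(max_missing = 1, min_maf = 0))$theta)
  # length statistics never appear for identity-coded or snp markers
  gmi <- simulate_scenario(spec, "ssr_id", 5, mu = 5e-4)
  expect_false("var_size" %in% names(summary_stats(gmi, "ssr_id")))
})

test_that("monomorphic data produce the degenerate statistic vector", {
  spec <- scenario_spec("1", c(B1 = 4, B2 = 4), 4, t1 = 50, t2 = 100,
                        tb1 = 10, ne_br = 100, ne_sc = 100, ne_cur = 50)
  gm <- simulate_scenario(spec, "ssr_length", 5, mu = 0, seed = 122)
  sv <- summary_stats(gm, "ssr_length")
  expect_equal(unname(sv["mean_he"]), 0)
  expect_equal(unname(sv["mean_alleles"]), 1)
})

test_that("model choice is near-certain for an exactly matching scenario", {
  set.seed(123)
  n <- 400
  statsA <- cbind(s1 = rnorm(n, 0, 0.2), s2 = rnorm(n, 0, 0.2))
  statsB <- cbind(s1 = rnorm(n, 5, 0.2), s2 = rnorm(n, 5, 0.2))
  sims <- list(A = list(stats = statsA, params = data.frame(x = rnorm(n))),
               B = list(stats = statsB, params = data.frame(x = rnorm(n))))
  res <- abc_model_choice(c(s1 = 0, s2 = 0), sims, retain_fraction = 0.05)
  expect_gt(res$posterior[["A"]], 0.95)
  expect_equal(sum(res$posterior), 1)
})

test_that("indistinguishable scenarios split the posterior evenly", {
  set.seed(124)
  posts <- replicate(20, {
    n <- 150
    statsA <- cbind(s1 = rnorm(n), s2 = rnorm(n))
    statsB <- cbind(s1 = rnorm(n), s2 = rnorm(n))
    sims <- list(A = list(stats = statsA), B = list(stats = statsB))
    abc_model_choice(c(s1 = 0, s2 = 0), sims,
                     retain_fraction = 0.2)$posterior[["A"]]
  })
  expect_lt(abs(mean(posts) - 0.5), 0.1)
})

test_that("zero-spread statistics are dropped with a warning", {
  set.seed(125)
  n <- 100
  sims <- list(A = list(stats = cbind(s1 = rnorm(n), s2 = rep(1, n))),
               B = list(stats = cbind(s1 = rnorm(n, 3), s2 = rep(1, n))))
  expect_warning(res <- abc_model_choice(c(s1 = 0, s2 = 1), sims, 0.2),
                 "zero-spread")
  expect_gt(res$posterior[["A"]], 0.5)
})

test_that("parameter posterior adjusts, clips and summarizes", {
  set.seed(126)
  n <- 2000
  x <- runif(n, 0, 10)
  stats <- cbind(s1 = x + rnorm(n, 0, 0.1))  # statistic tracks the parameter
  params <- data.frame(x = x)
  obs <- c(s1 = 5)
  post <- abc_parameter_posterior(obs, params, stats, retain_fraction = 0.05,
                                  support = list(x = c(0, 10)))
  expect_true(post$adjusted)
  expect_lt(abs(post$summary$peak - 5), 0.5)
  expect_true(all(post$samples$x >= 0 & post$samples$x <= 10))
  # constant parameter: point mass
  params2 <- data.frame(x = rep(4, n))
  post2 <- abc_parameter_posterior(obs, params2, stats, 0.05)
  expect_equal(unique(post2$samples$x), 4)
  expect_equal(post2$summary$peak, 4)
})

test_that("zero regression slope reduces to plain rejection sampling", {
  set.seed(127)
  n <- 1000
  params <- data.frame(x = runif(n))
  stats <- cbind(s1 = rnorm(n))        # statistic carries no information
  obs <- c(s1 = 0)
  post <- abc_parameter_posterior(obs, params, stats, retain_fraction = 0.1)
  ord <- order(fragdiv:::standardize_stats(stats, obs)$dist)[1:100]
  # slope ~ 0: adjusted samples stay close to the retained raw values
  expect_lt(max(abs(post$samples$x - params$x[ord])), 0.2)
})

test_that("combining identical densities is idempotent and normalized", {
  set.seed(128)
  x <- rnorm(3000, 5, 1)
  m <- list(samples = x, weights = rep(1, 3000))
  comb <- combine_posteriors(list(m, m), support = c(0, 10))
  dx <- comb$grid[2] - comb$grid[1]
  expect_equal(sum(comb$density) * dx, 1, tolerance = 1e-6)
  expect_lt(abs(comb$peak - 5), 0.3)
  # product of two shifted gaussians peaks midway
  y <- rnorm(3000, 6, 1)
  comb2 <- combine_posteriors(list(m, list(samples = y,
                                           weights = rep(1, 3000))),
                              support = c(0, 12))
  expect_lt(abs(comb2$peak - 5.5), 0.3)
  # disjoint supports are flagged
  z <- rnorm(3000, 50, 0.5)
  expect_error(combine_posteriors(list(m, list(samples = z,
                                               weights = rep(1, 3000))),
                                  support = c(0, 60)), "overlap")
})

test_that("census-centered priors stay inside the declared support", {
  pr <- default_priors(census = c(B1 = 20, B2 = 800))
  set.seed(129)
  for (i in 1:50) {
    pars <- fragdiv:::draw_params(pr, "1b", 2)
    expect_true(all(pars$ne_cur >= pr$ne_cur_range[1] - 1e-9))
    expect_true(all(pars$ne_cur <= pr$ne_cur_range[2] + 1e-9))
    expect_true(pars$tb1 <= pars$t1 && pars$t1 <= pars$t2)
  }
  expect_error(default_priors(t1_range = c(0, 10)), "positive")
})
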