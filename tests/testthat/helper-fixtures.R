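# Shared fixtures and independent oracles for the test suite.

# Small genotype matrix built directly from an allele-pair list.
# calls: list of length n_ind; each element a list of c(a1, a2) or NA per locus.
gm_from_calls <- function(calls, populations, loci = NULL, regions = NULL,
                          marker_kind = "ssr_length") {
  n <- length(calls); L <- length(calls[[1]])
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) for (j in seq_len(L)) {
    g <- calls[[i]][[j]]
    if (length(g) == 2L && !anyNA(g)) { a1[i, j] <- g[1]; a2[i, j] <- g[2] }
  }
  genotype_matrix(a1, a2, paste0("ind_", seq_len(n)), populations, loci,
                  marker_kind = marker_kind, regions = regions)
}

# Random dense genotype matrix for round-trip property tests.
random_gm <- function(n_pop = 3, n_per_pop = 4, n_loci = 5, max_alleles = 4,
                      miss_rate = 0.1, marker_kind = "ssr_length") {
  n <- n_pop * n_per_pop
  a1 <- matrix(NA_integer_, n, n_loci); a2 <- matrix(NA_integer_, n, n_loci)
  for (j in seq_len(n_loci)) {
    k <- sample(2:max_alleles, 1L)
    a1[, j] <- sample.int(k, n, replace = TRUE)
    a2[, j] <- sample.int(k, n, replace = TRUE)
    # ensure codes dense (every code observed)
    a1[seq_len(k), j] <- seq_len(k)
    miss <- stats::runif(n) < miss_rate
    miss[seq_len(min(k + 1L, n))] <- FALSE
    a1[miss, j] <- NA_integer_; a2[miss, j] <- NA_integer_
  }
  genotype_matrix(a1, a2, paste0("ind_", seq_len(n)),
                  rep(paste0("pop_", seq_len(n_pop)), each = n_per_pop),
                  paste0("L", seq_len(n_loci)), marker_kind = marker_kind)
}

# --- independent Weir-Cockerham oracle -------------------------------------
# Naive scalar implementation of the 1984 variance components, written
# directly from the per-allele definitions with explicit loops; gm restricted
# to populations with data is the caller's job.
wc_theta_oracle <- function(gm) {
  pops <- unique(gm$populations)
  num <- 0; den <- 0
  for (j in seq_along(gm$loci)) {
    ok <- !is.na(gm$a1[, j])
    ni <- sapply(pops, function(p) sum(ok & gm$populations == p))
    pops_j <- pops[ni > 0]
    ni <- ni[ni > 0]
    if (length(pops_j) < 2) next
    r <- length(pops_j)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    alleles <- sort(unique(na.omit(c(gm$a1[, j], gm$a2[, j]))))
    for (u in alleles) {
      p_i <- numeric(r); h_i <- numeric(r)
      for (q in seq_len(r)) {
        rows <- which(ok & gm$populations == pops_j[q])
        copies <- sum(gm$a1[rows, j] == u) + sum(gm$a2[rows, j] == u)
        p_i[q] <- copies / (2 * ni[q])
        h_i[q] <- mean(gm$a1[rows, j] != gm$a2[rows, j] &
                         (gm$a1[rows, j] == u | gm$a2[rows, j] == u))
      }
      pbar <- sum(ni * p_i) / sum(ni)
      ssq <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / sum(ni)
      a <- nbar / nc * (ssq - 1 / (nbar - 1) *
                          (pbar * (1 - pbar) - (r - 1) / r * ssq - hbar / 4))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * ssq -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# --- exhaustive rarefaction oracle -----------------------------------------
# Mean number of distinct alleles over all gene-copy subsets of size g.
rarefaction_oracle <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(copies), g)
  mean(apply(subsets, 2L, function(ix) length(unique(copies[ix]))))
}

# All partitions of N into at most `parts` positive counts (allele
# configurations at a locus with N gene copies).
integer_partitions <- function(N, max_part = N) {
  if (N == 0) return(list(integer(0)))
  out <- list()
  for (first in seq_len(min(N, max_part))) {
    for (rest in integer_partitions(N - first, first))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

# --- beta-binomial integral oracle for the Dirichlet-multinomial -----------
# P(sequence of draws with k copies of allele 1 out of n) under
# p ~ Beta(pi*A, (1-pi)*A), without the multinomial coefficient.
beta_integral_lik <- function(k, n, pi, f) {
  A <- (1 - f) / f
  stats::integrate(function(p)
    p^k * (1 - p)^(n - k) * stats::dbeta(p, pi * A, (1 - pi) * A),
    0, 1, rel.tol = 1e-12)$value
}

# --- exhaustive Mantel oracle ----------------------------------------------
mantel_exhaustive_oracle <- function(genetic, geographic_log) {
  n <- nrow(genetic)
  up <- upper.tri(genetic)
  r_obs <- stats::cor(genetic[up], geographic_log[up])
  perms <- gtools_permutations(n)
  rs <- apply(perms, 1L, function(pp)
    stats::cor(genetic[up], geographic_log[pp, pp][up]))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# all permutations of 1..n as a matrix (independent of the package's helper)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub), n - 1L))
  }))
}

# biallelic frequency vectors for quick Balding-Nichols fixtures
biallelic_freqs <- function(L, lo = 0.2, hi = 0.8) {
  replicate(L, { p <- stats::runif(1, lo, hi); c(p, 1 - p) },
            simplify = FALSE)
}
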