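#' Weir-Cockerham F_ST (theta)
#'
#' Multi-allelic Weir & Cockerham (1984) variance-components estimator.
#' For every locus and allele the among-population (a), among-individual
#' (b) and within-individual (c) components are computed from per-population
#' sample sizes, allele frequencies and observed heterozygote frequencies;
#' theta is the ratio of sums \eqn{\sum a / \sum (a+b+c)} over alleles and
#' loci. Loci are screened before estimation: missing-data fraction,
#' pooled minor-allele frequency, and (optionally) presence of data in
#' every population.
#'
#' @param gm a [genotype_matrix()].
#' @param scope `"global"` (all populations) or a character vector of two
#'   population IDs.
#' @param filters list with elements `max_missing` (drop loci missing in
#'   more than this fraction of in-scope individuals; default 0.25),
#'   `min_maf` (keep loci whose pooled minor-allele frequency exceeds this;
#'   default 0.05), `require_all_pops` (drop loci lacking data in any
#'   population; default FALSE).
#' @param n_perm permutations of individuals across populations for a
#'   one-sided p-value (0 = no test). The survey convention is 10,000
#'   iterations; the default here is off because pairwise matrices at that
#'   setting are expensive.
#' @param seed RNG seed for the permutation test.
#' @return list with `theta`, `per_locus` (named vector of single-locus
#'   theta), `n_loci_used`, `p_value` (NA unless `n_perm > 0`), and the
#'   variance-component sums `a`, `b`, `c`.
#' @export
wc_fst <- function(gm, scope = "global",
                   filters = list(max_missing = 0.25, min_maf = 0.05,
                                  require_all_pops = FALSE),
                   n_perm = 0, seed = NULL) {
  filters <- utils::modifyList(list(max_missing = 0.25, min_maf = 0.05,
                                    require_all_pops = FALSE), filters)
  if (!identical(scope, "global")) {
    if (length(scope) != 2L) stop("scope must be 'global' or two populations")
    gm <- gm_keep_pops(gm, scope)
  }
  pops <- unique(gm$populations)
  if (length(pops) < 2L) stop("need at least 2 populations in scope")
  keep <- filter_fst_loci(gm, pops, filters)
  if (!any(keep)) stop("no locus passes the F_ST filters")
  comp <- wc_components(gm, pops, which(keep))
  theta_obs <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  p_value <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      gp <- gm
      gp$populations <- sample(gm$populations)
      cp <- wc_components(gp, pops, which(keep))
      tp <- sum(cp$a) / sum(cp$a + cp$b + cp$c)
      if (!is.na(tp) && tp >= theta_obs) hits <- hits + 1L
    }
    p_value <- (1 + hits) / (1 + n_perm)
  }
  list(theta = theta_obs, per_locus = comp$per_locus,
       n_loci_used = sum(keep), p_value = p_value,
       a = sum(comp$a), b = sum(comp$b), c = sum(comp$c))
}

#' Pairwise Weir-Cockerham F_ST matrix
#'
#' @inheritParams wc_fst
#' @return a symmetric matrix of pairwise theta with zero diagonal
#'   (populations ordered by first appearance); `NA` where a pair has no
#'   usable loci.
#' @export
pairwise_fst <- function(gm, filters = list(max_missing = 0.25,
                                            min_maf = 0.05)) {
  pops <- unique(gm$populations)
  P <- length(pops)
  m <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    th <- tryCatch(wc_fst(gm, scope = c(pops[i], pops[j]),
                          filters = filters)$theta,
                   error = function(e) NA_real_)
    m[i, j] <- m[j, i] <- th
  }
  m
}

#' Linearized F_ST
#'
#' \eqn{M = (1 - F_{ST}) / F_{ST}}, linear in divergence under island-model
#' assumptions; the quantity regressed on log geographic distance in
#' isolation-by-distance tests. Non-positive estimates (possible for the
#' unbiased theta) map to `+Inf` with a warning.
#'
#' @param fst numeric vector or matrix of F_ST values in (0, 1].
#' @return M on the same shape as the input.
#' @export
linearize_fst <- function(fst) {
  if (any(fst > 1, na.rm = TRUE)) stop("F_ST cannot exceed 1")
  out <- ifelse(fst <= 0, Inf, (1 - fst) / fst)
  if (any(fst <= 0, na.rm = TRUE))
    warning("non-positive F_ST linearized to +Inf")
  if (is.matrix(fst)) diag(out) <- 0
  out
}

## ---- internals ----

filter_fst_loci <- function(gm, pops, filters) {
  n <- n_ind(gm)
  vapply(seq_len(n_loci(gm)), function(j) {
    ok <- !is.na(gm$a1[, j])
    if (mean(!ok) > filters$max_missing) return(FALSE)
    counts <- pooled_counts_locus(gm, j)
    if (length(counts) < 2L) return(FALSE)
    p <- counts / sum(counts)
    maf <- sort(p, decreasing = TRUE)[2]
    if (maf <= filters$min_maf) return(FALSE)
    if (isTRUE(filters$require_all_pops)) {
      for (pp in pops)
        if (!any(ok[gm$populations == pp])) return(FALSE)
    }
    TRUE
  }, TRUE)
}

# Weir & Cockerham (1984) per-locus, per-allele variance components
# (vectorized over alleles; populations without data at a locus drop out).
wc_components <- function(gm, pops, loci_idx) {
  r <- length(pops)
  popi <- match(gm$populations, pops)
  a_sum <- b_sum <- c_sum <- 0
  per_locus <- rep(NA_real_, length(loci_idx))
  for (jj in seq_along(loci_idx)) {
    j <- loci_idx[jj]
    a1 <- gm$a1[, j]; a2 <- gm$a2[, j]
    ok <- !is.na(a1) & !is.na(popi)
    if (!any(ok)) next
    p_ok <- popi[ok]; a1 <- a1[ok]; a2 <- a2[ok]
    K <- max(a1, a2)
    ni_full <- tabulate(p_ok, r)
    use <- ni_full > 0L
    rl <- sum(use)
    if (rl < 2L) next
    cnt <- matrix(tabulate((a1 - 1L) * r + p_ok, r * K) +
                    tabulate((a2 - 1L) * r + p_ok, r * K), r, K)
    het <- a1 != a2
    hcnt <- matrix(tabulate((a1[het] - 1L) * r + p_ok[het], r * K) +
                     tabulate((a2[het] - 1L) * r + p_ok[het], r * K), r, K)
    cnt <- cnt[use, , drop = FALSE]
    hcnt <- hcnt[use, , drop = FALSE]
    ni <- as.numeric(ni_full[use])
    nbar <- mean(ni)
    if (nbar <= 1) next  # all samples of one individual: components undefined
    nc <- (rl * nbar - sum(ni^2) / (rl * nbar)) / (rl - 1)
    pim <- cnt / (2 * ni)
    him <- hcnt / ni
    pbar <- colSums(ni * pim) / (rl * nbar)
    s2 <- colSums(ni * (pim - rep(pbar, each = rl))^2) / ((rl - 1) * nbar)
    hbar <- colSums(ni * him) / (rl * nbar)
    avec <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (rl - 1) / rl - hbar / 4) / (nbar - 1))
    bvec <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (rl - 1) / rl - hbar * (2 * nbar - 1) / (4 * nbar))
    cvec <- hbar / 2
    aj <- sum(avec); bj <- sum(bvec); cj <- sum(cvec)
    per_locus[jj] <- if ((aj + bj + cj) != 0) aj / (aj + bj + cj) else NA_real_
    a_sum <- a_sum + aj; b_sum <- b_sum + bj; c_sum <- c_sum + cj
  }
  names(per_locus) <- gm$loci[loci_idx]
  list(a = a_sum, b = b_sum, c = c_sum, per_locus = per_locus)
}
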