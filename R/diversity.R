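#' Rarefied allelic richness at one locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies drawn without replacement from the observed copies
#' (hypergeometric rarefaction):
#' \deqn{A_r(g) = \sum_i \left[1 - \binom{N - N_i}{g} / \binom{N}{g}\right]}
#' where \eqn{N_i} is the count of allele i and \eqn{N = \sum_i N_i}.
#' Evaluated with log-binomials for numerical stability.
#'
#' @param counts integer vector of gene-copy counts per allele.
#' @param g standard subsample size in gene copies (`g <= N`).
#' @return expected number of distinct alleles (numeric scalar).
#' @export
rarefied_allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1) stop("g must be >= 1")
  if (g > N) stop("g exceeds the available gene copies (N = ", N, ")")
  terms <- ifelse(N - counts < g, 1,
                  1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
  sum(terms)
}

#' Nei's unbiased expected heterozygosity at one locus
#'
#' \eqn{\hat H_e = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} with n the
#' number of gene copies.
#'
#' @param counts integer vector of gene-copy counts per allele.
#' @return unbiased gene diversity (0 for a monomorphic locus).
#' @export
expected_heterozygosity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("expected_heterozygosity needs at least 2 gene copies")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Within-population inbreeding coefficient F_IS
#'
#' Per locus, \eqn{F_{IS} = 1 - H_{obs}/\hat H_e} with the unbiased gene
#' diversity of [expected_heterozygosity()]; the across-locus mean weights
#' loci by the number of individuals genotyped. Loci monomorphic in the
#' sample (\eqn{\hat H_e = 0}) are undefined and skipped.
#'
#' @param gm a [genotype_matrix()] restricted to one population (use
#'   [gm_keep_pops()]); all individuals are treated as one sample.
#' @return list with `per_locus` (named numeric, `NA` where undefined),
#'   `mean` (weighted mean), and `n_ind` (individuals genotyped per locus).
#' @export
fis <- function(gm) {
  L <- n_loci(gm)
  out <- rep(NA_real_, L); w <- integer(L)
  for (j in seq_len(L)) {
    ok <- !is.na(gm$a1[, j])
    w[j] <- sum(ok)
    if (w[j] < 2L) next
    counts <- pooled_counts_locus(gm, j)
    he <- expected_heterozygosity(counts)
    if (he <= 0) next
    hobs <- mean(gm$a1[ok, j] != gm$a2[ok, j])
    out[j] <- 1 - hobs / he
  }
  names(out) <- gm$loci
  usable <- !is.na(out)
  list(per_locus = out,
       mean = if (any(usable)) sum(out[usable] * w[usable]) / sum(w[usable])
       else NA_real_,
       n_ind = stats::setNames(w, gm$loci))
}

#' Diversity summary table by population and region
#'
#' Per population: sample size, loci with data, distinct alleles, mean
#' rarefied allelic richness at the standard number of gene copies, mean
#' expected heterozygosity, and mean F_IS. Region rows aggregate over the
#' populations of each region, excluding populations below `min_pop_size`
#' individuals (flagged in the `excluded` column); the region's global
#' Weir-Cockerham F_ST over its included populations is attached.
#'
#' @param gm a [genotype_matrix()].
#' @param g_rarefy rarefaction standard in gene copies (default 40, i.e. 20
#'   diploid individuals). Populations with fewer copies at a locus
#'   contribute `NA` for that locus.
#' @param min_pop_size smallest population admitted to region aggregates.
#' @param fst_filters filters passed to [wc_fst()] for the region rows.
#' @return data.frame with one row per population and one per region.
#' @export
diversity_table <- function(gm, g_rarefy = 40, min_pop_size = 5,
                            fst_filters = list(max_missing = 0.25,
                                               min_maf = 0.05)) {
  pops <- unique(gm$populations)
  counts <- allele_counts(gm, pops)
  rows <- list()
  pop_stats <- list()
  for (p in pops) {
    sub <- gm_keep_pops(gm, p)
    np <- n_ind(sub)
    ar_l <- he_l <- rep(NA_real_, n_loci(gm))
    nall <- 0L; nloc <- 0L
    for (j in seq_len(n_loci(gm))) {
      cj <- counts[[j]][p, ]
      cj <- cj[cj > 0]
      N <- sum(cj)
      if (N == 0L) next
      nloc <- nloc + 1L
      nall <- nall + length(cj)
      if (N >= 2L) he_l[j] <- expected_heterozygosity(cj)
      if (N >= g_rarefy) ar_l[j] <- rarefied_allelic_richness(cj, g_rarefy)
    }
    fis_p <- fis(sub)
    pop_stats[[p]] <- list(ar = mean(ar_l, na.rm = TRUE),
                           he = mean(he_l, na.rm = TRUE),
                           fis = fis_p$mean)
    rows[[length(rows) + 1L]] <- data.frame(
      unit = "population", id = p, region = unname(gm$regions[p]),
      n_ind = np, n_loci = nloc, n_alleles = nall,
      ar = pop_stats[[p]]$ar, he = pop_stats[[p]]$he,
      fis = pop_stats[[p]]$fis, fst = NA_real_,
      excluded = np < min_pop_size, stringsAsFactors = FALSE)
  }
  for (r in unique(gm$regions)) {
    rpops <- names(gm$regions)[gm$regions == r]
    sizes <- vapply(rpops, function(p) sum(gm$populations == p), 0L)
    inc <- rpops[sizes >= min_pop_size]
    if (!length(inc)) next
    sub <- gm_keep_pops(gm, inc)
    nall_r <- sum(vapply(seq_len(n_loci(sub)), function(j)
      length(pooled_counts_locus(sub, j)), 0L))
    theta <- if (length(inc) >= 2L)
      tryCatch(wc_fst(sub, filters = fst_filters)$theta, error = function(e) NA_real_)
    else NA_real_
    st <- pop_stats[inc]
    rows[[length(rows) + 1L]] <- data.frame(
      unit = "region", id = r, region = r,
      n_ind = n_ind(sub), n_loci = n_loci(sub), n_alleles = nall_r,
      ar = mean(vapply(st, `[[`, 0, "ar"), na.rm = TRUE),
      he = mean(vapply(st, `[[`, 0, "he"), na.rm = TRUE),
      fis = mean(vapply(st, `[[`, 0, "fis"), na.rm = TRUE),
      fst = theta, excluded = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
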