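#' Great-circle distance matrix between populations
#'
#' Haversine distances on a sphere of radius 6371 km (via
#' \pkg{geosphere}).
#'
#' @param meta a [population_meta()] table.
#' @return symmetric matrix of distances in km, zero diagonal, dimnames =
#'   population IDs.
#' @export
great_circle_distances <- function(meta) {
  if (any(abs(meta$latitude) > 90)) stop("latitude out of range [-90, 90]")
  xy <- cbind(meta$longitude, meta$latitude)
  m <- geosphere::distm(xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(m) <- list(meta$population, meta$population)
  m
}

#' Mantel test of matrix association
#'
#' Pearson correlation between the upper triangles of a genetic-distance
#' matrix (typically linearized F_ST) and a geographic-distance matrix
#' (natural-log-transformed by default, the usual isolation-by-distance
#' scale). Significance is one-sided (positive association) from random
#' simultaneous row/column permutations of one matrix:
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})}; with
#' `exhaustive = TRUE` all \eqn{n!} relabellings are enumerated and
#' \eqn{p = \#\{r_{perm} \ge r_{obs}\} / n!}.
#'
#' @param genetic,geographic symmetric matrices with matching population
#'   order and zero diagonal.
#' @param log_distance log-transform the geographic distances (requires
#'   positive off-diagonal entries).
#' @param n_perm number of random permutations.
#' @param seed RNG seed.
#' @param exhaustive enumerate all permutations (n <= 8).
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(genetic, geographic, log_distance = TRUE,
                        n_perm = 9999, seed = NULL, exhaustive = FALSE) {
  n <- nrow(genetic)
  if (n < 4L) stop("too few populations for a permutation test (need >= 4)")
  if (!isTRUE(all.equal(dim(genetic), dim(geographic))))
    stop("matrix dimensions differ")
  if (max(abs(genetic - t(genetic))) > 1e-8 ||
      max(abs(geographic - t(geographic))) > 1e-8)
    stop("matrices must be symmetric")
  if (any(diag(genetic) != 0) || any(diag(geographic) != 0))
    stop("matrices must have zero diagonal")
  up <- upper.tri(genetic)
  geo <- geographic
  if (log_distance) {
    if (any(geo[up] <= 0))
      stop("zero or negative off-diagonal distance with log_distance = TRUE")
    geo <- log(geo)
  }
  x <- genetic[up]
  r_obs <- stats::cor(x, geo[up])
  perm_r <- function(ord) stats::cor(x, geo[ord, ord][up])
  if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, 0)
    list(r = r_obs, p = mean(rs >= r_obs - 1e-12), n_perm = length(perms))
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (perm_r(sample.int(n)) >= r_obs - 1e-12) hits <- hits + 1L
    }
    list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
  }
}

# All permutations of 1..n as a list (n small).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos - 1L)
  }
  out
}

#' Isolation-by-distance test within a region
#'
#' Convenience wrapper: pairwise F_ST within the region, linearized to
#' \eqn{M = (1-F_{ST})/F_{ST}}, against log great-circle distance.
#' Pairs with non-positive F_ST (infinite M) are excluded with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param meta a [population_meta()] table.
#' @param region region label to test.
#' @param min_pop_size populations below this size are dropped first.
#' @inheritParams mantel_test
#' @inheritParams wc_fst
#' @return list with `mantel` (from [mantel_test()]), `m_matrix`,
#'   `distance_km`, and the populations used.
#' @export
ibd_test <- function(gm, meta, region, min_pop_size = 5,
                     filters = list(max_missing = 0.25, min_maf = 0.05),
                     n_perm = 9999, seed = NULL) {
  pops <- meta$population[meta$region == region]
  sizes <- vapply(pops, function(p) sum(gm$populations == p), 0L)
  pops <- pops[sizes >= min_pop_size]
  sub <- gm_keep_pops(gm, pops)
  fstm <- pairwise_fst(sub, filters = filters)
  M <- suppressWarnings(linearize_fst(fstm))
  if (any(!is.finite(M[upper.tri(M)]))) {
    warning("pairs with non-positive F_ST excluded from the Mantel test")
    bad <- !is.finite(M)
    diag(bad) <- FALSE
    drop <- rownames(M)[colSums(bad) > 0]
    keep <- setdiff(rownames(M), drop)
    M <- M[keep, keep]
    pops <- keep
  }
  dk <- great_circle_distances(meta[match(pops, meta$population), ])
  mt <- mantel_test(M, dk, log_distance = TRUE, n_perm = n_perm, seed = seed)
  list(mantel = mt, m_matrix = M, distance_km = dk, populations = pops)
}
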