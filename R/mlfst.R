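#' Regional mean allele frequencies
#'
#' The reference frequencies \eqn{\pi} against which a focal population's
#' divergence F is estimated. `pooled` mode sums gene copies over all
#' individuals of the region; `pop_mean` averages per-population frequency
#' vectors with equal weight. Loci monomorphic in the region are flagged
#' (they carry no information about F and are excluded from the
#' likelihood).
#'
#' @param gm a [genotype_matrix()].
#' @param region region label (populations mapped to it by `gm$regions`).
#' @param mode `"pooled"` or `"pop_mean"`.
#' @param exclude_pop optional population ID excluded from the mean (for
#'   sensitivity analyses with the focal population left out).
#' @return object of class `regional_frequencies`: list with `freqs` (per
#'   locus, a frequency vector over dense allele codes), `monomorphic`
#'   (logical per locus), `n_copies` (regional gene copies per locus),
#'   `mode`, `region`.
#' @export
regional_mean_frequencies <- function(gm, region,
                                      mode = c("pooled", "pop_mean"),
                                      exclude_pop = NULL) {
  mode <- match.arg(mode)
  pops <- names(gm$regions)[gm$regions == region]
  pops <- setdiff(pops, exclude_pop)
  if (length(pops) < 2L)
    stop("region must contain at least 2 populations with data")
  sub <- gm_keep_pops(gm, pops)
  L <- n_loci(sub)
  counts <- allele_counts(sub, pops)
  freqs <- vector("list", L)
  mono <- logical(L)
  ncop <- integer(L)
  for (j in seq_len(L)) {
    m <- counts[[j]]
    tot <- colSums(m)
    ncop[j] <- sum(tot)
    if (ncop[j] == 0L) {
      warning("locus ", sub$loci[j], " has no regional data; excluded")
      mono[j] <- TRUE
      freqs[[j]] <- numeric(0)
      next
    }
    fr <- if (mode == "pooled") tot / sum(tot) else {
      rows <- rowSums(m) > 0
      pf <- sweep(m[rows, , drop = FALSE], 1L, rowSums(m[rows, , drop = FALSE]), "/")
      colMeans(pf)
    }
    freqs[[j]] <- fr
    mono[j] <- sum(fr > 0) < 2L
  }
  structure(list(freqs = stats::setNames(freqs, sub$loci),
                 monomorphic = stats::setNames(mono, sub$loci),
                 n_copies = stats::setNames(ncop, sub$loci),
                 mode = mode, region = region),
            class = "regional_frequencies")
}

#' Build a reference-frequency object from known frequency vectors
#'
#' For parameter-recovery experiments and external references: wraps a list
#' of per-locus frequency vectors as the `regional_frequencies` object
#' consumed by [estimate_mlfst()].
#'
#' @param freqs list of per-locus frequency vectors (each summing to 1).
#' @param n_copies assumed regional gene-copy count per locus (used only in
#'   the zero-frequency floor).
#' @return a `regional_frequencies` object.
#' @export
regional_frequencies <- function(freqs, n_copies = 1000) {
  bad <- !vapply(freqs, function(p) abs(sum(p) - 1) < 1e-9, TRUE)
  if (any(bad)) stop("frequency vector does not sum to 1 at locus ",
                     which(bad)[1])
  L <- length(freqs)
  nm <- names(freqs)
  if (is.null(nm)) nm <- paste0("L", seq_len(L))
  structure(list(freqs = stats::setNames(freqs, nm),
                 monomorphic = stats::setNames(
                   vapply(freqs, function(p) sum(p > 0) < 2L, TRUE), nm),
                 n_copies = stats::setNames(rep(n_copies, L), nm),
                 mode = "known", region = NA_character_),
            class = "regional_frequencies")
}

#' Dirichlet-multinomial log-likelihood of focal allele counts
#'
#' Balding-Nichols model: the focal population's allele frequencies are
#' Dirichlet with parameters \eqn{\alpha_i = \pi_i (1-F)/F} around the
#' regional mean \eqn{\pi}; marginalizing them out, a sample of n gene
#' copies with counts \eqn{n_i} has log-likelihood (up to the multinomial
#' coefficient, constant in F)
#' \deqn{\ln\Gamma(A) - \ln\Gamma(A+n) +
#'       \sum_i [\ln\Gamma(\alpha_i+n_i) - \ln\Gamma(\alpha_i)]}
#' with \eqn{A = (1-F)/F}.
#'
#' @param counts integer vector of focal gene-copy counts per allele.
#' @param pi regional mean frequency vector (same order as `counts`);
#'   must be positive wherever `counts > 0`.
#' @param f divergence parameter in (0, 1).
#' @return log-likelihood (numeric scalar).
#' @export
dirichlet_multinomial_loglik <- function(counts, pi, f) {
  if (f <= 0 || f >= 1) stop("F must lie strictly inside (0, 1)")
  if (length(counts) != length(pi)) stop("counts and pi lengths differ")
  n <- sum(counts)
  if (n < 1) stop("need at least one gene copy")
  if (any(counts > 0 & pi <= 0))
    stop("observed allele with zero regional frequency")
  A <- (1 - f) / f
  alpha <- pi * A
  obs <- counts > 0
  lgamma(A) - lgamma(A + n) +
    sum(lgamma(alpha[obs] + counts[obs]) - lgamma(alpha[obs]))
}

#' Maximum-likelihood local F_ST of a focal population
#'
#' Maximizes the summed Dirichlet-multinomial log-likelihood of the focal
#' population's allele counts over F, relative to regional mean
#' frequencies: a coarse log-spaced grid (200 points) followed by
#' golden-section refinement to |dF| < 1e-6. Loci monomorphic in the
#' region are skipped; alleles observed in the focal sample but absent
#' from the regional mean get their frequency floored at
#' \eqn{1/(2 N_{region} + k)} (the regional mean renormalized), since a
#' zero frequency would make the likelihood undefined.
#'
#' @param gm a [genotype_matrix()].
#' @param focal_population population ID.
#' @param freqs a [regional_mean_frequencies()] object.
#' @param bounds search interval for F.
#' @param counts_override optional list of per-locus focal count vectors
#'   (used by [single_individual_mlfst()]); when given, `focal_population`
#'   only labels the estimate.
#' @return object of class `mlfst_estimate`: list with `population`,
#'   `f_hat`, `loglik`, `n_loci`, `boundary` (TRUE when the maximum sits on
#'   a search bound).
#' @export
estimate_mlfst <- function(gm, focal_population, freqs,
                           bounds = c(1e-4, 0.999), counts_override = NULL) {
  loci <- names(freqs$freqs)
  counts_list <- list()
  for (j in seq_along(loci)) {
    if (freqs$monomorphic[j]) next
    pi <- freqs$freqs[[j]]
    cnt <- if (!is.null(counts_override)) counts_override[[loci[j]]] else {
      jj <- match(loci[j], gm$loci)
      ii <- which(gm$populations == focal_population)
      al <- c(gm$a1[ii, jj], gm$a2[ii, jj])
      al <- al[!is.na(al)]
      tabulate(al, nbins = length(pi))
    }
    if (is.null(cnt) || sum(cnt) == 0L) next
    if (length(cnt) < length(pi)) cnt <- c(cnt, rep(0L, length(pi) - length(cnt)))
    if (any(cnt > 0 & pi <= 0)) {
      floor_p <- 1 / (freqs$n_copies[j] + length(pi))
      pi[cnt > 0 & pi <= 0] <- floor_p
      pi <- pi / sum(pi)
    }
    counts_list[[length(counts_list) + 1L]] <- list(cnt = cnt, pi = pi)
  }
  if (!length(counts_list))
    stop("no usable polymorphic locus for population ", focal_population)
  negll <- function(f) -sum(vapply(counts_list, function(x)
    dirichlet_multinomial_loglik(x$cnt, x$pi, f), 0))
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = 200))
  vals <- vapply(grid, negll, 0)
  i0 <- which.min(vals)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(negll, c(lo, hi), tol = 1e-6)
  f_hat <- opt$minimum
  boundary <- f_hat <= bounds[1] * 1.01 || f_hat >= bounds[2] * 0.999 ||
    i0 %in% c(1L, length(grid))
  if (i0 == 1L) { f_hat <- bounds[1]; opt$objective <- vals[1] }
  if (i0 == length(grid)) { f_hat <- bounds[2]; opt$objective <- vals[length(grid)] }
  structure(list(population = focal_population, f_hat = f_hat,
                 loglik = -opt$objective, n_loci = length(counts_list),
                 boundary = boundary),
            class = "mlfst_estimate")
}

#' @export
print.mlfst_estimate <- function(x, ...) {
  cat(sprintf("ML-FST %s: F = %.5f (logL = %.3f, %d loci%s)\n",
              x$population, x$f_hat, x$loglik, x$n_loci,
              if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' ML-F_ST for every population of a region
#'
#' @inheritParams estimate_mlfst
#' @param region region label.
#' @param mode,exclude_focal reference-frequency mode and whether the focal
#'   population is left out of its own reference (default: included).
#' @return data.frame with columns `population`, `f_hat`, `loglik`,
#'   `n_loci`, `boundary`.
#' @export
mlfst_by_population <- function(gm, region, mode = "pooled",
                                exclude_focal = FALSE,
                                bounds = c(1e-4, 0.999)) {
  pops <- names(gm$regions)[gm$regions == region]
  rows <- lapply(pops, function(p) {
    fr <- regional_mean_frequencies(gm, region, mode = mode,
                                    exclude_pop = if (exclude_focal) p else NULL)
    est <- estimate_mlfst(gm, p, fr, bounds = bounds)
    data.frame(population = p, f_hat = est$f_hat, loglik = est$loglik,
               n_loci = est$n_loci, boundary = est$boundary,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Single-individual ML-F_ST per population
#'
#' Re-estimates each population's local F from the two gene copies of a
#' single individual, to discriminate sample-size artifacts from real
#' divergence signals.
#'
#' @inheritParams mlfst_by_population
#' @param choose `"first"` (first genotyped individual in input order) or
#'   `"random"` (seeded draw).
#' @param seed RNG seed for `choose = "random"`.
#' @return data.frame as [mlfst_by_population()], plus column `individual`.
#' @export
single_individual_mlfst <- function(gm, region, mode = "pooled",
                                    choose = c("first", "random"),
                                    seed = NULL, bounds = c(1e-4, 0.999)) {
  choose <- match.arg(choose)
  if (!is.null(seed)) set.seed(seed)
  pops <- names(gm$regions)[gm$regions == region]
  fr <- regional_mean_frequencies(gm, region, mode = mode)
  rows <- lapply(pops, function(p) {
    ii <- which(gm$populations == p)
    has_data <- ii[rowSums(!is.na(gm$a1[ii, , drop = FALSE])) > 0]
    if (!length(has_data)) return(NULL)
    pick <- if (choose == "first") has_data[1] else sample(has_data, 1L)
    cnts <- lapply(seq_along(gm$loci), function(j) {
      al <- c(gm$a1[pick, j], gm$a2[pick, j])
      al <- al[!is.na(al)]
      tabulate(al, nbins = length(fr$freqs[[j]]))
    })
    names(cnts) <- gm$loci
    est <- estimate_mlfst(gm, p, fr, bounds = bounds, counts_override = cnts)
    data.frame(population = p, individual = gm$individuals[pick],
               f_hat = est$f_hat, loglik = est$loglik, n_loci = est$n_loci,
               boundary = est$boundary, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
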