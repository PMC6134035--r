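#' Burrows' composite r-squared for one locus pair
#'
#' Composite digenic disequilibrium from unphased diploid genotypes:
#' \eqn{\hat\Delta = \frac{1}{n}\sum_i X_i Y_i / 2 - 2 \hat p_A \hat p_B}
#' (X, Y = copies of the focal allele carried at each locus), squared and
#' divided by the allele variances including their homozygote-excess
#' (within-locus Hardy-Weinberg disequilibrium) corrections:
#' \eqn{\hat r^2 = \hat\Delta^{*2} /
#'      [(p_A(1-p_A) + D_A)(p_B(1-p_B) + D_B)]},
#' \eqn{D_A = P_{AA} - p_A^2}. No phase information is required.
#'
#' @param x,y integer dosage vectors (0, 1, 2 copies of the focal allele at
#'   each of the two loci; `NA` = missing genotype).
#' @return list with `r2`, `n` (complete genotypes used), `delta`; `r2` is
#'   `NA` when either locus is monomorphic among the complete genotypes.
#' @export
burrows_rsq <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2L) return(list(r2 = NA_real_, n = n, delta = NA_real_))
  x <- x[ok]; y <- y[ok]
  pa <- mean(x) / 2; pb <- mean(y) / 2
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1)
    return(list(r2 = NA_real_, n = n, delta = NA_real_))
  delta <- sum(x * y) / (2 * n) - 2 * pa * pb
  da <- mean(x == 2L) - pa^2
  db <- mean(y == 2L) - pb^2
  va <- pa * (1 - pa) + da
  vb <- pb * (1 - pb) + db
  if (va <= 0 || vb <= 0) return(list(r2 = NA_real_, n = n, delta = delta))
  list(r2 = delta^2 / (va * vb), n = n, delta = delta)
}

#' Expected r-squared from sampling alone
#'
#' The component of mean composite r-squared attributable to the finite
#' sample rather than to drift, under random mating:
#' \eqn{1/S + 3.19/S^2} for \eqn{S \ge 30}, and
#' \eqn{0.0018 + 0.907/S + 4.44/S^2} for \eqn{S < 30}
#' (S = harmonic-mean sample size over locus pairs; the boundary S = 30
#' uses the large-sample branch).
#'
#' @param s harmonic-mean sample size (> 1).
#' @return expected sampling r-squared.
#' @export
expected_sample_rsq <- function(s) {
  if (s <= 1) stop("sample size must exceed 1")
  if (s >= 30) 1 / s + 3.19 / s^2
  else 0.0018 + 0.907 / s + 4.44 / s^2
}

#' Effective population size from drift r-squared
#'
#' Subtracts the sampling expectation from the mean composite r-squared and
#' inverts the drift relation under random mating:
#' \deqn{\hat N_e = \frac{1/3 + \sqrt{1/9 - 2.76\, r^2{}'}}{2 r^2{}'}}
#' for \eqn{S \ge 30} (coefficients 0.308 and 2.08 for S < 30). A
#' non-positive corrected r-squared carries no drift signal and returns
#' `+Inf`.
#'
#' @param r2_mean mean composite r-squared over locus pairs (after any MAF
#'   screen).
#' @param s harmonic-mean sample size.
#' @return list with `ne`, `r2_prime`, `exp_r2`, and `flag` (`"ok"`,
#'   `"infinite"`, or `"extreme_ld"` when the discriminant is negative).
#' @export
ld_ne_estimate <- function(r2_mean, s) {
  e <- expected_sample_rsq(s)
  r2p <- r2_mean - e
  if (r2p <= 0)
    return(list(ne = Inf, r2_prime = r2p, exp_r2 = e, flag = "infinite"))
  if (s >= 30) { third <- 1 / 3; coef <- 2.76 } else {
    third <- 0.308; coef <- 2.08
  }
  disc <- third^2 - coef * r2p
  if (disc < 0)
    return(list(ne = NA_real_, r2_prime = r2p, exp_r2 = e,
                flag = "extreme_ld"))
  list(ne = (third + sqrt(disc)) / (2 * r2p), r2_prime = r2p, exp_r2 = e,
       flag = "ok")
}

#' LD-based effective population size per population
#'
#' For every population: composite r-squared over all pairs of loci
#' (multi-allelic loci decomposed into allele-vs-rest pseudo-biallelic
#' comparisons, averaged within the pair; alleles below the MAF screen are
#' skipped), the harmonic-mean sample size over pairs, the sampling
#' correction, and the Ne estimate.
#'
#' @param gm a [genotype_matrix()].
#' @param maf within-population minor-allele-frequency screen (alleles with
#'   frequency below this, or above 1 - maf, are not used as focal
#'   alleles).
#' @param min_n minimum complete genotypes for a locus pair.
#' @return data.frame with one row per population: `population`, `r2_mean`,
#'   `s_harmonic`, `exp_r2`, `r2_prime`, `ne`, `n_pairs`, `flag`.
#' @export
ld_ne <- function(gm, maf = 0.02, min_n = 2) {
  pops <- unique(gm$populations)
  rows <- lapply(pops, function(p) {
    ii <- which(gm$populations == p)
    L <- n_loci(gm)
    # dosage vectors per locus per retained allele
    dosages <- list()
    for (j in seq_len(L)) {
      a1 <- gm$a1[ii, j]; a2 <- gm$a2[ii, j]
      al <- c(a1, a2); al <- al[!is.na(al)]
      if (!length(al)) next
      tab <- table(al)
      fr <- tab / sum(tab)
      use <- names(fr)[fr >= maf & fr <= 1 - maf]
      if (length(fr) == 2L && length(use) == 2L) use <- use[1]  # one df
      for (u in use) {
        uu <- as.integer(u)
        dosages[[length(dosages) + 1L]] <-
          list(locus = j, x = (a1 == uu) + (a2 == uu))
      }
    }
    r2s <- numeric(0); ns <- numeric(0)
    if (length(dosages) >= 2L) {
      loci_of <- vapply(dosages, `[[`, 0L, "locus")
      for (a in seq_len(length(dosages) - 1L)) for (b in (a + 1L):length(dosages)) {
        if (loci_of[a] == loci_of[b]) next
        res <- burrows_rsq(dosages[[a]]$x, dosages[[b]]$x)
        if (!is.na(res$r2) && res$n >= min_n) {
          r2s <- c(r2s, res$r2); ns <- c(ns, res$n)
        }
      }
    }
    if (!length(r2s))
      return(data.frame(population = p, r2_mean = NA_real_,
                        s_harmonic = NA_real_, exp_r2 = NA_real_,
                        r2_prime = NA_real_, ne = NA_real_, n_pairs = 0L,
                        flag = "no_pairs", stringsAsFactors = FALSE))
    s_h <- length(ns) / sum(1 / ns)
    est <- ld_ne_estimate(mean(r2s), s_h)
    data.frame(population = p, r2_mean = mean(r2s), s_harmonic = s_h,
               exp_r2 = est$exp_r2, r2_prime = est$r2_prime, ne = est$ne,
               n_pairs = length(r2s), flag = est$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Regression of LD-Ne on census size
#'
#' Ordinary least squares of log effective size on log census size (exact
#' counts where recorded, geometric category midpoints otherwise).
#' Populations with infinite or undefined Ne are excluded and counted.
#'
#' @param estimates output of [ld_ne()].
#' @param meta a [population_meta()] table.
#' @return list with `slope`, `intercept`, `f_statistic`, `p_value`,
#'   `r_squared`, `n_used`, `n_excluded`, and the fitted `model`.
#' @export
census_ne_regression <- function(estimates, meta) {
  m <- merge(estimates, data.frame(population = meta$population,
                                   census = census_midpoint(meta)),
             by = "population")
  ok <- is.finite(m$ne) & m$ne > 0 & is.finite(m$census)
  if (sum(ok) < 4L)
    stop("need at least 4 populations with finite Ne and census data")
  fit <- stats::lm(log(ne) ~ log(census), data = m[ok, ])
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       f_statistic = unname(fstat[1]),
       p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)),
       r_squared = sm$r.squared, n_used = sum(ok),
       n_excluded = sum(!ok), model = fit)
}
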