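#' Summary statistics of a genotype matrix for ABC
#'
#' The default statistic set per marker: mean alleles per locus, mean
#' unbiased expected heterozygosity per locus (pooled sample),
#' across-population Weir-Cockerham F_ST, and F_ST between the two regions
#' (regions pooled as two samples); length-coded SSRs additionally
#' contribute the mean across loci of the frequency-weighted allele-size
#' variance. Identity-coded SSRs and SNPs never receive length-based
#' statistics.
#'
#' @param gm a [genotype_matrix()] from a single marker set.
#' @param marker `"ssr_length"`, `"ssr_id"`, or `"snp"`.
#' @return named numeric vector (fixed order and length per marker).
#' @export
summary_stats <- function(gm, marker = c("ssr_length", "ssr_id", "snp")) {
  marker <- match.arg(marker)
  L <- n_loci(gm)
  mean_alleles <- 0; mean_he <- 0; var_size <- 0
  for (j in seq_len(L)) {
    cnt <- pooled_counts_locus(gm, j)
    k <- length(cnt)
    mean_alleles <- mean_alleles + k / L
    if (sum(cnt) >= 2L)
      mean_he <- mean_he + expected_heterozygosity(cnt) / L
    if (marker == "ssr_length" && k >= 1L) {
      sizes <- allele_sizes(gm, j)[as.integer(names(cnt))]
      p <- cnt / sum(cnt)
      var_size <- var_size + sum(p * (sizes - sum(p * sizes))^2) / L
    }
  }
  no_filter <- list(max_missing = 1, min_maf = 0)
  fst_global <- tryCatch(wc_fst(gm, filters = no_filter)$theta,
                         error = function(e) 0)
  gm_reg <- gm
  gm_reg$populations <- unname(gm$regions[gm$populations])
  gm_reg$regions <- stats::setNames(unique(gm_reg$populations),
                                    unique(gm_reg$populations))
  fst_regions <- tryCatch(wc_fst(gm_reg, filters = no_filter)$theta,
                          error = function(e) 0)
  out <- c(mean_alleles = mean_alleles, mean_he = mean_he,
           fst_global = fst_global, fst_regions = fst_regions)
  if (marker == "ssr_length") out <- c(out, var_size = var_size)
  out
}

#' Default ABC priors
#'
#' Uniform ranges for the event times and historic sizes, log-uniform for
#' the current (potentially tiny) population sizes and the SSR mutation
#' rate. The current-size prior can optionally be centered per population
#' on census estimates.
#'
#' @param ne_range historic size range (NeBr, NeSc).
#' @param t2_range,t1_range,tb1_range event-time ranges (generations);
#'   draws are made conditionally so that tb1 <= t1 <= t2.
#' @param ne_cur_range current focal size range (log-uniform).
#' @param mu_range SSR mutation-rate range (log-uniform).
#' @param census optional named vector of census sizes; when given, each
#'   focal population's current-size prior is log-uniform within a factor
#'   of `census_spread` of its census size (a diffuse census-centered
#'   prior), truncated to `ne_cur_range`.
#' @param census_spread multiplicative half-width of the census-centered
#'   prior.
#' @return a `prior_spec` list.
#' @export
default_priors <- function(ne_range = c(1000, 10000),
                           t2_range = c(100, 2000),
                           t1_range = c(10, 1000),
                           tb1_range = c(10, 1000),
                           ne_cur_range = c(50, 2000),
                           mu_range = c(1e-4, 1e-3),
                           census = NULL, census_spread = 4) {
  rngs <- list(ne_range, t2_range, t1_range, tb1_range, ne_cur_range, mu_range)
  if (any(vapply(rngs, function(r) r[1] <= 0 || r[2] <= r[1], TRUE)))
    stop("prior ranges must be positive with lower < upper")
  structure(list(ne_range = ne_range, t2_range = t2_range,
                 t1_range = t1_range, tb1_range = tb1_range,
                 ne_cur_range = ne_cur_range, mu_range = mu_range,
                 census = census, census_spread = census_spread),
            class = "prior_spec")
}

# One parameter draw; returns a named list of scalars (ne_cur possibly a
# vector for scenario 1b).
draw_params <- function(priors, scenario, n_pops) {
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  rlogunif <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))
  t2 <- runif1(priors$t2_range)
  t1 <- stats::runif(1, priors$t1_range[1], min(priors$t1_range[2], t2))
  tb1 <- stats::runif(1, priors$tb1_range[1], min(priors$tb1_range[2], t1))
  ne_br <- runif1(priors$ne_range)
  ne_sc <- runif1(priors$ne_range)
  ne_cur <- if (scenario == "1b" && !is.null(priors$census)) {
    lo <- pmax(priors$ne_cur_range[1], priors$census / priors$census_spread)
    hi <- pmin(priors$ne_cur_range[2], priors$census * priors$census_spread)
    hi <- pmax(hi, lo * 1.001)
    exp(stats::runif(n_pops, log(lo), log(hi)))
  } else if (scenario == "1b") {
    rlogunif(n_pops, priors$ne_cur_range)
  } else rlogunif(1L, priors$ne_cur_range)
  mu <- rlogunif(1L, priors$mu_range)
  list(t1 = t1, t2 = t2, tb1 = tb1, ne_br = ne_br, ne_sc = ne_sc,
       ne_cur = ne_cur, mu = mu)
}

params_to_spec <- function(pars, scenario, sample_sizes, outgroup_n) {
  if (scenario == "2")
    scenario_spec("2", sample_sizes, outgroup_n,
                  t1 = pars$t1, t2 = pars$t2,
                  ne_br = pars$ne_br, ne_sc = pars$ne_sc,
                  ne_cur = pmax(2, pars$ne_cur),
                  bottleneck_size = max(2, pars$ne_cur[1]))
  else
    scenario_spec(scenario, sample_sizes, outgroup_n,
                  t1 = pars$t1, t2 = pars$t2, tb1 = pars$tb1,
                  ne_br = pars$ne_br, ne_sc = pars$ne_sc,
                  ne_cur = pmax(2, pars$ne_cur))
}

#' Simulate an ABC reference table for one scenario
#'
#' Draws parameters from the priors, simulates a genotype matrix under the
#' scenario, and records parameters and summary statistics row by row.
#'
#' @param scenario `"1"`, `"1b"`, or `"2"`.
#' @param n_sims number of simulations.
#' @param priors a [default_priors()] object.
#' @param sample_sizes,outgroup_n sampling design (see [scenario_spec()]).
#' @param marker,n_loci marker set simulated.
#' @param seed RNG seed.
#' @return list with `params` (data.frame; `ne_cur` columns per population
#'   for scenario 1b) and `stats` (matrix, one row per simulation).
#' @export
abc_simulate <- function(scenario, n_sims, priors, sample_sizes, outgroup_n,
                         marker = "ssr_length", n_loci = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- length(sample_sizes)
  stat_rows <- vector("list", n_sims)
  par_rows <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    pars <- draw_params(priors, scenario, P)
    spec <- params_to_spec(pars, scenario, sample_sizes, outgroup_n)
    gm <- simulate_scenario(spec, marker, n_loci,
                            mu = if (marker == "snp") NULL else pars$mu)
    stat_rows[[s]] <- summary_stats(gm, marker)
    pv <- unlist(pars)
    par_rows[[s]] <- pv
  }
  list(params = as.data.frame(do.call(rbind, par_rows)),
       stats = do.call(rbind, stat_rows))
}

#' ABC scenario choice by logistic regression on the closest simulations
#'
#' Statistics are standardized by their median absolute deviation over all
#' simulations (zero-MAD statistics dropped with a warning), Euclidean
#' distances to the observed vector computed, the nearest
#' `retain_fraction` kept, and a multinomial logistic regression of the
#' scenario label on the statistics within the retained set evaluated at
#' the observed vector. If the regression is degenerate (e.g. one scenario
#' absent from the retained set) the retained-count proportions are
#' returned instead.
#'
#' @param observed named numeric vector of observed summary statistics.
#' @param sims named list: scenario -> list with `stats` (matrix) as
#'   produced by [abc_simulate()] (equal simulation counts per scenario).
#' @param retain_fraction fraction of simulations retained.
#' @return an `abc_result` list: `posterior` (named probabilities summing
#'   to 1), `retained` (counts per scenario), `threshold` (distance of the
#'   last retained simulation), `method` (`"logistic"` or
#'   `"rejection"`).
#' @export
abc_model_choice <- function(observed, sims, retain_fraction = 0.01) {
  if (length(sims) < 2L) stop("need at least 2 scenarios")
  counts <- vapply(sims, function(s) nrow(s$stats), 0L)
  if (length(unique(counts)) != 1L)
    stop("scenarios must have equal simulation counts")
  all_stats <- do.call(rbind, lapply(sims, `[[`, "stats"))
  labels <- factor(rep(names(sims), counts), levels = names(sims))
  std <- standardize_stats(all_stats, observed)
  n_retain <- max(2L, ceiling(retain_fraction * nrow(all_stats)))
  ord <- order(std$dist)[seq_len(n_retain)]
  retained <- table(labels[ord])
  post <- NULL; method <- "rejection"
  if (all(retained > 0L)) {
    df <- data.frame(scenario = labels[ord], std$stats[ord, , drop = FALSE])
    fit <- tryCatch(
      nnet::multinom(scenario ~ ., data = df, trace = FALSE, maxit = 500),
      error = function(e) NULL)
    if (!is.null(fit)) {
      newd <- as.data.frame(rbind(std$observed))
      names(newd) <- colnames(std$stats)
      pr <- stats::predict(fit, newdata = newd, type = "probs")
      post <- if (length(sims) == 2L)
        stats::setNames(c(1 - pr, pr), names(sims)) else
          stats::setNames(as.numeric(pr), colnames(pr))
      method <- "logistic"
    }
  }
  if (is.null(post))
    post <- as.numeric(retained) / sum(retained)
  names(post) <- names(sims)
  structure(list(posterior = post / sum(post),
                 retained = stats::setNames(as.integer(retained), names(sims)),
                 threshold = std$dist[ord[n_retain]],
                 retain_fraction = retain_fraction, method = method),
            class = "abc_result")
}

#' ABC parameter posterior with local-linear adjustment
#'
#' Rejection sampling on the retained simulations of one scenario, with the
#' local-linear regression correction: retained parameter values are
#' adjusted by a weighted linear regression on the (standardized)
#' statistics, evaluated at the observed vector, with Epanechnikov kernel
#' weights in distance. Adjusted samples are clipped to the prior support.
#'
#' @param observed named numeric vector of observed statistics.
#' @param params data.frame of simulated parameters (one row per
#'   simulation).
#' @param stats matrix of simulated statistics (rows aligned to `params`).
#' @param retain_fraction fraction retained.
#' @param support optional named list parameter -> c(lo, hi) for clipping
#'   and boundary flagging.
#' @return list with `samples` (adjusted parameters, retained rows),
#'   `weights`, `summary` (data.frame: parameter, peak, q05, q95,
#'   at_boundary), `adjusted` (FALSE when the regression was degenerate
#'   and plain rejection samples are returned).
#' @export
abc_parameter_posterior <- function(observed, params, stats,
                                    retain_fraction = 0.01, support = NULL) {
  std <- standardize_stats(stats, observed)
  n_retain <- max(2L, ceiling(retain_fraction * nrow(stats)))
  ord <- order(std$dist)[seq_len(n_retain)]
  d <- std$dist[ord]
  dmax <- max(d[n_retain], .Machine$double.eps)
  w <- 1 - (d / dmax)^2
  w[w <= 0] <- min(w[w > 0], 1e-6)  # keep the boundary simulation in
  X <- sweep(std$stats[ord, , drop = FALSE], 2L, std$observed)
  adj <- as.data.frame(params[ord, , drop = FALSE])
  adjusted <- TRUE
  for (cn in names(adj)) {
    y <- adj[[cn]]
    fit <- tryCatch(stats::lm.wfit(cbind(1, X), y, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) { adjusted <- FALSE; next }
    beta <- fit$coefficients[-1]
    adj[[cn]] <- y - as.numeric(X %*% beta)
    if (!is.null(support[[cn]]))
      adj[[cn]] <- pmin(pmax(adj[[cn]], support[[cn]][1]), support[[cn]][2])
  }
  summ <- do.call(rbind, lapply(names(adj), function(cn) {
    x <- adj[[cn]]
    pk <- weighted_density_peak(x, w)
    qs <- weighted_quantile(x, w, c(0.05, 0.95))
    at_b <- if (!is.null(support[[cn]])) {
      span <- diff(support[[cn]])
      min(abs(pk - support[[cn]])) < 0.01 * span
    } else FALSE
    data.frame(parameter = cn, peak = pk, q05 = qs[1], q95 = qs[2],
               at_boundary = at_b, stringsAsFactors = FALSE)
  }))
  list(samples = adj, weights = w, summary = summ, adjusted = adjusted)
}

#' Combine parameter posteriors across marker sets
#'
#' Kernel density estimate of each marker's weighted posterior on a common
#' grid over the prior support; the combined density is the renormalized
#' product (independent evidence pooling).
#'
#' @param per_marker list of lists, each with `samples` (numeric vector)
#'   and `weights`.
#' @param support c(lo, hi) grid range (prior support of the parameter).
#' @param n_grid grid size.
#' @return list with `grid`, `density` (integrates to 1), `peak`, `q05`,
#'   `q95`, and `per_marker_density` (matrix).
#' @export
combine_posteriors <- function(per_marker, support, n_grid = 512) {
  if (length(per_marker) < 2L) stop("need at least 2 marker posteriors")
  dens <- vapply(per_marker, function(m) {
    w <- m$weights / sum(m$weights)
    suppressWarnings(
      stats::density(m$samples, weights = w, from = support[1],
                     to = support[2], n = n_grid)$y)
  }, numeric(n_grid))
  logprod <- rowSums(log(pmax(dens, 1e-300)))
  prod_d <- exp(logprod - max(logprod))
  grid <- seq(support[1], support[2], length.out = n_grid)
  dx <- grid[2] - grid[1]
  # at the product's peak, every marker must retain appreciable density
  # relative to its own maximum, otherwise the posteriors are inconsistent
  i_peak <- which.max(prod_d)
  rel <- dens[i_peak, ] / apply(dens, 2L, max)
  if (any(rel < 1e-4))
    stop("marker posteriors do not overlap on the shared support")
  Z <- sum(prod_d) * dx
  dens_c <- prod_d / Z
  cdf <- cumsum(dens_c) * dx
  list(grid = grid, density = dens_c,
       peak = grid[which.max(dens_c)],
       q05 = grid[which.min(abs(cdf - 0.05))],
       q95 = grid[which.min(abs(cdf - 0.95))],
       per_marker_density = dens)
}

#' Convert event times from generations to calendar years
#'
#' @param generations scalar or vector of event times in generations.
#' @param gen_time_range c(low, high) generation time in years.
#' @return matrix (or vector for scalar input) with the low and high
#'   calendar ages in years.
#' @export
calibrate_event_times <- function(generations, gen_time_range) {
  if (any(generations < 0)) stop("generations must be >= 0")
  if (gen_time_range[1] <= 0 || gen_time_range[1] > gen_time_range[2])
    stop("generation-time range must satisfy 0 < low <= high")
  out <- cbind(low = generations * gen_time_range[1],
               high = generations * gen_time_range[2])
  if (length(generations) == 1L) out[1, ] else out
}

## ---- internals ----

standardize_stats <- function(stats, observed) {
  stats <- as.matrix(stats)
  observed <- observed[colnames(stats)]
  mads <- apply(stats, 2L, stats::mad)
  keep <- mads > 0
  if (!any(keep)) stop("all summary statistics have zero spread")
  if (!all(keep))
    warning("dropping zero-spread statistics: ",
            paste(colnames(stats)[!keep], collapse = ", "))
  s <- sweep(stats[, keep, drop = FALSE], 2L, mads[keep], "/")
  o <- observed[keep] / mads[keep]
  list(stats = s, observed = o,
       dist = sqrt(colSums((t(s) - o)^2)))
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which.max(cw >= p)], 0)
}

weighted_density_peak <- function(x, w) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- suppressWarnings(stats::density(x, weights = w / sum(w)))
  d$x[which.max(d$y)]
}
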