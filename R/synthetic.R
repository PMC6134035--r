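#' Draw population genotypes under the Balding-Nichols model
#'
#' Forward direction of the multinomial-Dirichlet model used by the local
#' F_ST likelihood: for each population with divergence parameter F, the
#' population's allele frequencies at a locus are Dirichlet with parameters
#' \eqn{\pi_i (1-F)/F} around the regional mean \eqn{\pi} (total mass
#' \eqn{(1-F)/F}, so E[p] = \eqn{\pi} and Var[p_i] = \eqn{F \pi_i (1-\pi_i)}),
#' and 2n gene copies are then drawn multinomially and paired at random into
#' diploid genotypes (Hardy-Weinberg within population).
#'
#' @param regional_freqs list with one numeric frequency vector per locus;
#'   each must sum to 1.
#' @param f_per_pop per-population F in [0, 1).
#' @param n_per_pop per-population diploid sample size.
#' @param seed optional RNG seed.
#' @param pop_ids,regions optional population IDs and population->region map.
#' @param marker_kind marker kind for the generated loci.
#' @return a [genotype_matrix()].
#' @export
simulate_balding_nichols <- function(regional_freqs, f_per_pop, n_per_pop,
                                     seed = NULL, pop_ids = NULL,
                                     regions = NULL,
                                     marker_kind = "ssr_length") {
  if (!is.null(seed)) set.seed(seed)
  bad <- !vapply(regional_freqs, function(p) abs(sum(p) - 1) < 1e-9, TRUE)
  if (any(bad)) stop("frequency vector does not sum to 1 at locus ",
                     which(bad)[1])
  if (any(f_per_pop < 0 | f_per_pop >= 1))
    stop("F must lie in [0, 1); F = 1 is degenerate")
  if (any(n_per_pop < 1)) stop("sample sizes must be >= 1")
  stopifnot(length(f_per_pop) == length(n_per_pop))
  P <- length(n_per_pop); L <- length(regional_freqs)
  if (is.null(pop_ids)) pop_ids <- paste0("pop_", seq_len(P))
  n_tot <- sum(n_per_pop)
  a1 <- matrix(NA_integer_, n_tot, L); a2 <- matrix(NA_integer_, n_tot, L)
  row0 <- c(0L, cumsum(n_per_pop))
  for (p in seq_len(P)) {
    Fp <- f_per_pop[p]; n <- n_per_pop[p]
    rows <- (row0[p] + 1L):row0[p + 1L]
    for (j in seq_len(L)) {
      pi <- regional_freqs[[j]]; k <- length(pi)
      pr <- if (Fp > 0) {
        g <- stats::rgamma(k, shape = pi * (1 - Fp) / Fp)
        if (sum(g) == 0) { g <- pi }  # guard against underflow at tiny alpha
        g / sum(g)
      } else pi
      copies <- sample.int(k, 2L * n, replace = TRUE, prob = pr)
      a1[rows, j] <- copies[seq_len(n)]
      a2[rows, j] <- copies[n + seq_len(n)]
    }
  }
  genotype_matrix(a1, a2,
                  individuals = paste0(rep(pop_ids, n_per_pop), "_",
                                       unlist(lapply(n_per_pop, seq_len))),
                  populations = rep(pop_ids, n_per_pop),
                  loci = paste0("L", seq_len(L)),
                  marker_kind = marker_kind, regions = regions)
}

#' Forward Wright-Fisher simulation of unlinked biallelic loci
#'
#' Discrete-generation random-mating Wright-Fisher reproduction for a diploid
#' population of constant size Ne, starting every locus at frequency 0.5,
#' with symmetric per-copy mutation. Loci are unlinked (free recombination),
#' so any linkage disequilibrium in the sample is generated purely by drift
#' in the finite population -- the signal the LD-based Ne estimator reads.
#'
#' @param ne diploid population size (>= 2).
#' @param sample_size individuals sampled without replacement at the end.
#' @param n_loci number of unlinked biallelic loci.
#' @param generations number of generations to evolve.
#' @param mu symmetric per-copy per-generation mutation (allele flip) rate.
#' @param seed optional RNG seed.
#' @return a [genotype_matrix()] with `marker_kind = "snp"`, one population.
#' @export
simulate_wright_fisher_ld <- function(ne, sample_size, n_loci,
                                      generations, mu = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (ne < 2) stop("ne must be >= 2")
  if (sample_size > ne) stop("sample_size cannot exceed ne")
  A1 <- matrix(stats::rbinom(ne * n_loci, 1L, 0.5), ne, n_loci)
  A2 <- matrix(stats::rbinom(ne * n_loci, 1L, 0.5), ne, n_loci)
  for (g in seq_len(generations)) {
    mothers <- sample.int(ne, ne, replace = TRUE)
    fathers <- sample.int(ne, ne, replace = TRUE)
    pickm <- matrix(stats::runif(ne * n_loci) < 0.5, ne, n_loci)
    pickf <- matrix(stats::runif(ne * n_loci) < 0.5, ne, n_loci)
    N1 <- ifelse(pickm, A1[mothers, , drop = FALSE], A2[mothers, , drop = FALSE])
    N2 <- ifelse(pickf, A1[fathers, , drop = FALSE], A2[fathers, , drop = FALSE])
    if (mu > 0) {
      flip1 <- matrix(stats::runif(ne * n_loci) < mu, ne, n_loci)
      flip2 <- matrix(stats::runif(ne * n_loci) < mu, ne, n_loci)
      N1 <- ifelse(flip1, 1L - N1, N1)
      N2 <- ifelse(flip2, 1L - N2, N2)
    }
    A1 <- N1; A2 <- N2
  }
  keep <- sample.int(ne, sample_size)
  genotype_matrix(A1[keep, , drop = FALSE] + 1L, A2[keep, , drop = FALSE] + 1L,
                  individuals = paste0("ind_", seq_len(sample_size)),
                  populations = rep("wf", sample_size),
                  loci = paste0("L", seq_len(n_loci)),
                  marker_kind = "snp")
}

#' Simulate RAD read bundles from known SSR genotypes
#'
#' Per individual and locus, a Poisson total read count is split between the
#' two true allele sequences (binomially, p = `het_bias` for heterozygotes)
#' and independent per-base substitution errors are applied, yielding the
#' (sequence, count) bundles consumed by the RAD-SSR caller.
#'
#' @param gm a [genotype_matrix()] of true `ssr_id` genotypes.
#' @param allele_seqs list, one entry per locus: character vector of allele
#'   sequences indexed by allele code; sequences must share one length per
#'   locus.
#' @param coverage_mean Poisson mean total reads per individual per locus.
#' @param error_rate per-base substitution error probability.
#' @param het_bias probability a read comes from the first allele of a
#'   heterozygote (0.5 = no allelic bias).
#' @param seed optional RNG seed.
#' @return a [read_bundle_set()].
#' @export
simulate_rad_reads <- function(gm, allele_seqs, coverage_mean,
                               error_rate = 0, het_bias = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (coverage_mean < 0) stop("coverage_mean must be >= 0")
  bases <- c("A", "C", "G", "T")
  out_ind <- character(0); out_loc <- character(0)
  out_seq <- character(0); out_cnt <- integer(0)
  for (j in seq_along(gm$loci)) {
    seqs <- allele_seqs[[j]]
    if (length(unique(nchar(seqs))) > 1L)
      stop("allele sequences must have uniform length at locus ", gm$loci[j])
    len <- nchar(seqs[1])
    for (i in seq_along(gm$individuals)) {
      a <- gm$a1[i, j]; b <- gm$a2[i, j]
      if (is.na(a)) next
      if (a > length(seqs) || b > length(seqs) ||
          is.na(seqs[a]) || is.na(seqs[b]))
        stop("allele without sequence mapping at locus ", gm$loci[j])
      total <- stats::rpois(1L, coverage_mean)
      if (total == 0L) next
      n1 <- if (a == b) total else stats::rbinom(1L, total, het_bias)
      reads <- c(rep(seqs[a], n1), rep(seqs[b], total - n1))
      if (error_rate > 0 && length(reads)) {
        nerr <- stats::rbinom(length(reads), len, error_rate)
        for (r in which(nerr > 0L)) {
          chars <- strsplit(reads[r], "")[[1]]
          pos <- sample.int(len, nerr[r])
          chars[pos] <- vapply(chars[pos], function(ch)
            sample(setdiff(bases, ch), 1L), "")
          reads[r] <- paste(chars, collapse = "")
        }
      }
      tab <- table(reads)
      out_ind <- c(out_ind, rep(gm$individuals[i], length(tab)))
      out_loc <- c(out_loc, rep(gm$loci[j], length(tab)))
      out_seq <- c(out_seq, names(tab))
      out_cnt <- c(out_cnt, as.integer(tab))
    }
  }
  read_bundle_set(out_ind, out_loc, out_seq, out_cnt)
}

#' Random allele sequences carrying a di-nucleotide repeat
#'
#' Builds, for every `ssr_id` locus of a genotype matrix, one sequence per
#' allele: a shared random flank, a central (AC)n di-nucleotide repeat, and
#' allele-distinguishing random bases, all of one uniform length per locus.
#'
#' @param gm a [genotype_matrix()].
#' @param seq_len read length in bases.
#' @param n_repeats repeat count of the embedded motif.
#' @param seed optional RNG seed.
#' @return list of character vectors, one per locus, indexed by allele code.
#' @export
make_allele_sequences <- function(gm, seq_len = 60, n_repeats = 8,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  motif <- strrep("AC", n_repeats)
  lapply(seq_along(gm$loci), function(j) {
    k <- max(c(gm$a1[, j], gm$a2[, j], 1L), na.rm = TRUE)
    flank_len <- seq_len - nchar(motif) - 8L
    if (flank_len < 1L) stop("seq_len too short for the embedded repeat")
    flank <- paste(sample(bases, flank_len, replace = TRUE), collapse = "")
    vapply(seq_len(k), function(a) {
      tag <- paste(sample(bases, 8L, replace = TRUE), collapse = "")
      paste0(flank, motif, tag)
    }, "")
  })
}

#' Configuration of a synthetic fragmentation study
#'
#' Defaults emulate the sampling design of the dwarf-birch survey: 29
#' fragmented-region and 10 continuous-region populations; realistic
#' per-population sample sizes (including several exhaustively sampled
#' remnants of 1-2 plants); four marker sets of 18 length-coded SSRs, 193
#' identity-coded RAD-SSRs, and 4775 + 3306 transition/transversion SNPs;
#' and stronger, census-dependent drift in the fragmented region.
#'
#' @param n_pop_fragmented,n_pop_continuous populations per region.
#' @param n_ind_fragmented,n_ind_continuous diploid sample sizes, recycled
#'   across populations. The fragmented default is a survey-like vector with
#'   small remnants.
#' @param n_rad_per_pop individuals per population carried into the RAD
#'   marker sets (populations with fewer than 3 samples are dropped from
#'   RAD, as tiny remnants typically fail library preparation).
#' @param loci named vector of locus counts per marker set.
#' @param base_f named per-region baseline divergence F; the per-population
#'   F scales with census size as `min(0.4, base_f * (1000 / census)^0.25)`,
#'   so small fragments drift harder.
#' @param coverage_mean,error_rate read-simulation settings for the bundles.
#' @param bundle_loci number of `ssr_id` loci for which read bundles are
#'   emitted (bundles are by far the bulkiest part of a fixture).
#' @param seed RNG seed; fixed seed gives a byte-identical fixture.
#' @return a `synthetic_study_config` list.
#' @export
synthetic_study_config <- function(
    n_pop_fragmented = 29, n_pop_continuous = 10,
    n_ind_fragmented = c(30, 25, 27, 32, 34, 21, 26, 33, 31, 30,
                         30, 33, 41, 31, 33, 31, 31, 32, 49, 30,
                         5, 29, 31, 31, 30, 49, 2, 1, 2),
    n_ind_continuous = c(30, 30, 30, 32, 32, 31, 23, 31, 29, 28),
    n_rad_per_pop = 6,
    loci = c(ssr_length = 18, ssr_id = 193, snp_ti = 4775, snp_tv = 3306),
    base_f = c(fragmented = 0.08, continuous = 0.02),
    coverage_mean = 40, error_rate = 0.001, bundle_loci = 25,
    seed = 1) {
  cfg <- list(n_pop_fragmented = n_pop_fragmented,
              n_pop_continuous = n_pop_continuous,
              n_ind_fragmented = rep_len(n_ind_fragmented, n_pop_fragmented),
              n_ind_continuous = rep_len(n_ind_continuous, n_pop_continuous),
              n_rad_per_pop = n_rad_per_pop, loci = loci, base_f = base_f,
              coverage_mean = coverage_mean, error_rate = error_rate,
              bundle_loci = min(bundle_loci, loci[["ssr_id"]]), seed = seed)
  if (any(unlist(cfg[c("n_ind_fragmented", "n_ind_continuous")]) < 1) ||
      any(loci < 1))
    stop("all counts must be >= 1")
  if (any(base_f < 0 | base_f >= 1)) stop("base_f must lie in [0, 1)")
  class(cfg) <- "synthetic_study_config"
  cfg
}

#' Read a study configuration from YAML
#' @param path YAML file; keys match the arguments of
#'   [synthetic_study_config()].
#' @return a `synthetic_study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$loci)) y$loci <- unlist(y$loci)
  if (!is.null(y$base_f)) y$base_f <- unlist(y$base_f)
  do.call(synthetic_study_config, y)
}

# Random allele-frequency vectors for one marker set.
random_regional_freqs <- function(n_loci, kind) {
  lapply(seq_len(n_loci), function(j) {
    if (kind == "snp") {
      p <- stats::rbeta(1, 0.8, 0.8)
      p <- min(max(p, 0.02), 0.98)
      c(p, 1 - p)
    } else {
      k <- sample(2:if (kind == "ssr_length") 12 else 18, 1L)
      g <- stats::rgamma(k, 1)
      g / sum(g)
    }
  })
}

#' Generate a complete synthetic study fixture
#'
#' Emits everything the analysis pipeline consumes: genotype matrices for the
#' four marker sets over a shared set of individuals (the RAD sets on a
#' subset of individuals, as in a real RAD survey), population metadata with
#' coordinates and census categories, and RAD read bundles for a subset of
#' the identity-coded SSR loci. Per-population divergence F is tied to the
#' drawn census size, so census category, drift and diversity co-vary the way
#' the analyses assume.
#'
#' @param config a [synthetic_study_config()].
#' @return list with elements `genotypes` (named list of four
#'   [genotype_matrix()] objects), `meta` (a [population_meta()] table),
#'   `bundles` (a [read_bundle_set()]), `allele_seqs`, and `true_f`
#'   (the generating per-population F).
#' @export
make_study_fixture <- function(config = synthetic_study_config()) {
  set.seed(config$seed)
  nf <- config$n_pop_fragmented; nc <- config$n_pop_continuous
  pops_f <- sprintf("F%02d", seq_len(nf))
  pops_c <- sprintf("C%02d", seq_len(nc))
  pops <- c(pops_f, pops_c)
  n_ind <- c(config$n_ind_fragmented, config$n_ind_continuous)
  region <- stats::setNames(rep(c("fragmented", "continuous"), c(nf, nc)), pops)

  # census sizes: exhaustively sampled remnants have census == sample size;
  # larger fragmented populations span the categories; continuous populations
  # are large
  census <- numeric(nf + nc)
  for (p in seq_len(nf)) {
    census[p] <- if (n_ind[p] <= 5) n_ind[p]
    else round(10^stats::runif(1, 1.2, 4))
  }
  census[nf + seq_len(nc)] <- round(10^stats::runif(nc, 2, 4))
  cat_of <- function(x) cut(x, c(0, 10, 100, 1000, 10000),
                            labels = c("1-10", "10-100", "100-1000",
                                       "1000-10000"))
  f_pop <- pmin(0.4, unname(config$base_f[region[pops]]) *
                  (1000 / census)^0.25)

  meta <- population_meta(
    population = pops,
    latitude = c(stats::runif(nf, 54.6, 58.4), stats::runif(nc, 69.2, 70.9)),
    longitude = c(stats::runif(nf, -5.0, -2.2), stats::runif(nc, 25.7, 28.0)),
    census_category = as.character(cat_of(census)),
    region = unname(region[pops]),
    census_count = ifelse(census <= 100, census, NA_real_))

  kinds <- c(ssr_length = "ssr_length", ssr_id = "ssr_id",
             snp_ti = "snp", snp_tv = "snp")
  genotypes <- list()
  for (set in names(config$loci)) {
    freqs <- random_regional_freqs(config$loci[[set]], kinds[[set]])
    gm <- simulate_balding_nichols(freqs, f_pop, n_ind, pop_ids = pops,
                                   regions = region,
                                   marker_kind = kinds[[set]])
    gm$loci <- paste0(set, "_", seq_along(gm$loci))
    colnames(gm$a1) <- colnames(gm$a2) <- gm$loci
    if (set != "ssr_length") {  # RAD sets: subset of individuals
      keep <- unlist(lapply(pops, function(p) {
        ii <- which(gm$populations == p)
        if (length(ii) < 3L) return(integer(0))
        ii[seq_len(min(config$n_rad_per_pop, length(ii)))]
      }))
      gm <- gm_subset(gm, ind = keep)
    }
    genotypes[[set]] <- gm
  }

  rad_gm <- gm_subset(genotypes$ssr_id, loci = seq_len(config$bundle_loci))
  allele_seqs <- make_allele_sequences(rad_gm)
  bundles <- simulate_rad_reads(rad_gm, allele_seqs,
                                coverage_mean = config$coverage_mean,
                                error_rate = config$error_rate)
  list(genotypes = genotypes, meta = meta, bundles = bundles,
       allele_seqs = allele_seqs, true_f = stats::setNames(f_pop, pops))
}

#' Write a study fixture to a directory
#'
#' Genotypes go out as Genepop (SSR sets) / VCF (SNP sets) plus a TSV copy of
#' everything, metadata and read bundles as TSV.
#'
#' @param fixture output of [make_study_fixture()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (set in names(fixture$genotypes)) {
    gm <- fixture$genotypes[[set]]
    write_genotypes(gm, file.path(dir, paste0(set, ".tsv")), "tsv")
    if (all(gm$marker_kind == "snp"))
      write_genotypes(gm, file.path(dir, paste0(set, ".vcf")), "vcf")
    else
      write_genotypes(gm, file.path(dir, paste0(set, ".gen")), "genepop")
  }
  write_population_meta(fixture$meta, file.path(dir, "meta.tsv"))
  write_read_bundles(fixture$bundles, file.path(dir, "bundles.tsv"))
  invisible(dir)
}
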