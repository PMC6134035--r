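#' Demographic scenario specification
#'
#' Piecewise-constant divergence histories for a focal region of fragmented
#' populations and a continuous out-group region, with no migration after
#' divergence:
#' \describe{
#'   \item{Scenario 1}{Focal populations diverge from an ancestral focal
#'     population (historic size `ne_br`) `t1` generations ago, stay at
#'     `ne_br` until a shared recent bottleneck `tb1` generations ago drops
#'     them to a single shared current size `ne_cur`.}
#'   \item{Scenario 1b}{As scenario 1, but each focal population has its own
#'     current size `ne_cur[i]` after its bottleneck.}
#'   \item{Scenario 2}{The bottleneck happens at colonization instead: the
#'     focal lineage is small from the regional divergence `t2` onwards --
#'     focal populations sit at their current sizes from `t1` to the
#'     present and the ancestral focal population at `bottleneck_size`
#'     between `t1` and `t2`. No post-divergence bottleneck event.}
#' }
#' At `t1` all focal populations merge into the ancestral focal population;
#' at `t2` the focal and out-group lineages merge, the ancestral population
#' persisting at the out-group size `ne_sc`. Times are in generations,
#' sizes in diploid individuals.
#'
#' @param scenario `"1"`, `"1b"`, or `"2"`.
#' @param sample_sizes named integer vector: diploid sample size per focal
#'   population.
#' @param outgroup_n diploid sample size of the out-group population.
#' @param t1,t2 divergence times (generations; `0 < t1 <= t2`).
#' @param tb1 bottleneck time (scenarios 1/1b; `0 < tb1 <= t1`).
#' @param ne_br historic (pre-bottleneck) focal-region size.
#' @param ne_sc out-group size (also the ancestral size beyond `t2`).
#' @param ne_cur current focal population size(s): scalar (1, 2) or one per
#'   population (1b).
#' @param bottleneck_size ancestral focal size after colonization
#'   (scenario 2 only).
#' @return a `scenario_spec` object.
#' @export
scenario_spec <- function(scenario = c("1", "1b", "2"), sample_sizes,
                          outgroup_n, t1, t2, tb1 = NULL,
                          ne_br, ne_sc, ne_cur, bottleneck_size = NULL) {
  scenario <- match.arg(scenario)
  P <- length(sample_sizes)
  if (is.null(names(sample_sizes)))
    names(sample_sizes) <- paste0("B", seq_len(P))
  ne_cur <- if (scenario == "1b") rep_len(ne_cur, P) else rep_len(ne_cur[1], P)
  if (scenario %in% c("1", "1b")) {
    if (is.null(tb1)) stop("scenarios 1/1b need a bottleneck time tb1")
    if (!(0 < tb1 && tb1 <= t1 && t1 <= t2))
      stop("event times must satisfy 0 < tb1 <= t1 <= t2")
    bottleneck_size <- NULL
  } else {
    if (!is.null(tb1)) stop("scenario 2 has no post-divergence bottleneck")
    if (!(0 < t1 && t1 <= t2)) stop("event times must satisfy 0 < t1 <= t2")
    if (is.null(bottleneck_size))
      stop("scenario 2 needs the colonization bottleneck size")
    if (bottleneck_size < 2) stop("sizes must be >= 2")
  }
  if (any(c(ne_br, ne_sc, ne_cur) < 2)) stop("sizes must be >= 2")
  if (any(sample_sizes < 1) || outgroup_n < 1)
    stop("sample sizes must be >= 1")
  structure(list(scenario = scenario,
                 sample_sizes = sample_sizes, outgroup_n = outgroup_n,
                 t1 = t1, t2 = t2, tb1 = tb1, ne_br = ne_br, ne_sc = ne_sc,
                 ne_cur = stats::setNames(ne_cur, names(sample_sizes)),
                 bottleneck_size = bottleneck_size),
            class = "scenario_spec")
}

# One coalescent genealogy under the scenario. Returns parent pointers,
# node times, and the tip layout (2 gene copies per diploid individual,
# grouped by population).
simulate_genealogy <- function(spec) {
  P <- length(spec$sample_sizes)
  tips_per_pop <- c(2L * spec$sample_sizes, 2L * spec$outgroup_n)
  T_ <- sum(tips_per_pop)
  n_nodes <- 2L * T_ - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  deme_of <- rep.int(seq_len(P + 1L), tips_per_pop)
  active <- split(seq_len(T_), deme_of)      # lineages per live deme
  active <- c(active, vector("list", 2L))    # slots for ancestral demes
  next_node <- T_ + 1L
  # ordered event queue; "resize" only moves the size function past tb1
  events <- if (spec$scenario == "2")
    list(list(t = spec$t1, what = "merge_focal"),
         list(t = spec$t2, what = "merge_regions"),
         list(t = Inf, what = "end"))
  else
    list(list(t = spec$tb1, what = "resize"),
         list(t = spec$t1, what = "merge_focal"),
         list(t = spec$t2, what = "merge_regions"),
         list(t = Inf, what = "end"))
  t_now <- 0
  n_live <- T_
  # per-deme diploid sizes in the current epoch (updated at events)
  sizes <- c(unname(spec$ne_cur), spec$ne_sc,
             if (spec$scenario == "2") spec$bottleneck_size else spec$ne_br,
             spec$ne_sc)
  repeat {
    if (n_live == 1L) break
    epoch_end <- events[[1]]$t
    k <- lengths(active)
    rates <- k * (k - 1) / (4 * sizes)
    total <- sum(rates)
    dt <- if (total > 0) stats::rexp(1L, total) else Inf
    if (t_now + dt >= epoch_end) {
      t_now <- epoch_end
      what <- events[[1]]$what
      if (what == "resize") {
        sizes[seq_len(P)] <- spec$ne_br
      } else if (what == "merge_focal") {
        active[[P + 2L]] <- c(unlist(active[seq_len(P)]), active[[P + 2L]])
        for (d in seq_len(P)) active[[d]] <- integer(0)
      } else if (what == "merge_regions") {
        active[[P + 3L]] <- c(active[[P + 1L]], active[[P + 2L]])
        active[[P + 1L]] <- integer(0); active[[P + 2L]] <- integer(0)
      } else if (what == "end") {
        stop("internal error: lineages remain after the final epoch")
      }
      events <- events[-1]
      next
    }
    t_now <- t_now + dt
    d <- sample.int(length(rates), 1L, prob = rates)
    av <- active[[d]]
    pair_pos <- sample.int(length(av), 2L)
    pair <- av[pair_pos]
    node <- next_node; next_node <- next_node + 1L
    parent[pair] <- node
    time[node] <- t_now
    av[pair_pos[1L]] <- node
    active[[d]] <- av[-pair_pos[2L]]
    n_live <- n_live - 1L
  }
  list(parent = parent, time = time, n_tips = T_,
       root = n_nodes,
       tip_pop = deme_of[seq_len(T_)],
       pop_names = c(names(spec$sample_sizes), "OUT"))
}

# Overlay mutations on a genealogy.
#   ssr: Poisson(mu * branch) symmetric single-step changes of repeat count,
#        each mutation also minting a new sequence identity.
#   snp: a single mutation placed uniformly on the total branch length.
mutate_tree <- function(tree, marker, mu) {
  n <- length(tree$parent)
  ord <- order(tree$time[(tree$n_tips + 1L):n], decreasing = TRUE) +
    tree$n_tips  # internal nodes, oldest first
  if (marker %in% c("ssr_length", "ssr_id")) {
    blen <- numeric(n)
    has_p <- tree$parent > 0L
    blen[has_p] <- tree$time[tree$parent[has_p]] - tree$time[has_p]
    nmut <- stats::rpois(n, mu * blen)
    len <- integer(n); id <- integer(n)
    len[tree$root] <- 100L; id[tree$root] <- 1L
    id_counter <- 1L
    for (v in c(ord, seq_len(tree$n_tips))) {
      # internal nodes oldest-first, then tips: parents before children
      p <- tree$parent[v]
      if (p == 0L) next
      if (nmut[v] > 0L) {
        step <- 2L * stats::rbinom(1L, nmut[v], 0.5) - nmut[v]
        newlen <- len[p] + step
        if (newlen < 2L) newlen <- 4L - newlen  # reflect away from collapse
        len[v] <- newlen
        id_counter <- id_counter + 1L
        id[v] <- id_counter
      } else {
        len[v] <- len[p]; id[v] <- id[p]
      }
    }
    if (marker == "ssr_length") len[seq_len(tree$n_tips)]
    else id[seq_len(tree$n_tips)]
  } else {
    blen <- numeric(n)
    has_p <- tree$parent > 0L
    blen[has_p] <- tree$time[tree$parent[has_p]] - tree$time[has_p]
    repeat {
      b <- sample.int(n, 1L, prob = blen)
      der <- descendants_of(tree, b)
      if (length(der) && length(der) < tree$n_tips) break
    }
    out <- rep(1L, tree$n_tips)
    out[der] <- 2L
    out
  }
}

# Tip descendants of node b (b included if a tip).
descendants_of <- function(tree, b) {
  if (b <= tree$n_tips) return(b)
  # collect by sweeping: mark b, then propagate to children via parent index
  mark <- logical(length(tree$parent))
  mark[b] <- TRUE
  # children have smaller time than parents; iterate nodes oldest-to-newest
  ord <- order(tree$time, decreasing = TRUE)
  for (v in ord) {
    p <- tree$parent[v]
    if (p > 0L && mark[p]) mark[v] <- TRUE
  }
  which(mark[seq_len(tree$n_tips)])
}

#' Simulate a genotype matrix under a demographic scenario
#'
#' Backward-in-time Kingman coalescent per unlinked locus, with lineages
#' coalescing within demes at rate \eqn{\binom{k}{2} / (2N(t))} per
#' generation and the merge events of the [scenario_spec()]. Microsatellite
#' loci mutate under the symmetric stepwise model at rate `mu` per
#' generation (length-coded alleles carry the repeat count, identity-coded
#' alleles a distinct integer per mutation, so homoplasy in length is not
#' homoplasy in identity); SNP loci carry a single mutation placed
#' uniformly on the genealogy, resampled until polymorphic in the sample
#' (RAD ascertainment).
#'
#' @param spec a [scenario_spec()].
#' @param marker `"ssr_length"`, `"ssr_id"`, or `"snp"`.
#' @param n_loci number of unlinked loci.
#' @param mu per-generation SSR mutation rate (ignored for SNPs).
#' @param seed optional RNG seed.
#' @return a [genotype_matrix()]; focal populations in region `"focal"`,
#'   the out-group population `OUT` in region `"outgroup"`.
#' @export
simulate_scenario <- function(spec, marker = c("ssr_length", "ssr_id", "snp"),
                              n_loci, mu = NULL, seed = NULL) {
  marker <- match.arg(marker)
  if (!is.null(seed)) set.seed(seed)
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (marker != "snp" && (is.null(mu) || mu < 0))
    stop("ssr markers need a mutation rate mu >= 0")
  P <- length(spec$sample_sizes)
  n_dip <- sum(spec$sample_sizes) + spec$outgroup_n
  a1 <- matrix(NA_integer_, n_dip, n_loci)
  a2 <- matrix(NA_integer_, n_dip, n_loci)
  for (j in seq_len(n_loci)) {
    tree <- simulate_genealogy(spec)
    al <- mutate_tree(tree, marker, mu)
    a1[, j] <- al[seq(1L, tree$n_tips, by = 2L)]
    a2[, j] <- al[seq(2L, tree$n_tips, by = 2L)]
  }
  if (marker != "snp") {
    # densify per locus (repeat counts / identities -> dense codes + labels)
    dense <- densify_alleles(a1, a2)
    labels <- if (marker == "ssr_length") dense$labels else NULL
    a1 <- dense$a1; a2 <- dense$a2
  } else labels <- NULL
  pops <- rep.int(c(names(spec$sample_sizes), "OUT"),
                  c(spec$sample_sizes, spec$outgroup_n))
  regions <- stats::setNames(c(rep("focal", P), "outgroup"),
                             c(names(spec$sample_sizes), "OUT"))
  genotype_matrix(a1, a2,
                  individuals = paste0(pops, "_", unlist(lapply(
                    c(spec$sample_sizes, spec$outgroup_n), seq_len))),
                  populations = pops,
                  loci = paste0("L", seq_len(n_loci)),
                  marker_kind = if (marker == "snp") "snp" else marker,
                  regions = regions, allele_labels = labels)
}

#' Mean pairwise coalescence time of a two-lineage sample
#'
#' Diagnostic used to validate the simulator: for a single constant-size
#' population the expected pairwise coalescence time is 2N generations.
#'
#' @param ne diploid size.
#' @param n_reps replicate loci.
#' @param seed RNG seed.
#' @return numeric vector of pairwise coalescence times.
#' @export
pairwise_tmrca <- function(ne, n_reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- scenario_spec("1", sample_sizes = c(B1 = 1L), outgroup_n = 1L,
                        t1 = 1e9, t2 = 1e9, tb1 = 1e9,
                        ne_br = ne, ne_sc = ne, ne_cur = ne)
  # with all events far in the future this is a single panmictic deme per
  # population; sample the two copies of one diploid in the focal deme
  vapply(seq_len(n_reps), function(i) {
    tree <- simulate_genealogy(spec)
    # coalescence time of tips 1 and 2 (the focal diploid's two copies)
    anc1 <- integer(0); v <- 1L
    while (v != 0L) { anc1 <- c(anc1, v); v <- tree$parent[v] }
    v <- 2L
    while (!(v %in% anc1)) v <- tree$parent[v]
    tree$time[v]
  }, 0)
}
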