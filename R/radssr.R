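#' Mine di-nucleotide SSR loci from catalog consensus sequences
#'
#' Scans each consensus for a perfect tandem repeat of a two-base motif with
#' distinct bases (homopolymers are never SSRs) repeated at least
#' `min_repeats` times, and keeps loci with data in strictly more than
#' `min_individuals` individuals. The longest qualifying run per locus is
#' reported.
#'
#' @param catalog named character vector of consensus sequences (ACGTN).
#' @param min_repeats minimum motif repeat count (>= 2).
#' @param min_individuals presence threshold; a locus present in exactly
#'   `min_individuals` individuals is excluded (strict inequality).
#' @param n_individuals named integer vector: individuals with data per
#'   locus. Defaults to `min_individuals + 1` for every locus (no presence
#'   information).
#' @return data.frame with columns `locus`, `consensus`, `motif`,
#'   `repeat_count`, `n_individuals`.
#' @export
find_dinucleotide_loci <- function(catalog, min_repeats = 5,
                                   min_individuals = 50,
                                   n_individuals = NULL) {
  if (min_repeats < 2) stop("min_repeats must be >= 2")
  if (length(catalog) == 0L)
    return(data.frame(locus = character(0), consensus = character(0),
                      motif = character(0), repeat_count = integer(0),
                      n_individuals = integer(0)))
  if (is.null(names(catalog)))
    names(catalog) <- paste0("locus_", seq_along(catalog))
  if (is.null(n_individuals))
    n_individuals <- stats::setNames(rep(min_individuals + 1L,
                                         length(catalog)), names(catalog))
  if (any(grepl("[^ACGTN]", toupper(catalog))))
    stop("consensus sequences may contain only A, C, G, T, N")
  bases <- c("A", "C", "G", "T")
  motifs <- c(t(outer(bases, bases, paste0)))
  motifs <- motifs[substr(motifs, 1, 1) != substr(motifs, 2, 2)]
  rows <- lapply(names(catalog), function(id) {
    s <- toupper(catalog[[id]])
    best_motif <- NA_character_; best_rep <- 0L
    for (m in motifs) {
      hits <- regmatches(s, gregexpr(paste0("(?:", m, ")+"), s))[[1]]
      if (length(hits)) {
        reps <- max(nchar(hits)) %/% 2L
        if (reps > best_rep) { best_rep <- reps; best_motif <- m }
      }
    }
    if (best_rep >= min_repeats &&
        n_individuals[[id]] > min_individuals)
      data.frame(locus = id, consensus = s, motif = best_motif,
                 repeat_count = best_rep, n_individuals = n_individuals[[id]],
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    data.frame(locus = character(0), consensus = character(0),
               motif = character(0), repeat_count = integer(0),
               n_individuals = integer(0))
  else out
}

#' Trim the read tails of a bundle set
#'
#' Removes the last `n_tail` bases of every sequence (the read tail carries
#' elevated sequencing error) and merges reads that become identical after
#' trimming, summing their counts.
#'
#' @param rb a [read_bundle_set()].
#' @param n_tail number of 3' bases to drop.
#' @return a trimmed `read_bundle_set`.
#' @export
trim_reads <- function(rb, n_tail = 7) {
  if (n_tail == 0L) return(rb)
  short <- nchar(rb$sequence) <= n_tail
  if (any(short))
    stop("read shorter than trim length: ", rb$sequence[which(short)[1]],
         " (individual ", rb$individual[which(short)[1]], ")")
  trimmed <- substr(rb$sequence, 1L, nchar(rb$sequence) - n_tail)
  agg <- stats::aggregate(rb$count,
                          by = list(individual = rb$individual,
                                    locus = rb$locus, sequence = trimmed),
                          FUN = sum)
  ord <- order(agg$individual, agg$locus, agg$sequence)
  agg <- agg[ord, ]
  read_bundle_set(agg$individual, agg$locus, agg$sequence, agg$x)
}

#' Call one SSR genotype from a trimmed read bundle
#'
#' Sequences supported by fewer than `min_allele_reads` identical reads are
#' discarded first; if the surviving reads total fewer than
#' `min_total_reads`, the call is missing. A single surviving sequence is a
#' homozygote; a second sequence is accepted as the other allele of a
#' heterozygote only when its count exceeds `het_fraction` of the bundle's
#' total (pre-filter) read count. With more than two qualifying sequences
#' the two highest-count sequences are taken (ties broken lexicographically)
#' and the call is flagged.
#'
#' @param sequences,counts parallel vectors: the distinct read sequences of
#'   one individual at one locus and their counts.
#' @param min_total_reads minimum surviving reads for a call.
#' @param min_allele_reads minimum identical reads supporting a sequence.
#' @param het_fraction minimum fraction of total reads for the second
#'   allele (strict inequality).
#' @return list with `alleles` (character vector of length 2, or `NULL` for
#'   missing), `support` (read counts of the called alleles), and `extra`
#'   (number of qualifying sequences beyond the two used).
#' @export
call_genotype <- function(sequences, counts, min_total_reads = 10,
                          min_allele_reads = 3, het_fraction = 0.10) {
  if (min_total_reads <= 0 || min_allele_reads <= 0)
    stop("thresholds must be positive")
  missing_call <- list(alleles = NULL, support = integer(0), extra = 0L)
  if (length(sequences) == 0L) return(missing_call)
  total <- sum(counts)
  keep <- counts >= min_allele_reads
  if (!any(keep) || sum(counts[keep]) < min_total_reads) return(missing_call)
  sequences <- sequences[keep]; counts <- counts[keep]
  ord <- order(-counts, sequences)
  sequences <- sequences[ord]; counts <- counts[ord]
  extra <- max(0L, length(sequences) - 2L)
  if (length(sequences) >= 2L && counts[2] > het_fraction * total)
    list(alleles = sequences[1:2], support = counts[1:2], extra = extra)
  else
    list(alleles = rep(sequences[1], 2L), support = counts[1],
         extra = if (length(sequences) > 1L) length(sequences) - 1L else 0L)
}

#' Call integer-coded SSR genotypes for a whole bundle set
#'
#' Applies [call_genotype()] to every (individual, locus) bundle and assigns
#' per-locus integer allele codes in order of first appearance across
#' individuals (individuals taken in lexicographic ID order, so the coding
#' does not depend on the row order of the input file). The codes are
#' arbitrary identities -- two alleles of equal length but different sequence
#' get distinct codes -- hence the result carries `marker_kind = "ssr_id"`.
#'
#' @inheritParams call_genotype
#' @param rb a trimmed [read_bundle_set()].
#' @param populations optional named vector individual -> population.
#' @return a [genotype_matrix()] with attribute `allele_sequences` (list per
#'   locus: sequence behind each integer code) and `n_multi_candidate`
#'   (count of calls where more than two sequences qualified).
#' @export
call_genotypes <- function(rb, min_total_reads = 10, min_allele_reads = 3,
                           het_fraction = 0.10, populations = NULL) {
  inds <- sort(unique(rb$individual))
  loci <- sort(unique(rb$locus))
  n <- length(inds); L <- length(loci)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  seq_codes <- vector("list", L)
  n_multi <- 0L
  idx <- split(seq_len(nrow(rb)), list(factor(rb$individual, inds),
                                       factor(rb$locus, loci)), drop = FALSE)
  for (j in seq_len(L)) {
    codes <- character(0)
    for (i in seq_len(n)) {
      rows <- idx[[paste(inds[i], loci[j], sep = ".")]]
      if (!length(rows)) next
      cl <- call_genotype(rb$sequence[rows], rb$count[rows],
                          min_total_reads, min_allele_reads, het_fraction)
      n_multi <- n_multi + (cl$extra > 0L)
      if (is.null(cl$alleles)) next
      for (s in unique(cl$alleles))
        if (!s %in% codes) codes <- c(codes, s)
      a1[i, j] <- match(cl$alleles[1], codes)
      a2[i, j] <- match(cl$alleles[2], codes)
    }
    seq_codes[[j]] <- codes
  }
  pops <- if (is.null(populations)) rep("pop_1", n) else
    as.character(populations[inds])
  gm <- genotype_matrix(a1, a2, inds, pops, loci, marker_kind = "ssr_id")
  attr(gm, "allele_sequences") <- stats::setNames(seq_codes, loci)
  attr(gm, "n_multi_candidate") <- n_multi
  gm
}

#' Flag loci with implausibly many unique genotypes
#'
#' A locus where the number of distinct diploid genotypes exceeds
#' `max_unique` most likely accumulates sequencing errors rather than real
#' alleles and is dropped. Loci with no data at all are dropped with their
#' own reason code.
#'
#' @param gm a [genotype_matrix()].
#' @param max_unique keep a locus only if its distinct non-missing diploid
#'   genotypes number `<= max_unique`.
#' @param unit count `"genotypes"` (distinct unordered diploid calls) or
#'   `"alleles"` (distinct alleles).
#' @return data.frame with columns `locus`, `n_unique`, `keep`, `reason`.
#' @export
filter_loci <- function(gm, max_unique = 40, unit = c("genotypes", "alleles")) {
  unit <- match.arg(unit)
  out <- data.frame(locus = gm$loci, n_unique = NA_integer_,
                    keep = FALSE, reason = "", stringsAsFactors = FALSE)
  for (j in seq_along(gm$loci)) {
    ok <- !is.na(gm$a1[, j])
    if (!any(ok)) {
      out$n_unique[j] <- 0L; out$reason[j] <- "no_data"
      next
    }
    nu <- if (unit == "genotypes")
      length(unique(paste(gm$a1[ok, j], gm$a2[ok, j])))
    else length(unique(c(gm$a1[ok, j], gm$a2[ok, j])))
    out$n_unique[j] <- nu
    if (nu > max_unique) out$reason[j] <- "too_many_genotypes"
    else out$keep[j] <- TRUE
  }
  out
}

#' Detect putative clones (identical multilocus genotypes)
#'
#' Two individuals are clonemates when their allele pairs agree at every
#' locus where both have data and they share at least `min_shared_loci` such
#' loci. Groups are the connected components of this relation; the first
#' member (input order) is retained as representative, the rest flagged for
#' removal.
#'
#' @param gm a [genotype_matrix()].
#' @param min_shared_loci minimum jointly genotyped loci for a comparison.
#' @return list with `groups` (list of individual-ID vectors, one per clone
#'   group of size >= 2), `flagged` (IDs to drop), and `keep` (IDs
#'   retained).
#' @export
detect_clones <- function(gm, min_shared_loci = 1) {
  n <- n_ind(gm); L <- n_loci(gm)
  if (min_shared_loci > L)
    stop("min_shared_loci exceeds the number of loci")
  # encode each unordered genotype as one integer for fast comparison
  kmax <- max(c(gm$a1, gm$a2), 1L, na.rm = TRUE) + 1L
  code <- gm$a1 * kmax + gm$a2  # NA propagates for missing calls
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    rows <- (i + 1L):n
    eq <- sweep(code[rows, , drop = FALSE], 2L, code[i, ], "==")
    shared <- rowSums(!is.na(eq))
    same <- shared >= min_shared_loci & shared == rowSums(eq, na.rm = TRUE)
    for (r in rows[same]) {
      ri <- find(i); rr <- find(r)
      if (ri != rr) parent[max(ri, rr)] <- min(ri, rr)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  groups <- split(gm$individuals, root)
  groups <- unname(groups[lengths(groups) >= 2L])
  flagged <- unlist(lapply(groups, `[`, -1L), use.names = FALSE)
  if (is.null(flagged)) flagged <- character(0)
  list(groups = groups, flagged = flagged,
       keep = setdiff(gm$individuals, flagged))
}
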