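#' Diploid genotype matrix with population and region structure
#'
#' The central data container of the package: unordered diploid allele calls
#' for a set of individuals at a set of loci, together with the assignment of
#' individuals to populations and populations to regions. Allele calls are
#' dense positive integer codes; `NA` in both slots marks a missing genotype.
#' Heterozygotes are stored order-independently (the smaller code first), so
#' A/B and B/A compare equal.
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele codes; `NA`
#'   for missing calls. A call is missing iff both slots are `NA`.
#' @param individuals character vector of individual IDs (rownames).
#' @param populations character vector, one population ID per individual.
#' @param loci character vector of locus IDs (colnames).
#' @param marker_kind per-locus marker class: `"ssr_length"` (alleles are
#'   fragment lengths / repeat counts, length statistics meaningful),
#'   `"ssr_id"` (alleles are arbitrary integer identities, length statistics
#'   forbidden), or `"snp"` (at most two alleles per locus). Recycled if
#'   length 1.
#' @param regions named character vector mapping population ID to region
#'   label; populations not named default to region `"all"`.
#' @param allele_labels optional list (one entry per locus) of character
#'   vectors giving the original allele label for each dense code.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, individuals, populations, loci,
                            marker_kind = "ssr_length", regions = NULL,
                            allele_labels = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(individuals); L <- length(loci)
  stopifnot(nrow(a1) == n, ncol(a1) == L, dim(a1) == dim(a2),
            length(populations) == n)
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing genotype: a1 and a2 must be NA together")
  if (any(a1[!is.na(a1)] < 1L) || any(a2[!is.na(a2)] < 1L))
    stop("allele codes must be positive integers (dense coding)")
  # canonical order: unordered pairs stored with the smaller code first
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  marker_kind <- rep_len(as.character(marker_kind), L)
  bad <- setdiff(unique(marker_kind), c("ssr_length", "ssr_id", "snp"))
  if (length(bad)) stop("unknown marker_kind: ", paste(bad, collapse = ", "))
  pops <- unique(as.character(populations))
  if (is.null(regions)) regions <- stats::setNames(rep("all", length(pops)), pops)
  missing_reg <- setdiff(pops, names(regions))
  if (length(missing_reg))
    regions <- c(regions, stats::setNames(rep("all", length(missing_reg)), missing_reg))
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  gm <- structure(list(
    a1 = a1, a2 = a2,
    individuals = as.character(individuals),
    populations = as.character(populations),
    loci = as.character(loci),
    marker_kind = marker_kind,
    regions = regions[pops],
    allele_labels = allele_labels
  ), class = "genotype_matrix")
  for (j in which(marker_kind == "snp")) {
    k <- n_alleles_locus(gm, j)
    if (k > 2L) stop("snp locus ", loci[j], " carries ", k, " alleles (max 2)")
  }
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individuals), "individuals x",
      length(x$loci), "loci;",
      length(unique(x$populations)), "populations in",
      length(unique(x$regions)), "region(s)\n")
  cat("marker kinds:", paste(sprintf("%s=%d", names(table(x$marker_kind)),
                                     table(x$marker_kind)), collapse = ", "), "\n")
  invisible(x)
}

#' Dimensions of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return number of individuals / loci.
#' @export
n_ind <- function(gm) length(gm$individuals)

#' @rdname n_ind
#' @export
n_loci <- function(gm) length(gm$loci)

n_alleles_locus <- function(gm, j) {
  length(unique(c(gm$a1[, j], gm$a2[, j])[!is.na(c(gm$a1[, j], gm$a2[, j]))]))
}

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param gm a [genotype_matrix()].
#' @param ind,loci index vectors (logical, integer, or character IDs);
#'   `NULL` keeps everything.
#' @param drop_unused_regions drop region entries for populations no longer
#'   present (default `TRUE`).
#' @return a `genotype_matrix`.
#' @export
gm_subset <- function(gm, ind = NULL, loci = NULL, drop_unused_regions = TRUE) {
  ii <- seq_along(gm$individuals)
  if (!is.null(ind)) {
    ii <- if (is.character(ind)) match(ind, gm$individuals) else ii[ind]
    if (anyNA(ii)) stop("unknown individual in subset")
  }
  jj <- seq_along(gm$loci)
  if (!is.null(loci)) {
    jj <- if (is.character(loci)) match(loci, gm$loci) else jj[loci]
    if (anyNA(jj)) stop("unknown locus in subset")
  }
  regions <- gm$regions
  pops <- unique(gm$populations[ii])
  if (drop_unused_regions) regions <- regions[names(regions) %in% pops]
  genotype_matrix(gm$a1[ii, jj, drop = FALSE], gm$a2[ii, jj, drop = FALSE],
                  gm$individuals[ii], gm$populations[ii], gm$loci[jj],
                  gm$marker_kind[jj], regions,
                  if (!is.null(gm$allele_labels)) gm$allele_labels[jj])
}

#' Keep only the individuals of the named populations
#' @param gm a [genotype_matrix()].
#' @param pops character vector of population IDs.
#' @return a `genotype_matrix`.
#' @export
gm_keep_pops <- function(gm, pops) {
  gm_subset(gm, ind = gm$populations %in% pops)
}

#' Per-population allele counts at every locus
#'
#' Counts gene copies (two per genotyped individual, missing calls excluded).
#'
#' @param gm a [genotype_matrix()].
#' @param pops populations to tabulate (default: all, in order of first
#'   appearance).
#' @return a list with one entry per locus: an integer matrix
#'   (populations x alleles) of gene-copy counts; allele columns named by
#'   dense code.
#' @export
allele_counts <- function(gm, pops = NULL) {
  if (is.null(pops)) pops <- unique(gm$populations)
  popf <- factor(gm$populations, levels = pops)
  keep <- !is.na(popf)
  out <- vector("list", length(gm$loci))
  names(out) <- gm$loci
  for (j in seq_along(gm$loci)) {
    al <- c(gm$a1[keep, j], gm$a2[keep, j])
    pp <- factor(rep(popf[keep], 2L), levels = pops)
    ok <- !is.na(al)
    codes <- sort(unique(al[ok]))
    tab <- table(pp[ok], factor(al[ok], levels = codes))
    m <- matrix(as.integer(tab), nrow = length(pops),
                dimnames = list(pops, as.character(codes)))
    out[[j]] <- m
  }
  out
}

#' Pooled allele counts at one locus
#' @keywords internal
pooled_counts_locus <- function(gm, j, ind = NULL) {
  if (is.null(ind)) ind <- seq_along(gm$individuals)
  al <- c(gm$a1[ind, j], gm$a2[ind, j])
  al <- al[!is.na(al)]
  if (!length(al)) return(integer(0))
  tb <- tabulate(al)
  nz <- which(tb > 0L)
  stats::setNames(tb[nz], as.character(nz))
}

#' Identity of two genotype matrices up to storage details
#' @keywords internal
gm_equal <- function(x, y) {
  isTRUE(all.equal(x$individuals, y$individuals)) &&
    isTRUE(all.equal(x$populations, y$populations)) &&
    isTRUE(all.equal(x$loci, y$loci)) &&
    identical(unname(x$a1), unname(y$a1)) &&
    identical(unname(x$a2), unname(y$a2))
}
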