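#' Read a genotype table
#'
#' Dispatches on `format`. All readers remap allele codes to dense positive
#' integers per locus (in increasing order of the original label) and keep the
#' original labels in `allele_labels`, so that length-based statistics for
#' `ssr_length` loci can recover fragment lengths via [allele_sizes()].
#'
#' Supported dialects:
#' \describe{
#'   \item{genepop}{Title line, one locus name per line (or a single
#'     comma-separated line), populations separated by `Pop` lines.
#'     Genotypes are 4-character (2-digit alleles) or 6-character (3-digit)
#'     tokens, auto-detected per file; `00`/`000` is the missing allele.
#'     Sample names of the form `"<population> <individual>"` (as written by
#'     [write_genotypes()]) are split back into population and individual
#'     IDs; otherwise populations are named `pop_1`, `pop_2`, ...}
#'   \item{vcf}{Minimal VCF 4.2 with a GT FORMAT field; biallelic records
#'     only. Parsed with \pkg{vcfR}. VCF carries no population structure:
#'     pass `populations` to assign it, otherwise all samples land in
#'     `pop_1`.}
#'   \item{tsv}{Tab-separated table with columns `individual`, `population`,
#'     `region`, then one column per locus holding `a1/a2` calls (`NA` for
#'     missing). An optional leading `# marker_kind:` comment line carries
#'     per-locus marker kinds.}
#' }
#'
#' @param path file path.
#' @param format one of `"genepop"`, `"vcf"`, `"tsv"`.
#' @param marker_kind default marker kind for formats that do not carry one
#'   (genepop, vcf).
#' @param populations optional character vector assigning each sample to a
#'   population (vcf only).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("genepop", "vcf", "tsv"),
                           marker_kind = "ssr_length", populations = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         genepop = read_genepop(path, marker_kind),
         vcf = read_vcf_gt(path, populations),
         tsv = read_genotypes_tsv(path, marker_kind))
}

#' Write a genotype table
#'
#' Inverse of [read_genotypes()]; output is byte-stable for fixed input and
#' re-readable with loss only of fields the dialect cannot carry (genepop
#' drops regions and marker kinds; VCF drops populations and regions).
#' SSR loci cannot be written to VCF.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param format one of `"genepop"`, `"vcf"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("genepop", "vcf", "tsv")) {
  format <- match.arg(format)
  if (n_ind(gm) == 0L || n_loci(gm) == 0L) stop("empty genotype matrix")
  if (format == "vcf" && any(gm$marker_kind != "snp"))
    stop("unsupported format: ssr loci cannot be written as VCF")
  switch(format,
         genepop = write_genepop(gm, path),
         vcf = write_vcf_gt(gm, path),
         tsv = write_genotypes_tsv(gm, path))
  invisible(path)
}

#' Original allele sizes at a locus
#'
#' For `ssr_length` loci returns the fragment length / repeat count behind
#' each dense allele code (the original file label when the matrix was read
#' from disk, the code itself otherwise). Refuses `ssr_id` loci, whose
#' integer codes are arbitrary identities.
#'
#' @param gm a [genotype_matrix()].
#' @param j locus index or ID.
#' @return numeric vector indexed by dense allele code.
#' @export
allele_sizes <- function(gm, j) {
  if (is.character(j)) j <- match(j, gm$loci)
  if (gm$marker_kind[j] == "ssr_id")
    stop("allele codes of ssr_id loci are identities, not lengths")
  k <- max(c(gm$a1[, j], gm$a2[, j]), 0L, na.rm = TRUE)
  if (!is.null(gm$allele_labels) && !is.null(gm$allele_labels[[j]])) {
    sz <- suppressWarnings(as.numeric(gm$allele_labels[[j]]))
    if (anyNA(sz)) stop("non-numeric allele labels at locus ", gm$loci[j])
    return(sz)
  }
  as.numeric(seq_len(max(k, 1L)))
}

## ---- genepop ----

read_genepop <- function(path, marker_kind = "ssr_length") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("genepop parse error: file too short")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("genepop parse error: no 'Pop' separator")
  header <- lines[2:(first_pop - 1)]
  loci <- if (length(header) == 1L && grepl(",", header[1])) {
    trimws(strsplit(header[1], ",")[[1]])
  } else trimws(header)
  L <- length(loci)
  pop_idx <- cumsum(is_pop)
  inds <- character(0); pops <- character(0); rows <- list()
  width <- NA_integer_
  for (i in seq(first_pop, length(lines))) {
    if (is_pop[i]) next
    ln <- lines[i]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L)
      stop("genepop parse error at line ", i, ": missing ',' separator")
    name <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(toks) != L)
      stop("genepop parse error at line ", i, ": expected ", L,
           " genotypes, found ", length(toks))
    w <- unique(nchar(toks))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop("genepop parse error at line ", i,
           ": genotype width must be 4 or 6 characters")
    if (is.na(width)) width <- w
    if (w != width)
      stop("genepop parse error at line ", i, ": inconsistent allele width")
    if (grepl("\\D", paste(toks, collapse = "")))
      stop("genepop parse error at line ", i, ": non-digit in genotype")
    if (grepl(" ", name)) {
      sp <- regmatches(name, regexpr(" ", name))
      pop <- sub(" .*$", "", name)
      ind <- sub("^[^ ]+ ", "", name)
    } else {
      pop <- paste0("pop_", pop_idx[i])
      ind <- name
    }
    inds <- c(inds, ind); pops <- c(pops, pop)
    rows[[length(rows) + 1L]] <- toks
  }
  half <- width %/% 2L
  n <- length(inds)
  raw1 <- matrix(NA_integer_, n, L); raw2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    g <- rows[[i]]
    a <- as.integer(substr(g, 1L, half))
    b <- as.integer(substr(g, half + 1L, width))
    miss <- a == 0L | b == 0L
    a[miss] <- NA_integer_; b[miss] <- NA_integer_
    raw1[i, ] <- a; raw2[i, ] <- b
  }
  dense <- densify_alleles(raw1, raw2)
  genotype_matrix(dense$a1, dense$a2, inds, pops, loci,
                  marker_kind = marker_kind,
                  allele_labels = dense$labels)
}

write_genepop <- function(gm, path) {
  labels <- lapply(seq_along(gm$loci), function(j) {
    lab <- if (!is.null(gm$allele_labels) && !is.null(gm$allele_labels[[j]]))
      gm$allele_labels[[j]]
    else as.character(seq_len(max(c(gm$a1[, j], gm$a2[, j], 1L), na.rm = TRUE)))
    if (any(suppressWarnings(as.integer(lab)) > 999L, na.rm = TRUE))
      stop("allele label exceeds 3-digit genepop coding at locus ", gm$loci[j])
    lab
  })
  fmt <- function(code, j) {
    ifelse(is.na(code), "000",
           formatC(as.integer(labels[[j]][code]), width = 3, flag = "0"))
  }
  out <- c("fragdiv genotype export", gm$loci)
  pops <- unique(gm$populations)
  for (p in pops) {
    out <- c(out, "Pop")
    for (i in which(gm$populations == p)) {
      g <- vapply(seq_along(gm$loci), function(j)
        paste0(fmt(gm$a1[i, j], j), fmt(gm$a2[i, j], j)), "")
      out <- c(out, paste0(p, " ", gm$individuals[i], " ,  ",
                           paste(g, collapse = " ")))
    }
  }
  writeLines(out, path)
}

## ---- TSV genotype table ----

write_genotypes_tsv <- function(gm, path) {
  kinds <- paste(sprintf("%s=%s", gm$loci, gm$marker_kind), collapse = "\t")
  call_str <- matrix("NA", n_ind(gm), n_loci(gm))
  has <- !is.na(gm$a1)
  call_str[has] <- paste0(gm$a1[has], "/", gm$a2[has])
  df <- data.frame(individual = gm$individuals,
                   population = gm$populations,
                   region = unname(gm$regions[gm$populations]),
                   call_str, check.names = FALSE)
  names(df)[-(1:3)] <- gm$loci
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# marker_kind:\t", kinds), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_genotypes_tsv <- function(path, marker_kind = "ssr_length") {
  first <- readLines(path, n = 1L)
  kinds <- NULL
  if (startsWith(first, "# marker_kind:")) {
    toks <- strsplit(sub("^# marker_kind:\\t?", "", first), "\t")[[1]]
    kv <- strsplit(toks, "=")
    kinds <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  need <- c("individual", "population", "region")
  if (!all(need %in% names(df)[1:3]))
    stop("tsv parse error: first columns must be individual, population, region")
  loci <- names(df)[-(1:3)]
  n <- nrow(df); L <- length(loci)
  raw1 <- matrix(NA_integer_, n, L); raw2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    v <- df[[j + 3L]]
    ok <- !is.na(v) & v != "NA" & v != ""
    if (any(ok)) {
      parts <- strsplit(v[ok], "/", fixed = TRUE)
      if (any(lengths(parts) != 2L))
        stop("tsv parse error: malformed call in locus ", loci[j])
      raw1[ok, j] <- as.integer(vapply(parts, `[`, "", 1L))
      raw2[ok, j] <- as.integer(vapply(parts, `[`, "", 2L))
    }
  }
  mk <- if (!is.null(kinds)) unname(kinds[loci]) else rep(marker_kind, L)
  regions <- stats::setNames(df$region, df$population)
  regions <- regions[!duplicated(names(regions))]
  dense <- densify_alleles(raw1, raw2)
  genotype_matrix(dense$a1, dense$a2, df$individual, df$population, loci,
                  marker_kind = mk, regions = regions,
                  allele_labels = dense$labels)
}

## ---- VCF (GT only) ----

read_vcf_gt <- function(path, populations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  fix <- v@fix  # keep matrix form even for a single record
  loci <- fix[, "ID"]
  loci[is.na(loci) | loci == "."] <-
    paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(loci) | loci == "."]
  inds <- colnames(gt)
  n <- length(inds); L <- nrow(gt)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    g <- gt[j, ]
    parts <- strsplit(g, "[/|]")
    ok <- !is.na(g) & lengths(parts) == 2L &
      !vapply(parts, function(p) any(p == "."), TRUE)
    a1[ok, j] <- as.integer(vapply(parts[ok], `[`, "", 1L)) + 1L
    a2[ok, j] <- as.integer(vapply(parts[ok], `[`, "", 2L)) + 1L
  }
  labels <- lapply(seq_len(L), function(j) c(fix[j, "REF"], fix[j, "ALT"]))
  if (is.null(populations)) populations <- rep("pop_1", n)
  genotype_matrix(a1, a2, inds, populations, unname(loci),
                  marker_kind = "snp", allele_labels = labels)
}

write_vcf_gt <- function(gm, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$individuals), collapse = "\t"))
  recs <- vapply(seq_along(gm$loci), function(j) {
    lab <- if (!is.null(gm$allele_labels) && !is.null(gm$allele_labels[[j]]))
      gm$allele_labels[[j]] else c("A", "C")
    ref <- lab[1]; alt <- if (length(lab) > 1L) lab[2] else "."
    gts <- ifelse(is.na(gm$a1[, j]), "./.",
                  paste0(gm$a1[, j] - 1L, "/", gm$a2[, j] - 1L))
    paste(c(gm$loci[j], j, gm$loci[j], ref, alt, ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, recs), path)
}

## ---- allele densification ----

# Remap raw integer allele codes to dense 1..k per locus (increasing original
# order); returns the original labels per locus. Bijective per locus.
densify_alleles <- function(raw1, raw2) {
  L <- ncol(raw1)
  a1 <- raw1; a2 <- raw2
  labels <- vector("list", L)
  for (j in seq_len(L)) {
    codes <- sort(unique(c(raw1[, j], raw2[, j])))
    codes <- codes[!is.na(codes)]
    if (length(codes)) {
      a1[, j] <- match(raw1[, j], codes)
      a2[, j] <- match(raw2[, j], codes)
    }
    labels[[j]] <- as.character(codes)
  }
  list(a1 = a1, a2 = a2, labels = labels)
}
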