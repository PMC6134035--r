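#' Read per-individual, per-locus read bundles
#'
#' A read bundle is the set of distinct (sequence, count) pairs observed for
#' one individual at one catalog locus; bundles are the input to the RAD-SSR
#' genotype caller. The on-disk form is a TSV with columns `individual`,
#' `locus`, `sequence`, `count`.
#'
#' @param path TSV file path.
#' @return a `read_bundle_set`: a data.frame with columns `individual`,
#'   `locus`, `sequence` (uppercase ACGTN), `count` (integer >= 1).
#' @export
read_read_bundles <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("individual", "locus", "sequence", "count")
  if (!identical(names(df)[seq_along(need)], need))
    stop("read-bundle parse error: columns must be ",
         paste(need, collapse = ", "))
  df$count <- as.integer(df$count)
  read_bundle_set(df$individual, df$locus, df$sequence, df$count)
}

#' Construct a read-bundle set
#'
#' @param individual,locus,sequence,count parallel vectors, one row per
#'   distinct sequence observed in one individual at one locus.
#' @return a `read_bundle_set` data.frame.
#' @export
read_bundle_set <- function(individual, locus, sequence, count) {
  sequence <- toupper(as.character(sequence))
  count <- as.integer(count)
  if (length(count) && (anyNA(count) || any(count < 1L)))
    stop("read counts must be integers >= 1")
  if (any(grepl("[^ACGTN]", sequence)))
    stop("read sequences may contain only A, C, G, T, N")
  key <- paste(individual, locus, sequence, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (individual, locus, sequence) rows in read bundles")
  structure(data.frame(individual = as.character(individual),
                       locus = as.character(locus),
                       sequence = sequence, count = count,
                       stringsAsFactors = FALSE),
            class = c("read_bundle_set", "data.frame"))
}

#' Write a read-bundle set as TSV
#' @param rb a `read_bundle_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_read_bundles <- function(rb, path) {
  utils::write.table(as.data.frame(rb), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Population metadata table
#'
#' Coordinates, census-size category and region for each population. Census
#' categories are the four order-of-magnitude bins used in the field survey.
#'
#' @param population character vector of population IDs.
#' @param latitude,longitude decimal degrees (WGS84; west longitude
#'   negative).
#' @param census_category one of `"1-10"`, `"10-100"`, `"100-1000"`,
#'   `"1000-10000"`.
#' @param region region label per population.
#' @param census_count optional exact census count (NA when only the
#'   category is known).
#' @return a `population_meta` data.frame.
#' @export
population_meta <- function(population, latitude, longitude, census_category,
                            region, census_count = NA_real_) {
  cats <- c("1-10", "10-100", "100-1000", "1000-10000")
  census_category <- as.character(census_category)
  if (!all(census_category %in% cats))
    stop("census_category must be one of ", paste(cats, collapse = ", "))
  latitude <- as.numeric(latitude); longitude <- as.numeric(longitude)
  if (any(!is.finite(latitude)) || any(!is.finite(longitude)))
    stop("latitude/longitude must be finite")
  if (any(abs(latitude) > 90)) stop("latitude out of range [-90, 90]")
  structure(data.frame(population = as.character(population),
                       latitude = latitude, longitude = longitude,
                       census_category = census_category,
                       census_count = as.numeric(census_count),
                       region = as.character(region),
                       stringsAsFactors = FALSE),
            class = c("population_meta", "data.frame"))
}

#' @rdname population_meta
#' @param path TSV path.
#' @export
read_population_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  population_meta(df$population, df$latitude, df$longitude,
                  df$census_category, df$region,
                  if ("census_count" %in% names(df)) df$census_count else NA)
}

#' @rdname population_meta
#' @param meta a `population_meta` table.
#' @export
write_population_meta <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Geometric midpoint of a census category
#'
#' Used when regressing effective size on census size: exact counts are used
#' where recorded, otherwise the geometric midpoint of the category bounds.
#'
#' @param meta a [population_meta()] table.
#' @return numeric vector of census size estimates, one per population.
#' @export
census_midpoint <- function(meta) {
  bounds <- list("1-10" = c(1, 10), "10-100" = c(10, 100),
                 "100-1000" = c(100, 1000), "1000-10000" = c(1000, 10000))
  mid <- vapply(meta$census_category,
                function(cc) sqrt(prod(bounds[[cc]])), 0)
  ifelse(is.finite(meta$census_count) & meta$census_count > 0,
         meta$census_count, mid)
}
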