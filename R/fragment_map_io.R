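FRAGMENT_MAP_COLUMNS <- c(
  "fragment_id", "fragment_length", "fragment_start", "fragment_end",
  "orientation", "chrom_id", "chrom_start", "chrom_end"
)

#' Write a fragment map to a tab-separated file
#'
#' Serializes the map as 8 tab-separated columns per line, in the column
#' order of [fragment_map_records()], with no header. The map is validated
#' first: per-chromosome ordering, disjointness and length consistency.
#'
#' @param records fragment map data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_fragment_map <- function(records, path) {
  map <- as.data.frame(records, stringsAsFactors = FALSE)
  validate_fragment_map(map)
  utils::write.table(
    map[, FRAGMENT_MAP_COLUMNS, drop = FALSE], file = path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a fragment map from a tab-separated file
#'
#' @param path path to a map written by [write_fragment_map()].
#' @return A validated fragment map data frame.
#' @export
read_fragment_map <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("fragment map '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(empty_fragment_map())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 8L)) {
    i <- which(nfield != 8L)[1L]
    stop(sprintf("'%s' line %d: expected 8 tab-separated columns, found %d",
                 path, i, nfield[i]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 8L, byrow = TRUE)
  ints <- suppressWarnings(apply(m[, c(2L, 3L, 4L, 7L, 8L), drop = FALSE], 2L,
                                 as.integer))
  ints <- matrix(ints, ncol = 5L)
  if (anyNA(ints)) {
    i <- which(rowSums(is.na(ints)) > 0L)[1L]
    stop(sprintf("'%s' line %d: non-integer coordinate", path, i),
         call. = FALSE)
  }
  fragment_map_records(
    fragment_id = m[, 1L],
    fragment_length = ints[, 1L],
    fragment_start = ints[, 2L],
    fragment_end = ints[, 3L],
    orientation = m[, 5L],
    chrom_id = m[, 6L],
    chrom_start = ints[, 4L],
    chrom_end = ints[, 5L]
  )
}

#' Export a fragment map as a BED6 genome-browser track
#'
#' Writes one BED6 line per placed fragment (chromosome, interval, fragment
#' id, score 0, strand). Gap records are not fragments and are omitted.
#'
#' @param records fragment map data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
map_to_bed_track <- function(records, path) {
  map <- as.data.frame(records, stringsAsFactors = FALSE)
  validate_fragment_map(map)
  map <- map[map$fragment_id != "GAP", , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   map$chrom_id, map$chrom_start, map$chrom_end,
                   map$fragment_id, map$orientation)
  writeLines(lines, path)
  invisible(path)
}
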