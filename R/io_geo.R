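#' Read a dominant marker table
#'
#' Reads a delimited text file of band phenotypes (individuals in rows, loci
#' in columns). The first row holds locus identifiers, the first column
#' individual identifiers. Cells must be 0 (band absent / null phenotype),
#' 1 (band present) or the missing code.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param missing_code string used for missing phenotypes (default `"NA"`).
#' @param sep field separator; `"\t"` by default, use `","` for CSV.
#' @return A `marker_matrix`: an integer matrix with values in
#'   \{0, 1, NA\}, individual ids as rownames and locus ids as colnames.
#' @export
read_marker_table <- function(path, missing_code = "NA", sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", na.strings = character(0))
  m <- as.matrix(raw)
  marker_matrix(m, individual_ids = rownames(raw), locus_ids = colnames(raw),
                missing_code = missing_code)
}

#' Construct and validate a marker matrix
#'
#' @param values matrix (character or numeric) of band phenotypes.
#' @param individual_ids,locus_ids identifiers; default taken from dimnames.
#' @param missing_code string treated as missing when `values` is character.
#' @return validated integer matrix of class `marker_matrix`.
#' @export
marker_matrix <- function(values, individual_ids = rownames(values),
                          locus_ids = colnames(values), missing_code = "NA") {
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("marker matrix needs at least 1 individual and 1 locus")
  if (is.null(individual_ids) || is.null(locus_ids))
    stop("individual and locus ids are required")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ids: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  if (is.character(values)) {
    v <- trimws(values)
    v[v == missing_code] <- NA_character_
    bad <- !is.na(v) & !(v %in% c("0", "1"))
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "non-binary phenotype %s at individual '%s', locus '%s' (only 0/1/%s allowed)",
        dQuote(values[idx[1L], idx[2L]]), individual_ids[idx[1L]],
        locus_ids[idx[2L]], missing_code))
    }
    x <- matrix(as.integer(v), nrow(values), ncol(values))
  } else {
    bad <- !is.na(values) & !(values %in% c(0, 1))
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("non-binary phenotype %s at individual '%s', locus '%s'",
                   values[idx[1L], idx[2L]], individual_ids[idx[1L]],
                   locus_ids[idx[2L]]))
    }
    x <- matrix(as.integer(values), nrow(values), ncol(values))
  }
  dimnames(x) <- list(individual_ids, locus_ids)
  class(x) <- c("marker_matrix", class(x))
  x
}

#' Write a marker table
#'
#' @param x a `marker_matrix`.
#' @param path output file.
#' @param missing_code string written for missing cells.
#' @param sep field separator.
#' @param comment optional character vector of `#`-prefixed header lines.
#' @export
write_marker_table <- function(x, path, missing_code = "NA", sep = "\t",
                               comment = NULL) {
  m <- matrix(as.character(unclass(x)), nrow(x), ncol(x))
  m[is.na(m)] <- missing_code
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("id", colnames(x)), collapse = sep), con)
  utils::write.table(cbind(rownames(x), m), con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample table
#'
#' Expected columns: `id`, `pop`, and either `lat`/`lon` in decimal degrees
#' or pre-projected planar `x_m`/`y_m` in metres.
#'
#' @param path TSV file.
#' @param sep field separator.
#' @return data.frame of class `sample_table`.
#' @export
read_sample_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  sample_table(df)
}

#' Construct and validate a sample table
#'
#' @param df data.frame with columns `id`, `pop` and coordinates
#'   (`lat`/`lon` degrees and/or `x_m`/`y_m` metres).
#' @return validated data.frame of class `sample_table`.
#' @export
sample_table <- function(df) {
  if (!all(c("id", "pop") %in% names(df)))
    stop("sample table needs 'id' and 'pop' columns")
  df$id <- as.character(df$id)
  df$pop <- as.character(df$pop)
  if (anyDuplicated(df$id))
    stop("duplicate sample ids")
  if (any(!nzchar(df$pop)) || anyNA(df$pop))
    stop("population labels must be non-empty")
  has_geo <- all(c("lat", "lon") %in% names(df))
  has_planar <- all(c("x_m", "y_m") %in% names(df))
  if (has_geo && !all(is.finite(df$lat) & is.finite(df$lon)))
    stop("non-finite lat/lon")
  if (has_planar && !all(is.finite(df$x_m) & is.finite(df$y_m)))
    stop("non-finite planar coordinates")
  class(df) <- unique(c("sample_table", class(df)))
  df
}

# Spherical transverse Mercator about (lat0, lon0); x east, y north, metres.
# Scale error ~ x^2/(2R^2): < 0.02% within 100 km of the central meridian.
.tmerc <- function(lat, lon, lat0, lon0, R = 6371008.8) {
  phi <- lat * pi / 180
  dl <- (lon - lon0) * pi / 180
  B <- cos(phi) * sin(dl)
  x <- R / 2 * log((1 + B) / (1 - B))
  y <- R * (atan2(tan(phi), cos(dl)) - lat0 * pi / 180)
  cbind(x_m = x, y_m = y)
}

#' Project geographic coordinates to planar metres
#'
#' Applies a spherical transverse-Mercator projection centred on the sample
#' centroid, so relative distances are preserved to well under 0.1% over
#' extents of ~100 km. Rows that already carry `x_m`/`y_m` pass through
#' unchanged when `keep_planar = TRUE`.
#'
#' @param st a `sample_table` with `lat`/`lon` in decimal degrees.
#' @param keep_planar if `TRUE` (default) and planar columns already exist,
#'   they are returned as-is.
#' @return the sample table with `x_m`, `y_m` columns filled in.
#' @export
project_coordinates <- function(st, keep_planar = TRUE) {
  st <- sample_table(st)
  if (keep_planar && all(c("x_m", "y_m") %in% names(st)) &&
      all(is.finite(st$x_m) & is.finite(st$y_m)))
    return(st)
  if (!all(c("lat", "lon") %in% names(st)))
    stop("no lat/lon columns to project and no planar coordinates present")
  lon_span <- diff(range(st$lon))
  if (any(st$lat > 0) && any(st$lat < 0) && lon_span > 6)
    warning("samples span both hemispheres over >6 degrees longitude; ",
            "a single local projection may distort distances")
  xy <- .tmerc(st$lat, st$lon, mean(range(st$lat)), mean(range(st$lon)))
  st$x_m <- xy[, "x_m"]
  st$y_m <- xy[, "y_m"]
  sample_table(st)
}

#' Pairwise geographic distances in metres
#'
#' Euclidean distances between planar sample coordinates.
#'
#' @param st a `sample_table` with planar `x_m`/`y_m` (see
#'   [project_coordinates()]).
#' @return symmetric matrix of distances in metres, zero diagonal, with
#'   sample ids as dimnames.
#' @export
pairwise_geo_distances <- function(st) {
  st <- sample_table(st)
  if (!all(c("x_m", "y_m") %in% names(st)))
    stop("planar coordinates missing; run project_coordinates() first")
  d <- as.matrix(stats::dist(cbind(st$x_m, st$y_m)))
  dimnames(d) <- list(st$id, st$id)
  d
}

#' Export dominant data in STRUCTURE one-row-per-individual format
#'
#' Dominant markers are written as one pseudo-haploid column per locus
#' (0/1 band phenotype, missing as -9), preceded by the individual id and an
#' integer population index.
#'
#' @param x a `marker_matrix`.
#' @param st matching `sample_table`.
#' @param path output file.
#' @export
write_structure <- function(x, st, path) {
  st <- sample_table(st)
  if (!identical(rownames(x), st$id))
    stop("sample table ids must match marker matrix rows exactly")
  m <- matrix(as.character(unclass(x)), nrow(x), ncol(x))
  m[is.na(m)] <- "-9"
  out <- cbind(st$id, as.integer(factor(st$pop, levels = unique(st$pop))), m)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV with a provenance header
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param seed seed recorded in the header comment (optional).
#' @export
write_result_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("aflpsgs"))
  hdr <- sprintf("# aflpsgs %s%s", ver,
                 if (is.null(seed)) "" else sprintf(" seed=%s", seed))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
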