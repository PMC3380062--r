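#' Build a validated feature table
#'
#' A feature is one detected peak in one map (mass spectrum): a retention time
#' in minutes, a mass in Daltons, the 1-based index of the map it came from,
#' and a non-negative intensity.  Feature tables are plain data frames with a
#' stable integer `uid` column assigned in input order, plus the attribute
#' `n_maps` (K).
#'
#' @param rt Retention times, minutes (> 0).
#' @param mz Masses, Daltons (> 0).
#' @param map Integer map indices in `1..n_maps`.
#' @param intensity Non-negative abundances.
#' @param n_maps Number of maps K; defaults to `max(map)` (0 for an empty
#'   table).
#' @return A `data.frame` of class `"feature_table"` with columns
#'   `uid, rt, mz, map, intensity`.
#' @export
feature_table <- function(rt, mz, map, intensity, n_maps = NULL) {
  n <- length(rt)
  if (length(mz) != n || length(map) != n || length(intensity) != n)
    stop("rt, mz, map and intensity must have equal length")
  bad <- which(!is.finite(rt) | rt <= 0)
  if (length(bad))
    stop("non-positive or missing retention time at row ", bad[1L])
  bad <- which(!is.finite(mz) | mz <= 0)
  if (length(bad))
    stop("non-positive or missing mass at row ", bad[1L])
  bad <- which(!is.finite(intensity) | intensity < 0)
  if (length(bad))
    stop("negative or missing intensity at row ", bad[1L])
  map <- as.integer(map)
  bad <- which(is.na(map) | map < 1L)
  if (length(bad))
    stop("map index must be a positive integer; offending row ", bad[1L])
  if (is.null(n_maps)) n_maps <- if (n) max(map) else 0L
  n_maps <- as.integer(n_maps)
  if (n && max(map) > n_maps)
    stop("map index exceeds n_maps")
  out <- data.frame(uid = seq_len(n), rt = as.numeric(rt), mz = as.numeric(mz),
                    map = map, intensity = as.numeric(intensity))
  attr(out, "n_maps") <- n_maps
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Number of maps in a feature table
#' @param x A [feature_table()].
#' @return Integer K.
#' @export
n_maps <- function(x) {
  k <- attr(x, "n_maps")
  if (is.null(k)) max(x$map, 0L) else k
}

#' Read a feature table from TSV/CSV
#'
#' The file must have a header with columns `map`, `rt`, `mz` and `intensity`
#' (any order; extra columns are ignored).  `uid`s are assigned in file order
#' and K is inferred as the largest map index.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [feature_table()].
#' @export
read_features <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- if (dialect == "tsv") utils::read.delim(path, check.names = FALSE)
        else utils::read.csv(path, check.names = FALSE)
  need <- c("map", "rt", "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    return(feature_table(numeric(0), numeric(0), integer(0), numeric(0)))
  feature_table(df$rt, df$mz, df$map, df$intensity)
}

#' Write an alignment to disk
#'
#' Writes a wide consensus table (`<path>`): one row per consensus with its
#' id, centre coordinates, size, and one intensity column per map
#' (`map_1 .. map_K`); maps not covered by a consensus get an empty cell, not
#' a zero, so downstream statistics can distinguish absence from zero
#' abundance.  A companion long table (`<path base>.assign.tsv`) maps every
#' feature uid to its consensus id.
#'
#' Before writing, the assignment is checked to be a partition of the feature
#' table: a feature assigned to two consensuses, or to none, raises an
#' integrity error (duplication/omission of raw features is exactly the
#' failure mode alignment must never exhibit).
#'
#' @param alignment An `"mcm_alignment"` from [align_features()].
#' @param features The feature table that was aligned.
#' @param path Output path for the wide table (TSV).
#' @return Invisibly, a list with the two file paths.
#' @export
write_alignment <- function(alignment, features, path) {
  stopifnot(inherits(alignment, "mcm_alignment"),
            inherits(features, "feature_table"))
  asg <- alignment$assignments
  if (anyDuplicated(asg$uid))
    stop("integrity error: feature assigned to more than one consensus")
  if (!setequal(asg$uid, features$uid) || nrow(asg) != nrow(features))
    stop("integrity error: assignment does not cover every feature exactly once")
  K <- alignment$n_maps
  cons <- alignment$consensuses
  wide <- data.frame(consensus_id = cons$consensus_id,
                     centre_rt = cons$centre_rt, centre_mz = cons$centre_mz,
                     size = cons$size)
  mat <- matrix(NA_real_, nrow(cons), K,
                dimnames = list(NULL, paste0("map_", seq_len(K))))
  row_of <- match(asg$consensus_id, cons$consensus_id)
  col_of <- features$map[match(asg$uid, features$uid)]
  z <- features$intensity[match(asg$uid, features$uid)]
  mat[cbind(row_of, col_of)] <- z
  wide <- cbind(wide, as.data.frame(mat))
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  long_path <- paste0(sub("\\.tsv$", "", path), ".assign.tsv")
  utils::write.table(asg[order(asg$uid), c("uid", "consensus_id")], long_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(wide = path, assignments = long_path))
}

#' Read back a long-format assignment table
#' @param path Path to a `.assign.tsv` written by [write_alignment()].
#' @return data.frame with columns `uid`, `consensus_id`.
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) stop("assignment file not found: ", path)
  utils::read.delim(path)
}
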