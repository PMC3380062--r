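#' Digit-aligned values (DAV) and dollar-separated string records
#'
#' The alignment algorithm operates on a *string list*: every feature is one
#' fixed-width record whose fields are zero-padded decimal strings separated
#' by `$`.  Because every field has the same width in every record,
#' lexicographic (byte) order of the records equals numeric order of the
#' leading field, so a single string sort orders the whole list by mass (or
#' by retention time for the rt-leading working lists).  Aligned features are
#' "whitened" -- their leading field is replaced by the letter `w`, which
#' sorts after every digit, so they sink to the bottom of the list and are
#' never re-scanned.
#'
#' @name dav
NULL

#' A fixed-width layout for one numeric field
#'
#' @param int_width Digits before the decimal point (>= 1).
#' @param dec_width Digits after the decimal point; `0` means an integer
#'   field with no decimal point (used for map index and origin columns).
#' @return A list of class `"dav_layout"`.
#' @export
dav_layout <- function(int_width, dec_width = 0L) {
  int_width <- as.integer(int_width); dec_width <- as.integer(dec_width)
  if (is.na(int_width) || int_width < 1L) stop("int_width must be >= 1")
  if (is.na(dec_width) || dec_width < 0L) stop("dec_width must be >= 0")
  structure(list(int_width = int_width, dec_width = dec_width),
            class = "dav_layout")
}

#' Encode numbers as digit-aligned values
#'
#' Values are zero-padded on both sides to `int_width` digits before and
#' `dec_width` digits after the decimal point, e.g. 1.5 becomes `"001.5000"`
#' under a (3, 4) layout.  Values are rounded (half to even) at `dec_width`
#' decimals; a value too large for `int_width` is an overflow error, never a
#' truncation.
#'
#' @param x Non-negative numbers.
#' @param layout A [dav_layout()], or `int_width` when `dec_width` is given.
#' @param dec_width Optional, together with an integer first argument.
#' @return Character vector of fixed-width strings.
#' @examples
#' dav_encode(1.5, dav_layout(3, 4))   # "001.5000"
#' @export
dav_encode <- function(x, layout, dec_width = NULL) {
  if (!inherits(layout, "dav_layout")) layout <- dav_layout(layout, dec_width)
  if (any(!is.finite(x)) || any(x < 0))
    stop("DAV values must be finite and non-negative")
  if (any(x >= 10^layout$int_width))
    stop("DAV overflow: value ", max(x), " does not fit in ",
         layout$int_width, " integer digit(s)")
  if (layout$dec_width == 0L) {
    sprintf(paste0("%0", layout$int_width, "d"), as.integer(round(x)))
  } else {
    out <- sprintf(paste0("%0", layout$int_width + layout$dec_width + 1L,
                          ".", layout$dec_width, "f"), x)
    # rounding at dec_width could carry past the integer width (e.g. 999.99995)
    if (any(nchar(out) != layout$int_width + layout$dec_width + 1L))
      stop("DAV overflow after rounding at ", layout$dec_width, " decimals")
    out
  }
}

#' Decode digit-aligned values back to numbers
#' @param s Character vector of DAV strings (no `$`).
#' @return Numeric vector.
#' @export
dav_decode <- function(s) as.numeric(s)

# Smallest number of decimals that represents every value of x exactly
# (to within floating-point slack), capped; used so that file-read data with
# a fixed printed precision round-trips losslessly.
decimals_needed <- function(x, cap = 8L) {
  if (!length(x)) return(0L)
  for (d in 0:cap) {
    y <- x * 10^d
    if (all(abs(y - round(y)) <= 1e-6 + abs(y) * 1e-10)) return(d)
  }
  cap
}

int_digits <- function(x) {
  if (!length(x)) return(1L)
  m <- max(floor(x), 0)
  if (m < 1) 1L else nchar(sprintf("%.0f", m))
}

#' Infer minimal field layouts for a feature table
#'
#' Widths are the smallest that fit every value in the dataset; decimal
#' widths follow the data's printed precision (capped at 8) and are never
#' zero for the measured fields, so an all-integer column still carries a
#' single padded `"0"` decimal.  The map-index and origin columns are
#' integer fields without a decimal point.
#'
#' @param features A [feature_table()] (non-empty).
#' @return Named list of [dav_layout()]s: `mz`, `rt`, `map`, `intensity`,
#'   `origin`.
#' @export
infer_dav_layouts <- function(features) {
  if (!nrow(features)) stop("cannot infer layouts from an empty feature table")
  val_layout <- function(x)
    dav_layout(int_digits(x), max(1L, decimals_needed(x)))
  list(
    mz = val_layout(features$mz),
    rt = val_layout(features$rt),
    map = dav_layout(int_digits(max(features$map))),
    intensity = val_layout(features$intensity),
    origin = dav_layout(int_digits(nrow(features)))
  )
}

#' Encode features as a mass-leading string list (S list)
#'
#' Record format is `m$r$w$z`: mass, retention time, map index, intensity.
#' The `$` byte sorts below every digit and never occurs inside a field, so
#' record order is decided entirely by the leading mass field (ties fall
#' through to the later fields, which makes the sort deterministic).
#'
#' @param features A [feature_table()].
#' @param layouts Layouts from [infer_dav_layouts()].
#' @return Character vector of records, one per row of `features`.
#' @export
encode_s_list <- function(features, layouts) {
  paste(dav_encode(features$mz, layouts$mz),
        dav_encode(features$rt, layouts$rt),
        dav_encode(features$map, layouts$map),
        dav_encode(features$intensity, layouts$intensity),
        sep = "$")
}

#' Encode an rt-leading working list with an origin column
#'
#' When a mass cluster is examined for retention-time structure it is copied
#' to a separate list whose records lead with retention time and carry an
#' extra `o` field holding each record's position in the S list, so that
#' after sorting by retention time every record can still be traced back.
#' Record format is `r$m$w$z$o`.
#'
#' @param features Rows of a [feature_table()] (the cluster members).
#' @param layouts Layouts from [infer_dav_layouts()].
#' @param origin Integer positions of these records in the S list.
#' @return Character vector of records.
#' @export
encode_r_list <- function(features, layouts, origin) {
  stopifnot(length(origin) == nrow(features))
  paste(dav_encode(features$rt, layouts$rt),
        dav_encode(features$mz, layouts$mz),
        dav_encode(features$map, layouts$map),
        dav_encode(features$intensity, layouts$intensity),
        dav_encode(origin, layouts$origin),
        sep = "$")
}

#' Split records back into their fields
#' @param records Character vector of `$`-separated records.
#' @param leading `"mz"` for S-list records, `"rt"` for working-list records
#'   (which carry the extra origin field).
#' @return data.frame of decoded numeric fields (`origin` present only for
#'   `leading = "rt"`); whitened records decode to `NA` in the leading field.
#' @export
decode_records <- function(records, leading = c("mz", "rt")) {
  leading <- match.arg(leading)
  parts <- strsplit(records, "$", fixed = TRUE)
  nf <- if (leading == "mz") 4L else 5L
  if (length(records) && any(lengths(parts) != nf))
    stop("malformed record: expected ", nf, " fields")
  m <- matrix(unlist(parts), ncol = nf, byrow = TRUE)
  lead <- suppressWarnings(as.numeric(m[, 1L]))  # "w" -> NA
  if (leading == "mz") {
    data.frame(mz = lead, rt = as.numeric(m[, 2L]),
               map = as.integer(m[, 3L]), intensity = as.numeric(m[, 4L]))
  } else {
    data.frame(rt = lead, mz = as.numeric(m[, 2L]),
               map = as.integer(m[, 3L]), intensity = as.numeric(m[, 4L]),
               origin = as.integer(m[, 5L]))
  }
}

#' Sort a string list lexicographically
#'
#' Byte-order (C locale) ascending sort.  For digit-leading records this is
#' numeric order of the leading field; whitened records (leading field `w`)
#' sort after all of them.  The sort is stable and ties on the full record
#' fall back to input order, so reruns are byte-reproducible.
#'
#' @param records Character vector of records.
#' @return Sorted character vector.
#' @seealso [string_order()] for the permutation itself.
#' @export
sort_strings <- function(records) records[string_order(records)]

#' Stable lexicographic order of records
#' @param records Character vector of records.
#' @return Integer permutation such that `records[string_order(records)]` is
#'   byte-sorted ascending.
#' @export
string_order <- function(records) order(records, method = "radix")

is_whitened <- function(records) startsWith(records, "w")

#' Whiten aligned records
#'
#' Replaces the leading field of the named records with the literal letter
#' `"w"`, leaving every other field untouched.  Whitened records sort after
#' all digit-leading records, so after the next sort they sit at the bottom
#' of the list and are skipped by the scanners.  Whitening an already
#' whitened record is an integrity error (it would mean a feature was
#' aligned twice).
#'
#' @param records Character vector of records.
#' @param idx Positions to whiten.
#' @return The modified character vector.
#' @export
whiten_records <- function(records, idx) {
  if (!length(idx)) return(records)
  if (any(idx < 1L | idx > length(records))) stop("whiten index out of range")
  if (any(is_whitened(records[idx])))
    stop("integrity error: record already whitened")
  records[idx] <- sub("^[^$]*", "w", records[idx])
  records
}
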