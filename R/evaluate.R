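#' Alignment quality statistics
#'
#' On two-map simulations with known ground truth, *sensitivity* is the
#' percentage of planted aligned TSMs recovered exactly (both features, and
#' nothing else, in one size-2 consensus) and *specificity* is the
#' percentage of planted non-aligned TSMs left as singletons.  On multi-map
#' simulations, per-size prediction errors compare the predicted per-size
#' consensus counts `c` against the planted counts `t`: a positive entry is
#' a false prediction (FP, too many consensuses of that size), a negative
#' one a missing hypothesis (MH).  On real data, where no truth exists, the
#' cumulative alignment curve (the per-size cumulative sum of aligned
#' features) summarises how well an alignment concentrates features into
#' large consensuses: lower curves are better.
#'
#' @name evaluation
NULL

# predicted consensus id and size for each uid
.pred_of <- function(alignment) {
  sz <- alignment$consensuses$size[match(alignment$assignments$consensus_id,
                                         alignment$consensuses$consensus_id)]
  data.frame(uid = alignment$assignments$uid,
             consensus_id = alignment$assignments$consensus_id, size = sz)
}

#' Sensitivity of an alignment against two-map ground truth
#'
#' The percentage of aligned TSMs that are *correctly* aligned: both planted
#' features sit together in a consensus of size exactly 2.  (Exact member-set
#' equality, not mere size match.)
#'
#' @param alignment An `"mcm_alignment"`.
#' @param truth A `"toy_sim"` from [simulate_two_map()].
#' @return Percentage in `[0, 100]`; `NA` with a warning if no aligned TSMs
#'   were planted.
#' @export
sensitivity <- function(alignment, truth) {
  stopifnot(inherits(alignment, "mcm_alignment"), inherits(truth, "toy_sim"))
  aligned <- truth$tsms$tsm_id[truth$tsms$category == "aligned"]
  P <- length(aligned)
  if (!P) { warning("no aligned TSMs planted; sensitivity undefined"); return(NA_real_) }
  pred <- .pred_of(alignment)
  pred <- pred[match(truth$membership$uid, pred$uid), ]
  correct <- 0L
  for (id in aligned) {
    rows <- which(truth$membership$tsm_id == id)
    cid <- unique(pred$consensus_id[rows])
    if (length(rows) == 2L && length(cid) == 1L &&
        pred$size[rows[1L]] == 2L)
      correct <- correct + 1L
  }
  100 * correct / P
}

#' Specificity of an alignment against two-map ground truth
#'
#' The percentage of non-aligned TSMs whose single feature remains a
#' singleton after alignment.
#'
#' @inheritParams sensitivity
#' @return Percentage in `[0, 100]`; `NA` with a warning if no non-aligned
#'   TSMs were planted.
#' @export
specificity <- function(alignment, truth) {
  stopifnot(inherits(alignment, "mcm_alignment"), inherits(truth, "toy_sim"))
  non <- truth$tsms$tsm_id[truth$tsms$category == "non_aligned"]
  Nn <- length(non)
  if (!Nn) { warning("no non-aligned TSMs planted; specificity undefined"); return(NA_real_) }
  pred <- .pred_of(alignment)
  uid_of <- truth$membership$uid[match(non, truth$membership$tsm_id)]
  sz <- pred$size[match(uid_of, pred$uid)]
  100 * sum(sz == 1L) / Nn
}

#' Per-size prediction errors (FP / MH)
#'
#' `e = c - t` per consensus size: positive entries are false predictions
#' (excess consensuses of that size), negative entries missing hypotheses.
#'
#' @param c Predicted per-size consensus counts (length K).
#' @param t True per-size TSM counts (length K).
#' @return Integer vector `c - t`.
#' @export
prediction_errors <- function(c, t) {
  if (length(c) != length(t))
    stop("`c` and `t` must have the same length (one entry per size 1..K)")
  as.integer(c) - as.integer(t)
}

#' Cumulative alignment curve (characteristic set)
#'
#' From the per-size counts `c`, the characteristic set is the cumulative
#' number of *features* aligned at each size, `s_i = sum_{j<=i} j*c_j`, with
#' `s_K = N` when the alignment conserves features, plus the normalized
#' curve `s / N` used for cross-algorithm comparison.
#'
#' @param c Per-size consensus counts, length K.
#' @param n_maps K (defaults to `length(c)`).
#' @param n_features If given, checked against `sum(i * c_i)`; a mismatch is
#'   an integrity error (features were duplicated or dropped).
#' @return List of class `"cam"`: `c`, `s`, `s_norm`, `n_maps`, `n_features`.
#' @export
cam <- function(c, n_maps = length(c), n_features = NULL) {
  if (length(c) != n_maps) stop("`c` must have one entry per size 1..n_maps")
  s <- cumsum(seq_along(c) * c)
  N <- s[length(s)]
  if (!is.null(n_features) && N != n_features)
    stop("integrity error: sum(i*c_i) = ", N, " but the alignment holds ",
         n_features, " features (duplication or omission)")
  structure(list(c = as.integer(c), s = s, s_norm = if (N > 0) s / N else s,
                 n_maps = n_maps, n_features = N),
            class = "cam")
}

#' Classify the shape of a cumulative alignment curve
#'
#' Patterns (on a K-map alignment): `"I"` (disastrous -- all consensuses are
#' singletons, the curve is already at 1 at size 1); `"II"` (perfect -- all
#' consensuses have full size, the curve is 0 through size K-1); `"IV-H"`
#' (biased high -- zero consensuses at the largest sizes, the curve is flat
#' at 1 before size K); `"IV-L"` (biased low -- zero consensuses at the
#' smallest sizes); `"III"` (normal) otherwise.  Counts are integers, so the
#' tests are exact, no epsilons.
#'
#' @param x A `"cam"` object.
#' @return One of `"I"`, `"II"`, `"III"`, `"IV-H"`, `"IV-L"`.
#' @export
classify_cam_pattern <- function(x) {
  stopifnot(inherits(x, "cam"))
  K <- x$n_maps; s <- x$s; N <- x$n_features
  if (K < 2L) return("I")
  if (s[1L] == N) return("I")
  if (s[K - 1L] == 0) return("II")
  if (s[K - 1L] == N) return("IV-H")   # no consensuses at the top sizes
  if (s[1L] == 0) return("IV-L")       # none at the bottom sizes
  "III"
}

#' Compare two cumulative alignment curves
#'
#' A lower curve concentrates more features in larger consensuses and is
#' preferred; curves are only comparable when one dominates the other
#' pointwise on the normalized scale.
#'
#' @param a,b `"cam"` objects over the same number of maps.
#' @return `"a"` or `"b"` (the preferred one), `"equal"`, or
#'   `"incomparable"` for crossing curves.
#' @export
compare_cam <- function(a, b) {
  stopifnot(inherits(a, "cam"), inherits(b, "cam"))
  if (a$n_maps != b$n_maps) stop("curves span different map counts")
  d <- a$s_norm - b$s_norm
  if (all(d == 0)) return("equal")
  if (all(d <= 0)) return("a")
  if (all(d >= 0)) return("b")
  "incomparable"
}

#' Plot a cumulative alignment curve
#' @param x A `"cam"` object.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.cam <- function(x, ...) {
  graphics::plot(seq_len(x$n_maps), x$s_norm, type = "b",
                 xlab = "consensus size (maps)",
                 ylab = "normalized cumulative aligned features",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
print.cam <- function(x, ...) {
  cat("CAM over", x$n_maps, "maps,", x$n_features, "features; pattern",
      classify_cam_pattern(x), "\n")
  cat("  s:", paste(x$s, collapse = " "), "\n")
  invisible(x)
}
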