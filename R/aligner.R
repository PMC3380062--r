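#' Greedy cluster scanning, consensus formation and the MCM alignment loop
#'
#' The aligner works in two alternating stages on sorted lists.  A scan of
#' the mass-sorted S list cuts it into *M-clusters*: maximal runs in which
#' consecutive masses differ by at most twice the mass tolerance.  The
#' tolerance is doubled because two features of the same metabolite can sit
#' on the two extreme boundaries of the window around the (unknown) true
#' mass.  Each M-cluster is copied to an rt-leading working list, sorted by
#' retention time, and cut the same way into *R-clusters* with twice the
#' retention-time tolerance.  Each R-cluster is a candidate consensus; it is
#' refined against the resolution condition (every member within `delta_r`
#' and `delta_m` of the midrange centre) and the collision condition (at
#' most one feature per map), and accepted only when the refined membership
#' has exactly the size currently demanded by the Map Coverage Maximization
#' loop, which asks for full-coverage consensuses first and then works down
#' to singletons.  Accepted members are whitened out of the S list; rejected
#' features stay in the pool and are re-scanned on the next pass.
#'
#' @name aligner
NULL

# numeric slack for boundary comparisons (values pass through fixed-decimal
# encoding, so equality at a tolerance boundary is meaningful)
.tol_pad <- function(tol) tol * (1 + 1e-12) + 1e-12

#' Cut a mass-sorted vector into M-clusters
#'
#' Greedy left-to-right scan: a new cluster starts whenever the gap between
#' consecutive masses exceeds `2 * delta_m` (evaluated at the heavier of the
#' two masses, which is the inclusive-safe choice for a mass-proportional
#' tolerance).  The clusters are disjoint, ordered and cover the input.
#'
#' @param mz Masses sorted ascending (error if not).
#' @param res A [resolution_set()].
#' @return List of integer index vectors, one per cluster, in scan order.
#' @export
scan_m_clusters <- function(mz, res) {
  if (is.unsorted(mz)) stop("scan_m_clusters expects masses sorted ascending")
  n <- length(mz)
  if (!n) return(list())
  if (n == 1L) return(list(1L))
  gap <- diff(mz)
  thr <- .tol_pad(2 * delta_m(res, mz[-1L]))
  ids <- cumsum(c(1L, as.integer(gap > thr)))
  unname(split(seq_len(n), ids))
}

#' Cut an rt-sorted vector into R-clusters
#'
#' Same greedy gap scan as [scan_m_clusters()] with the constant doubled
#' retention-time tolerance `2 * delta_r`.
#'
#' @param rt Retention times sorted ascending (error if not).
#' @param res A [resolution_set()].
#' @return List of integer index vectors.
#' @export
scan_r_clusters <- function(rt, res) {
  if (is.unsorted(rt)) stop("scan_r_clusters expects retention times sorted ascending")
  n <- length(rt)
  if (!n) return(list())
  if (n == 1L) return(list(1L))
  thr <- .tol_pad(2 * res$delta_r)
  ids <- cumsum(c(1L, as.integer(diff(rt) > thr)))
  unname(split(seq_len(n), ids))
}

#' Midrange consensus centre
#'
#' The centre of a consensus is the midpoint of the extreme members in each
#' dimension, `(min + max) / 2`, not the arithmetic mean -- this keeps the
#' centre unbiased when members pile up on one side of the window.
#'
#' @param rt,mz Member coordinates (non-empty).
#' @return Named numeric vector `c(rt = ..., mz = ...)`.
#' @examples
#' consensus_centre(c(1.1, 1.2), c(130.033, 130.035))  # mz centre 130.034
#' @export
consensus_centre <- function(rt, mz) {
  if (!length(rt) || length(rt) != length(mz))
    stop("consensus_centre needs matching non-empty rt and mz")
  c(rt = (min(rt) + max(rt)) / 2, mz = (min(mz) + max(mz)) / 2)
}

#' Refine an R-cluster into a consensus of a demanded size
#'
#' Iteratively removes members until a fixed point that is (i) free of
#' resolution violations -- every member within `delta_r` / `delta_m` of the
#' midrange centre recomputed over the current members -- and (ii) free of
#' collisions -- at most one feature per map, keeping per map the feature
#' closest to the centre in normalized distance
#' `sqrt((drt/delta_r)^2 + (dmz/delta_m)^2)`.  One member (the worst
#' offender) is removed per iteration and the centre is recomputed, so the
#' loop runs at most `nrow(members)` times.  The cluster is *accepted* only
#' when the fixed point has exactly `n` members; otherwise all its features
#' are left unaligned for later passes.
#'
#' @param members Rows of a [feature_table()] (columns `uid, rt, mz, map`).
#' @param n Demanded consensus size (current MCM stage).
#' @param res A [resolution_set()].
#' @return List: `accepted` (logical), `members` (retained rows),
#'   `excluded` (dropped rows), `centre_rt`, `centre_mz` (fixed-point
#'   centre; `NA` if all members were dropped).
#' @export
form_consensus <- function(members, n, res) {
  keep <- seq_len(nrow(members))
  ctr <- c(rt = NA_real_, mz = NA_real_)
  while (length(keep)) {
    rt <- members$rt[keep]; mz <- members$mz[keep]
    ctr <- consensus_centre(rt, mz)
    dm_tol <- delta_m(res, ctr[["mz"]])
    drt <- abs(rt - ctr[["rt"]]); dmz <- abs(mz - ctr[["mz"]])
    ndist <- sqrt((drt / res$delta_r)^2 + (dmz / dm_tol)^2)
    bad <- which(drt > .tol_pad(res$delta_r) | dmz > .tol_pad(dm_tol))
    if (length(bad)) {            # resolution violation: drop worst offender
      keep <- keep[-bad[which.max(ndist[bad])]]
      next
    }
    maps <- members$map[keep]
    dup <- unique(maps[duplicated(maps)])
    if (length(dup)) {            # collision: keep closest per map, drop worst
      droppable <- integer(0)
      for (mp in dup) {
        idx <- which(maps == mp)
        droppable <- c(droppable, idx[-which.min(ndist[idx])])
      }
      keep <- keep[-droppable[which.max(ndist[droppable])]]
      next
    }
    break
  }
  list(accepted = length(keep) == n,
       members = members[keep, , drop = FALSE],
       excluded = members[setdiff(seq_len(nrow(members)), keep), , drop = FALSE],
       centre_rt = ctr[["rt"]], centre_mz = ctr[["mz"]])
}

#' Align features across maps into consensus metabolites
#'
#' Full alignment loop.  For each demanded size `n` from K (all maps) down
#' to 2, passes are repeated until a pass accepts nothing: each pass sorts
#' the S list (whitened records sink to the bottom and are skipped), scans
#' M-clusters, and within each M-cluster sorts an rt-leading working list,
#' scans R-clusters and attempts to refine each into a size-`n` consensus.
#' Accepted members are whitened immediately.  Whatever remains after the
#' `n = 2` stage becomes singletons, so every feature ends in exactly one
#' consensus: the per-size counts always satisfy `sum(i * c_i) = N`.
#'
#' The scanners and the acceptance decisions read their numbers from the
#' encoded records, so the algorithm's behaviour is exactly that of the
#' string-sorted reference path; see the package vignette for numerical
#' details (tolerance padding at boundaries, fixed-decimal rounding).
#'
#' @param features A [feature_table()].
#' @param res A [resolution_set()].
#' @return Object of class `"mcm_alignment"`: `consensuses` (one row per
#'   consensus: id, centre, size), `assignments` (uid -> consensus id),
#'   `size_counts` (the c vector, length K), `n_features`, `n_maps`, and a
#'   `log` data frame of per-pass acceptance counts.
#' @export
align_features <- function(features, res = resolution_set()) {
  stopifnot(inherits(features, "feature_table"), inherits(res, "resolution_set"))
  N <- nrow(features)
  K <- n_maps(features)
  empty_cons <- data.frame(consensus_id = integer(0), centre_rt = numeric(0),
                           centre_mz = numeric(0), size = integer(0))
  if (!N) {
    return(structure(list(consensuses = empty_cons,
                          assignments = data.frame(uid = integer(0),
                                                   consensus_id = integer(0)),
                          size_counts = integer(max(K, 0L)),
                          n_features = 0L, n_maps = K,
                          log = data.frame(n = integer(0), pass = integer(0),
                                           accepted = integer(0))),
                     class = "mcm_alignment"))
  }

  layouts <- infer_dav_layouts(features)
  s_rec <- encode_s_list(features, layouts)         # index = uid
  # the scanners compare the numbers carried by the records, i.e. the values
  # after fixed-decimal rounding
  rt_dav <- dav_encode(features$rt, layouts$rt)
  mz_dav <- dav_encode(features$mz, layouts$mz)
  rt_v <- as.numeric(rt_dav)
  mz_v <- as.numeric(mz_dav)
  feat <- data.frame(uid = features$uid, rt = rt_v, mz = mz_v,
                     map = features$map)

  whitened <- logical(N)
  cons_id <- 0L
  cons_rows <- vector("list", 0L)
  assign_uid <- integer(0); assign_cons <- integer(0)
  log_n <- integer(0); log_pass <- integer(0); log_acc <- integer(0)

  accept <- function(uids, centre_rt, centre_mz) {
    cons_id <<- cons_id + 1L
    cons_rows[[cons_id]] <<- data.frame(consensus_id = cons_id,
                                        centre_rt = centre_rt,
                                        centre_mz = centre_mz,
                                        size = length(uids))
    assign_uid <<- c(assign_uid, uids)
    assign_cons <<- c(assign_cons, rep.int(cons_id, length(uids)))
    whitened[uids] <<- TRUE
    s_rec <<- whiten_records(s_rec, uids)
  }

  for (n in seq.int(K, 2L, by = -1L)) {
    if (K < 2L) break
    pass <- 0L
    repeat {
      pass <- pass + 1L
      active <- which(!whitened)
      if (length(active) < n) break
      # sort the S list: whitened records sort to the bottom; the active
      # prefix is in mass order
      ord <- string_order(s_rec)
      ord <- ord[!whitened[ord]]
      accepted_here <- 0L
      mcl <- scan_m_clusters(mz_v[ord], res)
      for (cl in mcl) {
        if (length(cl) < n) next                 # cannot reach size n
        s_pos <- ord[cl]                          # uids in S order
        # rt-leading working list with origin column, sorted by rt
        r_rec <- encode_r_list(feat[s_pos, ], layouts, origin = cl)
        r_ord <- string_order(r_rec)
        r_uid <- s_pos[r_ord]
        rcl <- scan_r_clusters(rt_v[r_uid], res)
        for (rc in rcl) {
          if (length(rc) < n) next
          mem <- feat[r_uid[rc], , drop = FALSE]
          if (length(unique(mem$map)) < n) next   # refinement cannot add maps
          fc <- form_consensus(mem, n, res)
          if (fc$accepted) {
            accept(fc$members$uid, fc$centre_rt, fc$centre_mz)
            accepted_here <- accepted_here + 1L
          }
        }
      }
      log_n <- c(log_n, n); log_pass <- c(log_pass, pass)
      log_acc <- c(log_acc, accepted_here)
      if (accepted_here == 0L) break
    }
  }

  # n = 1: every remaining feature is a singleton consensus
  for (uid in which(!whitened)) {
    accept(uid, rt_v[uid], mz_v[uid])
  }

  consensuses <- if (cons_id) do.call(rbind, cons_rows) else empty_cons
  assignments <- data.frame(uid = assign_uid, consensus_id = assign_cons)
  size_counts <- tabulate(consensuses$size, nbins = K)
  structure(list(consensuses = consensuses, assignments = assignments,
                 size_counts = size_counts, n_features = N, n_maps = K,
                 log = data.frame(n = log_n, pass = log_pass,
                                  accepted = log_acc)),
            class = "mcm_alignment")
}

#' @export
print.mcm_alignment <- function(x, ...) {
  cat("MCM alignment:", x$n_features, "features over", x$n_maps, "maps ->",
      nrow(x$consensuses), "consensuses\n")
  cat("  per-size counts c:", paste(x$size_counts, collapse = " "), "\n")
  invisible(x)
}
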