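# Independent oracles used by the unit and property tests.  These are
# deliberately naive (loops, exhaustive enumeration) and share no code with
# the implementation paths they check.

pad <- function(tol) tol * (1 + 1e-12) + 1e-12

# left-to-right gap scanner: start a new cluster when the gap to the
# previous value exceeds thr(previous, current)
oracle_gap_clusters <- function(values, thr_fun) {
  if (!length(values)) return(list())
  out <- list(1L)
  for (i in seq_along(values)[-1L]) {
    if (values[i] - values[i - 1L] > thr_fun(values[i - 1L], values[i])) {
      out[[length(out) + 1L]] <- i
    } else {
      out[[length(out)]] <- c(out[[length(out)]], i)
    }
  }
  out
}

# is a set of features a valid consensus (resolution + collision)?
oracle_valid_block <- function(members, res) {
  if (anyDuplicated(members$map)) return(FALSE)
  ctr_rt <- (min(members$rt) + max(members$rt)) / 2
  ctr_mz <- (min(members$mz) + max(members$mz)) / 2
  all(abs(members$rt - ctr_rt) <= pad(res$delta_r)) &&
    all(abs(members$mz - ctr_mz) <= pad(delta_m(res, ctr_mz)))
}

# exhaustive search over collision-free, resolution-consistent subsets:
# maximum size, ties broken by smallest summed normalized distance to the
# subset's own midrange centre
oracle_best_subset <- function(members, res) {
  n <- nrow(members)
  stopifnot(n <= 12L)
  best <- NULL; best_size <- 0L; best_dist <- Inf
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    sub <- members[idx, , drop = FALSE]
    if (!oracle_valid_block(sub, res)) next
    ctr_rt <- (min(sub$rt) + max(sub$rt)) / 2
    ctr_mz <- (min(sub$mz) + max(sub$mz)) / 2
    d <- sum(sqrt(((sub$rt - ctr_rt) / res$delta_r)^2 +
                  ((sub$mz - ctr_mz) / delta_m(res, ctr_mz))^2))
    if (length(idx) > best_size ||
        (length(idx) == best_size && d < best_dist)) {
      best <- idx; best_size <- length(idx); best_dist <- d
    }
  }
  best
}

# all partitions of a set of indices (Bell-number enumeration, small n only)
oracle_partitions <- function(items) {
  if (!length(items)) return(list(list()))
  first <- items[1L]
  rest <- oracle_partitions(items[-1L])
  out <- list()
  for (p in rest) {
    for (b in seq_along(p)) {
      q <- p; q[[b]] <- c(q[[b]], first)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(first))
  }
  out
}

# lexicographic coverage score: counts of blocks of size K, K-1, ..., 1
oracle_score <- function(blocks, K) {
  sizes <- lengths(blocks)
  rev(tabulate(sizes, nbins = K))
}

lex_greater <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1L]] > 0
}

# exhaustive reference aligner: split features into connectivity components
# under the doubled tolerances, enumerate all partitions of each component,
# keep only partitions whose every block is a valid consensus, and pick the
# one with lexicographically maximal coverage (size-K count first).
oracle_align <- function(features, res) {
  n <- nrow(features)
  K <- n_maps(features)
  comp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    near <- abs(features$rt[i] - features$rt[j]) <= pad(2 * res$delta_r) &&
      abs(features$mz[i] - features$mz[j]) <=
        pad(2 * delta_m(res, max(features$mz[i], features$mz[j])))
    if (near) comp[comp == comp[j]] <- comp[i]
  }
  blocks_out <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    stopifnot(length(idx) <= 10L)  # keep enumeration tractable
    best <- NULL; best_score <- NULL
    for (p in oracle_partitions(idx)) {
      ok <- all(vapply(p, function(b)
        oracle_valid_block(features[b, , drop = FALSE], res), logical(1)))
      if (!ok) next
      sc <- oracle_score(p, K)
      if (is.null(best) || lex_greater(sc, best_score)) {
        best <- p; best_score <- sc
      }
    }
    stopifnot(!is.null(best))
    blocks_out <- c(blocks_out, best)
  }
  blocks_out
}

# canonical form of a partition into uid sets, for equality comparison
canonical_blocks <- function(blocks, uids = NULL) {
  s <- vapply(blocks, function(b) paste(sort(b), collapse = ","), character(1))
  sort(s)
}

alignment_blocks <- function(alignment) {
  unname(split(alignment$assignments$uid, alignment$assignments$consensus_id))
}

# small literal feature table
ft <- function(rt, mz, map, intensity = rep(100, length(rt)), n_maps = NULL) {
  feature_table(rt, mz, map, intensity, n_maps = n_maps)
}

# write a small feature TSV, return path
write_feature_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
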