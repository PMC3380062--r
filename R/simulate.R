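#' Ground-truthed simulators
#'
#' Both simulators plant "true simulated metabolites" (TSMs) uniformly in a
#' retention-time x mass window and emit noisy observed features: each
#' feature's retention time is its TSM's plus `U(-g*delta_r, g*delta_r)` and
#' its mass is the TSM's plus `U(-g*delta_m(mz), g*delta_m(mz))`, where `g`
#' (the noise level, 0..1) scales the instrument resolution.  At `g <= 1`
#' every feature therefore still satisfies the resolution condition against
#' its own TSM, so a correct aligner should recover the planted structure
#' exactly.  TSM centres are rejection-sampled so that every pair of TSMs is
#' separated by more than four tolerances in retention time *or* in mass,
#' which makes the ground truth unambiguous (no two TSMs can merge); see the
#' vignette for why four.
#'
#' @name simulators
NULL

# rejection-sample n TSM centres with pairwise separation > 4*delta_r in rt
# OR > 4*delta_m in mass (delta_m taken at the heavier of the two)
sample_tsm_centres <- function(n, res, rt_range, mz_range, max_tries = 200L) {
  rt <- numeric(n); mz <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, rt_range[1], rt_range[2])
      m <- stats::runif(1, mz_range[1], mz_range[2])
      if (i == 1L) { ok <- TRUE }
      else {
        prev <- seq_len(i - 1L)
        sep <- abs(rt[prev] - r) > 4 * res$delta_r |
               abs(mz[prev] - m) > 4 * delta_m(res, pmax(mz[prev], m))
        ok <- all(sep)
      }
      if (ok) { rt[i] <- r; mz[i] <- m; break }
    }
    if (!ok)
      stop("could not place ", n, " separated TSMs in the given ranges; ",
           "reduce counts or enlarge the window")
  }
  data.frame(rt = rt, mz = mz)
}

noise_feature <- function(rt0, mz0, gamma, res) {
  c(rt = rt0 + stats::runif(1, -gamma * res$delta_r, gamma * res$delta_r),
    mz = mz0 + stats::runif(1, -gamma * delta_m(res, mz0),
                               gamma * delta_m(res, mz0)))
}

check_gamma <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1)
    stop("noise level must be a single number in [0, 1]")
  gamma
}

#' Simulate a two-map benchmark with aligned and non-aligned TSMs
#'
#' Plants `n_aligned` TSMs that each contribute one feature to *each* of the
#' two maps (so they should be recovered as size-2 consensuses) and
#' `n_nonaligned` TSMs that contribute a single feature to a randomly chosen
#' map (and should stay singletons).  TSM coordinates are uniform over
#' `rt_range` minutes and `mz_range` Daltons.  Intensities are log-normal
#' (meanlog 10, sdlog 1); they play no role in alignment.
#'
#' @param n_aligned Number of aligned TSMs (default 493; with the default
#'   `n_nonaligned` this yields 986 + 504 features).
#' @param n_nonaligned Number of non-aligned TSMs (default 504).
#' @param gamma Noise level in `[0, 1]`, as a fraction of the resolution.
#' @param res A [resolution_set()].
#' @param seed Mandatory integer seed; runs are byte-reproducible.
#' @param rt_range,mz_range TSM coordinate windows (minutes / Daltons).
#' @return List of class `"toy_sim"`: `features` (a [feature_table()]),
#'   `tsms` (tsm_id, category, size, rt, mz), `membership` (uid -> tsm_id),
#'   plus the generating settings.
#' @export
simulate_two_map <- function(n_aligned = 493, n_nonaligned = 504, gamma = 1,
                             res = resolution_set(), seed,
                             rt_range = c(1, 27), mz_range = c(1, 500)) {
  if (missing(seed)) stop("`seed` is mandatory")
  check_gamma(gamma)
  set.seed(seed)
  n_tsm <- n_aligned + n_nonaligned
  centres <- sample_tsm_centres(n_tsm, res, rt_range, mz_range)
  category <- rep(c("aligned", "non_aligned"), c(n_aligned, n_nonaligned))
  size <- ifelse(category == "aligned", 2L, 1L)
  rt <- numeric(0); mz <- numeric(0); map <- integer(0); tsm_of <- integer(0)
  for (i in seq_len(n_tsm)) {
    if (category[i] == "aligned") {
      # one feature in each map, independently noised
      maps <- sample(1:2, 2L)
      for (w in maps) {
        f <- noise_feature(centres$rt[i], centres$mz[i], gamma, res)
        rt <- c(rt, f[["rt"]]); mz <- c(mz, f[["mz"]])
        map <- c(map, w); tsm_of <- c(tsm_of, i)
      }
    } else {
      f <- noise_feature(centres$rt[i], centres$mz[i], gamma, res)
      rt <- c(rt, f[["rt"]]); mz <- c(mz, f[["mz"]])
      map <- c(map, sample(1:2, 1L)); tsm_of <- c(tsm_of, i)
    }
  }
  intensity <- stats::rlnorm(length(rt), meanlog = 10, sdlog = 1)
  features <- feature_table(rt, mz, map, intensity, n_maps = 2L)
  structure(list(
    features = features,
    tsms = data.frame(tsm_id = seq_len(n_tsm), category = category,
                      size = size, rt = centres$rt, mz = centres$mz),
    membership = data.frame(uid = features$uid, tsm_id = tsm_of),
    gamma = gamma, res = res, seed = seed
  ), class = "toy_sim")
}

#' Simulate a multi-map benchmark with planted consensus sizes
#'
#' Plants `n_per_size[s]` TSMs of every size `s` in `1..n_maps`; a size-`s`
#' TSM contributes one noised feature to each of `s` distinct, uniformly
#' chosen maps.  Returns the true per-size count vector `t`, against which
#' per-size prediction errors ([prediction_errors()]) are measured.
#'
#' @param n_maps Number of maps K (default 10).
#' @param n_per_size Integer vector of length `n_maps`: TSM counts per
#'   planted size (default 10 each).
#' @param gamma Noise level in `[0, 1]`.
#' @param res A [resolution_set()].
#' @param seed Mandatory integer seed.
#' @param rt_range,mz_range TSM coordinate windows.
#' @return List of class `"toy_sim"` as in [simulate_two_map()], plus `t`
#'   (true per-size counts).
#' @export
simulate_multi_map <- function(n_maps = 10L, n_per_size = rep(10L, n_maps),
                               gamma = 1, res = resolution_set(), seed,
                               rt_range = c(1, 27), mz_range = c(1, 500)) {
  if (missing(seed)) stop("`seed` is mandatory")
  check_gamma(gamma)
  n_maps <- as.integer(n_maps)
  if (length(n_per_size) != n_maps || any(n_per_size < 0))
    stop("`n_per_size` must give a non-negative count for each size 1..n_maps")
  set.seed(seed)
  sizes <- rep(seq_len(n_maps), n_per_size)
  n_tsm <- length(sizes)
  centres <- sample_tsm_centres(n_tsm, res, rt_range, mz_range)
  rt <- numeric(0); mz <- numeric(0); map <- integer(0); tsm_of <- integer(0)
  for (i in seq_len(n_tsm)) {
    maps <- sample(seq_len(n_maps), sizes[i])
    for (w in maps) {
      f <- noise_feature(centres$rt[i], centres$mz[i], gamma, res)
      rt <- c(rt, f[["rt"]]); mz <- c(mz, f[["mz"]])
      map <- c(map, w); tsm_of <- c(tsm_of, i)
    }
  }
  intensity <- stats::rlnorm(length(rt), meanlog = 10, sdlog = 1)
  features <- feature_table(rt, mz, map, intensity, n_maps = n_maps)
  structure(list(
    features = features,
    tsms = data.frame(tsm_id = seq_len(n_tsm),
                      category = ifelse(sizes > 1L, "aligned", "non_aligned"),
                      size = sizes, rt = centres$rt, mz = centres$mz),
    membership = data.frame(uid = features$uid, tsm_id = tsm_of),
    t = as.integer(tabulate(sizes, nbins = n_maps)),
    gamma = gamma, res = res, seed = seed
  ), class = "toy_sim")
}

#' @export
print.toy_sim <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$features), "features,",
      nrow(x$tsms), "TSMs,", n_maps(x$features), "maps, noise level",
      x$gamma, "\n")
  invisible(x)
}
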