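#' Consensus-of-tests differential metabolite detection
#'
#' After alignment, each consensus metabolite is a row of intensities over
#' the maps.  With maps labelled by one of two treatments, three two-group
#' tests are run per metabolite -- a Welch t-test, a moderated t-test with
#' variance shrinkage toward a pooled prior, and a permutation t-test -- and
#' a metabolite is called significantly differential only when *every* test
#' gives p below the significance level (default 0.001).  Requiring
#' agreement of all tests guards against the tests' well-known disagreement
#' in the extreme tails.  The three tests are simplified analogues of the
#' SAM / empirical-Bayes / Cyber-T family, not reimplementations; externally
#' computed p-value tables can be substituted via the `p_values` argument.
#'
#' @name diffstats
NULL

#' Build the consensus-by-map abundance matrix
#'
#' One row per consensus, one column per map; the entry is the intensity of
#' the consensus' member in that map, `NA` where the consensus does not
#' cover the map.  Rows with fewer than `min_per_group` observed values in
#' either treatment are flagged untestable (singletons always are).
#'
#' @param alignment An `"mcm_alignment"`.
#' @param features The aligned [feature_table()].
#' @param groups Treatment labels per map: either a vector of length K (two
#'   distinct values) or a data.frame with columns `map`, `group`.
#' @param min_per_group Minimum observed intensities per treatment for a row
#'   to be testable (default 2).
#' @return List of class `"abundance_matrix"`: `intensity` (matrix),
#'   `groups` (factor per column), `consensus` (centre/size table),
#'   `testable` (logical per row).
#' @export
build_abundance_matrix <- function(alignment, features, groups,
                                   min_per_group = 2L) {
  stopifnot(inherits(alignment, "mcm_alignment"),
            inherits(features, "feature_table"))
  K <- alignment$n_maps
  if (is.data.frame(groups)) {
    if (!all(c("map", "group") %in% names(groups)))
      stop("`groups` data.frame needs columns `map` and `group`")
    g <- rep(NA_character_, K)
    g[groups$map] <- as.character(groups$group)
  } else {
    g <- as.character(groups)
    if (length(g) != K) stop("`groups` must label all ", K, " maps")
  }
  if (anyNA(g)) stop("configuration error: map(s) without a group label: ",
                     paste(which(is.na(g)), collapse = ", "))
  g <- factor(g)
  if (nlevels(g) != 2L)
    stop("exactly two treatment groups are required, got ", nlevels(g))
  cons <- alignment$consensuses
  mat <- matrix(NA_real_, nrow(cons), K,
                dimnames = list(cons$consensus_id, paste0("map_", seq_len(K))))
  asg <- alignment$assignments
  row_of <- match(asg$consensus_id, cons$consensus_id)
  col_of <- features$map[match(asg$uid, features$uid)]
  mat[cbind(row_of, col_of)] <- features$intensity[match(asg$uid, features$uid)]
  n1 <- rowSums(!is.na(mat[, g == levels(g)[1L], drop = FALSE]))
  n2 <- rowSums(!is.na(mat[, g == levels(g)[2L], drop = FALSE]))
  structure(list(intensity = mat, groups = g, consensus = cons,
                 testable = n1 >= min_per_group & n2 >= min_per_group),
            class = "abundance_matrix")
}

# row-wise group summaries with NA omission
.row_group_stats <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  v <- rowSums((x - m)^2, na.rm = TRUE) / pmax(n - 1L, 1L)
  v[n < 2L] <- NA_real_
  list(n = n, mean = m, var = v)
}

# Welch t statistic + df per row of a two-group matrix
.row_welch <- function(x1, x2) {
  a <- .row_group_stats(x1); b <- .row_group_stats(x2)
  se2 <- a$var / a$n + b$var / b$n
  t <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1L) + (b$var / b$n)^2 / (b$n - 1L))
  list(t = t, df = df, diff = a$mean - b$mean,
       n1 = a$n, n2 = b$n, v1 = a$var, v2 = b$var)
}

#' Significantly differential metabolites by test consensus
#'
#' Runs the test panel on every testable row (log2 intensities by default)
#' and returns the metabolites for which *all* tests give `p < alpha`,
#' together with the full p-value table and the mean differential abundance
#' (group-1 mean minus group-2 mean on the analysis scale).
#'
#' Panel (simplified stand-ins, pluggable): `welch` -- Welch two-sample t;
#' `moderated` -- t with pooled per-row variance shrunk toward the average
#' pooled variance with `prior_df` prior degrees of freedom; `permutation`
#' -- Welch t referred to a label-permutation null pooled across *all* rows
#' (`n_perm` draws, the same permutations for every row).  Pooling the null
#' over rows is what makes p-values below `2 / choose(n, n1)` attainable at
#' small group sizes; a per-row permutation null cannot reach the default
#' `alpha` with typical replicate counts.
#'
#' @param amat An [build_abundance_matrix()] result.
#' @param alpha Significance level (default 0.001).
#' @param log2_transform Analyse `log2(intensity)`? Default `TRUE`.
#' @param n_perm Permutations for the permutation test (default 1000; the
#'   smallest attainable p is `1/(n_perm+1)`, so keep `n_perm >= 1/alpha`).
#' @param prior_df Prior degrees of freedom for the moderated test
#'   (default 4).
#' @param seed Optional seed for the permutation draws.
#' @param p_values Optional pre-computed p-value matrix (rows = consensuses,
#'   one column per test) replacing the built-in panel.
#' @param bh Apply Benjamini-Hochberg adjustment to each test's p-values
#'   before thresholding (off by default, matching the plain consensus
#'   rule).
#' @return List of class `"diff_result"`: `significant` (consensus ids),
#'   `table` (per-testable-row: consensus_id, mean_diff, one p column per
#'   test, `significant`), `alpha`.
#' @export
consensus_significant <- function(amat, alpha = 0.001, log2_transform = TRUE,
                                  n_perm = 1000L, prior_df = 4,
                                  seed = NULL, p_values = NULL, bh = FALSE) {
  stopifnot(inherits(amat, "abundance_matrix"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  rows <- which(amat$testable)
  if (!length(rows)) {
    warning("no testable rows; empty result")
    return(structure(list(significant = integer(0),
                          table = data.frame(), alpha = alpha),
                     class = "diff_result"))
  }
  x <- amat$intensity[rows, , drop = FALSE]
  if (log2_transform) x <- log2(x)
  g <- amat$groups
  i1 <- which(g == levels(g)[1L]); i2 <- which(g == levels(g)[2L])
  x1 <- x[, i1, drop = FALSE]; x2 <- x[, i2, drop = FALSE]
  w <- .row_welch(x1, x2)

  if (is.null(p_values)) {
    p_welch <- 2 * stats::pt(-abs(w$t), w$df)
    # moderated t: pooled variance shrunk toward the panel-wide mean
    df_pool <- w$n1 + w$n2 - 2L
    v_pool <- ((w$n1 - 1L) * w$v1 + (w$n2 - 1L) * w$v2) / df_pool
    s0 <- mean(v_pool[is.finite(v_pool)])
    v_mod <- (prior_df * s0 + df_pool * v_pool) / (prior_df + df_pool)
    t_mod <- w$diff / sqrt(v_mod * (1 / w$n1 + 1 / w$n2))
    p_mod <- 2 * stats::pt(-abs(t_mod), df_pool + prior_df)
    # permutation null of the Welch statistic, pooled across rows
    if (!is.null(seed)) set.seed(seed)
    nc <- ncol(x)
    t_obs <- abs(w$t)
    null_t <- vector("list", n_perm)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(nc)
      xp <- x[, perm, drop = FALSE]
      wp <- .row_welch(xp[, seq_along(i1), drop = FALSE],
                       xp[, -seq_along(i1), drop = FALSE])
      null_t[[b]] <- abs(wp$t[!is.na(wp$t)])
    }
    null_t <- sort(unlist(null_t))
    M <- length(null_t)
    exceed <- M - findInterval(t_obs - 1e-12, null_t)
    p_perm <- (1L + exceed) / (1L + M)
    p <- cbind(welch = p_welch, moderated = p_mod, permutation = p_perm)
  } else {
    p <- as.matrix(p_values)
    if (nrow(p) != length(rows))
      stop("`p_values` must have one row per testable consensus")
  }
  p_thr <- if (bh) apply(p, 2L, stats::p.adjust, method = "BH") else p
  if (is.null(dim(p_thr))) p_thr <- matrix(p_thr, nrow = 1L, dimnames = dimnames(p))
  sig <- rowSums(p_thr < alpha, na.rm = TRUE) == ncol(p) &
         rowSums(is.na(p_thr)) == 0L
  ids <- as.integer(rownames(amat$intensity)[rows])
  tab <- data.frame(consensus_id = ids, mean_diff = w$diff)
  tab <- cbind(tab, as.data.frame(p))
  tab$significant <- sig
  structure(list(significant = ids[sig], table = tab, alpha = alpha),
            class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat("Consensus differential analysis (alpha =", x$alpha, "):",
      length(x$significant), "significant of", nrow(x$table),
      "testable metabolites\n")
  invisible(x)
}

#' Retention time - mass density surface
#'
#' Two-dimensional Gaussian kernel density of the feature cloud over
#' (retention time, mass), with significant metabolites overlaid at their
#' consensus centres.  Bandwidths follow Scott's rule per dimension
#' (`sd * n^(-1/6)`); the returned grid is renormalized to integrate to 1.
#'
#' @param features A [feature_table()] (non-empty).
#' @param centres Optional data.frame with `rt`, `mz` columns (e.g. the
#'   significant consensuses' centres) returned as overlay points.
#' @param gridsize Grid resolution, default `c(100, 100)`.
#' @return List of class `"rm_surface"`: `rt` and `mz` grid vectors, `z`
#'   density matrix (integrates to 1), `points` (the overlay coordinates).
#' @export
rm_density_surface <- function(features, centres = NULL,
                               gridsize = c(100L, 100L)) {
  if (!nrow(features)) stop("empty feature set")
  rt <- features$rt; mz <- features$mz
  n <- length(rt)
  scott <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) s <- max(abs(v)) * 1e-3 + 1e-6
    4 * s * n^(-1 / 6)     # kde2d uses h/4 as the kernel sd
  }
  lims <- c(range(rt) + c(-1, 1) * scott(rt),
            range(mz) + c(-1, 1) * scott(mz))
  k <- MASS::kde2d(rt, mz, h = c(scott(rt), scott(mz)),
                   n = gridsize, lims = lims)
  dx <- diff(k$x[1:2]); dy <- diff(k$y[1:2])
  z <- k$z / (sum(k$z) * dx * dy)
  structure(list(rt = k$x, mz = k$y, z = z,
                 points = if (is.null(centres)) NULL
                          else centres[, c("rt", "mz")]),
            class = "rm_surface")
}

#' Plot a retention time - mass density surface
#' @param x An `"rm_surface"`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.rm_surface <- function(x, ...) {
  graphics::image(x$rt, x$mz, x$z, xlab = "retention time (min)",
                  ylab = "mass (Da)", ...)
  if (!is.null(x$points) && nrow(x$points))
    graphics::points(x$points$rt, x$points$mz, pch = 16)
  invisible(x)
}
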