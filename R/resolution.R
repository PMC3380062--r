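#' Retention-time / mass tolerance model
#'
#' A resolution set holds the two tolerances that decide whether features
#' observed in different maps (spectra) can be realisations of the same
#' metabolite: a constant retention-time tolerance `delta_r` (minutes) and a
#' mass tolerance that is proportional to the mass itself (`eps_ppm` parts per
#' million), reflecting that instrument mass error scales linearly with the
#' true mass.  A fixed-Dalton mode is provided for comparison runs against
#' tools that use a constant mass window.
#'
#' @param delta_r Retention-time tolerance in minutes.  Default 0.3, a typical
#'   LC-MS instrument value.
#' @param eps_ppm Relative mass tolerance in parts per million.  Default 10
#'   (so a 1 Da ion has a window of 0.00001 Da).  Used only in `"ppm"` mode.
#' @param mode `"ppm"` for mass-proportional tolerance (the default) or
#'   `"fixed_da"` for a constant window in Daltons.
#' @param delta_m_fixed Constant mass tolerance in Daltons; required in
#'   `"fixed_da"` mode (e.g. `0.0071` for comparison runs).
#' @return An object of class `"resolution_set"`.
#' @examples
#' res <- resolution_set()            # 0.3 min, 10 ppm
#' delta_m(res, 500)                  # 0.005 Da
#' @seealso [delta_m()]
#' @export
resolution_set <- function(delta_r = 0.3, eps_ppm = 10,
                           mode = c("ppm", "fixed_da"), delta_m_fixed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(delta_r) || length(delta_r) != 1L || !is.finite(delta_r) ||
      delta_r <= 0)
    stop("`delta_r` must be a single positive number (minutes)")
  if (mode == "ppm") {
    if (!is.numeric(eps_ppm) || length(eps_ppm) != 1L || !is.finite(eps_ppm) ||
        eps_ppm <= 0)
      stop("`eps_ppm` must be a single positive number (ppm)")
  } else {
    if (is.null(delta_m_fixed) || !is.numeric(delta_m_fixed) ||
        length(delta_m_fixed) != 1L || !is.finite(delta_m_fixed) ||
        delta_m_fixed <= 0)
      stop("`delta_m_fixed` must be a single positive number (Da) in 'fixed_da' mode")
  }
  structure(
    list(delta_r = delta_r, eps_ppm = eps_ppm, mode = mode,
         delta_m_fixed = delta_m_fixed),
    class = "resolution_set"
  )
}

#' Mass tolerance at a given mass
#'
#' In `"ppm"` mode the window is `eps_ppm * m * 1e-6` (strictly increasing in
#' `m`); in `"fixed_da"` mode it is the constant `delta_m_fixed`.
#'
#' @param res A [resolution_set()].
#' @param m Mass (Daltons); may be a vector.  Must be positive.
#' @return Numeric vector of tolerances, same length as `m`.
#' @export
delta_m <- function(res, m) {
  stopifnot(inherits(res, "resolution_set"))
  if (!is.numeric(m) || any(!is.finite(m)) || any(m <= 0))
    stop("`m` must be positive and finite")
  if (res$mode == "ppm") res$eps_ppm * m * 1e-6
  else rep_len(res$delta_m_fixed, length(m))
}

#' @export
print.resolution_set <- function(x, ...) {
  cat("Resolution set:\n  delta_r =", x$delta_r, "min\n")
  if (x$mode == "ppm") cat("  delta_m =", x$eps_ppm, "ppm (mass-proportional)\n")
  else cat("  delta_m =", x$delta_m_fixed, "Da (fixed)\n")
  invisible(x)
}
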