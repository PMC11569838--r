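#' Relative electrophoretic mobilities from a lane table
#'
#' Normalizes called band positions (or mobilities) to a reference lane,
#' conventionally the unmodified duplex run on the same nondenaturing gel.
#' Exactly one band per lane is expected.
#'
#' @param lanes a `data.frame` with columns `lane` (labels) and `position`
#'   (migration distance, mm, or mobility in arbitrary units; positive).
#' @param reference_lane label of the unmodified reference lane.
#' @return A `data.frame` with columns `lane`, `mobility`, `ratio`
#'   (mobility / reference mobility).
#' @export
relative_mobility <- function(lanes, reference_lane) {
  if (!all(c("lane", "position") %in% names(lanes)))
    stop("lane table needs columns 'lane' and 'position'")
  if (anyDuplicated(lanes$lane))
    stop("each lane must carry exactly one called band")
  if (any(!is.finite(lanes$position)) || any(lanes$position <= 0))
    stop("band positions must be positive")
  ref <- lanes$position[lanes$lane == reference_lane]
  if (length(ref) != 1L)
    stop("reference lane '", reference_lane, "' not found")
  data.frame(lane = lanes$lane, mobility = lanes$position,
             ratio = lanes$position / ref, stringsAsFactors = FALSE)
}

#' A modified/unmodified mobility pair
#'
#' @param mu_mod mobility (or migration distance) of the modified duplex.
#' @param mu_unmod same quantity for the unmodified duplex on the same gel.
#' @return Object of class `"mobility_pair"` with the ratio `mu_mod/mu_unmod`.
#' @export
mobility_pair <- function(mu_mod, mu_unmod) {
  if (!is.finite(mu_mod) || !is.finite(mu_unmod) || mu_mod <= 0 || mu_unmod <= 0)
    stop("mobilities must be positive")
  structure(list(mu_mod = mu_mod, mu_unmod = mu_unmod,
                 ratio = mu_mod / mu_unmod), class = "mobility_pair")
}

#' Apparent bend angle from retarded gel mobility
#'
#' Uses the cosine mobility rule for a centrally placed bend:
#' mu_mod / mu_unmod = cos(deflection / 2). A straight duplex (ratio 1) gives
#' an interior angle of 180 degrees; stronger retardation (smaller ratio)
#' means a stronger bend (smaller interior angle). Mobility ratios above 1 —
#' the modified duplex running faster than the unmodified one — are outside
#' the model and rejected.
#'
#' @param pair a [mobility_pair()], or a bare mobility ratio in (0, 1].
#' @param ratio_err optional one-sigma uncertainty of the ratio, propagated
#'   to the angle by first-order expansion of arccos.
#' @return Object of class `"bend_estimate"`: `interior_angle` and
#'   `deflection` in degrees (interior = 180 - deflection), `ratio`, and
#'   `interior_err` when `ratio_err` is supplied.
#' @export
bend_angle <- function(pair, ratio_err = NA_real_) {
  r <- if (inherits(pair, "mobility_pair")) pair$ratio else pair
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("mobility ratio must be a single positive number")
  if (r > 1)
    stop("anomalous mobility: modified duplex faster than the unmodified reference (ratio > 1)")
  deflection <- 2 * acos(r) * 180 / pi
  err <- NA_real_
  if (is.finite(ratio_err)) {
    ## d(deflection)/dr = -2/sqrt(1 - r^2); singular at r = 1
    err <- if (r < 1) 2 / sqrt(1 - r^2) * ratio_err * 180 / pi else Inf
  }
  structure(list(interior_angle = 180 - deflection, deflection = deflection,
                 ratio = r, interior_err = err), class = "bend_estimate")
}

#' @export
print.bend_estimate <- function(x, ...) {
  cat(sprintf("Bend estimate: interior angle %.2f deg", x$interior_angle))
  if (is.finite(x$interior_err)) cat(sprintf(" +/- %.2f", x$interior_err))
  cat(sprintf(" (deflection %.2f deg, mobility ratio %.5f)\n",
              x$deflection, x$ratio))
  invisible(x)
}
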