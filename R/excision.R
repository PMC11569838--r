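#' A single excision-product time course
#'
#' Band intensity of the labeled specific excision product (the 34-nt band
#' after templated extension) as a function of incubation time with a
#' repair-competent extract, for one substrate and one replicate. A time-zero
#' (no incubation / no extract) point carries the background signal and must
#' be present.
#'
#' @param time incubation times, minutes, strictly increasing, starting at 0.
#' @param intensity band intensities, arbitrary units, non-negative.
#' @param substrate substrate label.
#' @param replicate replicate identifier.
#' @return Object of class `"excision_timecourse"`.
#' @export
excision_timecourse <- function(time, intensity, substrate, replicate = 1L) {
  if (length(time) != length(intensity))
    stop("time and intensity differ in length")
  if (any(time < 0) || any(diff(time) <= 0))
    stop("times must be non-negative and strictly increasing")
  if (time[1] != 0)
    stop("a time-zero background point is required")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 substrate = substrate, replicate = replicate,
                 normalized = FALSE),
            class = "excision_timecourse")
}

#' Background-correct (and optionally rescale) a time course
#'
#' Subtracts the time-zero background intensity from every point; negative
#' corrected values are clamped to zero with a warning. With
#' `rescale = TRUE` the corrected course is divided by its maximum so the
#' strongest point reads 1 (a "relative efficiency" scale).
#'
#' @param tc an [excision_timecourse()].
#' @param rescale divide by the post-correction maximum.
#' @return The corrected `"excision_timecourse"`.
#' @export
normalize_timecourse <- function(tc, rescale = FALSE) {
  stopifnot(inherits(tc, "excision_timecourse"))
  bg <- tc$intensity[1]
  x <- tc$intensity - bg
  if (any(x < 0)) {
    warning("negative background-corrected intensities clamped to 0")
    x[x < 0] <- 0
  }
  if (all(x == 0))
    stop("empty signal: the whole course equals the background")
  if (rescale) x <- x / max(x)
  tc$intensity <- x
  tc$normalized <- TRUE
  tc
}

mean_course <- function(tcs, times) {
  m <- vapply(tcs, function(tc) tc$intensity[match(times, tc$time)],
              numeric(length(times)))
  rowMeans(matrix(m, nrow = length(times)))
}

#' Between-substrate excision-efficiency ratio
#'
#' Per-time ratio of replicate-mean product signals between two substrates,
#' time zero excluded, summarized by the unweighted mean over time points
#' with a percentile bootstrap interval obtained by resampling replicates
#' (not time points, which are not exchangeable within a course).
#' The ratio of replicate means, rather than a mean of per-replicate ratios,
#' keeps early low-signal time points from destabilizing the estimate.
#'
#' @param numerator,denominator lists of normalized [excision_timecourse()]
#'   replicates, one list per substrate. Time grids are intersected.
#' @param n_boot bootstrap draws.
#' @param seed optional integer; when given, the bootstrap is run under this
#'   seed and the caller's RNG state is left untouched.
#' @param conf confidence level of the percentile interval.
#' @return Object of class `"efficiency_ratio"`: `ratio_per_time`
#'   (data.frame time/ratio), `summary_ratio`, `ci_low`, `ci_high`,
#'   `n_boot`, `conf`.
#' @export
efficiency_ratio <- function(numerator, denominator, n_boot = 2000L,
                             seed = NULL, conf = 0.95) {
  if (inherits(numerator, "excision_timecourse")) numerator <- list(numerator)
  if (inherits(denominator, "excision_timecourse")) denominator <- list(denominator)
  if (!length(numerator) || !length(denominator))
    stop("at least one replicate per substrate is required")
  ok <- function(tcs) all(vapply(tcs, function(x)
    inherits(x, "excision_timecourse") && x$normalized, logical(1)))
  if (!ok(numerator) || !ok(denominator))
    stop("all courses must be normalized excision_timecourse objects")
  times <- Reduce(intersect, lapply(c(numerator, denominator), `[[`, "time"))
  times <- sort(times[times > 0])
  if (!length(times))
    stop("no common non-zero time points between the two substrate sets")
  den_mean <- mean_course(denominator, times)
  if (all(den_mean == 0))
    stop("denominator substrate has no signal beyond background")
  keep <- den_mean > 0
  times <- times[keep]
  ratio <- mean_course(numerator, times) / mean_course(denominator, times)
  summary_ratio <- mean(ratio)

  boot_stat <- function(idx_n, idx_d) {
    d <- mean_course(denominator[idx_d], times)
    if (any(d == 0)) return(NA_real_)
    mean(mean_course(numerator[idx_n], times) / d)
  }
  draw <- function() {
    boot_stat(sample.int(length(numerator), replace = TRUE),
              sample.int(length(denominator), replace = TRUE))
  }
  run_boot <- function() vapply(seq_len(n_boot), function(b) draw(), numeric(1))
  boots <- if (is.null(seed)) run_boot() else with_preserved_seed(seed, run_boot())
  boots <- boots[is.finite(boots)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(ratio_per_time = data.frame(time = times, ratio = ratio),
                 summary_ratio = summary_ratio,
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, conf = conf),
            class = "efficiency_ratio")
}

#' @export
print.efficiency_ratio <- function(x, ...) {
  cat(sprintf("Excision efficiency ratio: %.3f (%.0f%% bootstrap CI %.3f-%.3f, %d draws)\n",
              x$summary_ratio, 100 * x$conf, x$ci_low, x$ci_high, x$n_boot))
  print(x$ratio_per_time, row.names = FALSE)
  invisible(x)
}

#' Sample standard deviation of replicate measurements
#'
#' s = sqrt(sum((x_i - mean)^2) / (n - 1)), the n-1 form used for error bars
#' over independent experiments. At least two replicates are required.
#'
#' @param values numeric replicate values.
#' @return The sample standard deviation.
#' @export
replicate_sd <- function(values) {
  if (length(values) < 2L)
    stop("at least 2 replicates are needed for a standard deviation")
  stats::sd(values)
}

## Run `code` under `seed` without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
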