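# Per-rank mossy fibre input specifications and rate drawing.

.new_rank_spec <- function(kind, ...) {
  spec <- c(list(kind = kind), list(...))
  class(spec) <- "mzn_rank_spec"
  spec
}

#' Rank input specifications
#'
#' A rank input specification describes the distribution from which the
#' firing rates of one rank's mossy fibres are drawn. Four kinds are
#' supported, matching the input regimes used across the study:
#' * `rank_uniform()` — uniform on `[lo, hi]` (default 0-250 Hz);
#' * `rank_normal()` — normal with the given mean and SD (default SD 40),
#'   truncated at 0;
#' * `rank_discontinuous()` — uniform over a union of disjoint bands
#'   (default 50-110 and 180-300 Hz, spanning the 50-300 Hz range with a
#'   gap);
#' * `rank_sine()` — normal and narrow (SD 12.5 Hz) around a rank-dependent
#'   sinusoidal mean, the locomotor drive. The mean for rank `r` of `R` is
#'   `baseline + amplitude * sin(phase + 2*pi*wavelength_fraction*(r-1)/R)`,
#'   so `wavelength_fraction` is the fraction of one wavelength spanned by
#'   the whole row of ranks (1 = the row holds a full wavelength).
#'
#' All drawn rates are truncated at 0.
#'
#' @param lo,hi Rate bounds in Hz.
#' @param mean,sd Normal parameters in Hz.
#' @param bands Two-column matrix of disjoint, ordered `(lo, hi)` rate
#'   intervals.
#' @param wavelength_fraction Row-span of the ranks as a fraction of one
#'   drive wavelength (1, 3/4, 1/2, 1/4 in the swimming experiment).
#' @param phase_deg Cycle phase in degrees.
#' @param amplitude,baseline Sinusoid amplitude and baseline in Hz;
#'   `baseline - amplitude` must be non-negative so no rank mean is negative.
#' @param rank_sd Within-rank SD in Hz (12.5).
#' @return An object of class `mzn_rank_spec`.
#' @seealso [draw_rank_rates()], [rank_mean()]
#' @examples
#' draw_rank_rates(rank_uniform(), 10)
#' @name rank_spec
NULL

#' @rdname rank_spec
#' @export
rank_uniform <- function(lo = 0, hi = 250) {
  if (!(lo >= 0 && hi > lo)) stop("need 0 <= lo < hi", call. = FALSE)
  .new_rank_spec("uniform", lo = lo, hi = hi)
}

#' @rdname rank_spec
#' @export
rank_normal <- function(mean = 125, sd = 40) {
  if (mean < 0 || sd < 0) stop("mean and sd must be non-negative", call. = FALSE)
  .new_rank_spec("normal", mean = mean, sd = sd)
}

#' @rdname rank_spec
#' @export
rank_discontinuous <- function(bands = rbind(c(50, 110), c(180, 300))) {
  bands <- matrix(as.numeric(bands), ncol = 2)
  if (any(bands < 0) || any(bands[, 2] <= bands[, 1])) {
    stop("bands must be non-negative intervals with lo < hi", call. = FALSE)
  }
  if (nrow(bands) > 1 && any(bands[-1, 1] <= bands[-nrow(bands), 2])) {
    stop("bands must be disjoint and ordered", call. = FALSE)
  }
  .new_rank_spec("discontinuous", bands = bands)
}

#' @rdname rank_spec
#' @export
rank_sine <- function(wavelength_fraction = 1, phase_deg = 0,
                      amplitude = 100, baseline = 125, rank_sd = 12.5) {
  .check_positive(wavelength_fraction, "wavelength_fraction")
  if (baseline - amplitude < 0) {
    stop("baseline - amplitude must be >= 0 (no negative rank means)", call. = FALSE)
  }
  if (rank_sd < 0) stop("rank_sd must be >= 0", call. = FALSE)
  .new_rank_spec("sine_driven", wavelength_fraction = wavelength_fraction,
                 phase_deg = phase_deg, amplitude = amplitude,
                 baseline = baseline, rank_sd = rank_sd)
}

#' Mean drive of a rank under an input specification
#'
#' For a sine-driven spec this is the rank-dependent sinusoidal mean; for
#' the stationary kinds it is the distribution mean, identical across ranks.
#'
#' @param spec An `mzn_rank_spec`.
#' @param rank_index Rank position, 1-based.
#' @param n_ranks Total ranks in the row.
#' @return Mean rate in Hz.
#' @export
rank_mean <- function(spec, rank_index = 1, n_ranks = 41) {
  stopifnot(inherits(spec, "mzn_rank_spec"))
  switch(spec$kind,
    uniform = (spec$lo + spec$hi) / 2,
    normal = spec$mean,
    discontinuous = {
      w <- spec$bands[, 2] - spec$bands[, 1]
      sum(w * rowMeans(spec$bands)) / sum(w)
    },
    sine_driven = {
      theta <- spec$phase_deg * pi / 180 +
        2 * pi * spec$wavelength_fraction * (rank_index - 1) / n_ranks
      spec$baseline + spec$amplitude * sin(theta)
    },
    stop("unknown rank input kind: ", spec$kind, call. = FALSE))
}

#' Draw mossy fibre rates for one rank
#'
#' Draws `n_mossy` i.i.d. firing rates from the rank's input distribution,
#' truncated at 0, using the current RNG stream.
#'
#' @param spec An `mzn_rank_spec`.
#' @param n_mossy Number of mossy fibres in the rank.
#' @param rank_index,n_ranks Grid position, used only by sine-driven specs
#'   to locate the rank along the drive wavelength.
#' @return Numeric vector of `n_mossy` non-negative rates (Hz).
#' @examples
#' set.seed(1)
#' r <- draw_rank_rates(rank_discontinuous(), 1000)
#' any(r > 110 & r < 180)  # FALSE: the gap is empty
#' @export
draw_rank_rates <- function(spec, n_mossy, rank_index = 1, n_ranks = 41) {
  stopifnot(inherits(spec, "mzn_rank_spec"))
  n_mossy <- .check_count(n_mossy, "n_mossy")
  rates <- switch(spec$kind,
    uniform = stats::runif(n_mossy, spec$lo, spec$hi),
    normal = stats::rnorm(n_mossy, spec$mean, spec$sd),
    discontinuous = {
      w <- spec$bands[, 2] - spec$bands[, 1]
      b <- sample.int(nrow(spec$bands), n_mossy, replace = TRUE, prob = w)
      stats::runif(n_mossy, spec$bands[b, 1], spec$bands[b, 2])
    },
    sine_driven = stats::rnorm(n_mossy,
                               rank_mean(spec, rank_index, n_ranks),
                               spec$rank_sd),
    stop("unknown rank input kind: ", spec$kind, call. = FALSE))
  pmax(rates, 0)
}

#' Shift a rank input specification by a constant rate
#'
#' Returns the same specification with every rate (bounds, means,
#' baseline) moved by `delta` Hz — the input manipulation used by the
#' linearity diagnostics. Shifts that would push the support negative are
#' rejected.
#'
#' @param spec An `mzn_rank_spec`.
#' @param delta Shift in Hz.
#' @return A shifted `mzn_rank_spec`.
#' @export
shift_spec <- function(spec, delta) {
  stopifnot(inherits(spec, "mzn_rank_spec"))
  out <- switch(spec$kind,
    uniform = rank_uniform(spec$lo + delta, spec$hi + delta),
    normal = rank_normal(spec$mean + delta, spec$sd),
    discontinuous = rank_discontinuous(spec$bands + delta),
    sine_driven = rank_sine(spec$wavelength_fraction, spec$phase_deg,
                            spec$amplitude, spec$baseline + delta,
                            spec$rank_sd))
  out
}
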