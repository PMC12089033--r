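# Granular layer recoding: Golgi -> glomerulus inhibition, the granule cell
# firing decision, calibration of the inhibition constant, and assembly of
# per-file parallel fibre codes.

#' Granular layer parameters
#'
#' Internals of the inhibition chain and the granule firing rule. Golgi
#' cells sample mossy fibre terminal rates and glomeruli sample Golgi cell
#' rates (a two-stage mean-of-means); each granule cell dendrite compares a
#' randomly sampled excitation against a randomly sampled glomerular
#' inhibition.
#'
#' @param n_golgi Golgi units per field (10).
#' @param golgi_sample Terminal rates averaged by one Golgi unit (4).
#' @param glom_sample Golgi rates averaged by one glomerulus (4).
#' @param dendrites Dendrites per granule cell (4).
#' @param min_wins Dendritic wins (excitation > inhibition, strict) needed
#'   for the cell to fire; must be in `1..dendrites` (default 3).
#' @param rate_mode Firing-rate readout for active cells: `"all"` (mean of
#'   all dendritic excitation rates, the linear unit function) or
#'   `"winners"` (mean of winning dendrites only).
#' @return An object of class `mzn_granular`.
#' @export
mzn_granular <- function(n_golgi = 10, golgi_sample = 4, glom_sample = 4,
                         dendrites = 4, min_wins = 3,
                         rate_mode = c("all", "winners")) {
  p <- list(n_golgi = .check_count(n_golgi, "n_golgi"),
            golgi_sample = .check_count(golgi_sample, "golgi_sample"),
            glom_sample = .check_count(glom_sample, "glom_sample"),
            dendrites = .check_count(dendrites, "dendrites"),
            min_wins = .check_count(min_wins, "min_wins"),
            rate_mode = match.arg(rate_mode))
  if (p$min_wins > p$dendrites) {
    stop("min_wins must be in 1..dendrites", call. = FALSE)
  }
  class(p) <- "mzn_granular"
  p
}

#' Glomerular inhibition for one field
#'
#' Forms a population of Golgi unit rates (each the mean of a random sample
#' of the field's mossy terminal rates), then gives each glomerulus an
#' inhibition level `scale * mean(sample of Golgi rates) + offset`,
#' truncated at 0. The calibrated quantity is the additive `offset` (see
#' [calibrate_inhibition()]); `scale` is retained as a multiplicative
#' handle and defaults to 1. Uses the current RNG stream.
#'
#' @param rates Mossy terminal rates received by the field (Hz).
#' @param geom An [mzn_geometry()] object (supplies `glomeruli_per_field`).
#' @param params An [mzn_granular()] object.
#' @param scale Dimensionless multiplier on the sampled Golgi mean (>= 0).
#' @param offset Additive inhibition constant in Hz (may be negative; the
#'   resulting levels are floored at 0).
#' @return Numeric vector of `glomeruli_per_field` inhibition levels.
#' @examples
#' g <- mzn_geometry(scale = 0.02)
#' set.seed(1)
#' inh <- compute_field_inhibition(rep(100, 20), g, scale = 1)
#' all(inh == 100)  # means of constants
#' @export
compute_field_inhibition <- function(rates, geom, params = mzn_granular(),
                                     scale = 1, offset = 0) {
  stopifnot(inherits(geom, "mzn_geometry"), inherits(params, "mzn_granular"))
  if (!length(rates)) stop("empty field: no terminal rates", call. = FALSE)
  if (scale < 0) stop("'scale' must be >= 0", call. = FALSE)
  n <- length(rates)
  golgi <- colMeans(matrix(
    rates[sample.int(n, params$n_golgi * params$golgi_sample, replace = TRUE)],
    nrow = params$golgi_sample))
  g <- geom$glomeruli_per_field
  inh <- scale * colMeans(matrix(
    golgi[sample.int(params$n_golgi, g * params$glom_sample, replace = TRUE)],
    nrow = params$glom_sample)) + offset
  pmax(inh, 0)
}

#' Granule cell firing for one field
#'
#' Each granule cell draws `dendrites` inputs, each pairing a random
#' terminal rate (excitation) with a random glomerulus' inhibition; a
#' dendrite wins iff excitation strictly exceeds inhibition, the cell fires
#' iff at least `min_wins` dendrites win, and an active cell's rate is the
#' mean of its dendritic excitation rates. Uses the current RNG stream.
#'
#' @param rates Mossy terminal rates received by the field (Hz).
#' @param inhibition Glomerular inhibition levels for the field, from
#'   [compute_field_inhibition()].
#' @param geom An [mzn_geometry()] object (supplies `granule_per_field`).
#' @param params An [mzn_granular()] object.
#' @return A list with `n_granule`, `n_active`, `fraction` and
#'   `active_rates` (Hz, one per firing cell).
#' @export
evaluate_granule_firing <- function(rates, inhibition, geom,
                                    params = mzn_granular()) {
  stopifnot(inherits(geom, "mzn_geometry"), inherits(params, "mzn_granular"))
  if (!length(rates)) stop("empty field: no terminal rates", call. = FALSE)
  if (!length(inhibition)) stop("empty inhibition field", call. = FALSE)
  n_gc <- geom$granule_per_field
  d <- params$dendrites
  exc <- matrix(rates[sample.int(length(rates), n_gc * d, replace = TRUE)],
                nrow = d)
  inh <- matrix(inhibition[sample.int(length(inhibition), n_gc * d, replace = TRUE)],
                nrow = d)
  win <- exc > inh
  fires <- colSums(win) >= params$min_wins
  active_rates <- if (params$rate_mode == "all") {
    colMeans(exc)[fires]
  } else {
    (colSums(exc * win) / colSums(win))[fires]
  }
  list(n_granule = n_gc, n_active = sum(fires),
       fraction = mean(fires), active_rates = active_rates)
}

#' Run the granular layer over the whole input grid
#'
#' Applies [compute_field_inhibition()] and [evaluate_granule_firing()]
#' field by field, each field on its own RNG substream keyed by
#' `(seed, field index)`.
#'
#' @param layer An `mzn_input_layer` from [build_input_layer()].
#' @param params An [mzn_granular()] object.
#' @param scale,offset Inhibition constants (see
#'   [compute_field_inhibition()]).
#' @param seed Master seed for the stage.
#' @return An object of class `mzn_activity`: a list with `fields` (grid of
#'   per-field results), `fraction` (matrix of per-field active fractions)
#'   and the run parameters.
#' @export
run_granular <- function(layer, params = mzn_granular(), scale = 1,
                         offset = 0, seed = 1) {
  stopifnot(inherits(layer, "mzn_input_layer"))
  geom <- layer$geom
  nr <- geom$n_ranks
  f <- geom$fields_per_rank
  fields <- vector("list", nr)
  fraction <- matrix(NA_real_, nr, f)
  for (r in seq_len(nr)) {
    row <- vector("list", f)
    for (j in seq_len(f)) {
      fd <- layer$fields[[r]][[j]]
      row[[j]] <- .with_seed(mzn_substream(seed, "granular", (r - 1L) * f + j), {
        inh <- compute_field_inhibition(fd$rates, geom, params, scale, offset)
        evaluate_granule_firing(fd$rates, inh, geom, params)
      })
      fraction[r, j] <- row[[j]]$fraction
    }
    fields[[r]] <- row
  }
  structure(list(fields = fields, fraction = fraction, geom = geom,
                 params = params, scale = scale, offset = offset, seed = seed),
            class = "mzn_activity")
}

# Mean active fraction over a subset of fields at a given inhibition
# constant, under common random numbers so the calibration objective is an
# exactly monotone deterministic function of the constant. The draws are
# the very substreams run_granular() will use under the same master seed,
# so on the evaluated fields the calibrated run reproduces the achieved
# fraction exactly.
.eval_fraction <- function(layer, idx, params, scale, offset, seed) {
  geom <- layer$geom
  f <- geom$fields_per_rank
  fr <- numeric(length(idx))
  for (i in seq_along(idx)) {
    r <- (idx[i] - 1L) %/% f + 1L
    j <- (idx[i] - 1L) %% f + 1L
    fd <- layer$fields[[r]][[j]]
    fr[i] <- .with_seed(mzn_substream(seed, "granular", idx[i]), {
      inh <- compute_field_inhibition(fd$rates, geom, params, scale, offset)
      evaluate_granule_firing(fd$rates, inh, geom, params)$fraction
    })
  }
  mean(fr)
}

#' Calibrate the granular inhibition constant to a target active fraction
#'
#' Bisects on the inhibition constant until the mean active fraction over a
#' subsample of fields hits the target. The active fraction is monotone
#' non-increasing in the constant, and every evaluation reuses the same
#' dendritic draws (common random numbers), so bisection converges on a
#' deterministic objective. By default the additive `offset` is calibrated
#' with `scale` held at 1 — inhibition then tracks the local mossy mean
#' plus a constant, which keeps rate transmission at unit slope; calibrating
#' the multiplier instead is available via `mode = "scale"`.
#'
#' @param layer An `mzn_input_layer`.
#' @param target Target mean active fraction in (0, 1) (default the
#'   geometry's `active_fraction_target`).
#' @param tol Relative tolerance on the achieved fraction (default 0.1).
#' @param params An [mzn_granular()] object.
#' @param mode Which constant to calibrate: `"offset"` (additive, Hz) or
#'   `"scale"` (multiplicative).
#' @param n_eval_fields Number of fields in the calibration subsample
#'   (default: all fields, capped at 400).
#' @param seed Master seed for subsample choice and evaluation draws.
#' @param max_iter Bisection iterations (default 60).
#' @return An object of class `mzn_calibration`: `value` (the calibrated
#'   constant), `mode`, `scale`/`offset` as resolved, `achieved` fraction,
#'   `iterations`, `target`, `tol`.
#' @examples
#' g <- mzn_geometry(scale = 0.02, fields_per_rank = 10, n_ranks = 5)
#' layer <- build_input_layer(rank_uniform(), g, seed = 1)
#' cal <- calibrate_inhibition(layer, target = 0.3, seed = 1)
#' cal$achieved
#' @export
calibrate_inhibition <- function(layer, target = NULL, tol = 0.1,
                                 params = mzn_granular(),
                                 mode = c("offset", "scale"),
                                 n_eval_fields = NULL, seed = 1,
                                 max_iter = 60) {
  stopifnot(inherits(layer, "mzn_input_layer"))
  mode <- match.arg(mode)
  geom <- layer$geom
  if (is.null(target)) target <- geom$active_fraction_target
  if (!(target > 0 && target < 1)) {
    stop("'target' must be in (0, 1)", call. = FALSE)
  }
  n_fields <- geom$n_ranks * geom$fields_per_rank
  if (is.null(n_eval_fields)) n_eval_fields <- min(n_fields, 400L)
  idx <- .with_seed(mzn_substream(seed, "calibrate", 0L),
                    sort(sample.int(n_fields, min(n_eval_fields, n_fields))))
  obj <- function(theta) {
    if (mode == "offset") {
      .eval_fraction(layer, idx, params, 1, theta, seed)
    } else {
      .eval_fraction(layer, idx, params, theta, 0, seed)
    }
  }
  max_rate <- max(vapply(layer$fields,
                         function(rank) max(vapply(rank, function(fd) {
                           if (length(fd$rates)) max(fd$rates) else 0
                         }, 0)), 0))
  lo <- if (mode == "offset") -max_rate else 0
  hi <- if (mode == "offset") max_rate else 1
  f_lo <- obj(lo)
  if (f_lo < target) {
    warning("target fraction unreachable: even at the lower inhibition ",
            "bound the active fraction is ", signif(f_lo, 4),
            " < target ", target, "; returning the boundary")
    return(structure(list(value = lo, mode = mode,
                          scale = if (mode == "scale") lo else 1,
                          offset = if (mode == "offset") lo else 0,
                          achieved = f_lo, iterations = 0L,
                          target = target, tol = tol),
                     class = "mzn_calibration"))
  }
  f_hi <- obj(hi)
  grow <- 0L
  while (f_hi > target && grow < 12L) {  # widen until the target is bracketed
    hi <- hi * 2
    f_hi <- obj(hi)
    grow <- grow + 1L
  }
  if (f_hi > target) {
    stop(sprintf(paste0("calibration failed: bracket [%g, %g] gives active ",
                        "fractions [%g, %g] that do not straddle target %g"),
                 lo, hi, f_lo, f_hi, target), call. = FALSE)
  }
  it <- 0L
  f_mid <- f_lo
  while (it < max_iter) {
    mid <- (lo + hi) / 2
    f_mid <- obj(mid)
    if (f_mid > target) lo <- mid else hi <- mid
    it <- it + 1L
    if (abs(f_mid - target) <= tol * target * 0.1 && it >= 20L) break
  }
  value <- (lo + hi) / 2
  achieved <- obj(value)
  if (abs(achieved - target) > tol * target) {
    warning(sprintf("calibration achieved %.4g for target %.4g (tol %.0f%%)",
                    achieved, target, 100 * tol))
  }
  structure(list(value = value, mode = mode,
                 scale = if (mode == "scale") value else 1,
                 offset = if (mode == "offset") value else 0,
                 achieved = achieved, iterations = it,
                 target = target, tol = tol),
            class = "mzn_calibration")
}

#' Freeze inhibition constants without calibrating
#'
#' Wraps given inhibition constants in the calibration container, for runs
#' that must share a known constant (e.g. across phases of a sweep or
#' shifted-input comparisons) or for degenerate inputs where calibration is
#' not meaningful.
#'
#' @param offset Additive inhibition constant in Hz.
#' @param scale Multiplier on the sampled Golgi mean.
#' @param target,achieved Optional bookkeeping values.
#' @return An `mzn_calibration` object.
#' @export
as_calibration <- function(offset = 0, scale = 1, target = NA_real_,
                           achieved = NA_real_) {
  structure(list(value = if (scale != 1) scale else offset,
                 mode = if (scale != 1) "scale" else "offset",
                 scale = scale, offset = offset,
                 achieved = achieved, iterations = 0L,
                 target = target, tol = NA_real_),
            class = "mzn_calibration")
}

#' @export
print.mzn_calibration <- function(x, ...) {
  cat(sprintf("Inhibition calibration (%s): %s = %.4g\n", x$mode, x$mode, x$value))
  cat(sprintf("  target %.4g, achieved %.4g in %d bisection steps\n",
              x$target, x$achieved, x$iterations))
  invisible(x)
}

#' Assemble per-file parallel fibre codes
#'
#' Pools each file's active granule cells over its ranks: the active cells
#' of a file are the active parallel fibres converging on the corresponding
#' microzone sector, and the file density is the pooled active count over
#' the file's total granule complement.
#'
#' @param activity An `mzn_activity` from [run_granular()].
#' @return An object of class `mzn_file_codes`: a list with `files` (per
#'   file: `file_index`, `pf_rates`, `n_active`, `density`), `density` (the
#'   vector of file densities) and `geom`.
#' @export
assemble_file_codes <- function(activity) {
  stopifnot(inherits(activity, "mzn_activity"))
  geom <- activity$geom
  nr <- geom$n_ranks
  f <- geom$fields_per_rank
  for (r in seq_len(nr)) {
    if (length(activity$fields[[r]]) != f) {
      stop("incomplete activity grid: rank ", r, " has ",
           length(activity$fields[[r]]), " fields, expected ", f, call. = FALSE)
    }
  }
  files <- vector("list", f)
  density <- numeric(f)
  for (j in seq_len(f)) {
    rates <- unlist(lapply(seq_len(nr),
                           function(r) activity$fields[[r]][[j]]$active_rates),
                    use.names = FALSE)
    n_active <- length(rates)
    density[j] <- n_active / (nr * geom$granule_per_field)
    files[[j]] <- list(file_index = j, pf_rates = rates,
                       n_active = n_active, density = density[j])
  }
  structure(list(files = files, density = density, geom = geom),
            class = "mzn_file_codes")
}

#' @export
print.mzn_activity <- function(x, ...) {
  cat(sprintf("Granular layer activity: %d x %d fields, %d granule cells each\n",
              x$geom$n_ranks, x$geom$fields_per_rank, x$geom$granule_per_field))
  cat(sprintf("  inhibition: scale %.4g, offset %.4g Hz\n", x$scale, x$offset))
  cat(sprintf("  active fraction: mean %.4g (field SD %.3g)\n",
              mean(x$fraction), stats::sd(as.vector(x$fraction))))
  invisible(x)
}

#' @export
print.mzn_file_codes <- function(x, ...) {
  cat(sprintf("Parallel fibre file codes: %d files\n", length(x$files)))
  cat(sprintf("  density: mean %.4g (SD %.3g); active pf per file: mean %.0f\n",
              mean(x$density), stats::sd(x$density),
              mean(vapply(x$files, `[[`, 0, "n_active"))))
  invisible(x)
}
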