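# End-to-end microzone network runs and cross-layer summary statistics.

#' Simulate a full microzone network
#'
#' Runs the complete pipeline for one snapshot of the network: mossy fibre
#' input synthesis ([build_input_layer()]), calibration of the granular
#' inhibition constant to the sparse-code target ([calibrate_inhibition()]),
#' granular recoding into per-file parallel fibre codes ([run_granular()],
#' [assemble_file_codes()]), the molecular-layer cascade
#' ([simulate_stellate_layer()], [build_pc_networks()], [integrate_pc()])
#' and nuclear convergence ([project_to_nucleus()]). Every stage draws from
#' its own substream of `seed`, so a run is bit-reproducible from
#' `(configuration, seed)`.
#'
#' @param input A `mzn_rank_spec` (recycled over ranks), a list of one spec
#'   per rank, or one of `"uniform"`, `"normal"`, `"discontinuous"` for the
#'   default spec of that kind.
#' @param geom An [mzn_geometry()] object.
#' @param seed Master seed.
#' @param target Target active parallel fibre fraction (default the
#'   geometry's `active_fraction_target`).
#' @param calibration Optional pre-computed `mzn_calibration` (e.g. reused
#'   across runs that must share the inhibition constant); if `NULL`,
#'   calibrated here.
#' @param granular An [mzn_granular()] parameter set.
#' @param law An [stellate_law()] object.
#' @param branching An [mzn_branching()] object.
#' @param n_eval_fields Calibration subsample size (see
#'   [calibrate_inhibition()]).
#' @param keep_input If `TRUE`, the (large) input layer object is kept on
#'   the result.
#' @return An object of class `mzn_network` with, notably, `layers` (named
#'   list of the realised value vectors: `mossy` terminal rates, `pf`
#'   active parallel fibre rates, `stellate`, `compartment`, `soma`,
#'   `nuclear`), `fraction` (per-field active fraction matrix), `density`
#'   (per-file), `calibration`, and the stage objects `stellate`,
#'   `purkinje`, `nuclear`.
#' @examples
#' run <- mzn_network("uniform", mzn_geometry(scale = 0.02), seed = 1)
#' print(run)
#' @export
mzn_network <- function(input = "uniform", geom = mzn_geometry(), seed = 1,
                        target = NULL, calibration = NULL,
                        granular = mzn_granular(), law = stellate_law(),
                        branching = mzn_branching(),
                        n_eval_fields = NULL, keep_input = FALSE) {
  stopifnot(inherits(geom, "mzn_geometry"))
  if (is.character(input)) {
    input <- switch(match.arg(input, c("uniform", "normal", "discontinuous")),
                    uniform = rank_uniform(),
                    normal = rank_normal(),
                    discontinuous = rank_discontinuous())
  }
  layer <- build_input_layer(input, geom, seed = seed, branching = branching)
  if (is.null(calibration)) {
    calibration <- calibrate_inhibition(layer, target = target,
                                        n_eval_fields = n_eval_fields,
                                        seed = seed)
  } else if (!inherits(calibration, "mzn_calibration")) {
    stop("'calibration' must be an mzn_calibration object", call. = FALSE)
  }
  activity <- run_granular(layer, params = granular,
                           scale = calibration$scale,
                           offset = calibration$offset, seed = seed)
  files <- assemble_file_codes(activity)
  stellate <- simulate_stellate_layer(files, geom, law = law, seed = seed)
  networks <- build_pc_networks(geom, seed = seed)
  purkinje <- integrate_pc(stellate, networks, seed = seed)
  nuclear <- project_to_nucleus(purkinje, geom, seed = seed)

  mossy <- unlist(lapply(layer$fields,
                         function(rank) lapply(rank, `[[`, "rates")),
                  use.names = FALSE)
  pf <- unlist(lapply(files$files, `[[`, "pf_rates"), use.names = FALSE)
  run <- structure(list(
    geom = geom, seed = seed, specs = layer$specs,
    calibration = calibration,
    layers = list(mossy = mossy, pf = pf,
                  stellate = stellate$output,
                  compartment = as.vector(purkinje$compartments),
                  soma = purkinje$soma,
                  nuclear = nuclear$output),
    fraction = activity$fraction,
    density = files$density,
    stellate = stellate, purkinje = purkinje, nuclear = nuclear),
    class = "mzn_network")
  if (keep_input) run$input_layer <- layer
  run
}

#' Per-layer summary statistics of a network run
#'
#' One row per layer of the cascade (mossy terminal rates, active parallel
#' fibre rates, stellate outputs, Purkinje compartments, somata, nuclear
#' outputs) with count, mean, SD, min, max and realised range.
#'
#' @param run An `mzn_network`.
#' @return A `data.frame` with columns `layer`, `n`, `mean`, `sd`, `min`,
#'   `max`, `range`.
#' @export
layer_summaries <- function(run) {
  stopifnot(inherits(run, "mzn_network"))
  wanted <- c("mossy", "pf", "stellate", "compartment", "soma", "nuclear")
  missing <- setdiff(wanted, names(run$layers))
  if (length(missing)) {
    stop("incomplete run: missing layer(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(wanted, function(nm) {
    v <- run$layers[[nm]]
    data.frame(layer = nm, n = length(v), mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), range = diff(range(v)))
  })
  do.call(rbind, rows)
}

#' Mean conservation along the sampling cascade
#'
#' Checks that the grand mean is conserved at every adjacent layer pair
#' from the parallel fibre code onwards (pf -> stellate -> compartment ->
#' soma -> nuclear): each layer is built by averaging random samples of the
#' one before, so their grand means should agree within sampling error.
#' The standard error is estimated from bootstrap resamples of the upstream
#' layer combined with the downstream layer's own spread.
#'
#' @param run An `mzn_network`.
#' @param n_boot Bootstrap resamples of the upstream layer (default 50).
#' @param seed Seed for the bootstrap.
#' @return A `data.frame` with `upstream`, `downstream`, the two means,
#'   `diff`, `se` and `z = diff / se`.
#' @export
mean_conservation <- function(run, n_boot = 50, seed = 1) {
  stopifnot(inherits(run, "mzn_network"))
  chain <- c("pf", "stellate", "compartment", "soma", "nuclear")
  .with_seed(seed, {
    rows <- lapply(seq_len(length(chain) - 1), function(i) {
      up <- run$layers[[chain[i]]]
      down <- run$layers[[chain[i + 1]]]
      boots <- vapply(seq_len(n_boot), function(b) {
        mean(up[sample.int(length(up), length(up), replace = TRUE)])
      }, 0)
      se <- sqrt(stats::var(boots) + stats::var(down) / length(down))
      d <- mean(down) - mean(up)
      data.frame(upstream = chain[i], downstream = chain[i + 1],
                 mean_up = mean(up), mean_down = mean(down),
                 diff = d, se = se, z = d / se)
    })
    do.call(rbind, rows)
  })
}

#' Linearity of layer means under shifted inputs
#'
#' Fits each layer's grand mean against the mossy grand mean over a set of
#' runs that differ only by a uniform shift of the input rates (all sharing
#' one calibrated inhibition constant). Along a linear cascade the slope is
#' 1 at every layer.
#'
#' @param runs A list of at least three `mzn_network` runs.
#' @return A `data.frame` with `layer`, `slope`, `intercept`, `r_squared`.
#' @seealso [shift_spec()] to build the shifted inputs.
#' @export
linearity_check <- function(runs) {
  if (length(runs) < 3) {
    stop("need at least 3 runs differing by an input shift", call. = FALSE)
  }
  stopifnot(all(vapply(runs, inherits, TRUE, "mzn_network")))
  x <- vapply(runs, function(r) mean(r$layers$mossy), 0)
  if (stats::sd(x) < sqrt(.Machine$double.eps)) {
    stop("insufficient variation: the runs' mossy means are identical",
         call. = FALSE)
  }
  layers <- c("pf", "stellate", "compartment", "soma", "nuclear")
  rows <- lapply(layers, function(nm) {
    y <- vapply(runs, function(r) mean(r$layers[[nm]]), 0)
    fit <- stats::lm(y ~ x)
    data.frame(layer = nm, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = summary(fit)$r.squared)
  })
  do.call(rbind, rows)
}

#' Density regulation table
#'
#' The per-field and per-file active-cell percentages of a run: local
#' regulation of the number of active granule cells in each field becomes
#' tighter regulation of the number of active parallel fibres in a file.
#'
#' @param run An `mzn_network`.
#' @return A list of class `mzn_density`: `field_pct` (one value per
#'   field), `file_pct` (one per file), `sd_field`, `sd_file`.
#' @export
density_regulation <- function(run) {
  stopifnot(inherits(run, "mzn_network"))
  field_pct <- 100 * as.vector(run$fraction)
  file_pct <- 100 * run$density
  structure(list(field_pct = field_pct, file_pct = file_pct,
                 sd_field = stats::sd(field_pct),
                 sd_file = stats::sd(file_pct)),
            class = "mzn_density")
}

#' @export
print.mzn_density <- function(x, ...) {
  cat(sprintf("Active-cell density: %d fields, %d files\n",
              length(x$field_pct), length(x$file_pct)))
  cat(sprintf("  field %%: mean %.3g, SD %.3g\n", mean(x$field_pct), x$sd_field))
  cat(sprintf("  file  %%: mean %.3g, SD %.3g\n", mean(x$file_pct), x$sd_file))
  invisible(x)
}

#' @export
print.mzn_network <- function(x, ...) {
  cat("Microzone network run (seed ", format(x$seed), ")\n", sep = "")
  cat(sprintf("  inhibition %s = %.4g; active fraction %.4g (target %.4g)\n",
              x$calibration$mode, x$calibration$value,
              mean(x$fraction), x$calibration$target))
  s <- layer_summaries(x)
  cat("  layer cascade:\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("    %-11s n=%8d  mean %7.2f  sd %7.3f  range %7.2f\n",
                s$layer[i], s$n[i], s$mean[i], s$sd[i], s$range[i]))
  }
  invisible(x)
}

#' @export
summary.mzn_network <- function(object, ...) {
  out <- list(layers = layer_summaries(object),
              density = density_regulation(object),
              conservation = mean_conservation(object),
              calibration = object$calibration)
  class(out) <- "summary.mzn_network"
  out
}

#' @export
print.summary.mzn_network <- function(x, ...) {
  print(x$calibration)
  cat("\nLayer summaries:\n")
  print(x$layers, row.names = FALSE, digits = 4)
  cat("\n")
  print(x$density)
  cat("\nMean conservation (z = diff/se):\n")
  print(x$conservation[, c("upstream", "downstream", "diff", "z")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.mzn_network <- function(x, ...) {
  do.call(rbind, lapply(names(x$layers), function(nm) {
    v <- x$layers[[nm]]
    data.frame(layer = nm, unit = seq_along(v), value = v)
  }))
}

#' @export
plot.mzn_network <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(x$layers)) {
    graphics::hist(x$layers[[nm]], breaks = 40, main = nm,
                   xlab = "rate (normalised Hz)", col = "grey80", border = NA)
  }
  invisible(x)
}

#' Export a network run as tidy CSV files
#'
#' Writes `layers.csv` (layer, unit, value), `field_fractions.csv`,
#' `file_densities.csv` and `summary.csv` under `dir`.
#'
#' @param run An `mzn_network`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_network_csv <- function(run, dir) {
  stopifnot(inherits(run, "mzn_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("layers.csv", "field_fractions.csv",
                            "file_densities.csv", "summary.csv"))
  utils::write.csv(as.data.frame(run), paths[1], row.names = FALSE)
  fr <- run$fraction
  utils::write.csv(data.frame(rank = rep(seq_len(nrow(fr)), ncol(fr)),
                              file = rep(seq_len(ncol(fr)), each = nrow(fr)),
                              fraction = as.vector(fr)),
                   paths[2], row.names = FALSE)
  utils::write.csv(data.frame(file = seq_along(run$density),
                              density = run$density),
                   paths[3], row.names = FALSE)
  utils::write.csv(layer_summaries(run), paths[4], row.names = FALSE)
  invisible(paths)
}
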