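# Nuclear output layer: convergent random sampling of Purkinje outputs.

#' Project Purkinje outputs onto the nuclear group
#'
#' Each of the ~50 output cells of the nuclear group draws a uniformly
#' random sample size in `[nuclear_sample_min, nuclear_sample_max]`,
#' samples that many Purkinje somatic values without replacement from the
#' whole microzone, and outputs their mean.
#'
#' @param pcs An `mzn_purkinje` from [integrate_pc()], or a plain numeric
#'   vector of Purkinje somatic values.
#' @param geom An [mzn_geometry()] object.
#' @param seed Master seed for the stage.
#' @return An object of class `mzn_nuclear`: `output` (one rate per cell)
#'   and `sample_size`.
#' @export
project_to_nucleus <- function(pcs, geom, seed = 1) {
  stopifnot(inherits(geom, "mzn_geometry"))
  soma <- if (inherits(pcs, "mzn_purkinje")) pcs$soma else as.numeric(pcs)
  if (length(soma) < geom$nuclear_sample_max) {
    stop(sprintf("need at least nuclear_sample_max = %d Purkinje values, got %d",
                 geom$nuclear_sample_max, length(soma)), call. = FALSE)
  }
  .with_seed(mzn_substream(seed, "nuclear", 0L), {
    sizes <- sample(geom$nuclear_sample_min:geom$nuclear_sample_max,
                    geom$nuclear_cells, replace = TRUE)
    output <- vapply(sizes, function(sz) mean(soma[sample.int(length(soma), sz)]), 0)
    structure(list(output = output, sample_size = sizes, geom = geom,
                   seed = seed),
              class = "mzn_nuclear")
  })
}

#' @export
print.mzn_nuclear <- function(x, ...) {
  cat(sprintf("Nuclear group: %d output cells (samples of %d-%d Purkinje cells)\n",
              length(x$output), min(x$sample_size), max(x$sample_size)))
  cat(sprintf("  output mean %.3g, SD %.3g\n", mean(x$output), stats::sd(x$output)))
  invisible(x)
}
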