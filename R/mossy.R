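# Mossy fibre terminal branching and clustering: the replacement facsimile.
#
# Each mossy fibre terminates in a spaced-out sagittal row of terminal
# clusters (non-adjacent fields of its rank); cluster size is randomly
# variable and most clusters straddle field limits, splitting their
# terminals between neighbouring fields. The combined effect is that the
# rates received by any one field behave like an independent random sample,
# with replacement, of the rates received by the whole rank, even though
# each field holds fixed contacts from a small set of fibres.

#' Terminal branching and clustering parameters
#'
#' @param clusters_min,clusters_max Terminal clusters per mossy fibre
#'   (uniform integer, default 4-12), placed along the rank with a minimum
#'   centre-to-centre separation of `min_gap` fields (clusters are about a
#'   field wide and are separated by at least 200 um edge to edge, so their
#'   footprints are disjoint). On short ranks the cluster count is clamped
#'   to `fields_per_rank / min_gap`.
#' @param terminals_min,terminals_max Terminals per cluster (uniform
#'   integer, default 2-7).
#' @param max_field_share Cap on the terminals a single cluster leaves in
#'   one field (default 4, well under 1% of a ~700-terminal field); larger
#'   clusters necessarily straddle the field boundary, with the overflow
#'   split to the adjacent field. Must be at least `terminals_max / 2`.
#' @param min_gap Minimum circular centre-to-centre cluster separation in
#'   fields (default 3, which keeps the two-field footprints of a fibre's
#'   clusters disjoint).
#' @return An object of class `mzn_branching`.
#' @export
mzn_branching <- function(clusters_min = 4, clusters_max = 12,
                          terminals_min = 2, terminals_max = 7,
                          max_field_share = 4, min_gap = 3) {
  b <- list(clusters_min = .check_count(clusters_min, "clusters_min"),
            clusters_max = .check_count(clusters_max, "clusters_max"),
            terminals_min = .check_count(terminals_min, "terminals_min"),
            terminals_max = .check_count(terminals_max, "terminals_max"),
            max_field_share = .check_count(max_field_share, "max_field_share"),
            min_gap = .check_count(min_gap, "min_gap", min = 2))
  if (b$clusters_max < b$clusters_min || b$terminals_max < b$terminals_min) {
    stop("branching ranges must have max >= min", call. = FALSE)
  }
  if (2 * b$max_field_share < b$terminals_max) {
    stop("max_field_share must be at least terminals_max / 2 ",
         "(a straddling cluster has only two fields to land in)", call. = FALSE)
  }
  class(b) <- "mzn_branching"
  b
}

# Sample k positions on a circle of f fields with all circular gaps >= g,
# uniformly over valid sets: uniform start, plus a uniform composition of
# the slack f - k*g over the k gaps (stars and bars). Every valid set is
# reached by exactly k (start, composition) pairs, so sets are
# equiprobable.
.clustered_positions <- function(f, k, g) {
  if (k == 1) return(sample.int(f, 1))
  slack <- f - k * g
  if (slack < 0) stop("too many clusters for the number of fields", call. = FALSE)
  cuts <- sort(sample.int(slack + k - 1, k - 1))
  extra <- diff(c(0L, cuts, slack + k)) - 1L  # k parts summing to slack
  gaps <- g + extra
  start <- sample.int(f, 1)
  ((start + cumsum(c(0L, gaps[-k])) - 1L) %% f) + 1L
}

#' Distribute one rank's mossy fibre rates over its fields
#'
#' Assigns every mossy fibre a random number of terminal clusters along the
#' rank (minimum centre separation `min_gap` fields) and a random terminal
#' count per cluster, then splits each cluster binomially (random overlap
#' fraction) between its field and the adjacent field, so that most
#' clusters straddle field limits; a single cluster never leaves more than
#' `max_field_share` terminals in one field. Fields are nominal
#' subdivisions, so the rank is treated as circular to avoid artificial
#' end-of-row terminal deficits. Uses the current RNG stream.
#'
#' @param rank_rates Firing rate of each mossy fibre in the rank (Hz).
#' @param geom An [mzn_geometry()] object.
#' @param branching An [mzn_branching()] object.
#' @return A list with one element per field, each a list with `rates`
#'   (terminal-level rates, one entry per terminal) and `source` (the mossy
#'   fibre index behind each terminal).
#' @export
distribute_to_fields <- function(rank_rates, geom, branching = mzn_branching()) {
  stopifnot(inherits(geom, "mzn_geometry"), inherits(branching, "mzn_branching"))
  n_mossy <- length(rank_rates)
  if (n_mossy == 0) stop("rank_rates must be non-empty", call. = FALSE)
  f <- geom$fields_per_rank

  kmax <- min(branching$clusters_max, f %/% branching$min_gap)
  kmin <- min(branching$clusters_min, kmax)
  k <- sample(kmin:kmax, n_mossy, replace = TRUE)
  pos <- integer(sum(k))
  fib <- rep.int(seq_len(n_mossy), k)
  at <- 1L
  for (i in seq_len(n_mossy)) {
    pos[at:(at + k[i] - 1L)] <- .clustered_positions(f, k[i], branching$min_gap)
    at <- at + k[i]
  }
  n_cl <- length(pos)
  size <- sample(branching$terminals_min:branching$terminals_max, n_cl, replace = TRUE)
  # Straddle: a uniform fraction of each cluster overlaps the neighbouring
  # field; the per-field parts are clamped so neither exceeds the share cap.
  dir <- sample(c(-1L, 1L), n_cl, replace = TRUE)
  nb <- ((pos + dir - 1L) %% f) + 1L
  keep <- stats::rbinom(n_cl, size, 1 - stats::runif(n_cl))
  cap <- branching$max_field_share
  keep <- pmin(pmax(keep, size - cap), cap)

  field <- c(rep.int(pos, keep), rep.int(nb, size - keep))
  src <- c(rep.int(fib, keep), rep.int(fib, size - keep))
  ord <- order(field)
  field <- field[ord]
  src <- src[ord]
  bounds <- findInterval(0:f, field)  # counts per field via sorted positions
  out <- vector("list", f)
  for (j in seq_len(f)) {
    idx <- if (bounds[j + 1] > bounds[j]) src[(bounds[j] + 1):bounds[j + 1]] else integer(0)
    out[[j]] <- list(rates = rank_rates[idx], source = idx)
  }
  out
}

#' Build the full mossy fibre input layer
#'
#' Draws every rank's mossy fibre rates from its input specification and
#' distributes them over the rank's fields via terminal branching and
#' clustering. Each rank uses its own RNG substream keyed by
#' `(seed, rank_index)`, so the grid is reproducible independently of
#' execution order.
#'
#' @param specs A single `mzn_rank_spec` (recycled over ranks) or a list of
#'   one spec per rank.
#' @param geom An [mzn_geometry()] object.
#' @param seed Master seed for the layer.
#' @param branching An [mzn_branching()] object.
#' @return An object of class `mzn_input_layer`: a list with `fields` (a
#'   `n_ranks` x `fields_per_rank` list grid, see [distribute_to_fields()]),
#'   the generating `specs`, `geom`, `seed` and `branching`.
#' @examples
#' g <- mzn_geometry(scale = 0.02)
#' layer <- build_input_layer(rank_uniform(), g, seed = 1)
#' length(layer$fields[[1]])  # fields in rank 1
#' @export
build_input_layer <- function(specs, geom, seed = 1,
                              branching = mzn_branching()) {
  stopifnot(inherits(geom, "mzn_geometry"))
  if (inherits(specs, "mzn_rank_spec")) {
    specs <- rep(list(specs), geom$n_ranks)
  }
  if (length(specs) != geom$n_ranks) {
    stop(sprintf("need one rank spec per rank: got %d specs for %d ranks",
                 length(specs), geom$n_ranks), call. = FALSE)
  }
  mossy_per_rank <- geom$mossy_fibres_total %/% geom$n_ranks
  fields <- vector("list", geom$n_ranks)
  for (r in seq_len(geom$n_ranks)) {
    fields[[r]] <- .with_seed(mzn_substream(seed, "input", r), {
      rates <- draw_rank_rates(specs[[r]], mossy_per_rank, r, geom$n_ranks)
      distribute_to_fields(rates, geom, branching)
    })
  }
  structure(list(fields = fields, specs = specs, geom = geom, seed = seed,
                 branching = branching),
            class = "mzn_input_layer")
}

#' @export
print.mzn_input_layer <- function(x, ...) {
  counts <- field_terminal_counts(x)
  cat(sprintf("Mossy fibre input layer: %d ranks x %d fields (seed %s)\n",
              x$geom$n_ranks, x$geom$fields_per_rank, format(x$seed)))
  cat(sprintf("  terminals per field: mean %.0f (range %d-%d, target ~%d)\n",
              mean(counts), min(counts), max(counts),
              x$geom$terminals_per_field_target))
  kinds <- vapply(x$specs, `[[`, "", "kind")
  cat("  rank input kinds: ", paste(unique(kinds), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Terminal counts per field
#'
#' @param layer An `mzn_input_layer`.
#' @return Matrix (`n_ranks` x `fields_per_rank`) of terminal counts.
#' @export
field_terminal_counts <- function(layer) {
  stopifnot(inherits(layer, "mzn_input_layer"))
  t(vapply(layer$fields,
           function(rank) vapply(rank, function(fd) length(fd$rates), 0L),
           integer(layer$geom$fields_per_rank)))
}

#' Largest single-fibre share of a field's terminals
#'
#' @param layer An `mzn_input_layer`.
#' @return Matrix of the maximum fraction of any field's terminals
#'   contributed by a single mossy fibre (0 for empty fields).
#' @export
max_source_share <- function(layer) {
  stopifnot(inherits(layer, "mzn_input_layer"))
  t(vapply(layer$fields, function(rank) {
    vapply(rank, function(fd) {
      if (!length(fd$source)) return(0)
      max(tabulate(fd$source)) / length(fd$source)
    }, 0)
  }, numeric(layer$geom$fields_per_rank)))
}
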