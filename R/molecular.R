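# Molecular layer: the binomial stellate contact law, stellate unit
# outputs, Purkinje flank networks, dendritic-compartment sampling and
# somatic integration.

#' The binomial stellate contact law
#'
#' Under the sparse code ~420 parallel fibres crossing an inner-level
#' stellate territory are active, and each makes contact independently
#' with probability ~1/84, so the number of active inputs a stellate cell
#' receives is Binomial(420, 0.0119). The default `p_contact = 0.0119`
#' reproduces the printed probability table to 4 decimal places; set
#' `p_contact = 1000/84000` for the unrounded contact ratio.
#'
#' @param n_active Number of active parallel fibres through the territory
#'   (trial count, default 420).
#' @param p_contact Per-fibre contact probability (default 0.0119).
#' @param truncate_zero If `TRUE` (default), sample sizes drawn from the
#'   law are truncated to at least 1, since the mean-of-inputs unit
#'   function is undefined on an empty sample.
#' @return An object of class `mzn_stellate_law`.
#' @seealso [stellate_pmf()], [simulate_stellate_layer()]
#' @export
stellate_law <- function(n_active = 420, p_contact = 0.0119,
                         truncate_zero = TRUE) {
  n_active <- .check_count(n_active, "n_active")
  if (!(p_contact > 0 && p_contact < 1)) {
    stop("'p_contact' must be in (0, 1)", call. = FALSE)
  }
  structure(list(n_active = n_active, p_contact = p_contact,
                 truncate_zero = isTRUE(truncate_zero)),
            class = "mzn_stellate_law")
}

#' Probability mass of the stellate contact law
#'
#' @param x Number of active parallel fibres making contact; all values
#'   must lie in `0..n_active`.
#' @param law An [stellate_law()] object.
#' @return `P(X = x)` under Binomial(`n_active`, `p_contact`) (the
#'   untruncated law; truncation only affects sampling).
#' @examples
#' round(stellate_pmf(0:5, stellate_law()), 4)
#' @export
stellate_pmf <- function(x, law = stellate_law()) {
  stopifnot(inherits(law, "mzn_stellate_law"))
  if (any(x < 0 | x > law$n_active | x != round(x))) {
    stop("'x' must be integers in 0..n_active", call. = FALSE)
  }
  stats::dbinom(x, law$n_active, law$p_contact)
}

# Draw m sample sizes from the law (vectorised), honouring truncation.
.draw_sample_sizes <- function(m, law) {
  x <- stats::rbinom(m, law$n_active, law$p_contact)
  if (law$truncate_zero) {
    while (any(x == 0)) {
      z <- x == 0
      x[z] <- stats::rbinom(sum(z), law$n_active, law$p_contact)
    }
  }
  x
}

#' Simulate the stellate cell layer
#'
#' For every stellate unit (80 per sector), draws its number of active
#' inputs from the contact law and averages that many parallel fibre rates
#' sampled from the sector's file pool (without replacement when the pool
#' allows). Units sample only signals in their own file.
#'
#' @param files An `mzn_file_codes` from [assemble_file_codes()], or a
#'   plain list of numeric rate pools (one per sector).
#' @param geom An [mzn_geometry()] object.
#' @param law An [stellate_law()] object.
#' @param seed Master seed for the stage.
#' @return An object of class `mzn_stellate`: `output` (one rate per unit,
#'   `stellate_total` in all), `sector`, `depth_layer` (1-5, outermost
#'   first) and `n_inputs` per unit.
#' @export
simulate_stellate_layer <- function(files, geom, law = stellate_law(),
                                    seed = 1) {
  stopifnot(inherits(geom, "mzn_geometry"))
  pools <- if (inherits(files, "mzn_file_codes")) {
    lapply(files$files, `[[`, "pf_rates")
  } else {
    files
  }
  n_sectors <- geom$fields_per_rank
  if (length(pools) != n_sectors) {
    stop(sprintf("need %d file pools (one per sector), got %d",
                 n_sectors, length(pools)), call. = FALSE)
  }
  m <- geom$stellate_per_sector
  per_layer <- geom$stellate_per_flank
  output <- numeric(n_sectors * m)
  n_inputs <- integer(n_sectors * m)
  for (s in seq_len(n_sectors)) {
    pool <- pools[[s]]
    if (!length(pool)) {
      stop("degenerate input: file pool for sector ", s, " is empty",
           call. = FALSE)
    }
    at <- (s - 1L) * m
    .with_seed(mzn_substream(seed, "stellate", s), {
      x <- .draw_sample_sizes(m, law)
      np <- length(pool)
      for (i in seq_len(m)) {
        take <- if (x[i] <= np) sample.int(np, x[i]) else
          sample.int(np, x[i], replace = TRUE)
        output[at + i] <- mean(pool[take])
      }
      n_inputs[(at + 1L):(at + m)] <- x
    })
  }
  structure(list(output = output,
                 sector = rep(seq_len(n_sectors), each = m),
                 depth_layer = rep(rep(seq_len(5L), each = per_layer),
                                   times = n_sectors),
                 n_inputs = n_inputs,
                 geom = geom, law = law, seed = seed),
            class = "mzn_stellate")
}

#' @export
print.mzn_stellate <- function(x, ...) {
  cat(sprintf("Stellate layer: %d unit outputs (%d sectors x %d units)\n",
              length(x$output), max(x$sector), x$geom$stellate_per_sector))
  cat(sprintf("  inputs per unit: mean %.2f; output mean %.3g, SD %.3g\n",
              mean(x$n_inputs), mean(x$output), stats::sd(x$output)))
  invisible(x)
}

#' Build Purkinje flank afferent networks
#'
#' Each Purkinje cell receives inhibition from two flanking stellate
#' networks. Each flank is 16 of the 80 stellate units of the cell's own
#' sector plus up to 8 more from each sagittally neighbouring sector;
#' neighbour afferents are restricted to inner-level depth layers (outer
#' layers have too short a horizontal axon range), and edge sectors simply
#' lack one neighbour.
#'
#' @param geom An [mzn_geometry()] object.
#' @param seed Master seed for the stage.
#' @return An object of class `mzn_pc_networks`: a list `sectors`, each
#'   holding `pcs_per_sector` elements of two integer vectors of global
#'   stellate unit indices (`flank1`, `flank2`).
#' @export
build_pc_networks <- function(geom, seed = 1) {
  stopifnot(inherits(geom, "mzn_geometry"))
  n_sectors <- geom$fields_per_rank
  m <- geom$stellate_per_sector
  per_layer <- geom$stellate_per_flank
  inner_layers <- setdiff(seq_len(5L), geom$outer_depth_layers)
  inner_local <- unlist(lapply(inner_layers,
                               function(l) (l - 1L) * per_layer + seq_len(per_layer)))
  kmax <- geom$neighbour_stellate_max
  sectors <- vector("list", n_sectors)
  for (s in seq_len(n_sectors)) {
    pcs <- vector("list", geom$pcs_per_sector)
    .with_seed(mzn_substream(seed, "networks", s), {
      for (p in seq_len(geom$pcs_per_sector)) {
        flanks <- lapply(1:2, function(fl) {
          own <- (s - 1L) * m + sample.int(m, geom$stellate_per_flank)
          nb <- integer(0)
          for (ns in c(s - 1L, s + 1L)) {
            if (ns < 1L || ns > n_sectors) next
            k <- sample.int(kmax + 1L, 1L) - 1L  # uniform 0..kmax
            if (k > 0) {
              nb <- c(nb, (ns - 1L) * m + sample(inner_local, k))
            }
          }
          c(own, nb)
        })
        pcs[[p]] <- list(flank1 = flanks[[1]], flank2 = flanks[[2]])
      }
    })
    sectors[[s]] <- pcs
  }
  structure(list(sectors = sectors, geom = geom, seed = seed),
            class = "mzn_pc_networks")
}

#' Purkinje compartment sampling and somatic integration
#'
#' For each Purkinje cell, every dendritic compartment independently
#' averages `compartment_sample_size` stellate unit outputs sampled without
#' replacement from each flanking network (a unit may serve many
#' compartments); the compartment value is the mean over the two flanks and
#' the somatic value the mean over compartments.
#'
#' @param stellate An `mzn_stellate` from [simulate_stellate_layer()].
#' @param networks An `mzn_pc_networks` from [build_pc_networks()].
#' @param seed Master seed for the stage.
#' @return An object of class `mzn_purkinje`: `soma` (one value per
#'   Purkinje cell), `compartments` (matrix `compartments_per_pc` x
#'   `pcs_total`, flank-averaged), `compartments_flank1` (same but from the
#'   first flank only) and `sector` per cell.
#' @export
integrate_pc <- function(stellate, networks, seed = 1) {
  stopifnot(inherits(stellate, "mzn_stellate"),
            inherits(networks, "mzn_pc_networks"))
  geom <- networks$geom
  n_sectors <- length(networks$sectors)
  npc <- geom$pcs_per_sector
  nc <- geom$compartments_per_pc
  k <- geom$compartment_sample_size
  out <- stellate$output
  soma <- numeric(n_sectors * npc)
  comp <- matrix(NA_real_, nc, n_sectors * npc)
  comp1 <- matrix(NA_real_, nc, n_sectors * npc)
  for (s in seq_len(n_sectors)) {
    .with_seed(mzn_substream(seed, "purkinje", s), {
      for (p in seq_len(npc)) {
        net <- networks$sectors[[s]][[p]]
        for (fl in 1:2) {
          ids <- if (fl == 1) net$flank1 else net$flank2
          if (length(ids) < k) {
            stop("flank network smaller than the compartment sample size",
                 call. = FALSE)
          }
          vals <- vapply(seq_len(nc), function(ci) {
            mean(out[ids[sample.int(length(ids), k)]])
          }, 0)
          if (fl == 1) {
            comp1[, (s - 1L) * npc + p] <- vals
            comp[, (s - 1L) * npc + p] <- vals
          } else {
            comp[, (s - 1L) * npc + p] <-
              (comp[, (s - 1L) * npc + p] + vals) / 2
          }
        }
        soma[(s - 1L) * npc + p] <- mean(comp[, (s - 1L) * npc + p])
      }
    })
  }
  structure(list(soma = soma, compartments = comp,
                 compartments_flank1 = comp1,
                 sector = rep(seq_len(n_sectors), each = npc),
                 geom = geom, seed = seed),
            class = "mzn_purkinje")
}

#' @export
print.mzn_purkinje <- function(x, ...) {
  cat(sprintf("Purkinje layer: %d somatic outputs (%d compartments each)\n",
              length(x$soma), nrow(x$compartments)))
  cat(sprintf("  soma mean %.3g, SD %.3g, range %.3g\n",
              mean(x$soma), stats::sd(x$soma), diff(range(x$soma))))
  invisible(x)
}
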