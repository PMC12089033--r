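#' Network geometry: anatomical counts and dimensions
#'
#' Builds the geometry object that parameterises a whole microzone network:
#' the granular input layer (41 sagittal ranks x 100 fields per rank, each
#' field nominally 200 x 150 um with ~700 mossy fibre terminals and 9000
#' granule cells), the molecular middle layer (100 sectors, 4 Purkinje and
#' 80 stellate cells per sector) and the deep-nuclear output group (~50
#' cells, each sampling 30-50 Purkinje cells). Defaults reproduce the
#' printed anatomy; every count is configurable.
#'
#' @param n_ranks Number of sagittal granular-layer ranks feeding the
#'   middle microzone (default 41: 20 each side plus one beneath).
#' @param fields_per_rank Fields per rank; also the number of files and of
#'   microzone sectors (default 100).
#' @param field_sagittal_um,field_mediolateral_um Field footprint in um.
#' @param glomeruli_per_field Glomeruli receiving Golgi inhibition (700).
#' @param granule_per_field Granule cells per field (9000).
#' @param mossy_fibres_total Mossy fibres across the whole input layer
#'   (~80000), allocated evenly over ranks.
#' @param terminals_per_field_target Intended mean terminal count per field
#'   (~700).
#' @param pcs_per_sector Purkinje cells per sector (4).
#' @param stellate_per_sector Stellate cells per sector (80); must equal
#'   five depth layers of `stellate_per_flank`.
#' @param stellate_per_flank Same-sector stellate cells afferent to one
#'   Purkinje cell flank (16).
#' @param neighbour_stellate_max Maximum extra afferents recruited from
#'   each sagittally neighbouring sector (8).
#' @param outer_depth_layers Depth layers (of 5) counted as outer-level and
#'   hence ineligible to reach neighbouring sectors (default `1:2`).
#' @param compartments_per_pc Nominal 50 x 75 um dendritic compartments per
#'   Purkinje cell (16).
#' @param compartment_sample_size Stellate units averaged by one
#'   compartment per flank (6).
#' @param nuclear_cells Output cells in the nuclear group (50).
#' @param nuclear_sample_min,nuclear_sample_max Bounds on the number of
#'   Purkinje cells sampled by one output cell (30, 50).
#' @param pf_through_pc Parallel fibres passing through one Purkinje cell
#'   territory (350000).
#' @param pc_territory_sagittal_um,pc_territory_depth_um Purkinje territory
#'   plane in the sagittal/depth dimensions (200 x 300 um).
#' @param stellate_inner_territory_um Side of the (square) inner-level
#'   stellate dendritic territory (120 um).
#' @param pf_contacting_stellate Parallel fibres contacting one stellate
#'   cell (1000).
#' @param active_fraction_target Regulated fraction of co-active parallel
#'   fibres (0.005).
#' @param scale Density scale factor in (0, 1]; scales the per-field cell
#'   and terminal complement (granule cells, glomeruli, mossy fibres,
#'   terminal target) while preserving the rank/file topology. Used for
#'   reduced-size runs; 1 is the full network.
#' @return An object of class `mzn_geometry` (a named list).
#' @seealso [mzn_counts()] for the derived-count report,
#'   [pf_through_territory()] and [active_pf_count()] for the territory
#'   arithmetic the defaults encode.
#' @examples
#' g <- mzn_geometry()
#' mzn_counts(g)$n_fields   # 4100
#' @export
mzn_geometry <- function(n_ranks = 41,
                         fields_per_rank = 100,
                         field_sagittal_um = 200,
                         field_mediolateral_um = 150,
                         glomeruli_per_field = 700,
                         granule_per_field = 9000,
                         mossy_fibres_total = 80000,
                         terminals_per_field_target = 700,
                         pcs_per_sector = 4,
                         stellate_per_sector = 80,
                         stellate_per_flank = 16,
                         neighbour_stellate_max = 8,
                         outer_depth_layers = 1:2,
                         compartments_per_pc = 16,
                         compartment_sample_size = 6,
                         nuclear_cells = 50,
                         nuclear_sample_min = 30,
                         nuclear_sample_max = 50,
                         pf_through_pc = 350000,
                         pc_territory_sagittal_um = 200,
                         pc_territory_depth_um = 300,
                         stellate_inner_territory_um = 120,
                         pf_contacting_stellate = 1000,
                         active_fraction_target = 0.005,
                         scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0 || scale > 1) {
    stop("'scale' must be a single number in (0, 1]", call. = FALSE)
  }
  if (scale < 1) {
    glomeruli_per_field <- max(10L, round(glomeruli_per_field * scale))
    granule_per_field <- max(20L, round(granule_per_field * scale))
    mossy_fibres_total <- max(10L * n_ranks, round(mossy_fibres_total * scale))
    terminals_per_field_target <- max(20L, round(terminals_per_field_target * scale))
  }
  geom <- list(
    n_ranks = .check_count(n_ranks, "n_ranks"),
    fields_per_rank = .check_count(fields_per_rank, "fields_per_rank", min = 2),
    field_sagittal_um = .check_positive(field_sagittal_um, "field_sagittal_um"),
    field_mediolateral_um = .check_positive(field_mediolateral_um, "field_mediolateral_um"),
    glomeruli_per_field = .check_count(glomeruli_per_field, "glomeruli_per_field"),
    granule_per_field = .check_count(granule_per_field, "granule_per_field"),
    mossy_fibres_total = .check_count(mossy_fibres_total, "mossy_fibres_total"),
    terminals_per_field_target = .check_count(terminals_per_field_target, "terminals_per_field_target"),
    pcs_per_sector = .check_count(pcs_per_sector, "pcs_per_sector"),
    stellate_per_sector = .check_count(stellate_per_sector, "stellate_per_sector"),
    stellate_per_flank = .check_count(stellate_per_flank, "stellate_per_flank"),
    neighbour_stellate_max = .check_count(neighbour_stellate_max, "neighbour_stellate_max", min = 0),
    outer_depth_layers = as.integer(outer_depth_layers),
    compartments_per_pc = .check_count(compartments_per_pc, "compartments_per_pc"),
    compartment_sample_size = .check_count(compartment_sample_size, "compartment_sample_size"),
    nuclear_cells = .check_count(nuclear_cells, "nuclear_cells"),
    nuclear_sample_min = .check_count(nuclear_sample_min, "nuclear_sample_min"),
    nuclear_sample_max = .check_count(nuclear_sample_max, "nuclear_sample_max"),
    pf_through_pc = .check_count(pf_through_pc, "pf_through_pc"),
    pc_territory_sagittal_um = .check_positive(pc_territory_sagittal_um, "pc_territory_sagittal_um"),
    pc_territory_depth_um = .check_positive(pc_territory_depth_um, "pc_territory_depth_um"),
    stellate_inner_territory_um = .check_positive(stellate_inner_territory_um, "stellate_inner_territory_um"),
    pf_contacting_stellate = .check_count(pf_contacting_stellate, "pf_contacting_stellate"),
    active_fraction_target = active_fraction_target,
    scale = scale
  )
  class(geom) <- "mzn_geometry"
  mzn_counts(geom)  # side effect: raises on any violated invariant
  geom
}

#' Derived-count report for a network geometry
#'
#' Recomputes every derived count from the configuration and checks the
#' structural invariants (field grid size, one sector per file, five depth
#' layers of stellate cells, nuclear sampling bounds). This is the
#' validation entry point: it raises a configuration error naming the
#' failing relation.
#'
#' @param geom An [mzn_geometry()] object.
#' @return A list with `n_fields`, `n_sectors`, `stellate_total`,
#'   `pcs_total`, `compartment_total`, `mossy_per_rank` and
#'   `active_pf_per_stellate_territory`.
#' @examples
#' mzn_counts(mzn_geometry())
#' @export
mzn_counts <- function(geom) {
  stopifnot(inherits(geom, "mzn_geometry"))
  fail <- function(relation) {
    stop("geometry invariant violated: ", relation, call. = FALSE)
  }
  if (geom$stellate_per_sector != 5L * geom$stellate_per_flank) {
    fail("stellate_per_sector == 5 * stellate_per_flank (five depth layers)")
  }
  if (geom$nuclear_sample_min > geom$nuclear_sample_max) {
    fail("nuclear_sample_min <= nuclear_sample_max")
  }
  if (!(0 <= geom$active_fraction_target && geom$active_fraction_target <= 1)) {
    fail("active_fraction_target in [0, 1]")
  }
  if (length(geom$outer_depth_layers) &&
      (any(geom$outer_depth_layers < 1) || any(geom$outer_depth_layers > 5))) {
    fail("outer_depth_layers within 1..5")
  }
  if (5L - length(geom$outer_depth_layers) < 1L) {
    fail("at least one inner depth layer")
  }
  n_sectors <- geom$fields_per_rank
  pcs_total <- geom$pcs_per_sector * n_sectors
  if (geom$nuclear_sample_max > pcs_total) {
    fail("nuclear_sample_max <= pcs_total")
  }
  if (geom$mossy_fibres_total < geom$n_ranks) {
    fail("mossy_fibres_total >= n_ranks")
  }
  list(
    n_fields = geom$n_ranks * geom$fields_per_rank,
    n_sectors = n_sectors,
    stellate_total = geom$stellate_per_sector * n_sectors,
    pcs_total = pcs_total,
    compartment_total = geom$compartments_per_pc * pcs_total,
    mossy_per_rank = geom$mossy_fibres_total %/% geom$n_ranks,
    active_pf_per_stellate_territory = active_pf_count(
      pf_through_territory(geom$pf_through_pc,
                           geom$pc_territory_sagittal_um,
                           geom$pc_territory_depth_um,
                           geom$stellate_inner_territory_um),
      geom$active_fraction_target)
  )
}

#' Parallel fibres passing through a stellate dendritic territory
#'
#' Scales the number of parallel fibres crossing a Purkinje cell territory
#' down to the (square) territory of an inner-level stellate cell, assuming
#' parallel fibres are uniformly distributed in the sagittal plane:
#' `a / ((b * c) / t^2)`, rounded to the nearest integer. With the default
#' anatomy (350000 fibres through a 200 x 300 um Purkinje plane, 120 um
#' stellate territory) this gives ~84000.
#'
#' @param a Parallel fibres through the reference (Purkinje) territory.
#' @param b,c Reference territory dimensions in um.
#' @param t Side of the square stellate territory in um.
#' @return Integer count of fibres through the stellate territory.
#' @examples
#' pf_through_territory(350000, 200, 300, 120)  # 84000
#' @export
pf_through_territory <- function(a, b, c, t) {
  for (nm in c("a", "b", "c", "t")) .check_positive(get(nm), nm)
  round(a / ((b * c) / t^2))
}

#' Number of active parallel fibres in a population
#'
#' @param passing Total parallel fibres passing through the territory.
#' @param active_fraction Fraction of the general population active at any
#'   moment (the sparse-code density), in `[0, 1]`.
#' @return `round(passing * active_fraction)`. With 84000 passing fibres and
#'   the 0.5% sparse code this is 420 — the trial count of the stellate
#'   contact law.
#' @examples
#' active_pf_count(84000, 0.005)  # 420
#' @export
active_pf_count <- function(passing, active_fraction) {
  .check_positive(passing, "passing")
  if (length(active_fraction) != 1 || !is.finite(active_fraction) ||
      active_fraction < 0 || active_fraction > 1) {
    stop("'active_fraction' must be a single number in [0, 1]", call. = FALSE)
  }
  round(passing * active_fraction)
}

#' @export
print.mzn_geometry <- function(x, ...) {
  cts <- mzn_counts(x)
  cat("Microzone network geometry",
      if (x$scale < 1) sprintf("(density scale %.3g)", x$scale) else "", "\n")
  cat(sprintf("  input layer : %d ranks x %d fields = %d fields (%d glomeruli, %d granule cells / field)\n",
              x$n_ranks, x$fields_per_rank, cts$n_fields,
              x$glomeruli_per_field, x$granule_per_field))
  cat(sprintf("  mossy fibres: %d total (~%d per rank, ~%d terminals per field)\n",
              x$mossy_fibres_total, cts$mossy_per_rank, x$terminals_per_field_target))
  cat(sprintf("  microzone   : %d sectors; %d stellate (%d/sector), %d Purkinje (%d/sector), %d compartments\n",
              cts$n_sectors, cts$stellate_total, x$stellate_per_sector,
              cts$pcs_total, x$pcs_per_sector, cts$compartment_total))
  cat(sprintf("  nuclear     : %d output cells sampling %d-%d Purkinje cells\n",
              x$nuclear_cells, x$nuclear_sample_min, x$nuclear_sample_max))
  cat(sprintf("  sparse code : %.3g%% of %d pf through a stellate territory -> %d active\n",
              100 * x$active_fraction_target,
              pf_through_territory(x$pf_through_pc, x$pc_territory_sagittal_um,
                                   x$pc_territory_depth_um, x$stellate_inner_territory_um),
              cts$active_pf_per_stellate_territory))
  invisible(x)
}
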