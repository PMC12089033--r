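# Shared fixtures and independent oracles for the test suite.
# The oracles deliberately use naive loop implementations, independent of
# the package's vectorised code paths.

# Small geometries preserving the full rank/file topology at reduced
# per-field density.
tiny_geom <- function(fields_per_rank = 20, n_ranks = 11, scale = 0.05, ...) {
  mzn_geometry(n_ranks = n_ranks, fields_per_rank = fields_per_rank,
               scale = scale, ...)
}

swim_geom <- function() mzn_geometry(scale = 0.06, fields_per_rank = 30)

# Naive granule firing oracle: one cell at a time, one dendrite at a time.
oracle_granule_fraction <- function(rates, inhibition, n_granule,
                                    dendrites = 4, min_wins = 3) {
  fires <- 0L
  for (i in seq_len(n_granule)) {
    wins <- 0L
    for (d in seq_len(dendrites)) {
      e <- rates[sample.int(length(rates), 1)]
      v <- inhibition[sample.int(length(inhibition), 1)]
      if (e > v) wins <- wins + 1L
    }
    if (wins >= min_wins) fires <- fires + 1L
  }
  fires / n_granule
}

# Naive two-stage inhibition oracle: returns one field's worth of
# glomerular inhibition values.
oracle_inhibition <- function(rates, n_golgi = 10, golgi_sample = 4,
                              glom_sample = 4, n_glom = 700,
                              scale = 1, offset = 0) {
  golgi <- numeric(n_golgi)
  for (g in seq_len(n_golgi)) {
    s <- 0
    for (j in seq_len(golgi_sample)) s <- s + rates[sample.int(length(rates), 1)]
    golgi[g] <- s / golgi_sample
  }
  inh <- numeric(n_glom)
  for (k in seq_len(n_glom)) {
    s <- 0
    for (j in seq_len(glom_sample)) s <- s + golgi[sample.int(n_golgi, 1)]
    inh[k] <- pmax(scale * s / glom_sample + offset, 0)
  }
  inh
}

# Naive single-fibre terminal placement following the stated branching law:
# clusters ~ U{cmin..cmax} on the circular rank with circular centre gaps
# >= min_gap (rejection sampling), terminals ~ U{tmin..tmax}, binomial
# straddle split with per-field clamp and wrap-around neighbours. Returns
# the fibre's per-field terminal multiplicities (positive entries only).
oracle_fibre_multiplicities <- function(n_fields = 100, cmin = 4, cmax = 12,
                                        tmin = 2, tmax = 7, cap = 4,
                                        min_gap = 3) {
  k <- sample(cmin:cmax, 1)
  repeat {
    pos <- sort(sample.int(n_fields, k))
    gaps <- c(diff(pos), pos[1] + n_fields - pos[k])
    if (k == 1 || all(gaps >= min_gap)) break
  }
  counts <- integer(n_fields)
  for (p in pos) {
    size <- sample(tmin:tmax, 1)
    dir <- sample(c(-1L, 1L), 1)
    nb <- ((p + dir - 1) %% n_fields) + 1
    keep <- rbinom(1, size, 1 - runif(1))
    keep <- min(max(keep, size - cap), cap)
    counts[p] <- counts[p] + keep
    counts[nb] <- counts[nb] + (size - keep)
  }
  counts[counts > 0]
}

# Expected SD of stellate unit outputs for a pool with SD s, under the
# (possibly zero-truncated) contact law: sqrt(E[1/x]) * s.
oracle_stellate_sd_factor <- function(law) {
  x <- seq_len(law$n_active)
  pmf <- dbinom(x, law$n_active, law$p_contact)
  if (!law$truncate_zero) {
    pmf <- c(dbinom(0, law$n_active, law$p_contact), pmf)
    x <- c(1, x)  # never used at x = 0 in practice; truncated default avoids it
  }
  pmf <- pmf / sum(pmf)
  sqrt(sum(pmf / x))
}

# Naive nuclear projection oracle: SD of sample means of m ~ U{lo..hi}
# values drawn without replacement from a fixed population.
oracle_nuclear_sd <- function(population, lo, hi, n_cells, reps) {
  outs <- numeric(reps * n_cells)
  at <- 1L
  for (r in seq_len(reps)) {
    for (cell in seq_len(n_cells)) {
      m <- sample(lo:hi, 1)
      outs[at] <- mean(population[sample.int(length(population), m)])
      at <- at + 1L
    }
  }
  sd(outs)
}

# Synthetic file pools spanning ~60 normalised units: normal SD 10,
# truncated to a 60-unit window.
span60_pools <- function(n_pools, n_per_pool = 1845, center = 125) {
  replicate(n_pools, {
    x <- rnorm(n_per_pool, center, 10)
    x[x >= center - 30 & x <= center + 30]
  }, simplify = FALSE)
}
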