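# Terminal branching/clustering and the sampling-with-replacement facsimile.

test_that("per-field terminal totals and single-fibre shares match the anatomy", {
  g <- mzn_geometry()
  set.seed(21)
  rates <- draw_rank_rates(rank_uniform(), g$mossy_fibres_total %/% g$n_ranks)
  fields <- distribute_to_fields(rates, g)
  counts <- vapply(fields, function(fd) length(fd$rates), 0L)
  expect_length(fields, 100)
  expect_gte(mean(counts), 600)
  expect_lte(mean(counts), 800)
  shares <- vapply(fields, function(fd) max(tabulate(fd$source)) / length(fd$source), 0)
  expect_lt(max(shares), 0.01)
})

test_that("identical input rates pass through unchanged", {
  g <- tiny_geom()
  set.seed(1)
  fields <- distribute_to_fields(rep(77, 200), g)
  for (fd in fields) expect_true(all(fd$rates == 77))
})

test_that("a field's sources all belong to its own rank", {
  g <- tiny_geom()
  layer <- build_input_layer(rank_uniform(), g, seed = 5)
  per_rank <- g$mossy_fibres_total %/% g$n_ranks
  for (r in seq_len(g$n_ranks)) {
    src <- unlist(lapply(layer$fields[[r]], `[[`, "source"))
    expect_true(all(src >= 1 & src <= per_rank))
  }
})

test_that("distinct-fibre rates in a field are a fair sample of the rank", {
  # The pooled field rates repeat each sampled fibre's rate (multiplicity =
  # its terminal count), so the valid distributional comparison is between
  # the field's distinct sources and the rank's rate population.
  g <- mzn_geometry()
  set.seed(31)
  rates <- draw_rank_rates(rank_uniform(), 1951)
  fields <- distribute_to_fields(rates, g)
  pvals <- vapply(fields[seq(5, 95, by = 10)], function(fd) {
    distinct <- rates[unique(fd$source)]
    suppressWarnings(ks.test(distinct, rates))$p.value
  }, 0)
  expect_gt(min(pvals), 0.01)
})

test_that("the pooled field ECDF converges on the rank ECDF with density", {
  # ten times the terminal density (tenfold mossy fibres, same branching)
  # brings each field's received-rate distribution closer to the rank's
  g <- mzn_geometry()
  set.seed(41)
  rates1 <- draw_rank_rates(rank_uniform(), 1951)
  rates10 <- draw_rank_rates(rank_uniform(), 19510)
  f1 <- distribute_to_fields(rates1, g)
  f10 <- distribute_to_fields(rates10, g)
  ks_stat <- function(x, ref) suppressWarnings(ks.test(x, ref))$statistic
  d1 <- mean(vapply(f1[seq(10, 90, by = 20)],
                    function(fd) ks_stat(fd$rates, rates1), 0))
  d10 <- mean(vapply(f10[seq(10, 90, by = 20)],
                     function(fd) ks_stat(fd$rates, rates10), 0))
  expect_lt(d10, d1)
})

test_that("per-fibre field multiplicities follow the stated branching law", {
  g <- mzn_geometry()
  set.seed(51)
  rates <- draw_rank_rates(rank_uniform(), 1951)
  fields <- distribute_to_fields(rates, g)
  got <- unlist(lapply(fields, function(fd) {
    m <- tabulate(fd$source)
    m[m > 0]
  }))
  expect_lte(max(got), mzn_branching()$max_field_share)
  want <- unlist(replicate(4000, oracle_fibre_multiplicities(), simplify = FALSE))
  lev <- seq_len(mzn_branching()$max_field_share)
  tab <- rbind(tabulate(got, nbins = max(lev)), tabulate(want, nbins = max(lev)))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("the input layer grid is complete, typed and reproducible", {
  g <- tiny_geom()
  layer <- build_input_layer(rank_uniform(), g, seed = 9)
  expect_s3_class(layer, "mzn_input_layer")
  expect_length(layer$fields, g$n_ranks)
  expect_equal(sum(lengths(layer$fields)), g$n_ranks * g$fields_per_rank)
  layer2 <- build_input_layer(rank_uniform(), g, seed = 9)
  expect_identical(layer$fields, layer2$fields)
  layer3 <- build_input_layer(rank_uniform(), g, seed = 10)
  expect_false(identical(layer$fields, layer3$fields))
  expect_error(build_input_layer(rep(list(rank_uniform()), 3), g, seed = 1),
               "one rank spec per rank")
})

test_that("diagnostic matrices have the grid shape", {
  g <- tiny_geom()
  layer <- build_input_layer(rank_uniform(), g, seed = 2)
  counts <- field_terminal_counts(layer)
  shares <- max_source_share(layer)
  expect_equal(dim(counts), c(g$n_ranks, g$fields_per_rank))
  expect_equal(dim(shares), c(g$n_ranks, g$fields_per_rank))
  expect_true(all(shares > 0 & shares < 1))
})
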