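# Golgi-glomerulus inhibition, the granule firing rule, and calibration.

test_that("inhibition of a constant field is the scaled constant", {
  g <- tiny_geom()
  set.seed(1)
  expect_true(all(compute_field_inhibition(rep(80, 50), g, scale = 1) == 80))
  expect_true(all(compute_field_inhibition(rep(80, 50), g, scale = 0) == 0))
  expect_true(all(compute_field_inhibition(rep(80, 50), g, scale = 0.5,
                                           offset = 7) == 47))
  expect_error(compute_field_inhibition(numeric(0), g), "empty field")
  expect_error(compute_field_inhibition(rep(80, 50), g, scale = -1), ">= 0")
})

test_that("two-stage sampling narrows the inhibition distribution (CLT)", {
  g <- mzn_geometry()  # 700 glomeruli
  set.seed(2)
  rates <- runif(700, 0, 250)
  reps <- 30
  pkg <- replicate(reps, compute_field_inhibition(rates, g, scale = 1),
                   simplify = FALSE)
  orc <- replicate(reps, oracle_inhibition(rates), simplify = FALSE)
  pkg_means <- vapply(pkg, mean, 0)
  orc_means <- vapply(orc, mean, 0)
  # centred on the mossy mean, with a much narrower spread than the rates
  se <- sqrt(var(pkg_means) / reps + var(orc_means) / reps)
  expect_lt(abs(mean(pkg_means) - mean(orc_means)), 3 * se)
  expect_lt(abs(mean(pkg_means) - mean(rates)), 3 * sd(pkg_means) / sqrt(reps) +
              3 * sd(rates) / sqrt(length(rates)))
  expect_lt(mean(vapply(pkg, sd, 0)), sd(rates))
  expect_equal(mean(vapply(pkg, sd, 0)), mean(vapply(orc, sd, 0)),
               tolerance = 0.15)
})

test_that("granule firing obeys the dendritic win rule at its extremes", {
  g <- tiny_geom()
  set.seed(3)
  rates <- runif(100, 10, 250)
  res0 <- evaluate_granule_firing(rates, rep(1e6, 20), g)
  expect_equal(res0$fraction, 0)
  expect_length(res0$active_rates, 0)
  res1 <- evaluate_granule_firing(rates, rep(0, 20), g)
  expect_equal(res1$fraction, 1)
  expect_length(res1$active_rates, g$granule_per_field)
  expect_true(all(res1$active_rates >= min(rates) &
                  res1$active_rates <= max(rates)))
  resc <- evaluate_granule_firing(rep(50, 100), rep(0, 20), g)
  expect_true(all(resc$active_rates == 50))  # mean of constant dendritic rates
  expect_error(mzn_granular(min_wins = 5), "min_wins")
  expect_error(mzn_granular(min_wins = 0), "min_wins")
})

test_that("firing fractions match a naive brute-force oracle (miniature)", {
  g <- mzn_geometry(n_ranks = 5, fields_per_rank = 5, glomeruli_per_field = 10,
                    granule_per_field = 50, mossy_fibres_total = 500,
                    terminals_per_field_target = 20,
                    nuclear_sample_min = 5, nuclear_sample_max = 10)
  set.seed(4)
  rates <- runif(20, 0, 250)
  inh <- runif(10, 50, 200)
  reps <- 400
  pkg <- vapply(seq_len(reps), function(i) {
    evaluate_granule_firing(rates, inh, g)$fraction
  }, 0)
  orc <- vapply(seq_len(reps), function(i) {
    oracle_granule_fraction(rates, inh, 50)
  }, 0)
  se <- sqrt(var(pkg) / reps + var(orc) / reps)
  expect_lt(abs(mean(pkg) - mean(orc)), 3 * se)
})

test_that("calibration reaches sparse and dense targets", {
  g <- tiny_geom(scale = 0.1)
  layer <- build_input_layer(rank_uniform(), g, seed = 6)
  cal <- calibrate_inhibition(layer, target = 0.005, seed = 6)
  expect_s3_class(cal, "mzn_calibration")
  expect_gte(cal$achieved, 0.0045)
  expect_lte(cal$achieved, 0.0055)
  cal30 <- calibrate_inhibition(layer, target = 0.30, seed = 6)
  expect_equal(cal30$achieved, 0.30, tolerance = 0.1)
  expect_lt(cal30$value, cal$value)  # denser code needs less inhibition
  expect_error(calibrate_inhibition(layer, target = 0), "target")
})

test_that("an unreachable target returns the boundary with a warning", {
  g <- tiny_geom()
  # a large fraction of mossy rates are truncated to exactly 0, so even
  # zero inhibition cannot push the active fraction near 1 under the
  # strict-inequality 3-of-4 win rule
  layer <- build_input_layer(rank_normal(5, 30), g, seed = 7)
  expect_warning(
    cal <- calibrate_inhibition(layer, target = 0.95, mode = "scale", seed = 7),
    "unreachable")
  expect_equal(cal$value, 0)
})

test_that("the active fraction is monotone non-increasing in the offset", {
  g <- tiny_geom()
  layer <- build_input_layer(rank_uniform(), g, seed = 8)
  fr <- vapply(c(0, 40, 80, 120), function(off) {
    mean(run_granular(layer, offset = off, seed = 8)$fraction)
  }, 0)
  expect_true(all(diff(fr) <= 0))
  expect_lt(fr[4], fr[1])
})

test_that("active rates stay within the span of the field's mossy rates", {
  g <- tiny_geom()
  layer <- build_input_layer(rank_uniform(), g, seed = 12)
  act <- run_granular(layer, offset = 60, seed = 12)
  for (r in c(1, 5, 11)) {
    for (j in c(1, 10, 20)) {
      fd <- layer$fields[[r]][[j]]
      a <- act$fields[[r]][[j]]$active_rates
      if (length(a)) {
        expect_gte(min(a), min(fd$rates))
        expect_lte(max(a), max(fd$rates))
      }
    }
  }
})

test_that("file codes pool fields and tighten density regulation", {
  g <- tiny_geom(scale = 0.1)
  layer <- build_input_layer(rank_uniform(), g, seed = 13)
  act <- run_granular(layer, offset = 50, seed = 13)
  fc <- assemble_file_codes(act)
  expect_s3_class(fc, "mzn_file_codes")
  expect_length(fc$files, g$fields_per_rank)
  expect_equal(vapply(fc$files, `[[`, 0L, "n_active"),
               vapply(fc$files, function(f) length(f$pf_rates), 0L))
  expect_lt(sd(fc$density), sd(as.vector(act$fraction)))
  # an incomplete grid is refused
  act2 <- act
  act2$fields[[2]] <- act2$fields[[2]][-1]
  expect_error(assemble_file_codes(act2), "incomplete")
})

test_that("identical field activity gives identical file densities", {
  g <- tiny_geom()
  layer <- build_input_layer(rank_normal(100, 0), g, seed = 14)
  act <- run_granular(layer, offset = -10, seed = 14)  # all cells fire at 100
  expect_true(all(act$fraction == 1))
  fc <- assemble_file_codes(act)
  expect_true(all(fc$density == fc$density[1]))
  expect_true(all(unlist(lapply(fc$files, `[[`, "pf_rates")) == 100))
})
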