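# End-to-end runs, summaries and reproducibility (pipeline surface).

run_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- mzn_network("uniform", tiny_geom(scale = 0.1), seed = 3,
                            n_eval_fields = 150)
    }
    cache
  }
})

test_that("a network run carries every layer at its expected size", {
  run <- run_cached()
  g <- run$geom
  cts <- mzn_counts(g)
  s <- layer_summaries(run)
  expect_equal(s$layer, c("mossy", "pf", "stellate", "compartment", "soma",
                          "nuclear"))
  expect_equal(s$n[s$layer == "stellate"], cts$stellate_total)
  expect_equal(s$n[s$layer == "soma"], cts$pcs_total)
  expect_equal(s$n[s$layer == "compartment"], cts$compartment_total)
  expect_equal(s$n[s$layer == "nuclear"], g$nuclear_cells)
  expect_equal(s$range, s$max - s$min)
  broken <- run
  broken$layers$soma <- NULL
  expect_error(layer_summaries(broken), "missing layer")
})

test_that("reruns under a fixed seed are bit-identical", {
  g <- tiny_geom()
  r1 <- mzn_network("uniform", g, seed = 11, n_eval_fields = 60)
  r2 <- mzn_network("uniform", g, seed = 11, n_eval_fields = 60)
  expect_identical(r1$layers, r2$layers)
  expect_identical(r1$calibration$value, r2$calibration$value)
  r3 <- mzn_network("uniform", g, seed = 12, n_eval_fields = 60)
  expect_false(identical(r1$layers$nuclear, r3$layers$nuclear))
})

test_that("package simulators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(mzn_network("uniform", tiny_geom(), seed = 5, n_eval_fields = 40))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("a degenerate (constant) input propagates unchanged to all layers", {
  g <- tiny_geom()
  run <- mzn_network(rank_normal(100, 0), g, seed = 4,
                     calibration = as_calibration(offset = -10))
  s <- layer_summaries(run)
  expect_equal(s$mean, rep(100, 6))
  expect_equal(s$sd, rep(0, 6))
})

test_that("density regulation tightens from fields to files", {
  run <- run_cached()
  d <- density_regulation(run)
  expect_length(d$field_pct, mzn_counts(run$geom)$n_fields)
  expect_length(d$file_pct, run$geom$fields_per_rank)
  expect_lt(d$sd_file, d$sd_field)
  expect_equal(mean(d$field_pct), mean(d$file_pct), tolerance = 1e-9)
})

test_that("mean conservation holds along the cascade of a default run", {
  run <- run_cached()
  cons <- mean_conservation(run)
  expect_equal(nrow(cons), 4)
  expect_true(all(abs(cons$z) < 3))
})

test_that("linearity diagnostics reject underdetermined designs", {
  run <- run_cached()
  expect_error(linearity_check(list(run, run)), "at least 3")
  expect_error(linearity_check(list(run, run, run)),
               "insufficient variation")
})

test_that("CSV export writes the tidy layer bundle", {
  run <- run_cached()
  dir <- tempfile("mzn")
  paths <- write_network_csv(run, dir)
  expect_true(all(file.exists(paths)))
  layers <- read.csv(paths[1])
  expect_equal(sum(layers$layer == "soma"), mzn_counts(run$geom)$pcs_total)
  expect_equal(nrow(read.csv(paths[3])), run$geom$fields_per_rank)
  unlink(dir, recursive = TRUE)
})

test_that("print and summary methods run quietly", {
  run <- run_cached()
  expect_output(print(run), "layer cascade")
  expect_output(print(summary(run)), "Mean conservation")
  expect_output(print(run$calibration), "calibration")
  expect_s3_class(as.data.frame(run), "data.frame")
})
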