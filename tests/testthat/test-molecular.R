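# Stellate contact law, stellate layer, Purkinje networks and integration.

test_that("the contact law is a proper pmf with the derived mean", {
  law <- stellate_law()
  p <- stellate_pmf(0:420, law)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(sum((0:420) * p), 420 * 0.0119, tolerance = 1e-12)
  exact <- stellate_law(p_contact = 1000 / 84000)
  expect_equal(sum((0:420) * stellate_pmf(0:420, exact)), 5.0, tolerance = 1e-12)
  expect_error(stellate_pmf(-1, law), "0..n_active")
  expect_error(stellate_pmf(421, law), "0..n_active")
  expect_error(stellate_law(p_contact = 0), "p_contact")
})

test_that("stellate units average their own file's pool only", {
  g <- mzn_geometry()
  pools <- lapply(seq_len(100), function(s) rep(s, 50))  # pool s holds value s
  st <- simulate_stellate_layer(pools, g, seed = 1)
  expect_length(st$output, 8000)
  expect_equal(st$output, st$sector)  # every unit's mean is its sector id
  expect_equal(tabulate(st$sector), rep(80L, 100))
  expect_equal(range(st$depth_layer), c(1L, 5L))
  pools[[37]] <- numeric(0)
  expect_error(simulate_stellate_layer(pools, g, seed = 1), "sector 37")
})

test_that("sample sizes follow the (truncated) law", {
  g <- mzn_geometry()
  set.seed(2)
  pools <- replicate(100, runif(500, 0, 250), simplify = FALSE)
  st <- simulate_stellate_layer(pools, g, seed = 2)
  expect_true(all(st$n_inputs >= 1))  # zero-input units are truncated away
  law <- stellate_law()
  pmf <- stellate_pmf(1:30, law)
  pmf <- pmf / sum(pmf)
  expect_equal(mean(st$n_inputs), sum((1:30) * pmf), tolerance = 0.02)
})

test_that("stellate output spread matches the sampling-law oracle", {
  g <- mzn_geometry()
  set.seed(3)
  s_in <- 10
  pools <- replicate(100, rnorm(2000, 125, s_in), simplify = FALSE)
  st <- simulate_stellate_layer(pools, g, seed = 3)
  factor <- oracle_stellate_sd_factor(stellate_law())
  expect_equal(sd(st$output), s_in * factor, tolerance = 0.06)
})

test_that("flank networks respect size bounds and depth eligibility", {
  g <- mzn_geometry()
  nets <- build_pc_networks(g, seed = 4)
  m <- g$stellate_per_sector
  sizes_interior <- integer(0)
  for (s in c(2, 50, 99)) {
    for (p in 1:4) {
      for (fl in c("flank1", "flank2")) {
        ids <- nets$sectors[[s]][[p]][[fl]]
        sizes_interior <- c(sizes_interior, length(ids))
        own <- ids[(ids - 1) %/% m + 1 == s]
        nb <- ids[(ids - 1) %/% m + 1 != s]
        expect_length(own, 16)
        expect_true(all(((nb - 1) %/% m + 1) %in% c(s - 1, s + 1)))
        # neighbour afferents come only from inner depth layers (3-5)
        local <- (nb - 1) %% m + 1
        expect_true(all(local > 2 * g$stellate_per_flank))
      }
    }
  }
  expect_true(all(sizes_interior >= 16 & sizes_interior <= 32))
  for (s in c(1, 100)) {
    for (p in 1:4) {
      sz <- length(nets$sectors[[s]][[p]]$flank1)
      expect_gte(sz, 16)
      expect_lte(sz, 24)  # one neighbour missing at the edge
    }
  }
})

test_that("constant stellate outputs integrate to the same constant", {
  g <- mzn_geometry()
  pools <- replicate(100, rep(42, 30), simplify = FALSE)
  st <- simulate_stellate_layer(pools, g, seed = 5)
  nets <- build_pc_networks(g, seed = 5)
  pc <- integrate_pc(st, nets, seed = 5)
  expect_length(pc$soma, 400)
  expect_equal(dim(pc$compartments), c(16, 400))
  expect_true(all(pc$compartments == 42))
  expect_true(all(pc$soma == 42))
})

test_that("somata are the mean of their flank-averaged compartments", {
  g <- mzn_geometry()
  set.seed(6)
  pools <- replicate(100, runif(300, 0, 250), simplify = FALSE)
  st <- simulate_stellate_layer(pools, g, seed = 6)
  nets <- build_pc_networks(g, seed = 6)
  pc <- integrate_pc(st, nets, seed = 6)
  expect_equal(pc$soma, colMeans(pc$compartments))
  expect_lt(sd(pc$soma), sd(as.vector(pc$compartments)))
  expect_lt(sd(as.vector(pc$compartments)), sd(st$output))
})

test_that("a flank smaller than the compartment sample is refused", {
  g <- mzn_geometry(compartment_sample_size = 40)
  pools <- replicate(100, rep(1, 30), simplify = FALSE)
  st <- simulate_stellate_layer(pools, g, seed = 7)
  nets <- build_pc_networks(g, seed = 7)
  expect_error(integrate_pc(st, nets, seed = 7), "flank network smaller")
})
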