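test_that("build_fes converts weighted counts to free energies", {
  kT <- kBT(298)
  ## samples with 2:1 weights between two bins -> dF = kBT ln 2
  s <- c(0.25, 0.75)
  fes <- build_fes(s, axes = list(x = c(0, 0.5, 1)), weights = c(2, 1))
  expect_equal(fes$values[2] - fes$values[1], kT * log(2), tolerance = 1e-12)
  expect_equal(min(fes$values, na.rm = TRUE), 0)
  ## empty bins masked; samples outside grid dropped
  fes2 <- build_fes(c(0.1, 0.1, 7), axes = list(x = seq(0, 1, by = 0.25)))
  expect_identical(sum(fes2$mask), 1L)
  expect_identical(fes2$n_samples, 2L)
  expect_error(build_fes(c(7, 9), axes = list(x = c(0, 1))), "outside")

  ## 2D Gaussian samples reproduce the quadratic surface inside 2 sigma
  set.seed(31)
  n <- 1.5e6
  xy <- cbind(rnorm(n), rnorm(n))
  fg <- build_fes(xy, axes = list(x = list(n = 40, range = c(-3, 3)),
                                  y = list(n = 40, range = c(-3, 3))),
                  temperature = 298)
  mx <- fg$axes[[1]]$mids; my <- fg$axes[[2]]$mids
  ref <- outer(mx, my, function(a, b) kT * (a^2 + b^2) / 2)
  ref <- ref - min(ref)
  inside <- outer(mx, my, function(a, b) a^2 + b^2 < 4)
  expect_lt(max(abs(fg$values[inside] - ref[inside])), 0.1)

  ## shift invariance: scaling all weights leaves dF unchanged
  w <- runif(100) + 0.5
  s100 <- runif(100)
  f1 <- build_fes(s100, axes = list(x = seq(0, 1, by = 0.1)), weights = w)
  f2 <- build_fes(s100, axes = list(x = seq(0, 1, by = 0.1)), weights = 7 * w)
  expect_equal(f1$values, f2$values, tolerance = 1e-12)
})

test_that("find_global_min returns the first-lowest bin with the tie rule", {
  ## single-basin: center bin
  set.seed(5)
  s <- rnorm(5e4, mean = 0.55, sd = 0.08)
  fes <- build_fes(s, axes = list(x = seq(0, 1, by = 0.1)))
  m <- find_global_min(fes)
  expect_equal(m$coords, 0.55, tolerance = 1e-9)
  expect_equal(m$value, 0)
  ## two exactly equal minima -> lower flattened index wins
  fes2 <- build_fes(c(0.15, 0.85), axes = list(x = seq(0, 1, by = 0.1)))
  expect_identical(find_global_min(fes2)$flat_index, 2L)
})

test_that("decoupled-state analysis returns mean, pooled value and volume", {
  ## flat region: mean equals the flat value
  set.seed(7)
  rho <- runif(2e4, 0, 16)
  C <- ifelse(rho < 8, 0.5, 0.001)
  fes <- build_fes(cbind(rho, C),
                   axes = list(rho = list(n = 40, range = c(0, 16)),
                               C = list(n = 20, range = c(0, 1))))
  ds <- decoupled_state_value(fes, contact_threshold = 0.03, rho_min = 9)
  ## uniform-in-rho sampling -> every occupied bin holds ~the same count, so
  ## the whole surface (region included) is flat at F ~ 0
  expect_lt(abs(ds$value), 0.12)
  expect_equal(ds$volume, 4 / 3 * pi * (ds$rho_range[2]^3 - ds$rho_range[1]^3))
  expect_lt(ds$pooled, ds$value)   # pooling many bins lowers the macrostate F
  ## empty region errors with guidance
  expect_error(decoupled_state_value(fes, contact_threshold = 1e-9),
               "sample longer|extend")
  expect_error(decoupled_state_value(fes, rho_min = 99), "extend the grid")
  ## axis names are required
  fes_bad <- build_fes(cbind(rho, C),
                       axes = list(a = list(n = 10, range = c(0, 16)),
                                   b = list(n = 10, range = c(0, 1))))
  expect_error(decoupled_state_value(fes_bad), "axes")
})

test_that("standard-state correction has the stated magnitude and sign", {
  kT <- kBT(298)
  spec <- toy_binding_spec(depth = 0, radius = 5, r_max = 16, seed = 2)
  tr <- make_binding_trajectory(spec, n_samples = 4e4)
  fes <- build_fes(as.matrix(tr$samples),
                   axes = list(rho = list(n = 100, range = c(0, 16)),
                               C = list(n = 100, range = c(0, 1))))
  ## correction term alone: V_u = 2 V0 -> +kBT ln 2 = 0.4105
  r <- binding_free_energy(fes, decoupled_spec = list(contact_threshold = 0.01),
                           std_state = standard_state(
                             v_unbound = 2 * 1660.54))
  expect_equal(r$correction, kT * log(2), tolerance = 1e-9)
  expect_equal(r$correction, 0.4105, tolerance = 1e-3)
  ## V_u = V0 and F(min) = F(decoupled) -> dG = 0 (constructed directly)
  r0 <- binding_free_energy(fes, decoupled_spec = list(contact_threshold = 0.01),
                            std_state = standard_state(v_unbound = 1660.54))
  expect_equal(r0$correction, 0)
  ## correction monotonicity: +kBT per e-fold of V_u (mean convention)
  r_e <- binding_free_energy(fes, decoupled_spec = list(contact_threshold = 0.01),
                             std_state = standard_state(
                               v_unbound = exp(1) * 1660.54))
  expect_equal(r_e$dG - r0$dG, kT, tolerance = 1e-9)
})

test_that("the pooled two-state estimator matches the quadrature oracle", {
  spec <- toy_binding_spec(depth = 5, radius = 5, r_max = 16, seed = 3)
  tr <- make_binding_trajectory(spec, n_samples = 2e5)
  fes <- build_fes(as.matrix(tr$samples),
                   axes = list(rho = list(n = 100, range = c(0, 16)),
                               C = list(n = 100, range = c(0, 1))),
                   weights = tr$weights)
  r <- binding_free_energy(fes, decoupled_spec = list(contact_threshold = 0.01),
                           bound = "integrated", decoupled = "pooled")
  expect_lt(abs(r$dG - spec$dG_exact), 0.3)
  ## estimator consistency: error shrinks on average with more samples
  err_at <- function(n, seed) {
    sp <- toy_binding_spec(depth = 5, radius = 5, r_max = 16, seed = seed)
    t2 <- make_binding_trajectory(sp, n_samples = n)
    f2 <- build_fes(as.matrix(t2$samples),
                    axes = list(rho = list(n = 100, range = c(0, 16)),
                                C = list(n = 100, range = c(0, 1))))
    abs(binding_free_energy(f2,
                            decoupled_spec = list(contact_threshold = 0.01),
                            bound = "integrated",
                            decoupled = "pooled")$dG - sp$dG_exact)
  }
  e_small <- mean(vapply(1:4, function(s) err_at(5e3, s), numeric(1)))
  e_large <- mean(vapply(1:4, function(s) err_at(8e4, s), numeric(1)))
  expect_lt(e_large, e_small)
})

test_that("block analysis computes the SD of per-block estimates", {
  ## identical blocks -> SD 0
  expect_equal(block_sd(rep(c(1, 2, 3, 4), 10), n_blocks = 10), 0)
  ## i.i.d. normal, mean estimator: SD ~ sigma / sqrt(block size)
  set.seed(23)
  reps <- vapply(1:100, function(i) {
    block_sd(rnorm(1000, sd = 2), n_blocks = 10)
  }, numeric(1))
  expect_equal(mean(reps), 2 / sqrt(100), tolerance = 0.2)
  ## matrix input with a custom estimator
  m <- cbind(1:100, 101:200)
  expect_equal(block_sd(m, n_blocks = 5,
                        estimator = function(b) mean(b[, 2])), sd(c(110, 130, 150, 170, 190)))
  expect_error(block_sd(1:5, n_blocks = 10), "fewer samples")
  expect_error(block_sd(1:100, n_blocks = 1), "n_blocks")
})

test_that("FES text round trip preserves values, mask and axes", {
  set.seed(11)
  s <- cbind(runif(500, 0, 16), runif(500))
  fes <- build_fes(s, axes = list(rho = list(n = 12, range = c(0, 16)),
                                  C = list(n = 8, range = c(0, 1))))
  path <- file.path(withr::local_tempdir(), "fes.txt")
  write_fes(fes, path)
  f2 <- read_fes(path)
  expect_equal(f2$values, fes$values, tolerance = 1e-12)
  expect_identical(f2$mask, fes$mask)
  expect_equal(f2$weights, fes$weights, tolerance = 1e-12)
  expect_equal(f2$axes[[1]]$edges, fes$axes[[1]]$edges, tolerance = 1e-12)
  expect_identical(f2$axes[[2]]$name, "C")
  expect_equal(f2$temperature, fes$temperature)
})
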