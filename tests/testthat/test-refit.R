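test_that("objective components behave as specified on exact data", {
  host <- toy6("stiff")
  spec <- ghost_spec(host$params, n_frames = 120, seed = 2,
                     n_walkers = 32L, burn_in = 500L, stride = 60L)
  ds <- ghost_reference_dataset(host$topology, spec, host$coords0)
  cfg <- fit_config()
  ## dataset generated exactly by params -> J = 0 at p = p0
  J <- fm_objective(host$params, ds, host$topology, cfg,
                    params0 = host$params, components = TRUE)
  expect_equal(J$J_energy, 0, tolerance = 1e-20)
  expect_equal(J$J_force, 0, tolerance = 1e-20)
  expect_equal(J$J, 0, tolerance = 1e-20)

  ## doubling every frame leaves J unchanged (mean-based normalization)
  x <- param_vector(host$params)
  p2 <- set_param_vector(host$params,
                         stats::setNames(x * 1.15, names(x)))
  ds2 <- reference_dataset(
    ds$coords[, , rep(seq_len(ds$n_frames), 2)],
    rep(ds$energy, 2),
    ds$forces[, , rep(seq_len(ds$n_frames), 2)])
  expect_equal(fm_objective(p2, ds, host$topology, cfg, params0 = host$params),
               fm_objective(p2, ds2, host$topology, cfg,
                            params0 = host$params),
               tolerance = 1e-12)

  ## zero-variance reference energies -> normalization error with guidance
  ds_flat <- reference_dataset(ds$coords, rep(1.5, ds$n_frames), ds$forces)
  expect_error(fm_objective(p2, ds_flat, host$topology, cfg,
                            params0 = host$params), "variance")
})

test_that("objective matches a hand-expanded closed form for one bond", {
  ## single harmonic bond along x; residuals expanded by hand
  sys <- single_bond_system(k = 200, r0 = 1.5)
  r_t <- c(1.40, 1.48, 1.55, 1.62, 1.70)
  nf <- length(r_t)
  coords <- array(0, dim = c(2, 3, nf))
  coords[2, 1, ] <- r_t
  kg <- 240; r0g <- 1.45   # ghost labels
  E_ref <- kg * (r_t - r0g)^2
  F_ref <- array(0, dim = c(2, 3, nf))
  F_ref[1, 1, ] <- 2 * kg * (r_t - r0g)    # force on atom 1 (at origin)
  F_ref[2, 1, ] <- -2 * kg * (r_t - r0g)
  ds <- reference_dataset(coords, E_ref, F_ref)
  cfg <- fit_config(w_reg = 0)
  ## hand-expanded: model E = k (r - r0)^2 with trial k=200, r0=1.5
  dE <- 200 * (r_t - 1.5)^2 - E_ref
  dE <- dE - mean(dE)
  varE <- mean((E_ref - mean(E_ref))^2)
  J_E <- mean(dE^2) / varE
  dFx <- 2 * 200 * (r_t - 1.5) - 2 * kg * (r_t - r0g)
  varF <- mean(F_ref^2) - mean(F_ref)^2
  J_F <- mean(c(dFx^2, dFx^2, rep(0, 4 * nf))) / varF
  J <- fm_objective(sys$params, ds, sys$topology, cfg,
                    params0 = sys$params, components = TRUE)
  expect_equal(J$J_energy, J_E, tolerance = 1e-10)
  expect_equal(J$J_force, J_F, tolerance = 1e-10)
})

test_that("features-based and direct objective/gradient agree", {
  host <- toy6("stiff")
  spec <- ghost_spec(host$params, n_frames = 60, seed = 5, n_walkers = 20L,
                     burn_in = 300L, stride = 40L)
  ds <- ghost_reference_dataset(host$topology, spec, host$coords0)
  x <- param_vector(host$params)
  pert <- x * (1 + 0.2 * rep(c(1, -1), length.out = length(x)))
  p <- set_param_vector(host$params, stats::setNames(pert, names(x)))
  cfg <- fit_config()
  ft <- fmbind:::precompute_features(host$topology, p, ds$coords)
  ft$fref_flat <- as.numeric(aperm(ds$forces, c(2, 1, 3)))
  expect_equal(fm_objective(p, ds, host$topology, cfg, params0 = p,
                            features = ft),
               fm_objective(p, ds, host$topology, cfg, params0 = p),
               tolerance = 1e-12)
  ## analytic class gradient vs central finite differences (oracle)
  ga <- fmbind:::fm_objective_gradient(p, ds, host$topology, cfg, p, ft)
  gn <- vapply(seq_along(pert), function(i) {
    h <- 1e-6 * max(1, abs(pert[i]))
    xp <- pert; xp[i] <- xp[i] + h
    xm <- pert; xm[i] <- xm[i] - h
    (fm_objective(set_param_vector(host$params,
                                   stats::setNames(xp, names(x))),
                  ds, host$topology, cfg, params0 = p, features = ft) -
       fm_objective(set_param_vector(host$params,
                                     stats::setNames(xm, names(x))),
                    ds, host$topology, cfg, params0 = p, features = ft)) /
      (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1e-6)), 1e-5)
})

test_that("energies-only least squares recovers a single bond exactly", {
  sys <- single_bond_system(k = 250, r0 = 1.45)
  set.seed(4)
  r_t <- 1.45 + seq(-0.2, 0.2, length.out = 50)
  coords <- array(0, dim = c(2, 3, 50))
  coords[2, 1, ] <- r_t
  lab <- evaluate_trajectory(sys$topology, sys$params, coords, forces = TRUE)
  ds <- reference_dataset(coords, lab$components[, "total"], lab$forces)
  ## start away from the truth; energies-only, unregularized
  p0 <- sys$params; p0$bonds$k <- 180; p0$bonds$r0 <- 1.6
  fit <- fit_parameters(ds, sys$topology, p0,
                        fit_config(w_force = 0, w_reg = 0, tol = 1e-14))
  expect_equal(fit$params$bonds$k, 250, tolerance = 1e-6)
  expect_equal(fit$params$bonds$r0, 1.45, tolerance = 1e-6)
})

test_that("fit is deterministic, frozen-preserving and reduces errors", {
  host <- toy6("stiff")
  spec <- ghost_spec(host$params, n_frames = 400, seed = 11, n_walkers = 64L,
                     burn_in = 800L, stride = 100L)
  ds <- ghost_reference_dataset(host$topology, spec, host$coords0)
  x <- param_vector(host$params)
  pert <- x * (1 + 0.15 * rep(c(1, -1), length.out = length(x)))
  p0 <- set_param_vector(host$params, stats::setNames(pert, names(x)))
  cfg <- fit_config(max_iter = 120)
  f1 <- fit_parameters(ds, host$topology, p0, cfg)
  f2 <- fit_parameters(ds, host$topology, p0, cfg)
  ## determinism: bit-identical parameter vectors
  expect_identical(param_vector(f1$params), param_vector(f2$params))
  ## frozen entries byte-identical to input
  expect_identical(f1$params$lj, p0$lj)
  expect_identical(f1$params$scale14, p0$scale14)
  expect_identical(f1$params$dihedrals$n, p0$dihedrals$n)
  expect_identical(f1$params$dihedrals$delta, p0$dihedrals$delta)
  ## start at ghost truth with w_reg > 0 -> stays at the start
  f0 <- fit_parameters(ds, host$topology, host$params,
                       fit_config(max_iter = 30))
  expect_equal(param_vector(f0$params), param_vector(host$params),
               tolerance = 1e-6)
  ## refit reduces energy and force RMSE vs the perturbed start
  a_start <- assess(ds, host$topology, p0)
  a_fit <- assess(ds, host$topology, f1$params)
  expect_lt(a_fit$energy_rmse, a_start$energy_rmse)
  expect_lt(a_fit$force_rmse, a_start$force_rmse)
})

test_that("regularization monotonicity: stronger w_reg never lowers the data residual", {
  host <- toy6("stiff")
  spec <- ghost_spec(host$params, n_frames = 250, seed = 13, n_walkers = 50L,
                     burn_in = 600L, stride = 80L)
  ds <- ghost_reference_dataset(host$topology, spec, host$coords0)
  x <- param_vector(host$params)
  pert <- x * (1 + 0.2 * rep(c(-1, 1), length.out = length(x)))
  p0 <- set_param_vector(host$params, stats::setNames(pert, names(x)))
  data_term <- function(w_reg) {
    fit <- fit_parameters(ds, host$topology, p0,
                          fit_config(w_reg = w_reg, max_iter = 150))
    J <- fm_objective(fit$params, ds, host$topology, fit_config(w_reg = 0),
                      params0 = p0, components = TRUE)
    J$J_energy + J$J_force
  }
  d0 <- data_term(0); d1 <- data_term(0.1); d2 <- data_term(1)
  expect_lte(d0, d1 + 1e-9)
  expect_lte(d1, d2 + 1e-9)
})

test_that("assess implements the stated error conventions", {
  ## ghost + i.i.d. Gaussian force noise sigma = 2 -> force RMSE ~ 2 sqrt(3)
  top <- topology(types = c("a", "a"), masses = c(12, 12),
                  bonds = rbind(c(1, 2)))
  par <- parameter_set(
    bonds = data.frame(key = "a-a", k = 300, r0 = 1.5),
    angles = data.frame(key = character(), k = numeric(), theta0 = numeric()),
    lj = data.frame(type = "a", eps = 0, sigma = 3))
  gs <- ghost_spec(par, n_frames = 5000, stride = 5L, n_walkers = 250L,
                   burn_in = 100L, sigma_F = 2, seed = 21)
  ds <- ghost_reference_dataset(top, gs, rbind(c(0, 0, 0), c(1.5, 0, 0)))
  a <- assess(ds, top, par)   # 2 atoms x 5000 frames = 1e4 atom-frames
  expect_equal(a$force_rmse, 2 * sqrt(3), tolerance = 0.03)
  expect_equal(a$energy_rmse, 0, tolerance = 1e-10)
  ## bin counts account for every atom-frame
  expect_identical(sum(a$bin_counts), 2L * 5000L)

  ## heavy-atoms-first ordering of the per-atom series
  host <- toy6("stiff")
  hs <- ghost_spec(host$params, n_frames = 30, seed = 3, n_walkers = 15L,
                   burn_in = 200L, stride = 30L, sigma_F = 1)
  hd <- ghost_reference_dataset(host$topology, hs, host$coords0)
  ha <- assess(hd, host$topology, host$params)
  nh <- sum(host$topology$atoms$heavy)
  expect_true(all(host$topology$atoms$heavy[ha$atom_order[seq_len(nh)]]))
  expect_true(!any(host$topology$atoms$heavy[ha$atom_order[-seq_len(nh)]]))
})

test_that("force-error classification follows the published thresholds", {
  expect_identical(as.character(classify_force_errors(55)), "red")
  expect_identical(as.character(classify_force_errors(10)), "white")
  expect_identical(as.character(classify_force_errors(c(5, 12, 31, 51))),
                   c("white", "blue", "green", "red"))
  expect_identical(as.character(classify_force_errors(c(30, 50))),
                   c("blue", "green"))
  expect_error(classify_force_errors(-1), "non-negative")
})

test_that("reference datasets round-trip through the text format", {
  host <- toy6("stiff")
  spec <- ghost_spec(host$params, n_frames = 8, seed = 6, n_walkers = 8L,
                     burn_in = 100L, stride = 20L)
  ds <- ghost_reference_dataset(host$topology, spec, host$coords0)
  pre <- file.path(withr::local_tempdir(), "ref")
  write_reference_dataset(ds, pre, top = host$topology)
  ds2 <- read_reference_dataset(pre)
  expect_equal(ds2$coords, ds$coords, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ds2$energy, ds$energy, tolerance = 1e-12)
  expect_equal(ds2$forces, ds$forces, tolerance = 1e-12)
  expect_identical(ds2$meta$level, "ghost")
})
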