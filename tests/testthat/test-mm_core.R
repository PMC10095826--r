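test_that("bonded energies match closed forms at reference geometries", {
  sys <- single_bond_system(k = 300, r0 = 1.5)
  ## equilibrium geometry: zero bond energy, zero forces
  x <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  e <- evaluate_energy(sys$topology, sys$params, x)
  expect_equal(e[["bond"]], 0)
  expect_equal(e[["total"]], 0)
  expect_equal(evaluate_forces(sys$topology, sys$params, x),
               matrix(0, 2, 3))
  ## stretched bond: k (r - r0)^2
  x2 <- rbind(c(0, 0, 0), c(1.8, 0, 0))
  expect_equal(evaluate_energy(sys$topology, sys$params, x2)[["bond"]],
               300 * 0.3^2, tolerance = 1e-12)

  ## dihedral with the published barrier amplitude: E = k[1 + cos(n phi - d)]
  top <- topology(types = c("a", "b", "b", "a"), masses = rep(12, 4),
                  bonds = rbind(c(1, 2), c(2, 3), c(3, 4)))
  par <- parameter_set(
    bonds = data.frame(key = c("a-b", "b-b"), k = 0, r0 = 1.5),
    angles = data.frame(key = "a-b-b", k = 0, theta0 = pi / 2),
    dihedrals = data.frame(key = "a-b-b-a", k = 2.08, n = 2, delta = 0),
    lj = data.frame(type = c("a", "b"), eps = 0, sigma = 3))
  conf <- function(phi) rbind(c(1, 0, 1), c(0, 0, 1), c(0, 0, 0),
                              c(cos(phi), sin(phi), 0))
  expect_equal(evaluate_energy(top, par, conf(pi / 2))[["dihedral"]], 0,
               tolerance = 1e-12)
  expect_equal(evaluate_energy(top, par, conf(0))[["dihedral"]], 4.16,
               tolerance = 1e-12)
  ## periodicity: E(phi) = E(phi + 2 pi)
  for (phi in c(0.3, 1.1, 2.7))
    expect_equal(evaluate_energy(top, par, conf(phi))[["dihedral"]],
                 evaluate_energy(top, par, conf(phi + 2 * pi))[["dihedral"]],
                 tolerance = 1e-10)

  ## null Hamiltonian: everything zero -> total zero
  sysn <- chain5_system()
  pn <- sysn$params
  pn$bonds$k[] <- 0; pn$angles$k[] <- 0; pn$dihedrals$k[] <- 0
  pn$lj$eps[] <- 0
  topn <- sysn$topology; topn$atoms$charge[] <- 0
  expect_equal(evaluate_energy(topn, pn, chain5_coords())[["total"]], 0)
})

test_that("analytic forces equal central finite differences on random configs", {
  fixtures <- list(chain5 = chain5_system(), host = toy6("stiff"))
  bases <- list(chain5 = chain5_coords(), host = toy6("stiff")$coords0)
  for (nm in names(fixtures)) {
    sys <- fixtures[[nm]]
    cfgs <- random_configs(bases[[nm]], n = 12, sd = 0.12,
                           seed = match(nm, names(fixtures)))
    for (f in seq_len(dim(cfgs)[3])) {
      x <- cfgs[, , f]
      fa <- evaluate_forces(sys$topology, sys$params, x)
      expect_lt(max(abs(fa - fd_forces(sys$topology, sys$params, x))), 1e-5)
      ## Newton: net force vanishes for isolated systems
      expect_lt(max(abs(colSums(fa))), 1e-8)
    }
  }
})

test_that("energies are invariant and forces covariant under rigid motion", {
  sys <- toy6("stiff")
  set.seed(3)
  x <- sys$coords0 + matrix(rnorm(length(sys$coords0), sd = 0.1), ncol = 3)
  R <- rotation_matrix(axis = c(1, 2, 0.5), angle = 1.1)
  shift <- c(3.2, -1.1, 0.7)
  xr <- x %*% t(R) + rep(shift, each = nrow(x))
  e1 <- evaluate_energy(sys$topology, sys$params, x)
  e2 <- evaluate_energy(sys$topology, sys$params, xr)
  expect_lt(abs(e1[["total"]] - e2[["total"]]), 1e-8)
  f1 <- evaluate_forces(sys$topology, sys$params, x)
  f2 <- evaluate_forces(sys$topology, sys$params, xr)
  ## same magnitudes, rotated directions
  expect_equal(f2, f1 %*% t(R), tolerance = 1e-9)
})

test_that("evaluator error paths are explicit", {
  sys <- single_bond_system()
  ## missing parameter names the offending type key
  top_bad <- topology(types = c("a", "zz"), masses = c(12, 12),
                      bonds = rbind(c(1, 2)))
  expect_error(evaluate_energy(top_bad, sys$params, diag(2) %*%
                                 rbind(c(0, 0, 0), c(1.5, 0, 0))[1:2, ]),
               "a-zz|zz")
  ## overlapping nonbonded pair -> singularity error
  sys3 <- chain5_system()
  x <- chain5_coords()
  x[5, ] <- x[1, ] + 1e-8     # atoms 1 and 5 are a nonbonded pair
  expect_error(evaluate_energy(sys3$topology, sys3$params, x), "singular")
  ## non-finite coordinates rejected
  xb <- chain5_coords(); xb[2, 1] <- NA
  expect_error(evaluate_energy(sys3$topology, sys3$params, xb))
})

test_that("symmetry classes map instances to shared type keys", {
  host <- make_toy_host(8, "stiff")
  sc <- symmetry_classes(host$topology, host$params)
  ## alternating two-type ring: one ring-bond class covering 8 instances
  ring_keys <- sc$bonds[seq_len(8)]
  expect_length(unique(ring_keys), 1)
  expect_identical(sum(sc$bonds == ring_keys[1]), 8L)
  ## class count never exceeds instance count
  expect_true(all(sc$n_classes <=
                    c(nrow(host$topology$bonds), nrow(host$topology$angles),
                      nrow(host$topology$dihedrals),
                      max(1, nrow(host$topology$impropers)))))
  ## two distinct angle environments in the chain -> 2 classes
  sys <- chain5_system()
  sc5 <- symmetry_classes(sys$topology, sys$params)
  expect_identical(sc5$n_classes[["angles"]], 2L)
  ## generator metadata: ring dihedral key shared by all ring torsions
  dk <- term_type_keys(host$topology, "dihedrals")
  ring <- !grepl("hr", dk)
  expect_length(unique(dk[ring]), 1)
})

test_that("topology derives exclusions consistently with the bond graph", {
  sys <- chain5_system()
  top <- sys$topology
  ## chain 1-2-3-4-5: 1-2 pairs = bonds, 1-3 = {13,24,35}, 1-4 = {14,25},
  ## full nonbonded = {15}
  expect_identical(nrow(top$excl12), 4L)
  expect_setequal(paste(top$excl13[, 1], top$excl13[, 2]),
                  c("1 3", "2 4", "3 5"))
  expect_setequal(paste(top$pairs14[, 1], top$pairs14[, 2]),
                  c("1 4", "2 5"))
  expect_identical(paste(top$nb_pairs[, 1], top$nb_pairs[, 2]), "1 5")
  ## invalid terms rejected
  expect_error(topology(types = c("a", "a"), masses = c(1, 1),
                        bonds = rbind(c(1, 3))), "out of range")
  expect_error(topology(types = c("a", "a"), masses = c(1, 1),
                        bonds = rbind(c(1, 1))), "repeated")
})

test_that("topology, parameter and XYZ round trips are stable to 12 digits", {
  host <- toy6("stiff")
  tdir <- withr::local_tempdir()
  pt <- file.path(tdir, "host_params.txt")
  write_parameter_set(host$params, pt)
  p2 <- read_parameter_set(pt)
  expect_equal(param_vector(p2), param_vector(host$params),
               tolerance = 1e-12)
  expect_equal(p2$lj$eps, host$params$lj$eps, tolerance = 1e-12)
  expect_equal(p2$scale14, host$params$scale14, tolerance = 1e-12)

  tt <- file.path(tdir, "host_top.txt")
  write_topology(host$topology, tt)
  t2 <- read_topology(tt)
  expect_identical(t2$bonds, host$topology$bonds)
  expect_identical(t2$angles, host$topology$angles)
  expect_identical(t2$dihedrals, host$topology$dihedrals)
  expect_equal(t2$atoms$charge, host$topology$atoms$charge,
               tolerance = 1e-12)

  xt <- file.path(tdir, "traj.xyz")
  traj <- random_configs(host$coords0, 3, sd = 0.05)
  write_xyz(traj, xt, elements = host$topology$atoms$type,
            energies = c(1.5, -2.25, 3.125))
  tr2 <- read_xyz(xt)
  expect_equal(tr2, traj, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(tr2, "energies"), c(1.5, -2.25, 3.125))
  expect_identical(attr(tr2, "elements"), host$topology$atoms$type)
})
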