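## Shared fixtures, built in code at test time.

## small stiff toy host (ring of 6 units, 12 atoms) -- cheap default
toy6 <- function(stiffness = "stiff") make_toy_host(6, stiffness)

## 2-atom single harmonic bond system
single_bond_system <- function(k = 300, r0 = 1.5, charge = 0) {
  top <- topology(types = c("a", "a"), masses = c(12, 12),
                  charges = c(charge, -charge), bonds = rbind(c(1, 2)))
  params <- parameter_set(
    bonds = data.frame(key = "a-a", k = k, r0 = r0),
    angles = data.frame(key = character(), k = numeric(),
                        theta0 = numeric()),
    lj = data.frame(type = "a", eps = 0, sigma = 3))
  list(topology = top, params = params)
}

## 5-atom chain with bonds, angles, one dihedral; mixed types
chain5_system <- function() {
  top <- topology(types = c("a", "b", "b", "b", "a"),
                  masses = c(12, 14, 12, 14, 12),
                  charges = c(0.1, -0.05, -0.1, -0.05, 0.1),
                  bonds = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  params <- parameter_set(
    bonds = data.frame(key = c("a-b", "b-b"), k = c(300, 250),
                       r0 = c(1.4, 1.5)),
    angles = data.frame(key = c("a-b-b", "b-b-b"), k = c(50, 60),
                        theta0 = c(1.9, 2.0)),
    dihedrals = data.frame(key = c("a-b-b-b", "b-b-b-a"),
                           k = c(1.2, 1.2), n = c(3, 3), delta = c(0, 0)),
    lj = data.frame(type = c("a", "b"), eps = c(0.1, 0.15),
                    sigma = c(3.2, 3.4)))
  list(topology = top, params = params)
}

## roughly extended starting geometry for the chain
chain5_coords <- function() {
  rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.1, 1.3, 0),
        c(3.5, 1.4, 0.2), c(4.2, 2.6, -0.3))
}

random_configs <- function(base, n, sd = 0.1, seed = 1) {
  set.seed(seed)
  arr <- array(0, dim = c(nrow(base), 3, n))
  for (f in seq_len(n))
    arr[, , f] <- base + matrix(stats::rnorm(length(base), sd = sd),
                                ncol = 3)
  arr
}

## numeric central-difference forces: the independent oracle for the
## analytic gradient
fd_forces <- function(top, params, config, h = 1e-5) {
  f <- matrix(0, nrow(config), 3)
  for (i in seq_len(nrow(config))) for (k in 1:3) {
    xp <- config; xp[i, k] <- config[i, k] + h
    xm <- config; xm[i, k] <- config[i, k] - h
    f[i, k] <- -(evaluate_energy(top, params, xp)[["total"]] -
                   evaluate_energy(top, params, xm)[["total"]]) / (2 * h)
  }
  f
}

rotation_matrix <- function(axis = c(0, 0, 1), angle = 0.63) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  C <- 1 - c
  matrix(c(a[1]^2*C + c,        a[1]*a[2]*C - a[3]*s, a[1]*a[3]*C + a[2]*s,
           a[1]*a[2]*C + a[3]*s, a[2]^2*C + c,        a[2]*a[3]*C - a[1]*s,
           a[1]*a[3]*C - a[2]*s, a[2]*a[3]*C + a[1]*s, a[3]^2*C + c),
         3, 3, byrow = TRUE)
}
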