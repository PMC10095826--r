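## MM energy and analytic-force evaluator, vectorised across term instances
## AND frames.  Internal layout: coordinates as a 3 x N x F array; per-term
## scalar quantities live in T x F matrices; per-term vector quantities in
## 3 x T x F arrays.  Gas-phase only: no cutoff, no periodic images.
##
## A second entry point precomputes parameter-independent geometry features
## (bond lengths, angles, torsions and their coordinate gradients, plus the
## frozen non-bonded contribution) so that the force-matching objective can
## re-evaluate energies/forces for trial bonded parameters at a fraction of
## the cost.

cross3 <- function(a, b) {
  ## a, b: 3 x M -> 3 x M cross products
  rbind(a[2, ] * b[3, ] - a[3, ] * b[2, ],
        a[3, ] * b[1, ] - a[1, ] * b[3, ],
        a[1, ] * b[2, ] - a[2, ] * b[1, ])
}

## broadcast a T x F matrix (or T*F vector) over the 3 spatial components:
## returns the recycled vector; multiply with a 3 x T x F array on the LEFT
## so the result keeps the array dim attribute.
b3 <- function(m) rep(as.numeric(m), each = 3L)

## gather atom slices: X is 3 x N x F, idx a length-T atom vector
## -> 3 x T x F array
gather <- function(X, idx) X[, idx, , drop = FALSE]

## sum over the spatial component of a 3 x T x F array -> T x F matrix
csum <- function(a) {
  d <- dim(a)
  matrix(colSums(matrix(a, nrow = 3)), nrow = d[2], ncol = d[3])
}

## scatter-add per-instance force contributions (3 x T x F) onto atoms
scatter_add <- function(Fout, atoms, fv, sign = 1) {
  d <- dim(fv)
  for (c3 in 1:3) {
    m <- matrix(fv[c3, , ], nrow = d[2], ncol = d[3])
    agg <- rowsum(m, atoms)
    ids <- as.integer(rownames(agg))
    Fout[c3, ids, ] <- Fout[c3, ids, ] + sign * agg
  }
  Fout
}

## stack several (3 x T x F) contributions along the instance axis and
## scatter them with one keyed rowsum over (component, atom) rows; the
## contiguous reshape avoids strided slicing.
scatter_add_multi <- function(Fout, atoms_list, fv_list) {
  d <- dim(Fout)                       # 3 x N x F
  F <- d[3]
  M <- do.call(rbind, lapply(fv_list, function(a) matrix(a, ncol = F)))
  atoms <- unlist(atoms_list, use.names = FALSE)
  key <- 3L * (rep(atoms, each = 3L) - 1L) + rep_len(1:3, 3L * length(atoms))
  agg <- rowsum(M, key)
  ids <- as.integer(rownames(agg))
  Fm <- matrix(Fout, nrow = 3L * d[2])
  Fm[ids, ] <- Fm[ids, ] + agg
  array(Fm, dim = d)
}

## Resolve per-instance parameters once per (topology, params) pair.
resolve_params <- function(top, params) {
  sc <- symmetry_classes(top, params)  # errors on missing keys
  res <- list()
  if (nrow(top$bonds)) {
    i <- match(sc$bonds, params$bonds$key)
    res$bond <- list(idx = top$bonds, k = params$bonds$k[i],
                     r0 = params$bonds$r0[i], class = sc$bonds)
  }
  if (nrow(top$angles)) {
    i <- match(sc$angles, params$angles$key)
    res$angle <- list(idx = top$angles, k = params$angles$k[i],
                      theta0 = params$angles$theta0[i], class = sc$angles)
  }
  expand_torsion <- function(idx_mat, keys, table) {
    if (is.null(table) || !nrow(table) || !nrow(idx_mat)) return(NULL)
    rows <- lapply(seq_len(nrow(idx_mat)), function(t) {
      j <- which(table$key == keys[t])
      if (!length(j)) stop("no dihedral parameters for type key: ", keys[t])
      cbind(term = t, row = j)
    })
    map <- do.call(rbind, rows)
    list(idx = idx_mat[map[, "term"], , drop = FALSE],
         k = table$k[map[, "row"]], n = table$n[map[, "row"]],
         delta = table$delta[map[, "row"]], row = map[, "row"])
  }
  res$dihedral <- expand_torsion(top$dihedrals, sc$dihedrals, params$dihedrals)
  res$improper <- expand_torsion(top$impropers, sc$impropers, params$impropers)

  li <- match(top$atoms$type, params$lj$type)
  if (anyNA(li))
    stop("no LJ parameters for atom type(s): ",
         paste(unique(top$atoms$type[is.na(li)]), collapse = ", "))
  res$eps <- params$lj$eps[li]; res$sigma <- params$lj$sigma[li]
  res$q <- top$atoms$charge
  res$nb <- top$nb_pairs; res$p14 <- top$pairs14
  res$scale14 <- params$scale14
  res
}

## -- geometry kernels (parameter independent) --------------------------------

## bond lengths r (B x F) and dr/dr_i (3 x B x F); dr/dr_j = -dr/dr_i
geom_bonds <- function(X, idx) {
  B <- nrow(idx); F <- dim(X)[3]
  D <- gather(X, idx[, 1]) - gather(X, idx[, 2])
  r <- sqrt(csum(D * D))
  gi <- D / b3(r)
  list(r = r, gi = gi, B = B, F = F)
}

## angles theta (A x F) and dtheta/dr_i, dtheta/dr_k (3 x A x F)
geom_angles <- function(X, idx) {
  A <- nrow(idx); F <- dim(X)[3]; tf <- c(A, F)
  u <- gather(X, idx[, 1]) - gather(X, idx[, 2])
  v <- gather(X, idx[, 3]) - gather(X, idx[, 2])
  ru <- sqrt(csum(u * u)); rv <- sqrt(csum(v * v))
  cth <- matrix(pmin(1, pmax(-1, csum(u * v) / (ru * rv))), A, F)
  sth <- pmax(sqrt(1 - cth * cth), 1e-10)
  gi <- (u * b3(cth / (ru * ru)) - v * b3(1 / (ru * rv))) * b3(1 / sth)
  gk <- (v * b3(cth / (rv * rv)) - u * b3(1 / (ru * rv))) * b3(1 / sth)
  list(theta = acos(cth), gi = gi, gk = gk, A = A, F = F)
}

## torsions phi (T x F) and the four gradients (3 x T x F)
geom_torsions <- function(X, idx) {
  T_ <- nrow(idx); F <- dim(X)[3]; tf <- c(T_, F)
  flat <- function(a) matrix(a, nrow = 3)
  b1 <- flat(gather(X, idx[, 2]) - gather(X, idx[, 1]))
  b2 <- flat(gather(X, idx[, 3]) - gather(X, idx[, 2]))
  b3v <- flat(gather(X, idx[, 4]) - gather(X, idx[, 3]))
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3v)
  nb2 <- sqrt(colSums(b2 * b2))
  phi <- atan2(colSums(cross3(n1, n2) * b2) / nb2, colSums(n1 * n2))
  sn1 <- pmax(colSums(n1 * n1), 1e-20)
  sn2 <- pmax(colSums(n2 * n2), 1e-20)
  rep3 <- function(v) rep(v, each = 3)
  gi <- -n1 * rep3(nb2 / sn1)
  gl <- n2 * rep3(nb2 / sn2)
  t1 <- colSums(b1 * b2) / (nb2 * nb2)
  t2 <- colSums(b3v * b2) / (nb2 * nb2)
  gj <- -gi * rep3(1 + t1) + gl * rep3(t2)
  gk <- gi * rep3(t1) - gl * rep3(1 + t2)
  shape <- function(m) array(m, dim = c(3, T_, F))
  list(phi = matrix(phi, T_, F), gi = shape(gi), gj = shape(gj),
       gk = shape(gk), gl = shape(gl), T = T_, F = F)
}

## frozen non-bonded terms: energies per frame per component and forces
eval_nonbonded <- function(rp, X, forces = TRUE) {
  F <- dim(X)[3]
  comp <- matrix(0, nrow = F, ncol = 4,
                 dimnames = list(NULL, c("lj", "coulomb", "lj14",
                                         "coulomb14")))
  Fout <- if (forces) array(0, dim = dim(X)) else NULL
  ke <- fm_constants[["coulomb"]]
  one <- function(pairs, s_elec, s_vdw, lj_name, coul_name) {
    if (is.null(pairs) || !nrow(pairs)) return()
    P <- nrow(pairs); tf <- c(P, F)
    iv <- pairs[, 1]; jv <- pairs[, 2]
    D <- gather(X, iv) - gather(X, jv)
    r2 <- csum(D * D)
    if (any(r2 < 1e-12)) {
      bad <- which(r2 < 1e-12, arr.ind = TRUE)[1, ]
      stop("non-bonded singularity: atoms ", iv[bad[1]], " and ", jv[bad[1]],
           " closer than 1e-6 Angstrom (frame ", bad[2], ")")
    }
    eps <- sqrt(rp$eps[iv] * rp$eps[jv])
    sig <- (rp$sigma[iv] + rp$sigma[jv]) / 2
    sr6 <- (sig * sig / r2)^3             # sig^2/r2 recycles down columns
    elj <- (s_vdw * 4) * eps * (sr6 * sr6 - sr6)
    qq <- (s_elec * ke) * rp$q[iv] * rp$q[jv]
    r <- sqrt(r2)
    ec <- qq / r
    comp[, lj_name] <<- comp[, lj_name] + colSums(matrix(elj, P, F))
    comp[, coul_name] <<- comp[, coul_name] + colSums(matrix(ec, P, F))
    if (forces) {
      dlj <- (s_vdw * -12) * eps * sr6 * (2 * sr6 - 1) / r2   # dE/dr2
      dc <- -qq / (2 * r2 * r)
      fv <- D * b3(-2 * (dlj + dc))
      Fout <<- scatter_add_multi(Fout, list(iv, jv), list(fv, -fv))
    }
  }
  one(rp$nb, 1, 1, "lj", "coulomb")
  one(rp$p14, rp$scale14[["elec"]], rp$scale14[["vdw"]], "lj14", "coulomb14")
  list(components = comp, forces = Fout)
}

## -- full evaluator ----------------------------------------------------------

eval_mm_batch <- function(rp, X, forces = TRUE) {
  F <- dim(X)[3]
  Fout <- if (forces) array(0, dim = dim(X)) else NULL
  comp <- matrix(0, nrow = F, ncol = 9,
                 dimnames = list(NULL, c("bond", "angle", "dihedral",
                                         "improper", "lj", "coulomb",
                                         "lj14", "coulomb14", "total")))

  if (!is.null(rp$bond)) {
    g <- geom_bonds(X, rp$bond$idx)
    dr <- g$r - rp$bond$r0
    comp[, "bond"] <- colSums(matrix(rp$bond$k * dr * dr, g$B, F))
    if (forces) {
      fv <- g$gi * b3(-2 * rp$bond$k * dr)
      Fout <- scatter_add_multi(Fout, list(rp$bond$idx[, 1], rp$bond$idx[, 2]),
                                list(fv, -fv))
    }
  }
  if (!is.null(rp$angle)) {
    g <- geom_angles(X, rp$angle$idx)
    dth <- g$theta - rp$angle$theta0
    comp[, "angle"] <- colSums(matrix(rp$angle$k * dth * dth, g$A, F))
    if (forces) {
      coef <- b3(-2 * rp$angle$k * dth)
      fi <- g$gi * coef; fk <- g$gk * coef
      Fout <- scatter_add_multi(Fout,
        list(rp$angle$idx[, 1], rp$angle$idx[, 3], rp$angle$idx[, 2]),
        list(fi, fk, -(fi + fk)))
    }
  }
  tors <- function(tt, comp_name) {
    if (is.null(tt)) return()
    g <- geom_torsions(X, tt$idx)
    arg <- tt$n * g$phi - tt$delta
    comp[, comp_name] <<- comp[, comp_name] +
      colSums(matrix(tt$k * (1 + cos(arg)), g$T, F))
    if (forces) {
      coef <- b3(tt$k * tt$n * sin(arg))  # -dE/dphi
      Fout <<- scatter_add_multi(Fout,
        list(tt$idx[, 1], tt$idx[, 2], tt$idx[, 3], tt$idx[, 4]),
        list(g$gi * coef, g$gj * coef, g$gk * coef, g$gl * coef))
    }
  }
  tors(rp$dihedral, "dihedral")
  tors(rp$improper, "improper")

  nb <- eval_nonbonded(rp, X, forces = forces)
  comp[, colnames(nb$components)] <- nb$components
  if (forces) Fout <- Fout + nb$forces

  comp[, "total"] <- rowSums(comp[, 1:8, drop = FALSE])
  list(components = comp, forces = Fout)
}

## -- precomputed-features fast path for refitting ----------------------------

## Geometry features + frozen non-bonded baseline for a fixed trajectory.
## Bonded energies/forces for ANY trial bonded parameter set are then linear
## recombinations of these arrays.
precompute_features <- function(top, params, coords) {
  coords <- as_traj(coords)
  X <- aperm(coords, c(2, 1, 3))
  rp <- resolve_params(top, params)
  ft <- list(rp = rp, F = dim(X)[3], n_atoms = dim(X)[2])
  if (!is.null(rp$bond)) ft$bond <- geom_bonds(X, rp$bond$idx)
  if (!is.null(rp$angle)) ft$angle <- geom_angles(X, rp$angle$idx)
  if (!is.null(rp$dihedral)) ft$dihedral <- geom_torsions(X, rp$dihedral$idx)
  if (!is.null(rp$improper)) ft$improper <- geom_torsions(X, rp$improper$idx)
  ft$nb <- eval_nonbonded(rp, X, forces = TRUE)
  ft
}

## Evaluate total energies (length F) and forces (3 x N x F) for trial
## bonded parameters, reusing precomputed geometry.
eval_from_features <- function(ft, top, params, forces = TRUE) {
  rp <- resolve_params(top, params)
  F <- ft$F
  e <- rowSums(ft$nb$components)
  Fout <- if (forces) ft$nb$forces else NULL
  if (!is.null(ft$bond)) {
    g <- ft$bond
    dr <- g$r - rp$bond$r0
    e <- e + colSums(matrix(rp$bond$k * dr * dr, g$B, F))
    if (forces) {
      fv <- g$gi * b3(-2 * rp$bond$k * dr)
      Fout <- scatter_add_multi(Fout, list(rp$bond$idx[, 1], rp$bond$idx[, 2]),
                                list(fv, -fv))
    }
  }
  if (!is.null(ft$angle)) {
    g <- ft$angle
    dth <- g$theta - rp$angle$theta0
    e <- e + colSums(matrix(rp$angle$k * dth * dth, g$A, F))
    if (forces) {
      coef <- b3(-2 * rp$angle$k * dth)
      fi <- g$gi * coef; fk <- g$gk * coef
      Fout <- scatter_add_multi(Fout,
        list(rp$angle$idx[, 1], rp$angle$idx[, 3], rp$angle$idx[, 2]),
        list(fi, fk, -(fi + fk)))
    }
  }
  for (kind in c("dihedral", "improper")) {
    g <- ft[[kind]]; tt <- rp[[kind]]
    if (is.null(g) || is.null(tt)) next
    arg <- tt$n * g$phi - tt$delta
    e <- e + colSums(matrix(tt$k * (1 + cos(arg)), g$T, F))
    if (forces) {
      coef <- b3(tt$k * tt$n * sin(arg))
      Fout <- scatter_add_multi(Fout,
        list(tt$idx[, 1], tt$idx[, 2], tt$idx[, 3], tt$idx[, 4]),
        list(g$gi * coef, g$gj * coef, g$gk * coef, g$gl * coef))
    }
  }
  list(energy = e, forces = Fout)
}

#' Evaluate the MM energy of a configuration
#'
#' @param top An `fm_topology`.
#' @param params An `fm_parameters`.
#' @param config `N x 3` coordinate matrix in Angstrom (a single frame).
#' @return Named numeric vector of per-term energies (kcal/mol): bond, angle,
#'   dihedral, improper, lj, coulomb, lj14, coulomb14, total.
#' @export
evaluate_energy <- function(top, params, config) {
  X <- to_internal(config, top)
  rp <- resolve_params(top, params)
  out <- eval_mm_batch(rp, X, forces = FALSE)
  out$components[1, ]
}

#' Evaluate analytic atomic forces
#'
#' Forces are the exact negative gradient of [evaluate_energy()]; for an
#' isolated system they sum to zero.
#'
#' @inheritParams evaluate_energy
#' @return `N x 3` matrix of forces in kcal/mol/Angstrom.
#' @export
evaluate_forces <- function(top, params, config) {
  X <- to_internal(config, top)
  rp <- resolve_params(top, params)
  out <- eval_mm_batch(rp, X, forces = TRUE)
  t(matrix(out$forces, nrow = 3))
}

#' Evaluate energies and forces over a whole trajectory
#'
#' @inheritParams evaluate_energy
#' @param traj `N x 3 x F` coordinate array.
#' @param forces Compute forces too?
#' @return List with `components` (`F x 9` energy matrix, kcal/mol) and
#'   `forces` (`N x 3 x F` array, or `NULL`).
#' @export
evaluate_trajectory <- function(top, params, traj, forces = TRUE) {
  traj <- as_traj(traj)
  stopifnot(dim(traj)[1] == top$n_atoms)
  X <- aperm(traj, c(2, 1, 3))
  rp <- resolve_params(top, params)
  out <- eval_mm_batch(rp, X, forces = forces)
  if (forces) out$forces <- aperm(out$forces, c(2, 1, 3))
  out
}

to_internal <- function(config, top) {
  config <- as.matrix(config)
  stopifnot(ncol(config) == 3, nrow(config) == top$n_atoms,
            all(is.finite(config)))
  array(t(config), dim = c(3, nrow(config), 1))
}
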