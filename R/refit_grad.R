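## Analytic gradient of the force-matching objective with respect to the
## fit-enabled class parameters, using precomputed geometry features.
##
## The model energy/forces are linear recombinations of per-instance geometry
## features, so every dJ/dp reduces to inner products between the residuals
## and per-instance sensitivity scalars -- no scatter and no finite
## differences needed.  Validated against finite differences in the tests.

fm_objective_gradient <- function(params, dataset, top, config, params0,
                                  features) {
  ent <- param_entries(params)
  if (!length(ent)) return(numeric())
  rp <- resolve_params(top, params)
  ev <- eval_from_features(features, top, params,
                           forces = config$w_force > 0)
  nF <- dataset$n_frames; n_at <- dataset$n_atoms
  var_E <- stats::var(dataset$energy) * (nF - 1) / nF
  dE <- ev$energy - dataset$energy
  if (config$offset == "mean") dE <- dE - mean(dE)
  ## energy-term prefactor: dJ_E/dp = (2/(nF varE)) sum_f dE_f dE_f/dp
  ce <- config$w_energy * 2 / (nF * var_E)

  use_f <- config$w_force > 0
  if (use_f) {
    fref <- features$fref_flat
    var_F <- mean(fref * fref) - mean(fref)^2
    dF <- as.numeric(ev$forces) - fref
    M <- length(fref)
    cf <- config$w_force * 2 / (M * var_F)
  }

  ## per-section per-instance residual inner products (T x F each)
  ip <- list()
  sens_E <- list()
  if (!is.null(features$bond)) {
    g <- features$bond
    Dg <- if (use_f) {
      R <- array(dF, dim = c(3, n_at, nF))
      csum((gather(R, rp$bond$idx[, 1]) - gather(R, rp$bond$idx[, 2])) * g$gi)
    } else NULL
    ip$bond <- Dg
  }
  if (!is.null(features$angle)) {
    g <- features$angle
    if (use_f) {
      R <- array(dF, dim = c(3, n_at, nF))
      ri <- gather(R, rp$angle$idx[, 1])
      rk <- gather(R, rp$angle$idx[, 3])
      rj <- gather(R, rp$angle$idx[, 2])
      ip$angle <- csum(ri * g$gi) + csum(rk * g$gk) - csum(rj * (g$gi + g$gk))
    }
  }
  for (kind in c("dihedral", "improper")) {
    g <- features[[kind]]
    if (is.null(g) || is.null(rp[[kind]])) next
    if (use_f) {
      R <- array(dF, dim = c(3, n_at, nF))
      tt <- rp[[kind]]
      ip[[kind]] <- csum(gather(R, tt$idx[, 1]) * g$gi) +
        csum(gather(R, tt$idx[, 2]) * g$gj) +
        csum(gather(R, tt$idx[, 3]) * g$gk) +
        csum(gather(R, tt$idx[, 4]) * g$gl)
    }
  }

  ## class-level accumulation
  grad <- numeric(length(ent))
  names(grad) <- names(ent)
  sec_of <- vapply(ent, `[[`, "", "section")
  slot_of <- vapply(ent, `[[`, "", "slot")
  row_of <- vapply(ent, function(e) e$row, integer(1))

  for (q in seq_along(ent)) {
    sec <- sec_of[q]; slot <- slot_of[q]; row <- row_of[q]
    if (sec == "bond") {
      key <- params$bonds$key[row]
      sel <- which(rp$bond$class == key)
      g <- features$bond
      r <- g$r[sel, , drop = FALSE]
      dr <- r - rp$bond$r0[sel][1]
      k <- rp$bond$k[sel][1]
      if (slot == "k") {
        dEdp <- colSums(dr * dr)                      # per frame
        coef <- -2 * dr                               # dcoef/dk on forces
      } else {                                        # r0
        dEdp <- colSums(-2 * k * dr)
        coef <- matrix(2 * k, nrow(dr), ncol(dr))
      }
      gF <- if (use_f) sum(coef * ip$bond[sel, , drop = FALSE]) else 0
    } else if (sec == "angle") {
      key <- params$angles$key[row]
      sel <- which(rp$angle$class == key)
      g <- features$angle
      th <- g$theta[sel, , drop = FALSE]
      dth <- th - rp$angle$theta0[sel][1]
      k <- rp$angle$k[sel][1]
      if (slot == "k") {
        dEdp <- colSums(dth * dth)
        coef <- -2 * dth
      } else {                                        # theta0
        dEdp <- colSums(-2 * k * dth)
        coef <- matrix(2 * k, nrow(dth), ncol(dth))
      }
      gF <- if (use_f) sum(coef * ip$angle[sel, , drop = FALSE]) else 0
    } else {                                          # dihedral / improper
      tab <- if (sec == "dihedral") params$dihedrals else params$impropers
      tt <- rp[[sec]]
      sel <- which(tt$row == row)
      g <- features[[sec]]
      arg <- tt$n[sel][1] * g$phi[sel, , drop = FALSE] - tt$delta[sel][1]
      dEdp <- colSums(1 + cos(arg))                   # dE/dk
      coef <- tt$n[sel][1] * sin(arg)                 # dcoef/dk (force)
      gF <- if (use_f) sum(coef * ip[[sec]][sel, , drop = FALSE]) else 0
    }
    grad[q] <- ce * sum(dE * dEdp) + (if (use_f) cf * gF else 0)
  }

  ## regularization
  p <- param_vector(params); p0 <- param_vector(params0)
  s <- reg_scales(params0)
  grad + config$w_reg * 2 * (p - p0) / (s * s) / length(p)
}
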