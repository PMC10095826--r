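## Desk-scale stochastic sampler: overdamped Langevin (Euler-Maruyama) on
## analytic potentials, with optional well-tempered metadynamics biasing.

#' Analytic toy potential
#'
#' @param energy Function `x -> scalar` energy (kcal/mol); `x` is a numeric
#'   vector of length `ndim`.
#' @param gradient Function `x -> gradient vector`; if `NULL`, central finite
#'   differences (step 1e-6) are used.
#' @param ndim Dimensionality.
#' @param periodic Logical per dimension.
#' @param period Period per periodic dimension.
#' @param domain Length-2 guard (same for every dimension); trajectories
#'   leaving it abort with the offending step index.
#' @return An object of class `fm_potential`.
#' @export
toy_potential <- function(energy, gradient = NULL, ndim = 1,
                          periodic = rep(FALSE, ndim), period = rep(NA, ndim),
                          domain = c(-50, 50)) {
  if (is.null(gradient)) {
    gradient <- function(x) {
      g <- numeric(length(x))
      for (i in seq_along(x)) {
        h <- 1e-6
        xp <- x; xp[i] <- x[i] + h; xm <- x; xm[i] <- x[i] - h
        g[i] <- (energy(xp) - energy(xm)) / (2 * h)
      }
      g
    }
  }
  structure(list(energy = energy, gradient = gradient, ndim = ndim,
                 periodic = periodic, period = period, domain = domain),
            class = "fm_potential")
}

#' Harmonic well \eqn{U = k (x-x_0)^2 / 2}
#' @param k Force constant (kcal/mol/A^2).
#' @param x0 Minimum position.
#' @return `fm_potential`.
#' @export
harmonic_potential <- function(k, x0 = 0) {
  toy_potential(function(x) 0.5 * k * sum((x - x0)^2),
                function(x) k * (x - x0), ndim = length(x0))
}

#' Quartic double well \eqn{U = h[(x/a)^2-1]^2 + c x}
#'
#' Minima near \eqn{\pm a}, barrier height `h` at the symmetric point, tilted
#' by the linear coefficient `c` to make the wells inequivalent.
#'
#' @param barrier Barrier height h (kcal/mol).
#' @param a Half-separation of the minima (Angstrom).
#' @param tilt Linear tilt coefficient c (kcal/mol/A), default 0 (symmetric).
#' @return `fm_potential`.
#' @export
double_well_potential <- function(barrier, a = 3, tilt = 0) {
  toy_potential(
    function(x) barrier * (sum(x * x) / a^2 - 1)^2 + tilt * x[1],
    function(x) 4 * barrier * (sum(x * x) / a^2 - 1) * x / a^2 + tilt,
    ndim = 1, domain = c(-4 * a, 4 * a))
}

#' Well-tempered metadynamics configuration
#'
#' Defaults follow the spherical-CV binding protocol: initial Gaussian height
#' 0.24 kcal/mol, deposition interval 0.5 ps, bias factor 20, Gaussian width
#' 1 Angstrom (0.1 nm) on distance-like CVs (pi/16 and pi/8 are the
#' conventional widths for the polar and azimuthal angles).
#'
#' @param height Initial Gaussian height h0 (kcal/mol), > 0.
#' @param pace_time Deposition interval (ps); converted to steps with the
#'   integration time step.
#' @param bias_factor Well-tempered bias factor gamma > 1.
#' @param widths Per-CV Gaussian widths.
#' @param temperature System temperature (K).
#' @param grid_n Bias-grid resolution for 1D identity-CV runs (grid caching).
#' @return An object of class `fm_metad_config`.
#' @export
metad_config <- function(height = 0.24, pace_time = 0.5, bias_factor = 20,
                         widths = 1, temperature = 298, grid_n = 600L) {
  stopifnot(height > 0, bias_factor > 1, all(widths > 0), pace_time > 0)
  structure(list(height = height, pace_time = pace_time,
                 bias_factor = bias_factor, widths = widths,
                 temperature = temperature, grid_n = as.integer(grid_n)),
            class = "fm_metad_config")
}

## minimum-image difference for (possibly) periodic CV dimensions
cv_diff <- function(ds, periodic, period) {
  for (d in which(periodic)) {
    p <- period[d]
    ds[d, ] <- ds[d, ] - p * round(ds[d, ] / p)
  }
  ds
}

#' Evaluate the accumulated metadynamics bias
#'
#' Sums the deposited (tempered) Gaussians at query CV points, with
#' minimum-image wrapping on periodic dimensions.
#'
#' @param bias An `fm_bias` object (field of the [run_langevin()] result).
#' @param s Query points: numeric vector (one point, or many points for 1D)
#'   or `m x d` matrix.
#' @return Bias potential values (kcal/mol).
#' @export
bias_value <- function(bias, s) {
  d <- length(bias$widths)
  s <- if (is.matrix(s)) t(s) else matrix(s, nrow = d)
  m <- ncol(s)
  out <- numeric(m)
  H <- nrow(bias$hills)
  if (H == 0) return(out)
  centers <- t(as.matrix(bias$hills[, grep("^center", names(bias$hills)),
                                    drop = FALSE]))  # d x H
  h <- bias$hills$height
  for (q in seq_len(m)) {
    ds <- cv_diff(centers - s[, q], bias$periodic, bias$period)
    z <- colSums((ds / bias$widths)^2)
    out[q] <- sum(h * exp(-0.5 * z))
  }
  out
}

#' Overdamped Langevin dynamics with optional well-tempered metadynamics
#'
#' Euler-Maruyama integration of
#' \eqn{dx = \mu F dt + \sqrt{2 k_B T \mu\, dt}\, \eta} with uniform mobility
#' \eqn{\mu = 1/(m\gamma_f)} (any positive mobility leaves the Boltzmann
#' distribution invariant, so masses only set the time scale).  With
#' metadynamics enabled, Gaussians of height
#' \eqn{h_t = h_0 e^{-V(s_t)/(k_B \Delta T)}}, \eqn{\Delta T = (\gamma-1)T},
#' are deposited every `pace_time`.  The CV defaults to the coordinates
#' themselves; a custom CV mapping with gradient can be supplied.
#'
#' @param potential An `fm_potential`.
#' @param x0 Initial position.
#' @param n_steps Number of integration steps.
#' @param dt Time step (ps).  Stability heuristic for a stiffest force
#'   constant k: `dt <= 0.1 * mass * friction / (k * 418.4)`.
#' @param friction Friction coefficient (1/ps), default 1.
#' @param mass Particle mass (amu), default 12.
#' @param temperature Temperature (K), default 298.
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @param metad Optional [metad_config()].
#' @param cv Optional list `list(f = function(x) s, grad = function(x)`
#'   `d x ndim matrix, periodic, period)` mapping coordinates to CVs.
#' @param record_every Store every k-th frame.
#' @return An object of class `fm_cv_traj`: `positions` (frames x ndim),
#'   `cv` (frames x d), `bias_at_frame`, `time`, `bias` (`fm_bias`: hills
#'   data.frame, widths, bias factor, temperature), `dt`.
#' @export
run_langevin <- function(potential, x0, n_steps, dt, friction = 1, mass = 12,
                         temperature = 298, seed = 1L, metad = NULL,
                         cv = NULL, record_every = 1L) {
  set.seed(seed)
  mu <- fm_constants[["kcal_akma"]] / (mass * friction)  # A^2 / (kcal/mol ps)
  kT <- kBT(temperature)
  noise_sd <- sqrt(2 * kT * mu * dt)
  x <- as.numeric(x0)
  nd <- potential$ndim
  stopifnot(length(x) == nd)

  use_metad <- !is.null(metad)
  if (use_metad) {
    d_cv <- length(metad$widths)
    cv_f <- if (is.null(cv)) identity else cv$f
    cv_periodic <- if (is.null(cv)) potential$periodic[seq_len(d_cv)]
                   else cv$periodic
    cv_period <- if (is.null(cv)) potential$period[seq_len(d_cv)]
                 else cv$period
    pace_steps <- max(1L, as.integer(round(metad$pace_time / dt)))
    dT <- (metad$bias_factor - 1) * metad$temperature
    kBdT <- fm_constants[["kB"]] * dT
    hills <- matrix(numeric(), ncol = d_cv + 2L)
    ## grid cache for the common 1D identity-CV case
    use_grid <- is.null(cv) && nd == 1L && d_cv == 1L &&
      !isTRUE(cv_periodic[1])
    if (use_grid) {
      gx <- seq(potential$domain[1], potential$domain[2],
                length.out = metad$grid_n)
      gV <- numeric(metad$grid_n)
      gD <- numeric(metad$grid_n)   # dV/ds on the grid
      gstep <- gx[2] - gx[1]
    }
    bias_at <- function(s) {
      if (use_grid) {
        ii <- (s - gx[1]) / gstep
        i0 <- pmin(pmax(floor(ii), 0), metad$grid_n - 2)
        w <- ii - i0
        (1 - w) * gV[i0 + 1] + w * gV[i0 + 2]
      } else if (nrow(hills) == 0) 0 else {
        ds <- cv_diff(t(hills[, seq_len(d_cv), drop = FALSE]) - s,
                      cv_periodic, cv_period)
        sum(hills[, d_cv + 2L] * exp(-0.5 * colSums((ds / metad$widths)^2)))
      }
    }
    bias_grad <- function(s) {
      if (use_grid) {
        ii <- (s - gx[1]) / gstep
        i0 <- pmin(pmax(floor(ii), 0), metad$grid_n - 2)
        w <- ii - i0
        (1 - w) * gD[i0 + 1] + w * gD[i0 + 2]
      } else if (nrow(hills) == 0) numeric(d_cv) else {
        ds <- cv_diff(t(hills[, seq_len(d_cv), drop = FALSE]) - s,
                      cv_periodic, cv_period)
        z <- exp(-0.5 * colSums((ds / metad$widths)^2)) * hills[, d_cv + 2L]
        ## d/ds exp(-(s-c)^2/2w^2) = (c-s)/w^2 exp(.), and ds = c - s
        as.numeric((ds / metad$widths^2) %*% z)
      }
    }
  }

  n_rec <- n_steps %/% record_every
  pos <- matrix(NA_real_, nrow = n_rec, ncol = nd)
  cvs <- if (use_metad) matrix(NA_real_, nrow = n_rec, ncol = d_cv) else NULL
  bias_rec <- if (use_metad) numeric(n_rec) else NULL
  rec <- 0L

  for (step in seq_len(n_steps)) {
    f <- -potential$gradient(x)
    if (use_metad) {
      s <- cv_f(x)
      vb_grad <- bias_grad(s)
      if (is.null(cv)) {
        f[seq_len(d_cv)] <- f[seq_len(d_cv)] - vb_grad
      } else {
        f <- f - as.numeric(t(cv$grad(x)) %*% vb_grad)
      }
      if (step %% pace_steps == 0L) {
        v_here <- bias_at(s)
        h_t <- metad$height * exp(-v_here / kBdT)
        hills <- rbind(hills, c(s, step * dt, h_t))
        if (use_grid) {
          dg <- gx - s
          e <- h_t * exp(-0.5 * (dg / metad$widths)^2)
          gV <- gV + e
          gD <- gD + e * (-dg / metad$widths^2)
        }
      }
    }
    x <- x + mu * f * dt
    if (temperature > 0) x <- x + noise_sd * stats::rnorm(nd)
    for (d in which(potential$periodic)) {
      p <- potential$period[d]
      x[d] <- x[d] - p * round(x[d] / p)
    }
    if (any(x < potential$domain[1]) || any(x > potential$domain[2]))
      stop("trajectory diverged outside the domain guard at step ", step)
    if (step %% record_every == 0L) {
      rec <- rec + 1L
      pos[rec, ] <- x
      if (use_metad) {
        s <- cv_f(x)
        cvs[rec, ] <- s
        bias_rec[rec] <- bias_at(s)
      }
    }
  }

  bias <- NULL
  if (use_metad) {
    hdf <- as.data.frame(hills)
    names(hdf) <- c(paste0("center", seq_len(d_cv)), "time", "height")
    bias <- structure(list(hills = hdf[, c(paste0("center", seq_len(d_cv)),
                                           "time", "height")],
                           widths = metad$widths,
                           periodic = cv_periodic, period = cv_period,
                           bias_factor = metad$bias_factor,
                           temperature = metad$temperature),
                      class = "fm_bias")
  }
  structure(list(positions = pos,
                 cv = if (use_metad) cvs else pos,
                 bias_at_frame = bias_rec,
                 time = seq_len(n_rec) * record_every * dt,
                 bias = bias, dt = dt, seed = seed),
            class = "fm_cv_traj")
}

#' Free-energy surface from the accumulated well-tempered bias
#'
#' The standard well-tempered estimator
#' \eqn{F(s) = -\frac{\gamma}{\gamma-1} V_{bias}(s) + const}, shifted so the
#' minimum over the grid is zero.
#'
#' @param bias An `fm_bias` (from [run_langevin()]).
#' @param grid Numeric vector of 1D query points, or list of axis vectors for
#'   higher dimensions (evaluated on the tensor grid).
#' @param tail_average Fraction (0, 1) of the deposition history over which
#'   the instantaneous well-tempered estimates are time-averaged (1D only);
#'   0 uses the final bias alone.  Averaging over the converged tail is the
#'   standard way to damp the residual fluctuation of the estimator; additive
#'   offsets between checkpoints cancel in any free-energy difference.
#' @return For 1D: data.frame with `s` and `F` (kcal/mol).  For 2D: an
#'   `fes_grid`-compatible list with `values`, `axes`.
#' @export
fes_from_bias <- function(bias, grid, tail_average = 0) {
  if (nrow(bias$hills) == 0) stop("no deposited Gaussians in the bias state")
  g <- bias$bias_factor
  fac <- -g / (g - 1)
  if (!is.list(grid)) {
    if (tail_average > 0) {
      nh <- nrow(bias$hills)
      fracs <- seq(1 - tail_average, 1, length.out = 11)
      v <- rowMeans(vapply(fracs, function(fr) {
        b2 <- bias
        b2$hills <- bias$hills[seq_len(max(1, floor(fr * nh))), ,
                               drop = FALSE]
        bias_value(b2, grid)
      }, numeric(length(grid))))
    } else {
      v <- bias_value(bias, grid)
    }
    f <- fac * v
    data.frame(s = grid, F = f - min(f))
  } else {
    pts <- as.matrix(expand.grid(grid))
    v <- bias_value(bias, pts)
    f <- fac * v
    f <- f - min(f)
    list(values = array(f, dim = vapply(grid, length, integer(1))),
         axes = grid)
  }
}

#' Reweight biased frames to the unbiased ensemble
#'
#' Final-bias (constant-offset) reweighting: \eqn{w \propto
#' e^{+V_{final}(s)/k_B T}}, normalized to mean 1.  Overflow is guarded by a
#' max shift before exponentiation.
#'
#' @param traj An `fm_cv_traj` (or matrix of CV values).
#' @param bias An `fm_bias`.
#' @param temperature Temperature (K).
#' @return Per-frame weights with mean 1.
#' @export
reweight_frames <- function(traj, bias, temperature = 298) {
  s <- if (inherits(traj, "fm_cv_traj")) traj$cv else as.matrix(traj)
  v <- bias_value(bias, s)
  lw <- v / kBT(temperature)
  w <- exp(lw - max(lw))
  w / mean(w)
}
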