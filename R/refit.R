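#' Reference dataset for force matching
#'
#' Ordered frames of coordinates labelled with reference energies and per-atom
#' forces — the fitting target.  In the full workflow the labels come from a
#' quantum-chemical reference; here they may equally come from a ghost
#' Hamiltonian (see [ghost_reference_dataset()]).
#'
#' @param coords `N x 3 x F` coordinate array (Angstrom), F >= 2.
#' @param energy Length-F reference energies (kcal/mol).
#' @param forces `N x 3 x F` reference forces (kcal/mol/A).
#' @param meta List of metadata: `temperature` (K), `stride`, `level`
#'   (reference-level label), `seed`, noise sigmas.
#' @return An object of class `fm_refdata`.
#' @export
reference_dataset <- function(coords, energy, forces, meta = list()) {
  coords <- as_traj(coords)
  nf <- dim(coords)[3]
  if (nf < 2) stop("a reference dataset needs at least 2 frames")
  stopifnot(length(energy) == nf, all(is.finite(energy)),
            identical(dim(forces), dim(coords)), all(is.finite(forces)))
  structure(list(coords = coords, energy = energy, forces = forces,
                 meta = meta, n_frames = nf, n_atoms = dim(coords)[1]),
            class = "fm_refdata")
}

#' @export
print.fm_refdata <- function(x, ...) {
  cat("fm_refdata:", x$n_frames, "frames x", x$n_atoms, "atoms; level:",
      if (is.null(x$meta$level)) "?" else x$meta$level, "\n")
  invisible(x)
}

#' Fit configuration for force matching
#'
#' Energy and force data terms carry equal weight; the L2 regularization
#' weight defaults to 0.1 of the data weights (an intermediate level of
#' regularization).
#'
#' @param w_energy,w_force Data-term weights (equal by default).
#' @param w_reg Regularization weight; default `0.1 * w_energy`.
#' @param offset Energy-offset policy: `"mean"` removes the optimal least
#'   squares constant between MM and reference energies (they differ by an
#'   arbitrary zero), `"none"` compares raw values.
#' @param tol Relative objective-change tolerance for the optimizer.
#' @param max_iter Maximum optimizer iterations.
#' @param seed Stored for provenance (the fit itself is deterministic).
#' @return An object of class `fm_fit_config`.
#' @export
fit_config <- function(w_energy = 1, w_force = 1, w_reg = 0.1 * w_energy,
                       offset = c("mean", "none"), tol = 1e-10,
                       max_iter = 400L, seed = 1L) {
  stopifnot(w_energy >= 0, w_force >= 0, w_reg >= 0)
  structure(list(w_energy = w_energy, w_force = w_force, w_reg = w_reg,
                 offset = match.arg(offset), tol = tol,
                 max_iter = as.integer(max_iter), seed = seed),
            class = "fm_fit_config")
}

## Regularization scale per fit entry: s = max(|p0|, floor), floors keeping
## the penalty finite when the reference value is 0 (e.g. an absent torsional
## barrier).
reg_scales <- function(params0) {
  ent <- param_entries(params0)
  floors <- c(`bond:k` = 10, `bond:r0` = 0.1,
              `angle:k` = 5, `angle:theta0` = 0.1,
              `dihedral:k` = 0.5, `improper:k` = 0.5)
  vapply(ent, function(e) {
    fl <- floors[[paste(e$section, e$slot, sep = ":")]]
    max(abs(e$value), fl)
  }, numeric(1))
}

#' Force-matching objective function
#'
#' \eqn{J = w_E \hat J_E + w_F \hat J_F + w_{reg} \hat J_{reg}} with the
#' energy term the mean squared (offset-corrected) energy residual normalized
#' by the reference-energy variance, the force term the mean squared force
#' component residual normalized by the reference-force variance, and the
#' regularization term the mean squared scaled deviation from the reference
#' parameters over fit-enabled symmetry classes.
#'
#' @param params Trial `fm_parameters`.
#' @param dataset An `fm_refdata`.
#' @param top The shared `fm_topology`.
#' @param config An [fit_config()].
#' @param params0 Regularization anchor (defaults to `params`, giving
#'   `J_reg = 0`).
#' @param components Return the individual terms too?
#' @return Scalar objective, or a list with `J`, `J_energy`, `J_force`,
#'   `J_reg` when `components = TRUE`.
#' @export
fm_objective <- function(params, dataset, top, config = fit_config(),
                         params0 = params, components = FALSE,
                         features = NULL) {
  use_forces <- config$w_force > 0
  if (is.null(features)) {
    ev <- evaluate_trajectory(top, params, dataset$coords,
                              forces = use_forces)
    e_mm <- ev$components[, "total"]
    f_mm <- if (use_forces) as.numeric(ev$forces) else NULL
    f_ref <- if (use_forces) as.numeric(dataset$forces) else NULL
  } else {
    ev <- eval_from_features(features, top, params, forces = use_forces)
    e_mm <- ev$energy
    f_mm <- if (use_forces) as.numeric(ev$forces) else NULL
    f_ref <- if (use_forces) features$fref_flat else NULL
  }
  var_E <- stats::var(dataset$energy) * (dataset$n_frames - 1) /
    dataset$n_frames
  if (var_E < 1e-12)
    stop("reference energies have zero variance; cannot normalize the ",
         "energy term (check the dataset or set w_energy = 0)")
  dE <- e_mm - dataset$energy
  if (config$offset == "mean") dE <- dE - mean(dE)
  J_E <- mean(dE * dE) / var_E

  J_F <- 0
  if (use_forces) {
    var_F <- mean(f_ref * f_ref) - mean(f_ref)^2
    if (var_F < 1e-12)
      stop("reference forces have zero variance; cannot normalize the ",
           "force term")
    dF <- f_mm - f_ref
    J_F <- mean(dF * dF) / var_F
  }

  p <- param_vector(params); p0 <- param_vector(params0)
  J_reg <- if (length(p)) mean(((p - p0) / reg_scales(params0))^2) else 0

  J <- config$w_energy * J_E + config$w_force * J_F + config$w_reg * J_reg
  if (components) list(J = J, J_energy = J_E, J_force = J_F, J_reg = J_reg)
  else J
}

## bounds per fit entry: force constants >= 0, r0/theta0 positive,
## dihedral amplitudes unconstrained.
fit_bounds <- function(params0) {
  ent <- param_entries(params0)
  lower <- vapply(ent, function(e) {
    switch(paste(e$section, e$slot, sep = ":"),
           `bond:k` = 0, `angle:k` = 0, `bond:r0` = 0.1,
           `angle:theta0` = 0.05, -Inf)
  }, numeric(1))
  upper <- vapply(ent, function(e) {
    if (e$section == "angle" && e$slot == "theta0") pi else Inf
  }, numeric(1))
  list(lower = lower, upper = upper)
}

#' Fit bonded parameters by simultaneous energy- and force-matching
#'
#' Deterministic bounded quasi-Newton (L-BFGS-B) minimization of
#' [fm_objective()] over the fit-enabled symmetry-class parameters, starting
#' from and regularized towards `params0`.  Frozen parameters (charges, LJ,
#' 1-4 scales, periodicities, phases, any term with `fit_* = FALSE`) are
#' untouched.  Gradients over the class vector are analytic (exact inner
#' products with precomputed geometry features; validated against finite
#' differences in the test suite), and the optimisation runs in scaled
#' coordinates for conditioning.
#'
#' @param dataset An `fm_refdata`.
#' @param top The `fm_topology`.
#' @param params0 Starting (and regularization-anchor) `fm_parameters`.
#' @param config An [fit_config()].
#' @return An object of class `fm_fit`: `params` (fitted set), `value`,
#'   `trace` (objective evaluations), `converged`, `start`, `n_eval`.
#' @export
fit_parameters <- function(dataset, top, params0, config = fit_config()) {
  x0 <- param_vector(params0)
  if (!length(x0)) stop("no fit-enabled parameter classes")
  bounds <- fit_bounds(params0)
  trace_env <- new.env(); trace_env$tr <- numeric(); trace_env$n <- 0L

  ## geometry features are parameter independent: precompute once
  features <- precompute_features(top, params0, dataset$coords)
  features$fref_flat <- as.numeric(aperm(dataset$forces, c(2, 1, 3)))

  ## optimize in scaled coordinates z = x / s for conditioning
  s <- reg_scales(params0)
  fn <- function(z) {
    x <- z * s
    p <- set_param_vector(params0, stats::setNames(x, names(x0)))
    val <- fm_objective(p, dataset, top, config, params0 = params0,
                        features = features)
    trace_env$n <- trace_env$n + 1L
    trace_env$tr <- c(trace_env$tr, val)
    val
  }
  gr <- function(z) {
    x <- z * s
    p <- set_param_vector(params0, stats::setNames(x, names(x0)))
    fm_objective_gradient(p, dataset, top, config, params0, features) * s
  }
  opt <- stats::optim(x0 / s, fn, gr, method = "L-BFGS-B",
                      lower = bounds$lower / s, upper = bounds$upper / s,
                      control = list(maxit = config$max_iter,
                                     factr = config$tol / .Machine$double.eps,
                                     pgtol = 0))
  fitted <- set_param_vector(params0, stats::setNames(opt$par * s, names(x0)))
  structure(list(params = fitted, value = opt$value,
                 trace = trace_env$tr, n_eval = trace_env$n,
                 converged = opt$convergence == 0,
                 message = opt$message, start = params0, config = config),
            class = "fm_fit")
}

#' @export
print.fm_fit <- function(x, ...) {
  cat("fm_fit: objective", signif(x$value, 6), "after", x$n_eval,
      "evaluations;", if (x$converged) "converged" else
        paste("NOT converged:", x$message), "\n")
  invisible(x)
}

#' Assess a parameter set against a reference dataset
#'
#' Energy RMSE/MAE on offset-corrected energies (the optimal constant shift is
#' removed before comparing, since MM and reference zeros differ), and the
#' per-atom force-error convention: the per-frame-per-atom Euclidean norms
#' \eqn{\|\Delta F_i\|_2}, with the force RMSE defined as
#' \eqn{\sqrt{\mathrm{mean}_{t,i}\,\|\Delta F_i\|^2}} in kcal/(mol A atom).
#' The per-atom series is reported heavy-atoms-first.
#'
#' @param dataset An `fm_refdata`.
#' @param top The `fm_topology`.
#' @param params The `fm_parameters` under assessment.
#' @return An object of class `fm_assessment`: `energy_rmse`, `energy_mae`,
#'   `force_rmse`, `force_error_norms` (atoms x frames, heavy first),
#'   `atom_order`, `bin_counts`, `level`.
#' @export
assess <- function(dataset, top, params) {
  ev <- evaluate_trajectory(top, params, dataset$coords, forces = TRUE)
  dE <- ev$components[, "total"] - dataset$energy
  dE <- dE - mean(dE)
  dF <- ev$forces - dataset$forces
  norms <- sqrt(apply(dF * dF, c(1, 3), sum))  # atoms x frames
  ord <- order(!top$atoms$heavy)               # stable: heavy first
  norms <- norms[ord, , drop = FALSE]
  rownames(norms) <- as.character(ord)
  cls <- classify_force_errors(as.numeric(norms))
  structure(list(
    energy_rmse = sqrt(mean(dE * dE)),
    energy_mae = mean(abs(dE)),
    force_rmse = sqrt(mean(norms * norms)),
    force_error_norms = norms,
    atom_order = ord,
    bin_counts = table(cls),
    level = dataset$meta$level,
    n_frames = dataset$n_frames
  ), class = "fm_assessment")
}

#' @export
print.fm_assessment <- function(x, ...) {
  cat("fm_assessment (", x$n_frames, " frames",
      if (!is.null(x$level)) paste0(", reference: ", x$level), ")\n", sep = "")
  cat(sprintf("  energy RMSE %.4f MAE %.4f kcal/mol\n",
              x$energy_rmse, x$energy_mae))
  cat(sprintf("  force RMSE %.4f kcal/(mol A atom)\n", x$force_rmse))
  print(x$bin_counts)
  invisible(x)
}

#' Classify per-atom force-error norms into the standard plotting bins
#'
#' Red for errors > 50 kcal/(mol A), green for (30, 50], blue for (10, 30],
#' white otherwise.
#'
#' @param norms Non-negative force-error norms, kcal/(mol A).
#' @return Factor with levels white < blue < green < red.
#' @export
classify_force_errors <- function(norms) {
  if (any(norms < 0)) stop("force-error norms must be non-negative")
  threshold_classes(norms, c(10, 30, 50))
}

## reference-dataset text I/O -------------------------------------------------

#' Write / read a reference dataset as plain text
#'
#' Three files: `<prefix>.xyz` (coordinates), `<prefix>_energies.tsv`
#' (frame, E_ref in kcal/mol) and `<prefix>_forces.tsv` (frame, atom, fx, fy,
#' fz in kcal/mol/A), each with a commented header recording units and
#' metadata.
#'
#' @param dataset An `fm_refdata`.
#' @param prefix Path prefix.
#' @param top Optional topology supplying element labels for the XYZ file.
#' @return `write_reference_dataset` returns `prefix` invisibly;
#'   `read_reference_dataset` an `fm_refdata`.
#' @export
write_reference_dataset <- function(dataset, prefix, top = NULL) {
  el <- if (!is.null(top)) top$atoms$type else NULL
  write_xyz(dataset$coords, paste0(prefix, ".xyz"), elements = el)
  hdr <- sprintf("# %s", c("units: kcal/mol, Angstrom",
                           paste("level:", dataset$meta$level),
                           paste("temperature_K:", dataset$meta$temperature),
                           paste("seed:", dataset$meta$seed)))
  con <- file(paste0(prefix, "_energies.tsv"), "w")
  writeLines(c(hdr, "frame\tenergy"), con)
  writeLines(sprintf("%d\t%s", seq_len(dataset$n_frames),
                     fmt12(dataset$energy)), con)
  close(con)
  con <- file(paste0(prefix, "_forces.tsv"), "w")
  writeLines(c(hdr, "frame\tatom\tfx\tfy\tfz"), con)
  for (f in seq_len(dataset$n_frames)) {
    m <- dataset$forces[, , f]
    writeLines(sprintf("%d\t%d\t%s\t%s\t%s", f, seq_len(dataset$n_atoms),
                       fmt12(m[, 1]), fmt12(m[, 2]), fmt12(m[, 3])), con)
  }
  close(con)
  invisible(prefix)
}

#' @rdname write_reference_dataset
#' @export
read_reference_dataset <- function(prefix) {
  coords <- read_xyz(paste0(prefix, ".xyz"))
  en <- utils::read.delim(paste0(prefix, "_energies.tsv"), comment.char = "#")
  fo <- utils::read.delim(paste0(prefix, "_forces.tsv"), comment.char = "#")
  n <- dim(coords)[1]; nf <- dim(coords)[3]
  forces <- array(0, dim = c(n, 3, nf))
  forces[cbind(fo$atom, 1, fo$frame)] <- fo$fx
  forces[cbind(fo$atom, 2, fo$frame)] <- fo$fy
  forces[cbind(fo$atom, 3, fo$frame)] <- fo$fz
  hdr <- grep("^#", readLines(paste0(prefix, "_energies.tsv"), n = 10),
              value = TRUE)
  level <- sub("^# level: ?", "", grep("level:", hdr, value = TRUE))
  temp <- suppressWarnings(as.numeric(
    sub("^# temperature_K: ?", "", grep("temperature_K:", hdr, value = TRUE))))
  reference_dataset(coords, en$energy[order(en$frame)], forces,
                    meta = list(level = if (length(level)) level else NA,
                                temperature = if (length(temp)) temp else NA))
}
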