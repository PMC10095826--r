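#' Build a gridded free-energy surface from (weighted) samples
#'
#' \eqn{F(\mathrm{bin}) = -k_B T \ln(w_{bin}/\max w)}, min-shifted to zero;
#' empty bins are masked.  Samples outside the grid are dropped.
#'
#' @param samples Numeric vector (1D) or `m x d` matrix of CV samples.
#' @param axes List of axis definitions, one per CV: either a numeric vector
#'   of bin edges, or `list(name=, n=, range=, periodic=)`.  Names of the
#'   list elements name the CVs.
#' @param weights Optional per-sample weights (default 1).
#' @param temperature Temperature (K), default 298.
#' @return An object of class `fes_grid`: `values` (array of F, kcal/mol),
#'   `mask` (TRUE where sampled), `weights` (summed per bin), `axes`
#'   (edges/mids/name/periodic), `temperature`.
#' @export
build_fes <- function(samples, axes, weights = NULL, temperature = 298) {
  samples <- as.matrix(samples)
  d <- ncol(samples)
  stopifnot(length(axes) == d)
  if (is.null(weights)) weights <- rep(1, nrow(samples))
  stopifnot(length(weights) == nrow(samples), all(weights >= 0))
  ax <- vector("list", d)
  for (k in seq_len(d)) {
    a <- axes[[k]]
    if (is.numeric(a)) {
      edges <- a
      name <- if (!is.null(names(axes)[k]) && nzchar(names(axes)[k]))
        names(axes)[k] else paste0("cv", k)
      periodic <- FALSE
    } else {
      edges <- if (!is.null(a$edges)) a$edges
               else seq(a$range[1], a$range[2], length.out = a$n + 1)
      name <- if (!is.null(a$name)) a$name else
        if (!is.null(names(axes)[k]) && nzchar(names(axes)[k]))
          names(axes)[k] else paste0("cv", k)
      periodic <- isTRUE(a$periodic)
    }
    stopifnot(length(edges) >= 2, !is.unsorted(edges))
    ax[[k]] <- list(name = name, edges = edges,
                    mids = (edges[-1] + edges[-length(edges)]) / 2,
                    periodic = periodic)
  }
  nbins <- vapply(ax, function(a) length(a$mids), integer(1))
  idx <- matrix(0L, nrow = nrow(samples), ncol = d)
  inside <- rep(TRUE, nrow(samples))
  for (k in seq_len(d)) {
    i <- findInterval(samples[, k], ax[[k]]$edges, rightmost.closed = TRUE)
    inside <- inside & i >= 1 & i <= nbins[k]
    idx[, k] <- i
  }
  if (!any(inside)) stop("all samples fall outside the grid")
  idx <- idx[inside, , drop = FALSE]
  w <- weights[inside]
  flat <- as.integer(idx[, 1])
  if (d > 1) {
    mult <- cumprod(c(1, nbins[-d]))
    flat <- as.integer((idx - 1) %*% mult + 1)
  }
  wsum <- numeric(prod(nbins))
  agg <- rowsum(w, flat)
  wsum[as.integer(rownames(agg))] <- agg[, 1]
  kT <- kBT(temperature)
  mask <- wsum > 0
  vals <- rep(NA_real_, length(wsum))
  vals[mask] <- -kT * log(wsum[mask] / max(wsum))
  structure(list(values = array(vals, dim = nbins),
                 mask = array(mask, dim = nbins),
                 weights = array(wsum, dim = nbins),
                 axes = ax, temperature = temperature,
                 n_samples = sum(inside)),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("fes_grid over", paste(vapply(x$axes, `[[`, "", "name"),
                             collapse = " x "),
      "(", paste(dim(x$values), collapse = " x "), "bins );",
      sum(x$mask), "sampled bins;", x$n_samples, "samples\n")
  invisible(x)
}

#' Locate the global free-energy minimum
#'
#' Returns the first-lowest masked bin; ties are broken by the lowest
#' flattened (column-major) index.
#'
#' @param fes A `fes_grid`.
#' @return List with `index` (array index vector), `flat_index`, `value`
#'   (kcal/mol) and `coords` (bin midpoints).
#' @export
find_global_min <- function(fes) {
  v <- as.numeric(fes$values)
  v[!fes$mask] <- Inf
  if (all(is.infinite(v))) stop("empty free-energy surface")
  fi <- which.min(v)  # which.min returns the first minimum
  ai <- arrayInd(fi, dim(fes$values))[1, ]
  list(index = ai, flat_index = fi, value = v[fi],
       coords = vapply(seq_along(ai),
                       function(k) fes$axes[[k]]$mids[ai[k]], numeric(1)))
}

#' Reference free energy of the zero-contact decoupled state
#'
#' Over the region of a (rho, C) surface with contact below `contact_threshold`
#' and COM distance above `rho_min`, returns the sample-weighted mean free
#' energy (`value`), the pooled macrostate free energy
#' \eqn{-k_B T \ln(\sum_{region} w / \max w)} (`pooled`), and the geometric
#' volume proxy of the sampled decoupled shell
#' \eqn{V_u = \frac{4\pi}{3}(\rho_{hi}^3 - \rho_{lo}^3)} used by the
#' standard-state correction.
#'
#' @param fes A `fes_grid` whose axes include a distance axis and a contact
#'   axis (identified by name).
#' @param contact_threshold Contacts below this count as decoupled
#'   (default 0.01).
#' @param rho_min Lower COM-distance bound of the region (default: the
#'   distance-axis minimum).
#' @param rho_axis,contact_axis Axis names (defaults "rho" and "C").
#' @return List with `value`, `pooled`, `volume` (A^3), `n_bins`,
#'   `rho_range`.
#' @export
decoupled_state_value <- function(fes, contact_threshold = 0.01,
                                  rho_min = NULL, rho_axis = "rho",
                                  contact_axis = "C") {
  nms <- vapply(fes$axes, `[[`, "", "name")
  ir <- match(rho_axis, nms); ic <- match(contact_axis, nms)
  if (is.na(ir) || is.na(ic))
    stop("fes axes must include '", rho_axis, "' and '", contact_axis, "'")
  if (is.null(rho_min)) rho_min <- min(fes$axes[[ir]]$edges)
  if (rho_min >= max(fes$axes[[ir]]$edges))
    stop("rho_min exceeds the grid: extend the grid or sample farther out")
  mids_r <- fes$axes[[ir]]$mids; mids_c <- fes$axes[[ic]]$mids
  sel_r <- mids_r > rho_min; sel_c <- mids_c < contact_threshold
  dims <- dim(fes$values)
  in_region <- array(FALSE, dims)
  idx <- arrayInd(seq_along(in_region), dims)
  in_region[] <- sel_r[idx[, ir]] & sel_c[idx[, ic]]
  use <- in_region & fes$mask
  if (!any(use))
    stop("no sampled bins in the decoupled region; sample longer or extend ",
         "the grid / lower rho_min")
  w <- fes$weights[use]; f <- fes$values[use]
  kT <- kBT(fes$temperature)
  occ_r <- sort(unique(idx[use, ir]))
  edges_r <- fes$axes[[ir]]$edges
  rho_lo <- max(rho_min, edges_r[min(occ_r)])
  rho_hi <- edges_r[max(occ_r) + 1]
  list(value = sum(w * f) / sum(w),
       pooled = -kT * log(sum(w) / max(fes$weights)),
       volume = 4 / 3 * pi * (rho_hi^3 - rho_lo^3),
       n_bins = sum(use), rho_range = c(rho_lo, rho_hi))
}

#' Standard-state specification
#'
#' @param volume Standard-state volume V° (A^3 per molecule at 1 M), default
#'   1660.54.
#' @param temperature Temperature (K), default 298.
#' @param v_unbound Sampled unbound volume V_u (A^3); if `NULL`, taken from
#'   the decoupled-state analysis.
#' @return An object of class `fm_std_state`.
#' @export
standard_state <- function(volume = 1660.54, temperature = 298,
                           v_unbound = NULL) {
  stopifnot(volume > 0, temperature > 0,
            is.null(v_unbound) || v_unbound > 0)
  structure(list(volume = volume, temperature = temperature,
                 v_unbound = v_unbound), class = "fm_std_state")
}

#' Standard-state binding free energy from a (rho, C) free-energy surface
#'
#' Two-term estimator: the free-energy difference between the bound state and
#' the zero-contact decoupled state, plus the entropic standard-state
#' correction \eqn{+k_B T \ln(V_u/V°)} (positive sign: a larger sampled
#' unbound volume makes binding look less favorable by \eqn{k_B T} per
#' e-fold).  Negative values mean favorable binding.
#'
#' Two constructions are available for each state.  The default follows the
#' common minimum-based convention: bound = global-minimum bin value,
#' decoupled = sample-weighted mean over the region, correction
#' \eqn{+k_B T \ln(V_u/V°)}.  The `"integrated"` / `"pooled"` variants use
#' total Boltzmann weights of the two macrostates; the pooled decoupled value
#' then already contains the translational entropy of the whole sampled
#' shell, so the standard-state conversion enters with the opposite sign,
#' \eqn{-k_B T \ln(V_u/V°)}, making the estimator the exact two-state
#' identity \eqn{\Delta G° = -k_B T \ln[(N_b/N_u)(V_u/V°)]} (volume
#' independent, as it must be).  The minimum-based variant is biased for wide
#' flat basins; the methods vignette quantifies both on the toy square well.
#'
#' @param fes A `fes_grid` over (rho, C).
#' @param decoupled_spec List with `contact_threshold` and `rho_min`, passed
#'   to [decoupled_state_value()].
#' @param std_state A [standard_state()].
#' @param bound `"minimum"` (default) or `"integrated"`.
#' @param decoupled `"mean"` (default) or `"pooled"`.
#' @return List with `dG` (kcal/mol), `bound_value`, `decoupled_value`,
#'   `correction`, `v_unbound`.
#' @export
binding_free_energy <- function(fes, decoupled_spec = list(),
                                std_state = standard_state(),
                                bound = c("minimum", "integrated"),
                                decoupled = c("mean", "pooled")) {
  bound <- match.arg(bound); decoupled <- match.arg(decoupled)
  ds <- do.call(decoupled_state_value, c(list(fes = fes), decoupled_spec))
  kT <- kBT(std_state$temperature)
  f_dec <- if (decoupled == "mean") ds$value else ds$pooled
  if (bound == "minimum") {
    f_b <- find_global_min(fes)$value
  } else {
    ## bound macrostate: everything outside the decoupled region
    nms <- vapply(fes$axes, `[[`, "", "name")
    ir <- match("rho", nms); ic <- match("C", nms)
    thr <- if (!is.null(decoupled_spec$contact_threshold))
      decoupled_spec$contact_threshold else 0.01
    rmin <- if (!is.null(decoupled_spec$rho_min)) decoupled_spec$rho_min
            else min(fes$axes[[ir]]$edges)
    idx <- arrayInd(seq_along(fes$values), dim(fes$values))
    dec <- fes$axes[[ir]]$mids[idx[, ir]] > rmin &
      fes$axes[[ic]]$mids[idx[, ic]] < thr
    use <- fes$mask & !array(dec, dim(fes$values))
    if (!any(use)) stop("no sampled bins in the bound region")
    f_b <- -kT * log(sum(fes$weights[use]) / max(fes$weights))
  }
  vu <- if (!is.null(std_state$v_unbound)) std_state$v_unbound else ds$volume
  corr_sign <- if (decoupled == "pooled") -1 else 1
  corr <- corr_sign * kT * log(vu / std_state$volume)
  list(dG = (f_b - f_dec) + corr,
       bound_value = f_b, decoupled_value = f_dec,
       correction = corr, v_unbound = vu,
       bound_method = bound, decoupled_method = decoupled)
}

#' Block-analysis standard deviation of an estimator
#'
#' Splits the sample stream into `n_blocks` contiguous blocks, applies the
#' estimator per block, and returns the standard deviation (ddof = 1) of the
#' per-block estimates — the usual block-analysis uncertainty of a trajectory
#' average.
#'
#' @param x Numeric vector (sample stream) or matrix (rows = samples).
#' @param n_blocks Number of contiguous blocks (>= 2), default 10.
#' @param estimator Function mapping a block (vector / matrix) to a scalar.
#' @return Standard deviation across block estimates.
#' @export
block_sd <- function(x, n_blocks = 10, estimator = mean) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  stopifnot(n_blocks >= 2)
  if (n < n_blocks) stop("fewer samples than blocks")
  breaks <- floor(seq(0, n, length.out = n_blocks + 1))
  est <- vapply(seq_len(n_blocks), function(b) {
    sel <- seq(breaks[b] + 1, breaks[b + 1])
    if (!length(sel)) stop("empty block")
    if (is.matrix(x)) estimator(x[sel, , drop = FALSE]) else estimator(x[sel])
  }, numeric(1))
  stats::sd(est)
}

## FES text I/O ---------------------------------------------------------------

#' Write / read a free-energy surface as gridded text
#'
#' Header lines record the axes (name, edges, periodic); the value matrix
#' follows with unsampled bins encoded as the sentinel `NA`.
#'
#' @param fes A `fes_grid`.
#' @param path File path.
#' @return `write_fes` returns `path` invisibly; `read_fes` a `fes_grid`.
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# fmbind free-energy surface; kcal/mol; NA = unsampled", con)
  writeLines(paste0("# temperature\t", fmt12(fes$temperature)), con)
  for (a in fes$axes)
    writeLines(paste0("# axis\t", a$name, "\t", a$periodic, "\t",
                      paste(fmt12(a$edges), collapse = ",")), con)
  v <- fes$values
  w <- fes$weights
  m <- if (length(dim(v)) == 1 || is.null(dim(v))) cbind(v) else v
  writeLines("# values (rows = first axis), then weights", con)
  utils::write.table(format(m, digits = 15, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines("# weights", con)
  mw <- if (length(dim(w)) == 1 || is.null(dim(w))) cbind(w) else w
  utils::write.table(format(mw, digits = 15, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  lines <- readLines(path)
  temp <- as.numeric(strsplit(grep("^# temperature", lines, value = TRUE),
                              "\t")[[1]][2])
  ax_lines <- grep("^# axis", lines, value = TRUE)
  axes <- lapply(ax_lines, function(l) {
    p <- strsplit(l, "\t")[[1]]
    edges <- as.numeric(strsplit(p[4], ",")[[1]])
    list(name = p[2], edges = edges,
         mids = (edges[-1] + edges[-length(edges)]) / 2,
         periodic = as.logical(p[3]))
  })
  body <- lines[!grepl("^#", lines)]
  wstart <- grep("^# weights", lines)
  vals_end <- sum(!grepl("^#", lines[seq_len(wstart - 1)]))
  parse_block <- function(bl) {
    rows <- lapply(strsplit(trimws(bl), "\\s+"), as.numeric)
    do.call(rbind, rows)
  }
  v <- parse_block(body[seq_len(vals_end)])
  w <- parse_block(body[-seq_len(vals_end)])
  dims <- vapply(axes, function(a) length(a$mids), integer(1))
  structure(list(values = array(as.numeric(v), dim = dims),
                 mask = array(!is.na(v), dim = dims),
                 weights = array(as.numeric(w), dim = dims),
                 axes = axes, temperature = temp,
                 n_samples = NA_integer_),
            class = "fes_grid")
}
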