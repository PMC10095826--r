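#' Rational switching function for contact counting
#'
#' The pair contact weight \eqn{s(r) = [1-(r/r_0)^6]/[1-(r/r_0)^{12}]},
#' evaluated through the algebraically equivalent non-singular form
#' \eqn{1/(1+(r/r_0)^6)}, which removes the 0/0 at \eqn{r = r_0}
#' (where the value is exactly 1/2).  Strictly decreasing in `r`.
#'
#' @param r Distances (Angstrom), any shape.
#' @param r0 Switching distance constant (Angstrom), default 6.
#' @return Contact weights in (0, 1].
#' @export
switching_value <- function(r, r0 = 6) {
  if (any(r < 0)) stop("distances must be non-negative")
  if (r0 <= 0) stop("r0 must be positive")
  1 / (1 + (r / r0)^6)
}

#' Contact-number specification between two atom groups
#'
#' @param group_a,group_b Disjoint 1-based atom index vectors.
#' @param r0 Switching distance constant (Angstrom), default 6.
#' @param heavy_only Drop hydrogens from both groups (the convention used for
#'   free-energy analysis); all-atom mode is used for monitoring plots.
#' @return An object of class `fm_contact_spec`.
#' @export
contact_spec <- function(group_a, group_b, r0 = 6, heavy_only = TRUE) {
  group_a <- as.integer(group_a); group_b <- as.integer(group_b)
  if (!length(group_a) || !length(group_b)) stop("empty atom group")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (r0 <= 0) stop("r0 must be positive")
  structure(list(group_a = group_a, group_b = group_b, r0 = r0,
                 heavy_only = heavy_only), class = "fm_contact_spec")
}

#' Switching-function contact numbers with by-atom decomposition
#'
#' Computes \eqn{C = \sum_{i\in A}\sum_{j\in B} s(r_{ij})} per frame, along
#' with the by-A-atom decomposition \eqn{C_i}, which sums exactly to `C`.
#'
#' @param coords `N x 3` matrix or `N x 3 x F` trajectory array.
#' @param spec An [contact_spec()] object.
#' @param top Optional `fm_topology`, required when `spec$heavy_only` to
#'   identify hydrogens.
#' @return List with `C` (length-F numeric) and `Ci` (|A| x F matrix, rows
#'   named by atom index; rows for filtered-out atoms are zero).
#' @export
contact_number <- function(coords, spec, top = NULL) {
  traj <- as_traj(coords)
  ga <- spec$group_a; gb <- spec$group_b
  if (spec$heavy_only) {
    if (is.null(top))
      stop("heavy_only contact evaluation needs the topology for heavy flags")
    ga_use <- ga[top$atoms$heavy[ga]]
    gb_use <- gb[top$atoms$heavy[gb]]
  } else {
    ga_use <- ga; gb_use <- gb
  }
  if (!length(ga_use) || !length(gb_use))
    stop("empty atom group after heavy-atom filtering")
  nf <- dim(traj)[3]
  Ci <- matrix(0, nrow = length(ga), ncol = nf,
               dimnames = list(as.character(ga), NULL))
  X <- aperm(traj, c(2, 1, 3))
  for (ia in seq_along(ga)) {
    i <- ga[ia]
    if (!(i %in% ga_use)) next
    acc <- 0
    xi <- matrix(X[, i, ], nrow = 3)
    for (j in gb_use) {
      d <- xi - matrix(X[, j, ], nrow = 3)
      acc <- acc + switching_value(sqrt(colSums(d * d)), spec$r0)
    }
    Ci[ia, ] <- acc
  }
  list(C = colSums(Ci), Ci = Ci)
}

#' Classify by-atom contact numbers into the standard monitoring bins
#'
#' Red for contacts > 10, green for (5, 10], blue for (1, 5], white otherwise
#' (boundaries are strict on the upper side of each named bin).
#'
#' @param ci Non-negative contact numbers.
#' @return Factor with levels white < blue < green < red.
#' @export
classify_contact_map <- function(ci) {
  if (any(ci < 0)) stop("contact numbers must be non-negative")
  threshold_classes(ci, c(1, 5, 10))
}

threshold_classes <- function(x, cuts) {
  lv <- c("white", "blue", "green", "red")
  idx <- findInterval(x, cuts, left.open = TRUE) + 1L
  factor(lv[idx], levels = lv)
}

#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{COM}|^2 / \sum_i m_i}}; the
#' unweighted variant sets all masses to 1.
#'
#' @param coords `N x 3` matrix or `N x 3 x F` array.
#' @param indices Atom subset (default all).
#' @param masses Per-atom masses for the subset (or full length-N vector);
#'   ignored when `mass_weighted = FALSE`.
#' @param mass_weighted Use masses in the COM and the average? Default TRUE.
#' @return Per-frame Rg (Angstrom).
#' @export
radius_of_gyration <- function(coords, indices = NULL, masses = NULL,
                               mass_weighted = TRUE) {
  traj <- as_traj(coords)
  n <- dim(traj)[1]
  if (is.null(indices)) indices <- seq_len(n)
  if (length(indices) < 2) stop("radius of gyration needs at least 2 atoms")
  m <- if (!mass_weighted || is.null(masses)) rep(1, length(indices))
       else if (length(masses) == n) masses[indices] else masses
  stopifnot(length(m) == length(indices))
  sub <- traj[indices, , , drop = FALSE]
  nf <- dim(sub)[3]
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    x <- sub[, , f, drop = FALSE][, , 1]
    com <- colSums(x * m) / sum(m)
    d2 <- rowSums(sweep(x, 2, com)^2)
    out[f] <- sqrt(sum(m * d2) / sum(m))
  }
  out
}

#' Spherical coordinates of the guest COM about the host COM
#'
#' Computes the vector v = COM(guest) - COM(host) in the laboratory frame and
#' returns \eqn{(\rho, \theta, \phi)} with \eqn{\rho=|v|}, polar angle
#' \eqn{\theta \in [0,\pi]} from +z and azimuth \eqn{\phi \in (-\pi,\pi]}.
#' COMs are mass-weighted when masses are supplied.
#'
#' @param coords `N x 3` matrix or `N x 3 x F` array.
#' @param host,guest Non-empty atom index vectors.
#' @param masses Optional per-atom masses (length N).
#' @return `F x 3` matrix with columns rho, theta, phi.  Frames with rho = 0
#'   get NA angles (flagged with a warning).
#' @export
spherical_cv <- function(coords, host, guest, masses = NULL) {
  traj <- as_traj(coords)
  if (!length(host) || !length(guest)) stop("empty atom group")
  n <- dim(traj)[1]; nf <- dim(traj)[3]
  if (is.null(masses)) masses <- rep(1, n)
  com <- function(idx, f) {
    x <- traj[idx, , f, drop = FALSE][, , 1, drop = FALSE]
    x <- matrix(x, ncol = 3)
    colSums(x * masses[idx]) / sum(masses[idx])
  }
  out <- matrix(NA_real_, nrow = nf, ncol = 3,
                dimnames = list(NULL, c("rho", "theta", "phi")))
  for (f in seq_len(nf)) {
    v <- com(guest, f) - com(host, f)
    rho <- sqrt(sum(v * v))
    out[f, "rho"] <- rho
    if (rho > 0) {
      out[f, "theta"] <- acos(pmin(1, pmax(-1, v[3] / rho)))
      out[f, "phi"] <- atan2(v[2], v[1])
    }
  }
  if (anyNA(out[, "theta"]))
    warning("rho = 0 in ", sum(is.na(out[, "theta"])),
            " frame(s): theta/phi undefined")
  out
}
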