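#' Molecular topology
#'
#' Holds atoms (type label, mass, partial charge, heavy-atom flag), the bonded
#' term lists (bonds, angles, proper and improper dihedrals) and the exclusion
#' structure derived from the bond graph: 1-2 and 1-3 pairs are excluded from
#' non-bonded interactions, 1-4 pairs are evaluated with scaled non-bonded
#' parameters, and all remaining pairs interact with full strength.  Atom
#' indices are 0-free: everything is 1-based inside R; serialized files are
#' also 1-based.
#'
#' @param types Character vector of atom-type labels.
#' @param masses Numeric vector of atomic masses (amu).
#' @param charges Numeric vector of partial charges (e).
#' @param heavy Logical vector flagging non-hydrogen atoms.  Default: mass > 3.
#' @param bonds Two-column integer matrix of bonded atom pairs.
#' @param angles Three-column integer matrix (i, j, k with j central).  If
#'   `NULL`, derived from the bond graph.
#' @param dihedrals Four-column integer matrix of proper torsions
#'   (i-j-k-l along three consecutive bonds).  If `NULL`, derived from the
#'   bond graph.
#' @param impropers Optional four-column integer matrix of improper torsions.
#' @return An object of class `fm_topology`.
#' @export
topology <- function(types, masses, charges = rep(0, length(types)),
                     heavy = masses > 3, bonds,
                     angles = NULL, dihedrals = NULL, impropers = NULL) {
  n <- length(types)
  stopifnot(length(masses) == n, length(charges) == n, length(heavy) == n,
            all(masses > 0), all(is.finite(charges)))
  bonds <- as_term_matrix(bonds, 2L, n)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  if (is.null(angles)) angles <- derive_angles(adj, n)
  angles <- as_term_matrix(angles, 3L, n, allow_empty = TRUE)
  if (is.null(dihedrals)) dihedrals <- derive_dihedrals(adj, bonds)
  dihedrals <- as_term_matrix(dihedrals, 4L, n, allow_empty = TRUE)
  impropers <- as_term_matrix(impropers, 4L, n, allow_empty = TRUE)

  excl <- derive_exclusions(adj, n)
  obj <- structure(list(
    n_atoms = n,
    atoms = data.frame(type = as.character(types), mass = masses,
                       charge = charges, heavy = as.logical(heavy),
                       stringsAsFactors = FALSE),
    bonds = bonds, angles = angles, dihedrals = dihedrals,
    impropers = impropers,
    excl12 = excl$p12, excl13 = excl$p13, pairs14 = excl$p14,
    nb_pairs = excl$full
  ), class = "fm_topology")
  obj
}

as_term_matrix <- function(x, width, n_atoms, allow_empty = FALSE) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0) || length(x) == 0) {
    if (allow_empty) return(matrix(integer(), ncol = width))
    stop("term list with ", width, " columns must be non-empty")
  }
  x <- matrix(as.integer(x), ncol = width)
  if (any(x < 1L) || any(x > n_atoms))
    stop("atom index out of range in term list")
  if (any(apply(x, 1, anyDuplicated) > 0))
    stop("repeated atom index inside a bonded term")
  x
}

derive_angles <- function(adj, n) {
  out <- list()
  for (j in seq_len(n)) {
    nb <- sort(unique(adj[[j]]))
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    out[[length(out) + 1L]] <- cbind(cmb[1, ], j, cmb[2, ])
  }
  do.call(rbind, out)
}

derive_dihedrals <- function(adj, bonds) {
  out <- list()
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1]; k <- bonds[b, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i != l) out[[length(out) + 1L]] <- c(i, j, k, l)
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 4))
  m <- do.call(rbind, out)
  ## canonical orientation + dedup (i-j-k-l identical to l-k-j-i)
  flip <- m[, 2] > m[, 3] | (m[, 2] == m[, 3] & m[, 1] > m[, 4])
  m[flip, ] <- m[flip, 4:1]
  unique(m)
}

## Bond-graph walk: pairs at graph distance 1 (excl12), 2 (excl13), 3 (pairs14)
## and the remaining full-strength non-bonded pairs.
derive_exclusions <- function(adj, n) {
  dist_pairs <- function(depth) {
    out <- list()
    for (i in seq_len(n)) {
      reach <- i; frontier <- i
      for (d in seq_len(depth)) {
        frontier <- setdiff(unique(unlist(adj[frontier])), reach)
        reach <- c(reach, frontier)
      }
      js <- frontier[frontier > i]
      if (length(js)) out[[length(out) + 1L]] <- cbind(i, js)
    }
    if (!length(out)) return(matrix(integer(), ncol = 2))
    do.call(rbind, out)
  }
  p12 <- dist_pairs(1); p13 <- dist_pairs(2); p14 <- dist_pairs(3)
  key <- function(m) if (nrow(m)) m[, 1] * (n + 1) + m[, 2] else integer()
  all_ij <- t(utils::combn(n, 2))
  excluded <- c(key(p12), key(p13), key(p14))
  full <- all_ij[!(key(all_ij) %in% excluded), , drop = FALSE]
  list(p12 = p12, p13 = p13, p14 = p14, full = full)
}

#' @export
print.fm_topology <- function(x, ...) {
  cat("fm_topology:", x$n_atoms, "atoms (",
      sum(x$atoms$heavy), "heavy ),",
      nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$dihedrals), "dihedrals,", nrow(x$impropers), "impropers\n")
  cat("  atom types:", paste(unique(x$atoms$type), collapse = ", "), "\n")
  invisible(x)
}

## canonical type keys for parameter lookup -----------------------------------

bond_key <- function(ta, tb) {
  swap <- ta > tb
  paste(ifelse(swap, tb, ta), ifelse(swap, ta, tb), sep = "-")
}

## vectorised canonical keys (reverse the tuple when the reversed string
## compares lower)
canonical_key <- function(mat_types) {
  fwd <- apply(mat_types, 1, paste, collapse = "-")
  rev_ <- apply(mat_types[, rev(seq_len(ncol(mat_types))), drop = FALSE],
                1, paste, collapse = "-")
  ifelse(rev_ < fwd, rev_, fwd)
}

term_type_keys <- function(top, term = c("bonds", "angles", "dihedrals",
                                         "impropers")) {
  term <- match.arg(term)
  m <- top[[term]]
  if (!nrow(m)) return(character())
  tt <- matrix(top$atoms$type[m], nrow = nrow(m))
  canonical_key(tt)
}
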