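#' Multi-frame XYZ trajectory I/O
#'
#' Standard XYZ dialect: atom count line, comment line (carries
#' `frame <i>` and optionally `energy <E>`), then `element x y z` rows in
#' Angstrom.  A trajectory is an `N x 3 x F` numeric array with attributes
#' `elements` (per-atom labels) and optionally `energies` (per-frame, from the
#' comment lines).
#'
#' @param path File path.
#' @param coords `N x 3` matrix (single frame) or `N x 3 x F` array.
#' @param elements Per-atom element/type labels (recycled from attribute if
#'   missing).
#' @param energies Optional per-frame energies written into comment lines.
#' @return `read_xyz` returns the trajectory array; `write_xyz` returns
#'   `path` invisibly.
#' @export
write_xyz <- function(coords, path, elements = NULL, energies = NULL) {
  coords <- as_traj(coords)
  if (is.null(elements)) elements <- attr(coords, "elements")
  n <- dim(coords)[1]; nf <- dim(coords)[3]
  if (is.null(elements)) elements <- rep("X", n)
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(as.character(n), con)
    cmt <- paste("frame", f)
    if (!is.null(energies)) cmt <- paste(cmt, "energy", fmt12(energies[f]))
    writeLines(cmt, con)
    writeLines(sprintf("%s %s %s %s", elements,
                       fmt12(coords[, 1, f]), fmt12(coords[, 2, f]),
                       fmt12(coords[, 3, f])), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  pos <- 1L; frames <- list(); energies <- numeric(); elements <- NULL
  while (pos <= length(lines)) {
    n <- as.integer(lines[pos])
    cmt <- lines[pos + 1L]
    e <- regmatches(cmt, regexec("energy ([-+0-9.eE]+)", cmt))[[1]]
    energies <- c(energies, if (length(e) == 2) as.numeric(e[2]) else NA_real_)
    rows <- strsplit(trimws(lines[pos + 1L + seq_len(n)]), "\\s+")
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[2:4])))
    if (is.null(elements)) elements <- vapply(rows, `[[`, character(1), 1)
    frames[[length(frames) + 1L]] <- m
    pos <- pos + 2L + n
  }
  arr <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  attr(arr, "elements") <- elements
  if (!all(is.na(energies))) attr(arr, "energies") <- energies
  arr
}

## coerce a single frame or array to N x 3 x F
as_traj <- function(coords) {
  if (is.matrix(coords)) {
    stopifnot(ncol(coords) == 3)
    coords <- array(coords, dim = c(nrow(coords), 3, 1))
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  coords
}
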