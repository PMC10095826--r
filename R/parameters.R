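#' Molecular-mechanics parameter set
#'
#' The complete parameter model for the Amber-style potential
#' \deqn{E = \sum k_b (r - r_{eq})^2 + \sum k_a (\theta - \theta_{eq})^2 +
#'       \sum k_d [1 + \cos(n\phi - \delta)] + E_{LJ} + E_{Coul}}
#' Parameters are stored per canonical atom-type key, so every term instance
#' sharing a type automatically shares one parameter value: the type keys ARE
#' the symmetry classes used in refitting.  Charges, Lennard-Jones parameters
#' and the 1-4 scale factors are always frozen; dihedral periodicities and
#' phases are fixed; bonds/angles/dihedral amplitudes carry fit flags.
#'
#' @param bonds data.frame with columns `key`, `k` (kcal/mol/A^2), `r0` (A)
#'   and optional logical `fit_k`, `fit_r0` (default `TRUE`).
#' @param angles data.frame with columns `key`, `k` (kcal/mol/rad^2),
#'   `theta0` (rad) and optional `fit_k`, `fit_theta0`.
#' @param dihedrals data.frame with columns `key`, `k` (kcal/mol), `n`
#'   (integer periodicity >= 1), `delta` (rad) and optional `fit_k`.  Several
#'   rows may share a key (multi-term torsions).
#' @param impropers Same layout as `dihedrals`; frozen by default
#'   (`fit_k = FALSE`) unless explicitly enabled.
#' @param lj data.frame with columns `type`, `eps` (kcal/mol), `sigma` (A).
#' @param scale14 Named numeric, 1-4 scale factors `c(elec = 1/1.2, vdw = 0.5)`
#'   (Amber convention); always frozen.
#' @return An object of class `fm_parameters`.
#' @export
parameter_set <- function(bonds, angles, dihedrals = NULL, impropers = NULL,
                          lj, scale14 = c(elec = 1 / 1.2, vdw = 0.5)) {
  fill <- function(df, flags, default = TRUE) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (f in flags) if (is.null(df[[f]])) df[[f]] <- rep(default, nrow(df))
    df
  }
  bonds <- fill(bonds, c("fit_k", "fit_r0"))
  angles <- fill(angles, c("fit_k", "fit_theta0"))
  dihedrals <- fill(dihedrals, "fit_k")
  impropers <- fill(impropers, "fit_k", default = FALSE)
  stopifnot(all(bonds$k >= 0), all(angles$k >= 0))
  if (!is.null(dihedrals) && nrow(dihedrals)) {
    stopifnot(all(dihedrals$n >= 1), all(dihedrals$n == round(dihedrals$n)))
  }
  if (anyDuplicated(bonds$key)) stop("duplicate bond type key")
  if (anyDuplicated(angles$key)) stop("duplicate angle type key")
  structure(list(bonds = bonds, angles = angles,
                 dihedrals = dihedrals, impropers = impropers,
                 lj = as.data.frame(lj, stringsAsFactors = FALSE),
                 scale14 = scale14),
            class = "fm_parameters")
}

#' @export
print.fm_parameters <- function(x, ...) {
  cat("fm_parameters:", nrow(x$bonds), "bond types,",
      nrow(x$angles), "angle types,",
      if (is.null(x$dihedrals)) 0 else nrow(x$dihedrals), "dihedral terms,",
      nrow(x$lj), "LJ types\n")
  nf <- length(param_vector(x))
  cat("  fit-enabled parameters:", nf, " | 1-4 scales: elec",
      signif(x$scale14[["elec"]], 4), "vdw", x$scale14[["vdw"]], "\n")
  invisible(x)
}

## fit-vector packing ---------------------------------------------------------

## One entry per fit-enabled (type key, slot) pair; names are stable
## identifiers "<section>:<key>:<slot>[:<term#>]".
param_entries <- function(params) {
  ent <- list()
  add <- function(section, df, slot, flag, term_id = NULL) {
    if (is.null(df) || !nrow(df)) return()
    sel <- which(df[[flag]])
    for (i in sel) {
      nm <- paste(c(section, df$key[i], slot,
                    if (!is.null(term_id)) term_id[i]), collapse = ":")
      ent[[nm]] <<- list(section = section, row = i, slot = slot,
                         value = df[[slot]][i])
    }
  }
  add("bond", params$bonds, "k", "fit_k")
  add("bond", params$bonds, "r0", "fit_r0")
  add("angle", params$angles, "k", "fit_k")
  add("angle", params$angles, "theta0", "fit_theta0")
  if (!is.null(params$dihedrals) && nrow(params$dihedrals))
    add("dihedral", params$dihedrals, "k", "fit_k",
        term_id = seq_len(nrow(params$dihedrals)))
  if (!is.null(params$impropers) && nrow(params$impropers))
    add("improper", params$impropers, "k", "fit_k",
        term_id = seq_len(nrow(params$impropers)))
  ent
}

#' Extract the fit-enabled parameter vector
#'
#' @param params An `fm_parameters` object.
#' @return Named numeric vector, one entry per fit-enabled symmetry class
#'   parameter.
#' @export
param_vector <- function(params) {
  ent <- param_entries(params)
  vapply(ent, function(e) e$value, numeric(1))
}

#' Write a fit vector back into a parameter set
#'
#' Frozen entries are untouched; symmetry is preserved because parameters are
#' stored per type key.
#'
#' @param params An `fm_parameters` object.
#' @param x Named numeric vector as produced by [param_vector()].
#' @return Updated `fm_parameters` object.
#' @export
set_param_vector <- function(params, x) {
  ent <- param_entries(params)
  stopifnot(length(x) == length(ent))
  if (!is.null(names(x))) stopifnot(identical(names(x), names(ent)))
  sec_map <- c(bond = "bonds", angle = "angles",
               dihedral = "dihedrals", improper = "impropers")
  for (i in seq_along(ent)) {
    e <- ent[[i]]
    params[[sec_map[[e$section]]]][[e$slot]][e$row] <- x[[i]]
  }
  params
}

#' Map bonded term instances to shared-parameter symmetry classes
#'
#' Every bonded term instance is assigned the canonical atom-type key that
#' indexes its parameters; all instances sharing a key share parameter values
#' by construction.  Fails if the topology references a type key absent from
#' the parameter set.
#'
#' @param top An `fm_topology`.
#' @param params An `fm_parameters`.
#' @return List with per-term-kind character vectors of class ids and a
#'   `n_classes` summary.
#' @export
symmetry_classes <- function(top, params) {
  res <- list()
  for (kind in c("bonds", "angles", "dihedrals", "impropers")) {
    keys <- term_type_keys(top, kind)
    if (!length(keys)) { res[[kind]] <- character(); next }
    have <- params[[kind]]$key
    missing <- setdiff(unique(keys), have)
    if (length(missing))
      stop("no ", sub("s$", "", kind), " parameters for type key(s): ",
           paste(missing, collapse = ", "))
    res[[kind]] <- keys
  }
  res$n_classes <- vapply(res[c("bonds", "angles", "dihedrals", "impropers")],
                          function(k) length(unique(k)), integer(1))
  res
}

## serialization --------------------------------------------------------------

fmt12 <- function(x) sprintf("%.15g", x)

#' Write / read a parameter set as structured text
#'
#' Sectioned plain-text format (`[bonds]`, `[angles]`, `[dihedrals]`,
#' `[impropers]`, `[lj]`, `[scale14]`), tab-separated columns, numbers stored
#' with 15 significant digits so a round trip is stable to at least 12.
#'
#' @param params An `fm_parameters` object.
#' @param path File path.
#' @return `write_parameter_set` returns `path` invisibly;
#'   `read_parameter_set` returns an `fm_parameters` object.
#' @export
write_parameter_set <- function(params, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# fmbind parameter set; units kcal/mol, Angstrom, radian")
  dump_df <- function(name, df, numcols) {
    if (is.null(df) || !nrow(df)) return()
    w("[", name, "]")
    w(paste(colnames(df), collapse = "\t"))
    for (i in seq_len(nrow(df))) {
      vals <- vapply(colnames(df), function(cn) {
        v <- df[[cn]][i]
        if (is.numeric(v)) fmt12(v) else as.character(v)
      }, character(1))
      w(paste(vals, collapse = "\t"))
    }
  }
  dump_df("bonds", params$bonds)
  dump_df("angles", params$angles)
  dump_df("dihedrals", params$dihedrals)
  dump_df("impropers", params$impropers)
  dump_df("lj", params$lj)
  w("[scale14]")
  w("elec\t", fmt12(params$scale14[["elec"]]))
  w("vdw\t", fmt12(params$scale14[["vdw"]]))
  invisible(path)
}

read_sections <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  idx <- grep("^\\[", lines)
  sections <- list()
  for (s in seq_along(idx)) {
    name <- gsub("\\[|\\]", "", lines[idx[s]])
    end <- if (s < length(idx)) idx[s + 1] - 1 else length(lines)
    sections[[name]] <- lines[seq(idx[s] + 1, end)]
  }
  sections
}

parse_table <- function(lines) {
  if (is.null(lines) || !length(lines)) return(NULL)
  hdr <- strsplit(lines[1], "\t")[[1]]
  rows <- strsplit(lines[-1], "\t")
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(df) <- hdr
  for (cn in hdr) {
    v <- df[[cn]]
    if (all(v %in% c("TRUE", "FALSE"))) df[[cn]] <- as.logical(v)
    else if (!anyNA(suppressWarnings(as.numeric(v)))) df[[cn]] <- as.numeric(v)
  }
  df
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  sec <- read_sections(path)
  s14 <- do.call(rbind, strsplit(sec$scale14, "\t"))
  scale14 <- stats::setNames(as.numeric(s14[, 2]), s14[, 1])
  parameter_set(bonds = parse_table(sec$bonds),
                angles = parse_table(sec$angles),
                dihedrals = parse_table(sec$dihedrals),
                impropers = parse_table(sec$impropers),
                lj = parse_table(sec$lj),
                scale14 = scale14)
}

#' Write / read a topology as structured text
#'
#' Sections `[atoms]` (type, mass, charge, heavy), `[bonds]`, `[angles]`,
#' `[dihedrals]`, `[impropers]`; indices 1-based.
#'
#' @param top An `fm_topology` object.
#' @param path File path.
#' @return `write_topology` returns `path` invisibly; `read_topology` an
#'   `fm_topology`.
#' @export
write_topology <- function(top, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# fmbind topology; 1-based indices")
  w("[atoms]")
  w("type\tmass\tcharge\theavy")
  for (i in seq_len(top$n_atoms))
    w(top$atoms$type[i], "\t", fmt12(top$atoms$mass[i]), "\t",
      fmt12(top$atoms$charge[i]), "\t", top$atoms$heavy[i])
  for (kind in c("bonds", "angles", "dihedrals", "impropers")) {
    m <- top[[kind]]
    if (!nrow(m)) next
    w("[", kind, "]")
    for (i in seq_len(nrow(m))) w(paste(m[i, ], collapse = "\t"))
  }
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  sec <- read_sections(path)
  at <- parse_table(sec$atoms)
  parse_idx <- function(lines) {
    if (is.null(lines)) return(NULL)
    do.call(rbind, lapply(strsplit(lines, "\t"), as.integer))
  }
  topology(types = at$type, masses = at$mass, charges = at$charge,
           heavy = at$heavy,
           bonds = parse_idx(sec$bonds), angles = parse_idx(sec$angles),
           dihedrals = parse_idx(sec$dihedrals),
           impropers = parse_idx(sec$impropers))
}
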