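#' Affinity table container
#'
#' Per-guest experimental and computed binding free energies with block-
#' analysis standard deviations, plus protonation-variant annotations (one
#' guest may appear as several variants sharing one experimental value).
#'
#' @param df data.frame with columns `guest`, `variant` (`NA` for
#'   single-form guests), `dG_exp`, one `dG_<set>` column per parameter set
#'   and matching optional `sd_<set>` columns.
#' @return An object of class `fm_affinity_table` (a data.frame).
#' @export
affinity_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("guest", "dG_exp") %in% names(df)))
  if (is.null(df$variant)) df$variant <- NA_character_
  if (anyNA(df$dG_exp)) stop("experimental value missing for a scored guest")
  sp <- split(df$dG_exp, df$guest)
  if (any(vapply(sp, function(v) length(unique(v)) > 1, logical(1))))
    stop("variants of one guest must share one experimental value")
  class(df) <- c("fm_affinity_table", "data.frame")
  df
}

#' Computed-value column names of an affinity table
#' @param table An `fm_affinity_table`.
#' @return Character vector of parameter-set labels.
#' @export
affinity_sets <- function(table) {
  sub("^dG_", "", grep("^dG_(?!exp)", names(table), value = TRUE, perl = TRUE))
}

#' Collapse protonation variants of a guest by arithmetic averaging
#'
#' When a guest's pKa is close to the experimental pH, both protonation forms
#' are modelled and the final estimate is the average of the two results;
#' this replaces the variant rows by a single row with per-column means.
#'
#' @param table An `fm_affinity_table`.
#' @param guest Guest label whose variants are collapsed.
#' @param variants Expected variant labels (all must be present).
#' @return Collapsed `fm_affinity_table`.
#' @export
apply_protonation_average <- function(table, guest = "G5",
                                      variants = c("prot", "deprot")) {
  rows <- which(table$guest == guest)
  if (!setequal(table$variant[rows], variants) ||
      length(rows) != length(variants))
    stop("guest ", guest, " must have exactly the variants: ",
         paste(variants, collapse = ", "))
  num_cols <- grep("^(dG|sd)_", names(table), value = TRUE)
  out <- table
  out[rows[1], num_cols] <-
    as.list(colMeans(table[rows, num_cols, drop = FALSE]))
  out$variant[rows[1]] <- NA_character_
  out <- out[-rows[-1], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}

#' Signed, absolute and root-mean-squared errors
#'
#' `MSE = mean(exp - calc)` (the sign convention under which a systematic
#' overestimate of binding strength, calc more negative than exp, gives a
#' negative MSE), `MAE = mean |exp - calc|`,
#' `RMSE = sqrt(mean (exp - calc)^2)`.
#'
#' @param exp,calc Equal-length numeric vectors (kcal/mol).
#' @return List with `mse`, `mae`, `rmse`.
#' @export
error_metrics <- function(exp, calc) {
  if (length(exp) != length(calc)) stop("length mismatch")
  if (!length(exp)) stop("empty input")
  d <- exp - calc
  list(mse = mean(d), mae = mean(abs(d)), rmse = sqrt(mean(d * d)))
}

#' Kendall rank correlation by pair enumeration
#'
#' \eqn{\tau = (n_{conc} - n_{disc}) / \binom{n}{2}}; a pair tied in either
#' vector contributes zero to the numerator (tau-a, no tie correction in the
#' denominator).
#'
#' @param exp,calc Equal-length numeric vectors, length >= 2.
#' @return tau in \[-1, 1\]; `NA` with a warning when either vector is
#'   constant.
#' @export
kendall_tau <- function(exp, calc) {
  n <- length(exp)
  stopifnot(length(calc) == n, n >= 2)
  if (length(unique(exp)) == 1 || length(unique(calc)) == 1) {
    warning("constant vector: tau undefined")
    return(NA_real_)
  }
  s <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    s <- s + sign(exp[j] - exp[i]) * sign(calc[j] - calc[i])
  s / choose(n, 2)
}

#' Pearlman predictive index
#'
#' Pairwise rank agreement weighted by the magnitude of the predicted
#' free-energy difference:
#' \eqn{PI = \sum_{j>i} w_{ij} c_{ij} / \sum_{j>i} w_{ij}} with
#' \eqn{w_{ij} = |\Delta G^{calc}_j - \Delta G^{calc}_i|} and
#' \eqn{c_{ij} = +1} when the predicted pair orders like the experimental
#' pair, \eqn{-1} when opposite, 0 when the experimental pair is tied.
#' (Weighting by predicted differences emphasises pairs the model claims to
#' separate strongly; it is the convention that reproduces published CB8
#' metric tables, see the methods vignette.)
#'
#' @param exp,calc Equal-length numeric vectors, length >= 2.
#' @return PI in \[-1, 1\]; `NA` with a warning when all experimental values
#'   are equal (weights would all vanish under the experimental-weight
#'   convention and ordering is undefined).
#' @export
pearlman_pi <- function(exp, calc) {
  n <- length(exp)
  stopifnot(length(calc) == n, n >= 2)
  if (length(unique(exp)) == 1) {
    warning("all experimental values equal: PI undefined")
    return(NA_real_)
  }
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    w <- abs(calc[j] - calc[i])
    cij <- sign(calc[j] - calc[i]) * sign(exp[j] - exp[i])
    num <- num + w * cij
    den <- den + w
  }
  if (den == 0) {
    warning("all predicted values equal: PI undefined")
    return(NA_real_)
  }
  num / den
}

#' Full metric block for an affinity table
#'
#' Applies the protonation-averaging rule (when variant rows are present),
#' then computes MSE, MAE, RMSE, Kendall tau and Pearlman PI for every
#' computed column against the experimental reference.
#'
#' @param table An `fm_affinity_table`.
#' @param average_guest Guest to collapse by protonation averaging before
#'   scoring (`NULL` to skip); default "G5" when its variants are present.
#' @return data.frame with one row per metric (mse, mae, rmse, tau, pi) and
#'   one column per parameter set.
#' @export
affinity_metrics <- function(table, average_guest = "G5") {
  if (!is.null(average_guest) &&
      any(table$guest == average_guest & !is.na(table$variant)))
    table <- apply_protonation_average(table, average_guest)
  sets <- affinity_sets(table)
  out <- sapply(sets, function(s) {
    calc <- table[[paste0("dG_", s)]]
    em <- error_metrics(table$dG_exp, calc)
    c(mse = em$mse, mae = em$mae, rmse = em$rmse,
      tau = kendall_tau(table$dG_exp, calc),
      pi = pearlman_pi(table$dG_exp, calc))
  })
  as.data.frame(out)
}

#' Round half away from zero
#'
#' Published tables round half away from zero; base R's `round()` rounds half
#' to even.
#'
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reproduce the packaged affinity-table metric block
#'
#' Loads the packaged CB8-guest affinity fixture (or any same-shape table),
#' applies the G5 protonation-averaging rule and returns the metric block
#' both raw and rounded to one decimal (half away from zero), the precision
#' of the published table.
#'
#' @param table An `fm_affinity_table`; default [fixture_table1()].
#' @return List with `raw` and `rounded` metric blocks (data.frames with
#'   rows mse, mae, rmse, tau, pi).
#' @export
reproduce_table1_metrics <- function(table = fixture_table1()) {
  raw <- affinity_metrics(table)
  list(raw = raw, rounded = as.data.frame(lapply(raw, round_half_away),
                                          row.names = rownames(raw)))
}
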