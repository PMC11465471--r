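#' Pair-class coefficient table
#'
#' The interaction model assigns each unordered pair of topology classes
#' (solute, cation, anion) its own exponent coefficient gamma(a,b) and
#' internal dielectric eps_in(a,b). The solute-solute entry is pinned to the
#' canonical generalized Born values gamma = 4, eps_in = 1, so a system with
#' no ions reduces exactly to the canonical model.
#'
#' Entries can be given as named vectors using two-letter pair keys
#' (`ss`, `sc`, `sa`, `cc`, `ca`, `aa`; order within a key does not matter)
#' or as full symmetric 3x3 matrices with dimnames solute/cation/anion.
#'
#' @param gamma named vector or 3x3 matrix of gamma(a,b) >= 0.
#' @param eps_in named vector or 3x3 matrix of eps_in(a,b) in \[1, eps_out\].
#' @param eps_out solvent dielectric (default 78.5).
#' @return object of class `pair_class_table` with symmetric matrices
#'   `gamma` and `eps_in` plus scalar `eps_out`.
#' @examples
#' tab <- pair_class_table(gamma = c(sc = 4, sa = 0.2, cc = 4, ca = 0.2, aa = 4),
#'                         eps_in = c(sc = 54, sa = 8, cc = 54, ca = 8, aa = 8))
#' pair_class_lookup(tab, "solute", "solute")  # gamma 4, eps_in 1
#' @export
pair_class_table <- function(gamma = NULL, eps_in = NULL, eps_out = 78.5) {
  g <- .expand_pair_entries(gamma, default = 4)
  e <- .expand_pair_entries(eps_in, default = 1)
  # solute-solute is pinned: the canonical model applies within the solute
  g["solute", "solute"] <- 4
  e["solute", "solute"] <- 1
  tab <- structure(list(gamma = g, eps_in = e, eps_out = eps_out),
                   class = "pair_class_table")
  .check_pair_table(tab)
  tab
}

.expand_pair_entries <- function(x, default) {
  cls <- .topo_classes
  m <- matrix(default, 3, 3, dimnames = list(cls, cls))
  if (is.null(x)) return(m)
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(3, 3)))
    if (!is.null(dimnames(x))) x <- x[cls, cls]
    if (max(abs(x - t(x))) > 0) stop("pair-class matrix must be symmetric")
    m[, ] <- x
    return(m)
  }
  key_class <- c(s = "solute", c = "cation", a = "anion")
  for (key in names(x)) {
    parts <- strsplit(key, "")[[1]]
    if (length(parts) != 2 || !all(parts %in% names(key_class)))
      stop("bad pair key '", key, "' (use two of s/c/a, e.g. 'sc')")
    a <- key_class[parts[1]]; b <- key_class[parts[2]]
    m[a, b] <- x[[key]]
    m[b, a] <- x[[key]]
  }
  m
}

.check_pair_table <- function(tab) {
  if (any(!is.finite(tab$gamma)) || any(tab$gamma < 0))
    stop("gamma(a,b) must be finite and >= 0")
  if (any(!is.finite(tab$eps_in)) || any(tab$eps_in < 1))
    stop("eps_in(a,b) must be finite and >= 1")
  if (any(tab$eps_in > tab$eps_out))
    stop("eps_in(a,b) must not exceed eps_out (", tab$eps_out, ")")
  if (tab$gamma["solute", "solute"] != 4 || tab$eps_in["solute", "solute"] != 1)
    stop("the solute-solute entry is pinned to gamma = 4, eps_in = 1")
  invisible(tab)
}

#' Look up the coefficients of a class pair
#'
#' @param table a `pair_class_table`.
#' @param class_a,class_b topology class names; the result is symmetric in
#'   the two arguments.
#' @return named numeric vector `c(gamma, eps_in)`.
#' @export
pair_class_lookup <- function(table, class_a, class_b) {
  stopifnot(inherits(table, "pair_class_table"))
  .class_code(c(class_a, class_b))
  c(gamma = table$gamma[class_a, class_b],
    eps_in = table$eps_in[class_a, class_b])
}

#' Diagnose pair-table parameters against the recommended ranges
#'
#' Values outside the ranges explored when the model was parameterized
#' (gamma/4 in \[0, 2\], i.e. gamma in \[0, 8\]; eps_in in \[1, 78.5\]) draw
#' warnings but are accepted; eps_in below 1 or above eps_out is a hard
#' error (raised by the constructor and re-checked here).
#'
#' @param table a `pair_class_table`.
#' @return (invisibly) a character vector of warning messages, empty when
#'   all entries are inside the explored ranges. The warnings are also
#'   signalled via [warning()].
#' @export
validate_parameters <- function(table) {
  stopifnot(inherits(table, "pair_class_table"))
  .check_pair_table(table)
  msgs <- character(0)
  cls <- .topo_classes
  for (i in 1:3) for (j in i:3) {
    g <- table$gamma[i, j]
    if (g > 8) {
      msgs <- c(msgs, sprintf(
        "gamma(%s,%s) = %g is outside the explored range [0, 8]",
        cls[i], cls[j], g))
    }
  }
  for (m in msgs) warning(m, call. = FALSE)
  invisible(msgs)
}

#' @export
print.pair_class_table <- function(x, ...) {
  cat("pair_class_table (eps_out =", x$eps_out, ")\n")
  cat("gamma(a,b):\n"); print(x$gamma)
  cat("eps_in(a,b):\n"); print(x$eps_in)
  invisible(x)
}

#' Canonical generalized Born pair table
#'
#' gamma = 4 and eps_in = 1 for every class pair: all interactions use the
#' canonical Still form.
#' @param eps_out solvent dielectric.
#' @return a `pair_class_table`.
#' @export
canonical_pair_table <- function(eps_out = 78.5) {
  pair_class_table(gamma = c(ss = 4, sc = 4, sa = 4, cc = 4, ca = 4, aa = 4),
                   eps_in = c(ss = 1, sc = 1, sa = 1, cc = 1, ca = 1, aa = 1),
                   eps_out = eps_out)
}

#' Coulomb-in-water pair table
#'
#' eps_in = eps_out for every pair: the generalized Born bracket vanishes and
#' all interactions reduce to Coulomb's law screened by the solvent
#' dielectric (the primitive electrolyte model). Useful as a Debye-Hueckel
#' reference system.
#' @param eps_out solvent dielectric.
#' @return a `pair_class_table`.
#' @export
coulomb_pair_table <- function(eps_out = 78.5) {
  tab <- canonical_pair_table(eps_out)
  tab$eps_in[, ] <- eps_out
  tab$eps_in["solute", "solute"] <- 1  # pinned; solute-solute stays canonical
  tab
}

#' Convert concentration between mol/L and particles per cubic angstrom
#'
#' Uses the conversion factor 6.02e-4 (particles/A^3 per mol/L).
#'
#' @param c_mol_per_l concentration in mol/L (non-negative).
#' @return concentration in particles per cubic angstrom.
#' @examples
#' conc_to_per_A3(1.0)    # 6.02e-4
#' conc_to_per_A3(0.145)  # 8.729e-5
#' @export
conc_to_per_A3 <- function(c_mol_per_l) {
  if (any(c_mol_per_l < 0)) stop("concentration must be non-negative")
  c_mol_per_l * gbion_constants()$conc_factor
}

#' @rdname conc_to_per_A3
#' @param c_per_A3 concentration in particles per cubic angstrom.
#' @export
per_A3_to_conc <- function(c_per_A3) {
  if (any(c_per_A3 < 0)) stop("concentration must be non-negative")
  c_per_A3 / gbion_constants()$conc_factor
}
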