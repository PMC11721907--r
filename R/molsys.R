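#' Molecular formulas
#'
#' A molecular formula is a named integer vector of element counts, e.g.
#' protocatechuic acid is `c(C = 7, H = 6, O = 4)`.  Hill-notation strings
#' such as `"C7H6O4"` are accepted and parsed.
#'
#' @param x a named numeric vector of element counts, or a single
#'   Hill-notation string (`"C7H6O4"`, `"H2O"`).
#' @return an object of class `molecular_formula` (named integer vector).
#' @examples
#' molecular_formula("C7H6O4")
#' molecular_formula(c(H = 2))
#' @export
molecular_formula <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    counts <- parse_hill_formula(x)
  } else {
    if (is.null(names(x)) || any(names(x) == ""))
      stop("formula counts must be named by element symbol")
    counts <- as.integer(x)
    names(counts) <- names(x)
  }
  if (length(counts) == 0L) stop("formula must contain at least one element")
  if (any(counts < 1L)) stop("element counts must be >= 1")
  structure(counts, class = "molecular_formula")
}

parse_hill_formula <- function(s) {
  s <- trimws(s)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s))
    stop("cannot parse formula string: ", s)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  els <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(cnt, els, sum)
  counts <- as.integer(out)
  names(counts) <- names(out)
  counts
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula> ",
      paste0(names(x), unclass(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Basis-set orbital-counting rules
#'
#' Counting rules map an element symbol to its number of spatial orbitals
#' in a basis.  The shipped default is the minimal STO-3G set: H
#' contributes a single 1s orbital; C, N and O contribute 1s, 2s, 2px,
#' 2py, 2pz (five orbitals).  Other elements must be supplied explicitly.
#'
#' @param basis_name label for the rule set.
#' @param orbitals_per_element named integer vector, element -> spatial
#'   orbital count.
#' @return an object of class `basis_rules`.
#' @examples
#' sto3g_rules()
#' @export
basis_rules <- function(basis_name, orbitals_per_element) {
  if (length(orbitals_per_element) == 0L || is.null(names(orbitals_per_element)))
    stop("orbitals_per_element must be a non-empty named vector")
  counts <- as.integer(orbitals_per_element)
  if (any(counts < 1L)) stop("orbital counts must be >= 1")
  names(counts) <- names(orbitals_per_element)
  structure(list(basis_name = basis_name, orbitals_per_element = counts),
            class = "basis_rules")
}

#' @rdname basis_rules
#' @export
sto3g_rules <- function() {
  basis_rules("STO-3G", c(H = 1L, C = 5L, N = 5L, O = 5L))
}

#' Count spatial orbitals of a formula in a basis
#'
#' Sums, over the elements of the formula, the per-element spatial-orbital
#' count of the basis rules.  For protocatechuic acid (C7H6O4) in STO-3G
#' this gives 7*5 + 6*1 + 4*5 = 61 spatial orbitals.
#'
#' @param formula a [molecular_formula()] (or something coercible to one).
#' @param rules a [basis_rules()] object; default STO-3G.
#' @return integer number of spatial orbitals.
#' @examples
#' count_spatial_orbitals(molecular_formula("C7H6O4"))  # 61
#' @export
count_spatial_orbitals <- function(formula, rules = sto3g_rules()) {
  if (!inherits(formula, "molecular_formula")) formula <- molecular_formula(formula)
  stopifnot(inherits(rules, "basis_rules"))
  per <- rules$orbitals_per_element
  missing_el <- setdiff(names(formula), names(per))
  if (length(missing_el) > 0L)
    stop("element(s) not covered by basis rules '", rules$basis_name, "': ",
         paste(missing_el, collapse = ", "))
  sum(unclass(formula) * per[names(formula)])
}

#' Qubits needed for a spatial-orbital count
#'
#' One qubit per spin orbital; two spin orbitals per spatial orbital, so
#' the requirement is `2 * n_spatial_orbitals` (61 orbitals -> 122 qubits;
#' a 4-orbital active space -> 8 qubits).
#'
#' @param n_spatial_orbitals non-negative integer.
#' @return integer qubit count.
#' @export
qubit_requirement <- function(n_spatial_orbitals) {
  n <- as.integer(n_spatial_orbitals)
  if (any(is.na(n)) || any(n < 0L)) stop("n_spatial_orbitals must be >= 0")
  2L * n
}

#' Active-space specification
#'
#' An active space freezes `n_core_orbitals` doubly occupied core
#' orbitals, treats `n_active_orbitals` spatial orbitals (holding
#' `n_active_electrons` electrons) explicitly, and omits the remaining
#' external orbitals.  If `active_orbital_indices` is omitted, the default
#' selection centres the window on the Fermi level: the occupied orbitals
#' immediately below it plus the lowest virtuals, i.e. spatial orbitals
#' `n_core .. n_core + n_active - 1` in ascending-energy order.  This
#' HOMO/LUMO-centred default is a heuristic; supply explicit indices when
#' the chemistry calls for a different window.
#'
#' @param n_active_electrons positive integer.
#' @param n_active_orbitals positive integer.
#' @param n_core_orbitals non-negative integer (default 0).
#' @param active_orbital_indices optional 0-based spatial-orbital indices,
#'   length `n_active_orbitals`.
#' @return an object of class `active_space`.
#' @examples
#' active_space(4, 4, n_core_orbitals = 2)
#' @export
active_space <- function(n_active_electrons, n_active_orbitals,
                         n_core_orbitals = 0L,
                         active_orbital_indices = NULL) {
  n_e <- as.integer(n_active_electrons)
  n_o <- as.integer(n_active_orbitals)
  n_c <- as.integer(n_core_orbitals)
  stopifnot(n_e >= 1L, n_o >= 1L, n_c >= 0L)
  if (n_e > 2L * n_o)
    stop("n_active_electrons exceeds 2 * n_active_orbitals")
  if (is.null(active_orbital_indices))
    active_orbital_indices <- seq.int(n_c, n_c + n_o - 1L)
  idx <- as.integer(active_orbital_indices)
  if (length(idx) != n_o) stop("active_orbital_indices must have length n_active_orbitals")
  if (anyDuplicated(idx)) stop("active orbital indices must be distinct")
  if (any(idx < 0L)) stop("active orbital indices must be >= 0")
  if (n_c > 0L && any(idx < n_c))
    stop("active orbital indices overlap the core orbitals 0..", n_c - 1L)
  structure(list(n_active_electrons = n_e,
                 n_active_orbitals = n_o,
                 n_core_orbitals = n_c,
                 active_orbital_indices = idx),
            class = "active_space")
}

#' @export
print.active_space <- function(x, ...) {
  cat(sprintf("<active_space> (%de,%do), %d core, active MOs: %s\n",
              x$n_active_electrons, x$n_active_orbitals, x$n_core_orbitals,
              paste(x$active_orbital_indices, collapse = ",")))
  invisible(x)
}

#' Validate an active space against the full system
#'
#' Checks electron accounting (`n_total_electrons = 2*n_core +
#' n_active_electrons`), index ranges and core/active disjointness, and
#' returns the active space unchanged when everything balances.
#'
#' @param space an [active_space()].
#' @param n_total_orbitals total spatial orbitals of the system.
#' @param n_total_electrons total electrons of the system.
#' @return `space`, invisibly validated.
#' @export
validate_active_space <- function(space, n_total_orbitals, n_total_electrons) {
  stopifnot(inherits(space, "active_space"))
  n_orb <- as.integer(n_total_orbitals)
  n_el <- as.integer(n_total_electrons)
  if (n_orb < space$n_core_orbitals + space$n_active_orbitals)
    stop("system has ", n_orb, " orbitals; active space needs at least ",
         space$n_core_orbitals + space$n_active_orbitals)
  if (any(space$active_orbital_indices >= n_orb))
    stop("active orbital index out of range for a ", n_orb, "-orbital system")
  if (2L * space$n_core_orbitals + space$n_active_electrons != n_el)
    stop("electron accounting mismatch: 2*", space$n_core_orbitals, " core + ",
         space$n_active_electrons, " active != ", n_el, " total electrons")
  space
}

# small atomic-number table used for electron counting of geometries
.atomic_numbers <- c(H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L,
                     N = 7L, O = 8L, F = 9L, Ne = 10L, Na = 11L, Mg = 12L,
                     Al = 13L, Si = 14L, P = 15L, S = 16L, Cl = 17L, Ar = 18L)

#' Molecular geometry
#'
#' Ordered atoms with Cartesian coordinates in Angstrom; used only to feed
#' an external electronic-structure backend, never for integral evaluation
#' inside this package.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`.
#' @param charge integer total charge.
#' @param spin_multiplicity positive integer 2S+1; must match electron
#'   parity.
#' @return an object of class `molecular_geometry`.
#' @export
molecular_geometry <- function(atoms, charge = 0L, spin_multiplicity = 1L) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!all(atoms$element %in% names(.atomic_numbers)))
    stop("unknown element symbol(s): ",
         paste(setdiff(atoms$element, names(.atomic_numbers)), collapse = ", "))
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  mult <- as.integer(spin_multiplicity)
  if (mult < 1L) stop("spin multiplicity must be >= 1")
  n_el <- sum(.atomic_numbers[atoms$element]) - as.integer(charge)
  # n_unpaired = mult - 1 must share parity with the electron count
  if ((n_el - (mult - 1L)) %% 2L != 0L)
    stop("spin multiplicity ", mult, " inconsistent with ", n_el, " electrons")
  structure(list(atoms = atoms, charge = as.integer(charge),
                 spin_multiplicity = mult, n_electrons = n_el),
            class = "molecular_geometry")
}

#' Read a standard XYZ geometry file
#'
#' Standard XYZ: first line atom count, second line comment, then
#' `element x y z` records (Angstrom).
#'
#' @param path file path.
#' @inheritParams molecular_geometry
#' @return a [molecular_geometry()].
#' @export
read_xyz <- function(path, charge = 0L, spin_multiplicity = 1L) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("truncated XYZ file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("first XYZ line must be the atom count")
  if (length(lines) < 2L + n) stop("XYZ file declares ", n, " atoms but has fewer records")
  recs <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  if (any(lengths(recs) < 4L)) stop("malformed XYZ atom record")
  atoms <- data.frame(
    element = vapply(recs, `[[`, "", 1L),
    x = as.numeric(vapply(recs, `[[`, "", 2L)),
    y = as.numeric(vapply(recs, `[[`, "", 3L)),
    z = as.numeric(vapply(recs, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
  molecular_geometry(atoms, charge = charge, spin_multiplicity = spin_multiplicity)
}
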