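#' Parameterized circuit templates
#'
#' A `circuit_template` is an ordered gate list plus a declared number of
#' trainable parameters; it realizes the ansatz unitary `U(theta)`.
#' Every `parameter_slot` value in `0 .. n_parameters - 1` must be used
#' by at least one gate.
#'
#' @param n_qubits register size.
#' @param gates a data.frame of [gate()] rows.
#' @param n_parameters number of trainable parameters.
#' @return an object of class `circuit_template`.
#' @export
circuit_template <- function(n_qubits, gates, n_parameters) {
  n <- as.integer(n_qubits)
  np <- as.integer(n_parameters)
  stopifnot(n >= 1L, np >= 0L)
  .check_gates(gates, n)
  slots <- gates$slot[!is.na(gates$slot)]
  if (np > 0L) {
    used <- sort(unique(slots))
    if (!identical(used, 0:(np - 1L)))
      stop("parameter slots must be exactly {0..", np - 1L, "}, each used at least once")
  } else if (length(slots) > 0L) {
    stop("gates reference parameter slots but n_parameters = 0")
  }
  structure(list(n_qubits = n, gates = gates, n_parameters = np),
            class = "circuit_template")
}

#' @export
print.circuit_template <- function(x, ...) {
  cat(sprintf("<circuit_template> %d qubits, %d gates, %d parameters\n",
              x$n_qubits, nrow(x$gates), x$n_parameters))
  invisible(x)
}

#' Text diagram of a circuit template
#'
#' One line per gate, in application order; handy for docs and tests.
#'
#' @param template a [circuit_template()].
#' @return character vector of gate descriptions, invisibly (also printed).
#' @export
draw_circuit <- function(template) {
  g <- template$gates
  lines <- vapply(seq_len(nrow(g)), function(i) {
    if (g$kind[i] == "CNOT")
      sprintf("CNOT  q%d -> q%d", g$control[i], g$target[i])
    else if (g$kind[i] %in% c("RX", "RY", "RZ")) {
      if (!is.na(g$slot[i]))
        sprintf("%-4s  q%d  (%+.4g * theta[%d])", g$kind[i], g$target[i],
                g$scale[i], g$slot[i])
      else
        sprintf("%-4s  q%d  (%.6g)", g$kind[i], g$target[i], g$angle[i])
    } else sprintf("%-4s  q%d", g$kind[i], g$target[i])
  }, character(1))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Parameter and gate counts of a template
#'
#' @param template a [circuit_template()].
#' @return named integer vector `c(n_parameters =, n_gates =)`.
#' @export
counts <- function(template) {
  stopifnot(inherits(template, "circuit_template"))
  c(n_parameters = template$n_parameters, n_gates = nrow(template$gates))
}

# internal builders: rows collected in a list, one rbind at the end
.gl_new <- function() new.env(parent = emptyenv())
.gl_add <- function(env, g) {
  n <- length(env$rows <- c(env$rows, list(g)))
  invisible(n)
}
.gl_frame <- function(env) {
  if (is.null(env$rows)) return(gate("H", 0L)[0, ])
  do.call(rbind, env$rows)
}

#' Hardware-efficient ansatz circuits (versions v1-v5)
#'
#' Five fixed-layout hardware-efficient circuits built from Hadamards,
#' CNOT entanglers and RX/RY rotations, whose parameter and gate counts
#' satisfy, for register size N divisible by 4:
#'
#' | version | parameters  | gates  |
#' |---------|-------------|--------|
#' | v1      | N           | 5N/2   |
#' | v2      | N           | 5N/2   |
#' | v3      | 2(3N-2)     | 15N/2  |
#' | v4      | N           | 5N/2   |
#' | v5      | N           | 9N/4   |
#'
#' Layouts (the first N/2 qubits are the "occupied"/HOMO half, the second
#' half the virtual/LUMO half):
#'
#' * **v1** - Hadamards on the occupied half; one CNOT layer coupling
#'   qubit i to i + N/2 (occupied-virtual mixing); one CNOT layer pairing
#'   adjacent qubits within each half (spin mixing); then per occupied
#'   qubit an RX followed by an RY, each with its own parameter.
#' * **v2** - Hadamards on all qubits; the occupied-virtual CNOT layer;
#'   one parameterized rotation per qubit (RX on the first half, RY on
#'   the second).
#' * **v3** - Hadamards on all qubits and enlarged rotation layers:
#'   RX+RY on every qubit, the occupied-virtual CNOT layer, RX+RY on
#'   every qubit again, four ring CNOTs, and RX+RY on the interior
#'   qubits `1..N-2`; every rotation has its own parameter.
#' * **v4** - identical to v1 with the rotation order swapped (RY then
#'   RX), so its gate multiset equals v1's.
#' * **v5** - Hadamards on all qubits; CNOTs restricted to adjacent pairs
#'   within the occupied (HOMO) half; one parameterized RY per qubit.
#'
#' Hardware-efficient circuits start from `|0...0>`: the Hadamard layer
#' itself creates the occupation superposition.
#'
#' @param version one of `"v1" .. "v5"`.
#' @param n_qubits register size; must be even and >= 4, and divisible by
#'   4 for the within-half CNOT pairings (v1/v4/v5) to close.
#' @return a [circuit_template()].
#' @examples
#' counts(build_hardware_efficient("v1", 8))  # 8 parameters, 20 gates
#' @export
build_hardware_efficient <- function(version = c("v1", "v2", "v3", "v4", "v5"),
                                     n_qubits) {
  version <- match.arg(version)
  n <- as.integer(n_qubits)
  if (n < 4L || n %% 2L != 0L)
    stop("hardware-efficient ansatzes need an even n_qubits >= 4")
  if (version %in% c("v1", "v4", "v5") && n %% 4L != 0L)
    stop(version, " requires n_qubits divisible by 4 ",
         "(within-half CNOT pairing / gate count 9N/4 must be integral)")
  half <- n %/% 2L
  env <- .gl_new()
  slot <- 0L
  add_rot <- function(kind, q) {
    .gl_add(env, gate(kind, q, parameter_slot = slot))
    slot <<- slot + 1L
  }
  occ_virt_cnots <- function() {
    for (i in 0:(half - 1L)) .gl_add(env, gate("CNOT", i + half, control = i))
  }
  within_half_cnots <- function(offset) {
    for (j in seq.int(0L, half - 2L, by = 2L))
      .gl_add(env, gate("CNOT", offset + j + 1L, control = offset + j))
  }

  if (version %in% c("v1", "v4")) {
    for (q in 0:(half - 1L)) .gl_add(env, gate("H", q))
    occ_virt_cnots()
    within_half_cnots(0L)
    within_half_cnots(half)
    ord <- if (version == "v1") c("RX", "RY") else c("RY", "RX")
    for (q in 0:(half - 1L)) { add_rot(ord[1], q); add_rot(ord[2], q) }
  } else if (version == "v2") {
    for (q in 0:(n - 1L)) .gl_add(env, gate("H", q))
    occ_virt_cnots()
    for (q in 0:(half - 1L)) add_rot("RX", q)
    for (q in half:(n - 1L)) add_rot("RY", q)
  } else if (version == "v3") {
    for (q in 0:(n - 1L)) .gl_add(env, gate("H", q))
    for (q in 0:(n - 1L)) add_rot("RX", q)
    for (q in 0:(n - 1L)) add_rot("RY", q)
    occ_virt_cnots()
    for (q in 0:(n - 1L)) add_rot("RX", q)
    for (q in 0:(n - 1L)) add_rot("RY", q)
    ring <- list(c(0L, 1L), c(half, (half + 1L) %% n),
                 c(n - 1L, 0L), c(half - 1L, half))
    for (p in ring) .gl_add(env, gate("CNOT", p[2], control = p[1]))
    for (q in 1:(n - 2L)) add_rot("RX", q)
    for (q in 1:(n - 2L)) add_rot("RY", q)
  } else {  # v5
    for (q in 0:(n - 1L)) .gl_add(env, gate("H", q))
    within_half_cnots(0L)
    for (q in 0:(n - 1L)) add_rot("RY", q)
  }
  circuit_template(n, .gl_frame(env), slot)
}

# --- UCCSD ----------------------------------------------------------------

#' Spin-conserving excitations from the Hartree-Fock reference
#'
#' Enumerates the single and double excitations that define the UCCSD
#' parameter set: occupied spin orbitals are `0..n_a-1` (alpha block) and
#' `n_o..n_o+n_b-1` (beta block) for `n_a = ceiling(n_e/2)`,
#' `n_b = n_e - n_a`.  Singles conserve spin individually; doubles
#' conserve total Sz.  Ordering is singles before doubles, each block
#' lexicographic on its (occupied, virtual) index tuple.
#'
#' @param n_electrons number of electrons.
#' @param n_spin_orbitals number of spin orbitals (even).
#' @return list with elements `singles` (list of `c(i, a)`) and
#'   `doubles` (list of `c(i, j, a, b)` with `i < j`, `a < b`).
#' @export
uccsd_excitations <- function(n_electrons, n_spin_orbitals) {
  ne <- as.integer(n_electrons)
  nso <- as.integer(n_spin_orbitals)
  stopifnot(ne >= 1L, nso %% 2L == 0L, ne <= nso)
  n_o <- nso %/% 2L
  n_a <- (ne + 1L) %/% 2L
  n_b <- ne - n_a
  occ_a <- if (n_a > 0L) 0:(n_a - 1L) else integer(0)
  occ_b <- if (n_b > 0L) n_o + 0:(n_b - 1L) else integer(0)
  virt_a <- setdiff(0:(n_o - 1L), occ_a)
  virt_b <- setdiff(n_o + 0:(n_o - 1L), occ_b)
  occ <- c(occ_a, occ_b)
  is_alpha <- function(s) s < n_o

  singles <- list()
  for (i in sort(occ)) {
    virt <- if (is_alpha(i)) virt_a else virt_b
    for (a in virt) singles[[length(singles) + 1L]] <- c(i, a)
  }
  if (length(c(virt_a, virt_b)) == 0L)
    stop("no virtual spin orbitals: no excitations exist")

  doubles <- list()
  occ_pairs <- if (length(occ) >= 2L) utils::combn(sort(occ), 2L, simplify = FALSE) else list()
  virt_pairs <- if (length(c(virt_a, virt_b)) >= 2L)
    utils::combn(sort(c(virt_a, virt_b)), 2L, simplify = FALSE) else list()
  for (ij in occ_pairs) for (ab in virt_pairs) {
    if (sum(is_alpha(ij)) == sum(is_alpha(ab)))
      doubles[[length(doubles) + 1L]] <- c(ij[1], ij[2], ab[1], ab[2])
  }
  list(singles = singles, doubles = doubles)
}

# decode one Pauli term (x, z masks) into sorted qubits + letters
.pauli_factors <- function(x, z, n) {
  qs <- integer(0); ls <- character(0)
  for (q in 0:(n - 1L)) {
    b <- qubit_bit(q, n)
    hx <- bitwAnd(x, b) != 0L; hz <- bitwAnd(z, b) != 0L
    if (hx || hz) {
      qs <- c(qs, q)
      ls <- c(ls, if (hx && hz) "Y" else if (hx) "X" else "Z")
    }
  }
  list(qubits = qs, letters = ls)
}

# gates realizing exp(i * theta * gamma * P) for one Pauli string:
# basis change (H for X, RX(pi/2) for Y), CNOT parity ladder, RZ whose
# angle is -2*gamma*theta (parameter slot + chain-rule scale), undo.
.pauli_evolution_gates <- function(env, x, z, gamma, slot, n) {
  f <- .pauli_factors(x, z, n)
  if (length(f$qubits) == 0L) return(invisible())
  for (k in seq_along(f$qubits)) {
    if (f$letters[k] == "X") .gl_add(env, gate("H", f$qubits[k]))
    if (f$letters[k] == "Y") .gl_add(env, gate("RX", f$qubits[k], angle = pi / 2))
  }
  qs <- f$qubits
  if (length(qs) > 1L)
    for (k in 1:(length(qs) - 1L))
      .gl_add(env, gate("CNOT", qs[k + 1L], control = qs[k]))
  .gl_add(env, gate("RZ", qs[length(qs)], parameter_slot = slot,
                    parameter_scale = -2 * gamma))
  if (length(qs) > 1L)
    for (k in (length(qs) - 1L):1L)
      .gl_add(env, gate("CNOT", qs[k + 1L], control = qs[k]))
  for (k in seq_along(f$qubits)) {
    if (f$letters[k] == "X") .gl_add(env, gate("H", f$qubits[k]))
    if (f$letters[k] == "Y") .gl_add(env, gate("RX", f$qubits[k], angle = -pi / 2))
  }
  invisible()
}

#' Trotterized UCCSD ansatz circuit
#'
#' Builds the unitary coupled-cluster singles-and-doubles circuit: X
#' gates prepare the Hartree-Fock occupation from `|0...0>`, followed by
#' a single first-order Trotter step of `exp(T - T^dag)` with one
#' parameter per spin-conserving excitation (see [uccsd_excitations()]).
#' Each excitation generator `theta_k (t_k - t_k^dag)` is Jordan-Wigner
#' mapped to a sum of mutually commuting Pauli strings with imaginary
#' coefficients and realized exactly by the standard
#' basis-change / CNOT-ladder / RZ construction, so each factor conserves
#' particle number exactly and `theta = 0` prepares exactly the
#' Hartree-Fock state.
#'
#' @param n_electrons number of electrons.
#' @param n_spin_orbitals number of spin orbitals (= qubits).
#' @return a [circuit_template()].
#' @export
build_uccsd <- function(n_electrons, n_spin_orbitals) {
  ne <- as.integer(n_electrons)
  nso <- as.integer(n_spin_orbitals)
  exc <- uccsd_excitations(ne, nso)
  n_o <- nso %/% 2L
  n_a <- (ne + 1L) %/% 2L
  n_b <- ne - n_a
  env <- .gl_new()
  occ <- c(if (n_a > 0L) 0:(n_a - 1L), if (n_b > 0L) n_o + 0:(n_b - 1L))
  for (q in occ) .gl_add(env, gate("X", q))

  add_generator <- function(ops_t, slot) {
    # G = t - t^dag; ops rows apply left to right
    t_rev <- ops_t[rev(seq_len(nrow(ops_t))), , drop = FALSE]
    t_rev[, 2] <- 1L - t_rev[, 2]
    gen <- fermion_op(list(list(coeff = 1, ops = ops_t),
                           list(coeff = -1, ops = t_rev)), nso)
    col <- .jw_collect(gen, nso)
    if (length(col$coeff) && max(abs(Re(col$coeff))) > 1e-12)
      stop("excitation generator mapped to non-imaginary Pauli terms")
    for (k in seq_along(col$coeff))
      .pauli_evolution_gates(env, col$x[k], col$z[k], Im(col$coeff[k]), slot, nso)
  }

  slot <- 0L
  om <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE,
                             dimnames = list(NULL, c("index", "dagger")))
  for (s in exc$singles) {
    add_generator(om(s[2], 1L, s[1], 0L), slot)   # a^dag_a a_i
    slot <- slot + 1L
  }
  for (d in exc$doubles) {
    # a^dag_a a^dag_b a_j a_i for (i<j) -> (a<b)
    add_generator(om(d[3], 1L, d[4], 1L, d[2], 0L, d[1], 0L), slot)
    slot <- slot + 1L
  }
  circuit_template(nso, .gl_frame(env), slot)
}

#' Bind parameters and prepare the ansatz state
#'
#' Substitutes the parameter vector into the template's parameter slots
#' (applied angle = `parameter_scale * theta[slot]`) and applies the gate
#' list in order to the initial state, returning `U(theta)|psi>`.
#'
#' @param template a [circuit_template()].
#' @param theta numeric parameter vector of length `n_parameters`.
#' @param initial a [statevector()]; default `|0...0>`.
#' @return the prepared [statevector()].
#' @export
bind_circuit <- function(template, theta,
                         initial = init_state(template$n_qubits)) {
  stopifnot(inherits(template, "circuit_template"),
            inherits(initial, "statevector"))
  if (initial$n_qubits != template$n_qubits)
    stop("initial state qubit count does not match the template")
  theta <- as.numeric(theta)
  if (length(theta) != template$n_parameters)
    stop("parameter vector has length ", length(theta),
         " but the template declares ", template$n_parameters)
  if (any(!is.finite(theta))) stop("parameters must be finite")
  g <- template$gates
  bound <- !is.na(g$slot)
  g$angle[bound] <- g$scale[bound] * theta[g$slot[bound] + 1L]
  .run_circuit(initial, g)
}
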