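#' Statevectors
#'
#' A `statevector` holds the `2^n` complex amplitudes of an `n`-qubit
#' register.  Index convention (asserted by a dedicated test, since this
#' is the classic source of silent cross-framework bugs): **qubit 0 is the
#' most significant bit** of the amplitude index, so basis state
#' `|b_0 b_1 ... b_{n-1}>` sits at index `sum b_q * 2^(n-1-q)`.
#' All operations are pure: they return new states and never mutate.
#'
#' @param amplitudes complex vector of length `2^n`.
#' @param n_qubits number of qubits.
#' @param normalize_check require unit norm within 1e-10 (default TRUE).
#' @return an object of class `statevector`.
#' @export
statevector <- function(amplitudes, n_qubits, normalize_check = TRUE) {
  n <- as.integer(n_qubits)
  amps <- as.complex(amplitudes)
  if (length(amps) != bitwShiftL(1L, n))
    stop("amplitude vector length must be 2^n_qubits")
  if (normalize_check) {
    nrm <- sum(Mod(amps)^2)
    if (abs(nrm - 1) > 1e-10)
      stop("statevector is not normalized (|psi|^2 = ", format(nrm), ")")
  }
  structure(list(n_qubits = n, amplitudes = amps), class = "statevector")
}

#' @export
print.statevector <- function(x, ...) {
  cat(sprintf("<statevector> %d qubits (%d amplitudes)\n",
              x$n_qubits, length(x$amplitudes)))
  invisible(x)
}

#' Initialize a computational basis state
#'
#' With no occupation bits, returns `|0...0>`; with a bit list (one bit
#' per qubit, qubit 0 first), the corresponding basis state.
#'
#' @param n_qubits number of qubits (>= 1).
#' @param occupation_bits optional 0/1 vector of length `n_qubits`.
#' @param cap capacity guard on `n_qubits` (default 20).
#' @return a [statevector()].
#' @examples
#' init_state(2, c(1, 0))  # amplitude 1 at index 2
#' @export
init_state <- function(n_qubits, occupation_bits = NULL, cap = 20L) {
  n <- as.integer(n_qubits)
  if (n < 1L) stop("n_qubits must be >= 1")
  if (n > cap) stop("n_qubits = ", n, " exceeds the configured cap of ", cap)
  amps <- complex(bitwShiftL(1L, n))
  if (is.null(occupation_bits)) {
    amps[1] <- 1 + 0i
  } else {
    bits <- as.integer(occupation_bits)
    if (length(bits) != n) stop("occupation_bits must have length n_qubits")
    if (any(!bits %in% c(0L, 1L))) stop("occupation bits must be 0 or 1")
    idx <- sum(bits * 2^(n - 1 - (0:(n - 1L))))
    amps[idx + 1L] <- 1 + 0i
  }
  statevector(amps, n)
}

.gate_kinds <- c(H = 0L, X = 1L, RX = 2L, RY = 3L, RZ = 4L, CNOT = 5L)

#' Quantum gates
#'
#' Supported kinds: `H`, `X`, `RX`, `RY`, `RZ` (single qubit; rotations
#' carry an angle in radians) and `CNOT` (control + target).  A rotation
#' may bind its angle to a trainable circuit parameter via
#' `parameter_slot` (0-based) with chain-rule factor `parameter_scale`,
#' so the applied angle is `parameter_scale * theta[slot]`.
#'
#' @param kind gate name.
#' @param target target qubit (0-based).
#' @param control control qubit for CNOT.
#' @param angle rotation angle in radians (rotation kinds).
#' @param parameter_slot optional 0-based trainable-parameter index.
#' @param parameter_scale multiplier applied to the bound parameter.
#' @return a one-row data.frame gate record.
#' @export
gate <- function(kind, target, control = NA_integer_, angle = 0,
                 parameter_slot = NA_integer_, parameter_scale = 1) {
  if (!kind %in% names(.gate_kinds)) stop("unknown gate kind: ", kind)
  if (!is.finite(angle)) stop("gate angle must be finite")
  if (kind == "CNOT" && (is.na(control) || control == target))
    stop("CNOT needs a control distinct from its target")
  if (!is.na(parameter_slot) && !kind %in% c("RX", "RY", "RZ"))
    stop("only rotation gates can carry a trainable parameter")
  data.frame(kind = kind, target = as.integer(target),
             control = as.integer(control), angle = as.numeric(angle),
             slot = as.integer(parameter_slot),
             scale = as.numeric(parameter_scale),
             stringsAsFactors = FALSE)
}

.check_gates <- function(gates, n_qubits) {
  if (nrow(gates) == 0L) return(invisible(gates))
  if (any(gates$target < 0L | gates$target >= n_qubits))
    stop("gate target out of range for ", n_qubits, " qubits")
  is_cnot <- gates$kind == "CNOT"
  if (any(is_cnot & (is.na(gates$control) | gates$control < 0L |
                     gates$control >= n_qubits)))
    stop("CNOT control out of range for ", n_qubits, " qubits")
  if (any(is_cnot & gates$control == gates$target))
    stop("CNOT control equals target")
  invisible(gates)
}

# run the C++ kernel on a resolved gate table (angles already numeric)
.run_circuit <- function(state, gates) {
  if (nrow(gates) == 0L) return(state)
  out <- cpp_apply_circuit(state$amplitudes,
                           .gate_kinds[gates$kind],
                           gates$target,
                           ifelse(is.na(gates$control), -1L, gates$control),
                           gates$angle,
                           state$n_qubits)
  statevector(out, state$n_qubits, normalize_check = FALSE)
}

#' Apply a single gate
#'
#' Returns the new state `U |psi>` for the standard unitary of the gate
#' kind; the input state is unchanged.
#'
#' @param state a [statevector()].
#' @param g a [gate()] record.
#' @return a new [statevector()].
#' @export
apply_gate <- function(state, g) {
  stopifnot(inherits(state, "statevector"))
  .check_gates(g, state$n_qubits)
  .run_circuit(state, g)
}

#' Expectation value of a qubit Hamiltonian
#'
#' Computes `sum_t coeff_t <psi|P_t|psi>` (Hartree).  The result of a
#' Hermitian operator is real; an imaginary residue above 1e-9 raises an
#' error, otherwise it is discarded.
#'
#' @param state a [statevector()].
#' @param h a [qubit_op()] on the same number of qubits.
#' @return real expectation value.
#' @export
expectation <- function(state, h) {
  stopifnot(inherits(state, "statevector"), inherits(h, "qubit_op"))
  if (state$n_qubits != h$n_qubits)
    stop("qubit-count mismatch: state has ", state$n_qubits,
         ", Hamiltonian has ", h$n_qubits)
  v <- cpp_pauli_expectation(state$amplitudes, h$terms$x, h$terms$z,
                             h$terms$coeff, state$n_qubits)
  if (abs(Im(v)) > 1e-9)
    stop("expectation has non-negligible imaginary part: ", format(Im(v)))
  Re(v)
}
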