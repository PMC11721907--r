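# Bit-twiddling helpers shared by the Jordan-Wigner map, the dense-matrix
# builder and the determinant CI code.  Masks address spin orbitals /
# qubits; qubit q sits at bit position (n - 1 - q) of an amplitude index,
# while an orbital/determinant mask uses bit s for spin orbital s.

.vqe_env <- new.env(parent = emptyenv())

.popcount_table <- function() {
  tab <- .vqe_env$pop16
  if (is.null(tab)) {
    v <- 0:65535
    tab <- integer(65536L)
    for (b in 0:15) tab <- tab + bitwAnd(bitwShiftR(v, b), 1L)
    .vqe_env$pop16 <- tab
  }
  tab
}

# vectorized popcount for non-negative integers < 2^31
popcount <- function(v) {
  tab <- .popcount_table()
  lo <- bitwAnd(v, 65535L)
  hi <- bitwShiftR(v, 16L)
  tab[lo + 1L] + tab[hi + 1L]
}

# bit mask of qubit q (0-based) in the amplitude-index convention
qubit_bit <- function(q, n_qubits) bitwShiftL(1L, n_qubits - 1L - q)

# mask with amplitude-index bits set for qubits in `qs`
qubit_mask <- function(qs, n_qubits) {
  m <- 0L
  for (q in qs) m <- bitwOr(m, qubit_bit(q, n_qubits))
  m
}
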