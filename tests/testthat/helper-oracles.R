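# Independent oracles used across the suite.  These deliberately avoid the
# package's mask-based Pauli algebra and C++ kernels: matrices are built by
# Kronecker products and fermionic operators by direct ladder-operator
# action on occupation bitstrings, so agreement is a genuine cross-check.

# dense matrix of one Pauli-string label ("X0 Z2", "I", ...) on n qubits;
# qubit 0 is the most significant index bit, i.e. the leftmost Kronecker
# factor
oracle_pauli_matrix <- function(label, n) {
  one <- list(
    I = diag(2),
    X = matrix(c(0, 1, 1, 0), 2, 2),
    Y = matrix(c(0, 1i, -1i, 0), 2, 2),  # column-major: Y = [[0,-i],[i,0]]
    Z = diag(c(1, -1)))
  facs <- rep("I", n)
  label <- trimws(label)
  if (label != "I" && label != "") {
    for (tk in strsplit(label, "\\s+")[[1]]) {
      q <- as.integer(substring(tk, 2))
      facs[q + 1] <- substr(tk, 1, 1)
    }
  }
  m <- one[[facs[1]]]
  if (n > 1) for (q in 2:n) m <- kronecker(m, one[[facs[q]]])
  m
}

# dense matrix of a qubit_op via the Kronecker oracle
oracle_qubit_matrix <- function(h) {
  n <- h$n_qubits
  labs <- pauli_labels(h)
  m <- matrix(0 + 0i, 2^n, 2^n)
  for (i in seq_along(labs))
    m <- m + h$terms$coeff[i] * oracle_pauli_matrix(labs[i], n)
  m
}

# occupation of spin orbital s in amplitude index b (qubit s at bit n-1-s)
oracle_occ_bit <- function(b, s, n) bitwAnd(bitwShiftR(b, n - 1L - s), 1L)

# dense occupation-number-basis matrix of a fermion_op: ladder operators
# applied right-to-left to each basis column, with the fermionic sign
# (-1)^(number of occupied spin orbitals below the acted index)
oracle_fermion_matrix <- function(op) {
  n <- op$n_spin_orbitals
  dim <- 2^n
  m <- matrix(0 + 0i, dim, dim)
  for (b in 0:(dim - 1L)) {
    for (term in op$terms) {
      coeff <- term$coeff
      cur <- b
      ok <- TRUE
      if (!is.null(term$ops) && nrow(term$ops) > 0L) {
        for (r in rev(seq_len(nrow(term$ops)))) {   # rightmost acts first
          s <- term$ops[r, 1]; dag <- term$ops[r, 2] == 1L
          occ <- oracle_occ_bit(cur, s, n)
          if ((dag && occ == 1L) || (!dag && occ == 0L)) { ok <- FALSE; break }
          below <- if (s > 0L)
            sum(vapply(0:(s - 1L), function(t) oracle_occ_bit(cur, t, n), integer(1)))
          else 0L
          coeff <- coeff * (-1)^below
          cur <- bitwXor(cur, bitwShiftL(1L, n - 1L - s))
        }
      }
      if (ok) m[cur + 1L, b + 1L] <- m[cur + 1L, b + 1L] + coeff
    }
  }
  m
}

# a small deterministic Hermitian qubit_op for simulator tests
random_pauli_op <- function(n_qubits, n_terms, seed) {
  set.seed(seed)
  labs <- vapply(seq_len(n_terms), function(i) {
    k <- sample(1:min(3, n_qubits), 1)
    qs <- sort(sample(0:(n_qubits - 1L), k))
    paste(paste0(sample(c("X", "Y", "Z"), k, replace = TRUE), qs), collapse = " ")
  }, character(1))
  pauli_sum(c("I", labs), c(stats::runif(1, -1, 1), stats::runif(n_terms, -1, 1)),
            n_qubits)
}

# a random normalized statevector
random_state <- function(n_qubits, seed) {
  set.seed(seed)
  a <- complex(real = stats::rnorm(2^n_qubits), imaginary = stats::rnorm(2^n_qubits))
  statevector(a / sqrt(sum(Mod(a)^2)), n_qubits)
}

expect_close <- function(x, y, tol = 1e-9) expect_lt(max(abs(x - y)), tol)
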