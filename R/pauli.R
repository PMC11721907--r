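#' Qubit Hamiltonians (weighted Pauli-string sums)
#'
#' A `qubit_op` is a real-weighted sum of Pauli strings on `n_qubits`
#' qubits.  Internally each string is stored as a pair of bit masks
#' `(x, z)` meaning `i^{|x & z|} X^x Z^z` (qubit q at bit `n - 1 - q` of a
#' mask, matching the amplitude-index convention); `x & z` marks Y
#' factors, `x & !z` X factors, `z & !x` Z factors.  Real coefficients
#' make the operator Hermitian by construction.
#'
#' @param n_qubits number of qubits.
#' @param x,z integer mask vectors, one entry per term.
#' @param coeff real coefficients (Hartree).
#' @return an object of class `qubit_op`.
#' @export
qubit_op <- function(n_qubits, x, z, coeff) {
  n <- as.integer(n_qubits)
  stopifnot(n >= 1L, n <= 30L,
            length(x) == length(z), length(x) == length(coeff))
  if (!all(is.finite(coeff))) stop("coefficients must be finite")
  if (!is.numeric(coeff) || is.complex(coeff))
    stop("coefficients must be real (Hermitian operator)")
  lim <- bitwShiftL(1L, n)
  if (length(x) > 0L && (any(x < 0L) || any(x >= lim) || any(z < 0L) || any(z >= lim)))
    stop("Pauli factor index out of range for ", n, " qubits")
  structure(list(n_qubits = n,
                 terms = data.frame(x = as.integer(x), z = as.integer(z),
                                    coeff = as.numeric(coeff))),
            class = "qubit_op")
}

#' Build a qubit operator from Pauli-string labels
#'
#' Convenience constructor from human-readable strings like
#' `"Z0"`, `"X0 X1"`, `"Y2 Z3"`; `"I"` (or `""`) is the identity.
#'
#' @param labels character vector of Pauli strings.
#' @param coeff real coefficients, same length.
#' @param n_qubits number of qubits.
#' @return a [qubit_op()].
#' @examples
#' pauli_sum(c("I", "Z0 Z1"), c(2, 0.5), n_qubits = 2)
#' @export
pauli_sum <- function(labels, coeff, n_qubits) {
  n <- as.integer(n_qubits)
  xs <- integer(length(labels)); zs <- integer(length(labels))
  for (i in seq_along(labels)) {
    lab <- trimws(labels[i])
    if (lab == "" || lab == "I") next
    toks <- strsplit(lab, "\\s+")[[1]]
    for (tk in toks) {
      if (!grepl("^[XYZ][0-9]+$", tk)) stop("bad Pauli factor: ", tk)
      p <- substr(tk, 1, 1)
      q <- as.integer(substring(tk, 2))
      if (q >= n) stop("qubit index ", q, " out of range")
      b <- qubit_bit(q, n)
      if (bitwAnd(xs[i], b) || bitwAnd(zs[i], b))
        stop("duplicate qubit in Pauli string: ", lab)
      if (p %in% c("X", "Y")) xs[i] <- bitwOr(xs[i], b)
      if (p %in% c("Z", "Y")) zs[i] <- bitwOr(zs[i], b)
    }
  }
  qubit_op(n, xs, zs, coeff)
}

#' Pauli-string labels of a qubit operator
#'
#' @param h a [qubit_op()].
#' @return character vector, one label per term (identity = `"I"`).
#' @export
pauli_labels <- function(h) {
  stopifnot(inherits(h, "qubit_op"))
  n <- h$n_qubits
  vapply(seq_len(nrow(h$terms)), function(i) {
    x <- h$terms$x[i]; z <- h$terms$z[i]
    parts <- character(0)
    for (q in 0:(n - 1L)) {
      b <- qubit_bit(q, n)
      hx <- bitwAnd(x, b) != 0L; hz <- bitwAnd(z, b) != 0L
      if (hx && hz) parts <- c(parts, paste0("Y", q))
      else if (hx) parts <- c(parts, paste0("X", q))
      else if (hz) parts <- c(parts, paste0("Z", q))
    }
    if (length(parts) == 0L) "I" else paste(parts, collapse = " ")
  }, character(1))
}

#' @export
print.qubit_op <- function(x, n_show = 8L, ...) {
  cat(sprintf("<qubit_op> %d terms on %d qubits\n", nrow(x$terms), x$n_qubits))
  labs <- pauli_labels(x)
  k <- min(n_show, length(labs))
  for (i in seq_len(k))
    cat(sprintf("  %+12.8f * %s\n", x$terms$coeff[i], labs[i]))
  if (length(labs) > k) cat("  ...\n")
  invisible(x)
}

#' Dense Hermitian matrix of a qubit operator
#'
#' Builds the `2^n x 2^n` complex matrix explicitly.  Memory grows as
#' `4^n`; guarded by `dense_cap`.
#'
#' @param h a [qubit_op()].
#' @param dense_cap largest qubit count accepted (default 16).
#' @return a complex Hermitian matrix.
#' @export
qubit_matrix <- function(h, dense_cap = 16L) {
  stopifnot(inherits(h, "qubit_op"))
  n <- h$n_qubits
  if (n > dense_cap)
    stop("dense matrix over the ", dense_cap,
         "-qubit cap; raise dense_cap or use an iterative method")
  dim <- bitwShiftL(1L, n)
  m <- matrix(0 + 0i, dim, dim)
  cols <- 0:(dim - 1L)
  for (i in seq_len(nrow(h$terms))) {
    x <- h$terms$x[i]; z <- h$terms$z[i]; c0 <- h$terms$coeff[i]
    yph <- (1i)^(popcount(bitwAnd(x, z)) %% 4L)
    rows <- bitwXor(cols, x)
    sgn <- 1 - 2 * (popcount(bitwAnd(cols, z)) %% 2L)
    m[cbind(rows + 1L, cols + 1L)] <- m[cbind(rows + 1L, cols + 1L)] +
      c0 * yph * sgn
  }
  m
}

#' Smallest eigenvalues of a qubit Hamiltonian
#'
#' Exact dense diagonalization; returns the `k` smallest eigenvalues in
#' ascending order (Hartree).  This is the "reference by diagonalization"
#' path used to benchmark variational results.
#'
#' @param h a [qubit_op()].
#' @param k number of eigenvalues (default 1).
#' @param dense_cap passed to [qubit_matrix()].
#' @return numeric vector of length `k`, ascending.
#' @export
exact_spectrum <- function(h, k = 1L, dense_cap = 16L) {
  m <- qubit_matrix(h, dense_cap = dense_cap)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  sort(ev)[seq_len(min(k, length(ev)))]
}

#' Ground energy within a particle-number (and spin) sector
#'
#' A number-conserving qubit Hamiltonian is block diagonal over
#' computational basis states of fixed occupation count; this restricts
#' the dense matrix to the basis states with `n_particles` occupied
#' qubits (optionally also fixing the number occupied in the alpha block,
#' qubits `0 .. n/2 - 1`) and returns the block's lowest eigenvalue.
#' Used to compare against determinant CI, which works at fixed electron
#' number and Sz.
#'
#' @param h a [qubit_op()].
#' @param n_particles occupation count of the sector.
#' @param n_alpha optional count of occupied qubits in the first half of
#'   the register (the alpha spin block).
#' @param dense_cap passed to [qubit_matrix()].
#' @return lowest eigenvalue of the sector block (Hartree).
#' @export
exact_ground_in_sector <- function(h, n_particles, n_alpha = NULL,
                                   dense_cap = 16L) {
  stopifnot(inherits(h, "qubit_op"))
  n <- h$n_qubits
  idx <- 0:(bitwShiftL(1L, n) - 1L)
  keep <- popcount(idx) == n_particles
  if (!is.null(n_alpha)) {
    amask <- qubit_mask(0:(n %/% 2L - 1L), n)
    keep <- keep & (popcount(bitwAnd(idx, amask)) == n_alpha)
  }
  if (!any(keep)) stop("empty sector")
  m <- qubit_matrix(h, dense_cap = dense_cap)
  sub <- m[keep, keep, drop = FALSE]
  min(eigen(sub, symmetric = TRUE, only.values = TRUE)$values)
}
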