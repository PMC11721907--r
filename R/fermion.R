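#' Fermionic operators in second quantization
#'
#' A `fermion_op` is a sum of products of creation/annihilation operators
#' on spin orbitals, plus an optional scalar.  Each term is a list with
#' `coeff` (real) and `ops`, an integer matrix with one row per ladder
#' operator and columns `index` (0-based spin orbital) and `dagger`
#' (1 = creation, 0 = annihilation); rows apply left-to-right as written,
#' i.e. `ops[1, ]` is the leftmost operator.
#'
#' Spin-orbital convention (fixed package-wide, "blocked" layout): for an
#' active space of `n_o` spatial orbitals in ascending energy order, spin
#' orbitals `0 .. n_o-1` are the alpha orbitals and `n_o .. 2*n_o-1` their
#' beta partners.  Qubit q of the mapped Hamiltonian is spin orbital q.
#'
#' @param terms list of `list(coeff =, ops =)` entries; `ops = NULL` (or a
#'   0-row matrix) denotes the scalar identity term.
#' @param n_spin_orbitals number of spin orbitals the operator acts on.
#' @return an object of class `fermion_op`.
#' @export
fermion_op <- function(terms, n_spin_orbitals) {
  n <- as.integer(n_spin_orbitals)
  stopifnot(n >= 1L)
  for (t in terms) {
    if (!is.numeric(t$coeff) || !is.finite(t$coeff))
      stop("term coefficients must be finite numbers")
    if (!is.null(t$ops) && nrow(t$ops) > 0L) {
      if (any(t$ops[, 1] < 0L) || any(t$ops[, 1] >= n))
        stop("spin-orbital index out of range")
      key <- paste(t$ops[, 1], t$ops[, 2])
      if (anyDuplicated(key))
        stop("repeated identical ladder operator in a term (vanishing term)")
    }
  }
  structure(list(terms = terms, n_spin_orbitals = n), class = "fermion_op")
}

#' @export
print.fermion_op <- function(x, ...) {
  cat(sprintf("<fermion_op> %d terms on %d spin orbitals\n",
              length(x$terms), x$n_spin_orbitals))
  invisible(x)
}

# spin-orbital index of spatial-orbital position p (0-based within the
# active list) and spin ("a" or "b"), blocked layout
spin_orbital <- function(p, spin, n_spatial) {
  p + ifelse(spin == "b", n_spatial, 0L)
}

#' Active-space second-quantized Hamiltonian with frozen-core folding
#'
#' Builds `H = E_core' + sum h'_pq a^dag_p a_q + 1/2 sum (pq|rs)
#' a^dag_p a^dag_r a_s a_q` over the active spin orbitals.  The
#' `n_core_orbitals` lowest spatial orbitals are frozen doubly occupied
#' and folded into the constant and the effective one-body term:
#'
#' * `E_core' = core_energy + 2 sum_c h_cc + sum_cd (2(cc|dd) - (cd|dc))`
#' * `h'_pq  = h_pq + sum_c (2(pq|cc) - (pc|cq))`
#'
#' Orbitals outside core + active are discarded (external).  With no core
#' and the full orbital set, the operator reproduces the integrals
#' verbatim.
#'
#' @param ints an [integral_set()].
#' @param space an [active_space()]; validated against `ints` first.
#' @return a [fermion_op()] on `2 * n_active_orbitals` spin orbitals.
#' @export
build_fermionic_hamiltonian <- function(ints, space) {
  stopifnot(inherits(ints, "integral_set"))
  act_ints <- active_integrals(ints, space)
  n_o <- act_ints$n_orbitals
  h_eff <- act_ints$one_body
  g_act <- act_ints$two_body

  terms <- list(list(coeff = act_ints$core_energy, ops = NULL))
  spins <- c(0L, n_o)  # alpha offset 0, beta offset n_o
  for (pi in seq_len(n_o)) for (qi in seq_len(n_o)) {
    if (h_eff[pi, qi] == 0) next
    for (s in spins) {
      terms[[length(terms) + 1L]] <- list(
        coeff = h_eff[pi, qi],
        ops = matrix(c(pi - 1L + s, 1L,
                       qi - 1L + s, 0L), ncol = 2L, byrow = TRUE,
                     dimnames = list(NULL, c("index", "dagger"))))
    }
  }
  for (pi in seq_len(n_o)) for (qi in seq_len(n_o))
    for (ri in seq_len(n_o)) for (si in seq_len(n_o)) {
      v <- g_act[pi, qi, ri, si]
      if (v == 0) next
      for (s1 in spins) for (s2 in spins) {
        P <- pi - 1L + s1; Q <- qi - 1L + s1
        R <- ri - 1L + s2; S <- si - 1L + s2
        if (P == R || Q == S) next  # a^dag a^dag / a a on same index -> 0
        terms[[length(terms) + 1L]] <- list(
          coeff = 0.5 * v,
          ops = matrix(c(P, 1L, R, 1L, S, 0L, Q, 0L), ncol = 2L, byrow = TRUE,
                       dimnames = list(NULL, c("index", "dagger"))))
      }
    }
  fermion_op(terms, 2L * n_o)
}

# --- Jordan-Wigner machinery ---------------------------------------------
# Pauli-with-phase algebra in the (coeff, x, z) representation where an
# entry means coeff * X^x Z^z (Z applied first).  Single-qubit dictionary:
# X = (1, e, 0), Z = (1, 0, e), Y = (i, e, e).  Product rule:
# (c1,x1,z1)(c2,x2,z2) = (c1 c2 (-1)^{popcount(z1 & x2)}, x1^x2, z1^z2).

.pauli_mult <- function(A, B) {
  i <- rep(seq_along(A$coeff), each = length(B$coeff))
  j <- rep(seq_along(B$coeff), times = length(A$coeff))
  sgn <- 1 - 2 * (popcount(bitwAnd(A$z[i], B$x[j])) %% 2L)
  list(coeff = A$coeff[i] * B$coeff[j] * sgn,
       x = bitwXor(A$x[i], B$x[j]),
       z = bitwXor(A$z[i], B$z[j]))
}

# JW image of a single ladder operator on spin orbital p (0-based):
# a^dag_p = 1/2 (X_p - i Y_p) Z_0..Z_{p-1};  a_p = 1/2 (X_p + i Y_p) Z...
.jw_ladder <- function(p, dagger, n) {
  ep <- qubit_bit(p, n)
  chain <- if (p > 0L) qubit_mask(0:(p - 1L), n) else 0L
  s <- if (dagger) 1 else -1
  # 1/2 [ X_p Z^chain  +/-  (X_p Z_p) Z^chain ]
  list(coeff = c(0.5 + 0i, s * 0.5 + 0i),
       x = c(ep, ep),
       z = c(chain, bitwXor(ep, chain)))
}

.jw_term <- function(ops, n) {
  acc <- list(coeff = 1 + 0i, x = 0L, z = 0L)
  for (r in seq_len(nrow(ops)))
    acc <- .pauli_mult(acc, .jw_ladder(ops[r, 1], ops[r, 2] == 1L, n))
  acc
}

#' Jordan-Wigner transformation
#'
#' Maps a [fermion_op()] to a qubit operator: `a^dag_p -> 1/2 (X_p - i
#' Y_p) Z_0...Z_{p-1}` (and the conjugate for `a_p`), with one qubit per
#' spin orbital.  Products are expanded in the phase-tracked `X^x Z^z`
#' algebra, like Pauli strings are collected, and coefficients below
#' 1e-12 in magnitude are dropped.  A Hermitian input yields real
#' collected coefficients; a residual imaginary part above 1e-9 raises a
#' hermiticity error.
#'
#' @param op a [fermion_op()].
#' @param n_spin_orbitals number of spin orbitals / qubits (defaults to
#'   the operator's own count).
#' @return a [qubit_op()] on `n_spin_orbitals` qubits.
#' @export
jordan_wigner <- function(op, n_spin_orbitals = op$n_spin_orbitals) {
  stopifnot(inherits(op, "fermion_op"))
  n <- as.integer(n_spin_orbitals)
  if (n < op$n_spin_orbitals) stop("n_spin_orbitals smaller than operator support")
  if (n > 16L) stop("Jordan-Wigner mask representation supports at most 16 spin orbitals")
  col <- .jw_collect(op, n)
  im_max <- if (length(col$coeff)) max(abs(Im(col$coeff))) else 0
  if (im_max > 1e-9)
    stop("input operator is not Hermitian (imaginary Pauli coefficient ",
         format(im_max), ")")
  qubit_op(n_qubits = n, x = col$x, z = col$z, coeff = Re(col$coeff))
}

# expand + collect the JW image of a fermion_op, keeping complex
# coefficients (needed for anti-Hermitian excitation generators)
.jw_collect <- function(op, n) {
  coeffs <- list(); xs <- list(); zs <- list()
  k <- 0L
  for (t in op$terms) {
    k <- k + 1L
    if (is.null(t$ops) || nrow(t$ops) == 0L) {
      coeffs[[k]] <- t$coeff + 0i; xs[[k]] <- 0L; zs[[k]] <- 0L
    } else {
      pp <- .jw_term(t$ops, n)
      coeffs[[k]] <- t$coeff * pp$coeff; xs[[k]] <- pp$x; zs[[k]] <- pp$z
    }
  }
  cc <- unlist(coeffs); xx <- unlist(xs); zz <- unlist(zs)
  key <- xx * 65536 + zz  # exact doubles for n <= 16
  agg <- rowsum(cbind(Re(cc), Im(cc)), group = key)
  keys <- as.numeric(rownames(agg))
  keep <- sqrt(agg[, 1]^2 + agg[, 2]^2) >= 1e-12
  x <- as.integer(keys[keep] %/% 65536)
  z <- as.integer(keys[keep] %% 65536)
  raw <- complex(real = agg[keep, 1], imaginary = agg[keep, 2])
  # convert from the raw X^x Z^z algebra to standard Pauli-string
  # coefficients: P = i^{|Y|} X^x Z^z, so c_pauli = c_raw * (-i)^{|Y|}
  ny <- popcount(bitwAnd(x, z)) %% 4L
  list(x = x, z = z, coeff = raw * (complex(real = 0, imaginary = -1))^ny)
}

#' Particle-number operator as a qubit operator
#'
#' The Jordan-Wigner image of `N = sum_p a^dag_p a_p` is
#' `(n/2) I - 1/2 sum_p Z_p`.
#'
#' @param n_qubits number of qubits / spin orbitals.
#' @return a [qubit_op()].
#' @export
number_operator <- function(n_qubits) {
  n <- as.integer(n_qubits)
  qubit_op(n_qubits = n,
           x = integer(n + 1L),
           z = c(0L, vapply(0:(n - 1L), qubit_bit, integer(1), n_qubits = n)),
           coeff = c(n / 2, rep(-0.5, n)))
}
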