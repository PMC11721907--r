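#' Slater determinants
#'
#' A determinant is an occupation bit list over spin orbitals (1 =
#' occupied), in the package's blocked spin-orbital order: alpha spin
#' orbitals `0..n_o-1` then their beta partners.  Internally stored as a
#' bit mask (bit s = spin orbital s).
#'
#' @param occupation 0/1 vector over spin orbitals.
#' @return an object of class `slater_determinant`.
#' @export
slater_determinant <- function(occupation) {
  bits <- as.integer(occupation)
  if (any(!bits %in% c(0L, 1L))) stop("occupation entries must be 0 or 1")
  structure(list(occupation = bits,
                 mask = sum(bits * bitwShiftL(1L, seq_along(bits) - 1L)),
                 n_spin_orbitals = length(bits)),
            class = "slater_determinant")
}

.det_from_mask <- function(mask, n_so) {
  bits <- bitwAnd(bitwShiftR(mask, 0:(n_so - 1L)), 1L)
  structure(list(occupation = bits, mask = mask, n_spin_orbitals = n_so),
            class = "slater_determinant")
}

#' @export
print.slater_determinant <- function(x, ...) {
  cat("<determinant> |", paste(x$occupation, collapse = ""), ">\n", sep = "")
  invisible(x)
}

# occupied spin orbitals (0-based) of a determinant mask
.occ_list <- function(mask, n_so) which(bitwAnd(bitwShiftR(mask, 0:(n_so - 1L)), 1L) == 1L) - 1L

#' Hartree-Fock reference determinant
#'
#' Occupies the lowest `ceiling(n_e/2)` alpha and `floor(n_e/2)` beta
#' spin orbitals (ascending-energy order of the active orbital list).
#'
#' @param n_electrons electron count.
#' @param n_spin_orbitals spin-orbital count (even).
#' @return a [slater_determinant()].
#' @export
hf_determinant <- function(n_electrons, n_spin_orbitals) {
  ne <- as.integer(n_electrons); nso <- as.integer(n_spin_orbitals)
  stopifnot(nso %% 2L == 0L, ne <= nso)
  n_o <- nso %/% 2L
  n_a <- (ne + 1L) %/% 2L; n_b <- ne - n_a
  bits <- integer(nso)
  if (n_a > 0L) bits[1:n_a] <- 1L
  if (n_b > 0L) bits[n_o + 1:n_b] <- 1L
  slater_determinant(bits)
}

#' Enumerate determinants for FCI or CISD
#'
#' FCI enumerates every determinant with the requested electron count
#' (restricted to the reference's Sz sector when `conserve_sz = TRUE`,
#' the default: the benchmark systems are closed-shell singlets).  CISD
#' keeps the reference plus all determinants at most two excitations
#' away from it.  The returned order is deterministic (ascending bit
#' mask).
#'
#' @param n_electrons electron count.
#' @param n_spin_orbitals spin-orbital count.
#' @param level `"FCI"` or `"CISD"`.
#' @param reference reference [determinant()]; required for CISD,
#'   defaults to [hf_determinant()].
#' @param conserve_sz restrict to the reference's Sz sector.
#' @return list of [slater_determinant()] objects.
#' @export
enumerate_determinants <- function(n_electrons, n_spin_orbitals,
                                   level = c("FCI", "CISD"),
                                   reference = NULL,
                                   conserve_sz = TRUE) {
  level <- match.arg(level)
  ne <- as.integer(n_electrons); nso <- as.integer(n_spin_orbitals)
  if (ne > nso) stop("infeasible: more electrons than spin orbitals")
  stopifnot(nso %% 2L == 0L, nso <= 30L)
  n_o <- nso %/% 2L
  if (is.null(reference)) reference <- hf_determinant(ne, nso)
  stopifnot(inherits(reference, "slater_determinant"),
            reference$n_spin_orbitals == nso,
            sum(reference$occupation) == ne)

  masks <- if (conserve_sz) {
    amask_bits <- 0:(n_o - 1L)
    n_a <- sum(reference$occupation[1:n_o])
    n_b <- ne - n_a
    choose_masks <- function(orbs, k) {
      if (k == 0L) return(0L)
      combs <- utils::combn(orbs, k, simplify = FALSE)
      vapply(combs, function(cs) sum(bitwShiftL(1L, cs)), numeric(1))
    }
    am <- choose_masks(0:(n_o - 1L), n_a)
    bm <- choose_masks(n_o:(nso - 1L), n_b)
    as.vector(outer(am, bm, `+`))
  } else {
    combs <- utils::combn(0:(nso - 1L), ne, simplify = FALSE)
    vapply(combs, function(cs) sum(bitwShiftL(1L, cs)), numeric(1))
  }
  masks <- sort(as.integer(masks))
  if (level == "CISD") {
    nex <- popcount(bitwXor(masks, reference$mask)) %/% 2L
    masks <- masks[nex <= 2L]
  }
  lapply(masks, .det_from_mask, n_so = nso)
}

#' Fold an active space into effective integrals
#'
#' Applies frozen-core folding and active-window restriction to an
#' [integral_set()], returning the effective active-space integrals
#' (with the folded constant in `core_energy` and `n_electrons` set to
#' the active electron count).  The same folding used by
#' [build_fermionic_hamiltonian()], exposed so the determinant CI path
#' and the qubit path share one definition of the active problem.
#'
#' @param ints an [integral_set()].
#' @param space an [active_space()].
#' @return an [integral_set()] over the active orbitals only.
#' @export
active_integrals <- function(ints, space) {
  stopifnot(inherits(ints, "integral_set"))
  space <- validate_active_space(space, ints$n_orbitals, ints$n_electrons)
  core <- if (space$n_core_orbitals > 0L) seq_len(space$n_core_orbitals) else integer(0)
  act <- space$active_orbital_indices + 1L
  n_o <- space$n_active_orbitals
  h <- ints$one_body; g <- ints$two_body
  e_core <- ints$core_energy
  if (length(core) > 0L) {
    e_core <- e_core + 2 * sum(diag(h)[core])
    for (c1 in core) for (c2 in core)
      e_core <- e_core + 2 * g[c1, c1, c2, c2] - g[c1, c2, c2, c1]
  }
  h_eff <- h[act, act, drop = FALSE]
  if (length(core) > 0L) {
    for (pi in seq_len(n_o)) for (qi in seq_len(n_o)) {
      p <- act[pi]; q <- act[qi]
      for (c1 in core)
        h_eff[pi, qi] <- h_eff[pi, qi] + 2 * g[p, q, c1, c1] - g[p, c1, c1, q]
    }
  }
  integral_set(n_o, space$n_active_electrons, e_core,
               h_eff, g[act, act, act, act, drop = FALSE])
}

# spin-orbital helpers over an n_o-spatial-orbital active set
.sc_h <- function(ints, P, Q) {
  n_o <- ints$n_orbitals
  if (P %/% n_o != Q %/% n_o) return(0)
  ints$one_body[P %% n_o + 1L, Q %% n_o + 1L]
}
# physicists <PQ|RS> over spin orbitals = (pr|qs) * spin deltas
.sc_v <- function(ints, P, Q, R, S) {
  n_o <- ints$n_orbitals
  if (P %/% n_o != R %/% n_o || Q %/% n_o != S %/% n_o) return(0)
  ints$two_body[P %% n_o + 1L, R %% n_o + 1L, Q %% n_o + 1L, S %% n_o + 1L]
}

# parity sign of moving an electron i -> a given occupation mask `mask`
# (mask is the determinant BEFORE the move; i occupied, a empty)
.sc_move_sign <- function(mask, i, a) {
  lo <- min(i, a); hi <- max(i, a)
  if (hi - lo < 2L) return(1)
  between <- bitwAnd(mask, bitwShiftL(bitwShiftL(1L, hi - lo - 1L) - 1L, lo + 1L))
  1 - 2 * (popcount(between) %% 2L)
}

#' Slater-Condon matrix element between two determinants
#'
#' Standard Slater-Condon rules over the spin orbitals of `ints`
#' (interpreted as the active-space effective integrals, see
#' [active_integrals()]): diagonal `sum h_ii + 1/2 sum (J - K)`;
#' one-orbital difference `h_ia + sum (J - K)` with the fermionic parity
#' sign; two-orbital difference the antisymmetrized two-electron term
#' with sign; more than two differing spin orbitals give exactly zero.
#' The scalar `core_energy` is *not* included (it is a constant shift).
#'
#' @param d1,d2 [slater_determinant()] objects of equal length and electron
#'   count.
#' @param ints an [integral_set()] whose spatial orbital count is half
#'   the determinants' spin-orbital count.
#' @return matrix element in Hartree.
#' @export
slater_condon_element <- function(d1, d2, ints) {
  stopifnot(inherits(d1, "slater_determinant"), inherits(d2, "slater_determinant"),
            inherits(ints, "integral_set"))
  nso <- d1$n_spin_orbitals
  if (d2$n_spin_orbitals != nso)
    stop("determinants have different spin-orbital counts")
  if (nso != 2L * ints$n_orbitals)
    stop("determinant length does not match 2 * n_orbitals of the integrals")
  if (sum(d1$occupation) != sum(d2$occupation))
    stop("determinants have different electron counts")
  .sc_element_masks(d1$mask, d2$mask, nso, ints)
}

.sc_element_masks <- function(m1, m2, nso, ints) {
  diff <- bitwXor(m1, m2)
  nd <- popcount(diff)
  if (nd > 4L) return(0)
  if (nd == 0L) {
    occ <- .occ_list(m1, nso)
    e <- 0
    for (i in occ) e <- e + .sc_h(ints, i, i)
    for (i in occ) for (j in occ)
      e <- e + 0.5 * (.sc_v(ints, i, j, i, j) - .sc_v(ints, i, j, j, i))
    return(e)
  }
  if (nd == 2L) {
    i <- .occ_list(bitwAnd(m1, diff), nso)
    a <- .occ_list(bitwAnd(m2, diff), nso)
    sgn <- .sc_move_sign(m1, i, a)
    e <- .sc_h(ints, i, a)
    for (j in .occ_list(bitwAnd(m1, m2), nso))
      e <- e + .sc_v(ints, i, j, a, j) - .sc_v(ints, i, j, j, a)
    return(sgn * e)
  }
  # nd == 4: i < j leave, a < b arrive
  ij <- .occ_list(bitwAnd(m1, diff), nso)
  ab <- .occ_list(bitwAnd(m2, diff), nso)
  i <- ij[1]; j <- ij[2]; a <- ab[1]; b <- ab[2]
  s1 <- .sc_move_sign(m1, i, a)
  mid <- bitwOr(bitwAnd(m1, bitwNot(bitwShiftL(1L, i))), bitwShiftL(1L, a))
  s2 <- .sc_move_sign(mid, j, b)
  s1 * s2 * (.sc_v(ints, i, j, a, b) - .sc_v(ints, i, j, b, a))
}

#' CI ground-state energy (FCI or CISD) in an active space
#'
#' Builds the CI matrix over [enumerate_determinants()] with
#' Slater-Condon elements on the [active_integrals()] of `(ints,
#' space)`, diagonalizes it, and returns the lowest eigenvalue plus the
#' folded core energy — a total energy on the same scale as the
#' Jordan-Wigner qubit Hamiltonian's spectrum.  FCI is exact within the
#' active space; CISD truncates to singles and doubles from the
#' Hartree-Fock reference and is an upper bound to FCI.
#'
#' @param ints an [integral_set()].
#' @param space an [active_space()]; defaults to the full orbital window.
#' @param level `"FCI"` or `"CISD"`.
#' @param conserve_sz restrict to the closed-shell Sz sector (default).
#' @param dim_cap largest CI dimension accepted (default 8192).
#' @return energy in Hartree.
#' @export
ci_ground_energy <- function(ints, space = NULL, level = c("FCI", "CISD"),
                             conserve_sz = TRUE, dim_cap = 8192L) {
  level <- match.arg(level)
  if (is.null(space))
    space <- active_space(ints$n_electrons, ints$n_orbitals)
  act <- active_integrals(ints, space)
  nso <- 2L * act$n_orbitals
  dets <- enumerate_determinants(act$n_electrons, nso, level = level,
                                 conserve_sz = conserve_sz)
  if (length(dets) > dim_cap)
    stop("CI dimension ", length(dets), " exceeds the cap of ", dim_cap)
  m <- .ci_matrix(dets, act)
  min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) + act$core_energy
}

.ci_matrix <- function(dets, act_ints) {
  nd <- length(dets)
  nso <- dets[[1]]$n_spin_orbitals
  masks <- vapply(dets, `[[`, numeric(1), "mask")
  m <- matrix(0, nd, nd)
  for (r in seq_len(nd)) {
    # prefilter columns by excitation distance
    ndiff <- popcount(bitwXor(as.integer(masks[r]), as.integer(masks)))
    for (cc in which(ndiff <= 4L & seq_len(nd) >= r)) {
      v <- .sc_element_masks(as.integer(masks[r]), as.integer(masks[cc]), nso, act_ints)
      m[r, cc] <- v
      m[cc, r] <- v
    }
  }
  m
}

#' Hartree-Fock energy of the active-space reference determinant
#'
#' Diagonal Slater-Condon element of [hf_determinant()] on the active
#' integrals, plus the folded core energy.
#'
#' @inheritParams ci_ground_energy
#' @return energy in Hartree.
#' @export
hf_energy <- function(ints, space = NULL) {
  if (is.null(space))
    space <- active_space(ints$n_electrons, ints$n_orbitals)
  act <- active_integrals(ints, space)
  nso <- 2L * act$n_orbitals
  ref <- hf_determinant(act$n_electrons, nso)
  slater_condon_element(ref, ref, act) + act$core_energy
}
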