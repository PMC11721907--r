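om <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE,
                           dimnames = list(NULL, c("index", "dagger")))

test_that("Jordan-Wigner closed forms: number and hopping operators", {
  num <- jordan_wigner(fermion_op(list(list(coeff = 1, ops = om(0L, 1L, 0L, 0L))), 2))
  labs <- pauli_labels(num)
  expect_setequal(labs, c("I", "Z0"))
  expect_equal(num$terms$coeff[labs == "I"], 0.5)
  expect_equal(num$terms$coeff[labs == "Z0"], -0.5)

  hop <- jordan_wigner(fermion_op(list(
    list(coeff = 1, ops = om(0L, 1L, 1L, 0L)),
    list(coeff = 1, ops = om(1L, 1L, 0L, 0L))), 2))
  labs <- pauli_labels(hop)
  expect_setequal(labs, c("X0 X1", "Y0 Y1"))
  expect_equal(hop$terms$coeff, c(0.5, 0.5))

  # Z chain appears for non-adjacent hopping
  hop02 <- jordan_wigner(fermion_op(list(
    list(coeff = 1, ops = om(0L, 1L, 2L, 0L)),
    list(coeff = 1, ops = om(2L, 1L, 0L, 0L))), 3))
  expect_setequal(pauli_labels(hop02), c("X0 Z1 X2", "Y0 Z1 Y2"))
})

test_that("Jordan-Wigner rejects non-Hermitian operators", {
  expect_error(
    jordan_wigner(fermion_op(list(list(coeff = 1, ops = om(0L, 1L, 1L, 0L))), 2)),
    "Hermitian")
})

test_that("Jordan-Wigner preserves the spectrum of random fermionic operators", {
  # random two-body operator on 4 spatial orbitals = 8 spin orbitals,
  # against the brute-force occupation-number-basis matrix oracle
  ints <- random_integral_set(4, 4, seed = 31)
  fop <- build_fermionic_hamiltonian(ints, active_space(4, 4))
  hq <- jordan_wigner(fop)
  ev_qubit <- eigen(qubit_matrix(hq), symmetric = TRUE, only.values = TRUE)$values
  ev_ferm <- eigen(oracle_fermion_matrix(fop), symmetric = TRUE,
                   only.values = TRUE)$values
  expect_close(sort(ev_qubit), sort(ev_ferm), 1e-9)

  # and a lighter 2-orbital case with a different seed
  ints2 <- random_integral_set(2, 2, seed = 77)
  fop2 <- build_fermionic_hamiltonian(ints2, active_space(2, 2))
  hq2 <- jordan_wigner(fop2)
  expect_close(sort(eigen(qubit_matrix(hq2), symmetric = TRUE, only.values = TRUE)$values),
               sort(eigen(oracle_fermion_matrix(fop2), symmetric = TRUE,
                          only.values = TRUE)$values), 1e-10)
})

test_that("the mapped particle-number operator commutes with molecular Hamiltonians", {
  nop <- number_operator(4)
  expect_setequal(pauli_labels(nop), c("I", "Z0", "Z1", "Z2", "Z3"))
  expect_equal(sum(nop$terms$coeff[pauli_labels(nop) == "I"]), 2)

  ints <- fixture_integrals("h2")
  hq <- jordan_wigner(build_fermionic_hamiltonian(ints, active_space(2, 2)))
  hm <- qubit_matrix(hq)
  nm <- qubit_matrix(nop)
  expect_lt(max(Mod(hm %*% nm - nm %*% hm)), 1e-9)
})

test_that("frozen-core folding conserves the ground energy of the frozen sector", {
  ints <- fixture_integrals("syn3")   # 3 orbitals, 4 electrons
  h_full <- jordan_wigner(build_fermionic_hamiltonian(ints, active_space(4, 3)))
  h_froz <- jordan_wigner(build_fermionic_hamiltonian(
    ints, active_space(2, 2, n_core_orbitals = 1)))
  # full 6-qubit problem restricted to orbital 0 doubly occupied, N = 4
  m <- qubit_matrix(h_full)
  n <- 6L
  idx <- 0:(2^n - 1L)
  occ <- function(q) bitwAnd(idx, bitwShiftL(1L, n - 1L - q)) > 0
  nelec <- rowSums(sapply(0:(n - 1L), occ))
  keep <- occ(0L) & occ(3L) & nelec == 4
  e_restricted <- min(eigen(m[keep, keep], symmetric = TRUE,
                            only.values = TRUE)$values)
  e_folded <- exact_ground_in_sector(h_froz, 2, n_alpha = 1)
  expect_lt(abs(e_restricted - e_folded), 1e-9)
})

test_that("the full-space operator reproduces the integrals verbatim", {
  ints <- random_integral_set(2, 2, seed = 13)
  fop <- build_fermionic_hamiltonian(ints, active_space(2, 2))
  # constant term = bare core energy (no folding when n_core = 0)
  const <- Filter(function(t) is.null(t$ops), fop$terms)
  expect_equal(const[[1]]$coeff, ints$core_energy)
  # one-body alpha coefficient h_12 appears unchanged
  onebody <- Filter(function(t) !is.null(t$ops) && nrow(t$ops) == 2L &&
                      all(t$ops[, 1] == c(0L, 1L)), fop$terms)
  expect_equal(onebody[[1]]$coeff, ints$one_body[1, 2])
})

test_that("fermion_op rejects terms with repeated identical ladder operators", {
  expect_error(fermion_op(list(list(coeff = 1, ops = om(0L, 1L, 0L, 1L))), 2),
               "repeated")
})
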