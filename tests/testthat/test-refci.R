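test_that("determinant enumeration counts and ordering are correct", {
  # 2 electrons in 4 spin orbitals: Sz = 0 sector has 2 x 2 determinants
  d_sz <- enumerate_determinants(2, 4, "FCI", conserve_sz = TRUE)
  expect_length(d_sz, 4L)
  d_all <- enumerate_determinants(2, 4, "FCI", conserve_sz = FALSE)
  expect_length(d_all, choose(4, 2))
  # singles + doubles exhaust all excitations of a 2-electron system
  d_cisd <- enumerate_determinants(2, 4, "CISD")
  expect_equal(vapply(d_cisd, `[[`, numeric(1), "mask"),
               vapply(d_sz, `[[`, numeric(1), "mask"))
  # deterministic ascending-mask order
  masks <- vapply(d_all, `[[`, numeric(1), "mask")
  expect_equal(masks, sort(masks))
  expect_error(enumerate_determinants(5, 4), "infeasible")
  # CISD determinant sets nest inside FCI
  f6 <- enumerate_determinants(4, 8, "FCI")
  c6 <- enumerate_determinants(4, 8, "CISD")
  expect_true(all(vapply(c6, `[[`, numeric(1), "mask") %in%
                  vapply(f6, `[[`, numeric(1), "mask")))
  expect_lt(length(c6), length(f6) + 1L)
})

test_that("Slater-Condon rules: zero rule and oracle agreement", {
  ints <- random_integral_set(3, 4, seed = 91)
  act <- active_integrals(ints, active_space(4, 3))
  # determinants differing in three spin orbitals couple to exactly zero
  d1 <- slater_determinant(c(1, 1, 0, 1, 0, 0))
  d2 <- slater_determinant(c(0, 0, 1, 0, 1, 1))
  expect_identical(slater_condon_element(d1, d2, act), 0)

  # full CI matrix is Hermitian and spectrally identical to the qubit
  # Hamiltonian in the matching sector
  dets <- enumerate_determinants(4, 6, "FCI")
  m <- vapply(dets, function(a) vapply(dets, function(b)
    slater_condon_element(a, b, act), numeric(1)), numeric(length(dets)))
  expect_lt(max(abs(m - t(m))), 1e-12)
  hq <- jordan_wigner(build_fermionic_hamiltonian(ints, active_space(4, 3)))
  qm <- qubit_matrix(hq)
  idx <- 0:(2^6 - 1L)
  occs <- sapply(0:5, function(q) bitwAnd(idx, bitwShiftL(1L, 5L - q)) > 0)
  keep <- rowSums(occs) == 4 & rowSums(occs[, 1:3]) == 2
  ev_ci <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  ev_q <- sort(eigen(qm[keep, keep], symmetric = TRUE, only.values = TRUE)$values) -
    act$core_energy
  expect_close(ev_ci, ev_q, 1e-9)
})

test_that("HF diagonal element equals the UCCSD circuit at theta = 0", {
  ints <- fixture_integrals("h2")
  sp <- active_space(2, 2)
  act <- active_integrals(ints, sp)
  ref <- hf_determinant(2, 4)
  e_diag <- slater_condon_element(ref, ref, act) + act$core_energy
  h <- jordan_wigner(build_fermionic_hamiltonian(ints, sp))
  e_circ <- vqe_cost(numeric(3), build_uccsd(2, 4), h)
  expect_close(e_diag, e_circ, 1e-10)
})

test_that("FCI equals the Jordan-Wigner ground energy on every fixture", {
  cases <- list(list("h2", active_space(2, 2), 2L, 1L),
                list("syn3", active_space(4, 3), 4L, 2L),
                list("syn4", active_space(4, 4), 4L, 2L))
  for (cs in cases) {
    ints <- fixture_integrals(cs[[1]])
    e_fci <- ci_ground_energy(ints, cs[[2]], "FCI")
    hq <- jordan_wigner(build_fermionic_hamiltonian(ints, cs[[2]]))
    e_jw <- exact_ground_in_sector(hq, cs[[3]], n_alpha = cs[[4]])
    expect_lt(abs(e_fci - e_jw), 1e-9)
  }
})

test_that("CISD equals FCI exactly for two-electron systems", {
  ints <- fixture_integrals("h2")
  sp <- active_space(2, 2)
  expect_equal(ci_ground_energy(ints, sp, "CISD"),
               ci_ground_energy(ints, sp, "FCI"))
  # also with a frozen core: 2 active electrons in syn3
  ints3 <- fixture_integrals("syn3")
  sp3 <- active_space(2, 2, n_core_orbitals = 1)
  expect_equal(ci_ground_energy(ints3, sp3, "CISD"),
               ci_ground_energy(ints3, sp3, "FCI"))
})

test_that("variational nesting: FCI <= CISD <= HF on all fixtures", {
  cases <- list(list("h2", active_space(2, 2)),
                list("syn3", active_space(4, 3)),
                list("syn4", active_space(4, 4)),
                list("syn6", active_space(4, 4, n_core_orbitals = 1)))
  for (cs in cases) {
    ints <- fixture_integrals(cs[[1]])
    e_fci <- ci_ground_energy(ints, cs[[2]], "FCI")
    e_cisd <- ci_ground_energy(ints, cs[[2]], "CISD")
    e_hf <- hf_energy(ints, cs[[2]])
    expect_lte(e_fci, e_cisd + 1e-12)
    expect_lte(e_cisd, e_hf + 1e-12)
  }
})

test_that("determinant construction routes agree and shapes are enforced", {
  ints <- random_integral_set(2, 2, seed = 55)
  act <- active_integrals(ints, active_space(2, 2))
  d_bits <- slater_determinant(c(1, 0, 1, 0))
  d_mask <- vqebench:::.det_from_mask(d_bits$mask, 4L)
  expect_equal(d_bits$occupation, d_mask$occupation)
  expect_equal(slater_condon_element(d_bits, d_bits, act),
               slater_condon_element(d_mask, d_mask, act))
  expect_error(slater_condon_element(d_bits, slater_determinant(c(1, 0, 0, 0)), act),
               "electron counts")
  expect_error(slater_condon_element(d_bits, slater_determinant(c(1, 1)), act),
               "spin-orbital counts")
})
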