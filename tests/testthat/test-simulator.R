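test_that("amplitude-index convention: qubit 0 is the most significant bit", {
  expect_equal(which(Mod(init_state(2)$amplitudes) > 0), 1L)          # |00>
  expect_equal(which(Mod(init_state(2, c(1, 0))$amplitudes) > 0), 3L) # index 2
  expect_equal(which(Mod(init_state(2, c(0, 1))$amplitudes) > 0), 2L) # index 1
  expect_equal(which(Mod(init_state(3, c(1, 1, 1))$amplitudes) > 0), 8L)
  expect_error(init_state(25), "cap")
  # X on qubit 0 of 2 qubits flips the HIGH bit of the index
  st <- apply_gate(init_state(2), gate("X", 0))
  expect_equal(which(Mod(st$amplitudes) > 0), 3L)
})

test_that("standard gate actions: H, CNOT, rotations", {
  plus <- apply_gate(init_state(1), gate("H", 0))
  expect_close(plus$amplitudes, c(1, 1) / sqrt(2), 1e-12)

  bell <- apply_gate(apply_gate(init_state(2), gate("H", 0)),
                     gate("CNOT", 1, control = 0))
  expect_close(bell$amplitudes, c(1, 0, 0, 1) / sqrt(2), 1e-12)

  expect_close(apply_gate(init_state(1), gate("RX", 0, angle = 0))$amplitudes,
               c(1, 0), 1e-14)
  flipped <- apply_gate(init_state(1), gate("RY", 0, angle = pi))
  expect_close(Mod(flipped$amplitudes), c(0, 1), 1e-12)

  expect_error(apply_gate(init_state(2), gate("H", 5)), "range")
})

test_that("gate identities hold on random states", {
  st <- random_state(3, seed = 4)
  for (gs in list(list(gate("H", 1), gate("H", 1)),
                  list(gate("CNOT", 2, control = 0), gate("CNOT", 2, control = 0)),
                  list(gate("RX", 0, angle = 0.73), gate("RX", 0, angle = -0.73)),
                  list(gate("RZ", 2, angle = 1.1), gate("RZ", 2, angle = -1.1)))) {
    out <- apply_gate(apply_gate(st, gs[[1]]), gs[[2]])
    expect_close(out$amplitudes, st$amplitudes, 1e-10)
  }
})

test_that("norm is preserved over long random gate sequences", {
  set.seed(99)
  st <- init_state(4)
  kinds <- c("H", "X", "RX", "RY", "RZ", "CNOT")
  for (i in 1:1000) {
    k <- sample(kinds, 1)
    t <- sample(0:3, 1)
    g <- if (k == "CNOT") gate(k, t, control = sample(setdiff(0:3, t), 1))
    else gate(k, t, angle = stats::runif(1, -pi, pi))
    st <- apply_gate(st, g)
  }
  expect_lt(abs(sum(Mod(st$amplitudes)^2) - 1), 1e-9)
})

test_that("expectation values match closed forms and the dense oracle", {
  n <- 3
  zero <- init_state(n)
  for (q in 0:(n - 1))
    expect_equal(expectation(zero, pauli_sum(paste0("Z", q), 1, n)), 1)

  bell <- apply_gate(apply_gate(init_state(2), gate("H", 0)),
                     gate("CNOT", 1, control = 0))
  expect_close(expectation(bell, pauli_sum("Z0 Z1", 1, 2)), 1, 1e-12)
  expect_close(expectation(bell, pauli_sum("Z0", 1, 2)), 0, 1e-12)

  # identity coefficient passes through exactly; expectation is linear
  st <- random_state(2, seed = 8)
  expect_equal(expectation(st, pauli_sum("I", 2.5, 2)), 2.5)
  h1 <- pauli_sum(c("Z0", "X1"), c(0.4, -0.3), 2)
  h2 <- pauli_sum(c("Z0", "X1"), c(0.8, -0.6), 2)
  expect_close(2 * expectation(st, h1), expectation(st, h2), 1e-12)

  # random 6-qubit state / 30-term Hamiltonian vs explicit quadratic form
  h <- random_pauli_op(6, 30, seed = 21)
  st6 <- random_state(6, seed = 22)
  m <- oracle_qubit_matrix(h)
  quad <- Re(Conj(st6$amplitudes) %*% m %*% st6$amplitudes)
  expect_close(expectation(st6, h), as.numeric(quad), 1e-9)

  expect_error(expectation(init_state(2), pauli_sum("Z0", 1, 3)), "mismatch")
})

test_that("exact_spectrum returns ascending eigenvalues and matches the oracle", {
  expect_equal(exact_spectrum(pauli_sum("Z0", 1, 1), k = 2), c(-1, 1))
  expect_close(exact_spectrum(pauli_sum(c("Z0", "Z1", "I"), c(0.5, 0.5, 2), 2), 1),
               1, 1e-12)
  h <- random_pauli_op(6, 25, seed = 33)
  ev_pkg <- exact_spectrum(h, k = 64)
  ev_oracle <- sort(eigen(oracle_qubit_matrix(h), symmetric = TRUE,
                          only.values = TRUE)$values)
  expect_close(ev_pkg, ev_oracle, 1e-9)
  expect_error(qubit_matrix(h, dense_cap = 4), "cap")
})

test_that("the spectral minimum lower-bounds every expectation value", {
  h <- random_pauli_op(4, 20, seed = 41)
  e0 <- exact_spectrum(h, 1)
  for (s in 1:100)
    expect_gte(expectation(random_state(4, seed = 1000 + s), h), e0 - 1e-9)
})

test_that("statevector operations are pure (no observable mutation)", {
  st <- init_state(2)
  before <- st$amplitudes
  invisible(apply_gate(st, gate("X", 0)))
  expect_identical(st$amplitudes, before)
})
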