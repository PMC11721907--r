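test_that("hardware-efficient count formulas hold for the benchmark sizes", {
  for (n in c(4L, 8L, 12L, 16L)) {
    expect_equal(counts(build_hardware_efficient("v1", n)),
                 c(n_parameters = n, n_gates = 5L * n %/% 2L))
    expect_equal(counts(build_hardware_efficient("v2", n)),
                 c(n_parameters = n, n_gates = 5L * n %/% 2L))
    expect_equal(counts(build_hardware_efficient("v3", n)),
                 c(n_parameters = 2L * (3L * n - 2L), n_gates = 15L * n %/% 2L))
    expect_equal(counts(build_hardware_efficient("v4", n)),
                 c(n_parameters = n, n_gates = 5L * n %/% 2L))
    expect_equal(counts(build_hardware_efficient("v5", n)),
                 c(n_parameters = n, n_gates = 9L * n %/% 4L))
  }
  expect_error(build_hardware_efficient("v1", 7), "even")
  expect_error(build_hardware_efficient("v5", 6), "divisible by 4")
})

test_that("v1 and v4 differ only in rotation order (same gate multiset)", {
  g1 <- build_hardware_efficient("v1", 8)$gates
  g4 <- build_hardware_efficient("v4", 8)$gates
  expect_equal(sort(table(g1$kind)), sort(table(g4$kind)))
  expect_false(identical(g1$kind, g4$kind))
  # v1 applies RX before RY on each occupied qubit, v4 the reverse
  rot1 <- g1$kind[g1$kind %in% c("RX", "RY")]
  rot4 <- g4$kind[g4$kind %in% c("RX", "RY")]
  expect_equal(rot1[1:2], c("RX", "RY"))
  expect_equal(rot4[1:2], c("RY", "RX"))
})

test_that("v1 Hadamard layer survives zero rotations: <Z0> = 0 at theta = 0", {
  tpl <- build_hardware_efficient("v1", 4)
  st <- bind_circuit(tpl, numeric(tpl$n_parameters))
  expect_close(expectation(st, pauli_sum("Z0", 1, 4)), 0, 1e-10)
  # virtual-half qubits receive no Hadamard: occupied-virtual CNOTs copy
  # the superposition, so the joint parity with the control is fixed
  expect_close(expectation(st, pauli_sum("Z0 Z2", 1, 4)), 1, 1e-10)
})

test_that("v2/v3/v5 generically reach all computational basis states", {
  for (v in c("v2", "v3", "v5")) {
    tpl <- build_hardware_efficient(v, 4)
    ok <- 0L
    for (s in 1:50) {
      set.seed(s)
      th <- stats::runif(tpl$n_parameters, -pi, pi)
      st <- bind_circuit(tpl, th)
      if (all(Mod(st$amplitudes) > 1e-8)) ok <- ok + 1L
    }
    expect_gte(ok, 45L)
  }
})

test_that("spin-conserving excitation enumeration matches brute force", {
  exc <- uccsd_excitations(2, 4)
  expect_length(exc$singles, 2L)   # alpha 0->1, beta 2->3
  expect_length(exc$doubles, 1L)   # (0,2) -> (1,3)
  expect_equal(counts(build_uccsd(2, 4))[["n_parameters"]], 3L)

  # (4e,4o): brute-force count of Sz-conserving occupied->virtual moves
  exc2 <- uccsd_excitations(4, 8)
  is_a <- function(s) s < 4
  occ <- c(0, 1, 4, 5); virt <- c(2, 3, 6, 7)
  n_singles <- sum(outer(occ, virt,
                         Vectorize(function(i, a) is_a(i) == is_a(a))))
  pairs <- function(v) utils::combn(v, 2, simplify = FALSE)
  n_doubles <- sum(vapply(pairs(occ), function(ij)
    sum(vapply(pairs(virt), function(ab)
      sum(is_a(ij)) == sum(is_a(ab)), logical(1))), numeric(1)))
  expect_length(exc2$singles, n_singles)
  expect_length(exc2$doubles, n_doubles)
  expect_error(uccsd_excitations(4, 4), "no virtual")
})

test_that("UCCSD at theta = 0 prepares exactly the Hartree-Fock state", {
  tpl <- build_uccsd(2, 4)
  st <- bind_circuit(tpl, numeric(tpl$n_parameters))
  hf <- init_state(4, c(1, 0, 1, 0))  # alpha0 + beta0 occupied
  expect_close(st$amplitudes, hf$amplitudes, 1e-12)

  tpl2 <- build_uccsd(4, 8)
  st2 <- bind_circuit(tpl2, numeric(tpl2$n_parameters))
  hf2 <- init_state(8, c(1, 1, 0, 0, 1, 1, 0, 0))
  expect_close(st2$amplitudes, hf2$amplitudes, 1e-12)
})

test_that("UCCSD conserves particle number at random parameters", {
  tpl <- build_uccsd(4, 8)
  nop <- number_operator(8)
  for (s in 1:5) {
    set.seed(s)
    th <- stats::runif(tpl$n_parameters, -0.5, 0.5)
    st <- bind_circuit(tpl, th)
    expect_lt(abs(expectation(st, nop) - 4), 1e-9)
  }
})

test_that("parameter binding is deterministic and arity-checked", {
  tpl <- build_hardware_efficient("v3", 4)
  set.seed(12)
  th <- stats::runif(tpl$n_parameters, -pi, pi)
  expect_identical(bind_circuit(tpl, th)$amplitudes,
                   bind_circuit(tpl, th)$amplitudes)
  expect_error(bind_circuit(tpl, th[-1]), "length")
  expect_error(bind_circuit(tpl, th, init_state(6)), "match")
})

test_that("template validation catches unused and out-of-range slots", {
  g <- rbind(gate("RX", 0, parameter_slot = 0), gate("RY", 1, parameter_slot = 2))
  expect_error(circuit_template(2, g, 3), "slots")
  empty <- circuit_template(2, gate("H", 0)[0, ], 0)
  expect_equal(counts(empty), c(n_parameters = 0L, n_gates = 0L))
})
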