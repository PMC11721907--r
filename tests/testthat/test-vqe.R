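test_that("cost reduces to closed forms", {
  # constant Hamiltonian: cost is its coefficient for any parameters
  tpl <- build_hardware_efficient("v2", 4)
  h3 <- pauli_sum("I", 3, 4)
  set.seed(2)
  expect_equal(vqe_cost(stats::runif(4, -pi, pi), tpl, h3), 3)

  # single RY on |0> with h = Z0: cost = cos(theta)
  g <- gate("RY", 0, parameter_slot = 0)
  tpl1 <- circuit_template(1, g, 1)
  hz <- pauli_sum("Z0", 1, 1)
  for (th in c(0, 0.3, pi / 2, 2.2))
    expect_close(vqe_cost(th, tpl1, hz), cos(th), 1e-12)
})

test_that("UCCSD cost at theta = 0 equals the Hartree-Fock energy", {
  ints <- fixture_integrals("h2")
  sp <- active_space(2, 2)
  h <- jordan_wigner(build_fermionic_hamiltonian(ints, sp))
  tpl <- build_uccsd(2, 4)
  expect_close(vqe_cost(numeric(3), tpl, h), hf_energy(ints, sp), 1e-10)
})

test_that("parameter-shift gradient matches closed forms and finite differences", {
  tpl1 <- circuit_template(1, gate("RY", 0, parameter_slot = 0), 1)
  hz <- pauli_sum("Z0", 1, 1)
  expect_close(vqe_gradient(0, tpl1, hz), 0, 1e-12)
  expect_close(vqe_gradient(pi / 2, tpl1, hz), -1, 1e-12)

  # random 4-qubit templates vs central finite differences
  h <- random_pauli_op(4, 12, seed = 51)
  for (v in c("v1", "v3")) {
    tpl <- build_hardware_efficient(v, 4)
    set.seed(60)
    th <- stats::runif(tpl$n_parameters, -pi, pi)
    g <- vqe_gradient(th, tpl, h)
    fd <- vapply(seq_along(th), function(k) {
      e <- 1e-5
      tp <- th; tp[k] <- tp[k] + e
      tm <- th; tm[k] <- tm[k] - e
      (vqe_cost(tp, tpl, h) - vqe_cost(tm, tpl, h)) / (2 * e)
    }, numeric(1))
    expect_close(g, fd, 1e-4)
  }

  # scaled multi-gate parameters (UCCSD-style) still differentiate exactly
  tplu <- build_uccsd(2, 4)
  ints <- fixture_integrals("h2")
  hq <- jordan_wigner(build_fermionic_hamiltonian(ints, active_space(2, 2)))
  th <- c(0.11, -0.23, 0.31)
  g <- vqe_gradient(th, tplu, hq)
  fd <- vapply(1:3, function(k) {
    e <- 1e-6
    tp <- th; tp[k] <- tp[k] + e
    tm <- th; tm[k] <- tm[k] - e
    (vqe_cost(tp, tplu, hq) - vqe_cost(tm, tplu, hq)) / (2 * e)
  }, numeric(1))
  expect_close(g, fd, 1e-6)
})

test_that("a zero-parameter template converges at step one", {
  tpl <- circuit_template(2, rbind(gate("H", 0), gate("H", 1)), 0)
  h <- pauli_sum(c("Z0", "X1"), c(1, 0.5), 2)
  res <- vqe_minimize(tpl, h)
  expect_equal(res$steps_to_convergence, 1L)
  expect_true(res$converged)
  expect_length(res$trajectory, 1L)
  expect_close(res$energy, 0.5, 1e-10)  # <Z0> = 0, <X1> = 1 after H
})

test_that("minimization is deterministic and honors the convergence rule", {
  h <- random_pauli_op(4, 15, seed = 71)
  tpl <- build_hardware_efficient("v2", 4)
  cfg <- optimizer_config(seed = 5, max_steps = 300)
  r1 <- vqe_minimize(tpl, h, cfg = cfg)
  r2 <- vqe_minimize(tpl, h, cfg = cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$parameters, r2$parameters)

  # reported steps_to_convergence is the FIRST index satisfying the rule
  d <- abs(diff(r1$trajectory))
  if (r1$converged) {
    expect_equal(r1$steps_to_convergence, which(d < cfg$convergence_tol)[1])
    expect_true(all(d[seq_len(r1$steps_to_convergence - 1L)] >= cfg$convergence_tol))
  }
  expect_equal(r1$energy, r1$trajectory[length(r1$trajectory)])
  expect_lte(r1$steps_to_convergence, cfg$max_steps)
})

test_that("every recorded energy respects the variational bound", {
  h <- random_pauli_op(4, 15, seed = 81)
  e0 <- exact_spectrum(h, 1)
  for (v in c("v2", "v5")) {
    tpl <- build_hardware_efficient(v, 4)
    res <- vqe_minimize(tpl, h, cfg = optimizer_config(seed = 3, max_steps = 150))
    expect_true(all(res$trajectory >= e0 - 1e-9))
    expect_lte(res$energy, res$trajectory[1])  # descent from the start
  }
})

test_that("hitting max_steps reports converged = FALSE instead of erroring", {
  ints <- fixture_integrals("h2")
  hq <- jordan_wigner(build_fermionic_hamiltonian(ints, active_space(2, 2)))
  tpl <- build_uccsd(2, 4)
  res <- vqe_minimize(tpl, hq, cfg = optimizer_config(init_scheme = "zeros",
                                                      max_steps = 3))
  expect_false(res$converged)
  expect_equal(res$steps_to_convergence, 3L)
})

test_that("adam is available as a second optimizer and also descends", {
  ints <- fixture_integrals("h2")
  hq <- jordan_wigner(build_fermionic_hamiltonian(ints, active_space(2, 2)))
  tpl <- build_uccsd(2, 4)
  res <- vqe_minimize(tpl, hq, cfg = optimizer_config(method = "adam",
                                                      step_size = 0.05,
                                                      init_scheme = "zeros",
                                                      max_steps = 500))
  expect_lt(res$energy, res$trajectory[1])
})

test_that("trajectory CSV export has the step,energy shape", {
  tpl <- circuit_template(1, gate("RY", 0, parameter_slot = 0), 1)
  res <- vqe_minimize(tpl, pauli_sum("Z0", 1, 1),
                      cfg = optimizer_config(seed = 1, max_steps = 50))
  p <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(res, p)
  df <- utils::read.csv(p)
  expect_named(df, c("step", "energy"))
  expect_equal(df$step[1], 0L)
  expect_equal(nrow(df), length(res$trajectory))
})
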