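#' Optimizer configuration
#'
#' Settings for the classical loop that drives the variational
#' minimization.  The convergence rule follows the seventh-decimal
#' criterion: iteration stops at the first step whose energy differs from
#' the previous accepted energy by less than `convergence_tol` Hartree
#' (default 1e-7).
#'
#' @param method `"gradient_descent"` (default) or `"adam"`.
#' @param step_size positive learning rate (default 0.1).
#' @param max_steps maximum optimization steps (default 2000).
#' @param convergence_tol energy-difference tolerance in Hartree.
#' @param seed integer seed for random parameter initialization.
#' @param init_scheme `"uniform_random"` (uniform on -pi..pi, default) or
#'   `"zeros"` (natural for UCCSD, giving a Hartree-Fock start).
#' @return an object of class `optimizer_config`.
#' @export
optimizer_config <- function(method = c("gradient_descent", "adam"),
                             step_size = 0.1,
                             max_steps = 2000L,
                             convergence_tol = 1e-7,
                             seed = 1L,
                             init_scheme = c("uniform_random", "zeros")) {
  method <- match.arg(method)
  init_scheme <- match.arg(init_scheme)
  stopifnot(step_size > 0, max_steps >= 1L, convergence_tol > 0)
  structure(list(method = method, step_size = as.numeric(step_size),
                 max_steps = as.integer(max_steps),
                 convergence_tol = as.numeric(convergence_tol),
                 seed = as.integer(seed), init_scheme = init_scheme),
            class = "optimizer_config")
}

#' VQE cost function
#'
#' `C(theta) = <psi(theta)| H |psi(theta)>` with `|psi(theta)> =
#' U(theta)|psi>`; by the variational principle this upper-bounds the
#' ground-state energy of `H` for every `theta`.
#'
#' @param theta parameter vector.
#' @param template a [circuit_template()].
#' @param h a [qubit_op()].
#' @param initial initial [statevector()] (default `|0...0>`).
#' @return real energy in Hartree.
#' @export
vqe_cost <- function(theta, template, h,
                     initial = init_state(template$n_qubits)) {
  expectation(bind_circuit(template, theta, initial), h)
}

# cost evaluated from an explicitly resolved per-gate angle vector
.cost_from_angles <- function(angles, template, h, initial) {
  g <- template$gates
  g$angle <- angles
  expectation(.run_circuit(initial, g), h)
}

# precompiled form of a template + Hamiltonian + initial state: plain
# integer/numeric vectors so repeated evaluations skip data.frame overhead
.compile_run <- function(template, h, initial) {
  g <- template$gates
  list(kind = unname(.gate_kinds[g$kind]),
       target = g$target,
       control = ifelse(is.na(g$control), -1L, g$control),
       angle = g$angle,
       slot = g$slot,
       scale = g$scale,
       bound = which(!is.na(g$slot)),
       amps = initial$amplitudes,
       hx = h$terms$x, hz = h$terms$z, hc = h$terms$coeff,
       n = template$n_qubits)
}

.cr_angles <- function(cr, theta) {
  a <- cr$angle
  a[cr$bound] <- cr$scale[cr$bound] * theta[cr$slot[cr$bound] + 1L]
  a
}

.cr_cost <- function(cr, angles) {
  st <- cpp_apply_circuit(cr$amps, cr$kind, cr$target, cr$control, angles, cr$n)
  v <- cpp_pauli_expectation(st, cr$hx, cr$hz, cr$hc, cr$n)
  Re(v)
}

.cr_gradient <- function(cr, theta, n_parameters) {
  base <- .cr_angles(cr, theta)
  cpp_param_shift_gradient(cr$amps, cr$kind, cr$target, cr$control, base,
                           cr$bound - 1L, cr$slot[cr$bound],
                           cr$scale[cr$bound], n_parameters,
                           cr$hx, cr$hz, cr$hc, cr$n)
}

#' Analytic gradient by the parameter-shift rule
#'
#' Every trainable gate is an RX/RY/RZ rotation, whose generator has
#' eigenvalues +-1/2, so shifting that gate's angle by +-pi/2 gives the
#' exact derivative: for each gate `g` holding parameter `k` with
#' chain-rule scale `s_g`, the contribution is `s_g * (C(g+) - C(g-)) /
#' 2` and contributions over gates are summed.  When a parameter enters
#' exactly one unit-scale rotation (all hardware-efficient ansatzes) this
#' reduces to the familiar whole-parameter shift
#' `0.5 * [C(theta + pi/2 e_k) - C(theta - pi/2 e_k)]`.
#'
#' @inheritParams vqe_cost
#' @return numeric gradient vector, length `n_parameters`.
#' @export
vqe_gradient <- function(theta, template, h,
                         initial = init_state(template$n_qubits)) {
  stopifnot(inherits(template, "circuit_template"))
  theta <- as.numeric(theta)
  if (length(theta) != template$n_parameters)
    stop("parameter vector length mismatch")
  g <- template$gates
  bound <- which(!is.na(g$slot))
  if (length(bound) > 0L && !all(g$kind[bound] %in% c("RX", "RY", "RZ")))
    stop("parameter-shift gradient requires all parameterized gates to be rotations")
  cr <- .compile_run(template, h, initial)
  .cr_gradient(cr, theta, template$n_parameters)
}

#' Run the VQE optimization loop
#'
#' Initializes the parameters (by `cfg$init_scheme` under `cfg$seed`),
#' then iterates `theta <- theta - step_size * gradient` (or Adam
#' updates), recording the energy at every step.  Iteration stops at the
#' first step `k` with `|E_k - E_{k-1}| < convergence_tol` — the
#' seventh-decimal convergence rule at the default tolerance — or at
#' `max_steps`, in which case `converged = FALSE` is reported rather
#' than an error.  A non-finite energy raises an optimization-failure
#' error carrying the trajectory so far.  Runs are deterministic given
#' the configuration.
#'
#' @param template a [circuit_template()].
#' @param h a [qubit_op()].
#' @param initial initial [statevector()].
#' @param cfg an [optimizer_config()].
#' @return an object of class `vqe_result`: list with `energy` (Hartree),
#'   `parameters`, `trajectory` (energies per step, starting with the
#'   initial energy), `steps_to_convergence`, `converged`.
#' @export
vqe_minimize <- function(template, h,
                         initial = init_state(template$n_qubits),
                         cfg = optimizer_config()) {
  stopifnot(inherits(template, "circuit_template"),
            inherits(cfg, "optimizer_config"))
  np <- template$n_parameters
  theta <- switch(cfg$init_scheme,
    zeros = numeric(np),
    uniform_random = {
      old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
      set.seed(cfg$seed)
      stats::runif(np, -pi, pi)
    })
  gg <- template$gates
  pg <- which(!is.na(gg$slot))
  if (length(pg) > 0L && !all(gg$kind[pg] %in% c("RX", "RY", "RZ")))
    stop("parameter-shift gradient requires all parameterized gates to be rotations")
  cr <- .compile_run(template, h, initial)
  energies <- numeric(cfg$max_steps + 1L)
  energies[1] <- .cr_cost(cr, .cr_angles(cr, theta))
  if (np == 0L) {
    return(structure(list(energy = energies[1], parameters = numeric(0),
                          trajectory = energies[1],
                          steps_to_convergence = 1L, converged = TRUE),
                     class = "vqe_result"))
  }
  m <- numeric(np); v <- numeric(np)  # Adam state
  converged <- FALSE
  steps <- cfg$max_steps
  n_rec <- 1L
  for (k in seq_len(cfg$max_steps)) {
    grad <- .cr_gradient(cr, theta, np)
    if (cfg$method == "adam") {
      m <- 0.9 * m + 0.1 * grad
      v <- 0.999 * v + 0.001 * grad^2
      mhat <- m / (1 - 0.9^k)
      vhat <- v / (1 - 0.999^k)
      theta <- theta - cfg$step_size * mhat / (sqrt(vhat) + 1e-8)
    } else {
      theta <- theta - cfg$step_size * grad
    }
    e <- .cr_cost(cr, .cr_angles(cr, theta))
    if (!is.finite(e)) {
      cond <- structure(
        class = c("vqe_divergence_error", "error", "condition"),
        list(message = "optimization diverged to a non-finite energy",
             call = sys.call(-1L), trajectory = energies[seq_len(n_rec)]))
      stop(cond)
    }
    n_rec <- n_rec + 1L
    energies[n_rec] <- e
    if (abs(e - energies[n_rec - 1L]) < cfg$convergence_tol) {
      converged <- TRUE
      steps <- k
      break
    }
  }
  structure(list(energy = energies[n_rec], parameters = theta,
                 trajectory = energies[seq_len(n_rec)],
                 steps_to_convergence = steps, converged = converged),
            class = "vqe_result")
}

#' @export
print.vqe_result <- function(x, ...) {
  cat(sprintf("<vqe_result> E = %.10f Ha after %d steps (%s)\n",
              x$energy, x$steps_to_convergence,
              if (x$converged) "converged" else "max_steps reached"))
  invisible(x)
}

#' Export an optimization trajectory as CSV
#'
#' Writes `step,energy` rows (step 0 is the initial energy), the shape
#' used for optimization-trace figures.
#'
#' @param result a [vqe_result()] from [vqe_minimize()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(result, path) {
  stopifnot(inherits(result, "vqe_result"))
  df <- data.frame(step = seq_along(result$trajectory) - 1L,
                   energy = result$trajectory)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
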