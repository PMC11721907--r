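#' Benchmark configuration
#'
#' Describes one ansatz-by-active-space benchmark matrix: where the
#' integrals come from, which active spaces and ansatzes to run, and the
#' optimizer settings shared across rows.
#'
#' @param integral_source an [integral_set()], a fixture name accepted by
#'   [fixture_integrals()], or a path to an FCIDUMP file.
#' @param active_spaces list of [active_space()] objects (non-empty).
#' @param ansatzes character vector from `v1..v5`, `uccsd` (non-empty).
#' @param optimizer an [optimizer_config()].
#' @return an object of class `benchmark_config`.
#' @export
benchmark_config <- function(integral_source,
                             active_spaces,
                             ansatzes = c("v1", "v2", "v3", "v4", "v5", "uccsd"),
                             optimizer = optimizer_config()) {
  valid <- c("v1", "v2", "v3", "v4", "v5", "uccsd")
  bad <- setdiff(ansatzes, valid)
  if (length(bad) > 0L)
    stop("invalid ansatz label(s): ", paste(bad, collapse = ", "),
         "; valid labels are ", paste(valid, collapse = ", "))
  if (length(ansatzes) == 0L) stop("ansatz list must be non-empty")
  if (inherits(active_spaces, "active_space")) active_spaces <- list(active_spaces)
  if (length(active_spaces) == 0L) stop("active-space list must be non-empty")
  stopifnot(all(vapply(active_spaces, inherits, logical(1), "active_space")),
            inherits(optimizer, "optimizer_config"))
  structure(list(integral_source = integral_source,
                 active_spaces = active_spaces,
                 ansatzes = ansatzes,
                 optimizer = optimizer),
            class = "benchmark_config")
}

.resolve_integrals <- function(src) {
  if (inherits(src, "integral_set")) return(src)
  if (is.character(src) && length(src) == 1L) {
    if (src %in% c("h2", "syn3", "syn4", "syn6"))
      return(fixture_integrals(src))
    if (file.exists(src)) return(read_fcidump(src))
    stop("cannot resolve integral source '", src,
         "': not a known fixture name or an existing FCIDUMP path")
  }
  stop("integral_source must be an integral_set, fixture name, or FCIDUMP path")
}

.space_label <- function(space) sprintf("%d Orbitals", space$n_active_orbitals)

#' Run the benchmark matrix
#'
#' For each active space: builds the active-space qubit Hamiltonian,
#' computes the FCI and CISD reference energies by determinant CI, and
#' runs a VQE minimization for each requested ansatz.  Hardware-efficient
#' ansatzes start from `|0...0>` with uniform-random parameter
#' initialization; UCCSD starts from the Hartree-Fock state (via its X
#' preparation layer) with zero initialization.  Per-row seeds are
#' derived deterministically from the optimizer seed, so a rerun with the
#' same configuration is bit-identical.  A failing row is recorded (with
#' its error message) rather than aborting the matrix.
#'
#' @param cfg a [benchmark_config()].
#' @param verbose emit one summary line per row to stderr.
#' @return an object of class `benchmark_result`: `rows` (data.frame
#'   with ansatz, space, energy, steps, converged, error), `references`
#'   (data.frame with space, FCI, CISD), `trajectories` (named list of
#'   numeric vectors), `config`.
#' @export
run_benchmark <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "benchmark_config"))
  ints <- .resolve_integrals(cfg$integral_source)
  rows <- list(); refs <- list(); trajs <- list()
  row_id <- 0L
  for (si in seq_along(cfg$active_spaces)) {
    space <- cfg$active_spaces[[si]]
    space <- validate_active_space(space, ints$n_orbitals, ints$n_electrons)
    n_qubits <- qubit_requirement(space$n_active_orbitals)
    h <- jordan_wigner(build_fermionic_hamiltonian(ints, space))
    e_fci <- ci_ground_energy(ints, space, "FCI")
    e_cisd <- ci_ground_energy(ints, space, "CISD")
    refs[[si]] <- data.frame(space = .space_label(space),
                             FCI = e_fci, CISD = e_cisd,
                             stringsAsFactors = FALSE)
    for (ans in cfg$ansatzes) {
      row_id <- row_id + 1L
      seed_k <- (cfg$optimizer$seed + 1000L * row_id) %% 2147483647L
      res <- tryCatch({
        if (ans == "uccsd") {
          tpl <- build_uccsd(space$n_active_electrons, n_qubits)
          oc <- cfg$optimizer; oc$init_scheme <- "zeros"; oc$seed <- seed_k
          vqe_minimize(tpl, h, cfg = oc)
        } else {
          tpl <- build_hardware_efficient(ans, n_qubits)
          oc <- cfg$optimizer; oc$seed <- seed_k
          vqe_minimize(tpl, h, cfg = oc)
        }
      }, error = function(e) e)
      lab <- .space_label(space)
      if (inherits(res, "error")) {
        rows[[row_id]] <- data.frame(ansatz = ans, space = lab,
                                     energy = NA_real_, steps = NA_integer_,
                                     converged = NA,
                                     error = conditionMessage(res),
                                     stringsAsFactors = FALSE)
        if (verbose) message(sprintf("[%s | %s] FAILED: %s", ans, lab,
                                     conditionMessage(res)))
      } else {
        rows[[row_id]] <- data.frame(ansatz = ans, space = lab,
                                     energy = res$energy,
                                     steps = res$steps_to_convergence,
                                     converged = res$converged,
                                     error = NA_character_,
                                     stringsAsFactors = FALSE)
        trajs[[paste(ans, gsub(" ", "", lab), sep = "_")]] <- res$trajectory
        if (verbose)
          message(sprintf("[%s | %s] E = %.10f Ha in %d steps (FCI %.10f)",
                          ans, lab, res$energy, res$steps_to_convergence, e_fci))
      }
    }
  }
  structure(list(rows = do.call(rbind, rows),
                 references = do.call(rbind, refs),
                 trajectories = trajs,
                 config = cfg),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d rows, %d active space(s)\n",
              nrow(x$rows), nrow(x$references)))
  print(x$rows[, c("ansatz", "space", "energy", "steps", "converged")])
  invisible(x)
}

.num_fmt <- function(v) formatC(v, digits = 15, format = "g")

#' Write benchmark reports
#'
#' Emits into `output_dir`:
#'
#' * `energies.csv` — one row per ansatz plus `CISD` and `FCI` reference
#'   rows, one column per active space (the converged-energy table
#'   shape);
#' * `steps.csv` — steps to convergence, ansatz rows by space columns;
#' * `trajectories/<ansatz>_<space>.csv` — per-step energies (omitted
#'   entirely when no trajectories exist);
#' * `run_meta.json` — configuration echo, seed and package version.
#'
#' @param result a [run_benchmark()] result.
#' @param output_dir directory (created if missing).
#' @return character vector of files written, invisibly.
#' @export
write_reports <- function(result, output_dir) {
  stopifnot(inherits(result, "benchmark_result"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create output directory ", output_dir)
  written <- character(0)

  spaces <- unique(result$rows$space)
  ansatzes <- unique(result$rows$ansatz)
  wide <- function(field) {
    m <- matrix(NA_real_, length(ansatzes), length(spaces),
                dimnames = list(ansatzes, spaces))
    for (i in seq_len(nrow(result$rows)))
      m[result$rows$ansatz[i], result$rows$space[i]] <- result$rows[[field]][i]
    m
  }
  e_wide <- wide("energy")
  ref <- result$references
  e_tab <- rbind(e_wide,
                 CISD = ref$CISD[match(spaces, ref$space)],
                 FCI = ref$FCI[match(spaces, ref$space)])
  e_df <- data.frame(ansatz = rownames(e_tab),
                     apply(e_tab, 2, .num_fmt),
                     check.names = FALSE, stringsAsFactors = FALSE)
  f <- file.path(output_dir, "energies.csv")
  utils::write.csv(e_df, f, row.names = FALSE, quote = FALSE)
  written <- c(written, f)

  s_wide <- wide("steps")
  s_df <- data.frame(ansatz = rownames(s_wide),
                     apply(s_wide, 2, function(v) as.integer(v)),
                     check.names = FALSE, stringsAsFactors = FALSE)
  f <- file.path(output_dir, "steps.csv")
  utils::write.csv(s_df, f, row.names = FALSE, quote = FALSE)
  written <- c(written, f)

  if (length(result$trajectories) > 0L) {
    tdir <- file.path(output_dir, "trajectories")
    dir.create(tdir, showWarnings = FALSE)
    for (nm in names(result$trajectories)) {
      tf <- file.path(tdir, paste0(nm, ".csv"))
      df <- data.frame(step = seq_along(result$trajectories[[nm]]) - 1L,
                       energy = .num_fmt(result$trajectories[[nm]]))
      utils::write.csv(df, tf, row.names = FALSE, quote = FALSE)
      written <- c(written, tf)
    }
  }

  cfg <- result$config
  meta <- list(
    package = "vqebench",
    version = as.character(utils::packageVersion("vqebench")),
    integral_source = if (inherits(cfg$integral_source, "integral_set"))
      "<in-memory integral_set>" else as.character(cfg$integral_source),
    ansatzes = cfg$ansatzes,
    active_spaces = lapply(cfg$active_spaces, function(s)
      list(n_active_electrons = s$n_active_electrons,
           n_active_orbitals = s$n_active_orbitals,
           n_core_orbitals = s$n_core_orbitals,
           active_orbital_indices = s$active_orbital_indices)),
    optimizer = unclass(cfg$optimizer))
  f <- file.path(output_dir, "run_meta.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, f)
  invisible(written)
}

#' Read benchmark reports back
#'
#' Parses the CSV files written by [write_reports()] into the same row /
#' reference structure (trajectories included when present), enabling
#' round-trip checks and downstream plotting.
#'
#' @param output_dir directory previously passed to [write_reports()].
#' @return a `benchmark_result`-shaped list (without the live config).
#' @export
read_reports <- function(output_dir) {
  e_df <- utils::read.csv(file.path(output_dir, "energies.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  s_df <- utils::read.csv(file.path(output_dir, "steps.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  spaces <- setdiff(names(e_df), "ansatz")
  ansatzes <- setdiff(e_df$ansatz, c("CISD", "FCI"))
  rows <- list(); k <- 0L
  for (sp in spaces) for (an in ansatzes) {
    k <- k + 1L
    rows[[k]] <- data.frame(
      ansatz = an, space = sp,
      energy = as.numeric(e_df[e_df$ansatz == an, sp]),
      steps = as.integer(s_df[s_df$ansatz == an, sp]),
      stringsAsFactors = FALSE)
  }
  refs <- data.frame(space = spaces,
                     FCI = as.numeric(unlist(e_df[e_df$ansatz == "FCI", spaces])),
                     CISD = as.numeric(unlist(e_df[e_df$ansatz == "CISD", spaces])),
                     stringsAsFactors = FALSE)
  trajs <- list()
  tdir <- file.path(output_dir, "trajectories")
  if (dir.exists(tdir)) {
    for (tf in list.files(tdir, pattern = "\\.csv$", full.names = TRUE)) {
      nm <- sub("\\.csv$", "", basename(tf))
      trajs[[nm]] <- utils::read.csv(tf)$energy
    }
  }
  structure(list(rows = do.call(rbind, rows), references = refs,
                 trajectories = trajs, config = NULL),
            class = "benchmark_result")
}
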