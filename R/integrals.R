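#' Molecular integral sets
#'
#' An `integral_set` holds the electronic-structure input to everything
#' downstream: the scalar core (nuclear-repulsion plus any pre-folded)
#' energy, the one-electron integrals `<i|h|j>` over spatial orbitals, and
#' the two-electron integrals in **chemists' notation** `(ij|kl)`, all in
#' Hartree.  The one-body matrix must be symmetric and the two-body array
#' must obey the 8-fold real permutational symmetry
#' `(ij|kl) = (ji|kl) = (ij|lk) = (kl|ij) = ...` to 1e-10.
#'
#' @param n_orbitals number of spatial orbitals.
#' @param n_electrons number of electrons.
#' @param core_energy scalar constant energy (Hartree).
#' @param one_body `n x n` symmetric matrix (Hartree).
#' @param two_body `n x n x n x n` array, chemists' notation (Hartree).
#' @return an object of class `integral_set`.
#' @export
integral_set <- function(n_orbitals, n_electrons, core_energy, one_body, two_body) {
  n <- as.integer(n_orbitals)
  ne <- as.integer(n_electrons)
  stopifnot(n >= 1L, ne >= 0L, ne <= 2L * n)
  one_body <- as.matrix(one_body)
  if (!identical(dim(one_body), c(n, n)))
    stop("one_body must be ", n, " x ", n)
  if (max(abs(one_body - t(one_body))) > 1e-10)
    stop("one_body matrix is not symmetric")
  if (!identical(dim(two_body), rep(n, 4L)))
    stop("two_body must be ", n, "^4")
  dev <- .two_body_symmetry_deviation(two_body)
  if (dev > 1e-10)
    stop("two_body integrals violate 8-fold permutational symmetry (max dev ",
         format(dev), ")")
  structure(list(n_orbitals = n, n_electrons = ne,
                 core_energy = as.numeric(core_energy),
                 one_body = one_body, two_body = two_body,
                 convention = "chemists"),
            class = "integral_set")
}

#' @export
print.integral_set <- function(x, ...) {
  cat(sprintf("<integral_set> %d spatial orbitals, %d electrons, core %.8f Ha\n",
              x$n_orbitals, x$n_electrons, x$core_energy))
  invisible(x)
}

.two_body_perms <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3),
                        c(2, 1, 4, 3), c(3, 4, 1, 2), c(4, 3, 1, 2),
                        c(3, 4, 2, 1), c(4, 3, 2, 1))

.two_body_symmetry_deviation <- function(g) {
  dev <- 0
  for (p in .two_body_perms[-1])
    dev <- max(dev, max(abs(g - aperm(g, p))))
  dev
}

.two_body_symmetrize <- function(g) {
  acc <- g
  for (p in .two_body_perms[-1]) acc <- acc + aperm(g, p)
  acc / 8
}

#' Read an FCIDUMP integral file
#'
#' Parses the conventional FCIDUMP interchange format: a `&FCI`
#' namelist header carrying at least `NORB` and `NELEC` (terminated by
#' `&END` or `/`), followed by free-format records `value i j k l` with
#' 1-based indices.  Records are classified by their zero pattern:
#' all-zero indices give the core energy, `i j 0 0` the one-body
#' integrals, and four nonzero indices the two-body integrals `(ij|kl)`
#' in chemists' notation.  Each stored value is expanded to its full
#' permutational-symmetry orbit.
#'
#' @param path path to an FCIDUMP file (or a connection-readable file).
#' @return an [integral_set()].
#' @export
read_fcidump <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # --- header ---
  hstart <- grep("^\\s*&FCI", lines)
  if (length(hstart) == 0L) stop("FCIDUMP header error: no &FCI namelist")
  hend <- grep("(&END|/)\\s*$", lines)
  hend <- hend[hend >= hstart[1]][1]
  if (is.na(hend)) stop("FCIDUMP header error: unterminated namelist")
  header <- paste(lines[hstart[1]:hend], collapse = " ")
  header <- sub("^\\s*&FCI", "", header)
  header <- sub("(&END|/)\\s*$", "", header)
  get_field <- function(name) {
    m <- regmatches(header,
                    regexpr(paste0(name, "\\s*=\\s*-?[0-9]+"), header, ignore.case = TRUE))
    if (length(m) == 0L) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  norb <- get_field("NORB")
  nelec <- get_field("NELEC")
  if (is.na(norb)) stop("FCIDUMP header error: missing NORB")
  if (is.na(nelec)) stop("FCIDUMP header error: missing NELEC")

  body <- lines[-(hstart[1]:hend)]
  toks <- strsplit(trimws(body), "\\s+")
  bad <- lengths(toks) != 5L
  if (any(bad)) stop("malformed FCIDUMP record: '", body[which(bad)[1]], "'")
  vals <- as.numeric(vapply(toks, `[[`, "", 1L))
  idx <- matrix(as.integer(unlist(lapply(toks, `[`, 2:5))),
                ncol = 4L, byrow = TRUE)
  if (any(is.na(vals)) || any(is.na(idx)))
    stop("malformed numeric field in FCIDUMP record")
  if (any(idx > norb))
    stop("FCIDUMP index out of range: index exceeds NORB = ", norb)
  if (any(idx < 0L)) stop("FCIDUMP indices must be >= 0")

  core <- 0
  h1 <- matrix(0, norb, norb)
  g2 <- array(0, dim = rep(norb, 4L))
  for (r in seq_along(vals)) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]; l <- idx[r, 4]
    if (i == 0L && j == 0L && k == 0L && l == 0L) {
      core <- vals[r]
    } else if (k == 0L && l == 0L) {
      if (i == 0L || j == 0L) stop("malformed one-body record indices")
      h1[i, j] <- vals[r]; h1[j, i] <- vals[r]
    } else {
      if (any(c(i, j, k, l) == 0L)) stop("malformed two-body record indices")
      for (p in .two_body_perms) {
        q <- c(i, j, k, l)[p]
        g2[q[1], q[2], q[3], q[4]] <- vals[r]
      }
    }
  }
  integral_set(norb, nelec, core, h1, g2)
}

#' Write an FCIDUMP integral file
#'
#' Inverse of [read_fcidump()]: writes one record per
#' permutational-symmetry-unique integral.  Round-tripping reproduces the
#' integral set to full double precision.
#'
#' @param ints an [integral_set()].
#' @param path output file path.
#' @param ms2 twice the spin projection written to the header (default 0).
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(ints, path, ms2 = 0L) {
  stopifnot(inherits(ints, "integral_set"))
  n <- ints$n_orbitals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", n, ints$n_electrons, ms2), con)
  writeLines(sprintf(" ORBSYM=%s", paste(rep("1,", n), collapse = "")), con)
  writeLines(" ISYM=1,", con)
  writeLines("&END", con)
  fmt <- function(v, i, j, k, l) sprintf("%23.16e %3d %3d %3d %3d", v, i, j, k, l)
  out <- character(0)
  for (i in 1:n) for (j in 1:i) {
    ij <- (i - 1L) * i / 2L + j
    for (k in 1:i) for (l in 1:k) {
      kl <- (k - 1L) * k / 2L + l
      if (kl > ij) next
      v <- ints$two_body[i, j, k, l]
      if (v != 0) out <- c(out, fmt(v, i, j, k, l))
    }
  }
  for (i in 1:n) for (j in 1:i)
    if (ints$one_body[i, j] != 0)
      out <- c(out, fmt(ints$one_body[i, j], i, j, 0L, 0L))
  out <- c(out, fmt(ints$core_energy, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(path)
}

#' Synthetic molecular integral sets
#'
#' Generates a deterministic pseudo-random integral set emulating a
#' HOMO/LUMO-centred active space: one-body diagonal energies straddle the
#' Fermi level (occupied orbitals drawn in -2..-1.2 Ha, virtuals in
#' 0.9..1.6 Ha), off-diagonal one-body couplings and two-body fluctuations
#' sit two orders below the gap, and a symmetric Coulomb-like ridge
#' `(ii|jj) ~ 0.1 Ha` keeps electron addition/removal energetically
#' unfavourable, as for a real neutral molecule.  The two-body array is
#' exactly 8-fold symmetric and the output is reproducible in `seed`.
#'
#' @param n_orbitals number of spatial orbitals.
#' @param n_electrons number of electrons (`<= 2*n_orbitals`).
#' @param seed integer seed.
#' @return an [integral_set()].
#' @export
random_integral_set <- function(n_orbitals, n_electrons, seed = 1L) {
  n <- as.integer(n_orbitals)
  ne <- as.integer(n_electrons)
  stopifnot(n >= 1L, ne >= 0L, ne <= 2L * n)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  nocc <- (ne + 1L) %/% 2L
  eps <- sort(c(stats::runif(nocc, -2, -1.2),
                stats::runif(n - nocc, 0.9, 1.6)))
  off <- matrix(stats::rnorm(n * n, 0, 0.02), n, n)
  h1 <- diag(eps, n) + (off + t(off)) / 2 * (1 - diag(n))
  g <- array(stats::rnorm(n^4, 0, 0.01), dim = rep(n, 4L))
  g <- .two_body_symmetrize(g)
  coul <- matrix(stats::runif(n * n, 0.06, 0.12), n, n)
  coul <- (coul + t(coul)) / 2
  for (i in 1:n) for (j in 1:n) g[i, i, j, j] <- g[i, i, j, j] + coul[i, j]
  core <- stats::runif(1, 0, 1)
  integral_set(n, ne, core, h1, g)
}

#' Packaged integral fixtures
#'
#' Named small integral sets used throughout the tests and the benchmark
#' CLI.  `"h2"` is molecular hydrogen in STO-3G at 0.7414 Angstrom bond
#' length (restricted Hartree-Fock molecular-orbital integrals, read from
#' the packaged FCIDUMP).  The `"syn*"` fixtures are synthetic
#' [random_integral_set()] systems with fixed seeds: `syn3` a 3-orbital /
#' 4-electron system, `syn4` a 4-orbital / 4-electron system, `syn6` a
#' 6-orbital / 6-electron system.
#'
#' @param name one of `"h2"`, `"syn3"`, `"syn4"`, `"syn6"`.
#' @return an [integral_set()].
#' @export
fixture_integrals <- function(name = c("h2", "syn3", "syn4", "syn6")) {
  name <- match.arg(name)
  switch(name,
    h2 = read_fcidump(system.file("extdata", "h2_sto3g.fcidump",
                                  package = "vqebench", mustWork = TRUE)),
    syn3 = random_integral_set(3L, 4L, seed = 101L),
    syn4 = random_integral_set(4L, 4L, seed = 202L),
    syn6 = random_integral_set(6L, 6L, seed = 303L))
}
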