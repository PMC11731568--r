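# Deterministic synthetic-structure generators, so every module is
# testable without a download, plus the optional accession fetcher.
#
# Fixtures mimic only the naming and topology the selectors and filters
# need (CA traces, a macrocycle with a tail of named carbons); they are
# not chemically realistic.

#' Synthetic helical protein fixture
#'
#' An ideal-helix C-alpha trace (rise 1.5 A, 100 degree turn, radius
#' 2.3 A by default) with a repeating GLY/ALA/TRP residue pattern,
#' returned as PDB text.  `sigma > 0` adds seeded Gaussian coordinate
#' noise; with `sigma = 0` the output is independent of `seed` and
#' byte-identical across calls.
#'
#' @param n_residues Number of residues (one CA atom each).
#' @param seed RNG seed for the optional jitter.
#' @param sigma Jitter standard deviation in Angstrom.
#' @param rise,turn,radius Helix geometry (Angstrom, degrees, Angstrom).
#' @param chain Chain identifier.
#' @return A single character string of PDB ATOM records.
#' @export
make_toy_protein <- function(n_residues, seed = 1, sigma = 0,
                             rise = 1.5, turn = 100, radius = 2.3,
                             chain = "A") {
  stopifnot(n_residues >= 1)
  i <- seq_len(n_residues) - 1
  ang <- i * turn * pi / 180
  X <- cbind(radius * cos(ang), radius * sin(ang), rise * i)
  if (sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    X <- X + matrix(stats::rnorm(length(X), sd = sigma), ncol = 3)
  }
  resn <- rep(c("GLY", "ALA", "TRP"), length.out = n_residues)
  lines <- vapply(seq_len(n_residues), function(k) {
    pdb_atom_line("ATOM", k, "CA", resn[k], chain, k,
                  X[k, 1], X[k, 2], X[k, 3], 1, "C")
  }, character(1))
  paste(c(lines, "END"), collapse = "\n")
}

#' Synthetic chlorophyll-like cofactor fixture
#'
#' A near-planar 25-heavy-atom macrocycle (central MG, four pyrrole
#' nitrogens NA..ND, twenty ring carbons named C1A..C5D) with an optional
#' 15-atom tail named C6..C20 extending beyond 20 A from MG, so the tail
#' filter and MaxDist bin overflow can be exercised.  Small deterministic
#' radial/axial ripples break exact symmetry so that no atom triple is
#' collinear.  `sigma > 0` adds seeded Gaussian noise.
#'
#' @param with_tail Include the C6..C20 tail atoms.
#' @param seed RNG seed for the optional jitter.
#' @param sigma Jitter standard deviation in Angstrom.
#' @param chain Chain identifier.
#' @param res_seq Ligand residue number.
#' @return A single character string of PDB HETATM records (res name
#'   `CLA`).
#' @export
make_toy_cofactor <- function(with_tail = TRUE, seed = 1, sigma = 0,
                              chain = "A", res_seq = 1011) {
  names_ring <- c("MG", paste0("N", c("A", "B", "C", "D")),
                  paste0("C", rep(1:5, 4), rep(c("A", "B", "C", "D"),
                                               each = 5)))
  k <- seq_along(names_ring)
  elem <- c("MG", rep("N", 4), rep("C", 20))
  ang <- c(0, (0:3) * pi / 2 + 0.12,
           (seq_len(20) - 1) * 2 * pi / 20 + 0.31)
  rad <- c(0, rep(2.05, 4), 3.4 + 0.08 * sin(3 * seq_len(20)))
  X <- cbind(rad * cos(ang), rad * sin(ang), 0.06 * sin(5 * k))
  nm <- names_ring
  if (with_tail) {
    tail_names <- paste0("C", 6:20)
    tx <- 4.6 + 1.45 * (seq_along(tail_names) - 1)
    Xt <- cbind(tx, 0.35 * sin(seq_along(tail_names)),
                0.25 * cos(2 * seq_along(tail_names)))
    X <- rbind(X, Xt)
    nm <- c(nm, tail_names)
    elem <- c(elem, rep("C", length(tail_names)))
  }
  if (sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    X <- X + matrix(stats::rnorm(length(X), sd = sigma), ncol = 3)
  }
  lines <- vapply(seq_along(nm), function(i) {
    pdb_atom_line("HETATM", i, nm[i], "CLA", chain, res_seq,
                  X[i, 1], X[i, 2], X[i, 3], 1, elem[i])
  }, character(1))
  paste(c(lines, "END"), collapse = "\n")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Jittered copies of a template selection
#'
#' Independent Gaussian perturbation of every coordinate (sd = `sigma`),
#' deterministic given `seed`.  Used to build families of near-identical
#' structures for clustering-recovery experiments.
#'
#' @param template A `tsr_selection`.
#' @param n_copies Number of copies.
#' @param sigma Coordinate noise sd in Angstrom (0 gives exact copies).
#' @param seed RNG seed.
#' @return List of `tsr_selection` objects; provenance roles are suffixed
#'   `_j1`, `_j2`, ...
#' @export
jitter_family <- function(template, n_copies, sigma, seed = 1) {
  stopifnot(inherits(template, "tsr_selection"), n_copies >= 1,
            sigma >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n_copies), function(i) {
    s <- template
    n <- nrow(s$atoms)
    if (sigma > 0) {
      noise <- matrix(stats::rnorm(3 * n, sd = sigma), ncol = 3)
      s$atoms$x <- s$atoms$x + noise[, 1]
      s$atoms$y <- s$atoms$y + noise[, 2]
      s$atoms$z <- s$atoms$z + noise[, 3]
    }
    s$provenance$role <- paste0(s$provenance$role, "_j", i)
    s
  })
}

#' Fetch a structure from the PDB by accession
#'
#' Downloads `https://files.rcsb.org/download/<ID>.pdb` into a cache
#' directory and returns the cached path; a second call is a cache hit
#' with no network access.  Network failures raise a clear error (no
#' silent retries).
#'
#' @param accession 4-character PDB accession.
#' @param cache_dir Cache directory (created if needed).
#' @return Path to the cached PDB file.
#' @export
fetch_structure <- function(accession,
                            cache_dir = file.path(tempdir(),
                                                  "tsrkeys_cache")) {
  accession <- toupper(accession)
  if (!grepl("^[0-9][A-Z0-9]{3}$", accession)) {
    stop("not a valid PDB accession: ", accession, call. = FALSE)
  }
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(accession, ".pdb"))
  if (file.exists(dest)) return(dest)
  url <- paste0("https://files.rcsb.org/download/", accession, ".pdb")
  ok <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
    error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("could not fetch ", accession, " from the PDB ",
         "(network unavailable or unknown accession)", call. = FALSE)
  }
  dest
}
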