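# Baseline comparators: ultrafast shape recognition (USR) descriptors and
# optimal-superposition (Kabsch) RMSD.

#' Ultrafast shape recognition descriptors
#'
#' Twelve numbers: the first three moments (mean, standard deviation and
#' signed cube root of the third central moment) of the atom-distance
#' distributions about four reference points — the molecular centroid
#' (ctd), the atom closest to ctd (cst), the atom farthest from ctd
#' (fct) and the atom farthest from fct (ftf).  Invariant under rigid
#' motion.  Ties for cst/fct/ftf are broken by input order; zero-variance
#' distributions give sd 0 and skew term 0 (population moments).
#'
#' @param selection A `tsr_selection`, or an n x 3 coordinate matrix.
#' @return Numeric vector of length 12, named
#'   `ctd_mu1..ctd_mu3, cst_mu1.., fct_mu1.., ftf_mu1..`.
#' @export
usr_descriptors <- function(selection) {
  X <- selection_coords(selection)
  if (nrow(X) < 2) stop("need at least 2 atoms", call. = FALSE)
  dist_to <- function(p) sqrt(rowSums(sweep(X, 2, p)^2))
  ctd <- colMeans(X)
  d_ctd <- dist_to(ctd)
  cst <- X[which.min(d_ctd), ]
  fct <- X[which.max(d_ctd), ]
  d_fct <- dist_to(fct)
  ftf <- X[which.max(d_fct), ]
  moments <- function(d) {
    mu <- mean(d)
    m2 <- mean((d - mu)^2)
    m3 <- mean((d - mu)^3)
    c(mu, sqrt(m2), sign(m3) * abs(m3)^(1 / 3))
  }
  out <- c(moments(d_ctd), moments(dist_to(cst)),
           moments(dist_to(fct)), moments(dist_to(ftf)))
  names(out) <- paste0(rep(c("ctd", "cst", "fct", "ftf"), each = 3),
                       "_mu", rep(1:3, 4))
  out
}

#' USR similarity score
#'
#' Inverse scaled Manhattan distance between two 12-component USR
#' descriptors: `1 / (1 + mean(|d1 - d2|))`, in `(0, 1]` with 1 iff the
#' descriptors are equal.
#'
#' @param d1,d2 Length-12 descriptor vectors from [usr_descriptors()].
#' @return Similarity in `(0, 1]`.
#' @export
usr_similarity <- function(d1, d2) {
  stopifnot(length(d1) == 12, length(d2) == 12)
  1 / (1 + mean(abs(d1 - d2)))
}

selection_coords <- function(x) {
  if (inherits(x, "tsr_selection")) {
    as.matrix(x$atoms[, c("x", "y", "z")])
  } else {
    X <- as.matrix(x)
    stopifnot(ncol(X) == 3)
    X
  }
}

# Kabsch: minimal RMSD over proper rotations + translation for paired
# coordinate sets (rows correspond).
kabsch_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(P, Q))          # H = P^T Q
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diffs <- Q - P %*% t(R)
  sqrt(mean(rowSums(diffs^2)))
}

#' Minimal RMSD after optimal superposition
#'
#' Superposes `b` onto `a` with the optimal proper rotation and
#' translation (Kabsch) and returns the minimised root-mean-square
#' distance.  Atom correspondence:
#' * `"name"` (default): pair atoms by `atom_name` (exact for chemically
#'   identical cofactors/residues); duplicate or unmatched names are an
#'   error listing the mismatch.
#' * `"order"`: pair by position.
#' * `"permutation"`: search all one-to-one matchings (n <= 8 atoms) and
#'   return the global minimum; intended as a small-n oracle.
#'
#' @param a,b `tsr_selection` objects or n x 3 coordinate matrices.
#' @param correspondence `"name"`, `"order"` or `"permutation"`.
#' @return RMSD in Angstrom.
#' @export
rmsd_superposed <- function(a, b,
                            correspondence = c("name", "order",
                                               "permutation")) {
  correspondence <- match.arg(correspondence)
  A <- selection_coords(a)
  B <- selection_coords(b)
  if (correspondence == "name") {
    if (!inherits(a, "tsr_selection") || !inherits(b, "tsr_selection")) {
      stop("name correspondence needs selections with atom names",
           call. = FALSE)
    }
    na <- a$atoms$atom_name
    nb <- b$atoms$atom_name
    if (anyDuplicated(na) || anyDuplicated(nb)) {
      stop("duplicate atom names (",
           paste(unique(c(na[duplicated(na)], nb[duplicated(nb)])),
                 collapse = ", "),
           "); use correspondence = \"order\"", call. = FALSE)
    }
    if (!setequal(na, nb)) {
      stop("atom name mismatch: only in a: ",
           paste(setdiff(na, nb), collapse = ", "),
           "; only in b: ", paste(setdiff(nb, na), collapse = ", "),
           call. = FALSE)
    }
    B <- B[match(na, nb), , drop = FALSE]
    return(kabsch_rmsd(A, B))
  }
  if (nrow(A) != nrow(B)) {
    stop("atom count mismatch: ", nrow(A), " vs ", nrow(B), call. = FALSE)
  }
  if (correspondence == "order") return(kabsch_rmsd(A, B))
  n <- nrow(A)
  if (n > 8) {
    stop("permutation search limited to 8 atoms (", n, " given)",
         call. = FALSE)
  }
  perms <- all_permutations(n)
  min(vapply(seq_len(nrow(perms)), function(i) {
    kabsch_rmsd(A, B[perms[i, ], , drop = FALSE])
  }, numeric(1)))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
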