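# Cofactor local-environment statistics: inter-cofactor distances,
# contact residues within a cutoff, aromatic content and chain
# composition.  Heavy atoms only throughout.

AROMATIC_AA <- c("PHE", "TYR", "TRP")

#' Shortest distance between two selections
#'
#' Minimum Euclidean distance over all cross atom pairs.
#'
#' @param a,b `tsr_selection` objects or coordinate matrices.
#' @return Distance in Angstrom.
#' @export
min_distance <- function(a, b) {
  A <- selection_coords(a)
  B <- selection_coords(b)
  sqrt(max(0, min_sqdist(A, B)))
}

min_sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  min(d2)
}

#' Residues in contact with a cofactor
#'
#' Standard amino-acid residues of the model with any heavy atom within
#' `cutoff` of any heavy atom of the cofactor; waters are reported
#' separately.  The per-residue minimum atom distance is recorded.
#'
#' @param model A `tsr_structure`.
#' @param cofactor A `tsr_selection` (typically from [select_cofactor()]).
#' @param cutoff Contact cutoff in Angstrom (default 3.5).
#' @param include_waters Report water contacts in a `waters` table.
#' @return Object of class `tsr_contacts`: list with `role`, `cutoff`,
#'   `contacts` (chain, res_seq, res_name, min_dist), `aromatic_count`,
#'   `aromatic_fraction`, `n_contacts`, and optionally `waters`.
#' @export
contact_residues <- function(model, cofactor, cutoff = 3.5,
                             include_waters = FALSE) {
  stopifnot(inherits(model, "tsr_structure"),
            inherits(cofactor, "tsr_selection"))
  at <- model$atoms
  if (nrow(at) == 0) stop("empty model", call. = FALSE)
  C <- selection_coords(cofactor)
  prot <- at[!at$is_water & at$res_name %in% STANDARD_AA &
               !is_hydrogen(at), , drop = FALSE]
  contacts <- residue_contact_table(prot, C, cutoff)
  aromatic <- sum(contacts$res_name %in% AROMATIC_AA)
  res <- list(
    role = cofactor$provenance$role,
    cutoff = cutoff,
    contacts = contacts,
    n_contacts = nrow(contacts),
    aromatic_count = aromatic,
    aromatic_fraction = if (nrow(contacts) == 0) 0
      else aromatic / nrow(contacts),
    no_contacts = nrow(contacts) == 0
  )
  if (include_waters) {
    wat <- at[at$is_water & !is_hydrogen(at), , drop = FALSE]
    res$waters <- residue_contact_table(wat, C, cutoff)
  }
  structure(res, class = "tsr_contacts")
}

residue_contact_table <- function(atoms, C, cutoff) {
  empty <- data.frame(chain = character(), res_seq = integer(),
                      res_name = character(), min_dist = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(atoms) == 0 || cutoff <= 0) return(empty)
  P <- as.matrix(atoms[, c("x", "y", "z")])
  # per protein atom, squared distance to the nearest cofactor atom
  d2 <- outer(rowSums(P^2), rowSums(C^2), "+") - 2 * P %*% t(C)
  dmin <- sqrt(pmax(0, apply(d2, 1, min)))
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$res_name, sep = "\r")
  per_res <- tapply(dmin, key, min)
  hit <- per_res[per_res <= cutoff]
  if (length(hit) == 0) return(empty)
  parts <- strsplit(names(hit), "\r", fixed = TRUE)
  out <- data.frame(
    chain = vapply(parts, `[`, "", 1),
    res_seq = as.integer(vapply(parts, `[`, "", 2)),
    res_name = vapply(parts, `[`, "", 3),
    min_dist = as.numeric(hit),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chain, out$res_seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.tsr_contacts <- function(x, ...) {
  cat("tsr_contacts [", if (is.null(x$role)) "?" else x$role, "] ",
      x$n_contacts, " residues within ", x$cutoff, " A (",
      x$aromatic_count, " aromatic)\n", sep = "")
  invisible(x)
}

#' Aromatic count and fraction of a contact report
#'
#' Aromatic residues are PHE, TYR and TRP.  With no contacts the fraction
#' is reported as 0 alongside the `no_contacts` flag.
#'
#' @param report A `tsr_contacts` from [contact_residues()].
#' @return Named list `count`, `fraction`, `no_contacts`.
#' @export
aromatic_stats <- function(report) {
  stopifnot(inherits(report, "tsr_contacts"))
  list(count = report$aromatic_count,
       fraction = report$aromatic_fraction,
       no_contacts = report$no_contacts)
}

#' Amino-acid composition of a chain
#'
#' @param model A `tsr_structure`.
#' @param chain Chain identifier.
#' @return Data frame with `res_name`, `count` and `fraction` over the 20
#'   standard residues (fractions sum to 1).
#' @export
chain_composition <- function(model, chain) {
  at <- model$atoms
  prot <- at[!at$het & !at$is_water & at$chain_id == chain &
               at$res_name %in% STANDARD_AA, , drop = FALSE]
  if (nrow(prot) == 0) {
    stop("no standard residues in chain ", chain, call. = FALSE)
  }
  res <- unique(prot[, c("res_seq", "res_name")])
  counts <- table(factor(res$res_name, levels = STANDARD_AA))
  data.frame(res_name = STANDARD_AA,
             count = as.integer(counts),
             fraction = as.numeric(counts) / sum(counts),
             stringsAsFactors = FALSE)
}
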