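# Triangle enumeration, geometry, vertex ordering and integer key encoding.
#
# A molecule is represented by the multiset of keys over all C(n,3) atom
# triangles.  Each triangle contributes one key built from its ordered
# vertex labels, the binned longest edge (MaxDist) and the binned midpoint
# angle (Theta).

DEGENERATE_EPS <- 1e-6

#' Order the three vertices of a labeled triangle
#'
#' Rule-based ordering making key assignment deterministic and invariant
#' to input order and rigid motion: vertices are sorted by descending
#' integer label; ties among equal labels are broken by descending
#' distance to the triangle centroid; residual ties by ascending input
#' index.
#'
#' @param points 3 x 3 numeric matrix, one vertex per row.
#' @param labels Integer vector of length 3.
#' @return List with `order` (permutation of 1:3) and `labels` (the
#'   ordered labels `(l1, l2, l3)`).
#' @export
label_vertices <- function(points, labels) {
  stopifnot(is.matrix(points), nrow(points) == 3, ncol(points) == 3,
            length(labels) == 3)
  ctr <- colMeans(points)
  cd <- sqrt(rowSums(sweep(points, 2, ctr)^2))
  ord <- order(-as.integer(labels), -cd, seq_len(3L))
  list(order = ord, labels = as.integer(labels)[ord])
}

#' Longest edge and midpoint angle of an ordered triangle
#'
#' `maxdist` is the longest of the three edges.  `theta` is the angle at
#' the midpoint of the l1-l2 edge between the median to l3 and the
#' half-edge towards l2; obtuse values are replaced by their supplement so
#' that theta lies in (0, 90] degrees.
#'
#' @param points 3 x 3 numeric matrix in `(l1, l2, l3)` row order.
#' @return List with `maxdist` (Angstrom) and `theta` (degrees), or
#'   `NULL` for a degenerate triangle (coincident points, or l3 collinear
#'   with the l1-l2 edge).
#' @export
triangle_geometry <- function(points) {
  stopifnot(is.matrix(points), nrow(points) == 3, ncol(points) == 3)
  d12 <- sqrt(sum((points[1, ] - points[2, ])^2))
  d13 <- sqrt(sum((points[1, ] - points[3, ])^2))
  d23 <- sqrt(sum((points[2, ] - points[3, ])^2))
  if (min(d12, d13, d23) < DEGENERATE_EPS) return(NULL)
  mid <- (points[1, ] + points[2, ]) / 2
  v1 <- points[3, ] - mid
  v2 <- points[2, ] - mid
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 < DEGENERATE_EPS || n2 < DEGENERATE_EPS) return(NULL)
  cosang <- max(-1, min(1, sum(v1 * v2) / (n1 * n2)))
  ang <- acos(cosang) * 180 / pi
  theta <- if (ang > 90) 180 - ang else ang
  if (theta < 1e-9) return(NULL)  # collinear
  list(maxdist = max(d12, d13, d23), theta = theta)
}

#' Encode a labeled, binned triangle as one integer key
#'
#' Mixed-radix encoding over the tuple space `(l1, l2, l3, theta_bin,
#' dist_bin)`:
#' `key = ((l1-1) m^2 + (l2-1) m + (l3-1)) (nt nd) + (theta_bin-1) nd +
#' (dist_bin-1)`
#' with `m` labels, `nt` theta bins and `nd` distance bins.  The encoding
#' is injective over the valid tuple space and inverted exactly by
#' [decode_key()].
#'
#' @param l1,l2,l3 Ordered vertex labels (1..m).  Vectorised.
#' @param theta_bin,dist_bin 1-based bin indices.
#' @param config A [tsr_config()].
#' @return Non-negative numeric key(s).
#' @export
encode_key <- function(l1, l2, l3, theta_bin, dist_bin, config) {
  m <- config$m; nt <- config$n_theta; nd <- config$n_dist
  ok <- l1 >= 1 & l1 <= m & l2 >= 1 & l2 <= m & l3 >= 1 & l3 <= m &
    theta_bin >= 1 & theta_bin <= nt & dist_bin >= 1 & dist_bin <= nd
  if (!all(ok)) {
    stop("labels or bin indices out of configured range", call. = FALSE)
  }
  ((l1 - 1) * m^2 + (l2 - 1) * m + (l3 - 1)) * (nt * nd) +
    (theta_bin - 1) * nd + (dist_bin - 1)
}

#' Decode an integer key back to its label/bin tuple
#'
#' @param key Numeric key(s) produced by [encode_key()].
#' @param config The same [tsr_config()] used to encode.
#' @return Data frame with columns `l1`, `l2`, `l3`, `theta_bin`,
#'   `dist_bin`.
#' @export
decode_key <- function(key, config) {
  m <- config$m; nt <- config$n_theta; nd <- config$n_dist
  if (any(key < 0) || any(key >= m^3 * nt * nd)) {
    stop("key outside the configured code space", call. = FALSE)
  }
  geom <- key %% (nt * nd)
  lab <- (key - geom) / (nt * nd)
  dist_bin <- geom %% nd
  theta_bin <- (geom - dist_bin) / nd
  l3 <- lab %% m
  lab <- (lab - l3) / m
  l2 <- lab %% m
  l1 <- (lab - l2) / m
  data.frame(l1 = l1 + 1, l2 = l2 + 1, l3 = l3 + 1,
             theta_bin = theta_bin + 1, dist_bin = dist_bin + 1)
}

# Integer vertex labels for a selection under a config; atoms whose label
# is not in the map are dropped with a warning (e.g. nonstandard residues
# in CA mode, exotic elements in COFACTOR mode).
selection_labels <- function(selection, config) {
  src <- switch(config$mode,
    CA = selection$atoms$res_name,
    toupper(selection$atoms$element))
  if (!is.null(config$grouping_map)) {
    hit <- src %in% names(config$grouping_map)
    src[hit] <- unname(config$grouping_map[src[hit]])
  }
  lab <- unname(config$label_map[src])
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " atom(s) with unmapped label (",
            paste(unique(src[is.na(lab)]), collapse = ", "),
            ") dropped from key generation", call. = FALSE)
  }
  lab
}

#' Generate TSR keys for a selection
#'
#' Enumerates all C(n,3) atom triples, orders and labels the vertices
#' ([label_vertices()]), computes and bins MaxDist and Theta
#' ([triangle_geometry()]), applies the optional size-gap cutoff and
#' encodes each surviving triangle as one integer key.  Degenerate
#' (collinear or coincident) triangles are skipped with a warning.
#'
#' @param selection A `tsr_selection` whose mode matches `config$mode`.
#' @param config A [tsr_config()].
#' @return List of class `tsr_keys` with
#'   * `key_vector`: a `tsr_keyvector` (key -> frequency);
#'   * `triplets`: one row per retained triangle (`v1`..`v3` vertex ids,
#'     `l1`..`l3` labels, `maxdist`, `theta`, `theta_bin`, `dist_bin`,
#'     `key`);
#'   * `n_skipped`: number of degenerate triangles dropped.
#' @export
generate_keys <- function(selection, config) {
  stopifnot(inherits(selection, "tsr_selection"),
            inherits(config, "tsr_config"))
  if (selection$mode != config$mode) {
    stop("selection mode ", selection$mode, " does not match config mode ",
         config$mode, call. = FALSE)
  }
  lab_all <- selection_labels(selection, config)
  keep <- !is.na(lab_all)
  atoms <- selection$atoms[keep, , drop = FALSE]
  lab <- lab_all[keep]
  n <- nrow(atoms)
  if (n < 3) stop("need at least 3 labeled atoms", call. = FALSE)

  X <- as.matrix(atoms[, c("x", "y", "z")])
  idx <- utils::combn(n, 3L)
  A <- X[idx[1L, ], , drop = FALSE]
  B <- X[idx[2L, ], , drop = FALSE]
  C <- X[idx[3L, ], , drop = FALSE]
  dAB <- sqrt(rowSums((A - B)^2))
  dAC <- sqrt(rowSums((A - C)^2))
  dBC <- sqrt(rowSums((B - C)^2))
  maxd <- pmax(dAB, dAC, dBC)
  mind <- pmin(dAB, dAC, dBC)

  ok <- mind >= DEGENERATE_EPS
  if (!is.null(config$size_gap_cutoff)) {
    ok <- ok & maxd <= config$size_gap_cutoff
  }

  # vertex ordering: label desc, centroid distance desc, input index asc
  G <- (A + B + C) / 3
  CD <- cbind(sqrt(rowSums((A - G)^2)),
              sqrt(rowSums((B - G)^2)),
              sqrt(rowSums((C - G)^2)))
  L <- cbind(lab[idx[1L, ]], lab[idx[2L, ]], lab[idx[3L, ]])
  N <- nrow(L)
  ord <- matrix(vapply(seq_len(N), function(i) {
    order(-L[i, ], -CD[i, ], seq_len(3L))
  }, integer(3)), nrow = N, byrow = TRUE)

  pick <- function(k, M1, M2, M3) {
    sel <- ord[, k]
    out <- M1
    out[sel == 2L, ] <- M2[sel == 2L, , drop = FALSE]
    out[sel == 3L, ] <- M3[sel == 3L, , drop = FALSE]
    out
  }
  P1 <- pick(1L, A, B, C)
  P2 <- pick(2L, A, B, C)
  P3 <- pick(3L, A, B, C)
  Lo <- matrix(L[cbind(rep(seq_len(N), 3L), as.vector(ord))], nrow = N)

  mid <- (P1 + P2) / 2
  v1 <- P3 - mid
  v2 <- P2 - mid
  n1 <- sqrt(rowSums(v1^2))
  n2 <- sqrt(rowSums(v2^2))
  ok <- ok & n1 >= DEGENERATE_EPS & n2 >= DEGENERATE_EPS
  cosang <- pmax(-1, pmin(1, rowSums(v1 * v2) / pmax(n1 * n2, 1e-300)))
  ang <- acos(cosang) * 180 / pi
  theta <- ifelse(ang > 90, 180 - ang, ang)
  degenerate <- !(mind >= DEGENERATE_EPS & n1 >= DEGENERATE_EPS &
                    n2 >= DEGENERATE_EPS) | theta < 1e-9
  ok <- ok & !degenerate
  n_skipped <- sum(degenerate)
  if (n_skipped > 0) {
    warning(n_skipped, " degenerate triangle(s) skipped", call. = FALSE)
  }
  if (!any(ok)) stop("no valid triangles survive filtering", call. = FALSE)

  tb <- bin_index(theta[ok], config$theta_bins)
  db <- bin_index(maxd[ok], config$dist_bins)
  keys <- encode_key(Lo[ok, 1L], Lo[ok, 2L], Lo[ok, 3L], tb, db, config)

  ids <- atom_ids(atoms)
  iord <- matrix(idx[cbind(as.vector(t(ord)),
                           rep(seq_len(N), each = 3L))],
                 nrow = N, byrow = TRUE)
  triplets <- data.frame(
    v1 = ids[iord[ok, 1L]], v2 = ids[iord[ok, 2L]], v3 = ids[iord[ok, 3L]],
    l1 = Lo[ok, 1L], l2 = Lo[ok, 2L], l3 = Lo[ok, 3L],
    maxdist = maxd[ok], theta = theta[ok],
    theta_bin = tb, dist_bin = db, key = keys,
    stringsAsFactors = FALSE
  )
  tab <- table(keys)
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  kv <- new_key_vector(counts, config, selection$provenance)
  structure(list(key_vector = kv, triplets = triplets,
                 n_skipped = n_skipped),
            class = "tsr_keys")
}

atom_ids <- function(atoms) {
  paste(atoms$chain_id, atoms$res_name, atoms$res_seq, atoms$atom_name,
        sep = "/")
}

#' Key-frequency vector constructor
#'
#' @param counts Named numeric vector, names are keys, values positive
#'   frequencies.
#' @param config The [tsr_config()] the keys were generated under.
#' @param provenance Provenance list (source, chain, span, role).
#' @return Object of class `tsr_keyvector` with fields `counts`, `mode`,
#'   `config_hash`, `provenance`.
#' @export
new_key_vector <- function(counts, config, provenance = list()) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  if (length(counts) == 0 || any(counts <= 0)) {
    stop("key vector must have positive frequencies", call. = FALSE)
  }
  counts <- counts[order(as.numeric(names(counts)))]
  structure(list(counts = counts, mode = config$mode,
                 config_hash = config$hash, provenance = provenance),
            class = "tsr_keyvector")
}

#' @export
print.tsr_keyvector <- function(x, ...) {
  cat("tsr_keyvector [", x$mode, "] ", length(x$counts),
      " distinct / ", sum(x$counts), " total keys  (",
      paste(unlist(x$provenance), collapse = " "), ")\n", sep = "")
  invisible(x)
}
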