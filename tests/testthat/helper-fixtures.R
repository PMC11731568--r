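# Shared fixture builders for the test suite.  Everything is generated
# in code; no binary data.

toy_cofactor_selection <- function(with_tail = TRUE, sigma = 0, seed = 1) {
  model <- read_structure(make_toy_cofactor(with_tail = with_tail,
                                            sigma = sigma, seed = seed))
  select_cofactor(model, list(pdb_id = "TOY", role = "toy_cofactor",
                              chain = "A", res_seq = 1011,
                              res_name = "CLA"))
}

toy_protein_selection <- function(n = 10, seed = 1, sigma = 0, ...) {
  model <- read_structure(make_toy_protein(n, seed = seed, sigma = sigma,
                                           ...))
  select_calpha(model, "A")
}

# apply a rigid motion (rotation about an arbitrary axis + translation)
rigid_motion <- function(selection, angle = 0.7,
                         axis = c(1, 2, 3), shift = c(5, -3, 9)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  X <- as.matrix(selection$atoms[, c("x", "y", "z")]) %*% t(R)
  selection$atoms$x <- X[, 1] + shift[1]
  selection$atoms$y <- X[, 2] + shift[2]
  selection$atoms$z <- X[, 3] + shift[3]
  selection
}

shuffle_atoms <- function(selection, seed = 42) {
  set.seed(seed)
  selection$atoms <- selection$atoms[sample(nrow(selection$atoms)), ,
                                     drop = FALSE]
  rownames(selection$atoms) <- NULL
  selection
}

# random key vector over a small key universe, for property tests
random_key_vector <- function(config, n_keys = 8, max_key = 40,
                              max_freq = 5) {
  keys <- sample.int(max_key, n_keys)
  counts <- as.numeric(sample.int(max_freq, n_keys, replace = TRUE))
  names(counts) <- as.character(keys)
  new_key_vector(counts, config)
}

# a single TRP residue with its full 14-heavy-atom inventory (idealised
# planar-ish coordinates; geometry is irrelevant to the selection tests)
toy_trp_pdb <- function() {
  atoms <- c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1",
             "CE2", "CE3", "CZ2", "CZ3", "CH2")
  elem <- substr(atoms, 1, 1)
  set.seed(7)
  X <- matrix(runif(length(atoms) * 3, -3, 3), ncol = 3)
  lines <- vapply(seq_along(atoms), function(i) {
    tsrkeys:::pdb_atom_line("ATOM", i, atoms[i], "TRP", "A", 42,
                            X[i, 1], X[i, 2], X[i, 3], 1, elem[i])
  }, character(1))
  paste(c(lines, "END"), collapse = "\n")
}

toy_gly_pdb <- function() {
  atoms <- c("N", "CA", "C", "O")
  X <- rbind(c(0, 0, 0), c(1.5, 0.2, 0), c(2.1, 1.4, 0.5),
             c(3.2, 1.5, 1.1))
  lines <- vapply(seq_along(atoms), function(i) {
    tsrkeys:::pdb_atom_line("ATOM", i, atoms[i], "GLY", "A", 7,
                            X[i, 1], X[i, 2], X[i, 3], 1,
                            substr(atoms[i], 1, 1))
  }, character(1))
  paste(c(lines, "END"), collapse = "\n")
}

# brute-force UPGMA over a small distance matrix: returns merge heights
brute_upgma_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}

# brute-force adjusted Rand index by explicit pair enumeration
brute_ari <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  total <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / total
  maximum <- ((n11 + n10) + (n11 + n01)) / 2
  if (maximum == expected) return(1)
  (n11 - expected) / (maximum - expected)
}
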