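test_that("vertex ordering follows label, centroid distance, input index", {
  # plain label sort
  pts <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  res <- label_vertices(pts, c(2, 5, 1))
  expect_equal(res$labels, c(5, 2, 1))
  expect_equal(res$order, c(2, 1, 3))
  # tie among equal labels -> farther from centroid first
  pts2 <- rbind(c(4, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  cd <- sqrt(rowSums(sweep(pts2, 2, colMeans(pts2))^2))
  expect_gt(cd[1], cd[2])
  res2 <- label_vertices(pts2, c(3, 3, 1))
  expect_equal(res2$order, c(1, 2, 3))
  res2b <- label_vertices(pts2[c(2, 1, 3), ], c(3, 3, 1))
  expect_equal(res2b$order, c(2, 1, 3))  # same winner after swapping rows
  # all equal labels on an equilateral triangle -> input order preserved
  eq <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0))
  res3 <- label_vertices(eq, c(4, 4, 4))
  expect_equal(res3$order, 1:3)
})

test_that("triangle geometry matches analytic values and flags degeneracy", {
  g <- triangle_geometry(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)))
  expect_equal(g$maxdist, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(g$theta, atan2(2, 1) * 180 / pi, tolerance = 1e-9)  # 63.435
  eqg <- triangle_geometry(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)))
  expect_equal(eqg$theta, 90, tolerance = 1e-9)
  expect_equal(eqg$maxdist, 2, tolerance = 1e-12)
  expect_null(triangle_geometry(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0))))
  expect_null(triangle_geometry(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0))))
  # collinear but l3 away from the midpoint is still degenerate
  expect_null(triangle_geometry(rbind(c(0, 0, 0), c(2, 0, 0), c(5, 0, 0))))
})

test_that("key encoding is the documented mixed-radix code and inverts", {
  cfg <- tsr_config("COFACTOR", label_map = c(A = 1, B = 2, C = 3,
                                              D = 4, E = 5))
  expect_equal(encode_key(1, 1, 1, 1, 1, cfg), 0)
  expect_equal(encode_key(3, 2, 1, 5, 7, cfg), 28124)
  expect_error(encode_key(6, 1, 1, 1, 1, cfg), "out of configured range")
  expect_error(decode_key(cfg$m^3 * cfg$n_theta * cfg$n_dist, cfg),
               "code space")
  set.seed(11)
  tup <- data.frame(l1 = sample(5, 1000, TRUE), l2 = sample(5, 1000, TRUE),
                    l3 = sample(5, 1000, TRUE),
                    theta_bin = sample(30, 1000, TRUE),
                    dist_bin = sample(17, 1000, TRUE))
  keys <- encode_key(tup$l1, tup$l2, tup$l3, tup$theta_bin, tup$dist_bin,
                     cfg)
  expect_equal(decode_key(keys, cfg), tup, ignore_attr = TRUE)
})

test_that("key generation enumerates all triples and respects the cutoff", {
  sel <- toy_protein_selection(4)
  cfg <- tsr_config("CA")
  res <- generate_keys(sel, cfg)
  expect_equal(unname(count_keys(res$key_vector)["total"]), choose(4, 3))
  expect_equal(nrow(res$triplets), choose(4, 3))

  big <- toy_cofactor_selection(with_tail = TRUE)   # tail spans > 20 A
  cfg_cof <- tsr_config("COFACTOR")
  all_keys <- generate_keys(big, cfg_cof)
  expect_equal(unname(count_keys(all_keys$key_vector)["total"]),
               choose(40, 3))
  cut20 <- generate_keys(big, tsr_config("COFACTOR", size_gap_cutoff = 20))
  expect_lt(sum(cut20$key_vector$counts), choose(40, 3))
  expect_true(all(cut20$triplets$maxdist <= 20))
  expect_error(generate_keys(toy_protein_selection(2), cfg),
               "at least 3")
  expect_error(generate_keys(big, cfg), "does not match")
})

test_that("keys are invariant to rigid motion and atom input order", {
  cfgs <- list(CA = tsr_config("CA"), COFACTOR = tsr_config("COFACTOR"),
               AA = tsr_config("AA"))
  sels <- list(CA = toy_protein_selection(8),
               COFACTOR = toy_cofactor_selection(),
               AA = select_residue(read_structure(toy_trp_pdb()), "A", 42))
  for (mode in names(cfgs)) {
    kv <- generate_keys(sels[[mode]], cfgs[[mode]])$key_vector
    kv_rot <- generate_keys(rigid_motion(sels[[mode]]),
                            cfgs[[mode]])$key_vector
    kv_shuf <- generate_keys(shuffle_atoms(sels[[mode]]),
                             cfgs[[mode]])$key_vector
    expect_identical(kv$counts, kv_rot$counts)
    expect_identical(kv$counts, kv_shuf$counts)
  }
})

test_that("amino-acid grouping merges labels before ordering", {
  sel <- toy_protein_selection(9)   # GLY/ALA/TRP pattern
  plain <- generate_keys(sel, tsr_config("CA"))$key_vector
  grouped <- generate_keys(
    sel, tsr_config("CA", grouping_map = aa_grouping_map()))$key_vector
  expect_equal(sum(plain$counts), sum(grouped$counts))
  # TRP maps to PHE's label under grouping, so decoded labels change
  lab_plain <- decode_key(as.numeric(names(plain$counts)),
                          tsr_config("CA"))
  expect_true(18 %in% unlist(lab_plain[, 1:3]))       # TRP label
  lab_grp <- decode_key(as.numeric(names(grouped$counts)),
                        tsr_config("CA"))
  expect_false(18 %in% unlist(lab_grp[, 1:3]))
  expect_true(14 %in% unlist(lab_grp[, 1:3]))          # PHE label
})

test_that("a lightly jittered copy stays more similar than an unrelated molecule", {
  cfg <- tsr_config("CA")
  template <- toy_protein_selection(12)
  jit <- jitter_family(template, 1, sigma = 0.05, seed = 3)[[1]]
  other <- toy_protein_selection(12, turn = 124, radius = 3.1)
  kv <- generate_keys(template, cfg)$key_vector
  kv_jit <- generate_keys(jit, cfg)$key_vector
  kv_other <- generate_keys(other, cfg)$key_vector
  s_jit <- generalized_jaccard(kv, kv_jit)
  s_other <- generalized_jaccard(kv, kv_other)
  expect_gt(s_jit, s_other)
  expect_gt(s_jit, 0.5)
})

test_that("key and triplet files round-trip", {
  cfg <- tsr_config("COFACTOR")
  res <- generate_keys(toy_cofactor_selection(FALSE), cfg)
  kf <- tempfile(fileext = ".keys")
  tf <- tempfile(fileext = ".triplets")
  write_key_file(res$key_vector, kf, cfg)
  write_triplet_file(res, tf, cfg)
  kv2 <- read_key_file(kf)
  expect_equal(kv2$counts, res$key_vector$counts)
  expect_equal(kv2$mode, "COFACTOR")
  expect_equal(kv2$config_hash, cfg$hash)
  tr2 <- read_triplet_file(tf)
  expect_equal(nrow(tr2), sum(res$key_vector$counts))
  expect_equal(tr2$key, res$triplets$key)
  expect_equal(tr2$maxdist, res$triplets$maxdist, tolerance = 1e-9)
  expect_equal(tr2$theta, res$triplets$theta, tolerance = 1e-9)
  # malformed rows are rejected with a line number
  writeLines(c("# mode=COFACTOR", "key\tfrequency", "12\t3\textra"), kf)
  expect_error(read_key_file(kf), "line 3")
})

test_that("keys map back to their triangles across a store", {
  cfg <- tsr_config("COFACTOR")
  r1 <- generate_keys(toy_cofactor_selection(FALSE), cfg)
  r2 <- generate_keys(
    rigid_motion(toy_cofactor_selection(FALSE)), cfg)
  t1 <- r1$triplets; attr(t1, "provenance") <- "mol1"
  t2 <- r2$triplets; attr(t2, "provenance") <- "mol2"
  store <- list(t1, t2)
  key <- r1$triplets$key[1]
  hits <- map_key_to_triangles(key, store)
  expect_true(nrow(hits) >= 2)                 # present in both copies
  expect_setequal(unique(hits$provenance), c("mol1", "mol2"))
  expect_equal(nrow(map_key_to_triangles(-1, store)), 0)
  # multiplicity within one molecule is preserved
  dup_key <- as.numeric(names(which(r1$key_vector$counts >= 2)))[1]
  if (!is.na(dup_key)) {
    h1 <- map_key_to_triangles(dup_key, list(t1))
    expect_equal(nrow(h1), unname(r1$key_vector$counts[as.character(dup_key)]))
  }
})

test_that("bin overflow lands in the last bin on both sides", {
  cfg <- tsr_config("COFACTOR")   # 17 x 1 A bins
  sel <- toy_cofactor_selection(with_tail = TRUE)
  res <- generate_keys(sel, cfg)
  long <- res$triplets$maxdist > 17
  expect_true(any(long))          # tail triangles exceed the last boundary
  expect_true(all(res$triplets$dist_bin[long] == 17))
  expect_true(all(res$triplets$dist_bin >= 1 & res$triplets$dist_bin <= 17))
  expect_true(all(res$triplets$theta_bin >= 1 &
                    res$triplets$theta_bin <= 30))
})
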