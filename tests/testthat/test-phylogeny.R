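test_that("identical sequences have zero distance under every model", {
  al <- c(a = "MKLVNTWPQA", b = "MKLVNTWPQA")
  for (kind in c("p", "poisson", "poisson_gamma", "jtt_ml", "jtt_ml_gamma")) {
    expect_equal(pairwise_distance(al["a"], al["b"],
                                   distance_model(kind)), 0,
                 tolerance = 1e-6)
  }
})

test_that("closed-form distances match independent evaluation at p = 0.5", {
  # 10 of 20 sites differ
  a <- "AAAAAAAAAAAAAAAAAAAA"
  b <- "RRRRRRRRRRAAAAAAAAAA"
  expect_equal(pairwise_distance(a, b, distance_model("p")), 0.5)
  expect_equal(pairwise_distance(a, b, distance_model("poisson")),
               0.6931472, tolerance = 1e-6)
  expect_equal(pairwise_distance(a, b, distance_model("poisson_gamma", 5)),
               5 * (2^0.2 - 1), tolerance = 1e-6)
})

test_that("X counts as a mismatch and saturation raises an error", {
  # X never matches, even against X: sites 2 and 4 are mismatches here
  expect_equal(pairwise_distance("AXAX", "AXAR", distance_model("p")), 0.5)
  expect_error(pairwise_distance("AAAA", "RRRR", distance_model("poisson")),
               "saturated")
  expect_error(distance_matrix(c(a = "A---", b = "-RRR"),
                               distance_model("p")), "zero usable sites")
})

test_that("poisson_gamma dominates poisson and converges to it for large shape", {
  for (p in seq(0.05, 0.9, by = 0.05)) {
    pg <- smydfam:::p_to_distance(p, distance_model("poisson_gamma", 5))
    po <- smydfam:::p_to_distance(p, distance_model("poisson"))
    expect_gte(pg, po)
    pg_inf <- smydfam:::p_to_distance(p, distance_model("poisson_gamma", 1e6))
    expect_equal(pg_inf, po, tolerance = 1e-4)
  }
})

test_that("distance matrices are symmetric and permute with row order", {
  set.seed(31)
  m <- matrix(sample(c("A", "R", "N", "D", "-"), 6 * 50, replace = TRUE),
              6, 50)
  m[, 1:5] <- "A"
  rows <- stats::setNames(apply(m, 1, paste, collapse = ""), paste0("r", 1:6))
  D <- distance_matrix(as_alignment(rows), distance_model("p"))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  perm <- sample(6)
  D2 <- distance_matrix(as_alignment(rows[perm]), distance_model("p"))
  expect_equal(D2, D[names(rows)[perm], names(rows)[perm]])
})

test_that("JTT ML distance agrees with the p-distance to first order", {
  set.seed(32)
  base <- strsplit(random_filler(1000), "")[[1]]
  mut <- base
  idx <- sample(1000, 10)                 # p = 0.01
  mut[idx] <- ifelse(base[idx] == "A", "R", "A")
  d <- pairwise_distance(paste(base, collapse = ""),
                         paste(mut, collapse = ""),
                         distance_model("jtt_ml"))
  expect_equal(d, 0.01, tolerance = 0.25)
})

test_that("three-taxon NJ reproduces the closed-form star lengths", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  tip_len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                             tr$tip.label)
  expect_equal(tip_len[["A"]], 1)  # (dAB + dAC - dBC) / 2
  expect_equal(tip_len[["B"]], 1)
  expect_equal(tip_len[["C"]], 3)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive 4-taxon matrices exactly vs the LS oracle", {
  set.seed(33)
  for (trial in 1:10) {
    ra <- random_additive(4)
    nj <- neighbor_joining(ra$D)
    or <- ls_best_tree(ra$D)
    expect_equal(robinson_foulds(nj, or$tree), 0)
    o <- rownames(ra$D)
    expect_lt(max(abs(ape::cophenetic.phylo(nj)[o, o] - ra$D)), 1e-9)
  }
})

test_that("equal off-diagonal distances give a resolved tree of the exact total length", {
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  expect_equal(length(tr$tip.label), 4)
  # brute force over the 3 quartet topologies: best LS fit has total length 2
  or <- ls_best_tree(D)
  expect_equal(sum(tr$edge.length), sum(pmax(or$tree$edge.length, 0)),
               tolerance = 1e-9)
  # determinism under the lexicographic tie-break
  expect_identical(ape::write.tree(tr), ape::write.tree(neighbor_joining(D)))
})

test_that("split sets and Robinson-Foulds follow hand enumeration", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_equal(robinson_foulds(t1, t2), 2)
  expect_equal(robinson_foulds(star, t1), 1)
  expect_error(robinson_foulds(t1, ape::read.tree(text = "((a,b),(c,e));")),
               "different leaf sets")
  # independent cross-check on larger random trees
  set.seed(34)
  for (trial in 1:5) {
    x <- ape::unroot(ape::rtree(8))
    y <- ape::unroot(ape::rtree(8, tip.label = x$tip.label))
    expect_equal(robinson_foulds(x, y),
                 as.integer(phangorn::RF.dist(x, y)))
  }
})

test_that("bootstrap supports are percentages, seeded, and 100 on degenerate alignments", {
  # all columns identical: resampling cannot change the distance ranks
  col <- c(a = "A", b = "A", c = "R", d = "R", e = "N", f = "N")
  al <- vapply(col, function(ch) strrep(ch, 40), character(1))
  tr <- bootstrap_support(al, distance_model("p"),
                          column_policy("pairwise_deletion"),
                          bootstrap_config(50, seed = 5))
  s <- attr(tr, "support")
  expect_true(all(s[!is.na(s)] == 100))

  set.seed(35)
  cfg <- synth_config(seed = 11, core_len = 150,
                      class_counts = c(SMYD3 = 3, SMYD5 = 3, SMYDA = 3),
                      smyd4_subgroups = integer(0))
  fam <- generate_family(cfg)
  b1 <- bootstrap_support(fam$alignment, distance_model("poisson_gamma"),
                          column_policy("pairwise_deletion"),
                          bootstrap_config(60, seed = 17))
  b2 <- bootstrap_support(fam$alignment, distance_model("poisson_gamma"),
                          column_policy("pairwise_deletion"),
                          bootstrap_config(60, seed = 17))
  s1 <- attr(b1, "support")
  expect_true(all(s1 >= 0 & s1 <= 100, na.rm = TRUE))
  expect_identical(s1, attr(b2, "support"))
})
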