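# small labelled tree: two supported clades, one anchor in each
toy_tree <- function(s1 = 95, s2 = 95) {
  ape::read.tree(text = sprintf(
    "((q1:0.1,A3:0.1)%s:0.2,(q2:0.1,A5:0.1)%s:0.2,out:0.4);", s1, s2))
}

toy_anchors <- data.frame(id = c("A3", "A5"),
                          class = c("SMYD3", "SMYD5"),
                          subgroup = NA_character_,
                          stringsAsFactors = FALSE)

# minimal architecture stand-ins
fake_arch <- function(sig, classes) {
  structure(list(annotations = data.frame(
    type = classes, start = 1, end = 2, source = "external",
    stringsAsFactors = FALSE),
    signature = sig, finger_category = "canonical",
    mynd_extra_n = FALSE, mynd_extra_c = FALSE),
    class = "architecture")
}

test_that("a supported single-anchor clade assigns its class, with agreement", {
  set.seed(51)
  cfg <- synth_config(seed = 4, core_len = 300, divergence = 0.1)
  fam <- generate_family(cfg)
  ref <- fam$anchors$id[1]
  core <- core_region(ref, fam$truth$core_spans[ref, 1],
                      fam$truth$core_spans[ref, 2])
  res <- run_pipeline(pipeline_config(fam$alignment, core, fam$anchors,
                                      model = distance_model("poisson_gamma"),
                                      external = fam$annotations))
  m <- merge(fam$truth$table, res$assignments, by = "id")
  expect_true(all(m$class.x == m$class.y))
  non_anchor <- m[m$evidence == "clade", ]
  expect_true(all(non_anchor$agreement | is.na(non_anchor$agreement)))
})

test_that("mixed-anchor clades fall through to architecture-only evidence", {
  tr <- ape::read.tree(text =
    "((q1:0.1,(A3:0.1,A5:0.1)99:0.1)99:0.2,x:0.3,y:0.4);")
  arch <- list(q1 = fake_arch("S/ET+M|CTD", c("SET_N", "SET_C", "CTD")))
  a <- assign_classes(tr, arch, toy_anchors, min_support = 70)
  q1 <- a[a$id == "q1", ]
  expect_equal(q1$class, "SMYD3")
  expect_equal(q1$evidence, "architecture-only")
})

test_that("tree-architecture disagreement demotes to UNCLASSIFIED", {
  tr <- toy_tree()
  # q1 sits with the SMYD3 anchor but carries a Smyd5-style architecture
  arch <- list(q1 = fake_arch("S/ET+M|E", c("SET_N", "SET_C", "ACIDIC")))
  a <- assign_classes(tr, arch, toy_anchors, min_support = 70)
  q1 <- a[a$id == "q1", ]
  expect_equal(q1$class, "UNCLASSIFIED")
  expect_false(q1$agreement)
  # without architecture evidence the clade class stands
  a2 <- assign_classes(tr, list(), toy_anchors, min_support = 70)
  expect_equal(a2$class[a2$id == "q1"], "SMYD3")
})

test_that("unsupported clades are ignored and support raising is conservative", {
  tr <- toy_tree(s1 = 40, s2 = 95)
  a <- assign_classes(tr, list(), toy_anchors, min_support = 70)
  expect_equal(a$class[a$id == "q2"], "SMYD5")
  # q1's small clade is unsupported; the next clade up that contains q1 and
  # an anchor is the side {q1,A3} complement... classification must not use
  # the 40-support edge
  q1_row <- a[a$id == "q1", ]
  expect_false(identical(q1_row$clade_support, 40))
  # monotone conservatism: raising min_support never classifies an
  # UNCLASSIFIED leaf
  for (thr in c(50, 70, 90, 101)) {
    ath <- assign_classes(tr, list(), toy_anchors, min_support = thr)
    low <- assign_classes(tr, list(), toy_anchors, min_support = thr - 10)
    newly <- ath$class != "UNCLASSIFIED" & low$class == "UNCLASSIFIED"
    expect_false(any(newly))
  }
})

test_that("anchors missing from the tree raise an error", {
  tr <- toy_tree()
  bad <- rbind(toy_anchors, data.frame(id = "GHOST", class = "SMYD4",
                                       subgroup = NA))
  expect_error(assign_classes(tr, list(), bad), "GHOST")
})

test_that("assignments are invariant under leaf relabeling of non-anchors", {
  set.seed(52)
  cfg <- synth_config(seed = 6, core_len = 300, divergence = 0.1)
  fam <- generate_family(cfg)
  al <- fam$alignment
  D <- distance_matrix(al, distance_model("poisson_gamma"))
  tr <- neighbor_joining(D)
  a1 <- assign_classes(tr, list(), fam$anchors)
  # swap two non-anchor labels consistently
  non <- setdiff(tr$tip.label, fam$anchors$id)[1:2]
  tr2 <- tr
  tr2$tip.label[match(non, tr2$tip.label)] <- rev(non)
  a2 <- assign_classes(tr2, list(), fam$anchors)
  expect_equal(a2$class[a2$id == non[1]], a1$class[a1$id == non[2]])
  expect_equal(a2$class[a2$id == non[2]], a1$class[a1$id == non[1]])
})

test_that("subgroup assignment follows subgroup anchors within the class", {
  set.seed(53)
  cfg <- synth_config(seed = 8, core_len = 400, divergence = 0.2)
  fam <- generate_family(cfg)
  D <- distance_matrix(fam$alignment, distance_model("poisson_gamma"))
  tr <- neighbor_joining(D)
  a <- assign_classes(tr, list(), fam$anchors)
  a <- assign_subgroups(a, tr, fam$anchors)
  m <- merge(fam$truth$table, a, by = "id")
  s4 <- m[m$class.x == "SMYD4", ]
  expect_true(all(s4$subgroup.x == s4$subgroup.y))
  # leaves outside subgroup-bearing classes keep an unset subgroup
  expect_true(all(is.na(m$subgroup.y[m$class.x == "SMYDA"])))
})

test_that("ortholog suggestion minimizes patristic distance with support tie-break", {
  tr <- ape::read.tree(text =
    "((q:0.05,A4:0.05)90:0.2,(A3:0.25,x:0.1)40:0.05,y:0.4);")
  anchors <- data.frame(id = c("A3", "A4"), class = c("SMYD3", "SMYD4"),
                        subgroup = NA, stringsAsFactors = FALSE)
  s <- suggest_ortholog("q", tr, anchors)
  expect_equal(s$anchor, "A4")
  expect_error(suggest_ortholog("zz", tr, anchors), "not in tree")
  # equidistant anchors: higher path support wins
  tr2 <- ape::read.tree(text =
    "((q:0.1,w:0.1)95:0.1,(A3:0.1,x:0.1)30:0.1,(A4:0.1,y:0.1)90:0.1);")
  expect_equal(suggest_ortholog("q", tr2, anchors)$anchor, "A4")
})

test_that("patristic distances agree with brute-force path summation", {
  set.seed(54)
  for (trial in 1:5) {
    tr <- ape::unroot(ape::rtree(7))
    dm <- ape::cophenetic.phylo(tr)
    tips <- tr$tip.label
    for (k in 1:5) {
      ab <- sample(tips, 2)
      expect_equal(dm[ab[1], ab[2]],
                   patristic_bruteforce(tr, ab[1], ab[2]),
                   tolerance = 1e-10)
    }
  }
})

test_that("the bundled anchor table loads with valid classes and subgroups", {
  a <- read_anchors()
  expect_named(a, c("id", "class", "subgroup"))
  expect_true(all(a$class %in% c("SMYD3", "SMYD4", "SMYD5")))
  expect_true(all(is.na(a$subgroup) | nzchar(a$subgroup)))
  expect_true(all(c("SMYD5_HUMAN", "CG1868", "CG8378") %in% a$id))
})
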