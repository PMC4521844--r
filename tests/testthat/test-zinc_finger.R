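pat <- load_zn_pattern()

embed_finger <- function(f, left = 20, right = 20) {
  paste0(random_filler(left), f$seq, random_filler(right))
}

test_that("a peptide realizing the signature gives one canonical hit", {
  set.seed(1)
  f <- realize_finger(pat)
  pep <- embed_finger(f)
  hits <- enumerate_candidate_fingers(pep, pat)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$positions, f$positions + 20)
  expect_equal(hits[[1]]$category, "canonical")
  expect_equal(hits[[1]]$score, 0)
})

test_that("a single planted His-for-Cys swap is reported as one substitution", {
  set.seed(2)
  f <- realize_finger(pat)
  pep <- embed_finger(f)
  mut <- 20 + f$positions[5]  # first Cys of pair 3
  substr(pep, mut, mut) <- "H"
  b <- best_finger(enumerate_candidate_fingers(pep, pat))
  expect_equal(b$score, 1)
  expect_equal(b$deviations$kind, "ligand_substitution")
  expect_equal(b$deviations$location, "L5")
})

test_that("ligand-free sequences yield no hits", {
  expect_length(enumerate_candidate_fingers(strrep("A", 200), pat), 0)
  expect_error(enumerate_candidate_fingers(strrep("A", 50), pat,
                                           region = c(10, 60)),
               "outside sequence")
})

test_that("search equals exhaustive brute force on random ligand-sprinkled sequences", {
  set.seed(33)
  relax <- relax_policy(allow_half = FALSE)
  for (trial in 1:25) {
    pep <- peptide_with_ligands(sample(9:13, 1))
    a <- enumerate_candidate_fingers(pep, pat, relax = relax)
    b <- enumerate_fingers_bruteforce(pep, pat, relax = relax)
    expect_setequal(vapply(a, hit_key, character(1)),
                    vapply(b, hit_key, character(1)))
    sa <- sort(vapply(a, `[[`, numeric(1), "score"))
    sb <- sort(vapply(b, `[[`, numeric(1), "score"))
    expect_equal(sa, sb)
  }
})

test_that("best_finger prefers low score, then leftmost, then compact", {
  set.seed(3)
  f <- realize_finger(pat)
  g <- realize_finger(pat, ligands = c(L2 = "H", L6 = "H"))
  pep <- paste0(random_filler(5), g$seq, random_filler(30), f$seq,
                random_filler(5))
  hits <- enumerate_candidate_fingers(pep, pat)
  b <- best_finger(hits)
  expect_equal(b$score, 0)
  expect_equal(b$positions[1], 5 + nchar(g$seq) + 30 + 1)
  # two equal-score fingers: leftmost wins
  pep2 <- paste0(random_filler(5), f$seq, random_filler(30), f$seq)
  b2 <- best_finger(enumerate_candidate_fingers(pep2, pat))
  expect_equal(b2$positions[1], 6)
  expect_null(best_finger(list()))
})

test_that("categories follow the half-of-the-finger logic", {
  set.seed(4)
  realize_then_categorize <- function(...) {
    f <- realize_finger(pat, ...)
    b <- best_finger(enumerate_candidate_fingers(embed_finger(f), pat))
    b$category
  }
  expect_equal(realize_then_categorize(), "canonical")
  # long spacer between pairs 1 and 2 breaks the left half only
  expect_equal(realize_then_categorize(spacers = c(spacer_1_2 = 40)),
               "partial_right")
  # long spacer between pairs 3 and 4 breaks the right half only
  expect_equal(realize_then_categorize(spacers = c(spacer_3_4 = 30)),
               "partial_left")
  # substitutions in both halves: atypical (C3H-C3H-like)
  expect_equal(realize_then_categorize(ligands = c(L4 = "H", L7 = "H")),
               "atypical")
})

test_that("four-ligand hits equivalent to pairs 1 and 3 are categorized half", {
  set.seed(5)
  f <- realize_finger(pat)
  # keep only ligands 1, 2, 5, 6 (pairs 1 and 3); neutralize the rest
  res <- strsplit(f$seq, "")[[1]]
  res[f$positions[c(3, 4, 7, 8)]] <- "A"
  pep <- paste0(random_filler(10), paste(res, collapse = ""),
                random_filler(10))
  hits <- enumerate_candidate_fingers(pep, pat)
  expect_true(length(hits) >= 1)
  b <- best_finger(hits)
  expect_true(b$half)
  expect_equal(b$category, "half")
  expect_length(b$positions, 4)
  expect_equal(sum(b$deviations$kind == "missing_pair"), 2)
})

test_that("secondary-structure evidence is scored against pairs 3-4", {
  set.seed(6)
  f <- realize_finger(pat)
  pep <- embed_finger(f, 10, 10)
  b <- best_finger(enumerate_candidate_fingers(pep, pat))
  L <- nchar(pep)
  ss <- rep("-", L)
  p5 <- b$positions[5]; p8 <- b$positions[8]
  ss[(p5 - 4):(p5 - 2)] <- "E"
  ss[p5:(p5 + 5)] <- "H"
  expect_equal(ss_consistency(b, ss), "supported")
  expect_equal(ss_consistency(b, rep("-", L)), "unsupported")
  expect_equal(ss_consistency(b, NULL), "no_data")
  expect_error(ss_consistency(b, rep("-", p8 - 1)), "shorter")
})

test_that("finger report lists one row per non-overlapping finger", {
  set.seed(7)
  fcan <- realize_finger(pat)
  fhalf <- realize_finger(pat)
  res <- strsplit(fhalf$seq, "")[[1]]
  res[fhalf$positions[c(3, 4, 7, 8)]] <- "A"
  seqs <- c(one = embed_finger(fcan),
            two = paste0(random_filler(10), paste(res, collapse = ""),
                         random_filler(10)))
  rep1 <- finger_report(seqs, pat)
  expect_equal(rep1$category[rep1$id == "one"], "canonical")
  expect_equal(rep1$category[rep1$id == "two"], "half")
  expect_equal(nrow(finger_report(character(0), pat)), 0)
  # two disjoint fingers in one protein: both reported
  fx <- realize_finger(pat)
  two_fingers <- c(dual = paste0(random_filler(5), fcan$seq,
                                 random_filler(40), fx$seq,
                                 random_filler(5)))
  rep2 <- finger_report(two_fingers, pat)
  expect_equal(nrow(rep2), 2)
  expect_true(all(rep2$category == "canonical"))
})

test_that("mutating one extra ligand never decreases the best score", {
  set.seed(8)
  for (trial in 1:5) {
    f <- realize_finger(pat)
    pep <- embed_finger(f)
    prev <- best_finger(enumerate_candidate_fingers(pep, pat))$score
    order_mut <- sample(8)
    for (k in order_mut[1:4]) {
      pos <- 20 + f$positions[k]
      substr(pep, pos, pos) <- "H"
      hits <- enumerate_candidate_fingers(pep, pat)
      cur <- if (length(hits)) best_finger(hits)$score else Inf
      expect_gte(cur, prev)
      prev <- cur
    }
  }
})

test_that("canonical category implies a regular-expression match of the signature", {
  regex <- paste0(
    "C.{2}C", ".{9,21}", "C.{2}C", ".{4}", "C.{2}C", ".{8,17}", "C.{2}[CH]")
  set.seed(9)
  for (trial in 1:10) {
    f <- realize_finger(pat, spacers = c(
      spacer_1_2 = sample(9:21, 1), spacer_3_4 = sample(8:17, 1)))
    pep <- embed_finger(f)
    b <- best_finger(enumerate_candidate_fingers(pep, pat))
    expect_equal(b$category, "canonical")
    sub <- substr(pep, b$positions[1], b$positions[8])
    expect_match(sub, paste0("^", regex, "$"))
  }
})
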