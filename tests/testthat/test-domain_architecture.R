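test_that("acidic tract detection finds poly-E, E/D and rejects basic tails", {
  base <- paste0(strrep("K", 40), strrep("W", 10))
  # 10 E after 50 non-acidic residues: the longest suffix holding the 0.6
  # fraction stretches 6 residues into the W run (10/16 = 0.625)
  tr_e <- detect_acidic_tract(paste0(base, strrep("E", 10)))
  expect_equal(tr_e$composition_class, "E")
  expect_equal(c(tr_e$start, tr_e$end), c(45, 60))
  tr_ed <- detect_acidic_tract(paste0(base, strrep("ED", 5)))
  expect_equal(tr_ed$composition_class, "ED")
  expect_null(detect_acidic_tract(paste0(base, strrep("K", 10))))
  # 5 E can reach at most 8 qualifying residues, under the length floor
  expect_null(detect_acidic_tract(paste0(base, strrep("E", 5))))
})

test_that("acidic tract detection is invariant to prepending residues", {
  tail50 <- paste0(strrep("W", 30), strrep("E", 20))
  t1 <- detect_acidic_tract(tail50)
  t2 <- detect_acidic_tract(paste0(strrep("K", 100), tail50))
  expect_equal(t2$end - t2$start, t1$end - t1$start)
  expect_equal(t2$composition_class, t1$composition_class)
})

build_arch <- function(with_tpr = FALSE, with_ctd = FALSE,
                       with_acidic = FALSE, finger_cat = "canonical",
                       extra_c = FALSE) {
  set.seed(41)
  pat <- load_zn_pattern()
  f <- realize_finger(pat, ligands = if (finger_cat == "atypical")
    c(L3 = "H", L7 = "H") else NULL)
  core_seq <- paste0(random_filler(60), f$seq, random_filler(60),
                     random_filler(34))
  pieces <- c(if (with_tpr) random_filler(102), core_seq,
              if (with_ctd) random_filler(80),
              if (extra_c) realize_finger(pat)$seq,
              if (with_acidic) strrep("E", 15))
  seqstr <- paste(pieces, collapse = "")
  off <- if (with_tpr) 102 else 0
  flen <- nchar(f$seq)
  core <- smyd_core(set_n = c(off + 1, off + 60),
                    mynd = c(off + 61, off + 60 + flen),
                    set_c = c(off + 61 + flen, off + 120 + flen),
                    post_set = c(off + 121 + flen, off + 154 + flen))
  hit <- best_finger(enumerate_candidate_fingers(
    seqstr, pat, region = c(off + 1, off + 154 + flen)))
  extra <- if (extra_c) enumerate_candidate_fingers(
    seqstr, pat, region = c(off + 155 + flen, nchar(seqstr))) else list()
  ext <- NULL
  if (with_tpr) ext <- rbind(ext, data.frame(type = "TPR_N", start = 1,
                                             end = 102))
  if (with_ctd) {
    s <- off + 155 + flen
    ext <- rbind(ext, data.frame(type = "CTD", start = s, end = s + 79))
  }
  assemble_architecture(seqstr, core = core, finger = hit,
                        extra_fingers = extra, external = ext)
}

test_that("architecture signatures mirror the class-defining structures", {
  expect_equal(build_arch(with_ctd = TRUE)$signature, "S/ET+M|CTD")
  expect_equal(build_arch(with_tpr = TRUE, with_ctd = TRUE)$signature,
               "TPR_N|S/ET+M|CTD")
  arch5 <- build_arch(with_acidic = TRUE)
  expect_match(arch5$signature, "^S/ET\\+M\\|ED?S?$")  # tract class suffix
  expect_false(grepl("CTD|TPR", arch5$signature))
  a <- build_arch(with_tpr = TRUE, extra_c = TRUE, finger_cat = "atypical")
  expect_equal(a$signature, "TPR_N|S/ET+M|M")
  expect_true(a$mynd_extra_c)
})

test_that("architecture-to-class rules fire as specified and fall through", {
  expect_equal(architecture_class(build_arch(with_ctd = TRUE)), "SMYD3")
  expect_equal(architecture_class(build_arch(with_tpr = TRUE,
                                             with_ctd = TRUE)), "SMYD4")
  expect_equal(architecture_class(build_arch(with_acidic = TRUE)), "SMYD5")
  expect_equal(architecture_class(
    build_arch(with_tpr = TRUE, extra_c = TRUE, finger_cat = "atypical")),
    "ATYPICAL_TPR")
  expect_equal(architecture_class(build_arch(finger_cat = "atypical")),
               "SMYDA")
  # bare core with canonical finger: ambiguous, resolved by tree evidence
  expect_length(architecture_class(build_arch()), 0)
})

test_that("same signature implies the same candidate classes", {
  a1 <- build_arch(with_ctd = TRUE)
  a2 <- build_arch(with_ctd = TRUE)
  expect_identical(a1$signature, a2$signature)
  expect_identical(architecture_class(a1), architecture_class(a2))
})

test_that("the TPR heuristic flags tandem consensus repeats but not random sequence", {
  cons <- strrep(smydfam:::TPR_CONSENSUS, 3)
  hit <- detect_tpr_heuristic(paste0(cons, random_filler(100)))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$type, "TPR_N")
  expect_equal(hit$source, "detector")
  expect_lte(hit$start, 3)
  set.seed(42)
  false_pos <- 0
  for (trial in 1:100) {
    if (nrow(detect_tpr_heuristic(peptide_with_ligands(10, 200))) > 0) {
      false_pos <- false_pos + 1
    }
  }
  expect_equal(false_pos, 0)
})

test_that("overlapping annotations merge and out-of-range spans error", {
  set.seed(43)
  seqstr <- random_filler(200)
  ext <- data.frame(type = c("TPR_N", "TPR_N"), start = c(1, 30),
                    end = c(40, 70))
  a <- assemble_architecture(seqstr, external = ext, acidic = NULL)
  tpr <- a$annotations[a$annotations$type == "TPR_N", ]
  expect_equal(nrow(tpr), 1)
  expect_equal(c(tpr$start, tpr$end), c(1, 70))
  bad <- data.frame(type = "CTD", start = 150, end = 300)
  expect_error(assemble_architecture(seqstr, external = bad, acidic = NULL),
               "outside sequence")
})
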