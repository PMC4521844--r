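# Filler alphabet excludes ligand-capable residues (C, H, E) so that planted
# fingers are the only ligand octets in generated sequences.
FILLER_AA <- setdiff(AA_LETTERS, c("C", "H", "E"))

#' Realize a Zn finger string from the signature
#'
#' Builds a concrete finger peptide from the unrelaxed signature, optionally
#' overriding spacer lengths or ligand residues to plant deviations.
#'
#' @param pattern a [load_zn_pattern()] signature.
#' @param spacers named integer overrides by gap location (e.g.
#'   `c(spacer_1_2 = 31)`).
#' @param ligands named character overrides by slot (e.g. `c(L3 = "H")`).
#' @return list with `seq`, 1-based `positions` of the eight ligands within
#'   it, and the implied `deviations` (relative to the unrelaxed signature).
#' @export
realize_finger <- function(pattern, spacers = NULL, ligands = NULL) {
  gap_len <- floor((pattern$gap_min + pattern$gap_max) / 2)
  names(gap_len) <- pattern$gap_loc
  if (!is.null(spacers)) gap_len[names(spacers)] <- spacers
  lig <- vapply(pattern$ligand_allowed, `[`, character(1), 1)
  names(lig) <- paste0("L", 1:8)
  if (!is.null(ligands)) lig[names(ligands)] <- ligands
  pieces <- character(0)
  positions <- integer(8)
  at <- 0L
  for (k in 1:8) {
    pieces <- c(pieces, lig[k])
    at <- at + 1L
    positions[k] <- at
    if (k < 8) {
      fill <- paste(sample(FILLER_AA, gap_len[k], replace = TRUE),
                    collapse = "")
      pieces <- c(pieces, fill)
      at <- at + gap_len[k]
    }
  }
  seqstr <- paste(pieces, collapse = "")
  list(seq = seqstr, positions = positions,
       deviations = finger_deviations(positions, unname(lig), pattern))
}

#' Synthetic Smyd-family configuration
#'
#' Study conditions for the generator: per-class taxon counts mirroring the
#' family's class structure (three widespread classes, an arthropod-specific
#' one and the atypical TPR group, with the Smyd4 class split into its three
#' groups), a Yule tree per class hung off a fixed class backbone, and
#' independent-site protein evolution from a single family-root template
#' with planted class-diagnostic features held invariant.
#'
#' @param class_counts named integer vector of taxa per class.
#' @param smyd4_subgroups named integer vector splitting the SMYD4 count
#'   into the SMYD4 / SMYD4L / SMYD4I groups (must sum to
#'   `class_counts["SMYD4"]`).
#' @param divergence expected root-to-tip divergence within a class, in
#'   substitutions per site (default 0.3).
#' @param birth_rate Yule birth rate for within-class subtrees (default 1).
#' @param model substitution model, `"poisson"` (uniform 20-state) or
#'   `"jtt"`.
#' @param seed RNG seed (mandatory).
#' @param core_len approximate ungapped length of the SET-MYND core
#'   (default 2000; long cores make tree recovery near-deterministic).
#' @param tpr_repeats TPR repeats in the N-terminal block (default 3).
#' @param ctd_len length of the C-terminal TPR-fold domain block
#'   (default 100).
#' @param acidic_len,acidic_class length and composition (`"E"`, `"ED"`,
#'   `"EDS"`) of the Smyd5 C-terminal acidic tract (defaults 20, `"E"`).
#' @param finger_schedule per-class list of `spacers` / `ligands` overrides
#'   for [realize_finger()]; the default plants a canonical finger in
#'   Smyd3/Smyd4, an over-long pair-1-2 spacer in Smyd5 and the atypical
#'   group, and two His-for-Cys substitutions in SmydA.
#' @param mask_ligands keep planted finger, extra-finger and tract columns
#'   invariant during evolution (default `TRUE`; turning it off is the
#'   "decay" mode).
#' @return a `synth_config` list.
#' @export
synth_config <- function(class_counts = c(SMYD3 = 4, SMYD4 = 6, SMYD5 = 4,
                                          SMYDA = 4, ATYPICAL_TPR = 2),
                         smyd4_subgroups = c(SMYD4 = 2, SMYD4L = 2,
                                             SMYD4I = 2),
                         divergence = 0.3, birth_rate = 1,
                         model = c("poisson", "jtt"), seed,
                         core_len = 2000, tpr_repeats = 3, ctd_len = 100,
                         acidic_len = 20, acidic_class = "E",
                         finger_schedule = NULL, mask_ligands = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  model <- match.arg(model)
  stopifnot(all(class_counts >= 1), sum(class_counts) >= 4, divergence > 0)
  if ("SMYD4" %in% names(class_counts) &&
      sum(smyd4_subgroups) != class_counts[["SMYD4"]]) {
    stop("smyd4_subgroups must sum to the SMYD4 class count")
  }
  if (is.null(finger_schedule)) {
    finger_schedule <- list(
      SMYD3 = list(), SMYD4 = list(),
      SMYD5 = list(spacers = c(spacer_1_2 = 31)),
      SMYDA = list(ligands = c(L3 = "H", L7 = "H")),
      ATYPICAL_TPR = list(spacers = c(spacer_1_2 = 31)))
  }
  structure(list(class_counts = class_counts,
                 smyd4_subgroups = smyd4_subgroups,
                 divergence = divergence, birth_rate = birth_rate,
                 model = model, seed = as.integer(seed),
                 core_len = core_len, tpr_repeats = tpr_repeats,
                 ctd_len = ctd_len, acidic_len = acidic_len,
                 acidic_class = acidic_class,
                 finger_schedule = finger_schedule,
                 mask_ligands = mask_ligands),
            class = "synth_config")
}

# Yule subtree without the public n >= 4 restriction; branch lengths scaled
# so the mean root-to-tip path equals `depth`. Branches are floored at
# `min_branch` so every true split carries enough expected substitutions to
# be identifiable — a benchmark tree with a near-zero internal edge cannot
# be recovered by any method at finite sequence length.
yule_subtree <- function(n, birth_rate, depth, min_branch = 0.02) {
  if (n == 1) return(NULL)
  tr <- ape::rphylo(n, birth = birth_rate, death = 0)
  tips <- ape::node.depth.edgelength(tr)[seq_len(n)]
  tr$edge.length <- pmax(tr$edge.length * depth / mean(tips), min_branch)
  tr
}

#' Simulate a Yule tree
#'
#' Pure-birth tree with `n` leaves; branch lengths rescaled so the mean
#' root-to-tip path length equals `divergence`.
#'
#' @param n number of leaves (>= 4).
#' @param birth_rate Yule birth rate.
#' @param seed RNG seed.
#' @param divergence target mean root-to-tip path (substitutions per site).
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(n, birth_rate = 1, seed, divergence = 0.3) {
  if (n < 4) stop("need at least 4 leaves")
  set.seed(seed)
  yule_subtree(n, birth_rate, divergence)
}

#' Evolve protein sequences along a tree
#'
#' Independent-site substitution along each branch. Under the
#' `"poisson"` (uniform 20-state) model a site changes over a branch of
#' length `t` with probability `(19/20) * (1 - exp(-20 t / 19))`, the new
#' residue drawn uniformly from the other 19. Under `"jtt"` the leaves are
#' simulated with the empirical JTT matrix (via phangorn) and masked columns
#' restored to the root state afterwards. Masked sites never change.
#'
#' @param tree [ape::phylo] with branch lengths in substitutions per site.
#' @param root_seq root residue string.
#' @param model `"poisson"` or `"jtt"`.
#' @param mask logical vector (length of `root_seq`) marking invariant
#'   sites; `NULL` for none.
#' @param seed RNG seed.
#' @return named character vector of leaf sequences (tip-label order).
#' @export
evolve_sequences <- function(tree, root_seq, model = c("poisson", "jtt"),
                             mask = NULL, seed) {
  model <- match.arg(model)
  root <- strsplit(unname(root_seq[[1]]), "")[[1]]
  L <- length(root)
  if (is.null(mask)) mask <- rep(FALSE, L)
  if (length(mask) > L) stop("mask longer than root sequence")
  if (length(mask) < L) mask <- c(mask, rep(FALSE, L - length(mask)))
  set.seed(seed)
  n <- length(tree$tip.label)
  if (model == "jtt") {
    sim <- phangorn::simSeq(tree, l = L, type = "AA", model = "JTT",
                            rootseq = root)
    m <- toupper(as.character(sim))
    m[, mask] <- matrix(root[mask], nrow = nrow(m), ncol = sum(mask),
                        byrow = TRUE)
    out <- apply(m, 1, paste, collapse = "")
    return(out[tree$tip.label])
  }
  free <- which(!mask)
  nodes_seq <- vector("list", n + tree$Nnode)
  nodes_seq[[n + 1]] <- root
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    t_len <- ord$edge.length[e]
    s <- nodes_seq[[parent]]
    if (t_len > 0 && length(free) > 0) {
      p_change <- (19 / 20) * (1 - exp(-20 * t_len / 19))
      hit <- free[stats::runif(length(free)) < p_change]
      if (length(hit)) {
        repl <- AA_LETTERS[ceiling(stats::runif(length(hit)) * 19)]
        # uniform over the 19 residues other than the current one
        cur <- match(s[hit], AA_LETTERS)
        ri <- match(repl, AA_LETTERS)
        bump <- ri >= cur
        s[hit] <- AA_LETTERS[ifelse(bump, ri + 1, ri)]
      }
    }
    nodes_seq[[child]] <- s
  }
  out <- vapply(seq_len(n), function(i) paste(nodes_seq[[i]], collapse = ""),
                character(1))
  names(out) <- tree$tip.label
  out
}

TPR_CONSENSUS <- "AEAWYNLGNAYYKQGDYQKAIEYYQKALELDPRS"

# compose newick of class subtrees hanging off a pectinate backbone
compose_backbone <- function(subtrees, stem, backbone) {
  part <- function(k) {
    st <- subtrees[[k]]
    if (is.null(st$tree)) {
      paste0(st$tips, ":", stem)
    } else {
      nwk <- ape::write.tree(st$tree)
      paste0(sub(";$", "", nwk), ":", stem)
    }
  }
  acc <- part(1)
  for (k in seq_along(subtrees)[-1]) {
    acc <- paste0("(", acc, ":", backbone, ",", part(k), ":", backbone, ")")
  }
  ape::read.tree(text = paste0(acc, ";"))
}

#' Generate a synthetic Smyd-like protein family with ground truth
#'
#' Builds one family-root template (TPR block, SET-MYND core with an
#' embedded finger region, C-terminal TPR-fold domain, optional extra MYND
#' finger and acidic tract), evolves it along a class-structured tree, and
#' applies each class's planted features: class-specific finger realization
#' inside the core, and class-specific presence/absence of the flanking
#' blocks (absent blocks become gap columns, so the emitted alignment is the
#' true alignment; no indels are simulated). Planted feature columns are
#' held invariant unless `mask_ligands` is off.
#'
#' @param cfg a [synth_config()].
#' @return list with `seqs` (ungapped FASTA-ready sequences), `alignment`
#'   (true alignment), `truth` (true tree, per-sequence class/subgroup
#'   table, planted finger coordinates and deviation counts, domain spans,
#'   tract spans), `annotations` (external-style TPR_N/CTD annotation data
#'   frame), `anchors` (first member of each class and subgroup) and
#'   `config`.
#' @export
generate_family <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  pattern <- load_zn_pattern()
  classes <- names(cfg$class_counts)

  # per-class finger realizations
  fingers <- lapply(classes, function(cl) {
    sch <- cfg$finger_schedule[[cl]]
    if (is.null(sch)) sch <- list()
    realize_finger(pattern, spacers = sch$spacers, ligands = sch$ligands)
  })
  names(fingers) <- classes
  extra_finger <- realize_finger(pattern)   # canonical, for the atypical class
  w_finger <- max(vapply(fingers, function(f) nchar(f$seq), numeric(1)))

  # block layout
  w_tpr <- cfg$tpr_repeats * nchar(TPR_CONSENSUS)
  post_set_len <- 34
  set_n_len <- max(20, round(0.35 * (cfg$core_len - w_finger - post_set_len)))
  set_c_len <- max(20, cfg$core_len - w_finger - post_set_len - set_n_len)
  w_core <- set_n_len + w_finger + set_c_len + post_set_len
  w_ctd <- cfg$ctd_len
  w_mc <- nchar(extra_finger$seq)
  w_ac <- cfg$acidic_len
  blocks <- c(TPR = w_tpr, SET_N = set_n_len, FINGER = w_finger,
              SET_C = set_c_len, POST_SET = post_set_len, CTD = w_ctd,
              M_C = w_mc, ACIDIC = w_ac)
  offs <- cumsum(c(0, blocks))[seq_along(blocks)]
  names(offs) <- names(blocks)
  W <- sum(blocks)

  # family-root template over the full width
  fill <- function(n) paste(sample(FILLER_AA, n, replace = TRUE),
                            collapse = "")
  acid_pool <- strsplit(cfg$acidic_class, "")[[1]]
  acid_tail <- paste(sample(rep(acid_pool, length.out = max(w_ac, 1))),
                     collapse = "")
  root <- paste0(
    paste(rep(TPR_CONSENSUS, cfg$tpr_repeats), collapse = ""),
    fill(set_n_len), fill(w_finger), fill(set_c_len), fill(post_set_len),
    fill(w_ctd), extra_finger$seq, acid_tail)
  mask <- rep(FALSE, W)
  if (cfg$mask_ligands) {
    mask[(offs[["FINGER"]] + 1):(offs[["FINGER"]] + w_finger)] <- TRUE
    mask[(offs[["M_C"]] + 1):(offs[["M_C"]] + w_mc)] <- TRUE
    mask[(offs[["ACIDIC"]] + 1):(offs[["ACIDIC"]] + w_ac)] <- TRUE
  }

  # class tree: within-class Yule subtrees on a pectinate backbone
  tip_names <- list()
  subtrees <- list()
  subgroup_of <- character(0)
  for (cl in classes) {
    k <- cfg$class_counts[[cl]]
    if (cl == "SMYD4" && length(cfg$smyd4_subgroups) > 1) {
      groups <- names(cfg$smyd4_subgroups)
      parts <- list()
      for (g in groups) {
        ng <- cfg$smyd4_subgroups[[g]]
        nm <- sprintf("%s.%s.%02d", cl, g, seq_len(ng))
        st <- yule_subtree(ng, cfg$birth_rate, 0.5 * cfg$divergence)
        if (!is.null(st)) st$tip.label <- nm
        parts[[g]] <- list(tree = st, tips = nm)
        subgroup_of[nm] <- g
      }
      sub <- compose_backbone(parts, stem = 0.25 * cfg$divergence,
                              backbone = 0.25 * cfg$divergence)
      subtrees[[cl]] <- list(tree = sub, tips = sub$tip.label)
    } else {
      nm <- sprintf("%s.%02d", cl, seq_len(k))
      st <- yule_subtree(k, cfg$birth_rate, cfg$divergence)
      if (!is.null(st)) st$tip.label <- nm
      subtrees[[cl]] <- list(tree = st, tips = nm)
    }
    tip_names[[cl]] <- subtrees[[cl]]$tips
  }
  tree <- compose_backbone(subtrees, stem = 0.3 * cfg$divergence,
                           backbone = 0.3 * cfg$divergence)

  leaves <- evolve_sequences(tree, root, model = cfg$model, mask = mask,
                             seed = cfg$seed + 1L)

  presence <- list(
    SMYD3 = c("SET_N", "FINGER", "SET_C", "POST_SET", "CTD"),
    SMYD4 = c("TPR", "SET_N", "FINGER", "SET_C", "POST_SET", "CTD"),
    SMYD5 = c("SET_N", "FINGER", "SET_C", "POST_SET", "ACIDIC"),
    SMYDA = c("SET_N", "FINGER", "SET_C", "POST_SET"),
    ATYPICAL_TPR = c("TPR", "SET_N", "FINGER", "SET_C", "POST_SET", "M_C"))

  aln <- character(0)
  seqs <- character(0)
  truth_rows <- list()
  finger_truth <- list()
  domain_rows <- list()
  ann_rows <- list()
  for (cl in classes) {
    pres <- presence[[cl]]
    f <- fingers[[cl]]
    f_len <- nchar(f$seq)
    for (nm in tip_names[[cl]]) {
      row <- strsplit(leaves[[nm]], "")[[1]]
      # class surgery: planted finger (padded with gaps), absent blocks gapped
      fcols <- (offs[["FINGER"]] + 1):(offs[["FINGER"]] + w_finger)
      row[fcols] <- c(strsplit(f$seq, "")[[1]], rep("-", w_finger - f_len))
      for (b in setdiff(names(blocks), c(pres, "FINGER"))) {
        row[(offs[[b]] + 1):(offs[[b]] + blocks[[b]])] <- "-"
      }
      gapped <- paste(row, collapse = "")
      ungapped <- gsub("-", "", gapped, fixed = TRUE)
      aln[nm] <- gapped
      seqs[nm] <- ungapped
      # ungapped coordinates of each present block
      to_ungapped <- cumsum(row != "-")
      span <- function(b, width = blocks[[b]]) {
        c(to_ungapped[offs[[b]] + 1], to_ungapped[offs[[b]] + width])
      }
      fpos <- to_ungapped[offs[["FINGER"]] + f$positions]
      sub <- if (nm %in% names(subgroup_of)) subgroup_of[[nm]] else NA
      truth_rows[[nm]] <- data.frame(
        id = nm, class = cl, subgroup = sub,
        finger_category = categorize(structure(
          list(half = FALSE, deviations = f$deviations), class = "zn_hit")),
        n_deviations = nrow(f$deviations), stringsAsFactors = FALSE)
      finger_truth[[nm]] <- list(positions = fpos,
                                 deviations = f$deviations)
      add_dom <- function(type, b, width = blocks[[b]]) {
        sp <- span(b, width)
        domain_rows[[length(domain_rows) + 1]] <<- data.frame(
          id = nm, type = type, start = sp[1], end = sp[2],
          stringsAsFactors = FALSE)
      }
      if ("TPR" %in% pres) add_dom("TPR_N", "TPR")
      add_dom("SET_N", "SET_N")
      domain_rows[[length(domain_rows) + 1]] <- data.frame(
        id = nm, type = "MYND", start = fpos[1], end = fpos[8],
        stringsAsFactors = FALSE)
      add_dom("SET_C", "SET_C")
      add_dom("POST_SET", "POST_SET")
      if ("CTD" %in% pres) add_dom("CTD", "CTD")
      if ("M_C" %in% pres) add_dom("MYND_EXTRA", "M_C")
      if ("ACIDIC" %in% pres) add_dom("ACIDIC", "ACIDIC")
      if ("TPR" %in% pres) {
        sp <- span("TPR")
        ann_rows[[length(ann_rows) + 1]] <- data.frame(
          id = nm, type = "TPR_N", start = sp[1], end = sp[2],
          stringsAsFactors = FALSE)
      }
      if ("CTD" %in% pres) {
        sp <- span("CTD")
        ann_rows[[length(ann_rows) + 1]] <- data.frame(
          id = nm, type = "CTD", start = sp[1], end = sp[2],
          stringsAsFactors = FALSE)
      }
    }
  }

  truth_table <- do.call(rbind, c(unname(truth_rows),
                                  list(make.row.names = FALSE)))
  anchors <- do.call(rbind, lapply(classes, function(cl) {
    ids <- tip_names[[cl]]
    if (cl == "SMYD4" && length(cfg$smyd4_subgroups) > 1) {
      first_per_group <- tapply(ids, subgroup_of[ids], `[`, 1)
      data.frame(id = unname(first_per_group), class = cl,
                 subgroup = names(first_per_group), stringsAsFactors = FALSE)
    } else {
      data.frame(id = ids[1], class = cl, subgroup = NA_character_,
                 stringsAsFactors = FALSE)
    }
  }))
  core_span_of <- function(nm) {
    dr <- do.call(rbind, domain_rows)
    sn <- dr[dr$id == nm & dr$type == "SET_N", ]
    ps <- dr[dr$id == nm & dr$type == "POST_SET", ]
    c(sn$start[1], ps$end[1])
  }
  core_spans <- t(vapply(names(seqs), core_span_of, numeric(2)))
  colnames(core_spans) <- c("start", "end")

  list(seqs = seqs, alignment = as_alignment(aln),
       truth = list(tree = tree, table = truth_table,
                    fingers = finger_truth,
                    domains = do.call(rbind, c(domain_rows,
                                               list(make.row.names = FALSE))),
                    core_spans = core_spans),
       annotations = do.call(rbind, c(ann_rows,
                                      list(make.row.names = FALSE))),
       anchors = anchors, config = cfg)
}
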