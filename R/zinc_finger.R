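#' Load the MYND cross-brace Zn-finger signature
#'
#' Reads the bundled (or a user-supplied) signature file describing the
#' MYND-type cross-brace Zn finger: eight ligand slots grouped in four pairs
#' (pairs 1 and 3 bind the first Zn ion, pairs 2 and 4 the second), short
#' invariant within-pair spacing and longer variable spacers between pairs.
#' The bundled file is a synthetic reconstruction of the public signature,
#' built from the motif's published description, and is the single source of
#' truth for the unrelaxed bounds.
#'
#' @param path signature TSV; default the bundled
#'   `mynd_zf_pattern_synthetic.tsv`.
#' @return a `zn_pattern` list with `ligand_allowed` (8 character vectors),
#'   `gap_min`/`gap_max` (7 gaps between consecutive ligands) and `gap_loc`
#'   (gap names: `pair_1`, `spacer_1_2`, `pair_2`, `spacer_2_3`, `pair_3`,
#'   `spacer_3_4`, `pair_4`).
#' @export
load_zn_pattern <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mynd_zf_pattern_synthetic.tsv",
                        package = "smydfam")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  lig <- tab[tab$type == "ligand", , drop = FALSE]
  gap <- tab[tab$type == "gap", , drop = FALSE]
  if (nrow(lig) != 8 || nrow(gap) != 7) {
    stop("signature file must define 8 ligand slots and 7 gaps")
  }
  gmin <- as.integer(gap$min)
  gmax <- as.integer(gap$max)
  if (any(gmin < 0) || any(gmin > gmax)) stop("invalid gap bounds in signature")
  structure(list(
    ligand_allowed = lapply(strsplit(lig$allowed, ""), toupper),
    gap_min = gmin,
    gap_max = gmax,
    gap_loc = c("pair_1", "spacer_1_2", "pair_2", "spacer_2_3",
                "pair_3", "spacer_3_4", "pair_4")
  ), class = "zn_pattern")
}

SPACER_GAPS <- c(2L, 4L, 6L)  # gap indices that are between-pair spacers
PAIR_GAPS <- c(1L, 3L, 5L, 7L)

#' Relaxation policy for Zn-finger search
#'
#' Controls how far beyond the unrelaxed signature the search may reach.
#' Deviations are always reported relative to the unrelaxed signature.
#'
#' @param spacer_over residues a between-pair spacer may exceed its upper
#'   bound (default 100, enough to reach the longest spacers seen in plant
#'   Smyd relatives).
#' @param spacer_under residues a spacer may undershoot its lower bound
#'   (default 3).
#' @param pair_slack residues of slack on the short within-pair gaps
#'   (default 1).
#' @param allow_his_cys_swap allow His at Cys slots and vice versa
#'   (default `TRUE`).
#' @param allow_glu allow glutamic acid as a ligand (default `FALSE`).
#' @param allow_half when no full finger is found, search for half fingers
#'   (pairs 1 and 3 only, binding a single Zn ion; default `TRUE`).
#' @return a `relax_policy` list.
#' @export
relax_policy <- function(spacer_over = 100, spacer_under = 3, pair_slack = 1,
                         allow_his_cys_swap = TRUE, allow_glu = FALSE,
                         allow_half = TRUE) {
  stopifnot(spacer_over >= 0, spacer_under >= 0, pair_slack >= 0)
  structure(list(spacer_over = spacer_over, spacer_under = spacer_under,
                 pair_slack = pair_slack,
                 allow_his_cys_swap = allow_his_cys_swap,
                 allow_glu = allow_glu, allow_half = allow_half),
            class = "relax_policy")
}

relaxed_gap_bounds <- function(pattern, relax) {
  lo <- pattern$gap_min
  hi <- pattern$gap_max
  lo[SPACER_GAPS] <- pmax(0L, lo[SPACER_GAPS] - relax$spacer_under)
  hi[SPACER_GAPS] <- hi[SPACER_GAPS] + relax$spacer_over
  lo[PAIR_GAPS] <- pmax(0L, lo[PAIR_GAPS] - relax$pair_slack)
  hi[PAIR_GAPS] <- hi[PAIR_GAPS] + relax$pair_slack
  list(lo = lo, hi = hi)
}

relaxed_ligand_sets <- function(pattern, relax) {
  lapply(pattern$ligand_allowed, function(allowed) {
    s <- allowed
    if (relax$allow_his_cys_swap) s <- union(s, c("C", "H"))
    if (relax$allow_glu) s <- union(s, "E")
    s
  })
}

# Deviation list of a candidate ligand-position vector against the UNRELAXED
# pattern. `positions`/`residues` have length 8 (full) or 4 (half, pairs 1&3).
finger_deviations <- function(positions, residues, pattern, half = FALSE) {
  dev <- list()
  add <- function(kind, location, detail) {
    dev[[length(dev) + 1]] <<- data.frame(kind = kind, location = location,
                                          detail = detail,
                                          stringsAsFactors = FALSE)
  }
  if (half) {
    slot_idx <- c(1L, 2L, 5L, 6L)
    gaps <- diff(positions) - 1L
    glo <- c(pattern$gap_min[1],
             pattern$gap_min[2] + pattern$gap_min[3] + 2L + pattern$gap_min[4],
             pattern$gap_min[5])
    ghi <- c(pattern$gap_max[1],
             pattern$gap_max[2] + pattern$gap_max[3] + 2L + pattern$gap_max[4],
             pattern$gap_max[5])
    gloc <- c("pair_1", "spacer_1_3", "pair_3")
    add("missing_pair", "pair_2", "half finger: pair 2 absent")
    add("missing_pair", "pair_4", "half finger: pair 4 absent")
  } else {
    slot_idx <- 1:8
    gaps <- diff(positions) - 1L
    glo <- pattern$gap_min
    ghi <- pattern$gap_max
    gloc <- pattern$gap_loc
  }
  for (g in seq_along(gaps)) {
    if (gaps[g] > ghi[g]) {
      add("spacing_long", gloc[g],
          sprintf("%d residues (signature %d-%d)", gaps[g], glo[g], ghi[g]))
    } else if (gaps[g] < glo[g]) {
      add("spacing_short", gloc[g],
          sprintf("%d residues (signature %d-%d)", gaps[g], glo[g], ghi[g]))
    }
  }
  for (k in seq_along(slot_idx)) {
    allowed <- pattern$ligand_allowed[[slot_idx[k]]]
    if (!residues[k] %in% allowed) {
      add("ligand_substitution", paste0("L", slot_idx[k]),
          sprintf("%s at %d (signature %s)", residues[k], positions[k],
                  paste(allowed, collapse = "/")))
    }
  }
  if (length(dev)) do.call(rbind, dev) else
    data.frame(kind = character(0), location = character(0),
               detail = character(0), stringsAsFactors = FALSE)
}

new_zn_hit <- function(positions, residues, pattern, half = FALSE) {
  dev <- finger_deviations(positions, residues, pattern, half = half)
  hit <- structure(list(positions = positions, residues = residues,
                        half = half, deviations = dev, score = nrow(dev),
                        span = positions[length(positions)] - positions[1] + 1,
                        category = NA_character_),
                   class = "zn_hit")
  hit$category <- categorize(hit, pattern)
  hit
}

#' @export
print.zn_hit <- function(x, ...) {
  lab <- if (x$half) "half MYND-type Zn finger" else "MYND-type Zn finger"
  cat(sprintf("%s [%s], score %d\n", lab, x$category, x$score))
  cat("  ligands:", paste(sprintf("%s%d", x$residues, x$positions),
                          collapse = " "), "\n")
  if (nrow(x$deviations)) {
    cat("  deviations:\n")
    for (i in seq_len(nrow(x$deviations))) {
      cat(sprintf("    %s @ %s: %s\n", x$deviations$kind[i],
                  x$deviations$location[i], x$deviations$detail[i]))
    }
  }
  invisible(x)
}

#' Enumerate candidate cross-brace Zn fingers in a protein sequence
#'
#' Depth-first search over ligand-capable residues (Cys/His, optionally Glu)
#' for octets satisfying the relaxed signature bounds. Every returned hit
#' carries its complete deviation list relative to the unrelaxed signature
#' and a category (see [categorize()]). When no full finger exists and the
#' policy allows it, half fingers (pairs 1 and 3 only) are searched instead.
#'
#' @param seq residue string (or length-1 named character vector).
#' @param pattern a [load_zn_pattern()] signature.
#' @param region optional `c(start, end)` 1-based span restricting the
#'   search; positions in hits stay in full-sequence coordinates.
#' @param relax a [relax_policy()].
#' @return list of `zn_hit` objects (possibly empty), deduplicated.
#' @export
enumerate_candidate_fingers <- function(seq, pattern = load_zn_pattern(),
                                        region = NULL,
                                        relax = relax_policy()) {
  s <- unname(seq[[1]])
  n <- nchar(s)
  if (is.null(region)) region <- c(1L, n)
  if (region[1] < 1 || region[2] > n || region[1] > region[2]) {
    stop("region [", region[1], ", ", region[2],
         "] outside sequence of length ", n)
  }
  res <- strsplit(substr(s, region[1], region[2]), "")[[1]]
  offset <- region[1] - 1L
  cand_set <- unique(unlist(relaxed_ligand_sets(pattern, relax)))
  cand_pos <- which(res %in% cand_set)
  bounds <- relaxed_gap_bounds(pattern, relax)
  lig_sets <- relaxed_ligand_sets(pattern, relax)

  search_chain <- function(sets, lo, hi) {
    k <- length(sets)
    hits <- list()
    recurse <- function(slot, chosen) {
      if (slot > k) {
        hits[[length(hits) + 1]] <<- chosen
        return()
      }
      prev <- chosen[length(chosen)]
      lo_p <- prev + lo[slot - 1] + 1L
      hi_p <- prev + hi[slot - 1] + 1L
      ok <- cand_pos[cand_pos >= lo_p & cand_pos <= hi_p]
      ok <- ok[res[ok] %in% sets[[slot]]]
      for (p in ok) recurse(slot + 1L, c(chosen, p))
    }
    starts <- cand_pos[res[cand_pos] %in% sets[[1]]]
    for (p in starts) recurse(2L, p)
    hits
  }

  octets <- search_chain(lig_sets, bounds$lo, bounds$hi)
  hits <- lapply(octets, function(pos) {
    new_zn_hit(pos + offset, res[pos], pattern, half = FALSE)
  })
  if (length(hits) == 0 && isTRUE(relax$allow_half)) {
    half_sets <- lig_sets[c(1, 2, 5, 6)]
    lo <- c(bounds$lo[1],
            bounds$lo[2] + bounds$lo[3] + 2L + bounds$lo[4],
            bounds$lo[5])
    hi <- c(bounds$hi[1],
            bounds$hi[2] + bounds$hi[3] + 2L + bounds$hi[4],
            bounds$hi[5])
    quads <- search_chain(half_sets, lo, hi)
    hits <- lapply(quads, function(pos) {
      new_zn_hit(pos + offset, res[pos], pattern, half = TRUE)
    })
  }
  hits
}

#' Exhaustive brute-force Zn-finger enumeration (reference implementation)
#'
#' Independent oracle for [enumerate_candidate_fingers()]: enumerates every
#' combination of eight ligand-capable positions and filters by the relaxed
#' bounds. Feasible only for sequences with few candidate ligands; used in
#' validation, never in the pipeline.
#'
#' @inheritParams enumerate_candidate_fingers
#' @return list of `zn_hit` objects.
#' @export
enumerate_fingers_bruteforce <- function(seq, pattern = load_zn_pattern(),
                                         region = NULL,
                                         relax = relax_policy()) {
  s <- unname(seq[[1]])
  n <- nchar(s)
  if (is.null(region)) region <- c(1L, n)
  res <- strsplit(substr(s, region[1], region[2]), "")[[1]]
  offset <- region[1] - 1L
  cand_set <- unique(unlist(relaxed_ligand_sets(pattern, relax)))
  cand <- which(res %in% cand_set)
  bounds <- relaxed_gap_bounds(pattern, relax)
  lig_sets <- relaxed_ligand_sets(pattern, relax)
  hits <- list()
  if (length(cand) >= 8) {
    combos <- utils::combn(cand, 8)
    for (j in seq_len(ncol(combos))) {
      pos <- combos[, j]
      gaps <- diff(pos) - 1L
      if (any(gaps < bounds$lo) || any(gaps > bounds$hi)) next
      ok <- TRUE
      for (k in 1:8) {
        if (!res[pos[k]] %in% lig_sets[[k]]) { ok <- FALSE; break }
      }
      if (ok) {
        hits[[length(hits) + 1]] <- new_zn_hit(pos + offset, res[pos],
                                               pattern, half = FALSE)
      }
    }
  }
  hits
}

#' Pick the best Zn-finger hit
#'
#' Minimum deviation score; ties broken by leftmost first ligand, then by
#' smallest total span.
#'
#' @param hits list of `zn_hit` objects.
#' @return a `zn_hit`, or `NULL` when `hits` is empty.
#' @export
best_finger <- function(hits) {
  if (length(hits) == 0) return(NULL)
  score <- vapply(hits, `[[`, numeric(1), "score")
  p1 <- vapply(hits, function(h) h$positions[1], numeric(1))
  span <- vapply(hits, `[[`, numeric(1), "span")
  hits[[order(score, p1, span)[1]]]
}

LEFT_LOCS <- c("pair_1", "spacer_1_2", "pair_2", "L1", "L2", "L3", "L4")
RIGHT_LOCS <- c("pair_3", "spacer_3_4", "pair_4", "L5", "L6", "L7", "L8")

#' Categorize a Zn-finger hit
#'
#' `canonical` when the deviation list is empty; `half` for four-ligand hits
#' (pairs 1 and 3 only); `partial_left` / `partial_right` when exactly one
#' contiguous half of the finger (pairs 1-2 with their spacer, or pairs 3-4
#' with theirs) is deviation-free; `atypical` otherwise (e.g. a C3H-C3H
#' arrangement, or deviations confined to the central spacer).
#'
#' @param hit a `zn_hit`.
#' @param pattern the signature (unused beyond validation; categories depend
#'   only on the deviation list already stored in the hit).
#' @return category string.
#' @export
categorize <- function(hit, pattern = NULL) {
  if (isTRUE(hit$half)) return("half")
  dev <- hit$deviations
  if (nrow(dev) == 0) return("canonical")
  left_clean <- !any(dev$location %in% LEFT_LOCS)
  right_clean <- !any(dev$location %in% RIGHT_LOCS)
  if (right_clean && !left_clean) return("partial_right")
  if (left_clean && !right_clean) return("partial_left")
  "atypical"
}

#' Secondary-structure consistency of a Zn-finger hit
#'
#' A cross-brace MYND finger is expected to show a beta strand just upstream
#' of ligand pair 3 and an alpha helix spanning pairs 3 to 4. `supported`
#' requires an E-state run (>= 2) inside the `window` residues upstream of
#' pair 3 and an H-state run (>= 3) overlapping the pair-3-to-pair-4 span.
#'
#' @param hit a full `zn_hit`.
#' @param ss per-residue predicted states (`"H"`, `"E"`, `"-"`), as a single
#'   string or character vector covering the whole protein; `NULL` for no
#'   prediction.
#' @param window residues upstream of pair 3 searched for the strand
#'   (default 8).
#' @return `"supported"`, `"unsupported"`, or `"no_data"`.
#' @export
ss_consistency <- function(hit, ss, window = 8) {
  if (is.null(ss)) return("no_data")
  states <- if (length(ss) == 1 && nchar(ss[[1]]) > 1) {
    strsplit(ss[[1]], "")[[1]]
  } else as.character(ss)
  if (isTRUE(hit$half)) {
    p5 <- hit$positions[3]; p8 <- hit$positions[4]
  } else {
    p5 <- hit$positions[5]; p8 <- hit$positions[8]
  }
  if (p8 > length(states)) {
    stop("secondary-structure track (", length(states),
         ") shorter than the finger span (", p8, ")")
  }
  has_run <- function(x, state, len) {
    r <- rle(x == state)
    any(r$values & r$lengths >= len)
  }
  up <- states[max(1, p5 - window):(p5 - 1)]
  strand <- has_run(up, "E", 2)
  helix <- has_run(states[p5:p8], "H", 3)
  if (strand && helix) "supported" else "unsupported"
}

#' Per-sequence Zn-finger report
#'
#' Scans each sequence and reports, per sequence, every non-overlapping
#' finger found (best first, then the best hit disjoint from those already
#' reported, and so on) with its category, ligand positions, between-pair
#' spacer lengths and deviation summary. Sequences with no hit get a single
#' row with category `"none"`.
#'
#' @param seqs named character vector of residue strings.
#' @param pattern a [load_zn_pattern()] signature.
#' @param relax a [relax_policy()].
#' @param region optional span applied to every sequence.
#' @return data frame with columns id, category, p1..p8, spacer12, spacer23,
#'   spacer34, score, deviations.
#' @export
finger_report <- function(seqs, pattern = load_zn_pattern(),
                          relax = relax_policy(), region = NULL) {
  empty <- data.frame(id = character(0), category = character(0),
                      p1 = numeric(0), p2 = numeric(0), p3 = numeric(0),
                      p4 = numeric(0), p5 = numeric(0), p6 = numeric(0),
                      p7 = numeric(0), p8 = numeric(0),
                      spacer12 = numeric(0), spacer23 = numeric(0),
                      spacer34 = numeric(0), score = numeric(0),
                      deviations = character(0), stringsAsFactors = FALSE)
  if (length(seqs) == 0) return(empty)
  rows <- list()
  for (id in names(seqs)) {
    hits <- enumerate_candidate_fingers(seqs[[id]], pattern, region, relax)
    sel <- list()
    while (length(hits) > 0) {
      b <- best_finger(hits)
      sel[[length(sel) + 1]] <- b
      lo <- b$positions[1]; hi <- b$positions[length(b$positions)]
      hits <- Filter(function(h) {
        h$positions[length(h$positions)] < lo || h$positions[1] > hi
      }, hits)
    }
    if (length(sel) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        id = id, category = "none", p1 = NA, p2 = NA, p3 = NA, p4 = NA,
        p5 = NA, p6 = NA, p7 = NA, p8 = NA, spacer12 = NA, spacer23 = NA,
        spacer34 = NA, score = NA, deviations = "", stringsAsFactors = FALSE)
    } else {
      for (h in sel) {
        p <- rep(NA_integer_, 8)
        if (h$half) p[c(1, 2, 5, 6)] <- h$positions else p <- h$positions
        gaps <- diff(h$positions) - 1L
        sp <- if (h$half) c(NA, NA, NA) else gaps[SPACER_GAPS]
        devs <- if (nrow(h$deviations)) {
          paste(sprintf("%s@%s", h$deviations$kind, h$deviations$location),
                collapse = ";")
        } else ""
        rows[[length(rows) + 1]] <- data.frame(
          id = id, category = h$category, p1 = p[1], p2 = p[2], p3 = p[3],
          p4 = p[4], p5 = p[5], p6 = p[6], p7 = p[7], p8 = p[8],
          spacer12 = sp[1], spacer23 = sp[2], spacer34 = sp[3],
          score = h$score, deviations = devs, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
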