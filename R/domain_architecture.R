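#' Detect a C-terminal acidic tract
#'
#' Finds the longest C-terminal-anchored suffix in which the combined
#' fraction of glutamate, aspartate and serine is at least `min_fraction`
#' and whose length is at least `min_len`. The composition class is `E` when
#' glutamate alone reaches the fraction, `ED` when glutamate plus aspartate
#' do, and `EDS` otherwise; such tracts are the C-terminal hallmark of the
#' Smyd5 class (poly-E in vertebrates, E/D in most species, E/D/S in the
#' most basal ones).
#'
#' @param seq residue string.
#' @param min_len minimum tract length (default 10).
#' @param min_fraction minimum qualifying-residue fraction (default 0.6).
#' @return list with `start`, `end`, per-residue fractions and
#'   `composition_class`, or `NULL` when no tract qualifies.
#' @export
detect_acidic_tract <- function(seq, min_len = 10, min_fraction = 0.6) {
  res <- strsplit(unname(seq[[1]]), "")[[1]]
  L <- length(res)
  if (L < min_len) return(NULL)
  qual <- rev(cumsum(rev(res %in% c("E", "D", "S"))))  # qual[i]: count in i..L
  len <- L - seq_len(L) + 1
  ok <- which(qual / len >= min_fraction & len >= min_len)
  if (length(ok) == 0) return(NULL)
  start <- min(ok)  # longest qualifying suffix
  tract <- res[start:L]
  fE <- mean(tract == "E")
  fD <- mean(tract == "D")
  fS <- mean(tract == "S")
  cls <- if (fE >= min_fraction) "E" else if (fE + fD >= min_fraction) "ED" else "EDS"
  list(start = start, end = L, frac_E = fE, frac_D = fD, frac_S = fS,
       composition_class = cls)
}

#' SET-MYND core coordinates on an ungapped protein
#'
#' Span of the interrupted SET domain with its embedded MYND finger and the
#' post-SET region, in 1-based protein coordinates.
#'
#' @param set_n,mynd,set_c,post_set integer `c(start, end)` spans in
#'   N-to-C order; `mynd` sits inside the interruption of the SET domain.
#' @return a `smyd_core` list.
#' @export
smyd_core <- function(set_n, mynd, set_c, post_set) {
  spans <- list(SET_N = set_n, MYND = mynd, SET_C = set_c,
                POST_SET = post_set)
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    if (length(sp) != 2 || sp[1] > sp[2]) stop("bad span for ", nm)
  }
  starts <- vapply(spans, `[`, numeric(1), 1)
  if (is.unsorted(starts)) stop("core spans out of order")
  structure(spans, class = "smyd_core")
}

DOMAIN_TYPES <- c("TPR_N", "SET_N", "MYND", "SET_C", "POST_SET", "CTD",
                  "MYND_EXTRA", "ACIDIC")

#' Assemble a per-protein domain architecture
#'
#' Merges the core spans, the detected Zn finger, the detected acidic tract
#' and any external annotations (e.g. PFAM/InterPro results supplied as a
#' data frame) into an ordered annotation table with a class-diagnostic
#' signature string such as `"TPR_N|S/ET+M|CTD"`. Zn fingers outside the
#' core become `MYND_EXTRA`; overlapping annotations of the same type are
#' merged. External annotations take precedence over heuristic detections of
#' the same type.
#'
#' @param seq residue string.
#' @param core a [smyd_core()] (or `NULL` if unknown).
#' @param finger the core `zn_hit` from [best_finger()] (or `NULL`).
#' @param extra_fingers optional list of additional `zn_hit`s outside the
#'   core (reported as `MYND_EXTRA`).
#' @param external optional data frame of external annotations with columns
#'   `type`, `start`, `end` (types from `TPR_N`, `CTD`, `MYND`, ...).
#' @param acidic result of [detect_acidic_tract()]; computed from `seq` when
#'   missing.
#' @return an `architecture` list: `annotations` (ordered data frame),
#'   `signature`, `finger_category`.
#' @export
assemble_architecture <- function(seq, core = NULL, finger = NULL,
                                  extra_fingers = list(), external = NULL,
                                  acidic = detect_acidic_tract(seq)) {
  L <- nchar(unname(seq[[1]]))
  ann <- list()
  add <- function(type, start, end, source) {
    if (start > end || start < 1 || end > L) {
      stop("annotation ", type, " [", start, ", ", end,
           "] outside sequence of length ", L)
    }
    ann[[length(ann) + 1]] <<- data.frame(type = type, start = start,
                                          end = end, source = source,
                                          stringsAsFactors = FALSE)
  }
  if (!is.null(core)) {
    for (nm in names(core)) add(nm, core[[nm]][1], core[[nm]][2], "detector")
  }
  core_lo <- if (!is.null(core)) core$SET_N[1] else NA
  core_hi <- if (!is.null(core)) core$POST_SET[2] else NA
  place_finger <- function(h) {
    lo <- h$positions[1]
    hi <- h$positions[length(h$positions)]
    inside <- !is.na(core_lo) && lo >= core_lo && hi <= core_hi
    add(if (inside) "MYND" else "MYND_EXTRA", lo, hi, "detector")
  }
  if (!is.null(finger)) place_finger(finger)
  for (h in extra_fingers) place_finger(h)
  if (!is.null(acidic)) add("ACIDIC", acidic$start, acidic$end, "detector")
  if (!is.null(external) && nrow(external)) {
    for (i in seq_len(nrow(external))) {
      add(external$type[i], external$start[i], external$end[i], "external")
    }
  }
  tab <- if (length(ann)) do.call(rbind, ann) else
    data.frame(type = character(0), start = numeric(0), end = numeric(0),
               source = character(0), stringsAsFactors = FALSE)
  # merge overlaps within type
  merged <- list()
  for (tp in unique(tab$type)) {
    sub <- tab[tab$type == tp, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cur <- sub[1, ]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= cur$end + 1) {
        cur$end <- max(cur$end, sub$end[i])
        if (sub$source[i] == "external") cur$source <- "external"
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- sub[i, ]
      }
    }
    merged[[length(merged) + 1]] <- cur
  }
  tab <- if (length(merged)) do.call(rbind, merged) else tab
  tab <- tab[order(tab$start, tab$end), , drop = FALSE]
  rownames(tab) <- NULL

  has_core <- !is.null(core)
  mynd_extra <- tab[tab$type == "MYND_EXTRA", , drop = FALSE]
  extra_n <- has_core && any(mynd_extra$end < core_lo)
  extra_c <- has_core && any(mynd_extra$start > core_hi)
  parts <- c(
    if (extra_n) "M",
    if (any(tab$type == "TPR_N")) "TPR_N",
    if (has_core) "S/ET+M",
    if (any(tab$type == "CTD")) "CTD",
    if (extra_c) "M",
    if (!is.null(acidic)) acidic$composition_class
  )
  structure(list(annotations = tab,
                 signature = paste(parts, collapse = "|"),
                 finger_category = if (!is.null(finger)) finger$category
                                   else NA_character_,
                 acidic = acidic,
                 mynd_extra_n = extra_n, mynd_extra_c = extra_c),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat("architecture:", x$signature,
      if (!is.na(x$finger_category)) paste0("(core finger: ",
                                            x$finger_category, ")"), "\n")
  print(x$annotations)
  invisible(x)
}

#' Candidate Smyd classes of an architecture
#'
#' Pure function of the class-diagnostic signature (and the core-finger
#' category for the SmydA rule): core + C-terminal TPR-fold domain (CTD)
#' without an N-terminal TPR gives `SMYD3`; TPR_N + core + CTD gives
#' `SMYD4`; core + acidic tract without CTD or TPR_N gives `SMYD5`;
#' TPR_N + core + C-terminal extra MYND finger gives `ATYPICAL_TPR`;
#' a bare core (optionally with an N-terminal extra MYND finger) whose core
#' finger is non-canonical gives `SMYDA`. Anything else yields an empty set,
#' to be resolved by tree evidence.
#'
#' @param arch an [assemble_architecture()] result.
#' @return character vector of candidate class labels (possibly empty).
#' @export
architecture_class <- function(arch) {
  stopifnot(inherits(arch, "architecture"))
  types <- arch$annotations$type
  has <- function(t) t %in% types
  core <- has("SET_N") && has("SET_C")
  if (!core) return(character(0))
  tpr <- has("TPR_N")
  ctd <- has("CTD")
  acidic <- has("ACIDIC")
  if (ctd && !tpr) return("SMYD3")
  if (ctd && tpr) return("SMYD4")
  if (acidic && !ctd && !tpr) return("SMYD5")
  if (tpr && !ctd && arch$mynd_extra_c) return("ATYPICAL_TPR")
  if (!tpr && !ctd && !acidic && !arch$mynd_extra_c &&
      !is.na(arch$finger_category) && arch$finger_category != "canonical") {
    return("SMYDA")
  }
  character(0)
}

#' Load the bundled synthetic TPR profile
#' @param path profile TSV; default the bundled
#'   `tpr_profile_synthetic.tsv`.
#' @return 34 x 20 numeric score matrix (rows = repeat positions).
#' @keywords internal
load_tpr_profile <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tpr_profile_synthetic.tsv",
                        package = "smydfam")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  prof <- matrix(0, nrow = 34, ncol = length(AA_LETTERS),
                 dimnames = list(NULL, AA_LETTERS))
  for (i in seq_len(nrow(tab))) {
    for (r in strsplit(tab$residues[i], "")[[1]]) {
      prof[tab$position[i], r] <- tab$weight[i]
    }
  }
  prof
}

#' Heuristic detection of N-terminal TPR repeat blocks
#'
#' Scores every 34-residue window against the bundled synthetic TPR
#' position-weight profile and merges above-threshold windows (allowing
#' tandem repeats) into blocks. A fallback for running the synthetic
#' pipeline without external domain-scanning tools: always subordinate to
#' external annotations when both exist.
#'
#' @param seq residue string.
#' @param threshold minimum window score (default 12; a consensus repeat
#'   scores 15, random sequence stays below about 11).
#' @param profile score matrix from [load_tpr_profile()].
#' @return data frame of annotations (`type = "TPR_N"`, `source =
#'   "detector"`), zero rows when nothing scores above threshold.
#' @export
detect_tpr_heuristic <- function(seq, threshold = 12,
                                 profile = load_tpr_profile()) {
  res <- strsplit(unname(seq[[1]]), "")[[1]]
  L <- length(res)
  none <- data.frame(type = character(0), start = numeric(0),
                     end = numeric(0), source = character(0),
                     stringsAsFactors = FALSE)
  if (L < 34) return(none)
  idx <- match(res, colnames(profile))
  scores <- vapply(seq_len(L - 33), function(s) {
    cols <- idx[s:(s + 33)]
    sum(profile[cbind(seq_len(34), cols)], na.rm = TRUE)
  }, numeric(1))
  hits <- which(scores >= threshold)
  if (length(hits) == 0) return(none)
  blocks <- list()
  cur <- c(hits[1], hits[1] + 33)
  for (s in hits[-1]) {
    if (s <= cur[2] + 1) cur[2] <- s + 33 else {
      blocks[[length(blocks) + 1]] <- cur
      cur <- c(s, s + 33)
    }
  }
  blocks[[length(blocks) + 1]] <- cur
  do.call(rbind, lapply(blocks, function(b) {
    data.frame(type = "TPR_N", start = b[1], end = b[2], source = "detector",
               stringsAsFactors = FALSE)
  }))
}
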