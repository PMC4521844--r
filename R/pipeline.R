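#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end classification run:
#' input alignment (user-supplied or the generator's true alignment), core
#' coordinates on the reference, column policy, distance model, bootstrap
#' settings, anchors, external annotations and the support threshold.
#'
#' @param alignment named character vector of gapped rows.
#' @param core a [core_region()] naming a reference row.
#' @param anchors anchor data frame (see [read_anchors()]).
#' @param model a [distance_model()].
#' @param policy a [column_policy()].
#' @param bootstrap `NULL` to skip, or a [bootstrap_config()] (seed
#'   mandatory).
#' @param external optional annotation data frame (`id`, `type`, `start`,
#'   `end`).
#' @param min_support clade support threshold for classification
#'   (default 70).
#' @param pattern a [load_zn_pattern()] signature.
#' @param relax a [relax_policy()].
#' @param species optional named vector mapping sequence id to species.
#' @param out_dir optional directory for per-stage outputs.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(alignment, core, anchors,
                            model = distance_model(),
                            policy = column_policy("pairwise_deletion"),
                            bootstrap = NULL, external = NULL,
                            min_support = 70,
                            pattern = load_zn_pattern(),
                            relax = relax_policy(), species = NULL,
                            out_dir = NULL) {
  if (is.null(anchors) || nrow(anchors) == 0) {
    stop("configuration error: anchors are required for classification")
  }
  if (!inherits(core, "core_region")) stop("core must be a core_region")
  if (!core$reference %in% names(alignment)) {
    stop("configuration error: core reference '", core$reference,
         "' not in alignment")
  }
  missing_anchor <- setdiff(anchors$id, names(alignment))
  if (length(missing_anchor)) {
    stop("configuration error: anchor(s) not in alignment: ",
         paste(missing_anchor, collapse = ", "))
  }
  structure(list(alignment = as_alignment(alignment), core = core,
                 anchors = anchors, model = model, policy = policy,
                 bootstrap = bootstrap, external = external,
                 min_support = min_support, pattern = pattern,
                 relax = relax, species = species, out_dir = out_dir),
            class = "pipeline_config")
}

# per-row ungapped span corresponding to the extracted core block
core_spans_from_block <- function(al, block_cols) {
  t(vapply(names(al), function(id) {
    row <- strsplit(al[[id]], "")[[1]]
    before <- sum(row[seq_len(block_cols[1] - 1)] != "-")
    inside <- sum(row[block_cols[1]:block_cols[2]] != "-")
    if (inside == 0) return(c(NA_real_, NA_real_))
    c(before + 1, before + inside)
  }, numeric(2)))
}

#' Run the full Smyd classification pipeline
#'
#' Stages: core extraction from the alignment, distance matrix and
#' neighbor-joining tree (with optional bootstrap supports), Zn-finger scan
#' (core finger within each sequence's core span, extra fingers outside),
#' domain-architecture assembly (detectors plus external annotations), and
#' combined tree-plus-architecture class and subgroup assignment. Stage
#' failures abort with the stage name; outputs computed so far are attached
#' to the error condition.
#'
#' @param cfg a [pipeline_config()].
#' @return a `smyd_classification` object: list with `tree`, `assignments`,
#'   `summary` (per sequence: class, subgroup, finger category, signature,
#'   clade support), `class_counts`, `architectures`, `fingers`, `core`,
#'   `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines,
                    paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  note("pipeline start: ", length(cfg$alignment), " sequences, model ",
       cfg$model$kind, ", policy ", cfg$policy$mode)

  core_al <- stage("core", extract_core(cfg$alignment, cfg$core))
  block <- attr(core_al, "columns")
  spans <- core_spans_from_block(cfg$alignment, block)
  note("core block: alignment columns ", block[1], "-", block[2])

  tree <- stage("tree", {
    D <- distance_matrix(core_al, cfg$model, cfg$policy)
    tr <- neighbor_joining(D)
    if (!is.null(cfg$bootstrap)) {
      tr <- bootstrap_support(core_al, cfg$model, cfg$policy,
                              cfg$bootstrap, tree = tr)
    }
    tr
  })
  note("NJ tree built",
       if (!is.null(cfg$bootstrap)) paste0(" (", cfg$bootstrap$n_replicates,
                                           " bootstrap replicates)"))

  seqs <- gsub("-", "", cfg$alignment, fixed = TRUE)
  fingers <- stage("scan-fingers", {
    lapply(stats::setNames(names(seqs), names(seqs)), function(id) {
      span <- spans[id, ]
      hits <- enumerate_candidate_fingers(seqs[[id]], cfg$pattern,
                                          relax = cfg$relax)
      in_core <- Filter(function(h) {
        !anyNA(span) && h$positions[1] >= span[1] &&
          h$positions[length(h$positions)] <= span[2]
      }, hits)
      core_best <- best_finger(in_core)
      outside <- Filter(function(h) {
        anyNA(span) || h$positions[length(h$positions)] < span[1] ||
          h$positions[1] > span[2]
      }, hits)
      extras <- list()
      while (length(outside) > 0) {
        b <- best_finger(outside)
        extras[[length(extras) + 1]] <- b
        lo <- b$positions[1]; hi <- b$positions[length(b$positions)]
        outside <- Filter(function(h) {
          h$positions[length(h$positions)] < lo || h$positions[1] > hi
        }, outside)
      }
      list(core = core_best, extra = extras)
    })
  })
  note("finger scan done")

  arch <- stage("scan-domains", {
    lapply(stats::setNames(names(seqs), names(seqs)), function(id) {
      span <- spans[id, ]
      fg <- fingers[[id]]
      core <- NULL
      if (!anyNA(span)) {
        p <- if (!is.null(fg$core)) fg$core$positions else NULL
        core <- if (!is.null(p) && p[1] > span[1] &&
                    p[length(p)] < span[2] - 34) {
          smyd_core(set_n = c(span[1], p[1] - 1),
                    mynd = c(p[1], p[length(p)]),
                    set_c = c(p[length(p)] + 1, span[2] - 34),
                    post_set = c(span[2] - 33, span[2]))
        } else NULL
      }
      ext <- cfg$external
      if (!is.null(ext)) ext <- ext[ext$id == id, , drop = FALSE]
      assemble_architecture(seqs[[id]], core = core, finger = fg$core,
                            extra_fingers = fg$extra, external = ext)
    })
  })
  note("architecture assembly done")

  assignments <- stage("classify", {
    a <- assign_classes(tree, arch, cfg$anchors, cfg$min_support)
    assign_subgroups(a, tree, cfg$anchors, cfg$min_support)
  })
  note("classification done")

  summary_tab <- data.frame(
    id = assignments$id,
    class = assignments$class,
    subgroup = assignments$subgroup,
    finger_category = vapply(assignments$id, function(id) {
      f <- fingers[[id]]$core
      if (is.null(f)) "none" else f$category
    }, character(1)),
    signature = vapply(assignments$id, function(id) {
      arch[[id]]$signature
    }, character(1)),
    clade_support = assignments$clade_support,
    evidence = assignments$evidence,
    stringsAsFactors = FALSE)
  counts <- species_class_counts(assignments, cfg$species)

  out <- structure(list(tree = tree, assignments = assignments,
                        summary = summary_tab, class_counts = counts,
                        architectures = arch, fingers = fingers,
                        core_alignment = core_al, config = cfg,
                        log = log_lines),
                   class = "smyd_classification")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summary_tab,
                       file.path(cfg$out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(assignments,
                       file.path(cfg$out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_newick(tree, file.path(cfg$out_dir, "tree.nwk"))
    write_fasta(core_al, file.path(cfg$out_dir, "core_alignment.fasta"))
    writeLines(log_lines, file.path(cfg$out_dir, "pipeline.log"))
  }
  out
}

#' Class counts per species
#'
#' Cross-tabulates assignments by species and class (classes with assigned
#' subgroups are split into `CLASS:SUBGROUP` columns), the per-genome
#' class-catalog view of a classification.
#'
#' @param assignments output of [assign_classes()] (or the `assignments`
#'   element of a pipeline result).
#' @param species named vector mapping sequence id to species; ids missing
#'   from it are grouped under `"unspecified"`. `NULL` puts everything in
#'   one row.
#' @return a contingency table (rows = species, columns = class labels).
#' @export
species_class_counts <- function(assignments, species = NULL) {
  if (nrow(assignments) == 0) return(table(character(0), character(0)))
  sp <- if (is.null(species)) rep("all", nrow(assignments)) else {
    s <- species[assignments$id]
    ifelse(is.na(s), "unspecified", s)
  }
  lab <- ifelse(!is.na(assignments$subgroup),
                paste0(assignments$class, ":", assignments$subgroup),
                assignments$class)
  table(species = sp, class = lab)
}

#' @export
print.smyd_classification <- function(x, ...) {
  cat("Smyd family classification\n")
  cat("  sequences:", nrow(x$assignments), "\n")
  tab <- table(x$assignments$class)
  for (cl in names(tab)) cat(sprintf("  %-13s %d\n", cl, tab[[cl]]))
  boot <- x$config$bootstrap
  cat("  tree: neighbor joining",
      if (!is.null(boot)) sprintf("(%d bootstrap replicates)",
                                  boot$n_replicates) else "(no bootstrap)",
      "\n")
  invisible(x)
}

#' @method summary smyd_classification
#' @export
summary.smyd_classification <- function(object, ...) {
  cat("Per-sequence summary:\n")
  print(object$summary, row.names = FALSE)
  cat("\nClass counts:\n")
  print(object$class_counts)
  invisible(object$summary)
}

#' @method plot smyd_classification
#' @export
plot.smyd_classification <- function(x, ...) {
  cls <- factor(x$assignments$class[match(x$tree$tip.label,
                                          x$assignments$id)])
  cols <- grDevices::hcl.colors(max(3, nlevels(cls)), "Dark 3")
  ape::plot.phylo(x$tree, tip.color = cols[as.integer(cls)],
                  cex = 0.7, ...)
  if (!is.null(x$tree$node.label)) {
    ape::nodelabels(x$tree$node.label, frame = "none", cex = 0.6,
                    adj = c(1.2, -0.3))
  }
  graphics::legend("bottomleft", legend = levels(cls),
                   text.col = cols[seq_len(nlevels(cls))], bty = "n")
  invisible(x)
}
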