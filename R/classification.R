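CLASS_LABELS <- c("SMYD3", "SMYD4", "SMYD5", "SMYDA", "ATYPICAL_TPR",
                  "UNCLASSIFIED")

#' Read an anchor table
#'
#' Anchors are reference sequences of known class (and optionally subgroup)
#' present in the tree; the bundled default carries the five human SMYD
#' proteins plus the Drosophila Smyd4-class genes as subgroup anchors.
#'
#' @param path TSV with columns `id`, `class`, `subgroup`; default the
#'   bundled `smyd_anchors.tsv`.
#' @return data frame with columns id, class, subgroup.
#' @export
read_anchors <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "smyd_anchors.tsv", package = "smydfam")
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("id", "class", "subgroup") %in% names(tab)))
  bad <- setdiff(tab$class, CLASS_LABELS)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  tab$subgroup[tab$subgroup %in% c("NA", "")] <- NA
  tab
}

# numeric support per internal node (NA -> 100: unannotated point tree)
node_supports <- function(tree) {
  s <- attr(tree, "support")
  if (is.null(s)) {
    if (!is.null(tree$node.label)) {
      s <- suppressWarnings(as.numeric(tree$node.label))
    } else {
      s <- rep(NA_real_, tree$Nnode)
    }
  }
  ifelse(is.na(s), 100, s)
}

# all clades induced by internal edges (both sides), with edge support
clade_sides <- function(tree) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  sup <- node_supports(tree)
  out <- list()
  for (k in seq_along(parts)) {
    tips <- labs[parts[[k]]]
    if (length(tips) == n) next     # root
    comp <- setdiff(labs, tips)
    if (length(tips) >= 2) {
      out[[length(out) + 1]] <- list(tips = tips, support = sup[k])
    }
    if (length(comp) >= 2) {
      out[[length(out) + 1]] <- list(tips = comp, support = sup[k])
    }
  }
  out
}

# smallest supported clade containing `leaf` and >=1 anchor whose anchors are
# unanimous; returns list(label, anchors, support) or NULL
smallest_unanimous_clade <- function(leaf, clades, anchor_ids, anchor_label,
                                     min_support) {
  sizes <- vapply(clades, function(cl) length(cl$tips), numeric(1))
  for (k in order(sizes)) {
    cl <- clades[[k]]
    if (cl$support < min_support) next
    if (!leaf %in% cl$tips) next
    inside <- intersect(anchor_ids, cl$tips)
    if (length(inside) == 0) next
    lab <- unique(anchor_label[inside])
    if (length(lab) == 1) {
      return(list(label = lab, anchors = inside, support = cl$support))
    }
  }
  NULL
}

#' Assign Smyd classes from tree clades and architectures
#'
#' For each non-anchor leaf, the smallest clade induced by an internal edge
#' with bootstrap support at least `min_support` that contains the leaf and
#' at least one anchor, with all contained anchors of one class, provides the
#' tentative class. When the architecture proposes candidate classes, the
#' tentative class must be among them; otherwise the assignment is flagged as
#' a disagreement and demoted to `UNCLASSIFIED` (domain structure acts as an
#' independent check, not an override). Leaves in no qualifying clade but
#' with a unique architecture class get that class with architecture-only
#' evidence. Trees without support annotations are treated as fully
#' supported.
#'
#' @param tree [ape::phylo] tree with supports in `node.label` (percentage).
#' @param arch named list of [assemble_architecture()] results (may omit
#'   ids; missing entries contribute no architecture evidence).
#' @param anchors data frame as from [read_anchors()]; all anchor ids must
#'   be tree leaves.
#' @param min_support minimum bootstrap percentage for a clade to count
#'   (default 70).
#' @return data frame with columns id, class, subgroup, evidence,
#'   clade_anchors, clade_support, signature, agreement.
#' @export
assign_classes <- function(tree, arch, anchors, min_support = 70) {
  missing_anchor <- setdiff(anchors$id, tree$tip.label)
  if (length(missing_anchor)) {
    stop("anchor(s) missing from tree: ", paste(missing_anchor, collapse = ", "))
  }
  clades <- clade_sides(tree)
  anchor_class <- stats::setNames(anchors$class, anchors$id)
  rows <- lapply(sort(tree$tip.label), function(leaf) {
    sig <- if (!is.null(arch[[leaf]])) arch[[leaf]]$signature else NA
    if (leaf %in% anchors$id) {
      return(data.frame(id = leaf, class = anchor_class[[leaf]],
                        subgroup = NA_character_, evidence = "anchor",
                        clade_anchors = leaf, clade_support = NA_real_,
                        signature = sig, agreement = NA,
                        stringsAsFactors = FALSE))
    }
    ac <- if (!is.null(arch[[leaf]])) architecture_class(arch[[leaf]])
          else character(0)
    hit <- smallest_unanimous_clade(leaf, clades, anchors$id, anchor_class,
                                    min_support)
    if (!is.null(hit)) {
      agree <- if (length(ac) == 0) NA else hit$label %in% ac
      cls <- if (isFALSE(agree)) "UNCLASSIFIED" else hit$label
      ev <- if (isFALSE(agree)) "tree-architecture disagreement" else "clade"
      return(data.frame(id = leaf, class = cls, subgroup = NA_character_,
                        evidence = ev,
                        clade_anchors = paste(hit$anchors, collapse = ","),
                        clade_support = hit$support, signature = sig,
                        agreement = agree, stringsAsFactors = FALSE))
    }
    if (length(ac) == 1) {
      return(data.frame(id = leaf, class = ac, subgroup = NA_character_,
                        evidence = "architecture-only",
                        clade_anchors = "", clade_support = NA_real_,
                        signature = sig, agreement = NA,
                        stringsAsFactors = FALSE))
    }
    data.frame(id = leaf, class = "UNCLASSIFIED", subgroup = NA_character_,
               evidence = "no rule fired", clade_anchors = "",
               clade_support = NA_real_, signature = sig, agreement = NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Assign subgroups within the Smyd3 and Smyd4 classes
#'
#' Applies the same smallest-anchored-clade logic within a class, using the
#' subgroup-labelled anchors of that class (Smyd1/Smyd2/Smyd3 within the
#' Smyd3 class; Smyd4/Smyd4L/Smyd4I within the Smyd4 class). Leaves in no
#' supported subgroup clade keep an unset subgroup.
#'
#' @param assignments output of [assign_classes()].
#' @param tree the classified tree.
#' @param anchors anchor data frame with non-`NA` `subgroup` entries.
#' @param min_support minimum support (default 70).
#' @return `assignments` with the `subgroup` column filled where possible.
#' @export
assign_subgroups <- function(assignments, tree, anchors, min_support = 70) {
  sub_anchors <- anchors[!is.na(anchors$subgroup), , drop = FALSE]
  if (nrow(sub_anchors) == 0) return(assignments)
  clades <- clade_sides(tree)
  for (i in seq_len(nrow(assignments))) {
    id <- assignments$id[i]
    cls <- assignments$class[i]
    if (!cls %in% c("SMYD3", "SMYD4")) next
    sa <- sub_anchors[sub_anchors$class == cls, , drop = FALSE]
    if (nrow(sa) == 0) next
    if (id %in% sa$id) {
      assignments$subgroup[i] <- sa$subgroup[sa$id == id]
      next
    }
    hit <- smallest_unanimous_clade(
      id, clades, sa$id, stats::setNames(sa$subgroup, sa$id), min_support)
    if (!is.null(hit)) assignments$subgroup[i] <- hit$label
  }
  assignments
}

#' Suggest the closest reference ortholog for a query leaf
#'
#' Returns the anchor with minimal patristic distance to the query; ties are
#' broken by the higher support along the connecting path (minimum edge
#' support on the path), then lexicographically.
#'
#' @param query tip label.
#' @param tree [ape::phylo] tree.
#' @param anchors anchor data frame (ids must be tree leaves).
#' @return list with `anchor`, `distance`, `path_support`.
#' @export
suggest_ortholog <- function(query, tree, anchors) {
  if (!query %in% tree$tip.label) stop("query not in tree: ", query)
  ids <- intersect(anchors$id, tree$tip.label)
  if (length(ids) == 0) stop("no anchors present in tree")
  dm <- ape::cophenetic.phylo(tree)
  d <- dm[query, ids]
  sup <- node_supports(tree)
  n <- length(tree$tip.label)
  path_support <- function(a, b) {
    np <- ape::nodepath(tree, which(tree$tip.label == a),
                        which(tree$tip.label == b))
    s <- 100
    for (k in seq_len(length(np) - 1)) {
      u <- np[k]; v <- np[k + 1]
      if (u > n && v > n) {   # internal edge; support lives on the child
        row <- which((tree$edge[, 1] == u & tree$edge[, 2] == v) |
                       (tree$edge[, 1] == v & tree$edge[, 2] == u))[1]
        child <- tree$edge[row, 2]
        s <- min(s, sup[child - n])
      }
    }
    s
  }
  ps <- vapply(ids, function(a) path_support(query, a), numeric(1))
  pick <- order(d, -ps, ids)[1]
  list(anchor = ids[pick], distance = unname(d[pick]),
       path_support = unname(ps[pick]))
}
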