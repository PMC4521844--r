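#' Protein distance model
#'
#' Distance kinds: `"p"` (proportion of differing usable sites), `"poisson"`
#' (`-ln(1 - p)`), `"poisson_gamma"` (`a * ((1 - p)^(-1/a) - 1)` with gamma
#' shape `a`, the closed-form gamma-corrected distance), and `"jtt_ml"` /
#' `"jtt_ml_gamma"` (one-parameter maximum-likelihood time under the
#' empirical JTT exchangeability matrix, the gamma variant integrating rates
#' over a 5-category discrete gamma). The unknown residue `X` always counts
#' as a mismatch at p-distance level. The default gamma shape is 5.
#'
#' @param kind model kind (see above).
#' @param gamma_shape gamma shape parameter (default 5).
#' @return a `distance_model` list.
#' @export
distance_model <- function(kind = c("poisson_gamma", "p", "poisson",
                                    "jtt_ml", "jtt_ml_gamma"),
                           gamma_shape = 5) {
  kind <- match.arg(kind)
  if (kind %in% c("poisson_gamma", "jtt_ml_gamma")) {
    stopifnot(gamma_shape > 0)
  }
  structure(list(kind = kind, gamma_shape = gamma_shape),
            class = "distance_model")
}

p_to_distance <- function(p, model, pair = "pair") {
  switch(model$kind,
    p = p,
    poisson = {
      if (p >= 1) stop("saturated distance (p >= 1) for ", pair)
      -log(1 - p)
    },
    poisson_gamma = {
      if (p >= 1) stop("saturated distance (p >= 1) for ", pair)
      model$gamma_shape * ((1 - p)^(-1 / model$gamma_shape) - 1)
    },
    stop("p_to_distance undefined for kind ", model$kind)
  )
}

jtt_pair_distance <- function(res_a, res_b, model) {
  dat <- phangorn::phyDat(rbind(a = res_a, b = res_b), type = "AA")
  k <- if (model$kind == "jtt_ml_gamma") 5L else 1L
  shape <- if (model$kind == "jtt_ml_gamma") model$gamma_shape else 1
  d <- phangorn::dist.ml(dat, model = "JTT", k = k, shape = shape)
  as.numeric(d)[1]
}

#' Pairwise distance between two gapped alignment rows
#'
#' Usable sites are the columns kept by the policy where both rows are
#' non-gap; `p` is the fraction of usable sites at which the rows differ
#' (`X` counts as a difference, including against another `X`).
#'
#' @param a,b gapped residue strings of equal length.
#' @param model a [distance_model()].
#' @param policy a [column_policy()].
#' @return the distance (non-negative number).
#' @export
pairwise_distance <- function(a, b, model = distance_model(),
                              policy = column_policy("pairwise_deletion")) {
  al <- as_alignment(c(a = unname(a[[1]]), b = unname(b[[1]])))
  D <- distance_matrix(al, model, policy)
  D["a", "b"]
}

#' Pairwise distance matrix of an alignment
#'
#' Applies the column policy once, then computes all pairwise distances;
#' under pairwise deletion usable sites are recomputed per pair.
#'
#' @param al alignment (named character vector of gapped rows).
#' @param model a [distance_model()].
#' @param policy a [column_policy()].
#' @return symmetric numeric matrix with zero diagonal, dimnames = row ids.
#' @export
distance_matrix <- function(al, model = distance_model(),
                            policy = column_policy("pairwise_deletion")) {
  pr <- apply_column_policy(al, policy)
  m <- alignment_matrix(al)[, pr$kept, drop = FALSE]
  ids <- names(al)
  n <- length(ids)
  nongap <- m != "-"
  usable <- tcrossprod(nongap * 1)
  if (any(usable[upper.tri(usable)] == 0)) {
    idx <- which(usable == 0 & upper.tri(usable), arr.ind = TRUE)[1, ]
    stop("zero usable sites for pair (", ids[idx[1]], ", ", ids[idx[2]], ")")
  }
  if (model$kind %in% c("p", "poisson", "poisson_gamma")) {
    matches <- matrix(0, n, n)
    for (letter in AA_LETTERS) {   # X intentionally excluded: never a match
      ind <- (m == letter) * 1
      matches <- matches + tcrossprod(ind)
    }
    P <- (usable - matches) / usable
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- p_to_distance(
          P[i, j], model, pair = paste0("(", ids[i], ", ", ids[j], ")"))
      }
    }
  } else {
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        sites <- which(nongap[i, ] & nongap[j, ])
        D[i, j] <- D[j, i] <- jtt_pair_distance(m[i, sites], m[j, sites],
                                                model)
      }
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining (Q-criterion join selection,
#' canonical branch-length and matrix-update formulas), made fully
#' deterministic: when several joins minimize Q, the pair whose sorted
#' cluster labels (the lexicographically smallest leaf name in each cluster)
#' compare lowest is joined. Negative branch lengths are clamped to zero with
#' the deficit moved to the sibling edge; the number of clamped edges is
#' reported in the `"clamped"` attribute and the raw pre-clamp lengths in
#' `"raw_edge_length"`.
#'
#' @param D symmetric distance matrix with dimnames (>= 3 taxa).
#' @return an unrooted [ape::phylo] tree (trifurcating root node).
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  taxa <- rownames(D)
  n <- length(taxa)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(D < 0)) stop("negative distances")
  d <- D
  # active clusters: node id (>0 tip index, <0 internal), label = smallest leaf
  node_id <- seq_len(n)
  label <- taxa
  children <- list()   # keyed by internal counter: list of (node, length, raw)
  internal <- 0L
  clamped <- 0L

  clamp_pair <- function(vi, vj) {
    raw <- c(vi, vj)
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    if (any(raw < 0)) clamped <<- clamped + 1L
    list(vi = vi, vj = vj, raw = raw)
  }

  while (nrow(d) > 3) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    keys <- apply(cand, 1, function(ij) {
      lab <- sort(c(label[ij[1]], label[ij[2]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- 0.5 * d[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    vj <- d[i, j] - vi
    cl <- clamp_pair(vi, vj)
    internal <- internal + 1L
    children[[internal]] <- list(
      list(node = node_id[i], length = cl$vi, raw = cl$raw[1]),
      list(node = node_id[j], length = cl$vj, raw = cl$raw[2]))
    du <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                   c(du[keep], 0))
    lab_new <- c(label[keep], min(label[i], label[j]))
    id_new <- c(node_id[keep], -internal)
    dimnames(d_new) <- list(lab_new, lab_new)
    d <- d_new
    label <- lab_new
    node_id <- id_new
  }
  # final 3-way join
  v <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
         (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
         (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  raw <- v
  if (any(v < 0)) clamped <- clamped + 1L
  v <- pmax(v, 0)
  internal <- internal + 1L
  children[[internal]] <- lapply(1:3, function(k) {
    list(node = node_id[k], length = v[k], raw = raw[k])
  })
  root <- internal

  # renumber: tips 1..n, internals n+1.. in preorder from root
  n_internal <- internal
  new_id <- integer(n_internal)
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  raws <- numeric(0)
  counter <- n
  assign_ids <- function(int) {
    counter <<- counter + 1L
    new_id[int] <<- counter
    for (ch in children[[int]]) {
      if (ch$node < 0) assign_ids(-ch$node)
    }
  }
  assign_ids(root)
  emit <- function(int) {
    for (ch in children[[int]]) {
      child <- if (ch$node < 0) new_id[-ch$node] else ch$node
      edges <<- rbind(edges, c(new_id[int], child))
      lens <<- c(lens, ch$length)
      raws <<- c(raws, ch$raw)
      if (ch$node < 0) emit(-ch$node)
    }
  }
  emit(root)
  tree <- structure(list(edge = edges, edge.length = lens, Nnode = n_internal,
                         tip.label = taxa), class = "phylo")
  attr(tree, "order") <- "cladewise"
  attr(tree, "clamped") <- clamped
  attr(tree, "raw_edge_length") <- raws
  tree
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; splits are canonicalized as
#' the sorted leaf set on the side NOT containing the alphabetically first
#' leaf, collapsed to a single string. Trivial splits (one leaf on a side)
#' are excluded.
#'
#' @param tree an [ape::phylo] tree.
#' @return character vector (a set) of canonical split strings.
#' @export
bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (k in seq_along(parts)) {
    tips <- labs[parts[[k]]]
    if (length(tips) == n) next                # root / whole leaf set
    side <- if (ref %in% tips) setdiff(labs, tips) else tips
    if (length(side) < 2 || length(side) > n - 2) next
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the non-trivial bipartition sets.
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Bootstrap configuration
#' @param n_replicates number of column-resampling replicates (default 500).
#' @param seed RNG seed (mandatory).
#' @return a `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_replicates = 500, seed) {
  stopifnot(n_replicates >= 1, !missing(seed))
  structure(list(n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)), class = "bootstrap_config")
}

#' Bootstrap clade support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement (seeded), rebuilds the NJ
#' tree per replicate, and annotates each internal edge of the point-estimate
#' tree with the percentage of replicates containing the same bipartition.
#' Supports are written to `node.label` (empty at the root) and returned
#' numerically in the `"support"` attribute.
#'
#' @param al alignment (named character vector of gapped rows, >= 4).
#' @param model a [distance_model()].
#' @param policy a [column_policy()].
#' @param cfg a [bootstrap_config()].
#' @param tree optional point-estimate tree; computed from `al` when `NULL`.
#' @return the point tree with `node.label` supports (0-100).
#' @export
bootstrap_support <- function(al, model = distance_model(),
                              policy = column_policy("pairwise_deletion"),
                              cfg = bootstrap_config(500, seed = 1),
                              tree = NULL) {
  stopifnot(length(al) >= 4)
  if (is.null(tree)) {
    tree <- neighbor_joining(distance_matrix(al, model, policy))
  }
  m <- alignment_matrix(al)
  L <- ncol(m)
  point_splits <- bipartitions(tree)
  counts <- stats::setNames(numeric(length(point_splits)), point_splits)
  set.seed(cfg$seed)
  for (b in seq_len(cfg$n_replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    rep_al <- apply(m[, idx, drop = FALSE], 1, paste, collapse = "")
    rep_tree <- neighbor_joining(distance_matrix(rep_al, model, policy))
    hit <- intersect(point_splits, bipartitions(rep_tree))
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / cfg$n_replicates
  # map split -> internal node of the point tree
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  ref <- sort(tree$tip.label)[1]
  node_lab <- character(tree$Nnode)
  node_support <- rep(NA_real_, tree$Nnode)
  for (k in seq_along(parts)) {
    tips <- labs[parts[[k]]]
    if (length(tips) == length(labs)) next
    side <- if (ref %in% tips) setdiff(labs, tips) else tips
    key <- paste(sort(side), collapse = ",")
    if (key %in% names(support)) {
      node_lab[k] <- format(round(support[[key]], 1), trim = TRUE)
      node_support[k] <- support[[key]]
    }
  }
  tree$node.label <- node_lab
  attr(tree, "support") <- node_support
  attr(tree, "support_by_split") <- support
  tree
}
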