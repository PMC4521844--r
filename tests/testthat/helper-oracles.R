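# Independent reference implementations used to validate the package's own
# code paths. These deliberately share no code with the implementation.

# --- least-squares brute force over all unrooted topologies (4-6 taxa) -----

path_matrix <- function(tr) {
  ne <- nrow(tr$edge)
  pairs <- t(utils::combn(sort(tr$tip.label), 2))
  A <- matrix(0, nrow(pairs), ne)
  for (e in seq_len(ne)) {
    t2 <- tr
    t2$edge.length <- rep(0, ne)
    t2$edge.length[e] <- 1
    A[, e] <- ape::cophenetic.phylo(t2)[pairs]
  }
  list(A = A, pairs = pairs)
}

ls_best_tree <- function(D) {
  taxa <- sort(rownames(D))
  topos <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  best <- NULL
  best_rss <- Inf
  for (k in seq_along(topos)) {
    tp <- topos[[k]]
    pm <- path_matrix(tp)
    d <- D[pm$pairs]
    fit <- qr.solve(pm$A, d)
    rss <- sum((pm$A %*% fit - d)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- tp
      best$edge.length <- fit
    }
  }
  list(tree = best, rss = best_rss)
}

# random additive distance matrix from a random tree with positive lengths
random_additive <- function(n) {
  gen <- ape::unroot(ape::rtree(n, tip.label = paste0("t", seq_len(n))))
  gen$edge.length <- stats::runif(nrow(gen$edge), 0.1, 1)
  D <- ape::cophenetic.phylo(gen)
  o <- sort(rownames(D))
  list(tree = gen, D = D[o, o])
}

# --- patristic distance by explicit breadth-first path summation ------------

patristic_bruteforce <- function(tree, a, b) {
  n <- length(tree$tip.label)
  ia <- which(tree$tip.label == a)
  ib <- which(tree$tip.label == b)
  adj <- list()
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[as.character(u)]] <- rbind(adj[[as.character(u)]], c(v, w))
    adj[[as.character(v)]] <- rbind(adj[[as.character(v)]], c(u, w))
  }
  dist <- rep(NA_real_, n + tree$Nnode)
  dist[ia] <- 0
  queue <- ia
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (k in seq_len(nrow(adj[[as.character(u)]]))) {
      v <- adj[[as.character(u)]][k, 1]
      w <- adj[[as.character(u)]][k, 2]
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + w
        queue <- c(queue, v)
      }
    }
  }
  dist[ib]
}

# --- fixture builders -------------------------------------------------------

write_blast_fixture <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

blast_row <- function(q, s, evalue, bits, qstart, qend, sstart = qstart,
                      send = qend, pident = 90, len = qend - qstart + 1) {
  c(q, s, pident, len, 1, 0, qstart, qend, sstart, send,
    format(evalue, scientific = TRUE), bits)
}

random_filler <- function(n) {
  paste(sample(setdiff(c("A", "R", "N", "D", "Q", "G", "I", "L", "K", "M",
                         "F", "P", "S", "T", "W", "Y", "V"), character(0)),
               n, replace = TRUE), collapse = "")
}

# peptide carrying one canonical finger with `n_lig` extra ligand residues
# sprinkled outside it
peptide_with_ligands <- function(n_extra, length_total = 300) {
  base <- strsplit(random_filler(length_total), "")[[1]]
  pos <- sample(length_total, n_extra)
  base[pos] <- sample(c("C", "H"), n_extra, replace = TRUE)
  paste(base, collapse = "")
}

hit_key <- function(h) paste(h$positions, collapse = ",")
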