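#' Core region on an ungapped reference
#'
#' The continuous block comprising the interrupted SET domain, the MYND
#' finger and the post-SET domain, given as 1-based inclusive residue
#' coordinates on the ungapped reference sequence (for the human SMYD1
#' reference, residues 18 to 279).
#'
#' @param reference id of the reference row.
#' @param ref_start,ref_end 1-based inclusive span (defaults 18 and 279).
#' @return a `core_region` list.
#' @export
core_region <- function(reference, ref_start = 18, ref_end = 279) {
  stopifnot(ref_start >= 1, ref_start <= ref_end)
  structure(list(reference = reference, ref_start = as.integer(ref_start),
                 ref_end = as.integer(ref_end)),
            class = "core_region")
}

#' Extract the SET-MYND core block from an alignment
#'
#' Returns the contiguous block of alignment columns running from the column
#' holding reference residue `ref_start` to the column holding `ref_end`,
#' inclusive. Rows are preserved in order; rows that are all-gap within the
#' block are retained and listed in the `"allgap_rows"` attribute.
#'
#' @param al alignment (named character vector of gapped rows).
#' @param core a [core_region()]; `core$reference` must name a row of `al`.
#' @return the trimmed alignment, same row order.
#' @export
extract_core <- function(al, core) {
  stopifnot(inherits(core, "core_region"))
  if (!core$reference %in% names(al)) {
    stop("reference '", core$reference, "' not found in alignment")
  }
  ref <- strsplit(al[[core$reference]], "")[[1]]
  res_cols <- which(ref != "-")
  if (length(res_cols) < core$ref_end) {
    stop("reference has ", length(res_cols), " residues; core end ",
         core$ref_end, " out of range")
  }
  from <- res_cols[core$ref_start]
  to <- res_cols[core$ref_end]
  out <- vapply(al, function(r) substr(r, from, to), character(1))
  names(out) <- names(al)
  allgap <- names(out)[!grepl("[^-]", out)]
  attr(out, "allgap_rows") <- allgap
  attr(out, "columns") <- c(from, to)
  out
}

#' Alignment column policy
#'
#' Gap handling for distance computation: `partial_deletion` keeps columns
#' whose non-gap fraction is at least `coverage_cutoff` (ties at the cutoff
#' are kept); `complete_deletion` keeps only gap-free columns;
#' `pairwise_deletion` keeps all columns and defers to per-pair shared
#' non-gap sites. Coverage is computed over all rows including the reference.
#'
#' @param mode one of `"partial_deletion"`, `"pairwise_deletion"`,
#'   `"complete_deletion"`.
#' @param coverage_cutoff non-gap fraction for partial deletion
#'   (default 0.65).
#' @return a `column_policy` list.
#' @export
column_policy <- function(mode = c("partial_deletion", "pairwise_deletion",
                                   "complete_deletion"),
                          coverage_cutoff = 0.65) {
  mode <- match.arg(mode)
  stopifnot(coverage_cutoff > 0, coverage_cutoff <= 1)
  structure(list(mode = mode, coverage_cutoff = coverage_cutoff),
            class = "column_policy")
}

#' Apply a column policy to an alignment
#'
#' @param al alignment (named character vector of gapped rows).
#' @param policy a [column_policy()].
#' @return list with `kept`: kept column indices (all columns under pairwise
#'   deletion, minus all-gap columns), and `nongap`: logical rows x columns
#'   matrix from which per-pair usable sites derive (the shared non-gap sites
#'   of a pair are `which(nongap[i, ] & nongap[j, ])`).
#' @export
apply_column_policy <- function(al, policy) {
  stopifnot(inherits(policy, "column_policy"), length(al) > 0)
  m <- alignment_matrix(al)
  nongap <- m != "-"
  frac <- colMeans(nongap)
  kept <- switch(policy$mode,
    partial_deletion = which(frac >= policy$coverage_cutoff),
    complete_deletion = which(frac == 1),
    pairwise_deletion = which(frac > 0)
  )
  list(kept = as.integer(kept), nongap = nongap, mode = policy$mode)
}

#' Shared non-gap sites of a sequence pair under a policy result
#'
#' @param policy_result output of [apply_column_policy()].
#' @param i,j row ids or indices.
#' @return integer vector of column indices usable for the pair.
#' @export
pair_usable_sites <- function(policy_result, i, j) {
  ng <- policy_result$nongap
  cols <- intersect(which(ng[i, ] & ng[j, ]), policy_result$kept)
  as.integer(cols)
}
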