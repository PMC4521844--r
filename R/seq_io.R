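#' @keywords internal
"_PACKAGE"

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V")

#' Validate protein residue strings
#'
#' Checks that every sequence is a non-empty, gap-free string over the 20
#' standard amino-acid letters plus `X` (unknown residue). Coordinates in all
#' error messages and downstream reports are 1-based inclusive.
#'
#' @param seqs named character vector of residue strings.
#' @param allow_gaps if `TRUE`, the gap character `-` is also accepted
#'   (alignment rows).
#' @return `seqs`, invisibly, after validation.
#' @keywords internal
validate_residues <- function(seqs, allow_gaps = FALSE) {
  if (length(seqs) == 0) return(invisible(seqs))
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("every sequence must carry an id")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  alphabet <- c(AA_LETTERS, "X", if (allow_gaps) "-")
  pat <- paste0("[^", paste(gsub("-", "\\\\-", alphabet), collapse = ""), "]")
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (!nzchar(s)) stop("sequence '", ids[i], "' is empty")
    if (!allow_gaps && grepl("-", s, fixed = TRUE)) {
      stop("sequence '", ids[i], "' contains a gap character '-' at position ",
           regexpr("-", s, fixed = TRUE)[1])
    }
    bad <- regexpr(pat, s)
    if (bad > 0) {
      stop("sequence '", ids[i], "' has illegal residue character '",
           substr(s, bad, bad), "' at position ", bad)
    }
  }
  invisible(seqs)
}

#' Read protein sequences from a FASTA file
#'
#' Returns a named character vector of residue strings, in file order, with
#' the description (text after the first whitespace in the header) stored in
#' the `"desc"` attribute. Sequences are upper-cased and validated: ids must
#' be unique, residues must be the 20 standard letters plus `X`, and gap
#' characters are rejected.
#'
#' @param path path to a FASTA file.
#' @return named character vector of residues; attribute `desc` holds the
#'   per-record descriptions.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 first", "MKLV", ">s2", "ACDE"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    out <- character(0)
    attr(out, "desc") <- character(0)
    return(out)
  }
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  validate_residues(seqs, allow_gaps = FALSE)
  attr(seqs, "desc") <- stats::setNames(desc, ids)
  seqs
}

#' Write protein sequences (or alignment rows) to FASTA
#'
#' @param seqs named character vector of residue strings (gaps allowed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' Read a protein multiple alignment
#'
#' Reads an aligned-FASTA or Clustal file into a named character vector of
#' equal-length gapped rows (gap character `-`). Ungapping any row yields a
#' valid protein sequence.
#'
#' @param path path to the alignment file.
#' @param dialect `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return named character vector of gapped rows, all the same width.
#' @export
read_alignment <- function(path, dialect = c("fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "fasta") {
    set <- Biostrings::readAAStringSet(path)
    rows <- toupper(as.character(set))
    names(rows) <- sub("\\s.*$", "", names(set))
  } else {
    al <- seqinr::read.alignment(path, format = "clustal")
    rows <- toupper(unlist(al$seq))
    names(rows) <- al$nam
  }
  if (length(rows) == 0) stop("alignment has no rows: ", path)
  as_alignment(rows)
}

#' Assemble and validate an alignment from gapped rows
#'
#' @param rows named character vector of gapped residue strings.
#' @return the validated rows.
#' @export
as_alignment <- function(rows) {
  widths <- nchar(rows)
  if (length(unique(widths)) > 1) {
    off <- names(rows)[widths != widths[1]]
    stop("alignment rows differ in length; offending id(s): ",
         paste(off, collapse = ", "))
  }
  validate_residues(rows, allow_gaps = TRUE)
  ungapped <- gsub("-", "", rows, fixed = TRUE)
  if (any(!nzchar(ungapped))) {
    stop("all-gap row(s): ",
         paste(names(rows)[!nzchar(ungapped)], collapse = ", "))
  }
  rows
}

#' Alignment rows as a character matrix (one column per site)
#' @param al named character vector of gapped rows.
#' @return character matrix, rownames = ids.
#' @keywords internal
alignment_matrix <- function(al) {
  m <- do.call(rbind, strsplit(unname(al), ""))
  rownames(m) <- names(al)
  m
}

BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read 12-column tabular BLAST output (outfmt 6)
#'
#' Parses the standard 12-column tab-separated layout; extra columns are
#' ignored. Numeric fields are validated per line, coordinates are 1-based
#' inclusive.
#'
#' @param path path to a BLAST tabular file.
#' @return data frame with columns qseqid, sseqid, pident, length, mismatch,
#'   gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), 12), BLAST_COLS))
    num <- setdiff(BLAST_COLS, c("qseqid", "sseqid"))
    df[num] <- lapply(df[num], as.numeric)
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    stop("line ", which(nf < 12)[1], " has ", nf[nf < 12][1],
         " columns; 12 required")
  }
  df <- as.data.frame(do.call(rbind, lapply(fields, `[`, 1:12)),
                      stringsAsFactors = FALSE)
  names(df) <- BLAST_COLS
  num <- setdiff(BLAST_COLS, c("qseqid", "sseqid"))
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop("non-numeric ", col, " at line ", which(is.na(v))[1], ": '",
           df[[col]][which(is.na(v))[1]], "'")
    }
    df[[col]] <- v
  }
  bad <- df$qstart > df$qend
  if (any(bad)) stop("qstart > qend at line ", which(bad)[1])
  if (any(df$evalue < 0)) stop("negative evalue at line ", which(df$evalue < 0)[1])
  df
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]. Bootstrap
#' supports are stored as internal-node labels on the 0-100 percentage scale,
#' the dominant dialect for bootstrap trees; round-trips preserve topology,
#' branch lengths (to print precision) and support labels.
#'
#' @param path file path.
#' @return for `read_newick`, an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (open != close) {
    depth <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1L,
                           ifelse(strsplit(txt, "")[[1]] == ")", -1L, 0L)))
    off <- if (any(depth < 0)) which(depth < 0)[1] else nchar(txt)
    stop("unbalanced parentheses in Newick string near offset ", off)
  }
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tr)) stop("malformed Newick string: ", path)
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object (supports, if any, in `node.label`).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
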