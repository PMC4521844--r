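#' Homology-filter configuration
#'
#' Acceptance rules used when collecting Smyd candidates from BLASTP tabular
#' output: an expectation-value ceiling and a continuity requirement over the
#' SET-MYND core of the query.
#'
#' @param ref_id query/reference sequence id the hits were searched with.
#' @param ref_start,ref_end 1-based inclusive core span on the query (for the
#'   human SMYD1 reference this is residues 18-279).
#' @param evalue_max maximum accepted expectation value (default `1e-7`;
#'   candidates must score strictly below it).
#' @param min_core_coverage fraction of the core that a single HSP must cover
#'   (default 0.9).
#' @param max_internal_break maximum tolerated net indel imbalance within the
#'   covering HSP, in residues (default 10). Tabular BLAST rows do not expose
#'   individual gap lengths, so the break is measured as
#'   `|(qend - qstart) - (send - sstart)|`.
#' @return a `filter_config` list.
#' @export
filter_config <- function(ref_id, ref_start, ref_end,
                          evalue_max = 1e-7,
                          min_core_coverage = 0.9,
                          max_internal_break = 10) {
  stopifnot(evalue_max > 0, min_core_coverage > 0, min_core_coverage <= 1,
            ref_start >= 1, ref_start <= ref_end, max_internal_break >= 0)
  structure(list(ref_id = ref_id, ref_start = ref_start, ref_end = ref_end,
                 evalue_max = evalue_max,
                 min_core_coverage = min_core_coverage,
                 max_internal_break = max_internal_break),
            class = "filter_config")
}

# Deterministic hit ordering: lowest evalue, then highest bitscore, then
# subject id lexicographically.
order_hits <- function(hits, by_subject = TRUE) {
  if (by_subject) {
    order(hits$evalue, -hits$bitscore, hits$sseqid)
  } else {
    order(hits$evalue, -hits$bitscore, hits$qseqid)
  }
}

#' Filter BLAST hits by expectation value and core continuity
#'
#' A subject is accepted when (i) its best hit (lowest evalue, ties broken by
#' bitscore then subject id) has evalue below `cfg$evalue_max`, and (ii) a
#' single HSP covers at least `cfg$min_core_coverage` of the core span with
#' net indel imbalance no larger than `cfg$max_internal_break`. HSPs are never
#' merged to satisfy continuity.
#'
#' @param hits data frame from [read_blast_tab()]; all rows must share the
#'   query id `cfg$ref_id`.
#' @param cfg a [filter_config()].
#' @return data frame with one row per subject: `sseqid`, `accepted`,
#'   `evalue_pass`, `continuity_pass`, `reciprocal_pass` (`NA` until
#'   [reciprocal_best()] is applied), `best_evalue`, `core_coverage`,
#'   `reason`.
#' @export
filter_by_evalue_and_continuity <- function(hits, cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(hits) > 0 && any(hits$qseqid != cfg$ref_id)) {
    stop("hits mix query ids: expected '", cfg$ref_id, "', found '",
         setdiff(unique(hits$qseqid), cfg$ref_id)[1], "'")
  }
  core_len <- cfg$ref_end - cfg$ref_start + 1
  subjects <- sort(unique(hits$sseqid))
  rows <- lapply(subjects, function(sid) {
    h <- hits[hits$sseqid == sid, , drop = FALSE]
    h <- h[order_hits(h), , drop = FALSE]
    best_evalue <- h$evalue[1]
    evalue_pass <- best_evalue < cfg$evalue_max
    ov_lo <- pmax(h$qstart, cfg$ref_start)
    ov_hi <- pmin(h$qend, cfg$ref_end)
    coverage <- pmax(0, ov_hi - ov_lo + 1) / core_len
    breaks <- abs((h$qend - h$qstart) - (h$send - h$sstart))
    continuity_pass <- any(coverage >= cfg$min_core_coverage &
                             breaks <= cfg$max_internal_break)
    reason <- c(if (!evalue_pass) sprintf("evalue %.3g >= %.3g", best_evalue,
                                          cfg$evalue_max),
                if (!continuity_pass) "no single HSP with continuous core coverage")
    data.frame(sseqid = sid,
               accepted = evalue_pass && continuity_pass,
               evalue_pass = evalue_pass,
               continuity_pass = continuity_pass,
               reciprocal_pass = NA,
               best_evalue = best_evalue,
               core_coverage = max(coverage),
               reason = if (length(reason)) paste(reason, collapse = "; ") else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Reciprocal-best validation of filtered candidates
#'
#' A candidate passes when its top reverse-search hit (lowest evalue, ties by
#' highest bitscore, then subject id) is a member of the seed query set (the
#' human SMYD proteins or any later-added query). Candidates with no reverse
#' hits fail with reason "no reciprocal hit".
#'
#' @param verdicts output of [filter_by_evalue_and_continuity()].
#' @param reverse_hits data frame from [read_blast_tab()]; `qseqid` is the
#'   candidate, `sseqid` the seed-proteome sequence it hit.
#' @param seed_set character vector of seed sequence ids.
#' @return `verdicts` with `reciprocal_pass` filled in and `accepted`
#'   recomputed as the conjunction of all three rules.
#' @export
reciprocal_best <- function(verdicts, reverse_hits, seed_set) {
  verdicts$reciprocal_pass <- vapply(verdicts$sseqid, function(sid) {
    h <- reverse_hits[reverse_hits$qseqid == sid, , drop = FALSE]
    if (nrow(h) == 0) return(FALSE)
    h <- h[order(h$evalue, -h$bitscore, h$sseqid), , drop = FALSE]
    h$sseqid[1] %in% seed_set
  }, logical(1))
  no_hit <- !verdicts$sseqid %in% reverse_hits$qseqid
  fail <- !verdicts$reciprocal_pass
  verdicts$reason <- ifelse(
    fail & nzchar(verdicts$reason),
    paste(verdicts$reason,
          ifelse(no_hit, "no reciprocal hit", "reciprocal best not in seed set"),
          sep = "; "),
    ifelse(fail,
           ifelse(no_hit, "no reciprocal hit", "reciprocal best not in seed set"),
           verdicts$reason))
  verdicts$accepted <- verdicts$evalue_pass & verdicts$continuity_pass &
    verdicts$reciprocal_pass
  verdicts
}
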