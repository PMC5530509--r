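# assembly_eval: best-hit evaluation of assemblies against an annotated
# reference gene set, same-subject deduplication, summary statistics and
# dot-plot style match-segment export. Acceptance replaces the e-value-based
# filter of BLAST-style workflows by explicit alignment-length and identity
# thresholds (e-values depend on database size and tool internals).

#' Best-hit acceptance criteria
#'
#' @param min_alignment_length minimum alignment columns (default 500).
#' @param min_identity minimum identity fraction (default 0.85).
#' @return a list of class `acceptance_criteria`.
#' @export
acceptance_criteria <- function(min_alignment_length = 500L,
                                min_identity = 0.85) {
  stopifnot(min_alignment_length >= 1, min_identity > 0, min_identity <= 1)
  structure(list(min_alignment_length = as.integer(min_alignment_length),
                 min_identity = min_identity), class = "acceptance_criteria")
}

#' Best accepted hit of each reference query in a subject set
#'
#' At most one hit per query: the best-scoring local alignment across all
#' subjects and both strands, kept only if it meets the acceptance criteria
#' (mirrors a max-target-seqs-1, max-hsps-1 search followed by threshold
#' filtering).
#'
#' @param queries reference genes, a non-empty [sequence_set()].
#' @param subjects contigs (or reads), a non-empty [sequence_set()].
#' @param criteria an [acceptance_criteria()].
#' @param params an [alignment_params()].
#' @return data frame of accepted hits (query order preserved).
#' @export
best_hit_search <- function(queries, subjects,
                            criteria = acceptance_criteria(),
                            params = alignment_params()) {
  stopifnot(inherits(queries, "sequence_set"), nrow(queries) > 0,
            inherits(subjects, "sequence_set"), nrow(subjects) > 0)
  hits <- map_reads(queries, subjects, params)
  if (nrow(hits) == 0) return(hits)
  acc <- hits$columns >= criteria$min_alignment_length &
    hits$identity >= criteria$min_identity
  out <- hits[acc, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove redundant hits produced by the same subject region
#'
#' Among hits whose subject intervals (on the same subject) overlap by more
#' than `overlap_fraction` of the shorter interval, only the highest-scoring
#' is kept.
#'
#' @param hits data frame of one-per-query hits.
#' @param overlap_fraction overlap fraction of the shorter interval above
#'   which hits are considered redundant (default 0.5).
#' @return list with `kept` and `removed` hit data frames.
#' @export
dedupe_same_subject <- function(hits, overlap_fraction = 0.5) {
  if (nrow(hits) == 0) return(list(kept = hits, removed = hits))
  ord <- order(-hits$score, -hits$identity, hits$query_id, method = "radix")
  keep <- logical(nrow(hits))
  for (i in ord) {
    conflict <- FALSE
    for (j in which(keep)) {
      if (hits$subject_id[j] != hits$subject_id[i]) next
      ov <- min(hits$s_end[i], hits$s_end[j]) -
        max(hits$s_start[i], hits$s_start[j]) + 1
      shorter <- min(hits$s_end[i] - hits$s_start[i],
                     hits$s_end[j] - hits$s_start[j]) + 1
      if (ov > overlap_fraction * shorter) { conflict <- TRUE; break }
    }
    if (!conflict) keep[i] <- TRUE
  }
  list(kept = `rownames<-`(hits[keep, , drop = FALSE], NULL),
       removed = `rownames<-`(hits[!keep, , drop = FALSE], NULL))
}

#' Summarize accepted best hits against a reference
#'
#' Means and sample (n-1) standard deviations of percent identity and
#' alignment length (columns), the query alignment-length percentage
#' (aligned query span over query length), and the reference coverage
#' (accepted hits over reference size).
#'
#' @param hits data frame of accepted hits (one per query).
#' @param n_reference number of genes in the reference searched with.
#' @return one-row data frame (`*_pct` columns on the 0--100 scale,
#'   unrounded).
#' @export
summarize_hits <- function(hits, n_reference) {
  stopifnot(n_reference >= 1)
  if (nrow(hits) > n_reference) {
    stop("more hits (", nrow(hits), ") than reference entries (",
         n_reference, "); hits must be one-per-query")
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  qpct <- 100 * (hits$q_end - hits$q_start + 1) / hits$q_len
  data.frame(
    n_hits = nrow(hits), n_reference = n_reference,
    coverage_pct = 100 * nrow(hits) / n_reference,
    mean_identity_pct = if (nrow(hits)) mean(100 * hits$identity) else NA_real_,
    sd_identity_pct = if (nrow(hits)) sd0(100 * hits$identity) else NA_real_,
    mean_aln_len = if (nrow(hits)) mean(hits$columns) else NA_real_,
    sd_aln_len = if (nrow(hits)) sd0(hits$columns) else NA_real_,
    mean_query_len_pct = if (nrow(hits)) mean(qpct) else NA_real_,
    sd_query_len_pct = if (nrow(hits)) sd0(qpct) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Mapping summary of a read set against a reference
#'
#' @param reads a [sequence_set()].
#' @param reference a non-empty [sequence_set()].
#' @param params an [alignment_params()].
#' @return one-row data frame with `mapped_pct` (hits over total reads),
#'   `mean_coverage` (total aligned subject span over total reference
#'   length) and `error_rate_pct` (1 minus total matches over total columns),
#'   all unrounded.
#' @export
mapping_summary <- function(reads, reference, params = alignment_params()) {
  hits <- map_reads(reads, reference, params)
  ref_len <- sum(nchar(reference$sequence))
  data.frame(
    n_reads = nrow(reads), n_mapped = nrow(hits),
    mapped_pct = if (nrow(reads)) 100 * nrow(hits) / nrow(reads) else 0,
    mean_coverage = if (nrow(hits))
      sum(hits$s_end - hits$s_start + 1) / ref_len else 0,
    error_rate_pct = if (nrow(hits))
      100 * (1 - sum(hits$matches) / sum(hits$columns)) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Export dot-plot match segments between an assembly and a reference
#'
#' Reports, for every (reference, contig) pair and strand, the best local
#' match of at least `min_match` alignment columns, as a table suitable for
#' external dot-plot rendering. Forward and reverse matches are
#' distinguished by the `strand` column; coordinates are 1-based inclusive
#' on the forward strands.
#'
#' @param assembly contigs, a [sequence_set()].
#' @param reference reference genes, a [sequence_set()].
#' @param min_match minimum alignment columns of a reported segment
#'   (default 500).
#' @param params an [alignment_params()].
#' @return data frame with columns `ref_id`, `contig_id`, `r_start`,
#'   `r_end`, `c_start`, `c_end`, `strand`, `identity_pct`.
#' @export
dotplot_export <- function(assembly, reference, min_match = 500L,
                           params = alignment_params()) {
  stopifnot(min_match >= 1)
  rows <- list()
  for (i in seq_len(nrow(reference))) {
    res <- .cpp_map_one(reference$sequence[i], assembly$sequence,
                        params$match, params$mismatch, params$gap_open,
                        params$gap_extend, params$seed_k, params$band,
                        params$min_chain, -1L)
    for (u in which(res$found)) {
      cols <- res$matches[u] + res$mismatches[u] + res$insertions[u] +
        res$deletions[u]
      if (cols < min_match) next
      rows[[length(rows) + 1]] <- data.frame(
        ref_id = reference$id[i], contig_id = assembly$id[u],
        r_start = res$q_start[u] + 1L, r_end = res$q_end[u],
        c_start = res$s_start[u] + 1L, c_end = res$s_end[u],
        strand = res$strand[u],
        identity_pct = 100 * res$matches[u] / cols,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(ref_id = character(), contig_id = character(),
                      r_start = integer(), r_end = integer(),
                      c_start = integer(), c_end = integer(),
                      strand = character(), identity_pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
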