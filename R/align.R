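# pairwise_align: the internal alignment engine. Exact affine-gap local DP
# for small inputs, k-mer-seeded banded DP (with band widening) for larger
# ones, and semiglobal edit-distance location of adapter-like patterns.
# User-facing coordinates are 1-based inclusive; identity counts all
# alignment columns (matches + mismatches + gap columns) in the denominator.

#' Alignment scoring and seeding parameters
#'
#' Defaults are common nucleotide-search settings: match +2, mismatch -3,
#' affine gaps with open -5 and extend -2 (a gap of length L scores
#' `gap_open + L * gap_extend`), 11-mer seeds and a band half-width of 100
#' diagonals for the heuristic path.
#'
#' @param match positive match score.
#' @param mismatch negative mismatch penalty.
#' @param gap_open negative gap-opening penalty.
#' @param gap_extend negative per-base gap-extension penalty.
#' @param seed_k k-mer size used for heuristic seeding (>= 4).
#' @param band band half-width, in diagonals, around the seeded diagonal.
#' @param min_chain minimum number of k-mer seeds clustered within one
#'   band-wide diagonal window for the heuristic to consider a pair seeded
#'   (a BLAST-two-hit-style filter).
#' @param exact_max maximum sequence length (each side) for which
#'   `method = "auto"` uses the exhaustive DP.
#' @param min_map_score minimum alignment score for a hit to be reported by
#'   [map_reads()]; chance local alignments of unrelated long sequences
#'   score below this, real mappings far above it.
#' @return a list of class `alignment_params`.
#' @export
alignment_params <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                             gap_extend = -2L, seed_k = 11L, band = 100L,
                             min_chain = 2L, exact_max = 2000L,
                             min_map_score = 50L) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            seed_k >= 4, band >= 1, min_chain >= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 seed_k = as.integer(seed_k), band = as.integer(band),
                 min_chain = as.integer(min_chain),
                 exact_max = as.integer(exact_max),
                 min_map_score = as.integer(min_map_score)),
            class = "alignment_params")
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             strand = character(), score = integer(),
             matches = integer(), mismatches = integer(),
             insertions = integer(), deletions = integer(),
             columns = integer(), identity = numeric(),
             q_len = integer(), s_len = integer(),
             stringsAsFactors = FALSE)
}

hit_row <- function(raw, query_id, subject_id, q_len, s_len) {
  columns <- raw$matches + raw$mismatches + raw$insertions + raw$deletions
  data.frame(query_id = query_id, subject_id = subject_id,
             q_start = raw$q_start + 1L, q_end = raw$q_end,
             s_start = raw$s_start + 1L, s_end = raw$s_end,
             strand = raw$strand, score = raw$score,
             matches = raw$matches, mismatches = raw$mismatches,
             insertions = raw$insertions, deletions = raw$deletions,
             columns = columns, identity = raw$matches / columns,
             q_len = q_len, s_len = s_len, stringsAsFactors = FALSE)
}

#' Best-scoring local alignment of two DNA sequences
#'
#' Both strands of `b` are tried; the hit is reported on the forward strand of
#' both sequences with a `strand` column. With `method = "auto"` the result is
#' exhaustive Gotoh DP when both sequences are at most `params$exact_max`
#' bases, and a seeded banded heuristic otherwise. The heuristic widens its
#' band until the traceback no longer touches a band edge; when no seed is
#' shared and both sequences are small it falls back to the exhaustive DP, so
#' that on small inputs the two paths agree.
#'
#' @param a,b DNA strings (non-empty).
#' @param params an [alignment_params()].
#' @param method `"auto"`, `"exact"` or `"banded"`.
#' @return a one-row data frame (an alignment hit: coordinates 1-based
#'   inclusive, `identity = matches / columns`), or `NULL` when no
#'   positive-scoring local alignment exists.
#' @examples
#' local_align("ACGTACGT", "ACGTACGT")
#' @export
local_align <- function(a, b, params = alignment_params(),
                        method = c("auto", "exact", "banded")) {
  method <- match.arg(method)
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  a <- normalize_dna(a); b <- normalize_dna(b)
  small <- nchar(a) <= params$exact_max && nchar(b) <= params$exact_max
  use_exact <- method == "exact" || (method == "auto" && small)
  if (use_exact) {
    raw <- .cpp_align_exact(a, b, params$match, params$mismatch,
                            params$gap_open, params$gap_extend)
  } else {
    raw <- .cpp_align_seeded(a, b, params$match, params$mismatch,
                             params$gap_open, params$gap_extend,
                             params$seed_k, params$band, params$min_chain)
    if (!raw$found && !raw$has_seeds && small) {
      raw <- .cpp_align_exact(a, b, params$match, params$mismatch,
                              params$gap_open, params$gap_extend)
    }
  }
  if (!raw$found) return(NULL)
  hit_row(raw, "a", "b", nchar(a), nchar(b))
}

#' Locate a pattern in a text at bounded edit distance
#'
#' Semiglobal approximate matching: the full pattern must align (both pattern
#' ends anchored) somewhere inside the text (text ends free) at unit-cost edit
#' distance at most `max_edits`. Both strands of the pattern are searched;
#' spans are reported on the forward text. Overlapping candidate matches are
#' reduced to locally minimal-edit, non-overlapping spans (minimal edits
#' first, leftmost on ties).
#'
#' @param pattern non-empty DNA string.
#' @param text DNA string.
#' @param max_edits maximum number of edits (>= 0).
#' @param both_strands search the reverse complement of the pattern too.
#' @return data frame with columns `start`, `end` (1-based inclusive),
#'   `edits`, `strand`; zero rows when the pattern does not occur.
#' @examples
#' semiglobal_locate("ACGTACGTACGT", "TTTTACGTACGTACGTTTTT", max_edits = 1)
#' @export
semiglobal_locate <- function(pattern, text, max_edits, both_strands = TRUE) {
  stopifnot(length(pattern) == 1, length(text) == 1, max_edits >= 0)
  if (!nzchar(pattern)) stop("pattern must be non-empty")
  pattern <- normalize_dna(pattern); text <- normalize_dna(text)
  if (!nzchar(text)) {
    return(data.frame(start = integer(), end = integer(), edits = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  cand <- .cpp_edit_locate(pattern, text, as.integer(max_edits))
  cand <- data.frame(start = cand[, 1], end = cand[, 2], edits = cand[, 3],
                     strand = rep("+", nrow(cand)), stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- .cpp_edit_locate(reverse_complement(pattern), text,
                           as.integer(max_edits))
    cand <- rbind(cand,
                  data.frame(start = rc[, 1], end = rc[, 2], edits = rc[, 3],
                             strand = rep("-", nrow(rc)),
                             stringsAsFactors = FALSE))
  }
  out <- reduce_spans(cand)
  out$start <- out$start + 1L # to 1-based inclusive
  out
}

# greedy reduction: minimal edits first (ties: leftmost start, then shorter,
# then forward strand), dropping every candidate overlapping an accepted span
reduce_spans <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  ord <- order(cand$edits, cand$start, cand$end - cand$start,
               cand$strand != "+")
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(keep & cand$start < e & cand$end > s)) keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map reads against a reference set
#'
#' For each read, the best-scoring seeded local alignment across all
#' reference entries and both strands is reported (at most one hit per read).
#' Mapping is seed-driven: a read sharing no clustered `seed_k`-mer seeds
#' with any reference entry is unmapped and absent from the result, as is a
#' read whose best alignment scores below `params$min_map_score`. Ties are
#' broken by higher identity, then lexicographically smallest subject id.
#'
#' @param reads,reference [sequence_set()] objects (reference non-empty).
#' @param params an [alignment_params()].
#' @return data frame of alignment hits (one row per mapped read, in read
#'   order), with `query_id` = read id and `subject_id` = reference id.
#' @export
map_reads <- function(reads, reference, params = alignment_params()) {
  stopifnot(inherits(reads, "sequence_set"), inherits(reference, "sequence_set"))
  if (nrow(reference) == 0) stop("reference must be non-empty")
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    best <- best_subject_hit(reads$sequence[i], reference, params)
    if (!is.null(best)) {
      best$query_id <- reads$id[i]
      rows[[i]] <- best
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# best seeded hit of one query sequence against a subject set; NULL when no
# subject shares a seed or no positive-scoring alignment exists
best_subject_hit <- function(qseq, subjects, params, stop_score = -1L) {
  res <- .cpp_map_one(qseq, subjects$sequence, params$match, params$mismatch,
                      params$gap_open, params$gap_extend, params$seed_k,
                      params$band, params$min_chain, as.integer(stop_score))
  hit_idx <- which(res$found & res$score >= params$min_map_score)
  if (length(hit_idx) == 0) return(NULL)
  cols <- res$matches[hit_idx] + res$mismatches[hit_idx] +
    res$insertions[hit_idx] + res$deletions[hit_idx]
  ident <- res$matches[hit_idx] / cols
  ord <- order(-res$score[hit_idx], -ident, subjects$id[hit_idx],
               method = "radix")
  u <- hit_idx[ord[1]]
  raw <- list(q_start = res$q_start[u], q_end = res$q_end[u],
              s_start = res$s_start[u], s_end = res$s_end[u],
              strand = res$strand[u], score = res$score[u],
              matches = res$matches[u], mismatches = res$mismatches[u],
              insertions = res$insertions[u], deletions = res$deletions[u])
  hit_row(raw, "q", subjects$id[u], nchar(qseq), nchar(subjects$sequence[u]))
}
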