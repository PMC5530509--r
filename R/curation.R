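# adapter_curation: pre-assembly read filtering — fixed end trim, approximate
# adapter removal, minimum-length filter, chimeric-read removal. A chimera is
# a read retaining a full adapter match with at least `chimera_flank` bases on
# both sides after end-adjacent adapter trimming: end-adjacent residue is
# trimmable, an interior adapter implies a PCR fusion of two fragments.

#' Adapter specification
#'
#' @param name adapter name.
#' @param sequence adapter DNA sequence (length >= 8).
#' @param max_error_rate maximum fraction of edits tolerated when locating
#'   the adapter (default 0.20, the long-read nanopore setting; use 0.05 for
#'   high-accuracy consensus reads). The edit budget for a pattern of length
#'   L is `floor(max_error_rate * L)`.
#' @return a list of class `adapter_spec`.
#' @export
adapter_spec <- function(name, sequence, max_error_rate = 0.20) {
  sequence <- normalize_dna(sequence)
  stopifnot(nchar(sequence) >= 8, max_error_rate >= 0, max_error_rate < 0.5)
  structure(list(name = name, sequence = sequence,
                 max_error_rate = max_error_rate), class = "adapter_spec")
}

#' Read-curation configuration
#'
#' Defaults follow the long-read RenSeq curation recipe: remove 65 bases (the
#' length of the amplification adapter) from both read ends, search for
#' residual adapters at a platform-dependent error rate, drop reads shorter
#' than 150 bp, and remove reads that still carry an internal adapter
#' (chimeras).
#'
#' @param end_trim fixed number of bases removed from each end.
#' @param min_length minimum kept-read length after trimming.
#' @param adapters list of [adapter_spec()] objects.
#' @param chimera_flank minimum number of bases on both sides of a residual
#'   adapter for the read to be called chimeric; adapters closer than this to
#'   an end are trimmed off instead.
#' @return a list of class `curation_config`.
#' @export
curation_config <- function(end_trim = 65L, min_length = 150L,
                            adapters = list(), chimera_flank = 50L) {
  stopifnot(end_trim >= 0, min_length >= 1, chimera_flank >= 1)
  if (length(adapters) > 0 &&
      !all(vapply(adapters, inherits, TRUE, "adapter_spec"))) {
    stop("adapters must be a list of adapter_spec objects")
  }
  structure(list(end_trim = as.integer(end_trim),
                 min_length = as.integer(min_length),
                 adapters = adapters,
                 chimera_flank = as.integer(chimera_flank)),
            class = "curation_config")
}

#' Remove a fixed number of bases from both read ends
#'
#' @param read a one-row [sequence_set()].
#' @param n bases removed from each end; a read of length `<= 2n` becomes
#'   empty.
#' @return the trimmed one-row [sequence_set()] (quality sliced identically).
#' @export
trim_fixed_ends <- function(read, n) {
  stopifnot(inherits(read, "sequence_set"), nrow(read) == 1, n >= 0)
  len <- nchar(read$sequence)
  if (len <= 2 * n) {
    read$sequence <- ""
    if (!is.na(read$quality)) read$quality <- ""
    return(read)
  }
  read$sequence <- substr(read$sequence, n + 1, len - n)
  if (!is.na(read$quality)) read$quality <- substr(read$quality, n + 1, len - n)
  read
}

#' Detect adapter occurrences in a read
#'
#' Runs [semiglobal_locate()] for every configured adapter on both strands,
#' with edit budget `floor(max_error_rate * adapter_length)`.
#'
#' @param read a one-row [sequence_set()].
#' @param adapters list of [adapter_spec()] objects (non-empty).
#' @return data frame of spans sorted by `start`: columns `adapter`, `start`,
#'   `end` (1-based inclusive), `edits`, `strand`.
#' @export
detect_adapters <- function(read, adapters) {
  stopifnot(inherits(read, "sequence_set"), nrow(read) == 1,
            length(adapters) > 0)
  spans <- lapply(adapters, function(ad) {
    k <- floor(ad$max_error_rate * nchar(ad$sequence))
    sp <- semiglobal_locate(ad$sequence, read$sequence, max_edits = k)
    if (nrow(sp) > 0) sp$adapter <- ad$name
    sp
  })
  spans <- spans[vapply(spans, nrow, 1L) > 0]
  if (length(spans) == 0) {
    return(data.frame(adapter = character(), start = integer(),
                      end = integer(), edits = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(spans, function(s) {
    s[, c("adapter", "start", "end", "edits", "strand")]
  }))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Curate a single read
#'
#' Applies, in order: (1) fixed end trimming; (2) adapter detection; spans
#' starting or ending within `chimera_flank` bases of an end are trimmed off
#' together with everything outside them; (3) a surviving adapter span with at
#' least `chimera_flank` bases on both sides marks the read as chimeric
#' (removed whole, not split); (4) reads shorter than `min_length` after
#' trimming are removed as short.
#'
#' @param read a one-row [sequence_set()].
#' @param config a [curation_config()].
#' @return list with `read_id`, `decision` (`"kept"`, `"removed_short"`,
#'   `"removed_chimeric"`), `trimmed_sequence` (empty unless kept),
#'   `trimmed_quality`, `adapter_spans` (detected on the end-trimmed read),
#'   `removed_prefix_len`, `removed_suffix_len` (relative to the input read).
#' @export
curate_read <- function(read, config = curation_config()) {
  stopifnot(inherits(read, "sequence_set"), nrow(read) == 1,
            inherits(config, "curation_config"))
  orig_len <- nchar(read$sequence)
  r <- trim_fixed_ends(read, config$end_trim)
  prefix <- min(config$end_trim, orig_len)
  suffix <- min(config$end_trim, max(orig_len - config$end_trim, 0))

  spans <- if (length(config$adapters) > 0 && nchar(r$sequence) > 0) {
    detect_adapters(r, config$adapters)
  } else {
    data.frame(adapter = character(), start = integer(), end = integer(),
               edits = integer(), strand = character(),
               stringsAsFactors = FALSE)
  }

  # iteratively trim end-adjacent adapter spans (interior spans can become
  # end-adjacent once an outer span is trimmed off)
  lo <- 1L; hi <- nchar(r$sequence) # current kept window, 1-based inclusive
  active <- spans
  repeat {
    if (nrow(active) == 0 || hi < lo) break
    left_margin <- active$start - lo
    right_margin <- hi - active$end
    edge <- which(left_margin < config$chimera_flank |
                  right_margin < config$chimera_flank)
    if (length(edge) == 0) break
    i <- edge[1]
    if (left_margin[i] <= right_margin[i]) {
      lo <- max(lo, active$end[i] + 1L)
    } else {
      hi <- min(hi, active$start[i] - 1L)
    }
    active <- active[active$start >= lo & active$end <= hi, , drop = FALSE]
  }

  chimeric <- nrow(active) > 0 && hi >= lo
  final_seq <- if (hi >= lo) substr(r$sequence, lo, hi) else ""
  final_qual <- if (!is.na(r$quality) && hi >= lo) {
    substr(r$quality, lo, hi)
  } else if (!is.na(r$quality)) "" else NA_character_

  decision <- if (chimeric) {
    "removed_chimeric"
  } else if (nchar(final_seq) < config$min_length) {
    "removed_short"
  } else {
    "kept"
  }
  list(read_id = read$id,
       decision = decision,
       trimmed_sequence = if (decision == "kept") final_seq else "",
       trimmed_quality = if (decision == "kept") final_qual else NA_character_,
       adapter_spans = spans,
       removed_prefix_len = as.integer(prefix + (lo - 1L)),
       removed_suffix_len = as.integer(suffix +
                                         max(nchar(r$sequence) - hi, 0L)))
}

#' Curate a read set
#'
#' @param reads a [sequence_set()].
#' @param config a [curation_config()].
#' @return list with `kept` (a [sequence_set()] of trimmed kept reads, input
#'   order preserved), `decisions` (data frame of per-read outcomes) and
#'   `summary` (counts per decision plus length statistics of the kept reads).
#' @export
curate_set <- function(reads, config = curation_config()) {
  stopifnot(inherits(reads, "sequence_set"))
  outcomes <- lapply(seq_len(nrow(reads)),
                     function(i) curate_read(reads[i, ], config))
  decisions <- data.frame(
    read_id = vapply(outcomes, `[[`, "", "read_id"),
    decision = vapply(outcomes, `[[`, "", "decision"),
    n_adapter_spans = vapply(outcomes, function(o) nrow(o$adapter_spans), 1L),
    stringsAsFactors = FALSE)
  keep <- decisions$decision == "kept"
  kept <- sequence_set(
    id = decisions$read_id[keep],
    sequence = vapply(outcomes[keep], `[[`, "", "trimmed_sequence"),
    quality = vapply(outcomes[keep], `[[`, "", "trimmed_quality"),
    platform = if (nrow(reads)) reads$platform[1] else "unknown",
    read_type = if (nrow(reads)) reads$read_type[1] else "unknown")
  summary <- data.frame(
    n_input = nrow(reads),
    n_kept = sum(keep),
    n_removed_short = sum(decisions$decision == "removed_short"),
    n_removed_chimeric = sum(decisions$decision == "removed_chimeric"),
    stringsAsFactors = FALSE)
  if (sum(keep) > 0) {
    ls <- length_stats(kept)
    summary$total_bases <- ls$total_bases
    summary$n50 <- ls$n50
    summary$mean_length <- ls$mean_length
    summary$modal_length <- ls$modal_length
  }
  list(kept = kept, decisions = decisions, summary = summary)
}
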