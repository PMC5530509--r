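# nlr_motifs: six-frame translation, degenerate amino-acid motif scanning and
# none/partial/complete NLR classification. This is a lightweight,
# configurable motif engine in the spirit of MAST-based NLR annotation tools;
# the shipped motif set consists of well-known NB-ARC/LRR consensus motifs
# (P-loop, Kinase-2, GLPL, MHD-class, LRR repeat), editable by the user.

MOTIF_CATEGORIES <- c("pre_NB", "NB_ARC", "LRR")
MOTIF_ROLES <- c("ploop", "kinase2", "glpl", "mhd", "lrr", "other")

#' Define an amino-acid motif
#'
#' Patterns are degenerate amino-acid strings: plain letters match
#' themselves, `x` matches any residue, and bracketed classes such as
#' `[ILV]` match any member. A window matches when it has at most
#' `max_mismatches` mismatches at non-wildcard positions and contains no stop
#' (`*`).
#'
#' @param id motif name.
#' @param pattern degenerate pattern (>= 5 positions).
#' @param max_mismatches tolerated mismatches at non-wildcard positions.
#' @param category `"pre_NB"`, `"NB_ARC"` or `"LRR"`.
#' @param role the motif's role in the completeness rule: `"ploop"`,
#'   `"kinase2"`, `"glpl"`, `"mhd"`, `"lrr"` or `"other"`.
#' @return a list of class `motif_def`.
#' @export
motif_def <- function(id, pattern, max_mismatches = 1L,
                      category = c("NB_ARC", "pre_NB", "LRR"),
                      role = c("other", "ploop", "kinase2", "glpl", "mhd",
                               "lrr")) {
  category <- match.arg(category)
  role <- match.arg(role)
  pos <- parse_motif_pattern(pattern)
  stopifnot(length(pos) >= 5, max_mismatches < length(pos))
  structure(list(id = id, pattern = pattern, positions = pos,
                 max_mismatches = as.integer(max_mismatches),
                 category = category, role = role), class = "motif_def")
}

# split a degenerate pattern into per-position residue classes
# ('x' -> NA = wildcard)
parse_motif_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  pos <- list(); i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1
      while (j <= length(chars) && chars[j] != "]") j <- j + 1
      if (j > length(chars)) stop("unclosed '[' in motif pattern: ", pattern)
      pos[[length(pos) + 1]] <- chars[(i + 1):(j - 1)]
      i <- j + 1
    } else if (chars[i] == "x") {
      pos[[length(pos) + 1]] <- NA_character_
      i <- i + 1
    } else {
      pos[[length(pos) + 1]] <- chars[i]
      i <- i + 1
    }
  }
  pos
}

#' Default NLR motif set
#'
#' Ships the canonical NB-ARC and LRR consensus motifs used for coarse NLR
#' architecture calls: P-loop (`GGVGKTT`), Kinase-2 (`LLVLDDVW`), GLPL
#' (`GLPLAL`), an MHD-class motif (`xMHDx`) and the LRR repeat
#' (`LxxLxxLxL`). These are simple consensus placeholders for the richer
#' probabilistic motif models of dedicated NLR annotation tools; replace them
#' via `motif_def()` for calibrated analyses.
#'
#' @return list of [motif_def()] objects.
#' @export
default_nlr_motifs <- function() {
  list(
    motif_def("ploop", "GGVGKTT", 1L, "NB_ARC", "ploop"),
    motif_def("kinase2", "LLVLDDVW", 1L, "NB_ARC", "kinase2"),
    motif_def("glpl", "GLPLAL", 1L, "NB_ARC", "glpl"),
    motif_def("mhd", "xMHDx", 0L, "NB_ARC", "mhd"),
    motif_def("lrr", "LxxLxxLxL", 0L, "LRR", "lrr")
  )
}

#' Read a motif set from a configuration file
#'
#' The file is a JSON (or YAML) array of objects with keys `id`, `pattern`
#' and optionally `max_mismatches` (default 1), `category` (default
#' `"NB_ARC"`) and `role` (default `"other"`); see [motif_def()] for the
#' pattern syntax.
#'
#' @param path path to the motif configuration file.
#' @return list of [motif_def()] objects.
#' @export
read_motif_config <- function(path) {
  if (!file.exists(path)) stop("motif config not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML motif configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (length(raw) == 0) stop("motif config is empty: ", path)
  lapply(raw, function(m) {
    if (is.null(m$id) || is.null(m$pattern)) {
      stop("every motif needs 'id' and 'pattern' keys")
    }
    motif_def(m$id, m$pattern,
              max_mismatches = if (is.null(m$max_mismatches)) 1L else
                as.integer(m$max_mismatches),
              category = if (is.null(m$category)) "NB_ARC" else m$category,
              role = if (is.null(m$role)) "other" else m$role)
  })
}

#' Six-frame translation
#'
#' Standard genetic code; codons containing `N` translate to `X`; stop codons
#' are rendered `*`. Frames `-1`, `-2`, `-3` are the forward frames of the
#' reverse complement. Trailing incomplete codons are dropped.
#'
#' @param dna DNA string of length >= 3.
#' @return named character vector of six peptides (`+1`, `+2`, `+3`, `-1`,
#'   `-2`, `-3`).
#' @examples
#' six_frame_translate("ATGGCC")
#' @export
six_frame_translate <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1)
  dna <- normalize_dna(dna)
  if (nchar(dna) < 3) stop("sequence shorter than one codon")
  rc <- reverse_complement(dna)
  frames <- c(translate_frames(dna), translate_frames(rc))
  names(frames) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  frames
}

translate_frames <- function(s) {
  vapply(1:3, function(off) translate_one(substr(s, off, nchar(s))), "")
}

# codon-table translation via the Biostrings standard genetic code
translate_one <- function(s) {
  n <- nchar(s)
  if (n < 3) return("")
  starts <- seq(1, n - 2, by = 3)
  codons <- substring(s, starts, starts + 2)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X" # codons containing N (or other ambiguity)
  paste(aa, collapse = "")
}

#' Scan a peptide for motif occurrences
#'
#' Reports every window matching a motif pattern with at most its
#' `max_mismatches` mismatches at non-wildcard positions; windows containing
#' a stop (`*`) never match.
#'
#' @param peptide amino-acid string.
#' @param motifs list of [motif_def()] objects (non-empty).
#' @return data frame sorted by `aa_start`: columns `motif_id`, `aa_start`,
#'   `aa_end` (1-based inclusive), `mismatches`, `category`, `role`.
#' @export
scan_motifs <- function(peptide, motifs) {
  stopifnot(is.character(peptide), length(peptide) == 1, length(motifs) > 0)
  chars <- strsplit(peptide, "")[[1]]
  L <- length(chars)
  rows <- lapply(motifs, function(mo) {
    m <- length(mo$positions)
    W <- L - m + 1
    if (W < 1) return(NULL)
    mm <- integer(W)
    has_stop <- logical(W)
    for (p in seq_len(m)) {
      cp <- chars[p:(p + W - 1)]
      has_stop <- has_stop | cp == "*"
      cls <- mo$positions[[p]]
      if (!anyNA(cls)) mm <- mm + !(cp %in% cls)
    }
    hit <- which(mm <= mo$max_mismatches & !has_stop)
    if (length(hit) == 0) return(NULL)
    data.frame(motif_id = mo$id, aa_start = hit, aa_end = hit + m - 1L,
               mismatches = mm[hit], category = mo$category, role = mo$role,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(motif_id = character(), aa_start = integer(),
                      aa_end = integer(), mismatches = integer(),
                      category = character(), role = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$aa_start, out$aa_end, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# the ordered completeness rule, evaluated within one frame's hits:
# a P-loop-class hit, then a GLPL-class hit starting at or after its end,
# then >= 2 LRR hits downstream of the GLPL hit, all in order
frame_is_complete <- function(hits) {
  ploop <- hits[hits$role == "ploop" |
                  (hits$category == "pre_NB"), , drop = FALSE]
  if (nrow(ploop) == 0) return(FALSE)
  glpl <- hits[hits$role == "glpl", , drop = FALSE]
  lrr <- hits[hits$category == "LRR", , drop = FALSE]
  for (i in seq_len(nrow(ploop))) {
    g <- glpl[glpl$aa_start >= ploop$aa_end[i], , drop = FALSE]
    for (j in seq_len(nrow(g))) {
      n_lrr <- sum(lrr$aa_start >= g$aa_end[j])
      if (n_lrr >= 2) return(TRUE)
    }
  }
  FALSE
}

#' Classify a sequence as none / partial / complete NLR
#'
#' DNA input is translated in six frames and each frame scanned; peptide
#' input is scanned directly. The call is `complete` when the ordered motif
#' cassette (P-loop, then GLPL, then at least two LRR repeats downstream) is
#' present within a single frame; `partial` when any NB-ARC or LRR motif is
#' hit anywhere; `none` otherwise. For DNA the reported frame is the frame
#' satisfying the completeness rule (first in the order `+1 +2 +3 -1 -2 -3`),
#' or otherwise the frame maximizing the hit count (ties: lowest frame
#' index).
#'
#' @param x a DNA string, a one-row [sequence_set()], or a peptide when
#'   `is_peptide = TRUE`.
#' @param motifs list of [motif_def()] objects.
#' @param is_peptide set `TRUE` if `x` is an amino-acid sequence.
#' @return list with `call` (`"none"`, `"partial"`, `"complete"`),
#'   `frame_used`, `hits` (motif hits of the used frame) and `n_hits_total`.
#' @export
classify_sequence <- function(x, motifs = default_nlr_motifs(),
                              is_peptide = FALSE) {
  if (inherits(x, "sequence_set")) {
    stopifnot(nrow(x) == 1)
    x <- x$sequence
  }
  stopifnot(is.character(x), length(x) == 1)
  if (is_peptide) {
    frames <- c(protein = x)
  } else {
    frames <- six_frame_translate(x)
  }
  hits_by_frame <- lapply(frames, scan_motifs, motifs = motifs)
  complete_frames <- vapply(hits_by_frame, frame_is_complete, TRUE)
  n_hits <- vapply(hits_by_frame, nrow, 1L)
  if (any(complete_frames)) {
    f <- which(complete_frames)[1]
    call <- "complete"
  } else {
    f <- which.max(n_hits) # ties: first in frame order
    any_relevant <- any(vapply(hits_by_frame, function(h) {
      any(h$category %in% c("NB_ARC", "LRR"))
    }, TRUE))
    call <- if (any_relevant) "partial" else "none"
  }
  list(call = call, frame_used = names(frames)[f],
       hits = hits_by_frame[[f]], n_hits_total = sum(n_hits))
}

#' Motif-annotate a sequence set
#'
#' @param seqs a [sequence_set()].
#' @param motifs list of [motif_def()] objects.
#' @param is_peptide set `TRUE` for amino-acid sequences.
#' @return list with `table` (per-sequence call and frame) and `summary`
#'   (counts of none/partial/complete plus percentages of total reads and of
#'   motif-positive reads, 0--100 scale, unrounded).
#' @export
annotate_set <- function(seqs, motifs = default_nlr_motifs(),
                         is_peptide = FALSE) {
  stopifnot(inherits(seqs, "sequence_set"))
  calls <- lapply(seq_len(nrow(seqs)), function(i) {
    classify_sequence(seqs$sequence[i], motifs, is_peptide)
  })
  tab <- data.frame(
    id = seqs$id,
    call = vapply(calls, `[[`, "", "call"),
    frame = vapply(calls, `[[`, "", "frame_used"),
    n_hits = vapply(calls, function(cl) nrow(cl$hits), 1L),
    stringsAsFactors = FALSE)
  n <- nrow(tab)
  n_partial <- sum(tab$call == "partial")
  n_complete <- sum(tab$call == "complete")
  n_hit <- n_partial + n_complete
  summary <- data.frame(
    n_total = n, n_none = n - n_hit, n_partial = n_partial,
    n_complete = n_complete,
    hits_of_total_pct = if (n > 0) 100 * n_hit / n else 0,
    partial_of_hits_pct = if (n_hit > 0) 100 * n_partial / n_hit else 0,
    complete_of_hits_pct = if (n_hit > 0) 100 * n_complete / n_hit else 0,
    stringsAsFactors = FALSE)
  list(table = tab, summary = summary)
}
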