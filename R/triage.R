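# novel_triage: rapid identification of novel NLR genes. Reads are mapped to
# a reduced reference (with the genes of interest withheld); an empirical
# identity threshold (mean - k * SD of best-hit percent identity) defines
# "low-quality mapping" reads; those plus all unmapped reads are the novel-
# gene candidates, which are reassembled and scored against the withheld
# genes.

#' Triage configuration
#'
#' @param sd_multiplier how many sample standard deviations below the mean
#'   best-hit identity the candidate threshold sits (default 2).
#' @param recovery_criteria an [acceptance_criteria()] used to score
#'   recovery of withheld genes.
#' @param assembler `"toy"` (the built-in greedy overlap assembler) or
#'   `"none"` (candidates are returned unassembled; use an external long-read
#'   assembler and pass its contigs to [evaluate_recovery()]).
#' @param require_motifs filter assembled contigs to motif-positive ones
#'   (call `partial` or `complete`) before recovery scoring.
#' @return a list of class `triage_config`.
#' @export
triage_config <- function(sd_multiplier = 2.0,
                          recovery_criteria = acceptance_criteria(),
                          assembler = c("toy", "none"),
                          require_motifs = FALSE) {
  stopifnot(sd_multiplier > 0)
  structure(list(sd_multiplier = sd_multiplier,
                 recovery_criteria = recovery_criteria,
                 assembler = match.arg(assembler),
                 require_motifs = isTRUE(require_motifs)),
            class = "triage_config")
}

#' Remove entries from a reference set
#'
#' @param reference a [sequence_set()].
#' @param exclude_ids ids to withhold (all must be present, no duplicates).
#' @return the reduced [sequence_set()], order preserved.
#' @export
reduce_reference <- function(reference, exclude_ids) {
  stopifnot(inherits(reference, "sequence_set"))
  exclude_ids <- as.character(exclude_ids)
  if (anyDuplicated(exclude_ids)) {
    stop("duplicate ids in exclusion list: ",
         paste(unique(exclude_ids[duplicated(exclude_ids)]), collapse = ", "))
  }
  missing <- setdiff(exclude_ids, reference$id)
  if (length(missing) > 0) {
    stop("exclusion ids not present in reference: ",
         paste(missing, collapse = ", "))
  }
  reference[!reference$id %in% exclude_ids, ]
}

#' Empirical identity threshold
#'
#' `threshold = mean - multiplier * SD` over best-hit percent identities,
#' with the sample (n-1) standard deviation.
#'
#' @param identities numeric vector of percent identities (>= 2 values).
#' @param multiplier number of standard deviations (default 2).
#' @return list with `mean`, `sd`, `threshold` (percent scale).
#' @examples
#' identity_threshold(c(90, 92, 94)) # threshold 88
#' @export
identity_threshold <- function(identities, multiplier = 2.0) {
  if (length(identities) < 2) {
    stop("at least two identity values are required")
  }
  m <- mean(identities)
  s <- stats::sd(identities)
  list(mean = m, sd = s, threshold = m - multiplier * s)
}

#' Select novel-gene candidate reads
#'
#' Candidates are reads with no best hit against the reduced reference, plus
#' reads whose best-hit percent identity falls below the threshold. Input
#' order is preserved.
#'
#' @param reads the mapped [sequence_set()].
#' @param hits best-hit-per-read data frame from [map_reads()] against the
#'   reduced reference.
#' @param threshold percent-identity threshold (see [identity_threshold()]).
#' @return list with `candidates` (a [sequence_set()]), `n_unmapped`,
#'   `n_below_threshold`, `n_candidates`.
#' @export
select_candidates <- function(reads, hits, threshold) {
  stopifnot(inherits(reads, "sequence_set"))
  if (anyDuplicated(hits$query_id)) {
    stop("hits must be one best hit per read")
  }
  unmapped <- !(reads$id %in% hits$query_id)
  below_ids <- hits$query_id[100 * hits$identity < threshold]
  is_cand <- unmapped | reads$id %in% below_ids
  list(candidates = reads[is_cand, ],
       n_unmapped = sum(unmapped),
       n_below_threshold = length(below_ids),
       n_candidates = sum(is_cand))
}

#' Greedy overlap-layout toy assembler
#'
#' A deterministic, fixture-grade assembler for desk-scale experiments: the
#' highest-scoring overlapping pair meeting the overlap thresholds is merged
#' repeatedly until none remains. Dovetail overlaps and containments are
#' recognized on both strands; at a merge the overlap bases are taken from
#' the member with the lexicographically smaller id (a two-sequence majority
#' vote has no other deterministic resolution). Production analyses should
#' use a dedicated long-read assembler; this one exists so that the triage
#' stage can be exercised end to end.
#'
#' @param reads a non-empty [sequence_set()].
#' @param min_overlap minimum overlap alignment columns (default 300).
#' @param min_overlap_identity minimum overlap identity (default 0.90).
#' @param params an [alignment_params()].
#' @param end_slack tolerated unaligned overhang, in bases, when deciding
#'   that an overlap reaches a sequence end (default 50).
#' @return a [sequence_set()] of contigs with an attribute `members`, a named
#'   list mapping contig id to the member read ids.
#' @export
toy_assemble <- function(reads, min_overlap = 300L, min_overlap_identity = 0.90,
                         params = alignment_params(), end_slack = 50L) {
  stopifnot(inherits(reads, "sequence_set"), nrow(reads) > 0)
  seqs <- as.list(reads$sequence)
  names(seqs) <- reads$id
  members <- as.list(reads$id)
  names(members) <- reads$id

  overlap_of <- function(ida, idb) {
    raw <- .cpp_align_seeded(seqs[[ida]], seqs[[idb]], params$match,
                             params$mismatch, params$gap_open,
                             params$gap_extend, params$seed_k, params$band,
                             params$min_chain)
    if (!raw$found) return(NULL)
    cols <- raw$matches + raw$mismatches + raw$insertions + raw$deletions
    if (cols < min_overlap || raw$matches / cols < min_overlap_identity) {
      return(NULL)
    }
    la <- nchar(seqs[[ida]]); lb <- nchar(seqs[[idb]])
    qs <- raw$q_start + 1L; qe <- raw$q_end
    ss <- raw$s_start + 1L; se <- raw$s_end
    geom <- overlap_geometry(qs, qe, la, ss, se, lb, raw$strand, end_slack)
    if (is.null(geom)) return(NULL)
    c(list(a = ida, b = idb, score = raw$score, strand = raw$strand,
           qs = qs, qe = qe, ss = ss, se = se), geom)
  }

  # classify the overlap geometry on the forward strand of both sequences
  overlap_geometry <- function(qs, qe, la, ss, se, lb, strand, slack) {
    if (strand == "-") {
      # flip b: the hit covers b[ss..se] on the forward strand; after
      # reverse-complementing b it covers [lb-se+1 .. lb-ss+1]
      new_ss <- lb - se + 1L
      new_se <- lb - ss + 1L
      ss <- new_ss; se <- new_se
    }
    a_contained <- qs - 1 <= slack && la - qe <= slack
    b_contained <- ss - 1 <= slack && lb - se <= slack
    if (b_contained) return(list(type = "contain_b"))
    if (a_contained) return(list(type = "contain_a"))
    if (la - qe <= slack && ss - 1 <= slack) return(list(type = "a_then_b"))
    if (lb - se <= slack && qs - 1 <= slack) return(list(type = "b_then_a"))
    NULL # internal overlap only: paralog-style repeat, not a layout overlap
  }

  merge_pair <- function(ov) {
    ida <- ov$a; idb <- ov$b
    bseq <- seqs[[idb]]
    ss <- ov$ss; se <- ov$se
    if (ov$strand == "-") {
      bseq <- reverse_complement(bseq)
      lb <- nchar(bseq)
      ss <- lb - ov$se + 1L; se <- lb - ov$ss + 1L
    }
    aseq <- seqs[[ida]]
    use_a_overlap <- ida <= idb
    new_seq <- switch(ov$type,
      contain_b = aseq,
      contain_a = bseq,
      a_then_b = if (use_a_overlap) {
        paste0(substr(aseq, 1, ov$qe), substr(bseq, se + 1, nchar(bseq)))
      } else {
        paste0(substr(aseq, 1, ov$qs - 1), substr(bseq, ss, nchar(bseq)))
      },
      b_then_a = if (use_a_overlap) {
        paste0(substr(bseq, 1, ss - 1), aseq)
      } else {
        paste0(substr(bseq, 1, se), substr(aseq, ov$qe + 1, nchar(aseq)))
      })
    new_seq
  }

  # pair overlap cache, recomputed lazily for new contigs
  ids <- names(seqs)
  pairs <- list()
  add_pairs_for <- function(id, others) {
    for (o in others) {
      key <- paste(min(id, o), max(id, o), sep = "\r")
      ov <- overlap_of(min(id, o), max(id, o))
      pairs[[key]] <<- ov
    }
  }
  for (i in seq_along(ids)) {
    if (i < length(ids)) add_pairs_for(ids[i], ids[(i + 1):length(ids)])
  }

  counter <- 0L
  repeat {
    live <- pairs[!vapply(pairs, is.null, TRUE)]
    if (length(live) == 0) break
    scores <- vapply(live, function(p) p$score, 1)
    keys <- names(live)
    ord <- order(-scores, keys, method = "radix")
    ov <- live[[ord[1]]]
    counter <- counter + 1L
    new_id <- sprintf("ctg_%04d", counter)
    new_seq <- merge_pair(ov)
    new_members <- c(members[[ov$a]], members[[ov$b]])
    # retire the merged pair
    drop <- c(ov$a, ov$b)
    seqs[drop] <- NULL
    members[drop] <- NULL
    key_parts <- strsplit(names(pairs), "\r", fixed = TRUE)
    involves <- vapply(key_parts, function(p) any(p %in% drop), TRUE)
    pairs <- pairs[!involves]
    seqs[[new_id]] <- new_seq
    members[[new_id]] <- new_members
    if (length(seqs) > 1) {
      add_pairs_for(new_id, setdiff(names(seqs), new_id))
    }
  }

  out <- sequence_set(id = names(seqs),
                      sequence = unlist(seqs, use.names = FALSE),
                      read_type = "contig")
  attr(out, "members") <- members
  out
}

#' Score recovery of withheld genes from assembled contigs
#'
#' A withheld gene counts as recovered when, after same-subject
#' deduplication, some contig carries an accepted best hit for it.
#'
#' @param contigs assembled candidate contigs, a [sequence_set()].
#' @param withheld the withheld genes, a [sequence_set()].
#' @param criteria an [acceptance_criteria()].
#' @param params an [alignment_params()].
#' @return list with `per_gene` (gene id, recovered flag, identity percent,
#'   alignment length, contig id), `n_recovered`, `n_withheld`,
#'   `mean_identity_pct` and `sd_identity_pct` across recovered genes.
#' @export
evaluate_recovery <- function(contigs, withheld,
                              criteria = acceptance_criteria(),
                              params = alignment_params()) {
  stopifnot(inherits(withheld, "sequence_set"))
  per_gene <- data.frame(gene_id = withheld$id, recovered = FALSE,
                         identity_pct = NA_real_, aln_len = NA_integer_,
                         contig_id = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(contigs) && nrow(contigs) > 0 && nrow(withheld) > 0) {
    hits <- best_hit_search(withheld, contigs, criteria, params)
    hits <- dedupe_same_subject(hits)$kept
    idx <- match(hits$query_id, per_gene$gene_id)
    per_gene$recovered[idx] <- TRUE
    per_gene$identity_pct[idx] <- 100 * hits$identity
    per_gene$aln_len[idx] <- hits$columns
    per_gene$contig_id[idx] <- hits$subject_id
  }
  rec <- per_gene$identity_pct[per_gene$recovered]
  list(per_gene = per_gene,
       n_recovered = sum(per_gene$recovered),
       n_withheld = nrow(per_gene),
       mean_identity_pct = if (length(rec)) mean(rec) else NA_real_,
       sd_identity_pct = if (length(rec) > 1) stats::sd(rec) else
         if (length(rec) == 1) 0 else NA_real_)
}

#' Run the novel-gene triage end to end
#'
#' Maps reads to the reduced reference, computes the empirical identity
#' threshold, selects candidate reads, optionally assembles them with the
#' toy assembler (and optionally filters contigs for NLR motifs), and, when
#' the withheld genes are supplied, scores their recovery.
#'
#' @param reads curated reads, a [sequence_set()].
#' @param reference the full annotated reference, a [sequence_set()].
#' @param exclude_ids reference ids to withhold (see [reduce_reference()]).
#' @param config a [triage_config()].
#' @param params an [alignment_params()].
#' @param motifs motif set used when `config$require_motifs` is set.
#' @param withheld optional [sequence_set()] of the withheld genes for
#'   recovery evaluation (defaults to the excluded reference entries).
#' @return a triage report: list with `mean_identity`, `sd_identity`,
#'   `threshold` (percent), `n_mapped`, `n_unmapped`, `n_below_threshold`,
#'   `n_candidates`, `candidates`, `contigs` (or `NULL`), `hits`, and
#'   `recovery` (or `NULL`).
#' @export
run_triage <- function(reads, reference, exclude_ids,
                       config = triage_config(),
                       params = alignment_params(),
                       motifs = default_nlr_motifs(),
                       withheld = NULL) {
  stopifnot(inherits(reads, "sequence_set"), inherits(reference, "sequence_set"))
  reduced <- reduce_reference(reference, exclude_ids)
  if (is.null(withheld) && length(exclude_ids) > 0) {
    withheld <- reference[reference$id %in% exclude_ids, ]
  }
  hits <- map_reads(reads, reduced, params)
  th <- identity_threshold(100 * hits$identity, config$sd_multiplier)
  sel <- select_candidates(reads, hits, th$threshold)
  contigs <- NULL
  if (config$assembler == "toy" && nrow(sel$candidates) > 0) {
    contigs <- toy_assemble(sel$candidates, params = params)
    if (config$require_motifs && nrow(contigs) > 0) {
      ann <- annotate_set(contigs, motifs)
      keep_ids <- ann$table$id[ann$table$call != "none"]
      mem <- attr(contigs, "members")
      contigs <- contigs[contigs$id %in% keep_ids, ]
      attr(contigs, "members") <- mem[keep_ids]
    }
  }
  recovery <- NULL
  if (!is.null(withheld) && nrow(withheld) > 0) {
    recovery <- evaluate_recovery(contigs, withheld,
                                  config$recovery_criteria, params)
  }
  list(mean_identity = th$mean, sd_identity = th$sd,
       threshold = th$threshold,
       n_mapped = nrow(hits), n_unmapped = sel$n_unmapped,
       n_below_threshold = sel$n_below_threshold,
       n_candidates = sel$n_candidates,
       candidates = sel$candidates, contigs = contigs, hits = hits,
       recovery = recovery)
}
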