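# read_qc: read-set statistics (counts, yield, N50, mean/modal length) and
# alignment-derived accuracy summaries.

#' Length statistics of a read set
#'
#' N50 is the length of the smallest read such that reads at least that long
#' comprise at least half of all bases. The modal length is the most frequent
#' exact length (smallest on ties).
#'
#' @param reads a non-empty [sequence_set()].
#' @return list with `n_reads`, `total_bases`, `n50`, `mean_length`,
#'   `modal_length`.
#' @examples
#' length_stats(sequence_set(paste0("r", 1:5),
#'                           sapply(c(10, 9, 8, 7, 6), strrep, x = "A")))
#' @export
length_stats <- function(reads) {
  stopifnot(inherits(reads, "sequence_set"))
  if (nrow(reads) == 0) stop("cannot compute length statistics of an empty set")
  len <- nchar(reads$sequence)
  total <- sum(as.numeric(len))
  dec <- sort(len, decreasing = TRUE)
  n50 <- dec[which(cumsum(as.numeric(dec)) >= total / 2)[1]]
  tab <- table(len)
  modal <- as.integer(names(tab)[tab == max(tab)])[1] # names sorted ascending
  list(n_reads = length(len), total_bases = total, n50 = as.integer(n50),
       mean_length = total / length(len), modal_length = modal)
}

#' Alignment-derived accuracy statistics
#'
#' Per-read accuracy is the identity of the read's best alignment hit
#' (matches over all alignment columns). The modal accuracy is the mode of
#' accuracies binned at two decimal places on the percent scale (smallest on
#' ties). Unmapped reads are excluded from the accuracy values but enter the
#' mapped fraction.
#'
#' @param hits data frame of best hits, one per mapped read (see
#'   [map_reads()]).
#' @param total_reads total number of reads the hits were derived from.
#' @return list with `mean_accuracy`, `modal_accuracy`, `mean_error_rate`,
#'   `mapped_fraction`, `n_mapped`.
#' @export
accuracy_stats <- function(hits, total_reads) {
  if (total_reads < nrow(hits)) {
    stop("total_reads (", total_reads, ") is smaller than the number of hits (",
         nrow(hits), ")")
  }
  if (nrow(hits) == 0) {
    return(list(mean_accuracy = NA_real_, modal_accuracy = NA_real_,
                mean_error_rate = NA_real_, mapped_fraction = 0,
                n_mapped = 0L))
  }
  stopifnot(all(hits$columns > 0))
  acc <- hits$identity
  pct_binned <- round_half_up(100 * acc, 2)
  tab <- table(pct_binned)
  modal <- as.numeric(names(tab)[tab == max(tab)])[1] / 100
  list(mean_accuracy = mean(acc), modal_accuracy = modal,
       mean_error_rate = 1 - mean(acc),
       mapped_fraction = nrow(hits) / total_reads, n_mapped = nrow(hits))
}

#' Per-group QC report table
#'
#' One row per named read group with length statistics and, for groups that
#' carry a reference, mapping-derived accuracy statistics.
#'
#' @param groups named list of [sequence_set()] objects.
#' @param references optional named list of reference [sequence_set()]s
#'   (names matching `groups`); groups without a reference get `NA` accuracy
#'   fields.
#' @param params an [alignment_params()] used for mapping.
#' @return data frame with one row per group; percentage columns are on the
#'   0--100 scale.
#' @export
qc_table <- function(groups, references = list(),
                     params = alignment_params()) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    ls <- length_stats(g)
    row <- data.frame(group = nm, n_reads = ls$n_reads,
                      total_bases = ls$total_bases, n50 = ls$n50,
                      mean_length = ls$mean_length,
                      modal_length = ls$modal_length,
                      mean_accuracy_pct = NA_real_,
                      modal_accuracy_pct = NA_real_,
                      mean_error_rate_pct = NA_real_,
                      mapped_pct = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(references[[nm]])) {
      hits <- map_reads(g, references[[nm]], params)
      as <- accuracy_stats(hits, nrow(g))
      row$mean_accuracy_pct <- 100 * as$mean_accuracy
      row$modal_accuracy_pct <- 100 * as$modal_accuracy
      row$mean_error_rate_pct <- 100 * as$mean_error_rate
      row$mapped_pct <- 100 * as$mapped_fraction
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
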