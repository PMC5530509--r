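# formats_io: sequence containers and the FASTA/FASTQ/TSV/JSON boundary.
# Parsing and writing delegate to Biostrings; this layer adds the read-level
# metadata (platform, read type), input normalization and validation.

PLATFORMS <- c("nanopore", "pacbio", "unknown")
READ_TYPES <- c("template", "complement", "twoD", "subread", "roi",
                "contig", "unknown")

#' Construct a sequence set
#'
#' A `sequence_set` is the package's container for reads, baits, reference
#' genes and contigs: a data frame with columns `id`, `sequence`, `quality`
#' (Phred+33 string or `NA`), `platform` and `read_type`. Sequences are
#' normalized on construction: `U` becomes `T`, lowercase is uppercased, and
#' any other letter is mapped to `N` with a warning.
#'
#' @param id character vector of unique, non-empty record ids.
#' @param sequence character vector of DNA sequences.
#' @param quality optional character vector of per-base Phred+33 quality
#'   strings (same lengths as `sequence`), or `NA`.
#' @param platform one of `"nanopore"`, `"pacbio"`, `"unknown"` (recycled).
#' @param read_type one of `"template"`, `"complement"`, `"twoD"`,
#'   `"subread"`, `"roi"`, `"contig"`, `"unknown"` (recycled).
#' @param source_path optional path the records were read from.
#' @return an object of class `sequence_set`.
#' @examples
#' sequence_set(c("r1", "r2"), c("ACGT", "GGGTTU"))
#' @export
sequence_set <- function(id = character(), sequence = character(),
                         quality = NA_character_, platform = "unknown",
                         read_type = "unknown", source_path = NA_character_) {
  id <- as.character(id)
  sequence <- normalize_dna(as.character(sequence))
  n <- length(id)
  if (length(sequence) != n) stop("id and sequence must have equal length")
  if (n > 0 && any(!nzchar(id))) stop("record ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  quality <- rep_len(as.character(quality), max(n, 1L))[seq_len(n)]
  platform <- match.arg(rep_len(platform, max(n, 1L))[1], PLATFORMS)
  read_type <- match.arg(rep_len(read_type, max(n, 1L))[1], READ_TYPES)
  bad <- !is.na(quality) & nchar(quality) != nchar(sequence)
  if (any(bad)) {
    stop("quality length differs from sequence length for record(s): ",
         paste(id[bad], collapse = ", "))
  }
  out <- data.frame(id = id, sequence = sequence, quality = quality,
                    platform = rep_len(platform, n),
                    read_type = rep_len(read_type, n),
                    stringsAsFactors = FALSE)
  attr(out, "source_path") <- source_path
  class(out) <- c("sequence_set", "data.frame")
  out
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set with %d record(s)", nrow(x)))
  sp <- attr(x, "source_path")
  if (!is.na(sp)) cat(" from ", sp, sep = "")
  cat("\n")
  if (nrow(x) > 0) {
    show <- utils::head(x, 6)
    prev <- data.frame(id = show$id, length = nchar(show$sequence),
                       has_quality = !is.na(show$quality),
                       read_type = show$read_type)
    print(prev)
    if (nrow(x) > 6) cat("...", nrow(x) - 6, "more\n")
  }
  invisible(x)
}

#' @export
`[.sequence_set` <- function(x, i, ...) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source_path") <- attr(x, "source_path")
  class(out) <- c("sequence_set", "data.frame")
  out
}

# uppercase, U -> T, anything outside {A,C,G,T,N} -> N (with one warning)
normalize_dna <- function(x) {
  if (length(x) == 0) return(x)
  x <- chartr("U", "T", toupper(x))
  if (any(grepl("[^ACGTN]", x))) {
    warning("non-ACGTN letters replaced with N")
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

sniff_format <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) return("fasta") # empty file: treat as empty FASTA
    line <- trimws(line)
    if (nzchar(line)) {
      first <- substr(line, 1, 1)
      if (first == ">") return("fasta")
      if (first == "@") return("fastq")
      stop("cannot sniff sequence format of ", path,
           ": first record does not start with '>' or '@'")
    }
  }
}

# structural pre-check of a 4-line FASTQ so that malformed records can be
# reported by id (the Biostrings parser stops with a positional message only)
validate_fastq <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) == 0) return(invisible(TRUE))
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ ", path, ": number of lines is not a multiple of 4")
  }
  ids <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  seps <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  if (any(substr(ids, 1, 1) != "@") || any(substr(seps, 1, 1) != "+")) {
    stop("malformed FASTQ ", path, ": record header or separator line broken")
  }
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    nm <- sub("^@", "", sub("[ \t].*$", "", ids[bad]))
    stop("malformed FASTQ record(s) with quality length != sequence length: ",
         paste(nm, collapse = ", "))
  }
  qchars <- unlist(strsplit(quals, ""), use.names = FALSE)
  if (length(qchars) && any(utf8ToInt(paste(qchars, collapse = "")) < 33)) {
    stop("malformed FASTQ ", path, ": quality characters below Phred+33 range")
  }
  invisible(TRUE)
}

#' Read sequences from FASTA or FASTQ
#'
#' FASTQ qualities are interpreted as Phred+33. `format = "auto"` sniffs the
#' first non-blank character (`>` for FASTA, `@` for FASTQ). Multi-line
#' (wrapped) FASTA is accepted. An empty file yields an empty set.
#'
#' @param path file path.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @param platform,read_type tags applied to all records (see
#'   [sequence_set()]).
#' @return a [sequence_set()].
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           platform = "unknown", read_type = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- sniff_format(path)
  if (format == "fastq") {
    validate_fastq(path)
    ss <- tryCatch(
      Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
      error = function(e) stop("failed to parse FASTQ ", path, ": ",
                               conditionMessage(e)))
    qual <- as.character(S4Vectors::mcols(ss)$qualities)
  } else {
    ss <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) stop("failed to parse FASTA ", path, ": ",
                               conditionMessage(e)))
    qual <- rep(NA_character_, length(ss))
  }
  ids <- sub("[ \t].*$", "", names(ss))
  sequence_set(id = ids, sequence = as.character(ss), quality = qual,
               platform = platform, read_type = read_type, source_path = path)
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTA output is wrapped at 80 columns; FASTQ output requires a quality
#' string on every record and writes Phred+33.
#'
#' @param x a [sequence_set()].
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "sequence_set"))
  if (format == "fastq") {
    missing_q <- is.na(x$quality)
    if (any(missing_q)) {
      stop("cannot write FASTQ, records without quality: ",
           paste(x$id[missing_q], collapse = ", "))
    }
    ss <- Biostrings::BStringSet(x$sequence)
    names(ss) <- x$id
    q <- Biostrings::BStringSet(x$quality)
    Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = q)
  } else {
    ss <- Biostrings::BStringSet(x$sequence)
    names(ss) <- x$id
    Biostrings::writeXStringSet(ss, path, format = "fasta", width = 80)
  }
  invisible(path)
}

#' Write a tabular report as TSV or JSON
#'
#' Rows must share one key set. TSV output has a header line; JSON output is
#' an array of objects. Numeric columns whose name ends in `_pct` are rendered
#' as percentages with two decimals (half-up).
#'
#' @param rows a data frame, or a list of named lists sharing the same keys.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(rows)) {
    if (length(rows) > 0) {
      keys <- lapply(rows, function(r) sort(names(r)))
      if (length(unique(vapply(keys, paste, "", collapse = "\r"))) > 1) {
        stop("heterogeneous row keys in table")
      }
      rows <- do.call(rbind, lapply(rows, function(r) {
        as.data.frame(r, stringsAsFactors = FALSE)
      }))
    } else {
      rows <- data.frame()
    }
  }
  pct_cols <- grepl("_pct$|^pct_", names(rows)) &
    vapply(rows, is.numeric, TRUE)
  for (cn in names(rows)[pct_cols]) {
    rows[[cn]] <- format_pct(rows[[cn]], scale100 = TRUE)
  }
  if (format == "tsv") {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}
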