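# shared fixtures and oracles, generated in code (no stored data files)

rnd_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent Biostrings local-alignment score oracle (both strands), with
# the same scoring convention (gap of length L costs open + L * extend)
biostrings_local_score <- function(a, b, match = 2, mismatch = -3,
                                   gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  s1 <- Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend))
  s2 <- Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a),
    Biostrings::reverseComplement(Biostrings::DNAString(b)), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend))
  max(s1, s2, 0)
}

# brute-force semiglobal oracle: minimum edit distance of `pattern` against
# any substring of `text` (window lengths restricted to m +/- slack, which is
# sufficient for distances <= slack), via utils::adist
brute_min_window_edits <- function(pattern, text, slack) {
  m <- nchar(pattern); n <- nchar(text)
  best <- Inf
  lens <- max(1, m - slack):min(n, m + slack)
  for (s in seq_len(n)) {
    e <- pmin(s + lens - 1, n)
    subs <- unique(substring(text, s, e))
    d <- utils::adist(pattern, subs)
    best <- min(best, min(d))
    if (best == 0) break
  }
  best
}

# small simulated reference shared across tests (memoized per session)
fixture_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 20240915, n_families = 3,
                        paralogs_per_family = 2, novel_genes = 2,
                        gene_length_range = c(2400L, 3000L))
      cache <<- list(config = cfg, ref = simulate_reference(cfg))
    }
    cache
  }
})
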