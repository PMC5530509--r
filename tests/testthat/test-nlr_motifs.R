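# reverse-translate a peptide deterministically (first codon of each amino
# acid in the standard code)
pep2dna <- function(pep) {
  gc <- Biostrings::GENETIC_CODE
  first <- vapply(strsplit(pep, "")[[1]], function(a) {
    names(gc)[gc == a][1]
  }, "")
  paste(first, collapse = "")
}

test_that("six-frame translation follows the standard code", {
  fr <- six_frame_translate("ATGGCC")
  expect_equal(fr[["+1"]], "MA")
  expect_equal(fr[["-1"]], "GH") # +1 frame of revcomp GGCCAT
  expect_equal(six_frame_translate("ATNGCC")[["+1"]], "XA") # N -> X
  expect_equal(six_frame_translate("TAAGCC")[["+1"]], "*A") # stop rendered *
  expect_error(six_frame_translate("AT"), "codon")
  # frame names map onto the reverse complement's forward frames
  set.seed(70)
  dna <- rnd_dna(60)
  expect_equal(six_frame_translate(dna)[["-2"]],
               six_frame_translate(reverse_complement(dna))[["+2"]])
})

test_that("motif scanning respects mismatch budgets, wildcards and stops", {
  motifs <- default_nlr_motifs()
  ploop <- motifs[[1]]
  pep <- paste0("AAAAA", "GGVGKTT", "AAAAA")
  hits <- scan_motifs(pep, list(ploop))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$aa_start, 6)
  expect_equal(hits$aa_end, 12)

  # one substitution is tolerated, two are not (brute-force premise)
  expect_equal(nrow(scan_motifs("AAAAAGGVGKTAAAAAA", list(ploop))), 1)
  expect_equal(nrow(scan_motifs("AAAAAGGVGMTAAAAAA", list(ploop))), 0)

  # wildcards in the LRR pattern match any residue at x positions
  lrr <- motifs[[5]]
  expect_equal(nrow(scan_motifs("LQWLRPLKL", list(lrr))), 1)
  expect_equal(nrow(scan_motifs("LQWLRPAKL", list(lrr))), 0) # L position hit

  # a stop codon inside the window disqualifies it
  expect_equal(nrow(scan_motifs("AAGGV*KTTAA", list(ploop))), 0)

  # bracketed residue classes
  cls <- motif_def("cls", "[ILV]AAAA[DE]", 0L)
  expect_equal(nrow(scan_motifs("XVAAAADX", list(cls))), 1)
  expect_equal(nrow(scan_motifs("XGAAAADX", list(cls))), 0)
})

test_that("the ordered cassette rule separates complete from partial", {
  spacer <- strrep("A", 30)
  complete_pep <- paste0(spacer, "GGVGKTT", spacer, "GLPLAL", spacer,
                         "LAALAALAL", spacer, "LAALAALAL", spacer)
  partial_pep <- paste0(spacer, "GGVGKTT", spacer)
  none_pep <- strrep("AQWERTY", 30)

  dna_c <- pep2dna(complete_pep)
  expect_equal(classify_sequence(dna_c)$call, "complete")
  expect_equal(classify_sequence(dna_c)$frame_used, "+1")
  expect_equal(classify_sequence(pep2dna(partial_pep))$call, "partial")
  expect_equal(classify_sequence(pep2dna(none_pep))$call, "none")

  # complete call requires the order: LRRs before the P-loop do not count
  disordered <- paste0(spacer, "LAALAALAL", spacer, "LAALAALAL", spacer,
                       "GLPLAL", spacer, "GGVGKTT", spacer)
  expect_equal(classify_sequence(pep2dna(disordered))$call, "partial")

  # peptide input path
  expect_equal(classify_sequence(complete_pep, is_peptide = TRUE)$call,
               "complete")
})

test_that("classification is strand-symmetric", {
  fx <- fixture_reference()
  for (i in 1:4) {
    dna <- fx$ref$genes$sequence[i]
    expect_equal(classify_sequence(dna)$call,
                 classify_sequence(reverse_complement(dna))$call)
  }
})

test_that("a frameshift between cassette motifs demotes the call", {
  fx <- fixture_reference()
  ann <- fx$ref$annotation
  for (i in which(!ann$withheld)[1:4]) {
    dna <- fx$ref$genes$sequence[i]
    expect_equal(classify_sequence(dna)$call, "complete")
    # delete one base between the P-loop and the downstream motifs
    cut <- (ann$ploop_aa_start[i] + 10) * 3
    shifted <- paste0(substr(dna, 1, cut - 1),
                      substr(dna, cut + 1, nchar(dna)))
    expect_true(classify_sequence(shifted)$call %in% c("partial", "none"))
  }
})

test_that("set annotation reports counts and percentages", {
  fx <- fixture_reference()
  ann <- annotate_set(fx$ref$genes)
  expect_equal(ann$summary$n_complete, nrow(fx$ref$genes))
  expect_equal(ann$summary$complete_of_hits_pct, 100)
  # repeats whose six frames contain no leucine, hence no LRR-like windows
  none_set <- sequence_set(c("n1", "n2"),
                           c(strrep("GGC", 120), strrep("ACC", 120)))
  ann0 <- annotate_set(none_set)
  expect_equal(ann0$summary$n_none, 2)
  expect_equal(ann0$summary$hits_of_total_pct, 0)
})

test_that("motif sets load from a configuration file", {
  cfgf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(id = "ploop", pattern = "GGVGKTT", max_mismatches = 1,
         category = "NB_ARC", role = "ploop"),
    list(id = "lrr", pattern = "LxxLxxLxL", max_mismatches = 0,
         category = "LRR", role = "lrr")), cfgf, auto_unbox = TRUE)
  motifs <- read_motif_config(cfgf)
  expect_length(motifs, 2)
  expect_equal(motifs[[1]]$role, "ploop")
  expect_equal(nrow(scan_motifs("AAAGGVGKTTAAA", motifs)), 1)
  expect_error(read_motif_config("/nonexistent.json"), "not found")
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(id = "x")), bad, auto_unbox = TRUE)
  expect_error(read_motif_config(bad), "pattern")
})
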