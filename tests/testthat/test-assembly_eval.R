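test_that("best-hit search accepts full-length copies and rejects fragments", {
  fx <- fixture_reference()
  genes <- fx$ref$genes[c(1, 3), ] # one gene from each of two families
  contigs <- sequence_set(
    c("c_full", "c_frag"),
    c(genes$sequence[1], substr(genes$sequence[2], 1, 400)))
  hits <- best_hit_search(genes, contigs)
  expect_equal(hits$query_id, genes$id[1]) # only the full copy is accepted
  expect_equal(hits$identity, 1)
  # the 400 bp fragment is below the 500-column acceptance default
  relaxed <- best_hit_search(genes, contigs, acceptance_criteria(300, 0.85))
  expect_setequal(relaxed$query_id, genes$id[1:2])
})

test_that("same-subject deduplication keeps one hit per overlapping region", {
  mk <- function(q, s, s1, s2, score) {
    data.frame(query_id = q, subject_id = s, q_start = 1, q_end = s2 - s1 + 1,
               s_start = s1, s_end = s2, strand = "+", score = score,
               matches = score / 2, mismatches = 0, insertions = 0,
               deletions = 0, columns = s2 - s1 + 1,
               identity = (score / 2) / (s2 - s1 + 1),
               q_len = s2 - s1 + 1, s_len = 10000)
  }
  # two queries on the same contig span: higher score survives
  two <- rbind(mk("q1", "c1", 100, 2000, 3000), mk("q2", "c1", 150, 1900, 2800))
  dd <- dedupe_same_subject(two)
  expect_equal(dd$kept$query_id, "q1")
  expect_equal(dd$removed$query_id, "q2")

  # disjoint spans of one contig: both kept
  disj <- rbind(mk("q1", "c1", 100, 2000, 3000), mk("q2", "c1", 2500, 4000, 2800))
  expect_equal(nrow(dedupe_same_subject(disj)$kept), 2)

  # a chain of three mutually overlapping hits collapses to one
  chain <- rbind(mk("q1", "c1", 100, 2000, 3000),
                 mk("q2", "c1", 500, 2400, 2900),
                 mk("q3", "c1", 900, 2800, 2700))
  expect_equal(nrow(dedupe_same_subject(chain)$kept), 1)
  expect_equal(dedupe_same_subject(chain)$kept$query_id, "q1")
})

test_that("hit summaries use sample standard deviations", {
  mk <- function(q, ident) {
    data.frame(query_id = q, subject_id = "c", q_start = 1, q_end = 1000,
               s_start = 1, s_end = 1000, strand = "+", score = 1,
               matches = ident * 1000, mismatches = (1 - ident) * 1000,
               insertions = 0, deletions = 0, columns = 1000,
               identity = ident, q_len = 1000, s_len = 1000)
  }
  hits <- rbind(mk("a", 0.90), mk("b", 0.92), mk("c", 0.94))
  s <- summarize_hits(hits, 10)
  expect_equal(s$mean_identity_pct, 92)
  expect_equal(s$sd_identity_pct, 2)
  expect_equal(s$coverage_pct, 30)
  expect_equal(s$mean_query_len_pct, 100)
  expect_error(summarize_hits(hits, 2), "one-per-query")
})

test_that("self-evaluation of a reference is the identity case", {
  fx <- fixture_reference()
  genes <- fx$ref$genes
  hits <- best_hit_search(genes, genes)
  hits <- dedupe_same_subject(hits)$kept
  s <- summarize_hits(hits, nrow(genes))
  expect_equal(s$coverage_pct, 100)
  expect_equal(s$mean_identity_pct, 100)
  expect_equal(s$sd_identity_pct, 0)
  expect_equal(s$mean_query_len_pct, 100)
})

test_that("summaries are invariant under input order", {
  fx <- fixture_reference()
  genes <- fx$ref$genes
  hits <- best_hit_search(genes, genes)
  set.seed(9)
  s1 <- summarize_hits(hits, nrow(genes))
  s2 <- summarize_hits(hits[sample(nrow(hits)), ], nrow(genes))
  expect_equal(s1, s2)
})

test_that("mapping summaries recover planted coverage and error rate", {
  fx <- fixture_reference()
  genes <- fx$ref$genes
  cfg <- sim_config(seed = 51, coverage = 20, adapter = "",
                    chimera_rate = 0, off_target_fraction = 0,
                    error_profile = error_profile("perfect"))
  rr <- simulate_reads(genes, cfg)
  ms <- mapping_summary(rr$reads, genes)
  expect_equal(ms$mapped_pct, 100)
  expect_equal(ms$mean_coverage, 20, tolerance = 0.05)
  expect_equal(ms$error_rate_pct, 0)

  cfg2 <- sim_config(seed = 52, coverage = 5, adapter = "",
                     chimera_rate = 0, off_target_fraction = 0,
                     error_profile = error_profile("custom",
                                                   sub_rate = 0.02,
                                                   ins_rate = 0.01,
                                                   del_rate = 0.01))
  rr2 <- simulate_reads(genes, cfg2)
  ms2 <- mapping_summary(rr2$reads, genes)
  expect_equal(ms2$error_rate_pct, 4, tolerance = 0.5 / 4)
})

test_that("dot-plot export reports strand-resolved long matches", {
  fx <- fixture_reference()
  gene <- fx$ref$genes[1, ]
  # self comparison: one forward diagonal segment
  d1 <- dotplot_export(gene, gene)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$strand, "+")
  expect_equal(d1$r_start, 1)
  expect_equal(d1$r_end, nchar(gene$sequence))
  # reverse-complement contig: one reverse segment
  rc <- sequence_set("rc_contig", reverse_complement(gene$sequence))
  d2 <- dotplot_export(rc, gene)
  expect_equal(d2$strand, "-")
  # shared segment below the minimum match length is not reported
  set.seed(53)
  shared <- rnd_dna(400)
  a <- sequence_set("a", paste0(rnd_dna(800), shared))
  b <- sequence_set("b", paste0(shared, rnd_dna(800)))
  expect_equal(nrow(dotplot_export(a, b, min_match = 500)), 0)
  expect_equal(nrow(dotplot_export(a, b, min_match = 300)), 1)
})
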