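test_that("reference reduction removes exactly the excluded entries", {
  fx <- fixture_reference()
  genes <- fx$ref$genes
  red <- reduce_reference(genes, fx$ref$withheld_ids)
  expect_equal(nrow(red), nrow(genes) - length(fx$ref$withheld_ids))
  expect_equal(red$id, setdiff(genes$id, fx$ref$withheld_ids))
  expect_equal(reduce_reference(genes, character())$id, genes$id)
  expect_error(reduce_reference(genes, "not_there"), "not_there")
  expect_error(reduce_reference(genes, rep(genes$id[1], 2)), "duplicate")
})

test_that("the empirical threshold is mean minus multiples of the sample SD", {
  th <- identity_threshold(c(90, 92, 94), 2)
  expect_equal(th$mean, 92)
  expect_equal(th$sd, 2)
  expect_equal(th$threshold, 88)
  th0 <- identity_threshold(rep(95, 10))
  expect_equal(th0$sd, 0)
  expect_equal(th0$threshold, 95)
  expect_error(identity_threshold(95), "two")
})

test_that("the threshold estimator converges on normal samples", {
  set.seed(80)
  draws <- rnorm(10000, mean = 95, sd = 1.5)
  th <- identity_threshold(draws, 2)
  expect_equal(th$threshold, 92.0, tolerance = 0.1 / 92)
})

test_that("candidate selection pools unmapped and low-identity reads", {
  reads <- sequence_set(c("r1", "r2", "r3", "r4"),
                        replicate(4, rnd_dna(100)))
  hits <- data.frame(query_id = c("r1", "r2", "r3"),
                     identity = c(0.95, 0.94, 0.70))
  sel <- select_candidates(reads, hits, threshold = 88)
  expect_equal(sel$candidates$id, c("r3", "r4")) # low-identity + unmapped
  expect_equal(sel$n_unmapped, 1)
  expect_equal(sel$n_below_threshold, 1)
  expect_equal(sel$n_candidates, sel$n_unmapped + sel$n_below_threshold)

  all_perfect <- data.frame(query_id = c("r1", "r2", "r3", "r4"),
                            identity = rep(1, 4))
  expect_equal(select_candidates(reads, all_perfect, 88)$n_candidates, 0)
})

test_that("candidate selection is monotone in the SD multiplier", {
  set.seed(81)
  reads <- sequence_set(sprintf("r%03d", 1:60), replicate(60, rnd_dna(50)))
  hits <- data.frame(query_id = reads$id[1:55],
                     identity = pmin(1, rnorm(55, 0.95, 0.04)))
  prev <- NULL
  for (mult in c(0.5, 1, 2, 3)) {
    th <- identity_threshold(100 * hits$identity, mult)
    sel <- select_candidates(reads, hits, th$threshold)
    if (!is.null(prev)) expect_true(all(sel$candidates$id %in% prev))
    prev <- sel$candidates$id
  }
})

test_that("the toy assembler merges dovetail overlaps into contigs", {
  set.seed(82)
  gene <- rnd_dna(2000)
  a <- substr(gene, 1, 1200)
  b <- substr(gene, 701, 2000) # 500 bp overlap
  contigs <- toy_assemble(sequence_set(c("a", "b"), c(a, b)))
  expect_equal(nrow(contigs), 1)
  expect_equal(contigs$sequence, gene)
  expect_setequal(attr(contigs, "members")[[1]], c("a", "b"))

  # reverse-complement member is re-oriented before merging
  contigs2 <- toy_assemble(sequence_set(c("a", "b"),
                                        c(a, reverse_complement(b))))
  expect_equal(nrow(contigs2), 1)
  expect_true(contigs2$sequence == gene ||
                contigs2$sequence == reverse_complement(gene))

  # disjoint reads stay separate
  disjoint <- sequence_set(c("x", "y"), c(rnd_dna(800), rnd_dna(800)))
  expect_equal(nrow(toy_assemble(disjoint)), 2)
})

test_that("tiling reads assemble into a single accurate contig", {
  set.seed(83)
  gene <- rnd_dna(5000)
  starts <- c(seq(1, 3300, by = 300), 3501) # right-anchored final read
  reads <- sequence_set(
    sprintf("t%02d", seq_along(starts)),
    vapply(starts, function(s) substr(gene, s, s + 1499), ""))
  contigs <- toy_assemble(reads)
  expect_equal(nrow(contigs), 1)
  hit <- local_align(contigs$sequence, gene, method = "banded")
  expect_gte(hit$identity, 0.999)
  expect_gte(hit$columns, 5000 * 0.999)
})

test_that("withheld genes diverged beyond the threshold gap are recovered", {
  # the triage guarantee regime: the novel reads are a small fraction of the
  # library (as for a handful of fusion-domain genes in a large reference),
  # so the mean - 2 SD threshold sits well above their mapping identity and
  # every novel-origin read is selected deterministically
  cfg <- sim_config(seed = 84, n_families = 8, paralogs_per_family = 2,
                    novel_genes = 1, novel_divergence = 0.12,
                    gene_length_range = c(2500L, 3500L),
                    read_length_sdlog = 0.45,
                    read_length_meanlog = log(1400) + 0.45^2,
                    coverage = 25, error_profile = error_profile("perfect"),
                    chimera_rate = 0, off_target_fraction = 0, adapter = "")
  ref <- simulate_reference(cfg)
  rr <- simulate_reads(ref$genes, cfg)
  tr <- run_triage(rr$reads, ref$genes, ref$withheld_ids)

  # divergence (12%) exceeds the empirical threshold gap, so selection is
  # not a tail event: nearly all novel-origin reads fall below threshold
  expect_lte(100 - tr$threshold, 12)
  src <- setNames(rr$truth$source_gene, rr$truth$read_id)
  novel_reads <- names(src)[grepl("^novel", src)]
  selected <- tr$candidates$id
  expect_gte(mean(novel_reads %in% selected), 0.9)
  known_reads <- names(src)[!grepl("^novel", src)]
  expect_lte(mean(known_reads %in% selected), 0.1)

  expect_equal(tr$recovery$n_recovered, 1)
  expect_gte(tr$recovery$mean_identity_pct, 99.9) # error-free reassembly
})

test_that("recovery scoring marks withheld genes found in contigs", {
  fx <- fixture_reference()
  withheld <- fx$ref$genes[fx$ref$genes$id %in% fx$ref$withheld_ids, ]
  exact <- sequence_set(paste0("c_", withheld$id), withheld$sequence)
  rec <- evaluate_recovery(exact, withheld)
  expect_equal(rec$n_recovered, nrow(withheld))
  expect_equal(rec$mean_identity_pct, 100)
  expect_equal(rec$sd_identity_pct, 0)

  rec0 <- evaluate_recovery(sequence_set(), withheld)
  expect_equal(rec0$n_recovered, 0)
  expect_true(all(!rec0$per_gene$recovered))
})
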