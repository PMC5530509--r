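test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 90, n_families = 2, paralogs_per_family = 2,
                    novel_genes = 1, coverage = 2, chimera_rate = 0.1)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$genes$sequence, r2$genes$sequence)
  rr1 <- simulate_reads(r1$genes, cfg)
  rr2 <- simulate_reads(r2$genes, cfg)
  expect_identical(rr1$reads, rr2$reads)
  expect_identical(rr1$truth, rr2$truth)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_sequences(rr1$reads, f1, "fastq")
  write_sequences(rr2$reads, f2, "fastq")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("paralog divergence is realized as pairwise identity", {
  cfg <- sim_config(seed = 91, n_families = 4, paralogs_per_family = 2,
                    paralog_divergence = 0.05, novel_genes = 0,
                    gene_length_range = c(2800L, 3200L))
  ref <- simulate_reference(cfg)
  for (f in sprintf("fam%02d", 1:4)) {
    pair <- ref$genes[ref$annotation$family == f, ]
    hit <- local_align(pair$sequence[1], pair$sequence[2], method = "banded")
    expect_equal(100 * hit$identity, 95, tolerance = 1 / 95)
  }
  # zero divergence makes paralogs identical
  cfg0 <- sim_config(seed = 91, n_families = 2, paralogs_per_family = 3,
                     paralog_divergence = 0, novel_genes = 0)
  ref0 <- simulate_reference(cfg0)
  fam1 <- ref0$genes$sequence[ref0$annotation$family == "fam01"]
  expect_equal(length(unique(fam1)), 1)
})

test_that("every generated gene carries a complete motif cassette", {
  fx <- fixture_reference()
  ann <- annotate_set(fx$ref$genes)
  expect_true(all(ann$table$call == "complete"))
})

test_that("novel genes are diverged from every known gene", {
  cfg <- sim_config(seed = 92, n_families = 3, paralogs_per_family = 2,
                    novel_genes = 2, novel_divergence = 0.12)
  ref <- simulate_reference(cfg)
  known <- ref$genes[!ref$genes$id %in% ref$withheld_ids, ]
  for (nid in ref$withheld_ids) {
    nseq <- ref$genes$sequence[ref$genes$id == nid]
    best <- best_subject_hit <- map_reads(
      sequence_set(nid, nseq), known)
    expect_lte(best$identity, 0.90)
    # ...yet still a complete NLR
    expect_equal(classify_sequence(nseq)$call, "complete")
  }
  # same seed reproduces the same spiked genes
  ref2 <- simulate_reference(cfg)
  expect_identical(ref$genes, ref2$genes)
})

test_that("bait tiling covers every base with the expected bait count", {
  gene <- sequence_set("g", rnd_dna(600))
  baits <- design_baits(gene, 120, 60)
  expect_equal(nrow(baits), 9) # floor((600 - 120) / 60) + 1
  # step == length gives a non-overlapping tiling
  nb <- design_baits(gene, 120, 120)
  expect_equal(nrow(nb), 5)
  starts <- as.integer(sub(".*bait", "", nb$id))
  expect_equal(sum(nchar(nb$sequence)), 600)
  # every base covered when step <= bait length
  cov <- integer(600)
  b2 <- design_baits(gene, 120, 100)
  for (i in seq_len(nrow(b2))) {
    at <- regexpr(b2$sequence[i], gene$sequence, fixed = TRUE)
    cov[at:(at + 119)] <- cov[at:(at + 119)] + 1L
  }
  expect_true(all(cov >= 1))
})

test_that("planted error rates are realized in the truth table", {
  fx <- fixture_reference()
  cfg <- sim_config(seed = 93, coverage = 25, adapter = "",
                    chimera_rate = 0, off_target_fraction = 0,
                    error_profile = error_profile("nanopore_2d"))
  rr <- simulate_reads(fx$ref$genes, cfg)
  pre_error_len <- nchar(rr$reads$sequence) - rr$truth$n_ins + rr$truth$n_del
  total <- sum(pre_error_len)
  rate <- sum(rr$truth$n_sub + rr$truth$n_ins + rr$truth$n_del) / total
  expect_equal(rate, 0.09, tolerance = 0.01 / 0.09)
  ratio <- sum(rr$truth$n_ins) / sum(rr$truth$n_del)
  expect_equal(ratio, 0.5, tolerance = 0.2) # planted 2:4 insertion:deletion
  # error-free profile yields exact decorated substrings
  cfg0 <- sim_config(seed = 93, coverage = 2,
                     error_profile = error_profile("perfect"),
                     chimera_rate = 0, off_target_fraction = 0)
  rr0 <- simulate_reads(fx$ref$genes, cfg0)
  tr <- rr0$truth[1, ]
  gene <- fx$ref$genes$sequence[fx$ref$genes$id == tr$source_gene]
  insert <- substr(gene, tr$gene_start, tr$gene_end)
  core <- paste0(cfg0$adapter, insert, cfg0$adapter)
  if (tr$strand == "-") core <- reverse_complement(core)
  expect_equal(rr0$reads$sequence[1], core)
})

test_that("chimera planting follows the configured rate", {
  fx <- fixture_reference()
  cfg <- sim_config(seed = 94, coverage = 25, chimera_rate = 0.1,
                    off_target_fraction = 0)
  rr <- simulate_reads(fx$ref$genes, cfg)
  n <- nrow(rr$truth)
  k <- sum(rr$truth$is_chimera)
  ci <- qbinom(c(0.005, 0.995), n, 0.1)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
  expect_true(all(!is.na(rr$truth$second_source[rr$truth$is_chimera])))
})

test_that("simulated data exercises every curation decision class", {
  fx <- fixture_reference()
  # wide length distribution with a short-fragment tail so the 150 bp rule
  # has work to do
  cfg <- sim_config(seed = 95, coverage = 20, chimera_rate = 0.1,
                    off_target_fraction = 0.1,
                    read_length_sdlog = 0.7,
                    read_length_meanlog = log(700) + 0.7^2)
  rr <- simulate_reads(fx$ref$genes, cfg)
  ccfg <- curation_config(adapters = list(
    adapter_spec("amp", cfg$adapter, 0.20)))
  cur <- curate_set(rr$reads, ccfg)
  expect_gt(cur$summary$n_kept, 0)
  expect_gt(cur$summary$n_removed_chimeric, 0)
  expect_gt(cur$summary$n_removed_short, 0)
})
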