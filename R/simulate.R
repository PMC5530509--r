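# simulate: deterministic synthetic-data generator. Emulates the statistical
# structure a long-read RenSeq pipeline sees: clustered families of highly
# similar NLR-like genes carrying an ordered motif cassette, tiled capture
# baits, indel-rich platform error profiles, adapter-decorated reads, PCR
# chimeras joined by adapter sequence, and an off-target read fraction.
# Every stage derives its own sub-seed from the configured seed, so outputs
# are byte-reproducible and stages can be regenerated independently.

# fixed 65-base amplification-adapter stand-in (Illumina-style primer plus
# padding; a synthetic constant, not a vendor sequence)
DEFAULT_ADAPTER <- paste0("AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACG",
                          "CTCTTCCGATCTGCCTA")

#' Platform error profile
#'
#' Presets reflect the indel-dominated error structure of long-read
#' platforms: `nanopore_2d` (3% substitutions, 2% insertions, 4% deletions,
#' ~9% total, matching ~91% mean accuracy consensus reads) and `pacbio_roi`
#' (0.2%/0.1%/0.1%, matching >99.5% accuracy multi-pass consensus reads).
#'
#' @param name `"nanopore_2d"`, `"pacbio_roi"`, `"perfect"`, or `"custom"`.
#' @param sub_rate,ins_rate,del_rate per-base rates for `"custom"`.
#' @return a list of class `error_profile`.
#' @export
error_profile <- function(name = c("nanopore_2d", "pacbio_roi", "perfect",
                                   "custom"),
                          sub_rate = 0, ins_rate = 0, del_rate = 0) {
  name <- match.arg(name)
  rates <- switch(name,
    nanopore_2d = c(0.03, 0.02, 0.04),
    pacbio_roi = c(0.002, 0.001, 0.001),
    perfect = c(0, 0, 0),
    custom = c(sub_rate, ins_rate, del_rate))
  stopifnot(all(rates >= 0), all(rates < 0.3), sum(rates) < 0.5)
  structure(list(name = name, sub_rate = rates[1], ins_rate = rates[2],
                 del_rate = rates[3], total = sum(rates)),
            class = "error_profile")
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale RenSeq-like experiment: five families of
#' two paralogs (10 known genes) plus three withheld novel genes, gene
#' lengths 2.5--4.5 kb, reads with a log-normal length distribution with
#' mode ~2.8 kb truncated to [200, 20000] bp, 50x coverage, a 65-bp adapter
#' on both read ends, 2% PCR chimeras and a 20% off-target fraction.
#'
#' @param n_families number of paralog families.
#' @param paralogs_per_family genes per family.
#' @param paralog_divergence per-base substitution divergence of each
#'   paralog from its family ancestor (motif cassette positions are
#'   conserved).
#' @param gene_length_range min/max gene length in bp.
#' @param novel_genes number of withheld novel genes.
#' @param novel_divergence divergence of novel genes from a randomly chosen
#'   existing gene (must be at least `paralog_divergence`).
#' @param read_length_meanlog,read_length_sdlog log-normal read-length
#'   parameters; the default meanlog is chosen so the distribution mode is
#'   2800 bp at the default sdlog.
#' @param read_length_min,read_length_max truncation bounds in bp.
#' @param coverage mean per-gene coverage (x).
#' @param error_profile an [error_profile()].
#' @param adapter adapter sequence decorating every read (set `""` to
#'   disable decoration).
#' @param chimera_rate per-read probability of a PCR chimera.
#' @param off_target_fraction fraction of reads drawn from random off-target
#'   sequence.
#' @param bait_length,bait_step bait tiling parameters (see
#'   [design_baits()]).
#' @param seed mandatory integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_families = 5L, paralogs_per_family = 2L,
                       paralog_divergence = 0.05,
                       gene_length_range = c(2500L, 4500L),
                       novel_genes = 3L, novel_divergence = 0.12,
                       read_length_sdlog = 0.45,
                       read_length_meanlog = log(2800) + read_length_sdlog^2,
                       read_length_min = 200L, read_length_max = 20000L,
                       coverage = 50, error_profile = renseqr::error_profile(),
                       adapter = DEFAULT_ADAPTER, chimera_rate = 0.02,
                       off_target_fraction = 0.20, bait_length = 120L,
                       bait_step = 60L, seed) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  stopifnot(n_families >= 1, paralogs_per_family >= 1,
            paralog_divergence >= 0, paralog_divergence < 1,
            length(gene_length_range) == 2,
            gene_length_range[1] <= gene_length_range[2],
            novel_genes >= 0, novel_divergence >= paralog_divergence,
            coverage > 0, chimera_rate >= 0, chimera_rate < 1,
            off_target_fraction >= 0, off_target_fraction < 1)
  if (nchar(adapter) > 0 && nchar(adapter) < 8) {
    stop("adapter must be empty or at least 8 bases")
  }
  structure(list(
    n_families = as.integer(n_families),
    paralogs_per_family = as.integer(paralogs_per_family),
    paralog_divergence = paralog_divergence,
    gene_length_range = as.integer(gene_length_range),
    novel_genes = as.integer(novel_genes),
    novel_divergence = novel_divergence,
    read_length_meanlog = read_length_meanlog,
    read_length_sdlog = read_length_sdlog,
    read_length_min = as.integer(read_length_min),
    read_length_max = as.integer(read_length_max),
    coverage = coverage, error_profile = error_profile,
    adapter = normalize_dna(adapter), chimera_rate = chimera_rate,
    off_target_fraction = off_target_fraction,
    bait_length = as.integer(bait_length), bait_step = as.integer(bait_step),
    seed = as.integer(seed)), class = "sim_config")
}

# per-stage sub-seeds below 2^31
stage_seed <- function(seed, stage) {
  offsets <- c(reference = 101L, novel = 202L, reads = 303L, baits = 404L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

# synonymous codon table (no stops) from the standard genetic code
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# build one stop-free ORF (DNA) of ~len bp carrying the ordered motif
# cassette P-loop -> Kinase-2 -> GLPL -> MHD -> LRR x3; returns the gene and
# the protected (motif) base positions
build_cassette_gene <- function(len) {
  n_aa <- max(len %/% 3, 120L)
  prot <- sample(AA20, n_aa, replace = TRUE)
  lrr_inst <- function() {
    x <- sample(AA20, 9, replace = TRUE)
    x[c(1, 4, 7, 9)] <- "L"
    x
  }
  cassette <- list(
    ploop = strsplit("GGVGKTT", "")[[1]],
    kinase2 = strsplit("LLVLDDVW", "")[[1]],
    glpl = strsplit("GLPLAL", "")[[1]],
    mhd = c("L", "M", "H", "D", "V"),
    lrr1 = lrr_inst(), lrr2 = lrr_inst(), lrr3 = lrr_inst())
  rel <- c(ploop = 0.14, kinase2 = 0.25, glpl = 0.40, mhd = 0.55,
           lrr1 = 0.68, lrr2 = 0.78, lrr3 = 0.88)
  aa_protected <- integer()
  for (nm in names(cassette)) {
    at <- max(1L, round(rel[[nm]] * n_aa))
    idx <- at:(at + length(cassette[[nm]]) - 1L)
    prot[idx] <- cassette[[nm]]
    aa_protected <- c(aa_protected, idx)
  }
  tab <- codons_by_aa()
  codons <- vapply(prot, function(a) {
    ch <- tab[[a]]
    ch[sample.int(length(ch), 1)]
  }, "")
  gene <- paste(codons, collapse = "")
  protected <- sort(unique(as.vector(
    vapply(aa_protected, function(i) ((i - 1L) * 3L) + 1:3, integer(3)))))
  list(sequence = gene, protected = protected,
       motif_aa_start = vapply(names(cassette), function(nm) {
         as.integer(max(1L, round(rel[[nm]] * n_aa)))
       }, 1L))
}

# substitute exactly round(rate * n_mutable) bases, never inside protected
# positions; realized divergence therefore equals the nominal rate
mutate_gene <- function(sequence, rate, protected) {
  if (rate <= 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  mutable <- setdiff(seq_along(chars), protected)
  n_mut <- round(rate * length(chars))
  n_mut <- min(n_mut, length(mutable))
  pos <- sample(mutable, n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate an annotated NLR-like reference
#'
#' Each family is one random ancestor gene with a planted, in-frame,
#' stop-free motif cassette; paralogs are per-base substitution mutants of
#' the ancestor (cassette positions conserved, emulating purifying selection
#' on core motifs). Novel genes are generated with [spike_novel()] and
#' tagged `withheld` in the annotation.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (a [sequence_set()]; withheld novel genes
#'   included), `annotation` (family, divergence, withheld flag, motif
#'   cassette coordinates) and `withheld_ids`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  res <- with_seed(stage_seed(config$seed, "reference"), {
    ids <- character(); seqs <- character()
    fam <- character(); div <- numeric(); withheld <- logical()
    ploop_aa <- integer()
    ancestors <- list()
    for (f in seq_len(config$n_families)) {
      len <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1)
      anc <- build_cassette_gene(len)
      ancestors[[f]] <- anc
      for (p in seq_len(config$paralogs_per_family)) {
        # the first paralog is the ancestral copy itself, so a paralog pair
        # sits at the nominal divergence rather than twice it
        rate <- if (p == 1) 0 else config$paralog_divergence
        g <- mutate_gene(anc$sequence, rate, anc$protected)
        ids <- c(ids, sprintf("fam%02d_g%02d", f, p))
        seqs <- c(seqs, g)
        fam <- c(fam, sprintf("fam%02d", f))
        div <- c(div, rate)
        withheld <- c(withheld, FALSE)
        ploop_aa <- c(ploop_aa, anc$motif_aa_start[["ploop"]])
      }
    }
    list(ids = ids, seqs = seqs, fam = fam, div = div, withheld = withheld,
         ploop_aa = ploop_aa, ancestors = ancestors)
  })
  genes <- sequence_set(res$ids, res$seqs, read_type = "contig")
  annotation <- data.frame(id = res$ids, family = res$fam,
                           divergence = res$div, withheld = res$withheld,
                           ploop_aa_start = res$ploop_aa,
                           stringsAsFactors = FALSE)
  out <- list(genes = genes, annotation = annotation,
              withheld_ids = character(), ancestors = res$ancestors)
  if (config$novel_genes > 0) {
    sp <- spike_novel(out, config$novel_genes, config$novel_divergence,
                      stage_seed(config$seed, "novel"))
    out <- sp
  }
  out
}

#' Spike withheld novel genes into a simulated reference
#'
#' Each novel gene derives from a randomly chosen existing gene at the
#' stated substitution divergence (cassette positions conserved), so that it
#' still classifies as a complete NLR yet is diverged from every known gene.
#' Novel genes are present in the simulated sample but must be withheld from
#' the reference handed to the triage stage.
#'
#' @param reference output of [simulate_reference()] (or a compatible list
#'   with `genes`, `annotation`, `ancestors`).
#' @param n number of novel genes (>= 1).
#' @param divergence per-base substitution divergence from the source gene.
#' @param seed integer seed.
#' @return the augmented reference list, with `withheld_ids` set.
#' @export
spike_novel <- function(reference, n, divergence, seed) {
  stopifnot(n >= 1)
  genes <- reference$genes
  ann <- reference$annotation
  known <- ann[!ann$withheld, , drop = FALSE]
  res <- with_seed(seed, {
    ids <- character(); seqs <- character(); src <- character()
    for (k in seq_len(n)) {
      pick <- sample.int(nrow(known), 1)
      src_id <- known$id[pick]
      fam_idx <- match(known$family[pick], sprintf("fam%02d",
                                                  seq_along(reference$ancestors)))
      anc <- reference$ancestors[[fam_idx]]
      base_seq <- genes$sequence[genes$id == src_id]
      g <- mutate_gene(base_seq, divergence, anc$protected)
      ids <- c(ids, sprintf("novel_%02d", k))
      seqs <- c(seqs, g)
      src <- c(src, src_id)
    }
    list(ids = ids, seqs = seqs, src = src)
  })
  genes2 <- sequence_set(c(genes$id, res$ids),
                         c(genes$sequence, res$seqs), read_type = "contig")
  ann2 <- rbind(ann, data.frame(id = res$ids,
                                family = paste0("novel_from_", res$src),
                                divergence = divergence, withheld = TRUE,
                                ploop_aa_start = NA_integer_,
                                stringsAsFactors = FALSE))
  list(genes = genes2, annotation = ann2,
       withheld_ids = c(reference$withheld_ids, res$ids),
       ancestors = reference$ancestors)
}

#' Design tiled baits over a gene set
#'
#' Windows of `bait_length` bases every `step` bases per gene, with a final
#' right-anchored window so every base is covered when `step <=
#' bait_length`.
#'
#' @param genes a [sequence_set()].
#' @param bait_length bait length in bp (default 120; chosen above the
#'   96-column bait-hit rule).
#' @param step tiling step in bp (default 60).
#' @return a [sequence_set()] of baits named `<gene>_bait<k>`.
#' @export
design_baits <- function(genes, bait_length = 120L, step = 60L) {
  stopifnot(inherits(genes, "sequence_set"), nrow(genes) > 0,
            bait_length >= 1, step >= 1)
  if (bait_length > min(nchar(genes$sequence))) {
    stop("bait_length exceeds the shortest gene")
  }
  ids <- character(); seqs <- character()
  for (i in seq_len(nrow(genes))) {
    L <- nchar(genes$sequence[i])
    starts <- seq(1L, L - bait_length + 1L, by = step)
    if (starts[length(starts)] != L - bait_length + 1L) {
      starts <- c(starts, L - bait_length + 1L) # right-anchored final window
    }
    ids <- c(ids, sprintf("%s_bait%03d", genes$id[i], seq_along(starts)))
    seqs <- c(seqs, substring(genes$sequence[i], starts,
                              starts + bait_length - 1L))
  }
  sequence_set(ids, seqs)
}

# apply per-base substitution/insertion/deletion errors; returns the mutated
# sequence and realized event counts
apply_errors <- function(sequence, profile) {
  L <- nchar(sequence)
  if (profile$total == 0 || L == 0) {
    return(list(sequence = sequence, n_sub = 0L, n_ins = 0L, n_del = 0L))
  }
  chars <- strsplit(sequence, "")[[1]]
  u <- runif(L)
  is_sub <- u < profile$sub_rate
  is_del <- u >= profile$sub_rate & u < profile$sub_rate + profile$del_rate
  is_ins <- u >= profile$sub_rate + profile$del_rate &
    u < profile$sub_rate + profile$del_rate + profile$ins_rate
  out <- chars
  for (p in which(is_sub)) {
    out[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  if (any(is_ins)) {
    ins_bases <- sample(c("A", "C", "G", "T"), sum(is_ins), replace = TRUE)
    out[is_ins] <- paste0(out[is_ins], ins_bases)
  }
  out[is_del] <- ""
  list(sequence = paste(out, collapse = ""),
       n_sub = sum(is_sub), n_ins = sum(is_ins), n_del = sum(is_del))
}

phred_char <- function(error_rate) {
  q <- if (error_rate <= 0) 40L else
    as.integer(min(40, round(-10 * log10(error_rate))))
  intToUtf8(q + 33L)
}

#' Simulate long reads with ground truth
#'
#' Fragments are sampled from the genes (length log-normal, truncated, and
#' clamped to the gene length) until each gene reaches the target coverage;
#' off-target reads of random sequence are added to reach the configured
#' off-target fraction. With probability `chimera_rate` a read is a fusion of
#' two fragments joined by the adapter; every read is decorated with the
#' adapter on both ends; per-base errors follow the error profile (applied to
#' the full decorated read); strands are uniform. Quality strings are flat at
#' the Phred of the profile's total error rate. A truth record accompanies
#' every read.
#'
#' @param genes a [sequence_set()] of sample genes (including any withheld
#'   novel genes: they are part of the sample).
#' @param config a [sim_config()].
#' @return list with `reads` (a [sequence_set()] with qualities) and `truth`
#'   (data frame: `read_id`, `source_gene` (or `"off_target"`),
#'   `gene_start`, `gene_end`, `strand`, `is_chimera`, `second_source`,
#'   `n_sub`, `n_ins`, `n_del`, `has_adapters`).
#' @export
simulate_reads <- function(genes, config) {
  stopifnot(inherits(genes, "sequence_set"), nrow(genes) > 0,
            inherits(config, "sim_config"))
  prof <- config$error_profile
  adapter <- config$adapter
  with_seed(stage_seed(config$seed, "reads"), {
    draw_len <- function() {
      repeat {
        l <- round(rlnorm(1, config$read_length_meanlog,
                          config$read_length_sdlog))
        if (l >= config$read_length_min && l <= config$read_length_max) {
          return(as.integer(l))
        }
      }
    }
    # the sampled length is the read as the sequencer reports it, adapters
    # included; the insert is what remains after the two end adapters
    insert_len <- function() {
      max(draw_len() - 2L * nchar(adapter), 30L)
    }
    draw_fragment <- function() {
      gi <- sample.int(nrow(genes), 1)
      L <- nchar(genes$sequence[gi])
      flen <- min(insert_len(), L)
      fs <- sample.int(L - flen + 1L, 1)
      list(gene = genes$id[gi],
           seq = substr(genes$sequence[gi], fs, fs + flen - 1L),
           start = fs, end = fs + flen - 1L)
    }
    target_bases <- config$coverage * sum(nchar(genes$sequence))
    frags <- list(); tot <- 0
    while (tot < target_bases) {
      f <- draw_fragment()
      frags[[length(frags) + 1]] <- f
      tot <- tot + nchar(f$seq)
    }
    n_target <- length(frags)
    otf <- config$off_target_fraction
    n_off <- if (otf > 0) round(n_target * otf / (1 - otf)) else 0L

    reads <- vector("list", n_target + n_off)
    truth <- vector("list", n_target + n_off)
    qchar <- phred_char(prof$total)
    make_read <- function(idx, frag, is_off) {
      id <- sprintf("read_%05d", idx)
      chim <- runif(1) < config$chimera_rate
      second <- NA_character_
      core <- frag$seq
      if (chim) {
        f2 <- draw_fragment()
        second <- f2$gene
        core <- paste0(frag$seq, adapter, f2$seq)
      }
      decorated <- paste0(adapter, core, adapter)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") decorated <- reverse_complement(decorated)
      err <- apply_errors(decorated, prof)
      list(read = list(id = id, seq = err$sequence,
                       qual = strrep(qchar, nchar(err$sequence))),
           truth = data.frame(
             read_id = id,
             source_gene = if (is_off) "off_target" else frag$gene,
             gene_start = if (is_off) NA_integer_ else frag$start,
             gene_end = if (is_off) NA_integer_ else frag$end,
             strand = strand, is_chimera = chim, second_source = second,
             n_sub = err$n_sub, n_ins = err$n_ins, n_del = err$n_del,
             has_adapters = nchar(adapter) > 0,
             stringsAsFactors = FALSE))
    }
    idx <- 0L
    for (f in frags) {
      idx <- idx + 1L
      r <- make_read(idx, f, is_off = FALSE)
      reads[[idx]] <- r$read; truth[[idx]] <- r$truth
    }
    for (k in seq_len(n_off)) {
      idx <- idx + 1L
      f <- list(gene = "off_target", seq = random_dna(insert_len()),
                start = NA_integer_, end = NA_integer_)
      r <- make_read(idx, f, is_off = TRUE)
      reads[[idx]] <- r$read; truth[[idx]] <- r$truth
    }
    rs <- sequence_set(
      id = vapply(reads, function(r) r$id, ""),
      sequence = vapply(reads, function(r) r$seq, ""),
      quality = vapply(reads, function(r) r$qual, ""),
      platform = if (prof$name == "pacbio_roi") "pacbio" else "nanopore",
      read_type = if (prof$name == "pacbio_roi") "roi" else "twoD")
    tr <- do.call(rbind, truth)
    rownames(tr) <- NULL
    list(reads = rs, truth = tr)
  })
}
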