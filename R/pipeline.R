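# cli_report: configuration validation and the fixed-order pipeline driver
# (curate -> qc -> ontarget -> motifs -> [assembly] -> eval -> triage), with
# per-stage TSV/JSON reports and a manifest carrying input hashes, package
# version and seed. Long-read assembly itself is an external step: the
# pipeline either ingests pre-assembled contigs or, when explicitly allowed,
# uses the fixture-grade toy assembler.

PIPELINE_STAGES <- c("curate", "qc", "ontarget", "motifs", "assembly",
                     "eval", "triage")

pipeline_defaults <- function() {
  list(
    reads = NULL,            # path to FASTQ/FASTA reads (required)
    baits = NULL,            # path to bait FASTA (ontarget stage)
    reference = NULL,        # path to annotated reference FASTA (eval/triage)
    contigs = NULL,          # path to externally assembled contigs (eval)
    exclude_ids = NULL,      # path to one-id-per-line file (triage)
    out_dir = ".",
    seed = NULL,
    stages = PIPELINE_STAGES[PIPELINE_STAGES != "assembly"],
    end_trim = 65L, min_length = 150L, adapter_error_rate = 0.20,
    chimera_flank = 50L, adapter_fasta = NULL,
    min_bait_length = 96L, min_bait_identity = 0.80,
    eval_min_length = 500L, eval_min_identity = 0.85,
    dedupe_overlap = 0.5,
    dotplot_min_match = 500L,
    motif_config = NULL,
    sd_multiplier = 2.0, assembler = "none", require_motifs = FALSE,
    log_level = "info")
}

#' Validate a pipeline configuration
#'
#' Collects and reports all problems at once; unknown keys are rejected so
#' that typos never pass silently.
#'
#' @param config a named list of settings (see `pipeline_defaults` in the
#'   package sources), or a path to a JSON (or YAML, if the yaml package is
#'   available) file containing one.
#' @return the completed configuration list of class `pipeline_config`;
#'   errors with the full problem list otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required for YAML configs")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    errors <- c(errors, paste0("unknown configuration key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  num_pos <- c(end_trim = 0, min_length = 1, chimera_flank = 1,
               min_bait_length = 1, eval_min_length = 1,
               dotplot_min_match = 1)
  for (key in names(num_pos)) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || v < num_pos[[key]]) {
      errors <- c(errors, sprintf("%s must be a single number >= %g",
                                  key, num_pos[[key]]))
    }
  }
  for (key in c("min_bait_identity", "eval_min_identity", "dedupe_overlap")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      errors <- c(errors, paste0(key, " must be in (0, 1]"))
    }
  }
  if (!is.numeric(cfg$adapter_error_rate) || cfg$adapter_error_rate < 0 ||
      cfg$adapter_error_rate >= 0.5) {
    errors <- c(errors, "adapter_error_rate must be in [0, 0.5)")
  }
  if (!is.numeric(cfg$sd_multiplier) || cfg$sd_multiplier <= 0) {
    errors <- c(errors, "sd_multiplier must be positive")
  }
  if (!all(cfg$stages %in% PIPELINE_STAGES)) {
    errors <- c(errors, paste0("unknown stage(s): ",
                               paste(setdiff(cfg$stages, PIPELINE_STAGES),
                                     collapse = ", ")))
  }
  if (!cfg$assembler %in% c("none", "toy")) {
    errors <- c(errors, "assembler must be 'none' or 'toy'")
  }
  if (is.null(cfg$reads)) {
    errors <- c(errors, "reads input path is required")
  }
  for (key in c("reads", "baits", "reference", "contigs", "exclude_ids",
                "adapter_fasta", "motif_config")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p)) {
      errors <- c(errors, sprintf("%s file not found: %s", key, p))
    }
  }
  needs <- list(ontarget = "baits", eval = "reference", triage = "reference")
  for (st in names(needs)) {
    if (st %in% cfg$stages && is.null(cfg[[needs[[st]]]])) {
      errors <- c(errors, sprintf("stage '%s' requires the '%s' input",
                                  st, needs[[st]]))
    }
  }
  if ("triage" %in% cfg$stages && is.null(cfg$exclude_ids)) {
    errors <- c(errors, "stage 'triage' requires the 'exclude_ids' input")
  }
  if (length(errors) > 0) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' Run the RenSeq analysis pipeline
#'
#' Executes the enabled stages in fixed order (curate, qc, ontarget, motifs,
#' assembly hand-off, eval, triage) on the configured inputs, writing each
#' stage's TSV/JSON report into `out_dir` together with a manifest (input
#' MD5 hashes, package version, seed, per-stage status).
#'
#' @param config a [validate_config()]-accepted configuration (list or file
#'   path).
#' @return list of stage results (invisibly also written to `out_dir`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  results <- list()
  status <- setNames(rep("skipped", length(PIPELINE_STAGES)), PIPELINE_STAGES)

  reads <- read_sequences(cfg$reads)
  adapters <- list()
  if (!is.null(cfg$adapter_fasta)) {
    af <- read_sequences(cfg$adapter_fasta)
    adapters <- lapply(seq_len(nrow(af)), function(i) {
      adapter_spec(af$id[i], af$sequence[i], cfg$adapter_error_rate)
    })
  }

  cur_reads <- reads
  if ("curate" %in% cfg$stages) {
    log_msg(cfg, "curating ", nrow(reads), " reads")
    cc <- curation_config(cfg$end_trim, cfg$min_length, adapters,
                          cfg$chimera_flank)
    cur <- curate_set(reads, cc)
    cur_reads <- cur$kept
    write_table(cur$decisions, file.path(cfg$out_dir, "curate_decisions.tsv"),
                "tsv")
    write_table(cur$summary, file.path(cfg$out_dir, "curate_summary.tsv"),
                "tsv")
    results$curate <- cur$summary
    status["curate"] <- "done"
  }

  reference <- if (!is.null(cfg$reference)) read_sequences(cfg$reference)

  if ("qc" %in% cfg$stages) {
    log_msg(cfg, "computing read statistics")
    groups <- list(reads = cur_reads)
    refs <- if (!is.null(reference)) list(reads = reference) else list()
    qt <- qc_table(groups, refs)
    write_table(qt, file.path(cfg$out_dir, "qc_table.tsv"), "tsv")
    results$qc <- qt
    status["qc"] <- "done"
  }

  if ("ontarget" %in% cfg$stages) {
    log_msg(cfg, "computing on-target rate")
    baits <- read_sequences(cfg$baits)
    ot <- on_target_rate(cur_reads, baits,
                         bait_criteria(cfg$min_bait_length,
                                       cfg$min_bait_identity))
    write_table(ot$table, file.path(cfg$out_dir, "ontarget_reads.tsv"), "tsv")
    results$ontarget <- data.frame(on_target_pct = ot$rate_pct,
                                   n_on_target = ot$n_on_target,
                                   n_reads = ot$n_reads)
    write_table(results$ontarget,
                file.path(cfg$out_dir, "ontarget_summary.tsv"), "tsv")
    status["ontarget"] <- "done"
  }

  motifs <- if (!is.null(cfg$motif_config)) {
    read_motif_config(cfg$motif_config)
  } else {
    default_nlr_motifs()
  }
  if ("motifs" %in% cfg$stages) {
    log_msg(cfg, "scanning NLR motifs")
    ann <- annotate_set(cur_reads, motifs)
    write_table(ann$table, file.path(cfg$out_dir, "motif_calls.tsv"), "tsv")
    write_table(ann$summary, file.path(cfg$out_dir, "motif_summary.tsv"),
                "tsv")
    results$motifs <- ann$summary
    status["motifs"] <- "done"
  }

  contigs <- if (!is.null(cfg$contigs)) read_sequences(cfg$contigs)
  if ("assembly" %in% cfg$stages) {
    if (!is.null(contigs)) {
      status["assembly"] <- "external"
    } else if (cfg$assembler == "toy") {
      log_msg(cfg, "toy-assembling curated reads")
      contigs <- toy_assemble(cur_reads)
      write_sequences(contigs, file.path(cfg$out_dir, "toy_contigs.fasta"))
      status["assembly"] <- "toy"
    } else {
      stop("assembly stage enabled but no contigs supplied and assembler ",
           "is 'none' (external assembly is a shell-out boundary)")
    }
  }

  if ("eval" %in% cfg$stages && !is.null(contigs)) {
    log_msg(cfg, "evaluating assembly against reference")
    crit <- acceptance_criteria(cfg$eval_min_length, cfg$eval_min_identity)
    hits <- best_hit_search(reference, contigs, crit)
    hits <- dedupe_same_subject(hits, cfg$dedupe_overlap)$kept
    summ <- summarize_hits(hits, nrow(reference))
    write_table(hits, file.path(cfg$out_dir, "eval_hits.tsv"), "tsv")
    write_table(summ, file.path(cfg$out_dir, "eval_summary.tsv"), "tsv")
    dots <- dotplot_export(contigs, reference, cfg$dotplot_min_match)
    write_table(dots, file.path(cfg$out_dir, "eval_dotplot.tsv"), "tsv")
    results$eval <- summ
    status["eval"] <- "done"
  }

  if ("triage" %in% cfg$stages) {
    log_msg(cfg, "running novel-gene triage")
    exclude <- readLines(cfg$exclude_ids)
    exclude <- exclude[nzchar(trimws(exclude))]
    tc <- triage_config(cfg$sd_multiplier,
                        acceptance_criteria(cfg$eval_min_length,
                                            cfg$eval_min_identity),
                        assembler = if (cfg$assembler == "toy") "toy" else
                          "none",
                        require_motifs = cfg$require_motifs)
    tr <- run_triage(cur_reads, reference, exclude, tc, motifs = motifs)
    rep <- data.frame(mean_identity_pct = tr$mean_identity,
                      sd_identity_pct = tr$sd_identity,
                      threshold_pct = tr$threshold,
                      n_mapped = tr$n_mapped, n_unmapped = tr$n_unmapped,
                      n_below_threshold = tr$n_below_threshold,
                      n_candidates = tr$n_candidates,
                      n_recovered = if (!is.null(tr$recovery))
                        tr$recovery$n_recovered else NA_integer_)
    write_table(rep, file.path(cfg$out_dir, "triage_report.tsv"), "tsv")
    if (!is.null(tr$recovery)) {
      write_table(tr$recovery$per_gene,
                  file.path(cfg$out_dir, "triage_recovery.tsv"), "tsv")
    }
    results$triage <- rep
    status["triage"] <- "done"
  }

  manifest <- list(
    package = "renseqr",
    version = as.character(utils::packageVersion("renseqr")),
    seed = cfg$seed,
    stages = as.list(status),
    inputs = lapply(
      Filter(Negate(is.null),
             cfg[c("reads", "baits", "reference", "contigs", "exclude_ids",
                   "adapter_fasta")]),
      function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
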