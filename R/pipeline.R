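# End-to-end orchestration: design -> simulate -> process -> qc -> call
# -> concordance, with a manifest recording inputs, outputs and checksums.

#' Default pipeline configuration
#'
#' All stage thresholds live here with their standard values: 25 bp
#' target padding, the 80%/8x sample pass rule, the depth-8 call gate and
#' the mean-10 exon flag. A single shared seed fans out to per-stage
#' derived seeds (seed + stage index) so stages are independently
#' reproducible.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param sample_id Sample label used in output files.
#' @return Nested configuration list.
#' @export
default_config <- function(out_dir = tempfile("mipkit_run_"), seed = 1L,
                           sample_id = "sample1") {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    sample_id = sample_id,
    fixture = list(n_exons = 8L, exon_len = 500L, intron_len = 400L,
                   n_contigs = 1L),
    reference_fasta = NULL,
    targets_bed = NULL,
    design = list(pad_bp = 25L, gap_fill_len = 112L, tag_len = 8L,
                  max_oligo_len = 150L),
    variants = list(n_snv = 20L, n_indel = 0L),
    sim = list(molecules_per_probe = 30L, duplication_mean = 2,
               base_error_rate = 0, read_len = 100L),
    process = list(max_mismatch = 1L, cluster_hamming1 = FALSE),
    qc = list(min_frac = 0.80, min_depth = 8L, exon_flag_below = 10),
    caller = list(error_rate = 0.01, min_depth = 8L, min_gq = 20)
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override [default_config()] values.
#'
#' @param path YAML path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_in <- function(base, over) {
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge_in(base[[k]], over[[k]])
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  merge_in(cfg, user)
}

validate_config <- function(config) {
  bad <- character(0)
  need <- c("out_dir", "seed", "sample_id", "design", "variants", "sim",
            "process", "qc", "caller")
  bad <- c(bad, setdiff(need, names(config)))
  if (length(bad) > 0L) {
    stop("startup error: missing config keys: ", paste(bad, collapse = ", "))
  }
  for (f in c("reference_fasta", "targets_bed")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("startup error: ", f, " does not exist: ", config[[f]])
    }
  }
  # read-length feasibility against the widest possible arm + tag
  dpar <- do.call(design_params, config$design)
  longest_arm <- max(dpar$ext_arm_len_range, dpar$lig_arm_len_range)
  need_len <- longest_arm + dpar$tag_len + 1L
  if (config$sim$read_len < need_len) {
    stop("startup error: sim.read_len ", config$sim$read_len,
         " shorter than longest arm + tag_len + 1 (", need_len, ")")
  }
  if (config$sim$base_error_rate < 0 || config$sim$base_error_rate >= 0.5) {
    stop("startup error: sim.base_error_rate out of [0, 0.5)")
  }
  invisible(dpar)
}

#' Run the full smMIP pipeline
#'
#' Executes design, simulation, read processing, coverage QC, variant
#' calling and truth comparison in order, writing stage outputs and a
#' JSON manifest (with per-file MD5 checksums) to `config$out_dir`. The
#' manifest is written even when a stage fails, with the failing stage
#' and error recorded.
#'
#' @param config Configuration list (see [default_config()] /
#'   [read_config()]).
#' @return The manifest, invisibly; stage results are in
#'   `attr(manifest, "results")`.
#' @export
run_pipeline <- function(config) {
  dpar <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "mipkit",
    version = as.character(utils::packageVersion("mipkit")),
    seed = config$seed,
    sample_id = config$sample_id,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(),
    files = list()
  )
  results <- list()
  out <- function(name) file.path(config$out_dir, name)
  record <- function(stage, files = character(0)) {
    manifest$stages[[stage]] <<- list(status = "ok")
    for (f in files) manifest$files[[basename(f)]] <<- unname(tools::md5sum(f))
  }
  finish <- function(error = NULL) {
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    if (!is.null(error)) manifest$error <- error
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    attr(manifest, "results") <- results
    manifest
  }
  stage <- "inputs"
  res <- tryCatch({
    # stage 0: reference + targets
    if (!is.null(config$reference_fasta)) {
      reference <- read_fasta(config$reference_fasta)
      targets <- read_targets(config$targets_bed, reference = reference)
    } else {
      fx <- do.call(exon_fixture, c(config$fixture, list(seed = config$seed)))
      reference <- fx$reference
      targets <- fx$targets
      write_fasta(reference, out("reference.fa"))
      write_bed(targets, out("targets.bed"))
    }
    record("inputs", c(out("reference.fa"), out("targets.bed"))[
      file.exists(c(out("reference.fa"), out("targets.bed")))])
    results$reference <- reference
    results$targets <- targets

    stage <- "design"
    panel <- design_panel(reference, targets, dpar)
    write_probe_table(panel$probes, out("probes.tsv"))
    utils::write.table(panel$oligos, out("oligos.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("design", c(out("probes.tsv"), out("oligos.tsv")))
    results$panel <- panel

    stage <- "simulate"
    specs <- sample_variant_specs(
      reference, panel$probes,
      n_snv = config$variants$n_snv, n_indel = config$variants$n_indel,
      seed = config$seed + 1L
    )
    haps <- plant_variants(reference, specs)
    truth_sorted <- haps$truth[order(haps$truth$contig, haps$truth$pos1), ]
    write_vcf(truth_sorted, reference, paste0(config$sample_id, "_truth"),
              out("truth.vcf"))
    scfg <- sim_config(
      molecules_per_probe = config$sim$molecules_per_probe,
      duplication_mean = config$sim$duplication_mean,
      base_error_rate = config$sim$base_error_rate,
      read_len = config$sim$read_len,
      seed = config$seed + 2L
    )
    sim <- simulate_capture(panel$probes, haps, scfg)
    write_fastq(sim$r1, out("reads_R1.fastq"), mate = 1L)
    write_fastq(sim$r2, out("reads_R2.fastq"), mate = 2L)
    write_ledger(sim$ledger, out("ledger.tsv"))
    record("simulate", c(out("truth.vcf"), out("reads_R1.fastq"),
                         out("reads_R2.fastq"), out("ledger.tsv")))
    results$truth <- truth_sorted
    results$sim <- sim

    stage <- "process"
    proc <- process_reads(sim$r1, sim$r2, panel$probes,
                          max_mismatch = config$process$max_mismatch,
                          cluster_hamming1 = config$process$cluster_hamming1)
    write_molecule_table(proc$molecules, out("molecules.tsv"))
    record("process", out("molecules.tsv"))
    results$proc <- proc

    stage <- "qc"
    profile <- compute_depth(proc$molecules, panel$padded_targets)
    qc <- sample_pass(profile, config$qc$min_frac, config$qc$min_depth)
    exon_cov <- exon_mean_coverage(profile, targets, config$qc$exon_flag_below)
    write_qc_report(qc, exon_cov, out("qc.json"))
    record("qc", out("qc.json"))
    results$profile <- profile
    results$qc <- qc
    results$exon_cov <- exon_cov

    stage <- "call"
    cpar <- caller_params(config$caller$error_rate, config$caller$min_depth,
                          config$caller$min_gq)
    called <- call_variants(proc$molecules, reference, panel$padded_targets,
                            cpar)
    write_vcf(called$calls, reference, config$sample_id, out("calls.vcf"))
    record("call", out("calls.vcf"))
    results$called <- called

    stage <- "concordance"
    report <- compare_to_truth(called$calls, truth_sorted, profile,
                               min_depth = config$caller$min_depth,
                               genotyped = called$genotyped,
                               reference = reference)
    write_concordance_report(report, out("concordance.json"))
    record("concordance", out("concordance.json"))
    results$concordance <- report
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(res)) {
    manifest$stages[[stage]] <- list(status = "failed", error = res)
    mf <- finish(error = sprintf("stage '%s' failed: %s", stage, res))
    stop("pipeline stage '", stage, "' failed: ", res)
  }
  invisible(finish())
}
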