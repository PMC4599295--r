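# End-to-end orchestration: one config, fixed seed, derived per-stage seeds,
# TSV outputs and a manifest with content checksums.

#' Default miRNAs for synthetic studies (miR-200b arms)
#'
#' @return tibble `name`, `mature`.
#' @export
default_mirnas <- function() {
  fx <- mir200b_fixture()
  tibble(name = c("miR-200b-5p", "miR-200b-3p"),
         mature = c(fx$mature5p, fx$mature3p))
}

#' Simulate a complete two-condition seed-target study
#'
#' Builds a toy transcriptome in which a subset of genes carries one
#' implanted 8mer seed site for the chosen miRNA; intact targets are
#' repressed by `effect_log2fc` in condition B while a fraction of targets
#' lose their distal 3'UTR (and with it the repression); per-base UTR
#' coverage reflecting the loss status is simulated for every APA-bearing
#' transcript.
#'
#' @param seed master seed; stage seeds are derived at fixed offsets.
#' @param n_targets,n_background gene counts.
#' @param utr_lost_fraction fraction of target genes whose distal 3'UTR is
#'   lost (escaping repression).
#' @param effect_log2fc repression applied to intact targets (default -1).
#' @param baseline_mean,dispersion,n_reps count-model parameters.
#' @param depth,noise_sd,residual_fraction coverage-model parameters.
#' @param mirnas tibble `name`, `mature`; sites are implanted for the first.
#' @param n_sites_per_gene implanted sites per target (default 1).
#' @param utr_len 3'UTR length.
#' @return list: `genome`, `tx`, `site_truth`, `gene_truth`, `counts`,
#'   `samples`, `coverage`, `mirnas`.
#' @export
simulate_study <- function(seed, n_targets = 100L, n_background = 400L,
                           utr_lost_fraction = 0.1, effect_log2fc = -1,
                           baseline_mean = 1000, dispersion = 0.05,
                           n_reps = 3L, depth = 100, noise_sd = 5,
                           residual_fraction = 0.05,
                           mirnas = default_mirnas(),
                           n_sites_per_gene = 1L, utr_len = 400L) {
  n_genes <- n_targets + n_background
  world <- make_transcriptome(n_genes, seed = seed + 11L,
                              apa_fraction = 1, utr_len = utr_len)
  tx <- world$tx
  primary <- tx[!duplicated(tx$gene_id), ]        # UTR-bearing isoform
  withr::with_seed(seed + 12L, {
    target_genes <- sort(sample(primary$gene_id, n_targets))
    lost_genes <- sort(sample(target_genes,
                              round(utr_lost_fraction * n_targets)))
  })
  target_tx <- primary$transcript_id[primary$gene_id %in% target_genes]
  imp <- implant_seed_sites(tx, world$genome, mirnas,
                            n_sites_per_gene = n_sites_per_gene,
                            site_class = "8mer", seed = seed + 13L,
                            mirna_name = mirnas$name[1],
                            target_transcripts = target_tx)
  gene_truth <- tibble(
    gene_id = primary$gene_id,
    is_target = primary$gene_id %in% target_genes,
    utr_lost = primary$gene_id %in% lost_genes)
  sim <- simulate_mrna_counts(gene_truth, baseline_mean = baseline_mean,
                              dispersion = dispersion,
                              effect_log2fc = effect_log2fc,
                              n_reps = n_reps, seed = seed + 14L)
  cov <- list_rbind(lapply(seq_len(nrow(primary)), function(i) {
    simulate_coverage(primary[i, ],
                      utr_lost = primary$gene_id[i] %in% lost_genes,
                      depth = depth, noise_sd = noise_sd,
                      residual_fraction = residual_fraction,
                      seed = seed + 1000L + i)
  }))
  list(genome = imp$genome, tx = tx, site_truth = imp$truth,
       gene_truth = sim$truth, counts = sim$counts, samples = sim$samples,
       coverage = cov, mirnas = mirnas)
}

#' Analyze a seed-target study
#'
#' The analysis half of the pipeline: scans 3'UTRs for seed sites, filters
#' predicted targets (8mer by default), tests differential expression with
#' the simplified exact test, calls 3'UTR loss from coverage, classifies
#' per-gene outcomes and tests the target-set fold-change shift.
#'
#' @param study output of [simulate_study()] (or a list with the same
#'   elements built from real data).
#' @param alpha,min_fold outcome-classification thresholds.
#' @param tau,min_proximal 3'UTR-loss thresholds.
#' @param require_8mer site-class filter for predicted targets.
#' @param dispersion dispersion for the exact test (`NULL` = estimate).
#' @return list: `sites`, `targets`, `de`, `loss_calls`, `outcomes`,
#'   `shift`, `retention`.
#' @export
analyze_study <- function(study, alpha = 0.05, min_fold = 1.5, tau = 0.2,
                          min_proximal = 10, require_8mer = TRUE,
                          dispersion = NULL) {
  sites <- scan_transcriptome(study$tx, study$mirnas,
                              genome = study$genome)
  targets <- predicted_targets(sites, require_8mer = require_8mer)
  de <- de_exact_test(study$counts, study$samples, dispersion = dispersion,
                      alpha = alpha, min_fold = min_fold)
  segments <- segment_utr(study$tx[!duplicated(study$tx$gene_id), ])
  loss <- call_utr_loss(study$coverage, segments, tau = tau,
                        min_proximal = min_proximal)
  gene_map <- select(study$tx, "transcript_id", "gene_id")
  outcomes <- classify_target_outcome(de, loss, alpha = alpha,
                                      min_fold = min_fold,
                                      gene_map = gene_map)
  retention <- site_retention(sites, loss, segments)
  tgt_genes <- unique(targets$gene_id)
  lost_genes <- outcomes$gene_id[outcomes$utr_lost]
  intact <- setdiff(tgt_genes, lost_genes)
  bg <- setdiff(outcomes$gene_id, tgt_genes)
  det <- as_tibble(de)
  shift <- target_shift_test(
    det$log2fc[det$gene_id %in% intact],
    det$log2fc[det$gene_id %in% bg])
  list(sites = sites, targets = targets, de = de, loss_calls = loss,
       outcomes = outcomes, shift = shift, retention = retention)
}

#' Read and validate a pipeline run configuration
#'
#' YAML file (or list) of paths, thresholds and the mandatory random seed.
#'
#' @param config path to a YAML file or a named list.
#' @return validated config list with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a YAML path or a list")
  if (is.null(config$seed)) abort("config must set an explicit seed")
  defaults <- list(
    out_dir = "mirsight_run", n_targets = 100L, n_background = 400L,
    utr_lost_fraction = 0.1, effect_log2fc = -1, baseline_mean = 1000,
    dispersion = 0.05, n_reps = 3L, depth = 100, noise_sd = 5,
    n_small_rna_reads = 2000L, n_mrna_reads = 500L,
    max_unmatched = 2L, tau = 0.2, alpha = 0.05, min_fold = 1.5,
    require_8mer = TRUE, run_counter = FALSE, quiet = FALSE)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  stopifnot(config$tau > 0, config$alpha > 0, config$alpha < 1,
            config$min_fold >= 1, config$max_unmatched >= 0)
  config
}

log_msg <- function(quiet, ...) {
  if (!quiet) message("[mirsight] ", ...)
}

#' Run the full synthetic pipeline
#'
#' Stages: simulate, (optional) read counting, isomiR profiling, seed
#' scanning, 3'UTR-loss calling, target-response analysis. All outputs are
#' TSV/FASTA/GFF3 under `out_dir`; a manifest with the parameter echo and
#' md5 checksums of every output is written as YAML and returned.
#'
#' @param config YAML path or list; see [read_run_config()]. `seed` is
#'   mandatory.
#' @return manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  quiet <- isTRUE(cfg$quiet)
  seed <- as.integer(cfg$seed)

  log_msg(quiet, "stage simulate")
  study <- simulate_study(
    seed, n_targets = cfg$n_targets, n_background = cfg$n_background,
    utr_lost_fraction = cfg$utr_lost_fraction,
    effect_log2fc = cfg$effect_log2fc, baseline_mean = cfg$baseline_mean,
    dispersion = cfg$dispersion, n_reps = cfg$n_reps, depth = cfg$depth,
    noise_sd = cfg$noise_sd)
  write_fasta(setNames(study$genome, names(study$genome)),
              out("genome.fa"))
  write_gene_models(study$tx, out("models.gff3"))
  write_counts(study$counts, out("counts.tsv"))
  write_table(study$samples, out("samples.tsv"))
  write_table(study$gene_truth, out("truth_genes.tsv"))
  write_table(study$site_truth, out("truth_sites.tsv"))
  write_table(study$coverage, out("coverage.tsv"))

  locus <- synthetic_locus("hsa-mir-200b", study$mirnas$mature[1],
                           study$mirnas$mature[2], seed = seed + 21L)
  sr <- simulate_small_rna_reads(locus, isomir_distribution(),
                                 n_reads = cfg$n_small_rna_reads,
                                 seed = seed + 22L)
  write_fasta(setNames(sr$reads$seq, sr$reads$read_id),
              out("srna_reads.fa"))
  write_table(sr$truth, out("truth_srna.tsv"))

  counter_status <- "skipped"
  if (isTRUE(cfg$run_counter)) {
    log_msg(quiet, "stage count")
    mr <- simulate_mrna_reads(study$tx, study$genome,
                              n_reads = cfg$n_mrna_reads,
                              seed = seed + 23L)
    idx <- build_gene_index(study$tx, study$genome)
    mapped <- map_reads(mr$reads$seq, idx,
                        max_unmatched = cfg$max_unmatched)
    gene_counts <- count_genes(mapped, idx)
    write_table(gene_counts, out("mapped_gene_counts.tsv"))
    counter_status <- "run"
  }

  log_msg(quiet, "stage isomir")
  calls <- classify_reads(sr$reads$seq, locus)
  write_table(select(tabulate_isomirs(calls), -dplyr::any_of("subs")),
              out("isomirs.tsv"))
  write_table(heterogeneity_summary(calls), out("isomir_summary.tsv"))

  log_msg(quiet, "stages seedscan / utrloss / respond")
  res <- analyze_study(study, alpha = cfg$alpha, min_fold = cfg$min_fold,
                       tau = cfg$tau, require_8mer = cfg$require_8mer)
  write_table(res$sites, out("sites.tsv"))
  write_table(res$targets, out("targets.tsv"))
  write_table(tidy(res$de), out("de.tsv"))
  write_table(res$loss_calls, out("utrloss.tsv"))
  write_table(res$outcomes, out("outcomes.tsv"))
  write_table(tidy(res$shift), out("shift.tsv"))
  write_table(res$retention, out("site_retention.tsv"))

  files <- sort(list.files(cfg$out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.yaml"]
  manifest <- list(
    package = "mirsight",
    seed = seed,
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    stages = list(simulate = "run", count = counter_status,
                  isomir = "run", seedscan = "run", utrloss = "run",
                  respond = "run"),
    checksums = as.list(setNames(unname(tools::md5sum(files)),
                                 basename(files))))
  yaml::write_yaml(manifest, out("manifest.yaml"))
  log_msg(quiet, "done: ", cfg$out_dir)
  invisible(manifest)
}
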