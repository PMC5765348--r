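#' @title End-to-end substrate-discovery pipeline
#' @description Orchestrates simulate (or load) -> CPM filter -> the three
#'   differential comparisons at gene and intron level -> Class I-IV
#'   classification -> high-confidence merge -> summary and enrichment,
#'   writing all intermediates and a reproducibility manifest.
#' @name pipeline
NULL

#' Subset a count matrix to selected samples
#'
#' Features and library sizes are retained for the selected columns.
#'
#' @param cm a `count_matrix`; `sample_ids` columns to keep.
#' @return a `count_matrix`.
#' @export
subset_samples <- function(cm, sample_ids) {
  stopifnot(inherits(cm, "count_matrix"),
            all(sample_ids %in% colnames(cm$counts)))
  count_matrix(cm$counts[, sample_ids, drop = FALSE],
               library_sizes = cm$library_sizes[sample_ids])
}

#' Pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param sim a [sim_params()] object to simulate inputs, or NULL to load
#'   counts from files.
#' @param gene_counts,intron_counts,design,intron_map file paths (TSV/BED)
#'   used when `sim` is NULL; `intron_counts`/`intron_map` may be NULL to
#'   skip the intron stage.
#' @param fc_up fold-change threshold for up/down regulation (strict >).
#' @param fc_ip fold-change threshold for IP enrichment (inclusive >=).
#' @param fdr FDR threshold for all three comparisons.
#' @param min_cpm,min_samples expression filter (see [cpm_filter()]).
#' @param mode `"pooled"` tests both NMD-deficient genotypes as one group
#'   against wild type; `"per_genotype"` intersects the separate
#'   smg1-vs-N2 and smg1smg2-vs-N2 threshold sets.
#' @param intron_level run the intron-level stage.
#' @param enrich run biotype over-representation on the Class I set.
#' @param seed seed recorded in the manifest; with `sim` it overrides the
#'   simulation seed.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       sim = sim_params(),
                       gene_counts = NULL, intron_counts = NULL,
                       design = NULL, intron_map = NULL,
                       fc_up = 1.5, fc_ip = 2, fdr = 0.05,
                       min_cpm = 3, min_samples = 3,
                       mode = c("pooled", "per_genotype"),
                       intron_level = TRUE, enrich = TRUE,
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(fc_up >= 1, fc_ip >= 1, fdr > 0, min_cpm >= 0, min_samples >= 1)
  if (is.null(sim) && (is.null(gene_counts) || is.null(design)))
    stop("without simulation, gene_counts and design files are required")
  if (!is.null(sim) && !is.null(seed)) sim$seed <- seed
  if (is.null(seed)) seed <- if (!is.null(sim)) sim$seed else NA
  structure(list(out_dir = out_dir, sim = sim, gene_counts = gene_counts,
                 intron_counts = intron_counts, design = design,
                 intron_map = intron_map, fc_up = fc_up, fc_ip = fc_ip,
                 fdr = fdr, min_cpm = min_cpm, min_samples = min_samples,
                 mode = mode, intron_level = intron_level, enrich = enrich,
                 seed = seed),
            class = "run_config")
}

.samples_of <- function(design, genotype, fraction) {
  ids <- design$sample_id[design$genotype %in% genotype &
                            design$fraction == fraction]
  if (length(ids) == 0)
    stop("missing required samples for (", paste(genotype, collapse = "+"),
         ", ", fraction, ")")
  ids
}

.run_de <- function(cm, baseline_ids, treatment_ids) {
  sub <- subset_samples(cm, c(baseline_ids, treatment_ids))
  groups <- factor(rep(c("baseline", "treatment"),
                       c(length(baseline_ids), length(treatment_ids))),
                   levels = c("baseline", "treatment"))
  nb_exact_test(sub, groups)
}

## the three comparisons for one feature catalog; returns the list of
## de_result tables plus the thresholded comparison sets
.compare_level <- function(cm, design, cfg) {
  de <- list()
  if (cfg$mode == "pooled") {
    de$up <- .run_de(cm, .samples_of(design, "N2", "input"),
                     .samples_of(design, c("smg1", "smg1smg2"), "input"))
    up <- threshold_set(de$up, cfg$fc_up, cfg$fdr, "up")
    down <- threshold_set(de$up, cfg$fc_up, cfg$fdr, "down")
  } else {
    de$up_smg1 <- .run_de(cm, .samples_of(design, "N2", "input"),
                          .samples_of(design, "smg1", "input"))
    de$up_smg1smg2 <- .run_de(cm, .samples_of(design, "N2", "input"),
                              .samples_of(design, "smg1smg2", "input"))
    up <- intersect(threshold_set(de$up_smg1, cfg$fc_up, cfg$fdr, "up"),
                    threshold_set(de$up_smg1smg2, cfg$fc_up, cfg$fdr, "up"))
    down <- intersect(threshold_set(de$up_smg1, cfg$fc_up, cfg$fdr, "down"),
                      threshold_set(de$up_smg1smg2, cfg$fc_up, cfg$fdr, "down"))
  }
  de$ipA <- .run_de(cm, .samples_of(design, "smg1", "input"),
                    .samples_of(design, "smg1", "IP"))
  de$ipB <- .run_de(cm, .samples_of(design, "smg1smg2", "IP"),
                    .samples_of(design, "smg1", "IP"))
  sets <- comparison_sets(
    up = up, down = down,
    ipA = threshold_set(de$ipA, cfg$fc_ip, cfg$fdr, "up", inclusive = TRUE),
    ipB = threshold_set(de$ipB, cfg$fc_ip, cfg$fdr, "up", inclusive = TRUE),
    universe = rownames(cm$counts))
  list(de = de, sets = sets)
}

#' Run the full substrate-discovery pipeline
#'
#' Executes the three comparisons — (1) NMD-deficient inputs vs wild-type
#' inputs, (2) smg-1 IP vs smg-1 input, (3) smg-1 IP vs smg-1 smg-2 mock
#' IP — over gene features and (optionally) intron features, classifies,
#' merges the high-confidence substrate list, summarizes, and writes
#' results under `config$out_dir`: `de_<level>_<contrast>.tsv`,
#' `classes_gene.tsv`, `classes_intron.tsv`, `substrates.tsv`,
#' `summary.json`/`summary.tsv`, `enrichment.tsv` and `manifest.json`
#' (plus, in simulation mode, the toy annotation, counts, design and truth).
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage INFO messages.
#' @return invisibly, a list with the classification objects, substrate
#'   list, summary, de tables, and (simulation mode) truth and recovery.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  info <- function(...) if (!quiet) message("[ripclass] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL; biotypes <- NULL
  if (!is.null(config$sim)) {
    info("simulating genome and counts (n_genes=", config$sim$n_genes,
         ", seed=", config$sim$seed, ")")
    genome <- simulate_genome(config$sim)
    sim <- simulate_counts(genome, params = config$sim)
    truth <- genome$truth
    biotypes <- setNames(genome$models$genes$biotype, genome$models$genes$gene_id)
    gene_cm <- sim$genes; intron_cm <- sim$introns; design <- sim$design
    introns <- build_intron_catalog(genome$models)
    export_features(genome$models, file.path(config$out_dir, "genome.gtf"), "gtf")
    export_features(introns, file.path(config$out_dir, "introns.bed"), "bed")
    write_counts(gene_cm, file.path(config$out_dir, "counts_gene.tsv"))
    write_counts(intron_cm, file.path(config$out_dir, "counts_intron.tsv"))
    write.table(design, file.path(config$out_dir, "design.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(config$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    intron_map <- introns
  } else {
    gene_cm <- read_counts(config$gene_counts)
    design <- read_design(config$design)
    intron_cm <- if (!is.null(config$intron_counts))
      read_counts(config$intron_counts) else NULL
    intron_map <- if (!is.null(config$intron_map))
      read_intron_bed(config$intron_map) else NULL
    if (!is.null(intron_cm))
      intron_cm <- count_matrix(intron_cm$counts,
                                library_sizes = gene_cm$library_sizes[colnames(intron_cm$counts)])
  }
  gene_f <- cpm_filter(gene_cm, config$min_cpm, config$min_samples)
  info(nrow(gene_f$counts), " of ", nrow(gene_cm$counts),
       " gene features pass the ", config$min_cpm, " CPM filter")
  gl <- .compare_level(gene_f, design, config)
  for (nm in names(gl$de))
    write_de(gl$de[[nm]], file.path(config$out_dir,
                                    paste0("de_gene_", nm, ".tsv")))
  info("gene sets: up=", length(gl$sets$up), " down=", length(gl$sets$down),
       " ipA=", length(gl$sets$ipA), " ipB=", length(gl$sets$ipB))
  thresholds <- list(fc_up = config$fc_up, fc_ip = config$fc_ip,
                     fdr = config$fdr)
  gene_assign <- classify_features(gl$sets, thresholds)
  write.table(gene_assign, file.path(config$out_dir, "classes_gene.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  info("gene classes: ",
       paste(sprintf("%s=%d", levels(gene_assign$class),
                     as.integer(table(gene_assign$class))), collapse = " "))
  intron_assign <- NULL; intron_genes <- character(0)
  do_introns <- config$intron_level && !is.null(intron_cm) &&
    !is.null(intron_map)
  if (do_introns) {
    intron_f <- cpm_filter(intron_cm, config$min_cpm, config$min_samples)
    info(nrow(intron_f$counts), " of ", nrow(intron_cm$counts),
         " intron features pass the ", config$min_cpm, " CPM filter")
    il <- .compare_level(intron_f, design, config)
    for (nm in names(il$de))
      write_de(il$de[[nm]], file.path(config$out_dir,
                                      paste0("de_intron_", nm, ".tsv")))
    intron_assign <- classify_features(il$sets, thresholds)
    write.table(intron_assign, file.path(config$out_dir, "classes_intron.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    intron_genes <- classify_intron_genes(intron_assign, intron_map)
    info(sum(intron_assign$class == "I"), " Class I introns over ",
         length(intron_genes), " genes")
  }
  substrates <- merge_high_confidence(gene_assign, intron_genes)
  write.table(substrates, file.path(config$out_dir, "substrates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- summarize_classification(gene_assign, substrates, biotypes)
  write_summary(summary, file.path(config$out_dir, "summary.json"),
                file.path(config$out_dir, "summary.tsv"))
  info("high-confidence substrates: ", nrow(substrates))
  enrichment <- NULL
  if (config$enrich && !is.null(biotypes)) {
    terms <- data.frame(gene_id = names(biotypes), term = unname(biotypes),
                        stringsAsFactors = FALSE)
    study <- gene_assign$feature_id[gene_assign$class == "I"]
    if (length(study)) {
      enrichment <- test_enrichment(study, rownames(gene_f$counts),
                                    terms[terms$gene_id %in% rownames(gene_f$counts), ])
      write.table(enrichment, file.path(config$out_dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- evaluate_recovery(substrates, truth, gene_assign)
    info(sprintf("recovery vs truth: precision=%.3f recall=%.3f",
                 recovery$precision, recovery$recall))
  }
  manifest <- list(package = "ripclass",
                   version = as.character(packageVersion("ripclass")),
                   seed = config$seed,
                   mode = config$mode,
                   thresholds = thresholds,
                   min_cpm = config$min_cpm, min_samples = config$min_samples,
                   intron_level = config$intron_level,
                   set_sizes = as.list(attr(gene_assign, "set_sizes")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(gene_assignment = gene_assign,
                 intron_assignment = intron_assign,
                 intron_genes = intron_genes,
                 substrates = substrates, summary = summary,
                 de = gl$de, truth = truth, recovery = recovery,
                 enrichment = enrichment))
}
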