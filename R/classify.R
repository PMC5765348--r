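#' @title Three-comparison Class I-IV substrate classification
#' @description The taxonomy combines three comparisons: up/down regulation
#'   in NMD-deficient mutants vs wild-type inputs, enrichment in the SMG-2
#'   IP vs its input, and enrichment in the SMG-2 IP vs the mock-IP control.
#'   Let S = ipA intersect ipB (reliably SMG-2-associated). Then
#'   Class I = up & S (direct substrates), Class II = S minus up minus down
#'   (associated, expression unaltered), Class III = up and in neither IP
#'   set, Class IV = down and in neither IP set; everything else is
#'   unclassified. In particular a feature that is up and in exactly one IP
#'   set is unclassified, which is why the up set is larger than
#'   Class I + Class III.
#' @name classify
NULL

#' Threshold a differential-abundance table into a feature set
#'
#' The up/down regulation boundary is strict (fold-change > fc_min, per the
#' "fold-change > 1.5" rule); IP enrichment uses the inclusive "at least
#' twofold" rule (set `inclusive = TRUE`). FDR is strict (< fdr_max) in
#' both cases.
#'
#' @param de a `de_result`.
#' @param fc_min fold-change threshold (>= 1).
#' @param fdr_max FDR threshold.
#' @param direction `"up"` (2^logFC above fc_min) or `"down"` (2^logFC
#'   below 1/fc_min).
#' @param inclusive use >= / <= instead of > / < on the fold-change.
#' @return character vector of feature ids.
#' @export
threshold_set <- function(de, fc_min = 1.5, fdr_max = 0.05,
                          direction = c("up", "down"), inclusive = FALSE) {
  direction <- match.arg(direction)
  if (fc_min < 1) stop("fc_min must be >= 1")
  fc <- 2^de$logFC
  hit <- if (direction == "up") {
    if (inclusive) fc >= fc_min else fc > fc_min
  } else {
    if (inclusive) fc <= 1 / fc_min else fc < 1 / fc_min
  }
  de$feature_id[hit & de$fdr < fdr_max]
}

#' Bundle the four comparison sets
#'
#' @param up,down features increased/decreased in NMD-deficient mutants.
#' @param ipA features enriched in the smg-1 IP vs smg-1 input.
#' @param ipB features enriched in the smg-1 IP vs the smg-1 smg-2 mock IP.
#' @param universe all tested feature ids; the sets must be subsets.
#' @return A `comparison_sets` list.
#' @export
comparison_sets <- function(up, down, ipA, ipB, universe) {
  sets <- list(up = unique(up), down = unique(down),
               ipA = unique(ipA), ipB = unique(ipB))
  if (length(intersect(sets$up, sets$down)))
    stop("up and down sets must be disjoint")
  for (nm in names(sets))
    if (!all(sets[[nm]] %in% universe))
      stop("set '", nm, "' contains features outside the universe")
  structure(c(sets, list(universe = unique(universe))), class = "comparison_sets")
}

#' Classify features into Classes I-IV
#'
#' @param sets a [comparison_sets()] object.
#' @param thresholds list echoed into the result (fc_up, fc_ip, fdr).
#' @return A `class_assignment` data.frame (feature_id, class) where class
#'   is a factor with levels I, II, III, IV, unclassified; the thresholds
#'   are stored as an attribute.
#' @export
classify_features <- function(sets,
                              thresholds = list(fc_up = 1.5, fc_ip = 2, fdr = 0.05)) {
  stopifnot(inherits(sets, "comparison_sets"))
  S <- intersect(sets$ipA, sets$ipB)
  I <- intersect(sets$up, S)
  II <- setdiff(setdiff(S, sets$up), sets$down)
  either_ip <- union(sets$ipA, sets$ipB)
  III <- setdiff(sets$up, either_ip)
  IV <- setdiff(sets$down, either_ip)
  cls <- setNames(rep("unclassified", length(sets$universe)), sets$universe)
  cls[II] <- "II"; cls[I] <- "I"; cls[III] <- "III"; cls[IV] <- "IV"
  out <- data.frame(feature_id = sets$universe,
                    class = factor(unname(cls),
                                   levels = c("I", "II", "III", "IV", "unclassified")),
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  attr(out, "set_sizes") <- vapply(sets[c("up", "down", "ipA", "ipB")],
                                   length, integer(1))
  attr(out, "up_set") <- sets$up
  class(out) <- c("class_assignment", "data.frame")
  out
}

#' Genes with at least one Class I intron
#'
#' @param intron_assignment a `class_assignment` over intron features.
#' @param intron_to_gene data.frame mapping `intron_id` to `gene_id` (the
#'   intron catalog itself works). Every classified intron must be mapped.
#' @return character vector of gene ids, each once.
#' @export
classify_intron_genes <- function(intron_assignment, intron_to_gene) {
  stopifnot(inherits(intron_assignment, "class_assignment"))
  map <- setNames(as.character(intron_to_gene$gene_id),
                  as.character(intron_to_gene$intron_id))
  hit <- intron_assignment$feature_id[intron_assignment$class == "I"]
  if (any(!(hit %in% names(map))))
    stop("intron without gene mapping: ", setdiff(hit, names(map))[1])
  unique(unname(map[hit]))
}

#' Merge gene- and intron-level calls into the high-confidence list
#'
#' The substrate list is the union of gene-level Class I genes and genes
#' holding at least one Class I intron. Genes already Class I are not
#' double-counted; intron-identified genes are added regardless of their
#' gene-level label (typically Class II, the fraction-of-isoforms case).
#'
#' @param gene_assignment gene-level `class_assignment`.
#' @param intron_genes output of [classify_intron_genes()].
#' @return A `substrate_list` data.frame (gene_id, provenance in
#'   gene_level / intron_level / both).
#' @export
merge_high_confidence <- function(gene_assignment, intron_genes = character(0)) {
  stopifnot(inherits(gene_assignment, "class_assignment"))
  g1 <- gene_assignment$feature_id[gene_assignment$class == "I"]
  all_ids <- union(g1, intron_genes)
  prov <- ifelse(all_ids %in% g1 & all_ids %in% intron_genes, "both",
                 ifelse(all_ids %in% g1, "gene_level", "intron_level"))
  out <- data.frame(gene_id = all_ids, provenance = prov,
                    stringsAsFactors = FALSE)
  class(out) <- c("substrate_list", "data.frame")
  out
}

#' Summarize a classification
#'
#' Emits class sizes, the share of up-regulated features that are direct
#' substrates (|Class I| / |up| as a rounded percentage), the biotype
#' composition of Class I (notably the expressed-pseudogene fraction), the
#' substrate-list size, and the thresholds used.
#'
#' @param assignment a `class_assignment`.
#' @param substrates optional `substrate_list`.
#' @param biotypes optional named character vector gene_id -> biotype.
#' @param up optional explicit up-regulated feature set; defaults to the
#'   set recorded on the assignment (or Class I + Class III).
#' @return A `classification_summary` list.
#' @export
summarize_classification <- function(assignment, substrates = NULL,
                                     biotypes = NULL, up = NULL) {
  stopifnot(inherits(assignment, "class_assignment"))
  sizes <- table(assignment$class)
  if (is.null(up)) up <- attr(assignment, "up_set")
  if (is.null(up))
    up <- assignment$feature_id[assignment$class %in% c("I", "III")]
  n_up <- length(up)
  I <- assignment$feature_id[assignment$class == "I"]
  pct_class1_of_up <- if (n_up > 0) round(100 * length(I) / n_up) else 0
  biotype_tab <- NULL
  pct_pseudogene_of_class1 <- 0
  if (!is.null(biotypes) && length(I)) {
    biotype_tab <- table(.norm_biotype(biotypes[I]))
    n_ps <- sum(biotypes[I] == "pseudogene", na.rm = TRUE)
    pct_pseudogene_of_class1 <- round(100 * n_ps / length(I))
  }
  structure(list(
    class_sizes = as.list(sizes),
    n_up = n_up,
    pct_class1_of_up = pct_class1_of_up,
    class1_biotypes = if (is.null(biotype_tab)) NULL else as.list(biotype_tab),
    pct_pseudogene_of_class1 = pct_pseudogene_of_class1,
    n_substrates = if (is.null(substrates)) length(I) else nrow(substrates),
    substrate_provenance = if (is.null(substrates)) NULL else
      as.list(table(substrates$provenance)),
    thresholds = attr(assignment, "thresholds")
  ), class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat("Class sizes:",
      paste(sprintf("%s=%d", names(x$class_sizes), unlist(x$class_sizes)),
            collapse = ", "), "\n")
  cat("Up-regulated features:", x$n_up,
      sprintf("(Class I = %d%% of up)", x$pct_class1_of_up), "\n")
  if (!is.null(x$class1_biotypes))
    cat("Class I pseudogene share:", paste0(x$pct_pseudogene_of_class1, "%"), "\n")
  cat("High-confidence substrates:", x$n_substrates, "\n")
  invisible(x)
}

#' Write a classification summary as JSON and TSV
#' @param x a `classification_summary`.
#' @param json_path,tsv_path output paths (NULL skips).
#' @export
write_summary <- function(x, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(x, "classification_summary"))
  if (!is.null(json_path))
    jsonlite::write_json(unclass(x), json_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
  if (!is.null(tsv_path)) {
    flat <- c(unlist(x$class_sizes),
              n_up = x$n_up, pct_class1_of_up = x$pct_class1_of_up,
              pct_pseudogene_of_class1 = x$pct_pseudogene_of_class1,
              n_substrates = x$n_substrates)
    write.table(data.frame(metric = names(flat), value = unname(flat)),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}
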