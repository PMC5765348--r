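#' @title Synthetic genomes, counts and reads with known substrate labels
#' @description Generates toy data with the statistical structure of the
#'   six-condition design: three genotypes (N2 wild type, smg-1(-), and the
#'   smg-1(-) smg-2(-) double mutant), each with paired input and IP
#'   fractions in three biological replicates. Substrate genes come in two
#'   archetypes: expressed pseudogenes, whose whole transcript is a
#'   substrate (PTC share phi = 1), and PTC-isoform genes, where a fraction
#'   phi of transcripts retains a designated intron fragment. In
#'   NMD-deficient genotypes the PTC-bearing transcripts are stabilized
#'   f_up-fold; in the smg-1 IP they are preferentially recovered
#'   e-fold over a nonspecific input-proportional carryover of weight b;
#'   the mock IP from the double mutant (and the wild-type IP) contains
#'   carryover only. All generators are deterministic under the seed in
#'   the parameter set.
#' @name synthetic_data
NULL

#' Simulation parameters
#'
#' @param n_genes number of genes (>= 10).
#' @param substrate_fraction fraction of genes that are NMD substrates.
#' @param pseudogene_fraction fraction of genes that are expressed
#'   pseudogenes (a subset of the substrates, with phi = 1); must not
#'   exceed `substrate_fraction`.
#' @param phi_range range of the PTC-isoform share phi for non-pseudogene
#'   substrates (drawn uniformly).
#' @param f_up fold stabilization of PTC transcripts in NMD-deficient
#'   genotypes (>= 1).
#' @param ip_enrichment e, fold preference for substrate transcripts in the
#'   smg-1 IP (>= 1).
#' @param ip_background b in (0, 1), weight of the nonspecific
#'   input-proportional carryover in the IP composition.
#' @param dispersion negative-binomial dispersion of the counts
#'   (variance = mu + phi_NB * mu^2).
#' @param mean_log_expression,sd_log_expression log-normal baseline
#'   expression: lambda ~ lognormal(meanlog, sdlog). Defaults give a typical
#'   deep-coverage spread (median a few hundred counts per gene at the
#'   default library sizes).
#' @param library_size_range per-sample sequencing depth range (uniform).
#' @param control_ip_yield library-size multiplier for mock/control IPs,
#'   modeling their lower RNA yield.
#' @param intron_background pre-mRNA background: intron features of any
#'   expressed gene receive this fraction of the gene's baseline expression
#'   as genotype-independent coverage.
#' @param n_replicates biological replicates per (genotype, fraction)
#'   condition (>= 2; default 3).
#' @param read_length read length for the read-level generator.
#' @param seed RNG seed; all three generators are deterministic given it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_genes = 2000,
                       substrate_fraction = 0.10,
                       pseudogene_fraction = 0.05,
                       phi_range = c(0.1, 1),
                       f_up = 4,
                       ip_enrichment = 8,
                       ip_background = 0.2,
                       dispersion = 0.1,
                       mean_log_expression = log(100),
                       sd_log_expression = 1,
                       library_size_range = c(0.8e6, 1.2e6),
                       control_ip_yield = 0.25,
                       intron_background = 0.02,
                       n_replicates = 3,
                       read_length = 50,
                       seed = 42) {
  p <- as.list(environment())
  if (p$n_genes < 10) stop("n_genes must be >= 10")
  stopifnot(p$substrate_fraction > 0, p$substrate_fraction <= 1,
            p$pseudogene_fraction >= 0,
            p$pseudogene_fraction <= p$substrate_fraction,
            all(p$phi_range > 0), all(p$phi_range <= 1),
            p$f_up >= 1, p$ip_enrichment >= 1,
            p$ip_background > 0, p$ip_background < 1,
            p$dispersion >= 0, p$n_replicates >= 2)
  class(p) <- "sim_params"
  p
}

#' Simulate a toy genome with ground-truth substrate labels
#'
#' Genes carry 1-10 exons (PTC-isoform substrates at least 2) laid out
#' without overlap on five toy chromosomes.
#'
#' @param params a [sim_params()] object.
#' @return A `sim_genome`: list(models = `gene_models`,
#'   truth = `sim_truth` data.frame with per-gene labels, phi, the retained
#'   intron, and the expected input-contrast fold-change
#'   1 + phi * (f_up - 1)).
#' @export
simulate_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, {
    n <- params$n_genes
    ids <- sprintf("g%04d", seq_len(n))
    is_sub <- runif(n) < params$substrate_fraction
    p_ps <- if (params$substrate_fraction > 0)
      params$pseudogene_fraction / params$substrate_fraction else 0
    is_ps <- is_sub & (runif(n) < p_ps)
    has_ptc <- is_sub & !is_ps
    n_ex <- sample(1:10, n, replace = TRUE)
    n_ex[has_ptc] <- pmax(2L, n_ex[has_ptc])
    phi <- rep(0, n)
    phi[is_ps] <- 1
    phi[has_ptc] <- runif(sum(has_ptc), params$phi_range[1], params$phi_range[2])
    strand <- sample(c("+", "-"), n, replace = TRUE)
    chrom <- paste0("chrS", (seq_len(n) - 1L) %% 5L + 1L)
    cursor <- setNames(rep(1L, 5), paste0("chrS", 1:5))
    exon_rows <- vector("list", n)
    ret_idx <- rep(NA_integer_, n)
    ret_len <- rep(NA_integer_, n)
    exonic_len <- integer(n)
    for (i in seq_len(n)) {
      k <- n_ex[i]
      elen <- sample(100:300, k, replace = TRUE)
      ilen <- if (k > 1) sample(60:500, k - 1, replace = TRUE) else integer(0)
      start <- cursor[chrom[i]] + sample(200:1000, 1)
      starts <- start + cumsum(c(0L, head(elen, -1) + ilen))
      ends <- starts + elen - 1L
      exon_rows[[i]] <- data.frame(gene_id = ids[i], chrom = chrom[i],
                                   start = starts, end = ends,
                                   strand = strand[i], stringsAsFactors = FALSE)
      cursor[chrom[i]] <- ends[k]
      exonic_len[i] <- sum(elen)
      if (has_ptc[i]) {
        ret_idx[i] <- sample.int(k - 1, 1)
        ret_len[i] <- ilen[ret_idx[i]]
      }
    }
    exons <- do.call(rbind, exon_rows)
    biotype <- setNames(ifelse(is_ps, "pseudogene", "protein_coding"), ids)
    models <- gene_models(exons, biotype = biotype)
    truth <- data.frame(
      gene_id = ids,
      is_substrate = is_sub,
      is_pseudogene = is_ps,
      has_ptc_intron = has_ptc,
      phi = phi,
      retained_intron_index = ret_idx,
      retained_intron_id = ifelse(has_ptc, sprintf("%s:I%d", ids, ret_idx), NA),
      exonic_length = exonic_len,
      retained_length = ret_len,
      ## share of a PTC transcript's reads that fall in the retained intron
      r_share = ifelse(has_ptc, ret_len / (exonic_len + ret_len), 0),
      exp_fc_input = 1 + phi * (params$f_up - 1),
      stringsAsFactors = FALSE
    )
    class(truth) <- c("sim_truth", "data.frame")
    structure(list(models = models, truth = truth), class = "sim_genome")
  })
}

## per-genotype expected abundance structure (arbitrary units):
## gene_abund = lambda * (1 + phi (f_up - 1)) in NMD(-) inputs, lambda in N2;
## ptc_abund = phi lambda f_up (NMD(-)) or phi lambda (N2).
.abundances <- function(lambda, truth, params, nmd_deficient) {
  f <- if (nmd_deficient) params$f_up else 1
  ptc <- truth$phi * lambda * f
  gene <- lambda * (1 + truth$phi * (f - 1))
  list(gene = gene, ptc = ptc)
}

## expected composition (sums to 1) of a sample; IP samples mix the
## e-fold-preferred substrate transcripts with input-proportional carryover.
.composition <- function(ab, truth, params, specific) {
  T_in <- sum(ab$gene)
  if (!specific) {
    gene_int <- ab$gene / T_in
    ptc_int <- ab$ptc / T_in
  } else {
    b <- params$ip_background; e <- params$ip_enrichment
    gene_int <- ((1 - b) * e * ab$ptc + b * ab$gene) / T_in
    ptc_int <- ((1 - b) * e * ab$ptc + b * ab$ptc) / T_in
  }
  Z <- sum(gene_int)
  list(gene = gene_int / Z, ptc = ptc_int / Z, Z = Z, T_in = T_in)
}

#' Simulate count matrices for the full six-condition design
#'
#' Expected gene counts follow the composition structure described under
#' [synthetic_data]; intron features receive genotype-independent pre-mRNA
#' background plus, for retained introns of PTC-isoform substrates, the
#' phi-weighted retained-fragment share of the PTC transcripts. Counts are
#' drawn NB(mean, dispersion) at sampled library sizes; mock/control and
#' wild-type IP libraries are scaled by `control_ip_yield`. The intron
#' matrix reuses the gene-level library sizes (column sums of the gene
#' matrix), matching how intron-level CPM and normalization are computed
#' downstream.
#'
#' @param genome a [simulate_genome()] result.
#' @param truth its `sim_truth` (defaults to `genome$truth`).
#' @param params the same [sim_params()].
#' @return A `sim_counts` list: `genes` and `introns` (`count_matrix`),
#'   `design` (`sample_design`), `lambda`, and `expected` (per-sample
#'   expected gene means and PTC read shares, plus intron means).
#' @export
simulate_counts <- function(genome, truth = genome$truth, params = sim_params()) {
  stopifnot(inherits(genome, "sim_genome"), inherits(params, "sim_params"))
  withr::with_seed(params$seed + 1L, {
    n <- nrow(truth)
    lambda <- rlnorm(n, params$mean_log_expression, params$sd_log_expression)
    introns <- build_intron_catalog(genome$models)
    genotypes <- c("N2", "smg1", "smg1smg2")
    design <- expand.grid(replicate = seq_len(params$n_replicates),
                          fraction = c("input", "IP"),
                          genotype = genotypes,
                          stringsAsFactors = FALSE)
    design$sample_id <- sprintf("%s_%s_r%d", design$genotype, design$fraction,
                                design$replicate)
    design <- sample_design(design$sample_id, design$genotype,
                            design$fraction, design$replicate)
    ## per-(genotype, fraction) composition
    comp <- list()
    for (g in genotypes) {
      ab <- .abundances(lambda, truth, params, nmd_deficient = g != "N2")
      comp[[paste0(g, "_input")]] <- .composition(ab, truth, params, specific = FALSE)
      comp[[paste0(g, "_IP")]] <- .composition(ab, truth, params,
                                               specific = (g == "smg1"))
    }
    ## intron intensities (same normalizer as the sample's gene composition)
    leak <- params$intron_background * lambda
    intron_leak <- leak[match(introns$gene_id, truth$gene_id)]
    ret_pos <- match(truth$retained_intron_id, introns$intron_id)
    intron_int <- function(cond) {
      cmp <- comp[[cond]]
      v <- intron_leak * if (cond == "smg1_IP") params$ip_background else 1
      v <- v / (cmp$T_in * cmp$Z)
      has <- which(truth$has_ptc_intron)
      v[ret_pos[has]] <- v[ret_pos[has]] + cmp$ptc[has] * truth$r_share[has]
      v
    }
    gene_mean <- matrix(0, n, nrow(design),
                        dimnames = list(truth$gene_id, design$sample_id))
    intron_mean <- matrix(0, nrow(introns), nrow(design),
                          dimnames = list(introns$intron_id, design$sample_id))
    ptc_share <- gene_mean
    lib <- runif(nrow(design), params$library_size_range[1],
                 params$library_size_range[2])
    is_carry_ip <- design$fraction == "IP" & design$genotype != "smg1"
    lib[is_carry_ip] <- lib[is_carry_ip] * params$control_ip_yield
    for (s in seq_len(nrow(design))) {
      cond <- paste0(design$genotype[s], "_", design$fraction[s])
      cmp <- comp[[cond]]
      gene_mean[, s] <- lib[s] * cmp$gene
      ptc_share[, s] <- ifelse(cmp$gene > 0, cmp$ptc / cmp$gene, 0)
      intron_mean[, s] <- lib[s] * intron_int(cond)
    }
    size <- if (params$dispersion > 0) 1 / params$dispersion else Inf
    draw <- function(mu) {
      m <- matrix(rnbinom(length(mu), size = size, mu = mu), nrow(mu), ncol(mu),
                  dimnames = dimnames(mu))
      m
    }
    gcounts <- draw(gene_mean)
    icounts <- draw(intron_mean)
    gcm <- count_matrix(gcounts)
    icm <- count_matrix(icounts, library_sizes = gcm$library_sizes)
    structure(list(genes = gcm, introns = icm, design = design,
                   lambda = lambda,
                   expected = list(gene_mean = gene_mean,
                                   ptc_share = ptc_share,
                                   intron_mean = intron_mean,
                                   library_sizes = setNames(lib, design$sample_id))),
              class = "sim_counts")
  })
}

## place n reads uniformly along a transcript defined by genomic segments
## (sorted data.frame chrom/start/end); returns read blocks.
.place_reads <- function(segments, n_reads, read_len, prefix) {
  if (n_reads == 0)
    return(data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0)))
  seg_len <- segments$end - segments$start + 1L
  L <- sum(seg_len)
  rl <- min(read_len, L)
  offs <- cumsum(c(0L, head(seg_len, -1)))
  tstart <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
  rows <- vector("list", n_reads)
  for (j in seq_len(n_reads)) {
    t0 <- tstart[j]; t1 <- t0 + rl - 1L
    hit <- which(offs < t1 & offs + seg_len >= t0)
    bs <- pmax(segments$start[hit], segments$start[hit] + (t0 - 1L - offs[hit]))
    be <- pmin(segments$end[hit], segments$start[hit] + (t1 - 1L - offs[hit]))
    rows[[j]] <- data.frame(read_id = sprintf("%s_%d", prefix, j),
                            chrom = segments$chrom[hit],
                            start = as.integer(bs), end = as.integer(be),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate spliced reads realizing the expected counts
#'
#' For each sample and gene, a Poisson number of reads around the expected
#' count is placed uniformly along the mature transcript; the PTC-isoform
#' share is placed on the transcript form that retains the designated
#' intron, so a fraction of those reads overlaps the intron interval.
#' Intron pre-mRNA background is emitted as single-block reads inside
#' introns. Reads spanning splice junctions carry multiple blocks.
#'
#' @param genome a [simulate_genome()] result.
#' @param sim a [simulate_counts()] result (supplies the expectations).
#' @param params the same [sim_params()].
#' @param samples sample ids to generate (default: all in the design).
#' @return named list of `read_blocks`, one per sample, with attribute
#'   `expected_gene_counts` (the expectation of union-mode gene counts,
#'   accounting for reads that fall entirely within a retained intron).
#' @export
simulate_reads <- function(genome, sim, params = sim_params(),
                           samples = NULL) {
  stopifnot(inherits(genome, "sim_genome"), inherits(sim, "sim_counts"))
  if (is.null(samples)) samples <- sim$design$sample_id
  truth <- genome$truth
  me <- genome$models$merged_exons
  introns <- build_intron_catalog(genome$models)
  withr::with_seed(params$seed + 2L, {
    out <- list()
    exp_gene <- matrix(0, nrow(truth), length(samples),
                       dimnames = list(truth$gene_id, samples))
    for (s in samples) {
      mu <- sim$expected$gene_mean[, s]
      share <- sim$expected$ptc_share[, s]
      rows <- vector("list", nrow(truth))
      for (i in seq_len(nrow(truth))) {
        if (mu[i] <= 0) next
        n_tot <- rpois(1, mu[i])
        if (n_tot == 0) next
        n_ptc <- if (truth$has_ptc_intron[i]) rbinom(1, n_tot, share[i]) else 0L
        segs <- me[me$gene_id == truth$gene_id[i], c("chrom", "start", "end")]
        segs <- segs[order(segs$start), ]
        parts <- list()
        if (n_tot - n_ptc > 0)
          parts$normal <- .place_reads(segs, n_tot - n_ptc, params$read_length,
                                       sprintf("%s_%s_n", s, truth$gene_id[i]))
        if (n_ptc > 0) {
          ri <- introns[introns$intron_id == truth$retained_intron_id[i],
                        c("chrom", "start", "end")]
          segs_ptc <- rbind(segs, ri)
          segs_ptc <- segs_ptc[order(segs_ptc$start), ]
          parts$ptc <- .place_reads(segs_ptc, n_ptc, params$read_length,
                                    sprintf("%s_%s_p", s, truth$gene_id[i]))
        }
        rows[[i]] <- do.call(rbind, parts)
        ## expectation of union-mode gene counts: ptc reads entirely inside
        ## the retained intron do not touch the gene's merged exons
        if (truth$has_ptc_intron[i]) {
          L <- truth$exonic_length[i] + truth$retained_length[i]
          rl <- min(params$read_length, L)
          p_in <- max(0, truth$retained_length[i] - rl + 1) / (L - rl + 1)
          exp_gene[i, s] <- mu[i] * (1 - share[i] * p_in)
        } else exp_gene[i, s] <- mu[i]
      }
      ## pre-mRNA background reads inside introns
      imu <- sim$expected$intron_mean[, s]
      irows <- vector("list", nrow(introns))
      for (j in seq_len(nrow(introns))) {
        gi <- match(introns$gene_id[j], truth$gene_id)
        bg <- imu[j]
        if (!is.na(truth$retained_intron_id[gi]) &&
            identical(truth$retained_intron_id[gi], introns$intron_id[j]))
          next  # retained-intron coverage already comes from PTC reads
        n_bg <- rpois(1, bg)
        if (n_bg == 0) next
        irows[[j]] <- .place_reads(introns[j, c("chrom", "start", "end")],
                                   n_bg, params$read_length,
                                   sprintf("%s_%s_b", s, introns$intron_id[j]))
      }
      df <- do.call(rbind, c(rows, irows))
      if (is.null(df))
        df <- data.frame(read_id = character(0), chrom = character(0),
                         start = integer(0), end = integer(0))
      out[[s]] <- read_blocks(df$read_id, df$chrom, df$start, df$end)
    }
    attr(out, "expected_gene_counts") <- exp_gene
    out
  })
}

#' Precision and recall of a substrate list against simulation truth
#'
#' @param substrates a `substrate_list` (or character vector of gene ids).
#' @param truth a `sim_truth`.
#' @param assignment optional gene-level `class_assignment`; if given, the
#'   number of true substrates labeled Class II is reported (the
#'   associated-but-not-up analog).
#' @return list(precision, recall, tp, fp, fn, n_substrates_class2).
#'   Precision is NA when the substrate list is empty.
#' @export
evaluate_recovery <- function(substrates, truth, assignment = NULL) {
  called <- if (is.data.frame(substrates)) substrates$gene_id else substrates
  called <- unique(called)
  pos <- truth$gene_id[truth$is_substrate]
  tp <- length(intersect(called, pos))
  fp <- length(setdiff(called, pos))
  fn <- length(setdiff(pos, called))
  prec <- if (length(called) == 0) NA_real_ else tp / length(called)
  rec <- if (length(pos) == 0) 0 else tp / length(pos)
  n2 <- NA_integer_
  if (!is.null(assignment)) {
    cls2 <- assignment$feature_id[assignment$class == "II"]
    n2 <- length(intersect(cls2, pos))
  }
  list(precision = prec, recall = rec, tp = tp, fp = fp, fn = fn,
       n_substrates_class2 = n2)
}
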