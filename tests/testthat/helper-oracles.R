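# Independent brute-force oracles and random fixture generators.
# Oracles deliberately avoid the code paths they check: interval operations
# are verified by painting positions into logical vectors, read assignment
# by per-position membership lookup, tails by log-choose summation.

# maximal runs of TRUE positions -> intervals
paint_oracle <- function(starts, ends) {
  if (length(starts) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  hi <- max(ends)
  pos <- logical(hi + 1)
  for (i in seq_along(starts)) pos[starts[i]:ends[i]] <- TRUE
  r <- rle(pos)
  stop_at <- cumsum(r$lengths)
  start_at <- stop_at - r$lengths + 1
  keep <- r$values
  data.frame(start = start_at[keep], end = stop_at[keep])
}

# positions covered by intervals, as an integer set
positions_of <- function(starts, ends) {
  if (length(starts) == 0) return(integer(0))
  sort(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
}

random_exon_list <- function(n_max = 10, span = 2000) {
  k <- sample.int(n_max, 1)
  s <- sample.int(span, k, replace = TRUE)
  e <- s + sample.int(300, k, replace = TRUE) - 1L
  data.frame(chrom = "chrT", start = s, end = e, strand = "+")
}

# spacing > 0 lays genes out non-overlapping (each shifted by i * spacing)
random_gene_models <- function(n_genes, seed = NULL, spacing = 0) {
  gen <- function() {
    exlist <- lapply(seq_len(n_genes), function(i) {
      df <- random_exon_list()
      df$start <- df$start + (i - 1L) * as.integer(spacing)
      df$end <- df$end + (i - 1L) * as.integer(spacing)
      df$gene_id <- sprintf("g%03d", i)
      df
    })
    gene_models(do.call(rbind, exlist))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# per-position feature lookup for union-mode assignment
assign_oracle <- function(blocks, feat_df) {
  # feat_df: feature_id, chrom, start, end (possibly several rows per feature)
  hits <- character(0)
  for (b in seq_len(nrow(blocks))) {
    bp <- blocks$start[b]:blocks$end[b]
    for (f in seq_len(nrow(feat_df))) {
      if (feat_df$chrom[f] != blocks$chrom[b]) next
      if (any(bp >= feat_df$start[f] & bp <= feat_df$end[f]))
        hits <- c(hits, feat_df$feature_id[f])
    }
  }
  hits <- unique(hits)
  if (length(hits) == 0) return("no_feature")
  if (length(hits) > 1) return("ambiguous")
  hits
}

# hypergeometric upper tail by direct log-choose summation
hyper_tail_oracle <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

binom_tail_oracle <- function(k, n, p0) {
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p0) + (n - j) * log(1 - p0)))
}

# conditional exact p by explicit enumeration of the split distribution
exact_p_oracle <- function(y1, y2, n1, n2, phi) {
  s <- y1 + y2
  if (s == 0) return(1)
  a <- 0:s
  mu1 <- s * n1 / (n1 + n2)
  mu2 <- s * n2 / (n1 + n2)
  pr <- dnbinom(a, size = n1 / phi, mu = mu1) *
    dnbinom(s - a, size = n2 / phi, mu = mu2)
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[y1 + 1] * (1 + 1e-10)]))
}

# two-sided exact binomial small-p test (phi -> 0 limit)
binom_twosided_oracle <- function(y1, s, prob) {
  pr <- dbinom(0:s, s, prob)
  min(1, sum(pr[pr <= pr[y1 + 1] * (1 + 1e-10)]))
}

# the printed worked example: 585 gene-level Class I, 2003 Class II, 65 III,
# 66 IV out of a 14367-feature universe with 699 up; 171 intron-level genes
# of which 76 are gene-level Class I and 39 Class II (56 in neither).
printed_partition_fixture <- function() {
  n_universe <- 14367
  ids <- sprintf("G%05d", seq_len(n_universe))
  I <- ids[1:585]
  II <- ids[586:(585 + 2003)]
  III <- ids[(585 + 2003 + 1):(585 + 2003 + 65)]
  IV <- ids[(585 + 2003 + 65 + 1):(585 + 2003 + 65 + 66)]
  up_extra <- ids[(585 + 2003 + 65 + 66 + 1):(585 + 2003 + 65 + 66 + 49)]
  up <- c(I, III, up_extra)   # 585 + 65 + 49 = 699 up-regulated features
  down <- IV
  ipA <- c(I, II, up_extra)   # up_extra sits in exactly one IP set
  ipB <- c(I, II)
  sets <- comparison_sets(up, down, ipA, ipB, universe = ids)
  assignment <- classify_features(sets)
  intron_genes <- c(I[1:76], II[1:39], ids[(n_universe - 55):n_universe])
  biotypes <- setNames(rep("protein_coding", n_universe), ids)
  biotypes[I[1:131]] <- "pseudogene"
  list(assignment = assignment, sets = sets, intron_genes = intron_genes,
       biotypes = biotypes, up = up)
}

tiny_gtf <- function(path, lines = NULL) {
  if (is.null(lines)) lines <- c(
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "gA"; gene_biotype "protein_coding";',
    'chr1\ttest\texon\t301\t400\t.\t+\t.\tgene_id "gA"; gene_biotype "protein_coding";',
    'chr1\ttest\texon\t150\t250\t.\t-\t.\tgene_id "gB"; gene_biotype "pseudogene";')
  writeLines(lines, path)
  path
}
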