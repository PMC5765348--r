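#' @title Union-mode feature counting and the CPM expression filter
#' @description Reads are simplified spliced alignments: one or more aligned
#'   blocks per read (split at splice junctions). A read is assigned to a
#'   feature only if the set of features overlapped by any aligned position
#'   is exactly one; otherwise it is `ambiguous` (> 1) or `no_feature` (0).
#'   Strand is ignored (non-strand-specific libraries).
#' @name counting
NULL

#' Build a read-block table
#'
#' @param read_id character vector, one entry per block; blocks of one read
#'   share a read_id and must lie on one chromosome.
#' @param chrom,start,end block coordinates, 1-based inclusive.
#' @return A `read_blocks` data.frame.
#' @export
read_blocks <- function(read_id, chrom, start, end) {
  df <- data.frame(read_id = as.character(read_id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  .check_intervals(df, "read block")
  nchrom <- tapply(df$chrom, df$read_id, function(x) length(unique(x)))
  if (any(nchrom > 1))
    stop("read ", names(nchrom)[nchrom > 1][1], " has blocks on multiple chromosomes")
  class(df) <- c("read_blocks", "data.frame")
  df
}

## ---- feature index -----------------------------------------------------

#' Build an overlap index over a feature catalog
#'
#' @param features a `gene_models` object (features are genes, whose
#'   positions are their merged exons) or an `intron_catalog` (features are
#'   individual introns).
#' @return A `feature_index` (GRanges with a feature_id column plus the
#'   ordered universe of feature ids).
#' @export
feature_index <- function(features) {
  if (inherits(features, "gene_models")) {
    m <- features$merged_exons
    gr <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$start, m$end))
    S4Vectors::mcols(gr)$feature_id <- m$gene_id
    ids <- features$genes$gene_id
  } else if (inherits(features, "intron_catalog")) {
    gr <- GenomicRanges::GRanges(features$chrom,
                                 IRanges::IRanges(features$start, features$end))
    S4Vectors::mcols(gr)$feature_id <- features$intron_id
    ids <- features$intron_id
  } else stop("unknown feature collection type")
  structure(list(ranges = gr, feature_ids = ids), class = "feature_index")
}

#' Assign reads to features in union mode
#'
#' @param reads a `read_blocks` data.frame.
#' @param index a [feature_index()].
#' @return character vector, one entry per distinct read (in order of first
#'   appearance): a feature id, `"ambiguous"`, or `"no_feature"`.
#' @export
assign_reads <- function(reads, index) {
  stopifnot(inherits(index, "feature_index"))
  if (!inherits(reads, "read_blocks")) reads <- read_blocks(reads$read_id, reads$chrom, reads$start, reads$end)
  rid <- factor(reads$read_id, levels = unique(reads$read_id))
  if (nrow(reads) == 0) return(character(0))
  q <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(reads$start, reads$end))
  hits <- GenomicRanges::findOverlaps(q, index$ranges, ignore.strand = TRUE)
  out <- rep("no_feature", nlevels(rid))
  names(out) <- levels(rid)
  if (length(hits)) {
    hit_read <- as.integer(rid)[S4Vectors::queryHits(hits)]
    hit_feat <- S4Vectors::mcols(index$ranges)$feature_id[S4Vectors::subjectHits(hits)]
    nfeat <- tapply(hit_feat, hit_read, function(x) length(unique(x)))
    first <- tapply(hit_feat, hit_read, `[`, 1)
    idx <- as.integer(names(nfeat))
    out[idx] <- ifelse(nfeat == 1, first, "ambiguous")
  }
  unname(out)
}

## ---- count matrix ------------------------------------------------------

#' Construct a count matrix container
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   dimnames.
#' @param library_sizes per-sample positive totals (defaults to column
#'   sums); these are the denominators for CPM and normalization and are
#'   unchanged by feature filtering, so the intron-level analysis can reuse
#'   the gene-level library sizes.
#' @param stats optional per-sample assignment statistics.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, library_sizes = NULL, stats = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) stop("counts must have feature rownames")
    rownames(counts) <- character(0)
  }
  stopifnot(!is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- setNames(as.numeric(library_sizes), colnames(counts))
  structure(list(counts = counts, library_sizes = library_sizes, stats = stats),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " features x ", ncol(x$counts),
      " samples; median library size ",
      format(median(x$library_sizes), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Count reads against a feature catalog, per sample
#'
#' @param reads_by_sample named list of `read_blocks` tables, one per sample.
#' @param features a `gene_models`, `intron_catalog`, or prebuilt
#'   [feature_index()].
#' @param library_sizes optional externally supplied library sizes (e.g. the
#'   gene-level totals when counting introns); defaults to the number of
#'   assigned reads per sample.
#' @return A `count_matrix` whose `stats` element records assigned /
#'   ambiguous / no_feature / total per sample (assigned + ambiguous +
#'   no_feature = total).
#' @export
build_count_matrix <- function(reads_by_sample, features, library_sizes = NULL) {
  idx <- if (inherits(features, "feature_index")) features else feature_index(features)
  stopifnot(is.list(reads_by_sample), !is.null(names(reads_by_sample)))
  ids <- idx$feature_ids
  samples <- names(reads_by_sample)
  counts <- matrix(0L, nrow = length(ids), ncol = length(samples),
                   dimnames = list(ids, samples))
  stats <- data.frame(sample_id = samples, assigned = 0L, ambiguous = 0L,
                      no_feature = 0L, total = 0L, stringsAsFactors = FALSE)
  for (s in seq_along(samples)) {
    rd <- reads_by_sample[[s]]
    if (is.null(rd) || nrow(rd) == 0) {
      warning("sample ", samples[s], " has no reads; zero column emitted")
      next
    }
    a <- assign_reads(rd, idx)
    stats$total[s] <- length(a)
    stats$ambiguous[s] <- sum(a == "ambiguous")
    stats$no_feature[s] <- sum(a == "no_feature")
    hit <- a[!(a %in% c("ambiguous", "no_feature"))]
    stats$assigned[s] <- length(hit)
    if (length(hit)) {
      tab <- table(factor(hit, levels = ids))
      counts[, s] <- as.integer(tab)
    }
  }
  if (is.null(library_sizes)) library_sizes <- setNames(stats$assigned, samples)
  count_matrix(counts, library_sizes = library_sizes, stats = stats)
}

#' Counts per million
#'
#' @param cm a `count_matrix`.
#' @return matrix of counts[f, s] / library_sizes[s] * 1e6.
#' @export
cpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$library_sizes <= 0)) stop("library_sizes must be positive")
  sweep(cm$counts, 2, cm$library_sizes, "/") * 1e6
}

#' Filter features on a counts-per-million threshold
#'
#' A feature is retained iff its CPM is at least `min_cpm` in at least
#' `min_samples` samples. Library sizes are unchanged by filtering.
#'
#' @param cm a `count_matrix`.
#' @param min_cpm CPM cutoff (default 3, the usual expression minimum of
#'   three counts per million reads).
#' @param min_samples number of samples in which the cutoff must hold;
#'   defaults to 3, one full replicate group, so genotype-specific
#'   transcripts survive.
#' @return the filtered `count_matrix`.
#' @export
cpm_filter <- function(cm, min_cpm = 3, min_samples = 3) {
  stopifnot(inherits(cm, "count_matrix"))
  if (min_samples > ncol(cm$counts))
    stop("min_samples exceeds the number of samples")
  keep <- rowSums(cpm(cm) >= min_cpm) >= min_samples
  count_matrix(cm$counts[keep, , drop = FALSE],
               library_sizes = cm$library_sizes, stats = cm$stats)
}

## ---- sample design and IO ---------------------------------------------

#' Construct the sample design table
#'
#' @param sample_id,genotype,fraction,replicate vectors of equal length;
#'   genotype in {N2, smg1, smg1smg2}, fraction in {input, IP}.
#' @return A `sample_design` data.frame.
#' @export
sample_design <- function(sample_id, genotype, fraction, replicate) {
  genotype <- as.character(genotype)
  fraction <- as.character(fraction)
  if (!all(genotype %in% c("N2", "smg1", "smg1smg2")))
    stop("genotype must be one of N2, smg1, smg1smg2")
  if (!all(fraction %in% c("input", "IP")))
    stop("fraction must be input or IP")
  df <- data.frame(sample_id = as.character(sample_id), genotype = genotype,
                   fraction = fraction, replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  tab <- table(df$genotype, df$fraction)
  if (any(tab > 0 & tab < 2))
    warning("some (genotype, fraction) groups have fewer than 2 replicates")
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Read/write count matrices and design tables as TSV
#'
#' `write_counts` stores the matrix with a `feature_id` column and records
#' library sizes in a `#library_sizes:` header comment so filtering-stable
#' denominators survive the round-trip.
#'
#' @param cm a `count_matrix`; `path` a file path.
#' @return `read_counts` returns a `count_matrix`; `read_design` a
#'   `sample_design`.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#library_sizes:\t",
                    paste(sprintf("%s=%s", names(cm$library_sizes),
                                  format(cm$library_sizes, scientific = FALSE, trim = TRUE)),
                          collapse = "\t")), con)
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param path TSV path.
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1)
  libs <- NULL
  if (startsWith(first, "#library_sizes:")) {
    kv <- strsplit(strsplit(first, "\t")[[1]][-1], "=", fixed = TRUE)
    libs <- setNames(as.numeric(vapply(kv, `[`, character(1), 2)),
                     vapply(kv, `[`, character(1), 1))
  }
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  count_matrix(m, library_sizes = if (is.null(libs)) NULL else libs[colnames(m)])
}

#' @rdname write_counts
#' @export
read_design <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  sample_design(df$sample_id, df$genotype, df$fraction, df$replicate)
}

## ---- read formats ------------------------------------------------------

#' Read spliced reads from BED12
#'
#' Block coordinates come from blockStarts/blockSizes relative to chromStart
#' (0-based half-open in the file; converted to 1-based inclusive).
#'
#' @param path BED12 file.
#' @return A `read_blocks` data.frame.
#' @export
read_bed12 <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 12) stop("expected BED12 input")
  rows <- lapply(seq_len(nrow(bed)), function(i) {
    sizes <- as.integer(strsplit(sub(",$", "", bed[i, 11]), ",")[[1]])
    starts <- as.integer(strsplit(sub(",$", "", bed[i, 12]), ",")[[1]])
    data.frame(read_id = bed[i, 4], chrom = bed[i, 1],
               start = bed[i, 2] + starts + 1L,
               end = bed[i, 2] + starts + sizes,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  read_blocks(df$read_id, df$chrom, df$start, df$end)
}

#' Read spliced reads from a minimal SAM
#'
#' Only QNAME, RNAME, POS and CIGAR are consumed. CIGAR operations M, D
#' consume the reference within a block, N splits blocks (splice junction),
#' I and S consume nothing on the reference. Unmapped records (RNAME `*`)
#' are skipped.
#'
#' @param path SAM text file (headers allowed).
#' @return A `read_blocks` data.frame.
#' @export
read_sam_minimal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) stop("malformed SAM record: ", substr(ln, 1, 60))
    if (f[3] == "*" || f[6] == "*") next
    pos <- as.integer(f[4])
    ops <- regmatches(f[6], gregexpr("\\d+[MIDNS]", f[6]))[[1]]
    if (!nzchar(paste(ops, collapse = "")) ||
        nchar(paste(ops, collapse = "")) != nchar(f[6]))
      stop("unsupported CIGAR: ", f[6])
    cur_start <- pos; cur <- pos
    starts <- integer(0); ends <- integer(0)
    open <- FALSE
    for (op in ops) {
      n <- as.integer(sub("[MIDNS]", "", op))
      type <- sub("\\d+", "", op)
      if (type %in% c("M", "D")) {
        if (!open) { cur_start <- cur; open <- TRUE }
        cur <- cur + n
      } else if (type == "N") {
        if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur - 1L) }
        open <- FALSE
        cur <- cur + n
      }
      ## I and S consume nothing on the reference
    }
    if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur - 1L) }
    if (length(starts))
      out[[length(out) + 1]] <- data.frame(read_id = f[1], chrom = f[3],
                                           start = starts, end = ends,
                                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(read_blocks(character(0), character(0), integer(0), integer(0)))
  df <- do.call(rbind, out)
  read_blocks(df$read_id, df$chrom, df$start, df$end)
}
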