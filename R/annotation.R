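#' @title Gene models and intron-only catalogs
#' @description Coordinates are 1-based inclusive throughout (GTF convention);
#'   BED export converts to 0-based half-open. Exons of all transcripts of a
#'   gene are pooled before merging, and book-ended exons (no intervening
#'   base) merge into one interval so that no zero-length intron is emitted.
#' @name annotation
NULL

## ---- constructors -----------------------------------------------------

.biotypes <- c("protein_coding", "pseudogene", "lncRNA", "ncRNA", "other")

.norm_biotype <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !(x %in% .biotypes)] <- "other"
  x
}

.check_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 1)) stop(what, " start must be >= 1")
  bad <- which(df$end < df$start)
  if (length(bad))
    stop("validation error: ", what, " with end < start (row ", bad[1], ")")
  invisible(df)
}

#' Build a gene-model collection from an exon table
#'
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand` (1-based inclusive coordinates). Exons of all
#'   transcripts of a gene should be pooled here; transcript identity is
#'   deliberately discarded.
#' @param biotype named character vector mapping gene_id to one of
#'   `protein_coding`, `pseudogene`, `lncRNA`, `ncRNA`, `other`; unknown or
#'   missing entries become `other`.
#' @return An object of class `gene_models`: a list with data.frames
#'   `genes` (gene_id, chrom, strand, biotype), `exons` (as given) and
#'   `merged_exons` (sorted, disjoint, non-adjacent per gene).
#' @export
gene_models <- function(exons, biotype = NULL) {
  stopifnot("gene_id" %in% names(exons))
  if (!"strand" %in% names(exons)) exons$strand <- "."
  exons <- exons[, c("gene_id", "chrom", "start", "end", "strand")]
  exons$gene_id <- as.character(exons$gene_id)
  exons$chrom <- as.character(exons$chrom)
  .check_intervals(exons, "exon")
  ids <- unique(exons$gene_id)
  chrom_per_gene <- tapply(exons$chrom, exons$gene_id, function(x) unique(x))
  n_chrom <- vapply(chrom_per_gene, length, integer(1))
  if (any(n_chrom > 1))
    stop("gene ", names(chrom_per_gene)[n_chrom > 1][1],
         " has exons on multiple chromosomes")
  merged <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    m <- merge_exons(e)
    m$gene_id <- e$gene_id[1]
    m
  }))
  rownames(merged) <- NULL
  merged <- merged[order(match(merged$gene_id, ids), merged$start),
                   c("gene_id", "chrom", "start", "end", "strand")]
  rownames(merged) <- NULL
  bt <- setNames(rep("other", length(ids)), ids)
  if (!is.null(biotype)) {
    hit <- intersect(names(biotype), ids)
    bt[hit] <- .norm_biotype(biotype[hit])
  }
  genes <- data.frame(
    gene_id = ids,
    chrom   = vapply(ids, function(g) exons$chrom[match(g, exons$gene_id)], character(1)),
    strand  = vapply(ids, function(g) exons$strand[match(g, exons$gene_id)], character(1)),
    biotype = unname(bt[ids]),
    stringsAsFactors = FALSE
  )
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons, merged_exons = merged),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models: ", nrow(x$genes), " genes, ",
      nrow(x$exons), " exons (", nrow(x$merged_exons), " merged)\n", sep = "")
  invisible(x)
}

## ---- operations --------------------------------------------------------

#' Merge a gene's exons into disjoint intervals
#'
#' Overlapping or book-ended (end + 1 == next start) exons collapse into a
#' single interval; the positional union is preserved.
#'
#' @param exons data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   optionally `strand`. All exons must lie on one chromosome.
#' @return data.frame of sorted, pairwise disjoint, non-adjacent intervals.
#' @examples
#' merge_exons(data.frame(chrom = "chr1", start = c(101, 150), end = c(200, 250)))
#' @export
merge_exons <- function(exons) {
  if (!"strand" %in% names(exons)) exons$strand <- "."
  .check_intervals(exons, "exon")
  if (nrow(exons) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  if (length(unique(exons$chrom)) > 1)
    stop("merge_exons: exons lie on multiple chromosomes")
  r <- IRanges::reduce(IRanges::IRanges(exons$start, exons$end))
  strand <- if (length(unique(exons$strand)) == 1) exons$strand[1] else "."
  data.frame(chrom = exons$chrom[1],
             start = IRanges::start(r), end = IRanges::end(r),
             strand = strand, stringsAsFactors = FALSE)
}

#' Derive the intron-only catalog from gene models
#'
#' For a gene with k merged exons, emits the k - 1 intervening intervals
#' (merged_exons[i].end + 1) .. (merged_exons[i+1].start - 1) as introns.
#' Single-exon genes contribute none. Introns are computed per gene
#' independently; overlap between genes is permitted and resolved at
#' counting time.
#'
#' @param genes a `gene_models` object.
#' @return An `intron_catalog`: data.frame with `gene_id`, `intron_index`,
#'   `intron_id` (gene_id:I<index>), `chrom`, `start`, `end`, `strand`.
#' @export
build_intron_catalog <- function(genes) {
  stopifnot(inherits(genes, "gene_models"))
  me <- genes$merged_exons
  out <- lapply(split(me, me$gene_id), function(m) {
    m <- m[order(m$start), ]
    k <- nrow(m)
    if (k < 2) return(NULL)
    data.frame(gene_id = m$gene_id[1],
               intron_index = seq_len(k - 1),
               chrom = m$chrom[1],
               start = m$end[-k] + 1L,
               end = m$start[-1] - 1L,
               strand = m$strand[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), intron_index = integer(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  out <- out[order(match(out$gene_id, genes$genes$gene_id), out$intron_index), ]
  out$intron_id <- sprintf("%s:I%d", out$gene_id, out$intron_index)
  rownames(out) <- NULL
  class(out) <- c("intron_catalog", "data.frame")
  out[, c("gene_id", "intron_index", "intron_id", "chrom", "start", "end", "strand")]
}

## ---- GTF / BED io ------------------------------------------------------

.validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop("GTF parse error at line ", i, ": expected 9 tab-separated fields")
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop("GTF parse error at line ", i, ": non-numeric coordinates")
    if (e < s)
      stop("GTF validation error at line ", i, ": end < start")
  }
  invisible(TRUE)
}

#' Parse a GTF into gene models
#'
#' Reads exon records of an Ensembl-dialect GTF (gene_id and, if present,
#' gene_biotype attributes), pools exons per gene across transcripts and
#' computes merged exons.
#'
#' @param path path to a GTF file.
#' @return A `gene_models` object.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  .validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(gr) == 0) stop("GTF contains no exon records")
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("GTF exon records lack gene_id attributes")
  exons <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  exons$strand[exons$strand == "*"] <- "."
  biotype <- NULL
  if (!is.null(gr$gene_biotype)) {
    biotype <- tapply(as.character(gr$gene_biotype), exons$gene_id,
                      function(x) x[1])
    biotype <- setNames(as.character(biotype), names(biotype))
  }
  gene_models(exons, biotype = biotype)
}

#' Export gene models or an intron catalog
#'
#' GTF output is 1-based inclusive; BED output is 0-based half-open
#' (chromStart = start - 1, chromEnd = end). Both round-trip losslessly
#' through [parse_gtf()] / [read_intron_bed()].
#'
#' @param features a `gene_models` object (exported as one exon record per
#'   merged exon) or an `intron_catalog` (one record per intron).
#' @param path output file path.
#' @param format `"gtf"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
export_features <- function(features, path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  if (inherits(features, "gene_models")) {
    m <- features$merged_exons
    bt <- setNames(features$genes$biotype, features$genes$gene_id)
    if (format == "gtf") {
      lines <- sprintf(
        '%s\tripclass\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
        m$chrom, m$start, m$end, m$strand, m$gene_id, unname(bt[m$gene_id]))
    } else {
      lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       m$chrom, m$start - 1L, m$end, m$gene_id, m$strand)
    }
  } else if (inherits(features, "intron_catalog")) {
    if (format == "gtf") {
      lines <- sprintf(
        '%s\tripclass\tintron\t%d\t%d\t.\t%s\t.\tgene_id "%s"; intron_index "%d";',
        features$chrom, features$start, features$end, features$strand,
        features$gene_id, features$intron_index)
    } else {
      lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       features$chrom, features$start - 1L, features$end,
                       features$intron_id, features$strand)
    }
  } else stop("unknown feature collection type")
  writeLines(lines, path)
  invisible(path)
}

#' Read an intron catalog written as BED6
#'
#' @param path BED6 file whose name column is `gene_id:I<index>` as written
#'   by [export_features()].
#' @return An `intron_catalog`.
#' @export
read_intron_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("expected BED6 input")
  names(bed)[1:6] <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand")
  parts <- regmatches(bed$name, regexec("^(.*):I(\\d+)$", bed$name))
  if (any(vapply(parts, length, integer(1)) != 3))
    stop("intron name column must be gene_id:I<index>")
  out <- data.frame(
    gene_id = vapply(parts, `[`, character(1), 2),
    intron_index = as.integer(vapply(parts, `[`, character(1), 3)),
    intron_id = bed$name,
    chrom = bed$chrom,
    start = bed$chromStart + 1L,
    end = bed$chromEnd,
    strand = bed$strand,
    stringsAsFactors = FALSE
  )
  class(out) <- c("intron_catalog", "data.frame")
  out
}
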