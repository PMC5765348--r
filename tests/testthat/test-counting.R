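two_gene_models <- function() {
  gene_models(data.frame(
    gene_id = c("gA", "gA", "gB"),
    chrom = "chr1",
    start = c(101, 301, 360),
    end = c(200, 400, 500)))
}

test_that("union-mode assignment distinguishes unique, ambiguous, none", {
  idx <- feature_index(two_gene_models())
  rd <- read_blocks(c("r1", "r2", "r3"), "chr1",
                    start = c(150, 380, 250), end = c(160, 390, 260))
  expect_equal(assign_reads(rd, idx), c("gA", "ambiguous", "no_feature"))
  # spliced read whose blocks stay within one gene
  sp <- read_blocks(c("r4", "r4"), "chr1", c(190, 301), c(200, 310))
  expect_equal(assign_reads(sp, idx), "gA")
  expect_error(read_blocks(c("r5", "r5"), c("chr1", "chr2"), c(1, 1), c(10, 10)),
               "multiple chromosomes")
})

test_that("assignment matches the per-position lookup oracle on random reads", {
  gms <- random_gene_models(30, seed = 201)
  idx <- feature_index(gms)
  feat_df <- data.frame(feature_id = gms$merged_exons$gene_id,
                        chrom = gms$merged_exons$chrom,
                        start = gms$merged_exons$start,
                        end = gms$merged_exons$end)
  withr::with_seed(202, {
    n <- 400
    starts <- sample.int(2500, n, replace = TRUE)
    lens <- sample.int(120, n, replace = TRUE)
    spliced <- runif(n) < 0.3
    rows <- lapply(seq_len(n), function(i) {
      if (!spliced[i]) {
        data.frame(read_id = paste0("r", i), chrom = "chrT",
                   start = starts[i], end = starts[i] + lens[i])
      } else {
        gap <- sample.int(300, 1)
        data.frame(read_id = paste0("r", i), chrom = "chrT",
                   start = c(starts[i], starts[i] + lens[i] + gap + 1L),
                   end = c(starts[i] + lens[i], starts[i] + 2L * lens[i] + gap + 1L))
      }
    })
    rd <- do.call(rbind, rows)
    got <- assign_reads(read_blocks(rd$read_id, rd$chrom, rd$start, rd$end), idx)
    for (i in seq_len(n)) {
      blocks <- rd[rd$read_id == paste0("r", i), ]
      expect_identical(got[i], assign_oracle(blocks, feat_df))
    }
  })
})

test_that("count matrices conserve reads and are order-independent", {
  gms <- two_gene_models()
  rd <- read_blocks(paste0("r", 1:6), "chr1",
                    start = c(110, 120, 310, 380, 250, 600),
                    end = c(130, 140, 330, 390, 260, 650))
  cm <- build_count_matrix(list(s1 = rd), gms)
  expect_equal(unname(cm$counts[, 1]), c(3, 0))
  st <- cm$stats
  expect_equal(st$assigned + st$ambiguous + st$no_feature, st$total)
  expect_equal(unname(cm$library_sizes["s1"]), st$assigned)

  perm <- withr::with_seed(203, sample(nrow(rd)))
  rd2 <- read_blocks(rd$read_id[perm], rd$chrom[perm],
                     rd$start[perm], rd$end[perm])
  cm2 <- build_count_matrix(list(s1 = rd2), gms)
  expect_identical(cm$counts, cm2$counts)

  # against the intron catalog, exon-only reads vanish; the read inside
  # gA's intron (201-300) is the only one counted
  ic <- build_intron_catalog(gms)
  cmi <- build_count_matrix(list(s1 = rd), ic)
  expect_equal(unname(cmi$counts["gA:I1", 1]), 1)
  expect_equal(sum(cmi$counts), 1)
  expect_warning(build_count_matrix(list(s1 = rd, s2 = NULL), gms), "no reads")
})

test_that("counting simulated reads recovers known abundances", {
  gms <- random_gene_models(20, seed = 204, spacing = 4000)
  idx <- feature_index(gms)
  withr::with_seed(205, {
    expected <- setNames(sample(50:200, 20), gms$genes$gene_id)
    rows <- lapply(names(expected), function(g) {
      me <- gms$merged_exons[gms$merged_exons$gene_id == g, ]
      n <- rpois(1, expected[g])
      if (n == 0) return(NULL)
      pick <- sample(nrow(me), n, replace = TRUE)
      s <- me$start[pick] + floor(runif(n) * pmax(1, me$end[pick] - me$start[pick] - 20))
      data.frame(read_id = sprintf("%s_%d", g, seq_len(n)), chrom = me$chrom[1],
                 start = s, end = pmin(s + 20, me$end[pick]))
    })
    rd <- do.call(rbind, rows)
    cm <- build_count_matrix(list(s1 = read_blocks(rd$read_id, rd$chrom,
                                                   rd$start, rd$end)), gms)
    # assigned counts are Poisson around expectation minus ambiguity loss;
    # compare only genes whose merged exons overlap no other gene
    other <- gms$merged_exons
    for (g in names(expected)) {
      me <- gms$merged_exons[gms$merged_exons$gene_id == g, ]
      ov <- other[other$gene_id != g, ]
      clash <- any(ov$start <= max(me$end) & ov$end >= min(me$start))
      if (clash) next
      expect_lt(abs(cm$counts[g, 1] - expected[g]), 3 * sqrt(expected[g]) + 1)
    }
  })
})

rn <- function(m) if (is.null(rownames(m))) character(0) else rownames(m)

test_that("cpm_filter applies the 3-per-million rule and is monotone", {
  counts <- matrix(c(3, 3, 3,
                     0, 0, 0,
                     10, 2, 2), nrow = 3, byrow = TRUE,
                   dimnames = list(c("f1", "f2", "f3"), c("s1", "s2", "s3")))
  cm <- count_matrix(counts, library_sizes = rep(1e6, 3))
  kept <- cpm_filter(cm, min_cpm = 3, min_samples = 3)
  expect_identical(rownames(kept$counts), "f1")    # exactly 3 CPM everywhere
  expect_identical(kept$library_sizes, cm$library_sizes)
  expect_error(cpm_filter(cm, min_samples = 4), "min_samples")

  withr::with_seed(206, {
    for (rep in 1:20) {
      y <- matrix(rnbinom(200 * 4, mu = 5, size = 2), 200, 4,
                  dimnames = list(paste0("f", 1:200), paste0("s", 1:4)))
      libs <- runif(4, 5e5, 2e6)
      cm <- count_matrix(y, library_sizes = libs)
      min_cpm <- runif(1, 1, 10); min_samples <- sample(1:4, 1)
      got <- rn(cpm_filter(cm, min_cpm, min_samples)$counts)
      # direct row-wise recomputation
      keep <- apply(y, 1, function(r) sum(r / libs * 1e6 >= min_cpm) >= min_samples)
      expect_identical(got, names(keep)[keep])
      # monotone: raising the cutoff never adds features
      got_hi <- rn(cpm_filter(cm, min_cpm * 2, min_samples)$counts)
      expect_true(all(got_hi %in% got))
    }
  })
})

test_that("BED12 and minimal SAM readers reconstruct spliced blocks", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", "99", "400", "readA", "0", "+", "99", "400",
                     "0", "2", "51,60", "0,241"), collapse = "\t"), bed)
  rb <- read_bed12(bed)
  expect_equal(rb$start, c(100L, 341L))
  expect_equal(rb$end, c(150L, 400L))

  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               paste(c("readA", "0", "chr1", "100", "255", "51M240N60M",
                       "*", "0", "0", "*", "*"), collapse = "\t"),
               paste(c("readB", "0", "chr1", "200", "255", "5S20M2I10M3D10M",
                       "*", "0", "0", "*", "*"), collapse = "\t"),
               paste(c("readC", "4", "*", "0", "0", "*",
                       "*", "0", "0", "*", "*"), collapse = "\t")), sam)
  rs <- read_sam_minimal(sam)
  a <- rs[rs$read_id == "readA", ]
  expect_equal(a$start, c(100L, 391L))   # M/N walk matches the BED12 read
  expect_equal(a$end, c(150L, 450L))
  b <- rs[rs$read_id == "readB", ]
  # S and I consume nothing; M and D consume reference: 20+10+3+10 = 43
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(200L, 242L))
  expect_false("readC" %in% rs$read_id)
})

test_that("count matrix and design tables round-trip through TSV", {
  y <- matrix(1:6, 2, 3, dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  cm <- count_matrix(y, library_sizes = c(a = 100, b = 200, c = 300))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cm, path)
  back <- read_counts(path)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$library_sizes, cm$library_sizes)

  d <- suppressWarnings(
    sample_design(c("x1", "x2"), c("N2", "smg1"), c("input", "IP"), c(1, 1)))
  dp <- withr::local_tempfile(fileext = ".tsv")
  write.table(d, dp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(as.data.frame(suppressWarnings(read_design(dp))),
               as.data.frame(d))
  expect_error(sample_design("x", "smg3", "input", 1), "genotype")
})
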