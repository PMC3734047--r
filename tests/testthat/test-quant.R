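test_that("annotation round-trips through GFF3/TSV with interval normalization", {
  ann <- manual_annotation()
  gff <- withr::local_tempfile(fileext = ".gff3")
  rrna <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, gff, rrna)
  got <- read_annotation(gff, rrna)

  expect_identical(got$cds[c("gene_id", "replicon", "start", "end")],
                   ann$cds[c("gene_id", "replicon", "start", "end")])
  # the high-to-low raw interval (6000, 5000) is normalized to (5000, 6000)
  expect_identical(got$rrna$start, 5000L)
  expect_identical(got$rrna$end, 6000L)
  expect_identical(got$replicons$length, c(10000L, 8000L))

  # empty rRNA table -> empty exclusion set
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("replicon\tstart\tend", empty)
  expect_identical(nrow(read_annotation(gff, empty)$rrna), 0L)

  # CDS beyond replicon bounds is an error
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region chr1 1 2000",
               "chr1\tsynth\tCDS\t100\t2500\t.\t+\t0\tID=geneX"), bad)
  expect_error(read_annotation(bad, rrna), "bounds")
})

test_that("alignment grouping collates by read and ignores record order", {
  header <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:10000",
              "@SQ\tSN:chr2\tLN:8000")
  rec <- function(q, flag, rname, pos, nm) {
    sprintf("%s\t%d\t%s\t%d\t60\t36M\t*\t0\t0\t%s\t%s\tNM:i:%d",
            q, flag, rname, pos, strrep("A", 36), strrep("I", 36), nm)
  }
  recs <- c(rec("r1", 0, "chr1", 1001, 0),
            rec("r1", 256, "chr1", 3001, 0),
            rec("r1", 256, "chr2", 501, 1),
            rec("r2", 4, "chr1", 0, 0),      # unmapped: no locus
            rec("r3", 0, "chr2", 700, 0))
  recs[4] <- sub("chr1\t0\t60\t36M", "*\t0\t0\t*", recs[4], fixed = TRUE)

  sam1 <- withr::local_tempfile(fileext = ".sam")
  sam2 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(header, recs), sam1)
  writeLines(c(header, rev(recs)), sam2)

  g1 <- group_alignments(sam1)
  g2 <- group_alignments(sam2)
  expect_identical(g1, g2)
  expect_identical(sum(g1$read_id == "r1"), 3L)   # 3 loci, one group
  expect_false("r2" %in% g1$read_id)              # unmapped skipped
  expect_identical(g1$end, g1$start + 35L)
})

test_that("filtering drops mismatched and rRNA loci and tallies reads", {
  ann <- manual_annotation()  # rRNA chr1:5000-6000
  loci <- dplyr::bind_rows(
    mk_loci("r1", "chr1", 1100, nm = 1),        # mismatch -> read dropped
    mk_loci("r2", "chr1", 5500),                # rRNA -> dropped, tallied
    mk_loci("r3", "chr1", 5990),                # 1-bp overlap with rRNA
    mk_loci("r4", "chr1", 1200),                # clean genic
    mk_loci("r5", c("chr1", "chr2"), c(5500, 700))  # mixed rRNA + genic
  )
  flt <- filter_alignments(loci, ann)
  expect_identical(flt$stats$n_reads_input, 5L)
  expect_identical(flt$stats$n_reads_rrna, 2L)   # r2, r3 (not r5: survives)
  expect_identical(flt$stats$n_loci_dropped_mismatch, 1L)
  expect_identical(sort(unique(flt$loci$read_id)), c("r4", "r5"))
  expect_identical(flt$loci$n_loci[flt$loci$read_id == "r5"], 1L)
  expect_equal(flt$stats$frac_rrna, 2 / 5)

  # read-level granularity drops r5 entirely and tallies it as rRNA
  flt_r <- filter_alignments(loci, ann, granularity = "read")
  expect_identical(sort(unique(flt_r$loci$read_id)), "r4")
  expect_identical(flt_r$stats$n_reads_rrna, 3L)
})

test_that("fractional counting distributes 1/k / m weights and conserves mass", {
  ann <- manual_annotation()
  # r1: two loci in geneA and geneC -> 0.5 each; r2: unique in geneA -> 1
  loci <- dplyr::bind_rows(
    mk_loci("r1", c("chr1", "chr2"), c(1101, 801)),
    mk_loci("r2", "chr1", 1500)
  )
  flt <- filter_alignments(loci, ann)
  cnt <- count_reads(flt, ann)
  got <- stats::setNames(cnt$counts$count, cnt$counts$gene_id)
  expect_equal(unname(got["geneA"]), 1.5)
  expect_equal(unname(got["geneC"]), 0.5)
  expect_equal(cnt$library_size, 2)

  # 10 reads x 4 genic loci each: total counted weight 10 exactly
  loci4 <- purrr::map_dfr(1:10, function(i) {
    mk_loci(sprintf("m%02d", i), c("chr1", "chr1", "chr2", "chr2"),
            c(1101, 3101, 601, 901))
  })
  cnt4 <- count_reads(filter_alignments(loci4, ann), ann)
  expect_equal(cnt4$library_size, 10, tolerance = 1e-12)

  # intergenic locus contributes nothing
  cnt0 <- count_reads(filter_alignments(mk_loci("x", "chr1", 8000), ann), ann)
  expect_equal(cnt0$library_size, 0)
})

test_that("counts match the brute-force per-read oracle on random instances", {
  ann <- manual_annotation()
  set.seed(42)
  n_reads <- 120
  loci <- purrr::map_dfr(seq_len(n_reads), function(i) {
    k <- sample(1:3, 1)
    repl <- sample(c("chr1", "chr2"), k, replace = TRUE)
    start <- ifelse(repl == "chr1", sample(900:6500, k, replace = TRUE),
                    sample(400:1600, k, replace = TRUE))
    mk_loci(sprintf("r%04d", i), repl, start,
            nm = rbinom(k, 1, 0.15))
  })
  flt <- filter_alignments(loci, ann)
  cnt <- count_reads(flt, ann)
  oracle <- oracle_quantify(loci, ann)
  expect_equal(stats::setNames(cnt$counts$count, cnt$counts$gene_id),
               oracle$counts, tolerance = 1e-9)
  expect_identical(flt$stats$n_reads_retained, oracle$retained)
})

test_that("RPKM arithmetic: unit case, hand case, scale invariance, errors", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10)
  expect_equal(compute_rpkm(c(75, 25), c(1500, 500), 100),
               c(5e5, 5e5))
  base <- compute_rpkm(c(3, 7), c(400, 900), 10)
  expect_equal(compute_rpkm(c(6, 14), c(400, 900), 20), base)
  expect_error(compute_rpkm(1, 500, 0), "degenerate")
  expect_error(compute_rpkm(1, 0, 100))
})

test_that("pipeline recovers the programmed expression ranking", {
  cfg <- synth_config(n_genes = 8, n_rrn_regions = 0, conditions = "F16",
                      replicates_per_condition = 1, reads_per_sample = 20000,
                      rrna_read_fraction = 0, multimap_fraction = 0,
                      mismatch_fraction = 0, seed = 21)
  ann <- generate_annotation(cfg)
  lv <- stats::setNames(c(0, 0.001, 0.01, 0.05, 0.2, 0.8, 2, 5),
                        ann$cds$gene_id)
  prof <- expression_profile(ann, conditions = "F16", base_level = lv)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(simulate_alignments(ann, prof, cfg, "F16", 1), sam)
  rs <- quantify_samples(c(s1 = sam), ann,
                         tibble::tibble(sample_id = "s1", condition = "F16",
                                        replicate = 1))
  rpkm <- stats::setNames(rs$rpkm$s1, rs$rpkm$gene_id)
  # RPKM estimates reads-per-base: rank order must match the true levels
  expect_identical(order(rpkm), order(lv))
  # relative RPKM of two well-covered genes ~ relative read density
  expect_equal(unname(rpkm["gene008"] / rpkm["gene007"]), 5 / 2,
               tolerance = 0.15)
  expect_equal(unname(rpkm["gene001"]), 0)
})
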