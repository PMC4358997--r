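# SJ table dialect, annotation index construction, and junction filters.

test_that("SJ rows parse with strand and motif code mapping", {
  f <- tempfile()
  writeLines(c("chr1\t101\t200\t1\t1\t1\t42\t3\t38",
               "chr2\t500\t900\t0\t0\t0\t7\t0\t20"), f)
  tab <- read_sj_table(f)
  expect_equal(tab$chrom, c("chr1", "chr2"))
  expect_equal(tab$start[1], 101)
  expect_equal(tab$end[1], 200)
  expect_equal(tab$strand, c("+", "*"))
  expect_equal(tab$motif, c("GT/AG", "other"))
  expect_equal(tab$count, c(42, 7))
})

test_that("malformed SJ rows raise parse errors naming the line", {
  f <- tempfile()
  writeLines("chr1\t300\t200\t1\t1\t1\t42\t3\t38", f)
  expect_error(read_sj_table(f), "line 1")
  writeLines("chr1\t100\t200\t9\t1\t1\t42\t3\t38", f)
  expect_error(read_sj_table(f), "line 1")
  writeLines("chr1\t100\t200\t1\t1", f)
  expect_error(read_sj_table(f), "malformed")
})

test_that("a simulator-emitted SJ table round-trips through read and write", {
  sh <- get_shared_sim()
  d <- file.path(tempdir(), "rt")
  write_simulation(sh$sim, sh$jcm, d)
  f <- list.files(file.path(d, "sj"), full.names = TRUE)[1]
  tab <- read_sj_table(f)
  f2 <- tempfile()
  write_sj_table(tab, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("annotation index derives strand-aware introns from exon chains", {
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 1, 1, 201, 1, 1, 1, 201),
                             c(300, 300, 100, 300, 300, 300, 100, 300)),
    strand = rep(c("+", "-"), each = 4),
    type = rep(c("gene", "transcript", "exon", "exon"), 2),
    gene_id = rep(c("gp", "gm"), each = 4),
    transcript_id = rep(c(NA, "tp", "tp", "tp", NA, "tm", "tm", "tm"), 1))
  idx <- build_annotation_index(gr)
  jp <- idx$junctions[idx$junctions$strand == "+", ]
  jm <- idx$junctions[idx$junctions$strand == "-", ]
  expect_equal(c(jp$start, jp$end), c(101, 200))
  expect_equal(c(jp$donor, jp$acceptor), c(101, 200))
  expect_equal(c(jm$donor, jm$acceptor), c(200, 101))
})

test_that("shared introns collapse and overlapping-exon transcripts are skipped", {
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 1, 1, 201, 1, 1, 201, 1, 1, 90),
                             c(300, 300, 100, 300, 300, 100, 300, 300, 120, 300)),
    strand = "+",
    type = c("gene", "transcript", "exon", "exon",
             "transcript", "exon", "exon", "transcript", "exon", "exon"),
    gene_id = "g",
    transcript_id = c(NA, "t1", "t1", "t1", "t2", "t2", "t2",
                      "t3", "t3", "t3"))
  expect_warning(idx <- build_annotation_index(gr), "overlapping")
  expect_equal(nrow(idx$junctions), 1)
})

test_that("coverage, motif and shared-site filters match a brute-force oracle", {
  sh <- get_shared_sim()
  jcm <- sh$jcm
  # perturb: novel junctions sharing one, both, or no splice sites, odd
  # motifs, unknown strands, and low-coverage rows
  set.seed(31)
  sc <- jcm$junctions
  extra <- do.call(rbind, lapply(sample(which(sc$role == "canonical2"), 30),
    function(i) {
      r <- sc[i, ]
      type <- sample(c("novel_acc", "novel_don", "orphan", "badmotif",
                       "unknown_strand"), 1)
      if (type == "novel_acc") { r$end <- r$end - sample(5:40, 1) }
      if (type == "novel_don") { r$start <- r$start + sample(5:9, 1) }
      if (type == "orphan") { r$start <- r$start + 3; r$end <- r$end - 3 }
      if (type == "badmotif") { r$end <- r$end - sample(5:40, 1)
                                r$motif <- "other" }
      if (type == "unknown_strand") { r$end <- r$end - sample(5:40, 1)
                                      r$strand <- "*" }
      r$annotated <- 0L
      r
    }))
  keys <- paste(extra$chrom, extra$start, extra$end)
  extra <- extra[!duplicated(keys), ]
  ex_counts <- matrix(rpois(nrow(extra) * ncol(jcm$counts), 4),
                      nrow(extra), dimnames = list(NULL, colnames(jcm$counts)))
  big <- list(junctions = rbind(sc[, names(sc)], extra),
              counts = rbind(jcm$counts, ex_counts),
              samples = jcm$samples)
  rownames(big$counts) <- NULL

  f <- classify_and_filter(big, sh$index, min_total = 20)
  keep_oracle <- oracle_filter_keep(big$junctions, rowSums(big$counts),
                                    sh$index, 20)
  got <- paste(f$junctions$chrom, f$junctions$start, f$junctions$end)
  want <- paste(big$junctions$chrom, big$junctions$start,
                big$junctions$end)[keep_oracle]
  expect_setequal(got, want)

  # a junction with 19 total reads is removed
  expect_true(all(f$junctions$total >= 20))
  # novel_acceptor semantics
  na <- f$junctions[f$junctions$status == "novel_acceptor", ]
  expect_true(all(paste(na$chrom, na$strand, na$donor, sep = ":") %in%
                    sh$index$donors))
  expect_false(any(paste(na$chrom, na$strand, na$acceptor, sep = ":") %in%
                     sh$index$acceptors))
  # raising the cutoff never adds junctions
  f50 <- classify_and_filter(big, sh$index, min_total = 50)
  k50 <- paste(f50$junctions$chrom, f50$junctions$start, f50$junctions$end)
  expect_true(all(k50 %in% got))
})
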