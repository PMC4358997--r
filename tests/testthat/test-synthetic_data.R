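# Synthetic data generator: planted structure, determinism, count laws.

test_that("degenerate cryptic fraction yields a truth table with no cryptic sites", {
  cfg <- sim_config(n_genes = 20, frac_cryptic_genes = 0, frac_latent = 0,
                    frac_silent = 0, seed = 7)
  sim <- generate_genome_and_annotation(cfg)
  expect_true(all(is.na(sim$truth$cryptic_acceptor)))
  expect_true(all(sim$truth$class == "control"))
})

test_that("the same seed reproduces genome, annotation and counts byte-for-byte", {
  cfg <- sim_config(n_genes = 15, seed = 99)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  for (d in c(d1, d2)) {
    sim <- generate_genome_and_annotation(cfg)
    samples <- make_sample_sheet(cfg)
    jcm <- simulate_junction_counts(sim, samples, cfg)
    write_simulation(sim, jcm, d)
  }
  for (f in c("genome.fa", "truth.tsv", "samples.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # GTF lines identical apart from the date comment header
  g1 <- grep("^#", readLines(file.path(d1, "annotation.gtf")),
             value = TRUE, invert = TRUE)
  g2 <- grep("^#", readLines(file.path(d2, "annotation.gtf")),
             value = TRUE, invert = TRUE)
  expect_identical(g1, g2)
  sj1 <- list.files(file.path(d1, "sj"), full.names = TRUE)
  sj2 <- list.files(file.path(d2, "sj"), full.names = TRUE)
  expect_identical(lapply(sj1, readLines), lapply(sj2, readLines))
})

test_that("fixed offset and BP distance are recoverable by rescanning emitted sequences", {
  cfg <- sim_config(n_genes = 30, frac_cryptic_genes = 1, frac_latent = 0,
                    frac_silent = 0,
                    bp_distance_range = c(15, 15),
                    cryptic_offset_range = c(18, 18), seed = 3)
  sim <- generate_genome_and_annotation(cfg)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    seq <- Biostrings::subseq(sim$genome[[tr$chrom[i]]],
                              tr$canonical_start[i], tr$canonical_end[i])
    if (tr$strand[i] == "-") seq <- Biostrings::reverseComplement(seq)
    s <- strsplit(as.character(seq), "")[[1]]
    L <- length(s)
    # canonical intron ends in AG
    expect_identical(s[(L - 1):L], c("A", "G"))
    # exactly one additional AG, ending 18 bases upstream of the intron end
    ag_g <- which(s == "G" & c("", s[-L]) == "A")
    extra <- setdiff(ag_g, L)
    expect_length(extra, 1)
    expect_equal(L - extra, 18)
    # planted adenine 15 bases from the cryptic 3'SS in the
    # first-exonic-base convention: position (extra + 1) - 15
    bp_pos <- extra + 1 - 15
    expect_identical(s[bp_pos], "A")
    # and the truth table's genomic BP coordinate maps to that base
    bp_tx <- if (tr$strand[i] == "-") tr$canonical_end[i] - tr$bp_pos[i] + 1
             else tr$bp_pos[i] - tr$canonical_start[i] + 1
    expect_equal(bp_tx, bp_pos)
  }
})

test_that("control introns never carry an AG 10-30 bp upstream of the 3'SS", {
  sh <- get_shared_sim()
  tr <- sh$sim$truth
  ctl <- tr[tr$class == "control", ]
  for (i in seq_len(nrow(ctl))) {
    seq <- Biostrings::subseq(sh$sim$genome[[ctl$chrom[i]]],
                              ctl$canonical_start[i], ctl$canonical_end[i])
    if (ctl$strand[i] == "-") seq <- Biostrings::reverseComplement(seq)
    s <- strsplit(as.character(seq), "")[[1]]
    L <- length(s)
    ag_g <- which(s == "G" & c("", s[-L]) == "A")
    offs <- L - ag_g
    expect_false(any(offs >= 10 & offs <= 30))
  }
})

test_that("emitted SJ motifs match the genome's intron-terminal dinucleotides", {
  sh <- get_shared_sim()
  sc <- sh$jcm$junctions
  idx <- sample(seq_len(nrow(sc)), 40)
  for (i in idx) {
    five <- as.character(Biostrings::subseq(sh$sim$genome[[sc$chrom[i]]],
                                            sc$start[i], sc$start[i] + 1))
    three <- as.character(Biostrings::subseq(sh$sim$genome[[sc$chrom[i]]],
                                             sc$end[i] - 1, sc$end[i]))
    expect_identical(paste0(five, "/", three), sc$motif[i])
  }
})

test_that("count laws hold: zero psi, bounds, and the binomial large-sample mean", {
  cfg <- sim_config(n_genes = 5, n_mut = 100, n_wt = 100,
                    frac_cryptic_genes = 1, frac_latent = 0, frac_silent = 0,
                    psi_mut = 0, psi_wt = 0, seed = 12)
  sim <- generate_genome_and_annotation(cfg)
  samples <- make_sample_sheet(cfg)
  jcm <- simulate_junction_counts(sim, samples, cfg)
  cr <- jcm$junctions$role == "cryptic"
  expect_true(all(jcm$counts[cr, ] == 0))
  expect_true(all(jcm$counts >= 0))

  # rho -> 0, psi = 0.5, deep coverage: mean cryptic fraction near 0.5
  cfg2 <- sim_config(n_genes = 1, n_mut = 100, n_wt = 100,
                     frac_cryptic_genes = 1, frac_latent = 0,
                     frac_silent = 0, psi_mut = 0.5, psi_wt = 0.5,
                     overdispersion = 1e-9, mean_gene_depth = 10000,
                     seed = 13)
  sim2 <- generate_genome_and_annotation(cfg2)
  jcm2 <- simulate_junction_counts(sim2, make_sample_sheet(cfg2), cfg2)
  ro <- jcm2$junctions$role
  tot <- jcm2$counts[ro == "cryptic", ] + jcm2$counts[ro == "canonical2", ]
  frac <- jcm2$counts[ro == "cryptic", ] / tot
  expect_lt(abs(mean(frac) - 0.5), 0.01)
})

test_that("pooled mutant PSI reflects the planted usage fraction at depth 200", {
  cfg <- sim_config(n_genes = 60, n_mut = 8, n_wt = 8,
                    frac_cryptic_genes = 1, frac_latent = 0, frac_silent = 0,
                    psi_mut = 0.08, psi_wt = 0.003, mean_gene_depth = 200,
                    seed = 17)
  sim <- generate_genome_and_annotation(cfg)
  samples <- make_sample_sheet(cfg)
  jcm <- simulate_junction_counts(sim, samples, cfg)
  mut <- samples$condition == "mut"
  ro <- jcm$junctions$role
  c_mut <- rowSums(jcm$counts[ro == "cryptic", mut])
  a_mut <- rowSums(jcm$counts[ro == "canonical2", mut])
  pooled <- sum(c_mut) / sum(c_mut + a_mut)
  expect_gt(pooled, 0.06)
  expect_lt(pooled, 0.10)
})

test_that("impossible window configurations are rejected", {
  expect_error(sim_config(cryptic_offset_range = c(10, 40),
                          bp_distance_range = c(13, 17)),
               "coexist")
  expect_error(sim_config(psi_mut = 0.1, psi_wt = 0.2), "psi")
  expect_error(simulate_junction_counts(
    generate_genome_and_annotation(sim_config(n_genes = 2, seed = 1)),
    data.frame(sample = "S1", condition = "weird", cancer_type = "A",
               size_factor = 1),
    sim_config(n_genes = 2, seed = 1)),
    "unknown condition")
})
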