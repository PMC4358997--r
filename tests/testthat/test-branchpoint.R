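# Branch-point scoring, distance conventions, controls and the screen.

test_that("a unique perfect-consensus heptamer is the top call", {
  # pyrimidine 50-mer with one consensus-core heptamer whose adenine sits
  # at position 26; the terminal AG's adenine is inside min_dist
  tail <- paste0(strrep("C", 20), "TTCTTAC", strrep("T", 21), "AG")
  calls <- score_branchpoints(tail)
  expect_gt(nrow(calls), 0)
  expect_equal(calls$pos[calls$rank == 1], 26)
  expect_equal(calls$d_bp[calls$rank == 1], nchar(tail) + 1 - 26)
})

test_that("an adenine-free tail yields no calls", {
  expect_equal(nrow(score_branchpoints(strrep("CT", 25))), 0)
  expect_message(out <- score_branchpoints("ACGT"), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("ranking equals an exhaustive scan on random 50-mers", {
  set.seed(11)
  model <- bp_scoring_model()
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE,
                      prob = c(0.2, 0.3, 0.2, 0.3)), collapse = "")
    calls <- score_branchpoints(s, model)
    want <- oracle_bp_scan(s, model$pwm, model$background, model$min_dist)
    if (is.null(want)) {
      expect_equal(nrow(calls), 0)
    } else {
      expect_equal(calls$pos, want$pos)
      expect_equal(calls$score, want$score, tolerance = 1e-12)
    }
  }
})

test_that("BP distance is measured to the first exonic base", {
  expect_equal(bp_to_3ss_distance(486, 500, "+"), 15L)
  # the adenine of the acceptor's own AG: distance 2
  expect_equal(bp_to_3ss_distance(499, 500, "+"), 2L)
  # mirrored on the minus strand (acceptor at intron start)
  expect_equal(bp_to_3ss_distance(515, 501, "-"), 15L)
  expect_equal(bp_to_3ss_distance(502, 501, "-"), 2L)
})

test_that("fallback substitutes the second-ranked call outside the window", {
  calls <- data.frame(pos = c(460, 486), rank = c(1, 2))
  expect_equal(bp_distance_with_fallback(calls, 500, "+"),
               list(distance = 15L, rank = 2L))
  in_win <- data.frame(pos = 486, rank = 1)
  expect_equal(bp_distance_with_fallback(in_win, 500, "+"),
               list(distance = 15L, rank = 1L))
  only_bad <- data.frame(pos = 460, rank = 1)
  expect_equal(bp_distance_with_fallback(only_bad, 500, "+"),
               list(distance = 41L, rank = 1L))
  expect_null(bp_distance_with_fallback(NULL, 500, "+"))
})

test_that("control AG distances exclude the last 10 intron bases", {
  # planted: heptamer then one AG 25 bp from the BP-convention origin, and
  # one AG inside the last 10 bases
  L <- 80
  s <- rep("C", L)
  s[1:2] <- c("G", "T"); s[(L - 1):L] <- c("A", "G")
  bp_pos <- L + 1 - 40
  s[(bp_pos - 5):(bp_pos + 1)] <- c("T", "T", "C", "T", "C", "A", "T")
  ag_a <- L + 1 - 25  # contributes distance 25 - (L+1-40) + ... see below
  s[ag_a] <- "A"; s[ag_a + 1] <- "G"
  s[L - 5] <- "A"; s[L - 4] <- "G"   # inside last 10: never counted
  ctl <- data.frame(chrom = "c1", start = 1, end = L, strand = "+")
  genome <- Biostrings::DNAStringSet(c(c1 = paste(s, collapse = "")))
  d <- control_ag_distances(ctl, genome)
  # distance from planted BP to the AG's first downstream base
  expect_equal(d, (ag_a + 2) - bp_pos)
  # an intron with no AG outside the excluded zone contributes nothing
  s2 <- s
  s2[ag_a] <- "C"; s2[ag_a + 1] <- "C"
  genome2 <- Biostrings::DNAStringSet(c(c1 = paste(s2, collapse = "")))
  expect_length(control_ag_distances(ctl, genome2), 0)
})

test_that("control selection applies the strict coverage rule and clean donors", {
  counts <- matrix(c(rep(150L, 8), rep(100L, 8), rep(150L, 8), rep(30L, 8)),
                   4, 8, byrow = TRUE)
  f <- make_fjcm(counts, gene_ids = paste0("g", 1:4),
                 conditions = rep(c("mut", "wt"), each = 4),
                 status = c("annotated", "annotated", "annotated",
                            "novel_acceptor"))
  # give the novel acceptor the same donor as junction 3
  f$junctions$donor[4] <- f$junctions$donor[3]
  ctl <- select_controls(f, min_mean_cov = 100)
  expect_equal(ctl$gene_id, "g1")   # g2 mean exactly 100; g3 dirty donor
})

test_that("the screen lists every planted cryptic intron with in-window geometry", {
  sh <- get_shared_sim()
  f <- classify_and_filter(sh$jcm, sh$index, min_total = 20)
  usage <- test_differential_usage(f)
  screen <- potential_cryptic_screen(f, usage, sh$sim$genome)
  tr <- sh$sim$truth
  planted <- tr[tr$class %in% c("cryptic", "latent"), ]
  # those whose canonical junction survived the coverage cutoff
  ck <- paste(planted$chrom, planted$canonical_start,
              planted$canonical_end, planted$strand, sep = ":")
  surv <- f$junctions[f$junctions$total >= 20, ]
  covered <- ck %in% paste(surv$chrom, surv$start, surv$end, surv$strand,
                           sep = ":")
  expect_true(all(ck[covered] %in% screen$junction))
  # and the screen's geometry columns match the planted parameters
  m <- match(ck[covered], screen$junction)
  expect_true(all(screen$d_bp[m] >= 13 & screen$d_bp[m] <= 17))
  expect_true(all(screen$offset[m] >= 10 & screen$offset[m] <= 30))
})

test_that("rank-sum comparison behaves as a rank statistic", {
  x <- c(1:20)
  expect_gt(compare_distance_distributions(x, x)$p.value, 0.9)
  expect_lt(compare_distance_distributions(1:20, 31:50)$p.value, 1e-6)
  a <- rnorm(30); b <- rnorm(30, 1)
  p1 <- compare_distance_distributions(a, b)$p.value
  p2 <- compare_distance_distributions(a + 100, b + 100)$p.value
  expect_equal(p1, p2)
  expect_error(compare_distance_distributions(numeric(0), 1:3), "non-empty")
})

test_that("PWM-drawn planted heptamers at fixed distance are recovered as rank 1", {
  cfg <- sim_config(n_genes = 60, frac_cryptic_genes = 1, frac_latent = 0,
                    frac_silent = 0, bp_distance_range = c(15, 15),
                    cryptic_offset_range = c(15, 15), seed = 23)
  sim <- generate_genome_and_annotation(cfg)
  tr <- sim$truth
  model <- bp_scoring_model()
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    introns <- data.frame(chrom = tr$chrom[i], start = tr$canonical_start[i],
                          end = tr$canonical_end[i], strand = tr$strand[i])
    calls <- score_intron_branchpoints(introns, sim$genome, model)[[1]]
    calls$pos[calls$rank == 1] == tr$bp_pos[i]
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
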