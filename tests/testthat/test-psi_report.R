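# PSI arithmetic, the high-PSI screen, and heatmap matrices.

test_that("PSI arithmetic identities hold", {
  expect_equal(compute_psi(5, 45), 0.10)
  expect_equal(compute_psi(0, 37), 0)
  expect_true(is.na(compute_psi(0, 0)))
  expect_error(compute_psi(-1, 5), "non-negative")
  # invariance under common scaling of both counts
  set.seed(16)
  c0 <- sample(0:50, 30, replace = TRUE)
  a0 <- sample(1:50, 30, replace = TRUE)
  expect_equal(compute_psi(c0, a0), compute_psi(7L * c0, 7L * a0))
})

make_pt <- function(psi_mut, psi_wt, depth, frame = "out_of_frame") {
  n_mut <- length(psi_mut); n_wt <- length(psi_wt)
  cr <- matrix(round(depth * c(psi_mut, psi_wt)), 1)
  ca <- matrix(round(depth * (1 - c(psi_mut, psi_wt))), 1)
  rec <- data.frame(junction = "j1", frame = frame)
  psi <- matrix(compute_psi(as.vector(cr), as.vector(ca)), 1,
                dimnames = list("j1", NULL))
  list(psi = psi, cryptic = cr, canonical = ca, records = rec)
}

test_that("the screen applies strict thresholds, coverage and frame rules", {
  cond <- rep(c("mut", "wt"), each = 5)
  # median mutant PSI exactly 0.5 is excluded (strict inequality)
  pt <- make_pt(rep(0.5, 5), rep(0.05, 5), depth = 100)
  expect_equal(nrow(high_psi_screen(pt, cond)), 0)
  pt2 <- make_pt(rep(0.7, 5), rep(0.05, 5), depth = 100)
  expect_equal(nrow(high_psi_screen(pt2, cond)), 1)
  # in-frame twin rejected when the frame requirement is on
  pt3 <- make_pt(rep(0.7, 5), rep(0.05, 5), depth = 100, frame = "in_frame")
  expect_equal(nrow(high_psi_screen(pt3, cond)), 0)
  expect_equal(nrow(high_psi_screen(pt3, cond,
                                    require_out_of_frame = FALSE)), 1)
  # insufficient mutant coverage rejected
  pt4 <- make_pt(rep(0.7, 5), rep(0.05, 5), depth = 20)
  expect_equal(nrow(high_psi_screen(pt4, cond)), 0)
})

test_that("the screen is monotone in its thresholds", {
  set.seed(17)
  cond <- rep(c("mut", "wt"), each = 6)
  psis <- runif(40, 0, 1)
  keep_counts <- vapply(c(0.3, 0.5, 0.7), function(mm) {
    n <- 0
    for (p in psis) {
      pt <- make_pt(rep(p, 6), rep(0.1, 6), depth = 100)
      n <- n + nrow(high_psi_screen(pt, cond, mut_min = mm))
    }
    n
  }, numeric(1))
  expect_true(all(diff(keep_counts) <= 0))
})

test_that("z-scoring normalizes by library size and flags flat rows", {
  counts <- rbind(c(10, 20), c(0, 0))
  z <- zscore_matrix(counts, lib_sizes = c(1e6, 2e6))
  # equal counts-per-million: zero variance row
  expect_equal(unname(z$z[1, ]), c(0, 0))
  expect_true(all(z$flat))
  counts2 <- rbind(c(10, 40, 10, 40))
  z2 <- zscore_matrix(counts2, rep(1e6, 4))
  expect_equal(mean(z2$z[1, ]), 0, tolerance = 1e-9)
  expect_equal(sd(z2$z[1, ]), 1, tolerance = 1e-9)
})

test_that("relative expression scales each gene to a maximum of exactly 1", {
  expr <- rbind(g1 = c(10, 10, 5, 5, 2.5, 2.5), g2 = rep(4, 6),
                g3 = rep(0, 6))
  labs <- rep(c("CLL", "BRCA", "UM"), each = 2)
  rel <- relative_expression_matrix(expr, labs)
  expect_equal(unname(rel$rel["g1", ]), c(1, 0.5, 0.25))
  expect_equal(unname(rel$rel["g2", ]), c(1, 1, 1))
  expect_equal(unname(rel$rel["g3", ]), c(0, 0, 0))
  expect_true(rel$zero["g3"])
  # group-by oracle on random tables
  set.seed(18)
  ex <- matrix(runif(60, 0.1, 5), 10, 6)
  rel2 <- relative_expression_matrix(ex, labs)$rel
  for (g in 1:10) {
    mm <- tapply(ex[g, ], labs, mean)[colnames(rel2)]
    expect_equal(unname(rel2[g, ]), as.numeric(mm / max(mm)),
                 tolerance = 1e-12)
  }
  expect_equal(unname(apply(rel2, 1, max)), rep(1, 10))
})

test_that("clustering places identical rows adjacently and is permutation-stable", {
  m <- rbind(a = c(0, 0, 0), b = c(5, 5, 5), c = c(0, 0, 0))
  ord <- cluster_order(m, "complete")
  pos <- match(c("a", "c"), rownames(m)[ord$row_order])
  expect_equal(abs(diff(pos)), 1)
  set.seed(19)
  m2 <- matrix(rnorm(40), 8, 5,
               dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
  o1 <- cluster_order(m2, "complete")
  perm <- sample(8)
  o2 <- cluster_order(m2[perm, ], "complete")
  part1 <- cutree(o1$row_hclust, k = 3)
  part2 <- cutree(o2$row_hclust, k = 3)[rownames(m2)]
  # same partition structure up to label renaming
  expect_equal(length(unique(paste(part1, part2))), 3)
  # degenerate single-row input keeps identity order
  expect_equal(cluster_order(m2[1, , drop = FALSE])$row_order, 1)
})

test_that("mutant samples score higher on planted cryptic junctions", {
  sh <- get_shared_sim()
  tr <- sh$sim$truth
  ro <- sh$jcm$junctions$role
  cr_counts <- sh$jcm$counts[ro == "cryptic", , drop = FALSE]
  planted <- sh$jcm$junctions$gene_id[ro == "cryptic"] %in%
    tr$gene_id[tr$class == "cryptic"]
  z <- zscore_matrix(cr_counts[planted, , drop = FALSE],
                     sh$jcm$samples$lib_size)
  mut <- sh$jcm$samples$condition == "mut"
  expect_gt(mean(z$z[, mut]), mean(z$z[, !mut]))
})
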