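#' Build a sample sheet for the simulator
#'
#' Mutant and wild-type samples with cancer-type labels assigned round-robin
#' within each condition (a balanced covariate for the usage test) and
#' log-normal library-size factors.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns sample, condition (`mut`/`wt`),
#'   cancer_type, size_factor.
#' @export
make_sample_sheet <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 3L))
  n <- config$n_mut + config$n_wt
  cond <- rep(c("mut", "wt"), c(config$n_mut, config$n_wt))
  cancer <- unlist(lapply(c(config$n_mut, config$n_wt), function(k)
    rep_len(config$cancer_types, k)))
  data.frame(
    sample = sprintf("S%02d_%s", seq_len(n), cond),
    condition = cond,
    cancer_type = cancer,
    size_factor = rlnorm(n, 0, config$libsize_sdlog),
    stringsAsFactors = FALSE)
}

# beta-binomial draw with mean `mu` and intra-class correlation `rho`
rbetabinom <- function(m, size, mu, rho) {
  out <- integer(m)
  pos <- size > 0 & mu > 0
  mu <- rep_len(mu, m)
  if (rho <= 1e-12) {
    out[pos] <- rbinom(sum(pos), size[pos], mu[pos])
  } else if (any(pos)) {
    a <- mu[pos] * (1 - rho) / rho
    b <- (1 - mu[pos]) * (1 - rho) / rho
    p <- rbeta(sum(pos), a, b)
    out[pos] <- rbinom(sum(pos), size[pos], p)
  }
  out
}

#' Simulate junction-spanning read counts
#'
#' For each sample and intron the total depth is negative-binomial with mean
#' `mean_gene_depth` scaled by the sample's library-size factor and size
#' `depth_dispersion`. For introns carrying a cryptic AG, the cryptic
#' junction count is beta-binomial given the total with the
#' condition-specific usage fraction (psi) and overdispersion rho; the
#' canonical junction receives the remainder.
#'
#' @param sim output of [generate_genome_and_annotation()].
#' @param samples a sample sheet from [make_sample_sheet()].
#' @param config a [sim_config()].
#' @return a junction count matrix: list with `junctions` (the scaffold
#'   rows), `counts` (junctions x samples integer matrix), `samples`
#'   (sample sheet with library sizes appended).
#' @export
simulate_junction_counts <- function(sim, samples, config) {
  validate_sim_config(config)
  if (!all(samples$condition %in% c("mut", "wt")))
    stop("unknown condition label in sample sheet: ",
         paste(setdiff(samples$condition, c("mut", "wt")), collapse = ", "))
  set.seed(derive_seed(config$seed, 4L))
  truth <- sim$truth
  sc <- sim$scaffold
  n_s <- nrow(samples)
  counts <- matrix(0L, nrow(sc), n_s,
                   dimnames = list(junction_key(sc$chrom, sc$start, sc$end,
                                                sc$strand),
                                   samples$sample))
  for (g in seq_len(nrow(truth))) {
    rows <- which(sc$gene_id == truth$gene_id[g])
    role <- sc$role[rows]
    psi <- ifelse(samples$condition == "mut", truth$psi_mut[g],
                  truth$psi_wt[g])
    mu <- config$mean_gene_depth * samples$size_factor
    t1 <- rnbinom(n_s, size = config$depth_dispersion, mu = mu)
    t2 <- rnbinom(n_s, size = config$depth_dispersion, mu = mu)
    counts[rows[role == "canonical1"], ] <- t1
    if (any(role == "cryptic")) {
      cr <- rbetabinom(n_s, t2, psi, config$overdispersion)
      counts[rows[role == "cryptic"], ] <- cr
      counts[rows[role == "canonical2"], ] <- t2 - cr
    } else {
      counts[rows[role == "canonical2"], ] <- t2
    }
  }
  samples$lib_size <- colSums(counts)
  list(junctions = sc, counts = counts, samples = samples)
}

#' Write a simulated data set to disk
#'
#' Emits the genome FASTA, the GTF annotation, one SJ-format table per
#' sample (only junctions with at least one read, as an aligner would
#' report), the sample sheet, the truth table, and a per-gene expression
#' table (total junction-spanning reads per gene and sample).
#'
#' @param sim output of [generate_genome_and_annotation()].
#' @param jcm output of [simulate_junction_counts()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
write_simulation <- function(sim, jcm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv"),
    expression = file.path(dir, "gene_expression.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  rtracklayer::export(sim$annotation, paths$gtf, format = "gtf")
  write_tsv(jcm$samples, paths$samples)
  write_tsv(sim$truth, paths$truth)

  expr <- rowsum(jcm$counts, jcm$junctions$gene_id)
  write_tsv(data.frame(gene_id = rownames(expr), expr,
                       check.names = FALSE), paths$expression)

  sj_dir <- file.path(dir, "sj")
  dir.create(sj_dir, showWarnings = FALSE)
  paths$sj_dir <- sj_dir
  sc <- jcm$junctions
  strand_code <- ifelse(sc$strand == "+", 1L, ifelse(sc$strand == "-", 2L, 0L))
  motif_code <- match(sc$motif, SJ_MOTIFS) - 1L
  for (i in seq_len(ncol(jcm$counts))) {
    keep <- jcm$counts[, i] > 0
    tab <- data.frame(
      chrom = sc$chrom[keep], start = sc$start[keep], end = sc$end[keep],
      strand = strand_code[keep], motif = motif_code[keep],
      annotated = sc$annotated[keep],
      unique_reads = jcm$counts[keep, i], multi_reads = 0L, overhang = 30L)
    write.table(tab, file.path(sj_dir, paste0(colnames(jcm$counts)[i],
                                              ".SJ.out.tab")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(paths)
}
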