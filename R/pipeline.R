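## End-to-end orchestration: simulate -> classify -> test -> annotate ->
## branchpoint -> composition -> psi, with a manifest and summary report.

#' Default pipeline configuration
#'
#' Every published threshold is the default: coverage cutoff 20 reads
#' summed over samples, significance at BH-adjusted q < 0.1, proximal
#' window 10-30 bp upstream, BP window 13-17 bp with minimum BP distance
#' 8, control mean coverage > 100, PSI screen at median mutant PSI > 0.5,
#' wild-type < 0.2, mean mutant coverage >= 30.
#'
#' @param out_dir output directory.
#' @param seed global seed.
#' @param scope `"joint"` or `"per_cancer"` (junction filters and tests are
#'   recomputed separately for each analysis scope).
#' @param sim NULL, or a list of [sim_config()] arguments to generate the
#'   inputs; otherwise `genome`, `gtf`, `sj_dir`, `samples` paths must be
#'   given.
#' @param ... path or threshold overrides (min_total, alpha, bp_window,
#'   control_min_cov, screen thresholds, genome, gtf, sj_dir, samples,
#'   truth).
#' @return configuration list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, scope = "joint",
                            sim = NULL, ...) {
  cfg <- list(out_dir = out_dir, seed = seed, scope = scope, sim = sim,
              genome = NULL, gtf = NULL, sj_dir = NULL, samples = NULL,
              truth = NULL,
              min_total = 20, alpha = 0.1,
              bp_window = c(13L, 17L), min_bp_dist = 8L,
              control_min_cov = 100,
              screen_mut_min = 0.5, screen_wt_max = 0.2,
              screen_min_mut_cov = 30, screen_out_of_frame = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full cryptic 3'SS analysis pipeline
#'
#' @param config a [pipeline_config()] list, or the path to a YAML file of
#'   the same fields.
#' @return invisibly, a list with per-scope results, the manifest, and the
#'   summary table; all stage outputs are written as TSV under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$sim)) {
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    model <- bp_scoring_model(min_dist = config$min_bp_dist)
    sim <- generate_genome_and_annotation(scfg, model)
    samples <- make_sample_sheet(scfg)
    jcm0 <- simulate_junction_counts(sim, samples, scfg)
    paths <- write_simulation(sim, jcm0, file.path(config$out_dir, "sim"))
    config$genome <- paths$genome
    config$gtf <- paths$gtf
    config$sj_dir <- paths$sj_dir
    config$samples <- paths$samples
    config$truth <- paths$truth
    config$expression <- paths$expression
  }
  for (p in c("genome", "gtf", "sj_dir", "samples")) {
    if (is.null(config[[p]]) || !file.exists(config[[p]]))
      abort_stage("input", paste0("missing input: ", p))
  }

  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  index <- build_annotation_index(config$gtf)
  samples <- read_tsv(config$samples)
  jcm <- read_junction_counts(config$sj_dir, samples)
  truth <- if (!is.null(config$truth) && file.exists(config$truth))
    read_tsv(config$truth) else NULL

  scopes <- if (identical(config$scope, "per_cancer"))
    split(seq_len(nrow(samples)), samples$cancer_type)
  else list(joint = seq_len(nrow(samples)))

  results <- lapply(names(scopes), function(sc) {
    idx <- scopes[[sc]]
    sub <- list(junctions = jcm$junctions,
                counts = jcm$counts[, idx, drop = FALSE],
                samples = jcm$samples[idx, , drop = FALSE])
    run_scope(sub, index, genome, config, sc, truth)
  })
  names(results) <- names(scopes)

  manifest <- build_manifest(config, results)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  summary <- summary_report(list(results = results, manifest = manifest,
                                 truth = truth, config = config))
  write_tsv(summary, file.path(config$out_dir, "summary.tsv"))
  invisible(list(results = results, manifest = manifest, truth = truth,
                 summary = summary, config = config))
}

# one analysis scope: filters and tests recomputed on this sample subset
run_scope <- function(jcm, index, genome, config, scope_name, truth) {
  out_dir <- file.path(config$out_dir, scope_name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- bp_scoring_model(min_dist = config$min_bp_dist)

  fjcm <- classify_and_filter(jcm, index, min_total = config$min_total)
  usage <- test_differential_usage(fjcm, alpha = config$alpha)
  write_tsv(usage, file.path(out_dir, "usage.tsv"))

  records <- build_cryptic_records(usage, index)
  write_tsv(records, file.path(out_dir, "cryptic_sites.tsv"))
  sig <- records[!is.na(records$q) & records$q < config$alpha &
                   records$direction == "higher_in_mut", , drop = FALSE]

  # branch points for the canonical introns of significant records
  chosen <- choose_one_per_canonical(sig, seed = config$seed)
  bp <- NULL
  if (nrow(chosen) > 0) {
    canon <- unique(data.frame(chrom = chosen$chrom,
                               start = chosen$canonical_start,
                               end = chosen$canonical_end,
                               strand = chosen$strand,
                               stringsAsFactors = FALSE))
    calls <- score_intron_branchpoints(canon, genome, model)
    ck <- junction_key(chosen$chrom, chosen$canonical_start,
                       chosen$canonical_end, chosen$strand)
    bp <- do.call(rbind, lapply(seq_len(nrow(chosen)), function(i) {
      cl <- calls[[ck[i]]]
      if (is.null(cl) || nrow(cl) == 0) return(NULL)
      d1 <- bp_to_3ss_distance(cl$pos[cl$rank == 1],
                               chosen$novel_acceptor[i], chosen$strand[i])
      fb <- bp_distance_with_fallback(cl, chosen$novel_acceptor[i],
                                      chosen$strand[i], config$bp_window)
      dc <- bp_to_3ss_distance(cl$pos[cl$rank == 1],
                               chosen$canonical_acceptor[i],
                               chosen$strand[i])
      data.frame(junction = chosen$junction[i], canonical = ck[i],
                 d_bp_rank1 = d1, d_bp_used = fb$distance,
                 rank_used = fb$rank, d_bp_canonical = dc,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(bp))
    bp <- data.frame(junction = character(), canonical = character(),
                     d_bp_rank1 = integer(), d_bp_used = integer(),
                     rank_used = integer(), d_bp_canonical = integer())
  write_tsv(bp, file.path(out_dir, "bp_distances.tsv"))

  controls <- select_controls(fjcm, min_mean_cov = config$control_min_cov)
  ctrl_ag <- control_ag_distances(controls, genome, model)
  write_tsv(data.frame(d_bp = ctrl_ag),
            file.path(out_dir, "control_ag_distances.tsv"))
  ctrl_bp <- score_intron_branchpoints(controls, genome, model)
  ctrl_d3 <- vapply(seq_len(nrow(controls)), function(i) {
    cl <- ctrl_bp[[i]]
    if (nrow(cl) == 0) return(NA_integer_)
    bp_to_3ss_distance(cl$pos[cl$rank == 1],
                       acceptor_of(controls$start[i], controls$end[i],
                                   controls$strand[i]),
                       controls$strand[i])
  }, integer(1))
  ctrl_d3 <- ctrl_d3[!is.na(ctrl_d3)]

  tests <- list()
  if (nrow(bp) > 0 && length(ctrl_ag) > 0)
    tests$cryptic_vs_control_ag <-
      compare_distance_distributions(bp$d_bp_rank1, ctrl_ag)
  if (nrow(bp) > 0 && length(ctrl_d3) > 0)
    tests$canonical_vs_control_3ss <-
      compare_distance_distributions(bp$d_bp_canonical, ctrl_d3)

  screen <- potential_cryptic_screen(fjcm, usage, genome, model,
                                     coverage_cutoff = config$min_total,
                                     bp_window = config$bp_window,
                                     alpha = config$alpha)
  write_tsv(screen, file.path(out_dir, "potential_cryptic_screen.tsv"))

  # composition: control vs associated canonical vs proximal cryptic tails
  composition <- NULL
  prox <- sig[sig$locality == "proximal", , drop = FALSE]
  if (nrow(controls) > 0) {
    ctrl_prof <- tail_frequency_matrix(controls, genome)
    composition <- list(control = ctrl_prof)
    if (nrow(prox) > 0) {
      canon_prof <- tail_frequency_matrix(
        data.frame(chrom = prox$chrom,
                   start = prox$canonical_start, end = prox$canonical_end,
                   strand = prox$strand), genome)
      cryp_prof <- tail_frequency_matrix(
        data.frame(chrom = prox$chrom,
                   start = prox$novel_start, end = prox$novel_end,
                   strand = prox$strand), genome)
      composition$canonical <- canon_prof
      composition$cryptic <- cryp_prof
      composition$enrich_canonical <- adenine_enrichment(canon_prof, ctrl_prof)
      composition$enrich_cryptic <- adenine_enrichment(cryp_prof, ctrl_prof)
      write_tsv(composition$enrich_cryptic,
                file.path(out_dir, "adenine_enrichment_cryptic.tsv"))
    }
  }

  # PSI and heatmap matrices for significant proximal sites
  psi_res <- NULL
  if (nrow(prox) > 0) {
    pt <- psi_table(prox, fjcm)
    hits <- high_psi_screen(pt, fjcm$samples$condition,
                            mut_min = config$screen_mut_min,
                            wt_max = config$screen_wt_max,
                            min_mut_cov = config$screen_min_mut_cov,
                            require_out_of_frame = config$screen_out_of_frame)
    write_tsv(data.frame(junction = rownames(pt$psi), pt$psi,
                         check.names = FALSE),
              file.path(out_dir, "psi.tsv"))
    write_tsv(hits, file.path(out_dir, "high_psi_hits.tsv"))
    z <- zscore_matrix(pt$cryptic, fjcm$samples$lib_size)
    ord <- if (nrow(z$z) > 1) cluster_order(z$z, "complete") else NULL
    psi_res <- list(psi = pt, hits = hits, z = z, order = ord)
  }

  list(scope = scope_name, fjcm = fjcm, usage = usage, records = records,
       sig = sig, chosen = chosen, bp = bp, controls = controls,
       control_ag = ctrl_ag, control_d3 = ctrl_d3, tests = tests,
       screen = screen, composition = composition, psi = psi_res)
}

build_manifest <- function(config, results) {
  cfg_path <- file.path(config$out_dir, "config.yaml")
  cfg_serializable <- config[!vapply(config, is.function, logical(1))]
  yaml::write_yaml(cfg_serializable, cfg_path)
  list(
    package_version = as.character(packageVersion("cryptsplice")),
    seed = config$seed,
    config_hash = unname(md5sum(cfg_path)),
    scopes = lapply(results, function(r) list(
      scope = r$scope,
      n_junctions = nrow(r$fjcm$junctions),
      n_tested = sum(r$usage$tested),
      n_significant = sum(!is.na(r$usage$q) & r$usage$q < config$alpha),
      n_novel_acceptor = sum(r$records$direction == "higher_in_mut" &
                               !is.na(r$records$q), na.rm = TRUE),
      n_controls = nrow(r$controls))))
}

#' Summary report of a pipeline run
#'
#' Counts of tested and significant junctions, novel 3'SSs, the
#' proximal/distal and direction splits, the out-of-frame fraction, screen
#' tiers, and -- when a truth table is available -- planted-site recovery
#' metrics (sensitivity, empirical FDR, proximal fraction and out-of-frame
#' calibration of recovered sites).
#'
#' @param run result of [run_pipeline()] (or a list with `results`,
#'   `truth`, `config`).
#' @return data.frame with scope, metric, value.
#' @export
summary_report <- function(run) {
  cfg <- run$config
  rows <- list()
  add <- function(scope, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(scope = scope, metric = metric,
                                             value = value)
  for (r in run$results) {
    sc <- r$scope
    alpha <- cfg$alpha
    add(sc, "n_tested", sum(r$usage$tested))
    sig_all <- !is.na(r$usage$q) & r$usage$q < alpha
    add(sc, "n_significant", sum(sig_all))
    add(sc, "n_novel_3ss", nrow(r$records))
    sigrec <- r$sig
    add(sc, "n_sig_novel_3ss_mut", nrow(sigrec))
    add(sc, "n_proximal", sum(sigrec$locality == "proximal"))
    add(sc, "n_distal", sum(sigrec$locality == "distal"))
    add(sc, "out_of_frame_fraction",
        if (nrow(sigrec)) mean(sigrec$frame == "out_of_frame") else NA)
    add(sc, "n_controls", nrow(r$controls))
    add(sc, "screen_potential_introns",
        length(unique(r$screen$junction)))
    add(sc, "screen_covered", sum(r$screen$cryptic_covered))
    add(sc, "screen_significant", sum(r$screen$cryptic_significant))
    if (!is.null(r$psi))
      add(sc, "high_psi_hits", nrow(r$psi$hits))
    if (!is.null(r$tests$cryptic_vs_control_ag))
      add(sc, "ranksum_p_cryptic_vs_control_ag",
          r$tests$cryptic_vs_control_ag$p.value)
    if (!is.null(r$tests$canonical_vs_control_3ss))
      add(sc, "ranksum_p_canonical_vs_control_3ss",
          r$tests$canonical_vs_control_3ss$p.value)

    if (!is.null(run$truth)) {
      rec <- recovery_metrics(r, run$truth, alpha)
      for (m in names(rec)) add(sc, m, rec[[m]])
    }
  }
  do.call(rbind, rows)
}

# planted-site recovery against the simulator truth table
recovery_metrics <- function(r, truth, alpha = 0.1) {
  planted <- truth[truth$class == "cryptic", , drop = FALSE]
  pk <- cryptic_truth_keys(planted)
  called <- r$sig$junction
  n_rec <- sum(pk %in% called)
  rec_rows <- r$sig[r$sig$junction %in% pk, , drop = FALSE]
  planted_frame <- mean(planted$frame == "out_of_frame")
  rec_frame <- if (nrow(rec_rows)) mean(rec_rows$frame == "out_of_frame") else NA
  list(
    n_planted = nrow(planted),
    n_recovered = n_rec,
    sensitivity = if (nrow(planted)) n_rec / nrow(planted) else NA,
    empirical_fdr = if (length(called))
      sum(!(called %in% pk)) / length(called) else 0,
    recovered_proximal_fraction = if (nrow(rec_rows))
      mean(rec_rows$locality == "proximal") else NA,
    planted_out_of_frame = planted_frame,
    recovered_out_of_frame = rec_frame)
}

# junction keys of the planted cryptic junctions in a truth table
cryptic_truth_keys <- function(truth) {
  ifelse(truth$strand == "-",
         junction_key(truth$chrom, truth$cryptic_acceptor,
                      truth$canonical_end, truth$strand),
         junction_key(truth$chrom, truth$canonical_start,
                      truth$cryptic_acceptor, truth$strand))
}
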