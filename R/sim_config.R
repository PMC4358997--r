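#' Configuration for the synthetic splice-junction simulator
#'
#' Collects the generative parameters for [generate_genome_and_annotation()]
#' and [simulate_junction_counts()]. The simulator emits genes with three
#' exons and two introns; the last intron of each gene carries a planted
#' branch-point (BP) heptamer, a polypyrimidine tract and, for a configurable
#' fraction of genes, a single cryptic AG dinucleotide at a planted offset
#' upstream of the canonical 3' splice site.
#'
#' Gene classes drawn from the class fractions:
#' \describe{
#'   \item{cryptic}{carries a cryptic AG; cryptic usage fraction is
#'     `psi_mut` in mutants and `psi_wt` in wild-types (the differential
#'     sites the pipeline should recover).}
#'   \item{latent}{carries a cryptic AG used at the same low fraction
#'     `psi_latent` in both conditions (expressed but not differential).}
#'   \item{silent}{carries a cryptic AG that is never used (no cryptic
#'     junction reads), exercising the coverage tier of the sufficiency
#'     screen.}
#'   \item{control}{no cryptic AG; a fraction `decoy_ag_frac` of these
#'     receive a longer BP spacing and one decoy intronic AG well upstream
#'     of the canonical 3'SS, providing the null AG-distance distribution.}
#' }
#'
#' @param n_genes number of genes (one per chromosome).
#' @param n_mut,n_wt samples per condition.
#' @param cancer_types character vector of cancer-type labels, assigned
#'   round-robin within each condition.
#' @param frac_cryptic_genes fraction of genes given a differential cryptic
#'   3'SS.
#' @param frac_latent,frac_silent fractions of the remaining classes (see
#'   Details).
#' @param psi_mut,psi_wt mean cryptic usage fraction (PSI) per condition for
#'   cryptic genes; must satisfy `0 <= psi_wt <= psi_mut <= 1`.
#' @param psi_latent shared PSI of latent genes.
#' @param overdispersion beta-binomial intra-class correlation rho in [0, 1).
#' @param mean_gene_depth expected junction-spanning reads per intron per
#'   sample before library-size scaling.
#' @param depth_dispersion negative-binomial size parameter for per-intron
#'   depth.
#' @param bp_distance_range integer range (length 2) of planted distances
#'   from the BP adenine to the cryptic 3'SS, in the first-exonic-base
#'   convention (default 13-17 bp).
#' @param cryptic_offset_range integer range of planted cryptic-AG offsets,
#'   i.e. how many bases upstream of the canonical intron end the cryptic AG
#'   ends (default 10-30 bp).
#' @param noncryptic_bp_range BP-to-3'SS distance range for introns without
#'   a cryptic AG (typical spacing, default 21-30 bp).
#' @param decoy_ag_frac fraction of control genes given a decoy AG.
#' @param decoy_bp_range BP distance range for decoy-carrying introns; must
#'   leave room for an AG more than 30 bp upstream of the intron end and
#'   still downstream of the BP.
#' @param intron_length,exon_length lengths of simulated introns and exons.
#' @param libsize_sdlog log-normal sd of library-size factors.
#' @param seed global integer seed; all stages derive independent streams
#'   from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300, n_mut = 8, n_wt = 8,
                       cancer_types = c("CLL", "BRCA"),
                       frac_cryptic_genes = 0.2,
                       frac_latent = 0.05, frac_silent = 0.05,
                       psi_mut = 0.08, psi_wt = 0.003, psi_latent = 0.01,
                       overdispersion = 0.02,
                       mean_gene_depth = 200, depth_dispersion = 8,
                       bp_distance_range = c(13L, 17L),
                       cryptic_offset_range = c(10L, 30L),
                       noncryptic_bp_range = c(21L, 30L),
                       decoy_ag_frac = 0.3,
                       decoy_bp_range = c(36L, 44L),
                       intron_length = 100L, exon_length = 60L,
                       libsize_sdlog = 0.3,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$n_mut >= 1, cfg$n_wt >= 1,
            length(cfg$cancer_types) >= 1)
  if (!(cfg$psi_wt >= 0 && cfg$psi_wt <= cfg$psi_mut && cfg$psi_mut <= 1))
    stop("require 0 <= psi_wt <= psi_mut <= 1")
  if (!(cfg$overdispersion >= 0 && cfg$overdispersion < 1))
    stop("overdispersion must lie in [0, 1)")
  fr <- cfg$frac_cryptic_genes + cfg$frac_latent + cfg$frac_silent
  if (cfg$frac_cryptic_genes < 0 || cfg$frac_latent < 0 ||
      cfg$frac_silent < 0 || fr > 1)
    stop("gene class fractions must be non-negative and sum to at most 1")
  for (nm in c("bp_distance_range", "cryptic_offset_range",
               "noncryptic_bp_range", "decoy_bp_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1)
      stop(sprintf("%s must be a non-empty positive range", nm))
  }
  # The planted BP heptamer, tract and AGs must all fit in the scored
  # 50-base intron tail: the canonical-BP distance of a cryptic intron is
  # offset + bp distance.
  if (max(cfg$cryptic_offset_range) + max(cfg$bp_distance_range) > 50)
    stop("cryptic_offset_range and bp_distance_range cannot coexist within ",
         "the 50 bp intron tail")
  if (max(cfg$decoy_bp_range) > 50)
    stop("decoy_bp_range must lie within the 50 bp intron tail")
  if (min(cfg$decoy_bp_range) < 34)
    stop("decoy_bp_range must start at >= 34 so a decoy AG can sit more ",
         "than 30 bp upstream of the intron end yet downstream of the BP")
  if (cfg$intron_length < 60 || cfg$exon_length < 10)
    stop("introns must be >= 60 bp and exons >= 10 bp")
  invisible(cfg)
}
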