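#' Generate a synthetic genome, annotation and truth table
#'
#' Builds one chromosome per gene. Each gene has three exons and two introns
#' and sits on alternating strands. Intron tails follow the layout (5' to
#' 3'): purine filler (AG-free), branch-point heptamer drawn from the
#' scoring PWM, polypyrimidine tract, optional cryptic AG at the planted
#' offset, more tract, and the canonical terminal AG. The last intron of
#' each gene is the analysis intron recorded in the truth table; the first
#' intron is a plain intron that contributes a second junction per gene so
#' that junction usage is testable.
#'
#' Planted guarantees, by construction: every analysis intron's last 50
#' bases contain the BP heptamer with its adenine at the planted distance;
#' introns of cryptic/latent/silent genes contain exactly one AG ending
#' 10-30 bp upstream of the canonical intron end; control introns contain
#' no AG in that window (decoy AGs sit more than 30 bp upstream).
#'
#' @param config a [sim_config()].
#' @param model a [bp_scoring_model()]; planted heptamers are drawn from its
#'   PWM so that the scorer's self-consistency can be tested.
#' @return list with `genome` (DNAStringSet), `annotation` (GRanges with
#'   gene/transcript/exon features), `truth` (data.frame, one row per
#'   gene), and `scaffold` (data.frame of all emittable junctions with
#'   genomic coordinates, strand, motif and role).
#' @export
generate_genome_and_annotation <- function(config, model = bp_scoring_model()) {
  validate_sim_config(config)
  E <- as.integer(config$exon_length)
  L <- as.integer(config$intron_length)
  n <- as.integer(config$n_genes)

  set.seed(derive_seed(config$seed, 1L))  # gene structure stream
  n_cr <- round(config$frac_cryptic_genes * n)
  n_lat <- round(config$frac_latent * n)
  n_sil <- round(config$frac_silent * n)
  classes <- sample(rep(c("cryptic", "latent", "silent", "control"),
                        c(n_cr, n_lat, n_sil, n - n_cr - n_lat - n_sil)))
  strands <- rep(c("+", "-"), length.out = n)

  ri <- function(r, m) if (r[1] == r[2]) rep(r[1], m) else
    sample(seq(r[1], r[2]), m, replace = TRUE)

  has_ag <- classes %in% c("cryptic", "latent", "silent")
  offset <- ifelse(has_ag, ri(config$cryptic_offset_range, n), NA_integer_)
  d_cr <- ifelse(has_ag, ri(config$bp_distance_range, n), NA_integer_)
  decoy <- classes == "control" & runif(n) < config$decoy_ag_frac
  delta2 <- integer(n)  # canonical BP distance of the analysis intron
  delta2[has_ag] <- offset[has_ag] + d_cr[has_ag]
  delta2[decoy] <- ri(config$decoy_bp_range, sum(decoy))
  plain2 <- !has_ag & !decoy
  delta2[plain2] <- ri(config$noncryptic_bp_range, sum(plain2))
  decoy_offset <- rep(NA_integer_, n)
  if (any(decoy)) {
    # draw the decoy's BP-to-AG spacing (3-12 bp, below the 13-17 bp zone
    # occupied by genuine cryptic sites), then place the AG; the AG always
    # ends more than 30 bp upstream of the intron end
    hi <- pmin(12L, delta2[decoy] - 31L)
    d_dec <- 3L + floor(runif(sum(decoy)) * (hi - 3L + 1L))
    decoy_offset[decoy] <- delta2[decoy] - d_dec
  }
  delta1 <- ri(config$noncryptic_bp_range, n)

  psi_mut <- ifelse(classes == "cryptic", config$psi_mut,
                    ifelse(classes == "latent", config$psi_latent, 0))
  psi_wt <- ifelse(classes == "cryptic", config$psi_wt,
                   ifelse(classes == "latent", config$psi_latent, 0))

  set.seed(derive_seed(config$seed, 2L))  # sequence stream
  pad <- strrep("C", 10)
  seqs <- character(n)
  chroms <- sprintf("chr%d", seq_len(n))
  gene_ids <- sprintf("gene%03d", seq_len(n))
  glen <- 3L * E + 2L * L
  # transcript-direction coordinates of the gene parts
  i1s <- E + 1L; i1e <- E + L
  i2s <- 2L * E + L + 1L; i2e <- 2L * E + 2L * L

  gpos <- function(q, strand) if (strand == "-") 10L + glen - q + 1L else 10L + q

  scaffold <- vector("list", n)
  truth <- vector("list", n)
  ann <- vector("list", n)

  for (g in seq_len(n)) {
    st <- strands[g]
    e1 <- random_exon(E); e2 <- random_exon(E); e3 <- random_exon(E)
    int1 <- build_intron_tx(L, delta1[g], NA, NA, model)
    int2 <- build_intron_tx(L, delta2[g],
                            if (has_ag[g]) offset[g] else NA,
                            decoy_offset[g], model)
    tx <- paste0(e1, int1, e2, int2, e3)
    seqs[g] <- if (st == "-")
      paste0(pad, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tx))), pad)
    else paste0(pad, tx, pad)

    # genomic coordinates of the two canonical introns and optional cryptic
    j <- function(qs, qe) {
      a <- gpos(qs, st); b <- gpos(qe, st)
      c(min(a, b), max(a, b))
    }
    j1 <- j(i1s, i1e)
    j2 <- j(i2s, i2e)
    motif <- if (st == "-") "CT/AC" else "GT/AG"
    rows <- data.frame(
      gene_id = gene_ids[g], chrom = chroms[g],
      start = c(j1[1], j2[1]), end = c(j1[2], j2[2]), strand = st,
      motif = motif, role = c("canonical1", "canonical2"),
      annotated = c(1L, 1L), stringsAsFactors = FALSE)
    if (has_ag[g]) {
      jc <- j(i2s, i2e - offset[g])
      rows <- rbind(rows, data.frame(
        gene_id = gene_ids[g], chrom = chroms[g],
        start = jc[1], end = jc[2], strand = st, motif = motif,
        role = "cryptic", annotated = 0L, stringsAsFactors = FALSE))
    }
    scaffold[[g]] <- rows

    bp_q <- i2e - delta2[g] + 1L  # planted BP adenine, tx coordinates
    truth[[g]] <- data.frame(
      gene_id = gene_ids[g], class = classes[g], chrom = chroms[g],
      strand = st,
      canonical_start = j2[1], canonical_end = j2[2],
      canonical_acceptor = acceptor_of(j2[1], j2[2], st),
      cryptic_acceptor = if (has_ag[g])
        acceptor_of(j(i2s, i2e - offset[g])[1], j(i2s, i2e - offset[g])[2], st)
      else NA_integer_,
      cryptic_offset = offset[g],
      bp_pos = gpos(bp_q, st),
      bp_dist_cryptic = d_cr[g],
      bp_dist_canonical = delta2[g],
      decoy_offset = decoy_offset[g],
      psi_mut = psi_mut[g], psi_wt = psi_wt[g],
      frame = if (has_ag[g]) {
        if (offset[g] %% 3 == 0) "in_frame" else "out_of_frame"
      } else NA_character_,
      stringsAsFactors = FALSE)

    # annotation features (1-based inclusive)
    ex_q <- rbind(c(1L, E), c(E + L + 1L, 2L * E + L),
                  c(2L * E + 2L * L + 1L, glen))
    ex <- t(apply(ex_q, 1, function(r) j(r[1], r[2])))
    feats <- data.frame(
      chrom = chroms[g],
      start = c(10L + 1L, 10L + 1L, ex[, 1]),
      end = c(10L + glen, 10L + glen, ex[, 2]),
      strand = st,
      type = c("gene", "transcript", rep("exon", 3)),
      gene_id = gene_ids[g],
      transcript_id = c(NA, rep(paste0(gene_ids[g], ".t1"), 4)),
      stringsAsFactors = FALSE)
    ann[[g]] <- feats
  }

  genome <- Biostrings::DNAStringSet(setNames(seqs, chroms))
  annd <- do.call(rbind, ann)
  annotation <- GenomicRanges::GRanges(
    seqnames = annd$chrom,
    ranges = IRanges::IRanges(annd$start, annd$end),
    strand = annd$strand,
    type = annd$type, source = "cryptsplice_sim",
    gene_id = annd$gene_id, transcript_id = annd$transcript_id)

  list(genome = genome, annotation = annotation,
       truth = do.call(rbind, truth),
       scaffold = do.call(rbind, scaffold),
       config = config)
}

random_exon <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Draw a 7-mer from the PWM conditioned on the consensus yTnAy core
# (pyrimidines at the y positions, T at the conserved T, A at the BP
# position); the unconstrained positions are drawn from the full PWM
# columns. Draws containing an AG dinucleotide are rejected so that
# planted AG positions stay unique within the intron tail.
draw_heptamer <- function(pwm) {
  bases <- rownames(pwm)
  ydraw <- function(col) {
    p <- pwm[c("C", "T"), col]
    sample(c("C", "T"), 1, prob = p / sum(p))
  }
  for (i in 1:100) {
    h <- vapply(seq_len(ncol(pwm)), function(j)
      sample(bases, 1, prob = pwm[, j]), character(1))
    h[3] <- ydraw(3); h[7] <- ydraw(7)
    h[4] <- "T"; h[6] <- "A"
    if (!any(h[-length(h)] == "A" & h[-1] == "G")) return(h)
  }
  stop("could not draw an AG-free heptamer from the PWM")
}

# Build one intron in transcription direction. `delta` is the distance from
# the planted BP adenine to the first exonic base after the canonical
# acceptor. `cryptic_offset`, if not NA, plants an AG ending that many bases
# upstream of the intron end; `decoy_offset` likewise for control decoys.
build_intron_tx <- function(L, delta, cryptic_offset, decoy_offset, model) {
  s <- character(L)
  s[1:2] <- c("G", "T")
  s[(L - 1):L] <- c("A", "G")
  p_bp <- L + 1L - delta
  if (p_bp - 6L < 3L || p_bp + 1L > L - 2L)
    stop("planted BP does not fit inside the intron")
  hept <- draw_heptamer(model$pwm)
  s[(p_bp - 5L):(p_bp + 1L)] <- hept

  # polypyrimidine tract between heptamer and terminal AG
  tract_idx <- seq(p_bp + 2L, L - 2L)
  s[tract_idx] <- sample(c("C", "T"), length(tract_idx),
                         replace = TRUE, prob = c(0.45, 0.55))
  if (!is.na(cryptic_offset)) {
    gp <- L - cryptic_offset          # cryptic G
    s[gp - 1L] <- "A"; s[gp] <- "G"
  }
  if (!is.na(decoy_offset)) {
    gp <- L - decoy_offset
    s[gp - 1L] <- "A"; s[gp] <- "G"
  }

  # guanine filler upstream of the heptamer: purine background that cannot
  # form AG dinucleotides or spurious BP adenines
  s[seq(3L, p_bp - 6L)] <- "G"
  paste(s, collapse = "")
}
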