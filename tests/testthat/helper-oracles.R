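# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive results from first principles, without reusing the
# package's internal code paths.

# textbook Benjamini-Hochberg step-up with monotonicity cap
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive scan scoring every eligible adenine in a sequence
oracle_bp_scan <- function(seq, pwm, background, min_dist, window = 50) {
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  res <- NULL
  for (p in seq_len(L)) {
    if (s[p] != "A") next
    d <- L + 1 - p
    if (d < min_dist || d > window) next
    if (p < 6 || p + 1 > L) next
    ctx <- s[(p - 5):(p + 1)]
    sc <- 0
    bad <- FALSE
    for (j in 1:7) {
      i <- match(ctx[j], c("A", "C", "G", "T"))
      if (is.na(i)) { bad <- TRUE; break }
      sc <- sc + log2(pwm[i, j] / background[i])
    }
    if (bad) next
    res <- rbind(res, data.frame(pos = p, d_bp = d, score = sc))
  }
  if (is.null(res)) return(res)
  res[order(-round(res$score, 9), res$d_bp), ]
}

# brute-force application of the three junction filters in a fixed order
oracle_filter_keep <- function(j, totals, index, min_total) {
  allowed <- c("GT/AG", "CT/AC", "GC/AG", "CT/GC", "AT/AC", "GT/AT")
  keep <- logical(nrow(j))
  annk <- paste(index$junctions$chrom, index$junctions$start,
                index$junctions$end, index$junctions$strand)
  for (i in seq_len(nrow(j))) {
    st <- j$strand[i]
    if (st == "*") {
      st <- if (j$motif[i] %in% c("GT/AG", "GC/AG", "AT/AC")) "+"
            else if (j$motif[i] %in% c("CT/AC", "CT/GC", "GT/AT")) "-"
            else "*"
    }
    if (totals[i] < min_total) next
    if (!(j$motif[i] %in% allowed)) next
    don <- if (st == "-") j$end[i] else j$start[i]
    acc <- if (st == "-") j$start[i] else j$end[i]
    is_ann <- paste(j$chrom[i], j$start[i], j$end[i], st) %in% annk
    shares <- paste(j$chrom[i], st, don) %in%
      paste(index$junctions$chrom, index$junctions$strand,
            index$junctions$donor) ||
      paste(j$chrom[i], st, acc) %in%
      paste(index$junctions$chrom, index$junctions$strand,
            index$junctions$acceptor)
    if (!is_ann && !shares) next
    g <- index$genes
    ng <- sum(g$chrom == j$chrom[i] & g$strand == st &
                g$start <= j$start[i] & g$end >= j$end[i])
    if (ng != 1) next
    keep[i] <- TRUE
  }
  keep
}

# exhaustive-search association of a novel acceptor with a canonical one
oracle_associate <- function(strand, donor, novel_acc, candidates) {
  cand <- candidates[candidates$donor == donor &
                       candidates$acceptor != novel_acc, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  d <- if (strand == "-") cand$acceptor - novel_acc
       else novel_acc - cand$acceptor
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    if (is.null(best)) { best <- i; next }
    bd <- d[best]; di <- d[i]
    better <-
      (di < 0 && bd > 0) ||                       # downstream beats upstream
      (di < 0 && bd < 0 && di > bd) ||            # closer downstream
      (di > 0 && bd > 0 && di < bd) ||            # closer upstream
      (di == bd && cand$acceptor[i] < cand$acceptor[best])
    if (better) best <- i
  }
  list(acceptor = cand$acceptor[best], d = d[best])
}

# hand-rolled base counter for tail profiles
oracle_base_freq <- function(seqs) {
  w <- nchar(seqs[1])
  counts <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in seqs) {
    ch <- strsplit(s, "")[[1]]
    for (i in seq_len(w)) counts[ch[i], i] <- counts[ch[i], i] + 1
  }
  sweep(counts, 2, colSums(counts), "/")
}

# small filtered junction-count-matrix fixture built directly
make_fjcm <- function(counts, gene_ids, conditions,
                      cancers = rep("A", length(conditions)),
                      status = rep("annotated", nrow(counts))) {
  n <- nrow(counts)
  j <- data.frame(
    chrom = "chr1", start = seq(101, by = 1000, length.out = n),
    end = seq(600, by = 1000, length.out = n), strand = "+",
    motif = "GT/AG", annotated = 1L, total = rowSums(counts),
    status = status, gene_id = gene_ids, stringsAsFactors = FALSE)
  j$donor <- j$start; j$acceptor <- j$end
  samples <- data.frame(
    sample = sprintf("S%02d", seq_along(conditions)),
    condition = conditions, cancer_type = cancers,
    lib_size = pmax(colSums(counts), 1), stringsAsFactors = FALSE)
  colnames(counts) <- samples$sample
  list(junctions = j, counts = counts, samples = samples)
}

# default small simulation shared by several tests (generated once per run)
shared_sim_env <- new.env()
get_shared_sim <- function() {
  if (is.null(shared_sim_env$sim)) {
    cfg <- sim_config(n_genes = 120, n_mut = 8, n_wt = 8,
                      frac_cryptic_genes = 0.25, seed = 42)
    sim <- generate_genome_and_annotation(cfg)
    samples <- make_sample_sheet(cfg)
    jcm <- simulate_junction_counts(sim, samples, cfg)
    shared_sim_env$sim <- list(cfg = cfg, sim = sim, samples = samples,
                               jcm = jcm,
                               index = build_annotation_index(sim$annotation))
  }
  shared_sim_env$sim
}
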