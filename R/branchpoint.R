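## Branch-point scoring and BP-to-3'SS distance analyses.

#' Branch-point scoring model
#'
#' A position weight matrix over a 7-base window with the BP adenine at
#' window position 6, encoding the degenerate human BP consensus (yTnAy
#' core with a near-invariant adenine). Candidates are scored by the sum of
#' log2 odds against a uniform background. An external predictor's calls
#' can be substituted downstream via `external` tables where available; the
#' scanner interface (search the last 50 intron bases, minimum BP-to-3'SS
#' distance 8, pick the highest score) is fixed.
#'
#' @param pwm 4 x 7 column-stochastic matrix (rows A, C, G, T). The default
#'   places the yTnAy core at window positions 3-7: pyrimidine-rich
#'   positions 3 and 7 (C/T 0.4 each), strongly conserved T at position 4
#'   (0.90), the invariant adenine at position 6 (0.97), uniform
#'   elsewhere.
#' @param background base frequencies (default uniform).
#' @param min_dist minimum BP-to-3'SS distance in the first-exonic-base
#'   convention (default 8).
#' @param search_window how many terminal intron bases to search
#'   (default 50).
#' @return list of class `bp_scoring_model`.
#' @export
bp_scoring_model <- function(pwm = NULL, background = rep(0.25, 4),
                             min_dist = 8L, search_window = 50L) {
  if (is.null(pwm)) {
    uni <- rep(0.25, 4)
    y <- c(A = 0.1, C = 0.4, G = 0.1, T = 0.4)
    tt <- c(A = 0.04, C = 0.03, G = 0.03, T = 0.90)
    aa <- c(A = 0.97, C = 0.01, G = 0.01, T = 0.01)
    pwm <- cbind(uni, uni, y, tt, uni, aa, y)
    rownames(pwm) <- c("A", "C", "G", "T")
    colnames(pwm) <- paste0("p", 1:7)
  }
  stopifnot(nrow(pwm) == 4, ncol(pwm) == 7,
            all(abs(colSums(pwm) - 1) < 1e-6),
            length(background) == 4, abs(sum(background) - 1) < 1e-6)
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  names(background) <- rownames(pwm)
  structure(list(pwm = pwm, background = background,
                 min_dist = as.integer(min_dist),
                 search_window = as.integer(search_window)),
            class = "bp_scoring_model")
}

#' Score candidate branch points in an intron
#'
#' Every adenine within the last `search_window` bases of the intron whose
#' distance to the 3'SS (first exonic base after the acceptor minus the
#' adenine position) is at least `min_dist`, and whose full 7-base context
#' lies within the supplied sequence, is scored by PWM log2 odds. Calls are
#' ranked by score, ties broken toward the smaller distance.
#'
#' @param intron_seq intron sequence in transcription direction (character
#'   or DNAString); the last base is the acceptor G.
#' @param model a [bp_scoring_model()].
#' @return data.frame with pos (1-based position within `intron_seq`),
#'   d_bp, score, rank; zero rows when no adenine is eligible or the
#'   sequence is shorter than the PWM window.
#' @export
score_branchpoints <- function(intron_seq, model = bp_scoring_model()) {
  s <- strsplit(toupper(as.character(intron_seq)), "")[[1]]
  L <- length(s)
  empty <- data.frame(pos = integer(), d_bp = integer(), score = numeric(),
                      rank = integer())
  if (L < 7) {
    message("intron shorter than the PWM window; no branch-point calls")
    return(empty)
  }
  first <- max(1L, L - model$search_window + 1L)
  cand <- which(s == "A")
  cand <- cand[cand >= first & cand >= 6L & cand + 1L <= L]
  d <- L + 1L - cand
  cand <- cand[d >= model$min_dist]
  if (length(cand) == 0) return(empty)
  lo <- log2(model$pwm / model$background)
  score <- vapply(cand, function(p) {
    ctx <- s[(p - 5L):(p + 1L)]
    idx <- match(ctx, rownames(model$pwm))
    if (anyNA(idx)) return(NA_real_)
    sum(lo[cbind(idx, 1:7)])
  }, numeric(1))
  ok <- is.finite(score)
  cand <- cand[ok]; score <- score[ok]
  if (length(cand) == 0) return(empty)
  d <- L + 1L - cand
  # rank on scores rounded to 1e-9 so ties are resolved by distance, not
  # by floating-point summation order
  o <- order(-round(score, 9), d)
  data.frame(pos = cand[o], d_bp = d[o], score = score[o],
             rank = seq_along(o))
}

#' Distance from a branch point to a 3' splice site
#'
#' Measured to the first exonic base after the acceptor, so a BP that is
#' the adenine of the acceptor's own terminal AG has distance 2. Negative
#' distances (BP downstream of the acceptor being measured) are allowed
#' and reported as negative.
#'
#' @param bp_pos genomic position of the BP adenine.
#' @param acceptor genomic acceptor position.
#' @param strand `"+"` or `"-"`.
#' @return integer distance.
#' @export
bp_to_3ss_distance <- function(bp_pos, acceptor, strand) {
  n <- max(length(bp_pos), length(acceptor), length(strand))
  bp_pos <- rep_len(bp_pos, n)
  acceptor <- rep_len(acceptor, n)
  neg <- rep_len(strand == "-", n)
  as.integer(ifelse(neg, bp_pos - acceptor + 1L, acceptor + 1L - bp_pos))
}

#' BP-to-cryptic-3'SS distance with second-best fallback
#'
#' The distance from the highest-scoring BP of the canonical intron to the
#' cryptic acceptor; when that distance falls outside `window` and a
#' second-ranked call exists, the second call's distance is substituted
#' (and the rank recorded).
#'
#' @param calls ranked BP calls for the canonical 3'SS's intron, as genomic
#'   data (data.frame with columns pos (genomic) and rank).
#' @param cryptic_acceptor genomic position of the cryptic acceptor.
#' @param strand strand of the intron.
#' @param window acceptable distance window (default 13-17).
#' @return list(distance, rank) or NULL when there are no calls.
#' @export
bp_distance_with_fallback <- function(calls, cryptic_acceptor, strand,
                                      window = c(13L, 17L)) {
  if (is.null(calls) || nrow(calls) == 0) return(NULL)
  d1 <- bp_to_3ss_distance(calls$pos[calls$rank == 1], cryptic_acceptor,
                           strand)
  if (d1 >= window[1] && d1 <= window[2]) return(list(distance = d1, rank = 1L))
  if (any(calls$rank == 2)) {
    d2 <- bp_to_3ss_distance(calls$pos[calls$rank == 2], cryptic_acceptor,
                             strand)
    return(list(distance = d2, rank = 2L))
  }
  list(distance = d1, rank = 1L)
}

# intron sequence in transcription direction
intron_sequence <- function(genome, chrom, start, end, strand) {
  seq <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(seq)
}

# map transcription-direction intron positions to genomic coordinates
# (strand is a scalar here)
tx_to_genomic <- function(pos, start, end, strand) {
  if (identical(strand, "-")) end - pos + 1L else start + pos - 1L
}

#' Score branch points for a set of introns
#'
#' @param introns data.frame with chrom, start, end, strand (1-based
#'   inclusive intron coordinates).
#' @param genome DNAStringSet.
#' @param model a [bp_scoring_model()].
#' @return named list (by junction key) of call data.frames with genomic
#'   `pos` added.
#' @export
score_intron_branchpoints <- function(introns, genome,
                                      model = bp_scoring_model()) {
  out <- vector("list", nrow(introns))
  names(out) <- junction_key(introns$chrom, introns$start, introns$end,
                             introns$strand)
  for (i in seq_len(nrow(introns))) {
    seq <- intron_sequence(genome, introns$chrom[i], introns$start[i],
                           introns$end[i], introns$strand[i])
    calls <- score_branchpoints(seq, model)
    if (nrow(calls)) {
      calls$pos <- tx_to_genomic(calls$pos, introns$start[i],
                                 introns$end[i], introns$strand[i])
    }
    out[[i]] <- calls
  }
  out
}

#' Choose one cryptic site per canonical 3'SS
#'
#' When several cryptic acceptors share one canonical 3'SS, one is chosen
#' uniformly at random (seeded) for the BP distance analyses.
#'
#' @param records cryptic-site records.
#' @param seed integer seed.
#' @return subset of `records`.
#' @export
choose_one_per_canonical <- function(records, seed = 1L) {
  if (nrow(records) == 0) return(records)
  set.seed(derive_seed(seed, 5L))
  canon <- site_key(records$chrom, records$strand, records$canonical_acceptor)
  keep <- unlist(lapply(split(seq_len(nrow(records)), canon), function(i)
    if (length(i) == 1) i else sample(i, 1)))
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select control 3' splice sites
#'
#' Annotated junctions whose mean per-sample coverage is strictly greater
#' than `min_mean_cov` and whose donor is not shared by any surviving
#' novel acceptor.
#'
#' @param fjcm classified/filtered junction count matrix.
#' @param min_mean_cov mean-coverage threshold (default 100, strict).
#' @return data.frame of control junctions.
#' @export
select_controls <- function(fjcm, min_mean_cov = 100) {
  j <- fjcm$junctions
  mean_cov <- rowMeans(fjcm$counts)
  nov_donors <- site_key(j$chrom, j$strand, j$donor)[j$status == "novel_acceptor"]
  keep <- j$status == "annotated" & mean_cov > min_mean_cov &
    !(site_key(j$chrom, j$strand, j$donor) %in% nov_donors)
  out <- j[keep, , drop = FALSE]
  out$mean_cov <- mean_cov[keep]
  rownames(out) <- NULL
  out
}

#' Null distribution of intronic AG distances in control introns
#'
#' For each control intron, every intronic AG strictly downstream of the
#' highest-scoring BP and ending more than 10 bp before the intron end
#' contributes its BP-to-AG distance (same convention as
#' [bp_to_3ss_distance()], the AG's G playing the acceptor).
#'
#' @param controls control junctions from [select_controls()].
#' @param genome DNAStringSet.
#' @param model a [bp_scoring_model()].
#' @return numeric vector of pooled distances.
#' @export
control_ag_distances <- function(controls, genome,
                                 model = bp_scoring_model()) {
  dists <- numeric(0)
  for (i in seq_len(nrow(controls))) {
    seq <- intron_sequence(genome, controls$chrom[i], controls$start[i],
                           controls$end[i], controls$strand[i])
    calls <- score_branchpoints(seq, model)
    if (nrow(calls) == 0) next
    s <- strsplit(seq, "")[[1]]
    L <- length(s)
    p1 <- calls$pos[calls$rank == 1]
    ag_a <- which(s == "A" & c(s[-1], "") == "G")   # A of each AG
    ag_a <- ag_a[ag_a > p1 & (ag_a + 1L) <= L - 10L]
    if (length(ag_a))
      dists <- c(dists, (ag_a + 2L) - p1)  # first base after the G, minus BP
  }
  dists
}

#' Screen for introns with potential cryptic 3'SSs
#'
#' Lists introns whose canonical junction passes the coverage cutoff and
#' which contain an intronic AG 10-30 bp upstream of the annotated 3'SS
#' and 13-17 bp downstream of the highest-scoring predicted BP, flagging
#' whether the corresponding cryptic junction itself passes the coverage
#' cutoff and whether it was called significantly more used in mutants.
#'
#' @param fjcm classified/filtered junction count matrix.
#' @param usage usage test results.
#' @param genome DNAStringSet.
#' @param model a [bp_scoring_model()].
#' @param coverage_cutoff total-read cutoff (default 20).
#' @param offset_window AG-to-3'SS window (default 10-30 bp upstream).
#' @param bp_window BP-to-AG window (default 13-17 bp).
#' @param alpha q-value threshold for the significance flag.
#' @return data.frame with one row per (intron, potential AG).
#' @export
potential_cryptic_screen <- function(fjcm, usage, genome,
                                     model = bp_scoring_model(),
                                     coverage_cutoff = 20,
                                     offset_window = c(10L, 30L),
                                     bp_window = c(13L, 17L),
                                     alpha = 0.1) {
  j <- fjcm$junctions
  ann <- which(j$status == "annotated" & j$total >= coverage_cutoff)
  jk_all <- junction_key(j$chrom, j$start, j$end, j$strand)
  rows <- list()
  for (i in ann) {
    seq <- intron_sequence(genome, j$chrom[i], j$start[i], j$end[i],
                           j$strand[i])
    s <- strsplit(seq, "")[[1]]
    L <- length(s)
    calls <- score_branchpoints(seq, model)
    if (nrow(calls) == 0) next
    p1 <- calls$pos[calls$rank == 1]
    g_pos <- which(s == "G" & c("", s[-L]) == "A")   # G of each AG
    o <- L - g_pos
    d_bp <- g_pos + 1L - p1
    hit <- o >= offset_window[1] & o <= offset_window[2] &
      d_bp >= bp_window[1] & d_bp <= bp_window[2]
    for (gp in g_pos[hit]) {
      acc_gen <- tx_to_genomic(gp, j$start[i], j$end[i], j$strand[i])
      ck <- if (j$strand[i] == "-")
        junction_key(j$chrom[i], acc_gen, j$end[i], j$strand[i])
      else junction_key(j$chrom[i], j$start[i], acc_gen, j$strand[i])
      m <- match(ck, jk_all)
      covered <- !is.na(m) && j$total[m] >= coverage_cutoff
      um <- match(ck, usage$junction)
      signif <- !is.na(um) && isTRUE(usage$tested[um]) &&
        !is.na(usage$q[um]) && usage$q[um] < alpha &&
        identical(usage$direction[um], "higher_in_mut")
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jk_all[i], gene_id = j$gene_id[i],
        potential_acceptor = acc_gen, offset = L - gp,
        d_bp = gp + 1L - p1, cryptic_covered = covered,
        cryptic_significant = signif, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(junction = character(), gene_id = character(),
                      potential_acceptor = integer(), offset = integer(),
                      d_bp = integer(), cryptic_covered = logical(),
                      cryptic_significant = logical())
  out
}

#' Compare two BP-distance distributions
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test with normal
#' approximation and tie correction.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return list with statistic and p.value.
#' @export
compare_distance_distributions <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("both samples must be non-empty")
  wt <- wilcox.test(sample_a, sample_b, exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}
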