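## 3'-intron nucleotide composition and adenine enrichment.

#' Nucleotide frequency matrix over the last 50 intron bases
#'
#' Sequences are aligned at the 3'SS (positions -50..-1 in transcription
#' direction; minus-strand introns are reverse-complemented). Acceptors
#' whose intron is shorter than `width` are excluded with a message.
#'
#' @param acceptors data.frame with chrom, strand and 1-based intron
#'   start/end columns.
#' @param genome DNAStringSet.
#' @param width tail width (default 50).
#' @return list of class `nucleotide_profile`: `freq` (4 x width base
#'   frequencies, rows A/C/G/T), `a_counts`, `non_a_counts`, `n`
#'   (sequence count), `positions` (-width..-1).
#' @export
tail_frequency_matrix <- function(acceptors, genome, width = 50L) {
  keep <- (acceptors$end - acceptors$start + 1L) >= width
  if (any(!keep))
    message(sum(!keep), " intron(s) shorter than ", width, " bp excluded")
  acceptors <- acceptors[keep, , drop = FALSE]
  seqs <- character(nrow(acceptors))
  ok <- logical(nrow(acceptors))
  for (i in seq_len(nrow(acceptors))) {
    res <- tryCatch({
      if (acceptors$strand[i] == "-") {
        s <- Biostrings::subseq(genome[[acceptors$chrom[i]]],
                                acceptors$start[i],
                                acceptors$start[i] + width - 1L)
        as.character(Biostrings::reverseComplement(s))
      } else {
        as.character(Biostrings::subseq(genome[[acceptors$chrom[i]]],
                                        acceptors$end[i] - width + 1L,
                                        acceptors$end[i]))
      }
    }, error = function(e) NA_character_)
    if (is.na(res)) {
      warning("sequence unavailable for ", acceptors$chrom[i], "; skipped")
    } else {
      seqs[i] <- res; ok[i] <- TRUE
    }
  }
  seqs <- seqs[ok]
  if (length(seqs) == 0) stop("no usable sequences")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, 4, width, dimnames = list(bases, NULL))
  for (b in bases) if (b %in% rownames(cm)) counts[b, ] <- cm[b, ]
  structure(list(
    freq = sweep(counts, 2, colSums(counts), "/"),
    a_counts = counts["A", ],
    non_a_counts = colSums(counts) - counts["A", ],
    n = length(seqs),
    positions = seq(-width, -1L)), class = "nucleotide_profile")
}

#' Per-position adenine enrichment versus a control profile
#'
#' At each tail position, a Fisher exact test on the 2x2 table of adenine
#' versus non-adenine counts in the class profile against the control
#' profile. One-sided (enrichment) by default, matching the presentation
#' of adenine-enrichment bars with a raw p = 0.05 reference line; no
#' multiple-testing correction across positions.
#'
#' @param profile_class,profile_control profiles from
#'   [tail_frequency_matrix()] over the same positions.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return data.frame with position, p, neg_log10_p.
#' @export
adenine_enrichment <- function(profile_class, profile_control,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (profile_class$n == 0 || profile_control$n == 0)
    stop("both profiles must contain sequences")
  if (!identical(profile_class$positions, profile_control$positions))
    stop("profiles cover different positions")
  p <- vapply(seq_along(profile_class$positions), function(i) {
    tab <- matrix(c(profile_class$a_counts[i], profile_class$non_a_counts[i],
                    profile_control$a_counts[i],
                    profile_control$non_a_counts[i]),
                  nrow = 2, byrow = TRUE)
    fisher.test(tab, alternative = alternative)$p.value
  }, numeric(1))
  data.frame(position = profile_class$positions, p = p,
             neg_log10_p = -log10(p))
}
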