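## Pairing novel 3'SSs with their associated canonical 3'SSs and
## classifying distance, frame and proximal/distal status.

#' Signed distance between a novel and a canonical acceptor
#'
#' Measured in transcription direction: negative means the novel (cryptic)
#' 3'SS lies upstream of the canonical 3'SS. On the plus strand this is
#' `novel - canonical` of the intron end coordinates; on the minus strand
#' `canonical - novel` of the intron start coordinates.
#'
#' @param novel_acc,canon_acc acceptor coordinates (1-based, genomic).
#' @param strand `"+"` or `"-"`.
#' @return signed integer distance; zero raises an error (same site).
#' @export
signed_distance <- function(novel_acc, canon_acc, strand) {
  n <- max(length(novel_acc), length(canon_acc), length(strand))
  novel_acc <- rep_len(novel_acc, n)
  canon_acc <- rep_len(canon_acc, n)
  neg <- rep_len(strand == "-", n)
  d <- ifelse(neg, canon_acc - novel_acc, novel_acc - canon_acc)
  if (any(d == 0))
    stop("novel and canonical acceptor coincide (distance 0)")
  as.integer(d)
}

#' Associate a novel 3'SS with its canonical 3'SS
#'
#' Among annotated junctions sharing the novel junction's donor (5'SS), the
#' associated canonical 3'SS is the one whose acceptor is nearest
#' downstream (in transcription direction) of the novel acceptor; if no
#' annotated acceptor lies downstream, the nearest upstream one is used.
#' Ties are broken toward downstream, then toward the smaller genomic
#' coordinate.
#'
#' @param chrom,strand,donor,novel_acc the novel junction's chromosome,
#'   strand, donor position and acceptor position.
#' @param index annotation index from [build_annotation_index()].
#' @return one-row data.frame with the chosen canonical junction and the
#'   signed distance `d`, or NULL when the donor is shared with no
#'   annotated junction.
#' @export
associate_canonical <- function(chrom, strand, donor, novel_acc, index) {
  aj <- index$junctions
  cand <- aj[aj$chrom == chrom & aj$strand == strand & aj$donor == donor &
               aj$acceptor != novel_acc, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  d <- if (identical(strand, "-")) cand$acceptor - novel_acc
       else novel_acc - cand$acceptor
  down <- d < 0  # canonical acceptor downstream of the novel acceptor
  pick <- if (any(down)) {
    i <- which(down)
    i[order(-d[i], cand$acceptor[i])][1]   # least negative, then smaller coord
  } else {
    i <- which(!down)
    i[order(d[i], cand$acceptor[i])][1]
  }
  out <- cand[pick, , drop = FALSE]
  out$d <- as.integer(d[pick])
  rownames(out) <- NULL
  out
}

#' Classify a cryptic/canonical distance
#'
#' In-frame iff the absolute distance is divisible by three; proximal iff
#' the cryptic site lies 10-30 bp upstream of the canonical site
#' (boundaries inclusive, i.e. d in [-30, -10]).
#'
#' @param d signed distance (non-zero).
#' @return data.frame with columns frame and locality.
#' @export
classify_record <- function(d) {
  if (any(d == 0)) stop("distance 0 is not a cryptic site")
  data.frame(
    frame = ifelse(abs(d) %% 3 == 0, "in_frame", "out_of_frame"),
    locality = ifelse(d >= -30 & d <= -10, "proximal", "distal"),
    stringsAsFactors = FALSE)
}

#' Build the cryptic-site table
#'
#' Joins significant and non-significant novel acceptors from the usage
#' results to their associated canonical junctions and classifies each
#' record. Novel-donor junctions are excluded from 3'SS analyses.
#'
#' @param usage result of [test_differential_usage()].
#' @param index annotation index.
#' @param only_tested keep only junctions that were tested (default TRUE).
#' @return data.frame of cryptic-site records: novel and canonical intron
#'   coordinates (1-based start/end), signed distance d, frame, locality,
#'   usage statistics carried over.
#' @export
build_cryptic_records <- function(usage, index, only_tested = TRUE) {
  nov <- usage[usage$status == "novel_acceptor", , drop = FALSE]
  if (only_tested) nov <- nov[nov$tested, , drop = FALSE]
  if (nrow(nov) == 0) return(empty_records())
  recs <- vector("list", nrow(nov))
  for (i in seq_len(nrow(nov))) {
    don <- donor_of(nov$start[i], nov$end[i], nov$strand[i])
    acc <- acceptor_of(nov$start[i], nov$end[i], nov$strand[i])
    assoc <- associate_canonical(nov$chrom[i], nov$strand[i], don, acc, index)
    if (is.null(assoc)) next
    cl <- classify_record(assoc$d)
    recs[[i]] <- data.frame(
      junction = nov$junction[i], gene_id = nov$gene_id[i],
      chrom = nov$chrom[i], strand = nov$strand[i],
      novel_start = nov$start[i], novel_end = nov$end[i],
      novel_acceptor = acc, donor = don,
      canonical_start = assoc$start, canonical_end = assoc$end,
      canonical_acceptor = assoc$acceptor,
      d = assoc$d, frame = cl$frame, locality = cl$locality,
      usage_mut = nov$usage_mut[i], usage_wt = nov$usage_wt[i],
      direction = nov$direction[i], p = nov$p[i], q = nov$q[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) return(empty_records())
  rownames(out) <- NULL
  out
}

empty_records <- function() {
  data.frame(junction = character(), gene_id = character(),
             chrom = character(), strand = character(),
             novel_start = integer(), novel_end = integer(),
             novel_acceptor = integer(), donor = integer(),
             canonical_start = integer(), canonical_end = integer(),
             canonical_acceptor = integer(), d = integer(),
             frame = character(), locality = character(),
             usage_mut = numeric(), usage_wt = numeric(),
             direction = character(), p = numeric(), q = numeric(),
             stringsAsFactors = FALSE)
}

#' Signed-log2 distance histogram
#'
#' Bins cryptic-site distances as sign(d) * floor(log2(|d|)) split by
#' effect direction, plus a base-by-base inset over d in [-50, -1].
#'
#' @param records cryptic-site records from [build_cryptic_records()].
#' @return list with `log2` (bin, direction, count) and `inset`
#'   (d, direction, count).
#' @export
distance_histogram <- function(records) {
  if (nrow(records) == 0)
    return(list(log2 = data.frame(bin = integer(), direction = character(),
                                  count = integer()),
                inset = data.frame(d = integer(), direction = character(),
                                   count = integer())))
  bin <- sign(records$d) * floor(log2(abs(records$d)))
  log2_tab <- as.data.frame(table(bin = bin, direction = records$direction),
                            stringsAsFactors = FALSE)
  names(log2_tab)[3] <- "count"
  log2_tab$bin <- as.integer(log2_tab$bin)
  ins <- records[records$d >= -50 & records$d <= -1, , drop = FALSE]
  inset <- as.data.frame(table(d = ins$d, direction = ins$direction),
                         stringsAsFactors = FALSE)
  names(inset)[3] <- "count"
  inset$d <- as.integer(inset$d)
  list(log2 = log2_tab, inset = inset)
}
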