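## Junction ingestion: SJ-format tables, GTF-derived annotation index, and
## the novel-junction filters.

# SJ tab dialect motif codes 0..6 in order
SJ_MOTIFS <- c("other", "GT/AG", "CT/AC", "GC/AG", "CT/GC", "AT/AC", "GT/AT")

# motifs written in plus orientation; the complementary three imply minus
PLUS_MOTIFS <- c("GT/AG", "GC/AG", "AT/AC")
MINUS_MOTIFS <- c("CT/AC", "CT/GC", "GT/AT")

#' Read an SJ-format splice junction table
#'
#' Parses the nine-column tab-separated splice-junction dialect written by
#' the STAR aligner (chromosome, 1-based inclusive intron start and end,
#' strand code 0/1/2 for unknown/plus/minus, motif code 0-6, annotated
#' flag, unique reads, multimapping reads, maximum overhang). Unique-read
#' counts are retained as the junction coverage.
#'
#' @param path path to the table (no header).
#' @return data.frame with columns chrom, start, end, strand (`+`, `-`,
#'   `*`), motif (dinucleotide pair or `"other"`), annotated, count,
#'   multi, overhang.
#' @export
read_sj_table <- function(path) {
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               colClasses = c("character", rep("integer", 8))),
    error = function(e) stop("malformed SJ table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(tab) != 9)
    stop("malformed SJ table '", path, "': expected 9 columns, got ",
         ncol(tab), call. = FALSE)
  names(tab) <- c("chrom", "start", "end", "strand_code", "motif_code",
                  "annotated", "count", "multi", "overhang")
  bad <- which(!is.finite(tab$start) | !is.finite(tab$end) |
                 tab$start >= tab$end)
  if (length(bad))
    stop("malformed SJ table '", path, "': start >= end at line ", bad[1],
         call. = FALSE)
  bad <- which(!(tab$strand_code %in% 0:2) | !(tab$motif_code %in% 0:6))
  if (length(bad))
    stop("malformed SJ table '", path, "': invalid strand/motif code at line ",
         bad[1], call. = FALSE)
  data.frame(
    chrom = tab$chrom, start = tab$start, end = tab$end,
    strand = c("*", "+", "-")[tab$strand_code + 1L],
    motif = SJ_MOTIFS[tab$motif_code + 1L],
    annotated = tab$annotated, count = tab$count,
    multi = tab$multi, overhang = tab$overhang,
    stringsAsFactors = FALSE)
}

#' Write an SJ-format table
#'
#' Inverse of [read_sj_table()]; used for round-trip checks and for
#' emitting simulated data.
#'
#' @param df data.frame in the layout returned by [read_sj_table()].
#' @param path output path.
#' @export
write_sj_table <- function(df, path) {
  out <- data.frame(
    df$chrom, df$start, df$end,
    match(df$strand, c("*", "+", "-")) - 1L,
    match(df$motif, SJ_MOTIFS) - 1L,
    df$annotated, df$count, df$multi, df$overhang)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Assemble a junction count matrix from per-sample SJ tables
#'
#' Junctions observed in any sample form the union of rows; unobserved
#' entries are zero. Library size defaults to the per-sample column sum of
#' unique junction-spanning reads.
#'
#' @param sj_files named character vector of SJ table paths (names must
#'   match `samples$sample`) or a directory containing
#'   `<sample>.SJ.out.tab` files.
#' @param samples sample sheet data.frame with at least columns sample and
#'   condition (and optionally cancer_type, lib_size).
#' @return list with `junctions`, `counts`, `samples` (the junction count
#'   matrix structure used throughout).
#' @export
read_junction_counts <- function(sj_files, samples) {
  if (length(sj_files) == 1 && dir.exists(sj_files)) {
    sj_files <- setNames(file.path(sj_files,
                                   paste0(samples$sample, ".SJ.out.tab")),
                         samples$sample)
  }
  missing <- !file.exists(sj_files)
  if (any(missing))
    abort_stage("classify", paste0("missing SJ table(s): ",
                                   paste(sj_files[missing], collapse = ", ")))
  tabs <- lapply(sj_files, read_sj_table)
  all_j <- unique(do.call(rbind, lapply(tabs, function(t)
    t[c("chrom", "start", "end", "strand", "motif", "annotated")])))
  key <- junction_key(all_j$chrom, all_j$start, all_j$end, all_j$strand)
  dup <- duplicated(key)
  all_j <- all_j[!dup, ]; key <- key[!dup]
  counts <- matrix(0L, nrow(all_j), length(tabs),
                   dimnames = list(key, samples$sample))
  for (i in seq_along(tabs)) {
    k <- junction_key(tabs[[i]]$chrom, tabs[[i]]$start, tabs[[i]]$end,
                      tabs[[i]]$strand)
    counts[match(k, key), i] <- tabs[[i]]$count
  }
  if (is.null(samples$lib_size)) samples$lib_size <- colSums(counts)
  rownames(all_j) <- NULL
  list(junctions = all_j, counts = counts, samples = samples)
}

#' Build a splice-site annotation index from a GTF
#'
#' Introns are the gaps between consecutive exons of each transcript;
#' duplicate introns across transcripts are collapsed. Donor and acceptor
#' sets are strand-aware: on plus-strand introns the donor is the intron
#' start and the acceptor the intron end, mirrored on minus.
#'
#' @param gtf path to a GTF with gene/transcript/exon features, or a
#'   GRanges as returned by [rtracklayer::import()].
#' @return list with `junctions` (annotated introns with gene_id), `donors`
#'   and `acceptors` (strand-aware site key sets), and `genes` (gene
#'   spans). Transcripts with overlapping exons are skipped with a warning.
#' @export
build_annotation_index <- function(gtf) {
  gr <- if (is.character(gtf)) rtracklayer::import(gtf) else gtf
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = if (!is.null(gr$transcript_id)) gr$transcript_id else NA,
    stringsAsFactors = FALSE)
  ex <- df[df$type == "exon" & !is.na(df$transcript_id), ]
  juncs <- list()
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    if (any(e$start[-1] <= e$end[-nrow(e)])) {
      warning("transcript ", tx, " has overlapping exons; skipped")
      next
    }
    juncs[[tx]] <- data.frame(
      chrom = e$chrom[1], start = e$end[-nrow(e)] + 1L,
      end = e$start[-1] - 1L, strand = e$strand[1],
      gene_id = e$gene_id[1], stringsAsFactors = FALSE)
  }
  jd <- do.call(rbind, juncs)
  if (is.null(jd)) jd <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), strand = character(),
                                    gene_id = character())
  jd <- jd[!duplicated(junction_key(jd$chrom, jd$start, jd$end, jd$strand)), ]
  rownames(jd) <- NULL
  jd$donor <- donor_of(jd$start, jd$end, jd$strand)
  jd$acceptor <- acceptor_of(jd$start, jd$end, jd$strand)

  gn <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = gn$gene_id, chrom = gn$chrom,
                      start = gn$start, end = gn$end, strand = gn$strand,
                      stringsAsFactors = FALSE)
  list(junctions = jd,
       donors = unique(site_key(jd$chrom, jd$strand, jd$donor)),
       acceptors = unique(site_key(jd$chrom, jd$strand, jd$acceptor)),
       genes = genes)
}

# assign each junction to the genes whose span contains both intron ends on
# the same strand; returns a list column of gene id vectors
genes_overlapping <- function(junctions, index) {
  g <- index$genes
  lapply(seq_len(nrow(junctions)), function(i) {
    hit <- g$chrom == junctions$chrom[i] &
      (g$strand == junctions$strand[i] | junctions$strand[i] == "*") &
      g$start <= junctions$start[i] & g$end >= junctions$end[i]
    g$gene_id[hit]
  })
}

#' Classify junctions and apply the novel-junction filters
#'
#' Keeps junctions that (i) are covered by at least `min_total` unique
#' reads summed over the samples of the current analysis, (ii) have one of
#' the six spliceosomal motifs (GT/AG, CT/AC, GC/AG, CT/GC, AT/AC, GT/AT),
#' and (iii) are annotated or share a donor and/or acceptor with an
#' annotated junction. Junctions overlapping zero or multiple genes are
#' removed; survivors carry exactly one gene. Unknown-strand junctions with
#' an orientation-resolving motif have their strand inferred from the
#' motif.
#'
#' Status values: `annotated`, `novel_acceptor` (donor annotated, acceptor
#' not), `novel_donor`, `novel_both` (both sites annotated but the pairing
#' is new), `rejected` (shares neither site).
#'
#' @param jcm junction count matrix from [read_junction_counts()] or
#'   [simulate_junction_counts()].
#' @param index annotation index from [build_annotation_index()].
#' @param min_total minimum total read count (default 20).
#' @return the filtered matrix; `junctions` gains status, gene_id, total,
#'   donor and acceptor columns.
#' @export
classify_and_filter <- function(jcm, index, min_total = 20) {
  j <- jcm$junctions
  j$total <- as.integer(rowSums(jcm$counts))

  # infer strand from motif orientation where the aligner left it unknown
  unk <- j$strand == "*"
  j$strand[unk & j$motif %in% PLUS_MOTIFS] <- "+"
  j$strand[unk & j$motif %in% MINUS_MOTIFS] <- "-"

  j$donor <- donor_of(j$start, j$end, j$strand)
  j$acceptor <- acceptor_of(j$start, j$end, j$strand)
  jk <- junction_key(j$chrom, j$start, j$end, j$strand)
  annk <- junction_key(index$junctions$chrom, index$junctions$start,
                       index$junctions$end, index$junctions$strand)
  is_ann <- jk %in% annk
  don_ann <- site_key(j$chrom, j$strand, j$donor) %in% index$donors
  acc_ann <- site_key(j$chrom, j$strand, j$acceptor) %in% index$acceptors
  j$status <- ifelse(is_ann, "annotated",
              ifelse(don_ann & !acc_ann, "novel_acceptor",
              ifelse(!don_ann & acc_ann, "novel_donor",
              ifelse(don_ann & acc_ann, "novel_both", "rejected"))))

  glist <- genes_overlapping(j, index)
  ngenes <- lengths(glist)
  j$gene_id <- ifelse(ngenes == 1, vapply(glist, function(x)
    if (length(x)) x[1] else NA_character_, character(1)), NA_character_)

  keep <- j$total >= min_total &
    j$motif %in% c(PLUS_MOTIFS, MINUS_MOTIFS) &
    j$status != "rejected" &
    ngenes == 1
  out <- list(junctions = j[keep, , drop = FALSE],
              counts = jcm$counts[keep, , drop = FALSE],
              samples = jcm$samples)
  rownames(out$junctions) <- NULL
  out
}
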