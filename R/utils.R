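## Internal helpers shared across modules.

# Derive a deterministic child seed from a global seed so that independent
# stages (gene structure, sequence, counts, ...) consume independent streams.
# Kept below 2^31 - 1 so the result is a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Strand-aware junction key used for joins across tables.
junction_key <- function(chrom, start, end, strand) {
  paste(chrom, start, end, strand, sep = ":")
}

site_key <- function(chrom, strand, pos) paste(chrom, strand, pos, sep = ":")

# Donor (5'SS) and acceptor (3'SS) coordinates of an intron [start, end].
donor_of <- function(start, end, strand) {
  n <- max(length(start), length(end), length(strand))
  ifelse(rep_len(strand == "-", n), rep_len(end, n), rep_len(start, n))
}
acceptor_of <- function(start, end, strand) {
  n <- max(length(start), length(end), length(strand))
  ifelse(rep_len(strand == "-", n), rep_len(start, n), rep_len(end, n))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_stage <- function(stage, msg) {
  cond <- structure(
    class = c(paste0("cryptsplice_error_", stage), "cryptsplice_error",
              "error", "condition"),
    list(message = sprintf("[%s] %s", stage, msg), call = NULL))
  stop(cond)
}
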