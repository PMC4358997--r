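#!/usr/bin/env Rscript
# Stage 5: quantify cryptic-site usage as percent spliced in (PSI), screen
# for genes preferring the cryptic 3'SS, and build the heatmap matrices
# (library-normalized z-scores, relative expression, clustering orders).

library(cryptsplice)

samples <- read.table("results/data/samples.tsv", sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
jcm <- read_junction_counts("results/data/sj", samples)
index <- build_annotation_index("results/data/annotation.gtf")

fjcm <- classify_and_filter(jcm, index, min_total = 20)
usage <- test_differential_usage(fjcm, alpha = 0.1)
records <- build_cryptic_records(usage, index)
prox <- records[!is.na(records$q) & records$q < 0.1 &
                  records$direction == "higher_in_mut" &
                  records$locality == "proximal", ]

pt <- psi_table(prox, fjcm)
write.table(data.frame(junction = rownames(pt$psi), pt$psi,
                       check.names = FALSE),
            "results/psi.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
mut <- fjcm$samples$condition == "mut"
med_mut <- apply(pt$psi[, mut, drop = FALSE], 1, median, na.rm = TRUE)
cat(nrow(pt$psi), "proximal cryptic sites quantified; median mutant PSI",
    round(median(med_mut, na.rm = TRUE), 3), "-",
    round(mean(med_mut < 0.10, na.rm = TRUE) * 100),
    "% are included in <10% of transcripts\n")

hits <- high_psi_screen(pt, fjcm$samples$condition)
write.table(hits, "results/high_psi_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(nrow(hits), "genes prefer an out-of-frame cryptic 3'SS",
    "(median mutant PSI > 0.5, wild-type < 0.2, coverage >= 30)\n")

z <- zscore_matrix(pt$cryptic, fjcm$samples$lib_size)
ord <- cluster_order(z$z, "complete")
write.table(data.frame(junction = rownames(z$z), z$z, check.names = FALSE),
            "results/zscores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

expr <- read.table("results/data/gene_expression.tsv", sep = "\t",
                   header = TRUE, check.names = FALSE)
em <- as.matrix(expr[, -1]); rownames(em) <- expr$gene_id
rel <- relative_expression_matrix(em[prox$gene_id, , drop = FALSE],
                                  samples$cancer_type)
write.table(data.frame(gene_id = rownames(rel$rel), rel$rel,
                       check.names = FALSE),
            "results/relative_expression.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

two <- cutree(ord$col_hclust, k = 2)
agree <- max(mean((two == 1) == mut), mean((two == 2) == mut))
cat("two-cluster cut of the z-score columns separates mutants from",
    "wild-types with", round(agree * 100), "% agreement\n")
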