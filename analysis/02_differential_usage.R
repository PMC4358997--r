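#!/usr/bin/env Rscript
# Stage 2: classify junctions against the annotation and test each for
# differential usage between mutant and wild-type samples.
#
# Junctions need >= 20 reads summed over samples, a spliceosomal motif,
# and a shared annotated splice site; each is then tested with the
# beta-binomial likelihood-ratio test (cancer type as covariate) and
# BH-adjusted. Also re-runs the filter at coverage cutoffs 50/75/100 to
# report how many significant novel 3'SSs survive stricter cutoffs.

library(cryptsplice)

samples <- read.table("results/data/samples.tsv", sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
jcm <- read_junction_counts("results/data/sj", samples)
index <- build_annotation_index("results/data/annotation.gtf")

fjcm <- classify_and_filter(jcm, index, min_total = 20)
usage <- test_differential_usage(fjcm, alpha = 0.1)
write.table(usage, "results/usage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

n_sig <- sum(!is.na(usage$q) & usage$q < 0.1)
cat(nrow(fjcm$junctions), "junctions pass the filters;",
    sum(usage$tested), "tested;", n_sig, "significant at q < 0.1\n")
cat(sum(usage$status == "novel_acceptor" & !is.na(usage$q) & usage$q < 0.1),
    "significant novel 3'SSs\n")

sens <- coverage_cutoff_sensitivity(jcm, index, cutoffs = c(20, 50, 75, 100))
write.table(sens, "results/cutoff_sensitivity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("retention of significant novel 3'SSs at cutoffs 50/75/100:",
    paste(round(sens$retention[-1], 2), collapse = "/"), "\n")
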