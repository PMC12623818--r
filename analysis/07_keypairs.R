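#!/usr/bin/env Rscript
# Key miRNA-mRNA pair identification: Pearson correlation of every
# catalogued interaction across all samples, BH-FDR, the negative-
# correlation filter (FDR < 0.05, r < -0.3), and the opposing
# monotone-trend screen across Normal -> COCA1 -> COCA2 -> COCA3
# (miRNA falling, target mRNA rising, all three adjacent comparisons
# significant at p < 0.05).

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

cfg <- cohort_config()
cohort <- get_cohort()
interactions <- simulate_interaction_table(cohort, cfg)

pc <- pair_correlations(cohort$matrices$mirna, cohort$matrices$mrna,
                        interactions)
neg <- filter_negative_pairs(pc)
cat(nrow(pc), "catalogued pairs ->", nrow(neg),
    "pass FDR < 0.05 and r < -0.3\n")

key <- select_key_pairs(neg, cohort$matrices$mirna, cohort$matrices$mrna,
                        cohort$sample_labels)
cat("->", nrow(key), "key pairs after the opposing-trend screen\n\n")
print(key, row.names = FALSE)

planted <- paste(cohort$planted_pairs$mirna, cohort$planted_pairs$mrna)
cat("\nplanted pairs recovered:",
    sum(planted %in% paste(key$mirna, key$mrna)), "/", length(planted),
    "; false positives:", sum(!paste(key$mirna, key$mrna) %in% planted),
    "\n")
tsv(pc, "pair_correlations.tsv")
tsv(key, "key_pairs.tsv")
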