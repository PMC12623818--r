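#!/usr/bin/env Rscript
# Differential expression of CP vs healthy controls on each platform at
# the study thresholds (|log2FC| > 1, BH FDR < 0.05), plus lncRNA target
# prediction: cis by the 10 kb proximity rule, trans by coexpression
# (Pearson r > 0.5) against the differential mRNAs.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

cohort <- get_cohort()
g <- factor(ifelse(cohort$sample_labels == "Normal", "Normal", "CP"),
            levels = c("Normal", "CP"))

deg_lists <- list()
for (p in names(cohort$matrices)) {
  de <- differential_expression(cohort$matrices[[p]], g, case = "CP")
  degs <- call_degs(de)
  deg_lists[[p]] <- degs
  cat(sprintf("%-8s %4d features -> %3d DEGs (%d up / %d down)\n", p,
              nrow(de), nrow(degs), sum(degs$status == "up"),
              sum(degs$status == "down")))
  tsv(de, paste0("de_", p, ".tsv"))
}

coords <- cohort$feature_coordinates
lnc_coords <- coords[grepl("^lnc", coords$feature), ]
mrna_coords <- coords[grepl("^mRNA", coords$feature), ]
cis <- lncrna_cis_targets(lnc_coords, mrna_coords)
cat("cis targets within 10 kb:", nrow(cis), "lncRNA-mRNA pairs\n")

deg_mrna <- deg_lists$mrna$feature
trans <- lncrna_trans_targets(
  cohort$matrices$lncrna,
  cohort$matrices$mrna[, deg_mrna, drop = FALSE])
cat("trans targets (r > 0.5) against", length(deg_mrna), "DE mRNAs:",
    nrow(trans), "pairs\n")
tsv(rbind(cis, trans), "lncrna_targets.tsv")
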