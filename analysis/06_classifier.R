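#!/usr/bin/env Rscript
# The diagnostic classifier over {Normal, COCA1, COCA2, COCA3} from
# exosomal miRNA profiles: univariate logistic screen (p < 0.01),
# bootstrap stability selection (70% subsamples, significant in > 95%),
# LASSO reduction, then a grid-searched resilient-backpropagation network
# evaluated with confusion matrices on the train / test / full sets.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

cohort <- get_cohort()
X <- cohort$matrices$mirna
y <- cohort$sample_labels   # planted truth == recovered COCA labels here

sel <- select_feature_panel(
  X, y, stability_config(n_bootstrap = 200,
                         seed = child_seed(ROOT_SEED, "stab")),
  seed = child_seed(ROOT_SEED, "lasso"))
cat(sprintf("screen -> stability -> LASSO: %d -> %d -> %d features\n",
            length(sel$screened), length(sel$stable), length(sel$panel)))
cat("panel:", paste(sel$panel, collapse = ", "), "\n\n")

sp <- split_train_test(y, 0.8, seed = child_seed(ROOT_SEED, "split"))
bundle <- grid_search(X[sp$train, sel$panel, drop = FALSE], y[sp$train],
                      X[sp$test, sel$panel, drop = FALSE], y[sp$test],
                      seed = child_seed(ROOT_SEED, "grid"))
cat("grid search over", nrow(bundle$grid_table), "specifications; best:",
    bundle$grid_table$spec[bundle$best_index], "\n\n")

for (set in c("train", "test", "all")) {
  idx <- switch(set, train = sp$train, test = sp$test,
                all = seq_along(y))
  rep <- evaluate_classifier(bundle, X[idx, , drop = FALSE], y[idx])
  cat("--", set, "set --\n")
  print(rep)
  cat("\n")
}

save_classifier(bundle, file.path(RESULTS, "classifier.json"))
cat("model written to", file.path(RESULTS, "classifier.json"), "\n")
tsv(bundle$grid_table, "grid_search.tsv")
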