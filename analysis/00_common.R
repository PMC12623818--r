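# shared setup for the numbered analysis scripts: one root seed drives the
# whole workflow, and every script regenerates the cohort deterministically
# from it (01 additionally writes it to disk for outside use)

suppressPackageStartupMessages(library(exococa))

args <- commandArgs(trailingOnly = TRUE)
ROOT_SEED <- if (length(args) >= 2 && args[1] == "--seed") {
  as.integer(args[2])
} else 1L

RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

cohort_config <- function() simulation_config(seed = child_seed(ROOT_SEED, "sim"))
get_cohort <- function() simulate_cohort(cohort_config())

# per-platform consensus labels at the integration target K = 3
platform_labels_k3 <- function(cohort, n_iterations = 100) {
  cp <- cohort$sample_labels != "Normal"
  labs <- list()
  for (i in seq_along(cohort$matrices)) {
    p <- names(cohort$matrices)[i]
    cm <- consensus_matrix(cohort$matrices[[p]][cp, , drop = FALSE], 3,
                           consensus_params(n_iterations = n_iterations,
                                            seed = child_seed(ROOT_SEED,
                                                              "plat", i)))
    labs[[p]] <- stats::setNames(final_labels(cm, 3), rownames(cm))
  }
  labs
}

tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("  wrote", path, "\n")
}
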