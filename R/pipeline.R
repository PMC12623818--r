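#' Load a samples-by-features expression matrix from TSV
#'
#' First column holds sample ids, the header row feature ids. Duplicate
#' sample or feature ids, missing values and non-numeric cells are
#' rejected with the offending location.
#'
#' @param path tab-delimited file.
#' @return numeric matrix with sample rownames and feature colnames.
#' @export
load_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  df <- tryCatch(read.delim(path, check.names = FALSE,
                            colClasses = "character"),
                 error = function(e) stop_invalid("parse error in ", path,
                                                  ": ", conditionMessage(e)))
  if (ncol(df) < 2 || nrow(df) < 1)
    stop_invalid("parse error in ", path, ": need samples and features")
  samples <- df[[1]]
  features <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop_invalid("duplicated sample id: ",
                 samples[duplicated(samples)][1])
  if (anyDuplicated(features))
    stop_invalid("duplicated feature id: ",
                 features[duplicated(features)][1])
  mat <- matrix(NA_real_, nrow(df), length(features),
                dimnames = list(samples, features))
  for (j in seq_along(features)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop_invalid("non-numeric or missing value at row ", bad[1],
                   ", column '", features[j], "' of ", path)
    mat[, j] <- v
  }
  mat
}

#' Configuration for a full pipeline run
#'
#' Bundles the simulation settings, consensus-clustering parameters,
#' feature-selection thresholds, network grid, and analysis cutoffs under
#' one root seed. Stage problem sizes default to the scaled settings used
#' throughout the package's own analyses (100 consensus iterations, 200
#' stability resamples); the per-stage constructors keep the full-protocol
#' defaults.
#'
#' @param seed root integer seed; every stage derives its own sub-stream.
#' @param out_dir output directory.
#' @param sim a [simulation_config()] (its seed is overridden by a child
#'   of the root seed).
#' @param n_iterations consensus resampling iterations per K.
#' @param k_range cluster numbers swept per platform and for COCA.
#' @param n_bootstrap stability-selection resamples.
#' @param grid list of [network_spec()]s for the grid search.
#' @param platform_k fixed per-platform cluster number (default 3, the
#'   integration target); `NULL` selects K per platform by the
#'   min-PAC/max-silhouette rule of [select_k()].
#' @param coca_k fixed COCA cluster number (default 3, as in the study);
#'   `NULL` applies the Delta(K) rule of [select_k_coca()].
#' @param delta_threshold Delta(K) "no remarkable increase" cutoff.
#' @param fc_threshold,fdr_threshold DEG cutoffs.
#' @param pair_fdr_cut,pair_r_cut key-pair correlation cutoffs.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("exococa_run_"),
                            sim = simulation_config(),
                            n_iterations = 100, k_range = 2:10,
                            n_bootstrap = 200,
                            grid = default_network_grid(),
                            platform_k = 3L, coca_k = 3L,
                            delta_threshold = 0.1,
                            fc_threshold = 1, fdr_threshold = 0.05,
                            pair_fdr_cut = 0.05, pair_r_cut = -0.3) {
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 n_iterations = as.integer(n_iterations),
                 k_range = as.integer(k_range),
                 n_bootstrap = as.integer(n_bootstrap), grid = grid,
                 platform_k = platform_k, coca_k = coca_k,
                 delta_threshold = delta_threshold,
                 fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
                 pair_fdr_cut = pair_fdr_cut, pair_r_cut = pair_r_cut),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full stratification pipeline on a synthetic cohort
#'
#' Executes simulate -> differential expression -> per-platform consensus
#' clustering -> COCA integration -> signature scoring -> classifier ->
#' key-pair filtering, writing every intermediate to `config$out_dir` and
#' returning a manifest with a config snapshot and per-file checksums.
#' Re-running with the same config reproduces every checksum.
#'
#' @param config a [pipeline_config()].
#' @return list with all stage outputs and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out)) stop_invalid("cannot create output directory ", out)
  timing <- c()
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, sec = proc.time()[["elapsed"]] - t0)
  }

  # -- stage 1: cohort -------------------------------------------------
  st <- clock({
    sim <- config$sim
    sim$seed <- child_seed(config$seed, "sim")
    cohort <- simulate_cohort(sim)
    interactions <- simulate_interaction_table(cohort, sim)
    write_cohort(cohort, file.path(out, "cohort"), interactions)
    list(cohort = cohort, interactions = interactions)
  })
  cohort <- st$val$cohort
  interactions <- st$val$interactions
  timing["simulate"] <- st$sec
  labels <- cohort$sample_labels
  is_cp <- labels != "Normal"
  cp_vs_normal <- factor(ifelse(is_cp, "CP", "Normal"),
                         levels = c("Normal", "CP"))

  # -- stage 2: differential expression per platform -------------------
  st <- clock({
    de <- lapply(cohort$matrices, differential_expression,
                 labels = cp_vs_normal, case = "CP")
    degs <- lapply(de, call_degs, fc_threshold = config$fc_threshold,
                   fdr_threshold = config$fdr_threshold)
    for (p in names(de))
      write_tsv(de[[p]], file.path(out, paste0("de_", p, ".tsv")))
    list(de = de, degs = degs)
  })
  de <- st$val$de
  degs <- st$val$degs
  timing["diffexpr"] <- st$sec

  # -- stage 3: per-platform consensus clustering of CP samples --------
  st <- clock({
    sweeps <- list()
    platform_k <- integer(0)
    platform_labels <- list()
    for (i in seq_along(cohort$matrices)) {
      p <- names(cohort$matrices)[i]
      params <- consensus_params(k_range = config$k_range,
                                 n_iterations = config$n_iterations,
                                 seed = child_seed(config$seed, "platform", i))
      sw <- consensus_sweep(cohort$matrices[[p]][is_cp, , drop = FALSE],
                            params)
      k <- config$platform_k %||% select_k(sw)
      sweeps[[p]] <- sw
      platform_k[p] <- k
      platform_labels[[p]] <- stats::setNames(sw$labels[[as.character(k)]],
                                              names(labels)[is_cp])
      write_tsv(data.frame(K = sw$k_range, A = unname(sw$A),
                           PAC = unname(sw$pac),
                           silhouette = unname(sw$silhouette)),
                file.path(out, paste0("sweep_", p, ".tsv")))
    }
    list(sweeps = sweeps, platform_k = platform_k,
         platform_labels = platform_labels)
  })
  sweeps <- st$val$sweeps
  platform_k <- st$val$platform_k
  platform_labels <- st$val$platform_labels
  timing["consensus"] <- st$sec

  # -- stage 4: COCA integration --------------------------------------
  st <- clock({
    indicator <- build_indicator_matrix(platform_labels)
    coca_sweep <- coca_cluster(indicator,
                               consensus_params(k_range = config$k_range,
                                                n_iterations = config$n_iterations,
                                                seed = child_seed(config$seed,
                                                                  "coca")))
    delta <- delta_k(coca_sweep$A)
    k_coca <- config$coca_k %||% select_k_coca(delta, config$delta_threshold)
    raw <- coca_sweep$labels[[as.character(k_coca)]]
    exo_cp <- signature_score(cohort$matrices$mrna[is_cp, , drop = FALSE],
                              cohort$signature_gene_sets$exocrine,
                              "exocrine")$score
    coca_labels <- order_subtypes(raw, exo_cp)
    names(coca_labels) <- names(labels)[is_cp]
    write_tsv(data.frame(sample = rownames(indicator), indicator,
                         check.names = FALSE),
              file.path(out, "coca_indicator.tsv"))
    write_tsv(cbind(delta), file.path(out, "coca_delta.tsv"))
    write_tsv(data.frame(sample = names(coca_labels),
                         coca = as.character(coca_labels)),
              file.path(out, "coca_labels.tsv"))
    list(indicator = indicator, sweep = coca_sweep, delta = delta,
         k = k_coca, labels = coca_labels)
  })
  coca <- st$val
  timing["coca"] <- st$sec

  # full 4-class labeling over all samples
  cl_chr <- stats::setNames(rep("Normal", length(labels)), names(labels))
  cl_chr[names(coca$labels)] <- as.character(coca$labels)
  class_labels <- factor(cl_chr,
                         levels = c("Normal",
                                    paste0("COCA", seq_len(coca$k))))

  # -- stage 5: signature scoring -------------------------------------
  st <- clock({
    exo <- signature_score(cohort$matrices$mrna,
                           cohort$signature_gene_sets$exocrine, "exocrine")
    endo <- signature_score(cohort$matrices$mrna,
                            cohort$signature_gene_sets$endocrine, "endocrine")
    quad <- quadrant_assign(exo$score, endo$score, normal = !is_cp)
    scores <- data.frame(sample = exo$sample, group = class_labels,
                         exocrine = exo$score, endocrine = endo$score,
                         quadrant = quad)
    write_tsv(scores, file.path(out, "signature_scores.tsv"))
    scores
  })
  scores <- st$val
  timing["signatures"] <- st$sec

  # -- stage 6: classifier --------------------------------------------
  st <- clock({
    stab <- stability_config(n_bootstrap = config$n_bootstrap,
                             seed = child_seed(config$seed, "stab"))
    X <- cohort$matrices$mirna
    sel <- select_feature_panel(X, class_labels, stab,
                                seed = child_seed(config$seed, "lasso"))
    if (length(sel$panel) == 0)
      stop_invalid("classifier stage: empty feature panel")
    split <- split_train_test(class_labels, 0.8,
                              seed = child_seed(config$seed, "split"))
    bundle <- grid_search(X[split$train, sel$panel, drop = FALSE],
                          class_labels[split$train],
                          X[split$test, sel$panel, drop = FALSE],
                          class_labels[split$test],
                          grid = config$grid,
                          seed = child_seed(config$seed, "grid"))
    reports <- list(
      train = evaluate_classifier(bundle, X[split$train, , drop = FALSE],
                                  class_labels[split$train]),
      test = evaluate_classifier(bundle, X[split$test, , drop = FALSE],
                                 class_labels[split$test]),
      all = evaluate_classifier(bundle, X, class_labels))
    save_classifier(bundle, file.path(out, "classifier.json"))
    write_tsv(bundle$grid_table, file.path(out, "grid_search.tsv"))
    list(selection = sel, split = split, bundle = bundle, reports = reports)
  })
  classifier <- st$val
  timing["classifier"] <- st$sec

  # -- stage 7: key miRNA-mRNA pairs ----------------------------------
  st <- clock({
    pc <- pair_correlations(cohort$matrices$mirna, cohort$matrices$mrna,
                            interactions, fdr_cut = config$pair_fdr_cut,
                            r_cut = config$pair_r_cut)
    neg <- filter_negative_pairs(pc, config$pair_fdr_cut, config$pair_r_cut)
    key <- select_key_pairs(neg, cohort$matrices$mirna,
                            cohort$matrices$mrna, class_labels)
    write_tsv(pc, file.path(out, "pair_correlations.tsv"))
    write_tsv(key, file.path(out, "key_pairs.tsv"))
    list(correlations = pc, filtered = neg, key = key)
  })
  keypairs <- st$val
  timing["keypairs"] <- st$sec

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, c("manifest.json", "report.txt")))
  checksums <- tools::md5sum(files)
  names(checksums) <- sub(paste0("^", out, "/?"), "", names(checksums))
  manifest <- list(
    package_version = as.character(utils::packageVersion("exococa")),
    seed = config$seed,
    config = list(n_iterations = config$n_iterations,
                  k_range = config$k_range,
                  n_bootstrap = config$n_bootstrap,
                  delta_threshold = config$delta_threshold,
                  fc_threshold = config$fc_threshold,
                  fdr_threshold = config$fdr_threshold,
                  pair_fdr_cut = config$pair_fdr_cut,
                  pair_r_cut = config$pair_r_cut,
                  sim = unclass(config$sim)[setdiff(names(config$sim),
                                                    "seed")]),
    checksums = as.list(checksums),
    timing_sec = as.list(round(timing, 3)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  result <- list(manifest = manifest, cohort = cohort, de = de, degs = degs,
                 sweeps = sweeps, platform_k = platform_k, coca = coca,
                 class_labels = class_labels, scores = scores,
                 classifier = classifier, keypairs = keypairs,
                 out_dir = out)
  writeLines(write_report(result), file.path(out, "report.txt"))
  invisible(result)
}

#' Human-readable run summary
#'
#' One document covering cohort sizes, chosen K per platform, the COCA
#' Delta(K) table, signature-score group medians, the classifier panel and
#' confusion matrices, and the key pairs. Regenerating the report from the
#' same run result is idempotent.
#'
#' @param result a [run_pipeline()] result.
#' @return character vector of report lines.
#' @export
write_report <- function(result) {
  fmt_conf <- function(conf) {
    c(paste("   ", paste(sprintf("%8s", colnames(conf)), collapse = " ")),
      vapply(rownames(conf), function(r)
        paste(sprintf("%8s", c(r, conf[r, ])), collapse = " "), character(1)))
  }
  lines <- c("exococa pipeline report", "=======================", "")
  tab <- table(result$cohort$sample_labels)
  lines <- c(lines,
             sprintf("Cohort: %d samples (%s)", sum(tab),
                     paste(names(tab), tab, sep = "=", collapse = ", ")), "")
  lines <- c(lines, "Chosen K per platform:",
             sprintf("  %s: K = %d", names(result$platform_k),
                     result$platform_k), "")
  lines <- c(lines, sprintf("COCA: K = %d (Delta threshold rule)",
                            result$coca$k),
             utils::capture.output(print(result$coca$delta,
                                         row.names = FALSE)), "")
  med <- stats::aggregate(cbind(exocrine, endocrine) ~ group,
                          data = result$scores, FUN = median)
  lines <- c(lines, "Signature-score medians by group:",
             utils::capture.output(print(med, row.names = FALSE)), "")
  lines <- c(lines, sprintf("Classifier panel (%d features): %s",
                            length(result$classifier$bundle$panel),
                            paste(result$classifier$bundle$panel,
                                  collapse = ", ")), "")
  for (set in names(result$classifier$reports)) {
    rep <- result$classifier$reports[[set]]
    lines <- c(lines, sprintf("Confusion (%s), accuracy %.3f:", set,
                              rep$accuracy), fmt_conf(rep$confusion), "")
  }
  key <- result$keypairs$key
  lines <- c(lines, sprintf("Key miRNA-mRNA pairs: %d", nrow(key)))
  if (nrow(key))
    lines <- c(lines, sprintf("  %s -> %s (r = %.3f, fdr = %.2e)",
                              key$mirna, key$mrna, key$r, key$fdr))
  lines
}
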