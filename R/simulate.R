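#' Configuration for the synthetic multi-omics cohort generator
#'
#' Defines the study conditions the generator emulates: a derivation cohort
#' of 22 healthy controls and 89 chronic pancreatitis (CP) patients profiled
#' on four exosomal RNA platforms (mRNA, miRNA, lncRNA, circRNA), with three
#' planted CP subtypes of monotonically increasing severity.
#'
#' Informative features shift their group mean by `severity_step` (log2
#' scale) per severity level, upward for mRNA-like markers and signature
#' genes, downward for the planted miRNAs; decoy features are exchangeable
#' across groups. Planted miRNA-mRNA pairs couple an mRNA to its miRNA
#' through a decreasing affine map plus noise, so their negative correlation
#' does not rest on shared group structure alone.
#'
#' @param n_normal,n_cp numbers of healthy-control and CP samples.
#' @param subtype_proportions three nonnegative fractions summing to 1,
#'   splitting `n_cp` across the planted subtypes.
#' @param n_features named counts of features per platform
#'   (`mrna`, `mirna`, `lncrna`, `circrna`).
#' @param n_informative_mirnas number of miRNAs carrying subtype signal.
#' @param frac_informative fraction of informative features on the other
#'   platforms.
#' @param severity_step log2-scale mean shift per subtype severity level;
#'   0 gives a null cohort.
#' @param n_signature_genes planted genes per signature (exocrine, endocrine).
#' @param n_planted_pairs,n_decoy_pairs planted negatively-coupled
#'   miRNA-mRNA pairs, and null decoy pairs for the interaction table.
#' @param noise_sd log2-scale residual standard deviation.
#' @param dispersion negative-binomial overdispersion for `mode = "counts"`.
#' @param mode `"log2"` (default) or `"counts"`.
#' @param seed integer seed; the cohort is a pure function of the config.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_normal = 22, n_cp = 89,
                              subtype_proportions = c(1, 1, 1) / 3,
                              n_features = c(mrna = 300, mirna = 300,
                                             lncrna = 200, circrna = 150),
                              n_informative_mirnas = 60,
                              frac_informative = 0.2,
                              severity_step = 1,
                              n_signature_genes = 20,
                              n_planted_pairs = 5,
                              n_decoy_pairs = 495,
                              noise_sd = 0.5,
                              dispersion = 0.2,
                              mode = c("log2", "counts"),
                              seed = 1L) {
  mode <- match.arg(mode)
  counts <- c(n_normal = n_normal, n_cp = n_cp,
              n_informative_mirnas = n_informative_mirnas,
              n_signature_genes = n_signature_genes,
              n_planted_pairs = n_planted_pairs, n_features)
  if (any(counts <= 0) || any(counts != floor(counts)))
    stop_invalid("all counts must be positive integers")
  if (n_decoy_pairs < 0)
    stop_invalid("n_decoy_pairs must be nonnegative")
  if (length(subtype_proportions) != 3 || any(subtype_proportions < 0) ||
      abs(sum(subtype_proportions) - 1) > 1e-9)
    stop_invalid("subtype_proportions must be 3 nonnegative fractions summing to 1")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (severity_step < 0) stop_invalid("severity_step must be >= 0")
  req <- setdiff(c("mrna", "mirna", "lncrna", "circrna"), names(n_features))
  if (length(req)) stop_invalid("n_features missing platform(s): ",
                                paste(req, collapse = ", "))
  n_inf_mrna <- max(round(frac_informative * n_features[["mrna"]]),
                    2 * n_signature_genes + n_planted_pairs)
  if (n_inf_mrna > n_features[["mrna"]])
    stop_invalid("mrna platform too small for the requested signatures and pairs")
  if (n_informative_mirnas > n_features[["mirna"]] ||
      n_planted_pairs > n_informative_mirnas)
    stop_invalid("miRNA platform too small for the requested informative set")
  structure(list(
    n_normal = as.integer(n_normal), n_cp = as.integer(n_cp),
    subtype_proportions = subtype_proportions,
    n_features = vapply(n_features, as.integer, integer(1)),
    n_informative_mirnas = as.integer(n_informative_mirnas),
    frac_informative = frac_informative,
    n_informative_mrna = as.integer(n_inf_mrna),
    severity_step = severity_step,
    n_signature_genes = as.integer(n_signature_genes),
    n_planted_pairs = as.integer(n_planted_pairs),
    n_decoy_pairs = as.integer(n_decoy_pairs),
    noise_sd = noise_sd, dispersion = dispersion,
    mode = mode, seed = as.integer(seed)
  ), class = "sim_config")
}

# per-sample severity level: Normal=0, COCA1..3 = 1..3
severity_levels <- function(labels) {
  match(as.character(labels), c("Normal", "COCA1", "COCA2", "COCA3")) - 1L
}

#' Simulate a multi-platform exosome cohort with planted subtypes
#'
#' Draws four samples-by-features expression matrices sharing one sample
#' index, with planted subtype structure, signature gene sets, negatively
#' coupled miRNA-mRNA pairs, and genomic coordinates for lncRNA/mRNA
#' features (one synthetic chromosome, 0-based half-open intervals).
#'
#' @param config a [simulation_config()].
#' @return an object of class `multiomics_cohort`: a list with elements
#'   `matrices` (named list of samples x features matrices), `sample_labels`
#'   (factor Normal/COCA1/COCA2/COCA3), `signature_gene_sets`,
#'   `planted_pairs` (data frame `mirna`, `mrna`), `feature_coordinates`
#'   (data frame `chrom`, `start`, `end`, `feature`), and `truth`
#'   (per-platform informative feature ids, directions, and the config).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "cohort"))

  n_sub <- diff(round(cumsum(c(0, config$subtype_proportions)) * config$n_cp))
  if (any(n_sub < 1))
    stop_invalid("a subtype proportion allocates < 1 sample")
  labels <- factor(rep(c("Normal", "COCA1", "COCA2", "COCA3"),
                       c(config$n_normal, n_sub)),
                   levels = c("Normal", "COCA1", "COCA2", "COCA3"))
  n <- length(labels)
  samples <- sprintf("S%03d", seq_len(n))
  level <- severity_levels(labels)
  step <- config$severity_step
  sd0 <- config$noise_sd

  feature_ids <- function(platform, p) sprintf("%s_%04d", platform, seq_len(p))

  draw_platform <- function(p, n_up, n_down) {
    base <- runif(p, 5, 11)
    eff <- numeric(p)
    eff[seq_len(n_up)] <- step
    if (n_down > 0) eff[n_up + seq_len(n_down)] <- -step
    mu <- outer(level, eff) + matrix(base, n, p, byrow = TRUE)
    pmax(mu + matrix(rnorm(n * p, 0, sd0), n, p), 0)
  }

  p_m <- config$n_features[["mrna"]]
  p_mi <- config$n_features[["mirna"]]
  p_l <- config$n_features[["lncrna"]]
  p_c <- config$n_features[["circrna"]]
  n_inf_m <- config$n_informative_mrna
  n_inf_mi <- config$n_informative_mirnas
  n_inf_l <- round(config$frac_informative * p_l)
  n_inf_c <- round(config$frac_informative * p_c)

  mrna <- draw_platform(p_m, n_inf_m, 0)                       # markers rise
  mirna <- draw_platform(p_mi, 0, n_inf_mi)                    # miRNAs fall
  lncrna <- draw_platform(p_l, ceiling(n_inf_l / 2), floor(n_inf_l / 2))
  circrna <- draw_platform(p_c, ceiling(n_inf_c / 2), floor(n_inf_c / 2))

  dimnames(mrna) <- list(samples, feature_ids("mRNA", p_m))
  dimnames(mirna) <- list(samples, feature_ids("miR", p_mi))
  dimnames(lncrna) <- list(samples, feature_ids("lnc", p_l))
  dimnames(circrna) <- list(samples, feature_ids("circ", p_c))

  # planted signature genes sit in the informative (rising) mRNA block
  n_sig <- config$n_signature_genes
  exo <- colnames(mrna)[seq_len(n_sig)]
  endo <- colnames(mrna)[n_sig + seq_len(n_sig)]

  # planted miRNA-mRNA pairs: mRNA drawn as a decreasing affine function of
  # its (falling) miRNA, guaranteeing negative correlation
  n_pair <- config$n_planted_pairs
  pair_mirna <- colnames(mirna)[seq_len(n_pair)]
  pair_mrna <- colnames(mrna)[2 * n_sig + seq_len(n_pair)]
  for (i in seq_len(n_pair)) {
    x <- mirna[, pair_mirna[i]]
    b0 <- runif(1, 6, 9)
    mrna[, pair_mrna[i]] <- pmax(b0 - (x - mean(x)) + rnorm(n, 0, sd0), 0)
  }

  if (config$mode == "counts") {
    to_counts <- function(m) {
      mu <- 2^m
      matrix(rnbinom(length(m), mu = mu, size = 1 / config$dispersion),
             nrow(m), ncol(m), dimnames = dimnames(m))
    }
    mrna <- to_counts(mrna); mirna <- to_counts(mirna)
    lncrna <- to_counts(lncrna); circrna <- to_counts(circrna)
  }

  # genomic coordinates for lncRNA and mRNA features on one synthetic
  # chromosome; 0-based, half-open
  ids <- c(colnames(lncrna), colnames(mrna))
  starts <- sort(sample.int(5e6, length(ids)))
  lens <- sample(500:5000, length(ids), replace = TRUE)
  coords <- data.frame(chrom = "chrS", start = starts, end = starts + lens,
                       feature = ids, stringsAsFactors = FALSE)

  structure(list(
    matrices = list(mrna = mrna, mirna = mirna,
                    lncrna = lncrna, circrna = circrna),
    sample_labels = stats::setNames(labels, samples),
    signature_gene_sets = list(exocrine = exo, endocrine = endo),
    planted_pairs = data.frame(mirna = pair_mirna, mrna = pair_mrna,
                               stringsAsFactors = FALSE),
    feature_coordinates = coords,
    scale = config$mode,
    truth = list(
      informative = list(
        mrna = colnames(mrna)[seq_len(n_inf_m)],
        mirna = colnames(mirna)[seq_len(n_inf_mi)],
        lncrna = colnames(lncrna)[seq_len(n_inf_l)],
        circrna = colnames(circrna)[seq_len(n_inf_c)]),
      config = config)
  ), class = "multiomics_cohort")
}

#' @export
print.multiomics_cohort <- function(x, ...) {
  cat("multiomics_cohort:", length(x$sample_labels), "samples (",
      paste(table(x$sample_labels), collapse = "/"), ")\n")
  for (p in names(x$matrices))
    cat("  ", p, ":", ncol(x$matrices[[p]]), "features\n")
  invisible(x)
}

#' Simulate a toy single-cell expression matrix with planted markers
#'
#' Cells-by-genes log-normal expression in which each declared marker gene
#' is elevated (on the log2 scale) in exactly one cell type; used to
#' exercise one-vs-rest marker discovery.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param cell_type_labels either a length-`n_cells` vector of labels or the
#'   set of type names (cells then allocated in near-equal blocks).
#' @param marker_spec named list (one element per cell type) of named
#'   numeric vectors: names are marker gene ids, values are log2-fold
#'   elevations in that type (0 = no elevation).
#' @param seed integer seed.
#' @param noise_sd log2-scale residual standard deviation.
#' @return list with `matrix` (cells x genes, nonnegative) and `labels`.
#' @export
simulate_single_cell <- function(n_cells, n_genes, cell_type_labels,
                                 marker_spec = list(), seed = 1L,
                                 noise_sd = 0.5) {
  if (n_cells < 1 || n_genes < 1) stop_invalid("dimensions must be positive")
  if (length(cell_type_labels) == n_cells) {
    labels <- as.character(cell_type_labels)
  } else {
    types <- as.character(cell_type_labels)
    labels <- rep(types, each = ceiling(n_cells / length(types)))[seq_len(n_cells)]
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  all_markers <- unlist(lapply(marker_spec, names), use.names = FALSE)
  if (anyDuplicated(all_markers))
    stop_invalid("marker gene assigned to more than one cell type: ",
                 paste(unique(all_markers[duplicated(all_markers)]),
                       collapse = ", "))
  if (!all(all_markers %in% genes))
    stop_invalid("marker_spec names unknown genes")
  set.seed(child_seed(seed, "sc"))
  base <- runif(n_genes, 2, 8)
  mu <- matrix(base, n_cells, n_genes, byrow = TRUE,
               dimnames = list(sprintf("C%04d", seq_len(n_cells)), genes))
  for (type in names(marker_spec)) {
    spec <- marker_spec[[type]]
    rows <- labels == type
    mu[rows, names(spec)] <- sweep(mu[rows, names(spec), drop = FALSE], 2,
                                   spec, `+`)
  }
  mat <- pmax(mu + matrix(rnorm(n_cells * n_genes, 0, noise_sd),
                          n_cells, n_genes), 0)
  list(matrix = mat, labels = labels)
}

#' Build an interaction table of planted and decoy miRNA-mRNA pairs
#'
#' Emulates (at small scale) an experimentally supported miRNA-mRNA
#' interaction catalogue: all planted pairs plus `n_decoy_pairs` null pairs.
#' Decoys are drawn from background (non-informative) features of both
#' platforms, so a decoy carries no opposing-trend signal by construction.
#'
#' @param cohort a [simulate_cohort()] result with planted pairs.
#' @param config the [simulation_config()] used (supplies `n_decoy_pairs`
#'   and the seed for the decoy draw).
#' @return data frame with columns `mirna`, `mrna`; no duplicates.
#' @export
simulate_interaction_table <- function(cohort, config) {
  stopifnot(inherits(cohort, "multiomics_cohort"),
            inherits(config, "sim_config"))
  planted <- cohort$planted_pairs
  if (nrow(planted) == 0) stop_invalid("cohort has no planted pairs")
  bg_mir <- setdiff(colnames(cohort$matrices$mirna),
                    cohort$truth$informative$mirna)
  bg_mrna <- setdiff(colnames(cohort$matrices$mrna),
                     cohort$truth$informative$mrna)
  n_avail <- length(bg_mir) * length(bg_mrna)
  if (config$n_decoy_pairs > n_avail)
    stop_invalid("requested ", config$n_decoy_pairs,
                 " decoys but only ", n_avail, " background combinations exist")
  if (config$n_decoy_pairs == 0)
    return(planted)
  set.seed(child_seed(config$seed, "interactions"))
  idx <- sample.int(n_avail, config$n_decoy_pairs)
  decoys <- data.frame(
    mirna = bg_mir[((idx - 1) %% length(bg_mir)) + 1],
    mrna = bg_mrna[((idx - 1) %/% length(bg_mir)) + 1],
    stringsAsFactors = FALSE)
  out <- rbind(planted, decoys)
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out))
  out
}

#' Write gene sets in GMT format
#'
#' One line per set: name, description, tab-separated member genes.
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                  vapply(fields, `[`, character(1), 1))
}

#' Write a cohort to delimited text files
#'
#' Writes one tab-delimited matrix per platform (first column `sample`,
#' header of feature ids), a labels file, the two signature gene sets as
#' one GMT, the interaction table, planted pairs, and feature coordinates.
#'
#' @param cohort a `multiomics_cohort`.
#' @param directory output directory (created if needed).
#' @param interactions optional interaction table to write alongside.
#' @return invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, directory, interactions = NULL) {
  if (!nzchar(directory)) stop_invalid("directory must be a nonempty path")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop_invalid("cannot create ", directory)
  files <- c()
  for (p in names(cohort$matrices)) {
    f <- file.path(directory, paste0(p, ".tsv"))
    df <- data.frame(sample = rownames(cohort$matrices[[p]]),
                     cohort$matrices[[p]], check.names = FALSE)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[p] <- f
  }
  f <- file.path(directory, "labels.tsv")
  write.table(data.frame(sample = names(cohort$sample_labels),
                         label = as.character(cohort$sample_labels)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["labels"] <- f
  files["signatures"] <- write_gmt(cohort$signature_gene_sets,
                                   file.path(directory, "signatures.gmt"))
  f <- file.path(directory, "planted_pairs.tsv")
  write.table(cohort$planted_pairs, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files["planted_pairs"] <- f
  f <- file.path(directory, "coordinates.tsv")
  write.table(cohort$feature_coordinates, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files["coordinates"] <- f
  if (!is.null(interactions)) {
    f <- file.path(directory, "interactions.tsv")
    write.table(interactions, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["interactions"] <- f
  }
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#' @param directory directory holding the files.
#' @return a `multiomics_cohort` (without the generator's `truth` element).
#' @export
read_cohort <- function(directory) {
  platforms <- c("mrna", "mirna", "lncrna", "circrna")
  mats <- lapply(platforms, function(p) {
    load_expression_matrix(file.path(directory, paste0(p, ".tsv")))
  })
  names(mats) <- platforms
  lab <- read.delim(file.path(directory, "labels.tsv"),
                    stringsAsFactors = FALSE)
  labels <- factor(lab$label, levels = c("Normal", "COCA1", "COCA2", "COCA3"))
  names(labels) <- lab$sample
  coords <- read.delim(file.path(directory, "coordinates.tsv"),
                       stringsAsFactors = FALSE)
  pairs <- read.delim(file.path(directory, "planted_pairs.tsv"),
                      stringsAsFactors = FALSE)
  structure(list(
    matrices = mats,
    sample_labels = labels,
    signature_gene_sets = read_gmt(file.path(directory, "signatures.gmt")),
    planted_pairs = pairs,
    feature_coordinates = coords,
    scale = "log2",
    truth = NULL
  ), class = "multiomics_cohort")
}
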