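#' Benjamini-Hochberg step-up adjustment
#'
#' Monotone step-up FDR adjustment: sort p-values, multiply by m/rank, and
#' enforce monotonicity by a cumulative minimum from the largest rank down.
#'
#' @param p_values numeric vector of probabilities in \[0, 1\].
#' @return adjusted probabilities, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop_invalid("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  adj <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  out <- numeric(m)
  # clamp at the raw p so adjusted >= raw holds exactly in floating point
  out[o] <- pmax(adj, p_values[o])
  out
}

#' Two-group differential expression on the log2 scale
#'
#' Welch two-sided t-test per feature with log2 fold change computed from
#' group means of `log2(x + pseudocount)` values, and BH adjustment across
#' tested features. Features with zero variance in both groups are flagged
#' and not tested; the degenerate equal-mean zero-variance case is reported
#' with `p = 1` by convention (and `p = 0` when the constant means differ).
#'
#' @param matrix samples x features numeric matrix.
#' @param labels two-group factor/vector aligned with rows; the first level
#'   (or the level named `case`) is the case group of the fold change.
#' @param case optional case-group level; defaults to the second level so
#'   log2FC is case minus control.
#' @param pseudocount added before log2 when `log_scale = FALSE`.
#' @param log_scale if TRUE (default) the matrix is already log2-scale.
#' @return data frame with columns `feature`, `log2FC`, `p_value`, `fdr`,
#'   `status`, `tested`.
#' @export
differential_expression <- function(matrix, labels, case = NULL,
                                    pseudocount = 1, log_scale = TRUE) {
  labels <- as.factor(droplevels(as.factor(labels)))
  if (nlevels(labels) != 2) stop_invalid("labels must define exactly 2 groups")
  if (any(table(labels) < 2)) stop_invalid("each group needs >= 2 samples")
  if (nrow(matrix) != length(labels))
    stop_invalid("labels do not align with matrix rows")
  case <- case %||% levels(labels)[2]
  ctrl <- setdiff(levels(labels), case)
  x <- if (log_scale) matrix else log2(matrix + pseudocount)
  a <- x[labels == case, , drop = FALSE]
  b <- x[labels == ctrl, , drop = FALSE]
  lfc <- colMeans(a) - colMeans(b)
  va <- apply(a, 2, var)
  vb <- apply(b, 2, var)
  tested <- !(va == 0 & vb == 0)
  p <- rep(NA_real_, ncol(x))
  for (j in which(tested))
    p[j] <- t.test(a[, j], b[, j])$p.value
  degenerate <- which(!tested)
  p[degenerate] <- ifelse(abs(lfc[degenerate]) < 1e-12, 1, 0)
  fdr <- rep(NA_real_, ncol(x))
  fdr[tested] <- bh_adjust(p[tested])
  fdr[degenerate] <- p[degenerate]
  out <- data.frame(feature = colnames(x), log2FC = unname(lfc),
                    p_value = p, fdr = fdr,
                    status = "not-DE", tested = tested,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$status[out$log2FC > 1 & out$fdr < 0.05] <- "up"
  out$status[out$log2FC < -1 & out$fdr < 0.05] <- "down"
  out
}

#' Call differentially expressed features at strict thresholds
#'
#' Retains records with `|log2FC| > fc_threshold` and `fdr < fdr_threshold`
#' (both strict, so boundary values are excluded) and sets their status.
#'
#' @param records a [differential_expression()] table.
#' @param fc_threshold,fdr_threshold strict cutoffs (defaults 1 and 0.05).
#' @return the filtered records with `status` set to up/down.
#' @export
call_degs <- function(records, fc_threshold = 1, fdr_threshold = 0.05) {
  keep <- abs(records$log2FC) > fc_threshold & records$fdr < fdr_threshold
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  out$status <- ifelse(out$log2FC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

validate_coords <- function(coords, what) {
  need <- c("chrom", "start", "end", "feature")
  if (!all(need %in% names(coords)))
    stop_invalid(what, " coordinates need columns ",
                 paste(need, collapse = ", "))
  if (any(coords$start >= coords$end))
    stop_invalid(what, " coordinates contain start >= end")
  coords
}

coords_to_granges <- function(coords) {
  # 0-based half-open -> 1-based closed
  GenomicRanges::GRanges(coords$chrom,
                         IRanges::IRanges(coords$start + 1L, coords$end))
}

#' Cis-acting lncRNA target prediction by genomic proximity
#'
#' A protein-coding gene is a candidate cis target of a lncRNA when the gap
#' between their intervals on the same chromosome is at most `window` bases
#' (overlapping or adjacent intervals count as gap 0). Distance is measured
#' between closest interval boundaries, strand-ignorant.
#'
#' @param lnc_coords,gene_coords data frames with columns `chrom`, `start`,
#'   `end`, `feature`; 0-based half-open intervals.
#' @param window maximum gap in bases (default 10000).
#' @return data frame `lncrna`, `mrna`, `mode` ("cis"), `evidence` (gap).
#' @export
lncrna_cis_targets <- function(lnc_coords, gene_coords, window = 10000) {
  lnc_coords <- validate_coords(lnc_coords, "lncRNA")
  gene_coords <- validate_coords(gene_coords, "gene")
  gl <- coords_to_granges(lnc_coords)
  gg <- coords_to_granges(gene_coords)
  hits <- GenomicRanges::findOverlaps(gl, gg, maxgap = window)
  gap <- GenomicRanges::distance(gl[S4Vectors::queryHits(hits)],
                                 gg[S4Vectors::subjectHits(hits)])
  data.frame(lncrna = lnc_coords$feature[S4Vectors::queryHits(hits)],
             mrna = gene_coords$feature[S4Vectors::subjectHits(hits)],
             mode = "cis", evidence = as.numeric(gap),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Trans-acting lncRNA target prediction by coexpression
#'
#' Emits a pair whenever the Pearson correlation between a lncRNA and an
#' mRNA across samples exceeds `r_threshold` (strict).
#'
#' @param lnc_matrix,mrna_matrix samples x features matrices sharing the
#'   sample ordering. Zero-variance features are skipped with a warning.
#' @param r_threshold correlation cutoff (default 0.5).
#' @return data frame `lncrna`, `mrna`, `mode` ("trans"), `evidence` (r).
#' @export
lncrna_trans_targets <- function(lnc_matrix, mrna_matrix, r_threshold = 0.5) {
  if (nrow(lnc_matrix) != nrow(mrna_matrix))
    stop_invalid("matrices must share samples")
  keep_l <- apply(lnc_matrix, 2, var) > 0
  keep_m <- apply(mrna_matrix, 2, var) > 0
  if (!all(keep_l) || !all(keep_m))
    warning(sum(!keep_l) + sum(!keep_m),
            " zero-variance feature(s) skipped", call. = FALSE)
  r <- cor(lnc_matrix[, keep_l, drop = FALSE],
           mrna_matrix[, keep_m, drop = FALSE])
  idx <- which(r > r_threshold, arr.ind = TRUE)
  out <- data.frame(lncrna = rownames(r)[idx[, 1]],
                    mrna = colnames(r)[idx[, 2]],
                    mode = "trans", evidence = r[idx],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$lncrna, out$mrna), , drop = FALSE]
}
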