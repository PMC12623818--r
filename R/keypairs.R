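#' Pearson correlations of catalogued miRNA-mRNA pairs
#'
#' For every pair in the interaction table present in both matrices:
#' Pearson r across all samples, a two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`, and BH adjustment across all
#' tested pairs. Pairs naming absent or zero-variance features are skipped
#' with a warning.
#'
#' @param mirna_matrix,mrna_matrix samples x features matrices sharing the
#'   sample ordering.
#' @param interaction_table data frame with columns `mirna`, `mrna`
#'   (extra columns ignored).
#' @param fdr_cut,r_cut thresholds stored in the `passes_correlation` flag
#'   (strict; defaults 0.05 and -0.3).
#' @return data frame `mirna`, `mrna`, `r`, `p_value`, `fdr`,
#'   `passes_correlation`.
#' @export
pair_correlations <- function(mirna_matrix, mrna_matrix, interaction_table,
                              fdr_cut = 0.05, r_cut = -0.3) {
  if (nrow(mirna_matrix) != nrow(mrna_matrix))
    stop_invalid("matrices must share samples")
  tab <- interaction_table[, c("mirna", "mrna")]
  ok_feat <- tab$mirna %in% colnames(mirna_matrix) &
    tab$mrna %in% colnames(mrna_matrix)
  if (!all(ok_feat))
    warning(sum(!ok_feat), " pair(s) reference absent features; skipped",
            call. = FALSE)
  tab <- tab[ok_feat, , drop = FALSE]
  v_mir <- apply(mirna_matrix[, unique(tab$mirna), drop = FALSE], 2, var)
  v_mr <- apply(mrna_matrix[, unique(tab$mrna), drop = FALSE], 2, var)
  ok_var <- v_mir[tab$mirna] > 0 & v_mr[tab$mrna] > 0
  if (!all(ok_var))
    warning(sum(!ok_var), " pair(s) with a zero-variance member; skipped",
            call. = FALSE)
  tab <- tab[ok_var, , drop = FALSE]
  n <- nrow(mirna_matrix)
  r <- vapply(seq_len(nrow(tab)), function(i) {
    cor(mirna_matrix[, tab$mirna[i]], mrna_matrix[, tab$mrna[i]])
  }, numeric(1))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  fdr <- bh_adjust(p)
  data.frame(mirna = tab$mirna, mrna = tab$mrna, r = r, p_value = p,
             fdr = fdr,
             passes_correlation = fdr < fdr_cut & r < r_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Negative-correlation filter on pair correlations
#'
#' Keeps pairs with `fdr < fdr_cut` and `r < r_cut`, both strict, so a
#' pair exactly at a boundary is excluded.
#'
#' @param pairs a [pair_correlations()] table.
#' @param fdr_cut,r_cut strict cutoffs (defaults 0.05 and -0.3).
#' @return the filtered rows.
#' @export
filter_negative_pairs <- function(pairs, fdr_cut = 0.05, r_cut = -0.3) {
  out <- pairs[pairs$fdr < fdr_cut & pairs$r < r_cut, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monotone-trend screen across ordered groups
#'
#' Tests the three adjacent comparisons of the ordered groups (Normal vs
#' COCA1, COCA1 vs COCA2, COCA2 vs COCA3) with a two-sided test per
#' comparison. The verdict is `up` (or `down`) only when all three
#' comparisons are significant at `p_cut` and all mean differences share
#' the sign; otherwise `none`.
#'
#' @param values numeric per-sample expression of one feature.
#' @param group_labels ordered groups; all four must be present with >= 2
#'   samples each.
#' @param p_cut per-comparison cutoff (default 0.05).
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @param groups the ordered group names.
#' @return list with `monotone_direction` (`up`/`down`/`none`),
#'   `p_values`, and `directions` (sign of adjacent mean differences).
#' @export
trend_screen <- function(values, group_labels, p_cut = 0.05,
                         test = c("welch", "wilcoxon"),
                         groups = c("Normal", "COCA1", "COCA2", "COCA3")) {
  test <- match.arg(test)
  group_labels <- as.character(group_labels)
  missing <- groups[!groups %in% group_labels]
  if (length(missing))
    stop_invalid("missing group(s): ", paste(missing, collapse = ", "))
  if (any(table(factor(group_labels, levels = groups)) < 2))
    stop_invalid("every group needs >= 2 samples")
  m <- length(groups) - 1
  p <- numeric(m)
  dir <- numeric(m)
  for (i in seq_len(m)) {
    a <- values[group_labels == groups[i]]
    b <- values[group_labels == groups[i + 1]]
    p[i] <- if (test == "welch") {
      if (var(a) == 0 && var(b) == 0) {
        # degenerate zero-variance groups: p by the equal-means convention
        if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0
      } else t.test(a, b)$p.value
    } else suppressWarnings(wilcox.test(a, b)$p.value)
    dir[i] <- sign(mean(b) - mean(a))
  }
  names(p) <- names(dir) <- paste(groups[-length(groups)], groups[-1],
                                  sep = " vs ")
  verdict <- if (all(p < p_cut) && all(dir == 1)) "up"
             else if (all(p < p_cut) && all(dir == -1)) "down"
             else "none"
  list(monotone_direction = verdict, p_values = p, directions = dir)
}

#' Select key miRNA-mRNA pairs by opposing monotone trends
#'
#' Applies [trend_screen()] to both members of every correlation-filtered
#' pair and keeps those whose miRNA falls monotonically while the mRNA
#' rises (the direction of the planted miR-24-3p-like / S100A8-like
#' coupling); `mirrored = TRUE` additionally admits the opposite
#' combination. Output is sorted by r ascending.
#'
#' @param filtered_pairs a [filter_negative_pairs()] table.
#' @param mirna_matrix,mrna_matrix expression matrices.
#' @param labels ordered group labels aligned with the matrix rows.
#' @param mirrored also keep miRNA-up / mRNA-down pairs (default FALSE).
#' @param ... passed to [trend_screen()].
#' @return the key-pair rows with added columns `mirna_trend`,
#'   `mrna_trend`.
#' @export
select_key_pairs <- function(filtered_pairs, mirna_matrix, mrna_matrix,
                             labels, mirrored = FALSE, ...) {
  if (nrow(filtered_pairs) == 0) {
    out <- cbind(filtered_pairs, mirna_trend = character(0),
                 mrna_trend = character(0))
    return(out)
  }
  mir_trend <- vapply(unique(filtered_pairs$mirna), function(f) {
    trend_screen(mirna_matrix[, f], labels, ...)$monotone_direction
  }, character(1))
  mrna_trend <- vapply(unique(filtered_pairs$mrna), function(f) {
    trend_screen(mrna_matrix[, f], labels, ...)$monotone_direction
  }, character(1))
  out <- filtered_pairs
  out$mirna_trend <- mir_trend[out$mirna]
  out$mrna_trend <- mrna_trend[out$mrna]
  keep <- out$mirna_trend == "down" & out$mrna_trend == "up"
  if (mirrored)
    keep <- keep | (out$mirna_trend == "up" & out$mrna_trend == "down")
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$r), , drop = FALSE]
  rownames(out) <- NULL
  out
}
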