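#' One-vs-rest marker genes by Wilcoxon rank-sum test
#'
#' For each (gene, cell type): log2 fold change
#' `log2((mean_in + c) / (mean_out + c))` between the type and all other
#' cells, a two-sided Wilcoxon rank-sum p-value, and BH adjustment within
#' each cell type. Types with fewer than `min_cells` cells are skipped with
#' a warning.
#'
#' @param cell_matrix cells x genes nonnegative expression matrix.
#' @param cell_labels cell-type labels aligned with rows (>= 2 types).
#' @param pseudocount fold-change pseudocount on the expression scale
#'   (default 0.01).
#' @param min_cells minimum cells per type (default 3).
#' @return data frame `gene`, `cell_type`, `log2FC`, `p_value`, `fdr`.
#' @export
find_markers <- function(cell_matrix, cell_labels, pseudocount = 0.01,
                         min_cells = 3) {
  cell_labels <- as.vector(cell_labels)
  if (nrow(cell_matrix) != length(cell_labels))
    stop_invalid("labels do not align with cells")
  sizes <- table(cell_labels)
  types <- names(sizes)
  if (length(types) < 2)
    stop_invalid("need >= 2 cell types; one-vs-rest is undefined otherwise")
  small <- types[sizes < min_cells]
  if (length(small)) {
    warning("skipping type(s) with < ", min_cells, " cells: ",
            paste(small, collapse = ", "), call. = FALSE)
    types <- setdiff(types, small)
    if (length(types) < 1) stop_invalid("no type large enough to test")
  }
  res <- list()
  for (type in types) {
    inside <- cell_labels == type
    a <- cell_matrix[inside, , drop = FALSE]
    b <- cell_matrix[!inside, , drop = FALSE]
    lfc <- log2((colMeans(a) + pseudocount) / (colMeans(b) + pseudocount))
    p <- vapply(seq_len(ncol(cell_matrix)), function(j) {
      suppressWarnings(wilcox.test(a[, j], b[, j])$p.value)
    }, numeric(1))
    res[[type]] <- data.frame(gene = colnames(cell_matrix), cell_type = type,
                              log2FC = unname(lfc), p_value = p,
                              fdr = bh_adjust(p), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Top-n signature genes per cell type, pooled
#'
#' Per requested cell type, the `n` significant markers (fdr < `fdr_cut`)
#' with largest log2 fold change; the union across types, de-duplicated,
#' forms the signature. Fewer than `n` significant genes returns all of
#' them with a warning.
#'
#' @param markers a [find_markers()] table.
#' @param cell_types cell types whose markers are pooled.
#' @param n markers per type (default 40).
#' @param fdr_cut significance gate before ranking (default 0.05).
#' @return character vector of signature genes.
#' @export
top_n_markers <- function(markers, cell_types, n = 40, fdr_cut = 0.05) {
  missing <- setdiff(cell_types, markers$cell_type)
  if (length(missing))
    stop_invalid("no marker records for type(s): ",
                 paste(missing, collapse = ", "))
  sets <- lapply(cell_types, function(type) {
    tab <- markers[markers$cell_type == type & markers$fdr < fdr_cut, ,
                   drop = FALSE]
    if (nrow(tab) < n)
      warning("only ", nrow(tab), " significant markers for ", type,
              " (requested ", n, ")", call. = FALSE)
    tab$gene[order(-tab$log2FC)][seq_len(min(n, nrow(tab)))]
  })
  unique(unlist(sets))
}

#' Median signature score per sample
#'
#' A sample's score on a signature is the median of its expression over
#' the signature genes present in the matrix; absent genes are dropped
#' (with a message reporting the count).
#'
#' @param sample_matrix samples x genes matrix.
#' @param gene_set character vector of signature genes.
#' @param name signature name carried into the output.
#' @return data frame `sample`, `signature`, `score`.
#' @export
signature_score <- function(sample_matrix, gene_set, name = "signature") {
  present <- intersect(gene_set, colnames(sample_matrix))
  if (length(present) == 0)
    stop_invalid("no signature gene present in the matrix")
  dropped <- length(gene_set) - length(present)
  if (dropped > 0)
    message(dropped, " signature gene(s) absent from the matrix, dropped")
  score <- apply(sample_matrix[, present, drop = FALSE], 1, median)
  data.frame(sample = rownames(sample_matrix) %||%
               seq_len(nrow(sample_matrix)),
             signature = name, score = unname(score),
             stringsAsFactors = FALSE)
}

#' Four-quadrant assignment of samples by two signature scores
#'
#' Samples are placed by strict comparison of the exocrine (x) and
#' endocrine (y) score against the cut lines; ties fall to the "low" side.
#'
#' @param exo_scores,endo_scores aligned numeric score vectors.
#' @param x_cut,y_cut finite cut lines; default to the median score of the
#'   samples flagged in `normal` (the healthy-control reference), else the
#'   overall medians.
#' @param normal optional logical vector marking reference samples.
#' @return factor in `{low/low, high/low, low/high, high/high}`.
#' @export
quadrant_assign <- function(exo_scores, endo_scores, x_cut = NULL,
                            y_cut = NULL, normal = NULL) {
  if (length(exo_scores) != length(endo_scores))
    stop_invalid("score vectors differ in length")
  ref <- normal %||% rep(TRUE, length(exo_scores))
  x_cut <- x_cut %||% median(exo_scores[ref])
  y_cut <- y_cut %||% median(endo_scores[ref])
  if (!is.finite(x_cut) || !is.finite(y_cut))
    stop_invalid("cuts must be finite")
  x <- ifelse(exo_scores > x_cut, "high", "low")
  y <- ifelse(endo_scores > y_cut, "high", "low")
  factor(paste(x, y, sep = "/"),
         levels = c("low/low", "high/low", "low/high", "high/high"))
}
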