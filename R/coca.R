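#' Binary indicator matrix from per-platform cluster calls
#'
#' Codes each platform's subtype calls into one binary column per
#' (platform, cluster); every sample has exactly one 1 per platform, so row
#' sums equal the number of platforms.
#'
#' @param platform_labels named list of per-platform label vectors, all
#'   covering the same samples (names or order must agree).
#' @return binary matrix, columns named `<platform>:<cluster>`.
#' @export
build_indicator_matrix <- function(platform_labels) {
  if (length(platform_labels) < 1) stop_invalid("no platform labels given")
  n <- length(platform_labels[[1]])
  samples <- names(platform_labels[[1]])
  cols <- list()
  for (p in names(platform_labels)) {
    lab <- platform_labels[[p]]
    if (length(lab) != n)
      stop_invalid("platform ", p, " covers a different sample set")
    if (anyNA(lab)) stop_invalid("platform ", p, " has missing calls")
    if (!is.null(samples) && !is.null(names(lab)) &&
        !identical(names(lab), samples))
      stop_invalid("platform ", p, " sample names disagree")
    for (cl in sort(unique(as.vector(lab))))
      cols[[paste0(p, ":", cl)]] <- as.integer(lab == cl)
  }
  out <- do.call(cbind, cols)
  rownames(out) <- samples
  out
}

#' Recover per-platform labels from an indicator matrix
#'
#' Inverse of [build_indicator_matrix()]: for each platform prefix, the
#' label of a sample is the cluster whose indicator column carries its 1.
#'
#' @param indicator binary indicator matrix with `<platform>:<cluster>`
#'   column names.
#' @return named list of per-platform character label vectors.
#' @export
labels_from_indicator <- function(indicator) {
  parts <- strsplit(colnames(indicator), ":", fixed = TRUE)
  platform <- vapply(parts, `[`, character(1), 1)
  cluster <- vapply(parts, function(p) paste(p[-1], collapse = ":"),
                    character(1))
  out <- list()
  for (p in unique(platform)) {
    block <- indicator[, platform == p, drop = FALSE]
    if (any(rowSums(block) != 1))
      stop_invalid("platform ", p, " rows do not sum to 1")
    idx <- apply(block, 1, which.max)
    out[[p]] <- stats::setNames(cluster[platform == p][idx],
                                rownames(indicator))
  }
  out
}

#' Cluster-of-cluster-assignments (COCA) integration
#'
#' Consensus-clusters the binary indicator matrix of per-platform subtype
#' calls with the same resampled-PAM machinery used per platform. Pearson
#' distance on binary rows is well defined whenever rows are non-constant;
#' constant rows trigger a fallback to Jaccard distance (with a warning).
#'
#' @param indicator a [build_indicator_matrix()] result (>= 2 columns).
#' @param params a [consensus_params()].
#' @return a [consensus_sweep()] over `params$k_range`.
#' @export
coca_cluster <- function(indicator, params = consensus_params()) {
  if (ncol(indicator) < 2) stop_invalid("need >= 2 indicator columns")
  v <- apply(indicator, 1, var)
  if (any(v == 0)) {
    warning("constant indicator row(s); using Jaccard distance", call. = FALSE)
    X <- indicator > 0
    inter <- X %*% t(X)
    sums <- rowSums(X)
    uni <- outer(sums, sums, `+`) - inter
    d <- 1 - inter / pmax(uni, 1)
    diag(d) <- 0
    dimnames(d) <- list(rownames(indicator), rownames(indicator))
    consensus_sweep(indicator, params, distance = d)
  } else {
    consensus_sweep(indicator, params)
  }
}

#' Proportional increase in CDF area, Delta(K)
#'
#' The selection statistic for the COCA cluster number:
#' `Delta(2) = A(2)` and, for K > 2,
#' `Delta(K) = (A(K+1) - A(K)) / A(K)` (a forward difference). The
#' conventional backward-difference variant
#' `Delta(K) = (A(K) - A(K-1)) / A(K-1)` is available via
#' `convention = "backward"`.
#'
#' @param A_values numeric vector of CDF areas named by K, covering a
#'   contiguous K range starting at 2.
#' @param convention `"forward"` (default, as used here) or `"backward"`.
#' @return object of class `delta_series`: data frame with columns `K`,
#'   `A`, `delta` (NA where the difference is undefined at the range edge).
#' @export
delta_k <- function(A_values, convention = c("forward", "backward")) {
  convention <- match.arg(convention)
  ks <- as.integer(names(A_values))
  if (anyNA(ks) || ks[1] != 2 || any(diff(ks) != 1))
    stop_invalid("A_values must be named by a contiguous K range starting at 2")
  A <- as.numeric(A_values)
  delta <- rep(NA_real_, length(ks))
  delta[1] <- A[1]
  if (convention == "forward") {
    for (i in which(ks > 2)) {
      if (i + 1 > length(A)) next  # A(K+1) unavailable at the top edge
      if (A[i] == 0) stop_invalid("A(K) = 0 in a denominator at K = ", ks[i])
      delta[i] <- (A[i + 1] - A[i]) / A[i]
    }
  } else {
    for (i in which(ks > 2)) {
      if (A[i - 1] == 0) stop_invalid("A(K-1) = 0 in a denominator at K = ", ks[i])
      delta[i] <- (A[i] - A[i - 1]) / A[i - 1]
    }
  }
  structure(data.frame(K = ks, A = A, delta = delta),
            class = c("delta_series", "data.frame"))
}

#' Choose the COCA cluster number from a Delta(K) series
#'
#' Returns the smallest K >= 3 whose Delta(K) falls below `threshold` --
#' the point where increasing the cluster number no longer appreciably
#' increases the CDF area. If no K qualifies, the largest evaluated K is
#' returned with a warning.
#'
#' @param delta a [delta_k()] series.
#' @param threshold "no remarkable increase" cutoff on Delta (default 0.1).
#' @return chosen integer K.
#' @export
select_k_coca <- function(delta, threshold = 0.1) {
  if (!nrow(delta)) stop_invalid("empty delta series")
  ok <- delta$K >= 3 & !is.na(delta$delta) & delta$delta < threshold
  if (any(ok)) return(min(delta$K[ok]))
  warning("no K with Delta(K) < ", threshold, "; returning max K",
          call. = FALSE)
  max(delta$K)
}

#' Rename clusters by increasing severity
#'
#' Maps arbitrary cluster labels onto the ordinal names COCA1, COCA2, ...
#' in increasing order of the clusters' median severity (signature) score.
#' Ties on the median break by cluster size (smaller first, with a
#' message), so the relabeling is a deterministic bijection.
#'
#' @param labels cluster labels per sample.
#' @param severity_scores numeric per-sample scores aligned with `labels`.
#' @return factor of COCA names, levels in severity order.
#' @export
order_subtypes <- function(labels, severity_scores) {
  if (length(labels) != length(severity_scores) || anyNA(severity_scores))
    stop_invalid("scores must be available for all samples")
  cl <- unique(as.vector(labels))
  med <- vapply(cl, function(c2) median(severity_scores[labels == c2]),
                numeric(1))
  size <- vapply(cl, function(c2) sum(labels == c2), numeric(1))
  if (anyDuplicated(med))
    message("tied cluster medians; breaking ties by cluster size")
  ord <- order(med, size)
  new_names <- paste0("COCA", seq_along(cl))
  map <- stats::setNames(new_names, cl[ord])
  factor(map[as.character(labels)], levels = new_names)
}
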