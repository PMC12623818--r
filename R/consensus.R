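#' Parameters for Monti consensus clustering
#'
#' Defaults follow the protocol used throughout the workflow: 1000
#' iterations of 80% sample resampling from 2 to 10 clusters with PAM on a
#' Pearson-correlation distance.
#'
#' @param k_range integer cluster numbers to sweep (min >= 2).
#' @param n_iterations resampling iterations per K.
#' @param subsample_fraction fraction of samples drawn (without
#'   replacement) per iteration, in (0, 1].
#' @param inner_algorithm inner clusterer; only `"PAM"` is provided.
#' @param distance sample-sample metric; only `"pearson"` (1 - r).
#' @param seed integer seed for the resampling stream.
#' @return object of class `consensus_params`.
#' @export
consensus_params <- function(k_range = 2:10, n_iterations = 1000,
                             subsample_fraction = 0.8,
                             inner_algorithm = "PAM", distance = "pearson",
                             seed = 1L) {
  if (min(k_range) < 2) stop_invalid("min(k_range) must be >= 2")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop_invalid("subsample_fraction must lie in (0, 1]")
  if (n_iterations < 1) stop_invalid("n_iterations must be positive")
  inner_algorithm <- match.arg(inner_algorithm, "PAM")
  distance <- match.arg(distance, "pearson")
  structure(list(k_range = as.integer(sort(unique(k_range))),
                 n_iterations = as.integer(n_iterations),
                 subsample_fraction = subsample_fraction,
                 inner_algorithm = inner_algorithm, distance = distance,
                 seed = as.integer(seed)),
            class = "consensus_params")
}

#' Pearson correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` over the feature profiles of samples i and j;
#' symmetric with zero diagonal, range \[0, 2\].
#'
#' @param matrix samples x features matrix with >= 2 features.
#' @return samples x samples distance matrix.
#' @export
pearson_distance <- function(matrix) {
  if (ncol(matrix) < 2) stop_invalid("need >= 2 features")
  v <- apply(matrix, 1, var)
  if (any(v == 0))
    stop_invalid("zero-variance sample(s): ",
                 paste(rownames(matrix)[v == 0] %||%
                         which(v == 0), collapse = ", "))
  d <- 1 - cor(t(matrix))
  d[d < 0] <- 0  # guard tiny negative rounding
  diag(d) <- 0
  d
}

#' PAM k-medoids on a precomputed distance matrix
#'
#' Classical BUILD + SWAP partitioning around medoids, minimising the total
#' distance of samples to their nearest medoid. Ties break toward the
#' smallest index, so the fit is deterministic; `seed` is accepted for
#' interface symmetry with the stochastic stages but is not consumed.
#'
#' @param distance square distance matrix (or `dist`).
#' @param k number of medoids, in \[1, n\].
#' @param seed ignored (the algorithm is deterministic).
#' @return list with `labels` (1..k per sample), `medoids` (indices),
#'   `cost` (total within-cluster distance to medoid).
#' @export
pam_cluster <- function(distance, k, seed = NULL) {
  if (inherits(distance, "dist")) distance <- as.matrix(distance)
  n <- nrow(distance)
  if (!isTRUE(all.equal(dim(distance), c(n, n))) || n < 1)
    stop_invalid("distance must be a square matrix")
  if (k < 1 || k > n) stop_invalid("k must lie in [1, n]")
  .pam_rcpp(unname(distance), as.integer(k))
}

#' Consensus matrix from resampled PAM runs
#'
#' Monti consensus: entry (i, j) is the fraction of resamples containing
#' both i and j in which they were assigned to the same cluster. The
#' diagonal is set to 1; pairs never co-sampled are set to 0 with a
#' warning.
#'
#' @param matrix samples x features matrix.
#' @param k number of clusters for the inner PAM runs.
#' @param params a [consensus_params()]; `k_range` is ignored here.
#' @param distance optional precomputed sample distance matrix.
#' @return samples x samples consensus matrix in \[0, 1\].
#' @export
consensus_matrix <- function(matrix, k, params = consensus_params(),
                             distance = NULL) {
  d <- distance %||% pearson_distance(matrix)
  n <- nrow(d)
  m <- max(round(params$subsample_fraction * n), k)
  hits <- matrix(0, n, n)
  both <- matrix(0, n, n)
  set.seed(child_seed(params$seed, "consensus", k))
  for (it in seq_len(params$n_iterations)) {
    idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
    fit <- pam_cluster(d[idx, idx, drop = FALSE], k)
    same <- outer(fit$labels, fit$labels, `==`)
    hits[idx, idx] <- hits[idx, idx] + same
    both[idx, idx] <- both[idx, idx] + 1
  }
  if (any(both == 0))
    warning("some sample pairs were never co-sampled; consensus set to 0",
            call. = FALSE)
  cm <- ifelse(both > 0, hits / pmax(both, 1), 0)
  diag(cm) <- 1
  dimnames(cm) <- list(rownames(matrix), rownames(matrix))
  cm
}

upper_entries <- function(cm) cm[upper.tri(cm)]

#' Area under the empirical CDF of consensus entries
#'
#' Over the sorted upper-triangle entries x1 <= ... <= xm,
#' `A = sum_i (x_i - x_(i-1)) * i / m` -- the area under the step CDF of
#' the consensus distribution. Crisp matrices (all entries at 0/1) give
#' larger areas than ambiguous ones.
#'
#' @param cm consensus matrix (n >= 2).
#' @return numeric area in \[0, 1\].
#' @export
cdf_area <- function(cm) {
  if (nrow(cm) < 2) stop_invalid("need >= 2 samples")
  x <- sort(upper_entries(cm))
  m <- length(x)
  if (m < 2) return(0)
  sum(diff(x) * (seq_len(m)[-1] / m))
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of upper-triangle consensus entries strictly inside the
#' ambiguity window `(lower, upper)`; low PAC indicates a stable
#' clustering.
#'
#' @param cm consensus matrix.
#' @param lower,upper window bounds, `0 <= lower < upper <= 1`.
#' @return fraction in \[0, 1\].
#' @export
pac_score <- function(cm, lower = 0.1, upper = 0.9) {
  if (!(lower >= 0 && lower < upper && upper <= 1))
    stop_invalid("require 0 <= lower < upper <= 1")
  x <- upper_entries(cm)
  mean(x > lower & x < upper)
}

#' Mean silhouette width of a labeled partition
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)` with a the mean
#' within-cluster distance and b the smallest mean distance to another
#' cluster; members of singleton clusters contribute 0.
#'
#' @param distance square distance matrix.
#' @param labels cluster labels (>= 2 nonempty clusters).
#' @return mean silhouette width, with per-sample widths in
#'   `attr(, "widths")`.
#' @export
silhouette_width <- function(distance, labels) {
  if (inherits(distance, "dist")) distance <- as.matrix(distance)
  labels <- as.vector(labels)
  cl <- unique(labels)
  if (length(cl) < 2) stop_invalid("need >= 2 clusters")
  n <- nrow(distance)
  widths <- numeric(n)
  sizes <- table(labels)
  for (i in seq_len(n)) {
    if (sizes[[as.character(labels[i])]] == 1) { widths[i] <- 0; next }
    same <- labels == labels[i]
    a <- sum(distance[i, same]) / (sum(same) - 1)
    b <- min(vapply(cl[cl != labels[i]], function(c2) {
      mean(distance[i, labels == c2])
    }, numeric(1)))
    widths[i] <- (b - a) / max(a, b)
  }
  structure(mean(widths), widths = widths)
}

#' Final cluster labels from a consensus matrix
#'
#' Average-linkage agglomerative clustering of `1 - consensus`, cut at k.
#'
#' @param cm consensus matrix.
#' @param k number of clusters.
#' @return integer labels 1..k.
#' @export
final_labels <- function(cm, k) {
  if (k < 1 || k > nrow(cm)) stop_invalid("k must lie in [1, n]")
  hc <- hclust(as.dist(1 - cm), method = "average")
  unname(cutree(hc, k = k))
}

#' Consensus-clustering sweep over a range of cluster numbers
#'
#' Runs [consensus_matrix()] for each K in `params$k_range` and records the
#' final labels, CDF area A(K), PAC and mean silhouette per K.
#'
#' @param matrix samples x features matrix.
#' @param params a [consensus_params()].
#' @param distance optional precomputed sample distance matrix (used both
#'   for the inner PAM runs and the silhouette).
#' @return object of class `consensus_sweep`: lists `consensus` and
#'   `labels` keyed by K, numeric vectors `A`, `pac`, `silhouette`, and the
#'   `params`.
#' @export
consensus_sweep <- function(matrix, params = consensus_params(),
                            distance = NULL) {
  d <- distance %||% pearson_distance(matrix)
  ks <- params$k_range
  if (max(ks) > nrow(d)) stop_invalid("k_range exceeds the number of samples")
  out <- list(k_range = ks, consensus = list(), labels = list(),
              A = numeric(0), pac = numeric(0), silhouette = numeric(0),
              params = params)
  for (k in ks) {
    key <- as.character(k)
    cm <- consensus_matrix(matrix, k, params, distance = d)
    lab <- final_labels(cm, k)
    out$consensus[[key]] <- cm
    out$labels[[key]] <- lab
    out$A[key] <- cdf_area(cm)
    out$pac[key] <- pac_score(cm)
    out$silhouette[key] <- as.numeric(silhouette_width(d, lab))
  }
  structure(out, class = "consensus_sweep")
}

#' @export
print.consensus_sweep <- function(x, ...) {
  cat("consensus_sweep over K =", paste(x$k_range, collapse = ", "), "\n")
  print(data.frame(K = x$k_range, A = unname(x$A), PAC = unname(x$pac),
                   silhouette = unname(x$silhouette)), row.names = FALSE)
  invisible(x)
}

#' Choose K by lowest PAC, ties broken by largest silhouette
#'
#' PAC values within `pac_tolerance` of the minimum are treated as tied;
#' among the tied K the largest mean silhouette wins, remaining ties going
#' to the smallest K.
#'
#' @param sweep a [consensus_sweep()] covering >= 2 values of K.
#' @param pac_tolerance tie window on PAC (default 0.01).
#' @return the chosen integer K.
#' @export
select_k <- function(sweep, pac_tolerance = 0.01) {
  if (length(sweep$k_range) < 2) stop_invalid("sweep must cover >= 2 K values")
  pac <- sweep$pac
  cand <- names(pac)[pac <= min(pac) + pac_tolerance]
  sil <- sweep$silhouette[cand]
  best <- cand[sil >= max(sil) - 1e-12]
  min(as.integer(best))
}
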