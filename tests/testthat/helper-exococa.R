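# shared fixtures: everything is generated in code, nothing read from disk

# a reduced cohort for fast unit tests; study-sized cohorts are built
# explicitly where a test's property depends on the full conditions
small_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_normal = 10, n_cp = 30,
    n_features = c(mrna = 60, mirna = 60, lncrna = 30, circrna = 24),
    n_informative_mirnas = 12, n_signature_genes = 6,
    n_planted_pairs = 3, n_decoy_pairs = 30, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

small_cohort <- function(seed = 1L, ...) simulate_cohort(small_config(seed, ...))

fast_params <- function(seed = 1L, ...) {
  defaults <- list(k_range = 2:5, n_iterations = 30, seed = seed)
  do.call(consensus_params, utils::modifyList(defaults, list(...)))
}

# brute-force BH step-up: adjusted(i) = min over j >= i of p(j) * m / j on
# sorted values, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive PAM optimum: minimum cost over all medoid subsets of size k
pam_exhaustive_cost <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  sets <- utils::combn(n, k)
  for (j in seq_len(ncol(sets))) {
    cost <- sum(apply(d[, sets[, j], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of all
# assignments of the pooled ranks to group 1 (tie-free data only)
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  w_all <- apply(sets, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  # symmetric null: both tails counted once
  min(1, mean(abs(w_all - mu) >= abs(w_obs - mu)))
}

# canonical labels in order of first appearance, for partition comparison
relabel_first <- function(x) match(x, unique(x))

# Pearson r of two short vectors straight from the textbook formula
pearson_hand <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
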