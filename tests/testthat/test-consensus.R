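test_that("pearson distance matches 1 - r with its limit cases", {
  set.seed(1)
  m <- matrix(rnorm(5 * 12), 5, 12)
  m[2, ] <- m[1, ]                      # duplicate sample
  m[3, ] <- -(m[1, ] - mean(m[1, ])) + mean(m[1, ])  # anti-profile
  d <- pearson_distance(m)
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 2)
  expect_equal(unname(d), unname(1 - cor(t(m))), tolerance = 1e-12)
  expect_true(isSymmetric(d))
  bad <- m; bad[4, ] <- 7
  expect_error(pearson_distance(bad), "zero-variance sample")
})

test_that("PAM returns swap-stable local optima that usually attain the global one", {
  set.seed(2)
  attained <- integer(0)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    d <- as.matrix(dist(x))
    for (k in 2:min(4, n - 1)) {
      fit <- pam_cluster(d, k)
      opt <- pam_exhaustive_cost(d, k)
      expect_gte(fit$cost, opt - 1e-10)
      attained <- c(attained, abs(fit$cost - opt) < 1e-10)
      # local optimality: no single medoid exchange improves the cost
      med <- fit$medoids
      for (a in seq_along(med)) for (h in setdiff(seq_len(n), med)) {
        swapped <- med; swapped[a] <- h
        cost_h <- sum(apply(d[, swapped, drop = FALSE], 1, min))
        expect_gte(cost_h, fit$cost - 1e-10)
      }
    }
  }
  # BUILD+SWAP reaches the exhaustive optimum on the large majority of
  # instances (it is a local search, so not on every one)
  expect_gte(mean(attained), 0.85)
})

test_that("PAM agrees with the reference implementation's objective", {
  skip_if_not_installed("cluster")
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
    for (k in 2:4) {
      ours <- pam_cluster(d, k)$cost
      ref <- cluster::pam(as.dist(d), k)$objective[["swap"]] * n
      # both are BUILD+SWAP local searches; ours must never end up worse
      expect_lte(ours, ref + 1e-8)
    }
  }
})

test_that("PAM handles its limit cases and agrees with cluster::pam cost", {
  set.seed(3)
  d <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  fit <- pam_cluster(d, 6)
  expect_equal(fit$cost, 0)
  expect_equal(sort(fit$medoids), 1:6)
  # two tight, well-separated triples
  x <- rbind(matrix(rnorm(9, 0, 0.05), 3), matrix(rnorm(9, 10, 0.05), 3))
  fit2 <- pam_cluster(as.matrix(dist(x)), 2)
  expect_equal(fit2$labels[1:3], rep(fit2$labels[1], 3))
  expect_equal(fit2$labels[4:6], rep(fit2$labels[4], 3))
  expect_false(fit2$labels[1] == fit2$labels[4])
  expect_error(pam_cluster(d, 0), "k must lie")
  expect_error(pam_cluster(d, 7), "k must lie")
  skip_if_not_installed("cluster")
  for (k in 2:4) {
    ours <- pam_cluster(d, k)$cost
    ref <- cluster::pam(as.dist(d), k)$objective[["swap"]] * 6
    expect_lte(ours, ref + 1e-10)  # never worse than the reference optimum
  }
})

test_that("consensus matrix equals a brute-force co-assignment tally", {
  set.seed(4)
  m <- matrix(rnorm(6 * 10), 6, 10)
  params <- consensus_params(n_iterations = 20, subsample_fraction = 0.8,
                             seed = 99)
  cm <- consensus_matrix(m, 2, params)
  # replay the identical subsample stream and tally by hand
  d <- pearson_distance(m)
  hits <- both <- matrix(0, 6, 6)
  set.seed(child_seed(99, "consensus", 2))
  for (it in 1:20) {
    idx <- sort(sample.int(6, max(round(0.8 * 6), 2)))
    lab <- pam_cluster(d[idx, idx], 2)$labels
    hits[idx, idx] <- hits[idx, idx] + outer(lab, lab, `==`)
    both[idx, idx] <- both[idx, idx] + 1
  }
  want <- ifelse(both > 0, hits / pmax(both, 1), 0)
  diag(want) <- 1
  expect_equal(unname(cm), want, tolerance = 1e-12)
})

test_that("duplicated blocks give a 0/1 consensus; full sampling is binary", {
  m <- rbind(matrix(rep(c(1, 5, 2, 8), each = 4), 4, 4, byrow = FALSE) +
               matrix(rnorm(16, 0, 0.01), 4),
             matrix(rep(c(9, 1, 7, 0), each = 4), 4, 4, byrow = FALSE) +
               matrix(rnorm(16, 0, 0.01), 4))
  set.seed(10)
  cm <- consensus_matrix(m, 2, consensus_params(n_iterations = 50, seed = 1))
  expect_true(all(cm[1:4, 1:4] == 1))
  expect_true(all(cm[5:8, 5:8] == 1))
  expect_true(all(cm[1:4, 5:8] == 0))
  cm_full <- consensus_matrix(m, 2, consensus_params(subsample_fraction = 1,
                                                     n_iterations = 5,
                                                     seed = 1))
  expect_true(all(cm_full %in% c(0, 1)))
})

test_that("CDF area matches hand-evaluated step integrals", {
  # upper triangle {0, 0.5, 1}: A = 0.5 * 2/3 + 0.5 * 1
  cm <- diag(3)
  cm[upper.tri(cm)] <- c(0, 0.5, 1)
  cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
  expect_equal(cdf_area(cm), 0.5 * 2 / 3 + 0.5 * 1)
  # all entries equal: single jump, zero area
  cm2 <- matrix(0.7, 4, 4); diag(cm2) <- 1
  expect_equal(cdf_area(cm2), 0)
  # half 0s, half 1s among m = 6 entries: only increment at the first 1
  cm3 <- diag(4)
  cm3[upper.tri(cm3)] <- c(0, 0, 0, 1, 1, 1)
  cm3[lower.tri(cm3)] <- t(cm3)[lower.tri(cm3)]
  expect_equal(cdf_area(cm3), 1 * 4 / 6)
})

test_that("PAC counts the ambiguous window strictly", {
  cm <- diag(4)
  cm[upper.tri(cm)] <- c(0, 0.2, 0.5, 1, 1, 0)
  cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
  expect_equal(pac_score(cm), 2 / 6)        # 0.2 and 0.5 inside (0.1, 0.9)
  crisp <- diag(4); crisp[upper.tri(crisp)] <- rep(c(0, 1), 3)
  crisp[lower.tri(crisp)] <- t(crisp)[lower.tri(crisp)]
  expect_equal(pac_score(crisp), 0)
  amb <- matrix(0.5, 4, 4); diag(amb) <- 1
  expect_equal(pac_score(amb), 1)
  expect_error(pac_score(cm, lower = 0.9, upper = 0.1), "lower < upper")
})

test_that("silhouette matches a per-point hand oracle and cluster::silhouette", {
  x <- c(0, 0.2, 0.4, 5, 5.2, 9)
  d <- as.matrix(dist(x))
  lab <- c(1, 1, 1, 2, 2, 3)
  s <- silhouette_width(d, lab)
  hand <- vapply(1:6, function(i) {
    if (sum(lab == lab[i]) == 1) return(0)
    a <- mean(d[i, lab == lab[i] & seq_len(6) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(c2) mean(d[i, lab == c2]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(as.numeric(s), mean(hand), tolerance = 1e-12)
  expect_equal(attr(s, "widths"), hand, tolerance = 1e-12)
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(c(1, 1, 1, 2, 2, 2), dmatrix = d)
  expect_equal(as.numeric(silhouette_width(d, c(1, 1, 1, 2, 2, 2))),
               mean(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("silhouette of well-separated clusters is near 1, of random labels near 0", {
  set.seed(6)
  x <- rbind(matrix(rnorm(20, 0, 1e-3), 10, 2),
             matrix(rnorm(20, 50, 1e-3), 10, 2))
  d <- as.matrix(dist(x))
  expect_gt(as.numeric(silhouette_width(d, rep(1:2, each = 10))), 0.9)
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    pts <- matrix(rnorm(40), 20, 2)
    as.numeric(silhouette_width(as.matrix(dist(pts)),
                                sample(rep(1:2, each = 10))))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
  expect_error(silhouette_width(d, rep(1, 20)), ">= 2 clusters")
})

test_that("select_k minimises PAC and breaks ties by silhouette", {
  sweep <- structure(list(k_range = 2:4,
                          pac = c(`2` = 0.30, `3` = 0.02, `4` = 0.20),
                          silhouette = c(`2` = 0.9, `3` = 0.4, `4` = 0.5)),
                     class = "consensus_sweep")
  expect_equal(select_k(sweep), 3)
  tied <- structure(list(k_range = 2:4,
                         pac = c(`2` = 0.020, `3` = 0.015, `4` = 0.30),
                         silhouette = c(`2` = 0.8, `3` = 0.5, `4` = 0.9)),
                    class = "consensus_sweep")
  expect_equal(select_k(tied), 2)  # PAC within 0.01 tie -> silhouette decides
})

test_that("final labels recover blocks and are permutation-equivariant", {
  cm <- matrix(0, 6, 6)
  cm[1:3, 1:3] <- 1; cm[4:6, 4:6] <- 1
  lab <- final_labels(cm, 2)
  expect_equal(lab[1:3], rep(lab[1], 3))
  expect_equal(lab[4:6], rep(lab[4], 3))
  expect_false(lab[1] == lab[4])
  # hand-traced 4-sample average-linkage merge
  cm4 <- diag(4)
  cm4[upper.tri(cm4)] <- c(0.9, 0.2, 0.1, 0.3, 0.8, 0.15)
  cm4[lower.tri(cm4)] <- t(cm4)[lower.tri(cm4)]
  # 1-consensus: d12=0.1 merges first; then avg d({12},4)=0.45 beats
  # d({12},3)=0.85 and d34=0.85, so the 2-cluster cut is {1,2,4} vs {3}
  expect_equal(relabel_first(final_labels(cm4, 2)), c(1, 1, 2, 1))
  # permutation equivariance
  set.seed(9)
  m <- matrix(rnorm(8 * 6), 8, 6)
  cm8 <- consensus_matrix(m, 2, consensus_params(n_iterations = 40, seed = 5))
  perm <- sample(8)
  lab0 <- final_labels(cm8, 3)
  labp <- final_labels(cm8[perm, perm], 3)
  expect_equal(relabel_first(labp), relabel_first(lab0[perm]))
})

test_that("crisping an ambiguous consensus raises its CDF area", {
  set.seed(11)
  cm <- matrix(0.5, 6, 6) + matrix(runif(36, -0.1, 0.1), 6, 6)
  cm <- (cm + t(cm)) / 2; diag(cm) <- 1
  crisp <- (cm > 0.5) * 1; diag(crisp) <- 1
  expect_gt(cdf_area(crisp), cdf_area(cm))
  expect_equal(pac_score(crisp), 0)
})
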