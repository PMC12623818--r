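# independent logistic LRT oracle: deviances by direct likelihood
# maximisation with optim, no glm machinery
logistic_lrt_oracle <- function(x, yb) {
  nll <- function(beta, X) {
    eta <- X %*% beta
    sum(log(1 + exp(eta))) - sum(yb * eta)
  }
  f1 <- optim(c(0, 0), nll, X = cbind(1, x), method = "BFGS")
  f0 <- optim(0, nll, X = matrix(1, length(yb)), method = "BFGS")
  pchisq(2 * (f0$value - f1$value), df = 1, lower.tail = FALSE)
}

test_that("univariate screen keeps informative and drops null features", {
  set.seed(1)
  y <- factor(rep(c("Normal", "COCA1", "COCA2", "COCA3"), each = 12))
  X <- cbind(flat = rep(3, 48),
             null = rnorm(48),
             info = as.numeric(y) + rnorm(48, 0, 0.3),
             sep = ifelse(y == "COCA3", 10, 0) + rnorm(48, 0, 0.01))
  kept <- univariate_screen(X, y, stability_config())
  expect_true(all(c("info", "sep") %in% kept))
  expect_false("flat" %in% kept)
  expect_false("null" %in% kept)
  p <- attr(kept, "p_values")
  expect_equal(unname(p["sep"]), 0)  # perfect separation flagged significant
})

test_that("logistic LRT p-values match an optim-based oracle", {
  set.seed(2)
  for (rep in 1:5) {
    x <- rnorm(8)
    yb <- rbinom(8, 1, plogis(0.5 * x))
    if (length(unique(yb)) < 2) next
    got <- exococa:::logistic_lrt_p(x, yb)
    if (isTRUE(attr(got, "separated"))) next  # flagged path tested elsewhere
    expect_equal(as.numeric(got), logistic_lrt_oracle(x, yb),
                 tolerance = 1e-4)
  }
})

test_that("stability selection retains strong features and rejects noise", {
  set.seed(3)
  y <- factor(rep(c("Normal", "COCA1", "COCA2", "COCA3"), c(22, 30, 29, 30)))
  n <- length(y)
  X <- cbind(planted = as.numeric(y) * 3 + rnorm(n),  # >= 3 SD group shift
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n),
             constant = rep(1, n))
  cfg <- stability_config(n_bootstrap = 200, seed = 7)
  stable <- bootstrap_stability_select(X, y, colnames(X), cfg)
  expect_true("planted" %in% stable)
  expect_false("constant" %in% stable)
  freq <- attr(stable, "frequency")
  expect_equal(unname(freq["planted"]), 1)          # significant in 100%
  expect_true(all(freq[c("noise1", "noise2", "noise3")] <= 0.95))
})

test_that("pure-noise features never clear the stability bar", {
  ok <- vapply(1:5, function(s) {
    set.seed(s)
    y <- factor(rep(c("a", "b"), each = 20))
    X <- matrix(rnorm(40 * 10), 40, 10,
                dimnames = list(NULL, paste0("n", 1:10)))
    cfg <- stability_config(n_bootstrap = 100, seed = s)
    length(bootstrap_stability_select(X, y, colnames(X), cfg)) == 0
  }, logical(1))
  expect_true(all(ok))
})

test_that("LASSO reduction keeps planted features and stays within candidates", {
  set.seed(4)
  y <- factor(rep(c("Normal", "COCA1", "COCA2", "COCA3"), c(22, 30, 29, 30)))
  n <- length(y)
  planted <- sapply(1:5, function(i) as.numeric(y) * 2 + rnorm(n, 0, 0.5))
  colnames(planted) <- paste0("info", 1:5)
  noise <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("z", 1:30)))
  X <- cbind(planted, noise)
  panel <- suppressWarnings(lasso_select(X, y, colnames(X), seed = 11))
  expect_true(all(paste0("info", 1:5) %in% panel))
  expect_true(all(panel %in% colnames(X)))
  # duplicated informative feature: panel never exceeds the candidate set
  X2 <- cbind(X[, 1:6], dup = X[, "info1"])
  panel2 <- suppressWarnings(lasso_select(X2, y, colnames(X2), seed = 11))
  expect_lte(length(panel2), ncol(X2))
  expect_error(lasso_select(X, y, "info1", seed = 1), ">= 2 stable")
})

test_that("train/test splits are stratified, disjoint and reproducible", {
  y <- factor(rep(c("a", "b", "c", "d"), each = 25))
  sp <- split_train_test(y, 0.8, seed = 5)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_true(all(table(y[sp$train]) == 20))
  expect_true(all(table(y[sp$test]) == 5))
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_train_test(y, 0.8, seed = 5))
  expect_error(split_train_test(factor(c("a", "a", "b")), 0.8, 1),
               ">= 2 samples")
})

test_that("a linear (no-hidden-layer) network fits separable data exactly", {
  set.seed(6)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c("neg", "pos"), each = 20)
  net <- train_network(X, y, network_spec(hidden = integer(0),
                                          max_epochs = 200), seed = 1)
  expect_equal(mean(predict(net, X)$class == y), 1)
  # accepted-loss trajectory is non-increasing (convex instance)
  expect_true(all(diff(net$loss_trace) <= 1e-12))
})

test_that("a small hidden layer separates four Gaussian blobs", {
  set.seed(7)
  centers <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5), 4, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(20, 0, 0.5), 10, 2), 2, centers[i, ], `+`)))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(paste0("c", 1:4), each = 10))
  net <- train_network(X, y, network_spec(hidden = 8, max_epochs = 400),
                       seed = 2)
  expect_gte(mean(predict(net, X)$class == y), 0.95)
  pr <- predict(net, X)$prob
  expect_equal(unname(rowSums(pr)), rep(1, 40), tolerance = 1e-9)
})

test_that("training is deterministic given the seed", {
  set.seed(8)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("x", "y"), 15)
  n1 <- train_network(X, y, network_spec(max_epochs = 50), seed = 3)
  n2 <- train_network(X, y, network_spec(max_epochs = 50), seed = 3)
  expect_identical(n1$weights, n2$weights)
})

test_that("grid search picks the best test accuracy and records every spec", {
  set.seed(9)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 5), 30, 2))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("a", "b"), each = 30))
  sp <- split_train_test(y, 0.8, seed = 1)
  # an effectively untrained spec against a sane one
  grid <- list(network_spec(hidden = 16, max_epochs = 1, step0 = 1e-9),
               network_spec(hidden = integer(0), max_epochs = 200))
  b <- grid_search(X[sp$train, ], y[sp$train], X[sp$test, ], y[sp$test],
                   grid, seed = 4)
  expect_equal(nrow(b$grid_table), 2)
  expect_equal(b$best_index, 2)
  # single-spec grid returns that spec
  b1 <- grid_search(X[sp$train, ], y[sp$train], X[sp$test, ], y[sp$test],
                    grid[2], seed = 4)
  expect_equal(b1$best_index, 1)
  expect_error(grid_search(X, y, X, y, list(), 1), "empty")
})

test_that("evaluation metrics match the printed external-validation example", {
  # 107 subjects: 78 of 89 CP and 14 of 18 non-CP called correctly
  conf <- matrix(c(78, 11, 4, 14), 2, 2, byrow = TRUE,
                 dimnames = list(truth = c("CP", "non-CP"),
                                 predicted = c("CP", "non-CP")))
  m <- classification_metrics(conf)
  expect_equal(round(100 * m$sensitivity[["CP"]], 1), 87.6)
  expect_equal(round(100 * m$specificity[["CP"]], 1), 77.8)
  expect_equal(m$accuracy, (78 + 14) / 107)
})

test_that("evaluation metrics match a brute-force count oracle", {
  set.seed(10)
  lev <- c("w", "x", "y", "z")
  truth <- sample(lev, 60, TRUE)
  pred <- sample(lev, 60, TRUE)
  conf <- table(factor(truth, lev), factor(pred, lev))
  m <- classification_metrics(conf)
  expect_equal(m$accuracy, mean(truth == pred))
  for (cl in lev) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    expect_equal(unname(m$sensitivity[cl]), tp / (tp + fn))
    expect_equal(unname(m$specificity[cl]), tn / (tn + fp))
  }
})

test_that("prediction enforces the panel and reloads exactly from JSON", {
  set.seed(11)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 4), 30, 2))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("a", "b"), each = 30))
  sp <- split_train_test(y, 0.8, seed = 2)
  b <- grid_search(X[sp$train, ], y[sp$train], X[sp$test, ], y[sp$test],
                   list(network_spec(hidden = 4, max_epochs = 100)), seed = 5)
  expect_error(predict(b, X[, "f1", drop = FALSE]), "f2")
  f <- withr::local_tempfile(fileext = ".json")
  save_classifier(b, f)
  b2 <- load_classifier(f)
  expect_equal(predict(b2, X)$prob, predict(b, X)$prob, tolerance = 1e-12)
  expect_identical(b2$panel, b$panel)
})

test_that("the selection cascade is monotone and leak-free", {
  co <- simulate_cohort(small_config(seed = 17))
  y <- co$sample_labels
  X <- co$matrices$mirna
  sel <- suppressWarnings(
    select_feature_panel(X, y, stability_config(n_bootstrap = 50, seed = 3),
                         seed = 3))
  expect_true(all(sel$panel %in% sel$stable))
  expect_true(all(sel$stable %in% sel$screened))
  expect_true(all(sel$screened %in% colnames(X)))
  # standardisation parameters come from the training rows only
  sp <- split_train_test(y, 0.8, seed = 4)
  net <- train_network(X[sp$train, sel$panel, drop = FALSE], y[sp$train],
                       network_spec(max_epochs = 30), seed = 1)
  expect_equal(net$center, colMeans(X[sp$train, sel$panel, drop = FALSE]))
  expect_equal(net$scale,
               apply(X[sp$train, sel$panel, drop = FALSE], 2, sd))
})
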