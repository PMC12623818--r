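#' Configuration for the feature-selection cascade
#'
#' Thresholds of the univariate screen and the bootstrap stability
#' selection: features pass the screen at `p < p_univariate`, then must be
#' significant at `p < p_bootstrap` in strictly more than `retain_fraction`
#' of `n_bootstrap` resamples of `bootstrap_fraction` of the data.
#'
#' @param p_univariate univariate logistic screen cutoff (default 0.01).
#' @param bootstrap_fraction fraction of samples per resample (default 0.70).
#' @param n_bootstrap number of resamples (default 1000).
#' @param p_bootstrap per-resample significance cutoff (default 0.05).
#' @param retain_fraction stability bar, strict (default 0.95).
#' @param replace draw resamples with replacement (classical bootstrap)
#'   instead of the default 70% subsampling without replacement.
#' @param seed integer seed for the resampling stream.
#' @return object of class `stability_config`.
#' @export
stability_config <- function(p_univariate = 0.01, bootstrap_fraction = 0.70,
                             n_bootstrap = 1000, p_bootstrap = 0.05,
                             retain_fraction = 0.95, replace = FALSE,
                             seed = 1L) {
  probs <- c(p_univariate, p_bootstrap, retain_fraction)
  if (any(probs <= 0 | probs >= 1))
    stop_invalid("probabilities must lie in (0, 1)")
  if (bootstrap_fraction <= 0 || bootstrap_fraction > 1)
    stop_invalid("bootstrap_fraction must lie in (0, 1]")
  structure(list(p_univariate = p_univariate,
                 bootstrap_fraction = bootstrap_fraction,
                 n_bootstrap = as.integer(n_bootstrap),
                 p_bootstrap = p_bootstrap,
                 retain_fraction = retain_fraction,
                 replace = replace, seed = as.integer(seed)),
            class = "stability_config")
}

# Likelihood-ratio p-value of a single-feature logistic regression.
# Perfect separation drives the residual deviance to ~0; such features are
# maximally informative and are flagged with p = 0 rather than dropped.
logistic_lrt_p <- function(x, yb) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), yb, family = stats::binomial()))
  if (fit$deviance < 1e-6 && var(x) > 0)
    return(structure(0, separated = TRUE))
  p <- pchisq(fit$null.deviance - fit$deviance, df = 1, lower.tail = FALSE)
  structure(unname(p), separated = FALSE)
}

# one-vs-rest minimum LRT p across classes, per feature
ovr_min_p <- function(X, y, features) {
  classes <- levels(y)
  vapply(features, function(f) {
    x <- X[, f]
    if (var(x) == 0) return(1)
    min(vapply(classes, function(cl) {
      as.numeric(logistic_lrt_p(x, as.numeric(y == cl)))
    }, numeric(1)))
  }, numeric(1))
}

#' Univariate logistic screen, one-vs-rest across classes
#'
#' For each feature and each class, fits a single-feature logistic
#' regression of class-vs-rest and takes the likelihood-ratio p-value; a
#' feature is retained when `p < p_univariate` for any class. Perfectly
#' separating features are flagged and retained (p treated as 0).
#'
#' @param X samples x features matrix.
#' @param y class labels (>= 2 classes present).
#' @param config a [stability_config()].
#' @return character vector of retained feature ids, with the per-feature
#'   minimum p-values in `attr(, "p_values")`.
#' @export
univariate_screen <- function(X, y, config = stability_config()) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop_invalid("need >= 2 classes")
  p <- ovr_min_p(X, y, colnames(X))
  structure(colnames(X)[p < config$p_univariate], p_values = p)
}

#' Bootstrap stability selection of screened features
#'
#' Repeatedly draws a stratified subsample of `bootstrap_fraction` of the
#' samples (without replacement by default), refits the one-vs-rest
#' univariate logistic per feature, and keeps features significant
#' (`p < p_bootstrap` in any class) in strictly more than
#' `retain_fraction` of the resamples.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param features candidate feature ids (subset of `colnames(X)`).
#' @param config a [stability_config()].
#' @return character vector of stable feature ids, with per-feature
#'   selection frequencies in `attr(, "frequency")`.
#' @export
bootstrap_stability_select <- function(X, y, features,
                                       config = stability_config()) {
  if (!all(features %in% colnames(X)))
    stop_invalid("features must be columns of X")
  y <- droplevels(as.factor(y))
  idx_by_class <- split(seq_along(y), y)
  take <- vapply(idx_by_class, function(ix)
    max(2L, as.integer(round(config$bootstrap_fraction * length(ix)))),
    integer(1))
  if (any(take > lengths(idx_by_class)))
    stop_invalid("a class is too small for the requested subsample")
  hits <- stats::setNames(numeric(length(features)), features)
  set.seed(child_seed(config$seed, "stability"))
  for (t in seq_len(config$n_bootstrap)) {
    idx <- unlist(lapply(seq_along(idx_by_class), function(i) {
      sample(idx_by_class[[i]], take[i], replace = config$replace)
    }), use.names = FALSE)
    p <- ovr_min_p(X[idx, , drop = FALSE], y[idx], features)
    hits <- hits + (p < config$p_bootstrap)
  }
  freq <- hits / config$n_bootstrap
  structure(features[freq > config$retain_fraction], frequency = freq)
}

# stratified fold assignment for cross-validation, deterministic given seed
stratified_folds <- function(y, nfolds, seed) {
  set.seed(child_seed(seed, "folds"))
  foldid <- integer(length(y))
  for (ix in split(seq_along(y), y))
    foldid[sample(ix)] <- rep_len(seq_len(nfolds), length(ix))
  foldid
}

#' LASSO reduction of the stable feature set
#'
#' One-vs-rest L1-penalised logistic regression per class with the penalty
#' chosen by stratified cross-validation (minimum CV deviance); the panel
#' is the union of features with a non-zero coefficient in any class model.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param stable_features candidate ids (>= 2).
#' @param seed integer seed (drives the CV folds).
#' @param nfolds cross-validation folds (default 5).
#' @return character vector of panel feature ids.
#' @export
lasso_select <- function(X, y, stable_features, seed = 1L, nfolds = 5) {
  if (length(stable_features) < 2)
    stop_invalid("need >= 2 stable features for the LASSO stage")
  y <- droplevels(as.factor(y))
  Xs <- X[, stable_features, drop = FALSE]
  panel <- character(0)
  for (cl in levels(y)) {
    yb <- as.numeric(y == cl)
    foldid <- stratified_folds(factor(yb), nfolds, child_seed(seed, cl))
    cv <- glmnet::cv.glmnet(Xs, yb, family = "binomial", alpha = 1,
                            foldid = foldid)
    beta <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
    panel <- union(panel, names(beta)[beta != 0])
  }
  if (length(panel) == 0)
    stop_invalid("LASSO selected no feature; consider a weaker penalty ",
                 "(e.g. lambda.1se -> lambda.min or more folds)")
  stable_features[stable_features %in% panel]
}

#' Stratified train/test split
#'
#' Random partition of the samples into a training and a test set in
#' `train_fraction : (1 - train_fraction)` proportions within every class.
#'
#' @param y class labels (every class needs >= 2 samples).
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(y, train_fraction = 0.8, seed = 1L) {
  y <- droplevels(as.factor(y))
  if (any(table(y) < 2))
    stop_invalid("every class needs >= 2 samples to stratify")
  set.seed(child_seed(seed, "split"))
  train <- unlist(lapply(split(seq_along(y), y), function(ix) {
    n_tr <- min(max(round(train_fraction * length(ix)), 1), length(ix) - 1)
    sample(ix, n_tr)
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(seq_along(y), train)))
}

#' Specification of a feedforward network trained by resilient backprop
#'
#' @param hidden integer vector of hidden-layer sizes (may be empty for a
#'   softmax regression).
#' @param activation hidden nonlinearity, `"logistic"` or `"tanh"`.
#' @param loss `"cross-entropy"` (default) or `"sse"`.
#' @param step0,step_min,step_max initial and bounding per-weight step
#'   sizes of the rprop rule.
#' @param eta_plus,eta_minus step increase/decrease factors.
#' @param max_epochs epoch budget (default 500).
#' @param tol convergence tolerance on the accepted loss decrease.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(hidden = c(8), activation = c("logistic", "tanh"),
                         loss = c("cross-entropy", "sse"),
                         step0 = 0.1, step_min = 1e-6, step_max = 50,
                         eta_plus = 1.2, eta_minus = 0.5,
                         max_epochs = 500, tol = 1e-8) {
  activation <- match.arg(activation)
  loss <- match.arg(loss)
  hidden <- as.integer(hidden)
  if (any(hidden <= 0)) stop_invalid("hidden sizes must be positive")
  structure(list(hidden = hidden, activation = activation, loss = loss,
                 step0 = step0, step_min = step_min, step_max = step_max,
                 eta_plus = eta_plus, eta_minus = eta_minus,
                 max_epochs = as.integer(max_epochs), tol = tol),
            class = "network_spec")
}

spec_label <- function(spec) {
  sprintf("h=[%s] act=%s loss=%s",
          paste(spec$hidden, collapse = ","), spec$activation, spec$loss)
}

act_fun <- function(name) {
  switch(name,
         logistic = list(f = function(z) 1 / (1 + exp(-z)),
                         df = function(a) a * (1 - a)),
         tanh = list(f = tanh, df = function(a) 1 - a^2))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

net_forward <- function(weights, X, act) {
  A <- list(X)
  L <- length(weights)
  for (l in seq_len(L)) {
    Z <- cbind(1, A[[l]]) %*% weights[[l]]
    A[[l + 1]] <- if (l < L) act$f(Z) else softmax_rows(Z)
  }
  A
}

net_loss <- function(P, Tm, loss) {
  n <- nrow(Tm)
  if (loss == "cross-entropy") -sum(Tm * log(pmax(P, 1e-12))) / n
  else sum((Tm - P)^2) / (2 * n)
}

net_gradients <- function(weights, A, Tm, act, loss) {
  n <- nrow(Tm)
  L <- length(weights)
  P <- A[[L + 1]]
  delta <- if (loss == "cross-entropy") {
    (P - Tm) / n  # softmax + CE: dL/dZ collapses to P - T
  } else {
    G <- (P - Tm) / n
    P * (G - rowSums(G * P))  # softmax Jacobian applied to dL/dP
  }
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- crossprod(cbind(1, A[[l]]), delta)
    if (l > 1)
      delta <- (delta %*% t(weights[[l]][-1, , drop = FALSE])) *
        act$df(A[[l]])
  }
  grads
}

#' Train a softmax feedforward network by resilient backpropagation
#'
#' Full-batch training with per-weight adaptive steps (sign-based rprop:
#' steps grow by `eta_plus` while the gradient sign persists and shrink by
#' `eta_minus` when it flips) plus a global backtracking acceptance rule:
#' an epoch whose proposed update increases the loss is rejected, the
#' weights reverted and all steps halved, so the accepted loss trajectory
#' is non-increasing. Inputs are standardised on the training set and the
#' standardisation parameters stored for reuse at prediction time.
#'
#' @param X_train samples x features matrix.
#' @param y_train class labels.
#' @param spec a [network_spec()].
#' @param seed integer seed for the weight initialisation.
#' @return object of class `rprop_net` with weights, spec, class levels,
#'   standardisation parameters and the accepted-loss trace.
#' @export
train_network <- function(X_train, y_train, spec = network_spec(),
                          seed = 1L) {
  y_train <- droplevels(as.factor(y_train))
  lev <- levels(y_train)
  center <- colMeans(X_train)
  scale <- apply(X_train, 2, sd)
  scale[scale == 0] <- 1
  X <- sweep(sweep(X_train, 2, center), 2, scale, `/`)
  Tm <- outer(as.character(y_train), lev, `==`) * 1
  sizes <- c(ncol(X), spec$hidden, length(lev))
  act <- act_fun(spec$activation)

  set.seed(child_seed(seed, "net-init"))
  weights <- lapply(seq_len(length(sizes) - 1), function(l) {
    matrix(runif((sizes[l] + 1) * sizes[l + 1], -0.5, 0.5),
           sizes[l] + 1, sizes[l + 1])
  })
  steps <- lapply(weights, function(w) array(spec$step0, dim(w)))
  g_prev <- lapply(weights, function(w) array(0, dim(w)))

  A <- net_forward(weights, X, act)
  loss <- net_loss(A[[length(A)]], Tm, spec$loss)
  trace <- loss
  for (epoch in seq_len(spec$max_epochs)) {
    grads <- net_gradients(weights, A, Tm, act, spec$loss)
    if (any(!vapply(grads, function(g) all(is.finite(g)), logical(1))))
      stop_invalid("non-finite gradient at epoch ", epoch)
    proposal <- weights
    for (l in seq_along(weights)) {
      s <- grads[[l]] * g_prev[[l]]
      steps[[l]][s > 0] <- pmin(steps[[l]][s > 0] * spec$eta_plus,
                                spec$step_max)
      steps[[l]][s < 0] <- pmax(steps[[l]][s < 0] * spec$eta_minus,
                                spec$step_min)
      grads[[l]][s < 0] <- 0  # rprop+: skip adaptation after a sign flip
      proposal[[l]] <- weights[[l]] - sign(grads[[l]]) * steps[[l]]
    }
    A_new <- net_forward(proposal, X, act)
    loss_new <- net_loss(A_new[[length(A_new)]], Tm, spec$loss)
    if (!is.finite(loss_new))
      stop_invalid("non-finite loss at epoch ", epoch)
    if (loss_new <= loss + 1e-15) {
      improved <- loss - loss_new
      weights <- proposal
      A <- A_new
      loss <- loss_new
      g_prev <- grads
      trace <- c(trace, loss)
      if (improved < spec$tol) break
    } else {
      # reject: keep weights, shrink all steps, reset the sign memory
      steps <- lapply(steps, function(st) pmax(st * 0.5, spec$step_min))
      g_prev <- lapply(g_prev, function(g) array(0, dim(g)))
      if (max(vapply(steps, max, numeric(1))) <= spec$step_min) break
    }
  }
  structure(list(weights = weights, spec = spec, levels = lev,
                 features = colnames(X_train), center = center,
                 scale = scale, loss_trace = trace, final_loss = loss),
            class = "rprop_net")
}

#' Predict classes and probabilities from a trained network
#'
#' @param object an `rprop_net` (or a `classifier_bundle`, whose panel is
#'   enforced).
#' @param newdata samples x features matrix containing the model features.
#' @param ... unused.
#' @return list with `class` (factor) and `prob` (samples x classes matrix
#'   with rows summing to 1).
#' @export
predict.rprop_net <- function(object, newdata, ...) {
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop_invalid("missing model feature(s): ", paste(missing, collapse = ", "))
  X <- newdata[, object$features, drop = FALSE]
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  A <- net_forward(object$weights, X, act_fun(object$spec$activation))
  P <- A[[length(A)]]
  colnames(P) <- object$levels
  rownames(P) <- rownames(newdata)
  cls <- factor(object$levels[max.col(P, ties.method = "first")],
                levels = object$levels)
  list(class = cls, prob = P)
}

n_net_params <- function(net) sum(vapply(net$weights, length, numeric(1)))

#' Grid search over network specifications
#'
#' Trains every specification in the grid on the training set, evaluates
#' accuracy on the held-out test set, and keeps the specification with the
#' highest test accuracy (ties: fewer parameters, then grid order). The
#' full grid table is retained.
#'
#' @param X_train,y_train,X_test,y_test split data; columns of the X
#'   matrices are the feature panel.
#' @param grid non-empty list of [network_spec()] objects.
#' @param seed integer seed (per-spec children derive from it).
#' @return object of class `classifier_bundle`: `panel`, `network`,
#'   `grid_table`, `class_levels`.
#' @export
grid_search <- function(X_train, y_train, X_test, y_test,
                        grid = default_network_grid(), seed = 1L) {
  if (length(grid) == 0) stop_invalid("empty specification grid")
  rows <- list()
  fits <- list()
  errors <- character(0)
  for (i in seq_along(grid)) {
    fit <- tryCatch(train_network(X_train, y_train, grid[[i]],
                                  seed = child_seed(seed, "grid", i)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      errors <- c(errors, conditionMessage(fit))
      rows[[i]] <- data.frame(spec = spec_label(grid[[i]]), n_params = NA,
                              train_accuracy = NA, test_accuracy = NA)
      next
    }
    fits[[i]] <- fit
    acc_tr <- mean(predict(fit, X_train)$class == y_train)
    acc_te <- mean(predict(fit, X_test)$class == y_test)
    rows[[i]] <- data.frame(spec = spec_label(grid[[i]]),
                            n_params = n_net_params(fit),
                            train_accuracy = acc_tr, test_accuracy = acc_te)
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$test_accuracy))
  if (length(ok) == 0)
    stop_invalid("all specifications failed to train: ",
                 paste(unique(errors), collapse = "; "))
  best <- ok[order(-tab$test_accuracy[ok], tab$n_params[ok], ok)][1]
  structure(list(panel = colnames(X_train), network = fits[[best]],
                 grid_table = tab, best_index = best,
                 class_levels = fits[[best]]$levels),
            class = "classifier_bundle")
}

#' Default specification grid
#'
#' Hidden layouts `{(), (8), (16), (8, 4)}` crossed with logistic and tanh
#' activations, cross-entropy loss, learning-rate-free rprop steps.
#'
#' @param max_epochs epoch budget shared by all specs.
#' @return list of [network_spec()] objects.
#' @export
default_network_grid <- function(max_epochs = 300) {
  layouts <- list(integer(0), 8L, 16L, c(8L, 4L))
  grid <- list()
  for (h in layouts)
    for (a in c("logistic", "tanh"))
      grid[[length(grid) + 1]] <- network_spec(hidden = h, activation = a,
                                               max_epochs = max_epochs)
  grid
}

#' @export
predict.classifier_bundle <- function(object, newdata, ...) {
  predict(object$network, newdata, ...)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy (trace over total) and one-vs-rest sensitivity
#' `TP / (TP + FN)` and specificity `TN / (TN + FP)` per class, from a
#' square true-by-predicted count matrix.
#'
#' @param confusion square matrix, rows = truth, columns = prediction.
#' @return list with `confusion`, `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop_invalid("confusion matrix must be square")
  n <- sum(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- n - tp - fn - fp
  list(confusion = confusion, accuracy = sum(tp) / n,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Evaluate a classifier on labeled data
#'
#' @param bundle a `classifier_bundle` (or `rprop_net`).
#' @param X samples x features matrix containing the panel.
#' @param y true class labels drawn from the bundle's classes.
#' @return object of class `evaluation_report`: confusion matrix,
#'   accuracy, per-class sensitivity and specificity.
#' @export
evaluate_classifier <- function(bundle, X, y) {
  lev <- if (inherits(bundle, "classifier_bundle")) bundle$class_levels
         else bundle$levels
  if (!all(as.character(y) %in% lev))
    stop_invalid("unknown class label(s): ",
                 paste(setdiff(unique(as.character(y)), lev), collapse = ", "))
  pred <- predict(bundle, X)$class
  conf <- table(factor(y, levels = lev), factor(pred, levels = lev))
  dimnames(conf) <- list(truth = lev, predicted = lev)
  structure(classification_metrics(conf), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("accuracy:", round(x$accuracy, 4), "\n")
  print(x$confusion)
  invisible(x)
}

#' Serialise a classifier bundle to JSON
#'
#' Stores the panel, class order, standardisation parameters, layer shapes
#' and weights as structured text so the model reloads exactly.
#'
#' @param bundle a `classifier_bundle`.
#' @param path output file.
#' @export
save_classifier <- function(bundle, path) {
  net <- bundle$network
  obj <- list(panel = bundle$panel, class_levels = bundle$class_levels,
              spec = unclass(net$spec), center = as.list(net$center),
              scale = as.list(net$scale),
              weights = lapply(net$weights, function(w)
                list(dim = dim(w), values = as.vector(w))),
              grid_table = bundle$grid_table)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier bundle saved by [save_classifier()]
#' @param path JSON file.
#' @return a `classifier_bundle`.
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(network_spec, obj$spec[c("hidden", "activation", "loss",
                                           "step0", "step_min", "step_max",
                                           "eta_plus", "eta_minus",
                                           "max_epochs", "tol")])
  weights <- lapply(seq_len(nrow(obj$weights)), function(i) {
    matrix(obj$weights$values[[i]], obj$weights$dim[[i]][1],
           obj$weights$dim[[i]][2])
  })
  net <- structure(list(weights = weights, spec = spec,
                        levels = obj$class_levels, features = obj$panel,
                        center = unlist(obj$center),
                        scale = unlist(obj$scale),
                        loss_trace = NULL, final_loss = NULL),
                   class = "rprop_net")
  structure(list(panel = obj$panel, network = net,
                 grid_table = obj$grid_table, best_index = NA,
                 class_levels = obj$class_levels),
            class = "classifier_bundle")
}

#' Full feature-selection cascade: screen, stability, LASSO
#'
#' Convenience wrapper running [univariate_screen()],
#' [bootstrap_stability_select()] and [lasso_select()] in sequence; each
#' stage's survivors are the next stage's candidates, so
#' panel ⊆ stable ⊆ screened.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param config a [stability_config()].
#' @param seed integer seed for the LASSO folds.
#' @return list with `screened`, `stable`, `panel`.
#' @export
select_feature_panel <- function(X, y, config = stability_config(),
                                 seed = 1L) {
  screened <- univariate_screen(X, y, config)
  if (length(screened) == 0)
    return(list(screened = character(0), stable = character(0),
                panel = character(0)))
  stable <- bootstrap_stability_select(X, y, screened, config)
  panel <- if (length(stable) >= 2) {
    lasso_select(X, y, stable, seed = seed)
  } else stable
  list(screened = as.character(screened), stable = as.character(stable),
       panel = panel)
}
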