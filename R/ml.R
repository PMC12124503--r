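#' Seeded train/test split
#'
#' Disjoint, exhaustive split, stratified by a column (normally the
#' outcome) so both sets keep the class mix.  Strata too small to split
#' trigger a warning and an unstratified fallback.
#'
#' @param table data.frame/data.table.
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @param stratify_by optional column name.
#' @return list `train`, `test` (data.tables).
#' @export
split_train_test <- function(table, fraction = 0.7, seed = 1,
                             stratify_by = NULL) {
  if (!is_prob(fraction) || fraction <= 0 || fraction >= 1)
    stopf("'fraction' must lie in (0, 1)")
  dt <- data.table::as.data.table(table)
  n <- nrow(dt)
  set.seed(seed)
  if (!is.null(stratify_by)) {
    if (!stratify_by %in% names(dt))
      stopf("stratification column '%s' missing", stratify_by)
    g <- as.character(dt[[stratify_by]])
    if (min(table(g)) < 2) {
      warnf("stratum with fewer than 2 rows; falling back to simple split")
      stratify_by <- NULL
    } else {
      idx <- unlist(lapply(split(seq_len(n), g), function(ix) {
        k <- round(fraction * length(ix))
        k <- max(1L, min(k, length(ix) - 1L))
        sample(ix, k)
      }), use.names = FALSE)
      return(list(train = dt[sort(idx)], test = dt[-sort(idx)]))
    }
  }
  k <- round(fraction * n)
  idx <- sort(sample.int(n, k))
  list(train = dt[idx], test = dt[-idx])
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of the three-layer perceptron
#'
#' Deterministic evaluation of the fitted network: each node computes
#' the weighted sum of its inputs minus its bias, `M = X W - b`, and
#' passes it through the logistic activation `f(M) = 1 / (1 + e^-M)`.
#'
#' @param model an `mlp_model` from [train_mlp].
#' @param x numeric vector (one input) or matrix (rows = inputs) on the
#'   original feature scale.
#' @return probability (or vector of probabilities) in (0, 1).
#' @export
mlp_forward <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  X <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  if (ncol(X) != length(model$features))
    stopf("input has %d features; model expects %d",
          ncol(X), length(model$features))
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  H <- sigmoid(sweep(Xs %*% model$W1, 2, model$b1))
  drop(sigmoid(H %*% model$W2 - model$b2))
}

#' Train a single-hidden-layer neural network
#'
#' Three layers (input, one logistic hidden layer, logistic output)
#' trained by full-batch gradient descent on the cross-entropy loss,
#' with seeded uniform initialisation and standardised inputs.
#'
#' @param data training table.
#' @param outcome binary outcome column.
#' @param features feature columns.
#' @param hidden hidden-layer width (default 8).
#' @param epochs gradient steps (default 200).
#' @param lr learning rate (default 0.1).
#' @param seed RNG seed.
#' @return object of class `mlp_model`.
#' @export
train_mlp <- function(data, outcome, features, hidden = 8, epochs = 200,
                      lr = 0.1, seed = 1) {
  dt <- as.data.frame(data)
  y <- dt[[outcome]]
  if (!all(y %in% c(0, 1))) stopf("outcome must be binary 0/1")
  X <- as.matrix(dt[, features, drop = FALSE])
  storage.mode(X) <- "double"
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd); scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, `/`)
  n <- nrow(Xs); p <- ncol(Xs)
  set.seed(seed)
  W1 <- matrix(runif(p * hidden, -0.5, 0.5) / sqrt(p), p, hidden)
  b1 <- runif(hidden, -0.1, 0.1)
  W2 <- matrix(runif(hidden, -0.5, 0.5) / sqrt(hidden), hidden, 1)
  b2 <- runif(1, -0.1, 0.1)
  for (ep in seq_len(epochs)) {
    H <- sigmoid(sweep(Xs %*% W1, 2, b1))
    out <- drop(sigmoid(H %*% W2 - b2))
    eps <- 1e-12
    loss <- -mean(y * log(out + eps) + (1 - y) * log(1 - out + eps))
    if (!is.finite(loss)) stopf("non-finite loss at epoch %d", ep)
    d_out <- (out - y) / n                      # dL/dM_out
    gW2 <- crossprod(H, d_out)
    gb2 <- -sum(d_out)
    dH <- tcrossprod(d_out, W2) * H * (1 - H)   # n x hidden
    gW1 <- crossprod(Xs, dH)
    gb1 <- -colSums(dH)
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, center = center,
                 scale = scale_, features = features, outcome = outcome,
                 hidden = hidden, epochs = epochs, lr = lr, seed = seed),
            class = "mlp_model")
}

#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "prob"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  pr <- mlp_forward(object, X)
  if (type == "prob") pr else as.integer(pr > threshold)
}

gini_node <- function(n1, n) {
  p <- n1 / n
  2 * p * (1 - p)
}

# Best binary split of (x, y): returns list(split, decrease) or NULL.
best_split <- function(x, y) {
  o <- order(x)
  xo <- x[o]; yo <- y[o]
  n <- length(yo)
  cum1 <- cumsum(yo)
  nl <- seq_len(n - 1)
  valid <- xo[-n] < xo[-1]          # split between distinct values only
  if (!any(valid)) return(NULL)
  n1l <- cum1[nl]
  n1r <- cum1[n] - n1l
  nr <- n - nl
  g <- gini_node(cum1[n], n) -
    (nl * gini_node(n1l, nl) + nr * gini_node(n1r, nr)) / n
  g[!valid] <- -Inf
  i <- which.max(g)
  if (!is.finite(g[i]) || g[i] <= 1e-12) return(NULL)
  list(split = (xo[i] + xo[i + 1]) / 2, decrease = g[i])
}

grow_tree <- function(X, y, idx, mtry, min_node, max_depth, depth, acc) {
  n <- length(idx)
  n1 <- sum(y[idx])
  if (depth >= max_depth || n < 2 * min_node || n1 == 0 || n1 == n)
    return(list(leaf = TRUE, prob = n1 / n))
  tried <- sample.int(ncol(X), mtry)
  best <- NULL; best_var <- NA_integer_
  for (v in tried) {
    s <- best_split(X[idx, v], y[idx])
    if (!is.null(s) && (is.null(best) || s$decrease > best$decrease)) {
      best <- s; best_var <- v
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, prob = n1 / n))
  acc$gini[best_var] <- acc$gini[best_var] + n * best$decrease
  left <- idx[X[idx, best_var] <= best$split]
  right <- idx[X[idx, best_var] > best$split]
  list(leaf = FALSE, var = best_var, split = best$split,
       left = grow_tree(X, y, left, mtry, min_node, max_depth, depth + 1, acc),
       right = grow_tree(X, y, right, mtry, min_node, max_depth, depth + 1,
                         acc))
}

predict_tree <- function(node, X, idx, out) {
  if (node$leaf) { out[idx] <- node$prob; return(out) }
  go_left <- X[idx, node$var] <= node$split
  out <- predict_tree(node$left, X, idx[go_left], out)
  predict_tree(node$right, X, idx[!go_left], out)
}

#' Train a random forest of classification trees
#'
#' An ensemble of CART-style trees, each grown on an independent
#' bootstrap sub-sample with a random feature subset (`mtry`) tried at
#' every split; prediction is the majority vote.  Impurity (Gini)
#' importance is accumulated per feature while growing.
#'
#' @inheritParams train_mlp
#' @param ntree number of trees (default 500).
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param min_node minimum node size to attempt a split.
#' @param max_depth depth cap.
#' @return object of class `rf_model`.
#' @export
train_rf <- function(data, outcome, features, ntree = 500, mtry = NULL,
                     min_node = 5, max_depth = 12, seed = 1) {
  dt <- as.data.frame(data)
  y <- dt[[outcome]]
  if (!all(y %in% c(0, 1))) stopf("outcome must be binary 0/1")
  if (length(unique(y)) < 2)
    stopf("training data has a single outcome class; cannot fit")
  X <- as.matrix(dt[, features, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  mtry <- mtry %||% max(1L, floor(sqrt(p)))
  set.seed(seed)
  gini <- matrix(0, p, ntree, dimnames = list(features, NULL))
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    boot <- sample.int(n, n, replace = TRUE)
    acc <- new.env()
    acc$gini <- numeric(p)
    trees[[t]] <- grow_tree(X, y, boot, mtry, min_node, max_depth, 0L, acc)
    gini[, t] <- acc$gini / n
  }
  structure(list(trees = trees, features = features, outcome = outcome,
                 ntree = ntree, mtry = mtry, gini = gini, seed = seed),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, type = c("class", "prob"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X)
  votes <- numeric(n)
  for (tr in object$trees) {
    pr <- predict_tree(tr, X, seq_len(n), numeric(n))
    votes <- votes + as.integer(pr > 0.5)     # each tree votes a class
  }
  pr <- votes / object$ntree
  if (type == "prob") pr else as.integer(pr > threshold)
}

#' Variable importance
#'
#' `"mean_decrease_accuracy"`: seeded permutation importance - the drop
#' in test-set accuracy when a feature column is shuffled, averaged over
#' `n_rep` permutations (works for both model classes).
#' `"mean_decrease_gini"`: total impurity decrease attributed to each
#' feature across the forest's trees (random forests only).
#'
#' @param model an `rf_model` or `mlp_model`.
#' @param test test table (holding outcome and features).
#' @param method importance measure.
#' @param n_rep permutation repeats (accuracy method).
#' @param seed RNG seed for the permutations.
#' @return data.table `variable`, `importance`, sorted decreasing.
#' @export
var_importance <- function(model, test,
                           method = c("mean_decrease_accuracy",
                                      "mean_decrease_gini"),
                           n_rep = 5, seed = 1) {
  method <- match.arg(method)
  if (method == "mean_decrease_gini") {
    if (!inherits(model, "rf_model"))
      stopf("mean_decrease_gini is only defined for random forests")
    imp <- rowMeans(model$gini)
    out <- data.table::data.table(variable = names(imp),
                                  importance = unname(imp))
  } else {
    dt <- as.data.frame(test)
    y <- dt[[model$outcome]]
    base <- mean(predict(model, dt) == y)
    set.seed(seed)
    imp <- vapply(model$features, function(v) {
      drops <- vapply(seq_len(n_rep), function(r) {
        d2 <- dt
        d2[[v]] <- sample(d2[[v]])
        base - mean(predict(model, d2) == y)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    out <- data.table::data.table(variable = model$features,
                                  importance = unname(imp))
  }
  data.table::setorder(out, -importance)
  out[]
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity and specificity (percent) from predicted and
#' true 0/1 classes; positive class is 1.
#'
#' @param pred,truth 0/1 vectors.
#' @return list `tp`, `tn`, `fp`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  n <- tp + tn + fp + fn
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = 100 * (tp + tn) / n,
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' Evaluate a fitted classifier on held-out data
#'
#' @param model `rf_model` or `mlp_model`.
#' @param test test table disjoint from training.
#' @return one-row data.table: model class, outcome, confusion counts
#'   and accuracy/sensitivity/specificity in percent.
#' @export
evaluate_model <- function(model, test) {
  dt <- as.data.frame(test)
  if (nrow(dt) == 0) stopf("test set is empty")
  y <- dt[[model$outcome]]
  m <- confusion_metrics(predict(model, dt), y)
  data.table::data.table(
    model = class(model)[1], outcome = model$outcome,
    tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
    accuracy = m$accuracy, sensitivity = m$sensitivity,
    specificity = m$specificity)
}
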