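# Classical baselines on the 32-dimensional feature vectors. The five
# model families run with fixed, published hyperparameter sets (one per
# task); no tuning happens here. All learners are implemented in-package
# (no tree/SVM library is available in the runtime environment): CART
# with Gini impurity, bootstrap random forest over CART with per-split
# feature subsampling, distance-weighted KNN, one-vs-rest L2 logistic
# regression fit by Newton steps, and a linear SVM fit by dual coordinate
# descent with one-vs-one voting.

#' Baseline model specification
#'
#' Returns the hyperparameters used for each model family and task.
#'
#' @param family one of `"logistic_regression"`, `"random_forest"`,
#'   `"decision_tree"`, `"svm"`, `"knn"`.
#' @param task `"binary"` or `"threeclass"`; the two tasks use different
#'   published parameter sets.
#' @param params optional overrides.
#' @return an object of class `semg_baseline_spec`.
#' @export
baseline_spec <- function(family = c("random_forest", "logistic_regression",
                                     "decision_tree", "svm", "knn"),
                          task = c("binary", "threeclass"),
                          params = list()) {
  family <- match.arg(family)
  task <- match.arg(task)
  defaults <- list(
    binary = list(
      logistic_regression = list(solver = "newton-cg", max_iter = 60,
                                 multi_class = "ovr", C = 0.002),
      random_forest = list(max_depth = 15, n_estimators = 12,
                           criterion = "gini"),
      decision_tree = list(criterion = "gini", max_depth = 13),
      svm = list(decision_function_shape = "ovo", max_iter = 80,
                 kernel = "linear", C = 0.3),
      knn = list(n_neighbors = 7, metric = "minkowski",
                 weights = "distance")),
    threeclass = list(
      logistic_regression = list(solver = "newton-cg", max_iter = 65,
                                 multi_class = "ovr", C = 0.003),
      random_forest = list(max_depth = 14, n_estimators = 14,
                           criterion = "gini"),
      decision_tree = list(criterion = "gini", max_depth = 16),
      svm = list(decision_function_shape = "ovo", max_iter = 75,
                 kernel = "linear", C = 0.4),
      knn = list(n_neighbors = 8, metric = "minkowski",
                 weights = "distance")))
  p <- defaults[[task]][[family]]
  bad <- setdiff(names(params), names(p))
  check_that(length(bad) == 0,
             paste("unknown parameter(s) for", family, ":",
                   paste(bad, collapse = ", ")))
  p[names(params)] <- params
  structure(list(family = family, task = task, params = p),
            class = "semg_baseline_spec")
}

# -- CART --------------------------------------------------------------------

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# greedy CART; y is an integer vector in 1..n_classes
grow_tree <- function(x, y, n_classes, depth, max_depth, mtry,
                      min_split = 2) {
  counts <- tabulate(y, n_classes)
  node <- list(prob = counts / sum(counts))
  if (depth >= max_depth || length(y) < min_split ||
      gini_impurity(counts) == 0) {
    node$leaf <- TRUE
    return(node)
  }
  feats <- if (mtry < ncol(x)) sample.int(ncol(x), mtry) else seq_len(ncol(x))
  best <- list(gain = 0)
  parent_imp <- gini_impurity(counts)
  n <- length(y)
  for (f in feats) {
    v <- x[, f]
    ord <- order(v)
    vs <- v[ord]
    ys <- y[ord]
    # cumulative class counts left of each split position
    cc <- apply(outer(ys, seq_len(n_classes), "=="), 2, cumsum)
    if (is.null(dim(cc))) cc <- matrix(cc, nrow = 1)
    cut_ok <- which(diff(vs) > 0)
    for (i in cut_ok) {
      left <- cc[i, ]
      right <- counts - left
      imp <- (i * gini_impurity(left) + (n - i) * gini_impurity(right)) / n
      gain <- parent_imp - imp
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, feature = f,
                     threshold = (vs[i] + vs[i + 1]) / 2)
      }
    }
  }
  if (best$gain <= 0) {
    node$leaf <- TRUE
    return(node)
  }
  go_left <- x[, best$feature] <= best$threshold
  node$leaf <- FALSE
  node$feature <- best$feature
  node$threshold <- best$threshold
  node$left <- grow_tree(x[go_left, , drop = FALSE], y[go_left], n_classes,
                         depth + 1, max_depth, mtry, min_split)
  node$right <- grow_tree(x[!go_left, , drop = FALSE], y[!go_left],
                          n_classes, depth + 1, max_depth, mtry, min_split)
  node
}

predict_tree <- function(node, x) {
  n <- nrow(x)
  out <- matrix(0, n, length(node$prob))
  recurse <- function(node, idx) {
    if (isTRUE(node$leaf)) {
      out[idx, ] <<- matrix(node$prob, length(idx), length(node$prob),
                            byrow = TRUE)
      return(invisible())
    }
    go_left <- x[idx, node$feature] <= node$threshold
    if (any(go_left)) recurse(node$left, idx[go_left])
    if (any(!go_left)) recurse(node$right, idx[!go_left])
  }
  if (n > 0) recurse(node, seq_len(n))
  out
}

# -- logistic regression (one-vs-rest, L2, Newton) ---------------------------

fit_logistic_ovr <- function(x, y, n_classes, C, max_iter) {
  xb <- cbind(1, x)
  p <- ncol(xb)
  lambda <- 1 / C
  weights <- matrix(0, p, n_classes)
  for (cl in seq_len(n_classes)) {
    t_cl <- as.numeric(y == cl)
    w <- numeric(p)
    for (it in seq_len(max_iter)) {
      eta <- drop(xb %*% w)
      mu <- 1 / (1 + exp(-eta))
      grad <- drop(crossprod(xb, mu - t_cl)) + lambda * c(0, w[-1])
      s <- pmax(mu * (1 - mu), 1e-10)
      hess <- crossprod(xb * s, xb) + diag(c(0, rep(lambda, p - 1)))
      step <- tryCatch(solve(hess, grad), error = function(e) grad * 1e-3)
      w <- w - step
      if (max(abs(step)) < 1e-8) break
    }
    weights[, cl] <- w
  }
  weights
}

# -- linear SVM (one-vs-one, dual coordinate descent) ------------------------

fit_svm_pair <- function(x, t, C, max_iter) {
  # t in {-1, +1}; hinge-loss dual coordinate descent with bias folded in
  xb <- cbind(1, x)
  n <- nrow(xb)
  qd <- rowSums(xb^2)
  alpha <- numeric(n)
  w <- numeric(ncol(xb))
  for (pass in seq_len(max_iter)) {
    changed <- 0
    for (i in sample.int(n)) {
      g <- t[i] * sum(w * xb[i, ]) - 1
      pg <- g
      if (alpha[i] <= 0) pg <- min(g, 0)
      if (alpha[i] >= C) pg <- max(g, 0)
      if (abs(pg) > 1e-12) {
        old <- alpha[i]
        alpha[i] <- min(max(alpha[i] - g / qd[i], 0), C)
        w <- w + (alpha[i] - old) * t[i] * xb[i, ]
        changed <- changed + 1
      }
    }
    if (changed == 0) break
  }
  if (pass == max_iter && changed > 0) {
    message("svm: reached max_iter before convergence (as specified)")
  }
  w
}

# -- training front end ------------------------------------------------------

#' Train a classical baseline on feature vectors
#'
#' Features for the distance- and margin-based families (KNN, SVM,
#' logistic regression) are z-scored with statistics estimated on the
#' training set; tree-based families consume raw features.
#'
#' @param x numeric feature matrix (rows = windows).
#' @param y labels (factor or character); at least 2 classes.
#' @param spec a [baseline_spec()].
#' @param seed seed for the stochastic learners (forest bootstrap, SVM
#'   sweep order).
#' @return a `semg_model`.
#' @export
train_baseline <- function(x, y, spec, seed = 1L) {
  check_that(inherits(spec, "semg_baseline_spec"),
             "spec must be a semg_baseline_spec")
  x <- as.matrix(x)
  check_that(!anyNA(x), "feature matrix contains missing values")
  if (!is.factor(y)) y <- factor(y)
  classes <- levels(y)
  check_that(length(unique(y)) >= 2, "need at least 2 classes in training data")
  yi <- as.integer(y)
  nc <- length(classes)
  p <- spec$params
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  scale_mu <- NULL
  scale_sd <- NULL
  if (spec$family %in% c("knn", "svm", "logistic_regression")) {
    scale_mu <- colMeans(x)
    scale_sd <- pmax(apply(x, 2, stats::sd), 1e-12)
    x <- sweep(sweep(x, 2, scale_mu), 2, scale_sd, "/")
  }

  fit <- switch(
    spec$family,
    decision_tree = grow_tree(x, yi, nc, 0, p$max_depth, ncol(x)),
    random_forest = {
      mtry <- max(1, floor(sqrt(ncol(x))))
      lapply(seq_len(p$n_estimators), function(b) {
        idx <- sample.int(nrow(x), replace = TRUE)
        grow_tree(x[idx, , drop = FALSE], yi[idx], nc, 0, p$max_depth, mtry)
      })
    },
    knn = list(x = x, yi = yi),
    logistic_regression = fit_logistic_ovr(x, yi, nc, p$C, p$max_iter),
    svm = {
      pairs <- utils::combn(nc, 2, simplify = FALSE)
      ws <- lapply(pairs, function(pr) {
        sel <- yi %in% pr
        t_pm <- ifelse(yi[sel] == pr[1], 1, -1)
        fit_svm_pair(x[sel, , drop = FALSE], t_pm, p$C, p$max_iter)
      })
      list(pairs = pairs, weights = ws)
    })

  structure(list(spec = spec, fit = fit, classes = classes,
                 scale_mu = scale_mu, scale_sd = scale_sd),
            class = "semg_model")
}

#' Predict class probabilities and labels
#'
#' Probability rows sum to one; ties in the argmax break toward the
#' lower-ordered class.
#'
#' @param object a `semg_model`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return list with `prob` (matrix, one column per class) and `class`
#'   (factor of argmax labels).
#' @export
predict.semg_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  check_that(ncol(x) == length(object$scale_mu) || is.null(object$scale_mu),
             "feature dimension mismatch")
  if (!is.null(object$scale_mu)) {
    x <- sweep(sweep(x, 2, object$scale_mu), 2, object$scale_sd, "/")
  }
  nc <- length(object$classes)
  spec <- object$spec
  prob <- switch(
    spec$family,
    decision_tree = predict_tree(object$fit, x),
    random_forest = {
      acc <- matrix(0, nrow(x), nc)
      for (tree in object$fit) acc <- acc + predict_tree(tree, x)
      acc / length(object$fit)
    },
    knn = {
      k <- spec$params$n_neighbors
      tr <- object$fit$x
      yi <- object$fit$yi
      out <- matrix(0, nrow(x), nc)
      for (i in seq_len(nrow(x))) {
        d2 <- colSums((t(tr) - x[i, ])^2)
        nb <- order(d2)[seq_len(min(k, length(d2)))]
        d <- sqrt(d2[nb])
        if (any(d == 0)) {
          w <- as.numeric(d == 0)
        } else {
          w <- 1 / d
        }
        for (j in seq_along(nb)) out[i, yi[nb[j]]] <- out[i, yi[nb[j]]] + w[j]
      }
      out / rowSums(out)
    },
    logistic_regression = {
      eta <- cbind(1, x) %*% object$fit
      s <- 1 / (1 + exp(-eta))
      s / rowSums(s)
    },
    svm = {
      votes <- matrix(0, nrow(x), nc)
      margin <- matrix(0, nrow(x), nc)
      xb <- cbind(1, x)
      for (pi in seq_along(object$fit$pairs)) {
        pr <- object$fit$pairs[[pi]]
        f <- drop(xb %*% object$fit$weights[[pi]])
        win <- ifelse(f >= 0, pr[1], pr[2])
        for (cl in pr) {
          votes[win == cl, cl] <- votes[win == cl, cl] + 1
        }
        margin[, pr[1]] <- margin[, pr[1]] + f
        margin[, pr[2]] <- margin[, pr[2]] - f
      }
      # pseudo-probabilities: softmax over votes with a small margin
      # tie-break term (documented; SVMs are not calibrated here)
      sc <- votes + 0.01 * tanh(margin)
      e <- exp(sc - apply(sc, 1, max))
      e / rowSums(e)
    })
  colnames(prob) <- object$classes
  lab <- factor(object$classes[max.col(prob, ties.method = "first")],
                levels = object$classes, ordered = TRUE)
  list(prob = prob, class = lab)
}
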