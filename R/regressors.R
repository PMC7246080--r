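# The five regression architectures behind one interface. SVR is libsvm
# (e1071) with the IQR-based cost rule; RF is randomForest with a minimum
# leaf size of 5. Each model is fitted separately per shift direction.

#' Architectures and their hyperparameter tuning grids
#'
#' Hidden nodes 4..10 for the three ANNs, epsilon in
#' {0.01, 0.05, 0.1, 0.3, 0.5, 1.0} for SVR, and 10/30/50/70/100/150 trees
#' for RF.
#' @export
architecture_grids <- function() {
  list(br_ann = 4:10, lm_ann = 4:10, scg_ann = 4:10,
       svr = c(0.01, 0.05, 0.1, 0.3, 0.5, 1.0),
       rf = c(10L, 30L, 50L, 70L, 100L, 150L))
}

#' @rdname architecture_grids
#' @export
architectures <- function() names(architecture_grids())

#' SVR cost from the target interquartile range
#'
#' `C = IQR(y) / 1.349` (1.349 = IQR of the standard normal), a robust
#' estimate of the target scale. A zero IQR falls back to `C = 1` with a
#' warning.
#'
#' @param y Training targets (mm).
#' @export
svr_cost <- function(y) {
  iqr <- unname(diff(stats::quantile(y, c(0.25, 0.75))))
  if (iqr <= 0) {
    warning("IQR of the targets is zero; falling back to C = 1")
    return(1)
  }
  iqr / 1.349
}

#' Train an epsilon-insensitive support vector regressor
#'
#' RBF kernel with `gamma = 1/p` on z-scored inputs, cost from [svr_cost()]
#' computed on the (unstandardized) training targets.
#'
#' @param X Numeric feature matrix (n x p).
#' @param y Numeric targets (mm).
#' @param epsilon Half-width of the insensitive band (on z-scored targets).
#' @return A `ctv_regressor`.
#' @export
train_svr <- function(X, y, epsilon = 0.1) {
  d <- check_xy(X, y)
  std <- ann_standardize(d$X, d$y)
  cost <- svr_cost(d$y)
  if (diff(range(d$y)) < 1e-12) {
    # degenerate flat target: libsvm keeps no support vectors
    return(structure(list(architecture = "svr", fit = NULL,
                          constant = std$y_center, cost = cost,
                          epsilon = epsilon, gamma = 1 / ncol(d$X),
                          x_center = std$x_center, x_scale = std$x_scale,
                          y_center = std$y_center, y_scale = std$y_scale,
                          n_features = ncol(d$X)),
                     class = c("ctv_svr", "ctv_regressor")))
  }
  fit <- e1071::svm(std$Xs, std$ys_y, type = "eps-regression",
                    kernel = "radial", gamma = 1 / ncol(d$X),
                    cost = cost, epsilon = epsilon, scale = FALSE,
                    tolerance = 1e-6)
  structure(list(architecture = "svr", fit = fit, cost = cost,
                 epsilon = epsilon, gamma = 1 / ncol(d$X),
                 x_center = std$x_center, x_scale = std$x_scale,
                 y_center = std$y_center, y_scale = std$y_scale,
                 n_features = ncol(d$X)),
            class = c("ctv_svr", "ctv_regressor"))
}

#' Train a random forest regressor
#'
#' Bootstrap per tree, `mtry = ceiling(p/3)` random features per split,
#' minimum of 5 observations per leaf.
#'
#' @param X Numeric feature matrix (n x p), n >= 5.
#' @param y Numeric targets (mm).
#' @param n_trees Number of trees.
#' @param seed Seed for the bootstrap draws.
#' @return A `ctv_regressor`.
#' @export
train_rf <- function(X, y, n_trees = 100L, seed = 1L) {
  d <- check_xy(X, y, min_n = 5L)
  fit <- with_seed(seed, randomForest::randomForest(
    d$X, d$y, ntree = as.integer(n_trees),
    mtry = max(1L, ceiling(ncol(d$X) / 3)), nodesize = 5L))
  structure(list(architecture = "rf", fit = fit, n_trees = n_trees,
                 n_features = ncol(d$X)),
            class = c("ctv_rf", "ctv_regressor"))
}

#' Train any of the five architectures
#'
#' @param architecture One of `r paste(architectures(), collapse = ", ")`.
#' @param X,y Training data.
#' @param hyper The architecture's tuning value (hidden nodes, epsilon, or
#'   number of trees); defaults: 4 nodes, epsilon 0.1, 100 trees.
#' @param seed Seed for stochastic trainers.
#' @export
train_regressor <- function(architecture, X, y, hyper = NULL, seed = 1L) {
  architecture <- match.arg(architecture, architectures())
  switch(architecture,
    br_ann = train_br_ann(X, y, hidden_nodes = hyper %||% 4L, seed = seed),
    lm_ann = train_lm_ann(X, y, hidden_nodes = hyper %||% 4L, seed = seed),
    scg_ann = train_scg_ann(X, y, hidden_nodes = hyper %||% 4L, seed = seed),
    svr = train_svr(X, y, epsilon = hyper %||% 0.1),
    rf = train_rf(X, y, n_trees = hyper %||% 100L, seed = seed))
}

#' Predict shift components from a fitted regressor
#'
#' @param object A `ctv_regressor`.
#' @param newdata Feature matrix with the training column count.
#' @param ... Unused.
#' @return Numeric predictions, mm.
#' @export
predict.ctv_regressor <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$n_features) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         object$n_features)
  }
  if (!all(is.finite(X))) stop("non-finite values in newdata")
  if (inherits(object, "ctv_rf")) {
    return(unname(stats::predict(object$fit, X)))
  }
  Xs <- sweep(sweep(X, 2L, object$x_center), 2L, object$x_scale, "/")
  ys <- if (inherits(object, "ctv_svr")) {
    if (is.null(object$fit)) rep(0, nrow(Xs))
    else unname(stats::predict(object$fit, Xs))
  } else {
    ann_forward(object$fit$theta, Xs, object$fit$hidden_nodes)$yhat
  }
  ys * object$y_scale + object$y_center
}

#' Pick a hyperparameter by smallest training error
#'
#' Fits the architecture at every grid value and returns the value with the
#' smallest mean absolute training error; ties go to the smallest value.
#'
#' @param X,y Training data.
#' @param architecture Architecture name.
#' @param grid Candidate values; defaults to [architecture_grids()].
#' @param seed Seed reused for every candidate fit.
#' @return List with `value`, and `errors` (one MAE per grid value).
#' @export
select_hyperparameters <- function(X, y, architecture,
                                   grid = NULL, seed = 1L) {
  architecture <- match.arg(architecture, architectures())
  grid <- grid %||% architecture_grids()[[architecture]]
  if (!length(grid)) stop("empty hyperparameter grid")
  grid <- sort(grid)
  errors <- vapply(grid, function(g) {
    m <- train_regressor(architecture, X, y, hyper = g, seed = seed)
    mean(abs(stats::predict(m, X) - y))
  }, numeric(1))
  list(value = grid[which.min(errors)], grid = grid, errors = errors)
}

#' Serialize a fitted regressor to portable JSON
#'
#' ANN weights, the SVR support-vector expansion, or the RF tree list
#' (via [randomForest::getTree()]), together with the standardization
#' statistics, so a model survives a session boundary as plain text.
#'
#' @param model A `ctv_regressor`.
#' @param path Output file.
#' @export
write_model <- function(model, path) {
  base <- list(architecture = model$architecture,
               n_features = model$n_features)
  obj <- if (inherits(model, "ctv_rf")) {
    trees <- lapply(seq_len(model$fit$ntree), function(k) {
      if (model$fit$forest$ndbigtree[k] == 1L) {
        # single-leaf tree; getTree() cannot represent it
        matrix(c(0, 0, 0, 0, -1, model$fit$forest$nodepred[1L, k]),
               nrow = 1L)
      } else {
        unname(as.matrix(randomForest::getTree(model$fit, k,
                                               labelVar = FALSE)))
      }
    })
    c(base, list(trees = trees))
  } else if (inherits(model, "ctv_svr")) {
    c(base, list(sv = unname(as.matrix(model$fit$SV)),
                 coefs = as.numeric(model$fit$coefs),
                 rho = model$fit$rho, gamma = model$gamma,
                 epsilon = model$epsilon, cost = model$cost,
                 x_center = unname(model$x_center),
                 x_scale = unname(model$x_scale),
                 y_center = model$y_center, y_scale = model$y_scale))
  } else {
    c(base, list(theta = model$fit$theta,
                 hidden_nodes = model$fit$hidden_nodes,
                 x_center = unname(model$x_center),
                 x_scale = unname(model$x_scale),
                 y_center = model$y_center, y_scale = model$y_scale))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized regressor
#'
#' @param path JSON file written by [write_model()].
#' @return A `ctv_regressor` (`ctv_json_model`) usable with `predict()`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$n_features <- as.integer(obj$n_features)
  class(obj) <- c("ctv_json_model", "ctv_regressor_json")
  obj
}

#' @export
predict.ctv_json_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$n_features) stop("feature count mismatch")
  if (object$architecture == "rf") {
    preds <- vapply(object$trees, function(tr) {
      if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1L)
      # columns: left, right, split var, split point, status, prediction
      apply(X, 1L, function(x) {
        node <- 1L
        while (tr[node, 5L] != -1) {
          node <- if (x[tr[node, 3L]] <= tr[node, 4L]) tr[node, 1L]
                  else tr[node, 2L]
        }
        tr[node, 6L]
      })
    }, numeric(nrow(X)))
    return(rowMeans(matrix(preds, nrow = nrow(X))))
  }
  Xs <- sweep(sweep(X, 2L, object$x_center), 2L, object$x_scale, "/")
  ys <- if (object$architecture == "svr") {
    sv <- matrix(object$sv, ncol = object$n_features)
    K <- exp(-object$gamma * (outer(rowSums(Xs^2), rowSums(sv^2), "+") -
                                2 * (Xs %*% t(sv))))
    drop(K %*% object$coefs) - object$rho
  } else {
    ann_forward(object$theta, Xs, as.integer(object$hidden_nodes))$yhat
  }
  ys * object$y_scale + object$y_center
}
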