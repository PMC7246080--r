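# Single-hidden-layer regression networks (tanh hidden units, linear
# output) trained by the three classical batch backpropagation variants:
# Levenberg-Marquardt (mu0 = 0.001), Bayesian regularization inside the LM
# loop (mu0 = 0.005, MacKay evidence updates of alpha/beta), and Moller's
# scaled conjugate gradient (lambda0 = 5e-7). Inputs and targets are
# z-scored internally; all weights live in one parameter vector.

ann_n_weights <- function(p, h) h * (p + 1L) + h + 1L

ann_unpack <- function(theta, p, h) {
  W1 <- matrix(theta[seq_len(h * p)], nrow = h, ncol = p)
  b1 <- theta[h * p + seq_len(h)]
  w2 <- theta[h * p + h + seq_len(h)]
  b2 <- theta[h * p + 2L * h + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

ann_forward <- function(theta, X, h) {
  p <- ncol(X)
  w <- ann_unpack(theta, p, h)
  Z <- tanh(sweep(X %*% t(w$W1), 2L, w$b1, "+"))
  list(yhat = drop(Z %*% w$w2 + w$b2), Z = Z, w = w)
}

# Jacobian of the network output wrt the weights, n x W.
ann_jacobian <- function(fw, X, h) {
  Z <- fw$Z; w2 <- fw$w$w2
  dZ <- (1 - Z^2) * rep(w2, each = nrow(Z))     # n x h: w2_k * (1 - z_k^2)
  Jw1 <- matrix(0, nrow(X), h * ncol(X))
  for (j in seq_len(ncol(X))) {
    Jw1[, (j - 1L) * h + seq_len(h)] <- dZ * X[, j]
  }
  cbind(Jw1, dZ, Z, 1)
}

# Weight layout note: ann_jacobian orders W1 column-major (all hidden units
# for input 1, then input 2, ...), matching ann_unpack's matrix fill.

ann_init <- function(p, h, seed) {
  with_seed(seed, stats::runif(ann_n_weights(p, h), -0.5, 0.5))
}

ann_standardize <- function(X, y) {
  xc <- colMeans(X)
  xs <- apply(X, 2L, stats::sd)
  xs[!is.finite(xs) | xs < 1e-12] <- 1
  yc <- mean(y)
  ys <- stats::sd(y)
  if (!is.finite(ys) || ys < 1e-12) ys <- 1
  list(Xs = sweep(sweep(X, 2L, xc), 2L, xs, "/"), ys_y = (y - yc) / ys,
       x_center = xc, x_scale = xs, y_center = yc, y_scale = ys)
}

check_xy <- function(X, y, min_n = 2L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes disagree")
  if (nrow(X) < min_n) stop("need at least ", min_n, " samples")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in the training data")
  }
  list(X = X, y = y)
}

# Core LM loop; when `bayes` is TRUE the objective is
# beta * SSE + alpha * ||theta||^2 with evidence re-estimation of
# alpha/beta after every accepted step.
ann_train_lm <- function(X, y, hidden_nodes, seed, mu0, bayes,
                         max_epochs = 1000L, grad_tol = 1e-7,
                         mu_max = 1e10) {
  h <- as.integer(hidden_nodes)
  p <- ncol(X)
  n <- nrow(X)
  W <- ann_n_weights(p, h)
  theta <- ann_init(p, h, seed)
  mu <- mu0
  alpha <- if (bayes) 0 else NA_real_
  beta <- 1
  objective <- function(theta) {
    fw <- ann_forward(theta, X, h)
    r <- fw$yhat - y
    sse <- sum(r^2)
    obj <- if (bayes) beta * sse + alpha * sum(theta^2) else sse
    list(fw = fw, r = r, sse = sse, obj = obj)
  }
  cur <- objective(theta)
  trace_sse <- numeric(0)
  hyper <- NULL
  for (epoch in seq_len(max_epochs)) {
    J <- ann_jacobian(cur$fw, X, h)
    g <- 2 * (beta * drop(crossprod(J, cur$r)) +
                if (bayes) alpha * theta else 0)
    if (max(abs(g)) < grad_tol) break
    JtJ <- crossprod(J)
    rhs <- beta * drop(crossprod(J, cur$r)) + if (bayes) alpha * theta else 0
    accepted <- FALSE
    while (mu <= mu_max) {
      A <- beta * JtJ + diag(mu + if (bayes) alpha else 0, W)
      step <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (!is.null(step)) {
        cand_theta <- theta - step
        cand <- objective(cand_theta)
        if (is.finite(cand$obj) && cand$obj < cur$obj) {
          theta <- cand_theta
          cur <- cand
          mu <- max(mu / 10, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!accepted) break
    if (bayes) {
      # MacKay evidence update: effective number of parameters gamma.
      H <- 2 * beta * JtJ + diag(2 * max(alpha, 1e-12), W)
      Hin <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Hin)) {
        gamma <- W - 2 * max(alpha, 1e-12) * sum(diag(Hin))
        gamma <- min(max(gamma, 1e-6), W - 1e-6)
        ew <- sum(theta^2)
        alpha <- gamma / (2 * max(ew, 1e-12))
        beta <- max((n - gamma), 1e-6) / (2 * max(cur$sse, 1e-12))
        hyper <- rbind(hyper, c(epoch = epoch, alpha = alpha, beta = beta,
                                gamma = gamma))
        cur <- objective(theta)  # objective changed with alpha/beta
      }
    }
    trace_sse <- c(trace_sse, cur$sse)
  }
  list(theta = theta, hidden_nodes = h, sse_trace = trace_sse,
       hyper_trace = hyper, epochs = length(trace_sse))
}

# Moller's scaled conjugate gradient on the SSE surface.
ann_train_scg <- function(X, y, hidden_nodes, seed, lambda0 = 5e-7,
                          max_epochs = 1000L, grad_tol = 1e-7) {
  h <- as.integer(hidden_nodes)
  sigma0 <- 5e-5
  E <- function(theta) {
    fw <- ann_forward(theta, X, h)
    sum((fw$yhat - y)^2)
  }
  gradE <- function(theta) {
    fw <- ann_forward(theta, X, h)
    2 * drop(crossprod(ann_jacobian(fw, X, h), fw$yhat - y))
  }
  theta <- ann_init(ncol(X), h, seed)
  lambda <- lambda0; lambda_bar <- 0
  r <- -gradE(theta)
  p_dir <- r
  success <- TRUE
  e_cur <- E(theta)
  trace_sse <- e_cur
  delta <- 0; mu <- 0
  for (k in seq_len(max_epochs)) {
    if (max(abs(r)) < grad_tol) break
    if (success) {
      p2 <- sum(p_dir^2)
      if (p2 < 1e-300) break
      sigma <- sigma0 / sqrt(p2)
      s_vec <- (gradE(theta + sigma * p_dir) - gradE(theta)) / sigma
      delta <- sum(p_dir * s_vec)
    }
    delta_l <- delta + (lambda - lambda_bar) * sum(p_dir^2)
    if (delta_l <= 0) {
      lambda_bar <- 2 * (lambda - delta_l / sum(p_dir^2))
      delta_l <- -delta + lambda * sum(p_dir^2)
      lambda <- lambda_bar
    }
    mu <- sum(p_dir * r)
    alpha_step <- mu / delta_l
    theta_new <- theta + alpha_step * p_dir
    e_new <- E(theta_new)
    Delta <- 2 * delta_l * (e_cur - e_new) / mu^2
    if (is.finite(Delta) && Delta >= 0) {
      theta <- theta_new
      e_cur <- e_new
      r_new <- -gradE(theta)
      lambda_bar <- 0
      success <- TRUE
      if (k %% length(theta) == 0) {
        p_dir <- r_new                      # restart
      } else {
        beta_cg <- (sum(r_new^2) - sum(r_new * r)) / mu
        p_dir <- r_new + beta_cg * p_dir
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
      trace_sse <- c(trace_sse, e_cur)
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (!is.finite(Delta) || Delta < 0.25) {
      lambda <- lambda + delta * (1 - max(Delta, 0)) / sum(p_dir^2)
    }
    if (lambda > 1e20) break
  }
  list(theta = theta, hidden_nodes = h, sse_trace = trace_sse,
       epochs = length(trace_sse))
}

new_ann_regressor <- function(architecture, fit, std, p) {
  structure(list(architecture = architecture, fit = fit,
                 x_center = std$x_center, x_scale = std$x_scale,
                 y_center = std$y_center, y_scale = std$y_scale,
                 n_features = p),
            class = c("ctv_ann", "ctv_regressor"))
}

#' Train a Levenberg-Marquardt neural network
#'
#' Single hidden layer (tanh), linear output, full-batch LM on the
#' sum-of-squared error with mu multiplied/divided by 10 on rejected /
#' accepted steps (mu0 = 0.001). Stops at `max_epochs`, at gradient
#' infinity-norm < `grad_tol`, or when no step can be accepted.
#'
#' @param X Numeric feature matrix (n x p).
#' @param y Numeric target (shift component, mm).
#' @param hidden_nodes Hidden-layer width (the tuning grid is 4..10).
#' @param seed Seed for the weight initialization.
#' @param max_epochs,grad_tol Stopping controls.
#' @return A `ctv_regressor` with the fitted weights and the z-scoring
#'   statistics used at both fit and predict time.
#' @export
train_lm_ann <- function(X, y, hidden_nodes = 4L, seed = 1L,
                         max_epochs = 1000L, grad_tol = 1e-7) {
  d <- check_xy(X, y)
  std <- ann_standardize(d$X, d$y)
  fit <- ann_train_lm(std$Xs, std$ys_y, hidden_nodes, seed, mu0 = 0.001,
                      bayes = FALSE, max_epochs = max_epochs,
                      grad_tol = grad_tol)
  new_ann_regressor("lm_ann", fit, std, ncol(d$X))
}

#' Train a Bayesian-regularized neural network
#'
#' As [train_lm_ann()] (mu0 = 0.005) but minimizing
#' `beta * SSE + alpha * ||w||^2` with alpha and beta re-estimated after
#' every accepted step from the evidence / effective-number-of-parameters
#' update, which shrinks the weights on noisy targets.
#'
#' @inheritParams train_lm_ann
#' @export
train_br_ann <- function(X, y, hidden_nodes = 4L, seed = 1L,
                         max_epochs = 1000L, grad_tol = 1e-7) {
  d <- check_xy(X, y)
  std <- ann_standardize(d$X, d$y)
  fit <- ann_train_lm(std$Xs, std$ys_y, hidden_nodes, seed, mu0 = 0.005,
                      bayes = TRUE, max_epochs = max_epochs,
                      grad_tol = grad_tol)
  new_ann_regressor("br_ann", fit, std, ncol(d$X))
}

#' Train a scaled-conjugate-gradient neural network
#'
#' Moller's SCG with initial scale lambda = 5e-7; same architecture and
#' stopping rules as the LM variant.
#'
#' @inheritParams train_lm_ann
#' @export
train_scg_ann <- function(X, y, hidden_nodes = 4L, seed = 1L,
                          max_epochs = 1000L, grad_tol = 1e-7) {
  d <- check_xy(X, y)
  std <- ann_standardize(d$X, d$y)
  fit <- ann_train_scg(std$Xs, std$ys_y, hidden_nodes, seed,
                       max_epochs = max_epochs, grad_tol = grad_tol)
  new_ann_regressor("scg_ann", fit, std, ncol(d$X))
}
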