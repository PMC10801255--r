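#' Initialize the tabular classifier
#'
#' A one-hidden-layer fully connected network (the backbone used throughout:
#' input -> hidden ReLU layer -> softmax output). Weights are drawn uniformly
#' from a symmetric interval of half-width 1/sqrt(fan-in); biases start at 0.
#'
#' @param d input dimension.
#' @param hidden_width hidden layer width; 64 is the default backbone, 256
#'   is conventional for larger tables.
#' @param K number of output classes.
#' @param seed integer seed; initialization is deterministic given the seed.
#' @return An object of class `predictor_state` with parameter list `theta`
#'   (`W1` d x h, `b1`, `W2` h x K, `b2`), empty `optimizer_state`, and
#'   `step_count = 0`.
#' @export
init_predictor <- function(d, hidden_width = 64L, K = 2L, seed = 1L) {
  stopifnot(d >= 1, hidden_width >= 1, K >= 1)
  theta <- with_seed(substream_seed(seed, "init"), {
    s1 <- 1 / sqrt(d)
    s2 <- 1 / sqrt(hidden_width)
    list(
      W1 = matrix(stats::runif(d * hidden_width, -s1, s1), d, hidden_width),
      b1 = rep(0, hidden_width),
      W2 = matrix(stats::runif(hidden_width * K, -s2, s2), hidden_width, K),
      b2 = rep(0, K)
    )
  })
  structure(
    list(theta = theta, hidden_width = as.integer(hidden_width),
         d = as.integer(d), K = as.integer(K),
         optimizer_state = list(), step_count = 0L),
    class = "predictor_state"
  )
}

#' @export
print.predictor_state <- function(x, ...) {
  cat(sprintf("<predictor_state> %d -> %d -> %d, %d update step(s)\n",
              x$d, x$hidden_width, x$K, x$step_count))
  invisible(x)
}

# numerically stable row-wise softmax
softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

forward_pass <- function(state, X) {
  Z <- X %*% state$theta$W1
  Z <- sweep(Z, 2, state$theta$b1, `+`)
  H <- pmax(Z, 0)
  S <- H %*% state$theta$W2
  S <- sweep(S, 2, state$theta$b2, `+`)
  list(Z = Z, H = H, P = softmax_rows(S))
}

#' Predicted class probabilities
#'
#' @param state a `predictor_state`.
#' @param X feature matrix (rows are samples).
#' @return n x K matrix of softmax probabilities (rows sum to 1).
#' @export
predict_probs <- function(state, X) {
  forward_pass(state, as.matrix(X))$P
}

#' Predicted class labels (0-based; ties broken toward the lower class)
#'
#' @inheritParams predict_probs
#' @return integer vector of predicted labels in 0..K-1.
#' @export
predict_class <- function(state, X) {
  max.col(predict_probs(state, X), ties.method = "first") - 1L
}

#' Weighted cross-entropy loss and its exact gradient
#'
#' loss = sum_j w_j * CE(softmax(f(x_j)), y_j) / |batch|. The gradient is the
#' exact derivative (manual backpropagation); samples with weight 0 contribute
#' nothing.
#'
#' @param state a `predictor_state`.
#' @param X batch feature matrix.
#' @param y 0-based integer labels for the batch.
#' @param sample_weights nonnegative weights, one per batch row (default 1).
#' @return list with `loss` (scalar) and `gradient` (list matching `theta`).
#' @export
weighted_loss_grad <- function(state, X, y,
                               sample_weights = rep(1, length(y))) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m == 0L) stop("empty batch")
  if (length(sample_weights) != m) stop("one weight per batch row required")
  if (any(!is.finite(sample_weights)) || any(sample_weights < 0)) {
    stop("sample weights must be finite and nonnegative")
  }
  fw <- forward_pass(state, X)
  idx <- cbind(seq_len(m), y + 1L)
  p_true <- pmax(fw$P[idx], 1e-12)
  loss <- sum(sample_weights * (-log(p_true))) / m
  # dL/dS = w_j * (p - onehot(y)) / m, row-wise
  dS <- fw$P
  dS[idx] <- dS[idx] - 1
  dS <- dS * (sample_weights / m)
  dW2 <- crossprod(fw$H, dS)
  db2 <- colSums(dS)
  dH <- dS %*% t(state$theta$W2)
  dZ <- dH * (fw$Z > 0)
  dW1 <- crossprod(X, dZ)
  db1 <- colSums(dZ)
  list(loss = loss,
       gradient = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Mean cross-entropy of the model on a set of rows
#'
#' @param state a `predictor_state`.
#' @param X feature matrix; @param y 0-based labels.
#' @return scalar mean cross-entropy.
#' @export
mean_loss <- function(state, X, y) {
  X <- as.matrix(X)
  P <- forward_pass(state, X)$P
  p_true <- pmax(P[cbind(seq_len(nrow(X)), y + 1L)], 1e-12)
  mean(-log(p_true))
}

#' Apply an optimizer update to the predictor
#'
#' `sgd`: theta <- theta - eta * gradient. `adam`: standard first/second
#' moment update with (beta1, beta2, eps) = (0.9, 0.999, 1e-8) and bias
#' correction, keeping the accumulators in `optimizer_state`.
#'
#' @param state a `predictor_state`.
#' @param gradient parameter-shaped gradient list.
#' @param eta positive stepsize.
#' @param optimizer `"sgd"` or `"adam"`.
#' @return the updated `predictor_state` (`step_count` incremented).
#' @export
apply_update <- function(state, gradient, eta, optimizer = c("sgd", "adam")) {
  optimizer <- match.arg(optimizer)
  for (nm in names(state$theta)) {
    if (any(!is.finite(gradient[[nm]]))) {
      stop("non-finite gradient in parameter ", nm)
    }
  }
  if (optimizer == "sgd") {
    for (nm in names(state$theta)) {
      state$theta[[nm]] <- state$theta[[nm]] - eta * gradient[[nm]]
    }
  } else {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    t <- state$step_count + 1L
    if (is.null(state$optimizer_state$m)) {
      state$optimizer_state$m <- lapply(state$theta, function(p) p * 0)
      state$optimizer_state$v <- lapply(state$theta, function(p) p * 0)
    }
    for (nm in names(state$theta)) {
      g <- gradient[[nm]]
      state$optimizer_state$m[[nm]] <-
        b1 * state$optimizer_state$m[[nm]] + (1 - b1) * g
      state$optimizer_state$v[[nm]] <-
        b2 * state$optimizer_state$v[[nm]] + (1 - b2) * g^2
      mhat <- state$optimizer_state$m[[nm]] / (1 - b1^t)
      vhat <- state$optimizer_state$v[[nm]] / (1 - b2^t)
      state$theta[[nm]] <- state$theta[[nm]] - eta * mhat / (sqrt(vhat) + eps)
    }
  }
  state$step_count <- state$step_count + 1L
  for (nm in names(state$theta)) {
    if (any(!is.finite(state$theta[[nm]]))) {
      stop("non-finite parameters after update in ", nm)
    }
  }
  state
}

#' Serialize predictor parameters to JSON
#'
#' Writes a flat checkpoint with a shape manifest; [read_predictor_json()]
#' restores it.
#'
#' @param state a `predictor_state`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictor_json <- function(state, path) {
  obj <- list(
    d = state$d, hidden_width = state$hidden_width, K = state$K,
    step_count = state$step_count,
    shapes = lapply(state$theta, function(p) {
      if (is.matrix(p)) dim(p) else length(p)
    }),
    values = lapply(state$theta, as.numeric)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a predictor from a JSON checkpoint
#'
#' @param path path written by [write_predictor_json()].
#' @return a `predictor_state` (optimizer accumulators are not persisted).
#' @export
read_predictor_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- list()
  for (nm in names(obj$values)) {
    v <- as.numeric(obj$values[[nm]])
    sh <- unlist(obj$shapes[[nm]])
    theta[[nm]] <- if (length(sh) == 2) matrix(v, sh[1], sh[2]) else v
  }
  structure(
    list(theta = theta, hidden_width = as.integer(obj$hidden_width),
         d = as.integer(obj$d), K = as.integer(obj$K),
         optimizer_state = list(), step_count = as.integer(obj$step_count)),
    class = "predictor_state"
  )
}
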