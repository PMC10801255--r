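#' Exponentiated (negative-entropy mirror ascent) weight update
#'
#' The closed-form maximizer of the linearized objective plus a (1/gamma)
#' KL proximity term: lambda_i proportional to lambda_i * exp(gamma * scale *
#' v_i), renormalized to the simplex. The federated form uses `scale = E`
#' (the number of local iterations the snapshot losses stand in for).
#' Numerically stabilized by subtracting the maximum exponent.
#'
#' @param weights simplex vector (current lambda).
#' @param v real vector of per-group losses (the lambda-gradient).
#' @param gamma positive ascent stepsize.
#' @param scale positive multiplier on the exponent (default 1).
#' @return the updated simplex vector.
#' @export
exponentiated_update <- function(weights, v, gamma, scale = 1) {
  if (length(weights) != length(v)) stop("weights and v length mismatch")
  if (any(!is.finite(v))) stop("non-finite loss vector v")
  e <- gamma * scale * v
  w <- weights * exp(e - max(e))
  w / sum(w)
}

#' Project weights into the chi-square uncertainty ball
#'
#' If the input already satisfies D_f(|G| lambda || 1) <= rho it is returned
#' unchanged; otherwise the weights are contracted along the segment toward
#' the uniform vector until the ball constraint holds with equality (for the
#' chi-square ball this contraction has a closed form and coincides with the
#' Euclidean projection onto the ball-simplex intersection). `rho = 0`
#' returns the uniform vector.
#'
#' @param weights simplex vector.
#' @param rho nonnegative ball radius.
#' @return a simplex vector satisfying the ball constraint (within 1e-7).
#' @export
project_weights <- function(weights, rho) {
  if (rho < 0) stop("rho must be >= 0")
  if (!check_simplex(weights, tol = 1e-6)) stop("weights must lie on the simplex")
  G <- length(weights)
  u <- rep(1 / G, G)
  D <- chisq_ball_divergence(weights)
  if (D <= rho) return(weights)
  s <- sqrt(rho / D)
  u + s * (weights - u)
}

#' Centralized stochastic mirror descent ascent
#'
#' Alternates, per iteration: sample a minibatch, take a descent step on the
#' model with per-sample weight |G| * lambda_g(sample) (so uniform weights
#' reproduce plain training at the same stepsize; `rescale_weights = FALSE`
#' uses the raw lambda_g multiplier), then update lambda by an exponentiated
#' ascent step on the current per-group losses followed by projection into
#' the chi-square ball. Deterministic given `seed`.
#'
#' @param dataset a [tabular_dataset()].
#' @param grouping a `grouping_scheme` over the dataset's rows.
#' @param spec an [uncertainty_set_spec()] (its `rho` bounds the ball).
#' @param schedule list with `T` (iterations), `eta`, `gamma`, `batch_size`,
#'   and optionally `hidden_width` (default 64) and `optimizer`
#'   (default `"sgd"`).
#' @param seed integer master seed.
#' @param rescale_weights multiply per-sample weights by |G| (default TRUE).
#' @return list with `state` (final `predictor_state`), `weights` (final
#'   simplex vector), and `trace` (long data frame: iteration, loss, group,
#'   risk, weight).
#' @export
smda_run <- function(dataset, grouping, spec, schedule, seed = 1L,
                     rescale_weights = TRUE) {
  rows <- which(!is.na(grouping$group_of_row))
  G <- grouping$n_groups
  Tn <- schedule$T
  bs <- schedule$batch_size
  hw <- if (is.null(schedule$hidden_width)) 64L else schedule$hidden_width
  opt <- if (is.null(schedule$optimizer)) "sgd" else schedule$optimizer
  state <- init_predictor(dataset$d, hw, dataset$n_classes, seed = seed)
  lambda <- rep(1 / G, G)
  # pre-draw all batches so weight-free training with the same seed follows
  # the identical sample path
  batches <- with_seed(substream_seed(seed, "smda_batches"), {
    matrix(rows[sample.int(length(rows), Tn * bs, replace = TRUE)], Tn, bs)
  })
  scale_g <- if (rescale_weights) G else 1
  trace <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    b <- batches[t, ]
    w <- scale_g * lambda[grouping$group_of_row[b]]
    lg <- weighted_loss_grad(state, dataset$features[b, , drop = FALSE],
                             dataset$labels[b], w)
    state <- apply_update(state, lg$gradient, schedule$eta, opt)
    gr <- group_risks(state, dataset, grouping, rows)
    lambda <- project_weights(
      exponentiated_update(lambda, gr$risks, schedule$gamma, 1), spec$rho)
    trace[[t]] <- data.frame(iteration = t, loss = lg$loss,
                             group = seq_len(G), risk = gr$risks,
                             weight = lambda)
  }
  list(state = state, weights = lambda, trace = do.call(rbind, trace))
}
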