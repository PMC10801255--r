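#' Uncertainty-set specification
#'
#' Describes the f-divergence ball of group-weight distributions over which
#' the distributionally robust risk is maximized: a chi-square ball of radius
#' `rho` around the uniform weighting, at one of the four fairness levels.
#' `rho = 0` collapses the set to the uniform point (empirical risk
#' minimization); a very large `rho` admits a point mass on the worst group.
#'
#' @param level `"client"`, `"attribute"`, `"multilevel"` or `"agnostic"`.
#' @param rho ball radius, >= 0.
#' @param beta multilevel mixing coefficient in [0, 1] (probability a sampled
#'   row is weighted by its client weight rather than its attribute weight);
#'   ignored at the other levels.
#' @param divergence f-divergence of the ball; only `"chi2"`
#'   (f(t) = (t-1)^2) is implemented.
#' @return An object of class `uncertainty_set_spec`.
#' @export
uncertainty_set_spec <- function(level = c("client", "attribute",
                                           "multilevel", "agnostic"),
                                 rho = 0, beta = 0.5,
                                 divergence = "chi2") {
  level <- match.arg(level)
  divergence <- match.arg(divergence, "chi2")
  if (rho < 0) stop("rho must be >= 0")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  structure(list(level = level, rho = rho, beta = beta,
                 divergence = divergence),
            class = "uncertainty_set_spec")
}

#' Per-group empirical risks
#'
#' Mean cross-entropy of the model over each group's rows, with per-group
#' sample counts.
#'
#' @param state a `predictor_state`.
#' @param dataset a [tabular_dataset()].
#' @param rows row indices to evaluate (default: all rows the grouping
#'   covers).
#' @param grouping a `grouping_scheme`; its primary `group_of_row` map is
#'   used.
#' @return An object of class `group_risk_vector`: `risks`, `counts`,
#'   `n_groups`, `level`.
#' @export
group_risks <- function(state, dataset, grouping, rows = NULL) {
  if (is.null(rows)) rows <- which(!is.na(grouping$group_of_row))
  g <- grouping$group_of_row[rows]
  if (anyNA(g)) stop("some requested rows are outside the grouping")
  counts <- tabulate(g, nbins = grouping$n_groups)
  if (any(counts == 0)) {
    stop("group(s) with zero rows in the evaluated subset: ",
         paste(which(counts == 0), collapse = ", "))
  }
  P <- predict_probs(state, dataset$features[rows, , drop = FALSE])
  ce <- -log(pmax(P[cbind(seq_along(rows), dataset$labels[rows] + 1L)],
                  1e-12))
  risks <- as.numeric(tapply(ce, factor(g, levels = seq_len(grouping$n_groups)),
                             mean))
  structure(list(risks = risks, counts = counts,
                 n_groups = grouping$n_groups, level = grouping$level),
            class = "group_risk_vector")
}

#' Weighted group risk
#'
#' The lambda-player's objective F(theta, lambda) = sum_i lambda_i * f_i.
#'
#' @param risks a `group_risk_vector` or plain numeric vector of group risks.
#' @param weights simplex vector of matching length.
#' @return scalar weighted risk.
#' @export
weighted_risk <- function(risks, weights) {
  f <- if (inherits(risks, "group_risk_vector")) risks$risks else risks
  if (length(f) != length(weights)) stop("risks and weights length mismatch")
  sum(f * weights)
}

#' Variance-penalized fairness risk
#'
#' The intractable ancestor of the robust objective: count-weighted overall
#' risk plus C times the population variance of the per-group risks divided
#' by the number of groups. C = 0 recovers the overall risk; equal group
#' risks zero the penalty.
#'
#' @param risks a `group_risk_vector`.
#' @param C nonnegative utility/fairness balance constant.
#' @return scalar penalized risk.
#' @export
variance_penalized_risk <- function(risks, C = 0) {
  stopifnot(inherits(risks, "group_risk_vector"), C >= 0)
  G <- risks$n_groups
  if (C > 0 && G < 2) stop("need at least 2 groups when C > 0")
  rbar <- sum(risks$risks * risks$counts) / sum(risks$counts)
  v <- mean((risks$risks - mean(risks$risks))^2)  # population variance
  rbar + C * v / G
}

# Maximize sum(lambda * f) over the simplex intersected with the chi-square
# ball D_f(G*lambda || 1) <= rho, i.e. sum((lambda_i - 1/G)^2) <= rho/G.
# The maximizer is proj_simplex(u + t*f) for the dual stepsize t >= 0 at
# which the ball constraint is active (or the simplex-constrained maximum if
# the ball is slack there); solved by bisection on t.
dro_argmax_weights <- function(f, rho) {
  G <- length(f)
  u <- rep(1 / G, G)
  if (rho <= 0 || diff(range(f)) == 0) return(u)
  r2 <- rho / G
  # normalized ascent direction: the maximizer family proj_simplex(u + t*c)
  # is invariant to positive rescaling of f, and with max|c| = 1 the
  # projection saturates (reaches the best simplex face) for t of order 1
  c_dir <- f - mean(f)
  c_dir <- c_dir / max(abs(c_dir))
  dist2 <- function(t) {
    lam <- proj_simplex(u + t * c_dir)
    sum((lam - u)^2)
  }
  t_hi <- 1
  d_prev <- -1
  for (rep in 1:40) {
    d <- dist2(t_hi)
    if (d >= r2 || abs(d - d_prev) <= 1e-16) break
    d_prev <- d
    t_hi <- t_hi * 4
  }
  if (dist2(t_hi) < r2) {
    # ball slack at saturation: simplex-constrained maximum
    return(proj_simplex(u + t_hi * c_dir))
  }
  t_lo <- 0
  for (it in 1:200) {
    t_mid <- (t_lo + t_hi) / 2
    if (dist2(t_mid) < r2) t_lo <- t_mid else t_hi <- t_mid
  }
  proj_simplex(u + t_hi * c_dir)
}

#' Distributionally robust group risk
#'
#' The worst-case weighted risk over the chi-square uncertainty ball:
#' max over simplex lambda with D_f(|G| lambda || 1) <= rho of
#' sum_i lambda_i f_i, solved by bisection on the dual variable of the ball.
#' At rho = 0 this is the plain mean of the group risks; as rho grows past
#' |G|^2 it reaches the worst group's risk.
#'
#' @param risks a `group_risk_vector` or numeric vector.
#' @param spec an [uncertainty_set_spec()] (only `rho` is used here).
#' @return list with `value` (the robust risk) and `weights` (the maximizing
#'   simplex vector).
#' @export
dro_risk <- function(risks, spec) {
  f <- if (inherits(risks, "group_risk_vector")) risks$risks else risks
  rho <- if (inherits(spec, "uncertainty_set_spec")) spec$rho else spec
  lam <- dro_argmax_weights(f, rho)
  list(value = sum(lam * f), weights = lam)
}
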