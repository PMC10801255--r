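# Independent oracles used by the tests. These deliberately use different
# algorithms from the package implementation (algebraic active-set
# enumeration, numeric optimization, brute-force counting), so agreement is
# evidence of correctness rather than repetition.

# --- exact DRO maximizer by active-set enumeration -------------------------
# maximize sum(lambda * f) over the simplex intersected with
# sum((lambda_i - 1/G)^2) <= rho/G. Every stationary point restricted to a
# support T has the form lambda_T = 1/|T| + s * (f_T - mean(f_T)); enumerate
# all supports and both quadratic roots, keep feasible candidates, take the
# best by value.
oracle_dro <- function(f, rho) {
  G <- length(f)
  r2 <- rho / G
  best <- list(value = -Inf, weights = rep(1 / G, G))
  consider <- function(lam) {
    if (any(lam < -1e-12)) return()
    lam <- pmax(lam, 0)
    lam <- lam / sum(lam)
    if (sum((lam - 1 / G)^2) > r2 + 1e-10) return()
    v <- sum(lam * f)
    if (v > best$value) best <<- list(value = v, weights = lam)
  }
  supports <- lapply(seq_len(2^G - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(G) - 1)) > 0)
  })
  for (T in supports) {
    m <- length(T)
    lam0 <- rep(0, G); lam0[T] <- 1 / m
    consider(lam0)
    c_vec <- f[T] - mean(f[T])
    A <- sum(c_vec^2)
    if (A > 0) {
      rhs <- r2 - (G - m) / G^2 - m * (1 / m - 1 / G)^2
      if (rhs >= 0) {
        s <- sqrt(rhs / A)
        for (sg in c(1, -1)) {
          lam <- rep(0, G); lam[T] <- 1 / m + sg * s * c_vec
          consider(lam)
        }
      }
    }
  }
  best
}

# --- exact Euclidean projection onto ball-and-simplex by enumeration -------
oracle_project <- function(w, rho) {
  G <- length(w)
  r2 <- rho / G
  if (sum((w - 1 / G)^2) <= r2 + 1e-15) return(w)
  best <- list(dist = Inf, lam = rep(1 / G, G))
  consider <- function(lam) {
    if (any(lam < -1e-12)) return()
    lam <- pmax(lam, 0)
    lam <- lam / sum(lam)
    if (sum((lam - 1 / G)^2) > r2 + 1e-10) return()
    d <- sum((lam - w)^2)
    if (d < best$dist) best <<- list(dist = d, lam = lam)
  }
  supports <- lapply(seq_len(2^G - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(G) - 1)) > 0)
  })
  for (T in supports) {
    m <- length(T)
    lam0 <- rep(0, G); lam0[T] <- 1 / m
    consider(lam0)
    c_vec <- w[T] - mean(w[T])
    A <- sum(c_vec^2)
    if (A > 0) {
      rhs <- r2 - (G - m) / G^2 - m * (1 / m - 1 / G)^2
      if (rhs >= 0) {
        s <- sqrt(rhs / A)
        for (sg in c(1, -1)) {
          lam <- rep(0, G); lam[T] <- 1 / m + sg * s * c_vec
          consider(lam)
        }
      }
    }
  }
  best$lam
}

# --- numeric proximal maximization for the mirror-ascent step --------------
# argmax over the simplex of  <v, lambda> - (1/gamma) * KL(lambda || w),
# solved by bounded quasi-Newton on the weights themselves (the KL barrier
# keeps the optimum interior).
# The simplex constraint is absorbed by a softmax parametrization for a
# global quasi-Newton search (two starts, best objective kept), then the
# interior optimum is polished by damped Newton on the reduced coordinates
# (lambda_G = 1 - sum of the rest) to machine precision.
oracle_mirror_prox <- function(w, v, gamma) {
  G <- length(w)
  objective <- function(lam) sum(v * lam) - sum(lam * log(lam / w)) / gamma
  lam_of <- function(z) {
    e <- exp(z - max(z))
    e / sum(e)
  }
  neg_obj_z <- function(z) -objective(lam_of(z))
  neg_grad_z <- function(z) {
    lam <- lam_of(z)
    g_lam <- v - (log(lam / w) + 1) / gamma
    -(lam * (g_lam - sum(lam * g_lam)))
  }
  best <- NULL
  for (start in list(log(w), rep(0, G))) {
    fit <- stats::optim(start, neg_obj_z, neg_grad_z, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 5000))
    cand <- lam_of(fit$par)
    if (is.null(best) || objective(cand) > objective(best)) best <- cand
  }
  # Newton polish in the reduced coordinates; KL keeps the optimum interior
  x <- pmin(pmax(best[-G], 1e-12), 1 - 1e-12)
  for (it in 1:50) {
    lamG <- 1 - sum(x)
    g <- (v[-G] - v[G]) - (log(x / w[-G]) - log(lamG / w[G])) / gamma
    H <- -(diag(1 / x, G - 1) + 1 / lamG) / gamma
    step <- tryCatch(solve(H, g), error = function(e) g * 0)
    damp <- 1
    repeat {
      x_new <- x - damp * step
      if (all(x_new > 0) && sum(x_new) < 1) break
      damp <- damp / 2
      if (damp < 1e-8) { x_new <- x; break }
    }
    if (max(abs(x_new - x)) < 1e-15) { x <- x_new; break }
    x <- x_new
  }
  c(x, 1 - sum(x))
}

# --- finite-difference gradient of the weighted loss -----------------------
oracle_fd_gradient <- function(state, X, y, w, h = 1e-5) {
  g <- list()
  for (nm in names(state$theta)) {
    p <- state$theta[[nm]]
    gp <- p * 0
    for (j in seq_along(p)) {
      sp <- state; sp$theta[[nm]][j] <- p[j] + h
      sm <- state; sm$theta[[nm]][j] <- p[j] - h
      lp <- weighted_loss_grad(sp, X, y, w)$loss
      lm <- weighted_loss_grad(sm, X, y, w)$loss
      gp[j] <- (lp - lm) / (2 * h)
    }
    g[[nm]] <- gp
  }
  g
}

# chi-square ball divergence recomputed from its definition
chisq_divergence_oracle <- function(lambda) {
  G <- length(lambda)
  mean((G * lambda - 1)^2)
}

# --- small benchmark used across training tests ----------------------------
tiny_benchmark <- function(seed = 1, n = 400, n_clients = 2, alpha = 1,
                           attribute_shift = 1, label_noise = 0.05) {
  suppressMessages(make_benchmark(synthetic_spec(
    n = n, d = 5, K = 2, n_clients = n_clients, alpha = alpha,
    class_separation = 2, attribute_shift = attribute_shift,
    label_noise = label_noise, seed = seed)))
}

# flatten model parameters for comparisons
theta_vec <- function(state) unlist(state$theta, use.names = FALSE)
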