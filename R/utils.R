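#' @keywords internal
"_PACKAGE"

# Deterministic substream seeds: one master seed fans out to named streams
# (partition, init, batching, ...) so each component is independently
# reproducible. Kept below 2^31 - 1.
substream_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(master) * 7919 + h * 104729 + 17) %% 2147483647L)
}

# Run expr under a local RNG state seeded with `seed`, restoring the caller's
# RNG afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Largest-remainder apportionment of `total` items to proportions `p`.
# Ties in the fractional parts are broken by index (lowest first).
largest_remainder <- function(total, p) {
  p <- p / sum(p)
  raw <- total * p
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, seq_along(p), decreasing = c(TRUE, FALSE),
                 method = "radix")
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# chi-square divergence of |G| * lambda from the all-ones vector:
# D_f(|G| lambda || 1) = (1/|G|) * sum((|G| lambda_i - 1)^2), f(t) = (t-1)^2.
chisq_ball_divergence <- function(lambda) {
  g <- length(lambda)
  sum((g * lambda - 1)^2) / g
}

# Euclidean projection of x onto the probability simplex (sort-based).
proj_simplex <- function(x) {
  n <- length(x)
  u <- sort(x, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_len(n) > 0))
  tau <- (css[rho] - 1) / rho
  pmax(x - tau, 0)
}

check_simplex <- function(lambda, tol = 1e-9) {
  all(lambda >= -tol) && abs(sum(lambda) - 1) <= tol
}
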