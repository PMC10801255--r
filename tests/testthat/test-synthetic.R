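test_that("generator is deterministic and validates its spec", {
  sp <- synthetic_spec(n = 200, d = 6, K = 3, seed = 5)
  expect_identical(generate_population(sp), generate_population(sp))
  expect_error(synthetic_spec(d = 1, K = 4, class_separation = 2), "d must")
  expect_error(synthetic_spec(attribute_spec = list(
    list(name = "a", n_values = 2L, probs = c(0.7, 0.7)))), "sum to 1")
})

test_that("class-conditional means sit at the specified separation", {
  # moments oracle: empirical cell means within 4 sigma / sqrt(n) of the
  # construction, pairwise class-mean distances equal class_separation
  sp <- synthetic_spec(n = 10000, d = 6, K = 3, alpha = 1, n_clients = 2,
                       class_separation = 3, attribute_shift = 0,
                       label_noise = 0, seed = 21)
  ds <- generate_population(sp)
  mus <- t(sapply(0:2, function(k) {
    colMeans(ds$features[ds$labels == k, , drop = FALSE])
  }))
  for (a in 1:2) for (b in (a + 1):3) {
    expect_equal(sqrt(sum((mus[a, ] - mus[b, ])^2)), 3, tolerance = 0.05)
  }
  # per-cell feature SD is 1 by construction; 4 sigma/sqrt(n) mean bound
  n_k <- min(table(ds$labels))
  grand <- colMeans(mus)
  expect_lt(max(abs(grand)), 4 / sqrt(3 * n_k))
})

test_that("label marginals match the uniform class prior", {
  sp <- synthetic_spec(n = 10000, d = 4, K = 4, label_noise = 0, seed = 13)
  ds <- generate_population(sp)
  p <- 1 / 4
  se <- sqrt(p * (1 - p) / ds$n)
  for (k in 0:3) {
    expect_lt(abs(mean(ds$labels == k) - p), 3 * se)
  }
})

test_that("zero attribute shift leaves class-conditional moments unshifted", {
  # with the shift disabled the attribute groups share the same distribution;
  # a two-sample mean test should reject at roughly the nominal level
  pvals <- vapply(1:20, function(s) {
    sp <- synthetic_spec(n = 400, d = 3, K = 2, attribute_shift = 0,
                         label_noise = 0, seed = s)
    ds <- generate_population(sp)
    sel <- ds$labels == 0
    a <- ds$attributes$sex[sel]
    stats::t.test(ds$features[sel, 1][a == 0],
                  ds$features[sel, 1][a == 1])$p.value
  }, 0)
  expect_lt(sum(pvals < 0.05), 5)
})

test_that("wide class separation is linearly separable", {
  sp <- synthetic_spec(n = 1000, d = 5, K = 2, class_separation = 6,
                       attribute_shift = 0, label_noise = 0, seed = 31)
  ds <- generate_population(sp)
  # separation is wide enough for the fit to separate perfectly; the glm
  # convergence warnings are the expected symptom of that
  fit <- suppressWarnings(
    stats::glm(ds$labels ~ ds$features, family = stats::binomial()))
  acc <- mean((fit$fitted.values > 0.5) == (ds$labels == 1))
  expect_gt(acc, 0.99)
})

test_that("attribute shift monotonically separates attribute groups", {
  dist_between <- function(shift, s) {
    ds <- generate_population(synthetic_spec(
      n = 2000, d = 5, K = 2, attribute_shift = shift, label_noise = 0,
      seed = s))
    a <- ds$attributes$sex
    m0 <- colMeans(ds$features[a == 0, ])
    m1 <- colMeans(ds$features[a == 1, ])
    sqrt(sum((m0 - m1)^2))
  }
  for (s in 1:5) {
    d_small <- dist_between(0.5, s)
    d_large <- dist_between(2, s)
    expect_gt(d_large, d_small)
  }
})

test_that("benchmark manifests regenerate byte-identically", {
  bm <- tiny_benchmark(seed = 17)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(bm$manifest, path, auto_unbox = TRUE, digits = NA)
  bm2 <- suppressMessages(benchmark_from_manifest(path))
  expect_identical(bm$dataset, bm2$dataset)
  expect_identical(bm$partition, bm2$partition)
  expect_identical(bm$train$client_rows, bm2$train$client_rows)
  expect_identical(lapply(bm$groupings, `[[`, "group_of_row"),
                   lapply(bm2$groupings, `[[`, "group_of_row"))
})

test_that("lower alpha gives stronger client label divergence", {
  tv_between_clients <- function(alpha, s) {
    bm <- suppressMessages(make_benchmark(synthetic_spec(
      n = 600, d = 3, K = 3, n_clients = 2, alpha = alpha,
      label_noise = 0, seed = s)))
    tabs <- lapply(bm$partition$client_rows, function(rows) {
      tabulate(bm$dataset$labels[rows] + 1L, 3) /
        length(rows)
    })
    sum(abs(tabs[[1]] - tabs[[2]])) / 2
  }
  tv_low <- mean(vapply(1:10, function(s) tv_between_clients(0.1, s), 0))
  tv_high <- mean(vapply(1:10, function(s) tv_between_clients(1e4, s), 0))
  expect_gt(tv_low, tv_high)
})

test_that("per-client test share is the requested fraction", {
  bm <- tiny_benchmark(seed = 23, n = 600, n_clients = 3, alpha = 10)
  for (i in 1:3) {
    n_tot <- length(bm$partition$client_rows[[i]])
    n_te <- length(bm$test$client_rows[[i]])
    expect_lt(abs(n_te - 0.2 * n_tot), 0.02 * n_tot + 2)
  }
})
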