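test_that("tabular_dataset validates its invariants", {
  X <- matrix(rnorm(20), 10, 2)
  ds <- tabular_dataset(X, rep(0:1, 5), list(sex = rep(c(0L, 1L), 5)))
  expect_equal(ds$n, 10)
  expect_equal(ds$n_classes, 2)
  expect_error(tabular_dataset(X, rep(0, 10)), "at least 2 classes")
  expect_error(tabular_dataset(X, rep(0:1, 5), list(sex = rep(2L, 10))),
               "contiguous")
  expect_error(tabular_dataset(X, c(rep(0:1, 4), NA, 1)), "missing")
})

test_that("dirichlet partition is a true partition and is deterministic", {
  ds <- generate_population(synthetic_spec(n = 500, d = 4, K = 3,
                                           seed = 11, label_noise = 0))
  for (alpha in c(0.1, 1, 100)) {
    p <- partition_dirichlet(ds, 3, alpha, seed = 5)
    all_rows <- sort(unlist(p$client_rows))
    expect_identical(all_rows, seq_len(ds$n))
    expect_true(all(vapply(p$client_rows, length, 1L) >= 2))
    p2 <- partition_dirichlet(ds, 3, alpha, seed = 5)
    expect_identical(p, p2)
  }
})

test_that("huge alpha gives near-even per-class splits", {
  ds <- generate_population(synthetic_spec(n = 1200, d = 4, K = 4,
                                           seed = 3, label_noise = 0))
  for (s in 1:20) {
    p <- partition_dirichlet(ds, 2, 1e4, seed = s)
    for (k in 0:3) {
      rows_k <- which(ds$labels == k)
      share <- length(intersect(rows_k, p$client_rows[[1]])) / length(rows_k)
      expect_lt(abs(share - 0.5), 0.05)
    }
  }
})

test_that("client shares follow the symmetric Dirichlet moments", {
  # closed-form oracle: for 2 clients the client-1 share of a class is
  # Beta(alpha, alpha): mean 1/2, variance 1/(4 (2 alpha + 1))
  ds <- generate_population(synthetic_spec(n = 400, d = 3, K = 2,
                                           seed = 2, label_noise = 0))
  rows0 <- which(ds$labels == 0)
  shares <- vapply(1:1000, function(s) {
    p <- partition_dirichlet(ds, 2, 0.1, seed = s, min_per_client = 0)
    length(intersect(rows0, p$client_rows[[1]])) / length(rows0)
  }, 0)
  alpha <- 0.1
  expect_lt(abs(mean(shares) - 0.5), 0.05)
  expect_lt(abs(stats::var(shares) - 1 / (4 * (2 * alpha + 1))), 0.02)
})

test_that("infeasible minimum client size fails with a clear message", {
  ds <- generate_population(synthetic_spec(n = 60, d = 3, K = 2, seed = 1,
                                           label_noise = 0))
  expect_error(partition_dirichlet(ds, 4, 1, seed = 1, min_per_client = 50),
               "too small")
  # with alpha this small each class collapses onto one client, so one of
  # three clients is always starved: resampling cannot help
  expect_error(partition_dirichlet(ds, 3, 1e-4, seed = 1,
                                   min_per_client = 10, max_retries = 5),
               "alpha")
})

test_that("train/test split partitions each client and is seed-stable", {
  ds <- generate_population(synthetic_spec(n = 600, d = 4, K = 2, seed = 9))
  p <- partition_dirichlet(ds, 3, 1, seed = 4)
  sp <- split_train_test(p, ds, test_fraction = 0.2, seed = 8)
  for (i in 1:3) {
    tr <- sp$train$client_rows[[i]]
    te <- sp$test$client_rows[[i]]
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), p$client_rows[[i]])
    # 20% of the client, within one row per label stratum
    expect_lt(abs(length(te) / length(p$client_rows[[i]]) - 0.2), 0.05)
  }
  sp2 <- split_train_test(p, ds, test_fraction = 0.2, seed = 8)
  expect_identical(sp, sp2)
  sp3 <- split_train_test(p, ds, test_fraction = 0.2, seed = 9)
  expect_false(identical(sp$test$client_rows[[1]], sp3$test$client_rows[[1]]))
})

test_that("an 80/20 split of a 100-row client yields 80 train and 20 test", {
  X <- matrix(rnorm(200), 100, 2)
  ds <- tabular_dataset(X, rep(0:1, 50))
  p <- structure(list(client_rows = list(1:100), n_clients = 1L,
                      alpha = 1, seed = 1L),
                 class = "federated_partition")
  sp <- split_train_test(p, ds, test_fraction = 0.2, seed = 1)
  expect_length(sp$train$client_rows[[1]], 80)
  expect_length(sp$test$client_rows[[1]], 20)
})

test_that("groupings realize each fairness level", {
  X <- matrix(rnorm(24), 12, 2)
  labels <- rep(0:1, 6)
  # client 1 (rows 1-4) holds only sex = 0, so the client-1 x sex-1 cell is
  # empty; client 2 holds both sexes
  sex <- c(rep(0L, 6), rep(1L, 6))
  ds <- tabular_dataset(X, labels, list(sex = sex, outcome = labels))
  p <- structure(list(client_rows = list(1:4, 5:12), n_clients = 2L,
                      alpha = 1, seed = 1L),
                 class = "federated_partition")

  gc <- build_grouping(ds, p, "client")
  expect_equal(gc$n_groups, 2)
  expect_equal(gc$group_of_row, c(rep(1L, 4), rep(2L, 8)))

  # attribute grouping on the outcome column of a binary dataset: 2 groups
  ga <- build_grouping(ds, p, "attribute", "outcome")
  expect_equal(ga$n_groups, 2)
  expect_equal(ga$group_of_row, labels + 1L)

  gm <- build_grouping(ds, p, "multilevel", "sex")
  expect_equal(gm$client_group_of_row, gc$group_of_row)
  expect_equal(gm$n_attribute_groups, 2)

  # client 1 holds only sex = 0: one empty cell, compacted to 3 groups
  gu <- build_grouping(ds, p, "agnostic", "sex")
  expect_equal(gu$n_groups, 3)
  expect_equal(sum(gu$group_sizes), 12)
  # oracle: direct cross-tabulation of occupied cells
  tab <- table(client = c(rep(1, 4), rep(2, 8)), sex = sex)
  expect_equal(sum(tab > 0), 3)
  expect_setequal(gu$group_sizes, as.vector(tab[tab > 0]))

  expect_error(build_grouping(ds, p, "attribute", "race"), "unknown")
  expect_error(build_grouping(ds, p, "attribute"), "required")
})

test_that("agnostic group sizes equal the contingency table on random data", {
  for (s in 1:5) {
    bm <- tiny_benchmark(seed = s, n = 300, n_clients = 3)
    g <- build_grouping(bm$dataset, bm$train, "agnostic", "sex")
    # brute-force recount
    rows <- sort(unlist(bm$train$client_rows))
    client <- rep(NA_integer_, bm$dataset$n)
    for (i in 1:3) client[bm$train$client_rows[[i]]] <- i
    tab <- table(client[rows], bm$dataset$attributes$sex[rows])
    expect_setequal(g$group_sizes, as.vector(tab[tab > 0]))
    expect_equal(g$n_groups, sum(tab > 0))
  }
})

test_that("csv round trip preserves data and encodings", {
  bm <- tiny_benchmark(seed = 4, n = 120)
  dir <- withr::local_tempdir()
  write_benchmark(bm, dir)
  ds2 <- read_tabular_csv(file.path(dir, "data.csv"), label_col = "label",
                          attribute_cols = "sex")
  expect_equal(ds2$labels, bm$dataset$labels)
  expect_equal(ds2$attributes$sex, bm$dataset$attributes$sex)
  expect_equal(unname(ds2$features), unname(bm$dataset$features),
               tolerance = 1e-12)
})
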