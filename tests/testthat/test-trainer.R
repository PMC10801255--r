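fast_sched <- function(R = 3, E = 5, ...) {
  training_schedule(R = R, E = E, eta = 0.05, gamma = 1, batch_size = 16,
                    optimizer = "sgd", hidden_width = 16,
                    checkpoint_every = 1, ...)
}

test_that("local updates never read other clients' rows", {
  bm <- tiny_benchmark(seed = 5, n = 300, n_clients = 3, alpha = 1)
  ds <- bm$dataset
  sched <- fast_sched()
  # corrupt every row outside client 1; an isolated update cannot change
  rows1 <- bm$train$client_rows[[1]]
  X_bad <- ds$features
  X_bad[-rows1, ] <- NaN
  cl_clean <- fedufo:::client_view(ds, rows1)
  ds_bad <- ds; ds_bad$features <- X_bad
  cl_bad <- fedufo:::client_view(ds_bad, rows1)
  state <- init_predictor(ds$d, 16, 2, seed = 5)
  w <- list(lambda_client = rep(1 / 3, 3), lambda_attribute = NULL,
            client_index = 1L, level = "client", rescale = TRUE)
  a <- local_update(cl_clean, state, w, sched, beta = 1, seed = 5, round = 0)
  b <- local_update(cl_bad, state, w, sched, beta = 1, seed = 5, round = 0)
  expect_identical(a$state$theta, b$state$theta)
  expect_identical(a$v_client, b$v_client)
})

test_that("snapshot losses are computed on the broadcast model", {
  bm <- tiny_benchmark(seed = 8, n = 300, n_clients = 2, alpha = 1)
  cl <- fedufo:::client_view(bm$dataset, bm$train$client_rows[[1]])
  state <- init_predictor(bm$dataset$d, 16, 2, seed = 8)
  w <- list(lambda_client = c(0.5, 0.5), lambda_attribute = NULL,
            client_index = 1L, level = "client", rescale = TRUE)
  v <- vapply(c(0L, 1L, 5L), function(E) {
    local_update(cl, state, w, fast_sched(E = E), beta = 1,
                 seed = 8, round = 0)$v_client
  }, 0)
  expect_equal(v[1], v[2])
  expect_equal(v[1], v[3])
  # E = 0 leaves the model untouched
  res0 <- local_update(cl, state, w, fast_sched(E = 0), beta = 1,
                       seed = 8, round = 0)
  expect_identical(res0$state$theta, state$theta)
})

test_that("beta endpoints select the pure client / attribute paths", {
  bm <- tiny_benchmark(seed = 12, n = 300, n_clients = 2, alpha = 1)
  sched <- fast_sched(R = 2)
  r_client <- run_fedufo(bm, uncertainty_set_spec("client", 0.2),
                         sched, seed = 12)
  r_beta1 <- run_fedufo(bm, uncertainty_set_spec("multilevel", 0.2,
                                                 beta = 1), sched, seed = 12)
  expect_equal(r_beta1$final_state$theta, r_client$final_state$theta,
               tolerance = 1e-12)
  r_attr <- run_fedufo(bm, uncertainty_set_spec("attribute", 0.2),
                       sched, seed = 12)
  r_beta0 <- run_fedufo(bm, uncertainty_set_spec("multilevel", 0.2,
                                                 beta = 0), sched, seed = 12)
  expect_equal(r_beta0$final_state$theta, r_attr$final_state$theta,
               tolerance = 1e-12)
})

test_that("aggregation is the parameter-wise mean", {
  s <- init_predictor(3, 4, 2, seed = 1)
  expect_equal(aggregate_models(list(s, s))$theta, s$theta)
  neg <- s
  for (nm in names(neg$theta)) neg$theta[[nm]] <- -neg$theta[[nm]]
  agg <- aggregate_models(list(s, neg))
  expect_true(all(vapply(agg$theta, function(p) all(abs(p) < 1e-15), TRUE)))
  set.seed(2)
  trio <- lapply(1:3, function(i) init_predictor(3, 4, 2, seed = i))
  agg3 <- aggregate_models(trio)
  for (nm in names(agg3$theta)) {
    manual <- (trio[[1]]$theta[[nm]] + trio[[2]]$theta[[nm]] +
                 trio[[3]]$theta[[nm]]) / 3
    expect_equal(agg3$theta[[nm]], manual, tolerance = 1e-15)
  }
  mismatched <- init_predictor(4, 4, 2, seed = 9)
  expect_error(aggregate_models(list(s, mismatched)), "mismatch")
})

test_that("server weight update composes ascent and projection", {
  w <- list(lambda_client = rep(0.25, 4),
            lambda_attribute = c(0.5, 0.5))
  # equal losses leave both vectors unchanged
  same <- server_update_weights(w, rep(0.7, 4), matrix(0.3, 4, 2),
                                gamma = 2, E = 5, rho = 0.5)
  expect_equal(same$lambda_client, w$lambda_client)
  expect_equal(same$lambda_attribute, w$lambda_attribute)
  # gamma = 0 is a no-op
  frozen <- server_update_weights(w, runif(4), matrix(runif(8), 4, 2),
                                  gamma = 0, E = 5, rho = 0.5)
  expect_equal(frozen$lambda_client, w$lambda_client)
  # random inputs match composing the two primitive operations
  set.seed(21)
  vc <- runif(4); va <- matrix(runif(8), 4, 2)
  va[2, 1] <- NA  # an empty client/attribute cell contributes zero
  got <- server_update_weights(w, vc, va, gamma = 1.5, E = 3, rho = 4)
  expect_equal(got$lambda_client,
               project_weights(
                 exponentiated_update(w$lambda_client, vc, 1.5, 3), 4))
  expect_equal(got$lambda_attribute,
               project_weights(
                 exponentiated_update(w$lambda_attribute,
                                      colSums(va, na.rm = TRUE), 1.5, 3), 4))
  va[, 2] <- NA
  expect_error(server_update_weights(w, vc, va, 1, 5, 0.5), "no reporting")
})

test_that("weights remain feasible after every round at every level", {
  bm <- tiny_benchmark(seed = 14, n = 300, n_clients = 3, alpha = 0.5)
  sched <- fast_sched(R = 4)
  for (level in c("client", "attribute", "multilevel", "agnostic")) {
    run <- run_fedufo(bm, uncertainty_set_spec(level, 0.2, beta = 0.5),
                      sched, seed = 14)
    for (wh in run$weights_history) {
      expect_lt(abs(sum(wh$lambda_client) - 1), 1e-9)
      expect_lte(chisq_divergence_oracle(wh$lambda_client), 0.2 + 1e-7)
      if (!is.null(wh$lambda_attribute)) {
        expect_lt(abs(sum(wh$lambda_attribute) - 1), 1e-9)
        expect_lte(chisq_divergence_oracle(wh$lambda_attribute), 0.2 + 1e-7)
      }
    }
  }
})

test_that("local training is isolated and centralized matches its oracle", {
  bm <- tiny_benchmark(seed = 4, n = 240, n_clients = 2, alpha = 1)
  sched <- fast_sched(R = 2)
  loc <- run_local(bm, sched, seed = 4)
  expect_length(loc, 2)
  # centralized trace equals a direct pooled-training loop with the same
  # pre-drawn batches
  cen <- run_centralized(bm, sched, seed = 4)
  rows <- sort(unlist(bm$train$client_rows))
  batches <- fedufo:::with_seed(
    fedufo:::substream_seed(4, "central_batches"),
    matrix(rows[sample.int(length(rows), 10 * 16, replace = TRUE)], 10, 16))
  state <- init_predictor(bm$dataset$d, 16, 2, seed = 4)
  losses <- numeric(10)
  for (t in 1:10) {
    b <- batches[t, ]
    lg <- weighted_loss_grad(state, bm$dataset$features[b, , drop = FALSE],
                             bm$dataset$labels[b], rep(1, 16))
    state <- apply_update(state, lg$gradient, 0.05, "sgd")
    losses[t] <- lg$loss
  }
  expect_equal(cen$trace$loss, losses, tolerance = 1e-15)
  expect_identical(cen$final_state$theta, state$theta)
})

test_that("checkpoint selection minimizes pooled training loss", {
  bm <- tiny_benchmark(seed = 19, n = 240, n_clients = 2, alpha = 1)
  run <- run_fedavg(bm, fast_sched(R = 4), seed = 19)
  expect_length(run$checkpoints, 4)
  sel <- select_checkpoint(run, bm)
  rows <- sort(unlist(bm$train$client_rows))
  losses <- vapply(run$checkpoints, function(cp) {
    mean_loss(cp$state, bm$dataset$features[rows, , drop = FALSE],
              bm$dataset$labels[rows])
  }, 0)
  expect_equal(attr(sel, "checkpoint_round"),
               run$checkpoints[[which.min(losses)]]$round)
  single <- run; single$checkpoints <- run$checkpoints[2]
  expect_equal(attr(select_checkpoint(single, bm), "checkpoint_round"),
               run$checkpoints[[2]]$round)
})

test_that("round bookkeeping matches the schedule", {
  bm <- tiny_benchmark(seed = 22, n = 240, n_clients = 2, alpha = 1)
  sched <- training_schedule(R = 6, E = 2, eta = 0.05, gamma = 1,
                             batch_size = 8, optimizer = "sgd",
                             hidden_width = 8, checkpoint_every = 2)
  run <- run_fedufo(bm, uncertainty_set_spec("client", 0.1), sched, seed = 2)
  expect_equal(nrow(run$trace), 6 * 2)    # R rounds x N clients
  expect_length(run$weights_history, 6)   # one weight update per round
  expect_length(run$checkpoints, 3)       # floor(R / checkpoint_every)
})

test_that("agnostic evaluation is deterministic and recounts correctly", {
  bm <- tiny_benchmark(seed = 25, n = 400, n_clients = 2, alpha = 1)
  run <- run_fedavg(bm, fast_sched(R = 2), seed = 25)
  m1 <- agnostic_evaluate(run$final_state, bm, alpha_eval = 0.5, seed = 7)
  m2 <- agnostic_evaluate(run$final_state, bm, alpha_eval = 0.5, seed = 7)
  expect_identical(m1, m2)
  # recount oracle: rebuild the repartition and recount client accuracies
  test_rows <- sort(unlist(bm$test$client_rows))
  ds <- bm$dataset
  sub <- tabular_dataset(ds$features[test_rows, , drop = FALSE],
                         ds$labels[test_rows],
                         lapply(ds$attributes, `[`, test_rows))
  part <- partition_dirichlet(sub, 2, 0.5, seed = 7)
  pred <- predict_class(run$final_state, sub$features)
  accs <- vapply(part$client_rows, function(rows) {
    mean(pred[rows] == sub$labels[rows])
  }, 0)
  expect_equal(unname(m1$client_accuracy), unname(accs))
  expect_equal(m1$overall_acc, mean(pred == sub$labels))
})
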