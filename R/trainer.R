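#' Federated training schedule
#'
#' @param R number of communication rounds.
#' @param E local minibatch iterations per round (an epochs-style count can
#'   be converted via `epochs * ceiling(n_client / batch_size)`).
#' @param eta model stepsize.
#' @param gamma weight (mirror-ascent) stepsize.
#' @param batch_size minibatch size (default 32).
#' @param optimizer `"sgd"` or `"adam"`.
#' @param hidden_width backbone hidden width (default 64).
#' @param checkpoint_every store a checkpoint every this many rounds
#'   (default 5).
#' @return list of class `training_schedule`; total iterations T = R * E.
#' @export
training_schedule <- function(R = 10L, E = 5L, eta = 0.01, gamma = 1,
                              batch_size = 32L, optimizer = c("sgd", "adam"),
                              hidden_width = 64L, checkpoint_every = 5L) {
  optimizer <- match.arg(optimizer)
  stopifnot(R >= 1, E >= 0, eta > 0, gamma >= 0, batch_size >= 1,
            hidden_width >= 1, checkpoint_every >= 1)
  structure(list(R = as.integer(R), E = as.integer(E), eta = eta,
                 gamma = gamma, batch_size = as.integer(batch_size),
                 optimizer = optimizer, hidden_width = as.integer(hidden_width),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "training_schedule")
}

# Bundle one client's view of the training data. Holding only the client's
# own rows makes data isolation structural: a local update cannot read any
# other client's data.
client_view <- function(dataset, rows, attr_group_of_row = NULL,
                        cell_group_of_row = NULL) {
  list(features = dataset$features[rows, , drop = FALSE],
       labels = dataset$labels[rows],
       attr_group = if (!is.null(attr_group_of_row))
         attr_group_of_row[rows] else NULL,
       cell_group = if (!is.null(cell_group_of_row))
         cell_group_of_row[rows] else NULL,
       n = length(rows))
}

#' One client's local update for a communication round
#'
#' Runs `schedule$E` weighted descent iterations from the broadcast model.
#' Each sampled row's multiplier is its client weight with probability
#' `beta`, else its attribute-group weight (a Bernoulli drawn per row per
#' iteration on a dedicated substream). The reported loss signals are
#' computed on the SNAPSHOT (broadcast) model, not the locally updated one:
#' `v_client` on the client's full local set, `v_attr[k]` on the client's
#' rows in attribute group k (NA when the client holds no such rows).
#'
#' @param client a client data bundle (features, labels, optional
#'   `attr_group` / `cell_group` maps) as built by the federated drivers.
#' @param global_state the broadcast `predictor_state`.
#' @param weights list with `lambda_client` (simplex over clients),
#'   `lambda_attribute` (simplex over attribute groups or NULL),
#'   `client_index`, `level`, and `rescale` (logical: multiply weights by the
#'   group count so uniform weights give multiplier 1).
#' @param schedule a [training_schedule()].
#' @param beta client-vs-attribute mixing probability in [0, 1].
#' @param seed master seed; @param round 0-based round index (the two fan
#'   out to per-(round, client) batch and mixing substreams).
#' @return list: `state` (updated local model), `v_client` (scalar),
#'   `v_attr` (vector over attribute groups, NA for empty cells; NULL when
#'   no attribute weighting is in play).
#' @export
local_update <- function(client, global_state, weights, schedule, beta,
                         seed, round) {
  if (client$n < 1L) stop("empty client")
  i <- weights$client_index
  E <- schedule$E
  bs <- schedule$batch_size
  state <- global_state
  state$optimizer_state <- list()  # fresh local optimizer accumulators
  level <- weights$level
  N <- length(weights$lambda_client)
  sN <- if (weights$rescale) N else 1
  M <- if (!is.null(weights$lambda_attribute))
    length(weights$lambda_attribute) else 0L
  sM <- if (weights$rescale && M > 0) M else 1

  if (E > 0) {
    batches <- with_seed(
      substream_seed(seed, sprintf("batch_r%d_c%d", round, i)),
      matrix(sample.int(client$n, E * bs, replace = TRUE), E, bs))
    mix <- if (level == "multilevel") {
      with_seed(substream_seed(seed, sprintf("mix_r%d_c%d", round, i)),
                matrix(stats::runif(E * bs), E, bs))
    } else NULL
    for (t in seq_len(E)) {
      b <- batches[t, ]
      w <- switch(level,
        client = rep(sN * weights$lambda_client[i], bs),
        attribute = sM * weights$lambda_attribute[client$attr_group[b]],
        multilevel = ifelse(
          mix[t, ] < beta,
          sN * weights$lambda_client[i],
          sM * weights$lambda_attribute[client$attr_group[b]]),
        agnostic = sN * weights$lambda_client[client$cell_group[b]]
      )
      lg <- weighted_loss_grad(state, client$features[b, , drop = FALSE],
                               client$labels[b], w)
      state <- apply_update(state, lg$gradient, schedule$eta,
                            schedule$optimizer)
    }
  }

  # snapshot losses on the broadcast model
  v_client <- mean_loss(global_state, client$features, client$labels)
  v_attr <- NULL
  snap_group <- if (level == "agnostic") client$cell_group else client$attr_group
  snap_M <- if (level == "agnostic") N else M
  if (!is.null(snap_group)) {
    v_attr <- rep(NA_real_, snap_M)
    for (k in unique(snap_group)) {
      sel <- snap_group == k
      v_attr[k] <- mean_loss(global_state,
                             client$features[sel, , drop = FALSE],
                             client$labels[sel])
    }
  }
  list(state = state, v_client = v_client, v_attr = v_attr)
}

#' Aggregate local models
#'
#' Parameter-wise mean of the clients' local models. The default is the
#' unweighted mean over clients; `sizes` enables the conventional
#' sample-size-weighted variant.
#'
#' @param local_states list of `predictor_state` with identical shapes.
#' @param sizes optional client sample sizes for size-weighted averaging.
#' @return the aggregated `predictor_state` (optimizer accumulators cleared).
#' @export
aggregate_models <- function(local_states, sizes = NULL) {
  stopifnot(length(local_states) >= 1)
  ref <- local_states[[1]]
  w <- if (is.null(sizes)) rep(1, length(local_states)) else sizes
  w <- w / sum(w)
  for (s in local_states[-1]) {
    for (nm in names(ref$theta)) {
      if (!identical(dim(ref$theta[[nm]]), dim(s$theta[[nm]])) ||
          length(ref$theta[[nm]]) != length(s$theta[[nm]])) {
        stop("parameter shape mismatch in ", nm)
      }
    }
  }
  out <- ref
  for (nm in names(ref$theta)) {
    acc <- ref$theta[[nm]] * w[1]
    for (j in seq_along(local_states)[-1]) {
      acc <- acc + local_states[[j]]$theta[[nm]] * w[j]
    }
    out$theta[[nm]] <- acc
  }
  out$optimizer_state <- list()
  out
}

#' Server-side weight update
#'
#' Client weights: exponentiated update on the client snapshot losses with
#' exponent gamma * E, then projection into the chi-square ball of radius
#' rho. Attribute weights: the same update on the column SUMS of the
#' client-by-attribute snapshot-loss matrix (missing cells contribute 0 to
#' the sum).
#'
#' @param weights list with `lambda_client` and optionally
#'   `lambda_attribute`.
#' @param v_client numeric vector of client snapshot losses (length N).
#' @param v_attr_by_client N x M matrix of per-(client, attribute) snapshot
#'   losses, NA for empty cells; NULL when no attribute weights are kept.
#' @param gamma weight stepsize; @param E local iterations (exponent scale);
#' @param rho ball radius.
#' @return the updated weights list.
#' @export
server_update_weights <- function(weights, v_client, v_attr_by_client,
                                  gamma, E, rho) {
  weights$lambda_client <- project_weights(
    exponentiated_update(weights$lambda_client, v_client, gamma, E), rho)
  if (!is.null(weights$lambda_attribute)) {
    if (is.null(v_attr_by_client)) stop("attribute losses missing")
    col_ok <- colSums(!is.na(v_attr_by_client)) > 0
    if (any(!col_ok)) {
      stop("attribute group(s) with no reporting client: ",
           paste(which(!col_ok), collapse = ", "))
    }
    v_sum <- colSums(v_attr_by_client, na.rm = TRUE)
    weights$lambda_attribute <- project_weights(
      exponentiated_update(weights$lambda_attribute, v_sum, gamma, E), rho)
  }
  weights
}

# shared round loop for FedUFO and FedAvg (FedAvg = frozen uniform weights
# through the identical arithmetic, so the rho = 0 degeneration is exact)
fed_loop <- function(benchmark, spec, schedule, seed, rescale_weights,
                     size_weighted_agg, freeze_weights, method) {
  level <- spec$level
  ds <- benchmark$dataset
  train <- benchmark$train
  N <- train$n_clients
  grp <- benchmark$groupings[[level]]
  attr_map <- switch(level,
    client = NULL,
    attribute = grp$group_of_row,
    multilevel = grp$attribute_group_of_row,
    agnostic = NULL)
  cell_map <- if (level == "agnostic") grp$group_of_row else NULL
  M <- if (!is.null(attr_map)) max(attr_map, na.rm = TRUE) else 0L
  beta <- switch(level, client = 1, attribute = 0,
                 multilevel = spec$beta, agnostic = 1)
  n_primary <- if (level == "agnostic") grp$n_groups else N

  clients <- lapply(seq_len(N), function(i) {
    client_view(ds, train$client_rows[[i]], attr_map, cell_map)
  })
  sizes <- vapply(clients, `[[`, 1L, "n")

  state <- init_predictor(ds$d, schedule$hidden_width, ds$n_classes,
                          seed = seed)
  weights <- list(
    lambda_client = rep(1 / n_primary, n_primary),
    lambda_attribute = if (level %in% c("attribute", "multilevel"))
      rep(1 / M, M) else NULL,
    client_index = NA_integer_, level = level, rescale = rescale_weights
  )
  checkpoints <- list()
  weights_history <- list()
  trace <- vector("list", schedule$R)

  for (r in seq_len(schedule$R) - 1L) {
    locals <- vector("list", N)
    v_client <- numeric(N)
    v_attr <- if (!is.null(attr_map) || level == "agnostic") {
      matrix(NA_real_, N, if (level == "agnostic") grp$n_groups else M)
    } else NULL
    for (i in seq_len(N)) {
      w_i <- weights
      w_i$client_index <- i
      res <- local_update(clients[[i]], state, w_i, schedule, beta, seed, r)
      locals[[i]] <- res$state
      v_client[i] <- res$v_client
      if (!is.null(res$v_attr)) v_attr[i, ] <- res$v_attr
    }
    state <- aggregate_models(locals,
                              sizes = if (size_weighted_agg) sizes else NULL)
    if (!freeze_weights) {
      if (level == "agnostic") {
        # each cell is owned by exactly one client; the column sum over
        # clients is that owner's snapshot loss
        weights$lambda_client <- project_weights(
          exponentiated_update(weights$lambda_client,
                               colSums(v_attr, na.rm = TRUE),
                               schedule$gamma, schedule$E), spec$rho)
      } else if (level == "attribute") {
        weights <- server_update_weights(
          list(lambda_client = weights$lambda_client * 0 + 1 / N,
               lambda_attribute = weights$lambda_attribute),
          v_client * 0, v_attr, schedule$gamma, schedule$E, spec$rho)
        weights$level <- level; weights$rescale <- rescale_weights
      } else {
        lvl <- weights$level; rsc <- weights$rescale
        weights <- server_update_weights(weights, v_client, v_attr,
                                         schedule$gamma, schedule$E,
                                         spec$rho)
        weights$level <- lvl; weights$rescale <- rsc
      }
    }
    weights_history[[r + 1L]] <- weights[c("lambda_client",
                                           "lambda_attribute")]
    trace[[r + 1L]] <- data.frame(
      round = r + 1L, client = seq_len(N), snapshot_loss = v_client)
    if ((r + 1L) %% schedule$checkpoint_every == 0L) {
      checkpoints[[length(checkpoints) + 1L]] <-
        list(round = r + 1L, state = state)
    }
  }
  if (length(checkpoints) == 0L) {
    checkpoints[[1L]] <- list(round = schedule$R, state = state)
  }
  structure(
    list(final_state = state, checkpoints = checkpoints,
         weights_history = weights_history,
         trace = do.call(rbind, trace),
         config = list(spec = if (inherits(spec, "uncertainty_set_spec"))
                         unclass(spec) else spec,
                       schedule = unclass(schedule),
                       rescale_weights = rescale_weights,
                       size_weighted_agg = size_weighted_agg,
                       method = method),
         seed = as.integer(seed), method = method),
    class = "federated_run_result"
  )
}

#' Train with the unified fair federated algorithm
#'
#' R rounds of broadcast -> parallel local updates -> model aggregation ->
#' server weight update. The fairness level of `spec` selects which weight
#' vectors are maintained: client level uses only client weights (beta
#' forced to 1), attribute level only attribute weights (beta = 0),
#' multilevel both mixed by `spec$beta`, and agnostic a single weight vector
#' over the occupied client-by-attribute cells.
#'
#' @param benchmark a [make_benchmark()] result (or equivalent bundle with
#'   `dataset`, `train`, `groupings`).
#' @param spec an [uncertainty_set_spec()].
#' @param schedule a [training_schedule()].
#' @param seed integer master seed.
#' @param rescale_weights multiply per-sample weights by the group count so
#'   uniform weights reproduce FedAvg at the same stepsize (default TRUE);
#'   FALSE applies the raw lambda multiplier.
#' @param size_weighted_agg weight the aggregation by client sample sizes
#'   (default FALSE: plain unweighted mean over clients).
#' @return A `federated_run_result`: `final_state`, `checkpoints`,
#'   `weights_history`, per-round `trace`, `config`, `seed`.
#' @export
run_fedufo <- function(benchmark, spec, schedule, seed = 1L,
                       rescale_weights = TRUE, size_weighted_agg = FALSE) {
  stopifnot(inherits(spec, "uncertainty_set_spec"))
  fed_loop(benchmark, spec, schedule, seed, rescale_weights,
           size_weighted_agg, freeze_weights = FALSE, method = "fedufo")
}

#' FedAvg baseline
#'
#' Standard federated averaging: the identical round loop with the group
#' weights frozen at uniform (so every sample multiplier is 1 under the
#' default rescaling).
#'
#' @inheritParams run_fedufo
#' @return A `federated_run_result`.
#' @export
run_fedavg <- function(benchmark, schedule, seed = 1L,
                       rescale_weights = TRUE, size_weighted_agg = FALSE) {
  spec <- uncertainty_set_spec("client", rho = 0)
  fed_loop(benchmark, spec, schedule, seed, rescale_weights,
           size_weighted_agg, freeze_weights = TRUE, method = "fedavg")
}

#' Local-only baseline
#'
#' Trains one model per client on that client's own training rows for
#' R * E iterations with no communication.
#'
#' @inheritParams run_fedufo
#' @return list of per-client `federated_run_result`-shaped lists (fields
#'   `final_state`, `checkpoints`, `seed`).
#' @export
run_local <- function(benchmark, schedule, seed = 1L) {
  ds <- benchmark$dataset
  train <- benchmark$train
  lapply(seq_len(train$n_clients), function(i) {
    rows <- train$client_rows[[i]]
    cl <- client_view(ds, rows)
    state <- init_predictor(ds$d, schedule$hidden_width, ds$n_classes,
                            seed = seed)
    weights <- list(lambda_client = 1, lambda_attribute = NULL,
                    client_index = 1L, level = "client", rescale = TRUE)
    checkpoints <- list()
    for (r in seq_len(schedule$R) - 1L) {
      res <- local_update(cl, state, weights, schedule, beta = 1,
                          seed = substream_seed(seed, paste0("local", i)),
                          round = r)
      state <- res$state
      if ((r + 1L) %% schedule$checkpoint_every == 0L) {
        checkpoints[[length(checkpoints) + 1L]] <-
          list(round = r + 1L, state = state)
      }
    }
    if (!length(checkpoints)) {
      checkpoints[[1L]] <- list(round = schedule$R, state = state)
    }
    list(final_state = state, checkpoints = checkpoints,
         client = i, seed = as.integer(seed), method = "local")
  })
}

#' Centralized (pooled) baseline
#'
#' Plain training on the union of all clients' training rows for R * E
#' iterations; the upper envelope a federated method is compared against.
#'
#' @inheritParams run_fedufo
#' @return A `federated_run_result`-shaped list with a per-iteration loss
#'   trace.
#' @export
run_centralized <- function(benchmark, schedule, seed = 1L) {
  ds <- benchmark$dataset
  rows <- sort(unlist(benchmark$train$client_rows))
  state <- init_predictor(ds$d, schedule$hidden_width, ds$n_classes,
                          seed = seed)
  Tn <- schedule$R * schedule$E
  bs <- schedule$batch_size
  batches <- with_seed(substream_seed(seed, "central_batches"), {
    matrix(rows[sample.int(length(rows), Tn * bs, replace = TRUE)], Tn, bs)
  })
  loss_trace <- numeric(Tn)
  checkpoints <- list()
  for (t in seq_len(Tn)) {
    b <- batches[t, ]
    lg <- weighted_loss_grad(state, ds$features[b, , drop = FALSE],
                             ds$labels[b], rep(1, bs))
    state <- apply_update(state, lg$gradient, schedule$eta,
                          schedule$optimizer)
    loss_trace[t] <- lg$loss
    if (t %% (schedule$E * schedule$checkpoint_every) == 0L) {
      checkpoints[[length(checkpoints) + 1L]] <-
        list(round = t %/% schedule$E, state = state)
    }
  }
  if (!length(checkpoints)) {
    checkpoints[[1L]] <- list(round = schedule$R, state = state)
  }
  list(final_state = state, checkpoints = checkpoints,
       trace = data.frame(iteration = seq_len(Tn), loss = loss_trace),
       seed = as.integer(seed), method = "centralized")
}

#' Select the evaluation checkpoint by pooled training loss
#'
#' Restores each stored checkpoint and returns the one minimizing the total
#' (pooled mean) cross-entropy on all clients' training rows; ties go to the
#' earliest checkpoint.
#'
#' @param result a `federated_run_result` (or a run with `checkpoints`).
#' @param benchmark the benchmark the run trained on.
#' @return the selected `predictor_state`, with attribute
#'   `"checkpoint_round"`.
#' @export
select_checkpoint <- function(result, benchmark) {
  cps <- result$checkpoints
  if (!length(cps)) stop("no checkpoints stored")
  rows <- sort(unlist(benchmark$train$client_rows))
  ds <- benchmark$dataset
  losses <- vapply(cps, function(cp) {
    mean_loss(cp$state, ds$features[rows, , drop = FALSE], ds$labels[rows])
  }, 0)
  best <- which.min(losses)  # which.min returns the earliest minimum
  out <- cps[[best]]$state
  attr(out, "checkpoint_round") <- cps[[best]]$round
  out
}
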