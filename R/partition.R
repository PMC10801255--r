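#' Dirichlet (non-IID) partition of a dataset across simulated clients
#'
#' Splits rows across `n_clients` clients with label-distribution
#' heterogeneity controlled by a symmetric Dirichlet concentration `alpha`
#' (the LDA-style partition standard in the federated-learning literature).
#' For each class a proportion vector over clients is drawn from
#' Dirichlet(alpha, ..., alpha) and that class's rows are allocated to clients
#' by largest-remainder rounding. Small `alpha` gives strongly skewed client
#' label distributions; very large `alpha` approaches an even split.
#'
#' If any client would receive fewer than `min_per_client` rows the draw is
#' resampled (up to `max_retries` times) so that per-client group weights stay
#' well defined.
#'
#' @param dataset a [tabular_dataset()].
#' @param n_clients number of clients, >= 1.
#' @param alpha positive Dirichlet concentration.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @param min_per_client minimum rows any client may hold (default 2).
#' @param max_retries resampling budget before giving up (default 100).
#' @return An object of class `federated_partition` with fields
#'   `client_rows` (list of disjoint 1-based row-index vectors), `n_clients`,
#'   `alpha`, `seed`.
#' @export
partition_dirichlet <- function(dataset, n_clients, alpha, seed,
                                min_per_client = 2L, max_retries = 100L) {
  stopifnot(inherits(dataset, "tabular_dataset"))
  n_clients <- as.integer(n_clients)
  if (n_clients < 1L) stop("n_clients must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
  if (dataset$n < n_clients * min_per_client) {
    stop("dataset too small: ", dataset$n, " rows for ", n_clients,
         " clients at min_per_client=", min_per_client)
  }
  classes <- sort(unique(dataset$labels))
  client_rows <- with_seed(substream_seed(seed, "partition"), {
    result <- NULL
    for (attempt in seq_len(max_retries)) {
      rows <- vector("list", n_clients)
      for (k in classes) {
        idx <- which(dataset$labels == k)
        idx <- idx[sample.int(length(idx))]
        # symmetric Dirichlet draw via normalized gammas
        g <- stats::rgamma(n_clients, shape = alpha, rate = 1)
        if (all(g == 0)) {
          # numeric underflow at very small alpha: the Dirichlet limit is a
          # point mass on one uniformly chosen client
          g <- as.numeric(seq_len(n_clients) == sample.int(n_clients, 1))
        }
        counts <- largest_remainder(length(idx), g / sum(g))
        splits <- rep(seq_len(n_clients), counts)
        for (i in seq_len(n_clients)) {
          rows[[i]] <- c(rows[[i]], idx[splits == i])
        }
      }
      if (all(vapply(rows, length, 1L) >= min_per_client)) {
        result <- lapply(rows, sort)
        break
      }
    }
    if (is.null(result)) {
      stop("could not satisfy min_per_client=", min_per_client, " for ",
           n_clients, " clients with alpha=", alpha, " after ", max_retries,
           " retries (client sizes: ",
           paste(vapply(rows, length, 1L), collapse = ", "), ")")
    }
    result
  })
  structure(
    list(client_rows = client_rows, n_clients = n_clients,
         alpha = alpha, seed = as.integer(seed)),
    class = "federated_partition"
  )
}

#' @export
print.federated_partition <- function(x, ...) {
  cat(sprintf("<federated_partition> %d clients, alpha=%g, sizes: %s\n",
              x$n_clients, x$alpha,
              paste(vapply(x$client_rows, length, 1L), collapse = ", ")))
  invisible(x)
}

#' Per-client stratified train/test split
#'
#' Splits each client's rows into train and test sets, stratified by label
#' within the client. A client/label cell with fewer than 2 rows falls back
#' to an unstratified split for those rows (a message is emitted).
#'
#' @param partition a [partition_dirichlet()] result.
#' @param dataset the dataset the partition indexes.
#' @param test_fraction fraction held out per client, in (0, 1); default 0.2
#'   (the conventional 80/20 protocol).
#' @param seed integer seed.
#' @return list with `train` and `test`, each a `federated_partition`-shaped
#'   view (same client count, disjoint row sets within each client).
#' @export
split_train_test <- function(partition, dataset, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(partition, "federated_partition"))
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)")
  }
  res <- with_seed(substream_seed(seed, "split"), {
    train <- vector("list", partition$n_clients)
    test <- vector("list", partition$n_clients)
    for (i in seq_len(partition$n_clients)) {
      rows <- partition$client_rows[[i]]
      labs <- dataset$labels[rows]
      tr <- integer(0); te <- integer(0)
      small <- integer(0)
      for (k in unique(labs)) {
        cell <- rows[labs == k]
        if (length(cell) < 2L) {
          small <- c(small, cell)
          next
        }
        n_te <- round(test_fraction * length(cell))
        n_te <- max(0L, min(length(cell), n_te))
        pick <- cell[sample.int(length(cell), n_te)]
        te <- c(te, pick)
        tr <- c(tr, setdiff(cell, pick))
      }
      if (length(small)) {
        message("client ", i, ": ", length(small),
                " row(s) in singleton label cells split unstratified")
        n_te <- round(test_fraction * length(small))
        pick <- if (n_te > 0) small[sample.int(length(small), n_te)] else integer(0)
        te <- c(te, pick)
        tr <- c(tr, setdiff(small, pick))
      }
      train[[i]] <- sort(tr)
      test[[i]] <- sort(te)
    }
    list(train = train, test = test)
  })
  make_view <- function(rows) {
    structure(
      list(client_rows = rows, n_clients = partition$n_clients,
           alpha = partition$alpha, seed = partition$seed),
      class = "federated_partition"
    )
  }
  list(train = make_view(res$train), test = make_view(res$test))
}

#' Build a fairness grouping of rows
#'
#' Maps every row to a group index under one of the four fairness levels:
#' \describe{
#'   \item{client}{groups are the clients themselves (horizontal fairness).}
#'   \item{attribute}{groups are observed value-combinations of the named
#'     attribute columns (vertical fairness).}
#'   \item{multilevel}{both the client map and the attribute map are retained,
#'     for simultaneous client- and attribute-level constraints.}
#'   \item{agnostic}{groups are the occupied (client x attribute-combination)
#'     cells; empty cells are dropped and indices compacted.}
#' }
#'
#' @param dataset a [tabular_dataset()].
#' @param partition a `federated_partition` over the dataset's rows (for the
#'   grouping only the rows it covers are grouped; pass a train view to group
#'   training rows).
#' @param level one of `"client"`, `"attribute"`, `"multilevel"`, `"agnostic"`.
#' @param attribute_columns attribute column names; required unless
#'   `level = "client"`.
#' @return An object of class `grouping_scheme` with 1-based `group_of_row`
#'   (NA for rows outside the partition), `n_groups`, and for multilevel also
#'   `client_group_of_row` / `attribute_group_of_row`.
#' @export
build_grouping <- function(dataset, partition, level,
                           attribute_columns = NULL) {
  stopifnot(inherits(dataset, "tabular_dataset"),
            inherits(partition, "federated_partition"))
  level <- match.arg(level, c("client", "attribute", "multilevel", "agnostic"))
  n <- dataset$n
  covered <- sort(unlist(partition$client_rows))
  client_of_row <- rep(NA_integer_, n)
  for (i in seq_len(partition$n_clients)) {
    client_of_row[partition$client_rows[[i]]] <- i
  }

  attr_of_row <- NULL
  n_attr_groups <- NULL
  attr_labels <- NULL
  if (level != "client") {
    if (is.null(attribute_columns) || length(attribute_columns) == 0) {
      stop("attribute_columns required for level=", level)
    }
    unknown <- setdiff(attribute_columns, names(dataset$attributes))
    if (length(unknown)) {
      stop("unknown attribute column(s): ", paste(unknown, collapse = ", "))
    }
    cols <- dataset$attributes[attribute_columns]
    combo <- do.call(paste, c(cols, list(sep = "\r")))
    # groups are the OBSERVED value-combinations among covered rows, compacted
    observed <- sort(unique(combo[covered]))
    attr_of_row <- match(combo, observed)
    attr_of_row[-covered] <- NA_integer_
    n_attr_groups <- length(observed)
    attr_labels <- gsub("\r", ":", observed, fixed = TRUE)
  }

  out <- switch(level,
    client = list(group_of_row = client_of_row,
                  n_groups = partition$n_clients,
                  group_labels = paste0("client", seq_len(partition$n_clients))),
    attribute = list(group_of_row = attr_of_row,
                     n_groups = n_attr_groups,
                     group_labels = attr_labels),
    multilevel = list(group_of_row = client_of_row,
                      n_groups = partition$n_clients,
                      client_group_of_row = client_of_row,
                      n_client_groups = partition$n_clients,
                      attribute_group_of_row = attr_of_row,
                      n_attribute_groups = n_attr_groups,
                      group_labels = paste0("client",
                                            seq_len(partition$n_clients)),
                      attribute_group_labels = attr_labels),
    agnostic = {
      cell <- ifelse(is.na(client_of_row) | is.na(attr_of_row), NA,
                     paste(client_of_row, attr_of_row, sep = "\r"))
      occupied <- sort(unique(cell[covered]))
      g <- match(cell, occupied)
      list(group_of_row = g, n_groups = length(occupied),
           group_labels = gsub("\r", "x", occupied, fixed = TRUE))
    }
  )
  sizes <- tabulate(out$group_of_row[covered], nbins = out$n_groups)
  if (any(sizes == 0)) {
    stop("grouping at level=", level, " produced an empty group")
  }
  structure(
    c(out, list(level = level,
                source_attributes = attribute_columns,
                group_sizes = sizes)),
    class = "grouping_scheme"
  )
}

#' @export
print.grouping_scheme <- function(x, ...) {
  cat(sprintf("<grouping_scheme> level=%s, %d groups (sizes: %s)\n",
              x$level, x$n_groups, paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' Serialize a partition and grouping to JSON
#'
#' @param partition a `federated_partition`.
#' @param grouping optional `grouping_scheme`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_partition_json <- function(partition, grouping = NULL, path) {
  obj <- list(
    n_clients = partition$n_clients, alpha = partition$alpha,
    seed = partition$seed, client_rows = partition$client_rows
  )
  if (!is.null(grouping)) {
    obj$grouping <- list(level = grouping$level,
                         n_groups = grouping$n_groups,
                         group_of_row = grouping$group_of_row)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
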